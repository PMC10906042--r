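#' Circuit intermediate representation
#'
#' A gate list on a register of qubits.  Qubit 1 is the leftmost (most
#' significant) bit of basis-state labels; in Kraus circuits it is the
#' ancilla.  Supported gates: `X`, `SX` (square root of X), `H`,
#' `RZ` (param = angle), `CNOT` (qubits = c(control, target)),
#' `UNITARY` (param = explicit matrix on the listed qubits, kept opaque
#' for gate metrics) and `MEASURE`.
#'
#' @param n_qubits register size.
#' @param gates list of gates, each `list(name, qubits, param)`.
#' @param roles optional named list tagging qubit roles, e.g.
#'   `list(ancilla = 1L, system = 2:3)`.
#' @param phase tracked global phase (radians): the circuit's unitary
#'   semantics include a factor `exp(1i * phase)`.  Unobservable in
#'   measurement statistics and ignored by gate metrics; tracked so that
#'   composed unitaries are exact (the native RZ/SX/CNOT set cannot
#'   realize arbitrary determinant phases).
#' @return object of class `circuit_ir`.
#' @export
circuit_ir <- function(n_qubits, gates = list(), roles = NULL, phase = 0) {
  structure(list(n_qubits = as.integer(n_qubits), gates = gates,
                 roles = roles, phase = phase),
            class = "circuit_ir")
}

#' Construct a single gate entry for a circuit
#'
#' @param name gate name (`X`, `SX`, `H`, `RZ`, `CNOT`, `UNITARY`,
#'   `MEASURE`).
#' @param qubits target qubit indices (control first for `CNOT`).
#' @param param rotation angle (`RZ`) or explicit matrix (`UNITARY`).
#' @return a gate list usable in [circuit_ir()].
#' @export
gate <- function(name, qubits, param = NULL)
  list(name = name, qubits = as.integer(qubits), param = param)

#' @export
print.circuit_ir <- function(x, ...) {
  m <- circuit_metrics(x)
  cat("<circuit_ir>", x$n_qubits, "qubits,", length(x$gates),
      "gates (depth", m$depth, ",", m$cnot_count, "CNOT)\n")
  invisible(x)
}

## ---- fixed 2 x 2 / 4 x 4 gate matrices ----------------------------------
.g_X <- matrix(c(0, 1, 1, 0), 2, 2)
.g_H <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
.g_SX <- matrix(c(1 + 1i, 1 - 1i, 1 - 1i, 1 + 1i), 2, 2) / 2
.g_RZ <- function(theta) diag(exp(c(-1i, 1i) * theta / 2))
.g_CNOT <- matrix(c(1, 0, 0, 0,  0, 1, 0, 0,
                    0, 0, 0, 1,  0, 0, 1, 0), 4, 4)  # basis (control, target)

gate_matrix <- function(g) {
  switch(g$name,
         X = .g_X, H = .g_H, SX = .g_SX,
         RZ = .g_RZ(g$param),
         CNOT = .g_CNOT,
         UNITARY = g$param,
         MEASURE = NULL,
         stop("unknown gate: ", g$name))
}

#' Composed unitary of a circuit
#'
#' Multiplies out the gate list (MEASURE ignored) into the full
#' 2^n x 2^n unitary, qubit 1 = most significant bit.
#'
#' @param circ a `circuit_ir`.
#' @return complex matrix.
#' @export
circuit_unitary <- function(circ) {
  n <- circ$n_qubits
  U <- diag(2^n) + 0i
  for (g in circ$gates) {
    Gm <- gate_matrix(g)
    if (is.null(Gm)) next
    U <- embed_gate(Gm, g$qubits, n) %*% U
  }
  exp(1i * circ$phase) * U
}

## embed a 2^k gate matrix acting on `qubits` (given most-significant
## first) into the full 2^n space
embed_gate <- function(Gm, qubits, n) {
  k <- length(qubits)
  stopifnot(nrow(Gm) == 2^k)
  N <- 2^n
  bits <- function(idx, q) bitwAnd(bitwShiftR(idx, n - q), 1L)  # idx 0-based
  idx <- 0:(N - 1)
  sub <- integer(N)  # gate-space index of each basis state
  for (j in seq_len(k)) sub <- sub * 2L + bits(idx, qubits[j])
  rest <- idx
  for (j in seq_len(k))
    rest <- rest - bits(idx, qubits[j]) * 2^(n - qubits[j])
  U <- matrix(0i, N, N)
  for (s_in in 0:(2^k - 1)) {
    cols <- which(sub == s_in)           # 1-based positions
    for (s_out in 0:(2^k - 1)) {
      amp <- Gm[s_out + 1, s_in + 1]
      if (amp == 0) next
      out_idx <- rest[cols]
      for (j in seq_len(k))
        out_idx <- out_idx + bitwAnd(bitwShiftR(s_out, k - j), 1L) *
          2^(n - qubits[j])
      U[cbind(out_idx + 1L, cols)] <- amp
    }
  }
  U
}

#' Unitarize a Kraus operator by singular value decomposition
#'
#' Factors `M = U diag(sigma) Vdag` with singular values sorted
#' descending and clamped into `[0, 1]`.  A Kraus operator of a CPTP map
#' is a contraction, so values above `1 + 1e-8` raise an error.
#'
#' @param M d x d matrix (a contraction).
#' @return object of class `svd_factors`: `U`, `sigma`, `Vdag`.
#' @export
svd_unitarize <- function(M) {
  sv <- svd(M)
  if (any(sv$d > 1 + 1e-8))
    stop("operator is not a contraction: max singular value ",
         signif(max(sv$d), 6))
  structure(list(U = sv$u, sigma = pmin(pmax(sv$d, 0), 1),
                 Vdag = Conj(t(sv$v))),
            class = "svd_factors")
}

#' Dilation phases for a singular-value diagonal
#'
#' The nonunitary diagonal `diag(sigma)` is dilated to a diagonal unitary
#' on (ancilla x system) with phases `+acos(sigma_j)` on the ancilla-0
#' branch and `-acos(sigma_j)` on the ancilla-1 branch; conjugating by a
#' Hadamard on the ancilla then places `diag(sigma)` in the ancilla
#' 0 -> 0 block.
#'
#' @param sigma singular values in `[0, 1]`.
#' @return phase vector of length `2 * length(sigma)` (ancilla bit most
#'   significant).
#' @export
dilation_phases <- function(sigma) {
  if (any(sigma < -1e-12 | sigma > 1 + 1e-12))
    stop("singular values must lie in [0, 1]")
  phi <- acos(pmin(pmax(sigma, 0), 1))
  c(phi, -phi)
}

## Walsh function matrix W[j+1, k+1] = (-1)^popcount(j & k)
walsh_matrix <- function(n) {
  N <- 2^n
  jk <- outer(0:(N - 1), 0:(N - 1), function(j, k) {
    v <- bitwAnd(j, k)
    p <- 0L
    while (any(v > 0)) { p <- p + v %% 2L; v <- v %/% 2L }
    p
  })
  (-1)^jk
}

#' Walsh--Fourier coefficients of a phase vector
#'
#' Expands a length-2^n phase vector f in Walsh functions,
#' `a_j = 2^-n sum_k W_jk f_k`, so that `sum_j a_j W_jk = f_k` exactly.
#' `a_0` is a global phase.
#'
#' @param f real phase vector, length a power of two.
#' @return object of class `walsh_series`: `n_qubits`, `coefficients`,
#'   `phases` (the input).
#' @export
walsh_coefficients <- function(f) {
  n <- log2(length(f))
  if (n != round(n)) stop("phase vector length must be a power of two")
  n <- as.integer(n)
  W <- walsh_matrix(n)
  structure(list(n_qubits = n, coefficients = as.vector(W %*% f) / 2^n,
                 phases = f),
            class = "walsh_series")
}

#' Reconstruct the phase vector from a Walsh series
#' @param series a `walsh_series`.
#' @return numeric phase vector.
#' @export
walsh_reconstruct <- function(series) {
  as.vector(walsh_matrix(series$n_qubits) %*% series$coefficients)
}

#' Synthesize a diagonal unitary from its Walsh series
#'
#' Emits the product of Pauli-Z-string rotations `exp(i a_j Q_j)` as an
#' RZ/CNOT circuit with Gray-code term ordering, so that consecutive
#' Z-strings differ by one bit and parity-computing CNOTs cancel; for the
#' full series on n qubits the construction uses 2^n - 2 CNOTs (all-to-all
#' connectivity).  The global-phase term `a_0` is dropped; coefficients
#' with `|a_j| < drop_tol` are skipped and the resulting adjacent CNOT
#' pairs cancelled.
#'
#' @param series a `walsh_series`.
#' @param drop_tol coefficient drop threshold (default 1e-12).
#' @return `circuit_ir` whose unitary equals `diag(exp(1i * f))` up to
#'   the global phase `exp(1i * a_0)`.
#' @export
synthesize_diagonal <- function(series, drop_tol = 1e-12) {
  stopifnot(inherits(series, "walsh_series"))
  n <- series$n_qubits
  a <- series$coefficients
  gates <- list()
  emit_rz <- function(pattern, target) {
    ## pattern: vector of qubits in the Z string; j-index bit of qubit q
    ## has weight 2^(n - q)
    j <- sum(2^(n - pattern))
    if (abs(a[j + 1]) >= drop_tol)
      gates[[length(gates) + 1]] <<- gate("RZ", target, -2 * a[j + 1])
  }
  synth <- function(Q) {
    m <- length(Q)
    if (m == 1) { emit_rz(Q, Q); return(invisible()) }
    t <- Q[m]; rest <- Q[-m]
    synth(rest)
    emit_rz(t, t)
    prev <- 0L
    for (k in seq_len(2^(m - 1))) {
      g <- if (k < 2^(m - 1)) bitwXor(k, k %/% 2L) else 0L
      b <- as.integer(round(log2(bitwXor(g, prev))))     # changed bit
      gates[[length(gates) + 1]] <<- gate("CNOT", c(rest[b + 1], t))
      if (g != 0L) {
        patt <- c(rest[which(bitwAnd(g, 2^(seq_along(rest) - 1)) > 0)], t)
        emit_rz(patt, t)
      }
      prev <- g
    }
  }
  if (n == 0) stop("empty register")
  synth(seq_len(n))
  circuit_ir(n, cancel_cnot_pairs(gates), phase = a[1])
}

## peephole: remove adjacent identical CNOT pairs with no intervening
## gate touching either qubit
cancel_cnot_pairs <- function(gates) {
  repeat {
    removed <- FALSE
    i <- 1
    while (i < length(gates)) {
      g1 <- gates[[i]]
      if (g1$name == "CNOT") {
        j <- i + 1
        while (j <= length(gates)) {
          g2 <- gates[[j]]
          if (identical(g2$name, "CNOT") &&
              identical(g2$qubits, g1$qubits)) {
            gates <- gates[-c(i, j)]
            removed <- TRUE
            break
          }
          if (any(g2$qubits %in% g1$qubits)) break
          j <- j + 1
        }
        if (removed) break
      }
      i <- i + 1
    }
    if (!removed) return(gates)
  }
}

## native single-qubit decomposition: U = e^{i phase} RZ(phi + pi) SX
## RZ(theta + pi) SX RZ(lambda), from the ZYZ Euler angles of U.
## Returns list(gates, phase).
decompose_1q <- function(U, qubit) {
  det_u <- U[1, 1] * U[2, 2] - U[1, 2] * U[2, 1]
  Us <- U / sqrt(det_u)
  cth <- Mod(Us[1, 1]); sth <- Mod(Us[2, 1])
  theta <- 2 * atan2(sth, cth)
  if (sth < 1e-12) {              # diagonal
    phi <- 2 * Arg(Us[2, 2]); lam <- 0
  } else if (cth < 1e-12) {       # anti-diagonal
    phi <- 2 * Arg(Us[2, 1]); lam <- 0
  } else {
    phi <- Arg(Us[2, 2]) + Arg(Us[2, 1])
    lam <- Arg(Us[2, 2]) - Arg(Us[2, 1])
  }
  gl <- list(gate("RZ", qubit, lam), gate("SX", qubit),
             gate("RZ", qubit, theta + pi), gate("SX", qubit),
             gate("RZ", qubit, phi + pi))
  prod <- diag(2) + 0i
  for (g in gl) prod <- gate_matrix(g) %*% prod
  ov <- sum(Conj(prod) * U)
  list(gates = gl, phase = Arg(ov))
}

#' Full Kraus-operator circuit (SVD + dilated diagonal)
#'
#' Builds the postselection circuit for a Kraus operator M on
#' `n_sys` system qubits plus one ancilla (qubit 1): `Vdag` on the
#' system, Hadamard on the ancilla, the Walsh-synthesized dilated
#' singular-value diagonal on the full register, Hadamard on the ancilla,
#' `U` on the system, and measurement of all qubits.  The ancilla-0 block
#' of the composed unitary equals M, so keeping ancilla-0 records
#' realizes M|psi> without renormalization.  Single-qubit U/V factors are
#' decomposed to native RZ/SX gates; multi-qubit factors are kept as
#' opaque unitaries.
#'
#' @param M d x d Kraus operator (contraction), d = 2^n_sys.
#' @param n_sys number of system qubits.
#' @param drop_tol Walsh coefficient drop threshold.
#' @return `circuit_ir` on `n_sys + 1` qubits with roles
#'   `ancilla = 1`, `system = 2:(n_sys+1)`.
#' @export
build_kraus_circuit <- function(M, n_sys = log2(nrow(M)), drop_tol = 1e-12) {
  d <- nrow(M)
  if (n_sys != round(n_sys) || d != 2^round(n_sys) || ncol(M) != d)
    stop("Kraus operator dimension must be 2^n_sys")
  n_sys <- as.integer(round(n_sys))
  sv <- svd_unitarize(M)
  f <- dilation_phases(sv$sigma)
  dcirc <- synthesize_diagonal(walsh_coefficients(f), drop_tol)
  sysq <- seq_len(n_sys) + 1L
  phase <- dcirc$phase
  g <- list()
  add_u <- function(W) {
    if (n_sys == 1) {
      dec <- decompose_1q(W, sysq)
      phase <<- phase + dec$phase
      dec$gates
    } else list(gate("UNITARY", sysq, W))
  }
  g <- c(g, add_u(sv$Vdag))
  g <- c(g, list(gate("H", 1L)))
  g <- c(g, dcirc$gates)
  g <- c(g, list(gate("H", 1L)))
  g <- c(g, add_u(sv$U))
  g <- c(g, list(gate("MEASURE", seq_len(n_sys + 1L))))
  circuit_ir(n_sys + 1L, g, roles = list(ancilla = 1L, system = sysq),
             phase = phase)
}

#' Gate metrics of a circuit
#'
#' Depth is greedy as-soon-as-possible layering over unitary gates
#' (single-qubit gates on disjoint qubits share a layer; MEASURE is
#' excluded); an opaque multi-qubit UNITARY occupies one layer and
#' contributes zero CNOTs, flagged via `contains_opaque`.
#'
#' @param circ a `circuit_ir`.
#' @return list `depth`, `cnot_count`, `gate_counts`, `contains_opaque`.
#' @export
circuit_metrics <- function(circ) {
  busy <- integer(circ$n_qubits)
  cnot <- 0L
  counts <- integer(0)
  opaque <- FALSE
  for (g in circ$gates) {
    counts[g$name] <- (if (is.na(counts[g$name])) 0L else counts[g$name]) + 1L
    if (g$name == "MEASURE") next
    if (g$name == "CNOT") cnot <- cnot + 1L
    if (g$name == "UNITARY" && length(g$qubits) > 1) opaque <- TRUE
    lay <- max(busy[g$qubits]) + 1L
    busy[g$qubits] <- lay
  }
  list(depth = max(busy, 0L), cnot_count = cnot,
       gate_counts = as.list(counts), contains_opaque = opaque)
}

#' Export a circuit as OpenQASM 3 text
#'
#' Opaque multi-qubit unitaries are emitted as comments (they have no
#' native representation without further decomposition).
#'
#' @param circ a `circuit_ir`.
#' @param file optional path; if omitted the text is returned invisibly.
#' @return character vector of QASM lines (invisibly if written).
#' @export
export_qasm <- function(circ, file = NULL) {
  q <- function(i) sprintf("q[%d]", i - 1L)
  lines <- c("OPENQASM 3.0;", 'include "stdgates.inc";',
             sprintf("qubit[%d] q;", circ$n_qubits),
             sprintf("bit[%d] c;", circ$n_qubits))
  for (g in circ$gates) {
    lines <- c(lines, switch(g$name,
      X = sprintf("x %s;", q(g$qubits)),
      SX = sprintf("sx %s;", q(g$qubits)),
      H = sprintf("h %s;", q(g$qubits)),
      RZ = sprintf("rz(%.17g) %s;", g$param, q(g$qubits)),
      CNOT = sprintf("cx %s, %s;", q(g$qubits[1]), q(g$qubits[2])),
      UNITARY = sprintf("// opaque unitary on qubits %s",
                        paste(g$qubits - 1L, collapse = ", ")),
      MEASURE = "c = measure q;"))
  }
  if (!is.null(file)) { writeLines(lines, file); return(invisible(lines)) }
  lines
}
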