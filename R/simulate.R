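#' Run settings for circuit execution
#'
#' @param mode `"exact"` (squared statevector amplitudes) or `"shots"`
#'   (multinomial sampling).
#' @param n_shots shots per executed circuit in shots mode.
#' @param seed integer seed fixing all sampling (`NULL` to use the
#'   current RNG state).
#' @param times optional subset of time indices to evaluate (0-based;
#'   default: every point of the propagation grid).
#' @return object of class `run_settings`.
#' @export
run_settings <- function(mode = c("exact", "shots"), n_shots = 20000L,
                         seed = 1L, times = NULL) {
  mode <- match.arg(mode)
  if (mode == "shots") stopifnot(n_shots > 0)
  structure(list(mode = mode, n_shots = as.integer(n_shots), seed = seed,
                 times = times),
            class = "run_settings")
}

## apply a 2^k gate matrix on `qubits` (most-significant first) to a
## statevector of n qubits (qubit 1 = most significant bit)
apply_gate_state <- function(psi, n, Gm, q) {
  k <- length(q)
  dims <- rep(2L, n)
  arr <- array(psi, dims)                       # dim j <-> qubit n+1-j
  perm <- c(n + 1L - rev(q), setdiff(seq_len(n), n + 1L - rev(q)))
  arr <- aperm(arr, perm)
  m <- Gm %*% matrix(arr, 2^k)
  arr2 <- array(m, dims[perm])
  inv <- integer(n); inv[perm] <- seq_len(n)
  as.vector(aperm(arr2, inv))
}

#' Execute a circuit on the built-in statevector simulator
#'
#' Starts from |0...0>, applies the gate list, and returns the
#' computational-basis outcome distribution: exact squared amplitudes in
#' `"exact"` mode, multinomial counts in `"shots"` mode.  Outcome labels
#' are bitstrings with qubit 1 leftmost.
#'
#' @param circ a `circuit_ir` (at most 12 qubits).
#' @param settings a [run_settings()].
#' @return data.frame with columns `outcome`, `probability` and (shots
#'   mode) `counts`.
#' @export
run_circuit <- function(circ, settings = run_settings("exact")) {
  n <- circ$n_qubits
  if (n > 12) stop("register exceeds the simulator cap of 12 qubits")
  psi <- c(1 + 0i, rep(0i, 2^n - 1))
  for (g in circ$gates) {
    Gm <- gate_matrix(g)
    if (is.null(Gm)) next
    psi <- apply_gate_state(psi, n, Gm, g$qubits)
  }
  p <- Mod(psi)^2
  p <- p / sum(p)
  labels <- vapply(0:(2^n - 1), function(b)
    paste(as.integer(bitwAnd(bitwShiftR(b, (n - 1):0), 1L)), collapse = ""),
    character(1))
  if (settings$mode == "exact")
    return(data.frame(outcome = labels, probability = p))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  cnt <- as.vector(stats::rmultinom(1, settings$n_shots, p))
  data.frame(outcome = labels, probability = cnt / settings$n_shots,
             counts = cnt)
}

## deterministic unitary with psi as first column (Gram-Schmidt completion)
state_prep_unitary <- function(psi) {
  d <- length(psi)
  B <- matrix(0i, d, d)
  B[, 1] <- psi / sqrt(sum(Mod(psi)^2))
  j <- 1L
  for (col in 2:d) {
    repeat {
      v <- rep(0i, d); v[j] <- 1; j <- j + 1L
      for (c2 in seq_len(col - 1)) v <- v - sum(Conj(B[, c2]) * v) * B[, c2]
      nv <- sqrt(sum(Mod(v)^2))
      if (nv > 1e-6) { B[, col] <- v / nv; break }
    }
  }
  B
}

#' Population dynamics through the Kraus circuit ensemble
#'
#' Runs the full pipeline: superpropagators at every grid point, Kraus
#' decomposition, one postselection circuit per (Kraus operator,
#' initial-state eigencomponent, time point), statevector execution, and
#' assembly of populations by the operator-sum rule.  Joint ancilla-0
#' probabilities are *not* renormalized: the joint frequency of
#' (ancilla = 0, system = i) estimates `<i| M_k rho M_k^dag |i>`
#' directly, and populations are their sum over k.  A reference column
#' holds the populations from direct superoperator propagation.
#'
#' @param system a [system_spec()] (dimension must be a power of two).
#' @param settings a [propagation_settings()].
#' @param run a [run_settings()].
#' @param maps optional precomputed result of [propagate_map()].
#' @param floor relative Kraus drop floor (see [kraus_from_choi()]).
#' @param align phase-align Kraus operators between consecutive time
#'   points (cosmetic for per-operator curves; sums are invariant).
#' @return object of class `trajectory_table`: a data.frame with columns
#'   `time`, `state`, `population`, `reference`, plus attributes
#'   `joint` (per time point, a n_kraus x d matrix of joint ancilla-0
#'   probabilities) and `kraus_weights`.
#' @export
population_dynamics <- function(system, settings, run = run_settings("exact"),
                                maps = NULL, floor = 1e-9, align = TRUE) {
  d <- system$d
  n_sys <- log2(d)
  if (n_sys != round(n_sys))
    stop("circuit execution requires a power-of-two system dimension")
  n_sys <- as.integer(n_sys)
  if (is.null(maps)) maps <- propagate_map(system, settings)
  idx <- if (is.null(run$times)) 0:(length(maps) - 1L) else as.integer(run$times)
  if (!is.null(run$seed)) set.seed(run$seed)
  run1 <- run; run1$seed <- NULL
  ## initial-state eigencomponents
  e0 <- eigen(system$initial_state, symmetric = TRUE)
  comp <- which(e0$values > 1e-12)
  preps <- lapply(comp, function(i) state_prep_unitary(e0$vectors[, i]))
  wts <- e0$values[comp]
  sysq <- seq_len(n_sys) + 1L
  rho0v <- vectorize(system$initial_state)
  ksets <- list()
  rows <- list(); joint_list <- list(); weight_list <- list()
  prev_kset <- NULL
  for (n in idx) {
    Tn <- maps[[n + 1L]]
    kset <- kraus_from_choi(choi_from_map(Tn), floor = floor)
    if (align && !is.null(prev_kset))
      kset <- align_kraus_trajectory(list(prev_kset, kset))[[2]]
    prev_kset <- kset
    nk <- length(kset$operators)
    J <- matrix(0, nk, d)
    for (ci in seq_along(comp)) {
      for (k in seq_len(nk)) {
        circ <- build_kraus_circuit(kset$operators[[k]], n_sys)
        circ$gates <- c(list(gate("UNITARY", sysq, preps[[ci]])), circ$gates)
        res <- run_circuit(circ, run1)
        ## ancilla = 0 outcomes are the first d rows (ancilla is the MSB)
        J[k, ] <- J[k, ] + wts[ci] * res$probability[seq_len(d)]
      }
    }
    ref <- Re(diag(unvectorize(Tn$matrix %*% rho0v)))
    rows[[length(rows) + 1L]] <- data.frame(
      time = Tn$time, state = seq_len(d),
      population = colSums(J), reference = ref)
    joint_list[[length(joint_list) + 1L]] <- J
    weight_list[[length(weight_list) + 1L]] <- kset$weights
  }
  out <- do.call(rbind, rows)
  class(out) <- c("trajectory_table", "data.frame")
  attr(out, "joint") <- joint_list
  attr(out, "kraus_weights") <- weight_list
  attr(out, "run") <- run
  out
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat("<trajectory_table>", length(unique(x$time)), "time points,",
      max(x$state), "states\n")
  NextMethod()
}

#' Write a trajectory table (CSV) with per-Kraus joint probabilities
#'
#' @param tt a `trajectory_table`.
#' @param file output path.
#' @return the written data.frame, invisibly.
#' @export
write_trajectory <- function(tt, file) {
  joint <- attr(tt, "joint")
  times <- unique(tt$time)
  nk_max <- max(vapply(joint, nrow, integer(1)))
  wide <- do.call(rbind, lapply(seq_along(times), function(i) {
    J <- joint[[i]]
    sub <- tt[tt$time == times[i], ]
    for (k in seq_len(nk_max))
      sub[[paste0("joint_k", k)]] <-
        if (k <= nrow(J)) J[k, sub$state] else NA_real_
    sub
  }))
  utils::write.csv(wide, file, row.names = FALSE)
  invisible(wide)
}
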