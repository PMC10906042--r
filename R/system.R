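#' System specification for open-system propagation
#'
#' Bundles the system Hamiltonian (Hermitian, in internal energy units),
#' the attached baths, and the initial system state.  The propagation
#' basis is the eigenbasis of the bath coupling operators, which must be
#' diagonal: each bath carries its coupling eigenvalues in
#' `coupling_values`.
#'
#' @param hamiltonian d x d Hermitian matrix (internal energy units).
#' @param baths list of [bath_spec()] objects, one per independent bath;
#'   each must have `coupling_values` of length d.
#' @param initial_state d x d density matrix (positive semidefinite, unit
#'   trace) or a length-d pure-state vector (normalized internally).
#' @return object of class `system_spec` with elements `hamiltonian`,
#'   `d`, `baths`, `initial_state` (always a density matrix).
#' @export
system_spec <- function(hamiltonian, baths, initial_state) {
  H <- as.matrix(hamiltonian)
  if (nrow(H) != ncol(H)) stop("hamiltonian must be square")
  storage.mode(H) <- "complex"
  if (max(abs(H - Conj(t(H)))) > 1e-12)
    stop("hamiltonian must be Hermitian to 1e-12")
  d <- nrow(H)
  if (inherits(baths, "bath_spec")) baths <- list(baths)
  for (b in baths) {
    if (!inherits(b, "bath_spec")) stop("baths must be bath_spec objects")
    if (length(b$coupling_values) != d)
      stop("bath coupling_values length must equal system dimension ", d)
  }
  if (is.matrix(initial_state)) {
    rho <- initial_state
    storage.mode(rho) <- "complex"
    if (nrow(rho) != d || ncol(rho) != d) stop("initial_state has wrong dimension")
    if (max(abs(rho - Conj(t(rho)))) > 1e-10) stop("initial state must be Hermitian")
    if (abs(sum(diag(rho)) - 1) > 1e-10) stop("initial state must have unit trace")
    ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) stop("initial state must be positive semidefinite")
  } else {
    psi <- as.complex(initial_state)
    if (length(psi) != d) stop("initial_state has wrong dimension")
    psi <- psi / sqrt(sum(Mod(psi)^2))
    rho <- outer(psi, Conj(psi))
  }
  structure(list(hamiltonian = H, d = d, baths = baths, initial_state = rho),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat("<system_spec> d =", x$d, "with", length(x$baths), "bath(s)\n")
  invisible(x)
}

#' Propagation settings for the path-integral engine
#'
#' @param dt time step (> 0, internal time units).
#' @param n_steps number of steps (>= 1).
#' @param dk_max memory length in steps: influence-functional pairs
#'   separated by more than `dk_max` steps are dropped (finite-memory
#'   approximation); convergence in `dk_max` should be checked.
#' @param svd_cutoff relative singular-value threshold for bond
#'   truncation of the augmented path tensor (0 disables truncation,
#'   feasible only for small memory windows).
#' @param chi_max optional hard cap on the bond dimension.
#' @param trotter splitting scheme; only `"symmetric"` (influence windows
#'   centered on the path points) is implemented.
#' @return object of class `propagation_settings`.
#' @export
propagation_settings <- function(dt, n_steps, dk_max = 8L,
                                 svd_cutoff = 1e-10, chi_max = Inf,
                                 trotter = "symmetric") {
  stopifnot(dt > 0, n_steps >= 1, dk_max >= 1,
            svd_cutoff >= 0, svd_cutoff < 1)
  trotter <- match.arg(trotter, "symmetric")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 dk_max = as.integer(dk_max), svd_cutoff = svd_cutoff,
                 chi_max = chi_max, trotter = trotter),
            class = "propagation_settings")
}

## constructor for the d^2 x d^2 map-at-time-t container
new_superpropagator <- function(matrix, time) {
  structure(list(matrix = matrix, time = time,
                 vectorization = "column-stacking"),
            class = "superpropagator")
}

#' @export
print.superpropagator <- function(x, ...) {
  cat("<superpropagator> t =", x$time, " dim", nrow(x$matrix), "x",
      ncol(x$matrix), "(", x$vectorization, ")\n")
  invisible(x)
}
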