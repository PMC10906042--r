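#' Short-time system propagator
#'
#' Matrix exponential `U = exp(-i H dt)` of the (Hermitian) system
#' Hamiltonian, computed by eigendecomposition.
#'
#' @param system a [system_spec()].
#' @param dt time step (>= 0).
#' @return d x d unitary matrix.
#' @export
short_time_propagator <- function(system, dt) {
  stopifnot(inherits(system, "system_spec"), dt >= 0)
  H <- system$hamiltonian
  e <- eigen(H, symmetric = TRUE)
  V <- e$vectors
  V %*% (exp(-1i * e$values * dt) * Conj(t(V)))
}

## ---- influence-functional factors ---------------------------------------
## Composite path index x = (i, j), i = forward (ket) state fast, j =
## backward (bra) state slow, matching column-stacking vec(rho)[i + d(j-1)].
## For one bath with coupling eigenvalues f and coefficient eta, the pair
## weight between a later variable x and an earlier variable x' is
##   exp( -(f+_x - f-_x) (eta f+_x' - conj(eta) f-_x') ).
## Factors from independent baths multiply.

coupling_fp_fm <- function(f, d) {
  list(fp = rep(f, times = d), fm = rep(f, each = d))
}

## pair factor matrix P[x_later, x_earlier]; etas: one coefficient per bath
pair_factor_matrix <- function(baths, etas, d) {
  D2 <- d * d
  P <- matrix(1 + 0i, D2, D2)
  for (b in seq_along(baths)) {
    if (etas[b] == 0) next
    fv <- coupling_fp_fm(baths[[b]]$coupling_values, d)
    P <- P * exp(-outer(fv$fp - fv$fm,
                        etas[b] * fv$fp - Conj(etas[b]) * fv$fm))
  }
  P
}

## self-interaction factor vector D[x]
diag_factor_vec <- function(baths, etas, d) {
  v <- rep(1 + 0i, d * d)
  for (b in seq_along(baths)) {
    if (etas[b] == 0) next
    fv <- coupling_fp_fm(baths[[b]]$coupling_values, d)
    v <- v * exp(-(fv$fp - fv$fm) *
                   (etas[b] * fv$fp - Conj(etas[b]) * fv$fm))
  }
  v
}

## enforce the Hermiticity-preservation symmetry of a map matrix:
## T[(i,j),(i',j')] = conj(T[(j,i),(j',i')])
hermitize_map <- function(Tm, d) {
  P <- as.vector(t(matrix(seq_len(d * d), d, d)))
  (Tm + Conj(Tm[P, P])) / 2
}

## per-bath eta class tables and prebuilt factor matrices for the engine
build_engine_factors <- function(system, settings) {
  d <- system$d
  N <- settings$n_steps
  K <- min(settings$dk_max, N)
  tabs <- lapply(system$baths, eta_table,
                 dt = settings$dt, n_steps = N, kmax = K)
  cls <- function(name, s) vapply(tabs, function(tb) tb[[name]][s], complex(1))
  cls1 <- function(name) vapply(tabs, function(tb) tb[[name]], complex(1))
  list(
    K = K,
    Pint = lapply(seq_len(K), function(s)
      pair_factor_matrix(system$baths, cls("int", s), d)),
    Pk0 = lapply(seq_len(K), function(s)
      pair_factor_matrix(system$baths, cls("k0", s), d)),
    Dint = diag_factor_vec(system$baths, cls1("int_diag"), d),
    D00 = diag_factor_vec(system$baths, cls1("end_diag"), d),
    ## read-out corrections: ratios interior-class -> terminal-class
    Dterm = diag_factor_vec(system$baths,
                            cls1("end_diag") - cls1("int_diag"), d),
    Rnk = lapply(seq_len(K), function(s)
      pair_factor_matrix(system$baths, cls("Nk", s) - cls("int", s), d)),
    Rn0 = lapply(seq_len(K), function(s)
      pair_factor_matrix(system$baths, cls("N0", s) - cls("k0", s), d)),
    tabs = tabs
  )
}

## step the augmented-tensor MPS from path point k1-1 to k1
engine_step <- function(chain, k1, fac, Kmat, D2, cutoff, chi_max) {
  ## coupled prefix: sites within the memory window of the new variable
  Mlist <- list()
  for (s in seq_along(chain)) {
    dk <- k1 - chain[[s]]$time
    if (dk > fac$K) break
    M <- if (chain[[s]]$time == 0L) fac$Pk0[[dk]] else fac$Pint[[dk]]
    if (s == 1L) M <- M * Kmat
    Mlist[[s]] <- M
  }
  chain <- zip_front_mpo(chain, Mlist, chi_a = 1L, D2 = D2,
                         cutoff = cutoff, chi_max = chi_max)
  front <- array(0i, c(1, D2, D2))
  front[cbind(1L, seq_len(D2), seq_len(D2))] <- fac$Dint
  c(list(site3(front, k1)), chain)
}

## read out the t = 0 -> t_n map from the chain: convert the factors of the
## newest variable from interior-window to terminal-window classes, then
## contract.  The chain itself is left untouched (corrections are applied
## to a copy).
engine_readout <- function(chain, k1, fac, D2, d) {
  S <- length(chain)
  G1 <- chain[[1]]$G
  ## carry A[x_n, bond], front conditioned on x_n with the terminal
  ## diagonal ratio applied
  A <- aperm(G1, c(2, 1, 3))
  dim(A) <- c(D2, dim(G1)[3])
  A <- A * fac$Dterm
  for (s in seq_along(chain)[-1]) {
    G <- chain[[s]]$G; dG <- dim(G)
    dk <- k1 - chain[[s]]$time
    R <- if (dk > fac$K) NULL
         else if (chain[[s]]$time == 0L) fac$Rn0[[k1]] else fac$Rnk[[dk]]
    if (s < S) {
      if (is.null(R)) {
        A <- A %*% colSums(aperm(G, c(2, 1, 3)), dims = 1)
      } else {
        ## sum physical index with the x_n-dependent pair-correction weight
        Gp <- aperm(G, c(2, 1, 3))
        dim(Gp) <- c(dG[2], dG[1] * dG[3])
        An <- matrix(0i, D2, dG[3])
        for (x in seq_len(D2)) {
          W <- matrix(R[x, ] %*% Gp, dG[1], dG[3])
          An[x, ] <- A[x, , drop = FALSE] %*% W
        }
        A <- An
      }
    } else {
      ## last site carries the free initial index x_0 (kept)
      Tm <- A %*% matrix(G[, , 1], dG[1], dG[2])
      if (!is.null(R)) Tm <- Tm * R
      return(hermitize_map(Tm, d))
    }
  }
  stop("internal error: read-out reached end of chain")
}

#' Exact reduced-dynamics superpropagators by tensor-network path integral
#'
#' Propagates the discretized influence-functional path sum as a
#' matrix-product state over the memory window, and reads out the linear
#' map from t = 0 to every t_n on the time grid.  The returned maps are
#' full-interval maps, not step maps: non-Markovian dynamics is not
#' composed step-wise.
#'
#' @param system a [system_spec()].
#' @param settings a [propagation_settings()].
#' @return list of `superpropagator` objects at times `0, dt, ..., n*dt`
#'   (the first is the identity map), with attribute `max_bond`.
#' @export
propagate_map <- function(system, settings) {
  stopifnot(inherits(system, "system_spec"),
            inherits(settings, "propagation_settings"))
  d <- system$d
  D2 <- d * d
  N <- settings$n_steps
  K <- min(settings$dk_max, N)
  if (settings$svd_cutoff == 0 && D2^(K + 1) > 2^24)
    stop("memory window too large for untruncated propagation; ",
         "set svd_cutoff > 0 to enable bond truncation")
  U <- short_time_propagator(system, settings$dt)
  Kmat <- kronecker(Conj(U), U)
  fac <- build_engine_factors(system, settings)
  chain <- list(site3(array(fac$D00, c(1, D2, 1)), 0L))
  out <- vector("list", N + 1L)
  out[[1]] <- new_superpropagator(diag(D2) + 0i, 0)
  maxb <- 1
  for (k1 in seq_len(N)) {
    chain <- engine_step(chain, k1, fac, Kmat, D2,
                         settings$svd_cutoff, settings$chi_max)
    out[[k1 + 1L]] <- new_superpropagator(
      engine_readout(chain, k1, fac, D2, d), k1 * settings$dt)
    chain <- mps_prune(chain, min_time = k1 + 1L - K)
    chain <- mps_sweep_rl(chain)
    chain <- mps_sweep_lr(chain, settings$svd_cutoff, settings$chi_max)
    maxb <- max(maxb, mps_max_bond(chain))
  }
  attr(out, "max_bond") <- maxb
  attr(out, "settings") <- settings
  out
}

#' Brute-force path-enumeration superpropagators
#'
#' Evaluates the discretized path sum by explicit enumeration of all
#' forward/backward path pairs.  Exact within the same discretization and
#' memory truncation as [propagate_map()]; used as an oracle and for tiny
#' systems only (the enumeration is guarded at d^(2(n+1)) <= 2^20 paths).
#'
#' @inheritParams propagate_map
#' @return list of `superpropagator` objects at times `0, dt, ..., n*dt`.
#' @export
brute_force_map <- function(system, settings) {
  stopifnot(inherits(system, "system_spec"),
            inherits(settings, "propagation_settings"))
  d <- system$d
  D2 <- d * d
  N <- settings$n_steps
  if ((N + 1) * log(D2) > 20 * log(2))
    stop("path enumeration beyond guard (d^(2(n+1)) > 2^20)")
  K <- min(settings$dk_max, N)
  U <- short_time_propagator(system, settings$dt)
  Kmat <- kronecker(Conj(U), U)
  tabs <- lapply(system$baths, eta_table,
                 dt = settings$dt, n_steps = N, kmax = K)
  out <- vector("list", N + 1L)
  out[[1]] <- new_superpropagator(diag(D2) + 0i, 0)
  for (n in seq_len(N)) {
    ems <- lapply(tabs, eta_matrix, n_steps = n)
    npaths <- D2^(n + 1)
    idx <- 0:(npaths - 1)
    ## X[, k+1] = x_k (1-based composite path index at point k)
    X <- vapply(0:n, function(k) as.integer((idx %/% D2^k) %% D2 + 1),
                integer(npaths))
    w <- rep(1 + 0i, npaths)
    for (k in 0:(n - 1))
      w <- w * Kmat[cbind(X[, k + 2L], X[, k + 1L])]
    for (k in 0:n) {
      for (kp in 0:k) {
        etas <- vapply(ems, function(m) m[k + 1L, kp + 1L], complex(1))
        if (all(etas == 0)) next
        if (k == kp) {
          Dv <- diag_factor_vec(system$baths, etas, d)
          w <- w * Dv[X[, k + 1L]]
        } else {
          P <- pair_factor_matrix(system$baths, etas, d)
          w <- w * P[cbind(X[, k + 1L], X[, kp + 1L])]
        }
      }
    }
    grp <- factor(X[, n + 1L] + D2 * (X[, 1L] - 1L), levels = seq_len(D2^2))
    Tm <- matrix(complex(real = rowsum(Re(w), grp),
                         imaginary = rowsum(Im(w), grp)), D2, D2)
    out[[n + 1L]] <- new_superpropagator(Tm, n * settings$dt)
  }
  out
}
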