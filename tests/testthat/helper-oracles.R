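## Independent numerical oracles and small generators shared across the
## test files.  Everything here is deliberately written without reusing
## the package's own quadrature / tensor-network code paths.

## Gauss-Legendre nodes and weights on [0, 1] (Golub-Welsch)
gauss_legendre01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = (e$vectors[1, ])^2)
}

## Matsubara (pole-expansion) bath response for the Drude spectral
## density, valid for t > 0; converges geometrically in exp(-2*pi*t/beta)
drude_matsubara_alpha <- function(lambda, gamma, beta, t, nterms = 400) {
  nu <- 2 * pi * seq_len(nterms) / beta
  lambda * gamma * (1 / tan(beta * gamma / 2) - 1i) * exp(-gamma * t) +
    (4 * lambda * gamma / beta) * sum(nu * exp(-nu * t) / (nu^2 - gamma^2))
}

## Haar-ish random unitary via SVD of a Ginibre matrix
random_unitary <- function(d) {
  M <- matrix(stats::rnorm(d^2) + 1i * stats::rnorm(d^2), d)
  s <- svd(M)
  s$u %*% Conj(t(s$v))
}

random_contraction <- function(d) {
  M <- matrix(stats::rnorm(d^2) + 1i * stats::rnorm(d^2), d)
  M / (max(svd(M, nu = 0, nv = 0)$d) * (1 + 1e-12))
}

## equal-weight n-mode discretization of the Ohmic density with
## exponential cutoff: F(w) = int_0^w J/w' dw' = (pi/2) xi wc (1 - e^(-w/wc)),
## modes at the midpoints of equal F-slices, c_j^2 = w_j xi wc / n
ohmic_discrete_modes <- function(xi, wc, n_modes) {
  wj <- -wc * log(1 - (seq_len(n_modes) - 0.5) / n_modes)
  list(w = wj, c = sqrt(wj * xi * wc / n_modes))
}

## Exact reduced dynamics of a two-level system coupled through sigma_z
## to a finite set of truncated harmonic modes, with a factorized
## thermal initial bath state.  Returns the list of reduced density
## matrices at the requested times.  Pure dense eigendecomposition of
## the full system (x) bath Hamiltonian; independent of the path-integral
## machinery.
exact_discrete_bath_rho <- function(H, modes, beta, rho_s0, times,
                                    nlev = 12) {
  nm <- length(modes$w)
  a_op <- matrix(0, nlev, nlev)
  a_op[cbind(seq_len(nlev - 1), seq_len(nlev - 1) + 1)] <-
    sqrt(seq_len(nlev - 1))
  num <- Conj(t(a_op)) %*% a_op
  xop <- function(w) (a_op + Conj(t(a_op))) / sqrt(2 * w)
  Im_ <- diag(nlev)
  sz <- diag(c(1, -1))
  kr <- function(...) Reduce(kronecker, list(...))
  mode_mats <- function(j, M) {
    mats <- rep(list(Im_), nm)
    mats[[j]] <- M
    mats
  }
  Hfull <- kr(H, do.call(kr, rep(list(Im_), nm)))
  for (j in seq_len(nm)) {
    Hfull <- Hfull +
      kr(sz, do.call(kr, mode_mats(j, modes$c[j] * xop(modes$w[j])))) +
      kr(diag(2), do.call(kr, mode_mats(j, modes$w[j] * (num + 0.5 * Im_))))
  }
  rho_th <- function(w) {
    p <- exp(-beta * w * (0:(nlev - 1)))
    diag(p / sum(p))
  }
  rho0 <- kr(rho_s0, do.call(kr, lapply(modes$w, rho_th)))
  ee <- eigen(Hfull, symmetric = TRUE)
  V <- ee$vectors
  m2 <- nlev^nm
  lapply(times, function(t) {
    Ut <- V %*% (exp(-1i * ee$values * t) * Conj(t(V)))
    R <- Ut %*% rho0 %*% Conj(t(Ut))
    out <- matrix(0i, 2, 2)
    for (i in 1:2) for (j in 1:2)
      out[i, j] <- sum(diag(R[(i - 1) * m2 + seq_len(m2),
                              (j - 1) * m2 + seq_len(m2), drop = FALSE]))
    out
  })
}

## spin-boson system at the standard demonstration parameters
sb_demo_system <- function() build_spin_boson()

## small FMO-type system from the shipped synthetic Hamiltonian
fmo_demo_system <- function() {
  path <- system.file("extdata", "fmo4_hamiltonian_synthetic.json",
                      package = "krausdyn")
  build_fmo4(read_site_hamiltonian(path))
}
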