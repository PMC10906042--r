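#' Build a spin-boson model
#'
#' Two-level system `H_s = Omega * sigma_x + epsilon * sigma_z` coupled
#' through `sigma_z` (coupling eigenvalues +1, -1) to an Ohmic bath with
#' exponential cutoff.  All quantities are dimensionless
#' (`hbar = k_B = 1`).  The tunneling convention (no factor 1/2) is
#' isolated here; invariants are asserted against the matrix exponential
#' of this Hamiltonian, never against a hand-written period.
#'
#' @param omega tunneling frequency Omega.
#' @param epsilon asymmetry.
#' @param xi Kondo parameter of the Ohmic bath.
#' @param omega_c cutoff frequency.
#' @param beta inverse temperature.
#' @param initial `"up"` (the +1 eigenstate of the coupling operator),
#'   `"down"`, or an explicit state (vector or density matrix).
#' @return a [system_spec()].
#' @export
build_spin_boson <- function(omega = 1, epsilon = 0, xi = 0.1,
                             omega_c = 7.5, beta = 5, initial = "up") {
  H <- matrix(c(epsilon, omega, omega, -epsilon), 2, 2)
  bath <- bath_spec("ohmic_exponential", coupling = xi, cutoff = omega_c,
                    beta = beta, coupling_values = c(1, -1))
  st <- if (identical(initial, "up")) c(1, 0) else
    if (identical(initial, "down")) c(0, 1) else initial
  system_spec(H, list(bath), st)
}

#' Build a 4-site exciton-transfer model (FMO type)
#'
#' Frenkel--Holstein model of four chromophore sites: a 4 x 4 Hermitian
#' site Hamiltonian in cm^-1, with each site coupled to its own local
#' harmonic bath of identical Drude spectral density
#' `J(w) = 2 lambda gamma w / (w^2 + gamma^2)` (coupling eigenvalues:
#' the site-occupation indicator).  Energies are converted to internal
#' angular frequency (rad/fs); time is then in fs.
#'
#' @param hamiltonian_cm1 4 x 4 Hermitian matrix in cm^-1 (site basis).
#'   The electronic couplings of the Fenna-Matthews-Olson complex are
#'   tabulated in the structural-biology literature; a synthetic
#'   stand-in with literature-scale values ships in
#'   `system.file("extdata", "fmo4_hamiltonian_synthetic.json",
#'   package = "krausdyn")`.
#' @param lambda_cm1 reorganization energy (default 35 cm^-1).
#' @param gamma_cm1 phonon relaxation rate (default 106.18 cm^-1).
#' @param temperature_K temperature in kelvin (default 300).
#' @param initial_site site initially populated (default 1, the entry
#'   point of the 1 -> 2 -> 3 -> 4 transfer pathway).
#' @return a [system_spec()] in internal rad/fs units.
#' @export
build_fmo4 <- function(hamiltonian_cm1, lambda_cm1 = 35,
                       gamma_cm1 = 106.18, temperature_K = 300,
                       initial_site = 1L) {
  H <- as.matrix(hamiltonian_cm1)
  if (!all(dim(H) == c(4, 4))) stop("hamiltonian must be 4 x 4")
  if (max(abs(H - Conj(t(H)))) > 1e-9) stop("hamiltonian must be Hermitian")
  Hint <- convert_units(Re(H), "cm-1", "rad/fs")
  baths <- lapply(1:4, function(n) {
    cv <- numeric(4); cv[n] <- 1
    bath_spec("drude",
              coupling = convert_units(lambda_cm1, "cm-1", "rad/fs"),
              cutoff = convert_units(gamma_cm1, "cm-1", "rad/fs"),
              temperature = temperature_K, temperature_unit = "K",
              coupling_values = cv)
  })
  st <- numeric(4); st[initial_site] <- 1
  system_spec(Hint, baths, st)
}

#' Read a site Hamiltonian from a JSON matrix file
#'
#' Expects `{"units": "cm-1", "matrix": [[...], ...]}`; returns the
#' matrix (cm^-1).
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_site_hamiltonian <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- as.matrix(obj$matrix)
  if (!is.null(obj$units) && obj$units != "cm-1")
    stop("unsupported Hamiltonian units: ", obj$units)
  H
}

#' Deterministic fixture bundle for testing
#'
#' Generates, from one seed: random CPTP maps of dimension 2, 3 and 4
#' (full-rank Kraus sets from Ginibre matrices, normalized so that
#' `sum(M^H M) = I` exactly up to roundoff), random contractions, random
#' diagonal phase vectors, and a miniature spin-boson configuration.
#' Identical seeds give identical bundles.
#'
#' @param seed integer seed.
#' @return named list: `cptp` (kraus_set by dimension), `contractions`,
#'   `phase_vectors`, `spin_boson` (config list).
#' @export
generate_fixtures <- function(seed = 1L) {
  set.seed(seed)
  rg <- function(d) matrix(stats::rnorm(d^2) + 1i * stats::rnorm(d^2), d)
  cptp <- lapply(c(2, 3, 4), function(d) {
    Gs <- lapply(seq_len(d^2), function(i) rg(d))
    S <- Reduce(`+`, lapply(Gs, function(G) Conj(t(G)) %*% G))
    e <- eigen(S, symmetric = TRUE)
    Sinv2 <- e$vectors %*% (1 / sqrt(e$values) * Conj(t(e$vectors)))
    kraus_set(lapply(Gs, function(G) G %*% Sinv2))
  })
  names(cptp) <- paste0("d", c(2, 3, 4))
  contractions <- lapply(c(2, 2, 4), function(d) {
    M <- rg(d)
    M / (max(svd(M, nu = 0, nv = 0)$d) * (1 + 1e-12))
  })
  phase_vectors <- lapply(c(2, 4, 8), function(m) stats::runif(m, -pi, pi))
  list(cptp = cptp, contractions = contractions,
       phase_vectors = phase_vectors,
       spin_boson = list(omega = 1, epsilon = 0, xi = 0.1, omega_c = 7.5,
                         beta = 5, dt = 0.25, n_steps = 4, dk_max = 8))
}

## ---- configuration files -------------------------------------------------

#' Read / write a run configuration (JSON)
#'
#' A configuration bundles a model block (`spin_boson`, `fmo4` or
#' `custom`), a `propagation` block ([propagation_settings()] fields)
#' and an optional `run` block ([run_settings()] fields).
#'
#' @param path file path.
#' @return configuration list (class `krausdyn_config`).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

validate_config <- function(cfg) {
  if (is.null(cfg$model) || !cfg$model %in% c("spin_boson", "fmo4", "custom"))
    stop("config: `model` must be spin_boson, fmo4 or custom")
  if (is.null(cfg$propagation) ||
      is.null(cfg$propagation$dt) || is.null(cfg$propagation$n_steps))
    stop("config: `propagation` block with dt and n_steps is required")
  structure(cfg, class = c("krausdyn_config", "list"))
}

#' Build a system_spec from a configuration
#'
#' @param cfg a configuration list (see [read_config()]).
#' @return list with `system` ([system_spec()]) and `settings`
#'   ([propagation_settings()]).
#' @export
build_from_config <- function(cfg) {
  cfg <- validate_config(cfg)
  system <- switch(cfg$model,
    spin_boson = do.call(build_spin_boson, cfg$spin_boson %||% list()),
    fmo4 = {
      blk <- cfg$fmo4 %||% list()
      H <- if (!is.null(blk$hamiltonian_file))
        read_site_hamiltonian(blk$hamiltonian_file)
      else as.matrix(blk$hamiltonian_cm1)
      build_fmo4(H,
                 lambda_cm1 = blk$lambda_cm1 %||% 35,
                 gamma_cm1 = blk$gamma_cm1 %||% 106.18,
                 temperature_K = blk$temperature_K %||% 300,
                 initial_site = blk$initial_site %||% 1L)
    },
    custom = {
      blk <- cfg$custom
      baths <- lapply(blk$baths, function(b) {
        do.call(bath_spec, b)
      })
      system_spec(as.matrix(blk$hamiltonian), baths,
                  if (is.matrix(blk$initial_state))
                    as.matrix(blk$initial_state) else unlist(blk$initial_state))
    })
  p <- cfg$propagation
  settings <- propagation_settings(
    dt = p$dt, n_steps = p$n_steps,
    dk_max = p$dk_max %||% 8L,
    svd_cutoff = p$svd_cutoff %||% 1e-10,
    chi_max = p$chi_max %||% Inf)
  list(system = system, settings = settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
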