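test_that("short-time propagator is the unitary matrix exponential", {
  sys <- build_spin_boson(omega = 1, epsilon = 0.3)
  U0 <- short_time_propagator(sys, 0)
  expect_equal(U0, diag(2) + 0i, tolerance = 1e-14)
  dt <- 0.1
  U <- short_time_propagator(sys, dt)
  ## unitarity
  expect_lt(max(Mod(Conj(t(U)) %*% U - diag(2))), 1e-12)
  ## eigendecomposition oracle computed by hand
  H <- matrix(c(0.3, 1, 1, -0.3), 2, 2)
  om <- sqrt(0.3^2 + 1)
  Uref <- cos(om * dt) * diag(2) - 1i * sin(om * dt) * H / om
  expect_lt(max(Mod(U - Uref)), 1e-12)
  ## composition: 10 steps of dt equal one step of 10 dt
  U10 <- Reduce(`%*%`, rep(list(U), 10))
  expect_lt(max(Mod(U10 - short_time_propagator(sys, 10 * dt))), 1e-10)
  ## validation of non-Hermitian input
  expect_error(system_spec(matrix(c(0, 1i, 1i, 0), 2, 2),
                           sys$baths, c(1, 0)), "Hermitian")
})

test_that("zero coupling gives the pure unitary map at every time", {
  sys <- build_spin_boson(xi = 0)
  set <- propagation_settings(dt = 0.25, n_steps = 5, dk_max = 8,
                              svd_cutoff = 1e-12)
  mm <- propagate_map(sys, set)
  for (n in c(1, 3, 5)) {
    U <- short_time_propagator(sys, n * 0.25)
    expect_lt(max(Mod(mm[[n + 1]]$matrix - kronecker(Conj(U), U))), 1e-12)
  }
})

test_that("tensor-network propagation equals brute-force path enumeration", {
  sys <- sb_demo_system()
  set <- propagation_settings(dt = 0.25, n_steps = 4, dk_max = 8,
                              svd_cutoff = 1e-12)
  mm <- propagate_map(sys, set)
  bb <- brute_force_map(sys, set)
  for (n in 1:4)
    expect_lt(max(Mod(mm[[n + 1]]$matrix - bb[[n + 1]]$matrix)), 1e-10)
  ## also for a 4-site model with multiple baths
  fmo <- fmo_demo_system()
  set2 <- propagation_settings(dt = 10, n_steps = 2, dk_max = 3,
                               svd_cutoff = 1e-12)
  m2 <- propagate_map(fmo, set2)
  b2 <- brute_force_map(fmo, set2)
  expect_lt(max(Mod(m2[[3]]$matrix - b2[[3]]$matrix)), 1e-10)
})

test_that("brute force: identity at n = 0 and one-step closed form", {
  sys <- sb_demo_system()
  set <- propagation_settings(dt = 0.25, n_steps = 1, dk_max = 1,
                              svd_cutoff = 1e-12)
  bb <- brute_force_map(sys, set)
  expect_equal(bb[[1]]$matrix, diag(4) + 0i)
  ## one step: direct assembly of kernel x influence weights
  U <- short_time_propagator(sys, 0.25)
  K <- kronecker(Conj(U), U)
  tab <- eta_table(sys$baths[[1]], 0.25, 1)
  em <- eta_matrix(tab)
  f <- c(1, -1)
  fp <- rep(f, 2); fm <- rep(f, each = 2)
  D0 <- exp(-(fp - fm) * (em[1, 1] * fp - Conj(em[1, 1]) * fm))
  DN <- exp(-(fp - fm) * (em[2, 2] * fp - Conj(em[2, 2]) * fm))
  P10 <- exp(-outer(fp - fm, em[2, 1] * fp - Conj(em[2, 1]) * fm))
  Tref <- (DN * (K * P10)) %*% diag(D0)
  expect_lt(max(Mod(bb[[2]]$matrix - Tref)), 1e-12)
  ## enumeration guard
  expect_error(brute_force_map(sys, propagation_settings(
    dt = 0.25, n_steps = 12, dk_max = 12)), "guard")
})

test_that("maps preserve trace and Hermiticity at every time point", {
  fmo <- fmo_demo_system()
  set <- propagation_settings(dt = 10, n_steps = 6, dk_max = 2,
                              svd_cutoff = 1e-10)
  mm <- propagate_map(fmo, set)
  vecI <- as.vector(diag(4)) + 0i
  P <- as.vector(t(matrix(1:16, 4, 4)))
  set.seed(11)
  for (n in c(2, 4, 6)) {
    Tm <- mm[[n + 1]]$matrix
    expect_lt(max(Mod(Conj(vecI) %*% Tm - Conj(vecI))), 1e-8)
    ## Hermitian input -> Hermitian output
    A <- matrix(stats::rnorm(16) + 1i * stats::rnorm(16), 4)
    R <- A %*% Conj(t(A)); R <- R / sum(diag(R))
    out <- unvectorize(Tm %*% vectorize(R))
    expect_lt(max(Mod(out - Conj(t(out)))), 1e-10)
    ## complete positivity up to truncation noise
    expect_gt(min(eigen(choi_from_map(mm[[n + 1]])$matrix,
                        symmetric = TRUE, only.values = TRUE)$values), -1e-6)
  }
})

test_that("short-time dynamics matches exact discretized-bath propagation", {
  md <- ohmic_discrete_modes(0.1, 7.5, 2)
  db <- bath_spec("discrete", beta = 5, coupling_values = c(1, -1),
                  modes = md$w, mode_couplings = md$c)
  H <- matrix(c(0, 1, 1, 0), 2, 2)
  sysd <- system_spec(H, list(db), c(1, 0))
  set <- propagation_settings(dt = 0.25, n_steps = 3, dk_max = 3,
                              svd_cutoff = 1e-12)
  mm <- propagate_map(sysd, set)
  rho0 <- diag(c(1, 0)) + 0i
  exact <- exact_discrete_bath_rho(H, md, beta = 5, rho_s0 = rho0,
                                   times = (1:3) * 0.25, nlev = 12)
  for (n in 1:3) {
    rs <- unvectorize(mm[[n + 1]]$matrix %*% vectorize(rho0))
    expect_lt(max(Mod(rs - exact[[n]])), 5e-3)
  }
})

test_that("halving the time step leaves populations converged", {
  ## second-order discretization: dt = 0.25 is accurate to ~2e-3 and
  ## dt = 0.125 to a few 1e-4, so the 1e-3 convergence window applies
  ## from dt = 0.125 downward (memory length scaled to cover the same
  ## physical memory time)
  sys <- sb_demo_system()
  set1 <- propagation_settings(dt = 0.125, n_steps = 8, dk_max = 8,
                               svd_cutoff = 1e-11)
  set2 <- propagation_settings(dt = 0.0625, n_steps = 16, dk_max = 16,
                               svd_cutoff = 1e-11)
  rv <- vectorize(sys$initial_state)
  p1 <- vapply(propagate_map(sys, set1), function(S)
    Re(diag(unvectorize(S$matrix %*% rv))), numeric(2))
  p2 <- vapply(propagate_map(sys, set2), function(S)
    Re(diag(unvectorize(S$matrix %*% rv))), numeric(2))
  expect_lt(max(abs(p1 - p2[, seq(1, 17, by = 2)])), 1e-3)
})

test_that("untruncated propagation with an oversized memory is refused", {
  sys <- fmo_demo_system()
  set <- propagation_settings(dt = 5, n_steps = 8, dk_max = 8,
                              svd_cutoff = 0)
  expect_error(propagate_map(sys, set), "svd_cutoff")
})
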