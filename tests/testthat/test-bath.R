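test_that("spectral densities match their closed forms and constraints", {
  sb <- bath_spec("ohmic_exponential", coupling = 0.1, cutoff = 7.5,
                  beta = 5, coupling_values = c(1, -1))
  dr <- bath_spec("drude", coupling = 35, cutoff = 106.18,
                  beta = 1 / 208.5, coupling_values = c(1, 0, 0, 0))
  ## both families vanish at zero frequency
  expect_identical(evaluate_spectral_density(sb, 0), 0)
  expect_identical(evaluate_spectral_density(dr, 0), 0)
  ## grid-scan oracle: the Ohmic maximum sits at the cutoff frequency
  wg <- seq(0, 80, length.out = 40001)
  expect_equal(wg[which.max(evaluate_spectral_density(sb, wg))], 7.5,
               tolerance = 1e-3)
  ## Drude closed form at w = gamma: J(gamma) = lambda
  expect_equal(evaluate_spectral_density(dr, 106.18), 35, tolerance = 1e-12)
  ## non-negative, finite, vectorized
  expect_true(all(is.finite(evaluate_spectral_density(dr, wg))))
  expect_true(all(evaluate_spectral_density(sb, wg) >= 0))
  ## domain errors
  expect_error(evaluate_spectral_density(sb, -1), "non-negative")
  expect_error(bath_spec("ohmic_exponential", coupling = -1, cutoff = 1,
                         beta = 1, coupling_values = c(1, -1)))
  expect_error(bath_spec("drude", coupling = 1, cutoff = 0, beta = 1,
                         coupling_values = 1))
  expect_error(bath_spec("drude", coupling = 1, cutoff = 1,
                         coupling_values = 1), "exactly one")
})

test_that("bath response has the required symmetry and decay", {
  sb <- bath_spec("ohmic_exponential", coupling = 0.1, cutoff = 7.5,
                  beta = 5, coupling_values = c(1, -1))
  a <- bath_response(sb, c(-1.3, -0.4, 0, 0.4, 1.3))
  ## Im alpha(0) = 0; Re even, Im odd
  expect_equal(Im(a[3]), 0)
  expect_equal(Re(a[1:2]), Re(rev(a[4:5])), tolerance = 1e-12)
  expect_equal(Im(a[1:2]), -Im(rev(a[4:5])), tolerance = 1e-12)
  ## decay at long times (both families)
  expect_lt(Mod(bath_response(sb, 50)), 1e-4 * Mod(bath_response(sb, 0)))
  dr <- bath_spec("drude", coupling = 0.00659278, cutoff = 0.02,
                  temperature = 300, temperature_unit = "K",
                  coupling_values = 1)
  expect_lt(Mod(bath_response(dr, 500)), 1e-2 * Mod(bath_response(dr, 5)))
})

test_that("Drude bath response agrees with the Matsubara series oracle", {
  lam <- 35 * 2 * pi * 2.99792458e-5   # cm^-1 -> rad/fs
  gam <- 106.18 * 2 * pi * 2.99792458e-5
  beta <- convert_units(300, "K", "beta_radfs")
  dr <- bath_spec("drude", coupling = lam, cutoff = gam, beta = beta,
                  coupling_values = 1)
  for (t in c(2, 10, 40)) {
    aq <- bath_response(dr, t)
    am <- drude_matsubara_alpha(lam, gam, beta, t, nterms = 400)
    expect_lt(Mod(aq - am) / Mod(am), 2e-4)
  }
})

test_that("two independent quadrature schemes agree on alpha (ohmic)", {
  sb <- bath_spec("ohmic_exponential", coupling = 0.1, cutoff = 7.5,
                  beta = 5, coupling_values = c(1, -1))
  aq <- bath_response(sb, 1)
  ## fixed-order Gauss-Legendre on [0, 50 wc], 400 nodes
  g <- gauss_legendre01(400)
  w <- g$x * 375
  jw <- evaluate_spectral_density(sb, w)
  re <- 375 / pi * sum(g$w * jw / tanh(5 * w / 2) * cos(w))
  im <- -375 / pi * sum(g$w * jw * sin(w))
  expect_lt(Mod(aq - complex(real = re, imaginary = im)), 1e-8)
})

test_that("eta tables are stationary, bounded, and match 2-D quadrature", {
  sb <- bath_spec("ohmic_exponential", coupling = 0.1, cutoff = 7.5,
                  beta = 5, coupling_values = c(1, -1))
  dt <- 0.25
  tab <- eta_table(sb, dt = dt, n_steps = 6)
  em <- eta_matrix(tab)
  ## stationarity of interior pairs: eta_{3,2} = eta_{2,1}
  expect_equal(em[4, 3], em[3, 2], tolerance = 1e-12)
  expect_equal(em[5, 3], em[4, 2], tolerance = 1e-12)
  ## brute-force 2-D Gauss-Legendre quadrature of alpha over the two
  ## separation-1 interior windows
  g <- gauss_legendre01(24)
  t1 <- 1.5 * dt + g$x * dt
  t2 <- 0.5 * dt + g$x * dt
  am <- matrix(0i, 24, 24)
  for (i in 1:24) am[i, ] <- bath_response(sb, t1[i] - t2)
  eta_bf <- dt^2 * as.vector(t(g$w) %*% am %*% g$w)
  expect_lt(Mod(em[3, 2] - eta_bf), 1e-8)
  ## bound: |eta| <= double integral of |alpha| over the windows
  abs_bound <- dt^2 * as.vector(t(g$w) %*% Mod(am) %*% g$w)
  expect_lte(Mod(em[3, 2]), abs_bound)
  ## zero coupling kills every entry
  tab0 <- eta_table(bath_spec("ohmic_exponential", coupling = 0, cutoff = 7.5,
                              beta = 5, coupling_values = c(1, -1)),
                    dt = dt, n_steps = 4)
  expect_true(all(eta_matrix(tab0) == 0))
  ## end-point classes: the n = 1 window classes tile [0, dt] exactly, so
  ## their sum is the time-ordered double integral of alpha over the
  ## first step, int_0^dt dt' int_0^t' dt'' alpha(t'-t'')
  ##   = int_0^dt (dt - tau) alpha(tau) dtau
  em1 <- eta_matrix(tab, n_steps = 1)
  tau <- g$x * dt
  full <- dt * sum(g$w * (dt - tau) * bath_response(sb, tau))
  expect_lt(Mod(sum(em1) - full), 1e-6)
})

test_that("discrete-mode baths reproduce the mode-sum response exactly", {
  md <- ohmic_discrete_modes(0.1, 7.5, 2)
  db <- bath_spec("discrete", beta = 5, coupling_values = c(1, -1),
                  modes = md$w, mode_couplings = md$c)
  t <- 0.7
  direct <- sum(md$c^2 / (2 * md$w) *
                  (cos(md$w * t) / tanh(5 * md$w / 2) - 1i * sin(md$w * t)))
  expect_lt(Mod(bath_response(db, t) - direct), 1e-14)
})
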