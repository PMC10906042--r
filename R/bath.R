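#' Bath specification
#'
#' Describes a harmonic bath bilinearly coupled to the system through a
#' coupling operator that is diagonal in the propagation basis.  Two
#' continuum spectral-density families are supported,
#' \deqn{J_{ohmic}(\omega) = (\pi/2)\,\xi\,\omega\, e^{-\omega/\omega_c},}
#' \deqn{J_{drude}(\omega) = 2\lambda\gamma\omega / (\omega^2 + \gamma^2),}
#' plus a `discrete` family (a finite set of modes with couplings
#' \eqn{c_j}, equivalent to \eqn{J(\omega) = (\pi/2)\sum_j (c_j^2/\omega_j)
#' \delta(\omega-\omega_j)}) used to validate the pipeline against exact
#' finite-bath reference models.
#'
#' Units are the internal system (`hbar = k_B = 1`): frequencies and
#' energies share one unit, `beta` is its inverse.  The finite-temperature
#' bath response function is
#' \deqn{\alpha(t) = \frac{1}{\pi}\int_0^\infty J(\omega)\left[
#'   \coth(\beta\omega/2)\cos\omega t - i \sin\omega t\right]d\omega.}
#' An overall multiplicative `prefactor` (default 1) is exposed as an
#' advanced override because prefactor conventions for \eqn{J} and
#' \eqn{\alpha} differ across the literature; the default convention is
#' validated internally against exact discretized-bath propagation.
#'
#' @param family `"ohmic_exponential"`, `"drude"` or `"discrete"`.
#' @param coupling Kondo parameter xi (ohmic, dimensionless) or
#'   reorganization energy lambda (drude, energy units).  Ignored for
#'   `discrete`.
#' @param cutoff cutoff frequency omega_c (ohmic) or phonon relaxation
#'   rate gamma (drude).  Ignored for `discrete`.
#' @param beta inverse temperature (1/energy).  Exactly one of `beta`
#'   and `temperature` must be given; `temperature` is interpreted
#'   through `temperature_unit`.
#' @param coupling_values numeric vector of length d: eigenvalues of the
#'   system-bath coupling operator in the propagation basis (e.g. c(1,-1)
#'   for a sigma_z-coupled two-level system; a site-occupation indicator
#'   for site-local baths).
#' @param temperature optional temperature in `temperature_unit`.
#' @param temperature_unit `"internal"` (1/beta directly) or `"K"`
#'   (requires internal units of rad/fs).
#' @param modes,mode_couplings discrete-family mode frequencies
#'   \eqn{\omega_j} and couplings \eqn{c_j}.
#' @param prefactor advanced override scaling J(omega) (and hence
#'   alpha and all eta coefficients) by a constant.
#' @return object of class `bath_spec`.
#' @export
bath_spec <- function(family = c("ohmic_exponential", "drude", "discrete"),
                      coupling = NULL, cutoff = NULL, beta = NULL,
                      coupling_values, temperature = NULL,
                      temperature_unit = c("internal", "K"),
                      modes = NULL, mode_couplings = NULL,
                      prefactor = 1) {
  family <- match.arg(family)
  temperature_unit <- match.arg(temperature_unit)
  if (is.null(beta) == is.null(temperature))
    stop("exactly one of `beta` and `temperature` must be given")
  if (!is.null(temperature)) {
    if (temperature <= 0) stop("temperature must be positive")
    beta <- if (temperature_unit == "K") {
      convert_units(temperature, "K", "beta_radfs")
    } else 1 / temperature
  }
  if (beta <= 0) stop("beta must be positive")
  if (family == "discrete") {
    if (is.null(modes) || is.null(mode_couplings) ||
        length(modes) != length(mode_couplings))
      stop("discrete family requires matching `modes` and `mode_couplings`")
    if (any(modes <= 0)) stop("mode frequencies must be positive")
    coupling <- NA_real_
    cutoff <- NA_real_
  } else {
    if (is.null(coupling) || is.null(cutoff))
      stop("continuum families require `coupling` and `cutoff`")
    if (coupling < 0) stop("coupling must be non-negative")
    if (cutoff <= 0) stop("cutoff must be positive")
  }
  if (missing(coupling_values) || length(coupling_values) < 1)
    stop("`coupling_values` (one per system basis state) is required")
  structure(list(family = family, coupling = coupling, cutoff = cutoff,
                 beta = beta, coupling_values = as.numeric(coupling_values),
                 modes = modes, mode_couplings = mode_couplings,
                 prefactor = prefactor),
            class = "bath_spec")
}

#' @export
print.bath_spec <- function(x, ...) {
  cat("<bath_spec> family:", x$family, "\n")
  if (x$family == "discrete") {
    cat("  modes:", paste(signif(x$modes, 4), collapse = ", "), "\n")
  } else {
    cat("  coupling:", x$coupling, " cutoff:", x$cutoff, "\n")
  }
  cat("  beta:", x$beta, "\n")
  cat("  coupling_values:", paste(x$coupling_values, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the spectral density J(omega)
#'
#' @param spec a [bath_spec()].
#' @param omega non-negative frequency (vectorized).
#' @return J(omega), same length as `omega`.
#' @export
evaluate_spectral_density <- function(spec, omega) {
  stopifnot(inherits(spec, "bath_spec"))
  if (any(omega < 0)) stop("omega must be non-negative")
  omega * j_over_omega(spec, omega)
}

## J(omega)/omega -- analytic at omega = 0 for all families, which is what
## makes the coth(beta*omega/2) * J(omega) product regular at the origin.
j_over_omega <- function(spec, omega) {
  spec$prefactor * switch(spec$family,
    ohmic_exponential = (pi / 2) * spec$coupling * exp(-omega / spec$cutoff),
    drude = 2 * spec$coupling * spec$cutoff / (omega^2 + spec$cutoff^2),
    discrete = stop("discrete spectral density is a sum of delta functions; ",
                    "use the quadrature weights directly")
  )
}

## omega * coth(beta*omega/2), series-expanded near omega = 0:
## x*coth(x) = 1 + x^2/3 - x^4/45 + ...  with x = beta*omega/2.
omega_coth <- function(beta, omega) {
  x <- beta * omega / 2
  out <- numeric(length(omega))
  small <- abs(x) < 1e-4
  out[small] <- (2 / beta) * (1 + x[small]^2 / 3)
  out[!small] <- omega[!small] / tanh(x[!small])
  out
}

## Core quadrature: eta-like quantities share the form
##   (1/pi) * Int_0^inf J(w) [ coth(beta w/2) A(w) - i B(w) ] dw
## with family-specific handling:
##  - continuum: adaptive quadrature on [0, omega_max], omega_max = 50*cutoff
##    (integrands decay exponentially for the ohmic family and algebraically,
##    with the window kernels supplying extra 1/w^2, for drude);
##  - discrete: exact weighted sum over modes with weight c_j^2/(2 w_j).
## A and B must be vectorized and finite at w = 0.
quad_bath <- function(spec, A, B, rel_tol = 1e-10, subdivisions = 2000L) {
  if (spec$family == "discrete") {
    w <- spec$modes
    wt <- spec$prefactor * spec$mode_couplings^2 / (2 * w)
    re <- sum(wt * (1 / tanh(spec$beta * w / 2)) * A(w))
    im <- sum(wt * B(w))
    return(complex(real = re, imaginary = -im))
  }
  wmax <- 50 * spec$cutoff
  if (spec$coupling == 0) return(0 + 0i)
  f_re <- function(w) j_over_omega(spec, w) * omega_coth(spec$beta, w) * A(w)
  f_im <- function(w) j_over_omega(spec, w) * w * B(w)
  int1 <- stats::integrate(f_re, 0, wmax, rel.tol = rel_tol,
                           subdivisions = subdivisions, stop.on.error = FALSE)
  int2 <- stats::integrate(f_im, 0, wmax, rel.tol = rel_tol,
                           subdivisions = subdivisions, stop.on.error = FALSE)
  for (it in list(int1, int2)) {
    if (!it$message %in% c("OK", "roundoff error was detected")) {
      stop("bath quadrature failed: ", it$message,
           " (abs.error = ", signif(it$abs.error, 3), ")")
    }
  }
  complex(real = int1$value / pi, imaginary = -int2$value / pi)
}

#' Finite-temperature bath response function alpha(t)
#'
#' \eqn{\alpha(t) = (1/\pi)\int_0^\infty J(\omega)[\coth(\beta\omega/2)
#' \cos\omega t - i\sin\omega t]\,d\omega}.  The real part is even and the
#' imaginary part odd in t.  Note that for the Drude family the real part
#' diverges logarithmically at exactly t = 0 (J falls off only as
#' 1/omega); window-integrated influence coefficients remain finite.
#'
#' @param spec a [bath_spec()].
#' @param t time (scalar or vector).
#' @return complex alpha(t), same length as `t`.
#' @export
bath_response <- function(spec, t) {
  stopifnot(inherits(spec, "bath_spec"))
  vapply(t, function(ti) {
    s <- sign(ti); ta <- abs(ti)
    a <- quad_bath(spec, function(w) cos(w * ta), function(w) sin(w * ta))
    ## Drude: J(w) coth(beta w/2) -> 2*lambda*gamma/w at large w, so the
    ## truncated tail above omega_max contributes O(1/(omega_max t)); add
    ## it analytically through the cosine/sine integrals.
    if (spec$family == "drude" && spec$coupling > 0 && ta > 0) {
      W <- 50 * spec$cutoff
      lg <- spec$prefactor * 2 * spec$coupling * spec$cutoff
      a <- a + complex(real = -(lg / pi) * pracma::Ci(W * ta),
                       imaginary = -(lg / pi) * (pi / 2 - pracma::Si(W * ta)))
    }
    complex(real = Re(a), imaginary = s * Im(a))
  }, complex(1))
}

## ---- time-window kernels -------------------------------------------------
## F_W(w) = Int_a^b e^{i w t} dt = (b-a) e^{i w (a+b)/2} sinc(w (b-a)/2),
## numerically stable at w -> 0.
window_fourier <- function(w, a, b) {
  h <- (b - a) / 2
  x <- w * h
  s <- ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)
  (b - a) * exp(1i * w * (a + b) / 2) * s
}

## Off-diagonal window pair: eta = Int_{W1} dt' Int_{W2} dt'' alpha(t'-t''),
## W1 strictly later than W2.  With G = F_{W1} conj(F_{W2}),
##   eta = (1/pi) Int J(w) [coth Re G - i Im G] dw.
eta_window_pair <- function(spec, w1, w2) {
  quad_bath(spec,
            function(w) Re(window_fourier(w, w1[1], w1[2]) *
                           Conj(window_fourier(w, w2[1], w2[2]))),
            function(w) Im(window_fourier(w, w1[1], w1[2]) *
                           Conj(window_fourier(w, w2[1], w2[2]))))
}

## Diagonal window: eta = Int_a^b dt' Int_a^{t'} dt'' alpha(t'-t'')
##   = Int_0^L (L - tau) alpha(tau) dtau,  L = b - a, giving kernels
##   A(w) = (1 - cos wL)/w^2 = (L^2/2) sinc^2(wL/2)
##   B(w) = (wL - sin wL)/w^2  (series for small wL).
eta_window_diag <- function(spec, L) {
  A <- function(w) {
    x <- w * L / 2
    s <- ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)
    (L^2 / 2) * s^2
  }
  B <- function(w) {
    x <- w * L
    ifelse(abs(x) < 1e-4,
           w * L^3 / 6 * (1 - x^2 / 20),
           (x - sin(x)) / pmax(w, .Machine$double.xmin)^2)
  }
  quad_bath(spec, A, B)
}

## window of discretized path point k in an N-step trajectory with step dt:
## interior points own [t_k - dt/2, t_k + dt/2]; the ends own half windows,
## so the windows tile [0, N dt] exactly.
path_window <- function(k, n_steps, dt) {
  a <- max(0, k * dt - dt / 2)
  b <- min(n_steps * dt, k * dt + dt / 2)
  c(a, b)
}

#' Discretized influence-functional coefficients
#'
#' Tabulates the double time-window integrals of the bath response
#' function alpha over the discretization windows of an n-step path,
#' \deqn{\eta_{kk'} = \int_{W_k} dt' \int_{W_{k'}} dt''\, \alpha(t'-t''),}
#' (ordered \eqn{t' > t''} on the diagonal), in the quasi-adiabatic
#' propagator tradition.  Interior windows are centered on the path points
#' with full width dt; the two end points own half windows, so the windows
#' tile `[0, n_steps*dt]` exactly.  Interior-pair entries are stationary
#' (depend only on k - k'); entries involving an end point form the
#' special end-point classes.
#'
#' @param spec a [bath_spec()].
#' @param dt time step (> 0).
#' @param n_steps number of propagation steps (>= 1).
#' @param kmax optional memory truncation: entries with k - k' > kmax are
#'   not computed (treated as zero).  Defaults to `n_steps`.
#' @return object of class `eta_table` with components
#'   `int` (interior pair, by separation 1..kmax), `int_diag`,
#'   `k0` (interior k paired with the initial half window, by separation),
#'   `Nk` (terminal half window paired with interior k, by separation),
#'   `N0` (terminal paired with initial, by total length n = 1..kmax),
#'   `end_diag` (diagonal of a half window, identical for both ends),
#'   plus `dt`, `n_steps`, `kmax`.
#' @export
eta_table <- function(spec, dt, n_steps, kmax = n_steps) {
  stopifnot(inherits(spec, "bath_spec"), dt > 0, n_steps >= 1)
  kmax <- min(kmax, n_steps)
  N <- n_steps
  intr <- function(k) path_window(k, N + 2L, dt)  # interior window anywhere
  w0 <- c(0, dt / 2)
  zero_b <- (spec$family != "discrete" && spec$coupling == 0) ||
    (spec$family == "discrete" && all(spec$mode_couplings == 0))
  cz <- function(n) rep(0 + 0i, n)
  if (zero_b) {
    tab <- list(int = cz(kmax), int_diag = 0 + 0i, k0 = cz(kmax),
                Nk = cz(kmax), N0 = cz(kmax), end_diag = 0 + 0i)
  } else {
    ## stationarity: interior pairs depend on separation only
    int <- vapply(seq_len(kmax), function(s)
      eta_window_pair(spec, intr(2L + s), intr(2L)), complex(1))
    int_diag <- eta_window_diag(spec, dt)
    k0 <- vapply(seq_len(kmax), function(k)
      eta_window_pair(spec, intr(k), w0), complex(1))
    ## terminal half window [t_N - dt/2, t_N] vs interior k = N - s:
    ## translate to [s*dt - dt/2, s*dt] vs [-dt/2, dt/2] -> shift by dt/2
    Nk <- vapply(seq_len(kmax), function(s)
      eta_window_pair(spec, c(s * dt - dt / 2, s * dt), c(-dt / 2, dt / 2)),
      complex(1))
    N0 <- vapply(seq_len(kmax), function(n)
      eta_window_pair(spec, c(n * dt - dt / 2, n * dt), w0), complex(1))
    end_diag <- eta_window_diag(spec, dt / 2)
    tab <- list(int = int, int_diag = int_diag, k0 = k0, Nk = Nk, N0 = N0,
                end_diag = end_diag)
  }
  structure(c(tab, list(dt = dt, n_steps = n_steps, kmax = kmax)),
            class = "eta_table")
}

#' Dense lower-triangular eta matrix for an n-step trajectory
#'
#' Expands an [eta_table()] into the full (n+1) x (n+1) lower-triangular
#' complex matrix of coefficients for a trajectory read out at
#' `t = n_steps * dt`, applying the end-point window classes of both ends.
#' Entries beyond the memory truncation `kmax` are zero.
#'
#' @param tab an `eta_table`.
#' @param n_steps trajectory length; defaults to (and must not exceed)
#'   `tab$n_steps`.
#' @return complex matrix `eta[k+1, k'+1]`, k >= k', 0-based path indices.
#' @export
eta_matrix <- function(tab, n_steps = tab$n_steps) {
  stopifnot(inherits(tab, "eta_table"), n_steps <= tab$n_steps, n_steps >= 1)
  N <- n_steps
  m <- matrix(0 + 0i, N + 1L, N + 1L)
  for (k in 0:N) {
    for (kp in 0:k) {
      s <- k - kp
      if (s > tab$kmax) next
      m[k + 1L, kp + 1L] <-
        if (k == kp) {
          if (k == 0L || k == N) tab$end_diag else tab$int_diag
        } else if (k == N && kp == 0L) {
          tab$N0[s]
        } else if (kp == 0L) {
          tab$k0[s]
        } else if (k == N) {
          tab$Nk[s]
        } else {
          tab$int[s]
        }
    }
  }
  m
}
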