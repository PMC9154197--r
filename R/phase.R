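#' Linearization of the mean-field system along the limit cycle
#'
#' Evaluates the analytic 8x8 Jacobian at the point of the cycle with the
#' given phase (time along the orbit, `[0, T*)`).
#'
#' @param cycle a `ping_cycle`.
#' @param phase phase in time units.
#' @return 8x8 Jacobian matrix.
#' @export
linearize_along_cycle <- function(cycle, phase) {
  meanfield_jacobian(interp_cycle(cycle, phase), cycle$params)
}

#' Spectral derivative of periodic samples
#'
#' FFT-based differentiation of uniform samples of a smooth periodic
#' function over one period.
#'
#' @param x numeric vector of samples over `[0, period)`.
#' @param period the period (default 1).
#' @param order derivative order (1 or 2).
#' @return Derivative samples at the same grid.
#' @export
fft_derivative <- function(x, period = 1, order = 1) {
  n <- length(x)
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k[n / 2 + 1] <- 0  # drop the Nyquist mode
  w <- (2i * pi / period) * k
  Re(fft(fft(x) * w^order, inverse = TRUE)) / n
}

#' Solve the adjoint equation for the infinitesimal phase response curve
#'
#' Integrates `dZ/dt = -M^T(gamma(t)) Z` backward in time along the limit
#' cycle, for which the sought periodic solution is attracting, renormalizing
#' once per period until successive periods agree; the result is scaled to
#' satisfy the normalization `Z(t) . gamma'(t) = 1` (checked on the whole
#' grid).  The combined voltage component `Z_ei = Z_Ve + Z_Vi`, used by the
#' phase equation when both populations receive the drive, is cached together
#' with its FFT-based derivatives.
#'
#' @param cycle a `ping_cycle`.
#' @param n_theta number of stored phase points (default 1024).
#' @param n_fine internal cycle resolution used by the integrator.
#' @param tol integration tolerance.
#' @param max_periods maximum number of backward periods.
#' @param conv_tol successive-period convergence tolerance.
#' @return Object of class `ping_iprc` with fields `theta` (time units),
#'   `theta_norm`, `Z` (n x 8), `Zei`, `dZei`, `d2Zei`, `Tstar`,
#'   `normalization_residual`.
#' @export
solve_adjoint <- function(cycle, n_theta = 1024, n_fine = 4096,
                          tol = 1e-12, max_periods = 80, conv_tol = 1e-9) {
  stopifnot(inherits(cycle, "ping_cycle"))
  Tstar <- cycle$period
  ts <- seq(0, Tstar, length.out = n_fine + 1)[1:n_fine]
  cf <- as_cpp_forcing(NULL)
  states <- cpp_mf_integrate(as.numeric(cycle$x0), ts,
                             unclass(cycle$params), cf, NULL, tol)
  colnames(states) <- state_names
  derivs <- mf_derivs_matrix(states, ts, cycle$params, NULL)
  ad <- cpp_adjoint(states, derivs, Tstar, unclass(cycle$params),
                    tol, max_periods, conv_tol)
  if (!ad$converged)
    stop("adjoint iteration did not converge within max_periods")
  Zf <- ad$Z
  resid <- rowSums(Zf * derivs) - 1
  keep <- seq(1, n_fine, by = n_fine / n_theta)
  Z <- Zf[keep, , drop = FALSE]
  colnames(Z) <- paste0("Z_", state_names)
  Zei <- Z[, "Z_V_e"] + Z[, "Z_V_i"]
  structure(list(theta = ts[keep], theta_norm = ts[keep] / Tstar,
                 Z = Z, Zei = Zei,
                 dZei = fft_derivative(Zei, Tstar, 1),
                 d2Zei = fft_derivative(Zei, Tstar, 2),
                 Tstar = Tstar,
                 normalization_residual = max(abs(resid)),
                 periods_used = ad$periods),
            class = "ping_iprc")
}

#' @export
print.ping_iprc <- function(x, ...) {
  cat(sprintf("iPRC on %d phase points, T* = %.4f ms\n",
              length(x$theta), x$Tstar))
  cat(sprintf("  Z_ei range [%.4g, %.4g]; normalization residual %.2e\n",
              min(x$Zei), max(x$Zei), x$normalization_residual))
  invisible(x)
}

#' @export
plot.ping_iprc <- function(x, ...) {
  matplot(x$theta_norm, cbind(x$Z[, "Z_V_e"], x$Z[, "Z_V_i"], x$Zei),
          type = "l", lty = 1, col = c("red", "blue", "purple"),
          xlab = expression(theta / T^"*"), ylab = "iPRC", ...)
  abline(h = 0, col = "grey")
  legend("topleft", c("Z_Ve", "Z_Vi", "Z_ei"),
         col = c("red", "blue", "purple"), lty = 1, bty = "n")
  invisible(x)
}

# periodic cubic Hermite interpolation on a uniform grid (values + slopes)
periodic_hermite <- function(t, vals, ders, period) {
  n <- length(vals); h <- period / n
  s <- t %% period
  j <- pmin(floor(s / h), n - 1)
  j1 <- (j + 1) %% n
  u <- (s - j * h) / h
  (2 * u^3 - 3 * u^2 + 1) * vals[j + 1] + (u^3 - 2 * u^2 + u) * h * ders[j + 1] +
    (-2 * u^3 + 3 * u^2) * vals[j1 + 1] + (u^3 - u^2) * h * ders[j1 + 1]
}

#' Interpolate the iPRC voltage component
#'
#' @param iprc a `ping_iprc`.
#' @param theta phase(s) in time units (wrapped mod `T*`).
#' @param component `"ei"` for `Z_Ve + Z_Vi` (drive to both populations) or
#'   `"e"` for `Z_Ve` alone (E-only drive).
#' @return Interpolated iPRC value(s).
#' @export
iprc_eval <- function(iprc, theta, component = c("ei", "e")) {
  component <- match.arg(component)
  if (component == "ei")
    periodic_hermite(theta, iprc$Zei, iprc$dZei, iprc$Tstar)
  else {
    z <- iprc$Z[, "Z_V_e"]
    periodic_hermite(theta, z, fft_derivative(z, iprc$Tstar, 1), iprc$Tstar)
  }
}

#' Derivative of the cached `Z_ei` by spectral differentiation
#'
#' @param iprc a `ping_iprc`.
#' @return Samples of `dZ_ei/dtheta` on the iPRC phase grid.
#' @export
iprc_derivative_fft <- function(iprc) iprc$dZei

#' Right-hand side of the phase equation
#'
#' `dtheta/dt = 1 + g(t) * Z(theta)`, where `Z` is `Z_Ve + Z_Vi` when the
#' drive targets both populations and `Z_Ve` for an E-only drive.
#'
#' @param theta oscillator phase (time units, any lift).
#' @param t time (ms).
#' @param iprc a `ping_iprc`.
#' @param forcing a [forcing_spec()].
#' @return `dtheta/dt`.
#' @export
phase_ode_rhs <- function(theta, t, iprc, forcing) {
  comp <- if (forcing$to_e && forcing$to_i) "ei" else "e"
  1 + forcing_eval(forcing, t) * iprc_eval(iprc, theta, comp)
}

# pack the relevant iPRC component for the C++ phase integrator
zpack <- function(iprc, forcing = NULL) {
  both <- is.null(forcing) || (forcing$to_e && forcing$to_i)
  if (both) {
    list(Tstar = iprc$Tstar, z = iprc$Zei, zd = iprc$dZei, zd2 = iprc$d2Zei)
  } else {
    z <- iprc$Z[, "Z_V_e"]
    list(Tstar = iprc$Tstar, z = z,
         zd = fft_derivative(z, iprc$Tstar, 1),
         zd2 = fft_derivative(z, iprc$Tstar, 2))
  }
}

# integrate the phase equation, recording the (unwrapped) lift at rec_times
phase_flow <- function(theta0, t0, t1, rec_times, iprc, forcing,
                       tol = 1e-10, with_var = FALSE) {
  cpp_phase_flow(theta0, t0, t1, as.numeric(rec_times),
                 zpack(iprc, forcing), as_cpp_forcing(forcing),
                 tol, with_var)
}

#' Direct-perturbation estimate of the voltage iPRC
#'
#' Applies a small kick `eps` to one voltage coordinate at given phases of
#' the cycle and measures the asymptotic phase shift from the displaced
#' times of the later `V_e` maxima.  `shift / eps` is an independent check
#' of the adjoint-computed iPRC component (its defining property).
#'
#' @param cycle a `ping_cycle`.
#' @param phases phases (time units in `[0, T*)`) at which to kick.
#' @param eps kick size (default 1e-4).
#' @param component state coordinate kicked (default `V_e`).
#' @param n_periods relaxation horizon in periods.
#' @return Estimated iPRC values `shift/eps` at the requested phases.
#' @export
perturbation_phase_shift <- function(cycle, phases, eps = 1e-4,
                                     component = "V_e", n_periods = 20) {
  ci <- match(component, state_names)
  Tstar <- cycle$period
  cf <- as_cpp_forcing(NULL)
  vapply(phases, function(ph) {
    x <- as.numeric(interp_cycle(cycle, ph))
    x[ci] <- x[ci] + eps
    ev <- cpp_mf_events(x, 0, n_periods * Tstar, unclass(cycle$params),
                        cf, NULL, 1e-12)
    ve <- ev$states[, 2]
    main <- ve >= max(ve) - max(0.25 * diff(range(ve)), 1e-6)
    tl <- tail(ev$times[main], 1)
    # unperturbed reference: V_e maxima at (T* - ph) + k T*
    delta <- (((Tstar - ph) - tl) %% Tstar)
    if (delta > Tstar / 2) delta <- delta - Tstar
    delta / eps
  }, numeric(1))
}
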