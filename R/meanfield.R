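#' Right-hand side of the exact E-I mean-field model
#'
#' The 8-dimensional vector field for the mean firing rates, mean voltages
#' and synaptic variables of the coupled E and I populations.  A periodic
#' drive `g(t)` (and an optional square pulse, E-only) adds directly to the
#' voltage derivatives: the external current is `I_ext = Ibar + tau * g(t)`,
#' and the `tau` cancels against the `1/tau` of the voltage equation.
#'
#' @param state named or unnamed numeric vector of length 8 in the order
#'   `r_e, V_e, S_ee, S_ei, r_i, V_i, S_ie, S_ii`.
#' @param t time (ms); only relevant with time-dependent forcing.
#' @param params a [ping_params()] object.
#' @param forcing optional [forcing_spec()].
#' @return Named derivative vector of length 8.
#' @export
meanfield_rhs <- function(state, t = 0, params = ping_params(),
                          forcing = NULL) {
  params <- as_ping_params(params)
  if (any(!is.finite(state)))
    stop("non-finite state passed to meanfield_rhs (blow-up?)")
  dy <- cpp_mf_rhs(as.numeric(state), t, unclass(params),
                   as_cpp_forcing(forcing), NULL)
  setNames(dy, state_names)
}

# vectorized over rows; used to attach derivatives to sampled trajectories
mf_derivs_matrix <- function(states, times, params, forcing = NULL) {
  p <- params
  re <- states[, 1]; Ve <- states[, 2]; See <- states[, 3]; Sei <- states[, 4]
  ri <- states[, 5]; Vi <- states[, 6]; Sie <- states[, 7]; Sii <- states[, 8]
  g <- if (is.null(forcing)) 0 else forcing_eval(forcing, times)
  pv <- if (!is.null(forcing) && !is.null(forcing$pulse))
    square_pulse_eval(forcing$pulse, times) else 0
  ge <- if (is.null(forcing) || forcing$to_e) g else 0
  gi <- if (is.null(forcing) || forcing$to_i) g else 0
  d <- cbind(
    p$delta_e / (pi * p$tau_e^2) + 2 * re * Ve / p$tau_e,
    (Ve^2 + p$eta_e + p$Ie_ext_bar - (p$tau_e * pi * re)^2) / p$tau_e +
      See - Sei + ge + pv,
    (-See + p$J_ee * re) / p$tau_se,
    (-Sei + p$J_ei * ri) / p$tau_si,
    p$delta_i / (pi * p$tau_i^2) + 2 * ri * Vi / p$tau_i,
    (Vi^2 + p$eta_i + p$Ii_ext_bar - (p$tau_i * pi * ri)^2) / p$tau_i +
      Sie - Sii + gi,
    (-Sie + p$J_ie * re) / p$tau_se,
    (-Sii + p$J_ii * ri) / p$tau_si)
  colnames(d) <- state_names
  d
}

#' Jacobian of the mean-field vector field
#'
#' Analytic linearization of the autonomous part of the system (the periodic
#' drive is state-independent, so it does not enter).  Note the
#' `-(tau*pi*r)^2` terms couple the rates into the voltage equations.
#'
#' @inheritParams meanfield_rhs
#' @return 8x8 Jacobian matrix.
#' @export
meanfield_jacobian <- function(state, params = ping_params()) {
  p <- as_ping_params(params)
  re <- state[1]; Ve <- state[2]; ri <- state[5]; Vi <- state[6]
  J <- matrix(0, 8, 8, dimnames = list(state_names, state_names))
  J[1, 1] <- 2 * Ve / p$tau_e
  J[1, 2] <- 2 * re / p$tau_e
  J[2, 1] <- -2 * p$tau_e * pi^2 * re
  J[2, 2] <- 2 * Ve / p$tau_e
  J[2, 3] <- 1; J[2, 4] <- -1
  J[3, 1] <- p$J_ee / p$tau_se; J[3, 3] <- -1 / p$tau_se
  J[4, 5] <- p$J_ei / p$tau_si; J[4, 4] <- -1 / p$tau_si
  J[5, 5] <- 2 * Vi / p$tau_i
  J[5, 6] <- 2 * ri / p$tau_i
  J[6, 5] <- -2 * p$tau_i * pi^2 * ri
  J[6, 6] <- 2 * Vi / p$tau_i
  J[6, 7] <- 1; J[6, 8] <- -1
  J[7, 1] <- p$J_ie / p$tau_se; J[7, 7] <- -1 / p$tau_se
  J[8, 5] <- p$J_ii / p$tau_si; J[8, 8] <- -1 / p$tau_si
  J
}

#' Integrate the mean-field model
#'
#' Adaptive Runge-Kutta (Dormand-Prince 5(4)) integration with dense output.
#'
#' @param init initial state (see [network_state()]).
#' @param times output times (ms), increasing; integration runs from
#'   `times[1]` to `times[length(times)]`.
#' @param params a [ping_params()] object.
#' @param forcing optional [forcing_spec()].
#' @param drive_schedule optional step protocol for the tonic drives: a
#'   data.frame/matrix with columns `t, Ie, Ii`; from each `t` onward the
#'   listed tonic drives replace the baseline values.
#' @param tol local error tolerance (default `1e-12`).
#' @return A data.frame with column `t` and the 8 state columns.
#' @export
integrate_meanfield <- function(init, times, params = ping_params(),
                                forcing = NULL, drive_schedule = NULL,
                                tol = 1e-12) {
  params <- as_ping_params(params)
  stopifnot(length(init) == 8, !is.unsorted(times))
  if (any(!is.finite(init))) stop("non-finite initial state")
  sched <- if (is.null(drive_schedule)) NULL else
    as.matrix(drive_schedule[, 1:3])
  if (length(times) == 1 || diff(range(times)) == 0) {
    out <- matrix(rep(as.numeric(init), each = length(times)),
                  nrow = length(times))
  } else {
    out <- cpp_mf_integrate(as.numeric(init), as.numeric(times),
                            unclass(params), as_cpp_forcing(forcing),
                            sched, tol)
  }
  colnames(out) <- state_names
  data.frame(t = times, out)
}

# flow map (optionally with the 8x8 variational matrix)
mf_flow <- function(x, t0, t1, params, forcing = NULL, sched = NULL,
                    tol = 1e-12, with_var = FALSE) {
  cpp_mf_flow(as.numeric(x), t0, t1, unclass(params),
              as_cpp_forcing(forcing), sched, tol, with_var)
}

#' Locate the limit cycle of the unforced mean-field model
#'
#' Integrates past a transient, detects oscillations from the peak-to-trough
#' amplitude of `V_e`, estimates the period from successive global `V_e`
#' maxima, and refines orbit and period with a Newton (shooting) step on the
#' Poincare section `dV_e/dt = 0, d2V_e/dt2 < 0`.  The returned cycle is
#' re-phased so that phase 0 is the global maximum of `V_e`.
#'
#' If no oscillation survives the transient a `ping_no_cycle` object is
#' returned rather than an error, so parameter sweeps remain scan-friendly.
#'
#' @param params a [ping_params()] object.
#' @param t_transient transient to discard (ms); default 50 putative periods
#'   of a 30 ms gamma cycle.
#' @param tol integration tolerance.
#' @param n_samples number of uniform samples stored along the cycle.
#' @param amp_tol oscillation threshold on the `V_e` peak-to-trough amplitude
#'   over the last 5 putative periods.
#' @param init optional initial state.
#' @return A `ping_cycle` object (fields `period`, `t`, `states`, `derivs`,
#'   `x0`, `floquet`) or a `ping_no_cycle` object.
#' @examples
#' \donttest{
#' cyc <- find_limit_cycle(ping_params())
#' cyc$period   # about 24.234 ms
#' }
#' @export
find_limit_cycle <- function(params = ping_params(), t_transient = 1500,
                             tol = 1e-12, n_samples = 1024, amp_tol = 1e-4,
                             init = network_state()) {
  params <- as_ping_params(params)
  cf <- as_cpp_forcing(NULL)
  y1 <- cpp_mf_flow(as.numeric(init), 0, t_transient, unclass(params),
                    cf, NULL, 1e-10, FALSE)$y
  # oscillation test: V_e amplitude over a 5-period window (~150 ms)
  tw <- seq(0, 150, by = 0.05)
  win <- cpp_mf_integrate(y1, tw, unclass(params), cf, NULL, 1e-10)
  amp <- diff(range(win[, 2]))
  if (amp < amp_tol) {
    return(structure(list(params = params, amplitude = amp,
                          state = win[nrow(win), ]),
                     class = "ping_no_cycle"))
  }
  ev <- cpp_mf_events(y1, 0, 400, unclass(params), cf, NULL, 1e-11)
  if (length(ev$times) < 4)
    return(structure(list(params = params, amplitude = amp,
                          state = ev$y_end), class = "ping_no_cycle"))
  # keep only the global V_e maxima (the trace may carry a secondary local
  # maximum within one cycle)
  ve <- ev$states[, 2]
  main <- ve >= max(ve) - max(0.25 * diff(range(ve)), 1e-6)
  tt <- ev$times[main]
  if (length(tt) < 3)
    return(structure(list(params = params, amplitude = amp,
                          state = ev$y_end), class = "ping_no_cycle"))
  T0 <- mean(diff(tail(tt, 5)))
  x0 <- ev$states[main, , drop = FALSE][sum(main), ]

  ns <- newton_cycle(x0, T0, params, tol = tol)
  x0 <- ns$x; Tstar <- ns$T

  ts <- seq(0, Tstar, length.out = n_samples + 1)[1:n_samples]
  states <- cpp_mf_integrate(x0, ts, unclass(params), cf, NULL, tol)
  colnames(states) <- state_names
  derivs <- mf_derivs_matrix(states, ts, params, NULL)
  structure(list(params = params, period = Tstar, t = ts,
                 states = states, derivs = derivs, x0 = setNames(x0, state_names),
                 floquet = ns$floquet, residual = ns$residual,
                 tol = tol),
            class = "ping_cycle")
}

# Newton refinement of a periodic orbit of the autonomous system: unknowns
# (x, T), equations Phi_T(x) - x = 0 plus phase condition dVe/dt(x) = 0.
newton_cycle <- function(x0, T0, params, tol = 1e-12, max_iter = 25) {
  x <- as.numeric(x0); T <- T0
  cf <- as_cpp_forcing(NULL)
  res <- Inf
  for (it in seq_len(max_iter)) {
    fl <- cpp_mf_flow(x, 0, T, unclass(params), cf, NULL, tol, TRUE)
    FX <- fl$y - x
    fx <- cpp_mf_rhs(x, 0, unclass(params), cf, NULL)
    phase <- fx[2]                       # dVe/dt at section
    res <- max(abs(c(FX, phase)))
    if (res < 1e-10) break
    fT <- cpp_mf_rhs(fl$y, T, unclass(params), cf, NULL)
    J <- meanfield_jacobian(x, params)
    A <- rbind(cbind(fl$M - diag(8), fT),
               c(J[2, ], 0))
    dz <- tryCatch(solve(A, -c(FX, phase)), error = function(e) NULL)
    if (is.null(dz)) break
    x <- x + dz[1:8]; T <- T + dz[9]
  }
  fl <- cpp_mf_flow(x, 0, T, unclass(params), cf, NULL, tol, TRUE)
  mult <- eigen(fl$M, only.values = TRUE)$values
  list(x = x, T = T, floquet = mult, residual = res)
}

#' @export
print.ping_cycle <- function(x, ...) {
  cat(sprintf("PING limit cycle: T* = %.4f ms (%.2f Hz)\n",
              x$period, 1000 / x$period))
  cat(sprintf("  max r_e = %.4f, max r_i = %.4f spikes/ms\n",
              max(x$states[, "r_e"]), max(x$states[, "r_i"])))
  nt <- sort(Mod(x$floquet), decreasing = TRUE)
  cat(sprintf("  leading nontrivial Floquet multiplier |mu| = %.3g\n", nt[2]))
  invisible(x)
}

#' @export
print.ping_no_cycle <- function(x, ...) {
  cat(sprintf("no limit cycle: V_e amplitude %.2e below threshold\n",
              x$amplitude))
  invisible(x)
}

#' Does the result hold an oscillation?
#' @param x result of [find_limit_cycle()].
#' @return Logical.
#' @export
has_cycle <- function(x) inherits(x, "ping_cycle")

#' @export
plot.ping_cycle <- function(x, ...) {
  matplot(x$t, x$states[, c("r_e", "r_i")], type = "l", lty = 1,
          col = c("red", "blue"), xlab = "time (ms)",
          ylab = "rate (spikes/ms)", ...)
  legend("topright", c("r_e", "r_i"), col = c("red", "blue"), lty = 1,
         bty = "n")
  invisible(x)
}

# periodic cubic Hermite interpolation of the stored cycle at time(s) t
interp_cycle <- function(cycle, t) {
  n <- length(cycle$t); h <- cycle$period / n
  s <- t %% cycle$period
  j <- pmin(floor(s / h), n - 1)
  j1 <- (j + 1) %% n
  u <- (s - j * h) / h
  h00 <- 2 * u^3 - 3 * u^2 + 1; h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2;    h11 <- u^3 - u^2
  y0 <- cycle$states[j + 1, , drop = FALSE]
  y1 <- cycle$states[j1 + 1, , drop = FALSE]
  d0 <- cycle$derivs[j + 1, , drop = FALSE]
  d1 <- cycle$derivs[j1 + 1, , drop = FALSE]
  out <- h00 * y0 + h10 * h * d0 + h01 * y1 + h11 * h * d1
  colnames(out) <- state_names
  if (length(t) == 1) out[1, ] else out
}

#' Integral mean firing rates over one cycle
#'
#' Time-averages of `r_e` and `r_i` over one period.  On the uniform periodic
#' sampling grid the rectangle rule is spectrally accurate.
#'
#' @param cycle a `ping_cycle` (or a locked `ping_orbit`).
#' @return Named vector `c(R_e, R_i)` in spikes/ms.
#' @export
integral_mean_rates <- function(cycle) {
  c(R_e = mean(cycle$states[, "r_e"]), R_i = mean(cycle$states[, "r_i"]))
}

# quadratic (three-point) refinement of the maximum of a sampled periodic
# trace; returns c(t_max, value)
peak_quadratic <- function(tt, y, i = which.max(y), periodic = TRUE) {
  n <- length(y)
  if (periodic) {
    im <- ((i - 2) %% n) + 1; ip <- (i %% n) + 1
    h <- tt[2] - tt[1]
    y0 <- y[im]; y1 <- y[i]; y2 <- y[ip]
  } else {
    if (i == 1 || i == n) return(c(tt[i], y[i]))
    h <- tt[2] - tt[1]
    y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  }
  den <- (y0 - 2 * y1 + y2)
  dt <- if (den == 0) 0 else 0.5 * h * (y0 - y2) / den
  c(tt[i] + dt, y1 - 0.125 * (y0 - y2) * ifelse(den == 0, 0, (y0 - y2) / den))
}

#' I-to-E latency and relative phase on a cycle
#'
#' Time from the E-volley peak (maximum of `r_e`) to the following I-volley
#' peak (maximum of `r_i`), wrapped into `[0, T*)`, and the same difference
#' normalized by the period.
#'
#' @param cycle a `ping_cycle`.
#' @return Named vector `c(latency_ms, relative_phase)`.
#' @export
ei_latency <- function(cycle) {
  re <- cycle$states[, "r_e"]; ri <- cycle$states[, "r_i"]
  if (diff(range(re)) < 1e-12 || diff(range(ri)) < 1e-12)
    stop("flat rate trace: latency undefined")
  te <- peak_quadratic(cycle$t, re)[1]
  ti <- peak_quadratic(cycle$t, ri)[1]
  lat <- (ti - te) %% cycle$period
  c(latency_ms = lat, relative_phase = lat / cycle$period)
}

#' Equilibria of the mean-field model
#'
#' Solves the 8-dimensional root problem by reduction to the two rate
#' variables (at an equilibrium the voltages and synaptic variables are
#' explicit functions of `r_e, r_i`), Newton iteration from a grid of seeds,
#' and de-duplication.  Each equilibrium is tagged stable/unstable from the
#' eigenvalues of the analytic Jacobian.
#'
#' @param params a [ping_params()] object.
#' @param seeds rate seed values for the Newton runs.
#' @return List of equilibria; each has `state`, `eigenvalues`, `stable`,
#'   `residual`.
#' @export
find_equilibria <- function(params = ping_params(),
                            seeds = c(1e-3, 5e-3, 0.02, 0.05, 0.1, 0.2)) {
  p <- as_ping_params(params)
  Vof <- function(r, tau, delta) -delta / (2 * pi * tau * r)
  Fred <- function(z) {
    re <- z[1]; ri <- z[2]
    Ve <- Vof(re, p$tau_e, p$delta_e); Vi <- Vof(ri, p$tau_i, p$delta_i)
    c(Ve^2 + p$eta_e + p$Ie_ext_bar - (p$tau_e * pi * re)^2 +
        p$tau_e * (p$J_ee * re - p$J_ei * ri),
      Vi^2 + p$eta_i + p$Ii_ext_bar - (p$tau_i * pi * ri)^2 +
        p$tau_i * (p$J_ie * re - p$J_ii * ri))
  }
  Jred <- function(z) {
    re <- z[1]; ri <- z[2]
    Ve <- Vof(re, p$tau_e, p$delta_e); Vi <- Vof(ri, p$tau_i, p$delta_i)
    dVe <- p$delta_e / (2 * pi * p$tau_e * re^2)
    dVi <- p$delta_i / (2 * pi * p$tau_i * ri^2)
    matrix(c(2 * Ve * dVe - 2 * p$tau_e^2 * pi^2 * re + p$tau_e * p$J_ee,
             -p$tau_e * p$J_ei,
             p$tau_i * p$J_ie,
             2 * Vi * dVi - 2 * p$tau_i^2 * pi^2 * ri - p$tau_i * p$J_ii),
           2, 2, byrow = TRUE)
  }
  roots <- list()
  for (se in seeds) for (si in seeds) {
    z <- c(se, si); ok <- FALSE
    for (it in 1:60) {
      Fz <- Fred(z)
      if (max(abs(Fz)) < 1e-12) { ok <- TRUE; break }
      dz <- tryCatch(solve(Jred(z), -Fz), error = function(e) NULL)
      if (is.null(dz)) break
      # damped step keeping rates positive
      lam <- 1
      repeat {
        zn <- z + lam * dz
        if (all(zn > 0)) break
        lam <- lam / 2
        if (lam < 1e-8) break
      }
      if (lam < 1e-8) break
      z <- zn
    }
    if (ok && all(z > 0)) {
      dup <- any(vapply(roots, function(r)
        max(abs(r$z - z)) < 1e-8, logical(1)))
      if (!dup) roots <- c(roots, list(list(z = z)))
    }
  }
  lapply(roots, function(r) {
    re <- r$z[1]; ri <- r$z[2]
    st <- network_state(r_e = re, V_e = Vof(re, p$tau_e, p$delta_e),
                        S_ee = p$J_ee * re, S_ei = p$J_ei * ri,
                        r_i = ri, V_i = Vof(ri, p$tau_i, p$delta_i),
                        S_ie = p$J_ie * re, S_ii = p$J_ii * ri)
    ev <- eigen(meanfield_jacobian(st, p), only.values = TRUE)$values
    list(state = st, eigenvalues = ev, stable = all(Re(ev) < 0),
         residual = max(abs(meanfield_rhs(st, 0, p))))
  })
}

#' Locate a Hopf bifurcation along a one-parameter sweep
#'
#' Bisects on the real part of the leading complex eigenvalue pair of the
#' equilibrium as one tonic drive is varied; the imaginary part at the
#' crossing gives the emergent oscillation frequency.
#'
#' @param params baseline [ping_params()].
#' @param par_name parameter swept (default `Ie_ext_bar`).
#' @param interval parameter interval bracketing the crossing.
#' @param tol bisection tolerance in the parameter (default 1e-6).
#' @return List `par` (critical value), `eigenvalue`, `freq_hz`.
#' @export
find_hopf <- function(params = ping_params(), par_name = "Ie_ext_bar",
                      interval, tol = 1e-6) {
  lead <- function(v) {
    p <- as_ping_params(modifyList(unclass(params),
                                   setNames(list(v), par_name)))
    eq <- find_equilibria(p)
    if (!length(eq)) return(NULL)
    evs <- eq[[1]]$eigenvalues
    cx <- evs[abs(Im(evs)) > 1e-8]
    if (!length(cx)) return(NULL)
    cx[which.max(Re(cx))]
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- Re(lead(lo)); fhi <- Re(lead(hi))
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("interval does not bracket a Hopf crossing")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- Re(lead(mid))
    if (fm * flo <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  vh <- (lo + hi) / 2
  ev <- lead(vh)
  list(par = vh, eigenvalue = ev, freq_hz = 1000 * abs(Im(ev)) / (2 * pi))
}
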