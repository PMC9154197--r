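#' Phases of the time-T1 map under two periodic inputs
#'
#' Integrates the phase equation continuously under the combined drive
#' `g = A1 p1 + A2 p2` and records the oscillator phase every `T1` (the
#' primary period).  When the distractor period differs from `T1` the map is
#' time-dependent, but the sampled phases still diagnose whether the primary
#' entrainment survives.
#'
#' @param iprc a `ping_iprc`.
#' @param primary,distractor [von_mises_input()] objects; the distractor is
#'   re-timed by the placement rule of [arrange_two_inputs()].
#' @param n_iter number of recorded iterates (default 1000).
#' @param burn_in iterates discarded before recording (default 0).
#' @param theta0 initial phase.
#' @param tol integration tolerance.
#' @return List `phases` (wrapped to `[0, T*)`), `lift`, `T1`.
#' @export
time_T1_map_phases <- function(iprc, primary, distractor, n_iter = 1000,
                               burn_in = 0, theta0 = 0, tol = 1e-10) {
  fo <- arrange_two_inputs(primary, distractor)
  T1 <- primary$T
  ntot <- burn_in + n_iter
  fl <- phase_flow(theta0, 0, (ntot - 1) * T1, (0:(ntot - 1)) * T1,
                   iprc, fo, tol = tol)
  lift <- fl$theta[(burn_in + 1):ntot]
  list(phases = lift %% iprc$Tstar, lift = lift, T1 = T1)
}

#' Vector strength (synchronization index)
#'
#' Modulus of the mean unit vector of the phase angles: 1 for perfectly
#' clustered phases, about 0 for phases scattered around the circle.
#'
#' @param phases phases; interpreted as angles on a circle of circumference
#'   `period`.
#' @param period circle circumference (default `2*pi`, i.e. `phases` are
#'   already angles in radians).
#' @return `r` in `[0, 1]`.
#' @export
vector_strength <- function(phases, period = 2 * pi) {
  if (length(phases) < 1) stop("need at least one phase")
  Mod(mean(exp(2i * pi * phases / period)))
}

#' Robustness of primary entrainment against a distractor
#'
#' Equal-period pairs (`T2 = T1`) keep the combined forcing `T1`-periodic,
#' so the verdict is the rotation number of the combined stroboscopic map
#' (`locked` iff `rho_hat = 1` within 1e-4).  Unequal periods use the
#' synchronization index of 1000 time-`T1` iterates after a 100-iterate
#' burn-in (`locked` iff `r > threshold`).
#'
#' @param iprc a `ping_iprc`.
#' @param T1_rel primary period as a fraction of `T*`.
#' @param kappa2_values distractor coherences scanned.
#' @param T2_ratio_values distractor/primary period ratios scanned.
#' @param A1,A2 input strengths.
#' @param kappa1 primary coherence.
#' @param threshold vector-strength threshold for the `locked` verdict.
#' @param n_iter,burn_in iterates for the synchronization index.
#' @return data.frame with `T1_rel`, `kappa2`, `T2_ratio`, `metric`
#'   (`"rho"` or `"SI"`), `value`, `locked`.
#' @export
robustness_scan <- function(iprc, T1_rel, kappa2_values, T2_ratio_values,
                            A1 = 0.1, A2 = 0.1, kappa1 = 2,
                            threshold = 0.8, n_iter = 1000, burn_in = 100) {
  stopifnot(threshold > 0, threshold < 1)
  rows <- list()
  T1 <- T1_rel * iprc$Tstar
  for (k2 in kappa2_values) for (tr in T2_ratio_values) {
    p1 <- von_mises_input(A = A1, T = T1, kappa = kappa1, mu = 0)
    p2 <- von_mises_input(A = A2, T = tr * T1, kappa = k2)
    if (abs(tr - 1) < 1e-12) {
      fo <- arrange_two_inputs(p1, p2)
      rot <- rotation_number(iprc, fo, T = T1)
      rows <- c(rows, list(data.frame(
        T1_rel = T1_rel, kappa2 = k2, T2_ratio = tr, metric = "rho",
        value = rot$rho_hat, locked = abs(rot$rho_hat - 1) < 1e-4)))
    } else {
      ph <- time_T1_map_phases(iprc, p1, p2, n_iter = n_iter,
                               burn_in = burn_in)
      r <- vector_strength(ph$phases, period = iprc$Tstar)
      rows <- c(rows, list(data.frame(
        T1_rel = T1_rel, kappa2 = k2, T2_ratio = tr, metric = "SI",
        value = r, locked = r > threshold)))
    }
  }
  do.call(rbind, rows)
}

#' Distractor effect on the E-cell evoked response
#'
#' Integrates the doubly forced full model to steady behavior, then
#' evaluates the response factors (`Delta_alpha`, `Delta_sigma`,
#' `Delta_alpha_bar`) on each of `n_cycles` consecutive primary cycles
#' against the unperturbed cycle, reporting mean and standard deviation per
#' amplitude value.
#'
#' @param cycle unperturbed `ping_cycle`.
#' @param primary,distractor [von_mises_input()] templates (`mu` of the
#'   distractor is set by the placement rule).
#' @param vary `"A1"` or `"A2"`: which amplitude is swept.
#' @param values amplitude values.
#' @param n_cycles primary cycles aggregated (default 10).
#' @param settle_cycles primary cycles integrated before measuring.
#' @param tol integration tolerance.
#' @return data.frame with one row per amplitude value: means and sds of the
#'   three factors.
#' @export
distractor_response_factors <- function(cycle, primary, distractor,
                                        vary = c("A1", "A2"), values,
                                        n_cycles = 10, settle_cycles = 30,
                                        tol = 1e-10) {
  vary <- match.arg(vary)
  T1 <- primary$T
  re0 <- cycle$states[, "r_e"]
  max0 <- peak_quadratic(cycle$t, re0)[2]
  mean0 <- mean(re0)
  hw0 <- half_width(cycle$t, re0) / cycle$period
  rows <- list()
  for (v in values) {
    p1 <- primary; p2 <- distractor
    if (vary == "A1") p1$A <- v else p2$A <- v
    fo <- arrange_two_inputs(p1, p2)
    # with both inputs off the trajectory follows the unperturbed cycle, so
    # the measurement window is T*; otherwise one cycle of the primary
    Tw <- if (p1$A == 0 && p2$A == 0) cycle$period else T1
    y <- mf_flow(cycle$x0, 0, settle_cycles * T1, cycle$params, fo,
                 tol = tol)$y
    dt <- Tw / 256
    tt <- seq(settle_cycles * T1, settle_cycles * T1 + n_cycles * Tw,
              by = dt)
    tr <- cpp_mf_integrate(y, tt, unclass(cycle$params), as_cpp_forcing(fo),
                           NULL, tol)
    da <- ds <- dab <- numeric(n_cycles)
    for (k in seq_len(n_cycles)) {
      sel <- which(tt >= tt[1] + (k - 1) * Tw & tt < tt[1] + k * Tw)
      re <- tr[sel, 1]  # r_e column
      tk <- tt[sel]
      da[k] <- peak_quadratic(tk, re, periodic = FALSE)[2] / max0
      dab[k] <- mean(re) / mean0
      lev <- (max(re) + min(re)) / 2
      ab <- re >= lev
      i <- which.max(re)
      li <- i; while (li > 1 && ab[li - 1]) li <- li - 1
      ri <- i; while (ri < length(re) && ab[ri + 1]) ri <- ri + 1
      t1c <- if (li > 1)
        tk[li - 1] + dt * (lev - re[li - 1]) / (re[li] - re[li - 1]) else tk[1]
      t2c <- if (ri < length(re))
        tk[ri] + dt * (lev - re[ri]) / (re[ri + 1] - re[ri]) else tk[length(re)]
      ds[k] <- ((t2c - t1c) / 2 / Tw) / hw0
    }
    rows <- c(rows, list(data.frame(
      value = v, vary = vary,
      dalpha_mean = mean(da), dalpha_sd = sd(da),
      dsigma_mean = mean(ds), dsigma_sd = sd(ds),
      dalpha_bar_mean = mean(dab), dalpha_bar_sd = sd(dab))))
  }
  do.call(rbind, rows)
}

# locked base orbit for two identical antiphase inputs (period T, forcing
# period T/2): settle then Newton-refine the fixed point of the time-T map
antiphase_base_orbit <- function(cycle, T_rel = 0.84, kappa = 2, A = 0.1,
                                 settle = 40, tol = 1e-11) {
  T <- T_rel * cycle$period
  p1 <- von_mises_input(A = A, T = T, kappa = kappa, mu = 0)
  p2 <- von_mises_input(A = A, T = T, kappa = kappa, mu = T / 2)
  fo <- forcing_spec(list(p1, p2))
  y <- mf_flow(cycle$x0, 0, settle * T, cycle$params, fo, tol = tol)$y
  ob <- full_model_locking(cycle, fo, T = T, p = 1, q = 1, x_init = y,
                           tol = tol)
  if (!inherits(ob, "ping_orbit"))
    stop("could not lock the antiphase two-input base orbit")
  ob
}

# E-volley times from a finely sampled r_e trace (non-periodic window)
revolley_times <- function(tt, re, min_frac = 0.5, ref_max = max(re)) {
  thr <- min(re) + min_frac * (ref_max - min(re))
  n <- length(re)
  i <- which(re[2:(n - 1)] > re[1:(n - 2)] & re[2:(n - 1)] >= re[3:n]) + 1
  i <- i[re[i] > thr]
  vapply(i, function(j) peak_quadratic(tt, re, j, periodic = FALSE)[1],
         numeric(1))
}

# signed detector of the effective input: with input peaks at 0 and T/2
# (mod T), d = (t_e - t_p1) - (t_e - t_p2) over preceding peaks
effective_input_d <- function(t_e, T) {
  tp1 <- floor(t_e / T) * T
  tp2 <- floor((t_e - T / 2) / T) * T + T / 2
  (t_e - tp1) - (t_e - tp2)
}

#' Square-pulse phase response and switching between identical streams
#'
#' On the network entrained by two identical antiphase von Mises inputs, a
#' square current pulse to the E-cells is applied at a grid of phases
#' `t/T` of the entrained cycle (phase 0 = peak of the first input).  For
#' each phase the phase response `PRC = (T0 - T1)/T0` is measured from the
#' first E-volley interval after the pulse (positive = phase advance), and
#' the effective-input detector `d` is evaluated one cycle before the pulse
#' and again after a relaxation of `relax_periods` entrained periods; a sign
#' change flags a switch of the attended stream.
#'
#' @param cycle unperturbed `ping_cycle`.
#' @param phases pulse phases `t/T` in `[0, 1)`.
#' @param T_rel input period as a fraction of `T*` (default 0.84).
#' @param kappa,A input coherence and strength.
#' @param pulse a [square_pulse()] template (its onset is set per phase).
#' @param relax_periods entrained periods waited before re-measuring
#'   (default 30).
#' @param wait_cycles entrained cycles before the pulse is applied.
#' @param tol integration tolerance.
#' @return data.frame with `phase`, `prc`, `d_before`, `d_after`,
#'   `switched`, `entrained` (FALSE if post-pulse locking was lost).
#' @export
pulse_switch_prc <- function(cycle, phases = seq(0, 0.95, by = 0.05),
                             T_rel = 0.84, kappa = 2, A = 0.1,
                             pulse = square_pulse(), relax_periods = 30,
                             wait_cycles = 2, tol = 1e-10) {
  base <- antiphase_base_orbit(cycle, T_rel, kappa, A, tol = 1e-11)
  T0 <- base$T_input
  rows <- list()
  for (s in phases) {
    onset <- wait_cycles * T0 + s * T0
    fo <- base$forcing
    fo$pulse <- square_pulse(pulse$amplitude, pulse$duration, onset)
    t_end <- onset + (relax_periods + 4) * T0
    tt <- seq(0, t_end, by = T0 / 512)
    tr <- cpp_mf_integrate(as.numeric(base$x0), tt,
                           unclass(cycle$params), as_cpp_forcing(fo),
                           NULL, tol)
    # threshold volley detection on the pre-pulse amplitude: the pulse
    # itself can evoke a transient far taller than the entrained volleys
    te <- revolley_times(tt, tr[, 1], ref_max = max(tr[tt < onset, 1]))
    pre <- te[te < onset]
    post <- te[te >= onset]
    if (length(pre) < 1 || length(post) < 2) next
    T1 <- post[1] - tail(pre, 1)
    prc <- (T0 - T1) / T0
    d_bf <- effective_input_d(tail(pre, 1), T0)
    te_af <- post[post >= onset + relax_periods * T0][1]
    d_af <- if (is.na(te_af)) NA_real_ else effective_input_d(te_af, T0)
    tail_iv <- diff(tail(te, 5))
    entrained <- all(abs(tail_iv - T0) < 0.1 * T0)
    rows <- c(rows, list(data.frame(
      phase = s, prc = prc, d_before = d_bf, d_after = d_af,
      switched = !is.na(d_af) && sign(d_bf * d_af) == -1,
      entrained = entrained)))
  }
  do.call(rbind, rows)
}
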