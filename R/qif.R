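#' Sample Lorentzian bias currents
#'
#' The heterogeneous bias currents of the QIF neurons follow a Lorentzian
#' (Cauchy) distribution.  `mode = "deterministic"` returns the exact
#' quantiles `center + half_width * tan(pi/2 * (2j - n - 1)/(n + 1))`,
#' which remove sampling noise from network-versus-mean-field comparisons;
#' `mode = "random"` draws by inverse-CDF sampling under the given seed.
#'
#' @param n number of values.
#' @param center,half_width Lorentzian location and half-width.
#' @param mode `"deterministic"` (quantiles) or `"random"`.
#' @param seed RNG seed for random mode.
#' @return Numeric vector of length `n`.
#' @export
sample_lorentzian <- function(n, center = -5, half_width = 1,
                              mode = c("deterministic", "random"),
                              seed = NULL) {
  stopifnot(n >= 1, half_width > 0)
  mode <- match.arg(mode)
  if (mode == "deterministic") {
    j <- seq_len(n)
    center + half_width * tan(pi / 2 * (2 * j - n - 1) / (n + 1))
  } else {
    if (!is.null(seed)) set.seed(seed)
    u <- stats::runif(n)
    center + half_width * tan(pi * (u - 0.5))
  }
}

#' Parameters of the microscopic QIF network
#'
#' @param N_e,N_i population sizes.
#' @param params shared mean-field parameters ([ping_params()]).
#' @param V_th,V_reset threshold and reset voltages (defaults 500, -500).
#' @param eta_mode how the Lorentzian bias currents are sampled.
#' @param seed RNG seed for random sampling.
#' @return Object of class `qif_params`; includes the per-population
#'   refractory durations `T_ref = 2 * tau / V_th`.
#' @export
qif_params <- function(N_e = 5000, N_i = 5000, params = ping_params(),
                       V_th = 500, V_reset = -500,
                       eta_mode = c("deterministic", "random"),
                       seed = 1L) {
  eta_mode <- match.arg(eta_mode)
  params <- as_ping_params(params)
  if (eta_mode == "random") set.seed(seed)
  eta_e <- sample_lorentzian(N_e, params$eta_e, params$delta_e, eta_mode)
  eta_i <- sample_lorentzian(N_i, params$eta_i, params$delta_i, eta_mode)
  structure(list(N_e = N_e, N_i = N_i, params = params,
                 V_th = V_th, V_reset = V_reset,
                 T_ref_e = 2 * params$tau_e / V_th,
                 T_ref_i = 2 * params$tau_i / V_th,
                 eta_e = eta_e, eta_i = eta_i,
                 eta_mode = eta_mode, seed = seed),
            class = "qif_params")
}

#' Simulate the microscopic QIF E-I network
#'
#' Euler integration of the all-to-all coupled quadratic integrate-and-fire
#' network whose population averages the mean-field model reproduces in the
#' thermodynamic limit.  A threshold crossing emits a spike, resets the
#' voltage and holds the neuron refractory for `T_ref`; each pre-synaptic
#' spike increments the corresponding synaptic variable by
#' `J_ab / (N_b * tau_sb)` at the following step.
#'
#' @param qif a [qif_params()] object.
#' @param forcing optional [forcing_spec()] (square pulse targets E only).
#' @param t_end simulation end time (ms), starting at `t0 = 0`.
#' @param dt Euler step (default 1e-4 ms; must be <= 1e-3).
#' @param drive_schedule optional step protocol for the tonic drives (as in
#'   [integrate_meanfield()]).
#' @param init_V initial voltage (common to all neurons) or vector pair.
#' @param record_dt if positive, sample the synaptic variables this often.
#' @return Object of class `spike_raster`: data.frame `spikes` with columns
#'   `time`, `neuron`, `population`, plus the simulation metadata.
#' @export
simulate_qif <- function(qif, forcing = NULL, t_end, dt = 1e-4,
                         drive_schedule = NULL, init_V = -2,
                         record_dt = 0) {
  stopifnot(inherits(qif, "qif_params"), dt <= 1e-3)
  sched <- if (is.null(drive_schedule)) NULL else
    as.matrix(drive_schedule[, 1:3])
  V0e <- rep_len(init_V, qif$N_e)
  V0i <- rep_len(init_V, qif$N_i)
  res <- cpp_qif_simulate(qif$eta_e, qif$eta_i, V0e, V0i,
                          unclass(qif$params), as_cpp_forcing(forcing),
                          sched, 0, t_end, dt, qif$V_th, qif$V_reset,
                          record_dt)
  spikes <- data.frame(
    time = c(res$spike_t_e, res$spike_t_i),
    neuron = c(res$spike_id_e, res$spike_id_i + qif$N_e),
    population = rep(c("e", "i"),
                     c(length(res$spike_t_e), length(res$spike_t_i))))
  spikes <- spikes[order(spikes$time, spikes$neuron), ]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, N_e = qif$N_e, N_i = qif$N_i,
                 t_end = t_end, dt = dt, synaptic = res$synaptic),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("QIF raster: %d spikes from %d E + %d I neurons over %g ms\n",
              nrow(x$spikes), x$N_e, x$N_i, x$t_end))
  invisible(x)
}

#' Empirical population rate from a spike raster
#'
#' Bins spike counts and divides by `bin_width * N`, giving the population
#' rate in spikes/ms per neuron, directly comparable to the mean-field rate
#' variables.
#'
#' @param raster a `spike_raster` from [simulate_qif()].
#' @param population `"e"` or `"i"`.
#' @param bin_width bin size in ms (default 0.08).
#' @param t_range optional time range; defaults to `[0, t_end]`.
#' @return data.frame with `t` (bin centers) and `rate`.
#' @export
empirical_rate <- function(raster, population = "e", bin_width = 0.08,
                           t_range = NULL) {
  stopifnot(bin_width > 0)
  if (is.null(t_range)) t_range <- c(0, raster$t_end)
  N <- if (population == "e") raster$N_e else raster$N_i
  sp <- raster$spikes$time[raster$spikes$population == population]
  breaks <- seq(t_range[1], t_range[2] + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(sp, breaks, rightmost.closed = FALSE),
                  nbins = length(breaks) - 1)
  data.frame(t = head(breaks, -1) + bin_width / 2,
             rate = cnt / (bin_width * N))
}

#' Spiking-versus-mean-field validation run
#'
#' Runs the reference protocol (resting drive, tonic drive switched on, then
#' periodic von Mises drive added) in both the QIF network and the
#' mean-field model and reports the RMSE between the empirical and
#' mean-field E rates over the forced segment, relative to the peak rate.
#'
#' @param qif a [qif_params()] object.
#' @param A,kappa forcing strength and coherence of the von Mises drive.
#' @param T forcing period (ms); default half the reference gamma period.
#' @param t_switch time the tonic drive switches on.
#' @param t_forcing time the periodic drive switches on.
#' @param t_end end of the run.
#' @param bin_width rate bin (ms).
#' @param dt Euler step of the QIF simulation.
#' @return List with the raster, the empirical and mean-field rate traces,
#'   and `rmse_rel` (RMSE / peak mean-field rate over the forced segment).
#' @export
qif_validation_run <- function(qif, A = 0.1, kappa = 2, T = 24.234 / 2,
                               t_switch = 20, t_forcing = 50, t_end = 90,
                               bin_width = 0.08, dt = 1e-4) {
  pars <- qif$params
  sched <- data.frame(t = c(0, t_switch),
                      Ie = c(0, pars$Ie_ext_bar),
                      Ii = c(pars$Ii_ext_bar, pars$Ii_ext_bar))
  fo <- forcing_spec(von_mises_input(A = A, T = T, kappa = kappa),
                     t_on = t_forcing)
  ra <- simulate_qif(qif, forcing = fo, t_end = t_end, dt = dt,
                     drive_schedule = sched)
  emp <- empirical_rate(ra, "e", bin_width)
  init <- network_state(r_e = 1e-4, V_e = -2, r_i = 1e-4, V_i = -2)
  mf <- integrate_meanfield(init, emp$t, pars, forcing = fo,
                            drive_schedule = sched, tol = 1e-10)
  seg <- emp$t >= t_forcing & emp$t <= t_end
  err <- emp$rate[seg] - mf$r_e[seg]
  rmse_rel <- sqrt(mean(err^2)) / max(mf$r_e[seg])
  list(raster = ra, empirical = emp, meanfield = mf, rmse_rel = rmse_rel,
       forced_segment = c(t_forcing, t_end))
}
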