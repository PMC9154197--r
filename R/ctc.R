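#' Input-to-inhibition timing factor
#'
#' Normalized time difference between the maximum of the I-volley and the
#' (preceding) maximum of the periodic input over a cycle, `Delta_tau =
#' ((t_inh - t_p) mod T) / T`, in `[0, 1)`.  Values below 0.5 mean the input
#' volley precedes inhibition (a window for communication); values near 0 or
#' above 0.5 mean the input arrives under inhibition.  For 2:1 orbits (two
#' I-volleys per input cycle) one value per volley is returned.
#'
#' @param orbit a locked `ping_orbit`.
#' @param input which forcing input defines the peak times (default 1, the
#'   primary).
#' @return `Delta_tau`, or a vector `c(dtau1, dtau2)` for 2:1 orbits.
#' @export
delta_tau <- function(orbit, input = 1) {
  stopifnot(inherits(orbit, "ping_orbit"))
  Tin <- orbit$T_input
  mu <- orbit$forcing$inputs[[input]]$mu
  ri <- orbit$states[, "r_i"]
  n_volleys <- orbit$p
  pk <- find_volleys(orbit$t, ri, n_volleys)
  dt <- ((pk - mu) %% Tin) / Tin
  if (length(dt) > 1) sort(dt) else dt
}

# times of the n tallest distinct local maxima of a sampled periodic trace
find_volleys <- function(tt, y, n = 1) {
  ny <- length(y)
  prv <- c(ny, seq_len(ny - 1)); nxt <- c(2:ny, 1)
  is_max <- y > y[prv] & y >= y[nxt]
  idx <- which(is_max)
  if (!length(idx)) stop("no local maxima found (flat trace?)")
  idx <- idx[order(y[idx], decreasing = TRUE)]
  # keep peaks separated by at least 1/(2n) of the period
  sep <- (tt[2] - tt[1]) * ny / (2 * max(n, 1) + 2)
  keep <- integer(0)
  for (i in idx) {
    if (!length(keep) ||
        all(pmin(abs(tt[i] - tt[keep]),
                 max(tt) + tt[2] - tt[1] - abs(tt[i] - tt[keep])) > sep))
      keep <- c(keep, i)
    if (length(keep) == n) break
  }
  sort(vapply(keep, function(i) peak_quadratic(tt, y, i)[1], numeric(1)))
}

# half-width of the volley bracketing the global maximum of a sampled trace:
# level (max+min)/2, crossing times flanking the tallest peak
half_width <- function(tt, y) {
  lev <- (max(y) + min(y)) / 2
  i <- which.max(y)
  n <- length(y)
  above <- y >= lev
  # walk left/right (periodically) to the crossings
  li <- i
  while (above[((li - 2) %% n) + 1]) {
    li <- ((li - 2) %% n) + 1
    if (li == i) stop("trace never falls below half maximum")
  }
  ri <- i
  while (above[(ri %% n) + 1]) {
    ri <- (ri %% n) + 1
    if (ri == i) stop("trace never falls below half maximum")
  }
  h <- tt[2] - tt[1]
  lim <- ((li - 2) %% n) + 1
  rip <- (ri %% n) + 1
  # linear interpolation to the crossing level
  t1 <- tt[lim] + h * (lev - y[lim]) / (y[li] - y[lim])
  t2 <- tt[ri] + h * (lev - y[ri]) / (y[rip] - y[ri])
  w <- (t2 - t1) %% (n * h)
  w / 2
}

#' E-cell evoked-response factors of an entrained orbit
#'
#' Ratios comparing the E-volley of a locked orbit against the unperturbed
#' cycle: `Delta_alpha_bar` (time-averaged rate over one orbit period versus
#' over `T*`), `Delta_alpha` (peak rate ratio) and `Delta_sigma` (half-width
#' ratio, each half-width normalized by its own period; the half-maximum
#' level is `(max+min)/2` and the crossings flank the tallest E-volley).
#' At `A = 0` all three are exactly 1.
#'
#' @param orbit a locked `ping_orbit` (or, for the trivial reference, the
#'   cycle itself).
#' @param cycle the unperturbed `ping_cycle`.
#' @return Object of class `ctc_factors`: `delta_tau` (NA when `orbit` has
#'   no forcing), `delta_alpha_bar`, `delta_alpha`, `delta_sigma`.
#' @export
response_factors <- function(orbit, cycle) {
  re_A <- orbit$states[, "r_e"]; re_0 <- cycle$states[, "r_e"]
  if (diff(range(re_A)) < 1e-14) stop("flat r_e trace")
  dab <- mean(re_A) / mean(re_0)
  da <- peak_quadratic(orbit$t, re_A)[2] / peak_quadratic(cycle$t, re_0)[2]
  ds <- (half_width(orbit$t, re_A) / tail_period(orbit)) /
        (half_width(cycle$t, re_0) / cycle$period)
  dtau <- if (inherits(orbit, "ping_orbit")) delta_tau(orbit) else NA_real_
  structure(list(delta_tau = dtau, delta_alpha_bar = dab,
                 delta_alpha = da, delta_sigma = ds),
            class = "ctc_factors")
}

tail_period <- function(x) x$period

#' @export
print.ctc_factors <- function(x, ...) {
  cat(sprintf("CTC factors: dtau = %s, dalpha_bar = %.4f, dalpha = %.4f, dsigma = %.4f\n",
              paste(sprintf("%.3f", x$delta_tau), collapse = "/"),
              x$delta_alpha_bar, x$delta_alpha, x$delta_sigma))
  invisible(x)
}

#' Communication factors along Arnold-tongue sections
#'
#' For each amplitude, finds the staircase plateau of the `p:q` locking,
#' places `n_T` equally spaced `T/T*` points inside it, locates the locked
#' full-model orbit at each (continuing the solution along the section) and
#' evaluates the response factors.  Points where shooting fails are recorded
#' as unlocked with `NA` factors, never interpolated.
#'
#' @param cycle unperturbed `ping_cycle`.
#' @param iprc matching `ping_iprc`.
#' @param kappa forcing coherence.
#' @param A_values amplitudes of the sections.
#' @param n_T points per section.
#' @param p,q locking ratio.
#' @param margin fraction of the plateau kept away from each edge.
#' @param T_range scanned `T/T*` interval for the plateau search.
#' @return data.frame with `A`, `T_over_Tstar`, `locked`, `dtau`,
#'   `dalpha_bar`, `dalpha`, `dsigma`.
#' @export
tongue_section_sweep <- function(cycle, iprc, kappa = 2,
                                 A_values = seq(0.05, 0.2, by = 0.05),
                                 n_T = 10, p = 1, q = 1, margin = 0.04,
                                 T_range = NULL) {
  if (is.null(T_range)) T_range <- (p / q) * c(0.75, 1.1)
  rows <- list()
  for (A in A_values) {
    pl <- plateau_interval(iprc, A, kappa, p, q, T_range = T_range,
                           step = 0.004)
    if (is.null(pl$left)) next
    span <- pl$right - pl$left
    Ts <- seq(pl$left + margin * span, pl$right - margin * span,
              length.out = n_T)
    x_guess <- NULL
    for (tr in rev(Ts)) {  # continue from the right (weakly forced) side
      fo <- vm_forcing(A, tr * cycle$period, kappa)
      ob <- full_model_locking(cycle, fo, T = tr * cycle$period, p = p,
                               q = q, iprc = if (is.null(x_guess)) iprc
                                             else NULL,
                               x_init = x_guess)
      if (inherits(ob, "ping_orbit") && ob$stable) {
        x_guess <- ob$x0
        fx <- response_factors(ob, cycle)
        rows <- c(rows, list(data.frame(
          A = A, T_over_Tstar = tr, locked = TRUE,
          dtau = fx$delta_tau[1], dalpha_bar = fx$delta_alpha_bar,
          dalpha = fx$delta_alpha, dsigma = fx$delta_sigma)))
      } else {
        rows <- c(rows, list(data.frame(
          A = A, T_over_Tstar = tr, locked = FALSE, dtau = NA_real_,
          dalpha_bar = NA_real_, dalpha = NA_real_, dsigma = NA_real_)))
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$A, out$T_over_Tstar), ]
}
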