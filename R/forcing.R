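#' Periodic von Mises input
#'
#' A T-periodic input volley train shaped like a (circular normal) von Mises
#' density, `p(t) = exp(kappa * cos(2*pi*(t - mu)/T)) / I0(kappa)`, scaled so
#' that its temporal average over one period equals 1 for every coherence
#' `kappa`.  `kappa = 0` is the uniform (tonic) limit; large `kappa`
#' concentrates the volley around `t = mu` and approaches a periodic delta
#' train.  The drive applied to the network is `g(t) = A * p(t)`.
#'
#' @param A input strength (temporal average of the drive).
#' @param T input period (ms).
#' @param kappa coherence (von Mises concentration), `kappa >= 0`.
#' @param mu peak time (ms).
#' @return Object of class `von_mises_input`.
#' @export
von_mises_input <- function(A, T, kappa = 2, mu = 0) {
  stopifnot(is.numeric(A), is.numeric(T), T > 0, kappa >= 0)
  structure(list(A = A, T = T, kappa = kappa, mu = mu),
            class = "von_mises_input")
}

#' Evaluate a von Mises input
#'
#' Returns `A * p(t)`.  Evaluation is performed in log-space,
#' `exp(kappa*(cos(.) - 1)) / (exp(-kappa) I0(kappa))`, with an exponentially
#' scaled Bessel function, so arbitrarily large coherences do not overflow.
#'
#' @param input a [von_mises_input()].
#' @param t time(s) in ms; vectorized.
#' @return Drive value(s).
#' @export
von_mises_eval <- function(input, t) {
  i0e <- besselI(input$kappa, 0, expon.scaled = TRUE)
  cc <- cos(2 * pi * (t - input$mu) / input$T)
  input$A * exp(input$kappa * (cc - 1)) / i0e
}

#' Symbolic periodic pulse train (the kappa -> infinity limit)
#'
#' Represents `p(t) = T * sum_i delta(t - t0 - i*T)`.  It is never sampled on
#' a time grid: it is consumed only by the closed-form stroboscopic map and
#' the analytic Arnold-tongue boundaries.
#'
#' @param A input strength; @param T period (ms); @param t0 pulse time offset.
#' @return Object of class `pulse_train`.
#' @export
pulse_train <- function(A, T, t0 = 0) {
  stopifnot(T > 0)
  structure(list(A = A, T = T, t0 = t0), class = "pulse_train")
}

#' Square current pulse
#'
#' A brief square-wave current applied to the E-population voltage equation
#' only, used to probe phase shifting and switching between attended streams.
#'
#' @param amplitude pulse height (default 1.5).
#' @param duration pulse width in ms (default 2).
#' @param onset onset time in ms.
#' @return Object of class `square_pulse`.
#' @export
square_pulse <- function(amplitude = 1.5, duration = 2, onset = 0) {
  stopifnot(duration > 0)
  structure(list(amplitude = amplitude, duration = duration, onset = onset),
            class = "square_pulse")
}

#' Evaluate a square pulse
#' @param pulse a [square_pulse()].
#' @param t time(s), vectorized.
#' @return amplitude inside `[onset, onset + duration)`, 0 elsewhere.
#' @export
square_pulse_eval <- function(pulse, t) {
  ifelse(t >= pulse$onset & t < pulse$onset + pulse$duration,
         pulse$amplitude, 0)
}

#' Forcing specification
#'
#' Bundles one or two periodic von Mises inputs (primary first), an optional
#' square pulse, and the target populations receiving the periodic drive.
#' The drive enters the voltage equations directly (it adds to dV/dt); the
#' square pulse targets the E population only.
#'
#' @param inputs a [von_mises_input()] or list of 1-2 of them.
#' @param pulse optional [square_pulse()].
#' @param target which populations receive the periodic inputs; default both.
#' @param t_on time from which the periodic inputs are switched on.
#' @return Object of class `ping_forcing`.
#' @export
forcing_spec <- function(inputs = list(), pulse = NULL,
                         target = c("e", "i"), t_on = -Inf) {
  if (inherits(inputs, "von_mises_input")) inputs <- list(inputs)
  stopifnot(is.list(inputs), length(inputs) <= 2)
  for (in_ in inputs) stopifnot(inherits(in_, "von_mises_input"))
  if (!is.null(pulse)) stopifnot(inherits(pulse, "square_pulse"))
  target <- match.arg(target, c("e", "i"), several.ok = TRUE)
  structure(list(inputs = inputs, pulse = pulse,
                 to_e = "e" %in% target, to_i = "i" %in% target,
                 t_on = t_on),
            class = "ping_forcing")
}

#' Evaluate the periodic part of a forcing specification
#'
#' Sum of the von Mises drives, `g(t) = A1 p1(t) + A2 p2(t)`; the square
#' pulse is excluded (use [square_pulse_eval()]).
#'
#' @param forcing a [ping_forcing][forcing_spec()] object.
#' @param t time(s), vectorized.
#' @return `g(t)`.
#' @export
forcing_eval <- function(forcing, t) {
  g <- numeric(length(t))
  for (in_ in forcing$inputs) g <- g + von_mises_eval(in_, t)
  g[t < forcing$t_on] <- 0
  g
}

#' Place two periodic inputs
#'
#' Builds a two-input forcing with the peak of the slower input placed midway
#' between two consecutive peaks of the faster one.  With equal periods the
#' second input is in antiphase (`mu2 = T/2`); if `T2 >= T1` then
#' `mu2 = T1/2`, and if `T1 > T2` then `mu2 = T2/2`.  The primary input must
#' have its peak at `mu1 = 0`.
#'
#' @param primary,distractor [von_mises_input()] objects; `primary$mu` must
#'   be 0.
#' @param target populations receiving the drive.
#' @return A [ping_forcing][forcing_spec()] with the distractor re-timed.
#' @export
arrange_two_inputs <- function(primary, distractor, target = c("e", "i")) {
  stopifnot(inherits(primary, "von_mises_input"),
            inherits(distractor, "von_mises_input"))
  if (primary$mu != 0)
    stop("the primary input must have mu = 0")
  mu2 <- if (distractor$T >= primary$T) primary$T / 2 else distractor$T / 2
  distractor$mu <- mu2
  forcing_spec(list(primary, distractor), target = target)
}

#' @export
print.ping_forcing <- function(x, ...) {
  cat(sprintf("forcing: %d von Mises input(s)%s, targets %s%s\n",
              length(x$inputs),
              if (!is.null(x$pulse)) " + square pulse" else "",
              paste(c("E", "I")[c(x$to_e, x$to_i)], collapse = "+"),
              if (is.finite(x$t_on)) sprintf(", on from t=%g", x$t_on) else ""))
  for (in_ in x$inputs)
    cat(sprintf("  A=%g T=%g ms kappa=%g mu=%g\n",
                in_$A, in_$T, in_$kappa, in_$mu))
  invisible(x)
}

# empty forcing singleton used when no forcing is supplied
no_forcing <- function() forcing_spec()

# convert to the plain list the C++ backend expects
as_cpp_forcing <- function(forcing) {
  if (is.null(forcing)) forcing <- no_forcing()
  stopifnot(inherits(forcing, "ping_forcing"))
  pu <- NULL
  if (!is.null(forcing$pulse))
    pu <- list(amplitude = forcing$pulse$amplitude,
               duration = forcing$pulse$duration,
               onset = forcing$pulse$onset)
  list(inputs = lapply(forcing$inputs, function(i)
         list(A = i$A, T = i$T, kappa = i$kappa, mu = i$mu)),
       pulse = pu, to_e = forcing$to_e, to_i = forcing$to_i,
       t_on = forcing$t_on)
}
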