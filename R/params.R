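#' Mean-field model parameters
#'
#' Constructs the parameter set of the exact E-I mean-field model.  The
#' defaults reproduce the reference PING configuration used throughout the
#' package: identical membrane time constants for both populations, unit
#' Lorentzian half-widths, hyperpolarized Lorentzian centers, fast excitatory
#' (AMPA-like) and slower inhibitory (GABA_A-like) synapses, no recurrent
#' self-coupling and symmetric cross-coupling.
#'
#' @param tau_e,tau_i membrane time constants of the E and I populations (ms).
#' @param delta_e,delta_i half-widths of the Lorentzian distributions of the
#'   single-neuron bias currents.
#' @param eta_e,eta_i centers of the Lorentzian bias-current distributions.
#' @param tau_se,tau_si synaptic decay time constants of excitatory and
#'   inhibitory synapses (ms).
#' @param J_ee,J_ei,J_ie,J_ii synaptic strengths; `J_ab` couples pre-synaptic
#'   population `b` into post-synaptic population `a`.
#' @param Ie_ext_bar,Ii_ext_bar tonic external drives to the E and I cells.
#'
#' @return An object of class `ping_params` (a named list).
#' @examples
#' p <- ping_params()              # reference oscillator (tonic drive 10 to E)
#' p84 <- ping_params(Ie_ext_bar = 8.4)  # Hopf-proximal oscillator
#' @export
ping_params <- function(tau_e = 8, tau_i = 8,
                        delta_e = 1, delta_i = 1,
                        eta_e = -5, eta_i = -5,
                        tau_se = 1, tau_si = 5,
                        J_ee = 0, J_ei = 13, J_ie = 13, J_ii = 0,
                        Ie_ext_bar = 10, Ii_ext_bar = 0) {
  p <- list(tau_e = tau_e, tau_i = tau_i,
            delta_e = delta_e, delta_i = delta_i,
            eta_e = eta_e, eta_i = eta_i,
            tau_se = tau_se, tau_si = tau_si,
            J_ee = J_ee, J_ei = J_ei, J_ie = J_ie, J_ii = J_ii,
            Ie_ext_bar = Ie_ext_bar, Ii_ext_bar = Ii_ext_bar)
  validate_ping_params(p)
  structure(p, class = "ping_params")
}

validate_ping_params <- function(p) {
  num1 <- vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                   is.finite(x), logical(1))
  if (!all(num1))
    stop("all parameters must be finite numeric scalars; offending: ",
         paste(names(p)[!num1], collapse = ", "))
  pos <- c("tau_e", "tau_i", "tau_se", "tau_si", "delta_e", "delta_i")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  invisible(p)
}

#' @export
print.ping_params <- function(x, ...) {
  cat("E-I mean-field parameters (time in ms):\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}

as_ping_params <- function(p) {
  if (inherits(p, "ping_params")) return(p)
  if (is.list(p)) return(do.call(ping_params, p))
  stop("cannot interpret 'params'")
}

state_names <- c("r_e", "V_e", "S_ee", "S_ei", "r_i", "V_i", "S_ie", "S_ii")

#' Construct a network state vector
#'
#' @param r_e,V_e,S_ee,S_ei,r_i,V_i,S_ie,S_ii the 8 state coordinates (rates
#'   in spikes/ms, voltages dimensionless).
#' @return Named numeric vector of length 8.
#' @export
network_state <- function(r_e = 0.01, V_e = -2, S_ee = 0, S_ei = 0,
                          r_i = 0.01, V_i = -2, S_ie = 0, S_ii = 0) {
  setNames(c(r_e, V_e, S_ee, S_ei, r_i, V_i, S_ie, S_ii), state_names)
}
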