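# shared, lazily computed fixtures: the two reference oscillators and their
# iPRCs are reused across test files
.fixtures <- new.env(parent = emptyenv())

ref_cycle <- function() {
  if (is.null(.fixtures$cyc10))
    .fixtures$cyc10 <- find_limit_cycle(ping_params())
  .fixtures$cyc10
}

ref_iprc <- function() {
  if (is.null(.fixtures$ip10))
    .fixtures$ip10 <- solve_adjoint(ref_cycle())
  .fixtures$ip10
}

hopf_cycle <- function() {
  if (is.null(.fixtures$cyc84))
    .fixtures$cyc84 <- find_limit_cycle(ping_params(Ie_ext_bar = 8.4))
  .fixtures$cyc84
}

hopf_iprc <- function() {
  if (is.null(.fixtures$ip84))
    .fixtures$ip84 <- solve_adjoint(hopf_cycle())
  .fixtures$ip84
}

# power-series oracle for the modified Bessel function I0
bessel_i0_series <- function(x, terms = 40) {
  k <- 0:(terms - 1)
  sum((x / 2)^(2 * k) / factorial(k)^2)
}
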