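test_that("parameter constructor validates and defaults to the PING set", {
  p <- ping_params()
  expect_equal(p$tau_e, 8)
  expect_equal(p$tau_i, 8)
  expect_equal(p$delta_e, 1)
  expect_equal(p$eta_e, -5)
  expect_equal(p$tau_se, 1)
  expect_equal(p$tau_si, 5)
  expect_equal(p$J_ee, 0)
  expect_equal(p$J_ei, 13)
  expect_equal(p$J_ie, 13)
  expect_equal(p$J_ii, 0)
  expect_error(ping_params(tau_e = -1), "positive")
  expect_error(ping_params(delta_i = 0), "positive")
})

test_that("rates self-repel from zero and rhs errors on non-finite states", {
  p <- ping_params()
  st <- network_state(r_e = 0, V_e = 1.7)
  dy <- meanfield_rhs(st, params = p)
  expect_equal(dy[["r_e"]], p$delta_e / (pi * p$tau_e^2))
  expect_gt(dy[["r_e"]], 0)
  st[1] <- NaN
  expect_error(meanfield_rhs(st, params = p), "non-finite")
})

test_that("integrator agrees with an independent solver (deSolve)", {
  skip_if_not_installed("deSolve")
  p <- ping_params()
  y0 <- network_state(r_e = 0.02, V_e = -1, r_i = 0.03, V_i = -1.5)
  times <- seq(0, 50, by = 0.5)
  ours <- integrate_meanfield(y0, times, p)
  ref <- deSolve::ode(
    y = as.numeric(y0), times = times,
    func = function(t, y, parms) list(as.numeric(meanfield_rhs(y, t, p))),
    parms = NULL, method = "ode45", rtol = 1e-11, atol = 1e-11)
  expect_lt(max(abs(as.matrix(ours[, -1]) - ref[, -1])), 1e-6)
})

test_that("zero-length time span returns the initial state", {
  y0 <- network_state()
  out <- integrate_meanfield(y0, 0, ping_params())
  expect_equal(as.numeric(out[1, -1]), as.numeric(y0))
})

test_that("the reference drive protocol integrates without blow-up", {
  # tonic drive switched on at t = 20, periodic drive added at t = 50
  sched <- data.frame(t = c(0, 20), Ie = c(0, 10), Ii = c(0, 0))
  fo <- forcing_spec(von_mises_input(A = 0.1, T = 24.234 / 2, kappa = 2),
                     t_on = 50)
  out <- integrate_meanfield(network_state(r_e = 1e-4, r_i = 1e-4),
                             seq(0, 90, by = 0.05), ping_params(),
                             forcing = fo, drive_schedule = sched,
                             tol = 1e-10)
  expect_true(all(is.finite(as.matrix(out))))
  # quiescent before the switch, oscillating in the forced segment
  expect_lt(max(out$r_e[out$t < 19]), 0.01)
  expect_gt(max(out$r_e[out$t > 55]), 0.1)
  # nonnegativity of rates along the whole protocol
  expect_gt(min(out$r_e, out$r_i), -1e-9)
})

test_that("limit-cycle period matches the intrinsic gamma cycle", {
  cyc <- ref_cycle()
  expect_s3_class(cyc, "ping_cycle")
  expect_equal(cyc$period, 24.234, tolerance = 0.05 / 24.234)
  # periodicity of the converged orbit
  fl <- pingctc:::mf_flow(cyc$x0, 0, cyc$period, cyc$params, tol = 1e-12)
  expect_lt(max(abs(fl$y - cyc$x0)), 1e-7)
  # hyperbolic stability: nontrivial multipliers inside the unit circle
  m <- sort(Mod(cyc$floquet), decreasing = TRUE)
  expect_equal(m[1], 1, tolerance = 1e-6)
  expect_lt(m[2], 1)
  # phase origin at the V_e maximum
  expect_equal(which.max(cyc$states[, "V_e"]), 1)
})

test_that("the Hopf-proximal oscillator has the reported lower-gamma period", {
  cyc <- hopf_cycle()
  expect_equal(cyc$period, 30.5, tolerance = 0.1 / 30.5)
  expect_equal(1000 / cyc$period, 32.78, tolerance = 0.01)
})

test_that("no-cycle result is typed, not an exception", {
  nc <- find_limit_cycle(ping_params(Ie_ext_bar = 0))
  expect_s3_class(nc, "ping_no_cycle")
  expect_false(has_cycle(nc))
})

test_that("period is insensitive to the integration tolerance", {
  cyc8 <- find_limit_cycle(ping_params(), tol = 1e-8)
  cyc12 <- ref_cycle()
  expect_lt(abs(cyc8$period - cyc12$period), 1e-4)
})

test_that("integral mean rates are exact for constants and converged", {
  cyc <- ref_cycle()
  fake <- cyc
  fake$states[, "r_e"] <- 0.3
  expect_equal(integral_mean_rates(fake)[["R_e"]], 0.3)
  # spiking cells fire about once per macroscopic cycle
  mr <- integral_mean_rates(cyc)
  expect_equal(mr[["R_e"]], 1 / cyc$period, tolerance = 0.15)
  # quadrature self-convergence: halving the sampling changes R_e little
  half <- mean(cyc$states[seq(1, nrow(cyc$states), by = 2), "r_e"])
  expect_lt(abs(half - mr[["R_e"]]), 1e-8)
})

test_that("I-to-E latency and relative phase match the gamma cycle anatomy", {
  cyc <- ref_cycle()
  lt <- ei_latency(cyc)
  expect_equal(lt[["relative_phase"]], 0.18, tolerance = 0.02 / 0.18)
  expect_equal(lt[["latency_ms"]], 4, tolerance = 0.5 / 4)
  # identical traces give zero latency
  fake <- cyc
  fake$states[, "r_i"] <- fake$states[, "r_e"]
  fake$derivs[, "r_i"] <- fake$derivs[, "r_e"]
  expect_equal(ei_latency(fake)[["latency_ms"]], 0, tolerance = 1e-8)
  flat <- cyc
  flat$states[, "r_e"] <- 1
  expect_error(ei_latency(flat), "flat")
})

test_that("frequency increases with the tonic drive to the E-cells", {
  # below the Hopf crossing (about 8.13) the resting state is stable and no
  # oscillation exists at zero inhibitory drive
  expect_false(has_cycle(find_limit_cycle(ping_params(Ie_ext_bar = 7))))
  freqs <- vapply(c(8.5, 9, 11, 13, 15), function(v) {
    cyc <- find_limit_cycle(ping_params(Ie_ext_bar = v))
    1000 / cyc$period
  }, numeric(1))
  expect_true(all(diff(freqs) > 0))
  expect_gt(freqs[1], 25)
  expect_lt(freqs[5], 80)
})

test_that("equilibria solve the vector field and classify stability", {
  eq <- find_equilibria(ping_params())
  expect_gte(length(eq), 1)
  for (e in eq) expect_lt(e$residual, 1e-10)
  # inside the oscillatory region the coexisting equilibrium is unstable
  expect_false(any(vapply(eq, `[[`, logical(1), "stable")))
  # where a stable cycle exists the equilibrium inside it is unstable
  eq9 <- find_equilibria(ping_params(Ie_ext_bar = 9))
  expect_false(any(vapply(eq9, `[[`, logical(1), "stable")))
})

test_that("Hopf crossing has frequency bounded away from zero", {
  hp <- find_hopf(ping_params(), interval = c(6, 10))
  expect_gt(hp$freq_hz, 20)
  expect_lt(hp$par, 8.4)   # the 8.4 oscillator sits just above the crossing
})
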