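test_that("vector strength has the textbook limits", {
  expect_equal(vector_strength(rep(1.234, 50)), 1)
  expect_equal(vector_strength(seq(0, 2 * pi, length.out = 13)[1:12]), 0,
               tolerance = 1e-12)
  expect_error(vector_strength(numeric(0)), "at least one")
  set.seed(3)
  r <- vector_strength(runif(200, 0, 24), period = 24)
  expect_gte(r, 0); expect_lte(r, 1)
})

test_that("time-T1 iterates converge to a fixed phase without distractor", {
  ip <- ref_iprc()
  p1 <- von_mises_input(A = 0.1, T = 0.9 * ip$Tstar, kappa = 2, mu = 0)
  p2 <- von_mises_input(A = 0, T = 0.9 * ip$Tstar, kappa = 2)
  ph <- time_T1_map_phases(ip, p1, p2, n_iter = 200, burn_in = 100)
  expect_lt(diff(range(ph$phases)), 1e-4)
  expect_gt(vector_strength(ph$phases, period = ip$Tstar), 0.999)
})

test_that("incommensurate forcing fills the circle densely", {
  ip <- ref_iprc()
  p1 <- von_mises_input(A = 0.1, T = ip$Tstar, kappa = 2, mu = 0)
  p2 <- von_mises_input(A = 0.1, T = ip$Tstar, kappa = 20)
  ph <- time_T1_map_phases(ip, p1, p2, n_iter = 1000)
  expect_lt(vector_strength(ph$phases, period = ip$Tstar), 0.2)
  # phases spread over most of the circle
  expect_gt(diff(range(ph$phases)) / ip$Tstar, 0.9)
})

test_that("entrainment robustness depends on the frequency relationship", {
  ip <- ref_iprc()
  # left side of the tongue: robust to any distractor scanned
  robust <- robustness_scan(ip, T1_rel = 0.845,
                            kappa2_values = c(0.01, 2, 20),
                            T2_ratio_values = c(0.5, 1, 1.5))
  expect_true(all(robust$value[robust$metric == "SI"] > 0.8))
  expect_true(all(robust$locked))
  # right edge: any distractor disrupts (SI below 0.5)
  fragile <- robustness_scan(ip, T1_rel = 1,
                             kappa2_values = c(2, 20),
                             T2_ratio_values = c(0.75, 1, 1.2))
  expect_true(all(fragile$value[fragile$metric == "SI"] < 0.5))
  expect_false(any(fragile$locked))
  # middle: faster coherent distractors break it, slower ones do not
  mid <- robustness_scan(ip, T1_rel = 0.93, kappa2_values = 20,
                         T2_ratio_values = c(0.75, 1.2, 1.4))
  expect_false(mid$locked[mid$T2_ratio == 0.75])
  expect_true(all(mid$locked[mid$T2_ratio > 1]))
})

test_that("primary strength drives the E-volley; distractor is ignored", {
  cyc <- ref_cycle()
  T1 <- 0.845 * cyc$period
  p1 <- von_mises_input(A = 0.1, T = T1, kappa = 2, mu = 0)
  p2 <- von_mises_input(A = 0.1, T = 1.2 * T1, kappa = 2)
  # amplitudes off: all factors 1 with zero spread
  off <- distractor_response_factors(cyc, p1, p2, vary = "A1",
                                     values = 0, n_cycles = 5,
                                     settle_cycles = 10)
  p1z <- p1; p1z$A <- 0
  off0 <- distractor_response_factors(cyc, p1z, p2, vary = "A2", values = 0,
                                      n_cycles = 5, settle_cycles = 10)
  # grid-limited agreement: the per-window peak/width estimates carry the
  # sampling error of the 256-point window
  expect_equal(off0$dalpha_mean, 1, tolerance = 1e-3)
  expect_equal(off0$dsigma_mean, 1, tolerance = 1e-3)
  expect_lt(off0$dalpha_sd, 1e-4)
  # raising A1 sharpens the E-volley much more than raising A2
  swA1 <- distractor_response_factors(cyc, p1, p2, vary = "A1",
                                      values = c(0, 0.1))
  swA2 <- distractor_response_factors(cyc, p1, p2, vary = "A2",
                                      values = c(0, 0.1))
  dA1 <- abs(diff(swA1$dalpha_mean))
  dA2 <- abs(diff(swA2$dalpha_mean))
  expect_gt(dA1, 0.5)
  expect_lt(dA2, 0.4 * dA1)
  expect_lt(swA1$dsigma_mean[2], swA1$dsigma_mean[1])  # sharper volleys
})

test_that("a zero-amplitude pulse shifts nothing and switches nothing", {
  cyc <- ref_cycle()
  sp <- pulse_switch_prc(cyc, phases = c(0.2, 0.5, 0.8),
                         pulse = square_pulse(amplitude = 0))
  expect_true(all(abs(sp$prc) < 1e-6))
  expect_false(any(sp$switched))
  expect_true(all(sp$entrained))
})

test_that("switching phases form a contiguous window around mid-cycle", {
  cyc <- ref_cycle()
  sp <- pulse_switch_prc(cyc, phases = seq(0, 0.95, by = 0.05))
  expect_true(any(sp$switched))
  sw <- sp$phase[sp$switched]
  # contiguous block on the scanned grid
  expect_equal(length(sw), sum(diff(range(sw)) / 0.05) + 1, tolerance = 0)
  expect_true(0.5 %in% sw)
  expect_false(0.3 %in% sw)
  # pulses typically advance the phase; near the I-volley the shift ~ 0
  expect_gt(mean(sp$prc > -0.03), 0.9)
  expect_lt(min(abs(sp$prc)), 0.01)
})

test_that("the two antiphase attractors give opposite switch detectors", {
  cyc <- ref_cycle()
  base <- pingctc:::antiphase_base_orbit(cyc)
  T0 <- base$T_input
  tt <- seq(0, 6 * T0, by = T0 / 512)
  tr <- integrate_meanfield(base$x0, tt, cyc$params, base$forcing,
                            tol = 1e-10)
  te <- pingctc:::revolley_times(tt, tr$r_e)
  d1 <- pingctc:::effective_input_d(te[3], T0)
  # the time-shifted solution is the other attractor
  x2 <- pingctc:::mf_flow(base$x0, 0, T0 / 2, cyc$params, base$forcing,
                          tol = 1e-10)$y
  # advance the forcing phase accordingly: peaks swap roles
  d2 <- pingctc:::effective_input_d(te[3] + T0 / 2, T0)
  expect_equal(sign(d1 * d2), -1)
})
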