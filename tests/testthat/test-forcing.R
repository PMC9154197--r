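test_that("von Mises input reduces to the uniform drive at kappa = 0", {
  vm <- von_mises_input(A = 1, T = 20, kappa = 0)
  tt <- seq(0, 40, by = 0.37)
  expect_equal(von_mises_eval(vm, tt), rep(1, length(tt)))
})

test_that("peak value matches the Bessel-series oracle", {
  vm <- von_mises_input(A = 1, T = 20, kappa = 2, mu = 3)
  expect_equal(von_mises_eval(vm, 3), exp(2) / bessel_i0_series(2),
               tolerance = 1e-12)
  expect_equal(von_mises_eval(vm, 3), 3.2414, tolerance = 1e-4)
  # maximal at t = mu, periodic with period T
  tt <- seq(0, 20, by = 0.01)
  expect_equal(tt[which.max(von_mises_eval(vm, tt))], 3, tolerance = 0.02)
  expect_equal(von_mises_eval(vm, 7.3), von_mises_eval(vm, 7.3 + 20))
})

test_that("temporal average over one period is 1 for every coherence", {
  for (kap in c(0.5, 2, 20, 50)) {
    vm <- von_mises_input(A = 1, T = 17.3, kappa = kap)
    avg <- stats::integrate(function(t) von_mises_eval(vm, t), 0, 17.3,
                            rel.tol = 1e-12, abs.tol = 1e-13,
                            subdivisions = 2000L)$value / 17.3
    expect_equal(avg, 1, tolerance = 1e-10)
  }
})

test_that("large coherence concentrates the mass toward the delta limit", {
  vm <- von_mises_input(A = 1, T = 20, kappa = 200, mu = 10)
  inside <- stats::integrate(function(t) von_mises_eval(vm, t),
                             10 - 2, 10 + 2, rel.tol = 1e-10)$value
  total <- 20  # average 1 over the period
  expect_gt(inside / total, 0.99)
  expect_true(all(von_mises_eval(vm, seq(0, 20, by = 0.1)) >= 0))
})

test_that("two-input placement follows the antiphase/midpoint rule", {
  p1 <- von_mises_input(A = 0.1, T = 20, kappa = 2, mu = 0)
  eq <- arrange_two_inputs(p1, von_mises_input(A = 0.1, T = 20, kappa = 20))
  expect_equal(eq$inputs[[2]]$mu, 10)
  slow <- arrange_two_inputs(p1, von_mises_input(A = 0.1, T = 24, kappa = 2))
  expect_equal(slow$inputs[[2]]$mu, 10)
  fast <- arrange_two_inputs(p1, von_mises_input(A = 0.1, T = 10, kappa = 2))
  expect_equal(fast$inputs[[2]]$mu, 5)
  expect_error(arrange_two_inputs(von_mises_input(A = 1, T = 20, mu = 2),
                                  p1), "mu = 0")
  # combined drive is the sum of the two inputs
  tt <- seq(0, 30, by = 0.31)
  expect_equal(forcing_eval(slow, tt),
               von_mises_eval(slow$inputs[[1]], tt) +
                 von_mises_eval(slow$inputs[[2]], tt))
})

test_that("square pulse is a rectangle applied to the E population only", {
  sq <- square_pulse(onset = 5)
  expect_equal(square_pulse_eval(sq, 4.999), 0)
  expect_equal(square_pulse_eval(sq, 5), 1.5)
  expect_equal(square_pulse_eval(sq, 6.9), 1.5)
  expect_equal(square_pulse_eval(sq, 7), 0)
  expect_equal(stats::integrate(function(t) square_pulse_eval(sq, t),
                                0, 20, subdivisions = 2000L,
                                rel.tol = 1e-8)$value, 3, tolerance = 1e-4)
  # only dV_e/dt sees the pulse
  p <- ping_params()
  st <- network_state()
  fo <- forcing_spec(pulse = sq)
  d_on <- meanfield_rhs(st, t = 5.5, params = p, forcing = fo)
  d_off <- meanfield_rhs(st, t = 0, params = p, forcing = fo)
  expect_equal(d_on[["V_e"]] - d_off[["V_e"]], 1.5)
  expect_equal(d_on[-2], d_off[-2])
})

test_that("pulse train is symbolic and rejected by the ODE path", {
  pt <- pulse_train(A = 0.1, T = 20)
  expect_s3_class(pt, "pulse_train")
  expect_error(forcing_spec(pt))
})
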