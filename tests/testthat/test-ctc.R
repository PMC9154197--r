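# a locked orbit at a given T/T* for the reference oscillator
lock_at <- function(T_rel, A = 0.1, kappa = 2, p = 1, q = 1) {
  cyc <- ref_cycle()
  fo <- forcing_spec(von_mises_input(A = A, T = T_rel * cyc$period,
                                     kappa = kappa))
  full_model_locking(cyc, fo, p = p, q = q, iprc = ref_iprc())
}

test_that("response factors are exactly 1 on the unperturbed cycle", {
  cyc <- ref_cycle()
  fx <- response_factors(cyc, cyc)
  expect_identical(fx$delta_alpha_bar, 1)
  expect_identical(fx$delta_alpha, 1)
  expect_identical(fx$delta_sigma, 1)
})

test_that("delta_tau measures input-to-inhibition timing", {
  ob <- lock_at(0.9)
  expect_s3_class(ob, "ping_orbit")
  dt <- delta_tau(ob)
  expect_gte(dt, 0); expect_lt(dt, 1)
  # input peak coincident with the r_i peak gives 0: shift the input's mu
  # to the measured inhibition peak and recompute
  ri <- ob$states[, "r_i"]
  t_inh <- pingctc:::find_volleys(ob$t, ri, 1)
  ob2 <- ob
  ob2$forcing$inputs[[1]]$mu <- t_inh
  expect_equal(delta_tau(ob2), 0, tolerance = 1e-6)
})

test_that("mean-rate factor is consistent with the integral mean rates", {
  ob <- lock_at(0.9)
  cyc <- ref_cycle()
  fx <- response_factors(ob, cyc)
  expect_equal(fx$delta_alpha_bar,
               integral_mean_rates(ob)[["R_e"]] /
                 integral_mean_rates(cyc)[["R_e"]],
               tolerance = 1e-8)
})

test_that("high-frequency entrainment sharpens the E-volley", {
  cyc <- ref_cycle()
  left <- response_factors(lock_at(0.85, A = 0.2), cyc)
  expect_gt(left$delta_alpha, 1.5)   # much greater than 1
  expect_lt(left$delta_sigma, 0.6)   # much smaller than 1
  # near T/T* = 1 the E-volley barely changes
  right <- response_factors(lock_at(1.0, A = 0.1), cyc)
  expect_lt(abs(right$delta_alpha - 1), 0.15)
  expect_gt(right$delta_sigma, 0.9)
})

test_that("factors sweep the 1:1 tongue as in the CTC picture", {
  cyc <- ref_cycle(); ip <- ref_iprc()
  sw <- tongue_section_sweep(cyc, ip, kappa = 2, A_values = c(0.05, 0.1),
                             n_T = 8)
  sw <- sw[sw$locked, ]
  expect_gt(nrow(sw), 10)
  # the input-to-inhibition lead grows as T/T* decreases from the right edge
  for (A in unique(sw$A)) {
    s <- sw[sw$A == A, ]
    s <- s[s$dtau < 0.9, ]          # drop wrapped near-zero values
    expect_true(all(diff(s$dtau) < 0))
  }
  # left side reaches the ~0.4 lead; right side is close to 0 (mod 1)
  expect_gt(max(sw$dtau[sw$dtau < 0.9]), 0.25)
  expect_true(any(sw$dtau > 0.9 | sw$dtau < 0.05))
  # weak modulation of the mean rate across the whole tongue
  expect_lt(max(sw$dalpha_bar), 1.3)
})

test_that("1:2 entrainment modulates the E-volley like the 1:1 case", {
  cyc <- ref_cycle()
  ob <- lock_at(0.45, A = 0.1, q = 2)
  expect_s3_class(ob, "ping_orbit")
  expect_equal(ob$period, 2 * ob$T_input)
  fx <- response_factors(ob, cyc)
  expect_gt(fx$delta_alpha, 1)
  expect_lt(fx$delta_sigma, 1)
  expect_gte(fx$delta_tau, 0); expect_lt(fx$delta_tau, 1)
})

test_that("2:1 entrainment reports one timing factor per volley", {
  ob <- lock_at(1.85, A = 0.1, p = 2)
  expect_s3_class(ob, "ping_orbit")
  dt <- delta_tau(ob)
  expect_length(dt, 2)
  expect_true(all(dt >= 0 & dt < 1))
})
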