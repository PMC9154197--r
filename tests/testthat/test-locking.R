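test_that("stroboscopic map is a rigid rotation without forcing", {
  ip <- ref_iprc()
  fo0 <- forcing_spec(von_mises_input(A = 0, T = 17.7, kappa = 2))
  sm <- stroboscopic_map(4.2, ip, fo0)
  expect_equal(sm$lift, 4.2 + 17.7, tolerance = 1e-10)
  expect_equal(sm$theta, (4.2 + 17.7) %% ip$Tstar, tolerance = 1e-10)
})

test_that("pulsatile stroboscopic map is the explicit closed form", {
  ip <- ref_iprc()
  pt <- pulse_train(A = 0.07, T = 19)
  th <- 6.3
  sm <- stroboscopic_map(th, ip, pt)
  expect_equal(sm$lift, th + 19 + 0.07 * 19 * iprc_eval(ip, th))
  # two compositions
  sm2 <- stroboscopic_map(th, ip, pt, q = 2)
  th1 <- th + 19 + 0.07 * 19 * iprc_eval(ip, th)
  expect_equal(sm2$lift, th1 + 19 + 0.07 * 19 * iprc_eval(ip, th1))
})

test_that("the lift is orientation-preserving at moderate forcing", {
  ip <- ref_iprc()
  fo <- forcing_spec(von_mises_input(A = 0.1, T = 0.9 * ip$Tstar, kappa = 2))
  th <- seq(0, ip$Tstar, length.out = 17)[1:16]
  P <- vapply(th, function(t0) stroboscopic_map(t0, ip, fo)$lift, numeric(1))
  Pd <- vapply(th + 1e-3, function(t0)
    stroboscopic_map(t0, ip, fo)$lift, numeric(1))
  expect_true(all(Pd > P))
})

test_that("rotation number is exact for rigid rotations", {
  # weighted Birkhoff average on a synthetic rigid lift
  expect_equal(pingctc:::wba_rotation(seq(0, by = 3.21, length.out = 751)),
               3.21)
  ip <- ref_iprc()
  # A = 0: rho_hat = T/T* to near machine precision
  for (tr in c(0.8, 1.03)) {
    fo0 <- forcing_spec(von_mises_input(A = 0, T = tr * ip$Tstar, kappa = 2))
    expect_equal(rotation_number(ip, fo0)$rho_hat, tr, tolerance = 1e-9)
  }
})

test_that("rotation number locks to 1 inside the 1:1 plateau", {
  ip <- ref_iprc()
  fo <- forcing_spec(von_mises_input(A = 0.1, T = 0.9 * ip$Tstar, kappa = 2))
  rot <- rotation_number(ip, fo)
  expect_equal(rot$rho_hat, 1, tolerance = 1e-4)
})

test_that("staircase is monotone in T and trivial at A = 0", {
  ip <- ref_iprc()
  grid <- seq(0.7, 1.1, by = 0.05)
  sc0 <- devils_staircase(ip, A = 0, kappa = 2, grid)
  expect_equal(sc0$rho_hat, grid, tolerance = 1e-9)
  sc <- devils_staircase(ip, A = 0.1, kappa = 2, grid)
  expect_true(all(diff(sc$rho_hat) > -1e-9))
})

test_that("higher coherence widens the 1:1 plateau", {
  ip <- ref_iprc()
  lo <- plateau_interval(ip, A = 0.1, kappa = 0.5, T_range = c(0.75, 1.05),
                         step = 0.005)
  hi <- plateau_interval(ip, A = 0.1, kappa = 20, T_range = c(0.75, 1.05),
                         step = 0.005)
  expect_gt(hi$right - hi$left, lo$right - lo$left)
  # the lower-coherence plateau is enclosed in the higher-coherence one
  expect_lte(hi$left, lo$left + 1e-3)
  expect_gte(hi$right, lo$right - 1e-3)
})

test_that("continuation boundaries satisfy the defining equations", {
  ip <- ref_iprc()
  tng <- tongue_boundary_continuation(1, 1, ip, kappa = 2, A_max = 0.15)
  expect_identical(tng$left_status, "reached A_max")
  expect_identical(tng$right_status, "reached A_max")
  # tongue tip: both boundaries pass through T/T* = 1 at A -> 0
  expect_equal(tng$left$T_over_Tstar[1], 1, tolerance = 0.02)
  expect_equal(tng$right$T_over_Tstar[1], 1, tolerance = 0.02)
  # continuation closure ||G|| < 1e-9 on a sample of points
  for (side in c("left", "right")) {
    b <- tng[[side]]
    for (k in unique(round(seq(1, nrow(b), length.out = 4)))) {
      G <- pingctc:::tongue_G(c(b$theta[k], b$T_over_Tstar[k] * ip$Tstar,
                                b$A[k]), 1, 1, ip, kappa = 2)
      expect_lt(max(abs(G)), 1e-9)
    }
  }
  # boundaries bracket the staircase plateau at A = 0.1
  pl <- plateau_interval(ip, A = 0.1, kappa = 2, T_range = c(0.75, 1.05),
                         step = 0.005)
  sec <- tongue_section(tng, 0.1)
  expect_equal(unname(sec["left"]), pl$left, tolerance = 0.01)
  expect_equal(unname(sec["right"]), pl$right, tolerance = 0.01)
})

test_that("coherence-ordered tongues are nested", {
  ip <- ref_iprc()
  t05 <- tongue_boundary_continuation(1, 1, ip, kappa = 0.5, A_max = 0.1)
  t20 <- tongue_boundary_continuation(1, 1, ip, kappa = 20, A_max = 0.1)
  s05 <- tongue_section(t05, 0.1); s20 <- tongue_section(t20, 0.1)
  expect_lt(s20["left"], s05["left"])
  expect_gt(s20["right"], s05["right"])
})

test_that("pulsatile closed forms agree with high-coherence continuation", {
  ip <- ref_iprc()
  pt <- pulsatile_tongue_analytic(1, 1, ip, A_max = 0.1)
  # tip at A = 0 sits at T/T* = p/q
  expect_equal(pt$left$T_over_Tstar[1], 1)
  expect_equal(pt$right$T_over_Tstar[1], 1)
  # the reference oscillator has Z_min close to 0: right boundary stays
  # nearly vertical at T/T* ~ 1
  expect_lt(abs(pt$right$T_over_Tstar[nrow(pt$right)] - 1), 0.05)
  tng <- tongue_boundary_continuation(1, 1, ip, kappa = 200, A_max = 0.1)
  for (A in c(0.05, 0.1)) {
    pa <- tongue_section(pt, A); co <- tongue_section(tng, A)
    expect_lt(abs(pa["left"] - co["left"]) / co["left"], 0.05)
    expect_lt(abs(pa["right"] - co["right"]) / co["right"], 0.05)
  }
})

test_that("full-model shooting recovers the unperturbed cycle at A = 0", {
  cyc <- ref_cycle()
  fo0 <- forcing_spec(von_mises_input(A = 0, T = cyc$period, kappa = 2))
  ob <- full_model_locking(cyc, fo0, x_init = as.numeric(cyc$x0),
                           settle_periods = 0)
  expect_s3_class(ob, "ping_orbit")
  expect_equal(as.numeric(ob$x0), as.numeric(cyc$x0), tolerance = 1e-7)
})

test_that("full-model locking deviates only slightly from the phase
           reduction at moderate amplitude", {
  cyc <- ref_cycle(); ip <- ref_iprc()
  li <- locking_interval(cyc, ip, kappa = 2, A = 0.1, T_start = 0.92,
                         step = 0.01, bisect_tol = 2e-3)
  pl <- plateau_interval(ip, A = 0.1, kappa = 2, T_range = c(0.75, 1.06),
                         step = 0.005)
  expect_lt(abs(li$left - pl$left), 0.03)
  expect_lt(abs(li$right - pl$right), 0.03)
})
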