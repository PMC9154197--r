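test_that("analytic Jacobian has the exact synaptic entries", {
  p <- ping_params(J_ee = 3, J_ii = 7)
  st <- network_state(r_e = 0.05, V_e = 0.3, r_i = 0.02, V_i = -1)
  J <- meanfield_jacobian(st, p)
  expect_equal(J["S_ee", "r_e"], 3 / p$tau_se)
  expect_equal(J["S_ie", "r_e"], p$J_ie / p$tau_se)
  expect_equal(J["S_ei", "r_i"], p$J_ei / p$tau_si)
})

test_that("Jacobian matches central differences along the cycle", {
  cyc <- ref_cycle()
  set.seed(1)
  for (ph in runif(10) * cyc$period) {
    st <- as.numeric(interp_cycle(cyc, ph))
    J <- linearize_along_cycle(cyc, ph)
    h <- 1e-6
    Jfd <- matrix(0, 8, 8)
    for (j in 1:8) {
      sp <- st; sm <- st
      sp[j] <- sp[j] + h; sm[j] <- sm[j] - h
      Jfd[, j] <- (meanfield_rhs(sp, params = cyc$params) -
                   meanfield_rhs(sm, params = cyc$params)) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
  # trace is T*-periodic along the cycle
  expect_equal(sum(diag(linearize_along_cycle(cyc, 1.234))),
               sum(diag(linearize_along_cycle(cyc, 1.234 + cyc$period))))
})

test_that("adjoint solution satisfies the normalization identity", {
  ip <- ref_iprc()
  expect_lt(ip$normalization_residual, 1e-6)
  # Z . gamma' = 1 at every stored phase
  cyc <- ref_cycle()
  derivs <- pingctc:::mf_derivs_matrix(
    interp_cycle(cyc, ip$theta), ip$theta, cyc$params)
  expect_lt(max(abs(rowSums(ip$Z * derivs) - 1)), 1e-6)
  # periodic endpoints
  expect_equal(iprc_eval(ip, 0), iprc_eval(ip, cyc$period), tolerance = 1e-8)
})

test_that("iPRC shape distinguishes the two oscillator types", {
  ip <- ref_iprc()
  # reference oscillator: nearly input-insensitive at the I-volley, positive
  # elsewhere with the maximum shortly before the E-volley (early phases
  # carry the inhibition-dominated part of the cycle)
  expect_gt(max(ip$Zei), 2)
  expect_gt(min(ip$Zei), -0.15 * max(ip$Zei))
  th_max <- ip$theta_norm[which.max(ip$Zei)]
  expect_gt(th_max, 0.6)  # late in the cycle, before the next E-volley
  # Hopf-proximal oscillator: both signs, substantially negative
  ip84 <- hopf_iprc()
  expect_gt(max(ip84$Zei), 0)
  expect_lt(min(ip84$Zei), -0.3 * max(ip84$Zei))
})

test_that("adjoint matches direct perturbations of the full system", {
  cyc <- ref_cycle()
  ip <- ref_iprc()
  phases <- seq(0, cyc$period, length.out = 17)[1:16]
  direct <- perturbation_phase_shift(cyc, phases, eps = 1e-4)
  adjoint <- vapply(phases, function(ph) iprc_eval(ip, ph, "e"), numeric(1))
  expect_lt(max(abs(direct - adjoint)) / max(abs(adjoint)), 0.02)
})

test_that("iPRC is stable under grid refinement", {
  cyc <- ref_cycle()
  ipA <- solve_adjoint(cyc, n_theta = 512, n_fine = 2048)
  ipB <- solve_adjoint(cyc, n_theta = 512, n_fine = 4096)
  expect_lt(max(abs(ipA$Zei - ipB$Zei)), 1e-5)
})

test_that("spectral differentiation is exact on band-limited samples", {
  n <- 256; Tp <- 5
  tt <- seq(0, Tp, length.out = n + 1)[1:n]
  s <- sin(2 * pi * tt / Tp)
  d <- fft_derivative(s, Tp)
  expect_lt(max(abs(d - 2 * pi / Tp * cos(2 * pi * tt / Tp))), 1e-10)
  expect_lt(abs(mean(d)), 1e-12)
  # on the computed iPRC the spectral derivative matches central differences
  ip <- ref_iprc()
  h <- ip$theta[2] - ip$theta[1]
  n <- length(ip$Zei)
  cd <- (ip$Zei[c(2:n, 1)] - ip$Zei[c(n, 1:(n - 1))]) / (2 * h)
  expect_lt(max(abs(iprc_derivative_fft(ip) - cd)) / max(abs(cd)), 0.01)
})

test_that("phase equation reduces to drift without forcing and sums inputs", {
  ip <- ref_iprc()
  fo0 <- forcing_spec(von_mises_input(A = 0, T = 20, kappa = 2))
  expect_equal(phase_ode_rhs(3.7, 11.2, ip, fo0), 1)
  # g = A1 p1 + A2 p2 enters as a single scalar term
  p1 <- von_mises_input(A = 0.1, T = 20, kappa = 2, mu = 0)
  p2 <- von_mises_input(A = 0.2, T = 24, kappa = 5, mu = 10)
  fo2 <- forcing_spec(list(p1, p2))
  t <- 13.4; th <- 5.5
  expect_equal(phase_ode_rhs(th, t, ip, fo2),
               1 + (von_mises_eval(p1, t) + von_mises_eval(p2, t)) *
                 iprc_eval(ip, th))
  # zero forcing integrates to theta(t) = t + theta0
  fl <- pingctc:::phase_flow(2.5, 0, 37, c(0, 37), ip, fo0)
  expect_equal(fl$theta[2], 2.5 + 37, tolerance = 1e-10)
})
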