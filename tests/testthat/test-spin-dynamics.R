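test_that("dipolar rates match an independent step-by-step evaluation", {
  r <- dipolar_rates(dipolar_params())
  # independent oracle: literal constants evaluated term by term
  gamma_rad <- 2 * pi * 42.576 * 1e6            # rad/s/T
  b <- 1e-7 * 1.054571628e-34 * gamma_rad^2 / (158e-12)^3
  expect_equal(b, 1.9133493503e5, tolerance = 1e-9)
  w0 <- gamma_rad * 9.4
  tau <- 10e-12
  J0 <- tau
  J1 <- tau / (1 + (w0 * tau)^2)
  J2 <- tau / (1 + (2 * w0 * tau)^2)
  expect_equal(unname(r["R1"]), 0.3 * b^2 * (J1 + 4 * J2), tolerance = 1e-12)
  expect_equal(unname(r["R2"]), 0.15 * b^2 * (3 * J0 + 5 * J1 + 2 * J2),
               tolerance = 1e-12)
  # frozen values from the oracle
  expect_equal(unname(r["R1"]), 0.547958104713, tolerance = 1e-9)
  expect_equal(unname(r["R2"]), 0.548685263969, tolerance = 1e-9)
  # extreme narrowing: R1 ~= R2 within 0.2%
  expect_lt(abs(r["R1"] / r["R2"] - 1), 0.002)
  # near-linearity in tau_c in the narrowing limit
  r2 <- dipolar_rates(dipolar_params(tau_c = 20e-12))
  expect_equal(unname(r2["R1"] / r["R1"]), 2, tolerance = 0.01)
  expect_equal(unname(r2["R2"] / r["R2"]), 2, tolerance = 0.01)
  expect_error(dipolar_params(tau_c = -1), "positive")
})

test_that("two-pool systems have the documented fractions, offsets and balance", {
  sys <- two_pool_system("Fn1", "healthy")
  expect_equal(sys$P_A, 1.2e-6 / 80)   # 1.5e-8
  expect_equal(sys$P_A + sys$P_B, 1, tolerance = 1e-12)
  expect_equal(sys$delta_A, 2 * pi * sys$P_B * 500)
  expect_equal(sys$delta_B, 2 * pi * sys$P_A * 500)
  up <- two_pool_system("Fn1", "upregulated")
  expect_equal(up$P_A / sys$P_A, 10)
  po <- two_pool_system("Postn", "healthy")
  expect_equal(po$P_A, 1.1e-9 / 80)
  # detailed balance of exchange fluxes
  expect_equal(sys$k_AB * sys$P_A, sys$k_BA * sys$P_B, tolerance = 1e-15)
  # tau_ex interpretation switch
  fast <- two_pool_system("Fn1", "healthy", tau_ex_is_time = TRUE)
  expect_equal(fast$k_ex, 1000)
  expect_error(two_pool_system("Xyz"), "arg")
})

test_that("propagation is unitary without relaxation and follows closed forms", {
  sys <- water_system()
  pk <- make_raff2_packet(625, 1.0)
  M0 <- equilibrium_state(sys)
  M1 <- propagate(sys, pk, initial = M0, relaxation = FALSE, exchange = FALSE)
  expect_equal(sqrt(sum(as.numeric(M1[1, 2:7])^2)), sqrt(sum(M0^2)),
               tolerance = 1e-8)
  # pi pulse inverts Mz
  w1_hz <- 500
  pulse <- const_shape(w1_hz, duration = 1 / (2 * w1_hz), n = 1)
  Mp <- propagate(sys, pulse, relaxation = FALSE, exchange = FALSE)
  expect_equal(Mp$Mz[1], -1, tolerance = 1e-6)
  # inversion recovery of the dominant pool under zero RF
  zero <- const_shape(0, duration = 0.5, n = 8)
  tt <- c(0.1, 0.25, 0.5)
  Mr <- propagate(sys, zero, initial = equilibrium_state(sys, -1),
                  record_at = tt, exchange = FALSE)
  expect_equal(Mr$MzB, sys$P_B * (1 - 2 * exp(-sys$R1 * tt)), tolerance = 1e-8)
  # thermal equilibrium is a fixed point
  Me <- propagate(sys, zero, record_at = c(0.2, 0.5))
  expect_equal(Me$Mz, c(1, 1), tolerance = 1e-9)
  expect_error(propagate(sys, zero, record_at = 1.0), "within")
})

test_that("matrix-exponential and adaptive ODE propagation agree", {
  sys <- water_system()
  pk <- make_raff2_packet(625, 1.0, n_samples = 64)
  Ma <- propagate(sys, pk, method = "expm")
  Mb <- propagate(sys, pk, method = "ode")
  for (comp in c("MxA", "MyA", "MzA", "MxB", "MyB", "MzB")) {
    expect_equal(Mb[[comp]], Ma[[comp]], tolerance = 1e-7)
  }
})

test_that("decay curves start at +/-1 and are insensitive to protein upregulation", {
  pk <- make_raff2_packet(625, 1.0)
  h <- simulate_decay_curves(two_pool_system("Fn1", "healthy"), pk)
  u <- simulate_decay_curves(two_pool_system("Fn1", "upregulated"), pk)
  expect_equal(h$signal[h$polarity == "+Z"][1], 1, tolerance = 1e-12)
  expect_equal(h$signal[h$polarity == "-Z"][1], -1, tolerance = 1e-12)
  expect_equal(h$signal, u$signal, tolerance = 1e-6)
  fh <- fit_ss_model(h)
  fu <- fit_ss_model(u)
  expect_lt(abs(fh$R - fu$R), 0.01)
  expect_lt(abs(abs(fh$SS_fraction) - abs(fu$SS_fraction)), 0.005)
})

test_that("stretched packets decay faster: TL2.0 below TL0.6 at common times", {
  sys <- water_system()
  c06 <- simulate_decay_curves(sys, make_raff2_packet(625, 0.6))
  c20 <- simulate_decay_curves(sys, make_raff2_packet(625, 2.0))
  p06 <- c06[c06$polarity == "+Z", ]
  p20 <- c20[c20$polarity == "+Z", ]
  probe <- seq(0.02, min(max(p06$time), max(p20$time)), length.out = 7)
  s06 <- stats::approx(p06$time, p06$signal, probe)$y
  s20 <- stats::approx(p20$time, p20$signal, probe)$y
  expect_true(all(s20 < s06))
})

test_that("fitted R is stable under waveform sample doubling", {
  sys <- water_system()
  f1 <- fit_ss_model(simulate_decay_curves(sys, make_raff2_packet(625, 1.0, 128)))
  f2 <- fit_ss_model(simulate_decay_curves(sys, make_raff2_packet(625, 1.0, 256)))
  expect_lt(abs(f2$R - f1$R) / f1$R, 0.005)
})

test_that("steady-state fraction falls monotonically with the stretching factor", {
  tab <- simulate_relaxation_table(
    scenarios = "Fn1 healthy",
    methods = sprintf("RAFF2 TL%.1f", seq(0.6, 2.0, by = 0.2)),
    max_packets = 64, n_timepoints = 33)
  expect_true(all(diff(tab$SS) < 0))
  expect_true(all(tab$converged))
})
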