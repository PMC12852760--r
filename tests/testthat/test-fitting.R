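test_that("joint steady-state fit inverts its own forward model exactly", {
  tt <- seq(0, 0.144, length.out = 33)
  R_true <- 3.83
  ss_true <- 0.69
  cp <- data.frame(time = tt, signal = ss_forward(tt, R_true, ss_true))
  cm <- data.frame(time = tt, signal = ss_forward_minus(tt, R_true, ss_true))
  fit <- fit_ss_model(cp, cm)
  expect_equal(fit$R, R_true, tolerance = 1e-6)
  expect_equal(abs(fit$SS_fraction), ss_true, tolerance = 1e-6)
  expect_equal(fit$SI0_plus, 1, tolerance = 1e-6)
  expect_equal(fit$SI0_minus, -1, tolerance = 1e-6)
  expect_true(fit$converged)
  # homogeneity: common rescaling leaves R and the SS fraction unchanged
  fit3 <- fit_ss_model(transform(cp, signal = 3 * signal),
                       transform(cm, signal = 3 * signal))
  expect_equal(fit3$R, fit$R, tolerance = 1e-6)
  expect_equal(fit3$SS_fraction, fit$SS_fraction, tolerance = 1e-6)
  expect_equal(fit3$S_SS, 3 * fit$S_SS, tolerance = 1e-6)
  expect_equal(fit3$SI0_plus, 3 * fit$SI0_plus, tolerance = 1e-6)
  # broom-style accessors
  expect_equal(nrow(tidy(fit)), 5L)
  expect_true(glance(fit)$converged)
})

test_that("the steady-state model nests the monoexponential decay", {
  tt <- seq(0, 0.15, length.out = 12)
  y <- 2 * exp(-tt / 0.04)
  cp <- data.frame(time = tt, signal = y)
  cm <- data.frame(time = tt, signal = -y)
  f_ss <- fit_ss_model(cp, cm, fix_ss0 = TRUE)
  f_me <- fit_monoexp(cp)
  expect_equal(f_ss$R, 1 / f_me$T, tolerance = 1e-8)
  expect_error(fit_ss_model(cp, data.frame(time = tt + 1e-3, signal = -y)),
               "time grid")
  expect_error(fit_ss_model(cp[1:2, ], cm[1:2, ]), "3 time points")
})

test_that("monoexponential fits recover T on the protocol echo grids", {
  # T2 echo train grid
  tt <- c(0, 18.2, 36.4, 72.8) * 1e-3
  f <- fit_monoexp(data.frame(time = tt, signal = exp(-tt / 0.03)))
  expect_equal(f$T, 0.03, tolerance = 1e-8)
  # CW spin-lock duration grid
  tt2 <- c(0, 18, 36, 54) * 1e-3
  f2 <- fit_monoexp(data.frame(time = tt2, signal = 5 * exp(-tt2 / 0.04)))
  expect_equal(f2$T, 0.04, tolerance = 1e-8)
  expect_equal(f2$S0, 5, tolerance = 1e-8)
  # degenerate constant signal is flagged, not silently fitted
  fc <- fit_monoexp(data.frame(time = tt, signal = rep(2, 4)))
  expect_false(fc$converged)
  expect_equal(fc$T, Inf)
  expect_error(fit_monoexp(data.frame(time = tt, signal = rep(0, 4))), "zero")
  expect_error(fit_monoexp(data.frame(time = tt[1:2], signal = c(1, 0.5))),
               "3 time points")
})

test_that("B1 nutation fits recover the drive frequency", {
  tt <- seq(0, 1e-3, by = 0.125e-3)
  f620 <- fit_b1_nutation(tt, cos(2 * pi * 620 * tt))
  expect_equal(f620$b1_hz, 620, tolerance = 1e-3)
  f625 <- fit_b1_nutation(tt, cos(2 * pi * 625 * tt))
  expect_equal(f625$b1_hz, 625, tolerance = 1e-3)
  fs <- fit_b1_nutation(tt, 7 * cos(2 * pi * 620 * tt))
  expect_equal(fs$b1_hz, f620$b1_hz, tolerance = 1e-9)
  expect_equal(fs$amplitude, 7, tolerance = 1e-6)
  expect_error(fit_b1_nutation(tt[1:3], cos(2 * pi * 620 * tt[1:3])), "4 points")
})

test_that("pixel-wise maps equal the scalar fit and invert the forward model", {
  tt <- seq(0, 0.144, length.out = 9)
  # uniform noiseless stack
  y <- ss_forward(tt, R = 20, ss = 0.3)
  ym <- ss_forward_minus(tt, R = 20, ss = 0.3)
  stack_p <- array(rep(y, 6 * 5), c(9, 6, 5))
  stack_m <- array(rep(ym, 6 * 5), c(9, 6, 5))
  mp <- fit_map(stack_p, tt, model = "ss_model", paired_stack = stack_m)
  scal <- fit_ss_model(data.frame(time = tt, signal = y),
                       data.frame(time = tt, signal = ym))
  expect_equal(unname(mp$values[3, 3]), 1 / scal$R, tolerance = 1e-7)
  expect_equal(max(abs(mp$values - mp$values[1, 1])), 0, tolerance = 1e-9)
  expect_equal(unname(mp$ss[2, 4]), abs(scal$SS_fraction), tolerance = 1e-6)
  # two-region monoexponential stack
  Tmat <- matrix(0.03, 4, 4); Tmat[, 3:4] <- 0.06
  st <- array(0, c(9, 4, 4))
  for (i in 1:9) st[i, , ] <- exp(-tt[i] / Tmat)
  mme <- fit_map(st, tt, model = "monoexp")
  expect_equal(mme$values, Tmat, tolerance = 1e-6)
  # all-false mask flags everything
  m0 <- fit_map(st, tt, model = "monoexp", mask = matrix(FALSE, 4, 4))
  expect_true(all(is.na(m0$values)))
  expect_true(all(!m0$valid))
  expect_error(fit_map(st, tt[1:5]), "matching")
  expect_error(fit_map(st, tt, mask = matrix(TRUE, 3, 3)), "mask shape")
  expect_error(fit_map(st, tt, model = "ss_model"), "paired_stack")
  # tidy() gives a long pixel table
  td <- tidy(mme)
  expect_equal(nrow(td), 16L)
  expect_true(all(td$valid))
})

test_that("map fitting is invariant to time ordering", {
  tt <- seq(0, 0.144, length.out = 9)
  st <- array(0, c(9, 3, 3))
  for (i in 1:9) st[i, , ] <- 2 * exp(-tt[i] / 0.05)
  perm <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  m1 <- fit_map(st, tt, model = "monoexp")
  m2 <- fit_map(st[perm, , , drop = FALSE], tt[perm], model = "monoexp")
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
})

test_that("fitted R is accurate under 1% noise across many pixels", {
  tt <- seq(0, 0.144, length.out = 33)
  R_true <- 20
  npx <- 500
  set.seed(7)
  clean <- ss_forward(tt, R_true, ss = 0.3)
  clean_m <- ss_forward_minus(tt, R_true, ss = 0.3)
  stack_p <- array(clean, c(33, 25, 20)) +
    array(rnorm(33 * npx, 0, 0.01), c(33, 25, 20))
  stack_m <- array(clean_m, c(33, 25, 20)) +
    array(rnorm(33 * npx, 0, 0.01), c(33, 25, 20))
  mp <- fit_map(stack_p, tt, model = "ss_model", paired_stack = stack_m)
  err <- abs(1 / mp$values - R_true) / R_true
  expect_lt(stats::median(err, na.rm = TRUE), 0.02)
})
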