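test_that("RAFF2 packet durations match the preset table within its rounding", {
  presets <- raff2_presets()
  expect_equal(nrow(presets), 8L)
  for (i in seq_len(nrow(presets))) {
    pk <- make_raff2_packet(625, TL = presets$TL[i])
    expect_lt(abs(pk$packet_duration * 1e3 - presets$packet_ms[i]) /
                presets$packet_ms[i], 0.02)
    expect_lt(abs(pk$element_duration * 1e3 - presets$refocus_ms[i]) /
                presets$refocus_ms[i], 0.02)
  }
  # the printed examples
  pk1 <- make_raff2_packet(625, 1.0, 128)
  expect_true(pk1$packet_duration * 1e3 > 2.25 && pk1$packet_duration * 1e3 < 2.27)
  expect_equal(pk1$element_duration * 1e3, 0.57, tolerance = 0.02)
  pk06 <- make_raff2_packet(608, 0.6, 128)
  expect_equal(pk06$packet_duration * 1e3, 1.35, tolerance = 0.02)
  expect_equal(pk06$element_duration * 1e3, 0.34, tolerance = 0.02)
})

test_that("packet geometry: linear TL stretch, peak amplitude, sampling", {
  pk1 <- make_raff2_packet(625, 1.0)
  pk2 <- make_raff2_packet(625, 2.0)
  pk06 <- make_raff2_packet(625, 0.6)
  expect_equal(pk2$element_duration / pk1$element_duration, 2.0)
  expect_equal(pk06$element_duration / pk1$element_duration, 0.6)
  expect_equal(pk2$packet_duration, 2 * pk1$packet_duration)
  # max sampled amplitude reaches the nominal peak power
  expect_equal(max(pk1$shape$amplitude), 2 * pi * 625, tolerance = 1e-3)
  expect_true(all(pk1$shape$amplitude >= 0))
  # uniform sampling, 4 equal elements
  expect_equal(nrow(pk1$shape), 128L)
  dt <- attr(pk1$shape, "dt")
  expect_equal(diff(pk1$shape$time), rep(dt, 127))
  expect_equal(attr(pk1$shape, "duration"), 128 * dt)
  # alpha2 tilt bookkeeping: 45 degrees at TL = 1
  expect_equal(pk1$alpha2, 45)
})

test_that("phase is continuous within elements and interconverts with offsets", {
  pk <- make_raff2_packet(625, 1.0)
  dt <- attr(pk$shape, "dt")
  max_off <- max(abs(shape_offsets(pk$shape)))
  for (el in 0:3) {
    ph <- pk$shape$phase[(el * 32 + 1):(el * 32 + 32)]
    expect_lt(max(abs(diff(ph))), max_off * dt * (1 + 1e-6))
  }
  # lossless (amplitude, phase) <-> (amplitude, offset) interconversion
  set.seed(42)
  off <- rnorm(50, 0, 1000)
  sh <- rf_shape(time = (1:50 - 0.5) * 1e-5,
                 amplitude = runif(50, 0, 100),
                 phase = raffsim:::phase_from_offsets(off, 1e-5), dt = 1e-5)
  expect_equal(shape_offsets(sh), off, tolerance = 1e-10)
})

test_that("RAFFn packets: rank consistency, rank-1 geometry, peak powers", {
  pk2 <- make_raffn_packet(2, 625, 128)
  ref <- make_raff2_packet(625, 1.0, 128)
  expect_equal(pk2$shape$amplitude, ref$shape$amplitude)
  expect_equal(pk2$shape$phase, ref$shape$phase)
  pk1 <- make_raffn_packet(1, 625, 128)
  # constant amplitude and offset with ratio 1 (tan 45 deg) in each element
  a <- pk1$shape$amplitude[1:32]
  o <- shape_offsets(pk1$shape)[1:32]
  expect_equal(a, rep(a[1], 32))
  expect_equal(abs(o / a), rep(1, 32), tolerance = 1e-12)
  peaks <- vapply(1:5, function(r) make_raffn_packet(r)$omega1max_hz, numeric(1))
  expect_true(all(diff(peaks) <= 1e-9))
  expect_equal(peaks[1], 625)
  expect_equal(peaks[2], 625)
  # all ranks share the TL1.0 packet duration
  durs <- vapply(1:5, function(r) make_raffn_packet(r)$packet_duration, numeric(1))
  expect_equal(durs, rep(ref$packet_duration, 5))
  expect_error(make_raffn_packet(6), "rank")
})

test_that("invalid packet arguments are rejected with informative messages", {
  expect_error(make_raff2_packet(-625, 1.0), "omega1max_hz")
  expect_error(make_raff2_packet(625, 0), "TL")
  expect_error(make_raff2_packet(625, 1.0, n_samples = 130), "n_samples")
})

test_that("comparison pulses have the documented modulation shapes", {
  hs1 <- make_comparison_pulse("HS1", 4.5e-3, 2500, truncation_R = 20, n_samples = 257)
  i_max <- which.max(hs1$amplitude)
  expect_equal(i_max, 129L)  # midpoint
  expect_equal(max(hs1$amplitude), 2 * pi * 2500, tolerance = 1e-6)
  cw <- make_comparison_pulse("CW_SL", 18e-3, 1250)
  expect_equal(cw$amplitude, rep(2 * pi * 1250, nrow(cw)))
  expect_equal(max(abs(shape_offsets(cw))), 0)
  hs4 <- make_comparison_pulse("HS4", 4.5e-3, 2500, n_samples = 256)
  expect_equal(hs4$amplitude, rev(hs4$amplitude), tolerance = 1e-12)
  ahp <- make_comparison_pulse("AHP", 4e-3, 2500)
  n <- nrow(ahp)
  expect_equal(ahp$amplitude[n], 2 * pi * 2500, tolerance = 1e-3)
  expect_lt(abs(shape_offsets(ahp)[n]), 2 * pi * 2500 * 0.05) # ends near resonance
  expect_error(make_comparison_pulse("XYZ", 1e-3, 100), "arg")
})

test_that("pulse trains scale with packet count", {
  pk <- make_raff2_packet(625, 1.0)
  tr32 <- build_train(pk, 32)
  expect_true(tr32$total_duration * 1e3 > 72.3 && tr32$total_duration * 1e3 < 72.5)
  expect_equal(length(tr32$boundary_times), 33L)
  expect_equal(tr32$boundary_times[1], 0)
  expect_equal(tr32$boundary_times[33], tr32$total_duration)
  expect_equal(build_train(pk, 0)$total_duration, 0)
  expect_equal(build_train(pk, 64)$total_duration * 1e3, 144, tolerance = 0.01)
  expect_error(build_train(pk, -1), "n_packets")
})

test_that("shape files roundtrip: plain lossless, normalized within wrap", {
  pk <- make_raff2_packet(625, 1.0, 128)
  f <- withr::local_tempfile(fileext = ".shape")
  export_shape(pk$shape, f, dialect = "plain")
  back <- read_shape(f)
  expect_equal(back$amplitude, pk$shape$amplitude, tolerance = 1e-12)
  expect_equal(back$phase, pk$shape$phase, tolerance = 1e-12)
  expect_equal(nrow(back), 128L)
  fn <- withr::local_tempfile(fileext = ".shape")
  export_shape(pk$shape, fn, dialect = "normalized")
  lines <- readLines(fn)
  body <- lines[!startsWith(lines, "#")]
  amp_col <- as.numeric(vapply(strsplit(body, " "), `[`, character(1), 1))
  expect_equal(max(amp_col), 1.0, tolerance = 1e-12)
  backn <- read_shape(fn)
  expect_equal(backn$amplitude, pk$shape$amplitude, tolerance = 1e-9)
  dphi <- (backn$phase - pk$shape$phase) / (2 * pi)
  expect_equal(dphi, round(dphi), tolerance = 1e-9)  # equal modulo 2 pi
  # malformed files are rejected
  writeLines(lines[1:10], fn)
  expect_error(read_shape(fn), "truncated|parse")
  expect_error(read_shape(tempfile()), "not found")
})

test_that("rotary-echo residual is quantified and shrinks with sampling density", {
  sys <- water_system()
  dev <- vapply(c(128L, 256L, 512L), function(n) {
    pk <- make_raff2_packet(625, 1.0, n)
    M0 <- equilibrium_state(sys)
    M1 <- propagate(sys, pk, initial = M0, relaxation = FALSE, exchange = FALSE)
    sqrt(sum((as.numeric(M1[1, 2:7]) - M0)^2))
  }, numeric(1))
  # the residual rotation is a property of the continuous waveform; the
  # discretization contribution must not grow as samples double
  expect_lte(dev[2], dev[1] + 1e-9)
  expect_lte(dev[3], dev[2] + 1e-9)
  expect_lt(abs(dev[2] - dev[3]), abs(dev[1] - dev[2]) + 1e-9)
})
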