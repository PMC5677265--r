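test_that("generated vGRF profiles are seed-deterministic, nonnegative and swing-zero", {
  p <- gait_params(timing_jitter_sd = 0.005, amplitude_jitter_sd = 0.05,
                   noise_sd = 0.02)
  a <- generate_vgrf_profiles(p, 6, seed = 11)
  b <- generate_vgrf_profiles(p, 6, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$grf$grf_left >= 0))
  expect_true(all(a$grf$grf_right >= 0))

  # swing (outside every stance interval) is exactly zero
  for (f in c("left", "right")) {
    iv <- grfproxy:::stance_intervals(a$events, f)
    mask <- grfproxy:::stance_mask(a$events, f, nrow(a$grf))
    g <- a$grf[[paste0("grf_", f)]]
    expect_identical(g[!mask], rep(0, sum(!mask)))
  }
})

test_that("without stochastic terms all stance profiles are sample-identical", {
  p <- gait_params(cycle_duration = 1.0, sampling_rate = 128)
  prof <- generate_vgrf_profiles(p, 3, seed = 5)
  iv <- grfproxy:::stance_intervals(prof$events, "left")
  stances <- lapply(seq_len(nrow(iv)), function(i) {
    prof$grf$grf_left[(iv$ic[i]:(iv$fc[i] - 1L)) + 1L]
  })
  expect_equal(stances[[2]], stances[[1]])
  expect_equal(stances[[3]], stances[[1]])
})

test_that("generator hits the configured critical-point amplitudes", {
  # stance length divisible by 4 puts the peak/trough instants on the grid
  p <- gait_params(cycle_duration = 1.0, stance_fraction = 0.64,
                   double_support_fraction = 0.2, sampling_rate = 100,
                   peak1_amp = 770, peak2_amp = 750, trough_amp = 525,
                   body_weight = 700)
  prof <- generate_vgrf_profiles(p, 2, seed = 3)
  iv <- grfproxy:::stance_intervals(prof$events, "left")
  cyc <- prof$grf$grf_left[(iv$ic[1]:(iv$fc[1] - 1L)) + 1L]
  cp <- extract_critical_points(cyc)
  expect_equal(cp$vp1_value, 770)
  expect_equal(cp$tr_value, 525)
  expect_equal(cp$vp2_value, 750)
})

test_that("invalid gait parameters are rejected", {
  expect_error(gait_params(double_support_fraction = 0.7),
               class = "grfproxy_error_parameter")
  expect_error(gait_params(trough_amp = 900),
               class = "grfproxy_error_parameter")
  expect_error(gait_params(noise_sd = -1),
               class = "grfproxy_error_parameter")
  expect_error(gait_params(stance_fraction = 0.5, double_support_fraction = 0.05),
               class = "grfproxy_error_parameter")
  expect_error(generate_vgrf_profiles(gait_params(), 0),
               class = "grfproxy_error_parameter")
})

test_that("biomech recordings are seed-deterministic with the expected length", {
  p <- gait_params(cycle_duration = 1.0, noise_sd = 0.05)
  a <- generate_biomech_recording(p, 10, seed = 2)
  b <- generate_biomech_recording(p, 10, seed = 2)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(nrow(a), 1280L)  # 10 cycles x 1.0 s x 128 Hz
})

test_that("threshold detection recovers the generator's events within one sample", {
  p <- gait_params(timing_jitter_sd = 0.005, amplitude_jitter_sd = 0.02)
  rec <- generate_biomech_recording(p, 12, seed = 9)
  true <- attr(rec, "true_events")
  det <- detect_gait_events(rec, threshold = 10)
  for (f in c("left", "right")) for (e in c("IC", "FC")) {
    a <- sort(det$k[det$foot == f & det$event == e])
    b <- sort(true$k[true$foot == f & true$event == e])
    expect_length(a, length(b))
    expect_lte(max(abs(a - b)), 1)
  }
})

test_that("oracle generation evaluates single terms exactly", {
  # delayed unit impulse through 2.0 * ax_left(k - 1)
  model <- nma_model(oracle_term(2.0, "ax_left", 1), max_lag = 1)
  sig <- tibble::tibble(ax_left = c(0, 0, 0, 1, 0, 0, 0))
  out <- predict_nma(model, sig)
  expect_equal(out[-1], c(0, 0, 0, 2, 0, 0))

  empty <- oracle_spec(max_lag = 3)
  orc <- generate_oracle_recording(empty, 50, seed = 1)
  expect_identical(orc$grf_left, rep(0, 50))
  expect_identical(orc$grf_right, rep(0, 50))

  expect_error(oracle_spec(oracle_term(1, "ax_left", 0, 2, "az_left", 1, 1)),
               class = "grfproxy_error_parameter")
})

test_that("oracle recordings close under prediction with the generating model", {
  spec <- oracle_spec(oracle_term(1.5, "az_left", 2),
                      oracle_term(-0.3, "ax_left", 0, 1, "ax_left", 1, 1),
                      max_lag = 18)
  orc <- generate_oracle_recording(spec, 400, seed = 21)
  terms <- spec$terms
  model <- nma_model(terms, max_lag = orc$max_lag)
  pred <- predict_nma(model, orc$signals)
  k <- (orc$max_lag + 1):400
  expect_equal(pred[k], orc$grf_left[k], tolerance = 1e-14)
})
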