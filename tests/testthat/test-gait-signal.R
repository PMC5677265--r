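test_that("threshold crossings define IC and FC", {
  d <- tibble::tibble(grf_left = c(0, 5, 12, 300, 280, 8, 0),
                      grf_right = rep(0, 7))
  ev <- detect_gait_events(d, threshold = 10, min_phase = 0)
  expect_equal(ev$k[ev$foot == "left" & ev$event == "IC"], 2L)
  expect_equal(ev$k[ev$foot == "left" & ev$event == "FC"], 5L)
  expect_equal(nrow(dplyr::filter(ev, foot == "right")), 0L)

  # all-zero force: no events, not an error
  z <- tibble::tibble(grf_left = rep(0, 20), grf_right = rep(0, 20))
  expect_identical(nrow(detect_gait_events(z, min_phase = 0)), 0L)
  expect_error(detect_gait_events(d, threshold = -5),
               class = "grfproxy_error_parameter")
})

test_that("separated stance runs yield ordered event pairs and detection is idempotent", {
  g <- c(rep(0, 4), rep(100, 6), rep(0, 5), rep(90, 7), rep(0, 3))
  d <- tibble::tibble(grf_left = g, grf_right = rep(0, length(g)))
  ev <- detect_gait_events(d, min_phase = 0)
  left <- dplyr::filter(ev, foot == "left")
  expect_equal(left$k[left$event == "IC"], c(4L, 15L))
  expect_equal(left$k[left$event == "FC"], c(10L, 22L))

  # recompute events from the thresholded signal implied by the events
  mask <- grfproxy:::stance_mask(ev, "left", length(g))
  d2 <- tibble::tibble(grf_left = as.numeric(mask) * 50, grf_right = rep(0, length(g)))
  ev2 <- detect_gait_events(d2, min_phase = 0)
  expect_identical(dplyr::filter(ev2, foot == "left"), left)
})

test_that("debouncing rejects threshold chatter", {
  g <- c(rep(0, 20), rep(100, 3), rep(0, 20), rep(100, 30), rep(8, 2),
         rep(100, 30), rep(0, 20))
  d <- tibble::tibble(grf_left = g, grf_right = rep(0, length(g)))
  ev <- detect_gait_events(d, min_phase = 0.1, sampling_rate = 100)
  left <- dplyr::filter(ev, foot == "left")
  # the 3-sample blip is dropped; the 2-sample dip inside stance is bridged
  expect_equal(left$k[left$event == "IC"], 43L)
  expect_equal(left$k[left$event == "FC"], 105L)
})

test_that("exact membership is the force share with complementary weights", {
  d <- tibble::tibble(grf_left = c(600, 300, 0, 0, 0),
                      grf_right = c(200, 300, 500, 0, 0))
  m <- exact_membership(d)
  expect_equal(m$w_left[1], 0.75)
  expect_equal(m$w_right[1], 0.25)
  expect_equal(m$w_left[2], 0.5)        # equal loading
  expect_equal(m$w_left[3], 0)          # single-foot limit
  expect_equal(m$w_left[4:5], c(0, 0))  # undefined: carry last defined value
  expect_equal(m$w_left + m$w_right, rep(1, 5))

  lead <- exact_membership(tibble::tibble(grf_left = c(0, 100),
                                          grf_right = c(0, 0)))
  expect_equal(lead$w_left[1], 0.5)     # undefined before any defined sample
  expect_error(exact_membership(tibble::tibble(grf_left = -1, grf_right = 1)),
               class = "grfproxy_error_domain")
})

test_that("event membership ramps linearly across double support", {
  ev <- two_stance_events()
  m <- event_membership(ev, 15)
  expect_equal(m$w_left[1:5], rep(1, 5))                 # left single support
  expect_equal(m$w_left[6:10], c(1, 0.75, 0.5, 0.25, 0)) # ramp from right IC
  expect_equal(m$w_left[11:15], rep(0, 5))               # right single support
  expect_equal(m$w_left + m$w_right, rep(1, 15))
})

test_that("event membership sums to one and matches the exact weights outside double support", {
  p <- gait_params()
  rec <- generate_biomech_recording(p, 8, seed = 13)
  ev <- attr(rec, "true_events")
  em <- event_membership(ev, nrow(rec))
  xm <- exact_membership(rec)
  expect_equal(em$w_left + em$w_right, rep(1, nrow(rec)))
  expect_true(all(em$w_left >= 0 & em$w_left <= 1))

  pm <- phase_masks(ev, nrow(rec))
  defined <- rec$grf_left + rec$grf_right > 0
  outside <- !pm$double_support & defined
  expect_equal(em$w_left[outside], xm$w_left[outside])
  # and they genuinely differ somewhere inside double support
  expect_gt(max(abs(em$w_left - xm$w_left)[pm$double_support]), 0)
})

test_that("membership construction rejects flight phases", {
  ev <- tibble::tibble(foot = c("left", "left", "right", "right"),
                       event = c("IC", "FC", "IC", "FC"),
                       k = c(0L, 5L, 10L, 15L))
  expect_error(event_membership(ev, 15),
               class = "grfproxy_error_unsupported_input")
})

test_that("decomposition conserves the acceleration exactly", {
  d <- tibble::tibble(ax = c(2, -4), ay = c(1, 1), az = c(0, 3))
  m <- tibble::tibble(k = 0:1, w_left = c(0.25, 0.5), w_right = c(0.75, 0.5))
  dec <- decompose_acceleration(d, m)
  expect_equal(dec$ax_left, c(0.5, -2))
  expect_equal(dec$ax_left + dec$ax_right, d$ax)

  # identity membership routes everything to the left
  m1 <- tibble::tibble(k = 0:1, w_left = c(1, 1), w_right = c(0, 0))
  dec1 <- decompose_acceleration(d, m1)
  expect_equal(dec1$ax_left, d$ax)
  expect_equal(dec1$az_right, c(0, 0))

  rec <- generate_biomech_recording(gait_params(noise_sd = 0.1), 5, seed = 4)
  em <- event_membership(attr(rec, "true_events"), nrow(rec))
  dec2 <- decompose_acceleration(rec, em)
  for (axis in c("ax", "ay", "az")) {
    expect_equal(dec2[[paste0(axis, "_left")]] + dec2[[paste0(axis, "_right")]],
                 rec[[axis]])
  }
  expect_error(decompose_acceleration(d, m[1, ]),
               class = "grfproxy_error_structure")
})

test_that("cycles run from initial contact to initial contact", {
  ev <- tibble::tibble(foot = "left", event = rep(c("IC", "FC"), 3),
                       k = c(100L, 180L, 240L, 320L, 386L, 460L))
  cyc <- segment_cycles(ev, "left")
  expect_equal(cyc$start, c(100L, 240L))
  expect_equal(cyc$end, c(240L, 386L))
  expect_equal(nrow(cyc), 2L)  # n ICs -> n - 1 cycles

  one <- dplyr::filter(ev, k < 200)
  expect_equal(nrow(segment_cycles(one, "left")), 0L)

  prof <- generate_vgrf_profiles(gait_params(cycle_duration = 1.0), 6, seed = 2)
  cyc2 <- segment_cycles(prof$events, "left")
  expect_equal(length(unique(cyc2$end - cyc2$start)), 1L)  # jitter-free: equal length
})

test_that("critical points come from extremum scanning with early tie-breaks", {
  cyc <- c(0, 400, 700, 650, 500, 620, 690, 300, 0)
  cp <- extract_critical_points(cyc)
  expect_equal(cp$vp1_value, 700); expect_equal(cp$vp1_index, 2L)
  expect_equal(cp$tr_value, 500); expect_equal(cp$tr_index, 4L)
  expect_equal(cp$vp2_value, 690); expect_equal(cp$vp2_index, 6L)

  sym <- c(0, 300, 600, 400, 600, 300, 0)
  cps <- extract_critical_points(sym)
  expect_equal(cps$vp1_value, cps$vp2_value)

  err <- expect_error(extract_critical_points(c(0, 10, 50, 10, 0)),
                      class = "grfproxy_error_degenerate_shape")
  expect_equal(err$extremum$value, 50)
})

test_that("phase masks partition stance time", {
  ev <- walking_events(n_steps = 4, stance = 40, overlap = 12)
  n <- max(ev$k) + 5L
  pm <- phase_masks(ev, n)
  expect_identical(pm$double_support, pm$left_stance & pm$right_stance)
  expect_equal(sum(pm$left_single) + sum(pm$right_single) + sum(pm$double_support),
               sum(pm$left_stance | pm$right_stance))
  # overlap of 12 samples at each step transition
  runs <- rle(pm$double_support)
  expect_true(all(runs$lengths[runs$values] == 12L))
})
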