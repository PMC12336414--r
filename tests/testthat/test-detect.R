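test_that("digital silence yields zero events and zero seconds", {
  det <- detect_calls(audio_clip(numeric(16000 * 5)))
  expect_equal(nrow(det$events), 0)
  expect_true(all(det$seconds == 0))
})

test_that("a single mid-band burst is classified as a chick beg", {
  # one syllable, 0.3 s, centred at 3 kHz: inside the beg envelope
  sp <- call_type_spec("probe", freq_lo = 2.8, freq_hi = 3.2,
                       dur_lo = 0.29, dur_hi = 0.31, n_syllables = 1)
  ev <- data.frame(call_type = "chick_beg", start_s = 2, duration_s = 0.3,
                   position_m = 2)
  clip <- render_plot_night(ev, duration_s = 5, specs = call_type_specs(
    chick_beg = sp), seed = 21)
  det <- detect_calls(clip)
  expect_equal(nrow(det$events), 1)
  expect_equal(det$events$call_type, "chick_beg")
})

test_that("close-range purrs are recovered with no chick confusion", {
  set.seed(31)
  ev <- data.frame(call_type = "adult_purr",
                   start_s = seq(1, by = 4, length.out = 20),
                   duration_s = runif(20, 1, 2), position_m = 3)
  clip <- render_plot_night(ev, duration_s = 85, seed = 31)
  det <- detect_calls(clip)
  expect_gte(sum(det$events$call_type == "adult_purr"), 18)
  expect_equal(sum(det$events$call_type == "chick_beg"), 0)
  # seconds contract: detected purr seconds within 15% of ground truth
  truth <- sum(ev$duration_s)
  expect_lt(abs(det$seconds[["adult_purr"]] - truth) / truth, 0.15)
  # and never more than the clip duration
  expect_true(all(det$seconds <= clip_duration(clip)))
})

test_that("rendering attenuates calls monotonically with distance", {
  ev_near <- data.frame(call_type = "adult_purr", start_s = 1,
                        duration_s = 1.5, position_m = 2)
  ev_far <- ev_near
  ev_far$position_m <- 40
  near <- render_plot_night(ev_near, noise_db = -60, duration_s = 4,
                            seed = 5)
  far <- render_plot_night(ev_far, noise_db = -60, duration_s = 4, seed = 5)
  rms <- function(clip) sqrt(mean(clip$samples^2))
  expect_gt(rms(near), rms(far))
  am <- attenuation_model()
  d <- seq(0, 50, 5)
  expect_true(all(diff(arrival_amplitude(am, "adult_purr", d)) < 0))
})

test_that("detection results are stable under chunked processing", {
  set.seed(41)
  starts <- c(5, 30, 55, 70, 100)  # clear of the 60 s chunk boundary
  ev <- data.frame(call_type = "adult_chat", start_s = starts,
                   duration_s = runif(5, 0.8, 1.5), position_m = 4)
  clip <- render_plot_night(ev, duration_s = 110, seed = 41)
  whole <- detect_calls(clip, control = detector_control(chunk_s = 120))
  chunked <- detect_calls(clip, control = detector_control(chunk_s = 60))
  expect_equal(nrow(whole$events), nrow(chunked$events))
  expect_lt(abs(whole$seconds[["adult_chat"]] -
                  chunked$seconds[["adult_chat"]]),
            0.05 * whole$seconds[["adult_chat"]] + 0.05)
})

test_that("non-16 kHz audio fails loudly unless resampling is enabled", {
  clip <- audio_clip(rnorm(8000), sample_rate = 8000)
  expect_error(detect_calls(clip), "16 kHz")
  det <- detect_calls(clip, control = detector_control(resample = TRUE))
  expect_s3_class(det, "call_detections")
})

test_that("detection-range flags honour the closed boundary convention", {
  ranges <- detection_ranges()
  ev <- data.frame(
    call_type = c("chick_beg", "chick_beg", "adult_purr", "adult_purr"),
    position_m = c(17, -16, 26, -26.5),
    start_s = 0, duration_s = 0.3
  )
  out <- apply_detection_range(ev, ranges)
  expect_equal(out$detected, c(FALSE, TRUE, TRUE, FALSE))
  expect_error(detection_ranges(chick_beg = -2), "positive")
  expect_error(apply_detection_range(
    data.frame(call_type = "other", position_m = 0), ranges), "range")
})

test_that("detection range estimation follows the declared convention", {
  grid <- seq(-40, 40, by = 2)
  # symmetric detections out to 16 m
  est <- estimate_detection_range(grid, abs(grid) <= 16)
  expect_equal(est$range_m, 16)
  expect_false(est$censored)
  # asymmetric sides average: (26 + 30) / 2 = 28
  det <- (grid < 0 & abs(grid) <= 26) | (grid >= 0 & grid <= 30)
  est2 <- estimate_detection_range(grid, det)
  expect_equal(est2$range_m, 28)
  expect_equal(est2$left_m, 26)
  expect_equal(est2$right_m, 30)
  # censored: everything audible to the test limit
  est3 <- estimate_detection_range(grid, rep(TRUE, length(grid)))
  expect_equal(est3$range_m, 40)
  expect_true(est3$censored)
  # no detections at all
  expect_warning(est4 <- estimate_detection_range(grid, rep(FALSE, length(grid))),
                 "no detections")
  expect_equal(est4$range_m, 0)
})
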