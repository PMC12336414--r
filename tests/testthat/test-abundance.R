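test_that("response rate averages per-visit response proportions", {
  expect_equal(response_rate(matrix(1, 5, 7)), 1)
  # 2 nests x 2 visits: (2/2 + 1/2) / 2 = 0.75
  expect_equal(response_rate(matrix(c(1, 1, 0, 1), 2, 2)), 0.75)
  # binomial oracle at p = 0.3: the observed rate conditions on nests
  # responding at least once, so its expectation is p / (1 - (1-p)^7);
  # the corrected rate recovers p itself
  m <- simulate_playback_survey(flat_nests(5000, 0.3), 7, seed = 6L)
  h <- detection_history(m)
  se <- sqrt(0.3 * 0.7 / (nrow(h$matrix) * 7))
  expect_lt(abs(response_rate(h) - 0.3 / (1 - 0.7^7)), 3 * se)
  expect_lt(abs(response_rate(h, corrected = TRUE) - 0.3), 3 * se)
  expect_warning(r <- response_rate(matrix(numeric(0), 0, 7)), "missing")
  expect_true(is.na(r))
})

test_that("percent undetected follows the closed-form correction", {
  expect_equal(percent_undetected(1, 7), 0)
  expect_equal(percent_undetected(0.5, 7), 0.78125)
  expect_equal(percent_undetected(0, 7), 100)
  # strictly decreasing in both the response rate and the trial count
  r <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(percent_undetected(r, 7)) < 0))
  expect_true(all(diff(percent_undetected(0.3, 1:10)) < 0))
  expect_error(percent_undetected(1.2), "0, 1")
  expect_error(percent_undetected(0.5, 0), ">= 1")
})

test_that("AON estimates correct observed counts for non-responders", {
  # 27 observed at response rate 0.28 over 7 visits corrects to ~30.0
  expect_equal(27 / (1 - percent_undetected(0.28, 7) / 100), 30.0,
               tolerance = 0.01)

  m <- simulate_playback_survey(flat_nests(40, 0.3), 7, seed = 21L)
  h <- detection_history(m)
  est <- estimate_aon(h, seed = 31L)
  expect_equal(est$response_rate, response_rate(h, corrected = TRUE))
  # jackknife adjusts the plug-in correction only slightly at this size
  plug <- est$observed_aons / (1 - (1 - est$response_rate)^7)
  expect_lt(abs(est$corrected_aons - plug) / plug, 0.1)
  expect_gte(est$corrected_aons, est$observed_aons)
  expect_true(est$ci_low <= est$ci_high)
  expect_equal(est$n_boot, 999)

  # bit-reproducible bootstrap under a fixed seed
  est2 <- estimate_aon(h, seed = 31L)
  expect_identical(est[c("ci_low", "ci_high")], est2[c("ci_low", "ci_high")])

  # certainty: everyone responds every time
  all1 <- estimate_aon(detection_history(matrix(1, 12, 7)), seed = 1L)
  expect_equal(all1$corrected_aons, 12)
  expect_equal(all1$ci_low, 12)
  expect_equal(all1$ci_high, 12)
  expect_equal(all1$pct_undetected, 0)

  # visit-level resampling is available for sensitivity analysis
  estv <- estimate_aon(h, n_boot = 99, seed = 5L, resample = "visits")
  expect_true(estv$ci_low <= estv$ci_high)
})

test_that("detection histories keep only discovered nests and 0/1 entries", {
  m <- rbind(c(1, 0, 1), c(0, 0, 0), c(0, 1, 0))
  h <- detection_history(m)
  expect_equal(nrow(h$matrix), 2)
  expect_error(detection_history(matrix(c(1, 2), 1, 2)), "0/1")
  # long-format round trip preserves the matrix exactly
  m2 <- simulate_playback_survey(flat_nests(15, 0.6), 4, seed = 2L)
  long <- history_to_long(m2, "P01")
  h2 <- history_from_long(long)[["P01"]]
  expect_equal(unname(h2$matrix),
               unname(m2[rowSums(m2) >= 1, , drop = FALSE]))
})

test_that("range restriction keeps the receiver-audible span", {
  nests <- data.frame(nest_id = letters[1:5], plot_id = "P01",
                      position_m = c(-30, -25, 0, 25, 27))
  kept <- restrict_to_detection_range(nests, detection_ranges(),
                                      "adult_purr")
  expect_equal(kept$nest_id, c("b", "c", "d"))  # 26 m purr range
  # all nests out of range leaves nothing
  far <- data.frame(position_m = c(40, -45), nest_id = c("x", "y"))
  expect_equal(nrow(restrict_to_detection_range(far)), 0)
  # nearer-plot assignment caps positions at half the plot spacing
  wide <- data.frame(nest_id = "z", position_m = 29)
  expect_equal(nrow(restrict_to_detection_range(
    wide, detection_ranges(adult_purr = 35), plot_spacing_m = 56)), 0)

  # with the default geometry only a small fraction of nests is audible
  # from two plots
  col <- generate_colony(colony_config(seed = 17L))
  f <- overlap_fraction(col$nests, 30, 56)
  expect_gt(f, 0.005)
  expect_lt(f, 0.12)
  # chick detection ranges never overlap between plots
  expect_equal(overlap_fraction(col$nests, 16, 56), 0)
})
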