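test_that("colony generation respects the configuration and is reproducible", {
  cfg <- colony_config(seed = 5L)
  col <- generate_colony(cfg)
  counts <- table(col$nests$plot_id)
  expect_equal(nrow(col$plots), 10)
  expect_true(all(counts >= 10 & counts <= 30))
  expect_true(all(abs(col$nests$position_m) <= cfg$wall_halflength_m))
  expect_true(all(col$nests$response_prob[!col$nests$occupied] == 0))
  rp <- col$nests$response_prob[col$nests$occupied]
  expect_true(all(rp >= cfg$response_prob_range[1] &
                    rp <= cfg$response_prob_range[2]))

  # determinism: identical config + seed => identical nest tables
  col2 <- generate_colony(cfg)
  expect_identical(col$nests, col2$nests)
  expect_identical(col$plots, col2$plots)

  # empty colony is valid
  empty <- generate_colony(colony_config(nests_per_plot_range = c(0, 0)))
  expect_equal(nrow(empty$nests), 0)

  expect_error(colony_config(nests_per_plot_range = c(5, 2)), "min")
  expect_error(colony_config(response_prob_range = c(0.2, 1.4)), "0, 1")
})

test_that("plot-level response heterogeneity gives one probability per plot", {
  col <- generate_colony(colony_config(response_heterogeneity = "plot",
                                       prop_empty = 0, seed = 8L))
  per_plot <- tapply(col$nests$response_prob, col$nests$plot_id,
                     function(x) length(unique(x)))
  expect_true(all(per_plot == 1))
})

test_that("breeding outcomes hit the success target with early failures", {
  cfg <- colony_config(n_plots = 40, nests_per_plot_range = c(25, 25),
                       prop_empty = 0, seed = 3L)
  col <- generate_colony(cfg)
  col <- simulate_breeding_outcomes(col, 0.75, seed = 4L)
  out <- col$nests$outcome
  n <- nrow(col$nests)
  expect_gte(n, 1000)

  # conservation: every nest is a success, failure or empty
  expect_equal(sum(out == "success") +
                 sum(out %in% c("fail_incubation", "fail_chick")) +
                 sum(out == "empty"), n)

  # binomial oracle: sqrt(0.75 * 0.25 / 1000) ~ 0.014; allow 0.03
  expect_lt(abs(mean(out == "success") - 0.75), 0.03)

  # failure timing: >= 90% of failures by day 24 (or at incubation)
  fails <- out %in% c("fail_incubation", "fail_chick")
  early <- out == "fail_incubation" |
    (out == "fail_chick" & col$nests$failure_day <= 24)
  expect_gte(sum(early & fails) / sum(fails), 0.90)

  # hatch date present iff the egg hatched
  expect_true(all(is.na(col$nests$hatch_date[
    out %in% c("fail_incubation", "empty")])))
  expect_true(all(!is.na(col$nests$hatch_date[out == "success"])))

  # boundary: certain success
  all_succ <- simulate_breeding_outcomes(generate_colony(cfg), 1.0, seed = 5L)
  occ <- all_succ$nests$occupied
  expect_true(all(all_succ$nests$outcome[occ] == "success"))

  expect_error(simulate_breeding_outcomes(col, 1.2), "0, 1")
})

test_that("playback responses match their per-visit probabilities", {
  # closed form: 100 * (1 - 0.28)^7 = 10.03% never detected
  m <- simulate_playback_survey(flat_nests(10000, 0.28), 7, seed = 11L)
  expect_lt(abs(100 * mean(rowSums(m) == 0) - 10.03), 0.8)

  # calibration: per-visit response frequency within 3 binomial SEs
  p_hat <- mean(m)
  se <- sqrt(0.28 * 0.72 / length(m))
  expect_lt(abs(p_hat - 0.28), 3 * se)

  # certainty and boundary cases
  m1 <- simulate_playback_survey(flat_nests(20, 1), 7, seed = 1L)
  expect_true(all(m1 == 1))
  m0 <- simulate_playback_survey(flat_nests(20, 0.5, occupied = FALSE),
                                 7, seed = 1L)
  expect_true(all(m0 == 0))
  expect_error(simulate_playback_survey(flat_nests(5, 0.5), 0), ">= 1")
})

test_that("observer checks age chicks to within about a day", {
  col <- hatched_colony(n = 40, hatch = as.Date("2023-07-27"))
  chk <- simulate_observer_check(col, as.Date("2023-08-20"), seed = 9L)
  expect_true(all(chk$chick_present))
  expect_true(all(chk$true_age_days == 24))
  expect_true(all(abs(chk$estimated_age_days - 24) <= 1))
  expect_true(all(chk$tarsus_mm == round(chk$tarsus_mm, 1)))

  # failed-at-incubation nests are recorded absent
  col$nests$outcome[1] <- "fail_incubation"
  col$nests$hatch_date[1] <- NA
  chk2 <- simulate_observer_check(col, as.Date("2023-08-20"), seed = 9L)
  expect_false(chk2$chick_present[1])
  expect_true(is.na(chk2$tarsus_mm[1]))

  # growth-curve round trip: age -> tarsus -> age identity within rounding
  g <- tarsus_growth_params(noise_sd = 0)
  ages <- 5:30
  back <- age_from_tarsus(round(tarsus_at_age(ages, g), 1), g)
  expect_true(all(abs(back - ages) <= 1))
  expect_true(all(diff(tarsus_at_age(0:40, g)) > 0))
})

test_that("chick begging follows the rise-dip-plateau ontogeny", {
  expect_gt(chick_call_curve(14), chick_call_curve(2))
  expect_gt(chick_call_curve(25), 0.5 * chick_call_curve(14))
  expect_lt(chick_call_curve(25), chick_call_curve(14))
  expect_equal(chick_call_curve(-3), 0)
  # chicks can beg from day 0
  expect_gt(chick_call_curve(0), 0)
  # late rise disabled by default, available on request
  expect_equal(chick_call_curve(35), chick_call_curve(20))
  expect_gt(chick_call_curve(35, late_rise = TRUE), chick_call_curve(20))

  # simulated nightly seconds reproduce the shape through the season
  col <- hatched_colony(n = 60, hatch = as.Date("2023-07-10"))
  profiles <- make_chick_profiles(col, seed = 2L)
  night_secs <- function(date, seed) {
    ev <- simulate_nightly_calling(col, list(date = date), profiles,
                                   seed = seed)
    sum(ev$duration_s[ev$call_type == "chick_beg"])
  }
  at2 <- mean(vapply(1:6, function(i) {
    night_secs(as.Date("2023-07-12"), i)
  }, numeric(1)))
  at14 <- mean(vapply(1:6, function(i) {
    night_secs(as.Date("2023-07-24"), 100 + i)
  }, numeric(1)))
  at25 <- mean(vapply(1:6, function(i) {
    night_secs(as.Date("2023-08-04"), 200 + i)
  }, numeric(1)))
  expect_gt(at14, at2)
  expect_gt(at25, 0.5 * at14)
})

test_that("nightly calling respects the window, durations and occupancy", {
  col <- hatched_colony(n = 25)
  profiles <- make_chick_profiles(col, seed = 3L)
  ev <- simulate_nightly_calling(col, list(date = as.Date("2023-08-05")),
                                 profiles, seed = 13L)
  expect_true(all(ev$start_s >= 0 & ev$start_s + ev$duration_s <= 14400))
  specs <- call_type_specs()
  for (ty in names(specs)) {
    d <- ev$duration_s[ev$call_type == ty]
    expect_true(all(d >= specs[[ty]]$dur_lo & d <= specs[[ty]]$dur_hi))
  }
  # purr durations stay in the 1-2 s range over a large sample
  purr_d <- unlist(lapply(1:8, function(i) {
    e <- simulate_nightly_calling(col, list(date = as.Date("2023-08-05")),
                                  NULL, seed = 300 + i)
    e$duration_s[e$call_type == "adult_purr"]
  }))
  expect_gt(length(purr_d), 500)
  expect_true(all(purr_d >= 1 & purr_d <= 2))

  # an unoccupied colony is silent
  col$nests$occupied <- FALSE
  expect_equal(nrow(simulate_nightly_calling(
    col, list(date = as.Date("2023-08-05")), profiles, seed = 1L)), 0)

  expect_error(simulate_nightly_calling(
    col, list(date = as.Date("2024-01-01")), NULL), "season")
})
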