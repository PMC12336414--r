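make_records <- function(n = 40, n_moon = 10, n_windy = 5) {
  data.frame(
    plot_id = "P01",
    date = as.Date("2023-06-07") + seq_len(n) - 1,
    moon_fraction = c(rep(0.9, n_moon), rep(0.2, n - n_moon)),
    usable = c(rep(TRUE, n_moon), rep(FALSE, n_windy),
               rep(TRUE, n - n_moon - n_windy)),
    adult_purr_s = 100
  )
}

test_that("night filtering removes bright-moon and unusable nights", {
  recs <- make_records()
  kept <- filter_nights(recs)
  expect_equal(nrow(kept), 25)  # 40 - 10 full moon - 5 windy

  # strict boundary: > 0.75 removed, exactly 0.75 retained
  edge <- data.frame(moon_fraction = c(0.76, 0.75), usable = TRUE)
  expect_equal(filter_nights(edge)$moon_fraction, 0.75)

  # idempotence and identity on clean data
  expect_identical(filter_nights(kept), kept)
  clean <- data.frame(moon_fraction = 0.1, usable = TRUE)
  expect_identical(filter_nights(clean), clean)
})

test_that("the period split partitions the season at the cutoff", {
  recs <- data.frame(date = seq(as.Date("2023-06-07"),
                                as.Date("2023-08-29"), by = "day"))
  p <- split_periods(recs)
  expect_equal(nrow(p$adult) + nrow(p$chick), nrow(recs))
  expect_true(all(p$adult$date < as.Date("2023-07-14")))
  expect_true(all(p$chick$date >= as.Date("2023-07-14")))
  expect_equal(length(intersect(p$adult$date, p$chick$date)), 0)

  june <- data.frame(date = seq(as.Date("2023-06-01"),
                                as.Date("2023-06-30"), by = "day"))
  expect_equal(nrow(split_periods(june)$chick), 0)
})

test_that("mean call rate is the arithmetic mean, missing when empty", {
  expect_equal(mean_call_rate(c(10, 20, 30)), 20)
  expect_equal(mean_call_rate(rep(7.5, 12)), 7.5)
  expect_warning(empty <- mean_call_rate(numeric(0)), "missing")
  expect_true(is.na(empty))
  # independent summation oracle on a random series
  set.seed(2)
  x <- rlnorm(31, 3, 0.5)
  expect_equal(mean_call_rate(x), sum(x) / length(x))
})

test_that("accumulation plateaus behave like the running-mean criterion", {
  # constant series: zero slope everywhere, plateau at the minimum
  # evaluable size (the trailing window)
  pl <- accumulation_plateau(rep(5, 20), seed = 1)
  expect_equal(pl$nights_to_plateau, 5)
  expect_equal(pl$reached, 1)

  # linear trend with increment 10: the running mean climbs ~5 per added
  # night, never below the 0.1 threshold
  pl2 <- accumulation_plateau(seq(10, 300, by = 10), shuffle = FALSE)
  expect_true(is.na(pl2$nights_to_plateau))
  expect_equal(pl2$reached, 0)
  expect_gt(abs(pl2$final_slope), 0.1)

  # the running-mean curve at full n equals the plain mean, exactly,
  # for every ordering
  set.seed(3)
  x <- rlnorm(25, 4, 0.4)
  pl3 <- accumulation_plateau(x, n_orderings = 20, seed = 4,
                              keep_curves = TRUE)
  expect_equal(unname(pl3$curves[, 25]), rep(mean(x), 20))
  expect_true(all(pl3$per_ordering[!is.na(pl3$per_ordering)] <= 25))

  expect_error(accumulation_plateau(c(1, 2, 3)), "window")
})

test_that("noisier series need more nights to stabilise", {
  plateau_n <- function(sdlog) {
    mean(vapply(1:20, function(i) {
      set.seed(1000 + i)
      x <- rlnorm(40, log(100), sdlog)
      accumulation_plateau(x, n_orderings = 40,
                           seed = i)$nights_to_plateau
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(plateau_n(0.05), plateau_n(0.8))
})

test_that("nightly records aggregate detected events per plot-night", {
  nights <- data.frame(date = as.Date("2023-07-01") + 0:1,
                       moon_fraction = 0.2, usable = TRUE)
  ev <- data.frame(
    plot_id = c("P01", "P01", "P02", "P01"),
    date = as.Date(c("2023-07-01", "2023-07-01", "2023-07-01",
                     "2023-07-02")),
    call_type = c("adult_purr", "adult_purr", "chick_beg", "adult_chat"),
    duration_s = c(1.5, 2, 0.4, 1),
    detected = c(TRUE, TRUE, TRUE, FALSE)
  )
  recs <- nightly_call_records(ev, nights, plots = c("P01", "P02"))
  expect_equal(nrow(recs), 4)  # 2 plots x 2 nights
  r11 <- recs[recs$plot_id == "P01" & recs$date == as.Date("2023-07-01"), ]
  expect_equal(r11$adult_purr_s, 3.5)
  # undetected events never count
  r12 <- recs[recs$plot_id == "P01" & recs$date == as.Date("2023-07-02"), ]
  expect_equal(r12$adult_chat_s, 0)
  r21 <- recs[recs$plot_id == "P02" & recs$date == as.Date("2023-07-01"), ]
  expect_equal(r21$chick_beg_s, 0.4)
})
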