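#' Colony configuration
#'
#' Builds the configuration object that drives every synthetic stage:
#' colony geometry, playback response behaviour, breeding phenology and
#' the nightly calling model. Defaults describe a mid-sized stone-wall
#' colony of European storm petrels monitored over a June--August season:
#' ten plots of 10--30 nests strung along walls, receivers hearing about
#' half of each plot's 100 m wall section, per-visit playback response
#' probabilities averaging ~0.28, and overall breeding success near 0.75.
#'
#' @param n_plots number of study plots.
#' @param nests_per_plot_range integer `c(min, max)`; nest count per plot is
#'   drawn uniformly from this range.
#' @param wall_halflength_m half-length of the wall section belonging to a
#'   plot; nests sit at signed positions in `[-wall_halflength_m,
#'   wall_halflength_m]` metres from the plot centre.
#' @param plot_spacing_m distance between adjacent plot centres along the
#'   wall line; controls how often a nest is audible from two receivers.
#' @param prop_empty probability that a generated nest site is unoccupied.
#' @param response_prob_range per-visit playback response probability range;
#'   each nest draws its own probability uniformly from it (set
#'   `response_heterogeneity = "plot"` for a single plot-level draw).
#' @param response_heterogeneity `"nest"` (default) or `"plot"`.
#' @param season_start,season_end recording season (`Date`).
#' @param cutoff_date date splitting adult-call nights (before) from
#'   chick-call nights (on/after).
#' @param hatch_date_mean,hatch_date_sd hatch-date distribution (mean
#'   `Date`, SD in days) for successful breeding attempts.
#' @param overall_success_target probability that a breeding attempt
#'   fledges a chick.
#' @param incubation_failure_share fraction of failures occurring at the
#'   egg stage (never hatch).
#' @param chick_failure_p24 fraction of chick-stage failures occurring by
#'   day 24 post-hatch; failure days are exponential with the matching rate.
#' @param prop_male_present probability an occupied nest holds a purring
#'   territorial male.
#' @param purr_s_per_nest,chat_s_per_nest mean nightly seconds of purr and
#'   chat calling per contributing nest.
#' @param chick_peak_s mean peak nightly seconds of begging per chick
#'   (reached around two weeks post-hatch).
#' @param satiation_sdlog SD (log scale) of the per-chick-night lognormal
#'   satiation multiplier (mean 1).
#' @param plot_factor_sdlog SD (log scale) of a stable per-plot lognormal
#'   calling multiplier (habitat/receiver differences).
#' @param abundance_effect exponent coupling adult calling to plot size:
#'   total adult seconds scale as (occupied nests)^`abundance_effect`.
#'   1 is proportional calling; 0 decouples call rate from abundance
#'   (a null colony for calibration experiments).
#' @param usable_prob probability a night's recording is usable (not
#'   wrecked by wind or other disruptive noise).
#' @param full_moon_date a date of full moon used to phase the 29.53-day
#'   lunar cycle that supplies nightly moon illumination fractions.
#' @param tarsus_growth parameters of the chick tarsus growth curve, from
#'   [tarsus_growth_params()].
#' @param seed integer master seed recorded with the configuration.
#'
#' @return an object of class `colony_config` (a named list).
#' @seealso [generate_colony()], [run_experiment()]
#' @export
colony_config <- function(n_plots = 10,
                          nests_per_plot_range = c(10, 30),
                          wall_halflength_m = 50,
                          plot_spacing_m = 56,
                          prop_empty = 0.1,
                          response_prob_range = c(0.15, 0.42),
                          response_heterogeneity = c("nest", "plot"),
                          season_start = as.Date("2023-06-07"),
                          season_end = as.Date("2023-08-29"),
                          cutoff_date = as.Date("2023-07-14"),
                          hatch_date_mean = as.Date("2023-07-27"),
                          hatch_date_sd = 3,
                          overall_success_target = 0.75,
                          incubation_failure_share = 0.5,
                          chick_failure_p24 = 0.941,
                          prop_male_present = 0.9,
                          purr_s_per_nest = 20,
                          chat_s_per_nest = 4,
                          chick_peak_s = 40,
                          satiation_sdlog = 0.3,
                          plot_factor_sdlog = 0.1,
                          abundance_effect = 1,
                          usable_prob = 0.9,
                          full_moon_date = as.Date("2023-07-03"),
                          tarsus_growth = tarsus_growth_params(),
                          seed = 1L) {
  response_heterogeneity <- match.arg(response_heterogeneity)
  cfg <- list(
    n_plots = as.integer(n_plots),
    nests_per_plot_range = as.integer(nests_per_plot_range),
    wall_halflength_m = wall_halflength_m,
    plot_spacing_m = plot_spacing_m,
    prop_empty = prop_empty,
    response_prob_range = response_prob_range,
    response_heterogeneity = response_heterogeneity,
    season_start = as.Date(season_start),
    season_end = as.Date(season_end),
    cutoff_date = as.Date(cutoff_date),
    hatch_date_mean = as.Date(hatch_date_mean),
    hatch_date_sd = hatch_date_sd,
    overall_success_target = overall_success_target,
    incubation_failure_share = incubation_failure_share,
    chick_failure_p24 = chick_failure_p24,
    prop_male_present = prop_male_present,
    purr_s_per_nest = purr_s_per_nest,
    chat_s_per_nest = chat_s_per_nest,
    chick_peak_s = chick_peak_s,
    satiation_sdlog = satiation_sdlog,
    plot_factor_sdlog = plot_factor_sdlog,
    abundance_effect = abundance_effect,
    usable_prob = usable_prob,
    full_moon_date = as.Date(full_moon_date),
    tarsus_growth = tarsus_growth,
    seed = as.integer(seed)
  )
  validate_colony_config(cfg)
  class(cfg) <- "colony_config"
  cfg
}

validate_colony_config <- function(cfg) {
  stopifnot(cfg$n_plots >= 1, cfg$wall_halflength_m > 0)
  if (length(cfg$nests_per_plot_range) != 2 ||
      cfg$nests_per_plot_range[1] > cfg$nests_per_plot_range[2] ||
      any(cfg$nests_per_plot_range < 0)) {
    stop("`nests_per_plot_range` must be c(min, max) with 0 <= min <= max",
         call. = FALSE)
  }
  rp <- cfg$response_prob_range
  if (length(rp) != 2 || rp[1] > rp[2] || any(rp < 0) || any(rp > 1)) {
    stop("`response_prob_range` must be c(min, max) within [0, 1]",
         call. = FALSE)
  }
  for (p in c("prop_empty", "overall_success_target",
              "incubation_failure_share", "chick_failure_p24",
              "prop_male_present", "usable_prob")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", p), call. = FALSE)
    }
  }
  if (cfg$season_start >= cfg$season_end) {
    stop("`season_start` must precede `season_end`", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.colony_config <- function(x, ...) {
  cat("Colony configuration\n")
  cat(sprintf("  plots: %d, nests/plot: %d-%d, wall half-length: %g m\n",
              x$n_plots, x$nests_per_plot_range[1], x$nests_per_plot_range[2],
              x$wall_halflength_m))
  cat(sprintf("  response prob: %.2f-%.2f (%s-level)\n",
              x$response_prob_range[1], x$response_prob_range[2],
              x$response_heterogeneity))
  cat(sprintf("  season: %s to %s (split %s)\n",
              x$season_start, x$season_end, x$cutoff_date))
  cat(sprintf("  breeding success target: %.2f, seed: %d\n",
              x$overall_success_target, x$seed))
  invisible(x)
}

#' Generate a synthetic colony
#'
#' Lays out plots along a wall line and populates each with nest sites at
#' uniform positions within the plot's wall section. Each site is occupied
#' with probability `1 - prop_empty`; occupied nests draw a per-visit
#' playback response probability and a territorial-male flag. Each plot
#' also draws a stable lognormal calling multiplier.
#'
#' @param config a [colony_config()].
#' @param seed integer seed; defaults to `config$seed`. The same config and
#'   seed always reproduce the same colony.
#' @return an object of class `petrel_colony`: a list with elements
#'   `config`, `plots` (data frame: `plot_id`, `centre_m`,
#'   `calling_factor`) and `nests` (data frame: `nest_id`, `plot_id`,
#'   `position_m`, `occupied`, `response_prob`, `male_present`).
#' @export
generate_colony <- function(config = colony_config(), seed = config$seed) {
  validate_colony_config(config)
  with_seed(seed, {
    nest_choices <- seq(config$nests_per_plot_range[1],
                        config$nests_per_plot_range[2])
    n_nests <- nest_choices[sample.int(length(nest_choices),
                                       config$n_plots, replace = TRUE)]
    plots <- data.frame(
      plot_id = sprintf("P%02d", seq_len(config$n_plots)),
      centre_m = (seq_len(config$n_plots) - 1) * config$plot_spacing_m,
      calling_factor = rlnorm(config$n_plots,
                              meanlog = -config$plot_factor_sdlog^2 / 2,
                              sdlog = config$plot_factor_sdlog),
      stringsAsFactors = FALSE
    )
    nests <- do.call(rbind, lapply(seq_len(config$n_plots), function(i) {
      k <- n_nests[i]
      if (k == 0) return(NULL)
      rp_range <- config$response_prob_range
      rp <- if (config$response_heterogeneity == "plot") {
        rep(runif(1, rp_range[1], rp_range[2]), k)
      } else {
        runif(k, rp_range[1], rp_range[2])
      }
      data.frame(
        nest_id = sprintf("%s-N%03d", plots$plot_id[i], seq_len(k)),
        plot_id = plots$plot_id[i],
        position_m = runif(k, -config$wall_halflength_m,
                           config$wall_halflength_m),
        occupied = runif(k) >= config$prop_empty,
        response_prob = rp,
        male_present = runif(k) < config$prop_male_present,
        stringsAsFactors = FALSE
      )
    }))
    if (is.null(nests)) {
      nests <- data.frame(nest_id = character(), plot_id = character(),
                          position_m = numeric(), occupied = logical(),
                          response_prob = numeric(), male_present = logical(),
                          stringsAsFactors = FALSE)
    }
    nests$response_prob[!nests$occupied] <- 0
    nests$male_present[!nests$occupied] <- FALSE
    structure(list(config = config, plots = plots, nests = nests),
              class = "petrel_colony")
  })
}

#' @export
print.petrel_colony <- function(x, ...) {
  cat(sprintf("Synthetic storm petrel colony: %d plots, %d nest sites (%d occupied)\n",
              nrow(x$plots), nrow(x$nests), sum(x$nests$occupied)))
  invisible(x)
}

#' Simulate breeding outcomes
#'
#' Assigns each occupied nest an outcome (`success`, `fail_incubation`,
#' `fail_chick`), a hatch date where the egg hatches, and a failure day
#' (days post-hatch) for chick-stage failures. Unoccupied sites get
#' outcome `empty`. Breeding attempts succeed independently with
#' probability `overall_success_target`; failures split between the
#' incubation stage and an early-chick stage whose failure days are
#' exponential, calibrated so that `chick_failure_p24` of chick-stage
#' failures fall on or before day 24 post-hatch.
#'
#' @param colony a `petrel_colony`, or a nest data frame with an
#'   `occupied` column.
#' @param overall_success_target probability of fledging per breeding
#'   attempt; defaults to the colony configuration value.
#' @param seed integer seed (`NULL` = use current RNG stream).
#' @param config used for phenology parameters when `colony` is a bare
#'   nest data frame.
#' @return the input with added columns `outcome`, `hatch_date`,
#'   `failure_day`.
#' @export
simulate_breeding_outcomes <- function(colony,
                                       overall_success_target = NULL,
                                       seed = NULL,
                                       config = colony_config()) {
  is_col <- inherits(colony, "petrel_colony")
  cfg <- if (is_col) colony$config else config
  target <- overall_success_target %||% cfg$overall_success_target
  if (!is.numeric(target) || target < 0 || target > 1) {
    stop("`overall_success_target` must be in [0, 1]", call. = FALSE)
  }
  nests <- if (is_col) colony$nests else colony
  n <- nrow(nests)
  nests$outcome <- rep("empty", n)
  nests$hatch_date <- as.Date(rep(NA, n))
  nests$failure_day <- rep(NA_real_, n)
  occ <- which(nests$occupied)
  if (length(occ)) {
    res <- with_seed(seed, {
      success <- runif(length(occ)) < target
      # among failures, a share never hatches; the rest fail as chicks with
      # exponential failure days scaled so chick_failure_p24 fall by day 24
      fail_inc <- !success & runif(length(occ)) < cfg$incubation_failure_share
      rate <- -log(1 - cfg$chick_failure_p24) / 24
      fday <- rexp(length(occ), rate)
      fday <- pmin(fday, 45)  # chicks older than ~45 d effectively fledge
      hatch <- cfg$hatch_date_mean +
        round(rnorm(length(occ), 0, cfg$hatch_date_sd))
      list(success = success, fail_inc = fail_inc, fday = fday, hatch = hatch)
    })
    out <- ifelse(res$success, "success",
                  ifelse(res$fail_inc, "fail_incubation", "fail_chick"))
    nests$outcome[occ] <- out
    hatched <- out %in% c("success", "fail_chick")
    nests$hatch_date[occ[hatched]] <- res$hatch[hatched]
    nests$failure_day[occ[out == "fail_chick"]] <-
      ceiling(res$fday[out == "fail_chick"])
  }
  if (is_col) {
    colony$nests <- nests
    colony
  } else {
    nests
  }
}

#' Tarsus growth curve parameters
#'
#' Parameters of the monotone tarsus-vs-age stand-in used to age chicks
#' from tarsus length. The curve is von Bertalanffy,
#' `tarsus(age) = linf - (linf - l0) * exp(-k * age)`, which is strictly
#' increasing and hence invertible; only this monotone invertibility over
#' roughly the first 30 days post-hatch matters for aging. Values give a
#' ~8 mm hatchling tarsus approaching an ~23.5 mm asymptote.
#'
#' @param l0 tarsus length at hatching (mm).
#' @param linf asymptotic tarsus length (mm).
#' @param k growth rate (per day).
#' @param noise_sd SD of measurement noise (mm) added before rounding to
#'   the nearest 0.1 mm.
#' @return a named list of class `tarsus_growth_params`.
#' @export
tarsus_growth_params <- function(l0 = 8.3, linf = 23.5, k = 0.085,
                                 noise_sd = 0.04) {
  stopifnot(l0 > 0, linf > l0, k > 0, noise_sd >= 0)
  structure(list(l0 = l0, linf = linf, k = k, noise_sd = noise_sd),
            class = "tarsus_growth_params")
}

#' Tarsus length at a given chick age
#' @param age_days chick age in days (>= 0).
#' @param params [tarsus_growth_params()].
#' @return tarsus length in mm.
#' @export
tarsus_at_age <- function(age_days, params = tarsus_growth_params()) {
  stopifnot(all(age_days >= 0))
  params$linf - (params$linf - params$l0) * exp(-params$k * age_days)
}

#' Chick age estimated from tarsus length
#'
#' Inverse of [tarsus_at_age()]; ages are reliable to about +/- 1 day up
#' to roughly 30 days post-hatch, beyond which the curve flattens.
#'
#' @param tarsus_mm measured tarsus length (mm).
#' @param params [tarsus_growth_params()].
#' @return estimated age in days (clamped to >= 0; `Inf`-protected at the
#'   asymptote).
#' @export
age_from_tarsus <- function(tarsus_mm, params = tarsus_growth_params()) {
  frac <- (params$linf - tarsus_mm) / (params$linf - params$l0)
  frac <- pmin(pmax(frac, 1e-6), 1)
  pmax(-log(frac) / params$k, 0)
}

#' Simulate an observer breeding check
#'
#' Emulates the August endoscope check of every nest site: a chick is
#' recorded present iff its egg hatched before the check date and the
#' nest had not failed by then. Present chicks get a tarsus measurement
#' from the growth curve plus measurement noise, rounded to the nearest
#' 0.1 mm, and an age estimated by inverting the curve.
#'
#' @param colony a `petrel_colony` whose nests carry breeding outcomes
#'   (see [simulate_breeding_outcomes()]), or such a nest data frame.
#' @param check_date date of the check.
#' @param tarsus_growth [tarsus_growth_params()].
#' @param seed integer seed for measurement noise.
#' @return data frame: `nest_id`, `plot_id`, `chick_present`,
#'   `true_age_days`, `tarsus_mm`, `estimated_age_days`.
#' @export
simulate_observer_check <- function(colony,
                                    check_date,
                                    tarsus_growth = NULL,
                                    seed = NULL) {
  is_col <- inherits(colony, "petrel_colony")
  nests <- if (is_col) colony$nests else colony
  growth <- tarsus_growth %||%
    (if (is_col) colony$config$tarsus_growth else tarsus_growth_params())
  check_date <- as.Date(check_date)
  if (!"outcome" %in% names(nests)) {
    stop("nests carry no breeding outcomes; run simulate_breeding_outcomes() first",
         call. = FALSE)
  }
  age <- as.numeric(check_date - nests$hatch_date)
  hatched <- !is.na(age) & age >= 0
  alive <- hatched & (nests$outcome == "success" |
                        (nests$outcome == "fail_chick" &
                           nests$failure_day > age))
  rec <- data.frame(
    nest_id = nests$nest_id,
    plot_id = nests$plot_id,
    chick_present = alive,
    true_age_days = ifelse(alive, age, NA_real_),
    stringsAsFactors = FALSE
  )
  rec$tarsus_mm <- NA_real_
  rec$estimated_age_days <- NA_real_
  if (any(alive)) {
    tars <- with_seed(seed, {
      tarsus_at_age(age[alive], growth) +
        rnorm(sum(alive), 0, growth$noise_sd)
    })
    tars <- round(tars, 1)
    rec$tarsus_mm[alive] <- tars
    rec$estimated_age_days[alive] <- round(age_from_tarsus(tars, growth))
  }
  rec
}
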