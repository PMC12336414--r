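#' Chick begging-rate ontogeny curve
#'
#' Expected nightly seconds of begging as a function of chick age. Chicks
#' can beg from day 0; the rate ramps up over the first two weeks
#' post-hatch, dips slightly after the peak and then plateaus. An optional
#' late rise after day 30 is disabled by default because in field data it
#' rests on very few individuals.
#'
#' @param age_days chick age in days (values < 0 give 0).
#' @param peak_s nightly seconds at the peak of the curve.
#' @param peak_age age (days) at which the ramp tops out.
#' @param dip_level plateau level as a fraction of the peak.
#' @param dip_age age (days) by which the dip to the plateau is complete.
#' @param late_rise if `TRUE`, the rate climbs again after `late_rise_age`.
#' @param late_rise_age,late_rise_slope onset (days) and slope (fraction of
#'   peak per day) of the optional late rise.
#' @return expected seconds of begging per night (same length as
#'   `age_days`).
#' @export
chick_call_curve <- function(age_days, peak_s = 40, peak_age = 14,
                             dip_level = 0.85, dip_age = 18,
                             late_rise = FALSE, late_rise_age = 30,
                             late_rise_slope = 0.03) {
  shape <- numeric(length(age_days))
  a <- age_days
  ramp <- a >= 0 & a < peak_age
  shape[ramp] <- 0.03 + 0.97 * a[ramp] / peak_age
  dip <- a >= peak_age & a < dip_age
  shape[dip] <- 1 - (1 - dip_level) * (a[dip] - peak_age) / (dip_age - peak_age)
  plateau <- a >= dip_age
  shape[plateau] <- dip_level
  if (late_rise) {
    late <- a >= late_rise_age
    shape[late] <- shape[late] + late_rise_slope * (a[late] - late_rise_age)
  }
  peak_s * shape
}

#' Per-nest chick calling profiles
#'
#' Draws a stable per-chick baseline calling level (lognormal, mean
#' `peak_s`) for every nest whose egg hatched. The realised nightly rate
#' is this baseline shaped by [chick_call_curve()] and multiplied by a
#' per-night satiation factor.
#'
#' @param colony a `petrel_colony` with breeding outcomes.
#' @param seed integer seed.
#' @param baseline_sdlog SD (log scale) of the between-chick baseline
#'   variation.
#' @return data frame: `nest_id`, `baseline_call_s_per_night`.
#' @export
make_chick_profiles <- function(colony, seed = NULL, baseline_sdlog = 0.35) {
  nests <- colony$nests
  hatched <- !is.na(nests$hatch_date)
  ids <- nests$nest_id[hatched]
  base <- with_seed(seed, {
    colony$config$chick_peak_s *
      rlnorm(length(ids), meanlog = -baseline_sdlog^2 / 2,
             sdlog = baseline_sdlog)
  })
  data.frame(nest_id = ids, baseline_call_s_per_night = base,
             stringsAsFactors = FALSE)
}

#' Nightly recording conditions over a season
#'
#' Builds one record per night of the season with a moon illumination
#' fraction from a cosine 29.53-day lunar cycle phased on a supplied full
#' moon date, and a usability flag (wind or other disruptive noise makes a
#' night unusable with probability `1 - usable_prob`). Moon fraction is an
#' input to the analysis, not an ephemeris computation.
#'
#' @param config a [colony_config()].
#' @param seed integer seed for the usability flags.
#' @return data frame of class `night_conditions`: `date`,
#'   `moon_fraction`, `usable`.
#' @export
make_night_conditions <- function(config = colony_config(), seed = NULL) {
  dates <- seq(config$season_start, config$season_end, by = "day")
  phase <- 2 * pi * as.numeric(dates - config$full_moon_date) / 29.53
  moon <- (1 + cos(phase)) / 2
  usable <- with_seed(seed, runif(length(dates)) < config$usable_prob)
  out <- data.frame(date = dates, moon_fraction = moon, usable = usable)
  class(out) <- c("night_conditions", "data.frame")
  out
}

#' Simulate one night of calling across the colony
#'
#' Generates the true call events produced in the colony during the
#' 2200--0200 recording window of one night. Territorial males purr,
#' breeding adults chat, and hatched surviving chicks beg at an
#' age-dependent rate ([chick_call_curve()]) times a per-night lognormal
#' satiation factor. Event counts are Poisson around each nest's expected
#' nightly seconds; event durations are uniform within the call type's
#' duration range and start times uniform within the window.
#'
#' @param colony a `petrel_colony` with breeding outcomes.
#' @param night one row of [make_night_conditions()] (or any list with a
#'   `date`).
#' @param chick_profiles from [make_chick_profiles()]; `NULL` suppresses
#'   chick calling.
#' @param seed integer seed.
#' @param specs call type acoustic parameters, [call_type_specs()].
#' @param window_s length of the recording window in seconds.
#' @return data frame of true events: `nest_id`, `plot_id`, `call_type`,
#'   `start_s`, `duration_s`, `position_m`.
#' @export
simulate_nightly_calling <- function(colony, night, chick_profiles = NULL,
                                     seed = NULL,
                                     specs = call_type_specs(),
                                     window_s = 14400) {
  cfg <- colony$config
  nests <- colony$nests
  date <- as.Date(night$date)
  if (date < cfg$season_start || date > cfg$season_end) {
    stop("night is outside the configured season", call. = FALSE)
  }
  empty <- data.frame(nest_id = character(), plot_id = character(),
                      call_type = character(), start_s = numeric(),
                      duration_s = numeric(), position_m = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(nests) || !any(nests$occupied)) return(empty)

  pf <- setNames(colony$plots$calling_factor, colony$plots$plot_id)
  n_occ <- table(factor(nests$plot_id[nests$occupied],
                        levels = colony$plots$plot_id))
  # adult calling couples to plot size via the abundance_effect exponent:
  # per-nest means carry (n_occ / 20)^(effect - 1) so plot totals scale
  # as n_occ^effect
  eff_mult <- setNames(ifelse(n_occ > 0, (as.numeric(n_occ) / 20)^
                                (cfg$abundance_effect - 1), 0),
                       names(n_occ))

  with_seed(seed, {
    parts <- list()
    make_events <- function(idx, type, mean_s) {
      if (!length(idx)) return(NULL)
      spec <- specs[[type]]
      mean_dur <- mean(c(spec$dur_lo, spec$dur_hi))
      n_ev <- rpois(length(idx), mean_s / mean_dur)
      keep <- n_ev > 0
      if (!any(keep)) return(NULL)
      idx <- rep(idx[keep], n_ev[keep])
      dur <- runif(length(idx), spec$dur_lo, spec$dur_hi)
      data.frame(
        nest_id = nests$nest_id[idx],
        plot_id = nests$plot_id[idx],
        call_type = type,
        start_s = runif(length(idx), 0, window_s - dur),
        duration_s = dur,
        position_m = nests$position_m[idx],
        stringsAsFactors = FALSE
      )
    }

    adult_scale <- pf[nests$plot_id] * eff_mult[nests$plot_id]
    purr_idx <- which(nests$occupied & nests$male_present)
    if (length(purr_idx)) {
      mean_s <- rgamma(length(purr_idx), shape = 1.5,
                       scale = cfg$purr_s_per_nest / 1.5) *
        adult_scale[purr_idx]
      parts$purr <- make_events(purr_idx, "adult_purr", mean_s)
    }
    chat_idx <- which(nests$occupied)
    if (length(chat_idx)) {
      mean_s <- rgamma(length(chat_idx), shape = 1.5,
                       scale = cfg$chat_s_per_nest / 1.5) *
        adult_scale[chat_idx]
      parts$chat <- make_events(chat_idx, "adult_chat", mean_s)
    }
    if (!is.null(chick_profiles) && "hatch_date" %in% names(nests)) {
      age <- as.numeric(date - nests$hatch_date)
      alive <- !is.na(age) & age >= 0 &
        (nests$outcome == "success" |
           (nests$outcome == "fail_chick" & nests$failure_day > age))
      chick_idx <- which(alive & nests$nest_id %in% chick_profiles$nest_id)
      if (length(chick_idx)) {
        base <- chick_profiles$baseline_call_s_per_night[
          match(nests$nest_id[chick_idx], chick_profiles$nest_id)]
        shape <- chick_call_curve(age[chick_idx], peak_s = 1)
        satiation <- rlnorm(length(chick_idx),
                            meanlog = -cfg$satiation_sdlog^2 / 2,
                            sdlog = cfg$satiation_sdlog)
        parts$chick <- make_events(chick_idx, "chick_beg",
                                   base * shape * satiation)
      }
    }
    parts <- Filter(Negate(is.null), parts)
    if (!length(parts)) empty else do.call(rbind, c(parts, make.row.names = FALSE))
  })
}

#' Simulate a repeated playback survey
#'
#' Each occupied nest responds on each visit independently with its
#' per-visit response probability; unoccupied sites never respond.
#'
#' @param nests a nest data frame (e.g. `colony$nests`), or a
#'   `petrel_colony`.
#' @param n_visits number of survey visits (default 7, one per day).
#' @param seed integer seed.
#' @return a 0/1 matrix, nests x visits, with `nest_id` row names and the
#'   nest table attached as attribute `"nests"`. Rows include
#'   never-responding nests; see [detection_history()] for the observed
#'   (discovered AON) view.
#' @export
simulate_playback_survey <- function(nests, n_visits = 7, seed = NULL) {
  if (inherits(nests, "petrel_colony")) nests <- nests$nests
  if (n_visits < 1) stop("`n_visits` must be >= 1", call. = FALSE)
  n <- nrow(nests)
  m <- with_seed(seed, {
    matrix(rbinom(n * n_visits, 1, rep(nests$response_prob, n_visits)),
           nrow = n, ncol = n_visits)
  })
  rownames(m) <- nests$nest_id
  colnames(m) <- paste0("visit", seq_len(n_visits))
  attr(m, "nests") <- nests
  m
}
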