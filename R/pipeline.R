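#' Run the full monitoring experiment on a synthetic colony
#'
#' Chains every stage of the analysis on the event-level fast path:
#' generate a colony and its breeding outcomes; simulate nightly calling
#' over the season and keep the events inside each receiver's detection
#' range; build nightly call-rate records and apply the moon/usability
#' filters and the adult/chick period split; compute mean call rates and
#' accumulation plateaus per plot; run the repeated playback survey and
#' the detection-corrected AON estimates with bootstrap intervals;
#' simulate the August observer check; and fit the comparative models
#' linking acoustic and observer-based measures. Deterministic under a
#' fixed seed (all stage seeds derive from it).
#'
#' @param config a [colony_config()].
#' @param seed master seed (defaults to `config$seed`).
#' @param ranges a [detection_ranges()].
#' @param n_visits playback survey visits (default 7).
#' @param check_date observer breeding-check date.
#' @param n_boot bootstrap replicates for AON intervals (default 999).
#' @param plateau_orderings random orderings in the accumulation-curve
#'   procedure.
#' @return an object of class `experiment_report`; see
#'   [write_report()] for the on-disk form.
#' @export
run_experiment <- function(config = colony_config(), seed = config$seed,
                           ranges = detection_ranges(), n_visits = 7,
                           check_date = as.Date("2023-08-20"),
                           n_boot = 999, plateau_orderings = 100) {
  stages <- c("colony", "outcomes", "profiles", "nights", "calling",
              "playback", "observer", "boot", "plateau")
  ss <- derive_seeds(seed, length(stages), stages)

  colony <- generate_colony(config, seed = ss[["colony"]])
  colony <- simulate_breeding_outcomes(colony, seed = ss[["outcomes"]])
  profiles <- make_chick_profiles(colony, seed = ss[["profiles"]])
  nights <- make_night_conditions(config, seed = ss[["nights"]])

  night_seeds <- derive_seeds(ss[["calling"]], nrow(nights))
  types <- c("adult_purr", "adult_chat", "chick_beg")
  rec_rows <- vector("list", nrow(nights))
  for (i in seq_len(nrow(nights))) {
    ev <- simulate_nightly_calling(colony, nights[i, ], profiles,
                                   seed = night_seeds[i])
    ev <- apply_detection_range(ev, ranges)
    ev <- ev[ev$detected, , drop = FALSE]
    sums <- matrix(0, nrow(colony$plots), length(types),
                   dimnames = list(colony$plots$plot_id, types))
    if (nrow(ev)) {
      agg <- tapply(ev$duration_s, list(ev$plot_id, ev$call_type), sum)
      sums[rownames(agg), colnames(agg)] <-
        ifelse(is.na(agg), 0, agg)
    }
    rec_rows[[i]] <- data.frame(
      plot_id = colony$plots$plot_id,
      date = nights$date[i],
      moon_fraction = nights$moon_fraction[i],
      usable = nights$usable[i],
      adult_purr_s = sums[, "adult_purr"],
      adult_chat_s = sums[, "adult_chat"],
      chick_beg_s = sums[, "chick_beg"],
      stringsAsFactors = FALSE
    )
  }
  night_records <- do.call(rbind, c(rec_rows, make.row.names = FALSE))

  retained <- filter_nights(night_records)
  periods <- split_periods(retained, config$cutoff_date)

  plot_ids <- colony$plots$plot_id
  rate_for <- function(recs, col) {
    vapply(plot_ids, function(p) {
      suppressWarnings(mean_call_rate(recs[recs$plot_id == p, col]))
    }, numeric(1))
  }
  call_rates <- data.frame(
    plot_id = plot_ids,
    adult_purr_rate = rate_for(periods$adult, "adult_purr_s"),
    adult_chat_rate = rate_for(periods$adult, "adult_chat_s"),
    chick_beg_rate = rate_for(periods$chick, "chick_beg_s"),
    n_adult_nights = vapply(plot_ids, function(p) {
      sum(periods$adult$plot_id == p)
    }, numeric(1)),
    n_chick_nights = vapply(plot_ids, function(p) {
      sum(periods$chick$plot_id == p)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )

  plat_seeds <- derive_seeds(ss[["plateau"]], length(plot_ids) * 3)
  plateaus <- do.call(rbind, lapply(seq_along(plot_ids), function(i) {
    p <- plot_ids[i]
    one <- function(recs, col, ty, sd) {
      x <- recs[recs$plot_id == p, col]
      if (length(x) < 6) {
        return(data.frame(plot_id = p, call_type = ty,
                          nights_to_plateau = NA_real_, reached = NA_real_,
                          n_nights = length(x)))
      }
      pl <- accumulation_plateau(x, n_orderings = plateau_orderings,
                                 seed = sd)
      data.frame(plot_id = p, call_type = ty,
                 nights_to_plateau = pl$nights_to_plateau,
                 reached = pl$reached, n_nights = pl$n_nights)
    }
    rbind(one(periods$adult, "adult_purr_s", "adult_purr",
              plat_seeds[3 * i - 2]),
          one(periods$adult, "adult_chat_s", "adult_chat",
              plat_seeds[3 * i - 1]),
          one(periods$chick, "chick_beg_s", "chick_beg",
              plat_seeds[3 * i]))
  }))

  # playback survey and AON estimation over the purr-audible span
  pb_seeds <- derive_seeds(ss[["playback"]], length(plot_ids))
  boot_seeds <- derive_seeds(ss[["boot"]], length(plot_ids))
  aon_rows <- list()
  discovered <- list()
  for (i in seq_along(plot_ids)) {
    p <- plot_ids[i]
    nests_p <- colony$nests[colony$nests$plot_id == p, , drop = FALSE]
    nests_p <- restrict_to_detection_range(nests_p, ranges, "adult_purr",
                                           config$plot_spacing_m)
    if (!nrow(nests_p)) next
    m <- simulate_playback_survey(nests_p, n_visits, seed = pb_seeds[i])
    if (!any(rowSums(m) >= 1)) {
      warning("plot ", p, ": no playback responses; skipped")
      next
    }
    h <- detection_history(m, plot_id = p)
    est <- estimate_aon(h, n_boot = n_boot, seed = boot_seeds[i])
    discovered[[p]] <- rownames(h$matrix)
    aon_rows[[p]] <- data.frame(
      plot_id = p, observed_aons = est$observed_aons,
      response_rate = est$response_rate,
      pct_undetected = est$pct_undetected,
      corrected_aons = est$corrected_aons,
      ci_low = est$ci_low, ci_high = est$ci_high,
      stringsAsFactors = FALSE
    )
  }
  aon <- do.call(rbind, c(aon_rows, make.row.names = FALSE))

  # observer breeding check over the discovered AONs
  check <- simulate_observer_check(colony, check_date,
                                   seed = ss[["observer"]])
  observer <- do.call(rbind, lapply(aon$plot_id, function(p) {
    ids <- discovered[[p]]
    chk <- check[check$nest_id %in% ids, , drop = FALSE]
    succ <- sum(chk$chick_present)
    data.frame(plot_id = p, n_aons_checked = length(ids),
               successes = succ, failures = length(ids) - succ,
               n_chicks = succ,
               breeding_success = succ / length(ids),
               mean_est_chick_age = mean(chk$estimated_age_days,
                                         na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))

  dat <- merge(merge(aon, observer, by = "plot_id"), call_rates,
               by = "plot_id")
  fits <- list()
  if (nrow(dat) >= 4) {
    fits$purr_index <- fit_abundance_index(round(dat$corrected_aons),
                                           dat$adult_purr_rate,
                                           "adult_purr")
    fits$chat_index <- fit_abundance_index(round(dat$corrected_aons),
                                           dat$adult_chat_rate,
                                           "adult_chat")
    fits$chick_abundance <- fit_chick_abundance(dat$n_chicks,
                                                dat$chick_beg_rate)
    fits$breeding_success <- suppressWarnings(
      fit_breeding_success(dat$successes, dat$failures,
                           dat$chick_beg_rate))
    ratio_purr <- suppressWarnings(
      acoustic_breeding_success(dat$chick_beg_rate, dat$adult_purr_rate))
    ratio_chat <- suppressWarnings(
      acoustic_breeding_success(dat$chick_beg_rate, dat$adult_chat_rate))
    if (sum(!is.na(ratio_purr)) >= 4) {
      ok <- !is.na(ratio_purr)
      fits$acoustic_success_purr <- suppressWarnings(
        fit_breeding_success(dat$successes[ok], dat$failures[ok],
                             ratio_purr[ok],
                             predictor_name = "chick_over_purr_ratio"))
    }
    if (sum(!is.na(ratio_chat)) >= 4) {
      ok <- !is.na(ratio_chat)
      fits$acoustic_success_chat <- suppressWarnings(
        fit_breeding_success(dat$successes[ok], dat$failures[ok],
                             ratio_chat[ok],
                             predictor_name = "chick_over_chat_ratio"))
    }
  }
  correlations <- list(
    purr_vs_chat = correlate(dat$adult_purr_rate, dat$adult_chat_rate),
    chicks_vs_success = correlate(dat$n_chicks, dat$breeding_success)
  )

  summary_stats <- list(
    n_plots = nrow(dat),
    mean_pct_undetected = mean(dat$pct_undetected),
    overall_breeding_success = sum(dat$successes) /
      sum(dat$successes + dat$failures),
    mean_plateau_nights = vapply(types, function(ty) {
      mean(plateaus$nights_to_plateau[plateaus$call_type == ty],
           na.rm = TRUE)
    }, numeric(1)),
    mean_rate = vapply(paste0(types, "_rate"), function(cl) {
      mean(dat[[cl]], na.rm = TRUE)
    }, numeric(1))
  )

  manifest <- list(
    seed = seed,
    stage_seeds = as.list(ss),
    package_version = as.character(packageVersion("petrelcall")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(config = config, seed = seed,
                 night_records = night_records, call_rates = call_rates,
                 plateaus = plateaus, aon = aon, observer = observer,
                 model_data = dat, fits = fits,
                 correlations = correlations,
                 summary = summary_stats, manifest = manifest),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Monitoring experiment: %d plots, seed %d\n",
              x$summary$n_plots, x$seed))
  cat(sprintf("  mean %% undetected %.1f%%, overall breeding success %.2f\n",
              x$summary$mean_pct_undetected,
              x$summary$overall_breeding_success))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-22s estimate %6.2f (95%% CI %6.2f, %6.2f)%s\n", nm,
                f$estimate, f$ci_low, f$ci_high,
                if (isTRUE(f$significant)) " *" else ""))
  }
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Writes the stage tables as CSV, the model fits and summary as JSON,
#' and a reproducibility manifest (seeds, versions, per-file MD5
#' digests).
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(night_records = "night_records.csv",
             call_rates = "call_rates.csv",
             plateaus = "plateaus.csv",
             aon = "aon_estimates.csv",
             observer = "observer_checks.csv",
             model_data = "model_data.csv")
  for (nm in names(files)) {
    write_table(report[[nm]], file.path(dir, files[nm]))
  }
  fits_json <- lapply(report$fits, function(f) {
    f[c("response_name", "predictor_name", "family", "degree", "estimate",
        "ci_low", "ci_high", "significant", "aic", "pseudo_r2",
        "deviance_r2", "n")]
  })
  jsonlite::write_json(
    list(fits = fits_json, correlations = report$correlations,
         summary = report$summary),
    file.path(dir, "models.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  manifest <- report$manifest
  manifest$config <- unclass_dates(report$config)
  paths <- file.path(dir, c(files, "models.json"))
  manifest$file_digests <- as.list(setNames(unname(md5sum(paths)),
                                            basename(paths)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

unclass_dates <- function(x) {
  x <- unclass(x)
  lapply(x, function(v) {
    if (inherits(v, "Date")) as.character(v)
    else if (is.list(v)) unclass(v)
    else v
  })
}

#' Write a data table as CSV
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a data table with schema validation
#'
#' Reads a CSV and validates it against a declared schema: all schema
#' columns must be present, and every value must parse as the declared
#' type; a value that does not is reported with its row and column.
#'
#' @param path CSV path.
#' @param schema named character vector mapping column names to types
#'   (`"character"`, `"integer"`, `"numeric"`, `"logical"`, `"Date"`).
#'   `NULL` skips validation.
#' @return data frame with converted columns (schema columns first).
#' @export
read_table <- function(path, schema = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (is.null(schema)) return(utils::type.convert(df, as.is = TRUE))
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in names(schema)) {
    raw <- df[[col]]
    blank <- is.na(raw) | raw == ""
    conv <- switch(schema[[col]],
                   character = raw,
                   integer = suppressWarnings(as.integer(raw)),
                   numeric = suppressWarnings(as.numeric(raw)),
                   logical = as.logical(raw),
                   Date = as.Date(raw, optional = TRUE),
                   stop("unknown schema type: ", schema[[col]]))
    bad <- which(!blank & is.na(conv))
    if (length(bad)) {
      stop(sprintf("invalid %s value %s at row %d, column '%s' of %s",
                   schema[[col]], dQuote(raw[bad[1]]), bad[1], col,
                   basename(path)), call. = FALSE)
    }
    conv[blank] <- NA
    df[[col]] <- conv
  }
  df[, c(names(schema), setdiff(names(df), names(schema))), drop = FALSE]
}

#' Column schemas for the pipeline's table formats
#'
#' @name table_schemas
#' @return named character vectors usable with [read_table()].
NULL

#' @rdname table_schemas
#' @export
schema_nightly <- function() {
  c(plot_id = "character", date = "Date", moon_fraction = "numeric",
    usable = "logical", adult_purr_s = "numeric", adult_chat_s = "numeric",
    chick_beg_s = "numeric")
}

#' @rdname table_schemas
#' @export
schema_detection_history <- function() {
  c(plot_id = "character", nest_id = "character", visit = "integer",
    response = "integer")
}

#' @rdname table_schemas
#' @export
schema_nests <- function() {
  c(nest_id = "character", plot_id = "character", position_m = "numeric",
    occupied = "logical", response_prob = "numeric")
}

#' Read or write a colony configuration file
#'
#' Configurations round-trip through YAML (`.yml`/`.yaml`) or JSON
#' (anything else); dates are stored as ISO-8601 strings.
#'
#' @param config a [colony_config()].
#' @param path file path; the extension picks the format.
#' @return `write_colony_config`: `path` invisibly;
#'   `read_colony_config`: a `colony_config`.
#' @export
write_colony_config <- function(config, path) {
  x <- unclass_dates(config)
  x$tarsus_growth <- unclass(config$tarsus_growth)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_colony_config
#' @export
read_colony_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  tg <- x$tarsus_growth
  x$tarsus_growth <- NULL
  x <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  if (!is.null(tg)) x$tarsus_growth <- do.call(tarsus_growth_params, as.list(tg))
  do.call(colony_config, x)
}

#' Detection history to/from long-format tables
#'
#' @param m a response matrix from [simulate_playback_survey()].
#' @param plot_id plot identifier column value.
#' @return `history_to_long`: a long data frame (`plot_id`, `nest_id`,
#'   `visit`, `response`); `history_from_long`: a list of
#'   [detection_history()] objects, one per plot.
#' @export
history_to_long <- function(m, plot_id = NA_character_) {
  data.frame(
    plot_id = plot_id,
    nest_id = rep(rownames(m), ncol(m)),
    visit = rep(seq_len(ncol(m)), each = nrow(m)),
    response = as.integer(m),
    stringsAsFactors = FALSE
  )
}

#' @rdname history_to_long
#' @param long a long-format data frame matching
#'   [schema_detection_history()].
#' @export
history_from_long <- function(long) {
  lapply(split(long, long$plot_id), function(d) {
    detection_history(d[c("nest_id", "visit", "response")],
                      plot_id = d$plot_id[1])
  })
}
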