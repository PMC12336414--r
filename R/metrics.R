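#' Filter plot-nights for analysis
#'
#' Drops nights whose recordings are unusable (wind or other disruptive
#' noise) and nights when the moon was more than `moon_threshold` full
#' (storm petrel activity drops around full moon, so such nights are
#' excluded). Exclusion is strict: a moon fraction exactly at the
#' threshold is retained. The filter is idempotent.
#'
#' @param records data frame with logical `usable` and numeric
#'   `moon_fraction` columns (e.g. nightly call-rate records).
#' @param moon_threshold moon illumination fraction above which nights
#'   are excluded (default 0.75).
#' @return the retained rows of `records`.
#' @export
filter_nights <- function(records, moon_threshold = 0.75) {
  keep <- records$usable & records$moon_fraction <= moon_threshold
  records[keep, , drop = FALSE]
}

#' Split nights into adult and chick periods
#'
#' Adult call rates use nights strictly before the cutoff date (one week
#' before the earliest expected hatch); chick call rates use nights on or
#' after it. The two sets partition the input.
#'
#' @param records data frame with a `date` column.
#' @param cutoff_date the split date (default 14 July 2023).
#' @return list with elements `adult` and `chick`.
#' @export
split_periods <- function(records, cutoff_date = as.Date("2023-07-14")) {
  cutoff_date <- as.Date(cutoff_date)
  d <- as.Date(records$date)
  list(adult = records[d < cutoff_date, , drop = FALSE],
       chick = records[d >= cutoff_date, , drop = FALSE])
}

#' Mean nightly call rate
#'
#' Arithmetic mean of the retained nightly call seconds. An empty series
#' yields `NA` (never 0): a plot with no usable nights has no rate.
#'
#' @param nightly_seconds numeric vector of per-night call seconds.
#' @return mean seconds per night, or `NA_real_` for an empty series.
#' @export
mean_call_rate <- function(nightly_seconds) {
  nightly_seconds <- nightly_seconds[!is.na(nightly_seconds)]
  if (!length(nightly_seconds)) {
    warning("no retained nights; mean call rate is missing")
    return(NA_real_)
  }
  mean(nightly_seconds)
}

#' Accumulation-curve plateau of the mean call rate
#'
#' Determines how many nights of data are needed for the running mean
#' call rate to stabilise. Nights are drawn in random order without
#' replacement; after each added night the running mean is recomputed,
#' and the slope of the running-mean curve over a trailing window of
#' `window` points (ordinary least squares, seconds/night per added
#' night) is evaluated. The plateau for one ordering is the first number
#' of nights at which the absolute slope drops below `slope_threshold`;
#' the reported `nights_to_plateau` averages over orderings. With
#' `shuffle = FALSE` a single pass in the given night order is used.
#'
#' @param nightly_seconds numeric vector of nightly call seconds.
#' @param slope_threshold absolute slope below which the curve is flat
#'   (default 0.1).
#' @param n_orderings number of random orderings to average (default
#'   100).
#' @param window trailing window length (points) for the slope (default
#'   5); needs `length(nightly_seconds) >= window`.
#' @param seed integer seed for the orderings.
#' @param shuffle set `FALSE` to evaluate the single given ordering.
#' @param keep_curves if `TRUE`, the running-mean curve of every ordering
#'   is returned as a matrix (`curves`, orderings x nights).
#' @return list of class `plateau_result`: `nights_to_plateau` (mean over
#'   orderings that reached the plateau, or `NA` if none did), `reached`
#'   (fraction of orderings reaching it), `per_ordering` (integer vector,
#'   `NA` where not reached), `final_slope` (mean trailing slope at full
#'   n), plus the parameters used.
#' @export
accumulation_plateau <- function(nightly_seconds, slope_threshold = 0.1,
                                 n_orderings = 100, window = 5,
                                 seed = NULL, shuffle = TRUE,
                                 keep_curves = FALSE) {
  x <- nightly_seconds[!is.na(nightly_seconds)]
  n <- length(x)
  if (n < window) {
    stop("need at least `window` (", window, ") nights, got ", n,
         call. = FALSE)
  }
  if (!shuffle) n_orderings <- 1L
  res <- with_seed(seed, {
    per <- rep(NA_integer_, n_orderings)
    fin <- numeric(n_orderings)
    curves <- if (keep_curves) matrix(NA_real_, n_orderings, n) else NULL
    for (o in seq_len(n_orderings)) {
      ord <- if (shuffle) sample.int(n) else seq_len(n)
      rm_curve <- cumsum(x[ord]) / seq_len(n)
      if (keep_curves) curves[o, ] <- rm_curve
      slopes <- trailing_slopes(rm_curve, window)
      hit <- which(abs(slopes) < slope_threshold)
      if (length(hit)) per[o] <- hit[1] + window - 1L
      fin[o] <- slopes[length(slopes)]
    }
    list(per = per, fin = fin, curves = curves)
  })
  structure(list(
    nights_to_plateau = if (any(!is.na(res$per))) {
      mean(res$per, na.rm = TRUE)
    } else NA_real_,
    reached = mean(!is.na(res$per)),
    per_ordering = res$per,
    final_slope = mean(res$fin),
    n_nights = n,
    slope_threshold = slope_threshold,
    n_orderings = n_orderings,
    window = window,
    curves = res$curves
  ), class = "plateau_result")
}

# OLS slope of y over each trailing window of `window` points;
# slopes[k] is the slope ending at point k + window - 1
trailing_slopes <- function(y, window) {
  n <- length(y)
  xs <- seq_len(window)
  xc <- xs - mean(xs)
  denom <- sum(xc^2)
  vapply(seq_len(n - window + 1), function(i) {
    sum(xc * y[i:(i + window - 1)]) / denom
  }, numeric(1))
}

#' @export
print.plateau_result <- function(x, ...) {
  if (is.na(x$nights_to_plateau)) {
    cat(sprintf("plateau not reached over %d nights (final slope %.3f)\n",
                x$n_nights, x$final_slope))
  } else {
    cat(sprintf("plateau after %.1f nights (|slope| < %g, %d ordering%s, %.0f%% reached)\n",
                x$nights_to_plateau, x$slope_threshold, x$n_orderings,
                if (x$n_orderings > 1) "s" else "", 100 * x$reached))
  }
  invisible(x)
}

#' Nightly call-rate records from detected events
#'
#' Aggregates detected call events into one record per plot-night with
#' per-type call seconds, joined to the night's conditions.
#'
#' @param events event data frame with `plot_id`, `date`, `call_type`,
#'   `duration_s` and (optionally) a logical `detected` column, which is
#'   honoured when present.
#' @param nights a [make_night_conditions()] data frame.
#' @param plots character vector of plot ids to tabulate (defaults to
#'   those present in `events`).
#' @param call_types call type names (defaults to the three targets).
#' @return data frame: `plot_id`, `date`, `moon_fraction`, `usable`, one
#'   `<call_type>_s` column per type.
#' @export
nightly_call_records <- function(events, nights, plots = NULL,
                                 call_types = c("adult_purr", "adult_chat",
                                                "chick_beg")) {
  if ("detected" %in% names(events)) {
    events <- events[events$detected, , drop = FALSE]
  }
  plots <- plots %||% sort(unique(events$plot_id))
  grid <- expand.grid(plot_id = plots, date = nights$date,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- merge(grid, nights, by = "date", sort = FALSE)
  for (ty in call_types) {
    sub <- events[events$call_type == ty, , drop = FALSE]
    col <- paste0(ty, "_s")
    if (nrow(sub)) {
      agg <- aggregate(duration_s ~ plot_id + date, data = sub, FUN = sum)
      m <- merge(grid[c("plot_id", "date")], agg,
                 by = c("plot_id", "date"), all.x = TRUE, sort = FALSE)
      # merge() may reorder; re-align explicitly
      key <- paste(grid$plot_id, grid$date)
      grid[[col]] <- m$duration_s[match(key, paste(m$plot_id, m$date))]
      grid[[col]][is.na(grid[[col]])] <- 0
    } else {
      grid[[col]] <- 0
    }
  }
  grid[order(grid$plot_id, grid$date), c("plot_id", "date", "moon_fraction",
                                         "usable", paste0(call_types, "_s"))]
}
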