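#' Playback detection history
#'
#' Validates and normalises a nests-by-visits 0/1 response matrix from a
#' repeated playback survey. Rows are discovered apparently occupied
#' nests (AONs): nests that never responded are unobservable in the
#' field, so all-zero rows are dropped.
#'
#' @param x a 0/1 matrix (nests x visits), e.g. from
#'   [simulate_playback_survey()], or a data frame in long format with
#'   columns `nest_id`, `visit`, `response`.
#' @param plot_id optional plot identifier carried through to estimates.
#' @return list of class `detection_history`: `matrix`, `n_visits`,
#'   `plot_id`.
#' @export
detection_history <- function(x, plot_id = NA_character_) {
  if (is.data.frame(x)) {
    m <- tapply(x$response, list(x$nest_id, x$visit), function(v) v[1])
    m[is.na(m)] <- 0
    x <- m
  }
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) {
    stop("detection history must contain only 0/1 responses", call. = FALSE)
  }
  if (ncol(x) < 1) stop("need at least one visit", call. = FALSE)
  x <- x[rowSums(x) >= 1, , drop = FALSE]
  structure(list(matrix = x, n_visits = ncol(x), plot_id = plot_id),
            class = "detection_history")
}

as_history <- function(x, plot_id = NA_character_) {
  if (inherits(x, "detection_history")) x else detection_history(x, plot_id)
}

#' Playback response rate
#'
#' The average, over survey visits, of the proportion of discovered AONs
#' that responded on that visit. Because rows are conditioned on having
#' responded at least once, this observed rate slightly overstates the
#' underlying per-visit response probability; `corrected = TRUE` returns
#' the zero-truncated binomial estimate of that probability instead
#' (the value [estimate_aon()] uses for the detection correction).
#'
#' @param history a [detection_history()] (or coercible matrix).
#' @param corrected return the truncation-corrected per-visit response
#'   probability rather than the observed average proportion.
#' @return a probability; `NA` for a history with no nests.
#' @export
response_rate <- function(history, corrected = FALSE) {
  h <- as_history(history)
  if (nrow(h$matrix) == 0) {
    warning("no discovered nests; response rate is missing")
    return(NA_real_)
  }
  r_obs <- mean(colMeans(h$matrix))
  if (!corrected) return(r_obs)
  truncated_binomial_p(r_obs, h$n_visits)
}

# invert r_obs = p / (1 - (1 - p)^T), the mean per-visit response of a
# nest conditioned on responding at least once, to recover p. The
# estimate is floored at half a response per survey (0.5 / T): as the
# observed mean response count approaches its theoretical minimum of one
# the inversion degenerates towards p = 0 and the detection correction
# diverges.
truncated_binomial_p <- function(r_obs, T) {
  grid <- seq(1e-4, 1, length.out = 4096)
  g <- grid / (1 - (1 - grid)^T)
  p <- approx(g, grid, xout = pmin(pmax(r_obs, min(g)), 1), rule = 2)$y
  pmax(p, 0.5 / T)
}

# detection-corrected count; a correction below count resolution
# (under 0.5% of nests undetected) is treated as exact detection
corrected_count <- function(n, p, T) {
  miss <- (1 - p)^T
  ifelse(miss < 0.005, n, n / (1 - miss))
}

#' Percentage of nests left undetected
#'
#' With per-visit response rate `r` and `n_trials` independent survey
#' visits, the expected percentage of occupied nests that never respond
#' is `100 * (1 - r)^n_trials`.
#'
#' @param response_rate per-visit response probability in `[0, 1]`.
#' @param n_trials number of survey visits (>= 1; the protocol default is
#'   7).
#' @return percentage in `[0, 100)`.
#' @export
percent_undetected <- function(response_rate, n_trials = 7) {
  if (any(response_rate < 0 | response_rate > 1)) {
    stop("`response_rate` must be in [0, 1]", call. = FALSE)
  }
  if (any(n_trials < 1)) stop("`n_trials` must be >= 1", call. = FALSE)
  100 * (1 - response_rate)^n_trials
}

#' Estimate plot population size from a playback detection history
#'
#' Corrects the observed AON count for nests that never responded:
#' the point estimate is `observed / (1 - (1 - r)^T)` with `T` the
#' number of visits and `r` the truncation-corrected per-visit response
#' probability (see [response_rate()]; the raw observed rate would
#' under-correct because discovered nests are exactly those that
#' responded at least once), with a leave-one-nest-out jackknife bias
#' correction of the correction factor, which is convex in the response
#' rate and otherwise biased upward at small counts. The 95% interval
#' comes from a 999-replicate parametric bootstrap: whole surveys of the
#' estimated number of nests are simulated at the estimated response
#' probability, truncated to the nests that respond at least once, and
#' re-estimated; the percentile interval of those replicates (clamped to
#' bracket the point estimate) captures both response-rate uncertainty
#' and the binomial sampling of which nests are ever detected.
#' Visit-level resampling is available as a sensitivity analysis.
#'
#' @param history a [detection_history()] (or coercible matrix).
#' @param n_boot bootstrap replicates (default 999).
#' @param seed integer seed; fixed seed gives bit-reproducible intervals.
#' @param resample `"parametric"` (default) or `"visits"`.
#' @return list of class `aon_estimate`: `plot_id`, `observed_aons`,
#'   `response_rate` (truncation-corrected), `response_rate_observed`,
#'   `pct_undetected`, `corrected_aons`, `ci_low`, `ci_high`, `n_boot`,
#'   `n_visits`.
#' @export
estimate_aon <- function(history, n_boot = 999, seed = NULL,
                         resample = c("parametric", "visits")) {
  resample <- match.arg(resample)
  h <- as_history(history)
  m <- h$matrix
  n <- nrow(m)
  if (n == 0) stop("empty detection history", call. = FALSE)
  T <- h$n_visits
  r_obs <- mean(colMeans(m))
  if (r_obs <= 0) stop("response rate is zero; cannot correct counts",
                       call. = FALSE)
  p <- truncated_binomial_p(r_obs, T)
  plug <- corrected_count(n, p, T)
  # jackknife over nests: correct the convexity bias of the correction
  # factor while holding the observed count fixed
  corrected <- plug
  if (n > 1) {
    rs <- rowMeans(m)
    r_loo <- (sum(rs) - rs) / (n - 1)
    est_loo <- corrected_count(n - 1, truncated_binomial_p(r_loo, T), T) *
      n / (n - 1)
    corrected <- max(n * plug - (n - 1) * mean(est_loo), n)
  }
  boot <- with_seed(seed, {
    if (resample == "parametric") {
      n_sim <- max(n, round(corrected))
      k <- matrix(rbinom(n_boot * n_sim, T, p), nrow = n_boot)
      nb <- rowSums(k > 0)
      rb <- ifelse(nb > 0, rowSums(k) / (T * nb), NA_real_)
      corrected_count(nb, truncated_binomial_p(rb, T), T)
    } else {
      vapply(seq_len(n_boot), function(b) {
        mb <- m[, sample.int(T, T, replace = TRUE), drop = FALSE]
        nb <- sum(rowSums(mb) >= 1)
        rb <- mean(colMeans(mb[rowSums(mb) >= 1, , drop = FALSE]))
        corrected_count(nb, truncated_binomial_p(rb, T), T)
      }, numeric(1))
    }
  })
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  structure(list(plot_id = h$plot_id, observed_aons = n,
                 response_rate = p,
                 response_rate_observed = r_obs,
                 pct_undetected = percent_undetected(p, T),
                 corrected_aons = corrected,
                 ci_low = min(ci[1], corrected),
                 ci_high = max(ci[2], corrected),
                 n_boot = n_boot, n_visits = T),
            class = "aon_estimate")
}

#' @export
print.aon_estimate <- function(x, ...) {
  cat(sprintf("AON estimate%s: %d observed, %.1f corrected (95%% CI %.1f-%.1f)\n",
              if (is.na(x$plot_id)) "" else paste0(" [", x$plot_id, "]"),
              x$observed_aons, x$corrected_aons, x$ci_low, x$ci_high))
  cat(sprintf("  response rate %.3f over %d visits; %.1f%% of nests undetected\n",
              x$response_rate, x$n_visits, x$pct_undetected))
  invisible(x)
}

#' Restrict nests to the receiver's audible span
#'
#' Keeps nests whose position along the wall lies within the detection
#' range of the relevant call type, so observer-based measures cover the
#' same stretch of wall the receiver hears. When plot spacing is
#' supplied, a nest audible from two plots is assigned to the nearer
#' plot centre (positions beyond half the spacing belong to the
#' neighbour).
#'
#' @param nests nest data frame with `position_m`.
#' @param ranges a [detection_ranges()].
#' @param call_type which call type's range applies (default the purr
#'   used in playback).
#' @param plot_spacing_m distance between adjacent plot centres; `NULL`
#'   skips the nearer-plot rule.
#' @return the retained rows of `nests`.
#' @export
restrict_to_detection_range <- function(nests, ranges = detection_ranges(),
                                        call_type = "adult_purr",
                                        plot_spacing_m = NULL) {
  r <- unclass(ranges)[[call_type]]
  keep <- abs(nests$position_m) <= r
  if (!is.null(plot_spacing_m)) {
    keep <- keep & abs(nests$position_m) <= plot_spacing_m / 2
  }
  nests[keep, , drop = FALSE]
}

#' Fraction of nests audible from two plots
#'
#' With plots strung along a wall at a fixed spacing, a nest near a plot
#' edge can fall inside the detection range of both its own and the
#' neighbouring receiver.
#'
#' @param nests nest data frame with `position_m`.
#' @param range_m one-sided detection range (m).
#' @param plot_spacing_m distance between adjacent plot centres (m).
#' @return fraction of nests within `range_m` of two plot centres.
#' @export
overlap_fraction <- function(nests, range_m, plot_spacing_m) {
  own <- abs(nests$position_m) <= range_m
  neighbour <- abs(plot_spacing_m - abs(nests$position_m)) <= range_m
  mean(own & neighbour)
}
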