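#' Plot an abundance-index fit
#'
#' Scatter of plot population size against mean nightly call rate with
#' the fitted GLM curve. Requires ggplot2.
#'
#' @param fit a `model_fit` from [fit_abundance_index()] or
#'   [fit_chick_abundance()].
#' @param call_rate,aons the data the model was fitted to (original
#'   scale).
#' @return a ggplot object.
#' @export
plot_index_fit <- function(fit, call_rate, aons) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is needed for plotting", call. = FALSE)
  }
  grid <- data.frame(rate = seq(min(call_rate), max(call_rate),
                                length.out = 100))
  z <- (grid$rate - mean(call_rate)) / sd(call_rate)
  nd <- data.frame(z = z)
  for (d in seq_len(fit$degree)) nd[[paste0("z", d)]] <- z^d
  pr <- predict(fit$glm, newdata = nd, type = "link", se.fit = TRUE)
  inv <- fit$glm$family$linkinv
  grid$fit <- inv(pr$fit)
  grid$lo <- inv(pr$fit - 1.96 * pr$se.fit)
  grid$hi <- inv(pr$fit + 1.96 * pr$se.fit)
  ggplot2::ggplot(data.frame(rate = call_rate, aons = aons)) +
    ggplot2::geom_ribbon(data = grid,
                         ggplot2::aes(x = .data$rate, ymin = .data$lo,
                                      ymax = .data$hi), alpha = 0.2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$rate, y = .data$fit)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$rate, y = .data$aons)) +
    ggplot2::labs(x = "mean nightly call rate (s/night)",
                  y = fit$response_name) +
    ggplot2::theme_minimal()
}

#' Plot a fitted chick-age calling curve
#'
#' @param fit a `chick_age_fit` from [fit_chick_age_curve()].
#' @param data optional data frame with `age_days`, `call_rate_s`,
#'   `chick_id` to overlay the raw points.
#' @return a ggplot object.
#' @export
plot_chick_curve <- function(fit, data = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is needed for plotting", call. = FALSE)
  }
  g <- ggplot2::ggplot(fit$curve) +
    ggplot2::geom_ribbon(ggplot2::aes(x = .data$age_days,
                                      ymin = .data$fit_s - 1.96 * .data$se_s,
                                      ymax = .data$fit_s + 1.96 * .data$se_s),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(x = .data$age_days, y = .data$fit_s)) +
    ggplot2::labs(x = "chick age (days post-hatch)",
                  y = "nightly call rate (s)") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    g <- g + ggplot2::geom_point(
      data = data,
      ggplot2::aes(x = .data$age_days, y = .data$call_rate_s,
                   colour = factor(.data$chick_id)),
      alpha = 0.6, show.legend = FALSE)
  }
  g
}
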