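#' Mean-centre and standardise a variable
#'
#' Centres to mean 0 and scales to unit standard deviation (sample SD,
#' `n - 1` denominator). All continuous predictors are standardised
#' before model fitting so coefficients are comparable across models.
#'
#' @param values numeric vector with at least two distinct values.
#' @return standardized vector.
#' @export
standardize <- function(values) {
  values <- as.numeric(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardise a constant (or length-1) vector", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Fit one GLM and package it as a model fit
#'
#' Internal worker shared by the model-fitting front ends. The predictor
#' enters as raw polynomial terms of the standardized variable (powers of
#' a standardized predictor are well conditioned at these degrees).
#' Significance follows the CI rule: an effect is significant iff its
#' Wald 95% interval excludes zero.
#'
#' @noRd
fit_glm_degree <- function(y, z, family, degree, response_name,
                           predictor_name) {
  dat <- data.frame(z = z)
  for (d in seq_len(degree)) dat[[paste0("z", d)]] <- z^d
  form <- as.formula(paste("y ~", paste(paste0("z", seq_len(degree)),
                                        collapse = " + ")))
  dat$y <- y
  fit <- glm(form, family = family, data = dat)
  co <- summary(fit)$coefficients
  est <- co[-1, 1]
  se <- co[-1, 2]
  ci_lo <- est - qnorm(0.975) * se
  ci_hi <- est + qnorm(0.975) * se
  obs <- if (is.matrix(y)) y[, 1] / rowSums(y) else y
  structure(list(
    response_name = response_name,
    predictor_name = predictor_name,
    family = paste0(family$family, "_", family$link),
    degree = degree,
    coefficients = data.frame(term = rownames(co)[-1], estimate = est,
                              se = se, ci_low = ci_lo, ci_high = ci_hi,
                              row.names = NULL),
    estimate = unname(est[1]),
    ci_low = unname(ci_lo[1]),
    ci_high = unname(ci_hi[1]),
    significant = unname(ci_lo[1] > 0 | ci_hi[1] < 0),
    aic = AIC(fit),
    pseudo_r2 = suppressWarnings(cor(obs, fitted(fit)))^2,
    deviance_r2 = 1 - fit$deviance / fit$null.deviance,
    n = length(obs),
    glm = fit
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s ~ %s  [%s, degree %d, n = %d]\n", x$response_name,
              x$predictor_name, x$family, x$degree, x$n))
  cat(sprintf("  linear term: %.3f (95%% CI %.3f, %.3f) %s\n",
              x$estimate, x$ci_low, x$ci_high,
              if (isTRUE(x$significant)) "*" else "(CI crosses 0)"))
  if (x$degree > 1) {
    for (i in seq_len(nrow(x$coefficients))[-1]) {
      cat(sprintf("  %s: %.3f (95%% CI %.3f, %.3f)\n",
                  x$coefficients$term[i], x$coefficients$estimate[i],
                  x$coefficients$ci_low[i], x$coefficients$ci_high[i]))
    }
  }
  cat(sprintf("  AIC %.1f, R2 %.2f (deviance R2 %.2f)\n",
              x$aic, x$pseudo_r2, x$deviance_r2))
  if (!is.null(x$delta_aic)) {
    cat("  dAIC vs chosen:",
        paste(sprintf("degree %s: %+.1f", names(x$delta_aic), x$delta_aic),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select a polynomial degree by AIC
#'
#' Fits the candidate polynomial degrees in increasing order and keeps a
#' more complex model only when its AIC beats the current choice by more
#' than 2; ties (dAIC <= 2) retain the simpler model. dAIC values of all
#' candidates relative to the chosen model are reported on the returned
#' fit.
#'
#' @param y response (numeric vector, or two-column success/failure
#'   matrix for binomial models).
#' @param z standardized predictor.
#' @param family a [stats::family] object.
#' @param degrees candidate degrees (default 1:3).
#' @param response_name,predictor_name labels carried into the fit.
#' @return the chosen `model_fit`, with a `delta_aic` element.
#' @export
select_polynomial <- function(y, z, family, degrees = 1:3,
                              response_name = "response",
                              predictor_name = "predictor") {
  degrees <- sort(degrees)
  fits <- lapply(degrees, function(d) {
    fit_glm_degree(y, z, family, d, response_name, predictor_name)
  })
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  chosen <- 1
  for (i in seq_along(degrees)[-1]) {
    if (aics[chosen] - aics[i] > 2) chosen <- i
  }
  out <- fits[[chosen]]
  out$delta_aic <- setNames(aics - aics[chosen], degrees)
  out
}

#' Adult call rate as an index of population size
#'
#' Poisson log-link GLM of the plot population size (corrected AON
#' count) on the standardized mean nightly call rate of one adult call
#' type, with Wald 95% intervals. One fit per call type: purr and chat
#' rates covary, so they are never entered together. Polynomial degrees
#' are screened by AIC (see [select_polynomial()]).
#'
#' @param aons integer AON counts per plot (corrected estimates rounded
#'   to whole nests).
#' @param call_rate mean nightly call seconds per plot (standardized
#'   internally).
#' @param call_type label: `"adult_purr"` or `"adult_chat"`.
#' @param degrees candidate polynomial degrees.
#' @return a `model_fit`.
#' @export
fit_abundance_index <- function(aons, call_rate,
                                call_type = c("adult_purr", "adult_chat"),
                                degrees = 1:3) {
  call_type <- match.arg(call_type)
  if (any(aons != round(aons))) {
    stop("`aons` must be whole counts for a Poisson fit; round corrected estimates first",
         call. = FALSE)
  }
  if (length(aons) < 4) stop("need at least 4 plots", call. = FALSE)
  select_polynomial(as.integer(aons), standardize(call_rate),
                    poisson(link = "log"), degrees,
                    response_name = "population_size_aons",
                    predictor_name = paste0(call_type, "_rate"))
}

#' Chick call rate as an index of chick abundance
#'
#' Poisson log-link GLM of the observer-based chick count per plot on
#' the standardized mean nightly chick call rate.
#'
#' @param n_chicks chick counts per plot.
#' @param chick_rate mean nightly chick call seconds per plot.
#' @param degrees candidate polynomial degrees.
#' @return a `model_fit`.
#' @export
fit_chick_abundance <- function(n_chicks, chick_rate, degrees = 1:3) {
  if (any(n_chicks != round(n_chicks))) {
    stop("`n_chicks` must be whole counts", call. = FALSE)
  }
  select_polynomial(as.integer(n_chicks), standardize(chick_rate),
                    poisson(link = "log"), degrees,
                    response_name = "n_chicks",
                    predictor_name = "chick_beg_rate")
}

#' Breeding success against an acoustic predictor
#'
#' Binomial logit GLM of per-plot breeding success (successes = chicks
#' present at the observer check, failures = AONs without a chick) on a
#' standardized predictor, with polynomial degree chosen by AIC. If the
#' fit is separable (some fitted probabilities at 0/1 with runaway
#' coefficients), the model is refit with half a success and half a
#' failure added to every plot (a Haldane-style shrinkage) and flagged.
#'
#' @param successes,failures counts per plot.
#' @param predictor numeric predictor per plot (standardized internally),
#'   e.g. chick call rate or an acoustic success ratio.
#' @param predictor_name label for reports.
#' @param degrees candidate polynomial degrees.
#' @return a `model_fit`; element `separation` marks the fallback.
#' @export
fit_breeding_success <- function(successes, failures, predictor,
                                 predictor_name = "chick_beg_rate",
                                 degrees = 1:3) {
  if (any(successes + failures < 1)) {
    stop("every plot needs at least one breeding attempt", call. = FALSE)
  }
  y <- cbind(successes, failures)
  z <- standardize(predictor)
  fit <- suppressWarnings(
    select_polynomial(y, z, binomial(link = "logit"), degrees,
                      response_name = "breeding_success",
                      predictor_name = predictor_name))
  fit$separation <- FALSE
  p <- fitted(fit$glm)
  if (any(p < 1e-8 | p > 1 - 1e-8) ||
      any(abs(fit$coefficients$estimate) > 10)) {
    y2 <- cbind(successes + 0.5, failures + 0.5)
    fit <- suppressWarnings(
      select_polynomial(y2, z, binomial(link = "logit"), degrees,
                        response_name = "breeding_success",
                        predictor_name = predictor_name))
    fit$separation <- TRUE
    warning("separation detected; refit with 0.5 successes/failures added per plot")
  }
  fit
}

#' Autonomous acoustic breeding-success metric
#'
#' Per-plot chick call rate divided by adult call rate: an entirely
#' acoustic analogue of breeding success (chick abundance over breeding
#' pair abundance). Both adult call types are supported as denominator.
#'
#' @param chick_rate mean nightly chick call seconds per plot.
#' @param adult_rate mean nightly adult call seconds per plot (purr or
#'   chat).
#' @return the ratio; `NA` with a warning where `adult_rate` is 0 or
#'   missing.
#' @export
acoustic_breeding_success <- function(chick_rate, adult_rate) {
  out <- rep(NA_real_, length(chick_rate))
  ok <- !is.na(adult_rate) & adult_rate > 0
  out[ok] <- chick_rate[ok] / adult_rate[ok]
  if (any(!ok)) {
    warning(sum(!ok), " plot(s) with zero or missing adult call rate; ratio is missing there")
  }
  out
}

#' Pearson correlation with df and p
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list: `r`, `df` (n - 2), `p` (two-sided).
#' @export
correlate <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value)
}
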