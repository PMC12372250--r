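#' Log-linear risk model linking classifier score to time to 50% MAKE risk
#'
#' The model is `log10(days to 50% risk of MAKE) = intercept + slope * score`.
#' Under the linear risk-accrual assumption, a cohort at a given score
#' accumulates 50 events per 100 subjects over that time, which converts a
#' time to 50% risk into an incidence rate per 100 person-years.
#'
#' @param intercept Intercept `a` on the log10-days scale.
#' @param slope Slope `b` per unit of classifier score (negative: higher
#'   score, shorter time to risk).
#' @param days_per_year Calendar convention used to convert days to
#'   person-years (default 365.25).
#' @return An object of class `risk_model`.
#' @seealso [published_risk_model()] for the reported coefficients.
#' @export
risk_model <- function(intercept, slope, days_per_year = 365.25) {
  stopifnot(is.finite(intercept), is.finite(slope), days_per_year > 0)
  structure(list(intercept = unname(intercept), slope = unname(slope),
                 days_per_year = days_per_year, log_base = 10),
            class = "risk_model")
}

#' The published risk-model coefficients
#'
#' Returns the reported log-linear association
#' `log10(days to 50% risk) = 4.1446 - 0.9498 * score` as a [risk_model()].
#'
#' @inheritParams risk_model
#' @export
published_risk_model <- function(days_per_year = 365.25) {
  risk_model(4.1446, -0.9498, days_per_year = days_per_year)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> log10(days to 50% risk) = ",
      format(x$intercept), " + (", format(x$slope), ") * score\n", sep = "")
  invisible(x)
}

#' @export
tidy.risk_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    est <- summary(x$fit)$coefficients
    tibble::tibble(term = c("intercept", "slope"),
                   estimate = unname(est[, 1]),
                   std.error = unname(est[, 2]),
                   statistic = unname(est[, 3]),
                   p.value = unname(est[, 4]))
  } else {
    tibble::tibble(term = c("intercept", "slope"),
                   estimate = c(x$intercept, x$slope))
  }
}

#' @export
glance.risk_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    s <- summary(x$fit)
    tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                   nobs = length(s$residuals))
  } else {
    tibble::tibble(r.squared = NA_real_, sigma = NA_real_, nobs = NA_integer_)
  }
}

#' Predicted days to 50% risk of MAKE
#'
#' @param score Classifier score(s).
#' @param model A [risk_model()].
#' @return `10^(intercept + slope * score)` in days; strictly decreasing in
#'   score for negative slope.
#' @examples
#' days_to_half_risk(0.565, published_risk_model())  # ~4055 days
#' @export
days_to_half_risk <- function(score, model = published_risk_model()) {
  stopifnot(inherits(model, "risk_model"))
  10^(model$intercept + model$slope * score)
}

#' Incidence rate of MAKE per 100 person-years at a given score
#'
#' Converts the time to 50% risk into an incidence rate: 50 events per 100
#' subjects accrued over `t50` years gives `50 / t50_years` events per 100
#' person-years.
#'
#' @inheritParams days_to_half_risk
#' @return Incidence rate(s) per 100 person-years.
#' @examples
#' round(incidence_rate(0.565), 1)  # 4.5
#' round(incidence_rate(0.039), 2)  # 1.43
#' @export
incidence_rate <- function(score, model = published_risk_model()) {
  50 / (days_to_half_risk(score, model) / model$days_per_year)
}

#' Relative risk reduction between two scores
#'
#' @param score_before,score_after Scores before and after intervention.
#' @inheritParams days_to_half_risk
#' @return Percentage reduction `100 * (1 - rate_after / rate_before)`;
#'   zero when the scores are equal.
#' @export
relative_risk_reduction <- function(score_before, score_after,
                                    model = published_risk_model()) {
  100 * (1 - incidence_rate(score_after, model) / incidence_rate(score_before, model))
}

#' Empirical time to 50% risk via the 100-nearest-neighbour estimator
#'
#' For each target score, the 100 subjects with the closest scores are
#' selected — the 50 nearest with scores strictly above the target and the
#' 50 nearest at or below (when one side is exhausted near the extremes, the
#' 100 nearest overall are used). The person-time of the window divided by
#' its event count gives the average time until MAKE; halving it, under
#' linear risk accrual, gives the time at which 50% of a cohort at that
#' score is expected to have had an event.
#'
#' @param target_score Numeric vector of scores at which to estimate.
#' @param scores Cohort classifier scores (length >= 100).
#' @param outcomes Tibble with columns `followup_days` and `event`
#'   (logical or 0/1), row-aligned with `scores`.
#' @return Numeric vector of estimated days to 50% risk, one per target.
#'   A window with zero events is an error (undefined estimate).
#' @export
time_to_half_risk_empirical <- function(target_score, scores, outcomes) {
  stopifnot(is.data.frame(outcomes),
            all(c("followup_days", "event") %in% names(outcomes)),
            length(scores) == nrow(outcomes))
  n <- length(scores)
  if (n < 100L) abort("the nearest-neighbour estimator needs a cohort of at least 100 subjects")
  if (any(outcomes$followup_days < 0)) abort("negative follow-up time")
  followup <- outcomes$followup_days
  event <- as.logical(outcomes$event)
  vapply(target_score, function(target) {
    idx <- neighbour_window(target, scores)
    n_events <- sum(event[idx])
    if (n_events == 0L) {
      abort(paste0("no events among the 100 nearest neighbours of score ",
                   format(target), "; time to 50% risk is undefined there"))
    }
    (sum(followup[idx]) / n_events) / 2
  }, numeric(1))
}

# internal: indices of the 100-subject window around a target score.
# Distance ties are broken by original (patient) order via stable sorting.
neighbour_window <- function(target, scores) {
  below <- which(scores <= target)
  above <- which(scores > target)
  if (length(below) >= 50L && length(above) >= 50L) {
    bi <- below[order(target - scores[below])][1:50]
    ai <- above[order(scores[above] - target)][1:50]
    c(bi, ai)
  } else {
    order(abs(scores - target))[1:100]
  }
}

#' Fit the log-linear risk regression
#'
#' Ordinary least squares of `log10(t50_days)` on `score`.
#'
#' @param points Data frame with columns `score` and `t50_days` (> 0).
#' @param days_per_year Calendar convention carried into the returned model.
#' @return A [risk_model()] carrying the fitted `lm` in `$fit` (so `tidy()`
#'   and `glance()` report standard errors and fit quality).
#' @examples
#' pts <- tibble::tibble(score = c(0, 1), t50_days = 10^c(4.1446, 4.1446 - 0.9498))
#' tidy(fit_risk_regression(pts))
#' @export
fit_risk_regression <- function(points, days_per_year = 365.25) {
  stopifnot(is.data.frame(points), all(c("score", "t50_days") %in% names(points)))
  if (any(points$t50_days <= 0)) abort("all t50_days must be positive")
  if (length(unique(points$score)) < 2L) {
    abort("risk regression needs at least two distinct scores")
  }
  fit <- lm(log10(t50_days) ~ score, data = points)
  out <- risk_model(coef(fit)[[1]], coef(fit)[[2]], days_per_year = days_per_year)
  out$fit <- fit
  out
}

#' Estimate the empirical score-to-risk curve over a target grid
#'
#' Convenience wrapper applying [time_to_half_risk_empirical()] over a grid
#' of target scores (defaulting to interior quantiles of the observed
#' scores), dropping targets whose window contains no events.
#'
#' @inheritParams time_to_half_risk_empirical
#' @param targets Target scores; default an evenly spaced quantile grid.
#' @param n_targets Grid size when `targets` is not given.
#' @return Tibble with columns `score`, `t50_days`.
#' @export
estimate_risk_curve <- function(scores, outcomes, targets = NULL, n_targets = 50L) {
  if (is.null(targets)) {
    targets <- unname(quantile(scores, probs = seq(0.05, 0.95, length.out = n_targets)))
  }
  t50 <- vapply(targets, function(s) {
    tryCatch(time_to_half_risk_empirical(s, scores, outcomes),
             error = function(e) NA_real_)
  }, numeric(1))
  keep <- is.finite(t50)
  if (!all(keep)) {
    warn(paste0(sum(!keep), " target score(s) dropped: no events in their window"))
  }
  tibble::tibble(score = targets[keep], t50_days = t50[keep])
}
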