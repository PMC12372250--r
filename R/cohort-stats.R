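#' Stratify a cohort into score tertiles
#'
#' Cut points are the 1/3 and 2/3 empirical quantiles of the scores; values
#' tied with a cut point go to the lower stratum, so the degenerate
#' all-equal case puts everyone in the low stratum.
#'
#' @param scores Numeric scores, `n >= 3`.
#' @param patient_id Optional patient ids (default `"1"`, `"2"`, ...).
#' @return A tibble with columns `patient_id`, `score`, `tertile`
#'   (factor low / intermediate / high), with the cut points in
#'   `attr(, "cut_points")`.
#' @export
tertile_stratify <- function(scores, patient_id = NULL) {
  if (length(scores) < 3L) abort("tertile stratification needs at least 3 scores")
  if (is.null(patient_id)) patient_id <- as.character(seq_along(scores))
  cuts <- unname(quantile(scores, c(1, 2) / 3))
  tertile <- factor(
    ifelse(scores <= cuts[1], "low", ifelse(scores <= cuts[2], "intermediate", "high")),
    levels = c("low", "intermediate", "high")
  )
  out <- tibble::tibble(patient_id = as.character(patient_id),
                        score = scores, tertile = tertile)
  attr(out, "cut_points") <- cuts
  out
}

#' Hazard ratio of the highest versus lowest score tertile
#'
#' Fits a Cox proportional-hazards model with a single binary covariate
#' (high vs low tertile, intermediate excluded; Breslow tie handling) and
#' reports the hazard ratio with its Wald 95% confidence interval.
#'
#' @param strata Output of [tertile_stratify()].
#' @param outcomes Tibble with `patient_id`, `followup_days`, `event`.
#' @return A one-row tibble: `hazard_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `n_high`, `n_low`, `events_high`, `events_low`.
#' @export
hazard_ratio_high_vs_low <- function(strata, outcomes) {
  stopifnot(is.data.frame(strata), all(c("patient_id", "tertile") %in% names(strata)),
            all(c("patient_id", "followup_days", "event") %in% names(outcomes)))
  d <- dplyr::inner_join(strata, outcomes, by = "patient_id") |>
    dplyr::filter(.data$tertile %in% c("low", "high")) |>
    dplyr::mutate(high = as.integer(.data$tertile == "high"),
                  event = as.integer(as.logical(.data$event)))
  for (g in c("low", "high")) {
    if (sum(d$event[d$tertile == g]) == 0L) {
      abort(paste0("no events in the ", g, " tertile; hazard ratio is undefined"))
    }
  }
  fit <- survival::coxph(survival::Surv(followup_days, event) ~ high,
                         data = d, ties = "breslow")
  s <- summary(fit)
  tibble::tibble(
    hazard_ratio = unname(s$coefficients[1, "exp(coef)"]),
    ci_low = unname(s$conf.int[1, "lower .95"]),
    ci_high = unname(s$conf.int[1, "upper .95"]),
    p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
    n_high = sum(d$high == 1L), n_low = sum(d$high == 0L),
    events_high = sum(d$event[d$high == 1L]),
    events_low = sum(d$event[d$high == 0L])
  )
}

#' Paired Wilcoxon signed-rank test on before/after scores
#'
#' Zero differences are dropped; the exact signed-rank distribution is used
#' for up to 25 informative pairs and the normal approximation with
#' continuity correction beyond that. If every difference is zero the result
#' is flagged degenerate rather than erroring.
#'
#' @param before,after Paired numeric vectors (same patients, same order).
#' @param alternative Passed to [stats::wilcox.test()]; default two-sided.
#' @return A one-row tibble: `statistic`, `p_value`, `n_pairs`, `n_nonzero`,
#'   `method`, `degenerate`.
#' @export
paired_wilcoxon <- function(before, after, alternative = "two.sided") {
  stopifnot(length(before) == length(after))
  diffs <- after - before
  nz <- diffs[diffs != 0]
  if (length(nz) == 0L) {
    warn("all paired differences are zero; Wilcoxon statistic is degenerate")
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n_pairs = length(diffs), n_nonzero = 0L,
                          method = "degenerate", degenerate = TRUE))
  }
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    wilcox.test(nz, alternative = alternative, mu = 0,
                exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_pairs = length(diffs), n_nonzero = length(nz),
    method = if (exact) "exact" else "normal approximation",
    degenerate = FALSE
  )
}

#' Spearman association between baseline score and score change
#'
#' Rank correlation with average ranks for ties. With the score change
#' expressed as `after - before`, a negative rho means patients with higher
#' baseline scores achieve larger absolute score reductions.
#'
#' @param baseline_scores,deltas Equal-length numeric vectors, `n >= 3`.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_association <- function(baseline_scores, deltas) {
  stopifnot(length(baseline_scores) == length(deltas))
  if (length(deltas) < 3L) abort("Spearman association needs at least 3 pairs")
  if (var(baseline_scores) == 0 || var(deltas) == 0) {
    abort("Spearman correlation is undefined for a constant input vector")
  }
  ct <- suppressWarnings(
    cor.test(baseline_scores, deltas, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(deltas))
}
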