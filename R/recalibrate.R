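#' Model-predicted effect of an intervention on time to 50% MAKE risk
#'
#' Applies the fold-change table to every profile, rescores, converts scores
#' before and after to times to 50% risk, and summarises the per-patient
#' percentage change `100 * (t50_after - t50_before) / t50_before` across
#' the cohort (median by default; positive = benefit, longer time to risk).
#'
#' @param profiles Wide, imputed profile table (non-empty).
#' @param table A [fold_change_table()].
#' @param model A [classifier_model()].
#' @param risk A [risk_model()].
#' @param summary Cohort summary: `"median"` (default) or `"mean"`.
#' @return A single percentage.
#' @export
predicted_effect <- function(profiles, table, model, risk = published_risk_model(),
                             summary = c("median", "mean")) {
  summary <- match.arg(summary)
  profiles <- as_peptide_profiles(profiles)
  if (nrow(profiles) == 0L) abort("cannot compute a predicted effect on an empty cohort")
  before <- score_cohort(profiles, model)$score
  after <- score_cohort(apply_fold_changes(profiles, table), model)$score
  pct <- 100 * (10^(risk$slope * (after - before)) - 1)
  if (summary == "median") median(pct) else mean(pct)
}

#' Correction factor from observed and predicted effects
#'
#' The ratio of the trial-observed percentage change in time to MAKE to the
#' model-predicted percentage change in time to 50% MAKE risk.
#'
#' @param observed_pct Trial-observed percentage change (positive = benefit).
#' @param predicted_pct Model-predicted percentage change; must be nonzero.
#' @return `observed_pct / predicted_pct`.
#' @export
correction_factor <- function(observed_pct, predicted_pct) {
  stopifnot(is.finite(observed_pct), length(predicted_pct) == 1L)
  if (!is.finite(predicted_pct) || predicted_pct == 0) {
    abort(paste0(
      "predicted effect is ", format(predicted_pct), "; the correction factor ",
      "observed/predicted is undefined. The fold-change table has no effect on ",
      "the classifier score (identity or off-classifier table) - supply a table ",
      "that perturbs classifier peptides."
    ))
  }
  observed_pct / predicted_pct
}

#' Rescale a fold-change table by a correction factor
#'
#' Adjusted fold change = `fold_change ^ r`, i.e. every log fold change is
#' scaled by `r`. This preserves positivity, commutes with multiplicative
#' combination of interventions, and has exact identity (`r = 1`) and null
#' treatment (`r = 0`) limits.
#'
#' @param table A [fold_change_table()].
#' @param r Finite scaling exponent.
#' @return A calibrated `fold_change_table` (same intervention name).
#' @export
recalibrate_fold_changes <- function(table, r) {
  stopifnot(inherits(table, "fold_change_table"), is.finite(r))
  fold_change_table(table$fold_changes^r, table$intervention, calibrated = TRUE)
}

#' Calibrate an intervention's fold changes to a trial-observed effect
#'
#' Rescales the table so the model-predicted percentage change in time to
#' 50% MAKE risk matches the effect observed in the intervention's
#' randomized trial. In single-pass mode (`max_iter = 1`, the default) one
#' correction factor `r = observed / predicted` is computed and applied;
#' because the predicted effect is nonlinear in `r`, this does not generally
#' land exactly on the observed value. Iterative mode (`max_iter > 1`)
#' repeats correction until `|predicted - observed| <= tolerance`.
#'
#' @inheritParams predicted_effect
#' @param observed_pct Trial-observed percentage change in time to MAKE.
#' @param tolerance Convergence tolerance in percentage points.
#' @param max_iter Maximum number of correction passes (1 = single-pass).
#' @return A list with `table` (calibrated [fold_change_table()]) and
#'   `record`, a one-row tibble with `intervention`, `predicted_pct` (before
#'   calibration), `observed_pct`, `correction_factor` (cumulative exponent
#'   applied to the raw table), `achieved_pct` (predicted effect of the
#'   calibrated table), `iterations`, `converged`. Non-convergence is a
#'   warning, not an error.
#' @export
calibrate_intervention <- function(profiles, table, model,
                                   risk = published_risk_model(),
                                   observed_pct, tolerance = 0.5, max_iter = 1L,
                                   summary = c("median", "mean")) {
  summary <- match.arg(summary)
  stopifnot(is.finite(observed_pct), max_iter >= 1L, tolerance >= 0)
  initial <- predicted_effect(profiles, table, model, risk, summary)
  r_total <- 1
  current <- table
  pred <- initial
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    r_total <- r_total * correction_factor(observed_pct, pred)
    current <- recalibrate_fold_changes(table, r_total)
    pred <- predicted_effect(profiles, current, model, risk, summary)
    if (abs(pred - observed_pct) <= tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max_iter > 1L) {
    warn(paste0("calibration of '", table$intervention, "' did not reach ",
                tolerance, " percentage points after ", iter, " iterations ",
                "(achieved ", format(pred, digits = 4), "%, observed ",
                format(observed_pct, digits = 4), "%)"))
  }
  list(
    table = current,
    record = tibble::tibble(
      intervention = table$intervention,
      predicted_pct = initial,
      observed_pct = observed_pct,
      correction_factor = r_total,
      achieved_pct = pred,
      iterations = iter,
      converged = converged
    )
  )
}
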