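#' Specification of a synthetic CKD cohort
#'
#' Bundles the parameters of the synthetic-data generator. The defaults
#' emulate the study conditions of the analysis this package implements: a
#' 935-patient cohort, a 273-peptide classifier, baseline scores with median
#' 0.565, administrative follow-up with median 1.5 years, and event times
#' generated from the published log-linear risk model.
#'
#' @param n_patients Number of patients.
#' @param n_peptides Size of the peptide universe (ids `pep000001`, ...).
#' @param n_classifier_peptides Number of classifier peptides
#'   (`<= n_peptides`).
#' @param missing_rate Probability that any single intensity is missing
#'   (independent per cell), in `[0, 1]`.
#' @param score_location Target median of the baseline score distribution.
#' @param score_scale Target standard deviation of baseline scores. The
#'   default 0.45 matches an interquartile range of roughly 0.19-0.81.
#' @param followup_max_years Administrative censoring horizon; follow-up is
#'   drawn uniformly on `(0, followup_max_years)`, so the default 3 gives a
#'   median follow-up of 1.5 years.
#' @param risk_intercept,risk_slope Generative truth of the log-linear
#'   time-to-50%-risk model used for event times (defaults: the published
#'   coefficients 4.1446 and -0.9498).
#' @param seed Integer seed; identical spec + seed reproduces every output
#'   bit-identically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 935L, n_peptides = 2000L,
                        n_classifier_peptides = 273L, missing_rate = 0.3,
                        score_location = 0.565, score_scale = 0.45,
                        followup_max_years = 3, risk_intercept = 4.1446,
                        risk_slope = -0.9498, seed = 1L) {
  stopifnot(n_patients >= 1, n_peptides >= 1, n_classifier_peptides >= 1)
  if (n_classifier_peptides > n_peptides) {
    abort("n_classifier_peptides must not exceed n_peptides")
  }
  if (missing_rate < 0 || missing_rate > 1) abort("missing_rate must be in [0, 1]")
  stopifnot(score_scale > 0, followup_max_years > 0,
            is.finite(risk_intercept), is.finite(risk_slope))
  structure(
    list(n_patients = as.integer(n_patients), n_peptides = as.integer(n_peptides),
         n_classifier_peptides = as.integer(n_classifier_peptides),
         missing_rate = missing_rate, score_location = score_location,
         score_scale = score_scale, followup_max_years = followup_max_years,
         risk_intercept = risk_intercept, risk_slope = risk_slope,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_patients, " patients, ", x$n_peptides, " peptides (",
      x$n_classifier_peptides, " in classifier), missing rate ", x$missing_rate,
      ",\n  score ~ median ", x$score_location, " sd ", x$score_scale,
      ", follow-up <= ", x$followup_max_years, " y, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

peptide_universe <- function(spec) sprintf("pep%06d", seq_len(spec$n_peptides))

#' Generate a synthetic linear classifier
#'
#' Draws a classifier over a random subset of the peptide universe with
#' signed weights (both up- and down-regulated markers when more than one
#' peptide) and zero bias. Weight magnitudes are L1-normalised (sum of
#' absolute weights = 10) so that fold-change effect sizes have a stable
#' scale across seeds.
#'
#' @param spec A [cohort_spec()].
#' @return A [classifier_model()] named `"synthetic-ckd273"`.
#' @export
generate_classifier <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, 1L))
  ids <- sort(sample(peptide_universe(spec), spec$n_classifier_peptides))
  signs <- sample(c(-1, 1), length(ids), replace = TRUE)
  if (length(ids) > 1L && length(unique(signs)) == 1L) signs[1] <- -signs[1]
  mag <- abs(rnorm(length(ids))) + 0.1
  w <- signs * mag / sum(mag) * 10
  classifier_model(setNames(w, ids), bias = 0, transform = "log1p",
                   name = "synthetic-ckd273")
}

#' Generate synthetic peptide profiles with a calibrated score distribution
#'
#' Intensities are log-normal with peptide-specific baselines; a latent
#' per-patient severity raises up-regulated classifier markers and lowers
#' down-regulated ones, producing the score spread; each cell is then set
#' missing independently with probability `missing_rate`. The
#' classifier-marker log-intensities are then scaled by an exponent solved so
#' the induced score standard deviation matches `score_scale` (missingness
#' would otherwise inflate the spread), and finally shifted multiplicatively
#' (up-markers by `alpha`, down-markers by `1/alpha`) with `alpha` solved so
#' the induced score distribution has median `score_location`.
#'
#' @param spec A [cohort_spec()].
#' @param classifier The matching [generate_classifier()] output.
#' @return A list with `profiles` (wide tibble, `NA` = missing) and
#'   `true_scores` (tibble `patient_id`, `score`: classifier scores of the
#'   zero-imputed generated profiles).
#' @export
generate_profiles <- function(spec, classifier) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(classifier, "classifier_model"))
  if (!all(names(classifier$weights) %in% peptide_universe(spec))) {
    abort("classifier peptides must lie within the spec's peptide universe")
  }
  set.seed(derive_seed(spec$seed, 2L))
  n <- spec$n_patients
  p <- spec$n_peptides
  ids <- peptide_universe(spec)
  patient_id <- sprintf("pt%04d", seq_len(n))

  mu <- rnorm(p, mean = log(100), sd = 1)
  severity <- rnorm(n)
  noise <- matrix(rnorm(n * p, sd = 0.8), n, p)
  cls <- names(classifier$weights)
  loading <- setNames(rep(0, p), ids)
  loading[cls] <- sign(classifier$weights) * 0.3
  miss <- matrix(runif(n * p) < spec$missing_rate, n, p)
  logint <- sweep(noise, 2L, mu, `+`) + severity %o% loading
  cls_col <- match(cls, ids)

  # theta scales classifier-marker log-intensities (controls the score
  # spread, which missingness otherwise inflates); alpha multiplies
  # up-markers and divides down-markers (controls the score median).
  build <- function(theta, alpha) {
    m <- exp(logint)
    m[, cls_col] <- exp(theta * logint[, cls_col, drop = FALSE] +
                          rep(sign(classifier$weights) * log(alpha),
                              each = n))
    m[miss] <- NA_real_
    dimnames(m) <- list(patient_id, ids)
    m
  }
  score_of <- function(m) score_matrix(ifelse(is.na(m), 0, m), classifier)
  sd_at <- function(theta) stats::sd(score_of(build(theta, 1)))

  theta <- 1
  s1 <- sd_at(1)
  if (is.finite(s1) && s1 > 0) {
    if (sd_at(1e-4) >= spec$score_scale) {
      theta <- 1e-4  # indicator noise floor: take the closest achievable spread
    } else if (s1 > spec$score_scale) {
      theta <- uniroot(function(t) sd_at(t) - spec$score_scale,
                       c(1e-4, 1), tol = 1e-6)$root
    } else if (sd_at(4) > spec$score_scale) {
      theta <- uniroot(function(t) sd_at(t) - spec$score_scale,
                       c(1, 4), tol = 1e-6)$root
    } else {
      theta <- 4
    }
  }
  # monotone shift of classifier markers so the median score hits
  # score_location (g is nondecreasing in alpha)
  g <- function(log_alpha) median(score_of(build(theta, exp(log_alpha))))
  lo <- -12; hi <- 12
  alpha <- if (g(lo) < spec$score_location && g(hi) > spec$score_location) {
    exp(uniroot(function(la) g(la) - spec$score_location, c(lo, hi),
                tol = 1e-8)$root)
  } else {
    1  # degenerate (e.g. all-missing) profiles cannot be shifted
  }
  m <- build(theta, alpha)
  list(
    profiles = matrix_to_profiles(m),
    true_scores = tibble::tibble(patient_id = patient_id, score = score_of(m))
  )
}

#' Generate synthetic follow-up outcomes from classifier scores
#'
#' Event times are exponential with mean `2 * 10^(a + b * score)` days: under
#' linear risk accrual the time to 50% cumulative risk is half the mean
#' time to event. Administrative censoring times are uniform on
#' `(0, followup_max_years)`; the event indicator marks event before censoring.
#'
#' @param true_scores Tibble with `patient_id` and `score` (from
#'   [generate_profiles()]), or a bare numeric vector of scores.
#' @param spec A [cohort_spec()] supplying `(a, b)` and the follow-up horizon.
#' @return A tibble with `patient_id`, `followup_days`, `event` (logical).
#' @export
generate_outcomes <- function(true_scores, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.numeric(true_scores)) {
    true_scores <- tibble::tibble(
      patient_id = sprintf("pt%04d", seq_along(true_scores)),
      score = true_scores
    )
  }
  set.seed(derive_seed(spec$seed, 3L))
  t50 <- 10^(spec$risk_intercept + spec$risk_slope * true_scores$score)
  event_time <- rexp(nrow(true_scores), rate = 1 / (2 * t50))
  censor <- runif(nrow(true_scores), 0, spec$followup_max_years * 365.25)
  tibble::tibble(
    patient_id = true_scores$patient_id,
    followup_days = pmin(event_time, censor),
    event = event_time <= censor
  )
}

#' Generate synthetic per-intervention fold-change tables
#'
#' Each table covers a random subset of the classifier peptides plus some
#' non-classifier peptides. Log fold changes are normal; for classifier
#' peptides they are biased toward reversing the sign of the peptide's
#' weight (so treatment tends to lower the score), scaled per intervention
#' by a random potency factor. `benefit_bias = 0` gives unbiased tables.
#'
#' @param classifier A [classifier_model()].
#' @param k_interventions Number of interventions (`>= 1`).
#' @param spec A [cohort_spec()] (peptide universe and seed).
#' @param intervention_names Optional names; defaults to the six intervention
#'   classes of the study (MRA, SGLT2i, GLP1RA, ARB, olive oil, exercise)
#'   when `k_interventions == 6`.
#' @param subset_frac Probability that a classifier peptide is covered by a
#'   given table.
#' @param benefit_bias Mean magnitude of the weight-reversing log fold
#'   change component.
#' @param log_fc_sd Standard deviation of log fold changes.
#' @param n_nonclassifier Non-classifier peptides included per table.
#' @return A named list of `k_interventions` [fold_change_table()]s.
#' @export
generate_fold_change_tables <- function(classifier, k_interventions = 6L, spec,
                                        intervention_names = NULL,
                                        subset_frac = 0.35, benefit_bias = 0.05,
                                        log_fc_sd = 0.2, n_nonclassifier = 50L) {
  stopifnot(inherits(classifier, "classifier_model"), inherits(spec, "cohort_spec"),
            k_interventions >= 1L)
  if (is.null(intervention_names)) {
    intervention_names <- if (k_interventions == 6L) {
      c("MRA", "SGLT2i", "GLP1RA", "ARB", "OliveOil", "Exercise")
    } else {
      sprintf("intervention%02d", seq_len(k_interventions))
    }
  }
  stopifnot(length(intervention_names) == k_interventions,
            !anyDuplicated(intervention_names))
  set.seed(derive_seed(spec$seed, 4L))
  universe <- peptide_universe(spec)
  cls <- names(classifier$weights)
  other <- setdiff(universe, cls)
  tables <- lapply(seq_len(k_interventions), function(i) {
    covered <- cls[runif(length(cls)) < subset_frac]
    extra <- sample(other, min(n_nonclassifier, length(other)))
    potency <- runif(1, 0.5, 1.5)
    log_fc <- c(
      -sign(classifier$weights[covered]) * benefit_bias * potency +
        rnorm(length(covered), sd = log_fc_sd),
      rnorm(length(extra), sd = log_fc_sd)
    )
    fold_change_table(setNames(exp(log_fc), c(covered, extra)),
                      intervention_names[i])
  })
  setNames(tables, intervention_names)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_classifier()],
#' [generate_profiles()], [generate_outcomes()] and
#' [generate_fold_change_tables()] under one spec.
#'
#' @param spec A [cohort_spec()].
#' @param k_interventions Number of fold-change tables to generate.
#' @param ... Passed on to [generate_fold_change_tables()].
#' @return An object of class `synthetic_cohort`: list with `spec`,
#'   `classifier`, `profiles`, `true_scores`, `outcomes`, `fold_changes`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 150, n_peptides = 300,
#'                                    n_classifier_peptides = 40, seed = 7))
#' median(coh$true_scores$score)
#' @export
generate_cohort <- function(spec = cohort_spec(), k_interventions = 6L, ...) {
  classifier <- generate_classifier(spec)
  prof <- generate_profiles(spec, classifier)
  outcomes <- generate_outcomes(prof$true_scores, spec)
  tables <- generate_fold_change_tables(classifier, k_interventions, spec, ...)
  structure(
    list(spec = spec, classifier = classifier, profiles = prof$profiles,
         true_scores = prof$true_scores, outcomes = outcomes,
         fold_changes = tables),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$profiles), " patients, ",
      ncol(x$profiles) - 1L, " peptides, ", length(x$fold_changes),
      " interventions\n  median score ",
      format(median(x$true_scores$score), digits = 3), ", ",
      sum(x$outcomes$event), " events\n", sep = "")
  invisible(x)
}
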