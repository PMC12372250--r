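small_spec <- function(seed = 1, ...) {
  cohort_spec(n_patients = 200, n_peptides = 300, n_classifier_peptides = 50,
              seed = seed, ...)
}

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_classifier_peptides = 10, n_peptides = 5), "exceed")
  expect_error(cohort_spec(missing_rate = 1.2), "missing_rate")
  expect_error(cohort_spec(n_classifier_peptides = 0), "n_classifier_peptides")
  expect_s3_class(cohort_spec(), "cohort_spec")
})

test_that("identical spec and seed reproduce every output bit-identically", {
  a <- generate_cohort(small_spec(5))
  b <- generate_cohort(small_spec(5))
  expect_identical(a$classifier$weights, b$classifier$weights)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$true_scores, b$true_scores)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(lapply(a$fold_changes, `[[`, "fold_changes"),
                   lapply(b$fold_changes, `[[`, "fold_changes"))
  c <- generate_cohort(small_spec(6))
  expect_false(identical(a$profiles, c$profiles))
})

test_that("generated classifiers have the requested support and mixed signs", {
  spec <- small_spec(2)
  m <- generate_classifier(spec)
  expect_length(m$weights, 50)
  expect_true(any(m$weights > 0) && any(m$weights < 0))
  expect_true(all(names(m$weights) %in% sprintf("pep%06d", 1:300)))
  m273 <- generate_classifier(cohort_spec(seed = 2))
  expect_length(m273$weights, 273)
  # scoring is monotone increasing in a single positive-weight peptide
  m1 <- generate_classifier(cohort_spec(n_peptides = 10, n_classifier_peptides = 1,
                                        seed = 3))
  w <- abs(m1$weights)
  m1$weights[] <- w
  pep <- names(w)
  lo <- score_profile(setNames(1, pep), m1)
  hi <- score_profile(setNames(100, pep), m1)
  expect_lt(lo, hi)
})

test_that("missingness boundaries behave as specified", {
  none <- generate_profiles(small_spec(4, missing_rate = 0),
                            generate_classifier(small_spec(4, missing_rate = 0)))
  expect_false(anyNA(none$profiles))
  spec1 <- small_spec(4, missing_rate = 1)
  all_miss <- generate_profiles(spec1, generate_classifier(spec1))
  expect_true(all(is.na(as.matrix(all_miss$profiles[-1]))))
  # every score is the transform of the all-zero profile (bias = 0 here)
  expect_equal(unique(all_miss$true_scores$score), 0)
})

test_that("score distribution is calibrated to the requested median and scale", {
  for (seed in c(1, 9, 33)) {
    spec <- cohort_spec(n_patients = 935, n_peptides = 600,
                        n_classifier_peptides = 100, seed = seed)
    prof <- generate_profiles(spec, generate_classifier(spec))
    expect_lt(abs(median(prof$true_scores$score) - 0.565), 0.1)
    expect_lt(abs(stats::sd(prof$true_scores$score) - 0.45), 0.15)
  }
})

test_that("true scores equal the classifier scores of the generated profiles", {
  spec <- small_spec(7)
  cls <- generate_classifier(spec)
  prof <- generate_profiles(spec, cls)
  rescored <- score_cohort(impute_missing_as_zero(prof$profiles), cls)
  expect_equal(rescored$score, prof$true_scores$score)
})

test_that("outcome generation follows the exponential two-T50 law", {
  # b = 0: event times i.i.d. exponential with mean 2*10^a days
  spec <- cohort_spec(n_patients = 10000, n_peptides = 1, n_classifier_peptides = 1,
                      risk_intercept = 2.5, risk_slope = 0,
                      followup_max_years = 1e7, seed = 13)
  out <- generate_outcomes(rep(0.5, 10000), spec)
  expect_lt(abs(mean(out$followup_days) / (2 * 10^2.5) - 1), 0.05)
  # followup horizon ~ 0 gives no events
  spec0 <- cohort_spec(followup_max_years = 1e-9, seed = 13)
  out0 <- generate_outcomes(rnorm(500, 0.5, 0.4), spec0)
  expect_equal(sum(out0$event), 0L)
})

test_that("higher scores mean earlier events under a negative slope", {
  spec <- cohort_spec(n_patients = 6000, n_peptides = 1, n_classifier_peptides = 1,
                      followup_max_years = 1e6, seed = 15)
  set.seed(15)
  scores <- rnorm(6000, 0.5, 0.45)
  out <- generate_outcomes(scores, spec)
  tert <- tertile_stratify(scores)
  means <- tapply(out$followup_days, tert$tertile, mean)
  expect_true(means[["low"]] > means[["intermediate"]])
  expect_true(means[["intermediate"]] > means[["high"]])
  # censored version: higher-score half has more observed events
  spec2 <- cohort_spec(n_patients = 6000, n_peptides = 1,
                       n_classifier_peptides = 1, seed = 15)
  out2 <- generate_outcomes(scores, spec2)
  hi <- scores > median(scores)
  expect_gt(mean(out2$event[hi]), mean(out2$event[!hi]))
})

test_that("risk regression on a large uncensored cohort recovers the truth", {
  spec <- cohort_spec(n_patients = 10000, n_peptides = 1, n_classifier_peptides = 1,
                      followup_max_years = 1e6, seed = 29)
  set.seed(29)
  scores <- rnorm(10000, 0.5, 0.45)
  outcomes <- generate_outcomes(scores, spec)
  curve <- estimate_risk_curve(scores, outcomes, n_targets = 40)
  fit <- fit_risk_regression(curve)
  expect_lt(abs(fit$intercept - 4.1446), 0.15)
  expect_lt(abs(fit$slope - (-0.9498)), 0.15)
})

test_that("fold-change tables cover classifier subsets and honour the bias switch", {
  spec <- small_spec(3)
  cls <- generate_classifier(spec)
  tabs <- generate_fold_change_tables(cls, 6, spec)
  expect_length(tabs, 6)
  expect_setequal(names(tabs),
                  c("MRA", "SGLT2i", "GLP1RA", "ARB", "OliveOil", "Exercise"))
  expect_equal(nrow(enumerate_regimens(names(tabs))), 63L)
  for (t in tabs) expect_true(all(t$fold_changes > 0 & is.finite(t$fold_changes)))
  # with zero bias the median log fold change is near zero
  tabs0 <- generate_fold_change_tables(cls, 4, spec, benefit_bias = 0)
  lfc <- unlist(lapply(tabs0, function(t) log(t$fold_changes)))
  expect_lt(abs(median(lfc)), 0.05)
  # beneficial default tables lower the median score
  prof <- impute_missing_as_zero(generate_profiles(spec, cls)$profiles)
  before <- median(score_cohort(prof, cls)$score)
  after <- median(score_cohort(apply_fold_changes(prof, combine_interventions(tabs)),
                               cls)$score)
  expect_lt(after, before)
})
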