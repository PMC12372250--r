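test_that("correction factor is the observed/predicted ratio with a guarded zero", {
  expect_equal(correction_factor(30, 30), 1)
  expect_equal(correction_factor(20, 40), 0.5)
  expect_equal(correction_factor(40, 20), 2)
  expect_error(correction_factor(30, 0), "undefined")
})

test_that("power rescaling acts linearly on log fold changes", {
  t <- fold_change_table(c(p1 = 4, p2 = 0.25, p3 = 1), "t")
  expect_equal(recalibrate_fold_changes(t, 1)$fold_changes, t$fold_changes)
  expect_equal(unname(recalibrate_fold_changes(t, 0)$fold_changes), c(1, 1, 1))
  expect_equal(unname(recalibrate_fold_changes(t, 0.5)$fold_changes["p1"]), 2)
  expect_true(recalibrate_fold_changes(t, 0.5)$calibrated)
  set.seed(8)
  fc <- setNames(exp(rnorm(20)), sprintf("p%d", 1:20))
  tt <- fold_change_table(fc, "r")
  for (r in c(-0.5, 0.3, 2.7)) {
    expect_equal(log(recalibrate_fold_changes(tt, r)$fold_changes), r * log(fc))
  }
})

test_that("predicted effect is zero for identity tables and has its closed form", {
  fx <- random_fixture(13)
  profs <- dplyr::bind_rows(lapply(1:30, function(i) {
    p <- fx$profiles
    p$patient_id <- paste0("pt", i)
    dplyr::mutate(p, dplyr::across(-patient_id, ~ .x * runif(1, 0.5, 2)))
  }))
  ident <- fold_change_table(setNames(rep(1, 5), names(fx$intensities)[1:5]), "id")
  expect_equal(predicted_effect(profs, ident, fx$model), 0)
  expect_error(predicted_effect(profs[0, ], ident, fx$model), "empty")
  # a table shifting every score by exactly delta gives 100*(10^(-b*delta)-1);
  # the identity transform makes the shift exact and uniform across patients
  model_id <- classifier_model(c(p1 = 1), bias = 0, transform = "identity")
  profs3 <- tibble::tibble(patient_id = sprintf("r%d", 1:10), p1 = rep(5, 10))
  tab <- fold_change_table(c(p1 = 0.9), "shift")  # score 5 -> 4.5, delta -0.5
  risk <- published_risk_model()
  expect_equal(predicted_effect(profs3, tab, model_id, risk),
               100 * (10^(-risk$slope * 0.5) - 1))
  # beneficial synthetic table lowers scores, hence positive percentage
  spec <- cohort_spec(n_patients = 120, n_peptides = 200,
                      n_classifier_peptides = 40, missing_rate = 0, seed = 31)
  coh <- generate_cohort(spec, k_interventions = 2)
  prof <- impute_missing_as_zero(coh$profiles)
  expect_gt(predicted_effect(prof, coh$fold_changes[[1]], coh$classifier, risk), 0)
})

test_that("single-pass calibration applies exactly one correction factor", {
  spec <- cohort_spec(n_patients = 100, n_peptides = 150,
                      n_classifier_peptides = 30, missing_rate = 0, seed = 17)
  coh <- generate_cohort(spec, k_interventions = 1)
  prof <- impute_missing_as_zero(coh$profiles)
  tab <- coh$fold_changes[[1]]
  risk <- published_risk_model()
  pred0 <- predicted_effect(prof, tab, coh$classifier, risk)
  # observed equal to predicted: fixed point, table unchanged
  res <- calibrate_intervention(prof, tab, coh$classifier, risk,
                                observed_pct = pred0, max_iter = 1L)
  expect_equal(res$record$correction_factor, 1)
  expect_equal(res$table$fold_changes, tab$fold_changes)
  expect_true(res$record$converged)
  # observed = half the prediction: r = 0.5 and log fold changes halved
  res2 <- calibrate_intervention(prof, tab, coh$classifier, risk,
                                 observed_pct = pred0 / 2, max_iter = 1L)
  expect_equal(res2$record$correction_factor, 0.5)
  expect_equal(log(res2$table$fold_changes), 0.5 * log(tab$fold_changes))
})

test_that("iterative calibration converges to the observed effect on a fixture", {
  spec <- cohort_spec(n_patients = 100, n_peptides = 150,
                      n_classifier_peptides = 30, missing_rate = 0, seed = 17)
  coh <- generate_cohort(spec, k_interventions = 1)
  prof <- impute_missing_as_zero(coh$profiles)
  tab <- coh$fold_changes[[1]]
  risk <- published_risk_model()
  pred0 <- predicted_effect(prof, tab, coh$classifier, risk)
  target <- pred0 * 2.5
  res <- calibrate_intervention(prof, tab, coh$classifier, risk,
                                observed_pct = target, tolerance = 0.5,
                                max_iter = 25L)
  achieved <- predicted_effect(prof, res$table, coh$classifier, risk)
  expect_lte(abs(achieved - target), 0.5)
  expect_true(res$record$converged)
})

test_that("predicted effect is monotone in the calibration exponent for a beneficial table", {
  spec <- cohort_spec(n_patients = 80, n_peptides = 150,
                      n_classifier_peptides = 30, missing_rate = 0, seed = 19)
  coh <- generate_cohort(spec, k_interventions = 1)
  prof <- impute_missing_as_zero(coh$profiles)
  tab <- coh$fold_changes[[1]]
  effects <- vapply(seq(0, 1, by = 0.2), function(r) {
    predicted_effect(prof, recalibrate_fold_changes(tab, r), coh$classifier)
  }, numeric(1))
  expect_equal(effects[1], 0)
  expect_true(all(diff(effects) >= 0))
})

test_that("calibrating an identity table raises the division error", {
  p <- tibble::tibble(patient_id = c("a", "b"), p1 = c(2, 4), p2 = c(1, 3))
  ident <- fold_change_table(c(p1 = 1, p2 = 1), "id")
  expect_error(
    calibrate_intervention(p, ident, tiny_model(), observed_pct = 30),
    "undefined"
  )
})
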