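test_that("tertile stratification cuts at empirical terciles with lower-tie rule", {
  s <- tertile_stratify(c(1, 2, 3))
  expect_equal(as.character(s$tertile), c("low", "intermediate", "high"))
  all_equal <- tertile_stratify(rep(2, 9))
  expect_true(all(all_equal$tertile == "low"))
  expect_error(tertile_stratify(c(1, 2)), "at least 3")
  set.seed(12)
  s935 <- tertile_stratify(rnorm(935))
  counts <- sort(as.integer(table(s935$tertile)))
  expect_equal(sum(counts), 935L)
  expect_equal(counts, c(311L, 312L, 312L))
  cuts <- attr(s935, "cut_points")
  expect_true(all(s935$score[s935$tertile == "low"] <= cuts[1]))
  expect_true(all(s935$score[s935$tertile == "high"] > cuts[2]))
})

test_that("Cox fit matches an independent partial-likelihood maximiser on toy data", {
  # independent oracle: numerically maximise the Breslow partial likelihood
  breslow_loglik <- function(beta, time, status, x) {
    ll <- 0
    for (t in sort(unique(time[status == 1]))) {
      d <- which(time == t & status == 1)
      risk <- which(time >= t)
      ll <- ll + sum(beta * x[d]) -
        length(d) * log(sum(exp(beta * x[risk])))
    }
    ll
  }
  toy_sets <- list(
    list(time = c(2, 4, 1, 3), status = c(1, 1, 1, 1), x = c(1, 1, 0, 0)),
    list(time = c(1, 2, 3, 4, 5, 6), status = c(1, 0, 1, 1, 0, 1),
         x = c(1, 0, 1, 0, 1, 0)),
    list(time = c(2, 2, 4, 5, 7, 8, 9, 10), status = c(1, 1, 0, 1, 1, 0, 1, 0),
         x = c(1, 0, 1, 0, 1, 0, 1, 0))
  )
  for (d in toy_sets) {
    n <- length(d$time)
    strata <- tibble::tibble(
      patient_id = as.character(1:n),
      score = d$x,  # x = 1 marks the high tertile
      tertile = factor(ifelse(d$x == 1, "high", "low"),
                       c("low", "intermediate", "high"))
    )
    outcomes <- tibble::tibble(patient_id = as.character(1:n),
                               followup_days = d$time, event = d$status)
    fit <- hazard_ratio_high_vs_low(strata, outcomes)
    oracle <- stats::optimize(function(b) -breslow_loglik(b, d$time, d$status, d$x),
                              c(-10, 10), tol = 1e-9)$minimum
    expect_equal(log(fit$hazard_ratio), oracle, tolerance = 1e-4)
    expect_true(fit$ci_low <= fit$hazard_ratio && fit$hazard_ratio <= fit$ci_high)
  }
})

test_that("Cox HR is ~1 with CI spanning 1 under identical event patterns", {
  strata <- tibble::tibble(
    patient_id = as.character(1:40), score = rep(c(0, 1), each = 20),
    tertile = factor(rep(c("low", "high"), each = 20),
                     c("low", "intermediate", "high"))
  )
  outcomes <- tibble::tibble(
    patient_id = as.character(1:40),
    followup_days = rep(c(10, 20, 30, 40), 10),
    event = rep(c(1, 0), 20)
  )
  fit <- hazard_ratio_high_vs_low(strata, outcomes)
  expect_equal(fit$hazard_ratio, 1, tolerance = 1e-6)
  expect_lt(fit$ci_low, 1)
  expect_gt(fit$ci_high, 1)
  # stratum without events is named in the error
  outcomes$event[21:40] <- 0
  expect_error(hazard_ratio_high_vs_low(strata, outcomes), "high")
})

test_that("synthetic cohorts show elevated high-vs-low tertile hazard", {
  spec <- cohort_spec(n_patients = 935, n_peptides = 400,
                      n_classifier_peptides = 60, seed = 23)
  coh <- generate_cohort(spec, k_interventions = 1)
  strata <- tertile_stratify(coh$true_scores$score, coh$true_scores$patient_id)
  fit <- hazard_ratio_high_vs_low(strata, coh$outcomes)
  expect_gt(fit$hazard_ratio, 1)
  expect_gt(fit$ci_low, 1)
  expect_lt(fit$p_value, 0.05)
})

test_that("paired Wilcoxon matches exact sign-pattern enumeration for small n", {
  # independent oracle: enumerate all 2^n sign assignments of the ranked
  # absolute differences to get the exact two-sided p-value
  exact_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    mean_v <- n * (n + 1) / 4
    min(1, mean(abs(v_all - mean_v) >= abs(v_obs - mean_v) - 1e-9))
  }
  set.seed(41)
  for (n in c(5, 8, 12)) {
    for (rep in 1:3) {
      before <- rnorm(n)
      after <- before + rnorm(n, mean = -0.5)
      res <- paired_wilcoxon(before, after)
      expect_identical(res$method, "exact")
      expect_equal(res$p_value, exact_p(after - before), tolerance = 1e-12)
    }
  }
  # all differences negative at n=5: extreme one-sided exact p = 1/32
  b <- 1:5
  a <- b - runif(5, 0.1, 0.5)
  res <- paired_wilcoxon(b, a, alternative = "less")
  expect_equal(res$p_value, 1 / 32)
})

test_that("degenerate and large-sample Wilcoxon behaviour", {
  x <- rnorm(10)
  expect_warning(res <- paired_wilcoxon(x, x), "degenerate")
  expect_true(res$degenerate)
  set.seed(4)
  before <- rnorm(400)
  after <- before - abs(rnorm(400, 0.3))
  res2 <- paired_wilcoxon(before, after)
  expect_identical(res2$method, "normal approximation")
  expect_lt(res2$p_value, 1e-4)
})

test_that("Spearman association handles closed-form and null cases", {
  expect_equal(spearman_association(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  base <- runif(50)
  expect_equal(spearman_association(base, -exp(base))$rho, -1)
  set.seed(6)
  null <- spearman_association(rnorm(2000), rnorm(2000))
  expect_lt(abs(null$rho), 0.06)
  expect_error(spearman_association(rep(1, 10), rnorm(10)), "constant")
})
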