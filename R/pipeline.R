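#' Configuration of an end-to-end pipeline run
#'
#' Exactly one input source must be active: a synthetic [cohort_spec()], or
#' file paths to user data (peptide matrix TSV, fold-change TSV, classifier
#' JSON, outcomes CSV).
#'
#' @param synthetic A [cohort_spec()], or `NULL` when reading files.
#' @param paths Named list with elements `profiles`, `fold_changes`,
#'   `classifier` and optionally `outcomes`, or `NULL` when synthetic.
#' @param k_interventions Number of synthetic interventions.
#' @param trial_effects Optional named numeric vector mapping intervention
#'   name to the trial-observed percentage change in time to MAKE; when
#'   given, each table is calibrated before optimisation.
#' @param calibration `"single_pass"` (one correction factor, the default)
#'   or `"iterative"` (fixed-point refinement).
#' @param tolerance Calibration tolerance in percentage points.
#' @param max_iter Iteration cap for iterative calibration.
#' @param risk_source `"published_constants"` (default: intercept 4.1446,
#'   slope -0.9498) or `"refit"` (re-estimate the log-linear model from the
#'   cohort's outcomes via the nearest-neighbour estimator).
#' @param days_per_year Calendar convention for person-year conversion.
#' @param seed Root seed; all pipeline randomness derives from it.
#' @param output_dir Optional directory for [write_report()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = cohort_spec(), paths = NULL,
                       k_interventions = 6L, trial_effects = NULL,
                       calibration = c("single_pass", "iterative"),
                       tolerance = 0.5, max_iter = 25L,
                       risk_source = c("published_constants", "refit"),
                       days_per_year = 365.25, seed = NULL, output_dir = NULL) {
  calibration <- match.arg(calibration)
  risk_source <- match.arg(risk_source)
  if (is.null(synthetic) == is.null(paths)) {
    abort("exactly one of `synthetic` and `paths` must be supplied")
  }
  if (!is.null(paths)) {
    stopifnot(all(c("profiles", "fold_changes", "classifier") %in% names(paths)))
  }
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "cohort_spec"))
    if (!is.null(seed)) synthetic$seed <- as.integer(seed)
    seed <- synthetic$seed
  }
  if (is.null(seed)) seed <- 1L
  if (!is.null(trial_effects)) {
    stopifnot(is.numeric(trial_effects), !is.null(names(trial_effects)))
  }
  structure(
    list(synthetic = synthetic, paths = paths,
         k_interventions = as.integer(k_interventions),
         trial_effects = trial_effects, calibration = calibration,
         tolerance = tolerance, max_iter = as.integer(max_iter),
         risk_source = risk_source, days_per_year = days_per_year,
         seed = as.integer(seed), output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `synthetic` is a
#' mapping of [cohort_spec()] arguments, `paths` a mapping of file paths,
#' `trial_effects` a mapping of intervention name to observed percentage.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configs requires the yaml package")
  }
  doc <- yaml::read_yaml(path)
  args <- doc[setdiff(names(doc), c("synthetic", "paths", "trial_effects"))]
  args$synthetic <- if (!is.null(doc$synthetic)) do.call(cohort_spec, doc$synthetic) else NULL
  args$paths <- doc$paths
  if (!is.null(doc$trial_effects)) args$trial_effects <- unlist(doc$trial_effects)
  do.call(run_config, args)
}

#' Run the full in silico intervention pipeline
#'
#' Stages: load or generate the cohort; impute missing intensities as zero;
#' score baseline profiles; calibrate each intervention's fold changes
#' against its trial-observed effect (when `trial_effects` is configured);
#' enumerate all non-empty regimens and select the per-patient
#' score-minimising one; transform scores before and after into times to
#' 50% MAKE risk and incidence rates per 100 person-years; compute cohort
#' statistics (paired Wilcoxon, Spearman baseline-vs-delta association,
#' tertile hazard ratio when outcomes are available).
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `run_report`: list with `patients` (per-patient
#'   tibble), `regimen_freq`, `summary`, `calibration`, `stats`,
#'   `risk_model`, `classifier`, `optimization`, `config`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[peptrisk] ", ...)

  if (!is.null(config$synthetic)) {
    say("generating synthetic cohort (seed ", config$seed, ")")
    coh <- generate_cohort(config$synthetic, config$k_interventions)
    profiles <- coh$profiles
    classifier <- coh$classifier
    tables <- coh$fold_changes
    outcomes <- coh$outcomes
  } else {
    say("reading input files")
    profiles <- read_peptide_matrix(config$paths$profiles)
    classifier <- read_classifier_json(config$paths$classifier)
    tables <- read_fold_change_tsv(config$paths$fold_changes)
    outcomes <- if (!is.null(config$paths$outcomes)) {
      read_outcomes_csv(config$paths$outcomes)
    }
  }
  say(nrow(profiles), " patients, ", ncol(profiles) - 1L, " peptides, ",
      length(tables), " interventions")

  profiles <- impute_missing_as_zero(profiles)
  baseline <- score_cohort(profiles, classifier)

  risk <- if (config$risk_source == "published_constants") {
    published_risk_model(days_per_year = config$days_per_year)
  } else {
    if (is.null(outcomes)) abort("risk_source = 'refit' requires outcomes")
    say("refitting risk model from cohort outcomes")
    curve <- estimate_risk_curve(baseline$score, outcomes)
    fit_risk_regression(curve, days_per_year = config$days_per_year)
  }

  calibration <- NULL
  if (!is.null(config$trial_effects)) {
    say("calibrating ", length(config$trial_effects), " intervention(s) [",
        config$calibration, "]")
    max_iter <- if (config$calibration == "single_pass") 1L else config$max_iter
    calibrated <- lapply(names(config$trial_effects), function(nm) {
      if (!nm %in% names(tables)) {
        abort(paste0("trial effect given for unknown intervention '", nm, "'"))
      }
      calibrate_intervention(profiles, tables[[nm]], classifier, risk,
                             observed_pct = config$trial_effects[[nm]],
                             tolerance = config$tolerance, max_iter = max_iter)
    })
    calibration <- dplyr::bind_rows(lapply(calibrated, `[[`, "record"))
    for (i in seq_along(calibrated)) {
      tables[[names(config$trial_effects)[i]]] <- calibrated[[i]]$table
    }
  }

  say("optimising over ", 2^length(tables) - 1L, " regimens")
  opt <- select_optimal(profiles, tables, classifier)

  patients <- opt$best |>
    dplyr::mutate(
      t50_before = days_to_half_risk(.data$baseline_score, risk),
      t50_after = days_to_half_risk(.data$best_score, risk),
      rate_before = incidence_rate(.data$baseline_score, risk),
      rate_after = incidence_rate(.data$best_score, risk),
      relative_risk_reduction = relative_risk_reduction(.data$baseline_score,
                                                        .data$best_score, risk)
    )

  say("computing cohort statistics")
  stats <- list(
    wilcoxon = paired_wilcoxon(patients$baseline_score, patients$best_score),
    spearman = tryCatch(
      spearman_association(patients$baseline_score, patients$delta),
      error = function(e) {
        warn(conditionMessage(e))
        NULL
      }
    )
  )
  if (!is.null(outcomes)) {
    strata <- tertile_stratify(baseline$score, baseline$patient_id)
    stats$tertile_hr <- tryCatch(hazard_ratio_high_vs_low(strata, outcomes),
                                 error = function(e) {
                                   warn(conditionMessage(e))
                                   NULL
                                 })
  }

  regimen_freq <- tabulate_optimal_regimens(opt)
  summary <- tibble::tibble(
    n_patients = nrow(patients),
    n_regimens = nrow(opt$regimens),
    median_score_before = median(patients$baseline_score),
    median_score_after = median(patients$best_score),
    mean_decrease = mean(-patients$delta),
    median_rate_before = median(patients$rate_before),
    median_rate_after = median(patients$rate_after),
    median_relative_risk_reduction = median(patients$relative_risk_reduction)
  )
  say("median score ", format(summary$median_score_before, digits = 3), " -> ",
      format(summary$median_score_after, digits = 3), "; median rate ",
      format(summary$median_rate_before, digits = 3), " -> ",
      format(summary$median_rate_after, digits = 3), " per 100 person-years")

  report <- structure(
    list(patients = patients, regimen_freq = regimen_freq, summary = summary,
         calibration = calibration, stats = stats, risk_model = risk,
         classifier = classifier, optimization = opt, outcomes = outcomes,
         config = config),
    class = "run_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("<run_report> ", s$n_patients, " patients, ", s$n_regimens, " regimens\n",
      "  median score: ", format(s$median_score_before, digits = 3), " -> ",
      format(s$median_score_after, digits = 3), "\n",
      "  median incidence rate (/100 py): ",
      format(s$median_rate_before, digits = 3), " -> ",
      format(s$median_rate_after, digits = 3), "\n",
      "  median relative risk reduction: ",
      format(s$median_relative_risk_reduction, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.run_report <- function(x, ...) x$patients

#' @export
glance.run_report <- function(x, ...) x$summary

#' Write a pipeline report to CSV files
#'
#' Emits `per_patient.csv` (baseline score, best regimen and score, t50 and
#' incidence rate before/after, relative risk reduction), `regimen_frequency.csv`,
#' `summary.csv`, and `calibration.csv` when calibration ran.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    per_patient = file.path(dir, "per_patient.csv"),
    regimen_frequency = file.path(dir, "regimen_frequency.csv"),
    summary = file.path(dir, "summary.csv")
  )
  readr::write_csv(report$patients, paths["per_patient"])
  readr::write_csv(report$regimen_freq, paths["regimen_frequency"])
  readr::write_csv(report$summary, paths["summary"])
  if (!is.null(report$calibration)) {
    paths["calibration"] <- file.path(dir, "calibration.csv")
    readr::write_csv(report$calibration, paths["calibration"])
  }
  invisible(paths)
}
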