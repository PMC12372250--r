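#' Construct a per-intervention fold-change table
#'
#' A fold-change table records the multiplicative effect of one intervention
#' on peptide abundances: for each listed peptide, the ratio of average
#' abundance after treatment to before. Peptides absent from the table have
#' implicit fold change 1.
#'
#' @param fold_changes Named numeric vector of strictly positive, finite fold
#'   changes (names are peptide ids), or a data frame with columns
#'   `peptide_id` and `fold_change`.
#' @param intervention Intervention name.
#' @param calibrated Logical; whether the table has been recalibrated against
#'   a trial-observed effect (see [recalibrate_fold_changes()]).
#' @return An object of class `fold_change_table`.
#' @examples
#' fold_change_table(c(p1 = 0.5, p2 = 2), "SGLT2i")
#' @export
fold_change_table <- function(fold_changes, intervention, calibrated = FALSE) {
  if (is.data.frame(fold_changes)) {
    stopifnot(all(c("peptide_id", "fold_change") %in% names(fold_changes)))
    fold_changes <- setNames(fold_changes$fold_change, fold_changes$peptide_id)
  }
  if (length(fold_changes) && (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes))))) {
    abort("fold changes must be named by peptide id")
  }
  if (anyDuplicated(names(fold_changes))) abort("duplicate peptide ids in fold-change table")
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0)) {
    abort(paste0("intervention '", intervention, "': fold changes must be positive and finite"))
  }
  if (!is.character(intervention) || length(intervention) != 1L || !nzchar(intervention)) {
    abort("`intervention` must be a non-empty string")
  }
  structure(
    list(intervention = intervention, fold_changes = fold_changes,
         calibrated = isTRUE(calibrated)),
    class = "fold_change_table"
  )
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat("<fold_change_table> ", x$intervention,
    " (", length(x$fold_changes), " peptides",
    if (x$calibrated) ", calibrated", ")\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.fold_change_table <- function(x, ...) {
  tibble::tibble(
    intervention = x$intervention,
    peptide_id = names(x$fold_changes),
    fold_change = unname(x$fold_changes),
    calibrated = x$calibrated
  )
}

# internal: fold changes for given peptide ids, default 1
fc_for <- function(table, peptide_ids) {
  fc <- rep(1, length(peptide_ids))
  names(fc) <- peptide_ids
  shared <- intersect(peptide_ids, names(table$fold_changes))
  fc[shared] <- table$fold_changes[shared]
  fc
}

#' Apply an intervention's fold changes to peptide profiles
#'
#' Multiplies each peptide intensity by the intervention's fold change
#' (1 for peptides not in the table). Profiles must be imputed first; a zero
#' (below-detection) intensity stays exactly zero under multiplication.
#'
#' @param profiles Wide, imputed profile table.
#' @param table A [fold_change_table()].
#' @return The treated profile table, same shape and row order.
#' @examples
#' p <- tibble::tibble(patient_id = "a", p1 = 4, p2 = 10)
#' apply_fold_changes(p, fold_change_table(c(p1 = 0.5), "ARB"))
#' @export
apply_fold_changes <- function(profiles, table) {
  stopifnot(inherits(table, "fold_change_table"))
  m <- profile_matrix(profiles)
  if (anyNA(m)) {
    abort("profiles contain missing intensities; run impute_missing_as_zero() first")
  }
  fc <- fc_for(table, colnames(m))
  matrix_to_profiles(sweep(m, 2L, fc, `*`))
}

#' Combine several interventions into one fold-change table
#'
#' Joint treatment is modelled as independent effects: per peptide, the
#' product of fold changes across the member tables (absent peptide = 1).
#' The combined table is named by joining the sorted member names with `+`.
#'
#' @param tables Non-empty list of [fold_change_table()]s with distinct names.
#' @return A single `fold_change_table`.
#' @export
combine_interventions <- function(tables) {
  if (inherits(tables, "fold_change_table")) tables <- list(tables)
  if (length(tables) == 0L) abort("cannot combine an empty set of interventions")
  stopifnot(all(vapply(tables, inherits, logical(1), "fold_change_table")))
  nm <- vapply(tables, function(t) t$intervention, character(1))
  if (anyDuplicated(nm)) abort("duplicate intervention names in combination")
  all_ids <- unique(unlist(lapply(tables, function(t) names(t$fold_changes))))
  fc <- rep(1, length(all_ids))
  names(fc) <- all_ids
  for (t in tables) fc <- fc * fc_for(t, all_ids)
  fold_change_table(fc, paste(sort(nm), collapse = "+"),
                    calibrated = all(vapply(tables, function(t) t$calibrated, logical(1))))
}

#' Enumerate all non-empty intervention combinations
#'
#' With `k` available interventions there are `2^k - 1` candidate regimens.
#' The ordering is canonical and byte-stable: by regimen size, then
#' lexicographically by the `+`-joined sorted member names.
#'
#' @param intervention_names Character vector of `k >= 1` distinct names.
#' @return A tibble with columns `regimen` (joined name), `size`, and
#'   `members` (list column of character vectors).
#' @examples
#' nrow(enumerate_regimens(c("a", "b", "c")))  # 7
#' @export
enumerate_regimens <- function(intervention_names) {
  intervention_names <- as.character(intervention_names)
  if (length(intervention_names) == 0L) abort("need at least one intervention")
  if (anyDuplicated(intervention_names)) abort("intervention names must be distinct")
  k <- length(intervention_names)
  members <- unlist(
    lapply(seq_len(k), function(s) {
      combos <- utils::combn(sort(intervention_names), s, simplify = FALSE)
      combos[order(vapply(combos, paste, character(1), collapse = "+"))]
    }),
    recursive = FALSE
  )
  tibble::tibble(
    regimen = vapply(members, paste, character(1), collapse = "+"),
    size = lengths(members),
    members = members
  )
}

#' Select the score-minimising regimen for every patient
#'
#' Scores each patient under every enumerated regimen (combine the member
#' fold-change tables, apply them to the baseline profile, rescore) and
#' selects per patient the regimen attaining the lowest classifier score.
#' Ties are broken in favour of fewer interventions, then lexicographically —
#' parsimony minimises drug burden.
#'
#' @param profiles Wide, imputed baseline profile table.
#' @param tables List of [fold_change_table()]s (`k >= 1`), distinct names.
#' @param model A [classifier_model()].
#' @return An object of class `regimen_optimization` with elements
#'   `best` (tibble: `patient_id`, `baseline_score`, `best_regimen`,
#'   `n_interventions`, `best_score`, `delta`), `scores` (long tibble of all
#'   `2^k - 1` regimen scores per patient) and `regimens` (the enumeration).
#'   `tidy()` returns `best`; `glance()` a one-row cohort summary.
#' @export
select_optimal <- function(profiles, tables, model) {
  if (inherits(tables, "fold_change_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "fold_change_table")))
  names(tables) <- vapply(tables, function(t) t$intervention, character(1))
  if (anyDuplicated(names(tables))) abort("duplicate intervention names")
  profiles <- as_peptide_profiles(profiles)
  m <- profile_matrix(profiles)
  if (anyNA(m)) {
    abort("profiles contain missing intensities; run impute_missing_as_zero() first")
  }
  regimens <- enumerate_regimens(names(tables))
  baseline <- score_matrix(m, model)

  # only classifier peptides can move the score; restrict the sweep to them
  w <- model$weights
  x <- matrix(0, nrow(m), length(w), dimnames = list(rownames(m), names(w)))
  present <- intersect(names(w), colnames(m))
  x[, present] <- m[, present, drop = FALSE]
  logfc <- vapply(tables, function(t) log(fc_for(t, names(w))), numeric(length(w)))
  logfc <- matrix(logfc, nrow = length(w), dimnames = list(names(w), names(tables)))

  score_mat <- vapply(seq_len(nrow(regimens)), function(i) {
    fc <- exp(rowSums(logfc[, regimens$members[[i]], drop = FALSE]))
    as.numeric(model$bias +
                 apply_transform(sweep(x, 2L, fc, `*`), model$transform) %*% w)
  }, numeric(nrow(m)))
  score_mat <- matrix(score_mat, nrow = nrow(m),
                      dimnames = list(rownames(m), regimens$regimen))

  # canonical regimen order means which.min() realises the tie-break rule
  best_idx <- apply(score_mat, 1L, which.min)
  best <- tibble::tibble(
    patient_id = profiles$patient_id,
    baseline_score = baseline,
    best_regimen = regimens$regimen[best_idx],
    n_interventions = regimens$size[best_idx],
    best_score = score_mat[cbind(seq_len(nrow(m)), best_idx)],
    delta = score_mat[cbind(seq_len(nrow(m)), best_idx)] - baseline
  )
  scores <- tibble::as_tibble(score_mat, rownames = "patient_id") |>
    tidyr::pivot_longer(-"patient_id", names_to = "regimen", values_to = "score")
  structure(list(best = best, scores = scores, regimens = regimens,
                 model = model$name),
            class = "regimen_optimization")
}

#' @export
print.regimen_optimization <- function(x, ...) {
  cat("<regimen_optimization> ", nrow(x$best), " patients x ",
      nrow(x$regimens), " regimens (model ", x$model, ")\n", sep = "")
  cat("  median score ", format(median(x$best$baseline_score), digits = 3),
      " -> ", format(median(x$best$best_score), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.regimen_optimization <- function(x, ...) x$best

#' @export
glance.regimen_optimization <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$best),
    n_regimens = nrow(x$regimens),
    median_baseline = median(x$best$baseline_score),
    median_best = median(x$best$best_score),
    mean_decrease = mean(-x$best$delta)
  )
}

#' Tabulate optimal-regimen frequencies
#'
#' Counts how many patients have each regimen as their predicted optimum,
#' sorted by descending count; counts sum to the number of patients.
#'
#' @param results A `regimen_optimization` object or a tibble with a
#'   `best_regimen` column.
#' @return A tibble with columns `regimen`, `n_interventions`, `n_patients`.
#' @export
tabulate_optimal_regimens <- function(results) {
  best <- if (inherits(results, "regimen_optimization")) results$best else results
  stopifnot(is.data.frame(best), "best_regimen" %in% names(best))
  best |>
    dplyr::count(regimen = .data$best_regimen, name = "n_patients") |>
    dplyr::mutate(n_interventions = lengths(strsplit(.data$regimen, "+", fixed = TRUE)),
                  .after = "regimen") |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$regimen)
}
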