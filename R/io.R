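#' Read and write peptide matrices as TSV
#'
#' The on-disk peptide matrix format is tab-separated, one row per patient,
#' first column `patient_id`, one column per peptide id; an empty cell is a
#' missing intensity.
#'
#' @param profiles Wide profile table.
#' @param path File path.
#' @return `write_peptide_matrix()` returns `path` invisibly;
#'   `read_peptide_matrix()` a validated profile tibble.
#' @export
write_peptide_matrix <- function(profiles, path) {
  readr::write_tsv(as_peptide_profiles(profiles), path, na = "")
  invisible(path)
}

#' @rdname write_peptide_matrix
#' @export
read_peptide_matrix <- function(path) {
  x <- readr::read_tsv(path, na = "", show_col_types = FALSE,
                       col_types = readr::cols(patient_id = readr::col_character(),
                                               .default = readr::col_double()))
  as_peptide_profiles(x)
}

#' Read and write fold-change tables as TSV
#'
#' A single table is written with columns `peptide_id`, `fold_change`,
#' `intervention`, `calibrated`; a list of tables is written long with one
#' block per intervention. Reading returns a named list of
#' [fold_change_table()]s (grouped by the `intervention` column, or a single
#' unnamed-intervention table when that column is absent).
#'
#' @param tables A [fold_change_table()] or list of them.
#' @param path File path.
#' @return `write_fold_change_tsv()` returns `path` invisibly;
#'   `read_fold_change_tsv()` a named list of fold-change tables.
#' @export
write_fold_change_tsv <- function(tables, path) {
  if (inherits(tables, "fold_change_table")) tables <- list(tables)
  long <- dplyr::bind_rows(lapply(tables, as_tibble))
  readr::write_tsv(long[c("peptide_id", "fold_change", "intervention", "calibrated")],
                   path)
  invisible(path)
}

#' @rdname write_fold_change_tsv
#' @export
read_fold_change_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("peptide_id", "fold_change") %in% names(x)))
  if (!"intervention" %in% names(x)) x$intervention <- "intervention"
  if (!"calibrated" %in% names(x)) x$calibrated <- FALSE
  split(x, x$intervention) |>
    lapply(function(d) {
      fold_change_table(setNames(d$fold_change, d$peptide_id),
                        d$intervention[1], calibrated = all(d$calibrated))
    })
}

#' Read and write clinical outcome tables as CSV
#'
#' Columns: `patient_id`, `followup_days` (non-negative), `event` (0/1).
#'
#' @param outcomes Tibble with `patient_id`, `followup_days`, `event`.
#' @param path File path.
#' @return `write_outcomes_csv()` returns `path` invisibly;
#'   `read_outcomes_csv()` a tibble with logical `event`.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  stopifnot(all(c("patient_id", "followup_days", "event") %in% names(outcomes)))
  out <- dplyr::mutate(outcomes, event = as.integer(as.logical(.data$event)))
  readr::write_csv(out[c("patient_id", "followup_days", "event")], path)
  invisible(path)
}

#' @rdname write_outcomes_csv
#' @export
read_outcomes_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(patient_id = readr::col_character(),
                                               followup_days = readr::col_double(),
                                               event = readr::col_double()))
  if (any(x$followup_days < 0)) abort("negative followup_days in outcomes file")
  dplyr::mutate(x, event = as.logical(.data$event))
}
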