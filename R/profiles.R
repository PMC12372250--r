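#' Validate a wide table of peptide intensity profiles
#'
#' A peptide profile table is the central data object interventions act on:
#' one row per patient, a `patient_id` character column first, and one numeric
#' column per peptide. Intensities are non-negative; `NA` marks a missing
#' measurement (typically signal below the detection limit of the platform).
#'
#' @param x A data frame in the wide profile layout.
#' @return `x` as a tibble, invisibly validated (unique patient ids,
#'   non-negative intensities).
#' @examples
#' p <- tibble::tibble(patient_id = c("a", "b"), pep1 = c(1, NA), pep2 = c(0, 3))
#' as_peptide_profiles(p)
#' @export
as_peptide_profiles <- function(x) {
  if (!is.data.frame(x)) abort("peptide profiles must be a data frame")
  if (ncol(x) < 2L || names(x)[1] != "patient_id") {
    abort("profiles need a first column `patient_id` plus at least one peptide column")
  }
  x <- tibble::as_tibble(x)
  x$patient_id <- as.character(x$patient_id)
  if (anyDuplicated(x$patient_id)) abort("duplicate patient_id in profiles")
  mat <- x[-1]
  if (!all(vapply(mat, is.numeric, logical(1)))) {
    abort("all peptide columns must be numeric")
  }
  if (any(unlist(mat, use.names = FALSE) < 0, na.rm = TRUE)) {
    abort("peptide intensities must be non-negative")
  }
  x
}

#' Replace missing peptide intensities by zero
#'
#' Missing intensities generally reflect signal below the detection limit, so
#' they are imputed as exact zeros before scoring or in silico treatment.
#' Present values are returned unchanged.
#'
#' @param profiles A wide profile table (see [as_peptide_profiles()]).
#' @return The same table with every `NA` intensity replaced by `0`.
#' @examples
#' p <- tibble::tibble(patient_id = "a", p1 = 5, p2 = NA_real_)
#' impute_missing_as_zero(p)
#' @export
impute_missing_as_zero <- function(profiles) {
  profiles <- as_peptide_profiles(profiles)
  dplyr::mutate(profiles, dplyr::across(-"patient_id", ~ tidyr::replace_na(.x, 0)))
}

# internal: numeric matrix of intensities, rownames = patient ids
profile_matrix <- function(profiles) {
  profiles <- as_peptide_profiles(profiles)
  m <- as.matrix(profiles[-1])
  rownames(m) <- profiles$patient_id
  m
}

# internal: matrix -> wide tibble
matrix_to_profiles <- function(m) {
  tibble::as_tibble(m, rownames = "patient_id")
}
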