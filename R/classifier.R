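#' Construct a linear peptide classifier
#'
#' A pluggable stand-in for the CKD273 urinary peptide classifier: a linear
#' decision function over peptide intensities. Each peptide contributes
#' `weight * transform(intensity)`; peptides in the model but absent from a
#' profile contribute `transform(0)`, consistent with zero-imputation of
#' below-detection signals. The default `log1p` transform keeps zero
#' intensities in-domain.
#'
#' @param weights Named numeric vector of peptide weights (names are peptide
#'   ids); at least one weight must be nonzero. Both signs are allowed:
#'   up-regulated markers carry positive weights, down-regulated negative.
#' @param bias Scalar intercept added to the weighted sum.
#' @param transform Elementwise intensity transform applied before weighting:
#'   `"log1p"` (default) or `"identity"`.
#' @param name Label carried into scored output.
#' @return An object of class `classifier_model`.
#' @examples
#' m <- classifier_model(c(p1 = 1, p2 = -1), bias = 0, transform = "identity")
#' score_profile(c(p1 = 2, p2 = 1), m)
#' @export
classifier_model <- function(weights, bias = 0, transform = c("log1p", "identity"),
                             name = "classifier") {
  transform <- match.arg(transform)
  if (!is.numeric(weights) || is.null(names(weights)) || any(!nzchar(names(weights)))) {
    abort("`weights` must be a named numeric vector of peptide weights")
  }
  if (anyDuplicated(names(weights))) abort("duplicate peptide ids in weights")
  if (!any(weights != 0)) abort("classifier needs at least one nonzero weight")
  if (!is.numeric(bias) || length(bias) != 1L || !is.finite(bias)) {
    abort("`bias` must be a finite scalar")
  }
  structure(
    list(weights = weights, bias = unname(bias), transform = transform, name = name),
    class = "classifier_model"
  )
}

#' @export
print.classifier_model <- function(x, ...) {
  cat("<classifier_model> ", x$name, "\n",
    "  peptides: ", length(x$weights),
    " (", sum(x$weights > 0), " up, ", sum(x$weights < 0), " down)\n",
    "  bias: ", format(x$bias), ", transform: ", x$transform, "\n",
    sep = ""
  )
  invisible(x)
}

apply_transform <- function(x, transform) {
  switch(transform, identity = x, log1p = log1p(x),
         abort(paste0("unknown transform: ", transform)))
}

#' Score a single peptide profile
#'
#' Computes `bias + sum(weight * transform(intensity))` over the model's
#' peptides. The profile must already be imputed: a missing (`NA`) intensity
#' is an error, forcing explicit use of [impute_missing_as_zero()].
#'
#' @param intensities Named numeric vector of peptide intensities for one
#'   patient (names are peptide ids). Model peptides absent from the vector
#'   contribute `transform(0)`.
#' @param model A [classifier_model()].
#' @return A single finite numeric score.
#' @export
score_profile <- function(intensities, model) {
  stopifnot(inherits(model, "classifier_model"))
  if (anyNA(intensities)) {
    abort("profile contains missing intensities; run impute_missing_as_zero() first")
  }
  x <- setNames(rep(0, length(model$weights)), names(model$weights))
  shared <- intersect(names(model$weights), names(intensities))
  x[shared] <- intensities[shared]
  unname(model$bias + sum(model$weights * apply_transform(x, model$transform)))
}

#' Score a cohort of peptide profiles
#'
#' Applies the classifier row-wise to a wide profile table, preserving row
#' order. All profiles must be imputed (no `NA`).
#'
#' @param profiles Wide profile table (see [as_peptide_profiles()]).
#' @param model A [classifier_model()].
#' @return A tibble with columns `patient_id`, `score`, `model`.
#' @examples
#' p <- tibble::tibble(patient_id = c("a", "b"), p1 = c(2, 0), p2 = c(1, 0))
#' m <- classifier_model(c(p1 = 1, p2 = -1), transform = "identity")
#' score_cohort(p, m)
#' @export
score_cohort <- function(profiles, model) {
  stopifnot(inherits(model, "classifier_model"))
  profiles <- as_peptide_profiles(profiles)
  m <- profile_matrix(profiles)
  if (anyNA(m)) {
    abort("profiles contain missing intensities; run impute_missing_as_zero() first")
  }
  tibble::tibble(
    patient_id = profiles$patient_id,
    score = score_matrix(m, model),
    model = model$name
  )
}

# internal: vectorised scoring of an imputed intensity matrix
score_matrix <- function(m, model) {
  w <- model$weights
  present <- intersect(names(w), colnames(m))
  x <- matrix(0, nrow(m), length(w), dimnames = list(rownames(m), names(w)))
  x[, present] <- m[, present, drop = FALSE]
  as.numeric(model$bias + apply_transform(x, model$transform) %*% w)
}

#' Read / write a classifier as JSON
#'
#' Serialises a [classifier_model()] as a JSON document with fields `name`,
#' `transform`, `bias` and a `weights` object mapping peptide id to weight.
#'
#' @param model A [classifier_model()].
#' @param path File path.
#' @return `write_classifier_json()` returns `path` invisibly;
#'   `read_classifier_json()` returns a `classifier_model`.
#' @export
write_classifier_json <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  jsonlite::write_json(
    list(name = model$name, transform = model$transform, bias = model$bias,
         weights = as.list(model$weights)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  doc <- jsonlite::read_json(path)
  classifier_model(
    weights = unlist(doc$weights),
    bias = doc$bias,
    transform = doc$transform,
    name = doc$name
  )
}
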