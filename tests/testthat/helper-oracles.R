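# Independent oracles, kept deliberately naive: plain loops over peptides and
# regimens, no reuse of the package's vectorised code paths.

# direct elementwise score of one named intensity vector
oracle_score <- function(intensities, model) {
  f <- if (model$transform == "log1p") log1p else identity
  total <- model$bias
  for (pep in names(model$weights)) {
    x <- if (pep %in% names(intensities)) intensities[[pep]] else 0
    total <- total + model$weights[[pep]] * f(x)
  }
  total
}

# apply one fold-change table by looping over its peptides
oracle_apply <- function(intensities, table) {
  for (pep in names(table$fold_changes)) {
    if (pep %in% names(intensities)) {
      intensities[[pep]] <- intensities[[pep]] * table$fold_changes[[pep]]
    }
  }
  intensities
}

# brute-force optimum: every non-empty subset, tables applied sequentially.
# Subsets are visited by size then lexicographically, so a strict `<` update
# realises the fewest-then-lexicographic tie-break.
oracle_best_regimen <- function(intensities, tables, model) {
  nms <- vapply(tables, function(t) t$intervention, character(1))
  k <- length(tables)
  best <- NULL
  for (s in seq_len(k)) {
    combos <- utils::combn(sort(nms), s, simplify = FALSE)
    combos <- combos[order(vapply(combos, paste, character(1), collapse = "+"))]
    for (combo in combos) {
      x <- intensities
      for (nm in combo) x <- oracle_apply(x, tables[[which(nms == nm)]])
      sc <- oracle_score(x, model)
      if (is.null(best) || sc < best$score) {
        best <- list(score = sc, regimen = paste(combo, collapse = "+"), size = s)
      }
    }
  }
  best
}

# small random fixture for oracle-equivalence checks
random_fixture <- function(seed, n_peptides = 12, n_classifier = 6, k = 3) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n_peptides))
  cls <- sample(ids, n_classifier)
  model <- classifier_model(
    setNames(rnorm(n_classifier), cls),
    bias = rnorm(1), transform = sample(c("log1p", "identity"), 1)
  )
  intensities <- setNames(rexp(n_peptides, 1 / 50), ids)
  tables <- lapply(seq_len(k), function(i) {
    covered <- sample(ids, sample(2:n_peptides, 1))
    fold_change_table(setNames(exp(rnorm(length(covered), sd = 0.5)), covered),
                      paste0("drug", letters[i]))
  })
  profiles <- tibble::tibble(patient_id = "pt1", !!!as.list(intensities))
  list(model = model, intensities = intensities, tables = tables,
       profiles = profiles)
}

tiny_profiles <- function() {
  tibble::tibble(
    patient_id = c("a", "b", "c"),
    p1 = c(2, 0, 4),
    p2 = c(1, 0, 10),
    p3 = c(5, 5, 5)
  )
}

tiny_model <- function() {
  classifier_model(c(p1 = 1, p2 = -1), bias = 0, transform = "identity")
}
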