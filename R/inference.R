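## Permutation-based significance for cross-validated classification:
## bootstrap chance correction for LOOCV CV-values, and the permuted DFA
## (pDFA) with the ncce statistic (mean number of correctly
## cross-classified elements over balanced training-set selections,
## reported as a percentage of cross-classified elements), controlling for
## repeated sampling of individuals nested in groups.

#' Bootstrap chance correction for a LOOCV CV-value
#'
#' The observed CV-value is compared against a null distribution obtained
#' by permuting class labels over calls and recomputing the leave-one-out
#' CV-value. `P = (1 + #\{null >= observed\}) / (1 + n_randomizations)`
#' (add-one estimator, so P is never 0).
#'
#' @inheritParams fit_dfa
#' @param n_randomizations number of label permutations (warning below 100)
#' @param seed optional integer seed
#' @return a `bootstrap_result`: `observed` (CV %), `null` (vector of null
#'   CV %), `p_value`, `n_randomizations`, `seed`
#' @export
bootstrap_chance <- function(table, class_column, predictors,
                             n_randomizations = 1000, seed = NULL) {
  if (n_randomizations < 100)
    warning("fewer than 100 randomizations gives an unstable P-value")
  if (!is.null(seed)) set.seed(seed)
  xy <- build_xy(table, class_column, predictors)
  if (any(table(xy$y) < 2))
    stop("cannot leave out from a class with a single observation")
  y_codes <- as.integer(xy$y) - 1L
  K <- nlevels(xy$y)
  observed <- 100 * loocv_prop(xy$X, y_codes, K)
  null <- vapply(seq_len(n_randomizations), function(b)
    100 * loocv_prop(xy$X, sample(y_codes), K), numeric(1))
  p <- (1 + sum(null >= observed)) / (1 + n_randomizations)
  structure(list(observed = observed, null = null, p_value = p,
                 n_randomizations = n_randomizations, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Observed CV-value %.1f%%; null mean %.1f%%; P = %.4g (%d randomizations)\n",
    x$observed, mean(x$null), x$p_value, x$n_randomizations))
  invisible(x)
}

## --- crossed-design machinery ---------------------------------------------

## (subject x test-level) cells with at least min_cell calls; subjects
## usable only if they contribute >= 2 usable levels
make_cells <- function(y_codes, subject, min_cell = 2L, warn = TRUE) {
  key <- interaction(subject, y_codes, sep = "\r", drop = TRUE)
  idx <- split(seq_along(y_codes), key)
  idx <- idx[lengths(idx) >= min_cell]
  cell_subject <- sub("\r.*$", "", names(idx))
  usable <- names(which(table(cell_subject) >= 2))
  excluded <- setdiff(unique(as.character(subject)), usable)
  if (warn && length(excluded) > 0)
    warning("subjects excluded from the crossed design (fewer than 2 ",
            "test levels with >= ", min_cell, " calls): ",
            paste(excluded, collapse = ", "))
  keep <- cell_subject %in% usable
  list(cells = idx[keep], subjects = usable, excluded = excluded)
}

ncce_crossed <- function(X, y_codes, subject, K, n_selections,
                         train_fraction, min_cell = 2L, warn = TRUE) {
  cs <- make_cells(y_codes, subject, min_cell, warn)
  if (length(cs$subjects) == 0)
    stop("no subject satisfies the crossed design")
  n_train <- max(1L, floor(train_fraction * min(lengths(cs$cells))))
  ncce <- cpp_ncce_crossed(X, y_codes, unname(cs$cells), n_train, K,
                           n_selections)
  list(ncce = ncce, n_train_per_cell = n_train,
       n_cells = length(cs$cells), subjects = cs$subjects,
       excluded = cs$excluded)
}

## shuffle test labels within each (subject [x strata]) unit
permute_within <- function(y_codes, unit) {
  out <- y_codes
  for (ix in split(seq_along(y_codes), unit)) {
    if (length(ix) > 1) out[ix] <- y_codes[sample(ix)]
  }
  out
}

assert_counts_conserved <- function(y_perm, y_codes, subject) {
  for (ix in split(seq_along(y_codes), subject)) {
    if (!identical(sort(y_perm[ix]), sort(y_codes[ix])))
      stop("internal error: permutation altered within-subject label counts")
  }
  invisible(TRUE)
}

## --- nested-design machinery (between-subject test factors) ----------------

ncce_nested <- function(X, y_codes, subject, subj_level, K, n_selections,
                        train_fraction) {
  subj_calls <- split(seq_along(y_codes), subject)
  subj_calls <- subj_calls[names(subj_level)]
  by_level <- split(names(subj_level), subj_level)
  min_subj <- min(lengths(by_level))
  if (min_subj < 2)
    stop("nested design needs >= 2 subjects per test level")
  n_train_subj <- min(max(1L, floor(train_fraction * min_subj)),
                      min_subj - 1L)
  level_units <- lapply(by_level, function(subs)
    unname(lapply(subj_calls[subs], as.integer)))
  ncce <- cpp_ncce_nested(X, y_codes, unname(level_units), n_train_subj, K,
                          n_selections)
  list(ncce = ncce, n_train_subjects = n_train_subj,
       subjects = names(subj_level), excluded = character())
}

#' The ncce statistic for a (crossed) permuted DFA design
#'
#' For each of `n_selections` random balanced splits, a fixed number of
#' calls per (subject x test-level) cell is assigned to a training set and
#' the remainder to a cross-set; a linear discriminant model fitted to the
#' training set classifies the cross-set. ncce is the mean percentage of
#' correctly cross-classified elements over selections. Subjects that do
#' not contribute at least two test levels with two calls each are
#' excluded with a warning.
#'
#' @param table data.frame with predictors and factors
#' @param test_factor column name of the factor to classify
#' @param control_factor column naming the repeated-sampling subject
#'   (typically the individual)
#' @param predictors numeric predictor columns
#' @param n_selections number of balanced training-set selections
#' @param train_fraction fraction of each cell assigned to training
#'   (floored, minimum 1 call)
#' @param seed optional integer seed
#' @return list with `ncce` (% of cross-elements), selection settings and
#'   the included/excluded subjects
#' @export
ncce_statistic <- function(table, test_factor, control_factor, predictors,
                           n_selections = 100, train_fraction = 2 / 3,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- complete.cases(table[, predictors, drop = FALSE])
  tab <- table[keep, , drop = FALSE]
  xy <- build_xy(tab, test_factor, predictors)
  ncce_crossed(xy$X, as.integer(xy$y) - 1L,
               factor(tab[[control_factor]]), nlevels(xy$y),
               n_selections, train_fraction)
}

#' Permuted discriminant function analysis (pDFA)
#'
#' Significance of the ncce statistic under permutation of the test-factor
#' labels while controlling for repeated sampling of subjects.
#'
#' Two designs are supported. In the `crossed` design (test factor varies
#' within subjects, e.g. behavioural context within individuals) labels
#' are shuffled within each subject, conserving the subject's per-level
#' call counts; additional factors can be held constant by stratifying the
#' permutation within their levels via `stratify_by`. In the `nested`
#' design (test factor constant within subjects, e.g. group or sex) whole
#' subjects are re-assigned to test levels, so calls of one individual
#' never straddle the permutation unit, and training/cross splits select
#' whole subjects per level.
#'
#' `P = (1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' @inheritParams ncce_statistic
#' @param n_permutations number of label permutations
#' @param design `"crossed"` or `"nested"`
#' @param stratify_by optional column names held constant during crossed
#'   permutation
#' @return a `pdfa_result`: `observed` (ncce %), `null` (vector),
#'   `p_value`, design metadata and the excluded subjects
#' @export
crossed_pdfa <- function(table, test_factor, control_factor, predictors,
                         n_permutations = 1000, n_selections = 100,
                         train_fraction = 2 / 3, seed = NULL,
                         design = c("crossed", "nested"),
                         stratify_by = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  keep <- complete.cases(table[, predictors, drop = FALSE])
  tab <- table[keep, , drop = FALSE]
  xy <- build_xy(tab, test_factor, predictors)
  y_codes <- as.integer(xy$y) - 1L
  K <- nlevels(xy$y)
  subject <- factor(tab[[control_factor]])

  if (design == "crossed") {
    obs <- ncce_crossed(xy$X, y_codes, subject, K, n_selections,
                        train_fraction, warn = TRUE)
    unit <- if (is.null(stratify_by)) subject else
      interaction(c(list(subject), lapply(stratify_by, function(cc)
        factor(tab[[cc]]))), drop = TRUE)
    null <- vapply(seq_len(n_permutations), function(b) {
      y_perm <- permute_within(y_codes, unit)
      assert_counts_conserved(y_perm, y_codes, subject)
      ncce_crossed(xy$X, y_perm, subject, K, n_selections,
                   train_fraction, warn = FALSE)$ncce
    }, numeric(1))
  } else {
    lvl_by_subj <- tapply(as.character(xy$y), subject,
                          function(v) unique(v), simplify = FALSE)
    multi <- names(lvl_by_subj)[lengths(lvl_by_subj) > 1]
    if (length(multi) > 0)
      stop("nested design requires the test factor constant within ",
           "subjects; violated by: ", paste(multi, collapse = ", "))
    subj_level <- vapply(lvl_by_subj, `[[`, character(1), 1)
    obs <- ncce_nested(xy$X, y_codes, subject, subj_level, K, n_selections,
                       train_fraction)
    level_codes <- match(subj_level, levels(xy$y)) - 1L
    subj_calls <- split(seq_along(y_codes), subject)[names(subj_level)]
    null <- vapply(seq_len(n_permutations), function(b) {
      perm_level <- sample(level_codes)
      y_perm <- y_codes
      for (s in seq_along(subj_calls)) y_perm[subj_calls[[s]]] <- perm_level[s]
      names(perm_level) <- names(subj_level)
      ncce_nested(xy$X, y_perm, subject,
                  setNames(levels(xy$y)[perm_level + 1L], names(subj_level)),
                  K, n_selections, train_fraction)$ncce
    }, numeric(1))
  }
  p <- (1 + sum(null >= obs$ncce)) / (1 + n_permutations)
  structure(list(observed = obs$ncce, null = null, p_value = p,
                 n_permutations = n_permutations,
                 n_selections = n_selections, design = design,
                 test_factor = test_factor, control_factor = control_factor,
                 excluded_subjects = obs$excluded,
                 n_subjects = length(obs$subjects), seed = seed),
            class = "pdfa_result")
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf(
    "%s pDFA (%s | %s): ncce = %.2f%%, P = %.4g (%d permutations, %d subjects)\n",
    x$design, x$test_factor, x$control_factor, x$observed, x$p_value,
    x$n_permutations, x$n_subjects))
  invisible(x)
}
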