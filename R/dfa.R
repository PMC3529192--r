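## Linear discriminant analysis with leave-one-out cross-validation and
## stepwise variable selection under an absolute cross-validated
## improvement margin.

build_xy <- function(table, class_column, predictors) {
  if (!class_column %in% names(table))
    stop("class column not in table: ", class_column)
  missing <- setdiff(predictors, names(table))
  if (length(missing) > 0)
    stop("predictors not in table: ", paste(missing, collapse = ", "))
  X <- as.matrix(table[, predictors, drop = FALSE])
  if (!is.numeric(X)) stop("predictors must be numeric")
  if (anyNA(X))
    stop("NA values among predictors; restrict to complete cases first")
  y <- factor(table[[class_column]])
  list(X = X, y = y)
}

#' Fit a linear discriminant model
#'
#' Standard pooled within-class covariance solution with equal class priors
#' by default. Discriminant coefficients are the leading eigenvectors of
#' the between-class scatter whitened by the pooled covariance (at most
#' `min(K - 1, p)` functions).
#'
#' @param table data.frame of observations
#' @param class_column name of the factor column to discriminate
#' @param predictors character vector of numeric predictor columns
#' @param priors class prior probabilities (default equal)
#' @return a `dfa_model`
#' @export
fit_dfa <- function(table, class_column, predictors, priors = NULL) {
  xy <- build_xy(table, class_column, predictors)
  X <- xy$X; y <- xy$y
  K <- nlevels(y)
  n <- nrow(X); p <- ncol(X)
  if (K < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs n >= 2")
  if (p >= n) stop("more predictors than observations")
  priors <- priors %||% rep(1 / K, K)
  stopifnot(length(priors) == K, all(priors > 0))
  priors <- priors / sum(priors)

  means <- t(vapply(levels(y), function(l) colMeans(X[y == l, , drop = FALSE]),
                    numeric(p)))
  centered <- X - means[as.integer(y), , drop = FALSE]
  pooled <- crossprod(centered) / (n - K)
  ch <- tryCatch(chol(pooled), error = function(e) NULL)
  if (is.null(ch)) {
    v <- diag(pooled)
    suspects <- predictors[v < 1e-12 * max(v, 1)]
    stop("singular pooled covariance",
         if (length(suspects)) paste0(" (near-constant: ",
                                      paste(suspects, collapse = ", "), ")")
         else " (collinear predictors)")
  }
  grand <- colMeans(X)
  between <- crossprod(sweep(means, 2, grand) *
                         sqrt(as.numeric(table(y))))  / (K - 1)
  W <- chol2inv(ch)
  eig <- eigen(W %*% between)
  r <- min(K - 1, p)
  coef <- Re(eig$vectors[, seq_len(r), drop = FALSE])
  rownames(coef) <- predictors
  ## separation eigenvalues on the class-mean covariance scale (vanish
  ## when class means coincide, regardless of class sizes)
  between_u <- crossprod(sweep(means, 2, grand)) / (K - 1)
  eig_u <- eigen(W %*% between_u, only.values = TRUE)
  structure(list(labels = levels(y), means = means, pooled_cov = pooled,
                 pooled_inv = W, coef = coef,
                 eigenvalues = Re(eig_u$values[seq_len(r)]),
                 priors = priors, predictors = predictors,
                 class_column = class_column, n = n),
            class = "dfa_model")
}

#' @export
print.dfa_model <- function(x, ...) {
  cat("Linear discriminant model:", length(x$labels), "classes,",
      length(x$predictors), "predictors,", x$n, "observations\n")
  cat("Classes:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Classify observations with a fitted discriminant model
#'
#' Assigns each observation to the class with maximal discriminant score
#' (negative half squared Mahalanobis distance to the class mean under the
#' pooled covariance, plus log prior). Ties go to the first label in the
#' model's label order.
#'
#' @param model a [fit_dfa()] result
#' @param observation data.frame (or coercible) containing all model
#'   predictors; may have several rows
#' @return character vector of predicted class labels
#' @export
classify <- function(model, observation) {
  observation <- as.data.frame(observation)
  missing <- setdiff(model$predictors, names(observation))
  if (length(missing) > 0)
    stop("observation lacks predictors: ", paste(missing, collapse = ", "))
  X <- as.matrix(observation[, model$predictors, drop = FALSE])
  scores <- vapply(seq_along(model$labels), function(k) {
    d <- sweep(X, 2, model$means[k, ])
    -0.5 * rowSums((d %*% model$pooled_inv) * d) + log(model$priors[k])
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  model$labels[apply(scores, 1, which.max)]  # which.max: first max wins ties
}

#' Leave-one-out cross-validated classification
#'
#' Each observation is classified by a model fitted to all remaining
#' observations (equal priors). Folds whose pooled covariance is singular
#' score the held-out observation as misclassified, with a warning.
#'
#' @inheritParams fit_dfa
#' @return a `cv_result`: list with `predicted`, `confusion` (true x
#'   predicted, totalling n), `cv_value` (percent correct, 0-100) and `n`
#' @export
loocv <- function(table, class_column, predictors) {
  xy <- build_xy(table, class_column, predictors)
  if (any(table(xy$y) < 2))
    stop("cannot leave out from a class with a single observation")
  if (ncol(xy$X) >= nrow(xy$X) - 1) stop("more predictors than n - 1")
  codes <- cpp_lda_loocv(xy$X, as.integer(xy$y) - 1L, nlevels(xy$y))
  if (any(codes < 0))
    warning(sum(codes < 0),
            " fold(s) had a singular covariance; scored as misclassified")
  lv <- levels(xy$y)
  predicted <- rep(NA_character_, length(codes))
  predicted[codes >= 0] <- lv[codes[codes >= 0] + 1L]
  correct <- !is.na(predicted) & predicted == as.character(xy$y)
  pred_f <- factor(ifelse(is.na(predicted), "<none>", predicted),
                   levels = c(levels(xy$y),
                              if (anyNA(predicted)) "<none>"))
  confusion <- table(true = xy$y, predicted = pred_f)
  structure(list(predicted = predicted, confusion = confusion,
                 cv_value = 100 * mean(correct), n = length(correct)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Leave-one-out CV: %.1f%% correct (%d observations)\n",
              x$cv_value, x$n))
  print(x$confusion)
  invisible(x)
}

## fast LOOCV proportion correct used inside stepwise search
loocv_prop <- function(X, y_codes, K) {
  codes <- cpp_lda_loocv(X, y_codes, K)
  mean(codes == y_codes)
}

#' Stepwise predictor selection by cross-validated classification
#'
#' Starting from the forced set (or, when none is forced, the single best
#' predictor by LOOCV), every single-variable inclusion and exclusion is
#' evaluated by LOOCV each round; the best move is accepted only when it
#' improves the proportion correctly classified by at least `improvement`
#' (absolute, default 0.05 = five percentage points). The selected set is
#' capped at `max_predictors` (default: one less than the number of
#' classes). Forced predictors (e.g. duration in behavioural-context
#' analyses) are never removed.
#'
#' @inheritParams fit_dfa
#' @param candidates candidate predictor names (pre-screened for
#'   collinearity)
#' @param improvement minimum absolute improvement in proportion correct
#' @param max_predictors maximum size of the selected set
#' @param forced predictors always kept in the model
#' @return a `stepwise_trace`: list with `selected`, `trace` (one row per
#'   evaluated round), `cv` (final [loocv()] result)
#' @export
stepwise_select <- function(table, class_column, candidates,
                            improvement = 0.05, max_predictors = NULL,
                            forced = character()) {
  if (length(candidates) == 0) stop("empty candidate set")
  candidates <- union(forced, candidates)
  keep <- complete.cases(table[, candidates, drop = FALSE])
  tab <- table[keep, , drop = FALSE]
  xy <- build_xy(tab, class_column, candidates)
  y_codes <- as.integer(xy$y) - 1L
  K <- nlevels(xy$y)
  max_predictors <- max_predictors %||% max(K - 1L, 1L)
  prop_of <- function(set) loocv_prop(xy$X[, set, drop = FALSE], y_codes, K)

  trace <- list()
  if (length(forced) > 0) {
    current <- forced
  } else {
    singles <- vapply(candidates, function(pr) prop_of(pr), numeric(1))
    current <- candidates[which.max(singles)]
    trace[[1]] <- data.frame(move = "start", predictor = current,
                             cv_prop = max(singles), accepted = TRUE,
                             stringsAsFactors = FALSE)
  }
  current_prop <- prop_of(current)
  repeat {
    moves <- list()
    if (length(current) < max_predictors)
      for (pr in setdiff(candidates, current))
        moves[[length(moves) + 1L]] <- list(move = "include", predictor = pr,
                                            set = c(current, pr))
    if (length(current) > 1)
      for (pr in setdiff(current, forced))
        moves[[length(moves) + 1L]] <- list(move = "exclude", predictor = pr,
                                            set = setdiff(current, pr))
    if (length(moves) == 0) break
    props <- vapply(moves, function(m) prop_of(m$set), numeric(1))
    best <- which.max(props)   # ties: first in candidate order
    accepted <- props[best] >= current_prop + improvement
    trace[[length(trace) + 1L]] <-
      data.frame(move = moves[[best]]$move,
                 predictor = moves[[best]]$predictor,
                 cv_prop = props[best], accepted = accepted,
                 stringsAsFactors = FALSE)
    if (!accepted) break
    current <- moves[[best]]$set
    current_prop <- props[best]
  }
  structure(list(selected = current,
                 trace = do.call(rbind, trace),
                 cv = loocv(tab, class_column, current),
                 improvement = improvement,
                 max_predictors = max_predictors, forced = forced),
            class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("Stepwise DFA selection:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("Final LOOCV: %.1f%%\n", x$cv$cv_value))
  invisible(x)
}
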