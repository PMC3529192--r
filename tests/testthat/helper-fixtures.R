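# Fixtures are built in code at test time. Expensive shared artifacts
# (a small audio dataset; the default-world pipeline report) are computed
# once per test run and memoized here.

fixture_env <- new.env(parent = emptyenv())

# small audio dataset: 2 groups x 3 individuals x 3 contexts x 3 calls
small_dataset <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- synthetic_config(n_groups = 2, individuals_per_group = 3,
                            calls_per_context = 3, seed = 42)
    dir <- file.path(tempdir(), "closecall-small")
    fixture_env$small <- list(config = cfg,
                              dataset = generate_dataset(cfg, dir))
  }
  fixture_env$small
}

small_features <- function() {
  if (is.null(fixture_env$small_features)) {
    ds <- small_dataset()$dataset
    fixture_env$small_features <-
      extract_features(ds$annotations, ds$dir)
  }
  fixture_env$small_features
}

# pure-feature table with known class structure (no audio): K classes,
# n_per calls each, `signal` of the p predictors shifted by class
feature_fixture <- function(K = 4, n_per = 6, p = 3, signal = 0,
                            effect = 2, seed = 1) {
  set.seed(seed)
  y <- rep(paste0("c", seq_len(K)), each = n_per)
  X <- matrix(rnorm(K * n_per * p), ncol = p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  if (signal > 0)
    X[, seq_len(signal)] <- X[, seq_len(signal), drop = FALSE] +
      effect * as.integer(factor(y))
  data.frame(class = y, X, stringsAsFactors = FALSE)
}

# crossed-design table: subjects observed under every test level
crossed_fixture <- function(n_subjects = 8, levels = c("A", "B"),
                            n_per_cell = 4, p = 3, level_effect = 0,
                            subject_sd = 1, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subj_off <- rnorm(p, 0, subject_sd)
    for (l in seq_along(levels)) {
      X <- matrix(rnorm(n_per_cell * p), ncol = p)
      X <- sweep(X, 2, subj_off, "+")
      X[, 1] <- X[, 1] + level_effect * l
      rows[[length(rows) + 1L]] <- data.frame(
        subject = paste0("s", s), level = levels[l], X,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:2)] <- paste0("x", seq_len(p))
  out
}

# the default-world pipeline run used by the acceptance suite; inference
# effort is reduced from the 1000-permutation default to keep the test run
# inside its CPU budget (a compute scale, not a world parameter)
acceptance_report <- function() {
  if (is.null(fixture_env$acceptance)) {
    cfg <- pipeline_config(
      output_dir = file.path(tempdir(), "closecall-acceptance"),
      n_permutations = 200, n_randomizations = 500, n_selections = 50,
      seed = 20260910)
    fixture_env$acceptance <- suppressWarnings(run_pipeline(cfg))
  }
  fixture_env$acceptance
}
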