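## End-to-end orchestration: simulate (or ingest) -> measure -> VIF screen
## -> stepwise cross-validated DFA -> bootstrap / permuted-DFA inference,
## reported per call segment (whole / noisy / harmonic) and per
## classification target (individual within group; behavioural context
## overall and pairwise; group; sex).

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a dataset first) or `"real"` (read
#'   an existing annotation table + audio)
#' @param output_dir where the synthetic dataset and reports are written
#' @param synth a [synthetic_config()] (synthetic mode)
#' @param annotation_path,audio_root inputs (real mode)
#' @param params [spectrogram_params()]
#' @param vif_threshold maximum admissible VIF
#' @param improvement stepwise absolute improvement margin (proportion)
#' @param n_permutations,n_randomizations,n_selections inference effort
#' @param min_calls,min_contexts,sample_per_individual inclusion rule:
#'   individuals need `min_calls` calls in each of at least `min_contexts`
#'   contexts; surplus calls are down-sampled to `sample_per_individual`
#'   per (individual, context) cell
#' @param seed master seed; every stage derives its own child seed from it
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            output_dir = tempfile("closecall-"),
                            synth = synthetic_config(),
                            annotation_path = NULL, audio_root = NULL,
                            params = spectrogram_params(),
                            vif_threshold = 2.5, improvement = 0.05,
                            n_permutations = 1000, n_randomizations = 1000,
                            n_selections = 100,
                            min_calls = 5, min_contexts = 2,
                            sample_per_individual = 5, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "real" && (is.null(annotation_path) || is.null(audio_root)))
    stop("real mode needs annotation_path and audio_root")
  structure(list(mode = mode, output_dir = output_dir, synth = synth,
                 annotation_path = annotation_path, audio_root = audio_root,
                 params = params, vif_threshold = vif_threshold,
                 improvement = improvement,
                 n_permutations = n_permutations,
                 n_randomizations = n_randomizations,
                 n_selections = n_selections, min_calls = min_calls,
                 min_contexts = min_contexts,
                 sample_per_individual = sample_per_individual,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Apply the call-inclusion rule and down-sample surplus calls
#'
#' Individuals are retained only if they have at least `min_calls` calls in
#' each of at least `min_contexts` behavioural contexts; within each
#' (individual, context) cell, surplus calls are down-sampled to
#' `sample_per_individual`, reproducibly under `seed`. Operates on calls;
#' all segment rows of a retained call are kept.
#'
#' @param feature_table an [extract_features()] result (or any data.frame
#'   with `call_id`, `individual_id`, `context`)
#' @inheritParams pipeline_config
#' @return the filtered feature table
#' @export
apply_inclusion_rules <- function(feature_table, min_calls = 5,
                                  min_contexts = 2,
                                  sample_per_individual = 5, seed = NULL) {
  calls <- unique(feature_table[, c("call_id", "individual_id", "context")])
  counts <- table(calls$individual_id, calls$context)
  eligible <- rownames(counts)[rowSums(counts >= min_calls) >= min_contexts]
  if (length(eligible) == 0)
    stop("no individual satisfies the inclusion rule (", min_calls,
         " calls in >= ", min_contexts, " contexts)")
  calls <- calls[calls$individual_id %in% eligible, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  kept_calls <- character(0)
  cells <- split(calls$call_id,
                 interaction(calls$individual_id, calls$context, drop = TRUE))
  for (ids in cells[order(names(cells))]) {
    if (length(ids) > sample_per_individual)
      ids <- sample(ids, sample_per_individual)
    kept_calls <- c(kept_calls, ids)
  }
  out <- feature_table[feature_table$call_id %in% kept_calls, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## feature columns usable as predictors for one segment table: numeric,
## not all-NA, not constant
usable_predictors <- function(seg_tab) {
  ok <- vapply(FEATURE_COLS, function(cc) {
    v <- seg_tab[[cc]]
    sum(!is.na(v)) >= nrow(seg_tab) * 0.5 && var(v, na.rm = TRUE) > 1e-12
  }, logical(1))
  FEATURE_COLS[ok]
}

context_pairs <- function(contexts) {
  if (length(contexts) < 2) return(list())
  combn(sort(contexts), 2, simplify = FALSE)
}

#' Run the full close-call analysis pipeline
#'
#' Executes, per call segment (whole, noisy, harmonic): VIF screening of
#' the 14 measured parameters under the individual-in-group mixed-model
#' structure; per-group individual classification (stepwise LOOCV DFA with
#' bootstrap chance correction); crossed pDFAs for behavioural context
#' (overall and pairwise, stepwise-selected predictors with duration always
#' retained); and nested pDFAs for the group and sex cues (full
#' VIF-retained predictor set, whole individuals as permutation units).
#' Every stage derives its own seed from the master seed, making the run
#' reproducible end to end.
#'
#' @param config a [pipeline_config()]
#' @return an `analysis_report`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "synthetic") {
    synth_cfg <- config$synth
    synth_cfg$seed <- derive_seed(config$seed, "synth")
    ds <- generate_dataset(synth_cfg, file.path(config$output_dir, "dataset"))
    annotations <- ds$annotations
    audio_root <- ds$dir
  } else {
    annotations <- read_annotation_table(config$annotation_path)
    audio_root <- config$audio_root
  }

  features <- extract_features(annotations, audio_root, config$params)
  features <- apply_inclusion_rules(
    features, config$min_calls, config$min_contexts,
    config$sample_per_individual, seed = derive_seed(config$seed, "include"))

  segments <- intersect(c("whole", "noisy", "harmonic"), unique(features$segment))
  vif_reports <- list()
  individual_rows <- list()
  context_rows <- list()
  context_overall <- list()
  group_sex_rows <- list()
  param_summary <- list()

  for (seg in segments) {
    seg_tab <- features[features$segment == seg, , drop = FALSE]
    preds <- usable_predictors(seg_tab)

    ## Table-4 analogue: per-context mean (sd) of every measured parameter
    for (ctx in sort(unique(seg_tab$context))) {
      sub <- seg_tab[seg_tab$context == ctx, FEATURE_COLS, drop = FALSE]
      param_summary[[paste(seg, ctx)]] <- data.frame(
        segment = seg, context = ctx, parameter = FEATURE_COLS,
        mean = vapply(sub, mean, numeric(1), na.rm = TRUE),
        sd = vapply(sub, sd, numeric(1), na.rm = TRUE),
        n = vapply(sub, function(v) sum(!is.na(v)), numeric(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    }

    vif_rep <- select_noncollinear(seg_tab, preds, config$vif_threshold)
    vif_reports[[seg]] <- vif_rep
    retained <- vif_rep$retained

    ## individual classification, per group (Table 2 analogue)
    for (g in sort(unique(seg_tab$group_id))) {
      sub <- seg_tab[seg_tab$group_id == g, , drop = FALSE]
      sub <- sub[complete.cases(sub[, retained, drop = FALSE]), , drop = FALSE]
      nk <- table(sub$individual_id)
      sub <- sub[sub$individual_id %in% names(nk)[nk >= 2], , drop = FALSE]
      K <- length(unique(sub$individual_id))
      if (K < 2) next
      ## a predictor can be constant within one group's subset even though
      ## it varies over the full table
      retained_g <- retained[vapply(retained, function(p)
        var(sub[[p]]) > 1e-12, logical(1))]
      if (length(retained_g) == 0) next
      sel <- stepwise_select(sub, "individual_id", retained_g,
                             improvement = config$improvement)
      boot <- bootstrap_chance(sub, "individual_id", sel$selected,
                               n_randomizations = config$n_randomizations,
                               seed = derive_seed(config$seed,
                                                  paste("boot", seg, g)))
      individual_rows[[paste(seg, g)]] <- data.frame(
        segment = seg, group = g, n_individuals = K,
        random_pct = 100 / K, cv_value = boot$observed,
        p_value = boot$p_value, stars = significance_stars(boot$p_value),
        predictors = paste(sel$selected, collapse = "+"),
        stringsAsFactors = FALSE)
    }

    ## behavioural context: overall + pairwise crossed pDFAs (Table 3)
    ctxs <- sort(unique(seg_tab$context))
    comparisons <- c(if (length(ctxs) > 2) list(ctxs), context_pairs(ctxs))
    for (cmp in comparisons) {
      sub <- seg_tab[seg_tab$context %in% cmp, , drop = FALSE]
      sub <- sub[complete.cases(sub[, retained, drop = FALSE]), , drop = FALSE]
      label <- if (length(cmp) > 2) "overall" else paste(cmp, collapse = "-")
      res <- tryCatch({
        sel <- stepwise_select(sub, "context",
                               setdiff(retained, "duration"),
                               improvement = config$improvement,
                               forced = "duration")
        pd <- suppressWarnings(crossed_pdfa(
          sub, "context", "individual_id", sel$selected,
          n_permutations = config$n_permutations,
          n_selections = config$n_selections,
          seed = derive_seed(config$seed, paste("pdfa", seg, label)),
          design = "crossed"))
        data.frame(segment = seg, comparison = label,
                   n_individuals = pd$n_subjects, ncce = pd$observed,
                   p_value = pd$p_value,
                   stars = significance_stars(pd$p_value),
                   predictors = paste(sel$selected, collapse = "+"),
                   stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(segment = seg, comparison = label,
                   n_individuals = NA_integer_, ncce = NA_real_,
                   p_value = NA_real_, stars = "",
                   predictors = paste("skipped:", conditionMessage(e)),
                   stringsAsFactors = FALSE))
      if (length(cmp) > 2) context_overall[[paste(seg, label)]] <- res
      else context_rows[[paste(seg, label)]] <- res
    }

    ## group and sex cues: nested pDFAs on the VIF-retained set
    for (fac in c("group_id", "sex")) {
      sub <- seg_tab[complete.cases(seg_tab[, retained, drop = FALSE]), ,
                     drop = FALSE]
      res <- tryCatch({
        if (length(unique(sub[[fac]])) < 2) stop("single level")
        pd <- suppressWarnings(crossed_pdfa(
          sub, fac, "individual_id", retained,
          n_permutations = config$n_permutations,
          n_selections = config$n_selections,
          seed = derive_seed(config$seed, paste("pdfa", seg, fac)),
          design = "nested"))
        data.frame(segment = seg, factor = fac,
                   n_individuals = pd$n_subjects, ncce = pd$observed,
                   p_value = pd$p_value,
                   stars = significance_stars(pd$p_value),
                   stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(segment = seg, factor = fac, n_individuals = NA_integer_,
                   ncce = NA_real_, p_value = NA_real_,
                   stars = paste("skipped:", conditionMessage(e)),
                   stringsAsFactors = FALSE))
      group_sex_rows[[paste(seg, fac)]] <- res
    }
  }

  report <- structure(list(
    individual_table = rbind_rows(individual_rows),
    context_table = rbind_rows(context_rows),
    context_overall = rbind_rows(context_overall),
    group_sex_table = rbind_rows(group_sex_rows),
    parameter_summary = rbind_rows(param_summary),
    vif_reports = vif_reports,
    features = features,
    provenance = list(seed = config$seed,
                      n_permutations = config$n_permutations,
                      n_randomizations = config$n_randomizations,
                      n_selections = config$n_selections,
                      package_version =
                        as.character(utils::packageVersion("closecall")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "analysis_report")
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Close-call analysis report ==\n")
  cat("(seed ", x$provenance$seed, ", ", x$provenance$n_permutations,
      " permutations; stars: *** P<0.001, ** P<0.01, * P<0.05, • P<0.1;",
      " no multiple-testing correction across pairwise comparisons)\n\n",
      sep = "")
  cat("-- Individual vocal cue (LOOCV % with bootstrap P), per group --\n")
  print(x$individual_table, row.names = FALSE, digits = 4)
  cat("\n-- Behavioural context (crossed pDFA, ncce % of cross-elements) --\n")
  if (!is.null(x$context_overall)) {
    print(x$context_overall, row.names = FALSE, digits = 4)
    cat("\n")
  }
  print(x$context_table, row.names = FALSE, digits = 4)
  cat("\n-- Group and sex cues (nested pDFA) --\n")
  print(x$group_sex_table, row.names = FALSE, digits = 4)
  invisible(x)
}
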