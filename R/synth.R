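## Synthetic two-segment close-call generator.
##
## A close call is modelled as an initial broadband "noisy" segment (the
## individually stable foundation: band-limited Gaussian noise shaped by a
## single spectral resonance, mixed with a weak harmonic stack) followed,
## unless suppressed, by a tonal "harmonic" segment (a decaying harmonic
## stack) whose duration and fundamental frequency grade with the caller's
## behavioural context (digging, searching, moving). Individuals carry
## stable offsets on every control; groups add a smaller shared offset; sex
## has, by construction, no effect on any control.

CONTEXTS <- c("digging", "searching", "moving")
CONTROL_NAMES <- c("noisy_duration", "noisy_f0", "harmonic_duration",
                   "harmonic_f0", "envelope_peak", "mix_ratio")

#' Specify the population distribution of one generator control
#'
#' @param mean population mean; either a scalar (context-invariant) or a
#'   named vector with one entry per behavioural context.
#' @param sd within-individual (call-to-call) sd, scalar or per-context.
#' @param individual_sd between-individual sd of the stable offset.
#' @param group_sd between-group sd of the shared offset.
#' @return a `control_spec` list
#' @export
control_spec <- function(mean, sd, individual_sd = 0, group_sd = 0) {
  stopifnot(all(sd >= 0), individual_sd >= 0, group_sd >= 0)
  structure(list(mean = mean, sd = sd, individual_sd = individual_sd,
                 group_sd = group_sd), class = "control_spec")
}

control_value <- function(spec, field, context) {
  v <- spec[[field]]
  if (length(v) > 1) {
    if (is.null(names(v)) || !context %in% names(v))
      stop("per-context control value lacks entry for context ", context)
    unname(v[[context]])
  } else as.numeric(v)
}

#' Configuration of the synthetic close-call world
#'
#' Defaults are calibrated to the published per-segment, per-context
#' population values for banded mongoose close calls: harmonic-segment
#' durations of 0.03 / 0.06 / 0.08 s and fundamental frequencies of
#' 350 / 410 / 472 Hz for digging / searching / moving, noisy-segment
#' duration around 0.03-0.04 s, noisy F0 near 230 Hz and a spectral
#' envelope peak near 375 Hz. Noisy-segment controls are context-invariant
#' (the segment is the stable individual signature); harmonic-segment
#' controls grade with context. Published sds are population sds, split
#' here into within-individual, between-individual and between-group
#' components such that their quadrature sum approximates the printed
#' value, with the between-individual share dominant in the noisy segment
#' and minor in the harmonic segment.
#'
#' @param n_groups number of social groups
#' @param individuals_per_group individuals per group
#' @param calls_per_context calls generated per individual per context
#' @param contexts subset of `c("digging", "searching", "moving")`
#' @param sample_rate WAV sampling rate, Hz
#' @param seed integer seed making a dataset reproducible
#' @param noisy_duration,noisy_f0,harmonic_duration,harmonic_f0,envelope_peak,mix_ratio
#'   [control_spec()] objects for the six generated controls (seconds, Hz,
#'   seconds, Hz, Hz, amplitude ratio of harmonic stack to noise in the
#'   noisy segment).
#' @param p_harmonic_absent_digging probability that a digging call lacks
#'   the harmonic segment entirely.
#' @return a validated `synthetic_config` list
#' @export
synthetic_config <- function(n_groups = 4,
                             individuals_per_group = 8,
                             calls_per_context = 5,
                             contexts = CONTEXTS,
                             sample_rate = 44100,
                             seed = 1L,
                             noisy_duration = control_spec(0.035, 0.006, 0.004, 0.002),
                             noisy_f0 = control_spec(230, 20, 80, 25),
                             harmonic_duration = control_spec(
                               c(digging = 0.03, searching = 0.06, moving = 0.08),
                               c(digging = 0.015, searching = 0.02, moving = 0.02),
                               0.005, 0.002),
                             harmonic_f0 = control_spec(
                               c(digging = 350, searching = 410, moving = 472),
                               50, 25, 12),
                             envelope_peak = control_spec(375, 30, 120, 40),
                             mix_ratio = control_spec(0.32, 0.04, 0.10, 0.03),
                             p_harmonic_absent_digging = 0.5) {
  cfg <- list(n_groups = n_groups,
              individuals_per_group = individuals_per_group,
              calls_per_context = calls_per_context,
              contexts = contexts, sample_rate = sample_rate, seed = seed,
              controls = list(noisy_duration = noisy_duration,
                              noisy_f0 = noisy_f0,
                              harmonic_duration = harmonic_duration,
                              harmonic_f0 = harmonic_f0,
                              envelope_peak = envelope_peak,
                              mix_ratio = mix_ratio),
              p_harmonic_absent_digging = p_harmonic_absent_digging)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_groups < 1 || cfg$individuals_per_group < 1)
    stop("configuration error: need at least one group and one individual")
  if (cfg$calls_per_context < 1)
    stop("configuration error: calls_per_context must be >= 1")
  if (!all(cfg$contexts %in% CONTEXTS) || length(cfg$contexts) < 1)
    stop("configuration error: contexts must be a non-empty subset of ",
         paste(CONTEXTS, collapse = "/"))
  if (cfg$sample_rate <= 0) stop("configuration error: sample_rate must be > 0")
  p <- cfg$p_harmonic_absent_digging
  if (is.na(p) || p < 0 || p > 1)
    stop("configuration error: p_harmonic_absent_digging must lie in [0, 1]")
  for (nm in CONTROL_NAMES) {
    sp <- cfg$controls[[nm]]
    if (is.null(sp)) stop("configuration error: missing control ", nm)
    if (any(sp$sd < 0) || sp$individual_sd < 0 || sp$group_sd < 0)
      stop("configuration error: negative sd for control ", nm)
    if (nm %in% c("noisy_duration", "harmonic_duration") &&
        any(unlist(sp$mean) <= 0))
      stop("configuration error: durations must be > 0")
  }
  invisible(TRUE)
}

#' Draw the stable profile of one individual
#'
#' Offsets are drawn once per individual (Normal(0, individual_sd) per
#' control) and reused for all of that individual's calls; the group offset
#' (Normal(0, group_sd) per control) is shared by all members of a group.
#' Sex is assigned in alternation and has no effect on any control: the sex
#' cue is null by construction.
#'
#' @param config a [synthetic_config()]
#' @param group_id group identifier
#' @param individual_id individual identifier
#' @param group_offsets named numeric vector of this group's offsets; drawn
#'   here when `NULL` (then the profile owns a private group draw).
#' @param sex `"F"` or `"M"`
#' @return an `individual_profile` list
#' @export
draw_individual_profile <- function(config, group_id,
                                    individual_id = paste0(group_id, "-i1"),
                                    group_offsets = NULL, sex = c("F", "M")) {
  validate_synthetic_config(config)
  sex <- match.arg(sex)
  if (is.null(group_offsets)) group_offsets <- draw_group_offsets(config)
  ind <- vapply(config$controls, function(sp) rnorm(1, 0, sp$individual_sd),
                numeric(1))
  structure(list(individual_id = individual_id, group_id = group_id,
                 sex = sex, individual_offsets = ind,
                 group_offsets = group_offsets),
            class = "individual_profile")
}

draw_group_offsets <- function(config) {
  vapply(config$controls, function(sp) rnorm(1, 0, sp$group_sd), numeric(1))
}

## realized value of one control for one call
draw_control <- function(config, profile, name, context, lower) {
  sp <- config$controls[[name]]
  mu <- control_value(sp, "mean", context) +
    profile$individual_offsets[[name]] + profile$group_offsets[[name]]
  sdv <- control_value(sp, "sd", context)
  rtruncnorm_lower(1, mu, sdv, lower)
}

harmonic_stack <- function(n, f0, sample_rate, n_partials = 6,
                           decay_db_per_partial = 6) {
  t <- seq_len(n) / sample_rate
  nyq <- sample_rate / 2
  x <- numeric(n)
  for (k in seq_len(n_partials)) {
    fk <- k * f0
    if (fk >= nyq) break
    x <- x + 10^(-decay_db_per_partial * (k - 1) / 20) * sin(2 * pi * fk * t)
  }
  x
}

## two-pole resonator (constriction of the noise spectrum around f_peak)
resonate <- function(noise, f_peak, sample_rate, bandwidth = 500) {
  r <- exp(-pi * bandwidth / sample_rate)
  theta <- 2 * pi * f_peak / sample_rate
  stats::filter(noise, filter = c(2 * r * cos(theta), -r^2),
                method = "recursive")
}

raised_cos_ramp <- function(n) (1 - cos(pi * seq_len(n) / (n + 1))) / 2

#' Synthesize one close call
#'
#' The noisy segment is resonator-shaped Gaussian noise mixed with a weak
#' harmonic stack at the individual's noisy-segment F0 (stack RMS =
#' `mix_ratio` times noise RMS, about -10 dB at the default ratio 0.32).
#' The harmonic segment is a harmonic stack with partial k attenuated by
#' 6(k-1) dB at the context- and individual-dependent F0. Segments are
#' joined by a 5 ms raised-cosine cross-fade; the annotated boundary sits
#' at the fade midpoint. In the digging context the harmonic segment is
#' suppressed entirely with probability `p_harmonic_absent_digging`.
#'
#' @param profile an [draw_individual_profile()] result
#' @param context one of the configured behavioural contexts
#' @param config the [synthetic_config()]
#' @param call_id identifier written into the annotation
#' @param audio_path path recorded in the annotation (file is not written
#'   here; see [generate_dataset()])
#' @return list with `waveform` (peak-normalized to 0.9), `annotation`
#'   (one-row data.frame in the annotation-table schema) and `truth` (the
#'   drawn control values, for round-trip validation)
#' @export
synthesize_call <- function(profile, context, config, call_id = "call-1",
                            audio_path = NA_character_) {
  validate_synthetic_config(config)
  if (!context %in% config$contexts)
    stop("unknown context: ", context)
  fs <- config$sample_rate
  min_dur <- 0.005                      # numerical floor: outlasts the fade

  noisy_dur <- draw_control(config, profile, "noisy_duration", context, min_dur)
  noisy_f0 <- draw_control(config, profile, "noisy_f0", context, 110)
  env_peak <- draw_control(config, profile, "envelope_peak", context, 150)
  mix <- min(draw_control(config, profile, "mix_ratio", context, 0.02), 0.95)

  harmonic_present <- TRUE
  if (identical(context, "digging") &&
      runif(1) < config$p_harmonic_absent_digging) harmonic_present <- FALSE
  if (harmonic_present) {
    harm_dur <- draw_control(config, profile, "harmonic_duration", context, min_dur)
    harm_f0 <- draw_control(config, profile, "harmonic_f0", context, 110)
  } else {
    harm_dur <- NA_real_
    harm_f0 <- NA_real_
  }

  ## the cross-fade straddles the annotated boundary (half in each
  ## segment), so each segment keeps its drawn duration exactly
  n1 <- max(round(noisy_dur * fs), round(min_dur * fs))
  if (harmonic_present) {
    n2 <- max(round(harm_dur * fs), round(min_dur * fs))
    nfade <- min(round(0.005 * fs), n1 - 1L, n2 - 1L)
    h2 <- nfade %/% 2L          # fade samples inside the harmonic span
    h1 <- nfade - h2            # fade samples inside the noisy span
  } else {
    n2 <- 0L; nfade <- 0L; h1 <- 0L; h2 <- 0L
  }
  noise <- resonate(rnorm(n1 + h2), env_peak, fs)
  noise <- noise / sqrt(mean(noise^2))
  stack <- harmonic_stack(n1 + h2, noisy_f0, fs)
  stack <- stack / sqrt(mean(stack^2)) * mix
  noisy <- as.numeric(noise + stack)

  if (harmonic_present) {
    harm <- harmonic_stack(n2 + h1, harm_f0, fs)
    harm <- harm / sqrt(mean(harm^2))
    ramp <- raised_cos_ramp(nfade)
    noisy[(n1 + h2 - nfade + 1L):(n1 + h2)] <-
      noisy[(n1 + h2 - nfade + 1L):(n1 + h2)] * rev(ramp)
    harm[seq_len(nfade)] <- harm[seq_len(nfade)] * ramp
    wav <- numeric(n1 + n2)
    wav[seq_len(n1 + h2)] <- noisy
    wav[(n1 - h1 + 1L):(n1 + n2)] <- wav[(n1 - h1 + 1L):(n1 + n2)] + harm
    boundary <- n1
  } else {
    wav <- noisy
    boundary <- n1
  }
  ## edge ramps against clicks in the 16-bit output
  nedge <- min(round(0.002 * fs), floor(length(wav) / 4))
  if (nedge > 0) {
    wav[seq_len(nedge)] <- wav[seq_len(nedge)] * raised_cos_ramp(nedge)
    wav[(length(wav) - nedge + 1L):length(wav)] <-
      wav[(length(wav) - nedge + 1L):length(wav)] * rev(raised_cos_ramp(nedge))
  }
  if (length(wav) == 0 || all(wav == 0)) stop("zero-length or silent call")
  wav <- wav / max(abs(wav)) * 0.9

  n_total <- length(wav)
  annotation <- data.frame(
    call_id = call_id, audio_path = audio_path,
    individual_id = profile$individual_id, group_id = profile$group_id,
    sex = profile$sex, context = context,
    whole_start = 0, whole_end = n_total / fs,
    noisy_start = 0, noisy_end = boundary / fs,
    harmonic_start = if (harmonic_present) boundary / fs else NA_real_,
    harmonic_end = if (harmonic_present) n_total / fs else NA_real_,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    call_id = call_id, individual_id = profile$individual_id,
    group_id = profile$group_id, sex = profile$sex, context = context,
    noisy_duration = boundary / fs, noisy_f0 = noisy_f0,
    harmonic_present = harmonic_present,
    harmonic_duration = if (harmonic_present) (n_total - boundary) / fs else NA_real_,
    harmonic_f0 = harm_f0, envelope_peak = env_peak, mix_ratio = mix,
    stringsAsFactors = FALSE)
  list(waveform = wav, annotation = annotation, truth = truth)
}

#' Generate a complete synthetic close-call dataset
#'
#' Writes one 16-bit PCM mono WAV per call plus a tab-separated annotation
#' table (`annotations.tsv`, times in seconds with six decimals) and a
#' ground-truth control table (`truth.tsv`). Every individual receives
#' `calls_per_context` calls in every configured context; the run is fully
#' reproducible from `(config, config$seed)`.
#'
#' @param config a [synthetic_config()]
#' @param output_dir writable directory (created if absent)
#' @return invisibly, a list with `annotations`, `truth` and the file paths
#' @export
generate_dataset <- function(config, output_dir) {
  validate_synthetic_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create output directory: ", output_dir)
  audio_dir <- file.path(output_dir, "audio")
  dir.create(audio_dir, showWarnings = FALSE)
  set.seed(config$seed)

  annotations <- list()
  truths <- list()
  idx <- 0L
  for (g in seq_len(config$n_groups)) {
    group_id <- sprintf("G%02d", g)
    group_offsets <- draw_group_offsets(config)
    for (i in seq_len(config$individuals_per_group)) {
      individual_id <- sprintf("%s-I%02d", group_id, i)
      sex <- if (i %% 2 == 1) "F" else "M"
      profile <- draw_individual_profile(config, group_id, individual_id,
                                         group_offsets, sex)
      for (ctx in config$contexts) {
        for (k in seq_len(config$calls_per_context)) {
          idx <- idx + 1L
          call_id <- sprintf("%s-%s-%02d", individual_id, ctx, k)
          rel_path <- file.path("audio", paste0(call_id, ".wav"))
          call <- synthesize_call(profile, ctx, config, call_id, rel_path)
          write_wav(call$waveform, file.path(output_dir, rel_path),
                    config$sample_rate)
          annotations[[idx]] <- call$annotation
          truths[[idx]] <- call$truth
        }
      }
    }
  }
  ann <- do.call(rbind, annotations)
  tru <- do.call(rbind, truths)
  ann_path <- file.path(output_dir, "annotations.tsv")
  write_annotation_table(ann, ann_path)
  write.table(tru, file.path(output_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(annotations = ann, truth = tru, dir = output_dir,
                 annotation_path = ann_path))
}

SPAN_COLS <- c("whole_start", "whole_end", "noisy_start", "noisy_end",
               "harmonic_start", "harmonic_end")

#' Write / read the segment-annotation table
#'
#' Tab-separated text with header; times in seconds printed with six
#' decimals; harmonic columns empty when the segment is absent.
#'
#' @param annotations annotation data.frame
#' @param path file path
#' @return `path` (write) or the annotation data.frame (read)
#' @export
write_annotation_table <- function(annotations, path) {
  out <- annotations
  for (cc in SPAN_COLS) {
    out[[cc]] <- ifelse(is.na(annotations[[cc]]), "",
                        sprintf("%.6f", annotations[[cc]]))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  ann <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", stringsAsFactors = FALSE)
  needed <- c("call_id", "audio_path", "individual_id", "group_id", "sex",
              "context", SPAN_COLS)
  missing <- setdiff(needed, names(ann))
  if (length(missing) > 0)
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "))
  for (cc in SPAN_COLS) ann[[cc]] <- suppressWarnings(as.numeric(ann[[cc]]))
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann) {
  bad <- with(ann, whole_start >= whole_end | noisy_start >= noisy_end |
                (!is.na(harmonic_start) & harmonic_start >= harmonic_end))
  if (any(bad)) stop("degenerate span (start >= end) in calls: ",
                     paste(ann$call_id[bad], collapse = ", "))
  bad <- with(ann, !is.na(harmonic_start) & noisy_end > harmonic_start + 1e-9)
  if (any(bad)) stop("noisy span does not precede harmonic span in calls: ",
                     paste(ann$call_id[bad], collapse = ", "))
  invisible(TRUE)
}
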