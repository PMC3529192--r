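## Spectrogram-based measurement of the 14 standard call parameters:
## duration, -20 dB bandwidth / min / max frequency, mean peak frequency,
## energy quartiles (Q25/Q50/Q75) of the mean spectrum and of the
## maximum-amplitude frame, mean F0, and the F0 transition onset (F0 at
## segment onset minus F0 at segment middle) and offset (middle minus end).

FEATURE_COLS <- c("duration", "bandwidth_mean", "f0_mean", "onset", "offset",
                  "max_freq", "min_freq", "peak_freq_mean",
                  "q25_mean", "q50_mean", "q75_mean",
                  "q25_max", "q50_max", "q75_max")

#' Short-time Fourier analysis parameters
#'
#' Defaults follow the field convention for these calls: 1024-point FFT,
#' Hamming window, 96.87% overlap at 44.1 kHz, giving a frequency
#' resolution of 43.07 Hz (reported as 43 Hz) and a hop of 32 samples.
#'
#' @param fft_size FFT length in samples (positive power of two)
#' @param overlap_fraction window overlap in `[0, 1)`
#' @param sample_rate sampling rate, Hz
#' @return a `spectrogram_params` list with derived `hop` (samples) and
#'   `bin_width` (Hz)
#' @export
spectrogram_params <- function(fft_size = 1024, overlap_fraction = 0.9687,
                               sample_rate = 44100) {
  stopifnot(fft_size > 0, bitwAnd(fft_size, fft_size - 1L) == 0,
            overlap_fraction >= 0, overlap_fraction < 1, sample_rate > 0)
  hop <- max(1L, as.integer(round(fft_size * (1 - overlap_fraction))))
  structure(list(fft_size = as.integer(fft_size),
                 overlap_fraction = overlap_fraction,
                 sample_rate = sample_rate, hop = hop,
                 bin_width = sample_rate / fft_size,
                 window = "hamming"),
            class = "spectrogram_params")
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Compute a power spectrogram
#'
#' @param waveform numeric vector; must be at least one window long
#' @param params [spectrogram_params()]
#' @return a `spectrogram`: list with `power` (bins x frames matrix),
#'   `freqs` (bin center frequencies, Hz, 0..Nyquist), `times` (frame
#'   center times, s) and `params`
#' @export
compute_spectrogram <- function(waveform, params = spectrogram_params()) {
  nfft <- params$fft_size
  if (length(waveform) < nfft)
    stop("waveform shorter than one analysis window (", nfft, " samples)")
  starts <- seq(1L, length(waveform) - nfft + 1L, by = params$hop)
  win <- hamming_window(nfft)
  frames <- vapply(starts, function(s) waveform[s:(s + nfft - 1L)] * win,
                   numeric(nfft))
  spec <- mvfft(frames)
  nb <- nfft %/% 2L + 1L
  power <- Mod(spec[seq_len(nb), , drop = FALSE])^2
  structure(list(power = power,
                 freqs = (seq_len(nb) - 1L) * params$bin_width,
                 times = (starts - 1L + nfft / 2) / params$sample_rate,
                 params = params),
            class = "spectrogram")
}

## normalized autocorrelation of one analysis window via FFT
acf_normalized <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  if (all(x == 0)) return(rep(0, max_lag))
  nfft <- 2^ceiling(log2(2 * n))
  sp <- fft(c(x, rep(0, nfft - n)))
  ac <- Re(fft(Mod(sp)^2, inverse = TRUE)) / nfft
  lags <- seq_len(max_lag)
  ## unbiased-style normalization so long lags are not penalized
  ac[lags + 1L] / (ac[1L] * (1 - lags / n))
}

#' Estimate the fundamental frequency of a voiced segment
#'
#' Normalized autocorrelation on short windows with parabolic peak
#' interpolation. To avoid octave errors with harmonic stacks, the smallest
#' lag whose autocorrelation reaches 85% of the global maximum is taken as
#' the period. Windows whose maximum normalized autocorrelation falls below
#' the voicing threshold are flagged unvoiced (`NA`).
#'
#' @param waveform segment samples
#' @param sample_rate Hz
#' @param search_range F0 search interval in Hz (default 100-1000)
#' @param window_sec analysis window length, s (default 0.03; shrunk to the
#'   segment length for short segments)
#' @param step_sec hop between F0 analysis points, s
#' @param voicing_threshold minimum normalized autocorrelation for a window
#'   to count as voiced
#' @return list with per-window `times` and `f0` (NA where unvoiced) plus
#'   the summary points `onset`, `middle`, `end` (first, temporally
#'   central and last voiced windows) and `mean` over voiced windows
#' @export
estimate_f0 <- function(waveform, sample_rate, search_range = c(100, 1000),
                        window_sec = 0.03, step_sec = 0.01,
                        voicing_threshold = 0.3) {
  min_len <- ceiling(2 * sample_rate / search_range[1])
  if (length(waveform) < min_len)
    stop("segment too short for F0 estimation: need >= 2 periods of ",
         search_range[1], " Hz (", min_len, " samples)")
  win_n <- min(round(window_sec * sample_rate), length(waveform))
  step_n <- max(1L, round(step_sec * sample_rate))
  starts <- seq(1L, length(waveform) - win_n + 1L, by = step_n)
  lag_min <- max(2L, floor(sample_rate / search_range[2]))
  lag_max <- min(ceiling(sample_rate / search_range[1]), win_n - 1L)
  f0 <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    x <- waveform[starts[i]:(starts[i] + win_n - 1L)]
    r <- acf_normalized(x, lag_max)
    rr <- r[lag_min:lag_max]
    rmax <- max(rr)
    if (!is.finite(rmax) || rmax < voicing_threshold) next
    ## smallest-lag peak within 85% of the maximum (octave-error guard)
    cand <- which(rr >= 0.85 * rmax)
    peak <- cand[1]
    while (peak < length(rr) && rr[peak + 1] > rr[peak]) peak <- peak + 1L
    lag <- lag_min + peak - 1L
    ## parabolic interpolation of the peak lag
    if (lag > lag_min && lag < lag_max) {
      y1 <- r[lag - 1L]; y2 <- r[lag]; y3 <- r[lag + 1L]
      denom <- y1 - 2 * y2 + y3
      delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
      lag <- lag + max(-0.5, min(0.5, delta))
    }
    f0[i] <- sample_rate / lag
  }
  times <- (starts - 1L + win_n / 2) / sample_rate
  voiced <- which(!is.na(f0))
  if (length(voiced) == 0) {
    summary <- list(onset = NA_real_, middle = NA_real_, end = NA_real_,
                    mean = NA_real_)
  } else {
    mid <- voiced[which.min(abs(times[voiced] - times[length(times)] / 2 -
                                  times[1] / 2))]
    summary <- list(onset = f0[voiced[1]], middle = f0[mid],
                    end = f0[voiced[length(voiced)]],
                    mean = mean(f0[voiced]))
  }
  c(list(times = times, f0 = f0, n_voiced = length(voiced)), summary)
}

## linear interpolation of the frequency at which cumulative energy
## reaches fraction q of the total
quartile_freq <- function(power, freqs, q) {
  cum <- cumsum(power)
  total <- cum[length(cum)]
  target <- q * total
  j <- which(cum >= target)[1]
  if (j == 1L) return(freqs[1])
  f_lo <- freqs[j - 1L]
  frac <- (target - cum[j - 1L]) / (cum[j] - cum[j - 1L])
  f_lo + frac * (freqs[j] - f_lo)
}

#' Measure the 14 acoustic parameters of one labelled segment
#'
#' The mean spectrum is the per-bin mean power over all frames inside the
#' span; quartiles are the lowest frequencies at which cumulative energy of
#' that spectrum reaches 25/50/75% of the total (linearly interpolated
#' within the crossing bin), and are measured again on the single frame
#' with maximum total power (the `_max` variants). Minimum and maximum
#' frequency are the lowest/highest bins whose mean-spectrum power exceeds
#' the spectrum peak minus `threshold_db` (default -20 dB); bandwidth is
#' their difference. F0-derived values come from [estimate_f0()] and are
#' `NA` for unvoiced segments.
#'
#' @param waveform full-call samples
#' @param span `c(start, end)` of the segment in seconds
#' @param params [spectrogram_params()]
#' @param threshold_db min/max-frequency threshold below the spectral peak
#' @param f0_search F0 search range, Hz
#' @return one-row data.frame with the `FEATURE_COLS` columns
#' @export
measure_segment <- function(waveform, span, params = spectrogram_params(),
                            threshold_db = 20, f0_search = c(100, 1000)) {
  fs <- params$sample_rate
  if (span[1] < 0 || span[2] * fs > length(waveform) + 0.5 ||
      span[2] <= span[1])
    stop("span outside audio or degenerate: [", span[1], ", ", span[2], "]")
  i1 <- floor(span[1] * fs) + 1L
  i2 <- min(as.integer(round(span[2] * fs)), length(waveform))
  seg <- waveform[i1:i2]
  if (all(seg == 0)) stop("all-zero signal in span")
  if (length(seg) < params$fft_size)
    stop("span shorter than one analysis window")
  spg <- compute_spectrogram(seg, params)
  mean_spec <- rowMeans(spg$power)
  freqs <- spg$freqs
  peak <- max(mean_spec)
  thr <- peak * 10^(-threshold_db / 10)
  above <- which(mean_spec > thr)
  min_freq <- freqs[above[1]]
  max_freq <- freqs[above[length(above)]]
  max_frame <- spg$power[, which.max(colSums(spg$power))]
  f0 <- tryCatch(estimate_f0(seg, fs, search_range = f0_search),
                 error = function(e) list(onset = NA_real_, middle = NA_real_,
                                          end = NA_real_, mean = NA_real_,
                                          n_voiced = 0L))
  ## a transition needs at least two voiced analysis points; with one, the
  ## differences are identically zero, which is absence of evidence, not a
  ## flat contour
  transitions_ok <- f0$n_voiced >= 2
  data.frame(duration = span[2] - span[1],
             bandwidth_mean = max_freq - min_freq,
             f0_mean = f0$mean,
             onset = if (transitions_ok) f0$onset - f0$middle else NA_real_,
             offset = if (transitions_ok) f0$middle - f0$end else NA_real_,
             max_freq = max_freq, min_freq = min_freq,
             peak_freq_mean = freqs[which.max(mean_spec)],
             q25_mean = quartile_freq(mean_spec, freqs, 0.25),
             q50_mean = quartile_freq(mean_spec, freqs, 0.50),
             q75_mean = quartile_freq(mean_spec, freqs, 0.75),
             q25_max = quartile_freq(max_frame, freqs, 0.25),
             q50_max = quartile_freq(max_frame, freqs, 0.50),
             q75_max = quartile_freq(max_frame, freqs, 0.75))
}

#' Extract the feature table for an annotated call set
#'
#' Produces one row per (call, segment kind) for segment kinds
#' `whole`, `noisy` and (where annotated) `harmonic`, carrying the call's
#' factors alongside the 14 measured parameters. Segments that cannot be
#' measured (shorter than one analysis window, span outside the audio) are
#' excluded and listed in the `exclusions` attribute; a per-individual,
#' per-context call-count completeness report is attached as the
#' `completeness` attribute.
#'
#' @param annotations annotation data.frame ([read_annotation_table()]
#'   schema)
#' @param audio_root directory that `audio_path` entries are relative to
#' @param params [spectrogram_params()]
#' @return a `feature_table` data.frame
#' @export
extract_features <- function(annotations, audio_root = ".",
                             params = spectrogram_params()) {
  validate_annotations(annotations)
  paths <- file.path(audio_root, annotations$audio_path)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing audio for calls: ",
         paste(annotations$call_id[missing], collapse = ", "))
  rows <- list()
  exclusions <- list()
  for (r in seq_len(nrow(annotations))) {
    a <- annotations[r, ]
    wav <- read_wav(paths[r])
    spans <- list(whole = c(a$whole_start, a$whole_end),
                  noisy = c(a$noisy_start, a$noisy_end))
    if (!is.na(a$harmonic_start))
      spans$harmonic <- c(a$harmonic_start, a$harmonic_end)
    for (kind in names(spans)) {
      feats <- tryCatch(measure_segment(wav$waveform, spans[[kind]], params),
                        error = function(e) e)
      if (inherits(feats, "error")) {
        exclusions[[length(exclusions) + 1L]] <-
          data.frame(call_id = a$call_id, segment = kind,
                     reason = conditionMessage(feats),
                     stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(call_id = a$call_id, segment = kind,
                   individual_id = a$individual_id, group_id = a$group_id,
                   sex = a$sex, context = a$context,
                   stringsAsFactors = FALSE),
        feats)
    }
  }
  if (length(rows) == 0) stop("no measurable segments in annotation set")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  completeness <- as.data.frame(table(
    individual_id = annotations$individual_id,
    context = annotations$context), stringsAsFactors = FALSE)
  names(completeness)[3] <- "n_calls"
  attr(tab, "completeness") <- completeness
  attr(tab, "exclusions") <-
    if (length(exclusions)) do.call(rbind, exclusions) else
      data.frame(call_id = character(), segment = character(),
                 reason = character(), stringsAsFactors = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  tab
}
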