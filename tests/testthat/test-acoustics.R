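fs <- 44100

test_that("analysis parameters derive bin width 43 Hz and hop 32 samples", {
  p <- spectrogram_params(fft_size = 1024, overlap_fraction = 0.9687,
                          sample_rate = fs)
  expect_equal(p$bin_width, fs / 1024)       # 43.07 Hz, reported as 43
  expect_equal(round(p$bin_width), 43)
  expect_equal(p$hop, 32L)                   # round(1024 * 0.0313)
  expect_error(spectrogram_params(fft_size = 1000), "fft_size")
})

test_that("a bin-centered tone peaks in its own bin in every frame", {
  p <- spectrogram_params()
  f <- 10 * p$bin_width                      # 430.66 Hz, center of bin 11
  x <- sin(2 * pi * f * seq_len(4096) / fs)
  spg <- compute_spectrogram(x, p)
  peaks <- apply(spg$power, 2, which.max)
  expect_true(all(peaks == 11L))             # 1-based: bin 0 is row 1
  expect_error(compute_spectrogram(x[1:500], p), "shorter")
})

test_that("F0 estimation: pure tone, harmonic stack, noise", {
  t <- seq_len(round(0.2 * fs)) / fs
  est <- estimate_f0(sin(2 * pi * 440 * t), fs)
  for (point in c("onset", "middle", "end"))
    expect_equal(est[[point]], 440, tolerance = 43 / 440)
  # harmonic stack: no octave error
  stack <- rowSums(sapply(1:5, function(k)
    10^(-(k - 1) * 0.3) * sin(2 * pi * k * 350 * t)))
  est <- estimate_f0(stack, fs)
  expect_equal(est$mean, 350, tolerance = 5 / 350)
  # white noise: unvoiced
  set.seed(1)
  est <- estimate_f0(rnorm(length(t)), fs)
  expect_true(is.na(est$mean))
  expect_error(estimate_f0(sin(2 * pi * 440 * (1:200) / fs), fs),
               "too short")
})

test_that("segment measurement on known signals", {
  t <- seq_len(round(0.15 * fs)) / fs
  x <- sin(2 * pi * 440 * t)
  f <- measure_segment(x, c(0, 0.1))
  expect_equal(f$duration, 0.1)
  # single-line spectrum: quartiles collapse onto the tone
  expect_equal(f$q25_mean, 440, tolerance = 0.15)
  expect_equal(f$q50_mean, 440, tolerance = 0.15)
  expect_equal(f$q75_mean, 440, tolerance = 0.15)
  expect_lt(f$bandwidth_mean, 3 * 43.07)
  # constant F0: transition onset and offset vanish
  expect_equal(f$onset, 0, tolerance = 2)
  expect_equal(f$offset, 0, tolerance = 2)
  # quartile ordering and min/max bracketing the peak
  expect_lte(f$q25_mean, f$q50_mean)
  expect_lte(f$q50_mean, f$q75_mean)
  expect_lte(f$min_freq, f$peak_freq_mean)
  expect_lte(f$peak_freq_mean, f$max_freq)
  expect_error(measure_segment(x, c(0, 1)), "outside")
  expect_error(measure_segment(numeric(5000), c(0, 0.1)), "all-zero")
})

test_that("linear chirp 500 -> 300 Hz gives onset and offset near +100 Hz", {
  dur <- 0.3
  n <- round(dur * fs)
  tt <- seq_len(n) / fs
  # instantaneous frequency 500 -> 300 Hz over the span
  phase <- 2 * pi * (500 * tt - 0.5 * (200 / dur) * tt^2)
  f <- measure_segment(sin(phase), c(0, dur))
  expect_equal(f$onset, 100, tolerance = 25)
  expect_equal(f$offset, 100, tolerance = 25)
})

test_that("quartile monotonicity and energy normalization hold on random signals", {
  set.seed(21)
  p <- spectrogram_params()
  for (i in 1:12) {
    x <- rnorm(3000) * runif(1, 0.1, 1)
    if (i %% 2 == 0) x <- x + sin(2 * pi * runif(1, 150, 5000) * seq_len(3000) / fs)
    f <- measure_segment(x, c(0, 3000 / fs), p)
    expect_lte(f$q25_mean, f$q50_mean)
    expect_lte(f$q50_mean, f$q75_mean)
    expect_lte(f$q25_max, f$q50_max)
    expect_lte(f$q50_max, f$q75_max)
    # cumulative energy is normalized: the 100% quartile is the last bin
    spg <- compute_spectrogram(x, p)
    ms <- rowMeans(spg$power)
    expect_equal(closecall:::quartile_freq(ms, spg$freqs, 1),
                 spg$freqs[length(spg$freqs)])
  }
})

test_that("tightening the threshold toward 0 dB never widens the bandwidth", {
  set.seed(3)
  x <- as.numeric(stats::filter(rnorm(4000), 0.9, method = "recursive")) +
    sin(2 * pi * 800 * seq_len(4000) / fs)
  bw <- vapply(c(30, 20, 10, 6, 3), function(db)
    measure_segment(x, c(0, 4000 / fs), threshold_db = db)$bandwidth_mean,
    numeric(1))
  expect_true(all(diff(bw) <= 1e-9))
})

test_that("extraction produces per-segment rows with factors and propagates absence", {
  ds <- small_dataset()$dataset
  ft <- small_features()
  n_calls <- nrow(ds$annotations)
  n_harm_ann <- sum(!is.na(ds$annotations$harmonic_start))
  excl <- attr(ft, "exclusions")
  expect_equal(nrow(ft) + nrow(excl), 2 * n_calls + n_harm_ann)
  # suppressed digging harmonics yield no harmonic rows
  absent <- ds$annotations$call_id[is.na(ds$annotations$harmonic_start)]
  expect_false(any(ft$call_id[ft$segment == "harmonic"] %in% absent))
  expect_true(all(c("individual_id", "group_id", "sex", "context")
                  %in% names(ft)))
  comp <- attr(ft, "completeness")
  expect_equal(sum(comp$n_calls), n_calls)
  expect_error(extract_features(ds$annotations, tempdir()), "missing audio")
})

test_that("round trip: measured durations and F0 match the generator's truth", {
  ds <- small_dataset()$dataset
  ft <- small_features()
  harm <- merge(ft[ft$segment == "harmonic",
                   c("call_id", "duration", "f0_mean")],
                ds$truth[, c("call_id", "harmonic_duration", "harmonic_f0")])
  # duration to one hop equivalent; F0 within 5% of the drawn value
  expect_lt(max(abs(harm$duration - harm$harmonic_duration)), 32 / fs)
  expect_lt(max(abs(harm$f0_mean - harm$harmonic_f0) / harm$harmonic_f0),
            0.05)
  # extracted harmonic durations keep the context ordering
  m <- tapply(harm$duration,
              ds$truth$context[match(harm$call_id, ds$truth$call_id)], mean)
  expect_lt(m[["digging"]], m[["searching"]])
  expect_lt(m[["searching"]], m[["moving"]])
})
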