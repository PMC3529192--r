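test_that("configuration invariants are enforced", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(calls_per_context = 0), "calls_per_context")
  expect_error(synthetic_config(p_harmonic_absent_digging = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(contexts = "flying"), "contexts")
  expect_error(
    synthetic_config(noisy_duration = control_spec(-0.01, 0.001)),
    "durations")
  expect_error(control_spec(1, -1), "sd")
})

test_that("default control means follow the published per-segment values", {
  cfg <- synthetic_config()
  hd <- cfg$controls$harmonic_duration$mean
  expect_equal(unname(hd[c("digging", "searching", "moving")]),
               c(0.03, 0.06, 0.08))
  hf <- cfg$controls$harmonic_f0$mean
  expect_equal(unname(hf[c("digging", "searching", "moving")]),
               c(350, 410, 472))
  nd <- cfg$controls$noisy_duration$mean
  expect_gte(nd, 0.03); expect_lte(nd, 0.04)
})

test_that("individual profiles: determinism, degenerate sd, offset scale", {
  cfg <- synthetic_config(seed = 1)
  set.seed(99)
  p1 <- draw_individual_profile(cfg, "G01", "G01-I01")
  set.seed(99)
  p2 <- draw_individual_profile(cfg, "G01", "G01-I01")
  expect_identical(p1$individual_offsets, p2$individual_offsets)

  # degenerate sd: all individuals in a group share expected controls
  cfg0 <- synthetic_config(
    noisy_f0 = control_spec(230, 20, individual_sd = 0, group_sd = 0))
  offs <- replicate(5, draw_individual_profile(
    cfg0, "G01", group_offsets = setNames(rep(0, 6), names(cfg0$controls))
  )$individual_offsets[["noisy_f0"]])
  expect_true(all(offs == 0))

  # Monte-Carlo: offsets follow Normal(0, individual_sd)
  cfg50 <- synthetic_config(noisy_f0 = control_spec(230, 20, 50, 0))
  set.seed(123)
  g0 <- setNames(rep(0, 6), names(cfg50$controls))
  offs <- replicate(1000, draw_individual_profile(
    cfg50, "G01", group_offsets = g0)$individual_offsets[["noisy_f0"]])
  expect_gt(sd(offs), 45)
  expect_lt(sd(offs), 55)
})

test_that("forced harmonic suppression yields a noisy-only call", {
  cfg <- synthetic_config(p_harmonic_absent_digging = 1, seed = 2)
  set.seed(5)
  profile <- draw_individual_profile(cfg, "G01")
  call <- synthesize_call(profile, "digging", cfg)
  expect_true(is.na(call$annotation$harmonic_start))
  expect_equal(call$annotation$whole_end, call$annotation$noisy_end)
  expect_error(synthesize_call(profile, "flying", cfg), "unknown context")
})

test_that("with all sds zero the moving harmonic span is 0.08 s to a sample", {
  zero <- function(mean) control_spec(mean, 0, 0, 0)
  cfg <- synthetic_config(
    noisy_duration = zero(0.035), noisy_f0 = zero(230),
    harmonic_duration = control_spec(
      c(digging = 0.03, searching = 0.06, moving = 0.08), 0, 0, 0),
    harmonic_f0 = control_spec(
      c(digging = 350, searching = 410, moving = 472), 0, 0, 0),
    envelope_peak = zero(375), mix_ratio = zero(0.32))
  set.seed(7)
  profile <- draw_individual_profile(cfg, "G01")
  call <- synthesize_call(profile, "moving", cfg)
  span <- call$annotation$harmonic_end - call$annotation$harmonic_start
  expect_lt(abs(span - 0.08), 1.5 / 44100)           # one-sample rounding
  expect_lt(abs(call$annotation$noisy_end - 0.035), 1.5 / 44100)
})

test_that("dataset generation counts, spans and determinism", {
  cfg <- synthetic_config(n_groups = 2, individuals_per_group = 4,
                          calls_per_context = 5, seed = 31)
  d1 <- file.path(tempdir(), "ds-det-1")
  d2 <- file.path(tempdir(), "ds-det-2")
  ds1 <- generate_dataset(cfg, d1)
  ds2 <- generate_dataset(cfg, d2)
  expect_equal(nrow(ds1$annotations), 2 * 4 * 3 * 5)
  expect_equal(length(list.files(file.path(d1, "audio"), "\\.wav$")), 120)
  # byte-identical annotation tables under the same (config, seed)
  expect_identical(readLines(file.path(d1, "annotations.tsv")),
                   readLines(file.path(d2, "annotations.tsv")))
  # every individual has calls_per_context calls in every context
  counts <- table(ds1$annotations$individual_id, ds1$annotations$context)
  expect_true(all(counts == 5))
  # spans are valid and ordered
  expect_silent(validate_annotations <- read_annotation_table(
    file.path(d1, "annotations.tsv")))
})

test_that("generated controls grade with context and stay stable within individuals", {
  ds <- small_dataset()$dataset
  tru <- ds$truth
  # context gradation of harmonic duration (strict ordering of means)
  m <- tapply(tru$harmonic_duration, tru$context, mean, na.rm = TRUE)
  expect_lt(m[["digging"]], m[["searching"]])
  expect_lt(m[["searching"]], m[["moving"]])
  # per-context means near the configured 0.03 / 0.06 / 0.08 s
  cfg <- small_dataset()$config
  for (ctx in c("searching", "moving")) {
    v <- tru$harmonic_duration[tru$context == ctx]
    target <- cfg$controls$harmonic_duration$mean[[ctx]]
    expect_lt(abs(mean(v) - target), 2 * sd(v) / sqrt(length(v)) + 0.004)
  }
  # within-individual stability: between-individual variance of the noisy
  # envelope peak exceeds within-individual variance
  vb <- var(tapply(tru$envelope_peak, tru$individual_id, mean))
  vw <- mean(tapply(tru$envelope_peak, tru$individual_id, var))
  expect_gt(vb / vw, 1)
})

test_that("sex has no effect on any generated control (null cue)", {
  cfg <- synthetic_config(n_groups = 1, individuals_per_group = 2,
                          calls_per_context = 1, seed = 77)
  set.seed(77)
  g0 <- setNames(rep(0, 6), names(cfg$controls))
  profs <- lapply(seq_len(500), function(i)
    draw_individual_profile(cfg, "G01", paste0("I", i), g0,
                            sex = if (i %% 2) "F" else "M"))
  sexes <- vapply(profs, `[[`, character(1), "sex")
  for (ctrl in names(cfg$controls)) {
    offs <- vapply(profs, function(p) p$individual_offsets[[ctrl]],
                   numeric(1))
    if (sd(offs) == 0) next
    p <- t.test(offs[sexes == "F"], offs[sexes == "M"])$p.value
    expect_gt(p, 0.01)
  }
})
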