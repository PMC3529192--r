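---
title: "Methods: segmented close-call analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented close-call analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Short, low-amplitude contact calls ("close calls") of group-living
mammals such as the banded mongoose are single-syllable but internally
structured: an initial broadband **noisy segment** that is stable within
an individual across situations, followed — except during digging, when
it is often missing — by a tonal **harmonic segment** whose duration and
fundamental frequency (F0) grade with the caller's current behaviour
(digging, searching, moving between foraging patches). The package
implements the complete analysis chain needed to demonstrate this
*temporal segregation of information*: measure standard bioacoustic
parameters per labelled segment, screen them for multicollinearity under
the repeated-measures structure, classify calls by individual, context,
group and sex with cross-validated discriminant analysis, and attach
permutation-based significance that respects repeated sampling of
individuals nested in social groups. A calibrated synthetic call
generator provides a ground-truth world in which every stage can be
validated end to end.

## The synthetic world

`synthetic_config()` describes a population of callers. Each of six
generated controls (noisy-segment duration and F0, harmonic-segment
duration and F0, spectral-envelope peak, noise/harmonic mix ratio) has a
population mean, a within-individual (call-to-call) sd, a
between-individual sd and a between-group sd. An individual draws one
offset per control and keeps it for life; a group adds a smaller shared
offset; sex is assigned but never influences any control — the sex cue
is null *by construction*, which is what makes the pipeline's sex
analysis a type-I-error probe.

Default calibration follows the published per-segment population values
for banded mongoose close calls:

* harmonic duration 0.03 / 0.06 / 0.08 s and harmonic F0 350 / 410 /
  472 Hz for digging / searching / moving — the graded context cue;
* noisy-segment duration ≈ 0.035 s, noisy F0 ≈ 230 Hz, envelope peak
  ≈ 375 Hz, context-invariant. The published per-context noisy-segment
  means differ only within rounding (0.03–0.04 s) and the segment is
  described as stable across contexts, so the generator treats those
  differences as sampling noise. This is what makes "no context cue in
  the noisy segment" true in the generated world.

Published sds are *population* sds; the defaults split each into
components whose quadrature sum approximates the printed value, with the
between-individual share dominant for noisy-segment controls (e.g. noisy
F0: 80 Hz individual, 25 Hz group, 20 Hz within, vs a printed ≈ 94–138
Hz) and minor for harmonic-segment controls. That split is the package's
modelling choice — the published values only constrain the totals — and it
reproduces the published pattern: strong, significant individual
classification from the noisy segment, graded and significant context
classification from the harmonic segment. In the default world the
harmonic segment also retains a *mild* individual signature (the field
data show the same tendency — harmonic CV-values above chance but not
significant); this is deliberate, not tuned away.

Waveforms are the simplest signals whose measurements land in the
published ranges: the noisy segment is Gaussian noise shaped by a
two-pole resonator at the individual's envelope peak plus a −10 dB
harmonic stack at the noisy F0; the harmonic segment is a harmonic stack
with partial *k* attenuated by 6(*k* − 1) dB. Segments join through a
5 ms raised-cosine cross-fade that *straddles* the annotated boundary,
so each segment keeps its drawn duration exactly and the annotation
falls on the fade midpoint. Durations and frequencies are drawn from
normals truncated below (inverse-CDF sampling; durations additionally
floored at 5 ms so a segment always outlasts the fade). A digging call
loses its harmonic segment entirely with probability
`p_harmonic_absent_digging` (default 0.5: the published digging-context
duration of 0.01 ± 0.02 s *including* absences and the ≈ 0.03 s among
present segments are approximately reconciled at that rate).

What the generator does **not** emulate: vocal-tract resonances and
formants, background noise, microphone transfer functions, amplitude
cues, or temporal patterns across calls. A green test on synthetic data
therefore establishes that the *statistical machinery* recovers a known
ground truth, not that the measurements would be accurate on field
recordings.

## Acoustic measurement

The analysis grid is a 1024-point FFT with a Hamming window and 96.87 %
overlap at 44.1 kHz: bin width 43.07 Hz (reported as 43 Hz), hop 32
samples. (A published figure caption gives 97.87 % overlap and the text
a 0.07 ms time step; both are inconsistent with the 1024/96.87 %
combination and are treated as typos.)

Per labelled segment (whole call, noisy, harmonic — the harmonic row is
absent when the annotation has no harmonic span), 14 parameters are
measured. The mean spectrum is the per-bin mean power over frames inside
the span. Energy quartiles (Q25/Q50/Q75) are the lowest frequencies at
which cumulative energy reaches the target fraction, linearly
interpolated within the crossing bin to remove the 43 Hz quantization;
they are measured on the mean spectrum and again on the single frame
with maximum total power. Minimum/maximum frequency use a −20 dB
threshold relative to the mean-spectrum peak (the convention of the
measurement software the field uses); bandwidth is their difference,
which makes bandwidth monotone in the threshold by construction.

F0 is estimated by normalized autocorrelation on 30 ms windows (10 ms
steps, search range 100–1000 Hz, voicing threshold 0.3, parabolic peak
interpolation); octave errors with harmonic stacks are avoided by taking
the smallest lag reaching 85 % of the autocorrelation maximum. The
transition onset is F0 at the first voiced window minus F0 at the
temporally central voiced window; the offset is the central minus the
last. Two practical consequences:

* The synthetic noisy segment sits below the voicing threshold most of
  the time (it is, after all, shaped noise), so its F0-derived columns
  are largely `NA` and the pipeline drops them from that segment's
  predictor set. The individual signature travels through the spectral
  envelope (quartiles, peak, min/max frequency) instead.
* Segments shorter than one analysis window (23 ms) cannot be measured
  and are excluded with a logged reason — exactly the fate of very short
  digging harmonics, which is why per-comparison sample sizes shrink for
  digging pairs, as they do in the field data.

## Collinearity screening

For each predictor *j*, a linear mixed model regresses *j* on all other
predictors with random intercepts for group and individual-within-group
(lme4), and VIF*j* = 1/(1 − R²*j*) with R² the fixed-effects share of
fixed + residual variance. Random-intercept variance is deliberately
excluded from the denominator: folding it in would understate
collinearity among the fixed effects (the alternative is available via
`r2_denominator = "fixed_resid_random"`). The REML residual variance is
put on the same n − 1 denominator as `var()`, which makes the VIF agree
*exactly* with the classical OLS VIF whenever the variance components
hit zero; with few calls per individual REML may claim a spurious sliver
of random variance, so exact agreement with OLS is asymptotic in
calls-per-individual (the test suite states that world at 10 × 100).
Selection is greedy: drop the largest VIF above the 2.5 threshold,
recompute, repeat; ties break by the fixed predictor order, perfectly
collinear predictors get a capped VIF (10^6) with a warning.

## Discriminant classification

`fit_dfa()` is the standard pooled within-class covariance linear
discriminant with equal priors (the balanced five-calls-per-individual
design makes equal priors natural). Classification minimizes Mahalanobis
distance to the class mean; ties go to the first label in order.
Leave-one-out cross-validation refits without each observation (the
heavy loops run in compiled code); a fold with a singular covariance
scores its observation as misclassified, with a warning, so *n* is never
silently reduced. Reported "eigenvalues" are on the class-mean
covariance scale (no class-size weighting), so coincident class means
give values near zero.

Stepwise selection starts from the forced set (duration is always forced
in behavioural-context analyses) or, absent one, the best single
predictor by LOOCV; each round evaluates every single-variable inclusion
and exclusion by LOOCV and accepts the best move only if it improves the
proportion correct by at least 0.05 *absolute* — the "5 % improvement"
rule read as five percentage points, the convention of the stepwise
classification tool this workflow descends from. The selected set is
capped at one less than the number of classes. Whether the original
workflow used LOOCV or k-fold inside selection is not recorded; LOOCV is
used throughout for consistency.

## Inference

**Bootstrap chance correction** (individual identity): the observed
LOOCV CV-value is compared with CV-values under label permutation;
P = (1 + #{null ≥ observed})/(1 + n). The add-one estimator keeps
P ≥ 1/(n + 1) and matches a reported minimum of P < 0.001 at 1000
randomizations.

**Crossed pDFA** (behavioural context): the test statistic is *ncce*,
the mean number of correctly cross-classified elements over balanced
selections, reported as a **percentage of cross-elements** — the
published values are unitless and inconsistent with raw counts, and the
percentage scale is the only one that fits them all. Each selection
assigns a fixed number of calls per (individual × context) cell —
floor(2/3) of the smallest cell, minimum 1, configurable — to training
and the rest to the cross-set. Permutations shuffle context labels
*within* each individual, conserving the individual's per-level call
counts (asserted on every draw); additional factors can be held constant
by stratifying the permutation. Individuals lacking two contexts with
two measurable calls each are excluded with a warning, so eligibility is
recomputed per comparison, which is why the reported *n* differs across
pairwise tests.

**Nested pDFA** (group and sex, which are constant within an
individual): whole individuals are the permutation units — their labels
are re-assigned across individuals, and training/cross splits select
whole individuals per level — so calls of one individual never straddle
the permutation unit.

## Pipeline and reporting

`run_pipeline()` chains simulate (or ingest) → measure → inclusion rule
(≥ 5 calls in ≥ 2 contexts; surplus cells down-sampled to 5,
reproducibly) → VIF screen → per-group individual classification with
bootstrap significance → context pDFAs (overall and pairwise,
stepwise-selected predictors with duration forced) → group and sex
nested pDFAs. Group and sex pDFAs use the full VIF-retained predictor
set rather than a stepwise-selected one: the permutation null cannot
re-run a selection that was optimized against the tested factor, and for
a two-level factor the stepwise cap would reduce to cherry-picking a
single best predictor. Every stage derives its own seed from the master
seed, so the whole report regenerates bit-identically. Stars follow the
usual convention (␣•␣* ** *** at 0.1/0.05/0.01/0.001); no
multiple-testing correction is applied across the pairwise context
comparisons, matching the original workflow, and the report footer says
so.

## Numerical choices and degenerate inputs

* Truncated draws use the inverse CDF, exact even when an individual's
  offsets leave almost no mass above the bound.
* Spectrogram frames require the full window; measurement errors on
  shorter spans are caught per segment and logged, never fatal to the
  table.
* Perfect collinearity yields capped VIFs, not failures; constant
  predictors are an error.
* LOOCV folds with singular covariances are misclassifications by fiat
  (keeps *n* constant); whole fits with singular pooled covariance error
  and name the offending predictors.
* P-values are never 0 by construction; their floor 1/(n_perm + 1) is
  part of the contract.

## Known limitations

* The measured F0 of genuinely noisy segments is mostly undefined; the
  individual cue there is an envelope cue. Field F0 values for noisy
  segments reported by interactive software likely reflect similar
  near-threshold behaviour.
* The exact "adapted VIF" used in the original workflow is unpublished;
  only its OLS limit is verifiable, and this package's mixed VIF is its
  own declared construction.
* The published ncce scale (count vs percentage) is undefined in the
  source; the percentage reading cannot be cross-checked without the
  deposited recordings.
* Type-I calibration of the permutation tests is demonstrated on
  feature-level nulls; audio-level replicate calibration would cost two
  orders of magnitude more compute and is not part of the test suite.
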