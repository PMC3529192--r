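# closecall

Tools for analysing how single-syllable close calls — the short,
low-amplitude contact calls that group-living mammals such as the banded
mongoose (*Mungos mungo*) emit almost continuously while foraging —
encode several kinds of information at once in temporally distinct
segments:

* an **initial noisy segment** carrying a stable *individual signature*
  (and a weaker group signature),
* a **terminal harmonic segment** whose duration and fundamental
  frequency grade with the caller's current *behavioural context*
  (digging, searching, moving).

The package implements the full analysis chain from raw WAV audio to
significance tables, plus a calibrated synthetic call generator that
provides ground truth for validating every stage:

1. **synthesis** — two-segment calls (resonator-shaped noise + harmonic
   stack) with controllable individual, group, context and (null) sex
   structure; WAV output and a segment-annotation table;
2. **measurement** — 1024-point FFT spectrograms (Hamming, 96.87 %
   overlap, 43 Hz resolution) and the 14 standard parameters per
   labelled segment: duration, −20 dB bandwidth / min / max frequency,
   mean peak frequency, energy quartiles Q25/Q50/Q75 of the mean
   spectrum and of the maximum-amplitude frame, mean F0 and the F0
   transition onset/offset;
3. **collinearity screening** — variance inflation factors computed
   under the repeated-measures structure (random intercepts for group
   and individual-within-group, lme4), greedy elimination at VIF ≤ 2.5;
4. **classification** — linear discriminant analysis with leave-one-out
   cross-validation (LOOCV) and stepwise variable selection under an
   absolute 5-percentage-point improvement rule;
5. **inference** — bootstrap chance correction for CV-values
   (`P = (1 + #{null ≥ observed}) / (1 + n)`), and permuted DFA (pDFA)
   with the *ncce* statistic (mean % of correctly cross-classified
   elements over balanced training-set selections): *crossed* design for
   within-individual factors (context; labels permuted within
   individuals) and *nested* design for between-individual factors
   (group, sex; whole individuals as permutation units);
6. **pipeline** — inclusion rule (≥ 5 calls in ≥ 2 contexts,
   down-sampling to 5 per cell), per-group individual classification,
   overall + pairwise context pDFAs, group/sex pDFAs, and a
   reproducible report.

## Worked example

```r
library(closecall)

## a small synthetic world: 2 groups x 3 individuals x 3 contexts x 3 calls
cfg <- synthetic_config(n_groups = 2, individuals_per_group = 3,
                        calls_per_context = 3, seed = 42)
ds  <- generate_dataset(cfg, "demo")
ft  <- extract_features(ds$annotations, ds$dir)

## individual identity from the noisy segment
noisy <- ft[ft$segment == "noisy", ]
noisy <- noisy[complete.cases(noisy[, c("q25_mean", "peak_freq_mean")]), ]
loocv(noisy, "individual_id", c("q25_mean", "peak_freq_mean"))
```

On this run the noisy segment classifies its 6 individuals at 37.3 %
correct (51 measurable noisy segments) against a 16.7 % chance level —
the individual signature; with the full default world (8 individuals
per group, 5 calls per context) the per-group CV-values reach 29-47 %
against 12.5 % chance, all significant by bootstrap. The
harmonic segment instead carries the context cue:

```r
harm <- ft[ft$segment == "harmonic", ]
harm <- harm[complete.cases(harm[, c("duration", "f0_mean")]), ]
crossed_pdfa(harm, "context", "individual_id", c("duration", "f0_mean"),
             n_permutations = 999, seed = 1)
```

```
crossed pDFA (context | individual_id): ncce = 71.21%, P = 0.001 (999 permutations, 6 subjects)
```

The full pipeline (default world: 4 groups × 8 individuals × 3 contexts
× 5 calls, 1000 permutations; about 2 minutes on one CPU):

```r
report <- run_pipeline(pipeline_config(output_dir = "demo-pipeline", seed = 1))
print(report)
```

reproduces the published dissociation on synthetic data: noisy-segment
individual CV-values significant in all four groups (bootstrap
P < 0.05), harmonic-segment context ncce ≈ 61 % with P = 0.001 while the
noisy-segment context pDFA is far from significance (ncce ≈ 32 %,
P ≈ 0.7), sex (a null cue by construction) non-significant, and harmonic
durations ordered digging < searching < moving.

## Command line

```sh
closecall simulate --config world.cfg --out data --seed 7
closecall extract  --annotations data/annotations.tsv --audio-root data --out features.tsv
closecall vif      --features features.tsv --threshold 2.5 --out vif.txt
closecall pdfa     --features features.tsv --segment harmonic \
                   --test-factor context --n-perm 1000 --seed 7 --out pdfa.txt
closecall run      --config pipeline.cfg --out results --seed 7
```

See `vignettes/closecall-methods.Rmd` for the model, its assumptions,
the calibration of the synthetic world, and what a green test does and
does not establish.
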