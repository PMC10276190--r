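# specslope

Wide-band aperiodic (1/f) slope analysis for EEG power spectra.

The broadband, non-oscillatory part of a neural power spectrum falls off
with frequency roughly as a power law. On log-log axes its decay rate — the
aperiodic *exponent* or *slope* — changes with healthy aging, and it does so
differently in different frequency ranges: it flattens with age at low
frequencies and steepens at high frequencies, with a "knee" in between.
`specslope` is a toolkit for quantifying that behaviour over an unusually
wide range (4–1000 Hz) in multichannel EEG, for cohort studies that compare
age groups or cases (MCI/AD) against matched healthy controls.

## The model

The power spectral density is decomposed into aperiodic and periodic parts,
fit in log10-power space:

    P(f)  =  AP(f) + Σₙ Gₙ(f)
    AP(f) =  10^b · f^(−χ)                      (aperiodic: offset b, exponent χ)
    Gₙ(f) =  aₙ · exp(−(f − μₙ)² / 2σₙ²)        (Gaussian oscillatory peaks)

with the peaks adding in log10 power (the space the model is fit in).
Exponents are estimated two ways — an iterative aperiodic + peaks fit, and a
direct least-squares line on log P vs log f — in 100 Hz sliding windows
(centres 40–960 Hz, 20 Hz steps) and in two fixed bands: the low-frequency
range **LFR = 64–140 Hz** and the high-frequency range **HFR = 230–430 Hz**.
Windows whose endpoints touch ±4 Hz bands around 50 Hz and its harmonics are
excluded; fitted slopes below 0.01 are treated as missing.

## What is in the package

* **Synthetic cohorts** (`cohort_config()`, `simulate_subject()`,
  `simulate_cohort()`): multichannel recordings with a two-regime aperiodic
  spectrum (split near the empirical 175 Hz knee) whose LFR/HFR exponents
  follow configurable linear age trends (defaults −0.010/yr and +0.017/yr),
  an alpha peak that slows with age, a beta peak reduced in MCI/AD, 50 Hz
  line noise with harmonics, and injected artifacts (blinks, flat/bad
  channels, out-of-range repeats, fixation breaks).
* **I/O and montage** (`read_recording()`, `write_recording()`,
  `default_montage()`, `to_bipolar()`, `segment_epochs()`): internal
  float32 + JSON-sidecar layout and minimal 16-bit EDF (0.1 µV/bit); the
  printed 64-channel 10–10 electrode groups; nearest-neighbour bipolar
  re-referencing (112 virtual electrodes).
* **Artifact rejection** (`run_pipeline()`): the ordered rule set —
  fixation breaks (5° window), impedance > 25 kΩ, 6-SD time/frequency
  outlier repeats, >30% electrode drop, common-bad pooling (visual
  electrodes or >10% of the rest), 56–84 Hz negative-slope rejection,
  RMS bounds (1.25/2.5–35 µV), block validation — with the eyes-closed
  variant.
* **Spectra** (`multitaper_psd()`, `power_change_db()`,
  `power_change_linear()`, `pool_group()`): trial-averaged single-taper
  (Slepian, NW = 1) PSDs; group power changes in dB and on a linear scale.
* **Slope fitting** (`fit_spectral_model()`, `fit_loglog_line()`,
  `sliding_slopes()`, `band_slope()`, `find_knee()`, `knee_timescale()`).
* **Group statistics** (`compare_groups()`, `rank_sum_test()`,
  `kruskal_wallis_test()`, `cluster_significant()`, `bh_fdr()`,
  `bootstrap_median_sem()`, `regress_slope_vs_age()`,
  `pair_case_controls()`, `subsample_match_r2()`): nonparametric medians
  with 10,000-iteration bootstrap SEMs, ≥3-consecutive-bin cluster
  correction, Benjamini–Hochberg FDR, age regression, and ±1-year
  gender-matched case–control pairing.

## Worked example

Simulate a small artifact-free cohort on the nine high-priority posterior
electrodes, run every subject through rejection → PSD → slope profiling, and
regress the band exponents on age:

```r
library(specslope)
mon <- subset_montage(default_montage(),
                      get_group(default_montage(), "high_priority"))
co  <- cohort_config(n_subjects = 12, n_trials = 24, seed = 7)
sim <- simulate_cohort(co, no_artifacts(), montage = mon)
res <- analyze_cohort(sim$recordings, sim$metadata, montage = mon,
                      method = "loglog")
head(res$slopes[, c("id", "age", "lfr", "hfr", "alpha")], 4)
#>     id  age  lfr  hfr alpha
#> 1 s001 87.6 1.06 2.78  8.92
#> 2 s002 65.1 1.06 2.20  9.81
#> 3 s003 54.4 1.04 2.24 10.17
#> 4 s004 52.7 1.42 2.28  9.85

regress_slope_vs_age(res$slopes$age, res$slopes$hfr)
#> <regression_result> y = 1.474 + 0.01413 x, R2 = 0.660, p = 0.00131 (n = 12)
regress_slope_vs_age(res$slopes$age, res$slopes$lfr)
#> <regression_result> y = 1.738 + -0.009551 x, R2 = 0.471, p = 0.0138 (n = 12)
```

The HFR exponent rises with age (+0.014/yr here, generator target +0.017)
and the LFR exponent falls (−0.0096/yr, target −0.010); the oldest subject
has the flattest LFR spectrum, the steepest HFR spectrum, and the slowest
alpha. Group contrasts use the sliding-window profiles:

```r
gc <- compare_groups(res$profiles, age_group(res$slopes$age),
                     centres = res$centres, n_boot = 2000, seed = 1)
gc
#> <group_comparison> kw test, 47 windows, groups: mid vs old
#>   alpha 0.05: 0 cluster-significant window(s)
#>   alpha 0.01: 0 cluster-significant window(s)
```

Twelve subjects are too few for cluster-corrected significance — at the
40-subject scale used in `tests/testthat/test-acceptance.R`, correctly
signed significant clusters appear in both bands in ≥ 90% of replicates.

## Command line

```sh
inst/cli/specslope simulate --config cfg.json --out simdir --seed 3
inst/cli/specslope preprocess simdir/s001 outdir
inst/cli/specslope slopes --band LFR simdir/s001 slopes.tsv
```

See the methods vignette (`vignettes/aperiodic-slopes.Rmd`) for the model,
the defaults and their rationale, what the synthetic generator does and does
not emulate, and known limitations.
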