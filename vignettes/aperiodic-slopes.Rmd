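---
title: "Methods: wide-band aperiodic slope analysis in specslope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wide-band aperiodic slope analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

EEG power spectra combine oscillatory "bumps" with a broadband aperiodic
background whose power falls off with frequency. `specslope` quantifies the
decay rate of that background — the aperiodic exponent χ — over 4–1000 Hz,
where cohort studies report opposite age trends in a low-frequency range
(LFR, 64–140 Hz: flattening, roughly −0.010 exponent units per year) and a
high-frequency range (HFR, 230–430 Hz: steepening, roughly +0.017/yr), with
a slope minimum ("knee") near 175 Hz in posterior electrodes.

The spectral model, fit in log10-power space, is

$$P(f) = AP(f) + \sum_n G_n(f), \qquad AP(f) = 10^{b} f^{-\chi}, \qquad
G_n(f) = a_n \exp\!\left(-\frac{(f-\mu_n)^2}{2\sigma_n^2}\right).$$

One deliberate reading is baked in: **peaks add in log10 power**, because
that is the space the whole model is fit in (the literal equation writes a
plain sum, but the fitting procedure it refers to operates on log power;
we follow the fit space and document the choice here). With no peaks,
$\log_{10} P = b - \chi \log_{10} f$ exactly, which gives the package its
strongest oracle: any in-family spectrum must be recovered to numerical
tolerance (the acceptance suite demands $|\hat\chi - \chi| < 10^{-3}$).

# PSD estimation

Per-repeat periodograms use a single Slepian (DPSS) taper with
time–bandwidth product NW = 1 — "single taper" is all the source analysis
pins down, so NW is exposed and a Hann alternative is provided. The taper
is computed as the leading eigenvector of the tridiagonal matrix commuting
with the concentration operator (shifted power iteration plus
Rayleigh-quotient inverse iteration on a sparse tridiagonal; checked in the
tests against an independent DPSS implementation at n = 64 and n = 500).

Scaling is one-sided with the taper normalised to unit energy, so
$\sum_k S(f_k)\,\Delta f$ matches the epoch variance (Parseval, tested at
5% on white noise). Frequency spacing is the reciprocal of the epoch
length: 2 Hz for the 500 ms eyes-open pre-stimulus window, 0.5 Hz for 2 s
eyes-closed segments. Averaging over repeats shrinks estimator variance
roughly as 1/n. Subject-level spectra pool electrodes within a group by the
**mean of log10 power** (medians across *subjects*, log-means across a
subject's electrodes): log-domain pooling respects power-law structure —
pooling exponents 1 and 2 yields exactly 1.5 — and is configurable by
pooling a different group or operating on per-electrode spectra directly.

# Slope estimation

Two routes are provided and cross-checked (they must agree within
Δχ = 0.01 on peak-free spectra):

* `fit_loglog_line()` — ordinary least squares on (log f, log P), with
  explicit exclusion bands.
* `fit_spectral_model()` — the iterative aperiodic + peaks fit:
  (1) robust initial line (refit on the bins whose clamped positive
  residual lies below the 2.5th percentile, a config-exposed constant),
  (2) flatten, (3) iteratively take the largest residual maximum above
  `max(min_peak_height, peak_threshold × SD)`, seed a Gaussian with σ from
  the half-height width clamped to half the peak-width limits, subtract,
  stop at `max_n_peaks`, (4) joint bounded refit of all Gaussians
  (L-BFGS-B), (5) aperiodic refit on the peak-subtracted spectrum,
  (6) R² in log power.

The five fixed fit settings are: peak width limits [4, 8] Hz (eyes open)
or [1, 8] Hz (eyes closed — finer frequency resolution admits narrower
peaks), at most 5 peaks, minimum peak height 0.2 log10 units, peak
threshold 2.0 SD, aperiodic mode "fixed" (no knee term in the fit family).

Sliding-window profiles fit 100 Hz windows at centres 40, 60, …, 960 Hz,
clipped to [4, 1000] (first window [4, 90], last [910, 1000]; 47 windows).
±4 Hz around 50 Hz and every harmonic is a "noise peak". A window is
excluded outright when an endpoint lies inside a closed noise band —
"near the end points" is operationalised as *inside the band*, the
simplest faithful reading, with the margin configurable. Note the
consequence that centre 960 is excluded too (its endpoint 1000 Hz sits in
the 996–1004 Hz band), alongside every centre at a multiple of 100 Hz.
Interior noise-band bins are removed before fitting — the model-based fit
could absorb line peaks, but bin removal keeps the two fitting routes
comparable. Fitted exponents below 0.01 are recorded as missing with
reason `below_min_slope`; all missingness carries a reason
(`noise_peak_at_edge`, `below_min_slope`, `fit_failed`) and is dropped
pairwise by the group statistics. Sliding fits default to the model route;
the acceptance cohort runs use the direct line fit, which is equivalent on
these peak-free ranges and considerably faster.

`find_knee()` returns the centre frequency minimising the profile within
100–300 Hz (ties to the lowest frequency, boundary solutions flagged). On
an idealised two-regime spectrum — flat exponent then steeper exponent —
the profile has a *plateau*, not a V, so the argmin lands at the plateau
edge rather than the transition; the knee is only localisable when the
profile genuinely dips, as it does in real posterior spectra (tested with
a V-shaped local-exponent construction). `knee_timescale()` evaluates the
printed formula τ = 1/(2π f_knee) literally: f_knee = 175 Hz gives
τ ≈ 0.91 ms. The literature this analysis sits in quotes "~5 ms" for the
same knee — the formula and that figure are mutually inconsistent, and we
surface the formula's value rather than guess at an intended constant.

# Artifact rejection

Eyes-open order: (a) fixation breaks (eye eccentricity > 5° anywhere in
−0.5–0.75 s; skipped with a logged note when no eye data exist), (b)
impedance > 25 kΩ, (c) 6-SD outlier repeats in time and frequency domains
then electrodes with > 30% outliers, (d) common-bad pooling (flagged on
any visual/high-priority electrode, or on > 10% of the other good
electrodes), (e) rejection of electrodes whose 56–84 Hz slope is negative
(a plain line fit — the band is oscillation-free by construction, so the
full model is unnecessary), (f) RMS bounds (< 1.25 µV or > 35 µV) with a
second electrode drop and common-bad append, (g) block validation: at
least one good electrode in each of the left visual anterolateral
(P3, P1, PO3, O1), right visual anterolateral (P2, P4, PO4, O2) and
posteromedial (POz, Oz) groups. Eyes closed starts at (b), applies the RMS
rule (lower cutoff raised to 2.5 µV, since it acts on raw segments) *in
place of* the time-domain 6-SD screen, then the frequency-domain screen
and steps (d)–(g). The report records the executed stage order and the
fraction rejected at each stage.

Two reading decisions deserve emphasis:

* The 6-SD statistic is the **maximum pointwise |deviation|/SD** across
  samples (time) or log-power bins (frequency), with the repeat included
  in the mean and SD, and zero-SD points contributing nothing. Because the
  repeat is included, the largest attainable z is $(n-1)/\sqrt{n}$: the
  rule cannot fire below ~39 repeats no matter how large the spike. That
  is consistent with its intended regime (hundreds of repeats per
  subject); tests exercise it at n = 50. A repeat-level RMS z would be the
  natural alternative reading.
* **All boundary comparisons are strict**, matching the printed
  inequalities: 25 kΩ is kept, exactly 30% outliers is kept, exactly 10%
  common is not pooled.

The pipeline is monotone (injecting artifacts never reduces flags) and
idempotent on its own cleaned output; both are tested.

# The synthetic world

The generator exists so every downstream stage is testable without any
recording. Its defaults *are* the stated world of the analysis it
emulates; where that analysis is silent, a value was chosen once on
field-plausibility grounds and is documented here:

| parameter | default | status |
|---|---|---|
| sampling rate | 2500 Hz | stated |
| ages | uniform 50–88 yr, Mid/Old boundary 64 | stated |
| LFR age coefficient | −0.010 /yr | stated (eyes-open regression) |
| HFR age coefficient | +0.017 /yr | stated |
| alpha slowing | −0.016 Hz/yr (9.72 → 9.41 Hz across group medians) | derived |
| diagnosis mix | 93/5/2% healthy/MCI/AD | cohort proportions |
| fixation-break rate | 14.6% of repeats | stated rejection statistic |
| impedances | N(5.5, 1.8²) kΩ | stated post-rejection statistic |
| regime split | 175 Hz | the reported knee |
| reference exponents at 64 yr | 1.2 (LFR), 2.4 (HFR) | chosen: posterior wide-band EEG values |
| between-subject exponent SD | 0.15 | chosen to reproduce reported regression R² (~0.36–0.53) |
| 50 Hz pivot power | 10^−0.5 µV²/Hz, age-independent | chosen: cohort PSDs overlap below ~50 Hz |
| beta reduction in MCI/AD | ×0.48 | beta power roughly halves in cases |

Design notes. The aperiodic component is **two band-limited regimes**
joined continuously at the split, so the LFR- and HFR-governing exponents
can follow opposite age trends. It is **anchored at a 50 Hz pivot** rather
than a 1 Hz offset: age rotates the spectrum about the overlap region
instead of shifting it, which both matches the described cohort spectra
and keeps epoch RMS in the realistic 8–20 µV range (an early 1 Hz-anchored
version pushed flat-sloped elderly subjects over the 35 µV RMS bound —
an artefact of the parameterisation, not of aging). Time series come from
inverse-FFT synthesis with independent uniform phases and amplitudes
$\sqrt{P(f)\,f_s\,n/2}$, giving exact spectral control; 50 Hz and its
harmonics (geometrically decaying, factor 0.6) are realised as
single-bin PSD spikes, which is exactly a random-phase sinusoid at the bin
frequency. The EMG-like hump is a configurable log-Gaussian in frequency
(40–200 Hz, peaking near 100 Hz) and is **off by default**: no magnitude
is stated anywhere for it, and leaving it out keeps the parameter-recovery
oracles sharp. An optional fifth-order 1 kHz low-pass emulation is likewise
off (analyses stop at 800 Hz to avoid the roll-off region anyway).

What the generator does **not** emulate: volume conduction or any head
model (electrodes are independent realisations with jittered parameters,
so spatial statistics are meaningless), non-stationarity within a session,
realistic eye-movement traces (a scalar eccentricity series only), or
heavy-tailed artifact amplitude distributions. A green end-to-end test
therefore establishes that the *pipeline machinery* recovers known
spectral structure at realistic SNR and sample sizes — not that it would
behave identically on recorded EEG.

# Statistics

Group location comparisons are nonparametric (Kruskal–Wallis, Wilcoxon
rank-sum) on medians, with the SEM of the median from a 10,000-iteration
bootstrap (inner loop in C++; deterministic given a seed). The rank-sum
test enumerates the exact null distribution (subset-sum dynamic
programming) when the smaller group has ≤ 8 observations and there are no
ties, and otherwise uses the tie-corrected normal approximation without
continuity correction; the switch point sits just below the case–control
sample sizes (13–16 pairs) so those comparisons use well-calibrated
approximations, while the exact path is verified against brute-force
permutation enumeration for all n₁ + n₂ ≤ 10. Note one degenerate corner:
two *identical* groups necessarily contain ties, so "exact p = 1" for that
case is delivered by the tie-corrected path (z = 0), not by enumeration.

Frequency-resolved p-values are cluster-corrected by run length only: a
window is significant iff it belongs to ≥ 3 consecutive windows with
p < α, applied independently at α = 0.05 and 0.01; missing windows break
runs, and edge runs count. Across electrodes, Benjamini–Hochberg step-up
FDR is used under the independence assumption, taken at face value (no
Benjamini–Yekutieli inflation). Case–control analysis averages the matched
controls (same gender, ±1 year) into one data point per case using the
**median** — the analysis this mirrors says "averaged" in one place and
"median across controls" in another; we follow the median and expose
`aggregate = "mean"` — and compares pairs with the **sign-rank** test by
default, since the construction is explicitly paired (the unpaired
rank-sum remains available). R²-distribution matching subsamples both
groups to equal per-bin counts (bin width 0.05) without replacement.

# Numerical and engineering choices

* Strict inequalities at every threshold; half-open epoch windows
  \[start, end) with sample index `round(t·fs)`.
* The internal on-disk layout is float32 + JSON sidecar: round-trips are
  bit-exact for float32-representable data and at 1-in-10⁷ relative error
  otherwise; EDF export quantises at 0.1 µV/bit (half-LSB bound 0.05 µV).
  No EDF reader was available in the dependency stack, so a minimal
  16-bit EDF writer/reader (1 s records) is implemented in-package and
  verified by round-trip.
* The published 112-pair bipolar scheme is not itself printed; the package
  ships a *synthetic stand-in* (`inst/extdata/bipolar_pairs_synthetic.tsv`,
  and `default_bipolar_pairs()`): the 112 closest pairs on a planar 10-10
  grid, deterministic with label-order tie-breaks, editable as plain text.
* One top-level seed per simulation; per-subject and per-operation streams
  are derived from it, and every stochastic helper accepts an explicit
  seed (`withr::with_seed`, so the caller's RNG state is never disturbed).
* Scale-downs for test runtime are explicit in the tests: the acceptance
  cohort runs on the nine high-priority electrodes with 24 repeats per
  subject (the generator's defaults remain 64 channels × 300 repeats), and
  SEM bootstraps are skipped where only signs and p-values are consumed.

# Known limitations

* `aperiodic_mode = "fixed"` only; no knee term in the fit family (the
  knee is characterised through the slope profile instead).
* The sliding-window exponent near the regime split blends the two
  regimes; recovered transition frequencies are biased toward the plateau
  edge (see `find_knee()` above).
* The 56–84 Hz electrode-rejection slope is estimated over a narrow
  log-frequency span; at desk-scale repeat counts its sampling error is
  large, and a few percent of clean electrodes are expected casualties —
  the emulated pipeline reports ~19% electrode rejection at this stage on
  real data, so this is faithful, not a defect.
* Exact rank-sum enumeration is skipped in the presence of ties (the
  tie-corrected approximation is used regardless of sample size).
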