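---
title: "Modeling and detecting foveal-feedback masking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and detecting foveal-feedback masking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovealmask)
```

## The scientific problem

Peripheral object recognition is supported by *foveal feedback*: information
about a peripheral object is reprocessed in foveal retinotopic cortex some
150–250 ms after the object appears. Behaviorally, this feedback can be
probed by flashing a foveal noise patch at a variable stimulus onset
asynchrony (SOA) relative to a peripheral discrimination target. When the
noise arrives while the feedback signal is being processed, peripheral
discrimination drops; the timing and the spatial-frequency specificity of
that drop characterize what the feedback carries. The phenomena this
package is built to detect are (a) a transient sensitivity dip roughly
220 ms after peripheral onset, strongest for low-spatial-frequency (LSF)
foveal noise, and (b) a periodic, ~5 Hz modulation of the masking effect.

`fovealmask` implements the full measurement chain as testable code:
calibrated bandpass-noise stimulus synthesis; a generative
signal-detection-theory (SDT) observer with a parametric masking kernel;
the d′-over-TPO time-course construction; stratified permutation inference;
behavioral-oscillation spectra; and the staircase/QUEST/psychometric
machinery of a companion contrast-threshold experiment. Because every stage
has a generative counterpart, each statistical claim can be checked against
ground truth on synthetic data.

## Stimuli: calibrated bandpass pink noise

Noise patches are synthesized in the frequency domain: white Gaussian noise
is given a 1/f amplitude spectrum (random phase, zero DC), then filtered
with a Gaussian gain on the log2-frequency axis, normalized to a target RMS
contrast, and windowed by a Gaussian spatial envelope. Defaults mirror the
experiment: 6.5° patches at 256 × 256 px, band centers 0.9 / 3.6 / 12.5
cycles per character width (characters are ~1°, so c/char ≡ c/deg), a
1.6-octave bandwidth, 20% RMS contrast on a 71 cd/m² background (5% for
the threshold experiment), and a 1° envelope SD.

Three conventions required a decision:

* **Bandwidth.** "1.6 octaves" is read as the full width at half maximum
  (FWHM) of the Gaussian gain on the log2 axis — the common psychophysics
  convention — so the gain is 0.5 at ±0.8 octaves from the center. A ±1 SD
  reading is available via `convention = "sd"`.
* **Delivered vs. filter center.** A pure multiplicative Gaussian gain
  applied to a 1/f spectrum shifts the *realized* spectral peak about 0.32
  octaves below the nominal center (the 1/f tilt pulls the product down).
  A stimulus advertised as "centered at 3.6 c/deg" should actually peak
  there, so `make_band_noise()` uses a pink-compensated gain
  (`compensate_pink = TRUE`): the Gaussian is multiplied by f/f_c — still
  unity at the center — which flattens the 1/f input so the delivered
  amplitude spectrum is Gaussian-centred on the nominal frequency.
  `bandpass_gaussian_log2()` keeps the pure gain as its default, and
  `band_gain()` is the gain function itself (its measured FWHM is exactly
  the configured bandwidth).
* **RMS before the envelope.** The pixel resolution of the original patches
  and whether contrast was set before or after windowing are not published;
  we normalize pre-envelope (the envelope then attenuates contrast away
  from the center) and use a 256-px raster. Both are configurable.

The spectral-peak verifier `radial_spectrum_peak(..., refine = "quadratic")`
exploits the construction: the band's log amplitude is a quadratic in
log2 f, so fitting that quadratic over the above-half-maximum annuli gives
a sub-annulus peak estimate that is far more stable than the raw argmax on
the band's flat top. Note that with a 1.6-octave FWHM the *adjacent* bands'
gain tails overlap by a few percent (only the LSF–HSF pair is separated to
below 1%); "no frequency overlap" is an approximation of the design, not a
mathematical property of the filters.

## The generative observer

Responses follow equal-variance SDT for the same–different judgment, with
"different" as the signal class (the mapping is a convention; nothing
downstream depends on it). On a "different" trial the decision evidence is
Normal(d′, 1); on a "same" trial Normal(0, 1); the observer answers
"different" above a criterion c, and with probability `lapse` replaces the
response with a fair coin. Foveal noise reduces the effective d′ through a
band-specific kernel

> k(t) = depth · exp(−(t − t₀)² / 2σ²) + amp · (1 + cos(2π f t/1000 + φ)) / 2,

averaged over the 7 frame onsets of the 58.33 ms noise presentation, plus a
simultaneity cost proportional to the physical overlap between noise and
target. Effective d′ is clipped at zero. Defaults encode the phenomenology
the analysis targets: baseline d′ = 1.8 and c = 0.2 (a mildly conservative
observer near threshold), lapse 0.02, an LSF dip of 0.6 d′ units centered
at 220 ms (σ = 25 ms) versus shallow 0.2–0.25 dips near 185 ms for
MSF/HSF, a 5 Hz modulation of amplitude 0.5 (LSF), 0.25 (MSF), 0.1 (HSF),
and a simultaneity cost of 0.4. `null_observer()` zeroes every masking
term for calibration studies.

The session design is fixed by the experiment: a 120 Hz frame clock,
SOAs from −25 to 300 ms on the 8.33 ms grid (40 frames), 620 test trials
per session (20 no-noise + 200 per band, i.e. 5 repeats per frame per band,
a balanced shuffle standing in for "uniform but equally repeated"), three
sessions, truth balanced within band.

```{r design}
design_spec()
```

## From trials to d′ time courses

Per observer and condition the pipeline computes the Hautus-corrected
sensitivity index for each SOA frame,

> d′ = z((H + 0.5)/(H + M + 1)) − z((FA + 0.5)/(FA + CR + 1)),

which stays finite for empty and perfect cells, then pools temporally
overlapping noise presentations with a **trailing** 7-frame moving average:
the TPO bin labelled 50 ms averages frames 50–108.33 ms, so a 40-frame
series yields 34 bins and every bin describes a window during which noise
was physically present. Only full windows are emitted. Each observer's TPO
series is mean-centered (reductions read as negative values) and observers
are averaged with equal weight. d′-then-average is the default order; a
pooled-counts mode (sum the window's counts, then one d′) is available via
`dprime_mode = "pooled_counts"`. Frames whose pooled trial count falls
below half the condition's median per-frame count are dropped from all
observers symmetrically — the generalization of discarding a single
undersampled SOA.

## Permutation inference

All tests re-run the full pipeline on stratified permutations of the trial
table, with seeds derived deterministically from one master seed.

* **Dip test** (`dip_test`). Null datasets shuffle labels within
  observer × condition strata. Two modes are provided because the two
  natural descriptions of this shuffle differ in a subtle way:
  permuting SOA labels against intact (truth, response) pairs is exactly
  exchangeable under the null; permuting responses alone is *not*, because
  responses depend on truth — destroying that coupling inflates the null
  variance of the per-frame d′ and the test no longer holds its nominal
  level. `fovealmask` therefore stratifies the response shuffle within
  the truth class, which preserves each observer's hit and false-alarm
  rates; both modes then agree and hold the nominal level. The pointwise
  mode takes each bin's lower-tail α-quantile of the permuted centered d′
  as its critical value (reductions are negative, so this is the one-sided
  test at the 95th percentile of reduction magnitude, the convention behind
  per-TPO p-values); the `omnibus_min` mode uses the min-over-bins
  statistic for familywise control and is what the calibration studies
  exercise. p-values use the (r + 1)/(n + 1) convention.
* **Band-strength comparison** (`compare_noise_strength`). The statistic is
  the difference of the two bands' strongest impairments (each band's own
  minimum over TPO, avoiding any temporal bias); the null shuffles band
  labels within observer and recomputes both minima; the decision is
  two-tailed at the central 95% interval.
* **Implementation.** Trials within a (frame × truth × response) cell are
  exchangeable, so every stratified shuffle reduces to reallocating counts
  across cells; the engine draws those counts directly via sequential
  hypergeometric sampling, vectorized across permutations. This is exactly
  equivalent to trial-level shuffling and is what makes 500 × 1000
  permutation calibration runs affordable on one CPU. Moving average and
  centering are linear, so they are applied once to the observer-mean d′
  series per permutation.

## Behavioral oscillations

The group centered TPO series is multiplied by a Hanning taper of its own
length, zero-padded, Fourier transformed, and reported as amplitudes on a
grid capped at 20 Hz. The original report quotes frequencies at multiples
of ~0.79 Hz; a padded length of 151 frames at 8.33 ms reproduces that
spacing (Δf ≈ 0.795 Hz), and we document this as a reverse-engineered
convention — the padding itself was never published. Amplitude (modulus)
is reported rather than power, matching the figure axes; power and
Parseval-normalized scales are config options. Spectra are computed on the
group-average series (the permutation machinery operates on group curves);
per-observer spectra can be averaged instead via the exported pieces. The
DC bin is excluded from peak searches, and taper comes before padding.
`spectrum_permutation_test` applies the dip test's permutation stream to
the spectrum (one-tailed upper, per-frequency critical values);
`compare_spectrum_peaks` compares maximum amplitudes between bands on the
band-shuffle stream (two-tailed).

## Adaptive procedures and psychometric fits

The threshold experiment embeds characters in LSF or MSF background noise
at 0° or 10° eccentricity and tracks contrast with two interleaved
staircases (one ascending, one descending; 640 trials per observer). The
2-up-1-down rule — contrast down after two consecutive correct, up after
any error, multiplicative steps whose log size is halved after each of the
first three reversals (a documented default; the original schedule is
unpublished) — converges where p² = 0.5, i.e. 70.7% correct. QUEST is
implemented as grid-posterior Bayesian estimation with a Weibull likelihood
in log10 contrast, trials placed at the running posterior-mean threshold,
targeting 75%; the experiment's thresholding block is emulated by averaging
two independent runs.

Psychometric functions are fit by binomial maximum likelihood (cumulative
Gaussian in log10 contrast, or Weibull), guess rate 0.5, lapse bounded in
[0, 0.1], from a fixed multi-start grid so fits are deterministic. This is
deliberately *not* a reimplementation of the psignifit toolbox: the
threshold definition — the contrast where the fitted function reaches
70.7% — is the contract, not the fitting engine. Observers whose fitted
function cannot reach the target accuracy in a cell are excluded from that
character condition only; a global exclusion hook mirrors removal for poor
fixation. Group inference on the resulting threshold table is exported for
any standard mixed-model tool rather than re-implemented; a within-observer
sign-flip permutation test with Holm–Bonferroni correction is provided as a
self-contained alternative.

The synthetic threshold experiment (`simulate_exp2`) builds Weibull
observers whose true thresholds carry the qualitative interaction of
interest — MSF noise masks more than LSF at fixation (0.035 vs 0.020),
LSF more than MSF at 10° (0.25 vs 0.15), thresholds roughly an order of
magnitude higher peripherally — with lognormal observer variability
(SD 0.15) and small per-cell jitter.

## What the synthetic data do and do not show

The generator reproduces the statistical *structure* the analysis assumes:
SDT responses with SOA-dependent sensitivity, balanced designs, session
granularity, staircase dynamics. It deliberately omits much of real data:
sequential dependencies and fatigue, criterion drift, fixation losses
(fixation flags are generated valid; the exclusion path is exercised in
tests by construction), frame-timing jitter, and any mismatch between the
assumed and the true psychometric family. Passing tests therefore validate
the inferential machinery — type-I calibration, power against known
effects, parameter recovery — not the empirical claims about human foveal
feedback, which require the original (publicly deposited) data.

## Numerical choices and problem sizes

Tolerances: RMS calibration and mean luminance are exact to 1e-9 by
normalization; centering to 1e-12; the spectrum rejects inputs whose mean
exceeds 1e-9. Degenerate inputs (zero-variance patches, all-correct fits,
too-short series) yield classed errors or flagged non-converged fits, never
silent numbers. Validation studies in the test suite use sizes chosen to
keep a laptop run comfortable while leaving Monte-Carlo error well inside
the asserted bands: 500 null experiments × 1000 permutations (10 observers,
50 trials/frame) for type-I calibration; 100 replicates of 26 observers ×
600 trials for 5 Hz recovery; 20 cohorts of 5 observers × 640 trials for
the threshold interaction; 20–32 patches for stimulus calibration; 10⁴
staircase trials and 200 QUEST replicates for the adaptive procedures.

## Reproducing the analysis chain

The `analysis/` directory holds numbered drivers that run the whole chain
on synthetic data and write tidy tables under `results/`:
`01_generate_stimuli.R`, `02_simulate_experiment1.R`,
`03_timecourse_dip.R`, `04_oscillations.R`, `05_experiment2_thresholds.R`.
`scripts/acceptance.R` recomputes the headline calibration quantities from
scratch (see the README).
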