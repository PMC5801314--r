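---
title: "Measuring auditory memory-trace decay with the MMN: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring auditory memory-trace decay with the MMN: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmndecay)
```

## The measurement model

The mismatch negativity (MMN) is the negative deflection of the
deviant-minus-standard difference wave peaking 100–250 ms after the onset of
a deviant tone. `mmndecay` treats a subject's MMN as a latent Gaussian
component of peak amplitude $A < 0$ (µV), center latency $\ell$ (ms) and
width $\sigma_w$ (ms) riding on an obligatory response that is identical
across conditions and therefore cancels in the difference wave.

The quantity of interest is the survival of the auditory sensory memory
trace across a long (3 s) interstimulus interval. Each subject carries a
retention factor $d \in [0, 1]$: the short-ISI paradigm elicits the full
component $A$, the long-ISI paradigm the attenuated component $A \cdot d$.
The decay score is the difference of the two scored amplitudes,

$$\Delta = \hat a_{\text{short}} - \hat a_{\text{long}}
        \approx w \cdot A (1 - d),$$

where $w$ is the windowed-mean factor introduced by the scoring rule (below).
$\Delta = 0$ means no decay; since $A < 0$, stronger decay drives $\Delta$
negative, so *higher values mean less decay*. The generator couples the
standardized true decay score to the latent episodic-memory factor of the
neuropsychological battery with standardized weight `coupling_beta`
(default 0.4), which the hierarchical regression at the end of the chain
tries to recover.

## The two paradigms

* **Optimum-1** (short ISI): 3 blocks × 615 tones = 1845 events at a fixed
  0.5 s onset asynchrony. Each block opens with 15 standards (trace
  formation), then alternates standard/deviant strictly, so standards carry
  50% probability and each of the five deviant families (duration, gap,
  frequency, intensity, location) 10% of the 600 alternating events
  (60 slots each). Consecutive deviants never share a family — standard
  multi-deviant practice, configurable because the original description does
  not state it. Sub-variants (±10% frequency, ±10 dB intensity, ±800 µs
  interaural delay) split 50/50 and are pooled into one family at analysis.
* **Memory-Trace** (long ISI): 3 blocks × 154 tones = 462 events; 15 leading
  standards, then 26 duration and 26 frequency deviants per block separated
  by runs of 1–3 standards (51 runs summing to 87 per block, allocated by
  random surplus distribution). Every deviant follows a standard after
  exactly 3.0 s of silence; all other intervals are drawn from
  {0.5, 1.5, 3.0} s. The resulting composition is 306/462 = 66.2% standards
  and 78/462 = 16.9% per deviant family. Standards after deviants and the
  leading standards also draw from the ISI menu — the published description
  fixes only standard→standard intervals, so this is the package's choice.

Tones are harmonic complexes (500/1000/1500 Hz at 0/−3/−6 dB), 75 ms with
5 ms linear ramps; the duration deviant is 50 ms shorter, the gap deviant has
a 7 ms centered silent gap with 1 ms ramps. The interaural time difference is
realized as a whole-sample delay (error < 21 µs at 48 kHz); sub-sample
interpolation is deliberately not used.

## What the generator emulates — and what it does not

`simulate_cohort()` draws, per subject: group (defaults 16 SMI / 19 naMCI /
24 aMCI, the screened cohort; the analysis-sample Monte-Carlos use
14/19/24), age and education per group, per-family base amplitudes
(Gaussian, truncated negative, family means −2.1 to −1.2 µV with SD 1 µV,
matching typical fronto-central short-ISI values), retention $d$
(Beta-distributed; group means 0.5/0.45/0.3 with SD 0.15, giving aMCI the
strongest decay), and latency (Gaussian, 185 ± 18 ms).

Epochs (−100..350 ms, three fronto-central channels, 250 samples/s by
default) are the obligatory template plus white Gaussian noise
(`noise_sd_uv`, default 3 µV per sample/channel/trial) plus, for deviants,
the MMN component; `artifact_rate` (default 10%) of trials receive a
±150 µV Gaussian transient on one channel. Trial counts default to the
study's averages (≈750/150 standard/deviant for short ISI, 83/65 for long
ISI). The noise default is a design choice tuned once so that subject-level
amplitude standard errors land at ≈0.2–0.3 µV at those trial counts — the
regime in which MMN-presence tests behave as published; the true SNR of any
real recording is unknown and this value should not be read as an empirical
claim.

The battery has nine variables in two blocks: MVGT encoding/recall and ADAS
free recall load (0.85/0.85/0.75) on the memory factor; Trail-Making A/B,
digit span, digit-symbol, word fluency load (0.60–0.75) on the
attention/executive factor. The Everyday Cognition computation span uses a
generative factor correlation of 0.38, calibrated once so that its
*expected promax pattern loading* is 0.48 — principal-component loadings
inflate above factor correlations, and 0.48 is the observed value the
composites procedure must reject at its 0.50 threshold. Because that value
sits just below the threshold by construction, single cohorts exclude the
variable in only ~60% of replications; distribution-level checks (median
loading < 0.50) are the appropriate test, not per-cohort determinism.
TMT times and ADAS errors are generated on their natural "higher = worse"
scales and negated before standardization so every z-column reads
"higher = better".

Not emulated: 256-channel topographies, ocular/muscle artifact morphology,
1/f noise, latency jitter within subject, hearing-threshold calibration, and
any real clinical heterogeneity beyond the latent parameters above. Passing
tests therefore demonstrate that the *pipeline* is correct and well
calibrated under a known generative model — not that real recordings meet
the model's assumptions.

## Numerical choices in the ERP pipeline

* **Filter**: zero-phase band-pass, two second-order Butterworth sections
  run forward and backward (`signal::filtfilt`), a 24 dB/octave-equivalent
  rolloff with the published 1–35 Hz band. Measured response: 50 Hz
  attenuated > 4×, 10 Hz preserved within 1%.
* **Periodic extension**: published processing filters the continuous
  recording, in which stimulus-locked responses recur; filtering an isolated
  450 ms segment instead lets the 1 Hz high-pass remove local
  low-frequency mass and costs 7–11% of a Gaussian component's windowed
  mean. Each segment is therefore tiled five times and the middle copy kept,
  which emulates continuous-data filtering and reduces the distortion to
  ≈1%.
* **Order of operations**: filter → baseline → reject → average → resample
  (`filter_stage = "trial"`). A fast path (`filter_stage = "average"`)
  band-passes the per-condition average instead; by linearity both give
  identical waves whenever they reject the same trials (proven by test with
  artifacts disabled). The fast path measures peak-to-peak on unfiltered
  trials — the only behavioural difference, and the Monte-Carlo runs use it.
* **Rejection**: the published manual artifact screening is replaced by a
  reproducible peak-to-peak criterion (default 100 µV on the scored
  channels); under default contamination it removes ≈10% of trials, within
  the published "no more than 20%".
* **Resampling**: anti-aliased integer-factor decimation
  (`signal::decimate`) applied to averages; epochs generated at 250
  samples/s skip it. Interior accuracy ≈1% on band-limited content.
* **Scoring grid**: at 250 samples/s the time grid steps 4 ms, so search
  windows clip to grid points (e.g. the 125–275 ms duration window starts at
  128 ms) and latency agreement is defined as within one sample. Argmin ties
  break toward the earlier latency. A scoring window reaching past the epoch
  is clipped with a warning rather than an error.
* **Outlier rule**: single pass over the full cohort; IQR uses R's default
  inclusive quantile convention (`type = 7`). Exclusion requires the
  amplitude to exceed mean + 1.5·IQR *and* +2 µV in **both** long-ISI
  families.

## Composites and inference

PCA runs on the correlation matrix of the z-standardized battery; components
with eigenvalue ≥ 1 are retained (Kaiser) and promax-rotated (κ = 4, pattern
matrix) when more than one survives. The published procedure does not name
the oblique method or matrix; promax/pattern is the default and both are
arguments. Components are reflected so their salient variables load
positively, and a composite is $\sum_j \lambda_j z_j / \sum_j |\lambda_j|$
over variables with $|\lambda_j| \ge 0.50$ — the "weighted average"
normalizer is the package's choice since none is published. Follow-up
batteries reuse baseline z-parameters and loadings restricted to the
available variables, with weights renormalized.

The hierarchical models are ordinary least squares: reduced (age +
education) vs full (+ one MMN index), compared by
$F = \Delta R^2 (n - k - 1) / (1 - R^2_{full})$ with $(1, n - k - 1)$
degrees of freedom — identical to `anova()` on the nested fits (tested).
Standardized β comes from refitting on z-scored variables and equals the
Frisch–Waugh form (tested). VIF is computed from each predictor's $R^2$
against the others; flags follow the usual >10 / mean >1 / tolerance <0.1
screens. The short-ISI MMN enters as one MMN × deviant-family interaction
block tested jointly, rather than five separate models. Group contrasts are
fixed aMCI vs pooled naMCI/SMI. Presence tests are one-tailed toward
negative amplitudes with a Shapiro-Wilk gate (α = 0.05) choosing t vs
Wilcoxon; all other tests are two-sided at α = 0.05. Mixed-effects
group × deviant models are out of scope; the within-subject paradigm
contrast is the paired t-test equivalent.

## Problem sizes and expectations

The test suite and the acceptance script run, as the package's chosen study
sizes: 200 simulated studies at the analysis sample (n = 57, default SNR and
trial counts) for coupling recovery, 1000 null cohorts for nested-F
calibration, 2000 draws for presence-test type-I error, and 200 batteries at
n = 200 for the composite structure. Through the full measurement chain the
recovered standardized coupling averages ≈0.29 against a generative 0.4 —
the expected attenuation from scored-amplitude measurement error (reliability
≈0.8) times composite validity (≈0.95); the Monte-Carlo asserts the mean
within ±0.15 of truth and positivity in ≥95% of studies, not the naive
equality.

## Known limitations

* The generator's epochs are white-noise based; colored (1/f) EEG noise
  would lower effective degrees of freedom in the scoring window and widen
  amplitude standard errors at equal RMS.
* The two-stage scoring anchors windows per group on simulated labels; with
  very small groups the grand-average peak is itself noisy, which propagates
  into every subject's window placement.
* ΔMMN inherits measurement error from *two* paradigms; its reliability
  bounds the recoverable regression weight, and no disattenuation is
  attempted.
* The deviant-family interaction model stacks five rows per subject without
  a random intercept; its p-values are structural mirrors of the published
  analysis, not independence-respecting inference.
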