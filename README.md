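# mmndecay

Auditory memory-trace decay scores from mismatch negativity (MMN) paradigms.

## The problem

The MMN is a negative event-related potential (ERP) peaking roughly 100–250 ms
after a deviant tone interrupts a stream of identical standard tones. Its
amplitude after a **short** interstimulus interval (ISI) indexes pre-attentive
auditory discrimination; after a **long** ISI (> 2 s) it depends on how well
the sensory memory trace of the standard tone has survived the silent
interval. The difference

```
ΔMMN = MMN_amplitude(short ISI) − MMN_amplitude(long ISI)
```

isolates the decay of that trace: because MMN amplitudes are negative, ΔMMN is
0 when the trace survives intact and becomes more negative the more the
long-ISI MMN is attenuated (higher values = less decay). In older adults at
risk of dementia (subjective memory impairment, amnestic and non-amnestic mild
cognitive impairment), ΔMMN for the duration deviant is a candidate biomarker
for episodic-memory decline.

`mmndecay` implements the full measurement chain for researchers who want to
study, simulate, or re-analyze this design:

* **Paradigms** — the multi-deviant Optimum-1 sequence (1845 tones, three
  blocks, 0.5 s onset asynchrony, five deviant families at 10% each) and the
  Memory-Trace sequence (462 tones, every deviant following a standard after
  exactly 3 s, 66.2% standards / 16.9% per deviant family), plus harmonic
  tone synthesis (500/1000/1500 Hz partials at 0/−3/−6 dB, 75 ms, 5 ms ramps;
  duration, gap, frequency ±10%, intensity ±10 dB and 800 µs interaural-delay
  deviants) with WAV/event-table export.
* **Synthetic cohorts** — subjects with latent MMN amplitude `A`, retention
  factor `d ∈ [0,1]` (so the true decay score is `A(1−d)`), peak latency, and
  a nine-variable neuropsychological battery whose episodic-memory factor is
  coupled to the true decay score.
* **ERP pipeline** — zero-phase 1–35 Hz band-pass (24 dB/octave equivalent),
  −100..350 ms epochs with 100 ms baseline, peak-to-peak artifact rejection,
  averaging, resampling to 250 samples/s, deviant-minus-standard difference
  waves, Fz/FCz/Cz pooling.
* **Scoring** — two-stage MMN extraction (group grand-average peak anchors a
  40 ms window; subject amplitudes and own-peak latencies inside family
  search windows), ΔMMN, one-tailed presence tests (t or Wilcoxon after a
  Shapiro-Wilk gate), the paired short-vs-long ISI contrast, and the
  positive-outlier rule (> mean + 1.5·IQR **and** > 2 µV in both long-ISI
  deviant families).
* **Cognition** — PCA on the z-standardized battery, Kaiser retention,
  promax rotation, composites as loading-weighted averages of variables with
  |pattern loading| ≥ 0.50, and baseline-weight reuse for reduced follow-up
  batteries.
* **Inference** — hierarchical regression (age + education first, then an
  MMN index) with ΔR², nested F, standardized β, VIF/tolerance flags and
  residual-normality checks.

## Worked example

```r
library(mmndecay)

cfg <- simulation_config(seed = 1,
                         n_per_group = c(SMI = 14L, naMCI = 19L, aMCI = 24L))
res <- run_decay_study(cfg, families_opt1 = "duration")

fit <- fit_hierarchical(res$analysis, "memory_cs", added = "delta_mmn_dur")
print(fit)
#> <hier_reg> memory_cs ~ age_years + education_years [+ delta_mmn_dur] (n = 57)
#>   R2 reduced = 0.218, R2 full = 0.297, delta R2 = 0.079
#>   nested F(1, 53) = 5.93, p = 0.01828; beta[delta_mmn_dur] = 0.284

pc <- paradigm_contrast(res$analysis$opt1_dur_uv, res$analysis$memtra_dur_uv)
#> t(56) = -11.83, p = 7.2e-17, mean difference = -0.78 uV

mmn_presence_test(res$analysis$memtra_dur_uv)
#> wilcoxon, p = 2.6e-11, mean = -0.55 uV
```

Reading the output: adding the decay score to the covariate-only model
explains an extra 7.9% of the variance in the episodic-memory composite
(standardized β = 0.28, nested F(1, 53) = 5.93) — the simulated coupling
recovered through the entire EEG measurement chain, attenuated by measurement
noise as it would be in a real study. The paradigm contrast confirms the
long-ISI MMN is much smaller than the short-ISI MMN (mean difference
−0.78 µV), and the long-ISI duration MMN is still reliably present
(one-tailed p ≈ 1e-11). About 10% of trials were rejected at the default
100 µV peak-to-peak limit.

Paradigm generation is independent of the simulator:

```r
seq_opt1 <- generate_opt1_sequence(seed = 7)     # 1845 events, 3 blocks
export_sequence(seq_opt1, out_prefix = "opt1")   # WAV per block + events.tsv
```

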