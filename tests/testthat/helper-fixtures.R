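# Independent discrete windowed-mean oracle: mean of a unit Gaussian of width
# `width_ms` over the scoring window samples, computed from the closed form
# (never through the package's scoring code).
window_factor_discrete <- function(width_ms = 15, half_ms = 20, step_ms = 4) {
  t <- seq(-half_ms, half_ms, by = step_ms)
  mean(exp(-t^2 / (2 * width_ms^2)))
}

# Continuous numeric-integral version of the same oracle.
window_factor_integral <- function(width_ms = 15, half_ms = 20) {
  stats::integrate(function(t) exp(-t^2 / (2 * width_ms^2)),
                   -half_ms, half_ms)$value / (2 * half_ms)
}

# Small noise-free cohort with pinned latent parameters, for oracle tests.
noise_free_cohort <- function(n = 3, A = -2, d = 0.25, latency = 180,
                              seed = 11) {
  cfg <- simulation_config(seed = seed, noise_sd_uv = 0, artifact_rate = 0,
                           n_per_group = c(SMI = n, naMCI = 0L, aMCI = 0L))
  co <- simulate_cohort(cfg)
  co$A_duration <- A
  co$A_frequency <- A / 2
  co$decay <- d
  co$latency_ms <- latency
  co$true_delta_uv <- co$A_duration * (1 - co$decay)
  list(cohort = co, config = cfg)
}

# Build an erp_wave holding an analytic single-channel waveform.
analytic_wave <- function(values_fun, sample_rate = 250, subject = "S001",
                          paradigm = "opt1", label = "duration-standard") {
  t <- seq(-100, 350, by = 1000 / sample_rate)
  erp_wave(subject, paradigm, label, "frontocentral", t,
           matrix(values_fun(t), ncol = 1), n_trials_averaged = 1L,
           sample_rate = sample_rate)
}

# Manually built epoch set: data array time x channel x trial.
manual_epochs <- function(data, sample_rate = 250,
                          channels = c("Fz", "FCz", "Cz"),
                          condition = "standard", paradigm = "opt1",
                          subject = "S001") {
  t <- seq(-100, 350, by = 1000 / sample_rate)
  stopifnot(dim(data)[1] == length(t))
  mmndecay:::new_epoch_set(subject, paradigm, condition, channels, t, data,
                           sample_rate)
}
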