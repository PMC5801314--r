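test_that("band-pass attenuates out-of-band content and keeps the passband", {
  sr <- 250
  t <- seq(-100, 350, by = 1000 / sr) / 1000
  rms <- function(x) sqrt(mean(x^2))
  mk <- function(v) manual_epochs(array(rep(v, 3), dim = c(length(v), 3, 1)),
                                  sample_rate = sr)
  hi <- sin(2 * pi * 50 * t)
  out <- bandpass_filter(mk(hi))
  expect_lt(rms(out$data[, 1, 1]), rms(hi) / 4)   # >= 4x at 50 Hz

  dc <- rep(1, length(t))
  out_dc <- bandpass_filter(mk(dc))
  expect_lt(max(abs(out_dc$data[, 1, 1])), 0.01)

  mid <- sin(2 * pi * 10 * t)
  out_mid <- bandpass_filter(mk(mid))
  expect_equal(rms(out_mid$data[, 1, 1]), rms(mid), tolerance = 0.05)

  expect_error(bandpass_filter(mk(mid), 1, 200), "Nyquist")
  expect_error(bandpass_filter(mk(mid), 0, 35), "low_hz")
})

test_that("epoching baseline-corrects and drops out-of-bounds events", {
  sr <- 250
  rec <- matrix(rnorm(3 * sr * 4, mean = 7), ncol = 3,
                dimnames = list(NULL, c("Fz", "FCz", "Cz")))
  onsets <- c(0.05, 1.0, 2.0, 3.9)   # first and last don't fit the window
  expect_message(
    es <- epoch_and_baseline(rec, onsets, sr),
    "dropped 2")
  expect_equal(dim(es$data)[3], 2)   # conservation of in-bounds events
  expect_equal(attr(es, "dropped"), 2)
  pre <- es$time_ms < 0
  expect_equal(max(abs(colMeans(es$data[pre, , 1]))), 0, tolerance = 1e-10)
  expect_error(epoch_and_baseline(rec, numeric(0), sr), "empty")
})

test_that("artifact rejection is exact, conservative and errors sensibly", {
  t_n <- 113
  clean <- array(rnorm(t_n * 3 * 20, sd = 1), dim = c(t_n, 3, 20))
  es <- manual_epochs(clean)
  res <- reject_artifacts(es, limit_uv = 100)
  expect_equal(res$report$n_rejected, 0)
  expect_equal(res$report$fraction_rejected, 0)

  dirty <- clean
  dirty[50, 2, c(3, 11)] <- 500   # two contaminated trials
  res2 <- reject_artifacts(manual_epochs(dirty), limit_uv = 100)
  expect_equal(res2$report$n_rejected, 2)
  expect_equal(res2$report$n_retained + res2$report$n_rejected,
               res2$report$n_in)
  expect_identical(res2$epochs$data, clean[, , -c(3, 11)])

  expect_error(reject_artifacts(es, limit_uv = 0), "positive")
  all_bad <- array(1000 * rnorm(t_n * 3 * 4), dim = c(t_n, 3, 4))
  expect_error(reject_artifacts(manual_epochs(all_bad), 1), "all trials")
})

test_that("rejection under default contamination stays near its rate and under 20%", {
  cfg <- simulation_config(seed = 21, n_per_group = c(SMI = 2L, naMCI = 0L,
                                                      aMCI = 0L))
  co <- simulate_cohort(cfg)
  fr <- unlist(lapply(1:2, function(i) {
    ep <- simulate_epochs(co[i, ], "opt1", cfg,
                          conditions = c("standard", "duration"))
    sapply(ep, function(e) reject_artifacts(e, 100)$report$fraction_rejected)
  }))
  expect_equal(mean(fr), 0.1, tolerance = 0.35)
  expect_true(all(fr <= 0.20))
})

test_that("averaging and resampling preserve the waveform", {
  t_n <- 113
  one <- matrix(rnorm(t_n * 3), ncol = 3)
  same <- array(rep(one, 5), dim = c(t_n, 3, 5))
  avg <- average_and_downsample(manual_epochs(same), target_rate = 250)
  expect_equal(avg$values, one, tolerance = 1e-12)
  expect_equal(avg$n_trials_averaged, 5)

  pm <- array(c(one, -one), dim = c(t_n, 3, 2))
  avg0 <- average_and_downsample(manual_epochs(pm), 250)
  expect_equal(max(abs(avg0$values)), 0)

  empty <- manual_epochs(array(0, dim = c(t_n, 3, 0)))
  expect_error(average_and_downsample(empty), "no trials")

  # 1000 Hz noise-free simulated average downsampled to 250 matches the
  # generator's analytic waveform
  cfg <- simulation_config(seed = 13, noise_sd_uv = 0, artifact_rate = 0,
                           sample_rate = 1000,
                           n_per_group = c(SMI = 1L, naMCI = 0L, aMCI = 0L),
                           trials = list(opt1 = c(standard = 3L, deviant = 3L),
                                         memtra = c(standard = 3L, deviant = 3L)))
  co <- simulate_cohort(cfg)
  ep <- simulate_epochs(co[1, ], "opt1", cfg, conditions = "duration")$duration
  avg <- average_and_downsample(ep, target_rate = 250)
  t250 <- avg$time_ms
  expected <- mmndecay:::obligatory_template(t250) +
    mmndecay:::mmn_component(t250, co$A_duration[1], co$latency_ms[1], 15)
  interior <- t250 > -80 & t250 < 330
  expect_equal(avg$values[interior, 1], expected[interior], tolerance = 0.05)
})

test_that("difference waves and fronto-central pooling are exact linear ops", {
  t <- seq(-100, 350, by = 4)
  v <- matrix(rnorm(length(t) * 3), ncol = 3)
  w1 <- erp_wave("s", "opt1", "duration", c("Fz", "FCz", "Cz"), t, v, 10, 250)
  w2 <- erp_wave("s", "opt1", "standard", c("Fz", "FCz", "Cz"), t, v, 10, 250)
  expect_equal(max(abs(difference_wave(w1, w2)$values)), 0)

  c_wave <- matrix(rnorm(length(t) * 3), ncol = 3)
  w3 <- erp_wave("s", "opt1", "duration", c("Fz", "FCz", "Cz"), t, v + c_wave, 10, 250)
  w4 <- erp_wave("s", "opt1", "standard", c("Fz", "FCz", "Cz"), t, c_wave, 10, 250)
  expect_equal(difference_wave(w3, w4)$values, v, tolerance = 1e-12)

  w5 <- erp_wave("s", "opt1", "standard", c("Fz", "FCz", "Cz"), t + 4, v, 10, 250)
  expect_error(difference_wave(w1, w5), "time axes")

  fc <- frontocentral_mean(w1)
  expect_equal(fc$values[, 1], rowMeans(v))
  const <- erp_wave("s", "opt1", "x", c("Fz", "FCz", "Cz"), t,
                    matrix(rep(c(1, 2, 3), each = length(t)), ncol = 3), 1, 250)
  expect_equal(unique(frontocentral_mean(const)$values[, 1]), 2)
  perm <- erp_wave("s", "opt1", "x", c("Cz", "Fz", "FCz"), t,
                   v[, c(3, 1, 2)], 10, 250)
  expect_equal(frontocentral_mean(perm)$values, fc$values)
  miss <- erp_wave("s", "opt1", "x", c("Fz", "FCz", "Pz"), t, v, 10, 250)
  expect_error(frontocentral_mean(miss), "Cz")
})

test_that("the chain is linear in the input voltages (up to rejection)", {
  nf <- noise_free_cohort(n = 1, A = -1.5, d = 0.5)
  cfg <- nf$config
  cfg$trials <- list(opt1 = c(standard = 4L, deviant = 4L),
                     memtra = c(standard = 4L, deviant = 4L))
  ep <- simulate_epochs(nf$cohort[1, ], "opt1", cfg,
                        conditions = c("standard", "duration"))
  out1 <- process_subject(ep, filter_stage = "trial")
  k <- 2.5
  ep_k <- ep
  for (nm in names(ep_k)) ep_k[[nm]]$data <- ep_k[[nm]]$data * k
  out2 <- process_subject(ep_k, filter_stage = "trial")
  expect_equal(out2$difference$duration$values,
               k * out1$difference$duration$values, tolerance = 1e-9)
})

test_that("trial-level and average-level filtering agree without artifacts", {
  cfg <- simulation_config(seed = 17, artifact_rate = 0,
                           n_per_group = c(SMI = 1L, naMCI = 0L, aMCI = 0L),
                           trials = list(opt1 = c(standard = 30L, deviant = 20L),
                                         memtra = c(standard = 10L, deviant = 10L)))
  co <- simulate_cohort(cfg)
  ep <- simulate_epochs(co[1, ], "opt1", cfg,
                        conditions = c("standard", "duration"))
  a <- process_subject(ep, filter_stage = "trial")
  b <- process_subject(ep, filter_stage = "average")
  expect_equal(a$difference$duration$values, b$difference$duration$values,
               tolerance = 1e-9)
})
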