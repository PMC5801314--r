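test_that("the default cohort reproduces the study's group structure", {
  co <- simulate_cohort(simulation_config(seed = 2))
  expect_equal(nrow(co), 59)
  expect_equal(as.integer(table(co$group)[c("SMI", "naMCI", "aMCI")]),
               c(16L, 19L, 24L))
  expect_true(all(co$decay >= 0 & co$decay <= 1))
  expect_true(all(co$A_duration < 0))
  expect_true(all(co$age_years > 0 & co$education_years > 0))
  expect_true(all(mmndecay:::battery_layout()$variable %in% names(co)))
})

test_that("latent coupling behaves at its edges", {
  # no coupling: decay score and memory-block battery essentially uncorrelated
  cfg0 <- simulation_config(seed = 5, coupling_beta = 0,
                            n_per_group = c(SMI = 150L, naMCI = 150L, aMCI = 100L))
  co0 <- simulate_cohort(cfg0)
  mem_proxy <- rowMeans(scale(co0[, c("MVGT_enc", "MVGT_rec")]))
  r <- cor(co0$true_delta_uv, mem_proxy)
  expect_lt(abs(r), 3 / sqrt(nrow(co0)))

  # full retention: no decay, so the true decay score is identically zero
  cfg1 <- simulation_config(seed = 6,
                            decay_mean = c(SMI = 1, naMCI = 1, aMCI = 1),
                            decay_sd = 0)
  expect_true(all(simulate_cohort(cfg1)$true_delta_uv == 0))
})

test_that("stronger decay lowers expected retention and decay scores", {
  deltas <- sapply(c(0.2, 0.5, 0.8), function(dm) {
    cfg <- simulation_config(seed = 31,
                             decay_mean = c(SMI = dm, naMCI = dm, aMCI = dm))
    mean(simulate_cohort(cfg)$true_delta_uv)
  })
  expect_true(all(diff(deltas) > 0))  # higher retention -> delta closer to 0
})

test_that("battery has the two-block correlation structure", {
  cfg <- simulation_config(seed = 8, n_per_group = c(SMI = 100L, naMCI = 100L,
                                                     aMCI = 100L))
  co <- simulate_cohort(cfg)
  lay <- mmndecay:::battery_layout()
  z <- scale(co[, lay$variable])
  z[, negated_battery_variables()] <- -z[, negated_battery_variables()]
  cm <- cor(z)
  mem <- lay$variable[lay$block == "memory"]
  ef <- setdiff(lay$variable[lay$block == "ef"], "ECB")
  within <- c(cm[mem, mem][upper.tri(diag(length(mem)))],
              cm[ef, ef][upper.tri(diag(length(ef)))])
  between <- as.vector(cm[mem, ef])
  expect_gt(mean(within), mean(abs(between)))
})

test_that("simulation is reproducible and epochs carry the injected signal", {
  cfg <- simulation_config(seed = 4, n_per_group = c(SMI = 2L, naMCI = 0L,
                                                     aMCI = 0L))
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  s <- co1[1, ]
  e1 <- simulate_epochs(s, "opt1", cfg, conditions = c("standard", "duration"))
  e2 <- simulate_epochs(s, "opt1", cfg, conditions = c("standard", "duration"))
  expect_identical(e1$duration$data, e2$duration$data)

  # noise-free: deviant-minus-standard mean equals the injected Gaussian
  nf <- noise_free_cohort(n = 1, A = -2, d = 0.25)
  subj <- nf$cohort[1, ]
  ep <- simulate_epochs(subj, "memtra", nf$config,
                        conditions = c("standard", "duration"))
  dif <- rowMeans(ep$duration$data, dims = 2) -
    rowMeans(ep$standard$data, dims = 2)
  t_ms <- ep$duration$time_ms
  injected <- -2 * 0.25 * exp(-(t_ms - 180)^2 / (2 * 15^2))
  for (ch in 1:3) expect_equal(dif[, ch], injected, tolerance = 1e-12)
  expect_equal(min(injected), -0.5)  # A*d at the peak
})

test_that("artifact contamination matches its nominal rate", {
  cfg <- simulation_config(seed = 10, artifact_rate = 0.1,
                           trials = list(opt1 = c(standard = 1000L, deviant = 10L),
                                         memtra = c(standard = 83L, deviant = 65L)),
                           n_per_group = c(SMI = 1L, naMCI = 0L, aMCI = 0L))
  co <- simulate_cohort(cfg)
  ep <- simulate_epochs(co[1, ], "opt1", cfg, conditions = "standard")
  # count trials whose range is implausible for 3 uV noise alone
  d <- ep$standard$data
  p2p <- apply(matrix(d, nrow = dim(d)[1]), 2, function(v) max(v) - min(v))
  n_bad <- sum(colSums(matrix(p2p > 60, nrow = 3)) > 0)
  # binomial 99% interval around 100 of 1000
  expect_gt(n_bad, stats::qbinom(0.005, 1000, 0.1))
  expect_lt(n_bad, stats::qbinom(0.995, 1000, 0.1))
})

test_that("epoch containers round-trip losslessly and reject corrupt files", {
  cfg <- simulation_config(seed = 12, n_per_group = c(SMI = 1L, naMCI = 0L,
                                                      aMCI = 0L),
                           trials = list(opt1 = c(standard = 5L, deviant = 4L),
                                         memtra = c(standard = 5L, deviant = 4L)))
  co <- simulate_cohort(cfg)
  ep <- simulate_epochs(co[1, ], "opt1", cfg,
                        conditions = c("standard", "duration"))$duration
  p <- tempfile(fileext = ".epo")
  write_epochs(ep, p)
  back <- read_epochs(p)
  expect_identical(back$data, ep$data)
  expect_identical(back$channels, ep$channels)
  expect_equal(back$time_ms, ep$time_ms)
  expect_equal(back$sample_rate, ep$sample_rate)
  expect_identical(back$condition, ep$condition)

  expect_error(read_epochs(tempfile()), "not found")
  # container whose header lacks the channel table
  bad <- tempfile()
  con <- file(bad, "wb")
  writeChar("MMNEPOCH1\n", con, eos = NULL)
  hdr <- charToRaw('{"subject_id":"x","dim":[1,1,1],"time_ms":[0]}')
  writeBin(length(hdr), con, size = 4, endian = "little")
  writeBin(hdr, con)
  writeBin(0.0, con, size = 8, endian = "little")
  close(con)
  expect_error(read_epochs(bad), "channel")
  unlink(c(p, bad))
})
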