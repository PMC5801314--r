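test_that("grand averages behave as unweighted means", {
  w <- analytic_wave(function(t) -exp(-(t - 180)^2 / 450))
  expect_equal(grand_average(list(w))$values, w$values)
  expect_equal(grand_average(list(w, w, w))$values, w$values)
  w_neg <- w; w_neg$values <- -w_neg$values
  expect_equal(max(abs(grand_average(list(w, w_neg))$values)), 0)
  expect_error(grand_average(list()), "empty")
})

test_that("group peak detection finds minima with the documented tie-break", {
  g <- analytic_wave(function(t) -2 * exp(-(t - 180)^2 / 450))
  expect_equal(find_group_peak(g, "duration"), 180)
  expect_equal(find_group_peak(g, "frequency"), 180)

  # the 250/s grid runs -100, -96, ...: the last sample inside the 100-250 ms
  # window is 248 ms and the first inside 125-275 ms is 128 ms
  dec <- analytic_wave(function(t) -t)      # decreasing over any window
  expect_equal(find_group_peak(dec, "frequency"), 248)   # window end
  flat <- analytic_wave(function(t) rep(0, length(t)))
  expect_equal(find_group_peak(flat, "duration"), 128)   # earliest tie
  short <- analytic_wave(function(t) -t, sample_rate = 250)
  short$time_ms <- short$time_ms - 400     # window now outside epoch
  expect_error(find_group_peak(short, "gap"), "outside")
})

test_that("windowed-mean amplitude matches the numeric-integral oracle", {
  peak <- -2; width <- 15
  w <- analytic_wave(function(t) peak * exp(-(t - 180)^2 / (2 * width^2)))
  s <- score_subject(w, 180, "duration")
  # exact against the independent discrete closed form
  expect_equal(s$amplitude_uv, peak * window_factor_discrete(width),
               tolerance = 1e-9)
  # and within 5% of the continuous numeric integral
  expect_equal(s$amplitude_uv, peak * window_factor_integral(width),
               tolerance = 0.05)
  expect_equal(s$latency_ms, 180)

  z <- analytic_wave(function(t) rep(0, length(t)))
  sz <- score_subject(z, 180, "duration")
  expect_equal(sz$amplitude_uv, 0)
  expect_equal(sz$latency_ms, 128)   # first in-window sample on a flat wave

  expect_warning(score_subject(w, 340, "duration"), "clipped")
})

test_that("subject scores equal grand-average scores for identical cohorts", {
  w <- analytic_wave(function(t) -1.4 * exp(-(t - 200)^2 / 500))
  waves <- list(S001 = w, S002 = w, S003 = w)
  groups <- c(S001 = "SMI", S002 = "SMI", S003 = "SMI")
  sc <- score_cohort(waves, groups, "duration")
  g <- grand_average(waves)
  gs <- score_subject(g, find_group_peak(g, "duration"), "duration")
  expect_equal(sc$amplitude_uv, rep(gs$amplitude_uv, 3))
  expect_equal(sc$latency_ms, rep(gs$latency_ms, 3))
})

test_that("the decay score is the short-minus-long amplitude difference", {
  mk <- function(amp, par) {
    w <- analytic_wave(function(t) amp * exp(-(t - 180)^2 / 450),
                       paradigm = par)
    score_subject(w, 180, "duration")
  }
  s_short <- mk(-2, "opt1"); s_long <- mk(-1, "memtra")
  d <- delta_mmn(s_short, s_long)
  expect_equal(d$delta_uv, s_short$amplitude_uv - s_long$amplitude_uv)
  expect_lt(d$delta_uv, 0)
  expect_equal(delta_mmn(s_short, s_short)$delta_uv, 0)   # equal MMNs: no decay
  s_freq <- mk(-1, "memtra"); s_freq$family <- "frequency"
  expect_error(delta_mmn(s_short, s_freq), "families")
})

test_that("noise-free pipeline recovers the analytic decay score", {
  A <- -2; d_ret <- 0.25
  nf <- noise_free_cohort(n = 2, A = A, d = d_ret, latency = 180)
  cfg <- nf$config
  cfg$trials <- list(opt1 = c(standard = 3L, deviant = 3L),
                     memtra = c(standard = 3L, deviant = 3L))
  subj <- nf$cohort[1, ]
  waves <- lapply(c("opt1", "memtra"), function(par) {
    ep <- simulate_epochs(subj, par, cfg, conditions = c("standard", "duration"))
    process_subject(ep, filter_stage = "trial")$difference$duration
  })
  s1 <- score_subject(waves[[1]], 180, "duration")
  s2 <- score_subject(waves[[2]], 180, "duration")
  wf <- window_factor_discrete(15)
  expect_equal(s1$amplitude_uv, A * wf, tolerance = 0.05)
  expect_equal(s2$amplitude_uv, A * d_ret * wf, tolerance = 0.05)
  dd <- delta_mmn(s1, s2)
  expect_equal(dd$delta_uv, A * (1 - d_ret) * wf, tolerance = 0.05)
  expect_equal(s1$latency_ms, 180, tolerance = 4)  # one sample at 250/s

  # scored delta moves monotonically toward zero as retention grows
  deltas <- sapply(c(0.1, 0.5, 0.9), function(dr) {
    co <- noise_free_cohort(n = 1, A = A, d = dr, latency = 180)
    subj <- co$cohort[1, ]
    cfg2 <- co$config
    cfg2$trials <- cfg$trials
    ws <- lapply(c("opt1", "memtra"), function(par) {
      ep <- simulate_epochs(subj, par, cfg2,
                            conditions = c("standard", "duration"))
      process_subject(ep, filter_stage = "trial")$difference$duration
    })
    delta_mmn(score_subject(ws[[1]], 180, "duration"),
              score_subject(ws[[2]], 180, "duration"))$delta_uv
  })
  expect_true(all(diff(deltas) > 0))
})

test_that("positive-outlier exclusion requires both deviant families", {
  set.seed(33)
  n <- 30
  mk_scores <- function(dur, freq) {
    rbind(data.frame(subject_id = sprintf("S%03d", 1:n), family = "duration",
                     amplitude_uv = dur, stringsAsFactors = FALSE),
          data.frame(subject_id = sprintf("S%03d", 1:n), family = "frequency",
                     amplitude_uv = freq, stringsAsFactors = FALSE))
  }
  dur <- rnorm(n, -1, 0.4); freq <- rnorm(n, -0.4, 0.4)
  dur[c(3, 7)] <- c(2.6, 3.1); freq[c(3, 7)] <- c(2.5, 2.8)  # broken in both
  dur[12] <- 2.9                                             # one family only
  out <- flag_positive_outliers(mk_scores(dur, freq))
  expect_setequal(out$excluded, c("S003", "S007"))
  expect_false("S012" %in% out$excluded)

  clean <- flag_positive_outliers(mk_scores(rnorm(n, -1, 0.3),
                                            rnorm(n, -0.4, 0.3)))
  expect_length(clean$excluded, 0)
})

test_that("presence tests detect negative MMNs and stay calibrated", {
  set.seed(44)
  strong <- -2 + rnorm(20, sd = 0.01)
  res <- mmn_presence_test(strong)
  expect_lt(res$p_value, 0.001)

  sym <- c(-5:-1, 1:5) / 10      # exactly symmetric around zero
  res0 <- mmn_presence_test(sym)
  expect_equal(res0$p_value, 0.5, tolerance = 0.05)
  expect_error(mmn_presence_test(c(-1, 1)), "at least 3")
})

test_that("the paradigm contrast behaves under effect, null and sign flip", {
  set.seed(55)
  opt1 <- rnorm(30, -1.6, 0.5)
  memtra <- rnorm(30, -0.6, 0.5)
  pc <- paradigm_contrast(opt1, memtra)
  expect_lt(pc$p_value, 0.001)
  expect_lt(pc$mean_difference, 0)   # short-ISI MMN more negative

  same <- paradigm_contrast(opt1, opt1)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  flip <- paradigm_contrast(memtra, opt1)
  expect_equal(flip$t, -pc$t, tolerance = 1e-12)
})
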