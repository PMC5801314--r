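#' MMN search windows per deviant family
#'
#' The most-negative-peak search window after deviant onset: 100-250 ms for
#' frequency, intensity and location deviants; 125-275 ms for the duration
#' deviant; 134-284 ms for the gap deviant.
#'
#' @param family Deviant family name.
#' @return Numeric length-2, window start and end in ms.
#' @export
mmn_search_window <- function(family) {
  switch(family,
         duration = c(125, 275),
         gap = c(134, 284),
         frequency = , intensity = , location = c(100, 250),
         stop("mmn_search_window: unknown deviant family: ", family))
}

#' Grand-average wave across subjects
#'
#' Unweighted mean of per-subject waves (typically pooled fronto-central
#' difference waves within a diagnostic group).
#'
#' @param waves List of `erp_wave`s on a common time axis and channel set.
#' @return An `erp_wave` labelled with the number of subjects averaged.
#' @export
grand_average <- function(waves) {
  if (length(waves) == 0) stop("grand_average: empty group")
  ref <- waves[[1]]
  for (w in waves) {
    if (!isTRUE(all.equal(w$time_ms, ref$time_ms)))
      stop("grand_average: time axes differ")
    if (!identical(w$channels, ref$channels))
      stop("grand_average: channel sets differ")
  }
  vals <- Reduce(`+`, lapply(waves, `[[`, "values")) / length(waves)
  erp_wave(sprintf("grand(n=%d)", length(waves)), ref$paradigm, ref$label,
           ref$channels, ref$time_ms, vals,
           n_trials_averaged = length(waves), sample_rate = ref$sample_rate)
}

#' Latency of the most negative peak of a grand-average wave
#'
#' Argmin of the (single-channel) wave within the family's search window;
#' ties are broken toward the earlier latency.
#'
#' @param grand A single-channel `erp_wave` (e.g. from [grand_average()]).
#' @param family Deviant family, selects the search window.
#' @return Peak latency in ms.
#' @export
find_group_peak <- function(grand, family) {
  stopifnot(inherits(grand, "erp_wave"))
  win <- mmn_search_window(family)
  idx <- which(grand$time_ms >= win[1] & grand$time_ms <= win[2])
  if (length(idx) == 0)
    stop("find_group_peak: search window lies outside the epoch")
  v <- grand$values[idx, 1]
  grand$time_ms[idx[which.min(v)]]   # which.min takes the earliest tie
}

#' Score one subject's MMN amplitude and latency
#'
#' Two-stage scoring: amplitude is the mean voltage of the subject's
#' fronto-central difference wave in a 40 ms window centered at the
#' group-level grand-average peak; latency is the subject's own most negative
#' peak within the family's search window. A window extending past the epoch
#' is clipped with a warning.
#'
#' @param wave Single-channel fronto-central difference `erp_wave`.
#' @param group_peak_ms Group grand-average peak latency (ms), from
#'   [find_group_peak()].
#' @param family Deviant family.
#' @param window_ms Scoring window length, ms (40).
#' @return Data frame row: `subject_id`, `paradigm`, `family`,
#'   `amplitude_uv`, `latency_ms`, plus the windows used.
#' @export
score_subject <- function(wave, group_peak_ms, family, window_ms = 40) {
  stopifnot(inherits(wave, "erp_wave"))
  half <- window_ms / 2
  lo <- group_peak_ms - half
  hi <- group_peak_ms + half
  if (lo < min(wave$time_ms) || hi > max(wave$time_ms)) {
    warning("score_subject: scoring window clipped to the epoch")
    lo <- max(lo, min(wave$time_ms)); hi <- min(hi, max(wave$time_ms))
  }
  idx <- which(wave$time_ms >= lo & wave$time_ms <= hi)
  amp <- mean(wave$values[idx, 1])
  win <- mmn_search_window(family)
  sidx <- which(wave$time_ms >= win[1] & wave$time_ms <= win[2])
  lat <- wave$time_ms[sidx[which.min(wave$values[sidx, 1])]]
  data.frame(subject_id = wave$subject_id, paradigm = wave$paradigm,
             family = family, amplitude_uv = amp, latency_ms = lat,
             search_lo_ms = win[1], search_hi_ms = win[2],
             scoring_lo_ms = lo, scoring_hi_ms = hi,
             stringsAsFactors = FALSE)
}

#' Short-minus-long ISI difference score
#'
#' The auditory memory-trace decay score: MMN amplitude after the short ISI
#' (Optimum-1) minus MMN amplitude after the long ISI (Memory-Trace), for the
#' same subject and deviant family. Zero means no decay (the trace survives
#' the 3 s interval); because MMN amplitudes are negative, stronger decay
#' gives more negative values and higher values indicate less decay.
#'
#' @param opt1,memtra Score rows from [score_subject()] for the same subject
#'   and family, from the short- and long-ISI paradigms respectively.
#' @return Data frame row with `delta_uv` and its two components.
#' @export
delta_mmn <- function(opt1, memtra) {
  if (!identical(opt1$family, memtra$family))
    stop("delta_mmn: deviant families differ")
  if (!identical(opt1$subject_id, memtra$subject_id))
    stop("delta_mmn: subjects differ")
  data.frame(subject_id = opt1$subject_id, family = opt1$family,
             delta_uv = opt1$amplitude_uv - memtra$amplitude_uv,
             opt1_uv = opt1$amplitude_uv, memtra_uv = memtra$amplitude_uv,
             stringsAsFactors = FALSE)
}

#' Flag implausible positive Memory-Trace amplitudes
#'
#' Single-pass exclusion rule over the cohort's long-ISI scores: a subject is
#' excluded iff, for BOTH deviant families (duration and frequency), the
#' amplitude exceeds the cohort mean + 1.5 x interquartile range AND exceeds
#' +2 microvolts. Such abnormally positive difference scores indicate the
#' paradigm did not work for that subject.
#'
#' @param scores Data frame of Memory-Trace scores with columns `subject_id`,
#'   `family`, `amplitude_uv`, containing both `duration` and `frequency`
#'   rows.
#' @param iqr_type Quantile convention passed to [stats::IQR()] (default 7,
#'   the inclusive convention).
#' @return List with `excluded` (subject ids) and `details` (per-subject
#'   component values and the per-family cutoffs).
#' @export
flag_positive_outliers <- function(scores, iqr_type = 7) {
  fams <- c("duration", "frequency")
  if (!all(fams %in% scores$family))
    stop("flag_positive_outliers: both duration and frequency scores are required")
  cut <- sapply(fams, function(f) {
    a <- scores$amplitude_uv[scores$family == f]
    mean(a) + 1.5 * stats::IQR(a, type = iqr_type)
  })
  wide <- merge(
    scores[scores$family == "duration", c("subject_id", "amplitude_uv")],
    scores[scores$family == "frequency", c("subject_id", "amplitude_uv")],
    by = "subject_id", suffixes = c("_duration", "_frequency"))
  flag <- (wide$amplitude_uv_duration > cut["duration"] &
             wide$amplitude_uv_duration > 2 &
             wide$amplitude_uv_frequency > cut["frequency"] &
             wide$amplitude_uv_frequency > 2)
  list(excluded = wide$subject_id[flag],
       details = cbind(wide, flagged = flag),
       cutoffs = cut)
}

#' Test for the presence of an MMN (amplitudes below zero)
#'
#' Normality of the amplitude sample is assessed with the Shapiro-Wilk test
#' (alpha = 0.05); a one-tailed one-sample t-test against zero (alternative:
#' mean < 0) is used for normal samples and a one-tailed Wilcoxon signed-rank
#' test otherwise.
#'
#' @param amplitudes Numeric vector of per-subject MMN amplitudes
#'   (microvolts), n >= 3.
#' @return List: `test` (`"t"` or `"wilcoxon"`), `statistic`, `p_value`,
#'   `shapiro_p`, `n`, `mean`.
#' @export
mmn_presence_test <- function(amplitudes) {
  n <- length(amplitudes)
  if (n < 3) stop("mmn_presence_test: need at least 3 amplitudes")
  sw <- stats::shapiro.test(amplitudes)
  if (sw$p.value >= 0.05) {
    ht <- stats::t.test(amplitudes, mu = 0, alternative = "less")
    test <- "t"
  } else {
    ht <- stats::wilcox.test(amplitudes, mu = 0, alternative = "less",
                             exact = FALSE)
    test <- "wilcoxon"
  }
  list(test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
       shapiro_p = sw$p.value, n = n, mean = mean(amplitudes))
}

#' Within-subject contrast of short- vs long-ISI MMN amplitude
#'
#' Paired two-sided t-test of the Optimum-1 versus Memory-Trace duration
#' MMN amplitudes; a positive mean difference (Optimum-1 more negative ...
#' i.e. memtra minus opt1 positive) indicates attenuation of the MMN at the
#' 3 s ISI, the paradigm's memory-trace decay effect.
#'
#' @param opt1_uv,memtra_uv Paired numeric vectors of duration-deviant
#'   amplitudes (complete cases, same subject order).
#' @return List: `t`, `df`, `p_value`, `mean_difference` (opt1 - memtra),
#'   `conf_int`, `n`.
#' @export
paradigm_contrast <- function(opt1_uv, memtra_uv) {
  ok <- stats::complete.cases(opt1_uv, memtra_uv)
  if (sum(ok) < 3) stop("paradigm_contrast: need at least 3 complete pairs")
  diffs <- opt1_uv[ok] - memtra_uv[ok]
  if (stats::sd(diffs) == 0 && mean(diffs) == 0)
    return(list(t = 0, df = sum(ok) - 1, p_value = 1, mean_difference = 0,
                conf_int = c(0, 0), n = sum(ok)))
  ht <- stats::t.test(opt1_uv[ok], memtra_uv[ok], paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = unname(ht$estimate),
       conf_int = as.numeric(ht$conf.int), n = sum(ok))
}

#' Two-stage MMN scoring of a cohort of difference waves
#'
#' Applies the group-anchored two-stage procedure: per group (and paradigm x
#' family), the grand-average peak latency anchors the 40 ms scoring window,
#' then every subject's amplitude and own peak latency are extracted.
#'
#' @param waves Named list (by subject id) of per-subject single-channel
#'   difference `erp_wave`s for one paradigm and family.
#' @param groups Named character vector mapping subject id to group label;
#'   with `pooled = TRUE` a single cohort-wide anchor is used instead.
#' @param family Deviant family.
#' @param pooled Use one pooled anchor instead of per-group anchors (off by
#'   default).
#' @return Data frame of per-subject scores with a `group` and
#'   `group_peak_ms` column.
#' @export
score_cohort <- function(waves, groups, family, pooled = FALSE) {
  ids <- names(waves)
  grp <- if (pooled) rep("all", length(ids)) else as.character(groups[ids])
  out <- lapply(unique(grp), function(g) {
    sel <- ids[grp == g]
    peak <- find_group_peak(grand_average(waves[sel]), family)
    rows <- do.call(rbind, lapply(waves[sel], score_subject,
                                  group_peak_ms = peak, family = family))
    rows$group <- g
    rows$group_peak_ms <- peak
    rows
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
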