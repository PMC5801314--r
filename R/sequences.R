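# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

tone_duration_s <- function(kind) ifelse(kind == "duration", 0.025, 0.075)

new_paradigm_sequence <- function(paradigm, events, seed, soa_s = NULL, isi_menu_s = NULL) {
  structure(list(paradigm = paradigm, events = events, soa_s = soa_s,
                 isi_menu_s = isi_menu_s, seed = seed),
            class = "paradigm_sequence")
}

#' @export
print.paradigm_sequence <- function(x, ...) {
  tab <- table(deviant_family(x$events$kind))
  cat(sprintf("<paradigm_sequence> %s, %d events in %d blocks (seed %d)\n",
              x$paradigm, nrow(x$events), length(unique(x$events$block)), x$seed))
  print(tab)
  invisible(x)
}

# Draw a family sequence with given per-family slot counts and no two
# consecutive slots of the same family. Sequential weighted sampling with a
# feasibility guard: a family holding more than half of the remaining slots
# (rounded up) must be placed immediately.
draw_family_sequence <- function(counts) {
  fams <- names(counts)
  out <- character(sum(counts))
  prev <- ""
  for (i in seq_along(out)) {
    remaining <- sum(counts)
    cand <- fams[counts > 0 & fams != prev]
    if (length(cand) == 0)
      stop("sequence generation: no admissible family left (infeasible constraint)")
    forced <- cand[counts[cand] >= (remaining + 1) / 2]
    if (length(forced) >= 2)
      stop("sequence generation: two families each need more than half of the remaining slots")
    pick <- if (length(forced) == 1) forced else
      sample(cand, 1, prob = counts[cand])
    out[i] <- pick
    counts[pick] <- counts[pick] - 1L
    prev <- pick
  }
  out
}

# Split n_fam family slots into sub-variant kinds, half and half, in random order.
assign_subvariants <- function(family, n) {
  subs <- switch(family,
                 frequency = c("frequency_high", "frequency_low"),
                 intensity = c("intensity_loud", "intensity_soft"),
                 location  = c("location_left", "location_right"),
                 NULL)
  if (is.null(subs)) return(rep(family, n))
  sample(rep(subs, each = n / 2))
}

#' Generate an Optimum-1 stimulus sequence
#'
#' Builds the multi-deviant short-SOA paradigm: 3 blocks of 615 events (1845
#' total), each block beginning with 15 standard tones followed by 600 events
#' in strict standard/deviant alternation at a fixed 0.5 s stimulus-onset
#' asynchrony. Within a block each of the five deviant families (duration,
#' gap, frequency, intensity, location) fills exactly 60 of the 300 deviant
#' slots (10% of the alternating events); consecutive deviants always differ
#' in family, and sub-variants (high/low, loud/soft, left/right) split 50/50
#' within their family.
#'
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param n_blocks Number of blocks (default 3).
#' @return A `paradigm_sequence` whose `events` data frame has columns
#'   `block`, `onset_s` (from block start), `kind`, `isi_before_s` (silence
#'   since the previous tone's offset; `NA` for the first tone of a block).
#' @export
generate_opt1_sequence <- function(seed = 1L, n_blocks = 3L) {
  soa <- 0.5
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      fam_counts <- c(duration = 60L, gap = 60L, frequency = 60L,
                      intensity = 60L, location = 60L)
      fam_seq <- draw_family_sequence(fam_counts)
      kinds_dev <- character(length(fam_seq))
      for (f in names(fam_counts)) {
        idx <- which(fam_seq == f)
        kinds_dev[idx] <- assign_subvariants(f, length(idx))
      }
      kinds <- c(rep("standard", 15L),
                 as.vector(rbind(rep("standard", 300L), kinds_dev)))
      onset <- (seq_along(kinds) - 1) * soa
      dur <- tone_duration_s(kinds)
      isi <- c(NA_real_, onset[-1] - onset[-length(onset)] - dur[-length(dur)])
      data.frame(block = b, onset_s = round(onset, 6), kind = kinds,
                 isi_before_s = round(isi, 6), stringsAsFactors = FALSE)
    })
    new_paradigm_sequence("opt1", do.call(rbind, blocks), seed, soa_s = soa)
  })
}

# Randomly split `total` standards into `n_runs` inter-deviant runs of length
# min..max each: start all runs at min and distribute the surplus one by one.
allocate_runs <- function(n_runs, total, min_len = 1L, max_len = 3L) {
  if (total < n_runs * min_len || total > n_runs * max_len)
    stop(sprintf(
      "sequence generation: cannot place %d standards into %d runs of %d-%d",
      total, n_runs, min_len, max_len))
  len <- rep(min_len, n_runs)
  for (i in seq_len(total - n_runs * min_len)) {
    open <- which(len < max_len)
    j <- if (length(open) == 1) open else sample(open, 1)
    len[j] <- len[j] + 1L
  }
  len
}

#' Generate a Memory-Trace stimulus sequence
#'
#' Builds the long-ISI paradigm probing the persistence of the auditory
#' sensory memory trace: 3 blocks of 154 events (462 total). Each block starts
#' with 15 standard tones; the remaining 139 events are 26 duration deviants,
#' 26 frequency deviants (13 higher, 13 lower) and 87 interleaved standards,
#' arranged so that 1-3 standards separate consecutive deviants. Every deviant
#' follows a standard tone after a silent interval of exactly 3.0 s; all other
#' inter-stimulus intervals are drawn pseudorandomly from the menu
#' {0.5, 1.5, 3.0} s. Standards thus make up 306/462 = 66.2% of events and
#' each deviant family 78/462 = 16.9%.
#'
#' @inheritParams generate_opt1_sequence
#' @return A `paradigm_sequence`; see [generate_opt1_sequence()] for the
#'   `events` columns.
#' @export
generate_memtra_sequence <- function(seed = 1L, n_blocks = 3L) {
  isi_menu <- c(0.5, 1.5, 3.0)
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      dev_kinds <- sample(c(rep("duration", 26L),
                            rep("frequency_high", 13L), rep("frequency_low", 13L)))
      runs <- allocate_runs(n_runs = 51L, total = 87L)
      kinds <- rep("standard", 15L)
      for (i in seq_along(dev_kinds)) {
        kinds <- c(kinds, dev_kinds[i])
        if (i <= length(runs)) kinds <- c(kinds, rep("standard", runs[i]))
      }
      n <- length(kinds)
      is_dev <- kinds != "standard"
      isi <- c(NA_real_, sample(isi_menu, n - 1L, replace = TRUE))
      isi[is_dev] <- 3.0
      dur <- tone_duration_s(kinds)
      onset <- cumsum(c(0, dur[-n] + isi[-1]))
      data.frame(block = b, onset_s = round(onset, 6), kind = kinds,
                 isi_before_s = round(isi, 6), stringsAsFactors = FALSE)
    })
    new_paradigm_sequence("memtra", do.call(rbind, blocks), seed,
                          isi_menu_s = isi_menu)
  })
}

#' Export a paradigm sequence as audio plus an event table
#'
#' Writes one stereo 16-bit WAV file per block (tones rendered from their
#' specifications and placed at their onsets, silence elsewhere) and a single
#' tab-separated event table with columns `block`, `onset_s`, `kind`,
#' `isi_before_s` ('.' decimal separator, 6 decimal places). Re-reading the
#' event table with [read_event_table()] reconstructs the sequence's events.
#'
#' @param seq A `paradigm_sequence`.
#' @param specs Named list of tone specifications, as from
#'   [standard_and_deviant_specs()].
#' @param sample_rate Audio sample rate, samples/s.
#' @param out_prefix Path prefix; files `<prefix>_events.tsv` and
#'   `<prefix>_block<k>.wav` are created.
#' @param audio If `FALSE`, only the event table is written.
#' @return Character vector of the written file paths, invisibly.
#' @export
export_sequence <- function(seq, specs = standard_and_deviant_specs(),
                            sample_rate = 48000, out_prefix, audio = TRUE) {
  stopifnot(inherits(seq, "paradigm_sequence"))
  ev <- seq$events
  tsv <- paste0(out_prefix, "_events.tsv")
  out <- data.frame(block = ev$block,
                    onset_s = sprintf("%.6f", ev$onset_s),
                    kind = ev$kind,
                    isi_before_s = ifelse(is.na(ev$isi_before_s), "NA",
                                          sprintf("%.6f", ev$isi_before_s)))
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- tsv
  if (audio) {
    waves <- lapply(specs, synthesize_tone, sample_rate = sample_rate)
    for (b in unique(ev$block)) {
      eb <- ev[ev$block == b, ]
      last_kind <- eb$kind[nrow(eb)]
      total <- eb$onset_s[nrow(eb)] + tone_duration_s(last_kind)
      n <- ceiling(total * sample_rate)
      block_wave <- matrix(0, nrow = n, ncol = 2)
      for (i in seq_len(nrow(eb))) {
        w <- waves[[eb$kind[i]]]
        i0 <- round(eb$onset_s[i] * sample_rate) + 1L
        block_wave[i0:(i0 + nrow(w) - 1L), ] <- block_wave[i0:(i0 + nrow(w) - 1L), ] + w
      }
      p <- sprintf("%s_block%d.wav", out_prefix, b)
      write_wav(block_wave, p, sample_rate)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read an exported event table
#'
#' @param path A tab-separated event table written by [export_sequence()].
#' @return Data frame with columns `block`, `onset_s`, `kind`, `isi_before_s`.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("read_event_table: file not found: ", path)
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  needed <- c("block", "onset_s", "kind", "isi_before_s")
  if (!all(needed %in% names(ev)))
    stop("read_event_table: missing columns: ",
         paste(setdiff(needed, names(ev)), collapse = ", "))
  ev[needed]
}
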