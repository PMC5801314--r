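#' Acoustic specification of a harmonic stimulus tone
#'
#' A `tone_spec` describes one stimulus of the auditory paradigms: a harmonic
#' complex of three sinusoidal partials with linear onset/offset ramps, an
#' optional centered silent gap, an overall intensity offset relative to the
#' standard tone, and an optional interaural time difference (ITD) realized as
#' a whole-sample delay of one stereo channel.
#'
#' @param partial_freqs_hz Numeric length-3, partial frequencies in Hz.
#' @param partial_level_offsets_db Numeric length-3, per-partial level relative
#'   to the first partial in dB; the first entry must be 0.
#' @param duration_ms Tone duration in ms (including rise/fall ramps).
#' @param rise_fall_ms Linear rise and fall ramp length in ms.
#' @param gap Either `NULL` or a list with `gap_length_ms` (total silent-gap
#'   length, including its own ramps) and `gap_rise_fall_ms`; the gap is
#'   centered in the tone.
#' @param intensity_offset_db Overall level shift in dB relative to the
#'   standard tone (0 for the standard).
#' @param itd_us Signed interaural time difference in microseconds; positive
#'   values delay the right channel (tone lateralized to the left), negative
#'   values delay the left channel. 0 means diotic.
#'
#' @return An object of class `tone_spec`.
#' @export
tone_spec <- function(partial_freqs_hz = c(500, 1000, 1500),
                      partial_level_offsets_db = c(0, -3, -6),
                      duration_ms = 75,
                      rise_fall_ms = 5,
                      gap = NULL,
                      intensity_offset_db = 0,
                      itd_us = 0) {
  spec <- structure(
    list(partial_freqs_hz = as.numeric(partial_freqs_hz),
         partial_level_offsets_db = as.numeric(partial_level_offsets_db),
         duration_ms = as.numeric(duration_ms),
         rise_fall_ms = as.numeric(rise_fall_ms),
         gap = gap,
         intensity_offset_db = as.numeric(intensity_offset_db),
         itd_us = as.numeric(itd_us)),
    class = "tone_spec")
  validate_tone_spec(spec)
  spec
}

validate_tone_spec <- function(spec) {
  stopifnot(inherits(spec, "tone_spec"))
  if (length(spec$partial_freqs_hz) != 3L || any(spec$partial_freqs_hz <= 0))
    stop("tone_spec: exactly three positive partial frequencies are required")
  if (length(spec$partial_level_offsets_db) != 3L)
    stop("tone_spec: three partial level offsets are required")
  if (spec$partial_level_offsets_db[1] != 0)
    stop("tone_spec: the first partial is the level reference; its offset must be 0 dB")
  if (!is.finite(spec$duration_ms) || spec$duration_ms <= 0)
    stop("tone_spec: duration_ms must be positive")
  if (spec$rise_fall_ms < 0 || 2 * spec$rise_fall_ms > spec$duration_ms)
    stop("tone_spec: rise/fall ramps must be non-negative and fit inside the tone")
  if (!is.null(spec$gap)) {
    g <- spec$gap
    if (is.null(g$gap_length_ms) || is.null(g$gap_rise_fall_ms))
      stop("tone_spec: gap needs gap_length_ms and gap_rise_fall_ms")
    if (g$gap_length_ms <= 0 || g$gap_rise_fall_ms < 0 ||
        2 * g$gap_rise_fall_ms > g$gap_length_ms)
      stop("tone_spec: gap ramps must fit inside the gap")
    if (g$gap_length_ms >= spec$duration_ms - 2 * spec$rise_fall_ms)
      stop("tone_spec: gap must fit inside the tone plateau")
  }
  invisible(spec)
}

#' @export
print.tone_spec <- function(x, ...) {
  cat(sprintf("<tone_spec> %g ms, partials %s Hz, offset %+g dB, itd %+g us%s\n",
              x$duration_ms, paste(x$partial_freqs_hz, collapse = "/"),
              x$intensity_offset_db, x$itd_us,
              if (!is.null(x$gap)) sprintf(", gap %g ms", x$gap$gap_length_ms) else ""))
  invisible(x)
}

#' Standard and deviant tone specifications
#'
#' Returns the nine tone specifications used by the paradigms: the standard
#' tone (harmonic complex of 500/1000/1500 Hz partials, the second partial 3 dB
#' and the third 6 dB below the first, 75 ms long with 5 ms rise/fall) and the
#' deviants derived from it: duration (50 ms shorter), gap (7 ms centered
#' silent gap with 1 ms ramps), frequency (partials 10% higher or lower),
#' intensity (10 dB louder or softer) and location (800 microsecond interaural
#' time difference, left or right).
#'
#' @return Named list of [tone_spec()] objects with names `standard`,
#'   `duration`, `gap`, `frequency_high`, `frequency_low`, `intensity_loud`,
#'   `intensity_soft`, `location_left`, `location_right`.
#' @export
standard_and_deviant_specs <- function() {
  std <- tone_spec()
  list(
    standard       = std,
    duration       = tone_spec(duration_ms = 75 - 50),
    gap            = tone_spec(gap = list(gap_length_ms = 7, gap_rise_fall_ms = 1)),
    frequency_high = tone_spec(partial_freqs_hz = c(550, 1100, 1650)),
    frequency_low  = tone_spec(partial_freqs_hz = c(450, 900, 1350)),
    intensity_loud = tone_spec(intensity_offset_db = +10),
    intensity_soft = tone_spec(intensity_offset_db = -10),
    location_left  = tone_spec(itd_us = +800),
    location_right = tone_spec(itd_us = -800)
  )
}

#' Deviant family of a stimulus kind
#'
#' Maps a stimulus kind (e.g. `frequency_high`) onto its deviant family
#' (`frequency`); sub-variants (high/low, loud/soft, left/right) are pooled at
#' analysis time.
#'
#' @param kind Character vector of stimulus kinds.
#' @return Character vector of families (`standard`, `duration`, `gap`,
#'   `frequency`, `intensity`, `location`).
#' @export
deviant_family <- function(kind) {
  sub("_(high|low|loud|soft|left|right)$", "", kind)
}

# reference peak amplitude of the rendered standard tone; keeps +10 dB
# deviants clear of full scale in 16-bit audio
.tone_ref_amp <- 0.25

#' Synthesize a stimulus tone as a stereo waveform
#'
#' Renders a [tone_spec()] at the given sample rate: three sinusoidal partials
#' at the specified relative levels, linear rise/fall ramps, optional centered
#' silent gap (with its own short ramps), an overall linear gain of
#' `10^(intensity_offset_db/20)`, and the interaural time difference realized
#' by delaying one channel by `round(|itd_us| * sample_rate / 1e6)` samples.
#'
#' @param spec A [tone_spec()].
#' @param sample_rate Samples per second; must exceed twice the highest
#'   partial frequency.
#' @return A two-column matrix (`left`, `right`) of
#'   `round(duration_ms * sample_rate / 1000)` samples per channel.
#' @export
synthesize_tone <- function(spec, sample_rate = 48000) {
  validate_tone_spec(spec)
  if (sample_rate <= 2 * max(spec$partial_freqs_hz))
    stop("synthesize_tone: highest partial is at or above the Nyquist frequency")

  n <- round(spec$duration_ms * sample_rate / 1000)
  t <- (seq_len(n) - 1) / sample_rate
  amps <- 10^(spec$partial_level_offsets_db / 20)
  x <- rep(0, n)
  for (k in 1:3) x <- x + amps[k] * sin(2 * pi * spec$partial_freqs_hz[k] * t)
  x <- x / sum(amps) * .tone_ref_amp

  # linear onset/offset ramps
  env <- rep(1, n)
  nr <- round(spec$rise_fall_ms * sample_rate / 1000)
  if (nr > 0) {
    ramp <- seq(0, 1, length.out = nr)
    env[seq_len(nr)] <- ramp
    env[(n - nr + 1):n] <- rev(ramp)
  }

  # centered silent gap with its own fall/rise ramps
  if (!is.null(spec$gap)) {
    g <- spec$gap
    ng <- round(g$gap_length_ms * sample_rate / 1000)
    ngr <- round(g$gap_rise_fall_ms * sample_rate / 1000)
    mid <- n / 2
    i0 <- floor(mid - ng / 2) + 1L
    i1 <- i0 + ng - 1L
    genv <- rep(0, ng)
    if (ngr > 0) {
      genv[seq_len(ngr)] <- seq(1, 0, length.out = ngr)       # fall into gap
      genv[(ng - ngr + 1):ng] <- seq(0, 1, length.out = ngr)  # rise out
    }
    env[i0:i1] <- env[i0:i1] * genv
  }

  x <- x * env * 10^(spec$intensity_offset_db / 20)

  left <- x
  right <- x
  if (spec$itd_us != 0) {
    d <- round(abs(spec$itd_us) * sample_rate / 1e6)
    if (d >= n) stop("synthesize_tone: ITD delay exceeds tone length")
    delayed <- c(rep(0, d), x[seq_len(n - d)])
    if (spec$itd_us > 0) right <- delayed else left <- delayed
  }
  cbind(left = left, right = right)
}
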