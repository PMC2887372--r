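# Micromelody and singing-target stimulus construction.
#
# A micromelody is a seven-note melody whose adjacent-note intervals all have
# the same sub-semitone magnitude (the "interval scale", < 100 cents). The
# contour — the up/down/repeat pattern across the six transitions — is
# constrained to have two or three inversions (direction changes) and at most
# one note repetition. Notes are 200 ms, separated by 150 ms of silence, with
# 50 ms of trailing silence: 2.35 s in total.

# --- contours ----------------------------------------------------------------

#' Count contour inversions
#'
#' An inversion is a change of melodic direction: a sign flip between
#' consecutive non-zero steps. Zero (repeat) steps are skipped, so
#' `c(1, 0, -1)` contains one inversion.
#'
#' @param steps Integer vector of signed step directions (+1 up, -1 down,
#'   0 repeat).
#' @return Number of inversions.
#' @export
contour_inversions <- function(steps) {
  nz <- steps[steps != 0]
  if (length(nz) < 2L) return(0L)
  sum(diff(sign(nz)) != 0)
}

#' Count note repetitions in a contour
#'
#' A repetition is a zero step (two consecutive notes at the same pitch).
#'
#' @inheritParams contour_inversions
#' @return Number of zero steps.
#' @export
contour_repeats <- function(steps) sum(steps == 0L)

contour_admissible <- function(steps, n_notes = 7L) {
  if (n_notes == 7L) {
    contour_inversions(steps) %in% c(2L, 3L) && contour_repeats(steps) <= 1L
  } else {
    # 5-note singing targets: at least one inversion, no repeats
    contour_repeats(steps) == 0L && contour_inversions(steps) >= 1L
  }
}

#' Enumerate all admissible contours
#'
#' For 7-note micromelodies the admissible set is every step sequence in
#' \{-1, 0, +1\}^6 with two or three inversions and zero or one repetition.
#' For 5-note singing targets it is every sequence in \{-1, +1\}^4 with at
#' least one inversion (repeats are not used for singing targets).
#'
#' @param n_notes Number of notes, 7 (micromelody) or 5 (singing target).
#' @return Integer matrix, one admissible contour per row.
#' @export
admissible_contours <- function(n_notes = 7L) {
  n_notes <- as.integer(n_notes)
  if (!n_notes %in% c(5L, 7L)) stop("n_notes must be 5 or 7")
  key <- as.character(n_notes)
  cached <- .contour_cache[[key]]
  if (!is.null(cached)) return(cached)
  vals <- if (n_notes == 7L) c(-1L, 0L, 1L) else c(-1L, 1L)
  grid <- as.matrix(expand.grid(rep(list(vals), n_notes - 1L)))
  dimnames(grid) <- NULL
  keep <- apply(grid, 1L, contour_admissible, n_notes = n_notes)
  .contour_cache[[key]] <- grid[keep, , drop = FALSE]
  .contour_cache[[key]]
}

.contour_cache <- new.env(parent = emptyenv())

#' Sample a melodic contour
#'
#' Draws uniformly from the admissible contour set for the requested melody
#' length (see [admissible_contours()]). Uses R's global random stream;
#' `seed`, if given, is applied first via [set.seed()].
#'
#' @inheritParams admissible_contours
#' @param seed Optional integer seed.
#' @return Integer vector of `n_notes - 1` signed steps, class `"contour"`.
#' @examples
#' generate_contour(7, seed = 1)
#' @export
generate_contour <- function(n_notes = 7L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- admissible_contours(n_notes)
  steps <- pool[sample.int(nrow(pool), 1L), ]
  structure(as.integer(steps), class = "contour")
}

# --- micromelodies -----------------------------------------------------------

#' Specify a micromelody
#'
#' @param scale_cents Interval magnitude in cents shared by every non-repeat
#'   step; must be at least 1 and strictly below 100 (sub-semitone).
#' @param center_freq_hz Frequency of the middle (4th) note in Hz; the study
#'   frequencies are 250 (trained) and 500 (untrained).
#' @param contour A 6-step contour (see [generate_contour()]); sampled if
#'   omitted.
#' @param timbre `"pure"` (sine) or `"harmonic"` (first six equal-amplitude
#'   harmonics, a synthetic stand-in for a sung vowel).
#' @return An object of class `"micromelody_spec"`.
#' @export
micromelody_spec <- function(scale_cents, center_freq_hz = 250,
                             contour = generate_contour(7L),
                             timbre = c("pure", "harmonic")) {
  timbre <- match.arg(timbre)
  stopifnot(is.numeric(scale_cents), length(scale_cents) == 1L,
            is.numeric(center_freq_hz), length(center_freq_hz) == 1L,
            center_freq_hz > 0)
  if (scale_cents < 1 || scale_cents >= 100)
    stop("scale_cents must lie in [1, 100) cents")
  contour <- as.integer(contour)
  if (length(contour) != 6L || !contour_admissible(contour, 7L))
    stop("contour must be 6 admissible steps (2-3 inversions, <= 1 repeat)")
  structure(list(scale_cents = scale_cents, center_freq_hz = center_freq_hz,
                 contour = contour, timbre = timbre),
            class = "micromelody_spec")
}

#' Realize a micromelody from its specification
#'
#' The middle (4th) note is anchored at `center_freq_hz`; the remaining notes
#' are placed by accumulating the signed contour steps, each of magnitude
#' `scale_cents`, outward in both directions. Cents map to frequency ratios
#' via `2^(cents/1200)`. Timing is fixed: 200 ms notes, 150 ms gaps, 50 ms
#' trailing silence (2.35 s total).
#'
#' @param spec A [micromelody_spec()].
#' @return Object of class `"micromelody"` with fields `note_freqs_hz`
#'   (length 7), `note_cents` (relative to the center), timing constants and
#'   the spec.
#' @examples
#' mm <- realize_melody(micromelody_spec(20, contour = c(1, -1, 1, 0, -1, 1)))
#' mm$note_freqs_hz
#' @export
realize_melody <- function(spec) {
  stopifnot(inherits(spec, "micromelody_spec"))
  cum <- c(0, cumsum(spec$contour * spec$scale_cents))  # cents rel. to note 1
  cents_rel_center <- cum - cum[4L]
  structure(list(
    note_freqs_hz = spec$center_freq_hz * 2^(cents_rel_center / 1200),
    note_cents = cents_rel_center,
    note_duration_ms = 200, inter_note_gap_ms = 150, trailing_silence_ms = 50,
    spec = spec), class = "micromelody")
}

#' Total duration of a micromelody in seconds
#' @param mel A `"micromelody"` object.
#' @return Duration in seconds (2.35 for the standard timing).
#' @export
melody_duration_s <- function(mel) {
  stopifnot(inherits(mel, "micromelody"))
  n <- length(mel$note_freqs_hz)
  (n * mel$note_duration_ms + (n - 1L) * mel$inter_note_gap_ms +
      mel$trailing_silence_ms) / 1000
}

#' @export
print.micromelody <- function(x, ...) {
  cat(sprintf("micromelody: %d notes, scale %g c, center %g Hz, %s timbre\n",
              length(x$note_freqs_hz), x$spec$scale_cents,
              x$spec$center_freq_hz, x$spec$timbre))
  cat("  freqs (Hz):", paste(sprintf("%.2f", x$note_freqs_hz), collapse = " "),
      "\n")
  invisible(x)
}

#' Construct the "different" member of a discrimination pair
#'
#' Given a micromelody, samples another one at the same interval scale and
#' center frequency but with a different admissible contour, such that at
#' least two of the seven note frequencies differ — the construction used for
#' the "different" trials of the same/different task.
#'
#' @param mel A `"micromelody"`.
#' @param seed Optional integer seed.
#' @param max_tries Resampling budget before giving up (never reached in
#'   practice; the admissible set is large).
#' @return A `"micromelody"` differing from `mel` in at least two notes.
#' @export
make_different_pair <- function(mel, seed = NULL, max_tries = 1000L) {
  stopifnot(inherits(mel, "micromelody"))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    cand <- realize_melody(micromelody_spec(
      mel$spec$scale_cents, mel$spec$center_freq_hz,
      contour = generate_contour(7L), timbre = mel$spec$timbre))
    if (sum(abs(cand$note_freqs_hz - mel$note_freqs_hz) > 1e-9) >= 2L)
      return(cand)
  }
  stop("could not find a sufficiently different contour")
}

# --- singing targets ---------------------------------------------------------

#' Construct a five-note singing target melody
#'
#' Targets for the melodic singing tasks: five notes centered (3rd note) on
#' 252 Hz with adjacent intervals of a fixed magnitude, 50 cents ("mel50") or
#' 100 cents ("mel100").
#'
#' @param interval_cents Interval magnitude in cents, typically 50 or 100.
#' @param contour_steps 4 signed steps (+1/-1); sampled admissibly (at least
#'   one inversion, no repeats) if omitted.
#' @param center_freq_hz Frequency of the middle note (default 252).
#' @param seed Optional integer seed for contour sampling.
#' @return Object of class `"target_melody"` with `note_freqs_hz`,
#'   `note_cents` (relative to the center frequency), `interval_cents` and
#'   `contour_steps`.
#' @examples
#' target_melody(100, contour_steps = c(1, -1, 1, -1))
#' @export
target_melody <- function(interval_cents, contour_steps = NULL,
                          center_freq_hz = 252, seed = NULL) {
  stopifnot(is.numeric(interval_cents), length(interval_cents) == 1L,
            interval_cents > 0)
  if (is.null(contour_steps)) {
    contour_steps <- as.integer(generate_contour(5L, seed = seed))
  } else {
    contour_steps <- as.integer(contour_steps)
    if (length(contour_steps) != 4L || any(!contour_steps %in% c(-1L, 1L)))
      stop("contour_steps must be 4 steps of +1 or -1")
  }
  cum <- c(0, cumsum(contour_steps * interval_cents))
  cents <- cum - cum[3L]
  structure(list(note_freqs_hz = center_freq_hz * 2^(cents / 1200),
                 note_cents = cents, interval_cents = interval_cents,
                 contour_steps = contour_steps,
                 center_freq_hz = center_freq_hz),
            class = "target_melody")
}

#' @export
print.target_melody <- function(x, ...) {
  cat(sprintf("target melody: %g-cent intervals, center %g Hz\n",
              x$interval_cents, x$center_freq_hz))
  cat("  cents rel. center:", paste(sprintf("%+g", x$note_cents),
                                    collapse = " "), "\n")
  invisible(x)
}

# --- audio rendering ---------------------------------------------------------

raised_cosine_ramp <- function(n) (1 - cos(pi * seq_len(n) / n)) / 2

tone_burst <- function(freq_hz, n_samples, sample_rate, timbre, ramp_ms = 10) {
  t <- (seq_len(n_samples) - 1L) / sample_rate
  if (timbre == "pure") {
    y <- sin(2 * pi * freq_hz * t)
  } else {
    # first six equal-amplitude harmonics below Nyquist
    k <- seq_len(6L)
    k <- k[k * freq_hz < sample_rate / 2]
    y <- rowSums(sapply(k, function(h) sin(2 * pi * h * freq_hz * t)))
    y <- y / length(k)
  }
  nr <- min(round(ramp_ms / 1000 * sample_rate), floor(n_samples / 2))
  if (nr > 0L) {
    r <- raised_cosine_ramp(nr)
    y[seq_len(nr)] <- y[seq_len(nr)] * r
    y[n_samples - nr + seq_len(nr)] <- y[n_samples - nr + seq_len(nr)] * rev(r)
  }
  y
}

#' Render a micromelody to a waveform
#'
#' Produces the 2.35 s stimulus: seven tone bursts with 10 ms raised-cosine
#' on/off ramps (to avoid spectral splatter at note edges), 150 ms silent
#' gaps, and 50 ms of trailing silence. `"pure"` timbre renders sine tones;
#' `"harmonic"` renders six equal-amplitude harmonics.
#'
#' @param mel A `"micromelody"`.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param amplitude Peak amplitude in [0, 1].
#' @return Numeric waveform with attributes `sample_rate` and `duration_s`.
#' @export
render_audio <- function(mel, sample_rate = 44100, amplitude = 0.9) {
  stopifnot(inherits(mel, "micromelody"))
  n_note <- round(mel$note_duration_ms / 1000 * sample_rate)
  n_gap <- round(mel$inter_note_gap_ms / 1000 * sample_rate)
  n_tail <- round(mel$trailing_silence_ms / 1000 * sample_rate)
  pieces <- vector("list", 2L * length(mel$note_freqs_hz))
  for (i in seq_along(mel$note_freqs_hz)) {
    pieces[[2L * i - 1L]] <- amplitude *
      tone_burst(mel$note_freqs_hz[i], n_note, sample_rate, mel$spec$timbre)
    pieces[[2L * i]] <- numeric(if (i < length(mel$note_freqs_hz)) n_gap
                                else n_tail)
  }
  y <- unlist(pieces, use.names = FALSE)
  attr(y, "sample_rate") <- sample_rate
  attr(y, "duration_s") <- length(y) / sample_rate
  y
}

#' Write a waveform as a 16-bit PCM WAV file
#'
#' Minimal mono RIFF/WAVE writer. Samples are clipped to [-1, 1] and scaled
#' to 16-bit integers.
#'
#' @param waveform Numeric vector in [-1, 1].
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz; defaults to the waveform's
#'   `sample_rate` attribute, else 44100.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate = NULL) {
  if (is.null(sample_rate))
    sample_rate <- attr(waveform, "sample_rate") %||% 44100
  pcm <- as.integer(round(pmax(pmin(waveform, 1), -1) * 32767))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")        # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")       # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Write the JSON manifest accompanying a rendered stimulus
#'
#' @param mel A `"micromelody"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_stimulus_manifest <- function(mel, path) {
  stopifnot(inherits(mel, "micromelody"))
  jsonlite::write_json(list(
    scale_cents = mel$spec$scale_cents,
    center_freq_hz = mel$spec$center_freq_hz,
    timbre = mel$spec$timbre,
    contour_steps = mel$spec$contour,
    note_freqs_hz = mel$note_freqs_hz,
    note_duration_ms = mel$note_duration_ms,
    inter_note_gap_ms = mel$inter_note_gap_ms,
    trailing_silence_ms = mel$trailing_silence_ms
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
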