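# Pitch-trace analysis: cents conversion, voicing filter, frequency-state
# matrix, Viterbi segmentation into notes, and per-note statistics.
#
# A sung melody's f0 trace is converted to cents relative to 252 Hz, cleaned
# of unvoiced frames, smoothed, and expanded into a state matrix whose rows
# are candidate pitches on a fixed cents grid and whose columns are frames.
# The Viterbi algorithm finds the maximum-score state path under a Gaussian
# emission score and a constant penalty per state switch; during periods of
# small f0 change the path stays in one state, so the five longest
# constant-state runs are taken as the melody's notes. The middle 80% of each
# run yields the note's mean pitch and stability (SD), both in cents.

#' Construct a pitch trace
#'
#' A frame-wise record of fundamental frequency, signal power and
#' aperiodicity, as produced by an f0 extractor running every 32 samples on
#' 44.1 kHz audio (frame rate 44100/32 = 1378.125 Hz). Pitch is stored in
#' cents relative to `ref_hz`.
#'
#' @param f0_hz Per-frame f0 in Hz (give either this or `f0_cents`).
#' @param f0_cents Per-frame pitch in cents relative to `ref_hz`.
#' @param power Per-frame signal power (any linear scale); defaults to 1.
#' @param aperiodicity Per-frame aperiodicity in [0, 1]; defaults to 0.
#' @param frame_rate_hz Frames per second (default 1378.125).
#' @param ref_hz Cents reference (default 252, the singing target).
#' @return Object of class `"pitch_trace"` with equal-length vectors
#'   `time_s`, `f0_cents`, `power`, `aperiodicity`.
#' @export
pitch_trace <- function(f0_hz = NULL, f0_cents = NULL, power = NULL,
                        aperiodicity = NULL, frame_rate_hz = 44100 / 32,
                        ref_hz = 252) {
  if (is.null(f0_cents)) {
    if (is.null(f0_hz)) stop("supply f0_hz or f0_cents")
    f0_cents <- hz_to_cents(f0_hz, ref_hz)
  }
  n <- length(f0_cents)
  if (n == 0L) stop("empty trace")
  power <- if (is.null(power)) rep(1, n) else power
  aperiodicity <- if (is.null(aperiodicity)) rep(0, n) else aperiodicity
  stopifnot(length(power) == n, length(aperiodicity) == n, frame_rate_hz > 0)
  structure(list(time_s = (seq_len(n) - 1L) / frame_rate_hz,
                 f0_cents = as.numeric(f0_cents), power = as.numeric(power),
                 aperiodicity = as.numeric(aperiodicity),
                 frame_rate_hz = frame_rate_hz, ref_hz = ref_hz),
            class = "pitch_trace")
}

#' @export
print.pitch_trace <- function(x, ...) {
  cat(sprintf(
    "pitch trace: %d frames at %.3f Hz (%.2f s), ref %g Hz\n",
    length(x$f0_cents), x$frame_rate_hz,
    length(x$f0_cents) / x$frame_rate_hz, x$ref_hz))
  invisible(x)
}

#' Read a pitch trace from delimited text
#'
#' Expects columns `time_s`, `f0_hz`, `power`, `aperiodicity` (tab- or
#' whitespace-delimited, with header). The frame rate is inferred from the
#' median time step.
#'
#' @param path Input file.
#' @param ref_hz Cents reference (default 252).
#' @return A [pitch_trace()].
#' @export
read_pitch_trace <- function(path, ref_hz = 252) {
  d <- utils::read.table(path, header = TRUE)
  need <- c("time_s", "f0_hz", "power", "aperiodicity")
  if (!all(need %in% names(d)))
    stop("trace file must have columns: ", paste(need, collapse = ", "))
  fr <- 1 / stats::median(diff(d$time_s))
  pitch_trace(f0_hz = d$f0_hz, power = d$power,
              aperiodicity = d$aperiodicity, frame_rate_hz = fr,
              ref_hz = ref_hz)
}

#' Write a pitch trace as delimited text
#'
#' @param trace A [pitch_trace()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pitch_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pitch_trace"))
  utils::write.table(
    data.frame(time_s = trace$time_s,
               f0_hz = cents_to_hz(trace$f0_cents, trace$ref_hz),
               power = trace$power, aperiodicity = trace$aperiodicity),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Voiced-frame filter
#'
#' Frames are kept when aperiodicity is at most `max_aperiodicity` and power
#' is at least `min_power_frac` of the trace's median power — the usual
#' post-processing that strips breaths, onsets and silences before
#' segmentation.
#'
#' @param trace A [pitch_trace()].
#' @param max_aperiodicity Aperiodicity ceiling (default 0.2).
#' @param min_power_frac Power floor as a fraction of median power
#'   (default 0.01).
#' @return Logical vector, `TRUE` for retained frames.
#' @export
voiced_frames <- function(trace, max_aperiodicity = 0.2,
                          min_power_frac = 0.01) {
  stopifnot(inherits(trace, "pitch_trace"))
  ok <- is.finite(trace$f0_cents) &
    trace$aperiodicity <= max_aperiodicity &
    trace$power >= min_power_frac * stats::median(trace$power)
  ok
}

# moving median then Gaussian smoothing over time; edges renormalized
smooth_f0 <- function(f0, median_frames = 15L, gaussian_sd_frames = 10) {
  n <- length(f0)
  k <- min(median_frames, if (n %% 2L == 0L) n - 1L else n)
  if (k %% 2L == 0L) k <- k - 1L
  med <- if (k >= 3L) stats::runmed(f0, k) else f0
  if (gaussian_sd_frames <= 0) return(as.numeric(med))
  half <- ceiling(3 * gaussian_sd_frames)
  kern <- stats::dnorm(-half:half, sd = gaussian_sd_frames)
  # normalize by the locally available kernel mass so edges stay unbiased
  num <- stats::convolve(c(med), rev(kern), type = "open")
  den <- stats::convolve(rep(1, n), rev(kern), type = "open")
  (num / den)[(half + 1L):(half + n)]
}

#' Build the frequency-state matrix for segmentation
#'
#' Unvoiced frames (see [voiced_frames()]) are dropped; the retained f0 is
#' smoothed over time (moving median then Gaussian), and each frame is scored
#' against a grid of candidate pitches with a Gaussian emission score,
#' `-(state - smoothed_f0)^2 / (2 * emission_sd^2)`. The grid covers the
#' voiced pitch range plus a margin in steps of `grid_step_cents`.
#'
#' @param trace A [pitch_trace()].
#' @param grid_step_cents Grid resolution in cents (default 5).
#' @param grid_pad_cents Margin added above and below the voiced range
#'   (default 100).
#' @param median_frames Moving-median window in frames (default 15, ~11 ms).
#' @param gaussian_sd_frames Gaussian smoothing SD in frames (default 10).
#' @param emission_sd_cents Emission score SD in cents (default 25).
#' @param max_aperiodicity,min_power_frac Passed to [voiced_frames()].
#' @return Object of class `"state_matrix"`: `freq_states_cents` (rows),
#'   `scores` (states x frames), `frame_index` (into the original trace),
#'   `f0_cents` (retained raw pitch), `smoothed_cents`, `time_s`,
#'   `frame_rate_hz`.
#' @export
build_state_matrix <- function(trace, grid_step_cents = 5,
                               grid_pad_cents = 100, median_frames = 15L,
                               gaussian_sd_frames = 10,
                               emission_sd_cents = 25,
                               max_aperiodicity = 0.2,
                               min_power_frac = 0.01) {
  stopifnot(inherits(trace, "pitch_trace"), grid_step_cents > 0,
            emission_sd_cents > 0)
  keep <- voiced_frames(trace, max_aperiodicity, min_power_frac)
  if (!any(keep)) stop("no voiced frames after filtering")
  f0 <- trace$f0_cents[keep]
  sm <- smooth_f0(f0, median_frames, gaussian_sd_frames)
  lo <- floor((min(f0) - grid_pad_cents) / grid_step_cents) * grid_step_cents
  hi <- ceiling((max(f0) + grid_pad_cents) / grid_step_cents) * grid_step_cents
  grid <- seq(lo, hi, by = grid_step_cents)
  scores <- -outer(grid, sm, "-")^2 / (2 * emission_sd_cents^2)
  structure(list(freq_states_cents = grid, scores = scores,
                 frame_index = which(keep), f0_cents = f0,
                 smoothed_cents = sm,
                 time_s = trace$time_s[keep],
                 frame_rate_hz = trace$frame_rate_hz),
            class = "state_matrix")
}

#' Maximum-score state path (Viterbi)
#'
#' Dynamic programming over the state matrix: the path score is the sum of
#' per-frame emission scores minus `switch_penalty` for every change of
#' state. The constant switch cost means the transition maximum at each frame
#' reduces to "stay" versus "jump from the best state", giving O(states x
#' frames) time. Ties prefer staying in the current state, then the lower
#' state index.
#'
#' @param sm A `"state_matrix"`, or a bare numeric score matrix (states x
#'   frames).
#' @param switch_penalty Cost per state change, in emission-score units
#'   (default 8).
#' @return Integer vector of state indices, one per frame.
#' @export
viterbi_path <- function(sm, switch_penalty = 8) {
  scores <- if (inherits(sm, "state_matrix")) sm$scores else as.matrix(sm)
  stopifnot(is.numeric(scores), switch_penalty >= 0)
  n_states <- nrow(scores)
  n_frames <- ncol(scores)
  delta <- scores[, 1L]
  backptr <- matrix(0L, n_states, n_frames)
  backptr[, 1L] <- seq_len(n_states)
  for (t in seq_len(n_frames)[-1L]) {
    best_prev <- which.max(delta)          # lowest index on ties
    jump <- delta[best_prev] - switch_penalty
    stay_wins <- delta >= jump             # ties prefer staying
    backptr[, t] <- ifelse(stay_wins, seq_len(n_states), best_prev)
    delta <- pmax(delta, jump) + scores[, t]
  }
  path <- integer(n_frames)
  path[n_frames] <- which.max(delta)
  for (t in rev(seq_len(n_frames)[-1L]))
    path[t - 1L] <- backptr[path[t], t]
  path
}

#' Extract the notes of a sung melody from a state path
#'
#' Maximal constant-state runs of the Viterbi path are ranked by duration
#' (ties: earlier onset wins); the `n_notes` longest are reordered by onset
#' time and become the melody's notes. Each note's mean pitch and SD are
#' computed from the middle 80% of its frames' raw (unsmoothed) f0, dropping
#' `floor(0.1 n)` frames at each end, to exclude inter-note glides. If fewer
#' than `n_notes` runs exist the trial cannot be segmented and a classed
#' error (`"segmentation_error"`) is signalled, mirroring the exclusion of
#' unsegmentable vocalizations.
#'
#' Quality-control flags (heuristic stand-ins for visual verification):
#' `"adjacent_same_state"` — two retained notes in the same state abut,
#' suggesting one note split in two; `"short_segment"` — a note shorter than
#' 50 ms; `"ambiguous_ranking"` — the 5th and 6th longest runs differ by less
#' than 10 ms; `"short_for_trim"` — a note with fewer than 10 frames, whose
#' statistics use all frames.
#'
#' @param path Integer state path from [viterbi_path()].
#' @param sm The `"state_matrix"` the path was computed on.
#' @param n_notes Number of notes to extract (default 5).
#' @return Object of class `"segmented_melody"`: `notes` data.frame (one row
#'   per note: `onset_s`, `offset_s`, `n_frames`, `state_cents`,
#'   `mean_cents`, `sd_cents`) and `qc_flags` character vector.
#' @export
extract_notes <- function(path, sm, n_notes = 5L) {
  stopifnot(inherits(sm, "state_matrix"), length(path) == ncol(sm$scores))
  r <- rle(path)
  n_runs <- length(r$lengths)
  if (n_runs < n_notes) {
    stop(structure(
      list(message = sprintf(
        "only %d constant-state segments; %d notes required",
        n_runs, n_notes), call = sys.call()),
      class = c("segmentation_error", "error", "condition")))
  }
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  ord <- order(-r$lengths, run_start)
  top <- sort(ord[seq_len(n_notes)])       # back to temporal order
  qc <- character()
  ms_per_frame <- 1000 / sm$frame_rate_hz
  if (n_runs > n_notes) {
    gap <- (r$lengths[ord[n_notes]] - r$lengths[ord[n_notes + 1L]]) *
      ms_per_frame
    if (gap < 10) qc <- c(qc, "ambiguous_ranking")
  }
  notes <- lapply(top, function(i) {
    idx <- run_start[i]:run_end[i]
    f0 <- sm$f0_cents[idx]
    n <- length(f0)
    drop <- floor(0.1 * n)
    if (n < 10L) {
      mid <- f0
      qc <<- c(qc, "short_for_trim")
    } else {
      mid <- f0[(drop + 1L):(n - drop)]
    }
    if (n * ms_per_frame < 50) qc <<- c(qc, "short_segment")
    data.frame(onset_s = sm$time_s[run_start[i]],
               offset_s = sm$time_s[run_end[i]],
               n_frames = n,
               state_cents = sm$freq_states_cents[r$values[i]],
               mean_cents = mean(mid),
               sd_cents = if (length(mid) > 1L) stats::sd(mid) else 0)
  })
  for (k in seq_len(n_notes - 1L)) {
    if (r$values[top[k]] == r$values[top[k + 1L]] &&
        top[k + 1L] == top[k] + 1L)
      qc <- c(qc, "adjacent_same_state")
  }
  structure(list(notes = do.call(rbind, notes), qc_flags = unique(qc)),
            class = "segmented_melody")
}

#' @export
print.segmented_melody <- function(x, ...) {
  cat(sprintf("segmented melody: %d notes%s\n", nrow(x$notes),
              if (length(x$qc_flags))
                paste0(" [flags: ", paste(x$qc_flags, collapse = ", "), "]")
              else ""))
  print(x$notes, row.names = FALSE)
  invisible(x)
}

#' Segment a sung-melody pitch trace into notes
#'
#' Convenience wrapper: [build_state_matrix()], [viterbi_path()],
#' [extract_notes()].
#'
#' @inheritParams build_state_matrix
#' @inheritParams viterbi_path
#' @inheritParams extract_notes
#' @param ... Passed to [build_state_matrix()].
#' @return A `"segmented_melody"`; signals a `"segmentation_error"` if the
#'   path does not contain `n_notes` constant-state runs.
#' @export
segment_melody <- function(trace, n_notes = 5L, switch_penalty = 8, ...) {
  sm <- build_state_matrix(trace, ...)
  extract_notes(viterbi_path(sm, switch_penalty), sm, n_notes)
}

#' Write note segments as TSV
#'
#' @param seg A `"segmented_melody"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments <- function(seg, path) {
  stopifnot(inherits(seg, "segmented_melody"))
  out <- seg$notes
  out$flags <- paste(seg$qc_flags, collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simple-singing accuracy and stability
#'
#' For a sustained single-note vocalization: accuracy is the mean signed
#' error of voiced f0 from the target (the cents reference, i.e. 0 cents) and
#' stability is the SD of voiced f0 — smaller SD means steadier pitch.
#'
#' @param trace A [pitch_trace()] of one sustained note.
#' @param max_aperiodicity,min_power_frac Passed to [voiced_frames()].
#' @return Named numeric vector: `mean_error_cents`, `stability_cents`.
#' @export
simple_singing_stats <- function(trace, max_aperiodicity = 0.2,
                                 min_power_frac = 0.01) {
  keep <- voiced_frames(trace, max_aperiodicity, min_power_frac)
  if (!any(keep)) stop("no voiced frames after filtering")
  f0 <- trace$f0_cents[keep]
  c(mean_error_cents = mean(f0),
    stability_cents = if (length(f0) > 1L) stats::sd(f0) else 0)
}
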