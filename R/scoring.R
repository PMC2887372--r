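# The five melodic vocal-accuracy measures, per-condition summaries and
# between-session difference scores.
#
# A produced melody is the vector of five note means (cents relative to
# 252 Hz) from segmentation; the target is the corresponding five-note target
# melody. A perfect production of a scale-s target scores exactly
# (abs_error 0, abs_contour_error 0, contour_score 4, abs_interval_magnitude
# s, abs_interval_difference 0).

as_note_cents <- function(x) {
  if (inherits(x, "segmented_melody")) x <- x$notes$mean_cents
  if (inherits(x, "target_melody")) x <- x$note_cents
  x <- as.numeric(x)
  if (length(x) != 5L || any(!is.finite(x)))
    stop("a melody must be 5 finite note pitches in cents")
  x
}

#' Absolute pitch error from the target melody
#'
#' Mean of the absolute per-note errors, `mean(|produced_i - target_i|)`.
#' Absolute values prevent sharp and flat errors from cancelling.
#'
#' @param produced,target Five note pitches in cents (numeric vector,
#'   `"segmented_melody"` or `"target_melody"`).
#' @return Error in cents (>= 0).
#' @export
abs_error <- function(produced, target) {
  mean(abs(as_note_cents(produced) - as_note_cents(target)))
}

#' Absolute melody-contour error
#'
#' The produced melody is first normalized for overall pitch height by
#' subtracting its middle (3rd) note; the target likewise. The measure is the
#' mean absolute deviation between the two centered melodies, so singing the
#' whole melody flat or sharp by a constant costs nothing.
#'
#' @inheritParams abs_error
#' @return Error in cents (>= 0).
#' @export
abs_contour_error <- function(produced, target) {
  p <- as_note_cents(produced)
  t <- as_note_cents(target)
  mean(abs((p - p[3L]) - (t - t[3L])))
}

#' Contour score
#'
#' The number of the four note-to-note pitch changes produced in the correct
#' direction (up vs down) relative to the target. A produced repeat (zero
#' interval) is not a pitch change in any direction and scores as incorrect.
#'
#' @inheritParams abs_error
#' @return Integer 0-4.
#' @export
contour_score <- function(produced, target) {
  dp <- diff(as_note_cents(produced))
  dt <- diff(as_note_cents(target))
  if (any(dt == 0)) stop("target melody has a zero interval")
  sum(sign(dp) == sign(dt) & dp != 0)
}

#' Absolute interval magnitude
#'
#' Mean absolute size of the four produced intervals, regardless of
#' direction: `mean(|produced_{i+1} - produced_i|)`. For a perfect production
#' this equals the target's interval scale (50 for mel50, 100 for mel100).
#'
#' @param produced Five produced note pitches in cents.
#' @return Magnitude in cents (>= 0).
#' @export
abs_interval_magnitude <- function(produced) {
  mean(abs(diff(as_note_cents(produced))))
}

#' Absolute interval difference
#'
#' Mean absolute deviation between produced and target *signed* intervals
#' (e.g. -100 is 100 cents down to the next note, +50 is 50 cents up):
#' errors of both interval size and direction count, while uniform
#' transposition of the production costs nothing.
#'
#' @inheritParams abs_error
#' @return Error in cents (>= 0).
#' @export
abs_interval_difference <- function(produced, target) {
  mean(abs(diff(as_note_cents(produced)) - diff(as_note_cents(target))))
}

#' All five melodic performance measures for one trial
#'
#' @inheritParams abs_error
#' @return One-row data.frame: `abs_error_cents`, `abs_contour_error_cents`,
#'   `contour_score`, `abs_interval_magnitude_cents`,
#'   `abs_interval_difference_cents`.
#' @examples
#' tm <- target_melody(100, contour_steps = c(1, -1, 1, -1))
#' melodic_scores(tm$note_cents, tm)   # perfect production
#' @export
melodic_scores <- function(produced, target) {
  data.frame(
    abs_error_cents = abs_error(produced, target),
    abs_contour_error_cents = abs_contour_error(produced, target),
    contour_score = contour_score(produced, target),
    abs_interval_magnitude_cents = abs_interval_magnitude(produced),
    abs_interval_difference_cents = abs_interval_difference(produced, target))
}

measure_columns <- function(d) {
  intersect(c("abs_error_cents", "abs_contour_error_cents", "contour_score",
              "abs_interval_magnitude_cents", "abs_interval_difference_cents",
              "mean_error_cents", "stability_cents", "percent_correct"),
            names(d))
}

#' Condition summary: mean and standard error per cell
#'
#' Collapses a per-trial score table to one value per subject and cell, then
#' reports the across-subject mean and standard error (SD/sqrt(n)) per cell —
#' the shape of a group x session x scale results table. Trials flagged as
#' excluded (a logical `excluded` column, e.g. segmentation failures) are
#' dropped first and their count reported in the `n_excluded` attribute.
#'
#' @param scores Data.frame with a `subject` column, the design columns in
#'   `by`, and one or more measure columns.
#' @param by Design columns to summarise over (default
#'   `c("group", "session", "scale")`, intersected with what is present).
#' @return Data.frame with, per cell and measure, `mean`, `se` and `n`
#'   (subjects).
#' @export
summarize_scores <- function(scores, by = c("group", "session", "scale")) {
  stopifnot(is.data.frame(scores), "subject" %in% names(scores))
  by <- intersect(by, names(scores))
  if ("excluded" %in% names(scores)) {
    n_exc <- sum(scores$excluded)
    scores <- scores[!scores$excluded, , drop = FALSE]
  } else n_exc <- 0L
  meas <- measure_columns(scores)
  if (!length(meas)) stop("no measure columns found")
  per_subj <- aggregate(scores[meas],
                        by = scores[c("subject", by)], FUN = mean)
  long <- do.call(rbind, lapply(meas, function(m) {
    cells <- aggregate(per_subj[[m]], by = per_subj[by],
                       FUN = function(z) c(mean = mean(z),
                                           se = stats::sd(z) / sqrt(length(z)),
                                           n = length(z)))
    cbind(cells[by], measure = m, mean = cells$x[, "mean"],
          se = cells$x[, "se"], n = cells$x[, "n"])
  }))
  long <- long[do.call(order, long[c(by, "measure")]), , drop = FALSE]
  rownames(long) <- NULL
  attr(long, "n_excluded") <- n_exc
  long
}

#' Per-subject difference scores between two timepoints
#'
#' Deltas (second minus first session) per subject, cell and measure, the
#' quantity used to assess training-related improvement. Excluded trials are
#' dropped first; a subject present at only one timepoint in a cell is an
#' error.
#'
#' @param scores Per-trial data.frame with `subject`, `session` and measure
#'   columns (plus optional further design columns named in `by`).
#' @param sessions Length-2 vector naming the first and second timepoint as
#'   they appear in `session` (default `c("pre", "post")`).
#' @param by Extra design columns kept in the output (default `c("group",
#'   "scale")`, intersected with what is present).
#' @return Data.frame: `subject`, the `by` columns, `measure`, `delta`.
#' @export
difference_scores <- function(scores, sessions = c("pre", "post"),
                              by = c("group", "scale")) {
  stopifnot(is.data.frame(scores), all(c("subject", "session") %in%
                                         names(scores)),
            length(sessions) == 2L)
  if ("excluded" %in% names(scores))
    scores <- scores[!scores$excluded, , drop = FALSE]
  by <- intersect(by, names(scores))
  meas <- measure_columns(scores)
  per <- aggregate(scores[meas], by = scores[c("subject", "session", by)],
                   FUN = mean)
  a <- per[per$session == sessions[1L], , drop = FALSE]
  b <- per[per$session == sessions[2L], , drop = FALSE]
  key <- function(d) do.call(paste, c(d[c("subject", by)], sep = "\r"))
  if (!setequal(key(a), key(b)))
    stop("every subject/cell must be present at both timepoints")
  b <- b[match(key(a), key(b)), , drop = FALSE]
  out <- do.call(rbind, lapply(meas, function(m) {
    cbind(a[c("subject", by)], measure = m, delta = b[[m]] - a[[m]])
  }))
  rownames(out) <- NULL
  out
}

#' Write a per-trial score table as TSV
#'
#' @param scores Data.frame of per-trial scores with design labels.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
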