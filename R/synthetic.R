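# Synthetic listeners, singers and whole training cohorts.
#
# No recordings ship with the package: every analysis stage is exercised on
# simulated data with the statistical structure the pipeline assumes. A
# listener is a psychometric function for the same/different task; a singer
# is a generative model of sung pitch traces (systematic transposition,
# interval compression, per-note placement error, frame jitter, drift,
# glides, optional vibrato); a cohort couples both across two groups and two
# sessions with a training effect on discrimination thresholds and an
# optional, default-zero, effect on vocal parameters.

#' Construct a listener model
#'
#' Performance on the same/different micromelody task follows a logistic
#' psychometric function of log interval scale, rising from chance (50%) to
#' `1 - lapse`. The threshold is parameterized directly at the 70.7%-correct
#' point, the level a 2-down-1-up staircase tracks, so staircase convergence
#' can be validated against it exactly.
#'
#' @param threshold_cents Interval scale (cents) at which the listener is
#'   70.7% correct.
#' @param slope Logistic slope per octave of interval scale (default 2).
#' @param lapse Lapse rate in [0, 0.1]: asymptotic error rate from attention
#'   slips.
#' @param bias_same Probability of overriding the decision with a "same"
#'   response (response bias; default 0).
#' @return Object of class `"listener_model"`.
#' @export
listener_model <- function(threshold_cents, slope = 2, lapse = 0.02,
                           bias_same = 0) {
  stopifnot(threshold_cents > 0, slope > 0, lapse >= 0, lapse <= 0.1,
            bias_same >= 0, bias_same <= 1)
  p707 <- 1 / sqrt(2)
  q <- (p707 - 0.5) / (0.5 - lapse)
  if (q >= 1) stop("lapse too high to reach 70.7% correct")
  # anchor of the logistic so that p_correct(threshold) = 2^(-1/2)
  x0 <- threshold_cents * 2^(-stats::qlogis(q) / slope)
  structure(list(threshold_cents = threshold_cents, slope = slope,
                 lapse = lapse, bias_same = bias_same, x0 = x0),
            class = "listener_model")
}

#' Probability of a correct same/different response
#'
#' @param listener A [listener_model()].
#' @param scale_cents Interval scale(s) of the presented pair.
#' @return Probability in [0.5, 1 - lapse].
#' @export
p_correct <- function(listener, scale_cents) {
  stopifnot(inherits(listener, "listener_model"), all(scale_cents > 0))
  0.5 + (0.5 - listener$lapse) *
    stats::plogis(listener$slope * log2(scale_cents / listener$x0))
}

#' Simulate one same/different response
#'
#' The listener is correct with probability `p_correct(listener, scale)`
#' (identically for same and different pairs, so the staircase tracks the
#' psychometric function directly); with probability `bias_same` the response
#' is then overridden to "same".
#'
#' @param listener A [listener_model()].
#' @param is_same Logical: is the presented pair identical?
#' @param scale_cents Interval scale of the pair.
#' @param seed Optional integer seed.
#' @return Logical: did the listener respond "same"?
#' @export
simulate_response <- function(listener, is_same, scale_cents, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  correct <- stats::runif(1) < p_correct(listener, scale_cents)
  resp <- if (correct) is_same else !is_same
  if (listener$bias_same > 0 && stats::runif(1) < listener$bias_same)
    resp <- TRUE
  resp
}

#' Construct a singer model
#'
#' Generative parameters for sung pitch traces. Defaults describe a plausible
#' non-musician: an unbiased but noisy voice with moderate frame-to-frame
#' jitter and 60 ms pitch glides between notes.
#'
#' @param bias_cents Systematic transposition of everything sung (cents).
#' @param interval_gain Multiplicative compression (< 1) or expansion (> 1)
#'   of produced intervals.
#' @param note_noise_sd_cents SD of independent per-note placement error.
#' @param jitter_sd_cents SD of per-frame pitch jitter within a note.
#' @param drift_cents_per_s Linear pitch drift over the vocalization.
#' @param glide_ms Duration of the linear-in-cents glide between notes.
#' @param vibrato_amp_cents,vibrato_rate_hz Optional sinusoidal vibrato.
#' @return Object of class `"singer_model"`.
#' @export
singer_model <- function(bias_cents = 0, interval_gain = 1,
                         note_noise_sd_cents = 10, jitter_sd_cents = 15,
                         drift_cents_per_s = 0, glide_ms = 60,
                         vibrato_amp_cents = 0, vibrato_rate_hz = 5) {
  stopifnot(interval_gain > 0, note_noise_sd_cents >= 0,
            jitter_sd_cents >= 0, glide_ms >= 0, vibrato_amp_cents >= 0,
            vibrato_rate_hz >= 0)
  structure(list(bias_cents = bias_cents, interval_gain = interval_gain,
                 note_noise_sd_cents = note_noise_sd_cents,
                 jitter_sd_cents = jitter_sd_cents,
                 drift_cents_per_s = drift_cents_per_s, glide_ms = glide_ms,
                 vibrato_amp_cents = vibrato_amp_cents,
                 vibrato_rate_hz = vibrato_rate_hz),
            class = "singer_model")
}

#' Synthesize a sung pitch trace
#'
#' Emulates a vocalization as an f0 extractor would report it: frame-wise f0
#' (stored in cents relative to `ref_hz`), power and aperiodicity at the
#' standard frame rate. For a five-note target melody, each note is held for
#' `note_ms` with linear-in-cents glides of the singer's `glide_ms` between
#' notes; note centers are `bias + interval_gain * target + N(0,
#' note_noise_sd)`; frames carry Gaussian jitter, linear drift and optional
#' vibrato. Each note onset gets a brief high-aperiodicity burst and the
#' vocalization's first and last 10 ms get a power ramp, so the voicing
#' filter has realistic work to do.
#'
#' @param target A `"target_melody"`, or a single number: the target pitch of
#'   one sustained note in cents relative to `ref_hz` (simple singing).
#' @param singer A [singer_model()].
#' @param note_ms Note hold duration in ms; defaults to 600 for melodies and
#'   4000 for a single sustained note.
#' @param frame_rate_hz Frame rate (default 44100/32 = 1378.125).
#' @param ref_hz Cents reference (default 252).
#' @param onset_ms,onset_aperiodicity Duration and level of the aperiodic
#'   note-onset burst.
#' @param seed Optional integer seed.
#' @return A [pitch_trace()] with attribute `note_centers_cents`, the true
#'   per-note pitches the singer aimed at (for parameter-recovery checks).
#' @export
synthesize_trace <- function(target, singer = singer_model(), note_ms = NULL,
                             frame_rate_hz = 44100 / 32, ref_hz = 252,
                             onset_ms = 15, onset_aperiodicity = 0.6,
                             seed = NULL) {
  stopifnot(inherits(singer, "singer_model"))
  if (!is.null(seed)) set.seed(seed)
  if (inherits(target, "target_melody")) {
    target_cents <- target$note_cents
    if (is.null(note_ms)) note_ms <- 600
  } else {
    target_cents <- as.numeric(target)
    stopifnot(length(target_cents) == 1L)
    if (is.null(note_ms)) note_ms <- 4000
  }
  n_notes <- length(target_cents)
  centers <- singer$bias_cents + singer$interval_gain * target_cents +
    stats::rnorm(n_notes, 0, singer$note_noise_sd_cents)
  n_note <- max(2L, round(note_ms / 1000 * frame_rate_hz))
  n_glide <- round(singer$glide_ms / 1000 * frame_rate_hz)
  f0 <- numeric(0)
  onset_idx <- integer(0)
  for (i in seq_len(n_notes)) {
    onset_idx <- c(onset_idx, length(f0) + 1L)
    f0 <- c(f0, rep(centers[i], n_note))
    if (i < n_notes && n_glide > 0L)
      f0 <- c(f0, centers[i] + seq_len(n_glide) / (n_glide + 1L) *
                (centers[i + 1L] - centers[i]))
  }
  n <- length(f0)
  t <- (seq_len(n) - 1L) / frame_rate_hz
  f0 <- f0 + stats::rnorm(n, 0, singer$jitter_sd_cents) +
    singer$drift_cents_per_s * t
  if (singer$vibrato_amp_cents > 0)
    f0 <- f0 + singer$vibrato_amp_cents *
      sin(2 * pi * singer$vibrato_rate_hz * t)
  aper <- rep(0.05, n)
  n_on <- round(onset_ms / 1000 * frame_rate_hz)
  for (s in onset_idx)
    aper[s:min(n, s + n_on - 1L)] <- onset_aperiodicity
  power <- rep(1, n)
  n_ramp <- round(0.010 * frame_rate_hz)
  ramp <- seq_len(n_ramp) / n_ramp
  power[seq_len(n_ramp)] <- ramp
  power[n - n_ramp + seq_len(n_ramp)] <- rev(ramp)
  tr <- pitch_trace(f0_cents = f0, power = power, aperiodicity = aper,
                    frame_rate_hz = frame_rate_hz, ref_hz = ref_hz)
  attr(tr, "note_centers_cents") <- centers
  tr
}

# --- cohorts -----------------------------------------------------------------

#' Specify a two-group training cohort
#'
#' Defaults follow the study design: two groups of 10, two sessions
#' (pre/post), the seven test scales, 20 discrimination trials per scale and
#' cell, and 20 trials per singing task per session (four runs of five-trial
#' blocks). Training multiplies the trained group's post-session threshold by
#' `training_effect`; `nonspecific_effect` multiplies both groups' post
#' thresholds (test-retest improvement unrelated to training);
#' `vocal_effect` (default 0: training does not change the voice) is the
#' fractional reduction of the trained group's post-session singer error
#' parameters.
#'
#' Population parameters (`threshold_mean_cents` and the `singer_pop`
#' spreads) are field-plausible choices for non-musicians, not fitted values;
#' see the package vignette.
#'
#' @param n_per_group Subjects per group (default 10).
#' @param trials_per_scale Discrimination trials per scale cell (default 20;
#'   even).
#' @param trials_per_task Singing trials per task and session (default 20).
#' @param scales_cents Discrimination test scales.
#' @param center_freqs_hz,timbres Discrimination battery cells.
#' @param melody_intervals_cents Singing-task interval scales (default 50 and
#'   100).
#' @param training_effect Multiplier on trained-group post thresholds
#'   (default 0.5: thresholds halve).
#' @param nonspecific_effect Multiplier on all post thresholds (default 0.9).
#' @param vocal_effect Fractional reduction of trained-group post vocal error
#'   parameters, in [0, 1) (default 0).
#' @param threshold_mean_cents,threshold_log_sd Log-normal population of
#'   pre-training thresholds (median 25 c, log-SD 0.3).
#' @param singer_pop Named list of population spreads: `bias_sd`, `gain_sd`,
#'   `note_noise_mean`, `jitter_mean` (cents).
#' @param degenerate_fraction Fraction of melodic trials rendered degenerate
#'   (an aborted vocalization or an octave glitch) to exercise QC and
#'   exclusion paths
#'   (default 0.1, matching the order of exclusions seen in practice).
#' @param tasks Singing tasks to generate.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = 10L, trials_per_scale = 20L,
                        trials_per_task = 20L,
                        scales_cents = c(5, 10, 15, 20, 30, 40, 60),
                        center_freqs_hz = c(250, 500),
                        timbres = c("pure", "harmonic"),
                        melody_intervals_cents = c(50, 100),
                        training_effect = 0.5, nonspecific_effect = 0.9,
                        vocal_effect = 0, threshold_mean_cents = 25,
                        threshold_log_sd = 0.3,
                        singer_pop = list(bias_sd = 15, gain_sd = 0.12,
                                          note_noise_mean = 18,
                                          jitter_mean = 15),
                        degenerate_fraction = 0.1,
                        tasks = c("simple", "melodic")) {
  stopifnot(n_per_group >= 2L, training_effect > 0, nonspecific_effect > 0,
            vocal_effect >= 0, vocal_effect < 1,
            degenerate_fraction >= 0, degenerate_fraction <= 1)
  tasks <- match.arg(tasks, c("simple", "melodic"), several.ok = TRUE)
  structure(list(n_per_group = as.integer(n_per_group),
                 trials_per_scale = as.integer(trials_per_scale),
                 trials_per_task = as.integer(trials_per_task),
                 scales_cents = scales_cents,
                 center_freqs_hz = center_freqs_hz, timbres = timbres,
                 melody_intervals_cents = melody_intervals_cents,
                 training_effect = training_effect,
                 nonspecific_effect = nonspecific_effect,
                 vocal_effect = vocal_effect,
                 threshold_mean_cents = threshold_mean_cents,
                 threshold_log_sd = threshold_log_sd,
                 singer_pop = singer_pop,
                 degenerate_fraction = degenerate_fraction, tasks = tasks),
            class = "cohort_spec")
}

draw_singer <- function(pop) {
  singer_model(
    bias_cents = stats::rnorm(1, 0, pop$bias_sd),
    interval_gain = max(0.3, stats::rnorm(1, 0.9, pop$gain_sd)),
    note_noise_sd_cents = pop$note_noise_mean * exp(stats::rnorm(1, 0, 0.25)),
    jitter_sd_cents = pop$jitter_mean * exp(stats::rnorm(1, 0, 0.25)))
}

scale_singer_errors <- function(singer, factor) {
  s <- singer
  s$bias_cents <- s$bias_cents * factor
  s$note_noise_sd_cents <- s$note_noise_sd_cents * factor
  s$jitter_sd_cents <- s$jitter_sd_cents * factor
  s$interval_gain <- 1 - (1 - s$interval_gain) * factor
  s
}

degrade_trace <- function(trace, kind) {
  if (kind == "octave_glitch") {
    n <- length(trace$f0_cents)
    span <- 40L
    s <- sample.int(max(1L, n - span), 1L)
    trace$f0_cents[s:(s + span - 1L)] <-
      trace$f0_cents[s:(s + span - 1L)] + 1200
  }
  trace
}

#' Generate a full synthetic two-group study dataset
#'
#' Draws listeners and singers for every subject, applies the training,
#' nonspecific and vocal effects to the post session, and simulates both the
#' discrimination test battery and the singing tasks for every subject and
#' session. A `degenerate_fraction` of melodic trials is sabotaged (an
#' aborted single-note vocalization, or a transient octave glitch) so
#' downstream QC and exclusion paths are exercised. Fully reproducible from
#' `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Object of class `"cohort"`: `subjects` data.frame (ids, group,
#'   thresholds and singer parameters per session), `discrimination` trial
#'   log with design labels, `vocal` list of trial records (each with
#'   `subject`, `group`, `session`, `task`, `scale`, `target`, `trace`,
#'   `degenerate`), and `targets` (the five fixed target melodies per
#'   interval scale).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  groups <- c("control", "trained")
  sessions <- c("pre", "post")
  n <- spec$n_per_group * 2L
  subj <- data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    group = rep(groups, each = spec$n_per_group))
  subj$threshold_pre <- spec$threshold_mean_cents *
    exp(stats::rnorm(n, 0, spec$threshold_log_sd))
  subj$threshold_post <- subj$threshold_pre * spec$nonspecific_effect *
    ifelse(subj$group == "trained", spec$training_effect, 1)
  singers <- lapply(seq_len(n), function(i) draw_singer(spec$singer_pop))
  # five fixed pseudo-randomized targets per interval scale
  targets <- lapply(spec$melody_intervals_cents, function(iv)
    lapply(seq_len(5L), function(k) target_melody(iv)))
  names(targets) <- as.character(spec$melody_intervals_cents)

  battery <- test_battery_config(spec$scales_cents, spec$center_freqs_hz,
                                 spec$timbres, spec$trials_per_scale)
  disc <- list()
  vocal <- list()
  for (i in seq_len(n)) {
    for (ses in sessions) {
      th <- if (ses == "pre") subj$threshold_pre[i] else subj$threshold_post[i]
      listener <- listener_model(th)
      blk <- run_test_block(battery, listener)$trials
      blk$subject <- subj$subject[i]
      blk$group <- subj$group[i]
      blk$session <- ses
      disc[[length(disc) + 1L]] <- blk
      singer <- singers[[i]]
      if (ses == "post" && subj$group[i] == "trained" &&
          spec$vocal_effect > 0)
        singer <- scale_singer_errors(singer, 1 - spec$vocal_effect)
      if ("simple" %in% spec$tasks) {
        for (k in seq_len(spec$trials_per_task)) {
          vocal[[length(vocal) + 1L]] <- list(
            subject = subj$subject[i], group = subj$group[i], session = ses,
            task = "simple", scale = NA_real_, trial = k, target = 0,
            trace = synthesize_trace(0, singer), degenerate = "none")
        }
      }
      if ("melodic" %in% spec$tasks) {
        for (iv in spec$melody_intervals_cents) {
          tgt_pool <- targets[[as.character(iv)]]
          order_idx <- unlist(lapply(
            seq_len(ceiling(spec$trials_per_task / 5)),
            function(...) sample.int(5L)))[seq_len(spec$trials_per_task)]
          for (k in seq_len(spec$trials_per_task)) {
            tgt <- tgt_pool[[order_idx[k]]]
            deg <- "none"
            if (stats::runif(1) < spec$degenerate_fraction)
              deg <- sample(c("missing_note", "octave_glitch"), 1L)
            if (deg == "missing_note") {
              # aborted trial: the singer sustains the first note only,
              # leaving fewer than five constant-pitch segments
              tr <- synthesize_trace(tgt$note_cents[1], singer,
                                     note_ms = 3000)
            } else {
              tr <- synthesize_trace(tgt, singer)
              if (deg == "octave_glitch") tr <- degrade_trace(tr, deg)
            }
            vocal[[length(vocal) + 1L]] <- list(
              subject = subj$subject[i], group = subj$group[i],
              session = ses, task = sprintf("mel%g", iv), scale = iv,
              trial = k, target = tgt, trace = tr, degenerate = deg)
          }
        }
      }
    }
  }
  structure(list(spec = spec, subjects = subj, singers = singers,
                 discrimination = do.call(rbind, disc), vocal = vocal,
                 targets = targets, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d subjects x 2 sessions, %d discrimination trials, %d vocal trials\n",
    nrow(x$subjects), nrow(x$discrimination), length(x$vocal)))
  invisible(x)
}

#' Run the full behavioral analysis on a cohort
#'
#' Discrimination trials are summarised as percent correct per subject,
#' session and scale. Every melodic trace is segmented
#' ([segment_melody()]) and scored against its target
#' ([melodic_scores()]); trials whose segmentation fails are marked excluded
#' with a reason (never silently dropped). Simple-singing traces yield mean
#' error and stability.
#'
#' @param cohort A `"cohort"` from [generate_cohort()].
#' @param switch_penalty,... Passed to [segment_melody()].
#' @return List: `discrimination` (per subject/session/scale percent
#'   correct), `melodic` (per-trial five-measure table with `excluded` and
#'   `qc_flags`), `simple` (per-trial accuracy/stability), `exclusions`
#'   (log of excluded trials with reasons).
#' @export
analyze_cohort <- function(cohort, switch_penalty = 8, ...) {
  stopifnot(inherits(cohort, "cohort"))
  disc <- percent_correct(cohort$discrimination,
                          by = c("subject", "group", "session",
                                 "scale_cents"))
  names(disc)[names(disc) == "scale_cents"] <- "scale"
  mel <- list()
  simp <- list()
  excl <- list()
  for (rec in cohort$vocal) {
    if (rec$task == "simple") {
      st <- simple_singing_stats(rec$trace)
      simp[[length(simp) + 1L]] <- data.frame(
        subject = rec$subject, group = rec$group, session = rec$session,
        trial = rec$trial, mean_error_cents = st[["mean_error_cents"]],
        stability_cents = st[["stability_cents"]])
      next
    }
    seg <- tryCatch(segment_melody(rec$trace,
                                   switch_penalty = switch_penalty, ...),
                    segmentation_error = function(e) e)
    base <- data.frame(subject = rec$subject, group = rec$group,
                       session = rec$session, task = rec$task,
                       scale = rec$scale, trial = rec$trial)
    if (inherits(seg, "segmentation_error")) {
      excl[[length(excl) + 1L]] <- cbind(base, reason = conditionMessage(seg))
      mel[[length(mel) + 1L]] <- cbind(
        base, melodic_na_scores(), excluded = TRUE, qc_flags = "")
    } else {
      sc <- melodic_scores(seg, rec$target)
      mel[[length(mel) + 1L]] <- cbind(
        base, sc, excluded = FALSE,
        qc_flags = paste(seg$qc_flags, collapse = ";"))
    }
  }
  list(discrimination = disc,
       melodic = if (length(mel)) do.call(rbind, mel) else NULL,
       simple = if (length(simp)) do.call(rbind, simp) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame())
}

melodic_na_scores <- function() {
  data.frame(abs_error_cents = NA_real_, abs_contour_error_cents = NA_real_,
             contour_score = NA_integer_,
             abs_interval_magnitude_cents = NA_real_,
             abs_interval_difference_cents = NA_real_)
}
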