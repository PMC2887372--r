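# Same/different discrimination: fixed-level test battery and the 2-down-1-up
# adaptive training staircase.
#
# Training follows a transformed up-down rule: after two consecutive correct
# responses the interval scale moves one level harder (smaller), after any
# error one level easier. The rule converges on the stimulus level at which
# the probability of a correct response is sqrt(1/2) ~ 70.7%. A coarse phase
# on a fixed ladder runs until the fourth reversal of direction; a fine phase
# of exactly 70 trials then continues from the level that evoked the fourth
# reversal, with levels spaced 2 cents apart.

#' Configure the discrimination test battery
#'
#' Fixed-level same/different testing (no feedback): each cell of interval
#' scale x center frequency x timbre receives `trials_per_scale` trials,
#' exactly half "same" pairs and half "different" pairs.
#'
#' @param scales_cents Interval scales tested (default the seven study
#'   scales).
#' @param center_freqs_hz Center frequencies (250 trained, 500 untrained).
#' @param timbres Stimulus timbres included.
#' @param trials_per_scale Trials per cell; must be even so the same/different
#'   split is exact.
#' @return Object of class `"test_battery_config"`.
#' @export
test_battery_config <- function(scales_cents = c(5, 10, 15, 20, 30, 40, 60),
                                center_freqs_hz = c(250, 500),
                                timbres = c("pure", "harmonic"),
                                trials_per_scale = 20L) {
  trials_per_scale <- as.integer(trials_per_scale)
  stopifnot(length(scales_cents) >= 1L, all(scales_cents > 0),
            trials_per_scale >= 2L)
  if (trials_per_scale %% 2L != 0L)
    stop("trials_per_scale must be even (half same, half different)")
  timbres <- match.arg(timbres, c("pure", "harmonic"), several.ok = TRUE)
  structure(list(scales_cents = scales_cents,
                 center_freqs_hz = center_freqs_hz, timbres = timbres,
                 trials_per_scale = trials_per_scale),
            class = "test_battery_config")
}

#' Run a same/different test block against a listener model
#'
#' For every cell of the battery, generates micromelody pairs (the "different"
#' member via [make_different_pair()]), presents them to the listener in
#' randomized order with an exact 50/50 same/different mix, and records the
#' responses. No feedback reaches the listener.
#'
#' @param config A [test_battery_config()].
#' @param listener A [listener_model()].
#' @param seed Optional integer seed.
#' @return Object of class `"test_block"`: a `trials` data.frame (one row per
#'   trial: `scale_cents`, `center_freq_hz`, `timbre`, `is_same`,
#'   `response_same`, `correct`) plus the config.
#' @export
run_test_block <- function(config, listener, seed = NULL) {
  stopifnot(inherits(config, "test_battery_config"),
            inherits(listener, "listener_model"))
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(scale_cents = config$scales_cents,
                       center_freq_hz = config$center_freqs_hz,
                       timbre = config$timbres,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    n <- config$trials_per_scale
    is_same <- sample(rep(c(TRUE, FALSE), n / 2L))
    resp <- logical(n)
    for (k in seq_len(n)) {
      ref <- realize_melody(micromelody_spec(
        cell$scale_cents, cell$center_freq_hz, timbre = cell$timbre))
      if (!is_same[k]) make_different_pair(ref)  # draw the comparison stimulus
      resp[k] <- simulate_response(listener, is_same[k], cell$scale_cents)
    }
    rows[[i]] <- data.frame(scale_cents = cell$scale_cents,
                            center_freq_hz = cell$center_freq_hz,
                            timbre = cell$timbre, trial = seq_len(n),
                            is_same = is_same, response_same = resp,
                            correct = resp == is_same)
  }
  structure(list(trials = do.call(rbind, rows), config = config),
            class = "test_block")
}

#' Percent correct per condition cell
#'
#' Summarises a trial log as `100 * n_correct / n_trials` within each
#' combination of the grouping columns.
#'
#' @param trials Data.frame with a logical `correct` column (e.g.
#'   `run_test_block(...)$trials`, or a pooled multi-subject log with design
#'   labels).
#' @param by Character vector of grouping column names present in `trials`.
#' @return Data.frame with the grouping columns, `n_trials` and
#'   `percent_correct` in [0, 100].
#' @export
percent_correct <- function(trials, by = "scale_cents") {
  if (inherits(trials, "test_block")) trials <- trials$trials
  stopifnot(is.data.frame(trials), "correct" %in% names(trials),
            all(by %in% names(trials)))
  if (nrow(trials) == 0L) stop("no trials to summarise")
  agg <- aggregate(trials$correct, by = trials[by],
                   FUN = function(z) c(n = length(z), pc = 100 * mean(z)))
  out <- cbind(agg[by], n_trials = agg$x[, "n"],
               percent_correct = agg$x[, "pc"])
  out[do.call(order, out[by]), , drop = FALSE]
}

# --- staircase ---------------------------------------------------------------

#' Configure the 2-down-1-up training staircase
#'
#' @param coarse_levels_cents Descending coarse ladder of interval scales.
#'   The default spans the training range (60 down to 1 cent) through the
#'   tested scales.
#' @param n_reversals_coarse Reversals ending the coarse phase (default 4).
#' @param fine_trials Number of fine-phase trials (default 70).
#' @param fine_step_cents Fine-phase level spacing in cents (default 2).
#' @param start_level_cents Starting level; must be on the coarse ladder.
#' @param level_bounds_cents Clamp range for fine-phase levels (training range
#'   1-60 cents).
#' @return Object of class `"staircase_config"`.
#' @export
staircase_config <- function(coarse_levels_cents =
                               c(60, 50, 40, 30, 20, 15, 10, 8, 6, 4, 2, 1),
                             n_reversals_coarse = 4L, fine_trials = 70L,
                             fine_step_cents = 2, start_level_cents = 60,
                             level_bounds_cents = c(1, 60)) {
  stopifnot(all(diff(coarse_levels_cents) < 0), all(coarse_levels_cents > 0),
            fine_step_cents > 0, n_reversals_coarse >= 1L, fine_trials >= 0L,
            start_level_cents %in% coarse_levels_cents,
            length(level_bounds_cents) == 2L,
            level_bounds_cents[1] < level_bounds_cents[2])
  structure(list(coarse_levels_cents = coarse_levels_cents,
                 n_reversals_coarse = as.integer(n_reversals_coarse),
                 fine_trials = as.integer(fine_trials),
                 fine_step_cents = fine_step_cents,
                 start_level_cents = start_level_cents,
                 level_bounds_cents = level_bounds_cents),
            class = "staircase_config")
}

#' Initial staircase state
#'
#' @param config A [staircase_config()].
#' @return A `"staircase_state"` list: current `level_cents`, the consecutive
#'   correct counter, the direction of the last committed level change, and
#'   phase bookkeeping.
#' @export
staircase_state_init <- function(config) {
  structure(list(config = config, phase = "coarse",
                 level_cents = config$start_level_cents,
                 n_consecutive_correct = 0L,
                 last_direction = 0L,      # -1 harder, +1 easier, 0 none yet
                 reversal = FALSE,         # did the step just taken reverse?
                 n_reversals = 0L),
            class = "staircase_state")
}

# next level one rung harder (-1) or easier (+1); NA if clamped at the end
ladder_move <- function(state, direction) {
  cfg <- state$config
  if (state$phase == "coarse") {
    idx <- match(state$level_cents, cfg$coarse_levels_cents)
    new_idx <- idx - direction   # ladder is descending: harder = next index
    if (new_idx < 1L || new_idx > length(cfg$coarse_levels_cents)) return(NA)
    cfg$coarse_levels_cents[new_idx]
  } else {
    lv <- state$level_cents + direction * cfg$fine_step_cents
    if (lv < cfg$level_bounds_cents[1] || lv > cfg$level_bounds_cents[2])
      return(NA)
    lv
  }
}

#' Advance the staircase by one scored trial
#'
#' Implements the 2-down-1-up rule: after two consecutive correct responses
#' the level moves one step harder and the counter resets; after any error it
#' moves one step easier and the counter resets. A reversal is flagged when a
#' committed level change has the opposite direction to the previous committed
#' change; a stay forced by the ladder end (clamp) commits no change and is
#' never a reversal.
#'
#' @param state A `"staircase_state"`.
#' @param correct Logical: was the trial answered correctly?
#' @return The updated state; `state$reversal` reports whether this trial
#'   evoked a reversal and `state$level_cents` the level for the next trial.
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  state$reversal <- FALSE
  direction <- 0L
  if (correct) {
    state$n_consecutive_correct <- state$n_consecutive_correct + 1L
    if (state$n_consecutive_correct == 2L) {
      direction <- -1L
      state$n_consecutive_correct <- 0L
    }
  } else {
    direction <- +1L
    state$n_consecutive_correct <- 0L
  }
  if (direction != 0L) {
    new_level <- ladder_move(state, direction)
    if (!is.na(new_level)) {
      if (state$last_direction != 0L && direction != state$last_direction) {
        state$reversal <- TRUE
        state$n_reversals <- state$n_reversals + 1L
      }
      state$last_direction <- direction
      state$level_cents <- new_level
    }
  }
  state
}

#' Run a full coarse + fine training staircase
#'
#' Simulates same/different training trials (50% same pairs, feedback implied
#' by the adaptive rule) against a listener model. The coarse phase walks the
#' configured ladder until the fourth reversal; the fine phase then runs
#' exactly `fine_trials` trials starting from the level that evoked that
#' reversal, with `fine_step_cents` spacing, under the same rule.
#'
#' @param config A [staircase_config()].
#' @param listener A [listener_model()].
#' @param seed Optional integer seed.
#' @param max_coarse_trials Safety bound on coarse-phase length.
#' @return Object of class `"staircase_run"`: `trials` data.frame (`phase`,
#'   `level_cents`, `is_same`, `response_same`, `correct`, `reversal`),
#'   `fine_start_level_cents`, the reversal levels per phase, and
#'   `threshold_estimate_cents` (mean of fine-phase reversal levels, `NA` if
#'   none occurred).
#' @export
run_staircase <- function(config = staircase_config(), listener, seed = NULL,
                          max_coarse_trials = 10000L) {
  stopifnot(inherits(config, "staircase_config"),
            inherits(listener, "listener_model"))
  if (!is.null(seed)) set.seed(seed)
  state <- staircase_state_init(config)
  log_one <- function(state, is_same, resp) {
    data.frame(phase = state$phase, level_cents = state$level_cents,
               is_same = is_same, response_same = resp,
               correct = resp == is_same, reversal = NA)
  }
  trials <- vector("list", 0L)
  # coarse phase
  n <- 0L
  while (state$n_reversals < config$n_reversals_coarse) {
    n <- n + 1L
    if (n > max_coarse_trials) stop("coarse phase did not terminate")
    is_same <- runif(1) < 0.5
    resp <- simulate_response(listener, is_same, state$level_cents)
    row <- log_one(state, is_same, resp)
    state <- staircase_step(state, row$correct)
    row$reversal <- state$reversal
    trials[[length(trials) + 1L]] <- row
  }
  fine_start <- trials[[length(trials)]]$level_cents  # level at 4th reversal
  # fine phase: reset counters, keep direction history fresh
  state$phase <- "fine"
  state$level_cents <- fine_start
  state$n_consecutive_correct <- 0L
  state$last_direction <- 0L
  for (k in seq_len(config$fine_trials)) {
    is_same <- runif(1) < 0.5
    resp <- simulate_response(listener, is_same, state$level_cents)
    row <- log_one(state, is_same, resp)
    state <- staircase_step(state, row$correct)
    row$reversal <- state$reversal
    trials[[length(trials) + 1L]] <- row
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  fine_rev <- trials$level_cents[trials$reversal & trials$phase == "fine"]
  structure(list(
    trials = trials, config = config,
    fine_start_level_cents = fine_start,
    coarse_reversal_levels_cents =
      trials$level_cents[trials$reversal & trials$phase == "coarse"],
    fine_reversal_levels_cents = fine_rev,
    threshold_estimate_cents = if (length(fine_rev)) mean(fine_rev) else NA_real_),
    class = "staircase_run")
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf(
    "2-down-1-up staircase: %d coarse + %d fine trials\n",
    sum(x$trials$phase == "coarse"), sum(x$trials$phase == "fine")))
  cat(sprintf("  fine phase start: %g c; threshold estimate: %s c\n",
              x$fine_start_level_cents,
              formatC(x$threshold_estimate_cents, digits = 3)))
  invisible(x)
}

#' Write a staircase or test-block trial log as TSV
#'
#' @param run A `"staircase_run"` or `"test_block"`, or a bare trials
#'   data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(run, path) {
  trials <- if (is.data.frame(run)) run else run$trials
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
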