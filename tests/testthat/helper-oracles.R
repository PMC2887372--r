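# Independent oracles, written without reference to the package internals.

# Best path score by exhaustive enumeration over all states^frames paths.
brute_best_path_score <- function(scores, penalty) {
  S <- nrow(scores)
  T_ <- ncol(scores)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  em <- sapply(seq_len(T_), function(t) scores[paths[, t], t])
  if (is.null(dim(em))) em <- matrix(em, nrow = nrow(paths))
  switches <- if (T_ > 1L)
    rowSums(paths[, -1L, drop = FALSE] != paths[, -T_, drop = FALSE])
  else 0
  max(rowSums(em) - penalty * switches)
}

path_score <- function(scores, path, penalty) {
  sum(scores[cbind(path, seq_along(path))]) - penalty * sum(diff(path) != 0)
}

# Direction-change count written as an explicit scan (oracle for
# contour_inversions).
scan_inversions <- function(steps) {
  nz <- steps[steps != 0]
  inv <- 0L
  if (length(nz) >= 2L)
    for (k in 2:length(nz)) if (nz[k] * nz[k - 1L] < 0) inv <- inv + 1L
  inv
}

# Exhaustive count of admissible 7-note contours under the stated rules,
# enumerating all 3^6 step sequences directly.
brute_admissible_count_7 <- function() {
  count <- 0L
  for (code in 0:(3^6 - 1)) {
    steps <- integer(6)
    x <- code
    for (j in 1:6) { steps[j] <- (x %% 3) - 1L; x <- x %/% 3 }
    if (sum(steps == 0L) <= 1L && scan_inversions(steps) %in% c(2L, 3L))
      count <- count + 1L
  }
  count
}

# A noiseless singer used throughout parameter-recovery checks.
perfect_singer <- function() {
  singer_model(bias_cents = 0, interval_gain = 1, note_noise_sd_cents = 0,
               jitter_sd_cents = 0)
}
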