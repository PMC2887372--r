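test_that("trace construction and the standard frame rate", {
  tr <- pitch_trace(f0_cents = rep(0, 100))
  expect_equal(tr$frame_rate_hz, 1378.125)   # 44100 / 32
  expect_equal(tr$time_s[2] - tr$time_s[1], 32 / 44100)
  expect_error(pitch_trace(), "f0")
  expect_error(pitch_trace(f0_cents = 1, power = c(1, 2)))
})

test_that("trace files round-trip through delimited text", {
  set.seed(2)
  tr <- synthesize_trace(0, singer_model(jitter_sd_cents = 5), note_ms = 300)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pitch_trace(tr, path)
  back <- read_pitch_trace(path)
  expect_equal(back$f0_cents, tr$f0_cents, tolerance = 1e-9)
  expect_equal(back$frame_rate_hz, tr$frame_rate_hz, tolerance = 1e-6)
  expect_equal(back$aperiodicity, tr$aperiodicity)
})

test_that("voicing filter drops aperiodic and weak frames", {
  tr <- pitch_trace(f0_cents = rep(0, 10),
                    power = c(rep(1, 9), 1e-6),
                    aperiodicity = c(0.5, rep(0.1, 9)))
  keep <- voiced_frames(tr)
  expect_equal(keep, c(FALSE, rep(TRUE, 8), FALSE))
  expect_error(build_state_matrix(pitch_trace(f0_cents = rep(0, 5),
                                              aperiodicity = rep(1, 5))),
               "voiced")
})

test_that("state matrix scores peak at the smoothed f0", {
  tr <- pitch_trace(f0_cents = rep(0, 200))
  sm <- build_state_matrix(tr)
  expect_true(all(diff(sm$freq_states_cents) > 0))
  expect_equal(ncol(sm$scores), 200)
  argmax <- sm$freq_states_cents[apply(sm$scores, 2, which.max)]
  expect_true(all(argmax == 0))
  # two plateaus: the column argmax switches at the transition
  tr2 <- pitch_trace(f0_cents = c(rep(0, 300), rep(100, 300)))
  sm2 <- build_state_matrix(tr2)
  am <- sm2$freq_states_cents[apply(sm2$scores, 2, which.max)]
  expect_true(all(am[1:250] == 0))
  expect_true(all(am[351:600] == 100))
})

test_that("smoothing suppresses an isolated one-frame spike", {
  f0 <- rep(0, 301)
  f0[150] <- 1200   # octave glitch
  sm <- build_state_matrix(pitch_trace(f0_cents = f0))
  am <- sm$freq_states_cents[apply(sm$scores, 2, which.max)]
  expect_true(all(am == 0))
})

test_that("viterbi equals exhaustive enumeration on small instances", {
  set.seed(5)
  for (i in 1:1000) {
    S <- sample(2:4, 1)
    T_ <- sample(2:8, 1)
    sc <- matrix(rnorm(S * T_), S, T_)
    pen <- runif(1, 0, 3)
    p <- viterbi_path(sc, pen)
    expect_equal(path_score(sc, p, pen), brute_best_path_score(sc, pen),
                 tolerance = 1e-9)
  }
})

test_that("viterbi limit cases", {
  sc <- matrix(c(0.2, 1.5, -1), 3, 1)
  expect_equal(viterbi_path(sc, 5), 2L)   # single column: argmax
  set.seed(6)
  sc <- matrix(rnorm(40), 4, 10)
  p <- viterbi_path(sc, Inf)
  expect_equal(length(unique(p)), 1L)     # infinite penalty: constant path
  expect_equal(p[1], which.max(rowSums(sc)))
  # zero penalty: per-column argmax
  expect_equal(viterbi_path(sc, 0), apply(sc, 2, which.max))
})

test_that("note extraction: ranking, ordering and the middle-80% rule", {
  # constant-state runs with known lengths via a hand-built state matrix
  f0 <- c(rep(0, 120), rep(100, 30), rep(0, 100), rep(200, 140),
          rep(100, 90), rep(-100, 110))
  tr <- pitch_trace(f0_cents = f0)
  seg <- segment_melody(tr, n_notes = 5, gaussian_sd_frames = 0,
                        median_frames = 1)
  expect_equal(seg$notes$state_cents, c(0, 0, 200, 100, -100))
  expect_true(all(diff(seg$notes$onset_s) > 0))
  expect_equal(seg$notes$n_frames, c(120, 100, 140, 90, 110))
  expect_equal(seg$notes$mean_cents[1], mean(rep(0, 120)[13:108]))
  # a four-plateau trace cannot yield five notes
  f0_4 <- c(rep(0, 100), rep(100, 100), rep(0, 100), rep(100, 100))
  expect_error(segment_melody(pitch_trace(f0_cents = f0_4),
                              gaussian_sd_frames = 0, median_frames = 1),
               class = "segmentation_error")
})

test_that("middle-80% trimming drops floor(0.1 n) frames at each end", {
  f0 <- c(rep(c(0, 100, 0, 200, 300), each = 100))
  f0[301:400] <- 200 + seq(-49.5, 49.5, by = 1) * 0.2  # slope inside a note
  tr <- pitch_trace(f0_cents = f0)
  seg <- segment_melody(tr, gaussian_sd_frames = 0, median_frames = 1,
                        switch_penalty = 20)
  # note 4 statistics must come from frames 11..90 of its 100 frames
  vals <- f0[301:400][11:90]
  expect_equal(seg$notes$mean_cents[4], mean(vals), tolerance = 1e-6)
  expect_equal(seg$notes$sd_cents[4], sd(vals), tolerance = 1e-6)
})

test_that("segmentation recovers synthetic note means within 5 cents", {
  set.seed(13)
  tm <- target_melody(100, contour_steps = c(1, -1, 1, -1))
  for (i in 1:10) {
    tr <- synthesize_trace(tm, singer_model(note_noise_sd_cents = 0,
                                            jitter_sd_cents = 10))
    seg <- segment_melody(tr)
    expect_lt(max(abs(seg$notes$mean_cents - tm$note_cents)), 5)
  }
})

test_that("segmentation is equivariant to transposition on the grid", {
  set.seed(14)
  tm <- target_melody(50, contour_steps = c(-1, 1, 1, -1))
  tr <- synthesize_trace(tm, singer_model(jitter_sd_cents = 8))
  seg <- segment_melody(tr)
  shift <- 35  # a multiple of the 5-cent grid step keeps the grid aligned
  tr2 <- tr
  tr2$f0_cents <- tr$f0_cents + shift
  seg2 <- segment_melody(tr2)
  expect_equal(seg2$notes$mean_cents, seg$notes$mean_cents + shift,
               tolerance = 1e-9)
  expect_equal(seg2$notes$onset_s, seg$notes$onset_s)
})

test_that("QC flags fire on short and ambiguous segmentations", {
  # five plateaus, one of them very short (< 50 ms at 1378 Hz = < 69 frames)
  f0 <- c(rep(0, 200), rep(100, 40), rep(0, 200), rep(200, 200), rep(300, 200))
  seg <- segment_melody(pitch_trace(f0_cents = f0), gaussian_sd_frames = 0,
                        median_frames = 1, switch_penalty = 2)
  expect_true("short_segment" %in% seg$qc_flags)
  expect_true("short_for_trim" %in%
                segment_melody(pitch_trace(
                  f0_cents = rep(c(0, 100, 0, 100, 0, 100), each = 8)),
                  gaussian_sd_frames = 0, median_frames = 1,
                  switch_penalty = 0.5)$qc_flags)
})

test_that("simple singing statistics", {
  expect_equal(simple_singing_stats(pitch_trace(f0_cents = rep(0, 50))),
               c(mean_error_cents = 0, stability_cents = 0))
  expect_equal(simple_singing_stats(pitch_trace(f0_cents = rep(30, 50))),
               c(mean_error_cents = 30, stability_cents = 0))
  set.seed(15)
  tr <- pitch_trace(f0_cents = rnorm(2e4, 0, 20))
  st <- simple_singing_stats(tr)
  expect_lt(abs(st[["stability_cents"]] - 20), 1)
})
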