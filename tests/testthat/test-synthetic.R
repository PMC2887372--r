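test_that("listener psychometric hits its defining points", {
  l <- listener_model(15, lapse = 0.02)
  expect_equal(p_correct(l, 15), 2^-0.5, tolerance = 1e-12)
  expect_lt(p_correct(l, 0.01), 0.52)            # chance at tiny scales
  expect_gt(p_correct(l, 1000), 0.97)            # ceiling at huge scales
  expect_lte(p_correct(l, 1e9), 1 - l$lapse)
  expect_error(listener_model(-1))
  expect_error(listener_model(10, lapse = 0.4))
})

test_that("simulated responses track the psychometric function", {
  set.seed(30)
  l <- listener_model(20, lapse = 0)
  for (s in c(4, 20, 80)) {
    correct <- replicate(3000, {
      is_same <- runif(1) < 0.5
      simulate_response(l, is_same, s) == is_same
    })
    expect_equal(mean(correct), p_correct(l, s), tolerance = 0.035)
  }
  # bias_same = 1 always answers "same"
  lb <- listener_model(20, bias_same = 1)
  expect_true(all(replicate(20, simulate_response(lb, FALSE, 60))))
})

test_that("a noiseless unbiased singer produces a perfect score line", {
  tm <- target_melody(50, contour_steps = c(-1, 1, -1, 1))
  tr <- synthesize_trace(tm, perfect_singer())
  sc <- melodic_scores(segment_melody(tr), tm)
  expect_equal(sc$abs_error_cents, 0, tolerance = 1e-6)
  expect_equal(sc$abs_contour_error_cents, 0, tolerance = 1e-6)
  expect_equal(sc$contour_score, 4)
  expect_equal(sc$abs_interval_magnitude_cents, 50, tolerance = 1e-6)
  expect_equal(sc$abs_interval_difference_cents, 0, tolerance = 1e-6)
})

test_that("singer bias and gain propagate to the measures as defined", {
  tm <- target_melody(100, contour_steps = c(1, -1, 1, -1))
  biased <- singer_model(bias_cents = 50, note_noise_sd_cents = 0,
                         jitter_sd_cents = 0)
  sc <- melodic_scores(segment_melody(synthesize_trace(tm, biased)), tm)
  expect_equal(sc$abs_error_cents, 50, tolerance = 0.5)
  expect_equal(sc$abs_interval_difference_cents, 0, tolerance = 0.5)
  compressed <- singer_model(interval_gain = 0.5, note_noise_sd_cents = 0,
                             jitter_sd_cents = 0)
  sc2 <- melodic_scores(segment_melody(synthesize_trace(tm, compressed)), tm)
  expect_equal(sc2$abs_interval_magnitude_cents, 50, tolerance = 0.5)
})

test_that("trace structure: frame rate, glides, onsets, true centers", {
  tm <- target_melody(100, contour_steps = c(1, 1, -1, -1))
  tr <- synthesize_trace(tm, perfect_singer(), seed = 1)
  expect_equal(tr$frame_rate_hz, 1378.125)
  expect_equal(length(attr(tr, "note_centers_cents")), 5)
  expect_equal(attr(tr, "note_centers_cents"), tm$note_cents)
  # onset frames are aperiodic and get filtered out
  expect_gt(sum(tr$aperiodicity > 0.2), 0)
  expect_false(any(voiced_frames(tr) & tr$aperiodicity > 0.2))
  # glide frames exist strictly between note pitches (noiseless singer)
  at_a_center <- sapply(tr$f0_cents, function(v)
    any(abs(v - tm$note_cents) < 1e-9))
  expect_gt(sum(!at_a_center), 0)
})

test_that("same seed gives a bit-identical cohort", {
  spec <- cohort_spec(n_per_group = 2, trials_per_scale = 4,
                      trials_per_task = 2, scales_cents = c(10, 30),
                      center_freqs_hz = 250, timbres = "pure",
                      tasks = "melodic")
  a <- generate_cohort(spec, seed = 99)
  b <- generate_cohort(spec, seed = 99)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$discrimination, b$discrimination)
  expect_identical(lapply(a$vocal, function(r) r$trace$f0_cents),
                   lapply(b$vocal, function(r) r$trace$f0_cents))
  c2 <- generate_cohort(spec, seed = 100)
  expect_false(identical(a$subjects$threshold_pre,
                         c2$subjects$threshold_pre))
})

test_that("segmentation + scoring recover singer bias and interval gain", {
  set.seed(77)
  singer <- singer_model(bias_cents = 30, interval_gain = 0.8,
                         note_noise_sd_cents = 10, jitter_sd_cents = 15)
  tms <- replicate(100, target_melody(100), simplify = FALSE)
  produced <- t(sapply(tms, function(tm)
    segment_melody(synthesize_trace(tm, singer))$notes$mean_cents))
  targets <- t(sapply(tms, function(tm) tm$note_cents))
  fit <- lm(as.vector(produced) ~ as.vector(targets))
  expect_lt(abs(coef(fit)[1] - 30), 3)          # bias within 3 cents
  expect_lt(abs(coef(fit)[2] - 0.8), 0.05 * 0.8)  # gain within 5%
})

test_that("per-note absolute error matches the folded-normal mean", {
  set.seed(78)
  singer <- singer_model(bias_cents = 0, interval_gain = 1,
                         note_noise_sd_cents = 15, jitter_sd_cents = 10)
  tm <- target_melody(100, contour_steps = c(1, -1, 1, -1))
  errs <- replicate(100,
    abs_error(segment_melody(synthesize_trace(tm, singer)), tm))
  expect_equal(mean(errs), 15 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("degenerate trials are excluded with reasons, never dropped", {
  spec <- cohort_spec(n_per_group = 2, trials_per_scale = 4,
                      trials_per_task = 6, scales_cents = 20,
                      center_freqs_hz = 250, timbres = "pure",
                      tasks = "melodic", degenerate_fraction = 0.5,
                      melody_intervals_cents = 100)
  ch <- generate_cohort(spec, seed = 3)
  res <- analyze_cohort(ch)
  n_deg_missing <- sum(vapply(ch$vocal, function(r)
    r$degenerate == "missing_note", logical(1)))
  expect_gt(n_deg_missing, 0)
  expect_equal(sum(res$melodic$excluded), nrow(res$exclusions))
  expect_equal(nrow(res$melodic), length(ch$vocal))  # every trial accounted
  expect_true(all(nchar(res$exclusions$reason) > 0))
  # merged-note trials are the ones that cannot yield five segments
  expect_gte(sum(res$melodic$excluded), n_deg_missing * 0.8)
})

test_that("cohort analysis tables are consistent and complete", {
  spec <- cohort_spec(n_per_group = 2, trials_per_scale = 4,
                      trials_per_task = 2, scales_cents = c(10, 60),
                      center_freqs_hz = 250, timbres = "pure",
                      degenerate_fraction = 0)
  ch <- generate_cohort(spec, seed = 5)
  res <- analyze_cohort(ch)
  expect_equal(nrow(res$discrimination), 4 * 2 * 2)  # subj x sess x scale
  expect_true(all(res$discrimination$percent_correct >= 0 &
                    res$discrimination$percent_correct <= 100))
  expect_equal(nrow(res$simple), 4 * 2 * 2)          # subj x sess x trials
  expect_equal(nrow(res$melodic), 4 * 2 * 2 * 2)
  expect_true(all(!res$melodic$excluded))
})
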