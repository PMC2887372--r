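---
title: "Methods: micromelody discrimination and melodic vocal accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micromelody discrimination and melodic vocal accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromelody)
```

This vignette documents the models behind each stage of the pipeline, the
tunable parameters and their defaults, the numerical choices where the
procedure was genuinely open, and the limits of what the synthetic validation
shows.

## Stimuli

A micromelody is seven notes whose adjacent intervals all have one magnitude
(the *interval scale*, 1–99 cents). Cents and frequency are related by
$c = 1200\,\log_2(f/f_{\mathrm{ref}})$; melodies are realized by anchoring
the 4th note at the center frequency (250 or 500 Hz) and accumulating signed
steps of the scale outward, so the largest adjacent interval is exactly the
scale and always sub-semitone.

Contours are sampled uniformly from the full admissible set: all step
sequences in $\{-1, 0, +1\}^6$ with **two or three inversions** (direction
changes, counted between consecutive non-zero steps, so a repeat never breaks
an up–up run) and **at most one repetition** (zero step). Enumerating all
$3^6 = 729$ sequences and filtering is cheap and guarantees exact uniformity;
the set is cached. For the five-note singing targets no constraint is stated
by the task design beyond avoiding degenerate shapes, so the package requires
at least one inversion and no repeats; the targets used in a simulated study
are five fixed melodies per interval scale, presented in pseudo-random order
within blocks.

Timing is fixed — 200 ms notes, 150 ms inter-note gaps, 50 ms tail, 2.35 s
total — and asserted for every realized melody. Audio rendering uses 10 ms
raised-cosine onset/offset ramps (standard practice to avoid spectral
splatter; the exact ramp is not prescribed by the task) and either a sine
tone or six equal-amplitude harmonics. The harmonic timbre is a synthetic
stand-in for recorded vocal tones, which the package deliberately does not
model.

The "different" member of a discrimination pair keeps the scale and center
frequency, resamples the contour, and requires at least two differing notes;
rejection sampling from the admissible set terminates in a handful of draws.

## The 2-down-1-up staircase

Two consecutive correct responses move the interval scale one level harder
and reset the counter; any error moves it one level easier and resets the
counter. In steady state the level therefore sits where
$P(\text{correct})^2 = \tfrac12$, i.e. $P(\text{correct}) = 2^{-1/2} \approx
0.707$.

Choices the rule's verbal description leaves open, and what the package does:

* **Coarse ladder.** Only the range (60 down to 1 cent) is prescribed. The
  default ladder is `c(60, 50, 40, 30, 20, 15, 10, 8, 6, 4, 2, 1)`: it
  contains the 60 → 50 worked example and passes through the seven test
  scales. It is a plain argument of `staircase_config()`.
* **Reversals.** A reversal is a committed level change whose direction is
  opposite to the previous committed change. At a ladder end the level
  clamps; a forced stay commits no change and is **not** a reversal (standard
  staircase practice — counting clamp bounces would terminate runs at the
  floor artificially fast).
* **Phase boundary.** The trial that evokes the fourth reversal ends the
  coarse phase immediately, and the fine phase starts at that trial's level
  with 2-cent spacing, clamped to the 1–60 cent training range. The fine
  phase is exactly 70 trials.
* **Threshold summary.** The mean of fine-phase reversal levels is reported
  as `threshold_estimate_cents`. It is a convenience, not an input to any
  downstream table.

The tracking property is validated by simulation: for a listener whose
70.7% point is known by construction (below), the mean fine-phase correct
rate after the hand-off transient sits within two percentage points of
$2^{-1/2}$, and long fine phases (1500 trials) converge to it tightly.

## Listener model

`listener_model(threshold_cents, slope, lapse, bias_same)` gives

$$P(\text{correct} \mid s) \;=\; \tfrac12 + (\tfrac12 - \lambda)\,
\mathrm{logistic}\!\big(k \log_2 (s / x_0)\big),$$

rising from chance at vanishing interval scale $s$ to $1 - \lambda$. The
anchor $x_0$ is solved at construction so that the function passes through
$2^{-1/2}$ exactly at `threshold_cents` — parameterizing the listener at the
staircase's own convergence point makes staircase validation a direct
comparison rather than a psychometric fit. The same correctness probability
applies to "same" and "different" pairs (a symmetric observer); `bias_same`
optionally overrides responses toward "same" and defaults to 0. Any sigmoid
would do for pipeline validation; nothing downstream depends on the logistic
form.

## Segmentation of sung melodies

The f0 trace contract is frame-wise `(time, f0, power, aperiodicity)` at
44100/32 = 1378.125 Hz, from any extractor; pitch is converted to cents re
252 Hz (the singing target), which also normalizes registers across voices.

Numerical choices, all exposed as arguments of `build_state_matrix()` /
`segment_melody()`:

* **Voicing filter** (aperiodicity > 0.2 or power < 1% of the trace median
  removed): conventional f0 post-processing; the thresholds are not critical
  because the synthetic onsets are far above the ceiling and voiced frames
  far above the floor.
* **Smoothing**: moving median over 15 frames (~11 ms) — which annihilates
  isolated octave glitches — followed by a Gaussian of SD 10 frames,
  renormalized at the edges. There is no single canonical smoother for this
  job; a median first is the standard defence against octave errors.
* **State grid**: 5-cent bins spanning the voiced range ± 100 cents. Finer
  than any scored effect (the smallest produced intervals of interest are
  50 cents), coarse enough to keep the matrix small.
* **Emission and switch penalty**: column $t$ scores state $m$ as
  $-(m - \tilde f_t)^2 / (2\sigma_e^2)$ with $\sigma_e = 25$ cents; a
  constant penalty of 8 (emission units) applies per state change. With these
  values a 5-cent mis-state costs ~0.02 per frame, so a ≥ 50 ms plateau
  (≥ 69 frames) comfortably pays for its two switches, while 60 ms glides
  force the path through intermediate states; this is validated by parameter
  recovery rather than asserted. Hard column assignment and probabilistic
  scoring are both defensible formulations of state-matrix segmentation; the
  emission/penalty form used here is one consistent choice, isolated behind
  configuration.
* **Viterbi**: with a constant switch cost the per-frame transition maximum
  reduces to "stay vs jump from the best previous state", giving
  O(states × frames). Ties prefer staying, then the lower state. Optimality
  is tested against exhaustive path enumeration on a thousand random small
  instances.
* **Notes**: the five longest constant-state runs (ties: earlier onset),
  reordered by onset. Mean and SD per note use the middle 80% of the run's
  *raw* (unsmoothed) f0 — `floor(0.1 n)` frames dropped at each end — so
  glide tails do not contaminate note statistics. Runs shorter than 10 frames
  use all frames and are flagged.
* **Failure and QC**: fewer than five runs raises a classed
  `segmentation_error`; pipeline code records the trial as excluded with the
  reason. Heuristic flags (`adjacent_same_state`, `short_segment` < 50 ms,
  `ambiguous_ranking` when the 5th and 6th longest runs differ by < 10 ms)
  stand in for the visual inspection a human would apply — they approximate,
  and do not claim to reproduce, manual rejection criteria.

Segmentation is translation-equivariant (shifting a trace by a multiple of
the grid step shifts note means exactly), and recovers synthetic note means
within 5 cents at 10-cent frame jitter.

## The five melodic measures

With produced notes $p_{1..5}$ and target notes $t_{1..5}$ (cents re 252 Hz):

1. absolute error $\frac15\sum_i |p_i - t_i|$;
2. absolute contour error $\frac15\sum_i |(p_i - p_3) - (t_i - t_3)|$ —
   centering on the **middle note** (the documented reading; centering on the
   produced mean is a nearby alternative the package does not use);
3. contour score $\sum_{i=1}^{4}[\mathrm{sign}(\Delta p_i) =
   \mathrm{sign}(\Delta t_i)]$, where a produced zero interval counts as
   incorrect — a repeat is not a pitch change in the correct direction;
4. absolute interval magnitude $\frac14\sum_i |\Delta p_i|$;
5. absolute interval difference $\frac14\sum_i |\Delta p_i - \Delta t_i|$.

Perfect production gives (0, 0, 4, scale, 0); measures 2 and 5 are invariant
to uniform transposition; measure 3 is invariant to any interval-sign
preserving transformation. Summaries are mean ± SE (SD/√n over subjects) per
group × session × scale, computed after excluded trials are removed (with
counts retained); difference scores are per-subject post − pre values,
exported for external ANOVA/regression, which are deliberately out of scope.

## Singer model and simulated cohorts

`synthesize_trace()` holds each note 600 ms with 60 ms linear-in-cents glides
(linear in cents matches how sung transitions look on a log-frequency axis
and keeps the arithmetic exact; only the simple-singing cue duration, 4 s, is
prescribed by the task, and single notes default to it). Note centers are
$\mathrm{bias} + \mathrm{gain}\times\mathrm{target} +
\mathcal N(0,\sigma_{\mathrm{note}})$; frames add
$\mathcal N(0,\sigma_{\mathrm{jitter}})$, linear drift and optional vibrato;
each note onset carries a brief high-aperiodicity burst and the vocalization
has 10 ms power ramps, so the voicing filter is exercised on every trace.

Cohort defaults mirror the study design where it is stated: 2 groups × 10
subjects, two sessions, seven test scales, 20 discrimination trials per cell,
20 trials per singing task per session (four runs of five-trial blocks). The
rest is a population the analysis has to be plausible for, chosen once:
pre-training thresholds log-normal with median 25 cents and log-SD 0.3
(non-musicians hover near chance at the smallest scales and near ceiling at
60 cents); singer bias SD 15 cents, interval gain centered slightly
compressive at 0.9 (SD 0.12), note noise ~18 cents, jitter ~15 cents. These
are field-plausible values for untrained singers, not fitted to any dataset,
and the package labels them as such. Training multiplies the trained group's
post-session threshold by 0.5; a nonspecific factor of 0.9 applies to
everyone's post threshold (test–retest improvement); `vocal_effect = 0` by
default — training does not touch the voice — which builds in the
dissociation the pipeline must be able to detect: group-separated
discrimination deltas with null vocal deltas. One listener threshold governs
all frequencies and timbres, i.e. perfect generalization of training; the
battery still varies them so table shapes are right. 10% of melodic trials
are degenerate (an aborted single-note vocalization, which cannot yield five
segments, or a transient octave glitch), keeping the exclusion and QC
machinery honest.

What the synthetic validation does **not** show: real voices have correlated
(not white) jitter, vibrato idiosyncrasies, consonant artifacts, and octave
errors from the pitch extractor itself; real listeners drift, learn within a
session, and respond with biases that vary by timbre. Passing tests here
demonstrate that the computations implement their definitions and that the
pipeline recovers known parameters under its own generative assumptions — not
that those assumptions describe any particular dataset.

## Problem sizes used in validation

Simulation-based tests use reduced designs chosen for tight feedback loops:
200 staircase runs for the convergence check, 100 trials for parameter
recovery (recovering bias within 3 cents, gain within 5%, and the
folded-normal mean per-note error $\sigma\sqrt{2/\pi}$ within 10%), and a
5-per-group, 4-trials-per-task cohort for the dissociation check. The
generative *parameters* stay at the defaults above throughout; only the
number of replicates is scaled.

## Known limitations

* Pure-tone and harmonic stimuli only; no recorded vocal timbre.
* No loudness calibration: output WAVs are normalized digital amplitude.
* The YIN-style f0 extractor is an input contract, not part of the package.
* Inferential statistics (repeated-measures ANOVAs, post-hoc tests,
  regressions) are intentionally left to standard tools operating on the
  exported tables.
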