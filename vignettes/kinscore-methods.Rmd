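---
title: "Methods: distribution-aware severity scoring from pose keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distribution-aware severity scoring from pose keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its method: the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## From pose keypoints to a task window

The package consumes 2D pose-estimator output: per frame, each joint's
`(x, y)` in pixels plus a detector confidence in `[0, 1]`. Cleaning
proceeds in a fixed order — confidence filtering first, then smoothing —
because smoothing across hallucinated low-confidence detections would
smear their error into good frames:

1. observations with confidence below the threshold (default **0.5**, the
   conventional minimum for pose-estimator output) become missing;
2. interior gaps up to `max_gap` (default **15 frames**, 0.5 s at 30 fps)
   are linearly interpolated; longer gaps stay missing and are excluded
   from signals, since inventing half a second of motion would fabricate
   exactly the kinematics being measured;
3. each coordinate is smoothed by a centered moving average (default
   window **5 frames**, ≈ 0.17 s at 30 fps — narrow enough to preserve
   4 Hz tapping, wide enough to suppress single-frame jitter); edge
   frames use shrinking windows so the length never changes;
4. optionally, `y` is sign-flipped (image coordinates grow downward, but
   "vertical displacement" should be positive upward) and both axes are
   divided by the median shoulder–hip distance, giving camera-distance-free
   body units.

Task-window detection operationalizes "the task starts when the relevant
joints start moving": onset is the first frame where the smoothed joint
speed *and* the displacement from the initial baseline (median position
over the first 10 frames) both exceed thresholds; the task ends at the
first later frame where both quantities stay below
`baseline_fraction` (default 0.5) of their thresholds for a sustained
hold (default **15 frames**), or at the last frame if they never return.
Requiring *both* speed and displacement to return matters for severe
movements: amplitude decrement drives late-task speed toward the floor
while the limb is still visibly displaced, and a speed-only rule would
truncate such clips. Windows are half-open `[start, end)` in 0-based
frame indices throughout.

Thresholds are calibrated per task from labeled clips as a percentile
(default 20th) of within-window peak speeds and peak displacements. A raw
percentile of peaks lies *above* that same share of clips' own peaks by
definition, so those clips could never fire onset; the calibrated value
is therefore derated by a `safety` factor (default **0.5**) before use.
Half the 20th-percentile peak still sits far above resting jitter (which
is an order of magnitude smaller after smoothing), so the derating costs
no specificity. Clips where nothing clears the thresholds raise a typed
no-activity condition; the pipeline's documented fallback is the full
sequence.

For bilateral tasks the active limb is the side whose task joints travel
the greater path length within the window; exact ties break to the left
with a warning, and a side with no surviving detections falls back to the
other with a warning.

## Task-specific signals and the 12 features

Each task is scored from a deliberately minimal joint set, which keeps
irrelevant motion (trunk sway during finger tapping, say) out of the
signal: finger tapping uses the per-frame thumb–index distance; hand
movement the mean fingertip-to-palm distance over the available
fingertips; pronation–supination, toe tapping, leg agility and arising
from chair the vertical displacement of wrist, toe, knee and torso
relative to the window start; gait a per-*step* sequence of inter-ankle
distance peaks, baseline-subtracted by the first step, whose sampling
rate field stores the estimated step rate; postural stability the torso's
vertical displacement relative to the pull instant. The pull instant is
accepted as an annotation (`t_pull` in the clip metadata or argument);
absent one, the frame of peak torso speed inside the window stands in,
the pull-and-recover event being the fastest torso motion in the clip.

Cycle detection Savitzky–Golay-smooths the signal (window 11, order 3,
shrunk for short signals), finds local extrema, keeps those whose
topographic prominence exceeds a fraction (default 0.1) of the smoothed
range, enforces a minimum separation (default 0.1 s), and prunes to
strict peak/trough alternation. The prominence criterion — rather than a
fixed height — is what makes the detector amplitude-scale-free.

Twelve features are computed per signal, in a fixed order because the
model consumes them positionally. The velocity/acceleration/jerk features
are means of absolute 1st/2nd/3rd finite differences of the *task
signal* (not of raw joint traces) scaled by fps powers. The dominant
frequency is the power-weighted mean (spectral centroid) of the
detrended periodogram over 0.25–10 Hz — more stable on quasi-periodic
movement than the argmax, whose power is reported separately as
`max_fft`. Amplitude features come from adjacent peak–trough pairs;
decrement features (`dec_amp`, `dec_vel`) are least-squares slopes of
per-cycle amplitude and mean speed against *cycle index*, matching the
clinical notion of decrement per repetition rather than per second. When
fewer than two cycles exist the cycle-based features are `NA` — never
silent zeros — while difference-based features are still computed; the
model standardizes features with training-set statistics and imputes
`NA` at the training mean (0 after standardization). Up to 14 features
are supported by the interfaces; the 12 tabulated ones are implemented
and the remaining task-specific slots are left disabled, since no
concrete definition exists for them.

## The dual-branch ordinal model

Signals of arbitrary duration are linearly resampled to a fixed length
T = **256** samples and standardized by training-set mean and SD. The
convolutional branch applies three blocks of 1D convolution → batch
normalization → ReLU → max-pool 2 with (16, 32, 64) channels and kernels
(7, 5, 3), followed by global average pooling; the feature branch is an
MLP with widths (32, 16) and ReLU. These sizes are chosen for
desk-scale datasets (hundreds of clips, ~26k parameters) and are fully
overridable in `model_config()`.

The fused embedding feeds a cumulative-logit ordinal head with one shared
score and K − 1 thresholds. The thresholds are parameterized as
`b_1 = θ_1`, `b_k = b_{k-1} − exp(θ_k)`, so they are ordered for *any*
parameter value and the cumulative probabilities
`P(y > k) = sigmoid(s + b_{k+1})` are rank-consistent by construction —
no post-hoc sorting during training. At prediction time
`expand_distribution()` still defends against externally supplied
cumulative vectors by a running maximum from the right (logged when it
fires).

The loss per clip is `Huber_δ(μ̂ − t) + λ·σ̂²` with the panel mean `t` as
target, δ = 1 and λ default 0.1 (candidate grid {0, 0.01, 0.1, 1} for
cross-validated tuning). `σ̂²` is read as the *predicted* distribution's
variance: the regularizer pushes the model toward confident predictions,
and where raters disagree the Huber term's pull toward a fractional mean
keeps mass on several classes. The alternative reading — penalizing
distance to the *rater* variance — would make the loss depend on panel
spread directly; the implemented form is the one under which perfect-mean
predictions incur exactly `λ·σ̂²`, an identity the tests pin down.
Optimization is Adam, lr 1e-3, batch 32, 100 epochs, one model per task
(bilateral sides pooled as samples of the same task model). Everything —
im2col convolutions, batch-norm statistics, pooling argmax routing,
the ordered-threshold Jacobian, Adam — is implemented in-package in
plain matrix code and verified against numerical differentiation in the
test suite. Training is deterministic given the config seed; checkpoints
are self-describing JSON (config, standardization constants, weights).

## Consensus metrics

Panel summaries use the sample (n−1) standard deviation — a 1, 2, 2
panel has mean 1.67 and SD 0.58 to two decimals, whereas the population
formula would give 0.47. Agreement is decomposed into complete (all
raters equal), majority (a strict majority equal) and none, reported as
disjoint per-panel percentages summing to 100; two cumulative views are
added, the per-panel majority-or-better share and the per-*rating* share
(agreed ratings over total ratings, under which a 3-rater majority panel
contributes 2 of 3) — the latter is the convention that matches
"agreement percentage" computed over a ratings denominator.

The within-±1 accuracy applies `|μ̂ − t| ≤ 1` to the continuous predicted
mean against the continuous panel mean — not to rounded classes, since
rounding would re-introduce the single-label fiction the method is built
to avoid. The distribution-aware accuracy scores a prediction correct
when `|μ̂ − t| ≤ k·max(σ, σ_floor)`. A unanimous panel has σ = 0 and
would degenerate the criterion to a point; the floor (default **0.5**,
half a class) keeps it usable while preserving the intended behavior —
tight bands for high-consensus panels, wide ones where raters disagree.
`σ_floor = 0` restores the strict criterion. Band arithmetic uses
unrounded mean and SD; a `strict_paper` mode rounds both to two decimals
first, reproducing printed bands such as `[1.09, 2.25]` exactly, and
band endpoints count as inside (with a 1e-9 epsilon against float
round-off). Composite scores sum predicted means over all present
task/side entries, both sides of bilateral tasks included; the
medication contrast is the per-patient ON − OFF composite delta and the
fraction of patients with a negative delta.

Task complexity is the count of behavioral cues a rater must monitor:
2 for arising from chair (use of arms, rising speed) and 7 for gait
(stride amplitude and speed, foot lift, heel strike, turning, arm swing,
assistive device) per the scale's guidelines; the five repetitive-limb
items are each rated on speed, amplitude, hesitations, halts and
decrement (5 cues) and postural stability on steps to recover,
retropulsion and falling (3 cues) — these last assignments are the
package's reading of the item wording, configurable in `task_specs()`.
The complexity–consensus regressions are ordinary least squares of an
agreement statistic on complexity with the usual two-sided slope test.

## What the simulator emulates — and what it does not

The generator exists so that every stage is testable end-to-end without
clinical data. A clip is a static lead-in (2 s), a quasi-periodic task
segment (10 s), and a static tail (2 s) at 30 fps, with Gaussian keypoint
jitter (SD 1 px against a 100 px shoulder–hip scale) and realistic
confidences (≈ 2% of observations fall below 0.5, exercising the
filter). Latent severity `s ∈ [0, 4]` acts through four channels chosen
to mirror the constructs the exam scores: amplitude × (1 − 0.18·s),
frequency × (1 − 0.12·s), per-cycle amplitude decrement 0.02·s, and
per-cycle hesitation probability 0.05·s (frozen segments of 0.15–0.4 s).
The decrement saturates at 40% of the clip's severity-scaled amplitude:
without a floor, long clips would fade to a few percent of normal
amplitude, which a rater would score as halting rather than decrement,
and which no velocity-based end-detector could distinguish from rest.
Severity levels are statistically separable but overlapping — the
regime in which ordinal modeling is worth doing.

Raters are additive-bias-plus-noise: rater r scores
`clamp(round(s + bias_r + ε), 0, 4)` with `bias_r ~ N(0, 0.2)` fixed per
rater across the cohort and `ε ~ N(0, 0.15 + 0.07·complexity)` — the
simplest mechanism that produces both a complete/majority/none mixture
and dispersion growing with task complexity. Cohorts draw an integer OFF
severity per patient from a configurable distribution (default roughly
symmetric over 0–4, mode at moderate severity, matching a
surgery-evaluation population), and the ON severity is
`max(0, OFF − 1 + N(0, 0.3))`: a mean one-class dopaminergic improvement
with patient-level response variability.

Passing tests on this generator show that the pipeline recovers what the
generator encodes — monotone severity→kinematics mappings, a
complexity→dispersion mechanism, a medication effect. They do not show
robustness to what the generator omits: perspective and camera motion,
occlusion-correlated keypoint failures (missingness here is independent),
estimator-specific bias, tremor superimposed on voluntary movement,
within-task fatigue beyond the programmed decrement, or rater drift over
time. Results on synthetic cohorts are mechanism checks, not clinical
performance claims — the printed clinical accuracy tables of video-based
scoring systems require their private datasets and are out of scope here.

## Problem sizes and determinism

The shipped evaluation protocol is patient-grouped: patients (not clips)
are split 80/20 into training and held-out groups, preventing leakage of
a patient's other clips across the split, and one model is trained per
task. The default recovery experiment uses a 63-patient single-task
bilateral cohort — 200 training and 52 held-out clips at the full
training schedule (100 epochs) — which trains in about two minutes on
one CPU; the consensus experiment uses 400 panels per task. All
randomness flows from explicit integer seeds: cohort seeds derive
per-clip seeds, model seeds drive initialization and batch shuffling,
and repeated runs are bit-identical.

## Limitations

2D keypoints only (depth-dependent cues are invisible); no pose
estimation itself; the two optional task-specific feature slots are
interface-only; `t_pull` detection is a heuristic fallback when no
annotation exists; the rater model is additive and symmetric, with no
ordinal response styles (end-aversion, halo effects); and the ablation
harness reproduces the *design* of branch-ablation comparisons, not any
published ablation numbers.
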