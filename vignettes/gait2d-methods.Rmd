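---
title: "Markerless 2D gait analysis with gait2d: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless 2D gait analysis with gait2d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gait2d)
```

## What the package computes

gait2d turns per-frame 2D pose keypoints from a side-mounted camera into
spatiotemporal gait parameters and sagittal joint kinematics, and provides
the statistics battery used to validate one motion-capture system against
another. The processing chain is:

1. **Keypoint I/O** — per-frame JSON files in the BODY_25 dialect of the
   OpenPose estimator, or a long-format CSV. Points whose detection
   confidence is below a validity threshold (default 0.3) are treated as
   missing; interior gaps of at most 5 frames are filled by linear
   interpolation, longer gaps invalidate any overlapping gait cycle. An
   optional 4th-order zero-phase Butterworth low-pass (default cutoff 6 Hz)
   smooths each coordinate; both thresholds are exposed because the
   upstream estimator's error characteristics vary between setups.
2. **Camera geometry** — observed pixels are undistorted through the
   Brown–Conrady model (fixed-point inversion of the forward model, to
   1e-8 px), perspective-corrected by a supplied homography, and scaled to
   metres by a pinhole model at a fixed camera-to-path depth (default
   1.5 m) with the centre of the lens 0.805 m above the walking surface.
   The package consumes calibration parameters; it never estimates them
   from images. A per-frame rail offset column supports a camera that
   tracks the subject along a guide rail; the default is a static camera.
3. **Gait events** — the cycle start is the instant the ankle passes under
   the hip moving forward (the mid-swing crossing of
   `x_ankle - x_hip = 0`), sub-frame localised by linear interpolation.
   This crossing defines phase 0 of the normalised 0–100% cycle on which
   all peak phases are reported. Heel contacts are local minima of heel
   height that coincide with a drop of the heel's forward velocity below a
   fraction of its cycle maximum (see *Design choices*).
4. **Kinematics** — the hip angle is the signed angle of the thigh
   (hip→knee) against the laboratory downward vertical, flexion positive;
   the knee angle is 180° minus the interior angle at the knee, zero at
   full extension; the trailing limb angle (TLA) is the angle of the
   hip→big-toe line against the vertical, positive when the limb trails.
   Angle series are resampled to 101 points per cycle by linear
   interpolation, and peaks, peak phases (ties to the earliest sample) and
   ROM (= flexion peak − extension peak) are read off the resampled
   waveform without parabolic refinement, keeping the computation
   deterministic and tied to the normalisation everything else uses.
5. **Spatiotemporal parameters** — stride time is the cycle duration;
   stride length is the forward heel displacement between consecutive
   ipsilateral contacts; step length the forward distance from an
   ipsilateral to the next contralateral contact position; gait speed the
   forward mid-hip displacement divided by the stride time. Gait speed is
   deliberately *not* stride length over stride time: the two-system
   reference tables this package cross-checks against are not consistent
   with that ratio, implying an independent speed computation, and the
   mid-hip displacement is the natural one.
6. **Agreement statistics** — Shrout–Fleiss ICC forms (1,1)…(3,k) from the
   two-way ANOVA mean squares, with F-distribution confidence intervals
   (the absolute-agreement forms use the Satterthwaite approximation);
   Cronbach's alpha; the validity regression of the reference system on
   the candidate; and Bland–Altman analysis with fixed bias (mean of
   reference − candidate, t-based CI), 95% limits of agreement
   (bias ± 1.96 SD) and proportional bias (OLS of differences on pairwise
   means).

### Hip angle reference

Only hip and knee keypoints exist in a 2D keypoint set, so the hip angle is
measured against the laboratory vertical rather than a pelvis segment.
Marker-based systems that define the hip against a moving pelvis will
therefore differ systematically, particularly in hip flexion; this is a
documented convention difference, not an error, and it is one reason
hip-angle agreement between such systems is weaker than knee-angle
agreement.

## The synthetic walker

Because raw two-system recordings of this kind are not publicly
deposited, verification rests on a ground-truthed kinematic walker
(`walker_config()`, `generate_trial()`). The walker is a planar linkage:
the pelvis advances at `stride_length / stride_time`; each leg is driven by
periodic hip and knee waveforms with a 50% phase offset between sides;
heel and toe ride on a rigid foot attached to the shank with a constant
pitch offset. Segment lengths use standard anthropometric fractions of
stature (thigh 0.245 H, shank 0.246 H, foot 0.152 H, hip height 0.530 H,
ankle height 0.039 H), and the walker is placed vertically so the heel's
lowest point over the cycle lies on the walking surface.

Waveforms are built from peak constraints: each joint's flexion and
extension targets (value and phase) become knots of a periodic C1 curve
made of half-cosine segments, which attains every knot value exactly with
zero slope, so the configured peaks are the true peaks. Two further
constraints make the walker self-consistent:

* the knee waveform receives one extra interior knot at phase 0 whose
  value is solved from the leg geometry so that the ankle sits exactly
  under the hip at phase 0 moving forward — the phase convention of the
  peak targets and the event detector's cycle anchor then coincide by
  construction;
* the constant foot pitch is calibrated by root finding so that the
  implied TLA waveform peaks at the configured target.

Default targets are the comfortable-walk pooled means of the two-system
validation cohort the package emulates (stride 1399.2 mm / 1.016 s, hip
+31.7° at 12.5% / −13.7° at 70.9%, knee 65.6° at 90.9% / 6.2° at 57%, TLA
23.6°); `condition_preset()` supplies the maximum-speed and tandem
variants. Cohorts draw per-subject parameters around these presets with
the published between-subject SDs, truncated at ±2 SD and rejected if the
drawn targets give an infeasible linkage. Observation noise is Gaussian
pixel jitter plus uniform dropout applied to the projected keypoints, and
every generator is a pure function of its configuration and seed.

**What the walker does not emulate.** Pose-estimator error is not Gaussian
in real footage (it is heavy-tailed, temporally correlated and worst at
occlusions), the foot does not articulate during stance, double support is
not modelled, stride length and joint sweep are drawn independently
(the reference tables give no correlations), and the tandem condition is
represented only through its parameter preset — no lateral foot placement,
which a sagittal pipeline cannot see anyway. Passing recovery tests on the
walker therefore demonstrates that the pipeline's geometry, event logic
and summaries are correct and unbiased under jitter; it does not
demonstrate robustness to real markerless-estimation artefacts.

## Design choices and numerical conventions

* **Image conventions.** Pixel origin top-left with v downward; world x is
  the direction of progression and y is up with 0 at the floor. Stitching
  of a two-field camera reduces to adding a constant vertical offset to
  lower-field points.
* **Crossing rule.** "Ankle under the hip" is operationalised purely as
  the sign change of the horizontal offset; vertical proximity is not
  tested, since in the sagittal plane the forward crossing is the
  measurable event. An exact-zero sample is taken as the crossing time.
  Crossings closer than 0.4 s are merged; cycle durations outside
  [0.4, 2.5] s are invalid. These bounds bracket the reference cohort's
  stride times (0.86–1.10 s means) with wide margins.
* **Heel-contact gate.** The detector accepts a heel-height minimum as a
  contact when the heel's forward velocity drops below `vel_frac` of its
  cycle maximum within 0.1 s. The default is `vel_frac = 0.2`: across
  cohorts drawn with the published between-subject SDs the heel of a
  kinematically extreme but legitimate walker moves at 11–15% of its
  cycle-maximum velocity at the height minimum (stride length and joint
  sweep are drawn independently), and a 10% gate silently discards 6–11%
  of otherwise valid cycles. At 0.2 the yield is complete over the test
  cohorts while swing-phase minima (≥ 45% of cycle max) remain firmly
  rejected. Setups with cleaner stance behaviour can tighten the
  parameter.
* **Difference directions.** Per-system mean tables report
  candidate − reference; Bland–Altman bias is reference − candidate. Both
  are explicit in argument order and labelled in every output, since the
  published tables this package cross-checks use both conventions.
* **LR pooling.** The pooled mean is the unweighted mean of the two side
  means (validated against the reference tables); the pooled SD is taken
  over all cycles of both sides.
* **Classification bands.** ICC: poor < 0.5 ≤ moderate < 0.75 ≤ good
  < 0.9 ≤ excellent; all bands left-closed because the verbal definitions
  are ambiguous at the boundaries. The correlation band description in the
  source literature reads "greater than zero" for large; this is treated
  as the conventional 0.5 (Cohen) and documented here.
* **ICC forms.** Formulas follow the Shrout–Fleiss conventions;
  average-measures variants are the reporting default. For two raters
  Cronbach's alpha equals ICC(3,k) exactly, a property the test suite
  checks to 1e-10 over 1000 random matrices.
* **Missing data.** Listwise deletion per parameter with the retained n
  reported. No multiple-testing correction is applied (matching the
  emulated analysis); all tests are two-sided at alpha 0.05.
* **Smoothing.** The zero-phase pass runs a 2nd-order Butterworth forward
  and backward over each contiguous complete run, with odd (mirror)
  padding long enough for the filter transient to decay below 1e-11, which
  makes the filter exactly linear in the input — a property the tests
  exploit (constant offsets commute) and sloppy padding would break.
  `cutoff_hz = NULL` disables smoothing; it is off by default in
  `extract_trial()` because the synthetic fixtures are already band
  limited.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run: single trials of 4 strides
per side at 60 Hz for recovery checks; 30 jittered trials (≈ 230 cycles)
for the noise-bias check; cohorts of 2–10 subjects for the end-to-end and
determinism checks; n = 200 subjects for ICC calibration; 500 replicates
for regression-CI coverage; and 1000 random matrices for the alpha/ICC
identity. These sizes were chosen so every sampling check sits well inside
its tolerance band while the whole battery stays quick to run on one CPU.

## Known limitations

* The frontal-plane module provides stature-based scaling and path-offset
  estimation only; no frontal kinematics.
* Toe-off detection, stance/swing sub-phases, cadence, step width and
  double-support time are out of scope.
* The moving-rail camera is supported only through an externally supplied
  per-frame rail offset; no encoder model is estimated.
* The homography is consumed as a matrix; the mapping from camera
  elevation/tilt angles to that matrix is the caller's responsibility.
* Published headline ICC/regression values for real cohorts depend on
  human data that are not publicly available; the package reproduces the
  published tables' internal arithmetic and validates its estimators
  against known-truth simulations instead.
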