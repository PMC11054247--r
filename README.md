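# gait2d

Markerless 2D gait analysis from pose keypoints, with the full
method-comparison statistics battery used to validate one motion-capture
system against another.

## The problem

Clinical gait analysis with marker-based 3D systems (the Vicon class) is
accurate but expensive and burdensome: dozens of reflective markers,
laboratory visits, repeated trials. Markerless alternatives run a pose
estimator (OpenPose-style, BODY_25 keypoint layout) on ordinary video and
derive gait parameters from the estimated joint positions. Before such a
system can be used clinically its output must be shown to *agree* with the
established standard — not just correlate with it. gait2d implements both
halves of that problem for sagittal-plane level walking:

* the **measurement pipeline**: per-frame keypoints → lens undistortion and
  perspective correction → metric real-space coordinates → gait-cycle
  events → spatiotemporal parameters and hip/knee/trailing-limb kinematics;
* the **agreement battery**: intraclass correlations, Cronbach's alpha,
  validity regression and Bland–Altman analysis.

It is aimed at movement scientists and engineers building or validating
2D gait systems, and at anyone who needs a tested, ground-truthed
reference implementation of these computations.

## The core methods

**Gait cycle.** A cycle starts when the ankle of the observed limb passes
from behind to in front of the hip joint centre in the sagittal plane
(the mid-swing crossing of $x_{ankle}(t) - x_{hip}(t) = 0$, rising),
localised below the frame interval by linear interpolation, and is
normalised to 0–100%. Heel contacts are heel-height minima coinciding with
a drop of the heel's forward velocity. Per cycle the package computes
stride time, stride length and step length (heel-to-heel, mm), gait speed
(forward mid-hip displacement / stride time, m/s), peak flexion/extension
angles with their phases, ROM, and the trailing limb angle (TLA).

**Pixels to metres.** Brown–Conrady undistortion
$x_d = x_u(1 + k_1 r^2 + k_2 r^4 + k_3 r^6) + \text{tangential}$ inverted
by fixed-point iteration, a projective correction $H$, then pinhole
scaling at the camera-to-path depth $Z$:
$x = (u - c_x)\,Z/f_x$, $y = h_{lens} - (v - c_y)\,Z/f_y$.

**Agreement.** For an $n \times k$ subjects-by-systems matrix the two-way
ANOVA mean squares give the Shrout–Fleiss forms, e.g.
$\mathrm{ICC}(3,k) = (BMS - EMS)/BMS$ and
$\mathrm{ICC}(2,k) = (BMS - EMS)/(BMS + (JMS - EMS)/n)$, with
F-distribution 95% CIs; Cronbach's
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_j s_j^2 / s_{tot}^2\bigr)$;
Bland–Altman bias $\bar d$ ($d$ = reference − candidate), limits of
agreement $\bar d \pm 1.96\,s_d$, and proportional bias from the OLS of
$d$ on the pairwise means.

**Synthetic walker.** A planar linkage with anthropometric segment lengths
whose hip/knee waveforms are periodic cosine-segment curves hitting
configurable peak/phase targets exactly; the knee waveform is additionally
constrained so the ankle passes under the hip exactly at phase 0, and the
foot pitch is calibrated so the TLA peak hits its target. Every generated
trial carries exact ground truth, which is what the test suite measures
the pipeline against.

## Worked example

```r
library(gait2d)

# a ground-truthed synthetic trial: comfortable walking, 1 px keypoint jitter
cfg   <- walker_config(noise_px = 1, seed = 42)   # stride 1399.2 mm / 1.016 s
trial <- generate_trial(cfg)
ex    <- extract_trial(trial$side)
head(ex$results[, c("side", "cycle", "stride_time_s", "stride_length_mm",
                    "gait_speed_mps", "hip_flexion_peak", "tla_peak")], 4)
#>   side cycle stride_time_s stride_length_mm gait_speed_mps hip_flexion_peak tla_peak
#> 1    L     1         1.015             1396          1.378            31.84    23.44
#> 2    L     2         1.015             1402          1.377            31.87    23.64
#> 3    L     3         1.015             1397          1.378            31.65    23.55
#> 4    L     4         1.017             1404          1.375            31.74    23.56
```

Each row is one gait cycle: the configured stride (1399.2 mm, 1.016 s,
1.377 m/s) and hip flexion peak (31.7°) are recovered to a few mm, ms and
tenths of a degree under jitter.

```r
# two systems measuring 20 subjects: known truth, one system reads 14 mm low
ts <- generate_two_system(20, mu = 700, sigma_subject = 45, sigma_error = 12,
                          biases = c(0, -14), seed = 7)
icc(ts$matrix, "3,k")
#> ICC(3,k) = 0.985 [0.961, 0.994] (excellent), F(19,19) = 65.57, p = 2.01e-13, n = 20
bland_altman(ts$matrix[, 1], ts$matrix[, 2])
#> bias = 13.904 [7.149, 20.658] (p = 0.000379), LoA [-14.383, 42.190],
#> prop: y = -0.099x + 84.855 (p = 0.0787), n = 20
```

The consistency ICC is excellent (an additive offset does not reduce it),
while the Bland–Altman bias exposes the built-in 14 mm systematic
difference — the two statistics answering different validation questions.

A thin CLI wraps the same functions
(`inst/cli/gait2d simulate|extract|compare`).

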