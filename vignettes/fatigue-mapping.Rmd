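---
title: "Methods: rule-based visitor fatigue quantification from keypoint streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based visitor fatigue quantification from keypoint streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguemap)
```

## The model

Museum fatigue — the combined physical and cognitive load that builds up
during a long visit — shows up behaviorally as *compensatory postures*:
unconscious load-relieving configurations of the body. `fatiguemap`
operationalizes three of them from 2-D skeletal keypoints (COCO-17, as
produced by bottom-up human pose estimators):

* **squatting** — pronounced lowering of the center of mass, unloading the
  lower limbs;
* **hands-on-hips (akimbo)** — a hand-supported trunk posture easing the
  lumbar muscles;
* **single-leg raise** — intermittent load transfer to one leg.

All geometry lives in image coordinates (origin top-left, y increasing
downward); the package fixes this convention once and defines every
vertical comparison against it. Coordinates are made dimensionless by the
frame width W and height H, and by the shoulder width where an
individual-scale normalizer is needed, so the rules transfer across camera
resolutions and viewpoints.

### Per-frame rules

With hip/knee/ankle midpoints and interior joint angles (the angle at the
middle joint; a straight limb is near 180°, flexion is 180° minus the
interior angle), the per-frame classifiers are:

* **Squat**: vertical displacement ratio
  $\delta = (\bar{y}_{hip} - \bar{y}_{knee})/H > 0.10$ and knee interior
  angles below 120°. A standing figure has $\delta < 0$ under the y-down
  convention; the rule asks for the hip midpoint to sit well below the
  knee midpoint. The default requires *both* knees below the threshold;
  `squat_knee_mode = "min"` switches to the weaker one-knee reading, which
  is an equally defensible reading of the rule set — both are provided and
  the strict one is the default. The narrative "knee angle below 90°"
  description of a deep squat is treated as informal and not implemented.
* **Akimbo**: shoulder-width-normalized wrist–hip offset
  $\eta = |x_{wrist}-x_{hip}|/W_{shoulder} \in (0.30, 0.45)$ on both
  sides, elbow interior angles in (80°, 120°), normalized torso length
  $\tau \in (0.3, 0.7)$, and hip above wrist on each side
  ($y_{hip} < y_{wrist}$, y-down). $\eta$ uses the absolute offset: a
  signed version would be systematically negative on one body side.
  $\tau$ is the distance from the neck to the hip midpoint over H; since
  COCO-17 has no neck landmark, the shoulder midpoint is the neck proxy.
  The hip/wrist order check is anatomically debatable (it places the hips
  above the wrists in the image); it is implemented literally behind the
  `enforce_hip_wrist_order` flag, on by default.
* **Leg raise**: some knee interior angle in (70°, 130°) while the
  contralateral (support) knee flexion stays ≤ 15°, and ankle separation
  $\gamma = |x_{la}-x_{ra}|/W > 0.05$. The raised-leg bound applies to the
  interior angle and the support-leg bound to flexion: that mixed
  convention is the only one under which a one-leg stance can satisfy all
  three criteria simultaneously.

All interval conditions are strict (open intervals), matching the printed
inequality signs: boundary values such as $\eta = 0.30$ or
$\gamma = 0.05$ do not detect. Frames are evaluated for a posture only
when every joint that posture needs is detected with confidence at least
`conf_min` (default 0.3, a common operating point for bottom-up
estimators); this validity gate prevents misclassification under partial
occlusion. Degenerate geometry (coincident joints, zero shoulder width)
raises an error in the individual geometry operations but counts as a
non-detection inside the combined classifier `detect_pose()`, which
evaluates the three detectors in fixed priority order
SQUAT > AKIMBO > LEG_LIFT.

### Temporal confirmation and scoring

A posture accrues credit only after persisting m = 5 consecutive frames.
The implementation follows the counter semantics: the counter resets on
any break or label switch, and frame t carries a confirmed label only when
its run has reached length m at t — so a run of length L contributes
max(0, L − m + 1) confirmed frames and the first m − 1 frames of even a
long run are never counted. The alternative reading (back-crediting a
whole run once confirmed) is *not* implemented; consequently "six seconds
of confirmed squat" requires a raw run of 184 frames at 30 fps, and all
worked examples in the tests are stated in confirmed time.

Confirmed durations $f_i$ (in seconds, $f_i = \text{frames} \times
\Delta t$) are combined into the raw score
$F = \sum_i w_i f_i$ with weights $(w_{squat}, w_{akimbo}, w_{leg}) =
(0.5, 0.2, 0.3)$ — a 5:3:2 intensity ordering over squat > leg raise >
hands-on-hips, normalized to sum to one. The score is min–max normalized,
$S_v = \mathrm{clamp}((F - F_{min})/(F_{max} - F_{min}), 0, 1)$ with the
pilot-calibrated $F_{min} = 0$, $F_{max} = 20$ weighted seconds, and the
visitor is flagged fatigued when $S_v \ge \gamma = 0.15$ (the comparison
is inclusive: $F = 3.0$ weighted seconds normalizes to exactly 0.15 and
flags). $F_{max}$ carries no published unit; weighted seconds is the
natural unit of F and is adopted throughout. A second normalization mode
(`norm_mode = "window"`) scales by $\max_i w_i \cdot T_{win}$, the
largest score attainable in an observation window — the two printed
normalizations disagree, and the fixed pilot scale is the default because
the decision threshold was calibrated against it.

### Zone aggregation

The exhibition plan is partitioned into polygonal analysis units. For unit
i, $N_{t,i}$ counts unique visitors with at least one frame in the unit
and $N_{f,i}$ those flagged fatigued *on their zone-restricted
subsequence*: the keypoint stream is filtered by zone and the whole chain,
including confirmation, is re-run. A confirmed-length run split by a zone
boundary therefore re-confirms within each side, and fatigue does not
carry over between zones — a modeling choice the aggregation rule implies
but does not discuss; it is adopted literally. The Fatigue Index
$FI_i = N_{f,i}/N_{t,i} \in [0,1]$ is banded low/medium/high. The printed
bands (0.00–0.33, 0.34–0.66, 0.67–1.00) leave two-decimal gaps; the
package uses the continuous closure low $[0, 1/3]$, medium $(1/3, 2/3]$,
high $(2/3, 1]$, which agrees with the table at two-decimal resolution
and is total. Empty zones report FI = 0 with an explicit `empty` flag and
are excluded from museum-wide means.

Pre/post-intervention comparisons follow the percentage-point convention
(100·ΔFI): a drop from 0.6000 to 0.3611 is a 23.89 % decrease in that
convention. `relative_change()` provides the separate before/after
percent convention used for image-metric improvements.

## Camera coverage planning

Coverage is evaluated in 2-D plan view: mounting height is folded into the
effective observation radius, and each grid cell is atomic — covered or
not at its center. A cell is visible to a camera when its center lies
within the radius (closed), inside the symmetric angular wedge of half the
field of view about the heading (closed; fields of view are constrained to
90–120°), and the camera-to-center sightline crosses no occluder edge.
CAP is the percentage of cells seen by at least r selected cameras
(redundancy r; its on-site value is not published, so r is a parameter)
and UAP = 100 − CAP; both use exact rational arithmetic on cell counts.

The published deployment evaluates every camera combination; no selection
algorithm is named. The package provides both: `exhaustive_plan()`
enumerates subsets (guarded at $2^{20}$) and is the small-instance
optimality oracle; `greedy_plan()` selects by maximal marginal gain in
r-covered cells with deterministic lowest-id tie-breaks. At r = 1 the
objective is submodular, so greedy CAP is within $(1 - 1/e)$ of the
optimum — verified against the exhaustive oracle in the tests. The
site-reported CAP of 93.11 % depends on the building's unpublished 3-D
model and is out of reach at desk scale; only its arithmetic complement
(UAP 6.89 %) is reproduced.

## Frame-quality metrics and gating

Four sharpness/contrast measures are defined with population (1/N)
normalization, a 4-neighbor Laplacian kernel, the standard 3×3 Sobel pair
and replicate borders (operators are named in the source material but
kernels and border policy are not; these are the package's concrete
choices): Laplacian variance, mean Sobel gradient magnitude, Tenengrad
(mean squared magnitude) and RMS contrast. All four are exactly zero on
constant images and decrease monotonically under box blur. The color-cast
index D = max(R̄,Ḡ,B̄) − min(R̄,Ḡ,B̄) is computed over a region expected to
be neutral white, on the 8-bit scale.

The risk gate fuses five under-specified frame features; the package
fixes deterministic definitions — DCT high-frequency energy ratio
(orthonormal 2-D DCT-II, energy outside the lowest-frequency quadrant),
local-contrast variance (per-window RMS over a 16-px grid), Laplacian
variance, global channel-mean spread, and inter-frame Pearson
correlation — z-scores them against calibration statistics that must be
supplied or fitted on a clip (no hidden defaults; the reference
population and weights are not published), fuses linearly and routes each
frame once: BYPASS at or above the threshold, ROBUST below. The
deblurring and low-light enhancement networks themselves are external
components behind a command-template interface; they are not
reimplemented.

## The synthetic generator

`pose_figure()` builds a canonical stick figure with anthropometric
segment ratios — torso at 0.35 H for standing figures, inside the (0.3,
0.7) plausibility band — and poses it to satisfy each detector's criteria
with explicit margins (defaults: squat δ = 0.2 with 100° knees; η = 0.375
with 100° elbows; raised knee 100° with 2° support flexion), or to
satisfy none (neutral stance). Margins are script parameters, so boundary
behavior is directly testable. `gen_track()` adds Gaussian keypoint
jitter and Bernoulli joint dropout after posing; every generator is a
pure function of its seed and restores the caller's RNG state.

`gen_population()` gives each visitor a supra-threshold squat budget
(F = 3.5 weighted seconds, safely above the 3.0 decision boundary) with
the zone's probability p, and a sub-threshold budget (F = 1.0) otherwise,
with run lengths extended by m − 1 frames so the confirmed time hits the
budget exactly: the binomial truth is unambiguous under confirmation-edge
effects, and the zone FI estimator can be validated against
$\sqrt{p(1-p)/n}$ sampling error.

What the generator does *not* emulate: pose-estimator error structure
beyond isotropic jitter and independent dropout (real estimators produce
correlated, pose-dependent errors and identity switches), perspective
foreshortening, multi-person occlusion, or re-identification noise.
Passing tests therefore demonstrate the correctness of the rule chain and
its statistics, not field-grade robustness on real footage.

## Problem sizes and numerical choices

The validation suites use the study's own conditions at desk scale:
framewise recovery on scripted tracks of a few hundred frames at 30 fps;
1,000 random label sequences against a direct counter trace; binomial FI
recovery with p = 0.6, n = 200 visitors per seed over 50 seeds; planner
cross-checks on random instances of up to 30 cells and 12 candidates with
budget 3, where exhaustive enumeration stays cheap. Ties in the planners
break deterministically (lowest camera id; fewer cameras first, then
lexicographic). Floating-point boundary cases in the posture rules are
exercised with exact-representable margins; CAP/UAP identities hold
exactly because they are ratios of integer cell counts.

## Known limitations

* The rule thresholds are fixed operating points; no per-individual
  adaptation or physiological calibration (EMG, heart rate) is included.
* Cross-frame identity comes from the input stream; the package does no
  tracking or re-identification.
* Zone geometry lives in floor-plan meters; the camera-to-plan projection
  must be supplied as a per-camera homography.
* Coverage is planar; cameras and occluders with meaningful vertical
  extent are only approximated by the effective-radius fold-in.
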