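---
title: "Methods: camera-frame gait kinematics, cycle quality control and phenotyping"
author: "gaitsig"
output: rmarkdown::html_document
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`gaitsig` starts where a 3D pose estimator stops: with per-frame 3D positions
of seven lower-body landmarks (Root, left/right IAS, FLE, FAL) for a walking
trial, in millimetres, in the camera frame. From these it derives hip and
knee flexion-angle time series, normalizes them onto a common gait-cycle
grid, filters and corrects them with clustering, validates them against a
reference, and extracts interpretable markers of pathological (SCI) gait.
This vignette records the modelling choices, their rationale, and what the
accompanying synthetic experiments do and do not demonstrate.

## Included-angle convention

All four channels (`LHip`, `RHip`, `LKnee`, `RKnee`) are *included* angles:
for the knee, the angle between the vector from FLE to IAS and the vector
from FAL to FLE; for the hip, the analogous Root–IAS–FLE construction. The
arccosine maps into [0°, 180°], so 0° is a fully extended chain and there is
no signed hyperextension. We adopt this convention deliberately: it is
computable from any three points without an anatomical coordinate system,
which is exactly what a monocular pose estimator provides, and it keeps the
pipeline in the camera frame (world-frame conversion would add a root-joint
alignment step and its error). The cost is that flexion direction is not
distinguished from (rare) hyperextension; all downstream statistics inherit
this.

Degenerate inputs are rejected rather than patched: coincident landmarks
raise an error (`three_point_angle`), frames missing a landmark are dropped
and logged, never imputed, and a trial with fewer than 4 valid frames is
refused. The arccosine argument is clamped to [−1, 1] to absorb rounding.

## Time normalization

Trials differ in frame count (walking speed, camera frame rate), so every
angle series is mapped to 101 samples at cycle positions 0–100%. Two methods
are provided and selectable:

* `linear` (default): piecewise-linear interpolation at the 101 positions.
  It is exact for already-101-sample input and for linear segments, and is
  used for both up- and down-sampling.
* `block_average`: frames are assigned to their nearest cycle percent and
  averaged within each bin; empty bins are filled by linear interpolation
  between neighbouring non-empty bins. This is the "average the frames"
  flavour of downsampling; whether averaging should use fixed-size blocks or
  nearest-percent bins is a genuinely open choice — we use bins because they
  remain well-defined for any input length, including upsampling.

# The synthetic cohort: what it emulates

Clinical keypoint recordings of SCI gait are not publicly available, so the
generator (`generate_cohort`) defines the study conditions under which every
claim in this package is tested:

* **Template.** Left hip flexion is a raised cosine
  (mean 25°, amplitude 20°); left knee flexion is the sum of two periodic
  Gaussian bumps (18° at 15% of the cycle, width 0.08; 60° at 72%, width
  0.10); the right side lags by half a cycle. These values produce curves
  with the qualitative shape and magnitudes of normative sagittal gait. The
  hip mean is set to 25° rather than a smaller value so that the full cosine
  excursion stays strictly inside the representable [0°, 180°] range of the
  included-angle convention — a template that dips below 0° could not be
  rendered and recovered exactly, and would violate the angle-series
  contract.
* **Pathology.** SCI trials rescale each channel's range of motion (ROM)
  about its minimum by a factor of 0.5 by default: reduced peak flexion with
  an unchanged baseline, which is the qualitative SCI signature (reported
  clinical reductions cluster around 44–56%, hence a default scale of 0.5).
  The scaling is exact by construction, giving the parameter-recovery
  experiments a sharp ground truth.
* **Acquisition.** 40 trials per class; 60–250 frames per trial at 50 Hz;
  additive Gaussian angle noise (SD 2°, clamped to [0°, 180°]); keypoint
  noise (SD 2 mm); a smooth, endpoint-preserving timing warp (SD 0.02 cycle
  fractions) for inter-trial speed variability; and a 30% fraction of
  direction-reversed trials, rendered by rotating the skeleton half a turn
  about the vertical axis and swapping the left/right landmark labels — the
  recording artifact in which a subject crosses the field of view the other
  way. The 30% rate reflects that flip-corrected subsets in clinical
  practice grow substantially when reversed trials are recovered.
* **Rendering.** A planar sagittal forward-kinematics model places the
  skeleton so that the included angles reproduce the requested channels
  *exactly* (machine precision) for any angles in [0°, 180°]. This closes
  the loop: `compute_angle_series(forward_kinematics(A)) = A` within 1e-6°
  in the noiseless case, which the suite verifies over random templates.

What the generator does **not** emulate: pose-estimator error structure
(depth-dependent, temporally correlated, occlusion dropouts), asymmetric or
compensatory SCI waveforms beyond ROM scaling, multi-cycle trials needing
segmentation, and camera projection. Passing tests therefore demonstrate
correctness of the pipeline's algorithms under controlled conditions, not
clinical performance; the clinical accuracy figures of markerless gait
analysis cannot be reproduced without the original videos.

# Pose benchmarking

`procrustes_align` computes the closed-form similarity alignment: both point
sets are centred, the rotation comes from the SVD of the cross-covariance
with the standard sign-flip correction restricting the solution to proper
rotations, and the scale is the analytic ratio of traces. Reflections are
excluded on purpose — a mirrored fit would silently exchange anatomical left
and right, which is precisely the artifact the pipeline elsewhere detects
and corrects. Rank-deficient configurations (fewer than 3 landmarks,
collinear markers) are errors, not warnings. PA-MPJPE is computed per frame
by default, matching per-frame benchmark reporting; a per-trial alignment
mode is available. Frames invalid in either trajectory are excluded from
scoring but counted in the totals, mirroring detected-frame bookkeeping.

# Cycle quality control

Clustering uses plain Euclidean k-means on the flattened 4×101 matrices with
k-means++ seeding, at most 100 Lloyd rounds, and deterministic behaviour
under a seed. Channels are not standardized: all four share degree units and
rescaling would distort the relative weight of hip vs knee excursions.
Clusters that empty during iteration are re-seeded from the point farthest
from its centroid. k = 5 per class is the default, an empirical choice for
separating representative cycles, mirrored cycles and noise; it is a
parameter, not a fitted quantity.

Reversed-trial handling resolves a real ambiguity. A mirrored recording
swaps the left/right channels of the recovered angles; with a half-cycle
left/right phase offset this is indistinguishable from a half-cycle time
shift. We implement the correction as a left/right channel swap (the
interpretation consistent with moving trials "from one side to the other");
a time-reversal mode exists behind a flag for the alternative reading.
Detection compares each cluster centroid, after channel swap, with the
reference centroid (Pearson r > 0.9 and greater than the unswapped
correlation). Because a fully mirrored cohort is internally symmetric, the
reference orientation itself is anchored by majority: if mirrored clusters
hold more trials than the reference orientation, the anchor moves
(`resolve_orientation`). This assumes reversed recordings are the minority,
which is what the acquisition artifact implies; at the default 30% reversal
rate and 40 trials per class the majority is correct with overwhelming
probability, and the suite verifies detection precision and recall ≥ 0.95
under those conditions.

Typical-cluster selection (summed centroid ROM × cluster size) is a
documented heuristic standing in for an empirical manual choice; an explicit
override is always available and takes precedence.

# Validation statistics

The DTW distance is the classic unconstrained dynamic program with steps
{(i−1,j−1), (i−1,j), (i,j−1)} and absolute-difference (univariate) or
Euclidean (multivariate) pointwise costs, implemented in C++ for the
permutation test's ~10⁵ evaluations; backtracking prefers the diagonal on
ties, making paths deterministic. The distance is unnormalized by default
(path-length normalization is a flag). Per-joint univariate DTW is the
default granularity.

The permutation test shuffles the comparator series' time order (jointly
across channels) and reports p = (1/N)·Σ 1(D⁽ᵏ⁾ ≤ D_obs) with N = 8000 by
default. Shuffling one side suffices: under the null of no temporal
correspondence the comparator is exchangeable with its shuffles. The literal
estimator can return p = 0; an add-one smoothing option exists but is off by
default to match the plain formula. Under an iid white-noise null the test
is calibrated — the suite checks the empirical size of 500 replicates
against the 99% binomial band around 0.05.

Pearson r follows the covariance formula with a t-based two-sided p-value on
n − 2 degrees of freedom; zero-variance inputs are an error rather than
r = 0, because a silent zero would masquerade as evidence of no association.

# Phenotyping, classification and attribution

The interpretable classifier is nearest-centroid with per-class mean
centroids ("k-means classifier" in the unsupervised-learning sense), with
exact ties broken to the first label in sorted order. ROM reduction is
100·(ROM_ref − ROM_case)/ROM_ref on the class centroids — relative to the
reference class, which is the natural clinical reading of "percent
reduction". Undefined classification ratios (empty denominators) are
reported as NA, never as 0.

The supervised model is a single-hidden-layer MLP (width 100, ReLU,
inverted dropout 0.2, Adam at 1e-3, 300 full-batch iterations, logistic
output), trained on standardized flattened cycles with a stratified 25%
held-out split for honest metrics. The width-100 reading of an ambiguous
"100 hidden layers" architecture description is deliberate: hundreds of
stacked layers cannot be meaningfully trained in 300 iterations, while a
hidden *size* of 100 is the common default it matches. Width, depth-adjacent
settings, dropout and learning rate are all exposed in `mlp_config`.

Shapley attribution uses permutation sampling over the 404
(channel × cycle-percent) features: each of `n_samples` (default 512) draws
samples a feature ordering and a background cycle, switches the explained
instance's features in one at a time, and credits each output change to the
switched feature. Exact enumeration over 2⁴⁰⁴ coalitions is infeasible; the
sampling estimator is unbiased and, with the baseline defined as the mean
model output over the drawn backgrounds, *exactly* additive by telescoping —
the suite asserts the additivity gap is far below 1% of the output range.
Significant windows are contiguous runs of |attribution| above
mean + 2·SD of all absolute attributions, ranked by total absolute mass;
this explicit rule stands in for the unstated criterion behind
bounding-box attribution plots, and the threshold is overridable.

# Problem sizes and numerical tolerances

The shipped experiments use 40 + 40 trial cohorts, 500-replicate calibration
runs at 200 permutations, 200 enumeration checks for DTW, and 20 seeded
localization runs at 512 Shapley samples — sizes chosen so the full suite
completes in about two minutes while keeping Monte-Carlo bands narrow enough
for the stated thresholds. Key tolerances: forward-kinematics round trip
1e-6°, similarity invariance of PA-MPJPE 1e-9 mm, alignment residual vs a
generic optimizer 1e-6 mm, DTW vs enumeration 1e-10, ROM recovery ±5
percentage points at 2° noise.

# Known limitations

* No ankle angles: distal keypoints from monocular estimators are too
  unreliable for them, and the landmark set stops at the malleolus.
* Gait-cycle segmentation (heel-strike detection) is out of scope; trials
  are assumed to be single pre-segmented cycles.
* The included-angle convention cannot represent hyperextension as negative.
* The reversed/typical orientation anchor fails by design when mirrored
  trials are the majority *and* no external orientation information is
  supplied; the override path covers that case.
* Synthetic validation bounds algorithmic correctness only; clinical
  accuracy depends on the upstream pose estimator and cohort.
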