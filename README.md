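# gaitsig

Markerless gait kinematics, quality control and phenotyping for spinal cord
injury (SCI) research.

Clinical gait analysis after spinal cord injury traditionally requires a
marker-based motion-capture laboratory. Markerless 3D pose estimation from a
single camera promises the same kinematic read-outs — hip and knee flexion
over the gait cycle — outside the lab, but its output needs careful
post-processing before it is clinically usable: trials arrive at different
lengths and frame rates, some are recorded with the subject walking the
"wrong" way across the field of view (which silently swaps left and right),
and the derived angle signatures must be validated against motion-capture
references before any biomarker is trusted. `gaitsig` implements that whole
post-camera pipeline for researchers working with lower-body keypoint
trajectories (Root, left/right anterior superior iliac spine IAS, lateral
femoral epicondyle FLE, lateral malleolus FAL), plus a seeded synthetic gait
generator so every stage is testable without clinical recordings.

## What it computes

**Camera-frame flexion angles.** For each side, knee flexion is the included
angle of the IAS–FLE–FAL chain and hip flexion of the Root–IAS–FLE chain:

θ = arccos( a·b / |a||b| ),  with a = p_prox − p_mid, b = p_mid − p_dist,

so θ = 0° is a fully extended chain and θ ∈ [0°, 180°]. Angles stay in the
camera frame — no world-frame conversion is needed. Trials are then
time-normalized to 101 gait-cycle samples (0–100%).

**Pose benchmarking.** Predicted keypoints are scored against motion-capture
ground truth with the Procrustes-aligned mean per-joint position error

PA-MPJPE = (1/N) Σᵢ ‖Ŷᵢ − Yᵢ‖₂,

after the optimal similarity alignment (closed-form SVD solution, proper
rotations only), aggregated as mean ± sd (n) per stratum. A 20-marker
montage can be reduced to the 7 canonical landmarks by group averaging.

**Cycle quality control.** Normalized cycles are clustered per class with
k-means++ (default k = 5, 100 iterations). The typical cluster is selected by
a documented heuristic (summed centroid range of motion × cluster size,
anchored on the majority walking direction), mirrored clusters are detected
by correlating left/right-swapped centroids with the reference, and
direction-reversed trials are corrected by swapping the left/right channels —
yielding a smaller "typical" subset and a larger flip-corrected subset.

**Validation statistics.** Derived signatures are compared with a reference
via dynamic time warping, D(X,Y) = min_π Σ d(xᵢ, yⱼ); a permutation test,
p = (1/N) Σₖ 1(D⁽ᵏ⁾ ≤ D_obs) with N = 8000 shuffles; and the Pearson
correlation with a t-based p-value.

**Phenotyping and attribution.** Nearest-centroid classification of SCI vs
healthy cycles quantifies per-joint range-of-motion (ROM) reduction,
100·(ROM_ref − ROM_case)/ROM_ref; a small MLP (one hidden layer of 100
rectified units, dropout, Adam, 300 iterations) provides supervised
discrimination, and Monte-Carlo Shapley values attribute its decisions to
(channel, cycle-percent) features, which are merged into significant time
windows — candidate digital biomarkers.

## Worked example

```r
library(gaitsig)

cohort <- generate_cohort(cohort_config(n_per_class = 20, seed = 3))
report <- run_pipeline(cohort, pipeline_config(seed = 3,
                                               n_permutations = 500,
                                               shap_samples = 128))
print(report)
#> <phenotype_report> 40 trials (Healthy vs SCI)
#>   subsets: 15 typical, 29 after flip-correction (14 flipped)
#>   ROM reduction (% of reference): LHip=48.0 RHip=44.9 LKnee=49.1 RKnee=49.2
#>   centroid classifier accuracy: 1.000
#>   MLP held-out accuracy: 1.000
#>   top attributed window: RKnee 50-52% (increases-SCI-probability)

report$rom
#>   joint rom_reference rom_case reduction_pct max_flexion_diff
#> 1  LHip      40.62808 21.13016      47.99123         19.61462
#> 2  RHip      40.16173 22.13897      44.87545         18.96993
#> 3 LKnee      57.58656 29.33319      49.06243         28.47083
#> 4 RKnee      57.18223 29.03156      49.22976         28.46859
```

The cohort was generated with an SCI range-of-motion scale of 0.5, so the
recovered per-joint reductions near 50% confirm the pipeline end-to-end: the
14 direction-reversed trials injected by the generator were identified from
their mirrored cluster centroid and flip-corrected into the second subset,
the class centroids recovered the underlying templates, and the attribution
stage highlights the mid-cycle knee window that separates the classes.

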