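# gaitphase

Gait-phase clustering and clinical validation for foot-worn IMU data.

Standardized walk tests — four straight 10 m bouts separated by 180° turns —
are a staple of instrumented gait assessment in Parkinson's disease.
Spatio-temporal gait parameters are usually averaged over *all* straight
strides, which mixes steady-state walking with gait initiation, termination
and the transitions around turns. `gaitphase` implements the full analysis
chain needed to ask whether separating those gait phases sharpens the
clinical signal:

1. **Stride segmentation** — subsequence dynamic time warping (DTW) of a
   single-stride template against the medio-lateral gyroscope channel (GZ),
   with stride borders refined to local GZ minima and a file-driven
   correction interface replacing interactive editing.
2. **Turning isolation** — per foot, the stride turning angle
   `TA = ∫ GZ dt` (mid-stance to mid-stance); strides with `|TA| > 20°` are
   turning strides, and a gamma distribution fitted to the remaining `|TA|`
   extends the set to upper-tail strides adjacent to a detected turn.
3. **Constant / non-constant clustering** — each 10 m bout is split into
   steady ("constant") and non-steady strides by thirteen method variants:
   `N%crop` (N ∈ 5…25), and lower/upper thresholds on bout-normalized stride
   velocity or stride time from the median ± 5 %, a normal fit (mean ± SD),
   1-D k-means with K = 3 (extreme cluster centres), or the 25th/75th
   percentiles; a post-processor then enforces the
   acceleration → constant → deceleration ordering inside the first/last
   25 % of each bout.
4. **Gait parameters** — stride, swing and stance time from heel-strike and
   toe-off events; stride length, path length and toe clearance by
   gravity-corrected double integration between mid-stance samples with
   zero-velocity updates (ZUPT); sagittal heel-strike/toe-off angles; all
   lengths normalized by body height.
5. **Cluster aggregation** — per subject and gait cluster (baseline =
   all straight strides, constant, non-constant, turning): mean and
   coefficient of variation of each parameter, plus per-turn stride counts
   and durations.
6. **Clinical validation** — impaired vs unimpaired classification per gait
   cluster: stratified 60/40 split, balancing by undersampling, Fisher-score
   top-5 feature selection, SVM (linear / RBF) tuned by inner 5-fold
   cross-validated AUC over `C × γ` grids, and test-set ROC/AUC compared
   against the baseline cluster on identical splits.

Because raw patient recordings of this kind are generally not shareable, the
package includes a first-class synthetic generator (`generate_schedule()`,
`synthesize_imu()`, `generate_cohort()`) that emulates the 4×10 m protocol —
velocity ramps at bout boundaries, yaw pulses with exactly controlled
turning angles, ZUPT-consistent foot kinematics, and two-class cohorts with
configurable effect sizes — so every stage is testable end to end.

## Worked example

```r
library(gaitphase)

# simulate one subject's 4x10 m walk test and analyze it end to end
sched <- generate_schedule(seed = 42, time_jitter_cv = 0.04)
sim   <- synthesize_imu(sched, noise_sd = 1, seed = 42)
ana   <- analyze_subject(sim$left, sim$right, height_cm = 175,
                         methods = c("25%crop", "distr vel"))

table(ana$strides$`label_distr vel`)
#> acceleration     constant deceleration      turning
#>            8           51            5           24

ana$turns        # three turns per foot, pooled
#>   first last n_strides turning_time
#> 1     9   12         4     3.691406
#> 2    21   24         4     3.857422
#> 3    33   36         4     3.730469
#> ...

st <- ana$strides
st$label <- st$`label_distr vel`
feats <- subject_features(st, ana$turns)
round(feats[c("baseline.stride_velocity_mean", "constant.stride_velocity_mean",
              "non_constant.stride_velocity_mean", "constant.stride_time_cv",
              "turning.n_strides_mean", "turning.turning_time_mean")], 3)
#>     baseline.stride_velocity_mean     constant.stride_velocity_mean
#>                             0.606                             0.651
#> non_constant.stride_velocity_mean           constant.stride_time_cv
#>                             0.428                             0.091
#>            turning.n_strides_mean         turning.turning_time_mean
#>                             4.000                             3.701
```

Stride velocity is height-normalized (1/s), so 0.606 corresponds to about
1.06 m/s over a 1.75 m subject; the constant cluster walks faster than the
baseline average while the non-constant cluster (ramp strides) is slower —
the separation the clustering is designed to expose.

The whole chain, from cohort simulation to per-cluster AUCs, runs as

```r
res <- run_pipeline(pipeline_config(seed = 1, n_subjects = 16))
report_results(res$results)     # AUC per cluster vs baseline, % change
```

or from a shell via the thin CLI in `exec/`:

```sh
Rscript exec/gaitphase run --seed 1 --subjects 16 --out run1
Rscript exec/gaitphase simulate --seed 4 --subjects 4 --out simdata
```

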