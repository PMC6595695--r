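---
title: "Methods and design notes for gaitphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for gaitphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gaitphase` analyses 4×10 m walk tests recorded with a six-axis inertial
sensor on the lateral side of each shoe (accelerometer in g, gyroscope in
deg/s, 102.4 Hz; x posterior–anterior, y superior–inferior, z medio-lateral).
This vignette explains the models behind each stage, the tunable parameters
and why their defaults were chosen, what the synthetic generator does and
does not emulate, and the design decisions taken where the problem was
genuinely open.

## Stride segmentation

A stride is one gait cycle of one foot, delimited by consecutive minima of
the medio-lateral gyroscope channel GZ. Segmentation is template matching:
a single-stride GZ template is matched against the whole recording by
*subsequence* dynamic time warping. Both signals are z-normalized once,
globally; the DTW runs an unconstrained SPRING-style dynamic program
(absolute-difference local cost; diagonal/up/left steps) that yields, for
every endpoint, the accumulated cost of the best path from any start,
normalized by the template length, plus that start index (implemented in
C++, `src/dtw.cpp`). Candidate matches are local minima of the endpoint-cost
curve; they are accepted greedily in ascending cost under three filters:

* `distance_threshold` (default **0.5**): on z-normalized signals with the
  per-template-sample cost normalization used here, clean strides score
  roughly 0.03–0.3 and flat-signal pathologies score above ~0.55, so 0.5
  separates the two with margin. The threshold is a config knob and should
  be re-tuned if a different template or cost is used.
* `len_range` (default **c(0.6, 1.8)** × template length): warping is
  bounded not by a fixed global band but by the accepted match length.
  Slow gait-initiation strides genuinely last ~1.5× the habitual stride
  time, while sub-cycle shapes (a half stride) must be rejected, hence an
  asymmetric window.
* `overlap_tol` (default **3** samples): adjacent strides share the
  boundary trough sample, so candidate matches legitimately overlap by a
  sample or two; residual overlaps are clipped at the midpoint.

Borders are then refined to the *nearest strict local GZ minimum* within
`search_radius` (default 10 samples ≈ 100 ms). Snapping to the nearest
minimum (not the window argmin) makes refinement idempotent. Where manual
correction would be used interactively, `apply_corrections()` applies an
add/delete/replace edit list from a JSON file instead.

The packaged template (`gz_stride_template()`) is the canonical smooth
stride cycle rendered at 1.0 s; on real data the recommended practice is to
cut a template from one cleanly segmented stride of the same cohort.

## Within-stride events and gait parameters

Event detection is rule-based: mid-stance (MS) is the minimum of the
gyroscope magnitude in the middle 60 % of the segment (the foot-flat
quiet phase), toe-off (TO) the GZ maximum in the first half, heel-strike
(HS) the steepest negative GZ slope in the second half, with TO < HS
enforced. These rules are deliberately simple stand-ins for dedicated
event-detection literature; all are localized definitions that the
synthetic signals satisfy by construction, and they are configurable at
the code level.

Temporal parameters follow the heel-strike convention: stride time is the
interval between the heel strikes opening and closing the stride; swing is
the terminating TO→HS fraction; stance its complement. Note one semantic
consequence: when gait accelerates, the HS-to-HS stride time mixes the
durations of two adjacent cycles (≈ 0.46 T_i + 0.54 T_{i+1}); it equals the
boundary-to-boundary duration only in steady state. Tests therefore check
stride-time recovery on steady strides.

Stride length, path length and toe clearance come from strap-down
integration between consecutive MS samples: the sensor orientation is
estimated at the initial MS from the accelerometer under a static
assumption (measured specific force ≈ gravity), all samples are rotated so
gravity lies on +y, gravity is subtracted, and acceleration is integrated
twice with zero-velocity updates at both MS anchors; residual velocity
drift is removed linearly, which exactly cancels any constant acceleration
bias (such as a small orientation error projecting gravity into the
horizontal plane). Stride length is the horizontal displacement norm, path
length the 3-D arc length, toe clearance the maximal vertical excursion;
lengths are divided by body height in metres, so stride velocity
(= length/time) is in units of heights per second. The turning angle is
the trapezoidal integral of GZ between MS samples — a yaw projection that
is adequate for a laterally mounted sensor during flat-ground turning; a
full 3-D orientation filter is intentionally out of scope.

## Turning isolation

Per foot, strides with |TA| > `hard_threshold_deg` (default **20°**, a
conventional threshold for turning detection) are turning strides. A gamma
distribution (location 0) is then fitted by maximum likelihood
(`fitdistrplus`) to the |TA| of the remaining strides — a natural choice
for a positive, single-tailed quantity — and unmarked strides whose |TA|
reaches the fitted `q`-quantile (default **q = 0.9**, i.e. the upper 10 %
of the *fitted* distribution, since the distribution is fitted expressly
to define that tail) are added when index-adjacent to a marked stride,
iterated to a fixed point (`iterate = FALSE` gives the single-pass
variant; both are provided because either reading is defensible). Strides
marked by the hard rule are never removed. Degenerate samples (zero
variance, where the MLE is undefined) fall back to the empirical quantile.
With fewer than 3 residual strides the tail step is skipped with a warning.

One property worth stating plainly: because the tail threshold adapts to
the residual distribution, roughly 10 % of turn-adjacent straight strides
will be absorbed into a turn on statistically featureless data. This is by
design — such strides are transitions into/out of the turn — but it means
stride-level precision against a clean simulation truth is not exactly 1;
turn-level detection (three turns, each covering the true turn) is exact,
and that is what the acceptance suite asserts.

## Clustering straight strides

Straight strides between turns form bouts. Within each bout the clustering
parameter (stride velocity or stride time) is normalized by the bout mean
(the median method normalizes by the bout median, per its own definition),
and a lower/upper threshold pair declares a stride *constant* iff it lies
strictly between them:

| method | thresholds on the normalized parameter |
|---|---|
| `N%crop` | positional: first/last `round(N%·n)` strides (round half-up) |
| `median` | 0.95 and 1.05 after median normalization |
| `distr`  | mean ± SD (sample SD, ddof 1 — bouts are small) |
| `3means` | smallest and largest of the three 1-D k-means centres |
| `perc`   | empirical 25th / 75th percentiles (linear interpolation) |

Strict inequalities are used uniformly: for `3means` the thresholds are
themselves centres of non-constant strides and inclusive bounds would
absorb them. The k-means uses K = 3 (slow/medium/fast), five seeded
initializations — one spread over the 1/6, 3/6, 5/6 quantiles, four random
draws of three distinct values — Lloyd iteration with assignment ties
toward the lower-index centre, and keeps the run with the largest
*separation*, defined as the minimum pairwise distance between centres
(the cheapest direct reading of "separation"; all-random initializations
occasionally leave every run in a collapsed optimum, which the spread
start rules out).

The post-processor encodes that acceleration and deceleration can only
happen in the first and last 25 % of a bout (band size `ceiling(0.25 n)` so
the band is never empty): inside the head band everything up to the last
raw non-constant stride becomes *acceleration*, mirrored from the tail for
*deceleration*, and every other stride — including raw non-constant strides
outside the bands — becomes *constant*. The result always matches
`acceleration* constant* deceleration*`; reversing a bout swaps the two
ramp labels (for n ≥ 2; a single-stride bout is its own head and tail
band). By default the post-processor is applied to every method, including
crop methods, for which it is a no-op by construction in raw positions;
`raw = TRUE` exposes the unprocessed labels.

When both feet are pooled (the default; the study-level quantity is one
value per subject and cluster), the feet do not cross a turn boundary on
the same stride, so a 1–2-stride straight run of one foot can sit inside
the other foot's turning run. The subject-level pipeline folds straight
runs shorter than 4 strides that are enclosed by turning strides into the
turn window for bout splitting and assigns those strides to the
neighbouring bout; the elementary maximal-run operation is exported
unchanged as `split_into_bouts()`.

Bouts too small for a threshold method (< 3 strides, or < 3 distinct
values for k-means) fall back to `25%crop` labels rather than failing the
subject.

## Aggregation

Per subject and cluster, each parameter is summarized as mean and CV
(sd/|mean|, ddof 1); CVs of clusters with fewer than two strides, and all
features of empty clusters, are explicitly missing (`NA`), never silently
imputed at this stage. The signed turning angle of straight strides
straddles zero, so its aggregation uses |TA|. The baseline cluster is the
union of constant and non-constant strides, and the partition
(turning / constant / non-constant, exhaustive and disjoint over all
segmented strides) is asserted on every run — a stride escaping labelling
is an error, not a warning. No minimum-stride-count filter is imposed on
non-constant CVs; users should be aware those CVs can rest on few strides.

## Clinical validation

Subjects are labelled impaired iff the clinical subitem score (0–4) is
nonzero. The pipeline per gait cluster: stratified random 60/40
train/test split (stratification guarantees evaluability at small n);
random undersampling of the training majority class; per-feature median
imputation and z-score standardization fitted on the training set (an
RBF-SVM on mixed-unit features needs scaling); Fisher-score
(`(μ₁−μ₀)²/(s₁²+s₀²)`, sample variances) top-5 selection with ties broken
toward the canonical column order; SVM grid search over
C ∈ {0.01…100} × γ ∈ {0, 0.01…100} where γ = 0 selects the linear kernel,
scored by mean AUC of continuous decision values over stratified 5-fold
inner cross-validation (single-class folds are skipped with a warning);
refit of the best pair on the full training set; test AUC by the
Mann–Whitney rank statistic with midrank ties. Decision scores, not hard
predictions, feed the ROC. Everything data-dependent is fitted on training
rows only — the suite checks that mutating test rows leaves the selected
features and tuned hyperparameters bit-identical. Using one seed across
clusters and methods makes the comparisons paired (same split); no
multiple-testing correction is applied across the cluster×method grid —
the comparison is descriptive.

## The synthetic generator

The generator's job is to provide *controlled truth* for every stage, not
biomechanical realism. A schedule draws per-stride truth: four bouts of
eight strides (three acceleration, two constant, three deceleration) with
velocities ramping linearly from 50 % of the habitual 1.4 m/s, stride
lengths scaling with √velocity around 1.25 m (so slow strides are shorter
*and* longer-lasting), turns of four strides at ~45° each (alternating
direction, totalling ~180°), straight-stride TA ~ N(0, 3°), and optional
multiplicative stride-time jitter. The signal renderer emits a smooth GZ
cycle — boundary troughs, a swing peak at 25 % phase, a sharp dip whose
falling edge defines HS, and a stance bump — whose amplitudes are solved so
the integral vanishes separately over [0, 0.75] and [0.75, 1] of the
phase: mid-stance sits at 0.75, so any MS-to-MS integral of the cycle is
exactly zero and the integrated yaw equals the injected TA pulse (a wide
Gaussian in the next cycle's early swing) to within quadrature error. GX
carries a plateau with a deep notch at mid-stance so the gyroscope
magnitude has a unique MS minimum. The accelerometer carries gravity plus
sin⁴-shaped forward/vertical velocity bumps between MS anchors — flat at
the anchors, so the foot is genuinely static there (the ZUPT assumption)
and displacement equals the scheduled stride length exactly. Cohorts add
between-subject dispersion (habitual velocity SD 0.15 m/s, log-normal
stride-time-CV dispersion 0.4, ±1 habitual turn strides) and impairment
effects (velocity shift −0.2 m/s, stride-time CV ×2, +1 turning stride per
turn by default); without the dispersion every effect would be a
deterministic separator and validation AUCs would be trivially 1.

Not emulated: 3-D foot attitude dynamics, soft-tissue and impact
artifacts, freezing-of-gait episodes, asymmetric left/right impairment,
magnetometer effects, sensor bias/drift. Passing tests on this generator
therefore demonstrate the correctness of the algorithms under their stated
assumptions, not field performance on patient data.

## Numerical choices and degenerate inputs

* Sample indexing is 0-based with half-open `[start, end)` windows
  everywhere (files included); R's 1-based access happens only at slice
  time.
* Accelerometer g-units are converted with g₀ = 9.80665 m/s²; integration
  uses cumulative trapezoids (`pracma`).
* Percentiles use linear interpolation between order statistics; crop
  counts round half-up; the post-processing band is `ceiling(0.25 n)`.
* Gamma fits fall back to empirical quantiles at zero variance; constant
  signals yield empty segmentations (not errors) but degenerate strides
  fail event detection loudly.
* Fisher scores with both class variances zero are `Inf` (different means)
  or 0 (equal); infinite scores sort first, which is the intended ranking.
* All randomness flows from explicit integer seeds; per-subject seeds are
  drawn once from the cohort seed, so any subject can be regenerated alone.

## Problem sizes in the test suite

The suite exercises: 200 simulated walk tests for turning isolation; 10⁵
draws for the gamma-tail quantile (2 % analytic tolerance); 1000 random
bouts against sorting oracles and 100 seeds of tri-modal k-means recovery
(1 %); 1000 random labelings of the post-processing automaton; a 6-subject
signal-level cohort for partition invariants; noise-free recovery of TA
(1°), stride length (5 %), steady stride time (2 %) and the closed-form
1-D kinematic case (10⁻⁶); a 120-subject feature cohort with standardized
effect 2 (AUC ≥ 0.9) plus 50 permuted-label repeats (mean AUC in
[0.45, 0.55], run on a reduced 3×3 grid to keep the null study quick); and
two full 8-subject pipeline runs compared manifest-for-manifest. These
sizes were chosen to make the probabilistic checks stable across seeds
while keeping a full run in the order of a minute.

## Known limitations

* Event-detection rules are stand-ins; absolute swing/stance fractions and
  angle values should not be compared against literature without
  re-validating the rules on reference data.
* The turning angle is a single-axis yaw projection; sensors mounted with
  a different orientation, or turns on slopes, violate it.
* HS-based stride time differs from boundary duration during speed
  changes (documented above); this is a property of the definition, not a
  bug.
* The DTW threshold and length bounds are tuned to the packaged template;
  real recordings with strongly atypical stride shapes will need the
  correction interface or a cohort-specific template.
* Validation AUCs on small cohorts are coarse (few test subjects); the
  pipeline reports them without uncertainty intervals, mirroring the
  descriptive comparison it implements.
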