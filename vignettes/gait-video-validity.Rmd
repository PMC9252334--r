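---
title: "Video-based gait features: methods, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video-based gait features: methods, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpose)
```

# The measurement problem

A pressure-sensing walkway measures footfall times and positions directly;
a video camera measures neither.  What a pose-estimation network gives us
is, per frame, the pixel coordinates of body joints with a confidence
score.  This package turns those trajectories into the spatiotemporal
gait parameters clinicians use — cadence, step count, step width and its
variability, step-time variability, and (with metric depth) speed and
step length — and provides the statistics needed to ask whether the
video-derived numbers agree with a reference modality.

Two facts shape the whole design:

* **Pixels are not meters.**  A frontal camera sees the walker's scale
  change with distance, so no pixel distance is interpretable on its own.
  All 2D spatial features are therefore normalized by the *apparent hip
  width in the same frame*, which cancels the perspective scale and
  leaves a unitless quantity.  Rank correlations against a metric
  reference are unaffected by this monotone rescaling.
* **A planted foot is a density peak.**  During stance the ankle keypoint
  is stationary for a sustained stretch of frames; during swing it moves.
  In (time, x, y) space a stance is thus a dense cluster, which is why a
  spatiotemporal density clustering (ST-DBSCAN) detects footfalls: a
  point's neighbourhood is the set of samples within `eps_spatial` in
  space *and* `eps_temporal` in time, core points need `min_pts` such
  neighbours, and clusters grow exactly as in classical DBSCAN.  The heel
  strike is defined as the first timestep of a detected stance.

# Pipeline and parameters

`extract_bout()` runs, in order: confidence masking, gap interpolation,
zero-phase smoothing, per-foot stance detection, heel-strike extraction,
foot merging, feature computation.

**Confidence gating.**  Confidence scores are not calibrated across
estimators, so the masking threshold is keyed to the estimator tag: 0.50
(AlphaPose), 0.15 (Detectron), 0.65 (OpenPose), 0.50 otherwise — values
chosen by those tools' ecosystems so that roughly under 10% of timesteps
per joint need interpolation.  Masked or absent samples inside a track
are filled by linear interpolation from the adjacent observed timesteps
(`max_gap_frames = 15`, i.e. 0.5 s at 30 Hz, before the track is declared
broken).  Leading and trailing gaps are never extrapolated — an
extrapolated ankle would fabricate heel-strike geometry — they are
trimmed from the usable range instead.

**Smoothing.**  A second-order low-pass Butterworth filter with an 8 Hz
cutoff, applied forward and backward so the pass is zero-phase: gait
signal content lives well below 8 Hz, pose jitter well above, and zero
phase matters because a time shift would bias every event timestamp.  The
implementation pads both ends with odd signal reflection and initializes
the recursion at steady state, so a constant signal passes through to
machine precision and endpoint transients decay below 1e-13 (the pad
length is derived from the filter pole radii).  `signal::butter()`
supplies the coefficients; the zero-phase application is done in the
package because the zero-padding used by `signal::filtfilt()` distorts
endpoints.  As a by-product, the residual `raw - smoothed` yields a
robust per-joint estimate of the keypoint jitter (1.4826 × MAD), which
the detector reuses below.

**Stance detection.**  Each ankle is clustered separately on its
(t, x, y[, z]) samples.  The defaults were fixed by a synthetic recovery
study (see below) and are all exposed in configuration:

| parameter | default | units | role |
|---|---|---|---|
| `eps_spatial` | auto | px (m for 3D) | stationarity radius |
| `eps_hip_frac` | 0.06 | — | auto radius = fraction × median hip width |
| `noise_eps_mult` | 2.0 | — | radius floor = multiple × estimated jitter |
| `eps_temporal` | 0.13 | s | temporal radius (±3 frames at 30 Hz) |
| `min_pts` | 4 | points | core density (self included) |
| `min_stance_s` | 0.3 | s | minimum stance duration |
| `min_stride_s` | 0.65 | s | minimum same-foot strike separation |

The spatial radius has two floors.  The *geometric* floor scales with the
bout's median apparent hip width, because everything in the image scales
with subject distance.  The *noise* floor is a multiple of the estimated
keypoint jitter, because stationary samples must still find each other
under observation noise.  Whichever is larger wins.

Three post-filters convert clusters to stances.  (1) Same-foot clusters
that overlap, or that are nearly contiguous (≤ 0.2 s apart) *and*
co-located within `eps_spatial`, are merged: the latter are fragments of
one physical stance split by noise.  (2) Clusters shorter than
`min_stance_s` are discarded.  This threshold is above the duration of a
genuine image-space artifact: the swinging ankle's projection has a
turning point (the vertical clearance arc and the forward motion act on
the image ordinate with opposite signs), where the trajectory is briefly
quasi-stationary and can form a short false cluster.  True stances last
roughly 60% of a stride — at least ~0.45 s for even a fast simulated
walker — so 0.3 s separates the two populations.  (3) Two stances of the
same foot cannot begin less than a physiological stride apart; of a
same-foot pair starting within `min_stride_s` the shorter is dropped.
Finally, a stance whose first frame falls within the temporal radius of
the start of the observation window is discarded: it was already in
progress when the bout began, so its onset — the heel strike — cannot be
timed.  Bouts cropped from continuous walking always contain one such
straddling stance.

**Features.**  Cadence uses first-to-last strike span,
`60 (n - 1) / (t_n - t_1)`; step times and widths use only *valid* steps,
i.e. consecutive events from opposite feet at distinct frames
(consecutive same-foot events mean a missed strike and invalidate that
step, not the bout).  Step width divides by the hip width at the *later*
strike's frame — the moment of double support, when both positions are
simultaneously meaningful; conveniently the pelvis then sits roughly
midway between the two feet in depth, which makes the normalization
nearly unbiased under perspective.  All CVs use the sample (n−1) standard
deviation, the safer choice at 10–20 steps per bout (a flag switches to
the population form).  Counts are counts of heel strikes, not intervals.

# The validity statistics

The battery mirrors standard concurrent-validity practice:

* `dagostino_pearson()` — omnibus normality screen: K² is the sum of the
  squared normalizing transforms of sample skewness (D'Agostino 1970)
  and kurtosis (Anscombe–Glynn 1983), referred to χ² with 2 df.  Its
  outcome is *reported* with each correlation but does not switch the
  method: the rank correlation is used throughout, because gait features
  over a patient cohort are rarely normal.
* `spearman_right()` — rho is the Pearson correlation of average ranks;
  the p-value is right-tailed (the scientifically meaningful alternative
  is *positive* association with the reference).  For n ≤ 8 the p-value
  is exact by full enumeration of the n! pairings — at rho = −1 this
  correctly gives p = 1, the inclusive-count convention `cor.test` also
  uses; above that, the usual t approximation (whose absolute deviation
  from exact enumeration we measured at ≤ 0.02 at the crossover n = 8).
* `bonferroni_adjust()` — `min(1, factor × p)`.  `validity_report()`
  defaults the factor to the number of correlations sharing each
  reference feature (e.g. 18 for three estimators × two annotation
  methods × two walking directions), overridable in configuration.
* `wilcoxon_signed_rank()` — two-sided paired comparison for ON/OFF
  treatment states; exact by sign-pattern enumeration to 12 effective
  pairs, normal approximation with continuity and tie corrections above.
* `cutoff_sweep()` and `difference_metrics()` — the step-count cap
  analysis (OLS of video counts on reference counts under each cap) and
  the direct mean / mean-absolute / percent differences for features in
  shared units.

Repeated bouts per subject are treated as independent in the correlation
analysis — a deliberate simplification that matches bout-level validity
designs; a mixed-effects treatment is out of scope and noted as a caveat.

# What the simulator emulates — and what it does not

`simulate_walk()` emulates the recording geometry this pipeline targets:
a ~6 m straight walkway filmed at 30 Hz and 640×480 from a static camera
2 m before the near end, 1.2 m high, pitched 5° down, ~600 px focal
length (bout depths therefore span 2–8 m).  The walker draws step times,
lengths and widths from truncated normals (±3 sd and positivity; explicit
bounds for the shuffling regime), plants each ankle exactly at its strike
position for 60% of its stride, and swings it with a cosine-eased
horizontal profile and a sinusoidal vertical clearance arc.  Hips ride at
±15 cm of a pelvis that passes through the midpoints of successive
strikes.  Pixel noise is i.i.d. Gaussian; confidence dropout sends a
joint-frame's score below every default threshold with the configured
probability.  Bouts begin 0.3 s before the first in-walkway strike — in
mid-gait, as cropped video segments do — and end 0.4 s after the last.

Cohorts (`make_cohort()`) add the between-subject layer: each bout's
parameter *means* are drawn from population distributions.  The normal
preset is an unimpaired adult population (step length 0.55 ± 0.08 m,
step time 0.55 ± 0.06 s, step width 0.10 ± 0.025 m, ankle swing clearance
0.15 m).  The shuffling preset encodes the short-step regime in which
frontal-view clustering is known to fail: per-walk mean step length
10.8 ± 5.4 cm truncated to 4.8–19.2 cm, and — the kinematic hallmark of a
shuffle — minimal foot clearance (0.04 m).  The `on_off_paired` preset
gives each synthetic subject a pair of bouts with an additive treatment
effect on step length and step time; with the effect set to zero it is a
null generator for calibration checks.

The simulator is deliberately not a biomechanical model.  It has no
turning phases, no arm swing or trunk, no double-support kinematics, no
pose-estimator failure modes beyond isotropic jitter and dropout (real
estimators produce structured errors: left/right swaps, occlusion
streaks, identity switches), and its confidence scores are synthetic.
Passing the synthetic recovery suite therefore shows that the *algorithm
chain is correct and well-calibrated for the intended geometry*; it does
not certify accuracy on any particular real video corpus, which is what
the concurrent-validity statistics against a real reference are for.

# Calibration of the detection defaults

The clustering defaults cannot be derived a priori — they trade off three
regimes that pull in different directions — so they were fixed by a
recovery study on simulated cohorts (seeds disjoint from those used in
the acceptance tests), requiring simultaneously: exact step counts and
±1-frame strike timing on noise-free normal-preset cohorts; a high rank
correlation between estimated and true cadence under 2 px noise with 5%
dropout; and reproduction of the shuffling failure mode (automatic
undercounting with manual annotation unaffected).  The frozen defaults
achieve all three on held-out seeds; `scripts/acceptance.R` re-measures
them from scratch on any seed.

Two findings from that study are worth recording.  First, the spatial
radius is the critical dial: too small and noisy stance samples fail to
reach core density (stances fragment or vanish); too large and the
pre-landing swing samples join the stance cluster, timestamping every
strike early — the radius floor pair (geometric + noise-scaled) resolves
this.  Second, the image-space turning point of the swing arc is a
systematic false-stance generator that duration and stride-interval
filters must handle explicitly; it is not an artifact of noise and occurs
in noise-free projection too.

# Known limitations

* **Far-field resolvability.**  The image-space motion of a swinging
  ankle scales as 1/depth²; beyond ~7.5 m with this camera it approaches
  the stationarity radius, and consecutive stances can no longer be
  separated by density.  Short shuffling steps merge first (that is the
  mechanism the shuffling preset reproduces, and why bouts with more than
  20 reference steps are excluded by `filter_bouts()`); at the walkway's
  deepest strikes even normal strides occasionally acquire an early
  timestamp or, rarely, lose a strike.  This is a property of frontal
  geometry at 30 Hz, not a tunable defect.
* **2D widths are relative.**  Hip-width normalization cancels scale but
  also removes units; only rank-based comparisons against a metric
  reference are meaningful for 2D spatial features.
* **One walker, lateral-axis convention.**  Multi-person frames keep the
  highest-mean-confidence detection; the 2D lateral axis is the image
  x-axis, which assumes the camera faces down the walkway.
* **Direction inference is a convenience.**  `infer_direction()` uses the
  sign of the robust hip-width trend and abstains below the noise floor;
  an explicit direction label in the bout metadata always wins.
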