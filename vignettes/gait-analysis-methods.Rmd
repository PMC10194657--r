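---
title: "Multi-sensor gait analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sensor gait analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdmo)
```

## The problem

Wearable multi-sensor systems estimate spatio-temporal gait parameters —
cadence, stride length, walking speed, stance time, walking-bout duration
and length — from synchronized streams recorded on the body: a 3-axis
accelerometer and gyroscope on each foot, a lower-back inertial unit,
16-channel pressure insoles, and ankle-mounted time-of-flight distance
sensors (range limit 0.2 m, native 50 Hz). These digital mobility
outcomes (DMOs) matter clinically because laboratory gait is not
real-world gait; a body-worn reference system that can follow a person
through daily life must itself be validated, which is what the agreement
machinery in this package supports.

`gaitdmo` implements the full estimation chain, a marker-based
(stereophotogrammetric) reference pipeline, the agreement statistics used
to compare two systems, sensor-noise quality control, and a synthetic
recording generator that provides ground truth for every stage.

## The estimation pipeline

**Activity recognition.** A sliding 1 s window (50% overlap) is active
when the standard deviation of the acceleration norm exceeds
0.7 m/s&sup2; at the lower back and 2.1 m/s&sup2; at at least one foot;
active windows merge when closer than 0.5 s. The thresholds are the
established empirical values for this sensor placement; the windowing is
this package's choice (the rule itself is windowing-agnostic).

**Event detection.** Initial contacts (IC) and final contacts (FC) are
detected twice, independently:

* *Pressure insoles.* Channels binarize at `baseline + 3·sigma` with a
  50 ms hysteresis. The baseline is a low (10%) quantile rather than the
  median because a person standing between bouts keeps the insole loaded
  for long stretches; the noise scale comes from robust first differences,
  which are immune to the loading steps. An anatomical cluster (heel,
  midfoot, forefoot, toe) is active when at least two of its four
  channels are active; the IC of a contact episode is the earliest
  cluster onset, the FC the latest cluster release.
* *Foot IMU.* Within active intervals, trusted mid-swings are prominent
  maxima of the sagittal angular rate; the FC is the rate minimum in a
  window before each swing peak and the IC the minimum after it, windows
  bounded by the midpoints to adjacent peaks. The sagittal axis defaults
  to the second gyroscope column (the package's documented mounting
  convention: X forward, Y medio-lateral, Z up at flat stance) because no
  sign-robust automatic axis inference exists for symmetric rate
  profiles.

**Fusion.** Same-side, same-kind events match greedily within ±0.25 s,
one-to-one, ties toward the earlier IMU event. A matched pair becomes one
event at the insole time (direct contact sensing outranks inertial
inference); insole-only events are kept; IMU-only events survive only if
their IC–FC span contains at least 100 ms of contiguous sub-threshold
dwell on *both* ZUPT detectors (Angular Rate Energy < 0.5 and Moving
Variance < 0.005, both normalized to their active-portion maximum — the
"normalized unit" is trial-max normalization, a definition this package
fixes explicitly). Alternation (IC, FC, IC, …) is restored per side by
dropping the later of two consecutive same-kind events.

**Stride trajectories.** Orientation comes from a Madgwick filter
(gain `beta`, default 0.1; gyroscope propagation uses the exact
quaternion exponential with midpoint rates, the accelerometer correction
is the standard normalized gradient step). No magnetometer is used: yaw
is then unobservable, but stride length is the horizontal *norm* of a
displacement, so slow yaw drift between anchors cancels. Gravity-free
acceleration `R(q)·a − (0,0,9.81)` is integrated between consecutive
zero-velocity anchors — midpoints of dwells where the Angular Rate Energy
stays below 0.5 for at least 100 ms — forward from zero and backward from
zero, blended with a linear weight. The blended velocity is exactly zero
at both anchors and a constant acceleration bias cancels to first order.
Still periods longer than 1 s (standing breaks) are subdivided into 1 s
sub-dwells before anchoring: every instant of a still period is a valid
zero-velocity anchor, and short segments keep the linear de-drift
assumption honest; without the subdivision, the stride entering a break
inherits a step-shaped (not ramp-shaped) velocity-error profile that
linear blending cannot cancel, and its length error grows an order of
magnitude. The gain can be tuned with `optimize_beta()`, a grid search
minimizing stride-length error on trials with known truth (ties toward
the smaller gain; smaller gains trust the gyroscope more).

**Stride and bout assembly.** A stride is the interval between two
consecutive ipsilateral ICs; its stance ends at the enclosed FC. Strides
are valid iff duration is within [0.2 s, 3 s] and length is at least
0.15 m (bounds inclusive, as printed). Distance-sensor dips (in-range
readings during the contralateral pass) set an informational
`ds_verified` flag and never reject strides. Per side, strides separated
by less than 3 s form sequences; overlapping left/right sequences merge
into a bout; the chronologically first and last stride of each bout are
trimmed (gait initiation/termination); bouts need at least two left and
two right strides after trimming. Per bout:

* cadence = mean over strides of (60 / stride duration) × 2 steps/min —
  algebraically 120 / harmonic-mean(duration);
* walking speed = mean over strides of (stride length / stride duration);
* bout length = bilateral mean of the summed per-side stride lengths
  (both feet traverse the same path); bout duration = first IC to the
  last stride end. The last two are this package's conventions — the
  quantities are standard but their exact definitions are not printed
  anywhere authoritative; likewise trimming removes one stride per bout
  end regardless of side (the minimal reading of "first and last
  stride").

## The marker-based reference

Heel and toe markers per foot plus a rigid four-marker pelvis cluster.
Gaps shorter than 0.5 s are cubic-spline filled (longer gaps stay masked
and raise the trial's marker-gap flag); all coordinates pass a zero-lag
4th-order Butterworth low-pass at 7 Hz (forward–backward, odd-reflection
padding sized from the slowest pole's settling time). IC candidates are
local maxima of the heel-to-pelvis displacement along the instantaneous
walking direction (smoothed horizontal pelvis velocity; the pelvis center
is the cluster centroid), FC candidates are minima of the toe-to-pelvis
displacement. Candidates are refined within ±0.15 s using the 3-D marker
speed: the IC snaps to the *first* below-0.1 m/s sample (heel settling),
the FC to the *last* (toe about to leave). A plain speed argmin is
ambiguous — stance is a plateau of near-zero speed — which is why the
refinement is directional. Candidate peaks need 0.02 m of two-sided
prominence, which rejects filter jitter during quiet standing. Stride
length and speed come from heel positions at consecutive ipsilateral ICs;
stride/bout selection reuses the inertial criteria. The reference is a
pure function of the marker streams.

## Agreement statistics

Only bouts detected by both systems are compared: spans pair greedily by
temporal-overlap fraction (intersection over the shorter span, threshold
0.5 — the matching rule is this package's choice; the source convention
states only both-system detection). Per DMO: errors `E = test − ref`,
relative errors `E/ref × 100` (zero references excluded with a warning),
summarized by mean (bias), mean absolute (accuracy), median, median
absolute and interquartile range (precision; type-7 quantiles).
Shapiro–Wilk flags non-normal error series. Absolute agreement uses
ICC(2,1) — two-way random effects, absolute agreement, single measure —
from the mean-squares decomposition, with the F-based 95% confidence
interval and the conventional classes (poor < 0.5 ≤ moderate < 0.75 ≤
good ≤ 0.9 < excellent). Sample-size planning for a target CI width `w`
uses the Bonett-type approximation

n = 1 + 8 z² (1 − ρ)² (1 + (k − 1)ρ)² / (k (k − 1) w²),

rounded to the nearest integer; with k = 2 raters and w = 0.1 it yields
401, 295, 200, 119, 56 and 16 bouts for planning ICCs 0.70–0.95, the
published planning ladder.

```{r}
vapply(c(0.70, 0.75, 0.80, 0.85, 0.90, 0.95), icc_sample_size, integer(1))
```

## Sensor quality control

Static per-axis standard deviations (100 s) are screened against the
reference ceilings 3.31 mg (accelerometer) and 0.13 dps (gyroscope):
units exceeding them by more than 15% fail. Gyroscope bias instability is
the minimum of the overlapping Allan deviation over 30 log-spaced
averaging times from 2/fs to a tenth of the record — reported raw, with
no 0.664 correction factor, since the upstream convention is not printed.
The 60 s pre-session spot check estimates the per-axis gyroscope bias
(handed to the trajectory stage for removal), verifies the accelerometer
norm is within 9.81 ± 0.3 m/s² (tilt-insensitive) and aborts on motion.

## The synthetic world

The simulator states one fixed world rather than a tunable benchmark.
Defaults: 3 bouts × 10 strides per side, stride 1.2 m / 1.1 s (zero
between-stride spread), stance fraction 0.6, 5 s standing breaks and
lead-in/out, step width 0.2 m, swing foot lift 5 cm, 100 Hz. During
stance the foot is exactly stationary and flat; swings are minimum-jerk
horizontally with a sin² vertical lift and a sin² lateral excursion that
brings the ankles to 0.08 m at the contralateral pass (one distance-
sensor dip per stride). Noise defaults echo the screening ceilings
(3.31 mg, 0.13 dps) as white-noise magnitudes; insole noise is 0.5 force
units against a 100-unit active amplitude and marker noise 0.5 mm,
typical of force-sensing resistors and optical capture respectively.

Two modeling choices deserve justification:

* **Swing pitch.** The stated swing profile (horizontal minimum-jerk +
  vertical lift) produces zero angular rate, which would starve the
  IMU event detector. A zero-net sagittal pitch excursion
  θ(τ) = −A·sin(2π·u(τ)) with the time warp u'(τ) = 1 + cos(2πτ)/2
  (A = 10° by default) was added: its rate has a mid-swing maximum and
  sharp minima exactly at toe-off and landing — the signature real foot
  gyroscopes show — while stance remains perfectly still.
* **Bout topology.** Bouts begin with a toe-off from standing and end
  standing, so each side makes n+1 contacts and exactly n ground-truth
  strides, and the insoles stay loaded across breaks as real insoles do
  under a standing subject. The contact episode that spans the recording
  start produces one over-long stride that the duration filter removes —
  a consequence of the stated world, not a tuned behavior.

What the generator does **not** emulate: pathological signatures (tremor,
festination, asymmetry), turning or curvilinear paths (a kinematically
consistent arc model was judged not worth its complexity since stride
length is a displacement norm), soft-tissue artifact, insole drift and
hysteresis, marker occlusion statistics (gaps are injected explicitly),
and double-support force transfer. A green end-to-end test therefore
establishes internal consistency of the chain under realistic sensor
noise — not clinical validity on real cohorts, which requires real
recordings and the published multi-center protocol.

## Numerical choices and degenerate inputs

* Trapezoidal quadrature everywhere; g = 9.81 m/s² exactly.
* Detector normalization defines 0/0 = 0 (all-zero gyroscope yields an
  all-zero detector, no events, no error).
* An all-zero insole stream yields an empty event list, not an error;
  fewer than two zero-velocity anchors yield zero strides.
* Quantiles are type 7 (R default, linear interpolation).
* ICC is refused for n < 5 bouts or zero between-subject variance.
* The stuck-insole quality rule flags a channel that is constant across
  an entire dynamic activity interval; a fraction-of-time rule
  false-positives on legitimate standing loads.
* Event ties in fusion break toward the earlier IMU event; equal-error
  ties in the beta grid search break toward the smaller gain.

## Known limitations

Yaw is unobservable without a magnetometer (harmless for lengths, fatal
for heading-dependent outcomes, which are out of scope). The IMU event
detector assumes the documented mounting convention for the sagittal
axis. Turning bouts are not simulated. The marker FC refinement is
3–4 samples early on sharp toe-offs because the 7 Hz low-pass smears the
lift-off; stance-time comparisons against the reference inherit that
bias.
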