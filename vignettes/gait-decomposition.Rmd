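---
title: "Measuring gait decomposition: methods, parameters and design notes"
author: "gaitdecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gait decomposition: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdecomp)
```

## The measurement problem

Foot drop — weakness of the ankle dorsiflexors — forces compensations that
show up in three layers of a gait recording: spatiotemporal parameters
(velocity, step length/width, double support, foot clearance), sagittal
kinematic maxima (hip/knee flexion, ankle dorsi- and plantarflexion), and
*interjoint coordination*. The decomposition index targets the third layer:
how much of the gait cycle a person spends moving one joint of a pair while
holding the other still, a strategy that simplifies control but degrades
smoothness and adaptability. This package implements the full chain from
marker trajectories to condition-comparison statistics, with a synthetic
cohort generator standing in for participant recordings that are not
publicly available.

## The decomposition index

For each joint (hip, knee, ankle of the analyzed, paretic leg) the angular
velocity is the central finite difference of the low-pass filtered sagittal
angle. Within each gait cycle a joint is **paused** at a frame when
$|\omega(t)| < f \cdot \max_{\text{cycle}} |\omega|$; the default threshold
fraction is $f = 0.05$ (5% of the baseline velocity).

Two deliberately fixed interpretations:

* **Baseline velocity** is the joint's *peak absolute angular velocity
  within the current cycle* (per joint, per cycle). The source protocol
  does not define its reference; a per-cycle peak makes the threshold
  invariant to amplitude rescaling of the trajectory, which in turn makes
  the index comparable across joints, speeds and participants. This is the
  key interpretive choice of the implementation.
* **Frozen-joint floor.** A purely relative threshold is degenerate when a
  joint barely moves: its tiny velocity peaks would still define a
  "baseline" and the joint would rarely count as paused. A joint whose
  baseline falls below an absolute floor (default 1 °/s, well under any
  deliberate joint rotation) is therefore paused for its entire cycle.

The pair index is

$$D = 100 \cdot \frac{\#\{t:\ \text{exactly one of } a,b \text{ paused}\}}
      {\#\{t:\ \text{not both paused}\}}.$$

Frames where **both** joints are paused are excluded from numerator *and*
denominator: neither joint is "in motion" there, so such frames carry no
information about one-joint-at-a-time control. This convention is what
makes the analytic anchors exact on sampled data: two in-phase trajectories
give $D = 0$; a moving joint paired with a frozen one gives $D = 100$ even
though the moving joint itself has a few sub-threshold frames at its
velocity reversals (those frames are both-paused and drop out of the
base). If every frame is both-paused (all joints frozen) the index is
defined as 0. The index is symmetric, bounded in $[0, 100]$, invariant to
offsets and positive rescaling of either trajectory, and equals a direct
per-frame enumeration (a property the test suite checks against a
brute-force oracle).

### Filtering and velocities

Angle series are filtered with a second-order zero-phase Butterworth
low-pass (cutoff 6 Hz by default) before differentiation; the series is
demeaned and reflect-padded first, because `filtfilt` starts from zero
state and would otherwise leak start-up transients into short trials. On
*noise-free* synthetic signals the filter is counterproductive — it smears
an injected pause shorter than ~0.2 s below the detection threshold — so
closed-form recovery tests pass `filter_cutoff = NULL`. The pipeline
default stays at 6 Hz: real marker noise fragments the velocity signal into
spurious pauses without it.

## Gait events and cycles

Events are detected from marker coordinates (no force plates): **foot
contact** is the local maximum of the heel marker's anterior position
relative to the sacrum, **toe-off** the local minimum of the toe marker's
relative anterior position. The direction of progression is estimated as
the principal horizontal direction of sacrum displacement, so imported
trials need not be axis-aligned, and detection is invariant to lab-frame
translation and uniform speed. Candidate peaks must exceed the signal's
midrange and be separated by at least 0.4 s; additionally, the dominant
stride period is estimated from the signal's autocorrelation and peaks
closer than 0.55 of that period are merged, because impaired gait (e.g. a
hip that pauses just after contact) can plateau near an extremum and split
it into two candidate peaks. A gait cycle is the half-open frame interval
between two consecutive same-side contacts (1-based frame indices;
`[start, end)`), with incomplete first/last strides excluded and exactly
one toe-off kept per cycle. Cycles outside 0.4–3 s are flagged rather than
silently dropped.

## From markers to angles and metrics

Angles use a planar model in the progression (X–Z) plane: hip flexion is
the thigh's inclination from vertical, knee flexion the thigh–shank angle,
and the ankle angle the foot's pitch relative to the shank perpendicular
(dorsiflexion positive, plantarflexion negative; plantarflexion maxima are
reported as positive magnitudes). This is a deliberate simplification of a
full-body marker model: only sagittal angles feed the analysis.

Spatiotemporal definitions (per cycle, then stride-averaged): gait velocity
is the sacrum's horizontal path length over the cycle duration; step length
is the anterior heel-to-heel distance at each foot contact (ipsi- and
contralateral steps averaged); step width the mediolateral heel-to-heel
distance at the same contacts; double support the percentage of the cycle
with both feet in stance (from both sides' contact/toe-off sequences, and
reported as missing when contralateral events are unavailable); foot
clearance the peak swing toe height above the foot-flat stance baseline —
the *peak* definition is used because clearance magnitudes around
0.16–0.19 m are only consistent with peak toe height, not with minimum
clearance. Marker channels entering path-length and peak-height
computations are low-pass filtered first; summing raw noisy increments
inflates a 0.65 m/s velocity by roughly 17% at 2 mm marker noise, and the
maximum of an unfiltered noisy angle series is biased upward by 2–3°.

## The synthetic cohort

The generator's defaults emulate the study population this pipeline was
built for: 16 participants, four walking conditions (no assistance, AFO,
dorsiflexion-assist harness, full-assist harness), three trials of four
strides per condition, 100 Hz capture, self-selected speed 0.65 ± 0.25 m/s
with per-condition speed gains (+0.06, +0.07, +0.12 m/s for the three
assisted conditions), per-condition sagittal maxima means/SDs, foot
clearance 0.16–0.19 ± 0.02–0.05 m, and joint-pair pause targets of roughly
11–26% depending on pair and condition. Comfort ratings (0–10 visual
analog) are drawn with means 4.3/4.5/4.4 and SDs 2.9/2.3/2.3 for the three
assisted conditions.

Mechanics, in order:

1. **Waveform templates.** Each joint's healthy cycle is a fixed low-order
   harmonic sum (hip: 1 harmonic; knee and ankle: 2). Harmonic phases were
   chosen once so that (a) the heel-forward peak falls at the cycle
   boundary, (b) toe-off falls near 66% of the cycle (double support then
   averages ~30%), (c) plantarflexion peaks in pre-swing and dorsiflexion
   in stance/swing, and (d) the healthy template's decomposition lands
   inside the 5–10% window reported for unimpaired walking — a property of
   healthy gait the generator must reproduce, arising from how the three
   joints' velocity-reversal dwells overlap. Per-participant maxima rescale
   the templates (multiplicatively for hip/knee; affinely for the ankle so
   dorsi- and plantarflexion extrema hit their targets exactly on the
   sampled grid). Cycles are sampled on the half-open phase grid `[0, 1)`
   so tiled cycles are seamless and exactly periodic.
2. **Pause injection.** The configured pair-level targets are converted to
   per-joint pause fractions by solving the linear system
   $f_a + f_b = t_{ab}$ over the three pairs (non-negative for all default
   conditions), and each joint is frozen over a window at a fixed,
   pairwise-disjoint cycle phase (hip early stance, knee mid-stance, ankle
   swing — the last mirroring the absent dorsiflexion recovery of foot
   drop). The rest of the cycle is uniformly time-warped so duration and
   periodic continuity are preserved; measured pair indices then
   approximate the sum of the two joints' fractions plus the natural
   waveform dwell.
3. **Forward kinematics.** The pelvis advances at the trial speed; hip,
   knee, ankle, heel and toe markers follow from segment lengths (defaults
   0.42/0.43 m thigh/shank, 0.25 m heel-to-toe) and the sagittal angles,
   with the legs half a cycle out of phase and offset laterally by the step
   width. The whole leg chain is translated vertically per frame so the
   foot-sole minimum follows a prescribed profile — ground level through
   stance, a smooth bump peaking at the target clearance in mid-swing.
   Per-frame translation leaves every segment vector, hence every derived
   angle, untouched; it is the mechanism that lets the generator inject an
   exact clearance without solving inverse kinematics.
4. **Noise and reproducibility.** Stride-level angle offsets (0.5° SD) and
   i.i.d. Gaussian marker noise (2 mm SD) are added last. Each participant
   draws from an RNG stream derived from the master seed, so a cohort
   prefix is stable when the participant count changes, and a fixed seed
   reproduces the cohort bit for bit.

Ground truth recorded per trial: true speed, cycle length, per-cycle joint
maxima (from the emitted angle streams), injected joint and pair pause
fractions, clearance, and event frames. Event truth is computed from the
*clean* (pre-noise) markers with the same kinematic definition the detector
uses — the study's original events were identified manually, so no
independent event annotation exists; this convention makes noise-free
detection exact by construction and turns the noisy-detection test into a
genuine robustness check (observed: ≤ 3 frames at 2 mm noise).

What the generator does **not** emulate: frontal/transverse-plane motion,
circumduction or hip-hiking clearance strategies (clearance is injected in
the sagittal plane only), ground-reaction forces, stance-foot anchoring
(feet are not constrained to be stationary in stance — relative-coordinate
event detection is unaffected, but absolute foot trajectories are not
biomechanically exact), within-trial fatigue or cadence drift, and marker
occlusion/soft-tissue artifact beyond white noise. Passing recovery tests
on this cohort therefore demonstrates correctness of the *analysis chain*,
not validity on any particular clinical dataset.

## Statistics stage

Per-cycle values are averaged over cycles within a trial, then over trials
within a condition (unweighted at both levels), yielding one value per
participant × condition × metric. The condition comparison is a one-way
ANOVA treating each participant × condition mean as an independent
observation — with 16 participants and 4 conditions, df = (3, 60) — with
Tukey HSD contrasts and partial
$\eta^2 = SS_{\text{effect}} / (SS_{\text{effect}} + SS_{\text{error}})$
labeled small/medium/large at 0.02/0.13/0.26. This between-cells convention
reproduces the reference protocol's printed degrees of freedom; it ignores
the repeated-measures structure, which makes it conservative when
between-participant variance dominates. A repeated-measures variant
(`repeated = TRUE`, participant error stratum, df (3, 45)) is provided but
is not the default. In practice the distinction matters: with
between-participant speed SDs of ~0.25 m/s and condition gains of
~0.1 m/s, the between-cells ANOVA cannot flag velocity differences that
the repeated-measures variant finds easily; the decomposition metrics,
whose between-participant SDs are small, reach large effects under either
convention.

Normality is screened per metric with a one-sample KS test against a
normal with the sample's own mean and SD (estimated parameters make the
nominal p conservative — the Lilliefors caveat); the screen is advisory
and the pipeline proceeds parametrically regardless, matching the
reference protocol. Comfort scores are compared with three paired t-tests
at an adjusted α of 0.03, reproducing the protocol's stated Bonferroni
level verbatim (an exact 0.05/3 correction would be ~0.017; the
configuration key `comfort_alpha` accepts either).

Degenerate inputs are handled explicitly: a metric with zero variance
everywhere reports F = 0, p = 1, η² = 0; zero-variance paired differences
report t = 0, p = 1 with a `degenerate` flag; a zero-variance sample skips
the KS screen with a flag.

## Numerical and interface choices

* Frame indices are 1-based (R convention) with half-open `[start, end)`
  cycles throughout.
* The canonical trial format is a strict CSV dialect: a `#`-prefixed
  metadata block (`sample_rate`, `participant_id`, `condition`,
  `paretic_side`, `trial`, `units: m`), a `time` column, and
  `<marker>_<X|Y|Z>` coordinate triplets in meters. Deviations are errors,
  never guesses. TRC import/export is provided; C3D is not (binary format;
  no reader in the supported dependency set) and is rejected with an
  explicit message. Marker gaps up to 10 frames (100 ms) are linearly
  interpolated; longer dropouts are data-quality errors, since silently
  bridging them would corrupt velocity estimates.
* Pipeline stages communicate through files (trials → tidy per-cycle CSV →
  stats JSON/condition table), each stage writing a manifest with a config
  snapshot, seed, package version and file hashes; a fixed seed reproduces
  every analysis output byte for byte.
* Simulations in the test suite are sized to run on a single CPU in a few
  minutes: cohorts of 1–3 participants for recovery tests, one 16 ×
  4-condition cohort for the structural checks, 100-replicate Monte-Carlo
  checks for the KS screen, and 1000 replicates for the ANOVA type-I-error
  check.

## Known limitations

* The planar marker model cannot express frontal/transverse compensations;
  kinematic maxima and decomposition are sagittal only.
* The baseline-velocity interpretation (per-cycle peak) is one of several
  defensible readings of the source method; index magnitudes shift
  somewhat under a mean-velocity or trial-level reference, so comparisons
  should always state the convention.
* The 6 Hz default filter attenuates genuine sub-0.2 s pauses along with
  noise; studies of very brief freezing episodes should lower the cutoff
  or justify `NULL` on clean data.
* Reproducing the reference study's exact table values is out of reach by
  design: those numbers summarize 16 real participants whose recordings
  are not deposited. The package reproduces the *structure* (metric set,
  layout, df, effect-size conventions, healthy decomposition window), and
  its synthetic cohort matches the published summary statistics only in
  distribution.
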