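---
title: "Methods: image-based circadian locomotor analysis for fish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based circadian locomotor analysis for fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishrhythm)
```

## The measurement problem

Circadian locomotor rhythms in small fish are typically assayed by filming
animals in a bank of tanks over repeated light–dark (LD) cycles — one short
recording per hour (conventionally 1 min at 30 fps under a 12:12
photo-regimen) — and reducing each recording to a per-interval activity
score. Two image-based readouts are in common use:

* **Pixel activity** (frame differencing): the number of pixels whose
  intensity changes by more than a threshold between adjacent frames,
  summed within each tank's region of interest (ROI). Cheap, robust, fast;
  yields a single activity unit with no per-animal resolution.
* **Trajectory kinematics**: per-fish coordinates are extracted frame by
  frame (background subtraction, blob detection, identity linking) and
  reduced to standard endpoints — swimming speed and distance, angular
  velocity, meandering, and the freezing/swimming/rapid time–movement
  ratios.

`fishrhythm` implements both backends plus the circadian aggregation and
comparison statistics, and — because no public recordings accompany this
protocol class — a fully ground-truthed synthetic generator so every stage
is testable end to end.

## Coordinate and intensity conventions

Frames are 8-bit grayscale, origin top-left, x rightward, y downward,
0-based pixel coordinates; ROIs are half-open rectangles `[min, max)`.
RGB input is collapsed with ITU-R BT.601 luma weights
(0.299 R + 0.587 G + 0.114 B). Uncompressed AVI and uncompressed multi-page
TIFF are supported natively (both codecs are implemented in the package,
byte-validated against an independent third-party writer); compressed
codecs are rejected with an explicit error, mirroring the requirement that
recordings be transcoded to uncompressed AVI before analysis. Image stacks
carry no frame-rate metadata, so `read_frames()` demands an explicit `fps`
for TIFF — every kinematic quantity scales with it, and a silent default
would be a silent unit error. PNG directories are *not* supported: base R
exposes no zlib stream codec and no PNG package is assumed, so the two
formats above are the supported dialects.

## Pixel-activity backend

For adjacent frames $F_t, F_{t+1}$ and ROI $R$:

$$A_t = \#\{p \in R : |F_{t+1}(p) - F_t(p)| > \tau\}, \qquad \tau = 20$$

The threshold default of 20 (8-bit units) is a configuration knob, not a
claim: the original macro's threshold is not public. A per-interval scalar
is the mean count per frame pair, so interval length never rescales the
metric. Optional denoising is a single 3×3 median filter applied before
differencing — the minimal remedy for one-pixel "dark-line" acquisition
artefacts, which the synthetic renderer can inject on demand (`artifact =
"dark_lines"`); the filter is implemented exactly (median-of-medians
decomposition, verified against a direct oracle) and removes one-pixel
stripes completely while barely touching multi-pixel fish blobs.

## Tracking backend

1. **Background**: per-pixel temporal median over ≤ 25 frames evenly spaced
   across the recording. This assumes each pixel is fish-free in more than
   half the sampled frames; a fish that rests in one spot for most of a
   recording is absorbed into the background and becomes undetectable (see
   *Limitations*).
2. **Segmentation**: foreground is `|frame − background| > 30`; 8-connected
   components within each ROI with area in `[10 px, 10% of ROI]` become
   detections at their intensity-weighted centroids. If a tank yields more
   blobs than its expected fish count, the largest are kept.
3. **Linking**: within each tank, detections are assigned to tracks by
   minimum-total-distance matching (exhaustive over permutations for ≤ 4
   fish — the chamber holds 3 — greedy beyond), rejecting assignments
   farther than `max_jump × (gap + 1)` cm. Tracks may coast up to
   `max_gap = 5` frames; such gaps are filled by linear interpolation and
   counted in `n_interpolated`; longer gaps hold the last position.
   Exactly `expected_fish` full-length trajectories come back per tank, so
   every fish shares one time base.

Identity is maintained by **proximity only** — appearance-based
fingerprinting of individual fish is deliberately out of scope. Within-tank
identity swaps between similar fish leave tank-level circadian aggregates
unchanged, which is the quantity this pipeline consumes. The kinematics
stage also accepts externally produced coordinate CSVs
(`frame, tank_id, fish_id, x_cm, y_cm, interpolated`), so output from a
dedicated identity-preserving tracker can be analyzed directly.

## Kinematic endpoints

With positions in cm and $v_i = \|p_{i+1}-p_i\| \cdot \mathrm{fps}$:

* total distance $\sum v_i/\mathrm{fps}$; average speed $\bar v$;
* turning angle $\theta_i$: signed angle between successive headings,
  in $(-180°, 180°]$, undefined when either segment is below
  `displacement_epsilon` (a motionless fish has no heading);
* average angular velocity $\overline{|\theta|}\cdot\mathrm{fps}$ (deg/s),
  over defined angles — absolute values, because fish turn both ways and
  signed means cancel;
* meandering $\sum|\theta_i| / \text{distance}$ (deg/cm), i.e. path
  tortuosity; the per-step $\omega/v$ alternative is unstable at low speed
  and was rejected. Reported as 0 with a degeneracy flag when total
  distance is below epsilon;
* time–movement ratios: fractions of steps with $v < v_\mathrm{freeze}$
  (freezing), $v_\mathrm{freeze} \le v \le v_\mathrm{rapid}$ (swimming),
  $v > v_\mathrm{rapid}$ (rapid). They partition every trajectory, so they
  sum to exactly 1.
* sleep-like bouts: maximal runs of steps with $v < v_\mathrm{freeze}$
  whose duration **strictly exceeds** 5 s. The 5 s criterion is the
  operational definition of sleep-like quiescence in zebrafish; the strict
  inequality means a bout of exactly 5.0 s does not count.

Defaults $v_\mathrm{freeze} = 1$ cm/s and $v_\mathrm{rapid} = 10$ cm/s
follow common adult-zebrafish convention; the underlying protocol does not
state its cutoffs, so both are configuration, recorded in every output
table. Scaling space by $k$ scales distance and speed by $k$, leaves angles
unchanged and scales meandering by $1/k$; rigid motions and time reversal
leave all endpoints unchanged — these invariances are tested.

## Circadian assembly and statistics

Samples are labelled by clock time: light iff $t \bmod 24 \in
[\text{on}, \text{off})$ — half-open at both transitions (a sample exactly
at lights-on is light). Classification is by strict phase-mean comparison:
diurnal iff the light mean exceeds the dark mean, `ambiguous` on an exact
tie.

* **Min–max normalization** to $[0, 100]$ % per data set puts the two
  backends' incommensurable units on one scale; constant series are a hard
  error (the rule is undefined there), and the transform is invariant to
  positive affine rescalings of its input.
* **Spearman correlation** uses average ranks for ties; the two-sided p is
  exact by full enumeration of all $n!$ rank permutations for $n \le 8$
  and the $t$ approximation on $n-2$ df beyond.
* **Welch's unpaired t** with Satterthwaite df is used for two-sample
  contrasts — the two backends' units make equal-variance assumptions
  untenable.
* **Dunnett many-to-one comparisons** use pooled-variance t statistics
  against the control and a *seeded Monte Carlo* null for the family-wise
  adjusted p: groups are redrawn under equal means, and the adjusted p of
  group $i$ is the tail probability of the null maximum $|t|$ at
  $|t_i|$ (with the standard $+1$ correction). The statistics are pivotal,
  so the draw is exact up to Monte Carlo error; `mc_reps` defaults to
  100,000. Calibration is verified empirically: family-wise type-I error
  over 2,000 null replicates lies in $[0.04, 0.06]$ at nominal 0.05. The
  multiplicity property (adjusted p ≥ marginal p) is asserted against the
  marginal p of the *same* pooled statistic — against a Welch marginal it
  is not a theorem, since Welch p can exceed pooled p under variance
  heterogeneity.

How per-fish values pool into group statistics (fish as unit vs tank as
unit) is not fixed by the protocol; the pipeline emits per-fish, per-tank
and chamber-level series so either aggregation can be used; the
chamber-level mean is what `summarize_study()` reports.

## The synthetic world

The generator states one fixed world; its defaults were chosen once, from
the protocol's stated conditions plus field-typical values, and are not
adjusted to test outcomes:

* geometry: six 20 × 10 cm tanks, three fish each, 30 fps, 12:12 LD,
  one recording per hour;
* behaviour: a two-state (active/quiescent) continuous-time Markov chain,
  discretized at frame resolution, with phase-dependent exponential dwell
  times — diurnal: light 60 s active / 3 s quiescent dwells at 6 cm/s mean
  active speed (lognormal, σ\_log 0.4); dark 4 s / 20 s at 3 cm/s, giving
  an expected dark-phase mean speed ≈ 0.5 cm/s and quiescence bouts whose
  bulk exceeds the 5 s sleep criterion. The nocturnal profile mirrors the
  phases. Active motion is a correlated random walk (wrapped-normal turns,
  σ = 30°/frame) with reflecting walls (implemented by folding the
  unconstrained walk — fish live in tanks, not on tori); quiescence is a
  0.05 cm/s isotropic jitter (resting fish hold station but are not
  pinned);
* rendering: fish are anti-aliased dark disks (radius 4 px ≈ 1 cm at the
  default 4 px/cm) on a bright background (intensities 30 on 200),
  additive Gaussian noise σ = 3 — an IR-illuminated light-box scene is
  high-contrast and low-noise — plus optional dark-line artefacts;
* reproducibility: one RNG stream per fish derived from
  `(seed, tank, fish)`, so adding fish never perturbs existing ones; all
  RNG happens inside scoped seeds that restore the caller's state.

What a green test establishes — and what it does not: the synthetic world
has no shoaling, no wall preference, no photorealistic appearance, no
hydrodynamics, and its within-phase hour-to-hour variation comes only from
the stochastic behaviour model. Passing tests demonstrate the *pipeline*
measures that world faithfully; they cannot certify behaviour of real fish
or a specific camera.

## Numerical and design choices

* Pixel-to-cm calibration is a required config input; the camera geometry
  is unknowable from video alone.
* Frame-difference counts are symmetric in frame order and invariant to a
  brightness offset shared by both frames; tracking is likewise invariant
  to offsets shared by frame and background.
* Welch p on identical samples is exactly 1; Spearman on constant input is
  a hard error, not NA.
* The Dunnett null is redrawn per call from the user's `seed` argument;
  determinism is contractual and tested.
* Interpolated trajectory entries are flagged (`n_interpolated`, per-frame
  `observed`) so QC can reject heavily-coasted tracks.

## Scaling of heavy validations

To keep the validation suite inside a small CPU budget, video-rendering
tests use 10 s recordings instead of the chamber's 60 s (24 + 24 hourly
videos for the cross-method criterion) and the many-seed classification
property runs 20 seeds × 24 five-second intervals per profile rather than
100 seeds of full-length recordings; trajectory-level recoveries (speed,
quiescent fraction) use the full 1 h of frames, where the generator's 5%
tolerance is comfortably met. None of the scaled checks had its acceptance
threshold altered.

## Limitations

* **Median-background blindness**: a fish quiescent through most of a
  recording is absorbed into the background and yields no detections; the
  study pipeline scores such all-missing trajectories as stationary
  (speed 0), which is the correct circadian reading of "never moved enough
  to be seen" but underestimates any residual micro-movement. Ghost blobs
  (background contaminated at a vacated resting spot) can also appear in
  the rest phase.
* **Proximity identity**: when two fish blobs merge and split, labels can
  swap and brief centroid excursions occur. Tank-level aggregates are
  unaffected, but per-interval tank-mean speed through the proximity
  linker carries merge noise on the order of a few tenths of a cm/s —
  comparable to the *within-phase* hour-to-hour signal of the synthetic
  world. Cross-method validation therefore feeds the kinematics backend
  from coordinate tables (the idTracker-style CSV route); tracker accuracy
  is certified separately on non-approaching fish.
* The frame-differencing count saturates once per-frame displacement
  exceeds the fish diameter (≈ 60 cm/s at default geometry) — far above
  the simulated regime, but relevant for very fast species or low frame
  rates.
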