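---
title: "Kinematic analysis of marker-based motion capture in mice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic analysis of marker-based motion capture in mice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocapkit)
```

# The measurement problem

Marker-based motion capture of freely moving mice yields, per trial, a set
of 3D marker trajectories (mm, 300 frames/s in the recordings this package
is designed around) with occasional missing samples where a marker was
occluded, rare short reconstruction glitches, and a sub-millimeter noise
floor. `mocapkit` implements the analysis chain from raw labeled
trajectories to behavioral kinematics:

1. **repair** — linear interpolation of short tracking gaps and removal of
   short transient glitches ("jitter");
2. **quality** — marker visibility, gap-duration distributions,
   triangulation-residual summaries, and tracking error against marker
   pairs implanted at known separations;
3. **locomotion** — hip-midpoint reference speed, locomotory-episode
   segmentation, whole-trial summaries, motion relative to a moving
   substrate (treadmill belt, climbing wheel), head-plane orientation;
4. **motion index** — the average instantaneous speed of all markers, a
   whole-body activity measure that resolves sub-millimeter movements
   during behavioral stillness, with a noise-floor sensitivity sweep;
5. **swings** — limb-swing detection in three locomotor contexts and five
   per-swing kinematic measures plus peak-speed timing;
6. **tremor** — band-limited spectral decomposition, automatic tremor-band
   detection, Hilbert amplitude/phase, and cross-marker amplitude/phase
   correlation matrices.

Conventions: z is vertical (up), units are mm and seconds, frame indices
are 0-based and intervals half-open `[start, end)`, time is always
`frame / frame_rate`. A missing frame carries `NA` coordinates and is never
interpreted as the origin.

# Trajectory repair

Repair is deliberately minimal, because aggressive smoothing can destroy
the very features (tremor, micro-movements) the pipeline exists to
measure. Two operations only:

* **Gap filling** (`fill_short_gaps()`): interior gaps strictly shorter
  than 50 frames (~165 ms at 300 fps) are bridged per axis by linear
  interpolation between the flanking observed samples. Longer gaps and
  gaps touching the trial boundary stay missing. Interpolated frames are
  flagged, and per-swing kinematics refuse to use events that overlap
  them — bridged data keeps windowed speed estimates defined but must not
  masquerade as measured limb positions.
* **Jitter removal** (`remove_jitter()`): a jitter event is a localized
  deviation exceeding 0.05 mm in peak prominence lasting at most 3 frames
  (~10 ms). Each axis is screened separately on its residual against a
  9-frame running median: the running median is immune to deviations up to
  3 frames wide but absorbs anything wider, so 5-frame bumps — potentially
  real movement — are invisible to the detector by construction. Detected
  frames plus their immediate neighbors are replaced by linear
  interpolation. Per-axis screening was chosen (the alternative being the
  3D displacement magnitude) because reconstruction glitches are usually
  axis-specific and per-axis residuals are the more sensitive test. The
  operation is idempotent, and events abutting missing data are skipped
  rather than interpolated across a gap.

# Tracking quality

`quality_report()` aggregates per-frame visible-marker fractions,
per-marker visibility percentages, gap-duration ECDFs, residual summaries
and known-distance tracking error, each split into locomotory vs
stationary frames. Choices that the quality metrics pin down explicitly:

* a frame is *locomotory* when it lies inside a detected locomotion
  episode; a gap belongs to the state of its **start** frame;
* percentiles use the linear-interpolation definition
  (`stats::quantile`, type 7);
* the tracking error of a marker pair at known distance $d$ is
  $|\,\lVert p_a - p_b\rVert - d\,|$ per frame, and the per-marker error
  is half the pairwise error (both markers assumed to contribute
  equally);
* spatial maps bin a per-frame metric over the arena by the hip-midpoint
  position; the missing-marker-count variant first smooths counts with a
  100-frame moving average. Unvisited bins are empty (`NA`), never zero.

Tracking consistency ("what fraction of markers is visible in almost
every frame") is summarized as the 5th percentile of the per-frame visible
fraction, i.e. the fraction exceeded in 95% of frames — the lower tail is
the informative one for a quantity whose median saturates near 1.

# Locomotion

The body reference point is the midpoint of the two hip markers. Speed is
a centered windowed estimate: displacement between the window's endpoint
frames divided by the window duration. Two windows are used on purpose:
a 100-frame (~300 ms) window for episode detection, where temporal
resolution of onsets matters, and a 1 s window for reported locomotion
speeds, where stability matters. Both are configurable
(`pipeline_config()`).

A **locomotory episode** is a maximal interval with speed above 40 mm/s,
tolerating interior sub-threshold dips of at most 50 frames, with a total
duration of at least 100 frames. Episodes begin and end on
supra-threshold frames (the dip tolerance is interior only), and the
100-frame minimum counts dips, matching the plain reading of "faster than
40 mm/s for a minimum of 100 frames, allowing for brief dips". Undefined
speed counts as sub-threshold.

For treadmill and wheel trials, body motion is first re-expressed
relative to the substrate (`surface_relative()`):

* **belt**: the belt axis is the principal horizontal direction of the
  belt markers' displacement; the belt's translation is the per-frame mean
  displacement of visible belt markers along that axis, accumulated over
  time. Markers hand off naturally as they enter and leave the view
  because each frame's estimate uses whichever markers are visible at
  both ends of the step.
* **wheel**: the wheel plane and axis are fitted to the pooled rim-marker
  cloud (total least squares), the center and radius by an algebraic
  circle fit; the wheel's angular displacement is the mean wrapped
  angular step of visible rim markers, and body markers are rotated back
  by it about the fitted axis.

Frames with no usable surface marker are flagged undefined rather than
assumed static. Zero substrate motion leaves trajectories unchanged.

Head orientation (`head_orientation()`) fits a plane through headplate
corner markers per frame (SVD), projects the front-minus-back direction
into it, and reports z-y'-x'' Euler angles in degrees: yaw about vertical,
pitch positive nose-up, then roll about the forward axis. Frames with
fewer than three visible markers or a collinear configuration are
undefined.

# Motion index

The motion index (MI) is the mean windowed speed (10 frames, ~33 ms) of
all markers visible at a frame. Missing markers are excluded from the
average rather than invalidating the frame — occlusion of a single leg
marker should not erase the measurement. MI of a rigid translation equals
the translation speed for any marker count, which the tests assert.

The noise-floor sweep (`noise_floor_sweep()`) asks how small a detectable
movement must be for a group difference in stationary micro-movement to
remain resolvable: displacements below a floor f are clamped **to** f
(modeling a sensor that reports nothing smaller than its resolution;
discarding them instead would change sample sizes and conflate power with
resolution), and a two-sided Wilcoxon rank-sum p-value is recomputed per
floor. `project_residual_2d()` converts a 3D isotropic residual r to its
in-plane equivalent r·sqrt(2/3) for comparing against planar-video noise
floors. The 2D/3D choice for MI itself is exposed as `dims` (default 3D).

# Swing detection and kinematics

Treadmill locomotion is continuous, so the vertical ankle trajectory is
cleanly periodic: swings are the intervals between consecutive local
minima of z (`detect_swings_treadmill()`). Minima need a minimum
prominence (default 1 mm, suppressing tremor-scale ripples) and a minimum
separation (default half the stride period, estimated from the dominant
frequency of the vertical signal itself). Detection runs on a 5-frame
moving average; all metrics use raw samples.

Open-field and climbing locomotion are intermittent and interleaved with
non-locomotor limb movements, so vertical position alone is unreliable.
`detect_swings_accel()` computes 3D ankle speed over a 30-frame (~100 ms)
window, finds stretches above an adaptive threshold (mean + 1 SD of the
defined samples — the paper-scale constant is unstated, so the threshold
adapts to each trial), and delimits each stretch by the acceleration peak
preceding its fastest frame and the deceleration peak following it. The
rationale is mechanical: a locomotory step requires propulsion, hence a
distinct acceleration event, and ends with braking. Overlapping
candidates are merged.

Per-swing measures (`swing_metrics()`): duration; mean and maximum
frame-by-frame speed; height — the vertical extent for OF/TRM, or for
climbing the amplitude along the second principal component of the
swing's own centered 3D point cloud, which is invariant to the animal's
orientation around the wheel (asserted under random rotations); distance
(start-to-end straight line); path length (summed frame steps, always ≥
distance); and the signed offset of the peak-speed frame from the
vertical peak frame. Any swing containing missing or interpolated frames
is flagged invalid with NA measures.

# Tremor decomposition

Per marker and axis, on the longest stretch where all analyzed markers
are simultaneously visible:

1. **PSD**: Welch-averaged periodogram (Hann window, 2 s segments, 50%
   overlap, mean-detrended), restricted to 6–18 Hz. Segment averaging
   trades frequency resolution (0.5 Hz bins) for a stable curve, which
   the band-finding derivative needs.
2. **Smoothing**: smoothing spline with the penalty chosen by generalized
   cross-validation (`stats::smooth.spline`) — the parameter-free reading
   of an "automatically selected smoothing factor"; output clipped at 0.
3. **Band detection** (`find_tremor_band()`): from the global peak, walk
   outward; a boundary falls where the spectral derivative's magnitude,
   having first risen onto the peak's flank, drops below 10% of its
   maximum. If this yields an empty, inverted, or sub-2-bin band
   (e.g. when a sharp satellite peak owns the maximum derivative), the
   fallback takes the local minima flanking the peak. A spectrum with no
   interior maximum has no band, and all downstream tremor quantities for
   that series are reported as absent rather than zero.
4. **Amplitude/phase** (`band_hilbert()`): 4th-order Butterworth band-pass
   applied forward–backward (zero phase — mandatory for the phase series
   to mean anything), then the analytic signal via FFT; amplitude is its
   modulus, phase its argument. The first and last 0.5 s are flagged
   edge-unreliable and excluded from summaries and correlations.
5. **Windowed amplitude**: 150-frame (~500 ms) moving average.
6. **Correlations** (`tremor_correlations()`): amplitude — Pearson
   correlation of amplitude series; phase — the Fisher–Lee circular–
   circular correlation coefficient, computed with its O(n)
   trigonometric-moment identity. Linear correlation of wrapped angles is
   ill-defined; the circular coefficient is the defensible default (note
   that a constant phase offset, including antiphase, gives +1 — the
   statistic measures phase *locking*, not offset sign).

`tremor_summary()` averages amplitude across windows, axes and markers,
and splits amplitude by movement state at a 10 mm/s reference-speed
threshold.

# The synthetic generator

`generate_trial()` produces trials with exact ground truth — the package's
test bench. It emulates: intermittent locomotion as an alternating
exponential walk/pause renewal process (means 2 s / 3 s, 150 mm/s — a
typical exploratory gait speed) with a smoothly ramped speed profile and
wall reflection in a 300 mm arena; stance/swing ankle cycles as
raised-cosine vertical arcs with a cos²-pulse horizontal propulsion whose
peak-speed timing is configurable (so the three context-dependent timing
regimes can each be simulated); whole-body tremor as an additive sinusoid
with per-marker amplitudes and phase offsets (default 10 Hz, 0.2 mm —
mid-range of the classic 8–12 Hz band and of the 0.1–0.3 mm oscillations
seen in resting-body markers); an 8 Hz, 0.15 mm breathing oscillation on
the shoulder markers; 0.01 mm white positional noise (frame-to-frame
tracking noise is far smaller than the ~0.35 mm slowly varying accuracy
error, which the rigid-pair metrics address separately); and injected
occlusion gaps and ≤3-frame, 0.1 mm glitches whose exact positions are
returned as ground truth.

Layout: ten markers in five lateral pairs spaced exactly 14 mm apart
(shoulders, lumbar, hips, knees, ankles), with the ankle marker 14 mm and
the knee marker 28 mm above the heel — the implant geometry. Pair
distances are exact before noise, which pins the tracking-error metric to
zero on noiseless fixtures.

Two deliberate design points:

* **Treadmill gait is continuous**: cycles tile the trial, so the
  between-minima swing definition is well-posed and each cycle boundary
  is a sharp vertical minimum; the cycle phase is shifted so the first
  and last troughs fall in the trial interior. Open-field gait instead
  uses arcs separated by stance plateaus, which is what the
  acceleration-peak detector is for.
* **Episode ground truth** is defined by applying the (fixed,
  paper-specified) 40 mm/s / 100-frame / 50-frame-dip rule to the
  noise-free reference trajectory. The segmentation rule *is* the
  definition of an episode, so the noise-free segmentation is the correct
  truth for testing noise robustness; the correctness of the
  segmentation function itself is established separately against an
  independent fixed-point merging oracle.

What the generator does **not** emulate: skeletal biomechanics and joint
constraints, camera geometry and view-dependent occlusion, skin slippage,
marker-quality degradation over sessions, or behavioral variety
(grooming, rearing, sniffing). Passing recovery tests on synthetic trials
therefore demonstrates that the estimators invert the generative model
they were designed for at realistic noise levels — not that real mouse
data are this clean. The quality-metrics module exists precisely because
real recordings must document their own noise.

# Numerical choices and degenerate inputs

* Windowed quantities are NA wherever the window is incomplete or an
  endpoint is missing; summaries average over defined frames only.
* `detect_locomotion_episodes` treats NA speed as sub-threshold.
* Peak finding uses topographic prominence with ties broken toward the
  earlier frame; NA samples split the signal into independent stretches.
* The Welch PSD is scaled so a sinusoid of amplitude A integrates to
  A²/2 over the band (one-sided density, Hann-corrected).
* `smooth_spectrum` requires ≥ 8 bins; `power_spectrum` requires ≥ 2 s of
  signal; `band_hilbert` rejects bands touching 0 or Nyquist.
* Correlation entries for constant series are NA, flagged rather than
  silently zero; `noise_floor_sweep` returns p = 1 by convention when
  clamping makes both groups identical.
* Trials whose markers are never simultaneously visible for ≥ 2 s cannot
  be tremor-scanned and fail with an explicit error.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run on synthetic trials of 5–60
seconds at 300 fps (1,500–18,000 frames, 10 markers), 100 randomized
oracle instances of up to 2,000 frames per operation, and Monte-Carlo
checks of a few times 10⁵ draws. These sizes were chosen so every
statistical assertion has comfortable margins while the whole suite stays
fast enough to run on every change.

# Known limitations

* The accel-peak swing detector's adaptive threshold assumes each trial
  contains both stance and swing; a trial that is one long swing would
  mis-set the threshold.
* Belt correction assumes a straight belt axis; wheel correction assumes
  a rigid, circular rim with markers on it.
* The tremor band finder reports at most one band per series (the one
  around the global peak); genuinely multi-band oscillations are not
  decomposed.
* Phase correlations quantify locking, not directionality; lead/lag
  analysis would need cross-spectral phase, which is out of scope.
* The TSV exchange dialect is this package's convention; no proprietary
  capture formats are parsed.
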