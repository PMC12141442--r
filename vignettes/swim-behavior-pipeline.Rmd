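---
title: "From pose tracks to seizure ethograms: the swimetho pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pose tracks to seizure ethograms: the swimetho pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimetho)
```

## The problem

Convulsive seizures in larval zebrafish unfold as a stereotyped behavioral
progression: sporadic swimming gives way to sustained fast swimming along
the well perimeter ("whirlpool"), then to fast sinusoidal whole-body
convulsions with extreme tail bends, often ending with the larva on its
side (posture loss). Scoring this progression by eye does not scale to a
96-well plate, and single-point tracking misses the postural signatures
(tail curl, eye visibility) that distinguish the stages.

swimetho analyzes 8-key-point pose tracks of individual larvae recorded at
high frame rate (nominally 160 frames/s, 48,000 frames per 5-minute
epoch). It turns raw key-point coordinates into cleaned kinematic series,
a pixel-change activity score, egocentrically aligned feature windows, a
supervised five-class behavior classifier, and per-larva ethograms. A
built-in behavior simulator generates labelled tracks with the same
kinematic regimes, so every stage is testable without recorded video.

## Conventions

One coordinate convention is stated once and used everywhere: frames are
indexed from 0, coordinates follow the raster convention (origin top-left,
x rightward, y downward), and "up" is the negative y direction. The
canonical analysis unit is mm; pixel input is converted on load with
`mm_per_px` (default 0.0249 mm/px: a 6.38 mm well diameter — from the
0.32 cm&sup2; circular well area — spanning 256 px). Angular quantities are
reported counterclockwise-positive in a y-up frame; the raster y axis is
sign-flipped once, inside the angle computations.

The skeleton maps indices 0-7 to
`snout, eye_left, eye_right, rostral_trunk, center, caudal_trunk,
mid_tail, caudal_fin`. Only the five roles `snout`, both eyes, `center`
and `caudal_fin` carry semantics; the remaining midline names are a
package convention and the mapping is configurable
(`skeleton_spec()`). The centre of mass (COM) is the mean of the six
non-eye midline points — the eye points sit rostrally and would bias it.

Frames that fail any quality rule are masked invalid and excluded;
nothing is ever interpolated.

## Activity metric

For sequential frames, a pixel counts toward the activity score iff its
change is large both relative to its brightness and absolutely:

$$A_i = \sum_{x,y} \Big[ \tfrac{2\,|P_i - P_{i-1}|}{P_i + P_{i-1}} > T \Big] \cap \Big[ |P_i - P_{i-1}| > D \Big]$$

with `T = 0.1` and `D = 20` by default, both comparisons strict. Pixels
where the denominator is zero contribute nothing: the conjunction already
fails on the absolute condition, so no epsilon is needed. Arithmetic runs
in doubles so unsigned wraparound cannot occur. Total activity is the sum
over the epoch; larvae whose TP2 total falls strictly below 20,000 pixels
are flagged for exclusion (`flag_inactive()`) — in practice this
identifies larvae that did not survive treatment. Display uses
`log10(x + 1)`; the stored metric is linear counts.

## Cleaning cascade

`clean_track()` applies, in order:

1. **Speed gate** (`speed_max`, default 120 mm/s, the empirical ceiling of
   real larval swimming in a well): a frame is removed when the COM
   displacement from the *previous valid frame*, divided by the elapsed
   time across the actual frame gap, exceeds the limit. The gap-aware
   denominator means an already-removed frame cannot fabricate an
   apparent speed; the first valid frame is never removed.
2. **Well gate**: the center key-point strictly outside the circular well
   (closed-disk convention) removes the frame.
3. **COM gate**: any key-point further than `com_factor` (default 0.7)
   times the body length from the frame COM removes the frame. Body
   length defaults to the median midline polyline length over valid
   frames.
4. **Wavelet denoising**: each of the 16 coordinate series is denoised
   per contiguous valid segment (no bridging across removed frames, so
   discontinuities are not smeared).

A frame failing several rules is attributed to the first gate that fires.
Gates only ever set valid frames invalid.

### Denoising details

No wavelet machinery fitting this task is available among the package's
dependencies, so the transform is implemented here: a periodized
orthogonal multilevel DWT (sym4 by default; db4 and Haar are also
provided), verified by exact-reconstruction and energy-preservation
tests. Noise scale per feature is the classic MAD estimate on the
finest-level detail coefficients (median absolute deviation / 0.6745);
`estimate_sigma_batch()` averages the per-feature estimates across the
tracks of an acquisition. Shrinkage is soft thresholding at the universal
threshold $\sigma\sqrt{2\log n}$, applied to the *finest two* detail
levels only: white tracking jitter concentrates there (and that is where
sigma is estimated), while coarser bands carry the behavioral signal. For
violently convulsing larvae the finest bands contain genuine movement
harmonics, so the MAD estimate is biased upward; limiting the thresholded
bands bounds the resulting distortion. Constant segments and
`sigma = 0` pass through unchanged; segments shorter than twice the
filter length are returned unchanged with a warning. Series lengths that
are not a power-of-two multiple are end-reflected and trimmed after
reconstruction.

Because shrinkage can still perturb coordinates near segment boundaries,
the three gates are re-checked once on the final coordinates; any extra
removal keeps its rule attribution. This guarantees that no cleaned track
reports a speed above the gate, and makes cleaning idempotent (a second
pass removes nothing).

## Kinematics

All metrics share one frame index (`kinematic_series()`):

- **Speed** (mm/s): COM displacement over the gap-aware elapsed time;
  undefined on the first valid frame. Total distance is reported in m.
- **Tail angle** θ (deg, 0-180): unsigned angle between the tail vector
  (center → caudal fin) and the *caudal extension* of the body axis
  (snout → center). The extension convention is forced by the anchors: a
  straight larva reads 0°, a fully curled larva whose tail tip touches
  the snout reads 180°.
- **Heading change** (deg, wrapped to (−180, 180]): frame-to-frame
  rotation of the heading vector, which points center → snout — the
  direction the animal faces. Both signed values and magnitudes are
  emitted, since distribution summaries are usually taken on magnitudes.
- **Inter-eye distance** d (mm): Euclidean distance between the eye
  points, ≈ 0.2 mm upright and ≈ 0 when the larva lies on its side —
  the posture-loss proxy.

These are invariant under global rigid motion, scale correctly with the
calibration, and are verified against closed forms (e.g. circular motion
recovers the tangential speed $r\omega$ up to the chord-sampling factor
$\sin(x)/x$, below 0.5% at 160 fps).

## Windows, alignment, features

Tracks are cut into overlapping 60-frame windows (0.375 s at 160 fps),
default stride 15 frames — the stride is a package choice; only the
window length and overlap are fixed by the design. Windows containing any
invalid frame are dropped, not patched.

Egocentric alignment computes **one** rigid transform from the first
frame — a rotation about the first frame's center key-point taking its
heading to canonical up, then a translation of that center to the
origin — and applies it identically to all 60 frames. Later frames are
deliberately not re-canonicalized: within-window motion is the signal.
The pivot choice (first-frame center key-point) is a package convention.
Aligned windows flatten frame-major to vectors of length
60 × 8 × 2 = 960.

Feature vectors are centred by the per-feature training mean and divided
by the maximum absolute value *after* centring (zero-spread features
divide by 1) — "divide by the maximum" is ambiguous about ordering, and
post-centring maxima make the divisor a genuine scale. PCA retains the
smallest component count reaching 95% cumulative variance. Normalizers
and basis are fitted on the training split only and applied unchanged to
any other split, so test contamination is structurally impossible
(`fit_pipeline()` / `predict()`).

## Classifier and evaluation

`balanced_test_split()` draws 90/10 per class, balances the test set at
the smallest class's test count, and returns surplus test clips to
training. `fit_behavior_classifier()` trains a random forest (1,000
trees), k-nearest-neighbour, or RBF support-vector classifier on the
projected features. "Trained for one thousand iterations" maps to 1,000
trees for the forest; the SVC optimizer runs to convergence (its
interface exposes no iteration cap) and KNN has no training iterations —
stated rather than faked. Hyperparameter search is a small documented
grid under fixed seeds, not a mass sweep.

Evaluation reports the confusion matrix (rows = true, columns =
predicted), per-class precision TP/(TP+FP) and recall TP/(TP+FN), macro
averages, and an F1 computed literally from the confusion-matrix sums:
diagonal total over (diagonal total + half of both off-diagonal totals).
For single-label classification the two off-diagonal totals coincide, so
this F1 *equals overall accuracy* — the identity is asserted numerically
over random matrices in the test suite. The harmonic macro-F1 is reported
alongside (`macro_f1()`) because "average F score" is ambiguous between
the two.

## Ethograms

Per-frame labels come from majority vote over the covering windows; ties
break toward the *less severe* class in the fixed order stationary <
normal swim < whirlpool < convulsion < posture loss, so overlap
resolution cannot inflate seizure calls. Frames covered by no retained
window are "unscored"; class fractions are computed over scored frames
and sum to 1.

## The simulator

`simulate_motif()` builds an 8-point larva from a 4 mm body (a typical
larval length): a straight rostral axis with the three caudal segments
hinged at the center key-point by the programmed tail angle. A hinged
tail realizes the *measured* tail angle exactly — the measurement
compares the snout→center axis with the center→caudal-fin chord — which
a whole-body constant-curvature arc would not; exact realization is what
makes the parameter-recovery tests sharp. Eyes sit ±0.1 mm lateral of the
snout axis, collapsing to ~0 under posture loss.

Class regimes: stationary (jitter only), normal swim (150 ms half-sine
bursts peaking at 30 mm/s alternating with 350 ms decaying glides —
burst-and-glide at sub-50 mm/s speeds), whirlpool (perimeter orbit,
default 70 mm/s on a 2.5 mm radius), convulsion (150° tail oscillation at
10 Hz with speed bursts to 120 mm/s; such larvae steer wider of the wall
because the folded tail swings the trunk points far from the COM), and
posture loss (near-static, eyes collapsed). Positional jitter is
isotropic Gaussian, default sd 0.02 mm — below typical pose-estimation
error, keeping classes separable by construction. Everything is
deterministic under a seed; the generator returns its ground-truth
per-frame speed, tail angle and inter-eye distance so recovery can be
asserted.

What the simulator does *not* emulate: real pose-estimation error is
neither isotropic nor white (it spikes during fast motion and occlusion),
real behaviors blend and transition gradually, and real wells contain
debris and lighting gradients. Passing tests therefore demonstrate that
the pipeline's machinery is correct and self-consistent, not that the
desk-scale classifier performance transfers to recorded larvae.

## Validation scale and reproducibility

The validation suite trains on 100 simulated windows per class with a
balanced held-out split, a size at which the five synthetic regimes are
comfortably learnable while the whole suite stays quick to run; the
permutation control (labels shuffled before training) is averaged over
10 replicates evaluated on 250 balanced windows, which pins its
chance-level expectation of 0.2 to within ~±0.03. `scripts/acceptance.R`
recomputes all headline quantities from scratch for any seed.

## Known limitations

- 2-D capture: vertical (corkscrew) movement components are invisible,
  as in the underlying recording geometry.
- The speed gate and exclusion threshold are fixed configuration, not
  estimated from each cohort; `speed_histogram()` provides the
  diagnostic for re-deriving them on new data.
- MAD sigma estimation is biased upward on segments dominated by
  convulsive movement; batching across an acquisition
  (`estimate_sigma_batch()`) is the intended mitigation.
- The classifier ships untrained; real deployments need labelled clips
  from the actual recording system.
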