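---
title: "Methods: quantifying larval zebrafish locomotor state, anesthesia emergence, and brain-wide activity differences"
author: "larvalstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: larval state, emergence, and activity mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvalstate)
```

# The scientific problem

Glycine Encephalopathy raises glycine levels in the nervous system; in a
larval zebrafish model carrying a glial glycine transporter loss of function
(*glyt1-/-*), this manifests behaviorally as *lethargy*: individual swim
bouts look normal, but the immobile **dwell intervals** between them are
longer, and emergence from GABAergic/NMDA anesthetics (propofol, ketamine)
is delayed more than two-fold relative to siblings. Brain-wide
phospho-ERK/total-ERK (pERK/tERK) immunostaining localizes the difference
to elevated activity in hypnotic (preoptic) circuits.

This package implements the full quantitative chain needed for such a
study: video tracking of larvae in lanes, bout/dwell/lap statistics,
multi-endpoint anesthesia dose-response fits, checkpointed emergence-time
survival analysis, and voxel-wise activity mapping — together with a
seeded synthetic-data module that generates every input from stated
stochastic models, so the whole chain is testable without raw recordings.

# The synthetic-data generator

The generator *defines the study conditions* used by the test suite and
the acceptance script; its defaults are fixed once and documented here.

## Locomotion as a renewal process

A larva alternates immobile dwells and brief swim bouts:

* **Dwell times** are log-normal. The distributional family is a modeling
  choice (the behavioral literature reports heavy-tailed, non-normal dwell
  distributions but no parametric family); the sibling preset uses median
  5 s, sdlog 1, and the mutant preset doubles the median to 10 s — bouts
  initiated half as often, the lethargy phenotype.
* **Bout displacements** are gamma (mean 5 mm, shape 25) and identical
  between presets, matching the observation that bout *size* does not
  differ between genotypes. Each bout lasts 0.25 s and is traversed at
  constant velocity; within-bout kinematics (tail curvature, C-bends) are
  out of scope at the 5-fps long-recording timescale.
* **Direction** persists along the lane; a bout reaching a lane end stops
  at the wall and the heading flips for the next bout. Wall-stop (rather
  than reflecting the remainder of the displacement inside the bout) was
  chosen so that the recorded per-bout distance equals the displacement
  actually present in the emitted positions: the sum of ground-truth bout
  distances then equals the path length of the event-resolved position
  polyline *exactly*, a conservation invariant the tests assert.
* **Lap episodes** (runs of back-and-forth traversals with short rests)
  arrive as a Poisson process (sibling 6/h, mutant 3/h — clustered laps
  are less frequent in mutants) and consist of ~8 bouts separated by short
  dwells (median 0.5 s).
* Long recordings default to **5 fps**, webcam-class hardware for a 4-h
  recording; lanes are 65 x 3 mm.

Every generator is a pure function of its parameters and a seed: the same
seed reproduces the output bitwise, and the caller's RNG state is never
disturbed.

```{r}
presets <- genotypePresets()
tr <- simulateTrajectory(presets$sibling, duration = 600, laneLength = 65,
                         seed = 7)
tr
head(groundTruth(tr)$bouts, 3)
```

## Rendered videos, dose-response counts, emergence tables, stacks

`renderFrames()` paints a Gaussian blob per lane over a background that can
drift slowly in intensity with a spatially structured pattern (emulating
evaporation/illumination change — the disturbance the tracker's rolling
background model exists to cancel). `simulateDoseResponse()` draws binomial
response counts from a four-parameter logistic; `simulateEmergenceTimes()`
draws latent log-normal emergence times, rounds them *up* to the 5-min
checkpoint grid and right-censors beyond the follow-up horizon (default
360 min); `simulateActivityStacks()` builds per-fish pERK/tERK stack pairs
in which the planted ratio shift exists only inside a supplied ROI mask.

The emergence spread default (sdlog 0.2) was chosen to emulate the
near-maximal mutant-vs-sibling rank separations reported for this
phenotype at n ~ 20/group: published Dunn mean-rank differences are close
to their theoretical maximum, i.e. mutant and sibling emergence times barely
overlap. A 2x median delay with sdlog 0.2 reproduces that regime.

## What the generator does *not* emulate

Real recordings have occlusions, meniscus reflections, larva-shaped
(non-Gaussian) blobs and motion blur; real stacks have registration error,
anatomically structured staining and spatially correlated noise. Passing
tests on synthetic data therefore demonstrate the *correctness of the
algorithms against their own models*, not robustness to every artifact of
real data.

# Tracking

Positions are recovered by background subtraction: the background is the
per-pixel **median** over a window of frames (robust to the larva, which
occupies any one pixel only briefly), re-estimated every `updatePeriod`
frames (default 1000) from the trailing window. Detection subtracts the
background within a lane ROI, removes the spatially uniform component
(median of the difference — this makes the tracker exactly invariant to
adding a constant to all frames), optionally smooths, and thresholds the
absolute difference at 5x the robust noise SD (MAD) by default; the
threshold, like every detection criterion this assay family leaves
unstated, is a declared configurable choice. The centroid is the intensity-unweighted
mean of the above-threshold pixel coordinates of the **largest connected
component** (one larva per lane by design; smaller components are noise).
Coordinates are 0-based pixels, x = column, y = row, origin top-left,
sub-pixel centroids as floats. Missed detections are kept as invalid
samples, never interpolated by the tracker itself.

Numerical notes: with noise-free synthetic frames the MAD of the
difference image is zero, so the automatic threshold falls back to half
the peak difference; lane ROIs span the full frame width so a blob resting
against a lane end is not clipped (clipping biases the unweighted centroid
inward by ~1 px).

# Bout, dwell and lap analysis

Per-interval speed is smoothed with a centered 3-sample moving average and
segmented by hysteresis: a bout is a maximal run above `speedOff`
(default 1 mm/s) containing at least one interval above `speedOn`
(default 2 mm/s); bouts shorter than `minBout` (0.1 s) are dropped and
gaps shorter than `minDwell` (0.2 s) merge neighbours. Invalid runs of at
most 2 frames inside a candidate bout are bridged by linear interpolation;
longer gaps split the bout. Because smoothing spreads speed into flanking
intervals, run bounds are trimmed back to the raw above-threshold
intervals for *timing*, while the path length is accumulated over the full
run (the flanking dwell intervals contribute ~0 distance). Dwells are
measured between trimmed bout envelopes plus one frame interval — the
motion covers on average half of each partially-occupied boundary
interval — which removes the ~1-frame negative bias the envelope gap
would otherwise carry.

**Resolution floor.** At 5 fps with the default thresholds, a bout is
detectable only if its displacement exceeds roughly
`3 x speedOn x frame interval` (~1.2 mm, comfortably below the 5-mm mean;
recovery tests use >= 3 mm as the resolvable definition), and dwells
shorter than ~3 frame intervals merge into the surrounding bouts. Recovery
assertions (exact bout counts, 2% distances, dwell medians within one
frame interval) are made against planted processes whose events are all
resolvable; lap-episode dwells (median 0.5 s) are intentionally *below*
the floor and are recovered as merged multi-bout runs — which is exactly
what makes laps segmentable as excursions.

Laps: positions are projected onto the principal axis of the lane, bout
displacements are scanned for direction reversals, and an excursion of
same-direction bouts whose internal dwells are at most
`maxIntraLapDwell` with net amplitude >= `amplitudeMin` is a lap; the
period is the time to the next same-direction lap. Clustering is
single-linkage in time with a `maxGap` threshold; both thresholds are
exposed because neither has an established operational definition.

# Dose-response

The stimulus cycle is 30 s lights-on, 20 s lights-off ending with a tap,
then 10 s more darkness, repeated 5 times; cycles 4-5 are scored. A larva
responds to *light* if it moves during lights-on, to the *visual-motor
response* (VMR) if it moves within 5 s of the dark transition, and to
*tap* if it moves within 5 s of the tap. Pooling over scored cycles
defaults to "responds in either cycle"; per-cycle counting is available.
Proportions are normalized to the no-anesthetic baseline and clipped to
[0, 1] so the asymptotes of the fit stay interpretable.

The fit is the four-parameter logistic
`y = bottom + (top - bottom) / (1 + 10^((logEC50 - log10 d) * hill))`,
bounded least squares via Levenberg-Marquardt with multi-start over hill
and EC50 guesses (steep noiseless curves can make a single start
singular). "Constraining the Hill slope" is interpreted as bounding it
(default [-3, -0.5], descending); the bound is configurable. Weights are
optional; for binomial proportion panels the natural choice is
`n / (p(1-p))`, which the acceptance analyses use. A panel whose response
range is below `flatTol` (0.05) is flagged degenerate: asymptotes
collapse and the EC50 is reported unidentifiable rather than a number.

With the printed propofol dose series (0.05-10 uM) and n = 70 larvae per
dose, the EC50 of a planted (EC50 2 uM, hill -1.2) curve is recovered
exactly on noiseless panels and with a mean absolute error of ~13% under
binomial noise — the parameter correlations of a 7-dose panel with free
asymptotes and a bounded slope put that scale of uncertainty in the data
itself.

# Emergence analysis

Checkpoint tables (response to vibration every 5 min after washout)
convert to **first-passage** emergence times: the first positive
checkpoint, with later lapses ignored; never-responders are right-censored
at the last checkpoint. Group comparisons follow the field's convention for this assay:
Kruskal-Wallis + Dunn's multiple comparisons (Bonferroni-style adjustment
by default, Sidak and none available) on the *observed* times — rank tests
assume observed event times, so censored records are excluded there, with
a warning when a group empties — and Kaplan-Meier curves with a k-group
log-rank test on *all* records, where censoring is handled by the risk
sets. Ties are structural on a 5-min grid; all rank statistics use
midranks with tie-corrected variances, and the log-rank covariance is
inverted by an eigen pseudoinverse because a group whose risk set never
overlaps an event time makes it singular.

# Statistics module

Every procedure the pipeline needs is implemented from its defining
formula so the voxel mapper can call the identical kernel, and each is
tested against an independent oracle: exact Mann-Whitney p values against
full enumeration of group assignments, the normal mode against
`wilcox.test(correct = FALSE)`, Kruskal-Wallis against `kruskal.test`,
Dunn against a counting-based re-derivation, Kaplan-Meier against
`survival::survfit`, log-rank against `survival::survdiff` and a textbook
O-E/V implementation, BH-FDR against `p.adjust`, and the Type-II two-way
ANOVA against `car::Anova`. The exact Mann-Whitney enumerates midrank
assignments (permutation-exact, so ties are handled) for pooled sizes up
to 12; the continuity correction is off by default to match the Z-score
map definition. The two-way ANOVA uses Type-II sums of squares for
unbalanced designs (published workflows rarely state their convention) and
Sidak-adjusted pairwise genotype contrasts within each condition, pooled
residual MS, `p_adj = 1 - (1 - p)^k`.

# Activity mapping

Per fish, pERK is divided by tERK voxel-wise; voxels with tERK below a
floor are masked invalid rather than dividing by ~0. The floor defaults to
the 5th percentile of nonzero tERK — a guard intended for real stacks
whose unstained margins must be excluded. Note its interaction with the
complete-case rule: a quantile floor invalidates a fixed fraction of
voxels *per fish*, and a voxel is analyzed only if valid in **all** fish
of both groups, so with 32 fish a 5% per-fish floor retains only ~0.95^32
~ 19% of the volume. For synthetic stacks (tERK positive everywhere) the
analyses pass a small absolute floor instead.

Stacks can be block/linear-resampled to a target grid (300 x 679 x 80, the
resolution customary for whole-brain maps, is the configurable default
target for full-size data) and
smoothed per z-slice with a separable Gaussian whose borders are
renormalized, so a constant stack is preserved exactly and the interior
impulse response matches the closed-form kernel to ~1e-15. The declared
processing order is ratio -> downsample -> smooth -> test.

The group comparison computes, per analyzed voxel, the tie-corrected
normal Mann-Whitney Z across fish and the difference of group medians.
Thresholding is Benjamini-Hochberg FDR over the analyzed voxels (default
q = 0.05) or a fixed p cutoff (the figure-style 5e-5); flagged voxels get
the sign of the median difference. Rendering maps |median difference|
linearly to 0-65535 with saturation at 60% of the maximum over flagged
voxels, and emits maximum-intensity and SD z-projections. ROI summaries
average the ratio over each labelled region per fish and run the
genotype x condition ANOVA with Sidak contrasts per region.

The end-to-end power/calibration analyses run the chain with the identity
preprocess (sigma = 0): smoothing deliberately spreads a planted effect
across the ROI border, so with smoothing on, the out-of-ROI flagged
fraction measures kernel spill (a real, intended property of smoothing)
rather than the calibration of the test; spill is exercised by its own
tests instead.

```{r}
mask <- array(FALSE, c(24, 24, 4)); mask[8:14, 8:14, 2:3] <- TRUE
spec <- stackEffectSpec(mask, ratioShift = 0.3, noiseSd = 0.1,
                        nPerGroup = 16)
st <- simulateActivityStacks(spec, seed = 79)
rs <- ratioStacks(st, terkFloor = 1e-9)
tm <- thresholdMap(voxelZMap(rs[1:16], rs[17:32]), "fdr", 0.05)
tm
```

# Problem sizes used by tests and the acceptance script

The suite runs the generator-defined study conditions at sizes a desktop R session
handles in minutes: 30-min (not 4-h) lane records for the 24-vs-30-larvae
dwell power analysis (100 seeded replicates), 60-400 s rendered videos at
5 fps for tracking accuracy and the drift A/B comparison, 50-seed
replicates for EC50 recovery and the 64 x 64 x 8-voxel 16-fish-per-group
activity-map power/calibration runs. These sizes are the package's own
choices; all statistical conclusions they support (power >= 90-95%,
calibration within binomial error) are computed, not assumed.

# Known limitations

* One larva per lane; no identity tracking or occlusion handling.
* No posture/tail-curvature kinematics; velocity comes from centroids.
* The 4PL's EC50 is reported with no confidence interval; at 7 doses with
  free asymptotes its sampling error is of order 10% and should be treated
  accordingly.
* Registration of stacks is assumed done upstream; only dimension
  consistency is checked.
* Movement-detection thresholds and operational lap definitions vary
  between labs and are rarely published; the defaults here are declared,
  configurable stand-ins, and conclusions that depend on them
  should be checked for threshold sensitivity.
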