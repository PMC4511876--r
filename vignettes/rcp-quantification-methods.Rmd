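---
title: "Quantifying RCP images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RCP images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcpquant)
```

## The problem

Rolling circle amplification products (RCPs) read out single-molecule
assays — padlock probes, proximity ligation — as diffraction-limited
fluorescent spots. Three image-level properties decide how trustworthy the
readout is:

* **Brightness and signal-to-noise.** A compact RCP concentrates its
  fluorophores into a small volume, so its peak intensity stands further
  above the local background fluctuation.
* **Signal integrity.** A poorly collapsed RCP can disintegrate into a
  cluster of nearby foci of one color, so one molecule is counted several
  times.
* **Co-localization.** Dispersed products from neighboring amplification
  events can overlap across color channels.

`rcpquant` implements the quantification pipeline for all three, plus a
synthetic scene generator with exact ground truth so every stage can be
validated without microscope data.

## Pipeline and models

### Projection and thresholding

A z-stack is reduced to a pixelwise maximum and minimum projection; the
corrected image is their difference (floored at zero). Structure present at
every focal plane — slide background, autofluorescence — cancels, while
in-focus spots survive.

The detection threshold is automatic: the mode of the corrected image's
histogram estimates the background level, and the threshold is twice that
mode. Only pixels between the 2% and 98% percentiles of the intensity
distribution enter the histogram, so dead and hot pixels cannot shift the
mode. We read "2%–98% of the intensity range" as percentiles of the pixel
distribution rather than fractions of the dynamic range; percentiles match
the behavior of the established background-mode thresholding method this
rule follows and are robust to single extreme pixels. The clip range is
recorded in the result so the alternative reading can be compared. Binning
is 256 equal-width bins over the clipped range, the mode is the center of
the fullest bin, and ties break toward the lower bin (a conservative, lower
threshold). A constant image is its own mode.

### Spot segmentation and the cluster filter

Pixels at or above threshold are labeled as 8-connected components
(diffraction-limited spots are compact; 4-connectivity would fragment
diagonal contacts). Clustered RCPs are excluded by size and shape: objects
larger than 40 px or with form factor below 0.5 are removed, boundary
values kept.

The form factor is $4\pi A / P^2$ with $P$ a Crofton-style perimeter
estimate: $\pi/4$ times the count of 4-adjacent foreground/background
pixel edges. The raw edge count measures city-block boundary length and
overestimates the Euclidean perimeter of a digitized disk by $4/\pi$; a
radius-3 digital disk (area 29 px, a typical RCP) would score 0.465 and be
wrongly discarded by the 0.5 cut, and no digital disk could approach the
defining value 1. With the $\pi/4$ weighting, large digital disks converge
to form factor 1 and the radius-3 disk scores 0.75. The value is capped at
1 to absorb discretization overshoot for very small objects.

### Local-maxima detection

The proximity/integrity path detects signals differently: Gaussian
smoothing with a kernel SD of one pixel (the length scale of a
diffraction-limited spot), subtraction of the smoothed image's median
(floored at zero), then strict local maxima over the 8-neighborhood with
positive remaining value. A flat plateau of equal maximal values yields one
point at its centroid. An optional `min_prominence` floor (default 0)
suppresses shallow noise maxima; the pipeline sets it to each channel's
automatic intensity threshold so the maxima path and the segmentation path
share one notion of "above background". On low-noise data the default 0
reproduces the plain median-subtraction rule.

### Disk-based SNR

For each retained signal, the ratio $r$ is the maximum corrected intensity
within an inner disk (radius 3 px) around the signal divided by the sample
standard deviation of all pixels in the surrounding annulus (outer radius
7 px); in decibels, $\mathrm{SNR} = 20\log_{10} r$. The alternative
geometry (5, 12) is available for robustness checks. A pixel belongs to a
disk iff the Euclidean distance from its integer coordinate to the center
is at most the radius; the annulus is strictly outside the inner radius.
Disks are anchored on the object's brightest pixel rather than its
centroid — stable for slightly asymmetric spots — with the centroid
available by passing those coordinates directly to `measure_snr()`.

The measurement is valid only when the annulus samples pure background, so
a signal is kept only if (a) its outer disk lies fully inside the image,
(b) no other candidate center is closer than twice the outer radius (both
members of a too-close pair are dropped; the criterion is evaluated on all
candidates simultaneously, not greedily), and (c) no pixel of any other
segmented object — including objects already removed by the cluster
filter — intrudes into its outer disk. Retention is density-dependent: at
the reference study's densities roughly a quarter of detections survive;
at this package's default synthetic density about 80% do.

Sample SD ($n-1$) is used everywhere, for the annulus and for the
summaries (mean, SD, SEM). A zero annulus SD is a degenerate background:
the signal is dropped from summaries and counted.

### Same-color neighbor statistic and its nulls

Every detected signal (both colors pooled) is paired with its Euclidean
nearest other signal; the statistic is the fraction of signals whose
nearest neighbor has the same color. The relation is directed — each of
the $n$ signals contributes one pair, mutual pairs are not deduplicated.
Exact distance ties resolve toward the candidate with the smaller (row,
col). If an RCP disintegrates, its fragments are close together and share
a color, inflating the statistic.

The null hypothesis is spatial randomness with the observed per-color
counts: each Monte Carlo replicate places $n_1 + n_2$ points uniformly in
the image rectangle with fixed counts and recomputes the statistic
(default 10 replicates). Because the statistic is invariant to uniform
scaling, the rectangle's size is irrelevant; only its aspect ratio
(default 1040 × 1388, the acquisition geometry) and the counts matter. A
label-permutation variant (`permutation_null()`) keeps the observed
positions and shuffles colors; it conditions on the observed geometry —
including any clustering — and therefore tests label exchangeability
rather than complete spatial randomness. The random-placement null is the
primary one.

An exchangeability argument gives a closed form for the null same-color
probability,
$$p = \frac{n_1(n_1-1) + n_2(n_2-1)}{(n_1+n_2)(n_1+n_2-1)},$$
used as an independent oracle: the Monte Carlo mean must sit within three
Monte Carlo standard errors of it.

`integrity_test()` compares an observed frequency to its matched null by a
two-tailed one-sample t-test of the null's replicate frequencies against
the observed value, and additionally flags whether the observed value
falls within the null mean ± 2 null SD — the "within the margins of the
expected random frequency" reading, which is also what the end-to-end
tests assert. The t-test treats the observed value as fixed, so with many
null replicates it is sensitive to differences well inside the null's own
spread; the `within_2sd` flag is the more conservative summary and the two
are reported side by side. With several images per experiment replicate,
frequencies are pooled by counts (summed same-color pairs over summed
pairs), not averaged.

### Co-localization

Slide images: both channels are Gaussian smoothed (SD 1 px) and binarized
at one fixed threshold; the overlap is intersection over union of
foreground pixels. The shared threshold defaults to channel 1's automatic
mode threshold — a reproducible rule, since no fixed value is universal —
with an explicit override.

Solution-phase line scans: objects are detected per channel at ≥ 35
photomultiplier-tube units, kept if their area is within 2–30 px
(inclusive), and merged across channels into one RCP entity wherever pixel
sets intersect. An entity is positive in a channel if any of its pixels
reaches the threshold there (default; a mean-intensity rule is available),
and dual if positive in both. Dual fractions across conditions are
compared by one-way ANOVA with Fisher's LSD post hoc (pairwise t-tests on
the pooled within-group mean square, unadjusted).

### Two-group comparisons

`compare_groups()` mirrors the conventional workflow: each group is
checked for normality (one-sample Kolmogorov–Smirnov against a normal with
the group's estimated mean and SD, α = 0.05); if both pass, a two-tailed
Welch t-test, otherwise a Mann–Whitney U test. The KS test with estimated
parameters is anti-conservative about normality (it under-rejects), which
only makes the t-test branch more likely for near-normal data; strongly
skewed or tied data still routes to the rank-sum test. Zero-variance
groups are treated as non-normal.

## The synthetic scene generator

`generate_scene()` emulates the slide experiments the statistics were
designed for: two color channels, sparse diffraction-limited spots over
12–18 z-levels, uneven background, shot and read noise, and spatially
random placement with fixed per-color counts.

* **Geometry.** Parent centers are uniform over the field minus a border
  margin (default 12 px, at least the outer SNR disk radius), with a
  minimum pairwise separation (default 8 px) enforced by rejection
  sampling; an unplaceable spot raises an error naming it. Coordinates are
  1-based (row, col) with pixel centers at integer coordinates throughout
  the package.
* **Spots.** Each sub-focus is a 3-D Gaussian blob: lateral SD
  `psf_sigma_px` (default 1.2 px ≈ a diffraction-limited spot at ~0.5 µm
  pixels), axial SD 1 z-level, so every spot spans at least three
  z-levels. Per-RCP amplitudes are log-normal around `spot_amplitude`
  (default 3000 intensity units on a 14-bit-like scale, CV 0.25).
* **Modes.** `compact` renders one sub-focus per RCP at the parent
  center. `dispersed` draws a sub-focus count as 1 + Poisson(1.5)
  truncated to [1, 6], displaces sub-foci isotropically in-plane with SD
  4 px (truncated at 3 SD) and at most one z-level axially, and splits the
  parent amplitude across sub-foci with symmetric Dirichlet weights. The
  split conserves total fluorophore content between modes, which is what
  makes compact-versus-dispersed brightness comparisons meaningful. The
  dispersion law is a generator model, not a measured property: the
  reference experiments show disintegration qualitatively but never
  characterize sub-focus geometry, so these are knobs with defaults chosen
  to look like the published high-resolution images (fragments within a
  few pixels of each other).
* **Background and noise.** Background is a constant level (400) plus a
  smooth linear ramp (peak-to-peak 120) across the field, and an axial
  haze profile: mid-stack planes carry up to 30% more background than the
  stack ends (smooth cosine in z). The axial term matters: without it the
  corrected (max − min) background is a pure iid-noise range statistic
  whose histogram mode sits only ~6.5 SD below twice itself, leaving an
  irreducible ~10⁻³ false-positive pixel tail at any noise scale.
  Focus-dependent background is also what real stacks show; it leaves a
  deterministic pedestal in the corrected image that the mode-based
  threshold measures. Noise is shot noise (Poisson on
  `photons_per_unit × value`, default 4 photons per intensity unit, i.e.
  shot SD $\sqrt{v/4}$ intensity units) plus additive Gaussian read noise
  (SD 10).
* **What it does not emulate.** No full 3-D PSF, chromatic aberration,
  spectral cross-talk, structured-illumination artifacts, or tissue
  autofluorescence texture beyond the smooth gradient. Passing tests on
  these scenes validate the measurement code and the direction of the
  compaction effects — brighter/cleaner compact spots, inflated same-color
  frequencies for dispersed ones — not the published absolute intensities
  or decibel values, which depend on wet-lab material and detector
  settings.

`generate_point_set()` is the pure point-level analogue used by the Monte
Carlo null.

## Numerical and design choices

* All randomness flows from user-supplied seeds; replicate and stage seeds
  derive deterministically from one master seed, and identical
  configuration plus seed reproduces scenes and pipeline outputs
  byte-exactly.
* The nearest-neighbor search is an exact grid-hashed all-nearest-neighbor
  kernel in C++ (expected linear time for roughly uniform sets, ~10⁵
  points per replicate in well under a second), with the deterministic
  tie-break above; it is pinned against an $O(n^2)$ oracle in tests.
* Connected-component labeling is a breadth-first pass over foreground
  pixels, pinned against a naive flood fill.
* Thresholds are applied as ≥ comparisons; filter boundaries are
  inclusive on the keep side (area 40 kept, form factor 0.50 kept, areas
  2 and 30 kept, PMT 35 is signal).
* The automatic threshold and the SNR are computed on the corrected
  projection (not the raw maximum projection), consistent with correcting
  background before detection.
* Degenerate inputs are explicit: empty stacks, empty clip ranges, < 2
  points, zero annulus SD, zero-union overlap and zero-variance groups
  either error with a clear message or return flagged results rather than
  NaNs.

## Problem sizes used in the validation suite

The packaged tests exercise default 512 × 512 × 12 scenes with 120 spots
per color for the effect-recovery checks (10 paired seeds), smaller
128–256 px scenes for detection properties (20 seeds), 50-replicate Monte
Carlo nulls for the closed-form agreement check, and the published count
pairs (18,563 + 6,680 and 45,352 + 26,004) at 10 replicates for the
headline null frequencies. These sizes were chosen so the full suite
exercises every pipeline stage at realistic densities while remaining
comfortable to run repeatedly during development.

## Known limitations

* The generator's dispersion parameters are not fitted to data; only the
  direction and rough magnitude of the induced effects are meaningful.
* The mode-based threshold assumes background dominates the histogram
  (spot area fraction well under the 2% clip); dense fields need a
  different thresholding rule.
* Nearest-neighbor statistics carry no edge correction; for the default
  field sizes and counts the bias is far smaller than the Monte Carlo
  spread, and observed and null statistics share it.
* The solution-phase classifier assumes the two channels are aligned;
  there is no registration step.

## A worked example

```{r example, eval = FALSE}
library(rcpquant)

scene <- generate_scene(scene_config(mode = "dispersed", seed = 1))
proj <- lapply(list(scene$channel1, scene$channel2), project_stack)
thr <- lapply(proj, function(p) mode_threshold(p$corrected))

maxima <- lapply(1:2, function(ch)
  detect_maxima(proj[[ch]]$corrected, min_prominence = thr[[ch]]$threshold))
pts <- as_colored_points(maxima[[1]], maxima[[2]])

obs <- same_color_frequency(pts)
null <- monte_carlo_null(c(nrow(maxima[[1]]), nrow(maxima[[2]])),
                         dim(proj[[1]]$corrected), seed = 2)
integrity_test(obs$frequency, null)
```

The same flow runs end to end, with every intermediate table written to
disk, via `run_pipeline(run_config(scene = scene_config(...), seed = 1,
out_dir = "run1"))`.
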