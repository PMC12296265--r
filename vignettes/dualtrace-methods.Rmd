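---
title: "Mapping dual immediate-early-gene ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dual immediate-early-gene ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtrace)
```

## The problem

Activity-dependent labeling lets one visualize two neuronal ensembles in
the same brain: a population tagged during a first experience (a
persistent reporter such as eYFP driven by an immediate-early gene) and a
population active around perfusion (endogenous c-Fos protein). Cells
carrying both labels are the overlap ensemble, and the fraction of tagged
cells re-expressing c-Fos is a *reactivation proportion*. `dualtrace`
implements the full quantitative chain for such experiments: 3D
segmentation of both labels in confocal z-stacks, object-based
colocalization, registration of sections to 2D atlas plates, aggregation
to volume-normalized regional densities, and group-level network
statistics on regional correlations.

## Segmentation

The two labels have different morphologies and get different pipelines.

**Punctate (c-Fos-like) staining** — bright filled spheres:

1. Fourier band-pass per z-plane (difference of Gaussians in frequency
   space) passing lateral structures between `bandpassSmall` (2 voxels)
   and `bandpassLarge` (20 voxels);
2. rolling-ball background subtraction, implemented as grayscale opening
   with a disc of radius `rollingBallRadius` (15 voxels) applied per
   z-plane and subtracted;
3. 3D local-maxima detection over a lateral disc of radius
   `maximaRadius` (4 voxels; the z extent is scaled by the voxel
   anisotropy), with maxima below `minPeak` discarded (default: mean +
   4 SD of the filtered stack) and maxima closer than the radius
   deduplicated toward the brighter seed;
4. spot growth: a 26-connected flood from each seed, brightest seed
   first, claiming unlabeled voxels above `growFraction` (50%) of the
   seed intensity — two touching cells keep separate labels because each
   growth wave stops at voxels the other has claimed;
5. volume filtering to `[minVolume, maxVolume]` (30 voxels, unbounded).

**Soma-plus-process (eYFP-like) staining** — the same reporter fills
dendrites and axons, which must not be counted as cells:

1. rolling-ball background subtraction as above;
2. 3D Gaussian blur (`sigma` 2 voxels laterally, scaled along z);
3. a binary mask of the `topPercent` (0.5%) brightest voxels, using a
   strictly-greater comparison against the interpolated percentile so a
   constant image yields an empty mask;
4. watershed splitting of the masked intensity. The watershed is a 3D
   immersion with 26-connectivity: voxels are flooded in decreasing
   intensity order, new basins open at voxels with no labeled neighbour,
   and a basin merges into a deeper neighbour when its dynamics (peak
   minus merge level) fall below `tolerance` (0.2 on the normalized
   masked intensity);
5. volume filtering as above.

Process filaments survive the blur at a fraction of the soma intensity
and fall below the top-percentile cutoff, so they never seed objects.
The mask budget is the method's key assumption: somas must occupy less
than `topPercent` of the stack's voxels. In densely labeled fields the
percentage must be raised accordingly.

The interactive deletion of edge and ventricle artifacts used with real
tissue is replaced by an optional `edgeMargin` parameter that discards
objects whose centroid falls within a margin of the lateral borders; no
interactive editing is provided.

**Colocalization.** The two channels' label volumes are intersected;
every ordered object pair sharing a voxel yields a record whose percent
overlap is expressed relative to the channel-2 (c-Fos) object's volume.
Thresholding keeps records at or above `minPercent`; a channel-2 object
surviving in several records counts as one co-labeled cell, assigned to
its largest overlap with ties broken toward the lower channel-1 id. The
percent threshold for a given experiment is a required configuration
value — no default is assumed, since the appropriate stringency depends
on labeling chemistry.

**Validation arithmetic.** Automated counts are validated against manual
annotation via false positives (algorithm only) and false negatives
(annotator only). The estimated true-positive count is the average of
two derivations, (manual − FN) and (auto − FP); precision, recall and F1
follow as P = TP/(TP+FP), R = TP/(TP+FN), 1/F1 = (1/P + 1/R)/2.

## Registration and mapping

Sections are matched to an anterior-posterior atlas plate manually (the
z resolution of plate spacing makes automatic matching pointless), and
registered in 2D by a thin-plate spline fit to correspondence points —
conventionally 32 points seeded along the section contour. The TPS uses
the kernel U(r) = r² log r with an exact-interpolation default
(λ = 0); λ > 0 is available for noisy correspondences. The linear
system is solved in centered, unit-RMS coordinates: on raw micrometre
coordinates the kernel block dwarfs the affine block by ~10⁸ and the
system is numerically singular. With exactly three points the fit
reduces to the unique affine map.

Mapped cells are assigned to regions by an even-odd point-in-polygon
test against the plate's polygons; boundary points go to the
first-listed polygon, and points in no polygon are unassigned.
Hemisphere is the sign of the atlas x coordinate (midline x = 0 by
convention). Region areas come from Gauss's (shoelace) formula —
computed per hemisphere by clipping each polygon to the midline — and a
region's volume is its summed area times the physical stack thickness
(0.009 mm for a 9 µm stack).

## The data model and normalization

Slices (image metadata, per-channel objects, colocalization records,
registration, exclusions) nest inside mice, which nest inside an
experiment holding the ontology. Aggregation sums counts and volumes per
region and channel across a mouse's slices and reports densities in
cells/mm³. Three cleaning rules apply, in order:

* **exclusions** — damaged or misaligned regions annotated per
  hemisphere are omitted, together with their ontology descendants, from
  both counts and volumes; structures not expected to contain labeled
  cells (fiber tracts, ventricular systems) are always excluded;
* **outlier removal** — within every (group, region, channel), densities
  more than `k = 2` sample standard deviations from the group mean are
  dropped. The rule is single-pass (no iterative re-computation), uses
  the n−1 SD including the candidate row, and leaves groups with fewer
  than 3 values or zero SD untouched;
* **shared-region filter** — only (region, channel) cells with a density
  for every mouse in *both* groups are analyzed; a `minMice` switch
  relaxes this to a minimum per group.

Reactivation proportions are computed as raw count ratios
(co-labeled / tagged) per mouse and region; because numerator and
denominator share the region volume, the ratio is identical before or
after volume normalization whenever both are defined, and the count
ratio stays defined even where a volume is not.

## Network statistics

Pearson correlations between regional densities are computed across the
mice of each group, pairwise-complete, with two-sided asymptotic
p-values from t = r√(n−2)/√(1−r²) on n−2 degrees of freedom (|r| = 1
gives p = 0; pairs with n < 3 or a constant region are reported
missing). A functional network keeps the edges with |r| > `rMin`
(default 0.9) and p < `alpha`; the absolute value follows the treatment
of anti-correlated connections as edges, and a `signed` switch restricts
to positive r. `alpha` is deliberately a required analysis choice:
useful sparsity differs between channels, and the package does not infer
it.

Topology metrics are computed on the unweighted, sign-ignored skeleton
(edge weights are visualization attributes only): degree, clustering
coefficient (2·triangles/deg(deg−1), zero below degree 2), nodal
efficiency (mean inverse shortest-path length, 1/∞ = 0) with global
efficiency its network mean, and unnormalized betweenness counting each
unordered pair once. A threshold sweep recomputes the network means over
a grid of alphas as a stability check. No multiple-testing correction is
applied by default anywhere, favouring false positives over false
negatives in an exploratory workflow.

**Permutation differences.** For every pair, d = r_B − r_A is compared
to a null built by reshuffling the mouse group labels (preserving group
sizes; 1000 shuffles by default) and recomputing the difference.
P-values are two-sided on |d| with the add-one estimator
(#{|d₀| ≥ |d|} + 1)/(N + 1), which cannot report an impossible p = 0.
Whether the upstream convention was one- or two-sided is not documented;
two-sided is the conservative choice here and is recorded per result.

**Distribution comparison.** A region's vector of correlations to all
other regions is compared between groups with a two-sample
Kolmogorov-Smirnov test.

**Communities.** The two-community split takes the modularity matrix
B = A − kkᵀ/2m of the skeleton, splits by the sign of the leading
eigenvector when its eigenvalue is positive, and then applies the
method's standard fine-tuning stage: repeated Kernighan-Lin-style passes
in which every vertex is moved once and the best intermediate state is
kept. The refinement is started from the sign pattern of every
positive-eigenvalue eigenvector (the spectral bisection candidates) and
the best resulting split is kept — without this, the one-shot sign split
misses the exhaustive two-partition optimum on a few percent of small
graphs. A non-positive leading eigenvalue, or a split that does not
improve on a single community, returns one community.

## The synthetic generators

The package validates itself on synthetic data with known ground truth;
no imaging data ships with it.

**Image phantoms** use the default acquisition geometry of
1.08 × 1.08 × 3 µm voxels. Cells are Gaussian-profile spheres
(σ = radius/2, nominal radius 6 µm) placed with centre separation of at
least two radii and margins of one radius; the punctate default is 20
cells in a 128 × 128 × 24 field. The soma phantom adds
dimmer random-walk filaments (default 3 per cell, ~1.5 µm steps, 35% of
the soma peak) and uses a 160 × 160 × 24 field so the soma volume
fraction stays below the 0.5% mask budget the soma algorithm presumes —
the sparse-labeling regime the method targets. The noise model is
additive Gaussian background (mean 100, SD 20) under a multiplicative
low-frequency illumination field (default amplitude 20%), with the peak
signal set by the requested SNR (peak / noise SD, default 10). The
phantoms deliberately omit a real point-spread function, autofluorescent
artifacts, occlusion and anisotropic cell shapes, so segmentation scores
on them are upper bounds: passing them shows the pipeline recovers
idealized morphologies at realistic noise and illumination, not that it
matches human annotators on tissue.

**Dual-channel phantoms** co-locate a designed fraction of channel-2
cells at channel-1 centres (optionally jittered); the designed
fractional overlap of two equal spheres at distance d,
(4r + d)(2r − d)²/16r³, is recorded as ground truth.

**Count simulation** draws per-mouse regional densities from lognormal
marginals (median `baseMean` 5000, log-SD 0.3 — positive and
right-skewed, as densities are) coupled through a Gaussian copula whose
latent correlation matrix is the user's target; pairs can differ between
groups to plant group effects. Targets that are not positive
semidefinite are repaired by clipping negative eigenvalues to 10⁻⁸ and
renormalizing the diagonal; if repair distorts any entry by more than
0.1 the target is rejected as incoherent rather than silently changed,
and the repaired matrix is returned as the effective ground truth.
Sampling uses an eigendecomposition factor, so perfectly correlated
regions share one latent draw bit-for-bit and a target r = 1 reproduces
exactly in the sample.

## Numerical conventions

* Percentiles use linear interpolation (R type 7) and strict `>`.
* Labeling, growth and watershed use the 26-neighbourhood.
* Centroids are reported in micrometres with 0-based voxel centres.
* Image arrays are indexed [y, x, z]; atlas coordinates are x-right,
  y-up with the flip handled by the fitted registration.
* Zero-volume imported objects are dropped with a warning, not errors.
* TIFF output stores 16-bit values scaled by the stack maximum (the
  scale is returned and accepted on read).
* All stochastic functions take explicit seeds and restore the caller's
  RNG state; identical seeds reproduce results bit-for-bit.

## Validation scale

The test-suite and acceptance studies run at sizes chosen to make their
statistical claims meaningful at desk scale: segmentation is scored over
10 phantom seeds per algorithm; permutation calibration uses 500
replicate null datasets of 20 regions with 8 mice per group and 200
shuffles each (≈95,000 pairwise p-values); power uses 200 replicates of
a planted +0.9/−0.9 reversal at 12 mice per group; graph metrics are
checked against brute force on every labeled connected graph of 3–6
nodes, and community splits against exhaustive search on graphs of up to
8 nodes.

## Known limitations

* The soma mask budget ties detection to a global percentile: fields
  whose labeling density approaches `topPercent` lose dim cells first.
* Registration is 2D within a plate; nothing corrects through-plane
  tilt, and plate choice is manual metadata.
* Hemisphere assignment assumes the registered midline is x = 0.
* The permutation test assumes exchangeable mice under the null; batch
  structure within groups would violate it.
* Leading-eigenvector fine-tuning guarantees a local optimum over
  single-vertex moves from each spectral candidate, not the global
  two-partition optimum, although no counterexample at ≤ 8 nodes has
  been observed (0 mismatches over 2000 random graphs).
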