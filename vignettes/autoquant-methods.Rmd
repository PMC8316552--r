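---
title: "Methods: equal-area ring profiling, tandem-reporter flux and vacuole morphometry"
author: "autoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equal-area ring profiling, tandem-reporter flux and vacuole morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`autoquant` implements the quantification procedures that single-cell
autophagy and lysosome-positioning studies typically run on microscopy and
densitometry data: (1) the concentric equal-area ring analysis of a
marker's radial distribution in a cell, (2) tandem mCherry-GFP-LC3 puncta
scoring of autophagic flux, (3) rule-based classification and morphometry
of TEM-annotated autophagic vacuoles, and (4) the densitometry
normalizations and group statistics that accompany these assays. A
synthetic-scene generator with complete ground truth makes every stage
verifiable without instrument data.

## The ring model

A segmented cell is divided into $K = 4$ concentric rings of equal area.
Ring boundaries are uniformly scaled copies of the cell boundary about the
nucleus centroid: a pixel $x$ belongs to the region at scale $s \in (0,1)$
when its preimage $c + (x - c)/s$ (with $c$ the nucleus centroid) lies in
the cell mask. For a disk with a centered nucleus this reduces to
boundaries at radii $R\sqrt{k/K}$, which is the closed form the tests
check.

Two honest complications drive the implementation:

* **Non-convex cells.** A scaled copy of a non-convex outline about an
  off-center point need not nest inside the cell, so each scaled region is
  intersected with the cell mask and the scale factors are re-solved
  numerically — bisection on $s$ with areas measured by pixel counting —
  until each ring holds $1/K$ of the cell area within the tolerance
  `area_tol` (default 2%). Pixel rounding makes the area function only
  approximately monotone in $s$; the tolerance absorbs the jitter, and a
  partition that cannot reach tolerance raises an error that reports the
  achieved areas rather than returning a silently unequal partition.
* **Boundary ties.** A pixel on a ring boundary is assigned to the
  innermost scaled region that contains it, so every cell pixel receives
  exactly one label and the rings tile the cell mask exactly — an
  invariant asserted on every run.

Ring 1 is peripheral (touches the cell boundary) and ring $K$ is
perinuclear; output tables document this convention.

Per ring the package reports integrated intensity $I_k$, pixel area
$A_k$, density $d_k = I_k/A_k$, the **normalized density**
$n_k = d_k / d_{\mathrm{cell}}$ with
$d_{\mathrm{cell}} = \sum I_k / \sum A_k$ (uniform staining gives
$n_k = 1$ in every ring, any geometry), and the **intensity fraction**
$f_k = I_k / \sum I_k$. Both $n_k$ and $f_k$ are emitted because figure
conventions differ between studies; "normalized to the total intensity
density of the cell" names $n_k$, which is the primary metric here. Both
are invariant to rescaling the image by a constant.

Background is removed beforehand by the rolling-ball algorithm: the
background estimate is the grayscale opening of the image by a
hemispherical (ball) structuring element of radius 30 px (the standard
radius for this assay and the package default), and the difference is
clipped at zero. Opening with a non-flat ball preserves features smaller
than the ball (puncta) while tracking slow illumination gradients; a
constant image maps to exactly zero. For z-stacks the maximum-intensity
projection is taken **before** subtraction — the conventional listing
order (project, then subtract) — and the alternative order is not offered,
to keep outputs comparable.

## Segmentation

Ring analysis requires a cell mask, a nucleus mask and the nucleus
centroid. The nucleus is segmented from the DNA channel by Otsu
thresholding of a 3×3 median-filtered image, hole filling, one closing
with a 2-px disk, and keeping the largest component; the centroid is the
unweighted center of mass of the mask (no intensity weighting). The cell
is the above-threshold tracer component containing the nucleus, holes
filled, with the nucleus unioned in so containment always holds.
Automatic cell segmentation is a stand-in for manual outlining and is
validated only on synthetic scenes (IoU ≥ 0.95 nucleus, ≥ 0.9 cell);
manually drawn masks are first-class inputs via `load_manual_masks()`,
which clips a nucleus overhanging the cell by up to 10% of its area (with
a warning) and errors beyond that.

## Tandem-reporter scoring

In the mCherry-GFP-LC3 reporter, autophagosomes fluoresce in both
channels while the acidic autolysosome lumen quenches GFP, leaving
mCherry only. Scoring therefore is: every red punctum is an autophagic
vacuole (AV); red puncta with a matched green punctum are autophagosomes
(APG); the remainder are autolysosomes (AL), the flux readout. The
identity AV = APG + AL is asserted per cell.

Puncta are detected as local maxima of the scale-normalized
Laplacian-of-Gaussian response at scale `sigma` (default 2 px, matching a
diffraction-limited punctum at ~100 nm pixels) above a relative threshold
(default 0.1 × max response), with minimum separation $2\sigma$ and
deterministic tie-breaking toward the smallest (row, col). Red–green
matching is greedy on globally nearest pairs within `match_radius`
(default $2\sigma$), each green punctum used at most once; inputs are
sorted by (row, col) first so results do not depend on detection order.
GFP-positivity by detection matching is parameter-light; an alternative
mode thresholds the green intensity at red positions
(`green_mode = "intensity"`) for users who prefer the vendor-style rule.
Green-only puncta are logged but never counted. The detector replaces
unavailable vendor software and is validated against synthetic ground
truth only — the defaults are not claimed to match any instrument.

## Vacuole classification and morphometry

Annotated vacuoles (diameter plus seven ultrastructural booleans) are
classified by a fixed decision rule: below the 0.5 µm diameter gate →
excluded; at least two of the four autophagosome criteria (double
membrane, no attached ribosomes, luminal density similar to cytosol,
identifiable organelles in the lumen) → APG; otherwise at least one
single-membrane criterion → AUT; otherwise unclassified (logged, excluded
from AV). The APG rule takes precedence when both could apply, since it
is the stated positive test; "0.5 µm" is read as a minimum size gate and
is configurable. Per cell the package reports AV = APG + AUT counts, the
AV area fraction of the cell, mean APG/AUT areas and the maturation
percentages (%APG, %AUT of AV, summing to 100 whenever AV > 0). The
single-membrane class is treated as one class (autolysosomes) regardless
of naming variants. No EM pixel analysis is attempted: classification is
by eye upstream; the package implements the stated decision rule on the
annotations.

## Statistics

Band densitometry: marker/loading-control quotients (or marker/marker
ratios such as LC3-II/LC3-I), fold changes rescaled so the control-group
mean is 1, and compartment percentages summing to 100. The unpaired
two-sided t-test defaults to the pooled-variance Student form — the most
common reading of "unpaired t-test" — with Welch as a flag. One-way
ANOVA reports the omnibus F from between/within mean squares; pairwise
comparisons use t statistics on the pooled within-group variance with the
Šidák adjustment $p_\mathrm{adj} = 1-(1-p)^m$ over the $m$ requested
comparisons (Bonferroni, $p_\mathrm{adj} = \min(1, mp)$, is available but
unadvertised; two-way designs are out of scope). p-values come from the
t/F distribution functions in double precision. Both tests are
calibration-checked on simulated nulls (type-I error within 1 percentage
point of α = 0.05 over 2000 replicates).

## The synthetic world

The generator emulates the acquisitions this pipeline is built for, with
defaults chosen once as a realistic confocal scene: a 256×256 field at
0.05 µm/px (the 50 nm lateral voxel of a 63× confocal z-stack), one
mildly lobed star-shaped cell (low-order radial harmonics, amplitude ≤
0.12–0.15) filling most of the field, a round nucleus at a quarter of the
cell radius slightly offset from center, puncta rendered as isotropic 2-D
Gaussians (σ = 2 px, amplitude 100) truncated at 4σ, a constant
background of 5 with a low-order polynomial gradient of amplitude 2,
Poisson shot noise on the signal and Gaussian read noise (σ = 1).
Acquisition noise characteristics are not published for this class of
experiment; these values are documented defaults, not instrument claims.

Puncta are placed by sampling a target ring from the radial-placement law
(probability per ring), then a uniform pixel within that ring of the true
equal-area partition of the true geometry; the ground truth records the
**realized** per-ring intensity fractions of the clean (noise- and
background-free) marker image, so spill-over of spot tails across ring
boundaries is part of the truth rather than an error term. Tandem scenes
make the dual-positive count deterministic — exactly
`round(apg_fraction × n_puncta)` puncta appear in green — so composition
tests are exact. Vacuole and band tables carry their true classes and
fold changes as columns/attributes. All generators thread one seeded RNG
and restore the caller's RNG state; a fixed seed gives bit-identical
output, which the acceptance suite exploits for byte-level pipeline
determinism.

What a green test does **not** establish: the scenes contain a single
cell, no touching cells, no debris, no chromatic offset between channels,
isotropic Gaussian spots rather than a real PSF, and no axial blur in the
optional z-stack mode (puncta sit on single planes). Segmentation and
detection accuracies measured here are upper bounds on real-data
performance.

## Numerical choices

* Coordinates are 0-based (row, col) with pixel centers at integers;
  areas are pixel counts (µm² reported when pixel size is known).
* Equal-area solver: bisection to half the area tolerance per boundary
  (so ring differences stay within the full tolerance), at most 100
  iterations, hard error with achieved areas on failure.
* TIFF interchange uses an internal baseline codec (uncompressed,
  grayscale, multi-page; 8/16/32/64-bit) because no TIFF reader/writer
  was available among the supported dependencies; stacks are written as
  64-bit float pages so arrays round-trip exactly, and the test suite
  cross-checks the codec against an independent implementation.
  Compressed or tiled TIFFs are rejected with a clear error.
* Morphological erosion/dilation iterate offset-outer over valid index
  rectangles (vectorizable inner loops); out-of-image offsets are ignored
  (border convention: fewer offsets near the edge).
* YAML configs are schema-checked: unknown keys are errors, so typos
  cannot silently fall back to defaults.

## Known limitations

* No 3-D ring partition (projection comes first by design); no watershed
  splitting of touching cells; no learned segmentation.
* The LoG detector under-counts overlapping puncta closer than ~2σ;
  synthetic tandem scenes enforce a minimum separation of 4σ by default,
  real data need not.
* Whether the original radial analyses normalized by density ratio or
  intensity fraction varies between studies; both are emitted, and
  figure-level comparison is out of scope.
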