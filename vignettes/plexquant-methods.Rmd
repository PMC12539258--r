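---
title: "Methods and conventions in plexquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and conventions in plexquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`plexquant` quantifies multiplexed immunofluorescence (mIF) and imaging
mass cytometry (IMC) tissue images at single-cell level and scores the
spatial concordance of the two modalities. This vignette documents the
models behind each stage, the parameters a user may want to move, the
numerical conventions the implementation commits to, and what the
synthetic fixtures do and do not demonstrate.

## Coordinates

All geometry is in continuous micrometres with the origin at the top-left
pixel *corner*, x rightward (columns) and y downward (rows); the centre of
pixel `(r, c)` (1-based) is `((c − 0.5)·s, (r − 0.5)·s)` for pixel size
`s`. This makes mask↔point conversions unambiguous: a centroid computed
from a mask and a point drawn in μm coordinates land in the same frame.

## Spectral unmixing

The signal model is linear: per pixel, the acquired channel vector is
`c = M a + b` with non-negative abundances `a`, a channels × sources
matrix `M` whose columns are normalized emission spectra (one column per
fluorophore plus one for autofluorescence) and a per-channel background
offset `b`.

* `b` is the per-channel median of the unstained library image.
* Column `f` of `M` is the per-channel median over the `top_fraction`
  (default 0.01) brightest pixels of stain `f`'s primary channel,
  background-subtracted, clipped at zero, normalized to sum one. Medians
  over a bright-pixel subset are robust to the occasional saturated or
  dust pixel; the fraction is configurable.
* The unstained image doubles as the autofluorescence stain. If it is
  structureless (constant), its spectral column degenerates to zero; the
  model then falls back to an indicator of the designated
  autofluorescence channel, which keeps the matrix full rank without
  inventing signal.
* Abundances are recovered per pixel by non-negative least squares
  (active-set, via an unconstrained solve with NNLS refinement only where
  the unconstrained solution goes negative — the two coincide wherever the
  unconstrained solution is already feasible, so the shortcut is exact).
  Pixels are independent; the result does not depend on processing order.
  Whether the original acquisition software uses NNLS, ordinary least
  squares or sequential subtraction is not documented; the NNLS contract
  was chosen because it is the natural estimator under the non-negativity
  physics and is exactly invertible on noiseless forward simulations,
  which the tests exploit.
* A mixing matrix with condition number above ~1e10 is rejected with the
  singular values in the error message.

## Nuclear segmentation

Stages, in order: (i) foreground = pixels strictly exceeding the local
mean over a square window of side `window_um` (default 51 μm) minus
`offset` (default 0; larger values admit more foreground); (ii) hole
filling; (iii) removal of objects below `min_area_um2` (default 8 μm²,
well under a 6–10 μm nucleus); (iv) Euclidean distance transform;
(v, vi) watershed of the negated distance map restricted to the
foreground, merging basins whose peaks are closer than `min_peak_sep_um`
(default 4 μm). The defaults are exposed in the configuration; they are
working values for roughly nucleus-sized objects, not constants of the
method.

Numerical choices worth knowing:

* The local mean is computed with an exact integral image (replicated
  borders), not FFT convolution. FFT ringing leaves ±1e-13 residues in
  empty regions, which a strict `intensity > local mean` rule would
  amplify into spurious foreground; the integral image is exact, and its
  own cancellation residue is clamped at zero so a zero-intensity pixel
  can never exceed its local mean.
* Objects are labelled with 8-connectivity; watershed basins follow the
  underlying EBImage implementation. A constant or all-zero image yields
  an empty mask, not an error.

## Cell expansion and cytoplasm

Cells are nuclei extended by up to `max_dist_um` (default 5 μm): each
background pixel joins the nucleus with the smallest Euclidean *set*
distance (distance to the nearest nucleus pixel, computed on the pixel
grid), provided that distance is ≤ `max_dist_um`; ties go to the smaller
label id, which makes the partition deterministic. The implementation
(one distance transform per label, running minimum across labels) is
exactly equivalent to the brute-force per-pixel nearest-nucleus rule, and
the test suite asserts label-for-label equality against that oracle on
images up to 128². Cytoplasm is cell ∖ nucleus per label; a cell whose
expansion is blocked on all sides has an empty cytoplasm, and its
cytoplasm statistics are reported as missing (NA), never zero.

## Quantification, thresholds, phenotypes

Marker scores are summary statistics (mean, median, 75th, 90th
percentile; type-7 quantiles) of pixel intensities over nucleus,
cytoplasm and cell regions. Positivity is strict: a score exactly at the
threshold is negative, mirroring the "above the threshold" phrasing of
the rule. Phenotype keys map each positivity combination to a label; when
several rules match, the rule whose required-positive marker ranks
highest in the priority order wins. This generalizes the printed
CD3/CD163 example (membrane-proximal markers outrank diffuse ones)
deterministically; a full priority order over the key's markers is
assumed. Keys are validated at load time by enumerating all 2^M
combinations (M ≤ 12) — ambiguities that the priority cannot resolve are
reported with the offending combination rather than surfacing later as
data-dependent behaviour.

The classifier harness is deliberately thin: any model exposing class
probabilities can be plugged in. The unknown rule is strict ("below 30%"
→ unknown; exactly 30% keeps the label), and evaluation reports per-class
TPR/FPR, accuracy and MacroF1 over classes present in the truth (declared
but absent classes are excluded with a warning rather than contributing
zero F1).

## Tissue segmentation

The naive labelling (tumour iff cytokeratin-positive) is refined once:
connected groups of fewer than 5 stroma cells attached to a tumour group
of more than 10 cells become tumour, and symmetrically. Both inequalities
are strict, so a 5-cell island survives and a 10-cell neighbour does not
trigger reassignment. All reassignments are evaluated on the naive
labelling and applied simultaneously in a single pass — "a second step"
is read as one step, and the tests pin down that a second application
changes nothing on the fixtures used.

## TLS detection and IMC patches

Local density at a point is the disk count within `radius_um` (default
50 μm), self included, divided by the disk area, in cells/mm². Two
conventions are deliberate:

* The count uses the *open* disk (distance strictly below the radius),
  with squared distances within one part in 1e9 of the squared radius
  treated as boundary ties and excluded. Regular lattices place entire
  point shells at exactly the radius; the tie rule makes their counts
  independent of floating-point rounding of an irrational spacing, and
  the open-disk choice is consistent with the strict "density above
  2000 cells/mm²" rule — a uniform field at exactly the threshold
  intensity does not pass.
* The estimator itself (disk counts, 50 μm radius) is the package's
  choice; the underlying rule names only the threshold. Both radius and
  threshold are configurable.

TLS patches are alpha-shape components (alpha radius = density radius by
default) of the density-passing B cells, retained at ≥ 40 members; no
expansion is applied, so TLS membership is exactly the density-passing
set. IMC-style patches instead grow from connected components (≥ 25
member-type cells) of the neighbourhood graph and are expanded to every
cell whose centroid lies within `expand_um` (inclusive, per "within") of
the nearest core member's centroid — 10 μm for CD20 patches, 25 μm for
tumour patches. Distances are centroid-to-centroid because centroids are
the only geometry guaranteed to exist in an IMC cell table; expansion is
monotone in the radius.

The alpha shape is computed from the Delaunay triangulation (deldir),
keeping triangles with circumradius ≤ alpha; patch area is the summed
triangle area and the outline is the boundary-edge ring. Degenerate
inputs (fewer than three points, collinear configurations) fall back to
distance-linked components with a convex-hull outline of zero area.

The neighbourhood graph itself offers two constructions: mask expansion
(edge iff two cell masks touch after each grows by 4 μm, i.e. set
distance ≤ 8 μm) and Delaunay edges capped at 30 μm. Collinear centroid
sets, where no triangulation exists, degrade to the path graph along the
line — the limit of the triangulation as the points become collinear.

## Spatial concordance

Modalities are aligned with a closed-form least-squares similarity
transform (centred cross-covariance SVD; reflection only on request; an
affine fit is available for ≥ 3 non-collinear pairs) from at least 4
landmark pairs. Cross-type K uses the translation edge correction,
`e(u,v) = |W| / |W ∩ W_{v−u}|`, which is exact and simulation-free on
rectangular windows; a no-correction mode exists for diagnostics. The
radii grid defaults to 512 steps from 0 to a quarter of the shorter
window side, the standard guard against uncontrolled edge effects at
large r. The co-location score is the trapezoidal integral of
`L̂(r) − r`; the MAD test simulates the null conditionally on the
observed per-type counts (binomial CSR in the same window) and returns
the rank p-value `(1 + #{T_k ≥ T_obs}) / (nsim + 1)`, so 99 simulations
give a minimum attainable p of 0.01 — exactly the bound used by the
co-localization call (area > 0 and p ≤ 0.01). The reference curve of the
MAD statistic is the theoretical `L(r) = r`, not the simulation mean; the
choice matters little at the tested scales and keeps the statistic
deterministic given the pattern.

## Batch stability and sample QC

CVs use the sample standard deviation (n − 1); the estimator is not
specified by the underlying rule and n − 1 is the unbiased-variance
default. CVs of marker means are computed within cell type first and
averaged per marker over the cell types where the marker is declared
expressed, because absolute expression differs strongly between cell
types and pooling would measure that difference, not batch noise.
Fractions are reported as fractions (rendered as % by the CLI). Exactly
50% missing tissue is a WARN — FAIL requires strictly more than half.

## Synthetic fixtures: what they show and what they cannot

The generators produce: tissue images (Gaussian-blurred nuclear disks,
phenotype-determined marker levels over cell regions, truncated Gaussian
noise), point patterns (binomial/Poisson CSR, square lattices, Thomas
clusters), spectral-mixing scenes (sparse bright single-stain pixels plus
background) and control-pellet batch series (multinomial counts,
log-normal multiplicative expression noise with theoretical CV
`sqrt(exp(sigma²) − 1) ≈ sigma`). All are seed-deterministic, and the
ground truth they return satisfies the invariants of the consuming
modules by construction.

Two rendering details exist purely to keep synthetic zero-background
images well-posed: the disk blur uses a truncated separable Gaussian
kernel (radius 2σ) so intensities are exactly zero outside a compact
support, and the default nucleus separation (14 μm) keeps neighbouring
blur halos from merging. Real images have noise floors that make both
irrelevant; on real data the segmentation `offset` is the knob that plays
this role.

Passing on these fixtures demonstrates correctness of the *rules and
estimators* — boundary behaviour of every printed constant, exact
agreement with brute-force oracles, calibration of the Monte-Carlo test —
not performance on real tissue. The fixtures have no out-of-focus
regions, no staining artefacts, no marker spillover beyond what the
mixing model encodes, and disk-shaped nuclei; segmentation accuracy
numbers on them are upper bounds, not forecasts.

Problem sizes used by the test-suite and acceptance computations (60-cell
images at 1 μm/px, ≤ 500-point patterns, 99–199 CSR simulations, 100–500
replicate calibrations) were chosen so that each property is measured
with comfortable statistical margin while the whole suite stays
interactive on a laptop.

## Storage conventions

Images travel as plain multi-page TIFF plus a CSV channel manifest;
pyramidal multispectral containers must be converted upstream. Intensities
are stored as 32-bit samples after scaling into [0, 1] by a power-of-two
factor recorded in the manifest: the scaling is exact in binary floating
point and the quantization step is `scale/2^32` (relative ~2.3e-10), so
integer-valued camera counts round-trip exactly after rounding. Label
masks use 16-bit TIFF (≤ 65535 objects). Cell tables are UTF-8 comma CSV
with a documented column order and numeric fields written with enough
digits to reparse exactly; unknown columns pass through untouched. Patch
sets export as GeoJSON plus a membership CSV; graphs as edge-list CSV.

## Known limitations

* The Voronoi cell model has no membrane information; touching cells are
  split at equidistance, which merges or truncates irregular cells.
* The watershed peak-separation parameter approximates, not implements, a
  literal "local maxima at ≥ d apart" seed rule; heavily overlapping
  nuclei may still merge.
* The translation edge correction assumes a rectangular observation
  window; irregular ROIs would need a different correction.
* The MAD test conditions on observed counts; it tests spatial
  arrangement, not abundance agreement.
* Alpha-shape outlines with holes report the outer ring only (areas are
  computed from triangles and are unaffected).
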