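---
title: "Quantifying microtubule radiality and synapse morphology in T cells"
author: "SynapseMorph maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule radiality and synapse morphology in T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynapseMorph)
```

## The biological question

When a cytotoxic T lymphocyte (CTL) engages a target cell, or spreads on an
antibody-coated surface mimicking one, its cytoskeleton reorganizes: the
centrosome (the microtubule-organizing centre, MTOC) moves towards the
contact site, microtubules adopt a radial spoke-like arrangement around it,
filamentous actin clears from the synapse centre and accumulates in a
peripheral ring, and the cell footprint becomes round and smooth. Defects in
any of these steps — disorganized microtubules, irregular protrusive
morphology, an unpolarized centrosome, an incomplete actin ring — are
quantitative readouts of impaired synapse assembly.

SynapseMorph turns single-channel fluorescence images of such cells into
per-cell numbers for each of these readouts, and provides the two-group
statistics used to compare patient-derived and control cells.

## The Degree of Radiality (DoR)

The central statistic scores how radially the microtubule network is
arranged around the cell centre. For one tubulin image the pipeline is:

1. **Segmentation.** Otsu's global threshold on the raw intensities;
   8-connected components smaller than `minAreaPx` (default 100 px) are
   discarded and the largest survivor kept. The analysis is single-cell:
   images containing several cells must be cropped per cell first.
2. **Cell centre and reference fields.** The convex hull of the mask is
   filled and the centre of mass of the filled hull taken as the cell
   centre. At every hull pixel $p$ the *radial* unit field is
   $\hat r(p) = (p - c)/\lVert p - c\rVert$ and the *circular* field
   $\hat c(p)$ is $\hat r(p)$ rotated by 90°. A 1-px disk at the centre,
   where the direction is undefined, is excluded.
3. **Local filament orientation.** The structure tensor — the Gaussian-
   smoothed outer product of the Gaussian-scale image gradient, both at
   scale `sigmaPx` (default 1.5 px, about one filament width) — is
   diagonalized at every pixel. The eigenvector of the *smaller* eigenvalue
   gives the dominant stripe direction $t(p)$, an axial quantity defined
   modulo $\pi$; the eigenvalue contrast
   $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$ is the coherence in
   $[0,1]$.
4. **Radial sections.** An elliptical Fourier descriptor (EFD,
   Kuhl–Giardina) is fitted to the hull boundary; scaling it about the cell
   centre by $k/K$ ($k = 1..K$, default $K = 4$) yields intermediate
   contours, and section $k$ is the band between contours $k-1$ and $k$.
   The *relative radial distance* of section $k$ is the integer $k$; a
   pixel exactly on contour $k$ belongs to section $k$. The published
   convention of reporting "relative radial distance 2" therefore denotes
   the second of four sections.
5. **DoR.** Per section $s$, over the valid orientation pixels,
   $$\mathrm{DoR}(s) = \frac{\sum_{p\in s} |t(p)\cdot\hat r(p)|}
   {\max\left(\sum_{p\in s} |t(p)\cdot\hat c(p)|,\ \epsilon\right)}.$$
   Purely radial networks give large DoR, purely tangential ones 0, and an
   isotropic orientation field gives DoR $\to 1$ because
   $E|\cos\theta| = E|\sin\theta|$ for axial-uniform angles. The guard
   $\epsilon$ defaults to $10^{-6}$ times the section's pixel count, which
   keeps a zero denominator finite without affecting any realistic value
   and makes the statistic invariant to global intensity scaling.

```{r dor-example}
spec <- syntheticCellSpec(radialityAlpha = 1, seed = 7)
sim <- makeFilamentCell(spec)
profile <- analyzeRadiality(sim$image, cellId = "radial_demo")
as.data.frame(profile)
dorAt(profile, 2)
```

### Which pixels count

Two validity gates are applied before the sums, both exposed as parameters
of `analyzeRadiality()`:

* **Boundary shell** (`boundaryExcludePx`, default 4): the intensity step
  at the cell edge produces a strong, high-coherence orientation parallel
  to the boundary — i.e. spuriously tangential. Because two Gaussian
  passes and a finite-difference stencil spread that signal inwards, a
  4-px shell (about 2–3 tensor scales) at the mask boundary is excluded.
* **Intensity gate** (`intensityGate`, default on): orientation is only
  physically meaningful where there is filament signal. Pixels must exceed
  the Otsu threshold of the smoothed intensities inside the (eroded) mask;
  flat cytoplasm otherwise inherits a long-range orientation from the
  nearest edge or filament and dilutes DoR towards 1. A coherence floor
  (`coherenceMin`, default 0.2 in the pipeline wrapper; the low-level
  `orientationField()` defaults to 0 and keeps every hull pixel) acts the
  same way on noisy backgrounds.

### Known limitations of the statistic

* The innermost section sits on the MTOC itself: where many filaments
  converge, their summed intensity forms a dome whose gradient is radial,
  so the local stripe orientation is *tangential* regardless of how radial
  the network is. DoR in section 1 is therefore unreliable — one reason to
  report section 2.
* The outermost section borders the excluded edge shell and can be sparsely
  populated in small cells; its record carries `nPixels` so downstream code
  can weight or drop it.
* DoR compares summed projections, not filament counts; thick bundles
  contribute more pixels than single filaments.

## Morphology metrics

Cell outlines from the CD8 channel's maximum projection are summarized by
two complementary numbers computed by `shapeMetrics()`:

* **Roughness** $= P/P_{hull}$, the Crofton perimeter of the mask over that
  of its convex hull. It is 1 for convex shapes and grows with protrusive,
  small-scale boundary irregularity. Both perimeters use the *same*
  4-direction Crofton estimator so its discretization bias largely cancels
  in the ratio. (The estimator itself reproduces the scikit-image
  `perimeter_crofton` values bit-for-bit on identical masks; note that on
  long axis-aligned straight edges the 4-direction Crofton formula has a
  known ~5% negative bias — a property of the estimator, not a bug.)
* **Roundness** $= 4A/(\pi \cdot MA^2)$, with $MA$ the major-axis length of
  the moment-equivalent ellipse ($4\sqrt{\lambda_{max}}$ of the pixel
  coordinate covariance). It is 1 for a circle, $b/a$ for an ellipse, and
  captures large-scale elongation while being insensitive to local
  irregularity.

```{r morph-example}
rough <- cellMaskFromBinary(makeRoughMask(c(40, 40), epsilon = 0.3, lobes = 8L))
shapeMetrics(rough, "perturbed")[, c("roughness", "roundness")]
```

## Synapse geometry

`centrosomeDistance()` converts two annotated points (pericentrin punctum
and synapse centre, e.g. from `readAnnotations()` or `detectPunctum()`)
into an in-plane Euclidean distance in µm and assigns the reporting bin:
`<=1` (polarized, distance at most 1 µm), `1-3`, or `>3` µm. Both boundary
values are closed on the inner bin (1.0 µm → `<=1`, 3.0 µm → `1-3`). The
distance is measured in the 2-D projection plane, matching a manual
two-point measurement; no point-to-membrane-contour geometry is invented.

`factinProfiles()` samples bilinearly interpolated intensities at 0.5-px
steps along full-width lines through the cell centre (default angles 0, 45,
90, 135°), extended 4 px past the hull so boundary-localized signal such as
the actin ring is fully covered. Classifying actin organization from these
profiles (ring + clearance vs not) is deliberately left to the user: in the
motivating study that ranking was a blinded human judgement.

## Two-group statistics

`compareGroups()` implements the two tests used for per-cell image metrics:
Student's pooled-variance two-sample t (the scientific-computing default
for an "independent-samples t-test"; Welch's form via `welch = TRUE`) and
the Mann–Whitney U test, exact when the smaller group has ≤ 8 observations
without ties and normal-approximated with tie correction otherwise.
Completely tied data return p = 1. `batchReport()` applies the chosen test
per metric between exactly two groups and draws box plots with 1.5×IQR
whiskers (per-cell convention) or min–max whiskers (per-subject summaries).
No multiple-testing correction is applied by default, mirroring
discovery-phase reporting on small rare-disease cohorts; Benjamini–Hochberg
is available via `adjust = "BH"`.

## The synthetic-image generator

Real confocal data for this assay are not publicly deposited, so every
stage is validated against `makeFilamentCell()` /
`makeConjugateImage()` images with analytic ground truth. Design choices:

* **Straight filaments.** Each of `nFilaments` (default 60) anti-aliased
  segments is radial (from near the organizing centre to ~95% of the
  boundary) with probability `radialityAlpha`, otherwise a short tangential
  chord (8 px, well under the 15-px bound that keeps a chord's axial
  direction meaningful) placed uniformly along the radius. Straight
  segments make the drawn orientation an exact oracle; curvature would add
  realism but destroy it.
* **Footprint.** An ellipse (default semi-axes 26 × 21 px at 0.2 µm/px —
  a ~10 µm spread T cell) with optional boundary perturbation
  $r(\theta)\,(1+\varepsilon\cos m\theta)$ for roughness studies; the
  organizing centre defaults to a (3, −4) px offset from the footprint
  centre, as centrosomes are rarely exactly central.
* **Intensities.** Background 10, cytoplasm 100, filament peak ≈ 180,
  additive Gaussian noise `noiseSigma` (default 5) clamped at zero — a
  moderate-SNR confocal setting. The conjugate generator adds an F-actin
  boundary ring of sd 3 px (~0.6 µm, a realistic synaptic actin band) and
  a Gaussian pericentrin punctum of sd 2 px.
* **Seeding.** One seeded generator per call; the global RNG state is
  untouched and identical specs render bit-identical images.

What passing on these images does *not* show: robustness to uneven
illumination, deconvolution artifacts, curved or bundled filaments,
overlapping cells, or 3-D effects — the generator is a validation surface
for the estimators, not a microscope simulator (no PSF convolution or
photon statistics).

## Numerical choices and conventions

* Coordinates are 1-based `(row, col)` matrix indices, row axis down;
  physical distances are pixel displacements × `pixelSizeUm`. Orientation
  angles are measured from the column axis, modulo $\pi$; the circular
  field's rotation sign is fixed (+90°) and immaterial because DoR takes
  absolute dot products.
* Intensities are never rescaled at load; Otsu and the structure tensor
  are scale-tolerant, and tests assert DoR and segmentation invariance
  under global intensity scaling.
* Gaussian smoothing uses replicate (edge-clamped) boundaries so kernels
  remain valid near borders and on images smaller than the kernel.
* The structure tensor's coherence is defined as 0 wherever the tensor
  trace falls below $(10^{-10}\,\max|I|)^2$ — a floor that zeroes pure
  floating-point noise on constant images yet scales with intensity², thus
  preserving scale invariance.
* A pixel exactly on intermediate contour $k$ is assigned to section $k$
  (the section whose outer edge it is); hull pixels marginally outside the
  EFD reconstruction are clamped to section $K$ so the sections always
  partition the hull interior minus the centre disk.
* The first Fourier harmonic of an arc-length-parameterized ellipse is
  *not* the ellipse itself: for a 2:1 ellipse the first-harmonic axis
  ratio is 1.704, while the full reconstruction still spans a 2:1 extent.
  Tests pin both numbers.

## Problem sizes used in the validation suite

The test-suite and acceptance-script simulations use 30 cells per radiality
level for the monotonicity study (five levels, Spearman ρ of level means),
a 150-cell pool at α = 0.6 resampled into 200 two-group replicates for
type-I calibration, and 60-cell pools at α = 1.0 and 0.2 resampled into 100
replicates for power. Pool resampling keeps every replicate a valid draw
under exchangeability while the simulated-cell count stays proportionate
to a desk-scale study; the DoR limit cases use a disk with over $10^5$
pixels in its outer section so the Monte-Carlo comparison is tight.
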