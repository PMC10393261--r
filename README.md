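# SynapseMorph

Quantitative image analysis of T-cell immunological synapses from
single-channel fluorescence microscopy, for cell biologists and
immunologists comparing cytoskeletal organization between cell groups
(e.g. patient-derived vs healthy-donor CTLs spread on stimulating
surfaces).

The package computes, per cell:

* **Degree of Radiality (DoR)** of the microtubule network. After Otsu
  segmentation, the cell centre is the centroid of the filled convex hull;
  the local filament orientation t(p) comes from the structure tensor
  (eigenvector of the smaller eigenvalue, axial mod π); the hull is split
  into K radial sections by scaling an elliptical Fourier fit of its
  boundary about the centre; and per section

      DoR(s) = Σ_p |t(p)·r̂(p)| / max(Σ_p |t(p)·ĉ(p)|, ε)

  with r̂ and ĉ the radial and circular unit fields. Radial networks give
  DoR ≫ 1, tangential ones ≈ 0, isotropic ones ≈ 1. The headline per-cell
  value is DoR at relative radial distance 2 (the second of four
  sections).
* **Roundness** `4·area/(π·MA²)` (MA = moment-ellipse major axis) and
  **roughness** `P/P_hull` (4-direction Crofton perimeters of mask and
  convex hull) — large-scale elongation and small-scale boundary
  irregularity of the cell footprint.
* **Centrosome polarization**: Euclidean distance (µm) between the
  annotated pericentrin punctum and synapse centre, binned `<=1`, `1-3`,
  `>3` µm (both boundaries closed on the inner bin).
* **F-actin line profiles** through the cell centre at several angles, for
  assessing the synaptic actin ring and central clearance.
* **Two-group statistics**: Student's pooled t (Welch optional) and
  Mann–Whitney (exact for small untied samples), with box-plot reporting.

A seeded synthetic-image generator (`makeFilamentCell()`,
`makeConjugateImage()`, `makeRoughMask()`) renders filament cells,
conjugate stainings and rough masks with analytic ground truth, so the
whole pipeline is validated without access to the original confocal data.

## Worked example

```r
library(SynapseMorph)

spec <- syntheticCellSpec(radialityAlpha = 0.9, seed = 42)  # mostly radial
sim  <- makeFilamentCell(spec)
sim$image
#> ChannelImage 'tubulin': 65 x 65 px, 0.2 um/px, range [0, 191.8]

prof <- analyzeRadiality(sim$image, cellId = "demo")
prof
#> DoRProfile for 'demo':
#>  cell_id relative_distance       dor n_pixels
#>     demo                 1 1.2484421       87
#>     demo                 2 1.2251778      259
#>     demo                 3 2.1726192      343
#>     demo                 4 0.9178635       82
dorAt(prof, 2)
#> [1] 1.225178
```

DoR above 1 in the interior sections says the filaments run radially —
as they should for `radialityAlpha = 0.9`. (Section 1 sits on the
organizing-centre convergence dome and section 4 borders the cell edge;
see the vignette for why those are less reliable.)

```r
cm <- segmentCell(sim$image)
shapeMetrics(cm, "demo")[, c("area_px", "roughness", "roundness")]
#>   area_px roughness roundness
#> 1    1711         1 0.8055433

centrosomeDistance(list(image_id = "demo", row = 30, col = 46),
                   list(image_id = "demo", row = 31, col = 50), 0.2)
#>   cell_id distance_um bin
#> 1    demo   0.8246211 <=1
```

Roughness 1 = convex outline; roundness 0.81 = mildly elliptical; the
centrosome sits 0.82 µm from the synapse centre, i.e. polarized (`<=1`).
Comparing DoR between two groups of 30 cells:

```r
set.seed(1)
g1 <- rnorm(30, 1.5, 0.3); g2 <- rnorm(30, 0.9, 0.3)
compareGroups(g1, g2, "t_independent", metricName = "dor")
#>   metric_name n_a n_b   mean_a    mean_b statistic      p_value
#> 1         dor  30  30 1.524737 0.9398324  8.758648 3.324739e-12
```

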