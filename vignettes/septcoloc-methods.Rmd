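---
title: "Methods: septin–cytoskeleton colocalization and filament morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: septin-cytoskeleton colocalization and filament morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septcoloc)
```

## Scope and model

`septcoloc` quantifies how septins (SEPT9 and septin complexes)
associate with microtubules and actin in fluorescence microscopy. Three
analysis families are implemented, each validated against a synthetic
phantom generator with exact ground truth.

### The 3-D colocalization pipeline

Input is a two-channel stack (septin `SEP`, microtubule `MT`) with voxel
geometry, typically 108 × 108 × 200 nm. Every anisotropic operation
scales its axial extent by the z/xy voxel ratio so physical distances
are honored.

**Segmentation.** The cell mask triangle-thresholds the
Gaussian-smoothed channel sum (σ = 500 nm), applies a 3-D ellipsoidal
closing (650 nm) and rejects components below 50 µm³. The triangle rule
is used because the intensity histogram of a fluorescent cell on dark
background is strongly unimodal-skewed rather than bimodal; its
threshold lands just above the background peak and yields a generous
mask, which is intended — downstream statistics are restricted further.
The nucleus is found inside the cell from the diffuse-septin / low-MT
score `nuc_score = smooth(SEP) × (1 − smooth(MT))` (σ = 1 µm; channels
min–max normalized over the cell so the product is meaningful),
triangle-thresholded, and candidate components are kept only when their
median raw MT falls strictly below 0.5 × the cell-wide MT median. The
cytoplasmic volume exNuc = cell − nucleus carries all headline metrics.

**Bleed correction.** Spectral crosstalk is modeled as
`SEP_observed = SEP_true + α·MT`. Background per channel is the median
outside the cell (falling back, flagged, to the 1st percentile inside
when almost no outside voxels exist). The slope α is the median of
`(SEP − bg)/(MT − bg)` over exNuc voxels whose SEP intensity is at or
below the 25th percentile of SEP over exNuc — voxels least likely to
carry genuine septin — and whose background-subtracted MT clears a
positivity floor of twice the robust MT background noise SD (guarding
against ratio blow-up). Estimates above 0.30 are capped, above 0.60
rejected as diffuse cytosolic septin rather than bleed; both bounds are
configuration, as typical filter-set crosstalk is well below 30 %.
Where accepted, `SEP_corr = max(0, SEP − α·MT)`.

**Enhancement and skeletons.** The septin channel is
background-subtracted with an ellipsoidal white top-hat (500 nm); the
microtubule channel is high-pass filtered by subtracting a 2 µm Gaussian
blur (suppressing centrosomal flare). Both are enhanced with a 3-D
Frangi vesselness at three physical scales (150, 250, 400 nm — tube
radii bracketing a PSF-blurred microtubule), sensitivity constants
α = β = 0.5 and the standard auto rule c = half the maximum Hessian
norm per scale; Hessian eigenvalues come from the closed-form Cardano
(trigonometric) solution, and γ-normalization (σ²) makes scales
comparable so the voxelwise maximum is meaningful. Masks are grown by
hysteresis thresholding within the cell. The hysteresis levels default
to the 98th/90th percentile *of the active response support* (voxels
above 2 % of the in-cell maximum): quantiles of the raw in-cell
response would tie the mask size to the fraction of the cell that is
filamentous and segment faint texture in sparse fields, which
calibration on phantoms showed to be unusable — this is the one place
the implementation deviates from a plain in-cell quantile. Masks are
closed (1 voxel laterally), restricted to exNuc, thinned to 1-voxel
centerlines, and components below 1 µm geodesic length are discarded.

Thinning is a directional border thinning with endpoint preservation;
deletability uses the topological simple-point characterization for
(26, 6) connectivity (one 26-connected foreground component among the
26 neighbors, one 6-connected background component in the
18-neighborhood touching a face), with sequential re-checking. Lengths
are geodesic diameters over the 26-neighbor graph with anisotropic
Euclidean step costs.

**Metrics.** The skeleton-overlap fraction is the share of septin
skeleton voxels inside a 2-voxel lateral dilation of the MT mask —
about one lateral PSF FWHM (~220 nm at 108 nm/px), a tolerance buffer
for diffraction-limited channel offsets; axially the same physical
distance is used, rounded to voxels. The Manders coefficient is
Σ I_SEP(MT mask ∩ exNuc) / Σ I_SEP(exNuc), invariant to positive
rescaling of SEP. Both directions of the overlap are available
(`overlap_direction` in the configuration); the septin-skeleton-in-MT
direction is the default.

### The 2-D actin bundle quantifier

Multiscale Sato ridge response (σ = 1.5, 2.5, 4, 6, 8 px, bright
ridges: −λ₂ where the principal Hessian eigenvalue is negative,
maximum over scales), thresholded at `median + 5 × 1.4826 × MAD` of the
response image. Since 1.4826 × MAD consistently estimates a Gaussian
SD, the cut sits ≈ 5 σ above the noise floor yet ignores arbitrarily
bright outlier puncta, which destabilize Otsu. Objects under 15 px are
removed (8-connectivity). Each component is measured: length as the
geodesic length of its medial-axis skeleton, mean width as twice the
Euclidean distance-to-background averaged over skeleton pixels, aspect
ratio from the second-moment image ellipse (with the 1/12 px variance
term so 1-px lines stay finite). Classification: *bundle* if width
≥ 12 px (a three-fold increase over the 2–3 px single-filament width)
and aspect ≥ 3 (rejecting round aggregates) and length ≥ 10 µm (the
average single-filament length); *single* if narrower but long enough;
otherwise rejected. Pixel size is a required input — width rules are in
pixels, the length rule in µm.

### Neuron morphometry

The neurite mask thresholds the sum of min–max-normalized F-actin and
septin channels at 0.35 × Otsu (recovering dim thin neurites) and
removes components under 100 px. Growth-cone candidates are components
of the mask's morphological opening with a disk 2 px wider than the
median neurite half-width: the opening erases the shaft so only locally
wide structures (bulbs, varicosities, soma) survive. A candidate
becomes a growth cone when it contains a skeleton endpoint (terminal),
has area > 5 µm² and circularity 4πA/P² < 0.7 (perimeter from a
corrected chain-code estimator, so a digital disk scores ≈ 1), then is
dilated 3 px to recover labile membrane edges. The design differs from
an earlier residue-based construction (mask minus opening), which
selects exactly the *narrow* structures and cannot isolate bulbs; the
candidate construction is an implementation choice — only the
acceptance rules (area, circularity, terminality) are fixed by the
method. The axon shaft walks the spur-pruned skeleton proximally from
the cone junction for 20 µm (configurable), stopping at branch points,
and dilates the walked centerline to the local neurite width, minus
cone pixels. Pearson correlations are computed pixelwise per
compartment on background-corrected intensities (median outside the
neurite mask, clamped at zero); Cohen's d uses the n-weighted pooled
SD. A neuron is polarized when its longest neurite is at least twice
(inclusive) the second longest.

## The phantom generator

The generator emulates the statistical structure the analysis assumes,
not optical realism:

- **3-D stacks**: bounded-curvature random-walk centerlines (≤ 15°
  per step, ≥ 5 µm), rasterized as truth skeletons, blurred with a
  separable Gaussian PSF (σ 90/250 nm — consistent with a ~220 nm
  lateral FWHM), plus constant background, linear bleed
  `SEP += α·MT`, Poisson shot noise and Gaussian read noise. Truth
  masks are centerlines dilated to the PSF FWHM. A requested fraction
  of septin filaments reuses microtubule centerlines exactly; the rest
  keep ≥ 1 µm from them.
- The **photon budget** follows a 16-bit spinning-disk acquisition:
  background 200, diffuse tubulin pool 1000, diffuse septin pool 1500,
  filament ridge peak 3000 counts (the centerline amplitude is scaled
  so `filament_intensity` is the *post-PSF* ridge peak). At much lower
  counts the bleed estimator's quartile selection is shot-noise-
  truncated and biased low — the estimator presumes signal-driven, not
  noise-driven, dimness.
- The **cell** is an ellipsoid hugging the lateral crop; the 16-slice
  stack is a mid-cell axial substack (a whole cell does not fit in
  3.2 µm), so cell and nucleus extend beyond the axial crop. The
  tubulin pool varies smoothly (1.5 µm correlation length), tapers
  over 0.8 µm at the thin periphery, and is enriched perinuclearly
  (up to 1.8× within ~2 µm of the nucleus, as around a real MTOC);
  the septin pool occupies most of the cytoplasm with a sharp on/off
  occupancy (≈ 5 % septin-free interior patches) and is absent from a
  ~1.5 µm cortical band — the septin-dim, tubulin-positive population
  that the lowest-quartile selection relies on. The nucleus carries a
  bright diffuse septin pool and no tubulin. A sub-voxel Gaussian
  (80 nm) is applied after the camera noise, emulating the denoised
  and deconvolved stacks the analysis consumes; with raw shot noise
  the bleed estimator's quartile selection is noise-conditioned and
  biased low.
- **2-D bundle fields** place non-overlapping ribbons (widths 2–3 px
  and 14–18 px), round aggregates (aspect < 1.6) and saturated puncta
  on Gaussian noise (SD 15 on background 100 — a realistic staining
  noise floor; at an unrealistically clean SD of ~3 the large-σ Sato
  footprint of thin filaments survives the 5 σ cut and inflates their
  apparent width). Placement keeps 26 px clearance so filter footprints
  of neighboring objects do not bridge.
- **Neuron fields** draw gently curved (R ≥ 27 µm) non-crossing arc
  neurites from a soma disk, optionally ending in an elliptical bulb
  whose aspect is solved (Ramanujan perimeter) to hit the requested
  circularity; channels are compartment-weighted (F-actin
  cone-enriched, tubulin shaft-enriched). The pS9-GSK3β-like channel
  mixes standardized septin with a noise field orthogonalized against
  septin over the truth shaft, so the generated shaft correlation
  equals `ps9_rho` exactly by construction.

What passing phantom tests does **not** show: robustness to
deconvolution artifacts, depth-dependent PSFs, chromatic misalignment
beyond the built-in tolerance buffer, densely crossing filament
networks, or touching cells (the pipeline treats touching cells as one
component by design).

## Numerical choices and edge cases

- Histograms for the triangle rule use 256 bins; a constant input
  returns the constant with a `degenerate` flag rather than an error.
- Separable convolutions use mirror boundaries; distance transforms are
  exact (separable parabola algorithm) under anisotropic spacing.
- Binary morphology with physical radii thresholds the exact Euclidean
  distance transform, so structuring elements are true ellipsoids in
  voxel space.
- Empty masks, empty skeletons and zero denominators propagate as
  flagged missing values (`NA` plus a reason), never as crashes, so a
  batch run always yields a complete results table.
- The hysteresis support floor (2 % of the in-cell response maximum)
  and the bleed positivity floor (2 × robust background noise SD) are
  the two numerical guards added beyond the plain formulas; both are
  configuration-exposed.
- Pipeline problem sizes used in the validation suite: 128 × 128 × 16
  voxel stacks (the bleed and colocalization studies), 512² px bundle
  fields, 420² px neuron fields — sizes at which every stage's
  contract is measurable while a full validation run stays
  interactive.

## Known limitations

- The bleed estimator needs a septin-dim but tubulin-positive voxel
  population; on fields where septin is genuinely everywhere it will
  (correctly) reject with the diffuse-septin status rather than return
  a slope.
- Skeleton lengths are geodesic diameters, exact for unbranched
  filaments; heavily branched single components under-report total
  branch length.
- The neurite tracer consumes traced lengths for polarity calls; it
  does not re-trace neurites from images.
- ND2 input is not supported in this implementation; multi-page TIFF
  (with voxel sizes from configuration) is the exchange format.
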