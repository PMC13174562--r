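# septcoloc

Quantitative image analysis of septin association with the cytoskeleton
in fluorescence microscopy, for cell biologists studying how SEPT9 and
septin complexes decorate microtubules and actin. The package implements
three analysis families plus a synthetic phantom generator that provides
exact ground truth for validating every stage:

1. **3-D septin–microtubule colocalization** on two-channel spinning-disk
   stacks: cell / nucleus / cytoplasm (exNuc) segmentation, spectral
   bleed-through correction, curvilinear enhancement, skeletonization and
   two colocalization statistics.
2. **2-D actin bundle quantification**: a robust ridge segmentation and a
   width / aspect-ratio / length classifier separating single filaments
   from bundles.
3. **Neuron morphometry**: growth-cone and axon-shaft compartments,
   per-compartment Pearson correlations, Cohen's d effect sizes, and the
   neurite polarity call.

## The model

For a two-channel stack with septin channel *SEP* and microtubule channel
*MT* (voxels ~108 × 108 × 200 nm), the pipeline computes, inside the
cell-minus-nucleus volume (exNuc):

- the bleed slope **α** = median of (SEP − bg) / (MT − bg) over the
  lowest-quartile SEP voxels of exNuc (those least likely to carry true
  septin signal), capped/rejected outside a plausible crosstalk range,
  and the correction **SEP_corr = max(0, SEP − α·MT)**;
- a 3-D **Frangi vesselness** at three physical scales, with per-voxel
  Hessian eigenvalues from the closed-form (Cardano) solution of the
  characteristic cubic, ordered |λ₁| ≤ |λ₂| ≤ |λ₃|;
- filament masks by hysteresis thresholding, thinned to 1-voxel
  centerlines by topology-preserving 3-D thinning with physical-length
  pruning;
- the **skeleton-overlap fraction** — septin skeleton voxels within a
  2-voxel dilation of the MT mask (≈ one lateral PSF FWHM, ~220 nm, a
  tolerance buffer for diffraction-limited channel offsets) — and the
  **Manders coefficient** Σ I_SEP(MT mask) / Σ I_SEP(exNuc).

The 2-D actin quantifier applies a multiscale Sato ridge filter (σ = 1.5,
2.5, 4, 6, 8 px, bright ridges), thresholds the response at
**median + 5 × 1.4826 × MAD** (≈ 5 σ above the noise floor, robust to
saturated puncta where Otsu fails), removes objects < 15 px, and classes
a component as a *bundle* when mean width ≥ 12 px, aspect ratio ≥ 3 and
length ≥ 10 µm.

Neuron fields are segmented with an Otsu × 0.35 composite threshold;
growth cones are terminal bulb-like expansions (area > 5 µm²,
circularity 4πA/P² < 0.7, dilated 3 px); a neuron is *polarized* when
its longest neurite is at least twice the second longest.

## Worked example

```r
library(septcoloc)

# a synthetic two-channel stack with known ground truth
spec <- phantom_spec_3d(n_mt_filaments = 8, n_sep_filaments = 6,
                        coincidence_fraction = 1, seed = 11)
ph <- make_filament_stack_3d(spec)

res <- run_coloc3d(ph$pair)
res
#> coloc3d_result [cell1]
#>   alpha: 0.0509 (accepted)
#>   skeleton-overlap fraction: 0.990
#>   Manders coefficient: 0.031
#>   volumes (um^3): cell 463.6, nucleus 173.7, exNuc 289.9
```

With fully coincident septin and microtubule filaments
(`coincidence_fraction = 1`) the skeleton-overlap fraction is ~1: nearly
every septin centerline voxel falls within the buffered microtubule
mask. The recovered bleed slope (0.0509) matches the generator's
`alpha_true = 0.05`, and the Manders coefficient is small because most
septin intensity in this phantom is a diffuse cytosolic pool outside the
thin microtubule mask.

2-D bundles:

```r
f <- make_bundle_field_2d(bundle_field_spec(seed = 3))
quantify_bundles_2d(f$image, f$truth$pixel_size_um)
#> bundle_summary: 5 bundles of 28 objects (lengths 20.3, 23.2, 25.9, 17.3, 18.0 um)
```

The field was drawn with 5 wide ribbons, 10 single filaments, 3 round
aggregates and 10 bright puncta; exactly the 5 ribbons are counted as
bundles.

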