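# nucorg3d

Quantitative analysis of nuclear organization in 3D-FISH confocal stacks of
preimplantation-embryo nuclei.

Mouse embryos between the 2-cell and blastocyst stages reorganize their
centromeric (minor satellite) and pericentromeric (major satellite)
heterochromatin dramatically: pericentromeres first wrap around nucleolar
precursor bodies (NPBs) as shells and patches, then condense into
chromocenters, while centromeres adopt polarized (Rabl-like) arrangements.
Quantifying this from multichannel confocal z-stacks requires a chain of
image-analysis steps that are easy to get subtly wrong: nucleus extraction,
diffraction-scale spot detection, dark-region nucleolus segmentation, 3D
morphometry, and a statistically calibrated polarity test. `nucorg3d`
implements that chain as a tested R package, together with a ground-truthed
synthetic phantom generator so that every stage can be validated without
real microscopy data.

## What the package computes

Given a DNA counterstain channel plus one or two FISH channels on an
isotropic voxel grid (anisotropic stacks are resampled internally, nominal
spacing 0.1236 µm):

* **Nucleus segmentation** — background statistics by iterative κσ-clipping
  (the astronomy sky-estimator approach), an inclusive lower threshold
  `mean + f·sigma` with `f` the estimated signal-to-noise ratio clamped to
  [1, 2], volume attribute opening, morphological smoothing, and cavity
  filling (NPBs are dark voids that belong to the nucleus).
* **FISH signal segmentation** — white top-hat filtering (single scale for
  punctate centromere/telomere spots; an OR over three structuring-element
  scales for variably shaped pericentromeres), thresholded at
  `mean + 3.3·sigma`, gated by a wide-Gaussian bright-region mask and the
  nucleus ROI, followed by the published post-selection rules: minimum
  object volume 0.123 µm³, erosion-splitting of objects above 1.90 µm³,
  removal of flat small objects (flatness > 3, volume < 1 µm³), and a
  karyotype-count guard (above 40 objects, drop those below 1% of the total
  segmented spot volume).
* **NPB/nucleolus segmentation** — Otsu thresholding of the DNA crop with
  its Gaussian gradient magnitude (σ = 0.62 µm) added to amplify the dark
  round contours, nuclear-contour subtraction, opening, a 0.23 µm³ minimum,
  removal of low-roundness objects (< 0.5) below 94.5 µm³ and
  erosion-splitting of fused pairs above it, plus scripted edit lists that
  reify the manual correction step as auditable data.
* **Morphometry and interactions** — per-object volume, surface (smoothed
  isosurface estimator), sphericity `S_eq(V)/S` with
  `S_eq(V) = π^(1/3)(6V)^(2/3)`, flatness and elongation from the
  second-moment ellipsoid; compact/elongated classification of
  pericentromeres (roundness 0.8, minimum size 0.47 µm³); and
  signal-to-NPB interaction scoring (Null/Close/Low/Medium/Strong from the
  ratio of the contact surface to the equal-volume-sphere surface).
* **Nuclear polarity** — after moment normalization of the nucleus, the
  distance between the centromere centre of mass and the nucleus centre of
  mass, normalized by the equivalent-sphere radius, is compared with 500
  random patterns drawn uniformly over the nucleus; per-nucleus p-values
  are tested for population-level uniformity with a two-sided
  Kolmogorov–Smirnov test (α = 1%). Stage comparisons use two-sided
  Wilcoxon rank-sum tests.
* **Phantom generator** — ellipsoidal nuclei with textured DNA signal, dark
  spherical NPBs, five pericentromeric motif classes (shells, patches,
  chromocenters, beaded filaments, peripheral foci), punctate
  centromere/telomere marks (1 + 2 per telocentric chromosome), a von
  Mises–Fisher polarity knob ρ ∈ [0, 1], Gaussian PSF blur and
  Poisson–Gaussian noise — all with exact ground-truth label maps.

## Worked example

```r
library(nucorg3d)

spec <- phantom_presets("2cell_late", seed = 7)
run  <- run_pipeline(spec, pipeline_config(), out_dir = "results")
run$summaries[, c("nucleus", "nuclear_volume_um3", "npb_count",
                  "compact_fraction", "polarity_d", "polarity_p")]
```

```
# A tibble: 1 × 6
  nucleus nuclear_volume_um3 npb_count compact_fraction polarity_d polarity_p
    <int>              <dbl>     <int>            <dbl>      <dbl>      <dbl>
1       1              3852.         8            0.684     0.0882      0.634
```

One late-2-cell-like nucleus of ~3850 µm³ carrying 8 NPBs; about 68% of
its analyzable pericentromeres classify as compact (patches and emerging
chromocenters outnumber the remaining shells at this stage) and the
centromere distribution shows no significant polarity (p = 0.63 against
the uniform-placement null).
`results/` holds the nucleus label map (16-bit TIFF), per-object,
interaction and polarity CSV tables, and a JSON manifest. For real data,
replace the spec with `read_stack("embryo.tif", channel_map(dna = 1,
pericentromere = 2, centromere = 3))`.

`plot_slice()`, `plot_stage_boxplot()` and `autoplot()` on a polarity
result give quick visual checks; `tidy()`/`glance()` methods return tibble
summaries.

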