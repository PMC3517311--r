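---
title: "Models and methods behind nucorg3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucorg3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nucorg3d` quantifies nuclear organization in multichannel 3D-FISH
confocal stacks of preimplantation-embryo nuclei: nuclear volume, number
and volume of nucleolar precursor bodies (NPBs) and nucleoli, the shape
class of pericentromeric heterochromatin, its physical association with
NPBs, and the polarity of the centromere distribution. This vignette
explains each model and procedure, the parameters that matter, the choices
made where the design was genuinely open, and what the bundled synthetic
phantoms do and do not establish.

## Geometry conventions

Volumes are stored as column-major R arrays with `dim = (ny, nx, nz)`
(slice-last); voxel centres sit at `(index - 1) * spacing` micrometres.
All thresholds and structuring elements are interpreted on an isotropic
grid at the lateral pixel size (nominally 0.1236 µm); anisotropic stacks
(0.371 µm z-steps at acquisition) are first resampled along z by linear
interpolation of intensities (nearest-neighbour for label images, which
must never blend). The interpolation kind for the z-upsampling is not
uniquely determined by the problem; linear was chosen as the default for
intensity data and is configurable through `resample_isotropic()`.

Structuring elements are specified by their voxel **radii**, the ITK
convention: an element printed `(3, 3, 1)` is a 7 × 7 × 3 box. Two
internal consistency checks motivated this reading over the "extent"
alternative: the erosion element used for splitting juxtaposed spots is
specified as 1 × 1 × 1, which only has an effect as a radius (an extent-1
element is the identity); and the interaction dilation of 3 × 3 × 3 must
reach objects separated by just under 0.5 µm, which a radius-3 ball
(0.37 µm) does and an extent-3 element (0.12 µm) cannot.

## Nucleus segmentation

Most voxels of an embryo stack are background, so the nucleus threshold is
derived from background statistics alone, in the manner of astronomy sky
estimators: iterative κσ-clipping (exclude voxels above `mean + 3·sigma`,
recompute; at most 10 iterations), started from the median and
1.4826 × MAD so that a bright foreground occupying a third of the volume
cannot trap the first iteration. The lower threshold is the inclusive
`mean + f·sigma`, where the weighting factor `f` is the estimated
signal-to-noise ratio clamped to [1, 2]. The SNR estimator itself is not
uniquely specified by the thresholding scheme; `nucorg3d` uses
`(mean intensity above an Otsu split − background mean) / sigma`, which is
monotone in contrast and cheap; it is isolated in
`estimate_background()` so it can be replaced.

The binary mask then undergoes a 3D volume attribute opening (components
below `nucleus.min_volume_um3`, default 50 µm³, are removed — the smallest
blastocyst nuclei are around 200 µm³, so the default only rejects debris),
a morphological opening and closing with a 0.5 µm ball, and binary cavity
filling. Filling is essential, not cosmetic: NPBs and nucleoli are *dark*
in the DNA counterstain, so without it they are holes in the nucleus mask
and the downstream dark-region search (which intersects with the nucleus
ROI) would erase its own targets. The published account of this step —
transformations applied to "fill and smooth" the objects — is implemented
literally. Labels are ordered by decreasing volume and each nucleus is
cropped with a 2-voxel margin for all downstream work.

Degenerate inputs behave predictably: a constant image yields
`sigma = 0`, `f = 1`, and an all-foreground mask (threshold equals the
mean, inclusively), with warnings.

## FISH signal segmentation

Each cropped channel is denoised with a per-slice 2D median filter
(radius 1 pixel), z-scored globally, and rescaled to [0, 255]; every
downstream threshold is therefore invariant to offsets and gain.

Spots (centromeres, telomeres) are extracted at a single scale: a white
top-hat (image minus its grayscale opening by the radius-(3, 3, 1) box)
thresholded inclusively at `mean + 3.3·sd` *of the top-hat image*. A
top-hat residual image is background-dominated by construction — the
opening removes everything the element covers — so its global moments are
effectively background statistics. Pericentromeres take variable shapes
(shells, patches, chromocenters, filaments), so three element scales —
radii (3, 3, 1), (8, 8, 2), (15, 15, 1) — are OR-combined.

Two gates then remove peaks that are not biologically plausible: the
nucleus ROI, and a bright-region mask built by smoothing the channel with
a wide Gaussian (σ = 1.24 µm) and thresholding at `mean + 3.3·sigma` of
the *κσ-clipped background* of the smoothed image. Background rather than
whole-image moments matter here: when the signal is spread over many
similar chromocenters, a whole-image `mean + 3.3·sd` sits above the
majority of the smoothed peaks and would discard most true objects; the
gate's purpose is to reject peaks in the darkest, background-level areas,
which the clipped statistics express directly. For the same structural
reason the gate is off by default for the sparse punctate spot channels
(`signals.apply_bright_gate`), where the spots themselves dominate the
smoothed image's variability; it always applies to the pericentromere
path.

Binary structures below 0.123 µm³ (a sphere of 5 voxels diameter on the
nominal grid) are removed, and 26-connected components are labelled.
Spot labels then pass three selection rules with published constants:

1. objects above 1.90 µm³ — usually two juxtaposed spots — are eroded by
   a radius-1 element, relabelled, and the pieces grown back over the
   original support (one piece: keep the original; several: keep all);
2. objects with flatness above 3 are removed when smaller than 1 µm³;
3. if more than 40 objects remain (the diploid mouse chromosome number;
   80 is the analogous bound for a telomere channel, an extension beyond
   the published centromere analysis), objects below 1% of the total
   segmented spot volume are dropped. The "1%" is read as a volume
   fraction — the only dimensionally coherent interpretation of a
   per-object size comparison.

## NPB / nucleolus segmentation

NPBs and nucleoli appear as dark round voids after DNA staining. The
working image is the DNA crop plus its Gaussian gradient magnitude
(σ = 0.62 µm), which brightens the contours of the voids and sharpens the
class boundary. An Otsu threshold is computed per z-slice over the whole
cropped slice — including the extranuclear background, which anchors the
dark class at the void intensity level so the split lands between
nucleoplasm and {background, voids} even when voids are a small volume
fraction. The dark class is kept inside the nucleus, the 2-voxel inner
nuclear-contour shell is subtracted (dark voxels merely hugging the rim
are trimmed, not whole objects deleted), a 0.25 µm ball opening smooths
and separates, and objects below 0.23 µm³ are removed. A `volume3d` Otsu
mode replaces the per-slice statistics for late-stage data where nucleoli
are no longer spherical. Per-slice versus pooled 2D statistics is an open
choice; per-slice is the default because it adapts to depth-dependent
intensity loss.

Refinement uses a volume split at 94.5 µm³: below it, objects with
sphericity under 0.5 are removed (partial shells and slivers); at or above
it, the object is usually two abutting nucleoli and is erosion-split with
a radius-3 element. The manual correction step of the original workflow is
reified as data: an `edit_list()` of ordered removals and ellipsoid
additions, serializable as JSON and logged, so corrections are auditable
and replayable. Nuclei that cannot be corrected are flagged in the
summary table (`qc`), never silently dropped.

## Morphometry

Volume is voxel count × voxel volume, exactly. Surface area uses the
total variation of the Gaussian-smoothed object indicator (σ = 0.5 voxel):
exact for planar interfaces at any smoothing, with curvature bias of order
(σ/R)²; objects too small to carry the kernel (under 32 voxels or thinner
than 4 voxels) fall back to exposed-face counting. Plain voxel-face
counting as a general estimator would understate sphericity by roughly
1.5×, which is incompatible with round-object thresholds near 1. On this
estimator a digital ball of radius 10 voxels scores sphericity ≈ 0.98 and
a digital cube ≈ 0.82 against the closed form (π/6)^(1/3) ≈ 0.806.

Sphericity is defined as the surface of the equal-volume sphere,
`π^(1/3)·(6V)^(2/3)`, divided by the object's surface — 1 for a sphere and
lower for elongated or flat objects. The published prose states the
inverted ratio, but its own thresholds (compact above 0.8; nucleoli
removed below 0.5) are only coherent for this orientation, so the
thresholds' semantics were followed. Flatness and elongation are `b/c`
and `a/b` of the equivalent-ellipsoid axes `a ≥ b ≥ c` (2·√(5λ) from the
voxel second-moment eigenvalues, with a per-voxel moment term that makes
single-voxel objects report flatness = elongation = 1).

Pericentromeres are classified *compact* (sphericity > 0.8, volume
> 0.47 µm³), *elongated* (≤ 0.8, > 0.47 µm³) or *not analyzed*
(≤ 0.47 µm³).

Interactions between signals and NPBs dilate the NPB mask by a ball of
radius `interaction.dilation_um` (default 0.37 µm ≈ 3 voxels, i.e.
objects separated by less than ~0.5 µm interact); halo voxels keep the
identity of the nearest NPB. For each signal touching a halo, the
interaction surface is measured on the signal's boundary faces adjacent
to the halo (the signal side was chosen; the source description does not
fix it) and compared with the theoretical contact surface of the
equal-volume sphere. The category boundaries — Null (no contact), Close
(ratio ≤ 0.1), Low (≤ 0.5), Medium (≤ 1), Strong (> 1) — are explicit
artifacts of this implementation except for the published anchor that
ratios above 1 indicate strong interaction; they are configurable
(`interaction.breaks`).

## Nuclear polarity

The nucleus mask and the centromere centroids are moment-normalized: the
affine map translates to the mask centroid, rotates to the principal axes,
and rescales each axis by √(g/λᵢ) with g the geometric mean of the moment
eigenvalues — the three second moments become equal while the volume (and
hence the equivalent-sphere radius) is preserved. The polarity index `d`
is the distance between the centromere centre of mass and the nucleus
centre of mass divided by the equivalent-sphere radius. The null
distribution draws 500 patterns of the same number of points uniformly
over the mask's voxel centres (matching the discrete support of the
measured objects), transformed by the same normalization; the p-value is
the plain proportion of null distances at or above the observed one, so
p = 0 is attainable and p has resolution 1/500. Centromeres enter as
unweighted centroids of their labelled spots. Sampling happens in the
original space with the mask-derived transform applied afterwards; the
order matters only for anisotropic masks and is fixed this way throughout.
Per-nucleus seeds derive from a master seed plus the nucleus id, so
parallel and serial runs agree.

Population-level calibration uses the fact that, under uniform random
placement, per-nucleus p-values are uniform on [0, 1]; a two-sided
Kolmogorov–Smirnov test at α = 1% checks this per population. Stage
comparisons of any per-nucleus metric use two-sided Wilcoxon rank-sum
tests on adjacent stage pairs, reported unadjusted by default (a Holm
option exists), matching the practice of reporting raw per-comparison
p-values; rank-sum is the only applicable Wilcoxon variant for independent
groups of nuclei.

## The phantom generator

`phantom_spec()`/`generate_phantom()` render ground-truthed synthetic
stacks: an ellipsoidal nucleus with smooth intensity texture; dark
spherical NPBs (intensity set to the extranuclear background, because NPBs
appear as black round areas after DNA staining); per telocentric
chromosome one pericentromeric motif (shell around an NPB, patch on an
NPB, free chromocenter, beaded filament, or peripheral focus), one
centromeric mark and two telomeric marks; Gaussian PSF blur (isotropic,
σ = 0.25 µm, applied on the isotropic grid since the pipeline operates on
resampled data); and Poisson–Gaussian noise. Placement is rejection
sampling with a 1000-attempt cap per object and graduated relaxation of
separation constraints (every 250 failures the separations shrink by
0.8×), which mimics the crowding of real nuclei — in crowded late-stage
nuclei chromocenters may merge, exactly as pericentromeres of several
chromosomes coalesce in vivo. Distinct heterochromatin masses otherwise
keep a 0.8 µm gap so that they are resolvable objects rather than
accidental dumbbells.

Setting `spot_min_sep = 0` switches the generator to point-process mode:
every mutual-exclusion constraint (mark-mark separation, motif clearances,
whole-object boundary margins) is disabled and mark centres keep only a
half-voxel clearance from the nuclear envelope, so that ρ = 0 placement is
exactly spatially uniform. This is the mode the polarity-calibration
studies use — the permutation test's null hypothesis *is* iid uniform
placement, and a phantom with repulsive packing constraints would test a
different (and false) null: repulsion shrinks the variance of the
centromere centre of mass and pushes p-values toward 1. Detection
benchmarks keep the constraints; resolvable, non-overlapping spots are
what real well-imaged nuclei provide.

Polarity is a single knob ρ ∈ [0, 1] mapped to a von Mises–Fisher
concentration (κ = 10ρ/(1−ρ), capped at 10): ρ = 0 places mark directions
uniformly; ρ = 1 concentrates centromeres around one pole and distal
telomeres around the opposite pole, a Rabl-like arrangement. The cap
keeps ρ = 1 at hemisphere-level concentration — a full karyotype of
separated marks cannot live on a single ray.

Spots are rendered as flat-topped profiles (full intensity to 0.8 r,
cosine shoulder to 1.3 r) with multiplicative voxel-scale texture
(`speckle_sd`, default 0.25, demeaned per spot so texture never changes a
spot's total brightness) — hybridization signals are probe-filled
chromatin domains with internal granularity, not analytic Gaussians, and
perfectly smooth rendering interacts pathologically with discrete
grayscale openings (sub-voxel alignment can collapse the top-hat residual
of a smooth dome onto a slab). The default mark radius is 0.35 µm,
within the observed size range of satellite FISH puncta.

Stage presets (`phantom_presets()`) encode per-stage study conditions:
nuclear volumes falling from roughly 3500 µm³ at the 2-cell stage to
roughly 390 µm³ at the blastocyst stage; NPB counts drawn in [10, 15]
(early 2-cell), [8, 12] (late 2-cell), [1, 5] (4-cell), [3, 6] (8-cell),
[1, 3] (blastocyst); NPB radii matching the published median NPB volumes
(~29–65 µm³); and motif mixes moving from NPB-attached shells and patches
at the 2-cell stage to free chromocenters from the 4-cell stage on. The
haploid pronucleus preset carries 20 telocentric chromosomes, hence 20
centromeric and 40 telomeric marks. `generate_phantom(spec,
render = FALSE)` produces only the ground-truth geometry, an order of
magnitude faster, for placement and calibration studies.

### What phantom results do and do not show

The phantoms share the pipeline's own geometric vocabulary (ellipsoids,
balls, shells, cylinders) plus PSF and noise; they establish that the
implementation does what the procedure specifies at realistic scales,
contrasts and densities — exact karyotype recovery on noise-free
pronuclei, NPB count divergence confined to small objects under noise,
calibrated polarity p-values. They do not emulate chromatic aberration,
depth-dependent attenuation, spherical aberration, real chromatin texture,
or segmentation-adjacent biology (mitotic figures, apoptotic nuclei), so
passing tests bound implementation error, not real-data accuracy. The
"beaded filament" texture in particular is only coarsely emulated as a
cylinder with periodic intensity.

## Problem sizes and determinism

The test suite and the validation script run phantoms at full nominal
resolution where the claim depends on it (the haploid pronucleus at
0.1236 µm isotropic, roughly 160³ voxels) and at coarser spacing
(0.2–0.35 µm) where it does not (placement statistics, polarity
calibration with 50 populations × 12 nuclei × 500 null patterns; at
0.35 µm the voxel-centre discretization of the mask leaves a residual
bias of a few percent in the pooled p-value distribution, well below what
the per-population KS test at n = 12 can resolve). Every
stochastic stage takes an explicit seed; identical seeds give
bit-identical phantoms, segmentations and polarity results, and the
generator restores the caller's RNG state.

## Known limitations

* The gradient add-back in the NPB search suppresses a rim of roughly the
  gradient σ inside each void, so NPB volumes are systematically
  underestimated for voids below ~2 µm radius; counts are unaffected.
  The published workflow compensated with manual reconstruction, which is
  available here as edit lists.
* Top-hat masks of diffraction-scale spots are detection supports, not
  spot geometry; spot volumes should not be read as physical sizes.
* The compact/elongated fraction is only meaningful for spatially
  resolved heterochromatin masses; heavily merged chromocenters (crowded
  late-stage nuclei) bias the shape distribution of segmented objects
  regardless of the underlying motif mix.
* Blastocyst-stage nuclei sit near the lower size bound of several
  defaults (minimum nucleus volume, NPB radii); the `volume3d` Otsu mode
  is recommended there.
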