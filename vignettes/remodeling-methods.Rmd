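---
title: "Quantifying time-lapse bone remodeling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying time-lapse bone remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

remodelr quantifies local bone formation and resorption between two
registered HRpQCT sessions of the same radius. The chain is:

1. **Rigid registration.** The later session is rigidly mapped onto the
   earlier one. Multi-stack sessions use the ladder scheme: the stack pair
   with the largest cross-time overlap is registered first and its solution,
   propagated through the known reference-line offsets, initializes the
   neighbouring stacks. The moving session is interpolated exactly once,
   with the final composed transform, to avoid compounding blur.
2. **Masking.** The periosteal contour isolates the radius; a
   threshold-based split separates the cortical shell from the trabecular
   region, where the trabecular region is *every* noncortical voxel inside
   the periosteal contour (marrow included — thresholding later restricts to
   bone). Across a session pair the cortical mask is additive: a voxel
   cortical in either session is cortical in the pair. The fracture region
   is an input (slice interval or label volume), never auto-detected.
3. **Filtering and thresholding.** Both volumes pass through a constrained
   Gaussian filter (sigma 0.8 voxels, truncation 1.25, support 1 voxel; a
   3x3x3 kernel whose weights renormalize over the valid in-bounds
   neighbourhood so invalid voxels neither leak nor receive). Binary bone
   masks are taken at densities 200 to 920 mg HA/cm^3 in steps of 120; the
   trabecular region is only evaluated up to 680, above which it holds
   essentially no volume.
4. **Formation and resorption.** At each threshold, formation voxels are
   bone in the later mask but not the earlier; resorption voxels the
   reverse; both are divided by the earlier session's bone voxel count at
   that threshold. The integer identity
   `later = earlier + formed - resorbed` holds exactly, cell by cell.
   Fractions with an empty denominator propagate as flagged `NA`, never as
   zero. Intervals are labeled by the *earlier* session (a W1 row relates
   W1 to W3).

A comparator method is included: voxelwise density differences, a
difference threshold (125 mg HA/cm^3, with a 225 variant), removal of
connected clusters below a minimum size (5 or 30 voxels; 26-connectivity by
default), and fractions over the common evaluation volume. The
common-volume denominator is the convention of the studies that introduced
the method; a per-compartment bone-count denominator is available as an
option, but it inflates trabecular values (marrow events divided by a small
bone count) and inverts the qualitative compartment contrast the comparator
is known for.

Image quality is summarized as BST-SNR: mean cortical density divided by
the SD of densities in a 5-voxel ring immediately outside the periosteal
contour. Imaging through a cast multiplies the soft-tissue noise SD
(default factor 1.5) while leaving the mean signal unchanged, which lowers
BST-SNR by about the inverse of that factor.

## The synthetic digital radius

No patient images are distributable, so every stage is validated on a
generated phantom with known ground truth:

- **Geometry.** An elliptical (axis ratio 0.85), axially tapered (8 percent
  end-to-end) cortical shell around an orthogonal trabecular rod lattice
  with 30 percent random rod dropout. The ellipticity, taper and dropout
  give registration a unique optimum — a perfectly symmetric phantom
  aliases the similarity metric at the lattice period. Defaults: outer
  radius 3 mm, cortical thickness 0.8 mm, rod spacing 0.6 mm, rod thickness
  0.24 mm (the apparent trabecular thickness scale at 61 um voxels), voxel
  0.0607 mm.
- **Cortical interior structure.** 6 percent intracortical porosity (3x3x3
  pores strictly interior to the shell) and a smooth mineralization texture
  (SD 120 mg HA/cm^3, correlation length 3 voxels, floored above the
  cortical segmentation threshold). Real cortices are neither solid nor
  uniformly mineralized, and both features are what give high-threshold
  cortical masks their sensitivity to noise — and give planted cortical
  remodeling somewhere to happen.
- **Planted remodeling.** Events are planted against the *filtered* volume,
  greedily, as compact multi-voxel packets grown around sparse seeds
  (remodeling in vivo is organised in discrete packets; isolated one-voxel
  events would not survive resampling and filtering). A candidate patch is
  committed only if its voxels cross the target threshold and no
  threshold-crossing leaks into another planting event's measurement cell,
  so that on the noise-free, motion-free pair the measured counts equal the
  planted counts exactly — the package's own pipeline is its oracle, and
  the generator's ground-truth table is computed with the same masks the
  measurement builds. Default magnitudes follow the clinical reference
  values (trabecular 0.294/0.286 at 320; cortical 0.086/0.087 at 680).
  Newly formed bone is assigned 900 (trabecular packets) or 1200 (cortical
  densification and apposition) mg HA/cm^3: under the 3x3x3 kernel a
  half-space retains only about half the raw density, so new bone must be
  dense for its filtered value to cross the class threshold on an open
  surface.
- **Acquisition.** Per-session rigid motion, axial stack splitting with
  reference-line offsets, and additive Gaussian noise. The noise SD
  (default 220 mg HA/cm^3) is the one free calibration parameter, fitted
  once so that a zero-remodeling pair measures trabecular apparent
  fractions of about 0.29 at threshold 320 — the clinical contralateral
  baseline. The cortical apparent fraction then lands near 0.045 rather
  than the clinical 0.086: the phantom's cortical boundary is sharper than
  a PSF-blurred in-vivo image, and a single noise parameter cannot match
  both compartments. The compartment ordering (trabecular well above
  cortical) is reproduced.

## What passing tests do and do not show

The phantom validates the *machinery*: exact conservation, exact noise-free
recovery, registration accuracy, the monotone effect of noise on apparent
remodeling, and the qualitative disagreement between the multidensity and
thresholded-difference methods. It does not emulate scanner physics (PSF,
beam hardening, ring artifacts), fracture fragment displacement, or real
trabecular microarchitecture; agreement on the phantom therefore does not
certify accuracy on patient data.

One limit deserves emphasis. With noise calibrated to the ~0.29 trabecular
apparent-fraction floor, planted surface remodeling of that same magnitude
is largely *not* recoverable even after baseline correction: the noise
flips the very marginal surface voxels the planted events occupy, so the
net added signal is a fraction of the planted amount. Noise-free recovery
is exact and cortical recovery under full noise is within +/-0.02, but
trabecular recovery under calibrated noise falls far short of the planted
value — a property of the imaging conditions, not of the implementation.
The clinical source of those baseline numbers itself describes them as the
level of error in the calculation, which is precisely what this phantom
reproduces.

## Statistics

- **Partially overlapping samples.** Two variants of the
  partially-paired t statistic are provided. The pooled-variance form
  (default) reduces exactly to the pooled two-sample t test when no pairs
  exist; the unequal-variance (Welch-type) form reduces exactly to the
  paired t test when no unpaired observations exist. (The two reductions
  cannot both hold for a single variant: the pooled form only matches the
  paired t when the group SDs are equal.) Degrees of freedom interpolate
  between the paired and independent extremes,
  `(n12 - 1) + (na + nb + n12 - 1) / (na + nb + 2 n12) * (na + nb)`, with
  the Welch-Satterthwaite value replacing `(na + nb)` in the Welch variant.
  Monte-Carlo null calibration at the study's own sample structure
  (7 paired, 15/12 unpaired) keeps the empirical type-I error within
  [0.04, 0.06] at alpha = 0.05.
- **Holm step-down.** Ordered p-values are multiplied by `m - i + 1`,
  monotonicity enforced by running maxima, capped at 1; `stats::p.adjust`
  serves as the independent oracle in tests.
- **PLS with Q2/VIP selection.** PLS1 (NIPALS) on standardized (mean 0,
  SD 1) data. Components are added while leave-one-out Q2 improves by at
  least 0.0975. Q2 is defined as `1 - PRESS/TSS` with standardization
  refitted inside every fold (no leakage) and TSS about each training
  fold's mean. Variables are then ranked by VIP from the all-variable
  model and included as growing prefixes until Q2 stops improving
  (strict improvement by default; a `delta` mode reuses the 0.0975 rule).
  Everything is deterministic; `mixOmics::pls` cross-checks the latent
  scores in the test suite.

## Numerical choices and degenerate inputs

- Threshold comparison is inclusive (`>=`), declared so results reproduce
  bit-exactly.
- Central slice of an n-slice stack: index `floor(n/2)`, 0-based.
- The periosteal contour is a documented stand-in for a geodesic active
  contour: binarize at 320, veto speckle voxels lacking local filtered
  support (isolated suprathreshold noise would otherwise percolate into the
  largest component at casted noise levels), slicewise hole fill, largest
  26-connected component. The cortical split keeps threshold-connected
  components that touch the periosteal boundary and absorbs enclosed
  cavities by a 3D hole fill — unlike morphological closing this is exact
  on the phantom (closing overreaches into surface concavities). Dense
  trabecular islands not connected to the shell stay trabecular.
- Registration: normalized cross-correlation over sample points from the
  fixed image's dilated bone mask (robust to the casted mean shift),
  Nelder-Mead over 6 parameters, 3 pyramid levels (factor 2, Gaussian
  smoothing). Several candidate optima survive the coarse levels: a
  deterministic translation grid at the coarsest level and an axis-wise
  rotation sweep at the mid level guard against lattice-period aliasing.
  The rotation center is the fixed image's bone centroid.
- Problem sizes: the validation studies run on 96 x 128 x 128 voxel
  phantoms (one full-cross-section imaging stack) with 48 x 72 x 72 used
  for the quick parameter sweeps; these sizes were chosen as the smallest
  grids on which all compartment structures (shell, pores, rod lattice)
  coexist at scale.

## Known limitations

- Fracture-fragment kinematics beyond one rigid transform per session are
  out of scope, as is deformable registration.
- Scanner-native formats (AIM/ISQ) are not read; MetaImage and NIfTI are
  the interchange formats (TIFF stacks carry density/4096 as float
  samples).
- The phantom's cortical apparent-fraction baseline under noise is about
  half the clinical value (no PSF simulation; see above).
- Bone formation/resorption *rates* (time-normalized) are deliberately not
  reported; results are volume fractions per interval.
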