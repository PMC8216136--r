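# remodelr

Time-lapse HRpQCT analysis of local bone remodeling.

High-resolution peripheral quantitative CT (HRpQCT) can image the distal
radius in vivo at ~61 µm voxels with densities calibrated in mg
hydroxyapatite (HA) per cm³. When the same bone is imaged repeatedly —
for example over the first year after a distal radius fracture — rigidly
registering the sessions makes remodeling visible voxel by voxel.
`remodelr` implements that pipeline for researchers studying fracture
healing or longitudinal bone change:

- **Registration**: rigid, multiresolution ("pyramid") alignment of
  sessions, and "ladder" assembly of the adjacent, nonoverlapping axial
  stacks a clinical scan is acquired in, using their reference-line
  offsets.
- **Masking**: periosteal contouring, threshold-based cortical/trabecular
  splitting (the trabecular region is every noncortical voxel inside the
  periosteal contour), the *additive* pairwise cortical rule (cortical in
  either session ⇒ cortical), and a manually identified fracture/intact
  partition.
- **Quantification**: after a constrained Gaussian filter (σ = 0.8,
  truncate = 1.25, support = 1 voxel), binary bone masks are formed at
  densities 200…920 mg HA/cm³ in steps of 120 (trabecular: up to 680).
  At each threshold *T* and region, with `B_early(T)` and `B_late(T)` the
  registered bone masks,

  ```
  formation fraction  = |B_late(T) \ B_early(T)| / |B_early(T)|
  resorption fraction = |B_early(T) \ B_late(T)| / |B_early(T)|
  ```

  plus central-slice bone-volume profiles, BST-SNR image quality (mean
  cortical density / SD of the surrounding soft tissue), and a
  thresholded-difference comparator (|Δ| ≥ 125 mg HA/cm³, clusters < 5
  voxels removed; 225/30 variant).
- **Statistics**: a partially overlapping-samples t test (paired and
  unpaired observations together), Holm step-down correction, and PLS
  regression with leave-one-out Q², a ΔQ² ≥ 0.0975 component rule and
  VIP-sorted iterative variable inclusion.
- **Synthetic ground truth**: a digital radius phantom (elliptical
  tapered cortex with pores and mineralization texture around an
  irregular trabecular rod lattice) with planted formation/resorption
  packets, rigid inter-session motion, stack splitting and calibrated
  acquisition noise, so the whole pipeline is testable end to end without
  patient data.

## Worked example

```r
library(remodelr)

# a small synthetic bone with known remodeling
cfg   <- phantom_config(grid_shape = c(96, 128, 128))
ph    <- generate_phantom(cfg)
plant <- apply_remodeling(ph$volume, ph$mask, remodeling_spec())

# the full interval analysis (segment, filter, threshold ladder)
res <- run_interval(ph$volume, plant$volume, interval = "W1")
dplyr::filter(res$remodeling,
              (bone_type == "trabecular" & threshold == 320) |
              (bone_type == "cortical"   & threshold == 680)) |>
  dplyr::select(bone_type, threshold, earlier_voxels,
                formation_fraction, resorption_fraction)
#> # A tibble: 2 × 5
#>   bone_type  threshold earlier_voxels formation_fraction resorption_fraction
#>   <chr>          <dbl>          <int>              <dbl>               <dbl>
#> 1 cortical         680         257108             0.0860              0.0870
#> 2 trabecular       320          41802             0.294               0.286
```

The measured fractions equal the planted ones exactly on this noise-free,
motion-free pair (0.294/0.286 trabecular at 320 mg HA/cm³; 0.086/0.087
cortical at 680) — the generator and the measurement are held to the same
masks and filter, which is what makes the phantom a usable oracle. With
motion and noise switched on, `register_rigid_pyramid()` /
`ladder_register_stacks()` recover planted transforms to a few hundredths
of a voxel, and `autoplot(res$remodeling)` draws the fraction-vs-threshold
profiles per compartment.

Study-level wrappers: `simulate_study()` writes a full six-session
synthetic study (volumes, manifest, ground truth) to disk,
`analyze_study()` runs registration + quantification over all intervals,
`report_study()` summarizes median (IQR) fractions with partially-paired,
Holm-corrected formation-vs-resorption flags. A thin command-line
front-end lives in `inst/cli/remodelr.R`.

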