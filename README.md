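# nucshells

Concentric-shell radial profiling of nuclear marker distribution in 3D
fluorescence microscopy.

Nuclear-envelope proteins (SUN-domain proteins of the LINC complex, lamins,
and similar markers) are radially organised: dim in the nucleoplasm,
enriched towards the envelope. `nucshells` quantifies that organisation
from single-channel confocal Z-stacks and tests whether it changes between
conditions, with every stage validated on synthetic phantoms carrying
voxel-level ground truth.

## Method

For each nucleus in a stack:

1. **3D segmentation** — Gaussian smoothing (physical-unit sigma), Otsu's
   threshold (strictly-above foreground), ball-element morphology
   (default `closing(2), erosion(1)`), connected components with a
   physical volume filter, and removal of objects touching the lateral
   volume faces (objects clipped only by the first/last Z plane are kept).
2. **Exact Euclidean distance transform** — every nuclear voxel gets its
   distance *d* (µm) to the nearest background voxel centre, with axis
   steps weighted by the anisotropic voxel spacing.
3. **K concentric shells** — normalised depth nd = d / d_max ∈ (0, 1] is
   cut into K equal-width bins (default K = 24); layer
   ℓ = K + 1 − ⌈K·nd⌉, so layer 1 is the nuclear centre and layer 24 abuts
   the envelope.
4. **Profiles and regions of interest** — mean raw intensity per
   (nucleus, layer); blocks of 4 layers form RO-1 (centre, layers 1–4)
   … RO-6 (periphery, layers 21–24). Summary statistics are mean ± SEM
   across nuclei; enrichment is the RO-6/RO-1 fold change; two conditions
   are compared per layer or per RO with a two-sided pooled-variance
   (Student's unpaired) t-test at α = 0.05.

A synthetic-phantom module (`generate_phantom()`, `mcf10a_like()`,
`mda231_like()`) renders ellipsoidal / fold-perturbed nuclei with a known
radial intensity profile, punctate PSF-blurred speckles, Poisson + Gaussian
noise and border-touching distractors, plus the full ground truth — so the
whole pipeline is testable without microscope data.

## Worked example

```r
library(nucshells)

# control vs a 30% peripheral depletion, five phantoms each
ctrl <- lapply(1:5, function(s) mcf10a_like(seed = s))
trt  <- lapply(6:10, function(s) mcf10a_like(seed = s, peripheral_scale = 0.7))

profile_one <- function(ph, cond, id) {
  img <- ph$image; img$condition <- cond; img$source_id <- id
  labels <- segment_nuclei(img)
  shells <- assign_shells(distance_transform(labels), labels, K = 24)
  layer_profile(img, shells, labels)
}
pc <- bind_profiles(mapply(profile_one, ctrl, "control", paste0("c", 1:5),
                           SIMPLIFY = FALSE))
pt <- bind_profiles(mapply(profile_one, trt, "treated", paste0("t", 1:5),
                           SIMPLIFY = FALSE))

fold_change(aggregate_ro(pc))
#> [1] 2.19  (ground-truth fold of these phantoms: 2.21)

compare_groups(pc, pt, unit = "RO")[, c("index", "mean_a", "mean_b", "p")]
#>  index mean_a mean_b        p
#>      1  140.3  140.4 3.4e-01   <- centre: no effect, as simulated
#>      ...
#>      6  307.9  253.2 3.9e-14   <- periphery: depletion detected
```

The fold change says the marker is ~2.2-fold enriched in the outermost
shell block relative to the nuclear centre; the comparison table localises
the simulated treatment effect to the periphery (RO-6) while the centre
(RO-1) stays null.

For file-based batch runs, `run_config()` / `run_pipeline()` (or the thin
CLI wrapper in `inst/cli/nucshells.R` with a YAML config) write per-layer
CSVs, RO summaries, comparison tables, optional mask/shell TIFF exports
and a JSON manifest that makes every output reproducible from the inputs.

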