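# spotquant

Single-cell quantitation of nuclear-body stress phenotypes in
multi-channel fluorescence microscopy images.

Membrane-less nuclear bodies — Cajal bodies (CBs, marked by Coilin) and
nucleoli (NPM, Fibrillarin) — reorganize under genotoxic stress such as
platinum chemotherapy: CBs disperse into many small foci, collapse onto
the nucleolar rim (capping), relocate into the nucleolus, or dissolve
into diffuse nucleoplasmic signal. `spotquant` turns DAPI + immunostain
image stacks into per-cell quantitative readouts of these responses, for
cell biologists running imaging experiments on cultured cells.

The pipeline:

* **Nucleus segmentation** — Canny edge detection on the counterstain,
  isolated-pixel cleaning, morphological closing, hole filling, opening,
  8-connected labelling; then the classical exclusions (border-touching
  objects, areas > 4000 px as likely doublets, areas < 50 px as
  artefacts, both bounds exclusive). Any external segmenter can be
  plugged in via a validated label-map contract.
* **Spot detection**, two routes: a *contour* (Canny) route for accurate
  per-spot size, and a *Difference-of-Gaussians* route
  `response = G(I, σ₁) − G(I, σ₂)` (σ₁ = 1.5, σ₂ = 2.4 px) thresholded
  at `median + 4.5 · 1.4826 · MAD` over in-nucleus response pixels —
  data-derived, hence invariant to global intensity scaling. No
  size-based selection is applied to spots. Spot diameter is the
  equivalent-circle diameter `2·√(area/π)`.
* **Per-cell features and phenotype call** — spot count, diameter,
  intensity, nucleolar-overlap and capping-annulus fractions, nucleoplasm
  CV, classified into the five stress classes (`no_stress`,
  `nucleolar_capping`, `nucleolar_localization`,
  `nucleoplasmic_diffusion`, `cb_dispersion`) by a documented
  fixed-precedence rule cascade.
* **Population statistics** — per-condition summaries of CB number and
  diameter, unpaired Welch t-tests, violin-plot export, and an exact
  seeded t-SNE embedding with Mahalanobis metric
  `d(x,y) = √((x−y)ᵀ(Σ+εI)⁻¹(x−y))` for single-cell phenotype maps.
* **Synthetic scene generator** — renders fields of elliptical nuclei
  with nucleoli and phenotype-specific spot geometries under PSF blur,
  Poisson and Gaussian noise, with complete ground-truth tables; it is
  the validation oracle for every stage.

## Worked example

```r
library(spotquant)

scene <- generate_scene(scene_config(n_nuclei = 8), seed = 42)
scene
#> <synthetic_scene> 512x512 px, 8 nuclei, 12 spots, seed 42

lab  <- segment_nuclei_canny(scene$stack$channels$dapi)
filt <- filter_objects(lab, min_area_px = 50, max_area_px = 4000,
                       remove_border = TRUE)
det  <- detect_spots_dog(scene$stack$channels$red, filt$labels)
cells <- cell_features(scene$stack, filt$labels, det$labels, det$records)
cells$phenotype <- classify_cells(cells)
head(cells[, c("nucleus_id", "area_px", "spot_count_red",
               "spot_mean_diameter_px", "capping_fraction", "phenotype")])
#>   nucleus_id area_px spot_count_red spot_mean_diameter_px capping_fraction
#> 1          1    1956              2              7.090474             0.00
#> 2          2    2305              1              7.312733             0.00
#> 3          3    1082              0                    NA               NA
#> 4          4    2558              1              4.787307             0.00
#> 5          5    2585              4              4.931982             0.25
#> 6          6    3003              0                    NA               NA
#>                 phenotype
#> 1               no_stress
#> 2  nucleolar_localization
#> 3 nucleoplasmic_diffusion
#> 4               no_stress
#> 5           cb_dispersion
#> 6 nucleoplasmic_diffusion
```

Each row is one analysed nucleus: its pixel area, the number of detected
Coilin-like spots, their mean equivalent diameter in pixels (`NA` when a
cell has no spots — missing, never zero), the fraction of spots sitting
on the nucleolar boundary annulus, and the assigned stress phenotype.
Here nucleus 5 carries 4 small spots and is called dispersed, while the
spotless nuclei 3 and 6 show the low nucleoplasm CV typical of diffuse
Coilin and are called diffusion — matching the generated ground truth
(`scene$truth$nuclei$phenotype`).

An end-to-end multi-condition run (simulate → segment → spots → features
→ classify → embed → compare, with all artifacts persisted):

```r
summary <- run_pipeline(default_run_config(seed = 1, outdir = "out"))
```

or from a shell: `Rscript inst/scripts/spotquant-cli.R run-all --seed 1
--outdir out`.

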