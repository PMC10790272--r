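---
title: "Quantifying nuclear-body stress phenotypes with spotquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear-body stress phenotypes with spotquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotquant)
```

## The analysis problem

Genotoxic drugs reorganize membrane-less nuclear bodies. Cajal bodies
(CBs), marked by Coilin, typically appear as 1–2 bright foci per nucleus
near the nucleoli in unstressed cultured cells; under stress they disperse
into many small foci, collapse onto the nucleolar rim ("capping"),
relocate into the nucleolus, or dissolve into a diffuse nucleoplasmic
haze. Quantifying these responses from two- or three-channel
immunofluorescence images requires four ingredients:

1. a nucleus mask from the DNA counterstain (DAPI),
2. segmentation of intranuclear spots with per-spot size and intensity,
3. a per-cell feature vector and a phenotype call, and
4. population-level summaries: per-condition spot counts and diameters,
   significance tests, and a single-cell embedding.

`spotquant` implements this pipeline with two spot-segmentation routes
that are standard in the field: a *contour route* (Canny edge detection
followed by binary morphology), suited to measuring object size, and a
*Difference-of-Gaussians (DoG) route* (band-pass filtering followed by
thresholding), suited to robust counting of small foci. Because published
microscopy datasets of this kind are rarely deposited, the package ships a
synthetic scene generator with complete ground truth; every quantitative
claim made by the test suite is a recovery statement about that generator.

## The synthetic scene generator

`generate_scene()` renders fields of cultured-cell nuclei:

* **Nuclei** are ellipses with equal-area radius drawn from 18–32 px and
  relative axis perturbation up to 0.15 (mildly non-circular, so diameter
  estimators are exercised off the circular ideal). Nuclei are placed by
  rejection sampling with a boundary-to-boundary gap of at least 6 px —
  below that, the morphological closing used by the contour route can
  bridge two adjacent nucleus outlines into one object. The 18–32 px
  default keeps a single intact nucleus (max ≈ 3200 px²) inside the
  classical "> 4000 px removed as likely doublets" filter window; with
  radii much above 35 px the filter would systematically discard intact
  single nuclei, which is a property of the magnification the filter was
  designed for, not of the cells.
* **Nucleoli** are rendered per nucleus as a disk of 0.35 × the nucleus
  radius, dark in DAPI (chromatin-poor) and bright in the green
  (nucleophosmin-like) channel.
* **Spots** are disks of radius 2–5 px rendered in the red (Coilin-like)
  channel at peak 0.85 against a 0.25 nucleoplasm, i.e. a signal-to-noise
  ratio of (0.85 − 0.25)/0.10 = 6 at the default Gaussian noise sd of
  0.10. Spot centres keep `radius + 6` px clearance from the nucleus
  boundary (nuclear bodies are interior structures) and an edge-to-edge
  gap of at least `spot_min_gap_px` (default 3 px; validation suites that
  stipulate well-separated spots set 6).
* **Degradation** applies, in order: Gaussian PSF blur (sd 1 px), Poisson
  photon resampling (500 photons per unit intensity), additive Gaussian
  read noise (sd 0.10), and clipping to [0, 1].

The five phenotype geometries are:

| class | spots | geometry |
|---|---|---|
| `no_stress` | 1–2 | 5–10 px outside the nucleolar boundary |
| `nucleolar_capping` | 2–3 | centres on a ±1 px annulus at the boundary |
| `nucleolar_localization` | 1–3 | strictly inside the nucleolus, ≥ 3 px from its rim |
| `nucleoplasmic_diffusion` | 0 | red level raised to (nucleoplasm + peak)/2 |
| `cb_dispersion` | 4–8 | uniform over the nucleoplasm, small radii |

Two of these numbers deserve comment. The capping count is 2–3 rather
than 2–4: the classifier's first rule declares any cell with ≥ 4 spots
dispersed, with deliberate precedence (count evidence is the most robust
to mask noise), so a 4-spot capping cell is *by definition* ambiguous
under the rule set; disjoint ground-truth classes require the capping
draw to stay below the dispersion cutoff. The `no_stress` offset starts at
5 px rather than immediately at the boundary because the capping feature
uses a ±2 px annulus around the *estimated* nucleolar mask, whose
boundary carries 1–2 px of error; placing control spots closer would
deliberately manufacture class overlap.

All randomness flows through a single seeded stream
(`withr::with_seed`); identical `(config, seed)` reproduce scenes
bit-identically. What the generator does **not** emulate: overlapping or
clumped nuclei, cytoplasmic signal (e.g. the cytoplasmic SMN1 pool),
uneven illumination, 3D structure, and real texture inside nuclei. Tests
passing on these scenes therefore demonstrate correctness of the
machinery and its calibration on an idealized but noisy model, not
performance on clinical-grade images.

## Nucleus segmentation

`segment_nuclei_canny()` follows the classical recipe: Canny edges
(Gaussian smoothing, Sobel gradients, non-maximum suppression, hysteresis)
→ isolated-pixel cleaning → morphological closing (disc, 2 px) → hole
filling → opening (disc, 2 px) → 8-connected labelling. The hysteresis
thresholds default to `"auto"`: the high threshold is the Otsu threshold
of the gradient-magnitude image and the low one is 0.4 × high. This is a
deterministic stand-in for per-cell-type visual tuning; both thresholds
are exposed for override, and the same values should be used across
conditions of one experiment to avoid analysis bias.

`filter_objects()` applies the standard exclusions: objects touching the
image border, objects larger than 4000 px (likely two nuclei merged —
removed, never watershed-split), and objects smaller than 50 px (imaging
artefacts). Both area bounds are *exclusive*: areas of exactly 50 or
4000 px survive. The small-object cutoff is wired to nuclear and
nucleolar detections only — no size-based selection is ever applied to
spot channels. Any alternative segmenter (for example a star-convex
neural network run externally) can replace the contour route: the
contract is a non-negative integer label map of the input's shape,
checked by `validate_labelmap()`, after which filtering and all
downstream stages behave identically.

On noiseless default scenes the contour route recovers ≥ 95% of truth
nuclei at IoU ≥ 0.7 (typically IoU ≈ 0.95–0.97 at default noise).

## Spot detection

The **DoG route** computes
`response = blur(I, 1.5) − blur(I, 2.4)` (the classical ≈1.6 scale
ratio) and thresholds at

```
tau = median(response) + k * 1.4826 * MAD(response)
```

with both statistics over in-nucleus response pixels. The threshold is
data-derived, which makes detection exactly covariant under global
intensity scaling. Two calibration choices matter:

* `dog_threshold_k = 4.5`. The DoG-filtered noise field is spatially
  correlated, so per-pixel Gaussian tail arithmetic underestimates the
  false-positive rate; at k = 4 roughly 2% of spotless nuclei acquire a
  1-px spurious component, which is incompatible with keeping ≥ 99% of
  empty nuclei clean. k = 4.5 achieves ≈ 100% clean nuclei at no
  measurable cost in sensitivity (true spots respond at 10–15 robust
  sds).
* `boundary_guard_px = 7`. A band-pass filter responds to the nucleus rim
  itself with a positive annulus just inside the boundary; in
  diffusion-phenotype cells (rim step ≈ 0.5) that annulus crosses the
  threshold and its centroid falls *inside* the nucleus, creating phantom
  spots. Statistics and detections are therefore restricted to the
  nucleus mask eroded by 7 px. The simulator's `radius + 6` px interior
  spot margin guarantees spot cores survive the guard.

The **contour route** applies the nucleus recipe to the spot channel
(smoothing sd 1 px, closing 2 px, opening 1 px — a 2-px opening would
erase the smallest spots), with two adaptations: edges are confined to
the nucleus interior eroded by `2·sigma + 1` px so the nucleus rim is not
traced as an object on the spot channel, and the `"auto"` threshold uses
`median + 8 · 1.4826 · MAD` of the gradient magnitude over that interior
(the whole-image Otsu rule is miscalibrated on spot channels, where the
dominant edge is the nucleus rim). Diameters come out of this route
within ±2 px of truth for disk spots of radius 3–8 px.

Spots are assigned to the nucleus under their rounded centroid pixel;
centroids over background leave the spot unassigned (`nucleus_id = 0`,
kept in tables, excluded from per-cell statistics). Reported diameter is
the equivalent-circle diameter `2·sqrt(area/π)`; it is exact for disks
and well-defined for irregular bodies.

## Per-cell features and classification

`cell_features()` produces one row per nucleus: area; red-spot count,
mean equivalent diameter, mean intensity, total spot-area fraction;
spot-excluded nucleoplasm mean and coefficient of variation (CV) of the
red signal; the fraction of spot area inside the nucleolar mask; and the
fraction of spots whose centroids lie within a ±2 px annulus of the
nucleolar boundary. Statistics that are undefined for spotless cells are
explicit missing values, never sentinel zeros.

The nucleolar mask comes from `nucleolar_mask()`: Otsu thresholding of
the in-nucleus DAPI (mode `dapi_void`, nucleoli are chromatin-poor) or of
the in-nucleus green channel (mode `npm_high`). The channel is
pre-smoothed (sd 1.5 px) and the mask is opened by 1 px and hole-filled:
without this, shot-noise speckle chains onto the mask at the Otsu cut and
roughly doubles its area. Components under 25 px are discarded. The
`dapi_void` mode is the pipeline default because it remains valid in
stress conditions where the green nucleolar marker itself translocates.

`classify_cell()` applies a fixed-precedence rule cascade:

1. spot count ≥ 4 → `cb_dispersion`
2. capping fraction ≥ 0.5 (and ≥ 1 spot) → `nucleolar_capping`
3. nucleolar overlap ≥ 0.5 (and ≥ 1 spot) → `nucleolar_localization`
4. spot count = 0 and nucleoplasm CV ≤ 0.35 → `nucleoplasmic_diffusion`
5. otherwise → `no_stress`

Count-based evidence takes precedence because it is least sensitive to
mask error. The CV rule operationalizes "diffuse": raising the diffuse
level lowers relative noise texture (CV ≈ 0.18 in diffusion cells versus
≈ 0.40 in unstressed nucleoplasm at default noise), and it doubles as the
guard that keeps an unstressed cell whose spots were all missed out of
the diffusion class. The original phenotyping of this five-class taxonomy
was done by eye; these thresholds are this package's documented
operationalization, validated by ground-truth recovery (≥ 0.99 per class
at default conditions in the acceptance run), not by agreement with any
manual count.

## Embedding and statistics

`tsne_embed()` is an exact (non-Barnes-Hut) t-SNE with a Mahalanobis
input metric: distances are Euclidean after whitening by the inverse
Cholesky factor of the feature covariance, ridge-regularized by
`epsilon = 1e-3 · trace(S)/p` by default (a singular covariance with
`epsilon = 0` errors with instructions rather than silently
proceeding). The Mahalanobis choice makes the embedding invariant to
invertible linear reparameterizations of the feature vector, so feature
scaling conventions cannot change the picture. Perplexity defaults to 30
(requiring n > 90 cells), early exaggeration 12 for 250 of 1000
iterations, learning rate 200, momentum 0.5 → 0.8 — the standard
schedule. Initialization is the only stochastic step and is drawn under
the caller's seed, so identical inputs and seed reproduce coordinates
bit-identically. At ~300 cells the O(n²) exact gradient costs a few
seconds; for much larger populations an approximate implementation would
be preferable.

Group comparisons use the unpaired Welch t-test (unequal variances,
Welch–Satterthwaite df) via `welch_ttest()`; a pooled-variance variant is
available by flag. Degenerate inputs (both groups constant) raise an
error rather than reporting p = 0. No multiple-testing correction is
applied by default (per-comparison p-values are reported); Holm
correction is available in `compare_conditions()`. Violin plots are
exported together with the underlying per-cell CSV so every figure is
regenerable from persisted data.

## The pipeline and reproducibility

`run_pipeline()` chains simulate → segment → filter → detect → features →
classify → summarize → embed → compare, persisting every intermediate
table (CSV), the label maps (16-bit TIFF), the resolved configuration
(YAML) and a JSON summary. Per-scene seeds derive from the global seed by
`seed + 1000·condition_index + scene_index` and the embedding uses
`seed + 500000`, so one integer reproduces a run byte-for-byte. A thin
command-line wrapper (`inst/scripts/spotquant-cli.R`) exposes
`simulate`, `validate` and `run-all`; the per-stage operations are the
package functions themselves.

The validation suite and `scripts/acceptance.R` size their simulations at
roughly 100–130 scenes of 512×512 px with 8 nuclei each (≈ 200 nuclei
for count recovery, ≥ 100 cells per phenotype class for classification,
300 cells for the embedding), which keeps a full run in the
single-digit-minute range on one CPU while leaving the binomial error on
a 95% recovery bound below ±3%.

## Known limitations

* The contour route's `"auto"` thresholds are deterministic conventions,
  not universal: heavily textured counterstains may need manual
  thresholds, as in the original visually-tuned practice.
* Touching nuclei are removed (as oversized objects), not split; dense
  cultures lose interior cells and analysed cells then over-represent
  colony peripheries.
* Sub-pixel localization and spot deconvolution are out of scope; merged
  foci closer than about the large DoG scale are counted as one.
* The classifier assigns exactly one label; genuinely mixed phenotypes
  are resolved by the precedence order, not flagged.
* All geometry is in pixels and deliberately uncalibrated; no physical
  pixel size is assumed anywhere.
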