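small_cfg <- function(...) {
  args <- utils::modifyList(list(image_height_px = 256L,
                                 image_width_px = 256L, n_nuclei = 3L),
                            list(...))
  do.call(scene_config, args)
}

test_that("empty scenes and determinism honour the generation contract", {
  cfg <- small_cfg(n_nuclei = 0L)
  sc <- generate_scene(cfg, 11)
  expect_equal(nrow(sc$truth$nuclei), 0L)
  expect_equal(nrow(sc$truth$spots), 0L)
  expect_equal(dim(sc$stack$channels$dapi), c(256L, 256L))
  # same (config, seed) twice: bit-identical stacks and truth
  cfg2 <- small_cfg()
  a <- generate_scene(cfg2, 42)
  b <- generate_scene(cfg2, 42)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth, b$truth)
  # different seed changes pixels
  expect_false(identical(a$stack$channels$red,
                         generate_scene(cfg2, 43)$stack$channels$red))
})

test_that("forced dispersion with fixed spot count yields exact truth rows", {
  cfg <- scene_config(n_nuclei = 10L,
                      phenotype_mix = forced_mix("cb_dispersion"),
                      spots_per_cell = list(
                        no_stress = c(1L, 2L), nucleolar_capping = c(2L, 3L),
                        nucleolar_localization = c(1L, 3L),
                        nucleoplasmic_diffusion = c(0L, 0L),
                        cb_dispersion = c(6L, 6L)))
  sc <- generate_scene(cfg, 7)
  expect_equal(nrow(sc$truth$spots), 60L)
  expect_true(all(table(sc$truth$spots$nucleus_id) == 6L))
})

test_that("rendered spots reach the configured signal-to-noise ratio", {
  lv <- list(dapi = c(background = 0.03, nucleoplasm = 0.55,
                      nucleolus = 0.18, spot_peak = 0),
             red = c(background = 0.03, nucleoplasm = 0.3,
                     nucleolus = 0.3, spot_peak = 0.9),
             green = c(background = 0.03, nucleoplasm = 0.2,
                       nucleolus = 0.75, spot_peak = 0))
  cfg <- scene_config(n_nuclei = 6L, phenotype_mix = forced_mix("no_stress"),
                      intensity_levels = lv, noise_gaussian_sd = 0.05,
                      noise_poisson_scale = 0, psf_sigma_px = 0)
  sc <- generate_scene(cfg, 5)
  red <- sc$stack$channels$red
  at <- cbind(round(sc$truth$spots$centroid_r) + 1,
              round(sc$truth$spots$centroid_c) + 1)
  peak <- mean(red[at])
  # nucleoplasm level measured away from spots, at nucleus centres offset
  snr <- (peak - 0.3) / 0.05
  expect_gte(snr, 5)
})

test_that("phenotype geometries follow their class definitions", {
  ng <- list(centroid_r = 100, centroid_c = 100, a = 27, b = 24,
             theta = 0.3)
  no <- list(centroid_r = 102, centroid_c = 98, radius_px = 9)
  cfg <- scene_config()
  # diffusion renders no spots
  expect_equal(nrow(withr::with_seed(1,
    render_phenotype("nucleoplasmic_diffusion", ng, no, cfg))), 0L)
  withr::with_seed(2, {
    for (rep in 1:20) {
      cap <- render_phenotype("nucleolar_capping", ng, no, cfg)
      d <- sqrt((cap$centroid_r - no$centroid_r)^2 +
                  (cap$centroid_c - no$centroid_c)^2)
      expect_true(all(abs(d - no$radius_px) <= 1.5))
    }
    loc <- do.call(rbind, lapply(1:20, function(i)
      render_phenotype("nucleolar_localization", ng, no, cfg)))
    dl <- sqrt((loc$centroid_r - no$centroid_r)^2 +
                 (loc$centroid_c - no$centroid_c)^2)
    expect_true(all(dl < no$radius_px))
    # dispersion places strictly more spots than the unstressed class
    n_disp <- vapply(1:100, function(i)
      nrow(render_phenotype("cb_dispersion", ng, no, cfg)), numeric(1))
    n_norm <- vapply(1:100, function(i)
      nrow(render_phenotype("no_stress", ng, no, cfg)), numeric(1))
    expect_gt(mean(n_disp), mean(n_norm))
  })
  expect_error(render_phenotype("stressed", ng, no, cfg), "unknown")
})

test_that("per-class truth spot counts are ordered as expected", {
  ng <- list(centroid_r = 60, centroid_c = 60, a = 26, b = 24, theta = 0)
  no <- list(centroid_r = 60, centroid_c = 60, radius_px = 8.75)
  cfg <- scene_config()
  counts <- withr::with_seed(9, {
    vapply(phenotype_levels, function(cl)
      mean(vapply(1:60, function(i)
        nrow(render_phenotype(cl, ng, no, cfg)), numeric(1))),
      numeric(1))
  })
  expect_gt(counts[["cb_dispersion"]], counts[["nucleolar_capping"]])
  expect_gte(counts[["nucleolar_capping"]], counts[["no_stress"]])
  expect_gt(counts[["no_stress"]], counts[["nucleoplasmic_diffusion"]])
})

test_that("degradation operator has exact no-op and calibrated noise", {
  img <- matrix(0.5, 64, 64)
  expect_identical(degrade(img, 0, 0, 0), img)
  # blur of a constant is the constant
  expect_lt(max(abs(degrade(img, 3, 0, 0) - 0.5)), 1e-6)
  # additive noise sd recovered empirically
  noisy <- degrade(matrix(0.5, 512, 512), 0, 0.05, 0, seed = 3)
  expect_equal(sd(noisy), 0.05, tolerance = 0.05 * 0.05)
  expect_error(degrade(img, -1, 0, 0), "non-negative")
  # determinism given the seed
  expect_identical(degrade(img, 0, 0.1, 100, seed = 8),
                   degrade(img, 0, 0.1, 100, seed = 8))
})

test_that("truth tables are internally consistent", {
  sc <- generate_scene(scene_config(n_nuclei = 8L), 21)
  tr <- sc$truth
  expect_true(all(tr$spots$nucleus_id %in% tr$nuclei$nucleus_id))
  for (i in seq_len(nrow(tr$spots))) {
    sp <- tr$spots[i, ]
    nu <- tr$nuclei[tr$nuclei$nucleus_id == sp$nucleus_id, ]
    d2 <- ((sp$centroid_r - nu$centroid_r)^2 +
             (sp$centroid_c - nu$centroid_c)^2)
    expect_lt(sqrt(d2), max(nu$semi_major, nu$semi_minor))
  }
  # nuclei pairwise non-overlapping
  if (nrow(tr$nuclei) > 1) {
    dd <- as.matrix(dist(tr$nuclei[, c("centroid_r", "centroid_c")]))
    lim <- outer(pmax(tr$nuclei$semi_major, tr$nuclei$semi_minor),
                 pmax(tr$nuclei$semi_major, tr$nuclei$semi_minor), "+")
    expect_true(all(dd[upper.tri(dd)] > lim[upper.tri(lim)] + 2))
  }
})

test_that("pre-noise rendering attains its maximum at each spot centre", {
  cfg <- scene_config(n_nuclei = 6L, noise_gaussian_sd = 0,
                      noise_poisson_scale = 0)
  sc <- generate_scene(cfg, 31)
  red <- sc$stack$channels$red
  for (i in seq_len(nrow(sc$truth$spots))) {
    sp <- sc$truth$spots[i, ]
    r0 <- round(sp$centroid_r) + 1; c0 <- round(sp$centroid_c) + 1
    win <- red[(r0 - 4):(r0 + 4), (c0 - 4):(c0 + 4)]
    mx <- arrayInd(which.max(win), dim(win))
    expect_lte(max(abs(mx - 5)), 1.5)
  }
})

test_that("invalid configurations and crowding produce informative errors", {
  expect_error(scene_config(phenotype_mix = stats::setNames(
    c(0.5, 0.2, 0.1, 0.05, 0.05), phenotype_levels)), "sum to 1")
  expect_error(scene_config(nucleolus_radius_fraction = 0.9), "0.6")
  expect_error(scene_config(noise_gaussian_sd = -0.1), "noise")
  expect_error(
    generate_scene(scene_config(image_height_px = 150L,
                                image_width_px = 150L, n_nuclei = 12L), 1),
    "too crowded")
})
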