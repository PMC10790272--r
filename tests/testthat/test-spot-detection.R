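test_that("the DoG filter is linear, centred, and flat on constants", {
  expect_lt(max(abs(dog_filter(matrix(0.7, 40, 40)))), 1e-9)
  # response maximum at the centre of a Gaussian blob
  rr <- matrix(1:41 - 21, 41, 41)
  cc <- t(rr)
  blob <- exp(-(rr^2 + cc^2) / (2 * 2^2))
  resp <- dog_filter(blob, 1.5, 2.4)
  mx <- arrayInd(which.max(resp), dim(resp))
  expect_lte(max(abs(mx - 21)), 0.5)
  # linearity
  set.seed(2)
  img <- matrix(runif(30 * 30), 30)
  expect_lt(max(abs(dog_filter(0.37 * img) - 0.37 * dog_filter(img))), 1e-9)
  expect_error(dog_filter(img, 2.4, 1.5), "sigma_small")
})

test_that("dog_filter equals the brute-force convolution oracle", {
  set.seed(5)
  for (t in 1:3) {
    img <- matrix(runif(32 * 32), 32)
    expect_lt(max(abs(dog_filter(img, 1.5, 2.4) - dog_oracle(img, 1.5, 2.4))),
              1e-6)
  }
})

test_that("single rendered spots are found once, at the right place", {
  cfg <- scene_config(n_nuclei = 4L, phenotype_mix = forced_mix("no_stress"),
                      spots_per_cell = list(
                        no_stress = c(1L, 1L), nucleolar_capping = c(2L, 3L),
                        nucleolar_localization = c(1L, 3L),
                        nucleoplasmic_diffusion = c(0L, 0L),
                        cb_dispersion = c(4L, 8L)),
                      spot_radius_px = c(3, 3))
  sc <- generate_scene(cfg, 61)
  lab <- segment_nuclei_canny(sc$stack$channels$dapi)
  f <- filter_objects(lab, 50, 4000, TRUE)
  det <- detect_spots_dog(sc$stack$channels$red, f$labels)
  expect_equal(nrow(det$records), nrow(sc$truth$spots))
  for (i in seq_len(nrow(sc$truth$spots))) {
    sp <- sc$truth$spots[i, ]
    d <- sqrt((det$records$centroid_r - sp$centroid_r)^2 +
                (det$records$centroid_c - sp$centroid_c)^2)
    expect_lte(min(d), 1)
  }
})

test_that("well-separated spot pairs resolve into two detections", {
  cfg <- scene_config(n_nuclei = 5L, phenotype_mix = forced_mix("no_stress"),
                      spots_per_cell = list(
                        no_stress = c(2L, 2L), nucleolar_capping = c(2L, 3L),
                        nucleolar_localization = c(1L, 3L),
                        nucleoplasmic_diffusion = c(0L, 0L),
                        cb_dispersion = c(4L, 8L)),
                      spot_min_gap_px = 6)  # centre gap > 4 * sigma_large
  sc <- generate_scene(cfg, 62)
  lab <- segment_nuclei_canny(sc$stack$channels$dapi)
  f <- filter_objects(lab, 50, 4000, TRUE)
  det <- detect_spots_dog(sc$stack$channels$red, f$labels)
  counts <- table(det$records$nucleus_id)
  expect_true(all(counts == 2L))
  expect_equal(sum(counts), nrow(sc$truth$spots))
})

test_that("spotless nuclei stay spotless in at least 99% of cells", {
  no_spots <- list(no_stress = c(0L, 0L), nucleolar_capping = c(2L, 3L),
                   nucleolar_localization = c(1L, 3L),
                   nucleoplasmic_diffusion = c(0L, 0L),
                   cb_dispersion = c(4L, 8L))
  n_cells <- 0L; n_fp <- 0L
  for (s in 1:13) {
    sc <- generate_scene(scene_config(phenotype_mix = forced_mix("no_stress"),
                                      spots_per_cell = no_spots), 200 + s)
    lab <- segment_nuclei_canny(sc$stack$channels$dapi)
    f <- filter_objects(lab, 50, 4000, TRUE)
    det <- detect_spots_dog(sc$stack$channels$red, f$labels)
    n_cells <- n_cells + max(f$labels)
    n_fp <- n_fp + length(unique(det$records$nucleus_id))
  }
  expect_gte(n_cells, 100L)
  expect_gte(1 - n_fp / n_cells, 0.99)
})

test_that("detection is covariant under global intensity scaling", {
  sc <- generate_scene(scene_config(n_nuclei = 4L), 71)
  lab <- segment_nuclei_canny(sc$stack$channels$dapi)
  f <- filter_objects(lab, 50, 4000, TRUE)
  d1 <- detect_spots_dog(sc$stack$channels$red, f$labels)
  d2 <- detect_spots_dog(0.5 * sc$stack$channels$red, f$labels)
  expect_identical(d1$labels, d2$labels)
})

test_that("the contour route measures a noiseless disk spot accurately", {
  img <- matrix(0.2, 100, 100)
  rr <- matrix(1:100 - 50, 100, 100); cc <- t(rr)
  img[rr^2 + cc^2 <= 16] <- 0.9
  nuc <- matrix(0L, 100, 100)
  nuc[rr^2 + cc^2 <= 40^2] <- 1L
  # blank channel produces no spots
  blank <- detect_spots_canny(matrix(0.2, 100, 100), nuc)
  expect_equal(nrow(blank$records), 0L)
  det <- detect_spots_canny(img, nuc,
                            spot_params(method = "canny", canny_low = 0.05,
                                        canny_high = 0.12))
  expect_equal(nrow(det$records), 1L)
  expect_lt(abs(det$records$area_px - pi * 16) / (pi * 16), 0.35)
  expect_lt(abs(det$records$equiv_diameter_px - 8), 2)
})

test_that("contour and DoG routes agree on well-separated default spots", {
  cfg <- scene_config(n_nuclei = 6L, phenotype_mix = forced_mix("no_stress"),
                      spot_min_gap_px = 6)
  sc <- generate_scene(cfg, 81)
  lab <- segment_nuclei_canny(sc$stack$channels$dapi)
  f <- filter_objects(lab, 50, 4000, TRUE)
  a <- detect_spots_dog(sc$stack$channels$red, f$labels)
  b <- detect_spots_canny(sc$stack$channels$red, f$labels)
  expect_equal(nrow(a$records), nrow(b$records))
  expect_equal(sort(table(a$records$nucleus_id)),
               sort(table(b$records$nucleus_id)), ignore_attr = TRUE)
})

test_that("spot measurements are analytic on constructed objects", {
  lab <- matrix(0L, 40, 40)
  lab[5:13, 5:13] <- 1L   # 81 px square
  lab[30, 30] <- 2L       # single pixel
  img <- matrix(0.1, 40, 40); img[lab == 1L] <- 0.7
  m <- measure_spots(lab, img)
  expect_equal(m$area_px, c(81L, 1L))
  expect_equal(m$equiv_diameter_px, c(2 * sqrt(81 / pi), 2 / sqrt(pi)),
               tolerance = 1e-9)
  expect_equal(m$mean_intensity[1], 0.7)
  expect_equal(m$equiv_diameter_px^2 * pi / 4, m$area_px, tolerance = 1e-9)
  expect_equal(nrow(measure_spots(matrix(0L, 5, 5), matrix(0, 5, 5))), 0L)
})

test_that("centroid-containment assignment resolves straddling spots", {
  nuc <- matrix(0L, 20, 40)
  nuc[, 1:20] <- 1L; nuc[, 21:40] <- 2L
  spot <- matrix(0L, 20, 40)
  spot[9:11, 17:25] <- 1L   # 40% of pixels in nucleus 1, centroid in 2
  a <- assign_spots_to_nuclei(spot, nuc)
  expect_equal(unname(a["1"]), 2L)
  # centroid over background is unassigned
  nuc0 <- matrix(0L, 20, 40); nuc0[, 1:5] <- 3L
  expect_equal(unname(assign_spots_to_nuclei(spot, nuc0)["1"]), 0L)
  expect_error(assign_spots_to_nuclei(spot, matrix(0L, 5, 5)), "shape")
})
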