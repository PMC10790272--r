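disk_image <- function(n, centres, radius, fg = 0.8, bg = 0.05) {
  img <- matrix(bg, n, n)
  for (k in seq_len(nrow(centres))) {
    rr <- matrix(seq_len(n) - centres[k, 1], n, n)
    cc <- matrix(seq_len(n) - centres[k, 2], n, n, byrow = TRUE)
    img[rr^2 + cc^2 <= radius^2] <- fg
  }
  img
}

test_that("contour segmentation recovers filled disks at oracle accuracy", {
  expect_equal(max(segment_nuclei_canny(matrix(0.4, 64, 64))), 0L)
  one <- disk_image(128, cbind(64, 64), 20)
  lab <- segment_nuclei_canny(one)
  expect_equal(max(lab), 1L)
  oracle_area <- sum(one > 0.4)  # direct threshold of the noiseless disk
  expect_lt(abs(sum(lab == 1L) - oracle_area) / oracle_area, 0.10)
  expect_lt(abs(sum(lab == 1L) - pi * 400) / (pi * 400), 0.10)
  two <- disk_image(160, rbind(c(50, 50), c(110, 110)), 18)
  expect_equal(max(segment_nuclei_canny(two)), 2L)
  expect_error(segment_nuclei_canny(matrix(NaN, 8, 8)), "NA/NaN")
})

test_that("size/border filters use exclusive bounds and log each removal", {
  lab <- matrix(0L, 120, 220)
  lab[2:8, 2:8] <- 1L            # 49 px
  lab[2:6, 30:39] <- 2L          # 50 px
  lab[21:70, 51:130] <- 3L       # 4000 px
  lab[81:105, 141:220] <- 4L     # touches border (2000 px)
  f <- filter_objects(lab, min_area_px = 50, max_area_px = 4000,
                      remove_border = TRUE)
  kept_areas <- sort(as.integer(table(f$labels[f$labels > 0])))
  expect_equal(kept_areas, c(50L, 4000L))
  expect_setequal(f$log$reason, c("too_small", "border"))
  expect_equal(f$log$label[f$log$reason == "border"], 4L)
  # boundary forcing from the other side: 49 and 4001 both removed
  lab2 <- matrix(0L, 150, 150)
  lab2[2:8, 2:8] <- 1L                       # 49
  lab2[20:69, 20:99] <- 2L; lab2[70, 20] <- 2L  # 4001
  f2 <- filter_objects(lab2, 50, 4000, FALSE)
  expect_equal(max(f2$labels), 0L)
  expect_setequal(f2$log$reason, c("too_small", "too_large"))
  # no-op filter is the identity
  f3 <- filter_objects(lab, NULL, NULL, remove_border = FALSE)
  expect_identical(f3$labels, lab)
  expect_equal(nrow(f3$log), 0L)
})

test_that("filters are idempotent and monotone in the area window", {
  set.seed(4)
  lab <- spotquant:::label8(matrix(runif(80 * 80) > 0.7, 80))
  once <- filter_objects(lab, 5, 100, TRUE)
  twice <- filter_objects(once$labels, 5, 100, TRUE)
  expect_identical(once$labels, twice$labels)
  wide <- filter_objects(lab, 3, 200, TRUE)$labels
  narrow <- filter_objects(lab, 6, 80, TRUE)$labels
  expect_lte(max(narrow), max(wide))
  # every object surviving the narrow window also survives the wide one
  expect_true(all(narrow == 0 | wide > 0))
})

test_that("nucleus records report analytic geometry and intensity", {
  lab <- matrix(0L, 30, 30)
  lab[6:15, 6:15] <- 1L
  dapi <- matrix(0.1, 30, 30); dapi[lab == 1L] <- 0.4
  rec <- nucleus_records(lab, dapi)
  expect_equal(rec$area_px, 100L)
  expect_equal(rec$centroid_r, 9.5)   # 0-based rows 5..14
  expect_equal(rec$centroid_c, 9.5)
  expect_equal(rec$mean_dapi_intensity, 0.4)
  expect_false(rec$touches_border)
  expect_equal(nrow(nucleus_records(matrix(0L, 5, 5), matrix(0, 5, 5))), 0L)
  expect_error(nucleus_records(lab, matrix(0, 4, 4)), "shapes differ")
})

test_that("the pluggable segmenter contract accepts stubs and rejects junk", {
  img <- disk_image(100, cbind(50, 50), 15)
  stub <- function(dapi) {
    m <- matrix(0L, nrow(dapi), ncol(dapi))
    m[dapi > 0.4] <- 1L
    m
  }
  lab <- validate_labelmap(stub(img), dim(img))
  expect_equal(max(lab), 1L)
  # downstream filters behave identically on the stub's output
  f <- filter_objects(lab, 50, 4000, TRUE)
  expect_equal(max(f$labels), 1L)
  expect_error(validate_labelmap(matrix(0.5, 100, 100), dim(img)),
               "non-integer")
  expect_error(validate_labelmap(matrix(-1L, 100, 100), dim(img)),
               "negative")
  expect_error(validate_labelmap(matrix(0L, 10, 10), dim(img)), "shape")
})

test_that("default contour route recovers nearly all noiseless nuclei", {
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    sc <- generate_scene(scene_config(noise_gaussian_sd = 0,
                                      noise_poisson_scale = 0), 50 + s)
    lab <- segment_nuclei_canny(sc$stack$channels$dapi)
    f <- filter_objects(lab, 50, 4000, TRUE)
    tr <- sc$truth$nuclei
    for (i in seq_len(nrow(tr))) {
      total <- total + 1L
      L <- f$labels[round(tr$centroid_r[i]) + 1, round(tr$centroid_c[i]) + 1]
      if (L == 0L) next
      rr <- matrix(0:(nrow(lab) - 1), nrow(lab), ncol(lab))
      cc <- matrix(0:(ncol(lab) - 1), nrow(lab), ncol(lab), byrow = TRUE)
      u <- ((rr - tr$centroid_r[i]) * cos(tr$theta[i]) +
              (cc - tr$centroid_c[i]) * sin(tr$theta[i])) / tr$semi_major[i]
      v <- (-(rr - tr$centroid_r[i]) * sin(tr$theta[i]) +
              (cc - tr$centroid_c[i]) * cos(tr$theta[i])) / tr$semi_minor[i]
      tm <- u^2 + v^2 <= 1
      dm <- f$labels == L
      if (sum(tm & dm) / sum(tm | dm) >= 0.7) hits <- hits + 1L
    }
  }
  expect_gte(total, 20L)
  expect_gte(hits / total, 0.95)
})
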