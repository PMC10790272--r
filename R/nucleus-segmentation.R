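#' Segmentation parameters for the contour (Canny) route
#'
#' @param canny_sigma Gaussian pre-smoothing width in px.
#' @param canny_low,canny_high hysteresis thresholds on the Sobel gradient
#'   magnitude (intensity units per px), or `"auto"`: `high` is the Otsu
#'   threshold of the gradient magnitude and `low = 0.4 * high`.
#' @param close_radius_px,open_radius_px disc structuring-element radii for
#'   the morphological closing / opening steps.
#' @param min_area_px,max_area_px size filter bounds in px; objects are
#'   removed when strictly below `min_area_px` or strictly above
#'   `max_area_px` (the classical "< 50" / "> 4000" px cutoffs, both
#'   exclusive).
#' @param remove_border drop objects touching the image border.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(canny_sigma = 1.4, canny_low = "auto",
                       canny_high = "auto", close_radius_px = 2L,
                       open_radius_px = 2L, min_area_px = 50L,
                       max_area_px = 4000L, remove_border = TRUE) {
  p <- list(canny_sigma = canny_sigma, canny_low = canny_low,
            canny_high = canny_high,
            close_radius_px = as.integer(close_radius_px),
            open_radius_px = as.integer(open_radius_px),
            min_area_px = as.integer(min_area_px),
            max_area_px = as.integer(max_area_px),
            remove_border = isTRUE(remove_border))
  if (is.numeric(p$canny_low) && is.numeric(p$canny_high) &&
      p$canny_low >= p$canny_high)
    stopf("canny_low must be < canny_high")
  if (p$close_radius_px < 0L || p$open_radius_px < 0L)
    stopf("structuring-element radii must be >= 0")
  if (p$min_area_px >= p$max_area_px)
    stopf("min_area_px must be < max_area_px")
  class(p) <- "seg_params"
  p
}

sobel_gradients <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  list(gc = filter_mirror(img, kx),   # gradient along columns
       gr = filter_mirror(img, t(kx))) # gradient along rows
}

#' Canny edge map
#'
#' Gradient-based edge detection: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, then
#' hysteresis (weak edge pixels survive only in 8-connected components that
#' contain a strong pixel).
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param sigma smoothing width, px.
#' @param low,high hysteresis thresholds in gradient-magnitude units, or
#'   `"auto"` (Otsu of the magnitude; `low = 0.4 * high`).
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(image, sigma = 1.4, low = "auto", high = "auto") {
  assert_image(image)
  sm <- gaussian_blur(image, sigma)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gr^2 + g$gc^2)
  if (max(mag) < 1e-12) return(matrix(FALSE, nrow(image), ncol(image)))
  if (identical(high, "auto")) {
    high <- otsu_threshold(mag)
    low <- 0.4 * high
  } else if (identical(low, "auto")) {
    low <- 0.4 * high
  }
  # non-maximum suppression in 4 direction sectors
  ang <- atan2(g$gr, g$gc) %% pi
  sector <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8))
  sector[sector == 4L] <- 0L   # wrap: ~horizontal gradient
  nbr <- list(
    `0` = list(c(0L, 1L), c(0L, -1L)),    # gradient along cols
    `1` = list(c(1L, 1L), c(-1L, -1L)),   # diagonal
    `2` = list(c(1L, 0L), c(-1L, 0L)),    # gradient along rows
    `3` = list(c(1L, -1L), c(-1L, 1L))    # anti-diagonal
  )
  keep <- matrix(FALSE, nrow(image), ncol(image))
  for (s in 0:3) {
    d <- nbr[[as.character(s)]]
    ge <- mag >= shift_mat(mag, d[[1L]][1L], d[[1L]][2L]) &
      mag >= shift_mat(mag, d[[2L]][1L], d[[2L]][2L])
    keep <- keep | (sector == s & ge)
  }
  weak <- keep & (mag >= low)
  strong <- keep & (mag >= high)
  if (!any(strong)) return(matrix(FALSE, nrow(image), ncol(image)))
  comp <- label8(weak)
  good <- unique(comp[strong])
  comp %in% setdiff(good, 0L) & weak
}

canny_mask_pipeline <- function(image, sigma, low, high, close_radius,
                                open_radius) {
  edges <- canny_edges(image, sigma, low, high)
  if (!any(edges)) return(matrix(0L, nrow(image), ncol(image)))
  edges <- remove_isolated_pixels(edges)
  m <- binary_closing(edges * 1, close_radius)
  m <- fill_holes(m)
  m <- binary_opening(m, open_radius)
  label8(m > 0.5)
}

#' Segment nuclei from the DAPI channel by the contour route
#'
#' Canny edge detection on the counterstain, isolated-pixel cleaning,
#' morphological closing, hole filling, opening, then 8-connected component
#' labelling. A constant image yields an empty label map (not an error).
#' Size/border filtering is applied separately by [filter_objects()].
#'
#' @param dapi numeric matrix in `[0, 1]`.
#' @param params a [seg_params()] list.
#' @return integer label map (0 = background).
#' @export
segment_nuclei_canny <- function(dapi, params = seg_params()) {
  assert_image(dapi, "dapi")
  canny_mask_pipeline(dapi, params$canny_sigma, params$canny_low,
                      params$canny_high, params$close_radius_px,
                      params$open_radius_px)
}

#' Filter labelled objects by size and border contact
#'
#' An object is removed iff it touches the image border (when
#' `remove_border`), or its area is strictly greater than `max_area_px`
#' (objects above the cutoff likely represent multiple nuclei detected as
#' one, and are removed rather than split), or strictly smaller than
#' `min_area_px` (small detections are imaging artefacts). Thresholds are
#' exclusive: areas exactly equal to a bound are retained. Survivors are
#' relabelled compactly `1..K` preserving original label order.
#'
#' @param labelmap integer label map.
#' @param min_area_px,max_area_px optional bounds (NULL disables).
#' @param remove_border drop border-touching objects.
#' @return list with `labels` (filtered label map) and `log`
#'   (data.frame: `label`, `area_px`, `reason` for each removed object;
#'   reasons are `"border"`, `"too_large"`, `"too_small"`).
#' @export
filter_objects <- function(labelmap, min_area_px = NULL, max_area_px = NULL,
                           remove_border = TRUE) {
  if (!is.matrix(labelmap) || any(labelmap < 0))
    stopf("labelmap must be a matrix of non-negative integers")
  areas <- label_areas(labelmap)
  if (length(areas) == 0L)
    return(list(labels = labelmap,
                log = data.frame(label = integer(), area_px = integer(),
                                 reason = character())))
  ids <- as.integer(names(areas))
  border_ids <- unique(c(labelmap[1L, ], labelmap[nrow(labelmap), ],
                         labelmap[, 1L], labelmap[, ncol(labelmap)]))
  reason <- rep(NA_character_, length(ids))
  if (remove_border) reason[ids %in% border_ids] <- "border"
  if (!is.null(max_area_px))
    reason[is.na(reason) & areas > max_area_px] <- "too_large"
  if (!is.null(min_area_px))
    reason[is.na(reason) & areas < min_area_px] <- "too_small"
  keep <- ids[is.na(reason)]
  lut <- integer(max(labelmap) + 1L)
  lut[keep + 1L] <- seq_along(keep)
  list(labels = matrix(lut[labelmap + 1L], nrow(labelmap)),
       log = data.frame(label = ids[!is.na(reason)],
                        area_px = as.integer(areas[!is.na(reason)]),
                        reason = reason[!is.na(reason)]))
}

#' Per-nucleus measurement records
#'
#' One row per labelled nucleus: pixel area, unweighted centroid in 0-based
#' (row, col) coordinates, bounding box, border contact, and mean
#' counterstain intensity over member pixels.
#'
#' @param labelmap nucleus label map.
#' @param dapi counterstain channel, same shape.
#' @return data.frame with columns `nucleus_id`, `area_px`, `centroid_r`,
#'   `centroid_c`, `bbox_rmin`, `bbox_rmax`, `bbox_cmin`, `bbox_cmax`
#'   (0-based, inclusive), `touches_border`, `mean_dapi_intensity`.
#' @export
nucleus_records <- function(labelmap, dapi) {
  if (!all(dim(labelmap) == dim(dapi)))
    stopf("labelmap and dapi shapes differ")
  empty <- data.frame(nucleus_id = integer(), area_px = integer(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      bbox_rmin = integer(), bbox_rmax = integer(),
                      bbox_cmin = integer(), bbox_cmax = integer(),
                      touches_border = logical(),
                      mean_dapi_intensity = numeric())
  idx <- which(labelmap > 0L)
  if (length(idx) == 0L) return(empty)
  labs <- labelmap[idx]
  rc <- arrayInd(idx, dim(labelmap))
  sp <- function(v, f) tapply(v, labs, f)
  border_ids <- unique(c(labelmap[1L, ], labelmap[nrow(labelmap), ],
                         labelmap[, 1L], labelmap[, ncol(labelmap)]))
  ids <- sort(unique(labs))
  data.frame(
    nucleus_id = ids,
    area_px = as.integer(sp(rc[, 1L], length)),
    centroid_r = as.numeric(sp(rc[, 1L] - 1L, mean)),
    centroid_c = as.numeric(sp(rc[, 2L] - 1L, mean)),
    bbox_rmin = as.integer(sp(rc[, 1L] - 1L, min)),
    bbox_rmax = as.integer(sp(rc[, 1L] - 1L, max)),
    bbox_cmin = as.integer(sp(rc[, 2L] - 1L, min)),
    bbox_cmax = as.integer(sp(rc[, 2L] - 1L, max)),
    touches_border = ids %in% border_ids,
    mean_dapi_intensity = as.numeric(sp(dapi[idx], mean))
  )
}

#' Validate the pluggable-segmenter contract
#'
#' Any function `(dapi matrix) -> label map` may replace
#' [segment_nuclei_canny()] (e.g. a wrapper around a star-convex neural
#' segmenter run externally). The output must be an integer-valued matrix of
#' non-negative labels with the input's shape; downstream filters apply
#' identically regardless of the segmenter used.
#'
#' @param labelmap candidate segmenter output.
#' @param reference_dim expected `c(rows, cols)`.
#' @return the validated integer label map.
#' @export
validate_labelmap <- function(labelmap, reference_dim) {
  if (!is.matrix(labelmap))
    stopf("segmenter contract violation: output is not a matrix")
  if (!all(dim(labelmap) == reference_dim))
    stopf("segmenter contract violation: wrong shape (%s, expected %s)",
          paste(dim(labelmap), collapse = "x"),
          paste(reference_dim, collapse = "x"))
  if (anyNA(labelmap) || any(labelmap < 0))
    stopf("segmenter contract violation: negative or missing labels")
  if (any(labelmap != round(labelmap)))
    stopf("segmenter contract violation: non-integer label values")
  matrix(as.integer(labelmap), nrow(labelmap))
}
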