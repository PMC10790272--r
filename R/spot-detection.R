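#' Spot detection parameters
#'
#' Two detection routes are supported. The contour (`canny`) route applies
#' the same edge-detection + morphology sequence used for nuclei to the
#' spot channel, with *no* size-based selection of spots. The `dog` route
#' band-pass filters the channel with a Difference of Gaussians and
#' thresholds the response at
#' `median + dog_threshold_k * 1.4826 * MAD`, both statistics taken over
#' in-nucleus (nucleoplasm) response pixels, making the threshold
#' background-adaptive and invariant to global intensity scaling.
#'
#' @param method `"dog"` or `"canny"`.
#' @param dog_sigma_small,dog_sigma_large DoG scales in px (small < large;
#'   defaults 1.5 / 2.4, the classic 1.6 scale ratio).
#' @param dog_threshold_k threshold in multiples of the robust background
#'   spread (default 4.5, set so that spotless nuclei
#'   stay detection-free in at least 99% of cells at the default noise
#'   model).
#' @param boundary_guard_px erosion of the nucleus mask (px) before
#'   thresholding the DoG response: the band-pass response to the nucleus
#'   rim itself forms a thin annulus just inside the boundary which would
#'   otherwise be picked up as a spurious detection.
#' @param canny_sigma,canny_low,canny_high,close_radius_px,open_radius_px
#'   contour-route parameters, as in [seg_params()].
#' @param min_spot_area_px minimum spot area; default 0 (no size-based
#'   selection of spots).
#' @param in_nucleus_only drop detections whose centroid lies outside every
#'   nucleus.
#' @return list of class `spot_params`.
#' @export
spot_params <- function(method = c("dog", "canny"),
                        dog_sigma_small = 1.5, dog_sigma_large = 2.4,
                        dog_threshold_k = 4.5, boundary_guard_px = 7L,
                        canny_sigma = 1, canny_low = "auto",
                        canny_high = "auto", close_radius_px = 2L,
                        open_radius_px = 1L, min_spot_area_px = 0L,
                        in_nucleus_only = TRUE) {
  method <- match.arg(method)
  if (dog_sigma_small >= dog_sigma_large)
    stopf("dog_sigma_small must be < dog_sigma_large")
  if (dog_threshold_k <= 0) stopf("dog_threshold_k must be > 0")
  structure(list(method = method, dog_sigma_small = dog_sigma_small,
                 dog_sigma_large = dog_sigma_large,
                 dog_threshold_k = dog_threshold_k,
                 boundary_guard_px = as.integer(boundary_guard_px),
                 canny_sigma = canny_sigma, canny_low = canny_low,
                 canny_high = canny_high,
                 close_radius_px = as.integer(close_radius_px),
                 open_radius_px = as.integer(open_radius_px),
                 min_spot_area_px = as.integer(min_spot_area_px),
                 in_nucleus_only = isTRUE(in_nucleus_only)),
            class = "spot_params")
}

#' Difference-of-Gaussians band-pass filter
#'
#' `response = blur(image, sigma_small) - blur(image, sigma_large)` with
#' mirrored boundary handling. The response is signed; bright blobs of
#' radius comparable to the scales produce positive peaks.
#'
#' @param image numeric matrix.
#' @param sigma_small,sigma_large Gaussian widths in px, small < large.
#' @return numeric response matrix (same shape).
#' @export
dog_filter <- function(image, sigma_small = 1.5, sigma_large = 2.4) {
  assert_image(image)
  if (sigma_small >= sigma_large)
    stopf("sigma_small must be < sigma_large")
  if (sigma_small <= 0) stopf("sigmas must be positive")
  gaussian_blur(image, sigma_small) - gaussian_blur(image, sigma_large)
}

#' Per-spot measurements from a label map
#'
#' For each labelled object: pixel area, mean intensity over member pixels,
#' equivalent-circle diameter `2 * sqrt(area / pi)`, and unweighted centroid
#' in 0-based (row, col) coordinates.
#'
#' @param spot_labels integer label map of spots.
#' @param image intensity image, same shape.
#' @return data.frame with columns `spot_id`, `area_px`,
#'   `equiv_diameter_px`, `mean_intensity`, `centroid_r`, `centroid_c`.
#' @export
measure_spots <- function(spot_labels, image) {
  if (!all(dim(spot_labels) == dim(image)))
    stopf("spot_labels and image shapes differ")
  idx <- which(spot_labels > 0L)
  if (length(idx) == 0L)
    return(data.frame(spot_id = integer(), area_px = integer(),
                      equiv_diameter_px = numeric(),
                      mean_intensity = numeric(),
                      centroid_r = numeric(), centroid_c = numeric()))
  labs <- spot_labels[idx]
  rc <- arrayInd(idx, dim(spot_labels))
  ids <- sort(unique(labs))
  area <- as.integer(tapply(labs, labs, length))
  data.frame(
    spot_id = ids,
    area_px = area,
    equiv_diameter_px = 2 * sqrt(area / pi),
    mean_intensity = as.numeric(tapply(image[idx], labs, mean)),
    centroid_r = as.numeric(tapply(rc[, 1L] - 1L, labs, mean)),
    centroid_c = as.numeric(tapply(rc[, 2L] - 1L, labs, mean))
  )
}

#' Assign spots to parent nuclei by the centroid rule
#'
#' Each spot is assigned to the nucleus label found under its (rounded)
#' centroid pixel; a centroid over background yields `nucleus_id = 0`
#' (retained in tables but excluded from per-cell statistics). The rule is
#' a function: each spot maps to exactly one nucleus, even when its pixels
#' straddle several.
#'
#' @param spot_labels spot label map.
#' @param nucleus_labels nucleus label map, same shape.
#' @return integer vector of nucleus ids, named by spot id.
#' @export
assign_spots_to_nuclei <- function(spot_labels, nucleus_labels) {
  if (!all(dim(spot_labels) == dim(nucleus_labels)))
    stopf("spot and nucleus label maps differ in shape")
  cen <- label_centroids(spot_labels)
  if (is.null(cen) || nrow(cen) == 0L)
    return(stats::setNames(integer(0), character(0)))
  r <- pmin(pmax(round(cen[, "r"]) + 1L, 1L), nrow(nucleus_labels))
  c <- pmin(pmax(round(cen[, "c"]) + 1L, 1L), ncol(nucleus_labels))
  stats::setNames(as.integer(nucleus_labels[cbind(r, c)]),
                  as.character(cen[, "label"]))
}

finalize_spots <- function(spot_labels, image, nucleus_labels, params,
                           channel_role) {
  if (params$min_spot_area_px > 0L) {
    f <- filter_objects(spot_labels, min_area_px = params$min_spot_area_px,
                        max_area_px = NULL, remove_border = FALSE)
    spot_labels <- f$labels
  }
  assign <- assign_spots_to_nuclei(spot_labels, nucleus_labels)
  if (params$in_nucleus_only && length(assign)) {
    keep <- as.integer(names(assign)[assign > 0L])
    lut <- integer(max(spot_labels) + 1L)
    lut[keep + 1L] <- seq_along(keep)
    spot_labels <- matrix(lut[spot_labels + 1L], nrow(spot_labels))
    assign <- stats::setNames(assign[as.character(keep)],
                              as.character(seq_along(keep)))
  }
  rec <- measure_spots(spot_labels, image)
  rec$nucleus_id <- if (nrow(rec)) as.integer(assign[as.character(rec$spot_id)]) else integer(0)
  rec$channel_role <- rep(channel_role, nrow(rec))
  list(labels = spot_labels,
       records = rec[, c("spot_id", "nucleus_id", "channel_role", "area_px",
                         "equiv_diameter_px", "mean_intensity",
                         "centroid_r", "centroid_c")])
}

#' Detect intranuclear spots by DoG filtering and robust thresholding
#'
#' The DoG response is thresholded at `median + k * 1.4826 * MAD`, both
#' computed over nucleoplasm response pixels (the nucleus mask eroded by
#' `boundary_guard_px`), and detections are restricted to that guarded
#' region. Connected components (8-connectivity) above threshold become
#' spots; by default no size-based selection is applied.
#'
#' @param image spot channel, numeric matrix in `[0, 1]`.
#' @param nucleus_labels nucleus label map, same shape.
#' @param params [spot_params()].
#' @param channel_role recorded in the output table (`"red"` / `"green"`).
#' @return list with `labels` (spot label map) and `records`
#'   (data.frame of spot measurements with `nucleus_id` assignment).
#' @export
detect_spots_dog <- function(image, nucleus_labels, params = spot_params(),
                             channel_role = "red") {
  assert_image(image)
  if (!all(dim(image) == dim(nucleus_labels)))
    stopf("image and nucleus_labels shapes differ")
  nucmask <- nucleus_labels > 0L
  if (!any(nucmask)) {
    warning("empty nucleus mask: no spots can be assigned", call. = FALSE)
    return(list(labels = matrix(0L, nrow(image), ncol(image)),
                records = finalize_spots(matrix(0L, nrow(image), ncol(image)),
                                         image, nucleus_labels, params,
                                         channel_role)$records))
  }
  resp <- dog_filter(image, params$dog_sigma_small, params$dog_sigma_large)
  guard <- binary_erode(nucmask * 1, params$boundary_guard_px) > 0.5
  if (!any(guard)) guard <- nucmask
  v <- resp[guard]
  tau <- stats::median(v) + params$dog_threshold_k * stats::mad(v)
  binary <- (resp > tau) & guard
  finalize_spots(label8(binary), image, nucleus_labels, params, channel_role)
}

#' Detect spots by the contour (Canny) route
#'
#' Same contour -> clean -> close -> fill -> open -> label sequence as
#' nucleus segmentation, applied to the spot channel; no min/max area
#' filter is applied to spots by default.
#'
#' @inheritParams detect_spots_dog
#' @return list with `labels` and `records`, as [detect_spots_dog()].
#' @export
detect_spots_canny <- function(image, nucleus_labels, params = spot_params(method = "canny"),
                               channel_role = "red") {
  assert_image(image)
  if (!all(dim(image) == dim(nucleus_labels)))
    stopf("image and nucleus_labels shapes differ")
  # the nucleus rim contour is a ~1-px line at the boundary after
  # non-maximum suppression; a shallow erosion removes it without clipping
  # edge rings of legitimately boundary-adjacent spots
  confine <- as.integer(ceiling(2 * params$canny_sigma) + 1L)
  guard <- binary_erode((nucleus_labels > 0L) * 1, confine) > 0.5
  lo <- params$canny_low; hi <- params$canny_high
  if (identical(hi, "auto") && any(guard)) {
    # spot channels carry strong texture outside nuclei, so the nucleus
    # route's whole-image Otsu rule is miscalibrated here; use a robust
    # spread rule over the guarded nucleus interior instead
    g <- sobel_gradients(gaussian_blur(image, params$canny_sigma))
    v <- sqrt(g$gr^2 + g$gc^2)[guard]
    hi <- stats::median(v) + 8 * stats::mad(v)
    lo <- 0.4 * hi
  }
  edges <- canny_edges(image, params$canny_sigma, lo, hi)
  # confine contours to the guarded nucleus interior so the nucleus rim
  # itself is not traced as an object on the spot channel
  if (params$in_nucleus_only && any(guard)) edges <- edges & guard
  if (!any(edges))
    return(finalize_spots(matrix(0L, nrow(image), ncol(image)), image,
                          nucleus_labels, params, channel_role))
  edges <- remove_isolated_pixels(edges)
  m <- binary_closing(edges * 1, params$close_radius_px)
  m <- fill_holes(m)
  m <- binary_opening(m, params$open_radius_px)
  finalize_spots(label8(m > 0.5), image, nucleus_labels, params,
                 channel_role)
}
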