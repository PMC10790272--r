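#' Estimate the nucleolar region within one nucleus
#'
#' Two modes: `dapi_void` marks in-nucleus pixels whose counterstain falls
#' below the Otsu threshold of the in-nucleus DAPI distribution (nucleoli
#' are chromatin-poor, hence DAPI-dark); `npm_high` marks in-nucleus pixels
#' whose green (nucleophosmin-like) signal exceeds the in-nucleus Otsu
#' threshold. The mask is restricted to the nucleus and only connected
#' components of at least `min_area_px` are kept. A contrast-free nucleus
#' (uniform channel) yields an empty mask.
#'
#' @param nucleus_mask logical/0-1 matrix of one nucleus.
#' @param channel the DAPI channel (`dapi_void`) or green channel
#'   (`npm_high`), same shape.
#' @param mode `"dapi_void"` or `"npm_high"`.
#' @param min_area_px minimum component size (default 25 px, matching the
#'   small-detection artefact cutoff scale).
#' @param smooth_sigma_px Gaussian pre-smoothing of the channel before
#'   thresholding (suppresses shot-noise speckle that would otherwise chain
#'   onto the mask); 0 disables.
#' @return logical matrix.
#' @export
nucleolar_mask <- function(nucleus_mask, channel, mode = c("dapi_void",
                                                           "npm_high"),
                           min_area_px = 25L, smooth_sigma_px = 1.5) {
  mode <- match.arg(mode)
  if (!all(dim(nucleus_mask) == dim(channel)))
    stopf("nucleus_mask and channel shapes differ")
  m <- nucleus_mask > 0
  if (!any(m)) return(m)
  if (smooth_sigma_px > 0) channel <- gaussian_blur(channel, smooth_sigma_px)
  v <- channel[m]
  if (max(v) - min(v) < 1e-9) return(m & FALSE)
  th <- otsu_threshold(v)
  cand <- if (mode == "npm_high") m & (channel > th) else m & (channel < th)
  cand <- binary_opening(cand * 1, 1L) > 0.5
  if (!any(cand)) return(cand)
  lab <- label8(cand)
  areas <- label_areas(lab)
  keep <- as.integer(names(areas)[areas >= min_area_px])
  m2 <- matrix(lab %in% keep, nrow(lab))
  # nucleoli are solid bodies: noise holes in the thresholded mask would
  # fake a nearby boundary in the capping-annulus geometry
  fill_holes(m2) > 0.5 & (nucleus_mask > 0)
}

# distance (px) of each pixel from the boundary of a binary mask:
# positive inside, measured to nearest background; outside measured to mask
boundary_distance_maps <- function(mask) {
  list(inside = as.matrix(EBImage::distmap(mask * 1)),
       outside = as.matrix(EBImage::distmap((!mask) * 1)))
}

cell_features_one <- function(nucleus_px, stack, spot_labels, spot_rec,
                              nmask, annulus_px = 2) {
  red <- stack$channels$red
  nuc_area <- length(nucleus_px)
  n_spots <- nrow(spot_rec)
  spot_px <- which(spot_labels %in% spot_rec$spot_id & spot_labels > 0L)
  # spot-excluded nucleoplasm: nucleus minus 1-px-dilated spot mask
  if (length(spot_px)) {
    sm <- matrix(0, nrow(spot_labels), ncol(spot_labels))
    sm[spot_px] <- 1
    sm <- binary_dilate(sm, 1L)
    nucleo_px <- setdiff(nucleus_px, which(sm > 0.5))
  } else nucleo_px <- nucleus_px
  np_mean <- mean(red[nucleo_px])
  np_cv <- if (np_mean > 0) stats::sd(red[nucleo_px]) / np_mean else NA_real_

  if (n_spots == 0L) {
    return(data.frame(
      area_px = nuc_area, spot_count_red = 0L,
      spot_mean_diameter_px = NA_real_, spot_mean_intensity = NA_real_,
      spot_total_area_fraction = 0,
      nucleoplasm_mean_red = np_mean, nucleoplasm_cv_red = np_cv,
      nucleolar_overlap_fraction = NA_real_, capping_fraction = NA_real_))
  }
  overlap <- if (length(spot_px)) sum(nmask[spot_px]) / length(spot_px)
             else NA_real_
  if (any(nmask)) {
    bd <- boundary_distance_maps(nmask)
    ri <- pmin(pmax(round(spot_rec$centroid_r) + 1L, 1L), nrow(nmask))
    ci <- pmin(pmax(round(spot_rec$centroid_c) + 1L, 1L), ncol(nmask))
    at <- cbind(ri, ci)
    near_boundary <- ifelse(nmask[at] > 0,
                            bd$inside[at] <= annulus_px,
                            bd$outside[at] <= annulus_px)
  } else near_boundary <- rep(FALSE, n_spots)
  data.frame(
    area_px = nuc_area,
    spot_count_red = n_spots,
    spot_mean_diameter_px = mean(spot_rec$equiv_diameter_px),
    spot_mean_intensity = mean(spot_rec$mean_intensity),
    spot_total_area_fraction = min(1, sum(spot_rec$area_px) / nuc_area),
    nucleoplasm_mean_red = np_mean,
    nucleoplasm_cv_red = np_cv,
    nucleolar_overlap_fraction = overlap,
    capping_fraction = mean(near_boundary))
}

#' Per-cell feature vectors
#'
#' Computes, for each nucleus, the feature row consumed by the phenotype
#' classifier and the embedding: nucleus area; red-spot count, mean
#' equivalent diameter, mean intensity and total spot-area fraction;
#' spot-excluded nucleoplasm mean and coefficient of variation of the red
#' signal; the fraction of red-spot area inside the nucleolar mask; and the
#' fraction of spots whose centroid lies within a `±annulus_px` band of the
#' nucleolar boundary (the capping signature). Statistics that are
#' undefined for spotless nuclei are encoded as `NA`, never 0.
#'
#' @param stack a [channel_stack()].
#' @param nucleus_labels filtered nucleus label map.
#' @param spot_labels spot label map (same shape).
#' @param spot_records spot table from the detection step (must carry
#'   `nucleus_id`).
#' @param nucleolar_mode passed to [nucleolar_mask()].
#' @param annulus_px half-width of the capping annulus (px).
#' @return data.frame, one row per nucleus (`nucleus_id` first column).
#' @export
cell_features <- function(stack, nucleus_labels, spot_labels, spot_records,
                          nucleolar_mode = "dapi_void", annulus_px = 2) {
  ids <- sort(unique(nucleus_labels[nucleus_labels > 0L]))
  chan <- if (nucleolar_mode == "npm_high") stack$channels$green
          else stack$channels$dapi
  if (is.null(chan))
    stopf("channel required for nucleolar mode '%s' is missing",
          nucleolar_mode)
  if (is.null(stack$channels$red)) stopf("red channel missing")
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    # work on the nucleus bounding box for speed
    px <- which(nucleus_labels == id)
    rc <- arrayInd(px, dim(nucleus_labels))
    pad <- 3L
    rs <- max(1L, min(rc[, 1L]) - pad):min(nrow(chan), max(rc[, 1L]) + pad)
    cs <- max(1L, min(rc[, 2L]) - pad):min(ncol(chan), max(rc[, 2L]) + pad)
    sub_nuc <- nucleus_labels[rs, cs, drop = FALSE] == id
    sub_stack <- list(channels = lapply(stack$channels, function(ch)
      ch[rs, cs, drop = FALSE]))
    sub_spots <- spot_labels[rs, cs, drop = FALSE]
    rec <- spot_records[!is.na(spot_records$nucleus_id) &
                          spot_records$nucleus_id == id, , drop = FALSE]
    # express centroids in the crop frame
    if (nrow(rec)) {
      rec$centroid_r <- rec$centroid_r - (rs[1L] - 1L)
      rec$centroid_c <- rec$centroid_c - (cs[1L] - 1L)
    }
    nmask <- nucleolar_mask(sub_nuc, sub_stack$channels[[
      if (nucleolar_mode == "npm_high") "green" else "dapi"]],
      mode = nucleolar_mode)
    row <- cell_features_one(which(sub_nuc), sub_stack, sub_spots, rec,
                             nmask, annulus_px)
    rows[[k]] <- cbind(data.frame(nucleus_id = id), row)
  }
  if (!length(rows))
    return(data.frame(nucleus_id = integer(), area_px = integer(),
                      spot_count_red = integer(),
                      spot_mean_diameter_px = numeric(),
                      spot_mean_intensity = numeric(),
                      spot_total_area_fraction = numeric(),
                      nucleoplasm_mean_red = numeric(),
                      nucleoplasm_cv_red = numeric(),
                      nucleolar_overlap_fraction = numeric(),
                      capping_fraction = numeric()))
  do.call(rbind, rows)
}

#' Per-condition summary of spot count and diameter
#'
#' Mirrors the headline per-condition quantitation: mean, sd and n of the
#' per-cell spot count and of the mean spot diameter (cells without spots
#' are excluded pairwise from the diameter summary).
#'
#' @param cells feature table from [cell_features()], with a `condition`
#'   column.
#' @param condition_col name of the grouping column.
#' @return data.frame, one row per condition.
#' @export
condition_summary <- function(cells, condition_col = "condition") {
  if (!condition_col %in% names(cells))
    stopf("unknown condition column '%s'", condition_col)
  sd_or_na <- function(v) if (length(v) < 2L) NA_real_ else stats::sd(v)
  out <- lapply(split(cells, cells[[condition_col]]), function(g) {
    d <- g$spot_mean_diameter_px[!is.na(g$spot_mean_diameter_px)]
    data.frame(
      condition = g[[condition_col]][1L],
      n = nrow(g),
      spot_count_mean = mean(g$spot_count_red),
      spot_count_sd = sd_or_na(g$spot_count_red),
      spot_diameter_mean = if (length(d)) mean(d) else NA_real_,
      spot_diameter_sd = sd_or_na(d),
      n_diameter = length(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
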