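# Scene/analysis helpers shared across test files.

forced_mix <- function(class) {
  mix <- stats::setNames(rep(0, 5), phenotype_levels)
  mix[class] <- 1
  mix
}

# default-parameter analysis of one scene: segmentation, filtering, DoG
# spots, features; returns per-truth-nucleus rows matched by centroid
analyze_scene_vs_truth <- function(scene, with_features = TRUE) {
  lab <- segment_nuclei_canny(scene$stack$channels$dapi)
  f <- filter_objects(lab, min_area_px = 50, max_area_px = 4000,
                      remove_border = TRUE)
  det <- detect_spots_dog(scene$stack$channels$red, f$labels)
  tr <- scene$truth$nuclei
  tr$det_label <- f$labels[cbind(round(tr$centroid_r) + 1,
                                 round(tr$centroid_c) + 1)]
  tr$truth_count <- vapply(tr$nucleus_id, function(id)
    sum(scene$truth$spots$nucleus_id == id), integer(1))
  if (with_features) {
    cells <- cell_features(scene$stack, f$labels, det$labels, det$records)
    cells$predicted <- classify_cells(cells)
    tr <- merge(tr, cells, by.x = "det_label", by.y = "nucleus_id")
  } else {
    counts <- table(factor(det$records$nucleus_id,
                           levels = sort(unique(tr$det_label))))
    tr$det_count <- as.integer(counts[as.character(tr$det_label)])
    tr$det_count[is.na(tr$det_count)] <- 0L
    tr <- tr[tr$det_label > 0L, , drop = FALSE]
  }
  tr
}

# pool of analysed cells with known phenotype, built from forced-class scenes
class_pool <- function(class, n_scenes, seed0, config_args = list()) {
  rows <- vector("list", n_scenes)
  for (s in seq_len(n_scenes)) {
    args <- config_args
    args$phenotype_mix <- forced_mix(class)
    scene <- generate_scene(do.call(scene_config, args), seed0 + s)
    m <- analyze_scene_vs_truth(scene)
    if (nrow(m)) rows[[s]] <- m
  }
  do.call(rbind, rows)
}
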