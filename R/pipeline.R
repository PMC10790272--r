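#' Default end-to-end run configuration
#'
#' A nested configuration driving [run_pipeline()]: simulated conditions
#' (named phenotype mixes), scene settings, and per-stage parameter blocks.
#' Per-scene seeds are derived from the global seed by a fixed rule:
#' `scene_seed = seed + 1000 * condition_index + scene_index`, and the
#' embedding uses `seed + 500000`, so a run is fully reproducible from
#' `seed` alone.
#'
#' @param seed global integer seed.
#' @param outdir output directory.
#' @param n_scenes_per_condition scenes simulated per condition.
#' @param conditions named list: condition -> phenotype mix (probability
#'   vector over [phenotype_levels]). Defaults are a control-like mix
#'   (90% unstressed) and a dispersion-enriched, drug-like mix.
#' @param scene list of [scene_config()] overrides.
#' @return list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("spotquant_run_"),
                               n_scenes_per_condition = 4L,
                               conditions = list(
                                 control = c(no_stress = 0.9,
                                             nucleolar_capping = 0.025,
                                             nucleolar_localization = 0.025,
                                             nucleoplasmic_diffusion = 0.025,
                                             cb_dispersion = 0.025),
                                 treated = c(no_stress = 0.2,
                                             nucleolar_capping = 0.1,
                                             nucleolar_localization = 0.05,
                                             nucleoplasmic_diffusion = 0.05,
                                             cb_dispersion = 0.6)),
                               scene = list()) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(conditions = conditions,
                    n_scenes_per_condition = as.integer(n_scenes_per_condition),
                    scene = scene),
    segment = list(canny_sigma = 1.4, canny_low = "auto",
                   canny_high = "auto", close_radius_px = 2L,
                   open_radius_px = 2L, min_area_px = 50L,
                   max_area_px = 4000L, remove_border = TRUE),
    spots = list(method = "dog", dog_sigma_small = 1.5,
                 dog_sigma_large = 2.4, dog_threshold_k = 4.5,
                 boundary_guard_px = 7L),
    features = list(nucleolar_mode = "dapi_void", annulus_px = 2),
    classify = unclass(rule_thresholds()),
    embed = list(enabled = TRUE, perplexity = 30),
    compare = list(value = "spot_count_red", adjust = "none")),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Collects every problem at once rather than stopping at the first.
#'
#' @param config a run configuration list.
#' @return character vector of error messages; empty when the
#'   configuration is valid.
#' @export
validate_run_config <- function(config) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1L,
      "seed must be a single integer")
  sim <- config$simulate
  chk(is.list(sim$conditions) && length(sim$conditions) >= 1L &&
        !is.null(names(sim$conditions)),
      "simulate$conditions must be a named list of phenotype mixes")
  for (nm in names(sim$conditions)) {
    mix <- sim$conditions[[nm]]
    if (is.null(names(mix)) || !setequal(names(mix), phenotype_levels) ||
        any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
      errs <- c(errs, sprintf(
        "condition '%s': phenotype mix must be named by the 5 phenotypes and sum to 1", nm))
  }
  chk(sim$n_scenes_per_condition >= 1L,
      "n_scenes_per_condition must be >= 1")
  sc <- tryCatch(do.call(scene_config, sim$scene %||% list()),
                 error = function(e) conditionMessage(e))
  if (is.character(sc)) errs <- c(errs, sc)
  sg <- config$segment
  if (is.numeric(sg$canny_low) && is.numeric(sg$canny_high) &&
      sg$canny_low >= sg$canny_high)
    errs <- c(errs, "segment: canny_low must be < canny_high")
  if (!is.null(sg$min_area_px) && !is.null(sg$max_area_px) &&
      sg$min_area_px >= sg$max_area_px)
    errs <- c(errs, "segment: min_area_px must be < max_area_px")
  sp <- config$spots
  if (sp$dog_sigma_small >= sp$dog_sigma_large)
    errs <- c(errs, "spots: dog_sigma_small must be < dog_sigma_large")
  if (sp$dog_threshold_k <= 0)
    errs <- c(errs, "spots: dog_threshold_k must be > 0")
  if (!config$features$nucleolar_mode %in% c("dapi_void", "npm_high"))
    errs <- c(errs, "features: nucleolar_mode must be dapi_void or npm_high")
  th <- tryCatch(do.call(rule_thresholds, config$classify),
                 error = function(e) conditionMessage(e))
  if (is.character(th)) errs <- c(errs, paste("classify:", th))
  errs
}

analyze_stack <- function(stack, config) {
  segp <- seg_params(canny_sigma = config$segment$canny_sigma,
                     canny_low = config$segment$canny_low,
                     canny_high = config$segment$canny_high,
                     close_radius_px = config$segment$close_radius_px,
                     open_radius_px = config$segment$open_radius_px,
                     min_area_px = config$segment$min_area_px,
                     max_area_px = config$segment$max_area_px,
                     remove_border = config$segment$remove_border)
  raw <- segment_nuclei_canny(stack$channels$dapi, segp)
  filt <- filter_objects(raw, min_area_px = segp$min_area_px,
                         max_area_px = segp$max_area_px,
                         remove_border = segp$remove_border)
  spotp <- spot_params(method = config$spots$method,
                       dog_sigma_small = config$spots$dog_sigma_small,
                       dog_sigma_large = config$spots$dog_sigma_large,
                       dog_threshold_k = config$spots$dog_threshold_k,
                       boundary_guard_px = config$spots$boundary_guard_px)
  det <- if (spotp$method == "dog")
    detect_spots_dog(stack$channels$red, filt$labels, spotp, "red")
  else detect_spots_canny(stack$channels$red, filt$labels, spotp, "red")
  cells <- cell_features(stack, filt$labels, det$labels, det$records,
                         nucleolar_mode = config$features$nucleolar_mode,
                         annulus_px = config$features$annulus_px)
  nuclei <- nucleus_records(filt$labels, stack$channels$dapi)
  list(nucleus_labels = filt$labels, removal_log = filt$log,
       spot_labels = det$labels, spots = det$records,
       nuclei = nuclei, cells = cells)
}

#' Run the full analysis pipeline on simulated conditions
#'
#' Executes simulate -> segment -> filter -> detect spots -> features ->
#' classify -> summarize -> embed -> compare, persisting every intermediate
#' table (CSV), label maps (16-bit TIFF) and a machine-readable JSON
#' summary. Identical `config` + seed reproduce identical outputs.
#'
#' @param config a [default_run_config()]-style configuration.
#' @param write_labels_maps write per-scene label TIFFs (default TRUE).
#' @return the run summary (list), invisibly; artifacts in
#'   `config$outdir`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         write_labels_maps = TRUE) {
  errs <- validate_run_config(config)
  if (length(errs))
    stopf("invalid run config:\n%s", paste("-", errs, collapse = "\n"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  logline <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  conditions <- names(config$simulate$conditions)
  all_cells <- list(); all_spots <- list(); all_nuclei <- list()
  removal_tally <- c(border = 0L, too_large = 0L, too_small = 0L)
  truth_counts <- stats::setNames(integer(length(conditions)), conditions)
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    for (si in seq_len(config$simulate$n_scenes_per_condition)) {
      scene_seed <- config$seed + 1000L * ci + si
      sc_args <- config$simulate$scene %||% list()
      sc_args$phenotype_mix <-
        config$simulate$conditions[[cond]][phenotype_levels]
      scene <- tryCatch(
        generate_scene(do.call(scene_config, sc_args), scene_seed),
        error = function(e)
          stopf("simulate stage failed (condition %s, scene %d): %s",
                cond, si, conditionMessage(e)))
      res <- tryCatch(analyze_stack(scene$stack, config),
                      error = function(e)
                        stopf("analysis failed (condition %s, scene %d): %s",
                              cond, si, conditionMessage(e)))
      truth_counts[cond] <- truth_counts[cond] + nrow(scene$truth$nuclei)
      tal <- table(res$removal_log$reason)
      for (nm in names(tal))
        removal_tally[nm] <- removal_tally[nm] + tal[[nm]]
      tag <- sprintf("%s_scene%02d", cond, si)
      if (write_labels_maps) {
        dir.create(file.path(outdir, "labels"), showWarnings = FALSE)
        write_labels(res$nucleus_labels,
                     file.path(outdir, "labels", paste0(tag, "_nuclei.tif")))
        write_labels(res$spot_labels,
                     file.path(outdir, "labels", paste0(tag, "_spots.tif")))
      }
      for (nm in c("cells", "spots", "nuclei")) {
        df <- res[[nm]]
        if (nrow(df)) {
          df$condition <- cond; df$scene <- tag
          slot <- list(df); names(slot) <- tag
          if (nm == "cells") all_cells <- c(all_cells, slot)
          if (nm == "spots") all_spots <- c(all_spots, slot)
          if (nm == "nuclei") all_nuclei <- c(all_nuclei, slot)
        }
      }
      logline("[%s] %d nuclei analyzed, %d spots", tag,
              nrow(res$cells), nrow(res$spots))
    }
  }
  cells <- do.call(rbind, c(all_cells, list(make.row.names = FALSE)))
  spots <- do.call(rbind, c(all_spots, list(make.row.names = FALSE)))
  nuclei <- do.call(rbind, c(all_nuclei, list(make.row.names = FALSE)))
  if (is.null(cells) || nrow(cells) == 0L)
    stopf("no cells survived filtering; nothing to analyze")
  th <- do.call(rule_thresholds, config$classify)
  cells$phenotype <- classify_cells(cells, th)
  fractions <- withCallingHandlers(
    phenotype_fractions(cells$phenotype, cells$condition),
    warning = function(w) {
      logline("note: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  summary_tab <- condition_summary(cells)
  write_table(cells, file.path(outdir, "cells.csv"))
  write_table(spots, file.path(outdir, "spots.csv"))
  write_table(nuclei, file.path(outdir, "nuclei.csv"))
  write_table(fractions, file.path(outdir, "phenotype_fractions.csv"))
  write_table(summary_tab, file.path(outdir, "condition_summary.csv"))

  embedding <- NULL
  if (isTRUE(config$embed$enabled)) {
    feat_cols <- c("area_px", "spot_count_red", "spot_mean_diameter_px",
                   "spot_mean_intensity", "spot_total_area_fraction",
                   "nucleoplasm_mean_red", "nucleoplasm_cv_red",
                   "nucleolar_overlap_fraction", "capping_fraction")
    perp <- config$embed$perplexity
    if (nrow(cells) <= 3 * perp) {
      perp <- max(2, floor((nrow(cells) - 1) / 3) - 1)
      logline("note: perplexity reduced to %g for n = %d cells", perp,
              nrow(cells))
    }
    if (perp >= 2) {
      z <- standardize_features(as.matrix(cells[, feat_cols]))
      emb <- tsne_embed(z, seed = config$seed + 500000L, perplexity = perp)
      embedding <- data.frame(nucleus_id = cells$nucleus_id,
                              scene = cells$scene,
                              condition = cells$condition,
                              tsne1 = emb$coordinates[, 1L],
                              tsne2 = emb$coordinates[, 2L])
      write_table(embedding, file.path(outdir, "embedding.csv"))
    } else logline("note: too few cells for embedding; skipped")
  }

  comparisons <- NULL
  if (length(conditions) >= 2L) {
    comparisons <- compare_conditions(cells[[config$compare$value]],
                                      cells$condition,
                                      adjust = config$compare$adjust %||% "none")
    write_table(comparisons, file.path(outdir, "comparisons.csv"))
    violin_export(cells[[config$compare$value]], cells$condition,
                  file.path(outdir, "spot_count_violin.png"),
                  value_name = config$compare$value)
  }

  cfg_out <- rapply(unclass(config), function(x) x, how = "replace")
  yaml::write_yaml(cfg_out, file.path(outdir, "config.yaml"))
  summary <- list(
    package_version = as.character(utils::packageVersion("spotquant")),
    seed = config$seed,
    conditions = conditions,
    n_truth_nuclei = as.list(truth_counts),
    n_analyzed_cells = as.list(table(cells$condition)),
    n_spots = nrow(spots),
    removal_tally = as.list(removal_tally),
    phenotype_fractions = fractions,
    condition_summary = summary_tab,
    comparisons = comparisons)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(c(summary, list(cells = cells, spots = spots,
                            embedding = embedding)))
}
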