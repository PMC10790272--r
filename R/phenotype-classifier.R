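#' Rule thresholds for phenotype assignment
#'
#' Operational cutoffs for the five-class rule cascade. The original
#' phenotyping of stress classes was done by eye; these thresholds are the
#' package's documented, overridable operationalization.
#'
#' @param dispersion_min_count spot count at or above which a cell is
#'   called `cb_dispersion`.
#' @param capping_min_fraction minimum fraction of spots with centroids on
#'   the nucleolar-boundary annulus for `nucleolar_capping`.
#' @param nucleolar_min_overlap minimum fraction of spot area inside the
#'   nucleolar mask for `nucleolar_localization`.
#' @param diffusion_max_count maximum spot count for
#'   `nucleoplasmic_diffusion`.
#' @param diffusion_max_cv maximum spot-excluded nucleoplasm coefficient of
#'   variation for `nucleoplasmic_diffusion` (diffuse signal raises the
#'   mean, flattening relative texture).
#' @return list of class `rule_thresholds`.
#' @export
rule_thresholds <- function(dispersion_min_count = 4L,
                            capping_min_fraction = 0.5,
                            nucleolar_min_overlap = 0.5,
                            diffusion_max_count = 0L,
                            diffusion_max_cv = 0.35) {
  if (dispersion_min_count < 1L) stopf("dispersion_min_count must be >= 1")
  if (capping_min_fraction < 0 || capping_min_fraction > 1 ||
      nucleolar_min_overlap < 0 || nucleolar_min_overlap > 1)
    stopf("fraction thresholds must lie in [0, 1]")
  if (diffusion_max_count < 0) stopf("diffusion_max_count must be >= 0")
  if (diffusion_max_cv <= 0) stopf("diffusion_max_cv must be > 0")
  structure(list(dispersion_min_count = as.integer(dispersion_min_count),
                 capping_min_fraction = capping_min_fraction,
                 nucleolar_min_overlap = nucleolar_min_overlap,
                 diffusion_max_count = as.integer(diffusion_max_count),
                 diffusion_max_cv = diffusion_max_cv),
            class = "rule_thresholds")
}

#' Assign a nuclear-stress phenotype to one cell
#'
#' Deterministic first-match rule cascade, in fixed precedence (count-based
#' evidence is most robust to mask noise, so it wins):
#' 1. `cb_dispersion` when `spot_count >= dispersion_min_count`;
#' 2. `nucleolar_capping` when `capping_fraction >= capping_min_fraction`
#'    and at least one spot;
#' 3. `nucleolar_localization` when
#'    `nucleolar_overlap_fraction >= nucleolar_min_overlap` and at least
#'    one spot;
#' 4. `nucleoplasmic_diffusion` when `spot_count <= diffusion_max_count`
#'    and `nucleoplasm_cv_red <= diffusion_max_cv`;
#' 5. otherwise `no_stress`.
#'
#' Missing capping/overlap fields (possible only for spotless cells) never
#' match a rule. Every valid feature row receives exactly one label.
#'
#' @param features one feature row ([cell_features()]) as data.frame or
#'   named list.
#' @param thresholds a [rule_thresholds()].
#' @return a single phenotype label (character).
#' @export
classify_cell <- function(features, thresholds = rule_thresholds()) {
  f <- as.list(features)
  need <- c("spot_count_red", "capping_fraction",
            "nucleolar_overlap_fraction", "nucleoplasm_cv_red")
  if (!all(need %in% names(f)))
    stopf("malformed feature vector: missing %s",
          paste(setdiff(need, names(f)), collapse = ", "))
  n <- f$spot_count_red
  if (is.na(n) || n < 0) stopf("malformed feature vector: bad spot count")
  if (n > 0 && (is.na(f$capping_fraction) ||
                is.na(f$nucleolar_overlap_fraction))) {
    # spot-bearing cells must carry geometry fractions; treat as no-match
    f$capping_fraction <- f$capping_fraction %|NA|% -1
    f$nucleolar_overlap_fraction <- f$nucleolar_overlap_fraction %|NA|% -1
  }
  ge <- function(x, t) !is.na(x) && x >= t
  le <- function(x, t) !is.na(x) && x <= t
  if (n >= thresholds$dispersion_min_count) return("cb_dispersion")
  if (n >= 1L && ge(f$capping_fraction, thresholds$capping_min_fraction))
    return("nucleolar_capping")
  if (n >= 1L && ge(f$nucleolar_overlap_fraction,
                    thresholds$nucleolar_min_overlap))
    return("nucleolar_localization")
  if (n <= thresholds$diffusion_max_count &&
      le(f$nucleoplasm_cv_red, thresholds$diffusion_max_cv))
    return("nucleoplasmic_diffusion")
  "no_stress"
}

`%|NA|%` <- function(a, b) if (length(a) == 1L && is.na(a)) b else a

#' Classify every cell in a feature table
#'
#' @param cells feature table from [cell_features()].
#' @param thresholds a [rule_thresholds()].
#' @return character vector of labels, one per row.
#' @export
classify_cells <- function(cells, thresholds = rule_thresholds()) {
  vapply(seq_len(nrow(cells)), function(i)
    classify_cell(cells[i, , drop = FALSE], thresholds), character(1))
}

#' Phenotype fractions per condition
#'
#' Counts and fractions of each phenotype per condition; fractions sum to 1
#' within each condition. Emits a warning for conditions with fewer than
#' `min_cells` cells (manual phenotyping conventionally uses at least 300
#' cells per sample).
#'
#' @param labels character vector of phenotype labels.
#' @param condition parallel vector of condition keys.
#' @param min_cells warning floor (default 300).
#' @return data.frame: `condition`, `phenotype`, `n`, `fraction`.
#' @export
phenotype_fractions <- function(labels, condition, min_cells = 300L) {
  if (length(labels) == 0L) stopf("empty input")
  if (length(labels) != length(condition))
    stopf("labels and condition lengths differ")
  bad <- setdiff(unique(labels), phenotype_levels)
  if (length(bad)) stopf("unknown phenotype label(s): %s",
                         paste(bad, collapse = ", "))
  tab <- table(factor(condition),
               factor(labels, levels = phenotype_levels))
  small <- rownames(tab)[rowSums(tab) < min_cells]
  if (length(small))
    warning(sprintf("condition(s) below %d cells: %s", min_cells,
                    paste(small, collapse = ", ")), call. = FALSE)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("condition", "phenotype", "n")
  tot <- stats::ave(out$n, out$condition, FUN = sum)
  out$fraction <- out$n / tot
  out[order(out$condition, match(out$phenotype, phenotype_levels)), ,
      drop = FALSE]
}
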