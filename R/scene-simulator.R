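#' Phenotype labels of the five nuclear-stress classes
#' @export
phenotype_levels <- c("no_stress", "nucleolar_capping",
                      "nucleolar_localization", "nucleoplasmic_diffusion",
                      "cb_dispersion")

#' Synthetic fluorescence scene configuration
#'
#' Describes a cultured-cell field: round-ish, non-overlapping, slightly
#' elliptical nuclei with a darker (DAPI-void) nucleolar sub-region, 0--8
#' bright intranuclear spots per nucleus placed according to one of five
#' nuclear-stress phenotype geometries, plus PSF blur, Poisson photon noise
#' and additive Gaussian read noise.
#'
#' Default intensity levels give a spot signal-to-noise ratio
#' `(spot_peak - nucleoplasm) / noise_sd = (0.85 - 0.25) / 0.1 = 6` on the
#' red (Coilin-like) channel. The green channel carries a nucleolar
#' (NPM-like) marker; DAPI carries the counterstain with a darker
#' nucleolus.
#'
#' @param image_height_px,image_width_px scene dimensions.
#' @param n_nuclei number of nuclei to place (rejection sampling with a
#'   bounded retry count; an over-crowded request errors).
#' @param nucleus_radius_px `c(min, max)` equal-area radius range, px.
#' @param nucleus_eccentricity maximum relative axis perturbation: semi-axes
#'   are `r * (1 + s)` and `r * (1 - s)` with `s ~ U(0, value)`.
#' @param nucleolus_radius_fraction nucleolus radius as a fraction of the
#'   nucleus radius, in (0, 0.6].
#' @param phenotype_mix named probability vector over [phenotype_levels],
#'   summing to 1.
#' @param spots_per_cell named list of `c(min, max)` integer spot-count
#'   ranges per phenotype.
#' @param spot_radius_px `c(min, max)` spot radius range, px.
#' @param spot_min_gap_px minimum edge-to-edge gap between spots of one
#'   nucleus (px).
#' @param intensity_levels named list per channel role, each
#'   `c(background, nucleoplasm, nucleolus, spot_peak)` in `[0, 1]`.
#' @param noise_gaussian_sd additive Gaussian noise sd (normalized units).
#' @param noise_poisson_scale photons per unit intensity (0 disables
#'   Poisson resampling).
#' @param psf_sigma_px Gaussian blur width emulating the point-spread
#'   function.
#' @param bit_depth 8 or 16 (used when scenes are written to disk).
#' @return list of class `scene_config`.
#' @export
scene_config <- function(image_height_px = 512L, image_width_px = 512L,
                         n_nuclei = 8L,
                         nucleus_radius_px = c(18, 32),
                         nucleus_eccentricity = 0.15,
                         nucleolus_radius_fraction = 0.35,
                         phenotype_mix = stats::setNames(rep(0.2, 5),
                                                         phenotype_levels),
                         spots_per_cell = list(
                           no_stress = c(1L, 2L),
                           nucleolar_capping = c(2L, 3L),
                           nucleolar_localization = c(1L, 3L),
                           nucleoplasmic_diffusion = c(0L, 0L),
                           cb_dispersion = c(4L, 8L)),
                         spot_radius_px = c(2, 5),
                         spot_min_gap_px = 3,
                         intensity_levels = list(
                           dapi = c(background = 0.03, nucleoplasm = 0.55,
                                    nucleolus = 0.18, spot_peak = 0),
                           red = c(background = 0.03, nucleoplasm = 0.25,
                                   nucleolus = 0.25, spot_peak = 0.85),
                           green = c(background = 0.03, nucleoplasm = 0.20,
                                     nucleolus = 0.75, spot_peak = 0)),
                         noise_gaussian_sd = 0.1,
                         noise_poisson_scale = 500,
                         psf_sigma_px = 1,
                         bit_depth = 16L) {
  cfg <- structure(as.list(environment()), class = "scene_config")
  errs <- validate_scene_config(cfg)
  if (length(errs))
    stopf("invalid scene config:\n%s", paste("-", errs, collapse = "\n"))
  cfg
}

#' Validate a scene configuration
#'
#' @param cfg a `scene_config` (or plain list with the same fields).
#' @return character vector of error messages (empty when valid).
#' @export
validate_scene_config <- function(cfg) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(cfg$image_height_px >= 1 && cfg$image_width_px >= 1,
      "image dimensions must be positive")
  chk(cfg$n_nuclei >= 0, "n_nuclei must be non-negative")
  chk(length(cfg$nucleus_radius_px) == 2 &&
        cfg$nucleus_radius_px[1] <= cfg$nucleus_radius_px[2] &&
        cfg$nucleus_radius_px[1] > 0,
      "nucleus_radius_px must be a positive (min, max) range")
  chk(length(cfg$spot_radius_px) == 2 &&
        cfg$spot_radius_px[1] <= cfg$spot_radius_px[2] &&
        cfg$spot_radius_px[1] > 0,
      "spot_radius_px must be a positive (min, max) range")
  chk(cfg$nucleolus_radius_fraction > 0 &&
        cfg$nucleolus_radius_fraction <= 0.6,
      "nucleolus_radius_fraction must be in (0, 0.6]")
  chk(cfg$nucleus_eccentricity >= 0 && cfg$nucleus_eccentricity <= 0.3,
      "nucleus_eccentricity must be in [0, 0.3]")
  mix <- cfg$phenotype_mix
  chk(!is.null(names(mix)) && setequal(names(mix), phenotype_levels),
      "phenotype_mix must be named by the five phenotype labels")
  chk(all(mix >= 0) && abs(sum(mix) - 1) < 1e-9,
      "phenotype_mix must be non-negative and sum to 1 (within 1e-9)")
  for (role in names(cfg$intensity_levels)) {
    lv <- cfg$intensity_levels[[role]]
    chk(all(lv >= 0 & lv <= 1),
        sprintf("intensity_levels$%s must lie in [0,1]", role))
  }
  chk(cfg$spot_min_gap_px >= 0, "spot_min_gap_px must be >= 0")
  chk(cfg$noise_gaussian_sd >= 0, "noise_gaussian_sd must be >= 0")
  chk(cfg$noise_poisson_scale >= 0, "noise_poisson_scale must be >= 0")
  chk(cfg$psf_sigma_px >= 0, "psf_sigma_px must be >= 0")
  chk(cfg$bit_depth %in% c(8L, 16L), "bit_depth must be 8 or 16")
  errs
}

# ellipse membership/margin test for offsets (dr, dc) from the centre
inside_ellipse <- function(dr, dc, a, b, theta, margin = 0) {
  am <- a - margin; bm <- b - margin
  if (am <= 0 || bm <= 0) return(rep(FALSE, length(dr)))
  u <- (dr * cos(theta) + dc * sin(theta)) / am
  v <- (-dr * sin(theta) + dc * cos(theta)) / bm
  u^2 + v^2 <= 1
}

#' Place spots for one nucleus according to its phenotype geometry
#'
#' Geometries mirror the five stress classes seen in platinum-treated
#' cells: `no_stress` places 1--2 spots in the nucleoplasm adjacent to (but
#' clear of) the nucleolar boundary, reproducing the 1--2 Cajal bodies near
#' nucleoli typical of control cells; `nucleolar_capping` puts 2--4 spot
#' centres on a 1-px half-width annulus at the nucleolar boundary;
#' `nucleolar_localization` 1--3 spots strictly inside the nucleolus;
#' `nucleoplasmic_diffusion` no spots (the red nucleoplasm level is raised
#' to `(nucleoplasm + spot_peak) / 2` at render time); `cb_dispersion`
#' 4--8 spots uniformly over the nucleoplasm with radii from the lower half
#' of the configured range. Spot centres keep `radius + 6` px clearance
#' from the nucleus boundary and a `>= spot_min_gap_px` edge-to-edge gap
#' (centre separation `r_i + r_j + spot_min_gap_px`).
#'
#' Draws from the current RNG stream; [generate_scene()] wraps all calls in
#' a seeded stream.
#'
#' @param label one of [phenotype_levels].
#' @param nucleus_geometry list: `centroid_r`, `centroid_c`, `a`, `b`,
#'   `theta` (semi-axes px, orientation rad).
#' @param nucleolus_geometry list: `centroid_r`, `centroid_c`, `radius_px`.
#' @param config a [scene_config()].
#' @return data.frame: `centroid_r`, `centroid_c`, `radius_px`,
#'   `peak_intensity` (one row per spot; empty for diffusion).
#' @export
render_phenotype <- function(label, nucleus_geometry, nucleolus_geometry,
                             config) {
  if (!label %in% phenotype_levels)
    stopf("unknown phenotype label '%s'", label)
  if (config$nucleolus_radius_fraction > 0.6)
    stopf("nucleolus_radius_fraction > 0.6: geometry unsatisfiable")
  empty <- data.frame(centroid_r = numeric(), centroid_c = numeric(),
                      radius_px = numeric(), peak_intensity = numeric())
  if (label == "nucleoplasmic_diffusion") return(empty)
  ng <- nucleus_geometry; no <- nucleolus_geometry
  rng <- config$spots_per_cell[[label]]
  n_spots <- if (rng[1] == rng[2]) rng[1] else
    sample(rng[1]:rng[2], 1L)
  if (n_spots == 0L) return(empty)
  rad_range <- config$spot_radius_px
  if (label == "cb_dispersion")
    rad_range <- c(rad_range[1], mean(rad_range))
  peak0 <- config$intensity_levels$red[["spot_peak"]]
  placed <- empty
  for (i in seq_len(n_spots)) {
    r_spot <- stats::runif(1, rad_range[1], rad_range[2])
    if (label == "nucleolar_localization")
      r_spot <- min(r_spot, max(1.5, no$radius_px - 4))
    ok <- FALSE
    for (try in 1:200) {
      if (label == "no_stress") {
        d <- no$radius_px + stats::runif(1, 5, 10)
        phi <- stats::runif(1, 0, 2 * pi)
        rr <- no$centroid_r + d * sin(phi)
        cc <- no$centroid_c + d * cos(phi)
      } else if (label == "nucleolar_capping") {
        d <- no$radius_px + stats::runif(1, -1, 1)
        phi <- stats::runif(1, 0, 2 * pi)
        rr <- no$centroid_r + d * sin(phi)
        cc <- no$centroid_c + d * cos(phi)
      } else if (label == "nucleolar_localization") {
        dmax <- max(0.5, no$radius_px - r_spot - 3)
        d <- stats::runif(1, 0, dmax)
        phi <- stats::runif(1, 0, 2 * pi)
        rr <- no$centroid_r + d * sin(phi)
        cc <- no$centroid_c + d * cos(phi)
      } else { # cb_dispersion: uniform over the nucleus disc
        phi <- stats::runif(1, 0, 2 * pi)
        d <- sqrt(stats::runif(1)) * max(ng$a, ng$b)
        rr <- ng$centroid_r + d * sin(phi)
        cc <- ng$centroid_c + d * cos(phi)
      }
      if (!inside_ellipse(rr - ng$centroid_r, cc - ng$centroid_c,
                          ng$a, ng$b, ng$theta, margin = r_spot + 6))
        next
      if (nrow(placed) &&
          any(sqrt((placed$centroid_r - rr)^2 + (placed$centroid_c - cc)^2) <
                placed$radius_px + r_spot + config$spot_min_gap_px))
        next
      ok <- TRUE
      break
    }
    if (!ok) next  # geometry saturated: place as many as fit
    placed <- rbind(placed, data.frame(
      centroid_r = rr, centroid_c = cc, radius_px = r_spot,
      peak_intensity = peak0 * stats::runif(1, 0.95, 1.05)))
  }
  placed
}

#' Apply optical and photon degradation to a rendered image
#'
#' Gaussian PSF blur, then Poisson photon resampling (if
#' `noise_poisson_scale > 0`), then additive Gaussian read noise, clipped
#' to `[0, 1]`. Deterministic given the RNG state; pass `seed` to run in an
#' isolated seeded stream.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param psf_sigma_px blur width (0 = none).
#' @param noise_gaussian_sd additive noise sd (0 = none).
#' @param noise_poisson_scale photons per unit intensity (0 = none).
#' @param seed optional integer; when given, noise is drawn under
#'   [withr::with_seed()].
#' @return degraded numeric matrix in `[0, 1]`.
#' @export
degrade <- function(image, psf_sigma_px = 0, noise_gaussian_sd = 0,
                    noise_poisson_scale = 0, seed = NULL) {
  assert_image(image)
  if (psf_sigma_px < 0 || noise_gaussian_sd < 0 || noise_poisson_scale < 0)
    stopf("degradation parameters must be non-negative")
  run <- function() {
    out <- gaussian_blur(image, psf_sigma_px)
    if (noise_poisson_scale > 0)
      out <- matrix(stats::rpois(length(out),
                                 pmax(out, 0) * noise_poisson_scale) /
                      noise_poisson_scale, nrow(out))
    if (noise_gaussian_sd > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, noise_gaussian_sd),
                          nrow(out))
    clip01(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

draw_ellipse <- function(canvas, r0, c0, a, b, theta, value) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  rmax <- max(a, b)
  rs <- max(1L, floor(r0 + 1 - rmax)):min(nr, ceiling(r0 + 1 + rmax))
  cs <- max(1L, floor(c0 + 1 - rmax)):min(nc, ceiling(c0 + 1 + rmax))
  dr <- outer(rs - 1 - r0, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - 1 - c0)
  m <- inside_ellipse(as.vector(dr), as.vector(dc), a, b, theta)
  sub <- canvas[rs, cs, drop = FALSE]
  sub[matrix(m, length(rs))] <- value
  canvas[rs, cs] <- sub
  canvas
}

draw_disk_max <- function(canvas, r0, c0, radius, value) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  rs <- max(1L, floor(r0 + 1 - radius)):min(nr, ceiling(r0 + 1 + radius))
  cs <- max(1L, floor(c0 + 1 - radius)):min(nc, ceiling(c0 + 1 + radius))
  dr <- outer(rs - 1 - r0, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - 1 - c0)
  m <- matrix(dr^2 + dc^2 <= radius^2, length(rs))
  sub <- canvas[rs, cs, drop = FALSE]
  sub[m] <- pmax(sub[m], value)
  canvas[rs, cs] <- sub
  canvas
}

#' Generate a synthetic fluorescence scene with full ground truth
#'
#' Places non-overlapping elliptical nuclei by rejection sampling (erroring
#' with a "scene too crowded" message when placement fails), draws one
#' nucleolus per nucleus, assigns each nucleus a phenotype from
#' `phenotype_mix`, places spots per [render_phenotype()], renders the
#' three channels, and degrades them per [degrade()]. Regenerating with the
#' same `(config, seed)` yields a bit-identical stack.
#'
#' @param config a [scene_config()].
#' @param seed integer seed controlling every stochastic step.
#' @return list of class `synthetic_scene`: `stack` ([channel_stack()]),
#'   `truth` (list of data.frames `nuclei`, `spots`, `nucleoli`),
#'   `seed`, `config`.
#' @export
generate_scene <- function(config = scene_config(), seed = 1L) {
  errs <- validate_scene_config(config)
  if (length(errs))
    stopf("invalid scene config:\n%s", paste("-", errs, collapse = "\n"))
  withr::with_seed(seed, generate_scene_impl(config, seed))
}

generate_scene_impl <- function(config, seed) {
  H <- config$image_height_px; W <- config$image_width_px
  nuclei <- data.frame()
  attempts <- 0L; max_attempts <- 300L * max(1L, config$n_nuclei)
  while (nrow(nuclei) < config$n_nuclei) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stopf("scene too crowded: placed %d of %d nuclei in a %dx%d image",
            nrow(nuclei), config$n_nuclei, H, W)
    r <- stats::runif(1, config$nucleus_radius_px[1],
                      config$nucleus_radius_px[2])
    s <- stats::runif(1, 0, config$nucleus_eccentricity)
    a <- r * (1 + s); b <- r * (1 - s)
    theta <- stats::runif(1, 0, pi)
    rmax <- max(a, b)
    if (2 * (rmax + 4) >= min(H, W)) next
    r0 <- stats::runif(1, rmax + 4, H - 1 - rmax - 4)
    c0 <- stats::runif(1, rmax + 4, W - 1 - rmax - 4)
    if (nrow(nuclei)) {
      d <- sqrt((nuclei$centroid_r - r0)^2 + (nuclei$centroid_c - c0)^2)
      # boundary-to-boundary gap >= 6 px so closing cannot bridge contours
      if (any(d < pmax(nuclei$semi_major, nuclei$semi_minor) + rmax + 6))
        next
    }
    nuclei <- rbind(nuclei, data.frame(
      nucleus_id = nrow(nuclei) + 1L, centroid_r = r0, centroid_c = c0,
      radius_px = sqrt(a * b), semi_major = a, semi_minor = b,
      theta = theta,
      phenotype = sample(phenotype_levels, 1L,
                         prob = config$phenotype_mix[phenotype_levels])))
  }

  nucleoli <- data.frame()
  spots <- data.frame()
  if (nrow(nuclei)) {
    for (i in seq_len(nrow(nuclei))) {
      nu <- nuclei[i, ]
      rn <- config$nucleolus_radius_fraction * nu$radius_px
      dmax <- max(0, nu$semi_minor - rn - 3)
      d <- stats::runif(1, 0, min(dmax, 0.35 * nu$semi_minor))
      phi <- stats::runif(1, 0, 2 * pi)
      no <- data.frame(nucleus_id = nu$nucleus_id,
                       centroid_r = nu$centroid_r + d * sin(phi),
                       centroid_c = nu$centroid_c + d * cos(phi),
                       radius_px = rn)
      nucleoli <- rbind(nucleoli, no)
      sp <- render_phenotype(
        nu$phenotype,
        list(centroid_r = nu$centroid_r, centroid_c = nu$centroid_c,
             a = nu$semi_major, b = nu$semi_minor, theta = nu$theta),
        list(centroid_r = no$centroid_r, centroid_c = no$centroid_c,
             radius_px = rn),
        config)
      if (nrow(sp)) {
        sp$nucleus_id <- nu$nucleus_id
        sp$channel_role <- "red"
        spots <- rbind(spots, sp)
      }
    }
  }
  if (nrow(spots)) {
    spots$spot_id <- seq_len(nrow(spots))
    spots <- spots[, c("spot_id", "nucleus_id", "channel_role",
                       "centroid_r", "centroid_c", "radius_px",
                       "peak_intensity")]
  } else {
    spots <- data.frame(spot_id = integer(), nucleus_id = integer(),
                        channel_role = character(), centroid_r = numeric(),
                        centroid_c = numeric(), radius_px = numeric(),
                        peak_intensity = numeric())
  }

  lv <- config$intensity_levels
  channels <- lapply(lv, function(l) matrix(l[["background"]], H, W))
  for (i in seq_len(nrow(nuclei))) {
    nu <- nuclei[i, ]
    no <- nucleoli[i, ]
    diffuse <- nu$phenotype == "nucleoplasmic_diffusion"
    for (role in names(channels)) {
      np <- lv[[role]][["nucleoplasm"]]
      nl <- lv[[role]][["nucleolus"]]
      if (role == "red" && diffuse) {
        np <- (lv$red[["nucleoplasm"]] + lv$red[["spot_peak"]]) / 2
        nl <- np  # diffuse signal fills the whole nucleus
      }
      channels[[role]] <- draw_ellipse(channels[[role]], nu$centroid_r,
                                       nu$centroid_c, nu$semi_major,
                                       nu$semi_minor, nu$theta, np)
      channels[[role]] <- draw_ellipse(channels[[role]], no$centroid_r,
                                       no$centroid_c, no$radius_px,
                                       no$radius_px, 0, nl)
    }
  }
  for (j in seq_len(nrow(spots))) {
    sp <- spots[j, ]
    channels$red <- draw_disk_max(channels$red, sp$centroid_r,
                                  sp$centroid_c, sp$radius_px,
                                  sp$peak_intensity)
  }
  channels <- lapply(channels, function(ch)
    degrade(ch, config$psf_sigma_px, config$noise_gaussian_sd,
            config$noise_poisson_scale))

  structure(list(
    stack = channel_stack(channels, bit_depth = config$bit_depth),
    truth = list(nuclei = nuclei, spots = spots, nucleoli = nucleoli),
    seed = seed, config = config), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %dx%d px, %d nuclei, %d spots, seed %d\n",
              x$stack$height_px, x$stack$width_px, nrow(x$truth$nuclei),
              nrow(x$truth$spots), x$seed))
  invisible(x)
}

#' Write a scene's images and ground truth to disk
#'
#' Writes per-channel images (16-bit TIFF or 8-bit PNG per the configured
#' bit depth), the nuclei and spot ground-truth tables as CSV, and the
#' resolved configuration (with the seed) as a YAML file.
#'
#' @param scene a `synthetic_scene`.
#' @param outdir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, outdir, prefix = "scene") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (scene$config$bit_depth == 16L) "tif" else "png"
  paths <- c()
  for (role in names(scene$stack$channels)) {
    p <- file.path(outdir, sprintf("%s_%s.%s", prefix, role, ext))
    write_channel(scene$stack$channels[[role]], p)
    paths[role] <- p
  }
  paths["nuclei"] <- write_table(scene$truth$nuclei,
                                 file.path(outdir, paste0(prefix, "_nuclei.csv")))
  paths["spots"] <- write_table(scene$truth$spots,
                                file.path(outdir, paste0(prefix, "_spots.csv")))
  cfg <- scene$config
  cfg$phenotype_mix <- as.list(cfg$phenotype_mix)
  cfg$intensity_levels <- lapply(cfg$intensity_levels, as.list)
  yaml::write_yaml(c(list(seed = scene$seed), unclass(cfg)),
                   file.path(outdir, paste0(prefix, "_config.yaml")))
  paths["config"] <- file.path(outdir, paste0(prefix, "_config.yaml"))
  invisible(paths)
}
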