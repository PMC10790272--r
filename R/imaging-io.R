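#' Multi-channel fluorescence image stack
#'
#' A `channel_stack` bundles named 2D intensity channels sharing one pixel
#' grid. Channels are stored as numeric matrices normalized to `[0, 1]`
#' (intensities divided by `2^bit_depth - 1`). The `dapi` role (nuclear
#' counterstain) must be present, since all segmentation starts from it;
#' `red` and `green` carry immunostain signal (e.g. Coilin / NPM).
#'
#' @param channels named list of numeric matrices with identical dimensions;
#'   names must be drawn from `c("dapi", "red", "green")` and must include
#'   `"dapi"`.
#' @param bit_depth integer, 8 or 16: the acquisition bit depth the
#'   normalized values originated from.
#' @return An object of class `channel_stack`: a list with elements
#'   `channels`, `height_px`, `width_px`, `source_bit_depth`.
#' @export
channel_stack <- function(channels, bit_depth = 8L) {
  if (!is.list(channels) || is.null(names(channels)))
    stopf("channels must be a named list of matrices")
  bad <- setdiff(names(channels), c("dapi", "red", "green"))
  if (length(bad))
    stopf("unknown channel role(s): %s", paste(bad, collapse = ", "))
  if (!"dapi" %in% names(channels))
    stopf("missing required channel role 'dapi'")
  if (!bit_depth %in% c(8L, 16L))
    stopf("unsupported bit depth %s (must be 8 or 16)", bit_depth)
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stopf("channel dimension mismatch: %s",
          paste(vapply(dims, function(d) paste(d, collapse = "x"),
                       character(1)), collapse = " vs "))
  for (nm in names(channels)) {
    assert_image(channels[[nm]], nm)
    if (min(channels[[nm]]) < -1e-9 || max(channels[[nm]]) > 1 + 1e-9)
      stopf("channel '%s' not normalized to [0,1]", nm)
  }
  structure(
    list(channels = channels,
         height_px = nrow(channels[[1L]]),
         width_px = ncol(channels[[1L]]),
         source_bit_depth = as.integer(bit_depth)),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %d x %d px, %d-bit source, roles: %s\n",
              x$height_px, x$width_px, x$source_bit_depth,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

read_one_channel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, payload = FALSE)
    if (is.data.frame(info)) info <- as.list(info[1L, ])
    bits <- as.integer(info$bits.per.sample)
    if (!bits %in% c(8L, 16L))
      stopf("unsupported bit depth %d in %s (must be 8 or 16)", bits, path)
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
    list(img = raw / (2^bits - 1), bits = bits)
  } else if (ext == "png") {
    # png::readPNG already divides by the depth maximum
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
    list(img = raw, bits = 8L)
  } else {
    stopf("unsupported image format '%s' (TIFF or PNG expected)", ext)
  }
}

#' Read a multi-channel stack from per-channel image files
#'
#' Reads one single-plane grayscale 8- or 16-bit TIFF or PNG per channel and
#' normalizes intensities into `[0, 1]` by dividing by `2^bit_depth - 1`
#' (an 8-bit image with maximum pixel 255 maps to 1.0).
#'
#' @param paths named character vector of file paths; names are channel
#'   roles (`dapi`, `red`, `green`); the `dapi` role is required.
#' @return A [channel_stack()].
#' @export
read_stack <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stopf("paths must be a named vector (names = channel roles)")
  if (!"dapi" %in% names(paths))
    stopf("missing required channel role 'dapi'")
  reads <- lapply(paths, read_one_channel)
  channel_stack(lapply(reads, `[[`, "img"),
                bit_depth = max(vapply(reads, `[[`, integer(1), "bits")))
}

#' Write one normalized channel to disk
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path; `.tif`/`.tiff` writes 16-bit TIFF, `.png`
#'   writes 8-bit PNG.
#' @return `path`, invisibly.
#' @export
write_channel <- function(image, path) {
  assert_image(image)
  ext <- tolower(tools::file_ext(path))
  img <- clip01(image)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stopf("unsupported image format '%s'", ext)
  invisible(path)
}

#' Convert a normalized image to 8-bit integers
#'
#' Maps `[0, 1]` to the 0--255 dynamic range by rounding
#' `image * 255`, the convention used when high-bit-depth acquisitions are
#' rescaled to 8 bit for analysis.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @return integer matrix in 0..255.
#' @export
to_8bit <- function(image) {
  assert_image(image)
  m <- matrix(as.integer(round(clip01(image) * 255)), nrow(image))
  m
}

#' Write / read an integer label map as 16-bit TIFF
#'
#' Round-trips losslessly for label counts up to 65535; larger counts are
#' rejected rather than silently truncated.
#'
#' @param labelmap integer matrix, 0 = background.
#' @param path file path (TIFF).
#' @return `write_labels`: `path` invisibly; `read_labels`: integer matrix.
#' @export
write_labels <- function(labelmap, path) {
  if (!is.matrix(labelmap) || anyNA(labelmap) || any(labelmap < 0) ||
      any(labelmap != round(labelmap)))
    stopf("labelmap must be a matrix of non-negative integers")
  if (max(labelmap) > 65535L)
    stopf("label count %d exceeds 16-bit capacity (65535)", max(labelmap))
  tiff::writeTIFF(labelmap / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  matrix(as.integer(round(raw)), nrow(raw))
}

#' Write a record table as CSV
#'
#' Fixed column order as supplied; header row always present; missing values
#' written as empty cells (RFC-4180).
#'
#' @param records data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stopf("records must be a data.frame")
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
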