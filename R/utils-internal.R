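# Internal image primitives shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", name)
  if (anyNA(x)) stopf("%s contains NA/NaN pixels", name)
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Reflected (mirror, half-sample symmetric) index into 1..n for any integer i.
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

pad_mirror <- function(x, r) {
  if (r == 0L) return(x)
  ri <- mirror_index(seq(1L - r, nrow(x) + r), nrow(x))
  ci <- mirror_index(seq(1L - r, ncol(x) + r), ncol(x))
  x[ri, ci, drop = FALSE]
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Linear filtering with mirrored boundaries: pad, FFT-convolve, crop.
filter_mirror <- function(x, kernel) {
  r <- (dim(kernel)[1L] - 1L) %/% 2L
  p <- pad_mirror(x, r)
  y <- EBImage::filter2(p, kernel, boundary = "circular")
  nr <- nrow(x); nc <- ncol(x)
  as.matrix(y)[(r + 1L):(r + nr), (r + 1L):(r + nc), drop = FALSE]
}

gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k1 <- gaussian_kernel_1d(sigma)
  filter_mirror(x, outer(k1, k1))
}

shift_mat <- function(x, dr, dc, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  y <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  y[rs, cs] <- x[rs - dr, cs - dc]
  y
}

# Otsu threshold on a numeric vector (histogram with `levels` bins).
# EBImage::otsu operates on whole images only, so the subset version used for
# in-nucleus thresholds is computed here.
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(NA_real_)
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-12) return(lo)
  br <- seq(lo, hi, length.out = levels + 1L)
  h <- as.numeric(tabulate(findInterval(v, br, rightmost.closed = TRUE),
                           nbins = levels))
  mids <- (br[-1L] + br[-(levels + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot <- w[levels]; mtot <- mu[levels]
  wb <- w[-levels]; wf <- tot - wb
  ok <- wb > 0 & wf > 0
  bc <- rep(-Inf, levels - 1L)
  bc[ok] <- (mtot * wb[ok] / tot - mu[-levels][ok])^2 / (wb[ok] * wf[ok] / tot)
  mids[which.max(bc)]
}

# 8-connected component labelling; labels 1..K in raster (row-major) order of
# each component's first pixel. EBImage::bwlabel is 4-connected.
label8 <- function(binary) {
  binary <- binary > 0
  nr <- nrow(binary); nc <- ncol(binary)
  idx <- which(binary)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(out)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nb <- shift_mat(id, d[1L], d[2L], fill = 0L)
    both <- which(binary & nb > 0L)
    if (length(both))
      edges <- rbind(edges, cbind(id[both], nb[both]))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(), 0, 2) else edges,
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # relabel by raster order of first occurrence (row-major: order by row then col)
  rc <- arrayInd(idx, c(nr, nc))
  ord <- order(rc[, 1L], rc[, 2L])
  first_seen <- memb[ord][!duplicated(memb[ord])]
  relab <- integer(max(memb))
  relab[first_seen] <- seq_along(first_seen)
  out[idx] <- relab[memb]
  out
}

disc_brush <- function(radius) {
  if (radius <= 0) return(NULL)
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

binary_closing <- function(x, radius) {
  if (radius <= 0) return(x)
  as.matrix(EBImage::closing(x, disc_brush(radius)))
}

binary_opening <- function(x, radius) {
  if (radius <= 0) return(x)
  as.matrix(EBImage::opening(x, disc_brush(radius)))
}

binary_erode <- function(x, radius) {
  if (radius <= 0) return(x)
  as.matrix(EBImage::erode(x, disc_brush(radius)))
}

binary_dilate <- function(x, radius) {
  if (radius <= 0) return(x)
  as.matrix(EBImage::dilate(x, disc_brush(radius)))
}

fill_holes <- function(x) as.matrix(EBImage::fillHull(x))

# Remove foreground pixels with no 8-neighbour in the foreground.
remove_isolated_pixels <- function(x) {
  nb <- filter_mirror(x * 1, matrix(1, 3, 3)) - x
  x & (nb > 0.5)
}

# Per-label areas as named integer vector (names = label ids).
label_areas <- function(labelmap) {
  if (max(labelmap) == 0L) return(integer(0))
  tab <- tabulate(labelmap[labelmap > 0L])
  stats::setNames(tab, seq_along(tab))[tab > 0L]
}

# 0-based (row, col) centroids per label: matrix with columns r, c.
label_centroids <- function(labelmap) {
  idx <- which(labelmap > 0L)
  labs <- labelmap[idx]
  rc <- arrayInd(idx, dim(labelmap))
  r <- tapply(rc[, 1L] - 1, labs, mean)
  c <- tapply(rc[, 2L] - 1, labs, mean)
  cbind(r = as.numeric(r), c = as.numeric(c),
        label = as.integer(names(r)))
}
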