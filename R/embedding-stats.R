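#' Standardize a feature matrix for embedding
#'
#' Column-wise z-score using the population standard deviation; constant
#' columns map to 0; missing values are imputed to the column median before
#' scaling, with an imputation log attached as the `"imputations"`
#' attribute (data.frame: `column`, `n_imputed`).
#'
#' @param x numeric matrix (n >= 2 rows) or data.frame of numeric columns.
#' @return standardized numeric matrix.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("feature matrix must be numeric")
  if (nrow(x) < 2L) stopf("need at least 2 rows")
  log <- data.frame(column = character(), n_imputed = integer())
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (all(miss))
      stopf("column '%s' is entirely missing",
            colnames(x)[j] %||% as.character(j))
    if (any(miss)) {
      x[miss, j] <- stats::median(x[!miss, j])
      log <- rbind(log, data.frame(
        column = colnames(x)[j] %||% as.character(j),
        n_imputed = sum(miss)))
    }
  }
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  z <- sweep(x, 2L, mu)
  nz <- sd_pop > 1e-12
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, sd_pop[nz], "/")
  z[, !nz] <- 0
  attr(z, "imputations") <- log
  z
}

#' Mahalanobis pairwise distances
#'
#' `d(x, y) = sqrt((x - y)' (S + eps I)^{-1} (x - y))` with `S` the sample
#' covariance of the rows of `x`. With `epsilon = 0` and singular `S` an
#' error instructs the caller to regularize; the default regularizer is
#' `1e-3 * trace(S) / p`.
#'
#' @param x numeric matrix (observations in rows).
#' @param epsilon ridge added to the covariance diagonal; `NULL` uses the
#'   default.
#' @return `n x n` matrix of distances.
#' @export
mahalanobis_dist <- function(x, epsilon = NULL) {
  x <- as.matrix(x)
  S <- stats::cov(x)
  p <- ncol(x)
  if (is.null(epsilon)) epsilon <- 1e-3 * sum(diag(S)) / p
  Sr <- S + diag(epsilon, p)
  R <- tryCatch(chol(solve(Sr)), error = function(e) NULL)
  if (is.null(R))
    stopf(paste("feature covariance is singular; pass a positive epsilon",
                "(default 1e-3 * trace(S) / p)"))
  w <- x %*% t(R)
  as.matrix(stats::dist(w))
}

entropy_beta <- function(d2_row, beta) {
  p <- exp(-d2_row * beta)
  s <- sum(p)
  if (s < 1e-300) return(list(H = 0, p = rep(0, length(p))))
  H <- log(s) + beta * sum(d2_row * p) / s
  list(H = H, p = p / s)
}

perplexity_calibration <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    beta <- 1; bmin <- -Inf; bmax <- Inf
    for (it in 1:60) {
      eb <- entropy_beta(d2, beta)
      diff <- eb$H - target
      if (abs(diff) < 1e-5) break
      if (diff > 0) { bmin <- beta
        beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2
      } else { bmax <- beta
        beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2
      }
    }
    P[i, -i] <- eb$p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Seeded t-SNE embedding with Mahalanobis metric
#'
#' Exact (non-approximated) t-SNE of the rows of a standardized feature
#' matrix. Pairwise input distances are Mahalanobis (covariance-whitened,
#' ridge-regularized; see [mahalanobis_dist()]), or Euclidean on request.
#' The embedding is initialized from a seeded RNG and the gradient descent
#' is deterministic, so identical inputs and seed reproduce coordinates
#' bit-identically.
#'
#' @param x numeric matrix (n rows; `n > 3 * perplexity` required),
#'   standardized (see [standardize_features()]).
#' @param seed integer RNG seed for the initialization.
#' @param perplexity effective neighbourhood size (default 30).
#' @param epsilon covariance ridge; `NULL` = `1e-3 * trace(S) / p`.
#' @param metric `"mahalanobis"` (default) or `"euclidean"`.
#' @param max_iter,learning_rate,early_exaggeration,exaggeration_iter
#'   gradient-descent controls (standard values).
#' @return object of class `tsne_embedding`: list with `coordinates`
#'   (n x 2), `seed`, `perplexity`, `metric`, `epsilon`, `feature_names`.
#' @export
tsne_embed <- function(x, seed, perplexity = 30, epsilon = NULL,
                       metric = c("mahalanobis", "euclidean"),
                       max_iter = 1000L, learning_rate = 200,
                       early_exaggeration = 12, exaggeration_iter = 250L) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= 3 * perplexity)
    stopf("n (%d) must exceed 3 * perplexity (%g)", n, 3 * perplexity)
  D <- if (metric == "mahalanobis") mahalanobis_dist(x, epsilon)
       else as.matrix(stats::dist(x))
  P <- perplexity_calibration(D^2, perplexity)
  Y <- withr::with_seed(seed, matrix(stats::rnorm(n * 2L, sd = 1e-4), n))
  G <- matrix(0, n, 2L)      # update (momentum) term
  gains <- matrix(1, n, 2L)
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= exaggeration_iter) P * early_exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(0.01,
                  ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8))
    G <- momentum * G - learning_rate * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
    if (iter == exaggeration_iter) momentum <- 0.8
  }
  structure(list(coordinates = Y, seed = seed, perplexity = perplexity,
                 metric = metric,
                 epsilon = epsilon %||% NA_real_,
                 feature_names = colnames(x)),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("<tsne_embedding> %d cells, metric %s, perplexity %g, seed %d\n",
              nrow(x$coordinates), x$metric, x$perplexity, x$seed))
  invisible(x)
}

#' Unpaired two-sample t-test (Welch by default)
#'
#' Welch's unequal-variance statistic with Welch--Satterthwaite degrees of
#' freedom and a two-sided p-value; `pooled = TRUE` gives the classical
#' equal-variance test. Groups in which *both* samples are constant are
#' rejected (zero variance).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance statistic.
#' @return list: `t`, `df`, `p_value`, `mean_a`, `mean_b`, `method`.
#' @export
welch_ttest <- function(a, b, pooled = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs n >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stopf("non-finite values in input")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stopf("zero variance in both groups: t statistic undefined")
  ht <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
       method = if (pooled) "pooled" else "welch")
}

#' Pairwise condition comparisons of one per-cell quantity
#'
#' Welch tests for every pair of conditions; optional Holm correction
#' (off by default: per-comparison p-values are reported).
#'
#' @param values numeric vector of the per-cell quantity.
#' @param condition parallel condition keys.
#' @param adjust `"none"` or `"holm"`.
#' @param pooled passed to [welch_ttest()].
#' @return data.frame: `group_a`, `group_b`, `t`, `df`, `p_value`,
#'   `p_adjusted`, `mean_a`, `mean_b`.
#' @export
compare_conditions <- function(values, condition, adjust = c("none", "holm"),
                               pooled = FALSE) {
  adjust <- match.arg(adjust)
  groups <- split(values, condition)
  if (length(groups) < 2L) stopf("need at least 2 conditions")
  nm <- names(groups)
  pairs <- utils::combn(nm, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    w <- welch_ttest(groups[[pairs[1L, k]]], groups[[pairs[2L, k]]],
                     pooled = pooled)
    data.frame(group_a = pairs[1L, k], group_b = pairs[2L, k],
               t = w$t, df = w$df, p_value = w$p_value,
               mean_a = w$mean_a, mean_b = w$mean_b)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust == "holm") stats::p.adjust(out$p_value, "holm")
                    else out$p_value
  out
}

#' Export a violin plot of per-cell values by condition
#'
#' Writes the figure (PNG/SVG by extension) and, alongside, the underlying
#' per-cell values as a two-column CSV (`condition`, `value`) so the figure
#' can be regenerated. Degenerate single-value groups are drawn as points.
#'
#' @param values numeric vector.
#' @param condition parallel condition keys.
#' @param path_figure output figure path.
#' @param path_csv output CSV path (default: figure path with `.csv`).
#' @param value_name axis label.
#' @return invisible list with `figure` and `csv` paths.
#' @export
violin_export <- function(values, condition, path_figure,
                          path_csv = NULL,
                          value_name = "value") {
  if (length(values) == 0L) stopf("empty input")
  if (any(table(condition) == 0L)) stopf("empty group")
  df <- data.frame(condition = as.character(condition), value = values)
  path_csv <- path_csv %||% paste0(tools::file_path_sans_ext(path_figure),
                                   ".csv")
  utils::write.csv(df, path_csv, row.names = FALSE)
  multi <- names(which(table(df$condition) > 1L))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = condition, y = value)) +
    ggplot2::geom_violin(data = df[df$condition %in% multi, , drop = FALSE],
                         scale = "width", fill = "grey80") +
    ggplot2::stat_summary(fun = stats::median, geom = "point", size = 1.5) +
    ggplot2::labs(x = NULL, y = value_name) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path_figure, p, width = 6, height = 4, dpi = 150)
  invisible(list(figure = path_figure, csv = path_csv))
}
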