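# Independent oracles used by the numerical tests. These deliberately avoid
# the package's internal helpers: reflection is done by iterative folding and
# the convolution is a direct nested sum.

reflect_idx_oracle <- function(i, n) {
  while (any(i < 1 | i > n)) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
  }
  i
}

gaussian_blur_oracle <- function(img, sigma) {
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r:r))^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    ri <- reflect_idx_oracle(i + (-r:r), nrow(img))
    for (j in seq_len(ncol(img))) {
      ci <- reflect_idx_oracle(j + (-r:r), ncol(img))
      out[i, j] <- sum(img[ri, ci] * k2)
    }
  }
  out
}

dog_oracle <- function(img, s1, s2) {
  gaussian_blur_oracle(img, s1) - gaussian_blur_oracle(img, s2)
}

# exhaustive permutation p-value for the absolute Welch statistic
perm_pvalue_oracle <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  tstat <- function(x, y)
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  tobs <- abs(tstat(a, b))
  cmb <- utils::combn(length(pool), na)
  perm <- apply(cmb, 2, function(ix) abs(tstat(pool[ix], pool[-ix])))
  mean(perm >= tobs - 1e-12)
}
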