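# Independent oracles used to cross-check the package implementations.

# exhaustive per-box scan: count eps x eps boxes containing any TRUE pixel
oracle_box_count <- function(mask, eps) {
  h <- nrow(mask)
  w <- ncol(mask)
  n <- 0L
  for (r0 in seq(1L, h, by = eps)) {
    for (c0 in seq(1L, w, by = eps)) {
      block <- mask[r0:min(r0 + eps - 1L, h), c0:min(c0 + eps - 1L, w), drop = FALSE]
      if (any(block)) n <- n + 1L
    }
  }
  n
}

# brute-force Moran's I via the explicit O(N^2) double sum over a dense W
oracle_morans_i <- function(values, scheme = "rook", row_standardized = TRUE) {
  nr <- nrow(values)
  nc <- ncol(values)
  n <- nr * nc
  coord <- cbind(rep(seq_len(nr), times = nc), rep(seq_len(nc), each = nr))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dr <- abs(coord[i, 1] - coord[j, 1])
      dc <- abs(coord[i, 2] - coord[j, 2])
      neigh <- if (scheme == "rook") dr + dc == 1 else max(dr, dc) == 1
      if (neigh) w[i, j] <- 1
    }
  }
  if (row_standardized) w <- w / rowSums(w)
  x <- as.vector(values)
  z <- x - mean(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + w[i, j] * z[i] * z[j]
  (n / sum(w)) * s / sum(z^2)
}

# random logical mask with at least one TRUE pixel
random_mask <- function(h, w, p = 0.3) {
  m <- matrix(stats::runif(h * w) < p, h, w)
  if (!any(m)) m[sample(h * w, 1L)] <- TRUE
  m
}

# adjusted Rand index (mclust is available in the test environment)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
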