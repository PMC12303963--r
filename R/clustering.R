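#' Ward clustering of landscape factor scores
#'
#' Agglomerative hierarchical clustering of images by Ward's minimum
#' variance criterion on squared Euclidean distances between their factor
#' score profiles. The number of clusters is either fixed (default 8) or
#' chosen to maximize the mean silhouette width over `k = 2..10`.
#'
#' @param image_scores Numeric matrix `images x factors` (rownames = image
#'   ids), typically from [image_factor_scores()].
#' @param k Number of clusters, or `"auto"` for silhouette-based selection.
#' @param k_range Candidate `k` values searched when `k = "auto"`.
#' @return Object of class `cluster_solution`: list with `assignments`
#'   (named integer vector), `k`, `merge_heights` (non-decreasing),
#'   `mean_silhouette` (NA for `k = 1`), `profile` (per-cluster mean factor
#'   scores), `hclust` (the tree).
#' @export
ward_cluster <- function(image_scores, k = 8L, k_range = 2:10) {
  x <- as.matrix(image_scores)
  if (any(!is.finite(x))) stop("factor scores must be finite")
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("img", seq_len(n))
  d2 <- stats::dist(x)^2
  hc <- stats::hclust(d2, method = "ward.D")

  pick <- function(kk) {
    if (kk > n) stop("k = ", kk, " exceeds the number of images (", n, ")")
    stats::cutree(hc, k = kk)
  }
  if (identical(k, "auto")) {
    k_range <- k_range[k_range >= 2 & k_range <= n - 1]
    if (length(k_range) == 0L) stop("no feasible k in k_range for ", n, " images")
    sil <- vapply(k_range, function(kk) mean_silhouette(pick(kk), d2), numeric(1))
    k <- k_range[which.max(sil)]
  }
  k <- as.integer(k)
  assignments <- pick(k)
  msil <- if (k >= 2L) mean_silhouette(assignments, d2) else NA_real_

  profile <- rowsum(x, assignments) / as.vector(table(assignments))
  rownames(profile) <- paste0("type", rownames(profile))

  structure(
    list(assignments = assignments, k = k, merge_heights = hc$height,
         mean_silhouette = msil, profile = profile, hclust = hc),
    class = "cluster_solution"
  )
}

# mean silhouette width of a partition under a dissimilarity
mean_silhouette <- function(assignments, d) {
  if (length(unique(assignments)) < 2L) return(NA_real_)
  mean(cluster::silhouette(assignments, d)[, "sil_width"])
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d images in %d clusters (mean silhouette %.3f)\n",
              length(x$assignments), x$k, x$mean_silhouette))
  print(table(x$assignments))
  invisible(x)
}
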