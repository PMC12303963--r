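#' Simulate per-image healing ratings with planted consensus
#'
#' Emulates a preliminary rating study: a panel of raters scores each image
#' on the 7-point healing scale, with each image planted either as a
#' strong-consensus healing view (high mean, low spread) or a weaker view.
#' Ratings are drawn from a normal with the planted mean and spread,
#' rounded and clamped to 1..7. Default planted profiles: pass images have
#' mean in 5.5--6.5 and sd in 0.4--0.9; fail images mean 3.0--4.6 and sd
#' 0.5--1.0; the pass fraction 42/150 mirrors a 150-candidate shoot from
#' which 42 views survive selection.
#'
#' @param n_images Number of candidate images. Default 150.
#' @param n_raters Panel size. Default 23.
#' @param pass_fraction Fraction of images planted above the selection
#'   thresholds. Default `42/150`.
#' @param pass_mean_range,pass_sd_range,fail_mean_range,fail_sd_range
#'   Uniform ranges of the planted parameters.
#' @param seed Integer seed.
#' @return List with `ratings` (named list of integer vectors, one per
#'   image) and `planted` (data frame `image_id`, `planted_mean`,
#'   `planted_sd`, `planted_pass`).
#' @export
gen_healing_ratings <- function(n_images = 150L, n_raters = 23L,
                                pass_fraction = 42 / 150,
                                pass_mean_range = c(5.5, 6.5),
                                pass_sd_range = c(0.4, 0.9),
                                fail_mean_range = c(3.0, 4.6),
                                fail_sd_range = c(0.5, 1.0),
                                seed = 1L) {
  stopifnot(n_images >= 1L, n_raters >= 2L, pass_fraction >= 0, pass_fraction <= 1)
  with_local_seed(seed, {
    n_pass <- round(pass_fraction * n_images)
    pass <- sample(c(rep(TRUE, n_pass), rep(FALSE, n_images - n_pass)))
    mu <- ifelse(pass,
                 stats::runif(n_images, pass_mean_range[1L], pass_mean_range[2L]),
                 stats::runif(n_images, fail_mean_range[1L], fail_mean_range[2L]))
    sigma <- ifelse(pass,
                    stats::runif(n_images, pass_sd_range[1L], pass_sd_range[2L]),
                    stats::runif(n_images, fail_sd_range[1L], fail_sd_range[2L]))
    ids <- sprintf("img%03d", seq_len(n_images))
    ratings <- lapply(seq_len(n_images), function(i) {
      as.integer(pmin(7, pmax(1, round(stats::rnorm(n_raters, mu[i], sigma[i])))))
    })
    names(ratings) <- ids
    list(ratings = ratings,
         planted = data.frame(image_id = ids, planted_mean = mu,
                              planted_sd = sigma, planted_pass = pass,
                              stringsAsFactors = FALSE))
  })
}

#' Default planted loading matrix for semantic-differential simulation
#'
#' A simple-structure loading matrix: `n_items` items split evenly over `k`
#' factors, each item loading `loading` on its own factor and 0 elsewhere.
#'
#' @param n_items Number of items. Default 24.
#' @param k Number of factors. Default 6.
#' @param loading Primary loading. Default 0.7.
#' @return `n_items x k` matrix with item rownames from [sd_item_pairs()]
#'   when `n_items` is 24.
#' @export
default_sd_loadings <- function(n_items = 24L, k = 6L, loading = 0.7) {
  stopifnot(n_items >= k, k >= 1L, abs(loading) <= 1)
  lambda <- matrix(0, n_items, k)
  per <- ceiling(n_items / k)
  for (i in seq_len(n_items)) {
    lambda[i, ((i - 1L) %/% per) + 1L] <- loading
  }
  rownames(lambda) <- if (n_items == 24L) sd_item_pairs() else paste0("item", seq_len(n_items))
  colnames(lambda) <- paste0("Factor", seq_len(k))
  lambda
}

#' Simulate a semantic-differential rating matrix with planted factors
#'
#' Each image gets a latent factor-score vector (standard normal); each
#' participant-image response on each item is `F . lambda + noise`,
#' discretized to the 5-point scale by fixed cut points. Defaults mirror a
#' 58-participant, 42-image, 24-item design.
#'
#' @param n_participants,n_images Design dimensions. Defaults 58 and 42.
#' @param loadings Planted `items x k` loading matrix; default
#'   [default_sd_loadings()].
#' @param noise_sd Residual standard deviation per item; default
#'   `sqrt(1 - rowSums(loadings^2))` so the latent continuum is
#'   standardized.
#' @param cut_points Increasing thresholds mapping the latent value to
#'   scores 1..5. Default `c(-1.5, -0.5, 0.5, 1.5)`.
#' @param seed Integer seed.
#' @return List with `ratings` (array `participants x items x images`,
#'   values 1..5, dimnames set), `loadings` (the planted matrix),
#'   `factor_scores` (planted `images x k` matrix).
#' @export
gen_sd_ratings <- function(n_participants = 58L, n_images = 42L,
                           loadings = default_sd_loadings(),
                           noise_sd = NULL,
                           cut_points = c(-1.5, -0.5, 0.5, 1.5),
                           seed = 1L) {
  lambda <- as.matrix(loadings)
  n_items <- nrow(lambda)
  k <- ncol(lambda)
  if (is.null(noise_sd)) noise_sd <- sqrt(pmax(1 - rowSums(lambda^2), 0))
  noise_sd <- rep_len(noise_sd, n_items)
  stopifnot(all(diff(cut_points) > 0))

  with_local_seed(seed, {
    f <- matrix(stats::rnorm(n_images * k), n_images, k)
    ids <- sprintf("img%03d", seq_len(n_images))
    item_names <- rownames(lambda)
    if (is.null(item_names)) item_names <- paste0("item", seq_len(n_items))
    arr <- array(0L, dim = c(n_participants, n_items, n_images),
                 dimnames = list(sprintf("p%02d", seq_len(n_participants)),
                                 item_names, ids))
    signal <- tcrossprod(f, lambda)  # images x items
    for (img in seq_len(n_images)) {
      latent <- matrix(signal[img, ], n_participants, n_items, byrow = TRUE) +
        matrix(stats::rnorm(n_participants * n_items), n_participants, n_items) *
          matrix(noise_sd, n_participants, n_items, byrow = TRUE)
      arr[, , img] <- findInterval(latent, cut_points) + 1L
    }
    rownames(f) <- ids
    colnames(f) <- colnames(lambda)
    list(ratings = arr, loadings = lambda, factor_scores = f)
  })
}

#' Simulate a joint metrics-and-factor-score dataset with planted correlations
#'
#' Draws image-level rows from a multivariate normal whose correlation
#' matrix plants chosen correlations between the 18 color-metric columns
#' and the factor-score columns, emulating the input of the metric-factor
#' correlation table with known truth.
#'
#' @param n_images Number of image rows. Default 42.
#' @param target_corr Positive semi-definite correlation matrix over
#'   `metric_names` then `factor_names` (in that order); default identity
#'   (no planted association).
#' @param metric_names,factor_names Column names; defaults: the 18
#'   color-metric names (`brown_D`, `brown_H`, ... per [metrics_wide()])
#'   and `Factor1..Factor6`.
#' @param seed Integer seed.
#' @return List with `metrics` (data frame: `image_id` + metric columns)
#'   and `scores` (matrix `images x factors` with image rownames).
#' @export
gen_joint_dataset <- function(n_images = 42L, target_corr = NULL,
                              metric_names = default_metric_names(),
                              factor_names = paste0("Factor", 1:6),
                              seed = 1L) {
  p <- length(metric_names) + length(factor_names)
  if (is.null(target_corr)) target_corr <- diag(p)
  stopifnot(is.matrix(target_corr), nrow(target_corr) == p, ncol(target_corr) == p)
  if (max(abs(target_corr - t(target_corr))) > 1e-10) {
    stop("target correlation matrix must be symmetric")
  }
  e <- eigen(target_corr, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("target correlation matrix is not positive semi-definite")
  root <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)

  with_local_seed(seed, {
    z <- matrix(stats::rnorm(n_images * p), n_images, p)
    x <- z %*% root
    colnames(x) <- c(metric_names, factor_names)
    ids <- sprintf("img%03d", seq_len(n_images))
    metrics <- data.frame(image_id = ids,
                          x[, metric_names, drop = FALSE],
                          stringsAsFactors = FALSE, check.names = FALSE)
    scores <- x[, factor_names, drop = FALSE]
    rownames(scores) <- ids
    list(metrics = metrics, scores = scores)
  })
}

#' Default 18 color-metric column names
#'
#' @return Character vector: `D`, `H`, `C` for each of the six palette
#'   colors, in palette order.
#' @export
default_metric_names <- function() {
  colors <- default_palette()$name
  as.vector(t(outer(colors, c("D", "H", "C"), paste, sep = "_")))
}

#' Build a joint target correlation matrix from a cross-correlation block
#'
#' Convenience constructor for [gen_joint_dataset()]: identity within the
#' metric block and within the factor block, with the supplied
#' metric-by-factor cross-correlations.
#'
#' @param cross Numeric `n_metrics x n_factors` matrix of planted
#'   correlations.
#' @return A `(n_metrics + n_factors)` square correlation matrix (validated
#'   positive semi-definite by the generator).
#' @export
joint_target_corr <- function(cross) {
  cross <- as.matrix(cross)
  nm <- nrow(cross)
  nf <- ncol(cross)
  rbind(cbind(diag(nm), cross),
        cbind(t(cross), diag(nf)))
}
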