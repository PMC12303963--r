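#' Default box-counting scale ladder
#'
#' Twelve box sizes in geometric progression, 1, 2, 4, ..., 2048 pixels.
#' Sizes exceeding the shorter image side are dropped automatically by
#' [box_count()] callers via `clip_scales()`.
#'
#' @return Integer vector of box side lengths.
#' @export
default_box_scales <- function() as.integer(2^(0:11))

#' Clip a scale ladder to a mask's dimensions
#'
#' @param scales Integer vector of box sizes.
#' @param dims Length-2 integer `(H, W)`.
#' @return The scales not exceeding `min(dims)` (at least the smallest scale).
#' @export
clip_scales <- function(scales, dims) {
  keep <- scales <= min(dims)
  if (!any(keep)) keep[which.min(scales)] <- TRUE
  sort(unique(as.integer(scales[keep])))
}

#' Box counting of a binary mask
#'
#' For each box size `eps`, overlays a grid of `eps x eps` boxes anchored at
#' the top-left corner (partial boxes at the right and bottom edges count)
#' and counts the boxes containing at least one `TRUE` pixel.
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @param scales Positive integer box sizes; defaults to the dyadic ladder
#'   clipped to the mask.
#' @return An object of class `box_count_curve`: data frame with columns
#'   `epsilon` (increasing) and `n_boxes` (non-increasing), plus a
#'   `mask_size` attribute.
#' @export
box_count <- function(mask, scales = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("undefined metric: box counting needs a nonempty mask")
  dims <- dim(mask)
  if (is.null(scales)) scales <- clip_scales(default_box_scales(), dims)
  scales <- as.integer(scales)
  if (any(scales < 1L)) stop("box sizes must be positive integers")
  scales <- sort(unique(scales))

  idx <- which(mask, arr.ind = TRUE)
  n_boxes <- vapply(scales, function(eps) {
    br <- (idx[, 1L] - 1L) %/% eps
    bc <- (idx[, 2L] - 1L) %/% eps
    ncols <- (dims[2L] + eps - 1L) %/% eps
    length(unique(br * ncols + bc))
  }, numeric(1))

  out <- data.frame(epsilon = scales, n_boxes = n_boxes)
  attr(out, "mask_size") <- dims
  class(out) <- c("box_count_curve", "data.frame")
  out
}

#' Box-counting fractal dimension from a count curve
#'
#' Ordinary least squares of `log N(eps)` against `log(1/eps)`; the slope is
#' the dimension estimate `D`. Trailing scales where the count has saturated
#' at `N = 1` are trimmed beyond the first such scale, since they only
#' flatten the slope.
#'
#' @param curve A `box_count_curve` from [box_count()].
#' @return Object of class `fractal_fit`: list with `dimension`, `intercept`,
#'   `r_squared`, `scales_used`.
#' @examples
#' m <- matrix(TRUE, 64, 64)
#' fractal_dimension(box_count(m))$dimension  # ~2
#' @export
fractal_dimension <- function(curve) {
  stopifnot(inherits(curve, "box_count_curve"))
  eps <- curve$epsilon
  n <- curve$n_boxes

  # trim trailing N == 1 saturation beyond the first occurrence
  sat <- rev(cumprod(rev(n == 1))) == 1
  if (sum(sat) > 1L) {
    first_sat <- which(sat)[1L]
    keep <- seq_len(first_sat)
    eps <- eps[keep]
    n <- n[keep]
  }

  if (length(eps) < 3L) {
    stop("insufficient scales: need at least 3 usable box sizes, got ", length(eps))
  }
  if (length(unique(n)) == 1L) {
    stop("insufficient scales: box counts are constant across all scales")
  }

  x <- log(1 / eps)
  y <- log(n)
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(
    list(
      dimension = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = r2,
      scales_used = length(eps)
    ),
    class = "fractal_fit"
  )
}

#' Box-counting dimension of a mask in one step
#'
#' @param mask Logical matrix.
#' @param scales Optional scale ladder; defaults as in [box_count()].
#' @return A `fractal_fit`.
#' @export
box_dimension <- function(mask, scales = NULL) {
  fractal_dimension(box_count(mask, scales))
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> D = %.4f (R^2 = %.4f, %d scales)\n",
              x$dimension, x$r_squared, x$scales_used))
  invisible(x)
}
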