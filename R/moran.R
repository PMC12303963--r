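#' Coarsen a binary mask to a presence lattice
#'
#' Reduces an `H x W` mask to a `rows x cols` lattice whose cell values are
#' the block-mean presence of the color (fraction of `TRUE` pixels per
#' block, block edges by integer splitting). The lattice is the spatial unit
#' grid on which the Moran's I concentration index is computed; block means
#' generalize per-pixel binary presence to `[0, 1]` so the statistic is
#' tractable on megapixel images.
#'
#' @param mask Logical matrix.
#' @param lattice Length-2 integer `(rows, cols)`, each >= 2 and no larger
#'   than the mask dimensions.
#' @param weights_scheme `"rook"` (edge-sharing neighbors, default) or
#'   `"queen"` (edges + diagonals).
#' @param row_standardized Should each cell's neighbor weights sum to 1?
#'   Default `TRUE`.
#' @return Object of class `presence_lattice`: list with `values`
#'   (`rows x cols` numeric in `[0, 1]`), `weights_scheme`,
#'   `row_standardized`.
#' @export
coarsen_mask <- function(mask, lattice = c(100L, 100L),
                         weights_scheme = c("rook", "queen"),
                         row_standardized = TRUE) {
  stopifnot(is.matrix(mask), is.logical(mask))
  weights_scheme <- match.arg(weights_scheme)
  lattice <- as.integer(lattice)
  if (length(lattice) != 2L || any(lattice < 2L)) {
    stop("lattice must be at least 2 x 2")
  }
  if (any(lattice > dim(mask))) {
    stop("lattice (", lattice[1L], "x", lattice[2L],
         ") larger than the mask (", dim(mask)[1L], "x", dim(mask)[2L], ")")
  }
  values <- block_sums(mask, lattice) / block_areas(dim(mask), lattice)
  presence_lattice(values, weights_scheme, row_standardized)
}

#' Construct a presence lattice directly from values
#'
#' @param values Numeric matrix with entries in `[0, 1]`, at least 2 x 2.
#' @inheritParams coarsen_mask
#' @return A `presence_lattice`.
#' @export
presence_lattice <- function(values, weights_scheme = c("rook", "queen"),
                             row_standardized = TRUE) {
  weights_scheme <- match.arg(weights_scheme)
  stopifnot(is.matrix(values), is.numeric(values))
  if (length(values) < 4L || any(dim(values) < 2L)) stop("lattice must be at least 2 x 2")
  if (any(!is.finite(values)) || any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop("lattice values must lie in [0, 1]")
  }
  structure(
    list(values = values, weights_scheme = weights_scheme,
         row_standardized = row_standardized),
    class = "presence_lattice"
  )
}

#' Moran's I spatial autocorrelation on a lattice
#'
#' The concentration index
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with contiguity weights on the lattice grid. Values near +1 indicate the
#' color's presence is clustered into compact patches; values near -1
#' indicate dispersed, alternating placement (a checkerboard attains -1
#' under row-standardized rook weights); values near 0 indicate spatial
#' randomness.
#'
#' @param lattice A `presence_lattice` (from [coarsen_mask()] or
#'   [presence_lattice()]); its values must not all be equal.
#' @return Moran's I (scalar).
#' @examples
#' cb <- presence_lattice(outer(1:4, 1:4, function(i, j) (i + j) %% 2))
#' morans_i(cb)  # -1
#' @export
morans_i <- function(lattice) {
  stopifnot(inherits(lattice, "presence_lattice"))
  x <- lattice$values
  if (stats::var(as.vector(x)) == 0) {
    stop("degenerate input: lattice values are constant, Moran's I undefined")
  }
  z <- x - mean(x)
  nr <- nrow(z)
  nc <- ncol(z)

  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offsets <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (lattice$weights_scheme == "queen") {
    offsets <- c(offsets, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }

  nbr_sum <- matrix(0, nr, nc)   # sum of neighbor deviations per cell
  deg <- matrix(0, nr, nc)       # number of neighbors per cell
  for (off in offsets) {
    nbr_sum <- nbr_sum + shift(z, off[1L], off[2L])
    deg <- deg + shift(matrix(1, nr, nc), off[1L], off[2L])
  }

  n <- nr * nc
  if (lattice$row_standardized) {
    s <- sum(z * nbr_sum / deg)  # w_ij = 1/deg_i
    w_total <- n                 # each row of W sums to 1
  } else {
    s <- sum(z * nbr_sum)        # w_ij = 1 for neighbors
    w_total <- sum(deg)
  }
  (n / w_total) * s / sum(z^2)
}
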