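#' Shannon-Wiener diversity of color composition
#'
#' `H' = -sum(p_i log p_i)` over the color categories, with `0 log 0 = 0`.
#' `H'` is zero when a single category holds all classified area and reaches
#' its maximum `log(n)` when the categories are equally represented.
#'
#' @param proportions Nonnegative numeric vector summing to 1 (within 1e-9),
#'   e.g. from [composition_proportions()].
#' @return The diversity index, in `[0, log(length(proportions))]`.
#' @examples
#' global_diversity(c(0.5, 0.25, 0.25, 0, 0, 0))
#' @export
global_diversity <- function(proportions) {
  if (!is.numeric(proportions) || length(proportions) < 1L) {
    stop("proportions must be a numeric vector")
  }
  if (any(!is.finite(proportions)) || any(proportions < 0)) {
    stop("proportions must be finite and nonnegative")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", format(sum(proportions)), ")")
  }
  p <- proportions[proportions > 0]
  -sum(p * log(p))
}

#' Spatial evenness of one color across image blocks
#'
#' Partitions the mask into a `g_rows x g_cols` grid of blocks (block edges
#' by integer splitting), computes the share `p_b` of the color's pixels in
#' each block, and returns the Shannon entropy `-sum(p_b log p_b)`. With
#' `normalized = TRUE` the entropy is divided by `log(g_rows * g_cols)` so
#' the result lies in `[0, 1]`: 0 when the color is confined to one block, 1
#' when it is spread evenly over all blocks.
#'
#' This is the package's per-color spatial diversity convention, pairing a
#' color's evenness of placement with its fractal complexity and clustering.
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @param grid Length-2 integer `(g_rows, g_cols)`; product must be >= 2.
#' @param normalized Divide by the maximum entropy? Default `TRUE`.
#' @return Nonnegative scalar.
#' @export
per_color_spatial_diversity <- function(mask, grid = c(8L, 8L), normalized = TRUE) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("undefined metric: spatial diversity needs a nonempty mask")
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L) || prod(grid) < 2L) {
    stop("grid must give at least 2 blocks")
  }
  if (any(grid > dim(mask))) {
    stop("grid finer than the mask (", grid[1L], "x", grid[2L],
         " blocks on a ", dim(mask)[1L], "x", dim(mask)[2L], " mask)")
  }
  counts <- block_sums(mask, grid)
  p <- counts / sum(counts)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (normalized) h <- h / log(prod(grid))
  h
}

# per-block sums of a numeric/logical matrix, blocks by integer splitting:
# row r (1-based) belongs to block floor((r - 1) * g / H) + 1
block_sums <- function(m, grid) {
  ri <- ((seq_len(nrow(m)) - 1L) * grid[1L]) %/% nrow(m) + 1L
  ci <- ((seq_len(ncol(m)) - 1L) * grid[2L]) %/% ncol(m) + 1L
  rowsum_rows <- rowsum(m + 0, ri)
  out <- t(rowsum(t(rowsum_rows), ci))
  dimnames(out) <- NULL
  out
}

# per-block pixel counts (block areas) for the same splitting
block_areas <- function(dims, grid) {
  ri <- ((seq_len(dims[1L]) - 1L) * grid[1L]) %/% dims[1L] + 1L
  ci <- ((seq_len(dims[2L]) - 1L) * grid[2L]) %/% dims[2L] + 1L
  outer(tabulate(ri, grid[1L]), tabulate(ci, grid[2L]))
}
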