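#' Generate a deterministic binary test mask
#'
#' Rasterizes one of a family of patterns with known spatial structure,
#' used to validate the color metrics against analytic ground truth. For
#' iterated-function-system fractals the analytic similarity dimension is
#' attached as the `analytic_dimension` attribute:
#' Sierpinski carpet `log 8 / log 3`, Sierpinski triangle `log 3 / log 2`,
#' Cantor dust `log 4 / log 3`, Vicsek cross `log 5 / log 3`.
#'
#' @param kind One of `"sierpinski_carpet"`, `"sierpinski_triangle"`,
#'   `"cantor_dust"`, `"vicsek"`, `"filled"`, `"hline"`, `"checkerboard"`,
#'   `"disc_cluster"`.
#' @param size Length-2 `(H, W)` for non-IFS kinds. IFS kinds are square
#'   with side `base^depth`; when `size` is supplied it must agree.
#' @param depth Recursion depth for IFS kinds. Default 5.
#' @param cell Checkerboard cell side in pixels. Default 1.
#' @param n_discs,radius,disc_layout Disc-cluster parameters: number of
#'   discs, disc radius in pixels, and `"single"` (one compact disc at the
#'   center) or `"scattered"` (seeded random centers).
#' @param seed Integer seed for the randomized kinds. Default 1.
#' @return Logical matrix; IFS/filled/hline kinds carry an
#'   `analytic_dimension` attribute.
#' @examples
#' m <- gen_mask("sierpinski_carpet", depth = 3)
#' sum(m)  # 8^3
#' @export
gen_mask <- function(kind = c("sierpinski_carpet", "sierpinski_triangle",
                              "cantor_dust", "vicsek", "filled", "hline",
                              "checkerboard", "disc_cluster"),
                     size = NULL, depth = 5L, cell = 1L,
                     n_discs = 1L, radius = 8L,
                     disc_layout = c("single", "scattered"), seed = 1L) {
  kind <- match.arg(kind)
  disc_layout <- match.arg(disc_layout)

  ifs <- list(
    sierpinski_carpet = list(base = 3L, pattern = matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3),
                             dim = log(8) / log(3)),
    sierpinski_triangle = list(base = 2L, pattern = matrix(c(1, 1, 0, 1), 2, 2),
                               dim = log(3) / log(2)),
    cantor_dust = list(base = 3L, pattern = matrix(c(1, 0, 1, 0, 0, 0, 1, 0, 1), 3, 3),
                       dim = log(4) / log(3)),
    vicsek = list(base = 3L, pattern = matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3),
                  dim = log(5) / log(3))
  )

  if (kind %in% names(ifs)) {
    spec <- ifs[[kind]]
    depth <- as.integer(depth)
    if (depth < 1L) stop("depth must be >= 1")
    side <- spec$base^depth
    if (!is.null(size) && !all(size == side)) {
      stop(kind, " at depth ", depth, " is ", side, "x", side,
           "; requested size is incompatible")
    }
    m <- Reduce(function(acc, i) kronecker(acc, spec$pattern),
                seq_len(depth - 1L), spec$pattern)
    m <- m > 0
    attr(m, "analytic_dimension") <- spec$dim
    return(m)
  }

  if (is.null(size)) size <- c(128L, 128L)
  size <- as.integer(size)
  stopifnot(length(size) == 2L, all(size >= 1L))
  h <- size[1L]
  w <- size[2L]

  switch(kind,
    filled = {
      m <- matrix(TRUE, h, w)
      attr(m, "analytic_dimension") <- 2
      m
    },
    hline = {
      m <- matrix(FALSE, h, w)
      m[max(1L, h %/% 2L), ] <- TRUE
      attr(m, "analytic_dimension") <- 1
      m
    },
    checkerboard = {
      cell <- as.integer(cell)
      stopifnot(cell >= 1L)
      outer(seq_len(h), seq_len(w),
            function(i, j) ((i - 1L) %/% cell + (j - 1L) %/% cell) %% 2L == 0L)
    },
    disc_cluster = {
      m <- matrix(FALSE, h, w)
      centers <- if (disc_layout == "single" || n_discs == 1L) {
        matrix(c(h / 2, w / 2), 1L, 2L)
      } else {
        with_local_seed(seed, cbind(stats::runif(n_discs, 1, h),
                                    stats::runif(n_discs, 1, w)))
      }
      rows <- row(m)
      cols <- col(m)
      for (i in seq_len(nrow(centers))) {
        m <- m | ((rows - centers[i, 1L])^2 + (cols - centers[i, 2L])^2 <= radius^2)
      }
      m
    }
  )
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
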