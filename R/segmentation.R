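#' Segment an RGB image into per-category binary color masks
#'
#' Classifies each pixel against the palette's inclusive RGB ranges. In
#' `non_exclusive` mode a pixel belongs to every category whose three channel
#' ranges all contain it (the palette ranges overlap, so masks may too). In
#' `exclusive` mode each pixel is assigned to at most one category: the first
#' match in `precedence` order, so the masks partition the classified pixels.
#'
#' Pixels matching no category are unclassified; they are excluded from the
#' composition denominator rather than treated as a seventh category, and
#' their fraction is reported per image. Composition proportions are always
#' computed from the exclusive assignment so they sum to one.
#'
#' @param img An `rgb_image` (see [load_image()]) or an `H x W x 3` array.
#' @param palette A [color_palette()]; defaults to [default_palette()].
#' @param mode `"non_exclusive"` (default) or `"exclusive"`.
#' @param precedence Character vector ordering the palette names for
#'   exclusive assignment; defaults to [default_precedence()] for the default
#'   palette, palette order otherwise.
#' @return An object of class `color_mask_set`: a list with elements
#'   `masks` (named list of `H x W` logical matrices), `mode`, `precedence`,
#'   `unclassified_fraction`, and `proportions` (named numeric summing to 1
#'   when any pixel is classified, all zero otherwise).
#' @examples
#' img <- as_rgb_image(array(c(150, 60, 40) [c(1, 1, 2, 2, 3, 3)] / 255,
#'                           dim = c(1, 2, 3)))
#' seg <- segment_image(img)
#' seg$proportions["red"]
#' @export
segment_image <- function(img, palette = default_palette(),
                          mode = c("non_exclusive", "exclusive"),
                          precedence = NULL) {
  mode <- match.arg(mode)
  img <- if (inherits(img, "rgb_image")) unclass(img) else as_rgb_image(img)
  stopifnot(inherits(palette, "color_palette"))
  if (is.null(precedence)) {
    precedence <- if (setequal(palette$name, default_precedence())) {
      default_precedence()
    } else {
      palette$name
    }
  }
  if (!setequal(precedence, palette$name)) {
    stop("precedence must be a permutation of the palette names")
  }

  h <- dim(img)[1L]
  w <- dim(img)[2L]
  r <- matrix(img[, , 1L], h, w)
  g <- matrix(img[, , 2L], h, w)
  b <- matrix(img[, , 3L], h, w)

  in_range <- lapply(seq_len(nrow(palette)), function(i) {
    p <- palette[i, ]
    r >= p$r_lo & r <= p$r_hi &
      g >= p$g_lo & g <= p$g_hi &
      b >= p$b_lo & b <= p$b_hi
  })
  names(in_range) <- palette$name

  # exclusive assignment: first match in precedence order
  taken <- matrix(FALSE, h, w)
  excl <- vector("list", length(precedence))
  names(excl) <- precedence
  for (nm in precedence) {
    excl[[nm]] <- in_range[[nm]] & !taken
    taken <- taken | excl[[nm]]
  }
  excl <- excl[palette$name]

  n_classified <- sum(taken)
  counts <- vapply(excl, sum, numeric(1))
  proportions <- if (n_classified > 0L) counts / n_classified else counts * 0
  unclassified_fraction <- 1 - n_classified / (h * w)

  masks <- if (mode == "exclusive") excl else in_range
  structure(
    list(
      masks = masks,
      mode = mode,
      precedence = precedence,
      unclassified_fraction = unclassified_fraction,
      proportions = proportions
    ),
    class = "color_mask_set"
  )
}

#' Area proportions of the classified pixels
#'
#' Returns `p_i`, the fraction of classified pixels assigned to each color
#' category under exclusive assignment. These are the proportions consumed by
#' the composition diversity index [global_diversity()].
#'
#' @param maskset A `color_mask_set` from [segment_image()].
#' @return Named numeric vector summing to 1.
#' @export
composition_proportions <- function(maskset) {
  stopifnot(inherits(maskset, "color_mask_set"))
  if (all(maskset$proportions == 0)) {
    stop("degenerate input: no pixel was classified into any color category")
  }
  maskset$proportions
}

#' @export
print.color_mask_set <- function(x, ...) {
  d <- dim(x$masks[[1L]])
  cat(sprintf("<color_mask_set> %d x %d, mode = %s\n", d[1L], d[2L], x$mode))
  cat(sprintf("  unclassified fraction: %.4f\n", x$unclassified_fraction))
  cat("  proportions:", paste(sprintf("%s = %.3f", names(x$proportions), x$proportions),
                              collapse = ", "), "\n")
  invisible(x)
}
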