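#' Collision-free RGB sampling boxes for the default palette
#'
#' The default palette's ranges overlap (e.g. part of gray lies inside
#' brown), so a synthetic image meant to have unambiguous ground truth must
#' draw each color's pixels from a sub-box of its range that intersects no
#' other category's range. These sub-boxes were derived by hand from the
#' palette and are re-verified against it at every call: each box must lie
#' inside its own category's ranges and be channel-disjoint from every
#' other category's.
#'
#' @return Named list of 2x3 matrices (`lo`/`hi` rows, R/G/B columns), one
#'   per color, plus a `background` box matching no category.
#' @export
safe_color_boxes <- function() {
  box <- function(r, g, b) {
    m <- rbind(lo = c(r[1], g[1], b[1]), hi = c(r[2], g[2], b[2]))
    colnames(m) <- c("r", "g", "b")
    m
  }
  boxes <- list(
    red = box(c(131, 208), c(8, 90), c(2, 37)),
    yellow = box(c(185, 228), c(156, 194), c(116, 133)),
    brown = box(c(83, 122), c(79, 187), c(114, 194)),
    gray = box(c(174, 183), c(105, 184), c(134, 184)),
    white = box(c(212, 255), c(212, 255), c(212, 255)),
    green = box(c(76, 130), c(93, 199), c(38, 53)),
    background = box(c(0, 60), c(0, 60), c(0, 60))
  )
  verify_safe_boxes(boxes, default_palette())
  boxes
}

# assert each box sits inside its own category and avoids all others
verify_safe_boxes <- function(boxes, palette) {
  rng <- function(cat, ch) {
    p <- palette[palette$name == cat, ]
    c(p[[paste0(ch, "_lo")]], p[[paste0(ch, "_hi")]])
  }
  disjoint <- function(a, b) a[2] < b[1] || b[2] < a[1]
  for (nm in names(boxes)) {
    b <- boxes[[nm]]
    for (cat in palette$name) {
      inside <- all(vapply(c("r", "g", "b"), function(ch) {
        r <- rng(cat, ch)
        b["lo", ch] >= r[1] && b["hi", ch] <= r[2]
      }, logical(1)))
      avoids <- any(vapply(c("r", "g", "b"), function(ch) {
        disjoint(c(b["lo", ch], b["hi", ch]), rng(cat, ch))
      }, logical(1)))
      if (nm == cat && !inside) {
        stop("safe box for '", nm, "' leaves its own category range")
      }
      if (nm != cat && !avoids) {
        stop("safe box for '", nm, "' collides with category '", cat, "'")
      }
    }
  }
  invisible(TRUE)
}

# draw n RGB triples uniformly (integer channels) from a safe box
sample_box_colors <- function(box, n) {
  out <- matrix(0L, n, 3L, dimnames = list(NULL, c("r", "g", "b")))
  for (ch in c("r", "g", "b")) {
    out[, ch] <- sample(box["lo", ch]:box["hi", ch], n, replace = TRUE)
  }
  out
}

#' Paint ground-truth color masks into an RGB image
#'
#' Each mask's `TRUE` pixels are filled with values drawn from that color's
#' collision-free sampling box ([safe_color_boxes()]); remaining pixels get
#' background values matching no category. Exclusive segmentation of the
#' result recovers the masks exactly, under any precedence order.
#'
#' @param masks Named list of equal-size logical matrices; names must be
#'   palette colors; masks must be pairwise disjoint.
#' @param seed Integer seed for pixel-value sampling.
#' @return An `rgb_image`.
#' @export
gen_image_from_masks <- function(masks, seed = 1L) {
  stopifnot(is.list(masks), length(masks) >= 1L, !is.null(names(masks)))
  boxes <- safe_color_boxes()
  bad <- setdiff(names(masks), setdiff(names(boxes), "background"))
  if (length(bad)) stop("unknown color(s): ", paste(bad, collapse = ", "))
  dims <- dim(masks[[1L]])
  overlap <- Reduce(`+`, lapply(masks, function(m) m + 0L))
  if (any(overlap > 1L)) stop("masks must be pairwise disjoint")

  with_local_seed(seed, {
    npix <- prod(dims)
    img <- array(0L, dim = c(dims, 3L))
    bg <- sample_box_colors(boxes$background, npix)
    for (ch in 1:3) img[, , ch] <- matrix(bg[, ch], dims[1L], dims[2L])
    for (nm in names(masks)) {
      idx <- which(masks[[nm]])
      if (length(idx) == 0L) next
      vals <- sample_box_colors(boxes[[nm]], length(idx))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- vals[, ch]
        img[, , ch] <- plane
      }
    }
    as_rgb_image(img)
  })
}

#' Generate a synthetic landscape image with known color composition
#'
#' Emulates a garden photograph at the level the color metrics consume:
#' regions of the six palette colors with controllable area fractions and
#' spatial arrangement, painted with collision-free pixel values so the
#' planted per-color masks are recovered exactly by exclusive segmentation.
#'
#' Layouts: `"blocks"` fills row-major runs of exactly
#' `round(fraction * H * W)` pixels per color (exact compositions);
#' `"blobs"` grows each color from seeded random discs (compact patches,
#' compositions approximate -- the achieved masks are returned);
#' `"fractal_per_color"` places a Sierpinski-carpet pattern for each color
#' in its own vertical strip (high spatial complexity; fractions control
#' strip widths).
#'
#' @param composition Named numeric vector of target area fractions
#'   (names = palette colors); must sum to at most 1. The remainder is
#'   out-of-range background.
#' @param layout `"blocks"`, `"blobs"`, or `"fractal_per_color"`.
#' @param size Length-2 `(H, W)`. Default `c(128, 128)`.
#' @param seed Integer seed.
#' @return List with `image` (an `rgb_image`), `masks` (named list of
#'   planted logical masks), `composition` (achieved fractions of total
#'   image area).
#' @examples
#' out <- gen_landscape_image(c(green = 0.5, red = 0.5), "blocks",
#'                            size = c(32, 32), seed = 7)
#' out$composition
#' @export
gen_landscape_image <- function(composition,
                                layout = c("blocks", "blobs", "fractal_per_color"),
                                size = c(128L, 128L), seed = 1L) {
  layout <- match.arg(layout)
  size <- as.integer(size)
  stopifnot(length(size) == 2L, all(size >= 1L))
  if (is.null(names(composition)) || any(composition < 0)) {
    stop("composition must be a named vector of nonnegative fractions")
  }
  if (sum(composition) > 1 + 1e-9) stop("composition fractions must sum to at most 1")
  colors <- names(composition)
  h <- size[1L]
  w <- size[2L]
  npix <- h * w

  masks <- switch(layout,
    blocks = {
      counts <- round(composition * npix)
      if (sum(counts) > npix) stop("requested fractions unattainable at this size")
      m <- list()
      start <- 0L
      ord <- matrix(seq_len(npix), h, w, byrow = TRUE)  # row-major pixel order
      for (i in seq_along(colors)) {
        mk <- matrix(FALSE, h, w)
        if (counts[i] > 0L) mk[ord > start & ord <= start + counts[i]] <- TRUE
        m[[colors[i]]] <- mk
        start <- start + counts[i]
      }
      m
    },
    blobs = with_local_seed(seed + 1L, {
      assigned <- matrix(FALSE, h, w)
      rows <- row(assigned)
      cols <- col(assigned)
      m <- list()
      for (i in seq_along(colors)) {
        target <- round(composition[i] * npix)
        mk <- matrix(FALSE, h, w)
        attempts <- 0L
        while (sum(mk) < target && attempts < 200L) {
          attempts <- attempts + 1L
          r <- max(2, round(sqrt(max(target - sum(mk), 1) / pi) / 1.5))
          cr <- stats::runif(1, 1, h)
          cc <- stats::runif(1, 1, w)
          disc <- (rows - cr)^2 + (cols - cc)^2 <= r^2
          mk <- mk | (disc & !assigned)
          assigned <- assigned | mk
        }
        # trim overshoot in raster order so the target count is not exceeded
        excess <- sum(mk) - target
        if (excess > 0L) {
          drop_idx <- utils::tail(which(mk), excess)
          mk[drop_idx] <- FALSE
          assigned[drop_idx] <- FALSE
        }
        m[[colors[i]]] <- mk
      }
      m
    }),
    fractal_per_color = {
      share <- composition / sum(composition)
      edges <- round(cumsum(c(0, share)) * w)
      m <- list()
      for (i in seq_along(colors)) {
        mk <- matrix(FALSE, h, w)
        c0 <- edges[i] + 1L
        c1 <- edges[i + 1L]
        if (c1 >= c0) {
          strip_w <- c1 - c0 + 1L
          d <- max(1L, floor(log(min(h, strip_w)) / log(3)))
          pat <- gen_mask("sierpinski_carpet", depth = d)
          side <- nrow(pat)
          # tile the carpet over the strip
          reps_r <- ceiling(h / side)
          reps_c <- ceiling(strip_w / side)
          tiled <- do.call(rbind, rep(list(do.call(cbind, rep(list(pat), reps_c))), reps_r))
          mk[, c0:c1] <- tiled[seq_len(h), seq_len(strip_w)]
        }
        m[[colors[i]]] <- mk
      }
      m
    }
  )

  img <- gen_image_from_masks(masks, seed = seed)
  achieved <- vapply(masks, function(mk) sum(mk) / npix, numeric(1))
  list(image = img, masks = masks, composition = achieved)
}
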