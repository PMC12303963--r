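#' Construct a color palette of RGB range rules
#'
#' A palette is an ordered set of named color categories, each defined by
#' inclusive per-channel bounds on 8-bit RGB values. A pixel belongs to a
#' category when all three of its channel values fall inside that category's
#' ranges.
#'
#' @param entries A data frame with columns `name`, `r_lo`, `r_hi`, `g_lo`,
#'   `g_hi`, `b_lo`, `b_hi`. Bounds are inclusive integers in 0--255.
#' @return An object of class `color_palette` (a validated data frame).
#' @seealso [default_palette()] for the six-category garden palette.
#' @export
color_palette <- function(entries) {
  stopifnot(is.data.frame(entries))
  required <- c("name", "r_lo", "r_hi", "g_lo", "g_hi", "b_lo", "b_hi")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0L) {
    stop("palette is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  entries <- entries[, required]
  entries$name <- as.character(entries$name)
  if (anyDuplicated(entries$name)) {
    stop("palette category names must be distinct")
  }
  for (ch in c("r", "g", "b")) {
    lo <- entries[[paste0(ch, "_lo")]]
    hi <- entries[[paste0(ch, "_hi")]]
    if (any(lo != round(lo)) || any(hi != round(hi))) {
      stop("palette bounds must be integers")
    }
    if (any(lo < 0L) || any(hi > 255L) || any(lo > hi)) {
      stop("palette bounds must satisfy 0 <= lo <= hi <= 255 (channel ", ch, ")")
    }
  }
  rownames(entries) <- entries$name
  class(entries) <- c("color_palette", "data.frame")
  entries
}

#' Default six-category garden palette
#'
#' The six color categories (red, yellow, brown, gray, white, green) with the
#' inclusive RGB ranges used for traditional Japanese garden scenes: red for
#' autumn maple and ceremonial structures, yellow for gold leaf and ginkgo,
#' brown for timber and soil, gray for stone, white for sand and sky
#' reflections, green for foliage and moss.
#'
#' Note the ranges overlap: for instance `(150, 150, 150)` satisfies both
#' brown and gray. See [segment_image()] for how overlaps are resolved.
#'
#' @return A [color_palette()] with six rows.
#' @examples
#' default_palette()
#' @export
default_palette <- function() {
  color_palette(data.frame(
    name = c("red", "yellow", "brown", "gray", "white", "green"),
    r_lo = c(131L, 184L,  83L, 123L, 212L,  76L),
    r_hi = c(208L, 228L, 173L, 184L, 255L, 169L),
    g_lo = c(  8L, 156L,  79L, 105L, 212L,  93L),
    g_hi = c(120L, 194L, 187L, 184L, 255L, 199L),
    b_lo = c(  2L, 116L,  54L, 101L, 212L,  38L),
    b_hi = c( 82L, 133L, 194L, 184L, 255L, 113L)
  ))
}

#' Default precedence order for exclusive assignment
#'
#' When a pixel satisfies several categories' ranges and a partition is
#' required, it is assigned to the first matching category in this order
#' (most specific range volume first).
#'
#' @return Character vector of the six category names.
#' @export
default_precedence <- function() {
  c("white", "green", "red", "yellow", "gray", "brown")
}

#' Read or write a palette as YAML
#'
#' @param palette A [color_palette()].
#' @param path File path.
#' @return `write_palette` invisibly returns `path`; `read_palette` returns a
#'   [color_palette()].
#' @export
write_palette <- function(palette, path) {
  stopifnot(inherits(palette, "color_palette"))
  df <- palette
  class(df) <- "data.frame"
  entries <- lapply(seq_len(nrow(df)), function(i) {
    e <- as.list(df[i, ])
    lapply(e, function(v) if (is.numeric(v)) as.integer(v) else as.character(v))
  })
  yaml::write_yaml(list(palette = entries), path)
  invisible(path)
}

#' @rdname write_palette
#' @export
read_palette <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$palette)) stop("no 'palette' key in ", path)
  color_palette(do.call(rbind, lapply(raw$palette, as.data.frame)))
}
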