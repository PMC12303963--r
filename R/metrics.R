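#' Configuration for the per-color metric battery
#'
#' Collects the tunable parameters of the three color metrics: the
#' box-counting scale ladder, the Moran lattice size and weight scheme, and
#' the spatial-diversity block grid.
#'
#' @param box_scales Integer vector of box sizes; default dyadic ladder
#'   1..2048 (clipped per image).
#' @param moran_lattice Length-2 lattice dimensions for the concentration
#'   index; default `c(100, 100)`, capped at the mask dimensions.
#' @param weights_scheme `"rook"` or `"queen"` contiguity.
#' @param row_standardized Row-standardize the spatial weights?
#' @param diversity_grid Length-2 block grid for per-color spatial
#'   diversity; default `c(8, 8)`.
#' @param diversity_normalized Normalize spatial diversity to `[0, 1]`?
#' @return A list of class `metrics_config`.
#' @export
metrics_config <- function(box_scales = default_box_scales(),
                           moran_lattice = c(100L, 100L),
                           weights_scheme = c("rook", "queen"),
                           row_standardized = TRUE,
                           diversity_grid = c(8L, 8L),
                           diversity_normalized = TRUE) {
  weights_scheme <- match.arg(weights_scheme)
  stopifnot(length(moran_lattice) == 2L, all(moran_lattice >= 2),
            length(diversity_grid) == 2L, prod(diversity_grid) >= 2,
            all(box_scales >= 1))
  structure(
    list(box_scales = as.integer(box_scales),
         moran_lattice = as.integer(moran_lattice),
         weights_scheme = weights_scheme,
         row_standardized = isTRUE(row_standardized),
         diversity_grid = as.integer(diversity_grid),
         diversity_normalized = isTRUE(diversity_normalized)),
    class = "metrics_config"
  )
}

#' Compute the D / H' / C metric triplet for every color of an image
#'
#' For each color category with a nonempty mask: the box-counting fractal
#' dimension `D` of the mask, the per-color spatial diversity `H'`, and the
#' Moran's I concentration index `C` on the block-presence lattice. Colors
#' with empty masks (or masks too degenerate for a metric, e.g. constant
#' presence for Moran's I) yield `NA` entries with a warning, so downstream
#' correlations can use pairwise-complete observations.
#'
#' @param maskset A `color_mask_set` from [segment_image()].
#' @param config A [metrics_config()].
#' @param image_id Identifier copied into the output rows.
#' @return Data frame with one row per color: `image_id`, `color`, `D`,
#'   `r_squared`, `H_color`, `C`, `unclassified_fraction`.
#' @export
compute_color_metrics <- function(maskset, config = metrics_config(),
                                  image_id = NA_character_) {
  stopifnot(inherits(maskset, "color_mask_set"), inherits(config, "metrics_config"))
  dims <- dim(maskset$masks[[1L]])

  rows <- lapply(names(maskset$masks), function(color) {
    mask <- maskset$masks[[color]]
    out <- data.frame(image_id = image_id, color = color,
                      D = NA_real_, r_squared = NA_real_,
                      H_color = NA_real_, C = NA_real_,
                      unclassified_fraction = maskset$unclassified_fraction,
                      stringsAsFactors = FALSE)
    if (!any(mask)) {
      warning("empty mask for color '", color, "' (image ", image_id,
              "): metrics undefined", call. = FALSE)
      return(out)
    }
    fit <- tryCatch(
      box_dimension(mask, clip_scales(config$box_scales, dims)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      out$D <- fit$dimension
      out$r_squared <- fit$r_squared
    }
    grid <- pmin(config$diversity_grid, dims)
    out$H_color <- tryCatch(
      per_color_spatial_diversity(mask, grid, config$diversity_normalized),
      error = function(e) NA_real_
    )
    lat_dims <- pmin(config$moran_lattice, dims)
    out$C <- tryCatch(
      morans_i(coarsen_mask(mask, lat_dims, config$weights_scheme,
                            config$row_standardized)),
      error = function(e) {
        warning("concentration index undefined for color '", color,
                "' (image ", image_id, "): ", conditionMessage(e), call. = FALSE)
        NA_real_
      }
    )
    out
  })
  do.call(rbind, rows)
}
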