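#' Correlate color metrics with perceptual factors
#'
#' Pearson correlation between every color-metric column (the 18 metrics:
#' D, H', C for each of six colors) and every factor-score column, over
#' images, using pairwise-complete observations. Two-sided p-values come
#' from the t distribution with `n - 2` degrees of freedom; cells are
#' flagged `*` for p < 0.05 and `**` for p < 0.01. A Benjamini-Hochberg
#' adjusted p column can be added (off by default, matching raw-p
#' reporting conventions).
#'
#' @param metrics Data frame with an `image_id` column and one numeric
#'   column per metric (see [metrics_wide()]), or a numeric matrix with
#'   image rownames.
#' @param factor_scores Numeric matrix `images x factors` with image
#'   rownames (from [image_factor_scores()]).
#' @param adjust Add a `p_bh` column of BH-adjusted p-values? Default
#'   `FALSE`.
#' @return Data frame of class `correlation_table`: columns `metric`,
#'   `factor`, `r`, `p`, `n`, `flag` (and `p_bh` when requested). Constant
#'   or insufficient metric columns yield `NA` cells with a warning.
#' @export
correlate_metrics_factors <- function(metrics, factor_scores, adjust = FALSE) {
  fs <- as.matrix(factor_scores)
  if (is.null(rownames(fs))) stop("factor_scores needs image rownames")
  if (is.data.frame(metrics)) {
    if (!"image_id" %in% names(metrics)) stop("metrics needs an image_id column")
    m <- as.matrix(metrics[, setdiff(names(metrics), "image_id"), drop = FALSE])
    rownames(m) <- metrics$image_id
  } else {
    m <- as.matrix(metrics)
  }
  common <- intersect(rownames(m), rownames(fs))
  if (length(common) < 4L) stop("need at least 4 images shared between metrics and scores")
  m <- m[common, , drop = FALSE]
  fs <- fs[common, , drop = FALSE]

  rows <- list()
  for (mc in colnames(m)) {
    for (fc in colnames(fs)) {
      ok <- stats::complete.cases(m[, mc], fs[, fc])
      n <- sum(ok)
      if (n < 4L || stats::sd(m[ok, mc]) == 0 || stats::sd(fs[ok, fc]) == 0) {
        warning("cannot correlate '", mc, "' with '", fc,
                "': constant or insufficient pairwise-complete data", call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = mc, factor = fc, r = NA_real_, p = NA_real_, n = n,
          flag = "", stringsAsFactors = FALSE)
        next
      }
      r <- stats::cor(m[ok, mc], fs[ok, fc])
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mc, factor = fc, r = r, p = p, n = n,
        flag = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Reshape a tidy metrics table to one row per image
#'
#' Turns the long per-(image, color) output of [compute_color_metrics()]
#' into a wide table with one column per color-metric combination
#' (`brown_D`, `brown_H`, `brown_C`, `gray_D`, ...), the layout consumed by
#' [correlate_metrics_factors()].
#'
#' @param metrics_long Data frame with columns `image_id`, `color`, `D`,
#'   `H_color`, `C`.
#' @return Data frame with `image_id` plus 3 columns per color.
#' @export
metrics_wide <- function(metrics_long) {
  stopifnot(all(c("image_id", "color", "D", "H_color", "C") %in% names(metrics_long)))
  ids <- unique(metrics_long$image_id)
  colors <- unique(metrics_long$color)
  out <- data.frame(image_id = ids, stringsAsFactors = FALSE)
  for (col in colors) {
    sub <- metrics_long[metrics_long$color == col, ]
    i <- match(ids, sub$image_id)
    out[[paste0(col, "_D")]] <- sub$D[i]
    out[[paste0(col, "_H")]] <- sub$H_color[i]
    out[[paste0(col, "_C")]] <- sub$C[i]
  }
  out
}

#' Format a correlation table in wide journal layout
#'
#' One row per metric, one column per factor, cells `"r flag"` (e.g.
#' `"0.455**"`).
#'
#' @param ct A `correlation_table` from [correlate_metrics_factors()].
#' @param digits Decimal places for r. Default 3.
#' @return Data frame, metrics x factors, of formatted strings.
#' @export
format_correlation_table <- function(ct, digits = 3L) {
  stopifnot(inherits(ct, "correlation_table"))
  metrics <- unique(ct$metric)
  factors <- unique(ct$factor)
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (fc in factors) {
    sub <- ct[ct$factor == fc, ]
    i <- match(metrics, sub$metric)
    out[[fc]] <- ifelse(is.na(sub$r[i]), "NA",
                        paste0(formatC(sub$r[i], digits = digits, format = "f"),
                               sub$flag[i]))
  }
  out
}
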