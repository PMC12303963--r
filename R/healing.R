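#' Summarize per-image healing ratings
#'
#' Computes, for each image, the number of raters, mean, median (midpoint of
#' the central pair for even n), and sample standard deviation (n - 1
#' denominator) of its 7-point healing ratings.
#'
#' @param ratings Named list mapping image id to an integer vector of
#'   ratings in 1..7, or a long data frame with columns `image_id` and
#'   `rating`.
#' @return Data frame with columns `image_id`, `n_raters`, `mean`, `median`,
#'   `sd` (NA when n = 1).
#' @examples
#' summarize_healing_ratings(list(a = c(5, 5, 6, 7, 7)))
#' @export
summarize_healing_ratings <- function(ratings) {
  if (is.data.frame(ratings)) {
    stopifnot(all(c("image_id", "rating") %in% names(ratings)))
    ratings <- split(ratings$rating, ratings$image_id)
  }
  stopifnot(is.list(ratings), length(ratings) > 0L, !is.null(names(ratings)))
  rows <- lapply(names(ratings), function(id) {
    r <- ratings[[id]]
    if (length(r) < 1L) stop("image '", id, "' has no ratings")
    if (any(r != round(r)) || any(r < 1) || any(r > 7)) {
      stop("image '", id, "' has ratings outside the 1..7 scale")
    }
    data.frame(image_id = id, n_raters = length(r),
               mean = mean(r), median = stats::median(r),
               sd = stats::sd(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consensus-based sample selection filter
#'
#' An image is selected when its mean rating and median rating both meet
#' their thresholds (inclusive) and its standard deviation is strictly below
#' the consensus bound. The defaults (mean >= 5.0, median >= 5.0, sd < 1.2)
#' identify views that raters consistently judge as strongly healing.
#'
#' @param summaries Data frame from [summarize_healing_ratings()].
#' @param mean_min,median_min Inclusive lower bounds. Default 5.0.
#' @param sd_max Strict upper bound on the standard deviation. Default 1.2.
#' @return Character vector of selected `image_id`s, in input order.
#' @export
select_samples <- function(summaries, mean_min = 5.0, median_min = 5.0, sd_max = 1.2) {
  stopifnot(all(c("image_id", "mean", "median", "sd") %in% names(summaries)))
  keep <- summaries$mean >= mean_min &
    summaries$median >= median_min &
    !is.na(summaries$sd) & summaries$sd < sd_max
  summaries$image_id[keep]
}
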