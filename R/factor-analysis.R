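#' The 24 bipolar semantic-differential item pairs
#'
#' Default item labels for semantic-differential rating matrices: 24 bipolar
#' adjective pairs used to evaluate restorative qualities of landscape
#' scenes on a 5-point scale (5 = the first-named pole). Carried as metadata
#' only; the package does not interpret them.
#'
#' @return Character vector of length 24, `"Positive-Negative"` form.
#' @export
sd_item_pairs <- function() {
  c("Opened-Enclosed", "Neat-Squalid", "Orderly-Messy", "Harmonious-Discordant",
    "Balanced-Unbalanced", "Peaceful-Disturbing", "Calming-Stimulating",
    "Natural-Artificial", "Vibrant-Dull", "Coherent-Fragmented",
    "Comfortable-Uncomfortable", "Intimate-Distant", "Inviting-Repelling",
    "Warm-Cold", "Bright-Dark", "Complex-Simple", "Dynamic-Static",
    "Mysterious-Obvious", "Restorative-Draining", "Meditative-Distracting",
    "Relaxing-Tense", "Traditional-Contemporary", "Spiritual-Secular",
    "Unique-Common")
}

#' Six-factor eigenvalues from a published garden rating study
#'
#' Eigenvalues (rotated sums of squared loadings) of the six perceptual
#' factors retained in a published 24-item semantic-differential evaluation
#' of traditional Japanese garden scenes. Shipped as a worked input for the
#' contribution-rate bookkeeping of [contribution_rates()]: applied to these
#' values it reproduces the study's printed cumulative contribution of
#' 64.313% of total variance.
#'
#' @format Numeric vector of length 6.
#' @export
garden_sd_eigenvalues <- c(3.157, 2.839, 2.756, 2.538, 2.170, 1.975)

#' Contribution rates from factor eigenvalues
#'
#' In a factor analysis of standardized items, total variance equals the
#' number of items, so each factor's contribution rate is
#' `100 * eigenvalue / n_items` percent and the cumulative contribution is
#' the running sum.
#'
#' @param eigenvalues Numeric vector of factor eigenvalues (sums of squared
#'   loadings).
#' @param n_items Number of analyzed items (total variance). Default 24.
#' @return Data frame with columns `eigenvalue`, `contribution_rate_pct`,
#'   `cumulative_pct`.
#' @examples
#' contribution_rates(garden_sd_eigenvalues)
#' @export
contribution_rates <- function(eigenvalues, n_items = 24L) {
  stopifnot(is.numeric(eigenvalues), n_items >= 1)
  rate <- 100 * eigenvalues / n_items
  data.frame(eigenvalue = eigenvalues,
             contribution_rate_pct = rate,
             cumulative_pct = cumsum(rate))
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up in magnitude (the convention of
#' most published tables), unlike [round()]'s round-half-to-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Flatten semantic-differential ratings to an observation matrix
#'
#' @param sd_array Numeric array `participants x items x images` of 5-point
#'   scores (1..5). Dimnames, when present, identify participants, items and
#'   images.
#' @param observation_mode `"participant_by_image"` (default): one row per
#'   participant-image response; `"image_mean"`: one row per image, scores
#'   averaged over participants.
#' @return Numeric matrix `observations x items` with attributes
#'   `image_ids` and `participant_ids` aligned to its rows.
#' @export
sd_observations <- function(sd_array,
                            observation_mode = c("participant_by_image", "image_mean")) {
  observation_mode <- match.arg(observation_mode)
  stopifnot(is.array(sd_array), length(dim(sd_array)) == 3L)
  d <- dim(sd_array)
  item_names <- dimnames(sd_array)[[2L]]
  if (is.null(item_names)) item_names <- paste0("item", seq_len(d[2L]))
  image_names <- dimnames(sd_array)[[3L]]
  if (is.null(image_names)) image_names <- paste0("img", seq_len(d[3L]))
  participant_names <- dimnames(sd_array)[[1L]]
  if (is.null(participant_names)) participant_names <- paste0("p", seq_len(d[1L]))

  if (observation_mode == "participant_by_image") {
    # rows ordered image-major: all participants of image 1, then image 2, ...
    obs <- matrix(aperm(sd_array, c(1L, 3L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
    colnames(obs) <- item_names
    attr(obs, "image_ids") <- rep(image_names, each = d[1L])
    attr(obs, "participant_ids") <- rep(participant_names, times = d[3L])
  } else {
    obs <- t(apply(sd_array, c(2L, 3L), mean))
    colnames(obs) <- item_names
    rownames(obs) <- image_names
    attr(obs, "image_ids") <- image_names
    attr(obs, "participant_ids") <- NULL
  }
  obs
}

#' Pearson correlation matrix of the semantic-differential items
#'
#' @inheritParams sd_observations
#' @return Symmetric `items x items` correlation matrix.
#' @export
item_correlation_matrix <- function(sd_array,
                                    observation_mode = c("participant_by_image", "image_mean")) {
  obs <- sd_observations(sd_array, match.arg(observation_mode))
  if (nrow(obs) < 3L) stop("need at least 3 observations to correlate items")
  sds <- apply(obs, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance item(s): ", paste(colnames(obs)[sds == 0], collapse = ", "))
  }
  stats::cor(obs)
}

#' Principal-axis factor analysis with iterated communalities
#'
#' Extracts factors from a correlation matrix by principal-axis factoring:
#' the diagonal is replaced by communality estimates (initialized at the
#' squared multiple correlations) and the reduced matrix is
#' eigendecomposed, iterating until the communalities stabilize. The number
#' of factors is chosen by the Kaiser criterion -- eigenvalues of the
#' unreduced correlation matrix strictly greater than 1.0 -- or fixed.
#'
#' @param corr Symmetric correlation matrix (items on both axes).
#' @param retention `"kaiser"` (default) or `"fixed_k"`.
#' @param k Number of factors when `retention = "fixed_k"`.
#' @param tol Convergence tolerance on the communalities. Default 1e-6.
#' @param max_iter Maximum iterations. Default 100; non-convergence returns
#'   the last iterate flagged `converged = FALSE`.
#' @return Object of class `factor_solution`: list with `loadings`
#'   (items x k), `eigenvalues` (sums of squared loadings per factor),
#'   `contribution_rate_pct`, `cumulative_pct`, `communalities`,
#'   `uniquenesses`, `initial_eigenvalues` (of the unreduced matrix), `k`,
#'   `n_items`, `corr`, `rotation`, `rotmat`, `converged`, `iterations`.
#'   With no eigenvalue above 1 under Kaiser retention, an explicit empty
#'   solution (`k = 0`) is returned.
#' @export
principal_axis_factor <- function(corr, retention = c("kaiser", "fixed_k"),
                                  k = NULL, tol = 1e-6, max_iter = 100L) {
  retention <- match.arg(retention)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric")
  p <- nrow(corr)
  items <- rownames(corr)
  if (is.null(items)) items <- paste0("item", seq_len(p))

  init_eig <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(init_eig) < -1e-8) {
    stop("correlation matrix is not positive semi-definite")
  }
  if (retention == "kaiser") {
    k <- sum(init_eig > 1.0)
  } else {
    if (is.null(k) || k < 1L || k > p) stop("fixed_k retention needs 1 <= k <= n_items")
    k <- as.integer(k)
  }

  empty <- function() {
    structure(list(
      loadings = matrix(numeric(0), p, 0L, dimnames = list(items, NULL)),
      eigenvalues = numeric(0), contribution_rate_pct = numeric(0),
      cumulative_pct = numeric(0),
      communalities = stats::setNames(rep(0, p), items),
      uniquenesses = stats::setNames(rep(1, p), items),
      initial_eigenvalues = init_eig, k = 0L, n_items = p, corr = corr,
      rotation = "none", rotmat = matrix(numeric(0), 0L, 0L),
      converged = TRUE, iterations = 0L
    ), class = "factor_solution")
  }
  if (k == 0L) return(empty())

  # initial communalities: squared multiple correlations
  h2 <- tryCatch(1 - 1 / diag(solve(corr)),
                 error = function(e) 1 - 1 / diag(solve(corr + diag(1e-8, p))))
  h2 <- pmin(pmax(h2, 0), 1)

  converged <- FALSE
  heywood <- FALSE
  lambda <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    reduced <- corr
    diag(reduced) <- h2
    e <- eigen(reduced, symmetric = TRUE)
    vals <- pmax(e$values[seq_len(k)], 0)
    lambda <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
    h2_new <- rowSums(lambda^2)
    if (any(h2_new > 1)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 1)
    }
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      converged <- TRUE
      break
    }
    h2 <- h2_new
  }
  if (heywood) {
    warning("Heywood case: communality exceeded 1 and was clamped", call. = FALSE)
  }
  if (!converged) {
    warning("principal-axis iteration did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }

  dimnames(lambda) <- list(items, paste0("Factor", seq_len(k)))
  lambda <- positivize_columns(lambda)
  finish_solution(lambda, init_eig, corr, rotation = "none",
                  rotmat = diag(k), converged = converged, iterations = iter)
}

# sign convention: make each column's largest-magnitude loading positive
positivize_columns <- function(lambda) {
  for (j in seq_len(ncol(lambda))) {
    i <- which.max(abs(lambda[, j]))
    if (lambda[i, j] < 0) lambda[, j] <- -lambda[, j]
  }
  lambda
}

# assemble a factor_solution from a loading matrix
finish_solution <- function(lambda, init_eig, corr, rotation, rotmat,
                            converged, iterations) {
  ss <- colSums(lambda^2)
  cr <- contribution_rates(ss, n_items = nrow(lambda))
  h2 <- rowSums(lambda^2)
  structure(list(
    loadings = lambda,
    eigenvalues = unname(ss),
    contribution_rate_pct = cr$contribution_rate_pct,
    cumulative_pct = cr$cumulative_pct,
    communalities = stats::setNames(h2, rownames(lambda)),
    uniquenesses = stats::setNames(1 - h2, rownames(lambda)),
    initial_eigenvalues = init_eig,
    k = ncol(lambda), n_items = nrow(lambda), corr = corr,
    rotation = rotation, rotmat = rotmat,
    converged = converged, iterations = iterations
  ), class = "factor_solution")
}

# Kaiser's pairwise planar varimax: sweep all factor pairs, rotating each
# by the closed-form angle that maximizes the planar varimax criterion,
# until no pair moves. Unlike gradient/SVD formulations this also escapes
# the symmetric plateau where all rows load equally on a pair of factors.
varimax_pairwise <- function(lambda, normalize = TRUE, eps = 1e-6,
                             max_sweeps = 100L) {
  p <- nrow(lambda)
  k <- ncol(lambda)
  h <- if (normalize) sqrt(rowSums(lambda^2)) else rep(1, p)
  h[h == 0] <- 1
  w <- lambda / h
  rot <- diag(k)
  for (sweep in seq_len(max_sweeps)) {
    max_phi <- 0
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        x <- w[, i]
        y <- w[, j]
        u <- x^2 - y^2
        v <- 2 * x * y
        num <- 2 * (p * sum(u * v) - sum(u) * sum(v))
        den <- p * sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2)
        phi <- 0.25 * atan2(num, den)
        if (abs(phi) < 1e-12) next
        max_phi <- max(max_phi, abs(phi))
        g <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
        w[, c(i, j)] <- w[, c(i, j)] %*% g
        rot[, c(i, j)] <- rot[, c(i, j)] %*% g
      }
    }
    if (max_phi < eps) break
  }
  rot
}

#' Varimax rotation of a factor solution
#'
#' Kaiser-normalized varimax rotation (orthogonal; preserves communalities),
#' computed by the classic pairwise planar-rotation algorithm. After
#' rotation, factors are reordered by explained variance (descending) and
#' each column's largest-magnitude loading is made positive. With a single
#' factor the rotation is the identity.
#'
#' @param solution A `factor_solution` from [principal_axis_factor()], or a
#'   bare loading matrix.
#' @param eps Convergence tolerance of the rotation. Default 1e-6.
#' @return Same type as the input: a rotated `factor_solution` (with
#'   `rotation = "varimax"` and the accumulated orthonormal `rotmat`), or a
#'   list with `loadings` and `rotmat` for matrix input.
#' @export
varimax_rotate <- function(solution, eps = 1e-6) {
  is_sol <- inherits(solution, "factor_solution")
  lambda <- if (is_sol) solution$loadings else as.matrix(solution)
  k <- ncol(lambda)
  if (k < 2L) {
    rot <- diag(k)
  } else {
    rot <- varimax_pairwise(lambda, normalize = TRUE, eps = eps)
    lambda <- lambda %*% rot
    # reorder by explained variance, fix signs; fold both into the rotation
    ord <- order(colSums(lambda^2), decreasing = TRUE)
    perm <- diag(k)[, ord, drop = FALSE]
    lambda <- lambda[, ord, drop = FALSE]
    signs <- vapply(seq_len(k), function(j) {
      i <- which.max(abs(lambda[, j]))
      if (lambda[i, j] < 0) -1 else 1
    }, numeric(1))
    lambda <- sweep(lambda, 2L, signs, "*")
    rot <- rot %*% perm %*% diag(signs, k)
  }
  colnames(lambda) <- paste0("Factor", seq_len(k))

  if (!is_sol) {
    return(list(loadings = lambda, rotmat = rot))
  }
  out <- finish_solution(lambda, solution$initial_eigenvalues, solution$corr,
                         rotation = "varimax",
                         rotmat = solution$rotmat %*% rot,
                         converged = solution$converged,
                         iterations = solution$iterations)
  out
}

#' Screen items by loading size and cross-loading gap
#'
#' An item is dropped when its largest absolute loading is below `load_min`,
#' or when the gap between its largest and second-largest absolute loadings
#' is below `crossload_gap` (an ambiguous cross-loader). Surviving items are
#' assigned to their maximum-loading factor.
#'
#' @param solution A rotated `factor_solution` or a loading matrix.
#' @param load_min Minimum absolute loading. Default 0.40.
#' @param crossload_gap Minimum gap to the second-largest absolute loading.
#'   Default 0.20.
#' @return Data frame with columns `item`, `max_loading`, `second_loading`
#'   (absolute values), `retained`, `factor` (NA for dropped items).
#' @export
screen_loadings <- function(solution, load_min = 0.40, crossload_gap = 0.20) {
  lambda <- if (inherits(solution, "factor_solution")) solution$loadings else as.matrix(solution)
  if (ncol(lambda) < 1L) stop("cannot screen an empty solution")
  items <- rownames(lambda)
  if (is.null(items)) items <- paste0("item", seq_len(nrow(lambda)))
  a <- abs(lambda)
  res <- lapply(seq_len(nrow(a)), function(i) {
    v <- sort(a[i, ], decreasing = TRUE)
    top <- v[1L]
    second <- if (length(v) > 1L) v[2L] else 0
    keep <- top >= load_min && (top - second) >= crossload_gap
    data.frame(item = items[i], max_loading = top, second_loading = second,
               retained = keep,
               factor = if (keep) which.max(a[i, ]) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Factor scores for observations
#'
#' Thurstone regression scores by default: standardized item scores are
#' weighted by `solve(R) %*% lambda`. The Bartlett weighted-least-squares
#' alternative uses the uniquenesses. A singular correlation matrix falls
#' back to a ridge-regularized inverse (1e-8 on the diagonal) with a
#' warning.
#'
#' @param data Numeric matrix or data frame, `observations x items`,
#'   column-aligned with the solution's items.
#' @param solution A `factor_solution` with `k >= 1`.
#' @param method `"regression"` (default) or `"bartlett"`.
#' @return Numeric matrix `observations x k`; columns have mean 0.
#' @export
factor_scores <- function(data, solution, method = c("regression", "bartlett")) {
  method <- match.arg(method)
  stopifnot(inherits(solution, "factor_solution"))
  if (solution$k < 1L) stop("factor scores need at least one retained factor")
  x <- as.matrix(data)
  if (ncol(x) != solution$n_items) {
    stop("data has ", ncol(x), " items but the solution expects ", solution$n_items)
  }
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0] <- 0  # constant items carry no information
  lambda <- solution$loadings
  if (method == "regression") {
    w <- tryCatch(solve(solution$corr, lambda), error = function(e) {
      warning("singular correlation matrix; using ridge-regularized inverse",
              call. = FALSE)
      solve(solution$corr + diag(1e-8, solution$n_items), lambda)
    })
  } else {
    u_inv <- 1 / pmax(solution$uniquenesses, 1e-8)
    a <- lambda * u_inv                     # U^-1 Lambda
    w <- a %*% solve(crossprod(lambda, a))  # U^-1 L (L' U^-1 L)^-1
  }
  scores <- z %*% w
  colnames(scores) <- colnames(lambda)
  scores
}

#' Image-level factor scores
#'
#' Averages observation-level factor scores within each image and
#' standardizes each factor column across images (z-scores), the form
#' consumed by landscape clustering and metric-factor correlation.
#'
#' @param scores Matrix from [factor_scores()].
#' @param image_ids Character vector, one id per row of `scores` (for
#'   `participant_by_image` observations, the `image_ids` attribute of
#'   [sd_observations()]).
#' @return Matrix `images x k` of z-scored factor scores, rownames = image
#'   ids (in first-appearance order).
#' @export
image_factor_scores <- function(scores, image_ids) {
  stopifnot(nrow(scores) == length(image_ids))
  ids <- factor(image_ids, levels = unique(image_ids))
  means <- rowsum(scores, ids) / as.vector(table(ids))
  out <- scale(means)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise cosine similarity after greedily matching each reference
#' column to its best-aligned (sign-insensitive) estimate column. Used to
#' assess recovery of planted factor structure.
#'
#' @param estimated,reference Loading matrices with the same row count.
#' @return Numeric vector: absolute congruence of each reference factor with
#'   its matched estimated factor.
#' @export
tucker_congruence <- function(estimated, reference) {
  a <- as.matrix(estimated)
  b <- as.matrix(reference)
  stopifnot(nrow(a) == nrow(b))
  phi <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  avail <- seq_len(ncol(a))
  out <- numeric(ncol(b))
  for (j in seq_len(ncol(b))) {
    cong <- vapply(avail, function(i) abs(phi(a[, i], b[, j])), numeric(1))
    best <- which.max(cong)
    out[j] <- cong[best]
    avail <- avail[-best]
    if (length(avail) == 0L) break
  }
  out
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> %d items, %d factor(s), rotation = %s\n",
              x$n_items, x$k, x$rotation))
  if (x$k > 0L) {
    cat(sprintf("  cumulative contribution: %.3f%%\n",
                x$cumulative_pct[x$k]))
  }
  invisible(x)
}
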