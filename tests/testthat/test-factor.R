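test_that("item correlation matrices behave on duplicated and independent items", {
  withr::local_seed(41)
  # duplicated item -> off-diagonal r = 1
  arr <- array(sample(1:5, 10 * 3 * 4, replace = TRUE), dim = c(10, 3, 4))
  arr[, 2, ] <- arr[, 1, ]
  r <- item_correlation_matrix(arr)
  expect_equal(r[1, 2], 1)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)

  # independent items at large n stay near zero
  big <- array(sample(1:5, 10000 * 4, replace = TRUE), dim = c(100, 4, 100))
  rb <- item_correlation_matrix(big)
  expect_lt(max(abs(rb[upper.tri(rb)])), 0.05)

  # zero-variance item is named in the error
  arr[, 3, ] <- 3L
  expect_error(item_correlation_matrix(arr), "item3")
})

test_that("observation construction supports both analysis units", {
  sim <- gen_sd_ratings(n_participants = 5, n_images = 7, seed = 2)
  obs <- sd_observations(sim$ratings)
  expect_equal(dim(obs), c(35, 24))
  expect_equal(length(attr(obs, "image_ids")), 35)
  agg <- sd_observations(sim$ratings, "image_mean")
  expect_equal(dim(agg), c(7, 24))
  expect_equal(agg[3, 5], mean(sim$ratings[, 5, 3]))
})

test_that("an identity correlation matrix retains zero factors under Kaiser", {
  sol <- principal_axis_factor(diag(24))
  expect_equal(sol$k, 0)
  expect_equal(ncol(sol$loadings), 0)
  expect_equal(sol$communalities, setNames(rep(0, 24), paste0("item", 1:24)))
})

test_that("a one-factor model built analytically is recovered", {
  lambda <- rep(0.8, 12)
  sigma <- tcrossprod(lambda)
  diag(sigma) <- 1
  sol <- principal_axis_factor(sigma, retention = "fixed_k", k = 1)
  expect_equal(as.vector(sol$loadings), lambda, tolerance = 0.01)
  expect_true(sol$converged)
})

test_that("planted three-factor structure is recovered after rotation", {
  lam <- default_sd_loadings(24, 3, 0.7)
  congruences <- vapply(1:5, function(s) {
    sim <- gen_sd_ratings(n_participants = 25, n_images = 20,
                          loadings = lam, seed = 100 + s)
    r <- item_correlation_matrix(sim$ratings)
    sol <- varimax_rotate(principal_axis_factor(r, retention = "fixed_k", k = 3))
    mean(tucker_congruence(sol$loadings, lam))
  }, numeric(1))
  expect_gte(mean(congruences), 0.95)
})

test_that("varimax preserves communalities and returns an orthonormal rotation", {
  lam <- default_sd_loadings(24, 3, 0.7)
  sim <- gen_sd_ratings(n_participants = 25, n_images = 20, loadings = lam, seed = 55)
  sol <- principal_axis_factor(item_correlation_matrix(sim$ratings),
                               retention = "fixed_k", k = 3)
  rot <- varimax_rotate(sol)
  expect_equal(rot$communalities, sol$communalities, tolerance = 1e-8)
  expect_equal(crossprod(rot$rotmat), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  # the reproduced correlation structure is unchanged by rotation
  expect_equal(tcrossprod(rot$loadings), tcrossprod(sol$loadings), tolerance = 1e-8)
})

test_that("varimax undoes a known 45-degree rotation of simple structure", {
  simple <- rbind(matrix(c(0.8, 0), 8, 2, byrow = TRUE),
                  matrix(c(0, 0.8), 8, 2, byrow = TRUE))
  theta <- pi / 4
  mixed <- simple %*% matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  rec <- varimax_rotate(mixed)$loadings
  # recovery up to column order and sign (tied explained variances here)
  expect_equal(tucker_congruence(rec, simple), c(1, 1), tolerance = 1e-4)
  expect_equal(unname(sort(abs(rec[1, ]))), c(0, 0.8), tolerance = 1e-6)
  # already-simple structure is a fixed point
  fixed <- varimax_rotate(simple)$loadings
  expect_equal(tucker_congruence(fixed, simple), c(1, 1), tolerance = 1e-6)
})

test_that("pairwise varimax attains the same criterion as the reference rotation", {
  withr::local_seed(47)
  lam <- default_sd_loadings(24, 4, 0.7) + matrix(rnorm(96, sd = 0.08), 24, 4)
  h <- sqrt(rowSums(lam^2))
  w <- lam / h
  crit <- function(m) sum(colMeans(m^4) - colMeans(m^2)^2)
  mine <- varimax_rotate(lam)$loadings
  ref <- lam %*% stats::varimax(lam, normalize = TRUE, eps = 1e-10)$rotmat
  expect_equal(crit(mine / h), crit(ref / h), tolerance = 1e-6)
})

test_that("loading screens drop weak and cross-loading items", {
  lam <- rbind(c(0.849, 0.125, 0.156),
               c(0.390, 0.100, 0.050),
               c(0.550, 0.450, 0.020),
               c(0.100, 0.720, 0.050))
  rownames(lam) <- paste0("it", 1:4)
  sc <- screen_loadings(lam)
  expect_equal(sc$retained, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(sc$factor[1], 1L)
  expect_equal(sc$factor[4], 2L)
})

test_that("contribution-rate bookkeeping is internally consistent", {
  withr::local_seed(43)
  sim <- gen_sd_ratings(n_participants = 20, n_images = 15, seed = 77)
  sol <- varimax_rotate(principal_axis_factor(
    item_correlation_matrix(sim$ratings), retention = "fixed_k", k = 4))
  expect_equal(sol$contribution_rate_pct, 100 * sol$eigenvalues / 24)
  expect_equal(sol$cumulative_pct, cumsum(sol$contribution_rate_pct))
  expect_equal(sol$eigenvalues, unname(colSums(sol$loadings^2)))
  # rounding convention for published tables
  expect_equal(round_half_up(64.3125, 3), 64.313)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
})

test_that("factor scores reproduce planted factors on noise-free data", {
  lam <- default_sd_loadings(12, 2, 0.9)
  withr::local_seed(44)
  f <- matrix(rnorm(400), 200, 2)
  x <- f %*% t(lam) + matrix(rnorm(200 * 12, sd = 0.05), 200, 12)
  r <- cor(x)
  sol <- varimax_rotate(principal_axis_factor(r, retention = "fixed_k", k = 2))
  sc <- factor_scores(x, sol)
  expect_equal(colMeans(sc), c(0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  cc <- abs(cor(sc, f))
  expect_gte(max(cc[, 1]), 0.99)
  expect_gte(max(cc[, 2]), 0.99)
  # Bartlett scores agree with regression scores up to scaling here
  scb <- factor_scores(x, sol, method = "bartlett")
  expect_gte(min(abs(diag(cor(sc, scb)))), 0.99)
})

test_that("image-level scores are z-scored across images", {
  sim <- gen_sd_ratings(n_participants = 10, n_images = 12, seed = 3)
  obs <- sd_observations(sim$ratings)
  sol <- suppressWarnings(
    varimax_rotate(principal_axis_factor(item_correlation_matrix(sim$ratings),
                                         retention = "fixed_k", k = 6)))
  sc <- factor_scores(obs, sol)
  isc <- image_factor_scores(sc, attr(obs, "image_ids"))
  expect_equal(dim(isc), c(12, 6))
  expect_equal(colMeans(isc), rep(0, 6), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(apply(isc, 2, sd), rep(1, 6), tolerance = 1e-10, ignore_attr = TRUE)
})
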