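test_that("box counts match constructed values on reference masks", {
  expect_equal(box_count(matrix(TRUE, 256, 256), 2)$n_boxes, 16384)
  single <- matrix(FALSE, 64, 64)
  single[17, 40] <- TRUE
  expect_equal(box_count(single, c(1, 2, 4, 8, 64))$n_boxes, rep(1, 5))
  carpet <- gen_mask("sierpinski_carpet", depth = 5)
  expect_equal(box_count(carpet, 3)$n_boxes, 4096)  # 8^4 by self-similarity
})

test_that("box counting equals the exhaustive per-box oracle on small masks", {
  withr::local_seed(7)
  for (i in 1:12) {
    h <- sample(5:64, 1)
    w <- sample(5:64, 1)
    m <- random_mask(h, w, p = runif(1, 0.05, 0.6))
    scales <- c(1, 2, 3, 5, 7, 16)
    scales <- scales[scales <= min(h, w)]
    got <- box_count(m, scales)$n_boxes
    want <- vapply(scales, function(e) oracle_box_count(m, e), integer(1))
    expect_equal(got, as.numeric(want))
  }
})

test_that("box counts are non-increasing in box size", {
  withr::local_seed(8)
  for (i in 1:50) {
    m <- random_mask(sample(10:80, 1), sample(10:80, 1), p = runif(1, 0.02, 0.8))
    curve <- box_count(m, clip_scales(default_box_scales(), dim(m)))
    expect_true(all(diff(curve$n_boxes) <= 0))
    expect_true(all(curve$n_boxes >= 1))
  }
})

test_that("dimension estimates hit the analytic limits", {
  expect_equal(box_dimension(matrix(TRUE, 256, 256))$dimension, 2, tolerance = 0.01)
  hline <- gen_mask("hline", size = c(256, 256))
  expect_equal(box_dimension(hline)$dimension, 1, tolerance = 0.02)
  carpet <- gen_mask("sierpinski_carpet", depth = 5)
  fit <- box_dimension(carpet, c(1, 3, 9, 27, 81, 243))
  expect_equal(fit$dimension, log(8) / log(3), tolerance = 0.05)
  expect_gt(fit$r_squared, 0.999)
})

test_that("planted IFS dimensions are recovered at high resolution", {
  cases <- list(
    list(kind = "cantor_dust", depth = 6L, dim = log(4) / log(3)),
    list(kind = "sierpinski_triangle", depth = 9L, dim = log(3) / log(2)),
    list(kind = "sierpinski_carpet", depth = 6L, dim = log(8) / log(3))
  )
  for (cs in cases) {
    m <- gen_mask(cs$kind, depth = cs$depth)
    fit <- box_dimension(m)  # default dyadic ladder
    expect_equal(fit$dimension, cs$dim, tolerance = 0.08)
  }
})

test_that("degenerate curves are rejected with informative errors", {
  expect_error(box_count(matrix(FALSE, 4, 4)), "nonempty")
  single <- matrix(FALSE, 32, 32)
  single[1, 1] <- TRUE
  # every scale saturates at N = 1: constant counts, no usable slope
  expect_error(fractal_dimension(box_count(single, c(1, 2, 4, 8))), "insufficient")
  two <- box_count(matrix(TRUE, 16, 16), c(1, 2))
  expect_error(fractal_dimension(two), "insufficient")
  expect_error(box_count(matrix(TRUE, 4, 4), 0), "positive")
})

test_that("saturated tail scales are trimmed before the fit", {
  # a 4x4 filled block in a 64x64 mask: N = 1 for all eps >= 4 once covered
  m <- matrix(FALSE, 64, 64)
  m[1:4, 1:4] <- TRUE
  curve <- box_count(m, c(1, 2, 4, 8, 16, 32, 64))
  fit <- fractal_dimension(curve)
  # scales 4..64 all give N = 1; only the first saturated scale is kept,
  # leaving the exact dyadic points (1,16), (2,4), (4,1) with slope 2
  expect_equal(fit$scales_used, 3)
  expect_equal(fit$dimension, 2, tolerance = 1e-10)
})
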