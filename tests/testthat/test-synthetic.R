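test_that("mask generators are deterministic and carry analytic dimensions", {
  a <- gen_mask("sierpinski_carpet", depth = 5)
  b <- gen_mask("sierpinski_carpet", depth = 5)
  expect_identical(a, b)
  expect_equal(sum(a), 8^5)
  expect_equal(dim(a), c(243, 243))
  expect_equal(attr(a, "analytic_dimension"), log(8) / log(3))

  expect_equal(sum(gen_mask("sierpinski_triangle", depth = 4)), 3^4)
  expect_equal(sum(gen_mask("cantor_dust", depth = 4)), 4^4)
  expect_equal(sum(gen_mask("vicsek", depth = 4)), 5^4)
  expect_equal(sum(gen_mask("filled", size = c(128, 128))), 16384)

  s1 <- gen_mask("disc_cluster", size = c(50, 50), n_discs = 5, radius = 4,
                 disc_layout = "scattered", seed = 3)
  s2 <- gen_mask("disc_cluster", size = c(50, 50), n_discs = 5, radius = 4,
                 disc_layout = "scattered", seed = 3)
  expect_identical(s1, s2)
  expect_error(gen_mask("sierpinski_carpet", size = c(100, 100), depth = 4),
               "incompatible")
})

test_that("a unit checkerboard lattice attains Moran's I of -1", {
  cb <- gen_mask("checkerboard", size = c(4, 4), cell = 1)
  expect_equal(morans_i(presence_lattice(cb + 0)), -1, tolerance = 1e-12)
})

test_that("landscape images recover planted compositions through segmentation", {
  out <- gen_landscape_image(c(green = 0.5, red = 0.5), "blocks",
                             size = c(40, 40), seed = 8)
  seg <- segment_image(out$image, mode = "exclusive")
  expect_equal(unname(seg$proportions[c("green", "red")]), c(0.5, 0.5))

  blob <- gen_landscape_image(c(green = 0.4, brown = 0.3), "blobs",
                              size = c(80, 80), seed = 9)
  segb <- segment_image(blob$image, mode = "exclusive")
  expect_identical(segb$masks$green, blob$masks$green)
  expect_identical(segb$masks$brown, blob$masks$brown)

  frac <- gen_landscape_image(c(green = 0.6, gray = 0.4), "fractal_per_color",
                              size = c(81, 81), seed = 10)
  segf <- segment_image(frac$image, mode = "exclusive")
  expect_identical(segf$masks$green, frac$masks$green)
})

test_that("planted fractal structure survives the image -> mask -> D path", {
  carpet <- gen_mask("sierpinski_carpet", depth = 5)
  scene <- gen_image_from_masks(list(green = carpet), seed = 11)
  seg <- segment_image(scene, mode = "exclusive")
  fit <- box_dimension(seg$masks$green, 3^(0:5))
  expect_equal(fit$dimension, log(8) / log(3), tolerance = 0.05)
})

test_that("generators reject impossible requests", {
  expect_error(gen_landscape_image(c(green = 0.7, red = 0.7), "blocks"),
               "at most 1")
  expect_error(gen_landscape_image(c(0.5, 0.5), "blocks"), "named")
  expect_error(gen_image_from_masks(list(green = matrix(TRUE, 4, 4),
                                         red = matrix(TRUE, 4, 4))),
               "disjoint")
  expect_error(gen_image_from_masks(list(teal = matrix(TRUE, 2, 2))), "unknown")
})

test_that("safe sampling boxes are verified against the palette at runtime", {
  boxes <- safe_color_boxes()
  expect_setequal(names(boxes),
                  c(default_palette()$name, "background"))
  # every safe-box corner classifies to exactly its own category
  pal <- default_palette()
  for (nm in setdiff(names(boxes), "background")) {
    b <- boxes[[nm]]
    for (corner in list(b["lo", ], b["hi", ])) {
      img <- as_rgb_image(array(corner, dim = c(1, 1, 3)))
      seg <- segment_image(img, pal, mode = "non_exclusive")
      expect_equal(names(Filter(function(m) m[1, 1], seg$masks)), nm)
    }
  }
})

test_that("semantic-differential simulation matches the study design shape", {
  sim <- gen_sd_ratings(seed = 12)
  expect_equal(dim(sim$ratings), c(58, 24, 42))
  expect_true(all(sim$ratings %in% 1:5))
  expect_equal(dim(sim$loadings), c(24, 6))
  expect_equal(dim(sim$factor_scores), c(42, 6))
  # identical spec + seed -> bit-identical output
  expect_identical(sim$ratings, gen_sd_ratings(seed = 12)$ratings)
})

test_that("planted six-factor structure is recoverable at study dimensions", {
  sim <- gen_sd_ratings(seed = 13)
  sol <- varimax_rotate(principal_axis_factor(
    item_correlation_matrix(sim$ratings), retention = "fixed_k", k = 6))
  expect_gte(mean(tucker_congruence(sol$loadings, sim$loadings)), 0.9)
})

test_that("noise-free one-factor ratings are perfectly rank-correlated", {
  lam <- matrix(1, 6, 1)
  sim <- gen_sd_ratings(n_participants = 4, n_images = 30, loadings = lam,
                        noise_sd = 0, cut_points = c(-0.8, -0.3, 0.3, 0.8),
                        seed = 14)
  obs <- sd_observations(sim$ratings)
  expect_equal(min(cor(obs, method = "spearman")), 1)
})

test_that("joint datasets validate their target correlation matrix", {
  bad <- joint_target_corr(matrix(0.9, 18, 6))  # far from PSD
  expect_error(gen_joint_dataset(10, bad), "positive semi-definite")
  asym <- diag(24)
  asym[1, 2] <- 0.5
  expect_error(gen_joint_dataset(10, asym), "symmetric")
  jt <- gen_joint_dataset(30, seed = 15)
  expect_identical(jt$metrics, gen_joint_dataset(30, seed = 15)$metrics)
  expect_equal(names(jt$metrics), c("image_id", default_metric_names()))
})
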