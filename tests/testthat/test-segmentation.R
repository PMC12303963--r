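test_that("default palette carries the six canonical range rules", {
  p <- default_palette()
  expect_s3_class(p, "color_palette")
  expect_setequal(p$name, c("red", "yellow", "brown", "gray", "white", "green"))
  expect_equal(unlist(p["red", c("r_lo", "r_hi", "g_lo", "g_hi", "b_lo", "b_hi")],
                      use.names = FALSE),
               c(131, 208, 8, 120, 2, 82))
  expect_equal(unlist(p["white", c("r_lo", "r_hi", "g_lo", "g_hi", "b_lo", "b_hi")],
                      use.names = FALSE),
               c(212, 255, 212, 255, 212, 255))
  expect_equal(unlist(p["green", c("r_lo", "r_hi", "g_lo", "g_hi", "b_lo", "b_hi")],
                      use.names = FALSE),
               c(76, 169, 93, 199, 38, 113))
})

test_that("palette validation rejects malformed range tables", {
  bad <- data.frame(name = "x", r_lo = 10, r_hi = 5, g_lo = 0, g_hi = 1,
                    b_lo = 0, b_hi = 1)
  expect_error(color_palette(bad), "lo <= hi")
  dup <- default_palette()
  dup2 <- rbind(as.data.frame(unclass(dup)), as.data.frame(unclass(dup))[1, ])
  expect_error(color_palette(dup2), "distinct")
})

test_that("palette YAML round trip preserves all bounds", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_palette(default_palette(), path)
  back <- read_palette(path)
  expect_equal(as.data.frame(unclass(back)), as.data.frame(unclass(default_palette())))
})

test_that("single pixels classify by exhaustive range membership", {
  px <- function(r, g, b) {
    img <- as_rgb_image(array(c(r, g, b), dim = c(1, 1, 3)))
    seg <- segment_image(img, mode = "non_exclusive")
    names(Filter(function(m) m[1, 1], seg$masks))
  }
  expect_equal(px(150, 60, 40), "red")
  expect_equal(px(0, 0, 0), character(0))
  # overlap case: verified by hand against all six range triples
  expect_setequal(px(150, 150, 150), c("brown", "gray"))
  imgo <- as_rgb_image(array(c(150, 150, 150), dim = c(1, 1, 3)))
  sego <- segment_image(imgo, mode = "exclusive")
  expect_equal(names(Filter(function(m) m[1, 1], sego$masks)), "gray")
})

test_that("exclusive masks partition classified pixels and proportions sum to 1", {
  withr::local_seed(42)
  img <- as_rgb_image(array(sample(0:255, 40 * 40 * 3, replace = TRUE),
                            dim = c(40, 40, 3)))
  seg <- segment_image(img, mode = "exclusive")
  stack <- Reduce(`+`, lapply(seg$masks, function(m) m + 0L))
  expect_true(all(stack <= 1L))
  expect_equal(sum(seg$proportions), 1, tolerance = 1e-12)
  ne <- segment_image(img, mode = "non_exclusive")
  for (nm in names(seg$masks)) {
    expect_true(all(ne$masks[[nm]] >= seg$masks[[nm]]))  # superset, per color
  }
})

test_that("segmentation recovers generator ground truth exactly", {
  out <- gen_landscape_image(c(red = 0.6, green = 0.3, white = 0.1), "blocks",
                             size = c(40, 50), seed = 3)
  seg <- segment_image(out$image, mode = "exclusive")
  expect_equal(unname(seg$proportions[c("red", "green", "white")]),
               c(0.6, 0.3, 0.1))
  expect_identical(seg$masks$red, out$masks$red)
  expect_identical(seg$masks$green, out$masks$green)
  props <- composition_proportions(seg)
  expect_equal(sum(props), 1)
})

test_that("all-background images classify nothing and error on proportions", {
  img <- as_rgb_image(array(10L, dim = c(8, 8, 3)))
  seg <- segment_image(img, mode = "exclusive")
  expect_equal(seg$unclassified_fraction, 1)
  expect_true(all(seg$proportions == 0))
  expect_error(composition_proportions(seg), "degenerate")
})

test_that("image loading round-trips PNG, drops alpha, promotes grayscale", {
  path <- withr::local_tempfile(fileext = ".png")
  out <- gen_landscape_image(c(green = 1), "blocks", size = c(3, 3), seed = 1)
  write_image_png(out$image, path)
  expect_identical(unclass(load_image(path)), unclass(out$image))

  rgba <- array(runif(4 * 4 * 4), dim = c(4, 4, 4))
  p2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgba, p2)
  loaded <- load_image(p2)
  expect_equal(dim(loaded), c(4, 4, 3))
  expect_equal(unclass(loaded), array(round(rgba[, , 1:3] * 255), dim = c(4, 4, 3)),
               ignore_attr = TRUE)

  gray <- matrix(runif(9), 3, 3)
  p3 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(gray, p3)
  g <- load_image(p3)
  expect_equal(g[, , 1], g[, , 2])
  expect_equal(g[, , 1], g[, , 3])
})

test_that("unreadable or unsupported files raise I/O errors", {
  expect_error(load_image("no/such/file.png"), "not found")
  p <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", p)
  expect_error(load_image(p), "decode")
  p4 <- withr::local_tempfile(fileext = ".bmp")
  file.create(p4)
  expect_error(load_image(p4), "unsupported")
})
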