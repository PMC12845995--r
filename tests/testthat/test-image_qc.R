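test_that("all sharpness and contrast metrics vanish exactly on constant images", {
  img <- gen_test_images("constant", size = 16, value = 77)
  expect_equal(laplacian_variance(img), 0)
  expect_equal(edge_gradient_mean(img), 0)
  expect_equal(tenengrad(img), 0)
  expect_equal(rms_contrast(img), 0)
  nz <- gen_test_images("checkerboard", size = 16)
  expect_gt(laplacian_variance(nz), 0)
  expect_gt(edge_gradient_mean(nz), 0)
  expect_gt(tenengrad(nz), 0)
  expect_gt(rms_contrast(nz), 0)
  expect_error(laplacian_variance(matrix(0, 2, 2)), "3x3")
})

test_that("Laplacian variance matches the hand-computed impulse response", {
  img <- matrix(0, 5, 5); img[3, 3] <- 1
  # response: -4 at the impulse, +1 at its four neighbors, 0 elsewhere;
  # mean 0, variance (16 + 4) / 25
  expect_equal(laplacian_variance(img), 0.8)
})

test_that("Sobel responses on a vertical step edge are 4h columnwise", {
  h <- 100
  img <- gen_test_images("step", size = 6, step_height = h)
  gx <- fatiguemap:::conv3(img, fatiguemap:::.sobel_x)
  gy <- fatiguemap:::conv3(img, fatiguemap:::.sobel_y)
  mag <- sqrt(gx^2 + gy^2)
  expect_true(all(abs(mag[, 3:4] - 4 * h) < 1e-9))   # flanking the step
  expect_true(all(mag[, c(1, 2, 5, 6)] == 0))
  expect_equal(edge_gradient_mean(img), mean(mag))
  # shared-intermediate consistency: TG is the mean squared magnitude
  expect_equal(tenengrad(img), mean(mag^2))
})

test_that("EGM is rotation-invariant and TG quadratically homogeneous", {
  img <- gen_test_images("checkerboard", size = 12, period = 3)
  rot90 <- t(img)[, nrow(img):1]
  expect_equal(edge_gradient_mean(rot90), edge_gradient_mean(img))
  expect_equal(tenengrad(2 * img), 4 * tenengrad(img))
  expect_equal(rms_contrast(img + 50), rms_contrast(img))
})

test_that("RMS contrast of a two-pixel {0,1} image is one half", {
  expect_equal(rms_contrast(matrix(c(0, 1), 1, 2)), 0.5)
})

test_that("sharpness metrics decrease monotonically under repeated box blur", {
  img <- gen_test_images("checkerboard", size = 24, period = 4)
  lv <- egm <- tg <- numeric(4)
  cur <- img
  for (k in 1:4) {
    lv[k] <- laplacian_variance(cur)
    egm[k] <- edge_gradient_mean(cur)
    tg[k] <- tenengrad(cur)
    cur <- box_blur3(cur)
  }
  expect_true(all(diff(lv) < 0))
  expect_true(all(diff(egm) < 0))
  expect_true(all(diff(tg) < 0))
})

test_that("color-cast index is the channel-mean spread, permutation-invariant", {
  mk <- function(means) {
    a <- array(0, c(6, 6, 3))
    for (k in 1:3) a[, , k] <- means[k]
    a
  }
  cc <- color_cast_index(mk(c(251.04, 215.86, 101.64)))
  expect_equal(cc$D, 149.40)
  expect_equal(color_cast_index(mk(c(239.32, 237.04, 225.00)))$D, 14.32)
  expect_equal(color_cast_index(mk(c(120, 120, 120)))$D, 0)
  perm <- mk(c(101.64, 251.04, 215.86))
  expect_equal(color_cast_index(perm)$D, cc$D)
  # ROI restriction
  a <- mk(c(10, 10, 10)); a[1:3, 1:3, 1] <- 200
  expect_equal(color_cast_index(a, roi = c(4, 4, 3, 3))$D, 0)
  expect_error(color_cast_index(a, roi = c(5, 5, 9, 9)), "bounds")
  expect_error(color_cast_index(a, roi = c(1, 1, 0, 2)), "empty ROI")
})

test_that("IAQ features match a straight-line reimplementation", {
  set.seed(2)
  g <- outer(1:20, 1:20, function(i, j) 5 * i + 3 * j) +
    matrix(runif(400, 0, 40), 20, 20)
  prev <- g + matrix(rnorm(400, 0, 5), 20, 20)
  ours <- iaq_features(g, prev, window = 8, stride = 4)
  ref <- iaq_features_oracle(g, prev, window = 8, stride = 4)
  expect_equal(as.numeric(ours), as.numeric(ref), tolerance = 1e-10)
})

test_that("temporal and spectral features behave at their anchors", {
  img <- gen_test_images("checkerboard", size = 16)
  expect_equal(iaq_features(img, img)[["c_temp"]], 1)
  grad <- gen_test_images("gradient", size = 32)
  expect_lt(iaq_features(grad)[["r_hf"]], 0.01)  # energy stays low-frequency
  expect_gt(iaq_features(img)[["r_hf"]], 0.05)
  expect_equal(iaq_features(img)[["c_temp"]], 1) # no previous frame
  expect_error(iaq_features(img, gen_test_images("constant", size = 8)),
               "different sizes")
})

test_that("the risk gate z-scores, fuses and routes with inclusive threshold", {
  stats <- list(mean = rep(1, 5), sd = rep(2, 5))
  feats <- structure(rep(1, 5), class = "iaq_features")
  g0 <- iaq_gate(feats, stats, w = rep(0.2, 5), tau = 0)
  expect_equal(g0$score, 0)
  expect_equal(g0$decision, "BYPASS")        # boundary uses >=
  gz <- iaq_gate(structure(runif(5), class = "iaq_features"), stats,
                 w = rep(0, 5), tau = 0.5)
  expect_equal(gz$score, 0)
  expect_equal(gz$decision, "ROBUST")
  expect_error(iaq_gate(feats, list(mean = rep(0, 5), sd = rep(0, 5)),
                        rep(1, 5), 0), "zero")
  # monotone weights: inflating a feature never flips BYPASS to ROBUST
  w <- c(0.5, 0.1, 0.2, 0.1, 0.1)
  f1 <- structure(c(3, 1, 1, 1, 1), class = "iaq_features")
  f2 <- structure(c(5, 1, 1, 1, 1), class = "iaq_features")
  d1 <- iaq_gate(f1, stats, w, tau = 0.4)$score
  d2 <- iaq_gate(f2, stats, w, tau = 0.4)$score
  expect_gte(d2, d1)
})

test_that("routing partitions a frame sequence exactly once per frame", {
  frames <- list(gen_test_images("checkerboard", size = 16),
                 gen_test_images("blurred", size = 16),
                 gen_test_images("gradient", size = 16),
                 gen_test_images("constant", size = 16, value = 10))
  st <- fit_iaq_stats(frames)
  keep <- st$sd > 0
  st$sd[!keep] <- 1
  tab <- iaq_route(frames, st, w = c(1, 1, 1, 0, -1) * as.numeric(keep),
                   tau = 0.5)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$decision %in% c("ROBUST", "BYPASS")))
  expect_equal(tab$frame, 1:4)
})

test_that("PNG frames round-trip through the qc metric table", {
  img <- gen_test_images("checkerboard", size = 16) / 255
  f1 <- tempfile(fileext = ".png")
  png::writePNG(img, f1)
  rgb <- array(0, c(8, 8, 3)); rgb[, , 1] <- 0.8; rgb[, , 2] <- 0.4
  f2 <- tempfile(fileext = ".png")
  png::writePNG(rgb, f2)
  tab <- qc_metrics(c(f1, f2))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$rms[2], 0)
  expect_gt(tab$tg[1], 0)
  cc <- color_cast_index(read_image(f2))
  expect_equal(cc$D, 0.8 * 255, tolerance = 1e-2)
})

test_that("the enhancer interface substitutes paths into the command", {
  enh <- make_enhancer("cp {input} {output}")
  src <- tempfile(); writeLines("x", src)
  dst <- tempfile()
  out <- enh(src, dst)
  expect_equal(readLines(out), "x")
  expect_error(make_enhancer("no placeholders"))
})
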