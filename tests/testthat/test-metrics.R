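test_that("psnr matches closed forms and the brute-force definition", {
  a <- rand_image(6, 6, seed = 1)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 1), 20 * log10(255), tolerance = 1e-9)
  # MSE = 255^2 -> 0 dB
  z <- array(0, c(4, 4, 3))
  expect_equal(psnr(z, z + 255), 0, tolerance = 1e-9)
  expect_error(psnr(a, array(0, c(3, 3, 3))), "shape")

  withr::with_seed(2, {
    for (rep in 1:100) {
      h <- sample(2:5, 1); w <- sample(2:5, 1)
      x <- array(runif(h * w * 3) * 255, c(h, w, 3))
      y <- array(runif(h * w * 3) * 255, c(h, w, 3))
      mse <- 0
      for (i in 1:h) for (j in 1:w) for (c in 1:3) mse <- mse + (x[i, j, c] - y[i, j, c])^2
      mse <- mse / (h * w * 3)
      expect_lt(abs(psnr(x, y) - 10 * log10(255^2 / mse)), 1e-9)
    }
  })
})

test_that("HunterLab conversion is neutral-correct and matches a reference path", {
  gray <- rgb_to_hunterlab(c(128, 128, 128))
  expect_lt(abs(gray["a"]), 1e-6)
  expect_lt(abs(gray["b"]), 1e-6)
  white <- rgb_to_hunterlab(c(255, 255, 255))
  expect_equal(unname(white["L"]), 100, tolerance = 0.1)
  expect_gt(rgb_to_hunterlab(c(255, 140, 0))["a"], 0)   # saturated orange
  expect_lt(rgb_to_hunterlab(c(60, 200, 60))["a"], 0)   # saturated green
  expect_error(rgb_to_hunterlab(c(-1, 0, 0)), "\\[0, 255\\]")

  # independent oracle: the sRGB -> XYZ matrix re-derived from the
  # chromaticity coordinates of the primaries and the D65 white, rather
  # than taken from the tabulated matrix the implementation uses
  for (i in seq_len(nrow(hunterlab_grid()))) {
    rgb <- as.numeric(hunterlab_grid()[i, ])
    expect_lt(max(abs(rgb_to_hunterlab(rgb) - hunterlab_oracle(rgb))), 0.5)
  }
  # convertColor's primaries-based sRGB pipeline lands close as well
  cc <- grDevices::convertColor(matrix(c(225, 30, 30) / 255, 1), "sRGB", "XYZ") * 100
  mine <- rgb_to_hunterlab(c(225, 30, 30))
  xr <- cc[1] / 95.047; yr <- cc[2] / 100; zr <- cc[3] / 108.883
  expect_lt(abs(mine["L"] - 100 * sqrt(yr)), 1)
  expect_lt(abs(mine["a"] - 172.30 * (xr - yr) / sqrt(yr)), 1)
})

test_that("CCI is sign-consistent, mask-local and linear in Hunter a/(L b)", {
  gray <- const_fruit_image(8, 8, 3:6, 3:6, c(128, 128, 128))
  expect_equal(cci(gray$image, gray$mask), 0)

  green <- const_fruit_image(8, 8, 3:6, 3:6, c(70, 190, 60))
  orange <- const_fruit_image(8, 8, 3:6, 3:6, c(235, 140, 25))
  expect_lt(cci(green$image, green$mask), 0)
  expect_gt(cci(orange$image, orange$mask), 0)

  # background randomization leaves CCI unchanged
  withr::with_seed(3, {
    pert <- orange$image
    noise <- array(runif(8 * 8 * 3) * 255, c(8, 8, 3))
    m3 <- array(rep(orange$mask, 3), c(8, 8, 3))
    pert <- pert * m3 + noise * (1 - m3)
  })
  expect_identical(cci(pert, orange$mask), cci(orange$image, orange$mask))

  # direct arithmetic on a constant-color fruit
  lab <- rgb_to_hunterlab(c(235, 140, 25))
  expect_equal(cci(orange$image, orange$mask),
               unname(1000 * lab["a"] / (lab["L"] * lab["b"])))

  expect_error(cci(orange$image, matrix(0, 8, 8)), "empty")
})

test_that("CCI error is the symmetric L1 distance between the two indices", {
  a <- const_fruit_image(8, 8, 3:6, 3:6, c(235, 140, 25))
  b <- const_fruit_image(8, 8, 2:5, 2:5, c(70, 190, 60))
  expect_equal(cci_error(a$image, a$image, a$mask, a$mask), 0)
  e1 <- cci_error(a$image, b$image, a$mask, b$mask)
  e2 <- cci_error(b$image, a$image, b$mask, a$mask)
  expect_equal(e1, e2)
  expect_equal(e1, abs(cci(a$image, a$mask) - cci(b$image, b$mask)))
})

test_that("mlsl averages the local style loss over pairs", {
  ex <- feature_extractor("identity")
  cfg <- style_config(style_layers = "pixels", content_layers = "pixels")
  mk <- function(rgb) const_fruit_image(8, 8, 3:6, 3:6, rgb)
  p1 <- list(generated = mk(c(230, 150, 30))$image, truth = mk(c(230, 150, 30))$image,
             generated_mask = mk(1:3)$mask, truth_mask = mk(1:3)$mask)
  expect_equal(mlsl(list(p1, p1), ex, cfg), 0)

  g <- mk(c(120, 200, 60)); t2 <- mk(c(230, 150, 30))
  p2 <- list(generated = g$image, truth = t2$image,
             generated_mask = g$mask, truth_mask = t2$mask)
  single <- local_style_loss(extract_features(t2$image, ex, "pixels"),
                             extract_features(g$image, ex, "pixels"),
                             t2$mask, g$mask, cfg)
  expect_equal(mlsl(list(p2), ex, cfg), single)
  expect_equal(mlsl(list(p1, p2), ex, cfg), (0 + single) / 2)
  expect_error(mlsl(list(), ex, cfg), "empty")
})

test_that("miou equals the per-pixel confusion-matrix oracle", {
  # identity
  m <- rand_mask(6, 6, seed = 4)
  expect_equal(miou(m, m), 1)
  # left-half vs right-half fruit: both class IoUs 0
  l <- matrix(0, 4, 4); l[, 1:2] <- 1
  r <- matrix(0, 4, 4); r[, 3:4] <- 1
  expect_equal(miou(l, r), 0)
  # all-fruit prediction vs half-fruit truth -> (0.5 + 0) / 2
  all1 <- matrix(1, 4, 4)
  half <- matrix(0, 4, 4); half[1:2, ] <- 1
  expect_equal(miou(all1, half), 0.25)

  oracle <- function(preds, truths) {
    tp <- fp <- fn <- tn <- 0
    for (k in seq_along(preds)) {
      p <- preds[[k]]; g <- truths[[k]]
      for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
        if (p[i, j] == 1 && g[i, j] == 1) tp <- tp + 1
        if (p[i, j] == 1 && g[i, j] == 0) fp <- fp + 1
        if (p[i, j] == 0 && g[i, j] == 1) fn <- fn + 1
        if (p[i, j] == 0 && g[i, j] == 0) tn <- tn + 1
      }
    }
    (tp / (tp + fp + fn) + tn / (tn + fp + fn)) / 2
  }
  withr::with_seed(5, {
    for (rep in 1:100) {
      n <- sample(1:3, 1)
      preds <- lapply(seq_len(n), function(i) matrix(rbinom(16, 1, 0.5), 4, 4))
      truths <- lapply(seq_len(n), function(i) matrix(rbinom(16, 1, 0.5), 4, 4))
      expect_identical(miou(preds, truths), oracle(preds, truths))
    }
  })
  expect_error(miou(list(), list()), "non-empty")
})
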