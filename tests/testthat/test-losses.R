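id_extractor <- feature_extractor("identity")

feats_of <- function(img, layers = "pixels", ex = id_extractor) {
  extract_features(img, ex, layers)
}

test_that("extractors expose named layers with the documented geometry", {
  img <- rand_image(4, 4, seed = 2)
  f <- extract_features(img, id_extractor)
  expect_named(f, "pixels")
  expect_equal(dim(f$pixels), c(3, 4, 4))
  # channel-first pixels, exactly
  expect_equal(f$pixels[2, 3, 4], img[3, 4, 2])
  expect_error(extract_features(img, id_extractor, "Conv9_9"), "unknown layer")

  vgg <- feature_extractor("vgg", channels = c(4, 8, 8, 8, 8), seed = 3)
  img32 <- rand_image(16, 16, seed = 4)
  fv <- extract_features(img32, vgg, c("Conv1_1", "Conv2_1", "Conv3_1"))
  expect_equal(dim(fv$Conv1_1), c(4, 16, 16))
  expect_equal(dim(fv$Conv2_1), c(8, 8, 8))    # input size / 2
  expect_equal(dim(fv$Conv3_1), c(8, 4, 4))
  # deterministic: repeated calls identical
  expect_identical(fv, extract_features(img32, vgg, c("Conv1_1", "Conv2_1", "Conv3_1")))
})

test_that("gram matches hand values and the brute-force channel-pair loop", {
  # single channel of ones on 2x2: G = [[4]]
  expect_equal(gram(array(1, c(1, 2, 2))), matrix(4, 1, 1))
  # orthogonal flattened rows -> identity
  f <- array(0, c(2, 1, 2))
  f[1, 1, 1] <- 1; f[2, 1, 2] <- 1
  expect_equal(gram(f), diag(2))
  expect_equal(gram(array(0, c(3, 2, 2))), matrix(0, 3, 3))

  withr::with_seed(11, {
    for (rep in 1:100) {
      C <- sample(2:4, 1); H <- sample(2:5, 1); W <- sample(2:3, 1)
      f <- array(rnorm(C * H * W), c(C, H, W))
      G <- gram(f)
      Gb <- matrix(0, C, C)
      for (m in 1:C) for (n in 1:C) {
        Gb[m, n] <- sum(as.vector(f[m, , ]) * as.vector(f[n, , ]))
      }
      expect_lt(max(abs(G - Gb)), 1e-5)
      expect_equal(G, t(G))
      expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    }
  })
})

test_that("masked normalized gram is area-invariant for constant colors", {
  cvec <- c(0.9, 0.5, 0.1)
  make_const <- function(h, w, area_rows) {
    f <- array(0, c(3, h, w))
    m <- matrix(0, h, w)
    m[area_rows, ] <- 1
    for (ch in 1:3) f[ch, , ] <- cvec[ch] * m
    list(f = f, m = m)
  }
  small <- make_const(10, 1, 1:10)        # area 10
  big <- make_const(100, 10, 1:100)       # area 1000
  expect_equal(masked_normalized_gram(small$f, small$m), outer(cvec, cvec),
               tolerance = 1e-12)
  expect_equal(masked_normalized_gram(big$f, big$m), outer(cvec, cvec),
               tolerance = 1e-12)

  # all-ones mask reduces to gram / (H * W)
  f <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  expect_equal(masked_normalized_gram(f, matrix(1, 4, 5)), gram(f) / 20)

  expect_error(masked_normalized_gram(f, matrix(0, 4, 5)), "degenerate",
               class = "rindcast_degenerate_mask")

  # brute-force equivalence on random masked tensors
  withr::with_seed(12, {
    for (rep in 1:100) {
      C <- sample(2:4, 1); H <- sample(2:4, 1); W <- sample(2:4, 1)
      f <- array(rnorm(C * H * W), c(C, H, W))
      m <- matrix(rbinom(H * W, 1, 0.6), H, W)
      if (sum(m) == 0) m[1, 1] <- 1
      fm <- f
      for (ch in 1:C) fm[ch, , ] <- f[ch, , ] * m
      expect_lt(max(abs(masked_normalized_gram(f, m) - gram(fm) / sum(m))), 1e-5)
    }
  })
})

test_that("content loss follows the normalized squared-difference formula", {
  img <- rand_image(4, 4, seed = 5)
  fx <- feats_of(img)
  expect_equal(content_loss(fx, fx), 0)
  # uniform +1 shift, mean of 1 per layer; two listed layers sum to 2
  fy <- feats_of(img + 1)
  expect_equal(content_loss(fx, fy, c("pixels", "pixels")), 2)
  # single-pixel difference d on an N-element map -> d^2 / N
  img2 <- img
  img2[2, 3, 1] <- img2[2, 3, 1] + 7
  expect_equal(content_loss(fx, feats_of(img2)), 49 / (4 * 4 * 3))
})

test_that("local style loss is zero on identity, symmetric, and mask-local", {
  fr <- const_fruit_image(8, 8, 2:5, 3:6, c(230, 150, 30))
  cfg <- style_config(style_layers = "pixels", content_layers = "pixels")
  f <- feats_of(fr$image)
  expect_equal(local_style_loss(f, f, fr$mask, fr$mask, cfg), 0)

  other <- const_fruit_image(8, 8, 2:5, 3:6, c(120, 200, 60))
  g <- feats_of(other$image)
  l1 <- local_style_loss(f, g, fr$mask, other$mask, cfg)
  l2 <- local_style_loss(g, f, other$mask, fr$mask, cfg)
  expect_gt(l1, 0)
  expect_equal(l1, l2)

  # background-only perturbation leaves the local loss unchanged, exactly
  pert <- fr$image
  pert[, , 1] <- pert[, , 1] + 90 * (1 - fr$mask)
  expect_identical(local_style_loss(f, feats_of(pert), fr$mask, fr$mask, cfg),
                   local_style_loss(f, f, fr$mask, fr$mask, cfg))

  # degenerate mask errors name the layer
  expect_error(local_style_loss(f, g, matrix(0, 8, 8), fr$mask, cfg),
               "pixels", class = "rindcast_degenerate_mask")

  # closed form for constant colors on arbitrary-size masks
  c1 <- c(230, 150, 30); c2 <- c(120, 200, 60)
  pref <- 1 / (8 * 8 * 3)^2  # as_printed on the pixel layer
  expected <- pref * sum((outer(c1, c1) - outer(c2, c2))^2)
  expect_equal(local_style_loss(f, g, fr$mask, other$mask, cfg), expected,
               tolerance = 1e-10)
})

test_that("local perceptual loss decomposes into content + style", {
  cfg <- style_config(style_layers = "pixels", content_layers = "pixels")
  x <- const_fruit_image(8, 8, 2:5, 2:5, c(80, 190, 60))
  y <- const_fruit_image(8, 8, 2:5, 2:5, c(230, 150, 30))
  fx <- feats_of(x$image); fy <- feats_of(y$image)
  expect_equal(local_perceptual_loss(fx, fx, fx, x$mask, x$mask, cfg), 0)
  # identical styles zero the style term
  expect_equal(local_perceptual_loss(fx, fy, fy, y$mask, y$mask, cfg),
               content_loss(fx, fy, "pixels"))
  # additivity
  both <- local_perceptual_loss(fx, fy, fy, y$mask, x$mask, cfg)
  expect_equal(both, content_loss(fx, fy, "pixels") +
                 local_style_loss(fy, fy, y$mask, x$mask, cfg))
  # configurable weights scale the terms
  cfg2 <- style_config(style_layers = "pixels", content_layers = "pixels",
                       content_weight = 2, style_weight = 0)
  expect_equal(local_perceptual_loss(fx, fy, fy, y$mask, y$mask, cfg2),
               2 * content_loss(fx, fy, "pixels"))
})

test_that("global style loss follows its formula and is size-sensitive", {
  cfg <- style_config(style_layers = "pixels")
  a <- rand_image(2, 2, seed = 8)
  b <- rand_image(2, 2, seed = 9)
  fa <- feats_of(a); fb <- feats_of(b)
  expect_equal(style_loss_gatys(fa, fa, cfg), 0)
  expect_equal(style_loss_gatys(fa, fb, cfg),
               sum((gram(fa$pixels) - gram(fb$pixels))^2) / (2 * 2 * 3)^2)

  # doubling a constant-textured fruit's area: local loss invariant,
  # global and black-background losses change
  small <- const_fruit_image(8, 8, 3:4, 3:4, c(230, 150, 30), bg_rgb = c(0, 0, 0))
  big <- const_fruit_image(8, 8, 3:6, 3:4, c(230, 150, 30), bg_rgb = c(0, 0, 0))
  fs <- feats_of(small$image); fbg <- feats_of(big$image)
  lcfg <- style_config(style_layers = "pixels")
  expect_equal(local_style_loss(fs, fbg, small$mask, big$mask, lcfg), 0,
               tolerance = 1e-12)
  expect_gt(style_loss_gatys(fs, fbg, lcfg), 0)
  expect_gt(style_loss_blackbg(small$image, big$image, small$mask, big$mask,
                               id_extractor, lcfg), 0)
})

test_that("black-background loss zeroes background influence only", {
  cfg <- style_config(style_layers = "pixels")
  fr <- const_fruit_image(8, 8, 2:5, 3:6, c(230, 150, 30))
  expect_equal(style_loss_blackbg(fr$image, fr$image, fr$mask, fr$mask,
                                  id_extractor, cfg), 0)
  # background-only change -> 0 (background zeroed before comparing)
  pert <- fr$image
  pert[, , 2] <- pert[, , 2] + 60 * (1 - fr$mask)
  expect_equal(style_loss_blackbg(fr$image, pert, fr$mask, fr$mask,
                                  id_extractor, cfg), 0)
  # equals the global loss applied to mask-multiplied images
  other <- const_fruit_image(8, 8, 2:4, 2:4, c(120, 200, 60))
  blacken <- function(img, m) img * array(rep(m, 3), dim(img))
  expect_equal(
    style_loss_blackbg(fr$image, other$image, fr$mask, other$mask,
                       id_extractor, cfg),
    style_loss_gatys(feats_of(blacken(fr$image, fr$mask)),
                     feats_of(blacken(other$image, other$mask)), cfg))
})

test_that("style-difference matrices are symmetric and match pairwise calls", {
  cfg <- style_config(style_layers = "pixels")
  imgs <- lapply(1:4, function(i)
    const_fruit_image(8, 8, 2:5, 2:5, c(60 * i, 250 - 40 * i, 30))$image)
  masks <- lapply(1:4, function(i)
    const_fruit_image(8, 8, 2:5, 2:5, c(1, 1, 1))$mask)
  for (metric in c("gatys", "blackbg", "local")) {
    M <- style_difference_matrix(imgs, masks, metric, id_extractor, cfg)
    expect_equal(M, t(M))
    expect_equal(diag(M), rep(0, 4))
    # spot-check one pair against the direct call
    direct <- switch(metric,
      gatys = style_loss_gatys(feats_of(imgs[[1]]), feats_of(imgs[[3]]), cfg),
      local = local_style_loss(feats_of(imgs[[1]]), feats_of(imgs[[3]]),
                               masks[[1]], masks[[3]], cfg),
      blackbg = style_loss_blackbg(imgs[[1]], imgs[[3]], masks[[1]], masks[[3]],
                                   id_extractor, cfg))
    expect_equal(M[1, 3], direct)
  }
  # identical images -> zero matrix
  M0 <- style_difference_matrix(imgs[c(1, 1)], masks[c(1, 1)], "gatys",
                                id_extractor, cfg)
  expect_equal(M0, matrix(0, 2, 2))
  # quantization contract
  Mq <- style_difference_matrix(imgs, masks, "local", id_extractor, cfg,
                                quantize = TRUE)
  expect_true(all(Mq %in% 1:5))
  expect_error(style_difference_matrix(imgs, NULL, "local", id_extractor, cfg),
               "mask")
})

test_that("prefactor conventions rescale but never reorder single-layer comparisons", {
  imgs <- lapply(1:4, function(i)
    const_fruit_image(8, 8, 2:5, 2:5, c(50 * i, 240 - 30 * i, 40 + 10 * i)))
  cfg_p <- style_config(style_layers = "pixels", prefactor_convention = "as_printed")
  cfg_c <- style_config(style_layers = "pixels", prefactor_convention = "channels_only")
  Mp <- style_difference_matrix(lapply(imgs, `[[`, "image"),
                                lapply(imgs, `[[`, "mask"), "local",
                                id_extractor, cfg_p)
  Mc <- style_difference_matrix(lapply(imgs, `[[`, "image"),
                                lapply(imgs, `[[`, "mask"), "local",
                                id_extractor, cfg_c)
  up <- upper.tri(Mp)
  # exact scalar rescaling on a single layer: ratio (HWC)^2 / C^2
  expect_equal(Mc[up] / Mp[up], rep((8 * 8 * 3)^2 / 9, sum(up)))
  expect_equal(order(Mp[up]), order(Mc[up]))
})

test_that("eroded-mask local style loss is robust to background under the conv extractor", {
  vgg <- feature_extractor("vgg", channels = c(4, 8, 8, 8, 8), seed = 6)
  cfg <- style_config(style_layers = c("Conv1_1", "Conv2_1"))
  # fruit occupies 5..28; the eroded mask keeps 13..20, i.e. a margin of 8
  # pixels, beyond the Conv2_1 receptive-field radius (5)
  base <- const_fruit_image(32, 32, 5:28, 5:28, c(230, 150, 30))
  pert <- base$image
  pert[, , 1] <- pmin(255, pert[, , 1] + 120 * (1 - base$mask))
  eroded <- matrix(0, 32, 32)
  eroded[13:20, 13:20] <- 1
  fb <- extract_features(base$image, vgg, cfg$style_layers)
  fp <- extract_features(pert, vgg, cfg$style_layers)
  self <- local_style_loss(fb, fb, eroded, eroded, cfg)
  cross <- local_style_loss(fb, fp, eroded, eroded, cfg)
  ref <- local_style_loss(fb, extract_features(base$image * 0.5, vgg,
                                               cfg$style_layers),
                          eroded, eroded, cfg)
  expect_equal(self, 0)
  # background perturbation changes the eroded-mask loss far less than a
  # genuine fruit change does
  expect_lt(cross, 0.01 * ref)
})
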