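tiny_gen_cfg <- function(...) {
  args <- utils::modifyList(
    list(input_size = c(16, 16), stem_channels = c(8, 64), n_resblocks = 1L,
         n_max = 12L, batch_size = 2L, epochs = 2L),
    list(...))
  do.call(generator_config, args)
}

test_that("generator output obeys shape, range and stride arithmetic", {
  cfg <- tiny_gen_cfg()
  m <- build_generator(cfg, seed = 1)
  img <- rand_image(16, 16, seed = 1)
  out <- predict(m, img, rand_mask(16, 16, seed = 2), N = 5, composite = FALSE)
  expect_equal(dim(out), c(16, 16, 3))
  # scaled tanh bound holds on random weights
  expect_true(min(out) >= 0 && max(out) <= 255)
  # two stride-2 stems: bottleneck spatial size input/4
  X <- array(img, c(16, 16, 3, 1))
  p <- m$params
  h1 <- rindcast:::relu_fw(rindcast:::instnorm_fw(
    rindcast:::conv_fw(X / 127.5 - 1, p$stem1$W, p$stem1$b, 4L, 2L,
                       c(1L, 1L, 1L, 1L))$out,
    p$stem1_norm$gamma, p$stem1_norm$beta)$out)$out
  expect_equal(dim(h1)[1:2], c(8, 8))
  h2 <- rindcast:::conv_fw(h1, p$stem2$W, p$stem2$b, 4L, 2L,
                           c(1L, 1L, 1L, 1L))$out
  expect_equal(dim(h2)[1:3], c(4, 4, 64))
  # config validation
  expect_error(generator_config(stem_channels = c(16, 32)), "64")
  expect_error(generator_config(input_size = c(30, 30)), "divisible")
})

test_that("time-embedding gating is an exact per-channel multiply", {
  table <- matrix(1, 10, 64)
  f <- withr::with_seed(3, array(rnorm(64 * 4 * 4), c(64, 4, 4)))
  # all-ones vector: identity
  expect_identical(apply_time_embedding(f, 3, table, "encoder"), f)
  # all-zeros: annihilation
  table0 <- matrix(0, 10, 64)
  expect_identical(apply_time_embedding(f, 3, table0, "decoder"),
                   array(0, dim(f)))
  # selective doubling of channel 1
  table2 <- matrix(1, 10, 64)
  table2[7, 1] <- 2
  g <- apply_time_embedding(f, 7, table2, "encoder")
  expect_equal(g[1, , ], 2 * f[1, , ])
  expect_equal(g[-1, , ], f[-1, , ])
  # brute-force per-channel oracle
  tableR <- withr::with_seed(4, matrix(rnorm(10 * 64), 10, 64))
  g2 <- apply_time_embedding(f, 5, tableR, "encoder")
  for (k in c(1, 17, 64)) expect_equal(g2[k, , ], f[k, , ] * tableR[5, k])
  # interval range enforced
  expect_error(apply_time_embedding(f, 0, table), "1..10")
  expect_error(apply_time_embedding(f, 11, table), "1..10")
})

test_that("resize convolution doubles resolution via nearest neighbor", {
  f <- withr::with_seed(5, array(rnorm(6 * 8 * 8), c(6, 8, 8)))
  out <- resize_conv(f, out_channels = 4, seed = 2)
  expect_equal(dim(out), c(4, 16, 16))
  # the interpolation stage replicates each pixel into a 2x2 block
  up <- upsample_nearest(f)
  expect_equal(dim(up), c(6, 16, 16))
  for (k in 1:6) for (i in c(1, 5)) for (j in c(2, 7)) {
    expect_equal(unique(as.vector(up[k, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])),
                 f[k, i, j])
  }
  # constant input stays constant through interpolation
  expect_equal(upsample_nearest(array(3, c(2, 4, 4))), array(3, c(2, 8, 8)))
})

test_that("background re-fusion composites exactly and idempotently", {
  gen <- rand_image(8, 8, seed = 6)
  orig <- rand_image(8, 8, seed = 7)
  m <- rand_mask(8, 8, seed = 8)
  out <- composite_background(gen, orig, m)
  # mask extremes
  expect_identical(composite_background(gen, orig, matrix(0, 8, 8)), orig)
  expect_identical(composite_background(gen, orig, matrix(1, 8, 8)), gen)
  # checkerboard selection matches a per-pixel loop
  cb <- matrix(rep_len(c(0, 1), 64), 8, 8)
  got <- composite_background(gen, orig, cb)
  for (i in 1:8) for (j in 1:8) for (c in 1:3) {
    expect_identical(got[i, j, c], if (cb[i, j] == 1) gen[i, j, c] else orig[i, j, c])
  }
  # background pixels bit-equal to the original
  expect_identical(out[, , 1][m == 0], orig[, , 1][m == 0])
  # idempotence
  expect_identical(composite_background(out, orig, m), out)
  expect_error(composite_background(gen, orig, matrix(1, 4, 4)), "height and width")
})

test_that("prediction is deterministic and re-fuses the background", {
  m <- build_generator(tiny_gen_cfg(), seed = 3)
  img <- rand_image(16, 16, seed = 9)
  msk <- rand_mask(16, 16, seed = 10)
  p1 <- predict(m, img, msk, N = 4)
  p2 <- predict(m, img, msk, N = 4)
  expect_identical(p1, p2)
  for (ch in 1:3) {
    expect_identical(p1[, , ch][msk == 0], img[, , ch][msk == 0])
  }
  expect_true(min(p1) >= 0 && max(p1) <= 255)
  expect_error(predict(m, img, msk, N = 0), "1..12")
  expect_error(predict(m, img, msk, N = 13), "1..12")
})

make_gen_pairs <- function(n, h = 16, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      fr <- const_fruit_image(h, h, 4:12, 4:12,
                              c(80 + 15 * i, 200 - 12 * i, 50))
      tg <- const_fruit_image(h, h, 4:12, 4:12,
                              c(150 + 10 * i, 170 - 10 * i, 40))
      list(input = fr$image + array(runif(h * h * 3) * 4, c(h, h, 3)),
           input_mask = fr$mask,
           target = tg$image + array(runif(h * h * 3) * 4, c(h, h, 3)),
           target_mask = tg$mask,
           N = 2L + (i %% 3L))
    })
  })
}

test_that("generator training records history, stays finite and is reproducible", {
  pairs <- make_gen_pairs(4)
  cfg <- tiny_gen_cfg(epochs = 2L)
  m <- train_generator(pairs, cfg, seed = 6)
  expect_equal(nrow(m$history), 2)
  expect_true(all(is.finite(m$history$train_loss)))
  expect_true(all(m$history$train_loss >= 0))
  m2 <- train_generator(pairs, cfg, seed = 6)
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)
  # the per-step loss equals the module-level local perceptual loss
  ex <- feature_extractor("identity", scale = 1 / 255)
  lcfg <- rindcast:::default_pixel_loss_cfg()
  pp <- pairs[[1]]
  pred <- predict(m, pp$input, pp$input_mask, pp$N)
  lg <- rindcast:::perceptual_loss_grad(pp$input, pp$target, pred,
                                        pp$input_mask, pp$target_mask, ex, lcfg)
  direct <- local_perceptual_loss(
    extract_features(pp$input, ex), extract_features(pp$target, ex),
    extract_features(pred, ex), pp$target_mask, pp$input_mask, lcfg)
  expect_equal(lg$loss, direct, tolerance = 1e-10)
})

test_that("degenerate target masks are skipped with a warning", {
  pairs <- make_gen_pairs(3)
  pairs[[2]]$target_mask <- matrix(0, 16, 16)
  expect_warning(m <- train_generator(pairs, tiny_gen_cfg(epochs = 1L), seed = 1),
                 "degenerate")
  expect_equal(nrow(m$history), 1)
})

test_that("two-stage model selection ranks by MLSL then PSNR", {
  h <- tibble::tibble(epoch = 1:12,
                      val_mlsl = c(5, 4, 3, 2, 1, 1.5, 2.5, 3.5, 4.5, 5.5, 6, 7),
                      val_psnr = c(10, 11, 12, 13, 14, 30, 15, 16, 17, 18, 19, 20))
  sel <- rindcast:::select_generator_epoch(h, validated = TRUE)
  expect_length(sel$mlsl_top10, 10)
  expect_false(any(c(11, 12) %in% sel$mlsl_top10))
  expect_length(sel$psnr_top5, 5)
  expect_equal(sel$best_epoch, 6)   # best PSNR among the MLSL short list
})

test_that("the fixed-interval ablation drops embeddings and ignores N", {
  pairs <- make_gen_pairs(3)
  for (i in seq_along(pairs)) pairs[[i]]$N <- 5L
  cfg <- tiny_gen_cfg(epochs = 1L)
  fm <- train_fixed_interval_generator(pairs, cfg, seed = 2)
  expect_false(fm$cfg$use_embedding)
  expect_equal(fm$fixed_interval, 5L)
  expect_null(fm$params$emb_enc)
  # ignores the N argument entirely
  img <- pairs[[1]]$input; msk <- pairs[[1]]$input_mask
  expect_identical(predict(fm, img, msk, N = 3), predict(fm, img, msk, N = 11))
  # strictly fewer parameters than the merged model
  merged <- build_generator(tiny_gen_cfg(), seed = 2)
  expect_lt(count_parameters(fm), count_parameters(merged))
  expect_equal(count_parameters(merged) - count_parameters(fm),
               2L * 12L * 64L)   # the two n_max x 64 embedding tables
  # mixed-N input rejected
  mixed <- make_gen_pairs(3)
  expect_error(train_fixed_interval_generator(mixed, cfg, seed = 2), "single N")
  # one merged weight set serves all intervals; the ablation needs one per N
  served <- vapply(c(5L, 10L), function(n) {
    dim(predict(merged, img, msk, n))[1]
  }, numeric(1))
  expect_equal(served, c(16, 16))
})
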