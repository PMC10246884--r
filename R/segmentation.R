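# Fruit/background semantic segmentation: a U-Net style encoder-decoder
# trained with a smoothed Dice loss.

#' Segmentation network configuration
#'
#' @param input_size `c(H, W)`; both must be divisible by
#'   `2^encoder_depth`. Default `c(192, 256)` (landscape full-scale
#'   imagery); desk-scale runs typically use `c(64, 64)`.
#' @param encoder_depth Number of 2x2 max-pool downsampling stages.
#' @param base_channels Channels of the first encoder stage (doubled per
#'   stage).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 56).
#' @param epochs Training epochs (default 50).
#' @param binarize_threshold Probability threshold for [predict_mask()]
#'   (strict `>`; default 0.5).
#' @param use_norm Apply instance normalization after each convolution
#'   (default `FALSE` for the small configuration).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(input_size = c(192, 256), encoder_depth = 4L,
                       base_channels = 16L, learning_rate = 1e-3,
                       batch_size = 56L, epochs = 50L,
                       binarize_threshold = 0.5, use_norm = FALSE) {
  assert_that(encoder_depth >= 1, "encoder_depth must be >= 1")
  div <- 2^encoder_depth
  assert_that(all(input_size %% div == 0),
              sprintf("input size must be divisible by 2^depth = %d", div))
  assert_that(binarize_threshold > 0 && binarize_threshold < 1,
              "binarize_threshold must lie in (0, 1)")
  structure(list(input_size = input_size, encoder_depth = as.integer(encoder_depth),
                 base_channels = as.integer(base_channels),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 binarize_threshold = binarize_threshold, use_norm = use_norm),
            class = "seg_config")
}

#' Build a segmentation model
#'
#' Constructs the U-Net: an encoder of repeated (3x3 conv, ReLU) x2 blocks
#' with 2x2 stride-2 max pooling, a symmetric decoder with nearest-neighbor
#' upsampling and skip concatenations from the matching encoder stages, and
#' a final 1x1 convolution with sigmoid producing a per-pixel fruit
#' probability map of the input's H x W.
#'
#' @param cfg A [seg_config()].
#' @param seed Seed for weight initialization.
#' @return An object of class `seg_model`.
#' @export
build_segmentation_model <- function(cfg, seed = 1L) {
  d <- cfg$encoder_depth
  ch <- cfg$base_channels * 2^(0:d)      # stages 1..d, bottleneck = ch[d+1]
  params <- with_seed(derive_seed(seed, 61L), {
    p <- list()
    cin <- 3L
    for (i in seq_len(d)) {
      p[[paste0("enc", i, "_c1")]] <- init_conv(3L, cin, ch[i])
      p[[paste0("enc", i, "_c2")]] <- init_conv(3L, ch[i], ch[i])
      cin <- ch[i]
    }
    p[["bot_c1"]] <- init_conv(3L, ch[d], ch[d + 1])
    p[["bot_c2"]] <- init_conv(3L, ch[d + 1], ch[d + 1])
    for (i in rev(seq_len(d))) {
      above <- if (i == d) ch[d + 1] else ch[i + 1]
      p[[paste0("up", i)]] <- init_conv(3L, above, ch[i])
      p[[paste0("dec", i, "_c1")]] <- init_conv(3L, 2L * ch[i], ch[i])
      p[[paste0("dec", i, "_c2")]] <- init_conv(3L, ch[i], ch[i])
    }
    p[["out"]] <- init_conv(1L, ch[1], 1L)
    if (cfg$use_norm) {
      for (nm in names(p)) {
        if (nm != "out") p[[paste0(nm, "_norm")]] <- init_norm(ncol(p[[nm]]$W))
      }
    }
    p
  })
  structure(list(cfg = cfg, params = params, history = NULL, seed = seed),
            class = "seg_model")
}

# Forward pass on a (H, W, 3, B) batch of [0,255] images. Returns the
# probability map (H, W, 1, B) and, if want_cache, the tape for backprop.
unet_forward <- function(model, X, want_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  d <- cfg$encoder_depth
  caches <- list()
  push <- function(cc) caches[[length(caches) + 1L]] <<- cc
  cblock <- function(h, nm, k = 3L) {
    pr <- p[[nm]]
    cv <- conv_fw(h, pr$W, pr$b, k, 1L, same_pad(k))
    h <- cv$out
    norm_cache <- NULL
    if (cfg$use_norm) {
      nrm <- p[[paste0(nm, "_norm")]]
      no <- instnorm_fw(h, nrm$gamma, nrm$beta)
      h <- no$out
      norm_cache <- no$cache
    }
    rl <- relu_fw(h)
    if (want_cache) push(list(kind = "conv", nm = nm, conv = cv$cache,
                              norm = norm_cache, relu = rl$cache))
    rl$out
  }
  skips <- vector("list", d)
  h <- X / 127.5 - 1
  for (i in seq_len(d)) {
    h <- cblock(h, paste0("enc", i, "_c1"))
    h <- cblock(h, paste0("enc", i, "_c2"))
    skips[[i]] <- h
    mp <- maxpool_fw(h)
    if (want_cache) push(list(kind = "pool", level = i, cache = mp$cache))
    h <- mp$out
  }
  h <- cblock(h, "bot_c1")
  h <- cblock(h, "bot_c2")
  for (i in rev(seq_len(d))) {
    h <- upsample_fw(h)
    if (want_cache) push(list(kind = "upsample"))
    h <- cblock(h, paste0("up", i))
    c1 <- dim(h)[3]
    hcat <- array(0, dim(h) + c(0, 0, dim(skips[[i]])[3], 0))
    hcat[, , seq_len(c1), ] <- h
    hcat[, , c1 + seq_len(dim(skips[[i]])[3]), ] <- skips[[i]]
    if (want_cache) push(list(kind = "concat", level = i, c1 = c1))
    h <- hcat
    h <- cblock(h, paste0("dec", i, "_c1"))
    h <- cblock(h, paste0("dec", i, "_c2"))
  }
  pr <- p[["out"]]
  cv <- conv_fw(h, pr$W, pr$b, 1L, 1L, c(0L, 0L, 0L, 0L))
  if (want_cache) push(list(kind = "conv", nm = "out", conv = cv$cache,
                            norm = NULL, relu = NULL))
  sg <- sigmoid_fw(cv$out)
  if (want_cache) push(list(kind = "sigmoid", cache = sg$cache))
  list(prob = sg$out, caches = if (want_cache) caches else NULL)
}

# Reverse walk over the forward tape. dprob: gradient wrt the probability
# map. Returns the parameter gradient list.
unet_backward <- function(model, caches, dprob) {
  p <- model$params
  grads <- list()
  pending_skip <- list()
  dcur <- dprob
  for (cc in rev(caches)) {
    if (cc$kind == "sigmoid") {
      dcur <- sigmoid_bw(dcur, cc$cache)
    } else if (cc$kind == "conv") {
      if (!is.null(cc$relu)) dcur <- relu_bw(dcur, cc$relu)
      if (!is.null(cc$norm)) {
        nb <- instnorm_bw(dcur, cc$norm)
        nm_n <- paste0(cc$nm, "_norm")
        grads[[nm_n]] <- grads_add(grads[[nm_n]],
                                   list(gamma = nb$dgamma, beta = nb$dbeta))
        dcur <- nb$dX
      }
      cb <- conv_bw(dcur, cc$conv, p[[cc$nm]]$W)
      grads[[cc$nm]] <- grads_add(grads[[cc$nm]], list(W = cb$dW, b = cb$db))
      dcur <- cb$dX
    } else if (cc$kind == "concat") {
      dall <- dcur
      dcur <- dall[, , seq_len(cc$c1), , drop = FALSE]
      pending_skip[[as.character(cc$level)]] <-
        dall[, , -seq_len(cc$c1), , drop = FALSE]
    } else if (cc$kind == "upsample") {
      dcur <- upsample_bw(dcur)
    } else if (cc$kind == "pool") {
      dcur <- maxpool_bw(dcur, cc$cache)
      ps <- pending_skip[[as.character(cc$level)]]
      if (!is.null(ps)) dcur <- dcur + ps
    }
  }
  grads
}

#' Smoothed Dice loss
#'
#' `1 - (1 + 2 * sum(p * g)) / (1 + sum(p^2) + sum(g^2))`: the Dice
#' dissimilarity with 1 added to numerator and denominator so the loss is
#' finite and well-behaved even when prediction and truth are both empty.
#' For binary predictions the loss is 0 iff `pred == truth`, and it is
#' symmetric in its arguments.
#'
#' @param pred Predicted probability map (values in `[0, 1]`).
#' @param truth Binary ground-truth mask of the same shape.
#' @return Scalar in `[0, 1)`.
#' @export
dice_loss <- function(pred, truth) {
  assert_that(identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth)),
              "dice_loss: shape mismatch")
  num <- 1 + 2 * sum(pred * truth)
  den <- 1 + sum(pred * pred) + sum(truth * truth)
  1 - num / den
}

dice_grad <- function(pred, truth) {
  num <- 1 + 2 * sum(pred * truth)
  den <- 1 + sum(pred * pred) + sum(truth * truth)
  -(2 * truth * den - num * 2 * pred) / den^2
}

#' Predict a binary fruit mask
#'
#' Runs the segmentation network and binarizes the sigmoid probability map
#' with a strict `>` threshold (ties go to background).
#'
#' @param model A trained [build_segmentation_model()] object.
#' @param image `H x W x 3` array in `[0, 255]` (H, W must be divisible by
#'   `2^encoder_depth`).
#' @param threshold Probability threshold (default from the model's config).
#' @return Binary `H x W` matrix.
#' @export
predict_mask <- function(model, image, threshold = model$cfg$binarize_threshold) {
  check_image(image)
  X <- array(image, c(dim(image), 1))
  prob <- unet_forward(model, X)$prob
  m <- (prob[, , 1, 1] > threshold) * 1
  dim(m) <- dim(image)[1:2]
  m
}

seg_eval_set <- function(model, data, batch_size) {
  losses <- numeric(0)
  preds <- list(); truths <- list()
  idx <- seq_along(data)
  for (start in seq(1, length(data), by = batch_size)) {
    bi <- idx[start:min(start + batch_size - 1, length(data))]
    X <- stack_batch(lapply(data[bi], `[[`, "image"))
    prob <- unet_forward(model, X)$prob
    for (j in seq_along(bi)) {
      pm <- prob[, , 1, j]
      g <- data[[bi[j]]]$mask
      losses <- c(losses, dice_loss(pm, g))
      preds[[length(preds) + 1L]] <- (pm > model$cfg$binarize_threshold) * 1
      truths[[length(truths) + 1L]] <- g
    }
  }
  list(loss = mean(losses), miou = miou(preds, truths))
}

#' Train the segmentation network
#'
#' Optimizes the smoothed Dice loss with Adam (learning rate 0.001, moment
#' estimates 0.9/0.99) over mini-batches, recording Dice loss and MIoU on
#' the training and validation sets each epoch. The returned model carries
#' the weights of the epoch with the best validation MIoU (best training
#' MIoU if no validation set is given).
#'
#' @param train_data List of `list(image =, mask =)` examples (images
#'   `H x W x 3` in `[0, 255]`, masks binary `H x W`).
#' @param cfg A [seg_config()].
#' @param seed Integer seed: initialization and batch shuffling are pure
#'   functions of it.
#' @param val_data Optional validation list in the same format.
#' @param verbose Print per-epoch progress.
#' @return A `seg_model` with elements `params` (best checkpoint), `history`
#'   (tibble: epoch, train_loss, train_miou, val_loss, val_miou),
#'   `best_epoch`, `cfg`, `seed`.
#' @export
train_segmentation <- function(train_data, cfg, seed = 1L, val_data = NULL,
                               verbose = FALSE) {
  assert_that(length(train_data) > 0, "train_segmentation: empty training set")
  model <- build_segmentation_model(cfg, seed)
  opt <- adam_init(model$params)
  n <- length(train_data)
  bs <- min(cfg$batch_size, n)
  hist <- list()
  best <- list(score = -Inf, params = model$params, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(seed, 63L, ep), sample(n))
    ep_losses <- numeric(0)
    for (start in seq(1, n, by = bs)) {
      bi <- ord[start:min(start + bs - 1, n)]
      X <- stack_batch(lapply(train_data[bi], `[[`, "image"))
      fw <- unet_forward(model, X, want_cache = TRUE)
      B <- length(bi)
      dprob <- array(0, dim(fw$prob))
      bl <- 0
      for (j in seq_len(B)) {
        g <- train_data[[bi[j]]]$mask
        pm <- fw$prob[, , 1, j]
        bl <- bl + dice_loss(pm, g)
        dprob[, , 1, j] <- dice_grad(pm, g) / B
      }
      bl <- bl / B
      if (!is.finite(bl)) {
        stop_rindcast(sprintf("non-finite Dice loss at epoch %d (batch starting %d)",
                              ep, start))
      }
      ep_losses <- c(ep_losses, bl)
      grads <- unet_backward(model, fw$caches, dprob)
      st <- adam_step(model$params, grads, opt, lr = cfg$learning_rate)
      model$params <- st$params
      opt <- st$state
    }
    tr <- seg_eval_set(model, train_data, bs)
    va <- if (!is.null(val_data)) seg_eval_set(model, val_data, bs) else
      list(loss = NA_real_, miou = NA_real_)
    hist[[ep]] <- tibble(epoch = ep, train_loss = tr$loss, train_miou = tr$miou,
                         val_loss = va$loss, val_miou = va$miou)
    score <- if (!is.null(val_data)) va$miou else tr$miou
    if (score > best$score) best <- list(score = score, params = model$params,
                                         epoch = ep)
    if (verbose) {
      message(sprintf("epoch %d: dice %.4f, train MIoU %.4f, val MIoU %s",
                      ep, tr$loss, tr$miou,
                      if (is.na(va$miou)) "-" else sprintf("%.4f", va$miou)))
    }
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- dplyr::bind_rows(hist)
  model$seed <- seed
  model
}
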