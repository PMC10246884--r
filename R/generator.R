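# Time-conditioned mask-guided generative network.
#
# Encoder: stride-2 4x4 convolutions (second stage fixed at 64 channels)
# followed by a stack of identical 3x3 residual blocks. Decoder: resize
# convolutions (nearest-neighbor doubling + stride-1 4x4 convolution) and a
# final 3x3 convolution through a scaled tanh onto [0, 255]. Two trainable
# embedding tables map the integer time interval N to 64-dimensional gain
# vectors that gate (per-channel multiply) the 64 feature maps of the second
# encoder convolution and of the second decoder convolution. The generated
# fruit is composited back over the input frame via the mask (background
# re-fusion). Instance normalization + ReLU follow every convolution except
# the output layer. No discriminator: training drives the local perceptual
# loss.

#' Generator configuration
#'
#' @param input_size `c(H, W)`, divisible by 4 (two stride-2 stems).
#' @param stem_channels Channels of the two stride-2 4x4 stem convolutions;
#'   the second entry must be 64 (embedding-gating compatibility).
#' @param n_resblocks Number of identical 3x3 residual blocks at the
#'   bottleneck (default 5).
#' @param n_max Largest representable time interval in days (default 45,
#'   the observation span); valid intervals are `1..n_max`.
#' @param skip_mode `"concat"` (default) concatenates encoder features at
#'   matching decoder resolutions; `"add"` sums them (requires matching
#'   channel counts); `"none"` disables skips.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training epochs (default 80).
#' @param use_embedding Internal switch for the interval-embedding gating;
#'   `FALSE` builds the fixed-interval ablation architecture.
#' @return An object of class `gen_config`.
#' @export
generator_config <- function(input_size = c(192, 256), stem_channels = c(32, 64),
                             n_resblocks = 5L, n_max = 45L,
                             skip_mode = c("concat", "add", "none"),
                             learning_rate = 1e-3, batch_size = 32L,
                             epochs = 80L, use_embedding = TRUE) {
  skip_mode <- match.arg(skip_mode)
  assert_that(length(stem_channels) == 2 && stem_channels[2] == 64,
              "the second stem convolution must have exactly 64 channels")
  assert_that(all(input_size %% 4 == 0), "input size must be divisible by 4")
  assert_that(n_max >= 1, "n_max must be >= 1")
  if (skip_mode == "add") {
    assert_that(stem_channels[1] == 64,
                "skip_mode 'add' requires 64-channel first stem stage")
  }
  structure(list(input_size = input_size, stem_channels = as.integer(stem_channels),
                 n_resblocks = as.integer(n_resblocks), embedding_dim = 64L,
                 n_max = as.integer(n_max), skip_mode = skip_mode,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), use_embedding = isTRUE(use_embedding)),
            class = "gen_config")
}

#' Build the generative model
#'
#' @param cfg A [generator_config()].
#' @param seed Seed for weight initialization. Embedding tables are
#'   initialized at 1 (identity gating).
#' @return An object of class `gen_model`.
#' @export
build_generator <- function(cfg, seed = 1L) {
  c1 <- cfg$stem_channels[1]
  nres <- cfg$n_resblocks
  params <- with_seed(derive_seed(seed, 73L), {
    p <- list()
    p$stem1 <- init_conv(4L, 3L, c1)
    p$stem1_norm <- init_norm(c1)
    p$stem2 <- init_conv(4L, c1, 64L)
    p$stem2_norm <- init_norm(64L)
    for (r in seq_len(nres)) {
      p[[paste0("res", r, "_c1")]] <- init_conv(3L, 64L, 64L)
      p[[paste0("res", r, "_c1_norm")]] <- init_norm(64L)
      p[[paste0("res", r, "_c2")]] <- init_conv(3L, 64L, 64L)
      p[[paste0("res", r, "_c2_norm")]] <- init_norm(64L)
    }
    dec1_in <- switch(cfg$skip_mode, concat = 64L + c1, add = 64L, none = 64L)
    p$dec1 <- init_conv(4L, dec1_in, 64L)
    p$dec1_norm <- init_norm(64L)
    dec2_in <- switch(cfg$skip_mode, concat = 64L + 3L, add = 64L, none = 64L)
    p$dec2 <- init_conv(4L, dec2_in, 64L)
    p$dec2_norm <- init_norm(64L)
    p$outc <- init_conv(3L, 64L, 3L)
    if (cfg$use_embedding) {
      p$emb_enc <- matrix(1, cfg$n_max, 64L)
      p$emb_dec <- matrix(1, cfg$n_max, 64L)
    }
    p
  })
  structure(list(cfg = cfg, params = params, history = NULL, seed = seed),
            class = "gen_model")
}

#' Number of trainable parameters
#'
#' @param model A `gen_model` or `seg_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  n_params_list(model$params)
}

check_interval <- function(N, n_max) {
  assert_that(all(N == as.integer(N)) && all(N >= 1) && all(N <= n_max),
              sprintf("time interval N must be an integer in 1..%d", n_max))
  as.integer(N)
}

# Forward pass. X: (H, W, 3, B) in [0,255]; N: integer vector length B
# (ignored without embeddings). Returns raw generated batch in [0,255].
gen_forward <- function(model, X, N, want_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  B <- dim(X)[4]
  if (cfg$use_embedding) N <- rep_len(check_interval(N, cfg$n_max), B)
  caches <- list()
  push <- function(cc) caches[[length(caches) + 1L]] <<- cc
  cblock <- function(h, nm, k, stride, pad, act = TRUE) {
    pr <- p[[nm]]
    cv <- conv_fw(h, pr$W, pr$b, k, stride, pad)
    no <- instnorm_fw(cv$out, p[[paste0(nm, "_norm")]]$gamma,
                      p[[paste0(nm, "_norm")]]$beta)
    rl <- relu_fw(no$out)
    if (want_cache) push(list(kind = "conv", nm = nm, conv = cv$cache,
                              norm = no$cache, relu = rl$cache))
    rl$out
  }
  gate <- function(h, table_nm, N) {
    V <- t(p[[table_nm]][N, , drop = FALSE])   # 64 x B
    g <- array(0, dim(h))
    hw <- dim(h)[1] * dim(h)[2]
    for (b in seq_len(dim(h)[4])) g[, , , b] <- rep(V[, b], each = hw)
    if (want_cache) push(list(kind = "gate", table = table_nm, pre = h,
                              V = V, N = N))
    h * g
  }
  xn <- X / 127.5 - 1
  h1 <- cblock(xn, "stem1", 4L, 2L, c(1L, 1L, 1L, 1L))
  h <- cblock(h1, "stem2", 4L, 2L, c(1L, 1L, 1L, 1L))
  if (cfg$use_embedding) h <- gate(h, "emb_enc", N)
  for (r in seq_len(cfg$n_resblocks)) {
    if (want_cache) push(list(kind = "res_begin"))
    t <- cblock(h, paste0("res", r, "_c1"), 3L, 1L, same_pad(3L))
    t <- cblock(t, paste0("res", r, "_c2"), 3L, 1L, same_pad(3L))
    if (want_cache) push(list(kind = "res_add"))
    h <- h + t
  }
  # decoder stage 1: resize convolution back to H/2
  h <- upsample_fw(h)
  if (want_cache) push(list(kind = "upsample"))
  if (cfg$skip_mode == "concat") {
    hcat <- array(0, dim(h) + c(0, 0, dim(h1)[3], 0))
    hcat[, , seq_len(dim(h)[3]), ] <- h
    hcat[, , dim(h)[3] + seq_len(dim(h1)[3]), ] <- h1
    if (want_cache) push(list(kind = "concat", c1 = dim(h)[3], to = "h1"))
    h <- hcat
  } else if (cfg$skip_mode == "add") {
    if (want_cache) push(list(kind = "skip_add", to = "h1"))
    h <- h + h1
  }
  h <- cblock(h, "dec1", 4L, 1L, same_pad(4L))
  # decoder stage 2: resize convolution back to full resolution
  h <- upsample_fw(h)
  if (want_cache) push(list(kind = "upsample"))
  if (cfg$skip_mode == "concat") {
    hcat <- array(0, dim(h) + c(0, 0, 3L, 0))
    hcat[, , seq_len(dim(h)[3]), ] <- h
    hcat[, , dim(h)[3] + 1:3, ] <- xn
    if (want_cache) push(list(kind = "concat", c1 = dim(h)[3], to = "input"))
    h <- hcat
  }
  h <- cblock(h, "dec2", 4L, 1L, same_pad(4L))
  if (cfg$use_embedding) h <- gate(h, "emb_dec", N)
  pr <- p$outc
  cv <- conv_fw(h, pr$W, pr$b, 3L, 1L, same_pad(3L))
  if (want_cache) push(list(kind = "conv", nm = "outc", conv = cv$cache,
                            norm = NULL, relu = NULL))
  st <- scaled_tanh_fw(cv$out)
  if (want_cache) push(list(kind = "tanh", cache = st$cache))
  list(out = st$out, caches = if (want_cache) caches else NULL)
}

gen_backward <- function(model, caches, dout) {
  p <- model$params
  grads <- list()
  res_stack <- list()
  pending_h1 <- NULL
  dcur <- dout
  for (cc in rev(caches)) {
    if (cc$kind == "tanh") {
      dcur <- scaled_tanh_bw(dcur, cc$cache)
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
      # h1 feeds both stem2 and the decoder skip; merge the skip gradient
      # where the main path reaches h1
      if (cc$nm == "stem2" && !is.null(pending_h1)) {
        dcur <- dcur + pending_h1
        pending_h1 <- NULL
      }
    } else if (cc$kind == "gate") {
      hw <- dim(cc$pre)[1] * dim(cc$pre)[2]
      dtab <- grads[[cc$table]] %||% matrix(0, nrow(p[[cc$table]]), 64L)
      g <- array(0, dim(cc$pre))
      for (b in seq_len(dim(cc$pre)[4])) {
        g[, , , b] <- rep(cc$V[, b], each = hw)
        dV <- colSums(matrix(dcur[, , , b] * cc$pre[, , , b], hw, 64L))
        dtab[cc$N[b], ] <- dtab[cc$N[b], ] + dV
      }
      grads[[cc$table]] <- dtab
      dcur <- dcur * g
    } else if (cc$kind == "res_add") {
      res_stack[[length(res_stack) + 1L]] <- dcur
    } else if (cc$kind == "res_begin") {
      dcur <- dcur + res_stack[[length(res_stack)]]
      res_stack[[length(res_stack)]] <- NULL
    } else if (cc$kind == "upsample") {
      dcur <- upsample_bw(dcur)
    } else if (cc$kind == "concat") {
      dskip <- dcur[, , -seq_len(cc$c1), , drop = FALSE]
      dcur <- dcur[, , seq_len(cc$c1), , drop = FALSE]
      if (cc$to == "h1") pending_h1 <- grads_add(pending_h1, dskip)
      # the input-skip branch ends at the (constant) input image
    } else if (cc$kind == "skip_add") {
      if (cc$to == "h1") pending_h1 <- grads_add(pending_h1, dcur)
    }
  }
  grads
}

#' Apply a time-interval embedding gate to a feature tensor
#'
#' Channel `k` of the output equals channel `k` of the input multiplied by
#' element `k` of the embedding vector for interval `N` (per-channel scalar
#' gating; spatial shape unchanged).
#'
#' @param features `64 x H x W` array (channel-first).
#' @param N Integer interval in `1..nrow(table)`.
#' @param table Embedding table (`n_max x 64` matrix) from a `gen_model`
#'   (`params$emb_enc` or `params$emb_dec`).
#' @param site `"encoder"` or `"decoder"` (informational; both gate
#'   identically).
#' @return Gated `64 x H x W` array.
#' @export
apply_time_embedding <- function(features, N, table,
                                 site = c("encoder", "decoder")) {
  match.arg(site)
  d <- dim(features)
  assert_that(length(d) == 3 && d[1] == ncol(table),
              sprintf("features must have %d channels (channel-first)", ncol(table)))
  N <- check_interval(N, nrow(table))
  features * as.numeric(table[N, ])   # recycles over channel-first dim
}

#' Upsample a feature tensor by nearest neighbor
#'
#' Replicates each pixel into a 2x2 block (channel-first interface used by
#' [resize_conv()]).
#'
#' @param features `C x H x W` array.
#' @return `C x 2H x 2W` array.
#' @export
upsample_nearest <- function(features) {
  d <- dim(features)
  features[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L),
           drop = FALSE]
}

#' Resize convolution
#'
#' Doubles a feature map in height and width by nearest-neighbor
#' interpolation, then applies a stride-1 4x4 convolution - the
#' transposed-convolution replacement that avoids checkerboard artifacts.
#'
#' @param features `C x H x W` array (channel-first).
#' @param out_channels Output channel count.
#' @param weights,bias Optional convolution parameters (`(16*C) x
#'   out_channels` matrix / length-`out_channels` vector); freshly
#'   initialized from `seed` when omitted.
#' @param seed Seed for the default initialization.
#' @return `out_channels x 2H x 2W` array.
#' @export
resize_conv <- function(features, out_channels, weights = NULL, bias = NULL,
                        seed = 1L) {
  d <- dim(features)
  assert_that(length(d) == 3, "features must be a C x H x W array")
  if (is.null(weights)) {
    pr <- with_seed(derive_seed(seed, 79L), init_conv(4L, d[1], out_channels))
    weights <- pr$W; bias <- pr$b
  }
  up <- upsample_nearest(features)
  X <- chw_to_hwc1(up)
  out <- conv_fw(X, weights, bias %||% numeric(out_channels), 4L, 1L, same_pad(4L))$out
  hwc1_to_chw(out)
}

#' Background re-fusion
#'
#' Composites the generated fruit over the original frame through the mask:
#' `mask * generated + (1 - mask) * original`. Background pixels are
#' bit-equal to the original; the operation is idempotent for a fixed mask.
#'
#' @param generated,original `H x W x 3` images in `[0, 255]`.
#' @param mask Binary `H x W` matrix (1 = fruit).
#' @return Composited `H x W x 3` image.
#' @export
composite_background <- function(generated, original, mask) {
  check_same_hw(generated, original, "generated and original")
  check_same_hw(generated, mask, "image and mask")
  m3 <- array(rep(mask, 3), dim(generated))
  m3 * generated + (1 - m3) * original
}

#' Predict the rind color after N days
#'
#' Runs the full forward pass - encoder, interval-embedding gating,
#' resize-convolution decoder, scaled tanh - and re-fuses the background
#' from the input frame through the mask. Deterministic at inference.
#'
#' @param object A trained `gen_model`.
#' @param image Input `H x W x 3` image in `[0, 255]`.
#' @param mask Binary fruit mask of the input (from annotation or
#'   [predict_mask()]).
#' @param N Time interval in days (`1..n_max`).
#' @param composite Re-fuse the background (default `TRUE`; `FALSE` returns
#'   the raw generator output).
#' @param ... Unused.
#' @return `H x W x 3` predicted image in `[0, 255]`.
#' @export
predict.gen_model <- function(object, image, mask, N, composite = TRUE, ...) {
  check_image(image)
  check_mask(mask)
  check_same_hw(image, mask, "image and mask")
  if (object$cfg$use_embedding) check_interval(N, object$cfg$n_max)
  X <- array(image, c(dim(image), 1))
  raw <- gen_forward(object, X, N)$out
  gen <- array(raw[, , , 1], dim(image))
  if (composite) composite_background(gen, image, mask) else gen
}

# Default training loss configuration for the pixel-feature extractor: the
# mask-normalized style term already normalizes spatial extent, so the
# channels-only prefactor keeps its magnitude commensurate with the content
# term; the style weight emphasizes rind color fidelity over the (skip-aided)
# content reconstruction.
default_pixel_loss_cfg <- function() {
  style_config(content_layers = "pixels", style_layers = "pixels",
               style_layer_weights = 1, prefactor_convention = "channels_only",
               content_weight = 1, style_weight = 10)
}

# Local perceptual loss value + pixel gradient for one (x, y, yhat) triple.
perceptual_loss_grad <- function(x, y, yhat, x_mask, y_mask, extractor, cfg) {
  fx <- extractor_forward(extractor, x)$feats
  fy <- extractor_forward(extractor, y)$feats
  fh_fw <- extractor_forward(extractor, yhat, want_cache = TRUE)
  fh <- fh_fw$feats
  loss <- 0
  fgrads <- list()
  for (l in cfg$content_layers) {
    a <- fx[[l]]; b <- fh[[l]]
    nl <- length(b)
    loss <- loss + cfg$content_weight * mean((a - b)^2)
    fgrads[[l]] <- grads_add(fgrads[[l]], cfg$content_weight * 2 * (b - a) / nl)
  }
  for (l in cfg$style_layers) {
    fyl <- fy[[l]]; fhl <- fh[[l]]
    dl <- dim(fhl)
    my <- layer_mask(y_mask, dim(fyl)[2:3])
    mh <- layer_mask(x_mask, dl[2:3])
    if (sum(my) <= 0 || sum(mh) <= 0) {
      stop_rindcast(sprintf("degenerate mask at style layer '%s'", l),
                    class = "rindcast_degenerate_mask")
    }
    s <- sum(mh)
    mv <- rep(as.vector(mh), each = dl[1])
    Fm <- matrix(fhl, nrow = dl[1]) * mv
    Gh <- tcrossprod(Fm) / s
    Gy <- masked_normalized_gram(fyl, my)
    pref <- cfg$style_layer_weights[[l]] * style_prefactor(cfg, dim(fyl))
    D <- Gh - Gy
    loss <- loss + cfg$style_weight * pref * sum(D * D)
    dFm <- (cfg$style_weight * pref * 4 / s) * (D %*% Fm)
    dF <- array(dFm * mv, dl)
    fgrads[[l]] <- grads_add(fgrads[[l]], dF)
  }
  dpix <- extractor_backward(extractor, yhat, fh_fw$caches, fgrads)
  list(loss = loss, dpix = dpix)
}

gen_eval_pairs <- function(model, pairs, extractor, loss_cfg,
                           psnr_reference = "input") {
  ps <- numeric(0); ml <- list()
  for (pp in pairs) {
    pred <- predict(model, pp$input, pp$input_mask, pp$N)
    ref <- if (psnr_reference == "input") pp$input else pp$target
    ps <- c(ps, psnr(pred, ref))
    ml[[length(ml) + 1L]] <- list(generated = pred, truth = pp$target,
                                  generated_mask = pp$input_mask,
                                  truth_mask = pp$target_mask)
  }
  list(psnr = mean(ps[is.finite(ps)]), mlsl = mlsl(ml, extractor, loss_cfg))
}

#' Train the generative network
#'
#' Optimizes the local perceptual loss (content fidelity to the input plus
#' mask-normalized local style fidelity to the ground truth) with Adam -
#' there is no adversarial discriminator. Losses are evaluated on the
#' background-re-fused output using the ground-truth annotation masks; the
#' segmentation network supplies masks only at inference. Per-epoch total
#' loss, PSNR and MLSL are recorded on the training set (and validation set
#' if given), and the returned model carries the weights chosen by the
#' two-stage selection rule: among the 10 epochs with the best validation
#' MLSL, the epoch with the best validation PSNR.
#'
#' @param pairs List of training examples: each
#'   `list(input =, input_mask =, target =, target_mask =, N =)` with
#'   images `H x W x 3` in `[0, 255]`, binary masks, integer interval `N`.
#'   Pairs with a degenerate (empty) target mask are skipped with a warning.
#' @param cfg A [generator_config()].
#' @param seed Integer seed (initialization + shuffling).
#' @param loss_cfg A [style_config()]; defaults to the pixel-extractor
#'   configuration (content and style on the `"pixels"` layer,
#'   channels-only prefactor, style weight 10).
#' @param extractor Loss-network [feature_extractor()]; defaults to the
#'   identity extractor on the `[0, 1]` scale.
#' @param val_pairs Optional validation pairs (same format).
#' @param eval_subset Maximum pairs per set used for the per-epoch
#'   PSNR/MLSL bookkeeping (default 64).
#' @param psnr_reference `"input"` (default) or `"target"`.
#' @param verbose Print per-epoch progress.
#' @return A `gen_model` with `history` (tibble: epoch, train_loss,
#'   train_psnr, train_mlsl, val_psnr, val_mlsl), `selection` (the
#'   two-stage candidate sets), `best_epoch`, and the selected weights.
#' @export
train_generator <- function(pairs, cfg, seed = 1L, loss_cfg = NULL,
                            extractor = NULL, val_pairs = NULL,
                            eval_subset = 64L, psnr_reference = "input",
                            verbose = FALSE) {
  assert_that(length(pairs) > 0, "train_generator: empty training set")
  extractor <- extractor %||% feature_extractor("identity", scale = 1 / 255)
  loss_cfg <- loss_cfg %||% default_pixel_loss_cfg()
  keep <- vapply(pairs, function(p) sum(p$target_mask) > 0 && sum(p$input_mask) > 0,
                 logical(1))
  if (any(!keep)) {
    warn(sprintf("skipping %d pair(s) with a degenerate mask", sum(!keep)))
    pairs <- pairs[keep]
  }
  assert_that(length(pairs) > 0, "all pairs had degenerate masks")
  if (cfg$use_embedding) {
    for (p in pairs) check_interval(p$N, cfg$n_max)
  }
  model <- build_generator(cfg, seed)
  opt <- adam_init(model$params)
  n <- length(pairs)
  bs <- min(cfg$batch_size, n)
  ev_tr <- pairs[seq_len(min(eval_subset, n))]
  ev_va <- if (!is.null(val_pairs))
    val_pairs[seq_len(min(eval_subset, length(val_pairs)))]
  hist <- list()
  snapshots <- list()
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(seed, 83L, ep), sample(n))
    ep_loss <- numeric(0)
    for (start in seq(1, n, by = bs)) {
      bi <- ord[start:min(start + bs - 1, n)]
      B <- length(bi)
      X <- stack_batch(lapply(pairs[bi], `[[`, "input"))
      Ns <- vapply(pairs[bi], function(p) as.integer(p$N), integer(1))
      fw <- gen_forward(model, X, Ns, want_cache = TRUE)
      dout <- array(0, dim(fw$out))
      bl <- 0
      for (j in seq_len(B)) {
        pp <- pairs[[bi[j]]]
        gen <- array(fw$out[, , , j], dim(pp$input))
        comp <- composite_background(gen, pp$input, pp$input_mask)
        lg <- perceptual_loss_grad(pp$input, pp$target, comp,
                                   pp$input_mask, pp$target_mask,
                                   extractor, loss_cfg)
        bl <- bl + lg$loss
        m3 <- array(rep(pp$input_mask, 3), dim(gen))
        dout[, , , j] <- lg$dpix * m3 / B
      }
      bl <- bl / B
      assert_that(is.finite(bl) && bl >= 0,
                  sprintf("non-finite or negative loss at epoch %d", ep))
      ep_loss <- c(ep_loss, bl)
      grads <- gen_backward(model, fw$caches, dout)
      st <- adam_step(model$params, grads, opt, lr = cfg$learning_rate)
      model$params <- st$params
      opt <- st$state
    }
    tr <- gen_eval_pairs(model, ev_tr, extractor, loss_cfg, psnr_reference)
    va <- if (!is.null(ev_va))
      gen_eval_pairs(model, ev_va, extractor, loss_cfg, psnr_reference) else
      list(psnr = NA_real_, mlsl = NA_real_)
    hist[[ep]] <- tibble(epoch = ep, train_loss = mean(ep_loss),
                         train_psnr = tr$psnr, train_mlsl = tr$mlsl,
                         val_psnr = va$psnr, val_mlsl = va$mlsl)
    snapshots[[ep]] <- model$params
    if (verbose) {
      message(sprintf("epoch %d: loss %.5f, PSNR %.2f, MLSL %.5f%s", ep,
                      mean(ep_loss), tr$psnr, tr$mlsl,
                      if (!is.null(ev_va))
                        sprintf(" | val PSNR %.2f, MLSL %.5f", va$psnr, va$mlsl)
                      else ""))
    }
  }
  model$history <- dplyr::bind_rows(hist)
  sel <- select_generator_epoch(model$history, validated = !is.null(ev_va))
  model$selection <- sel
  model$best_epoch <- sel$best_epoch
  model$params <- snapshots[[sel$best_epoch]]
  model$seed <- seed
  model
}

# Two-stage model selection: the 10 epochs with the best (lowest) MLSL on
# the validation set, among which the 5 with the best (highest) PSNR; the
# selected epoch is the best-PSNR member.
select_generator_epoch <- function(history, validated = TRUE) {
  mlsl_col <- if (validated) history$val_mlsl else history$train_mlsl
  psnr_col <- if (validated) history$val_psnr else history$train_psnr
  stage1 <- history$epoch[order(mlsl_col)][seq_len(min(10L, nrow(history)))]
  stage2 <- stage1[order(-psnr_col[match(stage1, history$epoch)])]
  stage2 <- stage2[seq_len(min(5L, length(stage2)))]
  list(mlsl_top10 = sort(stage1), psnr_top5 = sort(stage2),
       best_epoch = stage2[1])
}

#' Train a fixed-interval generator (embedding-free ablation)
#'
#' Trains the identical architecture minus the two embedding tables on
#' pairs that all share one time interval. The resulting model ignores the
#' `N` argument at prediction time; serving several intervals this way
#' requires one weight set per interval, whereas the merged
#' (embedding-gated) model serves all of them from one.
#'
#' @param pairs Training pairs (see [train_generator()]); all must share
#'   the same `N`.
#' @param cfg A [generator_config()] (its `use_embedding` flag is forced
#'   off).
#' @param ... Passed on to [train_generator()].
#' @return A `gen_model` without embedding parameters; its `fixed_interval`
#'   element records the interval it serves.
#' @export
train_fixed_interval_generator <- function(pairs, cfg, ...) {
  Ns <- unique(vapply(pairs, function(p) as.integer(p$N), integer(1)))
  assert_that(length(Ns) == 1,
              sprintf("fixed-interval training requires a single N (got: %s)",
                      paste(sort(Ns), collapse = ", ")))
  cfg$use_embedding <- FALSE
  model <- train_generator(pairs, cfg, ...)
  model$fixed_interval <- Ns
  model
}
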