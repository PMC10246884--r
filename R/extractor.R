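# Loss-network feature extractors.
#
# Two extractors implement the same interface:
#  * "identity": a single layer ("pixels") equal to the channel-first pixel
#    array, optionally scaled. Exact closed-form unit tests and cheap
#    training run through it.
#  * "vgg": a 19-layer VGG-topology convolutional stack (blocks of 3x3
#    convolutions + ReLU with 2x2 max pooling between blocks, layers named
#    Conv<i>_<j>) with frozen, seeded random He-initialized weights. Random
#    convolutional features are a recognized basis for perceptual/style
#    metrics; the extractor is deterministic and immutable during loss
#    evaluation.

VGG_BLOCKS <- c(2L, 2L, 4L, 4L, 4L)

#' Construct a loss-network feature extractor
#'
#' @param type `"identity"` for the raw-pixel extractor or `"vgg"` for the
#'   VGG19-topology random-feature extractor (5 convolution blocks of
#'   2/2/4/4/4 conv+ReLU layers with 2x2 max pooling between blocks; layer
#'   `Conv<i>_<j>` is the activation after the j-th convolution of block i).
#' @param channels Channel widths per block for `type = "vgg"` (default a
#'   compact `c(8, 16, 32, 64, 64)`; the full-size topology would use
#'   `c(64, 128, 256, 512, 512)`).
#' @param seed Seed fixing the frozen random weights.
#' @param scale Multiplier applied to pixel values before extraction
#'   (default 1, i.e. features on the `[0, 255]` scale).
#' @param center Length-3 channel means subtracted (on the `[0, 255]` scale)
#'   before the convolutional stack; defaults to the customary ImageNet
#'   means for `"vgg"` and 0 for `"identity"`.
#' @return An object of class `feature_extractor`.
#' @export
feature_extractor <- function(type = c("identity", "vgg"),
                              channels = c(8, 16, 32, 64, 64),
                              seed = 19L, scale = 1,
                              center = NULL) {
  type <- match.arg(type)
  if (type == "identity") {
    ex <- list(type = type, layers = "pixels", scale = scale,
               center = center %||% c(0, 0, 0))
    return(structure(ex, class = "feature_extractor"))
  }
  assert_that(length(channels) == 5, "vgg extractor needs 5 block widths")
  layers <- unlist(lapply(seq_along(VGG_BLOCKS), function(i)
    paste0("Conv", i, "_", seq_len(VGG_BLOCKS[i]))))
  params <- with_seed(derive_seed(seed, 71L), {
    p <- list()
    cin <- 3L
    for (i in seq_along(VGG_BLOCKS)) {
      for (j in seq_len(VGG_BLOCKS[i])) {
        p[[paste0("Conv", i, "_", j)]] <- init_conv(3L, cin, channels[i])
        cin <- channels[i]
      }
    }
    p
  })
  structure(list(type = type, layers = layers, channels = channels,
                 params = params, scale = scale,
                 center = center %||% c(123.68, 116.779, 103.939)),
            class = "feature_extractor")
}

# channel-first (C,H,W) <-> batch tensor (H,W,C,1)
chw_to_hwc1 <- function(f) {
  d <- dim(f)
  array(aperm(f, c(2, 3, 1)), c(d[2], d[3], d[1], 1))
}
hwc1_to_chw <- function(x) {
  d <- dim(x)
  aperm(array(x, d[1:3]), c(3, 1, 2))
}

# Forward pass through the extractor, returning features at all tap points
# plus (optionally) the caches needed to backpropagate a feature-space
# gradient to pixel space.
extractor_forward <- function(extractor, image, want_cache = FALSE) {
  if (extractor$type == "identity") {
    f <- aperm(image, c(3, 1, 2)) * extractor$scale
    if (any(extractor$center != 0)) f <- f - extractor$center  # recycles over C fastest
    return(list(feats = list(pixels = f), caches = NULL))
  }
  x <- image
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - extractor$center[ch]) * extractor$scale
  h <- array(x, c(dim(x), 1))
  feats <- list()
  caches <- list()
  step <- 0L
  for (i in seq_along(VGG_BLOCKS)) {
    for (j in seq_len(VGG_BLOCKS[i])) {
      nm <- paste0("Conv", i, "_", j)
      p <- extractor$params[[nm]]
      cv <- conv_fw(h, p$W, p$b, k = 3L, stride = 1L, pad = same_pad(3L))
      rl <- relu_fw(cv$out)
      h <- rl$out
      step <- step + 1L
      if (want_cache) caches[[step]] <- list(kind = "conv", name = nm,
                                             conv = cv$cache, relu = rl$cache)
      feats[[nm]] <- hwc1_to_chw(h)
    }
    if (i < length(VGG_BLOCKS)) {
      mp <- maxpool_fw(h)
      h <- mp$out
      step <- step + 1L
      if (want_cache) caches[[step]] <- list(kind = "pool", pool = mp$cache)
    }
  }
  list(feats = feats, caches = if (want_cache) caches else NULL)
}

# Backpropagate per-layer feature gradients (named list, channel-first) to a
# pixel-space gradient (H x W x 3).
extractor_backward <- function(extractor, image, caches, feat_grads) {
  if (extractor$type == "identity") {
    g <- feat_grads[["pixels"]]
    if (is.null(g)) return(array(0, dim(image)))
    return(aperm(g, c(2, 3, 1)) * extractor$scale)
  }
  dh <- NULL
  for (s in rev(seq_along(caches))) {
    cc <- caches[[s]]
    if (cc$kind == "pool") {
      dh <- maxpool_bw(dh, cc$pool)
    } else {
      g <- feat_grads[[cc$name]]
      if (!is.null(g)) {
        g4 <- chw_to_hwc1(g)
        dh <- if (is.null(dh)) g4 else dh + g4
      }
      if (is.null(dh)) next
      dr <- relu_bw(dh, cc$relu)
      p <- extractor$params[[cc$name]]
      dh <- conv_bw(dr, cc$conv, p$W)$dX
    }
  }
  array(dh, dim(dh)[1:3]) * extractor$scale
}

#' Extract named feature maps from an image
#'
#' Runs the loss network forward and returns the activation tensors at the
#' requested layers, channel-first (`C_l x H_l x W_l`). Repeated calls are
#' identical (the extractor's weights are frozen).
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param extractor A [feature_extractor()].
#' @param layers Character vector of layer names (default: all layers the
#'   extractor exposes, e.g. `"Conv1_1"` ... `"Conv5_4"`, or `"pixels"`).
#' @return Named list of `C x H x W` arrays.
#' @export
extract_features <- function(image, extractor, layers = extractor$layers) {
  check_image(image)
  unknown <- setdiff(layers, extractor$layers)
  assert_that(length(unknown) == 0,
              sprintf("unknown layer name(s): %s", paste(unknown, collapse = ", ")))
  fw <- extractor_forward(extractor, image)
  fw$feats[layers]
}

# Nearest-neighbor resize of an image-resolution mask to a layer's H x W.
#' Resize a mask to a feature layer's resolution
#'
#' Nearest-neighbor downscaling (binarity-preserving) of an image-resolution
#' mask to the spatial size of a feature map.
#'
#' @param mask Binary `H x W` matrix.
#' @param hw Target size `c(H_l, W_l)`.
#' @return Binary `H_l x W_l` matrix.
#' @export
layer_mask <- function(mask, hw) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- pmin(H, floor((seq_len(hw[1]) - 0.5) / hw[1] * H) + 1L)
  ci <- pmin(W, floor((seq_len(hw[2]) - 0.5) / hw[2] * W) + 1L)
  mask[ri, ci, drop = FALSE]
}
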