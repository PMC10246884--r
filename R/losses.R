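# Perceptual loss functions: content loss, Gram matrices, the
# mask-normalized local style loss, the classical (global) style loss, the
# black-background variant, and the pairwise style-difference harness.

#' Configure the perceptual/style loss
#'
#' @param content_layers Layers for the content term (default `Conv4_2`,
#'   `Conv5_2`).
#' @param style_layers Layers for the style term (default `Conv1_1`,
#'   `Conv2_1`, `Conv3_1`, `Conv4_1`, `Conv5_1`).
#' @param style_layer_weights Per-style-layer weights `W_style,l`
#'   (non-negative; recycled to the number of style layers; default 1).
#' @param prefactor_convention Normalization of each style-layer term:
#'   `"as_printed"` uses `W_l / (H_l W_l C_l)^2` (the same structure as the
#'   global style loss); `"channels_only"` uses `W_l / C_l^2`, on the ground
#'   that the mask-sum division inside the local Gram already normalizes
#'   spatial extent. Both are exposed because the printed grouping is
#'   ambiguous; they rescale, never reorder, single-layer comparisons.
#' @param content_weight,style_weight Weights of the two terms in the local
#'   perceptual loss (default 1:1).
#' @return An object of class `style_config`.
#' @export
style_config <- function(content_layers = c("Conv4_2", "Conv5_2"),
                         style_layers = c("Conv1_1", "Conv2_1", "Conv3_1",
                                          "Conv4_1", "Conv5_1"),
                         style_layer_weights = 1,
                         prefactor_convention = c("as_printed", "channels_only"),
                         content_weight = 1, style_weight = 1) {
  prefactor_convention <- match.arg(prefactor_convention)
  w <- rep_len(style_layer_weights, length(style_layers))
  assert_that(all(w >= 0), "style layer weights must be non-negative")
  structure(list(content_layers = content_layers, style_layers = style_layers,
                 style_layer_weights = setNames(w, style_layers),
                 prefactor_convention = prefactor_convention,
                 content_weight = content_weight, style_weight = style_weight),
            class = "style_config")
}

style_prefactor <- function(cfg, dfeat) {
  C <- dfeat[1]; H <- dfeat[2]; W <- dfeat[3]
  switch(cfg$prefactor_convention,
         as_printed = 1 / (H * W * C)^2,
         channels_only = 1 / C^2)
}

#' Gram matrix of a feature tensor
#'
#' Flattens each channel of a `C x H x W` feature tensor into a vector and
#' returns the `C x C` matrix of their pairwise dot products (no
#' normalization). The result is symmetric and positive semi-definite and
#' summarizes channel co-activation (texture/style) independent of spatial
#' layout.
#'
#' @param feature `C x H x W` array.
#' @return `C x C` Gram matrix.
#' @export
gram <- function(feature) {
  assert_that(is.array(feature) && length(dim(feature)) == 3,
              "feature must be a C x H x W array")
  F <- matrix(feature, nrow = dim(feature)[1])
  tcrossprod(F)
}

#' Mask-normalized local Gram matrix
#'
#' Multiplies the feature maps by a (layer-resolution) mask, accumulates the
#' Gram matrix over the masked features and divides by the mask sum:
#' `gram(feature * mask) / sum(mask)`. For a region of constant per-channel
#' value `c`, the result is the outer product `c %o% c` regardless of region
#' area - the size invariance at the heart of the local style loss.
#'
#' @param feature `C x H x W` array.
#' @param mask `H x W` mask in `[0, 1]` with `sum(mask) > 0`.
#' @return `C x C` normalized Gram matrix.
#' @export
masked_normalized_gram <- function(feature, mask) {
  d <- dim(feature)
  assert_that(length(d) == 3, "feature must be a C x H x W array")
  assert_that(all(dim(mask) == d[2:3]),
              "mask shape must match the feature map's H x W")
  s <- sum(mask)
  if (s <= 0) stop_rindcast("degenerate mask: sum(mask) must be > 0",
                            class = "rindcast_degenerate_mask")
  Fm <- matrix(feature, nrow = d[1]) * rep(as.vector(mask), each = d[1])
  tcrossprod(Fm) / s
}

#' Content loss between two feature map sets
#'
#' Sum over content layers of the mean squared feature difference
#' (`1/(H_l W_l C_l) * sum((x - yhat)^2)`).
#'
#' @param x_feats,yhat_feats Named lists of `C x H x W` arrays (see
#'   [extract_features()]).
#' @param layers Layers to include.
#' @return Non-negative scalar; 0 iff the features agree on all layers.
#' @export
content_loss <- function(x_feats, yhat_feats, layers = names(x_feats)) {
  total <- 0
  for (l in layers) {
    a <- x_feats[[l]]; b <- yhat_feats[[l]]
    assert_that(!is.null(a) && !is.null(b), sprintf("layer '%s' missing", l))
    assert_that(identical(dim(a), dim(b)), sprintf("layer '%s' shape mismatch", l))
    total <- total + mean((a - b)^2)
  }
  total
}

local_style_layer_terms <- function(y_feats, yhat_feats, y_mask, yhat_mask, cfg) {
  lapply(cfg$style_layers, function(l) {
    fy <- y_feats[[l]]; fh <- yhat_feats[[l]]
    assert_that(!is.null(fy) && !is.null(fh), sprintf("style layer '%s' missing", l))
    my <- layer_mask(y_mask, dim(fy)[2:3])
    mh <- layer_mask(yhat_mask, dim(fh)[2:3])
    if (sum(my) <= 0 || sum(mh) <= 0) {
      stop_rindcast(sprintf("degenerate mask at style layer '%s'", l),
                    class = "rindcast_degenerate_mask")
    }
    Gy <- masked_normalized_gram(fy, my)
    Gh <- masked_normalized_gram(fh, mh)
    list(layer = l, Gy = Gy, Gh = Gh,
         pref = cfg$style_layer_weights[[l]] * style_prefactor(cfg, dim(fy)))
  })
}

#' Local (mask-normalized) style loss
#'
#' The package's core style distance between a reference image `y` and a
#' generated image `yhat`: a weighted sum over style layers of the squared
#' entrywise difference between the two mask-normalized Gram matrices. By
#' construction it ignores everything outside the masks and is invariant to
#' the area of a constant-textured masked region.
#'
#' @param y_feats,yhat_feats Feature map sets of the two images.
#' @param y_mask,yhat_mask Binary image-resolution masks; each is resized to
#'   every style layer's resolution by nearest neighbor.
#' @param cfg A [style_config()].
#' @return Non-negative scalar; 0 when `yhat == y` with equal masks;
#'   symmetric under swapping the two images.
#' @export
local_style_loss <- function(y_feats, yhat_feats, y_mask, yhat_mask,
                             cfg = style_config()) {
  terms <- local_style_layer_terms(y_feats, yhat_feats, y_mask, yhat_mask, cfg)
  sum(vapply(terms, function(t) t$pref * sum((t$Gh - t$Gy)^2), numeric(1)))
}

#' Local perceptual loss
#'
#' The generator's training objective: content loss between the input `x`
#' and the generated image `yhat` (structure fidelity) plus the local style
#' loss between the ground truth `y` and `yhat` (color/texture fidelity),
#' weighted by `cfg$content_weight` and `cfg$style_weight` (default 1:1).
#'
#' @param x_feats,y_feats,yhat_feats Feature map sets of input, ground truth
#'   and generated image.
#' @param y_mask,yhat_mask Masks for the style term.
#' @param cfg A [style_config()].
#' @return Non-negative scalar; 0 when `yhat == x == y` with equal masks.
#' @export
local_perceptual_loss <- function(x_feats, y_feats, yhat_feats,
                                  y_mask, yhat_mask, cfg = style_config()) {
  cfg$content_weight * content_loss(x_feats, yhat_feats, cfg$content_layers) +
    cfg$style_weight * local_style_loss(y_feats, yhat_feats, y_mask, yhat_mask, cfg)
}

#' Global (unmasked) style loss
#'
#' The classical style loss: a sum over style layers of
#' `W_l / (H_l W_l C_l)^2 * sum((G(yhat) - G(y))^2)` with unnormalized Gram
#' matrices. Unlike [local_style_loss()] it is sensitive to background
#' content and to the area the textured region occupies.
#'
#' @param y_feats,yhat_feats Feature map sets of the two images.
#' @param cfg A [style_config()] (style layers and weights are used).
#' @return Non-negative scalar.
#' @export
style_loss_gatys <- function(y_feats, yhat_feats, cfg = style_config()) {
  total <- 0
  for (l in cfg$style_layers) {
    fy <- y_feats[[l]]; fh <- yhat_feats[[l]]
    assert_that(!is.null(fy) && !is.null(fh), sprintf("style layer '%s' missing", l))
    assert_that(identical(dim(fy), dim(fh)), sprintf("style layer '%s' shape mismatch", l))
    d <- dim(fy)
    total <- total + cfg$style_layer_weights[[l]] / (d[1] * d[2] * d[3])^2 *
      sum((gram(fh) - gram(fy))^2)
  }
  total
}

#' Black-background style loss
#'
#' An intermediate baseline: multiply each image by its mask (black
#' background), then apply the global style loss to the masked images. This
#' removes background influence but remains sensitive to fruit size.
#'
#' @param y,yhat `H x W x 3` images in `[0, 255]`.
#' @param y_mask,yhat_mask Binary image-resolution masks.
#' @param extractor A [feature_extractor()].
#' @param cfg A [style_config()].
#' @return Non-negative scalar.
#' @export
style_loss_blackbg <- function(y, yhat, y_mask, yhat_mask, extractor,
                               cfg = style_config()) {
  check_same_hw(y, y_mask, "image and mask")
  check_same_hw(yhat, yhat_mask, "image and mask")
  blacken <- function(img, m) img * array(rep(m, 3), dim(img))
  fy <- extract_features(blacken(y, y_mask), extractor, cfg$style_layers)
  fh <- extract_features(blacken(yhat, yhat_mask), extractor, cfg$style_layers)
  style_loss_gatys(fy, fh, cfg)
}

#' Pairwise style-difference matrix
#'
#' Computes the style difference between every pair of a set of images under
#' one of the three metrics (global style loss, black-background variant, or
#' the local mask-normalized style loss), optionally quantized into 5
#' equal-width levels between the matrix minimum and maximum - the layout
#' used to compare the three metrics against human perception.
#'
#' @param images List of `H x W x 3` images.
#' @param masks List of binary masks (required for `"blackbg"` and
#'   `"local"`).
#' @param metric One of `"gatys"`, `"blackbg"`, `"local"`.
#' @param extractor A [feature_extractor()].
#' @param cfg A [style_config()].
#' @param quantize If `TRUE`, return integer levels 1..5 instead of raw
#'   values.
#' @return A symmetric matrix with zero diagonal (level 1 diagonal when
#'   quantized).
#' @export
style_difference_matrix <- function(images, masks = NULL,
                                    metric = c("gatys", "blackbg", "local"),
                                    extractor = feature_extractor("identity"),
                                    cfg = style_config(), quantize = FALSE) {
  metric <- match.arg(metric)
  n <- length(images)
  assert_that(n >= 2, "need at least 2 images")
  if (metric %in% c("blackbg", "local")) {
    assert_that(!is.null(masks) && length(masks) == n,
                sprintf("metric '%s' requires one mask per image", metric))
  }
  feats <- if (metric != "blackbg") {
    lapply(images, extract_features, extractor = extractor,
           layers = union(cfg$style_layers, character(0)))
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- switch(metric,
        gatys = style_loss_gatys(feats[[i]], feats[[j]], cfg),
        local = local_style_loss(feats[[i]], feats[[j]],
                                 masks[[i]], masks[[j]], cfg),
        blackbg = style_loss_blackbg(images[[i]], images[[j]],
                                     masks[[i]], masks[[j]], extractor, cfg))
    }
  }
  if (quantize) M <- quantize_levels(M, 5L)
  M
}

#' Quantize a matrix into equal-width levels
#'
#' @param M Numeric matrix.
#' @param levels Number of equal-width bins between `min(M)` and `max(M)`.
#' @return Integer matrix of levels `1..levels`.
#' @export
quantize_levels <- function(M, levels = 5L) {
  rng <- range(M)
  if (diff(rng) == 0) return(matrix(1L, nrow(M), ncol(M)))
  q <- findInterval(M, seq(rng[1], rng[2], length.out = levels + 1L),
                    rightmost.closed = TRUE, all.inside = TRUE)
  matrix(as.integer(q), nrow(M), ncol(M))
}
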