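# Image-quality and colorimetry metrics: PSNR, HunterLab, CCI, CCI error,
# mean local style loss (MLSL), MIoU.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` with the MSE taken over all pixels and
#' channels. Identical images have zero MSE and are reported as `Inf`.
#'
#' @param a,b Images (or any equally-shaped numeric arrays) on `[0, peak]`.
#' @param peak Peak signal value (default 255).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(a, b, peak = 255) {
  assert_that(identical(dim(a), dim(b)), "psnr inputs must have identical shapes")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# sRGB (D65) -> CIE XYZ (Y of white = 100).
SRGB_TO_XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                        0.2126729, 0.7151522, 0.0721750,
                        0.0193339, 0.1191920, 0.9503041),
                      3, 3, byrow = TRUE)
# White point taken as the matrix image of linear white so that neutral
# grays map to exactly a = b = 0 (numerically identical to the textbook
# D65 values 95.047/100/108.883).
WHITE_D65 <- setNames(rowSums(SRGB_TO_XYZ) * 100, c("X", "Y", "Z"))
HUNTER_KA_D65 <- 172.30
HUNTER_KB_D65 <- 67.20
WHITE_C <- c(X = 98.074, Y = 100, Z = 118.232)
HUNTER_KA_C <- 175
HUNTER_KB_C <- 70

#' Convert an sRGB color to Hunter Lab
#'
#' Linearizes sRGB values, converts to CIE XYZ and then to the Hunter Lab
#' opponent space (`L` lightness, `a` red-green, `b` yellow-blue; distinct
#' from CIELAB): `L = 100 sqrt(Y/Yn)`, `a = Ka (X/Xn - Y/Yn) / sqrt(Y/Yn)`,
#' `b = Kb (Y/Yn - Z/Zn) / sqrt(Y/Yn)`. The default white point is D65 with
#' `Ka = 172.30`, `Kb = 67.20`, consistent with sRGB camera imagery;
#' illuminant C (`Ka = 175`, `Kb = 70`) is available for the classical
#' colorimeter convention.
#'
#' @param rgb Length-3 vector in `[0, 255]`.
#' @param white `"D65"` (default) or `"C"`.
#' @return Named vector `c(L, a, b)`. Neutral grays map to `a = b = 0`.
#' @export
rgb_to_hunterlab <- function(rgb, white = c("D65", "C")) {
  white <- match.arg(white)
  assert_that(length(rgb) == 3 && all(is.finite(rgb)) &&
                all(rgb >= 0) && all(rgb <= 255),
              "rgb must be 3 values in [0, 255]")
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- as.numeric(SRGB_TO_XYZ %*% lin) * 100
  wp <- if (white == "D65") WHITE_D65 else WHITE_C
  ka <- if (white == "D65") HUNTER_KA_D65 else HUNTER_KA_C
  kb <- if (white == "D65") HUNTER_KB_D65 else HUNTER_KB_C
  xr <- xyz[1] / wp[1]; yr <- xyz[2] / wp[2]; zr <- xyz[3] / wp[3]
  sy <- sqrt(max(yr, 0))
  L <- 100 * sy
  if (sy == 0) return(c(L = 0, a = 0, b = 0))
  c(L = unname(L), a = unname(ka * (xr - yr) / sy), b = unname(kb * (yr - zr) / sy))
}

#' Citrus color index of the masked fruit region
#'
#' Averages the RGB values over the mask, converts the mean color to Hunter
#' Lab and returns `CCI = 1000 * a / (L * b)`. Negative for green rinds,
#' positive for orange - the standard maturity proxy. The index is a
#' function of the masked pixels only.
#'
#' Degenerate denominators (`L * b` near 0) do not occur for real rinds; if
#' the mean color is neutral (`|a|` also ~0) the index is defined as 0,
#' otherwise near-zero `b` is clamped at `1e-6` in magnitude with a warning.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param mask Binary `H x W` matrix with `sum(mask) > 0`.
#' @param white White point passed to [rgb_to_hunterlab()].
#' @return CCI scalar.
#' @export
cci <- function(image, mask, white = "D65") {
  check_image(image); check_mask(mask)
  check_same_hw(image, mask, "image and mask")
  assert_that(sum(mask) > 0, "cci: mask is empty")
  sel <- which(mask == 1)
  mean_rgb <- c(mean(image[, , 1][sel]), mean(image[, , 2][sel]),
                mean(image[, , 3][sel]))
  lab <- rgb_to_hunterlab(mean_rgb, white)
  if (abs(lab["a"]) < 1e-4 && abs(lab["L"] * lab["b"]) < 1e-3) return(0)
  b <- lab["b"]
  if (abs(b) < 1e-6) {
    warn("cci: near-neutral b clamped to 1e-6")
    b <- sign(b + (b == 0)) * 1e-6
  }
  unname(1000 * lab["a"] / (lab["L"] * b))
}

#' CCI error between a prediction and the ground truth
#'
#' The L1 distance between the two images' citrus color indices, each
#' computed over its own mask.
#'
#' @param pred,truth Images in `[0, 255]`.
#' @param pred_mask,truth_mask Binary masks.
#' @param white White point passed to [rgb_to_hunterlab()].
#' @return Non-negative scalar; 0 for identical image/mask pairs.
#' @export
cci_error <- function(pred, truth, pred_mask, truth_mask, white = "D65") {
  abs(cci(pred, pred_mask, white) - cci(truth, truth_mask, white))
}

#' Mean local style loss over an evaluation set
#'
#' The arithmetic mean of [local_style_loss()] between generated and
#' ground-truth images over a list of pairs; the accuracy metric for color
#' prediction (lower = closer rind style).
#'
#' @param pairs List of lists with elements `generated`, `truth`,
#'   `generated_mask`, `truth_mask`.
#' @param extractor A [feature_extractor()].
#' @param cfg A [style_config()].
#' @return Non-negative scalar.
#' @export
mlsl <- function(pairs, extractor, cfg = style_config()) {
  assert_that(length(pairs) > 0, "mlsl: empty pair list")
  vals <- vapply(pairs, function(p) {
    fg <- extract_features(p$generated, extractor, cfg$style_layers)
    ft <- extract_features(p$truth, extractor, cfg$style_layers)
    local_style_loss(ft, fg, p$truth_mask, p$generated_mask, cfg)
  }, numeric(1))
  mean(vals)
}

#' Mean intersection over union
#'
#' Pools confusion counts over the whole list (dataset-level convention) and
#' returns the mean of the fruit-class and background-class IoU. Set
#' `per_image = TRUE` to average per-image MIoU instead.
#'
#' @param preds,truths Equal-length lists of binary masks (or single masks).
#' @param per_image Average per image instead of pooling counts.
#' @return Scalar in `[0, 1]`.
#' @export
miou <- function(preds, truths, per_image = FALSE) {
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(truths)) truths <- list(truths)
  assert_that(length(preds) == length(truths) && length(preds) > 0,
              "miou needs equal-length, non-empty mask lists")
  one <- function(tp, fp, fn, tn) {
    iou_f <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
    iou_b <- if (tn + fp + fn == 0) 1 else tn / (tn + fp + fn)
    unname((iou_f + iou_b) / 2)
  }
  counts <- function(p, g) {
    assert_that(identical(dim(p), dim(g)), "miou: mask shape mismatch")
    c(tp = sum(p == 1 & g == 1), fp = sum(p == 1 & g == 0),
      fn = sum(p == 0 & g == 1), tn = sum(p == 0 & g == 0))
  }
  if (per_image) {
    mean(mapply(function(p, g) {
      ct <- counts(p, g); one(ct["tp"], ct["fp"], ct["fn"], ct["tn"])
    }, preds, truths))
  } else {
    ct <- rowSums(mapply(counts, preds, truths))
    one(ct["tp"], ct["fp"], ct["fn"], ct["tn"])
  }
}
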