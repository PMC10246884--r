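# Aggregate evaluation of a trained generator over a set of pairs.

#' Load paired examples into memory
#'
#' Materializes rows of a [build_pairs()] tibble as the in-memory example
#' lists consumed by [train_generator()] and [evaluate_generator()]. Each
#' distinct file is read once.
#'
#' @param pairs_tbl Tibble from [build_pairs()] (paths already resolved).
#' @param max_pairs Optional cap; a seeded random subset is taken when the
#'   table is larger.
#' @param seed Seed for the subset draw.
#' @return List of `list(input, input_mask, target, target_mask, N)`.
#' @export
load_pair_examples <- function(pairs_tbl, max_pairs = Inf, seed = 1L) {
  n <- nrow(pairs_tbl)
  if (n > max_pairs) {
    keep <- with_seed(derive_seed(seed, 91L), sample(n, max_pairs))
    pairs_tbl <- pairs_tbl[sort(keep), ]
  }
  img_cache <- new.env(parent = emptyenv())
  getim <- function(path, what) {
    key <- paste0(what, ":", path)
    if (is.null(img_cache[[key]])) {
      img_cache[[key]] <- if (what == "img") read_image(path) else read_mask(path)
    }
    img_cache[[key]]
  }
  purrr::pmap(pairs_tbl, function(interval_days, input_image, input_mask,
                                  target_image, target_mask, ...) {
    list(input = getim(input_image, "img"),
         input_mask = getim(input_mask, "mask"),
         target = getim(target_image, "img"),
         target_mask = getim(target_mask, "mask"),
         N = interval_days)
  })
}

#' Evaluate a trained generator on a pair set
#'
#' For every pair, predicts the target-day image from the input and
#' interval, then aggregates: mean PSNR against the configured reference
#' image (`"input"` by default - the background is re-fused from the input,
#' which makes the comparison well-defined without pixel correspondence to
#' the target; `"target"` available), MLSL against the ground truth, and
#' mean CCI error. If a segmentation model is supplied, prediction masks
#' come from it (instead of the ground-truth input masks) and the report
#' additionally carries the MIoU of those masks.
#'
#' @param model Trained `gen_model`.
#' @param pairs List of examples (see [load_pair_examples()]).
#' @param extractor [feature_extractor()] for the MLSL.
#' @param cfg [style_config()] for the MLSL.
#' @param psnr_reference `"input"` or `"target"`.
#' @param seg_model Optional trained `seg_model`.
#' @return One-row tibble: `psnr`, `mlsl`, `cci_error`, `miou`, `n_pairs`.
#' @export
evaluate_generator <- function(model, pairs, extractor = NULL, cfg = NULL,
                               psnr_reference = c("input", "target"),
                               seg_model = NULL) {
  psnr_reference <- match.arg(psnr_reference)
  assert_that(length(pairs) > 0, "evaluate_generator: empty pair set")
  extractor <- extractor %||% feature_extractor("identity", scale = 1 / 255)
  cfg <- cfg %||% default_pixel_loss_cfg()
  ps <- numeric(0); ce <- numeric(0); ml <- list()
  pred_masks <- list(); true_masks <- list()
  for (pp in pairs) {
    in_mask <- if (!is.null(seg_model)) predict_mask(seg_model, pp$input) else
      pp$input_mask
    if (sum(in_mask) == 0) in_mask <- pp$input_mask   # degenerate fallback
    pred <- predict(model, pp$input, in_mask, pp$N)
    ref <- if (psnr_reference == "input") pp$input else pp$target
    ps <- c(ps, psnr(pred, ref))
    ce <- c(ce, cci_error(pred, pp$target, in_mask, pp$target_mask))
    ml[[length(ml) + 1L]] <- list(generated = pred, truth = pp$target,
                                  generated_mask = in_mask,
                                  truth_mask = pp$target_mask)
    if (!is.null(seg_model)) {
      pred_masks[[length(pred_masks) + 1L]] <- in_mask
      true_masks[[length(true_masks) + 1L]] <- pp$input_mask
    }
  }
  tibble(
    psnr = mean(ps),
    mlsl = mlsl(ml, extractor, cfg),
    cci_error = mean(ce),
    miou = if (!is.null(seg_model)) miou(pred_masks, true_masks) else NA_real_,
    n_pairs = length(pairs)
  )
}

#' Write a metrics report as CSV
#'
#' Serializes evaluation rows in the standard report layout; infinite PSNR
#' values are written as the string `"inf"`.
#'
#' @param report Tibble of metric rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- as.data.frame(report)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && any(is.infinite(out[[col]]))) {
      out[[col]] <- ifelse(is.infinite(out[[col]]), "inf",
                           format(out[[col]], digits = 10))
    }
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
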