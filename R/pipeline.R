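# End-to-end orchestration: synthesize -> train segmentation -> train
# generator -> predict/evaluate -> k-fold. Every run function logs its
# resolved configuration and seed, and writes artifacts (checkpoints,
# history CSVs, reports) under an output directory so any result is
# reproducible from the log alone.

log_msg <- function(..., logfile = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Assemble a run configuration
#'
#' Collects the nested configurations the pipeline commands consume.
#' [load_run_config()] reads the same structure from a YAML file (omitted
#' fields keep their defaults).
#'
#' @param data_dir Dataset directory (holding `manifest.csv`).
#' @param out_dir Output directory for checkpoints, logs and reports.
#' @param seed Global integer seed.
#' @param synth Named list of [generate_dataset()] arguments.
#' @param seg Named list of [seg_config()] arguments.
#' @param gen Named list of [generator_config()] arguments.
#' @param pairing Named list: `n_min`, `n_max`, `same_view`, `max_pairs`.
#' @param split Named list: `ratios` (length 3) and/or `k`.
#' @param metrics Named list: `psnr_reference`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(data_dir = "data", out_dir = "runs", seed = 1L,
                       synth = list(), seg = list(), gen = list(),
                       pairing = list(), split = list(), metrics = list()) {
  cfg <- list(
    data_dir = data_dir, out_dir = out_dir, seed = as.integer(seed),
    synth = utils::modifyList(list(n_samples = 12L, days = 16L,
                                   views_per_sample = 1L, size = c(64L, 64L),
                                   dropout_prob = 0.05), synth),
    seg = do.call(seg_config, utils::modifyList(
      list(input_size = c(64L, 64L), encoder_depth = 3L, base_channels = 8L,
           batch_size = 8L, epochs = 8L), seg)),
    gen = do.call(generator_config, utils::modifyList(
      list(input_size = c(64L, 64L), stem_channels = c(16L, 64L),
           n_resblocks = 2L, batch_size = 4L, epochs = 10L), gen)),
    pairing = utils::modifyList(list(n_min = 2L, n_max = 10L,
                                     same_view = FALSE, max_pairs = 200L),
                                pairing),
    split = utils::modifyList(list(ratios = c(3, 1, 1), k = 5L), split),
    metrics = utils::modifyList(list(psnr_reference = "input"), metrics)
  )
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any subset of the `run_config` fields.
#' @param overrides Named list applied on top of the file (CLI flags).
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals <- utils::modifyList(vals, overrides)
  keep <- intersect(names(vals), names(formals(run_config)))
  do.call(run_config, vals[keep])
}

record_run <- function(cfg, out_dir, command) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, paste0(command, ".log"))
  resolved <- rapply(unclass(cfg), function(x) x, how = "list")
  yaml::write_yaml(resolved, file.path(out_dir, paste0(command, "_config.yaml")))
  log_msg("%s: seed %d, config written to %s", command, cfg$seed, out_dir,
          logfile = logfile)
  logfile
}

#' Save / load a model checkpoint
#'
#' A checkpoint is one file holding the weights together with the full
#' configuration, training history and seed.
#'
#' @param model A `seg_model` or `gen_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  assert_that(file.exists(path), sprintf("checkpoint not found: %s", path))
  readRDS(path)
}

#' Pipeline: synthesize a dataset
#'
#' @param cfg A [run_config()].
#' @return The manifest path, invisibly.
#' @export
run_synth <- function(cfg = run_config()) {
  logfile <- record_run(cfg, cfg$data_dir, "synth")
  args <- cfg$synth
  args$out_dir <- cfg$data_dir
  args$seed <- cfg$seed
  path <- do.call(generate_dataset, args)
  log_msg("synth: wrote %s (%d records)", path,
          nrow(load_manifest(path)), logfile = logfile)
  invisible(path)
}

seg_examples <- function(records) {
  lapply(seq_len(nrow(records)), function(i) {
    list(image = read_image(records$image_path[i]),
         mask = read_mask(records$mask_path[i]))
  })
}

gen_pair_examples <- function(records, pairing, seed) {
  tbl <- build_pairs(records, n_min = pairing$n_min, n_max = pairing$n_max,
                     same_view = pairing$same_view)
  assert_that(nrow(tbl) > 0, "no pairs in this partition under the interval range")
  load_pair_examples(tbl, max_pairs = pairing$max_pairs, seed = seed)
}

#' Pipeline: train the segmentation or generative stage
#'
#' Loads the manifest, applies the sample-disjoint 3:1:1 split, trains the
#' requested stage on the train partition with the val partition for epoch
#' bookkeeping/model selection, and writes a checkpoint plus history CSV.
#'
#' @param cfg A [run_config()].
#' @param stage `"seg"` or `"gen"`.
#' @return The trained model, invisibly.
#' @export
run_train <- function(cfg = run_config(), stage = c("seg", "gen")) {
  stage <- match.arg(stage)
  logfile <- record_run(cfg, cfg$out_dir, paste0("train_", stage))
  records <- load_manifest(file.path(cfg$data_dir, "manifest.csv"))
  split <- split_by_sample(records, cfg$split$ratios, cfg$seed)
  write_split(split, file.path(cfg$out_dir, "split.json"))
  tr <- filter_partition(records, split, "train")
  va <- filter_partition(records, split, "val")
  if (stage == "seg") {
    model <- train_segmentation(seg_examples(tr), cfg$seg,
                                seed = derive_seed(cfg$seed, 1L),
                                val_data = seg_examples(va))
    hist_path <- file.path(cfg$out_dir, "seg_history.csv")
    ckpt <- file.path(cfg$out_dir, "seg_checkpoint.rds")
  } else {
    model <- train_generator(gen_pair_examples(tr, cfg$pairing, cfg$seed),
                             cfg$gen, seed = derive_seed(cfg$seed, 2L),
                             val_pairs = gen_pair_examples(va, cfg$pairing,
                                                           cfg$seed),
                             psnr_reference = cfg$metrics$psnr_reference)
    hist_path <- file.path(cfg$out_dir, "gen_history.csv")
    ckpt <- file.path(cfg$out_dir, "gen_checkpoint.rds")
  }
  utils::write.csv(model$history, hist_path, row.names = FALSE)
  save_checkpoint(model, ckpt)
  log_msg("train-%s: %d epochs, best epoch %d, checkpoint %s", stage,
          nrow(model$history), model$best_epoch, ckpt, logfile = logfile)
  invisible(model)
}

#' Pipeline: predict future rind color for one image
#'
#' Predicts the composited image at each requested interval (the multi-panel
#' sweep layout). If no mask is given, the segmentation checkpoint produces
#' one.
#'
#' @param gen_checkpoint Path to a generator checkpoint.
#' @param image_path Input image (PNG/JPEG).
#' @param out_dir Output directory.
#' @param N Integer vector of intervals (days).
#' @param mask_path Optional mask PNG.
#' @param seg_checkpoint Optional segmentation checkpoint (required when
#'   `mask_path` is absent).
#' @return Tibble of (`N`, `path`) for the written images, invisibly.
#' @export
run_predict <- function(gen_checkpoint, image_path, out_dir, N = c(5, 10, 15, 20),
                        mask_path = NULL, seg_checkpoint = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- load_checkpoint(gen_checkpoint)
  image <- read_image(image_path)
  mask <- if (!is.null(mask_path)) {
    read_mask(mask_path)
  } else {
    assert_that(!is.null(seg_checkpoint),
                "either mask_path or seg_checkpoint is required")
    predict_mask(load_checkpoint(seg_checkpoint), image)
  }
  if (model$cfg$use_embedding) check_interval(N, model$cfg$n_max)
  out <- purrr::map_chr(N, function(n) {
    pred <- predict(model, image, mask, n)
    path <- file.path(out_dir, sprintf("predicted_N%02d.png", n))
    write_image(pred, path)
    path
  })
  log_msg("predict: wrote %d image(s) to %s", length(out), out_dir)
  invisible(tibble(N = N, path = out))
}

#' Pipeline: evaluate a trained generator on a partition
#'
#' @param cfg A [run_config()].
#' @param partition Partition to evaluate (default `"test"`).
#' @param use_seg_masks Produce prediction masks with the segmentation
#'   checkpoint instead of the annotations.
#' @return The metrics report tibble, invisibly.
#' @export
run_eval <- function(cfg = run_config(), partition = "test",
                     use_seg_masks = FALSE) {
  logfile <- record_run(cfg, cfg$out_dir, "eval")
  records <- load_manifest(file.path(cfg$data_dir, "manifest.csv"))
  split <- split_by_sample(records, cfg$split$ratios, cfg$seed)
  part <- filter_partition(records, split, partition)
  model <- load_checkpoint(file.path(cfg$out_dir, "gen_checkpoint.rds"))
  seg_model <- if (use_seg_masks)
    load_checkpoint(file.path(cfg$out_dir, "seg_checkpoint.rds"))
  pairs <- gen_pair_examples(part, cfg$pairing, cfg$seed)
  report <- evaluate_generator(model, pairs,
                               psnr_reference = cfg$metrics$psnr_reference,
                               seg_model = seg_model)
  report <- dplyr::mutate(report, partition = partition, .before = 1)
  write_report(report, file.path(cfg$out_dir, sprintf("eval_%s.csv", partition)))
  log_msg("eval[%s]: PSNR %.3f, MLSL %.5f, CCI error %.4f (%d pairs)",
          partition, report$psnr, report$mlsl, report$cci_error,
          report$n_pairs, logfile = logfile)
  invisible(report)
}

#' Pipeline: sample-wise k-fold cross-validation
#'
#' Trains and evaluates both stages once per fold (fold i as the test set)
#' and emits the standard per-fold table with rows (fold, set, miou, psnr,
#' mlsl, cci_error).
#'
#' @param cfg A [run_config()].
#' @param k Number of folds (default from `cfg$split$k`).
#' @return The per-fold report tibble, invisibly.
#' @export
run_kfold <- function(cfg = run_config(), k = cfg$split$k) {
  logfile <- record_run(cfg, cfg$out_dir, "kfold")
  records <- load_manifest(file.path(cfg$data_dir, "manifest.csv"))
  assignments <- kfold_by_sample(records, k, cfg$seed)
  rows <- list()
  for (i in seq_len(k)) {
    tr <- filter_partition(records, assignments[[i]], "train")
    te <- filter_partition(records, assignments[[i]], "test")
    seg <- train_segmentation(seg_examples(tr), cfg$seg,
                              seed = derive_seed(cfg$seed, i, 3L))
    gen <- train_generator(gen_pair_examples(tr, cfg$pairing, cfg$seed),
                           cfg$gen, seed = derive_seed(cfg$seed, i, 4L),
                           psnr_reference = cfg$metrics$psnr_reference)
    for (set in c("train", "test")) {
      recs <- if (set == "train") tr else te
      seg_miou <- miou(lapply(seq_len(nrow(recs)), function(j)
        predict_mask(seg, read_image(recs$image_path[j]))),
        lapply(recs$mask_path, read_mask))
      rep <- evaluate_generator(gen, gen_pair_examples(recs, cfg$pairing,
                                                       cfg$seed),
                                psnr_reference = cfg$metrics$psnr_reference)
      rows[[length(rows) + 1L]] <- tibble(fold = i, set = set, miou = seg_miou,
                                          psnr = rep$psnr, mlsl = rep$mlsl,
                                          cci_error = rep$cci_error)
    }
    log_msg("kfold: fold %d/%d done", i, k, logfile = logfile)
  }
  report <- dplyr::bind_rows(rows)
  write_report(report, file.path(cfg$out_dir, "kfold_report.csv"))
  invisible(report)
}
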