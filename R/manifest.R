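# Dataset manifest handling, temporal pairing and sample-disjoint splitting.
#
# A manifest row is one acquisition: (sample_id, day, view, image_path,
# mask_path). `day` is a relative integer index within a sample's series;
# (sample_id, day, view) is unique.

MANIFEST_COLS <- c("sample_id", "day", "view", "image_path", "mask_path")
VIEW_LEVELS <- c("front", "bottom", "side")

validate_manifest <- function(df, base_dir = NULL, check_paths = TRUE) {
  missing <- setdiff(MANIFEST_COLS, names(df))
  assert_that(length(missing) == 0,
              sprintf("manifest is missing column(s): %s", paste(missing, collapse = ", ")))
  df <- as_tibble(df)[MANIFEST_COLS]
  if (nrow(df) == 0) {
    df$day <- integer(0)
    return(df)
  }
  df$sample_id <- as.character(df$sample_id)
  assert_that(all(!is.na(df$day)) && all(df$day == as.integer(df$day)) && all(df$day >= 0),
              "manifest 'day' must be a non-negative integer")
  df$day <- as.integer(df$day)
  assert_that(all(df$view %in% VIEW_LEVELS),
              sprintf("manifest 'view' must be one of: %s", paste(VIEW_LEVELS, collapse = ", ")))
  key <- paste(df$sample_id, df$day, df$view, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop_rindcast(sprintf("duplicate manifest key: sample '%s', day %d, view '%s'",
                          d$sample_id, d$day, d$view))
  }
  if (!is.null(base_dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df$image_path)
    df$image_path[rel] <- file.path(base_dir, df$image_path[rel])
    rel <- !grepl("^(/|[A-Za-z]:)", df$mask_path)
    df$mask_path[rel] <- file.path(base_dir, df$mask_path[rel])
  }
  if (check_paths) {
    for (col in c("image_path", "mask_path")) {
      bad <- !file.exists(df[[col]])
      if (any(bad)) {
        stop_rindcast(sprintf("manifest references missing file(s), e.g. '%s'",
                              df[[col]][which(bad)[1]]))
      }
    }
  }
  df
}

#' Load a dataset manifest
#'
#' Reads a CSV (header `sample_id,day,view,image_path,mask_path`) or JSON
#' manifest describing one image series per fruit sample, validates it
#' (required columns, non-negative integer days, known views, unique
#' `(sample_id, day, view)` keys, existing image/mask files) and returns a
#' tibble of records.
#'
#' @param path Manifest file (`.csv` or `.json`).
#' @param check_paths Verify that every referenced image/mask file exists
#'   (default `TRUE`). Relative paths are resolved against the manifest's
#'   directory.
#' @return A tibble with columns `sample_id`, `day`, `view`, `image_path`,
#'   `mask_path`. An empty manifest yields a zero-row tibble.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  assert_that(file.exists(path), sprintf("manifest file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (file.info(path)$size == 0) {
    df <- tibble(sample_id = character(0), day = integer(0), view = character(0),
                 image_path = character(0), mask_path = character(0))
    return(df)
  }
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    json = {
      x <- jsonlite::fromJSON(path)
      if (length(x) == 0) data.frame(sample_id = character(0), day = character(0),
                                     view = character(0), image_path = character(0),
                                     mask_path = character(0)) else as.data.frame(x)
    },
    stop_rindcast(sprintf("unsupported manifest format '%s' (use CSV or JSON)", ext))
  )
  if (nrow(df) > 0 && "day" %in% names(df)) df$day <- as.integer(df$day)
  validate_manifest(df, base_dir = dirname(normalizePath(path)), check_paths = check_paths)
}

#' Write a dataset manifest
#'
#' @param records Manifest tibble (see [load_manifest()]).
#' @param path Output `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  records <- validate_manifest(records, check_paths = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = utils::write.csv(records, path, row.names = FALSE, quote = FALSE),
    json = jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = TRUE),
    stop_rindcast(sprintf("unsupported manifest format '%s' (use CSV or JSON)", ext))
  )
  invisible(path)
}

#' Build temporally paired training examples
#'
#' Enumerates all within-sample `(input, target)` record pairs whose day
#' difference `N = target$day - input$day` lies in `[n_min, n_max]`. Pairing
#' is within a sample only; by default views may differ between input and
#' target (the method does not require strict structural correspondence), and
#' `same_view = TRUE` restricts pairs to matching views.
#'
#' @param records Manifest tibble.
#' @param n_min,n_max Integer bounds on the time interval in days
#'   (`n_min >= 1`).
#' @param same_view Require input and target views to match (default `FALSE`).
#' @return A tibble with one row per pair: `sample_id`, `interval_days`,
#'   input and target `day`/`view`/`image_path`/`mask_path` columns
#'   (prefixed `input_` / `target_`).
#' @export
build_pairs <- function(records, n_min = 1L, n_max = 45L, same_view = FALSE) {
  assert_that(n_min >= 1, "n_min must be >= 1")
  assert_that(n_max >= n_min, "n_max must be >= n_min")
  records <- validate_manifest(records, check_paths = FALSE)
  if (nrow(records) == 0) return(empty_pairs())
  idx <- tidyr::crossing(i = seq_len(nrow(records)), j = seq_len(nrow(records)))
  a <- records[idx$i, ]; b <- records[idx$j, ]
  keep <- a$sample_id == b$sample_id &
    (b$day - a$day) >= n_min & (b$day - a$day) <= n_max
  if (same_view) keep <- keep & a$view == b$view
  a <- a[keep, ]; b <- b[keep, ]
  out <- tibble(
    sample_id = a$sample_id,
    interval_days = as.integer(b$day - a$day),
    input_day = a$day, input_view = a$view,
    input_image = a$image_path, input_mask = a$mask_path,
    target_day = b$day, target_view = b$view,
    target_image = b$image_path, target_mask = b$mask_path
  )
  dplyr::arrange(out, .data$sample_id, .data$input_day, .data$target_day,
                 .data$input_view, .data$target_view)
}

empty_pairs <- function() {
  tibble(sample_id = character(0), interval_days = integer(0),
         input_day = integer(0), input_view = character(0),
         input_image = character(0), input_mask = character(0),
         target_day = integer(0), target_view = character(0),
         target_image = character(0), target_mask = character(0))
}

#' Sample-disjoint train/validation/test split
#'
#' Randomly assigns whole samples (never individual images) to train,
#' validation and test partitions in the given ratios, so a sample's images
#' appear in exactly one partition. Partition sizes: validation and test get
#' `floor(n * ratio)` samples each and train takes the remainder, e.g. 10
#' samples at 3:1:1 give (6, 2, 2) and 107 give (65, 21, 21).
#'
#' @param records Manifest tibble (or any data frame with `sample_id`).
#' @param ratios Numeric length-3 vector of train:val:test proportions
#'   (default `c(3, 1, 1)`).
#' @param seed Integer seed; the split is a pure function of
#'   (sample set, ratios, seed).
#' @return A tibble `sample_id`, `partition` (factor train/val/test).
#' @export
split_by_sample <- function(records, ratios = c(3, 1, 1), seed = 1L) {
  assert_that(length(ratios) == 3 && all(ratios > 0), "ratios must be 3 positive numbers")
  ids <- sort(unique(as.character(records$sample_id)))
  n <- length(ids)
  assert_that(n >= 3, "need at least one sample per partition")
  assert_that(n >= 5, "need at least 5 distinct samples for a 3:1:1 split")
  n_val <- floor(n * ratios[2] / sum(ratios))
  n_test <- floor(n * ratios[3] / sum(ratios))
  n_train <- n - n_val - n_test
  shuffled <- with_seed(derive_seed(seed, 101L), sample(ids))
  tibble(
    sample_id = shuffled,
    partition = factor(rep(c("train", "val", "test"), c(n_train, n_val, n_test)),
                       levels = c("train", "val", "test"))
  ) |> dplyr::arrange(.data$sample_id)
}

#' Sample-wise k-fold cross-validation assignments
#'
#' Partitions the sample set evenly and randomly into `k` folds; the i-th
#' assignment uses fold i as the test set and the remaining samples for
#' training. Fold sizes differ by at most one, and across the `k`
#' assignments every sample is tested exactly once.
#'
#' @param records Manifest tibble (or any data frame with `sample_id`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A list of `k` tibbles, each with columns `sample_id` and
#'   `partition` (train/test); element `i` tests fold `i`. The underlying
#'   fold index per sample is attached as attribute `"folds"`.
#' @export
kfold_by_sample <- function(records, k = 5L, seed = 1L) {
  assert_that(k >= 2, "k must be >= 2")
  ids <- sort(unique(as.character(records$sample_id)))
  n <- length(ids)
  assert_that(k <= n, sprintf("k = %d exceeds the number of samples (%d)", k, n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  shuffled <- with_seed(derive_seed(seed, 202L), sample(ids))
  fold_of <- rep(seq_len(k), sizes)
  folds <- tibble(sample_id = shuffled, fold = fold_of) |>
    dplyr::arrange(.data$sample_id)
  out <- lapply(seq_len(k), function(i) {
    tibble(sample_id = folds$sample_id,
           partition = factor(ifelse(folds$fold == i, "test", "train"),
                              levels = c("train", "test")))
  })
  attr(out, "folds") <- folds
  out
}

#' Serialize / read a split assignment as JSON
#'
#' Splits are stored as a JSON object mapping `sample_id` to partition label.
#'
#' @param split Tibble with `sample_id` and `partition`.
#' @param path Output `.json` path.
#' @return `path` (write) or the split tibble (read).
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(as.list(setNames(as.character(split$partition), split$sample_id)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::fromJSON(path)
  tibble(sample_id = names(x),
         partition = factor(unlist(x), levels = unique(c("train", "val", "test", unlist(x)))))
}

# Restrict a manifest to the samples of one partition.
#' Filter manifest records by split partition
#'
#' @param records Manifest tibble.
#' @param split Split tibble from [split_by_sample()] or one element of
#'   [kfold_by_sample()].
#' @param partition Partition label to keep.
#' @return The subset of `records` whose samples are in `partition`.
#' @export
filter_partition <- function(records, split, partition) {
  keep <- split$sample_id[split$partition == partition]
  dplyr::filter(records, .data$sample_id %in% keep)
}
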