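# broom-style accessors and ggplot2 visualization for fitted models.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_text
#'   scale_fill_gradient labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' @export
print.seg_model <- function(x, ...) {
  cat("<seg_model> U-Net fruit segmentation\n")
  cat(sprintf("  input %dx%d, depth %d, base channels %d, %s params\n",
              x$cfg$input_size[1], x$cfg$input_size[2], x$cfg$encoder_depth,
              x$cfg$base_channels, format(count_parameters(x), big.mark = ",")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; best epoch %d (val MIoU %s)\n",
                nrow(x$history), x$best_epoch %||% NA,
                format(max(x$history$val_miou, na.rm = TRUE), digits = 4)))
  }
  invisible(x)
}

#' @export
print.gen_model <- function(x, ...) {
  cat("<gen_model> time-conditioned color-transformation generator\n")
  cat(sprintf("  input %dx%d, stem %s, %d resblocks, %s params, %s\n",
              x$cfg$input_size[1], x$cfg$input_size[2],
              paste(x$cfg$stem_channels, collapse = "->"), x$cfg$n_resblocks,
              format(count_parameters(x), big.mark = ","),
              if (x$cfg$use_embedding)
                sprintf("interval embeddings 1..%d", x$cfg$n_max)
              else sprintf("fixed interval%s",
                           if (!is.null(x$fixed_interval))
                             paste0(" N=", x$fixed_interval) else "")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; selected epoch %d\n",
                nrow(x$history), x$best_epoch %||% NA))
  }
  invisible(x)
}

#' Tidy the per-epoch training history
#'
#' @param x A fitted `seg_model` or `gen_model`.
#' @param ... Unused.
#' @return The history tibble (one row per epoch).
#' @method tidy seg_model
#' @export
tidy.seg_model <- function(x, ...) x$history %||% tibble()

#' @rdname tidy.seg_model
#' @method tidy gen_model
#' @export
tidy.gen_model <- function(x, ...) x$history %||% tibble()

#' One-row model summary
#'
#' @param x A fitted `seg_model` or `gen_model`.
#' @param ... Unused.
#' @return A one-row tibble with architecture and final-metric columns.
#' @method glance seg_model
#' @export
glance.seg_model <- function(x, ...) {
  h <- x$history
  tibble(epochs = if (is.null(h)) 0L else nrow(h),
         best_epoch = x$best_epoch %||% NA_integer_,
         best_val_miou = if (is.null(h)) NA_real_ else
           suppressWarnings(max(h$val_miou, na.rm = TRUE)),
         n_params = count_parameters(x))
}

#' @rdname glance.seg_model
#' @method glance gen_model
#' @export
glance.gen_model <- function(x, ...) {
  h <- x$history
  sel <- x$best_epoch %||% NA_integer_
  tibble(epochs = if (is.null(h)) 0L else nrow(h),
         selected_epoch = sel,
         val_psnr = if (is.null(h) || is.na(sel)) NA_real_ else
           h$val_psnr[h$epoch == sel],
         val_mlsl = if (is.null(h) || is.na(sel)) NA_real_ else
           h$val_mlsl[h$epoch == sel],
         n_params = count_parameters(x))
}

history_long <- function(h) {
  tidyr::pivot_longer(h, -"epoch", names_to = "metric", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
}

#' Plot a training history
#'
#' @param object A fitted `seg_model` or `gen_model`.
#' @param ... Unused.
#' @return A ggplot of each recorded metric against epoch.
#' @method autoplot seg_model
#' @export
autoplot.seg_model <- function(object, ...) {
  ggplot(history_long(tidy(object)), aes(.data$epoch, .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL, title = "Segmentation training history") +
    theme_minimal()
}

#' @rdname autoplot.seg_model
#' @method autoplot gen_model
#' @export
autoplot.gen_model <- function(object, ...) {
  ggplot(history_long(tidy(object)), aes(.data$epoch, .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL, title = "Generator training history") +
    theme_minimal()
}

#' Heat map of a style-difference matrix
#'
#' Visualizes a [style_difference_matrix()] (optionally 5-level quantized)
#' in the standard row/column sample layout.
#'
#' @param M Symmetric matrix of pairwise style differences.
#' @param quantize Show 5 equal-width levels instead of raw values.
#' @return A ggplot heat map.
#' @export
plot_style_matrix <- function(M, quantize = TRUE) {
  V <- if (quantize) quantize_levels(M, 5L) else M
  df <- tibble(
    i = rep(seq_len(nrow(V)), ncol(V)),
    j = rep(seq_len(ncol(V)), each = nrow(V)),
    value = as.vector(V)
  )
  ggplot(df, aes(.data$j, .data$i, fill = .data$value)) +
    geom_tile() +
    geom_text(aes(label = if (quantize) .data$value else
      signif(.data$value, 3)), size = 3) +
    scale_fill_gradient(low = "#fff5eb", high = "#d94801") +
    labs(x = "sample", y = "sample",
         fill = if (quantize) "level" else "difference") +
    theme_minimal()
}
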