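#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained model's training history
#'
#' @param x an `ivoct_model`.
#' @param ... unused.
#' @return tibble with one row per (run, epoch): learning rate, training
#'   loss, validation loss, validation Dice.
#' @method tidy ivoct_model
#' @export
tidy.ivoct_model <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x an `ivoct_model`.
#' @param ... unused.
#' @method glance ivoct_model
#' @export
glance.ivoct_model <- function(x, ...) {
  cfg <- x$net$config
  tibble::tibble(
    target = x$target,
    depth_levels = cfg$depth_levels,
    base_channels = cfg$base_channels,
    attention = cfg$attention,
    n_params = n_params(x),
    alpha = x$loss_params$alpha, beta = x$loss_params$beta,
    gamma = x$loss_params$gamma,
    best_val_dice = x$best$dice,
    best_run = x$best$run, best_epoch = x$best$epoch
  )
}

#' Per-frame evaluation table
#'
#' @param x an `ivoct_eval`.
#' @param ... unused.
#' @method tidy ivoct_eval
#' @export
tidy.ivoct_eval <- function(x, ...) x$per_frame

#' One-row evaluation summary
#'
#' @param x an `ivoct_eval`.
#' @param ... unused.
#' @method glance ivoct_eval
#' @export
glance.ivoct_eval <- function(x, ...) x$metrics

#' Plot a polar frame (log display)
#'
#' @param object an `ivoct_frame`.
#' @param ... unused.
#' @return a ggplot raster of the log-transformed frame, angle on the
#'   vertical axis, depth on the horizontal.
#' @method autoplot ivoct_frame
#' @export
autoplot.ivoct_frame <- function(object, ...) {
  d <- log_display(object)
  df <- tidyr::expand_grid(aline = seq_len(nrow(d)), depth = seq_len(ncol(d)))
  df$value <- as.vector(d)[(df$depth - 1L) * nrow(d) + df$aline]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$aline,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "depth (px)", y = "A-line") +
    ggplot2::theme_minimal()
}

#' Plot training curves
#'
#' @param object an `ivoct_model`.
#' @param ... unused.
#' @method autoplot ivoct_model
#' @export
autoplot.ivoct_model <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "val_dice"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = paste("training:", object$target)) +
    ggplot2::theme_minimal()
}

#' Plot evaluation metrics per frame
#'
#' @param object an `ivoct_eval`.
#' @param ... unused.
#' @method autoplot ivoct_eval
#' @export
autoplot.ivoct_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_frame,
                  ggplot2::aes(x = .data$frame, y = .data$dice,
                               fill = .data$degenerate)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$metrics$dice_mean,
                        linetype = "dashed") +
    ggplot2::labs(x = "frame", y = "Dice") +
    ggplot2::theme_minimal()
}

#' Render a palette-coded overlay with the conventional plaque colors
#'
#' @param overlay integer matrix over the fixed palette (polar or
#'   cartesian).
#' @return ggplot raster with one color per plaque class.
#' @export
plot_overlay <- function(overlay) {
  pal <- plaque_classes()
  cols <- c(lumen = "black", fibrous = "grey30", lipid_pool = "yellow",
            calcified_lipid = "red", fibrofatty = "orange",
            calcified_fibrous = "deepskyblue")
  df <- tidyr::expand_grid(row = seq_len(nrow(overlay)),
                           col = seq_len(ncol(overlay)))
  v <- as.vector(overlay)[(df$col - 1L) * nrow(overlay) + df$row]
  df$class <- factor(names(pal)[match(v, pal)], levels = names(pal))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
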