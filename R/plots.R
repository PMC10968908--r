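#' Plot a training history
#'
#' Line plot of per-epoch loss terms from [train_encoder()] or
#' [train_decoder()] histories. Requires ggplot2.
#'
#' @param history data.frame with an `epoch` column and one column per
#'   loss term.
#' @return a ggplot object.
#' @export
plot_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_input("the 'ggplot2' package is required for plotting")
  terms <- setdiff(names(history), "epoch")
  long <- do.call(rbind, lapply(terms, function(t)
    data.frame(epoch = history$epoch, term = t, value = history[[t]])))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot reconstructions next to their ground truths
#'
#' Raster grid of ground-truth / reconstruction pairs. Requires ggplot2.
#'
#' @param recons,gts aligned lists of `112 x 112 x 3` images.
#' @param max_pairs cap on the number of pairs shown.
#' @return a ggplot object.
#' @export
plot_reconstructions <- function(recons, gts, max_pairs = 8) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_input("the 'ggplot2' package is required for plotting")
  k <- min(length(recons), max_pairs)
  px <- do.call(rbind, lapply(seq_len(k), function(i) {
    rbind(image_to_df(gts[[i]], i, "stimulus"),
          image_to_df(recons[[i]], i, "reconstruction"))
  }))
  ggplot2::ggplot(px, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$rgb)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::facet_grid(row ~ pair) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

image_to_df <- function(im, pair, row_label) {
  H <- dim(im)[1]; W <- dim(im)[2]
  data.frame(x = rep(seq_len(W), each = H), y = rep(rev(seq_len(H)), W),
             rgb = grDevices::rgb(im[, , 1], im[, , 2], im[, , 3]),
             pair = pair, row = row_label)
}
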