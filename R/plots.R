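#' Plot a Voss indicator image
#'
#' Renders the 4 x N binary indicator matrix of a sequence as a tile image
#' (rows A, C, G, T top to bottom), the visual form in which descriptor
#' extraction sees the sequence.
#'
#' @param x A sequence string or a 4 x N Voss matrix.
#' @return A ggplot object.
#' @export
plot_voss <- function(x) {
  m <- if (is.character(x)) voss_encode(x) else x
  df <- tibble::tibble(
    row = factor(rep(rownames(m), each = ncol(m)),
                 levels = rev(c("A", "C", "G", "T"))),
    col = rep(seq_len(ncol(m)), times = nrow(m)),
    value = as.vector(t(m))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$value))) +
    ggplot2::geom_tile(colour = "grey80", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "black"),
                               guide = "none") +
    ggplot2::labs(x = "position", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mlp_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "set", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "mean squared error",
                  colour = NULL,
                  title = "Training history (dashed: selected epoch)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame.table(unclass(object), responseName = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("Accuracy %.1f%%", accuracy(object))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.holdout_eval <- function(object, ...) {
  ggplot2::ggplot(object$rounds,
                  ggplot2::aes(x = .data$round, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(x = "holdout round", y = "accuracy (%)",
                  title = sprintf("Mean accuracy %.1f%%",
                                  object$mean_accuracy)) +
    ggplot2::theme_minimal()
}
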