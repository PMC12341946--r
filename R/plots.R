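#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PCA score plot
#'
#' Samples on the first two principal components, colored by time and
#' shaped by strain/memory when those columns are present in the scores.
#'
#' @param object A `memory_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.memory_pca <- function(object, ...) {
  sc <- object$scores
  ve <- object$var_explained
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (all(c("time", "memory") %in% names(sc))) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$time), shape = .data$memory),
      size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
      colour = "time (min)"
    ) +
    ggplot2::theme_minimal()
}

#' Fold-change category transition heatmap
#'
#' Tile view of the transition counts between two time points (the same
#' numbers a Sankey/alluvial diagram displays), faceted by condition.
#'
#' @param object A [transition_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.memory_transitions <- function(object, ...) {
  plot_transitions(object)
}

#' @rdname autoplot.memory_transitions
#' @param transitions A [transition_table()] result.
#' @export
plot_transitions <- function(transitions, ...) {
  p <- ggplot2::ggplot(transitions,
                       ggplot2::aes(x = .data$from, y = .data$to,
                                    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "category (earlier time)", y = "category (later time)",
                  fill = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (all(c("strain", "memory") %in% names(transitions))) {
    p <- p + ggplot2::facet_grid(memory ~ strain)
  }
  p
}

#' Bar chart of effect classes by direction
#'
#' @param object A `memory_classes` tibble from [classify_genes()].
#' @param effect Which effect column to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.memory_classes <- function(object,
                                    effect = c("memory", "strain",
                                               "interaction"), ...) {
  effect <- match.arg(effect)
  col <- paste0(effect, "_effect")
  df <- tibble::as_tibble(object) %>%
    dplyr::filter(!is.na(.data$direction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_bar(fill = "grey40") +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = paste(effect, "effect"), y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Fitted and observed profile of one gene
#'
#' Observed log2 normalized expression over time, one panel per strain,
#' colored by memory condition, with the mean profile overlaid.
#'
#' @param norm A `memory_norm` object.
#' @param design Design tibble.
#' @param gene Gene ID.
#' @return A ggplot.
#' @export
plot_gene <- function(norm, design, gene) {
  m <- .as_count_matrix(norm$log2)
  if (!gene %in% rownames(m)) rlang::abort(paste0("unknown gene: ", gene))
  df <- design %>%
    dplyr::mutate(expr = m[gene, match(.data$sample, colnames(m))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$expr,
                                   colour = .data$memory)) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::facet_wrap(~strain) +
    ggplot2::labs(title = gene, x = "time (min)",
                  y = "log2 normalized expression") +
    ggplot2::theme_minimal()
}
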