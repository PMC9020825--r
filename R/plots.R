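#' Phase portrait of one gene
#'
#' Unspliced versus spliced abundance per cell with the fitted steady-state
#' line `u = gamma_hat * s`; induction-phase cells lie above the line,
#' repression-phase cells below.
#'
#' @param field A [velocity_field()].
#' @param gene Gene to plot.
#' @param clusters Optional per-cell labels used for colouring.
#' @return A ggplot object.
#' @export
plot_phase_portrait <- function(field, gene, clusters = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  if (!gene %in% rownames(field$s)) abort(sprintf("gene '%s' not in field.", gene))
  df <- tibble(
    s = field$s[gene, ],
    u = field$u[gene, ],
    cluster = if (is.null(clusters)) "cells" else as.character(clusters)
  )
  gam <- field$fits$gamma_hat[match(gene, field$fits$gene)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$u,
                                        colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(title = gene, x = "spliced", y = "unspliced") +
    ggplot2::theme_minimal()
  if (!is.na(gam)) {
    p <- p + ggplot2::geom_abline(slope = gam, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

#' Signature and coexpression profile along the cell ordering
#'
#' Cells on the x axis in order of increasing non-myogenic signature; the
#' two signature fractions as lines and the coexpression score as points,
#' with transition cells highlighted.
#'
#' @param object A scored [coexpression_transition()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_scores
#' @export
autoplot.signature_scores <- function(object, ...) {
  if (!"coexpression" %in% names(object)) {
    abort("run `coexpression_transition()` first.")
  }
  df <- filter(object, .data$scored)
  df <- arrange(df, .data$order)
  long <- tidyr::pivot_longer(
    select(df, "order", "s_m", "s_n", "coexpression"),
    cols = c("s_m", "s_n", "coexpression"),
    names_to = "score", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$order, y = .data$value,
                                     colour = .data$score)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(
      data = mutate(filter(df, .data$transition), score = "coexpression"),
      ggplot2::aes(y = .data$coexpression), colour = "gold", size = 1
    ) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold") %||% 0.2,
                        linetype = "dotted") +
    ggplot2::labs(x = "cells (by increasing non-myogenic signature)",
                  y = "score") +
    ggplot2::theme_minimal()
}

#' Driver-regulator recurrence barplot
#'
#' Frequency of appearance of each TF as a driver regulator across datasets.
#'
#' @param object A [cross_dataset_recurrence()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recurrence_table
#' @export
autoplot.recurrence_table <- function(object, ...) {
  df <- mutate(object, tf = factor(.data$tf, levels = rev(.data$tf)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$tf)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "datasets where called as driver regulator", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
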