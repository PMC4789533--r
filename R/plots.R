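#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_segment
#'   geom_hline geom_col scale_fill_viridis_c labs theme_minimal coord_fixed
#'   element_text theme
#' @export
ggplot2::autoplot

#' Heatmap of a connectivity matrix
#'
#' @param object An `fc_connectivity` matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_connectivity <- function(object, ...) {
  df <- tidyr::expand_grid(region_i = rownames(object),
                           region_j = colnames(object))
  df$weight <- as.vector(t(unclass(object)))
  df$region_i <- factor(df$region_i, levels = rownames(object))
  df$region_j <- factor(df$region_j, levels = rev(colnames(object)))
  ggplot(df, aes(x = .data$region_i, y = .data$region_j, fill = .data$weight)) +
    geom_tile() +
    scale_fill_viridis_c(name = "fibers") +
    coord_fixed() +
    labs(x = NULL, y = NULL, title = "Fiber-count connectivity") +
    theme_minimal(base_size = 8) +
    theme(axis.text.x = element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' Edge-wise permutation p values
#'
#' -log10 of the max-statistic corrected p per tested edge, with the
#' significance threshold drawn as a horizontal line.
#'
#' @param object An `fc_permutation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_permutation <- function(object, ...) {
  df <- dplyr::filter(object$edges, .data$tested)
  ggplot(df, aes(x = .data$edge, y = -log10(.data$p_corrected),
                 colour = .data$significant)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    labs(x = "edge index (upper triangle order)",
         y = expression(-log[10] ~ "corrected p"),
         colour = sprintf("p < %g", object$alpha),
         title = sprintf("Permutation group test (%d reassignments)",
                         object$n_permutations)) +
    theme_minimal()
}

#' Edge-score Spearman correlations
#'
#' @param object An `fc_correlation`.
#' @param ... Unused.
#' @return A ggplot (lollipop chart of rho per edge).
#' @export
autoplot.fc_correlation <- function(object, ...) {
  df <- dplyr::filter(object$edges, !.data$constant)
  df$label <- paste(df$region_i, df$region_j, sep = " - ")
  ggplot(df, aes(x = .data$rho, y = .data$label, colour = .data$significant)) +
    geom_segment(aes(x = 0, xend = .data$rho, yend = .data$label)) +
    geom_point() +
    labs(x = "Spearman rho (pooled subjects)", y = NULL,
         colour = sprintf("Holm p <= %g", object$alpha),
         title = "Edge-score correlation screen") +
    theme_minimal()
}

#' LOOCV confusion matrix
#'
#' @param object An `fc_loocv`.
#' @param ... Unused.
#' @return A ggplot (tile plot of truth vs prediction counts).
#' @export
autoplot.fc_loocv <- function(object, ...) {
  df <- dplyr::count(object$folds, .data$truth, .data$predicted)
  ggplot(df, aes(x = .data$truth, y = .data$predicted, fill = .data$n)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = .data$n), colour = "white") +
    scale_fill_viridis_c(name = "subjects") +
    coord_fixed() +
    labs(title = sprintf("LOOCV: accuracy %.2f%%", object$metrics$accuracy)) +
    theme_minimal()
}
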