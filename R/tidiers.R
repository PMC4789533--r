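#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a permutation test result
#'
#' @param x An `fc_permutation`.
#' @param ... Unused.
#' @return The per-edge tibble: indices, region names, `tested`, observed
#'   group-mean difference, group means/SDs, uncorrected and max-statistic
#'   corrected p values, and the significance flag.
#' @export
tidy.fc_permutation <- function(x, ...) x$edges

#' @rdname tidy.fc_permutation
#' @export
glance.fc_permutation <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$edges),
    n_tested = sum(x$edges$tested),
    n_significant = sum(x$edges$significant),
    n_permutations = x$n_permutations,
    alpha = x$alpha,
    method = x$method)
}

#' Tidy an edge-score correlation result
#'
#' @param x An `fc_correlation`.
#' @param ... Unused.
#' @return Per-edge tibble with `rho`, raw and Holm-adjusted p values, and
#'   significance flags.
#' @export
tidy.fc_correlation <- function(x, ...) x$edges

#' @rdname tidy.fc_correlation
#' @export
glance.fc_correlation <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$edges),
    family_size = x$family_size,
    n_significant = sum(x$edges$significant),
    alpha = x$alpha,
    n_subjects = x$n_subjects)
}

#' Tidy a LOOCV classification report
#'
#' @param x An `fc_loocv`.
#' @param ... Unused.
#' @return `tidy()`: per-fold tibble of truth and prediction. `glance()`: one
#'   row with confusion counts, sensitivity/specificity/accuracy (percent),
#'   and the classifier settings.
#' @export
tidy.fc_loocv <- function(x, ...) x$folds

#' @rdname tidy.fc_loocv
#' @export
glance.fc_loocv <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(n_folds = x$settings$n_folds,
                   regularization = x$settings$regularization,
                   positive_class = x$settings$positive_class))
}

#' Tidy a connectivity matrix into an edge list
#'
#' @param x An `fc_connectivity` matrix.
#' @param ... Unused.
#' @return Tibble with one row per upper-triangle edge (`region_i`,
#'   `region_j`, `weight`).
#' @export
tidy.fc_connectivity <- function(x, ...) {
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    region_i = rownames(x)[ut[, 1]],
    region_j = colnames(x)[ut[, 2]],
    weight = x[ut])
}
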