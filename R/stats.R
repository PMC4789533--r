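#' Edge-wise permutation test for group differences
#'
#' For every edge nonzero in at least one subject, the observed statistic is
#' the signed difference of group means (group A minus group B, groups taken
#' from the stack's factor levels). Each permutation randomly reassigns the
#' fixed group sizes to subjects and recomputes all edge statistics.
#' Two-sided p values use the add-one estimator
#' \eqn{p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\}) / (B + 1)}; corrected p
#' values use the single-step max-statistic over the tested edge family,
#' controlling the family-wise error rate. With `method = "exhaustive"` all
#' distinct assignments of subjects to the two group sizes are enumerated and
#' p values are exact proportions (the identity assignment included, so
#' p >= 1/choose(n, nA)).
#'
#' @param stack A [cohort_stack()].
#' @param n_permutations Number of random reassignments (default 10000).
#' @param alpha Significance level for the corrected significant-edge set
#'   (default 0.05).
#' @param seed RNG seed for the permutation draw.
#' @param method `"montecarlo"` (default) or `"exhaustive"` (small cohorts
#'   only; errors beyond 200000 assignments).
#' @return An `fc_permutation` object: a list with `edges` (tibble with per
#'   edge indices, names, `tested`, observed statistic, group means/SDs,
#'   `p_uncorrected`, `p_corrected`, `significant`) and metadata
#'   (`n_permutations`, `alpha`, `seed`, `method`, group sizes).
#' @export
permutation_group_test <- function(stack, n_permutations = 10000L, alpha = 0.05,
                                   seed = NULL,
                                   method = c("montecarlo", "exhaustive")) {
  stopifnot(inherits(stack, "cohort_stack"))
  method <- match.arg(method)
  if (n_permutations < 1) stop_input("n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  group <- stack$group
  nA <- sum(group == levels(group)[1])
  nB <- sum(group == levels(group)[2])
  if (nA < 2 || nB < 2) stop_input("each group needs at least 2 subjects")
  n <- nA + nB
  em <- edge_matrix(stack)
  E <- em$E
  tested <- colSums(E != 0) > 0
  isA <- group == levels(group)[1]
  obs <- colMeans(E[isA, , drop = FALSE]) - colMeans(E[!isA, , drop = FALSE])

  Et <- E[, tested, drop = FALSE]
  m <- ncol(Et)
  tol <- 1e-9 * (1 + max(abs(obs[tested]), 0))
  if (method == "exhaustive") {
    n_assign <- choose(n, nA)
    if (n_assign > 2e5) {
      stop_input("exhaustive enumeration infeasible: choose(%d, %d) = %g assignments",
                 n, nA, n_assign)
    }
    combos <- combn(n, nA)
    W <- matrix(-1 / nB, ncol(combos), n)
    for (r in seq_len(ncol(combos))) W[r, combos[, r]] <- 1 / nA
    Tperm <- abs(W %*% Et)
    n_eff <- ncol(combos)
    count_ge <- function(thresh) colSums(Tperm >= rep(thresh, each = n_eff) - tol)
    p_unc_t <- count_ge(abs(obs[tested])) / n_eff
    maxT <- apply(Tperm, 1, max)
    p_cor_t <- vapply(abs(obs[tested]),
                      function(o) sum(maxT >= o - tol) / n_eff, numeric(1))
  } else {
    W <- with_seed(seed, {
      W <- matrix(-1 / nB, n_permutations, n)
      for (r in seq_len(n_permutations)) {
        W[r, sample.int(n, nA)] <- 1 / nA
      }
      W
    })
    Tperm <- abs(W %*% Et)
    p_unc_t <- (1 + colSums(Tperm >= rep(abs(obs[tested]), each = n_permutations) - tol)) /
      (n_permutations + 1)
    maxT <- apply(Tperm, 1, max)
    p_cor_t <- vapply(abs(obs[tested]),
                      function(o) (1 + sum(maxT >= o - tol)) / (n_permutations + 1),
                      numeric(1))
  }

  p_unc <- p_cor <- rep(NA_real_, length(obs))
  p_unc[tested] <- p_unc_t
  p_cor[tested] <- pmax(p_cor_t, p_unc_t)   # max-statistic p dominates edge-wise p
  edges <- em$edges
  edges$tested <- tested
  edges$observed <- obs
  edges$mean_a <- colMeans(E[isA, , drop = FALSE])
  edges$mean_b <- colMeans(E[!isA, , drop = FALSE])
  edges$sd_a <- apply(E[isA, , drop = FALSE], 2, sd)
  edges$sd_b <- apply(E[!isA, , drop = FALSE], 2, sd)
  edges$p_uncorrected <- p_unc
  edges$p_corrected <- p_cor
  edges$significant <- !is.na(p_cor) & p_cor < alpha
  structure(list(edges = edges,
                 n_permutations = if (method == "exhaustive") choose(n, nA) else n_permutations,
                 alpha = alpha, seed = seed, method = method,
                 groups = stats::setNames(c(nA, nB), levels(group))),
            class = "fc_permutation")
}

#' @export
print.fc_permutation <- function(x, ...) {
  cat(sprintf("<fc_permutation> %d tested edge(s), %d significant at corrected p < %g (%s, %d reassignments)\n",
              sum(x$edges$tested), sum(x$edges$significant), x$alpha,
              x$method, x$n_permutations))
  invisible(x)
}

#' Significant edges of a screening result
#'
#' @param x An `fc_permutation` or `fc_correlation` object.
#' @return Tibble of the significant rows of the edge table.
#' @export
significant_edges <- function(x) {
  stopifnot(inherits(x, c("fc_permutation", "fc_correlation")))
  dplyr::filter(x$edges, .data$significant)
}

#' Spearman rank correlation coefficient
#'
#' Ranks both vectors (average ranks for ties) and returns the Pearson
#' correlation of the rank vectors. Chosen over Pearson for clinical scores
#' because they are ordinal. Errors on constant input, where the coefficient
#' is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 3L) stop_input("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop_input("missing values are not supported")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_input("Spearman correlation undefined for constant input")
  }
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Two-sided p for a Spearman coefficient via the large-sample t approximation.
spearman_p_tapprox <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p values ascending and rejects the k-th smallest while
#' \eqn{p_{(k)} \le \alpha / (m - k + 1)}, stopping at the first failure.
#' Adjusted p values are \eqn{\min(1, \max_{j \le k} (m - j + 1) p_{(j)})},
#' mapped back to the input order.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @param alpha Significance level for the rejection flags (default 0.05).
#' @return List with `adjusted` (numeric vector) and `reject` (logical
#'   vector), both in input order.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_input("p values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(list(adjusted = numeric(), reject = logical()))
  o <- order(p)
  adj_sorted <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  rej_sorted <- logical(m)
  for (k in seq_len(m)) {
    if (p[o][k] <= alpha / (m - k + 1)) rej_sorted[k] <- TRUE else break
  }
  adjusted <- numeric(m)
  reject <- logical(m)
  adjusted[o] <- adj_sorted
  reject[o] <- rej_sorted
  list(adjusted = adjusted, reject = reject)
}

#' Correlate edge weights with clinical scores
#'
#' Pools all subjects of both groups per edge, computes [spearman_rho()]
#' between edge weights and scores, obtains raw two-sided p values from the
#' large-sample t approximation, and applies [holm_bonferroni()] across the
#' tested edge family. Edges with constant weights are flagged and excluded
#' from the family.
#'
#' @param stack A [cohort_stack()].
#' @param edges Edge set to test: a data frame with columns `i`, `j` (as
#'   produced by [significant_edges()] or [tidy()] on an `fc_permutation`),
#'   or an integer vector of edge ids in upper-triangle order.
#' @param alpha Significance level on Holm-adjusted p values (default 0.001,
#'   the conventional reporting threshold for this screen).
#' @return An `fc_correlation` object: list with `edges` (tibble with `rho`,
#'   `p_raw`, `p_corrected`, `constant`, `significant`) and metadata.
#' @export
correlate_edges_with_scores <- function(stack, edges, alpha = 0.001) {
  stopifnot(inherits(stack, "cohort_stack"))
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  em <- edge_matrix(stack)
  if (is.data.frame(edges)) {
    stopifnot(all(c("i", "j") %in% names(edges)))
    ids <- match(paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j)),
                 paste(em$edges$i, em$edges$j))
    if (anyNA(ids)) stop_input("edge list contains pairs outside the region set")
  } else {
    ids <- as.integer(edges)
    if (any(ids < 1 | ids > nrow(em$edges))) stop_input("edge ids out of range")
  }
  if (length(ids) == 0L) stop_input("edge set must be nonempty")
  n <- length(stack$score)
  tab <- em$edges[ids, ]
  tab$rho <- NA_real_
  tab$p_raw <- NA_real_
  tab$constant <- FALSE
  for (r in seq_along(ids)) {
    w <- em$E[, ids[r]]
    if (sd(w) == 0 || sd(stack$score) == 0) {
      tab$constant[r] <- TRUE
      next
    }
    rho <- spearman_rho(w, stack$score)
    tab$rho[r] <- rho
    tab$p_raw[r] <- spearman_p_tapprox(rho, n)
  }
  ok <- !tab$constant
  tab$p_corrected <- NA_real_
  tab$significant <- FALSE
  if (any(ok)) {
    hb <- holm_bonferroni(tab$p_raw[ok], alpha = alpha)
    tab$p_corrected[ok] <- hb$adjusted
    tab$significant[ok] <- hb$reject
  }
  structure(list(edges = tab, alpha = alpha, n_subjects = n,
                 family_size = sum(ok)),
            class = "fc_correlation")
}

#' @export
print.fc_correlation <- function(x, ...) {
  cat(sprintf("<fc_correlation> %d edge(s) tested, %d significant at Holm-adjusted p <= %g (n = %d)\n",
              nrow(x$edges), sum(x$edges$significant), x$alpha, x$n_subjects))
  invisible(x)
}

#' Write screening results as CSV
#'
#' One row per edge with the permutation statistics and, when supplied, the
#' correlation columns - mirroring the layout of published edge tables
#' (region-name pair, group means and SDs, corrected p, rho).
#'
#' @param permutation An `fc_permutation`.
#' @param path CSV output path.
#' @param correlation Optional `fc_correlation` on a subset of the edges.
#' @return Invisibly, `path`.
#' @export
write_stats_csv <- function(permutation, path, correlation = NULL) {
  tab <- permutation$edges
  if (!is.null(correlation)) {
    cc <- correlation$edges[, c("edge", "rho", "p_raw", "p_corrected", "significant")]
    names(cc) <- c("edge", "rho", "rho_p_raw", "rho_p_corrected", "rho_significant")
    tab <- dplyr::left_join(tab, cc, by = "edge")
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
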