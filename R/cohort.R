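#' Synthetic cohort specification
#'
#' Parameters of a two-group cohort of per-subject fiber-count connectivity
#' matrices. Edge counts are negative binomial (fiber-count tables from real
#' connectomes are overdispersed, with SD on the order of the mean), group B
#' means are shifted multiplicatively at designated effect edges, and an
#' integer clinical score is linked linearly (plus Gaussian noise, rounded
#' and floored at 0) to designated score edges, emulating an MDS-UPDRS-like
#' ordinal motor score.
#'
#' @param n_group_a,n_group_b Subject counts per group (>= 2).
#' @param n_regions Number of regions (>= 2); default 39, the motor-related
#'   parcellation size.
#' @param baseline_mean Negative-binomial mean per edge.
#' @param dispersion Negative-binomial size (shape) parameter; the edge
#'   variance is `mu + mu^2/dispersion`, so smaller values mean more
#'   overdispersion.
#' @param effect_edges Data frame (or tibble) with columns `i`, `j`
#'   (1 <= i < j <= n_regions) and `shift`: multiplicative mean shift applied
#'   in group B at that edge.
#' @param score_edges Data frame with columns `i`, `j`, `slope`: per-unit
#'   contribution of the edge weight to the clinical score.
#' @param score_baseline,score_noise_sd Intercept and Gaussian noise SD of the
#'   score model.
#' @param group_names Length-2 character vector naming groups A and B.
#' @param seed RNG seed; all randomness in [make_cohort()] derives from it.
#' @return A `cohort_spec` object.
#' @seealso [demo_cohort_spec()] for the packaged demonstration cohort.
#' @export
cohort_spec <- function(n_group_a = 37L, n_group_b = 40L, n_regions = 39L,
                        baseline_mean = 20, dispersion = 2,
                        effect_edges = NULL, score_edges = NULL,
                        score_baseline = 10, score_noise_sd = 2,
                        group_names = c("SWEDD", "PD"), seed = 1L) {
  stopifnot(n_group_a >= 2, n_group_b >= 2, n_regions >= 2,
            baseline_mean > 0, dispersion > 0, score_noise_sd >= 0,
            length(group_names) == 2L)
  check_edge_df <- function(df, value_col) {
    if (is.null(df)) {
      return(tibble::tibble(i = integer(), j = integer(),
                            !!value_col := numeric()))
    }
    df <- tibble::as_tibble(df)
    stopifnot(all(c("i", "j", value_col) %in% names(df)))
    if (!all(df$i >= 1 & df$j <= n_regions & df$i < df$j)) {
      stop_input("edge indices must satisfy 1 <= i < j <= n_regions")
    }
    df
  }
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 n_regions = as.integer(n_regions),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 effect_edges = check_edge_df(effect_edges, "shift"),
                 score_edges = check_edge_df(score_edges, "slope"),
                 score_baseline = score_baseline,
                 score_noise_sd = score_noise_sd,
                 group_names = as.character(group_names),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Packaged demonstration cohort
#'
#' A 37-vs-40 cohort over the 39 motor-related regions with four planted
#' edges that carry both a group effect and a clinical-score link, the
#' configuration exercised throughout the package examples. The four edges
#' are the motor-circuit connections reported as jointly significant in the
#' SWEDD-vs-PD literature (left precentral-putamen, right posterior
#' cingulate-superior frontal, right posterior cingulate-paracentral, left
#' paracentral-superior frontal). All four effects are planted as increases
#' in group B with a common baseline mean, so that the max-statistic
#' permutation null is not dominated by heteroscedastic planted edges; the
#' score model gives a pooled edge-score correlation of about 0.65 and an
#' MDS-UPDRS-like score distribution (mean ~18, SD ~6).
#'
#' @param seed RNG seed.
#' @param shift Multiplicative group-B mean shift at the planted edges.
#' @param slope Score slope at the planted edges.
#' @return A `cohort_spec`.
#' @export
demo_cohort_spec <- function(seed = 1L, shift = 4, slope = 0.04) {
  regions <- motor_regions()
  idx <- function(name) match(name, regions$region_name)
  pairs <- rbind(
    c(idx("L_precentral"), idx("L_putamen")),
    c(idx("R_posteriorcingulate"), idx("R_superiorfrontal")),
    c(idx("R_paracentral"), idx("R_posteriorcingulate")),
    c(idx("L_paracentral"), idx("L_superiorfrontal")))
  i <- pmin(pairs[, 1], pairs[, 2])
  j <- pmax(pairs[, 1], pairs[, 2])
  cohort_spec(
    n_group_a = 37L, n_group_b = 40L, n_regions = nrow(regions),
    baseline_mean = 20, dispersion = 2,
    effect_edges = tibble::tibble(i = i, j = j, shift = shift),
    score_edges = tibble::tibble(i = i, j = j, slope = slope),
    score_baseline = 10, score_noise_sd = 2,
    seed = seed)
}

#' Generate a synthetic cohort of connectivity matrices
#'
#' Draws per-subject symmetric integer matrices with zero diagonal from the
#' negative-binomial edge model of a [cohort_spec()], applies the
#' multiplicative group-B shifts at the planted effect edges, and generates
#' integer clinical scores
#' `round(score_baseline + sum(slope * weight) + N(0, sd))`, floored at 0.
#' The same spec and seed always reproduce the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param region_names Optional region names for the matrix dimnames; default
#'   the motor-related table when `n_regions` is 39, else `r1..rn`.
#' @return A list with `stack` (a [cohort_stack()]) and `truth` (planted
#'   effect and score edges plus the expected correlation signs and the seed).
#' @export
make_cohort <- function(spec, region_names = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  nR <- spec$n_regions
  if (is.null(region_names)) {
    region_names <- if (nR == 39L) motor_regions()$region_name else paste0("r", seq_len(nR))
  }
  stopifnot(length(region_names) == nR)
  n <- spec$n_group_a + spec$n_group_b
  group <- factor(rep(spec$group_names, c(spec$n_group_a, spec$n_group_b)),
                  levels = spec$group_names)
  ut <- which(upper.tri(matrix(0, nR, nR)), arr.ind = TRUE)
  m_edges <- nrow(ut)
  mu <- matrix(spec$baseline_mean, n, m_edges)
  edge_index <- function(i, j) match(paste(i, j), paste(ut[, 1], ut[, 2]))
  if (nrow(spec$effect_edges) > 0) {
    cols <- edge_index(spec$effect_edges$i, spec$effect_edges$j)
    for (r in seq_len(nrow(spec$effect_edges))) {
      mu[group == spec$group_names[2], cols[r]] <-
        spec$baseline_mean * spec$effect_edges$shift[r]
    }
  }
  res <- with_seed(derive_seed(spec$seed, "cohort"), {
    E <- matrix(as.integer(rnbinom(n * m_edges, mu = as.vector(mu),
                                   size = spec$dispersion)),
                n, m_edges)
    noise <- rnorm(n, sd = spec$score_noise_sd)
    list(E = E, noise = noise)
  })
  E <- res$E
  lin <- rep(spec$score_baseline, n)
  if (nrow(spec$score_edges) > 0) {
    cols <- edge_index(spec$score_edges$i, spec$score_edges$j)
    lin <- lin + drop(E[, cols, drop = FALSE] %*% spec$score_edges$slope)
  }
  score <- pmax(0L, as.integer(round(lin + res$noise)))
  mats <- array(0L, c(nR, nR, n), dimnames = list(region_names, region_names, NULL))
  for (s in seq_len(n)) {
    M <- matrix(0L, nR, nR)
    M[upper.tri(M)] <- E[s, ]
    M <- M + t(M)
    mats[, , s] <- M
  }
  stack <- cohort_stack(mats, group, score,
                        subject_ids = sprintf("sub%03d", seq_len(n)))
  truth <- list(
    effect_edges = spec$effect_edges,
    score_edges = dplyr::mutate(spec$score_edges,
                                expected_sign = sign(.data$slope)),
    seed = spec$seed)
  list(stack = stack, truth = truth)
}

#' Cohort stack of connectivity matrices
#'
#' Per-subject region x region matrices stacked along a subject axis, with
#' group labels and integer clinical scores - the substrate of all group
#' statistics.
#'
#' @param matrices Numeric/integer array (region, region, subject); each
#'   slice must be symmetric with a zero diagonal. Region dimnames are used
#'   as region names when present.
#' @param group Factor (or character) of two group labels, one per subject,
#'   with at least 2 subjects per group. The first factor level is "group A"
#'   in all statistics.
#' @param score Integer clinical score per subject.
#' @param subject_ids Optional subject identifiers.
#' @return A `cohort_stack` object.
#' @export
cohort_stack <- function(matrices, group, score, subject_ids = NULL) {
  stopifnot(length(dim(matrices)) == 3L, dim(matrices)[1] == dim(matrices)[2])
  n <- dim(matrices)[3]
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop_input("group must have exactly two levels")
  if (any(table(group) < 2L)) stop_input("each group needs at least 2 subjects")
  stopifnot(length(group) == n, length(score) == n)
  for (s in seq_len(n)) {
    M <- matrices[, , s]
    if (max(abs(M - t(M))) > 0 || any(diag(M) != 0)) {
      stop_input("matrix for subject %d is not symmetric with zero diagonal", s)
    }
  }
  regions <- dimnames(matrices)[[1]] %||% paste0("r", seq_len(dim(matrices)[1]))
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(n))
  structure(list(matrices = matrices, group = group,
                 score = as.integer(score), subject_ids = subject_ids,
                 regions = regions),
            class = "cohort_stack")
}

#' @export
print.cohort_stack <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("<cohort_stack> %d regions, %d subjects (%s)\n",
              length(x$regions), length(x$group),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Upper-triangle edge representation of a stack: E is subjects x edges,
# `edges` indexes and names each column.
edge_matrix <- function(stack) {
  nR <- length(stack$regions)
  ut <- which(upper.tri(matrix(0, nR, nR)), arr.ind = TRUE)
  n <- dim(stack$matrices)[3]
  E <- matrix(0, n, nrow(ut))
  flat <- matrix(stack$matrices, nrow = nR * nR)
  lin <- (ut[, 2] - 1L) * nR + ut[, 1]
  for (s in seq_len(n)) E[s, ] <- flat[lin, s]
  list(E = E,
       edges = tibble::tibble(
         edge = seq_len(nrow(ut)),
         i = as.integer(ut[, 1]), j = as.integer(ut[, 2]),
         region_i = stack$regions[ut[, 1]],
         region_j = stack$regions[ut[, 2]]))
}

#' Write / read a cohort as CSV files
#'
#' One region x region CSV per subject plus a `subjects.csv` table
#' (`subject_id`, `group`, `score`).
#'
#' @param stack A [cohort_stack()].
#' @param dir Directory for the CSV files (created if missing).
#' @return `write_cohort_csv()` returns `dir` invisibly; `read_cohort_csv()`
#'   returns a `cohort_stack`.
#' @export
write_cohort_csv <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_len(dim(stack$matrices)[3])) {
    m <- stack$matrices[, , s]
    dimnames(m) <- list(stack$regions, stack$regions)
    write_connectivity_csv(m, file.path(dir, paste0(stack$subject_ids[s], ".csv")))
  }
  write.csv(data.frame(subject_id = stack$subject_ids,
                       group = as.character(stack$group),
                       score = stack$score),
            file.path(dir, "subjects.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  subj <- read.csv(file.path(dir, "subjects.csv"))
  mats <- NULL
  for (s in seq_len(nrow(subj))) {
    m <- read_connectivity_csv(file.path(dir, paste0(subj$subject_id[s], ".csv")))
    if (is.null(mats)) {
      mats <- array(0L, c(nrow(m), ncol(m), nrow(subj)),
                    dimnames = list(rownames(m), colnames(m), NULL))
    }
    mats[, , s] <- m
  }
  cohort_stack(mats, factor(subj$group, levels = unique(subj$group)),
               subj$score, subject_ids = subj$subject_id)
}
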