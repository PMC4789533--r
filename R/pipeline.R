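#' Pipeline configuration
#'
#' Validates and normalizes the settings for [run_pipeline()]. A run takes
#' its subjects either from a synthetic cohort spec, from a directory of
#' per-subject connectivity CSVs (see [write_cohort_csv()]), or from
#' per-subject imaging inputs (DWI + gradient table + labels + mask), which
#' are pushed through tensor fitting, tracking, and connectome construction
#' before the cohort-level statistics.
#'
#' @param cohort A [cohort_spec()], or a path to a cohort CSV directory, or
#'   `NULL` when `subjects` is given.
#' @param subjects Optional list of per-subject imaging inputs; each element
#'   is a list with `dwi`, `bvals`, `bvecs`, `labels`, `mask` paths plus
#'   `subject_id`, `group`, `score`.
#' @param tracking A [tracking_params()].
#' @param min_fibers Connectome fiber-count floor (default 5).
#' @param n_permutations Permutation count for the group test (default 10000).
#' @param alpha_group Corrected significance level of the permutation screen
#'   (default 0.05).
#' @param alpha_correlation Holm-adjusted significance level of the score
#'   screen (default 0.001).
#' @param regularization SVM cost (default 1).
#' @param positive_class Positive class for sensitivity; default group A.
#' @param seed Master seed; stage seeds are derived from it.
#' @param output_dir Optional directory for stage outputs (created on run).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = NULL, subjects = NULL,
                            tracking = tracking_params(), min_fibers = 5L,
                            n_permutations = 10000L, alpha_group = 0.05,
                            alpha_correlation = 0.001, regularization = 1,
                            positive_class = NULL, seed = 1L,
                            output_dir = NULL) {
  if (is.null(cohort) && is.null(subjects)) {
    stop_input("config needs a cohort spec/directory or per-subject imaging inputs")
  }
  if (n_permutations < 1) stop_input("n_permutations must be >= 1")
  for (a in c(alpha_group, alpha_correlation)) {
    if (a <= 0 || a >= 1) stop_input("alphas must lie in (0, 1)")
  }
  if (min_fibers < 0) stop_input("min_fibers must be >= 0")
  stopifnot(inherits(tracking, "tracking_params"), regularization > 0)
  if (is.character(cohort) && !dir.exists(cohort)) {
    stop_input("cohort directory '%s' does not exist", cohort)
  }
  if (!is.null(subjects)) {
    for (s in subjects) {
      for (f in c("dwi", "bvals", "bvecs", "labels", "mask")) {
        if (!file.exists(s[[f]])) stop_input("subject input '%s' does not exist", s[[f]])
      }
    }
  }
  structure(list(cohort = cohort, subjects = subjects, tracking = tracking,
                 min_fibers = as.integer(min_fibers),
                 n_permutations = as.integer(n_permutations),
                 alpha_group = alpha_group,
                 alpha_correlation = alpha_correlation,
                 regularization = regularization,
                 positive_class = positive_class,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `tracking`
#' is a mapping of [tracking_params()] fields; `cohort` is either a path or a
#' mapping of [cohort_spec()] fields (with `effect_edges`/`score_edges` as
#' lists of `{i, j, shift|slope}` records).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- y$cohort
  if (is.list(cohort)) {
    edges_df <- function(x, col) {
      if (is.null(x)) return(NULL)
      tibble::tibble(i = vapply(x, function(e) as.integer(e$i), integer(1)),
                     j = vapply(x, function(e) as.integer(e$j), integer(1)),
                     !!col := vapply(x, function(e) as.numeric(e[[col]]), numeric(1)))
    }
    cohort <- cohort_spec(
      n_group_a = cohort$n_group_a %||% 37L,
      n_group_b = cohort$n_group_b %||% 40L,
      n_regions = cohort$n_regions %||% 39L,
      baseline_mean = cohort$baseline_mean %||% 20,
      dispersion = cohort$dispersion %||% 2,
      effect_edges = edges_df(cohort$effect_edges, "shift"),
      score_edges = edges_df(cohort$score_edges, "slope"),
      score_baseline = cohort$score_baseline %||% 10,
      score_noise_sd = cohort$score_noise_sd %||% 2,
      group_names = unlist(cohort$group_names) %||% c("SWEDD", "PD"),
      seed = cohort$seed %||% y$seed %||% 1L)
  }
  tr <- y$tracking %||% list()
  pipeline_config(
    cohort = cohort, subjects = y$subjects,
    tracking = tracking_params(
      angle_threshold_deg = tr$angle_threshold_deg %||% 60,
      max_steps = tr$max_steps %||% 10000L,
      mask_dilation_voxels = tr$mask_dilation_voxels %||% 1L,
      step_epsilon = tr$step_epsilon %||% 1e-4),
    min_fibers = y$min_fibers %||% 5L,
    n_permutations = y$n_permutations %||% 10000L,
    alpha_group = y$alpha_group %||% 0.05,
    alpha_correlation = y$alpha_correlation %||% 0.001,
    regularization = y$regularization %||% 1,
    positive_class = y$positive_class,
    seed = y$seed %||% 1L,
    output_dir = y$output_dir)
}

#' Run the full connectivity analysis pipeline
#'
#' Executes, per subject when imaging inputs are given:
#' [fit_tensor_loglinear()] -> [track_fact()] -> [build_connectivity_matrix()];
#' then at cohort level: [permutation_group_test()] ->
#' [correlate_edges_with_scores()] on the permutation-significant edges ->
#' [loocv_linear_svm()] on the edges significant in both screens. All stage
#' outputs are written to `output_dir` (when set) in standard formats, and a
#' run report records per-stage wall-clock, input hashes, seeds, and warnings.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @return An `fc_run_report`: list with `stages` (tibble of stage, seconds,
#'   input hash), `permutation`, `correlation`, `loocv`, `selected_edges`,
#'   `stack`, `seed`, `warnings`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  warns <- character()
  t_stage <- function(name, input, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "factconn_stage_error")
    })
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      stage = name, seconds = proc.time()[["elapsed"]] - t0,
      input_hash = object_hash(input))
    res
  }

  # --- subject level ---------------------------------------------------
  if (!is.null(config$subjects)) {
    mats <- NULL
    meta <- list()
    for (s in config$subjects) {
      sid <- s$subject_id
      dwi <- t_stage(paste0("read_dwi:", sid), s,
                     read_dwi(s$dwi, s$bvals, s$bvecs))
      labels_img <- RNifti::readNifti(s$labels)
      labels <- array(as.integer(labels_img), dim = dim(labels_img))
      mask_img <- RNifti::readNifti(s$mask)
      mask <- array(as.numeric(mask_img) > 0, dim = dim(mask_img))
      regions <- motor_regions()
      present <- setdiff(unique(as.integer(labels)), 0L)
      if (!all(present %in% regions$region_id)) {
        rt <- tibble::tibble(region_id = sort(present),
                             region_name = paste0("region_", sort(present)),
                             hemisphere = NA_character_)
      } else rt <- regions
      parc <- parcellation(labels, rt)
      field <- t_stage(paste0("fit_tensor:", sid), dwi,
                       fit_tensor_loglinear(dwi, mask = dilate_mask(mask, 1L)))
      tracks <- t_stage(paste0("track:", sid), field,
                        track_fact(field, mask, config$tracking))
      W <- t_stage(paste0("connectome:", sid), tracks,
                   build_connectivity_matrix(tracks, parc, config$min_fibers))
      if (is.null(mats)) {
        mats <- array(0L, c(nrow(W), ncol(W), length(config$subjects)),
                      dimnames = list(rownames(W), colnames(W), NULL))
      }
      mats[, , length(meta) + 1L] <- W
      meta[[length(meta) + 1L]] <- list(id = sid, group = s$group, score = s$score)
    }
    stack <- cohort_stack(
      mats,
      factor(vapply(meta, `[[`, character(1), "group")),
      vapply(meta, function(m) as.integer(m$score), integer(1)),
      subject_ids = vapply(meta, `[[`, character(1), "id"))
    truth <- NULL
  } else if (is.character(config$cohort)) {
    stack <- t_stage("read_cohort", config$cohort, read_cohort_csv(config$cohort))
    truth <- NULL
  } else {
    sim <- t_stage("simulate_cohort", config$cohort, make_cohort(config$cohort))
    stack <- sim$stack
    truth <- sim$truth
  }

  # --- cohort level ----------------------------------------------------
  em <- edge_matrix(stack)
  n_untestable <- sum(colSums(em$E != 0) == 0)
  if (n_untestable > 0) {
    warns <- c(warns, sprintf("%d all-zero edge(s) excluded from testing", n_untestable))
  }
  perm <- t_stage("permutation_group_test", stack,
                  permutation_group_test(stack,
                                         n_permutations = config$n_permutations,
                                         alpha = config$alpha_group,
                                         seed = derive_seed(config$seed, "permutation")))
  sig <- significant_edges(perm)
  correlation <- NULL
  selected <- sig[0, c("edge", "i", "j", "region_i", "region_j")]
  loocv <- NULL
  if (nrow(sig) > 0) {
    correlation <- t_stage("correlate_edges_with_scores", sig,
                           correlate_edges_with_scores(stack, sig,
                                                       alpha = config$alpha_correlation))
    both <- significant_edges(correlation)
    selected <- both[, c("edge", "i", "j", "region_i", "region_j", "rho")]
    if (nrow(both) > 0) {
      feats <- build_feature_table(stack, both)
      loocv <- t_stage("loocv_linear_svm", feats,
                       loocv_linear_svm(feats,
                                        regularization = config$regularization,
                                        positive_class = config$positive_class))
    } else {
      warns <- c(warns, "no edge passed both screens; classifier skipped")
    }
  } else {
    warns <- c(warns, "no permutation-significant edge; downstream stages skipped")
  }

  report <- structure(list(
    stages = dplyr::bind_rows(stages),
    permutation = perm, correlation = correlation, loocv = loocv,
    selected_edges = selected, stack = stack, truth = truth,
    seed = config$seed, config = config, warnings = warns),
    class = "fc_run_report")
  if (!is.null(config$output_dir)) write_outputs(report, config$output_dir)
  report
}

#' @export
print.fc_run_report <- function(x, ...) {
  cat(sprintf("<fc_run_report> %d stage(s), %d permutation-significant edge(s), %d selected feature edge(s)\n",
              nrow(x$stages), sum(x$permutation$edges$significant),
              nrow(x$selected_edges)))
  if (!is.null(x$loocv)) {
    m <- x$loocv$metrics
    cat(sprintf("  LOOCV: sensitivity %.2f%%, specificity %.2f%%, accuracy %.2f%%\n",
                m$sensitivity, m$specificity, m$accuracy))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Per-subject matrices and the subject table as CSV, the edge statistics as
#' CSV, per-fold predictions as CSV, and a JSON summary with seeds,
#' parameters, metrics, and stage hashes.
#'
#' @param report An `fc_run_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_outputs <- function(report, dir) {
  stopifnot(inherits(report, "fc_run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(report$stack, file.path(dir, "matrices"))
  write_stats_csv(report$permutation, file.path(dir, "edge_stats.csv"),
                  correlation = report$correlation)
  if (!is.null(report$loocv)) {
    write.csv(report$loocv$folds, file.path(dir, "loocv_folds.csv"),
              row.names = FALSE)
  }
  summary <- list(
    seed = report$seed,
    n_permutations = report$permutation$n_permutations,
    alpha_group = report$permutation$alpha,
    alpha_correlation = if (!is.null(report$correlation)) report$correlation$alpha,
    selected_edges = report$selected_edges,
    metrics = if (!is.null(report$loocv)) report$loocv$metrics,
    # wall-clock excluded so identical runs write identical summaries
    stages = report$stages[, c("stage", "input_hash")],
    warnings = report$warnings)
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
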