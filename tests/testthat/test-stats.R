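test_that("exhaustive permutation p matches direct enumeration", {
  stack <- one_edge_stack(c(1, 2, 3), c(10, 11, 12))
  res <- permutation_group_test(stack, method = "exhaustive")
  # all C(6,3) = 20 assignments; only identity and full swap reach |T| = 9
  expect_equal(res$edges$p_uncorrected[1], 0.1)
  expect_equal(res$edges$p_uncorrected[1],
               brute_exhaustive_p(c(1, 2, 3), c(10, 11, 12)))
  # a second configuration against the independent enumerator
  a <- c(4, 7, 1, 3)
  b <- c(9, 2, 8)
  res2 <- permutation_group_test(one_edge_stack(a, b), method = "exhaustive")
  expect_equal(res2$edges$p_uncorrected[1], brute_exhaustive_p(a, b))
})

test_that("identical subjects give a zero statistic and p = 1", {
  stack <- one_edge_stack(rep(5, 4), rep(5, 5))
  res <- permutation_group_test(stack, n_permutations = 200, seed = 1)
  expect_equal(res$edges$observed[1], 0)
  expect_equal(res$edges$p_uncorrected[1], 1)
  expect_equal(res$edges$p_corrected[1], 1)
})

test_that("Monte-Carlo permutation p is seed-deterministic and validly bounded", {
  set.seed(8)
  stack <- one_edge_stack(rnorm(6, 0), rnorm(7, 1))
  r1 <- permutation_group_test(stack, n_permutations = 500, seed = 99)
  r2 <- permutation_group_test(stack, n_permutations = 500, seed = 99)
  expect_identical(r1$edges$p_uncorrected, r2$edges$p_uncorrected)
  expect_gt(r1$edges$p_uncorrected[1], 0)     # add-one estimator: never 0
  expect_lte(r1$edges$p_uncorrected[1], 1)
  expect_gte(r1$edges$p_corrected[1], r1$edges$p_uncorrected[1])
})

test_that("corrected p dominates uncorrected p across a multi-edge stack", {
  sim <- make_cohort(cohort_spec(n_group_a = 8, n_group_b = 9, n_regions = 6,
                                 seed = 4))
  res <- permutation_group_test(sim$stack, n_permutations = 500, seed = 5)
  tested <- res$edges$tested
  expect_true(all(res$edges$p_corrected[tested] >= res$edges$p_uncorrected[tested]))
  expect_true(all(res$edges$p_uncorrected[tested] > 0))
})

test_that("input validation rejects degenerate permutation requests", {
  stack <- one_edge_stack(c(1, 2, 3), c(4, 5, 6))
  expect_error(permutation_group_test(stack, n_permutations = 0), ">= 1")
  expect_error(permutation_group_test(stack, alpha = 1.2), "alpha")
  big <- one_edge_stack(rnorm(37), rnorm(40))
  expect_error(permutation_group_test(big, method = "exhaustive"), "infeasible")
})

test_that("spearman_rho matches monotone limits and the brute-force oracle", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(8, 6, 4, 2)), -1)
  # ties handled by average ranks, against an independent counting oracle
  x <- c(1, 2, 2, 4)
  y <- c(3, 1, 4, 4)
  expect_equal(spearman_rho(x, y), brute_spearman(x, y), tolerance = 1e-12)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(2, 5), 1:5), "constant")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:2, 2:3), "at least 3")
})

test_that("spearman_rho is invariant under strictly increasing transforms", {
  set.seed(12)
  for (i in 1:25) {
    x <- sample(1:6, 8, replace = TRUE)
    y <- rnorm(8)
    if (sd(x) == 0) next
    base <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), base, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y^3 + 5 * y), base, tolerance = 1e-12)
  }
})

test_that("holm_bonferroni reproduces hand-computed step-down adjustments", {
  res <- holm_bonferroni(c(0.001, 0.02, 0.04), alpha = 0.05)
  expect_equal(res$adjusted, c(0.003, 0.04, 0.04))
  expect_true(all(res$reject))
  res1 <- holm_bonferroni(c(1, 1, 1), alpha = 0.05)
  expect_equal(res1$adjusted, c(1, 1, 1))
  expect_false(any(res1$reject))
  # single p: adjusted equals raw
  expect_equal(holm_bonferroni(0.03, alpha = 0.05)$adjusted, 0.03)
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
  # step-down stops at the first failure even if later p values are small
  res2 <- holm_bonferroni(c(0.001, 0.2, 0.002), alpha = 0.05)
  expect_equal(res2$reject, c(TRUE, FALSE, TRUE))
})

test_that("holm_bonferroni agrees with p.adjust and the brute-force definition", {
  set.seed(31)
  for (i in 1:100) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    mine <- holm_bonferroni(p, alpha = 0.05)
    expect_equal(mine$adjusted, unname(p.adjust(p, method = "holm")),
                 tolerance = 1e-12)
    brute <- brute_holm(p, 0.05)
    expect_identical(mine$reject, brute$reject)
    expect_equal(mine$adjusted, brute$adjusted, tolerance = 1e-12)
  }
})

test_that("an exact monotone score link yields rho = 1 surviving correction", {
  set.seed(14)
  sim <- make_cohort(cohort_spec(n_group_a = 10, n_group_b = 10, n_regions = 5,
                                 seed = 14))
  w <- sim$stack$matrices[1, 2, ]
  stack <- cohort_stack(sim$stack$matrices, sim$stack$group,
                        as.integer(2 * w + 1))
  res <- correlate_edges_with_scores(stack, tibble::tibble(i = 1, j = 2),
                                     alpha = 0.001)
  expect_equal(res$edges$rho[1], 1)
  expect_true(res$edges$significant[1])
})

test_that("constant edges are flagged and excluded from the Holm family", {
  mats <- array(0L, c(3, 3, 8))
  set.seed(2)
  for (s in 1:8) {
    mats[1, 2, s] <- mats[2, 1, s] <- s
    mats[1, 3, s] <- mats[3, 1, s] <- 7L   # constant edge
  }
  stack <- cohort_stack(mats, rep(c("A", "B"), each = 4), score = 1:8)
  res <- correlate_edges_with_scores(stack, tibble::tibble(i = c(1, 1), j = c(2, 3)))
  expect_false(res$edges$constant[1])
  expect_true(res$edges$constant[2])
  expect_equal(res$family_size, 1)
  expect_true(is.na(res$edges$rho[2]))
})

test_that("tidy and glance expose the screening tables", {
  sim <- make_cohort(cohort_spec(n_group_a = 5, n_group_b = 5, n_regions = 4,
                                 seed = 8))
  perm <- permutation_group_test(sim$stack, n_permutations = 100, seed = 3)
  td <- tidy(perm)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("region_i", "region_j", "observed", "p_corrected") %in% names(td)))
  gl <- glance(perm)
  expect_equal(gl$n_edges, 6)
  expect_equal(gl$n_permutations, 100)
})
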