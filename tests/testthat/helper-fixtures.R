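# Shared builders and independent brute-force oracles.

# Tensor with axial eigenvalue `ax` along unit direction `dir`, radial `rad`.
oriented_tensor6 <- function(dir, ax = 1.5e-3, rad = 0.3e-3) {
  d <- dir / sqrt(sum(dir^2))
  D <- (ax - rad) * tcrossprod(d) + rad * diag(3)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

# Homogeneous tensor field with one direction everywhere (optionally a second
# direction for x >= split_x).
uniform_field <- function(dims, dir, dir2 = NULL, split_x = NULL,
                          ax = 1.5e-3, rad = 0.3e-3) {
  tensor6 <- array(0, c(dims, 6))
  v1 <- oriented_tensor6(dir, ax, rad)
  for (m in 1:6) tensor6[, , , m] <- v1[m]
  if (!is.null(dir2)) {
    v2 <- oriented_tensor6(dir2, ax, rad)
    for (m in 1:6) tensor6[split_x:dims[1], , , m] <- v2[m]
  }
  tensor_field_from_tensors(tensor6)
}

# Hand-built streamline between two voxels (straight line of points).
fake_streamline <- function(vox_from, vox_to) {
  structure(list(points = rbind(vox_from - 0.5, vox_to - 0.5),
                 voxel_path = rbind(vox_from, vox_to)),
            class = "streamline")
}

# Two-group stack with a single informative edge carrying per-subject values.
one_edge_stack <- function(values_a, values_b, score = NULL) {
  n <- length(values_a) + length(values_b)
  mats <- array(0, c(2, 2, n))
  vals <- c(values_a, values_b)
  for (s in seq_len(n)) {
    mats[1, 2, s] <- vals[s]
    mats[2, 1, s] <- vals[s]
  }
  cohort_stack(mats, rep(c("A", "B"), c(length(values_a), length(values_b))),
               score %||% rep(0L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force Spearman: average ranks by explicit counting, then the Pearson
# product-moment formula written out.
brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Literal Holm step-down: walk the sorted p values, rejecting while
# p_(k) <= alpha / (m - k + 1); adjusted p by the running-max definition.
brute_holm <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  going <- TRUE
  run_max <- 0
  adjusted <- numeric(m)
  for (k in seq_len(m)) {
    pk <- p[o[k]]
    if (going && pk <= alpha / (m - k + 1)) reject[o[k]] <- TRUE else going <- FALSE
    run_max <- max(run_max, (m - k + 1) * pk)
    adjusted[o[k]] <- min(1, run_max)
  }
  list(adjusted = adjusted, reject = reject)
}

# Exhaustive two-sided permutation p for one edge by direct enumeration.
brute_exhaustive_p <- function(values_a, values_b) {
  vals <- c(values_a, values_b)
  nA <- length(values_a)
  t_obs <- mean(values_a) - mean(values_b)
  combos <- combn(length(vals), nA)
  count <- 0L
  for (c in seq_len(ncol(combos))) {
    t_perm <- mean(vals[combos[, c]]) - mean(vals[-combos[, c]])
    if (abs(t_perm) >= abs(t_obs) - 1e-12) count <- count + 1L
  }
  count / ncol(combos)
}

angle_deg <- function(u, v) {
  c <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, c)) * 180 / pi
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
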