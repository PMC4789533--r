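#' Fit diffusion tensors by log-linear least squares
#'
#' Per masked voxel, solves \eqn{\ln(S/S_0) = -b\, g^\top D g} in least squares
#' over the six unique tensor components. \eqn{S_0} is the mean of the b = 0
#' measurements; signals are floored at \eqn{10^{-6} S_0} before the log.
#' Negative eigenvalues are clamped to 0 and the voxel is flagged `clamped`;
#' voxels with a near-degenerate leading eigenpair
#' (\eqn{|\lambda_1-\lambda_2| < 10^{-12}}) are flagged `low_confidence` but
#' remain valid for tracking.
#'
#' @param volume A [dwi_volume()].
#' @param mask Logical 3D array on the same grid; only masked voxels are fit.
#' @return A `tensor_field`: list with `tensor` (x, y, z, 6 array of
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `eigenvalues` (x, y, z, 3; sorted
#'   descending, clamped at 0), `e1` (x, y, z, 3 unit principal eigenvector
#'   with first-nonzero-positive sign convention), and logical volumes
#'   `valid`, `clamped`, `low_confidence`.
#' @export
fit_tensor_loglinear <- function(volume, mask = NULL) {
  stopifnot(inherits(volume, "dwi_volume"))
  dims <- dim(volume$signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!identical(dim(mask), dims)) stop_input("mask grid does not match the volume")
  scheme <- volume$scheme
  b0 <- which(scheme$bvals == 0)
  dwi <- which(scheme$bvals > 0)
  if (length(dwi) == 0L) stop_input("scheme has no diffusion-weighted measurements")
  X <- attenuation_design(scheme)[dwi, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < 6L) {
    stop_input("degenerate scheme: tensor design matrix has rank %d < 6", qrX$rank)
  }

  idx <- which(mask)
  nvox <- length(idx)
  field <- list(
    tensor = array(NA_real_, c(dims, 6)),
    eigenvalues = array(NA_real_, c(dims, 3)),
    e1 = array(NA_real_, c(dims, 3)),
    valid = array(FALSE, dims),
    clamped = array(FALSE, dims),
    low_confidence = array(FALSE, dims),
    voxel_size = volume$voxel_size,
    affine = volume$affine)
  class(field) <- "tensor_field"
  if (nvox == 0L) return(field)

  sig <- matrix(volume$signal, nrow = prod(dims))[idx, , drop = FALSE]
  s0 <- rowMeans(sig[, b0, drop = FALSE])
  s <- sig[, dwi, drop = FALSE]
  s <- pmax(s, 1e-6 * s0)               # signal floor before the log
  y <- -log(s / s0)                     # nvox x nmeas, y = X %*% dvec
  dvec <- t(qr.coef(qrX, t(y)))         # nvox x 6

  nxy <- dims[1] * dims[2]
  for (r in seq_len(nvox)) {
    li <- idx[r] - 1L
    i <- li %% dims[1] + 1L
    j <- (li %/% dims[1]) %% dims[2] + 1L
    k <- li %/% nxy + 1L
    ed <- eigen(vec_to_tensor(dvec[r, ]), symmetric = TRUE)
    lam <- ed$values
    clamped <- any(lam < 0)
    lam <- pmax(lam, 0)
    e1 <- fix_sign(ed$vectors[, 1])
    field$tensor[i, j, k, ] <- dvec[r, ]
    field$eigenvalues[i, j, k, ] <- lam
    field$e1[i, j, k, ] <- e1
    field$valid[i, j, k] <- all(is.finite(dvec[r, ]))
    field$clamped[i, j, k] <- clamped
    field$low_confidence[i, j, k] <- abs(lam[1] - lam[2]) < 1e-12
  }
  field
}

# Fixed eigenvector sign convention: first nonzero component positive.
fix_sign <- function(v) {
  nz <- which(abs(v) > 1e-14)
  if (length(nz) > 0L && v[nz[1]] < 0) v <- -v
  v
}

#' Build a tensor field directly from known per-voxel tensors
#'
#' Constructs the same structure as [fit_tensor_loglinear()] from a
#' (x, y, z, 6) array of tensor components, skipping the fit. Used to build
#' exactly specified fields for tracking tests and to track on phantom ground
#' truth.
#'
#' @param tensor6 Array (x, y, z, 6) of Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#' @param mask Logical array of voxels to decompose; default all.
#' @param voxel_size Voxel dimensions in mm.
#' @return A `tensor_field`.
#' @export
tensor_field_from_tensors <- function(tensor6, mask = NULL, voxel_size = c(2, 2, 2)) {
  dims <- dim(tensor6)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  field <- list(
    tensor = array(NA_real_, c(dims, 6)),
    eigenvalues = array(NA_real_, c(dims, 3)),
    e1 = array(NA_real_, c(dims, 3)),
    valid = array(FALSE, dims),
    clamped = array(FALSE, dims),
    low_confidence = array(FALSE, dims),
    voxel_size = voxel_size,
    affine = diag(c(voxel_size, 1)))
  class(field) <- "tensor_field"
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    if (!mask[i, j, k]) next
    dv <- tensor6[i, j, k, ]
    ed <- eigen(vec_to_tensor(dv), symmetric = TRUE)
    lam <- pmax(ed$values, 0)
    field$tensor[i, j, k, ] <- dv
    field$eigenvalues[i, j, k, ] <- lam
    field$e1[i, j, k, ] <- fix_sign(ed$vectors[, 1])
    field$valid[i, j, k] <- all(is.finite(dv))
    field$clamped[i, j, k] <- any(ed$values < 0)
    field$low_confidence[i, j, k] <- abs(lam[1] - lam[2]) < 1e-12
  }
  field
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> grid %s, %d valid voxel(s), %d clamped, %d low-confidence\n",
              paste(dim(x$valid), collapse = " x "), sum(x$valid),
              sum(x$clamped & x$valid), sum(x$low_confidence & x$valid)))
  invisible(x)
}

#' Principal diffusion direction at a voxel
#'
#' Returns the unit eigenvector of the largest eigenvalue, with the fixed
#' sign convention that the first nonzero component is positive. Callers
#' (tracking) re-orient the sign per propagation context. At a degenerate
#' leading eigenpair the decomposition's first vector is returned and the
#' voxel carries the `low_confidence` flag.
#'
#' @param field A `tensor_field`.
#' @param voxel Integer length-3 voxel index (1-based).
#' @return Unit length-3 numeric vector.
#' @export
principal_direction <- function(field, voxel) {
  stopifnot(inherits(field, "tensor_field"))
  voxel <- as.integer(voxel)
  dims <- dim(field$valid)
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > dims)) {
    stop_input("voxel index (%s) outside the grid", paste(voxel, collapse = ", "))
  }
  if (!field$valid[voxel[1], voxel[2], voxel[3]]) {
    stop_input("voxel (%s) is not valid in the tensor field", paste(voxel, collapse = ", "))
  }
  field$e1[voxel[1], voxel[2], voxel[3], ]
}

#' Fractional anisotropy map
#'
#' \deqn{FA = \sqrt{\tfrac12}\,
#'   \frac{\sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
#'                (\lambda_1-\lambda_3)^2}}
#'        {\sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}}}
#' with FA = 0 where all eigenvalues are zero. Values lie in \[0, 1\].
#'
#' @param field A `tensor_field`.
#' @return 3D numeric array (NA outside fitted voxels).
#' @export
fractional_anisotropy <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  l1 <- field$eigenvalues[, , , 1]
  l2 <- field$eigenvalues[, , , 2]
  l3 <- field$eigenvalues[, , , 3]
  num <- sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l1 - l3)^2)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  fa <- sqrt(0.5) * num / den
  fa[den == 0 & !is.na(den)] <- 0
  array(fa, dim = dim(field$valid))
}
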