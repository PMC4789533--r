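#' Diffusion-weighted volume
#'
#' A 4D signal array (x, y, z, measurement) with its acquisition scheme and a
#' voxel-to-world affine. The 4th dimension must match the scheme length.
#'
#' @param signal 4D non-negative numeric array.
#' @param scheme An [acquisition_scheme()].
#' @param voxel_size Length-3 voxel dimensions in mm.
#' @param affine 4 x 4 voxel-to-world transform; default is a scaling affine
#'   built from `voxel_size`.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, scheme, voxel_size = c(2, 2, 2), affine = NULL) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (length(dim(signal)) != 4L) stop_input("signal must be a 4D array")
  if (dim(signal)[4] != n_measurements(scheme)) {
    stop_input("4th signal dimension (%d) must equal scheme length (%d)",
               dim(signal)[4], n_measurements(scheme))
  }
  if (any(signal < 0)) stop_input("signal must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = voxel_size, affine = affine),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_volume> %d x %d x %d voxels, %d measurements, voxel %s mm\n",
              d[1], d[2], d[3], d[4], paste(x$voxel_size, collapse = " x ")))
  invisible(x)
}

# Map a symmetric tensor to its 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensor_to_vec <- function(D) c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])

vec_to_tensor <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

# Design matrix mapping the tensor 6-vector to b * g' D g per measurement.
attenuation_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(b * g[1, ]^2, b * g[2, ]^2, b * g[3, ]^2,
        2 * b * g[1, ] * g[2, ], 2 * b * g[1, ] * g[3, ], 2 * b * g[2, ] * g[3, ])
}

#' Simulate a diffusion-weighted signal from a tensor
#'
#' Monoexponential (Stejskal-Tanner) signal model
#' \eqn{S = S_0 \exp(-b\, g^\top D g)} evaluated for every measurement of an
#' acquisition scheme. b = 0 measurements return exactly `s0`.
#'
#' @param tensor 3 x 3 symmetric positive semi-definite diffusion tensor
#'   (mm^2/s).
#' @param scheme An [acquisition_scheme()].
#' @param s0 Baseline (non-diffusion-weighted) signal, unitless.
#' @return Numeric vector, one signal per measurement.
#' @examples
#' sch <- default_scheme()
#' simulate_dwi_signal(diag(3) * 0.7e-3, sch, s0 = 1000)[1] # b0: exactly 1000
#' @export
simulate_dwi_signal <- function(tensor, scheme, s0 = 1) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  tensor <- as.matrix(tensor)
  if (!all(dim(tensor) == c(3, 3)) || max(abs(tensor - t(tensor))) > 1e-12 * max(1, max(abs(tensor)))) {
    stop_input("tensor must be a symmetric 3 x 3 matrix")
  }
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(1, max(abs(ev)))) {
    stop_input("tensor must be positive semi-definite (min eigenvalue %.3g)", min(ev))
  }
  if (!is_number(s0) || s0 <= 0) stop_input("s0 must be a positive number")
  drop(s0 * exp(-attenuation_design(scheme) %*% tensor_to_vec(tensor)))
}

#' Add Rician noise to magnitude signals
#'
#' Each measurement is replaced by \eqn{|S + \eta_1 + i \eta_2|} with
#' \eqn{\eta_{1,2} \sim N(0, \sigma^2)} and \eqn{\sigma = s_0 / \mathrm{snr}},
#' the magnitude-MRI noise model. `snr = Inf` returns the input unchanged.
#'
#' @param signal Numeric array or vector of noise-free magnitudes.
#' @param s0 Baseline signal defining the noise scale.
#' @param snr Signal-to-noise ratio S0/sigma; `Inf` for noiseless.
#' @param seed Optional RNG seed (local to this call).
#' @return Array of the same shape as `signal`.
#' @export
add_rician_noise <- function(signal, s0, snr = Inf, seed = NULL) {
  stopifnot(snr > 0)
  if (!is.finite(snr)) return(signal)
  sigma <- s0 / snr
  with_seed(seed, {
    n1 <- array(rnorm(length(signal), sd = sigma), dim = dim(signal) %||% length(signal))
    n2 <- array(rnorm(length(signal), sd = sigma), dim = dim(signal) %||% length(signal))
    out <- sqrt((signal + n1)^2 + n2^2)
    if (!is.null(dim(signal))) dim(out) <- dim(signal)
    out
  })
}

#' Read a DWI volume from NIfTI + bvals/bvecs files
#'
#' @param dwi_path Path to a 4D NIfTI file.
#' @param bvals_path,bvecs_path FSL-style gradient table files.
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(dwi_path, bvals_path, bvecs_path) {
  img <- RNifti::readNifti(dwi_path)
  scheme <- read_bvals_bvecs(bvals_path, bvecs_path)
  if (length(dim(img)) != 4L) stop_input("%s is not a 4D NIfTI volume", dwi_path)
  affine <- structure(RNifti::xform(img), class = "matrix")
  dwi_volume(array(as.numeric(img), dim = dim(img)), scheme,
             voxel_size = RNifti::pixdim(img)[1:3],
             affine = matrix(as.numeric(affine), 4, 4))
}

#' Write a DWI volume as NIfTI + bvals/bvecs files
#'
#' The signal is stored at double precision so a write/read round trip is
#' bitwise exact.
#'
#' @param volume A [dwi_volume()].
#' @param dwi_path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param bvals_path,bvecs_path Output gradient table paths.
#' @return Invisibly, the three paths.
#' @export
write_dwi <- function(volume, dwi_path, bvals_path, bvecs_path) {
  stopifnot(inherits(volume, "dwi_volume"))
  img <- RNifti::asNifti(volume$signal)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::pixdim(img) <- c(volume$voxel_size, 1)
  RNifti::writeNifti(img, dwi_path, datatype = "double")
  write_bvals_bvecs(volume$scheme, bvals_path, bvecs_path)
  invisible(c(dwi_path, bvals_path, bvecs_path))
}

#' Write a 3D volume (mask, labels, FA map) as NIfTI
#'
#' @param vol 3D array (logical volumes are stored as 0/1 integers).
#' @param path Output path.
#' @param voxel_size Length-3 voxel dimensions in mm.
#' @param affine Optional 4 x 4 voxel-to-world transform.
#' @param datatype NIfTI storage type; default `"double"` (use `"int16"` for
#'   label volumes).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, voxel_size = c(2, 2, 2), affine = NULL,
                         datatype = "double") {
  if (is.logical(vol)) {
    vol <- array(as.integer(vol), dim = dim(vol))
    datatype <- "int16"
  }
  img <- RNifti::asNifti(vol)
  if (!is.null(affine)) img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
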