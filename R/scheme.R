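#' Diffusion acquisition scheme
#'
#' Bundles per-measurement b-values (s/mm^2) with unit gradient directions.
#' A valid scheme has at least one b = 0 measurement and at least six
#' non-collinear directions with b > 0, the minimum for a tensor fit.
#'
#' @param bvals Numeric vector of b-values, one per measurement (s/mm^2).
#' @param bvecs 3 x N numeric matrix of gradient directions (columns); rows
#'   may be supplied as N x 3 and are transposed. Directions for b > 0
#'   measurements must be unit-norm within 1e-6.
#' @return An object of class `acquisition_scheme`.
#' @seealso [default_scheme()] for the packaged 64-direction single-shell
#'   scheme, [read_bvals_bvecs()] for FSL-style text files.
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) == 3L && nrow(bvecs) != 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals)) {
    stop_input("bvecs must be 3 x N with N matching length(bvals)")
  }
  dimnames(bvecs) <- NULL
  if (any(bvals < 0)) stop_input("b-values must be non-negative")
  if (!any(bvals == 0)) stop_input("scheme needs at least one b = 0 measurement")
  dwi <- which(bvals > 0)
  norms <- sqrt(colSums(bvecs[, dwi, drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop_input("gradient directions for b > 0 must be unit-norm (max deviation %.2e)",
               max(abs(norms - 1)))
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "acquisition_scheme")
}

#' Default single-shell acquisition scheme
#'
#' One b = 0 measurement followed by `n_directions` gradient directions at a
#' single shell, mirroring a standard clinical DTI protocol (b = 1000 s/mm^2,
#' 64 directions, one b0). Directions are placed by a spherical Fibonacci
#' lattice, which is deterministic and near-uniform, giving a well-conditioned
#' tensor design matrix.
#'
#' @param n_directions Number of diffusion-weighted directions (default 64).
#' @param bval Shell b-value in s/mm^2 (default 1000).
#' @return An `acquisition_scheme`.
#' @export
default_scheme <- function(n_directions = 64, bval = 1000) {
  stopifnot(n_directions >= 6, bval > 0)
  i <- seq_len(n_directions) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n_directions
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (seq_len(n_directions) - 1)
  dirs <- rbind(r * cos(theta), r * sin(theta), z)
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  acquisition_scheme(c(0, rep(bval, n_directions)), cbind(c(0, 0, 0), dirs))
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("<acquisition_scheme> %d measurements (%d b0, shells: %s s/mm^2)\n",
              length(x$bvals), sum(x$bvals == 0),
              paste(sort(unique(x$bvals[x$bvals > 0])), collapse = ", ")))
  invisible(x)
}

n_measurements <- function(scheme) length(scheme$bvals)

#' Read FSL-style bvals/bvecs text files
#'
#' `bvals` is a whitespace-separated row (or column) of N numbers; `bvecs` is
#' 3 x N or N x 3 (auto-detected by shape). Direction columns whose norm
#' deviates from 1 by more than 1e-3 raise an error; smaller deviations are
#' normalized with a warning.
#'
#' @param bvals_path,bvecs_path File paths.
#' @return An `acquisition_scheme`.
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  raw <- as.matrix(read.table(bvecs_path))
  if (nrow(raw) == 3L && ncol(raw) != 3L) {
    bvecs <- raw
  } else if (ncol(raw) == 3L && nrow(raw) != 3L) {
    bvecs <- t(raw)
  } else if (nrow(raw) == 3L) { # 3 x 3: assume FSL layout (3 rows)
    bvecs <- raw
  } else {
    stop_input("bvecs file is neither 3 x N nor N x 3")
  }
  dwi <- which(bvals > 0)
  norms <- sqrt(colSums(bvecs[, dwi, drop = FALSE]^2))
  dev <- abs(norms - 1)
  if (any(dev > 1e-3)) {
    stop_input("bvec columns deviate from unit norm by up to %.3g (> 1e-3)", max(dev))
  }
  if (any(dev > 1e-6)) {
    warn("normalizing bvec columns with small non-unit norms (max deviation < 1e-3)")
    bvecs[, dwi] <- sweep(bvecs[, dwi, drop = FALSE], 2, norms, "/")
  }
  acquisition_scheme(bvals, bvecs)
}

#' Write FSL-style bvals/bvecs text files
#'
#' @param scheme An `acquisition_scheme`.
#' @param bvals_path,bvecs_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(scheme, bvals_path, bvecs_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bvals_path)
  writeLines(apply(scheme$bvecs, 1, function(r) {
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")
  }), bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}
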