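#' Bundle geometry for diffusion phantoms
#'
#' Describes one white-matter bundle as a straight segment or a sharp-corner
#' polyline between labeled endpoint regions. Coordinates are continuous voxel
#' coordinates: voxel (i, j, k) (1-based indices) spans
#' \eqn{[i-1, i) \times [j-1, j) \times [k-1, k)}, so voxel centers sit at
#' half-integers.
#'
#' @param waypoints Matrix (or list of length-3 vectors) of polyline vertices
#'   in voxel coordinates; 2 rows for a straight bundle, 3 for a single sharp
#'   bend. Tangents are analytic per segment.
#' @param start_region,end_region Distinct positive integer region ids planted
#'   at the two bundle ends.
#' @param width Cross-section width in voxels (diameter; >= 1). Voxels whose
#'   center lies within `width/2` of a segment axis belong to the bundle.
#' @param axial_diffusivity,radial_diffusivity Tensor eigenvalues along and
#'   across the local tangent, mm^2/s.
#' @return A `phantom_bundle` object.
#' @export
phantom_bundle <- function(waypoints, start_region, end_region, width = 1,
                           axial_diffusivity = 1.5e-3, radial_diffusivity = 0.3e-3) {
  if (is.list(waypoints)) waypoints <- do.call(rbind, waypoints)
  waypoints <- as.matrix(waypoints)
  stopifnot(ncol(waypoints) == 3L, nrow(waypoints) >= 2L)
  if (start_region == end_region) stop_input("bundle endpoint region ids must be distinct")
  stopifnot(start_region > 0, end_region > 0, width >= 1,
            axial_diffusivity > 0, radial_diffusivity > 0)
  structure(list(waypoints = waypoints,
                 start_region = as.integer(start_region),
                 end_region = as.integer(end_region),
                 width = width,
                 axial_diffusivity = axial_diffusivity,
                 radial_diffusivity = radial_diffusivity),
            class = "phantom_bundle")
}

#' Phantom specification
#'
#' Parameters of a synthetic diffusion acquisition: grid, bundles, background
#' diffusivity, baseline signal, SNR, and seed. Defaults mirror a standard
#' clinical single-shell protocol (b = 1000 s/mm^2, 64 directions + 1 b0,
#' ~2 mm voxels).
#'
#' @param grid_dims Integer length-3 voxel counts, all >= 4.
#' @param bundles List of [phantom_bundle()] objects.
#' @param voxel_size Voxel dimensions in mm.
#' @param background_diffusivity Isotropic diffusivity outside bundles, mm^2/s.
#' @param s0 Baseline signal (unitless).
#' @param snr S0/sigma for Rician noise; `Inf` = noiseless.
#' @param scheme Acquisition scheme; default [default_scheme()].
#' @param seed RNG seed for the noise draw.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_dims, bundles, voxel_size = c(2, 2, 2),
                         background_diffusivity = 0.7e-3, s0 = 1000,
                         snr = Inf, scheme = default_scheme(), seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 4L),
            background_diffusivity > 0, s0 > 0, snr > 0)
  if (inherits(bundles, "phantom_bundle")) bundles <- list(bundles)
  stopifnot(length(bundles) >= 1L,
            all(vapply(bundles, inherits, logical(1), "phantom_bundle")))
  structure(list(grid_dims = grid_dims, bundles = bundles,
                 voxel_size = as.numeric(voxel_size),
                 background_diffusivity = background_diffusivity,
                 s0 = s0, snr = snr, scheme = scheme, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Voxels (n x 3 index matrix) whose centers lie on a segment's cylinder, with
# the segment's unit tangent. Centers at (i - 0.5) in voxel coordinates.
rasterize_segment <- function(a, b, width, grid_dims) {
  tangent <- unit_norm(b - a)
  len <- sqrt(sum((b - a)^2))
  lo <- pmax(1L, floor(pmin(a, b) - width / 2 - 1) + 1L)
  hi <- pmin(grid_dims, ceiling(pmax(a, b) + width / 2 + 1))
  if (any(lo > hi)) return(list(voxels = matrix(0L, 0, 3), tangent = tangent))
  grid <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  centers <- sweep(grid, 2, c(0.5, 0.5, 0.5))
  rel <- sweep(centers, 2, a)
  s <- drop(rel %*% tangent)
  perp2 <- rowSums(rel^2) - s^2
  keep <- s >= -1e-9 & s <= len + 1e-9 & perp2 <= (width / 2)^2 + 1e-9
  list(voxels = grid[keep, , drop = FALSE], tangent = tangent)
}

# Anisotropic tensor with axial eigenvalue along `tangent`.
oriented_tensor <- function(tangent, axial, radial) {
  t <- unit_norm(tangent)
  (axial - radial) * tcrossprod(t) + radial * diag(3)
}

#' Generate a bundle phantom
#'
#' Builds a synthetic DWI acquisition from a [phantom_spec()]: bundle voxels
#' receive an anisotropic tensor oriented along the local path tangent,
#' background voxels an isotropic tensor; signals follow the Stejskal-Tanner
#' model with optional Rician noise. Parcellation labels are planted in small
#' blocks around each bundle end (covering the last two bundle voxels and the
#' two voxels beyond the end along the outward tangent, across the bundle
#' cross-section), so that streamlines terminating at or just past a bundle
#' end land in a labeled voxel. The tracking mask covers exactly the bundle
#' voxels.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `fc_phantom` with elements `dwi` ([dwi_volume()]),
#'   `parcellation` ([parcellation()]), `mask` (logical 3D array), `truth`
#'   (per-bundle voxel sets, per-voxel true tangents, expected endpoint-region
#'   pairs), and `tensor_true` (true tensor 6-vector field, for validation).
#' @examples
#' b <- phantom_bundle(rbind(c(5.5, 6.5, 6.5), c(14.5, 6.5, 6.5)), 1, 2)
#' ph <- make_bundle_phantom(phantom_spec(c(22, 13, 13), list(b)))
#' sum(ph$mask)
#' @export
make_bundle_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_dims
  nvox <- prod(dims)
  mask <- array(FALSE, dims)
  labels <- array(0L, dims)
  owner <- array(0L, dims)              # bundle id owning each voxel
  tangents <- array(NA_real_, c(dims, 3))
  bundle_voxels <- vector("list", length(spec$bundles))
  pairs <- vector("list", length(spec$bundles))

  for (bi in seq_along(spec$bundles)) {
    bun <- spec$bundles[[bi]]
    wp <- bun$waypoints
    vox_list <- list()
    for (si in seq_len(nrow(wp) - 1L)) {
      seg <- rasterize_segment(wp[si, ], wp[si + 1L, ], bun$width, dims)
      if (nrow(seg$voxels) == 0L) next
      for (r in seq_len(nrow(seg$voxels))) {
        v <- seg$voxels[r, ]
        prev <- owner[v[1], v[2], v[3]]
        if (prev == bi) next                      # corner voxel: first segment wins
        if (prev != 0L) {
          told <- tangents[v[1], v[2], v[3], ]
          if (abs(sum(told * seg$tangent)) < 1 - 1e-9) {
            stop_input("overlapping bundles with conflicting orientations at voxel (%d, %d, %d)",
                       v[1], v[2], v[3])
          }
          next
        }
        owner[v[1], v[2], v[3]] <- bi
        mask[v[1], v[2], v[3]] <- TRUE
        tangents[v[1], v[2], v[3], ] <- seg$tangent
        vox_list[[length(vox_list) + 1L]] <- v
      }
    }
    if (length(vox_list) == 0L) stop_input("bundle %d rasterizes to no voxels inside the grid", bi)
    bundle_voxels[[bi]] <- do.call(rbind, vox_list)
    # endpoint label blocks
    ends <- list(list(point = wp[1, ], outward = unit_norm(wp[1, ] - wp[2, ]),
                      region = bun$start_region),
                 list(point = wp[nrow(wp), ],
                      outward = unit_norm(wp[nrow(wp), ] - wp[nrow(wp) - 1L, ]),
                      region = bun$end_region))
    for (e in ends) {
      blk <- endpoint_block(e$point, e$outward, bun$width, dims)
      if (nrow(blk) == 0L) stop_input("bundle %d endpoint label block falls outside the grid", bi)
      for (r in seq_len(nrow(blk))) {
        labels[blk[r, 1], blk[r, 2], blk[r, 3]] <- e$region
      }
    }
    pairs[[bi]] <- c(bun$start_region, bun$end_region)
  }

  # tensor field: background isotropic, bundle voxels oriented
  tensor6 <- array(0, c(dims, 6))
  iso <- tensor_to_vec(diag(3) * spec$background_diffusivity)
  for (m in 1:6) tensor6[, , , m] <- iso[m]
  for (bi in seq_along(spec$bundles)) {
    bun <- spec$bundles[[bi]]
    vox <- bundle_voxels[[bi]]
    for (r in seq_len(nrow(vox))) {
      v <- vox[r, ]
      D <- oriented_tensor(tangents[v[1], v[2], v[3], ],
                           bun$axial_diffusivity, bun$radial_diffusivity)
      tensor6[v[1], v[2], v[3], ] <- tensor_to_vec(D)
    }
  }

  # signals: S = s0 * exp(-X %*% d) for every voxel at once
  X <- attenuation_design(spec$scheme)
  dmat <- matrix(tensor6, nrow = nvox, ncol = 6)
  signal <- spec$s0 * exp(-tcrossprod(dmat, X))   # nvox x nmeas
  signal <- array(signal, c(dims, n_measurements(spec$scheme)))
  signal <- add_rician_noise(signal, spec$s0, spec$snr,
                             seed = derive_seed(spec$seed, "rician"))

  region_ids <- sort(unique(unlist(pairs)))
  ptab <- tibble::tibble(region_id = region_ids,
                         region_name = paste0("region_", region_ids),
                         hemisphere = NA_character_)
  truth <- list(
    bundle_voxels = bundle_voxels,
    tangents = tangents,
    endpoint_pairs = tibble::tibble(
      bundle = seq_along(pairs),
      start_region = vapply(pairs, `[`, integer(1), 1L),
      end_region = vapply(pairs, `[`, integer(1), 2L)),
    seed = spec$seed)
  structure(list(
    dwi = dwi_volume(signal, spec$scheme, voxel_size = spec$voxel_size),
    parcellation = parcellation(labels, ptab),
    mask = mask,
    truth = truth,
    tensor_true = tensor6), class = "fc_phantom")
}

# Voxels forming an endpoint label block: within the bundle cross-section and
# with along-outward coordinate in [-1.5, 2.5] voxels of the bundle end.
endpoint_block <- function(point, outward, width, dims) {
  lo <- pmax(1L, floor(point - width / 2 - 3) + 1L)
  hi <- pmin(dims, ceiling(point + width / 2 + 3))
  grid <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  centers <- sweep(grid, 2, c(0.5, 0.5, 0.5))
  rel <- sweep(centers, 2, point)
  s <- drop(rel %*% outward)
  perp2 <- rowSums(rel^2) - s^2
  keep <- s >= -1.5 - 1e-9 & s <= 2.5 + 1e-9 & perp2 <= (width / 2)^2 + 1e-9
  grid[keep, , drop = FALSE]
}

#' @export
print.fc_phantom <- function(x, ...) {
  cat(sprintf("<fc_phantom> grid %s, %d bundle voxel(s), %d region(s)\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask),
              nrow(x$parcellation$region_table)))
  invisible(x)
}

#' Write phantom outputs to a directory
#'
#' Writes the 4D signal, label and mask volumes as NIfTI, the gradient table
#' as FSL-style `bvals`/`bvecs`, and the ground truth as JSON.
#'
#' @param phantom An `fc_phantom` from [make_bundle_phantom()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dwi(phantom$dwi, file.path(dir, "dwi.nii.gz"),
            file.path(dir, "bvals"), file.path(dir, "bvecs"))
  write_volume(phantom$parcellation$labels, file.path(dir, "labels.nii.gz"),
               voxel_size = phantom$dwi$voxel_size, datatype = "int16")
  write_volume(phantom$mask, file.path(dir, "mask.nii.gz"),
               voxel_size = phantom$dwi$voxel_size)
  truth <- list(
    endpoint_pairs = phantom$truth$endpoint_pairs,
    n_bundle_voxels = vapply(phantom$truth$bundle_voxels, nrow, integer(1)),
    seed = phantom$truth$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
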