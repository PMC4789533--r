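#' Tracking parameters for FACT propagation
#'
#' @param angle_threshold_deg Termination angle in degrees: the half-track
#'   stops when the angle between the incoming direction and the next voxel's
#'   (sign-aligned) principal direction exceeds this (default 60, the standard
#'   abrupt-turn criterion).
#' @param max_steps Cap on voxel transitions per half-track (default 10000).
#' @param mask_dilation_voxels 26-connected dilation of the tracking mask
#'   applied by [track_fact()], realizing "white matter and its neighbors"
#'   (default 1).
#' @param step_epsilon Nudge, in voxel units, applied along the propagation
#'   direction when crossing a voxel face, so corner/edge hits resolve to a
#'   unique next voxel (default 1e-4).
#' @return A `tracking_params` object.
#' @export
tracking_params <- function(angle_threshold_deg = 60, max_steps = 10000L,
                            mask_dilation_voxels = 1L, step_epsilon = 1e-4) {
  stopifnot(angle_threshold_deg > 0, angle_threshold_deg < 180,
            max_steps >= 1, mask_dilation_voxels >= 0, step_epsilon > 0)
  structure(list(angle_threshold_deg = angle_threshold_deg,
                 max_steps = as.integer(max_steps),
                 mask_dilation_voxels = as.integer(mask_dilation_voxels),
                 step_epsilon = step_epsilon),
            class = "tracking_params")
}

#' Dilate a voxel mask
#'
#' `k` rounds of 26-connected (face/edge/corner neighbor) binary dilation.
#'
#' @param mask Logical 3D array.
#' @param k Number of dilation rounds.
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, k = 1L) {
  dims <- dim(mask)
  for (round in seq_len(k)) {
    out <- mask
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      sx <- pmax(1L, pmin(dims[1], seq_len(dims[1]) - dx))
      sy <- pmax(1L, pmin(dims[2], seq_len(dims[2]) - dy))
      sz <- pmax(1L, pmin(dims[3], seq_len(dims[3]) - dz))
      shifted <- mask[sx, sy, sz, drop = FALSE]
      # zero out wrapped borders
      if (dx == 1) shifted[1, , ] <- FALSE else if (dx == -1) shifted[dims[1], , ] <- FALSE
      if (dy == 1) shifted[, 1, ] <- FALSE else if (dy == -1) shifted[, dims[2], ] <- FALSE
      if (dz == 1) shifted[, , 1] <- FALSE else if (dz == -1) shifted[, , dims[3]] <- FALSE
      out <- out | shifted
    }
    mask <- out
  }
  mask
}

in_grid <- function(v, dims) all(v >= 1L) && all(v <= dims)

# Exit of the axis-aligned unit voxel containing position p along direction d.
# Voxel (i, j, k) spans [i-1, i) x [j-1, j) x [k-1, k) in continuous voxel
# coordinates. Returns the parameter t > 0 to the nearest face crossing.
voxel_exit_t <- function(p, d, voxel) {
  t <- rep(Inf, 3)
  for (a in 1:3) {
    if (d[a] > 0) {
      t[a] <- (voxel[a] - p[a]) / d[a]
    } else if (d[a] < 0) {
      t[a] <- (voxel[a] - 1 - p[a]) / d[a]
    }
  }
  min(t)
}

# One FACT half-track from the seed center along `dir`. Returns the exit
# points and the voxels entered (excluding the seed voxel itself).
half_track <- function(seed, dir, field, mask, params) {
  dims <- dim(field$valid)
  cos_thr <- cos(params$angle_threshold_deg * pi / 180)
  p <- seed - 0.5
  v <- seed
  d <- dir
  pts <- vector("list", 0L)
  voxels <- vector("list", 0L)
  for (step in seq_len(params$max_steps)) {
    t <- voxel_exit_t(p, d, v)
    if (!is.finite(t)) break
    exit <- p + t * d
    pts[[length(pts) + 1L]] <- exit
    probe <- p + (t + params$step_epsilon) * d
    vn <- as.integer(floor(probe)) + 1L
    if (!in_grid(vn, dims)) break
    if (!mask[vn[1], vn[2], vn[3]]) break
    if (!field$valid[vn[1], vn[2], vn[3]]) break
    cand <- field$e1[vn[1], vn[2], vn[3], ]
    if (sum(cand * d) < 0) cand <- -cand
    # terminate on abrupt turn: angle(incoming, candidate) > threshold
    if (sum(cand * d) < cos_thr - 1e-12) break
    v <- vn
    voxels[[length(voxels) + 1L]] <- vn
    p <- probe
    d <- cand
  }
  list(points = pts, voxels = voxels)
}

#' Propagate one FACT streamline from a seed voxel
#'
#' Launches two half-tracks from the seed-voxel center along +e1 and -e1 and
#' concatenates them (the seed point is shared once). Each half-track advances
#' to the exit point of the current voxel (ray-box intersection, nudged by
#' `step_epsilon` across the face), re-orients to the next voxel's principal
#' direction (sign-aligned with the incoming direction), and terminates when
#' the next voxel is outside the mask or grid, is invalid, turns by more than
#' the angle threshold, or the step cap is reached.
#'
#' @param seed_voxel Integer length-3 voxel index (1-based).
#' @param field A `tensor_field`.
#' @param mask Logical 3D tracking mask (already dilated if desired; seeds
#'   outside it return `NULL`).
#' @param params A [tracking_params()].
#' @return A `streamline` (list with `points`, an n x 3 matrix of continuous
#'   voxel coordinates, and `voxel_path`, an m x 3 matrix of visited voxel
#'   indices), or `NULL` if both half-tracks terminate without leaving the
#'   seed voxel.
#' @export
propagate_from_seed <- function(seed_voxel, field, mask, params = tracking_params()) {
  stopifnot(inherits(field, "tensor_field"))
  dims <- dim(field$valid)
  seed <- as.integer(seed_voxel)
  if (!in_grid(seed, dims)) {
    stop_input("seed voxel (%s) outside the grid", paste(seed, collapse = ", "))
  }
  if (!mask[seed[1], seed[2], seed[3]]) return(NULL)
  if (!field$valid[seed[1], seed[2], seed[3]]) return(NULL)
  e1 <- field$e1[seed[1], seed[2], seed[3], ]
  fwd <- half_track(seed, e1, field, mask, params)
  bwd <- half_track(seed, -e1, field, mask, params)
  if (length(fwd$voxels) == 0L && length(bwd$voxels) == 0L) return(NULL)
  pts <- rbind(
    do.call(rbind, rev(bwd$points)),
    matrix(seed - 0.5, 1, 3),
    do.call(rbind, fwd$points))
  vox <- rbind(
    do.call(rbind, rev(bwd$voxels)),
    matrix(seed, 1, 3),
    do.call(rbind, fwd$voxels))
  structure(list(points = pts, voxel_path = vox), class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("<streamline> %d points, %d voxels, endpoints (%s) -- (%s)\n",
              nrow(x$points), nrow(x$voxel_path),
              paste(x$voxel_path[1, ], collapse = ","),
              paste(x$voxel_path[nrow(x$voxel_path), ], collapse = ",")))
  invisible(x)
}

#' Whole-volume FACT tractography
#'
#' Dilates the mask by `mask_dilation_voxels` (26-connectivity) to obtain the
#' tracking region, then calls [propagate_from_seed()] once per voxel of the
#' original (undilated) mask, in fixed column-major order. Tracking is fully
#' deterministic: identical inputs give identical streamline lists.
#'
#' @param field A `tensor_field`.
#' @param mask Logical 3D seed mask on the field's grid.
#' @param params A [tracking_params()].
#' @return A list of `streamline` objects (class `fc_streamlines`), with the
#'   dilated tracking mask and parameters attached as attributes.
#' @export
track_fact <- function(field, mask, params = tracking_params()) {
  stopifnot(inherits(field, "tensor_field"))
  if (!identical(dim(mask), dim(field$valid))) {
    stop_input("mask and tensor field grids differ")
  }
  tracking_mask <- if (params$mask_dilation_voxels > 0) {
    dilate_mask(mask, params$mask_dilation_voxels)
  } else mask
  seeds <- which(mask, arr.ind = TRUE)
  out <- vector("list", nrow(seeds))
  n <- 0L
  for (r in seq_len(nrow(seeds))) {
    seed <- seeds[r, ]
    if (!field$valid[seed[1], seed[2], seed[3]]) next
    s <- propagate_from_seed(seed, field, tracking_mask, params)
    if (!is.null(s)) {
      n <- n + 1L
      out[[n]] <- s
    }
  }
  structure(out[seq_len(n)], class = "fc_streamlines",
            tracking_mask = tracking_mask, params = params,
            voxel_size = field$voxel_size, affine = field$affine,
            grid_dims = dim(field$valid))
}

#' @export
print.fc_streamlines <- function(x, ...) {
  cat(sprintf("<fc_streamlines> %d streamline(s)\n", length(x)))
  invisible(x)
}

#' Write streamlines in TrackVis TRK format
#'
#' Binary TRK v2 with voxel-size and dimension header fields taken from the
#' source field; points are stored in TrackVis voxel-mm convention (continuous
#' voxel coordinate times voxel size).
#'
#' @param streamlines An `fc_streamlines` from [track_fact()].
#' @param path Output `.trk` path.
#' @return Invisibly, `path`.
#' @export
write_trk <- function(streamlines, path) {
  vs <- attr(streamlines, "voxel_size") %||% c(1, 1, 1)
  dims <- attr(streamlines, "grid_dims") %||% c(0L, 0L, 0L)
  affine <- attr(streamlines, "affine") %||% diag(4)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(dims), con, size = 2)                  # dim[3]
  writeBin(as.numeric(vs), con, size = 4)                    # voxel_size[3]
  writeBin(numeric(3), con, size = 4)                        # origin[3]
  writeBin(0L, con, size = 2)                                # n_scalars
  writeBin(raw(200), con)                                    # scalar names
  writeBin(0L, con, size = 2)                                # n_properties
  writeBin(raw(200), con)                                    # property names
  writeBin(as.numeric(t(affine)), con, size = 4)             # vox_to_ras
  writeBin(raw(444), con)                                    # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0)), con)              # voxel_order
  writeBin(raw(4), con)                                      # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4)   # image orientation
  writeBin(raw(2), con)                                      # pad1
  writeBin(raw(6), con)                                      # invert/swap flags
  writeBin(length(streamlines), con, size = 4)               # n_count
  writeBin(2L, con, size = 4)                                # version
  writeBin(1000L, con, size = 4)                             # hdr_size
  for (s in streamlines) {
    writeBin(nrow(s$points), con, size = 4)
    writeBin(as.numeric(t(sweep(s$points, 2, vs, "*"))), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis TRK file
#'
#' Companion reader for [write_trk()] round trips; supports TRK v2 without
#' per-point scalars or per-track properties.
#'
#' @param path `.trk` file path.
#' @return An `fc_streamlines` list (points only; voxel paths are not stored
#'   in TRK and are reconstructed as the containing voxels of each point).
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5))
  if (magic != "TRACK") stop_input("%s is not a TRK file", path)
  readBin(con, "raw", 1)
  dims <- readBin(con, "integer", 3, size = 2)
  vs <- readBin(con, "numeric", 3, size = 4)
  readBin(con, "numeric", 3, size = 4)
  n_scalars <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  affine <- matrix(readBin(con, "numeric", 16, size = 4), 4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4)
  readBin(con, "numeric", 6, size = 4)
  readBin(con, "raw", 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 2, size = 4)
  if (n_scalars != 0 || n_props != 0) stop_input("TRK scalars/properties unsupported")
  out <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4)
    pts <- matrix(readBin(con, "numeric", 3 * np, size = 4), ncol = 3, byrow = TRUE)
    pts <- sweep(pts, 2, vs, "/")
    out[[i]] <- structure(list(points = pts,
                               voxel_path = floor(pts) + 1L),
                          class = "streamline")
  }
  structure(out, class = "fc_streamlines", voxel_size = vs,
            grid_dims = as.integer(dims), affine = affine)
}

#' Dump streamline points as plain text
#'
#' One line per point (`track point x y z`), blank-line free, for diffing in
#' tests and quick inspection.
#'
#' @param streamlines An `fc_streamlines`.
#' @param path Output text path.
#' @return Invisibly, `path`.
#' @export
write_streamline_text <- function(streamlines, path) {
  lines <- unlist(lapply(seq_along(streamlines), function(i) {
    p <- streamlines[[i]]$points
    sprintf("%d %d %.8f %.8f %.8f", i, seq_len(nrow(p)), p[, 1], p[, 2], p[, 3])
  }))
  writeLines(lines, path)
  invisible(path)
}
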