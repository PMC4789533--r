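test_that("a straight ray through a homogeneous slab spans the full extent", {
  field <- uniform_field(c(14, 5, 5), c(1, 0, 0))
  mask <- array(FALSE, c(14, 5, 5))
  mask[3:12, 3, 3] <- TRUE
  s <- propagate_from_seed(c(7, 3, 3), field, mask)
  expect_s3_class(s, "streamline")
  # continuous x-extent covers the slab [2, 12): exits at both slab faces
  expect_equal(min(s$points[, 1]), 2, tolerance = 1e-3)
  expect_equal(max(s$points[, 1]), 12, tolerance = 1e-3)
  expect_equal(s$voxel_path[1, ], c(3L, 3L, 3L))
  expect_equal(s$voxel_path[nrow(s$voxel_path), ], c(12L, 3L, 3L))
})

test_that("propagation terminates at a 90-degree interface but crosses 45 degrees", {
  mask <- array(TRUE, c(12, 12, 5))
  f90 <- uniform_field(c(12, 12, 5), c(1, 0, 0), dir2 = c(0, 1, 0), split_x = 8)
  s <- propagate_from_seed(c(4, 6, 3), f90, mask)
  expect_equal(max(s$voxel_path[, 1]), 7)       # never enters the rotated region
  f45 <- uniform_field(c(12, 12, 5), c(1, 0, 0), dir2 = c(1, 1, 0), split_x = 8)
  s45 <- propagate_from_seed(c(4, 6, 3), f45, mask)
  expect_gt(max(s45$voxel_path[, 1]), 8)        # crosses and continues diagonally
  expect_gt(max(s45$voxel_path[, 2]), 6)
})

test_that("angle exactly at the threshold continues; just above terminates", {
  mask <- array(TRUE, c(12, 12, 5))
  rot <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
  at <- propagate_from_seed(c(4, 6, 3),
                            uniform_field(c(12, 12, 5), c(1, 0, 0),
                                          dir2 = rot(60), split_x = 8), mask)
  expect_gt(max(at$voxel_path[, 1]), 8)
  above <- propagate_from_seed(c(4, 6, 3),
                               uniform_field(c(12, 12, 5), c(1, 0, 0),
                                             dir2 = rot(61), split_x = 8), mask)
  expect_equal(max(above$voxel_path[, 1]), 7)
})

test_that("seeds outside the mask return NULL; outside the grid raise", {
  field <- uniform_field(c(8, 5, 5), c(1, 0, 0))
  mask <- array(FALSE, c(8, 5, 5))
  mask[3:6, 3, 3] <- TRUE
  expect_null(propagate_from_seed(c(1, 1, 1), field, mask))
  expect_error(propagate_from_seed(c(9, 3, 3), field, mask), "outside the grid")
})

test_that("max_steps caps each half-track", {
  field <- uniform_field(c(30, 5, 5), c(1, 0, 0))
  mask <- array(TRUE, c(30, 5, 5))
  s <- propagate_from_seed(c(15, 3, 3), field, mask,
                           tracking_params(max_steps = 3))
  expect_lte(nrow(s$voxel_path), 2 * 3 + 1)
})

test_that("track_fact seeds every masked voxel and is deterministic", {
  field <- uniform_field(c(14, 5, 5), c(1, 0, 0))
  mask <- array(FALSE, c(14, 5, 5))
  mask[3:12, 3, 3] <- TRUE
  tr1 <- track_fact(field, mask, tracking_params(mask_dilation_voxels = 0))
  expect_length(tr1, 10)
  # every seed yields the same endpoint voxel pair
  ends <- unique(t(sapply(tr1, function(s) {
    vp <- s$voxel_path
    c(vp[1, ], vp[nrow(vp), ])
  })))
  expect_equal(nrow(ends), 1)
  tr2 <- track_fact(field, mask, tracking_params(mask_dilation_voxels = 0))
  expect_identical(tr1, tr2)
})

test_that("an all-invalid field yields an empty streamline list", {
  tensor6 <- array(0, c(4, 4, 4, 6))
  field <- tensor_field_from_tensors(tensor6, mask = array(FALSE, c(4, 4, 4)))
  mask <- array(TRUE, c(4, 4, 4))
  expect_length(track_fact(field, mask), 0)
})

test_that("streamlines stay inside the dilated mask and reverse symmetrically", {
  field <- uniform_field(c(14, 6, 6), c(1, 0, 0))
  mask <- array(FALSE, c(14, 6, 6))
  mask[3:12, 3:4, 3:4] <- TRUE
  tracks <- track_fact(field, mask)
  dil <- attr(tracks, "tracking_mask")
  for (s in tracks) {
    for (r in seq_len(nrow(s$voxel_path))) {
      v <- s$voxel_path[r, ]
      expect_true(dil[v[1], v[2], v[3]])
    }
    ep <- rbind(s$voxel_path[1, ], s$voxel_path[nrow(s$voxel_path), ])
    rev_ep <- ep[2:1, ]
    # endpoint voxel pair is orientation-free
    expect_setequal(apply(ep, 1, paste, collapse = ","),
                    apply(rev_ep, 1, paste, collapse = ","))
  }
})

test_that("mask dilation is 26-connected", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  d <- dilate_mask(m, 1)
  expect_equal(sum(d), 27)
  expect_true(d[2, 2, 2])   # corner neighbor included
  # border voxels do not wrap
  m2 <- array(FALSE, c(3, 3, 3))
  m2[1, 1, 1] <- TRUE
  expect_equal(sum(dilate_mask(m2, 1)), 8)
})

test_that("TRK round trip preserves points to float precision", {
  field <- uniform_field(c(14, 5, 5), c(1, 0, 0))
  mask <- array(FALSE, c(14, 5, 5))
  mask[3:12, 3, 3] <- TRUE
  tracks <- track_fact(field, mask)
  path <- tempfile(fileext = ".trk")
  write_trk(tracks, path)
  back <- read_trk(path)
  expect_length(back, length(tracks))
  expect_equal(back[[1]]$points, tracks[[1]]$points, tolerance = 1e-5)
  txt <- tempfile(fileext = ".txt")
  write_streamline_text(tracks, txt)
  expect_equal(length(readLines(txt)), sum(sapply(tracks, function(s) nrow(s$points))))
})
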