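two_region_parc <- function(dims = c(10, 5, 5)) {
  labels <- array(0L, dims)
  labels[1:2, , ] <- 3L
  labels[(dims[1] - 1):dims[1], , ] <- 7L
  parcellation(labels, tibble::tibble(region_id = c(3L, 7L),
                                      region_name = c("A", "B"),
                                      hemisphere = c("L", "R")))
}

test_that("endpoints map to the labels of their terminal voxels", {
  parc <- two_region_parc()
  expect_equal(assign_endpoints(fake_streamline(c(1, 3, 3), c(10, 3, 3)), parc),
               c(3L, 7L))
  # background endpoint drops the fiber
  expect_null(assign_endpoints(fake_streamline(c(5, 3, 3), c(10, 3, 3)), parc))
  # both endpoints in one region: self-loop excluded
  expect_null(assign_endpoints(fake_streamline(c(1, 3, 3), c(2, 3, 3)), parc))
  expect_error(assign_endpoints(fake_streamline(c(1, 3, 3), c(11, 3, 3)), parc),
               "outside the parcellation")
})

test_that("fiber counting applies the minimum-fiber floor with boundary retained", {
  labels <- array(0L, c(12, 3, 3))
  labels[1, , ] <- 1L
  labels[6, , ] <- 2L
  labels[12, , ] <- 3L
  parc <- parcellation(labels, tibble::tibble(region_id = 1:3,
                                              region_name = c("r1", "r2", "r3"),
                                              hemisphere = NA))
  s12 <- replicate(6, fake_streamline(c(1, 2, 2), c(6, 2, 2)), simplify = FALSE)
  s13 <- replicate(4, fake_streamline(c(1, 2, 2), c(12, 2, 2)), simplify = FALSE)
  W <- build_connectivity_matrix(c(s12, s13), parc, min_fibers = 5)
  expect_equal(W["r1", "r2"], 6L)
  expect_equal(W["r1", "r3"], 0L)   # 4 < 5 excluded
  expect_true(isSymmetric(unclass(W)))
  expect_true(all(diag(W) == 0))
  # exactly 5 fibers are retained: only "< 5" is excluded
  W5 <- build_connectivity_matrix(c(s12[1:5]), parc, min_fibers = 5)
  expect_equal(W5["r1", "r2"], 5L)
  # thresholding is idempotent
  W2 <- W
  W2[W2 < 5] <- 0L
  expect_equal(unclass(W2), unclass(W))
})

test_that("an empty streamline list gives the all-zero matrix", {
  parc <- two_region_parc()
  W <- build_connectivity_matrix(list(), parc)
  expect_true(all(W == 0))
  expect_equal(dim(W), c(2L, 2L))
})

test_that("total upper-triangle count never exceeds the number of streamlines", {
  parc <- two_region_parc()
  set.seed(5)
  streams <- lapply(1:30, function(i) {
    fake_streamline(c(sample(10, 1), sample(5, 1), sample(5, 1)),
                    c(sample(10, 1), sample(5, 1), sample(5, 1)))
  })
  W <- build_connectivity_matrix(streams, parc, min_fibers = 0)
  expect_lte(sum(W[upper.tri(W)]), 30)
})

test_that("straight-bundle phantom recovers weight equal to the seed count", {
  b <- phantom_bundle(rbind(c(4.5, 5.5, 5.5), c(15.5, 5.5, 5.5)), 1, 2)
  ph <- make_bundle_phantom(phantom_spec(c(22, 11, 11), list(b)))
  w_seeds <- sum(ph$mask)
  field <- fit_tensor_loglinear(ph$dwi, mask = dilate_mask(ph$mask, 1))
  tracks <- track_fact(field, ph$mask)
  W <- build_connectivity_matrix(tracks, ph$parcellation)
  expect_equal(W["region_1", "region_2"], w_seeds)
})

test_that("the motor-region table has 39 regions: 19 bilateral pairs + brainstem", {
  tab <- motor_regions()
  expect_equal(nrow(tab), 39)
  expect_equal(sum(tab$hemisphere == "L"), 19)
  expect_equal(sum(tab$hemisphere == "R"), 19)
  expect_equal(tab$region_name[39], "brainstem")
  expect_false(anyDuplicated(tab$region_id) > 0)
  clusters <- unique(tab$cluster)
  expect_setequal(clusters, c("motor_premotor", "dlpfc", "cma", "sma",
                              "parietal", "subcortical", "brainstem"))
})

test_that("connectivity CSV round trips with region names", {
  parc <- two_region_parc()
  W <- build_connectivity_matrix(
    replicate(7, fake_streamline(c(1, 3, 3), c(10, 3, 3)), simplify = FALSE),
    parc)
  path <- tempfile(fileext = ".csv")
  write_connectivity_csv(W, path)
  back <- read_connectivity_csv(path)
  expect_equal(unclass(back)[, ], unclass(W)[, ])
  expect_equal(rownames(back), c("A", "B"))
})
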