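sch64 <- default_scheme()

signal_volume <- function(tensor6, scheme = sch64, s0 = 1000, dims = c(2, 2, 2)) {
  sig <- simulate_dwi_signal(
    matrix(c(tensor6[1], tensor6[4], tensor6[5],
             tensor6[4], tensor6[2], tensor6[6],
             tensor6[5], tensor6[6], tensor6[3]), 3, 3),
    scheme, s0)
  arr <- array(rep(sig, each = prod(dims)), c(dims, length(sig)))
  dwi_volume(arr, scheme)
}

test_that("log-linear fit recovers a noiseless tensor to high relative accuracy", {
  d_true <- c(1.5e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  field <- fit_tensor_loglinear(signal_volume(d_true))
  expect_lt(max(abs(field$tensor[1, 1, 1, ] - d_true)) / max(d_true), 1e-6)
  expect_equal(field$e1[1, 1, 1, ], c(1, 0, 0), tolerance = 1e-6)
  expect_false(field$clamped[1, 1, 1])
})

test_that("isotropy is preserved: equal eigenvalues from isotropic signals", {
  field <- fit_tensor_loglinear(signal_volume(c(rep(0.7e-3, 3), 0, 0, 0)))
  expect_equal(field$eigenvalues[1, 1, 1, ], rep(0.7e-3, 3), tolerance = 1e-9)
  expect_true(field$low_confidence[1, 1, 1])
})

test_that("a five-direction scheme raises a rank error", {
  dirs <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2))
  sch5 <- acquisition_scheme(c(0, rep(1000, 5)), cbind(c(0, 0, 0), dirs))
  expect_error(fit_tensor_loglinear(signal_volume(c(rep(1e-3, 3), 0, 0, 0), sch5)),
               "rank")
})

test_that("the fit is rotation-equivariant", {
  set.seed(11)
  D <- diag(c(1.7e-3, 0.5e-3, 0.2e-3))
  base <- fit_tensor_loglinear(signal_volume(c(diag(D), 0, 0, 0)))
  D_base <- matrix(c(base$tensor[1, 1, 1, c(1, 4, 5)],
                     base$tensor[1, 1, 1, c(4, 2, 6)],
                     base$tensor[1, 1, 1, c(5, 6, 3)]), 3, 3)
  for (rep in 1:5) {
    R <- random_rotation()
    DR <- R %*% D %*% t(R)
    d6 <- c(DR[1, 1], DR[2, 2], DR[3, 3], DR[1, 2], DR[1, 3], DR[2, 3])
    fit <- fit_tensor_loglinear(signal_volume(d6))
    D_fit <- matrix(c(fit$tensor[1, 1, 1, c(1, 4, 5)],
                      fit$tensor[1, 1, 1, c(4, 2, 6)],
                      fit$tensor[1, 1, 1, c(5, 6, 3)]), 3, 3)
    expect_lt(max(abs(D_fit - R %*% D_base %*% t(R))) / 1.7e-3, 1e-6)
  }
})

test_that("principal_direction follows the largest eigenvector with a fixed sign", {
  f <- tensor_field_from_tensors(array(rep(c(3e-3, 2e-3, 1e-3, 0, 0, 0),
                                           each = 8), c(2, 2, 2, 6)))
  expect_equal(principal_direction(f, c(1, 1, 1)), c(1, 0, 0))
  # rotated tensor: e1 = R (1,0,0) up to sign, checked against eigen() directly
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  DR <- R %*% diag(c(3e-3, 2e-3, 1e-3)) %*% t(R)
  f2 <- tensor_field_from_tensors(array(rep(c(DR[1, 1], DR[2, 2], DR[3, 3],
                                              DR[1, 2], DR[1, 3], DR[2, 3]),
                                            each = 8), c(2, 2, 2, 6)))
  e1 <- principal_direction(f2, c(2, 2, 2))
  expect_lt(angle_deg(e1, R %*% c(1, 0, 0)), 1e-6)
  # sign convention: first nonzero component positive
  expect_gt(e1[which(abs(e1) > 1e-14)[1]], 0)
  expect_error(principal_direction(f, c(5, 1, 1)), "outside the grid")
})

test_that("degenerate leading eigenpair is deterministic and flagged", {
  f <- tensor_field_from_tensors(array(rep(c(1e-3, 1e-3, 0.5e-3, 0, 0, 0),
                                           each = 8), c(2, 2, 2, 6)))
  expect_true(f$low_confidence[1, 1, 1])
  expect_true(f$valid[1, 1, 1])
  expect_identical(principal_direction(f, c(1, 1, 1)),
                   principal_direction(f, c(2, 2, 2)))
})

test_that("fractional anisotropy matches closed forms and stays in [0, 1]", {
  mk <- function(lams) tensor_field_from_tensors(
    array(rep(c(lams, 0, 0, 0), each = 1), c(1, 1, 1, 6)))
  expect_equal(fractional_anisotropy(mk(c(1, 1, 1) * 1e-3))[1, 1, 1], 0)
  expect_equal(fractional_anisotropy(mk(c(1e-3, 0, 0)))[1, 1, 1], 1)
  expect_equal(fractional_anisotropy(mk(c(3, 2, 1) * 1e-3))[1, 1, 1],
               sqrt(3 / 14), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    fa <- fractional_anisotropy(mk(sort(runif(3, 0, 3e-3), decreasing = TRUE)))[1, 1, 1]
    expect_gte(fa, 0)
    expect_lte(fa, 1)
  }
  # all-zero eigenvalues map to FA = 0 by convention
  expect_equal(fractional_anisotropy(mk(c(0, 0, 0)))[1, 1, 1], 0)
})
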