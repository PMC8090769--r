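test_that("straight phantoms orient corridor tensors along the axis", {
  spec <- phantom_spec()
  tf <- make_tensor_phantom(spec)
  expect_true(any(tf$corridor))
  idx <- which(tf$corridor, arr.ind = TRUE)
  for (r in sample(nrow(idx), 10)) {
    d6 <- tf$D[idx[r, 1], idx[r, 2], idx[r, 3], ]
    v <- principal_direction(d6)
    expect_equal(abs(v[2]), 1, tolerance = 1e-9)
    expect_gt(fractional_anisotropy(d6), 0.5)
  }
  # background is isotropic, below any tracking floor
  bg <- which(!tf$corridor, arr.ind = TRUE)[1, ]
  expect_lt(fractional_anisotropy(tf$D[bg[1], bg[2], bg[3], ]), 1e-9)
  # regeneration is bit-stable
  expect_identical(tf, make_tensor_phantom(spec))
})

test_that("curved phantoms align tensors with the analytic tangent", {
  spec <- phantom_spec("curved", shape = c(21, 21, 7))
  tf <- make_tensor_phantom(spec)
  idx <- which(tf$corridor, arr.ind = TRUE)
  expect_gt(nrow(idx), 20)
  ctr <- (spec$shape - 1) / 2 * spec$resolution
  R <- (min(spec$shape[1:2]) - 1) / 2 * spec$resolution * 0.8
  for (r in seq_len(nrow(idx))) {
    p <- (idx[r, ] - 1) * spec$resolution
    cx <- p[1] - ctr[1] + R / sqrt(2); cy <- p[2] - ctr[2] + R / sqrt(2)
    tang <- c(-cy, cx, 0) / sqrt(cx^2 + cy^2)
    v <- principal_direction(tf$D[idx[r, 1], idx[r, 2], idx[r, 3], ])
    ang <- acos(pmin(abs(sum(v * tang)), 1)) * 180 / pi
    expect_lt(ang, 2)
  }
})

test_that("crossing phantoms have a degenerate leading eigenspace at the overlap", {
  spec <- phantom_spec("crossing", shape = c(15, 15, 7))
  tf <- make_tensor_phantom(spec)
  ctr <- (dim(tf$mask) + 1) / 2
  d6 <- tf$D[ctr[1], ctr[2], ctr[3], ]
  lam <- eigen(spectre:::tensor_matrix(d6), symmetric = TRUE,
               only.values = TRUE)$values
  expect_lt(lam[1] - lam[2], 1e-12)
  expect_true(attr(principal_direction(d6), "degenerate"))
})

test_that("ramp color fields are affine and sampled exactly", {
  affine <- grid_affine(2)
  cv <- make_ramp_colorfield(c(5, 11, 5), affine, axis = 2, gain = 1 / 100)
  expect_equal(cv$data[3, 3, 3, 1], 0.04, tolerance = 1e-12)  # y = 4 mm
  expect_true(all(cv$data[, , , 2:3] == 0))
  expect_true(all(make_ramp_colorfield(c(3, 3, 3), affine,
                                       gain = 0)$data == 0))
  set.seed(61)
  pts <- cbind(runif(30, 0, 8), runif(30, 0, 20), runif(30, 0, 8))
  expect_equal(trilinear_sample(cv, pts)[, 1], pts[, 2] / 100,
               tolerance = 1e-12)
})

test_that("cap color fields paint the two corridor ends", {
  cv <- make_cap_colorfield(c(5, 21, 5), grid_affine(1), axis = 2,
                            cap_fraction = 0.2)
  expect_true(all(cv$data[, 1:5, , 3] == 1))    # low end: blue
  expect_true(all(cv$data[, 17:21, , 2] == 1))  # high end: green
  expect_true(all(cv$data[, 6:16, , ] == 0))
})

test_that("re-scan pairs perturb tensors but stay PSD and deterministic", {
  tf <- make_tensor_phantom(phantom_spec(shape = c(7, 11, 7)))
  zero <- make_rescan_pair(tf, 0)
  expect_identical(zero$scan1$D, zero$scan2$D)

  pair <- make_rescan_pair(tf, 0.1, seed = 5)
  expect_false(identical(pair$scan1$D, pair$scan2$D))
  expect_identical(pair$scan2$D, make_rescan_pair(tf, 0.1, seed = 5)$scan2$D)
  # PSD: no negative eigenvalues anywhere
  M <- matrix(pair$scan2$D, ncol = 6)
  mins <- apply(M[sample(nrow(M), 40), ], 1, function(d6)
    min(eigen(spectre:::tensor_matrix(d6), symmetric = TRUE,
              only.values = TRUE)$values))
  expect_true(all(mins >= -1e-15))
})
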