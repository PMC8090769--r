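test_that("gradient evaluation reproduces the closed-form Gaussian sum", {
  spec <- default_gradient_spec()
  # at the first Gaussian's center only its own (red) amplitude survives
  expect_equal(evaluate_gradient(spec, c(0, -60, 70))[1, 1], 0.5,
               tolerance = 1e-12)
  # second center: unit green
  expect_equal(evaluate_gradient(spec, c(0, 70, 0))[1, 2], 1.0,
               tolerance = 1e-12)
  # far from every center the field vanishes
  expect_lt(max(evaluate_gradient(spec, c(2000, 2000, 2000))), 1e-200)
  # independent hand evaluation at the origin: squared distances to the
  # three centers are 8500, 4900, 5300 with 2*sigma^2 = 5000
  expect_equal(as.vector(evaluate_gradient(spec, c(0, 0, 0))),
               c(0.5 * exp(-8500 / 5000), exp(-4900 / 5000),
                 exp(-5300 / 5000)),
               tolerance = 1e-12)
  expect_error(evaluate_gradient(spec, c(0, NA, 0)), "finite")
})

test_that("gradient evaluation is linear in the amplitudes", {
  spec <- default_gradient_spec()
  set.seed(11)
  pts <- matrix(runif(30, -100, 100), ncol = 3)
  for (rep in 1:10) {
    a <- matrix(runif(9), 3); b <- matrix(runif(9), 3)
    sa <- gradient_spec(a, spec$centers, spec$sigma)
    sb <- gradient_spec(b, spec$centers, spec$sigma)
    sab <- gradient_spec(a + b, spec$centers, spec$sigma)
    expect_equal(evaluate_gradient(sab, pts),
                 evaluate_gradient(sa, pts) + evaluate_gradient(sb, pts),
                 tolerance = 1e-12)
  }
})

test_that("each channel depends only on the distance to its own center", {
  spec <- default_gradient_spec()
  set.seed(12)
  pts <- matrix(runif(60, -120, 120), ncol = 3)
  vals <- evaluate_gradient(spec, pts)
  for (k in 1:3) {
    d2 <- rowSums(sweep(pts, 2, spec$centers[k, ])^2)
    scalar <- spec$amplitudes[k, k] * exp(-d2 / (2 * spec$sigma^2))
    expect_equal(vals[, k], scalar, tolerance = 1e-12)
  }
})

test_that("rasterization matches point evaluation and mirrors in x", {
  spec <- default_gradient_spec()
  # single voxel centered at the second Gaussian's center
  aff1 <- grid_affine(1, origin = c(0, 70, 0))
  cv1 <- rasterize_gradient(spec, c(1, 1, 1), aff1)
  expect_equal(cv1$data[1, 1, 1, 2], 1.0, tolerance = 1e-12)
  expect_identical(cv1$space, "template")

  dim3 <- c(7, 6, 5)
  affine <- grid_affine(c(10, 20, 25), origin = c(-30, -60, 10))
  cv <- rasterize_gradient(spec, dim3, affine)
  centers <- spectre:::grid_centers(dim3, affine)
  expect_equal(matrix(cv$data, ncol = 3), evaluate_gradient(spec, centers),
               tolerance = 1e-12)
  # all centers have x = 0, so a grid symmetric about x = 0 mirrors in x
  expect_equal(cv$data, cv$data[dim3[1]:1, , , , drop = FALSE],
               tolerance = 1e-12)
})

test_that("mask restriction zeroes outside, keeps inside, is idempotent", {
  set.seed(13)
  cv <- color_volume(array(runif(4 * 4 * 4 * 3), c(4, 4, 4, 3)),
                     grid_affine(1))
  expect_equal(restrict_to_mask(cv, array(TRUE, c(4, 4, 4)))$data, cv$data)
  expect_true(all(restrict_to_mask(cv, array(FALSE, c(4, 4, 4)))$data == 0))

  mask <- array((slice.index(array(0, c(4, 4, 4)), 1) +
                 slice.index(array(0, c(4, 4, 4)), 2) +
                 slice.index(array(0, c(4, 4, 4)), 3)) %% 2 == 0,
                c(4, 4, 4))
  masked <- restrict_to_mask(cv, mask)
  for (k in 1:3)
    expect_equal(masked$data[, , , k], cv$data[, , , k] * mask)
  expect_equal(restrict_to_mask(masked, mask)$data, masked$data)
  expect_error(restrict_to_mask(cv, array(TRUE, c(3, 4, 4))), "geometry")
})

test_that("warping pulls template content back through the field", {
  set.seed(14)
  dim3 <- c(6, 7, 5)
  affine <- grid_affine(2, origin = c(1, 2, 3))
  cv <- color_volume(array(runif(prod(dim3) * 2), c(dim3, 2)), affine)

  # identity field on the same grid reproduces the volume exactly
  out <- warp_colorvolume(cv, identity_deformation(dim3, affine))
  expect_equal(out$data, cv$data, tolerance = 1e-12)
  expect_identical(out$space, "subject")

  # sampling one full voxel further along +y shifts content by one voxel
  shifted <- warp_colorvolume(cv, translation_deformation(dim3, affine,
                                                          c(0, 2, 0)))
  expect_equal(shifted$data[, 1:6, , , drop = FALSE],
               cv$data[, 2:7, , , drop = FALSE], tolerance = 1e-12)

  # a constant volume stays constant wherever the warp stays in bounds
  const <- color_volume(array(0.4, c(dim3, 1)), affine)
  wc <- warp_colorvolume(const, identity_deformation(dim3, affine))
  expect_true(all(abs(wc$data - 0.4) < 1e-12))

  expect_error(warp_colorvolume(cv, NULL), "deformation")
  expect_error(warp_colorvolume(out, identity_deformation(dim3, affine)),
               "template")
})

test_that("pull-back interpolation is exact for affine channels", {
  dim3 <- c(8, 8, 8)
  affine <- grid_affine(1.5, origin = c(2, -1, 0))
  centers <- spectre:::grid_centers(dim3, affine)
  coeff <- c(0.03, 0.05, 0.01)
  vals <- 1 + centers %*% coeff
  cv <- color_volume(array(vals, c(dim3, 1)), affine)
  set.seed(15)
  # random smooth in-bounds warp
  pert <- matrix(runif(prod(dim3) * 3, -0.6, 0.6), ncol = 3)
  lo <- c(2, -1, 0) + 0.05
  hi <- c(2, -1, 0) + (dim3 - 1) * 1.5 - 0.05
  m <- centers + pert
  for (a in 1:3) m[, a] <- pmin(pmax(m[, a], lo[a]), hi[a])
  mapping <- array(m, c(dim3, 3))
  warped <- warp_colorvolume(cv, deformation_field(mapping, affine))
  expected <- 1 + matrix(mapping, ncol = 3) %*% coeff
  expect_equal(as.vector(warped$data), as.vector(expected),
               tolerance = 1e-10)
})
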