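test_that("trilinear sampling is exact at centers, midpoints and on affine fields", {
  set.seed(41)
  dim3 <- c(5, 6, 4)
  affine <- grid_affine(c(1, 2, 2.5), origin = c(-2, 0, 1))
  cv <- color_volume(array(runif(prod(dim3) * 2), c(dim3, 2)), affine)
  centers <- spectre:::grid_centers(dim3, affine)
  # voxel centers: exact values
  vals <- trilinear_sample(cv, centers)
  expect_equal(vals, matrix(cv$data, ncol = 2), tolerance = 1e-12)
  # midpoint between two voxel centers along x: the arithmetic mean
  mid <- trilinear_sample(cv, c(-1.5, 0, 1))
  expect_equal(as.vector(mid),
               as.vector((cv$data[1, 1, 1, ] + cv$data[2, 1, 1, ]) / 2),
               tolerance = 1e-12)
  # out of bounds: zero
  expect_equal(as.vector(trilinear_sample(cv, c(100, 0, 0))), c(0, 0))

  # affine channel reproduced exactly at random interior points
  coeff <- c(0.02, -0.03, 0.05)
  lin <- color_volume(array(pmax(2 + centers %*% coeff, 0), c(dim3, 1)),
                      affine)
  stopifnot(all(2 + centers %*% coeff > 0))
  pts <- cbind(runif(50, -2, 2), runif(50, 0, 10), runif(50, 1, 8.5))
  expect_equal(as.vector(trilinear_sample(lin, pts)),
               as.vector(2 + pts %*% coeff), tolerance = 1e-10)
})

test_that("aggregation sums colors along streamlines without length normalization", {
  affine <- grid_affine(10, origin = c(0, 0, 0))
  const <- color_volume(array(rep(c(0.2, 0, 0), each = 4^3), c(4, 4, 4, 3)),
                        affine, space = "subject")
  mk <- function(pts) structure(pts, class = c("streamline", "matrix", "array"))
  b1 <- list(streamlines = list(mk(rbind(c(5, 5, 5), c(6, 5, 5),
                                         c(7, 5, 5)))))
  expect_equal(aggregate_seed(b1, const), c(0.6, 0, 0), tolerance = 1e-12)

  # two streamlines of lengths 2 and 4 in a unit red field: red = 6
  unitred <- color_volume(array(rep(c(1, 0, 0), each = 4^3), c(4, 4, 4, 3)),
                          affine, space = "subject")
  b2 <- list(streamlines = list(mk(rbind(c(5, 5, 5), c(6, 5, 5))),
                                mk(matrix(rep(c(8, 9, 10), 4), 4,
                                          byrow = TRUE))))
  expect_equal(aggregate_seed(b2, unitred), c(6, 0, 0), tolerance = 1e-12)

  # ramp c1 = y/100: points at y = 10, 20, 30 sum to 0.6
  ramp <- make_ramp_colorfield(c(4, 4, 4), affine, axis = 2, gain = 1 / 100)
  b3 <- list(streamlines = list(mk(rbind(c(15, 10, 15), c(15, 20, 15),
                                         c(15, 30, 15)))))
  expect_equal(aggregate_seed(b3, ramp), c(0.6, 0, 0), tolerance = 1e-12)

  expect_warning(z <- aggregate_seed(list(streamlines = list()), const),
                 "empty")
  expect_equal(z, c(0, 0, 0))
})

test_that("aggregation is linear in the color field", {
  set.seed(42)
  affine <- grid_affine(2)
  mk <- function(pts) structure(pts, class = c("streamline", "matrix", "array"))
  bundle <- list(streamlines = lapply(1:5, function(i)
    mk(matrix(runif(9, 0, 8), ncol = 3))))
  a <- array(runif(5^3 * 2), c(5, 5, 5, 2))
  b <- array(runif(5^3 * 2), c(5, 5, 5, 2))
  cva <- color_volume(a, affine, space = "subject")
  cvb <- color_volume(b, affine, space = "subject")
  cvab <- color_volume(a + 2 * b, affine, space = "subject")
  expect_equal(aggregate_seed(bundle, cvab),
               aggregate_seed(bundle, cva) + 2 * aggregate_seed(bundle, cvb),
               tolerance = 1e-10)
})

test_that("a one-voxel region map reproduces the per-seed aggregate", {
  spec <- phantom_spec(shape = c(9, 15, 9))
  tf <- make_tensor_phantom(spec)
  model <- direction_model(tf, "tend")
  params <- tracking_params(noise = 0.1, max_steps = 30, seed = 3)
  cv <- make_cap_colorfield(dim(tf$mask), tf$affine)

  mask <- array(FALSE, c(5, 5, 5))
  mask[3, 3, 3] <- TRUE
  region_affine <- grid_affine(2, origin = c(4, 10, 4))  # voxel (3,3,3) at center
  region <- target_region(mask, region_affine)
  map <- compute_spectre(region, model, cv, params, n_seeds = 20)

  key <- which(mask)
  center <- spectre:::voxel_to_world(c(2, 2, 2), region_affine)
  bundle <- seed_bundle(as.vector(center), 20, model, params,
                        jitter = 2, voxel_key = key)
  expect_equal(map$data[3, 3, 3, ], aggregate_seed(bundle, cv),
               tolerance = 1e-12)
  # voxels outside the region are absent, not zero
  expect_true(all(is.nan(map$data[1, 1, 1, ])))
  expect_false(map$normalized)
  expect_error(compute_spectre(region, model,
                               make_cap_colorfield(dim(tf$mask), tf$affine,
                                                   space = "template"),
                               params, n_seeds = 2),
               "subject")
})

test_that("mid-corridor seeds see a symmetric green:blue mixture", {
  spec <- phantom_spec(shape = c(11, 21, 11))
  tf <- make_tensor_phantom(spec)
  model <- direction_model(tf, "tend")
  params <- tracking_params(noise = 0.1, max_steps = 60, seed = 8)
  cv <- make_cap_colorfield(dim(tf$mask), tf$affine, axis = 2)
  ctr <- (dim(tf$mask) - 1) / 2 * spec$resolution
  # two seeds mirrored about the corridor midplane agree within
  # Monte-Carlo tolerance, and each is green:blue balanced
  up <- aggregate_seed(seed_bundle(ctr + c(0, 1, 0), 300, model, params,
                                   jitter = 1, voxel_key = 1L), cv)
  dn <- aggregate_seed(seed_bundle(ctr - c(0, 1, 0), 300, model, params,
                                   jitter = 1, voxel_key = 2L), cv)
  expect_lt(abs(up[2] / up[3] - dn[2] / dn[3]), 0.2)
  expect_lt(abs((up[2] + dn[2]) / (up[3] + dn[3]) - 1), 0.15)
})

test_that("display normalization divides by the 80th-percentile brightness and clips", {
  mask <- array(TRUE, c(10, 1, 1))
  map <- spectre:::new_spectre_map(array(1:10, c(10, 1, 1, 1)),
                                   grid_affine(1), mask, 1L, NULL)
  norm <- normalize_for_display(map)
  # type-7 80th percentile of 1..10 is 8.2; values above it clip to 1
  expect_equal(norm$data[5, 1, 1, 1], 5 / 8.2, tolerance = 1e-12)
  expect_equal(norm$data[10, 1, 1, 1], 1)
  expect_true(norm$normalized)
  expect_error(normalize_for_display(norm), "already")

  # a map already scaled to p80 = 1 only clips
  map2 <- spectre:::new_spectre_map(array(1:10 / 8.2, c(10, 1, 1, 1)),
                                    grid_affine(1), mask, 1L, NULL)
  norm2 <- normalize_for_display(map2)
  expect_equal(norm2$data, pmin(map2$data, 1), tolerance = 1e-12)

  # normalization is scale invariant
  map3 <- spectre:::new_spectre_map(map$data * 37.5, grid_affine(1), mask,
                                    1L, NULL)
  expect_equal(normalize_for_display(map3)$data, norm$data,
               tolerance = 1e-12)

  # for continuous brightness, ~80% of region voxels end up <= 1
  set.seed(44)
  n <- 1000
  rnd <- spectre:::new_spectre_map(array(runif(3 * n), c(n, 1, 1, 3)),
                                   grid_affine(1), array(TRUE, c(n, 1, 1)),
                                   1L, NULL)
  nrm <- normalize_for_display(rnd)
  frac <- mean(apply(nrm$data, 1, sum) <= 1 + 1e-12)
  expect_lt(abs(frac - 0.8), 0.02)

  zero <- spectre:::new_spectre_map(array(0, c(4, 1, 1, 1)), grid_affine(1),
                                    array(TRUE, c(4, 1, 1)), 1L, NULL)
  expect_error(normalize_for_display(zero), "zero")
})
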