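test_that("a uniform field with zero noise yields straight 1 mm-spaced lines", {
  tf <- const_tensor_field(shape = c(9, 21, 9), dir = c(0, 1, 0))
  model <- direction_model(tf, "tend")
  params <- tracking_params(noise = 0, max_steps = 5, seed = 7)
  seed <- c(4, 10, 4)
  sl <- propagate(seed, model, params)
  expect_equal(nrow(sl), 11L)
  steps <- diff(unclass(sl))
  expect_true(all(abs(sqrt(rowSums(steps^2)) - 1) < 1e-9))
  # collinearity: all points on the y axis through the seed
  expect_lt(max(abs(sl[, 1] - 4)), 1e-6)
  expect_lt(max(abs(sl[, 3] - 4)), 1e-6)
  expect_identical(unname(attr(sl, "termination")),
                   c("max_steps", "max_steps"))
})

test_that("the step-length invariant holds under stochastic perturbation", {
  tf <- const_tensor_field(shape = c(15, 15, 15), dir = c(1, 1, 0))
  model <- direction_model(tf, "tend")
  for (s in c(0.05, 0.2)) {
    sl <- propagate(c(7, 7, 7), model,
                    tracking_params(noise = s, max_steps = 50, seed = 31))
    steps <- diff(unclass(sl))
    expect_true(all(abs(sqrt(rowSums(steps^2)) - 1) < 1e-6))
  }
})

test_that("an abrupt 90-degree interface terminates DTI tracking by angle", {
  shape <- c(11, 21, 11)
  tf_lo <- const_tensor_field(shape, dir = c(0, 1, 0))
  tf_hi <- const_tensor_field(shape, dir = c(1, 0, 0))
  D <- tf_lo$D
  D[, 12:21, , ] <- tf_hi$D[, 12:21, , ]   # +x fibers for y >= 11 mm
  tf <- tensor_field(D, tf_lo$affine, mask = tf_lo$mask)
  model <- direction_model(tf, "dti")
  sl <- propagate(c(5, 5, 5), model,
                  tracking_params(noise = 0, max_steps = 100,
                                  angle_threshold = 60,
                                  interp = "nearest", seed = 1))
  expect_true("angle" %in% attr(sl, "termination"))
  expect_lt(max(sl[, 2]), 12)   # never crosses into the +x slab
})

test_that("TEND carries streamlines through an orthogonal crossing", {
  spec <- phantom_spec("crossing", shape = c(21, 21, 9))
  tf <- make_tensor_phantom(spec)
  model <- direction_model(tf, "tend")
  # seed on the x corridor, left of the crossing
  sl <- propagate(c(8, 20, 8), model,
                  tracking_params(noise = 0, max_steps = 30, seed = 1))
  ends <- unclass(sl)[c(1, nrow(sl)), ]
  # spans the crossing: endpoints on both sides of the center x = 20
  expect_lt(min(ends[, 1]), 12)
  expect_gt(max(ends[, 1]), 28)
  # exit direction within 5 degrees of the incoming +x axis
  last_step <- sl[nrow(sl), ] - sl[nrow(sl) - 1, ]
  last_step <- last_step / sqrt(sum(last_step^2))
  expect_lt(acos(abs(last_step[1])) * 180 / pi, 5)
})

test_that("tracking is equivariant under global rotation", {
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shape <- c(25, 25, 9)
  tf1 <- const_tensor_field(shape, dir = c(0, 1, 0))
  tf2 <- const_tensor_field(shape, dir = as.vector(R %*% c(0, 1, 0)))
  ctr <- c(12, 12, 4)
  p <- tracking_params(noise = 0, max_steps = 6, seed = 5)
  sl1 <- propagate(ctr, direction_model(tf1, "tend"), p)
  sl2 <- propagate(ctr, direction_model(tf2, "tend"), p)
  rotated <- t(R %*% t(sweep(unclass(sl1), 2, ctr))) + rep(ctr, each = nrow(sl1))
  expect_equal(unclass(sl2), rotated, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("tracking is deterministic and validates its seed", {
  spec <- phantom_spec()
  tf <- make_tensor_phantom(spec)
  model <- direction_model(tf, "tend")
  params <- tracking_params(noise = 0.1, max_steps = 40, seed = 99)
  ctr <- (dim(tf$mask) - 1) / 2 * spec$resolution
  expect_identical(propagate(ctr, model, params),
                   propagate(ctr, model, params))
  expect_error(propagate(c(-10, 0, 0), model, params), "outside")
  # isotropic background: degenerate seed stops immediately
  iso <- propagate(c(1, 1, 1), model,
                   tracking_params(noise = 0, fa_floor = 0, seed = 1))
  expect_equal(nrow(iso), 1L)
  expect_identical(unname(attr(iso, "termination"))[1],
                   "undefined_direction")
})

test_that("bundles are reproducible and confined to the corridor", {
  spec <- phantom_spec(shape = c(11, 21, 11))
  tf <- make_tensor_phantom(spec)
  model <- direction_model(tf, "tend")
  params <- tracking_params(noise = 0.05, max_steps = 60, seed = 17)

  ctr <- (dim(tf$mask) - 1) / 2 * spec$resolution
  b1 <- seed_bundle(ctr, 100, model, params, jitter = 1,
                    mask = tf$corridor, voxel_key = 3L)
  b2 <- seed_bundle(ctr, 100, model, params, jitter = 1,
                    mask = tf$corridor, voxel_key = 3L)
  expect_identical(b1$streamlines, b2$streamlines)
  expect_length(b1$streamlines, 100L)

  # with the mask restricted to the corridor, every streamline leaves
  # through the corridor (mask exit), not sideways through low FA
  terms <- t(vapply(b1$streamlines,
                    function(s) attr(s, "termination"), c("", "")))
  expect_true(all(terms == "mask_exit"))
  ends <- t(vapply(b1$streamlines, function(s)
    unclass(s)[c(1, nrow(s)), 2], c(0, 0)))
  # corridor runs the full y extent: exits happen near the two ends
  expect_true(all(pmin(ends[, 1], ends[, 2]) < 6))
  expect_true(all(pmax(ends[, 1], ends[, 2]) > 34))
})

test_that("a single-streamline bundle equals one propagate call", {
  tf <- const_tensor_field(shape = c(9, 15, 9))
  model <- direction_model(tf, "tend")
  params <- tracking_params(noise = 0.1, max_steps = 10, seed = 43)
  b <- seed_bundle(c(4, 7, 4), 1, model, params, jitter = 0,
                   voxel_key = 5L)
  set.seed(spectre:::derive_seed(43L, 5L, 1L))
  direct <- spectre:::propagate_core(c(4, 7, 4), model, params, tf)
  expect_identical(b$streamlines[[1]], direct)
})

test_that("custom direction models plug into the marcher", {
  tf <- const_tensor_field(shape = c(9, 15, 9), dir = c(0, 1, 0))
  # a custom rule that always proposes +y reproduces the straight line
  model <- direction_model(tf, "custom",
                           direction_fun = function(p, v) c(0, 1, 0))
  sl <- propagate(c(4, 7, 4), model,
                  tracking_params(noise = 0, max_steps = 4, seed = 1))
  expect_equal(nrow(sl), 9L)
  expect_lt(max(abs(sl[, 1] - 4)), 1e-9)
  # an always-undefined rule terminates immediately
  model2 <- direction_model(tf, "custom",
                            direction_fun = function(p, v) NULL)
  sl2 <- propagate(c(4, 7, 4), model2,
                   tracking_params(noise = 0, max_steps = 4, seed = 1))
  expect_equal(nrow(sl2), 1L)
})
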