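# Synthetic phantoms: tensor corridors of known geometry, ramp and
# end-cap color fields, and re-scan pairs with controlled perturbations.
# They stand in for real acquisitions so every pipeline stage can be
# validated against analytic ground truth, entirely in memory.

#' Phantom specification
#'
#' Describes a tensor phantom: an anisotropic corridor (straight, curved
#' or crossing) embedded in an isotropic background on a regular grid.
#' Defaults emulate a clinical 2 mm acquisition; `resolution = 1.25`
#' gives a high-quality-acquisition analogue. Corridor eigenvalues
#' default to (1.7, 0.3, 0.3) um^2/ms (FA ~ 0.80, typical coherent white
#' matter); the background is isotropic at 0.7 um^2/ms (FA = 0), so the
#' corridor sits far above and the background below any sensible
#' anisotropy floor.
#'
#' @param geometry `"straight"`, `"curved"` or `"crossing"`.
#' @param shape Grid shape (3 integers).
#' @param resolution Isotropic voxel size in mm (default 2).
#' @param corridor_radius Corridor tube radius in mm.
#' @param lambda Corridor tensor eigenvalues (axial, radial, radial) in
#'   mm^2/s.
#' @param iso_diffusivity Background isotropic diffusivity (mm^2/s).
#' @param angle Straight geometry only: in-plane rotation of the corridor
#'   axis away from +y, degrees.
#' @param offset World-space shift (mm) of the corridor relative to the
#'   grid center; length 3.
#' @param seed RNG seed attached to the phantom (used by re-scan noise).
#' @param rescan_noise Default relative perturbation level for
#'   [make_rescan_pair()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("straight", "curved", "crossing"),
                         shape = c(15, 25, 15), resolution = 2,
                         corridor_radius = 3,
                         lambda = c(1.7e-3, 0.3e-3, 0.3e-3),
                         iso_diffusivity = 0.7e-3,
                         angle = 0, offset = c(0, 0, 0),
                         seed = 1L, rescan_noise = 0.05) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 3L), resolution > 0,
            corridor_radius > 0, length(lambda) == 3L, all(lambda > 0),
            lambda[1L] > lambda[2L], iso_diffusivity > 0,
            length(offset) == 3L, rescan_noise >= 0)
  fa_corr <- fractional_anisotropy(diag(lambda))
  if (fa_corr <= 0.15)
    stop("corridor eigenvalues give FA <= 0.15; corridor must sit above ",
         "the tracking anisotropy floor", call. = FALSE)
  structure(list(geometry = geometry, shape = shape,
                 resolution = resolution,
                 corridor_radius = corridor_radius, lambda = lambda,
                 iso_diffusivity = iso_diffusivity, angle = angle,
                 offset = as.numeric(offset), seed = as.integer(seed),
                 rescan_noise = rescan_noise),
            class = "phantom_spec")
}

# Corridor direction and membership for each world point. Returns
# list(inside = logical n, dir = n x 3, inside2/dir2 for the second
# corridor of a crossing).
corridor_geometry <- function(spec, pts) {
  ctr <- (spec$shape - 1) / 2 * spec$resolution + spec$offset
  px <- pts[, 1L] - ctr[1L]; py <- pts[, 2L] - ctr[2L]
  pz <- pts[, 3L] - ctr[3L]
  switch(spec$geometry,
    straight = {
      th <- spec$angle * pi / 180
      ax <- c(sin(th), cos(th), 0)
      # distance from the line through the center along ax
      along <- px * ax[1L] + py * ax[2L]
      dx <- px - along * ax[1L]; dy <- py - along * ax[2L]
      r <- sqrt(dx^2 + dy^2 + pz^2)
      list(inside = r <= spec$corridor_radius,
           dir = matrix(ax, nrow(pts), 3L, byrow = TRUE))
    },
    curved = {
      # quarter-circle arc in the x-y plane around a point offset in -x/-y
      R <- (min(spec$shape[1:2]) - 1) / 2 * spec$resolution * 0.8
      cx <- px + R / sqrt(2); cy <- py + R / sqrt(2)
      rad <- sqrt(cx^2 + cy^2)
      ang <- atan2(cy, cx)
      inside <- abs(rad - R) <= spec$corridor_radius &
        abs(pz) <= spec$corridor_radius &
        ang >= 0 & ang <= pi / 2
      tx <- -cy / pmax(rad, 1e-12); ty <- cx / pmax(rad, 1e-12)
      list(inside = inside, dir = cbind(tx, ty, 0))
    },
    crossing = {
      rx <- sqrt(py^2 + pz^2)   # corridor along x
      ry <- sqrt(px^2 + pz^2)   # corridor along y
      list(inside = rx <= spec$corridor_radius,
           dir = matrix(c(1, 0, 0), nrow(pts), 3L, byrow = TRUE),
           inside2 = ry <= spec$corridor_radius,
           dir2 = matrix(c(0, 1, 0), nrow(pts), 3L, byrow = TRUE))
    })
}

# Anisotropic tensor (6-vector rows) with axial direction t per row.
cigar_tensor_rows <- function(dirs, lambda) {
  tx <- dirs[, 1L]; ty <- dirs[, 2L]; tz <- dirs[, 3L]
  dl <- lambda[1L] - lambda[2L]
  cbind(lambda[2L] + dl * tx * tx, dl * tx * ty, dl * tx * tz,
        lambda[2L] + dl * ty * ty, dl * ty * tz,
        lambda[2L] + dl * tz * tz)
}

#' Build a tensor phantom
#'
#' Straight: one anisotropic corridor (optionally tilted in-plane).
#' Curved: a quarter-circle corridor with tangent-aligned tensors.
#' Crossing: two orthogonal corridors; in the overlap the two tensors
#' are averaged, producing an oblate tensor with a degenerate leading
#' eigenspace (the tie-break path of the trackers). Background voxels
#' carry the isotropic tensor. The returned field's validity mask covers
#' the whole grid (the anisotropy floor, not the mask, stops tracking in
#' the background); the corridor membership is available as element
#' `corridor` for building seed regions.
#'
#' @param spec A [phantom_spec()].
#' @return A [tensor_field()] with an extra logical element `corridor`.
#' @export
make_tensor_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  affine <- grid_affine(spec$resolution)
  pts <- grid_centers(spec$shape, affine)
  geo <- corridor_geometry(spec, pts)
  if (!any(geo$inside))
    stop("corridor lies outside the phantom grid", call. = FALSE)
  n <- nrow(pts)
  iso <- c(spec$iso_diffusivity, 0, 0, spec$iso_diffusivity, 0,
           spec$iso_diffusivity)
  D <- matrix(iso, n, 6L, byrow = TRUE)
  D[geo$inside, ] <- cigar_tensor_rows(geo$dir[geo$inside, , drop = FALSE],
                                       spec$lambda)
  corridor <- geo$inside
  if (!is.null(geo$inside2)) {
    D2 <- cigar_tensor_rows(geo$dir2[geo$inside2, , drop = FALSE],
                            spec$lambda)
    both <- geo$inside & geo$inside2
    only2 <- geo$inside2 & !geo$inside
    D[only2, ] <- D2[match(which(only2), which(geo$inside2)), ]
    if (any(both))
      D[both, ] <- (D[both, , drop = FALSE] +
                    D2[match(which(both), which(geo$inside2)), ,
                       drop = FALSE]) / 2
    corridor <- corridor | geo$inside2
  }
  tf <- tensor_field(array(D, c(spec$shape, 6L)), affine,
                     mask = array(TRUE, spec$shape))
  tf$corridor <- array(corridor, spec$shape)
  tf
}

#' Ramp color field (affine in one world axis)
#'
#' One channel is a linear function of a world coordinate,
#' `c = gain * coordinate` (negative values clamped to 0); the other
#' channels are zero. Because trilinear interpolation reproduces affine
#' fields exactly, aggregation results on ramps have closed forms.
#'
#' @param dim3 Grid shape.
#' @param affine Voxel-to-world affine.
#' @param axis World axis (1, 2 or 3) the ramp runs along.
#' @param gain Slope in 1/mm.
#' @param channel Channel carrying the ramp (default 1).
#' @param n_channels Total number of channels (default 3).
#' @param space Space tag for the resulting volume (default subject).
#' @return A [color_volume()].
#' @export
make_ramp_colorfield <- function(dim3, affine, axis = 2, gain = 0.01,
                                 channel = 1, n_channels = 3,
                                 space = "subject") {
  stopifnot(is.finite(gain), axis %in% 1:3, channel <= n_channels)
  pts <- grid_centers(dim3, affine)
  vals <- matrix(0, nrow(pts), n_channels)
  vals[, channel] <- pmax(gain * pts[, axis], 0)
  color_volume(array(vals, c(dim3, n_channels)), affine, space = space)
}

#' Two-end cap color field
#'
#' Paints the low end of a world axis in one channel and the high end in
#' another (value 1 inside each cap, 0 elsewhere). Seeded mid-corridor,
#' a symmetric tracker should aggregate the two cap colors in a 1:1
#' ratio, which makes this field a ground truth for end-to-end symmetry
#' checks.
#'
#' @param dim3 Grid shape.
#' @param affine Voxel-to-world affine.
#' @param axis World axis of the corridor (default 2).
#' @param cap_fraction Fraction of the axis extent painted at each end.
#' @param low_channel,high_channel Channels for the low/high caps
#'   (defaults: blue = 3 low, green = 2 high).
#' @param n_channels Total channels.
#' @param space Space tag (default subject).
#' @return A [color_volume()].
#' @export
make_cap_colorfield <- function(dim3, affine, axis = 2, cap_fraction = 0.15,
                                low_channel = 3, high_channel = 2,
                                n_channels = 3, space = "subject") {
  stopifnot(cap_fraction > 0, cap_fraction < 0.5)
  pts <- grid_centers(dim3, affine)
  x <- pts[, axis]
  lo <- min(x); hi <- max(x); span <- hi - lo
  vals <- matrix(0, nrow(pts), n_channels)
  vals[x <= lo + cap_fraction * span, low_channel] <- 1
  vals[x >= hi - cap_fraction * span, high_channel] <- 1
  color_volume(array(vals, c(dim3, n_channels)), affine, space = space)
}

#' Generate a re-scan pair of tensor fields
#'
#' Scan 1 is the input field; scan 2 adds independent symmetric
#' perturbations to the tensor components (Gaussian, standard deviation
#' `noise` times the field's largest absolute component) and re-projects
#' each perturbed tensor onto the positive semi-definite cone by
#' clamping negative eigenvalues. Perturbing tensors directly isolates
#' tracking-and-aggregation reproducibility from fitting noise; for
#' fitting tests use [simulate_dwi()] with Rician noise instead.
#'
#' @param tensors A [tensor_field()].
#' @param noise Relative perturbation level (>= 0).
#' @param seed RNG seed; defaults to 1.
#' @return List of two [tensor_field()]s, `scan1` and `scan2`, on the
#'   same grid.
#' @export
make_rescan_pair <- function(tensors, noise, seed = 1L) {
  stopifnot(inherits(tensors, "tensor_field"), noise >= 0)
  scan1 <- tensors
  if (noise == 0) return(list(scan1 = scan1, scan2 = tensors))
  set.seed(as.integer(seed))
  d <- dim(tensors$D)
  scale <- noise * max(abs(tensors$D))
  pert <- array(rnorm(prod(d), sd = scale), d)
  D2 <- tensors$D + pert
  n <- prod(d[1:3])
  M <- matrix(D2, n, 6L)
  M <- t(apply(M, 1L, function(d6) {
    e <- eigen(tensor_matrix(d6), symmetric = TRUE)
    if (all(e$values >= 0)) return(d6)
    tensor_vec(e$vectors %*% (pmax(e$values, 0) * t(e$vectors)))
  }))
  scan2 <- tensor_field(array(M, d), tensors$affine, mask = tensors$mask)
  scan2$corridor <- tensors$corridor
  list(scan1 = scan1, scan2 = scan2)
}

#' Simulate a diffusion-weighted acquisition from a tensor field
#'
#' Forward model `S = S0 exp(-b g' D g)`, optionally with Rician noise
#' (magnitude of the complex signal plus Gaussian noise in both
#' channels). Intended for validating the tensor fitting route.
#'
#' @param tensors A [tensor_field()].
#' @param bvals,bvecs Acquisition scheme (see [fit_tensors()]).
#' @param s0 Non-diffusion-weighted signal level.
#' @param rician_sigma Noise standard deviation (0 = noiseless).
#' @param seed RNG seed used when noise is added.
#' @return A 4D signal array matching the scheme.
#' @export
simulate_dwi <- function(tensors, bvals, bvecs, s0 = 100,
                         rician_sigma = 0, seed = 1L) {
  stopifnot(inherits(tensors, "tensor_field"))
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  d <- dim(tensors$D)
  n <- prod(d[1:3])
  Dm <- matrix(tensors$D, n, 6L)
  gx <- bvecs[, 1L]; gy <- bvecs[, 2L]; gz <- bvecs[, 3L]
  # g' D g per (voxel, volume)
  quad <- Dm[, 1L] %o% (gx * gx) + Dm[, 4L] %o% (gy * gy) +
          Dm[, 6L] %o% (gz * gz) + 2 * Dm[, 2L] %o% (gx * gy) +
          2 * Dm[, 3L] %o% (gx * gz) + 2 * Dm[, 5L] %o% (gy * gz)
  S <- s0 * exp(-sweep(quad, 2L, bvals, "*"))
  if (rician_sigma > 0) {
    set.seed(as.integer(seed))
    S <- sqrt((S + rnorm(length(S), sd = rician_sigma))^2 +
              rnorm(length(S), sd = rician_sigma)^2)
  }
  array(S, c(d[1:3], length(bvals)))
}

# A small fixed gradient scheme for simulations: 6 optimal directions
# (icosahedral) plus optional repeats, and nb0 b=0 volumes.
default_scheme <- function(b = 1000, nb0 = 1L, repeats = 1L) {
  phi <- (1 + sqrt(5)) / 2
  dirs <- rbind(c(1, phi, 0), c(-1, phi, 0), c(0, 1, phi),
                c(0, -1, phi), c(phi, 0, 1), c(-phi, 0, 1))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dirs <- dirs[rep(seq_len(6L), repeats), , drop = FALSE]
  bvecs <- rbind(matrix(0, nb0, 3L), dirs)
  bvals <- c(rep(0, nb0), rep(b, nrow(dirs)))
  list(bvals = bvals, bvecs = bvecs)
}
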