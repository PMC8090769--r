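# Core volume containers and geometry helpers.
#
# Conventions used throughout the package:
#  * world coordinates are mm in the right-handed space defined by each
#    volume's 4x4 voxel-to-world affine;
#  * voxel indices are 0-based in formulas, so the world position of the
#    R array element [i, j, k] is affine %*% c(i - 1, j - 1, k - 1, 1);
#  * grid axes must be orthogonal in world space (rotation * scale +
#    translation); sheared affines are rejected everywhere.

#' Validate a voxel-to-world affine
#'
#' Checks that `affine` is a finite 4x4 matrix whose last row is
#' `(0, 0, 0, 1)`, whose linear part is invertible and whose columns are
#' mutually orthogonal in world space (i.e. the grid decomposes into
#' rotation * scale plus translation). Sheared grids are rejected.
#'
#' @param affine A 4x4 numeric matrix.
#' @return The affine, invisibly, if valid; otherwise an error is thrown.
#' @keywords internal
validate_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
      !all(is.finite(affine)))
    stop("affine must be a finite 4x4 numeric matrix", call. = FALSE)
  if (!isTRUE(all.equal(affine[4L, ], c(0, 0, 0, 1), tolerance = 1e-8)))
    stop("affine last row must be (0, 0, 0, 1)", call. = FALSE)
  M <- affine[1:3, 1:3]
  G <- crossprod(M)
  if (abs(det(M)) < .Machine$double.eps)
    stop("affine linear part is singular", call. = FALSE)
  off <- G - diag(diag(G))
  if (max(abs(off)) > 1e-6 * max(diag(G)))
    stop("grid axes are not orthogonal in world space (sheared affine)",
         call. = FALSE)
  invisible(affine)
}

#' Build a simple axis-aligned affine
#'
#' Convenience constructor for an axis-aligned voxel-to-world affine with
#' isotropic or per-axis voxel sizes and a world origin at voxel
#' `(0, 0, 0)`.
#'
#' @param spacing Voxel edge length(s) in mm; length 1 or 3.
#' @param origin World position (mm) of the first voxel's center.
#' @return A 4x4 affine matrix.
#' @export
#' @examples
#' grid_affine(2, origin = c(-10, -10, 0))
grid_affine <- function(spacing = 1, origin = c(0, 0, 0)) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(is.finite(spacing)), all(spacing > 0),
            length(origin) == 3L, all(is.finite(origin)))
  affine <- diag(c(spacing, 1))
  affine[1:3, 4L] <- origin
  affine
}

#' Convert world coordinates to continuous 0-based voxel coordinates
#' @param points An n x 3 matrix (or length-3 vector) of world mm positions.
#' @param affine Voxel-to-world affine.
#' @return An n x 3 matrix of continuous 0-based voxel coordinates.
#' @keywords internal
world_to_voxel <- function(points, affine) {
  pts <- as_points(points)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4L])
}

#' Convert 0-based voxel coordinates to world coordinates
#' @inheritParams world_to_voxel
#' @param voxels An n x 3 matrix of (possibly fractional) 0-based indices.
#' @keywords internal
voxel_to_world <- function(voxels, affine) {
  v <- as_points(voxels)
  t(affine[1:3, 1:3] %*% t(v) + affine[1:3, 4L])
}

# Coerce a length-3 vector or n x 3 matrix to an n x 3 double matrix.
as_points <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("a point must have 3 coordinates",
                                   call. = FALSE)
    points <- matrix(as.numeric(points), nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix", call. = FALSE)
  storage.mode(points) <- "double"
  points
}

# World coordinates of every voxel center of a 3D grid, in array order
# (first index fastest). Returns an (nx*ny*nz) x 3 matrix.
grid_centers <- function(dim3, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(dim3[1L]) - 1,
                               j = seq_len(dim3[2L]) - 1,
                               k = seq_len(dim3[3L]) - 1))
  voxel_to_world(idx, affine)
}

#' Multi-channel color volume
#'
#' A K-channel scalar field on a regular 3D grid with a voxel-to-world
#' affine. This is the container for the template color gradient and for
#' its subject-space warp; channel values are unitless color weights,
#' nominally in `[0, 1]` but not clipped.
#'
#' @param data A 3D (single channel) or 4D `(x, y, z, channel)` numeric
#'   array; all values must be finite and non-negative.
#' @param affine 4x4 voxel-to-world affine (mm); axes must be orthogonal.
#' @param space Either `"template"` or `"subject"`; records which space the
#'   grid lives in so that warping direction errors are caught early.
#' @return An object of class `color_volume` with elements `data` (4D
#'   array), `affine` and `space`.
#' @export
#' @examples
#' cv <- color_volume(array(0.5, c(4, 4, 4, 3)), grid_affine(1))
#' dim(cv$data)
color_volume <- function(data, affine, space = c("template", "subject")) {
  space <- match.arg(space)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("color volume data must be a 3D or 4D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("color volume values must all be finite", call. = FALSE)
  if (any(data < 0))
    stop("color volume values must be non-negative", call. = FALSE)
  validate_affine(affine)
  structure(list(data = data, affine = affine, space = space),
            class = "color_volume")
}

#' @export
print.color_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<color_volume> %d x %d x %d grid, %d channel(s), %s space\n",
              d[1L], d[2L], d[3L], d[4L], x$space))
  invisible(x)
}

#' Dense deformation field (template coordinates per subject voxel)
#'
#' Represents a diffeomorphic template-to-subject mapping as a pull-back
#' lookup: for every voxel of the subject grid it stores the absolute
#' template-space coordinate (mm) whose content should be sampled there.
#' An absolute-coordinate field (rather than a displacement field) matches
#' the "sample template content at each subject voxel" semantics directly
#' and avoids displacement-convention ambiguity.
#'
#' @param mapping A 4D `(x, y, z, 3)` array of template-space mm coordinates.
#' @param affine Voxel-to-world affine of the *subject* grid.
#' @return An object of class `deformation_field`.
#' @seealso [identity_deformation()], [warp_colorvolume()]
#' @export
deformation_field <- function(mapping, affine) {
  d <- dim(mapping)
  if (length(d) != 4L || d[4L] != 3L)
    stop("deformation mapping must be an (x, y, z, 3) array", call. = FALSE)
  if (!all(is.finite(mapping)))
    stop("deformation vector components must be finite", call. = FALSE)
  validate_affine(affine)
  structure(list(mapping = mapping, affine = affine),
            class = "deformation_field")
}

#' Identity deformation on a given subject grid
#'
#' Maps every subject voxel to its own world coordinate, so warping with it
#' is a plain resampling. Useful for phantoms and for pipelines where
#' template and subject space coincide by construction.
#'
#' @param dim3 Grid shape (3 integers).
#' @param affine Voxel-to-world affine of the subject grid.
#' @return A [deformation_field()].
#' @export
identity_deformation <- function(dim3, affine) {
  centers <- grid_centers(dim3, affine)
  deformation_field(array(centers, c(dim3, 3L)), affine)
}

#' Translation deformation (sample template at an offset)
#'
#' Every subject voxel maps to its own world coordinate plus `shift`,
#' i.e. the warped image is the template translated by `-shift`.
#'
#' @param dim3 Grid shape.
#' @param affine Subject-grid affine.
#' @param shift Length-3 world-space offset in mm.
#' @return A [deformation_field()].
#' @export
translation_deformation <- function(dim3, affine, shift) {
  stopifnot(length(shift) == 3L, all(is.finite(shift)))
  centers <- grid_centers(dim3, affine)
  centers <- sweep(centers, 2L, as.numeric(shift), "+")
  deformation_field(array(centers, c(dim3, 3L)), affine)
}

#' Trilinearly sample a color volume at world positions
#'
#' Channel-wise trilinear interpolation: each point is mapped through the
#' inverse affine into continuous voxel coordinates and interpolated from
#' the 8 surrounding voxel centers. Points outside the convex hull of
#' voxel centers return 0 in every channel (out-of-bounds content carries
#' no meaning for the aggregation).
#'
#' @param cv A [color_volume()] (or any object with `data` and `affine`).
#' @param points n x 3 matrix (or length-3 vector) of world mm positions;
#'   must be finite.
#' @return An n x K matrix of interpolated channel values.
#' @export
#' @examples
#' cv <- color_volume(array(seq_len(8), c(2, 2, 2, 1)), grid_affine(1))
#' trilinear_sample(cv, c(0.5, 0, 0))  # mean of voxels 1 and 2
trilinear_sample <- function(cv, points) {
  pts <- as_points(points)
  if (!all(is.finite(pts)))
    stop("sample points must be finite", call. = FALSE)
  data <- cv$data
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]; K <- d[4L]
  nvox <- nx * ny * nz
  v <- world_to_voxel(pts, cv$affine)
  n <- nrow(v)
  out <- matrix(0, n, K)

  # snap coordinates within rounding error of the boundary onto it, so
  # that voxel centers on the last plane are not lost to float noise
  tol <- 1e-6
  for (a in 1:3) {
    na <- d[a]
    v[, a][v[, a] < 0 & v[, a] > -tol] <- 0
    v[, a][v[, a] > na - 1 & v[, a] < na - 1 + tol] <- na - 1
  }
  inb <- v[, 1L] >= 0 & v[, 1L] <= nx - 1 &
         v[, 2L] >= 0 & v[, 2L] <= ny - 1 &
         v[, 3L] >= 0 & v[, 3L] <= nz - 1
  if (!any(inb)) return(out)
  vv <- v[inb, , drop = FALSE]
  # lower corner, clamped so the upper corner stays in range when a
  # coordinate sits exactly on the last voxel center
  x0 <- pmin(floor(vv[, 1L]), nx - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(vv[, 2L]), ny - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(vv[, 3L]), nz - 2); z0 <- pmax(z0, 0)
  fx <- vv[, 1L] - x0; fy <- vv[, 2L] - y0; fz <- vv[, 3L] - z0
  if (nx == 1L) { x0 <- rep(0, nrow(vv)); fx <- rep(0, nrow(vv)) }
  if (ny == 1L) { y0 <- rep(0, nrow(vv)); fy <- rep(0, nrow(vv)) }
  if (nz == 1L) { z0 <- rep(0, nrow(vv)); fz <- rep(0, nrow(vv)) }

  acc <- matrix(0, nrow(vv), K)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fx else 1 - fx) *
         (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    xi <- pmin(x0 + dx, nx - 1); yi <- pmin(y0 + dy, ny - 1)
    zi <- pmin(z0 + dz, nz - 1)
    base <- 1 + xi + nx * (yi + ny * zi)
    for (k in seq_len(K))
      acc[, k] <- acc[, k] + w * data[base + (k - 1) * nvox]
  }
  out[inb, ] <- acc
  out
}
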