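# Template-space color gradient: a sum of three isotropic Gaussians, each
# feeding its own color channel, defined in template (MNI) coordinates and
# warped to subject space by a dense deformation field.

#' Gradient specification: three Gaussian color sources
#'
#' The template color field is
#' \deqn{c(r) = \sum_{i=1}^{3} a_i \exp(-|r_i - r|^2 / (2\sigma^2))}
#' where each `a_i` is a K-vector of non-negative channel amplitudes,
#' `r_i` a template-space center (mm) and `sigma` a shared width (mm).
#'
#' @param amplitudes 3 x K matrix; row i is the amplitude vector `a_i`
#'   (unitless color weights, all components >= 0).
#' @param centers 3 x 3 matrix; row i is the center `r_i` in template mm.
#' @param sigma Gaussian width in mm; must be positive.
#' @return An object of class `gradient_spec`.
#' @seealso [default_gradient_spec()] for the shipped fronto-occipital
#'   scheme, [evaluate_gradient()], [rasterize_gradient()].
#' @export
gradient_spec <- function(amplitudes, centers, sigma) {
  amplitudes <- as.matrix(amplitudes)
  centers <- as.matrix(centers)
  if (nrow(amplitudes) != 3L || nrow(centers) != 3L || ncol(centers) != 3L)
    stop("a gradient spec has exactly three (amplitude, center) pairs",
         call. = FALSE)
  if (!all(is.finite(amplitudes)) || any(amplitudes < 0))
    stop("amplitude components must be finite and >= 0", call. = FALSE)
  if (!all(is.finite(centers)))
    stop("centers must be finite", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a single positive number (mm)", call. = FALSE)
  structure(list(amplitudes = amplitudes, centers = centers,
                 sigma = as.numeric(sigma)),
            class = "gradient_spec")
}

#' The shipped fronto-occipital color gradient
#'
#' Returns the three-Gaussian RGB scheme used for deep-brain-stimulation
#' oriented coloring of the cortex: a red source over the occipital/
#' superior-parietal region at (0, -60, 70), a green source over the
#' frontal pole at (0, 70, 0) and a blue source over sensorimotor regions
#' at (0, 20, 70), all with a 50 mm width. Streamlines reaching frontal
#' cortex therefore pick up green, motor pathways blue and posterior
#' pathways red.
#'
#' @return A [gradient_spec()] with K = 3 channels.
#' @export
#' @examples
#' evaluate_gradient(default_gradient_spec(), c(0, -60, 70))
default_gradient_spec <- function() {
  gradient_spec(
    amplitudes = rbind(c(0.5, 0, 0),
                       c(0,   1, 0),
                       c(0,   0, 1)),
    centers    = rbind(c(0, -60, 70),
                       c(0,  70,  0),
                       c(0,  20, 70)),
    sigma = 50)
}

#' Evaluate the color gradient at template coordinates
#'
#' Computes the channel-wise Gaussian sum at each point; no normalization
#' is applied.
#'
#' @param spec A [gradient_spec()].
#' @param points n x 3 matrix (or length-3 vector) of template mm
#'   coordinates; must be finite.
#' @return An n x K matrix of channel values.
#' @export
evaluate_gradient <- function(spec, points) {
  stopifnot(inherits(spec, "gradient_spec"))
  pts <- as_points(points)
  if (!all(is.finite(pts)))
    stop("gradient evaluation points must be finite", call. = FALSE)
  K <- ncol(spec$amplitudes)
  out <- matrix(0, nrow(pts), K)
  denom <- 2 * spec$sigma^2
  for (i in 1:3) {
    d2 <- (pts[, 1L] - spec$centers[i, 1L])^2 +
          (pts[, 2L] - spec$centers[i, 2L])^2 +
          (pts[, 3L] - spec$centers[i, 3L])^2
    out <- out + exp(-d2 / denom) %o% spec$amplitudes[i, ]
  }
  out
}

#' Rasterize the color gradient onto a template grid
#'
#' Evaluates the gradient at every voxel center of the requested grid and
#' returns a template-space [color_volume()]. The template grid resolution
#' is free; 1 mm isotropic is a sensible default for MNI-space work.
#'
#' @param spec A [gradient_spec()].
#' @param dim3 Grid shape (3 positive integers).
#' @param affine Voxel-to-world affine of the template grid.
#' @return A [color_volume()] tagged `template`.
#' @export
rasterize_gradient <- function(spec, dim3, affine) {
  stopifnot(inherits(spec, "gradient_spec"))
  dim3 <- as.integer(dim3)
  if (length(dim3) != 3L || any(dim3 < 1L))
    stop("grid shape must be 3 positive integers", call. = FALSE)
  validate_affine(affine)
  vals <- evaluate_gradient(spec, grid_centers(dim3, affine))
  color_volume(array(vals, c(dim3, ncol(vals))), affine, space = "template")
}

#' Restrict a color volume to a binary mask
#'
#' Zeroes every channel outside the mask and leaves values inside
#' untouched. Used to confine the coloring to gray matter, white matter
#' or a lobe (e.g. prefrontal-only coloring for internal-capsule targets).
#' The mask must live on exactly the color grid; no implicit resampling.
#'
#' @param cv A [color_volume()].
#' @param mask Logical/0-1 array with the color volume's 3D shape.
#' @return The masked [color_volume()].
#' @export
restrict_to_mask <- function(cv, mask) {
  stopifnot(inherits(cv, "color_volume"))
  d <- dim(cv$data)
  if (is.null(dim(mask)) || !all(dim(mask)[1:3] == d[1:3]) ||
      length(dim(mask)) != 3L)
    stop("mask geometry must equal the color volume geometry ",
         "(no implicit resampling)", call. = FALSE)
  m <- array(as.numeric(mask != 0), d[1:3])
  cv$data <- cv$data * as.vector(m)  # recycles over channels
  cv
}

#' Warp a template color volume into subject space
#'
#' Pull-back resampling: for each voxel of the subject grid, the template
#' color volume is sampled by trilinear interpolation at the template
#' coordinate stored in the deformation field. Template positions outside
#' the template volume contribute 0. The result is tagged `subject`.
#'
#' A deformation field is always required; subject and template grids are
#' never silently assumed to coincide (use [identity_deformation()] to make
#' that choice explicit).
#'
#' @param cv_template A [color_volume()] tagged `template`.
#' @param warp A [deformation_field()] on the subject grid.
#' @return A subject-space [color_volume()].
#' @export
warp_colorvolume <- function(cv_template, warp) {
  stopifnot(inherits(cv_template, "color_volume"))
  if (missing(warp) || is.null(warp))
    stop("a deformation field is required; identity is never assumed",
         call. = FALSE)
  stopifnot(inherits(warp, "deformation_field"))
  if (!identical(cv_template$space, "template"))
    stop("warp_colorvolume expects a template-space color volume",
         call. = FALSE)
  d <- dim(warp$mapping)
  pts <- matrix(warp$mapping, ncol = 3L)
  vals <- trilinear_sample(cv_template, pts)
  color_volume(array(vals, c(d[1:3], ncol(vals))), warp$affine,
               space = "subject")
}
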