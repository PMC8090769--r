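# Diffusion tensor container, log-linear tensor fitting and the local
# direction rules (principal eigenvector, tensor deflection).

# 6-component tensor storage order, used for arrays and NIfTI export:
# (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) -- row-major upper triangle.
TENSOR_COMPONENTS <- c("xx", "xy", "xz", "yy", "yz", "zz")

#' Per-voxel diffusion tensor field
#'
#' @param D A 4D `(x, y, z, 6)` array of tensor components in the order
#'   `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)` (mm^2/s; the overall scale is
#'   irrelevant to tracking).
#' @param affine Voxel-to-world affine of the tensor grid.
#' @param mask Optional logical array of valid voxels; defaults to voxels
#'   with a non-zero tensor.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(D, affine, mask = NULL) {
  d <- dim(D)
  if (length(d) != 4L || d[4L] != 6L)
    stop("tensor data must be an (x, y, z, 6) array", call. = FALSE)
  if (!all(is.finite(D)))
    stop("tensor components must be finite", call. = FALSE)
  validate_affine(affine)
  if (is.null(mask)) {
    mask <- apply(abs(D), 1:3, sum) > 0
  }
  if (!all(dim(mask) == d[1:3]))
    stop("mask shape must match the tensor grid", call. = FALSE)
  mask <- array(mask != 0, d[1:3])
  structure(list(D = D, affine = affine, mask = mask), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("<tensor_field> %d x %d x %d grid, %d voxels in mask\n",
              d[1L], d[2L], d[3L], sum(x$mask)))
  invisible(x)
}

# 3x3 symmetric matrix from a 6-vector in package component order.
tensor_matrix <- function(d6) {
  matrix(c(d6[1L], d6[2L], d6[3L],
           d6[2L], d6[4L], d6[5L],
           d6[3L], d6[5L], d6[6L]), 3L, 3L)
}

# Inverse of tensor_matrix.
tensor_vec <- function(D) {
  c(D[1L, 1L], D[1L, 2L], D[1L, 3L], D[2L, 2L], D[2L, 3L], D[3L, 3L])
}

#' Fractional anisotropy of a diffusion tensor
#'
#' @param D A 3x3 symmetric tensor or a 6-vector in package order.
#' @return FA in `[0, 1]`; 0 for a zero tensor.
#' @export
fractional_anisotropy <- function(D) {
  if (length(D) == 6L) D <- tensor_matrix(D)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  ss <- sum(ev^2)
  if (ss <= 0) return(0)
  lm <- mean(ev)
  sqrt(1.5 * sum((ev - lm)^2) / ss)
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Standard unweighted ordinary-least-squares fit of the log signal,
#' `log S = log S0 - b g' D g`, solved jointly for all voxels. After the
#' fit, negative eigenvalues are clamped to zero (tensors must stay
#' positive semi-definite for deflection tracking) and the validity mask
#' keeps voxels whose mean b=0 signal is positive.
#'
#' @param dwi 4D `(x, y, z, volume)` array of diffusion-weighted signals.
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x n or n x 3 matrix of gradient directions (unit
#'   vectors; the b=0 rows may be zero).
#' @param affine Voxel-to-world affine of the DWI grid.
#' @return A [tensor_field()].
#' @export
fit_tensors <- function(dwi, bvals, bvecs, affine = diag(4)) {
  d <- dim(dwi)
  if (length(d) != 4L)
    stop("dwi must be a 4D (x, y, z, volume) array", call. = FALSE)
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (length(bvals) != d[4L] || nrow(bvecs) != d[4L])
    stop("bvals/bvecs must have one entry per DWI volume", call. = FALSE)
  b0 <- bvals <= max(bvals) * 1e-3 | bvals == 0
  ndir <- length(unique(apply(round(bvecs[!b0, , drop = FALSE], 6), 1,
                              paste, collapse = ",")))
  if (sum(!b0) < 6L || ndir < 6L)
    stop("tensor fitting needs at least 6 distinct non-zero-b directions",
         call. = FALSE)
  if (sum(b0) < 1L)
    stop("tensor fitting needs at least one b=0 volume", call. = FALSE)
  validate_affine(affine)

  gx <- bvecs[, 1L]; gy <- bvecs[, 2L]; gz <- bvecs[, 3L]
  X <- cbind(1,
             -bvals * gx * gx, -2 * bvals * gx * gy, -2 * bvals * gx * gz,
             -bvals * gy * gy, -2 * bvals * gy * gz, -bvals * gz * gz)

  nvox <- prod(d[1:3])
  S <- matrix(dwi, nrow = nvox, ncol = d[4L])
  s0 <- rowMeans(S[, b0, drop = FALSE])
  mask_v <- s0 > 0 & apply(S, 1L, function(r) all(is.finite(r)))

  Dv <- matrix(0, nvox, 6L)
  if (any(mask_v)) {
    Y <- t(log(pmax(S[mask_v, , drop = FALSE], .Machine$double.xmin)))
    beta <- qr.solve(X, Y)              # 7 x n_masked
    Dfit <- t(beta[2:7, , drop = FALSE])
    # clamp negative eigenvalues voxel-wise
    Dv[mask_v, ] <- t(apply(Dfit, 1L, function(d6) {
      e <- eigen(tensor_matrix(d6), symmetric = TRUE)
      if (all(e$values >= 0)) return(d6)
      lam <- pmax(e$values, 0)
      tensor_vec(e$vectors %*% (lam * t(e$vectors)))
    }))
  }
  tensor_field(array(Dv, c(d[1:3], 6L)), affine,
               mask = array(mask_v, d[1:3]))
}

#' Principal diffusion direction of a tensor
#'
#' Unit eigenvector of the largest eigenvalue, sign-aligned with an
#' incoming direction when one is given (otherwise the component of
#' largest magnitude is made positive, a deterministic convention).
#' When the two leading eigenvalues are indistinguishable
#' (`lambda1 - lambda2 < 1e-9 * trace`) the leading eigenspace is
#' degenerate: the result carries `attr(, "degenerate") = TRUE` and, if an
#' incoming direction was supplied, that direction is returned unchanged
#' so that propagation degrades gracefully.
#'
#' @param D 3x3 symmetric tensor (or 6-vector in package order).
#' @param v_in Optional incoming unit direction for sign alignment.
#' @return A unit 3-vector with a logical `degenerate` attribute.
#' @export
principal_direction <- function(D, v_in = NULL) {
  if (length(D) == 6L) D <- tensor_matrix(D)
  e <- eigen(D, symmetric = TRUE)
  degenerate <- (e$values[1L] - e$values[2L]) <
    1e-9 * max(sum(diag(D)), .Machine$double.xmin) ||
    sum(diag(D)) <= 0
  if (degenerate && !is.null(v_in))
    return(structure(v_in / sqrt(sum(v_in^2)), degenerate = TRUE))
  v <- e$vectors[, 1L]
  if (!is.null(v_in)) {
    if (sum(v * v_in) < 0) v <- -v
  } else if (v[which.max(abs(v))] < 0) {
    v <- -v
  }
  structure(v, degenerate = degenerate)
}

#' Tensor deflection (TEND) of an incoming direction
#'
#' Deflects the incoming unit direction by the local tensor:
#' `v_out = normalize(D v_in)`, sign-flipped so `v_out . v_in >= 0`.
#' An isotropic tensor leaves the direction unchanged; for `|D v_in| = 0`
#' the propagation direction is undefined and `NULL` is returned (the
#' tracker terminates there).
#'
#' @param v_in Unit 3-vector.
#' @param D 3x3 symmetric positive semi-definite tensor (or 6-vector).
#' @return A unit 3-vector, or `NULL` when the deflected direction is
#'   undefined.
#' @export
#' @examples
#' tend_step(c(1, 1, 0) / sqrt(2), diag(c(4, 1, 1)))  # (4,1,0)/sqrt(17)
tend_step <- function(v_in, D) {
  if (length(D) == 6L) D <- tensor_matrix(D)
  stopifnot(abs(sum(v_in^2) - 1) < 1e-6)
  w <- as.vector(D %*% v_in)
  nw <- sqrt(sum(w^2))
  if (!is.finite(nw) || nw <= sum(abs(D)) * 1e-14 || nw == 0) return(NULL)
  w <- w / nw
  if (sum(w * v_in) < 0) w <- -w
  w
}

#' Stochastically perturb a propagation direction
#'
#' Adds isotropic Gaussian noise scaled by the noise factor `s` and
#' renormalizes: `normalize(v + s * eps)` with `eps ~ N(0, I3)`. With
#' `s = 0` the direction is returned unchanged. Draws come from R's
#' global random number generator, so results are reproducible under
#' `set.seed()`.
#'
#' @param v Unit 3-vector.
#' @param s Non-negative noise factor (unitless).
#' @return A unit 3-vector.
#' @export
perturb_direction <- function(v, s) {
  stopifnot(s >= 0, abs(sum(v^2) - 1) < 1e-6)
  if (s == 0) return(v)
  repeat {
    w <- v + s * rnorm(3L)
    nw <- sqrt(sum(w^2))
    if (nw > 0) return(w / nw)  # zero norm has probability zero; retry
  }
}
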