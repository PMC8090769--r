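# Streamline propagation: parameter container, direction models and the
# bidirectional marcher. The DTI/TEND hot path runs in compiled code; a
# plug-in direction model (an R function of position and incoming
# direction) runs through an equivalent R loop so externally supplied
# peak/FOD fields can be used without recompiling.

TERM_LABELS <- c("running", "mask_exit", "max_steps", "angle", "low_fa",
                 "undefined_direction", "invalid_seed")

term_reason <- function(code) TERM_LABELS[code + 1L]

#' Tracking parameters
#'
#' @param step Step size `alpha` in mm (default 1 mm, appropriate for
#'   typical 1.25-2 mm diffusion acquisitions).
#' @param noise Noise factor `s` perturbing the propagation direction;
#'   useful values lie around 0.05 (near-deterministic) to 0.2 (strongly
#'   dispersed). Default 0.1.
#' @param max_steps Maximum number of steps per half-streamline.
#' @param angle_threshold Maximum turning angle per step, degrees.
#' @param fa_floor Anisotropy floor: propagation stops where fractional
#'   anisotropy falls below this value.
#' @param seed Optional integer seed for the random number generator; when
#'   set, tracking is fully reproducible (per-seed-voxel, per-streamline
#'   substreams are derived from it).
#' @param interp Tensor interpolation along the march: component-wise
#'   `"trilinear"` (default, smooth deflection) or `"nearest"`.
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(step = 1, noise = 0.1, max_steps = 250,
                            angle_threshold = 60, fa_floor = 0.1,
                            seed = NULL,
                            interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(is.numeric(step), length(step) == 1L, is.finite(step), step > 0,
            is.numeric(noise), length(noise) == 1L, noise >= 0,
            max_steps >= 1,
            angle_threshold > 0, angle_threshold <= 180,
            fa_floor >= 0)
  if (!is.null(seed)) stopifnot(seed == as.integer(seed))
  structure(list(step = step, noise = noise,
                 max_steps = as.integer(max_steps),
                 angle_threshold = angle_threshold, fa_floor = fa_floor,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 interp = interp),
            class = "tracking_params")
}

#' Direction model for streamline propagation
#'
#' Couples a tensor field with a local propagation rule. Built-in rules:
#' `"tend"` (tensor deflection, `normalize(D v_in)`) and `"dti"`
#' (principal eigenvector, sign-aligned with the incoming direction).
#' A custom rule -- e.g. peaks from an externally computed fiber
#' orientation distribution -- can be plugged in as a function
#' `f(point, v_in)` returning a unit 3-vector or `NULL` (undefined);
#' tracking masks, step control and perturbation are then still handled
#' by the package, through an R-level marcher.
#'
#' @param tensors A [tensor_field()] (still required for masks/FA and the
#'   seed direction even with a custom rule).
#' @param type `"tend"`, `"dti"` or `"custom"`.
#' @param direction_fun For `type = "custom"`: `function(point, v_in)`.
#' @return An object of class `direction_model`.
#' @export
direction_model <- function(tensors, type = c("tend", "dti", "custom"),
                            direction_fun = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(tensors, "tensor_field"))
  if (type == "custom" && !is.function(direction_fun))
    stop("a custom direction model needs direction_fun(point, v_in)",
         call. = FALSE)
  structure(list(tensors = tensors, type = type,
                 direction_fun = direction_fun),
            class = "direction_model")
}

# Trilinear (or nearest) tensor sample at a world point; NULL when outside
# the interpolable grid. R mirror of the compiled sampler, used by the
# custom-model marcher and by tests.
sample_tensor <- function(tf, point, interp = "trilinear") {
  d <- dim(tf$D)
  if (interp == "nearest") {
    v <- round(world_to_voxel(point, tf$affine))
    if (any(v < 0) || any(v >= d[1:3])) return(NULL)
    return(tensor_matrix(tf$D[v[1L] + 1L, v[2L] + 1L, v[3L] + 1L, ]))
  }
  cv <- list(data = tf$D, affine = tf$affine)
  v <- world_to_voxel(point, tf$affine)
  if (any(v < -1e-6) || any(v > d[1:3] - 1 + 1e-6)) return(NULL)
  tensor_matrix(as.vector(trilinear_sample(cv, point)))
}

# Nearest-voxel tracking mask test at a world point.
in_tracking_mask <- function(tf, point) {
  v <- round(world_to_voxel(point, tf$affine))
  if (any(v < 0) || any(v >= dim(tf$mask))) return(FALSE)
  isTRUE(tf$mask[v[1L] + 1L, v[2L] + 1L, v[3L] + 1L])
}

new_streamline <- function(points, seed, seed_index, term_backward,
                           term_forward) {
  structure(points,
            seed = as.numeric(seed), seed_index = as.integer(seed_index),
            termination = c(backward = term_backward,
                            forward = term_forward),
            class = c("streamline", "matrix", "array"))
}

#' @export
print.streamline <- function(x, ...) {
  tr <- attr(x, "termination")
  cat(sprintf("<streamline> %d points, terminated %s / %s\n", nrow(x),
              tr[["backward"]], tr[["forward"]]))
  invisible(x)
}

#' Propagate a single streamline from a seed point
#'
#' Bidirectional marching: the initial direction `v0` is the principal
#' eigenvector of the (interpolated) tensor at the seed; one half tracks
#' along `+v0`, the other along `-v0`, each stepping
#' `x <- x + step * d` with `d` from the direction model followed by
#' stochastic perturbation. The halves are concatenated with the seed as
#' an interior point. Each half stops when it leaves the tracking mask,
#' exhausts `max_steps`, turns by more than `angle_threshold`, reaches a
#' voxel with FA below `fa_floor`, or the model direction is undefined;
#' the reason is recorded per end.
#'
#' @param seed World mm position; must lie inside the tracking mask.
#' @param model A [direction_model()].
#' @param params A [tracking_params()]; if `params$seed` is set the RNG is
#'   seeded before tracking.
#' @param mask Optional logical array overriding the tensor field's mask.
#' @return A `streamline`: an L x 3 matrix of world points with attributes
#'   `seed`, `seed_index` and `termination`.
#' @export
propagate <- function(seed, model, params = tracking_params(), mask = NULL) {
  stopifnot(inherits(model, "direction_model"),
            inherits(params, "tracking_params"))
  seed <- as.numeric(seed)
  stopifnot(length(seed) == 3L, all(is.finite(seed)))
  tf <- model$tensors
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(tf$mask)))
    tf$mask <- array(mask != 0, dim(tf$mask))
  }
  if (!in_tracking_mask(tf, seed))
    stop("seed point lies outside the tracking mask", call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  propagate_core(seed, model, params, tf)
}

propagate_core <- function(seed, model, params, tf) {
  if (model$type %in% c("tend", "dti")) {
    res <- cpp_propagate(seed, tf$D, array(as.integer(tf$mask),
                                           dim(tf$mask)),
                         as.integer(dim(tf$mask)),
                         solve(tf$affine),
                         if (model$type == "tend") 1L else 0L,
                         params$step, params$noise, params$max_steps,
                         cos(params$angle_threshold * pi / 180),
                         params$fa_floor,
                         params$interp == "nearest")
    return(new_streamline(res$points, seed, res$seed_index,
                          term_reason(res$term_backward),
                          term_reason(res$term_forward)))
  }
  propagate_r(seed, model, params, tf)
}

# R marcher for custom direction models; mirrors the compiled path.
propagate_r <- function(seed, model, params, tf) {
  D0 <- sample_tensor(tf, seed, params$interp)
  single <- function(code)
    new_streamline(matrix(seed, 1L, 3L), seed, 1L, code, code)
  if (is.null(D0) || !in_tracking_mask(tf, seed))
    return(single("invalid_seed"))
  if (fractional_anisotropy(D0) < params$fa_floor)
    return(single("low_fa"))
  v0 <- principal_direction(D0)
  if (attr(v0, "degenerate")) return(single("undefined_direction"))
  v0 <- as.numeric(v0)

  cos_thresh <- cos(params$angle_threshold * pi / 180)
  half <- function(v_start) {
    x <- seed; vprev <- v_start
    pts <- matrix(0, 0L, 3L)
    for (n in seq_len(params$max_steps)) {
      D <- sample_tensor(tf, x, params$interp)
      if (is.null(D)) return(list(pts = pts, term = "mask_exit"))
      d <- model$direction_fun(x, vprev)
      if (is.null(d)) return(list(pts = pts, term = "undefined_direction"))
      d <- d / sqrt(sum(d^2))
      if (sum(d * vprev) < 0) d <- -d
      d <- perturb_direction(d, params$noise)
      if (sum(d * vprev) < cos_thresh)
        return(list(pts = pts, term = "angle"))
      xn <- x + params$step * d
      if (!in_tracking_mask(tf, xn))
        return(list(pts = pts, term = "mask_exit"))
      Dn <- sample_tensor(tf, xn, params$interp)
      if (is.null(Dn)) return(list(pts = pts, term = "mask_exit"))
      if (fractional_anisotropy(Dn) < params$fa_floor)
        return(list(pts = pts, term = "low_fa"))
      pts <- rbind(pts, xn)
      x <- xn; vprev <- d
    }
    list(pts = pts, term = "max_steps")
  }
  fwd <- half(v0)
  bwd <- half(-v0)
  nb <- nrow(bwd$pts)
  pts <- rbind(bwd$pts[rev(seq_len(nb)), , drop = FALSE],
               matrix(seed, 1L, 3L), fwd$pts)
  rownames(pts) <- NULL
  new_streamline(pts, seed, nb + 1L, bwd$term, fwd$term)
}

# Deterministic 31-bit sub-seed for (root seed, seed-voxel key, streamline
# index): keeps parallel or restarted runs reproducible.
derive_seed <- function(root, voxel_key = 0L, stream = 1L) {
  h <- (as.double(root) %% 2147483647) * 1000003 +
       as.double(voxel_key) * 7919 + as.double(stream) * 104729
  as.integer(h %% 2147483629) + 1L
}

#' Emit a bundle of streamlines from one seed voxel
#'
#' Launches `n` independent streamlines whose starting positions are
#' jittered uniformly within the seed's output voxel (edge length
#' `jitter` mm, centered on `seed`); jittering avoids grid aliasing in
#' super-resolved maps. With `params$seed` set, each streamline runs on
#' its own deterministically derived RNG substream, so bundles are
#' bit-reproducible and independent of execution order.
#'
#' Jittered positions that fall outside the tracking mask yield a
#' single-point streamline (termination `invalid_seed`) rather than an
#' error, so bundles always contain exactly `n` streamlines.
#'
#' @param seed World mm position of the seed-voxel center.
#' @param n Number of streamlines (500 is a sound default for map
#'   estimation; fewer suffice for tight DTI-like direction fields).
#' @param model A [direction_model()].
#' @param params A [tracking_params()].
#' @param jitter Edge length (mm) of the jitter cube; 0 disables jitter.
#' @param mask Optional tracking-mask override.
#' @param voxel_key Integer key identifying the seed voxel in substream
#'   derivation (set by [compute_spectre()]).
#' @return An object of class `streamline_bundle`: list with `seed`,
#'   `streamlines` (list of `streamline`s) and `params`.
#' @export
seed_bundle <- function(seed, n, model, params = tracking_params(),
                        jitter = 0, mask = NULL, voxel_key = 0L) {
  stopifnot(n >= 1, jitter >= 0)
  seed <- as.numeric(seed)
  tf <- model$tensors
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(tf$mask)))
    tf$mask <- array(mask != 0, dim(tf$mask))
  }
  streamlines <- vector("list", n)
  for (f in seq_len(n)) {
    if (!is.null(params$seed))
      set.seed(derive_seed(params$seed, voxel_key, f))
    start <- seed + if (jitter > 0) runif(3L, -jitter / 2, jitter / 2)
             else c(0, 0, 0)
    streamlines[[f]] <- if (in_tracking_mask(tf, start))
      propagate_core(start, model, params, tf)
    else
      new_streamline(matrix(start, 1L, 3L), start, 1L,
                     "invalid_seed", "invalid_seed")
  }
  structure(list(seed = seed, streamlines = streamlines, params = params,
                 n = as.integer(n)),
            class = "streamline_bundle")
}

#' @export
print.streamline_bundle <- function(x, ...) {
  cat(sprintf("<streamline_bundle> %d streamlines from seed (%.1f, %.1f, %.1f)\n",
              x$n, x$seed[1L], x$seed[2L], x$seed[3L]))
  invisible(x)
}
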