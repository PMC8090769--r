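# The core track-weighted aggregation: for every voxel of a target
# region, the subject-space color field is summed along all streamlines
# emitted there,
#     C_k(r) = sum_f sum_n c_k(x_n^{r,f}),
# with the color evaluated at fractional streamline positions by
# trilinear interpolation and no per-streamline length normalization
# (longer streamlines deliberately contribute more).

#' Target region for map computation
#'
#' The binary region mask lives on the *output* grid, which may be finer
#' than the diffusion grid -- seeding on the output grid is what yields
#' super-resolved maps (e.g. 0.5 mm maps from 1.25 mm data, 1 mm maps
#' from 2 mm data).
#'
#' @param mask Logical/0-1 3D array; must contain at least one voxel.
#' @param affine Voxel-to-world affine of the output grid.
#' @return An object of class `target_region` with `mask`, `affine` and
#'   the voxel edge lengths `resolution` (mm).
#' @export
target_region <- function(mask, affine) {
  if (length(dim(mask)) != 3L)
    stop("region mask must be a 3D array", call. = FALSE)
  validate_affine(affine)
  mask <- array(mask != 0, dim(mask))
  if (!any(mask)) stop("target region is empty", call. = FALSE)
  res <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(mask = mask, affine = affine, resolution = res),
            class = "target_region")
}

new_spectre_map <- function(data, affine, region, n_seeds, params,
                            normalized = FALSE) {
  structure(list(data = data, affine = affine, region = region,
                 n_seeds = n_seeds, params = params,
                 normalized = normalized),
            class = "spectre_map")
}

#' @export
print.spectre_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectre_map> %d x %d x %d grid, %d channel(s), %d region voxel(s), %s\n",
              d[1L], d[2L], d[3L], d[4L], sum(x$region),
              if (x$normalized) "display-normalized" else "un-normalized"))
  invisible(x)
}

#' Aggregate the color field along a streamline bundle
#'
#' Sums the trilinearly interpolated color channels over every point of
#' every streamline in the bundle. There is no normalization by
#' streamline length or count; a constant unit color field therefore
#' returns the total number of streamline points (the track-weighting
#' property).
#'
#' @param bundle A [seed_bundle()] result (or a plain list of point
#'   matrices in `$streamlines`).
#' @param cv The subject-space [color_volume()].
#' @return A length-K numeric vector `C_k` for the bundle's seed.
#' @export
aggregate_seed <- function(bundle, cv) {
  stopifnot(inherits(cv, "color_volume"))
  if (!identical(cv$space, "subject"))
    stop("aggregation expects the color volume in subject space",
         call. = FALSE)
  sls <- bundle$streamlines
  K <- dim(cv$data)[4L]
  if (length(sls) == 0L) {
    warning("empty bundle: returning a zero aggregate")
    return(numeric(K))
  }
  pts <- do.call(rbind, lapply(sls, function(s) unclass(s)[, , drop = FALSE]))
  colSums(trilinear_sample(cv, pts))
}

#' Compute a full track-weighted color map over a target region
#'
#' For every voxel of the target region, emits a bundle of `n_seeds`
#' streamlines (jittered within the output voxel) and aggregates the
#' subject-space color field along them. Deterministic under a fixed
#' `params$seed`: every (voxel, streamline) pair runs on its own derived
#' RNG substream.
#'
#' @param region A [target_region()] on the output grid.
#' @param model A [direction_model()].
#' @param cv Subject-space [color_volume()].
#' @param params A [tracking_params()].
#' @param n_seeds Streamlines per voxel (default 500).
#' @param mask Optional tracking-mask override.
#' @return A `spectre_map`; voxels outside the region are absent and
#'   stored as `NaN`.
#' @export
compute_spectre <- function(region, model, cv, params = tracking_params(),
                            n_seeds = 500, mask = NULL) {
  stopifnot(inherits(region, "target_region"),
            inherits(model, "direction_model"),
            inherits(cv, "color_volume"))
  if (!identical(cv$space, "subject"))
    stop("compute_spectre needs the color volume warped to subject space",
         call. = FALSE)
  dim3 <- dim(region$mask)
  K <- dim(cv$data)[4L]
  out <- array(NaN, c(dim3, K))
  idx <- which(region$mask)
  jitter <- min(region$resolution)
  vox <- arrayInd(idx, dim3) - 1L
  centers <- voxel_to_world(vox, region$affine)
  nvox_total <- prod(dim3)
  for (i in seq_along(idx)) {
    bundle <- seed_bundle(centers[i, ], n_seeds, model, params,
                          jitter = jitter, mask = mask,
                          voxel_key = idx[i])
    ck <- aggregate_seed(bundle, cv)
    out[idx[i] + nvox_total * (seq_len(K) - 1L)] <- ck
  }
  new_spectre_map(out, region$affine, region$mask, as.integer(n_seeds),
                  params)
}

#' Normalize a map for display
#'
#' Display normalization only: per-voxel brightness (the sum of the color
#' channels) is computed over the target region, all channels are divided
#' by its 80th percentile (linear interpolation between order statistics,
#' i.e. R's default quantile type 7), and the few "overexposed" channel
#' values are clipped to `[0, 1]`. Quantitative analyses (the icd index,
#' group averages) must use un-normalized maps.
#'
#' @param map An un-normalized `spectre_map`.
#' @param probs Percentile used for the brightness divisor (default 0.8).
#' @return The normalized `spectre_map` (flag set).
#' @export
normalize_for_display <- function(map, probs = 0.8) {
  stopifnot(inherits(map, "spectre_map"))
  if (map$normalized)
    stop("map is already display-normalized", call. = FALSE)
  K <- dim(map$data)[4L]
  vals <- matrix(map$data, ncol = K)[which(map$region), , drop = FALSE]
  brightness <- rowSums(vals)
  if (!any(is.finite(brightness)) || all(brightness == 0, na.rm = TRUE))
    stop("all-zero map: display scale is undefined", call. = FALSE)
  divisor <- quantile(brightness, probs = probs, na.rm = TRUE, names = FALSE,
                      type = 7)
  if (divisor <= 0)
    stop("non-positive brightness percentile: display scale is undefined",
         call. = FALSE)
  map$data <- pmin(pmax(map$data / divisor, 0), 1)
  map$normalized <- TRUE
  map
}
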