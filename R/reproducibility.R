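# Test-retest reproducibility: maps are warped to a common grid, grouped
# per subject, and summarized by the intraclass-distance index
#     icd = 100% * (1 - N * sum_n d(s_n1, s_n2) / sum_j sum_n d(s_j1, s_n2))
# where d is the squared Euclidean distance over all masked voxels and
# color channels, treated equally and without intensity normalization.
# The double sum in the denominator includes the j = n terms, exactly as
# the index is defined; an option excludes them for sensitivity checks.

# Coerce a spectre_map or plain array to list(data = 4D array, affine,
# present = logical 3D array of non-absent voxels).
as_map <- function(m, affine = NULL) {
  if (inherits(m, "spectre_map"))
    return(list(data = m$data, affine = m$affine, present = m$region))
  data <- m
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("maps must be spectre_map objects or 3D/4D arrays", call. = FALSE)
  present <- apply(is.finite(data), 1:3, all)
  list(data = data, affine = if (is.null(affine)) diag(4) else affine,
       present = present)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$affine, b$affine, tolerance = 1e-8))
}

#' Squared Euclidean distance between two maps
#'
#' Sum over all masked voxels and all channels of the squared value
#' difference; channels are weighted equally and the maps are compared
#' as-is (no intensity normalization).
#'
#' @param s_a,s_b Maps (`spectre_map` or 4D arrays) on the same grid.
#' @param mask Optional logical 3D array restricting the comparison; by
#'   default the voxels present in both maps.
#' @return A single non-negative number.
#' @export
map_distance <- function(s_a, s_b, mask = NULL) {
  a <- as_map(s_a); b <- as_map(s_b)
  if (!same_grid(a, b))
    stop("maps must share one grid (shape and affine)", call. = FALSE)
  m <- if (is.null(mask)) a$present & b$present else {
    if (!all(dim(mask) == dim(a$present)))
      stop("mask must live on the map grid", call. = FALSE)
    array(mask != 0, dim(a$present)) & a$present & b$present
  }
  diff <- matrix(a$data - b$data, ncol = dim(a$data)[4L])
  sum(diff[which(m), , drop = FALSE]^2)
}

#' Re-scan set: two maps per subject on one common grid
#'
#' @param scan1,scan2 Lists of maps (one per subject, same order); every
#'   map must share a single grid.
#' @param mask Optional analysis mask. Voxels absent in *any* map are
#'   dropped from the shared mask (complete-case analysis), so all
#'   distances compare identical supports.
#' @return An object of class `rescan_set`.
#' @export
rescan_set <- function(scan1, scan2, mask = NULL) {
  if (length(scan1) != length(scan2) || length(scan1) < 1L)
    stop("need the same positive number of maps per scan", call. = FALSE)
  maps1 <- lapply(scan1, as_map)
  maps2 <- lapply(scan2, as_map)
  all_maps <- c(maps1, maps2)
  for (m in all_maps[-1L])
    if (!same_grid(all_maps[[1L]], m))
      stop("all maps of a rescan set must share one grid", call. = FALSE)
  shared <- Reduce(`&`, lapply(all_maps, `[[`, "present"))
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(shared)))
      stop("mask must live on the map grid", call. = FALSE)
    shared <- shared & array(mask != 0, dim(shared))
  }
  structure(list(scan1 = maps1, scan2 = maps2, mask = shared,
                 n_subjects = length(scan1)),
            class = "rescan_set")
}

#' Intraclass-distance (icd) reproducibility index
#'
#' Quantifies how well subjects can be told apart from their maps across
#' scan sessions: within-subject scan-1 vs scan-2 squared distances are
#' related to all between-scan squared distances,
#' \deqn{icd = 100 (1 - N \sum_n d(s_{n1}, s_{n2}) /
#'        \sum_j \sum_n d(s_{j1}, s_{n2}))}
#' The index is 100% when every subject's two scans are identical while
#' subjects differ, and smaller for non-reproducible maps. The
#' denominator's double sum keeps its diagonal (j = n) terms as the
#' index is defined; `exclude_diagonal = TRUE` switches to the
#' conventional between-subject-only denominator for sensitivity
#' analysis. Adversarial inputs can in principle push the index below
#' 0%; negative values are reported as computed, not clamped.
#'
#' @param set A [rescan_set()].
#' @param exclude_diagonal Drop j = n terms from the denominator.
#' @return An object of class `icd_result`: list with `icd` (percent),
#'   `intra_sum`, `inter_sum`, `intra` (per-subject squared distances)
#'   and `n_subjects`.
#' @export
compute_icd <- function(set, exclude_diagonal = FALSE) {
  stopifnot(inherits(set, "rescan_set"))
  N <- set$n_subjects
  m <- set$mask
  d <- function(a, b) {
    diff <- matrix(a$data - b$data, ncol = dim(a$data)[4L])
    sum(diff[which(m), , drop = FALSE]^2)
  }
  intra <- vapply(seq_len(N),
                  function(n) d(set$scan1[[n]], set$scan2[[n]]), 0)
  inter <- 0
  for (j in seq_len(N)) for (n in seq_len(N)) {
    if (exclude_diagonal && j == n) next
    inter <- inter + d(set$scan1[[j]], set$scan2[[n]])
  }
  if (inter <= 0) {
    warning("all maps identical over the mask: icd undefined, reported as 100%")
    icd <- 100
  } else {
    icd <- 100 * (1 - N * sum(intra) / inter)
  }
  structure(list(icd = icd, intra_sum = sum(intra), inter_sum = inter,
                 intra = intra, n_subjects = N,
                 exclude_diagonal = exclude_diagonal),
            class = "icd_result")
}

#' @export
print.icd_result <- function(x, ...) {
  cat(sprintf("<icd_result> icd = %.2f%% over %d subject(s)\n",
              x$icd, x$n_subjects))
  invisible(x)
}

#' Warp a map onto a common analysis grid
#'
#' Pull-back resampling of every channel onto the common grid by
#' trilinear interpolation; the deformation field stores, for each
#' common-grid voxel, the subject-space coordinate to sample. A
#' common-grid voxel is marked absent (`NaN`) unless its whole
#' interpolation neighborhood lies inside the source map's region, so
#' partial-support voxels never leak into distance computations.
#'
#' @param map A `spectre_map` (un-normalized).
#' @param warp A [deformation_field()] on the common grid, mapping common
#'   voxels to subject mm coordinates.
#' @return A `spectre_map` on the common grid.
#' @export
warp_map_to_common <- function(map, warp) {
  stopifnot(inherits(map, "spectre_map"))
  if (missing(warp) || is.null(warp))
    stop("a deformation field is required; identity is never assumed",
         call. = FALSE)
  stopifnot(inherits(warp, "deformation_field"))
  d <- dim(warp$mapping)
  pts <- matrix(warp$mapping, ncol = 3L)
  K <- dim(map$data)[4L]

  src_data <- map$data
  src_data[!is.finite(src_data)] <- 0
  src <- list(data = src_data, affine = map$affine)
  vals <- trilinear_sample(src, pts)
  # support indicator: 1 only where all 8 source corners are in-region
  support <- list(data = array(as.numeric(map$region),
                               c(dim(map$region), 1L)),
                  affine = map$affine)
  w <- trilinear_sample(support, pts)
  present <- as.vector(w) > 1 - 1e-9
  vals[!present, ] <- NaN
  new_spectre_map(array(vals, c(d[1:3], K)), warp$affine,
                  array(present, d[1:3]), map$n_seeds, map$params,
                  map$normalized)
}

#' Voxel-wise group average of maps on a common grid
#'
#' Arithmetic mean per voxel and channel over the maps in which the voxel
#' is present; voxels absent everywhere stay absent.
#'
#' @param maps List of `spectre_map`s (or 4D arrays) on one grid.
#' @return A `spectre_map` whose region is the union of supports.
#' @export
group_average <- function(maps) {
  stopifnot(length(maps) >= 1L)
  ms <- lapply(maps, as_map)
  for (m in ms[-1L])
    if (!same_grid(ms[[1L]], m))
      stop("group averaging needs maps on one shared grid", call. = FALSE)
  d <- dim(ms[[1L]]$data)
  acc <- array(0, d)
  cnt <- array(0, d)
  for (m in ms) {
    ok <- array(rep(m$present, d[4L]), d)
    x <- m$data
    x[!ok] <- 0
    acc <- acc + x
    cnt <- cnt + ok
  }
  avg <- acc / cnt  # 0/0 -> NaN marks all-absent voxels
  region <- Reduce(`|`, lapply(ms, `[[`, "present"))
  first <- maps[[1L]]
  new_spectre_map(avg, ms[[1L]]$affine, region,
                  if (inherits(first, "spectre_map")) first$n_seeds else NA_integer_,
                  if (inherits(first, "spectre_map")) first$params else NULL)
}
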