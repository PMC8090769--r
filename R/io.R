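# File formats: NIfTI-1 volumes (via RNifti), MRtrix TCK streamlines
# (read/write) and TrackVis TRK (read only).
#
# Channel conventions for 4D NIfTI files: color volumes and maps store
# channels in the 4th dimension; tensor fields store the 6 components
# (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz); deformation fields store the 3 mapped
# world coordinates. Affines are written as sform (code 2) and must be
# orthogonal; maps store absent voxels as NaN in float files.

nifti_from <- function(data, affine) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::`sform<-`(img, structure(affine, code = 2L))
}

read_nifti_raw <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  affine <- structure(as.matrix(RNifti::xform(img)), imagedim = NULL,
                      code = NULL)
  attributes(affine) <- list(dim = dim(affine))
  tryCatch(validate_affine(affine),
           error = function(e) stop("bad NIfTI header in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  list(data = data, affine = affine)
}

#' Write a volume object to NIfTI-1
#'
#' Dispatches on the object class; data are written as float32 (masks as
#' uint8) with the affine stored as sform. Round-trips preserve data and
#' affine bit-exactly for float32-representable values.
#'
#' @param x A [color_volume()], [tensor_field()], [deformation_field()],
#'   `spectre_map`, or plain logical/numeric array (with `affine`).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine Affine for plain arrays; ignored for package objects.
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, affine = NULL) {
  UseMethod("write_volume")
}

#' @export
write_volume.color_volume <- function(x, path, affine = NULL) {
  RNifti::writeNifti(nifti_from(x$data, x$affine), path, datatype = "float")
  invisible(path)
}

#' @export
write_volume.tensor_field <- function(x, path, affine = NULL) {
  RNifti::writeNifti(nifti_from(x$D, x$affine), path, datatype = "float")
  invisible(path)
}

#' @export
write_volume.deformation_field <- function(x, path, affine = NULL) {
  RNifti::writeNifti(nifti_from(x$mapping, x$affine), path,
                     datatype = "float")
  invisible(path)
}

#' @export
write_volume.spectre_map <- function(x, path, affine = NULL) {
  # absent voxels stay NaN in the float file; display exports replace
  # them by 0 (see run_pipeline)
  RNifti::writeNifti(nifti_from(x$data, x$affine), path, datatype = "float")
  invisible(path)
}

#' @export
write_volume.default <- function(x, path, affine = NULL) {
  stopifnot(!is.null(affine))
  validate_affine(affine)
  if (is.logical(x)) {
    RNifti::writeNifti(nifti_from(array(as.integer(x), dim(x)), affine),
                       path, datatype = "uint8")
  } else {
    RNifti::writeNifti(nifti_from(x, affine), path, datatype = "float")
  }
  invisible(path)
}

#' Read NIfTI volumes into package containers
#'
#' `read_color_volume`, `read_tensor_field`, `read_deformation_field`,
#' `read_spectre_map` and `read_mask` wrap NIfTI reading with the
#' container-specific validation (component counts, orthogonal affine).
#' For maps, voxels stored as NaN are treated as absent.
#'
#' @param path A NIfTI-1 file.
#' @param space Space tag for color volumes.
#' @return The corresponding package object.
#' @export
read_color_volume <- function(path, space = c("template", "subject")) {
  raw <- read_nifti_raw(path)
  color_volume(raw$data, raw$affine, space = match.arg(space))
}

#' @rdname read_color_volume
#' @export
read_tensor_field <- function(path) {
  raw <- read_nifti_raw(path)
  d <- dim(raw$data)
  if (length(d) != 4L || d[4L] != 6L)
    stop("tensor NIfTI must have 6 components in the 4th dimension ",
         "(order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)", call. = FALSE)
  tensor_field(raw$data, raw$affine)
}

#' @rdname read_color_volume
#' @export
read_deformation_field <- function(path) {
  raw <- read_nifti_raw(path)
  d <- dim(raw$data)
  if (length(d) != 4L || d[4L] != 3L)
    stop("deformation NIfTI must have 3 components in the 4th dimension",
         call. = FALSE)
  deformation_field(raw$data, raw$affine)
}

#' @rdname read_color_volume
#' @export
read_spectre_map <- function(path) {
  raw <- read_nifti_raw(path)
  data <- raw$data
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  region <- apply(is.finite(data), 1:3, all)
  new_spectre_map(data, raw$affine, region, NA_integer_, NULL)
}

#' @rdname read_color_volume
#' @export
read_mask <- function(path) {
  raw <- read_nifti_raw(path)
  data <- raw$data
  if (length(dim(data)) == 4L && dim(data)[4L] == 1L)
    dim(data) <- dim(data)[1:3]
  structure(array(data != 0, dim(data)), affine = raw$affine)
}

#' Read FSL-style bval/bvec text files
#'
#' @param bval_path,bvec_path Whitespace-separated text files: one row of
#'   b-values; three rows (or columns) of gradient components.
#' @return List with `bvals` (vector) and `bvecs` (n x 3 matrix).
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (nrow(bv) == 3L && ncol(bv) != 3L) bv <- t(bv)
  if (ncol(bv) != 3L || nrow(bv) != length(bvals))
    stop("bvec table does not match the bval count", call. = FALSE)
  list(bvals = bvals, bvecs = unname(bv))
}

# ---- TCK (MRtrix) ---------------------------------------------------------

#' Write streamlines as an MRtrix TCK file
#'
#' Points are world mm, stored Float32LE; streamlines are separated by
#' NaN triplets and the stream is terminated by an Inf triplet, per the
#' format.
#'
#' @param streamlines A `streamline_bundle`, a list of n x 3 point
#'   matrices, or a single matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tck <- function(streamlines, path) {
  if (inherits(streamlines, "streamline_bundle"))
    streamlines <- streamlines$streamlines
  if (is.matrix(streamlines)) streamlines <- list(streamlines)
  streamlines <- lapply(streamlines, function(s) {
    s <- unclass(s)
    attributes(s) <- list(dim = dim(s))
    s
  })
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", length(streamlines)))
  # the offset line's own width feeds back into the offset; fix by
  # padding the offset to a stable width
  offset_line <- function(off) sprintf("file: . %d", off)
  base <- sum(nchar(header) + 1L) + nchar("END") + 1L
  off <- base + nchar(offset_line(10000000L)) + 1L
  header <- c(header, sprintf("file: . %08d", off), "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  pad <- off - (sum(nchar(header) + 1L))
  if (pad > 0) writeBin(raw(pad), con)
  for (s in streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(rep(NaN, 3L)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3L)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK file
#'
#' @param path A `.tck` file (Float32LE or Float64LE data).
#' @return A list of n x 3 matrices of world mm points.
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(trimws(first), "mrtrix tracks"))
    stop(path, " is not a TCK file (missing 'mrtrix tracks' magic)",
         call. = FALSE)
  datatype <- "Float32LE"
  offset <- NA_integer_
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("truncated TCK header in ", path, call. = FALSE)
    if (identical(trimws(line), "END")) break
    kv <- strsplit(line, ":", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = ":"))
    if (key == "datatype") datatype <- val
    if (key == "file") offset <- as.integer(sub("^\\.\\s*", "", val))
  }
  if (is.na(offset))
    stop("TCK header in ", path, " lacks the 'file' offset field",
         call. = FALSE)
  size <- switch(datatype, Float32LE = 4L, Float64LE = 8L,
                 stop("unsupported TCK datatype: ", datatype, call. = FALSE))
  seek(con, offset)
  n_total <- (file.size(path) - offset) %/% size
  vals <- readBin(con, "numeric", n = n_total, size = size,
                  endian = "little")
  pts <- matrix(vals[seq_len(length(vals) %/% 3L * 3L)], ncol = 3L,
                byrow = TRUE)
  breaks <- which(!is.finite(pts[, 1L]))
  out <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start)
      out[[length(out) + 1L]] <- pts[start:(b - 1L), , drop = FALSE]
    if (all(is.infinite(pts[b, ]))) break
    start <- b + 1L
  }
  out
}

# ---- TRK (TrackVis), read-only --------------------------------------------

#' Read a TrackVis TRK file
#'
#' Minimal reader: scalars and per-track properties are skipped; for
#' version-2 headers with a valid `vox_to_ras` matrix the points are
#' converted to world mm (TrackVis stores corner-anchored voxel-mm
#' coordinates), otherwise the raw coordinates are returned with a
#' warning.
#'
#' @param path A `.trk` file.
#' @return A list of n x 3 matrices.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6L))
  if (!startsWith(magic, "TRACK"))
    stop(path, " is not a TRK file (missing TRACK magic)", call. = FALSE)
  readBin(con, "integer", 3L, size = 2L, endian = "little")     # dim
  voxel_size <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")     # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)                                     # scalar names
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)                                     # property names
  vox_to_ras <- matrix(readBin(con, "numeric", 16L, size = 4L,
                               endian = "little"), 4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)           # reserved etc.
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L)
    stop("TRK header size field is ", hdr_size,
         " (expected 1000); wrong endianness or corrupt file",
         call. = FALSE)
  have_xform <- version >= 2L && vox_to_ras[4L, 4L] != 0
  if (!have_xform)
    warning("TRK file has no valid vox_to_ras; returning raw coordinates")
  out <- list()
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    vals <- readBin(con, "numeric", npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_props > 0L)
      readBin(con, "numeric", n_props, size = 4L, endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3,
                                                           drop = FALSE]
    if (have_xform) {
      vox <- sweep(m, 2L, voxel_size, "/") - 0.5   # corner-anchored mm
      m <- t(vox_to_ras[1:3, 1:3] %*% t(vox) + vox_to_ras[1:3, 4L])
    }
    out[[length(out) + 1L]] <- m
    if (n_count > 0L && length(out) >= n_count) break
  }
  out
}
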