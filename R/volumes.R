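#' 4-D fMRI volume container
#'
#' A light container for a registered BOLD series: a 4-D array (x, y, z, t),
#' a 4x4 voxel-to-world affine (MNI millimetres; 0-based voxel indices), and
#' the repetition time in seconds.
#'
#' @param data 4-D numeric array.
#' @param affine 4x4 invertible voxel-to-world matrix.
#' @param tr_seconds Repetition time in seconds (default 3, the acquisition
#'   this pipeline is tuned for).
#' @return An object of class \code{volume4d}.
#' @export
volume4d <- function(data, affine = diag(4), tr_seconds = 3) {
  if (length(dim(data)) != 4L) stop("'data' must be a 4-D array")
  if (dim(data)[4] < 2L) stop("a volume4d needs at least 2 timepoints")
  check_affine(affine)
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "volume4d")
}

#' 3-D scalar map container
#'
#' Holds a voxelwise scalar field (PE, ReHo, F, r, ...) together with its
#' affine and the mask of valid voxels. Values outside the mask are stored
#' as \code{NA}, never 0, so they cannot silently bias smoothing or
#' statistics.
#'
#' @param data 3-D numeric array; positions outside \code{mask} are forced
#'   to \code{NA}.
#' @param affine 4x4 voxel-to-world matrix.
#' @param mask 3-D logical array of the same shape as \code{data}.
#' @return An object of class \code{volume_map}.
#' @export
volume_map <- function(data, affine = diag(4), mask = NULL) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array")
  check_affine(affine)
  if (is.null(mask)) mask <- !is.na(data)
  if (!identical(dim(mask), dim(data)))
    stop("mask shape does not match data shape")
  mask <- array(as.logical(mask), dim = dim(data))
  data[!mask] <- NA_real_
  structure(list(data = data, affine = affine, mask = mask),
            class = "volume_map")
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible")
  invisible(TRUE)
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume4d: %d x %d x %d voxels, %d timepoints, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_map: %d x %d x %d, %d in-mask voxels, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], sum(x$mask),
              min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)))
  invisible(x)
}

# Voxel sizes (mm) along each axis, from the affine's column norms.
voxel_sizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

# World coordinates (mm) of voxel centers for 1-based array indices.
voxel_to_world <- function(affine, ijk) {
  ijk <- rbind(t(ijk) - 1, 1)  # affine maps 0-based indices
  t(affine %*% ijk)[, 1:3, drop = FALSE]
}

world_to_voxel <- function(affine, xyz) {
  xyz <- rbind(t(xyz), 1)
  t(solve(affine) %*% xyz)[, 1:3, drop = FALSE] + 1
}

as_nifti_image <- function(data, affine, pixdim4 = 1) {
  d <- dim(data)
  nd <- length(d)
  dimfield <- c(nd, d, rep(1L, 7L - nd))
  pd <- c(1, voxel_sizes(affine), if (nd == 4L) pixdim4, rep(0, 7L - nd))
  hdr <- RNifti::niftiHeader(list(dim = dimfield, pixdim = pd))
  img <- RNifti::asNifti(data, hdr)
  RNifti::`qform<-`(img, structure(affine, code = 2L))
}

#' Read a 4-D NIfTI file as a volume4d
#'
#' @param path Path to a NIfTI-1 file (.nii or .nii.gz).
#' @param tr_seconds Repetition time; if \code{NULL}, taken from the file's
#'   4th pixdim entry.
#' @return A [volume4d()].
#' @export
read_volume4d <- function(path, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("'", path, "' is not a 4-D image")
  if (is.null(tr_seconds)) {
    tr_seconds <- RNifti::pixdim(img)[4]
    if (!is.finite(tr_seconds) || tr_seconds <= 0) tr_seconds <- 3
  }
  volume4d(array(as.numeric(img), dim = dim(img)),
           affine = unclass_xform(img), tr_seconds = tr_seconds)
}

#' Read a 3-D NIfTI file as a volume_map
#'
#' Non-finite voxels become the out-of-mask sentinel (\code{NA}).
#'
#' @param path Path to a NIfTI-1 file.
#' @param mask Optional logical array overriding the NA-derived mask.
#' @return A [volume_map()].
#' @export
read_volume_map <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L) stop("'", path, "' is not a 3-D image")
  arr[!is.finite(arr)] <- NA_real_
  volume_map(arr, affine = unclass_xform(img), mask = mask)
}

unclass_xform <- function(img) {
  m <- RNifti::xform(img)
  matrix(as.numeric(m), 4L, 4L)
}

#' Write a volume_map (or volume4d, or logical mask array) to NIfTI
#'
#' Out-of-mask voxels of a \code{volume_map} are written as NaN. A JSON
#' sidecar with provenance metadata can be attached via \code{meta}.
#'
#' @param x A [volume_map()], [volume4d()], or a logical/numeric 3-D array
#'   (needs \code{affine} then).
#' @param path Output path (.nii or .nii.gz).
#' @param affine Affine for bare arrays.
#' @param meta Optional named list written to \code{<path>.json} (with any
#'   .nii/.nii.gz extension stripped first).
#' @return \code{path}, invisibly.
#' @export
write_nifti_map <- function(x, path, affine = NULL, meta = NULL) {
  if (inherits(x, "volume_map")) {
    arr <- x$data
    arr[!x$mask] <- NaN
    img <- as_nifti_image(arr, x$affine)
  } else if (inherits(x, "volume4d")) {
    img <- as_nifti_image(x$data, x$affine, pixdim4 = x$tr_seconds)
  } else {
    if (is.null(affine)) stop("'affine' is required for bare arrays")
    img <- as_nifti_image(array(as.numeric(x), dim = dim(x)), affine)
  }
  RNifti::writeNifti(img, path)
  if (!is.null(meta)) {
    side <- sub("\\.nii(\\.gz)?$", "", path)
    jsonlite::write_json(meta, paste0(side, ".json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

# Flatten the in-mask voxels of a 4-D array into a voxels x time matrix.
mask_series_matrix <- function(data4d, mask) {
  d <- dim(data4d)
  mat <- matrix(data4d, prod(d[1:3]), d[4])
  mat[as.vector(mask), , drop = FALSE]
}

# Scatter a vector of in-mask values back into a 3-D array (NA elsewhere).
unmask_map <- function(values, mask) {
  out <- array(NA_real_, dim = dim(mask))
  out[mask] <- values
  out
}
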