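#' Voxelwise permutation-entropy map
#'
#' Computes normalized permutation entropy for every in-mask voxel's time
#' series. The series are used exactly as supplied; temporal preprocessing
#' (volume discard, detrending) is the caller's responsibility — see
#' [run_entropy_stage()] for the full enforced stage order. Spatial
#' smoothing, when wanted, is applied to the resulting map afterwards
#' ([gaussian_smooth_map()]), never to the 4-D data, because pre-smoothing
#' inflates regional similarity and distorts the entropy.
#'
#' @param vol A [volume4d()].
#' @param mask 3-D logical array of voxels to evaluate; \code{NULL} means all.
#' @param params A [pe_params()] object.
#' @param force Compute even when [validate_pe_params()] rejects the
#'   (m, l, t) combination (a warning is still raised).
#' @return A [volume_map()] of \code{pe_norm} values in \[0, 1\].
#' @export
pe_map <- function(vol, mask = NULL, params = pe_params(), force = FALSE) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask shape does not match the volume")
  mask <- array(as.logical(mask), d[1:3])
  if (!any(mask)) stop("mask is empty")
  v <- validate_pe_params(d[4], params)
  if (!v$valid) {
    if (!force)
      stop("invalid PE parameters for series length ", d[4], ": ", v$message,
           " (use force = TRUE to override)")
    warning("computing PE despite failed validation: ", v$message, call. = FALSE)
  }
  X <- mask_series_matrix(vol$data, mask)
  volume_map(unmask_map(row_pe_norm(X, params), mask),
             affine = vol$affine, mask = mask)
}

#' Kendall's coefficient of concordance W
#'
#' Agreement among K rank series over n timepoints:
#' \deqn{W = \frac{\sum_i R_i^2 - n \bar R^2}{K^2 (n^3 - n) / 12}}
#' where \eqn{R_i} is the sum of the K ranks at timepoint i. W is 1 when all
#' columns carry identical rankings and near 0 for unrelated ones. Ties are
#' expected to be resolved upstream as midranks; no tie-correction term is
#' applied (BOLD values essentially never tie).
#'
#' @param rank_matrix Numeric matrix, n timepoints x K series of
#'   within-series ranks.
#' @return W, a scalar in \[0, 1\].
#' @export
kendall_w <- function(rank_matrix) {
  rank_matrix <- as.matrix(rank_matrix)
  n <- nrow(rank_matrix); K <- ncol(rank_matrix)
  if (K < 2L) stop("Kendall's W needs at least 2 series")
  if (n < 2L) stop("Kendall's W needs at least 2 timepoints")
  Ri <- rowSums(rank_matrix)
  (sum(Ri^2) - n * mean(Ri)^2) / (K^2 * (n^3 - n) / 12)
}

# Neighborhood offsets for ReHo cluster sizes 7 / 19 / 27 (center included).
reho_offsets <- function(neighborhood) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  switch(as.character(neighborhood),
         "7"  = g[ord <= 1L, , drop = FALSE],
         "19" = g[ord <= 2L, , drop = FALSE],
         "27" = g,
         stop("'neighborhood' must be 7, 19 or 27"))
}

#' Regional homogeneity (ReHo) map
#'
#' For each in-mask voxel, Kendall's W of the voxel's time series with its
#' in-mask neighbors (6, 18 or 26 of them plus the center, per
#' \code{neighborhood}). At mask edges the neighbor count K simply shrinks
#' to the available in-mask members; voxels left with fewer than 2 members
#' are excluded from the output mask. Like PE maps, ReHo maps are smoothed
#' (if at all) after computation.
#'
#' @param vol A [volume4d()].
#' @param mask 3-D logical array; \code{NULL} means all voxels.
#' @param neighborhood Cluster size: 7, 19 or 27 (default 27).
#' @return A [volume_map()] of W values in \[0, 1\].
#' @export
reho_map <- function(vol, mask = NULL, neighborhood = 27L) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask shape does not match the volume")
  mask <- array(as.logical(mask), d[1:3])
  if (!any(mask)) stop("mask is empty")
  nt <- d[4]
  offs <- reho_offsets(neighborhood)

  # per-voxel midranks along time, zero outside the mask
  X <- mask_series_matrix(vol$data, mask)
  Rk <- t(apply(X, 1L, rank))
  R4 <- array(0, dim = d)
  Rflat <- matrix(R4, prod(d[1:3]), nt)
  Rflat[as.vector(mask), ] <- Rk
  R4 <- array(Rflat, dim = d)

  S <- array(0, dim = d)            # sum of neighbor rank series
  Kcnt <- array(0, dim = d[1:3])    # in-mask neighbor count
  mnum <- array(as.numeric(mask), d[1:3])
  for (i in seq_len(nrow(offs))) {
    S <- S + shift_array(R4, offs[i, ])
    Kcnt <- Kcnt + shift_array(mnum, offs[i, ])
  }

  Ssq <- array(rowSums(matrix(S, prod(d[1:3]), nt)^2), d[1:3])
  Rbar <- Kcnt * (nt + 1) / 2       # exact mean of R_i under midranks
  W <- (Ssq - nt * Rbar^2) / (Kcnt^2 * (nt^3 - nt) / 12)
  keep <- mask & Kcnt >= 2
  W[!keep] <- NA_real_
  volume_map(W, affine = vol$affine, mask = keep)
}

# Zero-padded shift: out[v] = arr[v + off] (off recycled over any 4th dim).
shift_array <- function(arr, off) {
  d <- dim(arr)
  out <- array(0, dim = d)
  idx_dst <- lapply(1:3, function(a) max(1L, 1L - off[a]):min(d[a], d[a] - off[a]))
  if (any(vapply(idx_dst, length, integer(1)) == 0L)) return(out)
  idx_src <- lapply(1:3, function(a) idx_dst[[a]] + off[a])
  if (length(d) == 4L) {
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]], ] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]], , drop = FALSE]
  } else {
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]], drop = FALSE]
  }
  out
}

#' Masked Gaussian smoothing of a scalar map
#'
#' Separable discrete Gaussian convolution with \code{sigma_mm =
#' fwhm / (2 sqrt(2 ln 2))} per axis, converted to voxel units from the
#' affine's voxel sizes and truncated at 4 sigma. Smoothing is
#' mask-renormalized: the kernel weights are rescaled over the in-mask
#' support (numerator and denominator smoothed jointly), so out-of-mask
#' sentinels never leak in, constant maps are preserved exactly, and the
#' in-mask mean is preserved to high accuracy.
#'
#' @param map A [volume_map()].
#' @param fwhm_mm Full width at half maximum in millimetres (>= 0; 0 is the
#'   identity). The pipeline default is 8 mm.
#' @return A smoothed [volume_map()] on the same mask.
#' @export
gaussian_smooth_map <- function(map, fwhm_mm = 8) {
  stopifnot(inherits(map, "volume_map"))
  if (fwhm_mm < 0) stop("'fwhm_mm' must be non-negative")
  if (fwhm_mm == 0) return(map)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- voxel_sizes(map$affine)
  num <- map$data
  num[!map$mask] <- 0
  den <- array(as.numeric(map$mask), dim(map$mask))
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / vs[axis])
    num <- conv_axis(num, k, axis)
    den <- conv_axis(den, k, axis)
  }
  out <- array(NA_real_, dim(map$data))
  ok <- map$mask & den > 0
  out[ok] <- num[ok] / den[ok]
  volume_map(out, affine = map$affine, mask = map$mask)
}

gaussian_kernel_1d <- function(sigma_vox) {
  h <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-h:h)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# 1-D convolution along one axis of a 3-D array via a banded matrix product.
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  n <- d[axis]
  h <- (length(k) - 1L) %/% 2L
  Kmat <- matrix(0, n, n)
  for (off in -h:h) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    Kmat[cbind(i[ok], j[ok])] <- k[off + h + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  pd <- dim(a)
  a <- Kmat %*% matrix(a, n, prod(pd[-1]))
  aperm(array(a, pd), order(perm))
}

#' Mean of a map over a tissue mask
#'
#' Mean of the map's values over the intersection of its own mask with a
#' tissue mask (GM, WM, CSF, or whole brain), as used for tissue-level
#' entropy summaries.
#'
#' @param map A [volume_map()].
#' @param tissue_mask 3-D logical array.
#' @return Scalar mean.
#' @export
tissue_mean <- function(map, tissue_mask) {
  stopifnot(inherits(map, "volume_map"))
  if (!identical(dim(tissue_mask), dim(map$data)))
    stop("tissue mask shape does not match the map")
  sel <- map$mask & as.logical(tissue_mask)
  if (!any(sel)) stop("tissue mask does not intersect the map's mask")
  mean(map$data[sel])
}
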