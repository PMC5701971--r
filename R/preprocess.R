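#' Discard initial volumes of a 4-D series
#'
#' Removes the first \code{k} timepoints, the frames acquired while the
#' participant adapts to the scanner and the signal reaches steady state.
#' The default of 10 turns a 140-volume acquisition into the 130 timepoints
#' the entropy analysis expects.
#'
#' @param vol A [volume4d()].
#' @param k Number of leading timepoints to drop (default 10).
#' @return A [volume4d()] with \code{t - k} timepoints; affine unchanged.
#' @export
drop_initial_volumes <- function(vol, k = 10L) {
  stopifnot(inherits(vol, "volume4d"))
  k <- as.integer(k)
  nt <- dim(vol$data)[4]
  if (k < 0L) stop("'k' must be non-negative")
  if (k >= nt)
    stop(sprintf("cannot discard %d volumes from a series of %d", k, nt))
  if (k == 0L) return(vol)
  volume4d(vol$data[, , , (k + 1L):nt, drop = FALSE],
           affine = vol$affine, tr_seconds = vol$tr_seconds)
}

#' Remove linear signal drift from a time series
#'
#' Subtracts the ordinary-least-squares line of value on time index. The
#' residual series has zero mean and zero refitted slope; slow scanner drift
#' is removed while the rank structure that permutation entropy reads is
#' otherwise altered as little as a linear model allows. Note that
#' detrending is not a monotone transform, so PE before and after detrending
#' differ — the stage must run before entropy computation, as the pipeline
#' enforces.
#'
#' @param x Numeric vector (length >= 3) or a matrix with one series per row.
#' @return Residuals, same shape as the input.
#' @export
linear_detrend <- function(x) {
  if (is.matrix(x)) {
    n <- ncol(x)
    if (n < 3L) stop("need at least 3 timepoints to detrend")
    tt <- seq_len(n)
    B <- cbind(1, tt)
    # residual-maker applied from the right: X - X B (B'B)^-1 B'
    H <- B %*% solve(crossprod(B), t(B))
    return(snap_residual_dust(x - x %*% t(H), x))
  }
  if (length(x) < 3L) stop("need at least 3 timepoints to detrend")
  tt <- seq_along(x)
  snap_residual_dust(stats::lsfit(tt, x)$residuals, x)
}

# Residuals below the numerical precision of the fit are exact zeros: an
# exactly linear series must detrend to a constant series, not to rounding
# noise whose rank structure would be arbitrary.
snap_residual_dust <- function(r, x) {
  if (is.matrix(r)) {
    thr <- 1e-10 * apply(abs(x), 1L, max)
    r[apply(abs(r), 1L, max) <= thr, ] <- 0
  } else {
    if (max(abs(r)) <= 1e-10 * max(abs(x))) r[] <- 0
  }
  r
}

#' Regress nuisance covariates out of a time series
#'
#' Residualizes the series on an intercept plus the given regressor matrix
#' (global signal, motion parameters, CSF and WM means, ...). With no
#' regressors this reduces to mean-centering.
#'
#' @param x Numeric vector, the series.
#' @param nuisance Numeric matrix with one row per timepoint (may have zero
#'   columns), or \code{NULL} for intercept-only.
#' @return Residual series, same length as \code{x}.
#' @export
regress_nuisance <- function(x, nuisance = NULL) {
  n <- length(x)
  if (is.null(nuisance)) nuisance <- matrix(numeric(0), n, 0)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != n)
    stop(sprintf("nuisance rows (%d) do not match series length (%d)",
                 nrow(nuisance), n))
  X <- cbind(`(intercept)` = 1, nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  qr.resid(qrX, x)
}

#' Assemble a nuisance regressor set
#'
#' Binds the supplementary-analysis regressors — global signal, six motion
#' parameters, CSF mean, WM mean — into one labelled matrix, checking row
#' agreement. Components that are unavailable are simply omitted rather than
#' synthesized.
#'
#' @param global_signal,csf,wm Optional numeric vectors (one per timepoint).
#' @param motion Optional numeric matrix of motion parameters (timepoints x
#'   6, or any column count).
#' @return Numeric matrix with labelled columns (zero columns if nothing is
#'   supplied).
#' @export
nuisance_set <- function(global_signal = NULL, motion = NULL,
                         csf = NULL, wm = NULL) {
  parts <- list()
  if (!is.null(global_signal)) parts$global <- as.numeric(global_signal)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    parts$motion <- motion
  }
  if (!is.null(csf)) parts$csf <- as.numeric(csf)
  if (!is.null(wm)) parts$wm <- as.numeric(wm)
  if (!length(parts)) return(matrix(numeric(0), 0L, 0L))
  nr <- vapply(parts, NROW, integer(1))
  if (length(unique(nr)) != 1L)
    stop("nuisance components have differing numbers of timepoints")
  do.call(cbind, parts)
}

#' Mean time series over a voxel mask
#'
#' @param vol A [volume4d()].
#' @param mask 3-D logical array matching the volume's spatial shape.
#' @return Numeric vector of per-timepoint means over the masked voxels.
#' @export
extract_mean_signal <- function(vol, mask) {
  stopifnot(inherits(vol, "volume4d"))
  if (!identical(dim(mask), dim(vol$data)[1:3]))
    stop("mask shape does not match the volume")
  if (!any(mask)) stop("mask is empty")
  colMeans(mask_series_matrix(vol$data, array(as.logical(mask), dim(mask))))
}

# Apply discard -> detrend (-> optional nuisance regression) to all in-mask
# voxels and return the preprocessed voxels-by-time matrix plus a stage log.
preprocess_series <- function(vol, mask, discard = 10L, nuisance = NULL) {
  stages <- character(0)
  if (discard > 0L) {
    vol <- drop_initial_volumes(vol, discard)
    stages <- c(stages, sprintf("discard_initial_%d", discard))
  }
  X <- mask_series_matrix(vol$data, mask)
  X <- linear_detrend(X)
  stages <- c(stages, "linear_detrend")
  if (!is.null(nuisance) && NCOL(nuisance) > 0L) {
    X <- t(apply(X, 1L, regress_nuisance, nuisance = nuisance))
    stages <- c(stages, sprintf("regress_nuisance_%d_cols", NCOL(nuisance)))
  }
  list(series = X, stages = stages, affine = vol$affine,
       n_timepoints = ncol(X))
}
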