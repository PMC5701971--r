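GROUP_LEVELS <- c("NC", "EMCI", "LMCI", "AD")

#' Read a cohort design table
#'
#' Expects a delimited file with columns \code{subject_id, group, age, sex,
#' mmse, faq, cdr}. Group labels are ordered NC < EMCI < LMCI < AD (control,
#' early and late mild cognitive impairment, Alzheimer's disease). Sex may be
#' coded 0/1 or M/F (M = 0, F = 1; the mapping is recorded in run manifests).
#'
#' @param path CSV path.
#' @return A data.frame with \code{group} as a factor in canonical order.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "age", "sex", "mmse", "faq", "cdr")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df$group <- factor(df$group, levels = GROUP_LEVELS)
  if (is.character(df$sex)) df$sex <- ifelse(toupper(df$sex) == "F", 1, 0)
  df
}

# Stack a list of volume_maps sharing grid + mask into a subjects x voxels
# matrix over the common mask.
stack_maps <- function(maps) {
  stopifnot(length(maps) >= 2L, all(vapply(maps, inherits, logical(1), "volume_map")))
  mask <- maps[[1]]$mask
  affine <- maps[[1]]$affine
  for (m in maps[-1]) {
    if (!identical(dim(m$mask), dim(mask)))
      stop("subject maps are on different grids")
    mask <- mask & m$mask
  }
  if (!any(mask)) stop("no voxel is inside every subject's mask")
  Y <- t(vapply(maps, function(m) m$data[mask], numeric(sum(mask))))
  list(Y = Y, mask = mask, affine = affine)
}

# Partial F for the group factor at every column of Y (subjects x voxels),
# from full (intercept + covariates + group dummies) vs reduced
# (intercept + covariates) residual sums of squares.
partial_group_f <- function(Y, group, covmat, qr_reduced = NULL, rss_reduced = NULL) {
  n <- nrow(Y)
  group <- droplevels(factor(group))
  G <- nlevels(group)
  if (G < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 subjects")
  Xr <- cbind(1, covmat)
  if (is.null(qr_reduced)) qr_reduced <- qr(Xr)
  dummies <- stats::model.matrix(~group)[, -1, drop = FALSE]
  Xf <- cbind(Xr, dummies)
  qrf <- qr(Xf)
  if (qrf$rank < ncol(Xf)) stop("singular design: group dummies collinear with covariates")
  if (is.null(rss_reduced)) rss_reduced <- colSums(qr.resid(qr_reduced, Y)^2)
  rss_full <- colSums(qr.resid(qrf, Y)^2)
  df1 <- G - 1L
  df2 <- n - ncol(Xf)
  if (df2 < 1L) stop("no residual degrees of freedom")
  # guard against float dust: a reduced model that already fits to machine
  # precision, or a group improvement below relative precision, reads as F = 0
  scale <- colSums(Y^2) + .Machine$double.xmin
  num_raw <- rss_reduced - rss_full
  degenerate <- rss_reduced <= 1e-20 * scale | num_raw <= 1e-12 * rss_reduced
  f <- ifelse(degenerate, 0, (num_raw / df1) / (rss_full / df2))
  list(f = f, df1 = df1, df2 = df2, qr_reduced = qr_reduced,
       rss_reduced = rss_reduced)
}

#' Voxelwise covariate-adjusted group ANOVA
#'
#' At every in-mask voxel, the partial F statistic for the group factor from
#' a linear model with group indicators plus covariate columns (full vs
#' reduced residual-sum-of-squares F with df = (G-1, n-G-c)). With no
#' covariates this is textbook one-way ANOVA; with \code{covariates =
#' c("age", "sex")} it is the adjusted comparison used for group difference
#' mapping.
#'
#' @param maps List of per-subject [volume_map()]s on a common grid, in the
#'   same order as the rows of \code{design}.
#' @param design Cohort data.frame (see [read_cohort()]).
#' @param covariates Character vector of design columns to adjust for
#'   (default \code{c("age", "sex")}; use \code{NULL} for unadjusted).
#' @return List with \code{f_map} and \code{p_map} ([volume_map()]s) and the
#'   degrees of freedom \code{df1}, \code{df2}.
#' @export
voxelwise_group_f <- function(maps, design, covariates = c("age", "sex")) {
  if (length(maps) != nrow(design))
    stop("number of maps does not match the number of design rows")
  st <- stack_maps(maps)
  covmat <- covariate_matrix(design, covariates)
  res <- partial_group_f(st$Y, design$group, covmat)
  p <- stats::pf(res$f, res$df1, res$df2, lower.tail = FALSE)
  list(f_map = volume_map(unmask_map(res$f, st$mask), st$affine, st$mask),
       p_map = volume_map(unmask_map(p, st$mask), st$affine, st$mask),
       df1 = res$df1, df2 = res$df2)
}

covariate_matrix <- function(design, covariates) {
  if (is.null(covariates) || !length(covariates))
    return(matrix(numeric(0), nrow(design), 0L))
  missing_cols <- setdiff(covariates, names(design))
  if (length(missing_cols))
    stop("covariate column(s) not in design: ", paste(missing_cols, collapse = ", "))
  cm <- as.matrix(design[, covariates, drop = FALSE])
  if (anyNA(cm)) stop("covariates must be complete for adjusted models")
  storage.mode(cm) <- "double"
  cm
}

# Half-space neighbor offsets for 6/18/26-connectivity component labelling.
conn_offsets <- function(connectivity = 6L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  g <- switch(as.character(connectivity),
              "6"  = g[ord == 1L, , drop = FALSE],
              "18" = g[ord >= 1L & ord <= 2L, , drop = FALSE],
              "26" = g[ord >= 1L, , drop = FALSE],
              stop("'connectivity' must be 6, 18 or 26"))
  # keep one of each +/- pair
  keep <- apply(g, 1L, function(o) { nz <- o[o != 0]; nz[1] > 0 })
  g[keep, , drop = FALSE]
}

# Label connected components of a logical 3-D array. Returns membership per
# TRUE voxel (in `which` order), their linear indices, and component sizes.
label_clusters <- function(flag, connectivity = 6L) {
  d <- dim(flag)
  idx <- which(flag)
  if (!length(idx))
    return(list(membership = integer(0), idx = integer(0), sizes = integer(0)))
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  offs <- conn_offsets(connectivity)
  edges <- list()
  for (off in seq_len(nrow(offs))) {
    o <- offs[off, ]
    nb <- sweep(coords, 2L, o, "+")
    inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(inside)) next
    src <- which(inside)
    npos <- pos[nb[src, , drop = FALSE]]
    hit <- npos > 0L
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(src[hit], npos[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  list(membership = comp$membership, idx = idx, sizes = as.integer(comp$csize))
}

# Max connected-component size among voxels where f > f_crit.
max_cluster_size <- function(f_vals, mask, f_crit, connectivity) {
  flag <- array(FALSE, dim(mask))
  flag[mask] <- f_vals > f_crit
  lab <- label_clusters(flag, connectivity)
  if (!length(lab$sizes)) 0L else max(lab$sizes)
}

#' Permutation-based cluster-extent thresholding
#'
#' Forms clusters of voxels whose parametric group-F p-value falls below
#' \code{p_voxel} (default 0.005) and assesses each cluster's extent against
#' a familywise null distribution of maximum cluster sizes obtained by
#' permuting group labels (covariates held fixed) \code{n_perm} times. A
#' cluster is retained when its permutation familywise p-value
#' \code{(1 + #\{null >= size\}) / (n_perm + 1)} is at most
#' \code{extent_alpha}. This replaces parametric random-field cluster
#' correction with an assumption-light resampling scheme.
#'
#' @param maps,design,covariates As in [voxelwise_group_f()].
#' @param p_voxel Voxel-forming p threshold (default 0.005).
#' @param n_perm Number of label permutations (>= 100 unless \code{force}).
#' @param extent_alpha Familywise alpha for cluster extent (default 0.05).
#' @param connectivity Cluster connectivity: 6 (face, default), 18 or 26.
#' @param force Allow fewer than 100 permutations.
#' @return List with \code{clusters} (list of records: \code{name, size,
#'   peak_f, peak_ijk, peak_xyz, p_fwe, voxels}), the observed \code{f_map},
#'   \code{null_max_size}, and the size threshold \code{size_crit} (the
#'   (1 - extent_alpha) null quantile).
#' @export
cluster_threshold <- function(maps, design, covariates = c("age", "sex"),
                              p_voxel = 0.005, n_perm = 1000L,
                              extent_alpha = 0.05, connectivity = 6L,
                              force = FALSE) {
  if (p_voxel <= 0 || p_voxel >= 1) stop("'p_voxel' must be in (0, 1)")
  if (n_perm < 100L && !force)
    stop("n_perm < 100 gives a useless null; use force = TRUE to override")
  st <- stack_maps(maps)
  covmat <- covariate_matrix(design, covariates)
  obs <- partial_group_f(st$Y, design$group, covmat)
  f_crit <- stats::qf(1 - p_voxel, obs$df1, obs$df2)

  flag <- array(FALSE, dim(st$mask))
  flag[st$mask] <- obs$f > f_crit
  lab <- label_clusters(flag, connectivity)

  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    # a shuffled labelling can be collinear with the covariates in small
    # cohorts; such permutations are invalid designs and are redrawn
    pf_ <- NULL
    for (try in 1:25) {
      pf_ <- tryCatch(
        partial_group_f(st$Y, sample(design$group), covmat,
                        qr_reduced = obs$qr_reduced,
                        rss_reduced = obs$rss_reduced),
        error = function(e) NULL)
      if (!is.null(pf_)) break
    }
    if (is.null(pf_))
      stop("could not draw a non-singular label permutation; cohort too small")
    null_max[b] <- max_cluster_size(pf_$f, st$mask, f_crit, connectivity)
  }
  size_crit <- stats::quantile(null_max, 1 - extent_alpha, type = 1, names = FALSE)

  f_arr <- unmask_map(obs$f, st$mask)
  clusters <- list()
  if (length(lab$sizes)) {
    for (ci in order(lab$sizes, decreasing = TRUE)) {
      members <- lab$idx[lab$membership == ci]
      size <- length(members)
      p_fwe <- (1 + sum(null_max >= size)) / (n_perm + 1)
      if (p_fwe > extent_alpha) next
      fv <- f_arr[members]
      peak_lin <- members[which.max(fv)]
      peak_ijk <- drop(arrayInd(peak_lin, dim(st$mask)))
      clusters[[length(clusters) + 1L]] <- list(
        name = sprintf("cluster%02d", length(clusters) + 1L),
        size = size,
        peak_f = max(fv),
        peak_ijk = peak_ijk,
        peak_xyz = drop(voxel_to_world(st$affine, matrix(peak_ijk, 1L))),
        p_fwe = p_fwe,
        voxels = arrayInd(members, dim(st$mask)))
    }
  }
  list(clusters = clusters,
       f_map = volume_map(f_arr, st$affine, st$mask),
       df1 = obs$df1, df2 = obs$df2, f_crit = f_crit,
       null_max_size = null_max, size_crit = size_crit)
}

#' Spherical ROI mask from a world-space center
#'
#' Marks every voxel whose center lies within \code{radius} mm (Euclidean,
#' world space) of the given center; the voxel containing the center is
#' always included, so radius 0 selects exactly that voxel. No
#' partial-volume weighting.
#'
#' @param center Numeric length-3 world (MNI) coordinate in mm.
#' @param radius Sphere radius in mm (default 8, the ROI radius used for
#'   peak-coordinate spheres).
#' @param affine 4x4 voxel-to-world matrix of the target grid.
#' @param shape Integer length-3 grid shape.
#' @return 3-D logical array.
#' @export
sphere_roi_mask <- function(center, radius = 8, affine, shape) {
  if (radius < 0) stop("'radius' must be non-negative")
  shape <- as.integer(shape)
  ijk <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                               k = seq_len(shape[3])))
  xyz <- voxel_to_world(affine, ijk)
  d2 <- colSums((t(xyz) - center)^2)
  mask <- array(d2 <= radius^2, dim = shape)
  home <- round(drop(world_to_voxel(affine, matrix(center, 1L))))
  if (all(home >= 1) && all(home <= shape))
    mask[home[1], home[2], home[3]] <- TRUE
  if (!any(mask))
    stop("ROI sphere lies entirely outside the grid")
  mask
}

#' Mean of a map over an ROI mask
#'
#' @param map A [volume_map()].
#' @param roi_mask 3-D logical array (e.g. from [sphere_roi_mask()]).
#' @return Scalar mean over the intersection with the map's mask.
#' @export
roi_mean <- function(map, roi_mask) tissue_mean(map, roi_mask)

#' Pairwise post-hoc t tests with Bonferroni correction
#'
#' All pairwise two-sample t tests between groups on per-subject scalars
#' (pooled-variance by default, Welch by flag), with the raw p multiplied by
#' the number of pairs and capped at 1. Pairs involving a group with fewer
#' than 2 subjects are skipped with a warning.
#'
#' @param values Numeric vector of per-subject scalars (e.g. ROI mean PE).
#' @param group Factor of group labels, same length.
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return Data.frame with columns \code{group1, group2, t, df, mean_diff,
#'   p, p_bonf}.
#' @export
posthoc_pairwise <- function(values, group, welch = FALSE) {
  group <- droplevels(factor(group, levels = intersect(GROUP_LEVELS, unique(as.character(group)))))
  lev <- levels(group)
  if (length(lev) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(lev, 2L)
  n_pairs <- ncol(pairs)
  rows <- list()
  for (pi in seq_len(n_pairs)) {
    g1 <- pairs[1, pi]; g2 <- pairs[2, pi]
    x1 <- values[group == g1]; x2 <- values[group == g2]
    if (length(x1) < 2L || length(x2) < 2L) {
      warning(sprintf("pair %s-%s skipped: a group has < 2 subjects", g1, g2),
              call. = FALSE)
      next
    }
    tt <- stats::t.test(x1, x2, var.equal = !welch)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = g1, group2 = g2,
      t = unname(tt$statistic), df = unname(tt$parameter),
      mean_diff = mean(x1) - mean(x2),
      p = tt$p.value, p_bonf = min(1, tt$p.value * n_pairs))
  }
  if (!length(rows)) stop("no testable group pair")
  do.call(rbind, rows)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Write cluster and correlation result tables
#'
#' Emits the analysis outputs as delimited text: a cluster table (region
#' name, peak world coordinates, extent, peak F, familywise p), a
#' correlation table (ROI x score r and p), and a JSON run manifest.
#'
#' @param clusters List of cluster records (as from [cluster_threshold()]),
#'   possibly empty.
#' @param correlations Data.frame with columns \code{roi, score, r, p, n}
#'   (possibly zero rows), or \code{NULL}.
#' @param dir Output directory (created if needed).
#' @param manifest Named list of run metadata for the JSON manifest.
#' @return Invisible named list of the file paths written.
#' @export
report_tables <- function(clusters, correlations = NULL, dir,
                          manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl_df <- if (length(clusters)) {
    do.call(rbind, lapply(clusters, function(cl) data.frame(
      region = cl$name,
      peak_x = cl$peak_xyz[1], peak_y = cl$peak_xyz[2], peak_z = cl$peak_xyz[3],
      cluster_voxels = cl$size, peak_f = cl$peak_f, p_fwe = cl$p_fwe)))
  } else {
    data.frame(region = character(0), peak_x = numeric(0), peak_y = numeric(0),
               peak_z = numeric(0), cluster_voxels = integer(0),
               peak_f = numeric(0), p_fwe = numeric(0))
  }
  cluster_path <- file.path(dir, "cluster_table.csv")
  utils::write.csv(cl_df, cluster_path, row.names = FALSE)
  paths <- list(cluster_table = cluster_path)
  if (!is.null(correlations)) {
    corr_path <- file.path(dir, "correlation_table.csv")
    utils::write.csv(correlations, corr_path, row.names = FALSE)
    paths$correlation_table <- corr_path
  }
  manifest_path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(c(list(written = format(Sys.time(), tz = "UTC")), manifest),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$manifest <- manifest_path
  invisible(paths)
}
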