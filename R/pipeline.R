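#' Per-subject entropy stage: discard, detrend, PE and ReHo maps, smoothing
#'
#' Runs the enforced temporal stage order — initial-volume discard, linear
#' detrend, optional nuisance regression — then computes the voxelwise
#' permutation-entropy map (and optionally the ReHo map) from the
#' preprocessed series, and finally smooths the resulting maps. Smoothing is
#' deliberately the last stage: smoothing the 4-D data before entropy or
#' concordance computation inflates regional similarity, so it is never
#' offered.
#'
#' @param vol A [volume4d()].
#' @param mask 3-D logical brain mask (\code{NULL} = all voxels).
#' @param params A [pe_params()] object.
#' @param discard Initial volumes to drop (default 10).
#' @param fwhm_mm Smoothing FWHM in mm for the output maps (default 8; 0
#'   disables smoothing).
#' @param nuisance Optional nuisance regressor matrix (rows = retained
#'   timepoints), see [nuisance_set()].
#' @param compute_reho Also compute the ReHo map (default TRUE).
#' @param neighborhood ReHo cluster size (7/19/27).
#' @param force Propagated to [pe_map()] parameter validation.
#' @return List with \code{pe}, \code{reho} (smoothed [volume_map()]s;
#'   \code{reho} may be NULL) and \code{stages} (ordered character log).
#' @export
run_entropy_stage <- function(vol, mask = NULL, params = pe_params(),
                              discard = 10L, fwhm_mm = 8, nuisance = NULL,
                              compute_reho = TRUE, neighborhood = 27L,
                              force = FALSE) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mask <- array(as.logical(mask), d[1:3])
  prep <- preprocess_series(vol, mask, discard = discard, nuisance = nuisance)
  prep_vol <- volume4d(
    array(t_fill(prep$series, mask, prep$n_timepoints), c(d[1:3], prep$n_timepoints)),
    affine = vol$affine, tr_seconds = vol$tr_seconds)
  stages <- prep$stages
  pe <- pe_map(prep_vol, mask, params, force = force)
  stages <- c(stages, sprintf("pe_map_m%d_l%d", params$m, params$l))
  reho <- NULL
  if (compute_reho) {
    reho <- reho_map(prep_vol, mask, neighborhood = neighborhood)
    stages <- c(stages, sprintf("reho_map_k%d", neighborhood))
  }
  if (fwhm_mm > 0) {
    pe <- gaussian_smooth_map(pe, fwhm_mm)
    if (!is.null(reho)) reho <- gaussian_smooth_map(reho, fwhm_mm)
    stages <- c(stages, sprintf("gaussian_smooth_fwhm%gmm", fwhm_mm))
  }
  list(pe = pe, reho = reho, stages = stages)
}

# Scatter a voxels x time matrix back into a flat (voxels_total x time)
# layout with zeros outside the mask.
t_fill <- function(series, mask, nt) {
  flat <- matrix(0, length(mask), nt)
  flat[as.vector(mask), ] <- series
  flat
}

#' Group-level stage: ANOVA, clusters, ROI battery, correlations
#'
#' Reproduces the group-analysis graph: covariate-adjusted voxelwise group
#' ANOVA with permutation cluster-extent correction; ROI definition as 8-mm
#' spheres at detected cluster peaks (or a user-supplied ROI table);
#' per-subject ROI means; pairwise Bonferroni-corrected post-hoc tests; and
#' Pearson correlations of ROI PE with the clinical scores (MMSE, FAQ, CDR)
#' and, when available, with ROI ReHo and any auxiliary subject-level maps
#' (e.g. gray-matter volume or SUVR images). Score and map correlations are
#' computed in the pooled patient groups (EMCI+LMCI+AD) by default.
#'
#' @param pe_maps List of per-subject PE [volume_map()]s, ordered as
#'   \code{design} rows.
#' @param design Cohort data.frame ([read_cohort()] schema).
#' @param reho_maps Optional list of per-subject ReHo maps.
#' @param aux_maps Optional named list; each element a list of per-subject
#'   [volume_map()]s (e.g. \code{list(gmv = ...)}).
#' @param covariates Adjustment columns (default age + sex).
#' @param p_voxel,n_perm,extent_alpha,connectivity See [cluster_threshold()].
#' @param roi_table Optional data.frame \code{name, x, y, z, radius}
#'   overriding peak-derived ROIs.
#' @param roi_radius Radius for peak-derived ROI spheres (default 8 mm).
#' @param pool \code{"patients"} (EMCI+LMCI+AD, default) or \code{"all"}
#'   for the correlation analyses.
#' @param out_dir Optional directory for [report_tables()] output.
#' @param force Propagated to [cluster_threshold()].
#' @return List with \code{anova} (f/p maps + df), \code{clusters},
#'   \code{rois} (named list of masks), \code{roi_values} (subjects x ROI
#'   matrix of PE means), \code{posthoc} (named list of tables),
#'   \code{correlations} (long data.frame), and \code{paths} when
#'   \code{out_dir} was given.
#' @export
run_group_stage <- function(pe_maps, design, reho_maps = NULL, aux_maps = NULL,
                            covariates = c("age", "sex"), p_voxel = 0.005,
                            n_perm = 1000L, extent_alpha = 0.05,
                            connectivity = 6L, roi_table = NULL,
                            roi_radius = 8, pool = c("patients", "all"),
                            out_dir = NULL, force = FALSE) {
  pool <- match.arg(pool)
  anova <- voxelwise_group_f(pe_maps, design, covariates)
  cl <- cluster_threshold(pe_maps, design, covariates, p_voxel = p_voxel,
                          n_perm = n_perm, extent_alpha = extent_alpha,
                          connectivity = connectivity, force = force)
  affine <- pe_maps[[1]]$affine
  shape <- dim(pe_maps[[1]]$data)

  if (is.null(roi_table)) {
    roi_table <- if (length(cl$clusters)) {
      do.call(rbind, lapply(cl$clusters, function(c2) data.frame(
        name = c2$name, x = c2$peak_xyz[1], y = c2$peak_xyz[2],
        z = c2$peak_xyz[3], radius = roi_radius)))
    } else {
      data.frame(name = character(0), x = numeric(0), y = numeric(0),
                 z = numeric(0), radius = numeric(0))
    }
  }
  rois <- list()
  for (ri in seq_len(nrow(roi_table)))
    rois[[roi_table$name[ri]]] <- sphere_roi_mask(
      c(roi_table$x[ri], roi_table$y[ri], roi_table$z[ri]),
      roi_table$radius[ri], affine, shape)

  roi_values <- roi_value_matrix(pe_maps, rois)
  posthoc <- lapply(seq_along(rois), function(ri)
    posthoc_pairwise(roi_values[, ri], design$group))
  names(posthoc) <- names(rois)

  sel <- if (pool == "patients") design$group != "NC" else rep(TRUE, nrow(design))
  correlations <- correlation_battery(roi_values, design, sel,
                                      reho_maps = reho_maps,
                                      aux_maps = aux_maps, rois = rois)

  paths <- NULL
  if (!is.null(out_dir)) {
    manifest <- list(covariates = covariates, p_voxel = p_voxel,
                     n_perm = n_perm, extent_alpha = extent_alpha,
                     connectivity = connectivity, pool = pool,
                     sex_coding = "0 = male, 1 = female",
                     n_subjects = nrow(design),
                     rois = names(rois))
    paths <- report_tables(cl$clusters, correlations, out_dir, manifest)
    write_nifti_map(anova$f_map, file.path(out_dir, "group_f.nii.gz"),
                    meta = list(statistic = "partial F for group",
                                df = c(anova$df1, anova$df2)))
    write_nifti_map(anova$p_map, file.path(out_dir, "group_p.nii.gz"))
  }
  list(anova = anova, clusters = cl, rois = rois, roi_values = roi_values,
       posthoc = posthoc, correlations = correlations, paths = paths)
}

roi_value_matrix <- function(maps, rois) {
  out <- matrix(NA_real_, length(maps), length(rois),
                dimnames = list(NULL, names(rois)))
  for (ri in seq_along(rois))
    out[, ri] <- vapply(maps, roi_mean, numeric(1), roi_mask = rois[[ri]])
  out
}

# Long table of Pearson correlations: ROI PE vs clinical scores, vs ROI ReHo,
# vs ROI means of any auxiliary map set, over the selected subjects.
correlation_battery <- function(roi_values, design, sel, reho_maps = NULL,
                                aux_maps = NULL, rois = NULL) {
  rows <- list()
  add <- function(roi, score, ct) {
    rows[[length(rows) + 1L]] <<- data.frame(
      roi = roi, score = score, r = ct$r, p = ct$p, n = ct$n)
  }
  scores <- c("mmse", "faq", "cdr")
  for (ri in seq_len(ncol(roi_values))) {
    pe_v <- roi_values[sel, ri]
    for (sc in scores) {
      y <- design[[sc]][sel]
      if (stats::sd(y) == 0 || stats::sd(pe_v) == 0) next
      add(colnames(roi_values)[ri], sc, pearson_corr(pe_v, y))
    }
  }
  extra <- list()
  if (!is.null(reho_maps)) extra$reho <- reho_maps
  if (!is.null(aux_maps)) extra <- c(extra, aux_maps)
  for (label in names(extra)) {
    other <- roi_value_matrix(extra[[label]], rois)
    for (ri in seq_len(ncol(roi_values))) {
      pe_v <- roi_values[sel, ri]
      ov <- other[sel, ri]
      if (stats::sd(ov) == 0 || stats::sd(pe_v) == 0) next
      add(colnames(roi_values)[ri], label, pearson_corr(pe_v, ov))
    }
  }
  if (!length(rows))
    return(data.frame(roi = character(0), score = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0)))
  do.call(rbind, rows)
}

#' End-to-end pipeline on a synthetic cohort
#'
#' Convenience wrapper: simulate a cohort in memory, run the entropy stage
#' per subject inside the synthetic brain mask, then the group stage with
#' the implanted effect regions also reported as fixed ROIs.
#'
#' @param spec A [synthetic_spec()].
#' @param n_perm Permutations for cluster correction.
#' @param fwhm_mm Map smoothing FWHM.
#' @param use_effect_rois Use the implanted effect regions as the ROI set
#'   (default TRUE; otherwise ROIs come from detected cluster peaks).
#' @param out_dir Optional output directory for tables and maps.
#' @param force Propagated to both stages' parameter validation.
#' @param ... Passed to [run_group_stage()].
#' @return List with \code{cohort}, \code{entropy} (per-subject stage
#'   outputs), and \code{group} (group-stage results).
#' @export
run_pipeline <- function(spec, n_perm = 200L, fwhm_mm = 8,
                         use_effect_rois = TRUE, out_dir = NULL, force = FALSE,
                         ...) {
  cohort <- simulate_cohort(spec)
  brain <- cohort$masks$brain
  entropy <- lapply(cohort$volumes, run_entropy_stage, mask = brain,
                    fwhm_mm = fwhm_mm, force = force)
  pe_maps <- lapply(entropy, `[[`, "pe")
  reho_maps <- lapply(entropy, `[[`, "reho")
  roi_table <- NULL
  if (use_effect_rois) {
    roi_table <- do.call(rbind, lapply(spec$effect_regions, function(reg)
      data.frame(name = reg$name, x = reg$center[1], y = reg$center[2],
                 z = reg$center[3], radius = reg$radius)))
  }
  group <- run_group_stage(pe_maps, cohort$design, reho_maps = reho_maps,
                           n_perm = n_perm, roi_table = roi_table,
                           out_dir = out_dir, force = force, ...)
  list(cohort = cohort, entropy = entropy, group = group)
}
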