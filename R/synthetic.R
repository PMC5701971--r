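#' Specification for a synthetic resting-state cohort
#'
#' Describes a fully self-contained synthetic cohort whose structure mirrors
#' a four-group clinical resting-state study: NC/EMCI/LMCI/AD groups of
#' 30/33/32/29 subjects, 140-volume BOLD series at TR = 3 s (130 retained
#' after the standard 10-volume discard), group-dependent temporal
#' regularity implanted in spherical "effect" regions, neighborhood signal
#' sharing that raises ReHo with disease severity, and clinical scores
#' statistically coupled to the implanted regularity.
#'
#' Temporal regularity is controlled by an AR(1) coefficient phi: background
#' voxels use \code{phi_background}, effect-region voxels a subject-level
#' latent \code{theta} drawn around the group value \code{phi_group}. Higher
#' phi gives more regular series and hence lower permutation entropy, so the
#' default group gradient (NC 0.30 < EMCI 0.40 < LMCI 0.50 < AD 0.65 against
#' a 0.30 background) implants the patient-ward complexity decrease. A
#' shared series per effect region is mixed in with weight
#' \code{sqrt(rho_group)}, raising regional concordance (ReHo) with
#' severity. Scores are linear in theta (MMSE decreasing, FAQ increasing)
#' with additive noise, and CDR follows the group-wise clinical convention
#' (NC 0, EMCI/LMCI 0.5, AD 0.5 or 1).
#'
#' @param shape Grid shape in voxels (default 20 x 24 x 20).
#' @param voxel_mm Isotropic voxel size in mm (default 3).
#' @param timepoints Acquired volumes per subject, pre-discard (default 140).
#' @param tr_seconds Repetition time (default 3).
#' @param group_sizes Named integer vector NC/EMCI/LMCI/AD (default
#'   30/33/32/29).
#' @param phi_background Background AR(1) coefficient (default 0.30).
#' @param phi_group Named per-group effect-region AR(1) coefficients.
#' @param rho_group Named per-group shared-signal fractions in effect
#'   regions (variance proportion; default 0.20/0.30/0.40/0.55).
#' @param theta_sd SD of the subject-level jitter around the group phi
#'   (default 0.05; draws are truncated to \[0, 0.95\]).
#' @param effect_regions List of spheres \code{list(name, center, radius)}
#'   in world mm; \code{NULL} gives two 9-mm spheres at (-15, 0, 0) and
#'   (15, 0, 0).
#' @param score_model Coefficients for the clinical-score coupling:
#'   \code{mmse} and \code{faq} each \code{c(intercept, slope, sd)} applied
#'   to theta, and \code{cdr_ad_p1}, the probability an AD subject has CDR 1
#'   rather than 0.5.
#' @param age_mean,age_sd Age distribution (truncated to \[55, 90\]).
#' @param seed Master seed for [simulate_cohort()].
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(shape = c(20L, 24L, 20L),
                           voxel_mm = 3,
                           timepoints = 140L,
                           tr_seconds = 3,
                           group_sizes = c(NC = 30L, EMCI = 33L, LMCI = 32L, AD = 29L),
                           phi_background = 0.30,
                           phi_group = c(NC = 0.30, EMCI = 0.40, LMCI = 0.50, AD = 0.65),
                           rho_group = c(NC = 0.20, EMCI = 0.30, LMCI = 0.40, AD = 0.55),
                           theta_sd = 0.05,
                           effect_regions = NULL,
                           score_model = list(mmse = c(intercept = 35.7, slope = -22.6, sd = 2.0),
                                              faq = c(intercept = -12.6, slope = 42.5, sd = 3.0),
                                              cdr_ad_p1 = 0.68),
                           age_mean = 73, age_sd = 6,
                           seed = 20240101L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L), voxel_mm > 0,
            timepoints >= 20L, all(GROUP_LEVELS %in% names(group_sizes)),
            all(group_sizes >= 2L))
  if (phi_background < 0 || phi_background >= 1 ||
      any(phi_group < 0) || any(phi_group >= 1))
    stop("AR coefficients must lie in [0, 1)")
  if (any(rho_group < 0) || any(rho_group > 1))
    stop("shared-signal fractions must lie in [0, 1]")
  # grid centered on the world origin
  origin <- -(shape - 1) / 2 * voxel_mm
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- origin
  if (is.null(effect_regions)) {
    r <- min((shape - 1) * voxel_mm) / 6
    effect_regions <- list(
      list(name = "effectA", center = c(-2 * r, 0, 0), radius = r),
      list(name = "effectB", center = c(2 * r, 0, 0), radius = r))
  }
  for (reg in effect_regions) {
    v <- world_to_voxel(affine, matrix(reg$center, 1L))
    if (any(v < 1) || any(v > shape))
      stop("effect region '", reg$name, "' lies outside the grid")
  }
  structure(list(shape = shape, voxel_mm = voxel_mm, affine = affine,
                 timepoints = as.integer(timepoints), tr_seconds = tr_seconds,
                 group_sizes = group_sizes[GROUP_LEVELS],
                 phi_background = phi_background,
                 phi_group = phi_group[GROUP_LEVELS],
                 rho_group = rho_group[GROUP_LEVELS],
                 theta_sd = theta_sd,
                 effect_regions = effect_regions,
                 score_model = score_model,
                 age_mean = age_mean, age_sd = age_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: %dx%dx%d @ %g mm, %d timepoints, %d subjects (%s)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_mm, x$timepoints,
              sum(x$group_sizes),
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  cat(sprintf("  phi: background %.2f, groups %s\n", x$phi_background,
              paste(sprintf("%.2f", x$phi_group), collapse = "/")))
  invisible(x)
}

# Geometric tissue partition of the grid: an ellipsoid "brain" split into a
# CSF core (mock ventricles), a WM shell and a GM rind by normalized radius.
# Purely synthetic stand-ins to exercise tissue-level summaries.
tissue_masks <- function(spec) {
  ijk <- as.matrix(expand.grid(i = seq_len(spec$shape[1]),
                               j = seq_len(spec$shape[2]),
                               k = seq_len(spec$shape[3])))
  xyz <- voxel_to_world(spec$affine, ijk)
  semi <- (spec$shape - 1) / 2 * spec$voxel_mm
  re <- sqrt(colSums((t(xyz) / semi)^2))
  dim(re) <- spec$shape
  list(brain = re <= 1,
       csf = re <= 0.25,
       wm = re > 0.25 & re <= 0.6,
       gm = re > 0.6 & re <= 1)
}

effect_region_masks <- function(spec) {
  ms <- lapply(spec$effect_regions, function(reg)
    sphere_roi_mask(reg$center, reg$radius, spec$affine, spec$shape))
  names(ms) <- vapply(spec$effect_regions, `[[`, character(1), "name")
  ms
}

#' Simulate one voxel's BOLD-like series
#'
#' Draws a stationary unit-marginal-variance AR(1) series
#' \code{x_t = phi x_(t-1) + eps_t} (innovation SD \code{sqrt(1 - phi^2)}),
#' then, if a shared series is supplied, mixes it in as
#' \code{sqrt(rho) * shared + sqrt(1 - rho) * x}. Higher phi gives a more
#' regular series (lower permutation entropy); higher rho raises local
#' concordance with neighbors driven by the same shared series.
#'
#' @param phi AR(1) coefficient in \[0, 1).
#' @param n Number of timepoints.
#' @param rho Shared-signal variance fraction in \[0, 1\].
#' @param shared Optional shared series of length \code{n} (required when
#'   \code{rho > 0}).
#' @return Numeric vector of length \code{n}.
#' @export
simulate_voxel_series <- function(phi, n, rho = 0, shared = NULL) {
  if (phi < 0 || phi >= 1) stop("'phi' must lie in [0, 1)")
  if (rho < 0 || rho > 1) stop("'rho' must lie in [0, 1]")
  x <- drop(ar1_matrix(1L, n, phi))
  if (rho > 0) {
    if (is.null(shared) || length(shared) != n)
      stop("'shared' must be supplied with length n when rho > 0")
    x <- sqrt(rho) * shared + sqrt(1 - rho) * x
  }
  x
}

# V stationary AR(1) series of length n with unit marginal variance; phi may
# be a scalar or a length-V vector.
ar1_matrix <- function(V, n, phi) {
  phi <- rep_len(phi, V)
  innov_sd <- sqrt(1 - phi^2)
  X <- matrix(0, V, n)
  X[, 1] <- stats::rnorm(V)
  for (t in 2:n)
    X[, t] <- phi * X[, t - 1] + stats::rnorm(V, sd = innov_sd)
  X
}

#' Simulate one subject's 4-D volume
#'
#' Background voxels follow an AR(1) with \code{spec$phi_background};
#' effect-region voxels use the subject's latent regularity \code{theta} and
#' are mixed with one shared AR(1) series per effect region at fraction
#' \code{rho}. The full acquisition length (default 140 timepoints) is
#' produced; the pipeline discards the initial volumes itself.
#'
#' @param spec A [synthetic_spec()].
#' @param theta Subject's effect-region AR(1) coefficient.
#' @param rho Subject's shared-signal fraction.
#' @param seed Optional integer; when given, the RNG is seeded so the
#'   volume is bit-reproducible in isolation.
#' @return A [volume4d()].
#' @export
simulate_subject <- function(spec, theta, rho, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  V <- prod(spec$shape)
  nt <- spec$timepoints
  regions <- effect_region_masks(spec)
  phi_vox <- rep(spec$phi_background, V)
  for (rm in regions) phi_vox[as.vector(rm)] <- theta
  X <- ar1_matrix(V, nt, phi_vox)
  for (rm in regions) {
    if (rho > 0) {
      shared <- drop(ar1_matrix(1L, nt, theta))
      sel <- as.vector(rm)
      X[sel, ] <- sqrt(rho) * matrix(shared, sum(sel), nt, byrow = TRUE) +
        sqrt(1 - rho) * X[sel, , drop = FALSE]
    }
  }
  volume4d(array(X, dim = c(spec$shape, nt)), affine = spec$affine,
           tr_seconds = spec$tr_seconds)
}

# Truncated-normal draw by rejection (bounds well within 4 SD here).
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lower | out > upper
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lower | out > upper
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates the cohort design (groups, ages, sexes, latent regularity
#' theta, clinical scores coupled to theta) and one 4-D volume per subject,
#' plus the synthetic tissue masks and a "truth" record of every latent
#' value for recovery tests. With \code{dir} given, volumes and masks are
#' written as NIfTI, the design as \code{cohort.csv}, and the truth record
#' as \code{truth.json}; otherwise everything is returned in memory.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory.
#' @param volumes Generate the 4-D volumes (default TRUE); \code{FALSE}
#'   produces the design, masks and truth record only (the design draws are
#'   unchanged either way).
#' @param verbose Print a short progress note per 25 subjects.
#' @return A list with \code{design} (data.frame), \code{volumes} (list of
#'   [volume4d()], \code{NULL} when written to disk), \code{paths} (when
#'   \code{dir} given), \code{masks} (tissue + effect-region masks),
#'   \code{truth} (latent parameters incl. any score clipping), and
#'   \code{spec}.
#' @export
simulate_cohort <- function(spec, dir = NULL, volumes = TRUE, verbose = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  sizes <- spec$group_sizes
  n <- sum(sizes)
  group <- factor(rep(GROUP_LEVELS, times = sizes), levels = GROUP_LEVELS)
  id <- sprintf("S%03d", seq_len(n))

  theta <- pmin(pmax(spec$phi_group[as.character(group)] +
                       stats::rnorm(n, 0, spec$theta_sd), 0), 0.95)
  rho <- spec$rho_group[as.character(group)]
  age <- round(rtrunc_norm(n, spec$age_mean, spec$age_sd, 55, 90), 1)
  sex <- unlist(lapply(sizes, function(k) rep_len(c(0L, 1L), k)), use.names = FALSE)

  sm <- spec$score_model
  mmse_raw <- sm$mmse["intercept"] + sm$mmse["slope"] * theta +
    stats::rnorm(n, 0, sm$mmse["sd"])
  faq_raw <- sm$faq["intercept"] + sm$faq["slope"] * theta +
    stats::rnorm(n, 0, sm$faq["sd"])
  mmse <- pmin(pmax(round(mmse_raw), 0), 30)
  faq <- pmin(pmax(round(faq_raw), 0), 50)
  cdr <- ifelse(group == "NC", 0,
                ifelse(group == "AD",
                       ifelse(stats::runif(n) < sm$cdr_ad_p1, 1, 0.5), 0.5))

  design <- data.frame(subject_id = id, group = group, age = age, sex = sex,
                       mmse = as.numeric(mmse), faq = as.numeric(faq),
                       cdr = cdr, stringsAsFactors = FALSE)
  truth <- list(seed = spec$seed,
                theta = stats::setNames(theta, id),
                rho = stats::setNames(as.numeric(rho), id),
                phi_background = spec$phi_background,
                effect_regions = spec$effect_regions,
                mmse_clipped = id[mmse_raw > 30 | mmse_raw < 0],
                faq_clipped = id[faq_raw > 50 | faq_raw < 0])
  n_clip <- length(truth$mmse_clipped) + length(truth$faq_clipped)
  if (n_clip > 0)
    warning(sprintf("%d score value(s) clipped to instrument range (recorded in truth)",
                    n_clip), call. = FALSE)

  masks <- c(tissue_masks(spec), effect_region_masks(spec))
  subject_seeds <- (spec$seed + 7919L * seq_len(n)) %% .Machine$integer.max

  vols <- if (is.null(dir) && volumes) vector("list", n) else NULL
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(cohort = file.path(dir, "cohort.csv"),
                  truth = file.path(dir, "truth.json"))
    if (volumes)
      paths$volumes <- file.path(dir, paste0(id, "_bold.nii.gz"))
  }
  if (volumes) {
    for (i in seq_len(n)) {
      vol <- simulate_subject(spec, theta[i], rho[i], seed = subject_seeds[i])
      if (is.null(dir)) {
        vols[[i]] <- vol
      } else {
        write_nifti_map(vol, paths$volumes[i])
      }
      if (verbose && i %% 25L == 0L)
        message(sprintf("  simulated %d / %d subjects", i, n))
    }
  }
  if (!is.null(dir)) {
    utils::write.csv(design, paths$cohort, row.names = FALSE)
    for (mn in names(masks)) {
      p <- file.path(dir, paste0("mask_", mn, ".nii.gz"))
      write_nifti_map(masks[[mn]] * 1, p, affine = spec$affine)
      paths[[paste0("mask_", mn)]] <- p
    }
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  list(design = design, volumes = vols, paths = paths, masks = masks,
       truth = truth, spec = spec)
}
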