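---
title: "Mapping BOLD signal complexity with permutation entropy"
author: "pemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping BOLD signal complexity with permutation entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemap)
```

## The measurement

Permutation entropy (PE) quantifies the temporal complexity of a signal
through the distribution of its *ordinal patterns*. For a series
$x(1), \dots, x(N)$, embedding dimension $m$ and delay $l$, every window
$\{x(i), x(i+l), \dots, x(i+(m-1)l)\}$ is reduced to the permutation
$(j_1, \dots, j_m)$ that sorts it ascending. Equal values are ordered by
their original position — a stable sort — so every window maps to exactly one
of the $m!$ patterns. With pattern frequencies $P_g$ over the
$N - (m-1)l$ windows,

$$\mathrm{PE} = -\sum_g P_g \ln P_g, \qquad
  \mathrm{PE}_s = \mathrm{PE} / \ln(m!) \in [0, 1].$$

A strictly monotone (or constant) series visits a single pattern and scores
0; a series visiting all patterns equally often scores 1. Because only ranks
enter, $\mathrm{PE}_s$ is invariant under any strictly increasing transform
of the signal — scanner scaling, global intensity normalization and the like
cannot change it. For the same reason the question of whether voxel series
should be variance-normalized before PE is moot, and the package does not do
it.

Two length constraints govern the choice of $m$: all patterns must be able
to occur, $m! \le N - (m-1)l$, and the alphabet must not be undersampled,
$N \ge (m+1)!$. For the 130-timepoint series this pipeline targets
(140 acquired volumes at TR = 3 s, 10 discarded), $m = 4$, $l = 1$ is the
largest admissible setting ($120 \le 130 < 720$), and is the package
default. `validate_pe_params()` returns a verdict rather than raising so
exploratory settings can be logged and forced; the command-line front end
refuses invalid combinations unless `--force` is given.

## The voxelwise pipeline

Per subject, the enforced stage order is

1. **discard** the first 10 volumes (scanner equilibration),
2. **detrend** each voxel linearly (scanner drift),
3. optionally **regress nuisance signals** (global, motion, CSF, WM means),
4. compute the **PE map** (and the **ReHo map**) from the residual series,
5. **smooth the maps** with an 8-mm FWHM Gaussian.

Smoothing must follow, never precede, the entropy computation: smoothing the
4-D data mixes neighboring series and inflates regional similarity. The test
suite demonstrates this directly — pre-smoothed data more than double mean
ReHo on white noise. `run_entropy_stage()` emits an ordered stage log that
is written into each map's JSON sidecar, so the order is auditable per
output file.

Regional homogeneity (ReHo) is Kendall's coefficient of concordance $W$
between each voxel's series and its 26 neighbors (configurable to 6 or 18;
27-member clusters are the default). Ranks are midranks; no tie-correction
term is applied, since continuous BOLD values essentially never tie. At mask
edges the neighbor count simply shrinks, and voxels left with fewer than two
members are excluded rather than padded.

## Group statistics

Group differences are mapped with a covariate-adjusted voxelwise ANOVA: at
each voxel the partial $F$ for the group factor from a single linear model
with group indicators plus age and sex, i.e. the full-versus-reduced
residual-sum-of-squares $F$ with $(G-1,\, n-G-c)$ degrees of freedom. A
single model was preferred over residualize-then-ANOVA because the two
differ (the residualization route ignores the covariate degrees of freedom)
and the model-based partial $F$ is the standard formulation.

Cluster-level inference uses permutation rather than Gaussian-random-field
theory: voxels with parametric $p <$ 0.005 form connected components
(face adjacency by default, configurable to 18/26 — neighborhood conventions
differ across neuroimaging tools, so the choice is explicit rather than
silently matched to any of them), and each component's extent is referred to
the null distribution of the *maximum* cluster size under group-label
shuffling with covariates held fixed. Random-field correction needs
map-smoothness estimation machinery and is fragile at small grid sizes;
label permutation is assumption-light, exact under exchangeability, and its
calibration is itself testable — the suite verifies the familywise error
rate against its nominal level over 200 replicate null cohorts. One caveat
is inherent: cluster *size* is a discrete statistic, and on unsmoothed maps
its null distribution is so coarse that the test becomes conservative;
calibration is therefore demonstrated under the pipeline's operating
conditions (smoothed maps), where sizes vary richly.

ROIs are 8-mm-radius spheres at detected cluster peaks (or any user-supplied
coordinate table). Membership is voxel-center-in-sphere with no
partial-volume weighting; the voxel containing the center is always
included, so a zero radius degenerates to exactly that voxel. Post-hoc
pairwise comparisons use pooled-variance $t$ tests with Bonferroni
correction by the number of pairs (Welch available by flag). Correlations of
ROI PE with MMSE, FAQ and CDR (and with ROI ReHo or any auxiliary
subject-level map, e.g. gray-matter volume or FDG-SUVR images produced
elsewhere) are Pearson correlations over the pooled patient groups
(EMCI+LMCI+AD) by default, with an option to include controls. Treating the
three-valued CDR as numeric in a Pearson correlation is a deliberate
mirroring of common clinical practice and statistically crude; it is kept
because the pipeline's purpose is to reproduce that analysis style, and the
caveat stands here.

## What the synthetic cohort emulates — and what it does not

`synthetic_spec()` describes a four-group cohort (NC/EMCI/LMCI/AD of
30/33/32/29 subjects) of 140-volume series at TR = 3 s on a 20×24×20 grid of
3-mm voxels. Temporal regularity is the single complexity dial: every voxel
follows a stationary unit-variance AR(1) process, background voxels at
$\varphi_0 = 0.30$ and effect-region voxels at a subject-level latent
$\theta_i$ drawn around group means 0.30 / 0.40 / 0.50 / 0.65 (SD 0.05,
truncated to $[0, 0.95]$). AR(1) regularity was chosen over spectral
filtering because it is one parameter, provably monotone in expected PE over
the working range (verified by Monte Carlo with non-overlapping confidence
intervals), and trivial to calibrate. The group gradient was set once so
that the ordering is recoverable at $n \approx 30$ subjects per group with
130 timepoints.

ReHo coupling is implanted by mixing one shared AR(1) series per effect
region into its voxels with variance fraction $\rho$ rising with severity
(0.20 / 0.30 / 0.40 / 0.55), which makes the PE–ReHo correlation negative in
patients. Clinical scores are linear in $\theta_i$ — MMSE decreasing
(≈ 35.7 − 22.6 θ, SD 2), FAQ increasing (≈ −12.6 + 42.5 θ, SD 3), both
anchored to the configured group-φ values so group means land near typical
clinic values, then rounded and clipped to instrument ranges (clipping is
recorded in the truth file); CDR follows the clinical convention (NC 0,
EMCI/LMCI 0.5, AD 0.5 or 1 with probability 0.68 of 1). Ages are
$N(73, 6^2)$ truncated to [55, 90]; sex alternates within group. Tissue
masks are geometric stand-ins: an ellipsoidal "brain" split by normalized
radius into a CSF core, WM shell and GM rind, sufficient to exercise
tissue-level summaries but anatomically meaningless.

The generator deliberately does **not** emulate hemodynamic response shapes,
physiological (cardiac/respiratory) noise, head motion, scanner artifacts,
spatial autocorrelation of real BOLD data, or atrophy. Passing recovery
tests therefore shows that the pipeline correctly extracts the structure
this generative model implants — a necessary condition — not that it would
detect the same structure in clinical data, where effect sizes, noise
spectra and confounds are far less favorable.

## Numerical choices

- **Tie rule.** Equality is exact floating-point equality; tied values take
  position order. No epsilon is used, because an epsilon would make pattern
  identity depend on window alignment.
- **Entropy.** Natural logarithm throughout; $0 \ln 0 = 0$; normalization by
  $\ln(m!)$.
- **Detrending.** Ordinary least squares per voxel. Residuals below
  $10^{-10} \times \max|x|$ of a series are snapped to exact zeros so that
  an exactly linear series detrends to a constant series rather than to
  rounding dust whose rank pattern would be arbitrary.
- **Degenerate ANOVA.** Voxels where the reduced model already fits to
  machine precision, or where the group improvement is below relative
  precision ($10^{-12}$), report $F = 0$ rather than a 0/0 artifact.
- **Smoothing.** Separable discrete Gaussian with
  $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis, truncated at
  $4\sigma$ and renormalized over the in-mask support, so constants are
  preserved exactly and out-of-mask sentinels (stored as NaN, never 0)
  cannot leak in. Bit-level equivalence with any specific neuroimaging
  package's smoother is a non-goal.
- **Determinism.** The cohort generator is fully reproducible from its
  master seed; per-subject volumes are additionally seeded so single
  subjects can be regenerated in isolation.

## Problem sizes in the test suite

The suite exercises the full pipeline at sizes chosen to keep the default
run comfortably interactive while preserving the cohort structure: the
calibration tests use an 18³ null cohort of 32 subjects (≈ 2,500 in-mask
voxels) and 200 replicate 12³ noise cohorts of 24 subjects at 100
permutations each; the recovery tests run the full default 124-subject
cohort 20 times at a reduced 10×12×10 grid with the full 140-timepoint
series. The spatial grid is the only dimension reduced relative to the
default specification; group sizes and series length are kept at their
defaults because the recovery claims are about exactly those sample sizes.

## Known limitations

- The pipeline consumes already-registered volumes; slice timing,
  realignment and spatial normalization are out of scope and must be done
  upstream (their absence is logged loudly by the CLI).
- Permutation cluster correction assumes exchangeability of subjects under
  the null; strong covariate-by-group confounding would violate it.
- Kendall's W omits the tie-correction term; heavily quantized input would
  bias ReHo slightly downward.
- The CDR-as-numeric Pearson correlation caveat above.
- Mask-renormalized smoothing preserves the in-mask mean only approximately
  near mask boundaries (verified to well under 1% on the suite's
  geometries).
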