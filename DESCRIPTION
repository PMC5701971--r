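Package: pemap
Title: Voxelwise Permutation Entropy Mapping for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxelwise permutation entropy (ordinal-pattern Shannon
    entropy) and regional homogeneity (Kendall's W) maps from resting-state
    fMRI volumes, performs covariate-adjusted voxelwise group ANOVA with
    permutation-based cluster-extent correction, sphere-ROI extraction,
    Bonferroni-corrected post-hoc tests and clinical-score correlations, and
    provides a fully synthetic AR(1)-based cohort generator so the entire
    pipeline can be exercised and calibrated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
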