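# Brute-force permutation-entropy oracle: materialize every window, sort it
# lexicographically by (value, original position) — the stated tie rule —
# tally pattern counts, and take Shannon entropy directly. Independent of the
# package's insertion-rank encoding.
pe_brute_force <- function(x, m, l) {
  nw <- length(x) - (m - 1) * l
  pats <- character(nw)
  for (i in seq_len(nw)) {
    w <- x[i + (0:(m - 1)) * l]
    ord <- order(w, seq_along(w))  # explicit (value, position) lexicographic sort
    pats[i] <- paste(ord, collapse = "-")
  }
  p <- as.numeric(table(pats)) / nw
  list(pe = -sum(p * log(p)), pe_norm = -sum(p * log(p)) / log(factorial(m)),
       n_patterns = length(p))
}

# Constant-valued single-voxel-per-value map on a tiny grid, for stacking
# into toy group designs.
const_map <- function(value, shape = c(2L, 2L, 2L), affine = diag(4)) {
  volume_map(array(value, shape), affine)
}

# Minimal cohort design data.frame with the canonical schema.
toy_design <- function(group_sizes, seed = 1L) {
  set.seed(seed)
  groups <- factor(rep(names(group_sizes), times = group_sizes),
                   levels = c("NC", "EMCI", "LMCI", "AD"))
  n <- sum(group_sizes)
  data.frame(subject_id = sprintf("s%03d", seq_len(n)), group = groups,
             age = round(rnorm(n, 73, 6), 1), sex = rep_len(0:1, n),
             mmse = round(rnorm(n, 26, 3)), faq = round(pmax(rnorm(n, 6, 5), 0)),
             cdr = rep_len(c(0, 0.5), n), stringsAsFactors = FALSE)
}

# iid-noise subject maps on a given grid (for machinery-calibration tests).
noise_maps <- function(n_subjects, shape, affine = diag(4)) {
  lapply(seq_len(n_subjects), function(i)
    volume_map(array(rnorm(prod(shape)), shape), affine))
}
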