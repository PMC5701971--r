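test_that("pe_map agrees with the scalar entropy and honors the mask", {
  set.seed(10)
  arr <- array(rnorm(4 * 4 * 4 * 130), c(4, 4, 4, 130))
  # strictly increasing everywhere -> zero map
  inc <- array(rep(seq_len(130), each = 64), c(4, 4, 4, 130))
  zmap <- pe_map(volume4d(inc))
  expect_true(all(zmap$data == 0))
  # single-voxel mask equals the scalar path
  m <- array(FALSE, c(4, 4, 4)); m[2, 3, 1] <- TRUE
  vol <- volume4d(arr)
  pm <- pe_map(vol, m)
  expect_equal(pm$data[2, 3, 1], permutation_entropy(arr[2, 3, 1, ])$pe_norm,
               tolerance = 1e-14)
  expect_true(all(is.na(pm$data[!m])))
  # out-of-mask voxels carry NA, and invalid params are refused unless forced
  short <- volume4d(arr[, , , 1:40, drop = FALSE])
  expect_error(pe_map(short), "invalid PE parameters")
  expect_warning(pe_map(short, force = TRUE), "validation")
})

test_that("pe_map of long iid noise is near the upper bound", {
  set.seed(12)
  arr <- array(rnorm(2 * 2 * 1 * 10000), c(2, 2, 1, 10000))
  pm <- pe_map(volume4d(arr))
  expect_true(all(pm$data > 0.99))
})

test_that("kendall_w matches the textbook concordance formula", {
  # perfect agreement among 27 identical rank columns
  r <- rank(rnorm(30))
  expect_equal(kendall_w(matrix(r, 30, 27)), 1, tolerance = 1e-12)
  # exact rank reversal of two series, n even -> W = 0
  n <- 20
  expect_equal(kendall_w(cbind(1:n, n:1)), 0, tolerance = 1e-12)
  # random rank matrix vs independent evaluation
  set.seed(13)
  RM <- sapply(1:5, function(i) rank(rnorm(20)))
  Ri <- rowSums(RM)
  S <- sum((Ri - mean(Ri))^2)
  expect_equal(kendall_w(RM), 12 * S / (5^2 * (20^3 - 20)), tolerance = 1e-12)
  expect_error(kendall_w(matrix(1:5, 5, 1)), "2 series")
})

test_that("reho_map reduces to kendall_w on a full 3x3x3 neighborhood", {
  set.seed(14)
  arr <- array(rnorm(3 * 3 * 3 * 30), c(3, 3, 3, 30))
  rh <- reho_map(volume4d(arr))
  X <- matrix(arr, 27, 30)
  expect_equal(rh$data[2, 2, 2], kendall_w(apply(X, 1, rank)), tolerance = 1e-12)
  # a volume where all voxels share one series is perfectly concordant
  shared <- rnorm(30)
  arr2 <- array(rep(shared, each = 27), c(3, 3, 3, 30))
  expect_equal(max(abs(reho_map(volume4d(arr2))$data - 1), na.rm = TRUE), 0,
               tolerance = 1e-12)
})

test_that("reho excludes isolated voxels and shrinks K at mask edges", {
  set.seed(15)
  arr <- array(rnorm(5 * 5 * 5 * 20), c(5, 5, 5, 20))
  lone <- array(FALSE, c(5, 5, 5)); lone[3, 3, 3] <- TRUE
  rh <- reho_map(volume4d(arr), lone)
  expect_false(rh$mask[3, 3, 3])      # no neighbors -> dropped
  # a two-voxel mask keeps both, each with K = 2
  pair <- lone; pair[3, 3, 4] <- TRUE
  rh2 <- reho_map(volume4d(arr), pair)
  expect_true(all(rh2$mask[pair]))
  w12 <- kendall_w(cbind(rank(arr[3, 3, 3, ]), rank(arr[3, 3, 4, ])))
  expect_equal(rh2$data[3, 3, 3], w12, tolerance = 1e-12)
  # neighborhood 7 uses only face neighbors
  rh7 <- reho_map(volume4d(arr), neighborhood = 7)
  nbrs <- rbind(c(3,3,3), c(2,3,3), c(4,3,3), c(3,2,3), c(3,4,3), c(3,3,2), c(3,3,4))
  RM <- sapply(seq_len(nrow(nbrs)), function(i)
    rank(arr[nbrs[i, 1], nbrs[i, 2], nbrs[i, 3], ]))
  expect_equal(rh7$data[3, 3, 3], kendall_w(RM), tolerance = 1e-12)
})

test_that("masked Gaussian smoothing preserves constants and matches the kernel", {
  affine <- diag(c(3, 3, 3, 1))
  cmap <- volume_map(array(5, c(10, 10, 10)), affine)
  expect_lt(max(abs(gaussian_smooth_map(cmap, 8)$data - 5)), 1e-9)
  # fwhm 0 is the identity
  expect_identical(gaussian_smooth_map(cmap, 0)$data, cmap$data)
  expect_error(gaussian_smooth_map(cmap, -1), "non-negative")
  # impulse response matches the separable truncated Gaussian
  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1
  sm <- gaussian_smooth_map(volume_map(imp, affine), 8)
  sigma_vox <- 8 / (2 * sqrt(2 * log(2))) / 3
  h <- ceiling(4 * sigma_vox)
  k <- exp(-((-h:h)^2) / (2 * sigma_vox^2)); k <- k / sum(k)
  w <- function(d) k[h + 1 + d]
  for (off in list(c(0, 0, 0), c(2, 0, -1), c(1, 3, 2))) {
    expect_equal(sm$data[11 + off[1], 11 + off[2], 11 + off[3]],
                 w(off[1]) * w(off[2]) * w(off[3]), tolerance = 1e-9)
  }
  # in-mask mean preserved under renormalized smoothing
  set.seed(16)
  vals <- array(rnorm(1000), c(10, 10, 10))
  msk <- array(runif(1000) < 0.7, c(10, 10, 10))
  mp <- volume_map(vals, affine, msk)
  smp <- gaussian_smooth_map(mp, 8)
  expect_equal(mean(smp$data[msk]), mean(vals[msk]), tolerance = 5e-2)
  expect_true(all(is.na(smp$data[!msk])))
})

test_that("smoothing is mask-closed: outside values never leak in", {
  affine <- diag(c(3, 3, 3, 1))
  vals <- array(0, c(9, 9, 9))
  msk <- array(TRUE, c(9, 9, 9))
  msk[1:3, , ] <- FALSE
  vals[1:3, , ] <- 1e6          # huge values outside the mask
  vals[!msk] <- NA              # and as stored sentinels
  raw <- vals; raw[1:3, , ] <- 1e6
  mp <- volume_map(raw, affine, msk)
  sm <- gaussian_smooth_map(mp, 8)
  expect_true(all(abs(sm$data[msk]) < 1e-9))
})

test_that("smoothing the 4-D data before ReHo inflates regional similarity", {
  set.seed(17)
  d <- c(8, 8, 8); nt <- 40
  arr <- array(rnorm(prod(d) * nt), c(d, nt))
  affine <- diag(c(3, 3, 3, 1))
  vol <- volume4d(arr, affine)
  reho_after <- mean(reho_map(vol)$data, na.rm = TRUE)
  smoothed <- arr
  for (t in seq_len(nt))
    smoothed[, , , t] <- gaussian_smooth_map(
      volume_map(arr[, , , t], affine), 8)$data
  reho_presmooth <- mean(reho_map(volume4d(smoothed, affine))$data, na.rm = TRUE)
  expect_gt(reho_presmooth, reho_after * 2)   # measurably higher, not marginal
})

test_that("tissue_mean averages over the mask intersection", {
  cmap <- volume_map(array(0.7, c(4, 4, 4)), diag(4))
  tm <- array(FALSE, c(4, 4, 4)); tm[1:2, , ] <- TRUE
  expect_equal(tissue_mean(cmap, tm), 0.7)
  two <- volume_map(array(NA_real_, c(4, 4, 4)), diag(4),
                    mask = array(FALSE, c(4, 4, 4)))
  expect_error(tissue_mean(two, tm), "intersect")
  vals <- array(NA_real_, c(4, 4, 4))
  vals[1, 1, 1] <- 0.1; vals[2, 1, 1] <- 0.3
  vm <- volume_map(vals, diag(4))
  expect_equal(tissue_mean(vm, array(TRUE, c(4, 4, 4))), 0.2)
})
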