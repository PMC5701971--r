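test_that("cohort reading validates schema and canonicalizes groups", {
  f <- tempfile(fileext = ".csv")
  df <- toy_design(c(NC = 3, EMCI = 3, LMCI = 3, AD = 3))
  write.csv(df, f, row.names = FALSE)
  got <- read_cohort(f)
  expect_identical(levels(got$group), c("NC", "EMCI", "LMCI", "AD"))
  bad <- df; names(bad)[names(bad) == "mmse"] <- "MMSCORE"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_cohort(f), "missing column.*mmse")
  ugly <- df; ugly$group <- as.character(ugly$group); ugly$group[1] <- "CTRL"
  write.csv(ugly, f, row.names = FALSE)
  expect_error(read_cohort(f), "unknown group")
})

test_that("voxelwise F reduces to classical ANOVA identities", {
  set.seed(20)
  # two groups, no covariates: F equals the pooled t statistic squared
  vals <- c(rnorm(10), rnorm(12, 1))
  maps <- lapply(vals, const_map)
  des <- toy_design(c(NC = 10, AD = 12))
  fa <- voxelwise_group_f(maps, des, covariates = NULL)
  tt <- t.test(vals[1:10], vals[11:22], var.equal = TRUE)
  expect_equal(fa$f_map$data[1, 1, 1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_identical(c(fa$df1, fa$df2), c(1L, 20L))

  # three groups of three, values 1..9: hand sums of squares
  vals2 <- as.numeric(1:9)
  des2 <- toy_design(c(NC = 3, EMCI = 3, AD = 3))
  fa2 <- voxelwise_group_f(lapply(vals2, const_map), des2, covariates = NULL)
  # SSB = 3*((2-5)^2+(5-5)^2+(8-5)^2) = 54, SSW = 3 groups * 2 each = 6
  expect_equal(fa2$f_map$data[1, 1, 1], (54 / 2) / (6 / 6), tolerance = 1e-12)

  # identical maps across all subjects: F = 0 everywhere
  fa3 <- voxelwise_group_f(lapply(rep(2.5, 22), const_map), des)
  expect_true(all(fa3$f_map$data == 0))
})

test_that("covariate adjustment is a partial F with the right dfs", {
  set.seed(21)
  des <- toy_design(c(NC = 8, EMCI = 8, LMCI = 8, AD = 8))
  vals <- rnorm(32) + 0.05 * des$age
  fa <- voxelwise_group_f(lapply(vals, const_map), des, covariates = c("age", "sex"))
  full <- lm(vals ~ des$age + des$sex + des$group)
  red <- lm(vals ~ des$age + des$sex)
  an <- anova(red, full)
  expect_equal(fa$f_map$data[1, 1, 1], an$F[2], tolerance = 1e-10)
  expect_identical(c(fa$df1, fa$df2), c(3L, 32L - 6L))
  expect_error(voxelwise_group_f(lapply(vals, const_map), des,
                                 covariates = "weight"), "not in design")
})

test_that("connected components respect the connectivity definition", {
  flag <- array(FALSE, c(6, 6, 6))
  flag[1:2, 1:2, 1:2] <- TRUE          # blob A
  flag[3:4, 3:4, 3:4] <- TRUE          # blob B, touching A only at a corner
  lab6 <- pemap:::label_clusters(flag, 6L)
  expect_identical(length(lab6$sizes), 2L)
  expect_identical(sort(lab6$sizes), c(8L, 8L))
  lab26 <- pemap:::label_clusters(flag, 26L)
  expect_identical(length(lab26$sizes), 1L)
})

test_that("cluster thresholding recovers an implanted blob and only it", {
  set.seed(22)
  shape <- c(12, 12, 12)
  des <- toy_design(c(NC = 6, EMCI = 6, LMCI = 6, AD = 6))
  blob <- array(FALSE, shape)
  blob[4:8, 5:9, 4:5] <- TRUE          # 50-voxel rectangular blob
  effect <- c(NC = 0, EMCI = 1, LMCI = 2, AD = 3)
  maps <- lapply(seq_len(24), function(i) {
    v <- array(rnorm(prod(shape)), shape)
    v[blob] <- v[blob] + effect[as.character(des$group[i])] * 3
    volume_map(v, diag(4))
  })
  res <- cluster_threshold(maps, des, covariates = NULL, p_voxel = 0.005,
                           n_perm = 200)
  expect_identical(length(res$clusters), 1L)
  cl <- res$clusters[[1]]
  expect_identical(cl$size, 50L)
  expect_true(all(blob[cl$voxels]))
  expect_lte(cl$p_fwe, 0.05)
  expect_equal(cl$peak_f, max(res$f_map$data[blob]))
  # an all-zero F map yields no clusters
  flat <- lapply(rep(1, 24), const_map, shape = shape)
  res0 <- cluster_threshold(flat, des, covariates = NULL, n_perm = 100)
  expect_identical(length(res0$clusters), 0L)
  expect_error(cluster_threshold(maps, des, n_perm = 50), "n_perm")
})

test_that("sphere ROI masks match exhaustive center-distance enumeration", {
  affine <- diag(c(3, 3, 3, 1)); affine[1:3, 4] <- -15
  shape <- c(11, 11, 11)
  msk <- sphere_roi_mask(c(0, 0, 0), 8, affine, shape)
  cnt <- 0L
  for (i in 1:11) for (j in 1:11) for (k in 1:11) {
    xyz <- 3 * (c(i, j, k) - 1) - 15
    inside <- sum(xyz^2) <= 64
    cnt <- cnt + inside
    expect_identical(msk[i, j, k], inside)
  }
  expect_identical(sum(msk), cnt)
  # radius 0 selects exactly the voxel containing the center
  m0 <- sphere_roi_mask(c(1, -1, 0.5), 0, affine, shape)
  expect_identical(sum(m0), 1L)
  expect_true(m0[6, 6, 6])   # nearest voxel center to (1, -1, 0.5)
  expect_error(sphere_roi_mask(c(500, 0, 0), 8, affine, shape), "outside")
})

test_that("roi_mean averages inside the map mask and errors when disjoint", {
  cmap <- volume_map(array(0.42, c(5, 5, 5)), diag(c(3, 3, 3, 1)))
  roi <- array(FALSE, c(5, 5, 5)); roi[2:3, 2, 2] <- TRUE
  expect_equal(roi_mean(cmap, roi), 0.42)
  vals <- array(NA_real_, c(5, 5, 5))
  vals[cbind(1:3, 1, 1)] <- c(0.1, 0.2, 0.3)
  vm <- volume_map(vals, diag(c(3, 3, 3, 1)))
  roi3 <- array(FALSE, c(5, 5, 5)); roi3[cbind(1:3, 1, 1)] <- TRUE
  expect_equal(roi_mean(vm, roi3), 0.2)
  outside <- array(FALSE, c(5, 5, 5)); outside[5, 5, 5] <- TRUE
  expect_error(roi_mean(vm, outside), "intersect")
})

test_that("pairwise post-hocs match the pooled t formula with Bonferroni x pairs", {
  set.seed(24)
  g <- factor(rep(c("NC", "EMCI", "LMCI", "AD"), each = 10),
              levels = c("NC", "EMCI", "LMCI", "AD"))
  # identical groups: every adjusted p is 1
  same <- rep(rnorm(10), 4)
  ph0 <- posthoc_pairwise(same, g)
  expect_identical(nrow(ph0), 6L)
  expect_true(all(ph0$p_bonf == 1))
  # overwhelming separation survives correction
  x <- c(rnorm(10), rnorm(10), rnorm(10), rnorm(10, 20))
  ph1 <- posthoc_pairwise(x, g)
  expect_true(all(ph1$p_bonf[ph1$group2 == "AD"] < 0.001))
  # hand formula for one pair
  a <- x[g == "NC"]; b <- x[g == "AD"]
  sp <- sqrt(((9 * var(a)) + (9 * var(b))) / 18)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 10 + 1 / 10))
  row <- ph1[ph1$group1 == "NC" & ph1$group2 == "AD", ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$p_bonf, min(1, row$p * 6), tolerance = 1e-12)
  # undersized group is skipped with a warning
  g2 <- factor(c(rep("NC", 10), "AD"), levels = levels(g))
  expect_warning(expect_error(posthoc_pairwise(c(rnorm(10), 1), g2), "no testable"),
                 "< 2 subjects")
})

test_that("pearson_corr reproduces hand-computed values and edge cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -x)$r, -1, tolerance = 1e-12)
  y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  got <- pearson_corr(x, y)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  t_stat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(got$p, 2 * pt(-abs(t_stat), 3), tolerance = 1e-12)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_corr(c(1, 2), c(1, 2)), "3 complete")
})

test_that("report tables carry one row per cluster and ROI-score pair", {
  dir <- tempfile()
  paths <- report_tables(list(), NULL, dir)
  empty <- read.csv(paths$cluster_table)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("region", "peak_x", "cluster_voxels", "peak_f") %in% names(empty)))
  cl <- list(list(name = "cluster01", size = 50L, peak_f = 12.3,
                  peak_ijk = c(5, 6, 7), peak_xyz = c(12, 15, 18),
                  p_fwe = 0.01, voxels = NULL))
  corr <- expand.grid(roi = c("a", "b"), score = c("mmse", "faq", "cdr"),
                      stringsAsFactors = FALSE)
  corr$r <- 0.3; corr$p <- 0.01; corr$n <- 90
  paths2 <- report_tables(cl, corr, dir)
  tab <- read.csv(paths2$cluster_table)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$cluster_voxels, 50L)
  ct <- read.csv(paths2$correlation_table)
  expect_identical(nrow(ct), 2L * 3L)
  expect_true(file.exists(paths2$manifest))
})
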