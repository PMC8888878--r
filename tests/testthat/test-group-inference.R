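make_sample <- function(values, groups, grid = NULL, mask = NULL) {
  # values: subjects x voxels matrix wrapped into maps on a tiny grid
  if (is.null(grid)) grid <- volume_grid(c(4, 4, max(2, ceiling(ncol(values) / 16))))
  if (is.null(mask)) {
    mask <- array(FALSE, grid$dims)
    mask[seq_len(ncol(values))] <- TRUE
  }
  maps <- lapply(seq_len(nrow(values)), function(i) {
    m <- array(NA_real_, grid$dims)
    m[which(mask)] <- values[i, ]
    m
  })
  group_sample(maps, groups, grid, mask)
}

test_that("voxelwise ANOVA reproduces hand-computed and library results", {
  # {1,2,3}, {2,3,4}, {3,4,5}: SSB = 6, SSW = 6, F = 3, df (2, 6)
  vals <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), ncol = 1)
  grp <- rep(c("A", "B", "C"), each = 3)
  sm <- make_sample(vals, grp)
  res <- voxelwise_anova(sm)
  expect_equal(res$f_map[1], 3.0)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p_map[1],
               stats::pf(3, 2, 6, lower.tail = FALSE))

  # identical group means and variances: F = 0
  same <- matrix(rep(c(1, 2, 3), 3), ncol = 1)
  expect_equal(voxelwise_anova(make_sample(same, grp))$f_map[1], 0)

  # two groups: F equals the squared pooled t
  set.seed(10)
  v2 <- matrix(rnorm(12 * 30), nrow = 12)
  g2 <- rep(c("A", "B"), times = c(5, 7))
  r2 <- voxelwise_anova(make_sample(v2, g2))
  for (j in 1:30) {
    t_stat <- stats::t.test(v2[g2 == "A", j], v2[g2 == "B", j],
                            var.equal = TRUE)$statistic
    expect_equal(r2$f_map[j], unname(t_stat)^2, tolerance = 1e-10)
  }

  # three unbalanced groups against stats::oneway.test
  v3 <- matrix(rnorm(15 * 20), nrow = 15)
  g3 <- rep(c("A", "B", "C"), times = c(4, 6, 5))
  r3 <- voxelwise_anova(make_sample(v3, g3))
  for (j in c(1, 7, 20)) {
    ow <- stats::oneway.test(v3[, j] ~ g3, var.equal = TRUE)
    expect_equal(r3$f_map[j], unname(ow$statistic), tolerance = 1e-10)
    expect_equal(r3$p_map[j], ow$p.value, tolerance = 1e-10)
  }

  expect_error(voxelwise_anova(make_sample(v3[1:5, ], c("A", "A", "A", "A", "B"))),
               ">= 2 subjects")
})

test_that("type-I error is calibrated under the null", {
  set.seed(2024)
  grp <- rep(c("HC", "AUD-NCI", "ARCI"), times = c(8, 10, 6))
  hits <- 0; total <- 0
  for (rep in 1:20) {
    v <- matrix(rnorm(24 * 400), nrow = 24)
    r <- voxelwise_anova(make_sample(v, grp, grid = volume_grid(c(8, 8, 8))))
    p <- r$p_map[!is.na(r$p_map)]
    hits <- hits + sum(p < 0.05); total <- total + length(p)
  }
  expect_gt(hits / total, 0.04)
  expect_lt(hits / total, 0.06)
})

test_that("cluster extraction applies extent, connectivity and labeling rules", {
  grid <- volume_grid(c(12, 12, 12), voxel_mm = c(3, 3, 3))
  f <- array(0, grid$dims); p <- array(1, grid$dims)
  # blob of 5 and blob of 2
  f[2:6, 2, 2] <- c(5, 9, 6, 5, 5); p[2:6, 2, 2] <- 1e-5
  f[9:10, 9, 9] <- 7; p[9:10, 9, 9] <- 1e-5
  ct <- extract_clusters(f, p, grid, min_extent = 3)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$n_voxels, 5)
  expect_equal(ct$peak_f, 9)
  # peak voxel is inside the cluster, and MNI is the affine image
  expect_equal(c(ct$peak_i, ct$peak_j, ct$peak_k), c(2, 1, 1))
  expect_equal(c(ct$peak_x_mm, ct$peak_y_mm, ct$peak_z_mm),
               voxel_to_mni(grid, c(2, 1, 1)))

  # a peak engineered to map to MNI (33, 18, -18)
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(0, 0, -30)
  g2 <- volume_grid(c(12, 12, 12), affine = aff)
  f2 <- array(0, g2$dims); p2 <- array(1, g2$dims)
  f2[12, 7, 5] <- 10; f2[11, 7, 5] <- 8; f2[10, 7, 5] <- 8
  p2[10:12, 7, 5] <- 1e-5
  ct2 <- extract_clusters(f2, p2, g2, min_extent = 3)
  expect_equal(c(ct2$peak_x_mm, ct2$peak_y_mm, ct2$peak_z_mm), c(33, 18, -18))

  # diagonal-touching pair: one cluster under 26-connectivity, two under 6
  f3 <- array(0, grid$dims); p3 <- array(1, grid$dims)
  f3[3, 3, 3] <- 5; f3[4, 4, 4] <- 5; f3[5, 5, 4] <- 5
  p3[3, 3, 3] <- p3[4, 4, 4] <- p3[5, 5, 4] <- 1e-5
  c26 <- extract_clusters(f3, p3, grid, min_extent = 1, connectivity = 26)
  c6 <- extract_clusters(f3, p3, grid, min_extent = 1, connectivity = 6)
  expect_equal(nrow(c26), 1)
  expect_equal(nrow(c6), 3)

  # sum of cluster sizes never exceeds the supra-threshold count
  expect_lte(sum(c26$n_voxels), sum(p3 < 0.001))

  # ROI labeling of peaks
  roi <- array(FALSE, grid$dims); roi[2:6, 2, 2] <- TRUE
  ct4 <- extract_clusters(f, p, grid, min_extent = 3,
                          roi_labels = list(blob = roi))
  expect_equal(ct4$region, "blob")
  expect_equal(ct$region, "unlabeled")

  # rows come out ordered by peak F, descending, numbered 1..n
  ct5 <- extract_clusters(f3, p3, grid, min_extent = 1, connectivity = 6)
  expect_true(all(diff(ct5$peak_f) <= 0))
  expect_equal(ct5$cluster, seq_len(nrow(ct5)))

  # TSV writer emits the report column order
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(ct, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr, c("Clusters", "Number of voxels", "Regions", "MNI", "F"))
})

test_that("ROI ordering summarizes groups and runs Welch pairwise tests", {
  grid <- volume_grid(c(4, 4, 4))
  mask <- array(TRUE, grid$dims)
  roi <- array(FALSE, grid$dims); roi[1:2, 1, 1] <- TRUE
  grp <- rep(c("HC", "AUD-NCI", "ARCI"), each = 4)
  set.seed(3)
  shift <- rep(c(0, 1, 0.5), each = 4)
  maps <- lapply(seq_along(grp), function(i)
    array(rnorm(64, mean = shift[i], sd = 0.1), grid$dims))
  sm <- group_sample(maps, grp, grid, mask)
  ro <- roi_ordering(sm, roi)
  expect_equal(ro$ordering, "HC < ARCI < AUD-NCI")
  expect_equal(nrow(ro$pairwise), 3)
  expect_true(all(ro$pairwise$p_bonferroni >= ro$pairwise$p))
  expect_true(all(ro$pairwise$p_bonferroni <= 1))

  # identical maps: ties reported
  same <- lapply(seq_along(grp), function(i) array(1, grid$dims))
  ros <- roi_ordering(group_sample(same, grp, grid, mask), roi)
  expect_match(ros$ordering, "=")

  # single-voxel ROI: the subject value is that voxel
  roi1 <- array(FALSE, grid$dims); roi1[2, 1, 1] <- TRUE
  ro1 <- roi_ordering(sm, roi1)
  expect_equal(unname(ro1$subject_values[1]), maps[[1]][2, 1, 1])

  expect_error(roi_ordering(sm, array(FALSE, grid$dims)), "empty ROI")
})

test_that("permutation extent threshold is calibrated against the null", {
  grid <- volume_grid(c(6, 6, 6))
  mask <- array(TRUE, grid$dims)
  grp <- rep(c("HC", "AUD-NCI", "ARCI"), times = c(8, 8, 8))
  set.seed(61)
  maps <- lapply(seq_along(grp), function(i) array(rnorm(216), grid$dims))
  sm <- group_sample(maps, grp, grid, mask)
  pc <- permutation_cluster_extent(sm, p_thresh = 0.01, n_perm = 50, seed = 3)
  expect_length(pc$null_max_extent, 50)
  expect_true(all(pc$null_max_extent >= 0))
  expect_gte(pc$extent_threshold, 1)
  # on pure-null data the observed max extent rarely beats the threshold
  av <- voxelwise_anova(sm)
  obs <- extract_clusters(av$f_map, av$p_map, grid, p_thresh = 0.01,
                          min_extent = pc$extent_threshold)
  expect_lte(nrow(obs), 2)
})

test_that("behavior correlations handle perfect, missing and degenerate cases", {
  grid <- volume_grid(c(4, 4, 4))
  mask <- array(TRUE, grid$dims)
  roi <- array(FALSE, grid$dims); roi[1, 1, 1] <- TRUE
  grp <- c("HC", "HC", rep(c("AUD-NCI", "ARCI"), each = 5))
  set.seed(4)
  vals <- rnorm(12)
  maps <- lapply(vals, function(v) array(v, grid$dims))
  sm <- group_sample(maps, grp, grid, mask)
  cohort <- cohort_table(data.frame(
    id = sprintf("s%02d", 1:12), group = grp,
    ADS = c(0, 0, vals[3:12]),          # identical to the ROI values
    VAS = c(rnorm(11), NA),
    OCDS = rep(2, 12)))                 # constant
  out <- behavior_correlation(sm, cohort, list(roi = roi),
                              c("ADS", "VAS", "OCDS"))
  expect_equal(out$r[out$score == "ADS"], 1, tolerance = 1e-12)
  expect_equal(out$n[out$score == "VAS"], 9)   # one NA dropped pairwise
  expect_equal(out$note[out$score == "OCDS"], "insufficient variance")
  expect_true(is.na(out$r[out$score == "OCDS"]))

  # fewer than 3 complete pairs is flagged
  cohort2 <- cohort
  cohort2$VAS[3:10] <- NA
  out2 <- behavior_correlation(sm, cohort2, list(roi = roi), "VAS")
  expect_equal(out2$note, "insufficient data")
})
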