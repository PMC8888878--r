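#' Per-subject map sample for group inference
#'
#' Collects one 3D summary map per subject (static z, dynamic SD, or CV)
#' on a common grid and mask, with group labels.
#'
#' @param maps list of 3D arrays, one per subject.
#' @param groups group label per subject.
#' @param grid the shared [volume_grid()].
#' @param mask logical 3D analysis mask (usually GM).
#' @param measure name of the measure (e.g. "cv22").
#' @return object of class `group_sample`: `values` is subjects x voxels.
#' @export
group_sample <- function(maps, groups, grid, mask, measure = "map") {
  if (length(maps) != length(groups)) stop("one group label per map required")
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 subjects in each of >= 2 groups")
  vi <- which(mask)
  values <- do.call(rbind, lapply(maps, function(m) {
    if (!identical(dim(m), as.integer(grid$dims))) stop("map dims mismatch")
    m[vi]
  }))
  structure(list(values = values, groups = groups, grid = grid,
                 mask = mask, voxels = vi, measure = measure),
            class = "group_sample")
}

#' Voxelwise one-way fixed-effects ANOVA
#'
#' Per voxel, the between/within F statistic over the sample's groups,
#' df = (k - 1, N - k), p from the F distribution. Voxels with zero
#' between-group and zero within-group variance get F = 0, p = 1. Voxels
#' where any subject is missing (NA, e.g. undefined CV) are dropped from
#' the result maps.
#'
#' @param sample a [group_sample()].
#' @return list with 3D `f_map` and `p_map` (NA outside mask / at dropped
#'   voxels), `df`, and `n_dropped`.
#' @export
voxelwise_anova <- function(sample) {
  Y <- sample$values
  gf <- factor(sample$groups)
  k <- nlevels(gf)
  N <- nrow(Y)
  if (k < 2 || any(table(gf) < 2)) stop("need >= 2 subjects per group, >= 2 groups")
  ok <- colSums(is.na(Y)) == 0
  Yk <- Y[, ok, drop = FALSE]
  n_g <- as.numeric(table(gf))
  gmean <- colMeans(Yk)
  msum <- rowsum(Yk, gf)                    # k x voxels group sums
  gm_g <- msum / n_g
  ssb <- colSums(n_g * sweep(gm_g, 2, gmean)^2)
  sst <- colSums(sweep(Yk, 2, gmean)^2)
  ssw <- sst - ssb
  df1 <- k - 1; df2 <- N - k
  f <- rep(0, ncol(Yk))
  nz <- ssw > 0
  f[nz] <- (ssb[nz] / df1) / (ssw[nz] / df2)
  # zero within-group variance with real group differences: infinite evidence
  f[!nz & ssb > 1e-24] <- Inf
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[f == 0] <- 1
  mk <- function(v) {
    a <- array(NA_real_, sample$grid$dims)
    a[sample$voxels[ok]] <- v
    a
  }
  list(f_map = mk(f), p_map = mk(p), df = c(df1, df2),
       n_dropped = sum(!ok))
}

#' Extract supra-threshold clusters with MNI peaks
#'
#' Thresholds the p map at `p < p_thresh`, labels connected components
#' (26- or 6-connectivity), drops components smaller than `min_extent`
#' voxels, and reports each surviving cluster's size, peak-F voxel (0-based
#' index and MNI mm via the grid affine) and a region label: the name of
#' the ROI mask containing the peak, or "unlabeled". Rows are ordered by
#' peak F, descending.
#'
#' @param f_map,p_map 3D arrays from [voxelwise_anova()].
#' @param grid the [volume_grid()].
#' @param p_thresh uncorrected voxel threshold (default 0.001).
#' @param min_extent minimum cluster size in voxels (default 15).
#' @param connectivity 26 (default) or 6.
#' @param roi_labels optional named list of logical arrays for labeling.
#' @return a `cluster_table` data.frame with columns `cluster`,
#'   `n_voxels`, `region`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`,
#'   `peak_f`, plus 0-based `peak_i/j/k`.
#' @export
extract_clusters <- function(f_map, p_map, grid, p_thresh = 0.001,
                             min_extent = 15, connectivity = 26,
                             roi_labels = NULL) {
  if (!identical(dim(f_map), as.integer(grid$dims)) ||
      !identical(dim(p_map), as.integer(grid$dims)))
    stop("maps do not match the grid")
  supra <- !is.na(p_map) & p_map < p_thresh
  lab <- cpp_label_components(supra, as.integer(grid$dims), as.integer(connectivity))
  rows <- list()
  if (any(supra)) {
    for (cl in seq_len(max(lab))) {
      idx <- which(lab == cl)
      if (length(idx) < min_extent) next
      peak <- idx[which.max(f_map[idx])]
      ijk <- arrayInd(peak, grid$dims) - 1L
      mm <- voxel_to_mni(grid, as.integer(ijk))
      region <- "unlabeled"
      if (!is.null(roi_labels))
        for (nm in names(roi_labels))
          if (roi_labels[[nm]][peak]) { region <- nm; break }
      rows[[length(rows) + 1]] <- data.frame(
        n_voxels = length(idx), region = region,
        peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3],
        peak_f = f_map[peak],
        peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3])
    }
  }
  if (!length(rows)) {
    out <- data.frame(cluster = integer(0), n_voxels = integer(0),
                      region = character(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      peak_f = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0))
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(-out$peak_f), , drop = FALSE]
    out <- cbind(cluster = seq_len(nrow(out)), out)
    rownames(out) <- NULL
  }
  structure(out, class = c("cluster_table", "data.frame"))
}

#' Write a cluster table as TSV in report column order
#'
#' Columns: Clusters, Number of voxels, Regions, MNI (comma-joined mm
#' triple), F.
#' @param ct a `cluster_table`.
#' @param path output path.
#' @export
write_cluster_table <- function(ct, path) {
  df <- data.frame(
    Clusters = ct$cluster,
    `Number of voxels` = ct$n_voxels,
    Regions = ct$region,
    MNI = sprintf("%g, %g, %g", ct$peak_x_mm, ct$peak_y_mm, ct$peak_z_mm),
    F = sprintf("%.2f", ct$peak_f),
    check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Permutation-calibrated cluster extent threshold
#'
#' Estimates the null distribution of the maximum supra-threshold cluster
#' size by shuffling subject group labels: for each of `n_perm`
#' permutations, recompute the voxelwise ANOVA, threshold at
#' `p < p_thresh`, and record the largest connected component. The
#' returned quantile (default 95th percentile) can be used as a
#' principled `min_extent` in [extract_clusters()] in place of the fixed
#' default.
#'
#' @param x a [group_sample()].
#' @param p_thresh voxel threshold.
#' @param n_perm number of label permutations.
#' @param connectivity 26 or 6.
#' @param prob quantile of the null max-extent distribution.
#' @param seed RNG seed for the permutations.
#' @return list with `extent_threshold` (smallest integer extent whose
#'   null exceedance is below `1 - prob`) and `null_max_extent` (the
#'   permuted maxima).
#' @export
permutation_cluster_extent <- function(x, p_thresh = 0.001,
                                       n_perm = 200, connectivity = 26,
                                       prob = 0.95, seed = 1) {
  set.seed(seed)
  maxima <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- x
    perm$groups <- sample(x$groups)
    av <- voxelwise_anova(perm)
    supra <- !is.na(av$p_map) & av$p_map < p_thresh
    if (!any(supra)) { maxima[i] <- 0L; next }
    lab <- cpp_label_components(supra, as.integer(x$grid$dims),
                                as.integer(connectivity))
    maxima[i] <- max(tabulate(lab[lab > 0]))
  }
  list(extent_threshold = as.integer(stats::quantile(maxima, prob,
                                                     type = 1)) + 1L,
       null_max_extent = maxima)
}

#' ROI-level group summary, ordering and pairwise tests
#'
#' Averages each subject's map over the ROI, reports per-group mean and SD,
#' the ordering of group means (ties joined with "="), and Welch pairwise
#' t-tests with Bonferroni-adjusted p-values.
#'
#' @param sample a [group_sample()].
#' @param roi logical 3D ROI mask (nonempty).
#' @return list with `subject_values`, `group_stats` (data.frame),
#'   `ordering` (e.g. `"HC < ARCI < AUD-NCI"`), and `pairwise` (data.frame
#'   of Welch tests).
#' @export
roi_ordering <- function(sample, roi) {
  if (!any(roi)) stop("empty ROI mask")
  cols <- match(which(roi & sample$mask), sample$voxels)
  cols <- cols[!is.na(cols)]
  if (!length(cols)) stop("ROI does not intersect the analysis mask")
  vals <- rowMeans(sample$values[, cols, drop = FALSE], na.rm = TRUE)
  gf <- factor(sample$groups)
  stats_df <- data.frame(
    group = levels(gf),
    n = as.integer(table(gf)),
    mean = as.numeric(tapply(vals, gf, mean)),
    sd = as.numeric(tapply(vals, gf, stats::sd)))
  ord <- order(stats_df$mean)
  sep <- ifelse(diff(stats_df$mean[ord]) == 0, " = ", " < ")
  ordering <- paste0(stats_df$group[ord],
                     c(sep, ""), collapse = "")
  pairs <- utils::combn(levels(gf), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tt <- tryCatch(stats::t.test(vals[gf == a], vals[gf == b]),
                   error = function(e) NULL)  # essentially-constant data
    if (is.null(tt))
      data.frame(group1 = a, group2 = b, t = NA_real_, df = NA_real_,
                 p = NA_real_)
    else
      data.frame(group1 = a, group2 = b, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
  }))
  pw$p_bonferroni <- pmin(1, pw$p * nrow(pw))
  list(subject_values = vals, group_stats = stats_df,
       ordering = ordering, pairwise = pw)
}

#' Behavior-imaging correlations over patient groups
#'
#' Pearson correlation (two-sided test) between each behavioral score and
#' each subject's ROI-mean map value, by default restricted to the patient
#' groups (AUD-NCI, ARCI). Subjects with missing scores are dropped
#' pairwise; pairs with fewer than 3 complete observations or a constant
#' score get NA with a reason flag.
#'
#' @param sample a [group_sample()] (subject order must match `cohort`).
#' @param cohort a [cohort_table()] with one row per sample subject.
#' @param rois named list of logical ROI masks.
#' @param scores character vector of score column names.
#' @param groups groups to include.
#' @return data.frame with columns `score`, `roi`, `r`, `p`, `n`, `note`.
#' @export
behavior_correlation <- function(sample, cohort, rois, scores,
                                 groups = c("AUD-NCI", "ARCI")) {
  if (nrow(cohort) != nrow(sample$values))
    stop("cohort rows must match sample subjects")
  keep <- as.character(cohort$group) %in% groups
  out <- list()
  for (roi_name in names(rois)) {
    cols <- match(which(rois[[roi_name]] & sample$mask), sample$voxels)
    cols <- cols[!is.na(cols)]
    if (!length(cols)) stop(sprintf("ROI '%s' outside analysis mask", roi_name))
    roi_vals <- rowMeans(sample$values[, cols, drop = FALSE], na.rm = TRUE)
    for (sc in scores) {
      x <- as.numeric(cohort[[sc]])[keep]
      y <- roi_vals[keep]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n < 3) {
        out[[length(out) + 1]] <- data.frame(score = sc, roi = roi_name,
                                             r = NA_real_, p = NA_real_,
                                             n = n, note = "insufficient data")
        next
      }
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        out[[length(out) + 1]] <- data.frame(score = sc, roi = roi_name,
                                             r = NA_real_, p = NA_real_,
                                             n = n, note = "insufficient variance")
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      out[[length(out) + 1]] <- data.frame(score = sc, roi = roi_name,
                                           r = unname(ct$estimate),
                                           p = ct$p.value, n = n, note = "")
    }
  }
  do.call(rbind, out)
}
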