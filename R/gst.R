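#' Gray-matter global signal
#'
#' The global signal (GS) at each time point is the unweighted mean of the
#' BOLD values over all GM voxels; WM and CSF are excluded by construction
#' of the GM mask.
#'
#' @param run a [bold_run()].
#' @param masks a [brain_masks()] on the same grid.
#' @return object of class `global_series`: list with `values` (length-T
#'   numeric) and `tr`.
#' @export
global_signal <- function(run, masks) {
  if (!grids_equal(run$grid, masks$grid)) stop("run and masks on different grids")
  if (!any(masks$gm)) stop("gm mask is empty")
  gs <- colMeans(voxel_matrix(run, masks$gm))
  structure(list(values = gs, tr = run$tr), class = "global_series")
}

#' Fisher r-to-z transform
#'
#' atanh(r) after clamping r into `[-r_max, r_max]` with
#' `r_max = 1 - 1e-7`, so perfectly correlated series map to a large
#' finite z rather than infinity. Antisymmetric: `fisher_z(-r) = -fisher_z(r)`.
#'
#' @param r correlation value(s); `|r|` may exceed 1 by at most 1e-9
#'   (floating-point slack), anything larger is a domain error.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE))
    stop("correlation outside [-1, 1]")
  rmax <- 1 - 1e-7
  atanh(pmin(pmax(r, -rmax), rmax))
}

#' Static global-signal topography map
#'
#' Pearson correlation between every GM voxel series and the global
#' signal, Fisher r-to-z transformed. Voxels with zero temporal variance
#' get r = 0 (their count is reported via `message()`).
#'
#' @param run a [bold_run()].
#' @param gs a [global_series()] of matching length (computed from this
#'   run via [global_signal()] in the standard pipeline).
#' @param masks a [brain_masks()].
#' @return object of class `static_gst`: list with 3D fields `z` and `r`
#'   (NA outside GM), plus `n_zero_variance`.
#' @export
static_gst <- function(run, gs, masks) {
  g <- gs$values
  if (length(g) != run$n_volumes) stop("global series length does not match run")
  if (run$n_volumes < 3) stop("need at least 3 time points")
  Y <- voxel_matrix(run, masks$gm)
  gc <- g - mean(g)
  Yc <- Y - rowMeans(Y)
  den <- sqrt(rowSums(Yc^2) * sum(gc^2))
  r <- as.numeric(Yc %*% gc)
  zero <- den == 0
  r[!zero] <- r[!zero] / den[!zero]
  r[zero] <- 0
  if (any(zero))
    message(sprintf("static_gst: %d zero-variance voxels set to r = 0", sum(zero)))
  zmap <- rmap <- array(NA_real_, run$grid$dims)
  rmap[masks$gm] <- r
  zmap[masks$gm] <- fisher_z(r)
  structure(list(z = zmap, r = rmap, grid = run$grid,
                 n_zero_variance = sum(zero)),
            class = "static_gst")
}

#' Sliding-window specification
#'
#' @param length_tr window length in TRs (default 22; 30 is the standard
#'   robustness alternative).
#' @param step_tr step between window starts in TRs.
#' @export
window_spec <- function(length_tr = 22, step_tr = 1) {
  if (length_tr <= 2) stop("window length must exceed 2 TRs")
  if (step_tr < 1) stop("step must be >= 1")
  structure(list(length_tr = as.integer(length_tr),
                 step_tr = as.integer(step_tr), shape = "rectangular"),
            class = "window_spec")
}

#' Number of complete sliding windows
#'
#' `floor((T - length)/step) + 1`; only windows that fit entirely count.
#' @param n_time series length T.
#' @param spec a [window_spec()].
#' @export
n_windows <- function(n_time, spec) {
  if (spec$length_tr > n_time) stop("window longer than the series")
  (n_time - spec$length_tr) %/% spec$step_tr + 1L
}

#' Dynamic global-signal topography
#'
#' For every GM voxel and every rectangular window of `spec$length_tr`
#' samples starting at 0-based offsets `w * step`, the Pearson correlation
#' between the windowed voxel series and the windowed global signal,
#' Fisher r-to-z transformed. Windows where either series has zero
#' variance yield z = 0 (count recorded).
#'
#' @param run a [bold_run()].
#' @param gs a [global_series()].
#' @param spec a [window_spec()].
#' @param masks a [brain_masks()].
#' @return object of class `dynamic_gst`: `z_windows` (GM-voxels x windows
#'   matrix), `n_windows`, `voxels` (linear indices of GM voxels), `spec`,
#'   `grid`, `n_zero_variance`; SD/mean/CV maps are added by
#'   [summarize_dynamic()].
#' @export
dynamic_gst <- function(run, gs, spec = window_spec(), masks) {
  g <- gs$values
  if (length(g) != run$n_volumes) stop("global series length does not match run")
  if (spec$length_tr > run$n_volumes) stop("window longer than the series")
  Y <- voxel_matrix(run, masks$gm)
  res <- cpp_sliding_z(Y, g, spec$length_tr, spec$step_tr, 1 - 1e-7)
  structure(list(z_windows = res$z, n_windows = res$n_windows,
                 voxels = which(masks$gm), spec = spec, grid = run$grid,
                 n_zero_variance = res$n_zero_variance),
            class = "dynamic_gst")
}

#' @export
print.dynamic_gst <- function(x, ...) {
  cat(sprintf("<dynamic_gst> %d GM voxels, %d windows (length %d, step %d)%s\n",
              nrow(x$z_windows), x$n_windows, x$spec$length_tr,
              x$spec$step_tr,
              if (!is.null(x$sd_map)) ", summarized" else ""))
  invisible(x)
}

#' SD, mean and CV summary maps of the windowed z-series
#'
#' Per voxel over windows: sample SD (n-1 denominator), mean, and the
#' coefficient of variation CV = SD/|mean|. Because windowed Fisher-z
#' means can be near zero, the CV is stored as missing (NA) wherever
#' |mean| <= eps; the count of such voxels is recorded. A signed variant
#' (SD/mean, same guard) is available via `cv_mode = "signed"`.
#'
#' Summaries are computed on the Fisher-z scale by default. With
#' `scale = "r"` the windowed values are mapped back to correlations
#' (tanh) first; this is the appropriate scale for noise-free validation
#' data, where atanh's singularity at |r| -> 1 otherwise dominates the SD.
#'
#' @param result a [dynamic_gst()].
#' @param eps mean-magnitude guard for the CV denominator.
#' @param cv_mode `"abs"` (default) or `"signed"`.
#' @param scale `"z"` (default) or `"r"`.
#' @return the input with 3D `sd_map`, `mean_map`, `cv_map` (NA outside
#'   GM) and `n_cv_undefined` added.
#' @export
summarize_dynamic <- function(result, eps = 1e-3, cv_mode = c("abs", "signed"),
                              scale = c("z", "r")) {
  cv_mode <- match.arg(cv_mode)
  scale <- match.arg(scale)
  if (result$n_windows < 2) stop("need at least 2 windows to summarize")
  Z <- if (scale == "r") tanh(result$z_windows) else result$z_windows
  s <- summarize_z_matrix(Z, eps, cv_mode)
  mk <- function(v) { a <- array(NA_real_, result$grid$dims); a[result$voxels] <- v; a }
  result$sd_map <- mk(s$sd)
  result$mean_map <- mk(s$mean)
  result$cv_map <- mk(s$cv)
  result$cv_mode <- cv_mode
  result$n_cv_undefined <- sum(is.na(s$cv))
  result
}

# row-wise SD (n-1), mean and guarded CV of a voxels x windows z matrix;
# shared by summarize_dynamic() and the streaming cohort harness
summarize_z_matrix <- function(Z, eps, cv_mode) {
  mu <- rowMeans(Z)
  sd <- sqrt(rowSums((Z - mu)^2) / (ncol(Z) - 1))
  den <- if (cv_mode == "abs") abs(mu) else mu
  cv <- ifelse(abs(mu) > eps, sd / den, NA_real_)
  list(mean = mu, sd = sd, cv = cv)
}
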