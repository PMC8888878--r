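#' Preprocessing configuration
#'
#' Defaults follow the study protocol: discard 10 volumes, despike with
#' robust thresholds c1 = 2.5 and c2 = 4.0 (robust-SD units), nuisance
#' regression (Friston-24 + WM/CSF means + linear trend), 0.01-0.1 Hz
#' band-pass, 6 mm FWHM smoothing, and motion QC at 3 mm / 3 degrees.
#'
#' @param n_discard initial volumes to drop.
#' @param despike_c1,despike_c2 spike threshold and compression ceiling, in
#'   robust-SD units; `c1 < c2`.
#' @param band passband `c(low, high)` in Hz.
#' @param fwhm_mm Gaussian smoothing kernel FWHM in mm (0 = no smoothing).
#' @param max_trans_mm,max_rot_deg motion QC limits (strict `>` fails).
#' @param stages character vector choosing and ordering the stages applied
#'   after the discard: any of `"despike"`, `"regress"`, `"bandpass"`,
#'   `"smooth"`.
#' @param bandpass_method `"fft"` (rectangular frequency mask) or
#'   `"butterworth"` (4th-order zero-phase, needs the signal package).
#' @export
preprocess_config <- function(n_discard = 10, despike_c1 = 2.5,
                              despike_c2 = 4.0, band = c(0.01, 0.1),
                              fwhm_mm = 6,
                              max_trans_mm = 3, max_rot_deg = 3,
                              stages = c("despike", "regress", "bandpass", "smooth"),
                              bandpass_method = c("fft", "butterworth")) {
  if (n_discard < 0) stop("n_discard must be >= 0")
  if (!(despike_c1 < despike_c2)) stop("despike thresholds need c1 < c2")
  if (!(band[1] >= 0 && band[1] < band[2])) stop("band must satisfy 0 <= low < high")
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  bad <- setdiff(stages, c("despike", "regress", "bandpass", "smooth"))
  if (length(bad)) stop(sprintf("unknown stages: %s", paste(bad, collapse = ", ")))
  structure(list(n_discard = as.integer(n_discard),
                 despike_c1 = despike_c1, despike_c2 = despike_c2,
                 band = as.numeric(band), fwhm_mm = fwhm_mm,
                 max_trans_mm = max_trans_mm, max_rot_deg = max_rot_deg,
                 stages = stages,
                 bandpass_method = match.arg(bandpass_method)),
            class = "preprocess_config")
}

#' Drop the initial volumes of a run
#'
#' @param run a [bold_run()].
#' @param n_discard number of leading volumes to remove (default 10); must
#'   be smaller than the run length.
#' @export
discard_initial <- function(run, n_discard = 10) {
  if (n_discard >= run$n_volumes)
    stop("n_discard must be smaller than the number of volumes")
  if (n_discard == 0) return(run)
  bold_run(run$data[, , , -(seq_len(n_discard)), drop = FALSE],
           tr = run$tr, grid = run$grid)
}

#' Despike a single time course
#'
#' Fits a 3rd-order polynomial trend by least squares, measures the robust
#' residual scale sigma = 1.4826 * median(|residual|), and compresses any
#' point whose standardized residual s = residual/sigma exceeds `c1`
#' towards the fit:
#' fit + sigma * (c1 + (c2 - c1) * tanh((s - c1)/(c2 - c1))),
#' symmetrically for negative spikes. Sub-threshold points are returned
#' unchanged, so compressed values never exceed fit + sigma * c2 in
#' magnitude. A zero robust scale (constant residuals) returns the input.
#'
#' @param series numeric vector, length >= 8.
#' @param c1 spike threshold, robust-SD units.
#' @param c2 asymptotic ceiling, robust-SD units; `c2 > c1`.
#' @export
despike <- function(series, c1 = 2.5, c2 = 4.0) {
  n <- length(series)
  if (n < 8) stop("series too short to despike (need >= 8 points)")
  if (!(c1 < c2)) stop("need c1 < c2")
  tt <- seq_len(n)
  X <- stats::poly(tt, 3)
  fit <- stats::lm.fit(cbind(1, X), series)$fitted.values
  res <- series - fit
  sigma <- 1.4826 * stats::median(abs(res))
  if (sigma == 0) return(series)
  s <- res / sigma
  out <- series
  hi <- s > c1
  lo <- s < -c1
  out[hi] <- fit[hi] + sigma * (c1 + (c2 - c1) * tanh((s[hi] - c1) / (c2 - c1)))
  out[lo] <- fit[lo] - sigma * (c1 + (c2 - c1) * tanh((-s[lo] - c1) / (c2 - c1)))
  out
}

#' Nuisance regressor set
#'
#' @param design time x regressor numeric matrix.
#' @param names regressor labels.
#' @param n_volumes optional expected row count.
#' @export
nuisance_set <- function(design, names = colnames(design), n_volumes = NULL) {
  design <- as.matrix(design)
  if (any(!is.finite(design))) stop("nuisance design must be finite")
  if (!is.null(n_volumes) && nrow(design) != n_volumes)
    stop("nuisance rows do not match run length")
  zero <- apply(design, 2, function(x) all(x == 0))
  if (any(zero)) stop("nuisance design contains all-zero columns")
  colnames(design) <- names
  structure(design, class = c("nuisance_set", "matrix", "array"))
}

#' Friston-24 motion regressors
#'
#' The 6 rigid-body parameters R(t), their one-volume backward shifts
#' R(t-1) (first row zero-padded), and the element-wise squares of both.
#' All-zero columns (degenerate motion input) are dropped with a warning.
#'
#' @param motion a [motion_trace()] (or any 6-column matrix).
#' @return A [nuisance_set()] with up to 24 named columns.
#' @export
build_friston24 <- function(motion) {
  m <- unclass(as.matrix(motion))
  if (ncol(m) != 6L) stop("motion input must have 6 columns")
  if (nrow(m) < 2L) stop("need at least 2 time points")
  lag <- rbind(0, m[-nrow(m), , drop = FALSE])
  X <- cbind(m, lag, m^2, lag^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(X) <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
                   paste0(base, "_lag_sq"))
  zero <- apply(X, 2, function(x) all(x == 0))
  if (any(zero)) {
    warning(sprintf("build_friston24: dropping %d all-zero columns (degenerate motion)",
                    sum(zero)))
    X <- X[, !zero, drop = FALSE]
    if (ncol(X) == 0) stop("all motion regressors are zero")
  }
  nuisance_set(X)
}

#' WM and CSF mean-signal regressors
#'
#' @param run a [bold_run()].
#' @param masks a [brain_masks()] with nonempty wm and csf.
#' @return A [nuisance_set()] with columns `wm_mean`, `csf_mean`.
#' @export
tissue_regressors <- function(run, masks) {
  if (!grids_equal(run$grid, masks$grid)) stop("run and masks on different grids")
  if (!any(masks$wm)) stop("wm mask is empty")
  if (!any(masks$csf)) stop("csf mask is empty")
  Y <- voxel_matrix(run, masks$wm)
  wm_mean <- colMeans(Y)
  csf_mean <- colMeans(voxel_matrix(run, masks$csf))
  nuisance_set(cbind(wm_mean = wm_mean, csf_mean = csf_mean),
               n_volumes = run$n_volumes)
}

# extract a voxels x time matrix over a logical mask
voxel_matrix <- function(run, mask) {
  d <- dim(run$data)
  matrix(run$data[rep(which(mask), d[4]) +
                  rep((0:(d[4] - 1)) * prod(d[1:3]), each = sum(mask))],
         nrow = sum(mask))
}

# write a voxels x time matrix back into a run's data over a mask
set_voxel_matrix <- function(run, mask, Y) {
  d <- dim(run$data)
  run$data[rep(which(mask), d[4]) +
           rep((0:(d[4] - 1)) * prod(d[1:3]), each = sum(mask))] <- Y
  run
}

#' Regress nuisance signals out of every voxel
#'
#' Ordinary least squares of each voxel series on
#' `[intercept, linear trend, nuisance columns]`; the residuals replace the
#' data. Rank-deficient designs are handled by projection onto the design
#' column space (pivoted QR), with a warning.
#'
#' @param run a [bold_run()].
#' @param nuisance a [nuisance_set()] (or NULL for trend-only detrending).
#' @param mask optional logical array restricting the voxels processed
#'   (default: all voxels).
#' @export
regress_nuisance <- function(run, nuisance = NULL, mask = NULL) {
  n <- run$n_volumes
  if (!is.null(nuisance) && nrow(nuisance) != n)
    stop("nuisance rows do not match run length")
  X <- cbind(intercept = 1, trend = seq_len(n) - (n + 1) / 2)
  if (!is.null(nuisance)) X <- cbind(X, unclass(nuisance))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning(sprintf("regress_nuisance: design rank %d < %d columns; residuals via projection",
                    qx$rank, ncol(X)))
  if (is.null(mask)) mask <- array(TRUE, dim(run$data)[1:3])
  Y <- t(voxel_matrix(run, mask))           # time x voxels
  R <- qr.resid(qx, Y)
  set_voxel_matrix(run, mask, t(R))
}

#' Band-pass filter every voxel series
#'
#' Default is an ideal (rectangular) discrete-Fourier filter: coefficients
#' with frequency in `[low, high]` are kept, all others (including DC) are
#' zeroed, and the real signal is reconstructed. Applying it twice changes
#' nothing. A 4th-order zero-phase Butterworth alternative is available.
#'
#' @param run a [bold_run()].
#' @param low,high passband edges in Hz; `high` must be below Nyquist.
#' @param method `"fft"` or `"butterworth"`.
#' @param mask optional logical array restricting the voxels filtered.
#' @export
bandpass <- function(run, low = 0.01, high = 0.1,
                     method = c("fft", "butterworth"), mask = NULL) {
  method <- match.arg(method)
  nyq <- 1 / (2 * run$tr)
  if (!(low >= 0 && low < high)) stop("need 0 <= low < high")
  if (high >= nyq) stop(sprintf("high edge %g Hz is at/above Nyquist %g Hz", high, nyq))
  if (is.null(mask)) mask <- array(TRUE, dim(run$data)[1:3])
  Y <- t(voxel_matrix(run, mask))           # time x voxels
  n <- nrow(Y)
  if (method == "fft") {
    f <- frequency_axis(n, run$tr)
    keep <- f >= low & f <= high
    keep[1] <- FALSE
    Yf <- stats::mvfft(Y)
    Yf[!keep, ] <- 0
    Y <- Re(stats::mvfft(Yf, inverse = TRUE)) / n
  } else {
    if (!requireNamespace("signal", quietly = TRUE))
      stop("butterworth band-pass needs the signal package")
    bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
    Y <- apply(Y, 2, function(x) signal::filtfilt(bf, x))
  }
  set_voxel_matrix(run, mask, t(Y))
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian with per-axis sigma = fwhm / (voxel_size *
#' 2*sqrt(2*log(2))), truncated at 3.5 sigma; near edges the kernel is
#' renormalized over the in-volume support so constant volumes are
#' preserved. `fwhm_mm = 0` is the identity. Accepts a [bold_run()]
#' (smooths each volume) or a 3D array.
#'
#' @param x a [bold_run()] or 3D numeric array.
#' @param fwhm_mm kernel FWHM in mm, >= 0.
#' @param grid required when `x` is an array.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 6, grid = NULL) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (inherits(x, "bold_run")) {
    if (fwhm_mm == 0) return(x)
    for (t in seq_len(x$n_volumes))
      x$data[, , , t] <- smooth_array3(x$data[, , , t], fwhm_mm, x$grid$voxel_mm)
    return(x)
  }
  if (is.null(grid)) stop("grid is required when smoothing a bare array")
  if (fwhm_mm == 0) return(x)
  smooth_array3(x, fwhm_mm, grid$voxel_mm)
}

gauss_kernel_matrix <- function(n, sigma_vox) {
  half <- max(1L, ceiling(3.5 * sigma_vox))
  off <- -half:half
  w <- exp(-off^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

smooth_array3 <- function(a, fwhm_mm, voxel_mm) {
  d <- dim(a)
  sig <- fwhm_mm / (voxel_mm * 2 * sqrt(2 * log(2)))
  # axis 1
  K <- gauss_kernel_matrix(d[1], sig[1])
  a <- array(K %*% matrix(a, d[1]), d)
  # axis 2
  K <- gauss_kernel_matrix(d[2], sig[2])
  a <- aperm(array(K %*% matrix(aperm(a, c(2, 1, 3)), d[2]), d[c(2, 1, 3)]),
             c(2, 1, 3))
  # axis 3
  K <- gauss_kernel_matrix(d[3], sig[3])
  aperm(array(K %*% matrix(aperm(a, c(3, 1, 2)), d[3]), d[c(3, 1, 2)]),
        c(2, 3, 1))
}

#' Motion quality control
#'
#' Fails when the maximum absolute translation on any axis exceeds
#' `max_trans_mm` or the maximum absolute rotation exceeds `max_rot_deg`
#' (strictly greater; a subject exactly at the limit passes). Rotations in
#' the trace are radians; the degree threshold is converted internally.
#'
#' @param motion a [motion_trace()].
#' @param max_trans_mm,max_rot_deg thresholds.
#' @return list with `pass`, `max_translation_mm`, `max_rotation_deg`.
#' @export
motion_qc <- function(motion, max_trans_mm = 3, max_rot_deg = 3) {
  m <- unclass(as.matrix(motion))
  if (nrow(m) == 0) stop("empty motion trace")
  mt <- max(abs(m[, 1:3]))
  mr <- max(abs(m[, 4:6])) * 180 / pi
  list(pass = !(mt > max_trans_mm || mr > max_rot_deg),
       max_translation_mm = mt, max_rotation_deg = mr)
}

#' Full temporal preprocessing of one run
#'
#' Applies, in order: motion QC (abort on failure unless
#' `override_qc = TRUE`), volume discard, then the stages listed in
#' `config$stages` — per-voxel despiking over the brain (GM/WM/CSF union),
#' nuisance regression (Friston-24 + tissue means + intercept/trend),
#' band-pass, Gaussian smoothing. The stage order is configurable; the
#' order actually applied is recorded in the attached log.
#'
#' @param run a [bold_run()].
#' @param motion a [motion_trace()] matching the run.
#' @param masks a [brain_masks()] on the run grid.
#' @param config a [preprocess_config()].
#' @param override_qc proceed despite a motion QC failure.
#' @return The preprocessed [bold_run()] with a `log` attribute (list of
#'   stage parameters, QC maxima and modified-voxel counts).
#' @export
preprocess_run <- function(run, motion, masks, config = preprocess_config(),
                           override_qc = FALSE) {
  if (nrow(motion) != run$n_volumes)
    stop("motion trace does not match run length")
  qc <- motion_qc(motion, config$max_trans_mm, config$max_rot_deg)
  if (!qc$pass && !override_qc)
    stop(sprintf("motion QC failed (max %.2f mm, %.2f deg)",
                 qc$max_translation_mm, qc$max_rotation_deg))
  log <- list(qc = qc, config = config, stages_applied = character(0))

  run <- discard_initial(run, config$n_discard)
  if (config$n_discard > 0)
    motion <- motion_trace(unclass(motion)[-(seq_len(config$n_discard)), ,
                                           drop = FALSE])
  brain <- masks$gm | masks$wm | masks$csf

  for (stage in config$stages) {
    if (stage == "despike") {
      Y <- voxel_matrix(run, brain)
      Yd <- t(apply(Y, 1, despike, c1 = config$despike_c1,
                    c2 = config$despike_c2))
      log$despiked_points <- sum(Yd != Y)
      run <- set_voxel_matrix(run, brain, Yd)
    } else if (stage == "regress") {
      tis <- cbind(wm_mean = colMeans(voxel_matrix(run, masks$wm)),
                   csf_mean = colMeans(voxel_matrix(run, masks$csf)))
      nui <- cbind(unclass(build_friston24(motion)), tis)
      zero <- apply(nui, 2, function(x) all(x == 0))
      if (any(zero)) {
        warning(sprintf("preprocess_run: dropping %d all-zero nuisance columns",
                        sum(zero)))
        nui <- nui[, !zero, drop = FALSE]
      }
      run <- regress_nuisance(run, nuisance_set(nui), mask = brain)
    } else if (stage == "bandpass") {
      run <- bandpass(run, config$band[1], config$band[2],
                      method = config$bandpass_method, mask = brain)
    } else if (stage == "smooth") {
      run <- smooth_gaussian(run, config$fwhm_mm)
    }
    log$stages_applied <- c(log$stages_applied, stage)
  }
  attr(run, "log") <- log
  run
}
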