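#' Band-limited unit-variance random series
#'
#' White Gaussian noise restricted in the discrete Fourier domain to the
#' frequency band `band` (Hz), then rescaled to unit sample variance. This
#' is the shared "global" component of the synthetic signal model; it is
#' generated directly in the 0.01-0.1 Hz analysis band so that band-pass
#' preprocessing leaves it intact.
#'
#' @param n number of samples.
#' @param tr sampling interval in seconds.
#' @param band `c(low, high)` passband in Hz.
#' @return numeric vector of length `n`, mean 0, sample variance 1.
#' @export
band_limited_series <- function(n, tr, band = c(0.01, 0.1)) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- frequency_axis(n, tr)
  keep <- f >= band[1] & f <= band[2]
  keep[1] <- FALSE  # no DC
  xf[!keep] <- 0
  g <- Re(stats::fft(xf, inverse = TRUE)) / n
  g <- g - mean(g)
  g / stats::sd(g)
}

# per-bin frequency magnitude of an n-point DFT sampled at interval tr
frequency_axis <- function(n, tr) {
  k <- 0:(n - 1)
  pmin(k, n - k) / (n * tr)
}

#' Ground-truth parameters of the synthetic signal model
#'
#' The generative model for a voxel v at sample t (t = 0, 1, ...) is
#' \deqn{y_v(t) = b_v (1 + m_v \sin(2\pi t\,TR/\tau + \phi_v))\, g(t) + d_v(t) + \epsilon_v(t)}
#' where `g` is the shared band-limited component, `b_v` a static coupling
#' weight, `m_v` a modulation depth in [0, 1) controlling how strongly the
#' voxel's coupling waxes and wanes over the scan, `phi_v` a per-voxel
#' random phase, `d_v` a slow polynomial drift and `epsilon` white noise.
#' Group effects add ROI-specific offsets to `m_v`, so groups differ in the
#' *temporal variability* of coupling while static coupling stays matched.
#'
#' Default coupling and modulation fields are smooth deterministic spatial
#' patterns over the GM shell (coupling 0.7-1.3, modulation 0.05-0.35),
#' weak coupling in WM/CSF, zero outside the brain. The default group
#' effects raise modulation depth at the "right_insula" ROI in the order
#' HC < ARCI < AUD-NCI and in the reversed order at "precuneus".
#'
#' @param masks a [brain_masks()] from [make_phantom()] (or compatible).
#' @param coupling optional 3D array overriding the default b field.
#' @param modulation_depth optional 3D array overriding the default m field.
#' @param modulation_period modulation period tau in seconds.
#' @param noise_sd white-noise SD in signal units (g has unit variance).
#' @param drift_amp SD of the slow polynomial drift, signal units.
#' @param group_effects named list: group -> named numeric vector of
#'   ROI -> modulation-depth offset.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(masks,
                         coupling = NULL,
                         modulation_depth = NULL,
                         modulation_period = 60,
                         noise_sd = 1.0,
                         drift_amp = 0.5,
                         group_effects = default_group_effects()) {
  grid <- masks$grid
  dims <- grid$dims
  if (is.null(coupling) || is.null(modulation_depth)) {
    u <- normalized_coords(dims)
    f1 <- (1 + sin(2 * pi * (0.70 * u$x + 0.45 * u$y + 0.30 * u$z))) / 2
    f2 <- (1 + cos(2 * pi * (0.33 * u$x - 0.60 * u$y + 0.80 * u$z))) / 2
    if (is.null(coupling)) {
      # GM couples to the shared component with a smooth spatial profile;
      # WM/CSF carry only noise and drift (they are the nuisance proxies
      # the preprocessing regresses out, so they must not carry g)
      coupling <- array(0, dims)
      coupling[masks$gm] <- 0.7 + 0.6 * f1[masks$gm]
    }
    if (is.null(modulation_depth)) {
      modulation_depth <- array(0, dims)
      modulation_depth[masks$gm] <- 0.05 + 0.30 * f2[masks$gm]
    }
  }
  stopifnot(identical(dim(coupling), as.integer(dims)),
            identical(dim(modulation_depth), as.integer(dims)))
  if (any(abs(modulation_depth) >= 1))
    stop("modulation depth must satisfy |m| < 1 everywhere")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (modulation_period <= 0) stop("modulation_period must be > 0")
  truth <- structure(list(masks = masks, grid = grid,
                          coupling = coupling,
                          modulation_depth = modulation_depth,
                          modulation_period = modulation_period,
                          noise_sd = noise_sd, drift_amp = drift_amp,
                          group_effects = group_effects),
                     class = "ground_truth")
  # every group's effective depth must stay in (-1, 1)
  for (grp in names(group_effects)) modulation_for_group(truth, grp)
  truth
}

#' Default group-specific modulation-depth offsets
#'
#' HC < ARCI < AUD-NCI at the right insula (offsets 0, +delta/2, +delta)
#' and the reverse at the precuneus. The magnitudes are synthetic choices,
#' not estimates: delta is sized (by a calibration sweep documented in the
#' methods vignette) so the weakest adjacent-group CV contrast remains
#' reliably detectable at the study group sizes.
#' @param delta full modulation-depth increment between extreme groups.
#' @export
default_group_effects <- function(delta = 0.40) {
  list("HC"      = c(right_insula = 0,         precuneus = delta),
       "ARCI"    = c(right_insula = delta / 2, precuneus = delta / 2),
       "AUD-NCI" = c(right_insula = delta,     precuneus = 0))
}

normalized_coords <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  list(x = array(rep((0:(nx - 1)) / max(nx - 1, 1), ny * nz), dims),
       y = array(rep(rep((0:(ny - 1)) / max(ny - 1, 1), each = nx), nz), dims),
       z = array(rep((0:(nz - 1)) / max(nz - 1, 1), each = nx * ny), dims))
}

#' Effective modulation-depth field for one group
#'
#' Baseline depth plus the group's ROI offsets; errors if any voxel leaves
#' the valid range (-1, 1).
#' @param truth a [ground_truth()].
#' @param group group label present in `truth$group_effects`.
#' @return 3D array of modulation depths.
#' @export
modulation_for_group <- function(truth, group) {
  m <- truth$modulation_depth
  eff <- truth$group_effects[[group]]
  if (is.null(eff) && !group %in% names(truth$group_effects))
    stop(sprintf("group '%s' has no entry in group_effects", group))
  for (roi in names(eff)) {
    mask <- truth$masks$roi_labels[[roi]]
    if (is.null(mask)) stop(sprintf("ROI '%s' not found in masks", roi))
    m[mask] <- m[mask] + eff[[roi]]
  }
  if (any(abs(m) >= 1))
    stop(sprintf("group '%s' pushes modulation depth out of (-1, 1)", group))
  m
}

#' Cohort design: sizes, grid, temporal geometry, master seed
#'
#' Defaults mirror the study conditions: 400 volumes at TR 1 s and group
#' sizes HC 40, AUD-NCI 54, ARCI 26.
#'
#' @param n_per_group named counts per group.
#' @param dims phantom grid dims.
#' @param tr repetition time, seconds.
#' @param n_volumes volumes per run (before any discard).
#' @param seed master seed; all subject seeds derive from it.
#' @param max_window longest analysis window (TRs) the design must support.
#' @export
cohort_design <- function(n_per_group = c("HC" = 40, "AUD-NCI" = 54, "ARCI" = 26),
                          dims = c(16, 16, 16), tr = 1.0, n_volumes = 400,
                          seed = 20230901, max_window = 30) {
  if (any(n_per_group < 1)) stop("group counts must be >= 1")
  if (n_volumes <= max_window + 10)
    stop("n_volumes must exceed the longest window plus 10 discarded volumes")
  if (tr <= 0) stop("tr must be > 0")
  structure(list(n_per_group = n_per_group, dims = as.integer(dims), tr = tr,
                 n_volumes = as.integer(n_volumes), seed = as.integer(seed)),
            class = "cohort_design")
}

# stable 32-bit-range seed derived from a master seed and a string tag
derive_seed <- function(master, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147480009
  as.integer((h + (as.numeric(master) %% 2147480009) * 7919) %% 2147483587)
}

#' Simulate one subject's BOLD run and motion trace
#'
#' Draws the shared band-limited component, per-voxel phases, drifts and
#' white noise from `subject_seed`, assembles the voxel series by the
#' [ground_truth()] signal model on the in-brain voxels (background stays
#' exactly zero) and adds a small smooth random-walk motion trace kept
#' below QC thresholds.
#'
#' @param truth a [ground_truth()].
#' @param design a [cohort_design()].
#' @param group group label.
#' @param subject_seed integer seed; same seed, same run.
#' @param format `"array"` (default) returns a full [bold_run()];
#'   `"matrix"` skips the 4D embedding and returns the in-brain
#'   voxels-by-time matrix plus their linear indices — the same values the
#'   array path would hold, for memory-lean cohort sweeps.
#' @return list with `run` ([bold_run()]; or, for `format = "matrix"`, a
#'   list with `Y`, `voxels`, `tr`, `grid`), `motion` ([motion_trace()])
#'   and `shared` (the g(t) series, for validation work).
#' @export
simulate_subject <- function(truth, design, group, subject_seed,
                             format = c("array", "matrix")) {
  format <- match.arg(format)
  grid <- truth$grid
  if (!identical(grid$dims, as.integer(design$dims)))
    stop("ground truth grid does not match the design dims")
  masks <- truth$masks
  n <- design$n_volumes
  tr <- design$tr
  m3 <- modulation_for_group(truth, group)
  brain <- masks$gm | masks$wm | masks$csf
  bi <- which(brain)
  V <- length(bi)

  set.seed(as.integer(subject_seed))
  g <- band_limited_series(n, tr)
  phase <- balanced_phases(truth$coupling[bi] * m3[bi],
                           roi_items(masks, bi))
  # slow drift: centered polynomial basis, each column unit-SD, coefficients
  # scaled so the drift SD is about drift_amp
  tt <- seq(-1, 1, length.out = n)
  B <- cbind(tt, tt^2 - mean(tt^2), tt^3 - mean(tt^3) * 0 - tt * 3 / 5)
  B <- sweep(B, 2, apply(B, 2, stats::sd), "/")
  coefs <- matrix(stats::rnorm(V * 3), V, 3) * (truth$drift_amp / sqrt(3))
  omega <- 2 * pi * tr / truth$modulation_period

  Y <- cpp_simulate_voxels(g, truth$coupling[bi], m3[bi], phase, omega,
                           B, coefs, truth$noise_sd)
  motion <- simulate_motion(n)
  if (format == "matrix") {
    run <- list(Y = Y, voxels = bi, tr = tr, grid = grid, n_volumes = n)
  } else {
    arr <- array(0, c(grid$dims, n))
    nvox <- prod(grid$dims)
    arr[rep(bi, n) + rep((0:(n - 1)) * nvox, each = V)] <- Y
    run <- bold_run(arr, tr = tr, grid = grid)
  }
  list(run = run, motion = motion, shared = g)
}

# Two-point modulation phases (0 or pi), sign-balanced greedily against the
# coupling-weighted depths so the amplitude modulation cancels from the
# GM mean: the shared component then stays exactly recoverable from the
# global signal, and per-voxel windowed-correlation variability is
# attributable to the voxel's own modulation depth. `items` groups voxels
# that must share one sign (each ROI is one item, so its modulation stays
# spatially coherent and survives smoothing); all other voxels are
# balanced individually. Deterministic (no RNG).
balanced_phases <- function(w, items = seq_along(w)) {
  sums <- vapply(split(abs(w), items), sum, numeric(1))
  ord <- order(sums, decreasing = TRUE)
  sign_of <- numeric(length(sums))
  s_pos <- 0; s_neg <- 0
  for (i in ord) {
    if (s_pos <= s_neg) { sign_of[i] <- 0;  s_pos <- s_pos + sums[i] }
    else                { sign_of[i] <- pi; s_neg <- s_neg + sums[i] }
  }
  unname(sign_of[match(as.character(items), names(sums))])
}

# item ids for balanced_phases: each labeled ROI is a single item, every
# other in-brain voxel is its own item
roi_items <- function(masks, brain_idx) {
  items <- as.character(seq_along(brain_idx))
  for (nm in names(masks$roi_labels)) {
    hit <- which(masks$roi_labels[[nm]][brain_idx])
    items[hit] <- nm
  }
  items
}

# smooth random-walk motion, rescaled to stay well below 3 mm / 3 degrees
simulate_motion <- function(n) {
  step_sd <- c(rep(0.01, 3), rep(2e-4, 3))
  m <- vapply(step_sd, function(s) cumsum(stats::rnorm(n, sd = s)),
              numeric(n))
  m <- sweep(m, 2, m[1, ])
  cap <- c(rep(1.0, 3), rep(0.01, 3))
  mx <- apply(abs(m), 2, max)
  over <- mx > cap
  m[, over] <- sweep(m[, over, drop = FALSE], 2, (cap / mx)[over], "*")
  motion_trace(m, n_volumes = n)
}

#' Simulate a full three-group cohort
#'
#' Generates every subject with a seed derived from the design's master
#' seed and the subject id (so cohorts are reproducible and extensible),
#' draws behavioral scores per group, and either writes everything to
#' `dir` (NIfTI runs, motion text files, cohort TSV, ground-truth coupling
#' and modulation maps, JSON parameter sidecar) or streams subjects through
#' `per_subject` without keeping runs in memory.
#'
#' Behavioral scores are drawn independently of the imaging signal model
#' (normal or truncated-normal per group), so score-imaging correlations
#' are null by construction.
#'
#' @param truth a [ground_truth()].
#' @param design a [cohort_design()].
#' @param dir output directory, created if needed; `NULL` for no file output.
#' @param per_subject optional `function(sim, id, group)` applied to each
#'   simulated subject (`sim` as returned by [simulate_subject()]); its
#'   results are collected in the return value and the run is discarded.
#'   When `NULL` and `dir` is `NULL`, full runs are kept (memory heavy for
#'   large cohorts).
#' @param subject_format passed to [simulate_subject()] (`"array"` or
#'   `"matrix"`); file output requires `"array"`.
#' @return list with `cohort` ([cohort_table()]), `subjects` (list of
#'   per-subject results: file paths, `per_subject` values, or simulations).
#' @export
simulate_cohort <- function(truth, design, dir = NULL, per_subject = NULL,
                            subject_format = "array") {
  if (!is.null(dir) && subject_format != "array")
    stop("file output requires subject_format = 'array'")
  groups <- names(design$n_per_group)
  ids <- unlist(lapply(groups, function(g) {
    tag <- tolower(gsub("[^A-Za-z]", "", g))
    sprintf("%s%02d", tag, seq_len(design$n_per_group[[g]]))
  }))
  grp <- rep(groups, times = unlist(design$n_per_group))

  set.seed(derive_seed(design$seed, "behavioral-scores"))
  scores <- do.call(rbind, lapply(groups, function(g)
    simulate_scores(g, design$n_per_group[[g]])))
  cohort <- cohort_table(data.frame(id = ids, group = grp, scores,
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop(sprintf("cannot create output directory %s", dir))
  }

  subjects <- vector("list", length(ids))
  names(subjects) <- ids
  for (i in seq_along(ids)) {
    sim <- simulate_subject(truth, design, grp[i], derive_seed(design$seed, ids[i]),
                            format = subject_format)
    if (!is.null(per_subject)) {
      subjects[[i]] <- per_subject(sim, ids[i], grp[i])
    } else if (!is.null(dir)) {
      bold_path <- file.path(dir, paste0(ids[i], "_bold.nii.gz"))
      mot_path <- file.path(dir, paste0(ids[i], "_motion.txt"))
      write_bold(sim$run, bold_path)
      write_motion(sim$motion, mot_path)
      subjects[[i]] <- list(bold = bold_path, motion = mot_path)
    } else {
      subjects[[i]] <- sim
    }
  }

  if (!is.null(dir)) {
    write_cohort(cohort, file.path(dir, "cohort.tsv"))
    write_map(truth$coupling, truth$grid, file.path(dir, "truth_coupling.nii.gz"))
    write_map(truth$modulation_depth, truth$grid,
              file.path(dir, "truth_modulation.nii.gz"))
    params <- list(seed = design$seed, tr = design$tr,
                   n_volumes = design$n_volumes, dims = design$dims,
                   n_per_group = as.list(design$n_per_group),
                   modulation_period = truth$modulation_period,
                   noise_sd = truth$noise_sd, drift_amp = truth$drift_amp,
                   group_effects = truth$group_effects)
    jsonlite::write_json(params, file.path(dir, "simulation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = cohort, subjects = subjects)
}

# truncated-normal draw by inverse CDF
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

# Behavioral score distributions per group. HC column and AUD column follow
# the study's reported means/SDs; MMSE/MoCA for the two patient subgroups
# are truncated to respect the grouping rule (ARCI: MMSE < 24 and
# MoCA < 26; AUD-NCI: MMSE >= 24 and MoCA >= 26). Scores are independent
# of the imaging model.
simulate_scores <- function(group, n) {
  if (group == "HC") {
    data.frame(
      MMSE = rtnorm(n, 29.6, 0.6, upper = 30),
      MoCA = rtnorm(n, 26.3, 1.2, upper = 30),
      ADS = rtnorm(n, 1.50, 0.74, lower = 0),
      `CIWA-Ar` = rtnorm(n, 0.51, 0.12, lower = 0),
      OCDS = rtnorm(n, 2.23, 1.67, lower = 0),
      VAS = rtnorm(n, 1.63, 0.74, lower = 0),
      `PHQ-9` = rtnorm(n, 5.32, 1.74, lower = 0),
      pure_alcohol_total = rtnorm(n, 629.99, 192.17, lower = 0),
      check.names = FALSE)
  } else {
    nci <- group == "AUD-NCI"
    data.frame(
      MMSE = if (nci) rtnorm(n, 27.6, 1.5, lower = 24, upper = 30)
             else rtnorm(n, 22.0, 1.5, upper = 24 - 1e-9),
      MoCA = if (nci) rtnorm(n, 26.9, 0.9, lower = 26, upper = 30)
             else rtnorm(n, 21.5, 1.8, upper = 26 - 1e-9),
      ADS = rtnorm(n, 26.06, 3.55, lower = 0),
      `CIWA-Ar` = rtnorm(n, 8.15, 2.74, lower = 0),
      OCDS = rtnorm(n, 12.67, 2.57, lower = 0),
      VAS = rtnorm(n, 2.12, 0.89, lower = 0),
      `PHQ-9` = rtnorm(n, 6.79, 1.52, lower = 0),
      pure_alcohol_total = rtnorm(n, 325262.37, 30806.74, lower = 0),
      check.names = FALSE)
  }
}
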