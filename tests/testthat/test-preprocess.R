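test_that("volume discard trims correctly and composes", {
  grid <- volume_grid(c(6, 6, 6))
  run <- noise_run(grid, n_volumes = 40)
  expect_equal(discard_initial(run, 10)$n_volumes, 30)
  expect_identical(discard_initial(run, 0), run)
  expect_error(discard_initial(run, 40), "smaller")
  # discard n1 then n2 equals discard n1 + n2
  expect_equal(discard_initial(discard_initial(run, 5), 7)$data,
               discard_initial(run, 12)$data)
})

test_that("despike compresses only supra-threshold points, bounded by c2", {
  tt <- 1:100
  cubic <- 2 + 0.5 * tt - 0.02 * tt^2 + 1e-4 * tt^3
  expect_equal(despike(cubic), cubic, tolerance = 1e-8)

  set.seed(5)
  x <- rnorm(100, sd = 1)
  fit <- stats::lm.fit(cbind(1, stats::poly(1:100, 3)), x)$fitted.values
  res <- x - fit
  sigma <- 1.4826 * stats::median(abs(res))
  spiked <- x
  spiked[50] <- fit[50] + 10 * sigma
  out <- despike(spiked, 2.5, 4.0)
  # evaluate the compression formula directly as the oracle
  fit2 <- stats::lm.fit(cbind(1, stats::poly(1:100, 3)), spiked)$fitted.values
  res2 <- spiked - fit2
  sig2 <- 1.4826 * stats::median(abs(res2))
  s <- res2[50] / sig2
  expected <- fit2[50] + sig2 * (2.5 + 1.5 * tanh((s - 2.5) / 1.5))
  expect_equal(out[50], expected)
  expect_lt(out[50], spiked[50])
  expect_lt(out[50], fit2[50] + sig2 * 4.0)

  # all sub-threshold points pass through unchanged
  mild <- despike(x, c1 = 8, c2 = 10)
  expect_identical(mild, x)
  # constant residuals (sigma = 0) return the input
  expect_identical(despike(rep(3, 20)), rep(3, 20))
  expect_error(despike(1:5), "short")
})

test_that("Friston-24 design has the documented structure", {
  set.seed(8)
  mot <- motion_trace(matrix(rnorm(60, sd = 0.2), 10, 6))
  X <- build_friston24(mot)
  expect_equal(ncol(X), 24)
  expect_equal(colnames(X)[1:6], c("tx", "ty", "tz", "rx", "ry", "rz"))
  # backward shift with zero-padded first row
  expect_equal(unname(X[1, 7:12]), rep(0, 6))
  expect_equal(unname(X[2:10, 7]), unname(X[1:9, 1]))
  # squares
  expect_equal(unname(X[, 13:18]), unname(X[, 1:6]^2))

  cm <- motion_trace(matrix(rep(c(1, 2, 3, 0.1, 0.2, 0.3), each = 10), 10, 6))
  Xc <- build_friston24(cm)
  expect_equal(unname(Xc[5, "tx_sq"]), 1)
  expect_equal(unname(Xc[5, "ty_sq"]), 4)

  expect_warning(Xz <- build_friston24(motion_trace(cbind(matrix(0, 10, 3),
                                                          matrix(rnorm(30), 10, 3)))),
                 "all-zero")
  expect_lt(ncol(Xz), 24)
  expect_error(build_friston24(matrix(0, 10, 5)), "6 columns")
})

test_that("tissue regressors are mask means", {
  ph <- small_phantom()
  run <- noise_run(ph$grid, 20)
  run$data[rep(which(ph$masks$wm), 20) +
           rep((0:19) * prod(ph$grid$dims), each = sum(ph$masks$wm))] <- 5
  X <- tissue_regressors(run, ph$masks)
  expect_equal(unname(X[, "wm_mean"]), rep(5, 20))

  # checkerboard values {0, 2} average to 1
  wmidx <- which(ph$masks$wm)
  vals <- rep(c(0, 2), length.out = length(wmidx))
  for (t in 0:19)
    run$data[wmidx + t * prod(ph$grid$dims)] <- vals
  X2 <- tissue_regressors(run, ph$masks)
  expect_equal(unname(X2[, "wm_mean"]), rep(1, 20))

  bad <- ph$masks; bad$csf[] <- FALSE
  expect_error(tissue_regressors(run, bad), "csf mask is empty")
})

test_that("nuisance regression produces orthogonal residuals and exact fits", {
  ph <- small_phantom()
  run <- noise_run(ph$grid, 30)
  nui <- tissue_regressors(run, ph$masks)

  # a voxel that is an exact linear combination regresses to zero
  v <- which(ph$masks$gm)[1]
  for (t in 0:29)
    run$data[v + t * prod(ph$grid$dims)] <- 3 * nui[t + 1, "wm_mean"] + 7
  out <- regress_nuisance(run, nui)
  expect_lt(max(abs(out$data[v + (0:29) * prod(ph$grid$dims)])), 1e-8)

  # residuals orthogonal to every design column
  X <- cbind(1, seq_len(30) - 15.5, unclass(nui))
  R <- t(gstopo:::voxel_matrix(out, ph$masks$gm))
  dots <- crossprod(X, R)
  norms <- outer(sqrt(colSums(X^2)), sqrt(colSums(R^2)))
  expect_lt(max(abs(dots) / pmax(norms, 1e-12)), 1e-6)

  # duplicated columns take the projection path and leave residuals unchanged
  dup <- cbind(unclass(nui), unclass(nui))
  colnames(dup) <- c("a", "b", "a2", "b2")
  expect_warning(out2 <- regress_nuisance(run, nuisance_set(dup)), "rank")
  expect_equal(out2$data, out$data, tolerance = 1e-10)

  expect_error(regress_nuisance(run, nuisance_set(matrix(1:20, 20, 1))),
               "match run length")
  expect_error(nuisance_set(cbind(0, rnorm(10))), "all-zero")
})

test_that("rectangular band-pass follows exact DFT bin arithmetic", {
  grid <- volume_grid(c(4, 4, 4))
  n <- 390
  tt <- 0:(n - 1)
  mk <- function(f)
    bold_run(aperm(array(sin(2 * pi * f * tt), c(n, 4, 4, 4)), c(2, 3, 4, 1)),
             tr = 1, grid = grid)
  # 0.2 Hz is outside 0.01-0.1: output power < 1% of input power
  hi <- mk(0.2)
  out <- bandpass(hi, 0.01, 0.1)
  expect_lt(sum(out$data^2) / sum(hi$data^2), 0.01)

  # a bin-aligned 0.05 Hz sinusoid (k = 19.5? use k/n) passes unchanged
  k <- 20  # 20/390 = 0.0513 Hz, inside the band
  lo <- bold_run(aperm(array(sin(2 * pi * k * tt / n), c(n, 4, 4, 4)),
                       c(2, 3, 4, 1)), tr = 1, grid = grid)
  out2 <- bandpass(lo, 0.01, 0.1)
  expect_equal(out2$data, lo$data, tolerance = 1e-8)

  # idempotence of the rectangular mask
  rnd <- noise_run(grid, n)
  b1 <- bandpass(rnd, 0.01, 0.1)
  b2 <- bandpass(b1, 0.01, 0.1)
  expect_equal(b2$data, b1$data, tolerance = 1e-12)

  # spectrum is exactly zero outside the passband bins
  v <- b1$data[1, 1, 1, ]
  sp <- abs(stats::fft(v))
  f <- pmin(0:(n - 1), n - (0:(n - 1))) / n
  expect_lt(max(sp[f < 0.01 | f > 0.1]), 1e-9 * max(sp))

  expect_error(bandpass(rnd, 0.01, 0.6), "Nyquist")
})

test_that("Gaussian smoothing preserves constants and matches the sampled kernel", {
  grid <- volume_grid(c(13, 13, 13), voxel_mm = c(3, 3, 3))
  const <- array(2.5, c(13, 13, 13))
  expect_equal(smooth_gaussian(const, 6, grid), const, tolerance = 1e-12)
  expect_identical(smooth_gaussian(const, 0, grid), const)
  expect_error(smooth_gaussian(const, -1, grid), ">= 0")

  # delta response deep in the interior (full kernel support) equals the
  # directly evaluated normalized separable kernel
  delta <- array(0, c(13, 13, 13)); delta[7, 7, 7] <- 1
  sm <- smooth_gaussian(delta, 6, grid)
  sigma <- 6 / (3 * 2 * sqrt(2 * log(2)))
  half <- max(1, ceiling(3.5 * sigma))
  off <- -half:half
  w <- exp(-off^2 / (2 * sigma^2)); w <- w / sum(w)
  expected <- outer(outer(w, w), w)
  got <- sm[7 + off, 7 + off, 7 + off]
  expect_equal(got, expected, tolerance = 1e-12, ignore_attr = TRUE)
  # one-voxel offset over peak ratio
  expect_equal(sm[8, 7, 7] / sm[7, 7, 7], exp(-1 / (2 * sigma^2)))
})

test_that("motion QC applies strict thresholds", {
  zero <- motion_trace(matrix(0, 10, 6))
  expect_true(motion_qc(zero)$pass)

  m <- matrix(0, 10, 6); m[4, 2] <- 3.1
  expect_false(motion_qc(motion_trace(m))$pass)

  m2 <- matrix(0, 10, 6); m2[4, 5] <- 3.0 * pi / 180  # exactly 3 degrees
  qc <- motion_qc(motion_trace(m2))
  expect_true(qc$pass)
  expect_equal(qc$max_rotation_deg, 3)
  m3 <- matrix(0, 10, 6); m3[4, 5] <- 3.001 * pi / 180
  expect_false(motion_qc(motion_trace(m3))$pass)
})

test_that("the composed pipeline honors stage configuration and ordering", {
  ph <- small_phantom()
  design <- small_design()
  truth <- ground_truth(ph$masks)
  sim <- simulate_subject(truth, design, "HC", 21)

  # all stages disabled: identity after discard
  cfg0 <- preprocess_config(n_discard = 10, stages = character(0))
  out0 <- preprocess_run(sim$run, sim$motion, ph$masks, cfg0)
  expect_equal(out0$data, discard_initial(sim$run, 10)$data)

  # default pipeline demeans the GM signal (DC removal)
  cfg <- preprocess_config(n_discard = 10)
  out <- preprocess_run(sim$run, sim$motion, ph$masks, cfg)
  expect_lt(abs(mean(global_signal(out, ph$masks)$values)), 1e-6)
  expect_equal(attr(out, "log")$stages_applied,
               c("despike", "regress", "bandpass", "smooth"))

  # stage order changes the result on drift-heavy input
  heavy <- ground_truth(ph$masks, drift_amp = 5)
  simh <- simulate_subject(heavy, design, "HC", 22)
  a <- preprocess_run(simh$run, simh$motion, ph$masks,
                      preprocess_config(stages = c("regress", "bandpass")))
  b <- preprocess_run(simh$run, simh$motion, ph$masks,
                      preprocess_config(stages = c("bandpass", "regress")))
  expect_gt(max(abs(a$data - b$data)), 1e-4)

  # on noise-free, drift-free input the full pipeline preserves the rank
  # ordering of voxelwise correlation with the shared component
  clean <- ground_truth(ph$masks, noise_sd = 0, drift_amp = 0)
  simc <- simulate_subject(clean, design, "ARCI", 23)
  g <- simc$shared[-(1:10)]
  raw_r <- apply(gstopo:::voxel_matrix(discard_initial(simc$run, 10),
                                       ph$masks$gm), 1, stats::cor, y = g)
  # WM/CSF are exactly zero here, so their regressors are dropped loudly
  expect_warning(
    pre_c <- preprocess_run(simc$run, simc$motion, ph$masks,
                            preprocess_config(fwhm_mm = 0)),
    "all-zero")
  post_r <- apply(gstopo:::voxel_matrix(pre_c, ph$masks$gm), 1,
                  stats::cor, y = g)
  # near-perfect rank preservation; the residual slippage comes from the
  # band-pass clipping modulation sidebands at the band edges
  expect_gt(stats::cor(raw_r, post_r, method = "spearman"), 0.98)

  # QC failure aborts unless overridden
  badmot <- unclass(sim$motion); badmot[5, 1] <- 4
  expect_error(preprocess_run(sim$run, motion_trace(badmot), ph$masks, cfg0),
               "QC failed")
  ok <- preprocess_run(sim$run, motion_trace(badmot), ph$masks, cfg0,
                       override_qc = TRUE)
  expect_false(attr(ok, "log")$qc$pass)
})
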