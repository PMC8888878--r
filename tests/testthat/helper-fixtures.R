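# Shared fixtures: a small phantom and cohort design sized for unit tests.
# Everything is generated in code; no files ship with the package.

small_phantom <- function(dims = c(12, 12, 12)) make_phantom(dims)

small_design <- function(n = 2, n_volumes = 120, seed = 424241) {
  cohort_design(n_per_group = c("HC" = n, "AUD-NCI" = n, "ARCI" = n),
                dims = c(12, 12, 12), tr = 1, n_volumes = n_volumes,
                seed = seed)
}

# a bold_run filled with seeded white noise on a given grid
noise_run <- function(grid, n_volumes = 60, tr = 1, seed = 99) {
  set.seed(seed)
  bold_run(array(rnorm(prod(grid$dims) * n_volumes),
                 c(grid$dims, n_volumes)),
           tr = tr, grid = grid)
}

# brute-force windowed Pearson + Fisher z, the independent oracle for
# dynamic_gst: plain per-window two-pass stats::cor loop
brute_force_sliding_z <- function(Y, g, L, step) {
  nw <- (length(g) - L) %/% step + 1
  Z <- matrix(0, nrow(Y), nw)
  for (v in seq_len(nrow(Y))) {
    for (w in seq_len(nw)) {
      idx <- ((w - 1) * step + 1):((w - 1) * step + L)
      r <- suppressWarnings(stats::cor(Y[v, idx], g[idx]))
      if (is.na(r)) r <- 0
      r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
      Z[v, w] <- atanh(r)
    }
  }
  Z
}
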