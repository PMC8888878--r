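#' Validate and normalize a pipeline configuration
#'
#' Accepts a (possibly partial) configuration as a named list or a YAML
#' file path, fills in every documented default, and reports all
#' contradictions together. An empty configuration is valid and yields the
#' standard analysis: discard 10 volumes, 0.01-0.1 Hz band, 6 mm
#' smoothing, windows of 22 and 30 TRs at step 1, CV group inference at
#' p < 0.001 with 15-voxel minimum extent.
#'
#' @param config named list, YAML path, or NULL for all defaults.
#' @return normalized configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  dfl <- list(
    input = "simulate",
    output_dir = NULL,
    seed = 20230901,
    simulate = list(dims = c(16, 16, 16), voxel_mm = c(3, 3, 3),
                    n_per_group = c("HC" = 40, "AUD-NCI" = 54, "ARCI" = 26),
                    n_volumes = 400, tr = 1.0,
                    noise_sd = 1.0, drift_amp = 0.5, delta = 0.40,
                    modulation_period = 60),
    preprocess = list(n_discard = 10, despike_c1 = 2.5, despike_c2 = 4.0,
                      band = c(0.01, 0.1), fwhm_mm = 6,
                      max_trans_mm = 3, max_rot_deg = 3,
                      stages = c("despike", "regress", "bandpass", "smooth")),
    windows = c(22, 30), step = 1,
    cv = list(eps = 1e-3, mode = "abs"),
    group = list(measures = c("static_z", "sd", "cv"),
                 p_thresh = 0.001, min_extent = 15, connectivity = 26),
    scores = c("MMSE", "MoCA", "ADS", "OCDS", "VAS", "PHQ-9",
               "pure_alcohol_total"))
  cfg <- utils::modifyList(dfl, config)
  for (nm in c("simulate", "preprocess", "cv", "group"))
    if (!is.null(config[[nm]])) cfg[[nm]] <- utils::modifyList(dfl[[nm]], config[[nm]])

  errs <- character(0)
  band <- as.numeric(cfg$preprocess$band)
  if (length(band) != 2 || !(band[1] >= 0 && band[1] < band[2]))
    errs <- c(errs, sprintf("band must satisfy 0 <= low < high, got (%s)",
                            paste(band, collapse = ", ")))
  if (band[2] >= 1 / (2 * cfg$simulate$tr))
    errs <- c(errs, "band high edge at or above Nyquist")
  usable <- cfg$simulate$n_volumes - cfg$preprocess$n_discard
  if (any(cfg$windows > usable))
    errs <- c(errs, sprintf("window (%s) exceeds usable volumes (%d)",
                            paste(cfg$windows, collapse = ", "), usable))
  if (any(cfg$windows <= 2)) errs <- c(errs, "windows must exceed 2 TRs")
  if (cfg$step < 1) errs <- c(errs, "step must be >= 1")
  if (cfg$group$p_thresh <= 0 || cfg$group$p_thresh >= 1)
    errs <- c(errs, "p_thresh must be in (0, 1)")
  if (!cfg$group$connectivity %in% c(6, 26))
    errs <- c(errs, "connectivity must be 6 or 26")
  if (length(errs))
    stop(paste(c("invalid configuration:", errs), collapse = "\n  - "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full GST analysis pipeline
#'
#' Simulates (or ingests) a cohort, preprocesses every run, computes the
#' global signal, static GST z-map and dynamic GST SD/mean/CV maps for
#' each configured window length, runs three-group voxelwise ANOVA with
#' cluster extraction per measure, ROI-level ordering for every phantom
#' ROI, and behavior correlations over the patient groups. All outputs
#' (NIfTI maps, TSV tables, markdown report, JSON manifest) go to
#' `config$output_dir`; every file written is listed in the manifest with
#' its MD5 checksum. Deterministic given `config$seed`.
#'
#' @param config see [validate_config()]; `output_dir` must be set.
#' @param keep_subject_maps also write each subject's summary maps.
#' @return list with `cohort`, `samples` (per measure), `anova`,
#'   `clusters`, `orderings`, `correlations`, `manifest` (invisibly).
#' @export
run_pipeline <- function(config, keep_subject_maps = FALSE) {
  cfg <- validate_config(if (inherits(config, "pipeline_config")) unclass(config) else config)
  if (is.null(cfg$output_dir)) stop("config$output_dir must be set")
  out <- cfg$output_dir
  dir.create(file.path(out, "maps"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "tables"), recursive = TRUE, showWarnings = FALSE)
  if (keep_subject_maps)
    dir.create(file.path(out, "subjects"), showWarnings = FALSE)

  pp_cfg <- do.call(preprocess_config, cfg$preprocess)
  specs <- lapply(cfg$windows, window_spec, step_tr = cfg$step)
  names(specs) <- paste0("w", cfg$windows)

  # --- cohort: simulate on the phantom or ingest a directory -------------
  if (identical(cfg$input, "simulate")) {
    ph <- make_phantom(cfg$simulate$dims, cfg$simulate$voxel_mm)
    truth <- ground_truth(ph$masks,
                          modulation_period = cfg$simulate$modulation_period,
                          noise_sd = cfg$simulate$noise_sd,
                          drift_amp = cfg$simulate$drift_amp,
                          group_effects = default_group_effects(cfg$simulate$delta))
    design <- cohort_design(n_per_group = unlist(cfg$simulate$n_per_group),
                            dims = cfg$simulate$dims, tr = cfg$simulate$tr,
                            n_volumes = cfg$simulate$n_volumes,
                            seed = cfg$seed,
                            max_window = max(cfg$windows))
    masks <- ph$masks; grid <- ph$grid
    per_subject <- function(sim, id, group)
      subject_maps(sim$run, sim$motion, masks, pp_cfg, specs, cfg, id,
                   if (keep_subject_maps) file.path(out, "subjects") else NULL)
    sims <- simulate_cohort(truth, design, per_subject = per_subject)
    cohort <- sims$cohort
    subj <- sims$subjects
  } else {
    cohort <- read_cohort(file.path(cfg$input, "cohort.tsv"))
    first <- read_bold(file.path(cfg$input, paste0(cohort$id[1], "_bold.nii.gz")),
                       tr = cfg$simulate$tr)
    grid <- first$grid
    mask_paths <- c(gm = "gm.nii.gz", wm = "wm.nii.gz", csf = "csf.nii.gz")
    masks <- read_masks(as.list(file.path(cfg$input, mask_paths)), grid)
    subj <- lapply(seq_len(nrow(cohort)), function(i) {
      id <- cohort$id[i]
      run <- read_bold(file.path(cfg$input, paste0(id, "_bold.nii.gz")),
                       tr = cfg$simulate$tr)
      mot <- read_motion(file.path(cfg$input, paste0(id, "_motion.txt")),
                         n_volumes = run$n_volumes)
      subject_maps(run, mot, masks, pp_cfg, specs, cfg, id,
                   if (keep_subject_maps) file.path(out, "subjects") else NULL)
    })
    names(subj) <- cohort$id
  }

  # --- group inference ---------------------------------------------------
  measures <- character(0)
  for (m in cfg$group$measures)
    measures <- c(measures, if (m == "static_z") "static_z"
                  else paste0(m, "_", names(specs)))
  samples <- lapply(measures, function(m)
    group_sample(lapply(subj, `[[`, m), cohort$group, grid, masks$gm, m))
  names(samples) <- measures

  anova_res <- lapply(samples, voxelwise_anova)
  clusters <- list()
  files <- character(0)
  for (m in measures) {
    fz <- anova_res[[m]]
    p1 <- file.path(out, "maps", paste0("F_", m, ".nii.gz"))
    p2 <- file.path(out, "maps", paste0("p_", m, ".nii.gz"))
    write_map(fz$f_map, grid, p1); write_map(fz$p_map, grid, p2)
    ct <- extract_clusters(fz$f_map, fz$p_map, grid,
                           p_thresh = cfg$group$p_thresh,
                           min_extent = cfg$group$min_extent,
                           connectivity = cfg$group$connectivity,
                           roi_labels = masks$roi_labels)
    clusters[[m]] <- ct
    p3 <- file.path(out, "tables", paste0("clusters_", m, ".tsv"))
    write_cluster_table(ct, p3)
    files <- c(files, p1, p2, p3)
  }

  orderings <- list()
  cv_measures <- grep("^cv_", measures, value = TRUE)
  for (m in cv_measures)
    for (roi in names(masks$roi_labels))
      orderings[[paste(m, roi, sep = ".")]] <-
        roi_ordering(samples[[m]], masks$roi_labels[[roi]])
  ord_df <- data.frame(
    measure = sub("\\..*$", "", names(orderings)),
    roi = sub("^[^.]*\\.", "", names(orderings)),
    ordering = vapply(orderings, `[[`, character(1), "ordering"))
  p4 <- file.path(out, "tables", "roi_orderings.tsv")
  utils::write.table(ord_df, p4, sep = "\t", row.names = FALSE, quote = FALSE)

  corr <- NULL
  if (length(cv_measures)) {
    corr <- behavior_correlation(samples[[cv_measures[1]]], cohort,
                                 masks$roi_labels, cfg$scores)
    p5 <- file.path(out, "tables", "behavior_correlations.tsv")
    utils::write.table(corr, p5, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, p5)
  }
  files <- c(files, p4)

  report <- pipeline_report(cfg, cohort, clusters, ord_df, corr)
  p6 <- file.path(out, "report.md")
  writeLines(report, p6)
  files <- c(files, p6)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gstopo")),
    seed = cfg$seed, config = unclass(cfg),
    subjects = names(subj),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, samples = samples, anova = anova_res,
                 clusters = clusters, orderings = orderings,
                 correlations = corr, manifest = manifest,
                 masks = masks, grid = grid))
}

# preprocess one subject and compute its summary maps
subject_maps <- function(run, motion, masks, pp_cfg, specs, cfg, id,
                         subj_dir = NULL) {
  pre <- preprocess_run(run, motion, masks, pp_cfg)
  gs <- global_signal(pre, masks)
  st <- static_gst(pre, gs, masks)
  res <- list(static_z = st$z)
  for (wn in names(specs)) {
    dyn <- summarize_dynamic(dynamic_gst(pre, gs, specs[[wn]], masks),
                             eps = cfg$cv$eps, cv_mode = cfg$cv$mode)
    res[[paste0("sd_", wn)]] <- dyn$sd_map
    res[[paste0("mean_", wn)]] <- dyn$mean_map
    res[[paste0("cv_", wn)]] <- dyn$cv_map
  }
  if (!is.null(subj_dir))
    for (nm in names(res))
      write_map(res[[nm]], run$grid, file.path(subj_dir, paste0(id, "_", nm, ".nii.gz")))
  res
}

pipeline_report <- function(cfg, cohort, clusters, ord_df, corr) {
  lines <- c("# Global-signal topography pipeline report", "",
             sprintf("Seed: %d. Subjects: %d (%s).", cfg$seed, nrow(cohort),
                     paste(sprintf("%s n=%d", levels(cohort$group),
                                   as.integer(table(cohort$group))),
                           collapse = ", ")),
             sprintf("Windows: %s TRs, step %d. Band %g-%g Hz, smoothing %g mm.",
                     paste(cfg$windows, collapse = " and "), cfg$step,
                     cfg$preprocess$band[1], cfg$preprocess$band[2],
                     cfg$preprocess$fwhm_mm),
             "", "## Clusters per measure", "")
  for (m in names(clusters)) {
    ct <- clusters[[m]]
    lines <- c(lines, sprintf("- %s: %d cluster(s)%s", m, nrow(ct),
                              if (nrow(ct)) sprintf(" (largest %d voxels, peak F %.2f)",
                                                    max(ct$n_voxels), max(ct$peak_f))
                              else ""))
  }
  lines <- c(lines, "", "## ROI orderings (CV)", "",
             sprintf("- %s @ %s: %s", ord_df$measure, ord_df$roi, ord_df$ordering))
  if (!is.null(corr)) {
    nsig <- sum(corr$p < 0.05, na.rm = TRUE)
    lines <- c(lines, "", "## Behavior correlations", "",
               sprintf("%d of %d score-ROI pairs significant at p < 0.05 (uncorrected).",
                       nsig, nrow(corr)))
  }
  lines
}
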