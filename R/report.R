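#' Run configuration for the end-to-end comparisons
#'
#' Fully serializable description of a protocol-comparison or
#' similarity-comparison run: acquisition regimes (voxel sizes and noise
#' levels), phantom geometry, metric and similarity options, and a single
#' global seed from which every per-stage seed is derived by a fixed rule
#' (`stage_seed`), so a run is reproducible bit-for-bit from its
#' configuration.
#'
#' The default regimes mirror a 7-T resolution ladder plus a clinical 3-T
#' reference: voxel sizes 0.2x0.2x0.5, 0.2x0.2x0.4, 0.2x0.2x0.3 and
#' 0.4x0.4x0.5 mm^3, with noise scaled inversely to voxel volume so that
#' finer sampling costs SNR, as it does physically.
#'
#' @param regimes named list of regimes, each `list(voxel_size=, noise_sigma=)`.
#' @param grid_mm physical field of view (mm) of the phantom, cube edge.
#' @param n_branch_levels,vessel_intensity,background_intensity phantom
#'   parameters (see [build_vessel_tree()], [phantom_spec()]).
#' @param n_vessel_rois vessel ROI count (default 17).
#' @param snr_convention `"paper"` or `"nema"` (see [snr_difference()]).
#' @param edge_params list of [canny()] parameters.
#' @param similarity a [similarity_config()].
#' @param seed global integer seed.
#' @param out_dir output directory for report files.
#' @return object of class `run_config`.
#' @export
run_config <- function(regimes = default_regimes(),
                       grid_mm = 19.2,
                       n_branch_levels = 5L,
                       vessel_intensity = 300,
                       background_intensity = 60,
                       n_vessel_rois = 17L,
                       snr_convention = "paper",
                       edge_params = list(gaussian_sigma = 1.4, low = 0.1,
                                          high = 0.2),
                       similarity = similarity_config(),
                       seed = 1L,
                       out_dir = tempfile("angioqa_run_")) {
  abort_if(length(regimes) < 1L, "need at least one regime")
  for (r in regimes) {
    abort_if(is.null(r$voxel_size) || is.null(r$noise_sigma),
             "each regime needs voxel_size and noise_sigma")
  }
  structure(list(regimes = regimes, grid_mm = grid_mm,
                 n_branch_levels = as.integer(n_branch_levels),
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 n_vessel_rois = as.integer(n_vessel_rois),
                 snr_convention = snr_convention,
                 edge_params = edge_params, similarity = similarity,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_regimes <- function() {
  v7 <- list(acq1 = c(0.2, 0.2, 0.5), acq2 = c(0.2, 0.2, 0.4),
             acq3 = c(0.2, 0.2, 0.3))
  ref_vol <- prod(v7$acq1)
  regimes <- lapply(v7, function(vs) {
    # noise grows as voxels shrink: finer sampling costs SNR
    list(voxel_size = vs, noise_sigma = 10 * ref_vol / prod(vs))
  })
  # clinical 3-T reference: noise matched to the finest 7-T regime (the
  # study design pushes 7-T resolution until SNR parity with 3 T), but a
  # brighter background emulating the weaker background suppression at
  # lower field, which costs vessel-parenchyma contrast
  regimes$clinical3T <- list(voxel_size = c(0.4, 0.4, 0.5),
                             noise_sigma = regimes$acq3$noise_sigma,
                             background_intensity = 120)
  regimes
}

#' Per-stage seed derivation
#'
#' `stage_seed(global, stage, item)` = `global * 10000 + stage * 100 + item`,
#' kept below 2^31. Stable and documented so every stochastic stage of a
#' report is independently reproducible.
#' @param global global seed (integer).
#' @param stage stage index (0-99).
#' @param item item index within the stage (0-99).
#' @export
stage_seed <- function(global, stage, item = 0L) {
  as.integer((as.numeric(global) * 10000 + stage * 100 + item) %% 2147483647)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d regimes (%s), seed %d, out_dir %s\n",
              length(x$regimes), paste(names(x$regimes), collapse = ", "),
              x$seed, x$out_dir))
  invisible(x)
}

#' Read / write a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
config_to_yaml <- function(config, path) {
  x <- unclass(config)
  x$similarity <- unclass(x$similarity)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(similarity_config, x$similarity)
  x$similarity <- sim
  do.call(run_config, x)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  x <- unclass(config)
  x$out_dir <- NULL # location must not change the identity of a run
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

provenance <- function(config) {
  list(package = "angioqa",
       version = as.character(utils::packageVersion("angioqa")),
       config_hash = config_hash(config),
       global_seed = config$seed,
       seed_derivation = "stage_seed(global, stage, item) = global*10000 + stage*100 + item")
}

# p-value annotation convention used in the report tables
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

run_stage <- function(stage_name, config, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed (config %s): %s", stage_name,
                 config_hash(config), conditionMessage(e)), call. = FALSE)
  })
}

#' End-to-end acquisition-protocol comparison
#'
#' For each acquisition regime: simulate a repeat-acquisition pair of the
#' same vessel tree at the regime's voxel size and noise, register B onto A
#' (when misaligned), propagate the ROI set, compute per-ROI SNR and CNR,
#' then aggregate across ROIs, run the paired Wilcoxon test between all
#' regime pairs on the per-ROI CNR and SNR, and count Canny edge pixels on
#' the axial MIPs. Writes a metrics CSV, summary/test tables, an edge-count
#' table and a provenance log into `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param misalign optional [rigid_transform()] applied between A and B in
#'   every regime (identity default); when present, B is registered back
#'   onto A before the metrics.
#' @return object of class `report_bundle`: list of file paths plus the
#'   in-memory tables.
#' @export
run_protocol_comparison <- function(config = run_config(), misalign = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # tree kept at 75% of the field of view: vessels stay clear of the FOV
  # boundary, leaving parenchymal room around every ROI
  tree <- run_stage("phantom_tree", config,
                    build_vessel_tree(seed = stage_seed(config$seed, 1),
                                      n_branch_levels = config$n_branch_levels,
                                      extent = rep(config$grid_mm * 0.75, 3)))
  metrics <- list()
  edge_rows <- list()
  per_roi <- list()
  for (ri in seq_along(config$regimes)) {
    rg <- config$regimes[[ri]]
    rg_name <- names(config$regimes)[ri]
    res <- run_stage(paste0("regime_", rg_name), config, {
      gs <- round(config$grid_mm / rg$voxel_size)
      bg <- if (is.null(rg$background_intensity))
        config$background_intensity else rg$background_intensity
      spec <- phantom_spec(grid_shape = gs, voxel_size = rg$voxel_size,
                           vessel_intensity = config$vessel_intensity,
                           background_intensity = bg,
                           noise_sigma = rg$noise_sigma,
                           seed = stage_seed(config$seed, 2, ri))
      clean <- suppressWarnings(rasterize(tree, spec))
      mis <- if (is.null(misalign)) identity_transform() else misalign
      pair <- make_pair(clean, rg$noise_sigma,
                        seed_a = stage_seed(config$seed, 3, ri * 2),
                        seed_b = stage_seed(config$seed, 3, ri * 2 + 1),
                        misalignment = mis)
      if (!is.null(misalign)) {
        reg <- estimate_rigid(pair$volume_b, pair$volume_a)
        pair$volume_b <- resample_volume(pair$volume_b, reg, pair$volume_a,
                                         "linear")
      }
      rois <- default_roi_set(tree, clean, n_vessel = config$n_vessel_rois)
      rows <- list()
      for (j in seq_len(config$n_vessel_rois)) {
        vvox <- roi_voxels(rois, j)
        pvox <- roi_voxels(rois, rois$pairing[[as.character(j)]])
        s <- snr_difference(pair, vvox, convention = config$snr_convention,
                            acquisition_id = rg_name,
                            roi_label = sprintf("roi_%02d", j))
        cc <- cnr(pair$volume_a, vvox, pvox, acquisition_id = rg_name,
                  roi_label = sprintf("roi_%02d", j))
        cl <- rois$labels$caliber_class[rois$labels$label == j]
        rows[[j]] <- rbind(cbind(as.data.frame(s), caliber_class = cl),
                           cbind(as.data.frame(cc), caliber_class = cl))
      }
      em <- canny(mip(pair$volume_a, "axial"),
                  gaussian_sigma = config$edge_params$gaussian_sigma,
                  low = config$edge_params$low,
                  high = config$edge_params$high)
      list(metrics = do.call(rbind, rows),
           edges = data.frame(acquisition_id = rg_name,
                              edge_pixels = count_edges(em)))
    })
    per_roi[[rg_name]] <- res$metrics
    edge_rows[[rg_name]] <- res$edges
  }
  metrics_df <- do.call(rbind, per_roi)
  rownames(metrics_df) <- NULL
  edge_df <- do.call(rbind, edge_rows)
  rownames(edge_df) <- NULL

  summaries <- do.call(rbind, lapply(c("snr", "cnr"), function(mm) {
    s <- aggregate_metric(metrics_df[metrics_df$metric == mm, ],
                          group_by = "acquisition")
    cbind(metric = mm, s)
  }))

  # paired Wilcoxon between every couple of regimes, per metric, on the
  # per-ROI values; unadjusted p-values plus a Holm column side by side
  rg_names <- names(config$regimes)
  tests <- list()
  for (mm in c("snr", "cnr")) {
    for (i in seq_along(rg_names)) for (j in seq_along(rg_names)) {
      if (i >= j) next
      a <- metrics_df$value[metrics_df$metric == mm &
                              metrics_df$acquisition_id == rg_names[i]]
      b <- metrics_df$value[metrics_df$metric == mm &
                              metrics_df$acquisition_id == rg_names[j]]
      wt <- tryCatch(paired_wilcoxon(a, b), error = function(e) NULL)
      tests[[length(tests) + 1L]] <- data.frame(
        metric = mm, regime_a = rg_names[i], regime_b = rg_names[j],
        statistic = if (is.null(wt)) NA_real_ else wt$statistic,
        p_value = if (is.null(wt)) NA_real_ else wt$p_value,
        note = if (is.null(wt)) "degenerate: no variability" else "")
    }
  }
  tests_df <- do.call(rbind, tests)
  tests_df$signif <- ifelse(is.na(tests_df$p_value), "",
                            p_stars(tests_df$p_value))
  tests_df$p_holm <- stats::p.adjust(tests_df$p_value, method = "holm")

  paths <- list(
    metrics_csv = file.path(config$out_dir, "roi_metrics.csv"),
    summary_csv = file.path(config$out_dir, "metric_summaries.csv"),
    tests_csv = file.path(config$out_dir, "paired_tests.csv"),
    edges_csv = file.path(config$out_dir, "edge_counts.csv"),
    provenance_json = file.path(config$out_dir, "provenance.json"))
  utils::write.csv(metrics_df, paths$metrics_csv, row.names = FALSE)
  utils::write.csv(summaries, paths$summary_csv, row.names = FALSE)
  utils::write.csv(tests_df, paths$tests_csv, row.names = FALSE)
  utils::write.csv(edge_df, paths$edges_csv, row.names = FALSE)
  jsonlite::write_json(provenance(config), paths$provenance_json,
                       auto_unbox = TRUE, digits = NA)
  structure(list(paths = paths, metrics = metrics_df, summaries = summaries,
                 tests = tests_df, edges = edge_df,
                 provenance = provenance(config)),
            class = "report_bundle")
}

#' End-to-end cross-modality similarity comparison
#'
#' Simulates the phantom at the finest regime, renders the MRA-side axial
#' MIP and a sweep of DSA-like projections at increasing geometric
#' perturbation (rotation), and computes the cross-modality similarity
#' index for each, writing a JSON report row per perturbation.
#'
#' @param config a [run_config()].
#' @param rotations_deg numeric vector of projection rotations to sweep.
#' @return a `report_bundle` with the similarity table.
#' @export
run_similarity_comparison <- function(config = run_config(),
                                      rotations_deg = c(0, 2, 5, 10)) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rg <- config$regimes[[length(config$regimes) - 1L]] # finest 7-T regime
  if (is.null(rg)) rg <- config$regimes[[1L]]
  bundle <- run_stage("similarity", config, {
    tree <- build_vessel_tree(seed = stage_seed(config$seed, 1),
                              n_branch_levels = config$n_branch_levels,
                              extent = rep(config$grid_mm * 0.75, 3))
    gs <- round(config$grid_mm / rg$voxel_size)
    spec <- phantom_spec(grid_shape = gs, voxel_size = rg$voxel_size,
                         vessel_intensity = config$vessel_intensity,
                         background_intensity = config$background_intensity,
                         noise_sigma = rg$noise_sigma,
                         seed = stage_seed(config$seed, 2))
    clean <- suppressWarnings(rasterize(tree, spec))
    noisy <- add_noise(clean, rg$noise_sigma, stage_seed(config$seed, 3))
    mra <- mip(noisy, "axial")
    rows <- lapply(seq_along(rotations_deg), function(i) {
      dsa <- project_dsa_like(noisy, "axial",
                              rotation_deg = rotations_deg[i],
                              blur_sigma_px = 1, intensity_gamma = 1.5,
                              noise_sigma = 0.01,
                              seed = stage_seed(config$seed, 4, i))
      res <- compare_modality(mra, dsa, config$similarity)
      list(rotation_deg = rotations_deg[i], cwssi = res$cwssi,
           preprocessing_log = res$preprocessing_log)
    })
    rows
  })
  tab <- data.frame(rotation_deg = vapply(bundle, `[[`, numeric(1),
                                          "rotation_deg"),
                    cwssi = vapply(bundle, `[[`, numeric(1), "cwssi"))
  paths <- list(similarity_json = file.path(config$out_dir, "similarity.json"),
                provenance_json = file.path(config$out_dir, "provenance.json"))
  jsonlite::write_json(
    list(provenance = provenance(config), comparisons = bundle),
    paths$similarity_json, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(provenance(config), paths$provenance_json,
                       auto_unbox = TRUE, digits = NA)
  structure(list(paths = paths, similarity = tab,
                 provenance = provenance(config)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n  files:\n")
  for (p in x$paths) cat("   ", p, "\n")
  invisible(x)
}

#' Validate a similarity report JSON against the bundled schema
#'
#' Light structural validation: required fields and their types, as
#' declared in `inst/extdata/report_schema.json`.
#' @param path path to a `similarity.json` written by
#'   [run_similarity_comparison()].
#' @return `TRUE` (invisibly) or an error describing the first violation.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::read_json(system.file("extdata", "report_schema.json",
                                            package = "angioqa",
                                            mustWork = TRUE))
  j <- jsonlite::read_json(path)
  for (f in names(schema$required)) {
    abort_if(is.null(j[[f]]), sprintf("report misses required field '%s'", f))
  }
  for (f in names(schema$provenance_fields)) {
    abort_if(is.null(j$provenance[[f]]),
             sprintf("report provenance misses field '%s'", f))
  }
  for (cmp in j$comparisons) {
    abort_if(!is.numeric(cmp$rotation_deg) || !is.numeric(cmp$cwssi),
             "each comparison needs numeric rotation_deg and cwssi")
    abort_if(cmp$cwssi < 0 || cmp$cwssi > 1, "cwssi out of [0,1]")
  }
  invisible(TRUE)
}
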