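# End-to-end driver: simulate -> extract -> reproducibility -> survival ->
# report, with a run manifest for reproducibility.

#' Pipeline configuration
#'
#' A plain-list configuration for [run_pipeline()]. The single `seed` fans
#' out deterministically to per-stage seeds (stage index offsets of 1000),
#' so a config fully determines every artifact.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Global seed.
#' @param n_subjects Reproducibility-arm subject count.
#' @param n_cohort Survival-cohort size.
#' @param extractors Extractor setting names to run.
#' @param stages Character subset of
#'   `c("extract", "repro", "survival", "report")`.
#' @param grid_mode `"smoke"` (2 thresholds x 2 counts, few repeats) or
#'   `"full"` (the complete 315-cell grid).
#' @param repeats,folds Cross-validation shape.
#' @param phantom Base [phantom_spec()] (per-subject seeds derived from it).
#' @param noise_sd_hu Reconstruction noise scale.
#' @param n_signal Number of planted prognostic features in the synthetic
#'   cohort.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1, n_subjects = 3, n_cohort = 80,
                            extractors = c("L2i", "A3"),
                            stages = c("extract", "repro", "survival", "report"),
                            grid_mode = c("smoke", "full"),
                            repeats = 2, folds = 3,
                            phantom = phantom_spec(grid_shape = c(24, 24, 12),
                                                   tumor_radii_mm = c(7, 7, 5.5),
                                                   shell_radii_mm = c(13, 13, 7),
                                                   gap_mm = 1.5),
                            noise_sd_hu = 10, n_signal = 3) {
  grid_mode <- match.arg(grid_mode)
  bad <- setdiff(stages, c("extract", "repro", "survival", "report"))
  if (length(bad)) abort("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_subjects = n_subjects, n_cohort = n_cohort,
                 extractors = extractors, stages = stages,
                 grid_mode = grid_mode, repeats = repeats, folds = folds,
                 phantom = phantom, noise_sd_hu = noise_sd_hu,
                 n_signal = n_signal),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order. `extract` simulates one phantom
#' per subject, emulates every cell of the 3 x 7 reconstruction grid and
#' extracts all features for both ROIs under the configured extractor
#' settings, writing the long feature table. `repro` computes the pairwise
#' and generalized CCC tables. `survival` generates a synthetic cohort
#' keyed to the extracted feature ids (with a few planted prognostic
#' features) and runs the cross-validation grid. `report` produces the
#' Pareto/tally tables and clustering data. Each stage depends on its
#' predecessor's CSV, so stages can be re-run individually against an
#' existing output directory. A failing stage is recorded in the manifest
#' and downstream stages are skipped.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(unclass(config)),
                   seed = config$seed, stages = list(), outputs = list())
  paths <- list(features = file.path(config$outdir, "features.csv"),
                ccc_pairwise = file.path(config$outdir, "ccc_pairwise.csv"),
                ccc = file.path(config$outdir, "ccc_generalized.csv"),
                survival = file.path(config$outdir, "survival.csv"),
                cv = file.path(config$outdir, "cv_results.csv"),
                selection = file.path(config$outdir, "cv_selection.csv"),
                cindex = file.path(config$outdir, "univariate_cindex.csv"),
                front = file.path(config$outdir, "pareto_front.csv"),
                tallies = file.path(config$outdir, "extractor_tallies.csv"),
                clustering = file.path(config$outdir, "clustering.json"))
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) {
      manifest$stages[[name]] <<- "disabled"
      return(invisible(NULL))
    }
    if (failed) {
      manifest$stages[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch({ fun(); "ok" },
                    error = function(e) paste("failed:", conditionMessage(e)))
    manifest$stages[[name]] <<- res
    if (!identical(res, "ok")) failed <<- TRUE
  }

  run_stage("extract", function() {
    grid <- reconstruction_grid()
    rows <- list()
    for (i in seq_len(config$n_subjects)) {
      sid <- sprintf("S%03d", i)
      spec <- config$phantom
      spec$seed <- config$seed + 1000L + i
      ph <- generate_phantom(spec)
      for (g in seq_len(nrow(grid))) {
        key <- reconstruction_key(sid, grid$slice_thickness_mm[g], grid$asir_percent[g])
        vol <- reconstruct(ph$image, key, noise_sd_hu = config$noise_sd_hu,
                           seed = config$seed + 2000L + i * 101L + g)
        masks <- lapply(list(tumor = ph$tumor, parenchyma = ph$parenchyma),
                        resample_reference_mask,
                        target_zspacing_mm = key$slice_thickness_mm)
        ft <- extract_all(vol, masks, config$extractors, subject_id = sid)
        ft$subject_id <- sid
        ft$slice_thickness_mm <- key$slice_thickness_mm
        ft$asir_percent <- key$asir_percent
        rows[[length(rows) + 1L]] <- ft
      }
    }
    out <- do.call(rbind, rows)
    write_feature_table(out[, c("subject_id", "slice_thickness_mm", "asir_percent",
                                "roi", "extractor", "feature", "value")],
                        paths$features)
  })

  run_stage("repro", function() {
    if (!file.exists(paths$features)) abort("features.csv missing; run the extract stage first")
    ft <- read_feature_table(paths$features)
    # drop feature streams with undefined values before model fitting
    bad <- unique(ft$feature[!is.finite(ft$value)])
    if (length(bad)) ft <- ft[!(ft$feature %in% bad), , drop = FALSE]
    utils::write.csv(suppressMessages(pairwise_ccc_table(ft)), paths$ccc_pairwise,
                     row.names = FALSE)
    utils::write.csv(generalized_ccc_table(ft), paths$ccc, row.names = FALSE)
  })

  run_stage("survival", function() {
    if (!file.exists(paths$ccc)) abort("ccc_generalized.csv missing; run the repro stage first")
    ccc <- utils::read.csv(paths$ccc, stringsAsFactors = FALSE)
    ids <- make_feature_id(ccc$roi, ccc$extractor, ccc$feature)
    feats <- generate_cohort_features(config$n_cohort, ids, seed = config$seed + 3000L)
    sig <- with_seed(config$seed + 3500L,
                     sample(ids, min(config$n_signal, length(ids))))
    betas <- stats::setNames(rep(0.5, length(sig)), sig)
    spec <- survival_gen_spec(config$n_cohort, betas, seed = config$seed + 4000L)
    cohort <- generate_survival_cohort(spec, feats)
    utils::write.csv(cohort$subjects, paths$survival, row.names = FALSE)
    uc <- cindex_batch(cohort$features, cohort$subjects$time_months, cohort$subjects$event)
    uc <- ifelse(uc < 0.5, 1 - uc, uc)
    info <- cohort$feature_info
    utils::write.csv(data.frame(feature = info$feature, roi = info$roi,
                                extractor = info$extractor, cindex = uc),
                     paths$cindex, row.names = FALSE)
    grid <- if (config$grid_mode == "full") cv_grid_configs() else
      cv_grid_configs(feature_sets = c(config$extractors, "all"),
                      thresholds = c(0, 0.85), counts = c(2, 4))
    gr <- experiment_grid(cohort, ccc, grid = grid, folds = config$folds,
                          repeats = config$repeats, seed = config$seed + 5000L)
    utils::write.csv(gr$results, paths$cv, row.names = FALSE)
    utils::write.csv(gr$selection, paths$selection, row.names = FALSE)
  })

  run_stage("report", function() {
    if (!file.exists(paths$cindex)) abort("univariate_cindex.csv missing; run the survival stage first")
    ccc <- utils::read.csv(paths$ccc, stringsAsFactors = FALSE)
    cidx <- utils::read.csv(paths$cindex, stringsAsFactors = FALSE)
    rep_ <- suppressMessages(per_feature_extractor_analysis(ccc, cidx))
    utils::write.csv(rep_$global_front, paths$front, row.names = FALSE)
    utils::write.csv(rep_$tallies, paths$tallies, row.names = FALSE)
    # feature x (roi, extractor) matrix, ROIs joined as columns
    key <- paste(ccc$roi, ccc$extractor, sep = ".")
    mat <- tapply(ccc$ccc, list(ccc$feature, key), mean)
    cl <- suppressMessages(cluster_heatmap_data(mat))
    jsonlite::write_json(list(row_order = cl$row_order, col_order = cl$col_order,
                              row_tree = cl$row_tree, col_tree = cl$col_tree),
                         paths$clustering, auto_unbox = TRUE, digits = NA)
  })

  for (p in paths) {
    if (file.exists(p)) manifest$outputs[[basename(p)]] <- unname(tools::md5sum(p))
  }
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
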