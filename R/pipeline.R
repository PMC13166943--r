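## Pipeline orchestration: a single JSON config drives
## images -> masks -> thresholds -> endpoint table -> group statistics.
## Pure orchestration -- nothing here computes anything the library
## functions do not expose.

#' Read and validate a pipeline configuration
#'
#' The config is a single human-readable JSON document (schema_version 1)
#' listing the input manifest (field id, file path, channel map, group,
#' specimen id, optional ROIs), segmentation parameters, per-marker
#' threshold specifications (fixed cutoffs or control-derived), the
#' evaluability floor, and the statistics block (reference group,
#' metrics). Relative paths are resolved against the config file's
#' directory.
#'
#' @param path path to the config JSON.
#' @return validated config list (with \code{base_dir} attribute).
#' @seealso [runQuantification()], [makeFixtures()]
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  attr(cfg, "base_dir") <- dirname(normalizePath(path))
  attr(cfg, "config_path") <- normalizePath(path)
  validatePipelineConfig(cfg)
  cfg
}

resolvePath <- function(p, cfg) {
  base <- attr(cfg, "base_dir")
  if (is.null(base) || grepl("^(/|[A-Za-z]:)", p)) p
  else file.path(base, p)
}

#' @rdname readPipelineConfig
#' @param cfg a config list (as parsed from JSON).
#' @export
validatePipelineConfig <- function(cfg) {
  fail <- function(where, msg) stopf("config %s: %s", where, msg)
  if (is.null(cfg$schema_version) || cfg$schema_version != 1)
    fail("$schema_version", "must be 1")
  if (is.null(cfg$pixel_size_um) || cfg$pixel_size_um <= 0)
    fail("$pixel_size_um", "required and must be > 0")
  if (is.null(cfg$fields) || length(cfg$fields) == 0)
    fail("$fields", "at least one field is required")
  for (i in seq_along(cfg$fields)) {
    f <- cfg$fields[[i]]
    w <- sprintf("$fields[[%d]]", i)
    for (key in c("field_id", "specimen_id", "group", "path",
                  "channel_map"))
      if (is.null(f[[key]])) fail(paste0(w, "$", key), "required")
    if (!nzchar(f$group)) fail(paste0(w, "$group"), "must be non-empty")
    p <- resolvePath(f$path, cfg)
    if (!file.exists(p)) fail(paste0(w, "$path"),
                              sprintf("file not found: %s", p))
  }
  if (!is.null(cfg$thresholds)) {
    for (m in names(cfg$thresholds)) {
      t <- cfg$thresholds[[m]]
      w <- sprintf("$thresholds$%s", m)
      if (is.null(t$method)) fail(paste0(w, "$method"), "required")
      if (t$method == "fixed" && is.null(t$cutoff))
        fail(paste0(w, "$cutoff"), "required for fixed method")
      if (t$method != "fixed") {
        if (is.null(t$control_image)) fail(paste0(w, "$control_image"),
                                           "required for derived method")
        p <- resolvePath(t$control_image, cfg)
        if (!file.exists(p)) fail(paste0(w, "$control_image"),
                                  sprintf("file not found: %s", p))
        if (is.null(t$control_channel)) fail(paste0(w, "$control_channel"),
                                             "required for derived method")
      }
    }
  }
  if (!is.null(cfg$stats$reference_group)) {
    groups <- vapply(cfg$fields, function(f) f$group, character(1))
    if (!cfg$stats$reference_group %in% groups)
      fail("$stats$reference_group", "no field carries the reference group")
  }
  invisible(TRUE)
}

configSegParams <- function(cfg) {
  s <- cfg$segmentation
  if (is.null(s)) return(segmentationParams())
  get <- function(key, default) if (is.null(s[[key]])) default else s[[key]]
  segmentationParams(
    nuclearThresholdMethod = get("nuclear_threshold_method", "otsu"),
    nuclearFixedThreshold = get("nuclear_fixed_threshold", NA_real_),
    minNucleusAreaUm2 = get("min_nucleus_area_um2", 10),
    splitTouchingNuclei = get("split_touching_nuclei", FALSE),
    membraneThresholdMethod = get("membrane_threshold_method", "otsu"),
    membraneFixedThreshold = get("membrane_fixed_threshold", NA_real_),
    connectivity = get("connectivity", 8L),
    tissueDilationUm = get("tissue_dilation_um", 5))
}

configThresholds <- function(cfg, log) {
  out <- list()
  for (m in names(cfg$thresholds)) {
    t <- cfg$thresholds[[m]]
    if (t$method == "fixed") {
      out[[m]] <- deriveThreshold(NULL, m, "fixed", t$cutoff,
                                  controlId = "fixed")
      log(sprintf("threshold %s: fixed cutoff %g", m, t$cutoff))
    } else {
      p <- resolvePath(t$control_image, cfg)
      pages <- readTIFFGray(p)$pages
      if (t$control_channel > length(pages))
        stopf("config $thresholds$%s$control_channel: page %d out of range",
              m, t$control_channel)
      px <- pages[[t$control_channel]]
      out[[m]] <- deriveThreshold(px, m, t$method, t$parameter,
                                  controlId = basename(p))
      log(sprintf("threshold %s: %s(%g) on %s ch%d -> cutoff %.6g", m,
                  t$method, t$parameter, basename(p), t$control_channel,
                  cutoff(out[[m]])))
    }
  }
  out
}

fieldChannelMap <- function(f) {
  do.call(channelMap, lapply(f$channel_map, as.integer))
}

fieldROIs <- function(f) {
  if (is.null(f$rois)) return(NULL)
  lapply(f$rois, function(r)
    list(roi_id = r$roi_id, rows = as.integer(unlist(r$rows)),
         cols = as.integer(unlist(r$cols))))
}

#' Run the full quantification pipeline from a config
#'
#' For every field in the manifest: read the multichannel image, segment
#' the nuclear/membrane/tissue compartments, apply the positivity
#' thresholds, and emit one endpoint record per ROI; then flag
#' evaluability, summarize each metric by group, and run the configured
#' Mann-Whitney contrasts. A per-field failure is logged and skipped
#' without aborting the batch. Identical config + inputs produce
#' byte-identical output tables.
#'
#' @param config a config list from [readPipelineConfig()], or a path to
#'   the config JSON.
#' @param outputDir output directory (default
#'   \code{config$output_dir}, resolved against the config location);
#'   created if needed. \code{NA} suppresses file output.
#' @return (invisibly) list with \code{records}, \code{summaries},
#'   \code{comparisons}, \code{thresholds}, \code{log} (character
#'   vector), \code{status} (0 clean, 2 partial -- some fields failed)
#'   and \code{outputDir}.
#' @export
runQuantification <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  else validatePipelineConfig(config)
  logLines <- character(0)
  log <- function(msg) logLines <<- c(logLines, msg)
  cfgPath <- attr(config, "config_path")
  log(sprintf("metquant %s", as.character(utils::packageVersion("metquant"))))
  if (!is.null(cfgPath))
    log(sprintf("config %s md5 %s", basename(cfgPath),
                unname(tools::md5sum(cfgPath))))
  params <- configSegParams(config)
  thresholds <- configThresholds(config, log)
  for (m in c("total_met", "phospho_met"))
    if (is.null(thresholds[[m]]))
      stopf("config $thresholds: an entry for %s is required", m)
  membraneThr <- thresholds[["membrane_marker"]]
  nFailed <- 0L
  recs <- list()
  for (f in config$fields) {
    rec <- tryCatch({
      stack <- readMultichannelImage(resolvePath(f$path, config),
                                     fieldChannelMap(f),
                                     pixelSizeUm = config$pixel_size_um,
                                     fieldId = f$field_id)
      masks <- segmentCompartments(stack, params, membraneThr)
      quantifyField(stack, masks, thresholds, rois = fieldROIs(f),
                    specimenId = f$specimen_id, group = f$group,
                    connectivity = params@connectivity)
    }, error = function(e) {
      log(sprintf("FIELD FAILED %s: %s", f$field_id, conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) nFailed <- nFailed + 1L else {
      recs[[length(recs) + 1L]] <- rec
      log(sprintf("field %s: %d ROI(s), %d nuclei", f$field_id, nrow(rec),
                  sum(rec$nucleus_count)))
    }
  }
  if (length(recs) == 0) stopf("all fields failed; see log")
  records <- do.call(rbind, recs)
  minCells <- if (is.null(config$min_cells)) 3000 else config$min_cells
  records <- assessEvaluability(records, minCells)
  for (sid in unique(records$specimen_id[!records$evaluable]))
    log(sprintf("QC exclusion: specimen %s non-evaluable (< %d cells)",
                sid, minCells))
  metrics <- if (!is.null(config$stats$metrics))
    unlist(config$stats$metrics) else
    c("area_per_cell_um2_total_met", "area_per_cell_um2_phospho_met",
      "pct_map_total_met", "pct_map_phospho_met", "pct_map_dual",
      "pct_nap_total_met", "pct_nap_phospho_met", "phospho_total_ratio")
  reference <- config$stats$reference_group
  summaries <- list(); compRows <- list()
  for (m in metrics) {
    res <- tryCatch(
      summarizeGroups(records, m, reference = reference),
      error = function(e) {
        log(sprintf("stats skipped for %s: %s", m, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    res$summary <- cbind(metric = m, res$summary)
    res$comparisons <- cbind(metric = m, res$comparisons)
    summaries[[m]] <- res$summary
    compRows[[m]] <- res$comparisons
  }
  summaryTab <- if (length(summaries)) do.call(rbind, c(summaries,
                                                        make.row.names = FALSE))
                else NULL
  compTab <- if (length(compRows)) do.call(rbind, c(compRows,
                                                    make.row.names = FALSE))
             else NULL
  if (is.null(outputDir))
    outputDir <- if (!is.null(config$output_dir))
      resolvePath(config$output_dir, config) else NA
  if (!is.na(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeQuantTable(records, file.path(outputDir, "quant_records.csv"))
    if (!is.null(summaryTab))
      utils::write.csv(summaryTab, file.path(outputDir, "group_summary.csv"),
                       row.names = FALSE, na = "NA", eol = "\n")
    if (!is.null(compTab))
      utils::write.csv(compTab, file.path(outputDir,
                                          "group_comparisons.csv"),
                       row.names = FALSE, na = "NA", eol = "\n")
    jsonlite::write_json(thresholdsToList(thresholds),
                         file.path(outputDir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(logLines, file.path(outputDir, "run_log.txt"))
  }
  status <- if (nFailed > 0) 2L else 0L
  log(sprintf("done: %d field(s) quantified, %d failed", length(recs),
              nFailed))
  invisible(list(records = records, summaries = summaryTab,
                 comparisons = compTab, thresholds = thresholds,
                 log = logLines, status = status, outputDir = outputDir))
}

writeTruthSidecar <- function(truth, stem) {
  maskPages <- c(list(cell = truth@cellMask, nuclear = truth@nuclearMask,
                      membrane = truth@membraneMask), truth@positiveMasks)
  writeTIFFGray(lapply(maskPages,
                       function(m) matrix(ifelse(m, 255L, 0L), nrow(m))),
                paste0(stem, "_truth.tif"), bitDepth = 8L)
  jsonlite::write_json(list(
    nucleus_count = truth@nucleusCount,
    true_fraction = as.list(truth@trueFraction),
    true_area_per_cell_um2 = as.list(truth@trueAreaPerCellUm2),
    mask_tiff = basename(paste0(stem, "_truth.tif")),
    mask_pages = names(maskPages)),
    paste0(stem, "_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(NULL)
}

#' Read a ground-truth sidecar written by [makeFixtures()]
#'
#' @param jsonPath path to the \code{*_truth.json} sidecar.
#' @return a [GroundTruth-class].
#' @export
readGroundTruth <- function(jsonPath) {
  meta <- jsonlite::fromJSON(jsonPath, simplifyVector = FALSE)
  pages <- readTIFFGray(file.path(dirname(jsonPath), meta$mask_tiff))$pages
  names(pages) <- unlist(meta$mask_pages)
  toMask <- function(m) m > 0
  new("GroundTruth",
      cellMask = toMask(pages$cell), nuclearMask = toMask(pages$nuclear),
      membraneMask = toMask(pages$membrane),
      nucleusCount = as.integer(meta$nucleus_count),
      positiveMasks = lapply(pages[setdiff(names(pages),
                                           c("cell", "nuclear",
                                             "membrane"))], toMask),
      trueFraction = unlist(meta$true_fraction),
      trueAreaPerCellUm2 = unlist(meta$true_area_per_cell_um2))
}

#' Generate a ready-to-run synthetic fixture set
#'
#' Writes multichannel scene TIFFs, exact ground-truth sidecars, an
#' isotype-control image, and a validated pipeline config to
#' \code{outDir}. Deterministic: the same preset and seed produce
#' byte-identical files. Fixture configs set the evaluability floor to 0
#' because desk-scale scenes carry tens, not thousands, of cells.
#'
#' Presets: \code{"dose-response"} (3 dose groups -- vehicle, 1x and 10x
#' the IC50 -- times 4 replicate animals, sigmoidal phospho suppression,
#' total MET unchanged); \code{"expression-tiers"} (negligible / weak /
#' moderate / high expression, 3 fields each); \code{"nuclear-shift"}
#' (nuclear phospho fraction 0.3 vs 0.6, 5 specimens each);
#' \code{"isotype"} (background-only marker channels, 3 fields).
#'
#' @param preset preset name.
#' @param outDir output directory (created if needed).
#' @param seed base RNG seed.
#' @return (invisibly) the path to the written config JSON.
#' @export
makeFixtures <- function(preset, outDir, seed = 1L) {
  known <- c("dose-response", "expression-tiers", "nuclear-shift",
             "isotype")
  if (!preset %in% known)
    stopf("unknown preset '%s' (known: %s)", preset,
          paste(known, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  entries <- list()
  addEntry <- function(stem, spec, group, specimen) {
    sc <- generateScene(spec)
    cmap <- writeChannelStack(sc$stack, file.path(outDir,
                                                  paste0(stem, ".tif")))
    writeTruthSidecar(sc$truth, file.path(outDir, stem))
    entries[[length(entries) + 1L]] <<- list(
      field_id = stem, specimen_id = specimen, group = group,
      path = paste0(stem, ".tif"),
      channel_map = as.list(cmap))
  }
  baseFor <- function(preset) switch(preset,
    "dose-response" = scenePreset("high", seed),
    "expression-tiers" = scenePreset("moderate", seed),
    "nuclear-shift" = scenePreset("nuclear-low", seed),
    "isotype" = scenePreset("moderate", seed))
  reference <- NULL
  if (preset == "dose-response") {
    series <- generateDoseResponseSeries(baseFor(preset),
                                         doses = c(0, 1, 10), ic50 = 1,
                                         hill = 1, nReps = 4L, seed = seed)
    for (e in series) {
      group <- if (e$dose == 0) "vehicle" else sprintf("dose_%g", e$dose)
      stem <- sprintf("scene_d%g_r%d", e$dose, e$rep)
      cmap <- writeChannelStack(e$stack, file.path(outDir,
                                                   paste0(stem, ".tif")))
      writeTruthSidecar(e$truth, file.path(outDir, stem))
      entries[[length(entries) + 1L]] <- list(
        field_id = stem, specimen_id = sprintf("animal_d%g_r%d", e$dose,
                                               e$rep),
        group = group, path = paste0(stem, ".tif"),
        channel_map = as.list(cmap))
    }
    reference <- "vehicle"
  } else if (preset == "expression-tiers") {
    tiers <- c("negligible", "weak", "moderate", "high")
    k <- 0L
    for (tier in tiers) for (j in 1:3) {
      addEntry(sprintf("scene_%s_f%d", tier, j),
               scenePreset(tier, seed + k), tier,
               sprintf("pellet_%s", tier))
      k <- k + 1L
    }
    reference <- "negligible"
  } else if (preset == "nuclear-shift") {
    k <- 0L
    for (grp in c("nuclear_low", "nuclear_high")) for (j in 1:5) {
      addEntry(sprintf("scene_%s_a%d", grp, j),
               scenePreset(sub("_", "-", grp), seed + k), grp,
               sprintf("animal_%s_%d", grp, j))
      k <- k + 1L
    }
    reference <- "nuclear_low"
  } else {  # isotype
    for (j in 1:3) {
      spec <- baseFor(preset)
      spec@seed <- as.integer(seed + j - 1L)
      st <- generateIsotypeControl(spec)
      stem <- sprintf("isotype_f%d", j)
      cmap <- writeChannelStack(st, file.path(outDir, paste0(stem, ".tif")))
      entries[[length(entries) + 1L]] <- list(
        field_id = stem, specimen_id = sprintf("control_%d", j),
        group = "isotype", path = paste0(stem, ".tif"),
        channel_map = as.list(cmap))
    }
    reference <- "isotype"
  }
  ctrlSpec <- baseFor(preset)
  ctrlSpec@seed <- as.integer(seed + 10000L)
  ctrl <- generateIsotypeControl(ctrlSpec)
  ctrlMap <- writeChannelStack(ctrl, file.path(outDir, "isotype_control.tif"))
  thrEntry <- function(marker) list(
    method = "mean_plus_k_sd", parameter = 3,
    control_image = "isotype_control.tif",
    control_channel = unname(ctrlMap[[marker]]))
  cfg <- list(
    schema_version = 1,
    pixel_size_um = ctrlSpec@pixelSizeUm,
    segmentation = list(nuclear_threshold_method = "otsu",
                        min_nucleus_area_um2 = 10,
                        split_touching_nuclei = FALSE,
                        membrane_threshold_method = "otsu",
                        connectivity = 8, tissue_dilation_um = 5),
    thresholds = list(total_met = thrEntry("total_met"),
                      phospho_met = thrEntry("phospho_met")),
    min_cells = 0,
    stats = list(reference_group = reference),
    fields = entries,
    output_dir = "results")
  cfgPath <- file.path(outDir, "pipeline_config.json")
  jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(cfgPath)
}
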