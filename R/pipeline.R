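## cli_pipeline: end-to-end orchestration with config validation, logging
## and reproducible seeds.

.CONFIG_KEYS <- c("seed", "n_cases", "spacing_mm", "connectivity",
                  "pooling", "modalities", "out_dir", "run_label",
                  "phantom", "write_dicom", "log_level")
.PHANTOM_KEYS <- c("grid_px", "core_radius_mm", "core_irregularity",
                   "ring_width_mm", "n_landmarks")

#' Default pipeline configuration
#'
#' @param seed integer RNG seed propagated to every stage.
#' @param outDir output directory for the run.
#' @return named list accepted by \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(seed, outDir) {
  list(seed = seed, n_cases = 10, spacing_mm = 0.2, connectivity = 8,
       pooling = "macro",
       modalities = names(studyCutoffs()),
       out_dir = outDir, run_label = NULL, phantom = list(),
       write_dicom = FALSE, log_level = "info")
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and out-of-range values before any
#' stage runs.
#'
#' @param config named list or path to a YAML file.
#' @return the validated, completed configuration list.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("configuration requires a seed")
  if (is.null(config$out_dir)) stop("configuration requires out_dir")
  full <- defaultPipelineConfig(config$seed, config$out_dir)
  full[names(config)] <- config
  if (!full$connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8, got ", full$connectivity)
  if (!full$pooling %in% c("macro", "micro"))
    stop("pooling must be macro or micro")
  if (full$n_cases < 1) stop("n_cases must be >= 1")
  if (!all(full$modalities %in% names(studyCutoffs())))
    stop("unknown modalities: ",
         paste(setdiff(full$modalities, names(studyCutoffs())),
               collapse = ", "))
  bad <- setdiff(names(full$phantom), .PHANTOM_KEYS)
  if (length(bad))
    stop("unknown phantom keys: ", paste(bad, collapse = ", "))
  full
}

.pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[necromap] ", fmt), ...))
}

#' Run the full delineation-accuracy pipeline
#'
#' Phantom cohort generation, marker/landmark rigid co-registration,
#' per-ablation threshold sweeps, per-modality pooled cutoffs, summary ROC
#' curves, and size morphometry, written as CSV (and optionally DICOM)
#' under a run directory. Identical configuration and seed produce
#' identical numeric outputs.
#'
#' @param config named list or YAML path; see
#'   \code{\link{validatePipelineConfig}}.
#' @return the run manifest (list), invisibly; written to manifest.yaml.
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  label <- if (is.null(config$run_label))
    format(Sys.time(), "run-%Y%m%d-%H%M%S") else config$run_label
  runDir <- file.path(config$out_dir, label)
  dir.create(runDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   run_dir = runDir, stages = list(), outputs = character(0))

  ## stage: phantom cohort
  .pipe_log(config, "phantom: n_cases=%d seed=%d spacing=%.3g mm",
            config$n_cases, config$seed, config$spacing_mm)
  spec <- defaultStudySpec(config$seed)
  spec@spacingMm <- config$spacing_mm
  ph <- config$phantom
  if (!is.null(ph$grid_px)) spec@gridPx <- ph$grid_px
  if (!is.null(ph$core_radius_mm)) spec@coreRadiusMm <- ph$core_radius_mm
  if (!is.null(ph$core_irregularity))
    spec@coreIrregularity <- ph$core_irregularity
  if (!is.null(ph$ring_width_mm)) spec@ringWidthMm <- ph$ring_width_mm
  if (!is.null(ph$n_landmarks)) spec@nLandmarks <- ph$n_landmarks
  spec@valuesByZone <- spec@valuesByZone[config$modalities]
  spec@noiseSd <- spec@noiseSd[config$modalities]
  validObject(spec)
  cases <- generateCohort(config$n_cases, spec)
  ids <- sprintf("ablation_%02d", seq_along(cases))
  manifest$stages$phantom <- "ok"
  .pipe_log(config, "phantom: true areas %.1f-%.1f mm2",
            min(vapply(cases, function(x) x@truth$areaMm2, 0)),
            max(vapply(cases, function(x) x@truth$areaMm2, 0)))

  if (isTRUE(config$write_dicom)) {
    masks <- lapply(cases, function(cs) cs@reference)
    names(masks) <- paste0(ids, "_histology")
    written <- writeOutputs(masks = masks, outDir = file.path(runDir,
                                                              "dicom"))
    for (i in seq_along(cases)) {
      for (m in names(cases[[i]]@images)) {
        p <- file.path(runDir, "dicom",
                       sprintf("%s_%s.dcm", ids[i], m))
        writeImage(cases[[i]]@images[[m]], p)
        written <- c(written, p)
      }
    }
    manifest$outputs <- c(manifest$outputs, written)
  }

  ## stage: co-registration
  aligned <- vector("list", length(cases))
  regErr <- data.frame()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    tr <- estimateTransform(cs@reference, cs@truth$imageMarkerXY,
                            cs@truth$imageLandmarks)
    aligned[[i]] <- applyTransform(cs@reference, tr)
    tt <- cs@truth$transform
    regErr <- rbind(regErr, data.frame(
      ablation_id = ids[i],
      shift_err_px = sqrt((tr@dxPx - tt@dxPx)^2 + (tr@dyPx - tt@dyPx)^2),
      rot_err_deg = abs(tr@thetaDeg - tt@thetaDeg)))
  }
  utils::write.csv(regErr, file.path(runDir, "registration.csv"),
                   row.names = FALSE)
  manifest$stages$coregistration <- "ok"
  .pipe_log(config, "coregistration: max shift err %.3g px, max rot err %.3g deg",
            max(regErr$shift_err_px), max(regErr$rot_err_deg))

  ## stage: threshold sweeps
  sweeps <- list()
  sweepRows <- list()
  for (m in config$modalities) {
    sweeps[[m]] <- lapply(seq_along(cases), function(i) {
      cs <- cases[[i]]
      img <- cs@images[[m]]
      seed_xy <- defaultSeed(img, cs@truth$imageMarkerXY)
      sw <- thresholdSweep(img, aligned[[i]], seed_xy,
                           connectivity = config$connectivity,
                           ablationId = ids[i])
      sw
    })
    sweepRows[[m]] <- do.call(rbind, lapply(sweeps[[m]], function(s) {
      tb <- sweepTable(s)
      data.frame(ablation_id = s@ablationId, modality = m, tb)
    }))
  }
  allSweeps <- do.call(rbind, sweepRows)
  manifest$stages$sweep <- "ok"
  .pipe_log(config, "sweep: %d modality-ablation sweeps, %d rows total",
            length(config$modalities) * length(cases), nrow(allSweeps))

  ## stage: pooling (Table-2-shaped accuracy report)
  accRows <- list(); cutRows <- list(); pooledByMod <- list()
  for (m in config$modalities) {
    pc <- pooledCutoff(sweeps[[m]])
    pooledByMod[[m]] <- pc
    per <- data.frame(modality = m, pc$perAblation)
    pooledMetrics <- if (config$pooling == "macro") pc$macro else pc$micro
    pooledRow <- data.frame(
      modality = m, ablation_id = "pooled", threshold = pc$threshold,
      tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn),
      tpr = pooledMetrics[["tpr"]], fdr = pooledMetrics[["fdr"]],
      adr = pooledMetrics[["adr"]])
    accRows[[m]] <- rbind(per, pooledRow)
    cutRows[[m]] <- data.frame(modality = m, cutoff = pc$threshold)
    .pipe_log(config, "pool [%s]: cutoff %g, pooled tpr %.0f%% fdr %.0f%% adr %.2f",
              m, pc$threshold, 100 * pooledMetrics[["tpr"]],
              100 * pooledMetrics[["fdr"]], pooledMetrics[["adr"]])
  }
  accuracy <- do.call(rbind, accRows)
  writeOutputs(tables = list(sweeps = allSweeps, accuracy = accuracy,
                             cutoffs = do.call(rbind, cutRows)),
               outDir = runDir, overwrite = TRUE)
  manifest$stages$pool <- "ok"

  ## stage: summary ROC
  srocRows <- list()
  if (config$n_cases >= 2) {
    for (m in config$modalities) {
      sr <- summaryROC(sweeps[[m]])
      srocRows[[m]] <- data.frame(modality = m, auc = sr@auc)
    }
    utils::write.csv(do.call(rbind, srocRows),
                     file.path(runDir, "sroc_auc.csv"), row.names = FALSE)
    manifest$stages$sroc <- "ok"
  } else manifest$stages$sroc <- "skipped (single case)"

  ## stage: morphometry at the pooled cutoffs
  histSizes <- do.call(rbind, lapply(seq_along(cases), function(i) {
    s <- measureSize(maskValues(cases[[i]]@reference),
                     spacingMm(cases[[i]]@reference), ids[i], "Histology")
    s[, c("ablation_id", "area_mm2", "max_diameter_mm")]
  }))
  modSizes <- do.call(rbind, lapply(config$modalities, function(m) {
    thr <- pooledByMod[[m]]$threshold
    do.call(rbind, lapply(seq_along(cases), function(i) {
      cs <- cases[[i]]
      img <- cs@images[[m]]
      iso <- isolateAblation(img, thr,
                             defaultSeed(img, cs@truth$imageMarkerXY),
                             config$connectivity)
      if (iso$n_pixels == 0)
        return(data.frame(ablation_id = ids[i], modality = m,
                          area_mm2 = 0, max_diameter_mm = 0))
      measureSize(iso$mask, spacingMm(img), ids[i], m)
    }))
  }))
  report <- cohortReport(modSizes, histSizes,
                         modalities = config$modalities)
  writeOutputs(tables = list(sizes = modSizes, size_report = report),
               outDir = runDir, overwrite = TRUE)
  manifest$stages$sizes <- "ok"
  .pipe_log(config, "sizes: histology mean %.1f mm2",
            mean(histSizes$area_mm2))

  manifest$outputs <- c(manifest$outputs,
                        file.path(runDir,
                                  c("registration.csv", "sweeps.csv",
                                    "accuracy.csv", "cutoffs.csv",
                                    "sizes.csv", "size_report.csv")),
                        if (length(srocRows))
                          file.path(runDir, "sroc_auc.csv"))
  yaml::write_yaml(manifest, file.path(runDir, "manifest.yaml"))
  invisible(manifest)
}
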