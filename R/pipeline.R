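#' @include inference.R io.R
NULL

#' Read a study configuration from YAML
#'
#' Maps a flat YAML file onto [studyConfig()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A [studyConfig()] object.
#' @export
readStudyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(studyConfig))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(studyConfig, cfg)
}

#' Run a full association study
#'
#' For each requested score: load and align the imaging and behavioral
#' data, optionally residualize both blocks on the covariates, select the
#' retained dimensionality by leave-one-out cross-validation, fit the
#' canonical pair, assess significance by score permutation, map voxelwise
#' reliability by the Procrustes-aligned bootstrap, and write the
#' bootstrap-ratio map, the signed suprathreshold mask, a display-filled
#' mask, a machine-readable summary table and a log of all constants and
#' seeds. A failure in one score is logged and the remaining scores are
#' still processed. Scores are analyzed independently; reruns with the
#' same configuration produce byte-identical summaries.
#'
#' @param config a [studyConfig()] object.
#' @return Invisibly, a list with the per-score results, the summary data
#'   frame and the output paths.
#' @export
runStudy <- function(config) {
  stopifnot(is(config, "StudyConfig"))
  validObject(config)
  dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
  dataset <- loadSkeletonDataset(config@imagePath, config@maskPath,
                                 faThreshold = config@faThreshold)
  table <- loadBehaviorTable(config@tablePath, config@scoreNames,
                             config@covariateNames, config@idColumn)
  al <- alignSubjects(dataset, table)
  dataset <- al$dataset; table <- al$table
  n <- nSubjects(dataset); p <- nVoxels(dataset)
  qGrid <- if (is.na(config@qMax)) NULL
           else seq_len(min(config@qMax, n - 2L, p))
  meanFaVol <- array(0, dim(skeletonMask(dataset)))
  meanFaVol[voxelIndex(dataset)] <- colMeans(faMatrix(dataset))

  logLines <- c("skeletonCCA study run",
                sprintf("subjects: %d  voxels: %d", n, p),
                sprintf("nPerm: %d  bFolds: %d  threshold: %g  seed: %d",
                        config@nPerm, config@bFolds, config@threshold,
                        config@seed),
                sprintf("faThreshold: %g  qMax: %s  adjustment: %s",
                        config@faThreshold,
                        if (is.na(config@qMax)) "full" else config@qMax,
                        config@adjustment))
  rows <- list()
  results <- list()
  for (score in config@scoreNames) {
    res <- tryCatch(
      adjustedAndUnadjusted(dataset, table, score,
                            which = config@adjustment, qGrid = qGrid,
                            nPerm = config@nPerm, bFolds = config@bFolds,
                            threshold = config@threshold,
                            seed = config@seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      logLines <- c(logLines,
                    sprintf("score %s: FAILED (%s)", score,
                            conditionMessage(res)))
      next
    }
    results[[score]] <- res
    for (arm in names(res)) {
      r <- res[[arm]]
      rows[[paste(score, arm)]] <- data.frame(
        score = score, arm = arm, n = n, q = r$q,
        r = canonicalCorrelation(r$cca),
        p = pValue(r$permutation),
        cv_r = max(cvCorrelations(r$cv)),
        bootstrap_r_sd = stats::sd(r$saliency@bootstrapR),
        n_suprathreshold = sum(signedMask(r$saliency) != 0),
        n_perm = config@nPerm, b_folds = config@bFolds,
        threshold = config@threshold, seed = config@seed,
        stringsAsFactors = FALSE)
      logLines <- c(logLines,
                    sprintf("score %s (%s): Q=%d R=%.4f p=%.4g redraws=%d",
                            score, arm, r$q, canonicalCorrelation(r$cca),
                            pValue(r$permutation), r$saliency@redraws))
      base <- file.path(config@outputDir, paste0(score, "_", arm))
      meta <- list(score = score, arm = arm, q = r$q,
                   bFolds = config@bFolds, threshold = config@threshold,
                   seed = config@seed,
                   reference = S4Vectors::metadata(dataset)$reference)
      ratioVals <- bootstrapRatio(r$saliency)
      ratioVals[!is.finite(ratioVals)] <- 0
      writeSaliency(vectorToVolume(ratioVals, dataset,
                                   c(meta, kind = "ratio")),
                    paste0(base, "_ratio.nii.gz"))
      signedVol <- vectorToVolume(signedMask(r$saliency), dataset,
                                  c(meta, kind = "signed"))
      writeSaliency(signedVol, paste0(base, "_signed.nii.gz"))
      filled <- fillForDisplay(signedVol, meanFaVol, config@fillRadius)
      writeSaliency(filled, paste0(base, "_signed_filled.nii.gz"))
    }
  }
  summary <- do.call(rbind, rows)
  summaryPath <- file.path(config@outputDir, "summary.tsv")
  if (!is.null(summary))
    utils::write.table(summary, summaryPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  writeLines(logLines, file.path(config@outputDir, "run_log.txt"))
  invisible(list(results = results, summary = summary,
                 summaryPath = summaryPath, outputDir = config@outputDir))
}

#' Simulate a cohort from a YAML configuration and write it to disk
#'
#' Thin wrapper over [simConfig()], [generateCohort()] and
#' [writeCohort()]: the YAML keys are the `simConfig()` arguments plus
#' `outputDir`.
#'
#' @param configPath YAML file path.
#' @return Invisibly, the named vector of written paths.
#' @export
simulateCohortCommand <- function(configPath) {
  cfg <- yaml::read_yaml(configPath)
  outDir <- cfg$outputDir
  if (is.null(outDir))
    stop("config must name an outputDir", call. = FALSE)
  cfg$outputDir <- NULL
  known <- names(formals(simConfig))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cohort <- generateCohort(do.call(simConfig, cfg))
  writeCohort(cohort, outDir)
}
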