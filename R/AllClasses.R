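#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## Central data container: voxels are rows (features), subjects are columns,
## following the usual assay orientation. The analysis-facing accessor
## faMatrix() returns the transposed N x P view used by the fitting code.

#' SkeletonDataset: subjects-by-voxel features on a skeleton mask
#'
#' Container for a cohort's voxelwise white-matter features sampled on a
#' binary skeleton mask. Extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with one assay `"fa"` holding a P (voxels) x N (subjects) matrix,
#' per-voxel grid coordinates in `rowData` and the 3-D logical mask in
#' `metadata(x)$mask`.
#'
#' Column order of the flattened voxel dimension is the column-major raster
#' order of the mask array (first array index fastest), so two loads of the
#' same files produce bit-identical objects.
#'
#' @param fa numeric matrix, N subjects x P voxels (analysis orientation).
#' @param mask 3-D logical array; `sum(mask)` must equal P.
#' @param voxelIndex optional P x 3 integer matrix of voxel grid coordinates,
#'   one row per column of `fa`; defaults to the raster-order coordinates of
#'   `mask`.
#' @param subjectIds optional character vector of length N.
#' @param reference optional NIfTI header/image to copy geometry from when
#'   writing volumes derived from this dataset.
#'
#' @return A `SkeletonDataset` object.
#' @examples
#' mask <- array(TRUE, c(4, 4, 2))
#' fa <- matrix(runif(3 * 32), nrow = 3)
#' sd <- SkeletonDataset(fa, mask)
#' nVoxels(sd)
#' @export
SkeletonDataset <- function(fa, mask, voxelIndex = NULL, subjectIds = NULL,
                            reference = NULL) {
  fa <- as.matrix(fa)
  if (is.null(subjectIds))
    subjectIds <- sprintf("S%03d", seq_len(nrow(fa)))
  if (is.null(voxelIndex))
    voxelIndex <- maskCoordinates(mask)
  storage.mode(voxelIndex) <- "integer"
  if (ncol(fa) != nrow(voxelIndex))
    stop(sprintf("voxel count (%d) != mask count (%d)", ncol(fa),
                 nrow(voxelIndex)), call. = FALSE)
  a <- t(fa)
  colnames(a) <- subjectIds
  se <- SummarizedExperiment(
    assays = SimpleList(fa = a),
    rowData = DataFrame(i = voxelIndex[, 1], j = voxelIndex[, 2],
                        k = voxelIndex[, 3]),
    colData = DataFrame(subject = subjectIds, row.names = subjectIds))
  S4Vectors::metadata(se) <- list(mask = mask, reference = reference)
  new("SkeletonDataset", se)
}

#' Raster-order coordinates of a 3-D mask
#'
#' Returns the grid coordinates of the `TRUE` voxels of a 3-D logical array
#' in column-major raster order (first index fastest), the fixed column
#' order used throughout the package.
#'
#' @param mask 3-D logical array.
#' @return Integer matrix with one row per `TRUE` voxel and columns i, j, k.
#' @export
maskCoordinates <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  which(mask, arr.ind = TRUE)
}

setClass("SkeletonDataset", contains = "SummarizedExperiment")

setValidity("SkeletonDataset", function(object) {
  msg <- character()
  mask <- S4Vectors::metadata(object)$mask
  if (is.null(mask) || !is.logical(mask) || length(dim(mask)) != 3L)
    return("metadata(x)$mask must be a 3-D logical array")
  if (!"fa" %in% SummarizedExperiment::assayNames(object))
    return("assay 'fa' is missing")
  a <- SummarizedExperiment::assay(object, "fa")
  if (nrow(object) != sum(mask))
    msg <- c(msg, sprintf("voxel count (%d) != mask count (%d)",
                          nrow(object), sum(mask)))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("i", "j", "k") %in% colnames(rd))) {
    msg <- c(msg, "rowData must have columns i, j, k")
  } else {
    co <- cbind(rd$i, rd$j, rd$k)
    d <- dim(mask)
    lin <- (co[, 3] - 1) * d[1] * d[2] + (co[, 2] - 1) * d[1] + co[, 1]
    if (anyDuplicated(lin))
      msg <- c(msg, "duplicate voxel coordinates")
    if (any(co < 1L) || any(co[, 1] > d[1] | co[, 2] > d[2] | co[, 3] > d[3]))
      msg <- c(msg, "voxel coordinates outside the grid")
    else if (!all(mask[co]))
      msg <- c(msg, "voxel coordinates fall outside the mask")
  }
  if (ncol(object) < 3L)
    msg <- c(msg, "at least 3 subjects are required")
  if (length(a) && !all(is.finite(a)))
    msg <- c(msg, "non-finite feature values")
  if (length(msg)) msg else TRUE
})

#' BehaviorTable: per-subject behavioral scores and covariates
#'
#' Holds one or more behavioral score vectors (for example NEO PI-R factor
#' scores) and nuisance covariates (age, gender) for the subjects of a
#' paired [SkeletonDataset].
#'
#' @param scores numeric matrix N x S with score names as column names, or a
#'   named list/data.frame of numeric vectors.
#' @param covariates numeric matrix N x C (possibly zero columns) with
#'   covariate names as column names.
#' @param subjectIds character vector of length N.
#' @return A `BehaviorTable` object.
#' @examples
#' bt <- BehaviorTable(cbind(openness = rnorm(5)),
#'                     cbind(age = runif(5, 65, 80), gender = rbinom(5, 1, .5)),
#'                     sprintf("S%03d", 1:5))
#' scoreNames(bt)
#' @export
BehaviorTable <- function(scores, covariates = NULL, subjectIds = NULL) {
  scores <- as.matrix(as.data.frame(scores))
  n <- nrow(scores)
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(as.data.frame(covariates))
  if (ncol(covariates) == 0L) dim(covariates) <- c(n, 0L)
  if (is.null(subjectIds)) subjectIds <- sprintf("S%03d", seq_len(n))
  new("BehaviorTable", scores = scores, covariates = covariates,
      subjectIds = as.character(subjectIds))
}

setClass("BehaviorTable",
         representation(scores = "matrix", covariates = "matrix",
                        subjectIds = "character"))

setValidity("BehaviorTable", function(object) {
  msg <- character()
  n <- length(object@subjectIds)
  if (nrow(object@scores) != n)
    msg <- c(msg, "scores and subjectIds disagree on N")
  if (nrow(object@covariates) != n)
    msg <- c(msg, "covariates and subjectIds disagree on N")
  if (is.null(colnames(object@scores)) && ncol(object@scores) > 0)
    msg <- c(msg, "score columns must be named")
  if (!all(is.finite(object@scores)))
    msg <- c(msg, "missing or non-finite score values")
  if (length(object@covariates) && !all(is.finite(object@covariates)))
    msg <- c(msg, "missing or non-finite covariate values")
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "duplicate subject ids")
  if (length(msg)) msg else TRUE
})

#' ReducedBasis: truncated SVD of a column-centered feature matrix
#'
#' Right singular vectors (voxel loadings), singular values and the column
#' means of the centering step, as returned by [fitTruncatedSVD()].
#'
#' @slot components P x Q orthonormal matrix of voxel loadings.
#' @slot singularValues length-Q non-increasing positive singular values.
#' @slot columnMeans length-P column means used for centering; reused when
#'   projecting held-out subjects.
#' @slot q number of retained components.
#' @export
setClass("ReducedBasis",
         representation(components = "matrix", singularValues = "numeric",
                        columnMeans = "numeric", q = "integer"))

setValidity("ReducedBasis", function(object) {
  msg <- character()
  q <- object@q
  if (ncol(object@components) != q || length(object@singularValues) != q)
    msg <- c(msg, "component count disagrees with q")
  if (length(object@columnMeans) != nrow(object@components))
    msg <- c(msg, "columnMeans length disagrees with P")
  if (q >= 1) {
    if (is.unsorted(rev(object@singularValues)))
      msg <- c(msg, "singular values must be non-increasing")
    if (any(object@singularValues < 0))
      msg <- c(msg, "singular values must be non-negative")
    g <- crossprod(object@components) - diag(q)
    if (max(abs(g)) > 1e-8)
      msg <- c(msg, "components are not orthonormal")
  }
  if (length(msg)) msg else TRUE
})

#' CCASolution: a single canonical pair
#'
#' The one retained canonical pair relating reduced imaging scores to a
#' behavioral score: canonical weights E (imaging) and F (behavior), the
#' variates U and V, and their correlation R. The sign convention fixes
#' F > 0, so positive voxel weights mean higher feature values accompany
#' higher scores.
#'
#' @slot weightsX length-Q canonical weights on the reduced scores (E).
#' @slot weightY positive scalar weight on the centered score (F).
#' @slot variateX length-N imaging variate U (unit variance when R > 0).
#' @slot variateY length-N behavioral variate V.
#' @slot correlation canonical correlation R, between 0 and 1.
#' @export
setClass("CCASolution",
         representation(weightsX = "numeric", weightY = "numeric",
                        variateX = "numeric", variateY = "numeric",
                        correlation = "numeric"))

setValidity("CCASolution", function(object) {
  msg <- character()
  if (length(object@variateX) != length(object@variateY))
    msg <- c(msg, "variates differ in length")
  if (length(object@weightY) != 1L || object@weightY <= 0)
    msg <- c(msg, "weightY must be a positive scalar")
  r <- object@correlation
  if (r < -1e-12 || r > 1 + 1e-12)
    msg <- c(msg, "correlation outside [0, 1]")
  su <- stats::sd(object@variateX)
  sv <- stats::sd(object@variateY)
  if (is.finite(su) && is.finite(sv) && su > 0 && sv > 0) {
    if (abs(stats::cor(object@variateX, object@variateY) - r) > 1e-10)
      msg <- c(msg, "correlation does not match the variates")
  } else if (r != 0) {
    msg <- c(msg, "degenerate variates must carry correlation 0")
  }
  if (length(msg)) msg else TRUE
})

#' CVSelection: leave-one-out choice of the retained dimensionality
#'
#' @slot cvCorrelations cross-validated correlation per candidate q (names
#'   are the q values).
#' @slot selectedQ the argmax of `cvCorrelations`, ties broken toward the
#'   smallest q.
#' @slot nFolds number of leave-one-out folds (= N).
#' @export
setClass("CVSelection",
         representation(cvCorrelations = "numeric", selectedQ = "integer",
                        nFolds = "integer"))

setValidity("CVSelection", function(object) {
  qs <- as.integer(names(object@cvCorrelations))
  if (length(qs) == 0L || anyNA(qs))
    return("cvCorrelations must be named by integer q")
  best <- qs[which(object@cvCorrelations ==
                     max(object@cvCorrelations))]
  if (object@selectedQ != min(best))
    return("selectedQ must be the smallest argmax q")
  TRUE
})

#' PermutationResult: permutation test of the canonical correlation
#'
#' @slot observedR canonical correlation of the unpermuted data.
#' @slot nullRs canonical correlations under score permutation.
#' @slot pValue add-one permutation p-value:
#'   (1 + count of null at or above observed) / (1 + nPerm).
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used to draw the permutations.
#' @export
setClass("PermutationResult",
         representation(observedR = "numeric", nullRs = "numeric",
                        pValue = "numeric", nPerm = "integer",
                        seed = "integer"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (length(object@nullRs) != object@nPerm)
    msg <- c(msg, "nullRs length disagrees with nPerm")
  if (any(object@nullRs < -1e-12 | object@nullRs > 1 + 1e-12))
    msg <- c(msg, "null correlations outside [0, 1]")
  p <- (1 + sum(object@nullRs >= object@observedR)) / (1 + object@nPerm)
  if (abs(p - object@pValue) > 1e-12)
    msg <- c(msg, "pValue does not satisfy the add-one formula")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue outside (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SaliencyResult: voxelwise bootstrap weight distributions and ratios
#'
#' @slot weightDistribution B x P matrix of back-projected voxel weights,
#'   one row per bootstrap fold (sign-corrected, Procrustes-aligned).
#' @slot ratio length-P bootstrap ratios (fold mean / fold SD, SD with the
#'   N-1 denominator); voxels whose weight distribution has zero variance
#'   carry `sign(mean) * Inf` (0 when the mean is also 0) and are listed in
#'   `degenerateVoxels`.
#' @slot signedMask length-P values in -1/0/+1:
#'   `sign(ratio) * (|ratio| >= threshold)`.
#' @slot threshold bootstrap-ratio threshold (default 1.96).
#' @slot bFolds number of bootstrap folds retained.
#' @slot referenceWeights length-P full-data back-projected voxel weights
#'   used as the sign/alignment reference.
#' @slot bootstrapR per-fold canonical correlations (their SD summarizes the
#'   stability of R).
#' @slot redraws number of degenerate resamples that were redrawn.
#' @slot degenerateVoxels indices of zero-variance voxels.
#' @export
setClass("SaliencyResult",
         representation(weightDistribution = "matrix", ratio = "numeric",
                        signedMask = "numeric", threshold = "numeric",
                        bFolds = "integer", referenceWeights = "numeric",
                        bootstrapR = "numeric", redraws = "integer",
                        degenerateVoxels = "integer"))

setValidity("SaliencyResult", function(object) {
  msg <- character()
  p <- length(object@ratio)
  if (ncol(object@weightDistribution) != p)
    msg <- c(msg, "weightDistribution and ratio disagree on P")
  if (nrow(object@weightDistribution) != object@bFolds)
    msg <- c(msg, "weightDistribution and bFolds disagree on B")
  if (length(object@signedMask) != p)
    msg <- c(msg, "signedMask length disagrees with P")
  if (!all(object@signedMask %in% c(-1, 0, 1)))
    msg <- c(msg, "signedMask entries must be -1, 0 or +1")
  expect <- sign(object@ratio) * (abs(object@ratio) >= object@threshold)
  expect[is.nan(expect)] <- 0
  if (!identical(as.numeric(expect), as.numeric(object@signedMask)))
    msg <- c(msg, "signedMask does not match thresholded ratios")
  if (length(msg)) msg else TRUE
})

#' SaliencyVolume: a saliency statistic in mask geometry
#'
#' A 3-D volume carrying either continuous bootstrap ratios or a signed
#' suprathreshold mask (-1/0/+1), plus provenance metadata.
#'
#' @param values 3-D numeric array.
#' @param mask 3-D logical array of the same shape.
#' @param meta named list of provenance fields (score name, q, bFolds,
#'   threshold, seed, `kind` = "ratio" or "signed", `filled` flag,
#'   optional NIfTI `reference`).
#' @return A `SaliencyVolume`.
#' @export
SaliencyVolume <- function(values, mask, meta = list()) {
  if (is.null(meta$kind)) meta$kind <- "ratio"
  if (is.null(meta$filled)) meta$filled <- FALSE
  new("SaliencyVolume", values = values, mask = mask, meta = meta)
}

setClass("SaliencyVolume",
         representation(values = "array", mask = "array", meta = "list"))

setValidity("SaliencyVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask differ in shape")
  filled <- isTRUE(object@meta$filled)
  out <- object@values[!object@mask]
  if (!filled && length(out) && any(out[is.finite(out)] != 0))
    msg <- c(msg, "values must be zero outside the mask")
  if (identical(object@meta$kind, "signed")) {
    v <- object@values[is.finite(object@values)]
    if (!all(v %in% c(-1, 0, 1)))
      msg <- c(msg, "signed volume entries must be -1, 0 or +1")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic-cohort generator
#'
#' Defaults emulate a controls-sized elderly cohort with a planted rank-one
#' association between the voxel block and the score. See
#' [generateCohort()] for the generative model.
#'
#' @param nSubjects number of subjects N (default 160, a controls-sized
#'   cohort).
#' @param gridShape 3-D grid dimensions (default c(40, 48, 40)).
#' @param skeletonFraction fraction of grid voxels kept in the skeleton
#'   mask (default 0.26, about 2e4 voxels on the default grid).
#' @param nSalient number of salient (signal-carrying) voxels (default 50).
#' @param fracNegative share of salient voxels with negative loading
#'   (default 0.3).
#' @param rho target latent correlation between the planted latent variate
#'   and the score, at least 0 and below 1 (default 0.6, inside the 0.4-0.9 range typical
#'   of full-data fits at these cohort sizes).
#' @param noiseSd voxel noise standard deviation (default 1).
#' @param confoundBetaAge,confoundBetaGender linear effect of age (years)
#'   and gender (0/1) on the score (default 0).
#' @param smoothFwhm optional Gaussian smoothing FWHM (in voxels) applied to
#'   the noise field; 0 (default) disables spatial autocorrelation.
#' @param seed integer RNG seed; all outputs are pure functions of the
#'   configuration including the seed.
#' @return A `SimulationConfig`.
#' @examples
#' cfg <- simConfig(nSubjects = 30, gridShape = c(8, 8, 4),
#'                  skeletonFraction = 0.5, nSalient = 10, seed = 1)
#' @export
simConfig <- function(nSubjects = 160L, gridShape = c(40L, 48L, 40L),
                      skeletonFraction = 0.26, nSalient = 50L,
                      fracNegative = 0.3, rho = 0.6, noiseSd = 1,
                      confoundBetaAge = 0, confoundBetaGender = 0,
                      smoothFwhm = 0, seed = 1L) {
  new("SimulationConfig",
      nSubjects = as.integer(nSubjects), gridShape = as.integer(gridShape),
      skeletonFraction = skeletonFraction, nSalient = as.integer(nSalient),
      fracNegative = fracNegative, rho = rho, noiseSd = noiseSd,
      confoundBetaAge = confoundBetaAge,
      confoundBetaGender = confoundBetaGender,
      smoothFwhm = smoothFwhm, seed = as.integer(seed))
}

setClass("SimulationConfig",
         representation(nSubjects = "integer", gridShape = "integer",
                        skeletonFraction = "numeric", nSalient = "integer",
                        fracNegative = "numeric", rho = "numeric",
                        noiseSd = "numeric", confoundBetaAge = "numeric",
                        confoundBetaGender = "numeric",
                        smoothFwhm = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 3L)
    msg <- c(msg, "nSubjects must be at least 3")
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be three positive integers")
  if (object@skeletonFraction <= 0 || object@skeletonFraction >= 1)
    msg <- c(msg, "skeletonFraction must lie in (0, 1)")
  if (object@rho < 0 || object@rho >= 1)
    msg <- c(msg, "rho must lie in [0, 1)")
  if (object@fracNegative < 0 || object@fracNegative > 1)
    msg <- c(msg, "fracNegative must lie in [0, 1]")
  if (object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be positive")
  if (object@nSalient < 0L)
    msg <- c(msg, "nSalient must be non-negative")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: the planted signal of a synthetic cohort
#'
#' @slot salientCoords n x 3 integer coordinates of the salient voxels.
#' @slot salientSigns +1/-1 loading sign per salient voxel.
#' @slot latentScores the latent subject variate z driving both blocks.
#' @slot trueRho the target latent correlation.
#' @export
setClass("GroundTruth",
         representation(salientCoords = "matrix", salientSigns = "numeric",
                        latentScores = "numeric", trueRho = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (nrow(object@salientCoords) != length(object@salientSigns))
    msg <- c(msg, "salientCoords and salientSigns disagree")
  if (length(object@salientSigns) &&
      !all(object@salientSigns %in% c(-1, 1)))
    msg <- c(msg, "salient signs must be -1 or +1")
  if (length(msg)) msg else TRUE
})

#' StudyConfig: one full study run
#'
#' Defaults follow the published analysis constants: 10000 permutations,
#' B = 1000 bootstrap folds, bootstrap-ratio threshold 1.96, mean-FA mask
#' threshold 0.2.
#'
#' @param imagePath path to a 4-D NIfTI (or character vector of 3-D paths).
#' @param maskPath path to the binary skeleton mask NIfTI.
#' @param tablePath path to the delimited subject table.
#' @param outputDir directory for maps, summaries and logs.
#' @param scoreNames score columns to analyze (each gets its own fit).
#' @param covariateNames covariate columns (default age, gender).
#' @param idColumn subject-id column name (default "subject").
#' @param nPerm permutations for the significance test (default 10000).
#' @param bFolds bootstrap folds (default 1000).
#' @param threshold bootstrap-ratio threshold (default 1.96).
#' @param faThreshold mean-FA mask threshold (default 0.2).
#' @param qMax cap on the leave-one-out q grid; `NA` (default) uses the full
#'   1..N-2 range.
#' @param seed integer RNG seed for permutations and bootstrap.
#' @param adjustment "both", "unadjusted" or "adjusted" (covariate
#'   residualization arm).
#' @param fillRadius Chebyshev radius of the display fill (default 1).
#' @return A `StudyConfig`.
#' @export
studyConfig <- function(imagePath, maskPath, tablePath, outputDir,
                        scoreNames, covariateNames = c("age", "gender"),
                        idColumn = "subject", nPerm = 10000L,
                        bFolds = 1000L, threshold = 1.96,
                        faThreshold = 0.2, qMax = NA_integer_, seed = 1L,
                        adjustment = c("both", "unadjusted", "adjusted"),
                        fillRadius = 1L) {
  adjustment <- match.arg(adjustment)
  new("StudyConfig", imagePath = imagePath, maskPath = maskPath,
      tablePath = tablePath, outputDir = outputDir,
      scoreNames = scoreNames, covariateNames = covariateNames,
      idColumn = idColumn, nPerm = as.integer(nPerm),
      bFolds = as.integer(bFolds), threshold = threshold,
      faThreshold = faThreshold, qMax = as.integer(qMax),
      seed = as.integer(seed), adjustment = adjustment,
      fillRadius = as.integer(fillRadius))
}

setClass("StudyConfig",
         representation(imagePath = "character", maskPath = "character",
                        tablePath = "character", outputDir = "character",
                        scoreNames = "character",
                        covariateNames = "character", idColumn = "character",
                        nPerm = "integer", bFolds = "integer",
                        threshold = "numeric", faThreshold = "numeric",
                        qMax = "integer", seed = "integer",
                        adjustment = "character", fillRadius = "integer"))

setValidity("StudyConfig", function(object) {
  msg <- character()
  if (length(object@scoreNames) < 1L)
    msg <- c(msg, "at least one score name is required")
  if (object@nPerm < 99L)
    msg <- c(msg, "nPerm must be at least 99")
  if (object@bFolds < 10L)
    msg <- c(msg, "bFolds must be at least 10")
  if (object@threshold < 0)
    msg <- c(msg, "threshold must be non-negative")
  if (!object@adjustment %in% c("both", "unadjusted", "adjusted"))
    msg <- c(msg, "unknown adjustment mode")
  if (length(msg)) msg else TRUE
})
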