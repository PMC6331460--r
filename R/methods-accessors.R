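#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("faMatrix", "SkeletonDataset", function(x)
  t(SummarizedExperiment::assay(x, "fa")))

#' @rdname accessors
setMethod("skeletonMask", "SkeletonDataset", function(x)
  S4Vectors::metadata(x)$mask)

#' @rdname accessors
setMethod("voxelIndex", "SkeletonDataset", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  cbind(i = rd$i, j = rd$j, k = rd$k)
})

#' @rdname accessors
setMethod("subjectIds", "SkeletonDataset", function(x) colnames(x))

#' @rdname accessors
setMethod("nSubjects", "SkeletonDataset", function(x) ncol(x))

#' @rdname accessors
setMethod("nVoxels", "SkeletonDataset", function(x) nrow(x))

#' @rdname accessors
setMethod("subjectIds", "BehaviorTable", function(x) x@subjectIds)

#' @rdname accessors
setMethod("nSubjects", "BehaviorTable", function(x) length(x@subjectIds))

#' @rdname behavior-accessors
setMethod("behaviorScores", "BehaviorTable", function(x) x@scores)

#' @rdname behavior-accessors
setMethod("covariates", "BehaviorTable", function(x) x@covariates)

#' @rdname behavior-accessors
setMethod("scoreNames", "BehaviorTable", function(x) colnames(x@scores))

#' @rdname behavior-accessors
setMethod("getScore", "BehaviorTable", function(x, name) {
  if (!name %in% colnames(x@scores))
    stop("unknown score: ", name, call. = FALSE)
  v <- x@scores[, name]
  names(v) <- x@subjectIds
  v
})

#' @rdname fit-accessors
setMethod("components", "ReducedBasis", function(x) x@components)

#' @rdname fit-accessors
setMethod("singularValues", "ReducedBasis", function(x) x@singularValues)

#' @rdname fit-accessors
setMethod("selectedQ", "ReducedBasis", function(x) x@q)

#' @rdname fit-accessors
setMethod("canonicalCorrelation", "CCASolution", function(x) x@correlation)

#' @rdname fit-accessors
setMethod("canonicalWeights", "CCASolution", function(x)
  list(x = x@weightsX, y = x@weightY))

#' @rdname fit-accessors
setMethod("variates", "CCASolution", function(x)
  list(x = x@variateX, y = x@variateY))

#' @rdname fit-accessors
setMethod("selectedQ", "CVSelection", function(x) x@selectedQ)

#' @rdname fit-accessors
setMethod("cvCorrelations", "CVSelection", function(x) x@cvCorrelations)

#' @rdname fit-accessors
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname fit-accessors
setMethod("canonicalCorrelation", "PermutationResult",
          function(x) x@observedR)

#' @rdname fit-accessors
setMethod("nullDistribution", "PermutationResult", function(x) x@nullRs)

#' @rdname fit-accessors
setMethod("bootstrapRatio", "SaliencyResult", function(x) x@ratio)

#' @rdname fit-accessors
setMethod("signedMask", "SaliencyResult", function(x) x@signedMask)

setMethod("show", "SkeletonDataset", function(object) {
  cat("SkeletonDataset:", ncol(object), "subjects x", nrow(object),
      "skeleton voxels\n")
  cat("  grid:", paste(dim(skeletonMask(object)), collapse = " x "), "\n")
})

setMethod("show", "BehaviorTable", function(object) {
  cat("BehaviorTable:", nSubjects(object), "subjects\n")
  cat("  scores:", paste(scoreNames(object), collapse = ", "), "\n")
  cat("  covariates:",
      if (ncol(object@covariates)) paste(colnames(object@covariates),
                                         collapse = ", ") else "(none)",
      "\n")
})

setMethod("show", "ReducedBasis", function(object) {
  cat("ReducedBasis: q =", object@q, "components over",
      nrow(object@components), "voxels\n")
})

setMethod("show", "CCASolution", function(object) {
  cat(sprintf("CCASolution: R = %.4f (Q = %d, N = %d)\n",
              object@correlation, length(object@weightsX),
              length(object@variateX)))
})

setMethod("show", "CVSelection", function(object) {
  cat(sprintf("CVSelection: Q = %d (cv r = %.4f over %d candidates, N = %d)\n",
              object@selectedQ,
              max(object@cvCorrelations), length(object@cvCorrelations),
              object@nFolds))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: R = %.4f, p = %.4g (%d permutations)\n",
              object@observedR, object@pValue, object@nPerm))
})

setMethod("show", "SaliencyResult", function(object) {
  cat(sprintf(
    "SaliencyResult: B = %d folds, %d voxels, |ratio| >= %.2f at %d voxels (%d+/%d-)\n",
    object@bFolds, length(object@ratio), object@threshold,
    sum(object@signedMask != 0), sum(object@signedMask > 0),
    sum(object@signedMask < 0)))
})

setMethod("show", "SaliencyVolume", function(object) {
  cat("SaliencyVolume (", object@meta$kind, "):",
      paste(dim(object@values), collapse = " x "),
      if (isTRUE(object@meta$filled)) "[display-filled]" else "", "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: N = %d, grid %s, rho = %.2f, %d salient voxels, seed %d\n",
    object@nSubjects, paste(object@gridShape, collapse = "x"),
    object@rho, object@nSalient, object@seed))
})
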