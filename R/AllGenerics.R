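#' @include AllClasses.R
NULL

#' Accessors for skeletonCCA objects
#'
#' `faMatrix()` returns the N x P subjects-by-voxels feature matrix,
#' `skeletonMask()` the 3-D logical mask, `voxelIndex()` the P x 3 voxel
#' coordinates in raster order, and `subjectIds()` the subject identifiers.
#'
#' @param x a [SkeletonDataset] or [BehaviorTable].
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("faMatrix", function(x) standardGeneric("faMatrix"))

#' @rdname accessors
#' @export
setGeneric("skeletonMask", function(x) standardGeneric("skeletonMask"))

#' @rdname accessors
#' @export
setGeneric("voxelIndex", function(x) standardGeneric("voxelIndex"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' Accessors for behavioral data
#'
#' `behaviorScores()` returns the N x S score matrix, `covariates()` the
#' N x C covariate matrix, `getScore()` one named score vector.
#'
#' @param x a [BehaviorTable].
#' @param name score column name.
#' @name behavior-accessors
NULL

#' @rdname behavior-accessors
#' @export
setGeneric("behaviorScores", function(x) standardGeneric("behaviorScores"))

#' @rdname behavior-accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname behavior-accessors
#' @export
setGeneric("getScore", function(x, name) standardGeneric("getScore"))

#' @rdname behavior-accessors
#' @export
setGeneric("scoreNames", function(x) standardGeneric("scoreNames"))

#' Accessors for fitted objects
#'
#' Slot accessors for [ReducedBasis-class], [CCASolution-class],
#' [CVSelection-class], [PermutationResult-class] and
#' [SaliencyResult-class] objects.
#'
#' @param x a fitted object.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' @rdname fit-accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname fit-accessors
#' @export
setGeneric("canonicalCorrelation",
           function(x) standardGeneric("canonicalCorrelation"))

#' @rdname fit-accessors
#' @export
setGeneric("canonicalWeights", function(x) standardGeneric("canonicalWeights"))

#' @rdname fit-accessors
#' @export
setGeneric("variates", function(x) standardGeneric("variates"))

#' @rdname fit-accessors
#' @export
setGeneric("selectedQ", function(x) standardGeneric("selectedQ"))

#' @rdname fit-accessors
#' @export
setGeneric("cvCorrelations", function(x) standardGeneric("cvCorrelations"))

#' @rdname fit-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname fit-accessors
#' @export
setGeneric("nullDistribution", function(x) standardGeneric("nullDistribution"))

#' @rdname fit-accessors
#' @export
setGeneric("bootstrapRatio", function(x) standardGeneric("bootstrapRatio"))

#' @rdname fit-accessors
#' @export
setGeneric("signedMask", function(x) standardGeneric("signedMask"))
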