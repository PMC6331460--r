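#' @include AllClasses.R
NULL

#' Load a skeletonised voxelwise dataset from NIfTI files
#'
#' Reads per-subject skeleton feature images (one 4-D volume or a vector of
#' 3-D volume paths) together with a binary skeleton mask and assembles the
#' N x P subjects-by-voxels matrix. Voxel columns follow the column-major
#' raster order of the mask (first grid index fastest), a pure function of
#' the mask, so repeated loads are bit-identical.
#'
#' When `faThreshold > 0`, mask voxels whose across-subject mean feature
#' value is not strictly above the threshold are dropped (the conventional
#' mean-FA > 0.2 skeleton restriction); the stored mask is shrunk to the
#' surviving voxels so that P always equals the mask count.
#'
#' @param imagePath path to a 4-D NIfTI, or character vector of 3-D NIfTI
#'   paths (one per subject).
#' @param maskPath path to the mask NIfTI (nonzero = in mask).
#' @param faThreshold mean-feature threshold, >= 0; 0 disables filtering.
#'   Default 0.2.
#' @param subjectIds optional subject identifiers; defaults to file base
#'   names for 3-D lists, `S001...` for 4-D input.
#' @return A [SkeletonDataset].
#' @export
loadSkeletonDataset <- function(imagePath, maskPath, faThreshold = 0.2,
                                subjectIds = NULL) {
  if (faThreshold < 0)
    stop("faThreshold must be >= 0", call. = FALSE)
  maskImg <- RNifti::readNifti(maskPath)
  maskArr <- as.array(maskImg)
  if (length(dim(maskArr)) != 3L)
    stop("mask must be a 3-D volume", call. = FALSE)
  mask <- maskArr != 0
  if (length(imagePath) == 1L) {
    img <- as.array(RNifti::readNifti(imagePath))
    if (length(dim(img)) == 3L) dim(img) <- c(dim(img), 1L)
    if (length(dim(img)) != 4L)
      stop("image must be 3-D or 4-D", call. = FALSE)
    if (!identical(dim(img)[1:3], dim(mask)))
      stop("image grid and mask grid differ in shape", call. = FALSE)
    n <- dim(img)[4]
    x <- matrix(0, n, sum(mask))
    for (s in seq_len(n)) x[s, ] <- img[, , , s][mask]
    if (is.null(subjectIds)) subjectIds <- sprintf("S%03d", seq_len(n))
  } else {
    n <- length(imagePath)
    x <- matrix(0, n, sum(mask))
    for (s in seq_len(n)) {
      img <- as.array(RNifti::readNifti(imagePath[s]))
      if (!identical(dim(img), dim(mask)))
        stop("image grid and mask grid differ in shape", call. = FALSE)
      x[s, ] <- img[mask]
    }
    if (is.null(subjectIds))
      subjectIds <- sub("\\.nii(\\.gz)?$", "", basename(imagePath))
  }
  if (!all(is.finite(x)))
    stop("non-finite voxel values in the image data", call. = FALSE)
  if (faThreshold > 0) {
    keep <- colMeans(x) > faThreshold
    if (!any(keep))
      stop("no voxels survive the mean-feature threshold", call. = FALSE)
    coords <- maskCoordinates(mask)[keep, , drop = FALSE]
    mask2 <- array(FALSE, dim(mask))
    mask2[coords] <- TRUE
    mask <- mask2
    x <- x[, keep, drop = FALSE]
  }
  SkeletonDataset(x, mask, subjectIds = subjectIds,
                  reference = RNifti::niftiHeader(maskImg))
}

#' Load a behavioral score table from delimited text
#'
#' Reads a comma- (`.csv`) or tab-delimited (anything else) subject table
#' and extracts named score and covariate columns. Rows with any missing
#' value in a requested column are rejected and their subject ids reported
#' (stored in the `"rejected"` attribute and messaged); there is no
#' imputation. A character gender column is recoded through `genderMap`;
#' labels outside the map are an error.
#'
#' @param tablePath path to the delimited file (header required).
#' @param scoreColumns character vector of score column names.
#' @param covariateColumns character vector of covariate column names
#'   (possibly empty).
#' @param idColumn subject-id column name.
#' @param genderMap named numeric vector mapping gender labels to codes
#'   (default `c(F = 0, M = 1, female = 0, male = 1)`).
#' @return A [BehaviorTable]; rejected ids in `attr(x, "rejected")`.
#' @export
loadBehaviorTable <- function(tablePath, scoreColumns,
                              covariateColumns = character(),
                              idColumn = "subject",
                              genderMap = c(F = 0, M = 1,
                                            female = 0, male = 1)) {
  sep <- if (grepl("\\.csv$", tablePath, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(tablePath, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  need <- c(idColumn, scoreColumns, covariateColumns)
  missing <- setdiff(need, colnames(raw))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (sc in scoreColumns)
    if (!is.numeric(raw[[sc]]) && !all(is.na(raw[[sc]])))
      stop("non-numeric score column: ", sc, call. = FALSE)
  for (cv in covariateColumns) {
    if (is.character(raw[[cv]])) {
      lab <- raw[[cv]]
      bad <- !is.na(lab) & !lab %in% names(genderMap)
      if (any(bad))
        stop("unknown label(s) in column '", cv, "': ",
             paste(unique(lab[bad]), collapse = ", "), call. = FALSE)
      raw[[cv]] <- unname(genderMap[lab])
    }
  }
  used <- raw[, c(scoreColumns, covariateColumns), drop = FALSE]
  bad <- !stats::complete.cases(used)
  rejected <- as.character(raw[[idColumn]][bad])
  if (any(bad)) {
    message("rejected ", sum(bad), " subject(s) with missing values: ",
            paste(rejected, collapse = ", "))
    raw <- raw[!bad, , drop = FALSE]
  }
  if (nrow(raw) == 0L)
    stop("no complete rows in the table", call. = FALSE)
  out <- BehaviorTable(
    as.matrix(raw[, scoreColumns, drop = FALSE]),
    if (length(covariateColumns))
      as.matrix(raw[, covariateColumns, drop = FALSE]) else NULL,
    as.character(raw[[idColumn]]))
  attr(out, "rejected") <- rejected
  out
}

#' Align a dataset and a behavior table on shared subjects
#'
#' Restricts both objects to the intersection of their subject ids, in the
#' (deterministic) order the ids appear in the dataset, and reports how
#' many subjects were dropped from each side. Running the alignment twice
#' is a no-op.
#'
#' @param dataset a [SkeletonDataset].
#' @param table a [BehaviorTable].
#' @return List with the aligned `dataset` and `table`.
#' @export
alignSubjects <- function(dataset, table) {
  idsX <- subjectIds(dataset)
  idsY <- subjectIds(table)
  keep <- idsX[idsX %in% idsY]
  if (length(keep) == 0L)
    stop("no shared subject ids between dataset and table", call. = FALSE)
  dropped <- (length(idsX) - length(keep)) + (length(idsY) - length(keep))
  if (dropped > 0L)
    message("alignSubjects: dropped ", length(idsX) - length(keep),
            " imaging and ", length(idsY) - length(keep),
            " behavioral subject(s)")
  dsOut <- dataset[, match(keep, idsX)]
  ord <- match(keep, idsY)
  tabOut <- BehaviorTable(table@scores[ord, , drop = FALSE],
                          table@covariates[ord, , drop = FALSE],
                          idsY[ord])
  list(dataset = dsOut, table = tabOut)
}

#' Expand a per-voxel statistic into a volume
#'
#' Places a length-P vector into the mask geometry of a dataset, zero
#' outside the mask.
#'
#' @param values numeric length-P vector (mask raster order).
#' @param dataset a [SkeletonDataset] supplying mask and geometry.
#' @param meta provenance list for the resulting [SaliencyVolume].
#' @return A [SaliencyVolume].
#' @export
vectorToVolume <- function(values, dataset, meta = list()) {
  mask <- skeletonMask(dataset)
  if (length(values) != sum(mask))
    stop("value length disagrees with mask count", call. = FALSE)
  vol <- array(0, dim(mask))
  vol[voxelIndex(dataset)] <- values
  if (is.null(meta$reference))
    meta$reference <- S4Vectors::metadata(dataset)$reference
  SaliencyVolume(vol, mask, meta)
}

#' Write a saliency volume to NIfTI
#'
#' Writes the values of a [SaliencyVolume] as a NIfTI volume, copying the
#' affine/header from the reference (mask) image recorded in `meta` when
#' available. The object is validated first, so a continuous map with
#' nonzero values outside the mask (and not marked as display-filled) is an
#' error. Values are stored at double precision; a write/read round trip is
#' exact.
#'
#' @param volume a [SaliencyVolume].
#' @param outPath output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `outPath`.
#' @export
writeSaliency <- function(volume, outPath) {
  validObject(volume)
  ref <- volume@meta$reference
  img <- if (!is.null(ref)) RNifti::asNifti(volume@values, reference = ref)
         else RNifti::asNifti(volume@values)
  RNifti::writeNifti(img, outPath, datatype = "double")
  invisible(outPath)
}
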