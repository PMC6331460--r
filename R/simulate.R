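#' @include AllClasses.R
NULL

## Evaluate expr under a local RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards so the generator never perturbs it.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Random thin skeleton mask: one-voxel-thick axis-aligned sheet patches are
## accumulated until the target voxel count is reached, then thinned back to
## the exact count. Geometry is arbitrary by design; only the mask
## bookkeeping matters to the analysis.
makeSkeletonMask <- function(gridShape, skeletonFraction) {
  target <- max(1L, round(prod(gridShape) * skeletonFraction))
  mask <- array(FALSE, gridShape)
  guard <- 0L
  while (sum(mask) < target && guard < 10000L) {
    guard <- guard + 1L
    ax <- sample.int(3L, 1L)
    slice <- sample.int(gridShape[ax], 1L)
    other <- setdiff(1:3, ax)
    ext <- pmax(1L, round(gridShape[other] *
                            stats::runif(2, 0.3, 0.9)))
    lo <- vapply(seq_along(other), function(m)
      sample.int(gridShape[other[m]] - ext[m] + 1L, 1L), integer(1))
    idx <- vector("list", 3L)
    idx[[ax]] <- slice
    idx[[other[1]]] <- lo[1]:(lo[1] + ext[1] - 1L)
    idx[[other[2]]] <- lo[2]:(lo[2] + ext[2] - 1L)
    mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  }
  extra <- sum(mask) - target
  if (extra > 0L) {
    on <- which(mask)
    mask[sample(on, extra)] <- FALSE
  }
  mask
}

## Separable Gaussian smoothing of a 3-D field (optional spatial
## autocorrelation for the noise); fwhm in voxels.
smoothField <- function(vol, fwhm) {
  if (fwhm <= 0) return(vol)
  sigma <- fwhm / 2.3548
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  convAxis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
    out <- matrix(0, nrow = dm[1], ncol = ncol(m))
    for (t in seq_along(kern))
      out <- out + kern[t] * padded[t:(t + dm[1] - 1L), , drop = FALSE]
    aperm(array(out, dm), order(perm))
  }
  for (ax in 1:3) vol <- convAxis(vol, ax)
  vol
}

#' Generate a synthetic cohort with a planted brain-behavior association
#'
#' Simulates a cohort of N subjects on a random thin skeleton mask with a
#' rank-one latent link between the voxel block and the behavioral score:
#'
#' \deqn{X = s \, z a^\top + E, \qquad
#'       y = \alpha z + \beta_{age} \mathrm{age} +
#'           \beta_{gender} \mathrm{gender} + \epsilon}
#'
#' where `z ~ N(0,1)` is the latent subject variate, `a` is a unit-norm
#' voxel loading supported on `nSalient` voxels with signs set by
#' `fracNegative`, `E` has i.i.d. `N(0, noiseSd^2)` entries and
#' `eps ~ N(0,1)`. The calibration is closed form:
#' `alpha = rho / sqrt(1 - rho^2)` makes the population correlation between
#' `z` and `y` exactly `rho` (confounds at zero), and
#' `s = noiseSd * sqrt(nSalient)` gives every salient voxel a per-voxel
#' signal-to-noise ratio of 1, so the population correlation between the
#' oracle projection `X a` and `z` is `sqrt(nSalient / (nSalient + 1))`
#' (about 0.99 at the default 50 salient voxels) and the best linear
#' readout of `X` attains essentially the target correlation with `y`.
#' Ages are uniform on 65-80 years and gender is Bernoulli(1/2); with
#' nonzero confound coefficients, age and gender enter `y` only.
#'
#' All outputs are pure functions of the configuration (seed included).
#'
#' @param config a [simConfig()] object.
#' @return List with elements `dataset` ([SkeletonDataset]), `table`
#'   ([BehaviorTable] with score column `"score"` and covariates age and
#'   gender), and `truth` ([GroundTruth-class]).
#' @examples
#' cohort <- generateCohort(simConfig(nSubjects = 20, gridShape = c(8, 8, 4),
#'                                    skeletonFraction = 0.4, nSalient = 10,
#'                                    rho = 0.7, seed = 2))
#' cor(cohort$truth@latentScores, getScore(cohort$table, "score"))
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withLocalSeed(config@seed, {
    n <- config@nSubjects
    mask <- makeSkeletonMask(config@gridShape, config@skeletonFraction)
    p <- sum(mask)
    if (config@nSalient > p)
      stop(sprintf("nSalient (%d) exceeds mask size (%d)",
                   config@nSalient, p), call. = FALSE)
    coords <- maskCoordinates(mask)
    nsal <- config@nSalient
    sal <- if (nsal > 0L) sort(sample.int(p, nsal)) else integer(0)
    signs <- numeric(0)
    if (nsal > 0L) {
      nneg <- round(config@fracNegative * nsal)
      signs <- rep(1, nsal)
      if (nneg > 0L) signs[sample.int(nsal, nneg)] <- -1
    }
    a <- numeric(p)
    if (nsal > 0L) a[sal] <- signs / sqrt(nsal)
    z <- stats::rnorm(n)
    noise <- matrix(stats::rnorm(n * p, sd = config@noiseSd), n, p)
    if (config@smoothFwhm > 0) {
      # smooth each subject's noise over the full grid, resample on the mask
      for (s in seq_len(n)) {
        vol <- array(0, config@gridShape)
        vol[mask] <- noise[s, ]
        vol <- smoothField(vol, config@smoothFwhm)
        noise[s, ] <- vol[mask]
      }
    }
    sAmp <- config@noiseSd * sqrt(max(1L, nsal))
    x <- noise
    if (nsal > 0L) x <- x + sAmp * tcrossprod(z, a)
    age <- stats::runif(n, 65, 80)
    gender <- stats::rbinom(n, 1L, 0.5)
    eps <- stats::rnorm(n)
    alpha <- if (config@rho > 0) config@rho / sqrt(1 - config@rho^2) else 0
    y <- alpha * z + config@confoundBetaAge * age +
      config@confoundBetaGender * gender + eps
    ids <- sprintf("S%03d", seq_len(n))
    dataset <- SkeletonDataset(x, mask, coords, ids)
    table <- BehaviorTable(cbind(score = y),
                           cbind(age = age, gender = as.numeric(gender)),
                           ids)
    truth <- new("GroundTruth",
                 salientCoords = coords[sal, , drop = FALSE],
                 salientSigns = signs, latentScores = z,
                 trueRho = config@rho)
    list(dataset = dataset, table = table, truth = truth)
  })
}

#' Generate a null cohort (no brain-behavior association)
#'
#' Identical to [generateCohort()] with `rho = 0` (the latent coefficient
#' on the score is zero), modeling the null hypothesis that no link between
#' imaging and behavior exists. Salient loadings may still be planted in X
#' if `nSalient > 0`; the score is independent of them.
#'
#' @param config a [simConfig()] object; its `rho` is overridden to 0.
#' @return List with `dataset` and `table` (no ground truth).
#' @export
makeNullCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  cfg0 <- config
  cfg0@rho <- 0
  out <- generateCohort(cfg0)
  out["truth"] <- NULL
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes the cohort in the same layout consumed by
#' [loadSkeletonDataset()] and [loadBehaviorTable()]: a 4-D NIfTI image, a
#' mask NIfTI, a CSV subject table (subject, score, age, gender) and,
#' when ground truth is present, a TSV of salient voxel coordinates and
#' signs.
#'
#' @param cohort list as returned by [generateCohort()] or
#'   [makeNullCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- cohort$dataset
  mask <- skeletonMask(dataset)
  x <- faMatrix(dataset)
  vol4 <- array(0, c(dim(mask), nrow(x)))
  for (s in seq_len(nrow(x))) {
    v <- array(0, dim(mask))
    v[mask] <- x[s, ]
    vol4[, , , s] <- v
  }
  imagePath <- file.path(dir, "fa4d.nii.gz")
  maskPath <- file.path(dir, "mask.nii.gz")
  tablePath <- file.path(dir, "subjects.csv")
  RNifti::writeNifti(RNifti::asNifti(vol4), imagePath)
  RNifti::writeNifti(RNifti::asNifti(mask + 0), maskPath)
  tab <- data.frame(subject = subjectIds(dataset),
                    behaviorScores(cohort$table),
                    covariates(cohort$table),
                    check.names = FALSE)
  utils::write.csv(tab, tablePath, row.names = FALSE, quote = FALSE)
  paths <- c(image = imagePath, mask = maskPath, table = tablePath)
  if (!is.null(cohort$truth)) {
    truthPath <- file.path(dir, "ground_truth.tsv")
    gt <- cohort$truth
    utils::write.table(
      data.frame(i = gt@salientCoords[, 1], j = gt@salientCoords[, 2],
                 k = gt@salientCoords[, 3], sign = gt@salientSigns),
      truthPath, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, truth = truthPath)
  }
  invisible(paths)
}
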