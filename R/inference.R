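#' @include AllClasses.R latent.R simulate.R
NULL

#' Leave-one-out selection of the retained dimensionality
#'
#' For every candidate q, each subject is held out in turn: the truncated
#' SVD and the canonical fit are recomputed on the remaining N - 1
#' subjects, the fold solution's global sign is aligned to the full-data
#' solution (via the sign of the inner product of back-projected voxel
#' weights), and the held-out subject's centered feature row is projected
#' through the fold basis and weights to give a held-out imaging variate u,
#' paired with the held-out score variate v (the fold-standardized centered
#' score). The cross-validated correlation at q is the Pearson correlation
#' of the N pooled held-out (u, v) pairs, and the selected Q maximizes it
#' (ties broken toward the smallest q).
#'
#' Internally a single SVD per fold at the largest candidate q serves every
#' q, exploiting the orthogonality of SVD scores (per-component regression
#' coefficients are independent, so weights and projections accumulate over
#' components).
#'
#' @param dataset a [SkeletonDataset] (or an N x P matrix).
#' @param y numeric length-N behavioral score.
#' @param qGrid integer candidates within 1..min(N-2, P); default the full
#'   range.
#' @return A [CVSelection-class].
#' @export
loocvSelectQ <- function(dataset, y, qGrid = NULL) {
  x <- if (is(dataset, "SkeletonDataset")) faMatrix(dataset)
       else as.matrix(dataset)
  n <- nrow(x); p <- ncol(x)
  y <- as.numeric(y)
  if (length(y) != n) stop("y length disagrees with N", call. = FALSE)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (is.null(qGrid)) qGrid <- seq_len(min(n - 2L, p))
  qGrid <- sort(unique(as.integer(qGrid)))
  if (any(qGrid < 1L) || any(qGrid > min(n - 2L, p)))
    stop("qGrid must lie within 1..min(N-2, P)", call. = FALSE)
  qmax <- max(qGrid)

  # full-data reference: cumulative back-projected weights per q
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  yc <- y - mean(y)
  if (sqrt(sum(yc^2)) == 0)
    stop("behavioral score is constant", call. = FALSE)
  svF <- svd(xc, nu = qmax, nv = qmax)
  dF <- svF$d[seq_len(qmax)]
  okF <- dF >= 1e-10 * dF[1]
  betaF <- as.numeric(crossprod(svF$u[, seq_len(qmax), drop = FALSE], yc))
  betaF <- ifelse(okF, betaF / dF, 0)      # coefficient on score column j
  # WFcum[, q] = sum_{j<=q} betaF_j * V_j
  WFcum <- svF$v[, seq_len(qmax), drop = FALSE] %*%
    (upper.tri(matrix(1, qmax, qmax), diag = TRUE) * betaF)

  uHeld <- matrix(0, n, length(qGrid))
  vHeld <- numeric(n)
  for (fold in seq_len(n)) {
    xt <- x[-fold, , drop = FALSE]
    yt <- y[-fold]
    sdY <- stats::sd(yt)
    if (sdY == 0)
      stop(sprintf("constant score after removing subject %d", fold),
           call. = FALSE)
    mut <- colMeans(xt)
    xtc <- sweep(xt, 2L, mut)
    sv <- svd(xtc, nu = qmax, nv = qmax)
    db <- sv$d[seq_len(qmax)]
    ok <- db >= 1e-10 * db[1]
    ytc <- yt - mean(yt)
    betaB <- as.numeric(crossprod(sv$u[, seq_len(qmax), drop = FALSE], ytc))
    betaB <- ifelse(ok, betaB / db, 0)
    xo <- x[fold, ] - mut
    pj <- as.numeric(crossprod(sv$v[, seq_len(qmax), drop = FALSE], xo))
    rawU <- cumsum(betaB * pj)
    s2 <- cumsum((betaB * db)^2)          # ||fitted||^2 at each q
    sdFit <- sqrt(s2 / (n - 2L))
    # running fold weight vector and its inner product with the reference
    wb <- numeric(p)
    dotRef <- numeric(qmax)
    Vb <- sv$v
    for (qi in seq_len(qmax)) {
      wb <- wb + betaB[qi] * Vb[, qi]
      dotRef[qi] <- sum(wb * WFcum[, qi])
    }
    flip <- ifelse(dotRef < 0, -1, 1)
    uq <- ifelse(sdFit > 0, flip * rawU / sdFit, 0)
    uHeld[fold, ] <- uq[qGrid]
    vHeld[fold] <- (y[fold] - mean(yt)) / sdY
  }
  cvr <- vapply(seq_along(qGrid), function(m) {
    u <- uHeld[, m]
    if (stats::sd(u) == 0 || stats::sd(vHeld) == 0) return(0)
    stats::cor(u, vHeld)
  }, numeric(1))
  names(cvr) <- qGrid
  best <- qGrid[cvr == max(cvr)]
  new("CVSelection", cvCorrelations = cvr, selectedQ = as.integer(min(best)),
      nFolds = as.integer(n))
}

#' Permutation test of the canonical correlation
#'
#' Tests the observed canonical correlation at a fixed dimensionality q
#' against the null distribution obtained by permuting the behavioral
#' score. The reduced basis is computed once from the unpermuted feature
#' matrix (permuting the score leaves the feature block unchanged) and each
#' permutation refits the canonical pair on the same reduced scores. The
#' p-value uses the add-one estimator
#' `(1 + count of null at or above observed) / (1 + nPerm)`, so it is
#' never zero.
#'
#' @param dataset a [SkeletonDataset] or N x P matrix.
#' @param y numeric length-N behavioral score.
#' @param q retained dimensionality (selected on unpermuted data).
#' @param nPerm number of permutations (>= 99; default 10000).
#' @param seed RNG seed for the permutations.
#' @return A [PermutationResult-class].
#' @export
permutationTest <- function(dataset, y, q, nPerm = 10000L, seed = 1L) {
  x <- if (is(dataset, "SkeletonDataset")) faMatrix(dataset)
       else as.matrix(dataset)
  y <- as.numeric(y)
  n <- nrow(x)
  nPerm <- as.integer(nPerm)
  if (nPerm < 99L) stop("nPerm must be at least 99", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("behavioral score is constant", call. = FALSE)
  fit <- fitTruncatedSVD(x, q)
  obs <- fitCCASingle(fit$scores, y)@correlation
  u0 <- sweep(fit$scores, 2L, fit$basis@singularValues, "/") # orthonormal
  yc <- y - mean(y)
  nullRs <- withLocalSeed(seed, {
    ym <- vapply(seq_len(nPerm), function(b) yc[sample.int(n)],
                 numeric(n))
    num <- crossprod(u0, ym)                    # q x nPerm
    sqrt(colSums(num^2) / sum(yc^2))
  })
  nullRs <- pmin(1, pmax(0, nullRs))
  p <- (1 + sum(nullRs >= obs)) / (1 + nPerm)
  new("PermutationResult", observedR = obs, nullRs = as.numeric(nullRs),
      pValue = p, nPerm = nPerm, seed = as.integer(seed))
}

#' Bootstrap saliency mapping with Procrustes-aligned components
#'
#' Resamples subjects with replacement into B folds. Each fold's centered
#' feature matrix is decomposed by truncated SVD, its components are
#' aligned to the full-data components by orthogonal Procrustes rotation
#' (rotations and reflections), the canonical pair is refit on the aligned
#' fold scores against the resampled score, the fold's canonical weights
#' are back-projected to voxel space, and the fold solution's global sign
#' is flipped when its voxel weights correlate negatively with the
#' full-data reference weights. The per-voxel bootstrap ratio is the mean
#' of the B back-projected weights divided by their standard deviation
#' (N - 1 denominator); the signed suprathreshold mask keeps
#' `sign(ratio)` wherever `|ratio| >= threshold`.
#'
#' Folds whose resampled score is constant (or whose feature matrix loses
#' rank below q) are redrawn, up to 100 redraws. Voxels whose weight
#' distribution has zero variance get the sentinel `sign(mean) * Inf`
#' (0 if the mean is 0) and are flagged.
#'
#' @param dataset a [SkeletonDataset] or N x P matrix.
#' @param y numeric length-N behavioral score.
#' @param q retained dimensionality.
#' @param bFolds number of bootstrap folds (>= 10; default 1000).
#' @param threshold bootstrap-ratio threshold (default 1.96, the two-sided
#'   5 percent normal critical value).
#' @param seed RNG seed for the resampling.
#' @return A [SaliencyResult-class].
#' @export
bootstrapSaliency <- function(dataset, y, q, bFolds = 1000L,
                              threshold = 1.96, seed = 1L) {
  x <- if (is(dataset, "SkeletonDataset")) faMatrix(dataset)
       else as.matrix(dataset)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  bFolds <- as.integer(bFolds)
  if (bFolds < 10L) stop("bFolds must be at least 10", call. = FALSE)
  full <- fitTruncatedSVD(x, q)
  q <- full$basis@q
  vF <- full$basis@components
  ccaRef <- fitCCASingle(full$scores, y)
  wRef <- backproject(ccaRef, full$basis)
  out <- withLocalSeed(seed, {
    w <- matrix(0, bFolds, p)
    rb <- numeric(bFolds)
    redraws <- 0L
    for (b in seq_len(bFolds)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- y[idx]
        if (stats::sd(yb) > 0) {
          xbc <- sweep(x[idx, , drop = FALSE], 2L, colMeans(x[idx, ,
                                                              drop = FALSE]))
          sv <- svd(xbc, nu = q, nv = q)
          if (sv$d[q] >= 1e-10 * sv$d[1]) break
        }
        redraws <- redraws + 1L
        if (redraws > 100L)
          stop("too many degenerate bootstrap resamples", call. = FALSE)
      }
      pr <- procrustesAlign(sv$v[, seq_len(q), drop = FALSE], vF)
      scoresA <- sweep(sv$u[, seq_len(q), drop = FALSE], 2L,
                       sv$d[seq_len(q)], "*") %*% pr$rotation
      cca <- fitCCASingle(scoresA, yb)
      wb <- drop(pr$aligned %*% cca@weightsX)
      if (stats::sd(wb) > 0 && stats::sd(wRef) > 0 &&
          stats::cor(wb, wRef) < 0)
        wb <- -wb
      w[b, ] <- wb
      rb[b] <- cca@correlation
    }
    list(w = w, rb = rb, redraws = redraws)
  })
  m <- colMeans(out$w)
  sdv <- sqrt(colSums(sweep(out$w, 2L, m)^2) / (bFolds - 1L))
  degenerate <- which(sdv == 0)
  ratio <- ifelse(sdv > 0, m / sdv, sign(m) * Inf)
  ratio[sdv == 0 & m == 0] <- 0
  mask <- sign(ratio) * (abs(ratio) >= threshold)
  if (length(degenerate))
    warning(sprintf("%d voxel(s) with zero-variance weight distribution",
                    length(degenerate)))
  if (out$redraws > 0L)
    message("bootstrapSaliency: redrew ", out$redraws,
            " degenerate resample(s)")
  new("SaliencyResult", weightDistribution = out$w, ratio = ratio,
      signedMask = as.numeric(mask), threshold = threshold,
      bFolds = bFolds, referenceWeights = wRef, bootstrapR = out$rb,
      redraws = out$redraws, degenerateVoxels = as.integer(degenerate))
}

#' Thicken a signed suprathreshold mask for display
#'
#' Dilates each suprathreshold voxel's sign into neighboring voxels within
#' a Chebyshev radius wherever the mean feature value exceeds 0.2,
#' emulating the tract-thickening fill used when rendering skeleton
#' statistics. Analysis values are untouched: the output is display-only
#' and marked as such in its metadata. A fill voxel reached by both signs
#' takes the sign of the summed contributions (exact ties stay 0);
#' suprathreshold voxels always keep their own sign.
#'
#' @param volume a signed [SaliencyVolume] (values in -1/0/+1).
#' @param meanFa 3-D numeric array of mean feature values on the same grid.
#' @param radius non-negative integer Chebyshev radius; 0 returns the input
#'   unchanged (marked display-only).
#' @return A display-only [SaliencyVolume].
#' @export
fillForDisplay <- function(volume, meanFa, radius = 1L) {
  stopifnot(is(volume, "SaliencyVolume"))
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0", call. = FALSE)
  vals <- volume@values
  d <- dim(vals)
  if (!identical(dim(meanFa), d))
    stop("meanFa grid differs from the volume grid", call. = FALSE)
  meta <- volume@meta
  meta$filled <- TRUE
  meta$kind <- "signed"
  if (radius == 0L)
    return(SaliencyVolume(vals, volume@mask, meta))
  acc <- array(0, d)
  off <- -radius:radius
  for (dx in off) for (dy in off) for (dz in off) {
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    acc[sx, sy, sz] <- acc[sx, sy, sz] +
      vals[sx - dx, sy - dy, sz - dz]
  }
  out <- vals
  cand <- vals == 0 & meanFa > 0.2 & acc != 0
  out[cand] <- sign(acc)[cand]
  SaliencyVolume(out, volume@mask, meta)
}

#' Run the full inference chain for one score
#'
#' Convenience wrapper chaining leave-one-out dimensionality selection, the
#' full-data canonical fit, the permutation test and (optionally) the
#' bootstrap saliency map. Derived seeds: permutations use `seed`,
#' the bootstrap uses `seed + 1`.
#'
#' @param dataset a [SkeletonDataset] or N x P matrix.
#' @param y numeric length-N behavioral score.
#' @param qGrid candidate dimensionalities (default full 1..N-2 range).
#' @param nPerm permutations (default 10000).
#' @param bFolds bootstrap folds (default 1000).
#' @param threshold bootstrap-ratio threshold (default 1.96).
#' @param seed RNG seed.
#' @param doBootstrap set `FALSE` to skip the saliency step.
#' @return List with `cv` ([CVSelection-class]), `cca`
#'   ([CCASolution-class]), `permutation` ([PermutationResult-class]),
#'   `saliency` ([SaliencyResult-class] or `NULL`) and `q`.
#' @export
analyzeScore <- function(dataset, y, qGrid = NULL, nPerm = 10000L,
                         bFolds = 1000L, threshold = 1.96, seed = 1L,
                         doBootstrap = TRUE) {
  cv <- loocvSelectQ(dataset, y, qGrid)
  q <- selectedQ(cv)
  x <- if (is(dataset, "SkeletonDataset")) faMatrix(dataset)
       else as.matrix(dataset)
  fit <- fitTruncatedSVD(x, q)
  cca <- fitCCASingle(fit$scores, y)
  perm <- permutationTest(x, y, q, nPerm = nPerm, seed = seed)
  sal <- if (doBootstrap)
    bootstrapSaliency(x, y, q, bFolds = bFolds, threshold = threshold,
                      seed = seed + 1L) else NULL
  list(cv = cv, cca = cca, permutation = perm, saliency = sal, q = q)
}

#' Unadjusted and covariate-adjusted analyses of one score
#'
#' Runs the full chain twice: once on the raw feature matrix and score,
#' and once after residualizing both blocks on the table's covariates
#' (age and gender co-regression). Both arms use the same seeds, so they
#' differ only by the adjustment.
#'
#' @param dataset a [SkeletonDataset].
#' @param table a [BehaviorTable] carrying the score and covariates.
#' @param scoreName score column to analyze.
#' @param which "both" (default), "unadjusted" or "adjusted".
#' @inheritParams analyzeScore
#' @return Named list with elements `unadjusted` and/or `adjusted`, each as
#'   returned by [analyzeScore()].
#' @export
adjustedAndUnadjusted <- function(dataset, table, scoreName,
                                  which = c("both", "unadjusted",
                                            "adjusted"),
                                  qGrid = NULL, nPerm = 10000L,
                                  bFolds = 1000L, threshold = 1.96,
                                  seed = 1L, doBootstrap = TRUE) {
  which <- match.arg(which)
  y <- getScore(table, scoreName)
  out <- list()
  if (which %in% c("both", "unadjusted"))
    out$unadjusted <- analyzeScore(dataset, y, qGrid = qGrid,
                                   nPerm = nPerm, bFolds = bFolds,
                                   threshold = threshold, seed = seed,
                                   doBootstrap = doBootstrap)
  if (which %in% c("both", "adjusted")) {
    cov <- covariates(table)
    if (ncol(cov) == 0L)
      stop("adjustment requested but the table has no covariates",
           call. = FALSE)
    xr <- residualize(faMatrix(dataset), cov)
    yr <- residualize(y, cov)
    dsr <- SkeletonDataset(xr, skeletonMask(dataset),
                           voxelIndex(dataset), subjectIds(dataset))
    out$adjusted <- analyzeScore(dsr, yr, qGrid = qGrid, nPerm = nPerm,
                                 bFolds = bFolds, threshold = threshold,
                                 seed = seed, doBootstrap = doBootstrap)
  }
  out
}
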