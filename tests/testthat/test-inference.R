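test_that("leave-one-out selection finds the rank of a noise-free signal", {
  set.seed(41)
  z <- rnorm(30); a <- rnorm(50); a <- a / sqrt(sum(a^2))
  x <- z %o% a                       # exact rank 1
  suppressWarnings(cv <- loocvSelectQ(x, z + rnorm(30, sd = 1e-8), 1:5))
  expect_equal(selectedQ(cv), 1L)
  expect_gt(max(cvCorrelations(cv)), 0.99)

  # null data: the selection is still well-defined (argmax, ties smallest)
  xn <- matrix(rnorm(30 * 50), 30, 50)
  cvn <- loocvSelectQ(xn, rnorm(30), 1:5)
  expect_true(selectedQ(cvn) %in% 1:5)
  expect_lt(max(cvCorrelations(cvn)), 0.6)
  best <- as.integer(names(which(cvCorrelations(cvn) ==
                                   max(cvCorrelations(cvn)))))
  expect_equal(selectedQ(cvn), min(best))
})

test_that("cross-validated correlation tracks the generator oracle for a
          multi-spike signal", {
  # rho = 0.6 signal spread over 3 orthogonal spikes; the averaged CV curve
  # peaks at small q and its peak is near the oracle latent correlation
  set.seed(43)
  nrep <- 10; n <- 120; p <- 150
  curves <- matrix(0, nrep, 8)
  oracle <- numeric(nrep)
  for (i in 1:nrep) {
    zs <- matrix(rnorm(n * 3), n, 3)
    as <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
    x <- zs %*% t(as) * sqrt(p / 3) + matrix(rnorm(n * p), n, p)
    lat <- rowMeans(zs)
    y <- 0.6 / sqrt(1 - 0.36) * lat * sqrt(3) + rnorm(n)
    oracle[i] <- cor(lat, y)
    curves[i, ] <- cvCorrelations(loocvSelectQ(x, y, 1:8))
  }
  avg <- colMeans(curves)
  expect_lte(which.max(avg), 5L)
  expect_lt(abs(max(avg) - mean(oracle)), 0.15)
})

test_that("permutation p-values follow the add-one estimator and are
          reproducible", {
  co <- smallCohort(seed = 51, n = 40, rho = 0.7)
  y <- getScore(co$table, "score")
  pt <- permutationTest(co$dataset, y, 2, nPerm = 99, seed = 7)
  # add-one formula holds exactly
  expect_equal(pValue(pt),
               (1 + sum(nullDistribution(pt) >= canonicalCorrelation(pt))) /
                 (1 + 99))
  expect_gt(pValue(pt), 0)
  expect_lte(pValue(pt), 1)
  # observed beats every permutation here -> minimal attainable p
  expect_equal(pValue(pt), 1 / 100)

  # bit-exact reproducibility from the seed
  pt2 <- permutationTest(co$dataset, y, 2, nPerm = 99, seed = 7)
  expect_identical(nullDistribution(pt), nullDistribution(pt2))
  expect_identical(pValue(pt), pValue(pt2))

  # a score that the data cannot beat gives p = 1 when every null r wins:
  # use an anti-signal y orthogonal to the voxel block's top components
  # (observed r near 0 and many null r's above it -> p near 1, never > 1)
  ptn <- permutationTest(co$dataset, rnorm(40), 2, nPerm = 99, seed = 8)
  expect_lte(pValue(ptn), 1)

  # the vectorized null refits agree with explicit CCA refits
  x <- faMatrix(co$dataset)
  f <- fitTruncatedSVD(x, 2)
  set.seed(7)  # same stream as permutationTest's local seed
  yc <- y - mean(y)
  perms <- vapply(1:99, function(b) yc[sample.int(40)], numeric(40))
  explicit <- vapply(1:5, function(b)
    fitCCASingle(f$scores, perms[, b])@correlation, numeric(1))
  expect_equal(nullDistribution(pt)[1:5], explicit, tolerance = 1e-10)
})

test_that("bootstrap saliency aligns, sign-corrects, and thresholds", {
  co <- smallCohort(seed = 61, n = 60, rho = 0.7, nSalient = 20,
                    grid = c(8, 8, 4), fraction = 0.6)
  y <- getScore(co$table, "score")
  sal <- bootstrapSaliency(co$dataset, y, 2, bFolds = 120, seed = 9)

  # ratio is fold mean over fold SD (N-1 denominator)
  w <- sal@weightDistribution
  m <- colMeans(w); s <- apply(w, 2, sd)
  finite <- s > 0
  expect_equal(bootstrapRatio(sal)[finite], (m / s)[finite],
               tolerance = 1e-12)

  # sign correction: every fold's weights correlate non-negatively with
  # the reference, hence so does the mean weight vector
  cors <- apply(w, 1, function(wi)
    if (sd(wi) > 0) cor(wi, sal@referenceWeights) else 0)
  expect_true(all(cors >= 0))
  expect_gte(cor(m, sal@referenceWeights), 0)

  # signed mask encodes sign and threshold; raising the threshold can
  # only remove voxels
  sm <- signedMask(sal)
  expect_true(all(sm %in% c(-1, 0, 1)))
  expect_equal(sm, sign(bootstrapRatio(sal)) *
                 (abs(bootstrapRatio(sal)) >= sal@threshold),
               ignore_attr = TRUE)
  salHi <- bootstrapSaliency(co$dataset, y, 2, bFolds = 120,
                             threshold = 3, seed = 9)
  expect_true(all(which(signedMask(salHi) != 0) %in% which(sm != 0)))

  # determinism
  sal2 <- bootstrapSaliency(co$dataset, y, 2, bFolds = 120, seed = 9)
  expect_identical(bootstrapRatio(sal), bootstrapRatio(sal2))

  # planted salient voxels rank high and carry the planted sign
  sel <- salientColumns(co)
  lab <- seq_len(nVoxels(co$dataset)) %in% sel
  expect_gt(aucRank(abs(bootstrapRatio(sal)), lab), 0.8)
  hit <- lab & sm != 0
  if (any(hit)) {
    planted <- co$truth@salientSigns[match(which(hit), sel)]
    expect_gt(mean(sm[hit] == planted), 0.9)
  }
})

test_that("display fill dilates signs through high-FA neighbors only", {
  mask <- array(TRUE, c(7, 7, 7))
  vals <- array(0, c(7, 7, 7)); vals[4, 4, 4] <- 1
  vol <- SaliencyVolume(vals, mask, list(kind = "signed"))

  # radius 0 returns the input values untouched (marked display-only)
  f0 <- fillForDisplay(vol, array(0.5, c(7, 7, 7)), 0)
  expect_identical(f0@values, vals)
  expect_true(f0@meta$filled)

  # radius 1 with uniformly high mean FA: a full 27-voxel cube
  f1 <- fillForDisplay(vol, array(0.5, c(7, 7, 7)), 1)
  expect_equal(sum(f1@values == 1), 27)
  expect_true(all(which(f1@values == 1, arr.ind = TRUE) %in% 3:5))

  # a low-FA neighbor is never filled
  fa <- array(0.5, c(7, 7, 7)); fa[3, 4, 4] <- 0.1
  f2 <- fillForDisplay(vol, fa, 1)
  expect_equal(f2@values[3, 4, 4], 0)
  expect_equal(sum(f2@values == 1), 26)

  # opposite signs: fill resolves by the summed sign, ties stay zero
  vals2 <- array(0, c(7, 7, 7)); vals2[3, 4, 4] <- 1; vals2[5, 4, 4] <- -1
  f3 <- fillForDisplay(SaliencyVolume(vals2, mask, list(kind = "signed")),
                       array(0.5, c(7, 7, 7)), 1)
  expect_equal(f3@values[4, 4, 4], 0)      # reached by +1 and -1 equally
  expect_equal(f3@values[3, 4, 4], 1)      # originals keep their sign
  expect_equal(f3@values[5, 4, 4], -1)
})

test_that("covariate adjustment flattens a pure age effect", {
  # y is driven by age alone; the adjusted analysis must not call the
  # association significant (10 seeded replicates, allow one false alarm)
  sig <- 0L
  for (i in 1:10) {
    cfg <- simConfig(nSubjects = 40, gridShape = c(6, 6, 3),
                     skeletonFraction = 0.5, nSalient = 10, rho = 0,
                     confoundBetaAge = 0.5, seed = 700 + i)
    co <- generateCohort(cfg)
    res <- adjustedAndUnadjusted(co$dataset, co$table, "score",
                                 which = "adjusted", qGrid = 1:5,
                                 nPerm = 99, seed = 800 + i,
                                 doBootstrap = FALSE)
    sig <- sig + (pValue(res$adjusted$permutation) <= 0.05)
  }
  expect_lte(sig, 1L)

  # with no confounding, adjusted and unadjusted fits agree closely
  co <- smallCohort(seed = 71, n = 100, rho = 0.7, nSalient = 20)
  both <- adjustedAndUnadjusted(co$dataset, co$table, "score",
                                qGrid = 1:5, nPerm = 99, seed = 72,
                                doBootstrap = FALSE)
  expect_lt(abs(canonicalCorrelation(both$unadjusted$cca) -
                  canonicalCorrelation(both$adjusted$cca)), 0.05)

  # adjustment without covariates is a schema error
  bt <- BehaviorTable(cbind(score = getScore(co$table, "score")),
                      subjectIds = subjectIds(co$table))
  expect_error(adjustedAndUnadjusted(co$dataset, bt, "score",
                                     which = "adjusted", qGrid = 1:3,
                                     nPerm = 99),
               "no covariates")
})
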