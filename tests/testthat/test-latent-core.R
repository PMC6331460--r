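test_that("residualize matches an explicit normal-equations oracle", {
  # perfect fit: a column proportional to a covariate residualizes to zero
  age <- c(66, 70, 74, 78)
  expect_lt(max(abs(residualize(2 * age, cbind(age)))), 1e-10)

  # covariate orthogonal to a centered column leaves it unchanged
  colv <- c(1, -1, 1, -1)
  covar <- c(1, 1, -1, -1)            # orthogonal to colv and to intercept
  expect_lt(max(abs(residualize(colv, cbind(covar)) - colv)), 1e-10)

  # explicit normal-equations oracle on the 4x1 system
  block <- matrix(c(1, 2, 3, 4), ncol = 1)
  covar <- matrix(c(1, 1, 2, 2), ncol = 1)
  x <- cbind(1, covar)
  oracle <- block - x %*% solve(t(x) %*% x, t(x) %*% block)
  expect_lt(max(abs(residualize(block, covar) - oracle)), 1e-10)

  # residuals orthogonal to intercept and covariates on random instances
  set.seed(7)
  for (i in 1:10) {
    b <- matrix(rnorm(30 * 4), 30, 4)
    cv <- matrix(rnorm(30 * 2), 30, 2)
    r <- residualize(b, cv)
    expect_lt(max(abs(colSums(r))), 1e-8)
    expect_lt(max(abs(crossprod(cv, r))), 1e-8)
  }

  expect_error(residualize(matrix(rnorm(8), 4), cbind(c(1, 2, 3, 4),
                                                      c(2, 4, 6, 8))),
               "rank deficient")
})

test_that("truncated SVD reproduces the full-decomposition oracle", {
  set.seed(11)
  # full rank: reconstruction error vanishes
  x <- matrix(rnorm(6 * 4), 6, 4)
  f <- fitTruncatedSVD(x, 4)
  xc <- sweep(x, 2, colMeans(x))
  rec <- f$scores %*% t(components(f$basis))
  expect_lt(max(abs(rec - xc)), 1e-8)

  # exact rank 1: second singular value is numerically null relative to first
  z <- rnorm(9); a <- rnorm(12)
  sv <- svd(sweep(z %o% a, 2, colMeans(z %o% a)))
  expect_lt(sv$d[2], 1e-10 * sv$d[1])
  expect_warning(f1 <- fitTruncatedSVD(z %o% a, 3), "near-null")
  expect_equal(f1$basis@q, 1L)

  # discarded-energy identity against a full SVD oracle
  x <- matrix(rnorm(8 * 20), 8, 20)
  f <- fitTruncatedSVD(x, 3)
  xc <- sweep(x, 2, colMeans(x))
  dFull <- svd(xc)$d
  err <- sum((xc - f$scores %*% t(components(f$basis)))^2)
  expect_lt(abs(err - sum(dFull[-(1:3)]^2)), 1e-8)

  # orthonormality and score identity
  expect_lt(max(abs(crossprod(components(f$basis)) - diag(3))), 1e-10)
  expect_lt(max(abs(f$scores - xc %*% components(f$basis))), 1e-8)

  expect_error(fitTruncatedSVD(x, 0), "q must lie")
  expect_error(fitTruncatedSVD(x, 8), "q must lie")
})

test_that("Procrustes alignment recovers a planted orthogonal transform", {
  set.seed(5)
  v <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))

  # source equal to reference: identity rotation
  out <- procrustesAlign(v, v)
  expect_lt(max(abs(out$rotation - diag(4))), 1e-10)

  # column swap: the recovered rotation is that permutation matrix
  perm <- c(2, 1, 3, 4)
  out <- procrustesAlign(v[, perm], v)
  pmat <- diag(4)[perm, ]
  expect_lt(max(abs(out$rotation - pmat)), 1e-10)

  # random orthogonal transform (QR of a seeded Gaussian): recover G^T
  for (i in 1:20) {
    g <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    out <- procrustesAlign(v %*% g, v)
    expect_lt(max(abs(out$rotation - t(g))), 1e-8)
    expect_lt(max(abs(out$aligned - v)), 1e-8)
    # rotation is orthogonal, alignment never increases the distance
    expect_lt(max(abs(crossprod(out$rotation) - diag(4))), 1e-10)
    dBefore <- norm(v %*% g - v, "F")
    dAfter <- norm(out$aligned - v, "F")
    expect_lte(dAfter, dBefore + 1e-12)
  }

  expect_error(procrustesAlign(v[, 1:3], v), "shape")
  expect_error(procrustesAlign(matrix(rnorm(120), 30), v), "orthonormal")
})

test_that("single-pair CCA equals the multiple correlation of an OLS fit", {
  # worked 4x2 micro-system: R = 2/sqrt(5)
  s <- cbind(c(1, 0, -1, 0), c(0, 1, 0, -1))
  y <- c(1, 2, -1, 0)
  sol <- fitCCASingle(s, y)
  expect_equal(canonicalCorrelation(sol), 2 / sqrt(5), tolerance = 1e-12)

  # perfect association: a score column proportional to centered y
  y2 <- c(3, 1, 4, 1, 5, 9)
  s2 <- cbind(2 * (y2 - mean(y2)))
  expect_equal(fitCCASingle(s2, y2)@correlation, 1, tolerance = 1e-10)

  # y orthogonal to both score columns after centering: R = 0
  yOrth <- c(1, 2, 1, 2)
  expect_lt(fitCCASingle(s, yOrth)@correlation, 1e-10)

  # property loop: oracle equivalence, invariances, bounds, variate identity
  set.seed(13)
  for (i in 1:30) {
    n <- sample(8:40, 1); q <- sample(1:5, 1)
    sc <- matrix(rnorm(n * q), n, q)
    yy <- rnorm(n)
    sol <- fitCCASingle(sc, yy)
    r2 <- summary(lm(yy ~ sc))$r.squared
    expect_equal(sol@correlation, sqrt(r2), tolerance = 1e-8)
    expect_gte(sol@correlation, 0)
    expect_lte(sol@correlation, 1)
    expect_gt(sol@weightY, 0)
    expect_equal(cor(sol@variateX, sol@variateY), sol@correlation,
                 tolerance = 1e-10)
    # affine change of y and orthogonal rotation of scores leave R unchanged
    solAff <- fitCCASingle(sc, -2.5 * yy + 3)
    expect_equal(solAff@correlation, sol@correlation, tolerance = 1e-10)
    g <- qr.Q(qr(matrix(rnorm(q * q), q, q)))
    solRot <- fitCCASingle(sc %*% g, yy)
    expect_equal(solRot@correlation, sol@correlation, tolerance = 1e-10)
  }

  expect_error(fitCCASingle(s, rep(1, 4)), "constant")
  expect_error(fitCCASingle(cbind(1:6, 2 * (1:6)), rnorm(6)), "collinear")
})

test_that("back-projection reproduces the canonical variate in voxel space", {
  set.seed(17)
  x <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  f <- fitTruncatedSVD(x, 4)
  sol <- fitCCASingle(f$scores, y)

  # unit weight vector picks out one component column
  e1 <- c(1, 0, 0, 0)
  expect_equal(backproject(e1, f$basis), components(f$basis)[, 1])
  expect_equal(backproject(rep(0, 4), f$basis), rep(0, 40))

  # self-consistency: X_c w reproduces the imaging variate and R
  w <- backproject(sol, f$basis)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(cor(drop(xc %*% w), y), sol@correlation, tolerance = 1e-8)
  expect_error(backproject(c(1, 2), f$basis), "disagree")
})
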