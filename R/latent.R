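#' @include AllClasses.R
NULL

#' Residualize a data block on covariates
#'
#' Replaces each column of `block` by its least-squares residual after
#' regression on an intercept plus the given covariates. Used to produce
#' the age- and gender-adjusted arm of the analysis.
#'
#' @param block numeric matrix N x M (or a length-N vector).
#' @param covariates numeric matrix N x C.
#' @return Matrix (or vector, matching the input) of residuals, orthogonal
#'   to the intercept and to every covariate column.
#' @examples
#' age <- c(66, 70, 74, 78)
#' residualize(2 * age, cbind(age = age))   # numerically zero
#' @export
residualize <- function(block, covariates) {
  vec <- is.null(dim(block))
  block <- as.matrix(block)
  covariates <- as.matrix(covariates)
  n <- nrow(block)
  if (nrow(covariates) != n)
    stop("block and covariates disagree on N", call. = FALSE)
  x <- cbind(intercept = rep(1, n), covariates)
  if (n <= ncol(x))
    stop("need N > C + 1 for residualization", call. = FALSE)
  qx <- qr(x)
  if (qx$rank < ncol(x))
    stop("covariates are rank deficient after adding an intercept",
         call. = FALSE)
  res <- qr.resid(qx, block)
  if (vec) drop(res) else res
}

#' Truncated singular value decomposition of a feature matrix
#'
#' Column-centers the matrix and retains the leading `q` singular triplets.
#' The scores (left singular vectors scaled by their singular values) are
#' the reduced representation handed to the canonical correlation fit;
#' their columns are mutually orthogonal. Singular values smaller than
#' `1e-10` times the largest are dropped with a warning rather than kept
#' (they would be inverted downstream).
#'
#' @param x numeric matrix N x P.
#' @param q number of components, 1 <= q <= min(N - 1, P).
#' @return A list with `basis` (a [ReducedBasis-class]) and `scores`
#'   (N x q matrix, equal to the centered matrix times the components).
#' @examples
#' x <- matrix(rnorm(40), 8, 5)
#' fit <- fitTruncatedSVD(x, 2)
#' crossprod(components(fit$basis))  # identity
#' @export
fitTruncatedSVD <- function(x, q) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (!all(is.finite(x)))
    stop("non-finite values in the feature matrix", call. = FALSE)
  q <- as.integer(q)
  if (length(q) != 1L || is.na(q) || q < 1L || q > min(n - 1L, p))
    stop(sprintf("q must lie in 1..min(N-1, P) = 1..%d", min(n - 1L, p)),
         call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = q, nv = q)
  d <- sv$d[seq_len(q)]
  keep <- d >= 1e-10 * sv$d[1]
  if (!all(keep)) {
    warning(sprintf("dropping %d near-null component(s)", sum(!keep)))
    q <- sum(keep)
    d <- d[seq_len(q)]
  }
  v <- sv$v[, seq_len(q), drop = FALSE]
  scores <- sweep(sv$u[, seq_len(q), drop = FALSE], 2L, d, "*")
  basis <- new("ReducedBasis", components = v, singularValues = d,
               columnMeans = mu, q = q)
  list(basis = basis, scores = scores)
}

#' Orthogonal Procrustes alignment of component bases
#'
#' Finds the orthogonal matrix (rotations and reflections) that best maps
#' `source` onto `reference` in the Frobenius norm, and applies it. Used to
#' make SVD components comparable across bootstrap folds, whose components
#' are rotated and reflected versions of the full-data ones.
#'
#' @param source,reference P x Q matrices with orthonormal columns.
#' @return List with `rotation` (Q x Q orthogonal) and
#'   `aligned` (= `source %*% rotation`).
#' @examples
#' v <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
#' g <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
#' out <- procrustesAlign(v %*% g, v)
#' max(abs(out$aligned - v))  # ~ 0
#' @export
procrustesAlign <- function(source, reference) {
  source <- as.matrix(source); reference <- as.matrix(reference)
  if (!identical(dim(source), dim(reference)))
    stop("source and reference differ in shape", call. = FALSE)
  q <- ncol(source)
  if (max(abs(crossprod(source) - diag(q))) > 1e-8 ||
      max(abs(crossprod(reference) - diag(q))) > 1e-8)
    stop("inputs must have orthonormal columns", call. = FALSE)
  sv <- svd(crossprod(source, reference))
  rotation <- sv$u %*% t(sv$v)
  list(rotation = rotation, aligned = source %*% rotation)
}

#' Single-pair canonical correlation of reduced scores against one score
#'
#' With a one-column behavioral block, canonical correlation analysis
#' degenerates to the multiple correlation of the score on the reduced
#' imaging scores: the imaging weights E are proportional to the OLS
#' coefficients, and R is the square root of the coefficient of
#' determination. The fit keeps exactly one canonical pair and fixes the
#' sign convention `weightY > 0`, so `correlation` is always between 0
#' and 1.
#'
#' Variates are scaled to unit standard deviation (when non-degenerate):
#' `variateX = scores_centered %*% weightsX`,
#' `variateY = weightY * (y - mean(y))`.
#'
#' @param scores numeric matrix N x Q of reduced imaging scores (full
#'   column rank).
#' @param y numeric length-N behavioral score with nonzero variance.
#' @return A [CCASolution-class].
#' @examples
#' s <- cbind(c(1, 0, -1, 0), c(0, 1, 0, -1))
#' fitCCASingle(s, c(1, 2, -1, 0))  # R = 2/sqrt(5)
#' @export
fitCCASingle <- function(scores, y) {
  scores <- as.matrix(scores)
  y <- as.numeric(y)
  n <- nrow(scores); q <- ncol(scores)
  if (length(y) != n)
    stop("scores and y disagree on N", call. = FALSE)
  if (n <= q + 1L)
    stop("need N > Q + 1", call. = FALSE)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2) / (n - 1))
  if (sy == 0)
    stop("behavioral score is constant", call. = FALSE)
  sc <- sweep(scores, 2L, colMeans(scores))
  qs <- qr(sc)
  if (qs$rank < q)
    stop("reduced scores are collinear", call. = FALSE)
  beta <- qr.coef(qs, yc)
  fitted <- drop(sc %*% beta)
  sf <- sqrt(sum((fitted - mean(fitted))^2) / (n - 1))
  r <- if (sf > 0) stats::cor(fitted, yc) else 0
  r <- max(0, min(1, r))
  weightY <- 1 / sy
  if (sf > 0) {
    weightsX <- beta / sf
    u <- fitted / sf
  } else {
    weightsX <- beta   # all-zero coefficients
    u <- fitted        # all-zero variate
  }
  new("CCASolution", weightsX = as.numeric(weightsX), weightY = weightY,
      variateX = as.numeric(u), variateY = as.numeric(weightY * yc),
      correlation = r)
}

#' Back-project canonical weights to voxel space
#'
#' Maps length-Q canonical weights on the reduced scores back to a length-P
#' voxel weight vector through the SVD components, so that
#' `centered_X %*% voxel_weights` reproduces the imaging variate.
#'
#' @param weightsX length-Q canonical weights (E), or a [CCASolution-class].
#' @param basis a [ReducedBasis-class].
#' @return Numeric length-P voxel weight vector.
#' @export
backproject <- function(weightsX, basis) {
  if (is(weightsX, "CCASolution")) weightsX <- weightsX@weightsX
  if (length(weightsX) != basis@q)
    stop("weights and basis disagree on Q", call. = FALSE)
  drop(basis@components %*% weightsX)
}
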