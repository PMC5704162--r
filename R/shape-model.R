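# Karhunen-Loeve (PCA) point-distribution model of aligned shape vectors:
# mean shape + orthonormal modes of variation, truncated by explained
# variance.

MODEL_SCHEMA_VERSION <- "1.0"

#' Fit a point-distribution shape model to aligned shapes
#'
#' Eigen-decomposition of the sample covariance (divisor n - 1) of the
#' aligned shape vectors about their arithmetic mean, computed through the
#' singular value decomposition of the centred data matrix for numerical
#' stability when 2N exceeds the sample count. Eigenvector signs are fixed
#' so the largest-magnitude component of each column is positive, making
#' parameter signs reproducible across platforms.
#'
#' @param aligned an [AlignedShapes-class] (or any [ShapeSet-class] whose
#'   rows are already in a common frame).
#' @param side side label stored in the model; default taken from the
#'   aligned set's provenance.
#' @return a [ShapeModel-class] with `min(2N, n - 1)` modes.
#' @export
fitShapeModel <- function(aligned, side = NULL) {
  stopifnot(is(aligned, "ShapeSet"))
  X <- aligned@shapes
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 shapes to fit a shape model")
  if (is.null(side)) {
    sides <- unique(aligned@info$side)
    side <- if (length(sides) == 1L) sides else "both"
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc / sqrt(n - 1))
  mFull <- min(ncol(X), n - 1L)
  ev <- sv$d[seq_len(mFull)]^2
  B <- sv$v[, seq_len(mFull), drop = FALSE]
  flip <- vapply(seq_len(mFull), function(m) {
    col <- B[, m]
    sign(col[which.max(abs(col))])
  }, numeric(1))
  B <- sweep(B, 2L, flip, `*`)
  new("ShapeModel",
    meanShape = mu, basis = B, eigenvalues = ev,
    nSamples = as.integer(n), side = side,
    nPoints = aligned@nPoints, fiducialSlots = aligned@fiducialSlots
  )
}

#' Number of modes needed to reach a variance fraction
#'
#' @param model a [ShapeModel-class].
#' @param varianceFraction target cumulative explained-variance fraction
#'   in (0, 1].
#' @return the smallest M whose cumulative eigenvalue fraction reaches the
#'   target.
#' @export
chooseModes <- function(model, varianceFraction = 0.95) {
  stopifnot(is(model, "ShapeModel"))
  if (varianceFraction <= 0 || varianceFraction > 1) {
    stop("varianceFraction must be in (0, 1]")
  }
  ev <- model@eigenvalues
  tot <- sum(ev)
  if (tot <= 0) return(1L)
  frac <- cumsum(ev) / tot
  as.integer(which(frac >= varianceFraction - 1e-12)[1])
}

#' Project aligned shapes onto the model's leading modes
#'
#' Shape parameters \eqn{b_m = \langle P_s^m, x - \bar{x} \rangle} for
#' m = 1..M. Shapes must already be aligned into the model's frame (same
#' Procrustes gauge as the training set).
#'
#' @param model a [ShapeModel-class].
#' @param shapes one interleaved shape vector, or a matrix with one per
#'   row, or a [ShapeSet-class].
#' @param M number of leading modes (default: all).
#' @return numeric parameter vector (single shape) or matrix with M
#'   columns (one row per shape).
#' @export
projectShapes <- function(model, shapes, M = NULL) {
  stopifnot(is(model, "ShapeModel"))
  if (is(shapes, "ShapeSet")) shapes <- shapes@shapes
  single <- is.null(dim(shapes))
  X <- if (single) matrix(shapes, nrow = 1L) else as.matrix(shapes)
  if (ncol(X) != length(model@meanShape)) {
    stop("shape dimension does not match the model (expected ",
      length(model@meanShape), " coordinates)")
  }
  if (is.null(M)) M <- ncol(model@basis)
  M <- as.integer(M)
  if (M < 1L || M > ncol(model@basis)) stop("M out of range 1..", ncol(model@basis))
  b <- sweep(X, 2L, model@meanShape) %*% model@basis[, seq_len(M), drop = FALSE]
  if (single) as.vector(b) else b
}

#' Synthesize shapes from model parameters
#'
#' \eqn{x = \bar{x} + \sum_{m=1}^{M} P_s^m b_m}: the mean shape plus the
#' weighted modes. Zero parameters give the mean shape; parameters of
#' \eqn{\pm 2\sqrt{\lambda_m}} give the conventional two-standard-
#' deviation mode displays.
#'
#' @param model a [ShapeModel-class].
#' @param params numeric parameter vector of length M, or a matrix with
#'   one parameter row per shape.
#' @return interleaved shape vector, or a matrix of them (one per row).
#' @export
synthesizeShape <- function(model, params) {
  stopifnot(is(model, "ShapeModel"))
  single <- is.null(dim(params))
  b <- if (single) matrix(params, nrow = 1L) else as.matrix(params)
  M <- ncol(b)
  if (M > ncol(model@basis)) stop("more parameters than model modes")
  X <- b %*% t(model@basis[, seq_len(M), drop = FALSE])
  X <- sweep(X, 2L, model@meanShape, `+`)
  if (single) as.vector(X) else X
}

#' Mahalanobis distance between two parameter vectors
#'
#' \eqn{\sqrt{\sum_m (a_m - b_m)^2 / \lambda_m}} over the shared modes;
#' near-degenerate modes with \eqn{\lambda_m < 10^{-12} \lambda_1} are
#' excluded from the sum.
#'
#' @param model a [ShapeModel-class].
#' @param a,b numeric parameter vectors of equal length M.
#' @return non-negative scalar distance.
#' @export
mahalanobisShape <- function(model, a, b) {
  stopifnot(is(model, "ShapeModel"), length(a) == length(b))
  M <- length(a)
  ev <- model@eigenvalues[seq_len(M)]
  keep <- ev >= 1e-12 * model@eigenvalues[1]
  sqrt(sum((a[keep] - b[keep])^2 / ev[keep]))
}

#' Project aligned shapes into the tangent space at the mean
#'
#' Optional Kendall tangent-space projection (off by default in every
#' pipeline; the models use raw aligned coordinates): each shape is scaled
#' by \eqn{\langle x, \bar{x} \rangle / |\bar{x}|^2} removed, i.e. the
#' component along the mean is normalized.
#'
#' @param aligned an [AlignedShapes-class].
#' @return matrix of tangent-projected shape vectors.
#' @export
tangentProject <- function(aligned) {
  stopifnot(is(aligned, "AlignedShapes"))
  m <- aligned@meanShape
  X <- aligned@shapes
  coef <- as.vector(X %*% m) / sum(m^2)
  X / coef
}

#' Write a shape model container file
#'
#' JSON container holding the mean shape, eigenbasis, eigenvalues and
#' geometry metadata at full double precision; round-trips through
#' [readShapeModel()] exactly.
#'
#' @param model a [ShapeModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeShapeModel <- function(model, path) {
  stopifnot(is(model, "ShapeModel"))
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    side = model@side,
    n_points = model@nPoints,
    fiducial_slots = model@fiducialSlots,
    n_samples = model@nSamples,
    mean_shape = model@meanShape,
    eigenvalues = model@eigenvalues,
    basis = unname(model@basis)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a shape model container file
#'
#' @param path path written by [writeShapeModel()].
#' @return a [ShapeModel-class].
#' @export
readShapeModel <- function(path) {
  doc <- jsonlite::fromJSON(path)
  new("ShapeModel",
    meanShape = as.numeric(doc$mean_shape),
    basis = as.matrix(doc$basis),
    eigenvalues = as.numeric(doc$eigenvalues),
    nSamples = as.integer(doc$n_samples),
    side = doc$side,
    nPoints = as.integer(doc$n_points),
    fiducialSlots = as.integer(doc$fiducial_slots)
  )
}
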