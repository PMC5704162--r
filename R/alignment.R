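# Generalized Procrustes analysis: removes location, scale and orientation
# before shape modelling. Similarity (not rigid) superimposition;
# reflections are never allowed (left and right sides are modelled
# separately).

.asPointMatrix <- function(v) {
  if (is.matrix(v) && ncol(v) == 2L) v else devectorizePoints(v)
}

.centroidSize <- function(P) {
  # RMS distance of points to their centroid
  Pc <- sweep(P, 2L, colMeans(P))
  sqrt(sum(Pc^2) / nrow(P))
}

# optimal rotation (det +1, reflections disallowed) taking centred X onto
# centred Y; closed form for the planar case
.optimalRotation <- function(Xc, Yc) {
  A <- sum(Xc * Yc)
  B <- sum(Xc[, 1] * Yc[, 2] - Xc[, 2] * Yc[, 1])
  th <- atan2(B, A)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Align one shape to another by ordinary Procrustes superimposition
#'
#' Finds the similarity transform (translation, positive scale, rotation
#' with determinant +1 -- no reflection) minimizing the sum of squared
#' point distances from the transformed moving shape to the target, via
#' the closed-form least-squares solution.
#'
#' @param moving,target shape vectors (interleaved) or N x 2 point
#'   matrices with equal N.
#' @return list with `shape` (the transformed moving shape, interleaved),
#'   `transform` (list `tx`, `ty`, `scale`, `rotation` in radians), and
#'   `rmsd` (root-mean-square residual per point).
#' @export
alignPair <- function(moving, target) {
  X <- .asPointMatrix(moving)
  Y <- .asPointMatrix(target)
  if (nrow(X) != nrow(Y)) stop("shapes must have the same number of points")
  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx)
  Yc <- sweep(Y, 2L, my)
  nx <- sum(Xc^2)
  if (nx == 0 || sum(Yc^2) == 0) stop("degenerate shape: all points identical")
  R <- .optimalRotation(Xc, Yc)
  s <- sum(diag(R %*% crossprod(Xc, Yc))) / nx
  if (s <= 0) stop("degenerate configuration: non-positive optimal scale")
  fitted <- s * Xc %*% t(R)
  tvec <- my - as.vector(R %*% (s * mx))
  Z <- sweep(fitted, 2L, my, `+`)
  list(
    shape = vectorizePoints(Z),
    transform = list(
      tx = tvec[1], ty = tvec[2], scale = s,
      rotation = atan2(R[2, 1], R[1, 1])
    ),
    rmsd = sqrt(sum((Z - Y)^2) / nrow(Y))
  )
}

# rotation that puts the mean's first fiducial on the positive y-axis.
# This canonical gauge depends only on the mean's own geometry, so the
# aligned set is invariant to any common similarity transform of the
# inputs and to their ordering.
.gaugeRotation <- function(meanVec, fiducialSlots) {
  P <- devectorizePoints(meanVec)
  slot <- if (length(fiducialSlots)) fiducialSlots[1] else 1L
  v <- P[slot, ]
  ang <- atan2(v[2], v[1])
  th <- pi / 2 - ang
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Generalized Procrustes alignment of a shape set
#'
#' Iteratively superimposes all shapes: each shape is centred at the
#' origin and scaled to unit centroid size, then rotated to the current
#' mean; the mean is recomputed and renormalized to unit size until it
#' changes by less than `tol` or `maxIter` is reached. The rotational
#' gauge is fixed by rotating the converged mean so its first fiducial
#' points along the positive y-axis (the most-superior-marker
#' convention), which makes the result invariant to any common similarity
#' transform of the inputs.
#'
#' @param x a [ShapeSet-class], or a numeric matrix with one interleaved
#'   shape vector per row.
#' @param tol convergence tolerance on the mean-shape change
#'   (default 1e-10).
#' @param maxIter maximum number of iterations (default 100).
#' @return an [AlignedShapes-class]; on non-convergence the best iterate
#'   is returned with `converged = FALSE` and a warning.
#' @export
generalizedProcrustes <- function(x, tol = 1e-10, maxIter = 100L) {
  if (is(x, "ShapeSet")) {
    shapes <- x@shapes
    info <- x@info
    nPoints <- x@nPoints
    slots <- x@fiducialSlots
  } else {
    shapes <- as.matrix(x)
    if (ncol(shapes) %% 2L != 0L) stop("shape rows must have even length")
    nPoints <- ncol(shapes) %/% 2L
    info <- data.frame(
      subjectId = as.character(seq_len(nrow(shapes))),
      side = "left", group = "control", readerId = "r",
      repeatIndex = seq_len(nrow(shapes)), nPoints = nPoints
    )
    slots <- 1L
  }
  n <- nrow(shapes)
  if (n < 2L) stop("need at least 2 shapes")
  orig <- shapes
  Plist <- lapply(seq_len(n), function(i) devectorizePoints(shapes[i, ]))
  # centre and scale to unit centroid size
  Plist <- lapply(Plist, function(P) {
    Pc <- sweep(P, 2L, colMeans(P))
    cs <- sqrt(sum(Pc^2) / nrow(Pc))
    if (cs == 0) stop("degenerate shape: all points identical")
    Pc / cs
  })
  normalize <- function(P) {
    Pc <- sweep(P, 2L, colMeans(P))
    Pc / sqrt(sum(Pc^2) / nrow(Pc))
  }
  meanP <- Plist[[1]]
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    Plist <- lapply(Plist, function(P) P %*% t(.optimalRotation(P, meanP)))
    newMean <- normalize(Reduce(`+`, Plist) / n)
    delta <- sqrt(sum((newMean - meanP)^2))
    meanP <- newMean
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("generalized Procrustes did not converge in ", maxIter, " iterations")
  }
  G <- .gaugeRotation(vectorizePoints(meanP), slots)
  meanP <- meanP %*% t(G)
  Plist <- lapply(Plist, function(P) P %*% t(G))
  aligned <- t(vapply(Plist, vectorizePoints, numeric(2L * nPoints)))
  transforms <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- alignPair(orig[i, ], aligned[i, ])$transform
    data.frame(
      tx = tr$tx, ty = tr$ty, scale = tr$scale,
      rotation = tr$rotation
    )
  }))
  new("AlignedShapes",
    shapes = aligned, info = info, nPoints = as.integer(nPoints),
    fiducialSlots = as.integer(slots),
    meanShape = vectorizePoints(meanP), transforms = transforms,
    iterations = iter, converged = converged
  )
}

#' Mirror shapes across the y-axis into a common frame
#'
#' Utility for optionally pooling left and right sides: reflects each
#' shape about the vertical axis and reverses the point order (keeping the
#' first point first) so the contour remains counter-clockwise. Off by
#' default in every pipeline; sides are modelled separately.
#'
#' @param shapes matrix of interleaved shape vectors (rows).
#' @return matrix of mirrored shape vectors.
#' @export
mirrorShapes <- function(shapes) {
  shapes <- as.matrix(shapes)
  t(apply(shapes, 1L, function(v) {
    P <- devectorizePoints(v)
    P[, 1] <- -P[, 1]
    n <- nrow(P)
    vectorizePoints(P[c(1L, n:2L), , drop = FALSE])
  }))
}
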