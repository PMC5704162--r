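# Contour regularization: periodic cubic spline fit and fiducial-anchored
# arc-length re-parameterization into N corresponding control points.

.glEnv <- new.env(parent = emptyenv())

# 16-node Gauss-Legendre rule on [0, 1]; panels are aligned with spline
# knots, where the speed is smooth, so the rule is accurate to ~1e-14.
.gl16 <- function() {
  if (is.null(.glEnv$x)) {
    gl <- pracma::gaussLegendre(16, 0, 1)
    .glEnv$x <- gl$x
    .glEnv$w <- gl$w
  }
  .glEnv
}

#' Fit a periodic cubic spline to a closed contour
#'
#' Interpolating C2 periodic cubic spline through the contour points,
#' parameterized by cumulative chord length. Exact consecutive duplicate
#' points (including a repeated closing point) are collapsed with a
#' warning.
#'
#' @param x a [ContourReading-class] or a numeric n x 2 matrix of points.
#' @return an object of class `ContourSpline`: a list with `position(t)`,
#'   `speed(t)`, `arcLength(t)` (cumulative from the start point),
#'   `tAtArcLength(s)` (inverse), knot parameters `tk`, per-point arc
#'   lengths `knotArc`, `totalLength`, and `keptIndex` mapping input point
#'   indices to retained (deduplicated) ones.
#' @export
fitContourSpline <- function(x) {
  pts <- if (is(x, "ContourReading")) x@points else as.matrix(x)
  n0 <- nrow(pts)
  nxt <- c(2:n0, 1L)
  dup <- rowSums((pts - pts[nxt, , drop = FALSE])^2) == 0
  keep <- !c(FALSE, dup[-n0]) # drop a point equal to its predecessor
  if (dup[n0] && keep[n0]) keep[n0] <- FALSE # repeated closing point
  if (any(!keep)) {
    warning(sum(!keep), " duplicate consecutive point(s) collapsed")
  }
  keptIndex <- cumsum(keep) # a dropped point maps to its kept predecessor
  if (dup[n0] && !keep[n0]) keptIndex[n0] <- 1L
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 distinct points to fit a contour spline")
  closed <- rbind(pts, pts[1, ])
  chord <- sqrt(rowSums(diff(closed)^2))
  tk <- c(0, cumsum(chord))
  Tper <- tk[n + 1L]
  fx <- stats::splinefun(tk, closed[, 1], method = "periodic")
  fy <- stats::splinefun(tk, closed[, 2], method = "periodic")
  speed <- function(t) {
    t <- t %% Tper
    sqrt(fx(t, deriv = 1L)^2 + fy(t, deriv = 1L)^2)
  }
  gl <- .gl16()
  a <- tk[-(n + 1L)]
  h <- diff(tk)
  evalT <- rep(a, each = 16L) + as.vector(outer(gl$x, h))
  sp <- matrix(speed(evalT), nrow = 16L)
  panelLen <- as.vector(gl$w %*% sp) * h
  knotArc <- c(0, cumsum(panelLen))
  totalLength <- knotArc[n + 1L]

  arcTo <- function(t1) {
    # arc length from knot 0 to parameter t1 in [0, Tper]
    k <- findInterval(t1, tk, rightmost.closed = TRUE)
    k <- pmin(pmax(k, 1L), n)
    vapply(seq_along(t1), function(i) {
      ki <- k[i]
      d <- t1[i] - tk[ki]
      if (d <= 0) return(knotArc[ki])
      knotArc[ki] + sum(gl$w * speed(tk[ki] + gl$x * d)) * d
    }, numeric(1))
  }
  tAtArcLength <- function(s) {
    s <- s %% totalLength
    k <- findInterval(s, knotArc, rightmost.closed = TRUE)
    k <- pmin(pmax(k, 1L), n)
    vapply(seq_along(s), function(i) {
      ki <- k[i]
      lo <- tk[ki]
      hi <- tk[ki + 1L]
      ds <- s[i] - knotArc[ki]
      t1 <- lo + ds / panelLen[ki] * (hi - lo)
      for (it in 1:12) {
        f <- sum(gl$w * speed(lo + gl$x * (t1 - lo))) * (t1 - lo) - ds
        if (abs(f) < totalLength * 1e-13) break
        t1 <- t1 - f / speed(t1)
        if (t1 < lo) t1 <- lo
        if (t1 > hi) t1 <- hi
      }
      t1
    }, numeric(1))
  }
  structure(
    list(
      position = function(t) {
        t <- t %% Tper
        cbind(fx(t), fy(t))
      },
      speed = speed,
      arcLength = arcTo,
      tAtArcLength = tAtArcLength,
      tk = tk, knotArc = knotArc, totalLength = totalLength,
      keptIndex = keptIndex, nKnots = n
    ),
    class = "ContourSpline"
  )
}

#' @export
print.ContourSpline <- function(x, ...) {
  cat(sprintf(
    "ContourSpline: %d knots, total arc length %.6g\n",
    x$nKnots, x$totalLength
  ))
  invisible(x)
}

#' Interleave planar points into a shape vector
#'
#' @param points numeric N x 2 matrix.
#' @return numeric vector `c(x1, y1, x2, y2, ..., xN, yN)`.
#' @export
vectorizePoints <- function(points) {
  points <- as.matrix(points)
  as.vector(t(points))
}

#' Recover planar points from an interleaved shape vector
#'
#' @param v numeric vector of even length.
#' @return numeric N x 2 matrix.
#' @export
devectorizePoints <- function(v) {
  if (length(v) %% 2L != 0L) stop("shape vector must have even length")
  matrix(v, ncol = 2L, byrow = TRUE)
}

#' Resample a contour into N arc-length-regular control points
#'
#' Re-parameterizes the fitted spline by arc length, anchored at the
#' fiducial markers: the output point at each fiducial slot coincides with
#' the spline position of the corresponding input fiducial, and between
#' consecutive fiducials the points are equally spaced in arc length.
#' Traversal starts at the first fiducial and runs counter-clockwise.
#'
#' @param reading a [ContourReading-class].
#' @param nPoints total number of regularized points N (>= K + 2).
#' @param fiducialSlots strictly increasing 1-based slots of the K
#'   fiducials among the N output points; the first slot must be 1.
#' @return interleaved shape vector of length `2 * nPoints`, with
#'   attributes `nPoints` and `fiducialSlots`.
#' @export
resampleContour <- function(reading, nPoints, fiducialSlots) {
  sp <- fitContourSpline(reading)
  fid <- sp$keptIndex[reading@fiducialIndices]
  K <- length(fid)
  nPoints <- as.integer(nPoints)
  fiducialSlots <- as.integer(fiducialSlots)
  if (length(fiducialSlots) != K) {
    stop("fiducialSlots must have one slot per fiducial (K = ", K, ")")
  }
  if (nPoints < K + 2L) stop("nPoints must be at least K + 2")
  if (fiducialSlots[1] != 1L || any(diff(fiducialSlots) <= 0L) ||
    fiducialSlots[K] > nPoints) {
    stop("fiducialSlots must be strictly increasing, start at 1, and fit in nPoints")
  }
  counts <- diff(c(fiducialSlots, nPoints + 1L))
  if (any(counts < 1L)) stop("fiducial slot allocation infeasible")
  L <- sp$totalLength
  sFid <- sp$knotArc[fid]
  segLen <- diff(c(sFid, sFid[1] + L))
  if (any(segLen <= 0)) stop("fiducials must be distinct along the contour")
  sTarget <- unlist(lapply(seq_len(K), function(k) {
    sFid[k] + segLen[k] * (seq_len(counts[k]) - 1L) / counts[k]
  }))
  tt <- sp$tAtArcLength(sTarget)
  pts <- sp$position(tt)
  pts[fiducialSlots, ] <- sp$position(sp$tk[fid]) # fiducials land exactly
  structure(vectorizePoints(pts),
    nPoints = nPoints, fiducialSlots = fiducialSlots
  )
}

#' Default fiducial slots for a cohort
#'
#' Places fiducial k at `1 + round(N * f_k)` where `f_k` is the mean (over
#' readings) cumulative arc-length fraction from the first fiducial to
#' fiducial k. The slots are computed once per cohort from this first-pass
#' mean and then frozen, so every shape shares the same point-to-point
#' correspondence.
#'
#' @param readings list of [ContourReading-class] (or a [ShapeCohort-class]).
#' @param nPoints total number of regularized points N.
#' @return integer vector of K slots, starting at 1.
#' @export
defaultFiducialSlots <- function(readings, nPoints) {
  if (is(readings, "ShapeCohort")) readings <- readings@readings
  if (!length(readings)) stop("no readings")
  fr <- sapply(readings, function(r) {
    sp <- fitContourSpline(r)
    fid <- sp$keptIndex[r@fiducialIndices]
    s <- sp$knotArc[fid]
    (s - s[1]) / sp$totalLength
  })
  fr <- if (is.matrix(fr)) rowMeans(fr) else mean(fr)
  slots <- 1L + as.integer(round(nPoints * fr))
  # enforce strict increase and headroom of one point per trailing segment
  K <- length(slots)
  slots[1] <- 1L
  for (k in seq_len(K)[-1]) {
    slots[k] <- max(slots[k], slots[k - 1L] + 1L)
  }
  for (k in rev(seq_len(K))) {
    slots[k] <- min(slots[k], as.integer(nPoints) - (K - k))
  }
  if (any(diff(slots) <= 0L)) stop("fiducial slot allocation infeasible for this nPoints")
  slots
}

#' Resample every reading of a cohort into a corresponding shape set
#'
#' Computes (or accepts) one shared set of fiducial slots and resamples
#' every contour to the same N regularized points, yielding point-to-point
#' correspondence across the whole set.
#'
#' @param cohort a [ShapeCohort-class].
#' @param nPoints number of control points per shape (default 20, i.e. 40
#'   degrees of freedom per contour).
#' @param fiducialSlots optional integer slots; computed with
#'   [defaultFiducialSlots()] when `NULL`.
#' @param side optional filter: `"left"` or `"right"`.
#' @return a [ShapeSet-class].
#' @export
resampleCohort <- function(cohort, nPoints = 20L, fiducialSlots = NULL,
                           side = NULL) {
  stopifnot(is(cohort, "ShapeCohort"))
  readings <- cohort@readings
  if (!is.null(side)) {
    readings <- Filter(function(r) r@side == side, readings)
  }
  if (!length(readings)) stop("no readings to resample")
  if (is.null(fiducialSlots)) {
    fiducialSlots <- defaultFiducialSlots(readings, nPoints)
  }
  rows <- t(vapply(
    readings,
    function(r) as.numeric(resampleContour(r, nPoints, fiducialSlots)),
    numeric(2L * nPoints)
  ))
  new("ShapeSet",
    shapes = rows, info = cohortInfo(readings),
    nPoints = as.integer(nPoints), fiducialSlots = as.integer(fiducialSlots)
  )
}
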