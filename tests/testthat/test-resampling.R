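test_that("spline arc length matches the analytic circumference of a circle", {
  sp <- fitContourSpline(circlePoints(12L, 10))
  expect_lt(abs(sp$totalLength - 20 * pi) / (20 * pi), 0.005)
})

test_that("the spline interpolates its control points and collapses duplicates", {
  corners <- matrix(c(0, 0, 4, 0, 4, 4, 0, 4), ncol = 2L, byrow = TRUE)
  sp <- fitContourSpline(corners)
  expect_equal(sp$position(sp$tk[1:4]), corners, tolerance = 1e-12)

  withDup <- corners[c(1, 2, 2, 3, 4), ]
  expect_warning(spd <- fitContourSpline(withDup), "duplicate")
  s <- seq(0, 1, length.out = 37L)[-37L]
  expect_equal(
    spd$position(spd$tAtArcLength(s * spd$totalLength)),
    sp$position(sp$tAtArcLength(s * sp$totalLength)),
    tolerance = 1e-9
  )
  # the duplicate's fiducial index maps to its kept twin
  expect_equal(spd$keptIndex, c(1L, 2L, 2L, 3L, 4L))
  expect_error(
    suppressWarnings(fitContourSpline(corners[c(1, 2, 2, 3), ])),
    "at least 4 distinct"
  )
})

test_that("a uniform circle resamples to equal angular increments from the fiducial", {
  r <- circleReading(40L, 10)
  v <- resampleContour(r, 20L, 1L)
  P <- devectorizePoints(v)
  ang <- (atan2(P[, 2], P[, 1]) %% (2 * pi)) * 180 / pi
  expect_equal(ang, (0:19) * 18, tolerance = 1e-8)
  expect_equal(P[1, ], r@points[1, ]) # starts at the fiducial
})

test_that("resampling is idempotent on a shape equal to its own resampling", {
  r <- circleReading(40L, 10)
  v <- resampleContour(r, 20L, 1L)
  r2 <- ContourReading("c1", "left", "control", "r1", 0L,
    devectorizePoints(v), 1L, quiet = TRUE
  )
  v2 <- resampleContour(r2, 20L, 1L)
  expect_lt(max(abs(v2 - v)) / 10, 1e-9)
})

test_that("a square with corner fiducials gets 5 equally spaced points per side", {
  sq <- squareReading(perSide = 40L, half = 5)
  v <- resampleContour(sq, 20L, c(1L, 6L, 11L, 16L))
  P <- devectorizePoints(v)
  seg <- sqrt(rowSums((P[c(2:20, 1L), ] - P)^2))
  # side length 10, five points per side -> spacing 2, up to the spline's
  # corner overshoot
  expect_equal(seg, rep(2, 20L), tolerance = 5e-3)
  expect_equal(P[c(1L, 6L, 11L, 16L), ],
    matrix(c(-5, -5, 5, -5, 5, 5, -5, 5), ncol = 2L, byrow = TRUE),
    tolerance = 1e-9
  )
})

test_that("chord lengths are equal within each fiducial segment", {
  # constant-curvature contour: equal arc spacing implies equal chords
  r <- circleReading(48L, 10, nFid = 4L)
  v <- resampleContour(r, 20L, c(1L, 6L, 11L, 16L))
  P <- devectorizePoints(v)
  bounds <- c(1L, 6L, 11L, 16L, 21L)
  for (k in seq_len(4L)) {
    idx <- bounds[k]:(bounds[k + 1L] - 1L)
    nxt <- c(idx[-1L], if (k == 4L) 1L else bounds[k + 1L])
    chords <- sqrt(rowSums((P[nxt, , drop = FALSE] - P[idx, , drop = FALSE])^2))
    expect_lt(diff(range(chords)) / mean(chords), 1e-6)
  }
})

test_that("resampling is insensitive to the input hand-sampling density", {
  th1 <- 2 * pi * (seq_len(40L) - 1L) / 40L
  th2 <- 2 * pi * (seq_len(80L) - 1L) / 80L
  mk <- function(th) {
    r <- 10 + 0.8 * cos(2 * th) + 0.4 * sin(3 * th)
    ContourReading("b", "left", "control", "r1", 0L,
      cbind(r * cos(th), r * sin(th)), 1L, quiet = TRUE
    )
  }
  v1 <- resampleContour(mk(th1), 20L, 1L)
  v2 <- resampleContour(mk(th2), 20L, 1L)
  expect_lt(max(abs(v1 - v2)), 0.05) # within spline-approximation error, mm
})

test_that("resampled perimeter approaches the spline arc length as N grows", {
  tpl <- makeTemplate()
  sp <- fitContourSpline(tpl)
  slots <- defaultFiducialSlots(list(tpl), 20L)
  perim <- vapply(c(20L, 40L, 80L), function(N) {
    P <- devectorizePoints(resampleContour(tpl, N, 1L + (slots - 1L) * (N %/% 20L)))
    sum(sqrt(rowSums((P[c(2:N, 1L), ] - P)^2)))
  }, numeric(1))
  gaps <- sp$totalLength - perim
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) < 0)) # monotone convergence from below
})

test_that("vectorization follows the interleaved coordinate convention", {
  expect_equal(vectorizePoints(rbind(c(1, 2), c(3, 4))), c(1, 2, 3, 4))
  P <- circlePoints(20L, 3)
  expect_equal(devectorizePoints(vectorizePoints(P)), P)
  expect_length(vectorizePoints(P), 40L) # N = 20 gives 40 degrees of freedom
  expect_error(devectorizePoints(1:5), "even length")
})

test_that("infeasible slot allocations and short contours are rejected", {
  sq <- squareReading(perSide = 10L)
  expect_error(resampleContour(sq, 5L, c(1L, 2L, 3L, 4L)), "at least K \\+ 2")
  expect_error(resampleContour(sq, 20L, c(2L, 6L, 11L, 16L)), "start at 1")
  expect_error(resampleContour(sq, 20L, c(1L, 6L, 11L)), "one slot per fiducial")
})
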