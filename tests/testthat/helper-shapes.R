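# Fixture builders and a memoized full-pipeline run shared across tests.

circlePoints <- function(n, r = 1, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(r * cos(th), r * sin(th))
}

circleReading <- function(n = 40L, r = 10, nFid = 1L, subjectId = "c1",
                          side = "left", group = "control") {
  fid <- 1L + as.integer(round((seq_len(nFid) - 1L) * n / nFid))
  ContourReading(subjectId, side, group, "r1", 0L,
    points = circlePoints(n, r), fiducialIndices = fid, quiet = TRUE
  )
}

squareReading <- function(perSide = 40L, half = 5) {
  s <- seq(-half, half, length.out = perSide + 1L)[-(perSide + 1L)]
  pts <- rbind(
    cbind(s, -half), cbind(half, s), cbind(-s, half), cbind(-half, -s)
  )
  ContourReading("sq", "left", "control", "r1", 0L,
    points = pts, fiducialIndices = 1L + perSide * 0:3, quiet = TRUE
  )
}

# a ShapeSet built straight from a matrix of interleaved shape rows
makeTestShapeSet <- function(shapes, side = "left", group = NULL,
                             subjectId = NULL, readerId = NULL,
                             repeatIndex = NULL, slots = 1L) {
  shapes <- as.matrix(shapes)
  n <- nrow(shapes)
  info <- data.frame(
    subjectId = if (is.null(subjectId)) sprintf("s%03d", seq_len(n)) else subjectId,
    side = side,
    group = if (is.null(group)) "control" else group,
    readerId = if (is.null(readerId)) "r1" else readerId,
    repeatIndex = if (is.null(repeatIndex)) rep(0L, n) else as.integer(repeatIndex),
    nPoints = ncol(shapes) %/% 2L,
    stringsAsFactors = FALSE
  )
  new("ShapeSet",
    shapes = shapes, info = info,
    nPoints = as.integer(ncol(shapes) %/% 2L), fiducialSlots = as.integer(slots)
  )
}

applySimilarity <- function(v, rot = 0, scale = 1, tx = 0, ty = 0) {
  P <- devectorizePoints(v)
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2L, 2L)
  P <- scale * P %*% t(R)
  P[, 1] <- P[, 1] + tx
  P[, 2] <- P[, 2] + ty
  vectorizePoints(P)
}

.fixtureCache <- new.env(parent = emptyenv())

# the default-conditions left-side cohort and its full pipeline run,
# computed once per test session
sharedGen <- function() {
  if (is.null(.fixtureCache$gen)) {
    .fixtureCache$gen <- generateCohort(simulationConfig(sides = "left", seed = 42L))
  }
  .fixtureCache$gen
}

sharedPipeline <- function() {
  if (is.null(.fixtureCache$pipe)) {
    .fixtureCache$pipe <- runPipeline(sharedGen()$cohort, side = "left")
  }
  .fixtureCache$pipe
}

nullConfig <- function(seed = 7L, ...) {
  simulationConfig(
    sides = "left", seed = seed,
    latentModes = data.frame(
      mode = c("formation_height", "fissure_width"),
      controlMean = c(1, 1), subjectMean = c(1, 1), sd = c(0.05, 0.07)
    ),
    ...
  )
}

sharedNullGen <- function() {
  if (is.null(.fixtureCache$nullGen)) {
    .fixtureCache$nullGen <- generateCohort(nullConfig())
  }
  .fixtureCache$nullGen
}
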