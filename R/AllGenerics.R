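#' Number of shapes or readings in a container
#'
#' @param x a [ShapeCohort-class], [ShapeSet-class] or [ConsensusSet-class].
#' @return integer count.
#' @export
setGeneric("nShapes", function(x) standardGeneric("nShapes"))

#' Shape-vector matrix of a container
#'
#' One row per shape, interleaved \eqn{[x_1, y_1, \dots, x_N, y_N]} columns.
#'
#' @param x a [ShapeSet-class] or [ConsensusSet-class].
#' @return numeric matrix.
#' @export
setGeneric("shapeMatrix", function(x) standardGeneric("shapeMatrix"))

#' Provenance table of a container
#'
#' @param x a [ShapeCohort-class], [ShapeSet-class] or [ConsensusSet-class].
#' @return data.frame with one row per shape/reading.
#' @export
setGeneric("shapeInfo", function(x) standardGeneric("shapeInfo"))

#' Mean shape of an aligned set or model
#'
#' @param x an [AlignedShapes-class] or [ShapeModel-class].
#' @return numeric 2N shape vector.
#' @export
setGeneric("meanShape", function(x) standardGeneric("meanShape"))

#' Per-mode variances (eigenvalues) of a shape model
#'
#' @param x a [ShapeModel-class].
#' @return non-increasing numeric vector.
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' Orthonormal eigenbasis of a shape model
#'
#' @param x a [ShapeModel-class].
#' @return `2N x Mfull` matrix, one mode of variation per column.
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname nShapes
#' @export
setMethod("nShapes", "ShapeCohort", function(x) length(x@readings))

#' @rdname nShapes
#' @export
setMethod("nShapes", "ShapeSet", function(x) nrow(x@shapes))

#' @rdname nShapes
#' @export
setMethod("nShapes", "ConsensusSet", function(x) nrow(x@params))

#' @rdname shapeMatrix
#' @export
setMethod("shapeMatrix", "ShapeSet", function(x) x@shapes)

#' @rdname shapeMatrix
#' @export
setMethod("shapeMatrix", "ConsensusSet", function(x) x@shapes)

#' @rdname shapeInfo
#' @export
setMethod("shapeInfo", "ShapeCohort", function(x) cohortInfo(x))

#' @rdname shapeInfo
#' @export
setMethod("shapeInfo", "ShapeSet", function(x) x@info)

#' @rdname shapeInfo
#' @export
setMethod("shapeInfo", "ConsensusSet", function(x) x@info)

#' @rdname meanShape
#' @export
setMethod("meanShape", "AlignedShapes", function(x) x@meanShape)

#' @rdname meanShape
#' @export
setMethod("meanShape", "ShapeModel", function(x) x@meanShape)

#' @rdname eigenValues
#' @export
setMethod("eigenValues", "ShapeModel", function(x) x@eigenvalues)

#' @rdname basisMatrix
#' @export
setMethod("basisMatrix", "ShapeModel", function(x) x@basis)

setMethod("show", "ContourReading", function(object) {
  cat(sprintf(
    "ContourReading: subject %s (%s), %s side, reader %s repeat %d\n  %d points, %d fiducials, pixel spacing %.4g mm\n",
    object@subjectId, object@group, object@side, object@readerId,
    object@repeatIndex, nrow(object@points), length(object@fiducialIndices),
    object@pixelSpacingMm
  ))
})

setMethod("show", "ShapeCohort", function(object) {
  n <- length(object@readings)
  cat(sprintf("ShapeCohort with %d readings", n))
  if (n) {
    info <- cohortInfo(object)
    cat(sprintf(
      ": %d subjects, sides {%s}, %d readers",
      length(unique(info$subjectId)),
      paste(sort(unique(info$side)), collapse = ","),
      length(unique(info$readerId))
    ))
  }
  cat("\n")
})

setMethod("show", "ShapeSet", function(object) {
  cat(sprintf(
    "%s: %d shapes, %d control points, fiducial slots {%s}\n",
    class(object), nrow(object@shapes), object@nPoints,
    paste(object@fiducialSlots, collapse = ",")
  ))
})

setMethod("show", "AlignedShapes", function(object) {
  callNextMethod()
  cat(sprintf(
    "  GPA: %d iterations, converged = %s\n",
    object@iterations, object@converged
  ))
})

setMethod("show", "ShapeModel", function(object) {
  ev <- object@eigenvalues
  cat(sprintf(
    "ShapeModel (%s side): %d modes from %d shapes of %d points\n",
    object@side, length(ev), object@nSamples, object@nPoints
  ))
  if (length(ev)) {
    cum <- cumsum(ev) / sum(ev)
    m95 <- which(cum >= 0.95)[1]
    cat(sprintf("  95%% of variance in %d modes\n", m95))
  }
})

setMethod("show", "ConsensusSet", function(object) {
  cat(sprintf(
    "ConsensusSet: %d consensus shapes (M = %d modes)\n",
    nrow(object@params), object@M
  ))
})

setMethod("show", "LinearSVMModel", function(object) {
  cat(sprintf(
    "LinearSVMModel (%s side): M = %d, %d support vectors, cost = %g\n",
    object@side, object@M, nrow(object@supportVectors), object@cost
  ))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf(
    "ConfusionCounts (%d controls / %d subjects)\n  view C: TP %d TN %d FP %d FN %d\n  view S: TP %d TN %d FP %d FN %d\n",
    object@nControls, object@nSubjects,
    object@tpC, object@tnC, object@fpC, object@fnC,
    object@tpS, object@tnS, object@fpS, object@fnS
  ))
})

setMethod("show", "ModeSweepResult", function(object) {
  cat(sprintf(
    "ModeSweepResult (%s side, %s): M = 1..%d\n",
    object@side, object@evaluation, nrow(object@table)
  ))
})
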