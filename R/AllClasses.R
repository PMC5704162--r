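#' @import methods
NULL

#' A single hand-drawn closed hippocampal contour
#'
#' One delineation of a hippocampal outline on a coronal section, together
#' with its fiducial markers and provenance (subject, reader, repeat, side,
#' group). Coordinates are y-up Cartesian millimetres; the contour is closed
#' by convention (the last point connects back to the first, which is not
#' duplicated) and is stored counter-clockwise.
#'
#' @slot subjectId character scalar, opaque subject identifier.
#' @slot side `"left"` or `"right"`.
#' @slot group `"control"` (healthy) or `"subject"` (early AD).
#' @slot readerId character scalar, opaque reader identifier.
#' @slot repeatIndex integer >= 0, which repeat by this reader.
#' @slot points numeric matrix with columns `x`, `y` (mm), >= 4 rows.
#' @slot fiducialIndices strictly increasing 1-based indices into the rows
#'   of `points`; at least one.
#' @slot pixelSpacingMm positive numeric, isotropic pixel spacing of the
#'   source image (1 when coordinates are already metric).
#'
#' @export
setClass("ContourReading",
  representation(
    subjectId = "character",
    side = "character",
    group = "character",
    readerId = "character",
    repeatIndex = "integer",
    points = "matrix",
    fiducialIndices = "integer",
    pixelSpacingMm = "numeric"
  )
)

setValidity("ContourReading", function(object) {
  msgs <- character()
  if (length(object@subjectId) != 1L) msgs <- c(msgs, "subjectId must be a single string")
  if (!object@side %in% c("left", "right")) msgs <- c(msgs, "side must be 'left' or 'right'")
  if (!object@group %in% c("control", "subject")) msgs <- c(msgs, "group must be 'control' or 'subject'")
  if (length(object@repeatIndex) != 1L || object@repeatIndex < 0L)
    msgs <- c(msgs, "repeatIndex must be a single non-negative integer")
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L) msgs <- c(msgs, "points must be a numeric n x 2 matrix")
  else {
    if (nrow(p) < 4L) msgs <- c(msgs, "contour needs at least 4 points")
    if (anyNA(p) || any(!is.finite(p))) msgs <- c(msgs, "points must be finite")
  }
  fi <- object@fiducialIndices
  if (length(fi) < 1L) msgs <- c(msgs, "at least one fiducial index required")
  else {
    if (any(diff(fi) <= 0L)) msgs <- c(msgs, "fiducialIndices must be strictly increasing")
    if (any(fi < 1L) || any(fi > nrow(p)))
      msgs <- c(msgs, sprintf("fiducial index out of range 1..%d", nrow(p)))
  }
  if (length(object@pixelSpacingMm) != 1L || object@pixelSpacingMm <= 0)
    msgs <- c(msgs, "pixelSpacingMm must be a single positive number")
  if (length(msgs) == 0L && is.numeric(p) && ncol(p) == 2L && nrow(p) >= 4L) {
    if (polygonSignedArea(p) <= 0)
      msgs <- c(msgs, "contour must be counter-clockwise (positive signed area)")
    if (!isSimplePolygon(p))
      msgs <- c(msgs, "contour must be a simple polygon (no self-intersection)")
  }
  if (length(msgs)) msgs else TRUE
})

#' A cohort of contour readings
#'
#' @slot readings list of [ContourReading-class] objects, sorted by
#'   (subjectId, side, readerId, repeatIndex).
#' @slot metadata free-form named list.
#'
#' @export
setClass("ShapeCohort",
  representation(readings = "list", metadata = "list"),
  prototype(readings = list(), metadata = list())
)

setValidity("ShapeCohort", function(object) {
  msgs <- character()
  if (!all(vapply(object@readings, is, logical(1), "ContourReading")))
    return("all readings must be ContourReading objects")
  if (length(object@readings)) {
    info <- cohortInfo(object)
    grp <- unique(info[, c("subjectId", "group")])
    if (anyDuplicated(grp$subjectId))
      msgs <- c(msgs, "group label inconsistent across readings of a subject")
  }
  if (length(msgs)) msgs else TRUE
})

#' A set of regularized shape vectors with shared point correspondence
#'
#' Each row of `shapes` is one shape in interleaved
#' \eqn{[x_1, y_1, \dots, x_N, y_N]} order; every shape in the set shares
#' the same number of regularized control points and the same fiducial
#' slots, so point-to-point correspondence holds across the set.
#'
#' @slot shapes numeric matrix, one row per shape, `2 * nPoints` columns.
#' @slot info data.frame with one row per shape: `subjectId`, `side`,
#'   `group`, `readerId`, `repeatIndex`.
#' @slot nPoints number of regularized control points N.
#' @slot fiducialSlots 1-based indices of the regularized points that carry
#'   the fiducial markers; identical for every shape in the set.
#'
#' @export
setClass("ShapeSet",
  representation(
    shapes = "matrix",
    info = "data.frame",
    nPoints = "integer",
    fiducialSlots = "integer"
  )
)

setValidity("ShapeSet", function(object) {
  msgs <- character()
  if (ncol(object@shapes) != 2L * object@nPoints)
    msgs <- c(msgs, "shapes must have 2 * nPoints columns")
  if (nrow(object@shapes) != nrow(object@info))
    msgs <- c(msgs, "info must have one row per shape")
  fs <- object@fiducialSlots
  if (length(fs) && (any(fs < 1L) || any(fs > object@nPoints) || any(diff(fs) <= 0L)))
    msgs <- c(msgs, "fiducialSlots must be strictly increasing within 1..nPoints")
  if (length(msgs)) msgs else TRUE
})

#' Procrustes-aligned shape set
#'
#' A [ShapeSet-class] after generalized Procrustes analysis: every shape is
#' centred at the origin with unit centroid size (RMS distance of points to
#' centroid equal to 1), and `meanShape` is the arithmetic mean of the
#' aligned shapes renormalized to unit size.
#'
#' @slot meanShape numeric, the Procrustes mean shape vector.
#' @slot transforms data.frame, per-shape similarity parameters applied
#'   to the original shapes: `tx`, `ty` (mm), `scale`, `rotation` (radians).
#' @slot iterations number of GPA iterations performed.
#' @slot converged logical flag.
#'
#' @export
setClass("AlignedShapes",
  contains = "ShapeSet",
  representation(
    meanShape = "numeric",
    transforms = "data.frame",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("AlignedShapes", function(object) {
  msgs <- character()
  if (length(object@meanShape) != ncol(object@shapes))
    msgs <- c(msgs, "meanShape length must match shape dimension")
  n <- nrow(object@shapes)
  if (n) {
    xs <- object@shapes[, seq(1L, ncol(object@shapes), by = 2L), drop = FALSE]
    ys <- object@shapes[, seq(2L, ncol(object@shapes), by = 2L), drop = FALSE]
    cent <- cbind(rowMeans(xs), rowMeans(ys))
    if (max(abs(cent)) > 1e-8) msgs <- c(msgs, "aligned shapes must be centred at origin")
    sz <- sqrt((rowSums(xs^2) + rowSums(ys^2)) / object@nPoints -
      cent[, 1]^2 - cent[, 2]^2)
    if (max(abs(sz - 1)) > 1e-8) msgs <- c(msgs, "aligned shapes must have unit centroid size")
  }
  if (length(msgs)) msgs else TRUE
})

#' Karhunen-Loeve (principal component) point-distribution shape model
#'
#' Linear shape model \eqn{x = \bar{x} + P_s b_s}: a mean shape plus an
#' orthonormal eigenbasis of the aligned-shape covariance, with per-mode
#' variances (eigenvalues) sorted non-increasing.
#'
#' @slot meanShape numeric 2N vector.
#' @slot basis `2N x Mfull` matrix with orthonormal columns (modes of
#'   variation).
#' @slot eigenvalues non-negative, non-increasing per-mode variances.
#' @slot nSamples number of training shapes.
#' @slot side `"left"`, `"right"`, or `"both"`.
#' @slot nPoints number of control points N.
#' @slot fiducialSlots fiducial slots inherited from the training set.
#'
#' @export
setClass("ShapeModel",
  representation(
    meanShape = "numeric",
    basis = "matrix",
    eigenvalues = "numeric",
    nSamples = "integer",
    side = "character",
    nPoints = "integer",
    fiducialSlots = "integer"
  )
)

setValidity("ShapeModel", function(object) {
  msgs <- character()
  B <- object@basis
  if (nrow(B) != length(object@meanShape))
    msgs <- c(msgs, "basis rows must match meanShape length")
  if (ncol(B) != length(object@eigenvalues))
    msgs <- c(msgs, "one eigenvalue per basis column")
  if (ncol(B)) {
    G <- crossprod(B)
    if (max(abs(G - diag(ncol(B)))) > 1e-8)
      msgs <- c(msgs, "basis columns must be orthonormal")
  }
  ev <- object@eigenvalues
  if (length(ev) && (any(ev < -1e-12) || any(diff(ev) > 1e-12)))
    msgs <- c(msgs, "eigenvalues must be non-negative and non-increasing")
  if (ncol(B) > min(nrow(B), max(object@nSamples - 1L, 0L)))
    msgs <- c(msgs, "number of modes exceeds min(2N, nSamples - 1)")
  if (length(msgs)) msgs else TRUE
})

#' Per-subject consensus shapes in model space
#'
#' One consensus per (subject, side): the mean of the per-reading shape
#' parameters (repeats averaged within reader, then across readers),
#' back-projected through the model so the consensus contour is always a
#' legal shape in the model's span.
#'
#' @slot params numeric matrix, one row per consensus, M columns of shape
#'   parameters.
#' @slot shapes numeric matrix of back-projected shape vectors.
#' @slot info data.frame: `subjectId`, `side`, `group`, `nReadings`.
#' @slot M number of modes used in the averaging.
#' @slot nPoints,fiducialSlots geometry metadata from the model.
#'
#' @export
setClass("ConsensusSet",
  representation(
    params = "matrix",
    shapes = "matrix",
    info = "data.frame",
    M = "integer",
    nPoints = "integer",
    fiducialSlots = "integer"
  )
)

setValidity("ConsensusSet", function(object) {
  msgs <- character()
  if (nrow(object@params) != nrow(object@info) ||
    nrow(object@shapes) != nrow(object@info))
    msgs <- c(msgs, "params, shapes and info must agree in row count")
  if (ncol(object@params) != object@M)
    msgs <- c(msgs, "params must have M columns")
  if (length(msgs)) msgs else TRUE
})

#' Linear-kernel support vector machine over shape parameters
#'
#' Decision function \eqn{f(x) = \mathrm{sgn}[\sum_i \alpha_i y_i
#' K(x_i \cdot x) + b]} with the linear kernel \eqn{K(s) = \gamma s +
#' \beta}. Labels are encoded control = -1, early-AD subject = +1; a
#' decision value of exactly zero maps to the control class.
#'
#' @slot supportCoefficients per-support-vector weights \eqn{\alpha_i y_i}.
#' @slot supportVectors matrix of support vectors (rows), M columns.
#' @slot bias scalar b.
#' @slot kernelSlope,kernelIntercept linear-kernel slope \eqn{\gamma > 0}
#'   and intercept \eqn{\beta} (defaults 1 and 0: pure linear kernel).
#' @slot M number of shape parameters used.
#' @slot side which hippocampal side the model was trained on.
#' @slot cost soft-margin cost used in training.
#' @slot center,scaleFactors per-parameter standardization applied before
#'   the margin (training-set mean and standard deviation); support
#'   vectors are stored in the standardized space.
#'
#' @export
setClass("LinearSVMModel",
  representation(
    supportCoefficients = "numeric",
    supportVectors = "matrix",
    bias = "numeric",
    kernelSlope = "numeric",
    kernelIntercept = "numeric",
    M = "integer",
    side = "character",
    cost = "numeric",
    center = "numeric",
    scaleFactors = "numeric"
  )
)

setValidity("LinearSVMModel", function(object) {
  msgs <- character()
  if (length(object@supportCoefficients) != nrow(object@supportVectors))
    msgs <- c(msgs, "one coefficient per support vector")
  if (ncol(object@supportVectors) != object@M)
    msgs <- c(msgs, "support vectors must have M columns")
  if (length(object@center) != object@M || length(object@scaleFactors) != object@M)
    msgs <- c(msgs, "center and scaleFactors must have length M")
  if (object@kernelSlope <= 0) msgs <- c(msgs, "kernelSlope must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Confusion counts in the mirrored two-view bookkeeping
#'
#' Counts are kept per class view: view C treats controls as positives,
#' view S treats early-AD subjects as positives. The mirrored reporting
#' convention sets `TN_v = TP_v` numerically, and `FP_C = FN_S`,
#' `FP_S = FN_C` (the other class's misses show up as this view's false
#' positives); `confusionFromPredictions(..., mirror = FALSE)` gives the
#' textbook convention instead.
#'
#' @slot tpC,tnC,fpC,fnC control-view counts.
#' @slot tpS,tnS,fpS,fnS subject-view counts.
#' @slot nControls,nSubjects class sizes.
#'
#' @export
setClass("ConfusionCounts",
  representation(
    tpC = "integer", tnC = "integer", fpC = "integer", fnC = "integer",
    tpS = "integer", tnS = "integer", fpS = "integer", fnS = "integer",
    nControls = "integer", nSubjects = "integer"
  )
)

setValidity("ConfusionCounts", function(object) {
  msgs <- character()
  cnts <- c(
    object@tpC, object@tnC, object@fpC, object@fnC,
    object@tpS, object@tnS, object@fpS, object@fnS
  )
  if (any(cnts < 0L)) msgs <- c(msgs, "counts must be non-negative")
  if (object@tpC + object@fnC != object@nControls)
    msgs <- c(msgs, "TP_C + FN_C must equal nControls")
  if (object@tpS + object@fnS != object@nSubjects)
    msgs <- c(msgs, "TP_S + FN_S must equal nSubjects")
  if (length(msgs)) msgs else TRUE
})

#' Result of a mode-count sweep of the SVM classifier
#'
#' @slot table data.frame with one row per mode count M: the eight
#'   confusion counts plus per-view sensitivity, specificity, precision,
#'   accuracy and F-measure, and overall percent correct and kappa.
#' @slot counts list of [ConfusionCounts-class], one per M.
#' @slot evaluation `"resubstitution"` or `"k_fold"`.
#' @slot side hippocampal side.
#'
#' @export
setClass("ModeSweepResult",
  representation(
    table = "data.frame",
    counts = "list",
    evaluation = "character",
    side = "character"
  )
)

setValidity("ModeSweepResult", function(object) {
  if (nrow(object@table) && !identical(object@table$M, seq_len(nrow(object@table))))
    return("sweep rows must cover M = 1..M_max contiguously")
  TRUE
})
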