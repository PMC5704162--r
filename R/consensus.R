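# Model-space consensus of repeated readings: averaging hand-drawn
# contours in Cartesian coordinates can produce self-intersecting curves
# when readers disagree on boundary structure, so repeated readings are
# averaged in shape-parameter space and back-projected, which keeps the
# consensus inside the model's span of legal shapes.

#' Collapse repeated readings into one consensus shape per subject side
#'
#' Projects every aligned reading onto the model's first M modes, averages
#' the parameters in two stages -- repeats within each reader first, then
#' across readers, so a reader who repeated three times does not outweigh
#' one who repeated twice -- and back-projects the averaged parameters
#' through the model.
#'
#' @param model a [ShapeModel-class].
#' @param aligned an [AlignedShapes-class] carrying
#'   (subject, side, reader, repeat) provenance in its `info`.
#' @param M number of modes used for the averaging (default: all model
#'   modes, so truncation can be applied downstream).
#' @return a [ConsensusSet-class] with one row per (subject, side);
#'   subject sides with zero readings are simply absent.
#' @export
consensusBySubject <- function(model, aligned, M = NULL) {
  stopifnot(is(model, "ShapeModel"), is(aligned, "ShapeSet"))
  if (is.null(M)) M <- ncol(model@basis)
  M <- as.integer(M)
  if (M > ncol(model@basis)) stop("M exceeds the number of model modes")
  b <- projectShapes(model, aligned, M = M)
  if (is.null(dim(b))) b <- matrix(b, ncol = M)
  info <- aligned@info
  key <- paste(info$subjectId, info$side, sep = "\r")
  rows <- lapply(sort(unique(key)), function(k) {
    idx <- which(key == k)
    perReader <- lapply(split(idx, info$readerId[idx]), function(ii) {
      colMeans(b[ii, , drop = FALSE])
    })
    params <- colMeans(do.call(rbind, perReader))
    list(
      subjectId = info$subjectId[idx[1]], side = info$side[idx[1]],
      group = info$group[idx[1]], nReadings = length(idx), params = params
    )
  })
  params <- do.call(rbind, lapply(rows, `[[`, "params"))
  cinfo <- data.frame(
    subjectId = vapply(rows, `[[`, character(1), "subjectId"),
    side = vapply(rows, `[[`, character(1), "side"),
    group = vapply(rows, `[[`, character(1), "group"),
    nReadings = vapply(rows, `[[`, integer(1), "nReadings"),
    stringsAsFactors = FALSE
  )
  new("ConsensusSet",
    params = unname(params),
    shapes = synthesizeShape(model, params),
    info = cinfo, M = M,
    nPoints = model@nPoints, fiducialSlots = model@fiducialSlots
  )
}
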