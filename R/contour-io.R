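# Annotation data model and cohort file I/O (JSON / CSV).
#
# Coordinate frame: y-up Cartesian millimetres. Contours are closed by
# convention (first point not duplicated) and normalized to counter-
# clockwise orientation on load.

COHORT_SCHEMA_VERSION <- "1.0"

#' Signed area of a closed polygon
#'
#' Shoelace formula over the implicitly closed polygon (first point not
#' repeated). Positive for counter-clockwise orientation in a y-up frame.
#'
#' @param points numeric n x 2 matrix of vertices.
#' @return signed area (same squared units as the coordinates).
#' @export
polygonSignedArea <- function(points) {
  x <- points[, 1]
  y <- points[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Pairwise segment-intersection test over the implicitly closed polygon;
#' segments sharing an endpoint are exempt. Exact duplicate consecutive
#' vertices make the polygon non-simple.
#'
#' @param points numeric n x 2 matrix of vertices.
#' @return logical scalar.
#' @export
isSimplePolygon <- function(points) {
  n <- nrow(points)
  if (n < 3L) return(FALSE)
  p <- points
  q <- points[c(2:n, 1L), , drop = FALSE]
  if (any(rowSums((p - q)^2) == 0)) return(FALSE)
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    # skip adjacent segments (i, i+1) and the closing pair (1, n)
    js <- setdiff(seq(i + 1L, n), c(i, i + 1L, if (i == 1L) n))
    if (!length(js)) next
    d1 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[js, 1], p[js, 2])
    d2 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[js, 1], q[js, 2])
    d3 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2], p[i, 1], p[i, 2])
    d4 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2], q[i, 1], q[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
    # collinear overlap: treat touching interiors as intersection
    col <- which(d1 == 0 & d2 == 0)
    for (k in col) {
      j <- js[k]
      r1 <- range(p[i, 1], q[i, 1]); r2 <- range(p[j, 1], q[j, 1])
      s1 <- range(p[i, 2], q[i, 2]); s2 <- range(p[j, 2], q[j, 2])
      if (r1[1] < r2[2] && r2[1] < r1[2] && s1[1] <= s2[2] && s2[1] <= s1[2]) return(FALSE)
      if (s1[1] < s2[2] && s2[1] < s1[2] && r1[1] <= r2[2] && r2[1] <= r1[2]) return(FALSE)
    }
  }
  TRUE
}

#' Construct a contour reading
#'
#' Builds a [ContourReading-class], converting pixel coordinates to the
#' y-up metric frame when requested and normalizing orientation to
#' counter-clockwise (reversing the point order, and remapping fiducial
#' indices, when the input is clockwise).
#'
#' @param subjectId,side,group,readerId,repeatIndex provenance labels.
#' @param points numeric n x 2 matrix (>= 4 rows).
#' @param fiducialIndices strictly increasing 1-based indices into `points`.
#' @param pixelSpacingMm isotropic pixel spacing (mm per pixel); 1 for
#'   coordinates already in mm.
#' @param coords `"mm"` (default: y-up metric, used as-is) or `"pixels"`
#'   (image row/column frame: multiplied by `pixelSpacingMm` and y-flipped).
#' @param quiet suppress the orientation-normalization message.
#' @return a validated [ContourReading-class].
#' @export
ContourReading <- function(subjectId, side, group, readerId, repeatIndex,
                           points, fiducialIndices, pixelSpacingMm = 1,
                           coords = c("mm", "pixels"), quiet = FALSE) {
  coords <- match.arg(coords)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (coords == "pixels") {
    points <- points * pixelSpacingMm
    points[, 2] <- -points[, 2]
  }
  fiducialIndices <- as.integer(fiducialIndices)
  rec <- sprintf("%s/%s/%s/r%s", subjectId, side, readerId, repeatIndex)
  if (nrow(points) >= 3L && polygonSignedArea(points) < 0) {
    n <- nrow(points)
    points <- points[c(1L, n:2L), , drop = FALSE]
    fiducialIndices <- sort(ifelse(fiducialIndices == 1L, 1L, n - fiducialIndices + 2L))
    if (!quiet) message("contour ", rec, ": clockwise input reversed to counter-clockwise")
  }
  tryCatch(
    new("ContourReading",
      subjectId = as.character(subjectId), side = as.character(side),
      group = as.character(group), readerId = as.character(readerId),
      repeatIndex = as.integer(repeatIndex), points = unname(points),
      fiducialIndices = fiducialIndices, pixelSpacingMm = as.numeric(pixelSpacingMm)
    ),
    error = function(e) {
      stop("record ", rec, ": ", conditionMessage(e), call. = FALSE)
    }
  )
}

#' Provenance table of a cohort
#'
#' @param cohort a [ShapeCohort-class].
#' @return data.frame with columns `subjectId`, `side`, `group`,
#'   `readerId`, `repeatIndex`, `nPoints`.
#' @export
cohortInfo <- function(cohort) {
  rs <- if (is(cohort, "ShapeCohort")) cohort@readings else cohort
  data.frame(
    subjectId = vapply(rs, function(r) r@subjectId, character(1)),
    side = vapply(rs, function(r) r@side, character(1)),
    group = vapply(rs, function(r) r@group, character(1)),
    readerId = vapply(rs, function(r) r@readerId, character(1)),
    repeatIndex = vapply(rs, function(r) r@repeatIndex, integer(1)),
    nPoints = vapply(rs, function(r) nrow(r@points), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Construct a cohort from readings
#'
#' Readings are sorted by (subjectId, side, readerId, repeatIndex).
#'
#' @param readings list of [ContourReading-class] objects.
#' @param metadata free-form named list.
#' @return a validated [ShapeCohort-class].
#' @export
ShapeCohort <- function(readings = list(), metadata = list()) {
  if (length(readings)) {
    info <- cohortInfo(readings)
    ord <- order(info$subjectId, info$side, info$readerId, info$repeatIndex)
    readings <- readings[ord]
  }
  obj <- new("ShapeCohort", readings = readings, metadata = metadata)
  validObject(obj)
  obj
}

.readingToRecord <- function(r) {
  list(
    subject_id = r@subjectId, side = r@side, group = r@group,
    reader_id = r@readerId, repeat_index = r@repeatIndex,
    pixel_spacing_mm = r@pixelSpacingMm,
    points = unname(r@points),
    fiducial_indices = r@fiducialIndices
  )
}

.recordToReading <- function(rec, id) {
  need <- c(
    "subject_id", "side", "group", "reader_id", "repeat_index",
    "pixel_spacing_mm", "points", "fiducial_indices"
  )
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop(sprintf(
      "cohort record %s: missing field(s) %s", id,
      paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  pts <- rec$points
  if (is.list(pts)) {
    pts <- do.call(rbind, lapply(pts, function(p) as.numeric(unlist(p))))
  }
  pts <- as.matrix(pts)
  ContourReading(
    subjectId = rec$subject_id, side = rec$side, group = rec$group,
    readerId = rec$reader_id, repeatIndex = rec$repeat_index,
    points = pts, fiducialIndices = unlist(rec$fiducial_indices),
    pixelSpacingMm = rec$pixel_spacing_mm
  )
}

#' Read a cohort annotation file
#'
#' Reads the documented JSON or CSV annotation schema, enforcing all
#' contour invariants (clockwise contours are flipped to counter-clockwise
#' with a message; invalid records abort with the record named).
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; default guessed from the extension.
#' @return a [ShapeCohort-class] with readings sorted by
#'   (subjectId, side, readerId, repeatIndex).
#' @export
readCohort <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(doc$readings)) stop("cohort file ", path, ": missing 'readings'")
    readings <- lapply(seq_along(doc$readings), function(i) {
      .recordToReading(doc$readings[[i]], sprintf("#%d", i))
    })
    meta <- if (is.null(doc$metadata)) list() else doc$metadata
    ShapeCohort(readings, metadata = meta)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c(
      "subject_id", "side", "group", "reader_id", "repeat_index",
      "point_index", "x_mm", "y_mm", "is_fiducial"
    )
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(
        "cohort CSV ", path, ": missing column(s) ",
        paste(miss, collapse = ", ")
      )
    }
    if (!nrow(df)) return(ShapeCohort())
    key <- interaction(df$subject_id, df$side, df$reader_id, df$repeat_index,
      drop = TRUE
    )
    readings <- lapply(split(df, key), function(g) {
      g <- g[order(g$point_index), , drop = FALSE]
      spacing <- if ("pixel_spacing_mm" %in% names(g)) g$pixel_spacing_mm[1] else 1
      ContourReading(
        subjectId = g$subject_id[1], side = g$side[1], group = g$group[1],
        readerId = g$reader_id[1], repeatIndex = g$repeat_index[1],
        points = cbind(g$x_mm, g$y_mm),
        fiducialIndices = which(as.logical(g$is_fiducial)),
        pixelSpacingMm = spacing
      )
    })
    ShapeCohort(unname(readings))
  }
}

#' Write a cohort annotation file
#'
#' Coordinates are written with full double precision (>= 15 significant
#' digits) so that `readCohort(writeCohort(x))` round-trips exactly for
#' both formats.
#'
#' @param cohort a [ShapeCohort-class].
#' @param path output file path.
#' @param format `"json"` or `"csv"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path, format = c("auto", "json", "csv")) {
  stopifnot(is(cohort, "ShapeCohort"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") {
    doc <- list(
      schema_version = COHORT_SCHEMA_VERSION,
      metadata = cohort@metadata,
      readings = lapply(cohort@readings, .readingToRecord)
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- lapply(cohort@readings, function(r) {
      n <- nrow(r@points)
      data.frame(
        subject_id = r@subjectId, side = r@side, group = r@group,
        reader_id = r@readerId, repeat_index = r@repeatIndex,
        point_index = seq_len(n),
        x_mm = r@points[, 1], y_mm = r@points[, 2],
        is_fiducial = as.integer(seq_len(n) %in% r@fiducialIndices),
        pixel_spacing_mm = r@pixelSpacingMm,
        stringsAsFactors = FALSE
      )
    })
    df <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(
        subject_id = character(), side = character(), group = character(),
        reader_id = character(), repeat_index = integer(),
        point_index = integer(), x_mm = numeric(), y_mm = numeric(),
        is_fiducial = integer(), pixel_spacing_mm = numeric()
      )
    }
    # full precision so coordinates survive the round trip
    old <- options(digits = 17, scipen = 100)
    on.exit(options(old))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}
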