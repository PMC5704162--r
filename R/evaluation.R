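# Classification bookkeeping and statistics in the two-view convention
# used for hippocampal screening evaluation: counts are reported per class
# view (controls as positives, subjects as positives), with the mirrored
# convention TN_v = TP_v, FP_C = FN_S, FP_S = FN_C. A textbook convention
# is available behind `mirror = FALSE`.

.checkLabels <- function(x, what) {
  bad <- setdiff(unique(x), c("control", "subject"))
  if (length(bad)) {
    stop(what, " contains unseen label(s): ", paste(bad, collapse = ", "))
  }
}

#' Build confusion counts from truth and predicted labels
#'
#' For each view v, `TP_v` counts members of class v correctly classified
#' and `FN_v` the members of class v misclassified; `FP_v` counts members
#' of the other class classified as v. Under the default mirrored
#' reporting convention `TN_v` is set equal to `TP_v`; with
#' `mirror = FALSE`, `TN_v` is the other class's correct count (textbook
#' convention).
#'
#' @param truth,predicted character vectors of `"control"` / `"subject"`
#'   labels, equal length.
#' @param mirror logical; use the mirrored reporting convention
#'   (default TRUE).
#' @return a [ConfusionCounts-class].
#' @export
confusionFromPredictions <- function(truth, predicted, mirror = TRUE) {
  if (length(truth) != length(predicted)) stop("truth and predicted must have equal length")
  .checkLabels(truth, "truth")
  .checkLabels(predicted, "predicted")
  nC <- sum(truth == "control")
  nS <- sum(truth == "subject")
  tpC <- sum(truth == "control" & predicted == "control")
  tpS <- sum(truth == "subject" & predicted == "subject")
  fnC <- nC - tpC
  fnS <- nS - tpS
  new("ConfusionCounts",
    tpC = tpC, tnC = if (mirror) tpC else tpS, fpC = fnS, fnC = fnC,
    tpS = tpS, tnS = if (mirror) tpS else tpC, fpS = fnC, fnS = fnS,
    nControls = nC, nSubjects = nS
  )
}

#' Assemble confusion counts directly from the eight reported numbers
#'
#' @param tpC,tnC,fpC,fnC,tpS,tnS,fpS,fnS view-wise counts.
#' @return a [ConfusionCounts-class].
#' @export
ConfusionCounts <- function(tpC, tnC, fpC, fnC, tpS, tnS, fpS, fnS) {
  new("ConfusionCounts",
    tpC = as.integer(tpC), tnC = as.integer(tnC), fpC = as.integer(fpC),
    fnC = as.integer(fnC), tpS = as.integer(tpS), tnS = as.integer(tnS),
    fpS = as.integer(fpS), fnS = as.integer(fnS),
    nControls = as.integer(tpC + fnC), nSubjects = as.integer(tpS + fnS)
  )
}

.ratio <- function(num, den) {
  if (den == 0) {
    warning("0/0 metric reported as 1.0 (degenerate counts)")
    return(1)
  }
  num / den
}

#' Per-view classification metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' accuracy (TP+TN)/(TP+TN+FP+FN) over the view's own counts, and
#' F-measure, the harmonic mean of precision and sensitivity. Ratios with
#' zero denominator are reported as 1.0 with a warning (degenerate
#' fixtures only).
#'
#' @param counts a [ConfusionCounts-class].
#' @param view `"C"` (controls as positives) or `"S"` (subjects as
#'   positives).
#' @return named list: `sensitivity`, `specificity`, `precision`,
#'   `accuracy`, `fMeasure`.
#' @export
classMetrics <- function(counts, view = c("C", "S")) {
  stopifnot(is(counts, "ConfusionCounts"))
  view <- match.arg(view)
  g <- function(nm) slot(counts, paste0(nm, view))
  tp <- g("tp"); tn <- g("tn"); fp <- g("fp"); fn <- g("fn")
  sens <- .ratio(tp, tp + fn)
  spec <- .ratio(tn, tn + fp)
  prec <- .ratio(tp, tp + fp)
  acc <- .ratio(tp + tn, tp + tn + fp + fn)
  f <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  list(sensitivity = sens, specificity = spec, precision = prec,
    accuracy = acc, fMeasure = f)
}

#' Overall agreement metrics
#'
#' Percent correct, Cohen's kappa of the 2x2 truth-by-prediction
#' contingency (reconstructed from the counts), the 0/1-loss mean absolute
#' error (misclassified / total) and its square root as RMSE, and relative
#' absolute / root relative squared errors against a prior-probability
#' (majority-prior) baseline predictor whose per-instance absolute error
#' is the prior of the wrong class: baseline MAE `2 p_C p_S`, baseline
#' RMSE `sqrt(p_C p_S)`.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named list: `percentCorrect`, `kappa`, `mae`, `rmse`, `rae`,
#'   `rrse` (the last two in percent).
#' @export
overallMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  nC <- counts@nControls
  nS <- counts@nSubjects
  n <- nC + nS
  if (n == 0L) stop("empty counts")
  correct <- counts@tpC + counts@tpS
  # contingency: truth x prediction
  predC <- counts@tpC + counts@fpC # predicted control = correct C + S-missed-as-C
  predS <- n - predC
  po <- correct / n
  pe <- (nC * predC + nS * predS) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  mae <- (n - correct) / n
  rmse <- sqrt(mae)
  pC <- nC / n
  pS <- nS / n
  baseMae <- 2 * pC * pS
  baseRmse <- sqrt(pC * pS)
  list(
    percentCorrect = 100 * po,
    kappa = kappa,
    mae = mae,
    rmse = rmse,
    rae = if (baseMae > 0) 100 * mae / baseMae else NA_real_,
    rrse = if (baseRmse > 0) 100 * rmse / baseRmse else NA_real_
  )
}

#' Flatten confusion counts and metrics into one report row
#'
#' @param counts a [ConfusionCounts-class].
#' @return one-row data.frame with the eight counts, both views' metrics
#'   (suffix `_C` / `_S`) and the overall statistics.
#' @export
metricsRow <- function(counts) {
  mc <- classMetrics(counts, "C")
  ms <- classMetrics(counts, "S")
  ov <- overallMetrics(counts)
  data.frame(
    TP_C = counts@tpC, TP_S = counts@tpS, TN_C = counts@tnC,
    TN_S = counts@tnS, FP_C = counts@fpC, FP_S = counts@fpS,
    FN_C = counts@fnC, FN_S = counts@fnS,
    sensitivity_C = mc$sensitivity, sensitivity_S = ms$sensitivity,
    specificity_C = mc$specificity, specificity_S = ms$specificity,
    precision_C = mc$precision, precision_S = ms$precision,
    accuracy_C = mc$accuracy, accuracy_S = ms$accuracy,
    fMeasure_C = mc$fMeasure, fMeasure_S = ms$fMeasure,
    percentCorrect = ov$percentCorrect, kappa = ov$kappa,
    mae = ov$mae, rmse = ov$rmse, rae = ov$rae, rrse = ov$rrse
  )
}

#' Polygon area by trapezoidal integration
#'
#' Integrates y dx around the implicitly closed contour with the
#' trapezoidal rule: \eqn{A = \sum_i (x_i - x_{i+1})(y_i + y_{i+1}) / 2},
#' returned as a positive area for a simple polygon.
#'
#' @param points numeric n x 2 matrix of vertices (closed by convention).
#' @return area in squared coordinate units.
#' @export
polygonAreaTrapezoid <- function(points) {
  x <- points[, 1]
  y <- points[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum((x - xn) * (y + yn)) / 2)
}

#' Area-based screening benchmark
#'
#' The conventional single-measurement benchmark the shape model is
#' compared against: per subject and side, the contour areas of all
#' readings (trapezoidal integration) are averaged in Cartesian space;
#' each group's areas are summarized by a fitted Gaussian, and the overlap
#' count is the number of subjects misclassified by the two-Gaussian
#' likelihood-ratio rule (unequal variances) -- the subjects falling in
#' the ambiguous overlap of the two area distributions.
#'
#' @param cohort a [ShapeCohort-class].
#' @return named list with one entry per side: a list holding `areas`
#'   (data.frame `subjectId`, `group`, `area`), `fit` (per-group mean and
#'   sd), and `overlapCount`.
#' @export
areaBenchmark <- function(cohort) {
  stopifnot(is(cohort, "ShapeCohort"))
  info <- cohortInfo(cohort)
  areas <- vapply(cohort@readings, function(r) polygonAreaTrapezoid(r@points), numeric(1))
  out <- lapply(split(seq_len(nrow(info)), info$side), function(idx) {
    sub <- info[idx, , drop = FALSE]
    a <- areas[idx]
    key <- sub$subjectId
    perSubj <- tapply(a, key, mean)
    grp <- tapply(sub$group, key, function(g) g[1])
    df <- data.frame(
      subjectId = names(perSubj),
      group = as.character(grp[names(perSubj)]),
      area = as.numeric(perSubj), stringsAsFactors = FALSE
    )
    fit <- do.call(rbind, lapply(split(df$area, df$group), function(v) {
      data.frame(mean = mean(v), sd = stats::sd(v))
    }))
    muC <- fit["control", "mean"]; sdC <- fit["control", "sd"]
    muS <- fit["subject", "mean"]; sdS <- fit["subject", "sd"]
    if (is.na(sdC) || is.na(sdS) || sdC == 0 || sdS == 0) {
      stop("area benchmark needs at least 2 subjects per group")
    }
    llr <- stats::dnorm(df$area, muS, sdS, log = TRUE) -
      stats::dnorm(df$area, muC, sdC, log = TRUE)
    pred <- ifelse(llr > 0, "subject", "control")
    list(areas = df, fit = fit, overlapCount = sum(pred != df$group))
  })
  out
}
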