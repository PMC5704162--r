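# Linear-kernel SVM discrimination on truncated shape parameters, the
# mode-count sweep, and the averaged-indices operating optimum.
#
# Label encoding: control = -1, early-AD subject = +1. A decision value of
# exactly zero is mapped to the control class.

#' Train a soft-margin linear SVM on shape parameters
#'
#' Trains on the first M columns of the parameter matrix with a linear
#' kernel \eqn{K(s) = \gamma s + \beta} (defaults \eqn{\gamma = 1},
#' \eqn{\beta = 0}). Parameters are standardized (per-column mean and
#' standard deviation, stored in the model and re-applied at prediction
#' time) before the soft-margin fit, so the cost default of 1 is
#' scale-free -- aligned-shape parameters live on the unit-centroid-size
#' scale, where an unstandardized margin penalty would swamp the hinge
#' loss. Rows are sorted canonically before training, so the fit is
#' deterministic and independent of input order. The quadratic program is
#' solved by libsvm (via e1071) to tolerance 1e-6 with no randomized
#' heuristics.
#'
#' @param params numeric matrix of shape parameters, one sample per row.
#' @param labels `"control"` / `"subject"` labels, one per row.
#' @param M number of leading parameters to use (default: all columns).
#' @param cost soft-margin cost C (default 1).
#' @param side side label stored in the model.
#' @return a [LinearSVMModel-class].
#' @export
trainLinearSVM <- function(params, labels, M = NULL, cost = 1, side = "left") {
  X <- as.matrix(params)
  if (is.null(M)) M <- ncol(X)
  M <- as.integer(M)
  if (M < 1L || M > ncol(X)) stop("M out of range 1..", ncol(X))
  .checkLabels(labels, "labels")
  if (length(unique(labels)) < 2L) stop("both classes must be present for training")
  X <- X[, seq_len(M), drop = FALSE]
  ord <- do.call(order, c(as.data.frame(X), list(labels)))
  X <- X[ord, , drop = FALSE]
  labels <- labels[ord]
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  y <- factor(labels, levels = c("control", "subject"))
  fit <- e1071::svm(Xs, y,
    kernel = "linear", cost = cost, scale = FALSE,
    tolerance = 1e-6, shrinking = TRUE
  )
  # libsvm orients decision values positive towards its first stored label
  firstLabel <- fit$levels[fit$labels[1]]
  sgn <- if (firstLabel == "subject") 1 else -1
  new("LinearSVMModel",
    supportCoefficients = sgn * as.vector(fit$coefs),
    supportVectors = unname(as.matrix(fit$SV)),
    bias = sgn * (-fit$rho),
    kernelSlope = 1, kernelIntercept = 0,
    M = M, side = side, cost = cost,
    center = unname(ctr), scaleFactors = unname(scl)
  )
}

#' SVM decision values
#'
#' \eqn{f(x) = \sum_i \alpha_i y_i K(x_i \cdot x) + b} with
#' \eqn{K(s) = \gamma s + \beta}, evaluated in the model's standardized
#' parameter space (the stored per-column centre and scale are applied to
#' `x` first); positive values indicate the early-AD subject class.
#'
#' @param model a [LinearSVMModel-class].
#' @param x parameter vector of length M, or matrix with one sample per
#'   row.
#' @return numeric decision value(s).
#' @export
decisionValues <- function(model, x) {
  stopifnot(is(model, "LinearSVMModel"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != model@M) {
    stop("parameter dimension ", ncol(X), " does not match model M = ", model@M)
  }
  X <- sweep(sweep(X, 2L, model@center), 2L, model@scaleFactors, `/`)
  Kmat <- model@kernelSlope * X %*% t(model@supportVectors) + model@kernelIntercept
  d <- as.vector(Kmat %*% model@supportCoefficients) + model@bias
  if (single) d[1] else d
}

#' Classify shape parameters
#'
#' Sign of the decision value: positive maps to `"subject"`, negative to
#' `"control"`; an exact zero maps to `"control"` (documented tie-break).
#'
#' @param model a [LinearSVMModel-class].
#' @param x parameter vector or matrix (samples in rows).
#' @return character label(s).
#' @export
classifyShapes <- function(model, x) {
  d <- decisionValues(model, x)
  ifelse(d > 0, "subject", "control")
}

#' Sweep the SVM over mode counts M = 1..Mmax
#'
#' For each M, trains the linear SVM on the first M consensus shape
#' parameters and evaluates it, recording the confusion counts and the
#' full metrics row. Resubstitution (the default) evaluates on the
#' training set itself, which is optimistic by construction; seeded
#' k-fold cross-validation is provided as the honest alternative.
#'
#' @param consensus a [ConsensusSet-class] (or a list with `params` matrix
#'   and `group` labels).
#' @param Mmax largest mode count to sweep (default 10, capped at the
#'   parameter count).
#' @param evaluation `"resubstitution"` or `"k_fold"`.
#' @param cost soft-margin cost (default 1).
#' @param k number of folds for `"k_fold"` (default 5).
#' @param seed integer seed for the fold split.
#' @param side side label recorded in the result.
#' @return a [ModeSweepResult-class].
#' @export
modeSweep <- function(consensus, Mmax = 10L,
                      evaluation = c("resubstitution", "k_fold"),
                      cost = 1, k = 5L, seed = 1L, side = NULL) {
  evaluation <- match.arg(evaluation)
  if (is(consensus, "ConsensusSet")) {
    P <- consensus@params
    labels <- consensus@info$group
    if (is.null(side)) {
      sides <- unique(consensus@info$side)
      side <- if (length(sides) == 1L) sides else "both"
    }
  } else {
    P <- as.matrix(consensus$params)
    labels <- consensus$group
    if (is.null(side)) side <- "left"
  }
  Mmax <- min(as.integer(Mmax), ncol(P))
  n <- nrow(P)
  folds <- NULL
  if (evaluation == "k_fold") {
    rng <- .seededRNG(seed)
    folds <- sample(rep_len(seq_len(k), n))
    .restoreRNG(rng)
  }
  countsList <- vector("list", Mmax)
  rows <- vector("list", Mmax)
  for (M in seq_len(Mmax)) {
    pred <- character(n)
    if (evaluation == "resubstitution") {
      fit <- trainLinearSVM(P, labels, M = M, cost = cost, side = side)
      pred <- classifyShapes(fit, P[, seq_len(M), drop = FALSE])
    } else {
      for (f in seq_len(k)) {
        test <- folds == f
        fit <- trainLinearSVM(P[!test, , drop = FALSE], labels[!test],
          M = M, cost = cost, side = side
        )
        pred[test] <- classifyShapes(fit, P[test, seq_len(M), drop = FALSE])
      }
    }
    counts <- confusionFromPredictions(labels, pred)
    countsList[[M]] <- counts
    rows[[M]] <- cbind(M = M, metricsRow(counts))
  }
  new("ModeSweepResult",
    table = do.call(rbind, rows), counts = countsList,
    evaluation = evaluation, side = side
  )
}

#' Select the operating mode count from a sweep
#'
#' `"averaged_indices"` (the default) averages sensitivity, specificity,
#' precision, accuracy and F-measure over both class views for each M and
#' returns the smallest M attaining the maximum (ties break to the
#' simplest model). `"first_convergence"` returns the first M from which
#' the averaged index never changes again.
#'
#' @param sweep a [ModeSweepResult-class].
#' @param rule `"averaged_indices"` or `"first_convergence"`.
#' @return integer M.
#' @export
selectOptimum <- function(sweep, rule = c("averaged_indices", "first_convergence")) {
  stopifnot(is(sweep, "ModeSweepResult"))
  rule <- match.arg(rule)
  tab <- sweep@table
  if (!nrow(tab)) stop("empty sweep")
  cols <- c(
    "sensitivity_C", "sensitivity_S", "specificity_C", "specificity_S",
    "precision_C", "precision_S", "accuracy_C", "accuracy_S",
    "fMeasure_C", "fMeasure_S"
  )
  idx <- rowMeans(tab[, cols])
  if (rule == "averaged_indices") {
    as.integer(tab$M[which.max(idx)])
  } else {
    last <- idx[length(idx)]
    stable <- rev(cumprod(rev(abs(idx - last) < 1e-12))) == 1
    as.integer(tab$M[which(stable)[1]])
  }
}

#' Write a mode-sweep metrics table to CSV
#'
#' One row per mode count with the eight confusion counts, both views'
#' metrics and the overall statistics, mirroring the conventional layout
#' of published sweep tables.
#'
#' @param sweep a [ModeSweepResult-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSweepCSV <- function(sweep, path) {
  stopifnot(is(sweep, "ModeSweepResult"))
  utils::write.csv(sweep@table, path, row.names = FALSE)
  invisible(path)
}
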