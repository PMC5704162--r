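# Pipeline chaining and stage runner. The R functions are the primary
# interface; runStage() gives each stage a file-in / file-out form so the
# whole analysis can be scripted (see inst/scripts/hippomorph-cli.R for a
# thin command-line wrapper).

#' Run the full shape-analysis pipeline on one side of a cohort
#'
#' Chains resampling, generalized Procrustes alignment, shape-model
#' fitting, model-space consensus and the SVM mode sweep.
#'
#' @param cohort a [ShapeCohort-class].
#' @param side `"left"` or `"right"`.
#' @param nPoints regularized control points (default 20).
#' @param varianceFraction explained-variance threshold for the reported
#'   mode count (default 0.95).
#' @param Mmax sweep limit (default 10).
#' @param cost SVM soft-margin cost (default 1).
#' @param evaluation `"resubstitution"` (the historical protocol;
#'   optimistic) or `"k_fold"`.
#' @param seed seed for the k-fold split (unused under resubstitution).
#' @return list: `shapeSet`, `aligned`, `model`, `modes95`, `consensus`,
#'   `sweep`, `optimumM`.
#' @export
runPipeline <- function(cohort, side = "left", nPoints = 20L,
                        varianceFraction = 0.95, Mmax = 10L, cost = 1,
                        evaluation = c("resubstitution", "k_fold"),
                        seed = 1L) {
  evaluation <- match.arg(evaluation)
  shapeSet <- resampleCohort(cohort, nPoints = nPoints, side = side)
  aligned <- generalizedProcrustes(shapeSet)
  model <- fitShapeModel(aligned)
  m95 <- chooseModes(model, varianceFraction)
  Mcons <- min(max(as.integer(Mmax), m95), ncol(model@basis))
  consensus <- consensusBySubject(model, aligned, M = Mcons)
  sweep <- modeSweep(consensus,
    Mmax = Mmax, evaluation = evaluation, cost = cost, seed = seed
  )
  list(
    shapeSet = shapeSet, aligned = aligned, model = model, modes95 = m95,
    consensus = consensus, sweep = sweep, optimumM = selectOptimum(sweep)
  )
}

#' Assemble a pipeline configuration
#'
#' Flat key/value configuration, optionally loaded from a YAML file with
#' explicit overrides taking precedence.
#'
#' @param file optional YAML file of flat keys.
#' @param ... overrides (e.g. `cohort_in = "c.json"`, `seed = 7`).
#' @return named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(file = NULL, ...) {
  cfg <- list(
    cohort_in = NULL, cohort_out = NULL, truth_out = NULL,
    shapes_in = NULL, shapes_out = NULL,
    aligned_in = NULL, aligned_out = NULL,
    model_in = NULL, model_out = NULL,
    consensus_in = NULL, consensus_out = NULL,
    counts_in = NULL, metrics_out = NULL, report_out = NULL,
    n_points = 20L, variance_fraction = 0.95, m_max = 10L,
    evaluation = "resubstitution", cost = 1, seed = 1L, side = NULL
  )
  if (!is.null(file)) {
    fromFile <- yaml::read_yaml(file)
    cfg[names(fromFile)] <- fromFile
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "PipelineConfig")
}

.sidesOf <- function(info, cfg) {
  if (!is.null(cfg$side)) cfg$side else sort(unique(info$side))
}

.shapeSetToList <- function(x) {
  out <- list(
    shapes = unname(x@shapes), info = x@info,
    n_points = x@nPoints, fiducial_slots = x@fiducialSlots
  )
  if (is(x, "AlignedShapes")) {
    out$mean_shape <- x@meanShape
    out$transforms <- x@transforms
    out$iterations <- x@iterations
    out$converged <- x@converged
  }
  out
}

.listToShapeSet <- function(l) {
  info <- as.data.frame(l$info, stringsAsFactors = FALSE)
  base <- list(
    shapes = as.matrix(l$shapes), info = info,
    nPoints = as.integer(l$n_points),
    fiducialSlots = as.integer(l$fiducial_slots)
  )
  if (!is.null(l$mean_shape)) {
    do.call(new, c(list("AlignedShapes"), base, list(
      meanShape = as.numeric(l$mean_shape),
      transforms = as.data.frame(l$transforms),
      iterations = as.integer(l$iterations),
      converged = as.logical(l$converged)
    )))
  } else {
    do.call(new, c(list("ShapeSet"), base))
  }
}

.writeSided <- function(objs, path, toList) {
  jsonlite::write_json(lapply(objs, toList), path,
    auto_unbox = TRUE, digits = NA
  )
}

.readSided <- function(path, fromList) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyMatrix = TRUE)
  lapply(doc, fromList)
}

.modelToList <- function(m) {
  list(
    side = m@side, n_points = m@nPoints, fiducial_slots = m@fiducialSlots,
    n_samples = m@nSamples, mean_shape = m@meanShape,
    eigenvalues = m@eigenvalues, basis = unname(m@basis)
  )
}

.listToModel <- function(l) {
  new("ShapeModel",
    meanShape = as.numeric(l$mean_shape), basis = as.matrix(l$basis),
    eigenvalues = as.numeric(l$eigenvalues),
    nSamples = as.integer(l$n_samples), side = l$side,
    nPoints = as.integer(l$n_points),
    fiducialSlots = as.integer(l$fiducial_slots)
  )
}

.consensusToList <- function(x) {
  list(
    params = unname(x@params), shapes = unname(x@shapes), info = x@info,
    M = x@M, n_points = x@nPoints, fiducial_slots = x@fiducialSlots
  )
}

.listToConsensus <- function(l) {
  new("ConsensusSet",
    params = as.matrix(l$params), shapes = as.matrix(l$shapes),
    info = as.data.frame(l$info, stringsAsFactors = FALSE),
    M = as.integer(l$M), nPoints = as.integer(l$n_points),
    fiducialSlots = as.integer(l$fiducial_slots)
  )
}

.needs <- function(cfg, keys, stage) {
  miss <- keys[vapply(keys, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(miss)) {
    stop("stage '", stage, "' needs config key(s): ", paste(miss, collapse = ", "))
  }
}

.logStage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste(sprintf(...), collapse = "")))
}

.writeResolvedConfig <- function(cfg, outPath) {
  dest <- file.path(dirname(outPath), paste0(
    sub("\\.[A-Za-z]+$", "", basename(outPath)), ".resolved-config.yaml"
  ))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], dest)
}

#' Run one named pipeline stage with file artifacts
#'
#' Stages: `simulate` (write a synthetic cohort plus ground-truth
#' sidecar), `resample`, `align`, `fit`, `consensus`, `sweep` (metrics
#' CSV with one block of M rows per side), `evaluate` (metrics CSV from a
#' CSV of confusion counts), `report` (plain-text summary of a metrics
#' CSV). Each stage logs its parameters and counts, writes a resolved
#' configuration copy next to its main output, and stops with an error on
#' missing inputs.
#'
#' @param name stage name.
#' @param config a [pipelineConfig()].
#' @return the stage's main output path, invisibly.
#' @export
runStage <- function(name = c(
                       "simulate", "resample", "align", "fit",
                       "consensus", "sweep", "evaluate", "report"
                     ),
                     config = pipelineConfig()) {
  name <- match.arg(name)
  cfg <- config
  out <- switch(name,
    simulate = {
      .needs(cfg, "cohort_out", name)
      sides <- if (is.null(cfg$side)) c("left", "right") else cfg$side
      gen <- generateCohort(simulationConfig(seed = cfg$seed, sides = sides))
      writeCohort(gen$cohort, cfg$cohort_out)
      if (!is.null(cfg$truth_out)) {
        jsonlite::write_json(gen$truth[c("subjects", "readings")],
          cfg$truth_out,
          auto_unbox = TRUE, digits = NA
        )
      }
      .logStage(name, "%d readings, seed %d", nShapes(gen$cohort), cfg$seed)
      cfg$cohort_out
    },
    resample = {
      .needs(cfg, c("cohort_in", "shapes_out"), name)
      cohort <- readCohort(cfg$cohort_in)
      info <- cohortInfo(cohort)
      sides <- .sidesOf(info, cfg)
      sets <- lapply(sides, function(s) {
        resampleCohort(cohort, nPoints = cfg$n_points, side = s)
      })
      names(sets) <- sides
      .writeSided(sets, cfg$shapes_out, .shapeSetToList)
      .logStage(name, "%s side(s), N = %d", paste(sides, collapse = "+"), cfg$n_points)
      cfg$shapes_out
    },
    align = {
      .needs(cfg, c("shapes_in", "aligned_out"), name)
      sets <- .readSided(cfg$shapes_in, .listToShapeSet)
      aligned <- lapply(sets, generalizedProcrustes)
      .writeSided(aligned, cfg$aligned_out, .shapeSetToList)
      .logStage(name, "%d set(s) aligned", length(aligned))
      cfg$aligned_out
    },
    fit = {
      .needs(cfg, c("aligned_in", "model_out"), name)
      aligned <- .readSided(cfg$aligned_in, .listToShapeSet)
      models <- lapply(aligned, fitShapeModel)
      jsonlite::write_json(lapply(models, .modelToList), cfg$model_out,
        auto_unbox = TRUE, digits = NA
      )
      .logStage(name, "%d model(s) fitted", length(models))
      cfg$model_out
    },
    consensus = {
      .needs(cfg, c("aligned_in", "model_in", "consensus_out"), name)
      aligned <- .readSided(cfg$aligned_in, .listToShapeSet)
      models <- .readSided(cfg$model_in, .listToModel)
      cons <- lapply(names(aligned), function(s) {
        model <- models[[s]]
        m95 <- chooseModes(model, cfg$variance_fraction)
        M <- min(max(cfg$m_max, m95), ncol(model@basis))
        consensusBySubject(model, aligned[[s]], M = M)
      })
      names(cons) <- names(aligned)
      .writeSided(cons, cfg$consensus_out, .consensusToList)
      .logStage(name, "%d side(s)", length(cons))
      cfg$consensus_out
    },
    sweep = {
      .needs(cfg, c("consensus_in", "metrics_out"), name)
      cons <- .readSided(cfg$consensus_in, .listToConsensus)
      tabs <- lapply(names(cons), function(s) {
        sw <- modeSweep(cons[[s]],
          Mmax = cfg$m_max, evaluation = cfg$evaluation,
          cost = cfg$cost, seed = cfg$seed, side = s
        )
        cbind(side = s, sw@table)
      })
      tab <- do.call(rbind, tabs)
      utils::write.csv(tab, cfg$metrics_out, row.names = FALSE)
      .logStage(name, "%d rows", nrow(tab))
      cfg$metrics_out
    },
    evaluate = {
      .needs(cfg, c("counts_in", "metrics_out"), name)
      df <- utils::read.csv(cfg$counts_in)
      need <- c("TP_C", "TP_S", "TN_C", "TN_S", "FP_C", "FP_S", "FN_C", "FN_S")
      miss <- setdiff(need, names(df))
      if (length(miss)) {
        stop("counts file missing column(s): ", paste(miss, collapse = ", "))
      }
      rows <- lapply(seq_len(nrow(df)), function(i) {
        counts <- ConfusionCounts(
          df$TP_C[i], df$TN_C[i], df$FP_C[i], df$FN_C[i],
          df$TP_S[i], df$TN_S[i], df$FP_S[i], df$FN_S[i]
        )
        metricsRow(counts)
      })
      keep <- intersect(c("side", "M"), names(df))
      tab <- cbind(df[keep], do.call(rbind, rows))
      utils::write.csv(tab, cfg$metrics_out, row.names = FALSE)
      .logStage(name, "%d rows evaluated", nrow(tab))
      cfg$metrics_out
    },
    report = {
      .needs(cfg, c("counts_in", "report_out"), name)
      tab <- utils::read.csv(cfg$counts_in)
      lines <- c(
        sprintf("metrics report (%d rows)", nrow(tab)),
        utils::capture.output(print(tab))
      )
      writeLines(lines, cfg$report_out)
      .logStage(name, "written")
      cfg$report_out
    }
  )
  .writeResolvedConfig(cfg, out)
  invisible(out)
}
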