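#' Reference confusion counts from a clinical mode sweep
#'
#' The published per-mode confusion counts (both class views, mirrored
#' reporting convention) of a bilateral hippocampal SVM mode sweep on a
#' 63-participant cohort (30 controls, 33 early-AD subjects), shipped as
#' a plain CSV. These counts are the canonical input for validating the
#' metric conventions in [classMetrics()] and [overallMetrics()]; the
#' underlying clinical contours are not public, so only the counts are
#' reproduced here.
#'
#' @return data.frame with columns `side`, `M`, `TP_C`, `TP_S`, `TN_C`,
#'   `TN_S`, `FP_C`, `FP_S`, `FN_C`, `FN_S` (20 rows: M = 1..10 per
#'   side).
#' @export
referenceSweepCounts <- function() {
  path <- system.file("extdata", "reference_sweep_counts.csv",
    package = "hippoMorph", mustWork = TRUE
  )
  utils::read.csv(path, stringsAsFactors = FALSE)
}
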