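# Seed plumbing: all simulation randomness flows from one user seed
# through documented integer substreams (per subject / side / reader /
# repeat), so any part of a cohort can be regenerated stably. The global
# RNG state is always saved and restored.

.seededRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# sample n values from a vector without the length-1 expansion surprise
.sampleFrom <- function(vals, n = 1L) {
  vals[sample.int(length(vals), n, replace = TRUE)]
}

# deterministic substream id below 2^31 from a base seed and indices
.substream <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629 # largest prime below 2^31
  h <- as.numeric(seed) %% m
  for (v in idx) {
    h <- (h * 69069 + as.numeric(v) + 1) %% m
  }
  as.integer(h)
}
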