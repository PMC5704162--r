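test_that("confusion counts follow the mirrored two-view convention", {
  truth <- rep(c("control", "subject"), c(30L, 33L))
  pred <- truth
  pred[33L] <- "control" # one subject missed
  cc <- confusionFromPredictions(truth, pred)
  expect_identical(
    c(cc@tpC, cc@tpS, cc@tnC, cc@tnS, cc@fpC, cc@fpS, cc@fnC, cc@fnS),
    c(30L, 32L, 30L, 32L, 1L, 0L, 0L, 1L)
  )
  # all correct: no false counts anywhere
  allOk <- confusionFromPredictions(truth, truth)
  expect_identical(c(allOk@fpC, allOk@fpS, allOk@fnC, allOk@fnS), rep(0L, 4L))
  # degenerate predictor: everything called subject
  allS <- confusionFromPredictions(truth, rep("subject", 63L))
  expect_identical(c(allS@tpC, allS@fnC, allS@fpS), c(0L, 30L, 30L))
  expect_error(confusionFromPredictions(truth, rep("ad", 63L)), "unseen")
  # textbook convention differs only in TN
  std <- confusionFromPredictions(truth, pred, mirror = FALSE)
  expect_identical(std@tnC, 32L)
  expect_identical(std@tnS, 30L)
})

test_that("per-view metrics reproduce the reference 3- and 7-mode rows", {
  cc3 <- ConfusionCounts(29, 29, 2, 1, 31, 31, 1, 2)
  m3 <- classMetrics(cc3, "C")
  expect_equal(m3$sensitivity, 29 / 30, tolerance = 1e-12)
  expect_equal(round(m3$precision, 3), 0.935)
  expect_equal(round(m3$accuracy, 3), 0.951)
  cc7 <- ConfusionCounts(29, 29, 0, 1, 33, 33, 1, 0)
  m7 <- classMetrics(cc7, "C")
  expect_equal(m7$specificity, 1)
  expect_equal(round(m7$fMeasure, 3), 0.983)
  perfect <- ConfusionCounts(30, 30, 0, 0, 33, 33, 0, 0)
  mp <- classMetrics(perfect, "S")
  expect_true(all(unlist(mp) == 1))
})

test_that("every reference count row reproduces its printed metrics", {
  counts <- referenceSweepCounts()
  expected <- referenceClassMetrics()
  for (i in seq_len(nrow(counts))) {
    cc <- ConfusionCounts(
      counts$TP_C[i], counts$TN_C[i], counts$FP_C[i], counts$FN_C[i],
      counts$TP_S[i], counts$TN_S[i], counts$FP_S[i], counts$FN_S[i]
    )
    for (view in c("C", "S")) {
      m <- classMetrics(cc, view)
      got <- c(m$sensitivity, m$specificity, m$precision, m$accuracy, m$fMeasure)
      want <- as.numeric(expected[
        i, paste0(c("sens_", "spec_", "prec_", "acc_", "f_"), view)
      ])
      # agree with the printed 3-decimal values to half a printed unit
      expect_lt(max(abs(got - want)), 5.01e-4,
        label = sprintf("row %d view %s metric deviation", i, view)
      )
    }
  }
})

test_that("overall statistics reproduce the reference 3-mode values", {
  left <- ConfusionCounts(29, 29, 2, 1, 31, 31, 1, 2)
  ovL <- overallMetrics(left)
  expect_equal(round(ovL$percentCorrect, 4), 95.2381)
  expect_equal(round(ovL$kappa, 4), 0.9047)
  expect_equal(round(ovL$mae, 4), 0.0476)
  expect_equal(round(ovL$rmse, 4), 0.2182)
  right <- ConfusionCounts(30, 30, 1, 0, 32, 32, 0, 1)
  ovR <- overallMetrics(right)
  expect_equal(round(ovR$percentCorrect, 4), 98.4127)
  expect_equal(round(ovR$kappa, 4), 0.9682)
  expect_equal(round(ovR$mae, 4), 0.0159)
  expect_equal(round(ovR$rmse, 4), 0.1260)
  # 0/1-loss identities
  expect_equal(ovL$mae, 1 - ovL$percentCorrect / 100)
  expect_equal(ovL$rmse, sqrt(ovL$mae))
  # prior-probability baseline: close to (but not exactly) the published
  # tool-specific relative errors
  expect_equal(ovL$rae, 100 * (3 / 63) / (2 * (30 / 63) * (33 / 63)),
    tolerance = 1e-12
  )
  expect_lt(abs(ovL$rae - 9.54), 0.05)
  expect_lt(abs(ovL$rrse - 43.69), 0.05)
})

test_that("kappa is bounded, perfect only without errors, and null under chance", {
  perfect <- ConfusionCounts(30, 30, 0, 0, 33, 33, 0, 0)
  expect_equal(overallMetrics(perfect)$kappa, 1)
  imperfect <- ConfusionCounts(29, 29, 0, 1, 33, 33, 1, 0)
  expect_lt(overallMetrics(imperfect)$kappa, 1)
  set.seed(41)
  n <- 10000L
  truth <- sample(c("control", "subject"), n, replace = TRUE)
  pred <- sample(c("control", "subject"), n, replace = TRUE, prob = c(0.6, 0.4))
  k <- overallMetrics(confusionFromPredictions(truth, pred))$kappa
  expect_lt(abs(k), 0.05)
})

test_that("trapezoidal polygon area matches the shoelace oracle", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygonAreaTrapezoid(square), 1)
  shoelace <- function(P) {
    x <- P[, 1]; y <- P[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1L)
    r <- stats::runif(n, 1, 4)
    th <- sort(stats::runif(n, 0, 2 * pi))
    P <- cbind(r * cos(th), r * sin(th))
    expect_equal(polygonAreaTrapezoid(P), shoelace(P), tolerance = 1e-12)
  }
})

test_that("the area benchmark separates groups imperfectly, as designed", {
  bench <- areaBenchmark(sharedGen()$cohort)
  left <- bench$left
  expect_equal(nrow(left$areas), 63L)
  expect_lt(left$fit["subject", "mean"], left$fit["control", "mean"])
  expect_gt(left$overlapCount, 0L)
  expect_lt(left$overlapCount, 32L)
})

test_that("equal area distributions leave about half the cohort ambiguous", {
  bench <- areaBenchmark(sharedNullGen()$cohort)
  oc <- bench$left$overlapCount
  # binomial 95% band around 31.5 of 63
  expect_gte(oc, 24L)
  expect_lte(oc, 40L)
})
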