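sepClouds <- function(gap = 4, n1 = 30L, n2 = 33L, sd = 0.5, seed = 31L) {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(2 * n1, -gap / 2, sd), ncol = 2L),
    matrix(stats::rnorm(2 * n2, gap / 2, sd), ncol = 2L)
  )
  list(X = X, y = rep(c("control", "subject"), c(n1, n2)))
}

test_that("well-separated clouds are classified perfectly at resubstitution", {
  d <- sepClouds()
  fit <- trainLinearSVM(d$X, d$y)
  expect_equal(mean(classifyShapes(fit, d$X) == d$y), 1)
})

test_that("the XOR arrangement admits no linear separator", {
  X <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  y <- c("control", "control", "subject", "subject")
  fit <- trainLinearSVM(X, y, cost = 100)
  expect_lte(mean(classifyShapes(fit, X) == y), 0.75)
})

test_that("decision values match the stored dual form recomputed by hand", {
  d <- sepClouds(gap = 2, sd = 1)
  fit <- trainLinearSVM(d$X, d$y)
  # independent arithmetic straight from the slots
  Xs <- sweep(sweep(d$X, 2L, fit@center), 2L, fit@scaleFactors, `/`)
  manual <- vapply(seq_len(nrow(Xs)), function(j) {
    k <- fit@kernelSlope * (fit@supportVectors %*% Xs[j, ]) + fit@kernelIntercept
    sum(fit@supportCoefficients * k) + fit@bias
  }, numeric(1))
  expect_equal(decisionValues(fit, d$X), manual, tolerance = 1e-9)
})

test_that("support vectors on the positive side carry their own label", {
  d <- sepClouds()
  fit <- trainLinearSVM(d$X, d$y)
  sv <- fit@supportVectors # standardized space
  svOrig <- sweep(sweep(sv, 2L, fit@scaleFactors, `*`), 2L, fit@center, `+`)
  pred <- classifyShapes(fit, svOrig)
  expect_equal(pred, ifelse(fit@supportCoefficients > 0, "subject", "control"))
})

test_that("a decision value of exactly zero maps to the control class", {
  fit <- new("LinearSVMModel",
    supportCoefficients = c(1, -1),
    supportVectors = rbind(c(1, 0), c(-1, 0)),
    bias = 0, kernelSlope = 1, kernelIntercept = 0,
    M = 2L, side = "left", cost = 1,
    center = c(0, 0), scaleFactors = c(1, 1)
  )
  expect_equal(decisionValues(fit, c(0, 5)), 0)
  expect_equal(classifyShapes(fit, c(0, 5)), "control")
  expect_equal(classifyShapes(fit, c(0.5, 0)), "subject")
})

test_that("flipping all training labels flips every prediction", {
  d <- sepClouds(gap = 2, sd = 1)
  flip <- c(control = "subject", subject = "control")
  f1 <- trainLinearSVM(d$X, d$y)
  f2 <- trainLinearSVM(d$X, unname(flip[d$y]))
  set.seed(32)
  probe <- matrix(stats::rnorm(40), ncol = 2L)
  expect_equal(
    unname(flip[classifyShapes(f1, probe)]),
    classifyShapes(f2, probe)
  )
})

test_that("training is deterministic and order-independent", {
  d <- sepClouds(gap = 1.5, sd = 1)
  f1 <- trainLinearSVM(d$X, d$y)
  set.seed(33)
  perm <- sample(length(d$y))
  f2 <- trainLinearSVM(d$X[perm, ], d$y[perm])
  expect_equal(f1@supportVectors, f2@supportVectors)
  expect_equal(f1@supportCoefficients, f2@supportCoefficients)
  expect_equal(f1@bias, f2@bias)
})

test_that("single-class input is rejected", {
  expect_error(
    trainLinearSVM(matrix(1:8, ncol = 2L), rep("control", 4L)),
    "both classes"
  )
})

test_that("a looser margin penalty never fits the training data worse", {
  d <- sepClouds(gap = 1.2, sd = 1, n1 = 20L, n2 = 20L, seed = 39L)
  yNum <- ifelse(d$y == "subject", 1, -1)
  costs <- c(0.01, 0.1, 1, 10, 100)
  fits <- lapply(costs, function(co) trainLinearSVM(d$X, d$y, cost = co))
  # 0/1 resubstitution accuracy on this fixed fixture
  acc <- vapply(fits, function(f) mean(classifyShapes(f, d$X) == d$y), numeric(1))
  expect_true(all(diff(acc) >= 0))
  # and the guaranteed soft-margin property: total hinge slack shrinks
  hinge <- vapply(fits, function(f) {
    sum(pmax(0, 1 - yNum * decisionValues(f, d$X)))
  }, numeric(1))
  expect_true(all(diff(hinge) <= 1e-8))
})

test_that("the mode sweep covers M = 1..Mmax and is reproducible", {
  pipe <- sharedPipeline()
  sw <- pipe$sweep
  expect_s4_class(sw, "ModeSweepResult")
  expect_identical(sw@table$M, 1:10)
  sw2 <- modeSweep(pipe$consensus, Mmax = 10L)
  expect_identical(sw@table, sw2@table)
})

test_that("accuracy rises to the latent dimension then plateaus", {
  pipe <- sharedPipeline()
  acc <- (pipe$sweep@table$TP_C + pipe$sweep@table$TP_S) / 63
  # non-decreasing up to the 2 generative modes, within one sample
  expect_gte(acc[2], acc[1] - 1 / 63)
  # the default effect sizes support strong resubstitution accuracy by M <= 7
  expect_gte(max(acc[1:7]), 0.95)
})

sweepFromErrors <- function(errC, errS, nC = 30L, nS = 33L) {
  counts <- lapply(seq_along(errC), function(i) {
    ConfusionCounts(
      nC - errC[i], nC - errC[i], errS[i], errC[i],
      nS - errS[i], nS - errS[i], errC[i], errS[i]
    )
  })
  tab <- do.call(rbind, lapply(seq_along(counts), function(i) {
    cbind(M = i, metricsRow(counts[[i]]))
  }))
  new("ModeSweepResult",
    table = tab, counts = counts,
    evaluation = "resubstitution", side = "left"
  )
}

test_that("the averaged-indices rule picks the plateau onset", {
  # strictly improving until M = 7, flat afterwards
  sw <- sweepFromErrors(c(6, 5, 4, 3, 2, 1, 0, 0, 0, 0), rep(1, 10L))
  expect_identical(selectOptimum(sw), 7L)
  # all-identical rows tie-break to the simplest model
  swFlat <- sweepFromErrors(rep(2, 5L), rep(1, 5L))
  expect_identical(selectOptimum(swFlat), 1L)
  # a drop at the last M (overfitting signature) is never selected
  swDrop <- sweepFromErrors(c(3, 2, 1, 0, 2), c(1, 1, 1, 0, 3))
  expect_lt(selectOptimum(swDrop), 5L)
  expect_identical(selectOptimum(swDrop), 4L)
  # first-convergence rule: the index must never change afterwards
  expect_identical(selectOptimum(sw, rule = "first_convergence"), 7L)
})
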