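test_that("a rank-1 training set yields a single mode along the generator", {
  mu <- vectorizePoints(circlePoints(10L, 2))
  v <- rep(0, 20L)
  v[c(1, 4, 9)] <- c(3, -4, 1)
  v <- v / sqrt(sum(v^2))
  X <- rbind(mu - v, mu, mu + v)
  model <- fitShapeModel(makeTestShapeSet(X))
  ev <- eigenValues(model)
  expect_equal(ev[1], 1, tolerance = 1e-12) # var of t in {-1,0,1} with n-1
  expect_lt(ev[2] / ev[1], 1e-20)
  expect_equal(abs(sum(basisMatrix(model)[, 1] * v)), 1, tolerance = 1e-9)
})

test_that("eigenvalues match a dense covariance eigen-decomposition", {
  set.seed(8)
  X <- matrix(stats::rnorm(6 * 16), nrow = 6L)
  model <- fitShapeModel(makeTestShapeSet(X))
  dense <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(eigenValues(model), dense[seq_len(5L)], tolerance = 1e-10)
  # basis orthonormality is part of the class contract
  G <- crossprod(basisMatrix(model))
  expect_equal(G, diag(5L), tolerance = 1e-9)
})

test_that("isotropic point noise gives a flat eigenvalue spectrum", {
  set.seed(9)
  mu <- vectorizePoints(circlePoints(20L, 10))
  X <- sweep(matrix(stats::rnorm(500 * 40, sd = 0.3), nrow = 500L), 2L, mu, `+`)
  model <- fitShapeModel(makeTestShapeSet(X))
  ev <- eigenValues(model)
  expect_lt(ev[1] / mean(ev), 3)
})

test_that("chooseModes returns the smallest M reaching the variance fraction", {
  B <- diag(8L)[, 1:4]
  model <- new("ShapeModel",
    meanShape = rep(0, 8L), basis = B, eigenvalues = c(4, 3, 2, 1),
    nSamples = 6L, side = "left", nPoints = 4L, fiducialSlots = 1L
  )
  expect_identical(chooseModes(model, 0.90), 3L)
  expect_identical(chooseModes(model, 1.0), 4L)
  expect_identical(chooseModes(model, 0.1), 1L)
  expect_error(chooseModes(model, 0), "varianceFraction")
})

test_that("a 3-latent-mode cohort with small noise needs 3-5 modes for 95%", {
  set.seed(10)
  mu <- vectorizePoints(circlePoints(12L, 5))
  dirs <- qr.Q(qr(matrix(stats::rnorm(24 * 3), ncol = 3L)))
  scores <- matrix(stats::rnorm(60 * 3), ncol = 3L) %*% diag(c(1.2, 0.9, 0.6))
  X <- sweep(scores %*% t(dirs), 2L, mu, `+`) +
    matrix(stats::rnorm(60 * 24, sd = 0.03), nrow = 60L)
  model <- fitShapeModel(makeTestShapeSet(X))
  M <- chooseModes(model, 0.95)
  expect_gte(M, 3L)
  expect_lte(M, 5L)
})

test_that("projection and synthesis are mutually consistent", {
  pipe <- sharedPipeline()
  model <- pipe$model
  mu <- meanShape(model)
  Mfull <- ncol(basisMatrix(model))
  expect_equal(projectShapes(model, mu, M = 5L), rep(0, 5L), tolerance = 1e-9)
  b <- projectShapes(model, mu + 2 * basisMatrix(model)[, 1], M = 4L)
  expect_equal(b, c(2, 0, 0, 0), tolerance = 1e-9)
  expect_equal(synthesizeShape(model, rep(0, 3L)), mu, tolerance = 1e-12)
  lam1 <- eigenValues(model)[1]
  disp <- synthesizeShape(model, 2 * sqrt(lam1))
  expect_equal(disp, mu + 2 * sqrt(lam1) * basisMatrix(model)[, 1],
    tolerance = 1e-12
  )
  # completeness: full-mode round trip reproduces every training shape
  X <- shapeMatrix(pipe$aligned)
  back <- synthesizeShape(model, projectShapes(model, X, M = Mfull))
  expect_lt(max(abs(back - X)), 1e-9)
})

test_that("training parameter variances equal the eigenvalues", {
  pipe <- sharedPipeline()
  b <- projectShapes(pipe$model, shapeMatrix(pipe$aligned))
  expect_equal(unname(apply(b, 2L, stats::var)), eigenValues(pipe$model),
    tolerance = 1e-9
  )
  frac <- cumsum(eigenValues(pipe$model)) / sum(eigenValues(pipe$model))
  expect_true(all(diff(frac) >= -1e-15)) # nondecreasing
  expect_true(all(diff(diff(frac)) <= 1e-12)) # concave
})

test_that("Mahalanobis distance uses per-mode variances", {
  pipe <- sharedPipeline()
  model <- pipe$model
  a <- c(0.1, -0.2, 0.3)
  expect_equal(mahalanobisShape(model, a, a), 0)
  lam1 <- eigenValues(model)[1]
  expect_equal(mahalanobisShape(model, sqrt(lam1), 0), 1, tolerance = 1e-12)
})

test_that("squared Mahalanobis distances to the mean are chi-squared", {
  set.seed(12)
  mu <- vectorizePoints(circlePoints(10L, 5))
  dirs <- qr.Q(qr(matrix(stats::rnorm(20 * 6), ncol = 6L)))
  lam <- c(2, 1.5, 1, 0.7, 0.5, 0.3)
  scores <- sweep(matrix(stats::rnorm(800 * 6), ncol = 6L), 2L, sqrt(lam), `*`)
  X <- sweep(scores %*% t(dirs), 2L, mu, `+`)
  model <- fitShapeModel(makeTestShapeSet(X))
  M <- 6L
  b <- projectShapes(model, X, M = M)
  zero <- rep(0, M)
  d2 <- apply(b, 1L, function(bi) mahalanobisShape(model, bi, zero))^2
  ks <- stats::ks.test(d2, stats::pchisq, df = M)
  expect_gt(ks$p.value, 0.01)
})

test_that("shapes synthesized within 3 sigma are simple polygons", {
  pipe <- sharedPipeline()
  model <- pipe$model
  M <- chooseModes(model, 0.95)
  lam <- eigenValues(model)[seq_len(M)]
  set.seed(13)
  draws <- matrix(stats::rnorm(1000 * M), ncol = M)
  draws <- pmin(pmax(draws, -3), 3)
  draws <- sweep(draws, 2L, sqrt(lam), `*`)
  shapes <- synthesizeShape(model, draws)
  ok <- vapply(seq_len(1000L), function(i) {
    isSimplePolygon(devectorizePoints(shapes[i, ]))
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("the model container round-trips through its JSON file", {
  pipe <- sharedPipeline()
  path <- withr::local_tempfile(fileext = ".json")
  writeShapeModel(pipe$model, path)
  back <- readShapeModel(path)
  expect_equal(back@meanShape, pipe$model@meanShape, tolerance = 1e-12)
  expect_equal(back@basis, pipe$model@basis, tolerance = 1e-12)
  expect_equal(back@eigenvalues, pipe$model@eigenvalues, tolerance = 1e-12)
  expect_identical(back@side, pipe$model@side)
  expect_identical(back@fiducialSlots, pipe$model@fiducialSlots)
})

test_that("degenerate and mismatched inputs are rejected", {
  expect_error(fitShapeModel(makeTestShapeSet(matrix(stats::rnorm(8), 2L))),
    "at least 3"
  )
  pipe <- sharedPipeline()
  expect_error(projectShapes(pipe$model, rep(0, 10L)), "dimension")
})
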