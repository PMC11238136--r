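test_that("median polish handles constant, additive and outlier matrices", {
  f <- medianPolish(matrix(7, 3, 5))
  expect_equal(f@overall, 7)
  expect_equal(max(abs(f@residuals)), 0)
  # exactly additive matrix fits with zero residuals
  f2 <- medianPolish(matrix(c(1, 3, 2, 4), 2))
  expect_equal(max(abs(f2@residuals)), 0)
  # single spiked cell on a constant plate is isolated in its residual
  m <- matrix(5, 4, 4); m[2, 3] <- 15
  f3 <- medianPolish(m)
  expect_equal(f3@residuals[2, 3], 10, tolerance = 1e-9)
  expect_lt(max(abs(f3@residuals[-(2 + 4 * 2)])), 1e-9)
})

test_that("median polish reconstruction identity holds on random matrices", {
  set.seed(101)
  for (i in 1:20) {
    nr <- sample(3:12, 1); nc <- sample(3:12, 1)
    x <- matrix(rnorm(nr * nc, sd = 3), nr, nc)
    if (i %% 2 == 0) x[sample(length(x), ceiling(length(x) / 10))] <- NA
    f <- medianPolish(x, maxIter = 50)
    recon <- f@overall + outer(f@rowEffects, f@colEffects, `+`) + f@residuals
    expect_equal(recon[is.finite(x)], x[is.finite(x)], tolerance = 1e-9)
    if (f@converged) {
      expect_lt(max(abs(apply(f@residuals, 1, median, na.rm = TRUE))), 1e-6)
      expect_lt(max(abs(apply(f@residuals, 2, median, na.rm = TRUE))), 1e-6)
    }
    # cross-check against the reference implementation; a median polish is
    # not unique, so compare the residual mass the two decompositions leave
    ref <- suppressWarnings(
      stats::medpolish(x, eps = 1e-8, maxiter = 200, trace.iter = FALSE,
                       na.rm = TRUE))
    expect_equal(sum(abs(f@residuals), na.rm = TRUE),
                 sum(abs(ref$residuals), na.rm = TRUE), tolerance = 0.1)
  }
})

test_that("median polish is idempotent on its own residuals", {
  set.seed(7)
  x <- matrix(rnorm(96, sd = 2), 8, 12)
  f <- medianPolish(x, maxIter = 100)
  f2 <- medianPolish(f@residuals, maxIter = 100)
  expect_lt(abs(f2@overall), 1e-5)
  expect_lt(max(abs(f2@rowEffects)), 1e-5)
  expect_lt(max(abs(f2@colEffects)), 1e-5)
})

test_that("median polish rejects degenerate input", {
  expect_error(medianPolish(matrix(1, 1, 5)), "2x2")
  x <- matrix(1, 4, 4); x[2, ] <- NA
  expect_error(medianPolish(x), "row")
  x <- matrix(1, 4, 4); x[, 3] <- NA
  expect_error(medianPolish(x), "column")
})

test_that("percent activity scales to the negative-control median", {
  p <- makeFlatPlate(signalValue = 500, negValue = 1000)
  pa <- percentActivity(p)
  expect_equal(unique(pa[sampleMask(p)]), 50)
  expect_equal(median(pa[wellRoles(p) == "negative_control"]), 100)
  # invariant to global rescaling of the signal
  p2 <- makeFlatPlate(signalValue = 500 * 17, negValue = 1000 * 17,
                      posValue = 4000 * 17)
  pa2 <- percentActivity(p2)
  smp2 <- sampleMask(p2) | wellRoles(p2) == "negative_control"
  expect_equal(pa2[smp2], pa[smp2])
})

test_that("Z-factor matches closed forms and guards degenerate input", {
  # sigma_p = sigma_n = 0 -> perfect assay
  expect_equal(zFactor(c(10, 10), c(100, 100))$value, 1)
  # overlapping arms give a negative value
  neg <- c(90, 110); pos <- c(80, 100)     # means 100/90, sds 14.142...
  z <- zFactor(pos, neg)
  expect_equal(z$value, 1 - 3 * (sd(pos) + sd(neg)) / 10)
  expect_false(z$screenable)
  expect_error(zFactor(c(1, 1), c(1, 1)), "equal")
  expect_error(zFactor(1, c(1, 2)), "at least 2")
})

test_that("B-scores are invariant to global signal rescaling (log polish)", {
  spec <- syntheticScreenSpec(nPlates = 1, format = 96, seed = 5)
  p <- simulatePrimaryScreen(spec)$plates[[1]]
  b1 <- bScore(p)$bScore
  p2 <- PlateGrid(plateId(p), 96, "luminescence", signalMatrix(p) * 37,
                  wellRoles(p), compoundIds(p), p@library, wellDoses(p))
  b2 <- bScore(p2)$bScore
  expect_equal(b2, b1, tolerance = 1e-8)
})

test_that("a spiked strong hit on an otherwise null plate scores B <= -5", {
  spec <- syntheticScreenSpec(nPlates = 1, format = 96, hitFraction = 0,
                              noiseCv = 0.05, seed = 9)
  p <- simulatePrimaryScreen(spec)$plates[[1]]
  sig <- signalMatrix(p)
  smp <- which(sampleMask(p), arr.ind = TRUE)
  sig[smp[10, 1], smp[10, 2]] <- sig[smp[10, 1], smp[10, 2]] * 0.10
  p2 <- PlateGrid(plateId(p), 96, "luminescence", sig, wellRoles(p),
                  compoundIds(p), p@library, wellDoses(p))
  b <- bScore(p2)$bScore
  expect_lt(b[smp[10, 1], smp[10, 2]], -5)
})

test_that("hit calling uses the inclusive k-SD boundary on control B-scores", {
  negB <- c(-1, 0, 0, 1)                 # mean 0, sd ~0.816
  thr <- mean(negB) - 3 * sd(negB)
  expect_true(callHits(-10, negB))
  expect_false(callHits(-2, negB))
  expect_true(callHits(thr, negB))       # boundary inclusive
  expect_true(callHits(10, negB, direction = "up"))
  expect_identical(callHits(c(-10, 10), negB, direction = "both"),
                   c(TRUE, TRUE))
  expect_error(callHits(0, rep(1, 4)), "SD is 0")
  expect_error(callHits(0, c(0, 1)), "at least 4")
})

test_that("estimated positional effects track the injected multipliers", {
  spec <- syntheticScreenSpec(nPlates = 10, rowEffectSd = 0.2,
                              hitFraction = 0, noiseCv = 0.05, seed = 21)
  sim <- simulatePrimaryScreen(spec)
  cors <- vapply(seq_along(sim$plates), function(i) {
    p <- sim$plates[[i]]
    x <- log10(signalMatrix(p))
    x[!sampleMask(p)] <- NA
    f <- screenCascade:::maskedPolish(x, 50, 1e-6)
    cor(f$rowEffects, log10(sim$truth$plateEffects[[i]]$rowMult))
  }, numeric(1))
  expect_gt(min(cors), 0.95)
})
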