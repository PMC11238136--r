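test_that("inhibition and the ZIP expectation follow their closed forms", {
  expect_equal(inhibition(100), 0)
  expect_equal(inhibition(0), 1)
  expect_equal(inhibition(130), 0)          # stimulation clamps to 0
  expect_equal(inhibition(25), 0.75)
  expect_equal(zipExpected(0.5, 0.5), 0.75)
  expect_equal(zipExpected(0, 0.37), 0.37)  # null drug
  expect_equal(zipExpected(1, 0.37), 1)     # saturation
  expect_error(zipExpected(1.2, 0.5), "\\[0, 1\\]")
})

test_that("Bliss excess is exact on generator output and symmetric", {
  cv <- headroomCurves()
  sm <- simulateCombinationMatrix(
    surfaceSpec(cv$c1, cv$c2, doses1 = olaparibGrid, doses2 = olaparibGrid,
                delta = 10))
  ex <- blissExcessMatrix(sm$matrix)
  expect_equal(mean(ex, na.rm = TRUE), 10, tolerance = 1e-9)
  # manual cell: observed monotherapies 0.3/0.4, combo 0.58 -> excess 0
  v <- matrix(100, 5, 5)
  v[2, 1] <- 70; v[1, 2] <- 60; v[2, 2] <- 42
  m <- combinationMatrix("a", "b", c(0, 1, 2, 4, 8), c(0, 1, 2, 4, 8), v)
  expect_equal(blissExcessMatrix(m)[2, 2], 0)
  # exact transpose symmetry
  mt <- combinationMatrix("b", "a", m@doses2, m@doses1, t(v))
  expect_equal(blissExcessMatrix(mt), t(blissExcessMatrix(m)))
})

test_that("ZIP delta is near zero on exactly independent surfaces", {
  cv <- headroomCurves()
  sm <- simulateCombinationMatrix(
    surfaceSpec(cv$c1, cv$c2, doses1 = olaparibGrid, doses2 = olaparibGrid))
  delta <- zipDeltaMatrix(sm$matrix)
  expect_lt(max(abs(delta), na.rm = TRUE), 0.5)
  expect_true(all(is.na(delta[1, ])))
  expect_true(all(is.na(delta[, 1])))
})

test_that("injected constant delta is recovered by the fitted surface", {
  cv <- headroomCurves()
  for (d in c(5, 10, 20)) {
    sm <- simulateCombinationMatrix(
      surfaceSpec(cv$c1, cv$c2, doses1 = olaparibGrid,
                  doses2 = olaparibGrid, delta = d))
    expect_equal(overallSynergy(zipDeltaMatrix(sm$matrix)), d,
                 tolerance = 1.5 / d)   # within +-1.5 absolute
  }
})

test_that("an inert partner reduces ZIP delta to single-agent Bliss (zero)", {
  cv <- headroomCurves()
  inert <- doseResponseCurve(100, 100, 1, 1, degenerate = TRUE)
  sm <- simulateCombinationMatrix(
    surfaceSpec(cv$c1, inert, doses1 = olaparibGrid, doses2 = olaparibGrid))
  delta <- zipDeltaMatrix(sm$matrix)
  expect_lt(max(abs(delta), na.rm = TRUE), 0.5)
})

test_that("swapping the drugs changes fitted scores by less than 0.5", {
  cv <- headroomCurves()
  sm <- simulateCombinationMatrix(
    surfaceSpec(cv$c1, cv$c2, doses1 = olaparibGrid, doses2 = olaparibGrid,
                delta = 8))
  m <- sm$matrix
  mt <- combinationMatrix("b", "a", m@doses2, m@doses1, t(m@viability))
  d1 <- zipDeltaMatrix(m); d2 <- zipDeltaMatrix(mt)
  expect_lt(abs(overallSynergy(d1) - overallSynergy(d2)), 0.5)
  expect_lt(abs(msaScore(d1) - msaScore(d2)), 0.5)
})

test_that("overall, msa and classification behave on constructed deltas", {
  d <- matrix(NA_real_, 7, 7)
  d[2:7, 2:7] <- 4
  expect_equal(overallSynergy(d), 4)
  expect_equal(msaScore(d), 4)
  # one 3x3 block at +12 on an otherwise zero 6x6 region
  d[2:7, 2:7] <- 0
  d[3:5, 3:5] <- 12
  expect_equal(msaScore(d), 12)
  # msa dominates the mean of complete-window means
  set.seed(55)
  for (i in 1:10) {
    dd <- matrix(rnorm(36), 6, 6)
    w <- expand.grid(i = 1:4, j = 1:4)
    means <- mapply(function(i, j) mean(dd[i:(i + 2), j:(j + 2)]),
                    w$i, w$j)
    expect_gte(msaScore(dd), mean(means))
  }
  expect_true(classifySynergy(11.86))
  expect_false(classifySynergy(0.40))
  expect_true(classifySynergy(5))           # inclusive boundary
})

test_that("msa on a region smaller than the window warns and shrinks", {
  d <- matrix(NA_real_, 3, 3)
  d[2:3, 2:3] <- 6
  expect_warning(s <- msaScore(d), "smaller than the msa window")
  expect_equal(s, 6)
})

test_that("zipSynergy bundles scores and classification", {
  cv <- headroomCurves()
  sm <- simulateCombinationMatrix(
    surfaceSpec(cv$c1, cv$c2, doses1 = olaparibGrid, doses2 = olaparibGrid,
                delta = 10))
  rep <- zipSynergy(sm$matrix)
  expect_s4_class(rep, "SynergyReport")
  expect_true(isSynergistic(rep))
  expect_equal(overallScore(rep), 10, tolerance = 0.15)
  expect_gte(rep@msaScore, rep@overallScore - 0.5)
  expect_identical(dim(deltaMatrix(rep)), c(7L, 7L))
})
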