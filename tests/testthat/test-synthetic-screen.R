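test_that("degenerate generator settings give analytically exact plates", {
  spec <- syntheticScreenSpec(nPlates = 2, format = 96, baselineSignal = 1e4,
                              rowEffectSd = 0, colEffectSd = 0,
                              plateEffectSd = 0, noiseCv = 0,
                              hitFraction = 0, toxicFraction = 0, seed = 3)
  sim <- simulatePrimaryScreen(spec)
  for (p in sim$plates) {
    expect_equal(unique(signalMatrix(p)[sampleMask(p)]), 1e4)
    expect_equal(unique(signalMatrix(p)[wellRoles(p) == "negative_control"]),
                 1e4)
    expect_equal(unique(signalMatrix(p)[wellRoles(p) == "positive_control"]),
                 1e4 * spec$positiveControlActivity / 100)
  }
  via <- simulateViabilityScreen(spec, sim$truth)
  for (p in via)
    expect_equal(unique(percentActivity(p)[sampleMask(p)]), 100)
})

test_that("identical spec and seed give identical screens", {
  spec <- syntheticScreenSpec(nPlates = 2, seed = 17)
  a <- simulatePrimaryScreen(spec)
  b <- simulatePrimaryScreen(spec)
  expect_identical(lapply(a$plates, signalMatrix),
                   lapply(b$plates, signalMatrix))
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(simulateViabilityScreen(spec, a$truth),
                          signalMatrix),
                   lapply(simulateViabilityScreen(spec, b$truth),
                          signalMatrix))
})

test_that("ground truth is recoverable from noise-free spiked plates", {
  spec <- syntheticScreenSpec(nPlates = 1, format = 96, rowEffectSd = 0,
                              colEffectSd = 0, plateEffectSd = 0,
                              noiseCv = 0, hitFraction = 0.2,
                              toxicFraction = 0.2, seed = 13)
  sim <- simulatePrimaryScreen(spec)
  p <- sim$plates[[1]]
  pa <- percentActivity(p)
  tr <- sim$truth$compounds
  smp <- sampleMask(p)
  expect_equal(pa[smp][match(tr$compound_id, compoundIds(p)[smp])],
               tr$true_activity, tolerance = 1e-12)
  via <- simulateViabilityScreen(spec, sim$truth)[[1]]
  pv <- percentActivity(via)
  expect_equal(pv[smp][match(tr$compound_id, compoundIds(via)[smp])],
               tr$true_viability, tolerance = 1e-12)
})

test_that("viability simulation rejects mismatched truth", {
  spec <- syntheticScreenSpec(nPlates = 2, seed = 1)
  sim <- simulatePrimaryScreen(spec)
  truncated <- sim$truth
  truncated$compounds <- truncated$compounds[1:10, ]
  expect_error(simulateViabilityScreen(spec, truncated), "does not match")
})

test_that("ZIP-independent noise-free surfaces have zero Bliss excess", {
  cv <- headroomCurves()
  sm <- simulateCombinationMatrix(
    surfaceSpec(cv$c1, cv$c2, doses1 = olaparibGrid, doses2 = olaparibGrid))
  expect_lt(max(abs(blissExcessMatrix(sm$matrix)), na.rm = TRUE), 1e-9)
  expect_true(all(is.na(sm$truthDelta[1, ])))
  expect_equal(sm$matrix@viability[1, 1], 100)
})

test_that("an inert second drug leaves every column on drug 1's curve", {
  cv <- headroomCurves()
  inert <- doseResponseCurve(100, 100, 1, 1, degenerate = TRUE)
  sm <- simulateCombinationMatrix(
    surfaceSpec(cv$c1, inert, doses1 = olaparibGrid, doses2 = olaparibGrid))
  mono <- predictResponse(cv$c1, olaparibGrid)
  for (j in seq_along(olaparibGrid))
    expect_equal(sm$matrix@viability[, j], mono, tolerance = 1e-9)
})

test_that("surface replicates average and respect the seed", {
  cv <- headroomCurves()
  sf <- surfaceSpec(cv$c1, cv$c2, delta = 5, replicateCv = 0.05,
                    nReplicates = 3, seed = 99)
  a <- simulateCombinationMatrix(sf)
  b <- simulateCombinationMatrix(sf)
  expect_identical(a$matrix@viability, b$matrix@viability)
  expect_length(a$matrix@replicates, 3L)
  expect_equal(Reduce(`+`, a$matrix@replicates) / 3, a$matrix@viability)
})

test_that("extreme injected delta triggers the pre-clamp warning", {
  cv <- headroomCurves()
  expect_warning(
    simulateCombinationMatrix(surfaceSpec(cv$c1, cv$c2, delta = 60)),
    "pre-clamp")
})
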