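test_that("well-address display/parse is a bijection over each format", {
  for (fmt in c(96, 384)) {
    dims <- screenCascade:::plateDims(fmt)
    idx <- expand.grid(row = seq_len(dims[1]) - 1L,
                       column = seq_len(dims[2]) - 1L)
    names <- wellName(idx$row, idx$column, fmt)
    expect_false(anyDuplicated(names) > 0)
    back <- parseWell(names, fmt)
    expect_identical(back$row, idx$row)
    expect_identical(back$column, idx$column)
  }
  expect_identical(wellName(1, 2), "B03")
  expect_identical(parseWell("B03", 96), data.frame(row = 1L, column = 2L))
})

test_that("out-of-range and malformed well addresses are rejected", {
  expect_error(parseWell("Q01", 384), "unparseable")   # Q is beyond row P
  expect_error(parseWell("J01", 96), "row out of range")
  expect_error(parseWell("A13", 96), "column out of range")
  expect_error(wellName(8, 0, 96), "row index")
})

test_that("PlateGrid validity enforces roles, dims and annotation rules", {
  p <- makeFlatPlate()
  expect_s4_class(p, "PlateGrid")
  expect_identical(plateFormat(p), 96L)
  expect_true(all(signalMatrix(p)[sampleMask(p)] == 1000))
  role <- screenCascade:::controlLayout(96)
  sig <- matrix(1000, 8, 12)
  expect_error(PlateGrid("x", 96, "luminescence", sig,
                         matrix("mystery", 8, 12)), "unknown well role")
  expect_error(PlateGrid("x", 96, "luminescence", sig, role),
               "compound id")          # sample wells lack compound ids
  sig2 <- sig; sig2[1, 3] <- -5
  cid <- matrix(NA_character_, 8, 12); cid[role == "sample"] <- "c"
  dose <- matrix(NA_real_, 8, 12); dose[role == "sample"] <- 1
  expect_error(PlateGrid("x", 96, "luminescence", sig2, role, cid,
                         dose = dose), "non-negative")
})

test_that("long-table round trip is lossless on simulator output", {
  spec <- syntheticScreenSpec(nPlates = 2, format = 96, seed = 11)
  sim <- simulatePrimaryScreen(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLongTable(sim$plates, path)
  back <- readLongTable(path)
  expect_setequal(names(back),
                  paste0(names(sim$plates), ":luminescence"))
  for (p in sim$plates) {
    q <- back[[paste0(plateId(p), ":luminescence")]]
    expect_identical(plateFormat(q), plateFormat(p))
    expect_identical(wellRoles(q), wellRoles(p))
    expect_identical(compoundIds(q), compoundIds(p))
    expect_equal(signalMatrix(q), signalMatrix(p), tolerance = 1e-12)
  }
})

test_that("long-table reader reports duplicates and bad roles", {
  tab <- data.frame(plate_id = "P1", well = c("A01", "A01"),
                    compound_id = c("c1", "c2"), library = "L",
                    role = "sample", dose_uM = 1,
                    channel = "luminescence", signal = c(10, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  expect_error(readLongTable(path), "duplicate")
  tab$well <- c("A01", "A02"); tab$role <- c("sample", "wildcard")
  write.csv(tab, path, row.names = FALSE)
  expect_error(readLongTable(path), "unknown role")
})

test_that("a minimal two-well table yields one 96-format plate", {
  tab <- data.frame(plate_id = "P1", well = c("A01", "A02"),
                    compound_id = c("c1", "c2"), library = "L",
                    role = "sample", dose_uM = 1,
                    channel = "luminescence", signal = c(10, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  plates <- readLongTable(path)
  expect_length(plates, 1L)
  p <- plates[["P1:luminescence"]]
  expect_identical(plateFormat(p), 96L)
  expect_identical(sum(!is.na(signalMatrix(p))), 2L)
})

test_that("hit table is sorted by ratio, ties broken by B score", {
  rec <- data.frame(
    compound_id = c("a", "b", "c"), library = "L", dose_uM = 4,
    percent_activity = c(9.296, 9.680, 11.118),
    b_score = c(-27.727, -29.073, -12.797),
    percent_viability = c(37.101, 35.916, 40.557),
    viability_z = c(-2.215, -2.256, -2.093),
    ratio = c(3.991, 3.710, 3.710),
    is_luminescence_hit = TRUE, passes_counter_screen = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  writeHitTable(rec, path)
  out <- read.csv(path)
  expect_identical(out$compound_id, c("a", "b", "c"))  # tie: b_score asc
  expect_identical(out$ratio, c(3.991, 3.710, 3.710))
  # empty collection -> header-only file
  writeHitTable(rec[0, ], path)
  expect_identical(length(readLines(path)), 1L)
})
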