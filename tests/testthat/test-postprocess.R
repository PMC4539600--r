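mkUniform <- function(map, value = 0.7) {
  st <- initialState(map, defaultParameters())
  P <- st@point
  P[P > 0] <- value
  P[, "auxin"] <- value
  new("SpeciesState", point = P, mem = st@mem)
}

test_that("region averages: uniform field, partition recombination, oracle", {
  map <- miniMap()
  res <- asResult(map, mkUniform(map, 0.7))
  expect_equal(regionAverage(res, "auxin"), 0.7)
  # area-weighted partition means recombine exactly to the whole-root mean
  res2 <- asResult(map, randomState(map))
  types <- cellTypes()
  ns <- vapply(types, function(tp) length(regionMask(map, cellType = tp)),
               integer(1))
  ms <- vapply(types, function(tp) regionAverage(res2, "auxin",
                                                 cellType = tp), numeric(1))
  expect_equal(sum(ns * ms) / sum(ns), regionAverage(res2, "auxin"))
  # direct-summation oracle
  pts <- regionMask(map, cellType = "vascular")
  expect_equal(regionAverage(res2, "auxin", cellType = "vascular"),
               sum(res2@state@point[pts, "auxin"]) / length(pts))
  expect_error(regionAverage(res2, "auxin", tiers = 999), "empty region")
})

test_that("profiles: uniform flat, linearity, tier mode", {
  map <- miniMap()
  res <- asResult(map, mkUniform(map, 1.3))
  pr <- longitudinalProfile(res, "auxin", "row")
  expect_true(all(abs(pr$value - 1.3) < 1e-12))
  expect_true(all(diff(pr$position) > 0))
  # linearity: profile(a * field) = a * profile(field)
  res2 <- asResult(map, randomState(map))
  st3 <- res2@state
  st3@point <- st3@point * 2.5
  st3@mem <- st3@mem * 2.5
  res3 <- asResult(map, st3)
  p2 <- longitudinalProfile(res2, "CK", "row")
  p3 <- longitudinalProfile(res3, "CK", "row")
  expect_equal(p3$value, 2.5 * p2$value)
  # tier mode has one entry per selected tier
  pt <- longitudinalProfile(res2, "PINtotal", "tier",
                            cellType = c("vascular", "pericycle"))
  expect_equal(pt$position, sort(unique(mapCells(map)$tier[
    mapCells(map)$type %in% c("vascular", "pericycle")])))
})

test_that("fold change is a ratio of region averages", {
  map <- miniMap()
  res <- asResult(map, randomState(map))
  expect_equal(foldChange(res, res, "CK"), 1.0)
  st2 <- res@state; st2@point <- st2@point * 1.9
  res2 <- asResult(map, st2)
  expect_equal(foldChange(res2, res, "CK"), 1.9)
  stz <- res@state; stz@point[, "CK"] <- 0
  expect_error(foldChange(res, asResult(map, stz), "CK"), "zero")
})

test_that("trend comparison: identical, reversed, expectations", {
  a <- data.frame(position = 1:20, value = seq(2, 0.1, length.out = 20))
  b <- data.frame(position = 1:20, value = seq(0.1, 2, length.out = 20))
  same <- trendCompare(a, a)
  expect_equal(same$rankCorrelation, 1)
  expect_false(isTRUE(same$oppositeTrend))
  rev <- trendCompare(a, b)
  expect_equal(rev$rankCorrelation, -1)
  expect_true(rev$oppositeTrend)
  expect_true(trendCompare(a, expected = "decreasing")$pass)
  expect_false(trendCompare(a, expected = "increasing")$pass)
  flat <- data.frame(position = 1:20, value = rep(1, 20))
  expect_true(trendCompare(flat)$degenerate)
})

test_that("distal-maximum detection distinguishes peaked from flat profiles", {
  pos <- seq(0, 90, by = 3)
  peaked <- data.frame(position = pos, value = 2 * exp(-pos / 25) + 0.2)
  flat <- data.frame(position = pos, value = 1 + 0.01 * sin(pos))
  proximalPeak <- data.frame(position = pos, value = rev(peaked$value))
  expect_true(hasDistalMaximum(peaked))
  expect_false(hasDistalMaximum(flat))
  expect_false(hasDistalMaximum(proximalPeak))
})

test_that("exports are deterministic and round-trip", {
  map <- miniMap()
  res <- asResult(map, randomState(map))
  f1 <- tempfile(fileext = ".csv")
  exportCSV(res, f1, species = "auxin")
  back <- readFieldCSV(f1)
  expect_equal(unname(back),
               matrix(res@state@point[, "auxin"], map@dims[1], map@dims[2]),
               tolerance = 1e-15)
  # colour map: grid dimensions and byte-identical repeats
  g1 <- tempfile(fileext = ".png"); g2 <- tempfile(fileext = ".png")
  exportColormap(res, "auxin", g1)
  exportColormap(res, "auxin", g2)
  expect_identical(readBin(g1, "raw", file.size(g1)),
                   readBin(g2, "raw", file.size(g2)))
  img <- png::readPNG(g1)
  expect_equal(dim(img)[1:2], unname(as.integer(map@dims)))
  # profile CSV round trip
  pr <- longitudinalProfile(res, "auxin", "row")
  f2 <- tempfile(fileext = ".csv")
  exportCSV(pr, f2)
  back2 <- utils::read.csv(f2)
  expect_equal(back2$value, pr$value, tolerance = 1e-12)
})
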