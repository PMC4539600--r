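test_that("grid spec validity catches bad geometry", {
  expect_error(miniGridSpec(spacing = 3), "multiples of the grid spacing")
  spec <- miniGridSpec()
  spec@ezCellLengths <- c(24, 16)
  expect_error(validObject(spec), "non-decreasing")
  spec <- miniGridSpec()
  spec@fileWidths <- c(epidermis = 8, outer = 8, pericycle = 8, vascular = 12)
  expect_error(validObject(spec), "sum to rootHalfWidth")
})

test_that("the map partitions the grid and every cytosol point is enclosed", {
  map <- miniMap()
  expect_true(all(map@kind %in% c(1L, 2L)))
  expect_true(all(map@cellId[map@kind == 1L] > 0L))
  expect_true(all(map@cellId[map@kind == 2L] == 0L))
  # every neighbour of a cytosol point is wall or cytosol of the same cell
  nr <- map@dims[1]; nc <- map@dims[2]
  for (pt in which(map@kind == 1L)) {
    r <- (pt - 1L) %% nr + 1L; cl <- (pt - 1L) %/% nr + 1L
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- cl + d[2]
      expect_true(rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
      expect_true(map@kind[rr, cc] == 2L ||
                    map@cellId[rr, cc] == map@cellId[r, cl])
    }
  }
})

test_that("the default map is mirror symmetric", {
  map <- miniMap()
  lab <- exportMap(map)
  expect_identical(lab, lab[, rev(seq_len(ncol(lab)))])
  b <- map@boundary
  expect_identical(b$auxinInflux, rev(b$auxinInflux))
  expect_identical(b$auxinEfflux, rev(b$auxinEfflux))
})

test_that("tier indices count from the tip and EZ tiers span more rows", {
  map <- buildRootMap(defaultGridSpec(spacing = 4))
  cells <- mapCells(map)
  vasc <- cells[cells$fileType == "vascular" & cells$file == 4, ]
  vasc <- vasc[order(vasc$row0), ]
  expect_identical(vasc$tier, seq_len(nrow(vasc)))
  rowsPer <- vasc$row1 - vasc$row0
  mzRows <- rowsPer[vasc$zone == "MZ"]
  ezRows <- rowsPer[vasc$zone == "EZ"]
  expect_gt(min(ezRows), max(mzRows))
  # strictly increasing shootwards within the file
  expect_true(all(diff(vasc$tier) == 1))
})

test_that("cell pixel areas equal length x width over h^2", {
  for (h in c(2, 4)) {
    map <- buildRootMap(defaultGridSpec(spacing = h))
    cells <- mapCells(map)
    areas <- cellPixelArea(map, cells$cell)
    lens <- (cells$row1 - cells$row0) * h
    wids <- (cells$col1 - cells$col0) * h
    expect_equal(areas, lens * wids / h^2)
  }
})

test_that("interfaces match a brute-force pair scan of the label grid", {
  map <- miniMap()
  fc <- interfaces(map)
  # oracle: scan all 4-adjacent pairs directly
  nr <- map@dims[1]; nc <- map@dims[2]
  kinds <- character(0)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    for (d in list(c(1, 0), c(0, 1))) {
      rr <- r + d[1]; cc <- cl + d[2]
      if (rr > nr || cc > nc) next
      ka <- map@kind[r, cl]; kb <- map@kind[rr, cc]
      kinds <- c(kinds, if (ka == 1 && kb == 1) "cc"
                 else if (ka == 2 && kb == 2) "ww" else "membrane")
    }
  }
  expect_equal(nrow(fc), length(kinds))
  expect_equal(as.list(table(fc$kind)), as.list(table(kinds)))
  # membrane faces pair one cytosol (a) with one wall (b)
  mb <- fc[fc$kind == "membrane", ]
  expect_true(all(map@kind[mb$a] == 1L))
  expect_true(all(map@kind[mb$b] == 2L))
  # each unordered adjacency appears exactly once
  key <- paste(pmin(fc$a, fc$b), pmax(fc$a, fc$b))
  expect_false(any(duplicated(key)))
})

test_that("membrane faces per cell cover the cell perimeter", {
  map <- miniMap()
  topo <- rootTopology(map)
  cells <- mapCells(map)
  perim <- 2 * ((cells$row1 - cells$row0 - 1) + (cells$col1 - cells$col0 - 1))
  expect_equal(unname(topo$nMemC), perim)
})

test_that("region masks select and partition the cytosol", {
  map <- miniMap()
  nCyt <- sum(map@kind == 1L)
  types <- cellTypes()
  sizes <- vapply(types, function(tp)
    length(regionMask(map, cellType = tp)), integer(1))
  expect_equal(sum(sizes), nCyt)
  central <- regionMask(map, cellType = c("vascular", "pericycle"))
  others <- regionMask(map, cellType = setdiff(types,
                                               c("vascular", "pericycle")))
  expect_length(intersect(central, others), 0)
  expect_setequal(c(central, others), regionMask(map))
  # tier range selection
  t2 <- regionMask(map, tiers = 2)
  expect_true(all(map@cells$tier[map@cellId[t2]] == 2))
  expect_error(regionMask(map, cellType = "phloem"), "unknown cell type")
  expect_error(regionMask(map, zone = "DZ"), "unknown zone")
})

test_that("map export round-trips and PNG preview has grid dimensions", {
  map <- miniMap()
  csv <- tempfile(fileext = ".csv")
  exportMap(map, csv)
  lab <- as.matrix(utils::read.table(csv, sep = ","))
  dimnames(lab) <- NULL
  expect_equal(lab, exportMap(map))
  pngf <- tempfile(fileext = ".png")
  exportMap(map, pngf)
  img <- png::readPNG(pngf)
  expect_equal(dim(img)[1:2], unname(as.integer(map@dims)))
})

test_that("geometry that cannot be tiled is rejected with an explanation", {
  spec <- miniGridSpec()
  spec@rootLength <- spec@rootLength + 8
  expect_error(buildRootMap(spec), "cannot be tiled")
})
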