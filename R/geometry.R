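#' Default root geometry
#'
#' The shipped root layout: a 968 x 224 um root discretised at 2 um, with four
#' cell files per side (epidermis, outer ground-tissue file, pericycle/border,
#' vascular) mirrored about the central axis, two columella tiers and a
#' quiescent-centre tier at the distal tip, a meristematic zone of short 8-um
#' cells and an elongation zone whose cell lengths ramp from 12 to 40 um
#' shootwards.  All lengths are multiples of 4 um so the same layout can be
#' solved at halved resolution (h = 4 um).
#'
#' @param spacing grid spacing in um (default 2)
#' @return a \linkS4class{GridSpec}
#' @export
#' @examples
#' spec <- defaultGridSpec(spacing = 4)
#' map <- buildRootMap(spec)
defaultGridSpec <- function(spacing = 2) {
  new("GridSpec",
      spacing = spacing,
      rootLength = 968,
      rootHalfWidth = 112,
      colLengths = c(16, 16),
      qcLength = 8,
      mzLength = 320,
      mzCellLength = 8,
      ezCellLengths = c(12, 16, 20, 24, 28, 32, 36, 40),
      fileWidths = c(epidermis = 20, outer = 32, pericycle = 20,
                     vascular = 40),
      wallThickness = 1L)
}

#' Miniature root geometry for testing
#'
#' A small root map with the same qualitative anatomy as the default (mirrored
#' files, columella + QC tip, MZ then EZ) but far fewer grid points, used by
#' the test suite and for quick experimentation.
#'
#' @param spacing grid spacing in um (default 4)
#' @param nMZ number of MZ cell tiers (default 4)
#' @param nEZ number of EZ cell tiers appended after the ramp (default 1)
#' @return a \linkS4class{GridSpec}
#' @export
miniGridSpec <- function(spacing = 4, nMZ = 4, nEZ = 1) {
  ramp <- c(16, 24)
  new("GridSpec",
      spacing = spacing,
      rootLength = 16 + 8 + nMZ * 8 + sum(ramp) + nEZ * 24,
      rootHalfWidth = 32,
      colLengths = 16,
      qcLength = 8,
      mzLength = nMZ * 8,
      mzCellLength = 8,
      ezCellLengths = ramp,
      fileWidths = c(epidermis = 8, outer = 8, pericycle = 8, vascular = 8),
      wallThickness = 1L)
}

# longitudinal tier lengths from the tip, and per-tier zone bookkeeping
tierLengths <- function(spec) {
  lens <- c(spec@colLengths, spec@qcLength,
            rep(spec@mzCellLength, round(spec@mzLength / spec@mzCellLength)))
  lens <- c(lens, spec@ezCellLengths)
  used <- sum(lens)
  last <- spec@ezCellLengths[length(spec@ezCellLengths)]
  rem <- spec@rootLength - used
  if (rem < -1e-9)
    stop("rootLength shorter than tip + MZ + EZ ramp (", used, " um)")
  if (abs(rem / last - round(rem / last)) > 1e-9)
    stop("remaining root length (", rem, " um) cannot be tiled by EZ cells of ",
         last, " um; adjust rootLength")
  c(lens, rep(last, round(rem / last)))
}

#' Build the discretised root map
#'
#' Constructs the labelled grid of the root anatomy from a
#' \linkS4class{GridSpec}: mirrored cell files around the central axis,
#' columella and QC at the distal tip, MZ cells of fixed length, then EZ cells
#' of increasing length.  Cell walls (merged wall/plasma-membrane, one grid
#' point thick) lie on the lattice lines between cells; every cell is a
#' rectangle of cytosol points enclosed by wall points.  Shoot-boundary flags
#' are set on the proximal (last) wall row: auxin influx over the pericycle
#' and vascular files, auxin efflux over the epidermis files, gas exchange
#' everywhere.
#'
#' @param spec a valid \linkS4class{GridSpec}
#' @return a \linkS4class{RootMap}
#' @export
buildRootMap <- function(spec) {
  validObject(spec)
  h <- spec@spacing
  lens <- tierLengths(spec)
  widths <- spec@fileWidths  # outermost first
  halfFiles <- c("epidermis", "outer", "pericycle", "vascular")
  fileTypes <- c(halfFiles, rev(halfFiles))
  fileWidthSeq <- c(unname(widths[halfFiles]), rev(unname(widths[halfFiles])))

  rowB <- cumsum(c(0, lens)) / h + 1          # wall rows (1-based)
  colB <- cumsum(c(0, fileWidthSeq)) / h + 1  # wall cols
  nr <- as.integer(rowB[length(rowB)])
  nc <- as.integer(colB[length(colB)])
  nTiers <- length(lens)
  nFiles <- length(fileTypes)

  kind <- matrix(1L, nr, nc)
  kind[round(rowB), ] <- 2L
  kind[, round(colB)] <- 2L

  nColTiers <- length(spec@colLengths)
  qcTier <- nColTiers + 1L
  nMZ <- round(spec@mzLength / spec@mzCellLength)

  cells <- vector("list", nTiers * nFiles)
  cellId <- matrix(0L, nr, nc)
  k <- 0L
  for (t in seq_len(nTiers)) {
    for (f in seq_len(nFiles)) {
      k <- k + 1L
      r0 <- as.integer(round(rowB[t])); r1 <- as.integer(round(rowB[t + 1]))
      c0 <- as.integer(round(colB[f])); c1 <- as.integer(round(colB[f + 1]))
      type <- fileTypes[f]
      if (t <= nColTiers) {
        type <- "columella"
      } else if (t == qcTier && fileTypes[f] %in% c("pericycle", "vascular")) {
        type <- "QC"
      }
      zone <- if (type %in% c("columella", "QC")) "colqc"
        else if (t <= qcTier + nMZ) "MZ" else "EZ"
      cellId[(r0 + 1L):(r1 - 1L), (c0 + 1L):(c1 - 1L)] <- k
      cells[[k]] <- data.frame(cell = k, tier = t, file = f,
                               fileType = fileTypes[f], type = type,
                               zone = zone, row0 = r0, row1 = r1,
                               col0 = c0, col1 = c1,
                               stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)

  # shoot boundary: top wall row; flags by the file each column lies in
  colFile <- findInterval(seq_len(nc), round(colB))
  onLine <- seq_len(nc) %in% round(colB)
  ftype <- ifelse(onLine, NA_character_, fileTypes[pmin(colFile, nFiles)])
  boundary <- data.frame(
    col = seq_len(nc),
    point = (seq_len(nc) - 1L) * nr + nr,  # column-major index of (nr, col)
    auxinInflux = !is.na(ftype) & ftype %in% c("pericycle", "vascular"),
    auxinEfflux = !is.na(ftype) & ftype == "epidermis",
    gas = TRUE)

  new("RootMap", spec = spec, dims = c(nr, nc), kind = kind,
      cellId = cellId, cells = cells, boundary = boundary)
}

setValidity("RootMap", function(object) {
  msg <- character()
  if (!all(dim(object@kind) == object@dims)) msg <- c(msg, "kind dims mismatch")
  if (any(object@cellId[object@kind == 2L] != 0L))
    msg <- c(msg, "wall points must carry cellId 0")
  if (any(object@cellId[object@kind == 1L] == 0L))
    msg <- c(msg, "every cytosol point must belong to a cell")
  bt <- object@cells$fileType[match(
    seq_len(nrow(object@cells)), object@cells$cell)]
  if (length(msg)) msg else TRUE
})

#' Enumerate finite-volume interfaces
#'
#' Lists every unordered pair of 4-adjacent grid points exactly once, with its
#' kind (\code{cc} cytosol--cytosol within one cell, \code{membrane}
#' cytosol--wall, \code{ww} wall--wall) and, for membrane faces, the
#' orientation of the face as seen from the cytosol side (\code{rootward},
#' \code{shootward}, \code{lateral-in}, \code{lateral-out}).  These are the
#' faces the finite-volume scheme integrates fluxes over; every face has
#' length equal to the grid spacing.
#'
#' @param map a \linkS4class{RootMap}
#' @return data.frame with columns a, b (column-major point indices; for
#'   membrane faces a is the cytosol point), kind, orientation, faceLength
#' @export
interfaces <- function(map) {
  nr <- map@dims[1]; nc <- map@dims[2]
  kindv <- as.integer(map@kind)
  idx <- matrix(seq_len(nr * nc), nr, nc)

  vert <- cbind(as.vector(idx[-nr, ]), as.vector(idx[-1, ]))   # b = a + 1 row
  horiz <- cbind(as.vector(idx[, -nc]), as.vector(idx[, -1]))  # b right of a
  pairs <- rbind(vert, horiz)
  dirIsVert <- rep(c(TRUE, FALSE), c(nrow(vert), nrow(horiz)))

  ka <- kindv[pairs[, 1]]; kb <- kindv[pairs[, 2]]
  kindFace <- ifelse(ka == 1L & kb == 1L, "cc",
              ifelse(ka == 2L & kb == 2L, "ww", "membrane"))

  # for membrane faces put the cytosol point first
  swap <- kindFace == "membrane" & ka == 2L
  tmp <- pairs[swap, 1]; pairs[swap, 1] <- pairs[swap, 2]; pairs[swap, 2] <- tmp

  # orientation from the cytosol side
  rowA <- (pairs[, 1] - 1L) %% nr + 1L
  rowB <- (pairs[, 2] - 1L) %% nr + 1L
  colA <- (pairs[, 1] - 1L) %/% nr + 1L
  colB <- (pairs[, 2] - 1L) %/% nr + 1L
  centre <- (nc + 1) / 2
  orient <- rep(NA_character_, nrow(pairs))
  m <- kindFace == "membrane"
  orient[m & dirIsVert & rowB < rowA] <- "rootward"
  orient[m & dirIsVert & rowB > rowA] <- "shootward"
  lat <- m & !dirIsVert
  inward <- abs(colB[lat] - centre) < abs(colA[lat] - centre)
  orient[lat] <- ifelse(inward, "lateral-in", "lateral-out")

  data.frame(a = pairs[, 1], b = pairs[, 2], kind = kindFace,
             orientation = orient, faceLength = map@spec@spacing,
             stringsAsFactors = FALSE)
}

#' Select grid points by region
#'
#' Returns the column-major indices of the cytosol points matched by the
#' selector: by cell type, zone, tier range and/or longitudinal row range.
#' Selectors combine by intersection.  Wall points are excluded unless
#' \code{includeWalls} is TRUE (walls are never attributed to a region other
#' than a row range).
#'
#' @param map a \linkS4class{RootMap}
#' @param cellType character vector of cell types (see \code{cellTypes()})
#' @param zone character vector among "colqc", "MZ", "EZ"
#' @param tiers integer vector of tier indices (1 = most distal tier)
#' @param rows integer vector of grid rows (1 = distal tip)
#' @param includeWalls include wall points (row-range selection only)
#' @return integer vector of point indices
#' @export
regionMask <- function(map, cellType = NULL, zone = NULL, tiers = NULL,
                       rows = NULL, includeWalls = FALSE) {
  if (!is.null(cellType) && !all(cellType %in% CELL_TYPES))
    stop("unknown cell type(s): ",
         paste(setdiff(cellType, CELL_TYPES), collapse = ", "))
  if (!is.null(zone) && !all(zone %in% ZONES))
    stop("unknown zone(s): ", paste(setdiff(zone, ZONES), collapse = ", "))
  nr <- map@dims[1]
  cid <- as.integer(map@cellId)
  keep <- rep(TRUE, length(cid))
  cellOK <- rep(TRUE, nrow(map@cells))
  if (!is.null(cellType)) cellOK <- cellOK & map@cells$type %in% cellType
  if (!is.null(zone)) cellOK <- cellOK & map@cells$zone %in% zone
  if (!is.null(tiers)) cellOK <- cellOK & map@cells$tier %in% tiers
  isCyt <- as.integer(map@kind) == 1L
  keep <- isCyt & cid > 0L & cellOK[pmax(cid, 1L)]
  if (includeWalls && is.null(cellType) && is.null(zone) && is.null(tiers))
    keep <- rep(TRUE, length(cid))
  if (!is.null(rows)) {
    rowOf <- (seq_along(cid) - 1L) %% nr + 1L
    keep <- keep & rowOf %in% rows
  }
  which(keep)
}

#' @rdname regionMask
#' @export
cellTypes <- function() CELL_TYPES

#' Accessors for RootMap
#'
#' \code{mapCells} returns the per-cell table (id, tier, file, type, zone and
#' bounding wall lines); \code{gridSpacing} the spacing in um;
#' \code{cellPixelArea} the nominal pixel area of a cell, counting its cytosol
#' points plus half of each shared wall point and a quarter of each corner, so
#' that a cell of size L x W um contributes exactly (L/h)*(W/h) grid points.
#'
#' @param map a \linkS4class{RootMap}
#' @export
mapCells <- function(map) map@cells

#' @rdname mapCells
#' @export
gridSpacing <- function(map) map@spec@spacing

#' @rdname mapCells
#' @param cell cell id(s)
#' @export
cellPixelArea <- function(map, cell) {
  cl <- map@cells[match(cell, map@cells$cell), ]
  (cl$row1 - cl$row0) * (cl$col1 - cl$col0)
}

#' Export the root map as an integer label matrix
#'
#' Writes (or returns) a matrix of integer labels: 0 for wall points and the
#' cell-type code (1 epidermis .. 6 QC) for cytosol points, for quick visual
#' inspection.  With a path ending in .csv the matrix is written as CSV; with
#' .png an indexed colour preview is written.
#'
#' @param map a \linkS4class{RootMap}
#' @param path optional output path (.csv or .png); if NULL the matrix is
#'   returned
#' @return the label matrix, invisibly when written to a file
#' @export
exportMap <- function(map, path = NULL) {
  typeCode <- match(map@cells$type, CELL_TYPES)
  lab <- matrix(0L, map@dims[1], map@dims[2])
  cyt <- map@cellId > 0L
  lab[cyt] <- typeCode[map@cellId[cyt]]
  if (is.null(path)) return(lab)
  if (grepl("\\.csv$", path)) {
    utils::write.table(lab, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (grepl("\\.png$", path)) {
    pal <- grDevices::col2rgb(c("grey20", "#66c2a5", "#fc8d62", "#8da0cb",
                                "#e78ac3", "#a6d854", "#ffd92f")) / 255
    img <- array(0, dim = c(map@dims[1], map@dims[2], 3))
    for (ch in 1:3)
      img[, , ch] <- matrix(pal[ch, lab + 1L], map@dims[1], map@dims[2])
    png::writePNG(img[rev(seq_len(map@dims[1])), , , drop = FALSE], path)
  } else stop("path must end in .csv or .png")
  invisible(lab)
}
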