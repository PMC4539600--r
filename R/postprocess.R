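# Readouts from converged states: region averages, longitudinal profiles
# (per grid row or per cell tier), fold changes, colour maps and trend
# comparison.  Species names are the point species plus "PINtotal" and
# "AUX1total", which fold the membrane pools into the carrier totals.

resolveSpecies <- function(result, species) {
  P <- result@state@point
  if (species %in% colnames(P)) return(list(kind = "point", col = species))
  if (species %in% c("PINtotal", "AUX1total"))
    return(list(kind = "total",
                col = if (species == "PINtotal") "PINp" else "AUX1p",
                mem = if (species == "PINtotal") "PINpMem" else "AUX1pMem"))
  stop("unknown species '", species, "'")
}

#' Regional concentration average
#'
#' Arithmetic mean concentration over the cytosol points selected by the
#' region arguments (see \code{\link{regionMask}}).  For the carrier totals
#' (\code{species = "PINtotal"} or \code{"AUX1total"}) the membrane-pool
#' amounts of the selected cells are included, i.e. the average is total
#' carrier amount per unit cytosol area.
#'
#' @param result a \linkS4class{SteadyStateResult}
#' @param species point species name, "PINtotal" or "AUX1total"
#' @param ... region selectors passed to \code{\link{regionMask}}
#' @return mean concentration (uM)
#' @export
regionAverage <- function(result, species, ...) {
  sp <- resolveSpecies(result, species)
  pts <- regionMask(result@map, ...)
  if (!length(pts)) stop("empty region")
  P <- result@state@point
  if (sp$kind == "point") return(mean(P[pts, sp$col]))
  topo <- rootTopology(result@map)
  cellSel <- unique(topo$cellOf[pts])
  memSel <- topo$mem$cell %in% cellSel
  cytSel <- pts[topo$isCyt[pts]]
  (sum(P[cytSel, sp$col]) + sum(result@state@mem[memSel, sp$mem])) /
    length(cytSel)
}

#' Longitudinal concentration profile
#'
#' Profile of a species along the root axis.  Mode \code{"row"} averages
#' each cross-sectional grid row of the selected region (positions in um
#' from the tip); mode \code{"tier"} averages all points of each cell tier,
#' which smooths the membrane/cytosol contrast of the carrier proteins (the
#' membrane pools are included for the carrier totals).
#'
#' @param result a \linkS4class{SteadyStateResult}
#' @param species species name (see \code{\link{regionAverage}})
#' @param mode "row" or "tier"
#' @param ... region selectors passed to \code{\link{regionMask}}
#' @return data.frame (class \code{rootProfile}): position (um from tip for
#'   rows, tier index for tiers), value (uM)
#' @export
longitudinalProfile <- function(result, species, mode = c("row", "tier"),
                                ...) {
  mode <- match.arg(mode)
  sp <- resolveSpecies(result, species)
  map <- result@map
  P <- result@state@point
  pts <- regionMask(map, ...)
  if (!length(pts)) stop("empty region")
  nr <- map@dims[1]
  h <- map@spec@spacing
  vals <- P[pts, sp$col]
  if (mode == "row") {
    rowOf <- (pts - 1L) %% nr + 1L
    m <- tapply(vals, rowOf, mean)
    out <- data.frame(position = (as.integer(names(m)) - 1) * h,
                      value = as.numeric(m))
  } else {
    topo <- rootTopology(map)
    cellOfPts <- topo$cellOf[pts]
    tierOf <- map@cells$tier[cellOfPts]
    if (sp$kind == "total") {
      cellSel <- unique(cellOfPts)
      memSel <- which(topo$mem$cell %in% cellSel)
      memTier <- map@cells$tier[topo$mem$cell[memSel]]
      memVals <- result@state@mem[memSel, sp$mem]
      allTier <- c(tierOf, memTier)
      allVals <- c(vals, memVals)
    } else {
      allTier <- tierOf; allVals <- vals
    }
    m <- tapply(allVals, allTier, mean)
    out <- data.frame(position = as.integer(names(m)),
                      value = as.numeric(m))
  }
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  class(out) <- c("rootProfile", "data.frame")
  attr(out, "species") <- species
  attr(out, "mode") <- mode
  out
}

#' Fold change of a regional average between two runs
#'
#' \code{regionAverage(mutant)/regionAverage(wildType)} over the same region
#' of the same map.
#'
#' @param resultMut,resultWT two \linkS4class{SteadyStateResult}s on the
#'   same map
#' @param species species name
#' @param ... region selectors
#' @return ratio (dimensionless)
#' @export
foldChange <- function(resultMut, resultWT, species, ...) {
  if (!identical(resultMut@map@dims, resultWT@map@dims))
    stop("results are on different maps")
  wt <- regionAverage(resultWT, species, ...)
  if (wt == 0) stop("wild-type average is zero")
  regionAverage(resultMut, species, ...) / wt
}

#' Compare the trend of two profiles
#'
#' Resamples both profiles onto their common axis range (linear
#' interpolation) and reports monotonicity (Spearman rank correlation of
#' value against position per profile), the positions of the extrema, the
#' rank correlation between the profiles, and a pass/fail verdict against an
#' optional declared expectation for the first profile
#' (\code{"increasing"}/\code{"decreasing"} with position, i.e. shootwards).
#'
#' @param profileModel a \code{rootProfile} (or data.frame position/value)
#' @param profileRef optional second profile
#' @param expected optional "increasing" or "decreasing" for profileModel
#' @return list of class \code{trendReport}
#' @export
trendCompare <- function(profileModel, profileRef = NULL, expected = NULL) {
  mono <- function(pr) {
    if (nrow(pr) < 3 || stats::sd(pr$value) == 0) return(NA_real_)
    suppressWarnings(stats::cor(pr$position, pr$value, method = "spearman"))
  }
  rep <- list(
    monotonicityModel = mono(profileModel),
    argmaxModel = profileModel$position[which.max(profileModel$value)],
    argminModel = profileModel$position[which.min(profileModel$value)],
    degenerate = stats::sd(profileModel$value) == 0)
  if (!is.null(profileRef)) {
    lo <- max(min(profileModel$position), min(profileRef$position))
    hi <- min(max(profileModel$position), max(profileRef$position))
    if (hi <= lo) stop("profiles do not overlap")
    ax <- seq(lo, hi, length.out = 50)
    va <- stats::approx(profileModel$position, profileModel$value, ax)$y
    vb <- stats::approx(profileRef$position, profileRef$value, ax)$y
    rep$monotonicityRef <- mono(data.frame(position = ax, value = vb))
    rep$rankCorrelation <-
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_
      else suppressWarnings(stats::cor(va, vb, method = "spearman"))
    rep$oppositeTrend <- isTRUE(rep$monotonicityModel *
                                  rep$monotonicityRef < 0)
  }
  if (!is.null(expected)) {
    expected <- match.arg(expected, c("increasing", "decreasing"))
    rep$expected <- expected
    rep$pass <- isTRUE(if (expected == "increasing")
      rep$monotonicityModel > 0 else rep$monotonicityModel < 0)
  }
  class(rep) <- "trendReport"
  rep
}

#' @export
print.trendReport <- function(x, ...) {
  cat("trend report: monotonicity", signif(x$monotonicityModel, 3))
  if (!is.null(x$monotonicityRef))
    cat(", reference", signif(x$monotonicityRef, 3),
        ", rank correlation", signif(x$rankCorrelation, 3))
  if (!is.null(x$pass))
    cat("; expected", x$expected, "->", if (x$pass) "PASS" else "FAIL")
  cat("\n")
  invisible(x)
}

#' Does a profile have a distal maximum?
#'
#' A profile "has a distal maximum" when its maximum lies in the distal
#' third of the axis and is prominent: the mean over the distal third
#' exceeds the mean over the proximal third by at least the given factor.
#' This operationalises the qualitative pattern "concentration maximum near
#' the distal region, declining towards the proximal region".
#'
#' @param profile a \code{rootProfile}
#' @param prominence required distal/proximal mean ratio (default 1.2)
#' @return logical
#' @export
hasDistalMaximum <- function(profile, prominence = 1.2) {
  pos <- profile$position; val <- profile$value
  lo <- min(pos); hi <- max(pos)
  third <- (hi - lo) / 3
  distal <- val[pos <= lo + third]
  proximal <- val[pos >= hi - third]
  argmax <- pos[which.max(val)]
  (argmax <= lo + third) &&
    mean(distal) >= prominence * mean(proximal)
}

#' Export a concentration colour map
#'
#' Writes a PNG image of a species field, one pixel per grid point (image
#' dimensions equal the grid dimensions; the tip is at the bottom), using a
#' fixed documented scale: the viridis palette mapped linearly over
#' \code{zlim} (defaults to the field range) in uM.  Deterministic: the same
#' result yields byte-identical files.
#'
#' @param result a \linkS4class{SteadyStateResult}
#' @param species point species name
#' @param path output PNG path
#' @param zlim colour scale limits in uM (default range of the field)
#' @return invisibly, the zlim used
#' @export
exportColormap <- function(result, species, path, zlim = NULL) {
  sp <- resolveSpecies(result, species)
  if (sp$kind != "point") stop("colour maps are per grid point species")
  f <- matrix(result@state@point[, sp$col], result@map@dims[1],
              result@map@dims[2])
  if (is.null(zlim)) zlim <- range(f)
  pal <- grDevices::hcl.colors(256, "viridis")
  idx <- pmax(1L, pmin(256L, 1L + floor(255 * (f - zlim[1]) /
                                          max(zlim[2] - zlim[1], 1e-300))))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  img <- array(0, dim = c(nrow(f), ncol(f), 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, ], nrow(f), ncol(f))
  png::writePNG(img[rev(seq_len(nrow(f))), , , drop = FALSE], path)
  invisible(zlim)
}

#' Export a species field or profile as CSV
#'
#' Fields are written as a full-precision grid-shaped matrix (rows = grid
#' rows from the tip); profiles as two columns.  Round-trips exactly.
#'
#' @param x a \linkS4class{SteadyStateResult} or \code{rootProfile}
#' @param species species name (fields only)
#' @param path output CSV path
#' @export
exportCSV <- function(x, path, species = NULL) {
  if (is(x, "SteadyStateResult")) {
    sp <- resolveSpecies(x, species)
    if (sp$kind != "point") stop("CSV field export is per grid point species")
    f <- matrix(x@state@point[, sp$col], x@map@dims[1], x@map@dims[2])
    utils::write.table(format(f, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(unclass(x))[c("position", "value")],
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a field CSV back as a matrix
#'
#' @param path CSV written by \code{\link{exportCSV}}
#' @return numeric matrix
#' @export
readFieldCSV <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}
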