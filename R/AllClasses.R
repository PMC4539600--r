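#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal Cholesky crossprod t solve
#' @importFrom stats setNames
NULL

SPECIES_POINT <- c("auxin", "ET", "CK",
                   "PLSm", "PLSp",
                   "PINm", "PINp",
                   "AUX1m", "AUX1p",
                   "Ra", "Ras", "Re", "Res", "CTR1", "CTR1s", "X")
SPECIES_FACE <- c("PINpMem", "AUX1pMem")

CELL_TYPES <- c("epidermis", "outer", "pericycle", "vascular", "columella", "QC")
ZONES <- c("colqc", "MZ", "EZ")

#' Geometry specification for the discretised root
#'
#' Describes the gridded two-dimensional root: grid spacing, overall length and
#' half width, the tip region (columella tiers and the quiescent centre), the
#' meristematic zone (MZ, short cells of fixed length) and the elongation zone
#' (EZ, cell lengths increasing shootwards), and the widths of the four cell
#' files on each side of the central axis (epidermis, outer ground-tissue
#' file, pericycle/border, vascular).
#'
#' All lengths are in micrometres and must be positive multiples of the grid
#' spacing.  Cell walls (merged with the plasma membrane) are one grid point
#' thick and lie on the lattice lines between cells.
#'
#' @slot spacing grid spacing h (um); the reference resolution is 2 um
#' @slot rootLength total longitudinal extent (um), tip to shoot boundary
#' @slot rootHalfWidth half the lateral extent (um)
#' @slot colLengths lengths of the columella cell tiers at the distal tip (um)
#' @slot qcLength length of the quiescent-centre tier (um)
#' @slot mzLength total length of the meristematic zone (um)
#' @slot mzCellLength length of one MZ cell (um)
#' @slot ezCellLengths EZ cell lengths, non-decreasing shootwards (um); the
#'   last value is repeated until \code{rootLength} is filled
#' @slot fileWidths named widths (um) of the files on one side, outermost
#'   first: epidermis, outer, pericycle, vascular
#' @slot wallThickness wall thickness in grid points (only 1 is supported)
#' @export
setClass("GridSpec", representation(
  spacing = "numeric",
  rootLength = "numeric",
  rootHalfWidth = "numeric",
  colLengths = "numeric",
  qcLength = "numeric",
  mzLength = "numeric",
  mzCellLength = "numeric",
  ezCellLengths = "numeric",
  fileWidths = "numeric",
  wallThickness = "integer"
))

setValidity("GridSpec", function(object) {
  h <- object@spacing
  msg <- character()
  if (length(h) != 1L || !is.finite(h) || h <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  lens <- c(object@rootLength, object@rootHalfWidth, object@colLengths,
            object@qcLength, object@mzLength, object@mzCellLength,
            object@ezCellLengths, object@fileWidths)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "all lengths must be positive and finite")
  else if (any(abs(lens / h - round(lens / h)) > 1e-9))
    msg <- c(msg, "all lengths must be multiples of the grid spacing")
  if (is.unsorted(object@ezCellLengths))
    msg <- c(msg, "ezCellLengths must be non-decreasing shootwards")
  if (!identical(sort(names(object@fileWidths)),
                 sort(c("epidermis", "outer", "pericycle", "vascular"))))
    msg <- c(msg, "fileWidths must be named epidermis, outer, pericycle, vascular")
  else if (abs(sum(object@fileWidths) - object@rootHalfWidth) > 1e-9)
    msg <- c(msg, "fileWidths must sum to rootHalfWidth")
  if (object@wallThickness != 1L)
    msg <- c(msg, "only wallThickness = 1 grid point is supported")
  if (abs(object@mzLength / object@mzCellLength -
          round(object@mzLength / object@mzCellLength)) > 1e-9)
    msg <- c(msg, "mzLength must be a multiple of mzCellLength")
  if (length(msg)) msg else TRUE
})

#' Labelled two-dimensional root map
#'
#' The spatial substrate of the model: a matrix of grid points labelled as
#' cytosol or wall, the identity, type, zone and tier of every cell, and the
#' shoot-boundary flags at the proximal edge.  Row 1 is the distal tip; rows
#' increase shootwards.  Column 1 is the left epidermis edge.
#'
#' @slot spec the \linkS4class{GridSpec} the map was built from
#' @slot dims grid-point counts \code{c(rows, cols)}
#' @slot kind integer matrix, 1 = cytosol, 2 = wall
#' @slot cellId integer matrix; cell id for cytosol points, 0 on walls
#' @slot cells per-cell table: id, tier (1 at the tip, increasing shootwards),
#'   file index, type, zone, and bounding wall lines (row0/row1/col0/col1)
#' @slot boundary shoot-boundary table: grid column, point index (top wall
#'   row), and logical flags auxinInflux (pericycle+vascular files),
#'   auxinEfflux (epidermis files), gas (all)
#' @export
setClass("RootMap", representation(
  spec = "GridSpec",
  dims = "integer",
  kind = "matrix",
  cellId = "matrix",
  cells = "data.frame",
  boundary = "data.frame"
))

#' Kinetic and transport parameter set
#'
#' A named, non-negative parameter vector covering every reaction arrow of the
#' crosstalk network, diffusion coefficients, carrier permeabilities, boundary
#' exchange coefficients and shoot-side reference concentrations.  Use
#' \code{\link{defaultParameters}} for the calibrated defaults and
#' \code{\link{applyGenotype}} for mutant overrides.
#'
#' @slot values named numeric vector of parameter values
#' @slot flags named logical vector of model switches (e.g.
#'   \code{pls_auxin_regulation_off}, \code{ck_activates_auxin})
#' @export
setClass("KineticParameters", representation(
  values = "numeric",
  flags = "logical"
))

setValidity("KineticParameters", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(names(v)) || any(!nzchar(names(v))))
    msg <- c(msg, "all parameter values must be named")
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "all parameter values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Named genotype: a set of parameter overrides
#'
#' Encodes a mutant or overexpression line as multiplicative/absolute
#' overrides of \linkS4class{KineticParameters} keys plus model-ablation
#' flags.  The wild type carries no overrides.
#'
#' @slot name genotype name
#' @slot overrides named list; each element is either an absolute value
#'   (\code{list(set = x)}) or a multiplier (\code{list(mul = x)})
#' @slot flags named logical vector of ablation switches
#' @export
setClass("Genotype", representation(
  name = "character",
  overrides = "list",
  flags = "logical"
))

#' Solver settings
#'
#' Numerical controls for the finite-volume steady-state and trajectory
#' solvers.  Defaults follow the reference tolerances: 1e-5 for the Picard
#' (nonlinear) iteration and 1e-10 for the linear solves.
#'
#' @slot nonlinearTol relative Picard update tolerance
#' @slot linearTol relative residual tolerance of the linear solves
#' @slot maxPicardIters Picard sweep cap per pseudo-time step (and for the
#'   terminal polish)
#' @slot maxLinearIters conjugate-gradient iteration cap
#' @slot dt0 initial pseudo-time step (s)
#' @slot dtMax largest pseudo-time step (s)
#' @slot dtGrowEvery double the step every this many steps
#' @slot maxSteps pseudo-time step cap
#' @slot steadyTol steady-state criterion: max relative rate of change (1/s)
#' @slot preconditioner "cholesky" or "jacobi"
#' @export
setClass("SolverSettings", representation(
  nonlinearTol = "numeric",
  linearTol = "numeric",
  maxPicardIters = "integer",
  maxLinearIters = "integer",
  dt0 = "numeric",
  dtMax = "numeric",
  dtGrowEvery = "integer",
  maxSteps = "integer",
  steadyTol = "numeric",
  preconditioner = "character"
))

setValidity("SolverSettings", function(object) {
  if (object@nonlinearTol <= 0 || object@linearTol <= 0 ||
      object@steadyTol <= 0)
    "tolerances must be positive" else TRUE
})

#' Concentration state of all model species
#'
#' Concentrations (uM) of the 16 point species at every grid point plus the
#' membrane-bound PIN and AUX1 pools, which live on the membrane faces of each
#' cell (stored per face; zero anywhere else by construction).
#'
#' @slot point numeric matrix, grid points x species (column names are the
#'   species); non-hormone species are zero on wall points
#' @slot mem numeric matrix, membrane faces x c(PINpMem, AUX1pMem)
#' @export
setClass("SpeciesState", representation(
  point = "matrix",
  mem = "matrix"
))

#' Converged steady state with diagnostics
#'
#' @slot map the \linkS4class{RootMap} solved on
#' @slot state the final \linkS4class{SpeciesState}
#' @slot genotype genotype name
#' @slot converged logical
#' @slot iterations pseudo-time steps taken
#' @slot picardUpdate final relative Picard update per species
#' @slot rate final relative rate of change per species (1/s)
#' @slot time pseudo-time reached (s)
#' @slot ledger boundary/transport flux ledger (list; see
#'   \code{\link{fluxLedger}})
#' @slot params the genotype-applied \linkS4class{KineticParameters} used
#' @slot settings the \linkS4class{SolverSettings} used
#' @export
setClass("SteadyStateResult", representation(
  map = "RootMap",
  state = "SpeciesState",
  genotype = "character",
  converged = "logical",
  iterations = "integer",
  picardUpdate = "numeric",
  rate = "numeric",
  time = "numeric",
  ledger = "list",
  params = "KineticParameters",
  settings = "SolverSettings"
))

# ---- show methods -----------------------------------------------------------

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec: ", object@rootLength, " x ", 2 * object@rootHalfWidth,
      " um at h = ", object@spacing, " um\n", sep = "")
  cat("  tip: columella ", paste(object@colLengths, collapse = "+"),
      " um, QC ", object@qcLength, " um; MZ ", object@mzLength,
      " um (cells ", object@mzCellLength, " um)\n", sep = "")
  cat("  EZ ramp: ", paste(object@ezCellLengths, collapse = ", "),
      " um\n  file widths: ",
      paste(names(object@fileWidths), object@fileWidths,
            sep = "=", collapse = ", "), "\n", sep = "")
})

setMethod("show", "RootMap", function(object) {
  cat("RootMap: ", object@dims[1], " x ", object@dims[2], " grid points (",
      sum(object@kind == 1L), " cytosol), ", nrow(object@cells),
      " cells in ", max(object@cells$tier), " tiers\n", sep = "")
})

setMethod("show", "KineticParameters", function(object) {
  cat("KineticParameters: ", length(object@values), " constants, flags: ",
      paste(names(object@flags)[object@flags], collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "Genotype", function(object) {
  cat("Genotype '", object@name, "': ", length(object@overrides),
      " overrides", sep = "")
  if (any(object@flags)) cat("; flags:",
      paste(names(object@flags)[object@flags], collapse = ", "))
  cat("\n")
})

setMethod("show", "SteadyStateResult", function(object) {
  cat("SteadyStateResult [", object@genotype, "]: ",
      if (object@converged) "converged" else "NOT converged",
      " after ", object@iterations, " steps (t = ",
      signif(object@time, 4), " s)\n", sep = "")
  cat("  max relative rate: ", signif(max(object@rate), 3),
      " /s;  max Picard update: ", signif(max(object@picardUpdate), 3),
      "\n", sep = "")
})
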