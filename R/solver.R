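# Finite-volume discretisation and solvers.  Each grid point is a finite
# volume; fluxes are integrated over the faces enumerated by interfaces().
# Steady states are found by implicit pseudo-time stepping to stationarity
# with Picard linearisation of the nonlinear reaction/carrier terms at each
# step.  The symmetric positive-definite linear systems (diffusion + decay:
# ethylene, cytokinin, cytosolic PLS protein) are solved by preconditioned
# conjugate gradients to a relative residual of linearTol; the structurally
# asymmetric systems (auxin with carrier-mediated membrane crossing, and the
# PIN/AUX1 pools coupled through recycling) use a sparse direct factorisation.

#' Solver settings constructor
#'
#' @param nonlinearTol Picard (nonlinear) relative update tolerance
#'   (reference value 1e-5)
#' @param linearTol linear-solve relative residual tolerance (reference 1e-10)
#' @param maxPicardIters Picard sweeps per pseudo-time step
#' @param maxLinearIters conjugate-gradient iteration cap
#' @param dt0 initial pseudo-time step (s)
#' @param dtMax largest pseudo-time step (s)
#' @param dtGrowEvery double the step every this many steps
#' @param maxSteps pseudo-time step cap
#' @param steadyTol steady-state criterion on the max relative rate of
#'   change (1/s)
#' @param preconditioner "cholesky" or "jacobi"
#' @return a \linkS4class{SolverSettings}
#' @export
solverSettings <- function(nonlinearTol = 1e-5, linearTol = 1e-10,
                           maxPicardIters = 4L, maxLinearIters = 500L,
                           dt0 = 0.5, dtMax = 128, dtGrowEvery = 6L,
                           maxSteps = 600L, steadyTol = 1e-7,
                           preconditioner = "cholesky") {
  new("SolverSettings", nonlinearTol = nonlinearTol, linearTol = linearTol,
      maxPicardIters = as.integer(maxPicardIters),
      maxLinearIters = as.integer(maxLinearIters),
      dt0 = dt0, dtMax = dtMax, dtGrowEvery = as.integer(dtGrowEvery),
      maxSteps = as.integer(maxSteps), steadyTol = steadyTol,
      preconditioner = preconditioner)
}

# graph Laplacian (positive semi-definite, "outflow" convention) over np
# points from an edge list; w is a scalar or per-edge weight
lapFromEdges <- function(a, b, w, np) {
  if (length(w) == 1L) w <- rep(w, length(a))
  Matrix::sparseMatrix(i = c(a, b, a, b), j = c(b, a, a, b),
                       x = c(-w, -w, w, w), dims = c(np, np))
}

#' Build the solver topology cache for a root map
#'
#' Precomputes everything the finite-volume solver needs: point index sets,
#' face lists split by kind, PIN polarity-allowed membrane faces
#' (vascular/pericycle: rootward; epidermis and outer file: shootward;
#' columella/QC: lateral-outward), per-cell groupings for the recycling
#' redistribution, unweighted graph Laplacians for the cytosol, wall and
#' membrane face sets, and the shoot-boundary index sets.
#'
#' @param map a \linkS4class{RootMap}
#' @return a list (see source); treated as opaque by callers
#' @export
rootTopology <- function(map) {
  nr <- map@dims[1]; nc <- map@dims[2]; np <- nr * nc
  h <- map@spec@spacing
  kindv <- as.integer(map@kind)
  isCyt <- kindv == 1L
  cellOf <- as.integer(map@cellId)
  idxCyt <- which(isCyt)
  cellTypePt <- rep("", np)
  cellTypePt[idxCyt] <- map@cells$type[cellOf[idxCyt]]

  fc <- interfaces(map)
  cc <- fc[fc$kind == "cc", ]
  ww <- fc[fc$kind == "ww", ]
  mb <- fc[fc$kind == "membrane", ]
  memCell <- cellOf[mb$a]
  memType <- map@cells$type[memCell]
  pin <- (memType %in% c("vascular", "pericycle") & mb$orientation == "rootward") |
         (memType %in% c("epidermis", "outer") & mb$orientation == "shootward") |
         (memType %in% c("columella", "QC") & mb$orientation == "lateral-out")

  ncell <- nrow(map@cells)
  cytPos <- integer(np); cytPos[idxCyt] <- seq_along(idxCyt)
  cellOfCyt <- cellOf[idxCyt]
  nCytC <- tabulate(cellOfCyt, ncell)
  nMemC <- tabulate(memCell, ncell)
  nPinC <- tabulate(memCell[pin], ncell)

  # triplet patterns for the recycling coupling blocks (cyt point x face)
  couple <- function(faceSel) {
    fCell <- memCell[faceSel]
    byCell <- split(seq_along(fCell), fCell)
    cytByCell <- split(seq_along(idxCyt), cellOfCyt)
    iL <- vector("list", length(byCell)); jL <- iL
    for (k in seq_along(byCell)) {
      cid <- as.character(names(byCell)[k])
      pc <- cytByCell[[cid]]
      pf <- byCell[[k]]
      iL[[k]] <- rep(pc, times = length(pf))
      jL[[k]] <- rep(pf, each = length(pc))
    }
    list(i = unlist(iL, use.names = FALSE), j = unlist(jL, use.names = FALSE))
  }
  pinIdx <- which(pin)
  cplPin <- couple(pin)
  cplAll <- couple(rep(TRUE, nrow(mb)))

  nCytV <- length(idxCyt)
  AggCyt <- Matrix::sparseMatrix(i = cellOfCyt, j = seq_len(nCytV), x = 1,
                                 dims = c(ncell, nCytV))
  AggPin <- Matrix::sparseMatrix(i = memCell[pin], j = seq_along(pinIdx),
                                 x = 1, dims = c(ncell, length(pinIdx)))
  AggMem <- Matrix::sparseMatrix(i = memCell, j = seq_along(memCell), x = 1,
                                 dims = c(ncell, length(memCell)))

  Lcyt <- lapFromEdges(cc$a, cc$b, 1, np)
  Lwall <- lapFromEdges(ww$a, ww$b, 1, np)
  Lmem <- lapFromEdges(mb$a, mb$b, 1, np)
  LcytSub <- Lcyt[idxCyt, idxCyt, drop = FALSE]
  nmem <- nrow(mb)
  Smc <- Matrix::sparseMatrix(i = mb$a, j = seq_len(nmem), x = 1,
                              dims = c(np, nmem))
  Smw <- Matrix::sparseMatrix(i = mb$b, j = seq_len(nmem), x = 1,
                              dims = c(np, nmem))

  top <- map@boundary
  list(map = map, nr = nr, nc = nc, np = np, h = h,
       kindv = kindv, isCyt = isCyt, idxCyt = idxCyt, cytPos = cytPos,
       cellOf = cellOf, cellOfCyt = cellOfCyt, cellTypePt = cellTypePt,
       ncell = ncell, nCytC = nCytC, nMemC = nMemC, nPinC = nPinC,
       mem = list(cyt = mb$a, wall = mb$b, cell = memCell,
                  orient = mb$orientation, pin = pin),
       pinIdx = pinIdx, cplPin = cplPin, cplAll = cplAll,
       AggCyt = AggCyt, AggPin = AggPin, AggMem = AggMem,
       Smc = Smc, Smw = Smw,
       Lcyt = Lcyt, Lwall = Lwall, Lmem = Lmem, Lall = Lcyt + Lwall + Lmem,
       LcytSub = LcytSub,
       bnd = list(points = top$point, cols = top$col,
                  influx = top$point[top$auxinInflux],
                  efflux = top$point[top$auxinEfflux],
                  gas = top$point[top$gas]),
       cache = new.env(parent = emptyenv()))
}

#' Uniform initial state
#'
#' Small uniform positive concentrations (\code{init_conc}) on each species'
#' support: hormones everywhere (cytosol and wall), other species in the
#' cytosol only; receptor pairs start at 90/10 inactive/active of their
#' totals; membrane pools start at \code{init_conc} on their allowed faces.
#' No randomness.
#'
#' @param map a \linkS4class{RootMap} (or a topology from
#'   \code{\link{rootTopology}})
#' @param p a \linkS4class{KineticParameters}
#' @return a \linkS4class{SpeciesState}
#' @export
initialState <- function(map, p) {
  topo <- if (is(map, "RootMap")) rootTopology(map) else map
  v <- p@values
  c0 <- v[["init_conc"]]
  P <- matrix(0, topo$np, length(SPECIES_POINT),
              dimnames = list(NULL, SPECIES_POINT))
  P[, c("auxin", "ET", "CK")] <- c0
  cyt <- topo$isCyt
  for (sp in c("PLSm", "PLSp", "PINm", "PINp", "AUX1m", "AUX1p", "X"))
    P[cyt, sp] <- c0
  P[cyt, "Ra"] <- 0.9 * v[["Ra_total"]]; P[cyt, "Ras"] <- 0.1 * v[["Ra_total"]]
  P[cyt, "Re"] <- 0.9 * v[["Re_total"]]; P[cyt, "Res"] <- 0.1 * v[["Re_total"]]
  P[cyt, "CTR1"] <- 0.9 * v[["CTR_total"]]
  P[cyt, "CTR1s"] <- 0.1 * v[["CTR_total"]]
  nmem <- length(topo$mem$cyt)
  M <- matrix(0, nmem, 2, dimnames = list(NULL, SPECIES_FACE))
  M[topo$mem$pin, "PINpMem"] <- c0
  M[, "AUX1pMem"] <- c0
  new("SpeciesState", point = P, mem = M)
}

#' Preconditioned conjugate gradients
#'
#' Solves a symmetric positive-definite sparse system to a relative residual
#' of \code{tol}.  The preconditioner is either a cached sparse Cholesky
#' factorisation (strong; typically one or two iterations) or Jacobi
#' (diagonal).
#'
#' @param A dsCMatrix (symmetric sparse)
#' @param b right-hand side
#' @param x0 initial guess
#' @param tol relative residual tolerance
#' @param maxit iteration cap
#' @param prec function of the residual returning the preconditioned residual
#' @return list(x, iters, converged)
#' @export
pcgSolve <- function(A, b, x0 = NULL, tol = 1e-10, maxit = 500L,
                     prec = NULL) {
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(list(x = numeric(length(b)), iters = 0L,
                           converged = TRUE))
  x <- if (is.null(x0)) numeric(length(b)) else x0
  if (is.null(prec)) prec <- identity
  r <- b - as.numeric(A %*% x)
  z <- prec(r)
  pv <- z
  rz <- sum(r * z)
  it <- 0L; ok <- sqrt(sum(r^2)) / bn < tol
  while (!ok && it < maxit) {
    it <- it + 1L
    Ap <- as.numeric(A %*% pv)
    alpha <- rz / sum(pv * Ap)
    x <- x + alpha * pv
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / bn < tol) { ok <- TRUE; break }
    z <- prec(r)
    rzNew <- sum(r * z)
    pv <- z + (rzNew / rz) * pv
    rz <- rzNew
  }
  list(x = x, iters = it, converged = ok)
}

# cached SPD solve: builds (or reuses) the matrix and its Cholesky
# preconditioner for a given key, then runs PCG
spdSolve <- function(topo, key, buildA, b, x0, settings) {
  cache <- topo$cache
  ent <- cache[[key]]
  if (is.null(ent)) {
    A <- Matrix::forceSymmetric(buildA())
    prec <- if (settings@preconditioner == "jacobi") {
      dinv <- 1 / Matrix::diag(A)
      function(r) dinv * r
    } else {
      ch <- Matrix::Cholesky(A, LDL = FALSE)
      function(r) as.numeric(Matrix::solve(ch, r))
    }
    ent <- list(A = A, prec = prec)
    cache[[key]] <- ent
  }
  res <- pcgSolve(ent$A, b, x0 = x0, tol = settings@linearTol,
                  maxit = settings@maxLinearIters, prec = ent$prec)
  if (!res$converged)
    warning("PCG did not reach linearTol for ", key, call. = FALSE)
  res$x
}

# carrier scalings from the membrane pools (sigma = concentration * h)
carrierVelocities <- function(M, topo, v) {
  h <- topo$h
  sigP <- M[, "PINpMem"] * h
  sigA <- M[, "AUX1pMem"] * h
  list(vout = v[["P_PIN"]] *
         carrierScaling(sigP, v[["sigma_PIN_ref"]], v[["sigma_PIN_max"]]) / h,
       vin = v[["P_AUX1"]] *
         carrierScaling(sigA, v[["sigma_AUX1_ref"]], v[["sigma_AUX1_max"]]) / h)
}

# boundary auxin-efflux velocity per flagged top point: proportional to the
# local shootward membrane PIN of the epidermal cell beneath
boundaryEffluxVelocity <- function(M, topo, v) {
  eff <- topo$bnd$efflux
  key <- "bndEffFace"
  f <- topo$cache[[key]]
  if (is.null(f)) {
    f <- match(eff, ifelse(topo$mem$orient == "shootward",
                           topo$mem$wall, NA_integer_))
    topo$cache[[key]] <- f
  }
  sig <- ifelse(is.na(f), 0, M[f, "PINpMem"] * topo$h)
  v[["P_PIN"]] *
    carrierScaling(sig, v[["sigma_PIN_ref"]], v[["sigma_PIN_max"]]) / topo$h
}

# one Picard sweep of the semi-implicit step: solves/updates every species
# once, Gauss-Seidel over species, from the step-start state `prev` with the
# current iterate `st` supplying the lagged nonlinear terms
picardSweep <- function(st, prev, topo, p, dt, settings) {
  v <- p@values
  h <- topo$h; np <- topo$np
  cyt <- topo$isCyt; idxCyt <- topo$idxCyt
  P <- st$P; M <- st$M
  P0 <- prev$P; M0 <- prev$M
  invdt <- if (is.finite(dt)) 1 / dt else 0
  sCyt <- function(cols) {
    out <- lapply(cols, function(cn) P[idxCyt, cn])
    names(out) <- cols
    out
  }

  # ---- auxin: asymmetric system over all points (carriers, boundary) ----
  cv <- carrierVelocities(M, topo, v)
  mc <- topo$mem$cyt; mw <- topo$mem$wall
  diagv <- invdt + v[["d_auxin"]] * cyt
  vb <- boundaryEffluxVelocity(M, topo, v)
  iT <- c(mc, mc, mw, mw, topo$bnd$efflux)
  jT <- c(mc, mw, mw, mc, topo$bnd$efflux)
  xT <- c(cv$vout, -cv$vin, cv$vin, -cv$vout, vb)
  Acar <- Matrix::sparseMatrix(i = iT, j = jT, x = xT, dims = c(np, np))
  Aaux <- (v[["D_auxin"]] * topo$Lcyt + v[["D_auxin_wall"]] * topo$Lwall) / h^2 +
    Matrix::Diagonal(np, diagv) + Acar
  sA <- sCyt(c("auxin", "CK", "X"))
  syn <- auxinReactionRate(sA, p) + v[["d_auxin"]] * sA$auxin
  rhs <- P0[, "auxin"] * invdt
  rhs[idxCyt] <- rhs[idxCyt] + syn
  xb <- P[pmax(topo$bnd$influx - 1L, 1L), "X"]
  rhs[topo$bnd$influx] <- rhs[topo$bnd$influx] +
    v[["I0_auxin"]] / (1 + xb / v[["K_X_influx"]]) / h
  P[, "auxin"] <- as.numeric(Matrix::solve(Aaux, rhs))

  # ---- cytokinin then ethylene: SPD, PCG ----
  gasSolve <- function(sp, D, kb, cref, synCyt, d) {
    key <- sprintf("gas_%s_%g", sp, dt)
    b <- P0[, sp] * invdt
    b[idxCyt] <- b[idxCyt] + synCyt
    b[topo$bnd$gas] <- b[topo$bnd$gas] + kb * cref / h
    spdSolve(topo, key, function() {
      diagv <- invdt + d * cyt
      diagv[topo$bnd$gas] <- diagv[topo$bnd$gas] + kb / h
      D * (topo$Lcyt + topo$Lwall + topo$Lmem) / h^2 +
        Matrix::Diagonal(np, diagv)
    }, b, P[, sp], settings)
  }
  sC <- sCyt(c("auxin", "CK"))
  synCK <- cytokininReactionRate(sC, p, topo$cellTypePt[idxCyt]) +
    v[["d_CK"]] * sC$CK
  P[, "CK"] <- gasSolve("CK", v[["D_CK"]], v[["k_bnd_CK"]], v[["CK_shoot"]],
                        synCK, v[["d_CK"]])
  sE <- sCyt(c("auxin", "CK", "ET"))
  synET <- ethyleneReactionRate(sE, p) + v[["d_ET"]] * sE$ET
  P[, "ET"] <- gasSolve("ET", v[["D_ET"]], v[["k_bnd_ET"]], v[["ET_shoot"]],
                        synET, v[["d_ET"]])

  # ---- receptor pairs: exact pointwise backward-Euler 2x2 solves ----
  pair <- function(inact, act, aOn, bOff) {
    dtv <- if (is.finite(dt)) dt else 1e12
    a <- dtv * aOn; bb <- dtv * bOff
    den <- 1 + a + bb
    i0 <- P0[idxCyt, inact]; a0 <- P0[idxCyt, act]
    if (!is.finite(dt)) { tot <- i0 + a0
      P[idxCyt, inact] <<- tot * bb / (a + bb + 1e-300)
      P[idxCyt, act] <<- tot * a / (a + bb + 1e-300)
    } else {
      P[idxCyt, inact] <<- ((1 + bb) * i0 + bb * a0) / den
      P[idxCyt, act] <<- (a * i0 + (1 + a) * a0) / den
    }
  }
  pair("Ra", "Ras", v[["k_Ra_on"]] * P[idxCyt, "auxin"], v[["k_Ra_off"]])
  pair("Re", "Res",
       v[["k_Re_act"]] + v[["k_Re_PLS"]] * P[idxCyt, "PLSp"],
       v[["k_ET_bind"]] * P[idxCyt, "ET"])
  pair("CTR1", "CTR1s", v[["k_CTR_act"]] * P[idxCyt, "Res"],
       v[["k_CTR_deact"]])

  lin <- function(sp, prod, d) {
    dtv <- if (is.finite(dt)) dt else 1e12
    P[idxCyt, sp] <<- (P0[idxCyt, sp] / dtv * is.finite(dt) + prod) /
      (1 / dtv * is.finite(dt) + d)
  }
  lin("X", v[["k_X_syn"]] / (1 + P[idxCyt, "CTR1s"] / v[["K_X_CTR"]]),
      v[["d_X"]])

  # ---- mRNAs: pointwise ----
  sM <- sCyt(c("auxin", "CK", "X", "Ras", "PLSm", "PLSp", "PINm", "PINp",
               "AUX1m", "AUX1p"))
  trPLS <- plsExpressionRates(sM, p)$PLSm + v[["d_PLSm"]] * sM$PLSm
  lin("PLSm", trPLS, v[["d_PLSm"]])
  trPIN <- pinExpressionRates(sM, p)$PINm + v[["d_PINm"]] * sM$PINm
  lin("PINm", trPIN, v[["d_PINm"]])
  trA1 <- aux1ExpressionRates(sM, p)$AUX1m + v[["d_AUX1m"]] * sM$AUX1m
  lin("AUX1m", trA1, v[["d_AUX1m"]])

  # ---- PLS protein: SPD over cytosol ----
  key <- sprintf("PLSp_%g", dt)
  bb <- P0[idxCyt, "PLSp"] * invdt + v[["k_PLSp_tln"]] * P[idxCyt, "PLSm"]
  P[idxCyt, "PLSp"] <- spdSolve(topo, key, function()
    v[["D_PLSp"]] * topo$LcytSub / h^2 +
      Matrix::Diagonal(length(idxCyt), invdt + v[["d_PLSp"]]),
    bb, P[idxCyt, "PLSp"], settings)

  # ---- PIN and AUX1 carrier systems (cytosolic pool + membrane faces,
  #      coupled by conservative recycling; asymmetric, direct solve) ----
  carrierSystem <- function(spCyt, spMem, spMrna, faceSel, cpl, kExo,
                            kEndoFace, dProt, Dp, tln, mPerCell) {
    nCytV <- length(idxCyt)
    fIdx <- which(faceSel)
    nF <- length(fIdx)
    facePos <- integer(length(faceSel)); facePos[fIdx] <- seq_len(nF)
    dfTrip <- topo$cache[["dfTrip"]]
    if (is.null(dfTrip)) {
      T3 <- methods::as(topo$LcytSub, "TsparseMatrix")
      dfTrip <- list(i = T3@i + 1L, j = T3@j + 1L, x = T3@x)
      topo$cache[["dfTrip"]] <- dfTrip
    }
    # cpl$j indexes faces within the selected set; cpl$i within idxCyt
    jFace <- cpl$j
    cellOfSel <- topo$mem$cell[fIdx]
    iT <- c(dfTrip$i, seq_len(nCytV), cpl$i, nCytV + seq_len(nF),
            nCytV + jFace)
    jT <- c(dfTrip$j, seq_len(nCytV), nCytV + jFace, nCytV + seq_len(nF),
            cpl$i)
    nCcpl <- topo$nCytC[cellOfSel[cpl$j]]
    mCcpl <- mPerCell[cellOfSel[cpl$j]]
    xT <- c(dfTrip$x * Dp / h^2,
            rep(invdt + dProt + kExo, nCytV),
            -kEndoFace[jFace] / nCcpl,
            invdt + dProt + kEndoFace,
            -kExo / mCcpl)
    A <- Matrix::sparseMatrix(i = iT, j = jT, x = xT,
                              dims = c(nCytV + nF, nCytV + nF))
    b <- c(P0[idxCyt, spCyt] * invdt + tln * P[idxCyt, spMrna],
           M0[fIdx, spMem] * invdt)
    z <- as.numeric(Matrix::solve(A, b))
    P[idxCyt, spCyt] <<- z[seq_len(nCytV)]
    M[, spMem] <<- 0
    M[fIdx, spMem] <<- z[nCytV + seq_len(nF)]
  }
  kEndoPin <- v[["k_PIN_endo"]] /
    (1 + P[topo$mem$cyt[topo$pinIdx], "auxin"] / v[["K_PIN_endo_auxin"]])
  carrierSystem("PINp", "PINpMem", "PINm", topo$mem$pin, topo$cplPin,
                v[["k_PIN_exo"]], kEndoPin, v[["d_PINp"]], v[["D_PINp"]],
                v[["k_PINp_tln"]], topo$nPinC)
  carrierSystem("AUX1p", "AUX1pMem", "AUX1m",
                rep(TRUE, length(topo$mem$cyt)), topo$cplAll,
                v[["k_AUX1_exo"]],
                rep(v[["k_AUX1_endo"]], length(topo$mem$cyt)),
                v[["d_AUX1p"]], v[["D_AUX1p"]], v[["k_AUX1p_tln"]],
                topo$nMemC)

  list(P = P, M = M)
}

relUpdate <- function(a, b) {
  uP <- max(abs(a$P - b$P)) / (max(abs(a$P)) + 1e-12)
  uM <- if (length(a$M)) max(abs(a$M - b$M)) / (max(abs(a$M)) + 1e-12) else 0
  max(uP, uM)
}

perSpeciesRate <- function(a, b, dt) {
  r <- vapply(colnames(a$P), function(sp)
    max(abs(a$P[, sp] - b$P[, sp])) / (dt * (max(abs(a$P[, sp])) + 1e-12)),
    numeric(1))
  rm <- vapply(colnames(a$M), function(sp)
    max(abs(a$M[, sp] - b$M[, sp])) / (dt * (max(abs(a$M[, sp])) + 1e-12)),
    numeric(1))
  c(r, rm)
}

#' Solve for the steady state by Picard iteration
#'
#' Implicit pseudo-time stepping to stationarity: each step is a backward-
#' Euler update whose nonlinear reaction and carrier terms are re-linearised
#' by Picard sweeps (Gauss-Seidel over species) until the relative update
#' falls below \code{nonlinearTol} (or the sweep cap).  The pseudo-time step
#' grows geometrically from \code{dt0} to \code{dtMax}.  Stationarity is
#' declared when every species' maximum relative rate of change drops below
#' \code{steadyTol} and the final Picard update is below
#' \code{nonlinearTol}; non-convergence within \code{maxSteps} returns a
#' diagnostic result with \code{converged = FALSE}.
#'
#' @param map a \linkS4class{RootMap}
#' @param params \linkS4class{KineticParameters} (genotype not yet applied)
#' @param genotype a \linkS4class{Genotype} or genotype name (default "wt")
#' @param settings a \linkS4class{SolverSettings}
#' @param state optional initial \linkS4class{SpeciesState}
#' @param verbose print progress every 25 steps
#' @return a \linkS4class{SteadyStateResult}
#' @export
#' @examples
#' map <- buildRootMap(miniGridSpec())
#' res <- picardSteadyState(map, defaultParameters(),
#'                          settings = solverSettings(maxSteps = 50))
picardSteadyState <- function(map, params = defaultParameters(),
                              genotype = "wt",
                              settings = solverSettings(),
                              state = NULL, verbose = FALSE) {
  g <- if (is.character(genotype)) genotype(genotype) else genotype
  p <- applyGenotype(params, g)
  topo <- rootTopology(map)
  st0 <- if (is.null(state)) initialState(topo, p) else state
  st <- list(P = st0@point, M = st0@mem)
  dt <- settings@dt0
  tNow <- 0
  converged <- FALSE
  upd <- Inf
  rateV <- setNames(rep(Inf, length(SPECIES_POINT) + 2L),
                    c(SPECIES_POINT, SPECIES_FACE))
  nstep <- 0L
  for (step in seq_len(settings@maxSteps)) {
    nstep <- step
    if (step > 1L && (step - 1L) %% settings@dtGrowEvery == 0L &&
        dt < settings@dtMax) {
      dt <- min(dt * 2, settings@dtMax)
      rm(list = ls(topo$cache)[grep("^(gas|PLSp)_", ls(topo$cache))],
         envir = topo$cache)
    }
    prev <- st
    for (sweep in seq_len(settings@maxPicardIters)) {
      stOld <- st
      st <- picardSweep(st, prev, topo, p, dt, settings)
      upd <- relUpdate(st, stOld)
      if (upd < settings@nonlinearTol) break
    }
    rateV <- perSpeciesRate(st, prev, dt)
    tNow <- tNow + dt
    if (verbose && step %% 25L == 0L)
      message(sprintf("step %d  t=%.0f  dt=%.1f  rate=%.3g  upd=%.3g",
                      step, tNow, dt, max(rateV), upd))
    if (max(rateV) < settings@steadyTol && upd < settings@nonlinearTol) {
      converged <- TRUE
      break
    }
  }
  stS4 <- new("SpeciesState", point = st$P, mem = st$M)
  led <- fluxLedgerInternal(st, topo, p)
  new("SteadyStateResult", map = map, state = stS4, genotype = g@name,
      converged = converged, iterations = nstep,
      picardUpdate = c(all = upd), rate = rateV, time = tNow,
      ledger = led, params = p, settings = settings)
}

#' Assemble the discrete mass-balance operators
#'
#' Returns the per-species implicit finite-volume operators (matrix and
#' right-hand side) for the spatially coupled hormones at a given
#' linearisation state: one balance row per grid point combining transport
#' divergence, decay and the (lagged) reaction sources.  With \code{dt = Inf}
#' the pseudo-time mass term vanishes and \code{A \%*\% c - b} is the steady
#' mass-balance residual at state \code{c}.  The diffusive part of each
#' operator is symmetric positive definite.
#'
#' @param map a \linkS4class{RootMap}
#' @param state a \linkS4class{SpeciesState} (linearisation point)
#' @param params \linkS4class{KineticParameters}
#' @param genotype genotype or name
#' @param dt pseudo-time step (default Inf = steady operator)
#' @return named list (auxin, ET, CK) of list(A, b)
#' @export
assembleSystem <- function(map, state, params = defaultParameters(),
                           genotype = "wt", dt = Inf) {
  g <- if (is.character(genotype)) genotype(genotype) else genotype
  p <- applyGenotype(params, g)
  topo <- rootTopology(map)
  if (!all(dim(state@point) == c(topo$np, length(SPECIES_POINT))))
    stop("state/map dimensions are inconsistent")
  v <- p@values
  h <- topo$h; np <- topo$np
  cyt <- topo$isCyt; idxCyt <- topo$idxCyt
  P <- state@point; M <- state@mem
  invdt <- if (is.finite(dt)) 1 / dt else 0

  cv <- carrierVelocities(M, topo, v)
  mc <- topo$mem$cyt; mw <- topo$mem$wall
  vb <- boundaryEffluxVelocity(M, topo, v)
  Acar <- Matrix::sparseMatrix(
    i = c(mc, mc, mw, mw, topo$bnd$efflux),
    j = c(mc, mw, mw, mc, topo$bnd$efflux),
    x = c(cv$vout, -cv$vin, cv$vin, -cv$vout, vb), dims = c(np, np))
  Aaux <- (v[["D_auxin"]] * topo$Lcyt + v[["D_auxin_wall"]] * topo$Lwall) / h^2 +
    Matrix::Diagonal(np, invdt + v[["d_auxin"]] * cyt) + Acar
  sl <- function(cols) { o <- lapply(cols, function(cn) P[idxCyt, cn])
    names(o) <- cols; o }
  sA <- sl(c("auxin", "CK", "X"))
  bAux <- P[, "auxin"] * invdt
  bAux[idxCyt] <- bAux[idxCyt] + auxinReactionRate(sA, p) +
    v[["d_auxin"]] * sA$auxin
  xb <- P[pmax(topo$bnd$influx - 1L, 1L), "X"]
  bAux[topo$bnd$influx] <- bAux[topo$bnd$influx] +
    v[["I0_auxin"]] / (1 + xb / v[["K_X_influx"]]) / h

  gasOp <- function(sp, D, kb, cref, synCyt, d) {
    diagv <- invdt + d * cyt
    diagv[topo$bnd$gas] <- diagv[topo$bnd$gas] + kb / h
    A <- D * (topo$Lcyt + topo$Lwall + topo$Lmem) / h^2 +
      Matrix::Diagonal(np, diagv)
    b <- P[, sp] * invdt
    b[idxCyt] <- b[idxCyt] + synCyt
    b[topo$bnd$gas] <- b[topo$bnd$gas] + kb * cref / h
    list(A = A, b = b)
  }
  sC <- sl(c("auxin", "CK"))
  sE <- sl(c("auxin", "CK", "ET"))
  list(
    auxin = list(A = Aaux, b = bAux),
    ET = gasOp("ET", v[["D_ET"]], v[["k_bnd_ET"]], v[["ET_shoot"]],
               ethyleneReactionRate(sE, p) + v[["d_ET"]] * sE$ET, v[["d_ET"]]),
    CK = gasOp("CK", v[["D_CK"]], v[["k_bnd_CK"]], v[["CK_shoot"]],
               cytokininReactionRate(sC, p, topo$cellTypePt[idxCyt]) +
                 v[["d_CK"]] * sC$CK, v[["d_CK"]]))
}
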