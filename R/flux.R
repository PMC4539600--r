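# Explicit right-hand side, time integration, flux ledger and mass balance.
# The explicit RHS evaluates the same spatial discretisation as the implicit
# solver and serves as its cross-method verification oracle.

# instantaneous time derivative of the full state (uM/s per point/face)
rhsAll <- function(st, topo, p) {
  v <- p@values
  h <- topo$h
  P <- st$P; M <- st$M
  idxCyt <- topo$idxCyt
  dP <- matrix(0, topo$np, ncol(P), dimnames = dimnames(P))
  dM <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))

  # reactions (cytosol only)
  s <- lapply(colnames(P), function(cn) P[idxCyt, cn])
  names(s) <- colnames(P)
  dP[idxCyt, ] <- allReactionRates(s, p, topo$cellTypePt[idxCyt])

  # diffusion
  dP[, "auxin"] <- dP[, "auxin"] - as.numeric(
    ((v[["D_auxin"]] * topo$Lcyt + v[["D_auxin_wall"]] * topo$Lwall) %*%
       P[, "auxin"])) / h^2
  for (sp in c("ET", "CK")) {
    D <- v[[paste0("D_", sp)]]
    dP[, sp] <- dP[, sp] - D * as.numeric(topo$Lall %*% P[, sp]) / h^2
  }
  for (sp in c("PLSp", "PINp", "AUX1p")) {
    D <- v[[paste0("D_", sp)]]
    if (D > 0)
      dP[, sp] <- dP[, sp] - D * as.numeric(topo$Lcyt %*% P[, sp]) / h^2
  }

  # carrier-mediated auxin membrane crossing + boundary efflux
  cv <- carrierVelocities(M, topo, v)
  tmp <- cv$vin * P[topo$mem$wall, "auxin"] -
    cv$vout * P[topo$mem$cyt, "auxin"]          # net into cytosol, per face
  dP[, "auxin"] <- dP[, "auxin"] + as.numeric(topo$Smc %*% tmp) -
    as.numeric(topo$Smw %*% tmp)
  vb <- boundaryEffluxVelocity(M, topo, v)
  dP[topo$bnd$efflux, "auxin"] <- dP[topo$bnd$efflux, "auxin"] -
    vb * P[topo$bnd$efflux, "auxin"]

  # shoot boundary sources
  xb <- P[pmax(topo$bnd$influx - 1L, 1L), "X"]
  dP[topo$bnd$influx, "auxin"] <- dP[topo$bnd$influx, "auxin"] +
    v[["I0_auxin"]] / (1 + xb / v[["K_X_influx"]]) / h
  gp <- topo$bnd$gas
  dP[gp, "ET"] <- dP[gp, "ET"] + v[["k_bnd_ET"]] * (v[["ET_shoot"]] - P[gp, "ET"]) / h
  dP[gp, "CK"] <- dP[gp, "CK"] + v[["k_bnd_CK"]] * (v[["CK_shoot"]] - P[gp, "CK"]) / h

  # carrier recycling: uniform exocytosis to allowed faces, endocytosis
  # returned uniformly to the cell's cytosol (conservative by construction)
  recyc <- function(spCyt, spMem, agg, faceSel, kExo, kEndoFace, mPerCell) {
    fIdx <- which(faceSel)
    pc <- P[idxCyt, spCyt]
    pm <- M[fIdx, spMem]
    cellSumPc <- as.numeric(topo$AggCyt %*% pc)
    cellEndo <- as.numeric(agg %*% (kEndoFace * pm))
    dP[idxCyt, spCyt] <<- dP[idxCyt, spCyt] - kExo * pc +
      cellEndo[topo$cellOfCyt] / topo$nCytC[topo$cellOfCyt]
    fCell <- topo$mem$cell[fIdx]
    dM[fIdx, spMem] <<- dM[fIdx, spMem] - kEndoFace * pm -
      v[[if (spMem == "PINpMem") "d_PINp" else "d_AUX1p"]] * pm +
      kExo * cellSumPc[fCell] / mPerCell[fCell]
  }
  kEndoPin <- v[["k_PIN_endo"]] /
    (1 + P[topo$mem$cyt[topo$pinIdx], "auxin"] / v[["K_PIN_endo_auxin"]])
  recyc("PINp", "PINpMem", topo$AggPin, topo$mem$pin,
        v[["k_PIN_exo"]], kEndoPin, topo$nPinC)
  recyc("AUX1p", "AUX1pMem", topo$AggMem, rep(TRUE, length(topo$mem$cyt)),
        v[["k_AUX1_exo"]], rep(v[["k_AUX1_endo"]], length(topo$mem$cyt)),
        topo$nMemC)
  list(dP = dP, dM = dM)
}

#' Integrate the model in time
#'
#' Time-dependent mode, primarily used as a verification oracle for the
#' steady-state solver.  \code{method = "explicit"} is plain forward-Euler
#' time stepping of the finite-volume semi-discretisation (conditionally
#' stable: dt must resolve the fastest diffusion rate, roughly
#' \code{h^2 / (4 D_max)}); \code{method = "implicit"} takes backward-Euler
#' steps with Picard sweeps at a fixed dt.  \code{tEnd = 0} returns the
#' initial state unchanged.
#'
#' @param map a \linkS4class{RootMap}
#' @param params \linkS4class{KineticParameters}
#' @param genotype genotype or name
#' @param tEnd end time (s)
#' @param dt time step (s)
#' @param state optional initial \linkS4class{SpeciesState}
#' @param method "explicit" or "implicit"
#' @param settings \linkS4class{SolverSettings} (implicit mode)
#' @return a \linkS4class{SpeciesState} at tEnd
#' @export
integrateModel <- function(map, params = defaultParameters(),
                           genotype = "wt", tEnd, dt = 0.01, state = NULL,
                           method = c("explicit", "implicit"),
                           settings = solverSettings()) {
  method <- match.arg(method)
  if (tEnd < 0) stop("tEnd must be >= 0")
  g <- if (is.character(genotype)) genotype(genotype) else genotype
  p <- applyGenotype(params, g)
  topo <- rootTopology(map)
  st0 <- if (is.null(state)) initialState(topo, p) else state
  st <- list(P = st0@point, M = st0@mem)
  if (tEnd == 0) return(st0)
  nSteps <- ceiling(tEnd / dt - 1e-9)
  dt <- tEnd / nSteps
  if (method == "explicit") {
    for (k in seq_len(nSteps)) {
      d <- rhsAll(st, topo, p)
      st$P <- st$P + dt * d$dP
      st$M <- st$M + dt * d$dM
    }
    if (any(st$P < 0) || any(st$M < 0))
      warning("explicit integration produced negative concentrations; ",
              "reduce dt")
  } else {
    for (k in seq_len(nSteps)) {
      prev <- st
      for (sw in seq_len(settings@maxPicardIters)) {
        stOld <- st
        st <- picardSweep(st, prev, topo, p, dt, settings)
        if (relUpdate(st, stOld) < settings@nonlinearTol) break
      }
    }
  }
  new("SpeciesState", point = st$P, mem = st$M)
}

# boundary flux ledger from a (steady) internal state
fluxLedgerInternal <- function(st, topo, p) {
  v <- p@values
  h <- topo$h
  P <- st$P; M <- st$M
  rows <- list()
  infl <- topo$bnd$influx
  if (length(infl)) {
    xb <- P[pmax(infl - 1L, 1L), "X"]
    rows$influx <- data.frame(
      point = infl, species = "auxin",
      flux = v[["I0_auxin"]] / (1 + xb / v[["K_X_influx"]]) * h)
  }
  eff <- topo$bnd$efflux
  if (length(eff)) {
    vb <- boundaryEffluxVelocity(M, topo, v)
    rows$efflux <- data.frame(
      point = eff, species = "auxin",
      flux = -vb * P[eff, "auxin"] * h^2)
  }
  gp <- topo$bnd$gas
  rows$ET <- data.frame(point = gp, species = "ET",
                        flux = v[["k_bnd_ET"]] * (v[["ET_shoot"]] - P[gp, "ET"]) * h)
  rows$CK <- data.frame(point = gp, species = "CK",
                        flux = v[["k_bnd_CK"]] * (v[["CK_shoot"]] - P[gp, "CK"]) * h)
  bdf <- do.call(rbind, rows)
  rownames(bdf) <- NULL
  tot <- c(auxin_influx = sum(bdf$flux[bdf$species == "auxin" & bdf$flux > 0]),
           auxin_efflux = -sum(bdf$flux[bdf$species == "auxin" & bdf$flux < 0]),
           ET_net = sum(bdf$flux[bdf$species == "ET"]),
           CK_net = sum(bdf$flux[bdf$species == "CK"]))
  tot["auxin_net"] <- tot[["auxin_influx"]] - tot[["auxin_efflux"]]
  list(boundary = bdf, totals = tot)
}

#' Per-face and boundary flux ledger
#'
#' Recomputes the instantaneous fluxes of a result: the boundary ledger
#' (shoot-to-root auxin influx, epidermal efflux, ethylene/cytokinin
#' exchange) and, optionally, every membrane face's carrier-mediated auxin
#' flux.  Face fluxes are antisymmetric by construction (each unordered face
#' appears once, signed into the cytosol).
#'
#' @param result a \linkS4class{SteadyStateResult}
#' @param faces also return the per-membrane-face carrier fluxes
#' @return list with elements boundary (data.frame), totals (named numeric)
#'   and optionally faces (data.frame)
#' @export
fluxLedger <- function(result, faces = FALSE) {
  topo <- rootTopology(result@map)
  p <- result@params
  st <- list(P = result@state@point, M = result@state@mem)
  led <- fluxLedgerInternal(st, topo, p)
  if (faces) {
    v <- p@values
    cv <- carrierVelocities(st$M, topo, v)
    led$faces <- data.frame(
      cyt = topo$mem$cyt, wall = topo$mem$wall,
      orientation = topo$mem$orient,
      flux = (cv$vin * st$P[topo$mem$wall, "auxin"] -
              cv$vout * st$P[topo$mem$cyt, "auxin"]) * topo$h^2)
  }
  led
}

#' Global mass balance at a state
#'
#' Integrates the instantaneous rate of change of every species over the
#' whole domain (point area h^2 per grid point and membrane face).  At a
#' converged steady state, total synthesis - total decay + net boundary flux
#' is zero for every species, so the net rate relative to the species' gross
#' turnover measures how well mass balance closes.
#'
#' @param result a \linkS4class{SteadyStateResult}
#' @return data.frame: species, net production rate (uM um^2/s), gross
#'   turnover, and their ratio (relative imbalance)
#' @export
massBalance <- function(result) {
  topo <- rootTopology(result@map)
  p <- result@params
  st <- list(P = result@state@point, M = result@state@mem)
  d <- rhsAll(st, topo, p)
  h2 <- topo$h^2
  net <- colSums(d$dP) * h2
  net["PINp"] <- net[["PINp"]] + sum(d$dM[, "PINpMem"]) * h2
  net["AUX1p"] <- net[["AUX1p"]] + sum(d$dM[, "AUX1pMem"]) * h2
  v <- p@values
  decayOf <- c(auxin = "d_auxin", ET = "d_ET", CK = "d_CK", PLSm = "d_PLSm",
               PLSp = "d_PLSp", PINm = "d_PINm", PINp = "d_PINp",
               AUX1m = "d_AUX1m", AUX1p = "d_AUX1p", X = "d_X")
  gross <- vapply(colnames(st$P), function(sp) {
    base <- sum(st$P[, sp]) * h2
    dk <- if (sp %in% names(decayOf)) v[[decayOf[[sp]]]] else 1
    if (sp == "PINp") base <- base + sum(st$M[, "PINpMem"]) * h2
    if (sp == "AUX1p") base <- base + sum(st$M[, "AUX1pMem"]) * h2
    dk * base
  }, numeric(1))
  data.frame(species = colnames(st$P), net = net[colnames(st$P)],
             gross = gross,
             relative = abs(net[colnames(st$P)]) / (gross + 1e-300),
             row.names = NULL)
}
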