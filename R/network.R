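# Per-grid-point reaction kinetics of the crosstalk network.  All functions
# are vectorised over grid points: `s` is a named list (or data.frame) of
# concentration vectors in uM, and rates come back in uM/s.  Functional forms
# follow the single-cell network conventions: mass-action receptor steps,
# Michaelis-Menten activation factors and 1/(1 + c/K) repression factors.

.chk <- function(s, what) {
  for (nm in what) {
    v <- s[[nm]]
    if (is.null(v)) stop("species '", nm, "' missing from state")
    if (any(v < 0)) stop("negative concentration for species '", nm, "'")
  }
}

mm <- function(c, K) c / (K + c)          # saturating activation
rep1 <- function(c, K) 1 / (1 + c / K)    # saturating repression

#' Auxin reaction rate
#'
#' Net local auxin kinetics: synthesis (basal plus an ethylene-signalling-
#' activated term through X) modulated by cytokinin, minus first-order
#' turnover.  By default cytokinin inhibits auxin synthesis through a
#' saturating repression factor with a residual floor; the alternative
#' regulation (cytokinin activates auxin synthesis) is available through the
#' \code{ck_activates_auxin} flag.  Synthesis is strictly positive at zero
#' cytokinin, non-decreasing in X and (default) non-increasing in cytokinin.
#'
#' @param s named list of concentration vectors (needs auxin, CK, X)
#' @param p a \linkS4class{KineticParameters}
#' @param isCytosol logical; reactions run only in the cytosol, so FALSE
#'   returns zero
#' @return rate vector, uM/s
#' @export
auxinReactionRate <- function(s, p, isCytosol = TRUE) {
  .chk(s, c("auxin", "CK", "X"))
  v <- p@values
  r <- v[["r_auxin_CK"]]
  fCK <- if (paramFlag(p, "ck_activates_auxin"))
    1 + mm(s$CK, v[["K_auxin_CK"]])
  else
    r + (1 - r) * rep1(s$CK, v[["K_auxin_CK"]])
  syn <- (v[["k_auxin_basal"]] + v[["k_auxin_X"]] * mm(s$X, v[["K_auxin_X"]])) * fCK
  (syn - v[["d_auxin"]] * s$auxin) * as.numeric(isCytosol)
}

#' Cytokinin reaction rate
#'
#' Synthesis occurs only in the pericycle/border, vascular and columella cell
#' types and is inhibited by auxin (saturating); first-order turnover acts
#' everywhere in the cytosol.
#'
#' @inheritParams auxinReactionRate
#' @param cellType character vector (recycled) of cell types per point
#' @export
cytokininReactionRate <- function(s, p, cellType) {
  .chk(s, c("auxin", "CK"))
  v <- p@values
  permitted <- cellType %in% c("pericycle", "vascular", "columella")
  syn <- v[["k_CK_syn"]] * rep1(s$auxin, v[["K_CK_auxin"]]) * as.numeric(permitted)
  syn - v[["d_CK"]] * s$CK
}

#' Ethylene reaction rate
#'
#' Basal plus synergistic synthesis (increasing in both auxin and cytokinin,
#' each through a saturating factor) minus first-order turnover.  The rate is
#' independent of PLS protein, so steady-state ethylene is unchanged by loss
#' of PLS at the network level.
#'
#' @inheritParams auxinReactionRate
#' @export
ethyleneReactionRate <- function(s, p) {
  .chk(s, c("auxin", "CK", "ET"))
  v <- p@values
  syn <- v[["k_ET_basal"]] +
    v[["k_ET_syn"]] * mm(s$auxin, v[["K_ET_auxin"]]) * mm(s$CK, v[["K_ET_CK"]])
  syn - v[["d_ET"]] * s$ET
}

#' Receptor cascade rates
#'
#' Mass-action kinetics for the three receptor pairs and the downstream
#' ethylene signal X: auxin activates its receptor (Ra -> Ra*); ethylene
#' binding deactivates the ethylene receptor (Re* -> Re) while PLS protein
#' promotes the active pool; active receptor activates CTR1; X production is
#' repressed by active CTR1 and decays first order.  Each pair's rates sum to
#' zero, so the pair totals are conserved.
#'
#' @inheritParams auxinReactionRate
#' @return named list of rate vectors for Ra, Ras, Re, Res, CTR1, CTR1s, X
#' @export
receptorCascadeRates <- function(s, p) {
  .chk(s, c("auxin", "ET", "PLSp", "Ra", "Ras", "Re", "Res",
            "CTR1", "CTR1s", "X"))
  v <- p@values
  dRas <- v[["k_Ra_on"]] * s$auxin * s$Ra - v[["k_Ra_off"]] * s$Ras
  dRes <- (v[["k_Re_act"]] + v[["k_Re_PLS"]] * s$PLSp) * s$Re -
    v[["k_ET_bind"]] * s$ET * s$Res
  dCTRs <- v[["k_CTR_act"]] * s$Res * s$CTR1 - v[["k_CTR_deact"]] * s$CTR1s
  dX <- v[["k_X_syn"]] * rep1(s$CTR1s, v[["K_X_CTR"]]) - v[["d_X"]] * s$X
  list(Ra = -dRas, Ras = dRas, Re = -dRes, Res = dRes,
       CTR1 = -dCTRs, CTR1s = dCTRs, X = dX)
}

#' PLS expression rates
#'
#' PLS transcription is induced by the auxin signal (through active auxin
#' receptor Ra*) and repressed by downstream ethylene signalling X, above a
#' small basal floor; translation and first-order decay give the protein.
#' The \code{pls} genotype zeroes transcription and translation of functional
#' PLS; PLSox adds a constitutive transcription term (\code{k_PLSm_ox}); the
#' \code{pls_auxin_regulation_off} flag replaces the Ra* activation factor
#' with the fixed value \code{pls_ablation_act}, removing the auxin
#' dependence of PLS transcription.
#'
#' @inheritParams auxinReactionRate
#' @return named list with rate vectors PLSm, PLSp
#' @export
plsExpressionRates <- function(s, p) {
  .chk(s, c("Ras", "X", "PLSm", "PLSp"))
  v <- p@values
  act <- if (paramFlag(p, "pls_auxin_regulation_off"))
    v[["pls_ablation_act"]] else mm(s$Ras, v[["K_PLSm_Ra"]])
  tr <- v[["k_PLSm_basal"]] + v[["k_PLSm_ox"]] +
    v[["k_PLSm_auxin"]] * act * rep1(s$X, v[["K_PLSm_X"]])
  list(PLSm = tr - v[["d_PLSm"]] * s$PLSm,
       PLSp = v[["k_PLSp_tln"]] * s$PLSm - v[["d_PLSp"]] * s$PLSp)
}

#' PIN expression rates
#'
#' PIN transcription is the basal rate multiplied by an auxin-increasing
#' factor, an X-increasing factor and a saturating cytokinin repression
#' factor; the cytosolic protein pool gains translation and loses first-order
#' decay (membrane exchange is handled by the recycling module).
#'
#' @inheritParams auxinReactionRate
#' @return named list with rate vectors PINm, PINp (cytosolic pool, reaction
#'   part only)
#' @export
pinExpressionRates <- function(s, p) {
  .chk(s, c("auxin", "CK", "X", "PINm", "PINp"))
  v <- p@values
  tr <- v[["k_PINm_basal"]] *
    (1 + v[["a_PINm_auxin"]] * mm(s$auxin, v[["K_PINm_auxin"]])) *
    (1 + v[["a_PINm_X"]] * mm(s$X, v[["K_PINm_X"]])) *
    rep1(s$CK, v[["K_PINm_CK"]])
  list(PINm = tr - v[["d_PINm"]] * s$PINm,
       PINp = v[["k_PINp_tln"]] * s$PINm - v[["d_PINp"]] * s$PINp)
}

#' AUX1 expression rates
#'
#' AUX1 transcription increases with downstream ethylene signalling X above a
#' basal floor; translation and decay as for PIN.
#'
#' @inheritParams auxinReactionRate
#' @return named list with rate vectors AUX1m, AUX1p (cytosolic pool,
#'   reaction part only)
#' @export
aux1ExpressionRates <- function(s, p) {
  .chk(s, c("X", "AUX1m", "AUX1p"))
  v <- p@values
  tr <- v[["k_AUX1m_basal"]] + v[["k_AUX1m_X"]] * mm(s$X, v[["K_AUX1m_X"]])
  list(AUX1m = tr - v[["d_AUX1m"]] * s$AUX1m,
       AUX1p = v[["k_AUX1p_tln"]] * s$AUX1m - v[["d_AUX1p"]] * s$AUX1p)
}

#' All point-species reaction rates
#'
#' Convenience wrapper evaluating the full network at once; used by the
#' explicit time integrator and the mass-balance ledger.  Membrane-recycling
#' exchange is not included (see \code{\link{pinRecyclingRates}}).
#'
#' @inheritParams auxinReactionRate
#' @param cellType character vector of cell types per point
#' @return matrix of rates, points x species
#' @export
allReactionRates <- function(s, p, cellType) {
  n <- length(s$auxin)
  out <- matrix(0, n, length(SPECIES_POINT),
                dimnames = list(NULL, SPECIES_POINT))
  out[, "auxin"] <- auxinReactionRate(s, p)
  out[, "CK"] <- cytokininReactionRate(s, p, cellType)
  out[, "ET"] <- ethyleneReactionRate(s, p)
  rc <- receptorCascadeRates(s, p)
  for (nm in names(rc)) {
    col <- c(Ra = "Ra", Ras = "Ras", Re = "Re", Res = "Res",
             CTR1 = "CTR1", CTR1s = "CTR1s", X = "X")[[nm]]
    out[, col] <- rc[[nm]]
  }
  pls <- plsExpressionRates(s, p)
  out[, "PLSm"] <- pls$PLSm; out[, "PLSp"] <- pls$PLSp
  pin <- pinExpressionRates(s, p)
  out[, "PINm"] <- pin$PINm; out[, "PINp"] <- pin$PINp
  a1 <- aux1ExpressionRates(s, p)
  out[, "AUX1m"] <- a1$AUX1m; out[, "AUX1p"] <- a1$AUX1p
  out
}
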