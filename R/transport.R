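# Spatial flux primitives.  Flux convention: a face flux is reported in
# uM um^2/s per unit tissue depth (flux density times the face length h);
# dividing by the grid-point area h^2 gives the concentration rate it induces.

#' Diffusive face flux
#'
#' Fickian exchange between two adjacent grid points a distance
#' \code{spacing} apart: \code{D * (cA - cB) / spacing} per unit face length
#' (positive from a to b).  Species legality (hormones diffuse everywhere
#' including walls; all other species only between cytosol points of one
#' cell) is enforced by the solver's operator assembly; an illegal
#' face/species combination contributes zero flux.
#'
#' @param cA,cB concentrations (uM) at the two points
#' @param D diffusion coefficient (um^2/s), >= 0
#' @param spacing grid spacing (um)
#' @return flux per unit face length (uM um/s)
#' @export
diffusiveFlux <- function(cA, cB, D, spacing) {
  if (any(D < 0)) stop("D must be >= 0")
  D * (cA - cB) / spacing
}

# carrier-abundance scaling: linear in the membrane density below a cap,
# normalised so the reference density gives 1 (nominal permeability)
carrierScaling <- function(sigma, sigmaRef, sigmaMax) {
  pmin(sigma, sigmaMax) / sigmaRef
}

#' Carrier-mediated auxin membrane flux
#'
#' Net auxin flux into the cytosol across one membrane face:
#' influx \code{P_AUX1 * g(sigmaAUX1) * auxinWall} minus efflux
#' \code{P_PIN * h(sigmaPIN) * auxinCyt}, where g and h scale the nominal
#' permeabilities linearly with the local membrane carrier density (uM um,
#' concentration times spacing) up to a saturation cap, normalised so the
#' reference density gives the nominal permeability.  There is no passive
#' auxin crossing: with both carriers absent the flux is zero.  Efflux acts
#' only on faces carrying PIN under the cell type's polarity pattern, which
#' the solver encodes by keeping \code{sigmaPIN = 0} elsewhere.
#'
#' @param auxinCyt,auxinWall auxin (uM) on the cytosol and wall side
#' @param sigmaPIN,sigmaAUX1 membrane carrier densities (uM um)
#' @param p a \linkS4class{KineticParameters}
#' @return net flux into the cytosol per unit face length (uM um/s)
#' @export
auxinMembraneFlux <- function(auxinCyt, auxinWall, sigmaPIN, sigmaAUX1, p) {
  if (any(c(auxinCyt, auxinWall, sigmaPIN, sigmaAUX1) < 0))
    stop("negative inputs")
  v <- p@values
  influx <- v[["P_AUX1"]] *
    carrierScaling(sigmaAUX1, v[["sigma_AUX1_ref"]], v[["sigma_AUX1_max"]]) *
    auxinWall
  efflux <- v[["P_PIN"]] *
    carrierScaling(sigmaPIN, v[["sigma_PIN_ref"]], v[["sigma_PIN_max"]]) *
    auxinCyt
  influx - efflux
}

#' Passive gas-like membrane flux
#'
#' Ethylene and cytokinin diffuse freely across the plasma membrane: simple
#' diffusive exchange between the cytosol- and wall-side points of a
#' membrane face.
#'
#' @param cCyt,cWall concentrations (uM)
#' @param Dmem membrane-crossing diffusion coefficient (um^2/s)
#' @param spacing grid spacing (um)
#' @return net flux into the cytosol per unit face length (uM um/s)
#' @export
gasMembraneFlux <- function(cCyt, cWall, Dmem, spacing) {
  if (any(Dmem < 0)) stop("Dmem must be >= 0")
  Dmem * (cWall - cCyt) / spacing
}

#' Shoot-boundary fluxes
#'
#' Boundary exchange terms at the proximal edge of a converged (or current)
#' state: auxin influx on the pericycle/vascular boundary points, repressed
#' by local downstream ethylene signalling X
#' (\code{I0_auxin / (1 + X/K_X_influx)}); auxin efflux on the epidermal
#' boundary points, proportional to the local shootward membrane PIN density
#' and the local auxin; and diffusive ethylene/cytokinin exchange against the
#' fixed shoot-side reference concentrations on all boundary points.
#'
#' @param result a \linkS4class{SteadyStateResult} (or the list returned by
#'   the solver internals)
#' @return data.frame, one row per boundary point with columns col, species,
#'   flux (uM um^2/s per unit depth; positive into the root)
#' @export
shootBoundaryFluxes <- function(result) {
  led <- result@ledger
  led$boundary
}

#' Total rootward auxin flux
#'
#' Sum of the shoot-to-root auxin influx terms minus the epidermal
#' root-to-shoot efflux at the shoot boundary, from a converged state's flux
#' ledger.  Both the gross influx and the net (influx - efflux) are returned.
#'
#' @param result a \linkS4class{SteadyStateResult}
#' @return named numeric: gross, efflux, net (uM um^2/s per unit depth)
#' @export
totalRootwardFlux <- function(result) {
  b <- result@ledger$boundary
  a <- b[b$species == "auxin", ]
  gross <- sum(a$flux[a$flux > 0])
  eff <- -sum(a$flux[a$flux < 0])
  c(gross = gross, efflux = eff, net = gross - eff)
}
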