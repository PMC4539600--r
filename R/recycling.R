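# Exocytosis/endocytosis exchange of carrier protein between the cytosolic
# and membrane pools.  These are the pure per-unit kinetics; the geometric
# redistribution over a cell's membrane faces (uniform over polarity-allowed
# faces) is applied by the solver.

#' PIN recycling rates
#'
#' Exocytosis moves cytosolic PIN to the membrane at rate
#' \code{k_PIN_exo * pinCyt}; endocytosis returns membrane PIN at rate
#' \code{k_PIN_endo * pinMem / (1 + auxin/K_PIN_endo_auxin)} -- auxin
#' inhibits PIN internalisation.  The pair is conservative: the two rate
#' contributions sum to zero, so recycling alone never changes total carrier
#' protein.  At steady state \code{pinMem/pinCyt =
#' (k_exo/k_endo) * (1 + auxin/K)}.
#'
#' @param pinCyt,pinMem cytosolic and membrane PIN concentrations (uM)
#' @param auxin local auxin concentration (uM)
#' @param p a \linkS4class{KineticParameters}
#' @return list with elements \code{dCyt}, \code{dMem} (uM/s)
#' @export
pinRecyclingRates <- function(pinCyt, pinMem, auxin, p) {
  if (any(pinCyt < 0) || any(pinMem < 0) || any(auxin < 0))
    stop("negative inputs")
  v <- p@values
  exo <- v[["k_PIN_exo"]] * pinCyt
  endo <- v[["k_PIN_endo"]] * pinMem / (1 + auxin / v[["K_PIN_endo_auxin"]])
  list(dCyt = endo - exo, dMem = exo - endo)
}

#' AUX1 recycling rates
#'
#' Conservative first-order exchange between cytosolic and membrane AUX1
#' pools; unlike PIN, endocytosis is not modulated by auxin.  Steady ratio
#' \code{aux1Mem/aux1Cyt = k_exo/k_endo}.
#'
#' @param aux1Cyt,aux1Mem cytosolic and membrane AUX1 concentrations (uM)
#' @param p a \linkS4class{KineticParameters}
#' @return list with elements \code{dCyt}, \code{dMem} (uM/s)
#' @export
aux1RecyclingRates <- function(aux1Cyt, aux1Mem, p) {
  if (any(aux1Cyt < 0) || any(aux1Mem < 0)) stop("negative inputs")
  v <- p@values
  exo <- v[["k_AUX1_exo"]] * aux1Cyt
  endo <- v[["k_AUX1_endo"]] * aux1Mem
  list(dCyt = endo - exo, dMem = exo - endo)
}
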