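# Genotype registry.  The wild type has no overrides; aux1 halves the AUX1
# influx permeability (other influx carriers such as LAX remain); pls knocks
# out functional PLS production; PLSox adds a constitutive transcription
# term; etr1 reduces the ethylene-binding (receptor-deactivation) rate so the
# receptor keeps signalling -- i.e. dominant ethylene insensitivity; the
# double mutant combines pls and etr1.
GENOTYPES <- list(
  wt = list(overrides = list(), flags = c()),
  pls = list(overrides = list(
    k_PLSm_basal = list(set = 0),
    k_PLSm_auxin = list(set = 0),
    k_PLSm_ox = list(set = 0),
    k_PLSp_tln = list(set = 0)), flags = c()),
  PLSox = list(overrides = list(
    k_PLSm_ox = list(set = 2e-3)), flags = c()),
  etr1 = list(overrides = list(
    k_ET_bind = list(mul = 0.077)), flags = c()),
  `pls etr1` = list(overrides = list(
    k_PLSm_basal = list(set = 0),
    k_PLSm_auxin = list(set = 0),
    k_PLSm_ox = list(set = 0),
    k_PLSp_tln = list(set = 0),
    k_ET_bind = list(mul = 0.077)), flags = c()),
  aux1 = list(overrides = list(
    P_AUX1 = list(mul = 0.5)), flags = c())
)

#' Construct a named genotype
#'
#' Known genotypes: \code{wt}, \code{pls}, \code{etr1}, \code{pls etr1}
#' (alias \code{plsetr1}), \code{PLSox}, \code{aux1}.  Ablation flags (e.g.
#' \code{pls_auxin_regulation_off}, which removes the auxin dependence of
#' PLS transcription) can be attached to any genotype.
#'
#' @param name genotype name
#' @param flags character vector of ablation flag names to switch on
#' @return a \linkS4class{Genotype}
#' @export
#' @examples
#' genotype("pls")
#' genotype("wt", flags = "pls_auxin_regulation_off")
genotype <- function(name, flags = character()) {
  key <- if (identical(name, "plsetr1")) "pls etr1" else name
  if (!key %in% names(GENOTYPES))
    stop("unknown genotype '", name, "'; known: ",
         paste(names(GENOTYPES), collapse = ", "))
  g <- GENOTYPES[[key]]
  fl <- stats::setNames(rep(TRUE, length(flags)), flags)
  new("Genotype", name = key, overrides = g$overrides, flags = fl)
}

#' @rdname genotype
#' @export
genotypeNames <- function() names(GENOTYPES)

#' Apply a genotype to a parameter set
#'
#' Returns a modified copy of the parameters: absolute overrides are set,
#' multiplicative overrides are applied, and ablation flags are switched on.
#' The wild type returns an identical copy.  Overrides on disjoint keys
#' compose in any order, so \code{pls etr1} equals \code{etr1} applied after
#' \code{pls}.
#'
#' @param p a \linkS4class{KineticParameters}
#' @param g a \linkS4class{Genotype} (or genotype name)
#' @return a \linkS4class{KineticParameters}
#' @export
applyGenotype <- function(p, g) {
  if (is.character(g)) g <- genotype(g)
  for (nm in names(g@overrides)) {
    if (!nm %in% names(p@values))
      stop("genotype override references unknown parameter: ", nm)
    ov <- g@overrides[[nm]]
    if (!is.null(ov$set)) p@values[nm] <- ov$set
    if (!is.null(ov$mul)) p@values[nm] <- p@values[nm] * ov$mul
  }
  for (fl in names(g@flags)) {
    if (!fl %in% names(p@flags)) stop("unknown ablation flag: ", fl)
    p@flags[fl] <- g@flags[fl]
  }
  validObject(p)
  p
}
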