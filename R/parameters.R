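# Parameter registry: every rate constant of the crosstalk network, transport
# coefficient and boundary constant, with units and provenance.  Literature
# values: D_auxin = 220 um^2/s (Rutschow et al.), P_PIN in 0.5-5 um/s with
# median 2 (Kramer et al.), P_AUX1 = 1.5 +/- 0.3 um/s (Rutschow et al.).
# Constants marked "calibrated" were fitted once against the model-fitting
# criteria described in the methods vignette (wild-type auxin maximum at the
# QC, membrane-dominant carriers, cytokinin higher in the central files than
# the epidermis, and the wild-type/mutant trend suite).
PARAM_TABLE <- local({
  p <- function(value, unit, source, desc)
    list(value = value, unit = unit, source = source, desc = desc)
  list(
    # diffusion coefficients
    D_auxin       = p(220,  "um^2/s", "literature", "auxin diffusion, cytosol"),
    D_auxin_wall  = p(110,  "um^2/s", "calibrated", "auxin diffusion in the wall network"),
    D_ET          = p(600,  "um^2/s", "calibrated", "ethylene diffusion (everywhere)"),
    D_CK          = p(60,  "um^2/s", "calibrated", "cytokinin diffusion (everywhere)"),
    D_PLSp        = p(10,   "um^2/s", "calibrated", "PLS protein diffusion, cytosol"),
    D_PINp        = p(10,   "um^2/s", "calibrated", "PIN protein (cytosolic pool) diffusion"),
    D_AUX1p       = p(10,   "um^2/s", "calibrated", "AUX1 protein (cytosolic pool) diffusion"),
    # carrier permeabilities and membrane-abundance scaling
    P_PIN         = p(2.5,    "um/s",   "literature", "PIN efflux permeability at reference abundance"),
    P_AUX1        = p(1.5,  "um/s",   "literature", "AUX1 influx permeability at reference abundance"),
    sigma_PIN_ref = p(8,   "uM um",  "calibrated", "PIN membrane density giving nominal P_PIN"),
    sigma_PIN_max = p(24,  "uM um",  "calibrated", "PIN membrane density cap (saturation)"),
    sigma_AUX1_ref= p(1.2,   "uM um",  "calibrated", "AUX1 membrane density giving nominal P_AUX1"),
    sigma_AUX1_max= p(3.6,   "uM um",  "calibrated", "AUX1 membrane density cap"),
    # shoot boundary
    I0_auxin      = p(2.8,  "uM um/s","calibrated", "shoot-to-root auxin influx coefficient (pericycle+vascular)"),
    K_X_influx    = p(0.12,  "uM",     "calibrated", "X repression constant of shoot auxin influx"),
    k_bnd_ET      = p(5,    "um/s",   "calibrated", "shoot-boundary ethylene exchange velocity"),
    k_bnd_CK      = p(1,    "um/s",   "calibrated", "shoot-boundary cytokinin exchange velocity"),
    ET_shoot      = p(1.5,  "uM",     "calibrated", "shoot-side ethylene reference concentration"),
    CK_shoot      = p(0.1,  "uM",     "calibrated", "shoot-side cytokinin reference concentration"),
    # auxin kinetics
    k_auxin_basal = p(2e-5, "uM/s",   "calibrated", "basal auxin synthesis"),
    k_auxin_X     = p(2e-4,"uM/s",  "calibrated", "ethylene-signalling-activated auxin synthesis (max)"),
    K_auxin_X     = p(0.3,  "uM",     "calibrated", "half-saturation of X activation of auxin synthesis"),
    K_auxin_CK    = p(0.25,  "uM",     "calibrated", "cytokinin inhibition constant of auxin synthesis"),
    r_auxin_CK    = p(0.1,  "-",      "calibrated", "residual auxin synthesis fraction at saturating cytokinin"),
    d_auxin       = p(1e-3, "1/s",    "calibrated", "auxin turnover"),
    # cytokinin kinetics (synthesis restricted to pericycle/vascular/columella)
    k_CK_syn      = p(0.04, "uM/s",   "calibrated", "cytokinin synthesis (permitted cell types)"),
    K_CK_auxin    = p(0.03,  "uM",     "calibrated", "auxin inhibition constant of cytokinin synthesis"),
    d_CK          = p(6e-3, "1/s",    "calibrated", "cytokinin turnover"),
    # ethylene kinetics
    k_ET_basal    = p(2e-3, "uM/s",   "calibrated", "basal ethylene synthesis"),
    k_ET_syn      = p(1e-2, "uM/s",   "calibrated", "auxin+cytokinin synergistic ethylene synthesis (max)"),
    K_ET_auxin    = p(5e-3, "uM",     "calibrated", "auxin half-saturation of ethylene synthesis"),
    K_ET_CK       = p(5e-3, "uM",     "calibrated", "cytokinin half-saturation of ethylene synthesis"),
    d_ET          = p(1e-2, "1/s",    "calibrated", "ethylene turnover"),
    # auxin receptor
    Ra_total      = p(1,    "uM",     "calibrated", "total auxin receptor pool"),
    k_Ra_on       = p(1,    "1/(uM s)","calibrated","auxin receptor activation by auxin"),
    k_Ra_off      = p(6,    "1/s",    "calibrated", "auxin receptor deactivation"),
    # ethylene receptor (ETR1) and CTR1 (rates after Diaz & Alvarez-Buylla)
    Re_total      = p(1,    "uM",     "literature", "total ethylene receptor pool"),
    k_Re_act      = p(0.02, "1/s",    "calibrated", "basal receptor reactivation Re -> Re*"),
    k_Re_PLS      = p(0.6,    "1/(uM s)","calibrated","PLS promotion of the active receptor pool"),
    k_ET_bind     = p(1,    "1/(uM s)","literature","ethylene binding (deactivates receptor, Re* -> Re)"),
    CTR_total     = p(1,    "uM",     "literature", "total CTR1 pool"),
    k_CTR_act     = p(0.3,  "1/(uM s)","calibrated","CTR1 activation by active receptor"),
    k_CTR_deact   = p(0.3,  "1/s",    "calibrated", "CTR1 deactivation"),
    k_X_syn       = p(0.09, "uM/s",   "calibrated", "downstream ethylene signalling production (max)"),
    K_X_CTR       = p(0.05, "uM",     "calibrated", "CTR1* repression constant of X production"),
    d_X           = p(0.06, "1/s",    "calibrated", "X turnover"),
    # PLS expression
    k_PLSm_basal  = p(2e-5, "uM/s",   "calibrated", "basal PLS transcription floor"),
    k_PLSm_auxin  = p(4e-3, "uM/s",   "calibrated", "auxin-induced PLS transcription (max, via Ra*)"),
    K_PLSm_Ra     = p(0.15,  "uM",     "calibrated", "Ra* half-saturation of PLS transcription"),
    K_PLSm_X      = p(0.3,  "uM",     "calibrated", "X repression constant of PLS transcription"),
    d_PLSm        = p(1e-2, "1/s",    "calibrated", "PLS mRNA decay"),
    k_PLSp_tln    = p(0.1,  "1/s",    "calibrated", "PLS translation"),
    d_PLSp        = p(1e-2, "1/s",    "calibrated", "PLS protein decay"),
    k_PLSm_ox     = p(0,    "uM/s",   "calibrated", "constitutive PLS transcription (PLSox only)"),
    pls_ablation_act = p(0.5, "-",    "calibrated", "fixed activation replacing the Ra* factor when auxin regulation of PLS is ablated"),
    # PIN expression
    k_PINm_basal  = p(1.4e-3, "uM/s",   "calibrated", "basal PIN transcription"),
    a_PINm_auxin  = p(0.8,  "-",      "calibrated", "auxin activation amplitude of PIN transcription"),
    K_PINm_auxin  = p(0.3,  "uM",     "calibrated", "auxin half-saturation of PIN transcription"),
    a_PINm_X      = p(12,   "-",      "calibrated", "ethylene-signalling activation amplitude of PIN transcription"),
    K_PINm_X      = p(1.0, "uM",     "calibrated", "X half-saturation of PIN transcription"),
    K_PINm_CK     = p(3.0,  "uM",     "calibrated", "cytokinin repression constant of PIN transcription"),
    d_PINm        = p(1e-2, "1/s",    "calibrated", "PIN mRNA decay"),
    k_PINp_tln    = p(0.05, "1/s",    "calibrated", "PIN translation"),
    d_PINp        = p(6e-3, "1/s",    "calibrated", "PIN protein decay (both pools)"),
    k_PIN_exo     = p(0.2,  "1/s",    "calibrated", "PIN exocytosis (cytosol -> membrane)"),
    k_PIN_endo    = p(0.06, "1/s",    "calibrated", "PIN endocytosis at zero auxin"),
    K_PIN_endo_auxin = p(0.5, "uM",   "calibrated", "auxin inhibition constant of PIN endocytosis"),
    # AUX1 expression
    k_AUX1m_basal = p(2e-4, "uM/s",   "calibrated", "basal AUX1 transcription floor"),
    k_AUX1m_X     = p(2e-3, "uM/s",   "calibrated", "ethylene-signalling-activated AUX1 transcription (max)"),
    K_AUX1m_X     = p(0.2,  "uM",     "calibrated", "X half-saturation of AUX1 transcription"),
    d_AUX1m       = p(1e-2, "1/s",    "calibrated", "AUX1 mRNA decay"),
    k_AUX1p_tln   = p(0.05, "1/s",    "calibrated", "AUX1 translation"),
    d_AUX1p       = p(6e-3, "1/s",    "calibrated", "AUX1 protein decay (both pools)"),
    k_AUX1_exo    = p(0.2,  "1/s",    "calibrated", "AUX1 exocytosis"),
    k_AUX1_endo   = p(0.06, "1/s",    "calibrated", "AUX1 endocytosis (unregulated)"),
    # misc
    init_conc     = p(0.1,  "uM",     "calibrated", "uniform initial concentration for all species")
  )
})

#' Default kinetic and transport parameters
#'
#' Returns the shipped parameter set: literature values where available
#' (auxin diffusion 220 um^2/s; PIN efflux permeability 2 um/s within the
#' 0.5--5 range; AUX1 influx permeability 1.5 um/s) and constants calibrated
#' once against the model-fitting criteria described in the methods vignette.
#' Units: concentrations uM, lengths um, time s.
#'
#' @return a \linkS4class{KineticParameters}
#' @export
#' @examples
#' p <- defaultParameters()
#' param(p, "D_auxin")
defaultParameters <- function() {
  new("KineticParameters",
      values = vapply(PARAM_TABLE, function(x) x$value, numeric(1)),
      flags = c(ck_activates_auxin = FALSE,
                pls_auxin_regulation_off = FALSE,
                strict_flux = FALSE))
}

#' Parameter access and modification
#'
#' \code{param} reads one or more named constants; \code{setParam} returns a
#' modified copy; \code{paramFlag} reads a model switch.
#'
#' @param p a \linkS4class{KineticParameters}
#' @param name parameter name(s)
#' @export
param <- function(p, name) {
  miss <- setdiff(name, names(p@values))
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  p@values[name]
}

#' @rdname param
#' @param value replacement value(s)
#' @export
setParam <- function(p, name, value) {
  miss <- setdiff(name, names(p@values))
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  p@values[name] <- value
  validObject(p)
  p
}

#' @rdname param
#' @param flag flag name
#' @export
paramFlag <- function(p, flag) {
  if (!flag %in% names(p@flags)) stop("unknown flag: ", flag)
  unname(p@flags[flag])
}

#' @rdname param
#' @export
setParamFlag <- function(p, flag, value) {
  if (!flag %in% names(p@flags)) stop("unknown flag: ", flag)
  p@flags[flag] <- as.logical(value)
  p
}

#' Read and write parameter files
#'
#' Parameters are stored as a YAML mapping from constant name to value; the
#' shipped annotated default is at
#' \code{system.file("extdata", "parameters.yaml", package = "RootCrosstalk")}.
#' Unknown keys are rejected; missing keys fall back to the defaults.
#'
#' @param path YAML file path
#' @return \code{readParameters}: a \linkS4class{KineticParameters}
#' @export
readParameters <- function(path) {
  y <- yaml::read_yaml(path)
  p <- defaultParameters()
  vals <- y[["values"]]
  if (is.null(vals)) vals <- y
  flags <- y[["flags"]]
  known <- names(p@values)
  unknown <- setdiff(names(vals), c(known, "values", "flags"))
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  for (nm in intersect(names(vals), known))
    p@values[nm] <- as.numeric(vals[[nm]])
  if (!is.null(flags))
    for (nm in intersect(names(flags), names(p@flags)))
      p@flags[nm] <- as.logical(flags[[nm]])
  validObject(p)
  p
}

#' @rdname readParameters
#' @param p a \linkS4class{KineticParameters}
#' @export
writeParameters <- function(p, path) {
  yaml::write_yaml(list(values = as.list(p@values),
                        flags = as.list(p@flags)), path)
  invisible(path)
}

#' Parameter provenance table
#'
#' Name, default value, unit, provenance ("literature" or "calibrated") and a
#' one-line description for every constant.
#'
#' @return data.frame
#' @export
parameterTable <- function() {
  data.frame(name = names(PARAM_TABLE),
             value = vapply(PARAM_TABLE, function(x) x$value, numeric(1)),
             unit = vapply(PARAM_TABLE, function(x) x$unit, character(1)),
             source = vapply(PARAM_TABLE, function(x) x$source, character(1)),
             description = vapply(PARAM_TABLE, function(x) x$desc, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
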