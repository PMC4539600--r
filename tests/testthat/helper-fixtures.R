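# Shared fixtures: built in code, cached for the session.

.fix <- new.env(parent = emptyenv())

miniMap <- function(spacing = 4, nMZ = 4, nEZ = 1) {
  key <- sprintf("map_%g_%d_%d", spacing, nMZ, nEZ)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- buildRootMap(miniGridSpec(spacing, nMZ, nEZ))
  .fix[[key]]
}

# slow-diffusion parameter variant: same network, diffusion and turnover
# scaled so explicit Euler oracles are affordable on tiny fixtures
slowParams <- function() {
  p <- defaultParameters()
  p <- setParam(p, c("D_auxin", "D_auxin_wall", "D_ET", "D_CK",
                     "D_PLSp", "D_PINp", "D_AUX1p"),
                c(40, 20, 60, 40, 5, 5, 5))
  setParam(p, "d_auxin", 0.01)
}

# parameters with every source, sink and carrier off: pure diffusion
closedParams <- function() {
  p <- slowParams()
  zero <- c("P_PIN", "P_AUX1", "I0_auxin", "k_bnd_ET", "k_bnd_CK",
            "k_auxin_basal", "k_auxin_X", "k_CK_syn", "k_ET_basal",
            "k_ET_syn", "d_auxin", "d_CK", "d_ET")
  setParam(p, zero, rep(0, length(zero)))
}

# random species state on a map's support, reproducible
randomState <- function(map, p = defaultParameters(), seed = 42) {
  set.seed(seed)
  st <- initialState(map, p)
  P <- st@point
  pos <- P > 0
  P[pos] <- P[pos] * stats::runif(sum(pos), 0.2, 3)
  M <- st@mem
  pos <- M > 0
  M[pos] <- M[pos] * stats::runif(sum(pos), 0.2, 3)
  new("SpeciesState", point = P, mem = M)
}

# wrap a state into a result object for postprocessing tests
asResult <- function(map, state, p = defaultParameters(), genotype = "wt") {
  new("SteadyStateResult", map = map, state = state, genotype = genotype,
      converged = TRUE, iterations = 0L, picardUpdate = c(all = 0),
      rate = c(all = 0), time = 0, ledger = list(), params = p,
      settings = solverSettings())
}

# named list of species vectors at given values (for rate-function tests)
speciesList <- function(n = 1, ...) {
  base <- stats::setNames(rep(list(rep(0, n)), length(RootCrosstalk:::SPECIES_POINT)),
                          RootCrosstalk:::SPECIES_POINT)
  ov <- list(...)
  for (nm in names(ov)) base[[nm]] <- rep(ov[[nm]], length.out = n)
  base
}
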