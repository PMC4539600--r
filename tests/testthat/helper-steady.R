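# Memoised steady-state solves shared across test files.  The genotype batch
# runs on the full root layout at 4-um spacing (half the reference
# resolution); fixture solves use the miniature map.

steadyCache <- function(key, fun) {
  if (is.null(.fix[[key]])) .fix[[key]] <- fun()
  .fix[[key]]
}

miniSteady <- function(genotype = "wt", params = defaultParameters(),
                       spacing = 4, label = "") {
  key <- sprintf("mini_%s_%g_%s", genotype, spacing, label)
  steadyCache(key, function()
    picardSteadyState(miniMap(spacing = spacing), params, genotype,
                      settings = solverSettings()))
}

fullSteady <- function(genotype = "wt", flags = character()) {
  key <- paste0("full_", genotype, "_", paste(flags, collapse = "+"))
  steadyCache(key, function() {
    map <- steadyCache("fullmap", function()
      buildRootMap(defaultGridSpec(spacing = 4)))
    g <- genotype(genotype, flags = flags)
    picardSteadyState(map, defaultParameters(), g,
                      settings = solverSettings())
  })
}
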