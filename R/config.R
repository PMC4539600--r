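# Structured-text (YAML) configuration: geometry, parameter file, genotypes,
# solver controls and outputs.  This is the surface the command-line script
# (inst/scripts/rootsim.R) drives.

#' Read a simulation configuration
#'
#' YAML keys (all optional; defaults in parentheses): \code{geometry} --
#' mapping with \code{spacing_um} (2), \code{root_length_um},
#' \code{root_half_width_um}, \code{mz_length_um}, \code{mz_cell_length_um},
#' \code{ez_cell_lengths_um}, \code{file_widths_um} (mapping
#' epidermis/outer/pericycle/vascular), \code{columella_lengths_um},
#' \code{qc_length_um}; \code{parameters} -- path to a parameter YAML;
#' \code{genotypes} -- list of genotype names ("wt"); \code{solver} --
#' mapping of \code{\link{solverSettings}} arguments (camelCase);
#' \code{outputs} -- list of species to export ("auxin").
#'
#' @param path YAML file path
#' @return list with elements spec (\linkS4class{GridSpec}), params,
#'   genotypes, settings, outputs
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$geometry
  spec0 <- defaultGridSpec()
  pick <- function(key, default) if (!is.null(g[[key]])) g[[key]] else default
  spec <- new("GridSpec",
    spacing = pick("spacing_um", spec0@spacing),
    rootLength = pick("root_length_um", spec0@rootLength),
    rootHalfWidth = pick("root_half_width_um", spec0@rootHalfWidth),
    colLengths = as.numeric(pick("columella_lengths_um", spec0@colLengths)),
    qcLength = pick("qc_length_um", spec0@qcLength),
    mzLength = pick("mz_length_um", spec0@mzLength),
    mzCellLength = pick("mz_cell_length_um", spec0@mzCellLength),
    ezCellLengths = as.numeric(pick("ez_cell_lengths_um",
                                    spec0@ezCellLengths)),
    fileWidths = {
      fw <- pick("file_widths_um", as.list(spec0@fileWidths))
      unlist(fw)[c("epidermis", "outer", "pericycle", "vascular")]
    },
    wallThickness = 1L)
  params <- if (!is.null(y$parameters)) readParameters(y$parameters)
            else defaultParameters()
  settings <- do.call(solverSettings, if (is.null(y$solver)) list()
                      else y$solver)
  list(spec = spec,
       params = params,
       genotypes = if (is.null(y$genotypes)) "wt" else unlist(y$genotypes),
       settings = settings,
       outputs = if (is.null(y$outputs)) "auxin" else unlist(y$outputs))
}

#' Run a configured simulation batch
#'
#' Builds the root map, solves the steady state for each requested genotype
#' and writes, per genotype, the exported species fields (CSV), colour maps
#' (PNG), row profiles (CSV), the boundary flux ledger (CSV) and a run
#' metadata YAML into \code{outDir}.
#'
#' @param config a config list from \code{\link{readConfig}} (or a path)
#' @param outDir output directory (created if needed)
#' @param verbose print solver progress
#' @return named list of \linkS4class{SteadyStateResult}s, invisibly
#' @export
runSimulation <- function(config, outDir, verbose = FALSE) {
  if (is.character(config)) config <- readConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  map <- buildRootMap(config$spec)
  results <- list()
  for (gt in config$genotypes) {
    res <- picardSteadyState(map, config$params, gt,
                             settings = config$settings, verbose = verbose)
    tag <- gsub("[^A-Za-z0-9]+", "_", gt)
    for (sp in config$outputs) {
      exportCSV(res, file.path(outDir, paste0(tag, "_", sp, ".csv")),
                species = sp)
      exportColormap(res, sp, file.path(outDir,
                                        paste0(tag, "_", sp, ".png")))
      exportCSV(longitudinalProfile(res, sp, "row"),
                file.path(outDir, paste0(tag, "_", sp, "_profile.csv")))
    }
    utils::write.csv(res@ledger$boundary,
                     file.path(outDir, paste0(tag, "_boundary_flux.csv")),
                     row.names = FALSE)
    yaml::write_yaml(list(genotype = gt, converged = res@converged,
                          iterations = res@iterations,
                          pseudoTime_s = res@time,
                          maxRelRate = max(res@rate),
                          totals = as.list(res@ledger$totals)),
                     file.path(outDir, paste0(tag, "_run.yaml")))
    results[[gt]] <- res
  }
  invisible(results)
}
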