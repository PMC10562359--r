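# Run configuration: defaults, YAML loading, strict validation.

#' Default pipeline configuration
#'
#' The full configuration tree for [runPipeline()], with defaults sized for
#' a demonstration run. Override any subset via \code{...} (named top-level
#' entries; nested lists are merged key-wise). Unknown keys are a hard
#' error, never silently ignored.
#'
#' @param ... named overrides.
#' @return named list ("runConfig").
#' @export
#' @examples
#' cfg <- runConfig(seed = 7, harvestScenarios = c("BaseHarv", "NoHarv"))
runConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    outputDir = file.path(tempdir(), "carbonscape-run"),
    yearStart = 2015L, yearEnd = 2050L,
    climates = c("current", "warming"),
    harvestScenarios = c("BaseHarv", "LowHarv", "MaxHarv", "NoHarv"),
    # BaseHarv yearly removal target as a fraction of initial standing stock
    harvestTargetFraction = 0.03,
    landscape = list(),      # overrides for landscapeConfig()
    forest = list(),         # overrides for forestParams()
    emissions = list(),      # overrides for emissionConfig()
    scenarioYears = c(2030L, 2050L),
    prioritization = list(nFeatures = 6L, autocorrRange = 4, rule = "ABF",
                          warp = 8L, targetFraction = 0.10),
    accounting = list(price = 70, ensembleN = 20,
                      periods = list(c(2017, 2025), c(2026, 2033),
                                     c(2034, 2050)),
                      epsRelSd = 0.05, soilKRelSd = 0.10,
                      anthroIntervalRel = c(lower = 0.889, upper = 1.098)))
  cfg <- .mergeConfig(cfg, list(...), "config")
  # validate nested stage configs eagerly so bad keys fail at load time
  do.call(landscapeConfig, cfg$landscape)
  do.call(forestParams, cfg$forest)
  do.call(emissionConfig, cfg$emissions)
  cfg
}

.mergeConfig <- function(base, overrides, where) {
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(base[[nm]])) && length(base[[nm]])) {
      base[[nm]] <- .mergeConfig(base[[nm]], overrides[[nm]],
                                 paste0(where, "$", nm))
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file and merges it over the defaults of [runConfig()];
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @return named configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  do.call(runConfig, y)
}

#' Write a configuration to YAML
#' @param config configuration list.
#' @param path output path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
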