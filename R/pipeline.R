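# End-to-end pipeline: generation -> simulation -> emissions ->
# prioritization -> accounting, with provenance metadata and a run log.

.logLine <- function(logPath, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...))
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = logPath, append = TRUE)
}

.runStage <- function(name, logPath, outDir, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               file.path(outDir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  .logLine(logPath, "stage %-14s done in %.1f s", name,
           proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full assessment pipeline
#'
#' Executes every stage in dependency order: synthetic landscape and climate
#' generation, forest carbon simulation for the configured harvest x climate
#' scenarios, the anthropogenic inventory with scenario scaling,
#' biodiversity prioritization and regional protection-area selection, and
#' the integrated GHG accounting (budget table, regional nets, uncertainty
#' ensembles, neutrality probabilities, service accounts). Writes tables as
#' CSV, rasters as ASCII grids, provenance metadata as JSON and a run log
#' into \code{config$outputDir}. A failing stage leaves earlier outputs in
#' place together with a \code{FAILED} marker file.
#'
#' @param config list from [runConfig()] or [readRunConfig()].
#' @return (invisibly) a list with all stage results.
#' @export
runPipeline <- function(config = runConfig()) {
  outDir <- config$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run.log")
  if (file.exists(file.path(outDir, "FAILED")))
    unlink(file.path(outDir, "FAILED"))
  seed <- as.integer(config$seed)
  years <- config$yearStart:config$yearEnd
  .logLine(logPath, "carbonscape pipeline, seed %d, years %d-%d", seed,
           config$yearStart, config$yearEnd)

  ## landscape + climate ----------------------------------------------------
  landscape <- .runStage("landscape", logPath, outDir, {
    ls <- generateLandscape(do.call(landscapeConfig, config$landscape), seed)
    writeTableCsv(segmentTable(ls), file.path(outDir, "segments.csv"))
    writeTableCsv(regionTable(ls), file.path(outDir, "regions.csv"))
    writeAsciiGrid(regionMap(ls) + 0, file.path(outDir, "regions.asc"),
                   gridGeometry(ls))
    writeAsciiGrid(protectedMask(ls) + 0,
                   file.path(outDir, "protected_mask.asc"), gridGeometry(ls))
    ls
  })
  climates <- .runStage("climate", logPath, outDir, {
    cl <- lapply(config$climates, function(sc)
      generateClimate(sc, years, seed))
    names(cl) <- config$climates
    for (sc in names(cl))
      writeTableCsv(climateData(cl[[sc]]),
                    file.path(outDir, sprintf("climate_%s.csv", sc)))
    cl
  })

  ## forest simulation ------------------------------------------------------
  params <- do.call(forestParams, config$forest)
  seg <- segmentTable(landscape)
  initialStockM3 <- sum(seg$stem_volume * seg$area_m2 / 1e4)
  baseTarget <- config$harvestTargetFraction * initialStockM3
  runs <- .runStage("forest", logPath, outDir, {
    out <- list()
    for (hs in config$harvestScenarios) {
      sc <- harvestScenario(hs, years, baseTarget)
      for (cc in names(climates)) {
        run <- runScenario(landscape, sc, climates[[cc]], years,
                           params = params)
        out[[paste(hs, cc, sep = "_")]] <- run
        writeTableCsv(run$fluxes,
                      file.path(outDir,
                                sprintf("forest_fluxes_%s_%s.csv", hs, cc)))
      }
    }
    out
  })

  ## anthropogenic emissions ------------------------------------------------
  emissions <- .runStage("emissions", logPath, outDir, {
    emCfg <- config$emissions
    if (is.null(emCfg$scalePerArea)) emCfg$scalePerArea <- TRUE
    inv <- generateEmissionInventory(
      landscape, do.call(emissionConfig, emCfg), seed)
    writeTableCsv(pointSources(inv), file.path(outDir, "point_sources.csv"))
    trajectories <- list(WEM = scenarioTrajectory("WEM"),
                         WAM = scenarioTrajectory("WAM"))
    scaled <- list()
    regional <- list()
    for (tn in names(trajectories)) {
      for (yr in config$scenarioYears) {
        si <- scaleToScenario(inv, trajectories[[tn]], yr)
        key <- sprintf("%s_%d", tn, yr)
        scaled[[key]] <- si
        if (si@spatialValid) {
          rt <- regionalInventoryTotals(si)
          regional[[key]] <- rt
          writeTableCsv(rt,
                        file.path(outDir,
                                  sprintf("anthro_regional_%s.csv", key)))
        }
      }
    }
    list(base = inv, trajectories = trajectories, scaled = scaled,
         regional = regional)
  })

  ## biodiversity prioritization -------------------------------------------
  prior <- .runStage("prioritization", logPath, outDir, {
    pz <- config$prioritization
    feats <- generateBdFeatures(landscape, pz$nFeatures, pz$autocorrRange,
                                seed)
    pen <- landscapePenalties(landscape)
    featsPen <- applyConditionPenalty(feats, pen)
    ranking <- rankCells(featsPen, rule = pz$rule,
                         protectedMask = protectedMask(landscape),
                         warp = pz$warp)
    sel <- selectProtectionAreas(ranking, landscape,
                                 targetFraction = pz$targetFraction)
    writeAsciiGrid(rankSurface(ranking), file.path(outDir, "rank.asc"),
                   gridGeometry(landscape))
    writeAsciiGrid(sel$mask + 0, file.path(outDir, "new_protection.asc"),
                   gridGeometry(landscape))
    writeTableCsv(sel$summary, file.path(outDir, "protection_summary.csv"))
    writeTableCsv(representationCurves(ranking),
                  file.path(outDir, "representation_curves.csv"))
    list(features = feats, penalties = pen, ranking = ranking,
         selection = sel)
  })

  ## integrated accounting --------------------------------------------------
  accounting <- .runStage("accounting", logPath, outDir, {
    ac <- config$accounting
    budget <- buildBudgetTable(landUseReference())
    writeTableCsv(budgetData(budget), file.path(outDir, "budget_table.csv"))

    periods <- ac$periods
    periodTables <- lapply(runs, function(r) periodAverages(r$fluxes,
                                                            periods))
    for (nm in names(periodTables))
      writeTableCsv(periodTables[[nm]],
                    file.path(outDir, sprintf("forest_periods_%s.csv", nm)))

    # regional nets for each forest scenario x anthropogenic scenario year
    regionalNets <- list()
    for (key in names(emissions$regional)) {
      yr <- as.integer(sub("^.*_", "", key))
      for (rn in names(runs)) {
        r <- runs[[rn]]
        period <- c(max(yr - 2, min(r$years)), min(yr + 2, max(r$years)))
        rf <- r$regionFluxes
        rf <- rf[rf$year >= period[1] & rf$year <= period[2], ]
        if (!nrow(rf)) next
        fn <- stats::aggregate(nbe ~ region_id, rf, mean)
        net <- regionalNetEmissions(fn, emissions$regional[[key]])
        regionalNets[[paste(rn, key, sep = "_x_")]] <- net
      }
    }
    if (length(regionalNets)) {
      all <- do.call(rbind, Map(function(d, nm)
        cbind(combination = nm, d), regionalNets, names(regionalNets)))
      writeTableCsv(all, file.path(outDir, "regional_net_emissions.csv"))
    }

    # Monte-Carlo ensembles: forest NBE (parameter uncertainty) and the
    # anthropogenic national total (inventory interval), per scenario year
    baseRun <- runs[[1]]
    simulator <- function(p, subSeed) {
      pp <- params
      pp$eps <- p$eps
      pp$soilK <- params$soilK * p$soilKMult
      sc <- harvestScenario(baseRun$scenario, years, baseTarget)
      r <- runScenario(landscape, sc, climates[[baseRun$climateScenario]],
                       years, params = pp)
      mean(r$fluxes$nbe[r$fluxes$year >= ac$periods[[2]][1] &
                          r$fluxes$year <= ac$periods[[2]][2]])
    }
    forestEns <- runEnsemble(
      simulator,
      list(eps = list(dist = "normal", mean = params$eps,
                      sd = ac$epsRelSd * params$eps),
           soilKMult = list(dist = "lognormal", meanlog = 0,
                            sdlog = ac$soilKRelSd)),
      n = ac$ensembleN, seed = seed,
      label = sprintf("%s_%s_nbe", baseRun$scenario,
                      baseRun$climateScenario))

    # neutrality per forest scenario: the parameter-uncertainty spread from
    # the base ensemble, recentred on each scenario's own period mean
    baseMean <- mean(ensembleSamples(forestEns))
    scenarioMeans <- vapply(runs, function(r) {
      f <- r$fluxes
      mean(f$nbe[f$year >= ac$periods[[2]][1] &
                   f$year <= ac$periods[[2]][2]])
    }, numeric(1))
    anthroSamples <- list()
    neutrality <- list()
    for (key in names(emissions$scaled)) {
      tot <- nationalTotal(emissions$scaled[[key]])
      iv <- data.frame(sector = "all", mean = tot,
                       lower = tot * ac$anthroIntervalRel[["lower"]],
                       upper = tot * ac$anthroIntervalRel[["upper"]])
      anthroSamples[[key]] <- sampleInventoryUncertainty(iv, 5000, seed)
      for (rn in names(runs)) {
        fs <- ensembleSamples(forestEns) - baseMean + scenarioMeans[[rn]]
        neutrality[[paste(rn, key, sep = "_x_")]] <-
          neutralityProbability(fs, anthroSamples[[key]])
      }
    }
    writeTableCsv(
      data.frame(combination = names(neutrality),
                 probability = unlist(neutrality)),
      file.path(outDir, "neutrality_probability.csv"))

    # climate-regulation service accounts (no-harvest run for protected
    # scopes, per standard practice)
    services <- NULL
    noharvName <- grep("^NoHarv_current$", names(runs), value = TRUE)
    if (length(noharvName)) {
      nh <- runs[[noharvName]]
      lastPeriod <- periods[[length(periods)]]
      curMask <- protectedMask(landscape)
      tgtMask <- curMask | prior$selection$mask
      services <- list(
        currently_protected = climateServices(nh, landscape, curMask,
                                              lastPeriod,
                                              "currently_protected",
                                              price = ac$price),
        target_10pct = climateServices(nh, landscape, tgtMask, lastPeriod,
                                       "target_10pct", price = ac$price),
        whole_region = climateServices(nh, landscape, NULL, lastPeriod,
                                       "whole_region", price = ac$price))
      srv <- do.call(rbind, lapply(services, function(s)
        data.frame(scope = s@scope, net_sequestration = s@netSequestration,
                   c_storage_tgc = s@cStorage,
                   economic_value_meur = s@economicValue)))
      writeTableCsv(srv, file.path(outDir, "service_accounts.csv"))
    }

    list(budget = budget, periodTables = periodTables,
         regionalNets = regionalNets, forestEnsemble = forestEns,
         anthroSamples = anthroSamples, neutrality = neutrality,
         services = services)
  })

  meta <- list(package = "carbonscape",
               version = as.character(utils::packageVersion("carbonscape")),
               # hash over the scientific configuration; output paths excluded
               seed = seed,
               config_hash = .configHash(config[setdiff(names(config),
                                                        "outputDir")]),
               r_version = R.version.string,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               gwp = as.list(params$gwp))
  writeMetadataJson(meta, file.path(outDir, "metadata.json"))
  .logLine(logPath, "pipeline complete; outputs in %s", outDir)

  invisible(list(config = config, landscape = landscape,
                 climates = climates, runs = runs, emissions = emissions,
                 prioritization = prior, accounting = accounting,
                 metadata = meta))
}
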