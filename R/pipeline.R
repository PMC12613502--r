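# End-to-end orchestration: preprocess -> fit -> draw -> adjust -> rake ->
# summarize, with a run manifest for byte-level reproduction.

#' Configure a pipeline run
#'
#' @param simConfig a [SimConfig-class] to generate synthetic inputs, or
#'   `NULL` to read observed tables from `paths`.
#' @param paths named list of input paths (`counts`, `adjacency`,
#'   `ratios`, optionally `mapping`, `covariates` as an RDS-free CSV pair
#'   `covariatesUnit`/`covariatesUnitRace`) used when `simConfig` is
#'   `NULL`.
#' @param nDraws posterior draws (default 1000).
#' @param seed master seed for the whole run.
#' @param standardWeights a [StandardPopulation-class].
#' @param maskThreshold display-masking threshold on mean annual
#'   population (default 1000).
#' @param allSexFactor multiplier converting the modeled (female)
#'   person-years to the all-sex population the masking rule refers to.
#' @param compareYears the two years compared for percent change.
#' @param topK ranking depth.
#' @param benchmarkLevel stage-B raking margin label.
#' @param rakingTolerance,rakingMaxIterations stage-3 controls.
#' @param outDir output directory (created if needed).
#' @param writeDraws also write the full raked draw matrix (large).
#' @param useYearRW add the optional random-walk year effect to the model.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(simConfig = NULL, paths = list(),
                           nDraws = 1000L, seed = 1L,
                           standardWeights = standardPopulation(),
                           maskThreshold = 1000, allSexFactor = 2,
                           compareYears = c(2000L, 2019L), topK = 10L,
                           benchmarkLevel = "national",
                           rakingTolerance = 1e-8,
                           rakingMaxIterations = 1000L,
                           outDir = tempfile("pregsae_run_"),
                           writeDraws = FALSE, useYearRW = FALSE) {
  stopifnot(maskThreshold > 0, length(compareYears) == 2L)
  structure(list(simConfig = simConfig, paths = paths,
                 nDraws = as.integer(nDraws), seed = as.integer(seed),
                 standardWeights = standardWeights,
                 maskThreshold = maskThreshold,
                 allSexFactor = allSexFactor,
                 compareYears = as.integer(compareYears),
                 topK = as.integer(topK),
                 benchmarkLevel = benchmarkLevel,
                 rakingTolerance = rakingTolerance,
                 rakingMaxIterations = as.integer(rakingMaxIterations),
                 outDir = outDir, writeDraws = isTRUE(writeDraws),
                 useYearRW = isTRUE(useYearRW)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipelineConfig()] plus an optional `simConfig` block
#' whose entries are passed to [simConfig()].
#'
#' @param path YAML file.
#' @return A `"PipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simConfig)) y$simConfig <- do.call(simConfig, y$simConfig)
  if (!is.null(y$compareYears)) y$compareYears <- as.integer(y$compareYears)
  do.call(pipelineConfig, y)
}

.stageLog <- function(stage, t0) {
  message(sprintf("[pregsae] %-12s %6.1fs", stage,
                  as.numeric(proc.time()[3L]) - t0))
}

#' Run the full three-stage pipeline
#'
#' Executes preprocess, stage-1 model fit and posterior draws, stage-2
#' misclassification adjustment, stage-3 two-stage raking, and
#' summarization; writes every intermediate table, a raking report, and a
#' run manifest (config echo, seed, file checksums) to the output
#' directory. Any stage failure halts with the stage name; outputs written
#' so far are retained.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with the key artifacts (`summaryCounty`,
#'   `summaryNational`, `changes`, `changeSummaries`, `rankings`,
#'   `ratios`, `fit`, `rakedDraws`, `outDir`, ...).
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(simConfig = simConfig(nUnits = 12, seed = 5),
#'                       nDraws = 100)
#' res <- runPipeline(cfg)
#' head(as.data.frame(res$summaryNational))
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(proc.time()[3L])
  outputs <- character(0)
  put <- function(obj, name, writer = fwrite) {
    p <- file.path(config$outDir, name)
    if (is.data.frame(obj) || is(obj, "DFrame")) fwrite(as.data.frame(obj), p)
    else writer(obj, p)
    outputs <<- c(outputs, p)
    p
  }
  stage <- "inputs"
  res <- tryCatch({
    # ---- inputs ----------------------------------------------------------
    if (!is.null(config$simConfig)) {
      sim <- simulateStudy(config$simConfig)
      population <- sim$population
      adjacency <- sim$adjacency
      covariates <- sim$truth@covariates
      certCounts <- redistributeGarbage(sim$specific, sim$garbage)
      # ratio denominator: certificate deaths after cause-of-death
      # processing, i.e. the table the model is fitted to
      ratios <- estimateRatios(sim$trueDeaths, certCounts)
      put(sim$population, "population.csv", writeStratifiedCounts)
      put(sim$certDeaths, "certificate_deaths.csv", writeStratifiedCounts)
      truthTab <- cbind(as.data.frame(sim$truth@strata),
                        trueRate = sim$truth@trueRate)
      put(truthTab, "truth.csv")
      put(adjacency, "adjacency.csv", writeAdjacency)
    } else {
      counts <- readStratifiedCounts(config$paths$counts)
      if (!is.null(config$paths$mapping))
        counts <- mergeCounties(counts, readUnitMapping(config$paths$mapping))
      population <- counts
      certCounts <- counts
      adjacency <- readAdjacency(config$paths$adjacency)
      covariates <- NULL
      if (!is.null(config$paths$covariatesUnit))
        covariates$unit <- as.data.frame(fread(config$paths$covariatesUnit))
      if (!is.null(config$paths$covariatesUnitRace))
        covariates$unitRace <-
          as.data.frame(fread(config$paths$covariatesUnitRace))
      ratios <- readClassificationRatios(config$paths$ratios)
    }
    put(ratios, "classification_ratios.csv", writeClassificationRatios)
    .stageLog(stage <- "preprocess", t0)

    # ---- stage 1: small-area model --------------------------------------
    spec <- modelSpec(nDraws = config$nDraws, seed = config$seed,
                      useYearRW = config$useYearRW)
    design <- buildDesign(certCounts, covariates, adjacency, spec)
    fit <- fitModel(design)
    .stageLog(stage <- "fit", t0)
    drawsCert <- drawPosterior(fit)
    .stageLog(stage <- "draw", t0)

    # ---- stage 3 targets (from the unadjusted draws), then stage 2 ------
    targets <- buildTargets(drawsCert, population, ratios = ratios,
                            benchmarkLevel = config$benchmarkLevel,
                            tolerance = config$rakingTolerance,
                            maxIterations = config$rakingMaxIterations)
    drawsAdj <- adjustDraws(drawsCert, ratios)
    rm(drawsCert); gc(FALSE)
    .stageLog(stage <- "adjust", t0)

    # ---- stage 3: raking -------------------------------------------------
    raked <- rakeAllDraws(drawsAdj, population, targets)
    rm(drawsAdj); gc(FALSE)
    put(S4Vectors::metadata(raked)$rakingReport, "raking_report.csv")
    if (config$writeDraws) put(raked, "raked_draws.csv", writeRateDraws)
    .stageLog(stage <- "rake", t0)

    # ---- summarize -------------------------------------------------------
    std <- config$standardWeights
    stdDraws <- ageStandardize(raked, std)
    totDraws <- ageStandardize(collapseRaces(raked, population), std)
    natAge <- aggregateGeography(raked, population, "national")
    natStd <- ageStandardize(natAge, std)
    summaryCounty <- rbind(pointAndUI(stdDraws), pointAndUI(totDraws))
    summaryCounty <- applyMask(summaryCounty, population,
                               threshold = config$maskThreshold,
                               popScale = config$allSexFactor)
    summaryNational <- pointAndUI(natStd)
    put(summaryCounty, "summary_county.csv")
    put(summaryNational, "summary_national.csv")

    # percent changes per unit x race between the comparison years
    yrs <- config$compareYears
    changes <- NULL
    for (dset in list(stdDraws, totDraws)) {
      rd <- rowData(dset)
      i0 <- which(rd$year == yrs[1L]); i1 <- which(rd$year == yrs[2L])
      k0 <- paste(rd$unit[i0], rd$race[i0]); k1 <- paste(rd$unit[i1], rd$race[i1])
      i1 <- i1[match(k0, k1)]
      pc <- percentChange(rateMatrix(dset)[i0, , drop = FALSE],
                          rateMatrix(dset)[i1, , drop = FALSE])
      chunk <- S4Vectors::DataFrame(unit = rd$unit[i0], race = rd$race[i0], pc)
      changes <- if (is.null(changes)) chunk else rbind(changes, chunk)
    }
    changes <- applyMask(changes, population,
                         threshold = config$maskThreshold,
                         popScale = config$allSexFactor)
    put(changes, "summary_changes.csv")

    # county-change bookkeeping and rankings per race
    raceLabels <- c(strataLevels(raked)$races, "Total")
    changeSummaries <- lapply(stats::setNames(raceLabels, raceLabels),
      function(r) {
        sub <- changes[changes$race == r, ]
        if (all(sub$masked %in% TRUE)) NULL else countyChangeSummary(sub)
      })
    csTab <- do.call(rbind, lapply(names(changeSummaries), function(r) {
      s <- changeSummaries[[r]]
      if (is.null(s)) return(NULL)
      data.frame(race = r, as.data.frame(s))
    }))
    put(csTab, "county_change_summary.csv")
    lastYear <- summaryCounty[summaryCounty$year == yrs[2L], ]
    rankings <- do.call(rbind, lapply(raceLabels, function(r) {
      sub <- lastYear[lastYear$race == r, ]
      if (all(sub$masked %in% TRUE)) return(NULL)
      out <- suppressWarnings(rankUnits(sub, config$topK))
      out
    }))
    put(rankings, "rankings.csv")
    .stageLog(stage <- "summarize", t0)

    # ---- manifest --------------------------------------------------------
    manifest <- list(
      package = "pregsae",
      version = as.character(utils::packageVersion("pregsae")),
      seed = config$seed, nDraws = config$nDraws,
      maskThreshold = config$maskThreshold,
      allSexFactor = config$allSexFactor,
      compareYears = config$compareYears,
      benchmarkLevel = config$benchmarkLevel,
      synthetic = !is.null(config$simConfig),
      checksums = as.list(tools::md5sum(sort(outputs))))
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(summaryCounty = summaryCounty, summaryNational = summaryNational,
         changes = changes, changeSummaries = changeSummaries,
         rankings = rankings, ratios = ratios, fit = fit,
         rakedDraws = raked, stdDraws = stdDraws, totDraws = totDraws,
         natStd = natStd, population = population,
         truth = if (!is.null(config$simConfig)) sim$truth else NULL,
         outDir = config$outDir)
  }, error = function(e) {
    .stopf("pipeline failed in stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}
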