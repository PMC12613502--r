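# Synthetic-recovery evaluation: runs the full three-stage pipeline on a
# synthetic study with known truth and measures how well each stage does
# its job. Used by the test suite and the acceptance script.

#' Evaluate pipeline recovery on synthetic data
#'
#' Generates a synthetic study (200 counties, five racial/ethnic
#' populations, nine age bands, 2000-2019 by default), runs stage 1-3 and
#' the summaries, and returns recovery metrics against the known truth:
#'
#' * `correlation`: Pearson correlation between true and estimated
#'   age-standardized rates over all (unit, race, year) cells;
#' * `coverage`: share of strata whose true rate falls inside the 95%
#'   draw interval;
#' * `raceErrors`: per race, the absolute error of the national
#'   population-weighted rate against the realized self-report rate,
#'   before (`unadjusted`) and after (`adjusted`) misclassification
#'   adjustment, with the estimated ratio;
#' * `shrinkage`: RMSE against truth of modeled versus raw (deaths over
#'   person-years) age-standardized rates for small (masking-eligible)
#'   unit-race combinations;
#' * `rakingDiscrepancy`: achieved relative margin errors of stage 3;
#' * `changeSummary`: county-change bookkeeping for the all-race county
#'   percent changes between the first and last year.
#'
#' @param seed master seed for the synthetic study and the model draws.
#' @param nDraws posterior draws (default 1000).
#' @param config optional [SimConfig-class]; defaults to
#'   `simConfig(seed = seed)`.
#' @param std a [StandardPopulation-class] for the standardized metrics.
#' @return A list of metrics (see above) plus `nStrata`, `nDeaths`.
#' @export
evaluateSyntheticRecovery <- function(seed = 1L, nDraws = 1000L,
                                      config = NULL,
                                      std = standardPopulation()) {
  if (is.null(config)) config <- simConfig(seed = seed)
  sim <- simulateStudy(config)
  certCounts <- redistributeGarbage(sim$specific, sim$garbage)
  spec <- modelSpec(nDraws = nDraws, seed = seed)
  fit <- fitModel(buildDesign(certCounts, sim$truth@covariates,
                              sim$adjacency, spec))
  draws <- drawPosterior(fit)
  rm(fit); .gcLight()
  ratios <- estimateRatios(sim$trueDeaths, certCounts)
  targets <- buildTargets(draws, sim$population, ratios = ratios)
  pop <- population(sim$population)
  rd <- rowData(draws)
  races <- strataLevels(draws)$races

  # national population-weighted rates per race (pooled over all strata),
  # against the realized self-report rates the adjustment should recover
  natRate <- function(m, sel) sum(rowMeans(m[sel, , drop = FALSE]) *
                                    pop[sel]) / sum(pop[sel]) # per 1e5 via m
  mU <- rateMatrix(draws)
  unadjNat <- vapply(races, function(r) natRate(mU, rd$race == r), 0)
  rm(mU)
  adj <- adjustDraws(draws, ratios)
  rm(draws); .gcLight()
  mA <- rateMatrix(adj)
  adjNat <- vapply(races, function(r) natRate(mA, rd$race == r), 0)
  rm(mA)
  realizedNat <- vapply(races, function(r) {
    sel <- rd$race == r
    sum(deaths(sim$trueDeaths)[sel]) / sum(pop[sel]) * 1e5
  }, 0)
  ratioVec <- with(as.data.frame(ratioTable(ratios)),
                   stats::setNames(ratio, race))[races]
  raceErrors <- S4Vectors::DataFrame(
    race = races, ratio = as.numeric(ratioVec),
    realizedRate = realizedNat,
    unadjustedError = abs(unadjNat - realizedNat),
    adjustedError = abs(adjNat - realizedNat))

  raked <- rakeAllDraws(adj, sim$population, targets)
  rm(adj); .gcLight()
  rakingDisc <- S4Vectors::metadata(raked)$rakingDiscrepancy

  # coverage of the 95% draw interval over every stratum
  q <- .rowQuantiles(rateMatrix(raked), c(0.025, 0.975))
  trueRate5 <- sim$truth@trueRate * 1e5
  coverage <- mean(q[, 1L] <= trueRate5 & trueRate5 <= q[, 2L])

  # age-standardized estimates vs truth over (unit, race, year)
  stdDraws <- ageStandardize(raked, std)
  pu <- pointAndUI(stdDraws)
  truthDraws <- RateDraws(matrix(trueRate5, ncol = 1), sim$truth@strata,
                          levels = strataLevels(raked))
  truthStd <- ageStandardize(truthDraws, std)
  correlation <- stats::cor(pu$pointEstimate, rateMatrix(truthStd)[, 1L])

  # shrinkage: masking-eligible unit-race combinations (all-sex population
  # below the display threshold), modeled vs raw age-standardized rates
  nYears <- length(strataLevels(raked)$years)
  popUR <- rowsum(pop, paste(sim$population$unit, sim$population$race,
                             sep = "\r"))[, 1L] / nYears
  small <- names(popUR)[2 * popUR < 1000]
  rawRate <- deaths(sim$trueDeaths) / pop * 1e5
  rawStd <- ageStandardize(RateDraws(matrix(pmax(rawRate, 1e-12), ncol = 1),
                                     sim$truth@strata,
                                     levels = strataLevels(raked)), std)
  keyS <- paste(rowData(rawStd)$unit, rowData(rawStd)$race, sep = "\r")
  sel <- keyS %in% small
  tS <- rateMatrix(truthStd)[sel, 1L]
  shrinkage <- c(
    rawRMSE = sqrt(mean((rateMatrix(rawStd)[sel, 1L] - tS)^2)),
    modelRMSE = sqrt(mean((pu$pointEstimate[sel] - tS)^2)))

  # all-race county percent changes between the first and last year
  totStd <- ageStandardize(collapseRaces(raked, sim$population), std)
  rm(raked); .gcLight()
  rdT <- rowData(totStd)
  yrs <- range(strataLevels(totStd)$years)
  i0 <- which(rdT$year == yrs[1L]); i1 <- which(rdT$year == yrs[2L])
  i1 <- i1[match(rdT$unit[i0], rdT$unit[i1])]
  changes <- percentChange(rateMatrix(totStd)[i0, , drop = FALSE],
                           rateMatrix(totStd)[i1, , drop = FALSE])
  changes$unit <- rdT$unit[i0]
  changes$race <- "Total"
  changes <- applyMask(changes, sim$population, popScale = 2)
  changeSummary <- countyChangeSummary(changes)

  list(correlation = correlation, coverage = coverage,
       raceErrors = raceErrors, shrinkage = shrinkage,
       rakingDiscrepancy = rakingDisc,
       changeSummary = changeSummary,
       nStrata = length(trueRate5),
       nDeaths = sum(deaths(sim$trueDeaths)),
       nUnits = config@nUnits, nDraws = nDraws)
}
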