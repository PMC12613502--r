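#' @importClassesFrom S4Vectors DFrame
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
NULL

# ---------------------------------------------------------------------------
# StratifiedCounts
# ---------------------------------------------------------------------------

#' StratifiedCounts: deaths and person-years by county, race, age and year
#'
#' The universal exchange table of the pipeline: one row per stratum
#' (`unit`, `race`, `ageBand`, `year`) carrying `deaths` (non-negative;
#' fractional after garbage-code redistribution) and `population` (positive
#' person-years). Rows are kept in canonical order (unit, race, age band,
#' year) and the ordered level sets are stored in `metadata(x)$strataLevels`.
#'
#' @slot .Data,listData,... inherited from [S4Vectors::DFrame].
#' @seealso [StratifiedCounts()], [validateStrata()], [mergeCounties()]
#' @export
setClass("StratifiedCounts", contains = "DFrame")

setValidity("StratifiedCounts", function(object) {
  req <- c("unit", "race", "ageBand", "year", "deaths", "population")
  missing <- setdiff(req, colnames(object))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  d <- object$deaths
  p <- object$population
  if (any(!is.finite(d)) || any(d < 0))
    return("deaths must be finite and non-negative")
  if (any(!is.finite(p)) || any(p <= 0))
    return("population must be finite and strictly positive")
  key <- .strataKey(object$unit, object$race, object$ageBand, object$year)
  if (anyDuplicated(key))
    return("duplicated (unit, race, ageBand, year) keys")
  lv <- metadata(object)$strataLevels
  if (is.null(lv))
    return("metadata(x)$strataLevels is required")
  if (nrow(object) != prod(lengths(lv)))
    return(sprintf("table is not rectangular: %d rows, %d strata expected",
                   nrow(object), prod(lengths(lv))))
  TRUE
})

#' Construct a StratifiedCounts table
#'
#' @param df data.frame (or DFrame) with columns `unit`, `race`, `ageBand`,
#'   `year`, `deaths`, `population`. Must cover the full rectangular grid of
#'   strata (use [validateStrata()] to rectangularize raw input).
#' @param levels optional named list (`units`, `races`, `ageBands`, `years`)
#'   fixing the level order; derived from the data when `NULL` (units and
#'   races sorted, age bands by leading age, years ascending).
#' @return A [StratifiedCounts-class] object in canonical row order.
#' @examples
#' df <- expand.grid(unit = "U1", race = "White", ageBand = "15-19",
#'                   year = 2000:2001, stringsAsFactors = FALSE)
#' df$deaths <- c(1, 2); df$population <- c(1e5, 1e5)
#' StratifiedCounts(df)
#' @export
StratifiedCounts <- function(df, levels = NULL) {
  df <- as.data.frame(df)
  if (is.null(levels)) {
    levels <- list(units = sort(unique(as.character(df$unit))),
                   races = sort(unique(as.character(df$race))),
                   ageBands = .sortAgeBands(unique(as.character(df$ageBand))),
                   years = sort(unique(as.integer(df$year))))
  }
  o <- .strataOrder(df$unit, df$race, df$ageBand, df$year, levels)
  out <- DataFrame(unit = as.character(df$unit)[o],
                   race = as.character(df$race)[o],
                   ageBand = as.character(df$ageBand)[o],
                   year = as.integer(df$year)[o],
                   deaths = as.numeric(df$deaths)[o],
                   population = as.numeric(df$population)[o])
  metadata(out)$strataLevels <- levels
  new("StratifiedCounts", out)
}

#' @rdname deaths
#' @export
setMethod("deaths", "StratifiedCounts", function(x) x$deaths)

#' @rdname population
#' @export
setMethod("population", "StratifiedCounts", function(x) x$population)

#' @rdname strataLevels
#' @export
setMethod("strataLevels", "StratifiedCounts",
          function(x) metadata(x)$strataLevels)

#' @export
#' @describeIn StratifiedCounts-class compact display
setMethod("show", "StratifiedCounts", function(object) {
  lv <- metadata(object)$strataLevels
  cat(sprintf(
    "StratifiedCounts: %d strata (%d units x %d races x %d age bands x %d years)\n",
    nrow(object), length(lv$units), length(lv$races), length(lv$ageBands),
    length(lv$years)))
  cat(sprintf("  total deaths %.6g, total person-years %.6g\n",
              sum(object$deaths), sum(object$population)))
  callNextMethod()
})

# ---------------------------------------------------------------------------
# RateDraws
# ---------------------------------------------------------------------------

#' RateDraws: per-stratum vectors of mortality-rate draws
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single assay
#' `"rate"` holding a strata-by-draws matrix of mortality rates in deaths
#' per 100,000 person-years. `rowData` carries the stratum keys (`unit`,
#' `race`, `year`, and `ageBand` unless age-standardized away); columns are
#' draws, aligned across strata so draw *j* is one coherent posterior sample.
#'
#' @seealso [drawPosterior()], [adjustDraws()], [rakeAllDraws()],
#'   [ageStandardize()]
#' @export
setClass("RateDraws", contains = "SummarizedExperiment")

setValidity("RateDraws", function(object) {
  if (!"rate" %in% assayNames(object)) return("assay 'rate' is required")
  m <- assay(object, "rate")
  if (!all(c("unit", "race", "year") %in% colnames(rowData(object))))
    return("rowData must contain unit, race, year")
  mn <- suppressWarnings(min(m)); mx <- suppressWarnings(max(m))
  if (!is.finite(mn) || !is.finite(mx)) return("rates must be finite")
  if (mn <= 0) return("rates must be strictly positive")
  TRUE
})

#' Construct a RateDraws object
#'
#' @param rate numeric matrix, strata by draws, deaths per 100,000.
#' @param strata DFrame/data.frame of stratum keys (`unit`, `race`, `year`,
#'   optionally `ageBand`), one row per matrix row.
#' @param levels optional stratum level list stored in the metadata.
#' @return A [RateDraws-class] object.
#' @export
RateDraws <- function(rate, strata, levels = NULL) {
  rate <- as.matrix(rate)
  if (!is.null(dimnames(rate))) dimnames(rate) <- NULL
  rd <- DataFrame(as.data.frame(strata))
  se <- SummarizedExperiment(assays = list(rate = rate), rowData = rd)
  metadata(se)$strataLevels <- levels
  new("RateDraws", se)
}

#' @rdname nDraws
#' @export
setMethod("nDraws", "RateDraws", function(x) ncol(x))

#' @rdname rateMatrix
#' @export
setMethod("rateMatrix", "RateDraws", function(x) assay(x, "rate"))

#' @rdname strataLevels
#' @export
setMethod("strataLevels", "RateDraws", function(x) metadata(x)$strataLevels)

#' @export
#' @describeIn RateDraws-class compact display
setMethod("show", "RateDraws", function(object) {
  cat(sprintf("RateDraws: %d strata x %d draws (deaths per 100,000)\n",
              nrow(object), ncol(object)))
  m <- assay(object, "rate")
  cat(sprintf("  rate range [%.4g, %.4g], mean %.4g\n",
              min(m), max(m), mean(m)))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# SimConfig / SyntheticTruth
# ---------------------------------------------------------------------------

#' SimConfig: parameters of the synthetic vital-statistics generator
#'
#' Holds every knob of the synthetic study population: stratification
#' (counties, five racial/ethnic populations, 5-year age bands 10-14
#' through 50-54, years 2000-2019), population sizes (log-normal unit
#' totals spanning roughly hundreds to a million), the log-linear true-rate
#' model (baseline log rate, race offsets, age curve, time slopes,
#' covariate effects, proper-CAR spatial effects), certificate-race
#' misreporting, and the garbage-code fraction. Construct with
#' [simConfig()], which supplies study-condition defaults.
#'
#' @export
setClass("SimConfig", representation(
  nUnits = "integer", races = "character", ageBands = "character",
  years = "integer", popLognormalParams = "numeric",
  raceShareAlpha = "numeric", ageWeights = "numeric",
  popDriftMean = "numeric", popDriftSd = "numeric",
  baselineLogRate = "numeric", raceOffsets = "numeric",
  ageCurve = "numeric", timeSlope = "numeric", raceTimeSlopes = "numeric",
  covariateBetas = "numeric", spatialSd = "numeric", spatialRho = "numeric",
  misclassMatrix = "matrix", garbageFraction = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nUnits < 1L) return("nUnits must be a positive integer")
  for (f in c("races", "ageBands", "years")) {
    v <- slot(object, f)
    if (length(v) == 0L) return(paste(f, "must be nonempty"))
    if (anyDuplicated(v)) return(paste(f, "must be unique"))
  }
  nr <- length(object@races)
  if (length(object@raceOffsets) != nr) return("raceOffsets: one value per race")
  if (length(object@raceTimeSlopes) != nr)
    return("raceTimeSlopes: one value per race")
  if (length(object@raceShareAlpha) != nr)
    return("raceShareAlpha: one value per race")
  if (length(object@ageCurve) != length(object@ageBands))
    return("ageCurve: one value per age band")
  if (length(object@ageWeights) != length(object@ageBands))
    return("ageWeights: one value per age band")
  if (any(object@ageWeights <= 0)) return("ageWeights must be positive")
  m <- object@misclassMatrix
  if (!is.numeric(m) || nrow(m) != nr || ncol(m) != nr)
    return("misclassMatrix must be race x race")
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12))
    return("misclassMatrix rows must be nonnegative and sum to 1 (tol 1e-12)")
  if (object@garbageFraction < 0 || object@garbageFraction >= 1)
    return("garbageFraction must lie in [0, 1)")
  if (object@spatialSd < 0) return("spatialSd must be >= 0")
  if (object@spatialRho < 0 || object@spatialRho >= 1)
    return("spatialRho must lie in [0, 1)")
  if (length(object@popLognormalParams) != 2L ||
      object@popLognormalParams[2L] < 0)
    return("popLognormalParams must be c(meanlog, sdlog >= 0)")
  TRUE
})

#' SyntheticTruth: ground truth of a synthetic run
#'
#' The strictly positive true mortality rate for every stratum (deaths per
#' person-year), the centered spatial effects actually drawn, the covariate
#' tables used, and an echo of the generating [SimConfig-class].
#'
#' @export
setClass("SyntheticTruth", representation(
  strata = "DFrame", trueRate = "numeric", spatialEffects = "numeric",
  covariates = "list", config = "SimConfig"))

setValidity("SyntheticTruth", function(object) {
  if (any(!is.finite(object@trueRate)) || any(object@trueRate <= 0))
    return("trueRate must be finite and strictly positive")
  if (length(object@trueRate) != nrow(object@strata))
    return("trueRate length must match strata")
  if (length(object@spatialEffects) &&
      abs(mean(object@spatialEffects)) > 1e-8)
    return("spatialEffects must be centered")
  TRUE
})

#' @export
#' @describeIn SyntheticTruth-class compact display
setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d strata; rate range [%.3g, %.3g] per person-year\n",
              nrow(object@strata), min(object@trueRate), max(object@trueRate)))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# ClassificationRatios
# ---------------------------------------------------------------------------

#' ClassificationRatios: certificate-to-self-report death ratios
#'
#' For each racial/ethnic population (optionally per age band), the ratio of
#' deaths identified by self-report to deaths identified on the death
#' certificate. Multiplying a certificate-race death rate by its ratio
#' converts it to the self-report basis.
#'
#' @export
setClass("ClassificationRatios", representation(table = "DFrame"))

setValidity("ClassificationRatios", function(object) {
  tab <- object@table
  if (!all(c("race", "ratio") %in% colnames(tab)))
    return("table needs columns race and ratio")
  r <- tab$ratio
  if (any(!is.na(r) & (!is.finite(r) | r <= 0)))
    return("ratios must be positive and finite (or NA for undefined cells)")
  TRUE
})

#' Construct a ClassificationRatios object
#'
#' @param race character vector of race labels.
#' @param ratio positive ratios, aligned with `race`.
#' @param ageBand optional age-band labels for age-specific ratios.
#' @return A [ClassificationRatios-class] object.
#' @examples
#' classificationRatios(c("AIAN", "White"), c(1.4, 0.96))
#' @export
classificationRatios <- function(race, ratio, ageBand = NULL) {
  tab <- DataFrame(race = as.character(race), ratio = as.numeric(ratio))
  if (!is.null(ageBand)) tab$ageBand <- as.character(ageBand)
  new("ClassificationRatios", table = tab)
}

#' @rdname ratioTable
#' @export
setMethod("ratioTable", "ClassificationRatios", function(x) x@table)

#' @export
#' @describeIn ClassificationRatios-class compact display
setMethod("show", "ClassificationRatios", function(object) {
  cat("ClassificationRatios:\n")
  print(as.data.frame(object@table))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# FittedModel / RakingTargets / StandardPopulation
# ---------------------------------------------------------------------------

#' FittedModel: mode and curvature of the approximated posterior
#'
#' The result of [fitModel()]: penalized-likelihood mode of all fixed and
#' random effects, the negative Hessian of the log posterior at the mode
#' (with its Cholesky factorization), optimized variance hyperparameters,
#' and convergence diagnostics.
#'
#' @export
setClass("FittedModel", representation(
  theta = "numeric", hessian = "ANY", chol = "ANY", hyper = "numeric",
  converged = "logical", diagnostics = "list", design = "list"))

#' @export
#' @describeIn FittedModel-class compact display
setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel: %d parameters, converged: %s\n",
              length(object@theta), object@converged))
  if (length(object@hyper))
    cat("  hyper (SD scale):",
        paste(sprintf("%s=%.4g", names(object@hyper), object@hyper),
              collapse = ", "), "\n")
  cat(sprintf("  gradient max |g| = %.3g after %d Newton steps\n",
              object@diagnostics$gradNorm, object@diagnostics$iterations))
  invisible(NULL)
})

#' RakingTargets: margins each draw must match after calibration
#'
#' Stage-A targets are all-race expected death counts per
#' (unit, ageBand, year) cell; stage-B targets are benchmark death counts
#' per (race, ageBand, year) at the aggregate level. Each is a matrix with
#' one column per draw (or a single column for one draw).
#'
#' @export
setClass("RakingTargets", representation(
  stageAKeys = "DFrame", stageA = "matrix",
  stageBKeys = "DFrame", stageB = "matrix",
  benchmarkLevel = "character", tolerance = "numeric",
  maxIterations = "integer"))

setValidity("RakingTargets", function(object) {
  if (any(object@stageA < 0) || any(object@stageB < 0))
    return("targets must be nonnegative")
  if (object@tolerance <= 0) return("tolerance must be > 0")
  if (ncol(object@stageA) != ncol(object@stageB))
    return("stage A and B must cover the same draws")
  TRUE
})

#' StandardPopulation: age weights for rate standardization
#'
#' Positive weights over the six 5-year age bands 15-19 through 40-44,
#' normalized to sum to one. The defaults are uniform; supply Census-based
#' weights for a 2010-standard rate.
#'
#' @export
setClass("StandardPopulation",
         representation(bands = "character", weights = "numeric"))

setValidity("StandardPopulation", function(object) {
  expected <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44")
  if (!identical(object@bands, expected))
    return("bands must be exactly 15-19 ... 40-44")
  if (any(object@weights <= 0)) return("weights must be positive")
  if (abs(sum(object@weights) - 1) > 1e-12)
    return("weights must sum to 1")
  TRUE
})

#' Construct a StandardPopulation
#'
#' @param weights positive weights for the bands 15-19, 20-24, 25-29,
#'   30-34, 35-39, 40-44 (normalized internally). Default uniform.
#' @return A [StandardPopulation-class] object.
#' @examples
#' standardPopulation()                      # uniform weights
#' standardPopulation(c(10.6, 10.5, 10.2, 10.0, 10.1, 10.4))  # e.g. census counts
#' @export
standardPopulation <- function(weights = rep(1, 6)) {
  stopifnot(length(weights) == 6L)
  new("StandardPopulation",
      bands = c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44"),
      weights = as.numeric(weights) / sum(weights))
}

#' @export
#' @describeIn StandardPopulation-class compact display
setMethod("show", "StandardPopulation", function(object) {
  cat("StandardPopulation (ages 15-44):\n")
  print(stats::setNames(round(object@weights, 4), object@bands))
  invisible(NULL)
})
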