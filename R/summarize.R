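# Summarization: age standardization, geographic aggregation, point
# estimates and 95% uncertainty intervals from draw percentiles,
# posterior-probability significance, small-population masking, percent
# changes, county-change bookkeeping, and rankings. All comparisons are on
# full precision; rounding (half-up, one decimal) is display-only.

#' Age-standardize rate draws
#'
#' For each (unit, race, year) and each draw, the standardized rate is the
#' weighted sum of the age-specific rates over the bands 15-19 through
#' 40-44 using the standard population's weights. Bands outside 15-44 are
#' ignored; a missing band raises an error naming it.
#'
#' @param draws a [RateDraws-class] with an `ageBand` key.
#' @param std a [StandardPopulation-class] (default uniform weights).
#' @return A [RateDraws-class] keyed by (unit, race, year).
#' @export
ageStandardize <- function(draws, std = standardPopulation()) {
  stopifnot(is(draws, "RateDraws"), is(std, "StandardPopulation"))
  rd <- rowData(draws)
  if (!"ageBand" %in% colnames(rd)) .stopf("draws carry no ageBand")
  missing <- setdiff(std@bands, unique(rd$ageBand))
  if (length(missing))
    .stopf("age band(s) missing from draws: %s",
           paste(missing, collapse = ", "))
  .gcLight()
  keep <- rd$ageBand %in% std@bands
  w <- std@weights[match(rd$ageBand[keep], std@bands)]
  g <- paste(rd$unit[keep], rd$race[keep], rd$year[keep], sep = "\r")
  gf <- factor(g, levels = unique(g))
  m <- rowsum(rateMatrix(draws)[keep, , drop = FALSE] * w, gf,
              reorder = FALSE)
  first <- !duplicated(g)
  keys <- S4Vectors::DataFrame(unit = rd$unit[keep][first],
                               race = rd$race[keep][first],
                               year = rd$year[keep][first])
  RateDraws(unname(as.matrix(m)), keys, levels = strataLevels(draws))
}

#' Aggregate rate draws over geography
#'
#' Aggregate age-specific draws to a higher geographical level (e.g.
#' national) by population-weighting across units, per draw:
#' `sum(pop * rate) / sum(pop)` within each (race, ageBand, year) group.
#' Optionally collapses races as well (for all-race totals).
#'
#' @param draws a [RateDraws-class] with unit-level rows.
#' @param population aligned [StratifiedCounts-class] person-years.
#' @param level label for the aggregate unit (default `"national"`).
#' @param collapseRaces also population-weight across races, labelling the
#'   result `"Total"`.
#' @return A [RateDraws-class] at the aggregate level.
#' @export
aggregateGeography <- function(draws, population, level = "national",
                               collapseRaces = FALSE) {
  stopifnot(is(draws, "RateDraws"), is(population, "StratifiedCounts"))
  rd <- rowData(draws)
  .assertAligned(rd, population, "draws and population")
  if (nrow(rd) == 0L) .stopf("empty aggregate")
  pop <- population(population)
  race <- if (collapseRaces) rep("Total", nrow(rd)) else rd$race
  hasAge <- "ageBand" %in% colnames(rd)
  age <- if (hasAge) rd$ageBand else rep("*", nrow(rd))
  g <- paste(race, age, rd$year, sep = "\r")
  gf <- factor(g, levels = unique(g))
  num <- rowsum(rateMatrix(draws) * pop, gf, reorder = FALSE)
  den <- rowsum(pop, gf, reorder = FALSE)[, 1L]
  m <- as.matrix(num) / den
  first <- !duplicated(g)
  keys <- S4Vectors::DataFrame(unit = level, race = race[first],
                               year = rd$year[first])
  if (hasAge) keys$ageBand <- age[first]
  RateDraws(unname(m), keys, levels = strataLevels(draws))
}

#' Collapse races within each unit
#'
#' Population-weighted all-race ("Total") age-specific draws per unit,
#' used for county-level total-population summaries.
#'
#' @inheritParams aggregateGeography
#' @return A [RateDraws-class] with `race = "Total"` per unit.
#' @export
collapseRaces <- function(draws, population) {
  stopifnot(is(draws, "RateDraws"), is(population, "StratifiedCounts"))
  rd <- rowData(draws)
  .assertAligned(rd, population, "draws and population")
  pop <- population(population)
  hasAge <- "ageBand" %in% colnames(rd)
  age <- if (hasAge) rd$ageBand else rep("*", nrow(rd))
  g <- paste(rd$unit, age, rd$year, sep = "\r")
  gf <- factor(g, levels = unique(g))
  num <- rowsum(rateMatrix(draws) * pop, gf, reorder = FALSE)
  den <- rowsum(pop, gf, reorder = FALSE)[, 1L]
  m <- as.matrix(num) / den
  first <- !duplicated(g)
  keys <- S4Vectors::DataFrame(unit = rd$unit[first], race = "Total",
                               year = rd$year[first])
  if (hasAge) keys$ageBand <- age[first]
  RateDraws(unname(m), keys, levels = strataLevels(draws))
}

#' Point estimates and 95% uncertainty intervals
#'
#' The point estimate is the mean of the draws; the 95% uncertainty
#' interval spans their 2.5th and 97.5th percentiles, computed by linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param draws a [RateDraws-class] (at least 2 draws).
#' @return `DataFrame` with the stratum keys plus `pointEstimate`,
#'   `uiLower`, `uiUpper`.
#' @export
pointAndUI <- function(draws) {
  stopifnot(is(draws, "RateDraws"))
  if (nDraws(draws) < 2L) .stopf("at least 2 draws required")
  m <- rateMatrix(draws)
  q <- .rowQuantiles(m, c(0.025, 0.975))
  out <- rowData(draws)
  out$pointEstimate <- rowMeans(m)
  out$uiLower <- q[, 1L]
  out$uiUpper <- q[, 2L]
  out
}

#' Posterior-probability significance of a difference
#'
#' `p` is the fraction of aligned draws with `a - b > 0`; the difference is
#' called statistically significant when `p < 0.025` or `p > 0.975`
#' (strict inequalities), akin to a two-tailed test at alpha 0.05.
#'
#' @param drawsA,drawsB aligned draw vectors or matrices (equal draw
#'   counts; rows aligned).
#' @return List with `posteriorProbability` and `significant` (vectors for
#'   matrix input).
#' @export
compareSignificance <- function(drawsA, drawsB) {
  a <- if (is.matrix(drawsA)) drawsA else matrix(drawsA, nrow = 1L)
  b <- if (is.matrix(drawsB)) drawsB else matrix(drawsB, nrow = 1L)
  if (!all(dim(a) == dim(b))) .stopf("draws are not aligned")
  p <- rowMeans(a - b > 0)
  list(posteriorProbability = p, significant = p < 0.025 | p > 0.975)
}

#' Draw-wise percent change between two time points
#'
#' Computes `100 * (r1 - r0) / r0` for each draw, reports the mean as the
#' point estimate with percentile uncertainty intervals, and flags
#' significance from the posterior probability that the later rate exceeds
#' the earlier one.
#'
#' @param draws0,draws1 aligned draw matrices (or vectors) for the earlier
#'   and later year; earlier rates must be positive.
#' @param method `"drawwise"` (default; mean of draw-wise changes) or
#'   `"pointwise"` (change of draw means).
#' @return `DataFrame` with `percentChange`, `uiLower`, `uiUpper`,
#'   `posteriorProbability`, `significant`.
#' @export
percentChange <- function(draws0, draws1,
                          method = c("drawwise", "pointwise")) {
  method <- match.arg(method)
  d0 <- if (is.matrix(draws0)) draws0 else matrix(draws0, nrow = 1L)
  d1 <- if (is.matrix(draws1)) draws1 else matrix(draws1, nrow = 1L)
  if (!all(dim(d0) == dim(d1))) .stopf("draws are not aligned")
  if (any(d0 <= 0)) .stopf("baseline draws must be positive")
  ch <- 100 * (d1 - d0) / d0
  point <- if (method == "drawwise") rowMeans(ch)
           else 100 * (rowMeans(d1) - rowMeans(d0)) / rowMeans(d0)
  q <- .rowQuantiles(ch, c(0.025, 0.975))
  sig <- compareSignificance(d1, d0)
  S4Vectors::DataFrame(percentChange = point, uiLower = q[, 1L],
                       uiUpper = q[, 2L],
                       posteriorProbability = sig$posteriorProbability,
                       significant = sig$significant)
}

#' Mask small-population strata
#'
#' Suppresses displayed estimates for every (unit, race) combination whose
#' mean annual population over the full year range is strictly below the
#' threshold; masking applies to all years jointly, never year by year.
#' Masked rows keep their keys but carry `NA` in every value column.
#'
#' @param summary `DataFrame`/data.frame of summary rows with `unit` and
#'   `race` columns (race `"Total"` uses the all-race population).
#' @param population a [StratifiedCounts-class]; person-years are summed
#'   over age bands (and races for `"Total"`) per year, then averaged over
#'   years. Supply the all-sex population the display rule refers to (or
#'   set `popScale`).
#' @param threshold masking threshold (default 1000).
#' @param popScale multiplier applied to the population before comparison
#'   (e.g. 2 to approximate all-sex person-years from female-only tables).
#' @return The summary with a logical `masked` column and `NA`-blanked
#'   values for masked rows.
#' @export
applyMask <- function(summary, population, threshold = 1000,
                      popScale = 1) {
  stopifnot(is(population, "StratifiedCounts"))
  if (!all(c("unit", "race") %in% colnames(summary)))
    .stopf("summary needs unit and race columns")
  nYears <- length(strataLevels(population)$years)
  key <- paste(population$unit, population$race, sep = "\r")
  tot <- rowsum(population(population), key)[, 1L] / nYears
  totUnit <- rowsum(population(population),
                    as.character(population$unit))[, 1L] / nYears
  skey <- paste(summary$unit, summary$race, sep = "\r")
  meanPop <- unname(tot[match(skey, names(tot))])
  isTot <- as.character(summary$race) == "Total"
  meanPop[isTot] <- unname(totUnit[match(as.character(summary$unit)[isTot],
                                         names(totUnit))])
  if (anyNA(meanPop)) .stopf("population missing for some summary rows")
  masked <- meanPop * popScale < threshold
  out <- summary
  out$meanAnnualPopulation <- meanPop * popScale
  out$masked <- masked
  valueCols <- setdiff(colnames(out)[vapply(seq_len(ncol(out)), function(j)
    is.numeric(out[[j]]), TRUE)],
    c("year", "meanAnnualPopulation"))
  for (cn in valueCols) out[[cn]][masked] <- NA
  if ("significant" %in% colnames(out)) out$significant[masked] <- NA
  out
}

#' County-change bookkeeping
#'
#' Summarizes per-county percent changes: how many unmasked counties rose,
#' how many rose significantly, and the median change with its
#' interquartile range. Percentages are rounded half-up to one decimal for
#' display; medians and quartiles use linear-interpolation quantiles
#' (type 7).
#'
#' @param changes data.frame/DataFrame with columns `percentChange` and
#'   `significant` (and optionally `masked`, which filters rows).
#' @return List with `nUnits`, `nIncrease`, `pctIncrease`,
#'   `nSignificantIncrease`, `pctSignificantIncrease`, `medianChange`,
#'   `iqrLower`, `iqrUpper`.
#' @export
countyChangeSummary <- function(changes) {
  ch <- as.data.frame(changes)
  if ("masked" %in% colnames(ch)) ch <- ch[!ch$masked %in% TRUE, ]
  if (nrow(ch) == 0L) .stopf("no unmasked units to summarize")
  n <- nrow(ch)
  up <- ch$percentChange > 0
  sigUp <- up & ch$significant %in% TRUE
  q <- stats::quantile(ch$percentChange, c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  list(nUnits = n,
       nIncrease = sum(up),
       pctIncrease = roundHalfUp(100 * sum(up) / n, 1L),
       nSignificantIncrease = sum(sigUp),
       pctSignificantIncrease = roundHalfUp(100 * sum(sigUp) / n, 1L),
       medianChange = q[2L], iqrLower = q[1L], iqrUpper = q[3L])
}

#' Top-k units by point estimate
#'
#' Orders unmasked rows by descending point estimate, breaking ties by
#' unit identifier (deterministic). Requesting more rows than available
#' returns all with a warning.
#'
#' @param summary summary rows with `unit`, `pointEstimate`, and
#'   optionally `masked`.
#' @param k how many units to return.
#' @return The top-k rows in rank order, with a `rank` column.
#' @export
rankUnits <- function(summary, k = 10L) {
  s <- as.data.frame(summary)
  if ("masked" %in% colnames(s)) s <- s[!s$masked %in% TRUE, ]
  if (k > nrow(s)) {
    warning(sprintf("k = %d exceeds %d available rows; returning all",
                    k, nrow(s)), call. = FALSE)
    k <- nrow(s)
  }
  o <- order(-s$pointEstimate, as.character(s$unit))
  out <- s[o[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}
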