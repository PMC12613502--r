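# Shared fixtures: tiny stratified tables built in code, small synthetic
# configs, and a memoized full-scale recovery run shared by the
# acceptance-style tests.

makeCounts <- function(units = "U1", races = "White", ageBands = "15-19",
                       years = 2000L, deaths = 0, population = 1e5) {
  g <- expand.grid(year = as.integer(years), ageBand = ageBands,
                   race = races, unit = units, stringsAsFactors = FALSE)
  g <- g[, c("unit", "race", "ageBand", "year")]
  g$deaths <- rep_len(deaths, nrow(g))
  g$population <- rep_len(population, nrow(g))
  StratifiedCounts(g)
}

# one-rate-per-stratum RateDraws (nDraws columns of the same values)
makeDraws <- function(counts, rates, nDraws = 1L) {
  RateDraws(matrix(rep(rates, nDraws), ncol = nDraws),
            as.data.frame(counts)[, c("unit", "race", "ageBand", "year")],
            levels = strataLevels(counts))
}

smallConfig <- function(seed = 7L, nUnits = 12L, years = 2000:2004, ...) {
  simConfig(nUnits = nUnits, years = years, seed = seed, ...)
}

chainAdjacency <- function(units) {
  n <- length(units)
  data.frame(from = units[-n], to = units[-1L], stringsAsFactors = FALSE)
}

# full-scale synthetic recovery run (200 units, 1000 draws), computed once
.recoveryCache <- new.env(parent = emptyenv())
recoveryRun <- function() {
  if (is.null(.recoveryCache$ev))
    .recoveryCache$ev <- evaluateSyntheticRecovery(seed = 1L, nDraws = 1000L)
  .recoveryCache$ev
}
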