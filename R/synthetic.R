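#' @importFrom stats rlnorm rgamma rpois rbinom rnorm rmultinom setNames
NULL

.defaultRaces <- c("AIAN", "Asian", "Black", "Latina", "White")
.defaultAgeBands <- c("10-14", "15-19", "20-24", "25-29", "30-34",
                      "35-39", "40-44", "45-49", "50-54")

# Certificate misreporting: P(certificate race = column | true race = row).
# AIAN deaths are most often misreported (mainly as White), producing a
# self-report/certificate ratio near 1.4; Asian and Latina misreporting is
# mild, Black minimal, and White gains a small inflow from every group.
.defaultMisclass <- function() {
  m <- rbind(
    AIAN   = c(0.72, 0.00, 0.00, 0.02, 0.26),
    Asian  = c(0.00, 0.97, 0.00, 0.00, 0.03),
    Black  = c(0.00, 0.00, 0.995, 0.00, 0.005),
    Latina = c(0.00, 0.00, 0.005, 0.945, 0.05),
    White  = c(0.001, 0.001, 0.001, 0.002, 0.995))
  colnames(m) <- .defaultRaces
  m
}

#' Configure the synthetic vital-statistics generator
#'
#' Builds a [SimConfig-class] whose defaults emulate NVSS/NCHS-style county
#' tabulations of pregnancy-related mortality: 200 counties with female
#' populations spanning roughly 10^2 to 10^6 person-years, five racial and
#' ethnic populations (AIAN, Asian, Black, Latina, White) with unequal
#' population shares, 5-year age bands 10-14 through 50-54, years
#' 2000-2019, true rates of order 0.5-4 per 100,000 rising over time,
#' spatially correlated county effects, covariate effects, certificate-race
#' misreporting concentrated in the AIAN population, and a garbage-coded
#' share of deaths.
#'
#' @param nUnits number of counties.
#' @param races ordered race/ethnicity labels.
#' @param ageBands ordered 5-year age-band labels.
#' @param years inclusive year range.
#' @param popLognormalParams `c(meanlog, sdlog)` of unit total person-years
#'   (females, all modeled ages) in the first year.
#' @param raceShareAlpha Dirichlet concentration of within-unit race shares.
#' @param ageWeights relative female population by age band (normalized).
#' @param popDriftMean,popDriftSd mean and SD of the per-unit annual
#'   multiplicative population growth rate.
#' @param baselineLogRate log deaths per person-year for the reference race
#'   at the reference age band in the first year.
#' @param raceOffsets additive log-rate offsets per race.
#' @param ageCurve additive log-rate effects per age band.
#' @param timeSlope shared log-linear trend per year.
#' @param raceTimeSlopes per-race trend; defaults to `timeSlope` for all.
#' @param covariateBetas named effects `c(income = ..., poverty = ...)` on
#'   the log rate per SD of the standardized covariate.
#' @param spatialSd SD of the centered county spatial effects.
#' @param spatialRho proper-CAR autocorrelation parameter in `[0, 1)`.
#' @param misclassMatrix row-stochastic race-by-race matrix of
#'   P(certificate race | true race).
#' @param garbageFraction probability a death receives a garbage code.
#' @param seed master seed; each generator derives a fixed child seed.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nUnits = 20, seed = 1)
#' cfg@races
#' @export
simConfig <- function(nUnits = 200L,
                      races = .defaultRaces,
                      ageBands = .defaultAgeBands,
                      years = 2000:2019,
                      popLognormalParams = c(log(10000), 1.6),
                      raceShareAlpha = NULL,
                      ageWeights = NULL,
                      popDriftMean = 0.005,
                      popDriftSd = 0.01,
                      baselineLogRate = log(1.0e-5),
                      raceOffsets = NULL,
                      ageCurve = NULL,
                      timeSlope = log(2) / 17,
                      raceTimeSlopes = NULL,
                      covariateBetas = c(income = -0.15, poverty = 0.20),
                      spatialSd = 0.3,
                      spatialRho = 0.9,
                      misclassMatrix = NULL,
                      garbageFraction = 0.1,
                      seed = 1L) {
  races <- as.character(races)
  nr <- length(races)
  if (is.null(raceShareAlpha)) {
    raceShareAlpha <- if (identical(races, .defaultRaces))
      c(0.5, 0.8, 1.5, 2.0, 10.0) else rep(2, nr)
  }
  if (is.null(ageWeights)) {
    ageWeights <- if (identical(ageBands, .defaultAgeBands))
      c(0.105, 0.11, 0.115, 0.115, 0.115, 0.115, 0.115, 0.11, 0.10)
    else rep(1, length(ageBands))
  }
  if (is.null(raceOffsets)) {
    raceOffsets <- if (identical(races, .defaultRaces))
      c(AIAN = 0.9, Asian = -0.35, Black = 0.85, Latina = -0.05, White = 0)
    else setNames(rep(0, nr), races)
  }
  if (is.null(ageCurve)) {
    ageCurve <- if (identical(ageBands, .defaultAgeBands))
      c(-2.0, -0.5, -0.1, 0, 0.15, 0.45, 0.8, -1.0, -2.5)
    else rep(0, length(ageBands))
  }
  if (is.null(raceTimeSlopes)) raceTimeSlopes <- rep(timeSlope, nr)
  if (is.null(misclassMatrix)) {
    misclassMatrix <- if (identical(races, .defaultRaces)) .defaultMisclass()
    else diag(nr)
  }
  new("SimConfig",
      nUnits = as.integer(nUnits), races = races,
      ageBands = as.character(ageBands), years = as.integer(years),
      popLognormalParams = as.numeric(popLognormalParams),
      raceShareAlpha = as.numeric(raceShareAlpha),
      ageWeights = as.numeric(ageWeights) / sum(ageWeights),
      popDriftMean = popDriftMean, popDriftSd = popDriftSd,
      baselineLogRate = baselineLogRate,
      raceOffsets = setNames(as.numeric(raceOffsets), races),
      ageCurve = as.numeric(ageCurve),
      timeSlope = timeSlope,
      raceTimeSlopes = setNames(as.numeric(raceTimeSlopes), races),
      covariateBetas = covariateBetas,
      spatialSd = spatialSd, spatialRho = spatialRho,
      misclassMatrix = misclassMatrix,
      garbageFraction = garbageFraction, seed = as.integer(seed))
}

.configLevels <- function(config) {
  list(units = sprintf("U%04d", seq_len(config@nUnits)),
       races = config@races, ageBands = config@ageBands,
       years = config@years)
}

#' Generate stratified population denominators
#'
#' Unit totals are log-normal (spanning orders of magnitude so that some
#' units fall below the display-masking threshold), split across races by a
#' Dirichlet draw and across age bands by fixed weights, and drift smoothly
#' over years by a unit-specific multiplicative growth rate. Deaths are set
#' to zero; the result is a denominator table.
#'
#' @param config a [SimConfig-class].
#' @return A [StratifiedCounts-class] with `deaths = 0` and positive
#'   `population` for every stratum.
#' @examples
#' pop <- generatePopulation(simConfig(nUnits = 5, seed = 7))
#' range(population(pop))
#' @export
generatePopulation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(.childSeed(config@seed, 1L))
  lv <- .configLevels(config)
  n <- config@nUnits; nr <- length(lv$races)
  totals <- rlnorm(n, config@popLognormalParams[1L],
                   config@popLognormalParams[2L])
  # Dirichlet race shares via normalized gammas
  shares <- matrix(rgamma(n * nr, shape = rep(config@raceShareAlpha,
                                              each = n)), n, nr)
  if (nr == 1L) shares[] <- 1 else shares <- shares / rowSums(shares)
  growth <- 1 + rnorm(n, config@popDriftMean, config@popDriftSd)
  growth <- pmax(growth, 0.9)
  g <- .strataGrid(lv)
  iu <- match(g$unit, lv$units)
  ir <- match(g$race, lv$races)
  ia <- match(g$ageBand, lv$ageBands)
  it <- g$year - min(lv$years)
  pop <- totals[iu] * shares[cbind(iu, ir)] * config@ageWeights[ia] *
    growth[iu]^it
  df <- as.data.frame(g)
  df$deaths <- 0
  df$population <- pop
  StratifiedCounts(df, levels = lv)
}

#' Lattice adjacency for synthetic counties
#'
#' Arranges units on a near-square grid with rook neighbours; always
#' connected, which the CAR construction requires.
#'
#' @param units character vector of unit identifiers (or a [SimConfig-class]).
#' @return data.frame with columns `from`, `to` (undirected edge list).
#' @examples
#' gridAdjacency(sprintf("U%04d", 1:6))
#' @export
gridAdjacency <- function(units) {
  if (is(units, "SimConfig")) units <- .configLevels(units)$units
  n <- length(units)
  if (n == 1L) return(data.frame(from = character(), to = character()))
  ncolg <- ceiling(sqrt(n))
  row <- (seq_len(n) - 1L) %/% ncolg
  col <- (seq_len(n) - 1L) %% ncolg
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    right <- which(row == row[i] & col == col[i] + 1L)
    down <- which(row == row[i] + 1L & col == col[i])
    from <- c(from, rep(i, length(right) + length(down)))
    to <- c(to, right, down)
  }
  data.frame(from = units[from], to = units[to], stringsAsFactors = FALSE)
}

# CAR precision D - rho*A over the given units; errors if disconnected.
.carStructure <- function(adjacency, units, rho) {
  bad <- setdiff(unique(c(adjacency$from, adjacency$to)), units)
  if (length(bad))
    .stopf("adjacency references unknown units: %s",
           paste(utils::head(bad, 5L), collapse = ", "))
  n <- length(units)
  if (n == 1L)
    return(list(Q = Matrix::Matrix(0, 1, 1, sparse = TRUE), degrees = 0))
  gr <- igraph::graph_from_data_frame(
    adjacency[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = units))
  if (igraph::components(gr)$no > 1L)
    .stopf("adjacency graph is disconnected; spatial effects are undefined up to components")
  A <- igraph::as_adjacency_matrix(gr, sparse = TRUE)
  A <- A[units, units]
  A@x[] <- 1  # collapse any multi-edges
  d <- Matrix::rowSums(A)
  list(Q = Matrix::Diagonal(x = d) - rho * A, degrees = as.numeric(d))
}

# Sample centered spatial effects with SD exactly `sd` from a proper CAR.
.sampleSpatial <- function(adjacency, units, rho, sd) {
  n <- length(units)
  if (sd == 0 || n < 2L) return(setNames(rep(0, n), units))
  Q <- .carStructure(adjacency, units, rho)$Q
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Q), perm = TRUE, LDL = FALSE)
  z <- rnorm(n)
  u <- as.numeric(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                                system = "Pt"))
  u <- u - mean(u)
  s <- stats::sd(u)
  if (s > 0) u <- u * (sd / s)
  setNames(u, units)
}

#' Generate true stratified mortality rates
#'
#' The log true rate is linear: baseline + race offset + age effect +
#' race-specific time slope x (year - first year) + covariate effects +
#' centered CAR spatial effect. Covariates ("income" at unit level,
#' "poverty" at unit-by-race level) are drawn standard normal and
#' standardized to mean 0, SD 1.
#'
#' @param config a [SimConfig-class].
#' @param adjacency edge-list data.frame (`from`, `to`) over the config's
#'   units; must be connected.
#' @return A [SyntheticTruth-class].
#' @examples
#' cfg <- simConfig(nUnits = 4, seed = 2)
#' truth <- generateTrueRates(cfg, gridAdjacency(cfg))
#' range(truth@trueRate)
#' @export
generateTrueRates <- function(config, adjacency) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(.childSeed(config@seed, 2L))
  lv <- .configLevels(config)
  n <- config@nUnits
  u <- .sampleSpatial(adjacency, lv$units, config@spatialRho,
                      config@spatialSd)
  income <- rnorm(n)
  income <- as.numeric(scale(income))
  if (n == 1L) income <- 0
  pov <- matrix(rnorm(n * length(lv$races)), n, length(lv$races))
  pov <- if (length(pov) > 1L) matrix(as.numeric(scale(as.vector(pov))),
                                      n, length(lv$races)) else pov * 0
  g <- .strataGrid(lv)
  iu <- match(g$unit, lv$units)
  ir <- match(g$race, lv$races)
  ia <- match(g$ageBand, lv$ageBands)
  it <- g$year - min(lv$years)
  b <- config@covariateBetas
  bIncome <- if ("income" %in% names(b)) b[["income"]] else 0
  bPoverty <- if ("poverty" %in% names(b)) b[["poverty"]] else 0
  eta <- config@baselineLogRate +
    config@raceOffsets[ir] +
    config@ageCurve[ia] +
    config@raceTimeSlopes[ir] * it +
    bIncome * income[iu] +
    bPoverty * pov[cbind(iu, ir)] +
    u[iu]
  covariates <- list(
    unit = data.frame(unit = lv$units, income = income,
                      stringsAsFactors = FALSE),
    unitRace = data.frame(unit = rep(lv$units, length(lv$races)),
                          race = rep(lv$races, each = n),
                          poverty = as.vector(pov),
                          stringsAsFactors = FALSE))
  new("SyntheticTruth", strata = g, trueRate = as.numeric(exp(eta)),
      spatialEffects = u - mean(u), covariates = covariates,
      config = config)
}

#' Simulate Poisson death counts
#'
#' Deaths are independent Poisson with mean `population x trueRate` per
#' stratum.
#'
#' @param truth a [SyntheticTruth-class].
#' @param population a [StratifiedCounts-class] aligned with the truth.
#' @param seed integer seed.
#' @return A [StratifiedCounts-class] with simulated `deaths`.
#' @export
simulateDeaths <- function(truth, population, seed) {
  stopifnot(is(truth, "SyntheticTruth"), is(population, "StratifiedCounts"))
  .assertAligned(truth@strata, population, "truth and population")
  set.seed(.childSeed(seed, 3L))
  mu <- population(population) * truth@trueRate
  .setCol(population, "deaths", rpois(length(mu), mu))
}

#' Misreport race/ethnicity on death certificates
#'
#' Each stratum's deaths are reassigned to a certificate race by a single
#' multinomial draw with probabilities given by the row of `matrix` for the
#' stratum's true race. All-race totals per (unit, ageBand, year) cell are
#' conserved exactly; this is the mechanism that makes self-report to
#' certificate classification ratios differ from 1.
#'
#' @param deathsTab a [StratifiedCounts-class] of true-race deaths.
#' @param matrix row-stochastic race-by-race matrix
#'   P(certificate race = column | true race = row), rows/columns in the
#'   table's race order.
#' @param seed integer seed.
#' @return A [StratifiedCounts-class] of certificate-race deaths.
#' @export
misreportCertificateRace <- function(deathsTab, matrix, seed) {
  stopifnot(is(deathsTab, "StratifiedCounts"))
  lv <- strataLevels(deathsTab)
  nr <- length(lv$races)
  if (!is.numeric(matrix) || nrow(matrix) != nr || ncol(matrix) != nr ||
      any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-8))
    .stopf("misclassification matrix must be %d x %d row-stochastic", nr, nr)
  set.seed(.childSeed(seed, 4L))
  d <- deathsTab$deaths
  if (any(d != round(d))) .stopf("deaths must be integer counts to misreport")
  ir <- match(deathsTab$race, lv$races)
  # Certificate-race allocation via sequential binomial thinning, vectorized
  # over strata within each true race.
  alloc <- base::matrix(0, nrow(deathsTab), nr)
  for (r in seq_len(nr)) {
    rows <- which(ir == r)
    remaining <- d[rows]
    pLeft <- 1
    for (cc in seq_len(nr - 1L)) {
      p <- matrix[r, cc] / pLeft
      p <- min(max(p, 0), 1)
      x <- rbinom(length(rows), remaining, p)
      alloc[rows, cc] <- x
      remaining <- remaining - x
      pLeft <- pLeft - matrix[r, cc]
      if (pLeft <= 0) break
    }
    alloc[rows, nr] <- remaining
  }
  # Accumulate into certificate-race strata: the row for certificate race c
  # in the same (unit, ageBand, year) cell.
  newDeaths <- numeric(nrow(deathsTab))
  for (cc in seq_len(nr)) {
    contrib <- rowsum(alloc[, cc], .strataKey(deathsTab$unit, "x",
                                              deathsTab$ageBand,
                                              deathsTab$year),
                      reorder = FALSE)
    # rows of certificate race cc, in the same cell order as `contrib`
    target <- which(ir == cc)
    key <- .strataKey(deathsTab$unit[target], "x",
                      deathsTab$ageBand[target], deathsTab$year[target])
    newDeaths[target] <- contrib[match(key, rownames(contrib)), 1L]
  }
  .setCol(deathsTab, "deaths", newDeaths)
}

#' Split deaths into specific and garbage-coded tables
#'
#' Each death is independently flagged as garbage-coded with probability
#' `fraction`; the two returned tables sum exactly to the input.
#'
#' @param deathsTab a [StratifiedCounts-class].
#' @param fraction garbage probability in `[0, 1)`.
#' @param seed integer seed.
#' @return List with elements `specific` and `garbage`, both
#'   [StratifiedCounts-class].
#' @export
injectGarbageCodes <- function(deathsTab, fraction, seed) {
  stopifnot(is(deathsTab, "StratifiedCounts"))
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    .stopf("garbage fraction must lie in [0, 1); got %s", format(fraction))
  d <- deathsTab$deaths
  if (any(d != round(d))) .stopf("deaths must be integer counts")
  set.seed(.childSeed(seed, 5L))
  g <- rbinom(length(d), d, fraction)
  list(specific = .setCol(deathsTab, "deaths", d - g),
       garbage = .setCol(deathsTab, "deaths", g))
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: population, truth, Poisson deaths, certificate-race
#' misreporting, and garbage-code injection, all from one config and its
#' master seed.
#'
#' @param config a [SimConfig-class].
#' @param adjacency optional edge list; defaults to [gridAdjacency()].
#' @return List with `population`, `truth`, `trueDeaths`, `certDeaths`,
#'   `specific`, `garbage`, `adjacency`.
#' @examples
#' sim <- simulateStudy(simConfig(nUnits = 6, years = 2000:2002, seed = 3))
#' sum(deaths(sim$trueDeaths)) == sum(deaths(sim$certDeaths))
#' @export
simulateStudy <- function(config, adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- gridAdjacency(config)
  population <- generatePopulation(config)
  truth <- generateTrueRates(config, adjacency)
  trueDeaths <- simulateDeaths(truth, population, config@seed)
  certDeaths <- misreportCertificateRace(trueDeaths, config@misclassMatrix,
                                         config@seed)
  parts <- injectGarbageCodes(certDeaths, config@garbageFraction,
                              config@seed)
  list(population = population, truth = truth, trueDeaths = trueDeaths,
       certDeaths = certDeaths, specific = parts$specific,
       garbage = parts$garbage, adjacency = adjacency)
}
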