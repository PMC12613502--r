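test_that("degenerate config gives exactly the specified population", {
  cfg <- simConfig(nUnits = 1, races = "White", ageBands = "15-19",
                   years = 2000L, popLognormalParams = c(log(1000), 0),
                   seed = 1)
  pop <- generatePopulation(cfg)
  expect_equal(population(pop), 1000)
  expect_equal(deaths(pop), 0)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- smallConfig(seed = 42)
  p1 <- generatePopulation(cfg)
  p2 <- generatePopulation(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  adj <- gridAdjacency(cfg)
  t1 <- generateTrueRates(cfg, adj)
  t2 <- generateTrueRates(cfg, adj)
  expect_identical(t1@trueRate, t2@trueRate)
  d1 <- simulateDeaths(t1, p1, 42)
  d2 <- simulateDeaths(t1, p1, 42)
  expect_identical(deaths(d1), deaths(d2))
})

test_that("default populations span small and large counties", {
  pop <- generatePopulation(simConfig(seed = 1))
  nYears <- length(strataLevels(pop)$years)
  unitMean <- rowsum(population(pop), pop$unit)[, 1L] / nYears
  expect_gt(max(unitMean) / min(unitMean), 100)  # two orders of magnitude
  # all-sex population approximated as twice the female person-years
  expect_gt(sum(2 * unitMean < 1000), 0)
  expect_gt(sum(2 * unitMean > 100000), 0)
})

test_that("null model yields constant rates and time slope doubles them", {
  base <- list(nUnits = 4L, races = c("A", "B"), ageBands = c("15-19", "20-24"),
               years = 2000:2019, covariateBetas = c(income = 0, poverty = 0),
               spatialSd = 0, seed = 3)
  cfg0 <- do.call(simConfig, c(base, list(timeSlope = 0,
                                          baselineLogRate = log(2e-5))))
  tr0 <- generateTrueRates(cfg0, gridAdjacency(cfg0))
  expect_equal(unique(tr0@trueRate), 2e-5)
  cfg1 <- do.call(simConfig, c(base, list(timeSlope = log(2) / 19,
                                          baselineLogRate = log(2e-5))))
  tr1 <- generateTrueRates(cfg1, gridAdjacency(cfg1))
  r2000 <- tr1@trueRate[tr1@strata$year == 2000]
  r2019 <- tr1@trueRate[tr1@strata$year == 2019]
  expect_equal(r2019, 2 * r2000, tolerance = 1e-12)
})

test_that("spatial effects correlate more between neighbours", {
  units <- sprintf("U%04d", 1:3)
  adj <- chainAdjacency(units)   # U1 - U2 - U3
  u <- replicate(500, {
    cfg <- simConfig(nUnits = 3, races = "White", ageBands = "15-19",
                     years = 2000L, spatialSd = 1, spatialRho = 0.99,
                     seed = sample.int(1e6, 1))
    generateTrueRates(cfg, adj)@spatialEffects
  })
  expect_gt(cor(u[1, ], u[2, ]), cor(u[1, ], u[3, ]))
})

test_that("death counts follow Poisson moments", {
  cfg <- simConfig(nUnits = 1, races = "White", ageBands = "15-19",
                   years = 2000L, popLognormalParams = c(log(1e7), 0),
                   baselineLogRate = log(2e-5), timeSlope = 0,
                   spatialSd = 0, covariateBetas = c(income = 0, poverty = 0),
                   seed = 5)
  pop <- generatePopulation(cfg)
  truth <- generateTrueRates(cfg, gridAdjacency(cfg))
  expect_equal(unique(truth@trueRate), 2e-5)
  set.seed(99)
  counts <- vapply(sample.int(1e6, 1000), function(s)
    deaths(simulateDeaths(truth, pop, s)), 0)
  # mean 200, SE of the empirical mean sqrt(200/1000)
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200 / 1000))
})

test_that("zero rates give zero deaths", {
  cfg <- simConfig(nUnits = 2, races = "White", ageBands = "15-19",
                   years = 2000L, seed = 2)
  pop <- generatePopulation(cfg)
  truth <- generateTrueRates(cfg, gridAdjacency(cfg))
  truth@trueRate[] <- 1e-300   # effectively zero
  expect_equal(sum(deaths(simulateDeaths(truth, pop, 1))), 0)
})

test_that("certificate misreporting follows multinomial moments and conserves totals", {
  counts <- makeCounts(races = c("A", "B"), deaths = c(1000, 0))
  M <- rbind(c(0.8, 0.2), c(0, 1))
  # identity leaves the table unchanged
  same <- misreportCertificateRace(counts, diag(2), 1)
  expect_identical(deaths(same), deaths(counts))
  set.seed(11)
  certA <- vapply(sample.int(1e6, 1000), function(s)
    deaths(misreportCertificateRace(counts, M, s))[1L], 0)
  # E = 800, SE of mean = sqrt(1000*0.8*0.2)/sqrt(1000)
  expect_lt(abs(mean(certA) - 800), 3 * sqrt(1000 * 0.8 * 0.2 / 1000))
  # conservation per cell for an arbitrary matrix and seed
  counts2 <- makeCounts(units = c("U1", "U2"), races = c("A", "B"),
                        years = 2000:2001, deaths = c(5, 17, 3, 40, 0, 9, 2, 1))
  M2 <- rbind(c(0.5, 0.5), c(0.3, 0.7))
  cert2 <- misreportCertificateRace(counts2, M2, 77)
  cell <- function(x) rowsum(deaths(x), paste(x$unit, x$ageBand, x$year))
  expect_equal(cell(cert2), cell(counts2))
  expect_error(misreportCertificateRace(counts, rbind(c(0.5, 0.4), c(0, 1)), 1),
               "row-stochastic")
})

test_that("garbage injection is binomial and conserves per-stratum sums", {
  counts <- makeCounts(units = c("U1", "U2"), deaths = c(6000, 4000))
  parts0 <- injectGarbageCodes(counts, 0, 1)
  expect_equal(sum(deaths(parts0$garbage)), 0)
  set.seed(13)
  tot <- vapply(sample.int(1e6, 400), function(s)
    sum(deaths(injectGarbageCodes(counts, 0.5, s)$garbage)), 0)
  expect_lt(abs(mean(tot) - 5000), 3 * sqrt(10000 * 0.25 / 400))
  parts <- injectGarbageCodes(counts, 0.3, 5)
  expect_equal(deaths(parts$specific) + deaths(parts$garbage), deaths(counts))
  expect_error(injectGarbageCodes(counts, 1, 1), "fraction")
})

test_that("empirical rates converge to the truth for large populations", {
  cfg <- simConfig(nUnits = 1, races = "White", ageBands = "15-19",
                   years = 2000L, popLognormalParams = c(log(1e8), 0),
                   baselineLogRate = log(2e-4), timeSlope = 0,
                   spatialSd = 0, covariateBetas = c(income = 0, poverty = 0),
                   seed = 8)
  pop <- generatePopulation(cfg)
  truth <- generateTrueRates(cfg, gridAdjacency(cfg))
  d <- simulateDeaths(truth, pop, 8)
  expect_lt(abs(deaths(d) / population(pop) / 2e-4 - 1), 0.01)
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(simConfig(garbageFraction = 1.2), "garbageFraction")
  expect_error(simConfig(spatialRho = 1), "spatialRho")
  expect_error(simConfig(misclassMatrix = matrix(1, 2, 2)), "misclassMatrix")
  expect_error(simConfig(races = c("A", "A")), "unique")
  cfg <- smallConfig()
  disc <- data.frame(from = "U0001", to = "U0002")  # disconnected for 12 units
  expect_error(generateTrueRates(cfg, disc), "disconnected")
})
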