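test_that("design bundle has the documented shape", {
  counts <- makeCounts(units = c("U1", "U2"), races = c("A", "B"),
                       years = 2000:2001, deaths = 1)
  covs <- list(unit = data.frame(unit = c("U1", "U2"), income = c(1, 5)))
  adj <- data.frame(from = "U1", to = "U2")
  des <- buildDesign(counts, covs, adj, modelSpec())
  expect_equal(nrow(des$X), 8L)   # 2 units x 2 races x 1 band x 2 years
  inc <- as.numeric(des$X[, "cov_income"])
  expect_equal(mean(inc), 0, tolerance = 1e-12)
  expect_equal(sd(inc), 1, tolerance = 1e-12)
  # chain of 3 units: CAR degrees (1, 2, 1)
  units3 <- c("U1", "U2", "U3")
  counts3 <- makeCounts(units = units3, deaths = 0:2)
  des3 <- buildDesign(counts3, NULL, chainAdjacency(units3), modelSpec())
  expect_equal(des3$car$degrees, c(1, 2, 1))
  expect_error(buildDesign(counts, list(unit = data.frame(unit = "U1",
                                                          income = 1)),
                           adj, modelSpec()), "missing")
})

test_that("single-stratum fit recovers the Poisson MLE and its spread", {
  counts <- makeCounts(deaths = 200, population = 1e7)
  fit <- fitModel(buildDesign(counts, NULL, NULL,
                              modelSpec(nDraws = 1000, seed = 2)))
  expect_true(fit@converged)
  dr <- drawPosterior(fit)
  m <- rateMatrix(dr)[1L, ]
  expect_equal(mean(m), 2.0, tolerance = 0.02)          # D/P per 100,000
  expect_lt(abs(sd(m) / (2 / sqrt(200)) - 1), 0.25)      # delta-method SE
  # determinism
  m2 <- rateMatrix(drawPosterior(fit))[1L, ]
  expect_identical(m, m2)
})

test_that("fitted rates agree with an unpenalized Poisson GLM oracle", {
  set.seed(31)
  counts <- makeCounts(units = "U1", races = c("A", "B"),
                       years = 2000:2004,
                       deaths = rpois(10, 50), population = 1e6)
  des <- buildDesign(counts, NULL, NULL, modelSpec(nDraws = 2, seed = 1))
  fit <- fitModel(des)
  rateFit <- exp(as.numeric(des$X %*% fit@theta))
  df <- as.data.frame(counts)
  df$yearC <- df$year - mean(2000:2004)
  g <- stats::glm(deaths ~ race * yearC + offset(log(population)),
                  family = stats::poisson(), data = df)
  expect_equal(rateFit, as.numeric(stats::fitted(g) / df$population),
               tolerance = 1e-3)
})

test_that("doubling deaths and person-years leaves rate estimates unchanged", {
  sim <- simulateStudy(smallConfig(seed = 9, nUnits = 6))
  cert <- redistributeGarbage(sim$specific, sim$garbage)
  spec <- modelSpec(nDraws = 2, seed = 1)
  fit1 <- fitModel(buildDesign(cert, sim$truth@covariates, sim$adjacency,
                               spec))
  df2 <- as.data.frame(cert)
  df2$deaths <- df2$deaths * 2
  df2$population <- df2$population * 2
  cert2 <- StratifiedCounts(df2, levels = strataLevels(cert))
  fit2 <- fitModel(buildDesign(cert2, sim$truth@covariates, sim$adjacency,
                               spec))
  r1 <- exp(as.numeric(fit1@design$X %*% fit1@theta))
  r2 <- exp(as.numeric(fit2@design$X %*% fit2@theta))
  expect_equal(r1, r2, tolerance = 5e-3)
})

test_that("identical counts across units shrink unit effects toward zero", {
  units <- sprintf("U%04d", 1:9)
  counts <- makeCounts(units = units, years = 2000:2002,
                       deaths = 40, population = 1e6)
  fit <- fitModel(buildDesign(counts, NULL, gridAdjacency(units),
                              modelSpec(nDraws = 2, seed = 1)))
  u <- fit@theta[fit@design$blocks$unit]
  expect_lt(max(abs(u)), 1e-2)
})

test_that("the optional year random walk fits and stays identified", {
  sim <- simulateStudy(smallConfig(seed = 15, nUnits = 6))
  cert <- redistributeGarbage(sim$specific, sim$garbage)
  fit <- fitModel(buildDesign(cert, sim$truth@covariates, sim$adjacency,
                              modelSpec(nDraws = 2, seed = 1,
                                        useYearRW = TRUE)))
  expect_true(fit@converged)
  expect_true("year" %in% names(fit@hyper))
  expect_true(all(is.finite(fit@theta)))
})
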