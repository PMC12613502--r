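test_that("raking targets are additive expected death counts", {
  counts <- makeCounts(units = c("U1", "U2"), races = c("A", "B"),
                       deaths = 0, population = 1e5)
  # expected deaths: rate per 1e5 times person-years / 1e5
  dr <- makeDraws(counts, c(3, 7, 2, 8), nDraws = 2)
  tg <- buildTargets(dr, counts)
  expect_equal(as.numeric(tg@stageA[, 1L]), c(10, 10))   # cell totals 3+7, 2+8
  expect_equal(as.numeric(tg@stageB[, 1L]), c(5, 15))    # race margins 3+2, 7+8
  tg2 <- buildTargets(dr, counts)
  expect_identical(tg@stageA, tg2@stageA)                # determinism
  # one race: the cell target is that race's own expected deaths
  c1 <- makeCounts(units = c("U1", "U2"), deaths = 0, population = 1e5)
  d1 <- makeDraws(c1, c(4, 6))
  expect_equal(as.numeric(buildTargets(d1, c1)@stageA), c(4, 6))
  expect_error(buildTargets(dr, counts, drawIndex = 3L), "out of range")
})

test_that("ipfRake matches hand-worked and already-consistent tables", {
  # consistent table returns after one iteration, unchanged
  m <- rbind(c(1, 2), c(3, 4))
  res <- ipfRake(m, rowSums(m), colSums(m))
  expect_equal(res$table, m)
  expect_equal(res$iterations, 1L)
  # uniform 2x2 seed with rows (3,1), cols (2,2)
  res2 <- ipfRake(matrix(1, 2, 2), c(3, 1), c(2, 2))
  expect_equal(res2$table, rbind(c(1.5, 1.5), c(0.5, 0.5)),
               tolerance = 1e-8)
  # scale invariance of the seed table
  res3 <- ipfRake(matrix(17, 2, 2), c(3, 1), c(2, 2))
  expect_equal(res3$table, res2$table, tolerance = 1e-8)
  # infeasibility from blocking zeros raises, margins rescale with warning
  expect_error(ipfRake(rbind(c(0, 0), c(1, 1)), c(2, 2), c(2, 2)),
               "infeasible")
  expect_warning(ipfRake(matrix(1, 2, 2), c(2, 2), c(1, 1)), "rescaling")
})

test_that("ipfRake agrees with the loglin IPF oracle on random tables", {
  set.seed(123)
  for (i in 1:20) {
    m <- matrix(runif(12, 0.2, 3), 3, 4)
    r <- runif(3, 1, 5)
    cl <- runif(4, 1, 5)
    cl <- cl * sum(r) / sum(cl)
    mine <- ipfRake(m, r, cl, tolerance = 1e-12)$table
    target <- outer(r, cl) / sum(r)  # any table carrying the target margins
    oracle <- stats::loglin(target, margin = list(1, 2), start = m,
                            fit = TRUE, eps = 1e-12, iter = 200,
                            print = FALSE)$fit
    expect_equal(mine, oracle, tolerance = 1e-8)
  }
})

test_that("raking restores county totals and is a no-op without adjustment", {
  sim <- simulateStudy(smallConfig(seed = 33, nUnits = 8,
                                   baselineLogRate = log(2e-4)))
  cert <- redistributeGarbage(sim$specific, sim$garbage)
  fit <- fitModel(buildDesign(cert, sim$truth@covariates, sim$adjacency,
                              modelSpec(nDraws = 50, seed = 3)))
  dr <- drawPosterior(fit)
  pop <- population(sim$population)
  rd <- SummarizedExperiment::rowData(dr)
  cellKey <- paste(rd$unit, rd$ageBand, rd$year)
  cellTot <- function(x) rowsum(rateMatrix(x) * pop / 1e5, cellKey)
  # with real ratios: all-race cell totals return to pre-adjustment values
  ratios <- estimateRatios(sim$trueDeaths, cert)
  adj <- adjustDraws(dr, ratios)
  tg <- buildTargets(dr, sim$population, ratios = ratios)
  raked <- rakeAllDraws(adj, sim$population, tg)
  pre <- cellTot(dr); post <- cellTot(raked)
  expect_lt(max(abs(post - pre) / pmax(pre, 1e-300)), 1e-6)
  expect_true(all(rateMatrix(raked) > 0))
  # idempotence: raking an already-raked draw set moves nothing materially
  raked2 <- rakeAllDraws(raked, sim$population, tg)
  expect_lt(max(abs(rateMatrix(raked2) - rateMatrix(raked)) /
                  rateMatrix(raked)), 1e-6)
  # ratios of 1 upstream: raking is a no-op within tolerance
  ones <- classificationRatios(strataLevels(dr)$races,
                               rep(1, length(strataLevels(dr)$races)))
  tg1 <- buildTargets(dr, sim$population, ratios = ones)
  raked1 <- rakeAllDraws(dr, sim$population, tg1)
  expect_lt(max(abs(rateMatrix(raked1) - rateMatrix(dr)) / rateMatrix(dr)),
            1e-6)
})

test_that("single-draw targets select the matching column", {
  counts <- makeCounts(units = c("U1", "U2"), races = c("A", "B"),
                       deaths = 0, population = 1e5)
  m <- matrix(c(3, 7, 2, 8, 6, 14, 4, 16), nrow = 4)
  dr <- RateDraws(m, as.data.frame(counts)[, 1:4],
                  levels = strataLevels(counts))
  tg <- buildTargets(dr, counts, drawIndex = 2L)
  expect_equal(ncol(tg@stageA), 1L)
  expect_equal(as.numeric(tg@stageA[, 1L]), c(20, 20))
})
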