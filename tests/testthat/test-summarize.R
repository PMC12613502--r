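stdBands <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44")

test_that("age standardization reproduces closed-form weighted means", {
  counts <- makeCounts(ageBands = stdBands, deaths = 0)
  # identical rates in all bands: any weights give that rate back
  d1 <- makeDraws(counts, rep(2.5, 6), nDraws = 3)
  set.seed(4)
  w <- runif(6); std <- standardPopulation(w)
  expect_equal(as.numeric(rateMatrix(ageStandardize(d1, std))), rep(2.5, 3))
  # two effective bands via weights concentrated on them
  d2 <- makeDraws(counts, c(1, 3, 1e-12, 1e-12, 1e-12, 1e-12) + 1e-15)
  std5050 <- standardPopulation(c(1, 1, 1e-12, 1e-12, 1e-12, 1e-12))
  expect_equal(as.numeric(rateMatrix(ageStandardize(d2, std5050))), 2,
               tolerance = 1e-6)
  # weights (0.25, 0.75) on rates (4, ~0) give 1
  d3 <- makeDraws(counts, c(4, 1e-12, 1e-12, 1e-12, 1e-12, 1e-12))
  std2575 <- standardPopulation(c(0.25, 0.75, 1e-12, 1e-12, 1e-12, 1e-12))
  expect_equal(as.numeric(rateMatrix(ageStandardize(d3, std2575))), 1,
               tolerance = 1e-6)
  # bands outside 15-44 are ignored; a missing band errors by name
  cAll <- makeCounts(ageBands = c("10-14", stdBands, "45-49"), deaths = 0)
  dAll <- makeDraws(cAll, c(100, rep(2, 6), 100))
  expect_equal(as.numeric(rateMatrix(ageStandardize(dAll))), 2)
  cMiss <- makeCounts(ageBands = stdBands[-3], deaths = 0)
  expect_error(ageStandardize(makeDraws(cMiss, rep(1, 5))), "25-29")
  # standardized rates stay between the min and max band rates
  set.seed(9)
  r <- runif(6, 0.5, 5)
  dr <- makeDraws(counts, r)
  s <- as.numeric(rateMatrix(ageStandardize(dr, standardPopulation(runif(6)))))
  expect_gte(s, min(r)); expect_lte(s, max(r))
})

test_that("geographic aggregation is population-weighted", {
  counts <- makeCounts(units = c("U1", "U2"), deaths = 0,
                       population = c(9000, 1000))
  dr <- makeDraws(counts, c(1, 11), nDraws = 2)
  agg <- aggregateGeography(dr, counts)
  expect_equal(as.numeric(rateMatrix(agg)), c(2, 2))
  # equal populations: simple mean; single unit: identity
  countsEq <- makeCounts(units = c("U1", "U2"), deaths = 0, population = 500)
  expect_equal(as.numeric(rateMatrix(
    aggregateGeography(makeDraws(countsEq, c(1, 3)), countsEq))[1L]), 2)
  c1 <- makeCounts(units = "U1", deaths = 0)
  expect_equal(as.numeric(rateMatrix(
    aggregateGeography(makeDraws(c1, 7), c1))[1L]), 7)
})

test_that("point estimates and UIs follow the documented conventions", {
  counts <- makeCounts(deaths = 0)
  cst <- makeDraws(counts, 3, nDraws = 10)
  pu <- pointAndUI(cst)
  expect_equal(c(pu$pointEstimate, pu$uiLower, pu$uiUpper), c(3, 3, 3))
  seq1k <- RateDraws(matrix(1:1000, nrow = 1),
                     data.frame(unit = "U1", race = "A", ageBand = "15-19",
                                year = 2000L))
  pu2 <- pointAndUI(seq1k)
  expect_equal(pu2$pointEstimate, 500.5)
  expect_equal(pu2$uiLower, unname(quantile(1:1000, 0.025, type = 7)))
  expect_equal(pu2$uiUpper, unname(quantile(1:1000, 0.975, type = 7)))
  # ordering invariant on random draw vectors
  set.seed(101)
  m <- matrix(rlnorm(100 * 200), 100, 200)
  pr <- pointAndUI(RateDraws(m, data.frame(unit = sprintf("U%03d", 1:100),
                                           race = "A", year = 2000L)))
  expect_true(all(pr$uiLower <= pr$pointEstimate + 1e-12))
  expect_true(all(pr$pointEstimate <= pr$uiUpper + 1e-12))
  expect_error(pointAndUI(makeDraws(counts, 3, nDraws = 1)), "2 draws")
})

test_that("significance uses strict posterior-probability thresholds", {
  n <- 1000
  base <- rep(1, n)
  allPos <- base + 1
  expect_true(compareSignificance(allPos, base)$significant)
  expect_equal(compareSignificance(allPos, base)$posteriorProbability, 1)
  sym <- c(rep(2, n / 2), rep(0.5, n / 2))
  expect_false(compareSignificance(sym, base)$significant)
  expect_equal(compareSignificance(sym, base)$posteriorProbability, 0.5)
  mk <- function(k) base + c(rep(1, k), rep(-1, n - k))  # k positive diffs
  expect_false(compareSignificance(mk(25), base)$significant)   # p = 0.025
  expect_false(compareSignificance(mk(975), base)$significant)  # p = 0.975
  expect_true(compareSignificance(mk(980), base)$significant)   # p = 0.98
  expect_true(compareSignificance(mk(24), base)$significant)    # p = 0.024
  # symmetry: swapping the sets maps p to 1 - p with the same flag
  set.seed(7)
  a <- rlnorm(n); b <- rlnorm(n)
  f <- compareSignificance(a, b); g <- compareSignificance(b, a)
  expect_equal(f$posteriorProbability + g$posteriorProbability, 1)
  expect_equal(f$significant, g$significant)
  expect_error(compareSignificance(a, b[-1]), "aligned")
})

test_that("percent change reproduces printed-rate arithmetic", {
  n <- 1000
  # national rates 0.8 -> 1.7 per 100,000
  pc <- percentChange(rep(0.8, n), rep(1.7, n))
  expect_equal(pc$percentChange, 112.5)
  # AIAN rates 1.3 -> 3.5
  pc2 <- percentChange(rep(1.3, n), rep(3.5, n))
  expect_equal(pc2$percentChange, 100 * (3.5 - 1.3) / 1.3, tolerance = 1e-12)
  # no change
  expect_equal(percentChange(rep(2, n), rep(2, n))$percentChange, 0)
  # draw-wise and point-wise variants agree on constant draws
  expect_equal(percentChange(rep(0.8, n), rep(1.7, n),
                             method = "pointwise")$percentChange, 112.5)
  expect_error(percentChange(c(0, 1), c(1, 2)), "positive")
})

test_that("masking is a strict all-years rule at the population threshold", {
  counts <- makeCounts(units = c("U1", "U2"), years = 2000:2002, deaths = 0,
                       population = rep(c(999, 1000), each = 3))
  summ <- S4Vectors::DataFrame(unit = rep(c("U1", "U2"), each = 3),
                               race = "White", year = rep(2000:2002, 2),
                               pointEstimate = 1:6 / 1)
  out <- applyMask(summ, counts, threshold = 1000)
  expect_equal(out$masked, rep(c(TRUE, FALSE), each = 3))  # 999 masked, 1000 not
  expect_true(all(is.na(out$pointEstimate[out$masked])))
  expect_true(all(!is.na(out$pointEstimate[!out$masked])))
  # masking applies to all years jointly even if single years dip
  cVar <- makeCounts(units = "U1", years = 2000:2001, deaths = 0,
                     population = c(500, 2500))   # mean 1500
  sVar <- S4Vectors::DataFrame(unit = "U1", race = "White",
                               year = 2000:2001, pointEstimate = c(1, 2))
  expect_equal(applyMask(sVar, cVar)$masked, c(FALSE, FALSE))
  expect_error(applyMask(S4Vectors::DataFrame(unit = "U9", race = "White",
                                              pointEstimate = 1),
                         counts), "missing")
})

test_that("county-change bookkeeping counts, rounds, and summarizes", {
  ch <- data.frame(percentChange = c(10, 20, 30, 40),
                   significant = c(TRUE, TRUE, FALSE, FALSE))
  s <- countyChangeSummary(ch)
  expect_equal(s$nUnits, 4L)
  expect_equal(s$medianChange, 25)
  expect_equal(c(s$iqrLower, s$iqrUpper), c(17.5, 32.5))
  expect_equal(s$pctIncrease, 100)
  expect_equal(s$pctSignificantIncrease, 50)
  neg <- data.frame(percentChange = c(-5, -10), significant = c(TRUE, FALSE))
  expect_equal(countyChangeSummary(neg)$pctIncrease, 0)
  masked <- data.frame(percentChange = c(10, -99), significant = TRUE,
                       masked = c(FALSE, TRUE))
  expect_equal(countyChangeSummary(masked)$nUnits, 1L)
  expect_error(countyChangeSummary(masked[masked$percentChange > 50, ]),
               "no unmasked")
})

test_that("rankings are deterministic with identifier tie-breaks", {
  s <- data.frame(unit = c("C", "A", "B", "D"),
                  pointEstimate = c(5, 5, 9, 1),
                  masked = c(FALSE, FALSE, FALSE, FALSE))
  top <- rankUnits(s, 3)
  expect_equal(top$unit, c("B", "A", "C"))   # tie between A and C: id order
  s$masked[s$unit == "B"] <- TRUE
  expect_false("B" %in% rankUnits(s, 3)$unit)
  expect_warning(all4 <- rankUnits(s, 10), "exceeds")
  expect_equal(nrow(all4), 3L)
})

test_that("rounding is half-up on the display scale only", {
  expect_equal(roundHalfUp(99.44787, 1), 99.4)
  expect_equal(roundHalfUp(86.05, 1), 86.1)
  expect_equal(roundHalfUp(0.25, 1), 0.3)   # base round() would give 0.2
})
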