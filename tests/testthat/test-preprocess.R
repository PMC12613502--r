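test_that("identity mapping leaves a table unchanged and merging is additive", {
  counts <- makeCounts(units = c("A", "B", "C", "D", "E"),
                       deaths = 1:5, population = c(10, 20, 30, 40, 50))
  idmap <- data.frame(county = c("A", "B", "C", "D", "E"),
                      unit = c("A", "B", "C", "D", "E"))
  expect_equal(as.data.frame(mergeCounties(counts, idmap)),
               as.data.frame(counts))
  map <- data.frame(county = c("A", "B", "C", "D", "E"),
                    unit = c("AB", "AB", "C", "D", "E"))
  merged <- mergeCounties(counts, map)
  expect_equal(length(strataLevels(merged)$units), 4L)
  expect_equal(deaths(merged)[merged$unit == "AB"], 1 + 2)
  expect_equal(population(merged)[merged$unit == "AB"], 30)
  expect_equal(sum(deaths(merged)), sum(deaths(counts)))
  expect_error(mergeCounties(counts, map[-1, ]), "missing from mapping")
})

test_that("a 3143-county mapping collapses to 3110 stable units", {
  counties <- sprintf("C%04d", 1:3143)
  # merge the first 66 counties pairwise into 33 combined units
  unit <- counties
  unit[seq(2, 66, by = 2)] <- unit[seq(1, 66, by = 2)]
  counts <- makeCounts(units = counties, deaths = 1, population = 10)
  merged <- mergeCounties(counts, data.frame(county = counties, unit = unit))
  expect_equal(length(strataLevels(merged)$units), 3110L)
  expect_equal(sum(deaths(merged)), 3143)
})

test_that("garbage redistribution is proportional with a population fallback", {
  spec <- makeCounts(races = c("A", "B"), deaths = c(30, 70),
                     population = c(5000, 5000))
  garb <- makeCounts(races = c("A", "B"), deaths = c(4, 6),
                     population = c(5000, 5000))
  out <- redistributeGarbage(spec, garb)
  expect_equal(deaths(out), c(33, 77))
  # zero specific deaths: split by population shares
  spec0 <- makeCounts(races = c("A", "B"), deaths = c(0, 0),
                      population = c(2000, 8000))
  garb0 <- makeCounts(races = c("A", "B"), deaths = c(5, 0),
                      population = c(2000, 8000))
  out0 <- redistributeGarbage(spec0, garb0)
  expect_equal(deaths(out0), c(1, 4))
  # zero garbage is the identity
  zero <- makeCounts(races = c("A", "B"), deaths = 0)
  spec2 <- makeCounts(races = c("A", "B"), deaths = c(12, 3))
  expect_equal(deaths(redistributeGarbage(spec2, zero)), c(12, 3))
})

test_that("redistribution conserves totals on simulated data", {
  sim <- simulateStudy(smallConfig(seed = 21))
  out <- redistributeGarbage(sim$specific, sim$garbage)
  expect_lt(abs(sum(deaths(out)) - sum(deaths(sim$certDeaths))), 1e-9)
  cell <- function(x) rowsum(deaths(x), paste(x$unit, x$ageBand, x$year))
  expect_equal(cell(out), cell(sim$certDeaths), tolerance = 1e-12)
})

test_that("validateStrata rectangularizes and rejects bad tables", {
  df <- data.frame(unit = "U1", race = c("A", "A", "B"),
                   ageBand = "15-19", year = c(2000L, 2001L, 2000L),
                   deaths = c(1, 2, 3), population = 100)
  # missing (B, 2001) cell gets an explicit zero
  out <- validateStrata(df, fillPopulation = 100)
  expect_equal(nrow(out), 4L)
  expect_equal(deaths(out)[out$race == "B" & out$year == 2001], 0)
  expect_error(validateStrata(df), "missing strata")
  expect_error(validateStrata(rbind(df, df[1, ]), fillPopulation = 100),
               "duplicated keys")
  bad <- df; bad$deaths[1] <- -1
  expect_error(validateStrata(bad, fillPopulation = 100), "negative deaths")
  # a clean rectangular table passes through unchanged
  clean <- makeCounts(units = c("U1", "U2"), deaths = c(1, 2))
  expect_equal(as.data.frame(validateStrata(clean)), as.data.frame(clean))
})
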