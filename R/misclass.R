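#' Estimate race classification ratios from linked tables
#'
#' The classification ratio for a population is the number of deaths
#' identified by self-report divided by the number identified on the death
#' certificate, aggregated over the requested level. Cells with a zero
#' certificate denominator get an `NA` ratio and a warning (never a silent
#' default).
#'
#' @param trueDeaths a [StratifiedCounts-class] of self-report (true-race)
#'   deaths.
#' @param certDeaths an aligned [StratifiedCounts-class] of
#'   certificate-race deaths.
#' @param by aggregation level: `"race"` (default) or
#'   `c("race", "ageBand")`.
#' @return A [ClassificationRatios-class].
#' @examples
#' # two races, certificate counts (800, 1200) vs self-report (1000, 1000)
#' df <- expand.grid(unit = "U1", race = c("A", "B"), ageBand = "15-19",
#'                   year = 2000L, stringsAsFactors = FALSE)
#' df$population <- 1e6
#' tr <- df; tr$deaths <- c(1000, 1000)
#' ct <- df; ct$deaths <- c(800, 1200)
#' ratioTable(estimateRatios(StratifiedCounts(tr), StratifiedCounts(ct)))
#' @export
estimateRatios <- function(trueDeaths, certDeaths, by = "race") {
  stopifnot(is(trueDeaths, "StratifiedCounts"),
            is(certDeaths, "StratifiedCounts"))
  .assertAligned(trueDeaths, certDeaths, "self-report and certificate")
  by <- match.arg(by, c("race", "ageBand"), several.ok = TRUE)
  key <- do.call(paste, c(lapply(by, function(f) trueDeaths[[f]]),
                          list(sep = "\r")))
  kf <- factor(key, levels = unique(key))
  num <- rowsum(trueDeaths$deaths, kf)[, 1L]
  den <- rowsum(certDeaths$deaths, kf)[, 1L]
  ratio <- ifelse(den > 0 & num > 0, num / den, NA_real_)
  if (anyNA(ratio))
    warning(sprintf("zero self-report or certificate deaths for %d cell(s); ratio undefined (NA): %s",
                    sum(is.na(ratio)),
                    paste(gsub("\r", "/", names(num)[is.na(ratio)]),
                          collapse = ", ")), call. = FALSE)
  parts <- do.call(rbind, strsplit(levels(kf), "\r", fixed = TRUE))
  tab <- S4Vectors::DataFrame(race = parts[, 1L])
  if ("ageBand" %in% by) tab$ageBand <- parts[, 2L]
  tab$ratio <- as.numeric(ratio)
  new("ClassificationRatios", table = tab)
}

#' Adjust rate draws for certificate-race misreporting
#'
#' Multiplies every draw of every stratum by the classification ratio of
#' its race (and age band, when the ratio table is age-specific). The
#' adjustment is deterministic and draw-wise, so draw alignment and
#' positivity are preserved. Race-specific totals change, which generally
#' breaks all-race county totals; stage-3 raking repairs exactly that.
#'
#' @param draws a [RateDraws-class].
#' @param ratios a [ClassificationRatios-class] covering every race in the
#'   draws.
#' @param missing policy for races without a ratio: `"error"` (default) or
#'   `"one"` (explicit default ratio 1 with a warning).
#' @return A [RateDraws-class] of adjusted draws.
#' @export
adjustDraws <- function(draws, ratios, missing = c("error", "one")) {
  stopifnot(is(draws, "RateDraws"), is(ratios, "ClassificationRatios"))
  missing <- match.arg(missing)
  tab <- ratioTable(ratios)
  rd <- rowData(draws)
  if ("ageBand" %in% colnames(tab)) {
    if (!"ageBand" %in% colnames(rd))
      .stopf("age-specific ratios but draws carry no ageBand")
    key <- paste(rd$race, rd$ageBand, sep = "\r")
    tkey <- paste(tab$race, tab$ageBand, sep = "\r")
  } else {
    key <- as.character(rd$race)
    tkey <- as.character(tab$race)
  }
  r <- tab$ratio[match(key, tkey)]
  bad <- is.na(r)
  if (any(bad)) {
    races <- unique(rd$race[bad])
    if (missing == "error")
      .stopf("no classification ratio for: %s",
             paste(races, collapse = ", "))
    warning(sprintf("no classification ratio for %s; defaulting to 1",
                    paste(races, collapse = ", ")), call. = FALSE)
    r[bad] <- 1
  }
  .gcLight()
  m <- rateMatrix(draws) * r   # recycles down columns = row-wise scaling
  RateDraws(m, rd, levels = strataLevels(draws))
}
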