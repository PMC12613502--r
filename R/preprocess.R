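#' Merge counties into temporally stable units
#'
#' County boundaries change over time; analyses therefore pool counties
#' into stable geographical units before modeling. Deaths and person-years
#' are summed within each stable unit per (race, ageBand, year); grand
#' totals are conserved exactly.
#'
#' @param counts a [StratifiedCounts-class] keyed by county.
#' @param mapping data.frame with columns `county`, `unit` mapping every
#'   input county onto its stable unit (surjective; identity rows allowed).
#' @return A [StratifiedCounts-class] keyed by stable unit.
#' @examples
#' df <- expand.grid(unit = c("A", "B"), race = "White", ageBand = "15-19",
#'                   year = 2000L, stringsAsFactors = FALSE)
#' df$deaths <- c(2, 3); df$population <- c(100, 200)
#' x <- StratifiedCounts(df)
#' merged <- mergeCounties(x, data.frame(county = c("A", "B"),
#'                                       unit = c("AB", "AB")))
#' deaths(merged)  # 5
#' @export
mergeCounties <- function(counts, mapping) {
  stopifnot(is(counts, "StratifiedCounts"))
  if (!all(c("county", "unit") %in% colnames(mapping)))
    .stopf("mapping needs columns county and unit")
  lv <- strataLevels(counts)
  unmapped <- setdiff(lv$units, mapping$county)
  if (length(unmapped))
    .stopf("counties missing from mapping: %s%s",
           paste(utils::head(unmapped, 10L), collapse = ", "),
           if (length(unmapped) > 10L)
             sprintf(" (and %d more)", length(unmapped) - 10L) else "")
  newUnit <- mapping$unit[match(counts$unit, mapping$county)]
  key <- .strataKey(newUnit, counts$race, counts$ageBand, counts$year)
  d <- rowsum(counts$deaths, key, reorder = FALSE)
  p <- rowsum(counts$population, key, reorder = FALSE)
  first <- !duplicated(key)
  df <- data.frame(unit = newUnit[first], race = counts$race[first],
                   ageBand = counts$ageBand[first],
                   year = counts$year[first],
                   deaths = d[match(key[first], rownames(d)), 1L],
                   population = p[match(key[first], rownames(p)), 1L],
                   stringsAsFactors = FALSE)
  newLevels <- lv
  newLevels$units <- sort(unique(as.character(mapping$unit[
    mapping$county %in% lv$units])))
  StratifiedCounts(df, levels = newLevels)
}

#' Redistribute garbage-coded deaths
#'
#' Deaths assigned insufficiently specific underlying-cause codes are
#' reassigned proportionally: within each (unit, ageBand, year) cell the
#' cell's total garbage deaths are split across races in proportion to the
#' cell's specific deaths, falling back to population shares when the cell
#' has no specific deaths. Totals are conserved (to numerical precision)
#' and the result may carry fractional deaths.
#'
#' @param specific a [StratifiedCounts-class] of cause-specific deaths.
#' @param garbage an aligned [StratifiedCounts-class] of garbage-coded
#'   deaths.
#' @return A [StratifiedCounts-class] with redistributed deaths.
#' @export
redistributeGarbage <- function(specific, garbage) {
  stopifnot(is(specific, "StratifiedCounts"), is(garbage, "StratifiedCounts"))
  .assertAligned(specific, garbage, "specific and garbage")
  if (any(specific$deaths < 0) || any(garbage$deaths < 0))
    .stopf("negative death counts are invalid")
  cell <- .strataKey(specific$unit, "x", specific$ageBand, specific$year)
  cellF <- factor(cell, levels = unique(cell))
  ic <- as.integer(cellF)
  gCell <- rowsum(garbage$deaths, ic, reorder = TRUE)[, 1L]
  sCell <- rowsum(specific$deaths, ic, reorder = TRUE)[, 1L]
  pCell <- rowsum(specific$population, ic, reorder = TRUE)[, 1L]
  useSpec <- sCell[ic] > 0
  share <- ifelse(useSpec, specific$deaths / sCell[ic],
                  specific$population / pCell[ic])
  out <- .setCol(specific, "deaths", specific$deaths + gCell[ic] * share)
  out
}

#' Validate and rectangularize a stratified table
#'
#' Checks for duplicate keys, negative deaths and non-positive populations,
#' and fills missing (unit, race, ageBand, year) cells with explicit zero
#' deaths. All problems are reported together in one itemized error.
#'
#' @param counts data.frame or [StratifiedCounts-class].
#' @param levels optional stratum level list; derived from the data when
#'   `NULL`.
#' @param fillPopulation person-years for filled-in cells: a scalar, or a
#'   data.frame with columns `unit`, `race`, `ageBand`, `year`,
#'   `population`. Required if any cell is missing.
#' @return A validated [StratifiedCounts-class].
#' @export
validateStrata <- function(counts, levels = NULL, fillPopulation = NULL) {
  df <- if (is(counts, "StratifiedCounts")) as.data.frame(counts)
        else as.data.frame(counts)
  problems <- character()
  req <- c("unit", "race", "ageBand", "year", "deaths", "population")
  missingCols <- setdiff(req, colnames(df))
  if (length(missingCols))
    .stopf("missing columns: %s", paste(missingCols, collapse = ", "))
  key <- .strataKey(df$unit, df$race, df$ageBand, df$year)
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    problems <- c(problems, sprintf("duplicated keys: %s",
      paste(utils::head(gsub("\r", "/", dup), 5L), collapse = ", ")))
  if (any(df$deaths < 0, na.rm = TRUE))
    problems <- c(problems, sprintf("%d rows with negative deaths",
                                    sum(df$deaths < 0, na.rm = TRUE)))
  if (any(df$population <= 0, na.rm = TRUE))
    problems <- c(problems, sprintf("%d rows with non-positive population",
                                    sum(df$population <= 0, na.rm = TRUE)))
  if (length(problems))
    .stopf("invalid stratified table:\n  - %s",
           paste(problems, collapse = "\n  - "))
  if (is.null(levels)) {
    levels <- list(units = sort(unique(as.character(df$unit))),
                   races = sort(unique(as.character(df$race))),
                   ageBands = .sortAgeBands(unique(as.character(df$ageBand))),
                   years = sort(unique(as.integer(df$year))))
  }
  grid <- as.data.frame(.strataGrid(levels))
  gkey <- .strataKey(grid$unit, grid$race, grid$ageBand, grid$year)
  hit <- match(gkey, key)
  if (anyNA(hit)) {
    if (is.null(fillPopulation))
      .stopf("%d missing strata and no fillPopulation supplied",
             sum(is.na(hit)))
    grid$deaths <- ifelse(is.na(hit), 0, df$deaths[hit])
    if (is.data.frame(fillPopulation)) {
      fkey <- .strataKey(fillPopulation$unit, fillPopulation$race,
                         fillPopulation$ageBand, fillPopulation$year)
      fp <- fillPopulation$population[match(gkey, fkey)]
    } else {
      fp <- rep(as.numeric(fillPopulation), nrow(grid))
    }
    grid$population <- ifelse(is.na(hit), fp, df$population[hit])
    if (anyNA(grid$population))
      .stopf("fillPopulation does not cover all missing strata")
    df <- grid
  }
  StratifiedCounts(df, levels = levels)
}
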