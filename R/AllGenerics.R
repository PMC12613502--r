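#' @import methods
#' @useDynLib pregsae, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Death counts of a stratified table
#' @param x a [StratifiedCounts-class] object.
#' @return Numeric vector of deaths, one per stratum row.
#' @export
setGeneric("deaths", function(x) standardGeneric("deaths"))

#' Person-years of a stratified table
#' @param x a [StratifiedCounts-class] object.
#' @return Numeric vector of person-years, one per stratum row.
#' @export
setGeneric("population", function(x) standardGeneric("population"))

#' Stratum levels
#'
#' The ordered unit, race, age-band and year labels that define the
#' rectangular stratification of a table or draws object.
#' @param x a [StratifiedCounts-class] or [RateDraws-class] object.
#' @return Named list with elements `units`, `races`, `ageBands`, `years`.
#' @export
setGeneric("strataLevels", function(x) standardGeneric("strataLevels"))

#' Number of posterior draws
#' @param x a [RateDraws-class] object.
#' @return Integer draw count.
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' Rate draw matrix
#'
#' The strata-by-draws matrix of mortality rates (deaths per 100,000
#' person-years).
#' @param x a [RateDraws-class] object.
#' @return Numeric matrix with one row per stratum and one column per draw.
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))

#' Classification-ratio table
#' @param x a [ClassificationRatios-class] object.
#' @return `DataFrame` with key columns (`race`, optionally `ageBand`) and
#'   `ratio`.
#' @export
setGeneric("ratioTable", function(x) standardGeneric("ratioTable"))
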