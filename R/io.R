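# Delimited-text plumbing. Every table is comma-separated with a header
# row; adjacency is a two-column edge list; rate draws are wide
# (stratum keys + draw_1 ... draw_n).

#' @importFrom data.table fread fwrite
NULL

#' Read / write stratified count tables
#'
#' Columns: `unit`, `race`, `ageBand`, `year`, `deaths`, `population`.
#'
#' @param path file path.
#' @param x a [StratifiedCounts-class].
#' @param levels optional stratum levels for [StratifiedCounts()].
#' @return `readStratifiedCounts` returns a [StratifiedCounts-class];
#'   `writeStratifiedCounts` returns `path` invisibly.
#' @export
readStratifiedCounts <- function(path, levels = NULL) {
  df <- as.data.frame(fread(path))
  req <- c("unit", "race", "ageBand", "year", "deaths", "population")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    .stopf("%s: missing columns %s", path, paste(miss, collapse = ", "))
  StratifiedCounts(df, levels = levels)
}

#' @rdname readStratifiedCounts
#' @export
writeStratifiedCounts <- function(x, path) {
  stopifnot(is(x, "StratifiedCounts"))
  fwrite(as.data.frame(x), path)
  invisible(path)
}

#' Read / write adjacency edge lists
#'
#' Two columns `from`, `to`; undirected, no self-loops.
#'
#' @param path file path.
#' @param adjacency edge-list data.frame.
#' @return `readAdjacency` returns the edge-list data.frame.
#' @export
readAdjacency <- function(path) {
  df <- as.data.frame(fread(path, colClasses = "character"))
  if (ncol(df) < 2L) .stopf("%s: adjacency needs two columns", path)
  names(df)[1:2] <- c("from", "to")
  if (any(df$from == df$to)) .stopf("%s: self-loops are invalid", path)
  df[, 1:2]
}

#' @rdname readAdjacency
#' @export
writeAdjacency <- function(adjacency, path) {
  fwrite(adjacency[, c("from", "to")], path)
  invisible(path)
}

#' Read / write classification-ratio tables
#'
#' Columns: `race` (optionally `ageBand`) and `ratio`.
#'
#' @param path file path.
#' @param x a [ClassificationRatios-class].
#' @return `readClassificationRatios` returns a
#'   [ClassificationRatios-class].
#' @export
readClassificationRatios <- function(path) {
  df <- as.data.frame(fread(path))
  if (!all(c("race", "ratio") %in% colnames(df)))
    .stopf("%s: needs columns race, ratio", path)
  classificationRatios(df$race, df$ratio,
                       ageBand = if ("ageBand" %in% colnames(df))
                         df$ageBand)
}

#' @rdname readClassificationRatios
#' @export
writeClassificationRatios <- function(x, path) {
  stopifnot(is(x, "ClassificationRatios"))
  fwrite(as.data.frame(ratioTable(x)), path)
  invisible(path)
}

#' Read / write rate draws (wide delimited text)
#'
#' Stratum key columns followed by `draw_1 ... draw_n`. Mainly for modest
#' tables (summaries, small runs); full national draw matrices are large
#' and are written only on request.
#'
#' @param path file path.
#' @param x a [RateDraws-class].
#' @return `readRateDraws` returns a [RateDraws-class].
#' @export
readRateDraws <- function(path) {
  df <- as.data.frame(fread(path))
  drawCols <- grep("^draw_", colnames(df), value = TRUE)
  if (!length(drawCols)) .stopf("%s: no draw_* columns", path)
  keys <- df[, setdiff(colnames(df), drawCols), drop = FALSE]
  RateDraws(as.matrix(df[, drawCols, drop = FALSE]), keys)
}

#' @rdname readRateDraws
#' @export
writeRateDraws <- function(x, path) {
  stopifnot(is(x, "RateDraws"))
  m <- as.data.frame(rateMatrix(x))
  names(m) <- sprintf("draw_%d", seq_along(m))
  fwrite(cbind(as.data.frame(rowData(x)), m), path)
  invisible(path)
}

#' Read / write county-merge mappings
#'
#' Two columns `county`, `unit`.
#' @param path file path.
#' @param mapping data.frame with columns `county`, `unit`.
#' @return `readUnitMapping` returns the mapping data.frame.
#' @export
readUnitMapping <- function(path) {
  df <- as.data.frame(fread(path, colClasses = "character"))
  if (!all(c("county", "unit") %in% colnames(df)))
    .stopf("%s: needs columns county, unit", path)
  df
}

#' @rdname readUnitMapping
#' @export
writeUnitMapping <- function(mapping, path) {
  fwrite(mapping[, c("county", "unit")], path)
  invisible(path)
}
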