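# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stage offset.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
.childSeed <- function(seed, offset) {
  s <- (as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483647
  as.integer(s)
}

# Round half away from zero to `digits` decimals (display convention for
# reported percentages; base round() is round-half-even).
roundHalfUp <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Row-wise quantiles (type 7, linear interpolation) of a draws matrix.
.rowQuantiles <- function(m, probs) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  n <- ncol(m)
  if (n == 1L) return(matrix(m[, 1L], nrow(m), length(probs)))
  # type-7 positions: h = (n-1)p + 1, interpolate adjacent order statistics
  h <- (n - 1) * probs + 1
  lo <- floor(h)
  hi <- ceiling(h)
  g <- h - lo
  idx <- sort(unique(c(lo, hi)))
  out <- matrix(NA_real_, nrow(m), length(probs))
  for (i in seq_len(nrow(m))) {
    x <- sort(m[i, ], partial = idx)
    out[i, ] <- (1 - g) * x[lo] + g * x[hi]
  }
  out
}

# Canonical stratum ordering: unit slowest, then race, age band, year fastest.
.strataOrder <- function(unit, race, ageBand, year, levels) {
  order(match(unit, levels$units),
        match(race, levels$races),
        match(ageBand, levels$ageBands),
        match(year, levels$years))
}

.strataKey <- function(unit, race, ageBand, year) {
  paste(unit, race, ageBand, year, sep = "\r")
}

# Full rectangular grid of strata in canonical order.
.strataGrid <- function(levels) {
  g <- expand.grid(year = levels$years, ageBand = levels$ageBands,
                   race = levels$races, unit = levels$units,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  S4Vectors::DataFrame(unit = g$unit, race = g$race,
                       ageBand = g$ageBand, year = as.integer(g$year))
}

# Order age-band labels such as "10-14" by their leading number.
.sortAgeBands <- function(bands) {
  bands[order(suppressWarnings(as.numeric(sub("[-+].*$", "", bands))), bands)]
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Collect before/while allocating strata-by-draws matrices so freed
# temporaries are returned to the OS promptly.
.gcLight <- function() invisible(gc(FALSE))

# Replace a column of a StratifiedCounts without going through the DFrame
# list-replacement machinery (which does not accept subclass targets).
.setCol <- function(x, name, value) {
  x@listData[[name]] <- as.numeric(value)
  validObject(x)
  x
}

.assertAligned <- function(a, b, what = "tables") {
  ka <- .strataKey(a$unit, a$race, a$ageBand, a$year)
  kb <- .strataKey(b$unit, b$race, b$ageBand, b$year)
  if (length(ka) != length(kb) || !all(ka == kb)) {
    bad <- union(setdiff(ka, kb), setdiff(kb, ka))
    .stopf("strata of %s are not aligned; offending keys: %s%s",
           what, paste(utils::head(gsub("\r", "/", bad), 5L), collapse = ", "),
           if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else "")
  }
  invisible(TRUE)
}
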