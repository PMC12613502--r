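# Stage 3: two-stage iterative proportional fitting on expected death
# counts, applied draw by draw. Stage A forces race-specific counts to sum
# to the pre-adjustment all-race total of every (unit, ageBand, year) cell;
# stage B forces aggregate (race, ageBand, year) margins to a benchmark
# built from the misclassification-adjusted counts. The two margins are
# alternated until both hold, which removes order sensitivity.

#' Build raking targets from rate draws
#'
#' Stage-A targets are the all-race expected death counts per
#' (unit, ageBand, year) cell implied by the *unadjusted* draws, so that
#' calibration restores each county's pre-adjustment total. Stage-B targets
#' are the benchmark-level (race, ageBand, year) margins of the
#' *adjusted* counts after making them consistent with the stage-A cell
#' totals; when no adjusted draws are supplied the unadjusted counts are
#' used and raking is a no-op.
#'
#' @param unadjusted a [RateDraws-class] straight from the model.
#' @param population aligned [StratifiedCounts-class] person-years.
#' @param drawIndex single draw to target, or `NULL` (default) for all.
#' @param adjusted optional misclassification-adjusted [RateDraws-class];
#'   alternatively supply `ratios` and the adjusted counts are formed on
#'   the fly (equivalent, but avoids materializing a second draw matrix).
#' @param ratios optional [ClassificationRatios-class] used in place of
#'   `adjusted`.
#' @param benchmarkLevel label of the aggregate margin (default
#'   `"national"`).
#' @param tolerance relative margin tolerance for the raking loop.
#' @param maxIterations cap on raking iterations.
#' @return A [RakingTargets-class].
#' @export
buildTargets <- function(unadjusted, population, drawIndex = NULL,
                         adjusted = NULL, ratios = NULL,
                         benchmarkLevel = "national",
                         tolerance = 1e-8, maxIterations = 1000L) {
  stopifnot(is(unadjusted, "RateDraws"), is(population, "StratifiedCounts"))
  rd <- rowData(unadjusted)
  .assertAligned(rd, population, "draws and population")
  nd <- nDraws(unadjusted)
  if (!is.null(drawIndex)) {
    drawIndex <- as.integer(drawIndex)
    if (drawIndex < 1L || drawIndex > nd)
      .stopf("draw index %d out of range 1..%d", drawIndex, nd)
  }
  cols <- if (is.null(drawIndex)) seq_len(nd) else drawIndex
  pop <- population(population)
  popsc <- pop / 1e5
  keyA <- .strataKey(rd$unit, "*", rd$ageBand, rd$year)
  fA <- factor(keyA, levels = unique(keyA))
  iA <- as.integer(fA)
  firstA <- !duplicated(keyA)
  stageAKeys <- S4Vectors::DataFrame(unit = rd$unit[firstA],
                                     ageBand = rd$ageBand[firstA],
                                     year = rd$year[firstA])
  keyB <- .strataKey("*", rd$race, rd$ageBand, rd$year)
  fB <- factor(keyB, levels = unique(keyB))
  iB <- as.integer(fB)
  rateU <- rateMatrix(unadjusted)
  rateV <- if (!is.null(adjusted)) {
    stopifnot(is(adjusted, "RateDraws"))
    rateMatrix(adjusted)
  } else NULL
  rVec <- NULL
  if (is.null(rateV) && !is.null(ratios)) {
    stopifnot(is(ratios, "ClassificationRatios"))
    tab <- ratioTable(ratios)
    rVec <- tab$ratio[match(as.character(rd$race),
                            as.character(tab$race))]
    if (anyNA(rVec)) .stopf("ratios do not cover every race in the draws")
  }
  stageA <- matrix(0, nlevels(fA), length(cols))
  stageB <- matrix(0, nlevels(fB), length(cols))
  # draw blocks keep peak memory modest on long stratum vectors
  .gcLight()
  blocks <- split(seq_along(cols), ceiling(seq_along(cols) / 100))
  for (jb in blocks) {
    U <- rateU[, cols[jb], drop = FALSE] * popsc
    sA <- rowsum(U, iA, reorder = TRUE)
    stageA[, jb] <- sA
    if (is.null(rateV) && is.null(rVec)) {
      stageB[, jb] <- rowsum(U, iB, reorder = TRUE)
    } else {
      # rescale adjusted counts so each stage-A cell total is honored,
      # then aggregate to the benchmark margin
      V <- if (is.null(rateV)) U * rVec
           else rateV[, cols[jb], drop = FALSE] * popsc
      s <- sA / rowsum(V, iA, reorder = TRUE)
      V <- V * s[iA, , drop = FALSE]
      stageB[, jb] <- rowsum(V, iB, reorder = TRUE)
    }
  }
  # rowsum over integer codes sorts by code = first-occurrence order
  firstB <- !duplicated(keyB)
  stageBKeys <- S4Vectors::DataFrame(level = benchmarkLevel,
                                     race = rd$race[firstB],
                                     ageBand = rd$ageBand[firstB],
                                     year = rd$year[firstB])
  new("RakingTargets", stageAKeys = stageAKeys,
      stageA = unname(as.matrix(stageA)),
      stageBKeys = stageBKeys, stageB = unname(as.matrix(stageB)),
      benchmarkLevel = benchmarkLevel, tolerance = tolerance,
      maxIterations = as.integer(maxIterations))
}

#' Iterative proportional fitting of one table
#'
#' Alternately scales a nonnegative seed table to given row and column
#' targets until both margins match within a relative tolerance. Zero
#' cells are fixed points; a zero row or column blocking a positive target
#' is structurally infeasible and raises an error naming the margin.
#'
#' @param cellCounts nonnegative numeric matrix (e.g. units by races).
#' @param rowTargets,colTargets nonnegative target margins. Their totals
#'   must agree within tolerance; otherwise the column targets are
#'   rescaled with a warning.
#' @param tolerance relative margin tolerance (default `1e-8`).
#' @param maxIterations iteration cap (default 1000).
#' @return List with `table` (raked matrix), `iterations`, `discrepancy`
#'   (largest relative margin error on exit).
#' @examples
#' ipfRake(matrix(1, 2, 2), rowTargets = c(3, 1), colTargets = c(2, 2))$table
#' @export
ipfRake <- function(cellCounts, rowTargets, colTargets,
                    tolerance = 1e-8, maxIterations = 1000L) {
  m <- as.matrix(cellCounts)
  if (any(m < 0)) .stopf("cell counts must be nonnegative")
  stopifnot(length(rowTargets) == nrow(m), length(colTargets) == ncol(m))
  tr <- sum(rowTargets); tc <- sum(colTargets)
  if (tr <= 0) .stopf("row targets sum to zero")
  if (abs(tr - tc) > tolerance * max(tr, tc)) {
    warning(sprintf(
      "margin totals disagree (rows %.6g vs cols %.6g); rescaling column targets",
      tr, tc), call. = FALSE)
    colTargets <- colTargets * tr / tc
  }
  blockedRow <- rowTargets > 0 & rowSums(m) == 0
  if (any(blockedRow))
    .stopf("structurally infeasible: zero row(s) %s block positive row targets",
           paste(which(blockedRow), collapse = ", "))
  blockedCol <- colTargets > 0 & colSums(m) == 0
  if (any(blockedCol))
    .stopf("structurally infeasible: zero column(s) %s block positive column targets",
           paste(which(blockedCol), collapse = ", "))
  relErr <- function(current, target)
    max(abs(current - target) / pmax(target, 1e-300) *
          (target > 0 | current > 0))
  disc <- Inf
  for (it in seq_len(maxIterations)) {
    rs <- rowSums(m)
    if (relErr(rs, rowTargets) > tolerance) {
      f <- ifelse(rs > 0, rowTargets / rs, 1)
      m <- m * f
    }
    cs <- colSums(m)
    if (relErr(cs, colTargets) > tolerance) {
      f <- ifelse(cs > 0, colTargets / cs, 1)
      m <- m * rep(f, each = nrow(m))
    }
    disc <- max(relErr(rowSums(m), rowTargets),
                relErr(colSums(m), colTargets))
    if (disc <= tolerance) return(list(table = m, iterations = it,
                                       discrepancy = disc))
  }
  .stopf("IPF did not converge in %d iterations (discrepancy %.3g)",
         maxIterations, disc)
}

#' Rake all draws to their targets
#'
#' Applies the two-stage calibration jointly across every (ageBand, year)
#' slice and every draw: expected death counts (rate x person-years) are
#' alternately scaled to the stage-A cell margins and the stage-B benchmark
#' margins until both hold within the target tolerance, ending on a
#' stage-A pass so that every county's all-race total matches its
#' pre-adjustment value. Rates stay positive wherever the seed rates were
#' positive; masking-eligible small strata are raked like any other
#' (masking is display-only).
#'
#' @param draws the [RateDraws-class] to calibrate (normally the
#'   misclassification-adjusted draws).
#' @param population aligned [StratifiedCounts-class] person-years.
#' @param targets a [RakingTargets-class] covering the same draws.
#' @return A [RateDraws-class] with a per-slice raking report in
#'   `metadata(x)$rakingReport` (iterations and achieved margin
#'   discrepancies).
#' @export
rakeAllDraws <- function(draws, population, targets) {
  stopifnot(is(draws, "RateDraws"), is(population, "StratifiedCounts"),
            is(targets, "RakingTargets"))
  rd <- rowData(draws)
  .assertAligned(rd, population, "draws and population")
  nd <- nDraws(draws)
  if (ncol(targets@stageA) != nd)
    .stopf("targets cover %d draws but draws have %d",
           ncol(targets@stageA), nd)
  pop <- population(population)
  popsc <- pop / 1e5
  rate <- rateMatrix(draws)
  keyA <- .strataKey(rd$unit, "*", rd$ageBand, rd$year)
  fA <- factor(keyA, levels = unique(keyA))
  iA <- as.integer(fA)
  keyAt <- .strataKey(targets@stageAKeys$unit, "*",
                      targets@stageAKeys$ageBand, targets@stageAKeys$year)
  mA <- match(levels(fA), keyAt)
  if (anyNA(mA)) .stopf("stage-A targets do not cover all cells")
  A <- if (identical(mA, seq_along(mA))) targets@stageA
       else targets@stageA[mA, , drop = FALSE]
  keyB <- .strataKey("*", rd$race, rd$ageBand, rd$year)
  fB <- factor(keyB, levels = unique(keyB))
  iB <- as.integer(fB)
  keyBt <- .strataKey("*", targets@stageBKeys$race,
                      targets@stageBKeys$ageBand, targets@stageBKeys$year)
  mB <- match(levels(fB), keyBt)
  if (anyNA(mB)) .stopf("stage-B targets do not cover all margins")
  B <- targets@stageB[mB, , drop = FALSE]
  tol <- targets@tolerance
  # The compiled kernel iterates each draw to joint convergence in place,
  # so peak memory stays at one strata-by-draws matrix.
  .gcLight()
  C <- matrix(0, nrow(rate), nd)
  for (jb in split(seq_len(nd), ceiling(seq_len(nd) / 100)))
    C[, jb] <- rate[, jb, drop = FALSE] * popsc
  res <- .rakeCounts(C, iA - 1L, iB - 1L, A, B, tol,
                     targets@maxIterations)
  perAmax <- res$perA
  perBmax <- res$perB
  itersMax <- res$iterations
  for (jb in split(seq_len(nd), ceiling(seq_len(nd) / 100)))
    C[, jb] <- C[, jb, drop = FALSE] / popsc
  out <- RateDraws(C, rd, levels = strataLevels(draws))
  # per-(ageBand, year) slice report
  slice <- paste(rd$ageBand, rd$year, sep = "/")
  rep1 <- data.frame(slice = unique(slice), stringsAsFactors = FALSE)
  cellSlice <- paste(targets@stageAKeys$ageBand,
                     targets@stageAKeys$year, sep = "/")[mA]
  rep1$maxStageADiscrepancy <- as.numeric(
    tapply(perAmax, cellSlice, max)[rep1$slice])
  margSlice <- paste(targets@stageBKeys$ageBand,
                     targets@stageBKeys$year, sep = "/")[mB]
  rep1$maxStageBDiscrepancy <- as.numeric(
    tapply(perBmax, margSlice, max)[rep1$slice])
  rep1$iterations <- itersMax
  S4Vectors::metadata(out)$rakingReport <- rep1
  S4Vectors::metadata(out)$rakingDiscrepancy <- c(stageA = max(perAmax),
                                                  stageB = max(perBmax))
  out
}
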