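#' @importFrom Matrix sparseMatrix Diagonal crossprod forceSymmetric
#'   determinant Cholesky solve rowSums bdiag t
NULL

#' Specify the stage-1 small-area model
#'
#' Fixed effects: intercept, race indicators, standardized covariate
#' slopes, and race-specific linear year trends. Random effects: iid
#' Gaussian age-band effects and proper-CAR county effects (precision
#' `tau * (D - rho * A)` on the adjacency graph); optionally a shared
#' first-order random-walk year effect. Variance hyperparameters are
#' optimized on the log scale with weak half-normal penalties; the
#' posterior is approximated by a Gaussian at the penalized-likelihood
#' mode.
#'
#' @param nDraws number of posterior draws to simulate (default 1000).
#' @param seed seed for the posterior draws.
#' @param carRho CAR autocorrelation of the unit effects, in `[0, 1)`.
#' @param useYearRW add a shared RW1 year random effect.
#' @param fixedRidge tiny ridge precision on fixed effects (numerical
#'   stabilizer for sparse strata).
#' @param hyperStart starting SDs for (age, unit, year) random effects.
#' @param hyperPenaltyScale scale of the half-normal penalty on each
#'   random-effect SD.
#' @param gradTol Newton convergence tolerance on the scaled gradient.
#' @param maxNewton maximum Newton iterations per inner fit.
#' @param outerMaxit maximum Nelder-Mead evaluations for hyperparameters.
#' @param outerReltol relative tolerance of the hyperparameter search.
#' @return A list of class `"ModelSpec"`.
#' @export
modelSpec <- function(nDraws = 1000L, seed = 1L, carRho = 0.95,
                      useYearRW = FALSE, fixedRidge = 1e-4,
                      hyperStart = c(age = 0.5, unit = 0.5, year = 0.1),
                      hyperPenaltyScale = 1.5, gradTol = 1e-6,
                      maxNewton = 100L, outerMaxit = 120L,
                      outerReltol = 1e-4) {
  stopifnot(nDraws >= 1L, carRho >= 0, carRho < 1, fixedRidge > 0)
  structure(list(nDraws = as.integer(nDraws), seed = as.integer(seed),
                 carRho = carRho, useYearRW = isTRUE(useYearRW),
                 fixedRidge = fixedRidge, hyperStart = hyperStart,
                 hyperPenaltyScale = hyperPenaltyScale, gradTol = gradTol,
                 maxNewton = as.integer(maxNewton),
                 outerMaxit = as.integer(outerMaxit),
                 outerReltol = outerReltol),
            class = "ModelSpec")
}

#' Build the model design bundle
#'
#' Assembles the sparse design matrix (documented column order: intercept,
#' race indicators relative to the first race, standardized covariates,
#' race-specific centered-year slopes, age-band indicators, unit
#' indicators, optional year indicators), the log person-years offset, and
#' the CAR precision structure from the adjacency graph.
#'
#' @param counts a rectangular [StratifiedCounts-class] of (certificate)
#'   deaths and person-years.
#' @param covariates list with elements `unit` (data.frame `unit`, numeric
#'   columns) and/or `unitRace` (data.frame `unit`, `race`, numeric
#'   columns); every unit (and unit-race pair) must be covered.
#' @param adjacency edge-list data.frame over the table's units.
#' @param spec a `modelSpec()`.
#' @return A list bundle consumed by [fitModel()].
#' @export
buildDesign <- function(counts, covariates = NULL, adjacency = NULL,
                        spec = modelSpec()) {
  stopifnot(is(counts, "StratifiedCounts"))
  lv <- strataLevels(counts)
  n <- nrow(counts)
  nr <- length(lv$races); nu <- length(lv$units)
  na <- length(lv$ageBands); ny <- length(lv$years)
  iu <- match(counts$unit, lv$units)
  ir <- match(counts$race, lv$races)
  ia <- match(counts$ageBand, lv$ageBands)
  yearC <- counts$year - mean(lv$years)

  cols <- list(); prec <- list(); blocks <- list()
  addBlock <- function(name, i, j, x, precDiag, labels) {
    start <- sum(vapply(cols, function(z) z$p, 0L))
    cols[[name]] <<- list(i = i, j = j + start, x = x, p = length(labels))
    blocks[[name]] <<- seq.int(start + 1L, start + length(labels))
    prec[[name]] <<- precDiag
    names(blocks[[name]]) <<- labels
  }

  rows <- seq_len(n)
  # intercept
  addBlock("intercept", rows, rep(1L, n), rep(1, n), NULL, "(Intercept)")
  # race indicators (reference = first race)
  if (nr > 1L) {
    keep <- which(ir > 1L)
    addBlock("race", keep, ir[keep] - 1L, rep(1, length(keep)), NULL,
             paste0("race_", lv$races[-1L]))
  }
  # covariates, standardized over design rows
  covCols <- list()
  if (!is.null(covariates$unit)) {
    cu <- covariates$unit
    miss <- setdiff(lv$units, cu$unit)
    if (length(miss))
      .stopf("unit covariates missing for: %s",
             paste(utils::head(miss, 10L), collapse = ", "))
    for (nm in setdiff(colnames(cu), "unit"))
      covCols[[paste0("cov_", nm)]] <- cu[[nm]][match(counts$unit, cu$unit)]
  }
  if (!is.null(covariates$unitRace)) {
    cur <- covariates$unitRace
    ck <- paste(cur$unit, cur$race, sep = "\r")
    need <- paste(rep(lv$units, nr), rep(lv$races, each = nu), sep = "\r")
    miss <- setdiff(need, ck)
    if (length(miss))
      .stopf("unit-race covariates missing for %d pairs (e.g. %s)",
             length(miss), gsub("\r", "/", miss[1L]))
    rk <- paste(counts$unit, counts$race, sep = "\r")
    for (nm in setdiff(colnames(cur), c("unit", "race")))
      covCols[[paste0("cov_", nm)]] <- cur[[nm]][match(rk, ck)]
  }
  if (length(covCols)) {
    for (k in seq_along(covCols)) {
      v <- covCols[[k]]
      s <- stats::sd(v)
      covCols[[k]] <- if (s > 0) (v - mean(v)) / s else v * 0
    }
    vals <- unlist(covCols, use.names = FALSE)
    addBlock("covariates", rep(rows, length(covCols)),
             rep(seq_along(covCols), each = n), vals, NULL,
             names(covCols))
  }
  # race-specific linear year slopes (centered year)
  addBlock("slopes", rows, ir, yearC, NULL, paste0("slope_", lv$races))
  # age-band random effects (iid)
  addBlock("age", rows, ia, rep(1, n), "age", paste0("age_", lv$ageBands))
  # unit random effects (CAR), dropped for a single unit
  car <- NULL
  if (nu > 1L) {
    if (is.null(adjacency)) .stopf("adjacency required for unit effects")
    car <- .carStructure(adjacency, lv$units, spec$carRho)
    addBlock("unit", rows, iu, rep(1, n), "unit", paste0("unit_", lv$units))
  }
  # optional shared RW1 year effect
  if (isTRUE(spec$useYearRW) && ny > 1L) {
    iy <- match(counts$year, lv$years)
    addBlock("year", rows, iy, rep(1, n), "year", paste0("year_", lv$years))
  }

  p <- sum(vapply(cols, function(z) z$p, 0L))
  X <- sparseMatrix(i = unlist(lapply(cols, `[[`, "i")),
                    j = unlist(lapply(cols, `[[`, "j")),
                    x = unlist(lapply(cols, `[[`, "x")),
                    dims = c(n, p))
  colnames(X) <- unlist(lapply(blocks, names), use.names = FALSE)

  # RW1 structure matrix for the year block
  yearR <- NULL
  if (!is.null(blocks$year)) {
    D1 <- diff(diag(ny))
    yearR <- forceSymmetric(Matrix::Matrix(base::crossprod(D1), sparse = TRUE))
  }
  list(X = X, y = counts$deaths, offsetLog = log(counts$population),
       blocks = blocks, prec = prec, car = car, yearR = yearR,
       strata = S4Vectors::DataFrame(unit = counts$unit, race = counts$race,
                                     ageBand = counts$ageBand,
                                     year = counts$year),
       levels = lv, spec = spec, n = n, p = p)
}

# Full prior precision for given hyperparameter SDs.
.buildQ <- function(design, sdAge, sdUnit, sdYear = NULL) {
  spec <- design$spec
  q <- rep(spec$fixedRidge, design$p)
  Q <- Diagonal(x = q)
  b <- design$blocks
  if (!is.null(b$age))
    Q[b$age, b$age] <- Diagonal(length(b$age), 1 / sdAge^2)
  if (!is.null(b$unit))
    Q[b$unit, b$unit] <- design$car$Q / sdUnit^2 +
      Diagonal(length(b$unit), spec$fixedRidge)
  if (!is.null(b$year))
    Q[b$year, b$year] <- design$yearR / sdYear^2 +
      Diagonal(length(b$year), spec$fixedRidge)
  forceSymmetric(Q)
}

# Cholesky with deterministic jitter escalation: 1e-8 x mean diagonal,
# escalating tenfold up to 1e-4, then failure.
.cholJitter <- function(H) {
  md <- mean(Matrix::diag(H))
  for (jit in c(0, md * 10^seq(-8, -4))) {
    ch <- tryCatch(Cholesky(forceSymmetric(H + Diagonal(nrow(H), jit)),
                            perm = TRUE, LDL = FALSE),
                   error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, jitter = jit))
  }
  .stopf("curvature not positive definite after jitter escalation to 1e-4")
}

# Penalized Poisson log-likelihood (supports fractional deaths):
# sum(y * eta - mu) - theta' Q theta / 2  (constants dropped).
.penLoglik <- function(theta, design, Q) {
  eta <- as.numeric(design$X %*% theta) + design$offsetLog
  mu <- exp(eta)
  sum(design$y * eta - mu) - 0.5 * sum(theta * as.numeric(Q %*% theta))
}

# Inner Newton optimization of the latent vector at fixed hyperparameters.
.newtonMode <- function(design, Q, thetaStart = NULL) {
  spec <- design$spec
  p <- design$p
  theta <- if (is.null(thetaStart)) {
    th <- numeric(p)
    th[1L] <- log(max(sum(design$y), 0.5) / sum(exp(design$offsetLog)))
    th
  } else thetaStart
  gradScale <- 1 + sum(abs(design$y))
  ll <- .penLoglik(theta, design, Q)
  iter <- 0L; gnorm <- Inf; H <- NULL
  repeat {
    iter <- iter + 1L
    eta <- as.numeric(design$X %*% theta) + design$offsetLog
    mu <- exp(pmin(eta, 50))
    g <- as.numeric(Matrix::crossprod(design$X, design$y - mu)) -
      as.numeric(Q %*% theta)
    gnorm <- max(abs(g))
    if (gnorm < spec$gradTol * gradScale || iter > spec$maxNewton) break
    W <- Diagonal(x = mu)
    H <- forceSymmetric(Matrix::crossprod(design$X, W %*% design$X) + Q)
    ch <- .cholJitter(H)$chol
    step <- as.numeric(solve(ch, g))
    # backtracking line search on the penalized log-likelihood
    s <- 1
    for (k in 1:30) {
      cand <- theta + s * step
      llc <- .penLoglik(cand, design, Q)
      if (is.finite(llc) && llc >= ll - 1e-12) { theta <- cand; ll <- llc; break }
      s <- s / 2
    }
  }
  eta <- as.numeric(design$X %*% theta) + design$offsetLog
  mu <- exp(pmin(eta, 50))
  H <- forceSymmetric(Matrix::crossprod(design$X,
                                        Diagonal(x = mu) %*% design$X) + Q)
  list(theta = theta, H = H, loglik = ll, gradNorm = gnorm,
       iterations = iter, converged = gnorm < spec$gradTol * gradScale)
}

# Laplace approximation to the negative log marginal likelihood at the
# given hyperparameters (up to constants), with weak half-normal penalties
# on the SDs.
.laplaceCrit <- function(logSd, design, state) {
  spec <- design$spec
  sdAge <- exp(logSd[1L])
  sdUnit <- if (length(logSd) >= 2L) exp(logSd[2L]) else 1
  sdYear <- if (length(logSd) >= 3L) exp(logSd[3L]) else NULL
  Q <- .buildQ(design, sdAge, sdUnit, sdYear)
  fit <- .newtonMode(design, Q, state$theta)
  state$theta <- fit$theta
  ldQ <- 0
  b <- design$blocks
  if (!is.null(b$age)) ldQ <- ldQ - 2 * length(b$age) * log(sdAge)
  if (!is.null(b$unit))
    ldQ <- ldQ + design$car$logdet - 2 * length(b$unit) * log(sdUnit)
  if (!is.null(b$year))
    ldQ <- ldQ + state$yearLogdet - 2 * length(b$year) * log(sdYear)
  ldH <- as.numeric(determinant(fit$H, logarithm = TRUE)$modulus)
  pen <- 0.5 * sum((exp(logSd) / spec$hyperPenaltyScale)^2) - sum(logSd)
  -(fit$loglik + 0.5 * ldQ - 0.5 * ldH) + pen
}

#' Fit the small-area model
#'
#' Maximizes the penalized Poisson log-likelihood (log link, person-years
#' offset) over all fixed and random effects by sparse Newton iterations,
#' jointly optimizing the variance hyperparameters on the log scale via a
#' Laplace-approximate marginal criterion. Returns the mode, the curvature
#' (negative Hessian of the log posterior) and diagnostics; a
#' non-convergent fit raises an explicit error carrying the diagnostics.
#'
#' @param design a bundle from [buildDesign()].
#' @param strict error (rather than warn) when the gradient tolerance is
#'   not met.
#' @return A [FittedModel-class].
#' @export
fitModel <- function(design, strict = TRUE) {
  spec <- design$spec
  b <- design$blocks
  state <- new.env(parent = emptyenv())
  state$theta <- NULL
  hasAge <- !is.null(b$age); hasUnit <- !is.null(b$unit)
  hasYear <- !is.null(b$year)
  if (hasUnit && is.null(design$car$logdet)) {
    design$car$logdet <- as.numeric(determinant(
      design$car$Q + Diagonal(nrow(design$car$Q), spec$fixedRidge),
      logarithm = TRUE)$modulus)
  }
  if (hasYear) {
    state$yearLogdet <- as.numeric(determinant(
      design$yearR + Diagonal(nrow(design$yearR), spec$fixedRidge),
      logarithm = TRUE)$modulus)
  }
  hyper <- numeric(0)
  if (hasAge || hasUnit || hasYear) {
    start <- log(c(spec$hyperStart[["age"]],
                   if (hasUnit) spec$hyperStart[["unit"]],
                   if (hasYear) spec$hyperStart[["year"]]))
    opt <- if (length(start) == 1L) {
      stats::optim(start, .laplaceCrit, design = design, state = state,
                   method = "Brent", lower = log(1e-3), upper = log(20))
    } else {
      stats::optim(start, .laplaceCrit, design = design, state = state,
                   method = "Nelder-Mead",
                   control = list(maxit = spec$outerMaxit,
                                  reltol = spec$outerReltol))
    }
    sds <- exp(opt$par)
    hyper <- c(age = sds[1L],
               if (hasUnit) c(unit = sds[2L]),
               if (hasYear) c(year = sds[if (hasUnit) 3L else 2L]))
  }
  sdAge <- if (hasAge) hyper[["age"]] else 1
  sdUnit <- if (hasUnit) hyper[["unit"]] else 1
  sdYear <- if (hasYear) hyper[["year"]] else NULL
  Q <- .buildQ(design, sdAge, sdUnit, sdYear)
  fit <- .newtonMode(design, Q, state$theta)
  if (!fit$converged) {
    msg <- sprintf(
      "model did not converge: max |gradient| %.3g after %d iterations",
      fit$gradNorm, fit$iterations)
    if (strict) .stopf("%s", msg) else warning(msg, call. = FALSE)
  }
  chl <- .cholJitter(fit$H)
  theta <- fit$theta
  names(theta) <- colnames(design$X)
  new("FittedModel", theta = theta, hessian = fit$H, chol = chl$chol,
      hyper = hyper, converged = fit$converged,
      diagnostics = list(gradNorm = fit$gradNorm,
                         iterations = fit$iterations,
                         loglik = fit$loglik, jitter = chl$jitter),
      design = design)
}

#' Simulate rate draws from the approximated posterior
#'
#' Draws latent parameter vectors from the Gaussian approximation
#' `N(mode, H^-1)` at the penalized-likelihood mode, pushes them through
#' the log link, and scales to deaths per 100,000 person-years. A fixed
#' seed yields identical draws.
#'
#' @param fit a converged [FittedModel-class].
#' @param nDraws number of draws; defaults to the model spec.
#' @param seed seed; defaults to the model spec.
#' @return A [RateDraws-class], one row per stratum, one column per draw.
#' @export
drawPosterior <- function(fit, nDraws = NULL, seed = NULL) {
  stopifnot(is(fit, "FittedModel"))
  if (!fit@converged) .stopf("cannot draw from a non-converged fit")
  design <- fit@design
  spec <- design$spec
  if (is.null(nDraws)) nDraws <- spec$nDraws
  if (is.null(seed)) seed <- spec$seed
  set.seed(.childSeed(seed, 6L))
  p <- design$p
  Z <- matrix(rnorm(p * nDraws), p, nDraws)
  # H = P' L L' P  =>  theta = mode + P' L^{-T} z  has covariance H^{-1}
  Theta <- as.matrix(solve(fit@chol, solve(fit@chol, Z, system = "Lt"),
                           system = "Pt")) + fit@theta
  n <- design$n
  .gcLight()
  R <- matrix(0, n, nDraws)
  chunk <- max(1L, min(nDraws, as.integer(ceiling(2e7 / n))))
  idx <- 1L
  while (idx <= nDraws) {
    j <- idx:min(idx + chunk - 1L, nDraws)
    R[, j] <- exp(as.matrix(design$X %*% Theta[, j, drop = FALSE])) * 1e5
    idx <- idx + chunk
    .gcLight()
  }
  RateDraws(R, design$strata, levels = design$levels)
}
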