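## Maximum-likelihood fitting and prediction.

## finite logit of an observed proportion
safeLogit <- function(x) qlogis(pmin(pmax(x, 0.02), 0.98))

## data-driven starting values: intercepts at the logit of crude frequencies,
## all slopes at zero
naiveStart <- function(dd) {
  start <- setNames(numeric(dd$K), dd$parNames)
  setIntercept <- function(block, value) {
    nm <- paste0(block, "_(Intercept)")
    if (nm %in% dd$parNames) start[nm] <<- value
  }
  if (dd$family == "multiseason") {
    setIntercept("psi", safeLogit(mean(dd$anyDet > 0)))
    setIntercept("p", safeLogit(mean(dd$y > 0)))
  } else if (dd$family == "multistate") {
    any1 <- groupSum(as.numeric(dd$y > 0), dd$ss, dd$nSS) > 0
    has2 <- groupSum(as.numeric(dd$y == 2), dd$ss, dd$nSS) > 0
    setIntercept("psi", safeLogit(mean(any1)))
    setIntercept("R", safeLogit(if (any(any1)) mean(has2[any1]) else 0.5))
    setIntercept("p", safeLogit(mean(dd$y > 0)))
    setIntercept("delta", safeLogit(if (any(dd$y > 0)) mean(dd$y[dd$y > 0] == 2) else 0.5))
  } else {
    detA <- groupSum(dd$yA, dd$site, dd$nSite) > 0
    detB <- groupSum(dd$yB, dd$site, dd$nSite) > 0
    setIntercept("psi", safeLogit(mean(detA | detB)))
    setIntercept("p", safeLogit(mean(c(dd$yA, dd$yB))))
  }
  start
}

numGrad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' Fit an occupancy model by maximum likelihood
#'
#' Minimises the family's -2 log-likelihood by quasi-Newton (BFGS)
#' optimisation from \code{nStarts} seeded random starts plus one naive
#' start (intercepts at the logit of crude occupancy and detection
#' frequencies). The best start wins; ties go to the earlier start. The
#' covariance of the estimates is twice the inverse numerical Hessian of the
#' -2LL surface (i.e. the inverse observed information); when the Hessian is
#' singular the covariance is flagged unavailable. Estimates pushed to the
#' probability boundary (|logit| > 15, plausible when a species is detected
#' at essentially every site) are reported with a boundary flag, not
#' penalised. A warning is issued when a season has no detections at all,
#' since season-specific parameters are then weakly identified.
#'
#' @param spec an [OccuModelSpec-class].
#' @param history the matching [DetectionHistory-class].
#' @param covars a [SiteCovariates-class].
#' @param nStarts number of random starts in addition to the naive start.
#' @param seed integer seed for the random starts.
#' @param maxit optimiser iteration cap per start.
#' @return An [OccuFit-class].
#' @export
fitOccu <- function(spec, history, covars, nStarts = 10, seed = 1,
                    maxit = 500) {
  covars <- transformCovariates(covars)
  dd <- buildDesign(spec, history, covars)
  nll <- nllForFamily(spec@family)
  f <- function(par) nll(par, dd)
  ## identifiability caution: seasons without any detection
  if (spec@family != "twospecies") {
    s <- history@layout@seasons
    for (t in seq_len(nrow(s))) {
      cols <- s$firstWeek[t] + seq_len(s$nWeeks[t]) - 1L
      if (!any(history@observations[, cols] > 0))
        warning(sprintf("season %s %d has no detections; estimates may sit on the boundary",
                        s$label[t], s$year[t]))
    }
  }
  set.seed(seed)
  starts <- c(list(naiveStart(dd)),
              lapply(seq_len(nStarts), function(i) rnorm(dd$K)))
  runs <- lapply(starts, function(s0)
    tryCatch(optim(s0, f, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10)),
             error = function(e) NULL))
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok))
    stop("all optimisation starts failed for ", specLabel(spec))
  vals <- vapply(runs, function(r) if (is.null(r)) Inf else r$value, numeric(1))
  bestIdx <- which.min(vals)  # strict minimum => earliest start wins ties
  best <- runs[[bestIdx]]
  est <- setNames(best$par, dd$parNames)
  H <- tryCatch(optimHess(best$par, f), error = function(e) NULL)
  vc <- matrix(numeric(0), 0, 0)
  if (!is.null(H)) {
    vci <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vci) && all(is.finite(vci))) {
      vc <- (vci + t(vci)) / 2
      dimnames(vc) <- list(dd$parNames, dd$parNames)
    }
  }
  conv <- list(nStarts = length(starts), bestStart = bestIdx,
               startValues = vals,
               gradientNorm = sqrt(sum(numGrad(f, best$par)^2)),
               converged = best$convergence == 0,
               boundary = any(abs(est) > 15),
               vcovAvailable = nrow(vc) > 0)
  new("OccuFit", spec = spec, estimates = est, neg2LL = best$value,
      K = dd$K, AIC = best$value + 2 * dd$K, vcov = vc,
      convergence = conv, data = list(history = history, covars = covars,
                                      designs = dd))
}

## design row + parameter-block indices for one predicted probability
predictRow <- function(fit, what, covariateValue, season, species, effortDays) {
  dd <- fit@data$designs
  spec <- fit@spec
  covars <- fit@data$covars
  block <- switch(what,
                  occupancy = "psi", detection = "p",
                  conditional_occupancy = "R", conditional_detection = "delta")
  if (is.null(dd$blocks[[block]]))
    stop("'", what, "' is not a parameter of this family")
  cols <- dd$blocks[[block]]
  x <- setNames(numeric(length(cols)), cols)
  x[paste0(block, "_(Intercept)")] <- 1
  ind <- if (spec@family == "twospecies") {
    if (is.null(species)) stop("species required for two-species predictions")
    as.numeric(species %in% c("B", "red"))
  } else as.numeric(season == "summer")
  indName <- if (spec@family == "twospecies") "speciesB" else "seasonSummer"
  nmInd <- paste0(block, "_", indName)
  if (nmInd %in% cols) x[nmInd] <- ind
  covName <- paste0(block, "_cov")
  if (covName %in% cols) {
    if (is.null(covariateValue))
      covariateValue <- median(rawCovariate(covars, spec@covariate, season))
    tv <- transformValue(spec@covariate, covariateValue)
    x[covName] <- tv
    nmInt <- paste0(block, "_cov:", indName)
    if (nmInt %in% cols) x[nmInt] <- tv * ind
  }
  numName <- paste0(block, "_number")
  if (numName %in% cols) {
    if (is.null(effortDays)) effortDays <- 7
    x[numName] <- effortDays
  }
  list(x = x, idx = match(cols, dd$parNames), covariateValue = covariateValue)
}

rawCovariate <- function(covars, covariate, season) {
  col <- if (covariate %in% c("direct", "diffuse", "total"))
    paste0(covariate, "_", season) else covariate
  covars@raw[[col]]
}

transformValue <- function(covariate, value) {
  if (covariate %in% c("direct", "diffuse", "total")) sqrt(value)
  else if (covariate %in% c("cn", "ph", "p")) log(value)
  else value
}

#' Predict a probability from a fitted occupancy model
#'
#' Inverse-logit of the requested linear predictor, with a delta-method
#' standard error on the logit scale and a 95 percent confidence interval
#' back-transformed from \code{logit +/- 1.96 SE}. Habitat covariate values
#' are supplied on the raw measurement scale; the model's transform (square
#' root for solar, log for soil) is applied internally. Values outside the
#' fitted covariate range are returned with an extrapolation flag (intervals
#' widen sharply where the data are sparse).
#'
#' @param fit an [OccuFit-class].
#' @param what one of "occupancy", "detection", "conditional_occupancy",
#'   "conditional_detection".
#' @param covariateValue raw-scale value(s) of the model's habitat
#'   covariate; defaults to its observed median.
#' @param season "winter" or "summer" (multiseason/multistate families).
#' @param species "rusa"/"A" or "red"/"B" (two-species family).
#' @param effortDays active camera days for detection predictions
#'   (default 7).
#' @param level confidence level (default 0.95).
#' @return data.frame with columns \code{prob}, \code{se}, \code{lower},
#'   \code{upper}, \code{extrapolated}, one row per covariate value.
#' @export
predictProbabilities <- function(fit, what = "occupancy", covariateValue = NULL,
                                 season = "winter", species = "rusa",
                                 effortDays = NULL, level = 0.95) {
  z <- -qnorm((1 - level) / 2)
  values <- if (is.null(covariateValue)) list(NULL) else as.list(covariateValue)
  rows <- lapply(values, function(v) {
    pr <- predictRow(fit, what, v, season, species, effortDays)
    lp <- sum(pr$x * fit@estimates[pr$idx])
    seLogit <- if (nrow(fit@vcov) > 0)
      sqrt(drop(pr$x %*% fit@vcov[pr$idx, pr$idx, drop = FALSE] %*% pr$x))
    else NA_real_
    prob <- plogis(lp)
    extrap <- FALSE
    if (!is.null(pr$covariateValue) && !is.na(fit@spec@covariate)) {
      rng <- range(rawCovariate(fit@data$covars, fit@spec@covariate, season))
      extrap <- pr$covariateValue < rng[1] || pr$covariateValue > rng[2]
    }
    data.frame(prob = prob, se = prob * (1 - prob) * seLogit,
               lower = plogis(lp - z * seLogit),
               upper = plogis(lp + z * seLogit),
               extrapolated = extrap)
  })
  do.call(rbind, rows)
}

#' @importFrom stats qnorm
NULL
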