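## AIC ranking, candidate-set construction, probability-scale model
## averaging.

#' Akaike's Information Criterion
#'
#' \code{AIC = -2LL + 2K}, with -2LL twice the negative maximised
#' log-likelihood and K the number of estimated parameters.
#'
#' @param neg2LL twice the negative log-likelihood.
#' @param K number of estimated parameters (>= 0).
#' @return AIC value(s).
#' @export
aicScore <- function(neg2LL, K) {
  if (any(K < 0)) stop("K must be non-negative")
  neg2LL + 2 * K
}

#' Rank models by AIC and compute Akaike weights
#'
#' Produces the customary comparison table: models sorted by increasing
#' AIC, the AIC difference to the best model, and Akaike weights
#' \code{w_i = exp(-dAIC_i / 2) / sum_j exp(-dAIC_j / 2)}, which sum to one
#' over the compared set and are invariant to adding a constant to every
#' AIC. Ties are broken by smaller K, then label.
#'
#' @param fits list of [OccuFit-class] objects fitted to the same data, or
#'   a data.frame with columns \code{neg2LL} and \code{K} (and optionally
#'   \code{label}), e.g. transcribed from a published table.
#' @return data.frame with columns \code{label}, \code{neg2LL}, \code{K},
#'   \code{AIC}, \code{dAIC}, \code{w}, ordered by AIC.
#' @export
rankModels <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- data.frame(label = if ("label" %in% names(fits)) fits$label
                              else paste0("model", seq_len(nrow(fits))),
                      neg2LL = fits$neg2LL, K = as.integer(fits$K),
                      stringsAsFactors = FALSE)
  } else {
    shapes <- vapply(fits, function(f)
      paste(dim(f@data$history@observations), collapse = "x"), character(1))
    if (length(unique(shapes)) > 1)
      stop("fits were made on data of differing shapes")
    tab <- data.frame(label = vapply(fits, function(f) specLabel(f@spec), character(1)),
                      neg2LL = vapply(fits, function(f) f@neg2LL, numeric(1)),
                      K = vapply(fits, function(f) f@K, integer(1)),
                      stringsAsFactors = FALSE)
  }
  tab$AIC <- aicScore(tab$neg2LL, tab$K)
  tab <- tab[order(tab$AIC, tab$K, tab$label), , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1L]
  rel <- exp(-tab$dAIC / 2)
  tab$w <- rel / sum(rel)
  rownames(tab) <- NULL
  tab
}

COVARIATE_GROUPS <- list(solar = c("direct", "diffuse", "total"),
                         soil = c("cn", "ph", "p"),
                         plant = "axis1")

#' Build a candidate model set
#'
#' For the multiseason and two-species families: one covariate at a time,
#' with every combination of covariate mode on occupancy and detection in
#' \{none, additive, interaction\} except (none, none), i.e. eight models
#' per covariate, plus the shared factor-only null model in each group.
#' That yields 25 solar (3 covariates), 25 soil (3 covariates) and 9
#' plant-composition (1 covariate) specs, 59 in total. The multistate
#' family instead enumerates a fixed 2 x 3 x 2 grid: conditional occupancy
#' \{constant, Season\} x detection \{Season, State + Season,
#' State x Season\} x conditional detection \{constant, Season\} = 12
#' models. The seasonal (or species) factor is present in every model.
#'
#' @param family model family.
#' @param group "solar", "soil", "plant" or "all" (ignored for
#'   multistate).
#' @return list of [OccuModelSpec-class] objects.
#' @export
buildCandidateSet <- function(family = c("multiseason", "twospecies", "multistate"),
                              group = "all") {
  family <- match.arg(family)
  if (family == "multistate") {
    specs <- list()
    for (r in c("constant", "season"))
      for (p in c("season", "state_add", "state_int"))
        for (d in c("constant", "season"))
          specs[[length(specs) + 1L]] <- modelSpec(family, rTerms = r,
                                                  pStateTerms = p, deltaTerms = d)
    return(specs)
  }
  if (identical(group, "all"))
    return(do.call(c, lapply(names(COVARIATE_GROUPS), buildCandidateSet,
                             family = family)))
  covs <- COVARIATE_GROUPS[[group]]
  if (is.null(covs)) stop("unknown covariate group '", group, "'")
  specs <- list(modelSpec(family))  # shared factor-only null
  for (cv in covs)
    for (pm in c("none", "additive", "interaction"))
      for (dm in c("none", "additive", "interaction")) {
        if (pm == "none" && dm == "none") next
        specs[[length(specs) + 1L]] <- modelSpec(family, covariate = cv,
                                                 psiMode = pm, pMode = dm)
      }
  specs
}

#' Fit a set of candidate models
#'
#' Convenience wrapper that fits every spec in a candidate set and returns
#' the fits in the order given. Non-convergent models are kept with a
#' warning so that ranking can proceed over the models that did fit.
#'
#' @param specs list of [OccuModelSpec-class].
#' @param history,covars data as for [fitOccu()].
#' @param nStarts,seed,maxit passed to [fitOccu()].
#' @return list of [OccuFit-class].
#' @export
fitCandidateSet <- function(specs, history, covars, nStarts = 3, seed = 1,
                            maxit = 500) {
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    fits[[i]] <- tryCatch(
      suppressWarnings(fitOccu(specs[[i]], history, covars,
                               nStarts = nStarts, seed = seed + i, maxit = maxit)),
      error = function(e) {
        warning("fit failed for ", specLabel(specs[[i]]), ": ", conditionMessage(e))
        NULL
      })
  }
  fits[!vapply(fits, is.null, logical(1))]
}

#' Model-averaged probabilities over a covariate grid
#'
#' Averages predicted probabilities over a model set at the scale of the
#' probabilities themselves (not the regression coefficients), weighting by
#' Akaike weights renormalised over the supplied fits:
#' \code{pbar(x) = sum_m w_m phat_m(x)}, with unconditional variance
#' \code{sum_m w_m [var_m(x) + (phat_m(x) - pbar(x))^2]} that carries the
#' model-selection uncertainty. Models whose habitat covariate is not the
#' grid covariate are held at the observed median of their own covariate,
#' except that total solar radiation is constrained to equal the grid
#' direct (or diffuse) value plus the median of the complementary
#' component. Confidence intervals use a normal approximation on the
#' probability scale (clamped to [0, 1]); set \code{logitScale = TRUE} for
#' the logit-scale variant.
#'
#' @param fits list of [OccuFit-class] over the same data.
#' @param what "occupancy" or "detection".
#' @param covariate grid covariate name.
#' @param grid raw-scale values of the grid covariate.
#' @param season,species,effortDays passed to [predictProbabilities()].
#' @param level confidence level.
#' @param logitScale compute intervals on the logit scale.
#' @return data.frame: \code{value}, \code{prob}, \code{se}, \code{lower},
#'   \code{upper}.
#' @export
modelAverage <- function(fits, what = "occupancy", covariate = NULL,
                         grid = NULL, season = "winter", species = "rusa",
                         effortDays = NULL, level = 0.95, logitScale = FALSE) {
  cmp <- rankModels(fits)
  labels <- vapply(fits, function(f) specLabel(f@spec), character(1))
  w <- cmp$w[match(labels, cmp$label)]
  covars <- fits[[1L]]@data$covars
  if (is.null(covariate)) {
    grid <- NA_real_  # every model at the median of its own covariate
  } else {
    if (is.null(grid))
      grid <- median(rawCovariate(covars, covariate, season))
    if (!any(vapply(fits, function(f) identical(f@spec@covariate, covariate), logical(1))))
      stop("grid covariate '", covariate, "' appears in none of the fitted models")
  }
  z <- -qnorm((1 - level) / 2)
  out <- lapply(grid, function(g) {
    pm <- vapply(fits, function(f) {
      v <- modelValueForGrid(f@spec@covariate, covariate, g, covars, season)
      pr <- predictProbabilities(f, what, covariateValue = v, season = season,
                                 species = species, effortDays = effortDays)
      c(pr$prob, pr$se)
    }, numeric(2))
    pbar <- sum(w * pm[1L, ])
    vuncond <- sum(w * (pm[2L, ]^2 + (pm[1L, ] - pbar)^2))
    se <- sqrt(vuncond)
    if (logitScale) {
      seL <- se / (pbar * (1 - pbar))
      lo <- plogis(qlogis(pbar) - z * seL); hi <- plogis(qlogis(pbar) + z * seL)
    } else {
      lo <- max(0, pbar - z * se); hi <- min(1, pbar + z * se)
    }
    data.frame(value = g, prob = pbar, se = se, lower = lo, upper = hi)
  })
  do.call(rbind, out)
}

## covariate value for a model when predicting along a (possibly different)
## grid covariate: its own observed median, except total = direct + diffuse
modelValueForGrid <- function(modelCov, gridCov, g, covars, season) {
  if (is.na(modelCov)) return(NULL)
  if (is.null(gridCov)) return(median(rawCovariate(covars, modelCov, season)))
  if (modelCov == gridCov) return(g)
  if (modelCov == "total" && gridCov %in% c("direct", "diffuse")) {
    other <- setdiff(c("direct", "diffuse"), gridCov)
    return(g + median(rawCovariate(covars, other, season)))
  }
  median(rawCovariate(covars, modelCov, season))
}

#' Write a model-comparison table as CSV
#'
#' Exports the ranking in the customary column layout (Occupancy,
#' Detection, dAIC, w, K, neg2LL). Occupancy/Detection columns are split
#' out of the model labels where possible.
#'
#' @param comparison output of [rankModels()].
#' @param path CSV path.
#' @return Invisibly, the exported data.frame.
#' @export
writeComparisonCSV <- function(comparison, path) {
  piece <- function(lab, key) {
    m <- regmatches(lab, regexec(paste0(key, "\\(([^)]*)\\)"), lab))
    vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_, character(1))
  }
  out <- data.frame(Occupancy = piece(comparison$label, "psi"),
                    Detection = piece(comparison$label, "p"),
                    dAIC = round(comparison$dAIC, 2),
                    w = round(comparison$w, 2),
                    K = comparison$K,
                    neg2LL = round(comparison$neg2LL, 2))
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
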