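#' @import methods
#' @importFrom stats plogis qlogis optim optimHess median rnorm rbinom runif
#'   setNames dist as.dist cmdscale isoreg hclust cutree quantile var sd
#'   dnorm pnorm qnorm uniroot
#' @importFrom utils read.csv write.csv packageVersion
NULL

OBS_MISSING <- -1L

#' Season layout of a camera-trap study
#'
#' Describes how the weekly survey occasions of a study are grouped into
#' seasons (primary periods). Weeks are contiguous 7-day blocks counted from
#' each season's first day and are shared by all sites. Each season carries a
#' level label (\code{"winter"} or \code{"summer"}) used for the seasonal
#' factor in the occupancy and detection linear predictors; years never enter
#' the models, so the two winters (and the two summers) share parameters.
#'
#' @slot seasons data.frame with one row per season: \code{label}
#'   (winter/summer), \code{year}, \code{start} (\code{Date} of the first
#'   day), \code{firstWeek} (1-based index of the season's first occasion)
#'   and \code{nWeeks}.
#' @slot totalWeeks total number of weekly occasions across all seasons.
#'
#' @seealso [seasonLayout()], [DetectionHistory-class]
#' @exportClass SeasonLayout
setClass("SeasonLayout",
  representation(seasons = "data.frame", totalWeeks = "integer"),
  validity = function(object) {
    s <- object@seasons
    msg <- character()
    need <- c("label", "year", "start", "firstWeek", "nWeeks")
    if (!all(need %in% names(s)))
      return(paste("seasons must have columns", paste(need, collapse = ", ")))
    if (!all(s$label %in% c("winter", "summer")))
      msg <- c(msg, "season labels must be 'winter' or 'summer'")
    if (nrow(s) > 0) {
      expectFirst <- cumsum(c(1L, s$nWeeks[-nrow(s)]))
      if (!all(s$firstWeek == expectFirst))
        msg <- c(msg, "season weeks must be contiguous and non-overlapping")
      if (object@totalWeeks != sum(s$nWeeks))
        msg <- c(msg, "totalWeeks must equal sum of season nWeeks")
      if (any(s$nWeeks < 1)) msg <- c(msg, "each season needs >= 1 week")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a SeasonLayout
#'
#' @param labels character vector of season levels ("winter"/"summer").
#' @param years numeric vector of season years.
#' @param starts first calendar day of each season (`Date` or ISO strings);
#'   weeks are 7-day blocks from this day.
#' @param nWeeks integer vector, number of weekly occasions per season.
#' @return A [SeasonLayout-class] object.
#' @examples
#' seasonLayout(c("winter", "summer"), c(2010, 2010),
#'              c("2010-06-14", "2010-12-13"), c(13, 13))
#' @export
seasonLayout <- function(labels, years, starts, nWeeks) {
  starts <- as.Date(starts)
  nWeeks <- as.integer(nWeeks)
  df <- data.frame(label = as.character(labels), year = as.integer(years),
                   start = starts, firstWeek = cumsum(c(1L, nWeeks[-length(nWeeks)])),
                   nWeeks = nWeeks, stringsAsFactors = FALSE)
  new("SeasonLayout", seasons = df, totalWeeks = sum(nWeeks))
}

#' @describeIn seasonLayout number of seasons.
#' @param layout a [SeasonLayout-class].
#' @export
nSeasons <- function(layout) nrow(layout@seasons)

#' Map each weekly occasion to its season
#'
#' @param layout a [SeasonLayout-class].
#' @return Integer vector of length \code{totalWeeks}; entry w is the season
#'   index of occasion w.
#' @export
weekSeason <- function(layout) {
  rep(seq_len(nSeasons(layout)), layout@seasons$nWeeks)
}

setMethod("show", "SeasonLayout", function(object) {
  s <- object@seasons
  cat("SeasonLayout:", nrow(s), "seasons,", object@totalWeeks, "weekly occasions\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s %d: weeks %d-%d (from %s)\n", s$label[i], s$year[i],
                s$firstWeek[i], s$firstWeek[i] + s$nWeeks[i] - 1L,
                format(s$start[i])))
})

#' Weekly detection histories with effort
#'
#' The central data container: a site-by-week matrix of observation codes
#' plus a matching matrix of camera effort (active days per site-week, 0-7)
#' and the season layout. Weeks in which the camera was never active
#' (effort 0) are structurally missing and coded -1; weeks with partial
#' effort (1-6 days) are retained as observations, with effort available as
#' a detection covariate.
#'
#' Observation codes by history type:
#' \describe{
#'   \item{single}{0 = species not detected, 1 = detected.}
#'   \item{multistate}{0 = no detection, 1 = species detected but no adult
#'     male, 2 = adult male detected (code 2 subsumes 1 within a week).}
#'   \item{twospecies}{joint weekly code \code{yA + 2*yB} for species A and
#'     B, i.e. 0 = neither, 1 = A only, 2 = B only, 3 = both.}
#' }
#'
#' @slot siteIds character vector of site identifiers (rownames of matrices).
#' @slot layout the [SeasonLayout-class].
#' @slot observations integer site x week matrix of codes (-1 missing).
#' @slot effort integer site x week matrix of active camera days.
#' @slot type one of "single", "multistate", "twospecies".
#'
#' @seealso [detectionHistory()], [aggregateWeekly()], [readPAO()]
#' @exportClass DetectionHistory
setClass("DetectionHistory",
  representation(siteIds = "character", layout = "SeasonLayout",
                 observations = "matrix", effort = "matrix",
                 type = "character"),
  validity = function(object) {
    msg <- character()
    o <- object@observations; e <- object@effort
    if (!all(dim(o) == dim(e)))
      return("observations and effort must have identical dimensions")
    if (nrow(o) != length(object@siteIds))
      return("one matrix row per site id required")
    if (ncol(o) != object@layout@totalWeeks)
      return("one matrix column per weekly occasion required")
    if (!object@type %in% c("single", "multistate", "twospecies"))
      return("type must be single, multistate or twospecies")
    if (any(e < 0 | e > 7, na.rm = TRUE))
      msg <- c(msg, "effort must be active days in 0..7")
    if (!all((o == OBS_MISSING) == (e == 0)))
      msg <- c(msg, "observations must be -1 exactly where effort is 0")
    maxCode <- switch(object@type, single = 1L, multistate = 2L, twospecies = 3L)
    obs <- o[o != OBS_MISSING]
    if (length(obs) && (any(obs < 0) || any(obs > maxCode)))
      msg <- c(msg, sprintf("non-missing codes must lie in 0..%d for type '%s'",
                            maxCode, object@type))
    if (length(msg)) msg else TRUE
  })

#' Construct a DetectionHistory
#'
#' @param observations integer site x week code matrix (-1 where effort 0).
#' @param effort integer site x week matrix of active days (0-7).
#' @param layout a [SeasonLayout-class] whose totalWeeks matches the columns.
#' @param siteIds site identifiers; defaults to rownames(observations) or
#'   "site01", "site02", ...
#' @param type history type: "single", "multistate" or "twospecies".
#' @return A validated [DetectionHistory-class].
#' @export
detectionHistory <- function(observations, effort, layout, siteIds = NULL,
                             type = c("single", "multistate", "twospecies")) {
  type <- match.arg(type)
  observations <- as.matrix(observations); storage.mode(observations) <- "integer"
  effort <- as.matrix(effort); storage.mode(effort) <- "integer"
  if (is.null(siteIds))
    siteIds <- rownames(observations) %||% sprintf("site%02d", seq_len(nrow(observations)))
  dimnames(observations) <- list(siteIds, NULL)
  dimnames(effort) <- list(siteIds, NULL)
  new("DetectionHistory", siteIds = as.character(siteIds), layout = layout,
      observations = observations, effort = effort, type = type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn detectionHistory observation code matrix.
#' @param x a [DetectionHistory-class].
#' @export
observations <- function(x) x@observations

#' @describeIn detectionHistory effort (active days) matrix.
#' @export
effortMatrix <- function(x) x@effort

#' @describeIn detectionHistory site identifiers.
#' @export
siteIds <- function(x) x@siteIds

#' @describeIn detectionHistory the season layout.
#' @export
studyLayout <- function(x) x@layout

#' @describeIn detectionHistory history type string.
#' @export
historyType <- function(x) x@type

setMethod("show", "DetectionHistory", function(object) {
  o <- object@observations
  cat(sprintf("DetectionHistory ('%s'): %d sites x %d weeks, %d seasons\n",
              object@type, nrow(o), ncol(o), nSeasons(object@layout)))
  nm <- sum(o == OBS_MISSING)
  cat(sprintf("  missing site-weeks: %d (%.1f%%); detections: %d\n",
              nm, 100 * nm / length(o), sum(o > 0)))
})

#' Per-site habitat covariates
#'
#' Holds the site-level habitat measurements used as occupancy/detection
#' covariates: direct, diffuse and total solar radiation transmitted through
#' the canopy (total mols m^-2 day^-1, measured separately for winter and
#' summer), mineral soil C:N ratio, soil pH, Bray-2 available phosphorus
#' (ug g^-1), and the plant-composition NMDS axis-1 score. Solar covariates
#' enter models as square roots and soil covariates as natural logarithms
#' (see [transformCovariates()]); \code{transformed} records whether the
#' transform has been applied, and \code{raw} keeps the original scale for
#' median-policy prediction grids and back-transformation.
#'
#' @slot data data.frame, one row per site; column \code{site} plus any of
#'   \code{direct_winter, direct_summer, diffuse_winter, diffuse_summer,
#'   total_winter, total_summer, cn, ph, p, axis1}.
#' @slot raw the untransformed data.frame (identical to \code{data} until
#'   [transformCovariates()] is applied).
#' @slot transformed logical flag.
#' @exportClass SiteCovariates
setClass("SiteCovariates",
  representation(data = "data.frame", raw = "data.frame", transformed = "logical"),
  validity = function(object) {
    if (!"site" %in% names(object@data)) return("data must have a 'site' column")
    if (anyDuplicated(object@data$site)) return("duplicate site ids")
    TRUE
  })

#' Construct a SiteCovariates object
#'
#' @param data data.frame with a \code{site} column and covariate columns on
#'   the raw measurement scale.
#' @return A [SiteCovariates-class] with \code{transformed = FALSE}.
#' @export
siteCovariates <- function(data) {
  data <- as.data.frame(data)
  data$site <- as.character(data$site)
  new("SiteCovariates", data = data, raw = data, transformed = FALSE)
}

#' @describeIn siteCovariates covariate data.frame (current scale).
#' @param x a [SiteCovariates-class].
#' @export
covariateData <- function(x) x@data

setMethod("show", "SiteCovariates", function(object) {
  cat(sprintf("SiteCovariates: %d sites, %d covariates (%s scale)\n",
              nrow(object@data), ncol(object@data) - 1L,
              if (object@transformed) "transformed" else "raw"))
  cat(" ", paste(setdiff(names(object@data), "site"), collapse = ", "), "\n")
})

#' Symbolic occupancy model specification
#'
#' Describes which terms enter each linear predictor of one candidate model.
#' All probabilities use the logit link. A seasonal (or, for the two-species
#' family, species) factor is always present on occupancy and detection; at
#' most one habitat covariate enters a model, either additively (same slope
#' in both factor levels) or as an interaction (level-specific slopes).
#' Camera effort ("Number" of active days) is a detection covariate in every
#' multiseason and two-species model. The multistate family instead varies
#' the conditional-occupancy (R), detection (with or without a latent-state
#' effect) and conditional-detection (delta) structures over a fixed grid.
#'
#' @slot family "multiseason", "multistate" or "twospecies".
#' @slot covariate habitat covariate name ("direct", "diffuse", "total",
#'   "cn", "ph", "p", "axis1") or NA for the factor-only null model.
#' @slot psiMode covariate mode on occupancy: "none", "additive",
#'   "interaction".
#' @slot pMode covariate mode on detection: "none", "additive",
#'   "interaction".
#' @slot rTerms multistate conditional occupancy: "constant" or "season".
#' @slot pStateTerms multistate detection: "season", "state_add",
#'   "state_int".
#' @slot deltaTerms multistate conditional detection: "constant" or
#'   "season".
#' @slot etaFree logical; two-species co-occurrence parameter estimated
#'   (TRUE) or fixed at 0, i.e. independence (FALSE, default).
#' @slot effortTerm logical; include camera effort ("Number" of active
#'   days) in the detection predictor (default TRUE; ignored by the
#'   multistate family, whose model grid carries no effort term).
#' @seealso [modelSpec()], [specLabel()], [buildCandidateSet()]
#' @exportClass OccuModelSpec
setClass("OccuModelSpec",
  representation(family = "character", covariate = "character",
                 psiMode = "character", pMode = "character",
                 rTerms = "character", pStateTerms = "character",
                 deltaTerms = "character", etaFree = "logical",
                 effortTerm = "logical"),
  prototype(covariate = NA_character_, psiMode = "none", pMode = "none",
            rTerms = "constant", pStateTerms = "season",
            deltaTerms = "constant", etaFree = FALSE, effortTerm = TRUE),
  validity = function(object) {
    msg <- character()
    if (!object@family %in% c("multiseason", "multistate", "twospecies"))
      msg <- c(msg, "unknown family")
    if (!object@psiMode %in% c("none", "additive", "interaction") ||
        !object@pMode %in% c("none", "additive", "interaction"))
      msg <- c(msg, "modes must be none/additive/interaction")
    if (!is.na(object@covariate) &&
        !object@covariate %in% c("direct", "diffuse", "total", "cn", "ph", "p", "axis1"))
      msg <- c(msg, "unknown covariate")
    if (is.na(object@covariate) &&
        (object@psiMode != "none" || object@pMode != "none"))
      msg <- c(msg, "null model cannot carry covariate modes")
    if (!object@rTerms %in% c("constant", "season")) msg <- c(msg, "bad rTerms")
    if (!object@pStateTerms %in% c("season", "state_add", "state_int"))
      msg <- c(msg, "bad pStateTerms")
    if (!object@deltaTerms %in% c("constant", "season")) msg <- c(msg, "bad deltaTerms")
    if (length(msg)) msg else TRUE
  })

#' Construct an OccuModelSpec
#'
#' @param family model family.
#' @param covariate habitat covariate name or NA (factor-only model).
#' @param psiMode,pMode covariate mode on occupancy / detection.
#' @param rTerms,pStateTerms,deltaTerms multistate structures (ignored
#'   otherwise).
#' @param etaFree estimate the two-species co-occurrence parameter?
#' @param effortTerm include the effort ("Number") detection covariate?
#' @return An [OccuModelSpec-class].
#' @examples
#' modelSpec("multiseason", "direct", psiMode = "additive", pMode = "additive")
#' @export
modelSpec <- function(family = c("multiseason", "multistate", "twospecies"),
                      covariate = NA_character_,
                      psiMode = "none", pMode = "none",
                      rTerms = "constant", pStateTerms = "season",
                      deltaTerms = "constant", etaFree = FALSE,
                      effortTerm = TRUE) {
  family <- match.arg(family)
  new("OccuModelSpec", family = family, covariate = as.character(covariate),
      psiMode = psiMode, pMode = pMode, rTerms = rTerms,
      pStateTerms = pStateTerms, deltaTerms = deltaTerms, etaFree = etaFree,
      effortTerm = effortTerm)
}

setMethod("show", "OccuModelSpec", function(object) {
  cat("OccuModelSpec:", specLabel(object), "\n")
})

#' Maximum-likelihood fit of one occupancy model
#'
#' @slot spec the fitted [OccuModelSpec-class].
#' @slot estimates named numeric vector of logit-scale coefficients.
#' @slot neg2LL twice the negative maximised log-likelihood.
#' @slot K number of estimated parameters.
#' @slot AIC \code{neg2LL + 2 K}.
#' @slot vcov K x K covariance matrix of the estimates (inverse observed
#'   information); a 0 x 0 matrix when the Hessian was singular.
#' @slot convergence list: per-start values, best start index, gradient
#'   norm, boundary flag for estimates driven to the probability boundary.
#' @slot data list carrying the history and covariates used (for
#'   prediction).
#' @exportClass OccuFit
setClass("OccuFit",
  representation(spec = "OccuModelSpec", estimates = "numeric",
                 neg2LL = "numeric", K = "integer", AIC = "numeric",
                 vcov = "matrix", convergence = "list", data = "list"),
  validity = function(object) {
    if (abs(object@AIC - (object@neg2LL + 2 * object@K)) > 1e-8)
      return("AIC must equal neg2LL + 2K")
    if (nrow(object@vcov) > 0 && nrow(object@vcov) != object@K)
      return("vcov dimension must equal K")
    TRUE
  })

setMethod("show", "OccuFit", function(object) {
  cat("OccuFit:", specLabel(object@spec), "\n")
  cat(sprintf("  -2LL = %.2f  K = %d  AIC = %.2f\n",
              object@neg2LL, object@K, object@AIC))
  if (isTRUE(object@convergence$boundary))
    cat("  note: estimate(s) at probability boundary\n")
})

#' @describeIn modelSpec the spec of a fitted model.
#' @param fit an [OccuFit-class].
#' @export
fitSpec <- function(fit) fit@spec

#' @describeIn modelSpec logit-scale coefficient estimates of a fit.
#' @export
estimates <- function(fit) fit@estimates
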