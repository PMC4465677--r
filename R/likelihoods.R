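## Likelihood cores for the three hierarchical occupancy families.
## All probabilities are logit-linked; each family's nll returns twice the
## negative log-likelihood (-2LL) so that AIC = nll + 2K directly.

COV_DISPLAY <- c(direct = "Direct", diffuse = "Diffuse", total = "Total",
                 cn = "C:N ratio", ph = "pH", p = "P", axis1 = "Axis 1")

## covariate vector (transformed scale) for history sites, resolving
## seasonal solar columns by season label
covariateVector <- function(covars, name, seasonLabel, sites) {
  col <- if (name %in% c("direct", "diffuse", "total"))
    paste0(name, "_", seasonLabel) else name
  d <- covars@data
  if (!col %in% names(d))
    stop("covariate '", col, "' absent from SiteCovariates")
  v <- d[[col]][match(sites, d$site)]
  if (any(is.na(v))) stop("covariate '", col, "' missing for some sites")
  v
}

## long table of non-missing site-weeks
siteWeekTable <- function(history) {
  o <- history@observations; e <- history@effort
  ws <- weekSeason(history@layout)
  idx <- which(e > 0L, arr.ind = TRUE)
  data.frame(site = idx[, 1L], week = idx[, 2L], season = ws[idx[, 2L]],
             y = o[idx], effort = e[idx])
}

## occupancy/detection design columns for the season-or-species factor plus
## at most one habitat covariate in mode none/additive/interaction
factorCovDesign <- function(indicator, cov, mode, prefix, indName) {
  X <- cbind(`(Intercept)` = rep(1, length(indicator)))
  if (length(unique(indicator)) > 1L) X <- cbind(X, setNames2(indicator, indName))
  if (mode != "none") {
    X <- cbind(X, setNames2(cov, "cov"))
    if (mode == "interaction") X <- cbind(X, setNames2(cov * indicator, paste0("cov:", indName)))
  }
  colnames(X) <- paste0(prefix, "_", colnames(X))
  X
}
setNames2 <- function(v, nm) { m <- cbind(v); colnames(m) <- nm; m }

#' Build design matrices for an occupancy model
#'
#' Expands a symbolic [OccuModelSpec-class] into the numeric design
#' matrices its likelihood needs: an occupancy design with one row per
#' site-season (multiseason/multistate) or per site-species (two-species),
#' and a detection design with one row per active site-week (two rows, one
#' per species, for the two-species family). The seasonal factor has two
#' levels (winter/summer) shared across years; habitat covariates enter on
#' their transformed scale, additively or interacting with the factor;
#' camera effort (active days) is appended to every multiseason and
#' two-species detection design. Weeks with zero effort are excluded.
#'
#' @param spec an [OccuModelSpec-class].
#' @param history a [DetectionHistory-class] of the matching type.
#' @param covars a [SiteCovariates-class]; transformed automatically if
#'   still on the raw scale.
#' @return A list of design matrices, index vectors and parameter names
#'   consumed by [nllMultiseason()], [nllMultistate()], [nllTwospecies()]
#'   and [fitOccu()].
#' @export
buildDesign <- function(spec, history, covars) {
  covars <- transformCovariates(covars)
  fam <- spec@family
  expectType <- c(multiseason = "single", multistate = "multistate",
                  twospecies = "twospecies")[fam]
  if (history@type != expectType)
    stop("history type '", history@type, "' does not match family '", fam, "'")
  lay <- history@layout
  sw <- siteWeekTable(history)
  seasLab <- lay@seasons$label
  nSite <- length(history@siteIds)
  nSeas <- nSeasons(lay)

  if (fam %in% c("multiseason", "multistate")) {
    ## site-season grid, season-major: ss = (t-1)*nSite + i
    ssSeason <- rep(seq_len(nSeas), each = nSite)
    ssSite <- rep(seq_len(nSite), nSeas)
    summerSS <- as.numeric(seasLab[ssSeason] == "summer")
    sw$ss <- (sw$season - 1L) * nSite + sw$site
    summerSW <- as.numeric(seasLab[sw$season] == "summer")
    covSS <- covSW <- NULL
    if (!is.na(spec@covariate)) {
      covBySeason <- matrix(vapply(seq_len(nSeas), function(t)
        covariateVector(covars, spec@covariate, seasLab[t], history@siteIds),
        numeric(nSite)), nrow = nSite)
      covSS <- covBySeason[cbind(ssSite, ssSeason)]
      covSW <- covBySeason[cbind(sw$site, sw$season)]
    }
  }

  dd <- switch(fam,
    multiseason = {
      psiX <- factorCovDesign(summerSS, covSS, spec@psiMode, "psi", "seasonSummer")
      pX <- factorCovDesign(summerSW, covSW, spec@pMode, "p", "seasonSummer")
      if (spec@effortTerm) pX <- cbind(pX, p_number = sw$effort)
      anyDet <- groupSum(as.numeric(sw$y > 0), sw$ss, nSite * nSeas)
      list(family = fam, psiX = psiX, pX = pX, ss = sw$ss, y = sw$y,
           nSS = nSite * nSeas, anyDet = anyDet,
           blocks = list(psi = colnames(psiX), p = colnames(pX)))
    },
    multistate = {
      psiX <- factorCovDesign(summerSS, NULL, "none", "psi", "seasonSummer")
      rX <- if (spec@rTerms == "season")
        factorCovDesign(summerSS, NULL, "none", "R", "seasonSummer")
      else setNames2(rep(1, nSite * nSeas), "R_(Intercept)")
      pX <- factorCovDesign(summerSW, NULL, "none", "p", "seasonSummer")
      stateX <- switch(spec@pStateTerms,
        season = NULL,
        state_add = setNames2(rep(1, nrow(sw)), "p_stateMale"),
        state_int = {
          m <- cbind(rep(1, nrow(sw)), summerSW)
          colnames(m) <- c("p_stateMale", "p_stateMale:seasonSummer")
          m
        })
      dX <- if (spec@deltaTerms == "season")
        factorCovDesign(summerSW, NULL, "none", "delta", "seasonSummer")
      else setNames2(rep(1, nrow(sw)), "delta_(Intercept)")
      list(family = fam, psiX = psiX, rX = rX, pX = pX, stateX = stateX,
           dX = dX, ss = sw$ss, y = sw$y, nSS = nSite * nSeas,
           blocks = list(psi = colnames(psiX), R = colnames(rX),
                         p = c(colnames(pX), colnames(stateX)),
                         delta = colnames(dX)))
    },
    twospecies = {
      if (nSeas != 1L)
        stop("the two-species family expects a single-season history")
      yA <- sw$y %% 2L
      yB <- sw$y %/% 2L
      covSite <- if (!is.na(spec@covariate))
        covariateVector(covars, spec@covariate, seasLab[1L], history@siteIds)
      ## occupancy rows: species A then species B per site
      spB <- rep(c(0, 1), each = nSite)
      covOcc <- if (!is.na(spec@covariate)) rep(covSite, 2L)
      psiX <- factorCovDesign(spB, covOcc, spec@psiMode, "psi", "speciesB")
      ## detection rows: (site-week, species A) then (site-week, species B)
      spBW <- rep(c(0, 1), each = nrow(sw))
      covW <- if (!is.na(spec@covariate)) rep(covSite[sw$site], 2L)
      pX <- factorCovDesign(spBW, covW, spec@pMode, "p", "speciesB")
      if (spec@effortTerm) pX <- cbind(pX, p_number = rep(sw$effort, 2L))
      blocks <- list(psi = colnames(psiX), p = colnames(pX))
      if (spec@etaFree) blocks$eta <- "eta"
      list(family = fam, psiX = psiX, pX = pX, site = sw$site, yA = yA,
           yB = yB, nSite = nSite, nSW = nrow(sw), etaFree = spec@etaFree,
           blocks = blocks)
    })
  dd$parNames <- unlist(dd$blocks, use.names = FALSE)
  dd$K <- length(dd$parNames)
  dd$spec <- spec
  dd
}

blockPar <- function(par, dd, block) par[match(dd$blocks[[block]], dd$parNames)]

logClamp <- function(x) log(pmax(x, 1e-300))

## sum v by group over 1..n (groups with no rows contribute 0)
groupSum <- function(v, g, n) {
  out <- numeric(n)
  s <- rowsum(v, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Multiseason (implicit-dynamics) occupancy likelihood
#'
#' Twice the negative log-likelihood of a single-species multiseason
#' detection history. Seasons enter as independent primary periods (the
#' implicit-dynamics assumption: a season's occupancy state is drawn afresh,
#' so between-season changes are unmodelled). Per site-season the likelihood
#' mixes the occupied branch (Bernoulli weekly detections with probability
#' p) with the unoccupied branch, which has mass only when no week recorded
#' a detection:
#' \deqn{L = \psi \prod_w p^{y_w} (1-p)^{1-y_w} + (1-\psi)\,[\,\mathrm{all}\ y_w = 0\,]}
#'
#' @param par packed coefficient vector in the order \code{dd$parNames}.
#' @param dd design list from [buildDesign()].
#' @return -2 log-likelihood (scalar).
#' @export
nllMultiseason <- function(par, dd) {
  psi <- plogis(drop(dd$psiX %*% blockPar(par, dd, "psi")))
  p <- plogis(drop(dd$pX %*% blockPar(par, dd, "p")))
  condLL <- groupSum(dd$y * logClamp(p) + (1 - dd$y) * logClamp(1 - p),
                     dd$ss, dd$nSS)
  L <- psi * exp(condLL) + (1 - psi) * (dd$anyDet == 0)
  -2 * sum(logClamp(L))
}

#' Multistate occupancy likelihood with conditional detection
#'
#' Twice the negative log-likelihood of a three-state weekly history
#' (0 = no detection, 1 = species without the focal age-sex class,
#' 2 = focal class detected). Latent site-season states are: empty
#' (probability 1-psi), occupied without the focal class (psi(1-R)) and
#' occupied with it (psi R). Weekly detection uses p1 in state 2; in state 3
#' a week is detected with p2 and a detection includes the focal class with
#' conditional probability delta. Histories containing a code 2 put zero
#' mass on the first two states.
#'
#' @inheritParams nllMultiseason
#' @return -2 log-likelihood (scalar).
#' @export
nllMultistate <- function(par, dd) {
  psi <- plogis(drop(dd$psiX %*% blockPar(par, dd, "psi")))
  R <- plogis(drop(dd$rX %*% blockPar(par, dd, "R")))
  pPar <- blockPar(par, dd, "p")
  nBase <- ncol(dd$pX)
  lpBase <- drop(dd$pX %*% pPar[seq_len(nBase)])
  lp2 <- if (is.null(dd$stateX)) lpBase
         else lpBase + drop(dd$stateX %*% pPar[-seq_len(nBase)])
  p1 <- plogis(lpBase)
  p2 <- plogis(lp2)
  delta <- plogis(drop(dd$dX %*% blockPar(par, dd, "delta")))
  y <- dd$y
  all0 <- groupSum(as.numeric(y > 0), dd$ss, dd$nSS) == 0
  has2 <- groupSum(as.numeric(y == 2), dd$ss, dd$nSS) > 0
  ll2 <- groupSum((y == 1) * logClamp(p1) + (y == 0) * logClamp(1 - p1),
                  dd$ss, dd$nSS)
  ll3 <- groupSum((y == 0) * logClamp(1 - p2) +
                  (y == 1) * (logClamp(p2) + logClamp(1 - delta)) +
                  (y == 2) * (logClamp(p2) + logClamp(delta)),
                  dd$ss, dd$nSS)
  L <- (1 - psi) * all0 + psi * (1 - R) * exp(ll2) * (!has2) +
    psi * R * exp(ll3)
  -2 * sum(logClamp(L))
}

#' Two-species co-occurrence likelihood
#'
#' Twice the negative log-likelihood of paired weekly histories for species
#' A and B in one season. The site is in one of four latent states (both,
#' A only, B only, neither) with probabilities derived from psi_A, psi_B and
#' a log-scale co-occurrence parameter eta: psi_AB = psi_A psi_B exp(eta),
#' so eta = 0 gives independence. Weekly detections are conditionally
#' independent given the state, with species-specific logit-linked
#' probabilities. State probabilities pushed outside the Frechet bounds by
#' extreme eta are clamped and penalised rather than raising an error.
#'
#' @inheritParams nllMultiseason
#' @return -2 log-likelihood (scalar).
#' @export
nllTwospecies <- function(par, dd) {
  psiSp <- plogis(drop(dd$psiX %*% blockPar(par, dd, "psi")))
  psiA <- psiSp[seq_len(dd$nSite)]
  psiB <- psiSp[dd$nSite + seq_len(dd$nSite)]
  eta <- if (dd$etaFree) par[match("eta", dd$parNames)] else 0
  psiAB <- psiA * psiB * exp(eta)
  lo <- pmax(0, psiA + psiB - 1)
  hi <- pmin(psiA, psiB)
  pen <- sum(pmax(psiAB - hi, 0)^2 + pmax(lo - psiAB, 0)^2)
  psiAB <- pmin(pmax(psiAB, lo), hi)
  p <- plogis(drop(dd$pX %*% blockPar(par, dd, "p")))
  pA <- p[seq_len(dd$nSW)]
  pB <- p[dd$nSW + seq_len(dd$nSW)]
  sA <- groupSum(dd$yA * logClamp(pA) + (1 - dd$yA) * logClamp(1 - pA),
                 dd$site, dd$nSite)
  sB <- groupSum(dd$yB * logClamp(pB) + (1 - dd$yB) * logClamp(1 - pB),
                 dd$site, dd$nSite)
  noA <- groupSum(dd$yA, dd$site, dd$nSite) == 0
  noB <- groupSum(dd$yB, dd$site, dd$nSite) == 0
  L <- psiAB * exp(sA + sB) +
    (psiA - psiAB) * exp(sA) * noB +
    (psiB - psiAB) * exp(sB) * noA +
    (1 - psiA - psiB + psiAB) * (noA & noB)
  -2 * sum(logClamp(L)) + 1e4 * pen
}

nllForFamily <- function(family) {
  switch(family, multiseason = nllMultiseason, multistate = nllMultistate,
         twospecies = nllTwospecies)
}
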