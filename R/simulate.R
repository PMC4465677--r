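## Seeded synthetic camera-trap study generator: covariate landscape,
## camera effort, and detection histories under each likelihood family,
## with known parameters.

#' Default simulation configuration
#'
#' Returns the configuration of the synthetic study emulated by the
#' generator: a 25-site camera grid sampled over four seasons (two winters,
#' two summers) of 13 weekly occasions each; habitat covariates drawn from
#' truncated normal distributions calibrated so that each covariate's range
#' and mean match the study conditions (winter direct solar 0.0-5.0 mols
#' m^-2 day^-1 with mean 0.7, soil C:N 11-24 with mean 14.9, available P
#' 3-41 ug g^-1 with mean 13.5, and so on), with total solar = direct +
#' diffuse by construction; camera effort of 7 days per site-week thinned
#' by rare whole-week outages (probability \code{dropout}) and per-day
#' outages (probability \code{dayOut}); and logit-scale true parameters for
#' each model family. Red deer winter absence is reproduced by
#' season-specific occupancy probabilities near zero in winter.
#'
#' @param seed integer seed; recorded in the config and governing all
#'   draws.
#' @param nSites number of camera sites.
#' @param nWeeks weekly occasions per season.
#' @return A named list of class \code{"occuSimConfig"}.
#' @export
simulationConfig <- function(seed = 1, nSites = 25, nWeeks = 13) {
  layout <- seasonLayout(c("winter", "summer", "winter", "summer"),
                         c(2010, 2010, 2011, 2011),
                         c("2010-06-14", "2010-12-13", "2011-06-13", "2011-12-12"),
                         rep(nWeeks, 4))
  structure(list(
    seed = as.integer(seed),
    nSites = as.integer(nSites),
    layout = layout,
    covariates = list(
      direct_winter  = c(lo = 0.0, hi = 5.0, mean = 0.7, sd = 1.0),
      diffuse_winter = c(lo = 0.2, hi = 2.4, mean = 0.6, sd = 0.5),
      direct_summer  = c(lo = 0.3, hi = 9.5, mean = 1.9, sd = 1.0),
      diffuse_summer = c(lo = 0.4, hi = 5.3, mean = 1.4, sd = 1.0),
      cn             = c(lo = 11,  hi = 24,  mean = 14.9, sd = 3.0),
      ph             = c(lo = 5.4, hi = 6.9, mean = 6.2, sd = 0.5),
      p              = c(lo = 3,   hi = 41,  mean = 13.5, sd = 9.5),
      axis1          = c(lo = -2,  hi = 2,   mean = 0, sd = 1)),
    effort = list(dropout = 0.003, dayOut = 0.012),
    multiseason = list(
      psi = c(intercept = 0.7, seasonSummer = 0.25, direct = 0.8),
      p = c(intercept = -2.2, seasonSummer = 0, direct = 0.4, number = 0.15)),
    multistate = list(
      psi = c(intercept = 0.9, seasonSummer = 0.3),
      R = c(intercept = 0.9, seasonSummer = -1.2),
      p1 = c(intercept = -1.0, seasonSummer = 0),
      stateEffect = 0.5,
      delta = c(intercept = 0, seasonSummer = -1.1)),
    twospecies = list(
      psiA = 2.9, psiB = 1.27, eta = 0,
      pA = c(intercept = -2.0, direct = 0.5, number = 0.1),
      pB = c(intercept = -2.4, direct = 0, number = 0.1)),
    red = list(psiBySeason = c(0.005, 0.18, 0.03, 0.80), p = 0.2)),
    class = "occuSimConfig")
}

## truncated-normal draws whose *truncated* mean equals the target: the
## location parameter is solved by uniroot before rejection sampling
rtruncCalibrated <- function(n, lo, hi, mean, sd) {
  if (mean <= lo || mean >= hi) stop("infeasible range/mean combination")
  truncMean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  mu <- uniroot(function(m) truncMean(m) - mean,
                lower = lo - 6 * sd, upper = hi + 6 * sd)$root
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- rnorm(length(need), mu, sd)
    ok <- cand >= lo & cand <= hi
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic covariate landscape
#'
#' Draws per-site habitat covariates from the truncated normal
#' distributions in the config (each calibrated so its truncated mean
#' matches the configured mean) and sets total solar radiation to direct
#' plus diffuse by construction. Deterministic for a given config seed.
#'
#' @param config a [simulationConfig()] list.
#' @return A [SiteCovariates-class] on the raw scale.
#' @export
generateLandscape <- function(config) {
  set.seed(config$seed)
  n <- config$nSites
  d <- data.frame(site = sprintf("site%02d", seq_len(n)))
  for (nm in names(config$covariates)) {
    cc <- config$covariates[[nm]]
    d[[nm]] <- rtruncCalibrated(n, cc["lo"], cc["hi"], cc["mean"], cc["sd"])
  }
  d$total_winter <- d$direct_winter + d$diffuse_winter
  d$total_summer <- d$direct_summer + d$diffuse_summer
  siteCovariates(d)
}

simulateEffort <- function(config, nSites, totalWeeks) {
  e <- matrix(7L, nSites, totalWeeks,
              dimnames = list(sprintf("site%02d", seq_len(nSites)), NULL))
  drop <- matrix(runif(length(e)) < config$effort$dropout, nSites)
  e <- e - matrix(rbinom(length(e), 7L, config$effort$dayOut), nSites)
  e[drop] <- 0L
  e
}

#' Simulate a detection history under a model family
#'
#' Draws latent occupancy states per site-season from the configured
#' occupancy probabilities, then weekly observations given the state and
#' the detection model, on a simulated effort pattern (weeks with zero
#' effort are missing). For the multistate family a state-3 site-week is
#' coded \{0, 1, 2\} with probabilities \{1-p2, p2(1-delta), p2 delta\}.
#' For the two-species family (single summer season) the two species are
#' drawn from the four-state latent distribution implied by psi_A, psi_B
#' and eta.
#'
#' @param config a [simulationConfig()] list.
#' @param family "multiseason", "multistate" or "twospecies".
#' @param covars optional pre-drawn [SiteCovariates-class]; drawn from the
#'   config when NULL.
#' @param effort optional pre-drawn effort matrix.
#' @return A [DetectionHistory-class] of the matching type.
#' @export
simulateHistory <- function(config, family = c("multiseason", "multistate", "twospecies"),
                            covars = NULL, effort = NULL) {
  family <- match.arg(family)
  if (is.null(covars)) covars <- generateLandscape(config)
  set.seed(config$seed + match(family, c("multiseason", "multistate", "twospecies")))
  lay <- config$layout
  n <- config$nSites
  if (family == "twospecies")
    lay <- seasonLayout("summer", 2011,
                        lay@seasons$start[nrow(lay@seasons)],
                        lay@seasons$nWeeks[nrow(lay@seasons)])
  if (is.null(effort)) effort <- simulateEffort(config, n, lay@totalWeeks)
  ws <- weekSeason(lay)
  sLab <- lay@seasons$label
  raw <- covars@raw
  sqrtDirect <- cbind(winter = sqrt(raw$direct_winter),
                      summer = sqrt(raw$direct_summer))
  obs <- matrix(0L, n, lay@totalWeeks, dimnames = dimnames(effort))

  if (family == "multiseason") {
    pr <- config$multiseason
    for (t in seq_len(nSeasons(lay))) {
      summer <- as.numeric(sLab[t] == "summer")
      sq <- sqrtDirect[, sLab[t]]
      psi <- plogis(pr$psi["intercept"] + pr$psi["seasonSummer"] * summer +
                      pr$psi["direct"] * sq)
      z <- rbinom(n, 1L, psi)
      for (w in which(ws == t)) {
        p <- plogis(pr$p["intercept"] + pr$p["seasonSummer"] * summer +
                      pr$p["direct"] * sq + pr$p["number"] * effort[, w])
        obs[, w] <- z * rbinom(n, 1L, p)
      }
    }
  } else if (family == "multistate") {
    pr <- config$multistate
    for (t in seq_len(nSeasons(lay))) {
      summer <- as.numeric(sLab[t] == "summer")
      psi <- plogis(pr$psi["intercept"] + pr$psi["seasonSummer"] * summer)
      R <- plogis(pr$R["intercept"] + pr$R["seasonSummer"] * summer)
      occ <- rbinom(n, 1L, psi)
      male <- occ * rbinom(n, 1L, R)      # state: 0 empty, 1 occupied, 2 male
      state <- occ + male
      p1 <- plogis(pr$p1["intercept"] + pr$p1["seasonSummer"] * summer)
      p2 <- plogis(pr$p1["intercept"] + pr$stateEffect + pr$p1["seasonSummer"] * summer)
      delta <- plogis(pr$delta["intercept"] + pr$delta["seasonSummer"] * summer)
      for (w in which(ws == t)) {
        det2 <- rbinom(n, 1L, p2)          # state-3 sites: any detection
        male2 <- rbinom(n, 1L, delta)      # ...and does it include a male
        code3 <- det2 * (1L + male2)
        code2 <- rbinom(n, 1L, p1)
        obs[, w] <- ifelse(state == 2L, code3, ifelse(state == 1L, code2, 0L))
      }
    }
  } else {
    pr <- config$twospecies
    psiA <- plogis(pr$psiA); psiB <- plogis(pr$psiB)
    psiAB <- min(max(psiA * psiB * exp(pr$eta), max(0, psiA + psiB - 1)),
                 min(psiA, psiB))
    stateProb <- c(both = psiAB, Aonly = psiA - psiAB, Bonly = psiB - psiAB,
                   neither = 1 - psiA - psiB + psiAB)
    st <- sample(1:4, n, replace = TRUE, prob = stateProb)
    zA <- as.integer(st %in% c(1L, 2L)); zB <- as.integer(st %in% c(1L, 3L))
    sq <- sqrtDirect[, "summer"]
    for (w in seq_len(lay@totalWeeks)) {
      pA <- plogis(pr$pA["intercept"] + pr$pA["direct"] * sq + pr$pA["number"] * effort[, w])
      pB <- plogis(pr$pB["intercept"] + pr$pB["direct"] * sq + pr$pB["number"] * effort[, w])
      obs[, w] <- zA * rbinom(n, 1L, pA) + 2L * zB * rbinom(n, 1L, pB)
    }
  }
  obs[effort == 0L] <- OBS_MISSING
  type <- c(multiseason = "single", multistate = "multistate",
            twospecies = "twospecies")[family]
  detectionHistory(obs, effort, lay, type = type)
}

## red deer: season-specific occupancy drawn directly (winter near zero)
simulateRed <- function(config, effort) {
  set.seed(config$seed + 5L)
  lay <- config$layout
  n <- config$nSites
  ws <- weekSeason(lay)
  obs <- matrix(0L, n, lay@totalWeeks, dimnames = dimnames(effort))
  for (t in seq_len(nSeasons(lay))) {
    z <- rbinom(n, 1L, config$red$psiBySeason[t])
    for (w in which(ws == t))
      obs[, w] <- z * rbinom(n, 1L, config$red$p)
  }
  obs[effort == 0L] <- OBS_MISSING
  detectionHistory(obs, effort, lay, type = "single")
}

#' Generate the synthetic study fixture
#'
#' A complete synthetic analogue of the camera-trap study: 25 sites, four
#' 13-week seasons (25 x 52 observation matrices), shared effort, a
#' covariate landscape, and detection histories for every family — the
#' focal species (single-species multiseason), its adult-male multistate
#' version, a sparse second species that vacates the area in winter, and
#' the joint two-species history for the final summer assembled from the
#' two single-species histories (so the species are independent by
#' construction). Regeneration with the same seed is byte-stable, including
#' the optional files written to \code{dir} (PAO histories, covariate CSV
#' and a YAML manifest of the true parameters).
#'
#' @param seed integer seed.
#' @param dir optional directory to write the fixture bundle into.
#' @return list: \code{rusa}, \code{red}, \code{multistate},
#'   \code{twospecies} ([DetectionHistory-class]), \code{covars}
#'   ([SiteCovariates-class]), \code{config}.
#' @export
makeStudyFixture <- function(seed = 1, dir = NULL) {
  config <- simulationConfig(seed = seed)
  covars <- generateLandscape(config)
  set.seed(seed + 10L)
  effort <- simulateEffort(config, config$nSites, config$layout@totalWeeks)
  rusa <- simulateHistory(config, "multiseason", covars = covars, effort = effort)
  ms <- simulateHistory(config, "multistate", covars = covars, effort = effort)
  red <- simulateRed(config, effort)
  ## joint summer-2011 history from the independent single-species draws
  lay <- config$layout
  last <- nSeasons(lay)
  cols <- lay@seasons$firstWeek[last] + seq_len(lay@seasons$nWeeks[last]) - 1L
  oA <- rusa@observations[, cols]; oB <- red@observations[, cols]
  e4 <- effort[, cols]
  o2 <- ifelse(e4 == 0L, OBS_MISSING, pmax(oA, 0L) + 2L * pmax(oB, 0L))
  lay4 <- seasonLayout(lay@seasons$label[last], lay@seasons$year[last],
                       lay@seasons$start[last], lay@seasons$nWeeks[last])
  two <- detectionHistory(o2, e4, lay4, siteIds = rusa@siteIds, type = "twospecies")
  out <- list(rusa = rusa, red = red, multistate = ms, twospecies = two,
              covars = covars, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writePAO(rusa, file.path(dir, "rusa_multiseason.pao"), covars)
    writePAO(ms, file.path(dir, "rusa_multistate.pao"), covars)
    writePAO(two, file.path(dir, "twospecies_summer2011.pao"), covars)
    write.csv(covars@raw, file.path(dir, "site_covariates.csv"), row.names = FALSE)
    manifest <- config
    manifest$layout <- lapply(seq_len(nSeasons(config$layout)), function(i)
      as.list(transform(config$layout@seasons[i, ], start = format(start))))
    yaml::write_yaml(manifest, file.path(dir, "true_parameters.yaml"))
  }
  out
}
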