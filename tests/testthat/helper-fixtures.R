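## Shared in-code fixtures for the test suite.

## full covariate table for n sites (raw scale), deterministic per seed
makeCovars <- function(n, seed = 99) {
  set.seed(seed)
  siteCovariates(data.frame(
    site = sprintf("site%02d", seq_len(n)),
    direct_winter = runif(n, 0, 5), diffuse_winter = runif(n, 0.2, 2.4),
    direct_summer = runif(n, 0.3, 9.5), diffuse_summer = runif(n, 0.4, 5.3),
    cn = runif(n, 11, 24), ph = runif(n, 5.4, 6.9), p = runif(n, 3, 41),
    axis1 = rnorm(n)))
}

oneSeason <- function(nWeeks = 3, label = "winter", year = 2010,
                      start = "2010-06-14") {
  seasonLayout(label, year, start, nWeeks)
}

fourSeasons <- function(nWeeks = 13) {
  seasonLayout(c("winter", "summer", "winter", "summer"),
               c(2010, 2010, 2011, 2011),
               c("2010-06-14", "2010-12-13", "2011-06-13", "2011-12-12"),
               rep(nWeeks, 4))
}

## history for a single site with full effort
oneSiteHistory <- function(codes, layout, type = "single") {
  detectionHistory(matrix(as.integer(codes), 1), matrix(7L, 1, length(codes)),
                   layout, siteIds = "site01", type = type)
}

## random valid history on a layout (property-test input)
randomHistory <- function(nSites, layout, type = "single", seed = 1,
                          pMissing = 0.1) {
  set.seed(seed)
  maxCode <- c(single = 1L, multistate = 2L, twospecies = 3L)[type]
  W <- layout@totalWeeks
  eff <- matrix(sample(0:7, nSites * W, replace = TRUE,
                       prob = c(pMissing, rep((1 - pMissing) / 7, 7))),
                nSites, W)
  obs <- matrix(sample(0:maxCode, nSites * W, replace = TRUE), nSites, W)
  obs[eff == 0L] <- -1L
  detectionHistory(obs, eff, layout,
                   siteIds = sprintf("site%02d", seq_len(nSites)), type = type)
}

## image-record data.frame builder
imageRecords <- function(site, minutes, species = "rusa", age = "adult",
                         sex = "female", origin = "2010-06-15 12:00:00") {
  n <- max(length(site), length(minutes), length(species), length(age), length(sex))
  data.frame(site = rep_len(site, n),
             timestamp = as.POSIXct(origin, tz = "UTC") + rep_len(minutes, n) * 60,
             species = rep_len(species, n), age = rep_len(age, n),
             sex = rep_len(sex, n), stringsAsFactors = FALSE)
}

## independent brute-force UPGMA on a dissimilarity matrix: returns merge
## heights in order (the oracle for clusterGroupAverage)
bruteUPGMA <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      h <- mean(d[clusters[[a]], clusters[[b]]])
      if (h < best[1]) best <- c(h, a, b)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}

## total likelihood mass over the complete outcome space of one site
enumSum <- function(family, spec, layout, codes, par, cv,
                    type = c(multiseason = "single", multistate = "multistate",
                             twospecies = "twospecies")[family]) {
  nll <- switch(family, multiseason = nllMultiseason,
                multistate = nllMultistate, twospecies = nllTwospecies)
  W <- layout@totalWeeks
  grid <- do.call(expand.grid, rep(list(codes), W))
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    h <- oneSiteHistory(unlist(grid[i, ]), layout, type = type)
    dd <- buildDesign(spec, h, cv)
    tot <- tot + exp(-nll(par, dd) / 2)
  }
  tot
}
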