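## Plant-composition pipeline: cover-abundance scores -> importance values ->
## Bray-Curtis similarity -> NMDS ordination / UPGMA clustering -> SIMPER.

## midpoints of the modified Braun-Blanquet cover classes
## 1 = <1%, 2 = 1-5%, 3 = 6-25%, 4 = 26-50%, 5 = 51-75%, 6 = 76-100%
COVER_MIDPOINTS <- c(0.5, 3, 15.5, 38, 63, 88)

#' Convert cover-abundance scores to species importance values
#'
#' Cover-abundance is scored per species in each of seven fixed height tiers
#' on a 1-6 scale (class midpoints 0.5, 3, 15.5, 38, 63, 88 percent cover;
#' 0 = absent). The importance value of a species at a site is the sum of
#' class midpoints over tiers, reflecting occupied volume rather than
#' projected cover. Raising any class score never lowers the importance
#' value.
#'
#' @param scores long-format data.frame with columns \code{site},
#'   \code{species}, \code{tier}, \code{class} (integers 0-6).
#' @return Numeric sites x species matrix of importance values.
#' @export
coverToImportance <- function(scores) {
  need <- c("site", "species", "class")
  if (!all(need %in% names(scores)))
    stop("scores must have columns site, species, tier, class")
  cls <- scores$class
  if (any(cls < 0 | cls > 6 | cls != round(cls)))
    stop("cover-abundance class must be an integer in 0..6")
  mid <- ifelse(cls == 0, 0, COVER_MIDPOINTS[pmax(cls, 1)])
  sites <- sort(unique(as.character(scores$site)))
  spp <- sort(unique(as.character(scores$species)))
  m <- matrix(0, length(sites), length(spp), dimnames = list(sites, spp))
  agg <- tapply(mid, list(as.character(scores$site), as.character(scores$species)),
                sum, default = 0)
  m[rownames(agg), colnames(agg)] <- agg
  m
}

#' Standardise by site totals and fourth-root transform
#'
#' Each row (site) is divided by its total, accounting for differences in
#' total sampled volume between sites, and the proportions are then
#' fourth-root transformed to down-weight dominant species relative to rare
#' ones. Standardisation precedes the transform; scaling a row by a constant
#' leaves the output unchanged.
#'
#' @param imp non-negative sites x species importance matrix.
#' @param percent multiply proportions by 100 before the fourth root
#'   (default FALSE).
#' @return Transformed matrix of the same shape.
#' @export
standardizeFourthRoot <- function(imp, percent = FALSE) {
  imp <- as.matrix(imp)
  if (any(imp < 0)) stop("importance values must be non-negative")
  tot <- rowSums(imp)
  if (any(tot == 0)) stop("site(s) with no species: ",
                          paste(rownames(imp)[tot == 0], collapse = ", "))
  p <- imp / tot
  if (percent) p <- 100 * p
  p^0.25
}

#' Bray-Curtis similarity between sites
#'
#' S(i, j) = 1 - sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk), computed on the
#' (typically standardised, fourth-root transformed) abundance matrix.
#' Returns a symmetric matrix with unit diagonal. A pair of all-zero sites
#' has undefined similarity and is returned as NA with a warning.
#'
#' @param mat non-negative sites x species matrix.
#' @return Sites x sites similarity matrix in [0, 1].
#' @export
brayCurtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  d <- as.matrix(suppressWarnings(vegan::vegdist(mat, method = "bray")))
  s <- 1 - d
  diag(s) <- 1
  if (any(is.na(s))) warning("all-zero site pair(s): similarity undefined (NA)")
  dimnames(s) <- list(rownames(mat), rownames(mat))
  s
}

## Kruskal stress-1 of a configuration against a dissimilarity vector.
## Monotone fit by isotonic regression on the dissimilarity ordering, with
## primary (weak) tie treatment: ties in the dissimilarities are ordered by
## the current configuration distances so that tied pairs are unconstrained.
kruskalStress <- function(X, delta) {
  d <- as.vector(dist(X))
  ord <- order(delta, d)
  fit <- isoreg(d[ord])$yf
  sqrt(sum((d[ord] - fit)^2) / sum(d^2))
}

#' Non-metric multidimensional scaling of a similarity matrix
#'
#' Embeds sites in \code{dims} dimensions so that configuration distances
#' rank-match the input dissimilarities (1 - similarity), minimising Kruskal
#' stress-1. The monotone reference is fitted by isotonic regression
#' (primary tie treatment) and the configuration is optimised by
#' quasi-Newton descent, restarted from \code{restarts} random Gaussian
#' configurations plus one classical-scaling start; the lowest-stress
#' solution wins, ties broken by restart index. The returned configuration
#' is centred and rotated to its principal axes, so Axis 1 carries the main
#' compositional gradient. Stress is invariant to rotation, reflection and
#' uniform scaling.
#'
#' @param sim similarity matrix (see [brayCurtis()]).
#' @param dims embedding dimension (default 2).
#' @param restarts number of random starts (default 10).
#' @param seed integer seed controlling the random starts.
#' @param maxit iteration cap per start (default 500).
#' @param tol convergence tolerance on stress (default 1e-6).
#' @return List of class \code{"occuOrdination"}: \code{points} (sites x
#'   dims, columns Axis1, Axis2, ...), \code{stress}, \code{nRestarts},
#'   \code{converged}.
#' @export
nmdsOrdination <- function(sim, dims = 2, restarts = 10, seed = 1,
                           maxit = 500, tol = 1e-6) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n < dims + 1) stop("need at least dims + 1 sites")
  diss <- 1 - sim
  delta <- as.vector(as.dist(diss))
  obj <- function(x) kruskalStress(matrix(x, n, dims), delta)
  set.seed(seed)
  starts <- c(list(as.vector(cmdscale(as.dist(diss), k = dims))),
              lapply(seq_len(restarts), function(i) rnorm(n * dims)))
  best <- NULL
  converged <- FALSE
  for (i in seq_along(starts)) {
    o <- suppressWarnings(optim(starts[[i]], obj, method = "BFGS",
                                control = list(maxit = maxit, reltol = tol)))
    if (is.null(best) || o$value < best$value - 1e-12) {
      best <- o
      converged <- o$convergence == 0
    }
  }
  if (!converged)
    warning("NMDS iteration cap reached; returning best configuration found")
  X <- matrix(best$par, n, dims)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- X %*% svd(X)$v  # principal-axis rotation
  dimnames(X) <- list(rownames(sim), paste0("Axis", seq_len(dims)))
  structure(list(points = X, stress = best$value, nRestarts = restarts,
                 converged = converged),
            class = "occuOrdination")
}

#' @export
print.occuOrdination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d sites in %d dimensions, stress %.4f (%d restarts)\n",
              nrow(x$points), ncol(x$points), x$stress, x$nRestarts))
  invisible(x)
}

#' Group-average (UPGMA) clustering of sites
#'
#' Agglomerative clustering on Bray-Curtis dissimilarity (1 - similarity)
#' with group-average linkage, cut into \code{nGroups} clusters. Merge order
#' is deterministic; equal-height candidate merges are resolved by the
#' smallest pair of site indices.
#'
#' @param sim similarity matrix.
#' @param nGroups number of clusters, 1..n.
#' @return List: \code{labels} (named integer vector of group memberships)
#'   and \code{tree} (the \code{hclust} object, merge heights on the
#'   dissimilarity scale).
#' @export
clusterGroupAverage <- function(sim, nGroups) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (nGroups < 1 || nGroups > n) stop("nGroups must be in 1..", n)
  hc <- hclust(as.dist(1 - sim), method = "average")
  list(labels = cutree(hc, k = nGroups), tree = hc)
}

#' SIMPER: species contributions to between-group dissimilarity
#'
#' Decomposes the average Bray-Curtis dissimilarity between each pair of
#' groups into per-species contributions: for species k and a cross-pair of
#' sites (i, j), the term is |x_ik - x_jk| / sum_m (x_im + x_jm); the
#' contribution is its mean over all cross-pairs. Contributions sum exactly
#' to the average between-group dissimilarity.
#'
#' @param mat non-negative sites x species matrix.
#' @param groups group label per site (any atomic vector, >= 2 groups).
#' @return data.frame with columns \code{groupA}, \code{groupB},
#'   \code{species}, \code{contribution}, \code{cumulative},
#'   \code{avgDissimilarity}, sorted by decreasing contribution within each
#'   group pair.
#' @export
simperContrib <- function(mat, groups) {
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  if (length(groups) != nrow(mat)) stop("one group label per site required")
  gl <- sort(unique(groups))
  if (length(gl) < 2) stop("need at least two groups")
  if (any(tabulate(factor(groups, gl)) == 0)) stop("empty group")
  spp <- colnames(mat) %||% paste0("sp", seq_len(ncol(mat)))
  out <- list()
  for (a in seq_along(gl)) for (b in seq_along(gl)) {
    if (b <= a) next
    ia <- which(groups == gl[a]); ib <- which(groups == gl[b])
    contrib <- numeric(ncol(mat))
    for (i in ia) for (j in ib) {
      denom <- sum(mat[i, ] + mat[j, ])
      contrib <- contrib + abs(mat[i, ] - mat[j, ]) / denom
    }
    contrib <- contrib / (length(ia) * length(ib))
    o <- order(contrib, decreasing = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      groupA = gl[a], groupB = gl[b], species = spp[o],
      contribution = unname(contrib[o]),
      cumulative = unname(cumsum(contrib[o])),
      avgDissimilarity = sum(contrib), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

SOLAR_COVS <- c("direct_winter", "direct_summer", "diffuse_winter",
                "diffuse_summer", "total_winter", "total_summer")
SOIL_COVS <- c("cn", "ph", "p")

#' Apply modelling transforms to habitat covariates
#'
#' Solar-radiation covariates are square-root transformed and soil-fertility
#' covariates natural-log transformed before entering the linear predictors,
#' damping the leverage of infrequent large values. The square root is used
#' for solar radiation because zero values occur and a log with an arbitrary
#' offset is undesirable. NMDS axis scores are left unchanged. The raw scale
#' is retained in the object for prediction grids.
#'
#' @param covars a [SiteCovariates-class] on the raw scale.
#' @return A [SiteCovariates-class] with \code{transformed = TRUE}.
#' @export
transformCovariates <- function(covars) {
  if (covars@transformed) return(covars)
  d <- covars@raw
  for (v in intersect(SOLAR_COVS, names(d))) {
    if (any(d[[v]] < 0)) stop("negative solar radiation in ", v)
    d[[v]] <- sqrt(d[[v]])
  }
  for (v in intersect(SOIL_COVS, names(d))) {
    if (any(d[[v]] <= 0)) stop("non-positive soil covariate in ", v)
    d[[v]] <- log(d[[v]])
  }
  new("SiteCovariates", data = d, raw = covars@raw, transformed = TRUE)
}
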