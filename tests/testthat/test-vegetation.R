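test_that("cover-class midpoints sum across tiers into importance values", {
  long <- data.frame(site = c("s1", "s1", "s1", "s2"),
                     species = c("kanuka", "kanuka", "tawa", "tawa"),
                     tier = c(1, 2, 1, 3),
                     class = c(4, 4, 6, 2))
  imp <- coverToImportance(long)
  expect_equal(imp["s1", "kanuka"], 76)   # 38 + 38, midpoints of 26-50%
  expect_equal(imp["s1", "tawa"], 88)     # midpoint of 76-100%
  expect_equal(imp["s2", "kanuka"], 0)    # absent species
  expect_equal(imp["s2", "tawa"], 3)
  expect_error(coverToImportance(transform(long, class = c(4, 7, 6, 2))), "0..6")
})

test_that("raising a cover score never lowers the importance value", {
  set.seed(5)
  base <- data.frame(site = "s1", species = rep(c("a", "b"), each = 3),
                     tier = rep(1:3, 2), class = sample(0:6, 6, TRUE))
  imp0 <- coverToImportance(base)
  for (i in seq_len(nrow(base))) {
    if (base$class[i] == 6) next
    up <- base
    up$class[i] <- up$class[i] + 1
    expect_true(all(coverToImportance(up) >= imp0))
  }
})

test_that("standardisation to site proportions precedes the fourth root", {
  m <- rbind(s1 = c(1, 3))
  out <- standardizeFourthRoot(m)
  expect_equal(unname(out[1, ]), c(0.25, 0.75)^0.25, tolerance = 1e-12)
  expect_equal(unname(round(out[1, ], 4)), c(0.7071, 0.9306))
  ## single-species site standardises to exactly 1
  expect_equal(unname(standardizeFourthRoot(rbind(c(0, 5)))[1, ]), c(0, 1))
  ## scaling a row is a no-op after standardisation
  expect_equal(standardizeFourthRoot(rbind(c(2, 6))),
               standardizeFourthRoot(rbind(c(1, 3))))
  expect_error(standardizeFourthRoot(rbind(c(0, 0))), "no species")
})

test_that("Bray-Curtis matches the direct formula and its invariants", {
  expect_equal(brayCurtis(rbind(c(1, 2), c(1, 2)))[1, 2], 1)
  expect_equal(brayCurtis(rbind(c(1, 0), c(0, 2)))[1, 2], 0)
  expect_equal(brayCurtis(rbind(c(1, 3), c(2, 1)))[1, 2], 1 - 3 / 7,
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:3) {
    m <- matrix(rexp(5 * 4), 5, 4)
    s <- brayCurtis(m)
    expect_true(isSymmetric(s))
    expect_equal(unname(diag(s)), rep(1, 5))
    expect_true(all(s >= 0 & s <= 1))
    ## direct formula oracle
    for (a in 1:4) for (b in (a + 1):5) {
      expect_equal(s[a, b],
                   1 - sum(abs(m[a, ] - m[b, ])) / sum(m[a, ] + m[b, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("UPGMA clustering reproduces brute-force group-average merges", {
  ## two obvious pairs
  m <- rbind(a = c(10, 0, 0), b = c(9, 1, 0), c = c(0, 10, 0), d = c(0, 9, 1))
  s <- brayCurtis(m)
  cl <- clusterGroupAverage(s, 2)
  expect_equal(unname(cl$labels["a"]), unname(cl$labels["b"]))
  expect_equal(unname(cl$labels["c"]), unname(cl$labels["d"]))
  expect_true(cl$labels["a"] != cl$labels["c"])
  ## merge heights equal the brute-force UPGMA oracle
  expect_equal(sort(cl$tree$height), sort(bruteUPGMA(1 - s)), tolerance = 1e-12)
  set.seed(21)
  m2 <- matrix(rexp(6 * 5), 6)
  s2 <- brayCurtis(m2)
  cl2 <- clusterGroupAverage(s2, 3)
  expect_equal(sort(cl2$tree$height), sort(bruteUPGMA(1 - s2)), tolerance = 1e-12)
  ## degenerate cuts
  expect_equal(unname(clusterGroupAverage(s2, 1)$labels), rep(1L, 6))
  expect_equal(length(unique(clusterGroupAverage(s2, 6)$labels)), 6L)
  expect_error(clusterGroupAverage(s2, 7), "nGroups")
})

test_that("SIMPER contributions decompose the average between-group dissimilarity", {
  ## two singleton groups: contributions are the per-species terms of the pair
  m <- rbind(s1 = c(1, 3, 0), s2 = c(2, 1, 1))
  out <- simperContrib(m, c("A", "B"))
  denom <- sum(m[1, ] + m[2, ])
  expect_equal(sort(out$contribution), sort(abs(m[1, ] - m[2, ]) / denom),
               tolerance = 1e-12)
  expect_equal(out$avgDissimilarity[1], 1 - brayCurtis(m)[1, 2], tolerance = 1e-12)

  ## a species identical across all sites contributes zero
  m2 <- cbind(matrix(rexp(8), 4), fixed = rep(2, 4))
  out2 <- simperContrib(m2, c("A", "A", "B", "B"))
  expect_equal(out2$contribution[out2$species == "fixed"], 0)

  ## contributions sum to the mean cross-pair dissimilarity (enumeration)
  set.seed(13)
  m3 <- matrix(rexp(6 * 4), 6)
  g <- c("A", "A", "B", "B", "C", "C")
  out3 <- simperContrib(m3, g)
  s3 <- brayCurtis(m3)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    rows <- out3$groupA == pair[1] & out3$groupB == pair[2]
    ia <- which(g == pair[1]); ib <- which(g == pair[2])
    meanDiss <- mean(1 - s3[ia, ib])
    expect_equal(sum(out3$contribution[rows]), meanDiss, tolerance = 1e-10)
    expect_equal(out3$avgDissimilarity[rows][1], meanDiss, tolerance = 1e-10)
    ## sorted decreasing
    expect_true(all(diff(out3$contribution[rows]) <= 1e-12))
  }
  expect_error(simperContrib(m3, rep("A", 6)), "two groups")
})

test_that("NMDS recovers exact embeddings and matches an independent implementation", {
  ## three equidistant sites embed exactly in 2-D
  s <- matrix(0.4, 3, 3); diag(s) <- 1
  ord <- nmdsOrdination(s, restarts = 4, seed = 1)
  expect_lt(ord$stress, 1e-4)

  ## duplicated sites map to near-coincident points
  m <- rbind(a = c(5, 1, 0), b = c(5, 1, 0), c = c(0, 4, 2), d = c(1, 0, 6))
  s2 <- brayCurtis(m)
  ord2 <- nmdsOrdination(s2, restarts = 6, seed = 2)
  dd <- as.matrix(dist(ord2$points))
  expect_lt(dd["a", "b"], 0.05 * max(dd))

  ## toy dissimilarities from 3-D configurations (no exact 2-D embedding):
  ## minimised stress agrees with vegan (monoMDS engine, restarted) to 1e-3
  for (case in list(list(n = 8, seedX = 7, seedO = 5),
                    list(n = 10, seedX = 19, seedO = 8))) {
    set.seed(case$seedX)
    x <- matrix(rnorm(3 * case$n), case$n)
    diss <- as.matrix(dist(x)); diss <- diss / max(diss)
    ord3 <- nmdsOrdination(1 - diss, restarts = 10, seed = case$seedO)
    set.seed(123)
    ref <- suppressWarnings(suppressMessages(
      vegan::metaMDS(as.dist(diss), k = 2, trymax = 50, trace = 0,
                     smin = 1e-7, sratmax = 0.99999999, maxit = 500)))
    expect_gt(ord3$stress, 0.01)
    expect_equal(ord3$stress, ref$stress, tolerance = 1e-3)
  }
})

test_that("Kruskal stress is invariant to rotation, reflection and scaling", {
  set.seed(41)
  x <- matrix(rnorm(10), 5)
  delta <- as.vector(dist(matrix(rnorm(10), 5)))
  s0 <- occuCam:::kruskalStress(x, delta)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(occuCam:::kruskalStress(x %*% rot, delta), s0, tolerance = 1e-12)
  expect_equal(occuCam:::kruskalStress(3.7 * x, delta), s0, tolerance = 1e-12)
  expect_equal(occuCam:::kruskalStress(x %*% diag(c(-1, 1)), delta), s0,
               tolerance = 1e-12)
})

test_that("covariate transforms are sqrt for solar and log for soil", {
  cv <- siteCovariates(data.frame(site = c("s1", "s2"),
                                  direct_winter = c(4, 0), cn = c(15, 20),
                                  p = c(3, 41), axis1 = c(-1, 1)))
  tr <- transformCovariates(cv)
  expect_equal(covariateData(tr)$direct_winter, c(2, 0))  # zero needs no offset
  expect_equal(covariateData(tr)$p[1], log(3), tolerance = 1e-12)
  expect_equal(round(covariateData(tr)$p[1], 4), 1.0986)
  expect_equal(covariateData(tr)$axis1, c(-1, 1))
  expect_identical(transformCovariates(tr), tr)  # idempotent
  expect_error(transformCovariates(siteCovariates(
    data.frame(site = "s1", direct_winter = -1))), "negative solar")
  expect_error(transformCovariates(siteCovariates(
    data.frame(site = "s1", p = 0))), "non-positive")
})
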