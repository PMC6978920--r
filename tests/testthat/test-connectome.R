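test_that("correlation matrix matches the textbook Pearson formula", {
  # 3-ROI toy series of 10 fixed samples, nDrop = 0
  s <- rbind(c(1.2, 3.4, 2.2, 5.1, 4.4, 3.3, 2.8, 4.0, 3.1, 2.5),
             c(2.0, 2.9, 3.8, 4.1, 5.0, 2.2, 3.3, 4.4, 2.8, 3.0),
             c(9.1, 7.2, 6.3, 5.4, 4.5, 3.6, 2.7, 1.8, 0.9, 0.5))
  x <- RoiTimeSeriesSet(s, roiLabels = c("A", "B", "C"), dt = 2)
  cm <- correlationMatrix(x, nDrop = 0)
  pearson <- function(a, b) {
    n <- length(a)
    (sum(a * b) - n * mean(a) * mean(b)) /
      sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  }
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(zValues(cm)[i, j], atanh(pearson(s[i, ], s[j, ])),
                 tolerance = 1e-12)
})

test_that("a 150-ROI matrix has 11175 unique pairs and drops 9 volumes", {
  x <- simulateRoiTimeSeries(timeSeriesSimConfig(nRois = 150, nVolumes = 30,
                                                 seed = 1))
  cm <- correlationMatrix(x, nDrop = 9)
  expect_equal(nUniquePairs(cm), 11175L)
  expect_equal(sum(upper.tri(zValues(cm))), 11175L)
  expect_equal(S4Vectors::metadata(cm)$nDrop, 9L)
  # the first nDrop samples do not influence the result
  sig <- signals(x); sig[, 1:9] <- 999
  cm2 <- correlationMatrix(RoiTimeSeriesSet(sig, roiLabels = roiLabels(x),
                                            dt = 2), nDrop = 9)
  expect_equal(zValues(cm2), zValues(cm))
})

test_that("perfect anticorrelation lands on the negative clip bound", {
  tn <- 30
  a <- sin(seq_len(tn))
  x <- RoiTimeSeriesSet(rbind(a, -a), roiLabels = c("A", "B"), dt = 2)
  cm <- correlationMatrix(x, nDrop = 0)
  expect_equal(zValues(cm)[1, 2], atanh(-(1 - 1e-7)))
  # constant ROI flagged, not zeroed
  xc <- RoiTimeSeriesSet(rbind(a, rep(1, tn)), roiLabels = c("A", "B"),
                         dt = 2)
  expect_warning(cmc <- correlationMatrix(xc, nDrop = 0), "constant")
  expect_true(is.na(zValues(cmc)[1, 2]))
  expect_equal(S4Vectors::metadata(cmc)$undefinedRois, 2L,
               ignore_attr = TRUE)
})

test_that("density thresholding retains floor(d*pairs) edges, max weight 1", {
  set.seed(10)
  n <- 150
  z <- matrix(rnorm(n * n), n, n); z <- (z + t(z)) / 2
  cm <- zMatrixAsConnectivity(z)
  g <- thresholdDensity(cm, 0.15)
  expect_equal(S4Vectors::metadata(g)$nEdges, 1676L)  # floor(.15 * 11175)
  expect_equal(sum(edgeWeights(g)[upper.tri(edgeWeights(g))] != 0), 1676L)
  expect_equal(max(edgeWeights(g)), 1)
  gAll <- thresholdDensity(cm, 1)
  expect_equal(sum(edgeWeights(gAll)[upper.tri(edgeWeights(gAll))] != 0),
               11175L)
  expect_equal(max(edgeWeights(gAll)), 1)
  # retained edges are exactly the largest z values
  kept <- zValues(cm)[upper.tri(z)][edgeWeights(g)[upper.tri(z)] != 0]
  expect_equal(sort(kept, decreasing = TRUE),
               sort(zValues(cm)[upper.tri(z)], decreasing = TRUE)[1:1676])
})

test_that("thresholding ties break by ascending (row, column) index", {
  z <- matrix(0.5, 4, 4)
  cm <- zMatrixAsConnectivity(z)
  g <- thresholdDensity(cm, 0.5)  # 3 of 6 equal edges
  w <- edgeWeights(g)
  # first by (row, column): (1,2), (1,3), (1,4) -> column-major slots 1, 2, 4
  expect_equal(which(w[upper.tri(w)] != 0), c(1L, 2L, 4L))
  expect_match(S4Vectors::metadata(g)$tieBreak, "row, column")
  expect_error(thresholdDensity(cm, 1e-9), "no edges")
})

test_that("toy graphs reproduce hand-computed metrics", {
  tri <- matrix(0, 3, 3); tri[cbind(c(1, 1, 2), c(2, 3, 3))] <- 1
  tri <- tri + t(tri); dimnames(tri) <- list(LETTERS[1:3], LETTERS[1:3])
  g <- methods::new("BrainGraph", weights = tri, roiLabels = LETTERS[1:3],
                    hemisphere = rep("midline", 3), density = 1)
  m <- graphMetrics(g, nNulls = 0)
  expect_equal(unname(m$strength), rep(2, 3))
  expect_equal(unname(m$degree), rep(2L, 3))
  expect_equal(unname(m$clustering), rep(1, 3))
  expect_equal(m$pathLength, 1)
  # path A-B-C: clustering 0, degree(B) = 2, L = (1 + 1 + 2)/3
  pw <- matrix(0, 3, 3); pw[1, 2] <- pw[2, 3] <- 1; pw <- pw + t(pw)
  dimnames(pw) <- list(LETTERS[1:3], LETTERS[1:3])
  gp <- methods::new("BrainGraph", weights = pw, roiLabels = LETTERS[1:3],
                     hemisphere = rep("midline", 3), density = 2 / 3)
  mp <- graphMetrics(gp, nNulls = 0)
  expect_equal(unname(mp$degree["B"]), 2L)
  expect_equal(unname(mp$clustering), rep(0, 3))
  expect_equal(mp$pathLength, 4 / 3)
})

test_that("path length matches an exhaustive Floyd-Warshall oracle", {
  g <- randomBrainGraph(20, p = 0.25, seed = 33)
  got <- characteristicPathLength(g)
  want <- oraclePathLength(edgeWeights(g))
  expect_equal(got$pathLength, want$pathLength, tolerance = 1e-10)
  expect_equal(got$fractionUnreachable, want$fractionUnreachable)
})

test_that("strength never exceeds degree; equality iff unit weights", {
  for (s in 1:20) {
    g <- randomBrainGraph(10, p = 0.4, seed = s)
    expect_true(all(nodeStrength(g) <= nodeDegree(g) + 1e-12))
  }
  gU <- randomBrainGraph(8, p = 0.5, seed = 3)
  w <- sign(edgeWeights(gU))
  gUnit <- methods::new("BrainGraph", weights = w, roiLabels = roiLabels(gU),
                        hemisphere = hemispheres(gU),
                        density = gU@density)
  expect_equal(nodeStrength(gUnit), as.numeric(nodeDegree(gUnit)),
               ignore_attr = TRUE)
})

test_that("small-worldness of a random graph is near 1 against its nulls", {
  g <- randomBrainGraph(25, p = 0.3, seed = 12)
  m <- graphMetrics(g, nNulls = 30, seed = 4)
  expect_gt(m$smallWorldness, 0.75)
  expect_lt(m$smallWorldness, 1.35)
})

test_that("seed connectivity averages hemispheres and checks labels", {
  labs <- c("ACC_L", "ACC_R", "DLS_L", "DLS_R")
  z <- matrix(0, 4, 4)
  z[1, 3] <- z[3, 1] <- 0.4   # ACC_L - DLS_L
  z[2, 4] <- z[4, 2] <- 0.6   # ACC_R - DLS_R
  cm <- zMatrixAsConnectivity(z, labs)
  sc <- seedConnectivity(cm, "ACC", "DLS")
  expect_equal(sc$zLeft, 0.4)
  expect_equal(sc$zRight, 0.6)
  expect_equal(sc$zMean, 0.5)
  expect_error(seedConnectivity(cm, "PPC", "DLS"), "not present")
  # invariant to ROI column ordering
  perm <- c(3, 1, 4, 2)
  cmP <- zMatrixAsConnectivity(z[perm, perm], labs[perm])
  expect_equal(seedConnectivity(cmP, "ACC", "DLS")$zMean, 0.5)
})

test_that("high-strength subnetwork recovers planted nodes", {
  n <- 40
  w <- matrix(0, n, n)
  hubs <- 1:16
  for (i in hubs) for (j in hubs) if (i < j) w[i, j] <- 1
  w[17, 18] <- 0.5
  w <- w + t(w)
  labs <- sprintf("N%02d", 1:n); dimnames(w) <- list(labs, labs)
  g <- methods::new("BrainGraph", weights = w, roiLabels = labs,
                    hemisphere = rep("midline", n),
                    density = sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2))
  sub <- highStrengthSubnetwork(g, sMin = 14)  # hubs have strength 15 each
  expect_identical(sub$nodes, labs[hubs])
  expect_equal(nrow(sub$edges), choose(16, 2))
  # all below threshold -> empty set, not an error
  none <- highStrengthSubnetwork(g, sMin = 100)
  expect_length(none$nodes, 0)
  # single standout node
  one <- highStrengthSubnetwork(g, sMin = 14.5)
  expect_true(all(one$strength > 14.5))
})
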