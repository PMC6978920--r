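# Independent brute-force implementations used as oracles for the graph
# metrics, written as direct loops over the definitions.

oracleStrength <- function(w) rowSums(w)

oracleDegree <- function(w) rowSums(w != 0)

# geometric-mean triangle-intensity clustering, triple loop
oracleClustering <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) { out[i] <- 0; next }
    acc <- 0
    for (j in nb) for (h in nb) {
      if (j != h && w[j, h] > 0)
        acc <- acc + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# Floyd-Warshall all-pairs shortest paths on lengths 1/weight
oraclePathLength <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  dv <- d[upper.tri(d)]
  list(pathLength = mean(dv[is.finite(dv)]),
       fractionUnreachable = mean(!is.finite(dv)))
}

# rich-club phi by explicit club enumeration
oracleRichClub <- function(w, kv) {
  deg <- oracleDegree(w)
  vapply(kv, function(k) {
    club <- which(deg > k)
    if (length(club) < 2) return(NA_real_)
    sub <- w[club, club, drop = FALSE]
    2 * sum(sub[upper.tri(sub)] > 0) / (length(club) * (length(club) - 1))
  }, numeric(1))
}

# random weighted graph wrapped as a BrainGraph (weights in (0, 1], max 1)
randomBrainGraph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    a <- matrix(0, n, n)
    ut <- upper.tri(a)
    a[ut] <- (runif(sum(ut)) < p) * runif(sum(ut), 0.05, 1)
    if (sum(a > 0) >= 1) break
  }
  vals <- a[ut]
  pos <- which(vals > 0)
  vals[pos[which.max(vals[pos])]] <- 1  # force max weight 1
  a[ut] <- vals
  a <- a + t(a)
  labs <- sprintf("N%02d", seq_len(n))
  dimnames(a) <- list(labs, labs)
  methods::new("BrainGraph", weights = a, roiLabels = labs,
               hemisphere = rep("midline", n),
               density = sum(a[ut] > 0) / sum(ut))
}

# wrap a plain symmetric z matrix as a ConnectivityMatrix
zMatrixAsConnectivity <- function(z, labels = NULL) {
  n <- nrow(z)
  if (is.null(labels)) labels <- defaultRoiLabels(n)
  diag(z) <- NA_real_
  dimnames(z) <- list(labels, labels)
  cm <- methods::new("ConnectivityMatrix", zValues = z, roiLabels = labels,
                     hemisphere = hemisphereFromLabels(labels))
  S4Vectors::metadata(cm) <- list(undefinedRois = integer(0))
  cm
}

# hand-built trial log: counts of left/right object choices (+ optional WMEs)
makeTrialLog <- function(nLeft, nRight, nWme = 0, day = 1,
                         correct = TRUE) {
  n <- nLeft + nRight
  rec <- data.frame(
    day = day,
    kind = rep("object_choice", n),
    turn = rep(c("left", "right"), length.out = n),
    side = c(rep("left_well", nLeft), rep("right_well", nRight)),
    correct = rep_len(correct, n))
  if (nWme > 0) {
    rec <- rbind(rec, data.frame(day = day, kind = "wme",
                                 turn = rep("left", nWme),
                                 side = NA_character_, correct = NA))
  }
  TrialLog(rec)
}

# hand-built single cell
makeCell <- function(nPlanes = 20, fociPlanes = integer(0), fociCount = 1,
                     coverPlanes = integer(0), coverValue = 0.5,
                     visible = c(1, nPlanes), edgeCut = FALSE,
                     rat = "r1", region = "ACC") {
  foci <- matrix(0L, 1, nPlanes)
  foci[1, fociPlanes] <- as.integer(fociCount)
  cov <- matrix(0, 1, nPlanes)
  cov[1, coverPlanes] <- coverValue
  CellPopulation(
    data.frame(cellId = "c1", rat = rat, region = region,
               hemisphere = "left", nPlanes = nPlanes,
               visibleFirst = visible[1], visibleLast = visible[2],
               edgeCut = edgeCut),
    foci, cov)
}
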