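#' Fisher-z correlation matrix from ROI time series
#'
#' Pairwise Pearson correlations over all ROI pairs, computed after
#' discarding the first `nDrop` volumes (signal-equilibration frames are
#' excluded from the cross-correlation, 9 by convention here), then
#' variance-stabilized with the Fisher z-transform `atanh(r)`. To keep
#' perfectly (anti)correlated synthetic inputs finite, `|r|` is clipped at
#' `1 - clip` before the transform.
#'
#' @param series a [RoiTimeSeriesSet-class].
#' @param nDrop number of initial volumes to discard (default 9).
#' @param clip clipping margin on `|r|` (default `1e-7`).
#' @return a [ConnectivityMatrix-class]. Constant ROIs yield `NA` rows and
#'   are flagged in `metadata()$undefinedRois` with a warning, never
#'   silently zeroed.
#' @examples
#' x <- simulateRoiTimeSeries(timeSeriesSimConfig(nRois = 8, nVolumes = 100))
#' cm <- correlationMatrix(preprocessSeries(x))
#' cm
#' @export
correlationMatrix <- function(series, nDrop = 9, clip = 1e-7) {
  stopifnot(is(series, "RoiTimeSeriesSet"))
  tn <- nVolumes(series)
  stopIfNot(tn - nDrop >= 3L,
            "need at least 3 timepoints after dropping the first nDrop")
  sig <- signals(series)[, (nDrop + 1L):tn, drop = FALSE]
  v <- apply(sig, 1L, stats::var)
  undef <- which(v < .Machine$double.eps)
  r <- suppressWarnings(stats::cor(t(sig)))
  r <- pmin(pmax(r, -(1 - clip)), 1 - clip)
  z <- atanh(r)
  if (length(undef)) {
    z[undef, ] <- NA_real_
    z[, undef] <- NA_real_
    warning("constant ROI(s) have undefined correlations: ",
            paste(roiLabels(series)[undef], collapse = ", "), call. = FALSE)
  }
  diag(z) <- NA_real_
  dimnames(z) <- list(roiLabels(series), roiLabels(series))
  new("ConnectivityMatrix", zValues = z,
      roiLabels = roiLabels(series),
      hemisphere = hemispheres(series),
      metadata = list(nDrop = as.integer(nDrop), clip = clip,
                      undefinedRois = undef))
}

#' Number of unique ROI pairs
#'
#' `n(n-1)/2` unique off-diagonal pairs of a symmetric connectivity graph
#' (11,175 for the 150-ROI atlas).
#'
#' @param x a [ConnectivityMatrix-class], [BrainGraph-class], or an integer
#'   node count.
#' @return integer pair count
#' @export
nUniquePairs <- function(x) {
  n <- if (is.numeric(x)) as.integer(x) else nRois(x)
  (n * (n - 1L)) %/% 2L
}

#' Proportional density thresholding
#'
#' Retains the `floor(density * n(n-1)/2)` largest z values as undirected
#' edges (one ranking of signed z, most-positive first; ties broken by
#' ascending (row, column) upper-triangle index) and divides the retained
#' weights by the largest retained z, so all graphs have equal density and
#' edge weights spanning (0, 1] with maximum exactly 1.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param density fraction of pairs to retain, in (0, 1]; default 0.15
#'   (the "top 15 percent" convention).
#' @return a [BrainGraph-class]; `metadata()` records the retained-edge
#'   count, the normalization constant and the tie-break rule.
#' @export
thresholdDensity <- function(cm, density = 0.15) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  stopIfNot(density > 0 && density <= 1, "'density' must lie in (0, 1]")
  z <- zValues(cm)
  n <- nrow(z)
  if (length(metadata(cm)$undefinedRois))
    stop("cannot threshold a matrix with undefined (constant) ROIs",
         call. = FALSE)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  zv <- z[upper.tri(z)]
  m <- floor(density * length(zv))
  if (m < 1) stop("requested density retains no edges", call. = FALSE)
  ord <- order(-zv, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(m)]
  zmax <- zv[keep[1L]]
  w <- matrix(0, n, n, dimnames = dimnames(z))
  w[ut[keep, , drop = FALSE]] <- zv[keep] / zmax
  w <- w + t(w)
  out <- new("BrainGraph", weights = w, roiLabels = cm@roiLabels,
             hemisphere = cm@hemisphere, density = m / length(zv))
  metadata(out) <- list(requestedDensity = density, nEdges = m,
                        normalization = zmax,
                        tieBreak = "descending z, then ascending (row, column)")
  out
}

# igraph view of a BrainGraph (edge attribute 'weight')
asIgraph <- function(g) {
  igraph::graph_from_adjacency_matrix(edgeWeights(g), mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Node strength and degree
#'
#' Strength is the sum of incident edge weights; degree the number of
#' incident edges. With weights normalized to at most 1, strength never
#' exceeds degree.
#'
#' @param g a [BrainGraph-class].
#' @return named numeric (strength) or integer (degree) vector.
#' @export
nodeStrength <- function(g) {
  stopifnot(is(g, "BrainGraph"))
  rowSums(edgeWeights(g))
}

#' @rdname nodeStrength
#' @export
nodeDegree <- function(g) {
  stopifnot(is(g, "BrainGraph"))
  as.integer(rowSums(edgeWeights(g) != 0)) |>
    stats::setNames(roiLabels(g))
}

#' Weighted clustering coefficient (geometric-mean triangle intensity)
#'
#' Per node i: the sum over neighbour pairs (j, h) of the cube root of the
#' triangle weight product `w_ij w_ih w_jh`, divided by `k_i (k_i - 1)`
#' with binary degree `k_i`. Nodes with degree below 2 score 0.
#'
#' @param g a [BrainGraph-class].
#' @return named numeric vector of per-node coefficients.
#' @export
clusteringOnnela <- function(g) {
  stopifnot(is(g, "BrainGraph"))
  w <- edgeWeights(g)
  w13 <- w^(1 / 3)
  num <- diag(w13 %*% w13 %*% w13)
  k <- rowSums(w != 0)
  c_i <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  stats::setNames(c_i, roiLabels(g))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over node pairs, with edge length defined as
#' the reciprocal of the edge weight (strong connections are short).
#' Unreachable pairs are excluded from the mean and their fraction
#' reported, so disconnected graphs do not produce infinite means.
#'
#' @param g a [BrainGraph-class].
#' @return list with `pathLength` (mean over reachable pairs) and
#'   `fractionUnreachable`.
#' @export
characteristicPathLength <- function(g) {
  stopifnot(is(g, "BrainGraph"))
  ig <- asIgraph(g)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  dv <- d[upper.tri(d)]
  unreach <- !is.finite(dv)
  list(pathLength = mean(dv[!unreach]),
       fractionUnreachable = mean(unreach))
}

#' Graph metrics of a thresholded weighted brain graph
#'
#' Computes the full metric set: per-node strength and degree, weighted
#' clustering (geometric-mean formula), characteristic path length
#' (1/weight edge lengths, unreachable pairs excluded), and small-worldness
#' sigma = (C / <C_null>) / (L / <L_null>) against degree-preserving
#' rewired null graphs (Maslov-Sneppen edge swaps with the original weights
#' shuffled onto the rewired topology).
#'
#' @param g a [BrainGraph-class] with at least 3 nodes.
#' @param nNulls number of null graphs for small-worldness (default 100;
#'   set 0 to skip).
#' @param swapsPerEdge rewiring attempts per edge (default 10).
#' @param seed RNG seed for the null ensemble.
#' @return list with `strength`, `degree`, `clustering` (per node),
#'   `meanClustering`, `pathLength`, `fractionUnreachable`,
#'   `smallWorldness` (NA when `nNulls = 0`), and the null means.
#' @export
graphMetrics <- function(g, nNulls = 100, swapsPerEdge = 10, seed = 1L) {
  stopifnot(is(g, "BrainGraph"))
  stopIfNot(nRois(g) >= 3L, "graph metrics require at least 3 nodes")
  s <- nodeStrength(g)
  k <- nodeDegree(g)
  cl <- clusteringOnnela(g)
  pl <- characteristicPathLength(g)
  res <- list(strength = s, degree = k, clustering = cl,
              meanClustering = mean(cl), pathLength = pl$pathLength,
              fractionUnreachable = pl$fractionUnreachable,
              smallWorldness = NA_real_,
              nullClustering = NA_real_, nullPathLength = NA_real_)
  if (nNulls >= 1) {
    stopIfNot(sum(k) > 0, "small-worldness requires at least one edge")
    nulls <- withSeed(seed, {
      replicate(nNulls, {
        gn <- rewiredNull(g, swapsPerEdge)
        pln <- characteristicPathLength(gn)
        c(C = mean(clusteringOnnela(gn)), L = pln$pathLength)
      })
    })
    res$nullClustering <- mean(nulls["C", ])
    res$nullPathLength <- mean(nulls["L", ])
    res$smallWorldness <- (res$meanClustering / res$nullClustering) /
      (res$pathLength / res$nullPathLength)
  }
  res
}

# one degree-preserving (Maslov-Sneppen) null with shuffled weights
rewiredNull <- function(g, swapsPerEdge = 10) {
  ig <- asIgraph(g)
  m <- igraph::ecount(ig)
  igr <- igraph::rewire(ig, igraph::keeping_degseq(niter = swapsPerEdge * m))
  wts <- sample(igraph::E(ig)$weight)
  a <- igraph::as_adjacency_matrix(igr, sparse = FALSE)
  w <- matrix(0, nrow(a), ncol(a), dimnames = dimnames(edgeWeights(g)))
  ut <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  w[ut] <- wts
  w <- w + t(w)
  new("BrainGraph", weights = w, roiLabels = g@roiLabels,
      hemisphere = g@hemisphere, density = g@density)
}

#' Seed-based connectivity with hemisphere averaging
#'
#' For a seed region and each target region, returns the Fisher z between
#' the left-hemisphere instances, the right-hemisphere instances, and
#' their mean. Hemispheres are averaged because, in the emulated design,
#' left/right showed no systematic difference.
#'
#' @param cm a [ConnectivityMatrix-class] whose labels carry `_L`/`_R`
#'   suffixes.
#' @param seed seed region name without suffix (e.g. `"ACC"`).
#' @param targets character vector of target region names.
#' @return data.frame with columns `seed`, `target`, `zLeft`, `zRight`,
#'   `zMean`.
#' @export
seedConnectivity <- function(cm, seed = "ACC", targets = c("DLS", "DMS")) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  labs <- roiLabels(cm)
  pick <- function(region, side) {
    lab <- paste0(region, "_", side)
    i <- match(lab, labs)
    if (is.na(i))
      stop("ROI '", lab, "' not present in the label set", call. = FALSE)
    i
  }
  z <- zValues(cm)
  rows <- lapply(targets, function(tg) {
    zl <- z[pick(seed, "L"), pick(tg, "L")]
    zr <- z[pick(seed, "R"), pick(tg, "R")]
    data.frame(seed = seed, target = tg, zLeft = zl, zRight = zr,
               zMean = (zl + zr) / 2)
  })
  do.call(rbind, rows)
}

#' High-strength / high-degree subnetwork
#'
#' Identifies nodes whose strength exceeds `sMin` (and optionally whose
#' degree exceeds `kMin`) and returns the induced subgraph connectivity.
#' With several subjects' graphs, thresholds apply to across-subject mean
#' strength/degree (`perSubject = FALSE`, the default) or to each subject
#' separately with the union reported.
#'
#' @param graphs a [BrainGraph-class] or list of them (shared node set).
#' @param sMin strength threshold (default 15).
#' @param kMin degree threshold (default 40); only used for
#'   `criterion != "strength"`.
#' @param criterion `"strength"` (default), `"degree"`, or `"both"`.
#' @param perSubject apply thresholds per subject instead of to the mean.
#' @return list with `nodes` (labels), `strength`, `degree` (mean values
#'   for the selected nodes) and `edges` (induced mean-weight edge table).
#'   An empty selection returns empty components, not an error.
#' @export
highStrengthSubnetwork <- function(graphs, sMin = 15, kMin = 40,
                                   criterion = c("strength", "degree", "both"),
                                   perSubject = FALSE) {
  criterion <- match.arg(criterion)
  stopIfNot(sMin >= 0 && kMin >= 0, "thresholds must be non-negative")
  if (is(graphs, "BrainGraph")) graphs <- list(graphs)
  labs <- roiLabels(graphs[[1]])
  S <- sapply(graphs, nodeStrength)
  K <- sapply(graphs, nodeDegree)
  passes <- function(s, k) switch(criterion,
    strength = s > sMin,
    degree = k > kMin,
    both = s > sMin & k > kMin)
  sel <- if (perSubject) {
    apply(mapply(passes, as.data.frame(S), as.data.frame(K)), 1L, any)
  } else {
    passes(rowMeans(S), rowMeans(K))
  }
  nodes <- labs[sel]
  W <- Reduce(`+`, lapply(graphs, edgeWeights)) / length(graphs)
  sub <- W[sel, sel, drop = FALSE]
  ut <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
  edges <- data.frame(from = nodes[ut[, 1L]], to = nodes[ut[, 2L]],
                      weight = sub[ut])
  list(nodes = nodes,
       strength = rowMeans(S)[sel],
       degree = rowMeans(K)[sel],
       edges = edges)
}
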