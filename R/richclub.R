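#' Rich-club curve of a thresholded brain graph
#'
#' For each degree threshold k, the club is the set of nodes with (binary)
#' degree strictly greater than k, and phi(k) is the density of edges
#' within the club: `2 E_club / (N_club (N_club - 1))`. High phi at high k
#' means that hub nodes are preferentially wired to each other — the
#' rich-club organization of the network. The curve is computed on the
#' binary skeleton of the thresholded graph (the k-indexed convention); a
#' weighted variant normalizing the club's total edge weight by the
#' strongest E_club weights anywhere in the graph is available.
#'
#' phi is undefined (flagged, `NA`) where fewer than two nodes survive.
#' An optional null normalization divides phi(k) by its mean over
#' degree-preserving rewired graphs; it is off by default.
#'
#' @param g a [BrainGraph-class].
#' @param kMax largest threshold evaluated; default (and cap) is the
#'   maximum degree minus 1, the largest k at which a two-node club can
#'   exist.
#' @param weighted use the weighted variant (default `FALSE`).
#' @param nNulls number of degree-preserving nulls for normalization
#'   (0 = raw curve, the default).
#' @param seed RNG seed for the null ensemble.
#' @return a [RichClubCurve-class] over k = 0 ... kMax.
#' @examples
#' cm <- correlationMatrix(preprocessSeries(
#'   simulateRoiTimeSeries(timeSeriesSimConfig(nRois = 20, nVolumes = 150))))
#' richClubCurve(thresholdDensity(cm, 0.3))
#' @export
richClubCurve <- function(g, kMax = NULL, weighted = FALSE, nNulls = 0,
                          seed = 1L) {
  stopifnot(is(g, "BrainGraph"))
  deg <- nodeDegree(g)
  stopIfNot(max(deg) >= 1L, "rich club of an empty graph is undefined")
  if (is.null(kMax)) kMax <- max(deg) - 1L
  stopIfNot(kMax <= max(deg), "'kMax' must not exceed the maximum degree")
  kv <- 0:as.integer(kMax)
  phi <- .phiCurve(edgeWeights(g), deg, kv, weighted)
  if (nNulls >= 1) {
    nullPhi <- withSeed(seed, {
      rowMeans(replicate(nNulls, {
        gn <- rewiredNull(g)
        .phiCurve(edgeWeights(gn), nodeDegree(gn), kv, weighted)
      }))
    })
    phi <- phi / nullPhi
  }
  out <- new("RichClubCurve", k = kv, phi = unname(phi),
             defined = !is.na(phi))
  metadata(out) <- list(weighted = weighted, nNulls = nNulls)
  out
}

# phi over a k grid; NA where fewer than two club members
.phiCurve <- function(w, deg, kv, weighted = FALSE) {
  allw <- sort(w[upper.tri(w)][w[upper.tri(w)] > 0], decreasing = TRUE)
  vapply(kv, function(k) {
    club <- which(deg > k)
    nc <- length(club)
    if (nc < 2L) return(NA_real_)
    sub <- w[club, club]
    if (weighted) {
      # total club weight over the sum of the E_club strongest weights
      ec <- sum(sub[upper.tri(sub)] > 0)
      if (ec == 0L) return(0)
      sum(sub[upper.tri(sub)]) / sum(allw[seq_len(ec)])
    } else {
      2 * sum(sub[upper.tri(sub)] > 0) / (nc * (nc - 1))
    }
  }, numeric(1))
}

#' Per-subject rich-club curves as a long table
#'
#' Evaluates [richClubCurve()] on each graph over a common k grid and
#' stacks the results with subject annotations — the input format of
#' [richclubGroupComparison()].
#'
#' @param graphs named list of [BrainGraph-class] objects (one per
#'   subject-session).
#' @param kRange integer vector of thresholds to report.
#' @param info optional data.frame with one row per graph (e.g. subject,
#'   group, session) to be cbound to the output.
#' @return data.frame with columns of `info`, plus `k`, `phi`, `defined`.
#' @export
richClubTable <- function(graphs, kRange, info = NULL) {
  if (is(graphs, "BrainGraph")) graphs <- list(graphs)
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    deg <- nodeDegree(g)
    rc <- richClubCurve(g, kMax = max(deg) - 1L)
    idx <- match(kRange, richClubK(rc))
    phi <- ifelse(is.na(idx), NA_real_, richClubPhi(rc)[idx])
    d <- data.frame(k = as.integer(kRange), phi = phi,
                    defined = !is.na(phi))
    if (!is.null(info)) d <- cbind(info[rep(i, nrow(d)), , drop = FALSE], d)
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a rich-club curve
#'
#' @param x a [RichClubCurve-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot].
#' @export
setMethod("plot", signature(x = "RichClubCurve", y = "missing"),
  function(x, y, ...) {
    ok <- richClubDefined(x)
    graphics::plot(richClubK(x)[ok], richClubPhi(x)[ok], type = "b",
                   xlab = "degree threshold k",
                   ylab = expression(phi(k)), ...)
  })
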