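#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

#' ROI time-series container
#'
#' Holds resting-state signals for a set of labeled regions of interest
#' (ROIs), one row per ROI and one column per acquired volume, together with
#' hemisphere tags and the sampling interval. This is the common currency of
#' the preprocessing chain: simulation, detrending, nuisance regression and
#' band-pass filtering all consume and return objects of this class.
#'
#' @slot signals numeric matrix, ROIs in rows, volumes in columns.
#' @slot roiLabels character vector of region names, one per row. Bilateral
#'   regions carry a `_L`/`_R` suffix.
#' @slot hemisphere character vector, one of `"left"`, `"right"`,
#'   `"midline"` per ROI.
#' @slot dt sampling interval in seconds.
#'
#' The `metadata()` list (from [S4Vectors::Annotated]) carries optional
#' provenance: confound regressors used at simulation time, the planted
#' correlation matrix, and flags for zero-variance ROIs.
#'
#' @seealso [RoiTimeSeriesSet()] for the constructor,
#'   [detrendNormalize()], [regressNuisance()], [bandpassFilter()].
#' @export
setClass("RoiTimeSeriesSet",
  contains = "Annotated",
  representation(
    signals = "matrix",
    roiLabels = "character",
    hemisphere = "character",
    dt = "numeric"
  )
)

setValidity("RoiTimeSeriesSet", function(object) {
  msg <- character()
  if (!is.numeric(object@signals))
    msg <- c(msg, "'signals' must be a numeric matrix")
  if (length(object@roiLabels) != nrow(object@signals))
    msg <- c(msg, "one label per ROI row is required")
  if (anyDuplicated(object@roiLabels))
    msg <- c(msg, "ROI labels must be unique")
  if (length(object@hemisphere) != nrow(object@signals))
    msg <- c(msg, "one hemisphere tag per ROI row is required")
  if (!all(object@hemisphere %in% c("left", "right", "midline")))
    msg <- c(msg, "hemisphere tags must be 'left', 'right' or 'midline'")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "'dt' must be a single positive number")
  if (anyNA(object@signals))
    msg <- c(msg, "'signals' must not contain missing samples")
  if (length(msg)) msg else TRUE
})

#' Fisher-z connectivity matrix
#'
#' Symmetric ROI-by-ROI matrix of Fisher z-transformed Pearson correlations.
#' The diagonal is undefined and stored as `NA`; ROI labels and hemisphere
#' tags are carried from the originating series so that seed analyses can
#' resolve left/right instances.
#'
#' @slot zValues symmetric numeric matrix of z values (`NA` diagonal).
#' @slot roiLabels,hemisphere as in [RoiTimeSeriesSet-class].
#' @export
setClass("ConnectivityMatrix",
  contains = "Annotated",
  representation(
    zValues = "matrix",
    roiLabels = "character",
    hemisphere = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  z <- object@zValues
  msg <- character()
  if (nrow(z) != ncol(z))
    msg <- c(msg, "'zValues' must be square")
  off <- z; diag(off) <- 0
  if (anyNA(off)) {
    # allowed only for ROIs flagged as undefined (constant series)
    flagged <- metadata(object)$undefinedRois
    bad <- which(is.na(off), arr.ind = TRUE)
    if (is.null(flagged) ||
        !all(bad[, 1L] %in% flagged | bad[, 2L] %in% flagged))
      msg <- c(msg, "NA off-diagonal entries must be flagged in metadata$undefinedRois")
  } else if (nrow(z) == ncol(z) && max(abs(off - t(off))) > 1e-12) {
    msg <- c(msg, "'zValues' must be symmetric")
  }
  if (length(object@roiLabels) != nrow(z))
    msg <- c(msg, "one label per ROI is required")
  if (length(object@hemisphere) != nrow(z))
    msg <- c(msg, "one hemisphere tag per ROI is required")
  if (length(msg)) msg else TRUE
})

#' Thresholded, weight-normalized brain graph
#'
#' Undirected weighted graph over labeled ROIs obtained by proportional
#' density thresholding of a [ConnectivityMatrix-class]: the top fraction of
#' z values is retained and retained weights are divided by the largest
#' retained z, so edge weights lie in (0, 1] on realistic inputs and the
#' maximum weight is exactly 1.
#'
#' @slot weights symmetric numeric matrix; 0 marks an absent edge, the
#'   diagonal is 0 (no self-loops).
#' @slot roiLabels,hemisphere node labels and hemisphere tags.
#' @slot density fraction of all `n(n-1)/2` pairs retained as edges.
#'
#' `metadata()` records the requested density, the retained-edge count, the
#' normalization constant and the tie-break rule.
#' @export
setClass("BrainGraph",
  contains = "Annotated",
  representation(
    weights = "matrix",
    roiLabels = "character",
    hemisphere = "character",
    density = "numeric"
  )
)

setValidity("BrainGraph", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "'weights' must be square")
  if (any(diag(w) != 0)) msg <- c(msg, "self-loops are not allowed")
  if (max(abs(w - t(w))) > 1e-12) msg <- c(msg, "graph must be undirected (symmetric weights)")
  if (length(object@roiLabels) != nrow(w))
    msg <- c(msg, "one label per node is required")
  if (length(object@density) != 1L || object@density < 0 || object@density > 1)
    msg <- c(msg, "'density' must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Rich-club curve
#'
#' Rich-club coefficient phi(k) over a grid of degree thresholds k. At each
#' k the club is the set of nodes with degree strictly greater than k and
#' phi(k) is the edge density within the club; `defined` is `FALSE` where
#' fewer than two nodes survive.
#'
#' @slot k integer degree thresholds.
#' @slot phi numeric, phi(k) in `[0, 1]` where defined, `NA` otherwise.
#' @slot defined logical flag per k.
#' @export
setClass("RichClubCurve",
  contains = "Annotated",
  representation(
    k = "integer",
    phi = "numeric",
    defined = "logical"
  )
)

setValidity("RichClubCurve", function(object) {
  msg <- character()
  n <- length(object@k)
  if (length(object@phi) != n || length(object@defined) != n)
    msg <- c(msg, "'k', 'phi' and 'defined' must have equal length")
  ok <- object@defined
  if (any(ok) && (min(object@phi[ok]) < -1e-12 || max(object@phi[ok]) > 1 + 1e-12))
    msg <- c(msg, "phi must lie in [0, 1] where defined")
  if (any(!ok & !is.na(object@phi)))
    msg <- c(msg, "phi must be NA where undefined")
  if (is.unsorted(object@k, strictly = TRUE))
    msg <- c(msg, "'k' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Behavioral trial log
#'
#' Ordered record of attempted trials on the alternation maze. Object-choice
#' rows carry the turn direction, the side of the chosen object
#' (`left_well`/`right_well`) and a correctness flag; working-memory-error
#' (WME) rows mark a failed alternation and, as in the field's convention,
#' carry no object choice and do not count as trials.
#'
#' @slot records data.frame with columns `day` (integer, non-decreasing),
#'   `kind` (`"object_choice"` or `"wme"`), `turn` (`"left"`/`"right"`),
#'   `side` (`"left_well"`/`"right_well"` or `NA` for WME rows) and
#'   `correct` (logical, `NA` for WME rows), in temporal order.
#' @export
setClass("TrialLog",
  contains = "Annotated",
  representation(records = "data.frame")
)

setValidity("TrialLog", function(object) {
  r <- object@records
  msg <- character()
  need <- c("day", "kind", "turn", "side", "correct")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (is.unsorted(r$day))
      msg <- c(msg, "day indices must be non-decreasing")
    if (!all(r$kind %in% c("object_choice", "wme")))
      msg <- c(msg, "kind must be 'object_choice' or 'wme'")
    w <- r$kind == "wme"
    if (any(!is.na(r$side[w])) || any(!is.na(r$correct[w])))
      msg <- c(msg, "WME rows must not carry side or correctness")
    o <- !w
    if (any(is.na(r$side[o])) || any(is.na(r$correct[o])))
      msg <- c(msg, "object-choice rows must carry side and correctness")
    if (!all(r$side[o] %in% c("left_well", "right_well")))
      msg <- c(msg, "side must be 'left_well' or 'right_well'")
  }
  if (length(msg)) msg else TRUE
})

#' Candidate-cell population from an Arc catFISH z-stack experiment
#'
#' One row per candidate cell with its inclusion metadata, plus per-plane
#' measurements: nuclear foci counts and the fraction of the nuclear
#' perimeter covered by cytoplasmic labeling, both indexed by optical plane.
#'
#' @slot cells data.frame with columns `cellId`, `rat`, `region` (e.g. ACC,
#'   DLS, DMS), `hemisphere`, `nPlanes`, `visibleFirst`, `visibleLast`
#'   (plane range where the nucleus appears), `edgeCut` (logical). A
#'   `trueLabel` column is present for simulated populations.
#' @slot foci integer matrix, cells x planes: nuclear foci count above
#'   threshold per plane.
#' @slot coverage numeric matrix, cells x planes: cytoplasmic perimeter
#'   coverage fraction in `[0, 1]`.
#' @export
setClass("CellPopulation",
  contains = "Annotated",
  representation(
    cells = "data.frame",
    foci = "matrix",
    coverage = "matrix"
  )
)

setValidity("CellPopulation", function(object) {
  msg <- character()
  need <- c("cellId", "rat", "region", "hemisphere", "nPlanes",
            "visibleFirst", "visibleLast", "edgeCut")
  if (!all(need %in% names(object@cells)))
    return(paste("cells must have columns:", paste(need, collapse = ", ")))
  n <- nrow(object@cells)
  if (nrow(object@foci) != n || nrow(object@coverage) != n)
    msg <- c(msg, "foci and coverage must have one row per cell")
  if (n) {
    if (any(object@coverage < 0 | object@coverage > 1))
      msg <- c(msg, "coverage fractions must lie in [0, 1]")
    cc <- object@cells
    if (any(cc$visibleFirst < 1 | cc$visibleLast > cc$nPlanes |
            cc$visibleFirst > cc$visibleLast))
      msg <- c(msg, "visible plane range must lie within the stack")
  }
  if (length(msg)) msg else TRUE
})
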