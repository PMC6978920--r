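#' Construct an ROI time-series set
#'
#' @param signals numeric matrix, ROIs in rows, volumes in columns. A plain
#'   vector is treated as a single ROI.
#' @param roiLabels character vector of region names; defaults to the
#'   rownames of `signals` or `ROI001...`. Labels ending in `_L`/`_R` are
#'   used to infer hemisphere tags when `hemisphere` is missing.
#' @param hemisphere optional character vector (`"left"`, `"right"`,
#'   `"midline"`).
#' @param dt sampling interval in seconds (default 2, the standard EPI
#'   repetition time of the design emulated here).
#' @return a [RoiTimeSeriesSet-class]
#' @examples
#' x <- RoiTimeSeriesSet(matrix(rnorm(40), nrow = 4),
#'                       roiLabels = c("ACC_L", "ACC_R", "DLS_L", "DLS_R"))
#' nRois(x)
#' @export
RoiTimeSeriesSet <- function(signals, roiLabels = NULL, hemisphere = NULL,
                             dt = 2) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (is.null(roiLabels)) {
    roiLabels <- rownames(signals)
    if (is.null(roiLabels))
      roiLabels <- sprintf("ROI%03d", seq_len(nrow(signals)))
  }
  if (is.null(hemisphere)) hemisphere <- hemisphereFromLabels(roiLabels)
  rownames(signals) <- roiLabels
  new("RoiTimeSeriesSet", signals = signals, roiLabels = roiLabels,
      hemisphere = hemisphere, dt = as.numeric(dt))
}

#' Infer hemisphere tags from `_L`/`_R` label suffixes
#'
#' @param labels character vector of ROI labels.
#' @return character vector of `"left"`, `"right"` or `"midline"`.
#' @export
hemisphereFromLabels <- function(labels) {
  ifelse(grepl("_L$", labels), "left",
         ifelse(grepl("_R$", labels), "right", "midline"))
}

#' Construct a trial log
#'
#' @param records data.frame with columns `day`, `kind`, `turn`, `side`,
#'   `correct` (see [TrialLog-class]).
#' @return a [TrialLog-class]
#' @export
TrialLog <- function(records) {
  records <- as.data.frame(records)
  rownames(records) <- NULL
  new("TrialLog", records = records)
}

#' Construct a cell population
#'
#' @param cells per-cell data.frame (see [CellPopulation-class]).
#' @param foci integer matrix of per-plane nuclear foci counts.
#' @param coverage numeric matrix of per-plane cytoplasmic perimeter
#'   coverage fractions.
#' @return a [CellPopulation-class]
#' @export
CellPopulation <- function(cells, foci, coverage) {
  new("CellPopulation", cells = as.data.frame(cells),
      foci = as.matrix(foci), coverage = as.matrix(coverage))
}

## ---- generics ------------------------------------------------------------

#' @rdname RoiTimeSeriesSet-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))
#' @rdname RoiTimeSeriesSet-class
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname RoiTimeSeriesSet-class
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))
#' @rdname RoiTimeSeriesSet-class
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))
#' @rdname RoiTimeSeriesSet-class
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))
#' @rdname RoiTimeSeriesSet-class
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
#' @rdname ConnectivityMatrix-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))
#' @rdname BrainGraph-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))
#' @rdname BrainGraph-class
#' @export
setGeneric("graphDensity", function(x) standardGeneric("graphDensity"))
#' @rdname TrialLog-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("trialRecords", function(x) standardGeneric("trialRecords"))
#' @rdname CellPopulation-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))
#' @rdname CellPopulation-class
#' @export
setGeneric("fociMatrix", function(x) standardGeneric("fociMatrix"))
#' @rdname CellPopulation-class
#' @export
setGeneric("coverageMatrix", function(x) standardGeneric("coverageMatrix"))

## ---- methods -------------------------------------------------------------

#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("signals", "RoiTimeSeriesSet", function(x) x@signals)
#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("roiLabels", "RoiTimeSeriesSet", function(x) x@roiLabels)
#' @rdname ConnectivityMatrix-class
#' @export
setMethod("roiLabels", "ConnectivityMatrix", function(x) x@roiLabels)
#' @rdname BrainGraph-class
#' @export
setMethod("roiLabels", "BrainGraph", function(x) x@roiLabels)
#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("hemispheres", "RoiTimeSeriesSet", function(x) x@hemisphere)
#' @rdname ConnectivityMatrix-class
#' @export
setMethod("hemispheres", "ConnectivityMatrix", function(x) x@hemisphere)
#' @rdname BrainGraph-class
#' @export
setMethod("hemispheres", "BrainGraph", function(x) x@hemisphere)
#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("samplingInterval", "RoiTimeSeriesSet", function(x) x@dt)
#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("nRois", "RoiTimeSeriesSet", function(x) nrow(x@signals))
#' @rdname ConnectivityMatrix-class
#' @export
setMethod("nRois", "ConnectivityMatrix", function(x) nrow(x@zValues))
#' @rdname BrainGraph-class
#' @export
setMethod("nRois", "BrainGraph", function(x) nrow(x@weights))
#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("nVolumes", "RoiTimeSeriesSet", function(x) ncol(x@signals))
#' @rdname ConnectivityMatrix-class
#' @export
setMethod("zValues", "ConnectivityMatrix", function(x) x@zValues)
#' @rdname BrainGraph-class
#' @export
setMethod("edgeWeights", "BrainGraph", function(x) x@weights)
#' @rdname BrainGraph-class
#' @export
setMethod("graphDensity", "BrainGraph", function(x) x@density)
#' @rdname TrialLog-class
#' @export
setMethod("trialRecords", "TrialLog", function(x) x@records)
#' @rdname CellPopulation-class
#' @export
setMethod("cellTable", "CellPopulation", function(x) x@cells)
#' @rdname CellPopulation-class
#' @export
setMethod("fociMatrix", "CellPopulation", function(x) x@foci)
#' @rdname CellPopulation-class
#' @export
setMethod("coverageMatrix", "CellPopulation", function(x) x@coverage)

#' @rdname RichClubCurve-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("richClubK", function(x) standardGeneric("richClubK"))
#' @rdname RichClubCurve-class
#' @export
setGeneric("richClubPhi", function(x) standardGeneric("richClubPhi"))
#' @rdname RichClubCurve-class
#' @export
setGeneric("richClubDefined", function(x) standardGeneric("richClubDefined"))
#' @rdname RichClubCurve-class
#' @export
setMethod("richClubK", "RichClubCurve", function(x) x@k)
#' @rdname RichClubCurve-class
#' @export
setMethod("richClubPhi", "RichClubCurve", function(x) x@phi)
#' @rdname RichClubCurve-class
#' @export
setMethod("richClubDefined", "RichClubCurve", function(x) x@defined)

## ---- show ----------------------------------------------------------------

setMethod("show", "RoiTimeSeriesSet", function(object) {
  cat("RoiTimeSeriesSet:", nRois(object), "ROIs x", nVolumes(object),
      "volumes, dt =", object@dt, "s",
      sprintf("(%.1f min)\n", nVolumes(object) * object@dt / 60))
  cat("  hemispheres:", paste(sprintf("%s=%d",
      names(table(object@hemisphere)), table(object@hemisphere)),
      collapse = ", "), "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nRois(object)
  cat("ConnectivityMatrix:", n, "ROIs,", n * (n - 1L) / 2L,
      "unique pairs (Fisher z)\n")
  und <- metadata(object)$undefinedRois
  if (length(und))
    cat("  undefined (constant) ROIs:", paste(object@roiLabels[und],
        collapse = ", "), "\n")
})

setMethod("show", "BrainGraph", function(object) {
  n <- nRois(object)
  m <- sum(object@weights[upper.tri(object@weights)] != 0)
  cat(sprintf("BrainGraph: %d nodes, %d edges (density %.3f)\n",
              n, m, object@density))
  if (m > 0)
    cat(sprintf("  edge weights in [%.3f, %.3f]\n",
                min(object@weights[object@weights != 0]),
                max(object@weights)))
})

setMethod("show", "RichClubCurve", function(object) {
  cat("RichClubCurve: k =", min(object@k), "...", max(object@k),
      sprintf("(%d defined of %d)\n", sum(object@defined), length(object@k)))
})

setMethod("show", "TrialLog", function(object) {
  r <- object@records
  cat("TrialLog:", nrow(r), "records over", length(unique(r$day)),
      "day(s);", sum(r$kind == "object_choice"), "object-choice trials,",
      sum(r$kind == "wme"), "WMEs\n")
})

setMethod("show", "CellPopulation", function(object) {
  cat("CellPopulation:", nrow(object@cells), "cells,",
      ncol(object@foci), "optical planes;",
      sum(object@cells$edgeCut), "edge-cut\n")
  if ("trueLabel" %in% names(object@cells))
    cat("  planted labels:", paste(sprintf("%s=%d",
        names(table(object@cells$trueLabel)), table(object@cells$trueLabel)),
        collapse = ", "), "\n")
})
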