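## Delimited-text interfaces. Every file written by the package starts with
## a comment line naming the producing stage, a hash of the resolved
## parameters and the seed, so any output can be traced to its run.

configHash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

fileHeader <- function(stage, seed = NA, params = list(), extra = character()) {
  c(sprintf("# ratconnectome stage=%s config=%s seed=%s", stage,
            configHash(params), as.character(seed)),
    extra)
}

readHeaderField <- function(path, field) {
  ln <- readLines(path, n = 10L)
  ln <- ln[startsWith(ln, "#")]
  m <- regmatches(ln, regexpr(paste0(field, "=[^ ]+"), ln))
  m <- unlist(m)
  if (!length(m)) return(NA_character_)
  sub(paste0(field, "="), "", m[[1]])
}

.readTable <- function(path, expectedCols = NULL) {
  out <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      fill = FALSE, blank.lines.skip = TRUE),
    error = function(e)
      stop("parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE))
  if (!is.null(expectedCols) && !all(expectedCols %in% names(out)))
    stop("parse error in '", path, "': expected columns ",
         paste(expectedCols, collapse = ", "), call. = FALSE)
  out
}

#' Write / read ROI time series as delimited text
#'
#' Rows are volumes and columns ROIs; the header row carries the ROI
#' labels (with `_L`/`_R` hemisphere suffixes). Comment lines record the
#' producing stage, parameter hash, seed and sampling interval, which the
#' reader restores.
#'
#' @param x a [RoiTimeSeriesSet-class].
#' @param path file path.
#' @param stage stage name for the provenance header.
#' @param seed seed recorded in the header.
#' @return `readRoiTimeSeries` returns a [RoiTimeSeriesSet-class];
#'   `writeRoiTimeSeries` returns `path` invisibly.
#' @export
writeRoiTimeSeries <- function(x, path, stage = "simulate", seed = NA) {
  stopifnot(is(x, "RoiTimeSeriesSet"))
  hdr <- fileHeader(stage, seed,
                    list(dt = samplingInterval(x), nRois = nRois(x)),
                    sprintf("# dt=%s", format(samplingInterval(x))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(t(signals(x)), con, sep = "\t", row.names = FALSE,
                     col.names = roiLabels(x), quote = FALSE)
  invisible(path)
}

#' @rdname writeRoiTimeSeries
#' @export
readRoiTimeSeries <- function(path) {
  dt <- as.numeric(readHeaderField(path, "dt"))
  if (is.na(dt)) dt <- 2
  d <- .readTable(path)
  if (!nrow(d)) stop("parse error in '", path, "': no samples", call. = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m))
    stop("parse error in '", path, "': non-numeric samples", call. = FALSE)
  RoiTimeSeriesSet(t(m), roiLabels = colnames(d), dt = dt)
}

#' Write / read a behavioral trial log
#'
#' One row per attempted trial in temporal order; WME rows keep empty
#' side/correct fields, preserved exactly on round trip.
#'
#' @param log a [TrialLog-class].
#' @param path file path.
#' @param stage,seed provenance header fields.
#' @export
writeTrialLog <- function(log, path, stage = "behavior", seed = NA) {
  stopifnot(is(log, "TrialLog"))
  r <- trialRecords(log)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(fileHeader(stage, seed, list(n = nrow(r))), con)
  utils::write.table(r, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname writeTrialLog
#' @export
readTrialLog <- function(path) {
  d <- .readTable(path, c("day", "kind", "turn", "side", "correct"))
  d$side[d$side == "" | is.na(d$side)] <- NA_character_
  d$correct <- as.logical(d$correct)
  TrialLog(d)
}

#' Write / read a catFISH cell table (long format)
#'
#' One row per cell and optical plane with the foci count and perimeter
#' coverage for that plane; per-cell metadata repeats on each row.
#'
#' @param cells a [CellPopulation-class].
#' @param path file path.
#' @param stage,seed provenance header fields.
#' @export
writeCellTable <- function(cells, path, stage = "catfish", seed = NA) {
  stopifnot(is(cells, "CellPopulation"))
  cc <- cellTable(cells)
  np <- ncol(fociMatrix(cells))
  long <- cc[rep(seq_len(nrow(cc)), each = np), , drop = FALSE]
  long$plane <- rep(seq_len(np), nrow(cc))
  long$foci <- as.vector(t(fociMatrix(cells)))
  long$coverage <- as.vector(t(coverageMatrix(cells)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(fileHeader(stage, seed, list(nCells = nrow(cc), nPlanes = np)),
             con)
  utils::write.table(long, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  need <- c("cellId", "rat", "region", "hemisphere", "nPlanes",
            "visibleFirst", "visibleLast", "edgeCut", "plane", "foci",
            "coverage")
  d <- .readTable(path, need)
  d <- d[order(match(d$cellId, unique(d$cellId)), d$plane), , drop = FALSE]
  ids <- unique(d$cellId)
  np <- max(d$plane)
  if (nrow(d) != length(ids) * np)
    stop("parse error in '", path, "': incomplete plane records",
         call. = FALSE)
  metaCols <- setdiff(names(d), c("plane", "foci", "coverage"))
  cc <- d[d$plane == 1L, metaCols, drop = FALSE]
  rownames(cc) <- NULL
  foci <- matrix(as.integer(d$foci), ncol = np, byrow = TRUE)
  cover <- matrix(as.numeric(d$coverage), ncol = np, byrow = TRUE)
  CellPopulation(cc, foci, cover)
}

#' Write / read a symmetric connectivity matrix
#'
#' Full square matrix with ROI labels as header; the `NA` diagonal of a
#' Fisher-z matrix is preserved.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param path file path.
#' @param stage,seed provenance header fields.
#' @export
writeConnectivityMatrix <- function(cm, path, stage = "graph", seed = NA) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(fileHeader(stage, seed, list(nRois = nRois(cm))), con)
  utils::write.table(zValues(cm), con, sep = "\t", row.names = FALSE,
                     col.names = roiLabels(cm), quote = FALSE)
  invisible(path)
}

#' @rdname writeConnectivityMatrix
#' @export
readConnectivityMatrix <- function(path) {
  d <- .readTable(path)
  z <- as.matrix(d)
  labs <- colnames(d)
  if (nrow(z) != ncol(z))
    stop("parse error in '", path, "': matrix is not square", call. = FALSE)
  dimnames(z) <- list(labs, labs)
  out <- new("ConnectivityMatrix", zValues = z, roiLabels = labs,
             hemisphere = hemisphereFromLabels(labs))
  metadata(out) <- list(undefinedRois = integer(0))
  out
}

#' Export a brain graph as an edge list
#'
#' Standard three-column edge list (`from`, `to`, `weight`) compatible
#' with common network-visualization tools. A display cutoff can restrict
#' the export to strong edges (the conventional rendering threshold is
#' 0.3).
#'
#' @param g a [BrainGraph-class].
#' @param path file path.
#' @param minWeight minimum edge weight to export (default 0 = all).
#' @param stage,seed provenance header fields.
#' @return the edge data.frame, invisibly.
#' @export
writeEdgeList <- function(g, path, minWeight = 0, stage = "graph",
                          seed = NA) {
  stopifnot(is(g, "BrainGraph"))
  w <- edgeWeights(g)
  ut <- which(upper.tri(w) & w >= minWeight & w > 0, arr.ind = TRUE)
  edges <- data.frame(from = roiLabels(g)[ut[, 1L]],
                      to = roiLabels(g)[ut[, 2L]],
                      weight = w[ut])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(fileHeader(stage, seed,
                        list(density = graphDensity(g),
                             minWeight = minWeight)), con)
  utils::write.table(edges, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(edges)
}
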