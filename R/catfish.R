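#' Central inclusion window of a z-stack
#'
#' The "median fraction" window: `round(fraction * nPlanes)` planes (at
#' least 1) centered on the stack midpoint. For a 20-plane stack at the
#' default 0.2 this is planes 9-12.
#'
#' @param nPlanes stack depth.
#' @param fraction central fraction (default 0.2).
#' @return integer vector `c(first, last)`.
#' @export
centralWindow <- function(nPlanes, fraction = 0.2) {
  stopIfNot(nPlanes >= 5L, "stacks must have at least 5 planes")
  w <- max(1L, round(fraction * nPlanes))
  first <- (nPlanes - w) %/% 2L + 1L
  c(first, first + w - 1L)
}

#' Inclusion filter for candidate cells
#'
#' Keeps cells that are not cut off by the tissue edge and whose visible
#' plane range touches the central window of the stack (the "median 20
#' percent of optical planes" rule). `rule = "cover"` instead requires the
#' visible range to span the whole window.
#'
#' @param cells a [CellPopulation-class].
#' @param medianFraction central window fraction (default 0.2).
#' @param rule `"intersect"` (default) or `"cover"`.
#' @return a [CellPopulation-class] restricted to included cells;
#'   `metadata()$nExcluded` records how many were dropped.
#' @examples
#' pop <- simulateCellPopulation(cellSimConfig(nCells = 100))
#' inclusionFilter(pop)
#' @export
inclusionFilter <- function(cells, medianFraction = 0.2,
                            rule = c("intersect", "cover")) {
  stopifnot(is(cells, "CellPopulation"))
  rule <- match.arg(rule)
  cc <- cellTable(cells)
  keep <- logical(nrow(cc))
  for (np in unique(cc$nPlanes)) {
    w <- centralWindow(np, medianFraction)
    i <- cc$nPlanes == np
    keep[i] <- if (rule == "intersect")
      cc$visibleFirst[i] <= w[2] & cc$visibleLast[i] >= w[1]
    else
      cc$visibleFirst[i] <= w[1] & cc$visibleLast[i] >= w[2]
  }
  keep <- keep & !cc$edgeCut
  out <- CellPopulation(cc[keep, , drop = FALSE],
                        fociMatrix(cells)[keep, , drop = FALSE],
                        coverageMatrix(cells)[keep, , drop = FALSE])
  metadata(out) <- c(metadata(cells),
                     list(nExcluded = sum(!keep), inclusionRule = rule,
                          medianFraction = medianFraction))
  out
}

# longest run of TRUE in a logical vector
.longestRun <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Classify cells by subcellular Arc labeling
#'
#' Plane-based rules: a cell is *nuclear* positive if 1 or 2 foci (counts
#' above 2 do not qualify unless `fociRule = "atLeast1"`) are present on at
#' least four consecutive planes; *cytoplasmic* positive if perimeter
#' coverage of at least one third is present on at least two adjacent
#' planes; *double* if both; *negative* otherwise. Nuclear transcription
#' foci appear within 1-2 min of firing and cytoplasmic transcript
#' accumulates ~15-20 min later, so the two compartments index the two
#' behavioral epochs.
#'
#' @param cells a [CellPopulation-class] (normally the output of
#'   [inclusionFilter()]).
#' @param minNuclearPlanes consecutive-plane requirement (default 4).
#' @param minCytoPlanes adjacent-plane requirement (default 2).
#' @param coverageThreshold perimeter-coverage threshold (default 1/3).
#' @param fociRule `"oneOrTwo"` (default, literal) or `"atLeast1"`.
#' @return factor with levels `negative`, `nuclear`, `cytoplasmic`,
#'   `double`, one per cell.
#' @export
classifyCells <- function(cells, minNuclearPlanes = 4L, minCytoPlanes = 2L,
                          coverageThreshold = 1 / 3,
                          fociRule = c("oneOrTwo", "atLeast1")) {
  stopifnot(is(cells, "CellPopulation"))
  fociRule <- match.arg(fociRule)
  fm <- fociMatrix(cells)
  cv <- coverageMatrix(cells)
  n <- nrow(fm)
  lab <- character(n)
  for (i in seq_len(n)) {
    fOk <- if (fociRule == "oneOrTwo") fm[i, ] %in% c(1L, 2L) else fm[i, ] >= 1L
    nuc <- .longestRun(fOk) >= minNuclearPlanes
    cyt <- .longestRun(cv[i, ] >= coverageThreshold) >= minCytoPlanes
    lab[i] <- if (nuc && cyt) "double" else if (nuc) "nuclear" else
      if (cyt) "cytoplasmic" else "negative"
  }
  factor(lab, levels = c("negative", "nuclear", "cytoplasmic", "double"))
}

#' Per-rat, per-region ensemble counts
#'
#' Aggregates classified cells to the unit statistics are based on — the
#' animal: for each rat x region, the number of counted cells and the four
#' class fractions (summing to 1). Pooling is across images within a rat,
#' so duplicated images do not change the rat mean relative weightings
#' downstream (statistics run on rats, not cells).
#'
#' @param cells a [CellPopulation-class] of included cells.
#' @param labels factor from [classifyCells()]; computed if missing.
#' @return data.frame with columns `rat`, `region`, `nCells`,
#'   `fracNuclear`, `fracCytoplasmic`, `fracDouble`, `fracNegative`.
#' @export
ensembleCounts <- function(cells, labels = classifyCells(cells)) {
  stopifnot(is(cells, "CellPopulation"))
  cc <- cellTable(cells)
  stopIfNot(length(labels) == nrow(cc), "one label per cell is required")
  sp <- split(seq_len(nrow(cc)), list(rat = cc$rat, region = cc$region),
              drop = TRUE)
  rows <- lapply(names(sp), function(key) {
    idx <- sp[[key]]
    tl <- table(labels[idx])
    n <- length(idx)
    data.frame(rat = cc$rat[idx[1]], region = cc$region[idx[1]],
               nCells = n,
               fracNuclear = as.numeric(tl["nuclear"]) / n,
               fracCytoplasmic = as.numeric(tl["cytoplasmic"]) / n,
               fracDouble = as.numeric(tl["double"]) / n,
               fracNegative = as.numeric(tl["negative"]) / n)
  })
  out <- do.call(rbind, rows)
  out[order(out$rat, out$region), , drop = FALSE]
}

#' Attribute subcellular compartments to behavioral tasks
#'
#' Cytoplasmic labeling reflects the first behavioral epoch (transcripts
#' have had ~20 min to translocate) and nuclear labeling the second epoch
#' (1-2 min old foci). Task order is counterbalanced across rats, so the
#' mapping from compartment to task depends on which task each rat ran
#' first. Double-labeled cells were active in both epochs and count toward
#' both tasks (`doubles = "both"`, default) or can be excluded.
#'
#' @param counts data.frame from [ensembleCounts()].
#' @param taskOrder named character vector mapping rat id to the task run
#'   first, e.g. `c(rat1 = "WM/BAT", rat2 = "alternation")`.
#' @param tasks the two task names (default `c("WM/BAT", "alternation")`).
#' @param doubles `"both"` or `"exclude"`.
#' @return `counts` with added columns `taskFirst`, and per-task activity
#'   fractions named `frac<task>` keyed by task, not epoch.
#' @export
epochToTask <- function(counts, taskOrder,
                        tasks = c("WM/BAT", "alternation"),
                        doubles = c("both", "exclude")) {
  doubles <- match.arg(doubles)
  stopIfNot(all(counts$rat %in% names(taskOrder)),
            "every rat needs an entry in 'taskOrder'")
  stopIfNot(all(taskOrder[unique(counts$rat)] %in% tasks),
            "taskOrder values must be task names")
  dbl <- if (doubles == "both") counts$fracDouble else 0
  first <- unname(taskOrder[counts$rat])
  second <- ifelse(first == tasks[1], tasks[2], tasks[1])
  epoch1 <- counts$fracCytoplasmic + dbl  # earlier epoch: cytoplasmic
  epoch2 <- counts$fracNuclear + dbl      # recent epoch: nuclear
  out <- counts
  out$taskFirst <- first
  f1 <- paste0("frac.", make.names(tasks[1]))
  f2 <- paste0("frac.", make.names(tasks[2]))
  out[[f1]] <- ifelse(first == tasks[1], epoch1, epoch2)
  out[[f2]] <- ifelse(first == tasks[1], epoch2, epoch1)
  out
}

#' Ensemble similarity score
#'
#' Overlap of the ensembles active in the two epochs, normalized so that
#' statistical independence scores 0 and the maximal possible overlap
#' scores 1: `(pAB - pA pB) / (min(pA, pB) - pA pB)`, where pA and pB are
#' the fractions active in each epoch and pAB the double-labeled fraction.
#' Controls for overall activity-level differences between regions.
#'
#' @param pA,pB per-epoch active fractions, in (0, 1).
#' @param pAB observed overlap fraction, `0 <= pAB <= min(pA, pB)`.
#' @return numeric score; `NA` with a warning when the denominator is not
#'   positive (an epoch fraction of 1, or min = product).
#' @examples
#' similarityScore(0.10, 0.20, 0.05)  # 0.375
#' @export
similarityScore <- function(pA, pB, pAB) {
  stopIfNot(all(pA > 0 & pB > 0), "'pA' and 'pB' must be positive")
  stopIfNot(all(pAB >= 0 & pAB <= pmin(pA, pB) + 1e-12),
            "'pAB' must lie in [0, min(pA, pB)]")
  den <- pmin(pA, pB) - pA * pB
  out <- ifelse(den > 0, (pAB - pA * pB) / den, NA_real_)
  if (anyNA(out))
    warning("similarity undefined where min(pA, pB) equals pA*pB",
            call. = FALSE)
  out
}

#' Similarity scores per rat and region
#'
#' Convenience wrapper deriving pA (first epoch: cytoplasmic + double),
#' pB (second epoch: nuclear + double) and pAB (double) from ensemble
#' counts and applying [similarityScore()].
#'
#' @param counts data.frame from [ensembleCounts()].
#' @return `counts` with an added `similarity` column.
#' @export
ensembleSimilarity <- function(counts) {
  pA <- counts$fracCytoplasmic + counts$fracDouble
  pB <- counts$fracNuclear + counts$fracDouble
  counts$similarity <- similarityScore(pA, pB, counts$fracDouble)
  counts
}
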