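test_that("the central inclusion window follows the median-fraction rule", {
  expect_equal(centralWindow(20), c(9, 12))    # 4 planes of 20
  expect_equal(centralWindow(10), c(5, 6))     # 2 planes of 10
  expect_equal(centralWindow(5), c(3, 3))      # at least 1 plane
  expect_error(centralWindow(4), "at least 5")
})

test_that("inclusion filter drops edge-cut and off-window cells", {
  inWin <- makeCell(visible = c(1, 20))
  offWin <- makeCell(visible = c(1, 5))     # never reaches planes 9-12
  cut <- makeCell(visible = c(1, 20), edgeCut = TRUE)
  pop <- CellPopulation(
    rbind(cellTable(inWin), cellTable(offWin), cellTable(cut)),
    rbind(fociMatrix(inWin), fociMatrix(offWin), fociMatrix(cut)),
    rbind(coverageMatrix(inWin), coverageMatrix(offWin),
          coverageMatrix(cut)))
  kept <- inclusionFilter(pop)
  expect_equal(nrow(cellTable(kept)), 1L)
  expect_equal(S4Vectors::metadata(kept)$nExcluded, 2L)
  # the stricter "cover" rule also drops cells only touching the window
  touch <- makeCell(visible = c(1, 10))     # covers 9-10, not 11-12
  pop2 <- CellPopulation(rbind(cellTable(inWin), cellTable(touch)),
                         rbind(fociMatrix(inWin), fociMatrix(touch)),
                         rbind(coverageMatrix(inWin),
                               coverageMatrix(touch)))
  expect_equal(nrow(cellTable(inclusionFilter(pop2))), 2L)
  expect_equal(nrow(cellTable(inclusionFilter(pop2, rule = "cover"))), 1L)
})

test_that("classification follows the plane-based rules exactly", {
  cl <- function(cell, ...) as.character(classifyCells(cell, ...))
  # 1 focus on 4 consecutive planes -> nuclear
  expect_equal(cl(makeCell(fociPlanes = 6:9)), "nuclear")
  # only 3 consecutive planes -> negative
  expect_equal(cl(makeCell(fociPlanes = 6:8)), "negative")
  # 4 planes but not consecutive -> negative
  expect_equal(cl(makeCell(fociPlanes = c(5, 6, 8, 9))), "negative")
  # more than two foci per plane does not satisfy the criterion...
  expect_equal(cl(makeCell(fociPlanes = 6:10, fociCount = 3)), "negative")
  # ...unless the relaxed rule is requested
  expect_equal(cl(makeCell(fociPlanes = 6:10, fociCount = 3),
                  fociRule = "atLeast1"), "nuclear")
  # coverage >= 1/3 on two adjacent planes -> cytoplasmic
  expect_equal(cl(makeCell(coverPlanes = 10:11, coverValue = 0.34)),
               "cytoplasmic")
  # a single plane, or sub-threshold coverage, is not enough
  expect_equal(cl(makeCell(coverPlanes = 10, coverValue = 0.9)), "negative")
  expect_equal(cl(makeCell(coverPlanes = 10:11, coverValue = 0.32)),
               "negative")
  # both criteria -> double
  expect_equal(cl(makeCell(fociPlanes = 5:8, coverPlanes = 12:13,
                           coverValue = 0.5)), "double")
})

test_that("task attribution maps compartments by epoch order", {
  counts <- data.frame(rat = c("r1", "r2"), region = "ACC", nCells = 100,
                       fracNuclear = c(0.2, 0.3),
                       fracCytoplasmic = c(0.1, 0.05),
                       fracDouble = c(0.05, 0.1),
                       fracNegative = c(0.65, 0.55))
  ord <- c(r1 = "WM/BAT", r2 = "alternation")
  out <- epochToTask(counts, ord)
  # r1 ran WM/BAT first: its activity = cytoplasmic + double
  expect_equal(out$frac.WM.BAT[1], 0.1 + 0.05)
  expect_equal(out$frac.alternation[1], 0.2 + 0.05)
  # r2 ran alternation first: attributions swap roles
  expect_equal(out$frac.alternation[2], 0.05 + 0.1)
  expect_equal(out$frac.WM.BAT[2], 0.3 + 0.1)
  # swapping the declared order swaps the attributions exactly
  swapped <- epochToTask(counts, c(r1 = "alternation", r2 = "WM/BAT"))
  expect_equal(swapped$frac.WM.BAT, out$frac.alternation)
  expect_equal(swapped$frac.alternation, out$frac.WM.BAT)
  # totals conserved under attribution
  expect_equal(out$frac.WM.BAT + out$frac.alternation,
               counts$fracCytoplasmic + counts$fracNuclear +
                 2 * counts$fracDouble)
  # doubles can be excluded instead
  excl <- epochToTask(counts, ord, doubles = "exclude")
  expect_equal(excl$frac.WM.BAT[1], 0.1)
  expect_error(epochToTask(counts, c(r1 = "WM/BAT")), "every rat")
})

test_that("similarity score has its independence/overlap fixed points", {
  expect_equal(similarityScore(0.3, 0.4, 0.12), 0)          # independence
  expect_equal(similarityScore(0.3, 0.4, 0.3), 1)           # max overlap
  expect_equal(similarityScore(0.10, 0.20, 0.05), 0.375)
  # symmetric in (pA, pB)
  expect_equal(similarityScore(0.1, 0.2, 0.05),
               similarityScore(0.2, 0.1, 0.05))
  expect_warning(s <- similarityScore(1, 0.5, 0.5), "undefined")
  expect_true(is.na(s))
  expect_error(similarityScore(0, 0.2, 0), "positive")
})

test_that("per-rat aggregation is immune to image imbalance", {
  pop <- simulateCellPopulation(cellSimConfig(
    nCells = 600, rats = c("r1", "r2", "r3"), edgeCutFraction = 0,
    seed = 13))
  inc <- inclusionFilter(pop)
  counts <- ensembleCounts(inc)
  expect_true(all(abs(rowSums(counts[, c("fracNuclear", "fracCytoplasmic",
                                         "fracDouble", "fracNegative")]) -
                        1) < 1e-9))
  # duplicating every r1 cell (a second identical image) leaves the r1
  # fractions unchanged
  cc <- cellTable(inc)
  i1 <- which(cc$rat == "r1")
  dup <- CellPopulation(rbind(cc, cc[i1, ]),
                        rbind(fociMatrix(inc), fociMatrix(inc)[i1, ]),
                        rbind(coverageMatrix(inc),
                              coverageMatrix(inc)[i1, ]))
  countsDup <- ensembleCounts(dup)
  c1 <- counts[counts$rat == "r1", -3]      # drop nCells
  d1 <- countsDup[countsDup$rat == "r1", -3]
  rownames(c1) <- rownames(d1) <- NULL
  expect_equal(d1, c1)
})
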