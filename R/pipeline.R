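#' Study-level pipeline configuration
#'
#' Resolves every tunable parameter of the end-to-end demonstration
#' pipeline: the simulated longitudinal design (two age groups scanned
#' over several sessions), the preprocessing band, the graph thresholds,
#' the behavioral and catFISH generators, and the planted group-by-session
#' effects. Defaults reproduce the emulated study geometry: 5 subjects per
#' group, 3 scan sessions, 150 bilateral ROIs, 300 volumes at 2 s; graph
#' density 0.15, band 0.01-0.1 Hz, 9 equilibration volumes dropped,
#' strength/degree subnetwork thresholds 15/40, display cutoff 0.3,
#' central catFISH window 0.2, alpha 0.05. The planted effects give the
#' aged group a session-increasing ACC-DLS/DMS coupling and a
#' session-increasing hub-club coupling while the young group stays flat —
#' the pattern the group statistics are meant to recover.
#'
#' @param nPerGroup,nSessions,nRois,nVolumes,dt design geometry.
#' @param groups group labels; the *second* carries the planted session
#'   effects.
#' @param density,band,nDrop,sMin,kMin,displayCutoff,medianFraction,alpha
#'   analysis parameters (see the stage functions).
#' @param blockR,nBlocks,hubSet,hubR module structure of the planted
#'   covariance.
#' @param hubClubR list of per-session hub-club correlation targets, one
#'   numeric vector per group.
#' @param seedPairR list of per-session seed-pair (ACC-target) correlation
#'   targets, one vector per group.
#' @param seedRegion,targetRegions seed analysis regions.
#' @param driftAmplitude,nuisanceAmplitude,noiseSd nuisance model scales.
#' @param sideBias,pCorrect per-group per-day behavioral trajectories
#'   (lists of length-`nSessions` vectors).
#' @param pWme per-attempt working-memory-error probability.
#' @param nTrialsPerDay object-choice trials per day (default 32).
#' @param cellsPerRat,nPlanes,cellFractions catFISH generator settings
#'   (fractions: nuclear, cytoplasmic, double, negative).
#' @param richClubKRange k grid for the group comparison (`NULL` = data
#'   driven).
#' @param seed master RNG seed; all per-subject seeds derive from it.
#' @return a `list` of resolved parameters (class `studyConfig`).
#' @export
studyConfig <- function(nPerGroup = 5, nSessions = 3, nRois = 150,
                        nVolumes = 300, dt = 2,
                        groups = c("young", "aged"),
                        density = 0.15, band = c(0.01, 0.1), nDrop = 9,
                        sMin = 15, kMin = 40, displayCutoff = 0.3,
                        medianFraction = 0.2, alpha = 0.05,
                        blockR = 0.25, nBlocks = 6,
                        hubSet = seq(7, min(18, nRois)),
                        hubR = 0.35,
                        hubClubR = list(rep(0.35, nSessions),
                                        seq(0.35, 0.7,
                                            length.out = nSessions)),
                        seedPairR = list(rep(0.15, nSessions),
                                         seq(0.15, 0.65,
                                             length.out = nSessions)),
                        seedRegion = "ACC",
                        targetRegions = c("DLS", "DMS"),
                        driftAmplitude = 1, nuisanceAmplitude = 0.5,
                        noiseSd = 1,
                        sideBias = list(c(0.8, 0.65, 0.5)[seq_len(nSessions)],
                                        rep(0.9, nSessions)),
                        pCorrect = list(seq(0.55, 0.8,
                                            length.out = nSessions),
                                        rep(0.55, nSessions)),
                        pWme = 0.1, nTrialsPerDay = 32,
                        cellsPerRat = 400, nPlanes = 20,
                        cellFractions = c(0.2, 0.1, 0.05, 0.65),
                        richClubKRange = NULL,
                        seed = 1L) {
  cfg <- as.list(environment())
  names(cfg$hubClubR) <- names(cfg$seedPairR) <- groups
  names(cfg$sideBias) <- names(cfg$pCorrect) <- groups
  stopIfNot(length(groups) == 2L, "exactly two groups are supported")
  stopIfNot(density > 0 && density <= 1, "'density' must lie in (0, 1]")
  stopIfNot(band[1] > 0 && band[2] > band[1] && band[2] < 1 / (2 * dt),
            "band edges must satisfy 0 < low < high < Nyquist")
  class(cfg) <- "studyConfig"
  cfg
}

# simulation config of one subject-session acquisition
.sessionSimConfig <- function(cfg, group, subjectIdx, session) {
  labs <- defaultRoiLabels(cfg$nRois)
  pairs <- lapply(cfg$targetRegions, function(tg)
    list(c(paste0(cfg$seedRegion, "_L"), paste0(tg, "_L")),
         c(paste0(cfg$seedRegion, "_R"), paste0(tg, "_R"))))
  pairs <- unlist(pairs, recursive = FALSE)
  gi <- match(group, cfg$groups)
  timeSeriesSimConfig(
    nRois = cfg$nRois, nVolumes = cfg$nVolumes, dt = cfg$dt,
    roiLabels = labs, nBlocks = cfg$nBlocks, blockR = cfg$blockR,
    hubSet = cfg$hubSet, hubR = cfg$hubR,
    hubClubR = cfg$hubClubR[[gi]][session],
    seedPairs = pairs, seedPairR = cfg$seedPairR[[gi]][session],
    driftAmplitude = cfg$driftAmplitude,
    nuisanceAmplitude = cfg$nuisanceAmplitude, noiseSd = cfg$noiseSd,
    seed = childSeed(cfg$seed, (gi - 1) * 100000 + subjectIdx * 1000 + session))
}

#' Simulate the imaging arm of a study
#'
#' Generates one acquisition per subject and session under the planted
#' design of `cfg` and runs the signal-conditioning chain on each.
#'
#' @param cfg a [studyConfig()].
#' @param preprocess run [preprocessSeries()] on each acquisition
#'   (default `TRUE`).
#' @return data.frame-backed list: `info` (subject, group, session) and
#'   `series` (list of [RoiTimeSeriesSet-class], same order).
#' @export
simulateStudySeries <- function(cfg, preprocess = TRUE) {
  info <- expand.grid(subjectIdx = seq_len(cfg$nPerGroup),
                      group = cfg$groups, session = seq_len(cfg$nSessions),
                      stringsAsFactors = FALSE)
  info$subject <- paste0(substr(info$group, 1, 1), info$subjectIdx)
  series <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    sc <- .sessionSimConfig(cfg, info$group[i], info$subjectIdx[i],
                            info$session[i])
    x <- simulateRoiTimeSeries(sc)
    if (preprocess)
      x <- preprocessSeries(x, low = cfg$band[1], high = cfg$band[2])
    series[[i]] <- x
  }
  list(info = info[, c("subject", "group", "session")], series = series)
}

#' Seed-connectivity long table for a set of subjects
#'
#' Hemisphere-averaged seed-target Fisher z per subject, session and
#' target region, with the across-target mean in `value` — the input of
#' the group-by-session interaction test.
#'
#' @param cms list of [ConnectivityMatrix-class], one per row of `info`.
#' @param info data.frame with `subject`, `group`, `session`.
#' @param seedRegion,targetRegions regions passed to [seedConnectivity()].
#' @return data.frame: `subject`, `group`, `session`, one `z<target>`
#'   column per target, and `value` (their mean).
#' @export
seedConnectivityTable <- function(cms, info, seedRegion = "ACC",
                                  targetRegions = c("DLS", "DMS")) {
  stopIfNot(length(cms) == nrow(info),
            "'cms' and 'info' must align row by row")
  rows <- lapply(seq_along(cms), function(i) {
    sc <- seedConnectivity(cms[[i]], seedRegion, targetRegions)
    z <- stats::setNames(sc$zMean, paste0("z", sc$target))
    cbind(info[i, , drop = FALSE], as.data.frame(as.list(z)),
          value = mean(sc$zMean))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full demonstration pipeline
#'
#' Executes simulate -> preprocess -> connectome -> behavior / catFISH ->
#' group statistics on fully synthetic data, writing intermediate tables,
#' a run log and a summary report to `outDir`. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [studyConfig()].
#' @param outDir output directory (created if needed); `NULL` skips all
#'   file output.
#' @return (invisibly) a report list: `config`, `seedTable`,
#'   `seedAnova`, `richClub` (per-k comparison), `subnetwork`, `behavior`,
#'   `biasConnectivity` (pooled within-group-z correlation), `catfish`
#'   (per-rat counts with task attribution and similarity), and
#'   `similarityAnova`.
#' @examples
#' \donttest{
#' cfg <- studyConfig(nPerGroup = 2, nSessions = 2, nRois = 20,
#'                    nVolumes = 80, cellsPerRat = 100)
#' rep <- runPipeline(cfg, outDir = NULL)
#' rep$seedAnova
#' }
#' @export
runPipeline <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "studyConfig"))
  t0 <- Sys.time()
  emit <- function(name, writer) {
    if (!is.null(outDir)) writer(file.path(outDir, name))
  }
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit("config.json", function(p)
    jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE))

  ## imaging arm --------------------------------------------------------
  sim <- simulateStudySeries(cfg)
  cms <- lapply(sim$series, correlationMatrix, nDrop = cfg$nDrop)
  graphs <- lapply(cms, thresholdDensity, density = cfg$density)
  seedTab <- seedConnectivityTable(cms, sim$info, cfg$seedRegion,
                                   cfg$targetRegions)
  seedAnova <- mixedAnova(seedTab)
  rcTab <- richClubTable(graphs, kRange = .autoKRange(graphs, cfg),
                         info = sim$info)
  rcComp <- richclubGroupComparison(rcTab, alpha = cfg$alpha)
  lastSession <- sim$info$session == cfg$nSessions
  subnet <- lapply(split(which(lastSession), sim$info$group[lastSession]),
                   function(i) highStrengthSubnetwork(graphs[i],
                                                      sMin = cfg$sMin,
                                                      kMin = cfg$kMin))
  emit("seed_connectivity.tsv", function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(fileHeader("seed", cfg$seed, cfg["density"]), con)
    utils::write.table(seedTab, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  })
  emit("richclub_perk.tsv", function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(fileHeader("richclub", cfg$seed, cfg["density"]), con)
    utils::write.table(rcComp$perK, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  })
  if (!is.null(outDir)) {
    i <- which(sim$info$subject == sim$info$subject[1] &
                 sim$info$session == 1L)[1]
    writeRoiTimeSeries(sim$series[[i]],
                       file.path(outDir, "example_series.tsv"),
                       stage = "preprocess", seed = cfg$seed)
    writeConnectivityMatrix(cms[[i]],
                            file.path(outDir, "example_matrix.tsv"),
                            stage = "graph", seed = cfg$seed)
    writeEdgeList(graphs[[i]], file.path(outDir, "example_edges.tsv"),
                  minWeight = cfg$displayCutoff, seed = cfg$seed)
  }

  ## behavioral arm -----------------------------------------------------
  subjects <- unique(sim$info[, c("subject", "group")])
  behav <- lapply(seq_len(nrow(subjects)), function(i) {
    g <- subjects$group[i]
    log <- simulateTrialLog(behaviorSimConfig(
      nTrialsPerDay = cfg$nTrialsPerDay, nDays = cfg$nSessions,
      sideBias = cfg$sideBias[[g]], pCorrect = cfg$pCorrect[[g]],
      pWme = cfg$pWme,
      seed = childSeed(cfg$seed, 500000 + i)))
    cbind(subject = subjects$subject[i], group = g,
          summarizeSessions(log))
  })
  behavTab <- do.call(rbind, behav)
  emit("behavior_summary.tsv", function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(fileHeader("behavior", cfg$seed, list()), con)
    utils::write.table(behavTab, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  })
  # bias-connectivity correlation on within-group z-scores, pooling
  # subject x session observations (day d pairs with scan session d)
  m <- merge(seedTab, behavTab[, c("subject", "day", "responseBias")],
             by.x = c("subject", "session"), by.y = c("subject", "day"))
  zBias <- withinGroupZscore(m$responseBias, m$group)
  zConn <- withinGroupZscore(m$value, m$group)
  biasConn <- pooledCorrelation(zConn, zBias)

  ## catFISH arm --------------------------------------------------------
  rats <- subjects$subject
  taskOrder <- stats::setNames(
    rep(c("WM/BAT", "alternation"), length.out = length(rats)), rats)
  pop <- simulateCellPopulation(cellSimConfig(
    nCells = cfg$cellsPerRat * length(rats), nPlanes = cfg$nPlanes,
    fracNuclear = cfg$cellFractions[1],
    fracCytoplasmic = cfg$cellFractions[2],
    fracDouble = cfg$cellFractions[3],
    fracNegative = cfg$cellFractions[4],
    rats = rats, seed = childSeed(cfg$seed, 900001)))
  included <- inclusionFilter(pop, cfg$medianFraction)
  counts <- ensembleCounts(included)
  counts <- epochToTask(counts, taskOrder)
  counts <- ensembleSimilarity(counts)
  simTab <- data.frame(subject = counts$rat,
                       group = subjects$group[match(counts$rat,
                                                    subjects$subject)],
                       session = counts$region,  # within factor: region
                       value = counts$similarity)
  similarityAnova <- tryCatch(mixedAnova(simTab),
                              error = function(e) conditionMessage(e))
  emit("catfish_counts.tsv", function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(fileHeader("catfish", cfg$seed,
                          list(medianFraction = cfg$medianFraction)), con)
    utils::write.table(counts, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  })

  report <- list(config = cfg, seedTable = seedTab, seedAnova = seedAnova,
                 richClub = rcComp, subnetwork = subnet,
                 behavior = behavTab, biasConnectivity = biasConn,
                 catfish = counts, similarityAnova = similarityAnova)
  emit("run_log.txt", function(p) writeLines(c(
    sprintf("ratconnectome %s", as.character(utils::packageVersion("ratconnectome"))),
    sprintf("R %s", R.version.string),
    sprintf("seed %d", cfg$seed),
    sprintf("config %s", configHash(unclass(cfg))),
    sprintf("elapsed %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))), p))
  emit("report_summary.txt", function(p) {
    sink(p); on.exit(sink())
    cat("== seed-connectivity mixed ANOVA ==\n"); print(seedAnova)
    cat("\n== rich-club significant bands ==\n"); print(rcComp$bands)
    cat("\n== bias-connectivity pooled correlation ==\n")
    cat(sprintf("R = %.3f, F(%d,%d) = %.2f, p = %.4g\n", biasConn$R,
                biasConn$df[1], biasConn$df[2], biasConn$F, biasConn$p))
    cat("\n== high-strength subnetwork (last session) ==\n")
    for (g in names(subnet))
      cat(g, ":", paste(subnet[[g]]$nodes, collapse = ", "), "\n")
  })
  invisible(report)
}

# data-driven k grid: thresholds defined for every subject-session
.autoKRange <- function(graphs, cfg) {
  if (!is.null(cfg$richClubKRange)) return(cfg$richClubKRange)
  maxk <- min(vapply(graphs, function(g) max(nodeDegree(g)), numeric(1)))
  seq(1L, max(2L, as.integer(maxk - 1L)))
}
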