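#' Configuration for ROI time-series simulation
#'
#' Describes one simulated resting-state acquisition: a planted ROI-by-ROI
#' correlation structure (block modules, an optional densely coupled hub
#' set, and an optional named seed pair), plus additive drift, shared
#' nuisance components and white noise. The defaults emulate the acquisition
#' design the package targets: 150 bilateral ROIs, 300 volumes at a 2 s
#' sampling interval (10 min).
#'
#' @slot nRois,nVolumes,dt acquisition geometry.
#' @slot roiLabels ROI labels (`_L`/`_R` suffix marks hemisphere).
#' @slot blocks list of integer vectors partitioning `1:nRois` into modules.
#' @slot blockR within-module correlation target per block, each in `[0, 1)`.
#' @slot hubSet ROI indices forming a planted hub set (rich club).
#' @slot hubR correlation target between a hub and any non-hub ROI outside
#'   its own module.
#' @slot hubClubR correlation target among hub pairs (the club itself);
#'   defaults to `hubR`.
#' @slot seedPairs list of length-2 character vectors of ROI labels whose
#'   pairwise correlation is pinned to `seedPairR` (e.g. an ACC-DLS pair).
#' @slot seedPairR target correlation for the seed pairs (`NA` = none).
#' @slot driftAmplitude SD of the random linear/quadratic drift
#'   coefficients (arbitrary units).
#' @slot nuisanceAmplitude scale of shared nuisance components (two slow
#'   sinusoids below 0.01 Hz plus six smooth motion-like regressors).
#' @slot noiseSd SD of additive white noise.
#' @slot seed integer RNG seed.
#' @export
setClass("TimeSeriesSimConfig",
  representation(
    nRois = "integer", nVolumes = "integer", dt = "numeric",
    roiLabels = "character",
    blocks = "list", blockR = "numeric",
    hubSet = "integer", hubR = "numeric", hubClubR = "numeric",
    seedPairs = "list", seedPairR = "numeric",
    driftAmplitude = "numeric", nuisanceAmplitude = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("TimeSeriesSimConfig", function(object) {
  msg <- character()
  if (object@nRois < 2L) msg <- c(msg, "'nRois' must be >= 2")
  if (object@nVolumes < 4L) msg <- c(msg, "'nVolumes' must be >= 4")
  if (object@dt <= 0) msg <- c(msg, "'dt' must be positive")
  idx <- sort(unlist(object@blocks))
  if (!identical(idx, seq_len(object@nRois)))
    msg <- c(msg, "'blocks' must partition 1:nRois exactly once")
  if (length(object@blockR) != length(object@blocks))
    msg <- c(msg, "one within-module correlation target per block is required")
  targets <- c(object@blockR, object@hubR, object@hubClubR,
               object@seedPairR[!is.na(object@seedPairR)])
  if (any(targets < 0 | targets >= 1))
    msg <- c(msg, "all correlation targets must lie in [0, 1)")
  if (length(object@roiLabels) != object@nRois)
    msg <- c(msg, "one label per ROI is required")
  if (length(object@hubSet) &&
      (min(object@hubSet) < 1L || max(object@hubSet) > object@nRois))
    msg <- c(msg, "'hubSet' indices out of range")
  for (p in object@seedPairs)
    if (!all(p %in% object@roiLabels))
      msg <- c(msg, "seed-pair labels must be ROI labels")
  if (length(msg)) msg else TRUE
})

#' @describeIn TimeSeriesSimConfig-class Constructor with study defaults.
#' @param nRois,nVolumes,dt,roiLabels,blocks,blockR,hubSet,hubR,hubClubR
#'   see slots.
#' @param seedPairs,seedPairR,driftAmplitude,nuisanceAmplitude,noiseSd,seed
#'   see slots.
#' @param nBlocks number of sequential modules used when `blocks` is not
#'   given.
#' @export
timeSeriesSimConfig <- function(nRois = 150, nVolumes = 300, dt = 2,
                                roiLabels = defaultRoiLabels(nRois),
                                blocks = NULL, nBlocks = 6, blockR = 0.3,
                                hubSet = integer(0), hubR = 0.3,
                                hubClubR = hubR,
                                seedPairs = list(), seedPairR = NA_real_,
                                driftAmplitude = 1, nuisanceAmplitude = 0.5,
                                noiseSd = 1, seed = 1L) {
  nRois <- as.integer(nRois)
  if (is.null(blocks)) {
    grp <- sort(rep_len(seq_len(nBlocks), nRois))
    blocks <- split(seq_len(nRois), grp)
    names(blocks) <- NULL
  }
  blockR <- rep_len(blockR, length(blocks))
  new("TimeSeriesSimConfig",
      nRois = nRois, nVolumes = as.integer(nVolumes), dt = as.numeric(dt),
      roiLabels = roiLabels, blocks = blocks, blockR = as.numeric(blockR),
      hubSet = as.integer(hubSet), hubR = as.numeric(hubR),
      hubClubR = as.numeric(hubClubR),
      seedPairs = seedPairs, seedPairR = as.numeric(seedPairR),
      driftAmplitude = as.numeric(driftAmplitude),
      nuisanceAmplitude = as.numeric(nuisanceAmplitude),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Planted correlation matrix of a simulation configuration
#'
#' Builds the target correlation matrix (block-constant modules, hub rows,
#' pinned seed pairs) and projects it to the nearest positive-semidefinite
#' correlation matrix by eigenvalue clipping followed by diagonal
#' renormalization. This is the population correlation the simulated series
#' converge to; the projection can move targets slightly when the requested
#' structure is not exactly attainable.
#'
#' @param config a [TimeSeriesSimConfig-class].
#' @return symmetric positive-semidefinite correlation matrix with ROI
#'   labels as dimnames.
#' @export
plantedCorrelation <- function(config) {
  stopifnot(is(config, "TimeSeriesSimConfig"))
  validObject(config)
  n <- config@nRois
  R <- diag(n)
  for (b in seq_along(config@blocks)) {
    idx <- config@blocks[[b]]
    R[idx, idx] <- config@blockR[b]
  }
  hubs <- config@hubSet
  if (length(hubs)) {
    # hubs couple across the whole graph at hubR, and to each other at
    # hubClubR; existing stronger within-module coupling is kept
    R[hubs, ] <- pmax(R[hubs, ], config@hubR)
    R[, hubs] <- pmax(R[, hubs], config@hubR)
    R[hubs, hubs] <- pmax(config@hubClubR, R[hubs, hubs] * 0)
  }
  if (length(config@seedPairs) && !is.na(config@seedPairR)) {
    for (p in config@seedPairs) {
      i <- match(p[1], config@roiLabels); j <- match(p[2], config@roiLabels)
      R[i, j] <- R[j, i] <- config@seedPairR
    }
  }
  diag(R) <- 1
  # nearest-PSD projection: clip negative eigenvalues, restore unit diagonal
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 0) {
    lam <- pmax(e$values, 0)
    R <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    R <- (R + t(R)) / 2
    diag(R) <- 1
  }
  dimnames(R) <- list(config@roiLabels, config@roiLabels)
  R
}

#' Simulate an ROI time-series acquisition
#'
#' Draws `nVolumes` samples from the planted correlation structure of
#' `config` (via the symmetric matrix square root, so degenerate targets
#' such as r = 1 are reproduced exactly), then adds per-ROI linear plus
#' quadratic drift, shared slow nuisance components with random ROI
#' loadings, and white noise. Deterministic given `config@seed`.
#'
#' @param config a [TimeSeriesSimConfig-class].
#' @return a [RoiTimeSeriesSet-class]; `metadata()` holds `confounds` (the
#'   8 x time nuisance regressor matrix: six motion-like plus two slow
#'   physiological-like components), `plantedCorrelation`, and the seed.
#' @examples
#' cfg <- timeSeriesSimConfig(nRois = 10, nVolumes = 120, seed = 7)
#' x <- simulateRoiTimeSeries(cfg)
#' x
#' @export
simulateRoiTimeSeries <- function(config) {
  stopifnot(is(config, "TimeSeriesSimConfig"))
  validObject(config)
  n <- config@nRois; tn <- config@nVolumes; dt <- config@dt
  R <- plantedCorrelation(config)
  e <- eigen(R, symmetric = TRUE)
  sqrtm <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  withSeed(config@seed, {
    latent <- matrix(stats::rnorm(tn * n), tn, n) %*% sqrtm  # time x ROI
    tt <- seq_len(tn) / tn
    # drift: per-ROI intercept + linear + quadratic with random coefficients
    coefs <- matrix(stats::rnorm(3 * n, sd = config@driftAmplitude), 3, n)
    drift <- cbind(1, tt, tt^2) %*% coefs
    # nuisance: two slow sinusoids (< 0.01 Hz) standing in for
    # ventricular/white-matter signals, plus six smooth motion-like
    # regressors; all shared across ROIs through random loadings
    secs <- (seq_len(tn) - 1L) * dt
    f <- stats::runif(2, 0.002, 0.008)
    ph <- stats::runif(2, 0, 2 * pi)
    physio <- cbind(sin(2 * pi * f[1] * secs + ph[1]),
                    sin(2 * pi * f[2] * secs + ph[2]))
    motion <- sapply(seq_len(6), function(i) {
      w <- cumsum(stats::rnorm(tn))
      s <- stats::filter(w, rep(1 / 15, 15), sides = 2, circular = TRUE)
      as.numeric(scale(as.numeric(s)))
    })
    conf <- cbind(motion, physio)  # time x 8
    load <- matrix(stats::rnorm(8 * n), 8, n) * config@nuisanceAmplitude
    noise <- if (config@noiseSd > 0)
      matrix(stats::rnorm(tn * n, sd = config@noiseSd), tn, n) else 0
    y <- latent + drift + conf %*% load + noise + 100
    out <- RoiTimeSeriesSet(t(y), roiLabels = config@roiLabels, dt = dt)
    metadata(out) <- list(confounds = t(conf),
                          plantedCorrelation = R,
                          seed = config@seed)
    out
  })
}

## ---- behavior ------------------------------------------------------------

#' Configuration for behavioral trial-log simulation
#'
#' One simulated animal tested on the alternation maze for `nDays` sessions
#' of `nTrialsPerDay` object-choice trials each (32/day in the emulated
#' design). `sideBias` is the probability that an object choice is made on
#' the animal's fixed preferred side; `pWme` is the per-attempt probability
#' of a failed alternation, recorded as a working-memory error and not
#' logged as a trial.
#'
#' @slot nTrialsPerDay,nDays session geometry.
#' @slot sideBias probability in `[0, 1]` of choosing the preferred side;
#'   scalar, or one value per day for a drifting preference.
#' @slot pCorrect per-day accuracy trajectory (length `nDays`).
#' @slot pWme per-attempt probability of a same-direction turn.
#' @slot preferredSide `"left_well"` or `"right_well"`.
#' @slot seed integer RNG seed.
#' @export
setClass("BehaviorSimConfig",
  representation(
    nTrialsPerDay = "integer", nDays = "integer",
    sideBias = "numeric", pCorrect = "numeric", pWme = "numeric",
    preferredSide = "character", seed = "integer"
  )
)

setValidity("BehaviorSimConfig", function(object) {
  msg <- character()
  if (object@nTrialsPerDay < 1L) msg <- c(msg, "'nTrialsPerDay' must be positive")
  if (object@nDays < 1L) msg <- c(msg, "'nDays' must be positive")
  p <- c(object@sideBias, object@pCorrect, object@pWme)
  if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(object@pCorrect) != object@nDays)
    msg <- c(msg, "'pCorrect' must have one entry per day")
  if (!length(object@sideBias) %in% c(1L, object@nDays))
    msg <- c(msg, "'sideBias' must be scalar or one entry per day")
  if (!object@preferredSide %in% c("left_well", "right_well"))
    msg <- c(msg, "'preferredSide' must be 'left_well' or 'right_well'")
  if (length(msg)) msg else TRUE
})

#' @describeIn BehaviorSimConfig-class Constructor.
#' @param nTrialsPerDay,nDays,sideBias,pCorrect,pWme,preferredSide,seed see
#'   slots; `pCorrect` is recycled to `nDays`.
#' @export
behaviorSimConfig <- function(nTrialsPerDay = 32, nDays = 1, sideBias = 0.5,
                              pCorrect = 0.7, pWme = 0.1,
                              preferredSide = "left_well", seed = 1L) {
  new("BehaviorSimConfig",
      nTrialsPerDay = as.integer(nTrialsPerDay), nDays = as.integer(nDays),
      sideBias = as.numeric(sideBias),
      pCorrect = rep_len(as.numeric(pCorrect), as.integer(nDays)),
      pWme = as.numeric(pWme), preferredSide = preferredSide,
      seed = as.integer(seed))
}

#' Simulate a behavioral trial log
#'
#' Generates ordered attempted-trial records day by day. Each day starts
#' with a free-choice turn; on subsequent attempts the animal fails to
#' alternate with probability `pWme`, producing a WME record that carries
#' no object choice, and otherwise completes an object-choice trial whose
#' chosen side is the preferred side with probability `sideBias` and whose
#' correctness is Bernoulli with that day's `pCorrect`. A day ends when
#' `nTrialsPerDay` object-choice trials are logged.
#'
#' @param config a [BehaviorSimConfig-class].
#' @return a [TrialLog-class]
#' @examples
#' log <- simulateTrialLog(behaviorSimConfig(nDays = 2, sideBias = 0.8))
#' log
#' @export
simulateTrialLog <- function(config) {
  stopifnot(is(config, "BehaviorSimConfig"))
  validObject(config)
  other <- setdiff(c("left_well", "right_well"), config@preferredSide)
  biasByDay <- rep_len(config@sideBias, config@nDays)
  withSeed(config@seed, {
    rows <- vector("list", config@nDays)
    for (d in seq_len(config@nDays)) {
      nTrials <- 0L
      lastTurn <- sample(c("left", "right"), 1L)  # free first choice
      day <- list()
      # first attempt of the day is always an object-choice trial
      repeat {
        if (nTrials == 0L) {
          turn <- lastTurn
          isWme <- FALSE
        } else {
          isWme <- stats::runif(1) < config@pWme
          turn <- if (isWme) lastTurn else setdiff(c("left", "right"), lastTurn)
        }
        if (isWme) {
          day[[length(day) + 1L]] <- data.frame(
            day = d, kind = "wme", turn = turn,
            side = NA_character_, correct = NA)
        } else {
          side <- if (stats::runif(1) < biasByDay[d])
            config@preferredSide else other
          day[[length(day) + 1L]] <- data.frame(
            day = d, kind = "object_choice", turn = turn, side = side,
            correct = stats::runif(1) < config@pCorrect[d])
          nTrials <- nTrials + 1L
          lastTurn <- turn
        }
        if (nTrials >= config@nTrialsPerDay) break
      }
      rows[[d]] <- do.call(rbind, day)
    }
    TrialLog(do.call(rbind, rows))
  })
}

## ---- catFISH cells -------------------------------------------------------

#' Configuration for catFISH cell-population simulation
#'
#' Plants ground-truth nuclear / cytoplasmic / double / negative cells that
#' conform exactly to the plane-based classification rules: nuclear-positive
#' cells carry 1-2 foci on at least four consecutive planes, cytoplasmic
#' cells carry perimeter coverage of at least one third on at least two
#' adjacent planes, double cells both, negatives neither (including
#' boundary decoys: sub-threshold runs and over-threshold foci counts).
#'
#' @slot nCells number of candidate cells.
#' @slot nPlanes z-stack depth (default 20 planes at 1 um spacing).
#' @slot fracNuclear,fracCytoplasmic,fracDouble,fracNegative class
#'   fractions, summing to 1.
#' @slot edgeCutFraction fraction of cells flagged as cut off by the tissue
#'   edge (excluded from counting).
#' @slot rats,regions labels assigned uniformly to cells.
#' @slot seed integer RNG seed.
#' @export
setClass("CellSimConfig",
  representation(
    nCells = "integer", nPlanes = "integer",
    fracNuclear = "numeric", fracCytoplasmic = "numeric",
    fracDouble = "numeric", fracNegative = "numeric",
    edgeCutFraction = "numeric",
    rats = "character", regions = "character", seed = "integer"
  )
)

setValidity("CellSimConfig", function(object) {
  msg <- character()
  fr <- c(object@fracNuclear, object@fracCytoplasmic,
          object@fracDouble, object@fracNegative)
  if (abs(sum(fr) - 1) > 1e-9)
    msg <- c(msg, "class fractions must sum to 1")
  if (any(fr < 0)) msg <- c(msg, "class fractions must be non-negative")
  if (object@nPlanes < 5L) msg <- c(msg, "'nPlanes' must be >= 5")
  if (object@nCells < 1L) msg <- c(msg, "'nCells' must be positive")
  if (object@edgeCutFraction < 0 || object@edgeCutFraction > 1)
    msg <- c(msg, "'edgeCutFraction' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn CellSimConfig-class Constructor.
#' @param nCells,nPlanes,fracNuclear,fracCytoplasmic,fracDouble,fracNegative
#'   see slots.
#' @param edgeCutFraction,rats,regions,seed see slots.
#' @export
cellSimConfig <- function(nCells = 2000, nPlanes = 20,
                          fracNuclear = 0.2, fracCytoplasmic = 0.1,
                          fracDouble = 0.05, fracNegative = 0.65,
                          edgeCutFraction = 0.05,
                          rats = "rat1", regions = c("ACC", "DLS", "DMS"),
                          seed = 1L) {
  new("CellSimConfig", nCells = as.integer(nCells),
      nPlanes = as.integer(nPlanes),
      fracNuclear = fracNuclear, fracCytoplasmic = fracCytoplasmic,
      fracDouble = fracDouble, fracNegative = fracNegative,
      edgeCutFraction = edgeCutFraction,
      rats = rats, regions = regions, seed = as.integer(seed))
}

# place a run of `len` consecutive planes inside [lo, hi]
.sampleRun <- function(lo, hi, len) {
  start <- if (hi - len + 1L <= lo) lo else sample(lo:(hi - len + 1L), 1L)
  start + seq_len(len) - 1L
}

#' Simulate a catFISH cell population with planted labels
#'
#' @param config a [CellSimConfig-class].
#' @return a [CellPopulation-class] whose `cellTable()` includes a
#'   `trueLabel` column (`nuclear`, `cytoplasmic`, `double`, `negative`).
#' @examples
#' pop <- simulateCellPopulation(cellSimConfig(nCells = 50, seed = 3))
#' pop
#' @export
simulateCellPopulation <- function(config) {
  stopifnot(is(config, "CellSimConfig"))
  validObject(config)
  n <- config@nCells; np <- config@nPlanes
  w <- centralWindow(np)
  withSeed(config@seed, {
    labels <- sample(c("nuclear", "cytoplasmic", "double", "negative"),
                     n, replace = TRUE,
                     prob = c(config@fracNuclear, config@fracCytoplasmic,
                              config@fracDouble, config@fracNegative))
    foci <- matrix(0L, n, np)
    cover <- matrix(stats::runif(n * np, 0, 0.30), n, np)
    first <- integer(n); last <- integer(n)
    for (i in seq_len(n)) {
      # visible range always touches the central inclusion window and is
      # wide enough to host a four-plane nuclear run
      first[i] <- sample(seq_len(w[1]), 1L)
      last[i] <- sample(w[2]:np, 1L)
      if (last[i] - first[i] + 1L < 4L) last[i] <- min(np, first[i] + 3L)
      vis <- first[i]:last[i]
      cover[i, setdiff(seq_len(np), vis)] <- 0
      lab <- labels[i]
      if (lab %in% c("nuclear", "double")) {
        run <- .sampleRun(first[i], last[i],
                          min(sample(4:7, 1L), last[i] - first[i] + 1L))
        foci[i, run] <- sample(1:2, length(run), replace = TRUE)
      }
      if (lab %in% c("cytoplasmic", "double")) {
        run <- .sampleRun(first[i], last[i],
                          min(sample(2:4, 1L), last[i] - first[i] + 1L))
        cover[i, run] <- stats::runif(length(run), 0.34, 0.90)
      }
      if (lab == "negative") {
        u <- stats::runif(1)
        if (u < 0.2 && last[i] - first[i] >= 2L) {
          # decoy: a sub-threshold run of only 3 consecutive foci planes
          run <- .sampleRun(first[i], last[i], 3L)
          foci[i, run] <- sample(1:2, 3L, replace = TRUE)
        } else if (u < 0.35) {
          # decoy: many foci (> 2) never satisfy the nuclear rule
          run <- .sampleRun(first[i], last[i],
                            min(5L, last[i] - first[i] + 1L))
          foci[i, run] <- sample(3:5, length(run), replace = TRUE)
        } else if (u < 0.5) {
          # decoy: a single isolated plane above the coverage threshold
          hot <- sample(first[i]:last[i], 1L)
          cover[i, hot] <- stats::runif(1, 0.34, 0.9)
          # keep neighbours below threshold so only one plane is hot
          if (hot > 1L) cover[i, hot - 1L] <- min(cover[i, hot - 1L], 0.3)
          if (hot < np) cover[i, hot + 1L] <- min(cover[i, hot + 1L], 0.3)
        }
      }
    }
    cells <- data.frame(
      cellId = sprintf("cell%05d", seq_len(n)),
      rat = sample(config@rats, n, replace = TRUE),
      region = sample(config@regions, n, replace = TRUE),
      hemisphere = sample(c("left", "right"), n, replace = TRUE),
      nPlanes = np, visibleFirst = first, visibleLast = last,
      edgeCut = stats::runif(n) < config@edgeCutFraction,
      trueLabel = labels)
    out <- CellPopulation(cells, foci, cover)
    metadata(out) <- list(seed = config@seed)
    out
  })
}
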