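#' Extract ROI-mean time series from a labeled 4D volume
#'
#' Averages the intensity of all voxels sharing an atlas label at each
#' timepoint, producing one series per requested ROI. This is the optional
#' volume entry point; ROI-level delimited tables bypass it entirely.
#'
#' @param volume4d numeric 4D array (x, y, z, time), or a path to a 4D
#'   NIfTI file (read via the RNifti package).
#' @param atlas integer 3D array of the same spatial dimensions, or a path
#'   to a NIfTI label volume. Label 0 is background.
#' @param labels integer labels to extract; default: all positive labels
#'   present in the atlas, in increasing order.
#' @param roiLabels optional character names for the extracted ROIs
#'   (default `ROI<label>`).
#' @param dt sampling interval in seconds.
#' @param blurSigma optional isotropic Gaussian blur (voxels) applied to
#'   each volume before averaging; 0 (default) disables it, since ROI
#'   averaging already pools voxels.
#' @return a [RoiTimeSeriesSet-class]
#' @examples
#' vol <- array(0, c(4, 4, 2, 5)); atlas <- array(0L, c(4, 4, 2))
#' atlas[1:2, 1:2, 1] <- 1L; vol[1:2, 1:2, 1, ] <- 3
#' extractRoiSeries(vol, atlas, dt = 2)
#' @export
extractRoiSeries <- function(volume4d, atlas, labels = NULL,
                             roiLabels = NULL, dt = 2, blurSigma = 0) {
  if (is.character(volume4d)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
    volume4d <- as.array(RNifti::readNifti(volume4d))
  }
  if (is.character(atlas)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
    atlas <- as.array(RNifti::readNifti(atlas))
  }
  stopIfNot(length(dim(volume4d)) == 4L, "'volume4d' must be a 4D array")
  stopIfNot(identical(dim(volume4d)[1:3], dim(atlas)[1:3]),
            "atlas and volume must share spatial dimensions")
  atlas <- as.integer(round(atlas))
  present <- sort(unique(atlas[atlas > 0L]))
  if (is.null(labels)) labels <- present
  missing <- setdiff(labels, present)
  if (length(missing))
    stop("ROI label(s) absent from atlas: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tn <- dim(volume4d)[4]
  nvox <- prod(dim(volume4d)[1:3])
  flat <- matrix(volume4d, nrow = nvox, ncol = tn)
  if (blurSigma > 0) {
    for (t in seq_len(tn)) {
      v <- array(flat[, t], dim(volume4d)[1:3])
      flat[, t] <- as.vector(gaussianBlur3d(v, blurSigma))
    }
  }
  sig <- t(vapply(labels, function(l) colMeans(flat[atlas == l, , drop = FALSE]),
                  numeric(tn)))
  if (is.null(roiLabels)) roiLabels <- sprintf("ROI%d", labels)
  RoiTimeSeriesSet(sig, roiLabels = roiLabels, dt = dt)
}

# separable 3D Gaussian blur with reflecting edges (voxel units)
gaussianBlur3d <- function(v, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kx <- stats::dnorm(-r:r, sd = sigma); kx <- kx / sum(kx)
  smooth1 <- function(x) {
    n <- length(x)
    if (n <= r) return(x)  # too short along this axis to blur
    xp <- c(rev(x[seq_len(r)]), x, rev(x[seq.int(n - r + 1L, n)]))
    as.numeric(stats::filter(xp, kx, sides = 2))[r + seq_len(n)]
  }
  for (d in 1:3) v <- apply(v, setdiff(1:3, d), smooth1) |> aperm(order(c(d, setdiff(1:3, d))))
  v
}

#' Remove linear and quadratic trends and rescale to unit variance
#'
#' Per ROI, the least-squares fit of intercept + linear + quadratic time
#' terms is subtracted and the residual is rescaled to unit (sample)
#' variance — the intensity-normalization step of the conditioning chain.
#' ROIs left with zero variance are set to all zeros and flagged in
#' `metadata()$zeroVarianceRois` rather than propagating NaN.
#'
#' @param series a [RoiTimeSeriesSet-class] with at least 4 timepoints.
#' @param rescale rescale residuals to unit variance (default `TRUE`).
#' @return a [RoiTimeSeriesSet-class]
#' @export
detrendNormalize <- function(series, rescale = TRUE) {
  stopifnot(is(series, "RoiTimeSeriesSet"))
  tn <- nVolumes(series)
  stopIfNot(tn >= 4L, "detrending requires at least 4 timepoints")
  tt <- seq_len(tn) / tn
  X <- cbind(1, tt, tt^2)
  resid <- t(stats::lm.fit(X, t(signals(series)))$residuals)
  v <- apply(resid, 1L, stats::sd)
  zero <- which(v < .Machine$double.eps^0.5)
  if (rescale) {
    scl <- ifelse(v > 0, v, 1)
    resid <- resid / scl
  }
  if (length(zero)) {
    resid[zero, ] <- 0
    warning("zero-variance ROI(s) after detrending set to 0: ",
            paste(roiLabels(series)[zero], collapse = ", "), call. = FALSE)
  }
  out <- RoiTimeSeriesSet(resid, roiLabels = roiLabels(series),
                          hemisphere = hemispheres(series),
                          dt = samplingInterval(series))
  md <- metadata(series)
  md$zeroVarianceRois <- zero
  metadata(out) <- md
  out
}

#' Regress nuisance signals out of every ROI series
#'
#' Ordinary-least-squares residualization of each ROI series on an
#' intercept plus all confound regressors (motion-like components and
#' ventricular / white-matter signals). A rank-deficient confound matrix is
#' handled by pseudoinverse projection (via the SVD) with a warning, so
#' duplicated regressors give the same residual as a single copy.
#'
#' @param series a [RoiTimeSeriesSet-class].
#' @param confounds numeric matrix of confound regressors, either
#'   confound-by-time or time-by-confound (orientation is resolved against
#'   the series length). Defaults to `metadata(series)$confounds` when
#'   present.
#' @return a [RoiTimeSeriesSet-class] of residuals (mean removed).
#' @export
regressNuisance <- function(series, confounds = metadata(series)$confounds) {
  stopifnot(is(series, "RoiTimeSeriesSet"))
  stopIfNot(!is.null(confounds), "no confound regressors supplied")
  confounds <- as.matrix(confounds)
  tn <- nVolumes(series)
  if (ncol(confounds) != tn && nrow(confounds) == tn)
    confounds <- t(confounds)
  stopIfNot(ncol(confounds) == tn,
            "confounds must cover the same timepoints as the series")
  stopIfNot(nrow(confounds) <= tn - 2L,
            "more confound regressors than timepoints - 2")
  X <- cbind(1, t(confounds))                     # time x (1 + k)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient confound matrix; using pseudoinverse projection",
            call. = FALSE)
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * 1e-10
    U <- sv$u[, keep, drop = FALSE]
    resid <- t(signals(series)) - U %*% crossprod(U, t(signals(series)))
  } else {
    resid <- qr.resid(qx, t(signals(series)))
  }
  out <- RoiTimeSeriesSet(t(resid), roiLabels = roiLabels(series),
                          hemisphere = hemispheres(series),
                          dt = samplingInterval(series))
  metadata(out) <- metadata(series)
  out
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth band-pass applied forward and backward
#' ([signal::filtfilt]), i.e. zero phase shift and squared magnitude
#' response. The default band of 0.01-0.1 Hz isolates the low-frequency
#' fluctuations used for resting-state connectivity while removing drift
#' remnants and cardiac/respiratory aliases.
#'
#' @param series a [RoiTimeSeriesSet-class].
#' @param low,high band edges in Hz; must satisfy
#'   `0 < low < high < 1/(2 dt)` (the Nyquist frequency).
#' @param order Butterworth prototype order (default 4).
#' @return a [RoiTimeSeriesSet-class]
#' @examples
#' x <- RoiTimeSeriesSet(matrix(rnorm(600), 2), dt = 2)
#' y <- bandpassFilter(x)
#' @export
bandpassFilter <- function(series, low = 0.01, high = 0.1, order = 4) {
  stopifnot(is(series, "RoiTimeSeriesSet"))
  nyq <- 1 / (2 * samplingInterval(series))
  stopIfNot(low > 0 && high > low, "band edges must satisfy 0 < low < high")
  stopIfNot(high < nyq,
            sprintf("upper band edge must be below the Nyquist frequency (%g Hz)", nyq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  sig <- signals(series)
  filt <- t(apply(sig, 1L, function(x) signal::filtfilt(bf, x)))
  out <- RoiTimeSeriesSet(filt, roiLabels = roiLabels(series),
                          hemisphere = hemispheres(series),
                          dt = samplingInterval(series))
  metadata(out) <- metadata(series)
  out
}

#' Full signal-conditioning chain
#'
#' Applies, in order: detrending + intensity normalization, nuisance
#' regression (when confounds are available), and band-pass filtering.
#' The order mirrors standard resting-state practice.
#'
#' @param series a [RoiTimeSeriesSet-class].
#' @param confounds confound matrix, or `NULL` to use
#'   `metadata(series)$confounds` (skipped when absent).
#' @param low,high band edges in Hz.
#' @return a [RoiTimeSeriesSet-class]
#' @export
preprocessSeries <- function(series, confounds = NULL, low = 0.01, high = 0.1) {
  out <- detrendNormalize(series)
  conf <- if (is.null(confounds)) metadata(series)$confounds else confounds
  if (!is.null(conf)) out <- regressNuisance(out, conf)
  bandpassFilter(out, low = low, high = high)
}
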