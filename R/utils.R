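## internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream index; stays < 2^31.
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 9973) %% 2147483629)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Default ROI labels for a bilateral atlas
#'
#' Generates `n` ROI labels as hemisphere pairs (`_L`/`_R` suffix). The
#' first three region names are ACC, DLS and DMS — the seed and target
#' regions of the worked analyses — followed by generic region codes. An
#' odd `n` yields one final midline label.
#'
#' @param n number of ROIs.
#' @return character vector of length `n`.
#' @examples defaultRoiLabels(6)
#' @export
defaultRoiLabels <- function(n) {
  stopIfNot(n >= 1, "'n' must be positive")
  nRegions <- ceiling(n / 2)
  base <- c("ACC", "DLS", "DMS",
            sprintf("R%03d", seq_len(max(0L, nRegions - 3L)) + 3L))
  base <- base[seq_len(nRegions)]
  lab <- as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
  if (n %% 2 == 1L) lab[n] <- sub("_L$", "_M", lab[n])
  lab[seq_len(n)]
}
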