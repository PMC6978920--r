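#' Standardize measurements within groups
#'
#' Transforms values to z-scores computed separately within each group
#' (sample SD). Standardizing within groups before pooling removes
#' between-group mean offsets, so a pooled correlation cannot be driven by
#' a group difference alone (the Simpson's-paradox confound this procedure
#' exists to remove).
#'
#' @param values numeric vector.
#' @param groups factor/vector of group membership, same length.
#' @return numeric vector; groups with fewer than 2 members or zero
#'   variance yield `NA` with a warning.
#' @export
withinGroupZscore <- function(values, groups) {
  stopIfNot(length(values) == length(groups),
            "'values' and 'groups' must have equal length")
  out <- rep(NA_real_, length(values))
  bad <- character()
  for (g in unique(groups)) {
    i <- which(groups == g)
    s <- stats::sd(values[i])
    if (length(i) < 2L || !is.finite(s) || s == 0) {
      bad <- c(bad, as.character(g))
    } else {
      out[i] <- (values[i] - mean(values[i])) / s
    }
  }
  if (length(bad))
    warning("group(s) with <2 members or zero variance left NA: ",
            paste(bad, collapse = ", "), call. = FALSE)
  out
}

#' Pooled correlation with F test
#'
#' Pearson correlation of paired (typically within-group standardized)
#' values, with the regression F statistic `R^2 (n-2) / (1 - R^2)` on
#' (1, n-2) degrees of freedom and its two-sided p value.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return list with `R`, `F`, `df`, `p`, `n`.
#' @export
pooledCorrelation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stopIfNot(n >= 3L, "at least 3 complete pairs are required")
  stopIfNot(stats::sd(x) > 0 && stats::sd(y) > 0,
            "correlation undefined for zero-variance input")
  R <- stats::cor(x, y)
  Fv <- R^2 * (n - 2) / (1 - R^2)
  list(R = R, F = Fv, df = c(1L, n - 2L),
       p = stats::pf(Fv, 1, n - 2, lower.tail = FALSE), n = n)
}

#' Mixed (between x within) repeated-measures ANOVA
#'
#' Classical sums-of-squares decomposition for one between-subject factor
#' (group) crossed with one within-subject factor (session), with subjects
#' nested in groups: the group effect is tested against subject-within-
#' group variation, and session and the group x session interaction
#' against the session x subject-within-group residual. Fitting goes
#' through [stats::aov] with an `Error(subject)` stratum. The design must
#' be complete (every subject measured in every session); anything else is
#' an explicit error, not a silent fallback. No sphericity correction is
#' applied by default (uncorrected degrees of freedom are reported);
#' Greenhouse-Geisser is available.
#'
#' @param table data.frame with columns `subject`, `group`, `session`,
#'   `value` (extra columns ignored).
#' @param sphericity `"none"` (default) or `"greenhouse-geisser"`.
#' @param nPerm if > 0, adds permutation p values as a cross-check:
#'   subject-level group relabeling for the group and interaction effects,
#'   within-subject session shuffling for the session effect.
#' @param seed RNG seed for the permutations.
#' @return data.frame with rows `group`, `session`, `group:session` and
#'   columns `effect`, `df1`, `df2`, `F`, `p` (plus `pPerm`, `epsilon`
#'   when requested).
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:6), session = 1:3)
#' d$group <- rep(c("young", "aged"), each = 3)[match(d$subject,
#'             paste0("s", 1:6))]
#' d$value <- rnorm(nrow(d))
#' mixedAnova(d)
#' @export
mixedAnova <- function(table, sphericity = c("none", "greenhouse-geisser"),
                       nPerm = 0, seed = 1L) {
  sphericity <- match.arg(sphericity)
  need <- c("subject", "group", "session", "value")
  stopIfNot(all(need %in% names(table)),
            paste("table needs columns:", paste(need, collapse = ", ")))
  d <- data.frame(subject = factor(table$subject),
                  group = factor(table$group),
                  session = factor(table$session),
                  value = as.numeric(table$value))
  stopIfNot(!anyNA(d$value), "missing values are not supported")
  tab <- table(d$subject, d$session)
  if (any(tab != 1L))
    stop("unbalanced design: every subject must be measured exactly once ",
         "per session", call. = FALSE)
  g <- tapply(as.character(d$group), d$subject,
              function(x) length(unique(x)))
  if (any(g != 1L)) stop("each subject must belong to one group", call. = FALSE)
  if (nlevels(droplevels(d$group)) < 2L)
    stop("at least two groups are required", call. = FALSE)
  res <- .aovMixed(d)
  if (sphericity == "greenhouse-geisser") {
    eps <- .ggEpsilon(d)
    res$epsilon <- c(NA, eps, eps)
    within <- res$effect != "group"
    res$p[within] <- stats::pf(res$F[within],
                               eps * res$df1[within], eps * res$df2[within],
                               lower.tail = FALSE)
  }
  if (nPerm > 0) {
    obs <- res$F
    subj <- levels(d$subject)
    subjGroup <- d$group[match(subj, d$subject)]
    counts <- c(0, 0, 0)
    withSeed(seed, {
      for (b in seq_len(nPerm)) {
        dp <- d
        # group + interaction: relabel subjects
        permG <- sample(subjGroup)
        dp$group <- permG[match(dp$subject, subj)]
        Fg <- .aovMixed(dp)$F
        # session: shuffle measurements across sessions within each subject
        ds <- d
        for (sj in subj) {
          i <- which(ds$subject == sj)
          ds$value[i] <- d$value[sample(i)]
        }
        Fs <- .aovMixed(ds)$F
        counts <- counts + (c(Fg[1], Fs[2], Fg[3]) >= obs - 1e-12)
      }
    })
    res$pPerm <- (counts + 1) / (nPerm + 1)
  }
  res
}

# core aov fit + extraction
.aovMixed <- function(d) {
  fit <- stats::aov(value ~ group * session + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rn <- function(x) trimws(rownames(x))
  bG <- match("group", rn(between)); bR <- match("Residuals", rn(between))
  wS <- match("session", rn(within))
  wI <- match("group:session", rn(within)); wR <- match("Residuals", rn(within))
  data.frame(
    effect = c("group", "session", "group:session"),
    df1 = c(between$Df[bG], within$Df[wS], within$Df[wI]),
    df2 = c(between$Df[bR], within$Df[wR], within$Df[wR]),
    F = c(between$`F value`[bG], within$`F value`[wS],
          within$`F value`[wI]),
    p = c(between$`Pr(>F)`[bG], within$`Pr(>F)`[wS], within$`Pr(>F)`[wI]))
}

# Greenhouse-Geisser epsilon from the session x session covariance of
# subject measurements (pooled within groups)
.ggEpsilon <- function(d) {
  wide <- stats::reshape(d[c("subject", "session", "value")],
                         idvar = "subject", timevar = "session",
                         direction = "wide")
  Y <- as.matrix(wide[, -1, drop = FALSE])
  grp <- d$group[match(wide$subject, d$subject)]
  S <- Reduce(`+`, lapply(split(seq_len(nrow(Y)), grp), function(i) {
    stats::cov(Y[i, , drop = FALSE]) * (length(i) - 1)
  })) / (nrow(Y) - length(unique(grp)))
  k <- ncol(S)
  mbar <- mean(S)
  rowm <- rowMeans(S)
  num <- (k * mean(diag(S)) - k * mbar)^2  # k^2 (mean diag - grand mean)^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * mbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Per-k rich-club group/session comparison
#'
#' Runs [mixedAnova()] independently at every degree threshold k of a
#' per-subject rich-club table and reports per-k F and p values for the
#' group, session and interaction effects, together with contiguous bands
#' of significant k at an uncorrected alpha (the shaded-region style of
#' presentation). FDR correction across k is available but off by default.
#' A k where any design cell has fewer than 2 defined subjects, or where
#' any subject is missing a session, is flagged undefined and skipped.
#'
#' @param curveTable data.frame with columns `subject`, `group`,
#'   `session`, `k`, `phi`, `defined` (see [richClubTable()]).
#' @param kRange thresholds to test; default: all k present.
#' @param alpha significance level per k (default 0.05, uncorrected).
#' @param correction `"none"` (default) or `"fdr"` across k.
#' @return list with `perK` (data.frame: k, effect, df1, df2, F, p,
#'   significant) and `bands` (per effect, contiguous significant k runs).
#' @export
richclubGroupComparison <- function(curveTable, kRange = NULL, alpha = 0.05,
                                    correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  need <- c("subject", "group", "session", "k", "phi")
  stopIfNot(all(need %in% names(curveTable)),
            paste("curve table needs columns:", paste(need, collapse = ", ")))
  if (!"defined" %in% names(curveTable))
    curveTable$defined <- is.finite(curveTable$phi)
  if (is.null(kRange)) kRange <- sort(unique(curveTable$k))
  rows <- lapply(kRange, function(kk) {
    d <- curveTable[curveTable$k == kk & curveTable$defined, , drop = FALSE]
    d$value <- d$phi
    ok <- nrow(d) > 0L &&
      all(table(d$subject, d$session) == 1L) &&
      all(table(d$group[!duplicated(d$subject)]) >= 2L) &&
      length(unique(d$group)) >= 2L
    if (!ok)
      return(data.frame(k = kk, effect = c("group", "session",
                                           "group:session"),
                        df1 = NA, df2 = NA, F = NA, p = NA))
    a <- tryCatch(mixedAnova(d), error = function(e) NULL)
    if (is.null(a))
      return(data.frame(k = kk, effect = c("group", "session",
                                           "group:session"),
                        df1 = NA, df2 = NA, F = NA, p = NA))
    cbind(k = kk, a)
  })
  perK <- do.call(rbind, rows)
  if (correction == "fdr") {
    for (ef in unique(perK$effect)) {
      i <- perK$effect == ef
      perK$p[i] <- stats::p.adjust(perK$p[i], method = "BH")
    }
  }
  perK$significant <- !is.na(perK$p) & perK$p < alpha
  bands <- lapply(split(perK, perK$effect), function(pe) {
    pe <- pe[order(pe$k), ]
    sig <- pe$k[pe$significant]
    if (!length(sig)) return(data.frame(kFrom = integer(0), kTo = integer(0)))
    grp <- cumsum(c(TRUE, diff(sig) > 1))
    do.call(rbind, lapply(split(sig, grp), function(ks)
      data.frame(kFrom = min(ks), kTo = max(ks))))
  })
  list(perK = perK, bands = bands)
}
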