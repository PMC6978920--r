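#' Response-bias index of a testing session
#'
#' The absolute difference between the number of object choices made over
#' the left well (L) and over the right well (R), divided by the total
#' number of object-choice trials T: `|L - R| / T`. A value of 1 means
#' only one side was ever selected (maximal bias); 0 means no side
#' preference. Working-memory-error records are not trials and never enter
#' the numerator or denominator; the index is likewise independent of
#' correctness.
#'
#' @param log a [TrialLog-class].
#' @param day day index; `NULL` (default) pools all days in the log.
#' @return numeric in `[0, 1]`; `NA` (with a warning) when the selection
#'   contains no object-choice trial.
#' @examples
#' log <- simulateTrialLog(behaviorSimConfig(sideBias = 1))
#' responseBias(log)  # 1: every choice on the same side
#' @export
responseBias <- function(log, day = NULL) {
  stopifnot(is(log, "TrialLog"))
  r <- trialRecords(log)
  if (!is.null(day)) r <- r[r$day %in% day, , drop = FALSE]
  r <- r[r$kind == "object_choice", , drop = FALSE]
  if (nrow(r) == 0L) {
    warning("no object-choice trials in the selected day(s); bias undefined",
            call. = FALSE)
    return(NA_real_)
  }
  L <- sum(r$side == "left_well")
  R <- sum(r$side == "right_well")
  abs(L - R) / nrow(r)
}

#' Per-day session summary
#'
#' Percent correct and the response bias are computed over object-choice
#' trials only; WME rows are counted separately and are never logged as
#' trials.
#'
#' @param log a [TrialLog-class].
#' @param day day index (single day).
#' @return one-row data.frame: `day`, `nTrials`, `percentCorrect`, `nWme`,
#'   `responseBias`.
#' @export
sessionPerformance <- function(log, day) {
  stopifnot(is(log, "TrialLog"))
  r <- trialRecords(log)
  r <- r[r$day == day, , drop = FALSE]
  stopIfNot(nrow(r) > 0L, paste("log does not cover day", day))
  oc <- r[r$kind == "object_choice", , drop = FALSE]
  data.frame(
    day = day,
    nTrials = nrow(oc),
    percentCorrect = if (nrow(oc)) 100 * mean(oc$correct) else NA_real_,
    nWme = sum(r$kind == "wme"),
    responseBias = responseBias(log, day))
}

#' Summaries for a set of days
#'
#' Applies [sessionPerformance()] to each requested day and optionally the
#' mean of the daily response biases — the multi-day aggregate used when a
#' bias is reported for days adjacent to a scan.
#'
#' @param log a [TrialLog-class].
#' @param days integer vector; default: every day present.
#' @return data.frame of per-day rows with an attribute `meanBias`.
#' @export
summarizeSessions <- function(log, days = NULL) {
  stopifnot(is(log, "TrialLog"))
  if (is.null(days)) days <- sort(unique(trialRecords(log)$day))
  out <- do.call(rbind, lapply(days, function(d) sessionPerformance(log, d)))
  attr(out, "meanBias") <- mean(out$responseBias, na.rm = TRUE)
  out
}
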