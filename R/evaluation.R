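#' Match detections to reference annotations
#'
#' Each annotation owns a match window of `window_ms` centered on it; at
#' most one detection inside the window counts as a true positive, every
#' other detection is a false positive and every unmatched annotation a
#' false negative.  The pairing maximizes the number of true positives
#' (windows of neighboring annotations may overlap); among
#' maximum-cardinality pairings the closest-in-time pairing is preferred.
#'
#' @param annotations an [annotation_set] or numeric times (s), sorted.
#' @param detections numeric detection times (s), sorted, or a
#'   `detection_set`.
#' @param window_ms full match-window width (ms).
#' @return a `match_result` list: `tp_pairs` (two-column matrix of
#'   annotation/detection times), `fp` (unmatched detection times),
#'   `fn` (unmatched annotation times).
#' @export
match_beats <- function(annotations, detections, window_ms = 50) {
  ann <- if (inherits(annotations, "annotation_set"))
    annotations$beat_times else as.numeric(annotations)
  det <- if (inherits(detections, "detection_set")) detections$t
  else if (inherits(detections, "annotation_set")) detections$beat_times
  else as.numeric(detections)
  if (is.unsorted(ann, strictly = FALSE) ||
      is.unsorted(det, strictly = FALSE))
    stop("annotation and detection times must be sorted", call. = FALSE)
  half <- window_ms / 2000
  pair_from <- function(assign_det) {
    tp <- which(assign_det > 0)
    list(tp_pairs = cbind(annotation = ann[assign_det[tp]],
                          detection = det[tp]),
         fp = det[assign_det == 0],
         fn = ann[setdiff(seq_along(ann), assign_det[tp])])
  }
  greedy <- function(order_rule) {
    used <- logical(length(det))
    assign_det <- integer(length(det))     # which annotation each det serves
    for (i in seq_along(ann)) {
      j <- which(!used & abs(det - ann[i]) <= half)
      if (!length(j)) next
      pick <- switch(order_rule,
                     earliest = j[1L],
                     closest = j[which.min(abs(det[j] - ann[i]))])
      used[pick] <- TRUE
      assign_det[pick] <- i
    }
    assign_det
  }
  # earliest-in-window on sorted same-width windows maximizes matches;
  # closest-first is preferred when it reaches the same cardinality
  a_max <- greedy("earliest")
  a_close <- greedy("closest")
  assign_det <- if (sum(a_close > 0) >= sum(a_max > 0)) a_close else a_max
  structure(pair_from(assign_det), class = "match_result")
}

#' Beat-by-beat scores from a match result
#'
#' Sensitivity `Se = 100 TP / (TP + FN)`, positive predictivity
#' `+P = 100 TP / (TP + FP)`, detection error rate
#' `DER = 100 (FN + FP) / (TP + FN)`, plus jitter (detection minus
#' annotation, ms) and optional decision-delay statistics.  Metrics with
#' zero denominators are reported as `NA`, not zero.
#'
#' @param match a `match_result` from [match_beats], or `NULL` when
#'   giving counts directly.
#' @param tp,fp,fn counts (used when `match` is `NULL`): arithmetic-only
#'   scoring of published tallies.
#' @param delays optional per-TP decision delays (s).
#' @return a `score_report` list with counts and metrics.
#' @export
#' @examples
#' score_record(tp = 1468, fn = 103, fp = 63)
score_record <- function(match = NULL, tp = NULL, fp = NULL, fn = NULL,
                         delays = NULL) {
  jit <- numeric(0)
  if (!is.null(match)) {
    stopifnot(inherits(match, "match_result"))
    tp <- nrow(match$tp_pairs)
    fp <- length(match$fp)
    fn <- length(match$fn)
    if (tp > 0)
      jit <- (match$tp_pairs[, "detection"] -
                match$tp_pairs[, "annotation"]) * 1000
  }
  stopifnot(!is.null(tp), !is.null(fp), !is.null(fn))
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  sd_or_na <- function(v) if (length(v) > 1L) sd(v) else
    if (length(v) == 1L) 0 else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn,
    se = rate(tp, tp + fn),
    ppv = rate(tp, tp + fp),
    der = rate(fn + fp, tp + fn),
    jitter_mean = mean_or_na(jit), jitter_sd = sd_or_na(jit),
    delay_mean = mean_or_na(if (is.null(delays)) numeric(0)
                            else delays * 1000),
    delay_sd = sd_or_na(if (is.null(delays)) numeric(0)
                        else delays * 1000)),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(
    "<score_report> TP=%d FP=%d FN=%d | Se=%.2f%% +P=%.2f%% DER=%.2f%%\n",
    x$tp, x$fp, x$fn, x$se, x$ppv, x$der))
  if (!is.na(x$jitter_mean))
    cat(sprintf("  jitter %.2f +/- %.2f ms\n", x$jitter_mean, x$jitter_sd))
  invisible(x)
}

#' Aggregate per-record score reports
#'
#' Totals of TP/FP/FN, per-record mean and (n-1) standard deviation of
#' each percentage metric and of the jitter, and the fraction of records
#' whose DER exceeds an alarm threshold.  Records whose metric is
#' undefined (zero denominator) are excluded from that metric's mean,
#' with a count of exclusions.
#'
#' @param reports list of `score_report`s (>= 1).
#' @param der_alarm_pct DER threshold for the instability fraction.
#' @return a list of totals, mean/sd summaries and the DER exceedance
#'   fraction.
#' @export
aggregate_scores <- function(reports, der_alarm_pct = 60) {
  if (!length(reports)) stop("no reports to aggregate", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, TRUE, "score_report")))
  g <- function(f) vapply(reports, `[[`, numeric(1), f)
  msd <- function(v) {
    v_ok <- v[!is.na(v)]
    c(mean = if (length(v_ok)) mean(v_ok) else NA_real_,
      sd = if (length(v_ok) > 1L) sd(v_ok) else
        if (length(v_ok) == 1L) 0 else NA_real_,
      n_missing = sum(is.na(v)))
  }
  der <- g("der")
  list(totals = c(tp = sum(g("tp")), fp = sum(g("fp")), fn = sum(g("fn"))),
       se = msd(g("se")), ppv = msd(g("ppv")), der = msd(der),
       jitter = msd(g("jitter_mean")),
       frac_der_above = mean(der[!is.na(der)] > der_alarm_pct),
       n_records = length(reports))
}
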