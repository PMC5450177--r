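# Detection scoring: event matching against annotations and the
# Se / DER / Acc metrics, plus per-record table aggregation.

#' Match detected event times to ground truth
#'
#' Greedy one-to-one nearest matching within a tolerance: detections and
#' truth are paired closest-first; unmatched truth events count as false
#' negatives, unmatched detections as false positives.
#'
#' @param detected,truth Sorted numeric vectors of event times (s).
#' @param tol_s Matching tolerance in seconds (default 0.075, a common
#'   beat-matching window).
#' @return List with integer counts \code{tp}, \code{fn}, \code{fp};
#'   always \code{tp + fn == length(truth)} and
#'   \code{tp + fp == length(detected)}.
#' @export
match_events <- function(detected, truth, tol_s = 0.075) {
  if (tol_s <= 0) stop("tol_s must be positive")
  nd <- length(detected); nt <- length(truth)
  if (nd == 0L || nt == 0L)
    return(list(tp = 0L, fn = nt, fp = nd))
  pairs <- expand.grid(d = seq_len(nd), t = seq_len(nt))
  pairs$gap <- abs(detected[pairs$d] - truth[pairs$t])
  pairs <- pairs[pairs$gap <= tol_s, ]
  pairs <- pairs[order(pairs$gap), ]
  used_d <- logical(nd); used_t <- logical(nt); tp <- 0L
  for (r in seq_len(nrow(pairs))) {
    d <- pairs$d[r]; tt <- pairs$t[r]
    if (!used_d[d] && !used_t[tt]) {
      used_d[d] <- TRUE; used_t[tt] <- TRUE; tp <- tp + 1L
    }
  }
  list(tp = tp, fn = nt - tp, fp = nd - tp)
}

#' Detection performance metrics
#'
#' Sensitivity \code{Se = TP/(TP+FN)}, detection error rate
#' \code{DER = (FP+FN)/TP} and accuracy \code{Acc = TP/(TP+FP+FN)}, each
#' as a percentage rounded to two decimals. With no true positives the
#' DER denominator vanishes and DER is reported as \code{NA} with a
#' warning.
#'
#' @param tp,fn,fp Non-negative counts with \code{tp + fn > 0}.
#' @return Object of class \code{detection_report}: the counts plus
#'   \code{se}, \code{der}, \code{acc}.
#' @export
#' @examples
#' metrics(2600, 1, 6)  # se 99.96, der 0.27, acc 99.73
metrics <- function(tp, fn, fp) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0)
  if (tp + fn == 0) stop("no truth events: tp + fn must be positive")
  der <- if (tp > 0) round(100 * (fp + fn) / tp, 2) else {
    warning("no true positives: DER undefined")
    NA_real_
  }
  structure(list(tp = tp, fn = fn, fp = fp,
                 se = round(100 * tp / (tp + fn), 2),
                 der = der,
                 acc = round(100 * tp / (tp + fp + fn), 2)),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> TP %d / FN %d / FP %d | Se %.2f%% DER %s%% Acc %.2f%%\n",
              x$tp, x$fn, x$fp, x$se,
              if (is.na(x$der)) "NA" else sprintf("%.2f", x$der), x$acc))
  invisible(x)
}

#' Aggregate per-record failure counts
#'
#' @param fn,fp Per-record false-negative and false-positive counts.
#' @return List with \code{fn_total}, \code{fp_total}, \code{total}.
#' @export
summarize_failures <- function(fn, fp) {
  stopifnot(length(fn) == length(fp), length(fn) > 0)
  list(fn_total = sum(fn), fp_total = sum(fp), total = sum(fn) + sum(fp))
}

#' Published per-record R/T detection counts (MIT-BIH, first channel)
#'
#' Loads the packaged table of per-record beat totals, FN and FP counts
#' and the reported Se/DER/Acc percentages for the R and T detectors on
#' 16 MIT-BIH arrhythmia records.
#'
#' @return Data frame, one row per record.
#' @export
load_detection_counts <- function() {
  utils::read.csv(system.file("extdata", "mitbih_rt_counts.csv",
                              package = "ecgwave", mustWork = TRUE),
                  colClasses = c(record = "character"))
}

#' Published fitted AP parameters for 40 pathological/normal records
#'
#' Loads the packaged table of fitted (k, h_R, h_L) triples with their
#' clinical labels (myocardial ischemia, heart failure, normal) from the
#' European ST-T, BIDMC congestive heart failure and ECG-ID samples.
#'
#' @return Data frame with columns \code{record}, \code{k}, \code{h_R},
#'   \code{h_L}, \code{clinical}.
#' @export
load_pathology_params <- function() {
  utils::read.csv(system.file("extdata", "pathology_fit_params.csv",
                              package = "ecgwave", mustWork = TRUE),
                  colClasses = c(record = "character"))
}
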