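# Coverage QC and caller performance evaluation against a truth set.

#' Coverage QC over panel target bases
#'
#' @param depths integer vector of per-base (or per-locus) read depths over
#'   the panel targets.
#' @param thresholds depth thresholds to report (default 1, 5, 10, 20, 30,
#'   50, 100, 500, 1000 reads).
#' @param total_reads optional total read count to report.
#' @param dedup_rate optional deduplication rate to report.
#' @return list with `pct_at_depth` (named numeric, percent of bases at or
#'   above each threshold, one decimal), `total_reads`, `dedup_rate`.
#' @export
coverage_qc <- function(depths, thresholds = c(1, 5, 10, 20, 30, 50, 100, 500, 1000),
                        total_reads = NA_real_, dedup_rate = NA_real_) {
  if (!length(depths)) stop_bad("empty depth vector")
  pct <- vapply(thresholds, function(th)
    round_half_up(100 * mean(depths >= th), 1), 0)
  names(pct) <- as.character(thresholds)
  list(pct_at_depth = pct, total_reads = total_reads, dedup_rate = dedup_rate)
}

#' Sensitivity/specificity evaluation of calls against a truth set
#'
#' The assessable universe must be given explicitly: a (case, marker) pair
#' outside it is never counted, and negatives exist only where the universe
#' says so (a validation design where negative results are not re-tested
#' simply leaves them out, yielding specificity NA).
#'
#' @param calls data.frame (case, marker, positive) - the caller's verdicts.
#' @param truth data.frame (case, marker, positive) - the reference verdicts.
#' @param universe data.frame (case, marker) of assessable pairs; defaults
#'   to all pairs present in `truth`.
#' @return list with `per_marker` data.frame (marker, n, TP, FP, TN, FN,
#'   sensitivity, specificity) and `overall` (pooled sensitivity,
#'   specificity, accuracy), proportions in \[0,1\] or NA when undefined.
#' @export
evaluate_calls <- function(calls, truth, universe = NULL) {
  if (is.null(universe)) universe <- truth[, c("case", "marker")]
  key <- function(d) paste(d$case, d$marker, sep = "\r")
  uk <- key(universe)
  outside <- !(key(calls) %in% uk)
  if (any(outside)) {
    warning(sprintf("%d call(s) outside the assessable universe; excluded", sum(outside)))
    calls <- calls[!outside, , drop = FALSE]
  }
  tk <- key(truth)
  truth_pos <- setNames(truth$positive, tk)
  call_pos <- setNames(calls$positive, key(calls))
  u_truth <- unname(truth_pos[uk]); u_truth[is.na(u_truth)] <- FALSE
  u_call <- unname(call_pos[uk]); u_call[is.na(u_call)] <- FALSE

  ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_
  conf <- function(sel) {
    tp <- sum(u_call[sel] & u_truth[sel]); fp <- sum(u_call[sel] & !u_truth[sel])
    fn <- sum(!u_call[sel] & u_truth[sel]); tn <- sum(!u_call[sel] & !u_truth[sel])
    c(n = sum(sel), TP = tp, FP = fp, TN = tn, FN = fn,
      sensitivity = ratio_or_na(tp, tp + fn),
      specificity = ratio_or_na(tn, tn + fp))
  }
  markers <- sort(unique(universe$marker))
  per <- do.call(rbind, lapply(markers, function(m)
    data.frame(marker = m, t(conf(universe$marker == m)), stringsAsFactors = FALSE)))
  all_c <- conf(rep(TRUE, length(uk)))
  overall <- list(sensitivity = unname(all_c["sensitivity"]),
                  specificity = unname(all_c["specificity"]),
                  accuracy = ratio_or_na(all_c[["TP"]] + all_c[["TN"]], all_c[["n"]]))
  list(per_marker = per, overall = overall)
}

#' Byte-identity reproducibility check
#'
#' Runs `fun(...)` `n_reps` times and compares the serialized results; the
#' pipeline's analogue of re-running an assay in independent cycles and
#' demanding identical reports.
#'
#' @param fun a function returning any R object (must manage its own seed).
#' @param ... arguments passed to `fun`.
#' @param n_reps number of repetitions (default 2).
#' @return TRUE iff all runs are byte-identical after serialization.
#' @export
reproducibility_check <- function(fun, ..., n_reps = 2) {
  outs <- lapply(seq_len(n_reps), function(i) serialize(fun(...), NULL))
  all(vapply(outs[-1], identical, TRUE, outs[[1]]))
}
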