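# Evaluation statistics for screening runs: confusion-matrix metrics, rank
# AUC, prediction-random enrichment ratios, and benchmark-table aggregation.

#' Round half away from zero
#'
#' Fixed-precision rounding where `.5` always rounds up in magnitude,
#' matching how benchmark tables are conventionally printed (R's `round()`
#' rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.check_binary <- function(labels) {
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary 0/1")
  }
  as.integer(labels)
}

#' Confusion counts at a score threshold
#'
#' Predicted positive iff `score >= threshold` (default 0.5; the operating
#' point is configurable because published summary tables rarely state it).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @param threshold decision threshold.
#' @return object of class `confusion_counts`: list TP, FP, TN, FN.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- .check_binary(labels)
  pred <- scores >= threshold
  counts <- list(TP = sum(pred & labels == 1L),
                 FP = sum(pred & labels == 0L),
                 TN = sum(!pred & labels == 0L),
                 FN = sum(!pred & labels == 1L))
  structure(lapply(counts, as.integer), class = "confusion_counts")
}

#' Construct confusion counts directly
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return a `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- list(TP = TP, FP = FP, TN = TN, FN = FN)
  bad <- vapply(counts, function(v) v < 0 || v != round(v), TRUE)
  if (any(bad)) stop("confusion counts must be non-negative integers")
  structure(lapply(counts, as.integer), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Standard definitions: accuracy `(TP+TN)/total`, TPR `TP/(TP+FN)`,
#' precision `TP/(TP+FP)`, MCC
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A metric whose
#' denominator is zero is returned as `NA` (a flagged undefined sentinel,
#' never silently 0).
#'
#' @param c a `confusion_counts`.
#' @return named list: accuracy, tpr, precision, mcc.
#' @export
metrics_from_counts <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- as.numeric(c$TP); fp <- as.numeric(c$FP)
  tn <- as.numeric(c$TN); fn <- as.numeric(c$FN)
  total <- tp + fp + tn + fn
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else NA_real_
  list(accuracy = acc, tpr = tpr, precision = prec, mcc = mcc)
}

#' Rank (Mann-Whitney) ROC AUC
#'
#' Equals the probability that a random positive outscores a random
#' negative, ties counted half: computed from rank sums, so it is invariant
#' under any strictly monotone transform of the scores.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- .check_binary(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("roc_auc needs both a positive and a negative example")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Prediction-random enrichment ratio
#'
#' The enrichment of actives above a score cutoff relative to random
#' selection: `ratio = (N_sel_active / N_total_active) / (NN_sel / N_all)`,
#' i.e. predicted TPR over the random-guess rate. The algebraically
#' identical form `(N_sel_active / NN_sel) / (N_total_active / N_all)` is
#' computed as well and asserted equal.
#'
#' @param N_sel_active actives above the cutoff.
#' @param N_total_active all actives in the screen.
#' @param NN_sel all compounds above the cutoff.
#' @param N_all all screened compounds.
#' @param cutoff the score cutoff the counts refer to (bookkeeping only).
#' @return object of class `ratio_report`: the four counts plus `p_tpr`,
#'   `random_rate`, `ratio`, `cutoff`.
#' @export
prediction_random_ratio <- function(N_sel_active, N_total_active, NN_sel,
                                    N_all, cutoff = NA_real_) {
  if (NN_sel == 0) {
    stop(structure(class = c("undefined_metric_error", "error", "condition"),
                   list(message = "ratio undefined: no compounds selected",
                        call = NULL)))
  }
  if (!(N_sel_active <= N_total_active && N_total_active <= N_all &&
        N_sel_active <= NN_sel && NN_sel <= N_all && N_sel_active >= 0 &&
        N_total_active > 0)) {
    stop("invalid count tuple: need 0 <= N_sel_active <= min(N_total_active, NN_sel) and max(N_total_active, NN_sel) <= N_all")
  }
  p_tpr <- N_sel_active / N_total_active
  random_rate <- NN_sel / N_all
  ratio <- p_tpr / random_rate
  ratio_alt <- (N_sel_active / NN_sel) / (N_total_active / N_all)
  stopifnot(isTRUE(all.equal(ratio, ratio_alt, tolerance = 1e-12)))
  structure(list(N_sel_active = N_sel_active,
                 N_total_active = N_total_active,
                 NN_sel = NN_sel, N_all = N_all,
                 p_tpr = p_tpr, random_rate = random_rate, ratio = ratio,
                 cutoff = cutoff),
            class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf(
    "<ratio_report cutoff %s: TPR %.4f / random %.6f = ratio %.4f>\n",
    format(x$cutoff), x$p_tpr, x$random_rate, x$ratio))
  invisible(x)
}

#' Enrichment ratio of a screening result at a cutoff
#'
#' Convenience wrapper assembling the four counts from a ranked screen and
#' its known actives.
#'
#' @param result a `screening_result`.
#' @param active_ids known active ids among the scored compounds.
#' @param cutoff score cutoff (e.g. 0.99 or 0.9).
#' @return a `ratio_report`.
#' @export
screen_ratio <- function(result, active_ids, cutoff) {
  stopifnot(inherits(result, "screening_result"))
  rows <- result$rows
  sel <- rows$score >= cutoff
  prediction_random_ratio(
    N_sel_active = sum(sel & rows$compound_id %in% active_ids),
    N_total_active = sum(rows$compound_id %in% active_ids),
    NN_sel = sum(sel), N_all = nrow(rows), cutoff = cutoff)
}

#' Column means of a benchmark case table
#'
#' Arithmetic mean of each numeric column (AUC, accuracy, TPR, precision,
#' MCC, positive and negative counts), optionally rounded half-up to a
#' requested precision per column.
#'
#' @param rows data frame of per-case metric rows.
#' @param digits `NULL` for exact means, or a single/per-column digit count
#'   for half-up rounding.
#' @return named numeric vector of column means.
#' @export
summarize_cases <- function(rows, digits = NULL) {
  num <- vapply(rows, is.numeric, TRUE)
  m <- colMeans(rows[, num, drop = FALSE])
  if (!is.null(digits)) {
    digits <- rep_len(digits, length(m))
    m <- mapply(round_half_up, m, digits)
  }
  m
}

#' Reconstruct confusion counts from printed summary metrics
#'
#' Inverts a (TPR, precision, pos, neg) row back to integer counts:
#' `TP = round(tpr * pos)`, predicted positives `= round(TP / precision)`,
#' `FP = predicted - TP`, `FN = pos - TP`, `TN = neg - FP`. Errors if any
#' reconstructed count is negative (inconsistent row).
#'
#' @param tpr,precision printed rates.
#' @param pos_num,neg_num class sizes.
#' @return a `confusion_counts`.
#' @export
reconstruct_counts <- function(tpr, precision, pos_num, neg_num) {
  stopifnot(tpr >= 0, tpr <= 1, precision > 0, precision <= 1,
            pos_num >= 1, neg_num >= 0)
  tp <- round(tpr * pos_num)
  pred_pos <- round(tp / precision)
  fp <- pred_pos - tp
  fn <- pos_num - tp
  tn <- neg_num - fp
  if (any(c(tp, fp, fn, tn) < 0)) {
    stop("inconsistent summary row: reconstructed counts are negative")
  }
  confusion_counts(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Bundled reference benchmark tables
#'
#' `dude_best_cases()` returns the 19 best-performing DUD.E evaluation cases
#' (per-target AUC, accuracy, TPR, precision, MCC and class sizes) bundled
#' with the package as reference data for the aggregation checks.
#' `top20_ratio099()` returns the published 20 best large-scale screening
#' targets with their prediction-random ratios at cutoff 0.99.
#'
#' @return a data frame.
#' @export
dude_best_cases <- function() {
  utils::read.table(
    system.file("extdata", "dude_best_cases.tsv", package = "dfscreen",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname dude_best_cases
#' @export
top20_ratio099 <- function() {
  utils::read.table(
    system.file("extdata", "top20_ratio099.tsv", package = "dfscreen",
                mustWork = TRUE),
    header = TRUE, sep = "\t", quote = "", stringsAsFactors = FALSE)
}
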