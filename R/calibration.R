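#' Labeled score/activity pairs
#'
#' Joins structure-based scores with measured activities and the binary
#' substrate label used throughout calibration. Capped records (activity
#' known only as a lower bound) keep their label from the bound - every
#' capped benchmark peptide clears the activity cutoff - but are excluded
#' from rank correlations.
#'
#' @param records benchmark records (see [load_fixture()]) with `score`,
#'   `kcat_over_km` and `capped` columns.
#' @param cfg a [classification_config()].
#' @return `data.frame` with `peptide`, `score`, `activity`, `capped`,
#'   `label`.
#' @export
labeled_scores <- function(records, cfg = classification_config()) {
  data.frame(peptide = records$peptide,
             score = records$score,
             activity = records$kcat_over_km,
             capped = records$capped,
             label = classify_substrate(records$kcat_over_km, cfg),
             stringsAsFactors = FALSE)
}

#' Score cutoff capping false positives
#'
#' A peptide is predicted a substrate when its score is strictly below the
#' cutoff. The calibrated cutoff is the largest (least stringent)
#' candidate threshold that admits at most `max_fp` non-substrates.
#' Candidates are the observed non-substrate scores plus every observed
#' score minus 1 REU. On the packaged training set `max_fp = 1` yields the
#' loose cutoff -1105.
#'
#' @param data [labeled_scores()] output.
#' @param max_fp maximum admitted false positives.
#' @return the cutoff (REU). When `max_fp` is not binding (at least the
#'   number of non-substrates) a warning is raised and `Inf` returned.
#' @export
select_cutoff <- function(data, max_fp = 1) {
  neg <- data$score[data$label == "non-substrate"]
  assert_that(length(neg) >= 1, "at least one non-substrate required")
  if (max_fp >= length(neg)) {
    warning("max_fp admits every non-substrate; returning +Inf sentinel")
    return(Inf)
  }
  cand <- sort(unique(c(neg, data$score - 1)), decreasing = TRUE)
  for (t in cand) {
    if (sum(neg < t) <= max_fp) return(t)
  }
  -Inf
}

# Mann-Whitney pair-counting AUC: fraction of (substrate, non-substrate)
# pairs ranked correctly by the predictor (higher predictor = substrate),
# ties counted 1/2
auc_pair_count <- function(predictor, positive) {
  pos <- predictor[positive]
  neg <- predictor[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  gt <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# Matthews correlation coefficient of a confusion matrix
mcc_counts <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / den
}

#' Performance metrics at a score threshold
#'
#' Classifies each peptide as predicted substrate iff `score < threshold`
#' (strictly; this is the only convention under which the printed training
#' table reproduces the published confusion counts) and reports the
#' confusion matrix, sensitivity, specificity, Matthews correlation
#' coefficient, ROC AUC (Mann-Whitney pair counting with ties at 1/2,
#' using `-score` as the predictor) and Spearman rank correlation between
#' score and activity (midranks; capped records excluded, their bounds are
#' not exact activities). Metrics undefined on single-class input are
#' `NA`, never 0.
#'
#' @param data [labeled_scores()] output.
#' @param threshold score cutoff in REU.
#' @return object of class `performance_report`: counts `tp`, `fp`, `tn`,
#'   `fn`; `sensitivity`, `specificity`, `mcc`, `auc`, `spearman_rho` at
#'   full precision; `rounded` carries the same metrics at 2 decimals;
#'   `threshold`, `n`.
#' @examples
#' rep <- evaluate(labeled_scores(load_fixture("D-TRAINING")), -1105)
#' rep$rounded$sensitivity  # 0.79
#' @export
evaluate <- function(data, threshold) {
  pos <- data$label == "substrate"
  pred <- data$score < threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- auc_pair_count(-data$score, pos)
  un <- data[!data$capped, ]
  rho <- if (nrow(un) >= 3 && stats::sd(un$activity) > 0 && stats::sd(un$score) > 0)
    stats::cor(un$activity, un$score, method = "spearman") else NA_real_
  metrics <- list(tp = tp, fp = fp, tn = tn, fn = fn,
                  sensitivity = sens, specificity = spec,
                  mcc = mcc_counts(tp, fp, tn, fn),
                  auc = auc, spearman_rho = rho,
                  threshold = threshold, n = nrow(data))
  metrics$rounded <- lapply(metrics[c("sensitivity", "specificity", "mcc",
                                      "auc", "spearman_rho")],
                            function(v) if (is.na(v)) NA_real_ else round(v, 2))
  structure(metrics, class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance at threshold %g REU (n = %d)\n", x$threshold, x$n))
  cat(sprintf("  confusion: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat(sprintf("  sensitivity %s  specificity %s  MCC %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$mcc)))
  cat(sprintf("  AUC %s  Spearman rho %s (capped records excluded)\n",
              fmt(x$auc), fmt(x$spearman_rho)))
  invisible(x)
}

#' Loose / strict cutoff pair
#'
#' The calibrated thresholds: loose -1105 REU (admits at most one false
#' positive on the training set) and strict -1118 REU (admits none).
#' Comparison is strictly-less-than everywhere, so a score exactly at a
#' cutoff does not pass it.
#'
#' @param loose,strict cutoffs in REU; `strict <= loose` required.
#' @export
cutoff_pair <- function(loose = -1105, strict = -1118) {
  assert_that(strict <= loose, "strict cutoff must be <= loose cutoff")
  list(loose = loose, strict = strict)
}

#' @rdname cutoff_pair
#' @param scores `data.frame` with `peptide` and a score column
#'   (`reweighted` or `score`), e.g. a [table_scorer()] result.
#' @param cutoffs a [cutoff_pair()].
#' @return `apply_cutoffs()` returns `scores` with logical columns
#'   `passes_loose`, `passes_strict` appended (strict-passing implies
#'   loose-passing).
#' @export
apply_cutoffs <- function(scores, cutoffs = cutoff_pair()) {
  sc <- scores$reweighted %||% scores$score
  out <- scores
  out$passes_loose <- sc < cutoffs$loose
  out$passes_strict <- sc < cutoffs$strict
  out
}

#' @rdname evaluate
#' @param report a `performance_report`.
#' @param path output path for a JSON report.
#' @export
write_performance_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
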