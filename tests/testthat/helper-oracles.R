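# brute-force oracles shared across test files; deliberately independent of
# the package's implementation paths

# pair-counting AUC by explicit double loop
auc_brute <- function(predictor, positive) {
  pos <- predictor[positive]; neg <- predictor[!positive]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive scan over all candidate thresholds for the FP-capped cutoff
cutoff_brute <- function(scores, labels, max_fp) {
  neg <- scores[labels == "non-substrate"]
  cand <- sort(unique(c(neg, scores - 1)), decreasing = TRUE)
  ok <- cand[vapply(cand, function(t) sum(neg < t) <= max_fp, logical(1))]
  if (length(ok)) max(ok) else -Inf
}

# quick labeled-score frame constructor
make_labeled <- function(scores, labels, activity = NULL, capped = FALSE) {
  data.frame(peptide = sprintf("pep%03d", seq_along(scores)),
             score = scores,
             activity = activity %||% (2e4 * (labels == "substrate") + 5e3),
             capped = rep_len(capped, length(scores)),
             label = labels, stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random canonical hexamers
random_hexamers <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    r <- sample(aa, 5, replace = TRUE)
    paste0(r[1], r[2], "k", r[3], r[4], r[5])
  }, character(1))
}
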