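#' Reweighted score of an energy breakdown
#'
#' The per-model prediction statistic is the reweighted score: the sum of
#' the engine's total score, interface score (`I_sc`) and peptide score,
#' which effectively gives double weight to interface residues and triple
#' weight to peptide residues. Lower is better (REU convention).
#'
#' @param total_score,interface_score,peptide_score numeric vectors (REU).
#' @return numeric vector of reweighted scores.
#' @examples
#' reweighted_score(-900, -30, -20)  # -950
#' @export
reweighted_score <- function(total_score, interface_score, peptide_score) {
  comp <- cbind(total_score, interface_score, peptide_score)
  assert_that(all(is.finite(comp)), "all three score components must be finite")
  unname(total_score + interface_score + peptide_score)
}

#' Read a Rosetta-style score table
#'
#' Parses the whitespace-delimited `score.sc` dialect: rows prefixed
#' `SCORE:`, with the first such row a header whose last column
#' `description` holds the model id. When a `reweighted` column is absent
#' it is computed from `total_score`, `I_sc` and `pep_sc`.
#'
#' @param path file path.
#' @return `data.frame` of models with at least `model_id` and `reweighted`
#'   columns; all numeric score columns are retained.
#' @export
read_score_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- grep("^SCORE:", lines, value = TRUE)
  assert_that(length(rows) >= 2, "no SCORE: rows found in %s", path)
  toks <- lapply(rows, function(l) strsplit(trimws(sub("^SCORE:", "", l)), "\\s+")[[1]])
  header <- toks[[1]]
  assert_that(header[length(header)] == "description",
              "last header column must be 'description'")
  body <- toks[-1]
  assert_that(all(lengths(body) == length(header)),
              "ragged SCORE: rows: all rows must match the header width")
  mat <- do.call(rbind, body)
  colnames(mat) <- header
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  for (cc in setdiff(header, "description")) {
    out[[cc]] <- as.numeric(out[[cc]])
  }
  names(out)[names(out) == "description"] <- "model_id"
  if (is.null(out$reweighted)) {
    out$reweighted <- reweighted_score(out$total_score, out$I_sc, out$pep_sc)
  }
  out
}

#' @rdname read_score_table
#' @param models `data.frame` with numeric score columns and `model_id`.
#' @export
write_score_table <- function(models, path) {
  num <- setdiff(names(models), "model_id")
  header <- paste("SCORE:", paste(c(num, "description"), collapse = " "))
  body <- vapply(seq_len(nrow(models)), function(i) {
    paste("SCORE:", paste(c(format(unlist(models[i, num]), trim = TRUE,
                                   scientific = FALSE),
                            models$model_id[i]), collapse = " "))
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Select the template ensemble from a decoy set
#'
#' Decoy models of the reference substrate docked into the receptor are
#' ranked by reweighted score and the best `n_templates` (default 5) kept
#' as the threading template ensemble. Ties at the boundary are broken by
#' lexicographic `model_id`.
#'
#' @param decoys `data.frame` with `model_id` and a score column.
#' @param n_templates ensemble size.
#' @param score_column score column name (default `"reweighted"`).
#' @return the selected rows, ascending by score.
#' @export
select_templates <- function(decoys, n_templates = 5, score_column = "reweighted") {
  assert_that(nrow(decoys) >= n_templates,
              "need >= %d decoys, got %d", n_templates, nrow(decoys))
  assert_that(!anyDuplicated(decoys$model_id), "model_id must be unique")
  ord <- order(decoys[[score_column]], decoys$model_id)
  out <- decoys[ord[seq_len(n_templates)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-of-ensemble score aggregation
#'
#' A peptide threaded onto every template of the ensemble is scored by the
#' best (minimum) reweighted score across templates.
#'
#' @param per_template named numeric vector of per-template scores.
#' @return the minimum score.
#' @export
aggregate_best <- function(per_template) {
  assert_that(length(per_template) >= 1, "empty per-template score map")
  min(per_template)
}

#' Score peptides from a precomputed score table
#'
#' The docking engine itself is outside this package; its output is
#' consumed as a table mapping peptide sequences to one or more
#' per-template reweighted scores. Each requested peptide gets the best
#' (minimum) score over its templates. Peptides absent from the table are
#' reported in the `missing` attribute, never silently dropped or imputed.
#'
#' @param score_table `data.frame` with columns `peptide`, `reweighted`
#'   and optionally `model_id` (several rows per peptide = per-template
#'   breakdown).
#' @param peptides character vector of canonical peptides to score.
#' @return `data.frame` with `peptide`, `reweighted`, `scorer`; attribute
#'   `"missing"` lists unscored peptides.
#' @export
table_scorer <- function(score_table, peptides) {
  tab <- as.data.frame(score_table)
  tab$peptide <- canonicalize_peptide(tab$peptide)
  if (is.null(tab$model_id)) {
    dup <- tab[duplicated(tab$peptide) | duplicated(tab$peptide, fromLast = TRUE), ]
    if (nrow(dup)) {
      conflict <- tapply(dup$reweighted, dup$peptide,
                         function(v) length(unique(v)) > 1)
      if (any(conflict)) {
        stop2("conflicting duplicate score rows for: %s",
              paste(names(conflict)[conflict], collapse = ", "))
      }
    }
  }
  best <- tapply(tab$reweighted, tab$peptide, aggregate_best)
  peptides <- canonicalize_peptide(peptides)
  found <- peptides %in% names(best)
  out <- data.frame(peptide = peptides[found],
                    reweighted = unname(best[peptides[found]]),
                    scorer = rep("table", sum(found)),
                    stringsAsFactors = FALSE)
  attr(out, "missing") <- peptides[!found]
  out
}

#' @rdname table_scorer
#' @param pssm a [build_pssm()] model used as a stand-in scorer when no
#'   engine output is available. PSSM scores are negated so that lower =
#'   better, matching the REU orientation of every calibrated cutoff.
#' @export
pssm_surrogate_scorer <- function(pssm, peptides) {
  peptides <- canonicalize_peptide(peptides)
  if (length(peptides) == 0) {
    out <- data.frame(peptide = character(0), reweighted = numeric(0),
                      scorer = character(0), stringsAsFactors = FALSE)
    attr(out, "missing") <- character(0)
    return(out)
  }
  sc <- score_with_pssm(pssm, peptides)
  out <- data.frame(peptide = peptides, reweighted = -sc,
                    scorer = "surrogate", stringsAsFactors = FALSE)
  attr(out, "missing") <- character(0)
  out
}
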