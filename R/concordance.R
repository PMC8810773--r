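#' Substrate calls from heterogeneous published-style datasets
#'
#' Cell-based SILAC-MS quantification reports a heavy/light (H/L) ratio
#' per acetylation site: sites unaffected by deacetylase inhibition
#' (0.8 <= H/L <= 1.2) are non-substrates, sites enriched 2-fold and above
#' are substrates, anything between is intermediate. Peptide-array data
#' report in how many replicate experiments a peptide was called a
#' substrate: at most 1 replica = non-substrate, 3 and more = substrate,
#' 2 = intermediate. Band endpoints are inclusive.
#'
#' @param hl_ratio numeric vector of H/L ratios (> 0).
#' @return character vector of labels in
#'   `{"substrate", "non-substrate", "intermediate"}`.
#' @examples
#' classify_silac(c(1.0, 2.5, 1.5))  # non-substrate, substrate, intermediate
#' classify_array(c(0, 3, 2))
#' @export
classify_silac <- function(hl_ratio) {
  assert_that(all(!is.na(hl_ratio)) && all(hl_ratio > 0),
              "H/L ratios must be positive")
  ifelse(hl_ratio >= 2, "substrate",
         ifelse(hl_ratio >= 0.8 & hl_ratio <= 1.2, "non-substrate",
                "intermediate"))
}

#' @rdname classify_silac
#' @param replica_count number of replicate experiments calling the
#'   peptide a substrate (>= 0).
#' @export
classify_array <- function(replica_count) {
  assert_that(all(!is.na(replica_count)) && all(replica_count >= 0),
              "replica counts must be non-negative")
  ifelse(replica_count >= 3, "substrate",
         ifelse(replica_count <= 1, "non-substrate", "intermediate"))
}

#' Read SILAC-style and array-style peptide tables
#'
#' TSV readers for the two dataset dialects. Column names can be remapped
#' via `columns` (a named character vector, `internal = file column`).
#' Peptides of any length are accepted as long as the acetyl-lysine is
#' marked; the core P-2..P+3 hexamer is derived for matching. SILAC
#' records whose ratio was truncated in the source ("capped to fit the
#' plot") can be marked via an `overflow` column and are carried with the
#' flag set.
#'
#' @param path TSV file path.
#' @param columns optional column remapping.
#' @return `data.frame` with `peptide`, `core`, the dataset's value
#'   columns, `label`, and `overflow` (SILAC only).
#' @export
read_silac_table <- function(path, columns = c(peptide = "peptide",
                                               hl_ratio = "hl_ratio")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(columns %in% names(tab)), "missing columns: %s",
              paste(setdiff(columns, names(tab)), collapse = ", "))
  out <- data.frame(peptide = canonicalize_peptide(tab[[columns["peptide"]]]),
                    hl_ratio = as.numeric(tab[[columns["hl_ratio"]]]),
                    stringsAsFactors = FALSE)
  assert_that(all(!is.na(out$peptide)), "unmarked peptides in %s", path)
  out$core <- core_hexamer(out$peptide)
  out$overflow <- if (!is.null(tab$overflow)) as.logical(tab$overflow)
                  else rep(FALSE, nrow(out))
  out$label <- classify_silac(out$hl_ratio)
  out
}

#' @rdname read_silac_table
#' @export
read_array_table <- function(path, columns = c(peptide = "peptide",
                                               replica_count = "replica_count")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(columns %in% names(tab)), "missing columns: %s",
              paste(setdiff(columns, names(tab)), collapse = ", "))
  out <- data.frame(peptide = canonicalize_peptide(tab[[columns["peptide"]]]),
                    replica_count = as.integer(tab[[columns["replica_count"]]]),
                    stringsAsFactors = FALSE)
  assert_that(all(!is.na(out$peptide)), "unmarked peptides in %s", path)
  out$core <- core_hexamer(out$peptide)
  out$intensity <- if (!is.null(tab$intensity)) as.numeric(tab$intensity)
                   else rep(NA_real_, nrow(out))
  out$label <- classify_array(out$replica_count)
  out
}

#' Match datasets on core hexamers and quantify agreement
#'
#' Records from two datasets are joined on the core P-2..P+3 hexamer
#' around the modified lysine (flanking regions may differ). The summary
#' counts concordant and discordant substrate calls among pairs where
#' both labels are definite (intermediates are reported but not counted),
#' and the fraction of shared hexamers whose label is invariant to
#' flanking differences within each dataset.
#'
#' @param a,b `data.frame`s with `peptide`, `core` and `label` columns
#'   (see [read_silac_table()] / [read_array_table()]).
#' @return list with `pairs` (one row per matched record pair:
#'   `core`, `peptide_a`, `peptide_b`, `label_a`, `label_b`, `agreement`)
#'   and `summary` (`n_pairs`, `n_definite`, `concordant`, `discordant`,
#'   `concordance`, `flank_invariant_a`, `flank_invariant_b`).
#' @export
match_and_compare <- function(a, b) {
  a <- a[!is.na(a$core), , drop = FALSE]
  b <- b[!is.na(b$core), , drop = FALSE]
  shared <- intersect(a$core, b$core)
  pairs <- merge(
    data.frame(core = a$core, peptide_a = a$peptide, label_a = a$label,
               stringsAsFactors = FALSE),
    data.frame(core = b$core, peptide_b = b$peptide, label_b = b$label,
               stringsAsFactors = FALSE),
    by = "core")
  definite <- pairs$label_a != "intermediate" & pairs$label_b != "intermediate"
  pairs$agreement <- ifelse(!definite, "indeterminate",
                            ifelse(pairs$label_a == pairs$label_b,
                                   "concordant", "discordant"))
  conc <- sum(pairs$agreement == "concordant")
  disc <- sum(pairs$agreement == "discordant")
  flank_inv <- function(d) {
    d <- d[d$core %in% shared, , drop = FALSE]
    per <- tapply(d$label, d$core, function(l) length(unique(l)) == 1)
    if (length(per)) mean(per) else NA_real_
  }
  list(pairs = pairs,
       summary = list(n_pairs = nrow(pairs),
                      n_definite = sum(definite),
                      concordant = conc,
                      discordant = disc,
                      concordance = if (conc + disc > 0) conc / (conc + disc)
                                    else NA_real_,
                      flank_invariant_a = flank_inv(a),
                      flank_invariant_b = flank_inv(b)))
}
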