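#' Read a FASTA proteome
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a plain
#' named character vector of upper-case sequences; names are truncated at
#' the first whitespace (UniProt-style headers keep the accession token).
#'
#' @param path FASTA file path.
#' @return named character vector of protein sequences.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Read an acetylation-site table
#'
#' Tab-delimited table of reported acetylation sites in the
#' PhosphoSitePlus-like layout: columns `protein_id`, `position` (1-based
#' residue index of the modified lysine) and optionally `evidence`
#' (`"low-throughput"` / `"high-throughput"`) and `source`. By default
#' only sites with low-throughput support are kept, mirroring how the
#' screened acetylome was filtered.
#'
#' @param path TSV file path.
#' @param low_throughput_only keep only low-throughput-supported sites
#'   (default `TRUE`; ignored when the table has no `evidence` column).
#' @return `data.frame` of sites.
#' @export
read_acetyl_sites <- function(path, low_throughput_only = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position")
  assert_that(all(need %in% names(tab)), "columns %s are required",
              paste(need, collapse = ", "))
  tab$position <- as.integer(tab$position)
  assert_that(all(tab$position >= 1), "positions must be >= 1")
  if (low_throughput_only && !is.null(tab$evidence)) {
    tab <- tab[tab$evidence == "low-throughput", , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Extract candidate hexamers around acetylation sites
#'
#' For each site, takes the two leading and three trailing residues
#' around the modified lysine (1-based, inclusive window
#' `[position - 2, position + 3]`). Sites too close to a terminus for a
#' full hexamer, or whose reference residue is not lysine, are excluded
#' and reported. Identical hexamers from different proteins are
#' deduplicated; provenance keeps every (protein, site) pair.
#'
#' @param proteome named character vector of sequences (see
#'   [read_proteome()]).
#' @param sites site `data.frame` (see [read_acetyl_sites()]).
#' @return `data.frame` with `peptide` (canonical hexamer), `provenance`
#'   (`protein:K-site`, `;`-joined for duplicates), `n_sites`; attribute
#'   `"excluded"` is a `data.frame` of dropped sites with reasons.
#' @examples
#' extract_hexamers(c(P1 = "AASDKTIGYY"),
#'                  data.frame(protein_id = "P1", position = 5))
#' @export
extract_hexamers <- function(proteome, sites) {
  missing <- setdiff(unique(sites$protein_id), names(proteome))
  assert_that(length(missing) == 0, "proteins absent from proteome: %s",
              paste(missing, collapse = ", "))
  seqs <- toupper(proteome[sites$protein_id])
  len <- nchar(seqs)
  pos <- sites$position
  reason <- rep(NA_character_, nrow(sites))
  reason[pos < 3 | pos + 3 > len] <- "incomplete hexamer window"
  at_site <- substr(seqs, pos, pos)
  reason[is.na(reason) & at_site != "K"] <- "site residue is not lysine"
  keep <- is.na(reason)
  hex <- substr(seqs[keep], pos[keep] - 2L, pos[keep] + 3L)
  substr(hex, 3, 3) <- "k"
  prov <- sprintf("%s:K-%d", sites$protein_id[keep], pos[keep])
  agg <- split(prov, hex)
  out <- data.frame(peptide = names(agg),
                    provenance = vapply(agg, function(p)
                      paste(sort(unique(p)), collapse = ";"), character(1)),
                    n_sites = vapply(agg, function(p)
                      length(unique(p)), integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  excl <- data.frame(protein_id = sites$protein_id[!keep],
                     position = sites$position[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  out
}

#' Screen candidate peptides with a scorer and calibrated cutoffs
#'
#' Scores every candidate hexamer, classifies it against the loose and
#' strict cutoffs (strictly-less-than), and ranks hits ascending by score
#' (rank 1 = best/lowest REU). Peptides the scorer cannot cover are
#' reported, not dropped silently.
#'
#' @param peptides `data.frame` from [extract_hexamers()] (or any frame
#'   with a `peptide` column), or a character vector of hexamers.
#' @param scorer a function `peptides -> data.frame(peptide, reweighted)`;
#'   build one with [make_table_scorer()] or [make_surrogate_scorer()].
#' @param cutoffs a [cutoff_pair()].
#' @return object of class `screen_result`: `hits` (`peptide`, `score`,
#'   `passes_loose`, `passes_strict`, `rank`, provenance columns,
#'   `annotations`), `summary` (counts `n`, `n_loose`, `n_strict`,
#'   `n_proteins`, `n_missing`), `missing`.
#' @export
run_screen <- function(peptides, scorer, cutoffs = cutoff_pair()) {
  pep <- if (is.character(peptides)) {
    data.frame(peptide = canonicalize_peptide(peptides),
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(peptides)
  }
  scored <- scorer(pep$peptide)
  missing <- attr(scored, "missing") %||% setdiff(pep$peptide, scored$peptide)
  hits <- merge(pep, data.frame(peptide = scored$peptide,
                                score = scored$reweighted,
                                stringsAsFactors = FALSE),
                by = "peptide")
  hits <- apply_cutoffs(hits, cutoffs)
  hits <- hits[order(hits$score, hits$peptide), , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  hits$annotations <- rep("", nrow(hits))
  rownames(hits) <- NULL
  n_prot <- if (!is.null(hits$provenance)) {
    length(unique(sub(":.*$", "", unlist(strsplit(hits$provenance, ";")))))
  } else {
    NA_integer_
  }
  structure(list(hits = hits,
                 summary = list(n = nrow(hits),
                                n_loose = sum(hits$passes_loose),
                                n_strict = sum(hits$passes_strict),
                                n_proteins = n_prot,
                                n_missing = length(missing)),
                 missing = missing,
                 cutoffs = cutoffs),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Screen of %d peptides (cutoffs: loose %g, strict %g REU)\n",
              s$n, x$cutoffs$loose, x$cutoffs$strict))
  cat(sprintf("  pass loose: %d   pass strict: %d   proteins: %s   unscored: %d\n",
              s$n_loose, s$n_strict,
              ifelse(is.na(s$n_proteins), "?", s$n_proteins), s$n_missing))
  invisible(x)
}

#' Annotate screen hits with external site or protein lists
#'
#' Site lists (frames with `protein_id` + `position`) are matched exactly
#' on (protein, position) against hit provenance; interactor lists
#' (character vectors or frames with `protein_id` only) are matched at the
#' protein level. Each matched list name is appended to the hit's
#' `annotations` tag set, and per-list counts and fractions reported.
#'
#' @param screen a `screen_result`.
#' @param site_lists named list of annotation lists.
#' @return the `screen_result` with annotated hits and an
#'   `overlap` summary (`list` of `count` / `fraction` per list).
#' @export
annotate_overlap <- function(screen, site_lists) {
  hits <- screen$hits
  assert_that(!is.null(hits$provenance),
              "hits carry no provenance to match against")
  prov <- strsplit(hits$provenance, ";")
  hit_prot <- lapply(prov, function(p) sub(":.*$", "", p))
  hit_key <- lapply(prov, function(p) sub(":K-", ":", p, fixed = TRUE))
  overlap <- list()
  for (nm in names(site_lists)) {
    ll <- site_lists[[nm]]
    matched <- if (is.data.frame(ll) && !is.null(ll$position)) {
      keys <- sprintf("%s:%d", ll$protein_id, as.integer(ll$position))
      vapply(hit_key, function(k) any(k %in% keys), logical(1))
    } else {
      prot <- if (is.data.frame(ll)) ll$protein_id else as.character(ll)
      vapply(hit_prot, function(k) any(k %in% prot), logical(1))
    }
    hits$annotations[matched] <- ifelse(
      nzchar(hits$annotations[matched]),
      paste(hits$annotations[matched], nm, sep = ";"), nm)
    overlap[[nm]] <- list(count = sum(matched),
                          fraction = if (nrow(hits)) mean(matched) else 0)
  }
  screen$hits <- hits
  screen$overlap <- overlap
  screen
}

#' Scorer factories for screening
#'
#' `make_table_scorer()` wraps a precomputed score table; peptides missing
#' from the table are reported by the screen. `make_surrogate_scorer()`
#' wraps a PSSM as a negated-score stand-in with the same orientation
#' (lower = better) so the pipeline runs without the external engine.
#'
#' @param score_table see [table_scorer()].
#' @return a function `character -> data.frame(peptide, reweighted)`.
#' @export
make_table_scorer <- function(score_table) {
  force(score_table)
  function(peptides) table_scorer(score_table, peptides)
}

#' @rdname make_table_scorer
#' @param pssm see [pssm_surrogate_scorer()].
#' @param scale,offset linear mapping applied to the negated PSSM score so
#'   surrogate scores land on a REU-like scale; defaults keep the raw
#'   negated score (`scale = 1`, `offset = 0`).
#' @export
make_surrogate_scorer <- function(pssm, scale = 1, offset = 0) {
  force(pssm); force(scale); force(offset)
  function(peptides) {
    out <- pssm_surrogate_scorer(pssm, peptides)
    out$reweighted <- out$reweighted * scale + offset
    out
  }
}

#' @rdname run_screen
#' @param path output TSV path for ranked hits; a JSON summary is written
#'   alongside as `<path>.summary.json`.
#' @export
write_screen_result <- function(screen, path) {
  utils::write.table(screen$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(c(screen$summary, list(overlap = screen$overlap)),
                       paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
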