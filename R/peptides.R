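#' Acetyl-lysine peptide notation
#'
#' Peptides around an acetylated lysine are stored in a canonical notation:
#' upper-case one-letter amino-acid codes with the acetylated lysine written
#' as a lower-case `k` (e.g. `"EGkFVR"`). Readers additionally accept the
#' `"(K-Ac)"` and `"K[ac]"` dialects used in published tables. In hexamer
#' mode the modified lysine sits at position 3 of 6, i.e. the peptide spans
#' positions P-2..P+3 relative to the acetyl-lysine (P0).
#'
#' @param x character vector of peptides in any accepted notation.
#' @return `canonicalize_peptide()` returns the canonical form; invalid
#'   entries (no marked acetyl-lysine, several marks, or non-standard
#'   residues) are returned as `NA` with the offending index attached via
#'   attribute `"invalid"`.
#' @examples
#' canonicalize_peptide(c("EG(K-Ac)FVR", "EGK[ac]FVR", "EGkFVR"))
#' @export
canonicalize_peptide <- function(x) {
  raw <- as.character(x)
  # dialect marks first; any remaining lower-case k is already canonical.
  # \x01 shields the mark while the rest of the string is uppercased.
  s <- gsub("\\(K-Ac\\)", "\x01", raw, ignore.case = TRUE)
  s <- gsub("K\\[ac\\]", "\x01", s, ignore.case = TRUE)
  s <- gsub("k", "\x01", s, fixed = TRUE)
  out <- gsub("\x01", "k", toupper(s), fixed = TRUE)
  ok <- vapply(out, function(s) {
    sum(strsplit(s, "")[[1]] == "k") == 1 &&
      grepl("^[ACDEFGHIKLMNPQRSTVWYk]+$", s)
  }, logical(1), USE.NAMES = FALSE)
  res <- ifelse(ok, out, NA_character_)
  if (any(!ok)) attr(res, "invalid") <- which(!ok)
  res
}

#' @rdname canonicalize_peptide
#' @return `acetyl_position()` returns the 1-based index of the modified
#'   lysine within each canonical peptide.
#' @export
acetyl_position <- function(x) {
  vapply(x, function(s) {
    p <- regexpr("k", s, fixed = TRUE)
    if (p < 0) NA_integer_ else as.integer(p)
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname canonicalize_peptide
#' @return `is_hexamer()` returns `TRUE` for canonical peptides of length 6
#'   with the acetyl-lysine at position 3 (P-2..P+3 window).
#' @export
is_hexamer <- function(x) {
  nchar(x) == 6L & acetyl_position(x) == 3L & !is.na(x)
}

#' @rdname canonicalize_peptide
#' @return `core_hexamer()` returns the P-2..P+3 hexamer around the marked
#'   lysine of an arbitrary-length canonical peptide, or `NA` when fewer
#'   than two leading or three trailing residues are available.
#' @export
core_hexamer <- function(x) {
  pos <- acetyl_position(x)
  n <- nchar(x)
  ifelse(!is.na(pos) & pos >= 3L & pos + 3L <= n,
         substr(x, pos - 2L, pos + 3L), NA_character_)
}

#' Position labels of a peptide window
#'
#' Window positions are labelled relative to the acetyl-lysine (P0), e.g.
#' `P-2, P-1, P1, P2, P3` for a hexamer. The fixed P0 lysine is excluded:
#' it carries no selectivity information.
#'
#' @param length peptide length.
#' @param acetyl_index 1-based index of the acetyl-lysine.
#' @return character vector of `length - 1` labels.
#' @export
window_labels <- function(length = 6L, acetyl_index = 3L) {
  rel <- seq_len(length) - acetyl_index
  paste0("P", ifelse(rel > 0, rel, rel))[rel != 0]
}

# residues of canonical peptides at the window positions, as a matrix
# rows = peptides, cols = window labels
window_residues <- function(peptides, labels = NULL) {
  pos <- acetyl_position(peptides)
  len <- unique(nchar(peptides))
  assert_that(length(len) == 1L, "peptides must share a common length")
  assert_that(length(unique(pos)) == 1L,
              "peptides must share the acetyl-lysine position")
  labs <- labels %||% window_labels(len, pos[1])
  off <- as.integer(sub("^P", "", labs))
  idx <- pos[1] + off
  m <- do.call(rbind, strsplit(toupper(peptides), ""))[, idx, drop = FALSE]
  colnames(m) <- labs
  rownames(m) <- peptides
  m
}
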