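#' Benchmark peptide sets measured by the coupled acetate assay
#'
#' Loads one of the packaged benchmark datasets of acetylated hexamer
#' peptides with HDAC6 kinetic parameters and structure-based reweighted
#' scores, transcribed from the printed activity tables:
#'
#' * `"D-TRAINING"` - 26 peptides with precise kcat/KM values.
#' * `"D-CAPPED"` - 16 substrates whose KM fell below the assay detection
#'   limit, so only a lower bound on kcat/KM is known.
#' * `"D-EXTENDED"` - the union of the two sets above (42 records).
#' * `"D-TEST"` - 10 peptides selected from the acetylome screen for
#'   independent validation.
#'
#' @param name dataset tag, one of `"D-TRAINING"`, `"D-CAPPED"`,
#'   `"D-EXTENDED"`, `"D-TEST"`.
#' @return a `data.frame` of benchmark records with columns `peptide`
#'   (canonical notation, acetyl-lysine as lower-case `k`), `protein`,
#'   `site` (1-based position of the modified lysine), `kcat_over_km`
#'   (M^-1 s^-1), `kcat` (s^-1), `km` (uM), their standard errors
#'   (`*_se`) and bound directions (`*_bound`, one of `"exact"`,
#'   `"lower"`, `"upper"`), `score` (reweighted score, REU), `capped`
#'   (TRUE when kcat/KM is only a lower bound), `dataset`, and `note`.
#' @examples
#' tr <- load_fixture("D-TRAINING")
#' nrow(tr)        # 26
#' tr$peptide[1]   # "EGkFVR"
#' @export
load_fixture <- function(name) {
  tags <- c("D-TRAINING", "D-CAPPED", "D-EXTENDED", "D-TEST")
  if (!is.character(name) || length(name) != 1L || !name %in% tags) {
    stop2("unknown dataset tag %s; valid tags: %s",
          deparse(substitute(name)), paste(tags, collapse = ", "))
  }
  if (name == "D-EXTENDED") {
    out <- rbind(load_fixture("D-TRAINING"), load_fixture("D-CAPPED"))
    out$dataset <- "D-EXTENDED"
    rownames(out) <- NULL
    return(out)
  }
  file <- c("D-TRAINING" = "d_training.tsv",
            "D-CAPPED"   = "d_capped.tsv",
            "D-TEST"     = "d_test.tsv")[[name]]
  path <- system.file("extdata", file, package = "deacpredict", mustWork = TRUE)
  rec <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  rec$note[is.na(rec$note)] <- ""
  for (cc in c("kcat_over_km", "kcat_over_km_se", "kcat", "kcat_se",
               "km", "km_se", "score")) {
    rec[[cc]] <- as.numeric(rec[[cc]])  # all-NA columns must stay numeric
  }
  rec$peptide <- canonicalize_peptide(rec$peptide)
  rec$capped <- rec$kcat_over_km_bound == "lower"
  rec$dataset <- name
  rec
}

#' Read a peptide activity/score table
#'
#' Reads a user TSV/CSV table of peptides with optional kinetic and score
#' columns and normalizes it to the canonical benchmark-record layout.
#' Accepted peptide notations are `"(K-Ac)"`, `"K[ac]"` and lower-case `k`.
#' Numeric fields may carry a `>` or `<` prefix, which is parsed into the
#' value plus a bound direction (`"lower"` / `"upper"`) rather than being
#' silently coerced; thousands separators (`,`) and unicode minus signs are
#' handled.
#'
#' @param path file path.
#' @param sep field separator; default tab, use `","` for CSV.
#' @param hexamer_only reject peptides that are not marked hexamers
#'   (default `FALSE`; longer peptides are kept but flagged in `note`).
#' @return a `data.frame` in the [load_fixture()] layout.
#' @seealso [write_peptide_table()] for the inverse; the pair round-trips.
#' @export
read_peptide_table <- function(path, sep = "\t", hexamer_only = FALSE) {
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = "character", check.names = TRUE)
  assert_that("peptide" %in% names(raw), "column 'peptide' is required")
  pep <- canonicalize_peptide(raw$peptide)
  bad <- which(is.na(pep))
  if (length(bad)) {
    stop2("row %s: peptide %s has no single marked acetyl-lysine",
          paste(bad, collapse = ", "),
          paste(sQuote(raw$peptide[bad]), collapse = ", "))
  }
  n <- nrow(raw)
  out <- data.frame(peptide = pep, stringsAsFactors = FALSE)
  out$protein <- raw$protein %||% rep("", n)
  out$site <- if (is.null(raw$site)) rep(NA_integer_, n) else as.integer(raw$site)
  for (fld in c("kcat_over_km", "kcat", "km")) {
    parsed <- parse_bounded(raw[[fld]], fld, n)
    out[[fld]] <- parsed$value
    se_col <- paste0(fld, "_se")
    out[[se_col]] <- if (is.null(raw[[se_col]])) rep(NA_real_, n) else
      parse_bounded(raw[[se_col]], se_col, n)$value
    bcol <- paste0(fld, "_bound")
    out[[bcol]] <- if (!is.null(raw[[bcol]])) raw[[bcol]] else parsed$bound
  }
  out$score <- parse_bounded(raw$score, "score", n)$value
  out$note <- raw$note %||% rep("", n)
  out$note[is.na(out$note)] <- ""
  out$capped <- out$kcat_over_km_bound == "lower"
  out$dataset <- raw$dataset %||% rep("user", n)
  long <- !is_hexamer(out$peptide)
  if (any(long)) {
    if (hexamer_only) {
      stop2("row %s: peptide is not a marked hexamer",
            paste(which(long), collapse = ", "))
    }
    out$note[long] <- trimws(paste(out$note[long], "non-hexamer peptide"))
  }
  out
}

# parse numbers that may carry >/< bound prefixes, thousands separators and
# unicode minus; NULL column -> all-NA
parse_bounded <- function(x, field, n) {
  if (is.null(x)) {
    return(list(value = rep(NA_real_, n), bound = rep("exact", n)))
  }
  s <- gsub("[−–]", "-", trimws(as.character(x)))
  s <- gsub(",", "", s, fixed = TRUE)
  bound <- rep("exact", length(s))
  bound[startsWith(s, ">")] <- "lower"
  bound[startsWith(s, "<")] <- "upper"
  s <- trimws(sub("^[<>]", "", s))
  val <- suppressWarnings(as.numeric(s))
  bad <- which(!is.na(x) & nzchar(s) & is.na(val))
  if (length(bad)) {
    stop2("row %s: non-numeric value %s in column '%s'",
          paste(bad, collapse = ", "),
          paste(sQuote(x[bad]), collapse = ", "), field)
  }
  bound[is.na(val)] <- "exact"
  list(value = val, bound = bound)
}

#' @rdname read_peptide_table
#' @param records a benchmark-record `data.frame`.
#' @export
write_peptide_table <- function(records, path, sep = "\t") {
  cols <- c("peptide", "protein", "site",
            "kcat_over_km", "kcat_over_km_se", "kcat_over_km_bound",
            "kcat", "kcat_se", "kcat_bound", "km", "km_se", "km_bound",
            "score", "note", "capped", "dataset")
  keep <- intersect(cols, names(records))
  utils::write.table(records[keep], path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Audit kinetic self-consistency of a benchmark table
#'
#' For every record whose `kcat` and `km` are exact (not bounds), checks
#' that the printed catalytic efficiency agrees with `kcat / km` after unit
#' conversion (`10^6 * kcat[s^-1] / km[uM]` in M^-1 s^-1). Printed tables
#' round each quantity independently, so exact re-division cannot reproduce
#' the printed efficiency; a record is consistent when the relative
#' deviation is within the slack implied by half-unit-in-the-last-place
#' rounding of the three printed numbers.
#'
#' @param records a benchmark-record `data.frame` (see [load_fixture()]).
#' @return `records` with columns `computed_kcat_over_km`, `rel_dev`,
#'   `tolerance`, `assessable` and `consistent` appended.
#' @export
audit_kinetic_consistency <- function(records) {
  r <- records
  r$assessable <- r$kcat_bound == "exact" & r$km_bound == "exact" &
    r$kcat_over_km_bound == "exact" &
    !is.na(r$kcat) & !is.na(r$km) & !is.na(r$kcat_over_km)
  r$computed_kcat_over_km <- 1e6 * r$kcat / r$km
  r$rel_dev <- abs(r$computed_kcat_over_km / r$kcat_over_km - 1)
  r$tolerance <- 0.5 * printed_ulp(r$kcat) / r$kcat +
    0.5 * printed_ulp(r$km) / r$km +
    0.5 * printed_ulp(r$kcat_over_km) / r$kcat_over_km
  r$consistent <- ifelse(r$assessable, r$rel_dev <= r$tolerance, NA)
  r
}
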