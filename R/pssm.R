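#' Human proteome amino-acid background frequencies
#'
#' Average residue composition of the reviewed human proteome (UniProt
#' statistics, normalized over the 20 standard residues). Used as the
#' default PSSM background; a non-substrate peptide set can be supplied
#' instead to mirror differential-logo style backgrounds.
#'
#' @return named numeric vector over the 20 residues, summing to 1.
#' @export
human_aa_background <- function() {
  f <- c(A = 7.01, C = 2.30, D = 4.73, E = 7.10, F = 3.65, G = 6.58,
         H = 2.63, I = 4.33, K = 5.73, L = 9.97, M = 2.13, N = 3.59,
         P = 6.31, Q = 4.77, R = 5.64, S = 8.33, T = 5.36, V = 5.96,
         W = 1.22, Y = 2.66)
  f[AA20] / sum(f)
}

#' Build a position-specific scoring matrix from substrate peptides
#'
#' Log-odds weights per window position and residue:
#' `w(p, a) = log2((f(p, a) + pc * bg(a)) / ((1 + pc) * bg(a)))`
#' where `f` is the observed substrate frequency, `bg` the background
#' frequency and `pc` the pseudocount. The acetyl-lysine position (P0) is
#' fixed by construction and excluded from the window. Weights of residues
#' unobserved at a position are floored (default -10) so a vanishing
#' pseudocount cannot produce `-Inf`.
#'
#' @param substrates character vector of canonical peptides, all the same
#'   length with aligned acetyl-lysine.
#' @param background either a named frequency vector over the 20 residues
#'   or a character vector of non-substrate peptides whose positional
#'   pooled composition is used; default [human_aa_background()].
#' @param pseudocount pseudocount weight (default 0.1).
#' @param floor minimum weight for unobserved residues (default -10).
#' @return object of class `pssm_model`: `weights` (positions x 20
#'   matrix), `window`, `background`, `pseudocount`, `n_sequences`.
#' @export
build_pssm <- function(substrates, background = human_aa_background(),
                       pseudocount = 0.1, floor = -10) {
  assert_that(length(substrates) >= 1, "empty substrate set")
  substrates <- canonicalize_peptide(substrates)
  assert_that(all(!is.na(substrates)), "misaligned or invalid peptides")
  res <- window_residues(substrates)
  if (is.character(background)) {
    bg_res <- window_residues(canonicalize_peptide(background))
    tabs <- table(factor(as.vector(bg_res), levels = AA20))
    background <- as.numeric(tabs) / sum(tabs)
    names(background) <- AA20
  }
  assert_that(all(AA20 %in% names(background)),
              "background must cover the 20 standard residues")
  bg <- background[AA20] / sum(background[AA20])
  assert_that(all(bg > 0), "background frequencies must be positive")
  w <- t(apply(res, 2, function(col) {
    f <- as.numeric(table(factor(col, levels = AA20))) / length(col)
    lw <- log2((f + pseudocount * bg) / ((1 + pseudocount) * bg))
    pmax(lw, floor)
  }))
  colnames(w) <- AA20
  structure(list(weights = w, window = rownames(w), background = bg,
                 pseudocount = pseudocount, floor = floor,
                 n_sequences = length(substrates)),
            class = "pssm_model")
}

#' @export
print.pssm_model <- function(x, ...) {
  cat(sprintf("PSSM over window %s (n = %d sequences, pseudocount %g)\n",
              paste(x$window, collapse = " "), x$n_sequences, x$pseudocount))
  print(round(x$weights, 2))
  invisible(x)
}

#' Exact PSSM of a position-frequency model
#'
#' Converts a known positions x residues probability matrix (e.g. a
#' planted simulation motif) into its exact log-odds PSSM against a
#' background, with no sampling or pseudocount involvement. Positions
#' whose probabilities equal the background get exactly-zero weights.
#'
#' @param motif probability matrix, rows = window labels, columns = the
#'   20 residues, rows summing to 1.
#' @param background named background frequency vector.
#' @return a `pssm_model` (with `pseudocount = 0`, `n_sequences = 0`).
#' @export
motif_pssm <- function(motif, background = human_aa_background()) {
  bg <- background[colnames(motif)] / sum(background[colnames(motif)])
  assert_that(all(abs(rowSums(motif) - 1) < 1e-6), "motif rows must sum to 1")
  w <- log2(sweep(motif, 2, bg, `/`))
  w <- pmax(w, -10)
  structure(list(weights = w, window = rownames(motif), background = bg,
                 pseudocount = 0, floor = -10, n_sequences = 0L),
            class = "pssm_model")
}

#' Score peptides with a PSSM
#'
#' Sum of log-odds weights over the requested window positions (default:
#' all positions shared by the model and the peptide). Sub-window scoring
#' supports cross-dataset conventions such as scoring hexamers with a
#' trimer-derived matrix over P-2 and P-1 only.
#'
#' @param pssm a [build_pssm()] model.
#' @param peptides canonical peptides (equal length, aligned lysine).
#' @param positions optional character vector of window labels.
#' @return numeric vector of scores (higher = closer to the substrate
#'   motif).
#' @export
score_with_pssm <- function(pssm, peptides, positions = NULL) {
  peptides <- canonicalize_peptide(peptides)
  pep_labels <- window_labels(unique(nchar(peptides)),
                              unique(acetyl_position(peptides)))
  shared <- intersect(pssm$window, pep_labels)
  pos <- positions %||% shared
  missing <- setdiff(pos, shared)
  assert_that(length(missing) == 0,
              "positions absent from model or peptide window: %s",
              paste(missing, collapse = ", "))
  assert_that(length(pos) > 0, "incompatible window: no shared positions")
  res <- window_residues(peptides, labels = pos)
  sc <- vapply(seq_along(peptides), function(i) {
    sum(pssm$weights[cbind(pos, res[i, ])])
  }, numeric(1))
  names(sc) <- peptides
  sc
}

#' Cross-score datasets and correlate with measured activities
#'
#' Entry (i, j) is the Spearman rank correlation (midranks) between
#' dataset i's measured activities and the PSSM-j scores of dataset i's
#' peptides. Incompatible windows yield `NA` entries, never zero.
#'
#' @param datasets named list, each element `list(peptides =, activities =)`.
#' @param pssms named list of [build_pssm()] models.
#' @param positions optional fixed sub-window applied to every scoring.
#' @return matrix of Spearman rho, rows = datasets, cols = PSSMs.
#' @export
cross_correlation <- function(datasets, pssms, positions = NULL) {
  out <- matrix(NA_real_, nrow = length(datasets), ncol = length(pssms),
                dimnames = list(names(datasets), names(pssms)))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    assert_that(length(d$peptides) >= 3, "dataset %s has < 3 peptides",
                names(datasets)[i])
    for (j in seq_along(pssms)) {
      sc <- tryCatch(score_with_pssm(pssms[[j]], d$peptides, positions),
                     error = function(e) NULL)
      if (!is.null(sc)) {
        out[i, j] <- stats::cor(d$activities, sc, method = "spearman")
      }
    }
  }
  out
}

#' Differential position enrichment between substrate and background sets
#'
#' Per (position, residue) exact binomial test of the substrate count
#' against the background (non-substrate) frequency, in the style of
#' two-sample logo tools. Entries significant at `alpha` are returned with
#' their direction. No multiple-testing correction by default (matching
#' common two-sample-logo practice); `bonferroni = TRUE` divides `alpha`
#' by the number of tests.
#'
#' @param substrates,non_substrates aligned canonical peptide sets.
#' @param alpha significance level (default 0.05).
#' @param bonferroni apply Bonferroni correction (default `FALSE`).
#' @return `data.frame` with `position`, `residue`, `substrate_freq`,
#'   `background_freq`, `p_value`, `direction`.
#' @export
differential_positions <- function(substrates, non_substrates, alpha = 0.05,
                                   bonferroni = FALSE) {
  assert_that(length(substrates) > 0 && length(non_substrates) > 0,
              "both peptide sets must be non-empty")
  rs <- window_residues(canonicalize_peptide(substrates))
  rb <- window_residues(canonicalize_peptide(non_substrates))
  assert_that(identical(colnames(rs), colnames(rb)),
              "substrate and background windows are misaligned")
  rows <- list()
  n_tests <- ncol(rs) * length(AA20)
  thr <- if (bonferroni) alpha / n_tests else alpha
  for (p in colnames(rs)) {
    ns <- table(factor(rs[, p], levels = AA20))
    nb <- table(factor(rb[, p], levels = AA20))
    fb <- (as.numeric(nb) + 0.5) / (sum(nb) + 10)  # smoothed background rate
    for (a in seq_along(AA20)) {
      k <- as.numeric(ns[a]); n <- sum(ns)
      pv <- stats::binom.test(k, n, p = fb[a])$p.value
      # alpha >= 1 disables the filter (a modal count can have p exactly 1)
      if (pv < thr || thr >= 1) {
        rows[[length(rows) + 1]] <- data.frame(
          position = p, residue = AA20[a],
          substrate_freq = k / n,
          background_freq = as.numeric(nb[a]) / sum(nb),
          p_value = pv,
          direction = if (k / n > fb[a]) "enriched" else "depleted",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(position = character(0), residue = character(0),
                      substrate_freq = numeric(0), background_freq = numeric(0),
                      p_value = numeric(0), direction = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$p_value), ]
}

#' Serialize / deserialize a PSSM
#'
#' The matrix is written as TSV (rows = window positions, columns = the 20
#' residues) with a JSON sidecar (`<path>.json`) holding window labels,
#' background, pseudocount and training-set size. An information-content
#' logo matrix consumable by standard logo renderers is available via
#' `logo_matrix()`.
#'
#' @param pssm a `pssm_model`.
#' @param path TSV output path.
#' @export
write_pssm <- function(pssm, path) {
  utils::write.table(pssm$weights, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  jsonlite::write_json(list(window = pssm$window,
                            background = as.list(pssm$background),
                            pseudocount = pssm$pseudocount,
                            floor = pssm$floor,
                            n_sequences = pssm$n_sequences),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  w <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(weights = w, window = meta$window,
                 background = unlist(meta$background),
                 pseudocount = meta$pseudocount, floor = meta$floor,
                 n_sequences = meta$n_sequences),
            class = "pssm_model")
}

#' @rdname write_pssm
#' @return `logo_matrix()` returns a positions x residues matrix of
#'   per-residue information content (bits).
#' @export
logo_matrix <- function(pssm) {
  # per-position observed frequencies recovered from the log-odds weights
  f <- t(apply(pssm$weights, 1, function(w) {
    fr <- (2^w) * (1 + pssm$pseudocount) * pssm$background -
      pssm$pseudocount * pssm$background
    pmax(fr, 0)
  }))
  ic <- apply(f, 1, function(fr) {
    fr <- fr[fr > 0]
    log2(20) + sum(fr * log2(fr))
  })
  sweep(f, 1, ic, `*`)
}
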