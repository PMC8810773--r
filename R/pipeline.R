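# orchestration: benchmark evaluation and acetylome-style screening from a
# single validated config, with a provenance manifest in every bundle

FIXTURE_VERSION <- "printed-tables-v1"

config_manifest <- function(config, seed = NULL) {
  # the hash identifies the scientific configuration; where outputs land
  # must not change it
  config <- config[setdiff(names(config), "out_dir")]
  list(package = "deacpredict",
       version = as.character(utils::packageVersion("deacpredict")),
       fixture_version = FIXTURE_VERSION,
       seed = seed,
       config_hash = rlang::hash(config))
}

#' Run the benchmark evaluation pipeline
#'
#' End-to-end: load each requested dataset (packaged fixture tag or
#' peptide-table path), derive substrate labels from the activity cutoff,
#' evaluate the reweighted scores at the loose cutoff, and emit
#' per-dataset performance reports plus per-peptide prediction tables and
#' a provenance manifest (package version, fixture version, config hash).
#' Validation is fail-fast: a malformed config aborts before any
#' computation, and partial outputs are never written.
#'
#' @param config list with elements `datasets` (character vector of
#'   fixture tags and/or named file paths; required, non-empty),
#'   `cutoffs` (a [cutoff_pair()], default loose -1105 / strict -1118),
#'   `activity_cutoff` (M^-1 s^-1, default 1e4), optional `out_dir`
#'   and `seed`.
#' @return list with `reports` (named [evaluate()] results at the loose
#'   cutoff), `predictions` (named `data.frame`s with pass flags), and
#'   `manifest`.
#' @examples
#' res <- run_benchmark(list(datasets = "D-TRAINING"))
#' res$reports[["D-TRAINING"]]$rounded$sensitivity  # 0.79
#' @export
run_benchmark <- function(config) {
  assert_that(is.list(config), "config must be a list")
  ds <- config$datasets
  assert_that(length(ds) > 0, "config$datasets must name at least one dataset")
  cutoffs <- config$cutoffs %||% cutoff_pair()
  cls <- classification_config(config$activity_cutoff %||% 1e4)
  tags <- c("D-TRAINING", "D-CAPPED", "D-EXTENDED", "D-TEST")
  paths <- ds[!ds %in% tags]
  missing <- paths[!file.exists(paths)]
  assert_that(length(missing) == 0, "missing input file(s): %s",
              paste(missing, collapse = ", "))
  reports <- list(); predictions <- list()
  for (i in seq_along(ds)) {
    d <- ds[[i]]
    nm <- names(ds)[i] %||% ""
    if (!nzchar(nm)) nm <- if (d %in% tags) d else basename(d)
    rec <- if (d %in% tags) load_fixture(d) else read_peptide_table(d)
    lab <- labeled_scores(rec, cls)
    reports[[nm]] <- evaluate(lab, cutoffs$loose)
    pred <- apply_cutoffs(lab, cutoffs)
    pred$predicted <- ifelse(pred$passes_loose, "substrate", "non-substrate")
    predictions[[nm]] <- pred
  }
  bundle <- list(reports = reports, predictions = predictions,
                 manifest = config_manifest(config, config$seed))
  if (!is.null(config$out_dir)) {
    write_benchmark_bundle(bundle, config$out_dir)
  }
  bundle
}

write_benchmark_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$reports)) {
    write_performance_report(bundle$reports[[nm]],
                             file.path(out_dir, paste0(nm, "_report.json")))
    utils::write.table(bundle$predictions[[nm]],
                       file.path(out_dir, paste0(nm, "_predictions.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Run the screening pipeline
#'
#' Extract candidate hexamers around acetylation sites, score them with
#' the configured scorer, classify against the calibrated cutoffs, rank,
#' and optionally annotate with external site/interactor lists. Stage
#' record counts (sites in, excluded, peptides scored, unscored) are
#' collected so every filtering rule is auditable.
#'
#' @param config list with elements `proteome` (FASTA path or named
#'   character vector), `sites` (TSV path or `data.frame`), `scorer`
#'   (either `list(type = "table", table = <frame or score-table path>)`
#'   or `list(type = "surrogate", pssm = <pssm_model>)` - exactly one),
#'   optional `cutoffs`, `annotations` (named list of site/protein
#'   lists), `low_throughput_only` (default `TRUE`), `out_dir`.
#' @return a `screen_result` (see [run_screen()]) with an additional
#'   `stages` element of per-stage record counts.
#' @export
run_screen_pipeline <- function(config) {
  assert_that(is.list(config), "config must be a list")
  for (key in c("proteome", "sites", "scorer")) {
    assert_that(!is.null(config[[key]]), "config$%s is required", key)
  }
  sc <- config$scorer
  assert_that(is.list(sc) && length(sc$type) == 1 &&
                sc$type %in% c("table", "surrogate"),
              "scorer$type must be 'table' or 'surrogate'")
  scorer <- if (sc$type == "table") {
    tab <- sc$table
    if (is.character(tab)) {
      assert_that(file.exists(tab), "missing score table: %s", tab)
      tab <- read_score_table(tab)
      names(tab)[names(tab) == "model_id"] <- "peptide"
    }
    make_table_scorer(tab)
  } else {
    assert_that(inherits(sc$pssm, "pssm_model"), "scorer$pssm must be a PSSM")
    make_surrogate_scorer(sc$pssm, sc$scale %||% 1, sc$offset %||% 0)
  }
  proteome <- config$proteome
  if (is.character(proteome) && length(proteome) == 1 && file.exists(proteome)) {
    proteome <- read_proteome(proteome)
  }
  sites <- config$sites
  if (is.character(sites)) {
    assert_that(file.exists(sites), "missing site table: %s", sites)
    sites <- read_acetyl_sites(sites, config$low_throughput_only %||% TRUE)
  } else if (!is.null(sites$evidence) && (config$low_throughput_only %||% TRUE)) {
    sites <- sites[sites$evidence == "low-throughput", , drop = FALSE]
  }
  peptides <- extract_hexamers(proteome, sites)
  excluded <- attr(peptides, "excluded")
  result <- run_screen(peptides, scorer, config$cutoffs %||% cutoff_pair())
  if (!is.null(config$annotations)) {
    result <- annotate_overlap(result, config$annotations)
  }
  result$stages <- list(sites_in = nrow(sites),
                        sites_excluded = nrow(excluded),
                        peptides_unique = nrow(peptides),
                        peptides_scored = result$summary$n,
                        peptides_unscored = result$summary$n_missing)
  result$excluded <- excluded
  result$manifest <- config_manifest(config, config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_screen_result(result, file.path(config$out_dir, "screen_hits.tsv"))
  }
  result
}
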