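test_that("reweighted score is the sum of its three components", {
  expect_equal(reweighted_score(0, 0, 0), 0)
  expect_equal(reweighted_score(-900, -30, -20), -950)
  expect_error(reweighted_score(-900, NaN, -20), "finite")
  expect_error(reweighted_score(-900, Inf, -20), "finite")
  # parsed from a generated score table, the column equals an independent
  # spreadsheet-style recomputation of the component sum
  tmp <- tempfile()
  gen_score_file(sim_config(seed = 5), tmp, n_decoys = 40)
  tab <- read_score_table(tmp)
  expect_equal(tab$reweighted, tab$total_score + tab$I_sc + tab$pep_sc)
})

test_that("score tables round-trip through the SCORE: dialect", {
  tmp <- tempfile()
  planted <- gen_score_file(sim_config(seed = 3), tmp)
  expect_equal(readLines(tmp)[1],
               "SCORE: total_score I_sc pep_sc reweighted description")
  tab <- read_score_table(tmp)
  expect_equal(nrow(tab), 250)
  expect_equal(tab$reweighted, planted$reweighted)
  expect_equal(tab$model_id, planted$model_id)
  # byte-determinism of parsing
  expect_identical(read_score_table(tmp), tab)
  # reweighted column reconstructed when absent
  writeLines(c("SCORE: total_score I_sc pep_sc description",
               "SCORE: -900 -30 -20 m1"), tmp)
  expect_equal(read_score_table(tmp)$reweighted, -950)
})

test_that("template selection matches a full sort, with lexicographic ties", {
  set.seed(11)
  decoys <- data.frame(model_id = sprintf("d%03d", sample(250)),
                       reweighted = round(rnorm(250, -1000, 20), 2),
                       stringsAsFactors = FALSE)
  sel <- select_templates(decoys, 5)
  full <- decoys[order(decoys$reweighted, decoys$model_id), ]
  expect_equal(sel$model_id, full$model_id[1:5])
  expect_equal(sel$reweighted, sort(decoys$reweighted)[1:5])

  one <- decoys[7, , drop = FALSE]
  expect_equal(select_templates(one, 1)$model_id, one$model_id)

  tie <- data.frame(model_id = c("b", "a"), reweighted = c(-5, -5))
  expect_equal(select_templates(tie, 1)$model_id, "a")
  expect_error(select_templates(tie, 3), "need >= 3 decoys")
})

test_that("best-of-ensemble aggregation is the minimum over templates", {
  expect_equal(aggregate_best(c(-1105, -1090, -1123, -1100, -1110)), -1123)
  expect_equal(aggregate_best(-42), -42)
  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(sample(1:10, 1))
    expect_equal(aggregate_best(v), sort(v)[1])
  }
  expect_error(aggregate_best(numeric(0)), "empty")
  # composition invariant: best of the selected ensemble is the global
  # minimum whenever at least one template is kept
  set.seed(3)
  decoys <- data.frame(model_id = sprintf("d%02d", 1:50),
                       reweighted = rnorm(50, -1000, 30))
  for (n in c(1, 5, 50)) {
    sel <- select_templates(decoys, n)
    expect_equal(aggregate_best(sel$reweighted), min(decoys$reweighted))
  }
})

test_that("table-backed scoring covers requests and reports gaps", {
  fix <- load_fixture("D-TRAINING")
  tab <- data.frame(peptide = fix$peptide, reweighted = fix$score)
  out <- table_scorer(tab, c("EG(K-Ac)FVR", "SDkTIG"))
  expect_equal(out$reweighted, c(-1123, -1111))
  expect_equal(out$scorer, rep("table", 2))

  out2 <- table_scorer(tab, c("EGkFVR", "AAkAAA"))
  expect_equal(out2$peptide, "EGkFVR")
  expect_equal(attr(out2, "missing"), "AAkAAA")

  expect_equal(nrow(table_scorer(tab, character(0))), 0)

  # per-template rows aggregate by best score; conflicting duplicates
  # without template ids are an error
  multi <- data.frame(peptide = rep("EGkFVR", 3),
                      model_id = c("t1", "t2", "t3"),
                      reweighted = c(-1105, -1123, -1110))
  expect_equal(table_scorer(multi, "EGkFVR")$reweighted, -1123)
  dup <- data.frame(peptide = c("EGkFVR", "EGkFVR"), reweighted = c(-1, -2))
  expect_error(table_scorer(dup, "EGkFVR"), "conflicting")
})

test_that("PSSM surrogate scorer preserves REU orientation", {
  set.seed(13)
  peps <- unique(random_hexamers(60))[1:50]
  pssm <- build_pssm(sample(peps, 20))
  out <- pssm_surrogate_scorer(pssm, peps)
  expect_equal(out$scorer, rep("surrogate", 50))
  # ordering equals brute-force per-position weight summation, negated
  brute <- vapply(peps, function(p) {
    r <- strsplit(toupper(p), "")[[1]][-3]
    -sum(pssm$weights[cbind(pssm$window, r)])
  }, numeric(1))
  expect_equal(out$reweighted, unname(brute))
  # the consensus peptide attains the minimum (best) surrogate score
  cons <- apply(pssm$weights, 1, function(w) names(which.max(w)))
  consensus <- paste0(cons["P-2"], cons["P-1"], "k",
                      cons["P1"], cons["P2"], cons["P3"])
  all_sc <- pssm_surrogate_scorer(pssm, c(consensus, peps))$reweighted
  expect_equal(which.min(all_sc), 1L)
  # a uniform PSSM scores every peptide identically
  uni <- build_pssm(peps[1])
  uni$weights[] <- 0
  expect_equal(length(unique(pssm_surrogate_scorer(uni, peps)$reweighted)), 1L)
  expect_equal(nrow(pssm_surrogate_scorer(pssm, character(0))), 0)
})
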