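test_that("hexamer extraction takes P-2..P+3 and enforces boundaries", {
  out <- extract_hexamers(c(P1 = "AASDKTIGYY"),
                          data.frame(protein_id = "P1", position = 5))
  expect_equal(out$peptide, "SDkTIG")
  expect_equal(out$provenance, "P1:K-5")

  # too close to a terminus, or not a lysine: excluded with a reason
  sites <- data.frame(protein_id = "P1", position = c(2, 5, 8, 9))
  out2 <- extract_hexamers(c(P1 = "AKSDKTIKYYAA"), sites)
  excl <- attr(out2, "excluded")
  expect_equal(out2$peptide, c("SDkTIK", "TIkYYA"))
  expect_equal(excl$position, c(2, 9))
  expect_equal(excl$reason, c("incomplete hexamer window",
                              "site residue is not lysine"))
  expect_error(extract_hexamers(c(P1 = "AAA"),
                                data.frame(protein_id = "P9", position = 1)),
               "absent from proteome")
})

test_that("extraction equals a sliding-window oracle on synthetic proteomes", {
  gen <- gen_synthetic_proteome(sim_config(seed = 99, n = 200))
  out <- extract_hexamers(gen$proteome, gen$sites)
  # oracle: independent substring logic over the site table
  oracle <- character(0)
  for (i in seq_len(nrow(gen$sites))) {
    s <- gen$proteome[[gen$sites$protein_id[i]]]
    p <- gen$sites$position[i]
    if (p >= 3 && p + 3 <= nchar(s) && substr(s, p, p) == "K") {
      hex <- substr(s, p - 2, p + 3)
      substr(hex, 3, 3) <- "k"
      oracle <- c(oracle, hex)
    }
  }
  expect_equal(sort(out$peptide), sort(unique(oracle)))
  expect_equal(nrow(out) + length(oracle) - length(unique(oracle)) +
                 nrow(attr(out, "excluded")), nrow(gen$sites))

  # order independence: shuffling the site table changes nothing
  set.seed(1)
  shuf <- extract_hexamers(gen$proteome, gen$sites[sample(nrow(gen$sites)), ])
  expect_equal(shuf$peptide, out$peptide)
  expect_equal(shuf$provenance, out$provenance)

  # re-embedding: every hexamer occurs in its parent at the recorded site
  for (i in sample(nrow(out), 20)) {
    prov <- strsplit(out$provenance[i], ";")[[1]][1]
    prot <- sub(":.*", "", prov)
    pos <- as.integer(sub(".*:K-", "", prov))
    expect_equal(substr(gen$proteome[[prot]], pos - 2, pos + 3),
                 toupper(out$peptide[i]))
    expect_equal(substr(toupper(out$peptide[i]), 3, 3), "K")
  }
})

test_that("screening scores, classifies and ranks; capped fixture passes 12", {
  ca <- load_fixture("D-CAPPED")
  scorer <- make_table_scorer(data.frame(peptide = ca$peptide,
                                         reweighted = ca$score))
  res <- run_screen(ca$peptide, scorer, cutoff_pair())
  expect_equal(res$summary$n, 16)
  expect_equal(res$summary$n_loose, 12)
  expect_equal(res$hits$rank, 1:16)
  expect_equal(res$hits$score, sort(ca$score))
  expect_true(all(res$hits$passes_loose[res$hits$passes_strict]))
  expect_lte(res$summary$n_strict, res$summary$n_loose)
  expect_lte(res$summary$n_loose, res$summary$n)

  empty <- run_screen(character(0), scorer, cutoff_pair())
  expect_equal(empty$summary$n, 0)
  expect_equal(empty$summary$n_loose, 0)
})

test_that("screen counts equal a brute-force threshold filter", {
  set.seed(77)
  peps <- unique(random_hexamers(1200))[1:1000]
  pssm <- build_pssm(sample(peps, 100))
  scorer <- make_surrogate_scorer(pssm, scale = 4, offset = -1110)
  cuts <- cutoff_pair(loose = -1108, strict = -1116)
  res <- run_screen(peps, scorer, cuts)
  sc <- -4 * score_with_pssm(pssm, peps) - 1110
  expect_equal(res$summary$n, 1000)
  expect_equal(res$summary$n_loose, sum(sc < -1108))
  expect_equal(res$summary$n_strict, sum(sc < -1116))
  # unscored peptides are reported, not dropped
  tab_scorer <- make_table_scorer(data.frame(peptide = peps[1:900],
                                             reweighted = sc[1:900]))
  res2 <- run_screen(peps, tab_scorer, cuts)
  expect_equal(res2$summary$n, 900)
  expect_equal(sort(res2$missing), sort(peps[901:1000]))
})

test_that("overlap annotation matches set-intersection oracles", {
  gen <- gen_synthetic_proteome(sim_config(seed = 123, n = 100))
  hx <- extract_hexamers(gen$proteome, gen$sites)
  pssm <- build_pssm(hx$peptide[1:20])
  res <- run_screen(hx, make_surrogate_scorer(pssm), cutoff_pair(2, 0))

  # disjoint lists annotate nothing
  res0 <- annotate_overlap(res, list(ubi = data.frame(protein_id = "NOPE",
                                                      position = 1)))
  expect_equal(res0$overlap$ubi$count, 0)
  expect_equal(res0$overlap$ubi$fraction, 0)

  # a list equal to the hit sites annotates everything
  prov <- strsplit(res$hits$provenance, ";")
  all_sites <- do.call(rbind, lapply(prov, function(p) {
    data.frame(protein_id = sub(":.*", "", p),
               position = as.integer(sub(".*:K-", "", p)))
  }))
  res1 <- annotate_overlap(res, list(ubi = all_sites))
  expect_equal(res1$overlap$ubi$fraction, 1)
  expect_true(all(grepl("ubi", res1$hits$annotations)))

  # random protein-level list vs an explicit intersection oracle
  set.seed(5)
  some <- sample(names(gen$proteome), 10)
  res2 <- annotate_overlap(res, list(interactor = some))
  oracle <- vapply(prov, function(p) {
    any(sub(":.*", "", p) %in% some)
  }, logical(1))
  expect_equal(res2$overlap$interactor$count, sum(oracle))
  expect_equal(grepl("interactor", res2$hits$annotations), oracle)
})
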