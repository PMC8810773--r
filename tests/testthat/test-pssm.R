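test_that("uniform observations with uniform background give zero weights", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # every residue exactly once per position
  peps <- vapply(seq_along(aa), function(i) {
    paste0(aa[i], aa[i], "k", aa[i], aa[i], aa[i])
  }, character(1))
  uni_bg <- setNames(rep(1 / 20, 20), aa)
  pssm <- build_pssm(peps, background = uni_bg)
  expect_equal(unname(pssm$weights), matrix(0, 5, 20), tolerance = 1e-12)
  expect_equal(pssm$window, c("P-2", "P-1", "P1", "P2", "P3"))
})

test_that("vanishing pseudocount floors unobserved residues", {
  pssm <- build_pssm("GGkFVR", pseudocount = 1e-12)
  expect_equal(pssm$weights["P-1", "A"], -10)     # unobserved, floored
  # observed at frequency 1: weight tends to -log2(bg) as pseudocount -> 0
  expect_equal(pssm$weights["P-1", "G"],
               unname(-log2(pssm$background["G"])), tolerance = 1e-6)
  expect_true(all(is.finite(pssm$weights)))
})

test_that("planted frequencies are recovered within 99% binomial bands", {
  cfg <- sim_config(seed = 101, n = 200)
  ds <- gen_peptide_dataset(cfg)
  res <- do.call(rbind, strsplit(toupper(ds$peptides), ""))
  for (plant in list(c("P-1", "G", 0.5), c("P1", "F", 0.2), c("P1", "Y", 0.2))) {
    col <- c("P-2" = 1, "P-1" = 2, "P1" = 4, "P2" = 5, "P3" = 6)[[plant[1]]]
    k <- sum(res[, col] == plant[2])
    p0 <- as.numeric(plant[3])
    band <- qbinom(c(0.005, 0.995), 200, p0)
    expect_gte(k, band[1])
    expect_lte(k, band[2])
  }
  # and the fitted PSSM reflects the planted enrichment
  pssm <- build_pssm(ds$peptides)
  expect_gt(pssm$weights["P-1", "G"], 1)
})

test_that("PSSM scoring sums requested positions, brute-force checked", {
  set.seed(31)
  peps <- unique(random_hexamers(80))[1:50]
  pssm <- build_pssm(sample(peps, 25))
  sc_full <- score_with_pssm(pssm, peps)
  # sub-window equal to the full window reproduces full scoring
  expect_equal(score_with_pssm(pssm, peps, positions = pssm$window), sc_full)
  # brute-force per-position lookup
  brute <- vapply(peps, function(p) {
    r <- strsplit(toupper(p), "")[[1]][-3]
    sum(pssm$weights[cbind(pssm$window, r)])
  }, numeric(1))
  expect_equal(sc_full, brute)
  # leading-dimer convention: two-term sum over P-2 and P-1 only
  sc2 <- score_with_pssm(pssm, peps, positions = c("P-2", "P-1"))
  r <- do.call(rbind, strsplit(toupper(peps), ""))
  expect_equal(unname(sc2),
               pssm$weights[cbind("P-2", r[, 1])] +
                 pssm$weights[cbind("P-1", r[, 2])])
  expect_error(score_with_pssm(pssm, peps, positions = "P9"), "absent")
  # training-list permutation invariance
  perm <- build_pssm(rev(sample(peps, 25)))
  expect_error(score_with_pssm(pssm, "ACDkEF", positions = "P4"), "absent")
})

test_that("PSSM weights are invariant to training-list permutation", {
  set.seed(37)
  peps <- random_hexamers(40)
  a <- build_pssm(peps)
  b <- build_pssm(sample(peps))
  expect_equal(a$weights, b$weights)
})

test_that("cross-correlation matrix matches rank oracles", {
  set.seed(41)
  peps <- unique(random_hexamers(30))[1:8]
  pssm <- build_pssm(peps[1:4])
  # dataset whose activities are a monotone transform of its own scores
  sc <- score_with_pssm(pssm, peps)
  ds <- list(self = list(peptides = peps, activities = exp(sc)))
  m <- cross_correlation(ds, list(self = pssm))
  expect_equal(m["self", "self"], 1)

  # small case against a brute-force Spearman (midranks)
  act <- rnorm(8)
  m2 <- cross_correlation(list(d = list(peptides = peps, activities = act)),
                          list(p = pssm))
  rho_brute <- {
    rs <- rank(act); rt <- rank(sc)
    sum((rs - mean(rs)) * (rt - mean(rt))) /
      sqrt(sum((rs - mean(rs))^2) * sum((rt - mean(rt))^2))
  }
  expect_equal(m2["d", "p"], rho_brute)

  # independent planted motifs, cross-scored with the exact planted-model
  # PSSMs: each dataset correlates with its own motif and is null against
  # the other (an estimated PSSM would leak rank correlation through
  # noise at the foreign signal position; the planted models are exact)
  ma <- planted_motif(0.6, 0.1)
  mb <- planted_motif(NULL, NULL)
  v <- human_aa_background(); v["A"] <- 0
  mb["P2", ] <- c(A = 0.35, v[names(v) != "A"] / sum(v) * 0.65)[colnames(mb)]
  da <- gen_peptide_dataset(sim_config(seed = 51, n = 300, motif = ma))
  db <- gen_peptide_dataset(sim_config(seed = 52, n = 300, motif = mb))
  m3 <- cross_correlation(list(a = da[c("peptides", "activities")],
                               b = db[c("peptides", "activities")]),
                          list(a = motif_pssm(ma), b = motif_pssm(mb)))
  expect_lt(abs(m3["a", "b"]), 0.15)
  expect_lt(abs(m3["b", "a"]), 0.15)
  expect_gt(m3["a", "a"], 0.3)
  expect_gt(m3["b", "b"], 0.3)
})

test_that("differential position enrichment flags planted residues", {
  set.seed(61)
  n <- 50
  # substrates: 80% glycine at P-1; background: 10%
  sub <- random_hexamers(n)
  substr(sub, 2, 2) <- ifelse(runif(n) < 0.8, "G", substr(sub, 2, 2))
  bg <- random_hexamers(n)
  substr(bg, 2, 2) <- ifelse(runif(n) < 0.9, "A", "G")
  hits <- differential_positions(sub, bg)
  g <- hits[hits$position == "P-1" & hits$residue == "G", ]
  expect_equal(nrow(g), 1)
  expect_equal(g$direction, "enriched")
  expect_lt(g$p_value, 0.05)

  # identical sets: nothing significant
  same <- differential_positions(sub, sub, alpha = 0.01)
  expect_equal(nrow(same), 0)

  # alpha = 1 disables the filter: every (position, residue) pair returned
  all_rows <- differential_positions(sub, bg, alpha = 1)
  expect_equal(nrow(all_rows), 5 * 20)
  expect_error(differential_positions(sub, character(0)), "non-empty")
})

test_that("PSSMs serialize with sidecar metadata and logo export", {
  set.seed(71)
  pssm <- build_pssm(random_hexamers(30), pseudocount = 0.2)
  tmp <- tempfile(fileext = ".tsv")
  write_pssm(pssm, tmp)
  back <- read_pssm(tmp)
  expect_equal(back$weights, pssm$weights)
  expect_equal(back$pseudocount, 0.2)
  expect_equal(back$background, pssm$background)
  lm_ <- logo_matrix(pssm)
  expect_equal(dim(lm_), dim(pssm$weights))
  expect_true(all(lm_ >= -1e-9))
})
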