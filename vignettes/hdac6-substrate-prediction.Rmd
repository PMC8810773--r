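---
title: "Quantifying and predicting HDAC6 substrate selectivity"
author: "deacpredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and predicting HDAC6 substrate selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deacpredict)
```

## The problem

HDAC6 is a Zn²⁺-dependent lysine deacetylase with unusually broad
substrate selectivity. Because selectivity on short peptides tracks
selectivity on full-length proteins for this enzyme, hexamer peptides
(two residues before and three after the acetyl-lysine, written
P−2…P+3 with the modified lysine at P0) are a workable proxy for
substrates. `deacpredict` implements the computational workflow around
that idea: turn raw enzymology into catalytic efficiencies and binary
substrate calls, calibrate a structure-based score cutoff against them,
screen an acetylome, and compare substrate calls across heterogeneous
published-style datasets.

This vignette documents the models, the tunable parameters, the
synthetic-data generators used for testing, and the numerical and design
choices a maintainer should know about.

## Kinetics from coupled-assay time courses

The acetate assay couples deacetylation-released acetate to NADH
fluorescence. After standard-curve conversion of signal into µM product,
the model is classical steady-state enzymology:

1. **Initial velocities.** For each substrate concentration, `v0` is the
   OLS slope of product vs. time over the initial-rate window, defined as
   product ≤ 10% of the substrate concentration (`max_conversion = 0.10`).
   At least three retained timepoints are required; fewer is an error,
   not a silent fit.
2. **Michaelis–Menten fit.** `fit_michaelis_menten()` fits
   `v0/[E] = kcat·[S]/(KM + [S])` by unweighted nonlinear least squares
   (Gauss–Newton, `port` algorithm with positivity bounds). Requiring at
   least four substrate concentrations, with a quality flag raised when
   fewer than two lie below the fitted KM, mirrors the design rule used
   to build the benchmark sets. Standard errors are asymptotic (from the
   NLS Jacobian); the efficiency SE uses first-order error propagation.
   No bootstrap by default; a `weighted` switch supports `1/SE²` weights
   when velocity standard errors are available, since whether the
   original fits were weighted is not knowable.
3. **Detection-limit capping.** The assay cannot resolve KM below
   roughly 10–20 µM. When the fitted KM falls below `detection_limit`
   (default 20 µM, the conservative upper end), the fit is flagged
   `capped` and kcat/KM is reported as a *lower bound* computed at
   KM = detection limit. Capped values are stored as (value, bound)
   pairs throughout the package — never as plain floats — so they cannot
   silently enter rank correlations.
4. **Substrate call.** kcat/KM ≥ 10⁴ M⁻¹s⁻¹ (`classification_config()`),
   the conventional threshold for cellular catalytic effectiveness. The
   boundary is *inclusive*: the benchmark tables mark 9,000 M⁻¹s⁻¹ as a
   non-substrate and values from 11,000 up as substrates, leaving the
   boundary itself unstated; we include it.

**Initialization and restarts.** `kcat₀ = max(v0)/[E]`,
`KM₀ = median([S])`; on failure, up to five deterministic multiplicative
perturbations of the start (2×, ½×, 4×, …) are tried before a fit-failure
error carrying the optimizer diagnostics. Deterministic restarts keep the
fit a pure function of its inputs.

## The structure-based score and its calibration

The predictor itself (flexible peptide docking under catalytic-geometry
constraints) runs in an external engine; this package consumes its
output. The operative quantities are:

- **Reweighted score** = total score + interface score + peptide score
  (REU; lower is better). The identity is enforced at parse time when the
  column is absent.
- **Template ensemble.** From `nstruct = 250` decoys of the reference
  substrate complex, the top 5 by reweighted score become templates
  (`select_templates()`, ties broken lexicographically by model id so
  selection is total and reproducible). A peptide's score is the
  *minimum* over templates (`aggregate_best()`).
- **Catalysis-competent geometry.** Constraint files for the engine are
  generated by measuring distances (zinc coordination, acetyl-lysine
  pocket) and the cis-peptide dihedral between peptide residues 3 and 4
  directly on the input structure (`measure_constraints()`), so each
  template carries self-consistent restraints. Tolerances are
  configurable per constraint; the exact values used originally are not
  recoverable, so defaults are measured from the structure at hand.

**Cutoff calibration.** A peptide is *predicted* a substrate when its
score is strictly below the cutoff. `select_cutoff(data, max_fp)`
returns the largest threshold admitting at most `max_fp` false
positives, scanning the observed non-substrate scores plus all observed
scores minus 1 REU. On the packaged training set this yields the loose
cutoff −1105 (≤1 FP). The strict default −1118 is the published 0-FP
threshold; note that `select_cutoff(max_fp = 0)` returns −1117, an
equally valid but less stringent 0-FP threshold — both are kept, with
the published value as the `cutoff_pair()` default.

Strict-less-than comparison is a deliberate choice: three training
non-substrates score exactly −1105, and only under `score < cutoff` do
the printed scores reproduce the published confusion matrix
(tp 15, fp 1, tn 6, fn 4 → sensitivity 0.79, specificity 0.86,
MCC 0.59). A score exactly at a cutoff therefore does *not* pass.

**Metrics.** Sensitivity, specificity and MCC from the confusion counts;
AUC by the Mann–Whitney pair-counting statistic with ties worth ½ (tested
equivalent to the trapezoidal empirical-ROC area); Spearman ρ with
midranks. Capped records enter binary evaluation as positives but are
excluded from rank correlation — their activities are bounds, not values.
Metrics undefined on single-class input are reported as `NA`, never as 0.
Reports carry both full precision and 2-decimal roundings.

**Known near-matches.** Recomputing from the rounded printed benchmark
table gives AUC 0.79 and ρ −0.72 where the published analysis (run on
unrounded measurements) reported 0.78 and −0.66. These two quantities
are treated as near-match properties (|Δ| ≤ 0.07), not exact targets;
the confusion-matrix metrics reproduce exactly. One training record
(YKkFYE) prints a kcat/KM inconsistent with its own printed kcat and KM
beyond any rounding explanation (85,714 vs 40,000 M⁻¹s⁻¹); the fixture
transcribes it verbatim and `audit_kinetic_consistency()` flags it. The
audit's consistency rule is "within printed rounding": the relative
deviation between re-divided and printed efficiency must not exceed the
slack implied by half-unit-in-the-last-place rounding of the three
printed numbers. A literal two-significant-figure equality would reject
many legitimately rounded rows (e.g. 1.4/20 µM → 70,000 printed as
60,000 from unrounded values), so it is not used.

## Screening an acetylome

`extract_hexamers()` takes 1-based inclusive windows
`[site − 2, site + 3]`; sites whose window crosses a terminus, or whose
reference residue is not lysine, are excluded *and reported*. Identical
hexamers from different proteins are deduplicated with full provenance
retained (`protein:K-site`, all of them). Evidence filtering
(low-throughput-supported sites only) is a reader flag, default on.
`run_screen()` scores, classifies against both cutoffs, ranks ascending
by score, and emits stage counts so every filter is auditable;
`annotate_overlap()` intersects hits with external site lists (exact
protein+position) or interactor lists (protein-level). Scorer coverage
gaps are reported, never imputed — a silently dropped peptide would
corrupt downstream counts.

## PSSMs and cross-dataset concordance

`build_pssm()` uses pseudocount log-odds:
`w(p, a) = log2((f(p,a) + pc·bg(a)) / ((1 + pc)·bg(a)))` with
`pc = 0.1` by default and a floor of −10 for unobserved residues. The
acetyl-lysine position is excluded (it is fixed by construction). The
default background is the human proteome amino-acid composition;
passing a non-substrate peptide set instead mirrors differential-logo
backgrounds. The exact matrix construction of the originally used web
tools is not reproducible from public information; pseudocount log-odds
is a standard, well-defined stand-in, and both pseudocount and
background are configurable and serialized alongside the matrix.

Sub-window scoring (`positions =`) supports the conventions needed for
cross-dataset comparison, e.g. scoring hexamers with a trimer-derived
matrix over P−2/P−1 only. `cross_correlation()` reports Spearman ρ
between each dataset's activities and each PSSM's scores; incompatible
windows yield `NA` entries, not zeros. `differential_positions()` runs
per-(position, residue) exact binomial tests against the (smoothed)
background rate, uncorrected by default to match common two-sample-logo
practice, with a Bonferroni switch.

Concordance across published-style datasets uses the stated
classification bands — SILAC H/L: non-substrate in [0.8, 1.2], substrate
at ≥ 2; array replica count: non-substrate ≤ 1, substrate ≥ 3 — all
endpoints inclusive, intermediates kept as a third label and excluded
from agreement counting. Records are matched on the core P−2…P+3
hexamer so flank-variant peptides join; the summary also reports the
fraction of shared hexamers whose label is invariant to flanking
differences.

## The synthetic world

Generators are pure functions of `sim_config()` (one seed, byte-identical
reruns). Defaults state the world the analysis assumes, chosen once:

- kcat ∈ [0.2, 6] s⁻¹, KM ∈ [15, 200] µM — the training-set ranges;
- substrate concentrations spanning 10–2000 µM (the assay's range), six
  points by default;
- 5% relative Gaussian noise on product measurements (typical for the
  fluorescence readout; the recovery property "median KM error < 10%"
  holds at this level);
- activities log-uniform over 10³–10⁶ M⁻¹s⁻¹ (three decades, as
  measured), log-normal activity noise (kinetic errors scale roughly
  multiplicatively);
- score/activity coupling through a Gaussian copula with Pearson
  parameter `r = 2·sin(π·ρ/6)`, hitting a target Spearman directly
  (ρ = −0.66 by default, the calibrated protocol's headline
  association); ρ = −1 degenerates to exact monotone coupling;
- planted sequence motifs over a human-composition base: glycine 0.5 at
  P−1 and aromatics 0.4 at P+1 by default, the dominant features of
  deacetylase substrate logos. Unplanted positions follow the background
  rather than a uniform law — otherwise every position of every dataset
  would be "enriched" against the human background and independent
  motifs would correlate spuriously.

What the generators deliberately do **not** emulate: the coupled
detection chemistry (noise is phenomenological, not mechanistic),
realistic protein structure (the toy PDB exists to test geometry code),
position interdependence within peptides (sampling is position-wise
independent, which real substrates are not), and engine score physics
(surrogate scores are negated PSSM scores on a REU-like scale). A green
test against this world therefore establishes the correctness of the
estimation and selection machinery, not the biological accuracy of any
particular scorer.

One subtlety worth recording: when two datasets carry *independent*
planted motifs, cross-scoring with PSSMs *estimated* from a few hundred
peptides still leaks rank correlation — Spearman is scale-invariant, so
even tiny estimation noise at the position carrying the other dataset's
signal orders peptides. The null-correlation property is therefore
stated against the exact planted-model PSSMs (`motif_pssm()`), where
unplanted positions have exactly-zero weights; PSSM *estimation* quality
is tested separately via binomial recovery bands.

## Numerical choices and degenerate inputs

- OLS everywhere a line is fitted; degenerate designs (all
  concentrations equal, < 3 timepoints) are errors, not NA results.
- NLS restarts are deterministic; non-convergence after 5 restarts
  raises an error carrying the optimizer message.
- Template-selection ties break on lexicographic model id; cutoff
  candidates include observed scores − 1 REU so a 0-FP threshold exists
  even under perfect separation.
- Dihedrals are reported in (−180°, 180°], 0 = cis, and are invariant
  under rigid-body motion (tested with random rotations).
- Peptide notation is canonicalized to lower-case `k` before any
  matching or hashing; readers accept `(K-Ac)` and `K[ac]` dialects,
  thousands separators and Unicode minus signs.
- All thresholds compare strictly (`<`) for scores and inclusively
  (`≥`) for activities; both conventions are forced by the printed
  benchmark data, as discussed above.

## Limitations

- The packaged fixtures transcribe *printed* (rounded) values; analyses
  needing unrounded precision (exact AUC/ρ reproduction) are out of
  reach by construction, and one printed row is internally inconsistent
  (flagged by the audit).
- Acetylome-scale screening results depend on an external scoring
  engine; with the table scorer this package reproduces counts for any
  supplied score table but cannot regenerate the scores themselves. The
  PSSM surrogate keeps the pipeline runnable end-to-end but is a
  sequence model, blind to structure.
- Concordance analysis inherits the published datasets' thresholds;
  sites quantified under different protein-inference rules may join on
  the same core hexamer yet disagree for reasons the package does not
  model.
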