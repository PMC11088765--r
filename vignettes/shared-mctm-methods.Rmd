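---
title: "Deriving and validating a shared multicellular tumor signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a shared multicellular tumor signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Solid tumors are multicellular systems: malignant cells, fibroblasts,
endothelium, pericytes and immune cells exchange ligand signals that
reshape each other's transcriptional programs. If some of those
ligand-to-target circuits recur across otherwise very different cancers,
they are candidates for shared pathogenic mechanisms — and a gene
signature built from them should carry prognostic information in any
cancer cohort. `shmctm` implements that whole chain of reasoning as a
tested pipeline:

1. **Cell-cell interaction (CCI) inference per cancer.** Inputs are
   per-cancer, per-cell-type differential-expression (DEG) tables (tumor
   vs normal, retained at adjusted p < 0.05 and |log2FC| > 0.25) and a
   nonnegative ligand-by-gene *regulatory-potential prior*. For an
   ordered (sender, receiver) cell-type pair, each candidate ligand
   (a sender DEG present in the prior, either direction of change) is
   scored by the Pearson correlation, across a background gene universe,
   between its prior weight vector and the 0/1 indicator of receiver-DEG
   membership. The `top_n` ligands per pair keep their `top_k`
   highest-weight receiver-DEG targets. This is a deliberately
   transparent re-implementation of the ranking semantics of
   prior-based ligand-activity tools; it does not try to reproduce any
   particular tool's curated prior (see Non-goals below).
2. **Multicellular tumor models (MCTMs).** Per cancer, cell types become
   nodes and the number of distinct (ligand, target) records between a
   pair becomes the directed edge weight; the union of upstream
   regulators (URs) and downstream targets (DSs) is the model's gene set.
3. **Cross-cancer consensus (shared-MCTM).** A UR must (i) appear as a UR
   in *every* cancer and (ii) show the same sign of log2FC in the same
   cell type in at least `min_concordant` cancers (default 4, the
   4-of-5 rule). DSs pass the same two rules, with the additional
   requirement of linkage to at least one shared-UR in at least
   `ds_link_min_cancers` cancers (default 1). Each shared-UR is connected
   to every downstream cell type holding at least one of its shared-DSs,
   weighted by the count of such genes.
4. **Signature prioritization.** Shared-URs are clustered on their
   per-cell-type downstream interaction counts (Euclidean distance,
   agglomerative clustering, dendrogram cut at two); the cluster with
   more interactions in all cell types supplies the *top shared-URs*.
   Matrix-CAF (mCAF) markers are added by a two-step rule: top 10 marker
   log2FC against the other CAF subclusters, then a tumor-vs-normal DEG
   filter, then exclusion of genes already chosen. The union, with
   provenance, is the signature.
5. **Cohort scoring.** Expression cohorts get a rank-based single-sample
   gene-set score; protein (NPX) cohorts are QC'd (features with > 20%
   missing dropped, K-nearest-neighbor imputation with k = 10) and scored
   by the mean NPX of signature proteins. Scores dichotomize at the
   cohort mean.
6. **Survival validation.** Follow-up is administratively censored at the
   10-year horizon; scores (continuous) enter Cox proportional-hazards
   models with Efron tie handling, adjusted for sex, age at diagnosis,
   cancer type and sampling lag; Kaplan-Meier curves of score level
   crossed with sex are compared by the two-sided log-rank test;
   per-cancer screens exclude cancers with fewer than 20 death events;
   multiplicity is controlled by Benjamini-Hochberg FDR.

# Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `top_n` | 20 | ligands kept per cell-type pair; mirrors the convention of prior-based ligand-activity tools, admittedly arbitrary |
| `top_k` | 200 | targets kept per ligand; same convention |
| `min_concordant` | 4 | concordant cancers required (4 of 5); the consensus rule itself |
| `ds_link_min_cancers` | 1 | cancers in which a DS must be linked to a shared-UR; the linkage quorum is not uniquely determined by the consensus rules, so it is exposed |
| `linkage` | `"complete"` | hierarchical-clustering linkage; not dictated by the procedure, so exposed and oracle-tested per linkage |
| `max_missing` | 0.20 | protein QC threshold (features missing in *more than* 20% of samples are dropped; exactly 20% is kept) |
| `k` | 10 | imputation neighbors |
| `horizon_days` | 3652 | 10 years; the horizon is specified in years, and 3652 days covers two leap days |
| `min_events` | 20 | per-cancer death-event floor below which a stratum is skipped (and reported as skipped) |

# What the synthetic generator emulates — and what it does not

`sim_config()` + the `generate_*()` functions produce every input the
pipeline consumes, with the structure the analysis *assumes*:

- **DEG tables** contain three planted shared-URs (fibroblast sender) and
  five planted targets each ("cancer cell" receiver), carrying the
  planted sign in exactly `concordance_cancers` cancers (and the opposite
  sign elsewhere, so they remain present in all cancers). Decoys fail the
  rules in controlled, mutually exclusive ways: dropout decoys are absent
  from exactly one cancer (fail universality); sign-flip decoys are
  present everywhere with at most 3 of 5 concordant signs (fail
  concordance); decoy targets are linked and universal but
  sign-discordant. Filler genes are cancer-specific, so they can never
  pass universality. Consensus recovery can therefore be asserted
  *exactly*, which is the point of the decoy engineering.
- **The prior** is sparse gamma noise (60% density) with an additive
  `prior_signal` boost on planted ligand-target pairs.
- **Cohorts** draw a latent signature activity per sample
  (standard normal, +1 in the tumor arm); signature genes are the latent
  activity plus gene-specific Gaussian noise (s.d. 0.5), so the rank
  score and the mean-protein score both track it. Survival is exponential
  with hazard `h0 * exp(beta_score * s + 0.03 * (age - 62) +
  0.25 * male)` and `h0` fixed at a five-year median — exponential rather
  than Weibull because it is the simplest law satisfying proportional
  hazards and admits closed-form sanity checks. Independent exponential
  censoring is calibrated so about `censor_rate` of subjects censor
  before their event; administrative censoring applies at 10 years.
  Protein matrices add missing-completely-at-random gaps
  (`missing_rate`); MCAR is an explicit simplification, since the
  missingness mechanism of real plasma-proteomics panels is not
  characterized here.
- **Seeding.** One global seed fans out to per-table child seeds via a
  fixed counter scheme (`(seed + 97003 * counter) mod 2^31 - 1`), so
  generating an extra table never perturbs earlier ones, and every output
  is a pure function of the configuration.

What passing tests on these data do *not* show: recovery of any real
tumor's interaction network. The generator emulates the *derived* tables,
not raw single-cell counts; effect sizes are configurable rather than
calibrated to an empirical log2FC distribution (none is published for
this setting); cell-type proportions, batch structure, ambient
contamination and the correlation structure of real DEG calls are all
absent. The suite demonstrates that the machinery implements its stated
rules exactly and that the statistical stages are calibrated — not that
the biology of any particular cohort will reproduce.

# Numerical and design choices

- **Ligand-activity statistic.** The external tools this step emulates do
  not document their internals in the analysis being reproduced; this
  package adopts Pearson correlation of prior weights against target-set
  membership as the activity statistic, which reproduces the ranking
  semantics while staying auditable. Ligands with constant weights over
  the background have undefined correlation and are flagged `NA` and
  ranked last rather than erased silently. A background in which every
  gene (or no gene) is a receiver DEG makes the correlation undefined and
  is a hard error.
- **Background universe.** The background for a receiver defaults to the
  union of all genes in that cancer's DEG tables. A per-receiver-only
  universe would coincide with the receiver's DEG set and make the
  indicator constant, so the cancer-wide universe is the smallest choice
  that keeps the statistic defined; it is overridable.
- **Concordance ties.** log2FC of exactly 0 counts toward neither sign; a
  tie between positive and negative counts has no majority sign and
  qualifies nowhere. A gene may qualify in several cell types (all pairs
  kept) and in both the UR and DS roles (counted once in the gene
  union, reported in both tables — the role overlap is printed
  explicitly).
- **Cluster-dominance fallback.** "Larger in all cell types" is
  operationalized as column-wise mean dominance (all means >= , at least
  one >); when neither cluster dominates, the larger total count wins,
  and an exact total tie falls back to the cluster containing the
  lexicographically first row. Single-row and all-identical matrices
  return the trivial answer with a warning.
- **Single-sample score.** The score follows the weighted
  Kolmogorov-Smirnov random-walk construction with the kernel CDF
  estimate replaced by the empirical CDF — this removes a bandwidth
  choice while preserving the rank semantics, and makes the
  monotone-transform invariance exact. The statistic is the signed sum of
  the walk's extrema, which is bounded in [-1, 1]. This is a documented
  deviation from kernel-smoothed implementations; no alternative
  estimator is offered.
- **Imputation distances** are root-mean-square differences over mutually
  observed features (not raw Euclidean sums), so pairs with different
  overlap sizes are comparable; only neighbors observed for the target
  feature are eligible, with the feature mean as the last resort.
- **Cox details.** Efron approximation for ties (a tie-handling method
  must be fixed; Efron is the more accurate default); Wald 95% CIs;
  non-convergence and non-identifiability are flagged in the result row
  rather than raised, because a screening loop must survive a degenerate
  stratum. Constant exposures and strata with fewer than two events are
  errors, not flags, since no fit is meaningful there.
- **Ten years = 3652 days** (two leap days in any 10-year window
  starting 1 March – 28 Feb; the exact day count is a convention and is
  exposed as `horizon_days`).

# Problem sizes used by the test and acceptance suites

The suites run at sizes chosen to exercise every rule while keeping a
full run in minutes: consensus equivalence against a brute-force
nested-loop oracle on 200 random instances (50 genes, 5 cancers, 6 cell
types); planted-recovery across 20 seeds at the default configuration;
clustering-membership agreement on 100 random 12 x 4 integer matrices;
Cox parameter recovery with a planted log(2) hazard at 1000 patients and
100 replicates; null calibration of Cox and log-rank p-values over 500
replicates of 100 patients; Fisher agreement with hypergeometric
enumeration over all 46,375 two-by-two tables with total count at most
30. `scripts/acceptance.R` recomputes all of these from scratch at a
caller-supplied seed.

# Known limitations

- The ligand-activity statistic is a simplification; regression-based
  activity variants and receptor-expression filtering are out of scope.
- The consensus stage requires exact symbol matches across cancers; no
  ortholog or alias resolution is attempted.
- The per-cancer screen reports BH adjustment across retained cancers for
  one exposure; adjusting across features within a cancer is supported by
  running the screen per feature, but no joint correction is offered.
- Competing risks, time-varying covariates and formal proportionality
  diagnostics are not implemented.
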