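# shmctm — shared multicellular tumor models and mortality-associated signatures

`shmctm` is an R package plus analysis workflow for asking whether
different solid cancers share cell–cell interaction (CCI) circuits — a
ligand (upstream regulator, UR) in one cell type driving target genes
(downstream targets, DSs) in another — and whether a gene signature
distilled from those shared circuits predicts 10-year all-cause
mortality. It is written for computational biologists who have
per-cancer, per-cell-type differential-expression tables and a
ligand→target regulatory-potential prior, and who want the consensus
construction, signature prioritization, cohort scoring and survival
validation as tested, reusable functions rather than a one-off script.

## The method in brief

**CCI inference.** For sender cell type *s* and receiver *r* in one
cancer, each candidate ligand ℓ (a DEG of *s* present in the prior) is
scored by the Pearson correlation over a background gene universe *B*:

> activity(ℓ) = cor( w<sub>ℓ</sub>, 𝟙[g ∈ DEG<sub>r</sub>] ), g ∈ B

where w<sub>ℓ</sub> is ℓ's row of the regulatory-potential prior. The
top-n ligands per (s, r) pair keep their top-k highest-weight receiver
DEGs as targets.

**Shared-MCTM.** A UR is *shared* if it is a UR in every cancer and its
log2FC has the same sign in the same cell type in ≥ 4 of 5 cancers;
shared-DSs pass the same rules plus linkage to a shared-UR. Shared-URs
connect to downstream cell types weighted by their number of shared-DSs.

**Signature.** Shared-URs are clustered on their downstream interaction
counts (Euclidean, two-cluster cut); the dominant cluster plus
matrix-CAF markers (top-10 marker log2FC, then tumor-vs-normal DEG
filter) form the signature.

**Validation.** Per-sample scores — a rank-based single-sample gene-set
score on expression, the mean NPX of signature proteins after >20%
missingness QC and 10-NN imputation — enter Cox proportional-hazards
models (Efron ties, adjusted for sex, age at diagnosis, cancer type,
sampling lag) against 10-year mortality, with Kaplan–Meier/log-rank
comparisons of score level × sex and a 20-death-event floor for
per-cancer analyses.

A synthetic-data module generates every input with planted structure
(shared-URs, engineered decoys that fail each consensus rule, cohorts
with a configurable log-hazard per unit of latent signature activity),
so the entire pipeline is testable without restricted data.

## Worked example

The numbered drivers under `analysis/` run the whole chain on synthetic
data and narrate what they find (run them in order from the repository
root; outputs land under `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_infer_cci.R
Rscript analysis/03_shared_mctm.R
Rscript analysis/04_signature.R
Rscript analysis/05_score_cohorts.R
Rscript analysis/06_survival.R
```

Stage 3 prints the consensus model — with the default configuration the
three planted shared-URs and all fifteen planted targets are recovered
exactly, and nothing else:

```
<shared_mctm> 18 genes (3 shared-URs, 15 shared-DSs, 0 in both roles), 3 edges, 5 cancers
```

Stage 6 prints the survival validation of the signature scores on the
synthetic cohorts (planted log-hazard log 2 per unit latent activity,
200 patients):

```
mrna_score             HR 3.96 [2.63-5.98], p=4.7e-11 (156 events/200)
protein_score          HR 2.37 [1.91-2.95], p=1.1e-14 (153 events/200)
protein_score_female   HR 1.97 [1.40-2.75], p=8e-05 (72 events/90)
protein_score_male     HR 2.94 [2.14-4.03], p=2.4e-11 (81 events/110)
per-cancer screen: 5 retained, 0 skipped (<20 events)
log-rank across level x sex arms: chisq=49.50 (df=3), p=1e-10
```

The protein score is on the latent-activity scale, so its HR sits near
the planted value of 2; the rank-based mRNA score lives on a compressed
[-1, 1] scale, so its per-unit HR is larger. The same stage writes the
Kaplan–Meier step functions and the per-cancer screen to
`results/survival/`.

Equivalently, `run_pipeline(sim_config(seed = 1), "out_dir")` executes
all stages in one call and writes a manifest of md5-hashed outputs.

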