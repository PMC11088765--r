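#!/usr/bin/env Rscript
# Stage 5: cohort scoring. The expression cohort gets the rank-based
# single-sample gene-set score; the protein cohort is QC'd (>20% missing
# features dropped, KNN imputation with 10 neighbors) and scored by the
# mean NPX of signature proteins. Both scores are dichotomized at the
# cohort mean. Per-feature differential abundance (Wilcoxon, BH) compares
# the tumor and normal arms.

library(shmctm)

out <- "results/scoring"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

signature <- read_gmt("results/data/published_signature.gmt")[[1]]
expr <- read_cohort("results/data/cohort_expression", "expression")
prot_raw <- read_cohort("results/data/cohort_protein", "protein")

prot <- qc_and_impute(prot_raw, max_missing = 0.20, k = 10)
message(sprintf("protein QC: %d -> %d features, gaps imputed",
                ncol(prot_raw$abundance), ncol(prot$abundance)))

gscore <- gene_set_score(expr, signature)
pscore <- protein_score(prot, signature)
write_scores(gscore, file.path(out, "score_mrna.tsv"))
write_scores(pscore, file.path(out, "score_protein.tsv"))
message(sprintf("mRNA score: mean %.3f (cutoff), %d high / %d low",
                attr(gscore, "cutoff"), sum(gscore$level == "high"),
                sum(gscore$level == "low")))
message(sprintf("protein score: mean %.3f (cutoff), %d high / %d low",
                attr(pscore, "cutoff"), sum(pscore$level == "high"),
                sum(pscore$level == "low")))

de <- differential_abundance(expr, signature)
shmctm:::write_tsv(de, file.path(out, "differential_abundance.tsv"))
message(sprintf("differentially abundant signature genes (adj p < 0.05): %d of %d",
                sum(de$adj_p < 0.05), nrow(de)))
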