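#!/usr/bin/env Rscript
# Stage 1: generate every pipeline input with the statistical structure the
# downstream analysis assumes — per-cancer DEG tables with three planted
# shared-URs (plus engineered decoys), a ligand-target regulatory prior
# with boosted planted pairs, CAF subcluster marker tables, and two
# survival cohorts (expression and protein) whose hazard depends
# log-linearly on the latent signature activity.

library(shmctm)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1)
write_sim_config(cfg, file.path(out, "sim_config.yaml"))

degs <- generate_deg_tables(cfg)
write_deg_tables(degs, file.path(out, "deg"))
message(sprintf("DEG tables: %d cancers, %s rows each",
                length(degs), paste(vapply(degs, nrow, 1L), collapse = "/")))

prior <- generate_prior(cfg)
write_prior(prior, file.path(out, "prior.tsv"))
message(sprintf("prior: %d ligands x %d genes, %.0f%% nonzero",
                nrow(prior), ncol(prior), 100 * mean(prior > 0)))

caf <- generate_caf_markers(cfg)
write_tsv <- shmctm:::write_tsv
write_tsv(caf$markers, file.path(out, "caf_markers.tsv"))
write_tsv(caf$mcaf_tumor_vs_normal, file.path(out, "mcaf_tumor_vs_normal.tsv"))

# cohorts carry the *published* 16-gene signature so the scoring stages
# mirror the cohort validation; the synthetic pipeline's own signature is
# assembled in stage 4
gmt <- read_gmt(system.file("extdata", "published_signature.gmt",
                            package = "shmctm"))
signature <- unique(unlist(gmt))
write_gmt(list(published_signature = signature),
          file.path(out, "published_signature.gmt"))
expr <- generate_cohort(cfg, signature, "expression")
prot <- generate_cohort(cfg, signature, "protein")
write_cohort(expr, file.path(out, "cohort_expression"))
write_cohort(prot, file.path(out, "cohort_protein"))
message(sprintf("cohorts: %d samples each; %d events (expression arm), %.1f%% protein NAs",
                nrow(expr$abundance), sum(expr$samples$event),
                100 * mean(is.na(prot$abundance))))
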