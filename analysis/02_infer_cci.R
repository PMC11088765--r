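#!/usr/bin/env Rscript
# Stage 2: per-cancer cell-cell interaction inference. For every ordered
# cell-type pair, sender DEG ligands are ranked by the correlation of
# their prior regulatory potential with receiver DEG membership; the top
# ligands contribute their top weighted targets. Each cancer's records are
# collapsed into a multicellular tumor model graph.

library(shmctm)

data_dir <- "results/data"
out <- "results/cci"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

degs <- read_deg_tables(file.path(data_dir, "deg"))
prior <- read_prior(file.path(data_dir, "prior.tsv"))

cci_sets <- lapply(degs, infer_cci_for_cancer, prior = prior,
                   top_n = 20, top_k = 200)
all_cci <- do.call(rbind, cci_sets)
shmctm:::write_tsv(all_cci, file.path(out, "cci.tsv"))
message(sprintf("CCI records per cancer: %s",
                paste(vapply(cci_sets, nrow, 1L), collapse = "/")))

for (nm in names(cci_sets)) {
  g <- build_mctm(cci_sets[[nm]])
  write_mctm(g, file.path(out, paste0("mctm_", nm)))
  message(sprintf("MCTM %s: %d cell types, %d edges, %d genes (URs: %d)",
                  nm, length(g$nodes), nrow(g$edges), length(g$mctm_genes),
                  length(unique(cci_sets[[nm]]$ligand))))
}
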