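#!/usr/bin/env Rscript
# Stage 4: signature assembly. Shared-URs are clustered on their
# downstream interaction counts (Euclidean distance, two-cluster cut); the
# dominant cluster gives the top shared-URs. Matrix-CAF markers pass the
# two-step rule (top-10 marker log2FC, then tumor-vs-normal DEG filter,
# then exclusion of already-chosen genes). The union is the signature.

library(shmctm)

out <- "results/signature"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genes <- read.delim("results/shared_mctm/shared_mctm_genes.tsv",
                    stringsAsFactors = FALSE)
edges <- read.delim("results/shared_mctm/shared_mctm_edges.tsv",
                    stringsAsFactors = FALSE)
sm <- structure(list(
  shared_urs = genes[genes$role == "shared_ur",
                     c("gene", "cell_type", "sign", "n_concordant")],
  shared_dss = genes[genes$role == "shared_ds",
                     c("gene", "cell_type", "sign", "n_concordant")],
  edges = edges,
  genes = sort(unique(genes$gene)),
  cancers = character()), class = "shared_mctm")

icm <- interaction_count_matrix(sm)
shmctm:::write_tsv(data.frame(ur = rownames(icm), icm, check.names = FALSE),
                   file.path(out, "interaction_counts.tsv"))
top_urs <- prioritize_urs(icm)
message(sprintf("top shared-URs (%d of %d): %s",
                length(top_urs), nrow(icm),
                paste(top_urs, collapse = ", ")))

markers <- read.delim("results/data/caf_markers.tsv",
                      stringsAsFactors = FALSE)
mcaf_deg <- read.delim("results/data/mcaf_tumor_vs_normal.tsv",
                       stringsAsFactors = FALSE)
mcaf_cluster <- mcaf_deg$cell_type[1]
mcaf_genes <- select_mcaf_markers(
  markers[markers$cluster == mcaf_cluster, ], mcaf_deg,
  exclude = sub("@.*$", "", top_urs))
message(sprintf("mCAF markers surviving the DEG filter: %d of top 10",
                length(mcaf_genes)))

sig <- assemble_signature(sub("@.*$", "", top_urs), mcaf_genes)
write_signature(sig, file.path(out, "signature"))
message(sprintf("signature: %d genes (%d shared-URs + %d mCAF markers)",
                nrow(sig), sum(sig$provenance == "top_shared_ur"),
                sum(sig$provenance == "mcaf_marker")))
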