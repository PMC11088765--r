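#' Interaction-count matrix of shared-URs by downstream cell type
#'
#' Rows are the shared-URs of a shared-MCTM (as `gene@cell_type` when a
#' gene qualifies in several cell types, plain gene symbol otherwise),
#' columns the downstream cell types, entries the number of shared-DS
#' interactions (edge weights; 0 where no edge exists).
#'
#' @param x A `shared_mctm` object.
#' @return Integer matrix with dimnames.
#' @export
interaction_count_matrix <- function(x) {
  stopifnot(inherits(x, "shared_mctm"))
  if (nrow(x$shared_urs) == 0) {
    return(matrix(integer(), 0, 0))
  }
  key <- paste(x$shared_urs$gene, x$shared_urs$cell_type, sep = "@")
  label <- if (anyDuplicated(x$shared_urs$gene)) key else x$shared_urs$gene
  cts <- sort(unique(x$edges$ds_cell_type))
  m <- matrix(0L, nrow(x$shared_urs), max(length(cts), 1),
              dimnames = list(label,
                              if (length(cts)) cts else "none"))
  if (nrow(x$edges) == 0 || length(cts) == 0) return(m)
  edge_key <- paste(x$edges$ur, x$edges$ur_cell_type, sep = "@")
  for (i in seq_len(nrow(x$edges))) {
    r <- match(edge_key[i], key)
    m[r, x$edges$ds_cell_type[i]] <- as.integer(x$edges$n_shared_ds[i])
  }
  m
}

#' Prioritize top shared-URs by interaction-count clustering
#'
#' Rows of the interaction-count matrix are clustered by agglomerative
#' hierarchical clustering under Euclidean distance; the dendrogram is cut
#' into exactly two clusters, and the cluster with the larger number of
#' interactions in all cell types (column-wise mean dominance: every
#' per-cell-type mean at least as large, at least one strictly larger) is
#' the top cluster. When neither cluster dominates every column, the
#' cluster with the greater total count wins; an exact total tie falls
#' back to the cluster containing the lexicographically first row label.
#'
#' @param m Interaction-count matrix (rows: shared-URs, columns:
#'   downstream cell types), at least one row.
#' @param linkage Linkage method for [stats::hclust()]; default
#'   `"complete"`.
#' @return Character vector of top shared-UR row labels, sorted by total
#'   interaction count (decreasing, ties by label).
#' @export
prioritize_urs <- function(m, linkage = "complete") {
  stopifnot(is.matrix(m), nrow(m) >= 1)
  by_total <- function(rows) {
    tot <- rowSums(m[rows, , drop = FALSE])
    rows[order(-tot, rows)]
  }
  if (nrow(m) == 1) {
    warning("prioritize_urs: single shared-UR; returned as the trivial top set")
    return(rownames(m))
  }
  d <- stats::dist(m)
  if (max(d) == 0) {
    warning("prioritize_urs: all rows identical; degenerate clustering, ",
            "returning all shared-URs")
    return(by_total(rownames(m)))
  }
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = 2)
  rows1 <- rownames(m)[cl == 1]
  rows2 <- rownames(m)[cl == 2]
  mean1 <- colMeans(m[rows1, , drop = FALSE])
  mean2 <- colMeans(m[rows2, , drop = FALSE])
  top <- if (all(mean1 >= mean2) && any(mean1 > mean2)) {
    rows1
  } else if (all(mean2 >= mean1) && any(mean2 > mean1)) {
    rows2
  } else {
    # documented fallback: greater total count; then first row label
    t1 <- sum(m[rows1, , drop = FALSE])
    t2 <- sum(m[rows2, , drop = FALSE])
    if (t1 > t2) rows1
    else if (t2 > t1) rows2
    else if (min(rows1) < min(rows2)) rows1 else rows2
  }
  by_total(top)
}

#' Select matrix-CAF marker genes for the signature
#'
#' Two-step rule: take the `top_n` genes with the highest marker log2FC
#' for the target CAF cluster (ties broken by symbol), keep those that are
#' also tumor-vs-normal DEGs in that cluster, then drop any gene already
#' chosen elsewhere (e.g. the top shared-URs). Order of the surviving
#' genes is preserved.
#'
#' @param markers Marker table for the target cluster: columns `gene`,
#'   `log2fc` (and optionally `adj_p`).
#' @param tumor_vs_normal DEG table restricted to the target cluster
#'   (column `gene` is used).
#' @param exclude Genes to drop after filtering (default none).
#' @param top_n Number of top markers considered (default 10).
#' @return Character vector of selected marker genes (possibly empty,
#'   with a warning).
#' @export
select_mcaf_markers <- function(markers, tumor_vs_normal,
                                exclude = character(), top_n = 10) {
  if (is.null(markers) || nrow(markers) == 0) {
    stop("select_mcaf_markers: empty marker table", call. = FALSE)
  }
  ord <- order(-markers$log2fc, markers$gene)
  top <- utils::head(markers$gene[ord], top_n)
  kept <- top[top %in% unique(tumor_vs_normal$gene)]
  kept <- kept[!kept %in% exclude]
  if (length(kept) == 0) {
    warning("select_mcaf_markers: no markers survive the DEG/exclusion filters")
  }
  kept
}

#' Assemble the combined gene signature
#'
#' Unique union of the top shared-URs and the mCAF marker genes, with
#' per-gene provenance. Genes appearing in both lists are kept once with
#' provenance `top_shared_ur` (and a warning).
#'
#' @param top_urs Nonempty character vector of top shared-UR symbols.
#' @param mcaf_markers Nonempty character vector of mCAF marker symbols.
#' @return An object of class `signature_set`: data frame `gene`,
#'   `provenance` (`top_shared_ur` / `mcaf_marker`).
#' @export
assemble_signature <- function(top_urs, mcaf_markers) {
  top_urs <- unique(as.character(top_urs))
  mcaf_markers <- unique(as.character(mcaf_markers))
  if (length(top_urs) == 0 || length(mcaf_markers) == 0) {
    stop("assemble_signature: both gene lists must be nonempty",
         call. = FALSE)
  }
  overlap <- intersect(top_urs, mcaf_markers)
  if (length(overlap)) {
    warning("assemble_signature: gene(s) in both lists kept once as ",
            "top_shared_ur: ", paste(overlap, collapse = ", "))
  }
  out <- data.frame(
    gene = c(top_urs, setdiff(mcaf_markers, top_urs)),
    provenance = c(rep("top_shared_ur", length(top_urs)),
                   rep("mcaf_marker", length(setdiff(mcaf_markers, top_urs)))),
    stringsAsFactors = FALSE)
  class(out) <- c("signature_set", "data.frame")
  out
}

#' Write a signature as GMT and as a provenance TSV
#'
#' @param sig A `signature_set`.
#' @param prefix Path prefix; writes `<prefix>.gmt` and `<prefix>.tsv`.
#' @return Invisibly, the written paths.
#' @export
write_signature <- function(sig, prefix) {
  stopifnot(inherits(sig, "signature_set"))
  p1 <- paste0(prefix, ".gmt")
  p2 <- paste0(prefix, ".tsv")
  write_gmt(list(signature = sig$gene), p1,
            descriptions = "shared-MCTM derived gene signature")
  write_tsv(as.data.frame(sig), p2)
  invisible(c(p1, p2))
}
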