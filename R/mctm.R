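#' Build a multicellular tumor model graph from CCI records
#'
#' Collapses a cancer's CCI records into a directed cell-type graph: nodes
#' are the cell types that appear as sender or receiver, edges carry the
#' number of distinct (ligand, target) interactions between the pair, and
#' the model's gene set is the union of all URs (ligands) and DSs
#' (targets). Duplicate (sender, ligand, receiver, target) records are
#' deduplicated before counting.
#'
#' @param cci CCI data frame from [infer_cci_for_cancer()].
#' @return An object of class `mctm`: list with `cancer`, `nodes`,
#'   `edges` (data frame `sender`, `receiver`, `weight`) and `mctm_genes`.
#' @export
build_mctm <- function(cci) {
  if (is.null(cci) || nrow(cci) == 0) {
    warning("build_mctm: empty CCI set; returning empty graph")
    return(structure(list(cancer = NA_character_, nodes = character(),
                          edges = data.frame(sender = character(),
                                             receiver = character(),
                                             weight = integer(),
                                             stringsAsFactors = FALSE),
                          mctm_genes = character()),
                     class = "mctm"))
  }
  uniq <- unique(cci[, c("sender", "ligand", "receiver", "target")])
  counts <- stats::aggregate(list(weight = rep(1L, nrow(uniq))),
                             by = uniq[, c("sender", "receiver")],
                             FUN = sum)
  counts <- counts[order(counts$sender, counts$receiver), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(
    cancer = cci$cancer[1],
    nodes = sort(unique(c(uniq$sender, uniq$receiver))),
    edges = counts,
    mctm_genes = sort(unique(c(uniq$ligand, uniq$target)))
  ), class = "mctm")
}

#' @export
print.mctm <- function(x, ...) {
  cat(sprintf("<mctm> %s: %d cell types, %d edges, %d genes\n",
              x$cancer, length(x$nodes), nrow(x$edges),
              length(x$mctm_genes)))
  invisible(x)
}

#' Export an MCTM as an edge list and GraphML
#'
#' @param x An `mctm` object.
#' @param prefix Path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @return Invisibly, the written paths.
#' @export
write_mctm <- function(x, prefix) {
  stopifnot(inherits(x, "mctm"))
  p1 <- paste0(prefix, "_edges.tsv")
  write_tsv(x$edges, p1)
  p2 <- paste0(prefix, ".graphml")
  g <- igraph::graph_from_data_frame(
    x$edges[, c("sender", "receiver", "weight")],
    directed = TRUE,
    vertices = data.frame(name = x$nodes))
  igraph::write_graph(g, p2, format = "graphml")
  invisible(c(p1, p2))
}

#' Fisher's exact enrichment of a gene set against a trait set
#'
#' Two-sided Fisher's exact test on the 2x2 contingency of membership in
#' the query vs the trait gene set within a background universe (the test
#' used for GWAS-gene enrichment of MCTM genes, with all DEGs of the cell
#' type/cancer as background). Trait genes outside the background are
#' intersected away before tabulation.
#'
#' @param query Gene set to test; must be a nonempty subset of
#'   `background`.
#' @param trait_genes Trait-associated gene set (may extend outside the
#'   background).
#' @param background Background gene universe (nonempty).
#' @return One-row data frame: `n_overlap`, `odds_ratio` (conditional
#'   MLE), `p`.
#' @export
fisher_enrichment <- function(query, trait_genes, background) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(query) == 0) stop("fisher_enrichment: empty query", call. = FALSE)
  if (length(background) == 0) {
    stop("fisher_enrichment: empty background", call. = FALSE)
  }
  if (!all(query %in% background)) {
    stop("fisher_enrichment: query must be a subset of background",
         call. = FALSE)
  }
  trait <- intersect(unique(as.character(trait_genes)), background)
  a <- length(intersect(query, trait))
  b <- length(query) - a
  cc <- length(trait) - a
  d <- length(background) - a - b - cc
  ft <- fisher_test_2x2(a, b, cc, d)
  data.frame(n_overlap = a, odds_ratio = ft$odds_ratio, p = ft$p)
}

# two-sided exact test on counts (a, b) / (c, d); shared by the gene-set
# wrapper above and usable directly on tabulated counts
fisher_test_2x2 <- function(a, b, c, d) {
  ft <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2),
                           alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Batch enrichment over multiple trait sets with BH adjustment
#'
#' @param query Query gene set (subset of `background`).
#' @param trait_sets Named list of trait gene sets (e.g. from
#'   [read_gmt()]).
#' @param background Background gene universe.
#' @return Data frame with one row per trait set: `trait`, `n_overlap`,
#'   `odds_ratio`, `p`, `adj_p` (Benjamini-Hochberg across the batch).
#' @export
fisher_enrichment_batch <- function(query, trait_sets, background) {
  stopifnot(is.list(trait_sets), !is.null(names(trait_sets)))
  rows <- lapply(names(trait_sets), function(nm) {
    res <- fisher_enrichment(query, trait_sets[[nm]], background)
    cbind(data.frame(trait = nm, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
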