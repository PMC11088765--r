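#' Upstream regulators present in every cancer
#'
#' Step one of the consensus rules: the strict intersection of the
#' per-cancer UR (ligand) sets. A UR present in four of five cancers is
#' excluded.
#'
#' @param cci_sets List (length >= 2) of per-cancer CCI data frames.
#' @return Sorted character vector of universal UR symbols.
#' @export
universal_urs <- function(cci_sets) {
  stopifnot(is.list(cci_sets), length(cci_sets) >= 2)
  sets <- lapply(cci_sets, function(x) unique(x$ligand))
  sort(Reduce(intersect, sets))
}

#' Cross-cancer direction concordance of a gene's expression change
#'
#' For each cell type in which the gene is a DEG, counts the cancers with
#' positive and with negative log2FC (a log2FC of exactly 0 counts toward
#' neither sign; cancers lacking the gene as a DEG in that cell type
#' contribute to neither count). Cell types where the majority sign
#' reaches `min_concordant` cancers are reported; an exact positive /
#' negative tie has no majority and is not reported.
#'
#' @param gene A single gene symbol.
#' @param deg_tables List of per-cancer DEG tables.
#' @param min_concordant Minimum concordant cancers (default 4, i.e. the
#'   at-least-four-of-five rule).
#' @return Data frame `cell_type`, `sign` (+1/-1), `n_concordant`; empty
#'   if the gene qualifies nowhere.
#' @export
direction_concordance <- function(gene, deg_tables, min_concordant = 4) {
  stopifnot(length(gene) == 1, min_concordant >= 2)
  rows <- lapply(deg_tables, function(tab) {
    tab[tab$gene == gene, c("cell_type", "log2fc"), drop = FALSE]
  })
  rows <- do.call(rbind, rows)
  empty <- data.frame(cell_type = character(), sign = integer(),
                      n_concordant = integer(), stringsAsFactors = FALSE)
  if (is.null(rows) || nrow(rows) == 0) return(empty)
  out <- empty
  for (ct in sort(unique(rows$cell_type))) {
    fc <- rows$log2fc[rows$cell_type == ct]
    npos <- sum(fc > 0)
    nneg <- sum(fc < 0)
    if (max(npos, nneg) >= min_concordant && npos != nneg) {
      out <- rbind(out, data.frame(
        cell_type = ct,
        sign = if (npos > nneg) 1L else -1L,
        n_concordant = max(npos, nneg),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Build the shared multicellular tumor model
#'
#' Applies the four consensus steps across cancers: (1) URs present in
#' every cancer's CCI set; (2) of those, the (gene, cell type) pairs whose
#' direction of expression change agrees in at least `min_concordant`
#' cancers become shared-URs; (3) targets present as DSs in every cancer
#' and linked to at least one shared-UR in at least `ds_link_min_cancers`
#' cancers are filtered by the same concordance rule to give shared-DSs;
#' (4) each shared-UR (in its recorded cell type) is connected to every
#' downstream cell type holding at least one of its shared-DSs, the edge
#' weighted by the number of such shared-DS genes.
#'
#' A gene may qualify in more than one cell type (all qualifying pairs are
#' kept), and a gene may appear in both the shared-UR and shared-DS roles;
#' the gene union counts it once.
#'
#' @param cci_sets List (length >= 2) of per-cancer CCI data frames.
#' @param deg_tables List of per-cancer DEG tables (same cancers).
#' @param min_concordant Concordance threshold (default 4).
#' @param ds_link_min_cancers Minimum number of cancers in which a
#'   candidate shared-DS must be linked to a shared-UR (default 1).
#' @param match_sender_cell_type If `TRUE` (default) an edge from a
#'   shared-UR requires CCI records whose sender cell type equals the
#'   UR's recorded (concordant) cell type.
#' @return An object of class `shared_mctm`: `shared_urs` and
#'   `shared_dss` data frames (`gene`, `cell_type`, `sign`,
#'   `n_concordant`), `edges` (`ur`, `ur_cell_type`, `ds_cell_type`,
#'   `n_shared_ds`), `genes` (the deduplicated union) and `cancers`.
#' @export
build_shared_mctm <- function(cci_sets, deg_tables, min_concordant = 4,
                              ds_link_min_cancers = 1,
                              match_sender_cell_type = TRUE) {
  if (!is.list(cci_sets) || length(cci_sets) < 2) {
    stop("build_shared_mctm: need CCI sets from >= 2 cancers ",
         "(consensus undefined for a single cancer)", call. = FALSE)
  }
  stopifnot(length(deg_tables) == length(cci_sets))
  nonempty <- vapply(cci_sets, nrow, integer(1)) > 0
  if (!all(nonempty)) {
    stop("build_shared_mctm: every cancer must have a nonempty CCI set",
         call. = FALSE)
  }

  empty_tab <- data.frame(gene = character(), cell_type = character(),
                          sign = integer(), n_concordant = integer(),
                          stringsAsFactors = FALSE)
  empty_edges <- data.frame(ur = character(), ur_cell_type = character(),
                            ds_cell_type = character(),
                            n_shared_ds = integer(), stringsAsFactors = FALSE)
  cancers <- names(cci_sets)
  if (is.null(cancers)) cancers <- as.character(seq_along(cci_sets))

  finish <- function(urs, dss, edges) {
    structure(list(shared_urs = urs, shared_dss = dss, edges = edges,
                   genes = sort(unique(c(urs$gene, dss$gene))),
                   cancers = cancers,
                   params = list(min_concordant = min_concordant,
                                 ds_link_min_cancers = ds_link_min_cancers,
                                 match_sender_cell_type = match_sender_cell_type)),
              class = "shared_mctm")
  }

  # steps (1) + (2): universal URs with direction concordance
  ur_univ <- universal_urs(cci_sets)
  shared_urs <- empty_tab
  for (g in ur_univ) {
    conc <- direction_concordance(g, deg_tables, min_concordant)
    if (nrow(conc)) {
      shared_urs <- rbind(shared_urs,
                          cbind(data.frame(gene = g,
                                           stringsAsFactors = FALSE), conc))
    }
  }
  if (nrow(shared_urs) == 0) {
    warning("build_shared_mctm: no shared-URs survive; empty model")
    return(finish(empty_tab, empty_tab, empty_edges))
  }
  rownames(shared_urs) <- NULL
  ur_genes <- unique(shared_urs$gene)

  # step (3): shared-DS candidates, then the same concordance filter
  ds_univ <- sort(Reduce(intersect,
                         lapply(cci_sets, function(x) unique(x$target))))
  linked_n <- vapply(ds_univ, function(tg) {
    sum(vapply(cci_sets, function(x) {
      any(x$target == tg & x$ligand %in% ur_genes)
    }, logical(1)))
  }, integer(1))
  candidates <- ds_univ[linked_n >= ds_link_min_cancers]
  shared_dss <- empty_tab
  for (g in candidates) {
    conc <- direction_concordance(g, deg_tables, min_concordant)
    if (nrow(conc)) {
      shared_dss <- rbind(shared_dss,
                          cbind(data.frame(gene = g,
                                           stringsAsFactors = FALSE), conc))
    }
  }
  rownames(shared_dss) <- NULL

  # step (4): UR -> downstream cell-type edges, count of shared-DS genes
  all_cci <- do.call(rbind, cci_sets)
  edges <- empty_edges
  for (i in seq_len(nrow(shared_urs))) {
    ur <- shared_urs$gene[i]
    ur_ct <- shared_urs$cell_type[i]
    recs <- all_cci[all_cci$ligand == ur, , drop = FALSE]
    if (match_sender_cell_type) {
      recs <- recs[recs$sender == ur_ct, , drop = FALSE]
    }
    if (nrow(recs) == 0) next
    for (ds_ct in sort(unique(shared_dss$cell_type))) {
      ds_genes <- shared_dss$gene[shared_dss$cell_type == ds_ct]
      hit <- unique(recs$target[recs$receiver == ds_ct &
                                  recs$target %in% ds_genes])
      if (length(hit) >= 1) {
        edges <- rbind(edges, data.frame(
          ur = ur, ur_cell_type = ur_ct, ds_cell_type = ds_ct,
          n_shared_ds = length(hit), stringsAsFactors = FALSE))
      }
    }
  }
  rownames(edges) <- NULL
  finish(shared_urs, shared_dss, edges)
}

#' @export
print.shared_mctm <- function(x, ...) {
  n_both <- length(intersect(x$shared_urs$gene, x$shared_dss$gene))
  cat(sprintf(paste0("<shared_mctm> %d genes (%d shared-URs, %d shared-DSs,",
                     " %d in both roles), %d edges, %d cancers\n"),
              length(x$genes), length(unique(x$shared_urs$gene)),
              length(unique(x$shared_dss$gene)), n_both, nrow(x$edges),
              length(x$cancers)))
  invisible(x)
}

#' Serialize a shared-MCTM
#'
#' Writes `<prefix>_genes.tsv` (both roles, long form),
#' `<prefix>_edges.tsv` (figure-ready edge list for circular layouts) and
#' `<prefix>_summary.json`.
#'
#' @param x A `shared_mctm` object.
#' @param prefix Path prefix.
#' @return Invisibly, the written paths.
#' @export
write_shared_mctm <- function(x, prefix) {
  stopifnot(inherits(x, "shared_mctm"))
  genes <- rbind(
    cbind(x$shared_urs, role = rep("shared_ur", nrow(x$shared_urs))),
    cbind(x$shared_dss, role = rep("shared_ds", nrow(x$shared_dss))))
  p1 <- paste0(prefix, "_genes.tsv")
  p2 <- paste0(prefix, "_edges.tsv")
  p3 <- paste0(prefix, "_summary.json")
  write_tsv(genes, p1)
  write_tsv(x$edges, p2)
  summary <- list(
    n_genes = length(x$genes),
    n_shared_urs = length(unique(x$shared_urs$gene)),
    n_shared_dss = length(unique(x$shared_dss$gene)),
    n_role_overlap = length(intersect(x$shared_urs$gene, x$shared_dss$gene)),
    n_edges = nrow(x$edges),
    cancers = x$cancers,
    params = x$params)
  jsonlite::write_json(summary, p3, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
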