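#' Rank candidate ligands by prior-vs-DEG correlation
#'
#' Simplified ligand-activity inference: each candidate sender ligand is
#' scored by the Pearson correlation, across a background gene universe,
#' between its regulatory-potential weights in the prior and the 0/1
#' indicator of membership in the receiver cell type's DEG set. A ligand
#' whose prior weights concentrate on the receiver's DEGs scores high.
#' Background genes absent from the prior's columns contribute weight 0
#' (no known regulatory potential).
#'
#' @param prior Ligand x gene regulatory-potential matrix (nonnegative).
#' @param receiver_degs Character vector of receiver DEG symbols; must be
#'   a subset of `background`.
#' @param background Character vector of background gene symbols; must
#'   contain both members and non-members of `receiver_degs`.
#' @param candidate_ligands Character vector of ligands to score; must all
#'   be rows of `prior`.
#' @return Data frame with columns `ligand`, `activity`, sorted by
#'   decreasing activity with ties (and `NA` activities, from ligands with
#'   constant weights over the background) last, tie-broken by symbol.
#' @export
ligand_activities <- function(prior, receiver_degs, background,
                              candidate_ligands) {
  background <- unique(as.character(background))
  receiver_degs <- unique(as.character(receiver_degs))
  candidate_ligands <- unique(as.character(candidate_ligands))
  if (length(background) < 2) {
    stop("ligand_activities: background must contain >= 2 genes",
         call. = FALSE)
  }
  if (!all(receiver_degs %in% background)) {
    stop("ligand_activities: receiver_degs must be a subset of background",
         call. = FALSE)
  }
  missing_lig <- setdiff(candidate_ligands, rownames(prior))
  if (length(missing_lig)) {
    stop("ligand_activities: ligands absent from prior: ",
         paste(missing_lig, collapse = ", "), call. = FALSE)
  }
  ind <- as.numeric(background %in% receiver_degs)
  if (all(ind == 1) || all(ind == 0)) {
    stop("ligand_activities: degenerate background (all genes in, or none in, ",
         "the receiver DEG set); correlation undefined", call. = FALSE)
  }
  col_idx <- match(background, colnames(prior))
  in_prior <- !is.na(col_idx)
  activity <- vapply(candidate_ligands, function(lig) {
    w <- numeric(length(background))
    w[in_prior] <- prior[lig, col_idx[in_prior]]
    if (stats::sd(w) == 0) return(NA_real_)
    stats::cor(w, ind)
  }, numeric(1))
  out <- data.frame(ligand = candidate_ligands, activity = activity,
                    stringsAsFactors = FALSE)
  out <- out[order(-xtfrm(out$activity), out$ligand, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a ligand's top weighted targets among receiver DEGs
#'
#' @param prior Ligand x gene regulatory-potential matrix.
#' @param ligand A single ligand symbol present in `prior`.
#' @param receiver_degs Receiver DEG symbols.
#' @param top_k Maximum number of targets to return.
#' @return Data frame `target`, `weight`: the up-to-`top_k` receiver DEGs
#'   with the highest strictly positive prior weight for `ligand`, sorted
#'   by decreasing weight with ties broken by symbol.
#' @export
ligand_target_links <- function(prior, ligand, receiver_degs, top_k = 200) {
  stopifnot(length(ligand) == 1, top_k >= 1)
  if (!ligand %in% rownames(prior)) {
    stop("ligand_target_links: ligand not in prior: ", ligand, call. = FALSE)
  }
  targets <- intersect(unique(as.character(receiver_degs)), colnames(prior))
  w <- prior[ligand, targets]
  keep <- w > 0
  targets <- targets[keep]
  w <- w[keep]
  ord <- order(-w, targets)
  take <- utils::head(ord, top_k)
  data.frame(target = targets[take], weight = unname(w[take]),
             stringsAsFactors = FALSE)
}

#' Infer cell-cell interactions for one cancer
#'
#' For every ordered pair of distinct cell types in the cancer's DEG
#' table, candidate ligands (the sender's DEGs that are rows of the prior,
#' any direction of change) are ranked by [ligand_activities()] against
#' the receiver's DEG set; the `top_n` ligands are retained and each
#' contributes its [ligand_target_links()] (up to `top_k` targets). The
#' background defaults to the union of all genes in the cancer's DEG
#' tables, so it contains receiver DEGs and non-DEGs alike.
#'
#' @param degs DEG table for one cancer (columns `cancer`, `cell_type`,
#'   `gene`, `log2fc`, `adj_p`).
#' @param prior Ligand x gene regulatory-potential matrix.
#' @param top_n Ligands retained per (sender, receiver) pair.
#' @param top_k Targets retained per ligand.
#' @param background Optional background gene universe; defaults to all
#'   genes in `degs`.
#' @return Data frame of CCI records: `cancer`, `sender`, `ligand`,
#'   `receiver`, `target`, `weight`, `activity`. Directed: (A to B) and
#'   (B to A) are distinct records.
#' @export
infer_cci_for_cancer <- function(degs, prior, top_n = 20, top_k = 200,
                                 background = NULL) {
  empty <- data.frame(cancer = character(), sender = character(),
                      ligand = character(), receiver = character(),
                      target = character(), weight = numeric(),
                      activity = numeric(), stringsAsFactors = FALSE)
  if (nrow(degs) == 0) return(empty)
  cell_types <- sort(unique(degs$cell_type))
  if (length(cell_types) < 2) {
    warning("infer_cci_for_cancer: fewer than 2 cell types; empty CCI set")
    return(empty)
  }
  if (is.null(background)) background <- sort(unique(degs$gene))
  cancer_label <- degs$cancer[1]
  rows <- list()
  for (sender in cell_types) {
    sender_degs <- unique(degs$gene[degs$cell_type == sender])
    candidates <- intersect(sender_degs, rownames(prior))
    if (length(candidates) == 0) next
    for (receiver in setdiff(cell_types, sender)) {
      receiver_degs <- unique(degs$gene[degs$cell_type == receiver])
      if (length(receiver_degs) == 0) next
      if (all(background %in% receiver_degs)) {
        warning(sprintf(
          "infer_cci_for_cancer: degenerate background for receiver '%s'; pair skipped",
          receiver))
        next
      }
      acts <- ligand_activities(prior, receiver_degs, background, candidates)
      acts <- acts[!is.na(acts$activity), , drop = FALSE]
      acts <- utils::head(acts, top_n)
      for (i in seq_len(nrow(acts))) {
        links <- ligand_target_links(prior, acts$ligand[i], receiver_degs,
                                     top_k)
        if (nrow(links) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          cancer = cancer_label, sender = sender, ligand = acts$ligand[i],
          receiver = receiver, target = links$target, weight = links$weight,
          activity = acts$activity[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
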