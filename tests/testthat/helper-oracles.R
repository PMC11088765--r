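# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately re-derive every quantity with naive
# nested loops / enumeration and share no code with the package.

# --- consensus: nested-loop shared-MCTM ------------------------------------

oracle_concordance <- function(gene, deg_tables, min_concordant) {
  cts <- sort(unique(unlist(lapply(deg_tables, function(t) t$cell_type))))
  rows <- list()
  for (ct in cts) {
    npos <- 0L
    nneg <- 0L
    for (tab in deg_tables) {
      fc <- tab$log2fc[tab$gene == gene & tab$cell_type == ct]
      if (length(fc) == 1) {
        if (fc > 0) npos <- npos + 1L
        if (fc < 0) nneg <- nneg + 1L
      }
    }
    if (npos >= min_concordant && npos > nneg) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, sign = 1L, n_concordant = npos,
        stringsAsFactors = FALSE)
    } else if (nneg >= min_concordant && nneg > npos) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, sign = -1L, n_concordant = nneg,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(cell_type = character(), sign = integer(),
                      n_concordant = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

oracle_shared_mctm <- function(cci_sets, deg_tables, min_concordant = 4,
                               ds_link_min_cancers = 1) {
  genes <- sort(unique(unlist(lapply(deg_tables, function(t) t$gene))))
  concord_table <- function(candidates) {
    rows <- list()
    for (g in candidates) {
      conc <- oracle_concordance(g, deg_tables, min_concordant)
      for (r in seq_len(nrow(conc))) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, cell_type = conc$cell_type[r], sign = conc$sign[r],
          n_concordant = conc$n_concordant[r], stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0) {
      return(data.frame(gene = character(), cell_type = character(),
                        sign = integer(), n_concordant = integer(),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, rows)
  }

  ur_univ <- character()
  for (g in genes) {
    if (all(vapply(cci_sets, function(x) g %in% x$ligand, logical(1)))) {
      ur_univ <- c(ur_univ, g)
    }
  }
  shared_urs <- concord_table(ur_univ)
  ur_genes <- unique(shared_urs$gene)

  ds_cand <- character()
  for (g in genes) {
    in_all <- all(vapply(cci_sets, function(x) g %in% x$target, logical(1)))
    if (!in_all) next
    n_linked <- 0L
    for (x in cci_sets) {
      if (any(x$target == g & x$ligand %in% ur_genes)) n_linked <- n_linked + 1L
    }
    if (n_linked >= ds_link_min_cancers) ds_cand <- c(ds_cand, g)
  }
  shared_dss <- concord_table(ds_cand)

  edges <- list()
  for (r in seq_len(nrow(shared_urs))) {
    ur <- shared_urs$gene[r]
    ur_ct <- shared_urs$cell_type[r]
    for (ds_ct in sort(unique(shared_dss$cell_type))) {
      hits <- character()
      for (x in cci_sets) {
        for (i in seq_len(nrow(x))) {
          if (x$ligand[i] == ur && x$sender[i] == ur_ct &&
              x$receiver[i] == ds_ct) {
            tg <- x$target[i]
            ok <- any(shared_dss$gene == tg & shared_dss$cell_type == ds_ct)
            if (ok) hits <- union(hits, tg)
          }
        }
      }
      if (length(hits) >= 1) {
        edges[[length(edges) + 1L]] <- data.frame(
          ur = ur, ur_cell_type = ur_ct, ds_cell_type = ds_ct,
          n_shared_ds = length(hits), stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(ur = character(), ur_cell_type = character(),
               ds_cell_type = character(), n_shared_ds = integer(),
               stringsAsFactors = FALSE)
  list(shared_urs = shared_urs, shared_dss = shared_dss, edges = edges)
}

canon <- function(df) {
  df <- as.data.frame(df)
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- random toy instances for the consensus equivalence suite ---------------

random_consensus_instance <- function(n_cancers = 5, n_cell_types = 6,
                                      n_genes = 50, p_deg = 0.15) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  cts <- paste0("ct", seq_len(n_cell_types))
  deg_tables <- list()
  cci_sets <- list()
  for (k in seq_len(n_cancers)) {
    grid <- expand.grid(gene = genes, cell_type = cts,
                        stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < p_deg
    tab <- grid[keep, , drop = FALSE]
    if (nrow(tab) < 4) tab <- grid[sample.int(nrow(grid), 4), , drop = FALSE]
    tab$cancer <- sprintf("c%d", k)
    tab$log2fc <- sample(c(-1, 1), nrow(tab), TRUE) * runif(nrow(tab), 0.3, 2)
    tab$adj_p <- runif(nrow(tab), 0, 0.04)
    rownames(tab) <- NULL
    deg_tables[[sprintf("c%d", k)]] <- tab

    n_rec <- 40
    rows <- list()
    for (i in seq_len(n_rec)) {
      r <- tab[sample.int(nrow(tab), 1), ]
      recv <- tab[tab$cell_type != r$cell_type, , drop = FALSE]
      if (nrow(recv) == 0) next
      t2 <- recv[sample.int(nrow(recv), 1), ]
      rows[[length(rows) + 1L]] <- data.frame(
        cancer = sprintf("c%d", k), sender = r$cell_type, ligand = r$gene,
        receiver = t2$cell_type, target = t2$gene,
        weight = runif(1, 0.1, 1), activity = runif(1, -1, 1),
        stringsAsFactors = FALSE)
    }
    cci_sets[[sprintf("c%d", k)]] <- unique(do.call(rbind, rows))
  }
  list(cci_sets = cci_sets, deg_tables = deg_tables)
}

# --- agglomerative clustering: naive merge loop -----------------------------

oracle_agglom2 <- function(m, linkage = "complete") {
  n <- nrow(m)
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > 2) {
    best_i <- NA
    best_j <- NA
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        ld <- switch(linkage, complete = max(dd), single = min(dd),
                     average = mean(dd))
        if (ld < best_d) {
          best_d <- ld
          best_i <- i
          best_j <- j
        }
      }
    }
    clusters[[best_i]] <- c(clusters[[best_i]], clusters[[best_j]])
    clusters[[best_j]] <- NULL
  }
  membership <- integer(n)
  membership[clusters[[1]]] <- 1L
  membership[clusters[[2]]] <- 2L
  membership
}

same_partition2 <- function(a, b) {
  all(a == b) || all(a == (3L - b))
}

# --- Fisher: two-sided hypergeometric enumeration ---------------------------

oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # size of query
  n_ <- c + d         # outside query
  k <- a + c          # size of trait within background
  x_range <- max(0, k - n_):min(k, m)
  probs <- dhyper(x_range, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- GSVA-style score: explicit step-by-step walk ---------------------------

oracle_gene_set_score <- function(A, sig) {
  n <- nrow(A)
  p <- ncol(A)
  feats <- colnames(A)
  m <- sum(feats %in% sig)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    z <- numeric(p)
    for (f in seq_len(p)) {
      z[f] <- sum(A[, f] <= A[i, f]) / n
    }
    ord <- order(-z, feats)
    walk <- 0
    wmax <- -Inf
    wmin <- Inf
    hit_total <- 0
    for (f in ord) if (feats[f] %in% sig) hit_total <- hit_total + z[f]
    for (f in ord) {
      if (feats[f] %in% sig) {
        walk <- walk + z[f] / hit_total
      } else {
        walk <- walk - 1 / (p - m)
      }
      wmax <- max(wmax, walk)
      wmin <- min(wmin, walk)
    }
    scores[i] <- wmax + wmin
  }
  scores
}

# --- Wilcoxon rank-sum: exact enumeration (no ties) -------------------------

oracle_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
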