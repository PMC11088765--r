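#' Generate per-cancer differential-expression tables
#'
#' Emulates the derived per-cancer, per-cell-type DEG tables the pipeline
#' consumes (not raw single-cell data). Planted shared-URs are DEGs in the
#' fibroblast sender in every cancer, carrying the planted (positive) sign
#' in exactly `concordance_cancers` cancers and the opposite sign in the
#' rest; their planted targets behave the same way in the "cancer cell"
#' receiver. Decoy ligands violate the consensus rules in controlled ways
#' (absent from one cancer, or with a near-even sign split), and filler
#' genes are cancer-specific so they can never pass the universality rule.
#' Rows are retained only if `adj_p < 0.05` and `|log2fc| > 0.25`, the same
#' filter applied to real DEG calls.
#'
#' @param cfg A [sim_config()] object.
#' @return A named list (one element per cancer) of data frames with
#'   columns `cancer`, `cell_type`, `gene`, `log2fc`, `adj_p`.
#' @export
generate_deg_tables <- function(cfg) {
  validate_sim_config(cfg)
  lay <- sim_layout(cfg)
  out <- vector("list", cfg$n_cancers)
  names(out) <- lay$cancers

  for (ci in seq_len(cfg$n_cancers)) {
    set.seed(child_seed(cfg$seed, ci))
    gene <- character()
    cell_type <- character()
    sign <- numeric()

    add <- function(g, ct, s) {
      gene <<- c(gene, g)
      cell_type <<- c(cell_type, ct)
      sign <<- c(sign, s)
    }

    concordant <- ci <= cfg$concordance_cancers
    # planted URs: fibroblast DEG in every cancer, planted sign (+) in the
    # first `concordance_cancers` cancers, flipped in the remainder
    for (g in lay$planted_urs) {
      add(g, lay$sender_cell_type, if (concordant) 1 else -1)
    }
    # planted DSs: same schedule in the receiver cell type
    for (g in lay$planted_ds) {
      add(g, lay$receiver_cell_type, if (concordant) 1 else -1)
    }
    # dropout decoys: absent from their assigned cancer
    for (d in seq_along(lay$decoy_dropout)) {
      if (lay$dropout_cancer[d] != ci) {
        add(lay$decoy_dropout[d], lay$sender_cell_type, 1)
      }
    }
    # signflip decoys: present everywhere, discordant signs
    for (d in seq_along(lay$decoy_signflip)) {
      s <- if (ci %in% lay$flip_cancers[[d]]) -1 else 1
      add(lay$decoy_signflip[d], lay$sender_cell_type, s)
    }
    # decoy DSs: present everywhere in the receiver, near-even sign split
    for (g in lay$decoy_ds) {
      add(g, lay$receiver_cell_type, if (ci %in% lay$decoy_ds_neg) -1 else 1)
    }
    # background ligands: DEG in exactly one cancer
    bg <- lay$background_ligands[lay$bg_ligand_cancer == ci]
    for (g in bg) add(g, lay$sender_cell_type, sample(c(-1, 1), 1))
    # filler genes: cancer-specific, spread over cell types, random sign
    keep <- lay$filler_cancer == ci
    fg <- lay$fillers[keep]
    fct <- lay$filler_cell_type[keep]
    if (length(fg)) {
      fs <- sample(c(-1, 1), length(fg), replace = TRUE)
      gene <- c(gene, fg)
      cell_type <- c(cell_type, fct)
      sign <- c(sign, fs)
    }

    n <- length(gene)
    tab <- data.frame(
      cancer = lay$cancers[ci],
      cell_type = cell_type,
      gene = gene,
      log2fc = sign * cfg$log2fc_effect * stats::runif(n, 0.9, 1.1),
      adj_p = stats::runif(n, 0, cfg$deg_adj_p),
      stringsAsFactors = FALSE
    )
    # retention filter applied to real DEG calls
    tab <- tab[tab$adj_p < 0.05 & abs(tab$log2fc) > 0.25, , drop = FALSE]
    rownames(tab) <- NULL
    out[[ci]] <- tab
  }
  out
}

#' Generate a ligand-target regulatory-potential prior
#'
#' Nonnegative ligand x gene matrix standing in for a curated regulatory
#' prior. Background entries are sparse i.i.d. gamma noise (a fraction of
#' entries is exactly zero, as in curated ligand-target priors where most
#' pairs have no documented support); planted ligand-target pairs (each
#' planted UR to its planted targets, and to the decoy discordant targets)
#' receive an additive boost of `prior_signal`, so with `prior_signal = 0`
#' planted and background entries are identically distributed.
#'
#' @param cfg A [sim_config()] object.
#' @return A numeric matrix with ligand rownames and gene colnames.
#' @export
generate_prior <- function(cfg) {
  validate_sim_config(cfg)
  lay <- sim_layout(cfg)
  set.seed(child_seed(cfg$seed, cfg$n_cancers + 1L))
  n_entries <- cfg$n_ligands * cfg$n_genes
  w <- matrix(stats::rgamma(n_entries, shape = 1, rate = 4) *
                stats::rbinom(n_entries, 1, 0.6),
              nrow = cfg$n_ligands,
              dimnames = list(lay$ligands, lay$genes))
  for (ur in lay$planted_urs) {
    w[ur, lay$ds_of[[ur]]] <- w[ur, lay$ds_of[[ur]]] + cfg$prior_signal
    if (length(lay$decoy_ds)) {
      w[ur, lay$decoy_ds] <- w[ur, lay$decoy_ds] + cfg$prior_signal
    }
  }
  w
}

#' Generate CAF subcluster marker tables
#'
#' Emulates the fibroblast-subcluster inputs of the signature stage: a
#' per-cluster marker table (gene, cluster, log2fc, adj_p giving each
#' cluster's markers against the other clusters) and a tumor-vs-normal DEG
#' table restricted to the matrix-CAF cluster. The matrix-CAF cluster
#' ("CAF_C0") carries ten top markers by construction, of which eight are
#' also tumor-vs-normal DEGs, mirroring a two-step marker selection that
#' keeps eight genes.
#'
#' @param cfg A [sim_config()] object.
#' @param n_clusters Number of fibroblast subclusters (default 4).
#' @return A list with elements `markers` (all clusters) and
#'   `mcaf_tumor_vs_normal` (DEG table for the target cluster), plus the
#'   target cluster label in `mcaf_cluster`.
#' @export
generate_caf_markers <- function(cfg, n_clusters = 4) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, cfg$n_cancers + 2L))
  clusters <- sprintf("CAF_C%d", seq_len(n_clusters) - 1L)
  mcaf <- clusters[1]

  marker_rows <- list()
  for (k in seq_along(clusters)) {
    genes <- sprintf("MK%s_%02d", k - 1L, 1:14)
    marker_rows[[k]] <- data.frame(
      cluster = clusters[k],
      gene = genes,
      log2fc = sort(stats::runif(14, 0.3, 3), decreasing = TRUE),
      adj_p = stats::runif(14, 0, 0.01),
      stringsAsFactors = FALSE
    )
  }
  markers <- do.call(rbind, marker_rows)
  rownames(markers) <- NULL

  # of the ten top mCAF markers, eight are also tumor-vs-normal DEGs
  top10 <- markers$gene[markers$cluster == mcaf][1:10]
  deg_genes <- top10[c(1:4, 6:9)]
  mcaf_deg <- data.frame(
    cancer = "pooled",
    cell_type = mcaf,
    gene = deg_genes,
    log2fc = stats::runif(length(deg_genes), 0.5, 2),
    adj_p = stats::runif(length(deg_genes), 0, 0.01),
    stringsAsFactors = FALSE
  )
  list(markers = markers, mcaf_tumor_vs_normal = mcaf_deg, mcaf_cluster = mcaf)
}

#' Construct a cohort object
#'
#' Light container coupling a samples-by-features abundance matrix to
#' survival time, event indicator, group membership and basic covariates.
#'
#' @param abundance Numeric matrix, samples in rows, features in columns;
#'   `NA` marks missing values.
#' @param samples Data frame with columns `sample`, `group`,
#'   `survival_time`, `event`, `sex`, `age_at_diagnosis`, `cancer_type`,
#'   `sampling_lag`; one row per row of `abundance`.
#' @param assay `"expression"` or `"protein"`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(abundance, samples, assay = c("expression", "protein")) {
  assay <- match.arg(assay)
  stopifnot(is.matrix(abundance), nrow(abundance) == nrow(samples))
  required <- c("sample", "group", "survival_time", "event", "sex",
                "age_at_diagnosis", "cancer_type", "sampling_lag")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("cohort: samples table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(samples$survival_time < 0, na.rm = TRUE)) {
    stop("cohort: survival_time must be >= 0", call. = FALSE)
  }
  if (!all(samples$event %in% c(0L, 1L))) {
    stop("cohort: event must be 0/1", call. = FALSE)
  }
  rownames(abundance) <- samples$sample
  structure(list(abundance = abundance, samples = samples, assay = assay),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples x %d features (%s), %d events\n",
              nrow(x$abundance), ncol(x$abundance), x$assay,
              sum(x$samples$event)))
  invisible(x)
}

#' Subset a cohort by sample
#'
#' @param x A `cohort`.
#' @param idx Logical or integer index over samples.
#' @return The subsetted `cohort`.
#' @export
subset_cohort <- function(x, idx) {
  stopifnot(inherits(x, "cohort"))
  cohort(x$abundance[idx, , drop = FALSE],
         x$samples[idx, , drop = FALSE],
         assay = x$assay)
}

#' Generate a survival cohort with a planted signature effect
#'
#' Two-arm cohort (tumor vs normal, `cohort_n` samples each). Each sample
#' carries a latent signature activity `s` (standard normal, shifted by
#' `group_shift` in the tumor arm); every signature gene equals `s` plus
#' gene-specific Gaussian noise, so both the rank-based score and the mean
#' protein score track `s`. Survival times are exponential with hazard
#' `h0 * exp(beta_score * s + covariate effects)` (proportional hazards by
#' construction, with `h0` set to a five-year median at `s = 0`);
#' independent exponential censoring is calibrated so roughly
#' `censor_rate` of subjects are censored before their event, and
#' everything is administratively censored at 10 years (3652 days). The
#' protein variant adds missing-completely-at-random gaps at
#' `missing_rate`.
#'
#' @param cfg A [sim_config()] object.
#' @param signature Nonempty character vector of signature gene symbols.
#' @param assay `"expression"` (complete matrix) or `"protein"` (MCAR
#'   gaps); the two assays use distinct child seeds and therefore simulate
#'   independent cohorts.
#' @return A [cohort()] object.
#' @export
generate_cohort <- function(cfg, signature,
                            assay = c("expression", "protein")) {
  validate_sim_config(cfg)
  assay <- match.arg(assay)
  signature <- unique(as.character(signature))
  if (length(signature) == 0) {
    stop("generate_cohort: signature must be nonempty", call. = FALSE)
  }
  offset <- if (assay == "expression") 3L else 4L
  set.seed(child_seed(cfg$seed, cfg$n_cancers + offset))

  n <- 2L * cfg$cohort_n
  group <- rep(c("tumor", "normal"), each = cfg$cohort_n)
  s <- stats::rnorm(n) + cfg$group_shift * (group == "tumor")

  features <- c(signature,
                sprintf("BG%03d", seq_len(cfg$n_background_features)))
  abundance <- matrix(NA_real_, n, length(features),
                      dimnames = list(NULL, features))
  for (g in signature) {
    abundance[, g] <- s + stats::rnorm(n, sd = cfg$noise_sd)
  }
  for (g in setdiff(features, signature)) {
    abundance[, g] <- stats::rnorm(n)
  }

  sex <- sample(c("female", "male"), n, replace = TRUE)
  age <- round(stats::rnorm(n, 62, 8), 1)
  cancer_type <- sample(sprintf("cancer%02d", seq_len(cfg$n_cancers)),
                        n, replace = TRUE)
  sampling_lag <- round(stats::rexp(n, 1 / 180))

  h0 <- log(2) / (5 * 365.25)  # five-year median survival at s = 0
  lp <- cfg$beta_score * s + 0.03 * (age - 62) + 0.25 * (sex == "male")
  event_time <- stats::rexp(n, rate = h0 * exp(lp))
  # censoring uniforms drawn unconditionally so the same seed yields the
  # same censoring randomness at every censor_rate (monotone comparisons)
  u_cens <- stats::runif(n)
  if (cfg$censor_rate <= 0) {
    cens_time <- rep(Inf, n)
  } else if (cfg$censor_rate >= 1) {
    cens_time <- rep(0, n)
  } else {
    rate_c <- h0 * cfg$censor_rate / (1 - cfg$censor_rate)
    cens_time <- -log(u_cens) / rate_c
  }
  horizon <- 3652
  time <- pmin(event_time, cens_time, horizon)
  event <- as.integer(event_time <= cens_time & event_time <= horizon)

  samples <- data.frame(
    sample = sprintf("S%04d", seq_len(n)),
    group = group,
    survival_time = round(time, 1),
    event = event,
    sex = sex,
    age_at_diagnosis = age,
    cancer_type = cancer_type,
    sampling_lag = sampling_lag,
    stringsAsFactors = FALSE
  )

  if (assay == "protein" && cfg$missing_rate > 0) {
    mask <- stats::runif(length(abundance)) < cfg$missing_rate
    abundance[mask] <- NA_real_
  }
  cohort(abundance, samples, assay = assay)
}
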