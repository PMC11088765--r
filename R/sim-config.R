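#' Simulation configuration for synthetic pipeline inputs
#'
#' Builds and validates the configuration object consumed by
#' [generate_deg_tables()], [generate_prior()], [generate_cohort()] and
#' [generate_caf_markers()]. The generator plants a known multicellular
#' structure: a set of shared upstream-regulator ligands (shared-URs) that
#' are differentially expressed in a designated sender cell type with a
#' consistent direction of change across `concordance_cancers` cancers,
#' each regulating a block of downstream target genes (shared-DSs) in a
#' designated receiver cell type. Decoy ligands are engineered to fail the
#' consensus rules in controlled ways (absent from one cancer, or
#' sign-discordant in too many cancers), so consensus recovery can be
#' asserted exactly.
#'
#' @param n_cancers Number of simulated cancers (DEG tables). Default 5,
#'   matching a five-cancer design (breast, colon, liver, lung, ovary).
#' @param cell_types Character vector of at least 6 cell-type labels; must
#'   include `"fibroblast"` (the planted sender) and `"cancer cell"` (the
#'   planted receiver).
#' @param n_genes Size of the simulated gene universe (ligands included).
#' @param n_ligands Number of ligand symbols (rows of the prior).
#' @param n_planted_shared_urs Number of planted shared-URs.
#' @param n_planted_ds_per_ur Downstream targets planted per shared-UR.
#' @param n_decoy_dropout Decoy ligands absent from exactly one cancer
#'   (fail the all-cancer universality rule).
#' @param n_decoy_signflip Decoy ligands present in every cancer but
#'   sign-flipped in enough cancers that no direction reaches the
#'   concordance threshold of 4 out of 5.
#' @param n_decoy_ds Decoy downstream targets, linked to planted URs in the
#'   prior and differentially expressed in every cancer, but with
#'   discordant signs (present with a near-even sign split).
#' @param concordance_cancers Number of cancers carrying the planted sign
#'   for planted URs/DSs; in the remaining cancers the gene is still a DEG
#'   but with the opposite sign, so it stays universal. Default 5.
#' @param log2fc_effect Magnitude of planted/background log2 fold changes
#'   (before the |log2FC| > 0.25 retention filter).
#' @param deg_adj_p Upper bound for simulated adjusted p-values; must sit
#'   below the 0.05 retention threshold for planted rows to survive.
#' @param prior_signal Additive weight boost for planted ligand-target
#'   pairs in the regulatory prior; 0 removes the planted signal.
#' @param cohort_n Samples per cohort arm (tumor and normal).
#' @param beta_score True log-hazard per unit of latent signature activity.
#' @param censor_rate Target fraction of follow-up lost to independent
#'   (non-administrative) censoring; 0 disables it, 1 censors everyone at
#'   time zero.
#' @param missing_rate Missing-completely-at-random fraction applied to the
#'   protein variant of the cohort matrix.
#' @param group_shift Mean shift of latent signature activity in the tumor
#'   arm relative to the normal arm (drives cohort-level differential
#'   expression of signature genes).
#' @param noise_sd Gene-specific noise s.d. around the shared latent
#'   activity for signature features.
#' @param n_background_features Non-signature features in generated
#'   cohort matrices.
#' @param seed Global integer seed; per-table child seeds are derived from
#'   it (see Details).
#'
#' @details
#' One global seed fans out to per-table child seeds through a fixed
#' counter scheme: table `i` uses `(seed + 97003 * i) mod (2^31 - 1)`,
#' with counters 1..n_cancers for the DEG tables, then the prior, the
#' marker tables, the expression cohort and the protein cohort in that
#' order. Adding a table therefore never perturbs earlier ones.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_deg_tables()], [generate_prior()], [generate_cohort()]
#' @export
sim_config <- function(n_cancers = 5,
                       cell_types = c("fibroblast", "cancer cell",
                                      "macrophage", "endothelial",
                                      "T cell", "pericyte"),
                       n_genes = 300,
                       n_ligands = 40,
                       n_planted_shared_urs = 3,
                       n_planted_ds_per_ur = 5,
                       n_decoy_dropout = 2,
                       n_decoy_signflip = 2,
                       n_decoy_ds = 4,
                       concordance_cancers = 5,
                       log2fc_effect = 1.5,
                       deg_adj_p = 0.01,
                       prior_signal = 5,
                       cohort_n = 200,
                       beta_score = log(2),
                       censor_rate = 0.3,
                       missing_rate = 0.1,
                       group_shift = 1,
                       noise_sd = 0.5,
                       n_background_features = 40,
                       seed = 1L) {
  cfg <- list(
    n_cancers = as.integer(n_cancers),
    cell_types = as.character(cell_types),
    n_genes = as.integer(n_genes),
    n_ligands = as.integer(n_ligands),
    n_planted_shared_urs = as.integer(n_planted_shared_urs),
    n_planted_ds_per_ur = as.integer(n_planted_ds_per_ur),
    n_decoy_dropout = as.integer(n_decoy_dropout),
    n_decoy_signflip = as.integer(n_decoy_signflip),
    n_decoy_ds = as.integer(n_decoy_ds),
    concordance_cancers = as.integer(concordance_cancers),
    log2fc_effect = as.numeric(log2fc_effect),
    deg_adj_p = as.numeric(deg_adj_p),
    prior_signal = as.numeric(prior_signal),
    cohort_n = as.integer(cohort_n),
    beta_score = as.numeric(beta_score),
    censor_rate = as.numeric(censor_rate),
    missing_rate = as.numeric(missing_rate),
    group_shift = as.numeric(group_shift),
    noise_sd = as.numeric(noise_sd),
    n_background_features = as.integer(n_background_features),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object (or a bare list with the same fields).
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  counts <- c("n_cancers", "n_genes", "n_ligands", "n_planted_shared_urs",
              "n_planted_ds_per_ur", "concordance_cancers", "cohort_n")
  for (f in counts) {
    if (!isTRUE(cfg[[f]] >= 1)) {
      stop("sim_config: `", f, "` must be a positive count", call. = FALSE)
    }
  }
  for (f in c("n_decoy_dropout", "n_decoy_signflip", "n_decoy_ds")) {
    if (!isTRUE(cfg[[f]] >= 0)) {
      stop("sim_config: `", f, "` must be >= 0", call. = FALSE)
    }
  }
  for (f in c("censor_rate", "missing_rate", "deg_adj_p")) {
    if (!isTRUE(cfg[[f]] >= 0 && cfg[[f]] <= 1)) {
      stop("sim_config: `", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$concordance_cancers > cfg$n_cancers) {
    stop("sim_config: `concordance_cancers` cannot exceed `n_cancers`",
         call. = FALSE)
  }
  if (length(cfg$cell_types) < 6) {
    stop("sim_config: need at least 6 cell types", call. = FALSE)
  }
  if (!all(c("fibroblast", "cancer cell") %in% cfg$cell_types)) {
    stop("sim_config: cell_types must include \"fibroblast\" and \"cancer cell\"",
         call. = FALSE)
  }
  n_special <- cfg$n_planted_shared_urs + cfg$n_decoy_dropout +
    cfg$n_decoy_signflip
  if (cfg$n_ligands < n_special + cfg$n_cancers) {
    stop("sim_config: n_ligands too small for planted + decoy + background ligands",
         call. = FALSE)
  }
  n_targets <- cfg$n_planted_shared_urs * cfg$n_planted_ds_per_ur +
    cfg$n_decoy_ds
  if (cfg$n_genes < cfg$n_ligands + n_targets + cfg$n_cancers * 4) {
    stop("sim_config: n_genes too small for ligands + targets + filler genes",
         call. = FALSE)
  }
  invisible(cfg)
}

# Child-seed fan-out: one global seed, documented counter scheme.
# Counter assignments: 1..n_cancers = DEG tables; n_cancers+1 = prior;
# n_cancers+2 = CAF marker tables; n_cancers+3 = expression cohort;
# n_cancers+4 = protein cohort.
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 97003 * as.numeric(counter)) %% 2147483647)
}

# Deterministic symbol layout shared by all generators: which symbols are
# planted URs, decoys, planted/decoy targets and per-cancer filler genes.
# Pure function of cfg; no RNG.
sim_layout <- function(cfg) {
  validate_sim_config(cfg)
  ligands <- sprintf("LG%03d", seq_len(cfg$n_ligands))
  others <- sprintf("GN%04d", seq_len(cfg$n_genes - cfg$n_ligands))

  i <- 0L
  take <- function(pool, n) pool[seq_len(n) + i]
  planted_urs <- ligands[seq_len(cfg$n_planted_shared_urs)]
  i <- cfg$n_planted_shared_urs
  decoy_dropout <- if (cfg$n_decoy_dropout > 0) take(ligands, cfg$n_decoy_dropout) else character()
  i <- i + cfg$n_decoy_dropout
  decoy_signflip <- if (cfg$n_decoy_signflip > 0) take(ligands, cfg$n_decoy_signflip) else character()
  i <- i + cfg$n_decoy_signflip
  background_ligands <- ligands[seq.int(i + 1L, cfg$n_ligands)]

  n_ds <- cfg$n_planted_shared_urs * cfg$n_planted_ds_per_ur
  planted_ds <- others[seq_len(n_ds)]
  ds_of <- split(planted_ds,
                 rep(planted_urs, each = cfg$n_planted_ds_per_ur))[planted_urs]
  j <- n_ds
  decoy_ds <- if (cfg$n_decoy_ds > 0) others[seq_len(cfg$n_decoy_ds) + j] else character()
  j <- j + cfg$n_decoy_ds
  fillers <- others[seq.int(j + 1L, length(others))]

  # fillers and background ligands cycle through cancers so each is a DEG
  # in exactly one cancer (they can never satisfy all-cancer universality)
  filler_cancer <- rep(seq_len(cfg$n_cancers), length.out = length(fillers))
  filler_cell_type <- rep(cfg$cell_types, length.out = length(fillers))
  bg_ligand_cancer <- rep(seq_len(cfg$n_cancers),
                          length.out = length(background_ligands))

  # decoy schedules (deterministic): dropout decoy d is absent from cancer
  # ((d - 1) mod n_cancers) + 1; signflip decoy d is negative in two
  # consecutive cancers starting at d (mod n), positive elsewhere, which
  # caps either sign at n_cancers - 2 concordant cancers
  dropout_cancer <- if (cfg$n_decoy_dropout > 0) {
    ((seq_len(cfg$n_decoy_dropout) - 1L) %% cfg$n_cancers) + 1L
  } else integer()
  flip_cancers <- lapply(seq_len(cfg$n_decoy_signflip), function(d) {
    ((d - 1L + 0:1) %% cfg$n_cancers) + 1L
  })
  # decoy targets: near-even sign split so neither sign reaches 4 of 5
  decoy_ds_neg <- seq_len(floor(cfg$n_cancers / 2)) + ceiling(cfg$n_cancers / 2)

  list(
    ligands = ligands,
    genes = c(ligands, others),
    planted_urs = planted_urs,
    decoy_dropout = decoy_dropout,
    decoy_signflip = decoy_signflip,
    background_ligands = background_ligands,
    planted_ds = planted_ds,
    ds_of = ds_of,
    decoy_ds = decoy_ds,
    fillers = fillers,
    filler_cancer = filler_cancer,
    filler_cell_type = filler_cell_type,
    bg_ligand_cancer = bg_ligand_cancer,
    dropout_cancer = dropout_cancer,
    flip_cancers = flip_cancers,
    decoy_ds_neg = decoy_ds_neg,
    sender_cell_type = "fibroblast",
    receiver_cell_type = "cancer cell",
    cancers = sprintf("cancer%02d", seq_len(cfg$n_cancers))
  )
}
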