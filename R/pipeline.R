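#' Run the simulate-infer-consensus-signature-score-survive pipeline
#'
#' End-to-end orchestration of every stage over synthetic inputs: DEG
#' tables and a regulatory prior are generated, per-cancer CCIs inferred,
#' per-cancer MCTMs and the shared-MCTM built, the signature assembled
#' from the prioritized shared-URs plus the matrix-CAF markers, cohorts
#' generated and scored, and survival associations fitted. All artifacts
#' are written under `out_dir` and listed in a manifest with md5 content
#' hashes; a run log records the parameters. The whole run is a pure
#' function of the configuration (including its seed).
#'
#' @param cfg A [sim_config()] object (or a path to a YAML written by
#'   [write_sim_config()]).
#' @param out_dir Output directory.
#' @param top_n,top_k Ligand-activity retention parameters.
#' @param min_concordant Consensus concordance threshold.
#' @param max_missing,k Protein QC/imputation parameters.
#' @param horizon_days Follow-up horizon.
#' @param min_events Per-cancer screen threshold. The synthetic demo
#'   cohorts are modest, so the per-cancer screen will typically retain
#'   only cancers with enough deaths, as intended.
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_pipeline <- function(cfg, out_dir, top_n = 20, top_k = 200,
                         min_concordant = 4, max_missing = 0.20, k = 10,
                         horizon_days = 3652, min_events = 20) {
  if (is.character(cfg)) {
    if (!file.exists(cfg)) {
      stop("run_pipeline: config file not found: ", cfg, call. = FALSE)
    }
    cfg <- read_sim_config(cfg)
  }
  validate_sim_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("shmctm pipeline run"),
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("shmctm"))),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("params: top_n=%d top_k=%d min_concordant=%d",
                         top_n, top_k, min_concordant))

  # stage 1: simulate
  degs <- generate_deg_tables(cfg)
  prior <- generate_prior(cfg)
  markers <- generate_caf_markers(cfg)
  write_deg_tables(degs, file.path(out_dir, "deg"))
  write_prior(prior, file.path(out_dir, "prior.tsv"))
  write_tsv(markers$markers, file.path(out_dir, "caf_markers.tsv"))
  write_sim_config(cfg, file.path(out_dir, "sim_config.yaml"))

  # stage 2: per-cancer CCI inference + MCTMs
  cci_sets <- lapply(degs, infer_cci_for_cancer, prior = prior,
                     top_n = top_n, top_k = top_k)
  all_cci <- do.call(rbind, cci_sets)
  write_tsv(all_cci, file.path(out_dir, "cci.tsv"))
  for (nm in names(cci_sets)) {
    write_mctm(build_mctm(cci_sets[[nm]]),
               file.path(out_dir, paste0("mctm_", nm)))
  }

  # stage 3: consensus
  shared <- build_shared_mctm(cci_sets, degs, min_concordant = min_concordant)
  write_shared_mctm(shared, file.path(out_dir, "shared_mctm"))
  log_lines <- c(log_lines,
                 sprintf("shared-MCTM: %d genes, %d edges",
                         length(shared$genes), nrow(shared$edges)))

  # stage 4: signature
  icm <- interaction_count_matrix(shared)
  top_urs <- prioritize_urs(icm)
  mcaf <- select_mcaf_markers(
    markers$markers[markers$markers$cluster == markers$mcaf_cluster, ],
    markers$mcaf_tumor_vs_normal, exclude = top_urs)
  sig <- assemble_signature(sub("@.*$", "", top_urs), mcaf)
  write_signature(sig, file.path(out_dir, "signature"))
  log_lines <- c(log_lines,
                 sprintf("signature: %d genes (%d shared-URs, %d mCAF markers)",
                         nrow(sig), sum(sig$provenance == "top_shared_ur"),
                         sum(sig$provenance == "mcaf_marker")))

  # stage 5: cohorts + scoring
  expr <- truncate_followup(generate_cohort(cfg, sig$gene, "expression"),
                            horizon_days)
  prot_raw <- generate_cohort(cfg, sig$gene, "protein")
  prot <- truncate_followup(qc_and_impute(prot_raw, max_missing, k),
                            horizon_days)
  write_cohort(expr, file.path(out_dir, "cohort_expr"))
  write_cohort(prot_raw, file.path(out_dir, "cohort_prot"))
  gscore <- gene_set_score(expr, sig)
  pscore <- protein_score(prot, sig)
  write_scores(gscore, file.path(out_dir, "score_mrna.tsv"))
  write_scores(pscore, file.path(out_dir, "score_protein.tsv"))
  de <- differential_abundance(expr, sig$gene)
  write_tsv(de, file.path(out_dir, "differential_abundance.tsv"))

  # stage 6: survival (patients only)
  patients_e <- subset_cohort(expr, expr$samples$group == "tumor")
  patients_p <- subset_cohort(prot, prot$samples$group == "tumor")
  surv_rows <- rbind(
    cox_association(patients_e, gscore, name = "mrna_score"),
    cox_association(patients_p, pscore, name = "protein_score"))
  for (sx in c("female", "male")) {
    idx <- patients_p$samples$sex == sx
    if (sum(patients_p$samples$event[idx]) >= 2) {
      surv_rows <- rbind(surv_rows,
                         cox_association(patients_p, pscore, subset = idx,
                                         name = paste0("protein_score_", sx)))
    }
  }
  write_tsv(surv_rows, file.path(out_dir, "cox_associations.tsv"))
  screen <- per_cancer_screen(patients_e, gscore, min_events = min_events)
  write_tsv(screen, file.path(out_dir, "per_cancer_screen.tsv"))
  km <- km_logrank(patients_p, pscore, group2 = "sex")
  write_tsv(km$curves, file.path(out_dir, "km_curves.tsv"))
  log_lines <- c(log_lines,
                 sprintf("log-rank (protein level x sex): chisq=%.3f p=%.3g",
                         km$chisq, km$p))

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}
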