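make_cohort <- function(ab, group = NULL, assay = "expression") {
  n <- nrow(ab)
  if (is.null(group)) group <- rep(c("tumor", "normal"), length.out = n)
  samples <- data.frame(
    sample = sprintf("S%03d", seq_len(n)), group = group,
    survival_time = seq(100, 100 * n, 100), event = rep(c(1L, 0L),
                                                        length.out = n),
    sex = rep(c("female", "male"), length.out = n),
    age_at_diagnosis = 60, cancer_type = "ca",
    sampling_lag = 10, stringsAsFactors = FALSE)
  cohort(ab, samples, assay = assay)
}

test_that("missingness QC drops features strictly above the 20% boundary", {
  set.seed(61)
  ab <- matrix(rnorm(100 * 10), 100, 10,
               dimnames = list(NULL, sprintf("p%02d", 1:10)))
  ab[1:21, "p01"] <- NA  # 21% missing: dropped
  ab[1:20, "p02"] <- NA  # exactly 20%: kept
  co <- make_cohort(ab, assay = "protein")
  res <- qc_and_impute(co)
  expect_false("p01" %in% colnames(res$abundance))
  expect_true("p02" %in% colnames(res$abundance))
  expect_false(anyNA(res$abundance))
  # observed values untouched
  obs <- !is.na(ab[, colnames(res$abundance)])
  expect_identical(res$abundance[obs], ab[, colnames(res$abundance)][obs])
})

test_that("KNN imputation uses nearest-neighbor means", {
  # one gap among 11 identical samples: imputed value is the shared value
  ab <- matrix(rep(c(1, 2, 3), each = 11), 11, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  ab[1, "b"] <- NA
  res <- qc_and_impute(make_cohort(ab, assay = "protein"), max_missing = 0.5,
                       k = 10)
  expect_equal(res$abundance[1, "b"], 2)

  # gap filled by the mean of the k nearest samples
  set.seed(67)
  ab2 <- matrix(rnorm(20 * 4), 20, 4,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  ab2[1, "a"] <- NA
  res2 <- qc_and_impute(make_cohort(ab2, assay = "protein"),
                        max_missing = 0.5, k = 3)
  d <- apply(ab2[-1, c("b", "c", "d")], 1,
             function(r) sqrt(mean((r - ab2[1, c("b", "c", "d")])^2)))
  nb <- order(d)[1:3] + 1
  expect_equal(res2$abundance[1, "a"], mean(ab2[nb, "a"]))

  # no missing values: identity
  ab3 <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  co3 <- make_cohort(ab3, assay = "protein")
  expect_identical(qc_and_impute(co3)$abundance, co3$abundance)

  # a fully missing sample is an error
  ab4 <- ab3
  ab4[2, ] <- NA
  expect_error(qc_and_impute(make_cohort(ab4, assay = "protein")),
               "all features missing")
})

test_that("gene-set score equals the step-by-step random-walk oracle", {
  set.seed(71)
  ab <- matrix(rnorm(50), 5, 10,
               dimnames = list(NULL, sprintf("g%02d", 1:10)))
  sig <- c("g01", "g04", "g07")
  res <- gene_set_score(make_cohort(ab), sig)
  expect_equal(res$score, oracle_gene_set_score(ab, sig), tolerance = 1e-12)
  expect_true(all(res$score >= -1 & res$score <= 1))
  expect_equal(res$level, ifelse(res$score > mean(res$score), "high", "low"))
  expect_equal(attr(res, "cutoff"), mean(res$score))
})

test_that("gene-set score is invariant to monotone per-feature transforms", {
  set.seed(73)
  ab <- matrix(rnorm(20 * 12), 20, 12,
               dimnames = list(NULL, sprintf("g%02d", 1:12)))
  sig <- c("g02", "g05", "g09", "g11")
  base <- gene_set_score(make_cohort(ab), sig)$score
  ab2 <- ab
  ab2[, 1:6] <- exp(ab2[, 1:6])          # strictly increasing
  ab2[, 7:12] <- ab2[, 7:12]^3 + 100     # strictly increasing
  expect_equal(gene_set_score(make_cohort(ab2), sig)$score, base)
  # sample permutation equivariance
  perm <- sample(20)
  expect_equal(gene_set_score(make_cohort(ab[perm, , drop = FALSE]),
                              sig)$score, base[perm])
})

test_that("gene-set score separates samples by signature rank position", {
  # signature genes at the top ranks in sample 1, bottom ranks in sample 2
  ab <- rbind(c(10, 9, 8, 1, 2, 3, 4, 5),
              c(1, 2, 3, 10, 9, 8, 7, 6),
              c(5, 5, 5, 5, 5, 5, 5, 4))
  colnames(ab) <- sprintf("g%d", 1:8)
  res <- gene_set_score(make_cohort(ab), c("g1", "g2", "g3"))
  expect_gt(res$score[1], res$score[2])
  expect_error(gene_set_score(make_cohort(ab), c("g1", "zz")),
               "fewer than 2")
})

test_that("protein score is the mean of observed signature proteins", {
  ab <- matrix(c(1, 2, 3,
                 4, 5, 6,
                 7, 8, 9,
                 2, 2, 2), 4, 3, byrow = TRUE,
               dimnames = list(NULL, c("a", "b", "x")))
  co <- make_cohort(ab, assay = "protein")
  res <- protein_score(co, c("a", "b"))
  expect_equal(res$score, c(1.5, 4.5, 7.5, 2))
  # all signature proteins equal c: score = c
  expect_equal(res$score[4], 2)
  # single protein present: score equals that protein
  expect_equal(protein_score(co, c("a", "unseen"))$score, ab[, "a"],
               ignore_attr = TRUE)
  expect_error(protein_score(co, "unseen"), "no signature proteins")
  # missing values excluded pairwise
  ab[1, "a"] <- NA
  expect_equal(protein_score(make_cohort(ab, assay = "protein"),
                             c("a", "b"))$score[1], 2)
  # linearity: adding c to every signature protein shifts scores by c
  expect_equal(protein_score(make_cohort(ab + 5, assay = "protein"),
                             c("a", "b"))$score,
               protein_score(make_cohort(ab, assay = "protein"),
                             c("a", "b"))$score + 5)
})

test_that("differential abundance: wilcoxon p and mean-difference log2FC", {
  # case = control + 1 on the log2 scale: log2FC exactly 1
  ab <- matrix(c(rep(2, 6), rep(1, 6),
                 rep(5, 6), rep(4, 6)), ncol = 2,
               dimnames = list(NULL, c("f1", "f2")))
  co <- make_cohort(ab, group = rep(c("tumor", "normal"), each = 6))
  res <- differential_abundance(co)
  expect_equal(res$log2fc, c(1, 1))

  # identical symmetric distributions: p = 1 exactly
  ab2 <- matrix(c(1, 2, 3, 3, 2, 1), ncol = 1,
                dimnames = list(NULL, "f"))
  co2 <- make_cohort(ab2, group = rep(c("tumor", "normal"), each = 3))
  expect_equal(differential_abundance(co2)$p, 1)

  expect_error(differential_abundance(
    make_cohort(ab, group = rep("tumor", 12))), "nonempty")
})

test_that("wilcoxon p equals exact rank-sum enumeration on 6v6 toys", {
  set.seed(79)
  for (rep in 1:10) {
    a <- round(rnorm(6, 1), 3)
    b <- round(rnorm(6), 3)
    ab <- matrix(c(a, b), ncol = 1, dimnames = list(NULL, "f"))
    co <- make_cohort(ab, group = rep(c("tumor", "normal"), each = 6))
    res <- differential_abundance(co)
    expect_equal(res$p, oracle_wilcox_p(a, b), tolerance = 1e-12)
  }
})

test_that("BH adjustment across features is monotone in raw p", {
  set.seed(83)
  ab <- matrix(rnorm(40 * 8), 40, 8,
               dimnames = list(NULL, sprintf("f%d", 1:8)))
  ab[1:20, 1:2] <- ab[1:20, 1:2] + 2
  co <- make_cohort(ab, group = rep(c("tumor", "normal"), each = 20))
  res <- differential_abundance(co)
  expect_equal(res$adj_p, p.adjust(res$p, "BH"))
  ord <- order(res$p)
  expect_true(all(diff(res$adj_p[ord]) >= -1e-15))
})
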