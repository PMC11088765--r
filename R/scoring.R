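#' Missingness QC and K-nearest-neighbor imputation
#'
#' Drops features missing in more than `max_missing` of samples (the
#' 20 percent rule applied to the proteomics matrix; a feature missing in
#' exactly 20 percent of samples is kept) and fills the remaining gaps by
#' the mean of the `k` nearest samples. Distances are root-mean-square
#' differences over mutually observed features, so samples with different
#' missingness patterns remain comparable; only neighbors observed for
#' the feature being imputed are eligible, and if none exists the feature
#' mean is used. Observed values are never touched.
#'
#' @param proteins A [cohort()] with `NA` marking missing abundances.
#' @param max_missing Maximum tolerated missing fraction per feature
#'   (default 0.20).
#' @param k Number of nearest neighbors (default 10).
#' @return A `cohort` with filtered features and a complete matrix.
#' @export
qc_and_impute <- function(proteins, max_missing = 0.20, k = 10) {
  stopifnot(inherits(proteins, "cohort"))
  ab <- proteins$abundance
  if (any(rowSums(!is.na(ab)) == 0)) {
    stop("qc_and_impute: sample(s) with all features missing", call. = FALSE)
  }
  miss_frac <- colMeans(is.na(ab))
  ab <- ab[, miss_frac <= max_missing, drop = FALSE]
  if (ncol(ab) == 0) {
    stop("qc_and_impute: no features survive the missingness filter",
         call. = FALSE)
  }
  if (anyNA(ab)) {
    n <- nrow(ab)
    feat_means <- colMeans(ab, na.rm = TRUE)
    need <- which(rowSums(is.na(ab)) > 0)
    obs <- !is.na(ab)
    filled <- ab
    for (i in need) {
      # RMS distance over mutually observed features
      d <- vapply(seq_len(n), function(j) {
        if (j == i) return(Inf)
        shared <- obs[i, ] & obs[j, ]
        if (!any(shared)) return(Inf)
        sqrt(mean((ab[i, shared] - ab[j, shared])^2))
      }, numeric(1))
      for (f in which(!obs[i, ])) {
        elig <- which(obs[, f] & is.finite(d))
        if (length(elig) == 0) {
          filled[i, f] <- feat_means[f]
          next
        }
        nb <- elig[order(d[elig], elig)][seq_len(min(k, length(elig)))]
        filled[i, f] <- mean(ab[nb, f])
      }
    }
    ab <- filled
  }
  cohort(ab, proteins$samples, assay = proteins$assay)
}

#' Rank-based single-sample gene-set score
#'
#' GSVA-style score with the kernel density estimate replaced by the
#' empirical CDF: (1) each feature is transformed across samples to its
#' empirical-CDF value; (2) within each sample, features are ranked by
#' that value (descending, ties broken by feature symbol); (3) a weighted
#' Kolmogorov-Smirnov random walk runs down the ranked list with the
#' signature as the hit set, hit steps proportional to the CDF value
#' (weight exponent 1) and miss steps uniform; (4) the score is the
#' signed sum of the walk's maximum and minimum deviations (the
#' "difference of extrema" statistic), which lies in [-1, 1]. The score
#' is invariant to any strictly increasing per-feature transform of the
#' data.
#'
#' @param expr A [cohort()] (or a bare samples-by-features matrix) with at
#'   least 3 samples.
#' @param signature A `signature_set` or character vector; at least 2
#'   signature genes must be present among the features.
#' @return A score data frame `sample`, `score`, `level` (`high` iff
#'   score exceeds the cohort mean), with the cutoff stored in
#'   `attr(, "cutoff")`.
#' @export
gene_set_score <- function(expr, signature) {
  ab <- if (inherits(expr, "cohort")) expr$abundance else expr
  stopifnot(is.matrix(ab))
  sig <- if (inherits(signature, "signature_set")) signature$gene
         else unique(as.character(signature))
  if (nrow(ab) < 3) {
    stop("gene_set_score: need at least 3 samples", call. = FALSE)
  }
  present <- intersect(sig, colnames(ab))
  if (length(present) < 2) {
    stop("gene_set_score: fewer than 2 signature genes among features; ",
         "missing: ", paste(setdiff(sig, colnames(ab)), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(ab)
  p <- ncol(ab)
  m <- length(present)
  if (p <= m) {
    stop("gene_set_score: signature covers all features; walk undefined",
         call. = FALSE)
  }
  # empirical CDF value of each entry within its feature
  z <- apply(ab, 2, function(x) rank(x, ties.method = "max") / n)
  feat <- colnames(ab)
  is_hit <- feat %in% present
  scores <- vapply(seq_len(n), function(i) {
    ord <- order(-z[i, ], feat)
    hit <- is_hit[ord]
    v <- z[i, ord]
    steps <- ifelse(hit, v / sum(v[hit]), -1 / (p - m))
    walk <- cumsum(steps)
    max(walk) + min(walk)
  }, numeric(1))
  samples <- if (inherits(expr, "cohort")) expr$samples$sample
             else rownames(ab) %||% sprintf("S%04d", seq_len(n))
  score_vector(samples, scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

score_vector <- function(samples, scores) {
  cutoff <- mean(scores)
  out <- data.frame(
    sample = samples,
    score = scores,
    level = ifelse(scores > cutoff, "high", "low"),
    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}

#' Mean-abundance protein score
#'
#' Per-sample arithmetic mean of the observed NPX values of the proteins
#' encoded by signature genes (missing values excluded pairwise), with
#' mean-cutoff dichotomization into high and low groups.
#'
#' @param proteins A [cohort()] (typically after [qc_and_impute()]).
#' @param signature A `signature_set` or character vector; at least one
#'   signature protein must be present among the features.
#' @return A score data frame `sample`, `score`, `level`, with the cutoff
#'   in `attr(, "cutoff")`.
#' @export
protein_score <- function(proteins, signature) {
  stopifnot(inherits(proteins, "cohort"))
  sig <- if (inherits(signature, "signature_set")) signature$gene
         else unique(as.character(signature))
  present <- intersect(sig, colnames(proteins$abundance))
  if (length(present) == 0) {
    stop("protein_score: no signature proteins among features", call. = FALSE)
  }
  scores <- rowMeans(proteins$abundance[, present, drop = FALSE],
                     na.rm = TRUE)
  score_vector(proteins$samples$sample, unname(scores))
}

#' Per-feature cohort differential abundance
#'
#' Two-sided Wilcoxon rank-sum test of each feature between the case and
#' control arms, with log2FC reported as the difference of group means on
#' the log2 scale and Benjamini-Hochberg adjustment across features.
#'
#' @param x A [cohort()] whose `group` column holds the two arms.
#' @param features Features to test (default: all columns).
#' @param case,control The group labels (defaults `"tumor"` /
#'   `"normal"`).
#' @return Data frame `feature`, `log2fc`, `p`, `adj_p`.
#' @export
differential_abundance <- function(x, features = NULL, case = "tumor",
                                   control = "normal") {
  stopifnot(inherits(x, "cohort"))
  if (is.null(features)) features <- colnames(x$abundance)
  in_case <- x$samples$group == case
  in_ctrl <- x$samples$group == control
  if (!any(in_case) || !any(in_ctrl)) {
    stop("differential_abundance: both groups must be nonempty",
         call. = FALSE)
  }
  res <- lapply(features, function(f) {
    a <- x$abundance[in_case, f]
    b <- x$abundance[in_ctrl, f]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    wt <- suppressWarnings(stats::wilcox.test(a, b,
                                              alternative = "two.sided"))
    data.frame(feature = f, log2fc = mean(a) - mean(b), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Write a score vector as TSV
#'
#' Columns `sample`, `score`, `level`, `cutoff`.
#'
#' @param scores A score data frame from [gene_set_score()] or
#'   [protein_score()].
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  out$cutoff <- attr(scores, "cutoff")
  write_tsv(out, path)
}
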