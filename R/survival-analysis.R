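#' Administrative censoring at a follow-up horizon
#'
#' Implements the 10-year all-cause-mortality endpoint: samples whose
#' follow-up exceeds the horizon are censored there (event set to 0, time
#' set to the horizon); everyone else is unchanged.
#'
#' @param x A [cohort()].
#' @param horizon_days Follow-up horizon in days; default 3652 (10
#'   years).
#' @return The truncated `cohort`.
#' @export
truncate_followup <- function(x, horizon_days = 3652) {
  stopifnot(inherits(x, "cohort"), horizon_days > 0)
  over <- x$samples$survival_time > horizon_days
  x$samples$event[over] <- 0L
  x$samples$survival_time[over] <- horizon_days
  x
}

resolve_exposure <- function(x, exposure) {
  if (is.data.frame(exposure) && all(c("sample", "score") %in% names(exposure))) {
    return(exposure$score[match(x$samples$sample, exposure$sample)])
  }
  if (is.character(exposure) && length(exposure) == 1) {
    if (exposure %in% colnames(x$abundance)) {
      return(x$abundance[, exposure])
    }
    if (exposure %in% names(x$samples)) {
      return(x$samples[[exposure]])
    }
    stop("exposure '", exposure, "' not found among features or sample columns",
         call. = FALSE)
  }
  if (is.numeric(exposure) && length(exposure) == nrow(x$samples)) {
    return(exposure)
  }
  stop("exposure must be a feature name, a score data frame, or a numeric ",
       "vector of length n samples", call. = FALSE)
}

#' Cox proportional-hazards association of an exposure with mortality
#'
#' Partial-likelihood fit (Efron tie handling) of
#' `Surv(time, event) ~ exposure + covariates`, reporting the hazard
#' ratio per unit exposure with its Wald 95 percent confidence interval.
#' Covariates are auto-reduced: any requested covariate that is constant
#' in the analyzed stratum (e.g. sex within a sex subgroup, cancer type
#' within a single cancer) is dropped. Non-convergence and
#' non-identifiable fits are flagged in the result rather than raised.
#'
#' @param x A [cohort()] (typically after [truncate_followup()]).
#' @param exposure Feature name, score data frame (from the scoring
#'   functions), or numeric vector.
#' @param covariates Covariate column names in `x$samples`; default the
#'   full adjustment set.
#' @param subset Optional logical/integer index restricting the stratum.
#' @param name Label for the result row.
#' @return One-row data frame: `name`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `n`, `n_events`, `flag` (`ok`, `non_convergence` or
#'   `non_identifiable`).
#' @export
cox_association <- function(x, exposure,
                            covariates = c("sex", "age_at_diagnosis",
                                           "cancer_type", "sampling_lag"),
                            subset = NULL, name = "exposure") {
  stopifnot(inherits(x, "cohort"))
  if (!is.null(subset)) x <- subset_cohort(x, subset)
  ex <- resolve_exposure(x, exposure)
  df <- data.frame(time = x$samples$survival_time,
                   event = x$samples$event,
                   .exposure = ex)
  if (sum(df$event) < 2) {
    stop("cox_association: fewer than 2 events in stratum", call. = FALSE)
  }
  if (length(unique(df$.exposure[!is.na(df$.exposure)])) < 2) {
    stop("cox_association: exposure has zero variance", call. = FALSE)
  }
  kept <- character()
  for (cv in covariates) {
    v <- x$samples[[cv]]
    if (length(unique(v)) >= 2) {
      df[[cv]] <- v
      kept <- c(kept, cv)
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ .exposure",
    if (length(kept)) paste("+", paste(kept, collapse = " + ")) else ""))
  flag <- "ok"
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(fml, data = df, ties = "efron"),
             error = function(e) e),
    warning = function(w) {
      if (grepl("converge|infinite|singular|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE)) {
        flag <<- "non_convergence"
      }
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    return(data.frame(name = name, hr = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_,
                      n = nrow(df), n_events = sum(df$event),
                      flag = "non_convergence", stringsAsFactors = FALSE))
  }
  if (anyNA(stats::coef(fit))) flag <- "non_identifiable"
  sm <- summary(fit)
  beta <- stats::coef(fit)[".exposure"]
  se <- sm$coefficients[".exposure", "se(coef)"]
  pval <- sm$coefficients[".exposure", "Pr(>|z|)"]
  data.frame(name = name,
             hr = unname(exp(beta)),
             ci_low = unname(exp(beta - 1.96 * se)),
             ci_high = unname(exp(beta + 1.96 * se)),
             p = unname(pval),
             n = nrow(df),
             n_events = sum(df$event),
             flag = flag,
             stringsAsFactors = FALSE)
}

#' Per-cancer Cox screen with a minimum-events filter
#'
#' Fits the exposure association separately within each cancer type,
#' excluding cancers with fewer than `min_events` deaths (the
#' 20-death-event rule); excluded strata are listed with the reason
#' rather than silently dropped. `cancer_type` is removed from the
#' covariate set automatically within single-cancer strata, and BH
#' adjustment runs across the retained strata.
#'
#' @param x A [cohort()].
#' @param exposure As in [cox_association()].
#' @param covariates Covariate names (cancer type is dropped per
#'   stratum automatically).
#' @param min_events Minimum death events per cancer (default 20).
#' @return Data frame with one row per cancer type: the
#'   [cox_association()] columns plus `cancer_type`, `adj_p` and
#'   `skip_reason` (`NA` for retained strata).
#' @export
per_cancer_screen <- function(x, exposure,
                              covariates = c("sex", "age_at_diagnosis",
                                             "cancer_type", "sampling_lag"),
                              min_events = 20) {
  stopifnot(inherits(x, "cohort"))
  if (!"cancer_type" %in% names(x$samples)) {
    stop("per_cancer_screen: cancer_type column required", call. = FALSE)
  }
  rows <- list()
  for (ct in sort(unique(x$samples$cancer_type))) {
    idx <- x$samples$cancer_type == ct
    n_ev <- sum(x$samples$event[idx])
    if (n_ev < min_events) {
      rows[[ct]] <- data.frame(
        cancer_type = ct, name = "exposure", hr = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
        n = sum(idx), n_events = n_ev, flag = "skipped",
        skip_reason = sprintf("fewer than %d death events (%d)",
                              min_events, n_ev),
        stringsAsFactors = FALSE)
      next
    }
    res <- cox_association(x, exposure, covariates = covariates,
                           subset = idx, name = "exposure")
    res$cancer_type <- ct
    res$skip_reason <- NA_character_
    rows[[ct]] <- res[, c("cancer_type", "name", "hr", "ci_low", "ci_high",
                          "p", "n", "n_events", "flag", "skip_reason")]
  }
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  retained <- is.na(out$skip_reason)
  out$adj_p[retained] <- stats::p.adjust(out$p[retained], method = "BH")
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit estimates per arm with the two-sided log-rank test.
#' Arms are the signature-score level (high/low), optionally crossed with
#' a second grouping column such as sex (the level-by-sex curves used for
#' the survival figures). Empty arms are dropped with a warning.
#'
#' @param x A [cohort()].
#' @param level Character vector (or score data frame with a `level`
#'   column) giving each sample's high/low group.
#' @param group2 Optional name of a second grouping column in
#'   `x$samples` (e.g. `"sex"`).
#' @return List: `curves` (data frame `arm`, `time`, `n_risk`,
#'   `n_event`, `surv`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(x, level, group2 = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.data.frame(level) && "level" %in% names(level)) {
    level <- level$level[match(x$samples$sample, level$sample)]
  }
  arm <- as.character(level)
  if (!is.null(group2)) {
    arm <- paste(arm, x$samples[[group2]], sep = ".")
  }
  keep <- !is.na(arm)
  if (!all(keep)) {
    warning("km_logrank: samples with undefined arm dropped")
  }
  df <- data.frame(time = x$samples$survival_time[keep],
                   event = x$samples$event[keep],
                   arm = arm[keep], stringsAsFactors = FALSE)
  tab <- table(df$arm)
  if (any(tab == 0)) {
    warning("km_logrank: empty arm(s) dropped: ",
            paste(names(tab)[tab == 0], collapse = ", "))
  }
  if (length(unique(df$arm)) < 2) {
    stop("km_logrank: need at least 2 nonempty arms", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ arm, data = df)
  strata_labels <- sub("^arm=", "", rep(names(fit$strata), fit$strata))
  curves <- data.frame(arm = strata_labels, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = df,
                           rho = 0)
  dfree <- length(sd$n) - 1
  list(curves = curves, chisq = unname(sd$chisq), df = dfree,
       p = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE))
}
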