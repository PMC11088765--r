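surv_cohort <- function(time, event, sex = NULL, cancer_type = "ca",
                        exposure = NULL) {
  n <- length(time)
  ab <- matrix(if (is.null(exposure)) rnorm(n) else exposure, n, 1,
               dimnames = list(NULL, "x"))
  samples <- data.frame(
    sample = sprintf("S%03d", seq_len(n)), group = "tumor",
    survival_time = time, event = as.integer(event),
    sex = sex %||% rep(c("female", "male"), length.out = n),
    age_at_diagnosis = 60 + seq_len(n) %% 7,
    cancer_type = rep(cancer_type, length.out = n),
    sampling_lag = 5, stringsAsFactors = FALSE)
  cohort(ab, samples)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("follow-up truncation censors administratively at the horizon", {
  co <- surv_cohort(c(4000, 100, 3652, 5000), c(1, 1, 1, 0))
  res <- truncate_followup(co, 3652)
  expect_equal(res$samples$survival_time, c(3652, 100, 3652, 3652))
  expect_equal(res$samples$event, c(0L, 1L, 1L, 0L))
  # all-censored cohort keeps zero events
  co2 <- truncate_followup(surv_cohort(rep(5000, 4), rep(1, 4)))
  expect_equal(sum(co2$samples$event), 0)
})

test_that("KM estimates and log-rank match the hand-computed life table", {
  # arm A: events at 1, 3, 7, censored at 5; arm B: events at 2, 6,
  # censored at 4 and 8
  co <- surv_cohort(c(1, 3, 5, 7, 2, 4, 6, 8),
                    c(1, 1, 0, 1, 1, 0, 1, 0))
  level <- rep(c("high", "low"), each = 4)
  res <- km_logrank(co, level)

  a <- res$curves[res$curves$arm == "high", ]
  expect_equal(a$time, c(1, 3, 5, 7))
  expect_equal(a$surv, c(3 / 4, 1 / 2, 1 / 2, 0))
  b <- res$curves[res$curves$arm == "low", ]
  expect_equal(b$time, c(2, 4, 6, 8))
  expect_equal(b$surv, c(3 / 4, 3 / 4, 3 / 8, 3 / 8))

  # hand life-table log-rank: O_A = 3, E_A = 1/2 + 3/7 + 1/2 + 1/3 + 1/2,
  # V = 1/4 + 12/49 + 1/4 + 2/9 + 1/4
  e_a <- 1 / 2 + 3 / 7 + 1 / 2 + 1 / 3 + 1 / 2
  v <- 1 / 4 + 12 / 49 + 1 / 4 + 2 / 9 + 1 / 4
  expect_equal(res$chisq, (3 - e_a)^2 / v, tolerance = 1e-10)
  expect_equal(res$p, pchisq((3 - e_a)^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # KM invariants: starts at risk n, non-increasing
  expect_true(all(diff(a$surv) <= 0))
  expect_equal(a$n_risk[1], 4)
})

test_that("identical arms give log-rank statistic 0 and p 1", {
  t <- c(1, 2, 3, 4)
  co <- surv_cohort(c(t, t), c(1, 1, 0, 1, 1, 1, 0, 1))
  res <- km_logrank(co, rep(c("high", "low"), each = 4))
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-9)
})

test_that("clearly separated arms give a positive statistic and ordered curves", {
  co <- surv_cohort(c(1:5, 11:15), rep(1, 10))
  res <- km_logrank(co, rep(c("high", "low"), each = 5))
  expect_gt(res$chisq, 0)
  hi <- res$curves[res$curves$arm == "high", ]
  lo <- res$curves[res$curves$arm == "low", ]
  expect_true(all(hi$surv <= 1) && all(lo$surv <= 1))
  expect_lt(res$p, 0.05)
  expect_error(km_logrank(co, rep("high", 10)), "2 nonempty arms")
})

test_that("km arms can be crossed with sex", {
  co <- surv_cohort(1:12, rep(1, 12),
                    sex = rep(c("female", "female", "male", "male"), 3))
  res <- km_logrank(co, rep(c("high", "low"), 6), group2 = "sex")
  expect_setequal(unique(res$curves$arm),
                  c("high.female", "high.male", "low.female", "low.male"))
  expect_equal(res$df, 3)
})

test_that("cox association recovers a known hazard ratio structure", {
  set.seed(89)
  n <- 400
  x <- rnorm(n)
  t <- rexp(n, rate = 0.01 * exp(log(2) * x))
  co <- surv_cohort(t, rep(1, n), exposure = x)
  res <- cox_association(co, "x")
  expect_true(res$ci_low <= res$hr && res$hr <= res$ci_high)
  expect_gt(res$hr, 1.6)
  expect_lt(res$hr, 2.5)
  expect_equal(res$n, n)
  expect_equal(res$n_events, n)
  expect_equal(res$flag, "ok")
})

test_that("cox association is invariant to time-unit rescaling", {
  set.seed(97)
  n <- 150
  x <- rnorm(n)
  t <- rexp(n, 0.01 * exp(0.5 * x))
  ev <- rbinom(n, 1, 0.8)
  r1 <- cox_association(surv_cohort(t, ev, exposure = x), "x")
  r2 <- cox_association(surv_cohort(t / 365.25, ev, exposure = x), "x")
  expect_equal(r1$hr, r2$hr, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("cox covariates auto-reduce and degenerate exposures error or flag", {
  set.seed(101)
  co <- surv_cohort(rexp(60, 0.01), rep(1, 60),
                    sex = rep("female", 60), cancer_type = "one")
  # constant sex and cancer_type are dropped rather than breaking the fit
  res <- cox_association(co, "x")
  expect_equal(res$flag, "ok")
  # constant exposure is an error
  expect_error(cox_association(co, rep(1, 60)), "zero variance")
  # fewer than 2 events is an error
  co2 <- surv_cohort(rexp(10, 0.01), rep(0, 10))
  expect_error(cox_association(co2, "x"), "fewer than 2 events")
  # perfectly separating exposure is flagged, not a crash
  co3 <- surv_cohort(c(1:5, 100:104), c(rep(1, 5), rep(0, 5)),
                     exposure = rep(c(1, 0), each = 5))
  res3 <- cox_association(co3, "x")
  expect_true(res3$flag %in% c("non_convergence", "non_identifiable"))
})

test_that("per-cancer screen applies the 20-event exclusion at the boundary", {
  set.seed(103)
  mk <- function(n_events, n, label) {
    surv_cohort(rexp(n, 0.005), c(rep(1, n_events), rep(0, n - n_events)),
                cancer_type = label)
  }
  combine <- function(a, b, cc) {
    cohort(rbind(a$abundance, b$abundance, cc$abundance),
           within(rbind(a$samples, b$samples, cc$samples),
                  sample <- sprintf("S%04d", seq_len(length(sample)))))
  }
  co <- combine(mk(19, 60, "under"), mk(20, 60, "boundary"),
                mk(45, 60, "over"))
  res <- per_cancer_screen(co, "x", min_events = 20)
  expect_equal(nrow(res), 3)
  expect_equal(res$flag[res$cancer_type == "under"], "skipped")
  expect_match(res$skip_reason[res$cancer_type == "under"], "19")
  expect_true(all(is.na(res$skip_reason[res$cancer_type != "under"])))
  retained <- is.na(res$skip_reason)
  expect_equal(res$adj_p[retained], p.adjust(res$p[retained], "BH"))
  # retained set equals a brute-force event-count filter
  oracle <- vapply(split(co$samples$event, co$samples$cancer_type), sum,
                   numeric(1)) >= 20
  expect_equal(sort(res$cancer_type[retained]),
               sort(names(oracle)[oracle]))
})
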