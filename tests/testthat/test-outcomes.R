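test_that("cohort filter applies both exclusion rules in order", {
  parts <- data.frame(
    id = paste0("P", 1:6),
    baseline_egfr = c(70, 70, 19, 45, NA, 25),
    uacr = c(10, 50, 100, 20, 5, NA),
    stringsAsFactors = FALSE
  )
  out <- outcome_cohort_filter(parts)
  # 70/10: low risk out; 70/50: in (AND fails); 19/100: low eGFR out;
  # 45/20: in; NA rows: missing tally
  expect_setequal(out$included$id, c("P2", "P4"))
  expect_equal(unname(out$tally["excluded_low_risk"]), 1)
  expect_equal(unname(out$tally["excluded_low_egfr"]), 1)
  expect_equal(unname(out$tally["excluded_missing"]), 2)
  expect_equal(unname(out$tally["n_included"]), 2)
})

series_df <- function(days, egfr) data.frame(day = days, egfr = egfr)

test_that("sustained 40% decline is detected at the index measurement", {
  # baseline 50: threshold 30; drop to 25 at day 100, stays <= 28 to day 400
  s <- series_df(c(0, 100, 180, 300, 400), c(50, 25, 26, 28, 27))
  r <- derive_endpoint(s, baseline_egfr = 50, last_followup = 500)
  expect_true(r$event)
  expect_equal(r$time, 100)
  expect_equal(r$reason, "decline_sustained")
})

test_that("a transient dip below threshold is not an event", {
  s <- series_df(c(0, 100, 150, 300, 420), c(50, 25, 45, 44, 43))
  r <- derive_endpoint(s, baseline_egfr = 50, last_followup = 500)
  expect_false(r$event)
  expect_equal(r$time, 500)
})

test_that("renal replacement therapy start dominates any series", {
  s <- series_df(c(0, 100), c(50, 48))
  r <- derive_endpoint(s, baseline_egfr = 50, rrt_start = 30,
                       last_followup = 500)
  expect_true(r$event)
  expect_equal(r$time, 30)
  expect_equal(r$reason, "rrt")
})

test_that("sustained eGFR < 15 triggers the ESKD arm", {
  s <- series_df(c(0, 200, 260, 320), c(40, 14, 13, 12))
  r <- derive_endpoint(s, baseline_egfr = 40, last_followup = 400)
  expect_true(r$event)
  expect_equal(r$time, 200)
  expect_equal(r$reason, "eskd_sustained")
})

test_that("death censors and empty series censor at last follow-up", {
  s <- series_df(c(0, 100), c(50, 45))
  r <- derive_endpoint(s, baseline_egfr = 50, death = 200,
                       last_followup = 900)
  expect_false(r$event)
  expect_equal(r$time, 200)

  r2 <- derive_endpoint(series_df(numeric(0), numeric(0)),
                        baseline_egfr = 50, last_followup = 365)
  expect_false(r2$event)
  expect_equal(r2$time, 365)
})

test_that("a below-threshold tail without late confirmation is censored", {
  # drops at day 300 but no measurement occurs > 90 days later
  s <- series_df(c(0, 300, 350), c(50, 25, 24))
  r <- derive_endpoint(s, baseline_egfr = 50, last_followup = 380)
  expect_false(r$event)
})

test_that("endpoint derivation ignores redundant confirmatory measurements", {
  s1 <- series_df(c(0, 100, 250), c(50, 25, 24))
  s2 <- series_df(c(0, 100, 150, 180, 250), c(50, 25, 26, 25, 24))
  r1 <- derive_endpoint(s1, 50, last_followup = 400)
  r2 <- derive_endpoint(s2, 50, last_followup = 400)
  expect_equal(r1[c("time", "event", "reason")],
               r2[c("time", "event", "reason")])
  # idempotence: re-deriving on the same inputs is identical
  expect_identical(r1, derive_endpoint(s1, 50, last_followup = 400))
})

test_that("empirical AUC equals the U-statistic on hand examples", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1), n_boot = 0)
  expect_equal(r$auc, 1)
  r2 <- roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1), n_boot = 0)
  expect_equal(r2$auc, 0.75)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1), n_boot = 0), "both classes")
})

test_that("AUC matches pair enumeration including ties, and label flips", {
  set.seed(15)
  for (i in 1:10) {
    scores <- sample(1:6, 12, replace = TRUE)   # forces ties
    labels <- rbinom(12, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_curve(scores, labels, n_boot = 0)
    expect_equal(r$auc, auc_enumeration(scores, labels))
    flipped <- roc_curve(scores, 1 - labels, n_boot = 0)
    expect_equal(flipped$auc, 1 - r$auc)
  }
})

test_that("AUC and bootstrap CI agree with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, plogis(scores))
  r <- roc_curve(scores, labels, n_boot = 500, seed = 3)
  ref <- pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                             direction = "<"))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  expect_true(r$ci[1] < r$auc && r$auc < r$ci[2])
})

test_that("threshold selection maximises sensitivity above the floor", {
  # 10-point hand-built score set; exhaustive search oracle
  scores <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  labels <- c(0, 0, 1, 0, 0, 1, 0, 1, 1, 1)
  r <- roc_curve(scores, labels, n_boot = 0)
  sel <- select_threshold(r, min_specificity = 0.6)

  # oracle: exhaustive scan of every candidate threshold
  cands <- data.frame(t = c(sort(unique(scores)), Inf))
  cands$sens <- vapply(cands$t, function(t) mean(scores[labels == 1] >= t),
                       numeric(1))
  cands$spc <- vapply(cands$t, function(t) mean(scores[labels == 0] < t),
                      numeric(1))
  ok <- cands[cands$spc >= 0.6, ]
  best <- ok[order(-ok$sens, -ok$spc, ok$t)[1], ]
  expect_equal(sel$threshold, best$t)
  expect_equal(sel$sensitivity, best$sens)

  # specificity floor 0 -> sensitivity 1; the higher-specificity tie-break
  # picks the lowest positive score as threshold
  sel0 <- select_threshold(r, min_specificity = 0)
  expect_equal(sel0$sensitivity, 1)
  expect_equal(sel0$threshold, min(scores[labels == 1]))

  # unattainable floor warns and returns the max-specificity threshold
  expect_warning(selw <- select_threshold(r, min_specificity = 1.5),
                 "maximum-specificity")
  expect_equal(selw$specificity, max(r$spec))
})

test_that("perfectly separating scores select the separating threshold", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  sel <- select_threshold(roc_curve(scores, labels, n_boot = 0),
                          min_specificity = 0.9)
  expect_equal(sel$sensitivity, 1)
  expect_equal(sel$specificity, 1)
  expect_equal(sel$threshold, 10)
})

test_that("linear regression matches the normal equations", {
  df <- data.frame(
    pct_senescent = c(2, 4.1, 5.9, 8.2, 9.8, 12),
    uccr = 2^c(1, 2, 3, 4, 5, 6),
    baseline_egfr = c(90, 70, 55, 40, 30, 20),
    age = c(30, 40, 50, 55, 60, 70),
    uacr = c(5, 30, 80, 120, 200, 300)
  )
  fit <- linreg_senescence(df)
  X <- cbind(1, log2(df$uccr), df$baseline_egfr, df$age, df$uacr)
  beta <- solve(t(X) %*% X, t(X) %*% df$pct_senescent)
  expect_equal(fit$estimates$estimate, as.numeric(beta), tolerance = 1e-8)
})

test_that("exact linear fits and VIFs behave as expected", {
  set.seed(44)
  n <- 40
  df <- data.frame(
    uccr = 2^rnorm(n),
    baseline_egfr = rnorm(n),
    age = rnorm(n),
    uacr = abs(rnorm(n))
  )
  df$pct_senescent <- 2 * log2(df$uccr)   # exact dependence on one term
  fit <- suppressWarnings(linreg_senescence(df))  # perfect-fit warning
  est <- fit$estimates
  expect_equal(est$estimate[est$term == "log2_uccr"], 2, tolerance = 1e-8)
  expect_lt(est$p[est$term == "log2_uccr"], 1e-12)

  # VIF equals the 1/(1-R^2) oracle computed by hand
  X <- data.frame(log2_uccr = log2(df$uccr),
                  baseline_egfr = df$baseline_egfr,
                  age = df$age, uacr = df$uacr)
  for (v in names(X)) {
    r2 <- summary(lm(X[[v]] ~ ., data = X[setdiff(names(X), v)]))$r.squared
    expect_equal(unname(fit$vif[v]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("log-rank matches hand-tabulated risk-set arithmetic", {
  # group A: events at 1, 3; group B: event at 2, censored at 4
  time <- c(1, 3, 2, 4)
  event <- c(1, 1, 1, 0)
  group <- c("A", "A", "B", "B")
  r <- km_logrank(time, event, group)
  # hand computation: O_A = 2, E_A = 1/2 + 1/3 + 1/2 = 4/3,
  # V = 1/4 + 2/9 + 1/4 = 0.72222; chi2 = (2 - 4/3)^2 / V
  expect_equal(r$chi2, (2 - 4 / 3)^2 / (1 / 4 + 2 / 9 + 1 / 4),
               tolerance = 1e-10)

  # identical groups -> chi2 ~ 0
  t2 <- c(1, 2, 3, 1, 2, 3)
  e2 <- c(1, 1, 0, 1, 1, 0)
  g2 <- rep(c("A", "B"), each = 3)
  expect_lt(km_logrank(t2, e2, g2)$chi2, 1e-10)

  # survival drops to zero after every subject events
  km <- km_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(min(km$curves$surv), 0)
  expect_error(km_logrank(c(1, 2), c(1, 1), c("A", "A")), "group")
})

test_that("log-rank equals the Cox score test on ties-free data", {
  set.seed(3)
  n <- 40
  time <- rexp(n, 0.1) + seq(0, 1e-4, length.out = n)  # no ties
  event <- rbinom(n, 1, 0.7)
  group <- rep(c(0, 1), n / 2)
  r <- km_logrank(time, event, group)
  fit <- survival::coxph(survival::Surv(time, event) ~ group)
  expect_equal(r$chi2, unname(fit$score), tolerance = 1e-6)
})

test_that("Cox wrapper reports HRs, c-index and PH diagnostics", {
  cfg <- sim_config(n_participants = 400)
  coh <- gen_cohort(cfg, seed = 88)
  oc <- gen_outcomes(coh, cfg, seed = 88)
  fit <- cox_fit(oc$records, c("uccr_high", "baseline_egfr", "ln_acr"))
  tab <- fit$table
  expect_true(all(tab$ci_low <= tab$hr & tab$hr <= tab$ci_high))
  expect_true(fit$c_index > 0.5 && fit$c_index <= 1)
  expect_length(fit$ph_test_p, 3)

  # perfectly concordant risk score -> c-index 1 (monotone likelihood, so
  # the coefficient diverges; concordance is still well defined)
  df <- data.frame(time = c(5, 4, 3, 2, 1), event = 1, risk = 1:5)
  fit2 <- suppressWarnings(cox_fit(df, "risk"))
  expect_equal(unname(fit2$c_index), 1)

  expect_error(cox_fit(data.frame(time = 1:3, event = c(1, 1, 0),
                                  x = c(1, 1, 1)), "x"), "constant")
})

test_that("c-index comparison is reflexive and orders informative models", {
  cfg <- sim_config(n_participants = 600)
  coh <- gen_cohort(cfg, seed = 21)
  oc <- gen_outcomes(coh, cfg, seed = 21)
  covs <- c("baseline_egfr", "ln_acr", "age")
  same <- c_index_delta(oc$records, covs, covs)
  expect_equal(same$c_with, same$c_without)

  with_marker <- c_index_delta(oc$records, c("uccr_high", covs), covs)
  expect_gt(with_marker$c_with, with_marker$c_without - 0.005)
})
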