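#' Renal progression endpoint specification
#'
#' The composite CKD progression endpoint: end-stage kidney disease
#' (starting renal replacement therapy, or eGFR below
#' `eskd_egfr_threshold` maintained for more than `sustain_days`) or a
#' relative eGFR reduction of more than `decline_frac` from baseline,
#' likewise sustained.
#'
#' @param eskd_egfr_threshold ESKD eGFR threshold, mL/min (default 15).
#' @param sustain_days Days a below-threshold state must persist (default
#'   90, strict).
#' @param decline_frac Relative decline fraction (default 0.40).
#' @return List of class `endpoint_spec`.
#' @export
endpoint_spec <- function(eskd_egfr_threshold = 15, sustain_days = 90,
                          decline_frac = 0.40) {
  stopifnot(sustain_days > 0, decline_frac > 0, decline_frac < 1,
            eskd_egfr_threshold > 0)
  structure(list(eskd_egfr_threshold = eskd_egfr_threshold,
                 sustain_days = sustain_days,
                 decline_frac = decline_frac),
            class = "endpoint_spec")
}

#' Filter a cohort for outcome analysis
#'
#' Applies the two exclusion rules used to enrich for progression risk:
#' first, participants at low risk (baseline eGFR >= 60 mL/min AND uACR <=
#' 30 mg/mmol) are excluded; then participants with baseline eGFR < 20
#' mL/min (already at or near the endpoint) are excluded. Participants with
#' missing eGFR or uACR are excluded under a separate tally.
#'
#' @param participants Data.frame with columns `baseline_egfr` and `uacr`.
#' @return List with `included` (the retained rows) and `tally` (named
#'   integer vector: `n_input`, `excluded_low_risk`, `excluded_low_egfr`,
#'   `excluded_missing`, `n_included`).
#' @export
outcome_cohort_filter <- function(participants) {
  stopifnot(all(c("baseline_egfr", "uacr") %in% names(participants)))
  egfr <- participants$baseline_egfr
  acr <- participants$uacr
  missing <- !is.finite(egfr) | !is.finite(acr)
  low_risk <- !missing & egfr >= 60 & acr <= 30
  low_egfr <- !missing & !low_risk & egfr < 20
  keep <- !missing & !low_risk & !low_egfr
  list(
    included = participants[keep, , drop = FALSE],
    tally = c(n_input = nrow(participants),
              excluded_low_risk = sum(low_risk),
              excluded_low_egfr = sum(low_egfr),
              excluded_missing = sum(missing),
              n_included = sum(keep))
  )
}

#' Derive the progression endpoint for one participant
#'
#' Scans a time-sorted eGFR series for the earliest of: renal replacement
#' therapy start; a sustained drop below the ESKD threshold; or a sustained
#' relative decline of more than `decline_frac` from baseline. "Sustained"
#' is measurement-driven: a below-threshold measurement at day `d`
#' qualifies when at least one later measurement falls strictly more than
#' `sustain_days` after `d` and every measurement from `d` up to and
#' including the first such later measurement stays below threshold. The
#' event time is the day of the index measurement. Without an event the
#' record is censored at the earliest of death and last follow-up.
#'
#' @param series Data.frame with columns `day` (nondecreasing) and `egfr`.
#' @param baseline_egfr Baseline eGFR, mL/min (> 0).
#' @param rrt_start Day renal replacement therapy started, or `NA`.
#' @param death Day of death, or `NA` (death censors).
#' @param last_followup Last follow-up day.
#' @param spec An [endpoint_spec()].
#' @return List with `time` (days), `event` (logical) and `reason` (one of
#'   `"rrt"`, `"eskd_sustained"`, `"decline_sustained"`, `"censored"`).
#' @export
derive_endpoint <- function(series, baseline_egfr, rrt_start = NA,
                            death = NA, last_followup,
                            spec = endpoint_spec()) {
  stopifnot(baseline_egfr > 0)
  if (!is.null(series) && nrow(series) > 0) {
    if (is.unsorted(series$day)) {
      stop("`series$day` must be nondecreasing", call. = FALSE)
    }
  }
  cens_time <- min(c(death, last_followup), na.rm = TRUE)

  cand <- data.frame(time = numeric(0), reason = character(0))
  if (!is.na(rrt_start)) {
    cand <- rbind(cand, data.frame(time = rrt_start, reason = "rrt"))
  }
  if (!is.null(series) && nrow(series) > 0) {
    t_eskd <- first_sustained_below(series$day, series$egfr,
                                    spec$eskd_egfr_threshold,
                                    spec$sustain_days)
    if (!is.na(t_eskd)) {
      cand <- rbind(cand, data.frame(time = t_eskd,
                                     reason = "eskd_sustained"))
    }
    t_decl <- first_sustained_below(series$day, series$egfr,
                                    (1 - spec$decline_frac) * baseline_egfr,
                                    spec$sustain_days)
    if (!is.na(t_decl)) {
      cand <- rbind(cand, data.frame(time = t_decl,
                                     reason = "decline_sustained"))
    }
  }
  if (nrow(cand) > 0) {
    best <- which.min(cand$time)
    return(list(time = cand$time[best], event = TRUE,
                reason = cand$reason[best]))
  }
  list(time = cens_time, event = FALSE, reason = "censored")
}

# Earliest day d with egfr < thr such that some measurement occurs at
# day > d + sustain and all measurements in (d, first such day] are < thr.
first_sustained_below <- function(days, values, thr, sustain) {
  below <- values < thr
  for (i in seq_along(days)) {
    if (!below[i]) next
    later <- which(days > days[i] + sustain)
    if (!length(later)) return(NA_real_)   # no later confirmation possible
    j <- later[1]
    if (all(below[i:j])) return(days[i])
  }
  NA_real_
}

#' Derive endpoints for a whole cohort
#'
#' Vectorised wrapper over [derive_endpoint()].
#'
#' @param egfr_series Long data.frame `id`, `day`, `egfr`.
#' @param participants Data.frame with `id`, `baseline_egfr` and optional
#'   `rrt_start`, `death`, `last_followup` columns.
#' @param spec An [endpoint_spec()].
#' @return Data.frame `id`, `time`, `event`, `reason`.
#' @export
derive_endpoints <- function(egfr_series, participants,
                             spec = endpoint_spec()) {
  get_col <- function(col, default = NA_real_) {
    if (col %in% names(participants)) participants[[col]]
    else rep(default, nrow(participants))
  }
  rrt <- get_col("rrt_start")
  death <- get_col("death")
  lfu <- get_col("last_followup")
  out <- lapply(seq_len(nrow(participants)), function(i) {
    id <- participants$id[i]
    s <- egfr_series[egfr_series$id == id, , drop = FALSE]
    s <- s[order(s$day), , drop = FALSE]
    lf <- if (is.na(lfu[i])) max(s$day, 0) else lfu[i]
    r <- derive_endpoint(s, participants$baseline_egfr[i],
                         rrt_start = rrt[i], death = death[i],
                         last_followup = lf, spec = spec)
    data.frame(id = id, time = r$time, event = r$event, reason = r$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- ROC --------------------------------------------------------------------

#' Empirical ROC curve
#'
#' Empirical receiver operating characteristic for a score predicting a
#' binary label, with higher scores predicting the positive class. A case
#' is called positive at threshold `t` when `score >= t`; the threshold
#' grid is the observed scores plus `Inf`. The AUC is the Mann-Whitney
#' U-statistic `U / (n1 * n0)` (ties counted 1/2). The confidence interval
#' uses a seeded stratified bootstrap (resampling cases and controls
#' separately).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical); both classes required.
#' @param conf_level CI level, default 0.95.
#' @param n_boot Bootstrap replicates, default 2000; `0` skips the CI.
#' @param seed Seed for the bootstrap.
#' @return List of class `senuro_roc`: `thresholds`, `sens`, `spec`,
#'   `auc`, `ci` (length-2 or `NULL`), `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, conf_level = 0.95, n_boot = 2000,
                      seed = 1) {
  labels <- as.integer(as.logical(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  thresholds <- c(sort(unique(scores)), Inf)
  sens <- vapply(thresholds, function(t) mean(scores[labels == 1] >= t),
                 numeric(1))
  spc <- vapply(thresholds, function(t) mean(scores[labels == 0] < t),
                numeric(1))
  auc <- auc_u(scores, labels)
  ci <- NULL
  if (n_boot > 0) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        auc_u(c(sample(pos, n_pos, replace = TRUE),
                sample(neg, n_neg, replace = TRUE)),
              c(rep(1L, n_pos), rep(0L, n_neg)))
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(boot, c(alpha, 1 - alpha)))
  }
  structure(list(thresholds = thresholds, sens = sens, spec = spc,
                 auc = auc, ci = ci, n_pos = n_pos, n_neg = n_neg),
            class = "senuro_roc")
}

# AUC as the normalised Mann-Whitney U (average ranks; ties count 1/2).
auc_u <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.senuro_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d positives / %d negatives, AUC = %.3f",
              x$n_pos, x$n_neg, x$auc))
  if (!is.null(x$ci)) {
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci[1], x$ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.senuro_roc <- function(x, ...) {
  plot(1 - x$spec, x$sens, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Select a biomarker threshold prioritising specificity
#'
#' Among thresholds whose specificity is at least `min_specificity`,
#' returns the one maximising sensitivity; ties are broken toward higher
#' specificity, then toward the lower threshold value. If no threshold
#' attains the floor, the maximum-specificity threshold is returned with a
#' warning.
#'
#' @param roc A [roc_curve()] result.
#' @param min_specificity Specificity floor, default 0.9.
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
select_threshold <- function(roc, min_specificity = 0.9) {
  stopifnot(inherits(roc, "senuro_roc"))
  ok <- roc$spec >= min_specificity
  if (!any(ok)) {
    warning("no threshold attains the requested specificity; ",
            "returning the maximum-specificity threshold", call. = FALSE)
    ok <- roc$spec == max(roc$spec)
  }
  idx <- which(ok)
  ord <- order(-roc$sens[idx], -roc$spec[idx], roc$thresholds[idx])
  best <- idx[ord[1]]
  list(threshold = roc$thresholds[best],
       sensitivity = roc$sens[best],
       specificity = roc$spec[best])
}

# ---- regression and survival ------------------------------------------------

#' Linear model for histologic senescence on urinary clusterin
#'
#' Ordinary least squares of the senescent-epithelium percentage on
#' log2(uCCR), baseline eGFR, age and uACR, with per-covariate variance
#' inflation factors to check multicollinearity.
#'
#' @param data Data.frame with columns `pct_senescent`, `uccr`,
#'   `baseline_egfr`, `age`, `uacr`.
#' @return List with `fit` (the `lm`), `estimates` (data.frame `term`,
#'   `estimate`, `p`) and `vif` (named vector).
#' @export
linreg_senescence <- function(data) {
  req <- c("pct_senescent", "uccr", "baseline_egfr", "age", "uacr")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(pct_senescent = data$pct_senescent,
                   log2_uccr = log2(data$uccr),
                   baseline_egfr = data$baseline_egfr,
                   age = data$age, uacr = data$uacr)
  fit <- lm(pct_senescent ~ log2_uccr + baseline_egfr + age + uacr,
            data = df)
  if (fit$rank < 5) stop("singular design matrix", call. = FALSE)
  sm <- summary(fit)$coefficients
  list(
    fit = fit,
    estimates = data.frame(term = rownames(sm), estimate = sm[, 1],
                           p = sm[, 4], row.names = NULL,
                           stringsAsFactors = FALSE),
    vif = car::vif(fit)
  )
}

#' Kaplan-Meier curves with a log-rank test
#'
#' @param time,event Follow-up time and event indicator.
#' @param group Two-level grouping (e.g. uCCR above/below threshold).
#' @return List with `curves` (a `survfit`), `chi2` and `p` (log-rank,
#'   1 df for two groups).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(droplevels(group)) < 2) {
    stop("each group must be nonempty", call. = FALSE)
  }
  if (sum(event) < 1) stop("at least one event required", call. = FALSE)
  df <- data.frame(time = time, event = as.integer(event), group = group)
  curves <- survival::survfit(survival::Surv(time, event) ~ group,
                              data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi2 <- sd$chisq
  p <- pchisq(chi2, df = length(sd$n) - 1, lower.tail = FALSE)
  list(curves = curves, chi2 = unname(chi2), p = unname(p))
}

#' Cox proportional-hazards fit with c-index and PH check
#'
#' Partial-likelihood Cox regression (Efron tie handling) of the
#' progression endpoint on the given covariates, reporting hazard ratios
#' with Wald confidence intervals and p-values, Harrell's c-index, and a
#' proportional-hazards check correlating scaled Schoenfeld residuals with
#' time.
#'
#' @param records Data.frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param conf_level CI level, default 0.95.
#' @return List of class `senuro_cox`: `table` (data.frame `term`, `hr`,
#'   `ci_low`, `ci_high`, `p`), `c_index`, `ph_test_p` (named vector), and
#'   `fit`.
#' @export
cox_fit <- function(records, covariates, conf_level = 0.95) {
  stopifnot(all(c("time", "event") %in% names(records)),
            all(covariates %in% names(records)))
  if (sum(records$event) < 1) {
    stop("at least one event required", call. = FALSE)
  }
  for (cv in covariates) {
    if (length(unique(records[[cv]])) < 2) {
      stop("constant covariate: ", cv, call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0)) {
    stop("Cox model failed to converge", call. = FALSE)
  }
  sm <- summary(fit, conf.int = conf_level)
  tab <- data.frame(
    term = rownames(sm$coefficients),
    hr = unname(sm$coefficients[, "exp(coef)"]),
    ci_low = unname(sm$conf.int[, 3]),
    ci_high = unname(sm$conf.int[, 4]),
    p = unname(sm$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  zph <- tryCatch(survival::cox.zph(fit, transform = "identity"),
                  error = function(e) NULL)
  ph_p <- if (is.null(zph)) NULL else {
    tb <- zph$table
    setNames(tb[rownames(tb) != "GLOBAL", "p"],
             rownames(tb)[rownames(tb) != "GLOBAL"])
  }
  structure(list(table = tab,
                 c_index = unname(fit$concordance["concordance"]),
                 ph_test_p = ph_p,
                 fit = fit),
            class = "senuro_cox")
}

#' @export
print.senuro_cox <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties)\n")
  tab <- x$table
  tab$hr <- sprintf("%.3f", tab$hr)
  tab$ci <- sprintf("%.3f-%.3f", x$table$ci_low, x$table$ci_high)
  tab$p <- format.pval(x$table$p, digits = 3)
  print(tab[, c("term", "hr", "ci", "p")], row.names = FALSE)
  cat(sprintf("Harrell c-index: %.3f\n", x$c_index))
  invisible(x)
}

#' Harrell c-index with and without a covariate set
#'
#' Fits two Cox models on the same records and returns both concordance
#' indices, quantifying the discrimination added by (for example) the
#' uCCR indicator on top of clinical covariates.
#'
#' @param records Data.frame with `time`, `event` and covariates.
#' @param covariates_with,covariates_without Covariate name vectors.
#' @return List with `c_with`, `c_without`, and both fits.
#' @export
c_index_delta <- function(records, covariates_with, covariates_without) {
  fit_with <- cox_fit(records, covariates_with)
  fit_without <- cox_fit(records, covariates_without)
  list(c_with = fit_with$c_index,
       c_without = fit_without$c_index,
       fit_with = fit_with, fit_without = fit_without)
}
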