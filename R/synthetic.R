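#' Simulation configuration
#'
#' Parameters of the matched synthetic biopsy / urine-proteome / spatial /
#' outcome generator. Defaults emulate the study conditions of a
#' secondary-care CKD cohort: ~51 biopsy participants, median senescent
#' epithelium near 5%, a urinary clusterin analogue rank-correlated with
#' tissue senescence at 0.6, a 331-protein urinary panel with 8 true
#' senescence markers, CosMx-style spatial fields, and a 3-year follow-up
#' with roughly 15% sustained renal decline and a hazard ratio of 2.2 for
#' high urinary clusterin.
#'
#' @param n_participants Number of participants.
#' @param senescence_beta_age Additive age effect (per year) on the latent
#'   logit-scale senescence.
#' @param senescence_beta_egfr Additive eGFR effect (per mL/min, negative).
#' @param senescence_sd Residual SD of the latent logit senescence.
#' @param clusterin_rho_target Target Spearman correlation between uCCR and
#'   latent senescence (Gaussian copula).
#' @param n_proteins,n_true_markers Urinary panel size and number of true
#'   senescence markers (first marker is the clusterin analogue `CLU`).
#' @param marker_rho Population Spearman targets for the markers; recycled
#'   to `n_true_markers`. Default: `clusterin_rho_target` for CLU, then an
#'   even spread 0.55-0.85.
#' @param proteome_noise_sd Log-scale measurement noise SD of protein
#'   intensities.
#' @param spatial List: `field_size` (um, square side), `n_cells`,
#'   `celltype_props` (named PT/LOH_DCT/other, sums to 1),
#'   `cdkn1a_pos_frac` (fraction of PT cells with >= 2 CDKN1A transcripts),
#'   `clu_rate_background` (CLU transcript intensity, per um^2),
#'   `clu_rate_near_pos` (additive intensity within `enrichment_radius` um
#'   of CDKN1A+ PT centroids), `enrichment_radius` (um).
#' @param outcome List: `baseline_hazard` (per day), `log_hr_uccr_high`
#'   (log hazard ratio for uCCR above `uccr_threshold`), `uccr_threshold`
#'   (ug/mmol), `censor_rate` (per day, independent censoring),
#'   `followup_days` (administrative censoring horizon),
#'   `log_hr_egfr`, `log_hr_lnacr`, `log_hr_age`, `log_hr_sbp`,
#'   `log_hr_sexF` (other covariate effects on the progression hazard).
#' @param seed Default seed used by the generators.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_participants = 51,
                       senescence_beta_age = 0.030,
                       senescence_beta_egfr = -0.012,
                       senescence_sd = 0.55,
                       clusterin_rho_target = 0.6,
                       n_proteins = 331,
                       n_true_markers = 8,
                       marker_rho = NULL,
                       proteome_noise_sd = 1,
                       spatial = list(),
                       outcome = list(),
                       seed = 1) {
  spatial_defaults <- list(
    field_size = 1000, n_cells = 3000,
    celltype_props = c(PT = 0.5, LOH_DCT = 0.3, other = 0.2),
    cdkn1a_pos_frac = 0.3,
    clu_rate_background = 0.01, clu_rate_near_pos = 0.03,
    enrichment_radius = 15
  )
  outcome_defaults <- list(
    baseline_hazard = 1.2e-4, log_hr_uccr_high = log(2.2),
    uccr_threshold = 124.5, censor_rate = 1.5e-4, followup_days = 1095,
    log_hr_egfr = log(0.979), log_hr_lnacr = log(1.254),
    log_hr_age = log(0.976), log_hr_sbp = log(1.018),
    log_hr_sexF = log(1.022)
  )
  spatial <- utils::modifyList(spatial_defaults, spatial)
  outcome <- utils::modifyList(outcome_defaults, outcome)
  if (is.null(marker_rho)) {
    marker_rho <- if (n_true_markers == 0) numeric(0) else
      c(clusterin_rho_target,
        if (n_true_markers > 1)
          seq(0.55, 0.85, length.out = n_true_markers - 1))
  }
  marker_rho <- rep_len(marker_rho, n_true_markers)

  cfg <- list(
    n_participants = n_participants,
    senescence_beta_age = senescence_beta_age,
    senescence_beta_egfr = senescence_beta_egfr,
    senescence_sd = senescence_sd,
    clusterin_rho_target = clusterin_rho_target,
    n_proteins = n_proteins, n_true_markers = n_true_markers,
    marker_rho = marker_rho,
    proteome_noise_sd = proteome_noise_sd,
    spatial = spatial, outcome = outcome, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  sp <- cfg$spatial
  if (cfg$n_participants < 1) stop("n_participants must be >= 1",
                                   call. = FALSE)
  if (cfg$n_true_markers > cfg$n_proteins) {
    stop("n_true_markers must not exceed n_proteins", call. = FALSE)
  }
  p <- sp$celltype_props
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
    stop("celltype_props must lie in [0,1] and sum to 1", call. = FALSE)
  }
  if (sp$cdkn1a_pos_frac < 0 || sp$cdkn1a_pos_frac > 1) {
    stop("cdkn1a_pos_frac must lie in [0,1]", call. = FALSE)
  }
  rates <- c(sp$clu_rate_background, sp$clu_rate_near_pos,
             cfg$outcome$baseline_hazard, cfg$outcome$censor_rate)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (abs(cfg$clusterin_rho_target) > 1) {
    stop("clusterin_rho_target must lie in [-1,1]", call. = FALSE)
  }
  invisible(cfg)
}

# Gaussian-copula coupling: given standard-normal scores z, returns a new
# standard-normal vector whose population Spearman correlation with z is
# `rho_s` (copula parameter 2*sin(pi*rho_s/6)).
copula_partner <- function(z, rho_s) {
  rg <- 2 * sin(pi * rho_s / 6)
  rg * z + sqrt(1 - rg^2) * rnorm(length(z))
}

# Normal scores of a vector (rank-based, ties broken by average rank).
normal_scores <- function(x) {
  qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Generate a synthetic biopsy cohort
#'
#' Draws participants with age, sex, blood pressure, baseline eGFR (with a
#' consistent serum creatinine via the inverted CKD-EPI equation), uACR,
#' a latent senescent-epithelium percentage that increases with age and
#' decreases with eGFR on the logit scale, and a urinary
#' clusterin-to-creatinine ratio (uCCR) coupled to latent senescence by a
#' Gaussian copula targeting `clusterin_rho_target` in Spearman terms.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed; defaults to `cfg$seed`.
#' @return Data.frame with one row per participant: `id`, `age`, `sex`,
#'   `sbp`, `dbp`, `baseline_egfr`, `serum_creatinine`, `uacr`, `uccr`,
#'   `senescence_true` (latent %, the generator truth).
#' @export
gen_cohort <- function(cfg = sim_config(), seed = cfg$seed) {
  validate_sim_config(cfg)
  n <- cfg$n_participants
  with_seed(seed, {
    age <- pmin(pmax(rnorm(n, 56, 14), 19), 81)
    sex <- ifelse(runif(n) < 0.4, "F", "M")
    sbp <- rnorm(n, 137, 21)
    dbp <- rnorm(n, 80, 13)
    egfr <- pmin(pmax(rlnorm(n, log(45), 0.55), 8), 135)
    scr <- invert_ckd_epi(egfr, age, sex)

    latent <- qlogis(0.052) +
      cfg$senescence_beta_age * (age - 56) +
      cfg$senescence_beta_egfr * (egfr - 45) +
      rnorm(n, 0, cfg$senescence_sd)
    senescence <- 100 * plogis(latent)

    z <- normal_scores(latent)
    uccr <- exp(log(60) + 1.0 * copula_partner(z, cfg$clusterin_rho_target))
    uacr <- exp(log(85) + 1.3 * copula_partner(z, 0.3))

    data.frame(
      id = sprintf("P%03d", seq_len(n)),
      age = age, sex = sex, sbp = sbp, dbp = dbp,
      baseline_egfr = egfr, serum_creatinine = scr,
      uacr = uacr, uccr = uccr,
      senescence_true = senescence,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate per-cell biopsy classification records
#'
#' Simulates the per-cell classification table of one participant's biopsy:
#' cells are split across sections, a fixed proportion are tubular
#' epithelium, and each epithelial cell is P21+/KI67- with probability
#' `senescence_pct / 100` (the remaining epithelia are mostly double
#' negative with small proliferating and double-positive fractions).
#'
#' @param senescence_pct True senescent percentage in `[0, 100]`.
#' @param n_cells Total cells across sections.
#' @param n_sections Number of biopsy sections.
#' @param seed Seed.
#' @param participant_id Identifier stamped on the records.
#' @param p_epithelial Probability a cell is tubular epithelium.
#' @param clusterin Also draw a cytoplasmic clusterin status, with the
#'   given odds ratio of clusterin positivity for P21+ vs P21- cells.
#' @param clusterin_or Odds ratio used when `clusterin = TRUE`.
#' @return Data.frame of cell records (see [read_cell_table()] schema).
#' @export
gen_biopsy_cells <- function(senescence_pct, n_cells, n_sections = 2,
                             seed = 1, participant_id = "P001",
                             p_epithelial = 0.8, clusterin = FALSE,
                             clusterin_or = 2.14) {
  stopifnot(senescence_pct >= 0, senescence_pct <= 100, n_cells >= 1)
  with_seed(seed, {
    section <- sample(sprintf("S%d", seq_len(n_sections)), n_cells,
                      replace = TRUE)
    epithelial <- runif(n_cells) < p_epithelial
    ps <- senescence_pct / 100
    # class probabilities for epithelia: SEN exactly ps, remainder split
    rest <- 1 - ps
    probs <- c(SEN = ps, PROLIF = 0.05 * rest, DOUBLE_POS = 0.02 * rest,
               DOUBLE_NEG = 0.93 * rest)
    cls <- sample(names(probs), n_cells, replace = TRUE, prob = probs)
    # non-epithelial cells get an independent draw (mostly negative)
    cls_ne <- sample(names(probs), n_cells, replace = TRUE,
                     prob = c(0.03, 0.07, 0.01, 0.89))
    cls[!epithelial] <- cls_ne[!epithelial]
    p21 <- cls %in% c("SEN", "DOUBLE_POS")
    ki67 <- cls %in% c("PROLIF", "DOUBLE_POS")
    out <- data.frame(
      participant_id = participant_id,
      section_id = section,
      cell_id = sprintf("%s_C%05d", participant_id, seq_len(n_cells)),
      epithelial = epithelial,
      p21_nuclear = p21,
      ki67_nuclear = ki67,
      stringsAsFactors = FALSE
    )
    if (clusterin) {
      base_p <- 0.25                       # clusterin rate in P21- cells
      odds <- clusterin_or * base_p / (1 - base_p)
      p_pos <- ifelse(p21, odds / (1 + odds), base_p)
      out$clusterin_cytoplasmic <- runif(n_cells) < p_pos
    }
    out
  })
}

#' Generate a synthetic urinary proteome
#'
#' Builds a sample-by-protein intensity panel in which `n_true_markers`
#' proteins (the first named `CLU`) depend monotonically on participant
#' senescence through a Gaussian copula at the configured population
#' Spearman targets, and the remaining proteins are independent noise.
#' Per-sample urine-dilution and instrument-gain factors multiply the raw
#' intensities; the ADH spike-in carries the gain only and urinary
#' creatinine the dilution only, so spike-in-then-creatinine normalisation
#' removes both. A small fraction of proteins is "peptide-poor" (max unique
#' peptides < 2) to exercise the identification filter; markers always
#' pass it.
#'
#' @param senescence Numeric vector of participant senescence percentages
#'   (e.g. `gen_cohort(cfg)$senescence_true`).
#' @param cfg A [sim_config()].
#' @param seed Seed.
#' @return List with `samples` (a [proteomics_samples()]) and `truth`
#'   (data.frame `protein`, `is_marker`, `rho_target`, `in_sasp`).
#' @export
gen_proteome <- function(senescence, cfg = sim_config(), seed = cfg$seed) {
  validate_sim_config(cfg)
  n <- length(senescence)
  n_prot <- cfg$n_proteins
  n_mark <- cfg$n_true_markers
  with_seed(seed, {
    proteins <- c(if (n_mark > 0) c("CLU", sprintf("MARK%02d",
                                                   seq_len(n_mark))[-1]),
                  sprintf("PROT%04d", seq_len(n_prot - n_mark)))
    z <- normal_scores(senescence)
    sdlog <- cfg$proteome_noise_sd
    log_int <- matrix(rnorm(n * n_prot, 0, sdlog), n, n_prot,
                      dimnames = list(sprintf("P%03d", seq_len(n)), proteins))
    if (n_mark > 0) {
      for (j in seq_len(n_mark)) {
        if (sdlog == 0) {
          log_int[, j] <- z
        } else {
          log_int[, j] <- sdlog * copula_partner(z, cfg$marker_rho[j])
        }
      }
    }
    base_abundance <- rnorm(n_prot, 8, 1.5)      # per-protein mean log level
    log_int <- sweep(log_int, 2, base_abundance, "+")

    dilution <- rlnorm(n, 0, 0.5)                # urine concentration
    gain <- rlnorm(n, 0, 0.3)                    # instrument response
    intensities <- exp(log_int) * dilution * gain
    adh <- 5e4 * gain * rlnorm(n, 0, 0.02)
    creatinine <- 8 * dilution

    peptide_poor <- rep(FALSE, n_prot)
    if (n_prot > n_mark) {
      idx <- n_mark + seq_len(n_prot - n_mark)
      peptide_poor[sample(idx, size = round(0.05 * n_prot))] <- TRUE
    }
    up <- matrix(rpois(n * n_prot, 4) + 1L, n, n_prot,
                 dimnames = dimnames(log_int))
    up[, peptide_poor] <- matrix(rbinom(n * sum(peptide_poor), 1, 0.3),
                                 n, sum(peptide_poor))

    truth <- data.frame(
      protein = proteins,
      is_marker = seq_len(n_prot) <= n_mark,
      rho_target = c(cfg$marker_rho, rep(0, n_prot - n_mark)),
      stringsAsFactors = FALSE
    )
    truth$in_sasp <- truth$protein %in% sasp_reference()
    list(
      samples = proteomics_samples(intensities, adh, creatinine, up),
      truth = truth
    )
  })
}

#' Generate a synthetic spatial transcriptomics field
#'
#' Scatters typed cells uniformly on a square field, assigns per-cell
#' CDKN1A counts so that `cdkn1a_pos_frac` of proximal tubule (PT) cells
#' carry >= 2 transcripts, and lays down a CLU transcript point cloud as a
#' homogeneous Poisson process of intensity `clu_rate_background` plus an
#' additive intensity `clu_rate_near_pos` within `enrichment_radius` um of
#' each CDKN1A+ PT centroid. Per-cell CLU counts (for differential
#' expression) are the transcripts within 7 um of each centroid.
#'
#' @param cfg A [sim_config()] (the `spatial` sublist is used).
#' @param seed Seed.
#' @return A [spatial_field()] with genes `CDKN1A` and `CLU` counted.
#' @export
gen_spatial <- function(cfg = sim_config(), seed = cfg$seed) {
  validate_sim_config(cfg)
  sp <- cfg$spatial
  with_seed(seed, {
    n <- sp$n_cells
    L <- sp$field_size
    cells <- data.frame(
      cell_id = sprintf("C%05d", seq_len(n)),
      x = runif(n, 0, L), y = runif(n, 0, L),
      cell_type = sample(names(sp$celltype_props), n, replace = TRUE,
                         prob = sp$celltype_props),
      stringsAsFactors = FALSE
    )
    # CDKN1A counts: positives (>= 2) among PT at the configured fraction;
    # other cells and PT negatives carry 0-1 stray transcripts
    cdkn1a <- rbinom(n, 1, 0.15)
    is_pt <- cells$cell_type == "PT"
    pos <- is_pt & runif(n) < sp$cdkn1a_pos_frac
    cdkn1a[pos] <- 2L + rpois(sum(pos), 2)

    # background CLU point process
    n_bg <- rpois(1, sp$clu_rate_background * L^2)
    tx <- data.frame(gene = character(0), x = numeric(0), y = numeric(0))
    if (n_bg > 0) {
      tx <- data.frame(gene = "CLU", x = runif(n_bg, 0, L),
                       y = runif(n_bg, 0, L), stringsAsFactors = FALSE)
    }
    # additive bump: per CDKN1A+ PT cell, Poisson points uniform in a disk
    if (sp$clu_rate_near_pos > 0 && any(pos)) {
      r_e <- sp$enrichment_radius
      n_extra <- rpois(sum(pos), sp$clu_rate_near_pos * pi * r_e^2)
      centre_x <- rep(cells$x[pos], n_extra)
      centre_y <- rep(cells$y[pos], n_extra)
      m <- sum(n_extra)
      if (m > 0) {
        rad <- r_e * sqrt(runif(m))
        th <- runif(m, 0, 2 * pi)
        tx <- rbind(tx, data.frame(gene = "CLU",
                                   x = centre_x + rad * cos(th),
                                   y = centre_y + rad * sin(th),
                                   stringsAsFactors = FALSE))
      }
    }
    # per-cell CLU counts: transcripts within 7 um of the centroid
    clu_counts <- if (nrow(tx) > 0) {
      annulus_counts_per_cell(cells$x, cells$y, tx$x, tx$y, radius = 7)
    } else integer(n)
    counts <- cbind(CDKN1A = cdkn1a, CLU = clu_counts)
    spatial_field(cells, counts, tx)
  })
}

# Number of points within `radius` of each centre (chunked).
annulus_counts_per_cell <- function(cx, cy, px, py, radius) {
  out <- integer(length(cx))
  if (length(px) == 0) return(out)
  chunk <- max(1L, floor(4e6 / length(px)))
  for (start in seq(1L, length(cx), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(cx))
    d2 <- outer(cx[idx], px, "-")^2 + outer(cy[idx], py, "-")^2
    out[idx] <- rowSums(d2 <= radius^2)
  }
  out
}

#' Generate longitudinal outcomes for a cohort
#'
#' Simulates progression under a proportional-hazards model: the hazard of
#' sustained renal decline is `baseline_hazard * exp(lp)` with linear
#' predictor combining the binary high-uCCR indicator
#' (`log_hr_uccr_high`), baseline eGFR, ln(uACR), age, systolic blood
#' pressure and sex at the configured log hazard ratios (covariates
#' centred at typical cohort values). Censoring is independent
#' (exponential at `censor_rate`) with administrative censoring at
#' `followup_days`; a small death rate censors as well. eGFR visit series
#' are generated to match: progressors decline to 55% of baseline by their
#' event day and remain there, non-progressors drift mildly.
#'
#' @param participants Data.frame from [gen_cohort()].
#' @param cfg A [sim_config()] (the `outcome` sublist is used).
#' @param seed Seed.
#' @return List with `records` (data.frame `id`, `time`, `event`,
#'   `uccr_high`, `baseline_egfr`, `ln_acr`, `age`, `sbp`, `sex`,
#'   `true_event_day`) and `egfr_series` (long data.frame `id`, `day`,
#'   `egfr`).
#' @export
gen_outcomes <- function(participants, cfg = sim_config(), seed = cfg$seed) {
  validate_sim_config(cfg)
  oc <- cfg$outcome
  n <- nrow(participants)
  with_seed(seed, {
    uccr_high <- participants$uccr > oc$uccr_threshold
    ln_acr <- log(pmax(participants$uacr, 0.1))
    lp <- oc$log_hr_uccr_high * uccr_high +
      oc$log_hr_egfr * (participants$baseline_egfr - 45) +
      oc$log_hr_lnacr * (ln_acr - log(85)) +
      oc$log_hr_age * (participants$age - 56) +
      oc$log_hr_sbp * (participants$sbp - 137) +
      oc$log_hr_sexF * (participants$sex == "F")
    t_event <- rexp(n, rate = oc$baseline_hazard * exp(lp))
    t_cens <- if (oc$censor_rate > 0) rexp(n, oc$censor_rate) else Inf
    t_death <- rexp(n, 4e-5)
    t_obs_cens <- pmin(t_cens, t_death, oc$followup_days)
    event <- t_event <= t_obs_cens
    time <- pmax(pmin(t_event, t_obs_cens), 1)

    records <- data.frame(
      id = participants$id,
      time = time, event = event,
      uccr_high = uccr_high,
      baseline_egfr = participants$baseline_egfr,
      ln_acr = ln_acr,
      age = participants$age,
      sbp = participants$sbp,
      sex = participants$sex,
      true_event_day = ifelse(event, time, NA_real_),
      stringsAsFactors = FALSE
    )

    visit_days <- seq(0, oc$followup_days, by = 120)
    series <- lapply(seq_len(n), function(i) {
      base <- participants$baseline_egfr[i]
      days <- visit_days[visit_days <= max(time[i] + 240,
                                           360)]
      if (event[i]) {
        frac <- pmin(days / max(time[i], 1), 1)
        egfr <- base * (1 - 0.45 * frac)
      } else {
        egfr <- base * (1 - 0.08 * days / oc$followup_days)
      }
      egfr <- pmax(egfr + rnorm(length(days), 0, 0.015 * base), 4)
      data.frame(id = participants$id[i], day = days, egfr = egfr,
                 stringsAsFactors = FALSE)
    })
    list(records = records, egfr_series = do.call(rbind, series))
  })
}
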