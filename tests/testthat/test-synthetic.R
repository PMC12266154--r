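test_that("sim_config validates proportions, rates and marker counts", {
  expect_error(sim_config(n_true_markers = 400), "n_true_markers")
  expect_error(sim_config(spatial = list(celltype_props =
                                           c(PT = 0.7, LOH_DCT = 0.7,
                                             other = -0.4))),
               "celltype_props")
  expect_error(sim_config(spatial = list(clu_rate_background = -1)),
               "rates")
  expect_error(sim_config(clusterin_rho_target = 1.5), "rho_target")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_length(cfg$marker_rho, cfg$n_true_markers)
})

test_that("all generators are deterministic given the seed", {
  cfg <- sim_config(n_participants = 40,
                    spatial = list(n_cells = 100, field_size = 200))
  expect_identical(gen_cohort(cfg, seed = 7), gen_cohort(cfg, seed = 7))
  expect_identical(gen_biopsy_cells(7, 200, seed = 7),
                   gen_biopsy_cells(7, 200, seed = 7))
  coh <- gen_cohort(cfg, seed = 7)
  expect_identical(gen_proteome(coh$senescence_true, cfg, seed = 7),
                   gen_proteome(coh$senescence_true, cfg, seed = 7))
  f1 <- gen_spatial(cfg, seed = 7)
  f2 <- gen_spatial(cfg, seed = 7)
  expect_identical(f1$cells, f2$cells)
  expect_identical(f1$transcripts, f2$transcripts)
  expect_identical(gen_outcomes(coh, cfg, seed = 7),
                   gen_outcomes(coh, cfg, seed = 7))
  # and different seeds differ
  expect_false(identical(gen_cohort(cfg, seed = 7), gen_cohort(cfg, seed = 8)))
})

test_that("generators restore the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_cohort(sim_config(n_participants = 10), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("cohort uCCR hits the target rank correlation at large n", {
  cfg <- sim_config(n_participants = 2000)
  coh <- gen_cohort(cfg, seed = 42)
  rho <- cor(coh$uccr, coh$senescence_true, method = "spearman")
  expect_lt(abs(rho - cfg$clusterin_rho_target), 0.05)
})

test_that("zero betas decouple senescence from age and eGFR", {
  cfg <- sim_config(n_participants = 2000, senescence_beta_age = 0,
                    senescence_beta_egfr = 0)
  coh <- gen_cohort(cfg, seed = 11)
  expect_lt(abs(cor(coh$senescence_true, coh$age, method = "spearman")),
            0.06)
  expect_lt(abs(cor(coh$senescence_true, coh$baseline_egfr,
                    method = "spearman")), 0.06)
})

test_that("cohort serum creatinine is consistent with baseline eGFR", {
  coh <- gen_cohort(sim_config(n_participants = 50), seed = 19)
  back <- ckd_epi_2009(coh$serum_creatinine, coh$age, coh$sex)
  expect_equal(back, coh$baseline_egfr, tolerance = 1e-8)
})

test_that("biopsy generator hits the requested senescent fraction", {
  z <- gen_biopsy_cells(0, 500, seed = 1)
  expect_equal(senescent_fraction(z)$pct_senescent, 0)

  all_sen <- gen_biopsy_cells(100, 500, seed = 2)
  expect_equal(senescent_fraction(all_sen)$pct_senescent, 100)

  ten <- gen_biopsy_cells(10, 10000, seed = 3)
  r <- senescent_fraction(ten)
  sd3 <- 3 * sqrt(0.1 * 0.9 / r$n_epithelial) * 100
  expect_lt(abs(r$pct_senescent - 10), sd3)
})

test_that("noiseless proteome markers give perfect rank correlation", {
  coh <- gen_cohort(sim_config(n_participants = 30), seed = 4)
  cfg0 <- sim_config(n_participants = 30, n_proteins = 20,
                     n_true_markers = 3, proteome_noise_sd = 0)
  pr <- gen_proteome(coh$senescence_true, cfg0, seed = 4)
  norm <- normalize_proteome(pr$samples)
  out <- correlation_screen(norm, coh$senescence_true)
  for (p in pr$truth$protein[pr$truth$is_marker]) {
    expect_equal(out$rho[out$protein == p], 1)
  }
})

test_that("proteome truth table flags CLU as a SASP marker", {
  coh <- gen_cohort(sim_config(n_participants = 20), seed = 6)
  pr <- gen_proteome(coh$senescence_true, sim_config(n_participants = 20),
                     seed = 6)
  truth <- pr$truth
  expect_equal(sum(truth$is_marker), 8)
  expect_true(truth$in_sasp[truth$protein == "CLU"])
  expect_true(all(peptide_filter(pr$samples) != "" ))
  # markers always survive the peptide filter
  expect_true(all(truth$protein[truth$is_marker] %in%
                    peptide_filter(pr$samples)))
})

test_that("null spatial fields show no radial structure", {
  cfg <- sim_config(spatial = list(n_cells = 1500, field_size = 800,
                                   clu_rate_near_pos = 0))
  f <- gen_spatial(cfg, seed = 13)
  q <- classify_positive(f, "CDKN1A", cell_type = "PT")
  prof <- radial_enrichment(f, q, "CLU", n_background = nrow(f$cells),
                            seed = 13)
  expect_lt(mean(abs(prof$e)), 0.3)   # single-field bound, looser than the
                                      # 50-replicate calibration check
})

test_that("enriched fields concentrate signal inside the bump radius", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(spatial = list(
      n_cells = 1200, field_size = 700,
      clu_rate_background = 0.005, clu_rate_near_pos = 0.05,  # 10x contrast
      enrichment_radius = 15
    ))
    f <- gen_spatial(cfg, seed = 500 + s)
    q <- classify_positive(f, "CDKN1A", cell_type = "PT")
    prof <- radial_enrichment(f, q, "CLU", n_background = nrow(f$cells),
                              seed = s)
    near <- mean(prof$e[prof$radius <= 15])
    far <- mean(prof$e[prof$radius > 30])
    near > far
  }, logical(1))
  expect_true(all(hits))
})

test_that("null hazard gives calibrated log-rank rejections", {
  cfg <- sim_config(n_participants = 300,
                    outcome = list(log_hr_uccr_high = 0))
  p_vals <- vapply(1:30, function(s) {
    coh <- gen_cohort(cfg, seed = 700 + s)
    oc <- gen_outcomes(coh, cfg, seed = 700 + s)
    r <- oc$records
    km_logrank(r$time, r$event, r$uccr_high)$p
  }, numeric(1))
  # ~5% expected at alpha = 0.05; allow 3 binomial SDs
  expect_lte(sum(p_vals < 0.05), 0.05 * 30 + 3 * sqrt(30 * 0.05 * 0.95))
})

test_that("outcome generator produces usable eGFR trajectories", {
  cfg <- sim_config(n_participants = 120)
  coh <- gen_cohort(cfg, seed = 9)
  oc <- gen_outcomes(coh, cfg, seed = 9)
  expect_setequal(unique(oc$egfr_series$id), coh$id)
  expect_true(all(oc$records$time > 0))

  # derived endpoints broadly agree with the generator's event labels
  parts <- data.frame(id = coh$id, baseline_egfr = coh$baseline_egfr,
                      last_followup = cfg$outcome$followup_days,
                      stringsAsFactors = FALSE)
  ep <- derive_endpoints(oc$egfr_series, parts)
  agree <- mean(ep$event == oc$records$event)
  expect_gt(agree, 0.85)
})
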