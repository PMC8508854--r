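# Synthetic-data generator: manifest composition, cohort construction,
# planted effects, determinism.

test_that("manifest feature counts are rounding-exact fractions", {
  cfg <- generator_config(n_probes = 10, frac_sex_chrom = 0.2,
                          frac_snp_flag = 0.1, n_differential = 0,
                          n_predictive = 0, seed = 1)
  man <- generate_manifest(cfg)
  expect_equal(nrow(man), 10)
  expect_equal(sum(man$chrom %in% c("chrX", "chrY")), 2)
  expect_equal(sum(man$snp_flag), 1)
  expect_false(any(man$snp_flag & man$chrom %in% c("chrX", "chrY")))

  cfg2 <- generator_config(n_probes = 20000, frac_type2 = 0.84, seed = 2)
  man2 <- generate_manifest(cfg2)
  expect_equal(sum(man2$design_type == "II"), 16800)
  expect_false(any(duplicated(man2$probe_id)))
  expect_true(all(man2$chrom %in% paste0("chr", c(1:22, "X", "Y"))))
})

test_that("gene annotation gives the gene-summary stage multi-probe genes", {
  man <- generate_manifest(generator_config(n_probes = 5000, seed = 3))
  sizes <- table(man$gene[man$gene != ""])
  expect_gte(mean(sizes >= 4), 0.10)
})

test_that("generators are pure functions of config and seed", {
  cfg <- generator_config(n_probes = 300, seed = 7)
  expect_identical(generate_manifest(cfg), generate_manifest(cfg))
  man <- generate_manifest(cfg)
  c1 <- generate_cohort(cfg, man)
  c2 <- generate_cohort(cfg, man)
  expect_identical(c1, c2)
  expect_identical(generate_betas(man, c1$sheet, c1$truth, cfg),
                   generate_betas(man, c1$sheet, c1$truth, cfg))
  # a different seed changes the data
  cfg2 <- generator_config(n_probes = 300, seed = 8)
  expect_false(identical(generate_manifest(cfg2), man))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(frac_sex_chrom = 1.2), "configuration error")
  expect_error(generator_config(within_subject_corr = 1), "configuration")
  expect_error(generator_config(beta_precision = 0), "configuration")
  expect_error(generator_config(n_probes = 10, n_differential = 20),
               "configuration")
})

test_that("cohort labels agree with the metabolic classification", {
  sim <- small_sim(seed = 5, n_probes = 200)
  sheet <- sim$sheet
  expect_equal(nrow(sheet), 36)
  expect_equal(length(unique(sheet$subject_id)), 18)
  status <- classify_metabolic_status(sheet)
  base <- sheet$timepoint == "baseline"
  expect_true(all(status[base] == "MHO"))
  fup_stable <- !base & sheet$group == "stable_MHO"
  fup_unstable <- !base & sheet$group == "unstable_MHO"
  expect_true(all(status[fup_stable] == "MHO"))
  expect_true(all(status[fup_unstable] == "MUO"))
  # each subject appears once per timepoint, group constant within subject
  expect_true(all(table(sheet$subject_id, sheet$timepoint) == 1))
  expect_true(all(tapply(sheet$group, sheet$subject_id,
                         function(g) length(unique(g))) == 1))
})

test_that("metabolic criteria follow the boundary-inclusive rule", {
  row <- function(glu = 90, tg = 100, hdl = 60, sbp = 120, dbp = 75,
                  sex = "F", meds = FALSE) {
    data.frame(fasting_glucose = glu, triglycerides = tg, hdl = hdl,
               sbp = sbp, dbp = dbp, sex = sex, on_treatment = meds)
  }
  expect_equal(classify_metabolic_status(row()), "MHO")
  expect_equal(classify_metabolic_status(
    row(glu = 108, sbp = 154, dbp = 90, hdl = 54)), "MUO")
  # boundaries are inclusive: glucose exactly 100 counts, one criterion only
  expect_equal(count_metabolic_criteria(row(glu = 100)), 1L)
  expect_equal(classify_metabolic_status(row(glu = 100)), "MHO")
  expect_equal(count_metabolic_criteria(row(sbp = 135)), 1L)
  expect_equal(count_metabolic_criteria(row(dbp = 85)), 1L)
  expect_equal(count_metabolic_criteria(row(tg = 150)), 1L)
  # HDL threshold is sex-specific
  expect_equal(count_metabolic_criteria(row(hdl = 45, sex = "F")), 1L)
  expect_equal(count_metabolic_criteria(row(hdl = 45, sex = "M")), 0L)
  expect_error(classify_metabolic_status(row()[, -1]), "missing covariate")
})

test_that("beta matrices respect bounds, planted effects and correlation", {
  cfg <- generator_config(n_probes = 4000, n_differential = 60,
                          delta_beta = 0.15, seed = 11)
  sim <- simulate_cohort(cfg)
  b <- as.matrix(sim$beta_baseline[, -1])
  expect_true(all(b > 0 & b < 1))

  grp <- sim$sheet$group[match(colnames(b), sim$sheet$sample_id)]
  planted <- sim$truth$differential
  for (tp in c("beta_baseline", "beta_followup")) {
    m <- as.matrix(sim[[tp]][, -1])
    rownames(m) <- sim[[tp]]$probe_id
    d <- rowMeans(m[planted$probe_id, grp == "stable_MHO"]) -
      rowMeans(m[planted$probe_id, grp == "unstable_MHO"])
    # sign matches the planted direction at both time points
    expect_true(all(sign(d) == sign(planted$delta_beta)))
    expect_gte(mean(abs(d)), 0.10)
    expect_lte(mean(abs(d)), 0.20)
  }

  # within-subject correlation of M-values across time points
  mb <- as.matrix(beta_to_m(sim$beta_baseline)[, -1])
  mf <- as.matrix(beta_to_m(sim$beta_followup)[, -1])
  subj <- sub("_baseline", "", colnames(mb))
  mf <- mf[, match(paste0(subj, "_followup"), colnames(mf))]
  rho <- vapply(seq_len(nrow(mb)),
                function(i) stats::cor(mb[i, ], mf[i, ]), numeric(1))
  expect_gt(mean(rho, na.rm = TRUE), 0.55)
  expect_lt(mean(rho, na.rm = TRUE), 0.85)
})

test_that("detection p-values fail at about the configured rate", {
  cfg <- generator_config(n_probes = 5000, detection_fail_rate = 0.02,
                          seed = 13)
  sim <- simulate_cohort(cfg)
  d <- as.matrix(sim$detp_baseline[, -1])
  expect_equal(mean(d > 0.01), 0.02, tolerance = 0.15)
  expect_true(all(d >= 0 & d <= 0.5))
})
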