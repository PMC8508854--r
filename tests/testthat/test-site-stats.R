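# Kruskal-Wallis statistics, site validation, gene summaries and
# group descriptives.

test_that("Kruskal-Wallis matches hand computation and base R", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # ranks 1..6, rank sums 6 and 15: H = 12/42 * (36/3 + 225/3) - 21 = 27/7
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$p, stats::pchisq(27 / 7, 1, lower.tail = FALSE))

  set.seed(2)
  for (i in 1:40) {
    k <- sample(2:3, 1)
    g <- rep(seq_len(k), times = sample(3:8, k, replace = TRUE))
    x <- sample(1:6, length(g), replace = TRUE)   # heavy ties
    if (length(unique(x)) == 1) next
    ours <- kruskal_wallis(x, g)
    ref <- stats::kruskal.test(x, factor(g))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis degenerate and error contracts hold", {
  expect_equal(kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3)),
               list(H = 0, p = 1))
  kw <- kruskal_wallis(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(kw$H, 0, tolerance = 1e-12)
  expect_equal(kw$p, 1, tolerance = 1e-12)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), ">= 2 non-empty groups")
})

test_that("chi-square p agrees with the permutation oracle at small n", {
  set.seed(7)
  diffs <- numeric(15)
  for (i in 1:15) {
    n1 <- sample(5:8, 1)
    n2 <- sample(5:8, 1)
    x <- c(stats::rnorm(n1), stats::rnorm(n2, sample(0:1, 1)))
    if (i %% 3 == 0) x <- round(x)        # induce ties
    g <- rep(c("a", "b"), c(n1, n2))
    p_chi <- kruskal_wallis(x, g)$p
    p_perm <- perm_kw_p(x, g, n_perm = 4000)
    diffs[i] <- abs(p_chi - p_perm)
  }
  # the chi-square approximation is coarse at these n; the check guards
  # against implementation errors, not approximation error
  expect_lt(stats::median(diffs), 0.06)
  expect_lt(max(diffs), 0.20)
})

test_that("validate_sites keeps only sites significant at both time points", {
  sim <- small_sim(seed = 41, n_probes = 1200, n_differential = 20,
                   n_predictive = 5, predictive_log_or = 3)
  mb <- beta_to_m(sim$beta_baseline)
  mf <- beta_to_m(sim$beta_followup)

  # predictive probes are differential at baseline only: never validated
  pred <- sim$truth$predictive$probe_id
  diff <- sim$truth$differential$probe_id
  v <- validate_sites(c(pred, diff), sim$beta_baseline, sim$beta_followup,
                      mb, mf, sim$sheet)
  expect_true(all(v$probe_id %in% diff))

  # direction matches the planted sign for every recovered site
  planted_sign <- sign(sim$truth$differential$delta_beta[
    match(v$probe_id, diff)])
  expect_true(all(v$direction[planted_sign > 0] == "hyper_in_stable"))
  expect_true(all(v$direction[planted_sign < 0] == "hypo_in_stable"))
  expect_true(all(sign(v$delta_beta_baseline) == planted_sign))
  expect_true(all(sign(v$delta_beta_followup) == planted_sign))

  # alpha = 1 without concordance filter returns the full input set
  all_ids <- sort(c(pred, diff))
  v_all <- validate_sites(all_ids, sim$beta_baseline, sim$beta_followup,
                          mb, mf, sim$sheet, alpha = 1,
                          require_concordance = FALSE)
  expect_setequal(v_all$probe_id, all_ids)

  # sorted by min p then probe id
  expect_false(is.unsorted(pmin(v$p_baseline, v$p_followup)))
})

test_that("gene summaries report differential fractions per gene", {
  sim <- small_sim(seed = 43, n_probes = 1500, n_differential = 30,
                   n_predictive = 0)
  mb <- beta_to_m(sim$beta_baseline)
  mf <- beta_to_m(sim$beta_followup)
  v <- validate_sites(sim$truth$differential$probe_id,
                      sim$beta_baseline, sim$beta_followup, mb, mf,
                      sim$sheet)
  gs <- gene_summary(v, sim$beta_baseline, sim$beta_followup, mb, mf,
                     sim$sheet, sim$manifest)
  expect_true(all(gs$fraction_differential >= 0 &
                    gs$fraction_differential <= 100))
  expect_true(all(gs$n_differential <= gs$n_cpgs_on_array))
  expect_equal(gs$fraction_differential,
               100 * gs$n_differential / gs$n_cpgs_on_array)
  # every validated genic site's gene is present
  hit <- sim$manifest$gene[match(v$probe_id, sim$manifest$probe_id)]
  expect_setequal(gs$gene, unique(hit[hit != ""]))
  # genes whose single CpG is the validated one report 100%
  single <- gs[gs$n_cpgs_on_array == 1 &
                 gs$gene %in% hit, ]
  if (nrow(single) > 0) {
    expect_true(all(single$fraction_differential == 100))
  }
})

test_that("group descriptives use the documented tests and switches", {
  sim <- small_sim(seed = 44, n_probes = 200)
  sheet <- sim$sheet

  # constant covariate: p = 1 and zero SD
  sheet$constant <- 5
  d <- group_descriptives(sheet)
  cc <- d[d$variable == "constant", ]
  expect_true(all(cc$p_value == 1))
  expect_true(all(cc$sd_group1 == 0))

  # planted group indicator: strongly significant
  sheet$indicator <- as.numeric(sheet$group == "stable_MHO") +
    stats::rnorm(nrow(sheet), 0, 0.01)
  d2 <- group_descriptives(sheet)
  expect_true(all(d2$p_value[d2$variable == "indicator"] < 0.01))

  # categorical 0/9 vs 5/9 takes the Fisher path (expected counts < 5)
  sheet$flag <- FALSE
  sheet$flag[sheet$group == "unstable_MHO" &
               sheet$subject_id %in% sprintf("S%02d", 10:14)] <- TRUE
  d3 <- group_descriptives(sheet, categorical = c("flag"))
  expect_true(all(d3$test[d3$variable == "flag"] == "fisher"))
  expect_equal(d3$stat_group2[d3$variable == "flag" &
                                d3$timepoint == "baseline"],
               100 * 5 / 9, tolerance = 1e-9)
})

test_that("per-site type I error is calibrated on null data", {
  sim <- small_sim(seed = 45, n_probes = 5000, n_differential = 0,
                   delta_beta = 0, n_predictive = 0, predictive_log_or = 0)
  m <- beta_to_m(sim$beta_baseline)
  mm <- as.matrix(m[, -1])
  grp <- sim$sheet$group[match(colnames(mm), sim$sheet$sample_id)]
  kw <- methmarker:::kw_rows(mm, grp)
  rate <- mean(kw$p < 0.05)
  band <- 2.576 * sqrt(0.05 * 0.95 / 5000)
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
})
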