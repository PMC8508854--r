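# Independent oracles and small fixtures used across test files.

# Permutation oracle for the Kruskal-Wallis test: permutes group labels and
# recomputes H by direct rank arithmetic (no tie correction needed for the
# comparison because the H statistic under the same data has the same ties;
# the correction cancels in the >= comparison, but we recompute it anyway).
perm_kw_p <- function(values, groups, n_perm = 10000) {
  h_of <- function(g) {
    r <- rank(values)
    n <- length(values)
    rs <- tapply(r, g, sum)
    ng <- tabulate(factor(g))
    h <- 12 / (n * (n + 1)) * sum(rs^2 / ng) - 3 * (n + 1)
    tie <- table(r)
    den <- 1 - sum(tie^3 - tie) / (n^3 - n)
    if (den <= 0) 0 else h / den
  }
  h_obs <- h_of(groups)
  exceed <- vapply(seq_len(n_perm), function(i) {
    h_of(sample(groups)) >= h_obs - 1e-12
  }, logical(1))
  (1 + sum(exceed)) / (n_perm + 1)
}

# Brute-force PCA oracle: eigendecomposition of the sample covariance of a
# samples x variables matrix.
pca_oracle <- function(x) {
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-10
  list(values = ev$values[keep],
       vectors = ev$vectors[, keep, drop = FALSE])
}

# Ten-probe filtering fixture: 2 probes on chrX, 1 autosomal SNP-flagged
# probe, 1 autosomal probe failing detection in 2 of 10 samples, 6 clean.
make_filter_fixture <- function() {
  ids <- sprintf("cg%08d", 1:10)
  manifest <- tibble::tibble(
    probe_id = ids,
    chrom = c("chrX", "chrX", rep("chr1", 8)),
    pos = 1:10 * 100L,
    gene = "",
    design_type = "II",
    snp_flag = c(FALSE, FALSE, TRUE, rep(FALSE, 7))
  )
  samples <- paste0("s", 1:10)
  bmat <- matrix(0.5, 10, 10, dimnames = list(ids, samples))
  dmat <- matrix(0.001, 10, 10, dimnames = list(ids, samples))
  dmat[4, 1:2] <- 0.5                     # probe 4 fails in 2/10 samples
  to_tbl <- function(m) {
    dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)),
                     tibble::as_tibble(m))
  }
  list(beta = to_tbl(bmat), detp = to_tbl(dmat), manifest = manifest)
}

# Small simulated study shared by several tests.
small_sim <- function(seed = 42, n_probes = 2000, ...) {
  simulate_cohort(generator_config(n_probes = n_probes, seed = seed, ...))
}

# A quiet BMIQ wrapper: EM convergence warnings are exercised in their own
# test; elsewhere they are noise.
bmiq_quiet <- function(...) suppressWarnings(bmiq_normalize(...))

# A small fitted biomarker model and site table for plot-method tests.
sim_biomarker_plot_data <- function() {
  set.seed(77)
  x <- matrix(stats::rnorm(600), 100, 6,
              dimnames = list(NULL, sprintf("cg%02d", 1:6)))
  y <- stats::rbinom(100, 1, stats::plogis(1.5 * x[, 1]))
  fit <- backward_stepwise(as.data.frame(x), y)
  sites <- tibble::tibble(
    probe_id = c("cg01", "cg02"),
    direction = c("hyper_in_stable", "hypo_in_stable"),
    delta_beta_baseline = c(0.1, -0.12),
    delta_beta_followup = c(0.09, -0.11)
  )
  list(fit = fit, sites = sites)
}
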