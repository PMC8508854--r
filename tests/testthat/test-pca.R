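# PCA fit, variable contributions and the two-stage selection rules.

rand_m <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * p), p, n,
              dimnames = list(sprintf("p%04d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)),
                   tibble::as_tibble(m))
}

test_that("a single varying probe owns the first component", {
  tb <- tibble::tibble(probe_id = c("a", "b", "c"),
                       s1 = c(1, 0.5, 0.5), s2 = c(2, 0.5, 0.5),
                       s3 = c(3, 0.5, 0.5), s4 = c(4, 0.5, 0.5))
  p <- pca_fit(tb)
  expect_equal(p$explained_fraction[1], 1)
  expect_equal(abs(p$loadings["a", 1]), 1)
  vc <- variable_contributions(p)
  expect_equal(vc$PC1[vc$probe_id == "a"], 100)
})

test_that("fit matches the brute-force covariance eigendecomposition", {
  for (seed in 1:5) {
    tb <- rand_m(n = 20, p = 50, seed = seed)
    fit <- pca_fit(tb)
    x <- t(as.matrix(tb[, -1]))
    x <- sweep(x, 2, colMeans(x), "-")
    or <- pca_oracle(x)
    k <- length(or$values)
    expect_equal(fit$eigenvalues[1:k], or$values, tolerance = 1e-8)
    for (j in 1:k) {
      expect_equal(abs(sum(fit$loadings[, j] * or$vectors[, j])), 1,
                   tolerance = 1e-8)
    }
    expect_equal(unname(colSums(fit$contributions)),
                 rep(100, ncol(fit$contributions)), tolerance = 1e-8)
    expect_true(all(diff(fit$eigenvalues) <= 1e-8))
    # scores reproduce the centered data in the loading basis
    expect_equal(fit$scores %*% t(fit$loadings), x,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("two perfectly correlated equal-variance probes split PC1 50/50", {
  set.seed(9)
  z <- stats::rnorm(12)
  tb <- tibble::tibble(probe_id = c("a", "b"))
  tb <- dplyr::bind_cols(tb, tibble::as_tibble(
    matrix(rep(z, each = 2), 2, 12,
           dimnames = list(NULL, sprintf("s%02d", 1:12)))))
  p <- pca_fit(tb)
  vc <- variable_contributions(p)
  expect_equal(vc$PC1, c(50, 50), tolerance = 1e-8)
})

test_that("duplicating every sample preserves eigenvector directions", {
  tb <- rand_m(n = 10, p = 30, seed = 4)
  dup <- dplyr::bind_cols(tb, setNames(tb[, -1], paste0("d", names(tb)[-1])))
  f1 <- pca_fit(tb)
  f2 <- pca_fit(dup)
  k <- min(ncol(f1$loadings), ncol(f2$loadings), 5)
  for (j in 1:k) {
    expect_equal(abs(sum(f1$loadings[, j] * f2$loadings[, j])), 1,
                 tolerance = 1e-6)
  }
  # cross-products double while the variance denominator goes 9 -> 19
  expect_equal(f2$eigenvalues[1:k] / f1$eigenvalues[1:k],
               rep(18 / 19, k), tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  const <- tibble::tibble(probe_id = c("a", "b"),
                          s1 = c(1, 1), s2 = c(1, 1), s3 = c(1, 1))
  expect_error(pca_fit(const), "degenerate")
  expect_error(pca_fit(const[, 1:2]), "input error")
})

test_that("stage 1 returns the exact target count with deterministic ties", {
  tb <- rand_m(n = 10, p = 1000, seed = 6)
  fit <- pca_fit(tb)
  sel <- stage1_select(fit, selection_params(stage1_fraction = 0.01))
  expect_length(sel, 10)
  expect_true(all(sel %in% tb$probe_id))

  # all-equal contributions: lexicographically smallest ids win
  fake <- fit
  fake$contributions[] <- 100 / nrow(fake$contributions)
  sel_tie <- stage1_select(fake, selection_params(stage1_fraction = 0.005))
  expect_identical(sel_tie, sort(tb$probe_id)[1:5])

  expect_error(
    stage1_select(fit, selection_params(stage1_fraction = 1e-5)),
    "fewer than one probe")
})

test_that("stage 2 applies the strict half-max rule per component", {
  # PC1 contributions {A .08, B .05, C .039, D .01}: threshold .04
  fake <- structure(list(contributions = matrix(
    c(0.08, 0.05, 0.039, 0.01,
      0.01, 0.01, 0.01, 0.30),
    4, 2, dimnames = list(c("A", "B", "C", "D"), c("PC1", "PC2")))),
    class = "meth_pca")
  res <- stage2_select(fake, selection_params())
  expect_equal(res$thresholds_used, c(PC1 = 0.04, PC2 = 0.15))
  # A, B pass PC1; D passes PC2 only and union keeps it
  expect_identical(res$stage2_ids, c("A", "B", "D"))
  expect_true(all(res$stage2_ids %in% res$stage1_ids))

  res_int <- stage2_select(fake, selection_params(combine = "intersection"))
  expect_identical(res_int$stage2_ids, character(0))

  # all contributions equal on a component: everything passes there
  fake$contributions[, 1] <- 0.25
  res_eq <- stage2_select(fake, selection_params())
  expect_true(all(c("A", "B", "C", "D") %in% res_eq$stage2_ids))
})

test_that("double selection composes the stages consistently", {
  sim <- small_sim(seed = 31, n_probes = 1500, n_differential = 25,
                   n_predictive = 0)
  mb <- beta_to_m(sim$beta_baseline)
  mf <- beta_to_m(sim$beta_followup)
  res <- double_pca_select(mb, mf, selection_params(stage1_fraction = 0.05))
  expect_true(all(res$stage2_ids %in% res$stage1_ids))
  expect_length(res$stage1_ids, round(0.05 * nrow(mb)))

  # identical matrices at both time points: both stages on one geometry
  res_same <- double_pca_select(mf, mf,
                                selection_params(stage1_fraction = 0.05))
  fu <- pca_fit(mf)
  s1 <- stage1_select(fu, selection_params(stage1_fraction = 0.05))
  expect_identical(res_same$stage1_ids, sort(s1))
  bl <- pca_fit(mf[match(s1, mf$probe_id), ])
  expect_identical(res_same$stage2_ids,
                   stage2_select(bl, selection_params())$stage2_ids)

  expect_error(double_pca_select(mb[-1, ], mf, selection_params()),
               "probe sets differ")
})

test_that("contributions are invariant to eigenvector sign", {
  tb <- rand_m(n = 8, p = 40, seed = 12)
  fit <- pca_fit(tb)
  flipped <- fit
  flipped$loadings <- -flipped$loadings
  expect_equal(100 * sweep(flipped$loadings^2, 2,
                           colSums(flipped$loadings^2), "/"),
               fit$contributions, tolerance = 1e-12)
})
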