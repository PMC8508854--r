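# PCA with per-variable contributions and the two-stage longitudinal
# CpG selection.
#
# Samples are observations, probes are variables (p >> n). The fit runs
# through the SVD of the centered n x p matrix, so no p x p matrix is ever
# formed and memory stays linear in the probe count.

#' Selection parameters for the two-stage PCA selection
#'
#' @param stage1_fraction Fraction of probes retained by the follow-up
#'   (stage 1) selection; default 0.01 (the "around 1%" rule).
#' @param n_components Number of leading components considered (default 2).
#' @param stage2_rule Stage-2 threshold rule; only `"half_max"` (keep probes
#'   whose contribution exceeds half the best probe's contribution on that
#'   component) is implemented.
#' @param combine How per-component stage-2 keeps are combined (default
#'   `"union"`).
#' @return A `meth_selection_params` list.
#' @export
selection_params <- function(stage1_fraction = 0.01,
                             n_components = 2L,
                             stage2_rule = c("half_max"),
                             combine = c("union", "intersection")) {
  stage2_rule <- match.arg(stage2_rule)
  combine <- match.arg(combine)
  if (stage1_fraction <= 0 || stage1_fraction >= 1) {
    stop("configuration error: `stage1_fraction` must lie in (0, 1)",
         call. = FALSE)
  }
  if (n_components < 1) {
    stop("configuration error: `n_components` must be >= 1", call. = FALSE)
  }
  structure(list(stage1_fraction = stage1_fraction,
                 n_components = as.integer(n_components),
                 stage2_rule = stage2_rule,
                 combine = combine),
            class = c("meth_selection_params", "list"))
}

#' Principal component analysis of a probes-by-samples matrix
#'
#' Fits PCA with samples as observations and probes as variables, via the
#' singular value decomposition of the (column-centered) samples x probes
#' matrix. Eigenvector signs are fixed so the largest-magnitude loading in
#' each component is positive, making results reproducible; contributions
#' are invariant to this choice.
#'
#' @param m Methylation tibble (first column `probe_id`, then samples);
#'   M-values or beta values.
#' @param center Center each probe (default TRUE).
#' @param scale Scale each probe to unit variance (default FALSE, matching
#'   the base-R PCA default).
#' @return An object of class `meth_pca`: `eigenvalues` (non-increasing),
#'   `explained_fraction`, `loadings` (probes x components, unit-norm
#'   columns), `scores` (samples x components), `contributions` (probes x
#'   components, percentages summing to 100 per component).
#' @export
pca_fit <- function(m, center = TRUE, scale = FALSE) {
  x <- t(mat_of(m))                       # n samples x p probes
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3 || p < 2) {
    stop("input error: PCA needs >= 3 samples and >= 2 probes",
         call. = FALSE)
  }
  if (center) x <- sweep(x, 2, colMeans(x), "-")
  if (scale) {
    sds <- sqrt(colSums(x^2) / (n - 1))
    if (any(sds == 0)) {
      stop("degenerate input: constant probe(s) cannot be scaled",
           call. = FALSE)
    }
    x <- sweep(x, 2, sds, "/")
  }
  if (all(abs(x) < 1e-12)) {
    stop("degenerate input: matrix is constant", call. = FALSE)
  }

  sv <- svd(x)
  keep <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[keep]
  v <- sv$v[, keep, drop = FALSE]
  u <- sv$u[, keep, drop = FALSE]

  # deterministic sign: largest-|loading| entry positive in each component
  for (j in seq_along(d)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }

  eig <- d^2 / (n - 1)
  contrib <- 100 * sweep(v^2, 2, colSums(v^2), "/")
  scores <- sweep(u, 2, d, "*")
  dimnames(v) <- list(colnames(x), paste0("PC", seq_along(d)))
  dimnames(contrib) <- dimnames(v)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_along(d)))

  structure(list(
    eigenvalues = eig,
    explained_fraction = eig / sum(eig),
    loadings = v,
    scores = scores,
    contributions = contrib,
    center = center,
    scale = scale,
    n_samples = n,
    n_probes = p
  ), class = c("meth_pca", "list"))
}

#' @export
print.meth_pca <- function(x, ...) {
  cat("PCA:", x$n_samples, "samples x", x$n_probes, "probes,",
      length(x$eigenvalues), "components\n")
  ef <- round(100 * x$explained_fraction[seq_len(min(
    3, length(x$eigenvalues)))], 1)
  cat("  explained variance (%):", paste(ef, collapse = ", "), "...\n")
  invisible(x)
}

#' Per-variable contributions to each principal component
#'
#' The contribution of probe `j` to component `k` is
#' `100 * loading_jk^2 / sum_j loading_jk^2`, the percentage share of the
#' component's (unit) norm; each component's contributions sum to 100.
#'
#' @param p A fitted [pca_fit()] object.
#' @return A tibble with `probe_id` and one `PC<k>` column per component.
#' @export
variable_contributions <- function(p) {
  stopifnot(inherits(p, "meth_pca"))
  dplyr::bind_cols(tibble::tibble(probe_id = rownames(p$contributions)),
                   tibble::as_tibble(p$contributions))
}

# Deterministic per-component ranking: contribution desc, probe_id asc.
rank_by_contribution <- function(contrib, ids) {
  order(-contrib, ids)
}

#' Stage-1 selection: top contributors at follow-up
#'
#' Ranks probes by their contribution to each of the first `n_components`
#' components of the follow-up PCA and takes the top `q` per component,
#' with `q` chosen so the union across components has exactly
#' `round(stage1_fraction * n_probes)` probes. When the union jumps past
#' the target as `q` grows, the overshoot among the probes added at depth
#' `q` is trimmed by (max contribution desc, probe_id asc). Ties everywhere
#' break by (contribution desc, probe_id asc).
#'
#' @param followup A [pca_fit()] of the follow-up matrix.
#' @param params A [selection_params()].
#' @return Character vector of selected probe ids (sorted).
#' @export
stage1_select <- function(followup, params = selection_params()) {
  stopifnot(inherits(followup, "meth_pca"))
  ids <- rownames(followup$contributions)
  p <- length(ids)
  k <- min(params$n_components, ncol(followup$contributions))
  target <- round(params$stage1_fraction * p)
  if (target < 1) {
    stop("input error: `stage1_fraction` selects fewer than one probe",
         call. = FALSE)
  }
  ord <- lapply(seq_len(k), function(j) {
    rank_by_contribution(followup$contributions[, j], ids)
  })
  union_at <- function(q) {
    unique(unlist(lapply(ord, function(o) o[seq_len(q)])))
  }
  lo <- 1L
  hi <- p
  while (lo < hi) {                       # smallest q with |union| >= target
    mid <- (lo + hi) %/% 2L
    if (length(union_at(mid)) >= target) hi <- mid else lo <- mid + 1L
  }
  q <- lo
  u <- union_at(q)
  if (length(u) > target) {
    prev <- if (q > 1) union_at(q - 1L) else integer(0)
    added <- setdiff(u, prev)
    need <- target - length(prev)
    best <- apply(followup$contributions[added, seq_len(k), drop = FALSE],
                  1, max)
    added <- added[order(-best, ids[added])][seq_len(need)]
    u <- c(prev, added)
  }
  sort(ids[u])
}

#' Stage-2 selection: half-max contribution rule at baseline
#'
#' On each of the first (up to two) components of the baseline PCA fitted to
#' the stage-1 probes, keeps probes whose contribution strictly exceeds half
#' the maximum contribution on that component; per-component keeps are then
#' combined by union (default) or intersection.
#'
#' @param baseline A [pca_fit()] of the baseline matrix restricted to the
#'   stage-1 probes.
#' @param params A [selection_params()].
#' @return An object of class `meth_selection` with `stage1_ids`,
#'   `stage2_ids`, `thresholds_used` (percent, per component),
#'   `stage2_contrib` (tibble of per-probe contributions and keep flags)
#'   and `params`.
#' @export
stage2_select <- function(baseline, params = selection_params()) {
  stopifnot(inherits(baseline, "meth_pca"))
  ids <- rownames(baseline$contributions)
  if (length(ids) == 0) {
    stop("input error: empty stage-1 set", call. = FALSE)
  }
  k <- min(params$n_components, 2L, ncol(baseline$contributions))
  cm <- baseline$contributions[, seq_len(k), drop = FALSE]
  thr <- apply(cm, 2, max) / 2
  keep_mat <- sweep(cm, 2, thr, ">")
  kept <- if (params$combine == "union") {
    rowSums(keep_mat) > 0
  } else {
    rowSums(keep_mat) == k
  }
  contrib_tbl <- dplyr::bind_cols(
    tibble::tibble(probe_id = ids),
    tibble::as_tibble(cm),
    tibble::as_tibble(keep_mat, .name_repair = ~ paste0("kept_", .x)),
    tibble::tibble(kept = kept)
  )
  structure(list(
    stage1_ids = sort(ids),
    stage2_ids = sort(ids[kept]),
    thresholds_used = thr,
    stage2_contrib = contrib_tbl,
    stage1_contrib = NULL,
    params = params
  ), class = c("meth_selection", "list"))
}

#' @export
print.meth_selection <- function(x, ...) {
  cat("Two-stage PCA selection:\n")
  cat("  stage 1:", length(x$stage1_ids), "probes\n")
  cat("  stage 2:", length(x$stage2_ids), "probes (half-max thresholds ",
      paste(signif(x$thresholds_used, 3), collapse = "%, "), "%)\n",
      sep = "")
  invisible(x)
}

#' Double PCA selection across two time points
#'
#' Composes the full longitudinal selection: PCA of the follow-up matrix,
#' stage-1 top-contributor selection, PCA of the baseline matrix restricted
#' to the stage-1 probes, and the stage-2 half-max rule.
#'
#' @param baseline_m Baseline methylation tibble.
#' @param followup_m Follow-up methylation tibble with the identical probe
#'   set (subjects paired across time points).
#' @param params A [selection_params()].
#' @param center,scale Passed to [pca_fit()].
#' @return A `meth_selection` (see [stage2_select()]) whose `stage1_contrib`
#'   records the follow-up contributions of the stage-1 probes, plus the
#'   explained-variance fractions of both fits.
#' @export
double_pca_select <- function(baseline_m, followup_m,
                              params = selection_params(),
                              center = TRUE, scale = FALSE) {
  if (!identical(baseline_m$probe_id, followup_m$probe_id)) {
    stop("input error: baseline and follow-up probe sets differ",
         call. = FALSE)
  }
  fu <- pca_fit(followup_m, center = center, scale = scale)
  s1 <- stage1_select(fu, params)
  base_sub <- baseline_m[match(s1, baseline_m$probe_id), ]
  bl <- pca_fit(base_sub, center = center, scale = scale)
  res <- stage2_select(bl, params)
  kf <- min(params$n_components, ncol(fu$contributions))
  res$stage1_contrib <- dplyr::bind_cols(
    tibble::tibble(probe_id = s1),
    tibble::as_tibble(
      fu$contributions[match(s1, rownames(fu$contributions)),
                       seq_len(kf), drop = FALSE])
  )
  res$explained_fraction_followup <- fu$explained_fraction
  res$explained_fraction_baseline <- bl$explained_fraction
  res
}
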