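# Per-site Kruskal-Wallis validation, direction calls, gene-level
# differential fractions and Table-1-style group descriptives.

#' Kruskal-Wallis rank test
#'
#' Computes the Kruskal-Wallis H statistic on midranks with the tie
#' correction `H / (1 - sum(t^3 - t) / (N^3 - N))` and a p-value from the
#' chi-square approximation with `groups - 1` degrees of freedom. The
#' degenerate case where every value is tied returns `H = 0, p = 1`.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length; at least two non-empty groups.
#' @return Named list with `H` and `p`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    stop("input error: Kruskal-Wallis needs >= 2 non-empty groups",
         call. = FALSE)
  }
  n <- length(values)
  stopifnot(length(groups) == n)
  r <- rank(values)
  n_g <- tabulate(groups)
  n_g <- n_g[n_g > 0]
  rsum <- tapply(r, droplevels(groups), sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / n_g) - 3 * (n + 1)
  ties <- table(r)
  denom <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (denom <= 0) {
    return(list(H = 0, p = 1))          # all values tied
  }
  h <- h / denom
  list(H = h, p = stats::pchisq(h, df = length(n_g) - 1, lower.tail = FALSE))
}

# Row-wise two-group (or k-group) KW over a sites x samples matrix.
# Returns a tibble of H and p per row. Vectorised enough for the 5k-site
# calibration runs without per-site R call overhead dominating.
kw_rows <- function(mat, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- ncol(mat)
  rk <- t(apply(mat, 1, rank))
  if (nrow(mat) == 1) rk <- matrix(rk, 1, n)
  gi <- split(seq_len(n), groups)
  n_g <- lengths(gi)
  ss <- matrix(0, nrow(mat), k)
  for (j in seq_len(k)) ss[, j] <- rowSums(rk[, gi[[j]], drop = FALSE])
  h <- 12 / (n * (n + 1)) * rowSums(sweep(ss^2, 2, n_g, "/")) - 3 * (n + 1)
  denom <- apply(rk, 1, function(r) {
    t <- table(r)
    1 - sum(t^3 - t) / (n^3 - n)
  })
  h <- ifelse(denom <= 0, 0, h / denom)
  p <- ifelse(denom <= 0, 1,
              stats::pchisq(h, df = k - 1, lower.tail = FALSE))
  tibble::tibble(H = h, p = p)
}

# Compute per-site test results (KW on M at both time points, beta-scale
# deltas, direction call) for a set of probes.
site_tests <- function(probe_ids, baseline_beta, followup_beta,
                       baseline_m, followup_m, sheet) {
  bb <- mat_of(baseline_beta)
  fb <- mat_of(followup_beta)
  bm <- mat_of(baseline_m)
  fm <- mat_of(followup_m)
  probe_ids <- intersect(probe_ids, rownames(bm))

  grp_of <- function(cols) {
    g <- sheet$group[match(cols, sheet$sample_id)]
    if (anyNA(g)) {
      stop("input error: matrix samples missing from the sample sheet",
           call. = FALSE)
    }
    g
  }
  g_b <- grp_of(colnames(bm))
  g_f <- grp_of(colnames(fm))

  ib <- match(probe_ids, rownames(bm))
  if_ <- match(probe_ids, rownames(fm))
  kw_b <- kw_rows(bm[ib, , drop = FALSE], g_b)
  kw_f <- kw_rows(fm[if_, , drop = FALSE], g_f)

  delta <- function(b, g) {
    rowMeans(b[, g == "stable_MHO", drop = FALSE]) -
      rowMeans(b[, g == "unstable_MHO", drop = FALSE])
  }
  d_b <- delta(bb[ib, , drop = FALSE], g_b)
  d_f <- delta(fb[if_, , drop = FALSE], g_f)

  tibble::tibble(
    probe_id = probe_ids,
    H_baseline = kw_b$H,
    H_followup = kw_f$H,
    p_baseline = kw_b$p,
    p_followup = kw_f$p,
    delta_beta_baseline = d_b,
    delta_beta_followup = d_f,
    direction = dplyr::case_when(
      d_b > 0 & d_f > 0 ~ "hyper_in_stable",
      d_b < 0 & d_f < 0 ~ "hypo_in_stable",
      TRUE ~ "discordant"
    )
  )
}

#' Validate selected CpG sites by per-site Kruskal-Wallis tests
#'
#' For every stage-2 selected probe, tests the stable vs unstable group
#' difference with Kruskal-Wallis on M-values at baseline and follow-up,
#' reports group mean differences on the beta scale
#' (`mean(stable) - mean(unstable)`) with a hyper/hypo/discordant direction
#' call, and keeps sites significant at both time points (and, by default,
#' with a concordant direction).
#'
#' @param selected A `meth_selection` (from [double_pca_select()]) or a
#'   character vector of probe ids.
#' @param baseline_beta,followup_beta Beta tibbles (for deltas).
#' @param baseline_m,followup_m M-value tibbles (for the tests).
#' @param sheet Sample sheet mapping sample ids to groups.
#' @param alpha Per-time-point significance level (default 0.05).
#' @param require_concordance Drop sites whose group ordering flips between
#'   time points (default TRUE).
#' @return Tibble of validated sites sorted by `min(p)` ascending then
#'   `probe_id`, with columns `probe_id`, `H_baseline`, `H_followup`,
#'   `p_baseline`, `p_followup`, `delta_beta_baseline`,
#'   `delta_beta_followup`, `direction`.
#' @export
validate_sites <- function(selected, baseline_beta, followup_beta,
                           baseline_m, followup_m, sheet,
                           alpha = 0.05, require_concordance = TRUE) {
  ids <- if (inherits(selected, "meth_selection")) {
    selected$stage2_ids
  } else {
    as.character(selected)
  }
  if (length(ids) == 0) {
    stop("input error: empty selection", call. = FALSE)
  }
  res <- site_tests(ids, baseline_beta, followup_beta,
                    baseline_m, followup_m, sheet)
  keep <- res$p_baseline < alpha & res$p_followup < alpha
  if (require_concordance) keep <- keep & res$direction != "discordant"
  out <- res[keep, ]
  out[order(pmin(out$p_baseline, out$p_followup), out$probe_id), ]
}

#' Gene-level differential methylation summary
#'
#' For each gene carrying at least one validated site, tests every manifest
#' CpG annotated to that gene (Kruskal-Wallis at both time points, same
#' `alpha`) and reports the fraction found differential. The denominator is
#' the gene's manifest probe count; probes filtered out of the matrices are
#' untestable and count as non-differential.
#'
#' @param validated Tibble from [validate_sites()].
#' @param baseline_beta,followup_beta,baseline_m,followup_m,sheet As in
#'   [validate_sites()].
#' @param manifest Probe manifest with gene annotations.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `gene`, `n_cpgs_on_array`, `n_tested`,
#'   `n_differential`, `fraction_differential` (percent), sorted by
#'   fraction descending then gene.
#' @export
gene_summary <- function(validated, baseline_beta, followup_beta,
                         baseline_m, followup_m, sheet, manifest,
                         alpha = 0.05) {
  hit_genes <- manifest$gene[match(validated$probe_id, manifest$probe_id)]
  hit_genes <- sort(unique(hit_genes[!is.na(hit_genes) & hit_genes != ""]))
  absent <- validated$probe_id[!validated$probe_id %in% manifest$probe_id]
  if (length(absent) > 0) {
    warning("skipping ", length(absent),
            " validated probe(s) absent from the manifest", call. = FALSE)
  }
  if (length(hit_genes) == 0) {
    return(tibble::tibble(gene = character(), n_cpgs_on_array = integer(),
                          n_tested = integer(), n_differential = integer(),
                          fraction_differential = numeric()))
  }
  gene_probes <- manifest[manifest$gene %in% hit_genes,
                          c("probe_id", "gene")]
  testable <- gene_probes$probe_id %in% baseline_m$probe_id
  tests <- site_tests(gene_probes$probe_id[testable],
                      baseline_beta, followup_beta,
                      baseline_m, followup_m, sheet)
  tests$differential <- tests$p_baseline < alpha & tests$p_followup < alpha
  merged <- dplyr::left_join(gene_probes, tests[, c("probe_id",
                                                    "differential")],
                             by = "probe_id")
  out <- merged |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_cpgs_on_array = dplyr::n(),
      n_tested = sum(!is.na(.data$differential)),
      n_differential = sum(.data$differential, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction_differential =
                    100 * .data$n_differential / .data$n_cpgs_on_array)
  out[order(-out$fraction_differential, out$gene), ]
}

#' Group descriptives with the tests used for cohort tables
#'
#' Per continuous covariate: group means and SDs per time point with a
#' Kruskal-Wallis p-value. Per categorical covariate: group percentages
#' with a chi-square test (no continuity correction), switching to Fisher's
#' exact test when any expected cell count is below 5.
#'
#' @param sheet Sample sheet tibble (two groups).
#' @param continuous,categorical Covariate column names; defaults pick
#'   numeric columns and the sex/treatment flags.
#' @return Tibble with one row per covariate and time point: group
#'   summaries, `p_value`, `test`.
#' @export
group_descriptives <- function(sheet,
                               continuous = NULL,
                               categorical = NULL) {
  groups <- sort(unique(sheet$group))
  if (length(groups) != 2) {
    stop("input error: expected exactly two groups", call. = FALSE)
  }
  id_cols <- c("sample_id", "subject_id", "timepoint", "group")
  if (is.null(continuous)) {
    continuous <- setdiff(names(sheet)[vapply(sheet, is.numeric,
                                              logical(1))], id_cols)
  }
  if (is.null(categorical)) {
    categorical <- intersect(c("sex", "on_treatment"), names(sheet))
  }

  rows <- list()
  for (tp in unique(sheet$timepoint)) {
    d <- sheet[sheet$timepoint == tp, ]
    g <- factor(d$group, levels = groups)
    for (v in continuous) {
      x <- d[[v]]
      kw <- kruskal_wallis(x, g)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, timepoint = tp, type = "continuous",
        stat_group1 = mean(x[g == groups[1]]),
        sd_group1 = stats::sd(x[g == groups[1]]),
        stat_group2 = mean(x[g == groups[2]]),
        sd_group2 = stats::sd(x[g == groups[2]]),
        p_value = kw$p, test = "kruskal_wallis"
      )
    }
    for (v in categorical) {
      x <- as.factor(d[[v]])
      tab <- table(x, g)
      if (nrow(tab) < 2 || any(rowSums(tab) == 0)) {
        p <- 1
        test <- "none"
      } else {
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 5)) {
          p <- stats::fisher.test(tab)$p.value
          test <- "fisher"
        } else {
          p <- suppressWarnings(
            stats::chisq.test(tab, correct = FALSE)$p.value)
          test <- "chi_square"
        }
      }
      lev <- utils::tail(levels(x), 1)   # report share of the last level
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, timepoint = tp, type = "categorical",
        stat_group1 = 100 * mean(d[[v]][g == groups[1]] == lev),
        sd_group1 = NA_real_,
        stat_group2 = 100 * mean(d[[v]][g == groups[2]] == lev),
        sd_group2 = NA_real_,
        p_value = p, test = test
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "groups") <- groups
  out
}
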