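# Synthetic EPIC-like longitudinal cohort generator.
#
# The generator emulates the data regime of a small prospective methylation
# study: two groups of obese subjects (metabolically healthy at baseline;
# one group stays healthy, the other transitions to an unhealthy phenotype),
# two time points eleven years apart, and a probe space with the design
# quirks of the Infinium EPIC array (type I/II chemistry bias, sex-chromosome
# and SNP-adjacent probes, detection failures). Planted group-differential
# and baseline-predictive CpGs give every downstream stage a ground truth.

#' Generator configuration
#'
#' Bundles and validates every knob of the synthetic-cohort generator.
#'
#' @param n_probes Number of probes on the simulated array. The default
#'   20,000 keeps the probes >> samples regime of the 850k-scale EPIC array
#'   at desk scale; full scale is configurable.
#' @param n_subjects_per_group Subjects per group (stable / unstable MHO).
#' @param frac_sex_chrom Fraction of probes on chrX/chrY.
#' @param frac_snp_flag Fraction of probes flagged as SNP-adjacent
#'   (assigned among autosomal probes).
#' @param frac_type2 Fraction of probes with Infinium type II chemistry
#'   (0.84 mirrors the real EPIC share).
#' @param n_differential Number of planted group-differential CpGs (stable
#'   vs unstable difference present at both time points).
#' @param delta_beta Magnitude of the planted group difference in mean beta;
#'   each planted probe gets a random sign (hyper- or hypomethylated in the
#'   stable group).
#' @param n_predictive Number of planted baseline-predictive CpGs whose
#'   baseline M-value is associated with later transition.
#' @param predictive_log_or Planted log odds ratio per 1 SD of baseline
#'   M-value for predictive probes (random sign per probe).
#' @param within_subject_corr Correlation of a probe's M-values across the
#'   two time points within a subject, implemented as a subject random
#'   intercept on the M scale.
#' @param beta_precision Concentration `kappa` of the per-cell beta noise,
#'   `beta ~ Beta(m*kappa, (1-m)*kappa)`. The default 1000 corresponds to a
#'   technical replicate-level beta SD of about 0.016 at mid-methylation,
#'   in the published range for well-performing EPIC probes; stable
#'   between-subject biology enters separately through the subject
#'   intercept sized by `within_subject_corr`.
#' @param detection_fail_rate Per probe-by-sample probability of a failed
#'   measurement (detection p-value > 0.01).
#' @param type2_shrink Shrinkage of type II probe baseline means toward 0.5
#'   before noise, emulating the compressed type II dynamic range that BMIQ
#'   corrects.
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return A `meth_generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(n_probes = 500, seed = 1)
#' cfg$n_subjects_per_group
generator_config <- function(n_probes = 20000L,
                             n_subjects_per_group = 9L,
                             frac_sex_chrom = 0.04,
                             frac_snp_flag = 0.05,
                             frac_type2 = 0.84,
                             n_differential = 60L,
                             delta_beta = 0.15,
                             n_predictive = 2L,
                             predictive_log_or = 1.5,
                             within_subject_corr = 0.7,
                             beta_precision = 1000,
                             detection_fail_rate = 0.005,
                             type2_shrink = 0.3,
                             seed = 1L) {
  cfg <- list(
    n_probes = as.integer(n_probes),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    frac_sex_chrom = frac_sex_chrom,
    frac_snp_flag = frac_snp_flag,
    frac_type2 = frac_type2,
    n_differential = as.integer(n_differential),
    delta_beta = delta_beta,
    n_predictive = as.integer(n_predictive),
    predictive_log_or = predictive_log_or,
    within_subject_corr = within_subject_corr,
    beta_precision = beta_precision,
    detection_fail_rate = detection_fail_rate,
    type2_shrink = type2_shrink,
    seed = as.integer(seed)
  )
  fracs <- c("frac_sex_chrom", "frac_snp_flag", "frac_type2",
             "detection_fail_rate")
  for (f in fracs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("configuration error: `", f, "` must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (cfg$within_subject_corr < 0 || cfg$within_subject_corr >= 1) {
    stop("configuration error: `within_subject_corr` must lie in [0, 1)",
         call. = FALSE)
  }
  if (cfg$type2_shrink < 0 || cfg$type2_shrink >= 1) {
    stop("configuration error: `type2_shrink` must lie in [0, 1)",
         call. = FALSE)
  }
  if (cfg$beta_precision <= 0) {
    stop("configuration error: `beta_precision` must be > 0", call. = FALSE)
  }
  if (cfg$delta_beta < 0 || cfg$delta_beta >= 1) {
    stop("configuration error: `delta_beta` must lie in [0, 1)",
         call. = FALSE)
  }
  if (cfg$n_probes < 2 || cfg$n_subjects_per_group < 2) {
    stop("configuration error: need >= 2 probes and >= 2 subjects per group",
         call. = FALSE)
  }
  if (cfg$n_differential + cfg$n_predictive > cfg$n_probes) {
    stop("configuration error: planted probes exceed `n_probes`",
         call. = FALSE)
  }
  structure(cfg, class = c("meth_generator_config", "list"))
}

#' Generate a probe manifest
#'
#' Produces per-probe genomic and design metadata: chromosome, position,
#' gene annotation, Infinium design type and SNP-adjacency flag. Counts of
#' sex-chromosome, SNP-flagged and type II probes are rounding-exact
#' fractions of `n_probes`. Genes are sized so that a sizeable share carry
#' four or more probes, which the gene-level summary stage needs.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `probe_id`, `chrom`, `pos`, `gene`,
#'   `design_type`, `snp_flag`.
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "meth_generator_config"))
  n <- config$n_probes
  with_seed(config$seed, {
    probe_id <- sprintf("cg%08d", seq_len(n))

    n_sex <- round(config$frac_sex_chrom * n)
    n_snp <- round(config$frac_snp_flag * n)
    if (n_snp > n - n_sex) {
      stop("configuration error: SNP fraction exceeds autosomal share",
           call. = FALSE)
    }
    idx <- sample.int(n)                       # random placement of features
    sex_idx <- idx[seq_len(n_sex)]
    snp_idx <- idx[n_sex + seq_len(n_snp)]     # autosomal by construction

    chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
    if (n_sex > 0) {
      chrom[sex_idx] <- sample(c("chrX", "chrY"), n_sex,
                               replace = TRUE, prob = c(0.95, 0.05))
    }
    snp_flag <- rep(FALSE, n)
    snp_flag[snp_idx] <- TRUE

    n_t2 <- round(config$frac_type2 * n)
    design_type <- rep("I", n)
    design_type[sample.int(n, n_t2)] <- "II"

    # Gene structure: ~15% of genes carry 4-8 probes, the rest 1-3;
    # ~10% of probes are intergenic (empty annotation).
    gene <- character(n)
    n_genic <- n - round(0.10 * n)
    genic_idx <- sort(sample.int(n, n_genic))
    sizes <- integer(0)
    total <- 0L
    g <- 0L
    while (total < n_genic) {
      g <- g + 1L
      s <- if (stats::runif(1) < 0.15) sample(4:8, 1) else sample(1:3, 1)
      s <- min(s, n_genic - total)
      sizes <- c(sizes, s)
      total <- total + s
    }
    gene_names <- sprintf("GENE%05d", seq_along(sizes))
    gene[genic_idx] <- rep(gene_names, times = sizes)

    tibble::tibble(
      probe_id = probe_id,
      chrom = chrom,
      pos = sample.int(2.4e8, n, replace = TRUE),
      gene = gene,
      design_type = design_type,
      snp_flag = snp_flag
    )
  })
}

#' Count NCEP ATPIII metabolic syndrome criteria
#'
#' Vectorised over the rows of `data`. The five criteria are: elevated blood
#' pressure (SBP >= 135 mmHg or DBP >= 85 mmHg, counted once); fasting
#' glucose >= 100 mg/dL; low HDL cholesterol (< 40 mg/dL in men, < 50 mg/dL
#' in women); triglycerides >= 150 mg/dL; and any antihypertensive,
#' lipid-lowering or glucose-lowering treatment. All thresholds are
#' boundary-inclusive as written.
#'
#' @param data A data frame with columns `fasting_glucose`, `triglycerides`,
#'   `hdl`, `sbp`, `dbp`, `sex` ("M"/"F") and `on_treatment` (logical).
#' @return Integer vector of criteria counts (0-5).
#' @export
count_metabolic_criteria <- function(data) {
  req <- c("fasting_glucose", "triglycerides", "hdl", "sbp", "dbp",
           "sex", "on_treatment")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) {
    stop("input error: missing covariate(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(data$sex %in% c("M", "F"))) {
    stop("input error: `sex` must be \"M\" or \"F\"", call. = FALSE)
  }
  hdl_cut <- ifelse(data$sex == "M", 40, 50)
  as.integer(
    (data$sbp >= 135 | data$dbp >= 85) +
      (data$fasting_glucose >= 100) +
      (data$hdl < hdl_cut) +
      (data$triglycerides >= 150) +
      as.logical(data$on_treatment)
  )
}

#' Classify metabolic status under the NCEP ATPIII rule
#'
#' Subjects with abdominal obesity are metabolically healthy obese (MHO)
#' when fewer than two of the five metabolic syndrome criteria are present,
#' and metabolically unhealthy obese (MUO) otherwise. Abdominal obesity
#' (waist > 102 cm in men, > 88 cm in women) holds for all generated
#' subjects by construction.
#'
#' @inheritParams count_metabolic_criteria
#' @return Character vector, `"MHO"` or `"MUO"` per row.
#' @export
#' @examples
#' classify_metabolic_status(data.frame(
#'   fasting_glucose = c(90, 108), triglycerides = c(100, 100),
#'   hdl = c(60, 54), sbp = c(120, 154), dbp = c(75, 90),
#'   sex = c("F", "F"), on_treatment = c(FALSE, FALSE)))
classify_metabolic_status <- function(data) {
  ifelse(count_metabolic_criteria(data) < 2, "MHO", "MUO")
}

# Draw one covariate panel for a block of subject-rows with a prescribed
# set of active criteria. Active criteria are drawn above their thresholds,
# inactive ones below, so the phenotype classification is exact by
# construction.
draw_covariates <- function(n, sex, group, active) {
  stopifnot(nrow(active) == n)
  glucose <- ifelse(active$glucose,
                    stats::runif(n, 100, 135), stats::runif(n, 82, 99.5))
  sbp <- ifelse(active$bp,
                stats::runif(n, 135, 165), stats::runif(n, 105, 134))
  dbp <- ifelse(active$bp,
                stats::runif(n, 85, 100), stats::runif(n, 65, 84))
  hdl <- ifelse(active$hdl,
                ifelse(sex == "M", stats::runif(n, 28, 39.5),
                       stats::runif(n, 35, 49.5)),
                ifelse(sex == "M", stats::runif(n, 41, 70),
                       stats::runif(n, 51, 75)))
  # Baseline triglycerides run higher in the unstable group even when below
  # the criterion threshold, mirroring the cohort this emulates.
  tg_lo <- ifelse(group == "stable_MHO", 40, 60)
  tg_hi <- ifelse(group == "stable_MHO", 90, 145)
  tg <- ifelse(active$tg, stats::runif(n, 150, 260),
               stats::runif(n, tg_lo, tg_hi))
  waist <- ifelse(sex == "M", stats::runif(n, 103, 130),
                  stats::runif(n, 89, 120))
  tibble::tibble(
    fasting_glucose = round(glucose, 1),
    triglycerides = round(tg, 1),
    hdl = round(hdl, 1),
    sbp = round(sbp, 1),
    dbp = round(dbp, 1),
    waist = round(waist, 1),
    on_treatment = active$meds
  )
}

# Sample which of the five criteria are active given a target count.
sample_active <- function(n, counts) {
  crit <- c("bp", "glucose", "hdl", "tg", "meds")
  w <- c(bp = 0.30, glucose = 0.30, hdl = 0.15, tg = 0.15, meds = 0.10)
  out <- matrix(FALSE, n, 5, dimnames = list(NULL, crit))
  for (i in seq_len(n)) {
    if (counts[i] > 0) {
      out[i, sample(crit, counts[i], prob = w)] <- TRUE
    }
  }
  tibble::as_tibble(out)
}

#' Generate a longitudinal two-group cohort and its ground truth
#'
#' Builds the sample sheet (two groups of `n_subjects_per_group` subjects,
#' two time points each) and the truth set of planted probe effects.
#' Covariates are drawn so that, under [classify_metabolic_status()], stable
#' subjects are MHO at both time points while unstable subjects are MHO at
#' baseline and MUO at follow-up.
#'
#' @param config A [generator_config()].
#' @param manifest A manifest from [generate_manifest()]; planted probes are
#'   drawn from its autosomal, non-SNP-flagged probes so that truth survives
#'   probe filtering.
#' @return A list with `sheet` (tibble: `sample_id`, `subject_id`,
#'   `timepoint`, `group`, covariates) and `truth` (list with tibbles
#'   `differential` (`probe_id`, `delta_beta`) and `predictive`
#'   (`probe_id`, `log_or`), plus the seed).
#' @export
generate_cohort <- function(config, manifest) {
  stopifnot(inherits(config, "meth_generator_config"))
  n_g <- config$n_subjects_per_group
  with_seed(config$seed + 1L, {
    subject_id <- sprintf("S%02d", seq_len(2 * n_g))
    group <- rep(c("stable_MHO", "unstable_MHO"), each = n_g)
    sex <- sample(c("F", "M"), 2 * n_g, replace = TRUE, prob = c(0.7, 0.3))
    age0 <- pmin(pmax(round(stats::rnorm(2 * n_g,
                                         ifelse(group == "stable_MHO",
                                                45, 53), 10)), 25), 64)

    rows <- list()
    for (tp in c("baseline", "followup")) {
      muo <- tp == "followup" & group == "unstable_MHO"
      counts <- ifelse(muo,
                       sample(2:3, 2 * n_g, replace = TRUE,
                              prob = c(0.7, 0.3)),
                       sample(0:1, 2 * n_g, replace = TRUE,
                              prob = c(0.6, 0.4)))
      active <- sample_active(2 * n_g, counts)
      cov <- draw_covariates(2 * n_g, sex, group, active)
      rows[[tp]] <- dplyr::bind_cols(
        tibble::tibble(
          sample_id = paste0(subject_id, "_", tp),
          subject_id = subject_id,
          timepoint = tp,
          group = group,
          sex = sex,
          age = age0 + ifelse(tp == "followup", 11L, 0L)
        ),
        cov
      )
    }
    sheet <- dplyr::arrange(dplyr::bind_rows(rows),
                            .data$timepoint, .data$subject_id)

    eligible <- manifest$probe_id[
      !(manifest$chrom %in% c("chrX", "chrY")) & !manifest$snp_flag
    ]
    if (length(eligible) < config$n_differential + config$n_predictive) {
      stop("configuration error: not enough eligible probes to plant effects",
           call. = FALSE)
    }
    planted <- sample(eligible, config$n_differential + config$n_predictive)
    diff_ids <- planted[seq_len(config$n_differential)]
    pred_ids <- planted[config$n_differential + seq_len(config$n_predictive)]
    truth <- list(
      differential = tibble::tibble(
        probe_id = diff_ids,
        delta_beta = config$delta_beta *
          sample(c(-1, 1), config$n_differential, replace = TRUE)
      ),
      predictive = tibble::tibble(
        probe_id = pred_ids,
        log_or = config$predictive_log_or *
          sample(c(-1, 1), config$n_predictive, replace = TRUE)
      ),
      seed = config$seed
    )
    list(sheet = sheet, truth = truth)
  })
}

#' Generate beta-value and detection p-value matrices
#'
#' Draws per-cell beta values from a three-state (low / intermediate / high
#' methylation) landscape with beta-distributed noise, a subject random
#' intercept on the M scale sized to give `within_subject_corr` across time
#' points, type II design compression toward 0.5, planted group-differential
#' effects (additive on beta, present at both time points) and planted
#' baseline-predictive shifts on the M scale. Detection p-values are small
#' for good cells and elevated for failed cells.
#'
#' @param manifest Manifest tibble from [generate_manifest()].
#' @param sheet Sample sheet from [generate_cohort()].
#' @param truth Truth set from [generate_cohort()].
#' @param config A [generator_config()].
#' @return List with tibbles `beta_baseline`, `beta_followup`,
#'   `detp_baseline`, `detp_followup` (first column `probe_id`, one column
#'   per sample).
#' @export
generate_betas <- function(manifest, sheet, truth, config) {
  stopifnot(inherits(config, "meth_generator_config"))
  p <- nrow(manifest)
  subjects <- unique(sheet$subject_id)
  n_s <- length(subjects)
  sub_group <- sheet$group[match(subjects, sheet$subject_id)]
  if (!all(truth$differential$probe_id %in% manifest$probe_id)) {
    stop("input error: truth set refers to probes absent from the manifest",
         call. = FALSE)
  }

  kappa <- config$beta_precision
  rho <- config$within_subject_corr
  ln2 <- log(2)

  with_seed(config$seed + 2L, {
    # trimodal beta landscape: unmethylated / hemimethylated / methylated
    state <- sample(1:3, p, replace = TRUE, prob = c(0.40, 0.20, 0.40))
    m0 <- c(stats::rbeta(p, 3, 17),
            stats::rbeta(p, 10, 10),
            stats::rbeta(p, 17, 3))[(state - 1) * p + seq_len(p)]

    delta <- numeric(p)
    di <- match(truth$differential$probe_id, manifest$probe_id)
    delta[di] <- truth$differential$delta_beta
    # keep both group means inside (0.01, 0.99)
    ctr <- pmin(pmax(m0, 0.01 + abs(delta) / 2), 0.99 - abs(delta) / 2)
    mu_stable <- ctr + delta / 2      # delta = mean(stable) - mean(unstable)
    mu_unstable <- ctr - delta / 2

    # Type II dynamic-range compression is a measurement distortion, so it
    # shrinks the complete signal -- landscape and planted effect alike;
    # BMIQ is what restores comparability downstream.
    is_t2 <- manifest$design_type == "II"
    shrink <- function(x) {
      x[is_t2] <- 0.5 + (1 - config$type2_shrink) * (x[is_t2] - 0.5)
      x
    }
    mu_stable <- shrink(mu_stable)
    mu_unstable <- shrink(mu_unstable)
    ctr <- shrink(ctr)

    se_beta <- sqrt(ctr * (1 - ctr) / (kappa + 1))
    se_m <- se_beta / (ln2 * ctr * (1 - ctr))
    sd_b <- se_m * sqrt(rho / (1 - rho))
    intercept <- matrix(stats::rnorm(p * n_s, 0, sd_b), p, n_s)

    pred_shift <- numeric(p)
    pi_ <- match(truth$predictive$probe_id, manifest$probe_id)
    sd_tot <- se_m / sqrt(1 - rho)
    pred_shift[pi_] <- truth$predictive$log_or * sd_tot[pi_]

    draw_tp <- function(tp) {
      mu <- matrix(mu_unstable, p, n_s)
      mu[, sub_group == "stable_MHO"] <- mu_stable
      mu_m <- log2(mu / (1 - mu)) + intercept
      if (tp == "baseline") {
        unst <- sub_group == "unstable_MHO"
        mu_m[, unst] <- mu_m[, unst] + pred_shift
      }
      mb <- 2^mu_m / (1 + 2^mu_m)
      mb <- pmin(pmax(mb, 0.005), 0.995)
      b <- matrix(stats::rbeta(p * n_s, mb * kappa, (1 - mb) * kappa),
                  p, n_s)
      b <- pmin(pmax(b, 1e-6), 1 - 1e-6)
      rownames(b) <- manifest$probe_id
      colnames(b) <- paste0(subjects, "_", tp)
      b
    }
    draw_detp <- function(tp) {
      fail <- stats::runif(p * n_s) < config$detection_fail_rate
      d <- ifelse(fail, stats::runif(p * n_s, 0.02, 0.5),
                  stats::runif(p * n_s, 0, 0.005))
      d <- matrix(d, p, n_s)
      rownames(d) <- manifest$probe_id
      colnames(d) <- paste0(subjects, "_", tp)
      d
    }

    list(
      beta_baseline = tbl_of(draw_tp("baseline")),
      beta_followup = tbl_of(draw_tp("followup")),
      detp_baseline = tbl_of(draw_detp("baseline")),
      detp_followup = tbl_of(draw_detp("followup"))
    )
  })
}

#' Simulate a complete study in one call
#'
#' Convenience wrapper chaining [generate_manifest()], [generate_cohort()]
#' and [generate_betas()].
#'
#' @param config A [generator_config()].
#' @return List with `manifest`, `sheet`, `truth`, `beta_baseline`,
#'   `beta_followup`, `detp_baseline`, `detp_followup`.
#' @export
#' @examples
#' sim <- simulate_cohort(generator_config(n_probes = 300, seed = 7))
#' dim(sim$beta_baseline)
simulate_cohort <- function(config) {
  manifest <- generate_manifest(config)
  cohort <- generate_cohort(config, manifest)
  mats <- generate_betas(manifest, cohort$sheet, cohort$truth, config)
  c(list(manifest = manifest, sheet = cohort$sheet, truth = cohort$truth),
    mats)
}
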