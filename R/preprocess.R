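# Preprocessing: probe filtering, BMIQ design-bias normalization and
# beta <-> M transforms.

#' Filter probes by genomic location, SNP adjacency and detection quality
#'
#' Removes probes on the sex chromosomes, probes flagged as SNP-adjacent,
#' and low-quality probes whose detection p-value exceeds `p_cut` in at
#' least a fraction `frac_cut` of samples (boundary inclusive). A probe
#' failing several rules is counted once in the report, under the first
#' rule in the precedence sex > SNP > detection.
#'
#' @param beta Beta-value tibble (first column `probe_id`, then samples).
#' @param detp Detection p-value tibble aligned with `beta`.
#' @param manifest Probe manifest covering every probe in `beta`.
#' @param p_cut Detection p-value threshold (default 0.01).
#' @param frac_cut Fraction-of-samples threshold (default 0.10).
#' @return A list of class `meth_filter` with `beta` and `detp` (filtered,
#'   original order preserved) and `report`, a list with `n_input`,
#'   `n_removed_sex`, `n_removed_snp`, `n_removed_detection`, `n_retained`
#'   and `removed_ids` per reason.
#' @export
filter_probes <- function(beta, detp, manifest,
                          p_cut = 0.01, frac_cut = 0.10) {
  check_aligned(beta, detp, "beta and detection p-value matrices")
  idx <- match(beta$probe_id, manifest$probe_id)
  if (anyNA(idx)) {
    stop("input error: ", sum(is.na(idx)),
         " probe(s) in the matrix are absent from the manifest",
         call. = FALSE)
  }
  man <- manifest[idx, ]

  is_sex <- man$chrom %in% c("chrX", "chrY")
  is_snp <- man$snp_flag & !is_sex
  dmat <- mat_of(detp)
  frac_fail <- rowMeans(dmat > p_cut)
  is_det <- (frac_fail >= frac_cut) & !is_sex & !man$snp_flag

  drop <- is_sex | is_snp | is_det
  report <- list(
    n_input = nrow(beta),
    n_removed_sex = sum(is_sex),
    n_removed_snp = sum(is_snp),
    n_removed_detection = sum(is_det),
    n_retained = sum(!drop),
    removed_ids = list(
      sex = beta$probe_id[is_sex],
      snp = beta$probe_id[is_snp],
      detection = beta$probe_id[is_det]
    )
  )
  structure(
    list(beta = beta[!drop, ], detp = detp[!drop, ], report = report),
    class = c("meth_filter", "list")
  )
}

#' @export
print.meth_filter <- function(x, ...) {
  r <- x$report
  cat("Probe filter:", r$n_input, "probes in,", r$n_retained, "retained\n")
  cat("  removed: sex-chromosome", r$n_removed_sex,
      "| SNP-flagged", r$n_removed_snp,
      "| detection", r$n_removed_detection, "\n")
  invisible(x)
}

# --- three-state beta mixture ------------------------------------------------

# Method-of-moments beta parameters from a weighted sample.
mom_beta <- function(x, w) {
  sw <- sum(w)
  mu <- sum(w * x) / sw
  v <- sum(w * (x - mu)^2) / sw
  v <- max(v, 1e-8)
  t <- max(mu * (1 - mu) / v - 1, 1e-2)
  c(a = mu * t, b = (1 - mu) * t)
}

# Fit a 3-state beta mixture (unmethylated / hemimethylated / methylated)
# by EM with fixed quantile-cut initialisation (x < 0.2 / 0.2-0.8 / > 0.8),
# so the fit is deterministic. Convergence is the classic EM criterion --
# relative log-likelihood change below `tol` -- and the best-likelihood
# iterate is kept as a fallback because the moment-based M-step is not
# strictly monotone. The default iteration budget is deliberately modest:
# the mixture is a scoring device for state assignment, and running the
# misspecified three-beta fit to full ML convergence shrinks the
# hemimethylated state below its real share, which measurably degrades the
# fidelity of the downstream quantile map (effect-restoration RMSE rises);
# a capped fit keeps the type I and type II fits comparable. For large
# probe sets the fit runs on an order-statistics subsample (every k-th
# sorted value), which preserves the distribution and is deterministic;
# state assignment afterwards uses all probes. Returns parameters, weights
# and the hard state assignment by maximum posterior.
fit_beta_mixture3 <- function(x, max_iter = 25, tol = 1e-4,
                              fit_cap = 5000L) {
  xf <- x
  if (length(xf) > fit_cap) {
    xs <- sort(xf)
    xf <- xs[round(seq(1, length(xs), length.out = fit_cap))]
  }
  n <- length(xf)
  states_init <- cut(xf, c(-Inf, 0.2, 0.8, Inf), labels = FALSE)
  gamma <- matrix(0, n, 3)
  gamma[cbind(seq_len(n), states_init)] <- 1
  # guard: give empty initial states a whisker of mass
  gamma <- gamma * 0.97 + 0.01

  par <- matrix(0.5, 3, 2)
  w <- rep(1 / 3, 3)
  best <- NULL
  converged <- FALSE
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    for (k in 1:3) par[k, ] <- mom_beta(xf, gamma[, k])
    w <- colMeans(gamma)
    dens <- vapply(1:3, function(k) {
      w[k] * stats::dbeta(xf, par[k, 1], par[k, 2])
    }, numeric(n))
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    gamma <- dens / rs
    if (is.null(best) || ll >= best$ll) {
      best <- list(par = par, w = w, ll = ll)
    }
    if (it > 1 && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  par <- best$par
  w <- best$w
  # order states by mean so state 1 = unmethylated, 3 = methylated
  o <- order(par[, 1] / rowSums(par))
  par <- par[o, , drop = FALSE]
  w <- w[o]
  # hard assignment of ALL probes under the fitted parameters
  post <- vapply(1:3, function(k) {
    w[k] * stats::dbeta(x, par[k, 1], par[k, 2])
  }, numeric(length(x)))
  if (length(x) == 1) post <- matrix(post, 1, 3)
  list(par = par, w = w,
       state = max.col(post, ties.method = "first"),
       converged = converged)
}

#' BMIQ-style normalization of Infinium type II design bias
#'
#' Per sample, fits a three-state beta mixture (unmethylated /
#' hemimethylated / methylated) separately to type I and type II probes by
#' EM and hard-assigns each probe to a state by maximum posterior. Type II
#' probes in the unmethylated and methylated states are quantile-mapped
#' within their state onto the matching type I state distribution (midrank
#' source quantiles, empirical target quantiles); the hemimethylated state,
#' which lies in the sparse valley between the modes, is mapped by a linear
#' dilation anchored at the images of its boundaries, following the
#' published method's treatment of that state. Type I probes are returned
#' unchanged; rank order within each type II state is preserved because
#' every state map is monotone.
#'
#' @param beta Beta-value tibble.
#' @param manifest Manifest providing `design_type` for every probe.
#' @param max_iter Maximum EM iterations per mixture fit.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param min_class Minimum probes required per (non-empty) design class.
#' @param seed Unused except to break exact posterior ties deterministically;
#'   the EM initialisation is fixed quantile cut-points, so the procedure is
#'   otherwise deterministic.
#' @return Normalized beta tibble with values in (0, 1).
#' @export
bmiq_normalize <- function(beta, manifest, max_iter = 25, tol = 1e-4,
                           min_class = 50, seed = 1L) {
  idx <- match(beta$probe_id, manifest$probe_id)
  if (anyNA(idx)) {
    stop("input error: probes absent from the manifest", call. = FALSE)
  }
  dt <- manifest$design_type[idx]
  i1 <- which(dt == "I")
  i2 <- which(dt == "II")
  if (length(i2) == 0) {
    return(beta)                 # nothing to correct
  }
  if (length(i1) < min_class || length(i2) < min_class) {
    stop("input error: each non-empty design class needs >= ", min_class,
         " probes for the mixture fit", call. = FALSE)
  }
  b <- mat_of(beta)
  eps <- 1e-6
  n_noconv <- 0L
  for (s in seq_len(ncol(b))) {
    x1 <- b[i1, s]
    x2 <- b[i2, s]
    f1 <- fit_beta_mixture3(x1, max_iter = max_iter, tol = tol)
    f2 <- fit_beta_mixture3(x2, max_iter = max_iter, tol = tol)
    n_noconv <- n_noconv + !f1$converged + !f2$converged
    y <- x2
    in_u <- f2$state == 1
    in_h <- f2$state == 2
    in_m <- f2$state == 3
    # Outer states: within-state quantile map (midrank source quantiles
    # onto the empirical quantiles of the matching type I state); slopes
    # there are well determined because both states are densely populated.
    for (k in c(1, 3)) {
      in_k <- f2$state == k
      tgt <- x1[f1$state == k]
      if (sum(in_k) < 2 || length(tgt) < 10) next
      src <- x2[in_k]
      q <- (rank(src, ties.method = "average") - 0.5) / length(src)
      y[in_k] <- stats::quantile(tgt, probs = q, names = FALSE, type = 8)
    }
    # The hemimethylated state sits in the low-density valley where
    # quantile slopes are ill-conditioned, so it is mapped by a linear
    # dilation anchored at the images of the state boundaries (the
    # published method's device for this state).
    if (any(in_h)) {
      xl <- if (any(in_u)) max(x2[in_u]) else min(x2[in_h])
      xr <- if (any(in_m)) min(x2[in_m]) else max(x2[in_h])
      yl <- if (any(in_u)) max(y[in_u]) else xl
      yr <- if (any(in_m)) min(y[in_m]) else xr
      if (xr > xl && yr > yl) {
        y[in_h] <- yl + (x2[in_h] - xl) / (xr - xl) * (yr - yl)
      }
    }
    b[i2, s] <- pmin(pmax(y, eps), 1 - eps)
  }
  if (n_noconv > 0) {
    warning(n_noconv, " of ", 2 * ncol(b), " mixture fits stopped at the ",
            "iteration cap; best-likelihood iterates used", call. = FALSE)
  }
  tbl_of(b)
}

#' Transform beta values to M-values
#'
#' `M = log2(beta / (1 - beta))` after clipping beta to `[eps, 1 - eps]` so
#' the transform is finite everywhere.
#'
#' @param beta Beta-value tibble with values in `[0, 1]`.
#' @param eps Clipping bound (default 1e-6).
#' @return M-value tibble with the same axes.
#' @export
#' @examples
#' b <- tibble::tibble(probe_id = "cg1", s1 = 0.8)
#' beta_to_m(b)$s1  # log2(4) = 2
beta_to_m <- function(beta, eps = 1e-6) {
  b <- mat_of(beta)
  if (any(b < 0 | b > 1)) {
    stop("input error: beta values must lie in [0, 1]", call. = FALSE)
  }
  b <- pmin(pmax(b, eps), 1 - eps)
  tbl_of(log2(b / (1 - b)))
}

#' Transform M-values back to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`. The round trip is the
#' identity to within 1e-10 on `(eps, 1 - eps)`.
#'
#' @param m M-value tibble with finite values.
#' @return Beta-value tibble.
#' @export
m_to_beta <- function(m) {
  x <- mat_of(m)
  if (any(!is.finite(x))) {
    stop("input error: M-values must be finite", call. = FALSE)
  }
  tbl_of(stats::plogis(x * log(2)))
}
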