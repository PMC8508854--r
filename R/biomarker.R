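# Backward stepwise logistic regression over baseline methylation of
# validated CpG sites, reporting odds ratios with Wald confidence intervals.

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an optional ridge penalty on the
#' non-intercept coefficients (an escape hatch for separation in small-n,
#' many-predictor regimes). Wald standard errors come from the inverse of
#' the (penalized) observed information.
#'
#' @param x Data frame or matrix of predictors (samples x predictors), no
#'   intercept column.
#' @param y Binary response (0/1 or logical).
#' @param penalty Ridge penalty `lambda >= 0` added as `lambda * I` to the
#'   information of non-intercept terms; default 0 (pure ML).
#' @param max_iter,tol IRLS iteration controls.
#' @return List of class `meth_logit`: `coefficients` (with intercept),
#'   `se`, `vcov`, `fitted`, `deviance`, `aic`, `n`, `penalty`,
#'   `converged`.
#' @export
fit_logistic <- function(x, y, penalty = 0, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (ncol(x) > 0 && any(apply(x, 2, stats::sd) == 0)) {
    stop("input error: constant predictor column", call. = FALSE)
  }
  n <- nrow(x)
  if (penalty == 0 && n < ncol(x) + 1) {
    stop("input error: n < predictors + 1 requires `penalty` > 0",
         call. = FALSE)
  }
  xm <- cbind(`(Intercept)` = 1, x)
  p <- ncol(xm)
  pen <- diag(c(0, rep(penalty, p - 1)), p, p)

  b <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(xm %*% b)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (all(w < 1e-10)) break
    info <- crossprod(xm, xm * w) + pen
    grad <- crossprod(xm, y - mu) - pen %*% b
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) break
    b_new <- b + drop(step)
    if (max(abs(b_new - b)) < tol * (1 + max(abs(b)))) {
      b <- b_new
      converged <- TRUE
      break
    }
    b <- b_new
  }
  if (!converged && penalty == 0 &&
      (max(abs(b)) > 50 ||
       any(stats::plogis(drop(xm %*% b)) %in% c(0, 1)))) {
    stop("separation error: the groups are perfectly separated; ",
         "refit with `penalty` > 0", call. = FALSE)
  }
  eta <- drop(xm %*% b)
  mu <- stats::plogis(eta)
  info <- crossprod(xm, xm * (mu * (1 - mu))) + pen
  vc <- tryCatch(solve(info), error = function(e) {
    stop("separation error: singular information matrix; ",
         "refit with `penalty` > 0", call. = FALSE)
  })
  dev <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                    (1 - y) * log(pmax(1 - mu, 1e-12)))
  names(b) <- colnames(xm)
  dimnames(vc) <- list(colnames(xm), colnames(xm))
  structure(list(
    coefficients = b,
    se = sqrt(diag(vc)),
    vcov = vc,
    fitted = mu,
    deviance = dev,
    aic = dev + 2 * p,
    n = n,
    penalty = penalty,
    converged = converged
  ), class = c("meth_logit", "list"))
}

#' Odds ratio with a Wald confidence interval
#'
#' `OR = exp(b)` with bounds `exp(b +/- z * se)` at the requested level.
#'
#' @param coefficient Log-odds coefficient.
#' @param se Standard error (> 0 unless `level = 0`).
#' @param level Confidence level in `[0, 1)` (default 0.95).
#' @return Named list `or`, `low`, `high`.
#' @export
#' @examples
#' odds_ratio_ci(0, 1)     # OR 1, CI about (0.141, 7.10)
odds_ratio_ci <- function(coefficient, se, level = 0.95) {
  z <- stats::qnorm((1 + level) / 2)
  list(or = exp(coefficient),
       low = exp(coefficient - z * se),
       high = exp(coefficient + z * se))
}

#' Backward stepwise logistic regression
#'
#' Starting from all candidate predictors (standardized to unit SD by
#' default, so odds ratios are per 1 SD), iteratively removes the term with
#' the largest Wald p-value until every remaining free term satisfies
#' `p < alpha_stay` (criterion `"wald_p"`), or removes terms while doing so
#' lowers the AIC (criterion `"aic"`). Forced-in covariates are never
#' eliminated. Ties break by term name. The empty (intercept-only) model is
#' a valid outcome.
#'
#' @param x Data frame of candidate predictors (samples x predictors);
#'   columns named by probe id / covariate.
#' @param y Binary response: 1 = transition to the unhealthy phenotype.
#' @param alpha_stay Stay threshold for the Wald criterion (default 0.05).
#' @param criterion `"wald_p"` (default) or `"aic"`.
#' @param forced Character vector of column names never eliminated (e.g. a
#'   clinical covariate such as baseline triglycerides).
#' @param penalty Ridge penalty passed to [fit_logistic()]; default 0.
#' @param standardize Standardize predictors to unit SD (default TRUE).
#' @param level Confidence level for the odds-ratio intervals.
#' @return Object of class `meth_biomarker`: tibble `model` (term,
#'   coefficient, se, odds_ratio, ci_low, ci_high, p_value, forced),
#'   `trace` (tibble of eliminated terms and criterion values), the final
#'   `fit`, and fitting metadata. `tidy()` and `glance()` methods are
#'   provided.
#' @export
backward_stepwise <- function(x, y, alpha_stay = 0.05,
                              criterion = c("wald_p", "aic"),
                              forced = character(),
                              penalty = 0, standardize = TRUE,
                              level = 0.95) {
  criterion <- match.arg(criterion)
  x <- as.data.frame(x)
  if (ncol(x) < 1) {
    stop("input error: need >= 1 candidate predictor", call. = FALSE)
  }
  stopifnot(all(forced %in% names(x)))
  y <- as.numeric(y)

  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  if (standardize) {
    sds <- apply(xm, 2, stats::sd)
    if (any(sds == 0)) {
      stop("input error: constant predictor column", call. = FALSE)
    }
    xm <- scale(xm)
  }

  terms <- colnames(xm)
  trace <- list()
  fit <- fit_logistic(xm[, terms, drop = FALSE], y, penalty = penalty)
  repeat {
    free <- setdiff(terms, forced)
    if (length(free) == 0) break
    if (criterion == "wald_p") {
      z <- fit$coefficients[free] / fit$se[free]
      pv <- 2 * stats::pnorm(-abs(z))
      worst <- free[order(-pv, free)][1]
      if (pv[worst] < alpha_stay) break
      crit_val <- unname(pv[worst])
    } else {
      aics <- vapply(free, function(tm) {
        keep <- setdiff(terms, tm)
        if (length(keep) == 0) {
          f0 <- fit_logistic(xm[, keep, drop = FALSE], y, penalty = penalty)
          return(f0$aic)
        }
        fit_logistic(xm[, keep, drop = FALSE], y, penalty = penalty)$aic
      }, numeric(1))
      worst <- free[order(aics, free)][1]
      if (aics[worst] >= fit$aic) break
      crit_val <- unname(aics[worst])
    }
    terms <- setdiff(terms, worst)
    trace[[length(trace) + 1]] <- tibble::tibble(
      dropped = worst, criterion_value = crit_val)
    fit <- fit_logistic(xm[, terms, drop = FALSE], y, penalty = penalty)
  }

  b <- fit$coefficients[terms]
  se <- fit$se[terms]
  if (length(terms) > 0) {
    ci <- odds_ratio_ci(b, se, level)
    pv <- 2 * stats::pnorm(-abs(b / se))
    model <- tibble::tibble(
      term = terms,
      coefficient = unname(b),
      se = unname(se),
      odds_ratio = unname(ci$or),
      ci_low = unname(ci$low),
      ci_high = unname(ci$high),
      p_value = unname(pv),
      forced = terms %in% forced
    )
  } else {
    model <- tibble::tibble(
      term = character(), coefficient = numeric(), se = numeric(),
      odds_ratio = numeric(), ci_low = numeric(), ci_high = numeric(),
      p_value = numeric(), forced = logical()
    )
  }
  trace_tbl <- if (length(trace) > 0) {
    dplyr::bind_rows(trace) |>
      dplyr::mutate(step = dplyr::row_number(), .before = 1)
  } else {
    tibble::tibble(step = integer(), dropped = character(),
                   criterion_value = numeric())
  }
  structure(list(
    model = model,
    trace = trace_tbl,
    fit = fit,
    n_initial = ncol(xm),
    n_final = length(terms),
    criterion = criterion,
    alpha_stay = alpha_stay,
    penalty = penalty,
    standardized = standardize,
    level = level
  ), class = c("meth_biomarker", "list"))
}

#' @export
print.meth_biomarker <- function(x, digits = 3, ...) {
  cat("Backward stepwise logistic model (", x$criterion, "): ",
      x$n_initial, " candidates -> ", x$n_final, " retained\n", sep = "")
  if (nrow(x$model) > 0) {
    tab <- x$model
    cat(sprintf("  %-14s OR %8s  95%% CI (%s - %s)  p = %s%s\n",
                tab$term,
                signif(tab$odds_ratio, digits),
                signif(tab$ci_low, digits),
                signif(tab$ci_high, digits),
                signif(tab$p_value, 2),
                ifelse(tab$forced, "  [forced]", "")), sep = "")
  } else {
    cat("  (intercept-only model)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stepwise biomarker model
#'
#' @param x A `meth_biomarker` object.
#' @param ... Unused.
#' @return One row per retained term: `term`, `estimate` (log odds per
#'   1 SD when standardized), `std.error`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p.value`, `forced`.
#' @exportS3Method generics::tidy
tidy.meth_biomarker <- function(x, ...) {
  dplyr::rename(x$model, estimate = "coefficient", std.error = "se",
                p.value = "p_value")
}

#' One-line summary of a stepwise biomarker model
#'
#' @param x A `meth_biomarker` object.
#' @param ... Unused.
#' @return One-row tibble: candidate and retained counts, deviance, AIC,
#'   sample size, criterion, penalty.
#' @exportS3Method generics::glance
glance.meth_biomarker <- function(x, ...) {
  tibble::tibble(
    n = x$fit$n,
    n_candidates = x$n_initial,
    n_retained = x$n_final,
    deviance = x$fit$deviance,
    aic = x$fit$aic,
    criterion = x$criterion,
    penalty = x$penalty
  )
}
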