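# ggplot2 methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score plot of a fitted PCA
#'
#' Scatter of the sample scores on two components, optionally coloured by
#' group.
#'
#' @param object A `meth_pca` from [pca_fit()].
#' @param components Two component indices (default 1:2).
#' @param sheet Optional sample sheet; when given, points are coloured by
#'   `group`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.meth_pca <- function(object, components = 1:2, sheet = NULL, ...) {
  k <- components[1:2]
  df <- tibble::tibble(
    sample_id = rownames(object$scores),
    x = object$scores[, k[1]],
    y = object$scores[, k[2]]
  )
  lab <- function(i) {
    sprintf("PC%d (%.1f%%)", i, 100 * object$explained_fraction[i])
  }
  if (!is.null(sheet)) {
    df$group <- sheet$group[match(df$sample_id, sheet$sample_id)]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                          colour = .data$group))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(k[1]), y = lab(k[2])) +
    ggplot2::theme_minimal()
}

#' Forest plot of a stepwise biomarker model
#'
#' Odds ratios with confidence intervals on a log scale, one row per
#' retained term.
#'
#' @param object A `meth_biomarker` from [backward_stepwise()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.meth_biomarker <- function(object, ...) {
  df <- object$model
  if (nrow(df) == 0) {
    stop("input error: intercept-only model has nothing to plot",
         call. = FALSE)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio,
                                   y = stats::reorder(.data$term,
                                                      .data$odds_ratio))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (per 1 SD baseline M)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-site methylation difference plot
#'
#' Beta-scale group differences of validated sites at both time points,
#' coloured by direction call.
#'
#' @param sites Validated-site tibble from [validate_sites()].
#' @return A ggplot object.
#' @export
plot_site_deltas <- function(sites) {
  df <- tidyr::pivot_longer(
    sites[, c("probe_id", "direction",
              "delta_beta_baseline", "delta_beta_followup")],
    cols = dplyr::starts_with("delta_beta"),
    names_to = "timepoint", values_to = "delta_beta",
    names_prefix = "delta_beta_"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_beta,
                                   y = .data$probe_id,
                                   colour = .data$direction,
                                   shape = .data$timepoint)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Delta * beta ~ "(stable - unstable)"),
                  y = NULL) +
    ggplot2::theme_minimal()
}
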