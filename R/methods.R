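#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted vulnerability-type factor analysis
#'
#' @param x An `svf_efa` object.
#' @param threshold Loading threshold used to flag included cells.
#' @param ... Unused.
#' @return A tibble with one row per indicator x factor: `indicator`,
#'   `factor`, `loading`, `included` (|loading| at or above the threshold).
#' @method tidy svf_efa
#' @export
tidy.svf_efa <- function(x, threshold = x$threshold, ...) {
  L <- x$loadings
  tibble(
    indicator = rep(rownames(L), times = ncol(L)),
    factor = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L),
    included = abs(as.vector(L)) >= threshold
  )
}

#' One-row summary of a fitted vulnerability-type factor analysis
#'
#' @param x An `svf_efa` object.
#' @param ... Unused.
#' @return A tibble: `n`, `k`, `n_indicators`, `n_included`,
#'   `prop_variance` (share of total correlation-matrix variance carried by
#'   the first k eigenvalues), `min_congruence` vs the reference pattern (if
#'   labelled).
#' @method glance svf_efa
#' @export
glance.svf_efa <- function(x, ...) {
  tibble(
    n = x$n,
    k = x$k,
    n_indicators = nrow(x$loadings),
    n_included = length(svf_included_indicators(x)),
    prop_variance = sum(x$eigenvalues[seq_len(x$k)]) / sum(x$eigenvalues),
    min_congruence = if (is.null(x$congruence)) NA_real_ else min(x$congruence)
  )
}

#' Loading heatmap of a fitted factor analysis
#'
#' @param object An `svf_efa` object.
#' @param threshold Cells at or above this absolute loading are outlined.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot svf_efa
#' @export
autoplot.svf_efa <- function(object, threshold = object$threshold, ...) {
  td <- tidy(object, threshold = threshold)
  td$indicator <- factor(td$indicator, levels = rev(rownames(object$loadings)))
  td$factor <- factor(td$factor, levels = colnames(object$loadings))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$factor, y = .data$indicator)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$loading), colour = "grey85") +
    ggplot2::geom_tile(
      data = td[td$included, ], fill = NA,
      colour = "black", linewidth = 0.5
    ) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading)),
      size = 2.6
    ) +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "white",
      high = "#B2182B", limits = c(-1, 1)
    ) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "loading",
      title = "Vulnerability-type loadings",
      subtitle = paste0("outlined: |loading| ≥ ", threshold)
    ) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Forest plot of risk-factor shift estimates
#'
#' Hodges-Lehmann location shifts (with confidence intervals) of each
#' non-reference risk-factor stratum against its reference, per metric.
#'
#' @param object An `svf_associations` tibble.
#' @param metrics Metrics to display (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot svf_associations
#' @export
autoplot.svf_associations <- function(object, metrics = unique(object$metric), ...) {
  d <- object[!object$reference & object$metric %in% metrics &
    !is.na(object$estimate), , drop = FALSE]
  d$label <- paste0(d$risk_factor, ": ", d$level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(
      x = "Hodges–Lehmann shift vs reference", y = NULL,
      title = "Risk-factor associations"
    ) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Distribution of vulnerability scores
#'
#' @param scores A score tibble from [svf_score()].
#' @return A ggplot of the simple and family-weighted score distributions.
#' @export
plot_score_distribution <- function(scores) {
  d <- tidyr::pivot_longer(scores[, c("simple", "weighted")],
    cols = dplyr::everything(),
    names_to = "score", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::facet_wrap(~score, scales = "free") +
    ggplot2::labs(
      x = "score", y = "families",
      title = "Vulnerability score distributions"
    ) +
    ggplot2::theme_minimal(base_size = 10)
}
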