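#' Forest plot of per-protein MR estimates
#'
#' Odds ratios with 95% confidence intervals on a log scale, one row per
#' protein (and facet per stratum when several are present); FDR-significant
#' proteins are highlighted when an `fdr_p` column exists.
#'
#' @param results MR results tibble (e.g. from [run_overall()] or
#'   [mr_ivw_all()]).
#' @param fdr_threshold Highlight cutoff on `fdr_p`.
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(results, fdr_threshold = 0.05) {
  d <- dplyr::filter(tibble::as_tibble(results), !.data$is_na)
  if (nrow(d) == 0) stop_data("plot_mr_forest: no analyzable results")
  d$significant <- if ("fdr_p" %in% names(d)) {
    !is.na(d$fdr_p) & d$fdr_p < fdr_threshold
  } else {
    FALSE
  }
  d$protein_id <- stats::reorder(d$protein_id, d$or)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$protein_id,
                                       colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
      guide = "none"
    ) +
    ggplot2::labs(
      x = "OR per SD of genetically predicted protein (95% CI)",
      y = NULL
    ) +
    ggplot2::theme_minimal()
  if (length(unique(d$stratum)) > 1) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}

#' Scatter diagnostic of an IVW fit
#'
#' Per-SNP outcome effects against exposure effects with their 95% error
#' bars and the fitted IVW slope through the origin — the standard visual
#' check that the instruments tell one consistent dose-response story.
#'
#' @param object An `ivw_fit` from [ivw_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ivw_fit <- function(object, ...) {
  if (object$is_na) stop_data("autoplot.ivw_fit: fit is not analyzable")
  d <- tibble::as_tibble(object$data)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_gx, y = .data$beta_gy)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_gy - 1.96 * .data$se_gy,
      ymax = .data$beta_gy + 1.96 * .data$se_gy
    ), width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$beta, intercept = 0,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "SNP effect on protein (SD per allele)",
      y = "SNP effect on disease (log OR per allele)",
      title = sprintf("IVW slope %.3f (se %.3f)", object$beta, object$se)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
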