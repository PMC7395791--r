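#' Decomposition plot for an RA prediction
#'
#' Bar chart of the multiplicative RA decomposition: the
#' effect-correlation/heritability term, the LD+MAF term, the
#' PGS-variance ratio, and their product.
#'
#' @param object an `ra_prediction`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ra_prediction <- function(object, ...) {
  df <- tidy(object)
  df$term <- factor(df$term, levels = df$term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "multiplier",
                  title = sprintf("Predicted RA = %.3f (%s mode)",
                                  object$ra, object$mode)) +
    ggplot2::theme_minimal()
}

#' Observed versus predicted RA across replicates
#'
#' Box plots of the observed RA and the three deterministic predictions
#' over replicates, one facet per scenario/population pair.
#'
#' @param records replicate records from [run_scenario()].
#' @return A ggplot.
#' @export
plot_ra_replicates <- function(records) {
  valid <- records[records$m_t > 0, ]
  long <- tidyr::pivot_longer(
    valid,
    cols = c("ra_obs", "ra_pred_known", "ra_pred_heuristic", "ra_pred_naive"),
    names_to = "estimate", values_to = "ra"
  )
  long$estimate <- factor(
    long$estimate,
    levels = c("ra_obs", "ra_pred_known", "ra_pred_heuristic", "ra_pred_naive"),
    labels = c("observed", "known causals", "heuristic", "naive")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate, y = .data$ra)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_grid(scenario_id ~ population_pair) +
    ggplot2::labs(x = NULL, y = "relative accuracy") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bias summary plot
#'
#' Signed relative bias of each predictor (with jackknife error bars)
#' per scenario and population pair.
#'
#' @param bias bias summaries from [summarize_bias()].
#' @return A ggplot.
#' @export
plot_bias_summary <- function(bias) {
  ggplot2::ggplot(bias, ggplot2::aes(x = .data$mode, y = .data$signed_bias_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$signed_bias_pct - .data$jackknife_se,
                   ymax = .data$signed_bias_pct + .data$jackknife_se),
      width = 0.15) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_grid(scenario_id ~ population_pair) +
    ggplot2::labs(x = NULL, y = "signed bias of predicted RA (%)") +
    ggplot2::theme_bw()
}
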