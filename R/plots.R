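#' Rank-abundance (Whittaker) plot
#'
#' Species rank against natural-log abundance, one line per sample,
#' optionally faceted by treatment.
#'
#' @param configs Configurations tibble from [as_configurations()].
#' @param samples Optional character vector of sample ids to keep.
#' @param facet_by_treatment Facet panels by treatment.
#' @return A ggplot object.
#' @export
plot_rank_abundance <- function(configs, samples = NULL,
                                facet_by_treatment = FALSE) {
  if (!is.null(samples)) configs <- configs[configs$sample_id %in% samples, ]
  ra <- rank_abundance(configs)
  ra <- dplyr::left_join(ra, dplyr::select(configs, "sample_id", "treatment"),
                         by = "sample_id")
  p <- ggplot2::ggplot(ra, ggplot2::aes(x = .data$rank, y = .data$log_abundance,
                                        group = .data$sample_id,
                                        colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Species rank", y = "ln(abundance)",
                  colour = "Sample") +
    ggplot2::theme_minimal()
  if (facet_by_treatment) p <- p + ggplot2::facet_wrap(~treatment)
  p
}

#' Mean biodiversity number per treatment
#'
#' Bar chart of the mean fitted theta per treatment with one-standard-
#' deviation error bars.
#'
#' @param fits Tibble with `treatment` and `theta` columns ([fit_sad()] or
#'   [test_neutrality()] output).
#' @return A ggplot object.
#' @export
plot_theta_means <- function(fits) {
  autoplot(theta_group_comparison(fits))
}

#' @rdname theta_group_comparison
#' @param object A `theta_anova` object.
#' @param ... Ignored.
#' @export
autoplot.theta_anova <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$treatment, y = .data$mean_theta,
                                  fill = .data$treatment)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_theta - .data$sd_theta,
                                        ymax = .data$mean_theta + .data$sd_theta),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "Mean fundamental biodiversity number θ") +
    ggplot2::theme_minimal()
}

#' @rdname exact_neutrality_test
#' @param object A `neutrality_test` object.
#' @param ... Ignored.
#' @export
autoplot.neutrality_test <- function(object, ...) {
  d <- tibble::tibble(logL = object$logL_sims)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$logL)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$logL_obs, colour = "red") +
    ggplot2::geom_vline(xintercept = object$mean_logL_sims,
                        linetype = "dashed") +
    ggplot2::labs(x = "Simulated log-likelihood",
                  y = "Count",
                  title = sprintf("Observed logL (red) vs %d simulations; p = %.4f",
                                  object$n_sims, object$p_value)) +
    ggplot2::theme_minimal()
}
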