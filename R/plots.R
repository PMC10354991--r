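# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
#' @method autoplot abundance_tbl
autoplot.abundance_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample_id, y = .data$rel_pct,
                               fill = .data$site_id)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = NULL, y = "relative abundance (%)", fill = "integration site",
      title = sprintf("Site abundance (%s)",
                      attr(object, "method") %||% "reads")
    ) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot theta_fit
autoplot.theta_fit <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$d, y = .data$theta)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$converged)) +
    ggplot2::labs(
      x = "distinct fragment lengths (d)",
      y = expression(hat(theta)),
      title = "Fragment-length MLE vs raw shear-site diversity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a read-processing rejection funnel
#'
#' @param funnel Tibble from [rejection_funnel()].
#' @return A ggplot.
#' @export
plot_funnel <- function(funnel) {
  funnel$stage <- factor(funnel$stage, levels = funnel$stage)
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "read pairs",
                  title = "Oligo-parsing funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a merge-window sweep
#'
#' @param sweep Tibble from [sweep_window()].
#' @param default_window Reference line (default 7).
#' @return A ggplot.
#' @export
plot_window_sweep <- function(sweep, default_window = 7) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$window,
                                      y = .data$n_sites)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = default_window, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "merge window (bp)", y = "integration sites",
                  title = "Site count vs merge window") +
    ggplot2::theme_minimal()
}
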