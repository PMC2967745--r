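#' Scree plot of covariance eigenvalues
#'
#' Plots the descending eigenvalue curve with the scree-elbow component
#' count marked, for judging how many latent factors the data support.
#'
#' @param x A `clinarica_ica` / `clinarica_ensemble` object, or a numeric
#'   vector of descending eigenvalues.
#' @return A ggplot object.
#' @export
plot_scree <- function(x) {
  lam <- if (is.numeric(x)) x else x$eigenvalues
  if (is.null(lam)) abort("no eigenvalues found in x.")
  k <- n_components_scree(lam)
  df <- tibble::tibble(index = seq_along(lam), eigenvalue = lam)
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$eigenvalue)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = k + 0.5, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::annotate("text", x = k + 0.7, y = max(lam),
                      label = sprintf("retain %d", k), hjust = 0, size = 3) +
    ggplot2::labs(x = "component", y = "eigenvalue",
                  title = "Scree of the clinarray covariance") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.clinarica_ica <- function(object, ...) plot_scree(object)

#' Loading-distribution plot for an ensemble
#'
#' Shows each biomarker's absolute loadings across all converged runs and
#' components (one point per run x component), ordered by mean.
#'
#' @param object A `clinarica_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.clinarica_ensemble <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$converged)
  ord <- df |>
    dplyr::group_by(.data$biomarker) |>
    dplyr::summarise(m = mean(.data$abs_loading)) |>
    dplyr::arrange(.data$m)
  df$biomarker <- factor(df$biomarker, levels = ord$biomarker)
  ggplot2::ggplot(df, ggplot2::aes(.data$abs_loading, .data$biomarker)) +
    ggplot2::geom_jitter(height = 0.2, alpha = 0.2, size = 0.4) +
    ggplot2::labs(x = "absolute loading", y = NULL,
                  title = "Ensemble loading distribution") +
    ggplot2::theme_minimal()
}

#' Consensus result plot
#'
#' Mean absolute loading per biomarker with the top-fraction threshold and
#' both significance calls.
#'
#' @param object A `clinarica_consensus`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.clinarica_consensus <- function(object, ...) {
  df <- tidy(object)
  df$biomarker <- factor(df$biomarker, levels = rev(df$biomarker))
  df$call <- dplyr::case_when(
    df$significant_topfrac & df$significant_argmax ~ "both rules",
    df$significant_topfrac ~ "top-fraction only",
    df$significant_argmax ~ "argmax only",
    TRUE ~ "not significant"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_abs_loading, .data$biomarker,
                                   colour = .data$call)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$biomarker),
                          colour = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$threshold_value,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean absolute loading", y = NULL, colour = NULL,
                  title = "Consensus significant biomarkers",
                  subtitle = sprintf("threshold %.3g (%s basis); methods %s",
                                     object$threshold_value,
                                     object$threshold_basis,
                                     if (object$methods_agree) "agree" else "disagree")) +
    ggplot2::theme_minimal()
}
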