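#' Plot an association battery
#'
#' Dot plot of the partial Spearman rho for every predictor x outcome
#' pair, annotated with its two-tailed p-value.
#'
#' @param object A `cpm_associations` tibble from
#'   [run_association_battery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpm_associations <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$outcome, y = .data$rho, colour = .data$predictor
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(
      size = 3,
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("p=%.3g", .data$p)),
      position = ggplot2::position_dodge(width = 0.4),
      vjust = -1, size = 3, show.legend = FALSE
    ) +
    ggplot2::labs(
      y = "partial Spearman rho", x = NULL,
      title = "Network strength associations",
      subtitle = paste0("covariates: ", d$covariates[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a lesion analysis
#'
#' Whole-brain vs lesioned association per canonical network; segments
#' show the change the lesion induced, labels give Steiger's Z.
#'
#' @param object A `cpm_lesion` tibble from [lesion_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpm_lesion <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object),
    c("rho_whole", "rho_lesioned"),
    names_to = "model", names_prefix = "rho_", values_to = "rho"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$network, y = .data$rho, colour = .data$model
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(group = .data$network), colour = "grey40") +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(
      data = as_tibble(object),
      ggplot2::aes(
        x = .data$network,
        y = pmax(.data$rho_whole, .data$rho_lesioned, na.rm = TRUE),
        label = sprintf("Z=%.2f", .data$steiger_z)
      ),
      inherit.aes = FALSE, vjust = -1, size = 3
    ) +
    ggplot2::labs(
      y = "partial Spearman rho", x = "lesioned network",
      title = "Whole-brain vs lesioned associations",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot leave-one-out CPM predictions
#'
#' Predicted vs observed behavior from the leave-one-out folds, one panel
#' per model polarity.
#'
#' @param object A `cpm_model` from [train_cpm_loo()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpm_model <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$predictions,
    c("predicted_high", "predicted_low"),
    names_to = "polarity", names_prefix = "predicted_",
    values_to = "predicted"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$observed, y = .data$predicted
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~polarity) +
    ggplot2::labs(
      x = "observed behavior", y = "LOO-predicted behavior",
      title = "Leave-one-out CPM predictions"
    ) +
    ggplot2::theme_minimal()
}

#' Tidy an association battery (identity on its columns)
#' @param x A `cpm_associations` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.cpm_associations <- function(x, ...) as_tibble(x)

#' Tidy a lesion analysis (identity on its columns)
#' @param x A `cpm_lesion` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.cpm_lesion <- function(x, ...) as_tibble(x)
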