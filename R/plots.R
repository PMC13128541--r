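#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_hline geom_vline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a robustness curve
#'
#' Natural connectivity (mean +/- sd ribbon) against the fraction of
#' randomly removed nodes.
#'
#' @param object A `robustness_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.robustness_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$fraction, y = .data$mean_nc)) +
    geom_ribbon(aes(ymin = .data$mean_nc - .data$sd_nc,
                    ymax = .data$mean_nc + .data$sd_nc), alpha = 0.25) +
    geom_line() + geom_point(size = 1) +
    labs(x = "fraction of nodes removed", y = "natural connectivity") +
    theme_minimal()
}

#' Plot Zi-Pi node roles
#'
#' Participation coefficient against within-module degree z-score, with
#' the conventional role thresholds drawn (Pi = 0.62, Zi = 2.5).
#'
#' @param object A `node_role_table` from [zi_pi()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.node_role_table <- function(object, ...) {
  ggplot(object, aes(x = .data$pi, y = .data$zi, colour = .data$role)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = 2.5, linetype = "dashed") +
    geom_vline(xintercept = 0.62, linetype = "dashed") +
    labs(x = "participation coefficient (Pi)",
         y = "within-module degree z-score (Zi)", colour = NULL) +
    theme_minimal()
}

#' Plot a SPEC-OCCU table
#'
#' Specificity against occupancy per habitat; the specialist corner
#' (both > 0.7 by default) is delimited with dashed lines.
#'
#' @param object A `spec_occu_table` from [spec_occu()].
#' @param spec_min,occu_min Threshold lines (default 0.7).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spec_occu_table <- function(object, spec_min = 0.7, occu_min = 0.7, ...) {
  ggplot(object, aes(x = .data$occupancy, y = .data$specificity,
                     colour = .data$specialist)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = spec_min, linetype = "dashed") +
    geom_vline(xintercept = occu_min, linetype = "dashed") +
    facet_wrap(~habitat) +
    labs(x = "occupancy", y = "specificity", colour = "specialist") +
    theme_minimal()
}

#' Plot per-sample cohesion by treatment
#'
#' Total cohesion per sample, grouped by a metadata column when sample
#' metadata is joined in.
#'
#' @param object A `cohesion_result` from [cohesion()].
#' @param meta Optional sample metadata tibble with `sample_id` and
#'   `treatment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohesion_result <- function(object, meta = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(meta)) df <- df |> left_join(meta, by = "sample_id")
  long <- df |>
    pivot_longer(c("pos_cohesion", "neg_cohesion", "total_cohesion"),
                 names_to = "component", values_to = "value")
  p <- if ("treatment" %in% names(long)) {
    ggplot(long, aes(x = .data$treatment, y = .data$value)) +
      ggplot2::geom_boxplot()
  } else {
    ggplot(long, aes(x = .data$sample_id, y = .data$value)) +
      ggplot2::geom_col()
  }
  p + facet_wrap(~component, scales = "free_y") +
    labs(x = NULL, y = "cohesion") + theme_minimal()
}
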