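#' Heatmap of a signed connectivity matrix
#'
#' Nodes optionally ordered by a module partition, with module
#' boundaries drawn.
#'
#' @param W connectivity matrix.
#' @param partition optional partition used to order nodes.
#' @return a ggplot.
#' @export
plot_connectivity <- function(W, partition = NULL) {
  W <- as.matrix(W)
  labels <- rownames(W)
  ord <- seq_len(nrow(W))
  if (!is.null(partition)) ord <- order(as_affiliation(partition))
  W <- W[ord, ord]
  df <- as_tibble(as.table(W), .name_repair = ~ c("row", "col", "weight")) |>
    mutate(row = factor(.data$row, levels = rev(labels[ord])),
           col = factor(.data$col, levels = labels[ord]))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a posterior-predictive check
#'
#' @param object a `posterior_predictive` table.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.posterior_predictive <- function(object, ...) {
  df <- object |>
    pivot_longer(cols = c("obs_mean_rt", "obs_error_rate"),
                 names_to = "measure", values_to = "observed") |>
    mutate(
      predicted = ifelse(.data$measure == "obs_mean_rt",
                         .data$pred_mean_rt, .data$pred_error_rate),
      lo = ifelse(.data$measure == "obs_mean_rt", .data$rt_lo, .data$er_lo),
      hi = ifelse(.data$measure == "obs_mean_rt", .data$rt_hi, .data$er_hi),
      measure = ifelse(.data$measure == "obs_mean_rt", "mean RT (s)",
                       "error rate"))
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted,
                                   colour = .data$session)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0, alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "observed", y = "posterior predictive") +
    ggplot2::theme_minimal()
}

#' Plot joint-model slopes with credible intervals and Bayes factors
#'
#' @param object a `joint_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.joint_fit <- function(object, ...) {
  df <- object$betas %||% joint_beta_summary(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$median, .data$parameter)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$q2.5,
                                         xmax = .data$q97.5),
                            height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("BF = %.2g", .data$bf)),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "slope on brain-network change (95% CrI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the headline brain-behaviour relation of a pipeline run
#'
#' @param object a `pipeline_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pipeline_result <- function(object, ...) {
  ch <- object$summary_wide
  ggplot2::ggplot(ch, ggplot2::aes(.data$d_diversity, .data$d_efficiency)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::labs(
      x = "change in hippocampal diversity coefficient",
      y = "change in memory-retrieval efficiency") +
    ggplot2::theme_minimal()
}

#' Diversity change per node with significance marks
#'
#' @param node_tests output of [node_change_tests()].
#' @param q FDR threshold for the significance mark.
#' @return a ggplot.
#' @export
plot_node_changes <- function(node_tests, q = 0.05) {
  df <- node_tests |>
    mutate(sig = .data$p_adj < q,
           node = factor(.data$node,
                         levels = node_tests$node[order(node_tests$median_change)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$median_change, .data$node,
                                   colour = .data$sig)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "median diversity change (post - pre)", y = NULL,
                  colour = sprintf("FDR < %.2g", q)) +
    ggplot2::theme_minimal(base_size = 9)
}
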