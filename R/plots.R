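#' Plot module evaluation against the null benchmarks
#'
#' One panel per statistic (AUC, cross-omic rho): observed module values
#' as points, null mean +/- SD as gray points and ranges. Modules passing
#' the full classification are drawn darker.
#'
#' @param object a `module_evaluation` tibble (or `module_discovery`).
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot module_evaluation
autoplot.module_evaluation <- function(object, ...) {
  ev <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    dplyr::transmute(ev, module_id = .data$module_id, statistic = "AUC",
                     observed = .data$auc, null_mean = .data$auc_null_mean,
                     null_sd = .data$auc_null_sd,
                     disease_associated = .data$disease_associated),
    dplyr::transmute(ev, module_id = .data$module_id,
                     statistic = "cross-omic rho",
                     observed = .data$rho, null_mean = .data$rho_null_mean,
                     null_sd = .data$rho_null_sd,
                     disease_associated = .data$disease_associated)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$module_id)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$null_mean - .data$null_sd,
                   ymax = .data$null_mean + .data$null_sd),
      colour = "gray60"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_mean), colour = "gray60") +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$observed, alpha = .data$disease_associated),
      colour = "#1b6ca8", size = 3
    ) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.45, `TRUE` = 1),
                                guide = "none") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "statistic (observed vs null mean ± SD)") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot module_discovery
autoplot.module_discovery <- function(object, ...) {
  autoplot.module_evaluation(object$evaluation, ...)
}

#' Plot one consensus module's co-occurrence subnetwork
#'
#' Nodes are module features coloured by omic; edges are co-occurrence
#' relations weighted by their frequency across subsample runs.
#'
#' @param result a `module_discovery` (or `consensus_modules`).
#' @param module_id which module to draw (default: the first).
#' @param seed layout seed.
#' @return A ggplot.
#' @export
plot_module_network <- function(result, module_id = NULL, seed = 1L) {
  modules <- if (inherits(result, "module_discovery")) result$modules else result
  module_id <- module_id %||% modules$members$module_id[1]
  mem <- dplyr::filter(modules$members, .data$module_id == !!module_id)
  edg <- dplyr::filter(modules$edges, .data$module_id == !!module_id)
  stopifnot(nrow(mem) > 0)
  g <- igraph::graph_from_data_frame(
    edg[, c("feature_a", "feature_b", "frequency")],
    directed = FALSE, vertices = mem$feature
  )
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(feature = igraph::V(g)$name,
                          x = xy[, 1], y = xy[, 2],
                          omic = omic_of_feature(igraph::V(g)$name))
  seg <- dplyr::left_join(edg, nodes, by = c("feature_a" = "feature")) |>
    dplyr::left_join(nodes, by = c("feature_b" = "feature"),
                     suffix = c("", "_b"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_b,
                   yend = .data$y_b, linewidth = .data$frequency),
      colour = "gray70"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$omic), size = 4
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   label = sub("^[A-Za-z]+:", "", .data$feature)),
      vjust = -1.1, size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5), limits = c(0, 1)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "omic", linewidth = "co-occurrence")
}
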