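#' Tidy a metabolic network into its edge table
#'
#' @param x A `metabolic_network`.
#' @param ... Unused.
#' @return A tibble `from`, `to`, `metabolite`.
#' @method tidy metabolic_network
#' @export
tidy.metabolic_network <- function(x, ...) {
  as_tibble(x$edges)
}

#' One-row summary of a metabolic network
#'
#' @param x A `metabolic_network`.
#' @param ... Unused.
#' @return A one-row tibble with node, edge and component counts and the
#'   average shortest path length.
#' @method glance metabolic_network
#' @export
glance.metabolic_network <- function(x, ...) {
  s <- network_summary(x)
  tibble(
    n_nodes = s$n_nodes, n_edges_parallel = s$n_edges_parallel,
    n_edges_simple = s$n_edges_simple, n_components = s$n_components,
    avg_shortest_path = s$avg_shortest_path,
    mode = x$mode, collapsed = x$collapsed
  )
}

#' Tidy a keystone report
#'
#' @param x A `keystone_report`.
#' @param ... Unused.
#' @return The per-candidate tibble with threshold pass indicators and the
#'   `selected` flag.
#' @method tidy keystone_report
#' @export
tidy.keystone_report <- function(x, ...) {
  as_tibble(x$candidates)
}

#' One-row summary of a keystone selection
#'
#' @param x A `keystone_report`.
#' @param ... Unused.
#' @return A one-row tibble with candidate/selection counts, thresholds
#'   and quantile configuration.
#' @method glance keystone_report
#' @export
glance.keystone_report <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$candidates),
    n_selected = nrow(x$selected),
    load_threshold = x$thresholds$load_score,
    expr_threshold = x$thresholds$rel_expr,
    load_quantile = x$config$load_quantile,
    expr_quantile = x$config$expr_quantile,
    tie_policy = x$config$tie_policy
  )
}

#' Plot load score against relative expression for keystone selection
#'
#' Scatter of every scored node with the two empirical selection
#' thresholds as dashed lines; nodes passing both criteria (the selected
#' key functionalities) are highlighted.
#'
#' @param object A `keystone_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot keystone_report
#' @export
autoplot.keystone_report <- function(object, ...) {
  df <- object$candidates |>
    filter(!is.na(.data$rel_expr)) |>
    mutate(status = if_else(.data$selected, "key functionality", "other"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$load_score,
                                   y = .data$rel_expr)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status,
                                     shape = .data$status), size = 2) +
    ggplot2::geom_vline(xintercept = object$thresholds$load_score,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = object$thresholds$rel_expr,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_colour_manual(values = c("key functionality" = "#b2182b",
                                            "other" = "grey40")) +
    ggplot2::labs(
      x = "load score", y = "relative gene expression (KOTA / KOGA)",
      colour = NULL, shape = NULL,
      title = "Key-functionality selection",
      subtitle = sprintf(
        "dashed lines: top %.0f%% load score, top %.0f%% relative expression",
        100 * object$config$load_quantile, 100 * object$config$expr_quantile
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a topology table
#'
#' Degree against betweenness centrality on log axes, point size
#' proportional to load score, choke points highlighted.
#'
#' @param object A `konet_topology` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot konet_topology
#' @export
autoplot.konet_topology <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$degree > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree,
                                   y = .data$betweenness + 1)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$load_score,
                                     colour = .data$choke_point),
                        alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey40"),
                                 labels = c(`TRUE` = "choke point",
                                            `FALSE` = "other")) +
    ggplot2::labs(x = "node degree", y = "betweenness centrality + 1",
                  size = "load score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a metabolic network
#'
#' Force-directed layout (reproducible via `seed`) with nodes sized by
#' degree; parallel metabolite edges are drawn once.
#'
#' @param object A `metabolic_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metabolic_network
#' @export
autoplot.metabolic_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object, simple = TRUE)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(
    node_id = object$nodes$node_id, x = xy[, 1], y = xy[, 2],
    degree = edge_counts(object, "simple")$degree
  )
  edges <- distinct(object$edges, .data$from, .data$to) |>
    left_join(rename(nodes, from_x = "x", from_y = "y"),
              by = c(from = "node_id")) |>
    left_join(rename(nodes, to_x = "x", to_y = "y"),
              by = c(to = "node_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$from_x, y = .data$from_y,
                   xend = .data$to_x, yend = .data$to_y),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
      colour = "#2166ac", alpha = 0.8
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "degree")
}
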