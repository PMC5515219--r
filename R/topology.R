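#' Betweenness centrality of network nodes
#'
#' For each node `n`, sums `sigma_st(n) / sigma_st` over unordered node
#' pairs `{s, t}` with `s != n != t`, where `sigma_st` counts shortest paths
#' between `s` and `t` and `sigma_st(n)` those passing through `n`
#' (endpoints excluded). Path finding runs on the simple underlying graph:
#' parallel metabolite edges never change hop distances. Pairs in different
#' components contribute zero.
#'
#' @param net A `metabolic_network`.
#' @param normalized Divide by `(N-1)(N-2)/2`, the number of node pairs.
#'   Off by default; ranking within a fixed network is unaffected.
#' @return A named numeric vector over node ids.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "metabolic_network"))
  if (nrow(net$nodes) == 0) abort("Network has no nodes.")
  g <- as_igraph(net, simple = TRUE)
  b <- igraph::betweenness(g, directed = FALSE, weights = NULL)
  if (normalized) {
    n <- nrow(net$nodes)
    b <- if (n > 2) b / ((n - 1) * (n - 2) / 2) else b * 0
  }
  b[net$nodes$node_id]
}

# degree and total-edge count under an edge-counting convention
edge_counts <- function(net, convention) {
  if (convention == "parallel") {
    edges <- net$edges
  } else {
    edges <- distinct(net$edges, .data$from, .data$to)
  }
  ends <- c(edges$from, edges$to)
  k <- table(factor(ends, levels = net$nodes$node_id))
  list(degree = as.numeric(k), sigma_e = nrow(edges))
}

#' Topological load scores
#'
#' The load score of node `n` is its betweenness centrality divided by the
#' product of its node degree `k_n` and the total number of edges in the
#' network: `load(n) = sum_{s != n != t} (sigma_st(n) / sigma_st) / (k_n *
#' sum_e)`. High-load nodes ("load points") carry many metabolite
#' conversion routes relative to their connectivity. Degree and total edge
#' count follow the chosen convention: `"parallel"` (default) counts one
#' edge per shared metabolite, `"simple"` counts node adjacencies once.
#' Isolated nodes get load score 0.
#'
#' @inheritParams betweenness_centrality
#' @param edge_count_convention `"parallel"` or `"simple"`.
#' @return A named numeric vector over node ids, with attribute `sigma_e`.
#' @export
load_score <- function(net, edge_count_convention = c("parallel", "simple"),
                       normalized = FALSE) {
  edge_count_convention <- match.arg(edge_count_convention)
  b <- betweenness_centrality(net, normalized = normalized)
  ec <- edge_counts(net, edge_count_convention)
  ls <- ifelse(ec$degree > 0 & ec$sigma_e > 0,
               b / (ec$degree * ec$sigma_e), 0)
  names(ls) <- net$nodes$node_id
  attr(ls, "sigma_e") <- ec$sigma_e
  ls
}

# 1/occurrence weights per edge; occurrence(m) = number of nodes whose
# pair-set touches metabolite m
metabolite_occurrence <- function(net) {
  long <- purrr::map2_dfr(net$nodes$node_id, net$nodes$pair_set,
                          function(id, ps) {
    tibble(node = id, metabolite = pair_set_metabolites(ps))
  })
  counts <- long |> count(.data$metabolite, name = "occurrence")
  setNames(counts$occurrence, counts$metabolite)
}

#' Occurrence-weighted load scores
#'
#' Variant load score in which shortest paths are computed with edge
#' lengths equal to `occurrence(m)`, where `occurrence(m)` counts the
#' nodes whose pair-set contains metabolite `m`. Edges through ubiquitous
#' (currency-like) metabolites thereby cost more than edges through
#' rarely-shared, pathway-specific ones, restricting load points to nodes
#' within pathways. Between a node pair linked by several metabolites the
#' cheapest (rarest) label is used. Requires pair-set information (not
#' available on imported networks).
#'
#' @inheritParams load_score
#' @return A named numeric vector over node ids, labelled with attribute
#'   `variant = "occurrence_weighted"`.
#' @export
weighted_load_score <- function(net,
                                edge_count_convention = c("parallel",
                                                          "simple")) {
  edge_count_convention <- match.arg(edge_count_convention)
  stopifnot(inherits(net, "metabolic_network"))
  if (nrow(net$nodes) == 0) abort("Network has no nodes.")
  occ <- metabolite_occurrence(net)
  if (nrow(net$edges) > 0 && !all(net$edges$metabolite %in% names(occ))) {
    abort(paste(
      "Edge metabolites missing from node pair-sets;",
      "weighted load scores need pair-set annotations."
    ))
  }
  w <- if (nrow(net$edges) > 0) occ[net$edges$metabolite] else numeric(0)
  g <- as_igraph(net, simple = TRUE, weights = as.numeric(w))
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = igraph::E(g)$weight)
  b <- b[net$nodes$node_id]
  ec <- edge_counts(net, edge_count_convention)
  ls <- ifelse(ec$degree > 0 & ec$sigma_e > 0,
               b / (ec$degree * ec$sigma_e), 0)
  names(ls) <- net$nodes$node_id
  attr(ls, "sigma_e") <- ec$sigma_e
  attr(ls, "variant") <- "occurrence_weighted"
  ls
}

#' Choke points: consumers or producers of unique metabolites
#'
#' A choke point is a KO (or node group) whose pair-set contains at least
#' one metabolite that no other member of the subset touches — the sole
#' consumer and/or producer of that metabolite in the community.
#'
#' @param pair_map Reaction-pair map tibble.
#' @param ko_subset KOs forming the community under consideration.
#' @return A tibble `ko_id`, `unique_metabolites` (list-column), one row per
#'   choke point.
#' @export
choke_points <- function(pair_map, ko_subset) {
  pair_map <- validate_pair_map(pair_map)
  ko_subset <- unique(ko_subset)
  long <- pair_map |>
    filter(.data$ko_id %in% ko_subset) |>
    tidyr::pivot_longer(c("substrate", "product"), values_to = "metabolite") |>
    distinct(.data$ko_id, .data$metabolite)
  occurrence <- count(long, .data$metabolite, name = "n_kos")
  long |>
    inner_join(occurrence, by = "metabolite") |>
    filter(.data$n_kos == 1) |>
    group_by(.data$ko_id) |>
    summarise(unique_metabolites = list(sort(.data$metabolite)),
              .groups = "drop") |>
    arrange(.data$ko_id)
}

#' Per-node topology table
#'
#' Computes degree, betweenness centrality, load score, the
#' occurrence-weighted load-score variant (when pair-sets are available)
#' and the choke-point flag for every node of a reconstructed network.
#'
#' @inheritParams load_score
#' @param weighted Also compute the occurrence-weighted variant (needs
#'   pair-set annotations).
#' @return A tibble of class `konet_topology` with columns `node_id`,
#'   `members` (list), `degree`, `betweenness`, `load_score`,
#'   `weighted_load_score`, `choke_point`, `unique_metabolites` (list),
#'   `isolated`; attributes `sigma_e`, `edge_count_convention`.
#' @export
topology_table <- function(net,
                           edge_count_convention = c("parallel", "simple"),
                           normalized = FALSE, weighted = TRUE) {
  edge_count_convention <- match.arg(edge_count_convention)
  stopifnot(inherits(net, "metabolic_network"))
  b <- betweenness_centrality(net, normalized = normalized)
  ec <- edge_counts(net, edge_count_convention)
  ls <- load_score(net, edge_count_convention, normalized = normalized)
  has_pairs <- any(vapply(net$nodes$pair_set, nrow, integer(1)) > 0)
  wls <- if (weighted && has_pairs) {
    as.numeric(weighted_load_score(net, edge_count_convention))
  } else {
    rep(NA_real_, nrow(net$nodes))
  }
  # choke-point status over node groups: a group's pair-set vs all others'
  if (has_pairs) {
    node_pairs <- tibble(ko_id = net$nodes$node_id) |>
      mutate(pair_set = net$nodes$pair_set) |>
      tidyr::unnest("pair_set")
    cp <- choke_points(node_pairs, net$nodes$node_id)
  } else {
    cp <- tibble(ko_id = character(), unique_metabolites = list())
  }
  out <- tibble(
    node_id = net$nodes$node_id,
    members = net$nodes$members,
    degree = ec$degree,
    betweenness = as.numeric(b),
    load_score = as.numeric(ls),
    weighted_load_score = wls,
    choke_point = net$nodes$node_id %in% cp$ko_id,
    unique_metabolites = purrr::map(
      net$nodes$node_id,
      ~ cp$unique_metabolites[[match(.x, cp$ko_id)]] %||% character(0)
    ),
    isolated = ec$degree == 0
  )
  structure(out,
            class = c("konet_topology", class(out)),
            sigma_e = ec$sigma_e,
            edge_count_convention = edge_count_convention)
}

#' Write a topology table
#'
#' @param topo A `konet_topology` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  write_tsv_na(select(
    as_tibble(topo), "node_id", "members", "degree", "betweenness",
    "load_score", "weighted_load_score", "choke_point", "unique_metabolites"
  ), path)
}

#' Network-level summary statistics
#'
#' Reports node and edge counts (both conventions), connected components,
#' the average shortest path length over connected node pairs (disconnected
#' pairs are excluded and counted separately) and degree-distribution
#' quantiles. Small average shortest path lengths at these network sizes
#' indicate small-world organisation.
#'
#' @param net A `metabolic_network`.
#' @return A list with fields `n_nodes`, `n_edges_parallel`,
#'   `n_edges_simple`, `n_components`, `avg_shortest_path`,
#'   `n_disconnected_pairs`, `degree_quantiles`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  g <- as_igraph(net, simple = TRUE)
  n <- nrow(net$nodes)
  comp <- igraph::components(g)
  sizes <- comp$csize
  n_connected_pairs <- sum(sizes * (sizes - 1) / 2)
  total_pairs <- n * (n - 1) / 2
  avg_sp <- if (n_connected_pairs > 0) {
    igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  } else {
    NA_real_
  }
  deg <- edge_counts(net, "parallel")$degree
  list(
    n_nodes = n,
    n_edges_parallel = nrow(net$edges),
    n_edges_simple = nrow(distinct(net$edges, .data$from, .data$to)),
    n_components = comp$no,
    avg_shortest_path = avg_sp,
    n_disconnected_pairs = total_pairs - n_connected_pairs,
    degree_quantiles = quantile(deg, c(0, 0.25, 0.5, 0.75, 1), names = TRUE)
  )
}
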