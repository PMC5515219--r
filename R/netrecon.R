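#' Community-wide metabolic network objects
#'
#' A `metabolic_network` holds enzyme nodes (KO groups) and undirected
#' metabolite-labelled edges. Nodes carry their member KOs and the
#' (substrate, product) pair-set those members catalyse; one edge exists per
#' metabolite shared between two nodes' pair-sets, so parallel edges between
#' a node pair (one per distinct shared metabolite) are part of the model.
#'
#' @param nodes Tibble with `node_id`, list-columns `members` and `pair_set`.
#' @param edges Tibble with `from`, `to`, `metabolite`; `from < to`.
#' @param mode Edge semantics used to build the network.
#' @param collapsed Whether redundant nodes have been merged.
#' @return An object of class `metabolic_network`.
#' @keywords internal
new_metabolic_network <- function(nodes, edges, mode, collapsed = FALSE) {
  structure(
    list(nodes = nodes, edges = edges, mode = mode, collapsed = collapsed),
    class = "metabolic_network"
  )
}

#' Construct a metabolic network from an edge table
#'
#' Builds a `metabolic_network` directly from metabolite-labelled edges,
#' e.g. for ad-hoc topological analyses of externally defined graphs.
#' Pair-sets are left empty unless a `pair_map` is supplied.
#'
#' @param edges Tibble with columns `from`, `to`, `metabolite` (a
#'   `metabolite` column is added with label `"m"` if missing). Self-loops
#'   are rejected.
#' @param nodes Optional character vector of node ids (to include isolated
#'   nodes); defaults to the nodes present in `edges`.
#' @param pair_map Optional tibble `ko_id`, `substrate`, `product` giving
#'   pair-sets for the nodes.
#' @return A `metabolic_network` with mode `"manual"`.
#' @export
metabolic_network <- function(edges, nodes = NULL, pair_map = NULL) {
  edges <- as_tibble(edges)
  if (!"metabolite" %in% names(edges)) edges$metabolite <- "m"
  assert_cols(edges, c("from", "to", "metabolite"), "edges")
  if (any(edges$from == edges$to)) abort("Self-loops are not allowed.")
  edges <- edges |>
    mutate(lo = pmin(.data$from, .data$to), hi = pmax(.data$from, .data$to),
           from = .data$lo, to = .data$hi) |>
    select("from", "to", "metabolite") |>
    distinct() |>
    arrange(.data$from, .data$to, .data$metabolite)
  node_id <- sort(unique(c(edges$from, edges$to, nodes)))
  empty_ps <- tibble(substrate = character(), product = character())
  pair_sets <- rep(list(empty_ps), length(node_id))
  if (!is.null(pair_map)) {
    pair_map <- validate_pair_map(pair_map)
    pair_sets <- purrr::map(node_id, function(id) {
      pair_map |>
        filter(.data$ko_id == id) |>
        select("substrate", "product")
    })
  }
  nodes_tbl <- tibble(
    node_id = node_id,
    members = purrr::map(node_id, ~.x),
    pair_set = pair_sets
  )
  new_metabolic_network(nodes_tbl, edges, mode = "manual")
}

# canonical string form of a pair-set, used for redundancy grouping
pair_set_key <- function(pairs) {
  paste(sort(paste(pairs$substrate, pairs$product, sep = "\r")),
        collapse = "\n")
}

# metabolites touched by a pair-set (as substrate or product)
pair_set_metabolites <- function(pairs) {
  unique(c(pairs$substrate, pairs$product))
}

# edges between nodes given their pair-sets, under either mode
compute_edges <- function(nodes, mode) {
  empty <- tibble(from = character(), to = character(),
                  metabolite = character())
  if (nrow(nodes) < 2) return(empty)
  if (mode == "shared_metabolite") {
    long <- purrr::map2_dfr(nodes$node_id, nodes$pair_set, function(id, ps) {
      tibble(node = id, metabolite = pair_set_metabolites(ps))
    })
    joined <- inner_join(long, long, by = "metabolite",
                         relationship = "many-to-many",
                         suffix = c("_a", "_b")) |>
      filter(.data$node_a < .data$node_b)
  } else {
    subs <- purrr::map2_dfr(nodes$node_id, nodes$pair_set, function(id, ps) {
      tibble(node = id, metabolite = unique(ps$substrate))
    })
    prods <- purrr::map2_dfr(nodes$node_id, nodes$pair_set, function(id, ps) {
      tibble(node = id, metabolite = unique(ps$product))
    })
    joined <- inner_join(prods, subs, by = "metabolite",
                         relationship = "many-to-many",
                         suffix = c("_a", "_b")) |>
      filter(.data$node_a != .data$node_b) |>
      mutate(
        lo = pmin(.data$node_a, .data$node_b),
        hi = pmax(.data$node_a, .data$node_b),
        node_a = .data$lo, node_b = .data$hi
      )
  }
  joined |>
    distinct(.data$node_a, .data$node_b, .data$metabolite) |>
    rename(from = "node_a", to = "node_b") |>
    select("from", "to", "metabolite") |>
    arrange(.data$from, .data$to, .data$metabolite)
}

#' Reconstruct a community-wide metabolic network
#'
#' Builds the redundant (one node per KO) network over a KO subset. In the
#' default `shared_metabolite` mode an undirected edge labelled with
#' metabolite `m` connects every pair of KOs whose pair-sets both touch `m`
#' (as substrate or product) — a connectivity-centred view of community
#' metabolism. In `complementary` mode `m` must be a product of one KO and a
#' substrate of the other. Self-loops are never created; KOs in the subset
#' but absent from the pair map are dropped with a warning.
#'
#' @param pair_map Tibble `ko_id`, `substrate`, `product`
#'   (see [read_pair_map()]).
#' @param ko_subset Character vector of KOs to include.
#' @param mode `"shared_metabolite"` (default) or `"complementary"`.
#' @param exclude_metabolites Optional character vector of currency
#'   metabolites (e.g. water, ATP) removed from pair-sets before building.
#' @return A `metabolic_network`.
#' @export
build_network <- function(pair_map, ko_subset,
                          mode = c("shared_metabolite", "complementary"),
                          exclude_metabolites = NULL) {
  mode <- match.arg(mode)
  pair_map <- validate_pair_map(pair_map)
  ko_subset <- unique(ko_subset)
  if (length(ko_subset) == 0) abort("`ko_subset` must be non-empty.")
  if (!is.null(exclude_metabolites)) {
    pair_map <- filter(
      pair_map,
      !(.data$substrate %in% exclude_metabolites),
      !(.data$product %in% exclude_metabolites)
    )
  }
  known <- ko_subset[ko_subset %in% pair_map$ko_id]
  dropped <- setdiff(ko_subset, known)
  if (length(dropped) > 0) {
    warn(sprintf(
      "%d KO(s) absent from the reaction-pair map were excluded: %s%s",
      length(dropped), paste(head(dropped, 5), collapse = ", "),
      if (length(dropped) > 5) ", ..." else ""
    ))
  }
  if (length(known) == 0) {
    abort("No KO in `ko_subset` has reaction-pair annotations.")
  }
  known <- sort(known)
  pair_sets <- pair_map |>
    filter(.data$ko_id %in% known) |>
    group_by(.data$ko_id) |>
    dplyr::group_split() |>
    purrr::map(~ select(.x, "substrate", "product"))
  names(pair_sets) <- pair_map |>
    filter(.data$ko_id %in% known) |>
    distinct(.data$ko_id) |>
    arrange(.data$ko_id) |>
    pull("ko_id")
  nodes <- tibble(
    node_id = known,
    members = purrr::map(known, ~.x),
    pair_set = unname(pair_sets[known])
  )
  new_metabolic_network(nodes, compute_edges(nodes, mode), mode,
                        collapsed = FALSE)
}

#' Season-specific KO subset
#'
#' Restricts a network reconstruction to KOs with evidence of expression in
#' one sampling date: KOs with positive transcript abundance that also carry
#' reaction-pair annotations.
#'
#' @param pair_map Reaction-pair map tibble.
#' @param kota Tibble `ko_id`, `abundance` (or `kota`) of transcript
#'   abundances for the season.
#' @return Character vector of retained KO identifiers, sorted.
#' @export
season_subset <- function(pair_map, kota) {
  pair_map <- validate_pair_map(pair_map)
  assert_cols(kota, "ko_id", "kota")
  val_col <- intersect(c("abundance", "kota"), names(kota))[1]
  if (is.na(val_col)) abort("`kota` needs an `abundance` or `kota` column.")
  expressed <- kota$ko_id[kota[[val_col]] > 0]
  sort(intersect(unique(expressed), unique(pair_map$ko_id)))
}

#' Collapse redundant nodes
#'
#' Merges KOs with identical (substrate, product) pair-sets — typically
#' subunits of the same enzyme complex — into a single node group, then
#' recomputes edges between groups. Within the non-redundant network no two
#' groups share a pair-set and no two edges between the same group pair
#' carry the same metabolite label. Collapsing is idempotent and conserves
#' the member KO set.
#'
#' @param net A `metabolic_network` (typically one node per KO).
#' @return A collapsed `metabolic_network`.
#' @export
collapse_redundant <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  keys <- vapply(net$nodes$pair_set, pair_set_key, character(1))
  members_all <- net$nodes$members
  groups <- split(seq_len(nrow(net$nodes)), keys)
  nodes <- purrr::map_dfr(unname(groups), function(idx) {
    members <- sort(unique(unlist(members_all[idx])))
    tibble(
      node_id = paste(members, collapse = ";"),
      members = list(members),
      pair_set = net$nodes$pair_set[idx[1]]
    )
  }) |>
    arrange(.data$node_id)
  new_metabolic_network(nodes, compute_edges(nodes, net$mode), net$mode,
                        collapsed = TRUE)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "<metabolic_network> %d node%s, %d metabolite edge%s (mode: %s%s)\n",
    nrow(x$nodes), if (nrow(x$nodes) == 1) "" else "s",
    nrow(x$edges), if (nrow(x$edges) == 1) "" else "s",
    x$mode, if (x$collapsed) ", non-redundant" else ""
  ))
  invisible(x)
}

#' Convert a metabolic network to an igraph graph
#'
#' @param net A `metabolic_network`.
#' @param simple Drop parallel metabolite edges (keeps one edge per node
#'   pair), as used for shortest-path computations.
#' @param weights Optional numeric edge weights aligned with `net$edges`
#'   rows; under `simple = TRUE` the minimum weight among parallel edges is
#'   kept.
#' @return An igraph object with vertex attribute `name`.
#' @export
as_igraph <- function(net, simple = FALSE, weights = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  edges <- net$edges
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(edges))
    edges$weight <- weights
  }
  if (simple) {
    if (is.null(weights)) {
      edges <- distinct(edges, .data$from, .data$to)
    } else {
      edges <- edges |>
        group_by(.data$from, .data$to) |>
        summarise(weight = min(.data$weight), .groups = "drop")
    }
  }
  igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = tibble(name = net$nodes$node_id)
  )
}

#' Export a metabolic network to disk
#'
#' Formats: `graphml` (node attribute `members`, edge attribute
#' `metabolite`), `sif` (`groupA<TAB>metabolite<TAB>groupB`, isolated nodes
#' on single-field lines) and `edge_tsv` (header `from/to/metabolite`;
#' isolated nodes as rows with `to` and `metabolite` `NA`). All formats
#' round-trip through [import_network()] with identical node members and
#' edge labels.
#'
#' @param net A `metabolic_network`.
#' @param path Destination file path.
#' @param format One of `"graphml"`, `"sif"`, `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("graphml", "sif", "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "metabolic_network"))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("Directory does not exist: %s", dir))
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = FALSE,
      vertices = tibble(
        name = net$nodes$node_id,
        members = vapply(net$nodes$members, paste, character(1),
                         collapse = ";")
      )
    )
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    edge_lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$metabolite,
                          net$edges$to)
    isolated <- setdiff(net$nodes$node_id,
                        unique(c(net$edges$from, net$edges$to)))
    writeLines(c(edge_lines, isolated), path)
  } else {
    isolated <- setdiff(net$nodes$node_id,
                        unique(c(net$edges$from, net$edges$to)))
    df <- bind_rows(
      net$edges,
      tibble(from = isolated, to = NA_character_, metabolite = NA_character_)
    )
    readr::write_tsv(df, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Import a metabolic network written by [export_network()]
#'
#' Pair-sets are not serialised by the exchange formats, so the imported
#' object carries node members and metabolite-labelled edges only (pair_set
#' columns are empty); topology measures that need only the graph structure
#' work unchanged.
#'
#' @param path File to read.
#' @param format One of `"graphml"`, `"sif"`, `"edge_tsv"`.
#' @return A `metabolic_network`.
#' @export
import_network <- function(path, format = c("graphml", "sif", "edge_tsv")) {
  format <- match.arg(format)
  empty_ps <- tibble(substrate = character(), product = character())
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    node_id <- igraph::V(g)$name
    members <- split_semicolon(igraph::V(g)$members)
    el <- igraph::as_edgelist(g)
    edges <- tibble(
      from = pmin(el[, 1], el[, 2]),
      to = pmax(el[, 1], el[, 2]),
      metabolite = if (igraph::ecount(g) > 0) {
        igraph::E(g)$metabolite
      } else character(0)
    )
  } else if (format == "sif") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    is_edge <- lengths(parts) == 3
    edges <- tibble(
      a = vapply(parts[is_edge], `[`, character(1), 1),
      metabolite = vapply(parts[is_edge], `[`, character(1), 2),
      b = vapply(parts[is_edge], `[`, character(1), 3)
    ) |>
      mutate(from = pmin(.data$a, .data$b), to = pmax(.data$a, .data$b)) |>
      select("from", "to", "metabolite")
    node_id <- sort(unique(c(edges$from, edges$to,
                             vapply(parts[!is_edge], `[`, character(1), 1))))
    members <- split_semicolon(node_id)
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          na = "NA", progress = FALSE)
    edges <- filter(df, !is.na(.data$to))
    node_id <- sort(unique(c(df$from, edges$to)))
    members <- split_semicolon(node_id)
  }
  edges <- arrange(edges, .data$from, .data$to, .data$metabolite)
  if (format == "graphml") {
    ord <- order(node_id)
    node_id <- node_id[ord]
    members <- members[ord]
  }
  nodes <- tibble(
    node_id = node_id,
    members = members,
    pair_set = rep(list(empty_ps), length(node_id))
  )
  new_metabolic_network(nodes, edges, mode = "imported",
                        collapsed = any(lengths(members) > 1))
}
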