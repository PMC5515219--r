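#' Configuration for the synthetic multi-omics generator
#'
#' The generator emulates the KO-annotated count structure of coupled
#' metagenomic (MG) and metatranscriptomic (MT) libraries over a community
#' whose metabolic network is built from pathway-like modules connected by
#' planted bridge KOs. Each module is a clique: every member KO converts
#' the module hub metabolite into a member-specific product, so all members
#' share the hub. Bridge KOs link the private products of one gateway KO
#' per module pair, making each bridge a cut-vertex candidate with minimal
#' degree — a ground-truth topological load point. Bridges additionally
#' receive an MT expression boost, so they are the planted keystone genes.
#'
#' @param n_modules Number of pathway-like modules (default 4).
#' @param kos_per_module KOs per module (default 14).
#' @param n_bridge_kos Planted bridge KOs (default 4); must not exceed the
#'   number of module pairs.
#' @param n_redundant_per_module Extra subunit KOs per module that share an
#'   existing member's pair-set exactly (exercises non-redundant
#'   collapsing; default 1).
#' @param genes_per_ko Integer range `c(min, max)` of genes per KO.
#' @param mg_depth,mt_depth Expected library sizes (default 2e5 each).
#' @param expression_effect MT fold-boost of planted keystone KOs
#'   (default 10).
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param abundance_sd Log-normal sdlog of per-KO community abundance.
#' @param read_length Read length used for effective lengths (default 100).
#' @param gene_length Integer range of gene lengths in nucleotides.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_modules = 4, kos_per_module = 14,
                         n_bridge_kos = 4, n_redundant_per_module = 1,
                         genes_per_ko = c(1, 3),
                         mg_depth = 2e5, mt_depth = 2e5,
                         expression_effect = 10, dispersion = 0.3,
                         abundance_sd = 0.5, read_length = 100,
                         gene_length = c(300, 1500)) {
  cfg <- list(
    n_modules = n_modules, kos_per_module = kos_per_module,
    n_bridge_kos = n_bridge_kos,
    n_redundant_per_module = n_redundant_per_module,
    genes_per_ko = genes_per_ko, mg_depth = mg_depth, mt_depth = mt_depth,
    expression_effect = expression_effect, dispersion = dispersion,
    abundance_sd = abundance_sd, read_length = read_length,
    gene_length = gene_length
  )
  if (any(vapply(cfg[c("n_modules", "kos_per_module", "mg_depth",
                       "mt_depth", "expression_effect", "read_length")],
                 function(v) v <= 0, logical(1)))) {
    abort("All sizes, depths and effects must be positive.")
  }
  if (n_bridge_kos < 0 || n_redundant_per_module < 0 || dispersion < 0) {
    abort("Bridge/redundant counts and dispersion must be non-negative.")
  }
  structure(cfg, class = "synth_config")
}

# module pairs ordered ring-adjacent first, then remaining chords
module_pairs <- function(n_modules) {
  if (n_modules < 2) return(matrix(integer(0), ncol = 2))
  ring <- cbind(seq_len(n_modules),
                c(seq_len(n_modules)[-1], 1L))
  ring <- ring[ring[, 1] != ring[, 2], , drop = FALSE]
  ring <- unique(t(apply(ring, 1, sort)))
  all_pairs <- t(utils::combn(n_modules, 2))
  key <- function(m) paste(m[, 1], m[, 2])
  chords <- all_pairs[!(key(all_pairs) %in% key(ring)), , drop = FALSE]
  rbind(ring, chords)
}

#' Generate a modular reaction-pair map with planted bridges
#'
#' @param cfg A `synth_config`.
#' @param seed Integer seed (structure is deterministic; kept for a uniform
#'   interface).
#' @return A list with `pair_map` (tibble `ko_id`, `substrate`, `product`),
#'   and `truth`: a list holding `planted_keystones`, `module_assignment`
#'   (tibble `ko_id`, `module`, `role`), and `expression_multiplier`
#'   (tibble `ko_id`, `multiplier`).
#' @export
generate_pair_map <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  pairs_avail <- module_pairs(cfg$n_modules)
  if (cfg$n_bridge_kos > nrow(pairs_avail)) {
    abort(sprintf(
      "Cannot place %d bridge KO(s) across %d module pair(s).",
      cfg$n_bridge_kos, nrow(pairs_avail)
    ))
  }
  ko_counter <- 0L
  next_ko <- function() {
    ko_counter <<- ko_counter + 1L
    sprintf("K%05d", ko_counter)
  }
  rows <- list()
  assign_rows <- list()
  gateway_use <- integer(cfg$n_modules)  # gateways consumed per module
  module_kos <- vector("list", cfg$n_modules)
  for (m in seq_len(cfg$n_modules)) {
    hub <- sprintf("C%02d000", m)
    kos <- character(cfg$kos_per_module)
    for (i in seq_len(cfg$kos_per_module)) {
      kos[i] <- next_ko()
      rows[[length(rows) + 1]] <- tibble(
        ko_id = kos[i], substrate = hub,
        product = sprintf("C%02d%03d", m, i)
      )
    }
    module_kos[[m]] <- kos
    assign_rows[[length(assign_rows) + 1]] <- tibble(
      ko_id = kos, module = m, role = "member"
    )
    # redundant subunit copies of the first member's reaction
    for (r in seq_len(cfg$n_redundant_per_module)) {
      if (cfg$n_redundant_per_module == 0) break
      ko <- next_ko()
      rows[[length(rows) + 1]] <- tibble(
        ko_id = ko, substrate = hub, product = sprintf("C%02d%03d", m, 1L)
      )
      assign_rows[[length(assign_rows) + 1]] <- tibble(
        ko_id = ko, module = m, role = "redundant"
      )
    }
  }
  bridges <- character(cfg$n_bridge_kos)
  for (b in seq_len(cfg$n_bridge_kos)) {
    if (cfg$n_bridge_kos == 0) break
    p <- pairs_avail[b, 1]
    q <- pairs_avail[b, 2]
    # attach to the next unused gateway KO's private product in each module
    gw_p <- gateway_use[p] %% cfg$kos_per_module + 1L
    gw_q <- gateway_use[q] %% cfg$kos_per_module + 1L
    gateway_use[p] <- gateway_use[p] + 1L
    gateway_use[q] <- gateway_use[q] + 1L
    bridges[b] <- next_ko()
    rows[[length(rows) + 1]] <- tibble(
      ko_id = bridges[b],
      substrate = sprintf("C%02d%03d", p, gw_p),
      product = sprintf("C%02d%03d", q, gw_q)
    )
    assign_rows[[length(assign_rows) + 1]] <- tibble(
      ko_id = bridges[b], module = NA_integer_, role = "bridge"
    )
  }
  assignment <- bind_rows(assign_rows)
  truth <- list(
    planted_keystones = bridges,
    module_assignment = assignment,
    expression_multiplier = tibble(
      ko_id = assignment$ko_id,
      multiplier = if_else(assignment$ko_id %in% bridges,
                           cfg$expression_effect, 1)
    )
  )
  list(pair_map = bind_rows(rows), truth = truth)
}

#' Generate a gene catalogue for a synthetic community
#'
#' Gene counts per KO and gene lengths are drawn uniformly from the
#' configured ranges; effective length is `max(1, length - read_length +
#' 1)`, the number of positions a read of the configured length can start
#' at.
#'
#' @param truth Ground truth from [generate_pair_map()].
#' @param cfg A `synth_config`.
#' @param seed Integer seed.
#' @return A catalogue tibble (`gene_id`, `effective_length`, `ko_ids`
#'   list-column, plus `gene_length`).
#' @export
generate_catalogue <- function(truth, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  kos <- truth$module_assignment$ko_id
  withr::with_seed(seed, {
    n_genes <- sample(cfg$genes_per_ko[1]:cfg$genes_per_ko[2],
                      length(kos), replace = TRUE)
    lens <- sample(cfg$gene_length[1]:cfg$gene_length[2], sum(n_genes),
                   replace = TRUE)
    tibble(
      gene_id = sprintf("g%06d", seq_len(sum(n_genes))),
      gene_length = lens,
      effective_length = pmax(1, lens - cfg$read_length + 1),
      ko_ids = purrr::map(rep(kos, times = n_genes), ~.x)
    )
  })
}

#' Generate coupled MG and MT count tables
#'
#' Per-gene metagenomic means are proportional to effective length times a
#' log-normal per-KO community abundance, scaled to the configured depth;
#' counts are negative-binomial with the configured overdispersion.
#' Metatranscriptomic means use the same baseline multiplied by each KO's
#' expression multiplier (the planted boost for keystone KOs), so expected
#' relative expression is flat except at planted KOs.
#'
#' @param catalogue Catalogue from [generate_catalogue()].
#' @param truth Ground truth from [generate_pair_map()].
#' @param cfg A `synth_config`.
#' @param seed Integer seed.
#' @return A list with tibbles `mg` and `mt` (`gene_id`, `count`).
#' @export
generate_counts <- function(catalogue, truth, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  ko <- vapply(catalogue$ko_ids, `[`, character(1), 1)
  mult <- truth$expression_multiplier$multiplier[
    match(ko, truth$expression_multiplier$ko_id)
  ]
  withr::with_seed(seed, {
    kos <- truth$module_assignment$ko_id
    a_ko <- setNames(rlnorm(length(kos), 0, cfg$abundance_sd), kos)
    w_mg <- catalogue$effective_length * a_ko[ko]
    w_mt <- w_mg * mult
    mu_mg <- cfg$mg_depth * w_mg / sum(w_mg)
    mu_mt <- cfg$mt_depth * w_mt / sum(w_mt)
    draw <- function(mu) {
      if (cfg$dispersion == 0) {
        stats::rpois(length(mu), mu)
      } else {
        rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
      }
    }
    list(
      mg = tibble(gene_id = catalogue$gene_id, count = draw(mu_mg)),
      mt = tibble(gene_id = catalogue$gene_id, count = draw(mu_mt))
    )
  })
}

#' Simulate a complete synthetic multi-omics community
#'
#' Runs [generate_pair_map()], [generate_catalogue()] and
#' [generate_counts()] under sub-seeds derived from `seed`, and adds a
#' pathway map (one pathway per module plus one grouping the bridges).
#'
#' @param cfg A `synth_config` (defaults used when omitted).
#' @param seed Integer seed; the whole bundle is deterministic given
#'   `cfg` and `seed`.
#' @return A list of class `synth_bundle` with elements `pair_map`,
#'   `truth`, `catalogue`, `mg_counts`, `mt_counts`, `pathway_map`, `cfg`,
#'   `seed`.
#' @export
simulate_community <- function(cfg = synth_config(), seed = 1L) {
  seed <- as.integer(seed)
  pm <- generate_pair_map(cfg, seed)
  catalogue <- generate_catalogue(pm$truth, cfg, seed + 1L)
  counts <- generate_counts(catalogue, pm$truth, cfg, seed + 2L)
  assignment <- pm$truth$module_assignment
  pathway_map <- bind_rows(
    assignment |>
      filter(!is.na(.data$module)) |>
      mutate(pathway_id = sprintf("pw_module%02d", .data$module)) |>
      select("pathway_id", "ko_id"),
    tibble(pathway_id = "pw_bridge",
           ko_id = pm$truth$planted_keystones)
  )
  structure(
    list(
      pair_map = pm$pair_map, truth = pm$truth, catalogue = catalogue,
      mg_counts = counts$mg, mt_counts = counts$mt,
      pathway_map = pathway_map, cfg = cfg, seed = seed
    ),
    class = "synth_bundle"
  )
}

#' Write a synthetic bundle to disk
#'
#' Writes every pipeline input as TSV plus a YAML config and a JSON
#' manifest with per-file MD5 checksums, so a pipeline run on the bundle
#' can be compared against ground truth.
#'
#' @param bundle A `synth_bundle` from [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv_na(select(bundle$catalogue, "gene_id", "effective_length",
                      "ko_ids"), p("catalogue.tsv"))
  write_tsv_na(bundle$mg_counts, p("mg_counts.tsv"))
  write_tsv_na(bundle$mt_counts, p("mt_counts.tsv"))
  write_tsv_na(bundle$pair_map, p("pair_map.tsv"))
  write_tsv_na(bundle$pathway_map, p("pathway_map.tsv"))
  truth_tbl <- bundle$truth$module_assignment |>
    left_join(bundle$truth$expression_multiplier, by = "ko_id") |>
    mutate(planted_keystone =
             .data$ko_id %in% bundle$truth$planted_keystones)
  write_tsv_na(truth_tbl, p("ground_truth.tsv"))
  yaml::write_yaml(c(unclass(bundle$cfg), list(seed = bundle$seed)),
                   p("config.yaml"))
  files <- c("catalogue.tsv", "mg_counts.tsv", "mt_counts.tsv",
             "pair_map.tsv", "pathway_map.tsv", "ground_truth.tsv",
             "config.yaml")
  jsonlite::write_json(
    list(files = as.list(setNames(
      unname(tools::md5sum(vapply(files, p, character(1)))), files
    ))),
    p("manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Keystone recovery metrics against planted ground truth
#'
#' Expands selected node groups to member KOs and scores them against the
#' planted keystones: sensitivity (recovered fraction of planted KOs) and
#' the false-positive rate among non-planted KOs.
#'
#' @param report A `keystone_report`.
#' @param truth Ground truth from a `synth_bundle`.
#' @return A one-row tibble `n_planted`, `n_selected_kos`, `n_recovered`,
#'   `sensitivity`, `false_positive_rate`.
#' @export
keystone_recovery <- function(report, truth) {
  stopifnot(inherits(report, "keystone_report"))
  planted <- truth$planted_keystones
  selected_kos <- unique(unlist(report$selected$members))
  universe <- unique(unlist(report$candidates$members))
  non_planted <- setdiff(universe, planted)
  tibble(
    n_planted = length(planted),
    n_selected_kos = length(selected_kos),
    n_recovered = length(intersect(selected_kos, planted)),
    sensitivity = length(intersect(selected_kos, planted)) /
      max(1, length(planted)),
    false_positive_rate = length(setdiff(selected_kos, planted)) /
      max(1, length(non_planted))
  )
}
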