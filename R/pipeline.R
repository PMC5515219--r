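#' Run the full multi-omics network pipeline
#'
#' Orchestrates quantification (length-normalised KO abundances and
#' relative expression), season-specific network reconstruction,
#' non-redundant collapsing, topology scoring and keystone selection, and
#' writes every intermediate table plus a provenance record to the output
#' directory.
#'
#' @param config A named list or path to a YAML file with fields:
#'   * `catalogue`, `mg_counts`, `mt_counts`, `pair_map`: input paths
#'     (required); `pathway_map`, `protein`: optional paths;
#'   * `depth` (optional common subsampling depth), `seed` (default 1),
#'     `mode`, `edge_count_convention`, `collapse` (default TRUE),
#'     `load_quantile`, `expr_quantile`, `tie_policy`, `group_expr`,
#'     `mt_only_policy`, `exclude_metabolites`;
#'   * `out_dir`: output directory (required).
#' @return Invisibly, a list with `profile`, `network`, `topology`,
#'   `keystones`, `summary`, `enrichment` (NULL without a pathway map) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    depth = NULL, seed = 1L, mode = "shared_metabolite",
    edge_count_convention = "parallel", collapse = TRUE,
    load_quantile = 0.10, expr_quantile = 0.10,
    tie_policy = "include_ties", group_expr = "max",
    mt_only_policy = "flag", exclude_metabolites = NULL,
    pathway_map = NULL, protein = NULL
  )
  cfg <- modifyList(defaults, config)
  for (field in c("catalogue", "mg_counts", "mt_counts", "pair_map",
                  "out_dir")) {
    if (is.null(cfg[[field]])) {
      abort(sprintf("[config] Missing required field `%s`.", field))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)

  inputs <- stage("read", list(
    catalogue = read_gene_catalogue(cfg$catalogue),
    mg = read_counts(cfg$mg_counts),
    mt = read_counts(cfg$mt_counts),
    pair_map = read_pair_map(cfg$pair_map),
    pathway_map = if (!is.null(cfg$pathway_map)) {
      read_pathway_map(cfg$pathway_map)
    },
    protein = if (!is.null(cfg$protein)) read_protein_abundance(cfg$protein)
  ))

  profile <- stage("quantify", {
    prof <- ko_profile(
      inputs$mg, inputs$mt, inputs$catalogue, protein = inputs$protein,
      depth = cfg$depth, seed = cfg$seed, policy = cfg$mt_only_policy
    )
    write_ko_profile(prof, out("ko_profile.tsv"))
    prof
  })

  net <- stage("build-net", {
    kos <- season_subset(inputs$pair_map,
                         select(profile, "ko_id", kota = "kota"))
    if (length(kos) == 0) abort("No expressed KO has pair annotations.")
    n <- build_network(inputs$pair_map, kos, mode = cfg$mode,
                       exclude_metabolites = cfg$exclude_metabolites)
    if (isTRUE(cfg$collapse)) n <- collapse_redundant(n)
    export_network(n, out("network.graphml"), "graphml")
    export_network(n, out("network_edges.tsv"), "edge_tsv")
    n
  })

  topo <- stage("topology", {
    tt <- topology_table(net, edge_count_convention =
                           cfg$edge_count_convention)
    write_topology(tt, out("topology.tsv"))
    jsonlite::write_json(network_summary(net), out("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tt
  })

  report <- stage("keystone", {
    rep <- select_key_functionalities(
      topo, profile, load_quantile = cfg$load_quantile,
      expr_quantile = cfg$expr_quantile, tie_policy = cfg$tie_policy,
      group_expr = cfg$group_expr
    )
    write_keystone_report(rep, out("keystones.tsv"), seed = cfg$seed)
    rep
  })

  enrichment <- NULL
  if (!is.null(inputs$pathway_map)) {
    enrichment <- stage("enrichment", {
      selected <- unique(unlist(report$selected$members))
      background <- unique(unlist(report$candidates$members))
      enr <- pathway_enrichment(selected, background, inputs$pathway_map)
      write_tsv_na(enr, out("pathway_enrichment.tsv"))
      enr
    })
  }

  stage("provenance", {
    outputs <- list.files(cfg$out_dir, full.names = TRUE)
    outputs <- outputs[!grepl("provenance\\.json$", outputs)]
    jsonlite::write_json(
      list(
        config = cfg[!vapply(cfg, is.null, logical(1))],
        software = paste0("konet ",
                          as.character(packageVersion("konet"))),
        checksums = as.list(setNames(unname(tools::md5sum(outputs)),
                                     basename(outputs)))
      ),
      out("provenance.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  })

  invisible(list(
    profile = profile, network = net, topology = topo, keystones = report,
    summary = network_summary(net), enrichment = enrichment,
    out_dir = cfg$out_dir
  ))
}
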