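#' Select genes encoding key community functionalities
#'
#' Identifies keystone candidates as network nodes lying simultaneously in
#' the top fraction of the load-score distribution (topological criterion:
#' "load points") and the top fraction of the relative-expression
#' distribution (activity criterion). Thresholds are the empirical
#' `(1 - q)` quantiles over the ranked entities; with distinct scores
#' exactly `ceiling(q * N)` entities pass each single criterion.
#'
#' A collapsed node group's relative expression is aggregated over its
#' member KOs (maximum by default). KOs flagged `MT-only` (transcripts but
#' no detected gene copies) have no defined ratio and are excluded from the
#' expression ranking unless `include_mt_only = TRUE` ranks them above all
#' finite values.
#'
#' @param topo A `konet_topology` table (see [topology_table()]).
#' @param profiles KO profile tibble with `ko_id` and `rel_expr` (see
#'   [ko_profile()]).
#' @param load_quantile,expr_quantile Top fractions in (0, 1]; default 0.10.
#' @param tie_policy `"include_ties"` (default): every entity scoring at or
#'   above the threshold passes, so ties at the cut are kept;
#'   `"strict"`: exactly `ceiling(q * N)` entities pass, ties broken by
#'   node id for determinism.
#' @param group_expr Aggregation of member-KO relative expression into a
#'   node value: `"max"` (default), `"sum"` or `"mean"`.
#' @param include_mt_only Rank MT-only KOs above all finite ratios instead
#'   of excluding them.
#' @return A `keystone_report`: list with `selected` (tibble of passing
#'   nodes), `candidates` (all scored nodes), `thresholds`, and `config`.
#' @export
select_key_functionalities <- function(topo, profiles,
                                       load_quantile = 0.10,
                                       expr_quantile = 0.10,
                                       tie_policy = c("include_ties",
                                                      "strict"),
                                       group_expr = c("max", "sum", "mean"),
                                       include_mt_only = FALSE) {
  tie_policy <- match.arg(tie_policy)
  group_expr <- match.arg(group_expr)
  assert_cols(topo, c("node_id", "members", "load_score"), "topo")
  assert_cols(profiles, c("ko_id", "rel_expr"), "profiles")
  if (nrow(topo) == 0) abort("Topology table is empty.")
  if (nrow(profiles) == 0) abort("Profile table is empty.")
  if (load_quantile <= 0 || load_quantile > 1 ||
      expr_quantile <= 0 || expr_quantile > 1) {
    abort("Quantiles must lie in (0, 1].")
  }

  expr_vals <- profiles$rel_expr
  if (include_mt_only) {
    finite_max <- suppressWarnings(max(expr_vals, na.rm = TRUE))
    mt_only <- grepl("MT-only", profiles$flags %||% "")
    expr_vals[mt_only] <- if (is.finite(finite_max)) finite_max * 2 else 1
  }
  expr_tbl <- tibble(ko_id = profiles$ko_id, rel_expr = expr_vals)

  agg_fun <- switch(group_expr, max = max, sum = sum, mean = mean)
  node_expr <- tibble(node_id = topo$node_id, ko_id = topo$members) |>
    tidyr::unnest_longer("ko_id") |>
    inner_join(expr_tbl, by = "ko_id") |>
    filter(!is.na(.data$rel_expr)) |>
    group_by(.data$node_id) |>
    summarise(rel_expr = agg_fun(.data$rel_expr), .groups = "drop")

  candidates <- as_tibble(topo) |>
    select("node_id", "members", "degree", "betweenness", "load_score",
           dplyr::any_of(c("choke_point", "unique_metabolites"))) |>
    left_join(node_expr, by = "node_id")

  top_threshold <- function(x, q) {
    x <- x[!is.na(x)]
    sort(x, decreasing = TRUE)[ceiling(q * length(x))]
  }
  thr_load <- top_threshold(candidates$load_score, load_quantile)
  thr_expr <- top_threshold(candidates$rel_expr, expr_quantile)

  # a node with zero relative expression is never "highly expressed",
  # whatever the empirical threshold
  if (tie_policy == "include_ties") {
    pass_load <- !is.na(candidates$load_score) &
      candidates$load_score >= thr_load
    pass_expr <- !is.na(candidates$rel_expr) &
      candidates$rel_expr >= thr_expr & candidates$rel_expr > 0
  } else {
    k_load <- ceiling(load_quantile * sum(!is.na(candidates$load_score)))
    k_expr <- ceiling(expr_quantile * sum(!is.na(candidates$rel_expr)))
    ord_load <- order(-candidates$load_score, candidates$node_id,
                      na.last = TRUE)
    ord_expr <- order(-candidates$rel_expr, candidates$node_id,
                      na.last = TRUE)
    pass_load <- pass_expr <- rep(FALSE, nrow(candidates))
    pass_load[ord_load[seq_len(k_load)]] <- TRUE
    pass_expr[ord_expr[seq_len(k_expr)]] <- TRUE
    pass_expr <- pass_expr & dplyr::coalesce(candidates$rel_expr, 0) > 0
  }
  candidates <- mutate(candidates, pass_load = pass_load,
                       pass_expr = pass_expr,
                       selected = pass_load & pass_expr)

  structure(
    list(
      selected = filter(candidates, .data$selected) |>
        select(-"pass_load", -"pass_expr", -"selected") |>
        arrange(desc(.data$load_score)),
      candidates = candidates,
      thresholds = list(load_score = thr_load, rel_expr = thr_expr),
      config = list(
        load_quantile = load_quantile, expr_quantile = expr_quantile,
        tie_policy = tie_policy, group_expr = group_expr,
        include_mt_only = include_mt_only
      )
    ),
    class = "keystone_report"
  )
}

#' @export
print.keystone_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<keystone_report> %d of %d nodes selected\n",
      "  load score >= %.4g (top %.0f%%), relative expression >= %.4g ",
      "(top %.0f%%)\n"
    ),
    nrow(x$selected), nrow(x$candidates),
    x$thresholds$load_score, 100 * x$config$load_quantile,
    x$thresholds$rel_expr, 100 * x$config$expr_quantile
  ))
  if (nrow(x$selected) > 0) {
    print(head(select(x$selected, -dplyr::any_of("unique_metabolites")), 10))
  }
  invisible(x)
}

#' Write a keystone report (TSV plus JSON sidecar)
#'
#' @param report A `keystone_report`.
#' @param path Output TSV path; a `.json` sidecar with thresholds, config
#'   and package version is written next to it.
#' @param seed Optional seed recorded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_keystone_report <- function(report, path, seed = NULL) {
  stopifnot(inherits(report, "keystone_report"))
  write_tsv_na(report$selected, path)
  sidecar <- sub("\\.tsv$", "", path)
  sidecar <- paste0(sidecar, ".json")
  jsonlite::write_json(
    list(
      thresholds = report$thresholds,
      config = report$config,
      n_selected = nrow(report$selected),
      n_candidates = nrow(report$candidates),
      seed = seed,
      software = paste0("konet ", as.character(packageVersion("konet")))
    ),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Pathway over-representation among selected KOs
#'
#' One-sided Fisher's exact test per pathway of whether selected KOs are
#' over-represented relative to the background, with Benjamini-Hochberg
#' adjustment across tested pathways. Pathways without selected members are
#' reported with p = 1.
#'
#' @param selected Character vector of selected KO ids (subset of
#'   `background`).
#' @param background Character vector: the universe of KOs considered.
#' @param pathway_map Tibble `pathway_id`, `ko_id`.
#' @return A tibble `pathway_id`, `n_selected_in`, `n_pathway`,
#'   `odds_ratio`, `p_value`, `fdr` sorted by p-value.
#' @export
pathway_enrichment <- function(selected, background, pathway_map) {
  assert_cols(pathway_map, c("pathway_id", "ko_id"), "pathway_map")
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background)) {
    abort("`selected` must be a subset of `background`.")
  }
  pathways <- pathway_map |>
    filter(.data$ko_id %in% background) |>
    distinct(.data$pathway_id, .data$ko_id)
  n_sel <- length(selected)
  n_bg <- length(background)
  res <- pathways |>
    group_by(.data$pathway_id) |>
    summarise(
      n_selected_in = sum(.data$ko_id %in% selected),
      n_pathway = n(),
      .groups = "drop"
    ) |>
    mutate(
      test = purrr::map2(.data$n_selected_in, .data$n_pathway, function(a, m) {
        tab <- matrix(c(a, n_sel - a, m - a, n_bg - n_sel - (m - a)),
                      nrow = 2)
        ft <- stats::fisher.test(tab, alternative = "greater")
        tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
      })
    ) |>
    tidyr::unnest("test") |>
    mutate(p_value = if_else(.data$n_selected_in == 0, 1, .data$p_value))
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  arrange(res, .data$p_value, .data$pathway_id)
}

#' Compare per-pathway betweenness between two seasonal networks
#'
#' For each pathway, pairs the betweenness values of KOs present in both
#' seasonal topology tables and reports the median per-KO fold change
#' (season B over season A) and a two-sided Wilcoxon signed-rank p-value on
#' the paired differences. Fold changes are undefined when a KO has zero
#' betweenness in either season; such pairs are excluded from the median
#' and counted. Pathways with fewer than `min_shared` shared KOs are
#' skipped with a warning.
#'
#' @param topo_a,topo_b `konet_topology` tables for the two seasons; node
#'   groups are expanded to their member KOs (a KO inherits its group's
#'   betweenness).
#' @param pathway_map Tibble `pathway_id`, `ko_id`.
#' @param min_shared Minimum shared KOs per pathway (default 2).
#' @return A tibble `pathway_id`, `n_shared`, `n_zero_excluded`,
#'   `median_fold_change`, `wilcoxon_p`.
#' @export
compare_seasonal_betweenness <- function(topo_a, topo_b, pathway_map,
                                         min_shared = 2) {
  assert_cols(pathway_map, c("pathway_id", "ko_id"), "pathway_map")
  expand <- function(topo, col) {
    tibble(ko_id = topo$members, b = topo$betweenness) |>
      tidyr::unnest_longer("ko_id") |>
      group_by(.data$ko_id) |>
      summarise(!!col := max(.data$b), .groups = "drop")
  }
  paired <- inner_join(expand(topo_a, "b_a"), expand(topo_b, "b_b"),
                       by = "ko_id") |>
    inner_join(distinct(pathway_map, .data$pathway_id, .data$ko_id),
               by = "ko_id")
  results <- paired |>
    group_by(.data$pathway_id) |>
    dplyr::group_map(function(df, key) {
      if (nrow(df) < min_shared) {
        warn(sprintf(
          "Pathway %s skipped: only %d shared KO(s).", key$pathway_id[1],
          nrow(df)
        ))
        return(NULL)
      }
      nonzero <- df$b_a > 0 & df$b_b > 0
      mfc <- if (any(nonzero)) {
        median(df$b_b[nonzero] / df$b_a[nonzero])
      } else {
        NA_real_
      }
      p <- if (all(df$b_b == df$b_a)) {
        1  # no signed ranks to test
      } else {
        suppressWarnings(
          stats::wilcox.test(df$b_b, df$b_a, paired = TRUE)$p.value
        )
      }
      tibble(
        pathway_id = key$pathway_id[1],
        n_shared = nrow(df),
        n_zero_excluded = sum(!nonzero),
        median_fold_change = mfc,
        wilcoxon_p = p
      )
    }) |>
    bind_rows()
  if (nrow(results) == 0) {
    return(tibble(pathway_id = character(), n_shared = integer(),
                  n_zero_excluded = integer(),
                  median_fold_change = numeric(), wilcoxon_p = numeric()))
  }
  arrange(results, .data$pathway_id)
}
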