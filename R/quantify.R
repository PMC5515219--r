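#' Subsample a count table to a fixed sequencing depth
#'
#' Draws `depth` reads without replacement from the mapped-read counts
#' (multivariate hypergeometric), so metagenomic and metatranscriptomic
#' libraries can be brought to identical depths before comparison. Counts
#' must still be integers, i.e. subsampling happens before fractional
#' multi-mapping weights are applied.
#'
#' @param counts Tibble with columns `gene_id`, `count` (non-negative
#'   integers).
#' @param depth Number of reads to draw; must not exceed the total count.
#' @param seed Integer seed; the draw is reproducible given `seed`.
#' @return A tibble with the same `gene_id` order and subsampled `count`.
#' @export
subsample_counts <- function(counts, depth, seed) {
  assert_cols(counts, c("gene_id", "count"), "counts")
  x <- counts$count
  if (any(x < 0) || any(!is.finite(x))) {
    abort("Counts must be finite and non-negative.")
  }
  if (any(abs(x - round(x)) > 1e-8)) {
    abort(paste(
      "Fractional counts detected: subsampling operates on integer",
      "mapped-read counts. Subsample before applying multi-mapping weights."
    ))
  }
  x <- round(x)
  total <- sum(x)
  if (depth > total) {
    abort(sprintf(
      "Requested depth %d exceeds available reads %d.", as.integer(depth),
      as.integer(total)
    ))
  }
  if (depth < 0) abort("`depth` must be non-negative.")
  out <- withr::with_seed(seed, {
    # sequential conditional hypergeometric draws give a multivariate
    # hypergeometric sample without materialising individual reads
    drawn <- numeric(length(x))
    left_to_draw <- depth
    left_in_urn <- total
    for (i in seq_along(x)) {
      left_in_urn <- left_in_urn - x[i]
      if (left_to_draw == 0) break
      if (left_in_urn == 0) {
        drawn[i] <- left_to_draw
        left_to_draw <- 0
        break
      }
      drawn[i] <- rhyper(1, m = x[i], n = left_in_urn, k = left_to_draw)
      left_to_draw <- left_to_draw - drawn[i]
    }
    drawn
  })
  tibble(gene_id = counts$gene_id, count = out)
}

#' Distribute multi-mapped reads as fractional counts
#'
#' Each read contributes `1 / (number of genes it maps to)` to every gene it
#' maps to, so the summed fractional counts conserve the total number of
#' reads exactly.
#'
#' @param assignments Tibble with columns `read_id` and `gene_ids` (a
#'   list-column of character vectors, or a semicolon-separated character
#'   column).
#' @return A tibble with columns `gene_id`, `count` (fractional).
#' @export
weight_multimapped <- function(assignments) {
  assert_cols(assignments, c("read_id", "gene_ids"), "assignments")
  gene_ids <- assignments$gene_ids
  if (is.character(gene_ids)) gene_ids <- split_semicolon(gene_ids)
  n_genes <- lengths(gene_ids)
  if (any(n_genes == 0)) {
    bad <- assignments$read_id[n_genes == 0]
    abort(sprintf("Read(s) with empty gene set: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  long <- tibble(
    gene_id = unlist(gene_ids, use.names = FALSE),
    weight = rep(1 / n_genes, times = n_genes)
  )
  long |>
    group_by(.data$gene_id) |>
    summarise(count = sum(.data$weight), .groups = "drop") |>
    arrange(.data$gene_id)
}

#' Normalise per-gene counts by effective gene length
#'
#' Divides each gene's count by its effective length (positions available
#' for read starts), yielding abundances in reads per nucleotide of
#' effective length. Longer genes accrue proportionally more reads at equal
#' copy number; this removes that bias.
#'
#' @param counts Tibble with columns `gene_id`, `count`.
#' @param catalogue Gene catalogue (see [read_gene_catalogue()]).
#' @return A tibble with columns `gene_id`, `abundance`.
#' @export
normalize_by_length <- function(counts, catalogue) {
  assert_cols(counts, c("gene_id", "count"), "counts")
  catalogue <- validate_gene_catalogue(catalogue)
  missing <- setdiff(counts$gene_id, catalogue$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("Gene(s) absent from catalogue: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  counts |>
    inner_join(select(catalogue, "gene_id", "effective_length"),
               by = "gene_id") |>
    mutate(abundance = .data$count / .data$effective_length) |>
    select("gene_id", "abundance")
}

#' Aggregate length-normalised gene abundances to KO level
#'
#' Each KO's abundance is the sum over the genes assigned to it. Genes with
#' no KO assignment are dropped; genes carrying several KO assignments
#' contribute their full abundance to each assigned KO by default
#' (`multi_ko = "full"`), or a `1/k` share with `multi_ko = "split"`.
#'
#' @param normalized Tibble with columns `gene_id`, `abundance`.
#' @param catalogue Gene catalogue.
#' @param multi_ko How genes with multiple KO assignments contribute.
#' @return A tibble with columns `ko_id`, `abundance`, sorted by `ko_id`.
#' @export
aggregate_ko <- function(normalized, catalogue,
                         multi_ko = c("full", "split")) {
  multi_ko <- match.arg(multi_ko)
  assert_cols(normalized, c("gene_id", "abundance"), "normalized")
  catalogue <- validate_gene_catalogue(catalogue)
  long <- catalogue |>
    select("gene_id", "ko_ids") |>
    tidyr::unnest_longer("ko_ids", values_to = "ko_id") |>
    filter(!is.na(.data$ko_id))
  joined <- inner_join(normalized, long, by = "gene_id")
  if (multi_ko == "split") {
    joined <- joined |>
      group_by(.data$gene_id) |>
      mutate(abundance = .data$abundance / n()) |>
      ungroup()
  }
  joined |>
    group_by(.data$ko_id) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    arrange(.data$ko_id)
}

#' Relative gene expression per KO
#'
#' Computes relative expression as the ratio of the normalised transcript
#' abundance (KOTA) to the normalised gene-copy abundance (KOGA). A KO with
#' transcripts but no detected gene copies has an undefined ratio; the
#' default policy flags it `MT-only` (relative expression `NA`, excluded
#' from downstream percentile ranking), the alternative substitutes the
#' smallest non-zero KOGA as a pseudocount denominator.
#'
#' @param koga Tibble with columns `ko_id`, `abundance` (gene-copy side).
#' @param kota Tibble with columns `ko_id`, `abundance` (transcript side).
#' @param policy `"flag"` (default) or `"pseudocount"` for MT-only KOs.
#' @return A tibble with columns `ko_id`, `koga`, `kota`, `rel_expr`,
#'   `flags` over the union of the two key sets.
#' @export
relative_expression <- function(koga, kota, policy = c("flag", "pseudocount")) {
  policy <- match.arg(policy)
  assert_cols(koga, c("ko_id", "abundance"), "koga")
  assert_cols(kota, c("ko_id", "abundance"), "kota")
  if (any(koga$abundance < 0) || any(kota$abundance < 0)) {
    abort("Abundances must be non-negative.")
  }
  prof <- full_join(
    rename(as_tibble(koga), koga = "abundance"),
    rename(as_tibble(kota), kota = "abundance"),
    by = "ko_id"
  ) |>
    mutate(
      koga = dplyr::coalesce(.data$koga, 0),
      kota = dplyr::coalesce(.data$kota, 0)
    )
  mt_only <- prof$koga == 0 & prof$kota > 0
  denom <- prof$koga
  flags <- rep("", nrow(prof))
  if (policy == "pseudocount") {
    pos <- prof$koga[prof$koga > 0]
    if (length(pos) == 0 && any(mt_only)) {
      abort("No positive gene-copy abundance available for pseudocount.")
    }
    denom[mt_only] <- min(pos)
    flags[mt_only] <- "MT-only:pseudocount"
  } else {
    flags[mt_only] <- "MT-only"
  }
  rel <- ifelse(prof$kota == 0, 0, ifelse(denom > 0, prof$kota / denom, NA))
  if (policy == "flag") rel[mt_only] <- NA_real_
  prof |>
    mutate(rel_expr = rel, flags = flags) |>
    arrange(.data$ko_id)
}

#' Build a full per-KO multi-omic profile
#'
#' Convenience wrapper running length normalisation, KO aggregation and
#' relative expression for a metagenomic (MG) and a metatranscriptomic (MT)
#' count table, optionally attaching ingested protein abundances and
#' optionally equalising the two libraries' depths by subsampling first.
#'
#' @param mg_counts,mt_counts Per-gene count tibbles (`gene_id`, `count`).
#' @param catalogue Gene catalogue.
#' @param protein Optional tibble `ko_id`, `protein` (normalised spectral
#'   index, ingested as-is).
#' @param depth Optional common subsampling depth applied to both layers.
#' @param seed Seed for subsampling (required when `depth` is given).
#' @param policy MT-only policy passed to [relative_expression()].
#' @param multi_ko Passed to [aggregate_ko()].
#' @return A tibble with columns `ko_id`, `koga`, `kota`, `protein`,
#'   `rel_expr`, `flags`.
#' @export
ko_profile <- function(mg_counts, mt_counts, catalogue, protein = NULL,
                       depth = NULL, seed = NULL,
                       policy = c("flag", "pseudocount"),
                       multi_ko = c("full", "split")) {
  policy <- match.arg(policy)
  multi_ko <- match.arg(multi_ko)
  if (!is.null(depth)) {
    if (is.null(seed)) abort("`seed` is required when subsampling to `depth`.")
    mg_counts <- subsample_counts(mg_counts, depth, seed)
    mt_counts <- subsample_counts(mt_counts, depth, seed + 1L)
  }
  koga <- aggregate_ko(normalize_by_length(mg_counts, catalogue), catalogue,
                       multi_ko = multi_ko)
  kota <- aggregate_ko(normalize_by_length(mt_counts, catalogue), catalogue,
                       multi_ko = multi_ko)
  prof <- relative_expression(koga, kota, policy = policy)
  if (!is.null(protein)) {
    assert_cols(protein, c("ko_id", "protein"), "protein")
    prof <- left_join(prof, as_tibble(protein), by = "ko_id")
  } else {
    prof$protein <- NA_real_
  }
  select(prof, "ko_id", "koga", "kota", "protein", "rel_expr", "flags")
}

#' Write a KO profile table
#'
#' @param profile Output of [ko_profile()] or [relative_expression()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ko_profile <- function(profile, path) {
  cols <- intersect(c("ko_id", "koga", "kota", "protein", "rel_expr", "flags"),
                    names(profile))
  write_tsv_na(select(profile, dplyr::all_of(cols)), path)
}
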