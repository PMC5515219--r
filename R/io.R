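#' Read a gene catalogue table
#'
#' The gene catalogue links gene identifiers to their effective length (the
#' number of positions available to generate mapped reads, used as the
#' normalisation denominator) and their KO assignments.
#'
#' Expected TSV columns: `gene_id`, `effective_length`, `ko_ids`
#' (semicolon-separated list, empty string for unannotated genes).
#'
#' @param path Path to a tab-separated file with header.
#' @param ko_pattern Regular expression each KO identifier must match.
#' @return A tibble with columns `gene_id`, `effective_length` and a
#'   list-column `ko_ids`.
#' @export
read_gene_catalogue <- function(path, ko_pattern = "^K[0-9]+$") {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = "NA", progress = FALSE)
  assert_cols(df, c("gene_id", "effective_length", "ko_ids"), "catalogue")
  df$effective_length <- as.numeric(df$effective_length)
  df$ko_ids[is.na(df$ko_ids)] <- ""
  validate_gene_catalogue(
    tibble(
      gene_id = df$gene_id,
      effective_length = df$effective_length,
      ko_ids = split_semicolon(df$ko_ids)
    ),
    ko_pattern = ko_pattern
  )
}

#' Validate a gene catalogue
#'
#' Checks uniqueness of gene identifiers, positivity of effective lengths and
#' the KO identifier pattern. Accepts `ko_ids` as a list-column or a
#' semicolon-separated character column.
#'
#' @param catalogue A data frame with `gene_id`, `effective_length`, `ko_ids`.
#' @inheritParams read_gene_catalogue
#' @return The catalogue as a validated tibble with a list-column `ko_ids`.
#' @export
validate_gene_catalogue <- function(catalogue, ko_pattern = "^K[0-9]+$") {
  assert_cols(catalogue, c("gene_id", "effective_length", "ko_ids"),
              "catalogue")
  catalogue <- as_tibble(catalogue)
  if (is.character(catalogue$ko_ids)) {
    catalogue$ko_ids <- split_semicolon(catalogue$ko_ids)
  }
  if (anyDuplicated(catalogue$gene_id)) {
    dup <- unique(catalogue$gene_id[duplicated(catalogue$gene_id)])
    abort(sprintf("Duplicated gene_id in catalogue: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (any(!is.finite(catalogue$effective_length)) ||
      any(catalogue$effective_length < 1)) {
    abort("All effective lengths must be finite and >= 1.")
  }
  all_kos <- unique(unlist(catalogue$ko_ids))
  bad <- all_kos[!grepl(ko_pattern, all_kos)]
  if (length(bad) > 0) {
    abort(sprintf("KO identifiers not matching '%s': %s",
                  ko_pattern, paste(head(bad, 5), collapse = ", ")))
  }
  catalogue
}

#' Read a per-gene count table
#'
#' @param path Path to a TSV with header columns `gene_id`, `count`.
#' @return A tibble with columns `gene_id`, `count`.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    count = readr::col_double()
  ), na = "NA", progress = FALSE)
  if (any(!is.finite(df$count)) || any(df$count < 0)) {
    abort("Counts must be finite and non-negative.")
  }
  as_tibble(df)
}

#' Read read-to-gene assignments
#'
#' Each row records one read and the set of genes it mapped to
#' (semicolon-separated). Used as input to [weight_multimapped()].
#'
#' @param path Path to a TSV with header columns `read_id`, `gene_ids`.
#' @return A tibble with `read_id` and list-column `gene_ids`.
#' @export
read_assignments <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(),
    gene_ids = readr::col_character()
  ), na = "NA", progress = FALSE)
  df$gene_ids[is.na(df$gene_ids)] <- ""
  tibble(read_id = df$read_id, gene_ids = split_semicolon(df$gene_ids))
}

#' Read a KO reaction-pair map
#'
#' A reaction-pair map assigns each KO a pair-set of (substrate, product)
#' metabolites, emulating reactant-pair annotations. Accepted formats:
#' TSV with header columns `ko_id`, `substrate`, `product` (one pair per
#' line), or JSON of the form `{"K00001": [["C001","C002"], ...], ...}`.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` file.
#' @return A tibble with columns `ko_id`, `substrate`, `product`.
#' @export
read_pair_map <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- purrr::imap(lst, function(pairs, ko) {
      if (length(pairs) == 0) {
        return(tibble(ko_id = character(), substrate = character(),
                      product = character()))
      }
      tibble(
        ko_id = ko,
        substrate = purrr::map_chr(pairs, 1),
        product = purrr::map_chr(pairs, 2)
      )
    })
    df <- bind_rows(rows)
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(
      ko_id = readr::col_character(),
      substrate = readr::col_character(),
      product = readr::col_character()
    ), na = "NA", progress = FALSE)
  }
  validate_pair_map(df)
}

#' Validate a reaction-pair map
#'
#' @param pair_map Data frame with columns `ko_id`, `substrate`, `product`.
#' @return The pair map as a de-duplicated tibble.
#' @export
validate_pair_map <- function(pair_map) {
  assert_cols(pair_map, c("ko_id", "substrate", "product"), "pair_map")
  pair_map <- as_tibble(pair_map)
  bad <- !nzchar(pair_map$substrate) | !nzchar(pair_map$product) |
    is.na(pair_map$substrate) | is.na(pair_map$product)
  if (any(bad)) {
    abort("Metabolite identifiers in the pair map must be non-empty strings.")
  }
  distinct(pair_map, .data$ko_id, .data$substrate, .data$product)
}

#' Read a pathway membership map
#'
#' Long-format table mapping pathways to member KOs.
#'
#' @param path Path to a TSV with header columns `pathway_id`, `ko_id`.
#' @return A tibble with columns `pathway_id`, `ko_id`.
#' @export
read_pathway_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    pathway_id = readr::col_character(),
    ko_id = readr::col_character()
  ), na = "NA", progress = FALSE)
  distinct(as_tibble(df))
}

#' Read a protein abundance table
#'
#' Ingests per-KO protein abundances (e.g. normalised spectral index values)
#' computed upstream; spectral processing is out of scope here.
#'
#' @param path Path to a TSV with header columns `ko_id`, `protein`.
#' @return A tibble with columns `ko_id`, `protein`.
#' @export
read_protein_abundance <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    ko_id = readr::col_character(),
    protein = readr::col_double()
  ), na = "NA", progress = FALSE)
  if (any(df$protein < 0, na.rm = TRUE)) {
    abort("Protein abundances must be non-negative.")
  }
  as_tibble(df)
}

#' Write a tibble as a UTF-8, LF-terminated TSV with NA markers
#'
#' @param df Data frame to write. List-columns are collapsed with semicolons.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_na <- function(df, path) {
  df <- as_tibble(df)
  is_list <- vapply(df, is.list, logical(1))
  for (col in names(df)[is_list]) {
    df[[col]] <- vapply(df[[col]], function(v) paste(v, collapse = ";"),
                        character(1))
  }
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}
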