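# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

path3_net <- function() {
  # a - b - c
  metabolic_network(tibble::tibble(
    from = c("a", "b"), to = c("b", "c"), metabolite = c("m1", "m2")
  ))
}

star3_net <- function() {
  # hub h with leaves l1..l3
  metabolic_network(tibble::tibble(
    from = c("h", "h", "h"), to = c("l1", "l2", "l3"),
    metabolite = c("m1", "m2", "m3")
  ))
}

tiny_catalogue <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    effective_length = c(100, 700, 70, 250),
    ko_ids = list("K00001", "K00001", "K00002", character(0))
  )
}

tiny_pair_map <- function() {
  tibble::tibble(
    ko_id = c("KO1", "KO1", "KO2", "KO3"),
    substrate = c("A", "C", "B", "D"),
    product = c("B", "B", "A", "E")
  )
}
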