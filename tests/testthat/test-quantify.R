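test_that("subsampling everything returns the input table", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), count = c(5, 5))
  out <- subsample_counts(counts, depth = 10, seed = 1)
  expect_equal(out, counts)

  single <- tibble::tibble(gene_id = "g1", count = 100)
  expect_equal(subsample_counts(single, 40, seed = 99)$count, 40)
})

test_that("subsampling draws have hypergeometric-consistent means", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), count = c(8000, 2000))
  draws <- vapply(1:500, function(s) {
    subsample_counts(counts, 1000, seed = s)$count[1]
  }, numeric(1))
  # binomial moments bound the hypergeometric draw from above
  se <- sqrt(1000 * 0.8 * 0.2 / 500)
  expect_lt(abs(mean(draws) - 800), 3 * se)
  expect_true(all(draws + (1000 - draws) == 1000))
})

test_that("subsampling is deterministic and validates its inputs", {
  counts <- tibble::tibble(gene_id = letters[1:5], count = c(3, 9, 0, 4, 11))
  a <- subsample_counts(counts, 12, seed = 42)
  b <- subsample_counts(counts, 12, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a$count), 12)
  expect_error(subsample_counts(counts, 1000, seed = 1),
               "exceeds available")
  frac <- tibble::tibble(gene_id = "g1", count = 1.5)
  expect_error(subsample_counts(frac, 1, seed = 1), "before applying")
})

test_that("multi-mapping weights split reads equally and conserve totals", {
  one <- tibble::tibble(read_id = "r1", gene_ids = list(c("g1", "g2")))
  expect_equal(weight_multimapped(one)$count, c(0.5, 0.5))

  rep3 <- tibble::tibble(read_id = paste0("r", 1:3),
                         gene_ids = list("g1", "g1", "g1"))
  expect_equal(weight_multimapped(rep3)$count, 3.0)

  mixed <- tibble::tibble(
    read_id = c("r1", "r2"),
    gene_ids = list("g1", c("g1", "g2", "g3"))
  )
  out <- weight_multimapped(mixed)
  expect_equal(out$count[out$gene_id == "g1"], 1 + 1 / 3)
  expect_equal(out$count[out$gene_id == "g2"], 1 / 3)
  expect_equal(sum(out$count), 2, tolerance = 1e-12)

  bad <- tibble::tibble(read_id = "r9", gene_ids = list(character(0)))
  expect_error(weight_multimapped(bad), "empty gene set")
})

test_that("read conservation holds exactly on random assignment tables", {
  withr::with_seed(11, {
    for (i in 1:100) {
      n_reads <- sample(1:200, 1)
      genes <- sprintf("g%03d", 1:30)
      asn <- tibble::tibble(
        read_id = sprintf("r%04d", seq_len(n_reads)),
        gene_ids = lapply(seq_len(n_reads),
                          function(...) sample(genes, sample(1:5, 1)))
      )
      expect_equal(sum(weight_multimapped(asn)$count), n_reads,
                   tolerance = 1e-9)
    }
  })
})

test_that("length normalisation divides by effective length", {
  cat <- tiny_catalogue()
  out <- normalize_by_length(
    tibble::tibble(gene_id = c("g1", "g2"), count = c(7, 7)), cat
  )
  # equal counts, 7x length ratio -> 7x abundance ratio
  expect_equal(out$abundance, c(7 / 100, 7 / 700))
  expect_equal(
    normalize_by_length(tibble::tibble(gene_id = "g1", count = 0),
                        cat)$abundance,
    0
  )
  expect_error(
    normalize_by_length(tibble::tibble(gene_id = "missing", count = 1), cat),
    "missing"
  )
})

test_that("KO aggregation sums member genes and matches a brute-force oracle", {
  cat <- tiny_catalogue()
  norm <- tibble::tibble(gene_id = c("g1", "g2", "g4"),
                         abundance = c(0.1, 0.2, 5))
  out <- aggregate_ko(norm, cat)
  expect_equal(out$ko_id, "K00001")  # g4 has no KO and contributes nowhere
  expect_equal(out$abundance, 0.3)

  withr::with_seed(21, {
    for (i in 1:10) {
      n_genes <- sample(50:1000, 1)
      kos <- sprintf("K%05d", 1:20)
      cat_big <- tibble::tibble(
        gene_id = sprintf("g%04d", seq_len(n_genes)),
        effective_length = sample(100:1000, n_genes, replace = TRUE),
        ko_ids = lapply(seq_len(n_genes), function(...) {
          sample(kos, sample(0:2, 1))
        })
      )
      ab <- stats::runif(n_genes)
      norm_big <- tibble::tibble(gene_id = cat_big$gene_id, abundance = ab)
      got <- aggregate_ko(norm_big, cat_big)
      # brute force: iterate genes, add full abundance to every assigned KO
      expected <- setNames(numeric(length(kos)), kos)
      for (g in seq_len(n_genes)) {
        for (ko in cat_big$ko_ids[[g]]) {
          expected[ko] <- expected[ko] + ab[g]
        }
      }
      expected <- expected[expected > 0 | names(expected) %in% got$ko_id]
      expect_equal(setNames(got$abundance, got$ko_id),
                   expected[sort(names(expected))])
    }
  })
})

test_that("multi-KO genes contribute fully by default, fractionally on demand", {
  cat <- tibble::tibble(
    gene_id = "g1", effective_length = 100,
    ko_ids = list(c("K00001", "K00002"))
  )
  norm <- tibble::tibble(gene_id = "g1", abundance = 0.4)
  expect_equal(aggregate_ko(norm, cat)$abundance, c(0.4, 0.4))
  expect_equal(aggregate_ko(norm, cat, multi_ko = "split")$abundance,
               c(0.2, 0.2))
})

test_that("relative expression is the KOTA/KOGA ratio with MT-only policies", {
  koga <- tibble::tibble(ko_id = "K1", abundance = 0.1)
  expect_equal(
    relative_expression(koga,
                        tibble::tibble(ko_id = "K1",
                                       abundance = 0.2))$rel_expr,
    2.0
  )
  expect_equal(
    relative_expression(koga,
                        tibble::tibble(ko_id = "K1",
                                       abundance = 0))$rel_expr,
    0
  )

  mt_only <- relative_expression(
    tibble::tibble(ko_id = "K1", abundance = 0),
    tibble::tibble(ko_id = "K1", abundance = 0.3),
    policy = "flag"
  )
  expect_equal(mt_only$flags, "MT-only")
  expect_true(is.na(mt_only$rel_expr))

  pseudo <- relative_expression(
    tibble::tibble(ko_id = c("K1", "K2"), abundance = c(0, 0.05)),
    tibble::tibble(ko_id = c("K1", "K2"), abundance = c(0.3, 0.1)),
    policy = "pseudocount"
  )
  expect_equal(pseudo$rel_expr[pseudo$ko_id == "K1"], 0.3 / 0.05)

  expect_error(
    relative_expression(tibble::tibble(ko_id = "K1", abundance = -1),
                        tibble::tibble(ko_id = "K1", abundance = 1)),
    "non-negative"
  )
})

test_that("scaling all transcript abundances scales every ratio equally", {
  withr::with_seed(5, {
    koga <- tibble::tibble(ko_id = sprintf("K%02d", 1:30),
                           abundance = stats::runif(30, 0.01, 1))
    kota <- tibble::tibble(ko_id = koga$ko_id,
                           abundance = stats::runif(30, 0.01, 2))
  })
  base <- relative_expression(koga, kota)
  scaled <- relative_expression(
    koga, dplyr::mutate(kota, abundance = abundance * 7.5)
  )
  expect_equal(scaled$rel_expr, base$rel_expr * 7.5)
  expect_identical(order(scaled$rel_expr), order(base$rel_expr))
})
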