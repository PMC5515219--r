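make_topo <- function(load_scores, members = NULL) {
  ids <- names(load_scores)
  tibble::tibble(
    node_id = ids,
    members = members %||% lapply(ids, identity),
    degree = rep(2, length(ids)),
    betweenness = unname(load_scores) * 4,
    load_score = unname(load_scores),
    choke_point = FALSE,
    unique_metabolites = rep(list(character(0)), length(ids))
  )
}

test_that("top-decile load criterion passes ceiling(q*N) distinct scores", {
  withr::with_seed(7, {
    scores <- setNames(sample(seq(0.01, 1, length.out = 20)),
                       sprintf("K%05d", 1:20))
  })
  topo <- make_topo(scores)
  prof <- tibble::tibble(ko_id = names(scores), rel_expr = 1, flags = "")
  rep <- select_key_functionalities(topo, prof, load_quantile = 0.10,
                                    expr_quantile = 1)
  expect_equal(sum(rep$candidates$pass_load), 2)
  expect_setequal(
    rep$candidates$node_id[rep$candidates$pass_load],
    names(sort(scores, decreasing = TRUE))[1:2]
  )
})

test_that("degenerate expression ties all pass under include_ties", {
  scores <- setNames(seq(0.1, 1, length.out = 10), sprintf("K%05d", 1:10))
  topo <- make_topo(scores)
  prof <- tibble::tibble(ko_id = names(scores), rel_expr = 2, flags = "")
  rep <- select_key_functionalities(topo, prof, expr_quantile = 0.10,
                                    tie_policy = "include_ties")
  expect_true(all(rep$candidates$pass_expr))
  strict <- select_key_functionalities(topo, prof, expr_quantile = 0.10,
                                       tie_policy = "strict")
  expect_equal(sum(strict$candidates$pass_expr), 1)
})

test_that("selection equals an independent double filter on random tables", {
  withr::with_seed(17, {
    for (i in 1:5) {
      n <- 200
      ids <- sprintf("K%05d", seq_len(n))
      scores <- setNames(stats::rexp(n), ids)
      expr <- stats::rexp(n) + 0.001
      topo <- make_topo(scores)
      prof <- tibble::tibble(ko_id = ids, rel_expr = expr, flags = "")
      rep <- select_key_functionalities(topo, prof, load_quantile = 0.10,
                                        expr_quantile = 0.10)
      # brute force: independently computed thresholds, then intersect
      thr_l <- sort(scores, decreasing = TRUE)[ceiling(0.1 * n)]
      thr_e <- sort(expr, decreasing = TRUE)[ceiling(0.1 * n)]
      expected <- ids[scores >= thr_l & expr >= thr_e]
      expect_setequal(rep$selected$node_id, expected)
      # every reported keystone satisfies both criteria (re-check pass)
      expect_true(all(rep$selected$load_score >= thr_l))
      sel_expr <- rep$selected$rel_expr
      expect_true(all(sel_expr >= thr_e))
    }
  })
})

test_that("stricter load quantiles never add selected nodes", {
  withr::with_seed(27, {
    n <- 100
    ids <- sprintf("K%05d", seq_len(n))
    topo <- make_topo(setNames(stats::rexp(n), ids))
    prof <- tibble::tibble(ko_id = ids, rel_expr = stats::rexp(n) + 0.001,
                           flags = "")
  })
  previous <- NULL
  for (q in c(0.5, 0.25, 0.10, 0.05)) {
    sel <- select_key_functionalities(topo, prof, load_quantile = q,
                                      expr_quantile = 0.25)$selected$node_id
    if (!is.null(previous)) expect_true(all(sel %in% previous))
    previous <- sel
  }
})

test_that("the q = 1 ceiling selects exactly the positively expressed nodes", {
  ids <- sprintf("K%05d", 1:12)
  topo <- make_topo(setNames(seq(0, 1.1, length.out = 12), ids))
  prof <- tibble::tibble(
    ko_id = ids,
    rel_expr = c(rep(0, 3), seq(0.5, 4, length.out = 9)),
    flags = ""
  )
  rep <- select_key_functionalities(topo, prof, load_quantile = 1,
                                    expr_quantile = 1)
  expect_setequal(rep$selected$node_id, ids[prof$rel_expr > 0])
})

test_that("group expression aggregates over member KOs", {
  topo <- make_topo(setNames(c(1, 0.5), c("grp", "single")),
                    members = list(c("K00001", "K00002"), "K00003"))
  prof <- tibble::tibble(ko_id = sprintf("K%05d", 1:3),
                         rel_expr = c(0.1, 5, 1), flags = "")
  rep <- select_key_functionalities(topo, prof, load_quantile = 1,
                                    expr_quantile = 1)
  cand <- rep$candidates
  expect_equal(cand$rel_expr[cand$node_id == "grp"], 5)  # max over members
  rep_mean <- select_key_functionalities(topo, prof, load_quantile = 1,
                                         expr_quantile = 1,
                                         group_expr = "mean")
  expect_equal(rep_mean$candidates$rel_expr[cand$node_id == "grp"], 2.55)
})

test_that("MT-only KOs are excluded from ranking unless opted in", {
  ids <- sprintf("K%05d", 1:10)
  topo <- make_topo(setNames(seq_len(10) / 10, ids))
  prof <- tibble::tibble(
    ko_id = ids,
    rel_expr = c(NA, seq(0.1, 0.9, length.out = 9)),
    flags = c("MT-only", rep("", 9))
  )
  rep <- select_key_functionalities(topo, prof, expr_quantile = 0.2)
  expect_false("K00001" %in% rep$candidates$node_id[rep$candidates$pass_expr])
  opted <- select_key_functionalities(topo, prof, expr_quantile = 0.2,
                                      include_mt_only = TRUE)
  expect_true("K00001" %in% opted$candidates$node_id[opted$candidates$pass_expr])
})

test_that("enrichment p-values match direct hypergeometric tail sums", {
  # pathway identical to the selected set: smallest achievable p
  sel <- sprintf("K%05d", 1:10)
  bg <- sprintf("K%05d", 1:20)
  pw <- tibble::tibble(pathway_id = "pwA", ko_id = sel)
  res <- pathway_enrichment(sel, bg, pw)
  expect_equal(res$p_value, oracle_hypergeom_tail(10, 10, 20, 10),
               tolerance = 1e-12)

  # disjoint pathway: one-sided p of 1
  pw_dis <- tibble::tibble(pathway_id = "pwB",
                           ko_id = sprintf("K%05d", 11:20))
  expect_equal(pathway_enrichment(sel, bg, pw_dis)$p_value, 1)

  # 2x2: 8 selected in pathway, 2 selected outside, 10 unselected in
  # pathway, 80 unselected outside
  bg2 <- sprintf("K%05d", 1:100)
  sel2 <- sprintf("K%05d", 1:10)
  pw2 <- tibble::tibble(pathway_id = "pwC",
                        ko_id = sprintf("K%05d", c(1:8, 11:20)))
  res2 <- pathway_enrichment(sel2, bg2, pw2)
  expect_equal(res2$p_value, oracle_hypergeom_tail(8, 18, 100, 10),
               tolerance = 1e-12)

  expect_error(pathway_enrichment(c(sel, "K99999"), bg, pw), "subset")
})

test_that("BH adjustment is monotone and matches the step-up formula", {
  withr::with_seed(37, {
    bg <- sprintf("K%05d", 1:200)
    sel <- sample(bg, 30)
    pw <- tibble::tibble(
      pathway_id = rep(sprintf("pw%02d", 1:12), each = 15),
      ko_id = sample(bg, 180, replace = TRUE)
    )
  })
  res <- pathway_enrichment(sel, bg, pw)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$fdr, oracle_bh(res$p_value))
  expect_true(all(diff(res$fdr[order(res$p_value)]) >= -1e-12))
})

test_that("seasonal betweenness comparison reports paired fold changes", {
  ids <- sprintf("K%05d", 1:10)
  topo_a <- make_topo(setNames(rep(1, 10), ids))
  topo_a$betweenness <- seq(2, 20, by = 2)
  pw <- tibble::tibble(pathway_id = "pwA", ko_id = ids)

  identical_res <- compare_seasonal_betweenness(topo_a, topo_a, pw)
  expect_equal(identical_res$median_fold_change, 1)
  expect_equal(identical_res$wilcoxon_p, 1)

  topo_b <- topo_a
  topo_b$betweenness <- topo_a$betweenness * 4
  res4 <- compare_seasonal_betweenness(topo_a, topo_b, pw)
  expect_equal(res4$median_fold_change, 4)

  small <- tibble::tibble(pathway_id = "tiny", ko_id = "K00001")
  expect_warning(out <- compare_seasonal_betweenness(topo_a, topo_b, small),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("signed-rank p-values match exhaustive null enumeration", {
  withr::with_seed(47, {
    for (i in 1:5) {
      n <- 10
      a <- stats::runif(n, 1, 5)
      b <- a + stats::rnorm(n, 0.4, 1)
      # enforce no zeros / tied absolute differences for the exact case
      while (any(b == a) || anyDuplicated(abs(b - a))) {
        b <- a + stats::rnorm(n, 0.4, 1)
      }
      ids <- sprintf("K%05d", seq_len(n))
      topo_a <- make_topo(setNames(rep(1, n), ids))
      topo_a$betweenness <- a
      topo_b <- topo_a
      topo_b$betweenness <- b
      pw <- tibble::tibble(pathway_id = "pwA", ko_id = ids)
      res <- compare_seasonal_betweenness(topo_a, topo_b, pw)
      expect_equal(res$wilcoxon_p, oracle_signed_rank_p(b, a),
                   tolerance = 1e-12)
    }
  })
})

test_that("zero-betweenness pairs are excluded from medians but counted", {
  ids <- sprintf("K%05d", 1:6)
  topo_a <- make_topo(setNames(rep(1, 6), ids))
  topo_a$betweenness <- c(0, 2, 2, 2, 2, 2)
  topo_b <- topo_a
  topo_b$betweenness <- c(5, 8, 8, 8, 8, 0)
  pw <- tibble::tibble(pathway_id = "pwA", ko_id = ids)
  res <- compare_seasonal_betweenness(topo_a, topo_b, pw)
  expect_equal(res$n_zero_excluded, 2)
  expect_equal(res$median_fold_change, 4)
})
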