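# Independent oracles used to cross-check the implementation. These are
# deliberately written without igraph and without reusing package internals.

# Betweenness by explicit all-pairs BFS path counting on an undirected
# simple graph given as an edge data frame (columns from, to) over `nodes`.
# For each source, a BFS records hop distances and counts shortest paths by
# summing predecessor counts; a node n lies on an s-t geodesic iff
# d(s,n) + d(n,t) = d(s,t), contributing sigma_sn * sigma_nt / sigma_st.
oracle_betweenness <- function(edges, nodes) {
  nn <- length(nodes)
  idx <- setNames(seq_len(nn), nodes)
  adj <- vector("list", nn)
  for (v in seq_len(nn)) adj[[v]] <- integer(0)
  for (i in seq_len(nrow(edges))) {
    a <- idx[[edges$from[i]]]; b <- idx[[edges$to[i]]]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  dist <- matrix(Inf, nn, nn)
  sigma <- matrix(0, nn, nn)
  for (s in seq_len(nn)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- dist[s, v] + 1
            nxt <- union(nxt, w)
          }
          if (dist[s, w] == dist[s, v] + 1) {
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          }
        }
      }
      frontier <- nxt
    }
  }
  b <- numeric(nn)
  for (s in seq_len(nn - 1)) {
    for (t in (s + 1):nn) {
      if (is.infinite(dist[s, t])) next
      on_path <- dist[s, ] + dist[t, ] == dist[s, t]
      on_path[c(s, t)] <- FALSE
      contrib <- numeric(nn)
      contrib[on_path] <- sigma[s, on_path] * sigma[t, on_path] / sigma[s, t]
      b <- b + contrib
    }
  }
  setNames(b, nodes)
}

# Upper-tail hypergeometric probability P(X >= a) by direct summation of
# binomial-coefficient ratios for a 2x2 table with margins fixed:
# a successes among n_draw draws from n_success successes in n_total.
oracle_hypergeom_tail <- function(a, n_success, n_total, n_draw) {
  upper <- min(n_success, n_draw)
  terms <- vapply(a:upper, function(k) {
    exp(lchoose(n_success, k) + lchoose(n_total - n_success, n_draw - k) -
          lchoose(n_total, n_draw))
  }, numeric(1))
  sum(terms)
}

# Exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n sign
# assignments (no ties, no zeros assumed).
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_null <- as.vector(signs %*% r)
  p_ge <- mean(w_null >= w_obs)
  p_le <- mean(w_null <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Benjamini-Hochberg adjustment from the defining step-up formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Random Erdos-Renyi edge table over n nodes with edge probability prob.
random_er_edges <- function(n, prob) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < prob
  tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2],
                 metabolite = sprintf("m%04d", which(keep)))
}

# Random modular edge table: `k` dense blocks plus sparse inter-block edges.
random_modular_edges <- function(n_blocks, block_size, p_in = 0.6,
                                 p_out = 0.02) {
  nodes <- sprintf("b%d_%02d", rep(seq_len(n_blocks), each = block_size),
                   rep(seq_len(block_size), n_blocks))
  block <- rep(seq_len(n_blocks), each = block_size)
  pairs <- t(combn(seq_along(nodes), 2))
  same <- block[pairs[, 1]] == block[pairs[, 2]]
  keep <- runif(nrow(pairs)) < ifelse(same, p_in, p_out)
  tibble::tibble(from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]],
                 metabolite = sprintf("m%04d", which(keep)))
}

# Random reaction-pair map over n_kos KOs and a metabolite alphabet.
random_pair_map <- function(n_kos, n_metabolites, max_pairs = 4) {
  mets <- sprintf("C%03d", seq_len(n_metabolites))
  rows <- lapply(seq_len(n_kos), function(i) {
    k <- sample(max_pairs, 1)
    tibble::tibble(
      ko_id = sprintf("K%05d", i),
      substrate = sample(mets, k, replace = TRUE),
      product = sample(mets, k, replace = TRUE)
    )
  })
  df <- dplyr::bind_rows(rows)
  df[df$substrate != df$product, ]
}
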