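# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the tail probability is a combinatorial count, the
# BH oracle is the step-up definition applied literally, and the distance
# oracle is Floyd-Warshall on a dense matrix.

# P(X >= k) for X ~ Hypergeometric(N, K, n), by counting draws
oracle_tail_count <- function(k, K, n, N) {
  if (k <= 0) {
    return(1)
  }
  js <- k:min(K, n)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# same quantity by literal enumeration of all size-n subsets (tiny N only)
oracle_tail_enum <- function(k, K, n, N) {
  if (k <= 0) {
    return(1)
  }
  if (n == 0) {
    return(0)
  }
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K) >= k   # category = elements 1..K
  mean(hits)
}

# Benjamini-Hochberg step-up, from the definition: sort ascending, multiply
# p_(i) by m/i, enforce monotonicity from the top, cap at 1, unsort.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# all-pairs shortest-path matrix by Floyd-Warshall over an edge list
oracle_distance_matrix <- function(nodes, edge_a, edge_b) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  ia <- match(edge_a, nodes)
  ib <- match(edge_b, nodes)
  for (e in seq_along(ia)) {
    d[ia[e], ib[e]] <- 1
    d[ib[e], ia[e]] <- 1
  }
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# mean distance between two in-graph sets, pairs deduplicated unordered,
# unreachable excluded; mirrors the documented contract, not the code
oracle_avg_distance <- function(dmat, set_a, set_b) {
  pairs <- unique(t(apply(expand.grid(a = set_a, b = set_b,
                                      stringsAsFactors = FALSE), 1L,
                          function(r) sort(c(r[["a"]], r[["b"]])))))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  d <- dmat[cbind(pairs[, 1L], pairs[, 2L])]
  list(mean = mean(d[is.finite(d)]), n_unreachable = sum(is.infinite(d)))
}

# a random seed-centric interactome for property tests
random_interactome <- function(n_seeds = 5L, n_partners = 30L,
                               n_edges = 60L, p_novel = 0.5,
                               name = "random") {
  seeds <- sprintf("S%03d", seq_len(n_seeds))
  partners <- sprintf("P%03d", seq_len(n_partners))
  a <- sample(seeds, n_edges, replace = TRUE)
  b <- sample(c(seeds, partners), n_edges, replace = TRUE)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  novel <- runif(length(a)) < p_novel
  assemble_interactome(
    seeds,
    known = ppi_edges(a[!novel], b[!novel], source = "k"),
    novel = ppi_edges(a[novel], b[novel], source = "n"),
    name = name
  )
}
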