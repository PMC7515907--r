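#' Average shortest-path distance between two gene sets
#'
#' Unweighted, undirected breadth-first distances over all distinct unordered
#' pairs `{a, b}` with `a` in `set_a`, `b` in `set_b`, `a != b`. Unreachable
#' pairs are excluded from the mean and counted separately (no imputation by
#' default — see `impute`). Genes absent from the network are dropped with a
#' warning.
#'
#' @param net an `interactome`.
#' @param set_a,set_b character vectors of gene symbols; `set_b` defaults to
#'   `set_a` (within-set average).
#' @param impute optional finite distance to substitute for unreachable pairs
#'   (sensitivity analysis); `NULL` (default) excludes them.
#' @return a `distance_summary`: list with `mean_distance`, `n_pairs_used`,
#'   `n_pairs_unreachable`.
#' @export
avg_shortest_path <- function(net, set_a, set_b = set_a, impute = NULL) {
  stopifnot(inherits(net, "interactome"))
  g <- interactome_graph(net)
  nodes <- igraph::V(g)$name
  a <- unique(normalize_symbols(set_a))
  b <- unique(normalize_symbols(set_b))
  miss <- sum(!a %in% nodes) + sum(!b %in% nodes)
  if (miss > 0L) {
    warning("dropping ", miss, " gene(s) absent from the network")
    a <- a[a %in% nodes]
    b <- b[b %in% nodes]
  }
  dist_summary(g, a, b, impute = impute)
}

# kernel shared with random_set_null; a and b are in-graph gene names
dist_summary <- function(g, a, b, impute = NULL, dm = NULL) {
  if (length(a) == 0L || length(b) == 0L ||
      (length(a) == 1L && identical(a, b))) {
    stop("no usable pairs: both sets must map to the network and ",
         "contain at least one distinct pair")
  }
  if (is.null(dm)) {
    dm <- igraph::distances(g, v = a, to = b)
  } else {
    dm <- dm[a, b, drop = FALSE]
  }
  # unordered dedup: pairs present both ways (shared genes) count once
  pa <- rep(rownames(dm), times = ncol(dm))
  pb <- rep(colnames(dm), each = nrow(dm))
  ok <- pa != pb
  key <- paste(pmin(pa, pb), pmax(pa, pb), sep = "\r")
  first <- ok & !duplicated(key)
  d <- as.vector(dm)[first]
  if (length(d) == 0L) {
    stop("no usable pairs after deduplication")
  }
  unreachable <- is.infinite(d)
  if (!is.null(impute)) {
    d[unreachable] <- impute
    used <- d
    n_unreach <- sum(unreachable)
  } else {
    used <- d[!unreachable]
    n_unreach <- sum(unreachable)
  }
  structure(
    list(
      mean_distance = if (length(used) > 0L) mean(used) else NaN,
      n_pairs_used = length(used),
      n_pairs_unreachable = n_unreach
    ),
    class = "distance_summary"
  )
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("<distance summary> mean ", format(x$mean_distance, digits = 4),
      " over ", x$n_pairs_used, " pairs (",
      x$n_pairs_unreachable, " unreachable)\n", sep = "")
  invisible(x)
}

#' Shortest-path null comparison against random gene sets
#'
#' Compares an observed average shortest-path distance with an empirical null
#' built from random gene sets sampled uniformly (without replacement within
#' a draw) from a background list. Two usages:
#'
#' * **Within-set** (`set_b = NULL`): the observed statistic is the average
#'   distance within `set_a`; each null draw of `set_size` genes is scored by
#'   its own within-set average. Asks "is this gene set more tightly
#'   interconnected than a random one?"
#' * **Between-set** (`set_b` given): the observed statistic is the average
#'   distance between `set_a` and `set_b`; null draws replace `set_b`. Asks
#'   "is this gene set closer to `set_a` than a random one?"
#'
#' The empirical p-value uses the add-one pseudocount,
#' `p = (r + 1) / (n_samples + 1)` with `r` the number of null means less
#' than or equal to the observed mean ("closer than random" test), so p is
#' never exactly zero. Fixed `seed` gives identical null distributions; the
#' caller's RNG state is left untouched.
#'
#' @param net an `interactome`.
#' @param set_a character vector of gene symbols.
#' @param set_b optional reference set (between-set mode).
#' @param set_size size of each null draw; defaults to the (in-network) size
#'   of the varied set.
#' @param background character vector to sample from (e.g. a genome-wide gene
#'   list of ~20,000 symbols). Draws that miss the network entirely yield
#'   `NA` null means and are excluded from `r` and the pseudocount
#'   denominator.
#' @param n_samples number of null draws (>= 1), default 1000.
#' @param seed integer RNG seed.
#' @return a `null_comparison`: list with `observed` (a `distance_summary`),
#'   `null_means`, `empirical_p`, `seed`, `n_samples`, `mode`.
#' @export
random_set_null <- function(net, set_a, set_b = NULL, set_size = NULL,
                            background, n_samples = 1000, seed = 1) {
  stopifnot(inherits(net, "interactome"), n_samples >= 1)
  g <- interactome_graph(net)
  nodes <- igraph::V(g)$name
  background <- unique(normalize_symbols(background))
  a <- unique(normalize_symbols(set_a))
  a_in <- a[a %in% nodes]
  if (length(a_in) < length(a)) {
    warning("dropping ", length(a) - length(a_in),
            " set_a gene(s) absent from the network")
  }
  between <- !is.null(set_b)
  if (between) {
    b <- unique(normalize_symbols(set_b))
    b_in <- b[b %in% nodes]
    if (is.null(set_size)) {
      set_size <- length(b_in)
    }
    observed <- dist_summary(g, a_in, b_in)
    dm_all <- igraph::distances(g, v = a_in)  # rows: set_a, cols: all nodes
  } else {
    if (is.null(set_size)) {
      set_size <- length(a_in)
    }
    observed <- dist_summary(g, a_in, a_in)
  }
  if (set_size > length(background)) {
    stop("set_size (", set_size, ") exceeds the background (",
         length(background), ")")
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed))

  null_means <- vapply(seq_len(n_samples), function(i) {
    draw <- sample(background, set_size)
    draw <- draw[draw %in% nodes]
    res <- tryCatch({
      if (between) {
        dist_summary(g, a_in, draw, dm = dm_all)
      } else {
        dist_summary(g, draw, draw)
      }
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$mean_distance)) NA_real_
    else res$mean_distance
  }, numeric(1L))

  usable <- !is.na(null_means)
  r <- sum(null_means[usable] <= observed$mean_distance)
  structure(
    list(
      observed = observed,
      null_means = null_means,
      empirical_p = (r + 1) / (sum(usable) + 1),
      seed = as.integer(seed),
      n_samples = as.integer(n_samples),
      mode = if (between) "between-set" else "within-set"
    ),
    class = "null_comparison"
  )
}

#' @export
print.null_comparison <- function(x, ...) {
  cat("<shortest-path null> ", x$mode, ": observed mean ",
      format(x$observed$mean_distance, digits = 4),
      ", empirical p = ", format(x$empirical_p, digits = 4),
      " (", x$n_samples, " draws, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
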