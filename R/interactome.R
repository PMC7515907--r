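#' Construct a table of PPI edges
#'
#' Builds a canonical edge table for use with [assemble_interactome()]. Edge
#' identity is unordered: endpoints are stored sorted lexicographically, so
#' `ppi_edges("A", "B")` and `ppi_edges("B", "A")` are the same edge.
#'
#' @param a,b character vectors of endpoint gene symbols (recycled to a common
#'   length).
#' @param source free-text provenance tag(s), e.g. `"HPRD"`, `"BioGRID"`,
#'   `"predicted"`.
#' @param allow_self_loops keep edges with `a == b` (homodimers)? If `FALSE`
#'   (default, the usual PPI convention) a self-loop is an error naming the
#'   pair.
#' @return data.frame with columns `a`, `b`, `source`, endpoints normalized
#'   and sorted within each row.
#' @export
ppi_edges <- function(a, b, source = "", allow_self_loops = FALSE) {
  if (length(a) == 0L) {
    return(data.frame(a = character(), b = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  a <- normalize_symbols(a)
  b <- normalize_symbols(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  source <- rep_len(as.character(source), n)
  loops <- a == b
  if (any(loops) && !allow_self_loops) {
    stop("self-loop edge(s) not allowed (set allow_self_loops = TRUE): ",
         paste(utils::head(unique(a[loops]), 5L), collapse = ", "))
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  data.frame(a = lo, b = hi, source = source, stringsAsFactors = FALSE)
}

# Accept either a two/three-column data.frame (gene_a, gene_b[, source]) or
# the output of ppi_edges(); return the canonical form.
as_ppi_edges <- function(x, allow_self_loops = FALSE, default_source = "") {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(ppi_edges(character(), character()))
  }
  stopifnot(is.data.frame(x))
  cols <- names(x)
  ga <- if ("a" %in% cols) x$a else x$gene_a
  gb <- if ("b" %in% cols) x$b else x$gene_b
  if (is.null(ga) || is.null(gb)) {
    stop("edge table must have columns a/b or gene_a/gene_b")
  }
  src <- if ("source" %in% cols) x$source else default_source
  ppi_edges(ga, gb, source = src, allow_self_loops = allow_self_loops)
}

#' Assemble a seed-centric interactome
#'
#' Combines known (curated) and novel (predicted) PPI edge tables around a set
#' of seed genes into a single network object. Every retained edge touches at
#' least one seed. Duplicate unordered pairs are stored once; a pair present
#' in both the known and the novel input is stored once with provenance
#' `"known"` (a prediction of an already-curated pair is a confirmation, not a
#' new edge). Assembly is order-independent: permuting the input edge rows
#' yields an identical object.
#'
#' @param seeds character vector of seed gene symbols (non-empty).
#' @param known,novel edge tables as returned by [ppi_edges()], or data.frames
#'   with columns `gene_a`, `gene_b` and optionally `source`. Either may be
#'   `NULL`.
#' @param name label for the network.
#' @param strict if `TRUE` (default), an edge touching no seed is an error; if
#'   `FALSE` such edges are dropped and their count recorded in the
#'   `n_dropped` attribute (and reported via a message).
#' @param allow_self_loops passed to edge canonicalization.
#' @return an object of class `interactome`: a list with elements `name`,
#'   `seeds` (sorted character) and `edges` (data.frame `a`, `b`,
#'   `provenance`, `source`, sorted by endpoints). The attribute
#'   `n_confirmed` counts novel input pairs that duplicated a known pair.
#' @seealso [classify_nodes()], [summarize_per_seed()], [interactome_nodes()]
#' @examples
#' net <- assemble_interactome(
#'   seeds = c("IFT88", "BBS1"),
#'   known = ppi_edges("IFT88", "IFT57"),
#'   novel = ppi_edges(c("BBS1", "IFT88"), c("BAK1", "IFT57"))
#' )
#' net
#' @export
assemble_interactome <- function(seeds, known = NULL, novel = NULL,
                                 name = "interactome", strict = TRUE,
                                 allow_self_loops = FALSE) {
  if (length(seeds) == 0L) {
    stop("seed set must be non-empty")
  }
  seeds <- sort(unique(normalize_symbols(seeds)))
  known <- as_ppi_edges(known, allow_self_loops = allow_self_loops)
  novel <- as_ppi_edges(novel, allow_self_loops = allow_self_loops)

  edges <- rbind(
    cbind(known, provenance = rep_len("known", nrow(known))),
    cbind(novel, provenance = rep_len("novel", nrow(novel)))
  )
  edges <- edges[, c("a", "b", "provenance", "source")]

  touches <- edges$a %in% seeds | edges$b %in% seeds
  n_dropped <- sum(!touches)
  if (n_dropped > 0L) {
    if (strict) {
      off <- edges[!touches, , drop = FALSE]
      stop(n_dropped, " edge(s) touch no seed, e.g. ",
           off$a[1L], "-", off$b[1L],
           " (use strict = FALSE to drop them)")
    }
    message("dropping ", n_dropped, " edge(s) with no seed endpoint")
    edges <- edges[touches, , drop = FALSE]
  }

  key <- paste(edges$a, edges$b, sep = "\r")
  known_keys <- unique(key[edges$provenance == "known"])
  n_confirmed <- length(intersect(known_keys,
                                  key[edges$provenance == "novel"]))
  # known precedence: any pair seen in the known input stays known
  edges$provenance[key %in% known_keys] <- "known"
  # merge source tags of duplicate rows, then keep one row per pair
  src <- vapply(split(edges$source, key), function(s) {
    s <- sort(unique(s[nzchar(s)]))
    paste(s, collapse = ";")
  }, character(1L))
  first <- !duplicated(key)
  edges <- edges[first, , drop = FALSE]
  edges$source <- unname(src[paste(edges$a, edges$b, sep = "\r")])
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL

  structure(
    list(name = name, seeds = seeds, edges = edges),
    n_dropped = n_dropped,
    n_confirmed = n_confirmed,
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  prov <- table(factor(x$edges$provenance, levels = c("known", "novel")))
  cat("<interactome> ", x$name, "\n", sep = "")
  cat("  seeds: ", length(x$seeds),
      "; nodes: ", length(interactome_nodes(x)),
      "; edges: ", nrow(x$edges),
      " (", prov[["known"]], " known, ", prov[["novel"]], " novel)\n",
      sep = "")
  invisible(x)
}

#' Node set of an interactome
#'
#' The node set is the union of the seeds and all edge endpoints; seeds with
#' no incident edge are still nodes.
#'
#' @param net an `interactome`.
#' @return sorted character vector of gene symbols.
#' @export
interactome_nodes <- function(net) {
  stopifnot(inherits(net, "interactome"))
  sort(unique(c(net$seeds, net$edges$a, net$edges$b)))
}

#' Classify nodes as seed, known or novel interactor
#'
#' Non-seed nodes are `novel_interactor` when every incident edge is a
#' predicted (novel) PPI, and `known_interactor` when at least one incident
#' edge is curated. Seeds keep role `seed` regardless of their incident
#' edges. The roles partition the node set.
#'
#' @param net an `interactome`.
#' @return named character vector (names = node symbols, values in
#'   `c("seed", "known_interactor", "novel_interactor")`).
#' @export
classify_nodes <- function(net) {
  stopifnot(inherits(net, "interactome"))
  nodes <- interactome_nodes(net)
  role <- setNames(rep("novel_interactor", length(nodes)), nodes)
  kn <- net$edges$provenance == "known"
  role[unique(c(net$edges$a[kn], net$edges$b[kn]))] <- "known_interactor"
  role[net$seeds] <- "seed"
  role
}

#' Per-seed interaction summary
#'
#' Counts, for each seed, its incident known and novel PPIs and lists the
#' novel partners. An edge joining two seeds contributes to the counts of
#' both; the distinct-edge totals over the whole network are attached as
#' attributes `total_known_edges` and `total_novel_edges`.
#'
#' @param net an `interactome`.
#' @return data.frame with one row per seed: `seed`, `k_known`, `n_novel`,
#'   and a list-column `novel_partners`.
#' @export
summarize_per_seed <- function(net) {
  stopifnot(inherits(net, "interactome"))
  e <- net$edges
  res <- lapply(net$seeds, function(s) {
    inc <- e$a == s | e$b == s
    partner <- ifelse(e$a[inc] == s, e$b[inc], e$a[inc])
    prov <- e$provenance[inc]
    list(k = sum(prov == "known"),
         n = sum(prov == "novel"),
         novel = sort(unique(partner[prov == "novel"])))
  })
  out <- data.frame(
    seed = net$seeds,
    k_known = vapply(res, `[[`, integer(1L), "k"),
    n_novel = vapply(res, `[[`, integer(1L), "n"),
    stringsAsFactors = FALSE
  )
  out$novel_partners <- lapply(res, `[[`, "novel")
  attr(out, "total_known_edges") <- sum(e$provenance == "known")
  attr(out, "total_novel_edges") <- sum(e$provenance == "novel")
  out
}

#' Cross-reference novel edges against a functional-interaction table
#'
#' Matches predicted edges against a reference table of gene pairs carrying
#' relation labels (for example functional-interaction databases). Matching is
#' by unordered pair; a pair listed in both orders in the reference yields a
#' single match with its labels merged.
#'
#' @param novel_edges edge table ([ppi_edges()] or `gene_a`/`gene_b` columns).
#' @param reference data.frame whose first two columns are gene symbols and
#'   whose third column is a relation label (columns `gene_a`, `gene_b`,
#'   `relation` are used if present).
#' @return data.frame `a`, `b`, `relation` for the matching edges only;
#'   multiple labels are joined with `"; "`.
#' @export
cross_reference_edges <- function(novel_edges, reference) {
  novel <- as_ppi_edges(novel_edges)
  if (nrow(novel) == 0L || is.null(reference) || nrow(reference) == 0L) {
    return(data.frame(a = character(), b = character(),
                      relation = character(), stringsAsFactors = FALSE))
  }
  cols <- names(reference)
  ra <- if ("gene_a" %in% cols) reference$gene_a else reference[[1L]]
  rb <- if ("gene_b" %in% cols) reference$gene_b else reference[[2L]]
  rl <- if ("relation" %in% cols) reference$relation else reference[[3L]]
  ra <- normalize_symbols(ra)
  rb <- normalize_symbols(rb)
  rkey <- paste(pmin(ra, rb), pmax(ra, rb), sep = "\r")
  labels <- vapply(split(as.character(rl), rkey), function(s) {
    paste(sort(unique(s)), collapse = "; ")
  }, character(1L))
  novel <- novel[!duplicated(paste(novel$a, novel$b)), , drop = FALSE]
  nkey <- paste(novel$a, novel$b, sep = "\r")
  hit <- nkey %in% names(labels)
  data.frame(a = novel$a[hit], b = novel$b[hit],
             relation = unname(labels[nkey[hit]]),
             stringsAsFactors = FALSE)
}

#' Convert an interactome to an igraph graph
#'
#' Vertices carry a `role` attribute (from [classify_nodes()]); edges carry
#' `provenance` and `source`.
#'
#' @param net an `interactome`.
#' @return an [igraph::igraph] object (undirected).
#' @export
interactome_graph <- function(net) {
  stopifnot(inherits(net, "interactome"))
  nodes <- interactome_nodes(net)
  role <- classify_nodes(net)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("a", "b", "provenance", "source")],
    directed = FALSE,
    vertices = data.frame(name = nodes, role = unname(role[nodes]),
                          stringsAsFactors = FALSE)
  )
  igraph::graph_attr(g, "name") <- net$name
  g
}
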