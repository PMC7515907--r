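#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability that two gene sets share at least the observed
#' number of genes when the query is drawn uniformly from the background:
#' `P(X >= k)` with `X ~ Hypergeometric(N = |background|, K = |category|,
#' n = |query|)` and `k = |query intersect category|`. Genes of the query or
#' category that are absent from the background are dropped with a warning
#' (annotation tables are incomplete in practice; this mirrors how
#' over-representation tools handle unannotated genes).
#'
#' @param query,category,background character vectors of gene symbols
#'   (deduplicated internally).
#' @return a single p-value.
#' @examples
#' bg <- sprintf("G%03d", 1:20)
#' hypergeom_overlap_pvalue(bg[1:5], bg[3:7], bg)
#' @export
hypergeom_overlap_pvalue <- function(query, category, background) {
  background <- unique(as.character(background))
  if (length(background) == 0L) {
    stop("background must be non-empty")
  }
  query <- unique(as.character(query))
  category <- unique(as.character(category))
  n_out <- sum(!query %in% background) + sum(!category %in% background)
  if (n_out > 0L) {
    warning("dropping ", n_out,
            " query/category gene(s) absent from the background")
    query <- query[query %in% background]
    category <- category[category %in% background]
  }
  overlap_tail_pvalue(k = length(intersect(query, category)),
                      K = length(category),
                      n = length(query),
                      N = length(background))
}

# P(X >= k), X ~ Hypergeometric(N, K, n); the single statistical kernel used
# by every overlap report in the package.
overlap_tail_pvalue <- function(k, K, n, N) {
  stopifnot(N >= 1L, K <= N, n <= N, k <= min(K, n))
  if (k <= 0L) {
    return(1)
  }
  stats::phyper(k - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; output order matches input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Read a term-annotation table
#'
#' Expects tab-separated columns `term_id`, `term_name`, `gene` (header
#' required). The annotation universe is the union of annotated genes.
#'
#' @param path input TSV.
#' @return data.frame `term_id`, `term_name`, `gene` with genes normalized.
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", stringsAsFactors = FALSE)
  required <- c("term_id", "term_name", "gene")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L) {
    stop("annotation table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tab$gene <- normalize_symbols(tab$gene)
  unique(tab[required])
}

#' Read gene annotations from a GAF 2.x file
#'
#' Minimal GO Annotation File reader: column 3 (object symbol) is the gene,
#' column 5 the term id; comment lines starting with `!` are skipped and
#' qualifiers are ignored. Term names are not carried by GAF, so `term_name`
#' equals `term_id`.
#'
#' @param path input GAF file (uncompressed).
#' @return data.frame as in [read_annotation_tsv()].
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      gene = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 5L
  if (any(short)) {
    stop("malformed GAF line ", which(short)[1L], " in ", path)
  }
  tab <- data.frame(
    term_id = vapply(fields, `[[`, character(1L), 5L),
    gene = normalize_symbols(vapply(fields, `[[`, character(1L), 3L)),
    stringsAsFactors = FALSE
  )
  tab$term_name <- tab$term_id
  unique(tab[c("term_id", "term_name", "gene")])
}

#' Over-representation of annotation terms in a query gene set
#'
#' Scores every term of a collection against a query set with the one-sided
#' hypergeometric test and adjusts across all tested terms with
#' Benjamini-Hochberg. Annotations are used as given (no ontology-graph
#' propagation). The background defaults to the union of all annotated genes.
#'
#' @param query character vector of gene symbols.
#' @param annotations annotation data.frame (`term_id`, `term_name`, `gene`),
#'   e.g. from [read_annotation_tsv()] or [read_gaf()].
#' @param background background gene set; `NULL` for the annotation universe.
#' @param alpha significance level for the `enriched` flag on the BH-adjusted
#'   p-value (default 0.05).
#' @param min_overlap report only terms with at least this many query genes
#'   (default 1; the adjustment always spans all tested terms).
#' @return data.frame sorted by `adjusted_p`, then `p_value`, then `term_id`:
#'   columns `term_id`, `term_name`, `term_size`, `overlap_count`, `p_value`,
#'   `adjusted_p`, `enriched`, plus a list-column `overlapping_genes`.
#' @export
enrich_genesets <- function(query, annotations, background = NULL,
                            alpha = 0.05, min_overlap = 1L) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    stop("annotation collection must be non-empty")
  }
  stopifnot(alpha >= 0, alpha <= 1)
  genes_by_term <- split(annotations$gene, annotations$term_id)
  term_name <- tapply(annotations$term_name, annotations$term_id,
                      function(x) x[[1L]])
  if (is.null(background)) {
    background <- unique(annotations$gene)
  }
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  dropped <- sum(!query %in% background)
  if (dropped > 0L) {
    message("dropping ", dropped, " query gene(s) absent from the background")
    query <- query[query %in% background]
  }
  N <- length(background)
  n <- length(query)
  terms <- sort(names(genes_by_term))
  rows <- lapply(terms, function(tid) {
    members <- unique(genes_by_term[[tid]])
    members <- members[members %in% background]
    ov <- intersect(query, members)
    list(term_size = length(members),
         overlap = sort(ov),
         p = overlap_tail_pvalue(length(ov), length(members), n, N))
  })
  p <- vapply(rows, `[[`, numeric(1L), "p")
  adj <- bh_adjust(p)
  out <- data.frame(
    term_id = terms,
    term_name = as.character(term_name[terms]),
    term_size = vapply(rows, `[[`, integer(1L), "term_size"),
    overlap_count = vapply(rows, function(r) length(r$overlap), integer(1L)),
    p_value = p,
    adjusted_p = adj,
    stringsAsFactors = FALSE
  )
  out$enriched <- out$adjusted_p < alpha
  out$overlapping_genes <- lapply(rows, `[[`, "overlap")
  out <- out[out$overlap_count >= min_overlap, , drop = FALSE]
  out <- out[order(out$adjusted_p, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Term enrichment in a seed's network neighborhood
#'
#' The query set is the seed's interacting partners — known and novel alike,
#' the seed itself excluded — and every term of the annotation collection is
#' tested for over-representation in that neighborhood. Statistically
#' significant terms can be read as network-based term assignments for the
#' seed, which is informative for seeds with few direct annotations.
#'
#' @param net an `interactome`.
#' @param seed a seed gene of `net`.
#' @inheritParams enrich_genesets
#' @return see [enrich_genesets()]; zero rows when the seed has no partners.
#' @export
neighborhood_enrichment <- function(net, seed, annotations,
                                    background = NULL, alpha = 0.05) {
  stopifnot(inherits(net, "interactome"))
  seed <- normalize_symbols(seed)
  stopifnot(length(seed) == 1L)
  if (!seed %in% net$seeds) {
    stop(seed, " is not a seed of the interactome")
  }
  e <- net$edges
  inc <- e$a == seed | e$b == seed
  partners <- setdiff(unique(ifelse(e$a[inc] == seed, e$b[inc], e$a[inc])),
                      seed)
  suppressMessages(
    enrich_genesets(partners, annotations, background = background,
                    alpha = alpha)
  )
}
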