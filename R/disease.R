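#' Filter disease-gene associations by score
#'
#' Keeps genes associated with the named disease with score strictly greater
#' than the threshold (the DisGeNET-style convention: `score > 0.2` retains
#' only well-curated associations).
#'
#' @param associations data.frame with columns `gene`, `disease`, `score`
#'   (scores in `[0, 1]`).
#' @param disease disease label (exact match).
#' @param threshold score cut-off in `[0, 1]`; strict inequality.
#' @return deduplicated character vector of gene symbols; empty (with a
#'   warning) for an unknown disease.
#' @export
filter_disease_genes <- function(associations, disease, threshold = 0.2) {
  stopifnot(is.data.frame(associations),
            all(c("gene", "disease", "score") %in% names(associations)),
            threshold >= 0, threshold <= 1)
  score <- as.numeric(associations$score)
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop("association scores must lie in [0, 1]")
  }
  hit <- associations$disease == disease
  if (!any(hit)) {
    warning("no associations for disease: ", disease)
    return(character())
  }
  sort(unique(normalize_symbols(
    associations$gene[hit & !is.na(score) & score > threshold]
  )))
}

#' Assemble a disease-specific interactome
#'
#' Convenience wrapper around [assemble_interactome()] with the disease genes
#' as seeds; predicted edges are optional (disease interactomes are often
#' built from curated PPIs only).
#'
#' @param disease_genes character vector of seed genes.
#' @param known,novel edge tables (see [assemble_interactome()]).
#' @param name network label.
#' @param ... passed to [assemble_interactome()].
#' @return an `interactome`.
#' @export
build_disease_interactome <- function(disease_genes, known, novel = NULL,
                                      name = "disease", ...) {
  assemble_interactome(disease_genes, known = known, novel = novel,
                       name = name, ...)
}

# shared engine for node-set / gene-set overlap reports
overlap_report <- function(name_a, name_b, genes_a, genes_b,
                           background_size, novel_genes_a) {
  genes_a <- unique(genes_a)
  genes_b <- unique(genes_b)
  if (background_size < max(length(genes_a), length(genes_b))) {
    stop("background_size (", background_size,
         ") smaller than one of the gene sets")
  }
  shared <- sort(intersect(genes_a, genes_b))
  structure(
    list(
      name_a = name_a, name_b = name_b,
      size_a = length(genes_a), size_b = length(genes_b),
      shared_genes = shared,
      shared_novel = sort(intersect(shared, novel_genes_a)),
      p_value = overlap_tail_pvalue(length(shared), length(genes_a),
                                    length(genes_b), background_size),
      background_size = background_size,
      test = "hypergeometric upper tail"
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap> ", x$name_a, " (", x$size_a, ") vs ", x$name_b,
      " (", x$size_b, ")\n", sep = "")
  cat("  shared genes: ", length(x$shared_genes),
      " (", length(x$shared_novel), " novel interactors)",
      "; p = ", format(x$p_value, digits = 4),
      " [", x$test, ", background ", x$background_size, "]\n", sep = "")
  invisible(x)
}

#' Overlap between two interactomes
#'
#' Intersects the full node sets (seeds plus interactors) of two networks and
#' scores the overlap with the one-sided hypergeometric test against a fixed
#' background size (default 20,000, roughly the number of human
#' protein-coding genes). `shared_novel` reports which shared genes are novel
#' interactors *of the first network* — the convention used when asking how
#' many predicted interactors of a seed network re-occur in a disease
#' network.
#'
#' @param net_a,net_b `interactome` objects.
#' @param background_size assumed universe size; must be at least as large as
#'   either node set.
#' @param roles node roles of `net_a`, defaulting to `classify_nodes(net_a)`.
#' @return an `overlap_report`: sizes, shared genes, shared novel interactors
#'   and the hypergeometric p-value.
#' @export
interactome_overlap <- function(net_a, net_b, background_size = 20000,
                                roles = NULL) {
  stopifnot(inherits(net_a, "interactome"), inherits(net_b, "interactome"))
  if (is.null(roles)) {
    roles <- classify_nodes(net_a)
  }
  overlap_report(
    net_a$name, net_b$name,
    interactome_nodes(net_a), interactome_nodes(net_b),
    background_size,
    names(roles)[roles == "novel_interactor"]
  )
}
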