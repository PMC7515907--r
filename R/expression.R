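#' Differential-expression filter
#'
#' Applies the fold-change / p-value thresholds used throughout the package:
#' a gene is over-expressed when its linear fold change exceeds
#' `fc_threshold` and under-expressed when it falls below `1/fc_threshold`,
#' in both cases at `p < p_threshold`. All inequalities are strict, so a gene
#' at exactly fold change 2 or exactly p = 0.05 is retained in neither set.
#'
#' @param records data.frame with columns `gene`, `fold_change`, `p_value`.
#'   Fold changes are linear case/control ratios; set `log2_input = TRUE` for
#'   log2 ratios.
#' @param fc_threshold linear fold-change threshold (> 1); default 2.
#' @param p_threshold p-value threshold; default 0.05.
#' @param log2_input are the fold changes log2-scaled?
#' @return list with character vectors `over` and `under` (disjoint by
#'   construction). Records with non-positive or missing fold change are
#'   rejected with a warning.
#' @export
de_filter <- function(records, fc_threshold = 2, p_threshold = 0.05,
                      log2_input = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("gene", "fold_change", "p_value") %in% names(records)),
            fc_threshold > 0, p_threshold > 0)
  fc <- as.numeric(records$fold_change)
  if (log2_input) {
    fc <- 2^fc
  }
  p <- as.numeric(records$p_value)
  bad <- is.na(fc) | fc <= 0 | is.na(p)
  if (any(bad)) {
    warning("rejecting ", sum(bad),
            " record(s) with non-positive or missing fold change/p-value")
    records <- records[!bad, , drop = FALSE]
    fc <- fc[!bad]
    p <- p[!bad]
  }
  gene <- normalize_symbols(records$gene)
  list(
    over = sort(unique(gene[fc > fc_threshold & p < p_threshold])),
    under = sort(unique(gene[fc < 1 / fc_threshold & p < p_threshold]))
  )
}

#' Expressed-gene filter on abundance records
#'
#' A gene counts as expressed when its abundance reaches the threshold
#' (inclusive; the conventional cut-off is TPM >= 2) in *at least one* of the
#' provided contexts (tissues/regions) — per-context thresholding followed by
#' a union. Per-context gene sets are attached as the `by_context` attribute.
#'
#' @param records data.frame with columns `gene`, `context`, `tpm`.
#' @param tpm_threshold abundance threshold (>= 0), inclusive; default 2.
#' @return character vector of expressed genes with attribute `by_context`
#'   (named list of per-context gene sets).
#' @export
expressed_filter <- function(records, tpm_threshold = 2) {
  stopifnot(is.data.frame(records),
            all(c("gene", "context", "tpm") %in% names(records)),
            tpm_threshold >= 0)
  tpm <- as.numeric(records$tpm)
  if (any(is.na(tpm) | tpm < 0)) {
    stop("tpm values must be non-negative")
  }
  gene <- normalize_symbols(records$gene)
  keep <- tpm >= tpm_threshold
  by_context <- lapply(split(gene[keep], records$context[keep]),
                       function(g) sort(unique(g)))
  structure(sort(unique(gene[keep])), by_context = by_context)
}

#' Overlap of a gene set with an interactome's nodes
#'
#' Intersects a differential-expression (or any other) gene set with the
#' node set of a network and scores it hypergeometrically, reporting also how
#' many of the shared genes are novel interactors of the network.
#'
#' @param net an `interactome`.
#' @param de_genes character vector of genes (e.g. the union of the `over`
#'   and `under` sets of [de_filter()]).
#' @param background_size assumed universe size (default 20,000).
#' @param roles node roles, defaulting to `classify_nodes(net)`.
#' @return an `overlap_report` (see [interactome_overlap()]).
#' @export
de_overlap_report <- function(net, de_genes, background_size = 20000,
                              roles = NULL) {
  stopifnot(inherits(net, "interactome"))
  if (is.null(roles)) {
    roles <- classify_nodes(net)
  }
  overlap_report(
    net$name, "gene set",
    interactome_nodes(net), unique(as.character(de_genes)),
    background_size,
    names(roles)[roles == "novel_interactor"]
  )
}
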