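#' Genes of a list present in two interactomes
#'
#' The triad intersection: members of `gene_list` (for example aging-related
#' genes) that occur in the node sets of *both* networks (for example a
#' disease interactome and the cilia interactome).
#'
#' @param gene_list character vector of gene symbols.
#' @param net_a,net_b `interactome` objects.
#' @return sorted character vector.
#' @export
triad_intersection <- function(gene_list, net_a, net_b) {
  stopifnot(inherits(net_a, "interactome"), inherits(net_b, "interactome"))
  genes <- unique(normalize_symbols(gene_list))
  sort(intersect(intersect(genes, interactome_nodes(net_a)),
                 interactome_nodes(net_b)))
}

#' Extract the subnetwork around a core gene set
#'
#' Collects, across one or more networks, every edge incident to a core gene.
#' The same unordered pair occurring in several networks appears once with
#' sources merged (known provenance takes precedence over novel). Each node
#' of the subnetwork is annotated with membership flags: whether it is a core
#' gene and which input networks it belongs to — the information needed to
#' render the classic three-way (e.g. disease / aging / seed-network)
#' figures.
#'
#' @param core non-empty character vector of core genes.
#' @param nets a single `interactome` or a list of them.
#' @return a `triad_subnetwork`: list with `core_genes`, `edges` (data.frame
#'   `a`, `b`, `provenance`, `source`) and `nodes` (data.frame with `gene`,
#'   `in_core` and one logical `in_<name>` column per network).
#' @export
extract_subnetwork <- function(core, nets) {
  if (length(core) == 0L) {
    stop("core gene set must be non-empty")
  }
  core <- sort(unique(normalize_symbols(core)))
  if (inherits(nets, "interactome")) {
    nets <- list(nets)
  }
  stopifnot(length(nets) > 0L,
            all(vapply(nets, inherits, logical(1L), "interactome")))
  net_names <- vapply(seq_along(nets), function(i) {
    nm <- nets[[i]]$name
    if (is.null(nm) || !nzchar(nm)) paste0("net", i) else nm
  }, character(1L))

  picked <- lapply(nets, function(net) {
    e <- net$edges
    e[e$a %in% core | e$b %in% core, , drop = FALSE]
  })
  edges <- do.call(rbind, picked)
  key <- paste(edges$a, edges$b, sep = "\r")
  if (nrow(edges) > 0L) {
    known_keys <- unique(key[edges$provenance == "known"])
    edges$provenance[key %in% known_keys] <- "known"
    src <- vapply(split(edges$source, key), function(s) {
      paste(sort(unique(s[nzchar(s)])), collapse = ";")
    }, character(1L))
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$source <- unname(src[paste(edges$a, edges$b, sep = "\r")])
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }

  genes <- sort(unique(c(core[core %in% unlist(lapply(nets, interactome_nodes))],
                         edges$a, edges$b)))
  nodes <- data.frame(gene = genes, in_core = genes %in% core,
                      stringsAsFactors = FALSE)
  for (i in seq_along(nets)) {
    nodes[[paste0("in_", make.names(net_names[i]))]] <-
      genes %in% interactome_nodes(nets[[i]])
  }
  structure(list(core_genes = core, edges = edges, nodes = nodes),
            class = "triad_subnetwork")
}

#' @export
print.triad_subnetwork <- function(x, ...) {
  cat("<triad subnetwork> ", length(x$core_genes), " core genes, ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Direction of an expression fold change
#'
#' Maps a linear fold change to `up` / `down` / `flat`: `up` when
#' `log2(fc) > flat_band`, `down` when `log2(fc) < -flat_band`, `flat`
#' otherwise. With the default `flat_band = 0` only a fold change of exactly
#' 1 is flat.
#'
#' @param fc positive numeric vector of linear fold changes.
#' @param flat_band half-width of the flat zone on the log2 scale (>= 0).
#' @return character vector in `c("up", "down", "flat")`.
#' @export
direction_from_fold_change <- function(fc, flat_band = 0) {
  fc <- as.numeric(fc)
  if (any(is.na(fc) | fc <= 0)) {
    stop("fold changes must be positive")
  }
  stopifnot(flat_band >= 0)
  lfc <- log2(fc)
  ifelse(lfc > flat_band, "up", ifelse(lfc < -flat_band, "down", "flat"))
}

#' Classify disease-versus-development expression direction
#'
#' For each gene, compares the direction of its disease fold change (e.g. AD
#' versus non-AD hippocampus) with the direction of its developmental fold
#' change (e.g. adult versus fetal expression) and assigns one of four
#' categories: `under_AD_over_aging` (down in disease, up in development),
#' `over_AD_under_aging` (up in disease, down in development),
#' `same_direction` (both up or both down), `unclassified` (either direction
#' flat). The first three categories partition the genes with two non-flat
#' directions.
#'
#' @param ad_fc,dev_fc positive numeric vectors of linear fold changes
#'   (recycled to a common length).
#' @param flat_band see [direction_from_fold_change()].
#' @param genes optional gene symbols for the rows.
#' @return data.frame with columns `gene` (if given), `ad_direction`,
#'   `aging_direction`, `category`.
#' @export
classify_direction <- function(ad_fc, dev_fc, flat_band = 0, genes = NULL) {
  n <- max(length(ad_fc), length(dev_fc))
  ad <- direction_from_fold_change(rep_len(ad_fc, n), flat_band)
  dev <- direction_from_fold_change(rep_len(dev_fc, n), flat_band)
  category <- rep("unclassified", n)
  category[ad == "down" & dev == "up"] <- "under_AD_over_aging"
  category[ad == "up" & dev == "down"] <- "over_AD_under_aging"
  category[ad == dev & ad != "flat"] <- "same_direction"
  out <- data.frame(ad_direction = ad, aging_direction = dev,
                    category = category, stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    out <- cbind(gene = normalize_symbols(rep_len(genes, n)), out,
                 stringsAsFactors = FALSE)
  }
  out
}

#' Developmental fold change from a two-point age series
#'
#' Computes, per gene, the ratio of its abundance at an "old" time point over
#' a "young" time point from a long-format age series — the two-time-point
#' comparison (e.g. 40 years versus 8 post-conceptional weeks) rather than a
#' trend fit. Genes with zero young-abundance have an undefined ratio; they
#' are excluded with a warning and listed in the `undefined_genes` attribute.
#'
#' @param series data.frame with columns `gene`, `age_label`, `abundance`.
#' @param young_label,old_label the two age labels to compare (both must be
#'   present in the series).
#' @return named numeric vector of fold changes (old/young), with attribute
#'   `undefined_genes`.
#' @export
dev_fold_change <- function(series, young_label, old_label) {
  stopifnot(is.data.frame(series),
            all(c("gene", "age_label", "abundance") %in% names(series)))
  for (lab in c(young_label, old_label)) {
    if (!lab %in% series$age_label) {
      stop("age label not present in the series: ", lab)
    }
  }
  gene <- normalize_symbols(series$gene)
  ab <- as.numeric(series$abundance)
  young <- tapply(ab[series$age_label == young_label],
                  gene[series$age_label == young_label], mean)
  old <- tapply(ab[series$age_label == old_label],
                gene[series$age_label == old_label], mean)
  shared <- sort(intersect(names(young), names(old)))
  fc <- setNames(as.numeric(old[shared]) / as.numeric(young[shared]), shared)
  undef <- shared[as.numeric(young[shared]) == 0]
  if (length(undef) > 0L) {
    warning("excluding ", length(undef),
            " gene(s) with zero abundance at ", young_label)
    fc <- fc[!names(fc) %in% undef]
  }
  attr(fc, "undefined_genes") <- undef
  fc
}
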