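# Level-1 ATC anatomical categories (letter -> standard name)
ATC_LEVEL1 <- c(
  A = "alimentary tract and metabolism",
  B = "blood and blood forming organs",
  C = "cardiovascular system",
  D = "dermatologicals",
  G = "genito-urinary system and sex hormones",
  H = "systemic hormonal preparations",
  J = "antiinfectives for systemic use",
  L = "antineoplastic and immunomodulating agents",
  M = "musculo-skeletal system",
  N = "nervous system",
  P = "antiparasitic products",
  R = "respiratory system",
  S = "sensory organs",
  V = "various"
)

#' Read a drug-target table
#'
#' Tab-separated columns `drug_id`, `drug_name`, `target_gene`, `atc_codes`
#' (`;`-separated, may be empty) and optionally `indications`
#' (`;`-separated). One row per drug-target pair.
#'
#' @param path input TSV.
#' @return data.frame in the above layout, genes normalized.
#' @export
read_drug_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", stringsAsFactors = FALSE)
  required <- c("drug_id", "drug_name", "target_gene", "atc_codes")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L) {
    stop("drug table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"indications" %in% names(tab)) {
    tab$indications <- ""
  }
  tab$target_gene <- normalize_symbols(tab$target_gene)
  tab
}

split_semi <- function(x) {
  toks <- trimws(strsplit(if (is.na(x) || !nzchar(x)) "" else x, ";",
                          fixed = TRUE)[[1L]])
  toks[nzchar(toks)]
}

#' Map drugs onto an interactome and stratify by target roles
#'
#' A drug is retained when at least one of its target genes is a node of the
#' network. Its stratum is decided by the roles of *all* its in-network
#' targets: `known_only` when every target is a seed or known interactor
#' (seeds count as known: they are established genes), `novel_only` when
#' every target is a novel interactor, and `both` otherwise.
#'
#' @param net an `interactome`.
#' @param drugs drug-target table (see [read_drug_table()]).
#' @param roles node roles, defaulting to `classify_nodes(net)`.
#' @return data.frame with one row per retained drug: `drug_id`,
#'   `drug_name`, `stratum`, list-columns `targets_in_net`, `atc_codes`,
#'   `indications`.
#' @export
map_drug_targets <- function(net, drugs, roles = NULL) {
  stopifnot(inherits(net, "interactome"), is.data.frame(drugs))
  if (is.null(roles)) {
    roles <- classify_nodes(net)
  }
  nodes <- names(roles)
  drugs$target_gene <- normalize_symbols(drugs$target_gene)
  per_drug <- split(seq_len(nrow(drugs)), drugs$drug_id)
  rows <- lapply(per_drug, function(idx) {
    targets <- unique(drugs$target_gene[idx])
    in_net <- sort(targets[targets %in% nodes])
    if (length(in_net) == 0L) {
      return(NULL)
    }
    r <- roles[in_net]
    novel <- r == "novel_interactor"
    stratum <- if (all(novel)) "novel_only"
               else if (any(novel)) "both"
               else "known_only"
    list(
      drug_id = drugs$drug_id[idx[1L]],
      drug_name = drugs$drug_name[idx[1L]],
      stratum = stratum,
      targets_in_net = in_net,
      atc_codes = sort(unique(unlist(lapply(drugs$atc_codes[idx],
                                            split_semi)))),
      indications = sort(unique(unlist(lapply(
        if (is.null(drugs$indications)) character() else drugs$indications[idx],
        split_semi))))
    )
  })
  rows <- Filter(Negate(is.null), rows)
  out <- data.frame(
    drug_id = vapply(rows, `[[`, character(1L), "drug_id"),
    drug_name = vapply(rows, `[[`, character(1L), "drug_name"),
    stratum = vapply(rows, `[[`, character(1L), "stratum"),
    stringsAsFactors = FALSE
  )
  out$targets_in_net <- lapply(rows, `[[`, "targets_in_net")
  out$atc_codes <- lapply(rows, `[[`, "atc_codes")
  out$indications <- lapply(rows, `[[`, "indications")
  rownames(out) <- NULL
  out
}

#' Drug counts per ATC level-1 category and target stratum
#'
#' Tabulates mapped drugs by the first letter of their ATC codes. A drug
#' carrying several codes counts once per *distinct* level-1 category (and
#' once per category even when several of its codes share the letter); drugs
#' with no ATC code fall into an `unclassified` bin. Within a category each
#' drug contributes to exactly one stratum, so strata sum to the category's
#' distinct-drug count.
#'
#' @param mapped output of [map_drug_targets()].
#' @return data.frame `category`, `category_name`, `stratum`, `n_drugs`,
#'   with attributes `n_drugs_total` (distinct drugs) and `n_genes_total`
#'   (distinct targeted in-network genes).
#' @export
atc_summary <- function(mapped) {
  stopifnot(is.data.frame(mapped))
  cats <- lapply(mapped$atc_codes, function(codes) {
    lv1 <- unique(toupper(substr(codes, 1L, 1L)))
    if (length(lv1) == 0L) "unclassified" else lv1
  })
  n <- lengths(cats)
  long <- data.frame(
    category = unlist(cats),
    stratum = rep(mapped$stratum, n),
    drug_id = rep(mapped$drug_id, n),
    stringsAsFactors = FALSE
  )
  long <- unique(long)
  counts <- as.data.frame(table(category = long$category,
                                stratum = factor(long$stratum,
                                                 levels = c("known_only",
                                                            "novel_only",
                                                            "both"))),
                          stringsAsFactors = FALSE)
  names(counts)[3L] <- "n_drugs"
  counts <- counts[order(counts$category, counts$stratum), , drop = FALSE]
  counts$category_name <- ifelse(
    counts$category %in% names(ATC_LEVEL1),
    ATC_LEVEL1[counts$category],
    counts$category
  )
  counts <- counts[, c("category", "category_name", "stratum", "n_drugs")]
  rownames(counts) <- NULL
  attr(counts, "n_drugs_total") <- length(unique(mapped$drug_id))
  attr(counts, "n_genes_total") <-
    length(unique(unlist(mapped$targets_in_net)))
  counts
}

#' Filter mapped drugs by indication
#'
#' Keeps drugs carrying at least one indication from the given list
#' (case-insensitive exact label matching; no ontology mapping).
#'
#' @param mapped output of [map_drug_targets()].
#' @param diseases character vector of indication labels.
#' @return the matching rows of `mapped`, with attribute `genes` (distinct
#'   in-network genes targeted by the matching drugs).
#' @export
filter_by_indication <- function(mapped, diseases) {
  stopifnot(is.data.frame(mapped))
  want <- tolower(trimws(as.character(diseases)))
  hit <- vapply(mapped$indications, function(ind) {
    any(tolower(ind) %in% want)
  }, logical(1L))
  out <- mapped[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genes") <- sort(unique(unlist(out$targets_in_net)))
  out
}
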