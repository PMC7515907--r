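#' Specification for the synthetic-data generators
#'
#' A validated parameter bundle shared by [gen_ppi_study()],
#' [gen_overlap_pair()], [gen_expression_study()] and
#' [gen_annotations_and_drugs()]. Generators are pure functions of the spec:
#' the same spec yields byte-identical outputs, and the caller's RNG state is
#' never disturbed.
#'
#' Defaults emulate the shape of a published cilia interactome study: a
#' 20,000-gene universe, 165 seed genes averaging about 6.1 known and 4.6
#' predicted interactions each, with about a third of the seeds lacking any
#' curated interaction; overlap geometry of 400- and 1,600-node networks
#' sharing 90 genes; 5% planted over- and under-expressed genes with fold
#' changes beyond 2.5x at p < 0.01; and an ATC mixture dominated by nervous,
#' respiratory and cardiovascular drugs.
#'
#' @param seed integer RNG seed.
#' @param n_background_genes universe size (symbolic genes `G00001`, ...).
#' @param n_seed_genes number of seed genes.
#' @param mean_known_degree,mean_novel_degree Poisson means of per-seed known
#'   and novel edge counts.
#' @param zero_known_fraction fraction of seeds forced to zero known edges
#'   (exactly `round(fraction * n_seed_genes)` seeds).
#' @param overlap_sizes node counts of the two networks of
#'   [gen_overlap_pair()].
#' @param planted_overlap number of genes shared by the pair.
#' @param de_over_fraction,de_under_fraction fractions of the universe
#'   planted as over/under-expressed.
#' @param fc_over_range,fc_under_range fold-change ranges of the planted
#'   genes (linear scale); planted p-values are drawn strictly below 0.01.
#' @param dev_same_fraction fraction of planted DE genes whose developmental
#'   fold change moves in the same direction as the disease fold change.
#' @param n_terms,term_size_range unplanted annotation terms: count and size
#'   range.
#' @param planted_term_size,planted_term_fraction size of the planted term
#'   and the fraction of the designated seed's partners it covers.
#' @param atc_mix named integer vector: drugs to plant per ATC level-1
#'   letter.
#' @param n_unclassified_drugs drugs without any ATC code.
#' @return an object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(seed = 1L,
                           n_background_genes = 20000L,
                           n_seed_genes = 165L,
                           mean_known_degree = 6.1,
                           mean_novel_degree = 4.6,
                           zero_known_fraction = 0.34,
                           overlap_sizes = c(400L, 1600L),
                           planted_overlap = 90L,
                           de_over_fraction = 0.05,
                           de_under_fraction = 0.05,
                           fc_over_range = c(2.5, 8),
                           fc_under_range = c(1 / 8, 1 / 2.5),
                           dev_same_fraction = 0.37,
                           n_terms = 50L,
                           term_size_range = c(10L, 100L),
                           planted_term_size = 20L,
                           planted_term_fraction = 0.8,
                           atc_mix = c(N = 10L, R = 5L, C = 5L),
                           n_unclassified_drugs = 2L) {
  spec <- list(
    seed = as.integer(seed),
    n_background_genes = as.integer(n_background_genes),
    n_seed_genes = as.integer(n_seed_genes),
    mean_known_degree = mean_known_degree,
    mean_novel_degree = mean_novel_degree,
    zero_known_fraction = zero_known_fraction,
    overlap_sizes = as.integer(overlap_sizes),
    planted_overlap = as.integer(planted_overlap),
    de_over_fraction = de_over_fraction,
    de_under_fraction = de_under_fraction,
    fc_over_range = fc_over_range,
    fc_under_range = fc_under_range,
    dev_same_fraction = dev_same_fraction,
    n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range),
    planted_term_size = as.integer(planted_term_size),
    planted_term_fraction = planted_term_fraction,
    atc_mix = atc_mix,
    n_unclassified_drugs = as.integer(n_unclassified_drugs)
  )
  fracs <- c(spec$zero_known_fraction, spec$de_over_fraction,
             spec$de_under_fraction, spec$dev_same_fraction,
             spec$planted_term_fraction)
  stopifnot(all(fracs >= 0 & fracs <= 1),
            spec$n_background_genes >= 1L,
            spec$n_seed_genes >= 1L,
            spec$n_seed_genes < spec$n_background_genes,
            spec$mean_known_degree >= 0, spec$mean_novel_degree >= 0,
            length(spec$overlap_sizes) == 2L,
            all(spec$overlap_sizes >= 1L),
            spec$planted_overlap >= 0L,
            spec$de_over_fraction + spec$de_under_fraction <= 1,
            all(spec$fc_over_range > 1), all(spec$fc_under_range < 1),
            all(spec$fc_under_range > 0),
            spec$planted_term_size >= 1L,
            spec$n_unclassified_drugs >= 0L)
  if (spec$planted_overlap > min(spec$overlap_sizes) - 1L) {
    stop("planted_overlap exceeds the smaller network's non-seed budget")
  }
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic spec> seed ", x$seed, ": ", x$n_seed_genes,
      " seeds over ", x$n_background_genes, " genes\n", sep = "")
  invisible(x)
}

# run expr with a private, seeded RNG stream; the caller's stream is restored
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed %% (.Machine$integer.max - 7L)))
  force(expr)
}

synthetic_genes <- function(n) {
  sprintf("G%05d", seq_len(n))
}

#' Generate a synthetic seed-centric PPI study
#'
#' Draws per-seed known and novel edge counts from Poisson distributions
#' around the spec's mean degrees (zero-truncated for seeds that must keep a
#' known edge), forces exactly `round(zero_known_fraction * n_seed_genes)`
#' seeds to zero known edges, and attaches each seed's partners as distinct
#' non-seed genes, so a seed's known and novel partner sets never collide and
#' per-seed counts are exact.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `seeds`, `known_edges`, `novel_edges` (edge
#'   data.frames), `background` (the gene universe) and `truth` — a list
#'   holding the per-seed summary (`per_seed`: data.frame `seed`, `k_known`,
#'   `n_novel` plus partner list-columns), the zero-known seed ids and edge
#'   totals.
#' @export
gen_ppi_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng(spec$seed, {
    genes <- synthetic_genes(spec$n_background_genes)
    seeds <- genes[seq_len(spec$n_seed_genes)]
    pool <- genes[-seq_len(spec$n_seed_genes)]
    n0 <- round(spec$zero_known_fraction * spec$n_seed_genes)
    zero_known <- sort(sample(seeds, n0))
    k_deg <- stats::rpois(spec$n_seed_genes, spec$mean_known_degree)
    k_deg <- pmax(k_deg, 1L)            # non-forced seeds keep >= 1 known edge
    k_deg[seeds %in% zero_known] <- 0L
    n_deg <- stats::rpois(spec$n_seed_genes, spec$mean_novel_degree)
    if (any(k_deg + n_deg > length(pool))) {
      stop("per-seed degree exceeds the non-seed universe; ",
           "increase n_background_genes or lower the mean degrees")
    }
    known_p <- vector("list", spec$n_seed_genes)
    novel_p <- vector("list", spec$n_seed_genes)
    for (i in seq_len(spec$n_seed_genes)) {
      draw <- sample(pool, k_deg[i] + n_deg[i])
      known_p[[i]] <- sort(draw[seq_len(k_deg[i])])
      novel_p[[i]] <- sort(draw[k_deg[i] + seq_len(n_deg[i])])
    }
    per_seed <- data.frame(seed = seeds, k_known = k_deg, n_novel = n_deg,
                           stringsAsFactors = FALSE)
    per_seed$known_partners <- known_p
    per_seed$novel_partners <- novel_p
    list(
      seeds = seeds,
      known_edges = ppi_edges(rep(seeds, k_deg), unlist(known_p),
                              source = "synthetic_known"),
      novel_edges = ppi_edges(rep(seeds, n_deg), unlist(novel_p),
                              source = "synthetic_pred"),
      background = genes,
      truth = list(
        per_seed = per_seed,
        zero_known_seeds = zero_known,
        n_known_edges = sum(k_deg),
        n_novel_edges = sum(n_deg)
      )
    )
  })
}

#' Generate two interactomes with a planted node overlap
#'
#' Builds two hub-and-spoke networks over disjoint exclusive gene blocks plus
#' a shared block of exactly `planted_overlap` genes present in both. In the
#' first network, half of the shared genes (rounded down) are attached by
#' novel edges — so the planted shared-novel count is known — and everything
#' else by known edges; the second network uses known edges only, mirroring a
#' disease network built from curated sources.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `net_a`, `net_b` (interactomes) and `truth` (shared
#'   genes, `n_shared`, `n_shared_novel`, the two node counts).
#' @export
gen_overlap_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng(spec$seed + 1L, {
    size_a <- spec$overlap_sizes[1L]
    size_b <- spec$overlap_sizes[2L]
    ov <- spec$planted_overlap
    genes <- synthetic_genes(spec$n_background_genes)
    need <- ov + (size_a - ov) + (size_b - ov)
    if (need > length(genes)) {
      stop("overlap geometry exceeds the gene universe")
    }
    shared <- if (ov > 0L) genes[seq_len(ov)] else character()
    excl_a <- genes[ov + seq_len(size_a - ov)]
    excl_b <- genes[ov + (size_a - ov) + seq_len(size_b - ov)]
    hub_a <- excl_a[1L]
    hub_b <- excl_b[1L]
    n_novel_shared <- ov %/% 2L
    novel_shared <- shared[seq_len(n_novel_shared)]
    known_shared <- setdiff(shared, novel_shared)
    net_a <- assemble_interactome(
      hub_a,
      known = ppi_edges(rep(hub_a, length(c(excl_a[-1L], known_shared))),
                        c(excl_a[-1L], known_shared),
                        source = "synthetic_known"),
      novel = ppi_edges(rep(hub_a, length(novel_shared)), novel_shared,
                        source = "synthetic_pred"),
      name = "net_a"
    )
    net_b <- assemble_interactome(
      hub_b,
      known = ppi_edges(rep(hub_b, length(c(excl_b[-1L], shared))),
                        c(excl_b[-1L], shared),
                        source = "synthetic_known"),
      name = "net_b"
    )
    list(
      net_a = net_a, net_b = net_b,
      truth = list(shared_genes = sort(shared), n_shared = ov,
                   n_shared_novel = n_novel_shared,
                   size_a = size_a, size_b = size_b)
    )
  })
}

#' Generate synthetic expression tables with planted differential expression
#'
#' Plants disjoint over- and under-expressed gene sets with fold changes
#' drawn inside the spec's ranges and p-values strictly below 0.01; all other
#' genes receive fold changes within (0.7, 1.4) and uniform p-values, so the
#' default thresholds (fold change beyond 2x at p < 0.05) recover the planted
#' sets exactly. A two-point age series is planted so that a chosen fraction
#' of the DE genes moves in the same direction developmentally and the rest
#' in the opposite direction, giving known direction-category counts. A
#' per-region abundance (TPM) table is drawn alongside.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `de_table` (`gene`, `fold_change`, `p_value`),
#'   `abundance_table` (`gene`, `context`, `tpm`), `age_series` (`gene`,
#'   `age_label`, `abundance`; labels `"8 pcw"` and `"40 yrs"`), and `truth`
#'   (planted `over`/`under` sets, per-DE-gene `category` data.frame,
#'   category counts, and the expressed-gene set implied by the TPM draws).
#' @export
gen_expression_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng(spec$seed + 2L, {
    genes <- synthetic_genes(spec$n_background_genes)
    n <- length(genes)
    n_over <- round(spec$de_over_fraction * n)
    n_under <- round(spec$de_under_fraction * n)
    de_idx <- sample(n, n_over + n_under)
    over <- sort(genes[de_idx[seq_len(n_over)]])
    under <- sort(genes[de_idx[n_over + seq_len(n_under)]])

    fc <- exp(stats::runif(n, log(0.7), log(1.4)))
    p <- stats::runif(n)
    fc[match(over, genes)] <- stats::runif(n_over, spec$fc_over_range[1L],
                                           spec$fc_over_range[2L])
    fc[match(under, genes)] <- stats::runif(n_under, spec$fc_under_range[1L],
                                            spec$fc_under_range[2L])
    p[match(c(over, under), genes)] <-
      stats::runif(n_over + n_under, 0, 0.009)
    de_table <- data.frame(gene = genes, fold_change = fc, p_value = p,
                           stringsAsFactors = FALSE)

    # developmental fold change: planted same/opposite direction per DE gene
    de_genes <- c(over, under)
    de_dir <- rep(c("up", "down"), c(n_over, n_under))
    n_same <- round(spec$dev_same_fraction * length(de_genes))
    same_idx <- sample(length(de_genes), n_same)
    is_same <- seq_along(de_genes) %in% same_idx
    dev_fc <- exp(stats::runif(n, log(0.8), log(1.25)))
    dev_up <- (de_dir == "up" & is_same) | (de_dir == "down" & !is_same)
    n_up <- sum(dev_up)
    dev_fc[match(de_genes[dev_up], genes)] <-
      stats::runif(n_up, spec$fc_over_range[1L], spec$fc_over_range[2L])
    dev_fc[match(de_genes[!dev_up], genes)] <-
      stats::runif(length(de_genes) - n_up,
                   spec$fc_under_range[1L], spec$fc_under_range[2L])

    category <- ifelse(is_same, "same_direction",
                       ifelse(de_dir == "up", "over_AD_under_aging",
                              "under_AD_over_aging"))
    young <- stats::runif(n, 2, 10)
    age_series <- data.frame(
      gene = rep(genes, 2L),
      age_label = rep(c("8 pcw", "40 yrs"), each = n),
      abundance = c(young, young * dev_fc),
      stringsAsFactors = FALSE
    )

    regions <- c("hippocampus", "frontal cortex", "cerebellum")
    tpm <- stats::rexp(n * length(regions), rate = 1 / 4)
    abundance_table <- data.frame(
      gene = rep(genes, length(regions)),
      context = rep(regions, each = n),
      tpm = tpm,
      stringsAsFactors = FALSE
    )
    expressed <- sort(unique(abundance_table$gene[abundance_table$tpm >= 2]))

    list(
      de_table = de_table,
      abundance_table = abundance_table,
      age_series = age_series,
      truth = list(
        over = over, under = under,
        directions = data.frame(gene = de_genes, de_direction = de_dir,
                                category = category,
                                stringsAsFactors = FALSE),
        category_counts = c(
          under_AD_over_aging = sum(category == "under_AD_over_aging"),
          over_AD_under_aging = sum(category == "over_AD_under_aging"),
          same_direction = sum(category == "same_direction")
        ),
        expressed = expressed
      )
    )
  })
}

#' Generate a synthetic annotation collection and drug-target table
#'
#' Plants one annotation term covering a chosen fraction of a designated
#' seed's network neighborhood (the seed with the most partners), embeds it
#' among random terms, and builds a drug table realizing the spec's ATC
#' mixture with strata cycled over known-only / novel-only / both target
#' roles. The first drug of every ATC category carries the indication label
#' `"MDD"` so indication filtering has a planted answer.
#'
#' @param spec a [synthetic_spec()].
#' @param study optionally, a pre-computed [gen_ppi_study()] result for the
#'   same spec (regenerated from the spec when omitted).
#' @return list with `annotations` (data.frame `term_id`, `term_name`,
#'   `gene`), `drugs` (drug-target table), `background`, `net` (the study
#'   interactome) and `truth` (planted term bookkeeping: term id, target
#'   seed, overlap `k`, term/neighborhood/background sizes; ATC counts per
#'   category and stratum; indication counts).
#' @export
gen_annotations_and_drugs <- function(spec, study = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(study)) {
    study <- gen_ppi_study(spec)
  }
  net <- assemble_interactome(study$seeds, study$known_edges,
                              study$novel_edges, name = "synthetic")
  roles <- classify_nodes(net)
  with_rng(spec$seed + 3L, {
    genes <- study$background
    ps <- study$truth$per_seed
    n_partners <- lengths(ps$known_partners) + lengths(ps$novel_partners)
    target_i <- which.max(n_partners)
    target_seed <- ps$seed[target_i]
    partners <- sort(unique(c(ps$known_partners[[target_i]],
                              ps$novel_partners[[target_i]])))
    n_hit <- min(round(spec$planted_term_fraction * length(partners)),
                 spec$planted_term_size, length(partners))
    hit <- sort(sample(partners, n_hit))
    filler <- sample(setdiff(genes, partners),
                     spec$planted_term_size - n_hit)
    planted_members <- sort(c(hit, filler))

    sizes <- sample(spec$term_size_range[1L]:spec$term_size_range[2L],
                    spec$n_terms, replace = TRUE)
    ann <- data.frame(
      term_id = c(rep("T0000", spec$planted_term_size),
                  rep(sprintf("T%04d", seq_len(spec$n_terms)), sizes)),
      gene = c(planted_members,
               unlist(lapply(sizes, function(s) sample(genes, s)))),
      stringsAsFactors = FALSE
    )
    ann$term_name <- paste("synthetic term", ann$term_id)
    ann <- unique(ann[, c("term_id", "term_name", "gene")])

    known_pool <- names(roles)[roles %in% c("seed", "known_interactor")]
    novel_pool <- names(roles)[roles == "novel_interactor"]
    mix <- spec$atc_mix
    strata_cycle <- c("known_only", "novel_only", "both")
    rows <- list()
    truth_atc <- list()
    drug_no <- 0L
    for (cat in names(mix)) {
      m <- mix[[cat]]
      if (m > 0L && length(novel_pool) == 0L) {
        stop("atc_mix requires novel-role targets but the network has none")
      }
      strata <- rep_len(strata_cycle, m)
      for (j in seq_len(m)) {
        drug_no <- drug_no + 1L
        id <- sprintf("D%04d", drug_no)
        targets <- switch(strata[j],
          known_only = sample(known_pool, 1L),
          novel_only = sample(novel_pool, 1L),
          both = c(sample(known_pool, 1L), sample(novel_pool, 1L))
        )
        rows[[length(rows) + 1L]] <- data.frame(
          drug_id = id,
          drug_name = paste0("drug_", id),
          target_gene = targets,
          atc_codes = sprintf("%s05AA%02d", cat, j),
          indications = if (j == 1L) "MDD" else "",
          stringsAsFactors = FALSE
        )
      }
      truth_atc[[cat]] <- data.frame(
        category = cat,
        stratum = strata_cycle,
        n_drugs = as.integer(table(factor(strata, levels = strata_cycle))),
        stringsAsFactors = FALSE
      )
    }
    for (j in seq_len(spec$n_unclassified_drugs)) {
      drug_no <- drug_no + 1L
      id <- sprintf("D%04d", drug_no)
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = id, drug_name = paste0("drug_", id),
        target_gene = sample(known_pool, 1L),
        atc_codes = "", indications = "",
        stringsAsFactors = FALSE
      )
    }
    drugs <- do.call(rbind, rows)
    list(
      annotations = ann,
      drugs = drugs,
      background = genes,
      net = net,
      truth = list(
        planted_term = list(term_id = "T0000", seed = target_seed,
                            k = n_hit, term_size = spec$planted_term_size,
                            n_partners = length(partners),
                            background_size = length(genes)),
        atc = if (length(truth_atc) > 0L) {
          do.call(rbind, c(truth_atc, list(make.row.names = FALSE)))
        } else {
          data.frame(category = character(), stratum = character(),
                     n_drugs = integer(), stringsAsFactors = FALSE)
        },
        n_unclassified = spec$n_unclassified_drugs,
        n_indication_mdd = sum(vapply(names(mix),
                                      function(cat) mix[[cat]] > 0L,
                                      logical(1L)))
      )
    )
  })
}
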