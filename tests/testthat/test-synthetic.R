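small_spec <- function(seed = 4) {
  synthetic_spec(seed = seed, n_background_genes = 2500, n_seed_genes = 40)
}

test_that("generators are pure functions of the spec", {
  spec <- small_spec()
  expect_identical(gen_ppi_study(spec), gen_ppi_study(spec))
  expect_identical(gen_overlap_pair(spec), gen_overlap_pair(spec))
  expect_identical(gen_expression_study(spec), gen_expression_study(spec))
  expect_identical(gen_annotations_and_drugs(spec),
                   gen_annotations_and_drugs(spec))
  # and leave the caller's RNG stream alone
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(gen_ppi_study(spec))
  expect_identical(runif(1), before)
})

test_that("the PPI generator honors the zero-known contract", {
  spec <- small_spec()
  st <- gen_ppi_study(spec)
  ps <- st$truth$per_seed
  expect_equal(sum(ps$k_known == 0), round(0.34 * 40))
  expect_setequal(ps$seed[ps$k_known == 0], st$truth$zero_known_seeds)

  all_novel <- synthetic_spec(seed = 4, n_background_genes = 2500,
                              n_seed_genes = 40, zero_known_fraction = 1)
  st2 <- gen_ppi_study(all_novel)
  expect_equal(nrow(st2$known_edges), 0L)
  expect_gt(nrow(st2$novel_edges), 0L)

  expect_error(
    gen_ppi_study(synthetic_spec(n_background_genes = 30, n_seed_genes = 20,
                                 mean_known_degree = 40)),
    "exceeds"
  )
})

test_that("per-seed summaries of a generated study reproduce the truth", {
  st <- gen_ppi_study(small_spec())
  net <- assemble_interactome(st$seeds, st$known_edges, st$novel_edges)
  s <- summarize_per_seed(net)
  expect_identical(s$seed, sort(st$truth$per_seed$seed))
  ord <- match(s$seed, st$truth$per_seed$seed)
  expect_equal(s$k_known, st$truth$per_seed$k_known[ord])
  expect_equal(s$n_novel, st$truth$per_seed$n_novel[ord])
  expect_identical(s$novel_partners, st$truth$per_seed$novel_partners[ord])
  expect_equal(attr(s, "total_known_edges"), st$truth$n_known_edges)
  expect_equal(attr(s, "total_novel_edges"), st$truth$n_novel_edges)
})

test_that("the overlap-pair generator plants node overlap exactly", {
  zero <- synthetic_spec(seed = 2, planted_overlap = 0)
  pz <- gen_overlap_pair(zero)
  ovz <- interactome_overlap(pz$net_a, pz$net_b, 20000)
  expect_equal(length(ovz$shared_genes), 0L)
  expect_equal(ovz$p_value, 1)

  spec <- synthetic_spec(seed = 2, planted_overlap = 90)
  pair <- gen_overlap_pair(spec)
  expect_equal(length(interactome_nodes(pair$net_a)), 400L)
  expect_equal(length(interactome_nodes(pair$net_b)), 1600L)
  ov <- interactome_overlap(pair$net_a, pair$net_b, 20000)
  expect_identical(ov$shared_genes, pair$truth$shared_genes)
  expect_equal(length(ov$shared_novel), pair$truth$n_shared_novel)
  expect_lt(ov$p_value, 1e-6)

  expect_error(synthetic_spec(planted_overlap = 500,
                              overlap_sizes = c(400, 1600)),
               "budget")
})

test_that("expression truths are sufficient without rerunning the generator", {
  ex <- gen_expression_study(small_spec())
  de <- de_filter(ex$de_table)
  expect_identical(de$over, ex$truth$over)
  expect_identical(de$under, ex$truth$under)
  expect_identical(as.character(expressed_filter(ex$abundance_table)),
                   ex$truth$expressed)
  # zero planted fractions give empty DE sets
  none <- synthetic_spec(seed = 4, n_background_genes = 500,
                         n_seed_genes = 10, de_over_fraction = 0,
                         de_under_fraction = 0)
  de0 <- de_filter(gen_expression_study(none)$de_table)
  expect_length(de0$over, 0L)
  expect_length(de0$under, 0L)
})

test_that("the planted annotation term is recovered and calibratable", {
  spec <- small_spec()
  ad <- gen_annotations_and_drugs(spec)
  info <- ad$truth$planted_term
  res <- neighborhood_enrichment(ad$net, info$seed, ad$annotations,
                                 background = ad$background)
  plant <- res[res$term_id == info$term_id, ]
  expect_equal(plant$overlap_count, info$k)
  # the truth record alone predicts the p-value
  expect_equal(plant$p_value,
               oracle_tail_count(info$k, info$term_size, info$n_partners,
                                 info$background_size),
               tolerance = 1e-12)
  expect_true(plant$enriched)

  # planting at the background rate must not be flagged: one hit out of a
  # large term over a small neighborhood is unremarkable
  flat <- synthetic_spec(seed = 4, n_background_genes = 2500,
                         n_seed_genes = 40, planted_term_fraction = 0.05,
                         planted_term_size = 100)
  ad2 <- gen_annotations_and_drugs(flat)
  res2 <- neighborhood_enrichment(ad2$net, ad2$truth$planted_term$seed,
                                  ad2$annotations,
                                  background = ad2$background)
  plant2 <- res2[res2$term_id == "T0000", ]
  if (nrow(plant2) > 0) {
    expect_false(plant2$enriched)
  }
  expect_gte(oracle_tail_count(ad2$truth$planted_term$k, 100,
                               ad2$truth$planted_term$n_partners, 2500),
             0.05)
})

test_that("an empty ATC mixture populates only the unclassified bin", {
  spec <- synthetic_spec(seed = 4, n_background_genes = 2500,
                         n_seed_genes = 40, atc_mix = integer(0),
                         n_unclassified_drugs = 3)
  ad <- gen_annotations_and_drugs(spec)
  s <- atc_summary(map_drug_targets(ad$net, ad$drugs))
  expect_identical(unique(s$category), "unclassified")
  expect_equal(sum(s$n_drugs), 3L)
})
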