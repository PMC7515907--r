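test_that("symbol normalization is idempotent and validates input", {
  x <- c(" ift88", "C14orf177", "bbs1 ")
  once <- normalize_symbols(x)
  expect_identical(normalize_symbols(once), once)
  expect_identical(once, c("IFT88", "C14ORF177", "BBS1"))
  expect_error(normalize_symbols(""), "empty")
  expect_error(normalize_symbols("A B"), "whitespace")
})

test_that("edge identity is unordered and self-loops are gated", {
  e1 <- ppi_edges("A", "B")
  e2 <- ppi_edges("B", "A")
  expect_identical(e1, e2)
  expect_error(ppi_edges("A", "A"), "self-loop")
  loop <- ppi_edges("A", "A", allow_self_loops = TRUE)
  expect_identical(loop$a, loop$b)
})

test_that("a pair in both known and novel inputs is stored once as known", {
  net <- assemble_interactome("A",
                              known = ppi_edges("A", "B", source = "HPRD"),
                              novel = ppi_edges("A", "B", source = "pred"))
  expect_equal(nrow(net$edges), 1L)
  expect_identical(net$edges$provenance, "known")
  expect_identical(net$edges$source, "HPRD;pred")
  expect_equal(attr(net, "n_confirmed"), 1L)
})

test_that("unordered duplicates within a source collapse to one edge", {
  net <- assemble_interactome("A",
                              novel = ppi_edges(c("A", "B"), c("B", "A")))
  expect_equal(nrow(net$edges), 1L)
  expect_identical(net$edges$provenance, "novel")
})

test_that("strict assembly rejects seedless edges; lenient drops and counts", {
  known <- ppi_edges(c("A", "C"), c("B", "D"))
  expect_error(assemble_interactome("A", known = known), "C-D")
  expect_message(
    net <- assemble_interactome("A", known = known, strict = FALSE),
    "dropping 1"
  )
  expect_equal(nrow(net$edges), 1L)
  expect_equal(attr(net, "n_dropped"), 1L)
  expect_error(assemble_interactome(character()), "non-empty")
})

test_that("assembly is order-independent", {
  set.seed(11)
  for (rep in 1:5) {
    seeds <- sprintf("S%02d", 1:4)
    ka <- sample(seeds, 20, replace = TRUE)
    kb <- sprintf("P%02d", sample(15, 20, replace = TRUE))
    na_ <- sample(seeds, 15, replace = TRUE)
    nb <- sprintf("P%02d", sample(15, 15, replace = TRUE))
    perm_k <- sample(20)
    perm_n <- sample(15)
    n1 <- assemble_interactome(seeds, ppi_edges(ka, kb), ppi_edges(na_, nb))
    n2 <- assemble_interactome(sample(seeds),
                               ppi_edges(ka[perm_k], kb[perm_k]),
                               ppi_edges(na_[perm_n], nb[perm_n]))
    expect_identical(n1$edges, n2$edges)
    expect_identical(n1$seeds, n2$seeds)
  }
})

test_that("node roles follow the any-known rule and partition the nodes", {
  net <- assemble_interactome("A", novel = ppi_edges("A", "B"))
  expect_identical(classify_nodes(net)[["B"]], "novel_interactor")

  # B touched by one known and one novel edge -> known interactor
  net2 <- assemble_interactome(c("A", "C"),
                               known = ppi_edges("A", "B"),
                               novel = ppi_edges("C", "B"))
  expect_identical(classify_nodes(net2)[["B"]], "known_interactor")

  set.seed(7)
  for (rep in 1:10) {
    net3 <- random_interactome(n_seeds = 4L, n_partners = 25L, n_edges = 50L)
    roles <- classify_nodes(net3)
    expect_setequal(names(roles), interactome_nodes(net3))
    counts <- table(factor(roles, c("seed", "known_interactor",
                                    "novel_interactor")))
    expect_equal(sum(counts), length(interactome_nodes(net3)))
    expect_equal(counts[["seed"]], length(net3$seeds))
    # every novel interactor needs at least one novel edge of its own
    expect_lte(counts[["novel_interactor"]],
               sum(net3$edges$provenance == "novel"))
  }
})

test_that("per-seed summaries count seed-seed edges once per incident seed", {
  star <- assemble_interactome("HUB",
                               novel = ppi_edges(rep("HUB", 4),
                                                 sprintf("P%d", 1:4)))
  s <- summarize_per_seed(star)
  expect_equal(s$k_known, 0L)
  expect_equal(s$n_novel, 4L)
  expect_identical(s$novel_partners[[1L]], sprintf("P%d", 1:4))

  net <- assemble_interactome(c("A", "B"),
                              known = ppi_edges("A", "B"),
                              novel = ppi_edges(c("A", "B"), c("X", "Y")))
  s2 <- summarize_per_seed(net)
  expect_equal(s2$k_known, c(1L, 1L))        # the A-B edge counts for both
  expect_equal(attr(s2, "total_known_edges"), 1L)
  expect_equal(attr(s2, "total_novel_edges"), 2L)
  expect_false("X" %in% s2$seed)             # non-seed nodes get no row
})

test_that("cross-referencing matches unordered pairs and merges labels", {
  novel <- ppi_edges(c("IFT57", "DYNLL2"), c("CLTA", "KIF2B"))
  ref <- data.frame(gene_a = c("CLTA", "IFT57", "AAA"),
                    gene_b = c("IFT57", "CLTA", "BBB"),
                    relation = c("part of the same complex", "complex",
                                 "other"))
  hits <- cross_reference_edges(novel, ref)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$a, "CLTA")
  expect_identical(hits$b, "IFT57")
  expect_identical(hits$relation, "complex; part of the same complex")
  expect_equal(nrow(cross_reference_edges(novel, ref[0, ])), 0L)
})
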