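test_that("the full 3x3 direction table maps to the right categories", {
  # with flat_band = 0.2, fc = 1.1 is flat; 2 is up; 0.4 is down
  fc_for <- c(up = 2, down = 0.4, flat = 1.1)
  expected <- rbind(
    c("up",   "up",   "same_direction"),
    c("up",   "down", "over_AD_under_aging"),
    c("up",   "flat", "unclassified"),
    c("down", "up",   "under_AD_over_aging"),
    c("down", "down", "same_direction"),
    c("down", "flat", "unclassified"),
    c("flat", "up",   "unclassified"),
    c("flat", "down", "unclassified"),
    c("flat", "flat", "unclassified")
  )
  for (i in seq_len(nrow(expected))) {
    call <- classify_direction(fc_for[[expected[i, 1]]],
                               fc_for[[expected[i, 2]]], flat_band = 0.2)
    expect_identical(call$ad_direction, expected[i, 1])
    expect_identical(call$aging_direction, expected[i, 2])
    expect_identical(call$category, expected[i, 3])
  }
})

test_that("direction calls behave at the exact boundary and reject bad fc", {
  expect_identical(direction_from_fold_change(1.0), "flat")
  expect_identical(direction_from_fold_change(c(1.8, 0.4)), c("up", "down"))
  expect_identical(direction_from_fold_change(1.1, flat_band = 0.2), "flat")
  expect_error(direction_from_fold_change(0), "positive")
  expect_error(classify_direction(-1, 2), "positive")
})

test_that("swapping the two fold changes swaps the opposite categories", {
  set.seed(13)
  fc1 <- exp(runif(50, -2, 2))
  fc2 <- exp(runif(50, -2, 2))
  fwd <- classify_direction(fc1, fc2)$category
  rev <- classify_direction(fc2, fc1)$category
  both_dir <- fwd != "unclassified"
  expect_identical(
    fwd[both_dir] == "over_AD_under_aging",
    rev[both_dir] == "under_AD_over_aging"
  )
  expect_identical(fwd[fwd == "same_direction"], rev[fwd == "same_direction"])
})

test_that("triad intersection keeps only genes present in both networks", {
  net_a <- assemble_interactome("A", known = ppi_edges(rep("A", 3),
                                                       c("X", "Y", "Z")))
  net_b <- assemble_interactome("B", known = ppi_edges(rep("B", 2),
                                                       c("Y", "Z")))
  expect_identical(triad_intersection(c("Y", "Z", "Q"), net_a, net_b),
                   c("Y", "Z"))
  expect_identical(triad_intersection(c("Q", "R"), net_a, net_b),
                   character())
  # planted triad: 30 of 200 listed genes placed in both nets
  listed <- sprintf("L%03d", 1:200)
  planted <- listed[1:30]
  na2 <- assemble_interactome("HA", known = ppi_edges(rep("HA", 60),
                                                      c(planted, listed[101:130])))
  nb2 <- assemble_interactome("HB", known = ppi_edges(rep("HB", 60),
                                                      c(planted, listed[131:160])))
  expect_identical(triad_intersection(listed, na2, nb2), sort(planted))
})

test_that("subnetwork extraction keeps core-incident edges and merges nets", {
  net1 <- assemble_interactome(c("A", "B"),
                               known = ppi_edges(c("B", "B"), c("X", "C")),
                               name = "one")
  net2 <- assemble_interactome("C",
                               novel = ppi_edges(c("C", "C"), c("B", "D")),
                               name = "two")
  sub <- extract_subnetwork("B", list(net1, net2))
  # only edges touching B; the B-C pair known in net1 and novel in net2
  # appears once, as known
  expect_equal(nrow(sub$edges), 2L)
  key <- paste(sub$edges$a, sub$edges$b)
  expect_setequal(key, c("B C", "B X"))
  expect_identical(sub$edges$provenance[key == "B C"], "known")
  expect_true(all(c("in_core", "in_one", "in_two") %in% names(sub$nodes)))
  expect_identical(sub$nodes$gene[sub$nodes$in_core], "B")
  expect_true(sub$nodes$in_two[sub$nodes$gene == "C"])
  expect_error(extract_subnetwork(character(), net1), "non-empty")
})

test_that("developmental fold changes come from the two labeled time points", {
  series <- data.frame(
    gene = c("A", "A", "B", "B", "C", "C"),
    age_label = rep(c("8 pcw", "40 yrs"), 3),
    abundance = c(2, 4, 5, 5, 0, 3)
  )
  expect_warning(fc <- dev_fold_change(series, "8 pcw", "40 yrs"),
                 "zero abundance")
  expect_equal(fc[["A"]], 2.0)
  expect_equal(fc[["B"]], 1.0)
  expect_false("C" %in% names(fc))
  expect_identical(attr(fc, "undefined_genes"), "C")
  expect_error(dev_fold_change(series, "8 pcw", "99 yrs"), "99 yrs")
})

test_that("generator direction categories are recovered by classification", {
  spec <- synthetic_spec(seed = 21, n_background_genes = 3000,
                         n_seed_genes = 30)
  ex <- gen_expression_study(spec)
  dev <- dev_fold_change(ex$age_series, "8 pcw", "40 yrs")
  de_genes <- ex$truth$directions$gene
  ad_fc <- ex$de_table$fold_change[match(de_genes, ex$de_table$gene)]
  calls <- classify_direction(ad_fc, dev[de_genes], genes = de_genes)
  counts <- table(calls$category)
  expect_equal(counts[["same_direction"]],
               ex$truth$category_counts[["same_direction"]])
  expect_equal(counts[["over_AD_under_aging"]],
               ex$truth$category_counts[["over_AD_under_aging"]])
  expect_equal(counts[["under_AD_over_aging"]],
               ex$truth$category_counts[["under_AD_over_aging"]])
  expect_identical(calls$category, ex$truth$directions$category)
})
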