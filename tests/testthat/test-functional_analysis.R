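test_that("rank-sum P values match closed-form extremes and symmetry", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3)), 1)
  # complete separation at n = m = 20: far beyond 1e-6
  expect_lt(mann_whitney_u(1:20 + 100, 1:20), 1e-6)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
  # invariance under strictly monotone transforms
  set.seed(4)
  a <- rnorm(15)
  b <- rnorm(12, 0.5)
  expect_equal(mann_whitney_u(a, b), mann_whitney_u(exp(a), exp(b)))
})

test_that("small tie-free samples are handled by exact enumeration", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(1:8, 1)
    m <- sample(1:8, 1)
    a <- rnorm(n)
    b <- rnorm(m)
    expect_equal(mann_whitney_u(a, b), mwu_enumerated(a, b), tolerance = 1e-12)
  }
})

test_that("cellular co-component counts pairs through shared-complex binders", {
  cc <- annotation_set("CC", list(CC1 = c("TF1", "TF2"), CC2 = c("TF3")))
  regs <- list(
    TF1 = toy_regulon("TF1", bound = "g1", ko = "g2"),
    TF2 = toy_regulon("TF2", bound = "g2", ko = "g1"),
    TF3 = toy_regulon("TF3", bound = "g3", ko = "g4")
  )
  # (TF1, g2): TF2 binds g2 and shares CC1 with TF1 -> counted
  # (TF3, g4): no other TF binds g4 -> not counted
  f <- cc_cocomponent_frequency(
    data.frame(tf = c("TF1", "TF3"), gene_id = c("g2", "g4")), regs, cc)
  expect_identical(c(f$numerator, f$denominator), c(1L, 2L))
  # the permutation statistic closure agrees with the direct computation
  g <- toy_genes()
  stat <- make_cc_statistic(regs, cc, g, tf_subset = c("TF1", "TF3"))
  expect_equal(stat(list(match("g2", g$gene_id), match("g4", g$gene_id)), NULL),
               f$frequency)
})

test_that("biological co-process frequency follows planted term sharing", {
  bp <- annotation_set("BP", list(BP1 = c("gb", "k1"), BP2 = "k2"))
  regs <- list(TF1 = toy_regulon("TF1", bound = "gb", ko = c("k1", "k2", "k3")))
  f <- bp_coprocess_frequency(
    data.frame(tf = "TF1", gene_id = c("k1", "k2", "k3")), regs, bp)
  # k1 shares BP1 with the bound gene; k2 has a term but not shared; k3 none
  expect_identical(c(f$numerator, f$denominator), c(1L, 3L))
})

test_that("co-membership frequencies never decrease when annotation coverage grows", {
  set.seed(11)
  genes <- sprintf("g%02d", 1:20)
  regs <- list(TF1 = toy_regulon("TF1", bound = genes[1:4], ko = genes[5:10]),
               TF2 = toy_regulon("TF2", bound = genes[11:14], ko = genes[15:20]))
  pairs <- data.frame(tf = rep(c("TF1", "TF2"), each = 3),
                      gene_id = c(genes[5:7], genes[15:17]))
  for (i in 1:10) {
    terms <- lapply(1:4, function(j) sample(genes, sample(2:6, 1)))
    names(terms) <- paste0("BP", 1:4)
    base <- annotation_set("BP", terms)
    grown <- annotation_set("BP", c(terms, list(BPX = genes)))
    expect_gte(bp_coprocess_frequency(pairs, regs, grown)$frequency,
               bp_coprocess_frequency(pairs, regs, base)$frequency)
    cc_base <- annotation_set("CC", c(terms, list(T1 = "TF1")))
    cc_grown <- annotation_set("CC", c(terms, list(T1 = "TF1"),
                                       list(ALL = c("TF1", "TF2", genes))))
    expect_gte(cc_cocomponent_frequency(pairs, regs, cc_grown)$frequency,
               cc_cocomponent_frequency(pairs, regs, cc_base)$frequency)
  }
})

test_that("correlation groups behave like Pearson r and detect planted blocks", {
  # identical rows correlate at exactly 1; affine transforms leave r unchanged
  expr <- matrix(rnorm(5 * 20), 5, 20,
                 dimnames = list(c("b1", "k1", "k2", "b2", "k3"), NULL))
  expr["k1", ] <- expr["b1", ]
  expr["k2", ] <- 3 * expr["b1", ] + 2
  regs <- list(TF1 = toy_regulon("TF1", bound = c("b1", "b2"),
                                 ko = c("k1", "k2", "k3")))
  ct <- coexpression_contrast(
    data.frame(tf = "TF1", gene_id = c("k1", "k2")),
    data.frame(tf = "TF1", gene_id = "k3"),
    regs, expr, n_boot = 50, seed = 1)
  r_b1 <- ct$values_a[1:2]  # k1 x b1, k2 x b1 (column-major over bound)
  expect_equal(unname(r_b1), c(1, 1))

  # planted latent blocks: SAR genes correlate with bound genes, non-SAR do not
  sim <- simulate_dataset(fixture_config(planted_enrichment = 5, seed = 17))
  regs2 <- filter_regulons(sim$regulons, sim$genes)
  ints <- filter_intra_by_separation(sim$interactions)
  adj <- build_coloc_adjacency(sim$genes, map_genes_to_segments(sim$genes, ints), ints)
  tabs <- sar_pair_tables(classify_sar_all(regs2, adj))
  ct2 <- coexpression_contrast(tabs$sar, tabs$nonsar, regs2, sim$expr,
                               n_boot = 50, seed = 2)
  expect_gt(ct2$median_a, ct2$median_b)
  expect_lt(ct2$p, 0.05)
})

test_that("pairs with too few shared conditions are skipped", {
  expr <- matrix(NA_real_, 2, 10, dimnames = list(c("b1", "k1"), NULL))
  expr["b1", 1:6] <- rnorm(6)
  expr["k1", 5:10] <- rnorm(6)   # only 2 shared conditions with b1
  regs <- list(TF1 = toy_regulon("TF1", bound = "b1", ko = "k1"))
  ct <- coexpression_contrast(data.frame(tf = "TF1", gene_id = "k1"),
                              data.frame(tf = character(), gene_id = character()),
                              regs, expr, n_boot = 10)
  expect_identical(length(ct$values_a), 0L)
  expect_identical(attr(ct, "n_skipped"), 1L)
})

test_that("degenerate contrasts return the no-contrast sentinel", {
  ct <- contrast_result(rep(1, 5), rep(1, 7))
  expect_true(is.na(ct$p))
  expect_match(ct$note, "identical")
  ct2 <- contrast_result(numeric(0), rnorm(5))
  expect_true(is.na(ct2$p))
  expect_match(ct2$note, "empty")
})

test_that("expression variability is rank-invariant under scaling", {
  expr <- matrix(rnorm(40 * 10), 40, 10,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  expr["g01", ] <- 5  # constant row
  a <- sprintf("g%02d", 1:20)
  b <- sprintf("g%02d", 21:40)
  ct <- expression_variability_contrast(a, b, expr, n_boot = 50, seed = 3)
  expect_identical(unname(ct$values_a[1]), 0)
  ct2 <- expression_variability_contrast(a, b, 2 * expr, n_boot = 50, seed = 3)
  expect_equal(ct2$values_a, 2 * ct$values_a)
  expect_equal(ct2$p, ct$p)
})

test_that("bootstrap intervals bracket the sample median and cover the truth", {
  set.seed(21)
  x <- rnorm(30)
  ci <- bootstrap_median_ci(x, n_boot = 500, seed = 9)
  expect_lte(ci[1], stats::median(x))
  expect_gte(ci[2], stats::median(x))
  # coverage of the true median over repeated sampling, within 5 points of nominal
  covered <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    y <- rnorm(30)
    ci <- bootstrap_median_ci(y, n_boot = 200, seed = 6000 + i)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})
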