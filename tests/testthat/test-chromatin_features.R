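test_that("motif presence frequency hits the trivial extremes", {
  pairs <- data.frame(tf = c("TF1", "TF1", "TF2"),
                      gene_id = c("g1", "g2", "g1"))
  none <- motif_table(data.frame(tf = character(), gene = character()))
  expect_identical(motif_presence_frequency(pairs, none)$frequency, 0)
  all_mot <- motif_table(data.frame(tf = pairs$tf, gene = pairs$gene_id))
  expect_identical(motif_presence_frequency(pairs, all_mot)$frequency, 1)
  some <- motif_table(data.frame(tf = "TF1", gene = "g2"))
  expect_equal(motif_presence_frequency(pairs, some)$frequency, 1 / 3)
})

test_that("occupancy profiles average position-wise and respect set structure", {
  occ <- matrix(1, 4, 500, dimnames = list(paste0("g", 1:4), NULL))
  prof <- promoter_occupancy_profile(c("g1", "g2"), occ)
  expect_identical(prof$profile, rep(1, 500))
  expect_identical(unname(prof$per_gene), c(1, 1))
  # single-gene profile equals that gene's track
  occ["g3", ] <- seq_len(500)
  expect_identical(promoter_occupancy_profile("g3", occ)$profile,
                   as.numeric(seq_len(500)))
  # union of disjoint sets = size-weighted mean of the two profiles
  set.seed(8)
  occ2 <- matrix(rnorm(6 * 500, 1, 0.2), 6, 500,
                 dimnames = list(paste0("h", 1:6), NULL))
  pa <- promoter_occupancy_profile(paste0("h", 1:2), occ2)$profile
  pb <- promoter_occupancy_profile(paste0("h", 3:6), occ2)$profile
  pu <- promoter_occupancy_profile(paste0("h", 1:6), occ2)$profile
  expect_equal(pu, (2 * pa + 4 * pb) / 6, tolerance = 1e-12)
  # unknown genes are skipped with a message
  expect_message(promoter_occupancy_profile(c("g1", "nope"), occ), "skipped")
  expect_error(promoter_occupancy_profile("nope", occ), "no gene")
})

test_that("promoter windows are oriented to transcription direction", {
  v <- as.numeric(1:500)
  expect_identical(orient_profile(v, "+"), v)
  expect_identical(orient_profile(v, "-"), rev(v))
  expect_error(orient_profile(v[-1], "+"))
})

test_that("planted occupancy offsets are recovered by the contrast", {
  sim <- simulate_dataset(fixture_config(planted_enrichment = 5, seed = 23))
  sar <- unique(unlist(sim$ground_truth$sar_genes, use.names = FALSE))
  bound <- unique(unlist(lapply(sim$regulons, function(r) r$bound$gene_id)))
  ct <- occupancy_contrast(setdiff(sar, bound), setdiff(bound, sar),
                           sim$occupancy, n_boot = 50, seed = 4)
  expect_gt(ct$median_a, ct$median_b)
  expect_lt(ct$p, 0.01)
  # planted offset = 0.5: SAR profile sits pointwise above the bound profile
  expect_true(all(attr(ct, "profile_a") > attr(ct, "profile_b") - 0.3))
})

test_that("binding-TF counts contrast detects a planted deficit", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:400)
  sar <- genes[1:200]
  other <- genes[201:400]
  counts <- c(rpois(200, 1), rpois(200, 4))
  tf_ids <- sprintf("TF%02d", 1:12)
  bound_lists <- lapply(tf_ids, function(tf) character(0))
  names(bound_lists) <- tf_ids
  for (i in seq_along(genes)) {
    k <- min(counts[i], length(tf_ids))
    if (k > 0) {
      for (tf in sample(tf_ids, k)) {
        bound_lists[[tf]] <- c(bound_lists[[tf]], genes[i])
      }
    }
  }
  regs <- lapply(tf_ids, function(tf) {
    toy_regulon(tf, bound = if (length(bound_lists[[tf]])) bound_lists[[tf]] else "gX",
                ko = "gY")
  })
  names(regs) <- tf_ids
  ct <- tf_count_contrast(sar, other, regs, n_boot = 50, seed = 5)
  expect_lt(ct$median_a, ct$median_b)
  expect_lt(ct$p, 1e-3)
  # a gene bound by nothing counts zero
  ct0 <- tf_count_contrast("unbound_gene", other, regs, n_boot = 10)
  expect_identical(ct0$values_a, 0L)
})

test_that("affinity contrast separates colocalized binding events and is rank-invariant", {
  g <- toy_genes()
  ints <- toy_interactions()
  adj <- build_coloc_adjacency(g, map_genes_to_segments(g, ints), ints)
  # bound g4 colocalizes with ko g1 (inter); bound g5 does not
  reg <- tf_regulon("TF1",
                    data.frame(gene_id = c("g4", "g5"),
                               binding_p = c(1e-5, 1e-3),
                               binding_score = c(5, 3), stringsAsFactors = FALSE),
                    c("g1", "g2"))
  cl <- list(TF1 = classify_sar(reg, adj))
  ct <- affinity_contrast(list(TF1 = reg), cl, n_boot = 10)
  expect_identical(ct$values_a, 5)
  expect_identical(ct$values_b, 3)

  # larger synthetic case: monotone transform of scores leaves P unchanged
  sim <- simulate_dataset(fixture_config(planted_enrichment = 5, seed = 29))
  regs <- filter_regulons(sim$regulons, sim$genes)
  ints2 <- filter_intra_by_separation(sim$interactions)
  adj2 <- build_coloc_adjacency(sim$genes,
                                map_genes_to_segments(sim$genes, ints2), ints2)
  cls <- classify_sar_all(regs, adj2)
  ct1 <- affinity_contrast(regs, cls, n_boot = 10, seed = 1)
  regs_t <- lapply(regs, function(r) {
    r$bound$binding_score <- exp(r$bound$binding_score)
    r
  })
  ct2 <- affinity_contrast(regs_t, cls, n_boot = 10, seed = 1)
  expect_equal(ct1$p, ct2$p)

  # planted score shift on colocalized events is recovered
  set.seed(33)
  regs_s <- lapply(names(regs), function(tf) {
    r <- regs[[tf]]
    coloc <- cls[[tf]]$bound$coloc_inter | cls[[tf]]$bound$coloc_intra
    r$bound$binding_score <- rnorm(nrow(r$bound)) + ifelse(coloc, 1.5, 0)
    r
  })
  names(regs_s) <- names(regs)
  ct3 <- affinity_contrast(regs_s, cls, n_boot = 10, seed = 2)
  expect_gt(ct3$median_a, ct3$median_b)
  expect_lt(ct3$p, 0.01)
})
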