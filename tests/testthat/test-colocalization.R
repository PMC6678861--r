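test_that("gene-segment mapping uses nearest-point distance on the same chromosome", {
  g <- gene_table(data.frame(gene_id = c("ga", "gb", "gc"),
                             chrom = c("chr1", "chr1", "chr2"),
                             strand = "+",
                             tss = c(5000L, 7000L, 5000L)))
  segs <- data.frame(segment_id = c("sA", "sB"),
                     chrom = c("chr1", "chr2"),
                     start = c(6000L, 6000L), end = c(8000L, 8000L))
  ints <- interaction_set(segs, data.frame(seg_a = "sA", seg_b = "sB", fdr = 1e-5))
  map <- map_genes_to_segments(g, ints, tss_window_bp = 2500)
  expect_identical(map$map$ga, "sA")      # gap 1000 <= 2500
  expect_identical(map$map$gb, "sA")      # TSS inside the interval
  expect_identical(map$map$gc, "sB")      # same coordinates, own chromosome only
  tight <- map_genes_to_segments(g, ints, tss_window_bp = 999)
  expect_identical(tight$map$ga, character(0))  # gap 1000 > 999
  expect_identical(tight$map$gb, "sA")          # containment maps at any window
})

test_that("intra separation filter keeps >= 60 kb midpoint distances only", {
  segs <- data.frame(segment_id = c("x1", "x2", "x3", "y1"),
                     chrom = c("chr1", "chr1", "chr1", "chr2"),
                     start = c(9500L, 68500L, 69500L, 1000L),
                     end = c(10500L, 69500L, 70500L, 2000L))
  pairs <- data.frame(seg_a = c("x1", "x1", "x1"),
                      seg_b = c("x2", "x3", "y1"),
                      fdr = 1e-5)
  ints <- interaction_set(segs, pairs)
  out <- filter_intra_by_separation(ints, min_sep_bp = 60000)
  # midpoints 10000 vs 69000 (59 kb apart): removed; 10000 vs 70000: kept
  expect_identical(sort(paste(out$pairs$seg_a, out$pairs$seg_b)),
                   sort(c("x1 x3", "x1 y1")))
  # inter pair untouched at any cutoff
  huge <- filter_intra_by_separation(ints, min_sep_bp = 1e9)
  expect_identical(huge$pairs$kind, "inter")
})

test_that("colocalization needs two distinct interacting segments", {
  g <- toy_genes()
  ints <- toy_interactions()
  map <- map_genes_to_segments(g, ints)
  expect_true(genes_colocalized("g1", "g4", map, ints, "inter"))
  expect_false(genes_colocalized("g1", "g4", map, ints, "intra"))
  expect_true(genes_colocalized("g1", "g3", map, ints, "intra"))

  # both genes on the same single segment, no pair: not colocalized
  g2 <- gene_table(data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                              strand = "+", tss = c(5000L, 5500L, 150000L)))
  ints2 <- toy_interactions()
  map2 <- map_genes_to_segments(g2, ints2)
  expect_identical(map2$map$a, map2$map$b)
  expect_false(genes_colocalized("a", "b", map2, ints2, "either"))

  # gene with empty segment set is never colocalized
  g3 <- gene_table(data.frame(gene_id = c("far", "g4"), chrom = c("chr1", "chr2"),
                              strand = "+", tss = c(50000L, 5000L)))
  map3 <- map_genes_to_segments(g3, ints2)
  expect_identical(map3$map$far, character(0))
  expect_false(genes_colocalized("far", "g4", map3, ints2, "either"))
})

test_that("classify_sar flags knockout genes colocalized with any bound gene", {
  g <- toy_genes()
  ints <- toy_interactions()
  map <- map_genes_to_segments(g, ints)
  adj <- build_coloc_adjacency(g, map, ints)
  cl <- classify_sar(toy_regulon(bound = "g4", ko = c("g1", "g2")), adj)
  expect_identical(cl$sar_genes, "g1")       # via s1-s4 inter contact
  expect_identical(cl$nonsar_genes, "g2")
  expect_true(cl$ko$coloc_inter[cl$ko$gene_id == "g1"])
  expect_false(cl$ko$coloc_intra[cl$ko$gene_id == "g1"])
  expect_identical(cl$partners$bound_gene, "g4")
  expect_identical(cl$partners$ko_gene, "g1")

  # no interactions at all: every knockout gene is non-SAR
  empty <- toy_interactions(pairs = data.frame(seg_a = "s1", seg_b = "s4",
                                               fdr = 1)[0, ])
  adj0 <- build_coloc_adjacency(g, map_genes_to_segments(g, empty), empty)
  cl0 <- classify_sar(toy_regulon(bound = "g4", ko = c("g1", "g2")), adj0)
  expect_identical(length(cl0$sar_genes), 0L)
})

test_that("pooled frequency counts pairs in both directions", {
  g <- toy_genes()
  ints <- toy_interactions()
  adj <- build_coloc_adjacency(g, map_genes_to_segments(g, ints), ints)
  cl <- list(classify_sar(toy_regulon(bound = "g4", ko = c("g1", "g2")), adj))
  f <- pooled_frequency(cl, "ko_vs_bound", "inter")
  expect_identical(c(f$numerator, f$denominator), c(1L, 2L))
  expect_identical(f$frequency, 0.5)
  fb <- pooled_frequency(cl, "bound_vs_ko", "inter")
  expect_identical(c(fb$numerator, fb$denominator), c(1L, 1L))
  expect_error(pooled_frequency(list(), "ko_vs_bound", "inter"))
  expect_error(frequency_result("d", "m", 3, 2))
})

test_that("partner counts match enumeration and are symmetric in total", {
  # b1 colocalized with k1 and k2: bound-side count {b1: 2}, ko-side {1, 1}
  g <- gene_table(data.frame(gene_id = c("b1", "k1", "k2"),
                             chrom = c("chr1", "chr2", "chr3"),
                             strand = "+", tss = 5000L))
  segs <- data.frame(segment_id = c("sb", "sk1", "sk2"),
                     chrom = c("chr1", "chr2", "chr3"),
                     start = 4000L, end = 6000L)
  ints <- interaction_set(segs, data.frame(seg_a = c("sb", "sb"),
                                           seg_b = c("sk1", "sk2"), fdr = 1e-5))
  adj <- build_coloc_adjacency(g, map_genes_to_segments(g, ints), ints)
  cl <- list(classify_sar(tf_regulon("TF1",
                                     data.frame(gene_id = "b1", binding_p = 1e-3,
                                                binding_score = 3,
                                                stringsAsFactors = FALSE),
                                     c("k1", "k2")), adj))
  ko_side <- partner_count_summary(cl, "ko_vs_bound")
  b_side <- partner_count_summary(cl, "bound_vs_ko")
  expect_identical(ko_side$counts$n_partners, c(1, 1))
  expect_identical(b_side$counts$n_partners, 2)
  expect_identical(ko_side$total_pairs, b_side$total_pairs)
})

test_that("adding interactions never lowers frequencies; stricter separation never raises intra", {
  for (seed in c(3, 11, 27)) {
    inst <- random_instance(seed)
    reg <- inst$regulon
    base_ints <- inst$interactions
    freq_of <- function(ints, mode, min_sep = 0) {
      ints <- filter_intra_by_separation(ints, min_sep_bp = min_sep)
      adj <- build_coloc_adjacency(inst$genes,
                                   map_genes_to_segments(inst$genes, ints), ints)
      pooled_frequency(list(classify_sar(reg, adj)), "ko_vs_bound", mode)$frequency
    }
    # add every remaining segment pair as a contact
    segs <- base_ints$segments$segment_id
    all_pairs <- expand.grid(seg_a = segs, seg_b = segs, stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$seg_a < all_pairs$seg_b, ]
    all_pairs$fdr <- 1e-5
    richer <- interaction_set(base_ints$segments,
                              rbind(base_ints$pairs[c("seg_a", "seg_b", "fdr")],
                                    all_pairs))
    for (mode in c("inter", "intra", "either")) {
      expect_gte(freq_of(richer, mode), freq_of(base_ints, mode))
    }
    expect_lte(freq_of(base_ints, "intra", min_sep = 50000),
               freq_of(base_ints, "intra", min_sep = 10000))
  }
})
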