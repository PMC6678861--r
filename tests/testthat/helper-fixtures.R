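# Small deterministic toys used across the unit tests.

toy_genes <- function() {
  gene_table(data.frame(
    gene_id = paste0("g", 1:6),
    chrom = rep(c("chr1", "chr2"), each = 3),
    strand = c("+", "-", "+", "-", "+", "-"),
    tss = rep(c(5000L, 75000L, 150000L), 2),
    stringsAsFactors = FALSE
  ))
}

# one segment centred on each toy gene TSS; contacts:
#   s1-s4 inter, s1-s3 intra (sep 145 kb), s2-s3 intra (sep 75 kb)
toy_interactions <- function(pairs = NULL) {
  segments <- data.frame(
    segment_id = paste0("s", 1:6),
    chrom = rep(c("chr1", "chr2"), each = 3),
    start = rep(c(4000L, 74000L, 149000L), 2),
    end = rep(c(6000L, 76000L, 151000L), 2),
    stringsAsFactors = FALSE
  )
  if (is.null(pairs)) {
    pairs <- data.frame(
      seg_a = c("s1", "s1", "s2"),
      seg_b = c("s4", "s3", "s3"),
      fdr = 1e-5,
      stringsAsFactors = FALSE
    )
  }
  interaction_set(segments, pairs, fdr_cutoff = 1e-4)
}

toy_regulon <- function(tf = "TF1", bound = "g3", ko = c("g1", "g2")) {
  tf_regulon(tf,
             data.frame(gene_id = bound, binding_p = 1e-4,
                        binding_score = 4, stringsAsFactors = FALSE),
             ko)
}

# random small instance for oracle-equivalence checks: genes on few
# chromosomes, arbitrary segments (overlapping, multi-mapping, unmapped
# genes all possible), random contact list, random regulon
random_instance <- function(seed) {
  set.seed(seed)
  n_genes <- sample(8:50, 1)
  n_chrom <- sample(2:4, 1)
  chroms <- paste0("chr", seq_len(n_chrom))
  genes <- gene_table(data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tss = sample.int(200000L, n_genes),
    stringsAsFactors = FALSE
  ))
  n_seg <- sample(6:30, 1)
  start <- sample.int(195000L, n_seg)
  segments <- data.frame(
    segment_id = sprintf("s%02d", seq_len(n_seg)),
    chrom = sample(chroms, n_seg, replace = TRUE),
    start = start,
    end = start + sample.int(5000L, n_seg),
    stringsAsFactors = FALSE
  )
  n_pair <- sample(5:100, 1)
  ia <- sample.int(n_seg, n_pair, replace = TRUE)
  ib <- sample.int(n_seg, n_pair, replace = TRUE)
  ok <- ia != ib
  pairs <- data.frame(seg_a = segments$segment_id[ia[ok]],
                      seg_b = segments$segment_id[ib[ok]],
                      fdr = runif(sum(ok), 0, 1e-4),
                      stringsAsFactors = FALSE)
  interactions <- interaction_set(segments, pairs, fdr_cutoff = 1e-4)
  ids <- sample(genes$gene_id)
  nb <- sample(2:4, 1)
  nk <- sample(2:4, 1)
  regulon <- tf_regulon("TFr",
                        data.frame(gene_id = ids[seq_len(nb)],
                                   binding_p = 1e-4, binding_score = 4,
                                   stringsAsFactors = FALSE),
                        ids[nb + seq_len(nk)])
  list(genes = genes, interactions = interactions, regulon = regulon)
}
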