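# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain double loops over data frames.

# segments within the TSS window of a gene, computed by direct scan
naive_gene_segments <- function(gene_id, genes, segments, window = 2500) {
  g <- genes[genes$gene_id == gene_id, ]
  hits <- character(0)
  for (i in seq_len(nrow(segments))) {
    if (segments$chrom[i] != g$chrom) next
    d <- if (g$tss < segments$start[i]) {
      segments$start[i] - g$tss
    } else if (g$tss > segments$end[i]) {
      g$tss - segments$end[i]
    } else 0
    if (d <= window) hits <- c(hits, segments$segment_id[i])
  }
  hits
}

naive_colocalized <- function(gene_a, gene_b, genes, interactions, mode,
                              window = 2500) {
  sa <- naive_gene_segments(gene_a, genes, interactions$segments, window)
  sb <- naive_gene_segments(gene_b, genes, interactions$segments, window)
  pr <- interactions$pairs
  for (i in seq_len(nrow(pr))) {
    if (pr$kind[i] != mode) next
    if ((pr$seg_a[i] %in% sa && pr$seg_b[i] %in% sb) ||
        (pr$seg_a[i] %in% sb && pr$seg_b[i] %in% sa)) {
      return(TRUE)
    }
  }
  FALSE
}

# full SAR classification by double loop over (ko gene, bound gene)
naive_classify <- function(regulon, genes, interactions, window = 2500) {
  ko <- regulon$ko_affected
  bound <- regulon$bound$gene_id
  res <- data.frame(gene_id = ko, coloc_inter = FALSE, coloc_intra = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ko)) {
    for (b in bound) {
      if (!res$coloc_inter[i] &&
          naive_colocalized(ko[i], b, genes, interactions, "inter", window)) {
        res$coloc_inter[i] <- TRUE
      }
      if (!res$coloc_intra[i] &&
          naive_colocalized(ko[i], b, genes, interactions, "intra", window)) {
        res$coloc_intra[i] <- TRUE
      }
    }
  }
  res
}

# exact two-sided rank-sum P by exhaustive enumeration of all rank
# assignments (tie-free inputs); mirrors the usual doubling convention
mwu_enumerated <- function(a, b) {
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  all_ranks <- seq_len(n + m)
  u_all <- apply(combos, 2, function(idx) sum(all_ranks[idx]) - n * (n + 1) / 2)
  if (u_obs > n * m / 2) {
    p1 <- mean(u_all >= u_obs)
  } else {
    p1 <- mean(u_all <= u_obs)
  }
  min(1, 2 * p1)
}
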