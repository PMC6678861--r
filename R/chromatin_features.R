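#' Motif presence frequency of a (TF, gene) pair set
#'
#' Fraction of pairs for which the TF's DNA motif is present in the gene's
#' promoter. Comparing SAR and non-SAR pair sets asks whether SAR genes
#' simply lack the sequence signal for direct binding.
#'
#' @param pairs data.frame with columns `tf`, `gene_id`
#' @param motifs a [motif_table()]
#' @return A [frequency_result()].
#' @export
motif_presence_frequency <- function(pairs, motifs) {
  if (nrow(pairs) == 0) stop("no pairs: zero denominator")
  hit <- has_motif(motifs, pairs$tf, pairs$gene_id)
  frequency_result("pairs", "motif_presence", sum(hit), nrow(pairs))
}

#' Average promoter nucleosome occupancy profile of a gene set
#'
#' Position-wise mean occupancy over the 500 promoter positions
#' \eqn{[-500, -1]} upstream of the TSS in transcription direction (tracks
#' are stored strand-oriented, so the last position abuts the TSS), plus a
#' per-gene scalar mean. Genes without a track are skipped with a message.
#'
#' @param gene_set character vector of gene ids
#' @param occ occupancy matrix genes x 500, as from [read_occupancy()]
#' @return List with `profile` (length 500), `per_gene` (named vector),
#'   `n_genes`, `n_skipped`.
#' @export
promoter_occupancy_profile <- function(gene_set, occ) {
  present <- intersect(unique(gene_set), rownames(occ))
  n_skipped <- length(unique(gene_set)) - length(present)
  if (n_skipped > 0) {
    message("promoter_occupancy_profile: no track for ", n_skipped, " gene(s), skipped")
  }
  if (length(present) == 0) stop("occupancy available for no gene in set")
  m <- occ[present, , drop = FALSE]
  list(profile = unname(colMeans(m)),
       per_gene = rowMeans(m),
       n_genes = length(present),
       n_skipped = n_skipped)
}

#' Promoter occupancy contrast between two gene sets
#'
#' Rank test on per-gene mean promoter occupancy. For the bound-vs-SAR
#' comparison, genes belonging to both sets should be excluded by the
#' caller beforehand (see [run_pipeline()]), since a gene that is both
#' bound and SAR would sit on both sides.
#'
#' @param genes_a,genes_b character vectors of gene ids
#' @param occ occupancy matrix
#' @param n_boot,seed bootstrap parameters
#' @return A [contrast_result()] carrying the two profiles as attributes
#'   `profile_a`, `profile_b`.
#' @export
occupancy_contrast <- function(genes_a, genes_b, occ, n_boot = 1000, seed = NULL) {
  pa <- promoter_occupancy_profile(genes_a, occ)
  pb <- promoter_occupancy_profile(genes_b, occ)
  out <- contrast_result(pa$per_gene, pb$per_gene, "group A", "group B",
                         n_boot = n_boot, seed = seed)
  attr(out, "profile_a") <- pa$profile
  attr(out, "profile_b") <- pb$profile
  out
}

#' Orient a promoter window to transcription direction
#'
#' Given raw per-base values over the 500 bp immediately upstream of a TSS
#' in genome coordinates, returns the window oriented so the last position
#' abuts the TSS on the coding strand: for minus-strand genes the vector is
#' reversed.
#'
#' @param values numeric vector of length 500, genome order (left to right)
#' @param strand `"+"` or `"-"`
#' @return Numeric vector of length 500 in transcription direction.
#' @export
orient_profile <- function(values, strand) {
  stopifnot(length(values) == 500, strand %in% c("+", "-"))
  if (strand == "-") rev(values) else values
}

#' Binding-TF count contrast between two gene sets
#'
#' Per-gene count of distinct TFs binding it (at the load-time binding
#' cutoff), compared by rank test. Genes bound by no TF count 0.
#'
#' @param genes_a,genes_b character vectors of gene ids
#' @param regulons named list of [tf_regulon()]
#' @param n_boot,seed bootstrap parameters
#' @return A [contrast_result()].
#' @export
tf_count_contrast <- function(genes_a, genes_b, regulons,
                              n_boot = 1000, seed = NULL) {
  bound_all <- unlist(lapply(regulons, function(r) unique(r$bound$gene_id)),
                      use.names = FALSE)
  tab <- table(bound_all)
  count_of <- function(set) {
    set <- unique(set)
    n <- as.integer(tab[set])
    n[is.na(n)] <- 0L
    n
  }
  contrast_result(count_of(genes_a), count_of(genes_b), "group A", "group B",
                  n_boot = n_boot, seed = seed)
}

#' Binding-affinity contrast of colocalized vs other binding events
#'
#' Group A holds the binding scores of (TF, bound gene) events whose bound
#' gene colocalizes with >= 1 knockout-affected gene of the same TF; group B
#' the remaining binding events. A rank test asks whether the colocalized
#' regulatory mode rides on stronger TF-DNA binding.
#'
#' @param regulons named list of filtered [tf_regulon()]
#' @param classifications list of [classify_sar()] results (same TFs)
#' @param n_boot,seed bootstrap parameters
#' @return A [contrast_result()] (A = colocalized events, B = others).
#' @export
affinity_contrast <- function(regulons, classifications,
                              n_boot = 1000, seed = NULL) {
  a <- numeric(0)
  b <- numeric(0)
  for (tf in names(regulons)) {
    bound <- regulons[[tf]]$bound
    cl <- classifications[[tf]]$bound
    stopifnot(identical(bound$gene_id, cl$gene_id))
    coloc <- cl$coloc_inter | cl$coloc_intra
    a <- c(a, bound$binding_score[coloc])
    b <- c(b, bound$binding_score[!coloc])
  }
  contrast_result(a, b, "colocalized events", "other events",
                  n_boot = n_boot, seed = seed)
}
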