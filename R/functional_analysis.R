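#' Mann-Whitney (Wilcoxon rank-sum) test P value
#'
#' Exact enumeration (via the exact null distribution of the rank-sum) when
#' both samples are small (`min(n, m) <= 8`) and tie-free; otherwise the
#' tie-corrected normal approximation without continuity correction. The
#' test is rank-based, so P values are invariant under strictly monotone
#' transforms of the pooled values.
#'
#' @param a,b numeric samples (nonempty)
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`
#' @return P value in (0, 1].
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0
  if (min(length(a), length(b)) <= 8 && !ties) {
    stats::wilcox.test(a, b, alternative = alternative, exact = TRUE)$p.value
  } else {
    suppressWarnings(
      stats::wilcox.test(a, b, alternative = alternative,
                         exact = FALSE, correct = FALSE)$p.value
    )
  }
}

#' Percentile bootstrap confidence interval for a median
#'
#' @param x numeric sample
#' @param n_boot number of resamples (default 1000)
#' @param conf confidence level (default 0.95)
#' @param seed optional integer seed for the resampling
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(x, n_boot = 1000, conf = 0.95, seed = NULL) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(NA_real_, NA_real_))
  boot <- function() {
    meds <- vapply(seq_len(n_boot),
                   function(i) stats::median(x[sample.int(length(x), replace = TRUE)]),
                   numeric(1))
    alpha <- (1 - conf) / 2
    unname(stats::quantile(meds, c(alpha, 1 - alpha), type = 7))
  }
  if (is.null(seed)) boot() else withseed(seed, boot())
}

#' Two-group contrast: medians, rank test, bootstrap intervals
#'
#' The common result container for every downstream contrast. When a group
#' is empty, or all values across both groups are identical (so ranks carry
#' no information), the contrast degenerates: `p` is `NA` and `note` says
#' why, rather than fabricating a P value.
#'
#' @param values_a,values_b numeric value vectors (NAs dropped)
#' @param label_a,label_b group labels
#' @param n_boot bootstrap resamples for the median CIs
#' @param seed optional seed for the bootstrap
#' @return A `contrast_result`: list with the value vectors, `median_a`,
#'   `median_b`, `ci_a`, `ci_b`, `p`, `n_boot`, `note`.
#' @export
contrast_result <- function(values_a, values_b, label_a = "A", label_b = "B",
                            n_boot = 1000, seed = NULL) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  note <- NA_character_
  p <- NA_real_
  if (length(values_a) == 0 || length(values_b) == 0) {
    note <- "no contrast: empty group"
  } else if (length(unique(c(values_a, values_b))) == 1) {
    note <- "no contrast: all values identical"
  } else {
    p <- mann_whitney_u(values_a, values_b)
  }
  structure(list(
    values_a = values_a, values_b = values_b,
    label_a = label_a, label_b = label_b,
    median_a = if (length(values_a)) stats::median(values_a) else NA_real_,
    median_b = if (length(values_b)) stats::median(values_b) else NA_real_,
    ci_a = bootstrap_median_ci(values_a, n_boot = n_boot, seed = seed),
    ci_b = bootstrap_median_ci(values_b, n_boot = n_boot,
                               seed = if (is.null(seed)) NULL else seed + 1L),
    p = p, n_boot = n_boot, note = note
  ), class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast_result: %s (n=%d, median %.4g) vs %s (n=%d, median %.4g), P %s\n",
              x$label_a, length(x$values_a), x$median_a,
              x$label_b, length(x$values_b), x$median_b,
              if (is.na(x$p)) paste0("NA [", x$note, "]")
              else format(x$p, digits = 4)))
  invisible(x)
}

#' Cellular co-component frequency of SAR pairs
#'
#' For each (TF, SAR gene) pair, counts it when some other TF binds the
#' gene and shares at least one cellular-component term with the pair's TF
#' (flat set semantics). This is the observable behind the co-complex
#' interpretation: an unbound TF can still reach its SAR gene through a
#' shared complex with a TF that does bind it.
#'
#' @param sar_pairs data.frame with columns `tf`, `gene_id`
#' @param regulons named list of filtered [tf_regulon()] defining which TFs
#'   bind which genes
#' @param cc an [annotation_set()] of category `"CC"` (TFs annotated as genes)
#' @return A [frequency_result()].
#' @export
cc_cocomponent_frequency <- function(sar_pairs, regulons, cc) {
  if (nrow(sar_pairs) == 0) stop("no SAR pairs: zero denominator")
  tf_ids <- names(regulons)
  shared <- tf_cc_shared_matrix(tf_ids, cc)
  bound_by <- lapply(regulons, function(r) r$bound$gene_id)
  hit <- vapply(seq_len(nrow(sar_pairs)), function(i) {
    tf <- sar_pairs$tf[i]
    g <- sar_pairs$gene_id[i]
    others <- tf_ids[tf_ids != tf & vapply(bound_by, function(b) g %in% b, logical(1))]
    length(others) > 0 && any(shared[tf, others])
  }, logical(1))
  frequency_result("sar_pairs", "cc_cocomponent", sum(hit), nrow(sar_pairs))
}

#' Biological co-process frequency of a pair set
#'
#' For each (TF, gene) pair, counts it when the gene shares at least one
#' biological-process term with any gene bound by that TF. Computed
#' separately for SAR and non-SAR pair sets to contrast the two.
#'
#' @param pairs data.frame with columns `tf`, `gene_id`
#' @param regulons named list of filtered [tf_regulon()]
#' @param bp an [annotation_set()] of category `"BP"`
#' @return A [frequency_result()].
#' @export
bp_coprocess_frequency <- function(pairs, regulons, bp) {
  stopifnot(identical(bp$category, "BP"))
  if (nrow(pairs) == 0) stop("no pairs: zero denominator")
  gene_terms <- invert_terms(bp)
  tf_union <- lapply(regulons, function(r) {
    unique(unlist(gene_terms[r$bound$gene_id], use.names = FALSE))
  })
  hit <- vapply(seq_len(nrow(pairs)), function(i) {
    gt <- gene_terms[[pairs$gene_id[i]]]
    !is.null(gt) && any(gt %in% tf_union[[pairs$tf[i]]])
  }, logical(1))
  frequency_result("pairs", "bp_coprocess", sum(hit), nrow(pairs))
}

invert_terms <- function(annotations) {
  genes <- unlist(annotations$terms, use.names = FALSE)
  terms <- rep(names(annotations$terms), lengths(annotations$terms))
  split(terms, genes)
}

#' Co-expression contrast: SAR vs non-SAR pairs against bound genes
#'
#' Group A pools the Pearson correlation (over conditions,
#' pairwise-complete) of every (SAR gene, bound gene of the same TF)
#' combination; group B does the same for non-SAR knockout-affected genes.
#' Pairs with fewer than 3 shared non-missing conditions, and genes without
#' expression rows, are skipped (counts attached as attribute `n_skipped`).
#'
#' @param sar_pairs,nonsar_pairs data.frames with columns `tf`, `gene_id`
#' @param regulons named list of filtered [tf_regulon()]
#' @param expr expression matrix (genes x conditions) as from
#'   [read_expression()]
#' @param n_boot,seed bootstrap parameters for the median CIs
#' @return A [contrast_result()] (A = SAR, B = non-SAR).
#' @export
coexpression_contrast <- function(sar_pairs, nonsar_pairs, regulons, expr,
                                  n_boot = 1000, seed = NULL) {
  a <- pair_correlations(sar_pairs, regulons, expr)
  b <- pair_correlations(nonsar_pairs, regulons, expr)
  out <- contrast_result(a$r, b$r, "SAR", "non-SAR", n_boot = n_boot, seed = seed)
  attr(out, "n_skipped") <- a$n_skipped + b$n_skipped
  out
}

pair_correlations <- function(pairs, regulons, expr) {
  r_all <- numeric(0)
  n_skipped <- 0L
  for (tf in unique(pairs$tf)) {
    ko <- intersect(pairs$gene_id[pairs$tf == tf], rownames(expr))
    bound <- intersect(regulons[[tf]]$bound$gene_id, rownames(expr))
    n_skipped <- n_skipped +
      sum(!pairs$gene_id[pairs$tf == tf] %in% rownames(expr))
    if (length(ko) == 0 || length(bound) == 0) next
    r <- stats::cor(t(expr[ko, , drop = FALSE]), t(expr[bound, , drop = FALSE]),
                    use = "pairwise.complete.obs")
    shared <- crossprod_nonmissing(expr[ko, , drop = FALSE],
                                   expr[bound, , drop = FALSE])
    r[shared < 3] <- NA
    n_skipped <- n_skipped + sum(shared < 3)
    r_all <- c(r_all, r[!is.na(r)])
  }
  list(r = r_all, n_skipped = n_skipped)
}

crossprod_nonmissing <- function(a, b) {
  tcrossprod(!is.na(a) * 1, !is.na(b) * 1)
}

#' Pairwise co-expression among bound genes, by colocalization status
#'
#' Within each TF, all-pairs Pearson correlations among bound genes that
#' colocalize with >= 1 knockout-affected gene of the TF (group A) versus
#' among bound genes that do not (group B), pooled across TFs. TFs with
#' fewer than 2 bound genes in a class contribute nothing to that class.
#'
#' @param regulons named list of filtered [tf_regulon()]
#' @param classifications list of [classify_sar()] results (same TFs)
#' @param expr expression matrix
#' @param n_boot,seed bootstrap parameters
#' @return A [contrast_result()] (A = colocalized, B = non-colocalized).
#' @export
pairwise_bound_coexpression <- function(regulons, classifications, expr,
                                        n_boot = 1000, seed = NULL) {
  a <- numeric(0)
  b <- numeric(0)
  for (tf in names(regulons)) {
    cl <- classifications[[tf]]
    coloc <- cl$bound$gene_id[cl$bound$coloc_inter | cl$bound$coloc_intra]
    noncoloc <- setdiff(cl$bound$gene_id, coloc)
    a <- c(a, within_set_correlations(coloc, expr))
    b <- c(b, within_set_correlations(noncoloc, expr))
  }
  contrast_result(a, b, "colocalized bound", "non-colocalized bound",
                  n_boot = n_boot, seed = seed)
}

within_set_correlations <- function(gene_set, expr) {
  gene_set <- intersect(gene_set, rownames(expr))
  if (length(gene_set) < 2) return(numeric(0))
  r <- stats::cor(t(expr[gene_set, , drop = FALSE]), use = "pairwise.complete.obs")
  vals <- r[upper.tri(r)]
  vals[!is.na(vals)]
}

#' Expression variability contrast
#'
#' Per-gene variability is the standard deviation across conditions
#' (`metric = "cv"` divides by the mean absolute level instead), compared
#' between two gene sets by rank test. Used to ask whether SAR genes are
#' noisier than the rest of the genome.
#'
#' @param genes_a,genes_b character vectors of gene ids
#' @param expr expression matrix
#' @param metric `"sd"` (default) or `"cv"`
#' @param n_boot,seed bootstrap parameters
#' @return A [contrast_result()].
#' @export
expression_variability_contrast <- function(genes_a, genes_b, expr,
                                            metric = c("sd", "cv"),
                                            n_boot = 1000, seed = NULL) {
  metric <- match.arg(metric)
  variability <- function(set) {
    set <- intersect(set, rownames(expr))
    if (length(set) == 0) return(numeric(0))
    m <- expr[set, , drop = FALSE]
    s <- apply(m, 1, stats::sd, na.rm = TRUE)
    if (metric == "cv") s <- s / abs(rowMeans(m, na.rm = TRUE))
    unname(s)
  }
  contrast_result(variability(genes_a), variability(genes_b),
                  "group A", "group B", n_boot = n_boot, seed = seed)
}

#' Collect SAR / non-SAR pair tables from classifications
#'
#' @param classifications list of [classify_sar()] results
#' @return List with data.frames `sar` and `nonsar`, each with columns
#'   `tf`, `gene_id`.
#' @export
sar_pair_tables <- function(classifications) {
  mk <- function(field) {
    df <- do.call(rbind, lapply(classifications, function(cl) {
      g <- cl[[field]]
      if (length(g) == 0) return(NULL)
      data.frame(tf = cl$tf_id, gene_id = g, stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- data.frame(tf = character(), gene_id = character())
    rownames(df) <- NULL
    df
  }
  list(sar = mk("sar_genes"), nonsar = mk("nonsar_genes"))
}
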