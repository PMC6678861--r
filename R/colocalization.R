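#' Map genes to nearby interaction segments
#'
#' A gene maps to every segment on its chromosome whose interval lies within
#' `tss_window_bp` of the gene's TSS (distance 0 if the TSS falls inside the
#' segment). Genes with no nearby segment map to the empty set and are
#' retained: they can never be colocalized but still count in frequency
#' denominators.
#'
#' @param genes a [gene_table()]
#' @param interactions an [interaction_set()]
#' @param tss_window_bp maximum TSS-to-segment distance (default 2500 bp)
#' @return A `gene_segment_map`: list with `map` (named list gene_id ->
#'   character vector of segment ids) and `tss_window_bp`.
#' @export
map_genes_to_segments <- function(genes, interactions, tss_window_bp = 2500) {
  segs <- interactions$segments
  map <- stats::setNames(vector("list", nrow(genes)), genes$gene_id)
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    si <- which(segs$chrom == ch)
    if (length(si) == 0) {
      map[gi] <- list(character(0))
      next
    }
    # distance from TSS to nearest point of the segment interval
    left <- outer(genes$tss[gi], segs$end[si], "-")      # >0 when TSS right of segment
    right <- outer(segs$start[si], genes$tss[gi], "-")   # >0 when TSS left of segment
    d <- pmax(left, t(right), 0)
    hit <- d <= tss_window_bp
    map[gi] <- lapply(seq_along(gi), function(i) segs$segment_id[si][hit[i, ]])
  }
  structure(list(map = map, tss_window_bp = tss_window_bp),
            class = "gene_segment_map")
}

#' Drop short-range intra-chromosomal interactions
#'
#' Intra-chromosomal pairs whose segments are separated by less than
#' `min_sep_bp` are removed to control for linear genomic proximity;
#' inter-chromosomal pairs are untouched. Separation is measured
#' midpoint-to-midpoint by default (`anchor = "edge"` uses the gap between
#' the closest interval edges instead).
#'
#' @param interactions an [interaction_set()]
#' @param min_sep_bp minimum retained separation (default 60000 bp)
#' @param anchor `"midpoint"` (default) or `"edge"`
#' @return The filtered `interaction_set`.
#' @export
filter_intra_by_separation <- function(interactions, min_sep_bp = 60000,
                                       anchor = c("midpoint", "edge")) {
  anchor <- match.arg(anchor)
  segs <- interactions$segments
  pairs <- interactions$pairs
  ia <- match(pairs$seg_a, segs$segment_id)
  ib <- match(pairs$seg_b, segs$segment_id)
  if (anchor == "midpoint") {
    mid <- (segs$start + segs$end) / 2
    sep <- abs(mid[ia] - mid[ib])
  } else {
    sep <- pmax(segs$start[ib] - segs$end[ia], segs$start[ia] - segs$end[ib], 0)
  }
  keep <- pairs$kind == "inter" | sep >= min_sep_bp
  out <- interactions
  out$pairs <- pairs[keep, , drop = FALSE]
  rownames(out$pairs) <- NULL
  attr(out, "min_sep_bp") <- min_sep_bp
  out
}

#' Are two genes colocalized in the nucleus?
#'
#' TRUE iff some segment of `gene_a` and some distinct segment of `gene_b`
#' form an interacting pair of the requested kind. A shared segment alone is
#' not colocalization: the interaction list, not co-mapping, defines spatial
#' proximity.
#'
#' @param gene_a,gene_b gene ids
#' @param map a [map_genes_to_segments()] result
#' @param interactions an [interaction_set()]
#' @param mode `"inter"`, `"intra"`, or `"either"`
#' @return Logical flag.
#' @export
genes_colocalized <- function(gene_a, gene_b, map, interactions,
                              mode = c("inter", "intra", "either")) {
  mode <- match.arg(mode)
  sa <- map$map[[gene_a]]
  sb <- map$map[[gene_b]]
  if (is.null(sa) || is.null(sb)) stop("gene not present in segment map")
  if (length(sa) == 0 || length(sb) == 0) return(FALSE)
  pairs <- interactions$pairs
  if (mode != "either") pairs <- pairs[pairs$kind == mode, , drop = FALSE]
  any((pairs$seg_a %in% sa & pairs$seg_b %in% sb) |
      (pairs$seg_a %in% sb & pairs$seg_b %in% sa))
}

#' Precompute the gene-level colocalization adjacency
#'
#' Expands the segment-pair contact list into two symmetric gene x gene
#' logical matrices (inter and intra), using the gene-segment map. This is
#' the workhorse behind SAR classification and the permutation statistic:
#' once built, any colocalization query is a matrix lookup.
#'
#' @inheritParams genes_colocalized
#' @param genes a [gene_table()]
#' @return A `coloc_adjacency`: list with `gene_ids`, `inter`, `intra`
#'   (logical matrices) and `either` (their union).
#' @export
build_coloc_adjacency <- function(genes, map, interactions) {
  n <- nrow(genes)
  ids <- genes$gene_id
  stopifnot(identical(names(map$map), ids))
  seg_genes <- split(rep(seq_len(n), lengths(map$map)),
                     unlist(map$map, use.names = FALSE))
  mats <- list(inter = matrix(FALSE, n, n), intra = matrix(FALSE, n, n))
  for (kind in c("inter", "intra")) {
    pr <- interactions$pairs[interactions$pairs$kind == kind, , drop = FALSE]
    if (nrow(pr) == 0) next
    la <- seg_genes[pr$seg_a]
    lb <- seg_genes[pr$seg_b]
    la[vapply(la, is.null, logical(1))] <- list(integer(0))
    lb[vapply(lb, is.null, logical(1))] <- list(integer(0))
    ra <- unlist(Map(function(x, y) rep(x, each = length(y)), la, lb), use.names = FALSE)
    rb <- unlist(Map(function(x, y) rep(y, times = length(x)), la, lb), use.names = FALSE)
    if (length(ra) > 0) {
      keep <- ra != rb  # a gene is not colocalized with itself
      mats[[kind]][cbind(ra[keep], rb[keep])] <- TRUE
      mats[[kind]][cbind(rb[keep], ra[keep])] <- TRUE
    }
  }
  dimnames(mats$inter) <- dimnames(mats$intra) <- list(ids, ids)
  structure(list(gene_ids = ids, inter = mats$inter, intra = mats$intra,
                 either = mats$inter | mats$intra),
            class = "coloc_adjacency")
}

#' Classify SAR genes for one TF
#'
#' A knockout-affected gene is a SAR (spatially adjacent regulated) gene of
#' its TF if it is colocalized, inter- or intra-chromosomally, with at least
#' one gene bound by that TF. Per-mode flags are kept separate so the inter
#' and intra frequencies are independently reproducible; partner bound genes
#' are recorded, and bound-side flags (bound gene colocalized with >= 1
#' knockout-affected gene) are computed for the reverse direction.
#'
#' @param regulon a filtered [tf_regulon()]
#' @param adjacency a [build_coloc_adjacency()] result
#' @return A `sar_classification`: list with `tf_id`, `ko` (data.frame
#'   gene_id / coloc_inter / coloc_intra / sar / n_partners), `bound`
#'   (data.frame gene_id / coloc_inter / coloc_intra / n_partners),
#'   `partners` (data.frame bound_gene / ko_gene / mode) and the derived
#'   `sar_genes` / `nonsar_genes` vectors.
#' @export
classify_sar <- function(regulon, adjacency) {
  ki <- match(regulon$ko_affected, adjacency$gene_ids)
  bi <- match(regulon$bound$gene_id, adjacency$gene_ids)
  if (anyNA(ki) || anyNA(bi)) stop("regulon gene absent from adjacency gene table")
  sub_inter <- adjacency$inter[ki, bi, drop = FALSE]
  sub_intra <- adjacency$intra[ki, bi, drop = FALSE]
  sub_either <- sub_inter | sub_intra
  ko <- data.frame(
    gene_id = regulon$ko_affected,
    coloc_inter = rowSums(sub_inter) > 0,
    coloc_intra = rowSums(sub_intra) > 0,
    n_partners = rowSums(sub_either),
    stringsAsFactors = FALSE
  )
  ko$sar <- ko$coloc_inter | ko$coloc_intra
  bound <- data.frame(
    gene_id = regulon$bound$gene_id,
    coloc_inter = colSums(sub_inter) > 0,
    coloc_intra = colSums(sub_intra) > 0,
    n_partners = colSums(sub_either),
    stringsAsFactors = FALSE
  )
  partners <- rbind(
    partner_pairs(sub_inter, regulon, "inter"),
    partner_pairs(sub_intra, regulon, "intra")
  )
  structure(list(tf_id = regulon$tf_id, ko = ko, bound = bound,
                 partners = partners,
                 sar_genes = ko$gene_id[ko$sar],
                 nonsar_genes = ko$gene_id[!ko$sar]),
            class = "sar_classification")
}

partner_pairs <- function(sub, regulon, mode) {
  idx <- which(sub, arr.ind = TRUE)
  data.frame(bound_gene = regulon$bound$gene_id[idx[, 2]],
             ko_gene = regulon$ko_affected[idx[, 1]],
             mode = rep(mode, nrow(idx)),
             stringsAsFactors = FALSE)
}

#' Classify SAR genes for every analyzable TF
#'
#' @param regulons named list of filtered [tf_regulon()]
#' @param adjacency a [build_coloc_adjacency()] result
#' @return Named list of [classify_sar()] results.
#' @export
classify_sar_all <- function(regulons, adjacency) {
  lapply(regulons, classify_sar, adjacency = adjacency)
}

#' Pooled colocalization frequency across TFs
#'
#' In direction `ko_vs_bound`, the denominator is the total number of
#' (TF, knockout-affected gene) pairs over all TFs and the numerator counts
#' those whose gene is colocalized (in the requested mode) with at least one
#' bound gene of the same TF. Direction `bound_vs_ko` swaps the roles.
#'
#' @param classifications list of [classify_sar()] results
#' @param direction `"ko_vs_bound"` or `"bound_vs_ko"`
#' @param mode `"inter"`, `"intra"`, or `"either"`
#' @return A `frequency_result`: list with `direction`, `mode`, `numerator`,
#'   `denominator`, `frequency`.
#' @export
pooled_frequency <- function(classifications,
                             direction = c("ko_vs_bound", "bound_vs_ko"),
                             mode = c("inter", "intra", "either")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  side <- if (direction == "ko_vs_bound") "ko" else "bound"
  num <- 0L
  den <- 0L
  for (cl in classifications) {
    df <- cl[[side]]
    flag <- switch(mode,
                   inter = df$coloc_inter,
                   intra = df$coloc_intra,
                   either = df$coloc_inter | df$coloc_intra)
    num <- num + sum(flag)
    den <- den + nrow(df)
  }
  if (den == 0) stop("no (TF, gene) pairs: zero denominator")
  frequency_result(direction, mode, num, den)
}

#' @rdname pooled_frequency
#' @param numerator,denominator pair counts
#' @export
frequency_result <- function(direction, mode, numerator, denominator) {
  stopifnot(denominator > 0, numerator >= 0, numerator <= denominator)
  structure(list(direction = direction, mode = mode,
                 numerator = as.integer(numerator),
                 denominator = as.integer(denominator),
                 frequency = numerator / denominator),
            class = "frequency_result")
}

#' @export
print.frequency_result <- function(x, ...) {
  cat(sprintf("frequency_result: %s / %s  %d/%d = %.2f%%\n",
              x$direction, x$mode, x$numerator, x$denominator, 100 * x$frequency))
  invisible(x)
}

#' Partner-count distribution per gene
#'
#' For each gene on the chosen side, the number of colocalized partner genes
#' on the other side of the same TF, plus the grand total of colocalized
#' (bound gene, knockout-affected gene) pairs. The grand total is identical
#' whichever side it is summed from: each colocalized pair is counted once
#' per side, which is the reconciliation between a significant
#' knockout-side enrichment and a non-significant bound-side one.
#'
#' @inheritParams pooled_frequency
#' @return List with `counts` (data.frame tf / gene_id / n_partners) and
#'   `total_pairs`.
#' @export
partner_count_summary <- function(classifications,
                                  direction = c("ko_vs_bound", "bound_vs_ko")) {
  direction <- match.arg(direction)
  side <- if (direction == "ko_vs_bound") "ko" else "bound"
  counts <- do.call(rbind, lapply(classifications, function(cl) {
    data.frame(tf = cl$tf_id, gene_id = cl[[side]]$gene_id,
               n_partners = cl[[side]]$n_partners, stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(counts = counts, total_pairs = sum(counts$n_partners))
}
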