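#' Filter configuration for regulon exclusions
#'
#' @param proximity_bp same-chromosome TSS-to-TSS distance below which a
#'   gene counts as "close to" a gene of the other set (default 3000 bp).
#' @param min_set_size a TF is analyzable only if both filtered sets are
#'   strictly larger than this (default 20, i.e. "more than 20" genes).
#' @return A `filter_config` list.
#' @export
filter_config <- function(proximity_bp = 3000, min_set_size = 20) {
  stopifnot(proximity_bp >= 0, min_set_size >= 1)
  structure(list(proximity_bp = proximity_bp, min_set_size = min_set_size),
            class = "filter_config")
}

#' Remove mutually overlapping and linearly proximal genes from a regulon
#'
#' A knockout-affected gene is excluded if it is itself a bound gene of the
#' TF, or lies within `proximity_bp` (TSS to TSS, same chromosome) of any
#' bound gene; symmetrically, bound genes overlapping or proximal to
#' knockout-affected genes are excluded. Both exclusions are computed from
#' the original, pre-filter sets simultaneously, so the result does not
#' depend on which side is processed first and the operation is idempotent.
#'
#' @param regulon a [tf_regulon()]
#' @param genes a [gene_table()] covering all regulon genes
#' @param cfg a [filter_config()]
#' @return The filtered `tf_regulon`, with attribute `excluded` giving
#'   per-side exclusion counts.
#' @export
exclude_mutual_and_proximal <- function(regulon, genes, cfg = filter_config()) {
  b <- regulon$bound$gene_id
  k <- regulon$ko_affected
  missing <- setdiff(c(b, k), genes$gene_id)
  if (length(missing) > 0) {
    stop("regulon gene(s) absent from gene table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  ko_drop <- k %in% b | min_cross_distance(k, b, genes) < cfg$proximity_bp
  b_drop <- b %in% k | min_cross_distance(b, k, genes) < cfg$proximity_bp
  out <- tf_regulon(regulon$tf_id,
                    regulon$bound[!b_drop, , drop = FALSE],
                    k[!ko_drop])
  attr(out, "excluded") <- c(bound = sum(b_drop), ko = sum(ko_drop))
  out
}

# Minimum same-chromosome TSS distance from each gene in `from` to the gene
# set `to`; Inf where `to` has no gene on that chromosome.
min_cross_distance <- function(from, to, genes) {
  if (length(from) == 0) return(numeric(0))
  if (length(to) == 0) return(rep(Inf, length(from)))
  fi <- match(from, genes$gene_id)
  ti <- match(to, genes$gene_id)
  out <- rep(Inf, length(from))
  for (ch in unique(genes$chrom[fi])) {
    f_here <- which(genes$chrom[fi] == ch)
    t_tss <- genes$tss[ti][genes$chrom[ti] == ch]
    if (length(t_tss) == 0) next
    d <- abs(outer(genes$tss[fi][f_here], t_tss, "-"))
    out[f_here] <- apply(d, 1, min)
  }
  out
}

#' Keep TFs whose filtered sets are both large enough
#'
#' Retains TFs with strictly more than `min_set_size` bound genes and
#' strictly more than `min_set_size` knockout-affected genes.
#'
#' @param regulons named list of [tf_regulon()] (already filtered)
#' @param cfg a [filter_config()]
#' @return The retained sublist.
#' @export
select_analyzable <- function(regulons, cfg = filter_config()) {
  keep <- vapply(regulons, function(r) {
    nrow(r$bound) > cfg$min_set_size && length(r$ko_affected) > cfg$min_set_size
  }, logical(1))
  regulons[keep]
}

#' Apply both regulon filters to a collection
#'
#' Convenience wrapper: [exclude_mutual_and_proximal()] on every regulon,
#' then [select_analyzable()]. Per-TF exclusion counts are attached as the
#' `exclusion_log` attribute.
#'
#' @inheritParams select_analyzable
#' @param genes a [gene_table()]
#' @return Named list of analyzable, filtered regulons.
#' @export
filter_regulons <- function(regulons, genes, cfg = filter_config()) {
  filtered <- lapply(regulons, exclude_mutual_and_proximal, genes = genes, cfg = cfg)
  log <- do.call(rbind, lapply(filtered, function(r) {
    data.frame(tf = r$tf_id,
               excluded_bound = attr(r, "excluded")[["bound"]],
               excluded_ko = attr(r, "excluded")[["ko"]],
               n_bound = nrow(r$bound), n_ko = length(r$ko_affected),
               stringsAsFactors = FALSE)
  }))
  out <- select_analyzable(filtered, cfg)
  attr(out, "exclusion_log") <- log
  out
}
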