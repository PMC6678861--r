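#' Draw a chromosome-matched random gene set
#'
#' Each gene of `gene_ids` is replaced by a gene drawn uniformly from the
#' same chromosome, so the per-chromosome composition of the output equals
#' that of the input (TF regulation is chromosome-biased, and the null must
#' preserve that bias). Within one drawn set, genes are sampled without
#' replacement per chromosome, so the result is a genuine gene set of the
#' stated size; the actual genes themselves are eligible draws.
#'
#' @param gene_ids character vector of gene ids to match
#' @param genes a [gene_table()]
#' @return Character vector of the same length.
#' @export
draw_matched_random_set <- function(gene_ids, genes) {
  idx <- match(gene_ids, genes$gene_id)
  if (anyNA(idx)) stop("gene id(s) absent from gene table")
  pools <- split(seq_len(nrow(genes)), genes$chrom)
  needs <- table(genes$chrom[idx])
  out <- integer(0)
  for (ch in names(needs)) {
    pool <- pools[[ch]]
    n <- needs[[ch]]
    if (length(pool) < n) {
      stop("chromosome ", ch, " has ", length(pool),
           " candidate genes but ", n, " are needed")
    }
    out <- c(out, pool[sample.int(length(pool), n)])
  }
  genes$gene_id[out]
}

#' Chromosome-matched permutation test for a pooled statistic
#'
#' The engine behind every empirical P value in the pipeline. `statistic`
#' is evaluated on the real per-TF gene sets, then on `n_reps` independent
#' replicates in which the gene sets are replaced by chromosome-matched
#' random sets (see [draw_matched_random_set()]). The empirical P value is
#' the fraction of replicates whose statistic is strictly greater than the
#' observed one: ties count as not exceeding. When no replicate exceeds,
#' `p_report` states the resolution bound `< 1/n_reps`. A conservative
#' `(exceed + 1) / (n_reps + 1)` estimator is available via `estimator`.
#'
#' For the colocalization test, both the knockout-affected and the bound
#' side are randomized each replicate (`randomize = "both"`); for the
#' cellular co-component test only the SAR-gene side is randomized
#' (`randomize = "ko_only"`), with the bound sets of all TFs held fixed.
#'
#' Replicate r draws from a substream seeded by the r-th value of a seed
#' sequence derived once from `seed`, so results are bit-reproducible and
#' independent of evaluation order.
#'
#' @param statistic function(ko_sets, bound_sets) -> numeric scalar, where
#'   both arguments are per-TF lists of integer row indices into `genes`.
#'   See [make_frequency_statistic()] and [make_cc_statistic()].
#' @param regulons named list of filtered [tf_regulon()]; the
#'   knockout-affected side of each regulon is the "ko" side of the test
#'   (for the co-component test, pass regulons whose `ko_affected` holds the
#'   SAR genes).
#' @param genes a [gene_table()]
#' @param n_reps number of randomized replicates (default 10000)
#' @param seed integer master seed
#' @param randomize `"both"` or `"ko_only"`
#' @param estimator `"strict"` (exceed / n_reps, default) or
#'   `"conservative"` ((exceed + 1) / (n_reps + 1))
#' @return A `permutation_result`: list with `observed`, `null_sample`,
#'   `n_reps`, `exceed_count`, `tie_count`, `p_empirical`, `p_report`,
#'   `estimator`, `seed`.
#' @export
permutation_test <- function(statistic, regulons, genes, n_reps = 10000,
                             seed = 1, randomize = c("both", "ko_only"),
                             estimator = c("strict", "conservative")) {
  randomize <- match.arg(randomize)
  estimator <- match.arg(estimator)
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1)

  pools <- split(seq_len(nrow(genes)), genes$chrom)
  chrom_idx <- match(genes$chrom, names(pools))

  prep_side <- function(ids) {
    idx <- match(ids, genes$gene_id)
    if (anyNA(idx)) stop("regulon gene absent from gene table")
    needs <- tabulate(chrom_idx[idx], nbins = length(pools))
    used <- which(needs > 0)
    short <- used[needs[used] > lengths(pools)[used]]
    if (length(short) > 0) {
      stop("chromosome ", names(pools)[short[1]], " has fewer candidate genes than needed")
    }
    list(idx = idx, chroms = used, needs = needs[used])
  }
  ko_prep <- lapply(regulons, function(r) prep_side(r$ko_affected))
  bound_prep <- lapply(regulons, function(r) prep_side(r$bound$gene_id))
  ko_real <- lapply(ko_prep, `[[`, "idx")
  bound_real <- lapply(bound_prep, `[[`, "idx")

  observed <- statistic(ko_real, bound_real)

  draw <- function(prep) {
    unlist(lapply(seq_along(prep$chroms), function(j) {
      pool <- pools[[prep$chroms[j]]]
      pool[sample.int(length(pool), prep$needs[j])]
    }), use.names = FALSE)
  }

  rep_seeds <- withseed(seed, sample.int(2147483646L, n_reps))
  null_sample <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    rko <- lapply(ko_prep, draw)
    rbound <- if (randomize == "both") lapply(bound_prep, draw) else bound_real
    null_sample[r] <- tryCatch(
      statistic(rko, rbound),
      error = function(e) stop("statistic failed at replicate ", r, ": ",
                               conditionMessage(e))
    )
  }

  exceed <- sum(null_sample > observed)
  ties <- sum(null_sample == observed)
  p <- if (estimator == "strict") exceed / n_reps else (exceed + 1) / (n_reps + 1)
  p_report <- if (exceed == 0 && estimator == "strict") {
    sprintf("< %g", 1 / n_reps)
  } else {
    format(p, digits = 4)
  }
  structure(list(observed = observed, null_sample = null_sample,
                 n_reps = n_reps, exceed_count = exceed, tie_count = ties,
                 p_empirical = p, p_report = p_report,
                 estimator = estimator, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: observed = %.4g, null mean = %.4g, P %s (%d/%d exceed, %s)\n",
    x$observed, mean(x$null_sample),
    if (x$exceed_count == 0 && x$estimator == "strict") x$p_report
    else paste("=", format(x$p_empirical, digits = 4)),
    x$exceed_count, x$n_reps, x$estimator))
  invisible(x)
}

#' Pooled colocalization frequency statistic for the permutation test
#'
#' Returns a closure computing, for per-TF index sets, the pooled fraction
#' of genes on the chosen side colocalized with >= 1 gene of the other side
#' of the same TF, using a precomputed [build_coloc_adjacency()].
#'
#' @param adjacency a [build_coloc_adjacency()] result; its gene order must
#'   match the `genes` table handed to [permutation_test()]
#' @param mode `"inter"`, `"intra"`, or `"either"`
#' @param direction `"ko_vs_bound"` or `"bound_vs_ko"`
#' @return function(ko_sets, bound_sets) -> frequency in \[0, 1\].
#' @export
make_frequency_statistic <- function(adjacency,
                                     mode = c("inter", "intra", "either"),
                                     direction = c("ko_vs_bound", "bound_vs_ko")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  M <- adjacency[[mode]]
  function(ko_sets, bound_sets) {
    num <- 0L
    den <- 0L
    for (t in seq_along(ko_sets)) {
      sub <- M[ko_sets[[t]], bound_sets[[t]], drop = FALSE]
      if (direction == "ko_vs_bound") {
        num <- num + sum(.rowSums(sub, nrow(sub), ncol(sub)) > 0)
        den <- den + length(ko_sets[[t]])
      } else {
        num <- num + sum(.colSums(sub, nrow(sub), ncol(sub)) > 0)
        den <- den + length(bound_sets[[t]])
      }
    }
    num / den
  }
}

#' Cellular co-component frequency statistic for the permutation test
#'
#' Returns a closure computing, for per-TF SAR-gene index sets, the fraction
#' of (TF, gene) pairs for which some other TF binds the gene and shares a
#' cellular-component term with the pair's TF. Used with
#' `randomize = "ko_only"`: the TF side of each pair is fixed.
#'
#' @param regulons named list of filtered [tf_regulon()] providing, for every
#'   TF, the bound sets that define "TFs binding a gene"
#' @param cc an [annotation_set()] of category `"CC"` in which TFs appear as
#'   genes
#' @param genes a [gene_table()]
#' @param tf_subset TF ids, in the order the per-TF sets will be handed to
#'   the closure (defaults to all of `regulons`); lets the randomized side
#'   cover a subset of TFs while binding and co-component relations still
#'   come from the full collection
#' @return function(ko_sets, bound_sets) -> frequency in \[0, 1\]
#'   (`bound_sets` is ignored; binding is taken from `regulons`).
#' @export
make_cc_statistic <- function(regulons, cc, genes, tf_subset = names(regulons)) {
  tf_ids <- names(regulons)
  shared <- tf_cc_shared_matrix(tf_ids, cc)
  binders <- gene_binder_index(regulons, genes)
  tpos <- match(tf_subset, tf_ids)
  if (anyNA(tpos)) stop("tf_subset contains TFs absent from regulons")
  function(ko_sets, bound_sets) {
    num <- 0L
    den <- 0L
    for (t in seq_along(ko_sets)) {
      ti <- tpos[t]
      S <- shared[ti, ]
      for (g in ko_sets[[t]]) {
        bt <- binders[[g]]
        bt <- bt[bt != ti]
        if (length(bt) > 0 && any(S[bt])) num <- num + 1L
      }
      den <- den + length(ko_sets[[t]])
    }
    num / den
  }
}

# TF x TF logical matrix: do two TFs share >= 1 CC term?
tf_cc_shared_matrix <- function(tf_ids, cc) {
  stopifnot(identical(cc$category, "CC"))
  inc <- vapply(cc$terms, function(g) tf_ids %in% g,
                logical(length(tf_ids)))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = length(tf_ids))
  shared <- tcrossprod(inc * 1) > 0
  dimnames(shared) <- list(tf_ids, tf_ids)
  shared
}

# per-gene list of indices (into names(regulons)) of TFs binding that gene
gene_binder_index <- function(regulons, genes) {
  binders <- vector("list", nrow(genes))
  gidx <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)
  for (t in seq_along(regulons)) {
    gi <- gidx[regulons[[t]]$bound$gene_id]
    gi <- gi[!is.na(gi)]
    for (g in gi) binders[[g]] <- c(binders[[g]], t)
  }
  binders[vapply(binders, is.null, logical(1))] <- list(integer(0))
  binders
}

# evaluate expr under a temporary seed without clobbering the caller's RNG
withseed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
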