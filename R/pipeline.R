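#' Configuration for a full pipeline run
#'
#' Every tunable has the analysis's canonical default: binding P cutoff
#' 0.005, interaction FDR cutoff 1e-4, 3 kb linear proximity exclusion,
#' set-size threshold 20 (strictly more required), 2.5 kb TSS-segment
#' window, 60 kb intra-chromosomal separation filter, 10,000 permutation
#' replicates, 1000 bootstrap resamples. One global seed drives everything;
#' per-stage substreams are derived from it so toggling one analysis does
#' not perturb another's draws.
#'
#' @param sim a [sim_config()] used when `input_dir` is NULL; its seed is
#'   overridden by a substream of `seed`
#' @param input_dir optional dataset directory (see [read_dataset()])
#' @param binding_p_cutoff,fdr_cutoff load-time score cutoffs
#' @param proximity_bp,min_set_size regulon filter parameters
#' @param tss_window_bp gene-to-segment mapping window
#' @param min_intra_sep_bp intra-chromosomal separation filter
#' @param n_reps permutation replicates
#' @param n_boot bootstrap resamples
#' @param estimator empirical P estimator, `"strict"` or `"conservative"`
#' @param seed global integer seed
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       binding_p_cutoff = 0.005, fdr_cutoff = 1e-4,
                       proximity_bp = 3000, min_set_size = 20,
                       tss_window_bp = 2500, min_intra_sep_bp = 60000,
                       n_reps = 10000, n_boot = 1000,
                       estimator = c("strict", "conservative"), seed = 1) {
  structure(list(sim = sim, input_dir = input_dir,
                 binding_p_cutoff = binding_p_cutoff, fdr_cutoff = fdr_cutoff,
                 proximity_bp = proximity_bp, min_set_size = min_set_size,
                 tss_window_bp = tss_window_bp,
                 min_intra_sep_bp = min_intra_sep_bp,
                 n_reps = as.integer(n_reps), n_boot = as.integer(n_boot),
                 estimator = match.arg(estimator), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full SAR analysis pipeline
#'
#' Executes, in order: input loading (or synthesis), regulon filtering, the
#' intra-chromosomal separation filter, gene-segment mapping, SAR
#' classification, pooled colocalization frequencies in both directions,
#' the chromosome-matched permutation tests (inter, intra, and cellular
#' co-component), the functional contrasts (biological co-process,
#' co-expression, pairwise bound-gene co-expression, expression
#' variability) and the chromatin contrasts (motif presence, promoter
#' occupancy, binding-TF counts, binding affinity). Structural invariants
#' (separation and proximity bounds, set sizes, SAR partition, pair-total
#' symmetry) are asserted on every run. Fully deterministic given the
#' config seed.
#'
#' @param config a [run_config()]
#' @param out_dir optional output directory; when given, writes
#'   `summary.json`, the per-TF frequency table, the SAR pair table and the
#'   partner-count tables
#' @return Invisibly, a list with `summary` (the machine-readable result
#'   tree), plus the intermediate objects (`data`, `regulons`,
#'   `classifications`, `adjacency`, `permutations`, `contrasts`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  seeds <- withseed(config$seed, sample.int(2147483646L, 10))

  # stage 1: inputs
  if (is.null(config$input_dir)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- seeds[1]
    data <- simulate_dataset(sim_cfg)
  } else {
    data <- read_dataset(config$input_dir,
                         binding_p_cutoff = config$binding_p_cutoff,
                         fdr_cutoff = config$fdr_cutoff)
  }

  # stage 2: regulon filters
  fcfg <- filter_config(proximity_bp = config$proximity_bp,
                        min_set_size = config$min_set_size)
  regulons <- filter_regulons(data$regulons, data$genes, fcfg)
  if (length(regulons) == 0) stop("pipeline: no analyzable TF after filtering")

  # stage 3: interaction separation filter + gene-segment map
  interactions <- filter_intra_by_separation(data$interactions,
                                             min_sep_bp = config$min_intra_sep_bp)
  map <- map_genes_to_segments(data$genes, interactions,
                               tss_window_bp = config$tss_window_bp)
  adjacency <- build_coloc_adjacency(data$genes, map, interactions)

  # stage 4: SAR classification + frequencies
  classifications <- classify_sar_all(regulons, adjacency)
  freq <- list(
    inter = pooled_frequency(classifications, "ko_vs_bound", "inter"),
    intra = pooled_frequency(classifications, "ko_vs_bound", "intra"),
    either = pooled_frequency(classifications, "ko_vs_bound", "either"),
    bound_inter = pooled_frequency(classifications, "bound_vs_ko", "inter"),
    bound_intra = pooled_frequency(classifications, "bound_vs_ko", "intra")
  )
  pairs_tab <- sar_pair_tables(classifications)
  assert_pipeline_invariants(regulons, data$genes, interactions,
                             classifications, freq, fcfg, config)

  # stage 5: permutation tests
  perms <- list(
    inter = permutation_test(make_frequency_statistic(adjacency, "inter"),
                             regulons, data$genes, n_reps = config$n_reps,
                             seed = seeds[2], randomize = "both",
                             estimator = config$estimator),
    intra = permutation_test(make_frequency_statistic(adjacency, "intra"),
                             regulons, data$genes, n_reps = config$n_reps,
                             seed = seeds[3], randomize = "both",
                             estimator = config$estimator),
    bound_inter = permutation_test(
      make_frequency_statistic(adjacency, "inter", "bound_vs_ko"),
      regulons, data$genes, n_reps = config$n_reps,
      seed = seeds[4], randomize = "both", estimator = config$estimator),
    bound_intra = permutation_test(
      make_frequency_statistic(adjacency, "intra", "bound_vs_ko"),
      regulons, data$genes, n_reps = config$n_reps,
      seed = seeds[5], randomize = "both", estimator = config$estimator)
  )
  cc_perm <- NULL
  if (nrow(pairs_tab$sar) > 0) {
    sar_regulons <- lapply(regulons, function(r) {
      sar <- pairs_tab$sar$gene_id[pairs_tab$sar$tf == r$tf_id]
      tf_regulon(r$tf_id, r$bound, sar)
    })
    keep <- vapply(sar_regulons, function(r) length(r$ko_affected) > 0, logical(1))
    cc_perm <- permutation_test(
      make_cc_statistic(regulons, data$cc, data$genes,
                        tf_subset = names(sar_regulons)[keep]),
      regulons = sar_regulons[keep], genes = data$genes,
      n_reps = config$n_reps, seed = seeds[6], randomize = "ko_only",
      estimator = config$estimator)
  }

  # stage 6: functional contrasts
  cc_freq <- if (nrow(pairs_tab$sar) > 0) {
    cc_cocomponent_frequency(pairs_tab$sar, regulons, data$cc)
  }
  bp_sar <- if (nrow(pairs_tab$sar) > 0) {
    bp_coprocess_frequency(pairs_tab$sar, regulons, data$bp)
  }
  bp_nonsar <- if (nrow(pairs_tab$nonsar) > 0) {
    bp_coprocess_frequency(pairs_tab$nonsar, regulons, data$bp)
  }
  coexpr <- coexpression_contrast(pairs_tab$sar, pairs_tab$nonsar, regulons,
                                  data$expr, n_boot = config$n_boot,
                                  seed = seeds[7])
  bound_coexpr <- pairwise_bound_coexpression(regulons, classifications,
                                              data$expr,
                                              n_boot = config$n_boot,
                                              seed = seeds[8])
  sar_union <- unique(pairs_tab$sar$gene_id)
  other_genes <- setdiff(data$genes$gene_id, sar_union)
  variability <- expression_variability_contrast(sar_union, other_genes,
                                                 data$expr,
                                                 n_boot = config$n_boot,
                                                 seed = seeds[9])

  # stage 7: chromatin contrasts
  motif_sar <- if (nrow(pairs_tab$sar) > 0) {
    motif_presence_frequency(pairs_tab$sar, data$motifs)
  }
  motif_nonsar <- if (nrow(pairs_tab$nonsar) > 0) {
    motif_presence_frequency(pairs_tab$nonsar, data$motifs)
  }
  bound_union <- unique(unlist(lapply(regulons, function(r) r$bound$gene_id),
                               use.names = FALSE))
  both <- intersect(bound_union, sar_union)  # ambiguous genes excluded
  occ_bound <- occupancy_contrast(setdiff(sar_union, both),
                                  setdiff(bound_union, both),
                                  data$occupancy, n_boot = config$n_boot,
                                  seed = seeds[10])
  occ_other <- occupancy_contrast(setdiff(sar_union, both),
                                  setdiff(other_genes, bound_union),
                                  data$occupancy, n_boot = config$n_boot,
                                  seed = seeds[10])
  tf_counts <- tf_count_contrast(sar_union, other_genes, data$regulons,
                                 n_boot = config$n_boot, seed = seeds[10])
  affinity <- affinity_contrast(regulons, classifications,
                                n_boot = config$n_boot, seed = seeds[10])

  summary <- build_summary(config, data, regulons, classifications, freq,
                           pairs_tab, perms, cc_perm, cc_freq, bp_sar,
                           bp_nonsar, coexpr, bound_coexpr, variability,
                           motif_sar, motif_nonsar, occ_bound, occ_other,
                           tf_counts, affinity)

  if (!is.null(out_dir)) {
    write_pipeline_outputs(summary, classifications, pairs_tab, out_dir)
  }

  invisible(list(summary = summary, data = data, regulons = regulons,
                 classifications = classifications, adjacency = adjacency,
                 permutations = c(perms, list(cc = cc_perm)),
                 contrasts = list(coexpr = coexpr, bound_coexpr = bound_coexpr,
                                  variability = variability,
                                  occ_bound = occ_bound, occ_other = occ_other,
                                  tf_counts = tf_counts, affinity = affinity)))
}

assert_pipeline_invariants <- function(regulons, genes, interactions,
                                       classifications, freq, fcfg, config) {
  segs <- interactions$segments
  mid <- (segs$start + segs$end) / 2
  intra <- interactions$pairs[interactions$pairs$kind == "intra", , drop = FALSE]
  if (nrow(intra) > 0) {
    sep <- abs(mid[match(intra$seg_a, segs$segment_id)] -
               mid[match(intra$seg_b, segs$segment_id)])
    if (any(sep < config$min_intra_sep_bp)) {
      stop("invariant violated: retained intra pair below separation cutoff")
    }
  }
  for (r in regulons) {
    if (length(intersect(r$bound$gene_id, r$ko_affected)) > 0) {
      stop("invariant violated: bound and knockout sets overlap for ", r$tf_id)
    }
    d <- min_cross_distance(r$ko_affected, r$bound$gene_id, genes)
    if (any(d < fcfg$proximity_bp)) {
      stop("invariant violated: cross-set TSS distance below proximity cutoff for ",
           r$tf_id)
    }
    if (!(nrow(r$bound) > fcfg$min_set_size &&
          length(r$ko_affected) > fcfg$min_set_size)) {
      stop("invariant violated: retained TF with too-small gene sets: ", r$tf_id)
    }
  }
  for (cl in classifications) {
    if (!setequal(c(cl$sar_genes, cl$nonsar_genes), cl$ko$gene_id) ||
        length(intersect(cl$sar_genes, cl$nonsar_genes)) > 0) {
      stop("invariant violated: SAR/non-SAR do not partition knockout genes")
    }
  }
  for (f in freq) {
    if (f$frequency < 0 || f$frequency > 1) stop("invariant violated: frequency outside [0,1]")
  }
  ko_total <- partner_count_summary(classifications, "ko_vs_bound")$total_pairs
  b_total <- partner_count_summary(classifications, "bound_vs_ko")$total_pairs
  if (ko_total != b_total) {
    stop("invariant violated: colocalized pair totals differ between sides")
  }
  invisible(TRUE)
}

build_summary <- function(config, data, regulons, classifications, freq,
                          pairs_tab, perms, cc_perm, cc_freq, bp_sar,
                          bp_nonsar, coexpr, bound_coexpr, variability,
                          motif_sar, motif_nonsar, occ_bound, occ_other,
                          tf_counts, affinity) {
  freq_node <- function(f) {
    if (is.null(f)) return(NULL)
    list(numerator = f$numerator, denominator = f$denominator,
         frequency = f$frequency)
  }
  perm_node <- function(p) {
    if (is.null(p)) return(NULL)
    list(observed = p$observed, null_mean = mean(p$null_sample),
         p_empirical = p$p_empirical, p_report = p$p_report,
         exceed_count = p$exceed_count, n_reps = p$n_reps)
  }
  contrast_node <- function(ct) {
    if (is.null(ct)) return(NULL)
    list(n_a = length(ct$values_a), n_b = length(ct$values_b),
         median_a = ct$median_a, median_b = ct$median_b,
         ci_a = ct$ci_a, ci_b = ct$ci_b, p = ct$p,
         note = if (is.na(ct$note)) NULL else ct$note)
  }
  list(
    schema_version = "1.0",
    seed = config$seed,
    counts = list(
      n_genes = nrow(data$genes),
      n_segments = nrow(data$interactions$segments),
      n_pairs_loaded = nrow(data$interactions$pairs),
      n_tfs_input = length(data$regulons),
      n_tfs_analyzable = length(regulons),
      n_ko_pairs = sum(vapply(classifications, function(cl) nrow(cl$ko), numeric(1))),
      n_sar_pairs = nrow(pairs_tab$sar)
    ),
    frequencies = lapply(freq, freq_node),
    permutation = c(lapply(perms, perm_node), list(cc_cocomponent = perm_node(cc_perm))),
    functional = list(
      cc_cocomponent = freq_node(cc_freq),
      bp_coprocess_sar = freq_node(bp_sar),
      bp_coprocess_nonsar = freq_node(bp_nonsar),
      coexpression = contrast_node(coexpr),
      pairwise_bound_coexpression = contrast_node(bound_coexpr),
      expression_variability = contrast_node(variability)
    ),
    chromatin = list(
      motif_sar = freq_node(motif_sar),
      motif_nonsar = freq_node(motif_nonsar),
      occupancy_sar_vs_bound = contrast_node(occ_bound),
      occupancy_sar_vs_other = contrast_node(occ_other),
      tf_count_sar_vs_other = contrast_node(tf_counts),
      affinity_coloc_vs_other = contrast_node(affinity)
    )
  )
}

write_pipeline_outputs <- function(summary, classifications, pairs_tab, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  per_tf <- do.call(rbind, lapply(classifications, function(cl) {
    data.frame(tf = cl$tf_id,
               n_ko = nrow(cl$ko), n_bound = nrow(cl$bound),
               n_sar = length(cl$sar_genes),
               freq_inter = mean(cl$ko$coloc_inter),
               freq_intra = mean(cl$ko$coloc_intra),
               stringsAsFactors = FALSE)
  }))
  write_tsv(per_tf, file.path(out_dir, "per_tf_frequencies.tsv"))
  write_tsv(pairs_tab$sar, file.path(out_dir, "sar_pairs.tsv"))
  ko_counts <- partner_count_summary(classifications, "ko_vs_bound")$counts
  bound_counts <- partner_count_summary(classifications, "bound_vs_ko")$counts
  write_tsv(ko_counts, file.path(out_dir, "partner_counts_ko_side.tsv"))
  write_tsv(bound_counts, file.path(out_dir, "partner_counts_bound_side.tsv"))
  invisible(out_dir)
}
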