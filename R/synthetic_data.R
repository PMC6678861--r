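#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the statistical structure of the real inputs:
#' genes laid out at fixed spacing on multiple chromosomes, kilobase
#' segments tiling the genome, a contact list with a planted excess of
#' (bound gene, knockout-affected gene) segment contacts, overlapping flat
#' annotations, a block-correlated expression matrix, occupancy tracks
#' elevated at designated promoters, and motif presence lists. Defaults are
#' yeast-like: 16 chromosomes, ~2 kb gene spacing, ~3 kb segments (about
#' 4000 genome-wide), 136 TFs, 112 expression conditions.
#'
#' With `planted_enrichment = 1` the generator is an exact null for every
#' pipeline test: plantable (bound, KO) segment pairs are drawn at
#' `min(1, planted_enrichment * background_contact_rate)` in place of (not
#' in addition to) the background rate.
#'
#' @param n_chromosomes,genes_per_chromosome,gene_spacing_bp genome layout
#' @param segment_length_bp segment tile size (bp)
#' @param n_tfs,bound_size,ko_size regulon sizes
#' @param background_contact_rate Bernoulli contact probability per segment
#'   pair
#' @param planted_enrichment fold elevation of the contact probability on
#'   eligible (bound, KO) segment pairs (>= 1; 1 = exact null)
#' @param cc_coplanting_prob probability a TF joins each cellular-component
#'   term
#' @param bp_coplanting_prob probability a planted SAR gene joins its TF's
#'   biological-process term
#' @param n_conditions expression conditions (default 112)
#' @param expr_block_correlation loading of block genes on their TF's latent
#'   expression factor (in \[0, 1))
#' @param occupancy_offset_sar additive promoter occupancy offset on planted
#'   SAR genes
#' @param motif_rate_sar,motif_rate_other motif presence rates for planted
#'   SAR vs other knockout-affected pairs
#' @param segment_gap_frac fraction of segments removed, to create unmapped
#'   genes deliberately (default 0)
#' @param proximity_bp cross-set linear separation the generator respects
#'   when assigning bound/KO genes, matching the pipeline's exclusion rule
#' @param min_intra_sep_bp intra-chromosomal separation below which no
#'   contact is planted (matching the pipeline's separation filter)
#' @param seed integer seed; fixed seed gives byte-identical output files
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 16, genes_per_chromosome = 375,
                       gene_spacing_bp = 2000, segment_length_bp = 3000,
                       n_tfs = 136, bound_size = 80, ko_size = 160,
                       background_contact_rate = 1.5e-4, planted_enrichment = 3,
                       cc_coplanting_prob = 0.3, bp_coplanting_prob = 0.5,
                       n_conditions = 112, expr_block_correlation = 0.6,
                       occupancy_offset_sar = 0.5,
                       motif_rate_sar = 0.30, motif_rate_other = 0.32,
                       segment_gap_frac = 0, proximity_bp = 3000,
                       min_intra_sep_bp = 60000, seed = 1) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              gene_spacing_bp = as.integer(gene_spacing_bp),
              segment_length_bp = as.integer(segment_length_bp),
              n_tfs = as.integer(n_tfs),
              bound_size = as.integer(bound_size),
              ko_size = as.integer(ko_size),
              background_contact_rate = background_contact_rate,
              planted_enrichment = planted_enrichment,
              cc_coplanting_prob = cc_coplanting_prob,
              bp_coplanting_prob = bp_coplanting_prob,
              n_conditions = as.integer(n_conditions),
              expr_block_correlation = expr_block_correlation,
              occupancy_offset_sar = occupancy_offset_sar,
              motif_rate_sar = motif_rate_sar,
              motif_rate_other = motif_rate_other,
              segment_gap_frac = segment_gap_frac,
              proximity_bp = as.integer(proximity_bp),
              min_intra_sep_bp = as.integer(min_intra_sep_bp),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 1,
              gene_spacing_bp >= 1, segment_length_bp >= 1,
              n_tfs >= 1, bound_size >= 1, ko_size >= 1,
              background_contact_rate >= 0, background_contact_rate <= 1,
              planted_enrichment >= 1,
              cc_coplanting_prob >= 0, cc_coplanting_prob <= 1,
              bp_coplanting_prob >= 0, bp_coplanting_prob <= 1,
              n_conditions >= 3,
              expr_block_correlation >= 0, expr_block_correlation < 1,
              motif_rate_sar >= 0, motif_rate_sar <= 1,
              motif_rate_other >= 0, motif_rate_other <= 1,
              segment_gap_frac >= 0, segment_gap_frac < 1)
    if (genes_per_chromosome * n_chromosomes < 2 * (bound_size + ko_size)) {
      stop("infeasible config: need genes_per_chromosome * n_chromosomes >= ",
           "2 * (bound_size + ko_size)")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Scaled configuration used for fixtures and calibration runs
#'
#' A reduced genome (8 chromosomes x 125 genes, ~660 segments) with contact
#' rate 1e-3. The density is chosen so the background contact network
#' remains much larger than any planted excess, as in real interaction
#' data, where called contacts outnumber the colocalized regulatory pairs
#' by orders of magnitude; a planted signal then shifts the observed
#' frequency without materially inflating the permutation null. A full
#' permutation run on this scale takes under a second.
#'
#' @param planted_enrichment fold contact enrichment (1 = null)
#' @param seed integer seed
#' @param ... overrides passed on to [sim_config()]
#' @return A `sim_config`.
#' @export
fixture_config <- function(planted_enrichment = 1, seed = 1, ...) {
  sim_config(n_chromosomes = 8, genes_per_chromosome = 125,
             gene_spacing_bp = 2000, segment_length_bp = 3000,
             n_tfs = 8, bound_size = 25, ko_size = 30,
             background_contact_rate = 1e-3,
             planted_enrichment = planted_enrichment, seed = seed, ...)
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Produces every input the pipeline consumes, self-consistently, plus a
#' ground-truth record of the planted (bound, KO) contacts and the true SAR
#' labels they imply. Contacts are Bernoulli per eligible segment pair;
#' planting only touches pairs the pipeline's own filters would keep
#' (distinct segments; inter-chromosomal, or intra-chromosomal separated by
#' at least `min_intra_sep_bp`), so a planted SAR label is recoverable by
#' construction. Background contacts cover all separations, so the
#' separation filter is still exercised.
#'
#' @param config a [sim_config()]
#' @return A `sim_data` list: `config`, `genes`, `interactions`, `regulons`,
#'   `cc`, `bp`, `expr`, `occupancy`, `motifs`, `ground_truth` (list with
#'   `planted_pairs` data.frame tf/bound_gene/ko_gene, per-TF `sar_genes`,
#'   and `planted_contacts` data.frame seg_a/seg_b).
#' @export
simulate_dataset <- function(config = sim_config()) {
  withseed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  chrom_names <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  n_genes <- cfg$n_chromosomes * cfg$genes_per_chromosome
  chrom_len <- cfg$genes_per_chromosome * cfg$gene_spacing_bp

  genes <- gene_table(data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    chrom = rep(chrom_names, each = cfg$genes_per_chromosome),
    strand = rep_len(c("+", "-"), n_genes),
    tss = rep((seq_len(cfg$genes_per_chromosome) - 1L) * cfg$gene_spacing_bp +
                cfg$gene_spacing_bp %/% 2L, cfg$n_chromosomes),
    stringsAsFactors = FALSE
  ))

  segs_per_chrom <- max(1L, chrom_len %/% cfg$segment_length_bp)
  seg_start <- (seq_len(segs_per_chrom) - 1L) * cfg$segment_length_bp + 1L
  segments <- data.frame(
    segment_id = sprintf("s%05d", seq_len(segs_per_chrom * cfg$n_chromosomes)),
    chrom = rep(chrom_names, each = segs_per_chrom),
    start = rep(seg_start, cfg$n_chromosomes),
    end = rep(seg_start + cfg$segment_length_bp - 1L, cfg$n_chromosomes),
    stringsAsFactors = FALSE
  )
  if (cfg$segment_gap_frac > 0) {
    drop <- sample.int(nrow(segments), round(cfg$segment_gap_frac * nrow(segments)))
    if (length(drop) > 0) segments <- segments[-drop, , drop = FALSE]
    rownames(segments) <- NULL
  }
  S <- nrow(segments)
  seg_chrom_id <- match(segments$chrom, chrom_names)
  seg_mid <- (segments$start + segments$end) / 2

  # segment containing each TSS (NA where gaps removed it)
  seg_of_gene <- rep(NA_integer_, n_genes)
  for (ci in seq_len(cfg$n_chromosomes)) {
    gi <- which(genes$chrom == chrom_names[ci])
    si <- which(seg_chrom_id == ci)
    if (length(si) == 0) next
    pos <- findInterval(genes$tss[gi], segments$start[si])
    ok <- pos >= 1 & genes$tss[gi] <= segments$end[si][pmax(pos, 1)]
    seg_of_gene[gi[ok]] <- si[pos[ok]]
  }

  # -- TF gene sets, respecting the cross-set linear proximity rule --------
  tf_ids <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  nb <- max(0L, as.integer(ceiling(cfg$proximity_bp / cfg$gene_spacing_bp)) - 1L)
  gene_chrom_id <- rep(seq_len(cfg$n_chromosomes), each = cfg$genes_per_chromosome)
  bound_sets <- vector("list", cfg$n_tfs)
  ko_sets <- vector("list", cfg$n_tfs)
  for (t in seq_len(cfg$n_tfs)) {
    perm <- sample.int(n_genes)
    bmask <- logical(n_genes)
    kmask <- logical(n_genes)
    nb_cnt <- 0L
    nk_cnt <- 0L
    near_set <- function(g, mask) {
      if (nb == 0L) return(FALSE)
      off <- seq_len(nb)
      nbrs <- c(g - off, g + off)
      nbrs <- nbrs[nbrs >= 1 & nbrs <= n_genes]
      nbrs <- nbrs[gene_chrom_id[nbrs] == gene_chrom_id[g]]
      any(mask[nbrs])
    }
    for (g in perm) {
      need_b <- cfg$bound_size - nb_cnt
      need_k <- cfg$ko_size - nk_cnt
      if (need_b == 0L && need_k == 0L) break
      try_b_first <- need_b / cfg$bound_size >= need_k / cfg$ko_size
      placed <- FALSE
      if (try_b_first && need_b > 0L && !kmask[g] && !near_set(g, kmask)) {
        bmask[g] <- TRUE; nb_cnt <- nb_cnt + 1L; placed <- TRUE
      }
      if (!placed && need_k > 0L && !bmask[g] && !near_set(g, bmask)) {
        kmask[g] <- TRUE; nk_cnt <- nk_cnt + 1L; placed <- TRUE
      }
      if (!placed && !try_b_first && need_b > 0L && !kmask[g] && !near_set(g, kmask)) {
        bmask[g] <- TRUE; nb_cnt <- nb_cnt + 1L
      }
    }
    if (nb_cnt < cfg$bound_size || nk_cnt < cfg$ko_size) {
      stop("infeasible config: could not place disjoint, non-proximal gene sets")
    }
    bound_sets[[t]] <- which(bmask)
    ko_sets[[t]] <- which(kmask)
  }

  # -- contacts: background everywhere except plantable pairs --------------
  M <- S * (S - 1) / 2
  plantable <- plantable_pairs(bound_sets, ko_sets, seg_of_gene, seg_chrom_id,
                               seg_mid, S, cfg$min_intra_sep_bp)
  plant_keys <- unique(plantable$key)
  p_plant <- min(1, cfg$planted_enrichment * cfg$background_contact_rate)
  drawn_keys <- plant_keys[stats::runif(length(plant_keys)) < p_plant]

  n_bg <- stats::rbinom(1, M, cfg$background_contact_rate)
  bg_keys <- pair_rank_to_key(sample.int(M, n_bg), S)
  bg_keys <- setdiff(bg_keys, plant_keys)

  all_keys <- c(bg_keys, drawn_keys)
  ij <- key_to_pair(all_keys, S)
  pairs <- data.frame(seg_a = segments$segment_id[ij$i],
                      seg_b = segments$segment_id[ij$j],
                      fdr = stats::runif(length(all_keys), 0, 1e-4),
                      stringsAsFactors = FALSE)
  interactions <- interaction_set(segments, pairs, fdr_cutoff = 1e-4)

  planted_idx <- plantable[plantable$key %in% drawn_keys, , drop = FALSE]
  planted_pairs <- data.frame(
    tf = tf_ids[planted_idx$tf],
    bound_gene = genes$gene_id[planted_idx$b],
    ko_gene = genes$gene_id[planted_idx$k],
    stringsAsFactors = FALSE
  )
  sar_truth <- lapply(seq_len(cfg$n_tfs), function(t) {
    unique(planted_pairs$ko_gene[planted_pairs$tf == tf_ids[t]])
  })
  names(sar_truth) <- tf_ids
  planted_sar_all <- unique(unlist(sar_truth, use.names = FALSE))

  # -- regulons ------------------------------------------------------------
  regulons <- lapply(seq_len(cfg$n_tfs), function(t) {
    b <- bound_sets[[t]]
    bp_vals <- 10^(-stats::runif(length(b), 2.35, 6))
    tf_regulon(tf_ids[t],
               data.frame(gene_id = genes$gene_id[b], binding_p = bp_vals,
                          binding_score = -log10(bp_vals),
                          stringsAsFactors = FALSE),
               genes$gene_id[ko_sets[[t]]])
  })
  names(regulons) <- tf_ids

  # -- annotations ---------------------------------------------------------
  n_cc <- max(8L, as.integer(round(cfg$n_tfs / 6)))
  cc_terms <- lapply(seq_len(n_cc), function(i) {
    tfs_in <- tf_ids[stats::runif(cfg$n_tfs) < cfg$cc_coplanting_prob]
    genes_in <- genes$gene_id[stats::runif(n_genes) < 0.02]
    unique(c(tfs_in, genes_in))
  })
  names(cc_terms) <- sprintf("CC%03d", seq_len(n_cc))
  # every TF belongs to at least one component
  for (tf in tf_ids) {
    if (!any(vapply(cc_terms, function(g) tf %in% g, logical(1)))) {
      pick <- sample.int(n_cc, 1)
      cc_terms[[pick]] <- c(cc_terms[[pick]], tf)
    }
  }
  cc <- annotation_set("CC", cc_terms[lengths(cc_terms) > 0])

  bp_terms <- lapply(seq_len(cfg$n_tfs), function(t) {
    b <- genes$gene_id[bound_sets[[t]]]
    members <- b[stats::runif(length(b)) < 0.7]
    sar_t <- sar_truth[[t]]
    members <- c(members, sar_t[stats::runif(length(sar_t)) < cfg$bp_coplanting_prob])
    unique(members)
  })
  names(bp_terms) <- sprintf("BP%03d", seq_len(cfg$n_tfs))
  n_bp_bg <- 30L
  bg_terms <- lapply(seq_len(n_bp_bg), function(i) {
    genes$gene_id[stats::runif(n_genes) < 0.01]
  })
  names(bg_terms) <- sprintf("BPbg%03d", seq_len(n_bp_bg))
  bp_all <- c(bp_terms, bg_terms)
  bp <- annotation_set("BP", bp_all[lengths(bp_all) > 0])

  # -- expression: latent block factors ------------------------------------
  expr <- matrix(stats::rnorm(n_genes * cfg$n_conditions), n_genes,
                 dimnames = list(genes$gene_id,
                                 sprintf("cond%03d", seq_len(cfg$n_conditions))))
  block <- integer(n_genes)
  for (t in seq_len(cfg$n_tfs)) {
    members <- union(bound_sets[[t]],
                     match(sar_truth[[t]], genes$gene_id))
    members <- members[!is.na(members)]
    members <- members[block[members] == 0L]
    block[members] <- t
  }
  factors <- matrix(stats::rnorm(cfg$n_tfs * cfg$n_conditions), cfg$n_tfs)
  lam <- cfg$expr_block_correlation
  in_block <- which(block > 0L)
  if (length(in_block) > 0 && lam > 0) {
    expr[in_block, ] <- lam * factors[block[in_block], , drop = FALSE] +
      sqrt(1 - lam^2) * expr[in_block, , drop = FALSE]
  }

  # -- occupancy and motifs ------------------------------------------------
  occupancy <- matrix(stats::rnorm(n_genes * 500, mean = 1, sd = 0.2),
                      n_genes, 500, dimnames = list(genes$gene_id, NULL))
  sar_rows <- match(planted_sar_all, genes$gene_id)
  if (length(sar_rows) > 0) {
    occupancy[sar_rows, ] <- occupancy[sar_rows, ] + cfg$occupancy_offset_sar
  }

  motif_rows <- do.call(rbind, lapply(seq_len(cfg$n_tfs), function(t) {
    kg <- genes$gene_id[ko_sets[[t]]]
    is_sar <- kg %in% sar_truth[[t]]
    rate <- ifelse(is_sar, cfg$motif_rate_sar, cfg$motif_rate_other)
    keep <- stats::runif(length(kg)) < rate
    if (!any(keep)) return(NULL)
    data.frame(tf = tf_ids[t], gene = kg[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(motif_rows)) {
    motif_rows <- data.frame(tf = character(), gene = character())
  }
  motifs <- motif_table(motif_rows)

  structure(list(config = cfg, genes = genes, interactions = interactions,
                 regulons = regulons, cc = cc, bp = bp, expr = expr,
                 occupancy = occupancy, motifs = motifs,
                 ground_truth = list(
                   planted_pairs = planted_pairs,
                   sar_genes = sar_truth,
                   planted_contacts = data.frame(
                     seg_a = segments$segment_id[pmin(key_i(drawn_keys, S),
                                                      key_j(drawn_keys, S))],
                     seg_b = segments$segment_id[pmax(key_i(drawn_keys, S),
                                                      key_j(drawn_keys, S))],
                     stringsAsFactors = FALSE))),
            class = "sim_data")
}

# cross pairs of (bound segment, ko segment) per TF that the pipeline's
# filters keep: distinct segments, inter or intra separated >= min_sep
plantable_pairs <- function(bound_sets, ko_sets, seg_of_gene, seg_chrom_id,
                            seg_mid, S, min_sep) {
  out <- vector("list", length(bound_sets))
  for (t in seq_along(bound_sets)) {
    b <- bound_sets[[t]]
    k <- ko_sets[[t]]
    bi <- rep(b, times = length(k))
    ki <- rep(k, each = length(b))
    sa <- seg_of_gene[bi]
    sb <- seg_of_gene[ki]
    ok <- !is.na(sa) & !is.na(sb) & sa != sb
    same <- ok & seg_chrom_id[sa] == seg_chrom_id[sb]
    ok[same] <- abs(seg_mid[sa[same]] - seg_mid[sb[same]]) >= min_sep
    if (!any(ok)) next
    i <- pmin(sa[ok], sb[ok])
    j <- pmax(sa[ok], sb[ok])
    out[[t]] <- data.frame(tf = t, b = bi[ok], k = ki[ok],
                           key = (i - 1) * S + j)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(tf = integer(), b = integer(),
                                      k = integer(), key = numeric())
  res
}

# uniform rank in 1..choose(S,2) -> canonical pair key (i-1)*S + j, i < j
pair_rank_to_key <- function(rank, S) {
  if (length(rank) == 0) return(numeric(0))
  cum <- cumsum(S - seq_len(S - 1))
  i <- findInterval(rank - 0.5, c(0, cum))
  j <- i + (rank - c(0, cum)[i])
  (i - 1) * S + j
}

key_i <- function(key, S) as.integer((key - 1) %/% S + 1)
key_j <- function(key, S) as.integer((key - 1) %% S + 1)

key_to_pair <- function(key, S) {
  list(i = key_i(key, S), j = key_j(key, S))
}

#' Write a synthetic dataset as the plain TSV files the readers consume
#'
#' @param sim a [simulate_dataset()] result
#' @param dir output directory (created if needed)
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genes = file.path(dir, "genes.tsv"),
    segments = file.path(dir, "segments.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    binding = file.path(dir, "binding.tsv"),
    knockout = file.path(dir, "knockout.tsv"),
    cc = file.path(dir, "annotations_cc.tsv"),
    bp = file.path(dir, "annotations_bp.tsv"),
    expression = file.path(dir, "expression.tsv"),
    occupancy = file.path(dir, "occupancy.tsv"),
    motifs = file.path(dir, "motifs.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_gene_table(sim$genes, paths["genes"])
  write_interactions(sim$interactions, paths["interactions"], paths["segments"])
  write_regulons(sim$regulons, paths["binding"], paths["knockout"])
  write_annotations(sim$cc, paths["cc"])
  write_annotations(sim$bp, paths["bp"])
  write_expression(sim$expr, paths["expression"])
  write_occupancy(sim$occupancy, paths["occupancy"])
  write_motifs(sim$motifs, paths["motifs"])
  jsonlite::write_json(sim$ground_truth, paths["ground_truth"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory
#' @param binding_p_cutoff,fdr_cutoff load-time cutoffs
#' @return A list with the same data elements as [simulate_dataset()]
#'   (ground truth included when present).
#' @export
read_dataset <- function(dir, binding_p_cutoff = 0.005, fdr_cutoff = 1e-4) {
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  out <- list(
    genes = genes,
    interactions = read_interactions(file.path(dir, "interactions.tsv"),
                                     file.path(dir, "segments.tsv"),
                                     fdr_cutoff = fdr_cutoff),
    regulons = read_regulons(file.path(dir, "binding.tsv"),
                             file.path(dir, "knockout.tsv"),
                             binding_p_cutoff = binding_p_cutoff,
                             genes = genes),
    cc = read_annotations(file.path(dir, "annotations_cc.tsv")),
    bp = read_annotations(file.path(dir, "annotations_bp.tsv")),
    expr = read_expression(file.path(dir, "expression.tsv")),
    occupancy = read_occupancy(file.path(dir, "occupancy.tsv")),
    motifs = read_motifs(file.path(dir, "motifs.tsv"))
  )
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt$sar_genes <- lapply(gt$sar_genes, as.character)
    out$ground_truth <- gt
  }
  out
}

#' Write the canonical null / weak / strong fixture suite
#'
#' Three [fixture_config()] datasets at planted enrichments 1, 2 and 5,
#' with a JSON manifest of seeds and configurations. Re-running with the
#' same seed reproduces identical files.
#'
#' @param out_dir output directory
#' @param seed master seed for the suite
#' @return Invisibly, the manifest list.
#' @export
write_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  enrich <- c(null = 1, weak = 2, strong = 5)
  sub_seeds <- withseed(seed, sample.int(2147483646L, length(enrich)))
  manifest <- list(seed = seed, fixtures = list())
  for (i in seq_along(enrich)) {
    name <- names(enrich)[i]
    cfg <- fixture_config(planted_enrichment = enrich[[i]], seed = sub_seeds[i])
    sim <- simulate_dataset(cfg)
    write_dataset(sim, file.path(out_dir, name))
    manifest$fixtures[[name]] <- list(dir = name, seed = sub_seeds[i],
                                      config = unclass(cfg))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
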