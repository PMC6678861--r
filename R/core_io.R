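#' Construct a validated gene table
#'
#' The gene table is the coordinate backbone of the analysis: one row per
#' gene with its chromosome, strand and transcription start site (TSS). All
#' distance rules (gene-segment mapping, linear proximity exclusion) are
#' anchored on the TSS. Coordinates are 1-based; the TSS is a single base.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `strand` (`"+"` or
#'   `"-"`) and `tss` (integer, >= 1).
#' @return A `gene_table` (a validated data.frame).
#' @export
gene_table <- function(df) {
  req <- c("gene_id", "chrom", "strand", "tss")
  if (!is.data.frame(df)) stop("gene table must be a data.frame")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("gene table is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- df[req]
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  tss <- suppressWarnings(as.integer(df$tss))
  bad <- which(is.na(tss))
  if (length(bad) > 0) {
    stop("non-integer tss at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  df$tss <- tss
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(df$tss < 1)) stop("tss must be >= 1 (1-based coordinates)")
  if (any(!nzchar(df$chrom))) stop("chromosome must be nonempty")
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Read a gene table from a TSV file
#'
#' @param path TSV with header `gene_id`, `chrom`, `strand`, `tss`.
#' @return A [gene_table()].
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "chrom", "strand", "tss"))
  gene_table(df)
}

#' @rdname read_gene_table
#' @param genes a `gene_table`
#' @export
write_gene_table <- function(genes, path) {
  write_tsv(as.data.frame(genes), path)
}

#' Construct a validated interaction set
#'
#' An interaction set holds the kilobase-resolution genome segments and the
#' filtered list of unordered segment pairs called as 3D contacts. Pair kind
#' (`inter`/`intra`) is recomputed from the segments' chromosomes; if the
#' input carries a `kind` column it must agree. Pairs are canonicalized
#' (`seg_a < seg_b`), deduplicated, and self pairs are rejected. Only pairs
#' with `fdr <= fdr_cutoff` are retained.
#'
#' @param segments data.frame with `segment_id`, `chrom`, `start`, `end`
#'   (1-based, closed intervals).
#' @param pairs data.frame with `seg_a`, `seg_b`, `fdr` and optionally `kind`.
#' @param fdr_cutoff FDR cutoff applied at load time (default `1e-4`).
#' @return An `interaction_set` list with elements `segments`, `pairs`,
#'   `fdr_cutoff`.
#' @export
interaction_set <- function(segments, pairs, fdr_cutoff = 1e-4) {
  seg_req <- c("segment_id", "chrom", "start", "end")
  if (length(setdiff(seg_req, names(segments))) > 0) {
    stop("segments need columns: ", paste(seg_req, collapse = ", "))
  }
  segments <- segments[seg_req]
  segments$segment_id <- as.character(segments$segment_id)
  segments$chrom <- as.character(segments$chrom)
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  if (anyDuplicated(segments$segment_id)) stop("duplicate segment_id")
  if (any(segments$start < 1) || any(segments$end < 1)) {
    stop("segment coordinates must be positive (1-based)")
  }
  if (any(segments$start > segments$end)) stop("segment start > end")

  pr_req <- c("seg_a", "seg_b", "fdr")
  if (length(setdiff(pr_req, names(pairs))) > 0) {
    stop("pairs need columns: ", paste(pr_req, collapse = ", "))
  }
  pairs$seg_a <- as.character(pairs$seg_a)
  pairs$seg_b <- as.character(pairs$seg_b)
  pairs$fdr <- as.numeric(pairs$fdr)
  unknown <- setdiff(c(pairs$seg_a, pairs$seg_b), segments$segment_id)
  if (length(unknown) > 0) {
    stop("unknown segment id in pairs: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (any(pairs$seg_a == pairs$seg_b)) stop("self segment pair not allowed")

  pairs <- pairs[pairs$fdr <= fdr_cutoff, , drop = FALSE]
  chrom_of <- stats::setNames(segments$chrom, segments$segment_id)
  kind <- ifelse(chrom_of[pairs$seg_a] == chrom_of[pairs$seg_b], "intra", "inter")
  if ("kind" %in% names(pairs)) {
    mism <- which(as.character(pairs$kind) != kind)
    if (length(mism) > 0) {
      stop("pair kind label inconsistent with segment chromosomes at row(s): ",
           paste(utils::head(mism, 5), collapse = ", "))
    }
  }
  # canonical unordered representation, deduplicated
  swap <- pairs$seg_a > pairs$seg_b
  tmp <- pairs$seg_a[swap]
  pairs$seg_a[swap] <- pairs$seg_b[swap]
  pairs$seg_b[swap] <- tmp
  key <- paste(pairs$seg_a, pairs$seg_b)
  keep <- !duplicated(key)
  pairs <- data.frame(seg_a = pairs$seg_a[keep], seg_b = pairs$seg_b[keep],
                      kind = kind[keep], fdr = pairs$fdr[keep],
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(segments = segments, pairs = pairs, fdr_cutoff = fdr_cutoff),
            class = "interaction_set")
}

#' Read an interaction set (segment table + BEDPE-like pair table)
#'
#' @param pairs_path TSV with columns `seg_a`, `seg_b`, `fdr` and optional
#'   `kind`; rows above the FDR cutoff are dropped at load time.
#' @param segments_path TSV with `segment_id`, `chrom`, `start`, `end`.
#' @param fdr_cutoff FDR cutoff (default `1e-4`, the value used to call the
#'   contacts in the source interaction data).
#' @return An [interaction_set()].
#' @export
read_interactions <- function(pairs_path, segments_path, fdr_cutoff = 1e-4) {
  segments <- read_tsv_checked(segments_path, c("segment_id", "chrom", "start", "end"))
  pairs <- read_tsv_checked(pairs_path, c("seg_a", "seg_b", "fdr"))
  interaction_set(segments, pairs, fdr_cutoff = fdr_cutoff)
}

#' @rdname read_interactions
#' @param interactions an `interaction_set`
#' @export
write_interactions <- function(interactions, pairs_path, segments_path) {
  write_tsv(interactions$segments, segments_path)
  write_tsv(interactions$pairs, pairs_path)
}

#' Construct a TF regulon
#'
#' A regulon couples one TF's bound-gene set (with ChIP binding scores) and
#' its knockout-affected gene set.
#'
#' @param tf_id TF identifier.
#' @param bound data.frame with `gene_id`, `binding_p`, `binding_score`.
#' @param ko_affected character vector of knockout-affected gene ids.
#' @return A `tf_regulon` list.
#' @export
tf_regulon <- function(tf_id, bound, ko_affected) {
  if (is.null(bound) || nrow(bound) == 0) {
    bound <- data.frame(gene_id = character(), binding_p = numeric(),
                        binding_score = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "binding_p", "binding_score") %in% names(bound)))
  bound$gene_id <- as.character(bound$gene_id)
  if (anyDuplicated(bound$gene_id)) stop("duplicate bound gene for TF ", tf_id)
  rownames(bound) <- NULL
  structure(list(tf_id = as.character(tf_id), bound = bound,
                 ko_affected = unique(as.character(ko_affected))),
            class = "tf_regulon")
}

#' Read TF regulons from binding and knockout tables
#'
#' Bound sets are defined by the ChIP binding P-value cutoff (inclusive);
#' the stored `binding_score` is `-log10(binding_p)`, a per-event binding
#' affinity proxy. Gene ids absent from `genes` are dropped with a message
#' reporting the count. TFs present only in the knockout table get an empty
#' bound set (and vice versa); such regulons carry `missing_binding` /
#' `missing_ko` attributes.
#'
#' @param binding_path TSV with `tf`, `gene`, `binding_p` rows.
#' @param ko_path TSV with `tf`, `gene` rows.
#' @param binding_p_cutoff binding P-value cutoff (default `0.005`).
#' @param genes optional [gene_table()] used to drop unknown gene ids.
#' @param score `"neglog10"` (default) stores `-log10(binding_p)` as the
#'   binding score; `"raw"` stores `binding_p` unchanged.
#' @return Named list of [tf_regulon()].
#' @export
read_regulons <- function(binding_path, ko_path, binding_p_cutoff = 0.005,
                          genes = NULL, score = c("neglog10", "raw")) {
  score <- match.arg(score)
  binding <- read_tsv_checked(binding_path, c("tf", "gene", "binding_p"))
  ko <- read_tsv_checked(ko_path, c("tf", "gene"))
  binding$tf <- as.character(binding$tf)
  binding$gene <- as.character(binding$gene)
  ko$tf <- as.character(ko$tf)
  ko$gene <- as.character(ko$gene)
  if (!is.null(genes)) {
    known <- genes$gene_id
    n_drop <- sum(!binding$gene %in% known) + sum(!ko$gene %in% known)
    if (n_drop > 0) {
      message("read_regulons: dropping ", n_drop, " rows with gene ids absent from gene table")
    }
    binding <- binding[binding$gene %in% known, , drop = FALSE]
    ko <- ko[ko$gene %in% known, , drop = FALSE]
  }
  binding <- binding[binding$binding_p <= binding_p_cutoff, , drop = FALSE]
  tfs <- sort(unique(c(binding$tf, ko$tf)))
  regs <- lapply(tfs, function(tf) {
    b <- binding[binding$tf == tf, , drop = FALSE]
    bs <- if (score == "neglog10") -log10(b$binding_p) else b$binding_p
    r <- tf_regulon(tf,
                    data.frame(gene_id = b$gene, binding_p = b$binding_p,
                               binding_score = bs, stringsAsFactors = FALSE),
                    ko$gene[ko$tf == tf])
    attr(r, "missing_binding") <- !tf %in% binding$tf
    attr(r, "missing_ko") <- !tf %in% ko$tf
    r
  })
  stats::setNames(regs, tfs)
}

#' @rdname read_regulons
#' @param regulons named list of `tf_regulon`
#' @export
write_regulons <- function(regulons, binding_path, ko_path) {
  b <- do.call(rbind, lapply(regulons, function(r) {
    if (nrow(r$bound) == 0) return(NULL)
    data.frame(tf = r$tf_id, gene = r$bound$gene_id,
               binding_p = r$bound$binding_p, stringsAsFactors = FALSE)
  }))
  if (is.null(b)) b <- data.frame(tf = character(), gene = character(), binding_p = numeric())
  k <- do.call(rbind, lapply(regulons, function(r) {
    if (length(r$ko_affected) == 0) return(NULL)
    data.frame(tf = r$tf_id, gene = r$ko_affected, stringsAsFactors = FALSE)
  }))
  if (is.null(k)) k <- data.frame(tf = character(), gene = character())
  write_tsv(b, binding_path)
  write_tsv(k, ko_path)
}

#' Construct a flat annotation set (GO-style term -> gene mapping)
#'
#' Flat set semantics: no ontology graph, a term is just a nonempty gene set.
#' TFs are annotated as genes.
#'
#' @param category `"CC"` (cellular component) or `"BP"` (biological process).
#' @param terms named list mapping term id to a character vector of gene ids.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(category, terms) {
  category <- match.arg(category, c("CC", "BP"))
  if (length(terms) > 0 && is.null(names(terms))) stop("terms must be named")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  empty <- names(terms)[lengths(terms) == 0]
  if (length(empty) > 0) stop("empty term(s): ", paste(utils::head(empty, 5), collapse = ", "))
  structure(list(category = category, terms = terms), class = "annotation_set")
}

#' Read a flat annotation table
#'
#' @param path TSV with columns `term`, `category`, `gene`.
#' @param category optional filter, `"CC"` or `"BP"`; required if the file
#'   mixes categories.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, category = NULL) {
  df <- read_tsv_checked(path, c("term", "category", "gene"))
  if (!is.null(category)) df <- df[df$category == category, , drop = FALSE]
  cats <- unique(df$category)
  if (length(cats) != 1) {
    stop("annotation file holds categories [", paste(cats, collapse = ", "),
         "]; pass `category` to select one")
  }
  annotation_set(cats, split(as.character(df$gene), as.character(df$term)))
}

#' @rdname read_annotations
#' @param annotations an `annotation_set`
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    term = rep(names(annotations$terms), lengths(annotations$terms)),
    category = annotations$category,
    gene = unlist(annotations$terms, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Read an expression matrix (genes x conditions)
#'
#' Rows with fewer than 3 non-missing values are dropped with a message;
#' the dropped count is attached as attribute `n_dropped`.
#'
#' @param path TSV, first column `gene_id`, remaining columns conditions;
#'   missing values as `NA`.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("expression file must start with a gene_id column")
  ids <- as.character(df$gene_id)
  if (anyDuplicated(ids)) stop("duplicate gene_id in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  ok <- rowSums(!is.na(m)) >= 3
  if (any(!ok)) {
    message("read_expression: dropping ", sum(!ok), " rows with < 3 non-missing values")
  }
  out <- m[ok, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' @rdname read_expression
#' @param expr numeric matrix with gene rownames
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read promoter nucleosome occupancy tracks
#'
#' One row per gene, 500 columns covering promoter positions
#' \eqn{[-500, -1]} relative to the TSS in transcription direction, so the
#' last column abuts the TSS regardless of strand (tracks are stored already
#' strand-oriented; see [orient_profile()]).
#'
#' @param path TSV, first column `gene_id`, then 500 numeric columns.
#' @return Numeric matrix genes x 500.
#' @export
read_occupancy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("occupancy file must start with a gene_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (ncol(m) != 500) stop("occupancy track must have 500 positions, got ", ncol(m))
  rownames(m) <- as.character(df$gene_id)
  if (anyDuplicated(rownames(m))) stop("duplicate gene_id in occupancy table")
  m
}

#' @rdname read_occupancy
#' @param occ numeric matrix genes x 500
#' @export
write_occupancy <- function(occ, path) {
  df <- data.frame(gene_id = rownames(occ), occ, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("gene_id", paste0("p", seq_len(ncol(occ))))
  write_tsv(df, path)
}

#' Read a motif presence list
#'
#' Rows are (TF, gene) pairs for which the TF's DNA motif is present in the
#' gene's promoter (without the TF binding there). Absence of a row means no
#' motif.
#'
#' @param path TSV with columns `tf`, `gene`.
#' @return A `motif_table` data.frame.
#' @export
read_motifs <- function(path) {
  df <- read_tsv_checked(path, c("tf", "gene"))
  motif_table(df)
}

#' @rdname read_motifs
#' @param motifs a `motif_table`
#' @export
write_motifs <- function(motifs, path) {
  write_tsv(as.data.frame(motifs), path)
}

#' @rdname read_motifs
#' @param df data.frame with columns `tf`, `gene`
#' @export
motif_table <- function(df) {
  stopifnot(all(c("tf", "gene") %in% names(df)))
  df <- data.frame(tf = as.character(df$tf), gene = as.character(df$gene),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$tf, df$gene)), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("motif_table", "data.frame")
  df
}

#' Test motif presence for (TF, gene) pairs
#'
#' @param motifs a [motif_table()]
#' @param tf,gene character vectors (recycled to common length)
#' @return Logical vector.
#' @export
has_motif <- function(motifs, tf, gene) {
  paste(tf, gene) %in% paste(motifs$tf, motifs$gene)
}

# -- internal TSV helpers ----------------------------------------------------

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
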