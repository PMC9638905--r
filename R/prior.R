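# Construction of the binary TF-target prior from an accessible-chromatin
# peak atlas, motif-scan hits, and gene annotation. Coordinates follow the
# BED convention (0-based, half-open) throughout.

# ---- readers ------------------------------------------------------------

#' Read a peak atlas from BED3+name
#'
#' @param path BED file with columns chrom, start, end, name (no header).
#' @return data.frame with `chrom`, `start`, `end`, `peak_id`.
#' @export
read_peak_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("peak BED needs 4 columns (chrom, start, end, name)")
  bed <- bed[, 1:4]
  names(bed) <- c("chrom", "start", "end", "peak_id")
  if (any(bed$start >= bed$end)) stop("peak with start >= end")
  if (anyDuplicated(bed$peak_id)) stop("duplicate peak ids")
  bed
}

#' Read motif-scan hits in the FIMO tab-delimited dialect
#'
#' Expects the standard columns (`motif_id`, `motif_alt_id`,
#' `sequence_name`, `start`, `stop`, `strand`, `score`, `p-value`,
#' `q-value`, `matched_sequence`); `sequence_name` is matched to peak ids.
#' Hits above `max_p` are dropped defensively (the upstream scan threshold
#' is re-applied on load).
#'
#' @param path FIMO TSV path.
#' @param max_p p-value threshold (default `1e-5`).
#' @return data.frame with `motif_id`, `peak_id`, `score`, `p_value`.
#' @export
read_fimo <- function(path, max_p = 1e-5) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  need <- c("motif_id", "sequence_name", "score", "p-value")
  if (!all(need %in% names(tab)))
    stop("FIMO table lacks columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  out <- data.frame(motif_id = tab$motif_id, peak_id = tab$sequence_name,
                    score = tab$score, p_value = tab[["p-value"]],
                    stringsAsFactors = FALSE)
  out[out$p_value <= max_p, , drop = FALSE]
}

#' Read a gene annotation table
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `tss`,
#'   `three_prime_end`, `strand`.
#' @return the validated data.frame.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "three_prime_end", "strand")
  if (!all(need %in% names(ann)))
    stop("gene annotation lacks columns: ", paste(setdiff(need, names(ann)), collapse = ", "))
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids")
  plus <- ann$strand == "+"
  if (any(plus & ann$tss > ann$three_prime_end) ||
      any(!plus & ann$tss < ann$three_prime_end))
    stop("tss/3'-end order inconsistent with strand")
  ann
}

#' Read a TF expression-presence table
#'
#' @param path TSV: first column TF id, remaining columns the fraction of
#'   samples expressing the TF per tumor type (values in `[0, 1]`).
#' @return numeric matrix, TFs x tumor types.
#' @export
read_tf_presence <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("presence values outside [0, 1]")
  m
}

# ---- operations ---------------------------------------------------------

gene_windows <- function(ann, flank) {
  lo <- pmin(ann$tss, ann$three_prime_end)
  hi <- pmax(ann$tss, ann$three_prime_end)
  data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
             start = pmax(lo - flank, 0), end = hi + flank,
             tss = ann$tss, stringsAsFactors = FALSE)
}

#' Assign accessible peaks to genes
#'
#' A peak is assigned to a gene when it overlaps (by at least 1 bp) the
#' gene's transcription unit (the span between the TSS and the 3' end)
#' extended by `flank` bp. Because the window is the whole unit span, the
#' strand-aware rule ("upstream of the TSS and downstream of the 3' end")
#' and a symmetric expansion of the span coincide. Negative window starts
#' are clipped to 0. A peak may be assigned to several genes; with
#' `nearest_only = TRUE` each peak keeps only the gene with the closest TSS
#' among its window hits (ties to the first gene in annotation order).
#'
#' @param atlas peak data.frame (`chrom`, `start`, `end`, `peak_id`;
#'   0-based half-open).
#' @param ann gene annotation data.frame (see [read_gene_annotation()]).
#' @param flank window extension in bp (default 100 kb).
#' @param nearest_only keep only the nearest-TSS gene per peak.
#' @return named list: gene id -> character vector of assigned peak ids
#'   (empty vectors for genes without peaks). Peaks on chromosomes absent
#'   from the annotation are skipped with a warning.
#' @export
assign_peaks_to_genes <- function(atlas, ann, flank = 1e5, nearest_only = FALSE) {
  stopifnot(flank >= 0)
  win <- gene_windows(ann, flank)
  unknown <- setdiff(unique(atlas$chrom), unique(ann$chrom))
  if (length(unknown)) {
    warning("peaks on chromosomes absent from the annotation skipped: ",
            paste(unknown, collapse = ", "))
    atlas <- atlas[!(atlas$chrom %in% unknown), , drop = FALSE]
  }
  gr_peak <- GenomicRanges::GRanges(
    atlas$chrom, IRanges::IRanges(atlas$start + 1L, atlas$end))  # to 1-based closed
  gr_win <- GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(win$start + 1L, win$end))
  ov <- GenomicRanges::findOverlaps(gr_peak, gr_win)
  pi <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  if (nearest_only && length(pi)) {
    mid <- (atlas$start[pi] + atlas$end[pi]) / 2
    d <- abs(mid - win$tss[gi])
    keep <- unlist(lapply(split(seq_along(pi), pi), function(ii) ii[which.min(d[ii])]),
                   use.names = FALSE)
    pi <- pi[keep]; gi <- gi[keep]
  }
  out <- split(atlas$peak_id[pi], factor(win$gene_id[gi], levels = win$gene_id))
  lapply(out, as.character)
}

#' Aggregate motif scores over each gene's assigned peaks
#'
#' Entry (gene, motif) is the maximum motif score across the gene's
#' assigned peaks, or 0 when no assigned peak carries the motif.
#'
#' @param assignment gene -> peak-id list from [assign_peaks_to_genes()].
#' @param hits motif hit data.frame from [read_fimo()] (columns `motif_id`,
#'   `peak_id`, `score`).
#' @return numeric matrix, genes x motifs.
#' @export
aggregate_motif_scores <- function(assignment, hits) {
  motifs <- sort(unique(hits$motif_id))
  genes <- names(assignment)
  scores <- matrix(0, length(genes), length(motifs),
                   dimnames = list(genes, motifs))
  if (!length(motifs)) return(scores)
  peak_of_gene <- data.frame(
    gene = rep(genes, lengths(assignment)),
    peak_id = unlist(assignment, use.names = FALSE), stringsAsFactors = FALSE)
  joined <- merge(peak_of_gene, hits, by = "peak_id")
  if (nrow(joined)) {
    agg <- stats::aggregate(score ~ gene + motif_id, data = joined, FUN = max)
    scores[cbind(agg$gene, agg$motif_id)] <- agg$score
  }
  scores
}

#' Filter TFs by expression presence
#'
#' A TF is retained when it is expressed in at least `threshold` of samples
#' in at least one tumor type (i.e. its maximum presence across types
#' reaches the threshold).
#'
#' @param presence TFs x tumor-types matrix of presence fractions.
#' @param threshold minimum presence fraction (default 0.5).
#' @param tfs optional TF universe; TFs absent from `presence` are dropped
#'   with a warning.
#' @return character vector of retained TF ids.
#' @export
filter_tfs_by_expression <- function(presence, threshold = 0.5, tfs = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!is.null(tfs)) {
    miss <- setdiff(tfs, rownames(presence))
    if (length(miss))
      warning("TFs absent from the presence table dropped: ",
              paste(miss, collapse = ", "))
    presence <- presence[intersect(tfs, rownames(presence)), , drop = FALSE]
  }
  keep <- apply(presence, 1, max, na.rm = TRUE) >= threshold
  rownames(presence)[keep]
}

#' Per-TF predicted target peak sets
#'
#' @param hits motif hit data.frame (`motif_id`, `peak_id`).
#' @param tfs optional TF subset.
#' @return named list: TF -> character vector of peak ids with a hit.
#' @export
tf_target_peak_sets <- function(hits, tfs = NULL) {
  if (is.null(tfs)) tfs <- sort(unique(hits$motif_id))
  sets <- split(hits$peak_id, factor(hits$motif_id, levels = tfs))
  lapply(sets, function(p) unique(as.character(p)))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Collapse redundant TFs by target-set Jaccard similarity
#'
#' Iterates to convergence: while any surviving pair has Jaccard index above
#' `cutoff`, the pair with the highest index is handled first (ties by
#' lexicographically smallest pair); each member of the pair is scored by
#' its mean Jaccard index against all other survivors, and the member with
#' the larger mean is removed (ties: the lexicographically larger id is
#' removed). Empty target sets have Jaccard 0 against everything. Running
#' the procedure again on its own output removes nothing further.
#'
#' @param target_sets named list: TF -> peak-id vector.
#' @param cutoff Jaccard threshold in (0, 1] (default 0.5; pairs strictly
#'   above it are redundant).
#' @return character vector of removed TF ids (possibly empty).
#' @export
deduplicate_tfs_by_jaccard <- function(target_sets, cutoff = 0.5) {
  stopifnot(cutoff > 0, cutoff <= 1)
  alive <- names(target_sets)
  removed <- character(0)
  repeat {
    if (length(alive) < 2) break
    J <- matrix(0, length(alive), length(alive), dimnames = list(alive, alive))
    for (a in seq_along(alive)) for (b in seq_along(alive)) if (a < b) {
      J[a, b] <- J[b, a] <- jaccard(target_sets[[alive[a]]], target_sets[[alive[b]]])
    }
    offend <- which(J > cutoff, arr.ind = TRUE)
    offend <- offend[offend[, 1] < offend[, 2], , drop = FALSE]
    if (!nrow(offend)) break
    # most redundant pair first; ties by lexicographically smallest pair
    pa <- pmin(alive[offend[, 1]], alive[offend[, 2]])
    pb <- pmax(alive[offend[, 1]], alive[offend[, 2]])
    jv <- J[offend]
    pick <- order(-jv, pa, pb)[1]
    a <- alive[offend[pick, 1]]; b <- alive[offend[pick, 2]]
    mean_j <- function(x) mean(J[x, setdiff(alive, x)])
    drop_tf <- if (mean_j(a) > mean_j(b)) a
               else if (mean_j(b) > mean_j(a)) b
               else max(a, b)   # lexicographic tie-break
    removed <- c(removed, drop_tf)
    alive <- setdiff(alive, drop_tf)
  }
  removed
}

#' Binarize aggregated motif scores into the TF-target prior
#'
#' `C[g, tf] = 1` iff the aggregated (max-pooled) motif score of `tf` over
#' `g`'s assigned peaks is positive — i.e. at least one assigned peak
#' carries a significant hit — and `tf` survived expression filtering and
#' deduplication. Rows are restricted to `gene_panel` when given. TFs with
#' an all-zero column are retained but reported via a message.
#'
#' @param scores genes x motifs matrix from [aggregate_motif_scores()].
#' @param retained_tfs TFs surviving [filter_tfs_by_expression()] and
#'   [deduplicate_tfs_by_jaccard()]; must be a subset of the score columns.
#' @param gene_panel optional character vector restricting (and ordering)
#'   the gene rows, e.g. the modelled expression panel.
#' @return binary matrix, genes x TFs.
#' @export
build_prior <- function(scores, retained_tfs = colnames(scores),
                        gene_panel = NULL) {
  if (!all(retained_tfs %in% colnames(scores)))
    stop("retained_tfs not all present in score columns")
  C <- (scores[, retained_tfs, drop = FALSE] > 0) + 0L
  if (!is.null(gene_panel)) {
    C <- C[intersect(gene_panel, rownames(C)), , drop = FALSE]
  }
  empty <- colnames(C)[colSums(C) == 0]
  if (length(empty))
    message("TF(s) with no targets retained: ", paste(empty, collapse = ", "))
  C
}

#' Full prior-construction pipeline
#'
#' peaks -> gene windows -> max-pooled motif scores -> expression filter ->
#' Jaccard deduplication -> binary prior.
#'
#' @param peaks peak atlas data.frame (or BED path).
#' @param hits motif hits data.frame (or FIMO TSV path).
#' @param genes gene annotation data.frame (or TSV path).
#' @param presence presence matrix (or TSV path).
#' @param flank assignment window flank (bp).
#' @param min_presence expression-presence threshold.
#' @param jaccard_cutoff deduplication threshold.
#' @param max_p motif p-value re-filter applied when `hits` is a data.frame
#'   too.
#' @param gene_panel optional expression gene panel for the rows.
#' @param nearest_only passed to [assign_peaks_to_genes()].
#' @return list with `prior` (binary genes x TFs), `scores`, `assignment`,
#'   `removed_tfs`, `retained_tfs`.
#' @export
build_prior_pipeline <- function(peaks, hits, genes, presence,
                                 flank = 1e5, min_presence = 0.5,
                                 jaccard_cutoff = 0.5, max_p = 1e-5,
                                 gene_panel = NULL, nearest_only = FALSE) {
  if (is.character(peaks)) peaks <- read_peak_bed(peaks)
  if (is.character(hits)) hits <- read_fimo(hits, max_p = max_p)
  else hits <- hits[hits$p_value <= max_p, , drop = FALSE]
  if (is.character(genes)) genes <- read_gene_annotation(genes)
  if (is.character(presence)) presence <- read_tf_presence(presence)

  assignment <- assign_peaks_to_genes(peaks, genes, flank = flank,
                                      nearest_only = nearest_only)
  expressed <- filter_tfs_by_expression(presence, min_presence,
                                        tfs = sort(unique(hits$motif_id)))
  sets <- tf_target_peak_sets(hits, tfs = expressed)
  removed <- deduplicate_tfs_by_jaccard(sets, cutoff = jaccard_cutoff)
  retained <- setdiff(expressed, removed)
  scores <- aggregate_motif_scores(assignment, hits)
  retained <- intersect(retained, colnames(scores))
  prior <- build_prior(scores, retained, gene_panel = gene_panel)
  list(prior = prior, scores = scores, assignment = assignment,
       removed_tfs = removed, retained_tfs = retained)
}

#' Write a prior matrix as TSV and sparse triplets
#'
#' @param prior binary genes x TFs matrix.
#' @param path output TSV path (genes as rows); a companion
#'   `<path>.triplets.tsv` holds the sparse (gene, tf) pairs.
#' @return `path`, invisibly.
#' @export
write_prior <- function(prior, path) {
  utils::write.table(data.frame(gene_id = rownames(prior), prior,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  nz <- which(prior != 0, arr.ind = TRUE)
  utils::write.table(data.frame(gene_id = rownames(prior)[nz[, 1]],
                                tf_id = colnames(prior)[nz[, 2]]),
                     paste0(path, ".triplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
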