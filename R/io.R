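# Plain-text input/output: tab-separated matrices for cohorts and priors,
# BED/FIMO-style outputs for the simulated prior inputs, and a model
# checkpoint.

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a cohort from TSV files
#'
#' @param alterations TSV: tumors x genes binary matrix (first column tumor
#'   id).
#' @param expression TSV: tumors x genes log-scale expression.
#' @param labels TSV with columns `tumor_id`, `cancer_type`.
#' @param prior TSV: genes x TFs binary matrix.
#' @return a `citrus_cohort`.
#' @export
read_cohort <- function(alterations, expression, labels, prior) {
  alt <- read_matrix_tsv(alterations)
  expr <- read_matrix_tsv(expression)
  lab <- utils::read.delim(labels, stringsAsFactors = FALSE)
  if (!all(c("tumor_id", "cancer_type") %in% names(lab)))
    stop("labels TSV needs columns tumor_id, cancer_type")
  pri <- read_matrix_tsv(prior)
  ord <- rownames(alt)
  citrus_cohort(alt, expr[ord, , drop = FALSE],
                lab$cancer_type[match(ord, lab$tumor_id)], pri)
}

#' Write a cohort to a directory of TSV files
#'
#' Produces `alterations.tsv`, `expression.tsv`, `labels.tsv`, `prior.tsv`
#' in the formats read by [read_cohort()].
#'
#' @param cohort a `citrus_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$alterations, file.path(dir, "alterations.tsv"), "tumor_id")
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"), "tumor_id")
  utils::write.table(data.frame(tumor_id = rownames(cohort$alterations),
                                cancer_type = as.character(cohort$cancer_type)),
                     file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(cohort$prior, file.path(dir, "prior.tsv"), "gene_id")
  invisible(dir)
}

#' Write simulated prior-builder inputs in their on-disk formats
#'
#' Emits `peaks.bed` (BED3+name), `fimo.tsv` (FIMO dialect),
#' `genes.tsv` and `presence.tsv`, the formats consumed by
#' [build_prior_pipeline()].
#'
#' @param sim output of [simulate_prior_inputs()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_prior_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$peaks, file.path(dir, "peaks.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fimo <- data.frame(motif_id = sim$hits$motif_id,
                     motif_alt_id = sim$hits$motif_id,
                     sequence_name = sim$hits$peak_id,
                     start = 1L, stop = 10L, strand = "+",
                     score = sim$hits$score,
                     `p-value` = sim$hits$p_value,
                     `q-value` = NA, matched_sequence = "",
                     check.names = FALSE)
  utils::write.table(fimo, file.path(dir, "fimo.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(sim$presence, file.path(dir, "presence.tsv"), "tf_id")
  invisible(dir)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding all parameter arrays, the
#' prior mask, the label vocabularies, the configuration and the
#' normalization statistics; [load_citrus_model()] restores a fully
#' functional model.
#'
#' @param model a `citrus_model`.
#' @param path checkpoint path (`.rds`).
#' @return `path` invisibly, or the restored model.
#' @export
save_citrus_model <- function(model, path) {
  stopifnot(inherits(model, "citrus_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_citrus_model
#' @export
load_citrus_model <- function(path) {
  structure(readRDS(path), class = "citrus_model")
}
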