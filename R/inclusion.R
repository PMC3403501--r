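#' Transcript-level quantification table
#'
#' Builds the transcript table consumed by the inclusion-rate stage. Each row
#' is one transcript with its host gene, the set of cassette exons it covers,
#' and its per-sample abundance (FPKM, as estimated upstream by a transcript
#' assembler).
#'
#' @param transcript_id,gene_id character vectors, one entry per transcript.
#' @param includes_exon list of character vectors: the exon ids each
#'   transcript covers (may be empty).
#' @param abundance numeric matrix, transcripts x samples, nonnegative, with
#'   column names naming the samples.
#' @return A data frame of class \code{transcript_quant} with a list column
#'   \code{includes_exon} and one numeric column per sample.
#' @export
transcript_quant <- function(transcript_id, gene_id, includes_exon, abundance) {
  abundance <- as.matrix(abundance)
  stopifnot(length(transcript_id) == length(gene_id),
            length(transcript_id) == length(includes_exon),
            nrow(abundance) == length(transcript_id))
  if (is.null(colnames(abundance))) stop("abundance must have sample names")
  if (anyNA(abundance) || any(abundance < 0))
    stop("abundances must be nonnegative and non-missing")
  df <- data.frame(transcript_id = as.character(transcript_id),
                   gene_id = as.character(gene_id),
                   stringsAsFactors = FALSE)
  df$includes_exon <- lapply(includes_exon, as.character)
  df <- cbind(df, as.data.frame(abundance))
  class(df) <- c("transcript_quant", "data.frame")
  df
}

tq_samples <- function(transcripts) {
  setdiff(colnames(transcripts), c("transcript_id", "gene_id", "includes_exon"))
}

#' Read a transcript table from disk
#'
#' Tab-separated with header
#' \code{transcript_id<TAB>gene_id<TAB>exon_ids<TAB><sample columns...>},
#' where \code{exon_ids} lists the covered exons separated by semicolons
#' (empty for a transcript covering none of the cassette exons of interest).
#'
#' @param path file path.
#' @return A [transcript_quant()] table.
#' @export
read_transcript_quant <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "gene_id", "exon_ids")
  if (!all(need %in% colnames(df)))
    stop("transcript table must have columns ", paste(need, collapse = ", "))
  samples <- setdiff(colnames(df), need)
  if (length(samples) == 0) stop("transcript table has no sample columns")
  inc <- strsplit(ifelse(is.na(df$exon_ids), "", df$exon_ids), ";", fixed = TRUE)
  inc <- lapply(inc, function(v) v[nzchar(v)])
  transcript_quant(df$transcript_id, df$gene_id, inc,
                   as.matrix(df[, samples, drop = FALSE]))
}

#' Gene expression as the sum over its transcripts
#'
#' The expression of a gene in a sample is the sum of FPKM over all
#' transcripts of that gene.
#'
#' @param transcripts a [transcript_quant()] table.
#' @param gene gene id.
#' @param sample sample id.
#' @return Nonnegative scalar.
#' @export
gene_expression <- function(transcripts, gene, sample) {
  rows <- transcripts$gene_id == gene
  if (!any(rows)) stop("unknown gene: ", gene)
  if (!sample %in% tq_samples(transcripts)) stop("unknown sample: ", sample)
  sum(transcripts[rows, sample])
}

#' Inclusion rate of an exon in one sample
#'
#' The ratio between the exon's expression (sum of FPKM over all transcripts
#' covering the exon) and the host gene's expression (sum over all the
#' gene's transcripts). \code{NA} when the gene is not expressed in the
#' sample, since 0/0 carries no splicing information.
#'
#' @param transcripts a [transcript_quant()] table.
#' @param exon_id exon id.
#' @param gene_id the exon's host gene.
#' @param sample sample id.
#' @return Value in \eqn{[0, 1]}, or \code{NA}.
#' @export
exon_inclusion_rate <- function(transcripts, exon_id, gene_id, sample) {
  rows <- which(transcripts$gene_id == gene_id)
  if (length(rows) == 0) stop("host gene has no transcripts: ", gene_id)
  total <- sum(transcripts[rows, sample])
  if (total == 0) return(NA_real_)
  covers <- vapply(transcripts$includes_exon[rows],
                   function(v) exon_id %in% v, FALSE)
  sum(transcripts[rows[covers], sample]) / total
}

#' Inclusion-rate matrix with expression filtering
#'
#' Computes per-sample inclusion rates for every exon whose host gene passes
#' the expression filter: genes with low FPKM yield unreliable inclusion
#' estimates, so rates are kept only for genes whose expression is strictly
#' above the per-sample percentile threshold (computed across all genes in
#' that sample) in at least \code{min_samples} samples. Cells of retained
#' exons are computed in every sample and are \code{NA} only where the gene
#' is not expressed at all.
#'
#' @param transcripts a [transcript_quant()] table.
#' @param exons data frame with columns \code{exon_id}, \code{gene_id}
#'   defining the candidate cassette-exon universe.
#' @param samples sample ids to use; defaults to all sample columns.
#' @param percentile expression percentile (in (0, 100)) a gene must exceed.
#' @param min_samples minimum number of qualifying samples per gene; datasets
#'   with fewer samples than this are ineligible.
#' @return An \code{inclusion_matrix}: list with \code{values} (exon x
#'   sample matrix), \code{exon_ids}, \code{gene_ids}, \code{sample_ids}.
#' @export
build_inclusion_matrix <- function(transcripts, exons, samples = NULL,
                                   percentile = 80, min_samples = 6L) {
  if (is.null(samples)) samples <- tq_samples(transcripts)
  stopifnot(percentile > 0, percentile < 100)
  if (length(samples) < min_samples)
    stop("dataset ineligible: ", length(samples), " samples but at least ",
         min_samples, " are required")
  if (anyDuplicated(exons$exon_id)) stop("duplicate exon ids in universe")
  genes <- unique(transcripts$gene_id)
  expr <- vapply(samples, function(s)
    vapply(genes, function(g) gene_expression(transcripts, g, s), 0),
    numeric(length(genes)))
  expr <- matrix(expr, nrow = length(genes),
                 dimnames = list(genes, samples))
  # per-sample threshold across the gene-expression distribution; a gene
  # qualifies when strictly above it in >= min_samples samples
  thr <- apply(expr, 2, stats::quantile, probs = percentile / 100,
               names = FALSE)
  qualifies <- sweep(expr, 2, thr, ">")
  keep_genes <- rownames(expr)[rowSums(qualifies) >= min_samples]
  keep <- exons$gene_id %in% keep_genes
  exons_kept <- exons[keep, , drop = FALSE]
  values <- matrix(NA_real_, nrow = nrow(exons_kept), ncol = length(samples),
                   dimnames = list(exons_kept$exon_id, samples))
  for (i in seq_len(nrow(exons_kept))) {
    for (s in samples) {
      values[i, s] <- exon_inclusion_rate(transcripts,
                                          exons_kept$exon_id[i],
                                          exons_kept$gene_id[i], s)
    }
  }
  inclusion_matrix(values, gene_ids = exons_kept$gene_id)
}

#' Inclusion-rate matrix container
#'
#' @param values numeric exon x sample matrix with values in \eqn{[0, 1]} or
#'   \code{NA}; rownames are exon ids, colnames sample ids.
#' @param gene_ids host gene of each exon row.
#' @return An object of class \code{inclusion_matrix}.
#' @export
inclusion_matrix <- function(values, gene_ids) {
  values <- as.matrix(values)
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("values must have exon ids as rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("values must have sample ids as colnames")
  if (length(gene_ids) != nrow(values))
    stop("gene_ids must have one entry per exon row")
  if (nrow(values) > 0 && !all(is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("inclusion values must lie in [0, 1]")
  }
  structure(list(values = values,
                 exon_ids = as.character(rownames(values)),
                 gene_ids = as.character(gene_ids),
                 sample_ids = colnames(values)),
            class = "inclusion_matrix")
}

#' @export
print.inclusion_matrix <- function(x, ...) {
  cat(sprintf("inclusion_matrix: %d exons x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read / write inclusion matrices
#'
#' Tab-separated; the first two columns are \code{exon_id} and
#' \code{gene_id}, followed by one column per sample. Missing values are
#' encoded as \code{NA}.
#'
#' @param path file path.
#' @rdname inclusion_matrix_io
#' @export
read_inclusion_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("exon_id", "gene_id") %in% colnames(df)))
    stop("inclusion matrix file must start with exon_id and gene_id columns")
  samples <- setdiff(colnames(df), c("exon_id", "gene_id"))
  vals <- as.matrix(df[, samples, drop = FALSE])
  rownames(vals) <- df$exon_id
  inclusion_matrix(vals, df$gene_id)
}

#' @param x an \code{inclusion_matrix}.
#' @rdname inclusion_matrix_io
#' @export
write_inclusion_matrix <- function(x, path) {
  df <- data.frame(exon_id = x$exon_ids, gene_id = x$gene_ids,
                   x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
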