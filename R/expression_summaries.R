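# RPKM, expressed-gene flagging and read-concentration summaries.

#' Construct an expression matrix
#'
#' @param counts gene x sample matrix of nonnegative integer read counts with
#'   gene row names.
#' @param gene_length per-gene length in bp (annotated expressed-sequence
#'   length supplied by the caller).
#' @param library_size per-sample total mapped reads. This is the mapped-read
#'   total, not the column sum of `counts` (reads mapping outside annotated
#'   genes count toward it).
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_length, library_size) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), all(counts >= 0),
            length(gene_length) == nrow(counts),
            length(library_size) == ncol(counts))
  if (any(gene_length <= 0)) stop("gene lengths must be positive")
  if (any(library_size <= 0)) stop("library sizes must be positive")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
  }
  structure(list(counts = counts, gene_length = as.numeric(gene_length),
                 library_size = as.numeric(library_size)),
            class = "expression_matrix")
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM[g, s] = counts[g, s] / ((gene_length[g] / 1000) *
#' (library_size[s] / 1e6))`.
#'
#' @param mat an [expression_matrix()].
#' @return gene x sample numeric matrix.
#' @export
rpkm <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  denom <- outer(mat$gene_length / 1000, mat$library_size / 1e6)
  mat$counts / denom
}

#' Expressed-gene flag
#'
#' A gene is called expressed when its read total across all samples reaches
#' `min_total` (default 20, the minimal-evidence threshold under which about
#' half of annotated rice genes are detectably expressed in seedlings).
#'
#' @param mat an [expression_matrix()].
#' @param min_total minimum summed count (default 20).
#' @return named logical vector per gene.
#' @export
expressed_flag <- function(mat, min_total = 20) {
  stopifnot(inherits(mat, "expression_matrix"))
  rowSums(mat$counts) >= min_total
}

#' Read share of the most highly expressed genes
#'
#' Fraction of a sample's in-gene reads carried by the top `quantile` of
#' genes ranked by count (descending; ties at the cutoff broken by gene id so
#' the statistic is deterministic). RNA-Seq libraries are typically dominated
#' by a small set of genes — e.g. the top decile often carries over three
#' quarters of reads.
#'
#' @param mat an [expression_matrix()].
#' @param sample sample name or column index.
#' @param quantile top fraction of genes (default 0.10).
#' @return fraction in (0, 1].
#' @export
top_share <- function(mat, sample, quantile = 0.10) {
  stopifnot(inherits(mat, "expression_matrix"),
            quantile > 0, quantile <= 1)
  x <- mat$counts[, sample]
  if (sum(x) == 0) stop("all-zero counts in sample ", sample)
  ord <- order(-x, rownames(mat$counts))
  n_top <- ceiling(quantile * length(x))
  sum(x[ord[seq_len(n_top)]]) / sum(x)
}

#' Direction summary of a DE table
#'
#' @param de_table data frame with a `log2fc` column.
#' @return list with `n_up` (`log2fc > 0`), `n_down` (`log2fc < 0`), `n_zero`,
#'   and fractions `frac_up`, `frac_down` of the directed genes.
#' @export
de_direction_summary <- function(de_table) {
  stopifnot("log2fc" %in% names(de_table))
  lfc <- de_table$log2fc
  n_up <- sum(lfc > 0, na.rm = TRUE)
  n_down <- sum(lfc < 0, na.rm = TRUE)
  directed <- n_up + n_down
  list(n_up = n_up, n_down = n_down,
       n_zero = sum(lfc == 0, na.rm = TRUE),
       frac_up = if (directed) n_up / directed else 0,
       frac_down = if (directed) n_down / directed else 0)
}
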