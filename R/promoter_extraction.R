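# Strand-aware promoter windows: the W bp strictly upstream of each gene's
# TSS (default W = 1000), reported 5'->3' on the gene's coding strand. The
# TSS base itself is excluded; windows are truncated (never dropped) at
# contig boundaries; soft-masked bases are uppercased and N is retained.

#' Extract upstream promoter windows
#'
#' For a `+` strand gene the window covers genomic positions
#' `[tss - window, tss - 1]`; for a `-` strand gene, positions
#' `[tss + 1, tss + window]` reverse-complemented, so every returned sequence
#' reads 5'->3' toward the TSS on the gene's own strand.
#'
#' @param genome a `Biostrings::DNAStringSet`, or path to a genome FASTA.
#' @param genes gene-record data frame (see [read_gene_annotation()]).
#' @param window window width W in bp (default 1000).
#' @return object of class `promoter_set`: list with `window` and data frame
#'   `promoters` (`gene_id`, `sequence` uppercase ACGTN, `length`,
#'   `truncated` = `length < window`).
#' @export
extract_promoters <- function(genome, genes, window = 1000) {
  stopifnot(window >= 1)
  window <- as.integer(window)
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("genome FASTA not found: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_contig <- !(genes$contig %in% names(genome))
  if (any(missing_contig)) {
    stop("contig(s) absent from genome for gene(s): ",
         paste(genes$gene_id[missing_contig], collapse = ", "))
  }
  clen <- setNames(Biostrings::width(genome), names(genome))
  bad_tss <- genes$tss < 1L | genes$tss > clen[genes$contig]
  if (any(bad_tss)) {
    stop("TSS outside contig for gene(s): ",
         paste(genes$gene_id[bad_tss], collapse = ", "))
  }
  n <- nrow(genes)
  seqs <- character(n)
  for (i in seq_len(n)) {
    tss <- genes$tss[i]
    L <- clen[[genes$contig[i]]]
    if (genes$strand[i] == "+") {
      from <- max(1L, tss - window)
      to <- tss - 1L
      if (to < from) {
        seqs[i] <- ""
      } else {
        seqs[i] <- as.character(Biostrings::subseq(genome[[genes$contig[i]]],
                                                   from, to))
      }
    } else {
      from <- tss + 1L
      to <- min(L, tss + window)
      if (to < from) {
        seqs[i] <- ""
      } else {
        s <- Biostrings::subseq(genome[[genes$contig[i]]], from, to)
        seqs[i] <- as.character(Biostrings::reverseComplement(s))
      }
    }
  }
  seqs <- toupper(seqs)
  df <- data.frame(gene_id = genes$gene_id, sequence = seqs,
                   length = nchar(seqs), truncated = nchar(seqs) < window,
                   stringsAsFactors = FALSE)
  structure(list(window = window, promoters = df), class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoter(s), window %d bp, %d truncated\n",
              nrow(x$promoters), x$window, sum(x$promoters$truncated)))
  invisible(x)
}

#' Write promoters as FASTA plus a TSV manifest
#'
#' FASTA headers are `gene_id|window|truncated`. Genes with empty windows are
#' listed in the manifest but omitted from the FASTA (zero-length records).
#'
#' @param promoters a `promoter_set`.
#' @param fasta_path output FASTA path.
#' @param manifest_path optional TSV manifest path.
#' @return `fasta_path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, fasta_path, manifest_path = NULL) {
  stopifnot(inherits(promoters, "promoter_set"))
  df <- promoters$promoters
  nonempty <- df$length > 0L
  dss <- Biostrings::DNAStringSet(df$sequence[nonempty])
  names(dss) <- sprintf("%s|%d|%s", df$gene_id[nonempty], promoters$window,
                        tolower(df$truncated[nonempty]))
  Biostrings::writeXStringSet(dss, fasta_path)
  if (!is.null(manifest_path)) {
    write_tsv_manifest(df[, c("gene_id", "length", "truncated")],
                       manifest_path, list(window = promoters$window))
  }
  invisible(fasta_path)
}
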