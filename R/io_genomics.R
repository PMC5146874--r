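# Readers/writers for the standard formats the pipeline touches, mapped onto
# the shared in-memory types:
#   gene records  — data.frame(gene_id, contig, strand, start, end, tss),
#                   1-based inclusive coordinates (GFF3-native); the TSS is the
#                   5' end of the gene feature (start on "+", end on "-").
#   DE table      — data.frame(gene_id, log2fc, fdr) filtered at an FDR cutoff.
#   motif set     — see motif_set() in motif_model.R.

#' Read gene annotations from GFF3 or BED
#'
#' Parses a GFF3 (1-based inclusive) or BED (0-based half-open, converted on
#' read) annotation into a gene-record table with one row per feature and a
#' strand-derived transcriptional start site (TSS). The format is auto-detected
#' from the file extension (`.bed` vs anything else = GFF3).
#'
#' @param annotation_file path to a GFF3 or BED file.
#' @param feature_type GFF3 feature type to keep (column 3); default `"gene"`.
#'   Ignored for BED input.
#' @return data frame with columns `gene_id`, `contig`, `strand` (`"+"`/`"-"`),
#'   `start`, `end` (1-based inclusive) and `tss` (= `start` on `"+"`, `end`
#'   on `"-"`). Features with unknown strand (`"."`/`"*"`) are skipped with a
#'   warning; duplicated gene ids are an error.
#' @export
read_gene_annotation <- function(annotation_file, feature_type = "gene") {
  if (!file.exists(annotation_file)) {
    stop("annotation file not found: ", annotation_file)
  }
  is_bed <- grepl("\\.bed$", annotation_file, ignore.case = TRUE)
  if (!is_bed) {
    validate_gff3_lines(annotation_file)
    gr <- rtracklayer::import(annotation_file, format = "gff3")
    df <- as.data.frame(gr, stringsAsFactors = FALSE)
    if (!is.null(df$type)) {
      df <- df[as.character(df$type) == feature_type, , drop = FALSE]
    }
    ids <- if (!is.null(df$ID)) as.character(df$ID) else as.character(df$Name)
  } else {
    gr <- rtracklayer::import(annotation_file, format = "bed")
    df <- as.data.frame(gr, stringsAsFactors = FALSE)
    ids <- as.character(df$name)
  }
  if (nrow(df) == 0L) {
    warning("no '", feature_type, "' features found in ", annotation_file)
    return(empty_gene_table())
  }
  if (any(is.na(ids) | ids == "")) {
    stop("annotation features without an ID/name in ", annotation_file)
  }
  strand <- as.character(df$strand)
  keep <- strand %in% c("+", "-")
  if (any(!keep)) {
    warning(sum(!keep), " feature(s) with unknown strand skipped: ",
            paste(head(ids[!keep], 5L), collapse = ", "))
  }
  genes <- data.frame(
    gene_id = ids[keep],
    contig  = as.character(df$seqnames)[keep],
    strand  = strand[keep],
    start   = df$start[keep],
    end     = df$end[keep],
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  genes
}

empty_gene_table <- function() {
  data.frame(gene_id = character(0), contig = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             tss = integer(0), stringsAsFactors = FALSE)
}

# Cheap structural pre-check so malformed GFF3 errors name the line number.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 8L)) {
    bad <- which(body)[which(nfield < 8L)[1L]]
    stop("malformed GFF3 line ", bad, " in ", path,
         ": expected >= 8 tab-separated fields, found ", nfield[nfield < 8L][1L])
  }
  invisible(TRUE)
}

#' Write gene records as GFF3
#'
#' @param genes gene-record data frame (see [read_gene_annotation()]).
#' @param path output path.
#' @param feature_type feature type written in column 3.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path, feature_type = "gene") {
  lines <- c("##gff-version 3",
             sprintf("%s\tckreg\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$contig, feature_type, genes$start, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Reads a TSV of per-gene log2 fold changes and FDR values and retains the
#' rows passing the FDR cutoff used to call differential expression
#' (default 1e-4).
#'
#' @param tsv_file TSV with header columns `gene_id`, `log2fc`, `fdr`.
#' @param fdr_threshold retain rows with `fdr <= fdr_threshold`.
#' @param tissue_label optional label attached as attribute `"tissue"`.
#' @return data frame `gene_id`, `log2fc`, `fdr` (all retained rows satisfy
#'   the cutoff); attributes `"tissue"` and `"fdr_threshold"`. The number of
#'   dropped rows is reported via [message()].
#' @export
read_de_table <- function(tsv_file, fdr_threshold = 1e-4, tissue_label = "") {
  df <- read_tsv_manifest(tsv_file)
  need <- c("gene_id", "log2fc", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("DE table ", tsv_file, " missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("empty DE table: ", tsv_file)
    df$log2fc <- numeric(0)
    df$fdr <- numeric(0)
  }
  if (!is.numeric(df$fdr)) stop("non-numeric fdr column in ", tsv_file)
  if (!is.numeric(df$log2fc)) stop("non-numeric log2fc column in ", tsv_file)
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) {
    stop("fdr values outside [0, 1] in ", tsv_file)
  }
  keep <- !is.na(df$fdr) & df$fdr <= fdr_threshold
  message(sum(!keep), " row(s) dropped at FDR threshold ", fdr_threshold)
  out <- df[keep, need, drop = FALSE]
  if (anyDuplicated(out$gene_id)) {
    stop("duplicated gene_id in DE table ", tsv_file)
  }
  rownames(out) <- NULL
  attr(out, "tissue") <- tissue_label
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Write a differential-expression table
#'
#' @param de DE table (`gene_id`, `log2fc`, `fdr`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  write_tsv_manifest(de[, c("gene_id", "log2fc", "fdr")], path,
                     list(fdr_threshold = attr(de, "fdr_threshold") %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a motif file into a motif set
#'
#' One k-mer (or degenerate pattern such as `AAGAT[T/C]TT`) per line, with an
#' optional tab-separated score (e.g. a protein-binding-microarray E-score).
#' Degenerate patterns are expanded to plain k-mers; the expanded k-mers of a
#' scored pattern inherit its score.
#'
#' @param text_file path to the motif list.
#' @param name motif-set name (defaults to the file name).
#' @return a `motif_set` object (see [motif_set()]).
#' @export
read_motif_file <- function(text_file, name = basename(text_file)) {
  lines <- readLines(text_file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) stop("no motifs in ", text_file)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kmers <- character(0)
  scores <- numeric(0)
  any_score <- any(lengths(parts) > 1L)
  for (p in parts) {
    expanded <- expand_degenerate(toupper(p[[1L]]))
    kmers <- c(kmers, expanded)
    if (any_score) {
      s <- if (length(p) > 1L) suppressWarnings(as.numeric(p[[2L]])) else NA_real_
      if (length(p) > 1L && is.na(s)) stop("non-numeric motif score in ", text_file)
      scores <- c(scores, rep(s, length(expanded)))
    }
  }
  motif_set(kmers, scores = if (any_score) scores else NULL, name = name)
}

#' Write a motif set to a plain-text motif file
#'
#' @param ms a `motif_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_file <- function(ms, path) {
  stopifnot(inherits(ms, "motif_set"))
  if (is.null(ms$scores)) {
    writeLines(ms$kmers, path)
  } else {
    writeLines(paste(ms$kmers, format(ms$scores, trim = TRUE), sep = "\t"), path)
  }
  invisible(path)
}
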