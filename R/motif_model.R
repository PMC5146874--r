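# Fixed-length motif sets and exact-match scanning.
#
# Scanning is deliberately exact (set membership of each length-k window),
# matching how protein-binding-microarray 8-mer lists are used: a promoter
# either contains one of the top-scoring 8-mers or it does not. Position
# weight matrices are provided as descriptive output only.

#' Construct a motif set
#'
#' A named set of fixed-length DNA k-mers, optionally scored (e.g. by
#' protein-binding-microarray E-score). Duplicate k-mers are collapsed.
#'
#' @param kmers character vector of equal-length ACGT strings.
#' @param scores optional numeric vector parallel to `kmers`.
#' @param name set label.
#' @return object of class `motif_set`: list with `name`, `k`, `kmers`
#'   (unique, sorted) and `scores` (named by k-mer, or `NULL`).
#' @export
motif_set <- function(kmers, scores = NULL, name = "motifs") {
  kmers <- toupper(as.character(kmers))
  if (!length(kmers)) {
    return(structure(list(name = name, k = 0L, kmers = character(0),
                          scores = NULL), class = "motif_set"))
  }
  if (any(grepl("[^ACGT]", kmers))) {
    stop("non-ACGT character in k-mer(s): ",
         paste(head(kmers[grepl("[^ACGT]", kmers)], 3L), collapse = ", "))
  }
  k <- unique(nchar(kmers))
  if (length(k) != 1L) {
    stop("k-mers of mixed lengths: ", paste(sort(k), collapse = ", "))
  }
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(kmers))
    scores <- tapply(as.numeric(scores), kmers, function(x) x[[1L]])
    scores <- scores[sort(unique(kmers))]
  }
  structure(list(name = name, k = as.integer(k),
                 kmers = sort(unique(kmers)), scores = scores),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("motif_set '%s': %d k-mer(s) of length %d%s\n", x$name,
              length(x$kmers), x$k,
              if (is.null(x$scores)) "" else " (scored)"))
  invisible(x)
}

#' Expand a degenerate motif pattern into plain k-mers
#'
#' Bracket groups list alternative bases, e.g. the extended type-B response
#' regulator motif `"AAGAT[T/C]TT"` expands to `AAGATTTT` and `AAGATCTT`.
#'
#' @param pattern string of ACGT letters and bracket groups `[X/Y/...]`.
#' @return character vector of equal-length ACGT k-mers (Cartesian product of
#'   the alternatives).
#' @export
expand_degenerate <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  if (!grepl("^([ACGT]|\\[[ACGT](/[ACGT])*\\])+$", pattern)) {
    stop("invalid motif pattern: '", pattern,
         "' (ACGT letters and bracket groups like [T/C] only)")
  }
  tokens <- regmatches(pattern,
                       gregexpr("\\[[ACGT/]+\\]|[ACGT]", pattern))[[1L]]
  choices <- lapply(tokens, function(t) {
    if (startsWith(t, "[")) strsplit(gsub("[\\[\\]]", "", t, perl = TRUE),
                                     "/", fixed = TRUE)[[1L]] else t
  })
  grid <- expand.grid(rev(choices), stringsAsFactors = FALSE)
  sort(unique(apply(grid[, rev(seq_along(choices)), drop = FALSE],
                    1L, paste0, collapse = "")))
}

# Union of a motif set's k-mers and (optionally) their reverse complements;
# windows are counted once per position even when a palindrome matches both
# orientations, because the union is a set.
scan_patterns <- function(motifset, both_strands) {
  pats <- motifset$kmers
  if (both_strands && length(pats)) pats <- union(pats, rev_comp(pats))
  pats
}

#' Count exact motif occurrences in one sequence
#'
#' Counts every (possibly overlapping) position at which the length-k window
#' equals a k-mer of the set or, when `both_strands = TRUE`, the reverse
#' complement of one. Windows containing `N` never match; palindromic matches
#' are counted once per position.
#'
#' @param sequence ACGTN string.
#' @param motifset a [motif_set()].
#' @param both_strands scan both orientations (default `TRUE`).
#' @return integer occurrence count (0 for empty sequences, empty sets, or
#'   `k > nchar(sequence)`).
#' @export
scan_sequence <- function(sequence, motifset, both_strands = TRUE) {
  stopifnot(inherits(motifset, "motif_set"))
  pats <- scan_patterns(motifset, both_strands)
  if (!length(pats) || !nzchar(sequence) || motifset$k > nchar(sequence)) {
    return(0L)
  }
  pd <- Biostrings::PDict(pats)
  sum(Biostrings::countPDict(pd, Biostrings::DNAString(toupper(sequence))))
}

#' Scan a promoter set for motif occurrences
#'
#' Vectorized [scan_sequence()] over the promoters of a
#' [extract_promoters()] result; genes with empty promoters get count 0.
#'
#' @param promoters a `promoter_set`.
#' @param motifset a [motif_set()].
#' @param both_strands scan both orientations (default `TRUE`).
#' @return hit table: data frame `gene_id`, `occurrence_count`, `has_hit`
#'   (`has_hit` iff `occurrence_count >= 1`).
#' @export
scan_promoters <- function(promoters, motifset, both_strands = TRUE) {
  stopifnot(inherits(promoters, "promoter_set"), inherits(motifset, "motif_set"))
  df <- promoters$promoters
  if (nrow(df) == 0L) stop("empty promoter set")
  counts <- integer(nrow(df))
  pats <- scan_patterns(motifset, both_strands)
  scannable <- nchar(df$sequence) >= motifset$k & motifset$k > 0L
  if (length(pats) && any(scannable)) {
    pd <- Biostrings::PDict(pats)
    dss <- Biostrings::DNAStringSet(toupper(df$sequence[scannable]))
    m <- Biostrings::vcountPDict(pd, dss)
    counts[scannable] <- as.integer(colSums(m))
  }
  data.frame(gene_id = df$gene_id, occurrence_count = counts,
             has_hit = counts >= 1L, stringsAsFactors = FALSE)
}

#' Build a position frequency matrix from k-mers
#'
#' Descriptive summary of a k-mer collection in the style of the matrices used
#' to visualise transcription-factor binding preferences. Column `j`, base `b`
#' is `(pseudocount + sum of weights of k-mers with b at j) /
#' (4 * pseudocount + sum of weights)`.
#'
#' @param kmers character vector of equal-length k-mers.
#' @param weights nonnegative weights (default uniform); e.g. PBM E-scores.
#' @param pseudocount added per cell (default 0).
#' @return 4 x k numeric matrix with rows `A`, `C`, `G`, `T`; every column
#'   sums to 1.
#' @export
build_pfm <- function(kmers, weights = NULL, pseudocount = 0) {
  kmers <- toupper(as.character(kmers))
  stopifnot(length(kmers) >= 1L, pseudocount >= 0)
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mers of mixed lengths")
  if (is.null(weights)) weights <- rep(1, length(kmers))
  stopifnot(length(weights) == length(kmers), all(weights >= 0))
  if (sum(weights) == 0) stop("all-zero weights")
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, nrow = 4L, ncol = k, dimnames = list(bases, NULL))
  chars <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  for (j in seq_len(k)) {
    for (b in bases) {
      mat[b, j] <- sum(weights[chars[, j] == b])
    }
  }
  sweep(mat + pseudocount, 2L, colSums(mat) + 4 * pseudocount, "/")
}

#' Write a motif hit table as TSV
#'
#' @param hits hit table from [scan_promoters()].
#' @param path output path.
#' @param manifest named list recorded in the comment header.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, manifest = list()) {
  write_tsv_manifest(hits, path, manifest)
}
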