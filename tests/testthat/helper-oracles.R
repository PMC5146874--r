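# Independent oracles kept deliberately naive: these re-derive results from
# first principles (all-substrings scans, textbook formulas) without touching
# the package's computational paths.

# brute-force exact-match scan: every window compared against the k-mer set
# (and, optionally, against the set of reverse complements)
brute_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

brute_scan <- function(seq, kmers, both_strands = TRUE) {
  if (!length(kmers)) return(0L)
  k <- nchar(kmers[1])
  n <- nchar(seq)
  if (k > n || n == 0L) return(0L)
  pats <- kmers
  if (both_strands) pats <- unique(c(pats, brute_revcomp(kmers)))
  windows <- substring(seq, seq_len(n - k + 1L), k:n)
  sum(windows %in% pats)
}

# textbook Pearson correlation from sums
hand_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_kmers <- function(n_kmers, k) {
  unique(vapply(seq_len(n_kmers), function(i) random_seq(k), character(1)))
}

# small ready-made nCounter panel with hand-controllable counts
toy_panel <- function(neg = c(4, 6, 5, 5, 5, 5, 5, 5), lanes = 2L,
                      endo = 100, pos = c(1000, 500, 250, 100, 50, 25),
                      ref = c(800, 800, 800),
                      lane_mult = rep(1, lanes),
                      condition = rep(c("treated", "control"),
                                      length.out = lanes)) {
  counts <- outer(c(endo, pos, neg, ref), lane_mult)
  rownames(counts) <- c(sprintf("e%d", seq_along(endo)),
                        sprintf("p%d", seq_along(pos)),
                        sprintf("n%d", seq_along(neg)),
                        sprintf("r%d", seq_along(ref)))
  nanostring_panel(counts,
                   rep(c("endogenous", "positive", "negative", "reference"),
                       c(length(endo), length(pos), length(neg), length(ref))),
                   condition)
}
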