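test_that("degenerate patterns expand to the Cartesian product of alternatives", {
  expect_setequal(expand_degenerate("AAGAT[T/C]TT"), c("AAGATTTT", "AAGATCTT"))
  expect_equal(expand_degenerate("AGAT"), "AGAT")
  expect_setequal(expand_degenerate("[A/C][G/T]"), c("AG", "AT", "CG", "CT"))
  expect_error(expand_degenerate("A[]G"), "invalid")
  expect_error(expand_degenerate("A[[A/C]]G"), "invalid")
  expect_error(expand_degenerate("AXGT"), "invalid")
})

test_that("scan_sequence counts overlapping exact matches on the requested strands", {
  expect_equal(scan_sequence("AGATAGAT", motif_set("AGAT"), both_strands = FALSE), 2L)
  # revcomp(AAGATTTT) = AAAATCTT occurs once
  expect_equal(scan_sequence("CCAAAATCTTCC", motif_set("AAGATTTT"),
                             both_strands = TRUE), 1L)
  expect_equal(scan_sequence("CCAAAATCTTCC", motif_set("AAGATTTT"),
                             both_strands = FALSE), 0L)
  # overlapping occurrences all counted
  expect_equal(scan_sequence("AAAA", motif_set("AA"), both_strands = FALSE), 3L)
  # vacuous cases
  expect_equal(scan_sequence("ACGTACGT", motif_set(character(0))), 0L)
  expect_equal(scan_sequence("", motif_set("ACGT")), 0L)
  expect_equal(scan_sequence("ACG", motif_set("ACGTACGT")), 0L)
  # N never matches
  expect_equal(scan_sequence("ANGT", motif_set("ACGT"), both_strands = FALSE), 0L)
  expect_equal(scan_sequence("ACGTNACGT", motif_set("ACGT"), both_strands = FALSE), 2L)
})

test_that("both-strand scan decomposes into forward scans for palindrome-free sets", {
  set.seed(31)
  for (i in 1:20) {
    kmers <- random_kmers(4, 6)
    kmers <- kmers[!kmers %in% brute_revcomp(kmers)]  # drop palindromes
    if (!length(kmers)) next
    ms <- motif_set(kmers)
    s <- random_seq(400)
    expect_equal(scan_sequence(s, ms, both_strands = TRUE),
                 scan_sequence(s, ms, both_strands = FALSE) +
                   scan_sequence(brute_revcomp(s), ms, both_strands = FALSE))
  }
})

test_that("palindromic matches are counted once per position", {
  # ACGT is its own reverse complement
  expect_equal(scan_sequence("ACGTACGT", motif_set("ACGT"), both_strands = TRUE), 2L)
})

test_that("adding k-mers to a set never decreases occurrence counts", {
  set.seed(77)
  for (i in 1:10) {
    s <- random_seq(300)
    base <- random_kmers(3, 5)
    extra <- union(base, random_kmers(2, 5))
    expect_gte(scan_sequence(s, motif_set(extra)),
               scan_sequence(s, motif_set(base)))
  }
})

test_that("scan_promoters agrees with the brute-force all-substrings oracle", {
  set.seed(19)
  toy <- make_toy_genome(n_genes = 30, n_contigs = 2, seed = 19)
  ms <- motif_set(random_kmers(5, 8))
  planted <- plant_motifs(toy$genome, toy$genes, ms, p0 = 0.5, p1 = 0.5,
                          seed = 20)
  prom <- extract_promoters(planted$genome, toy$genes, window = 1000)
  hits <- scan_promoters(prom, ms, both_strands = TRUE)
  oracle <- vapply(prom$promoters$sequence, brute_scan, integer(1),
                   kmers = ms$kmers, both_strands = TRUE, USE.NAMES = FALSE)
  expect_equal(hits$occurrence_count, oracle)
  expect_equal(hits$has_hit, oracle >= 1L)

  # genes with empty promoters get count zero
  prom$promoters$sequence[1] <- ""
  prom$promoters$length[1] <- 0L
  hits2 <- scan_promoters(prom, ms)
  expect_equal(hits2$occurrence_count[1], 0L)
})

test_that("position frequency matrices have unit column sums and honor weights", {
  one_hot <- build_pfm("ACGT")
  expect_equal(one_hot[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(diag(one_hot[c("A", "C", "G", "T"), ]), rep(1, 4),
               ignore_attr = TRUE)

  m <- build_pfm(c("AA", "AC"))
  expect_equal(unname(m["A", 1]), 1)
  expect_equal(m[c("A", "C"), 2], c(A = 0.5, C = 0.5))

  w <- build_pfm(c("AA", "CA"), weights = c(2, 1))
  expect_equal(w[c("A", "C"), 1], c(A = 2 / 3, C = 1 / 3))

  set.seed(3)
  kk <- random_kmers(10, 6)
  r <- build_pfm(kk, weights = runif(length(kk)), pseudocount = 0.5)
  expect_equal(colSums(r), rep(1, 6), tolerance = 1e-12)
  expect_error(build_pfm(c("AA", "AC"), weights = c(0, 0)), "all-zero")
})

test_that("motif sets validate their k-mers", {
  expect_error(motif_set(c("ACGT", "ACG")), "mixed length")
  expect_error(motif_set("ACGU"), "non-ACGT")
  expect_equal(length(motif_set(c("ACGT", "ACGT"))$kmers), 1L)
})
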