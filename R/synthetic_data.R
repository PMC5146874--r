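# Seeded generators for every input the pipeline consumes, with known ground
# truth. The generators emulate the study design the pipeline targets: a
# hormone-treatment experiment with three treated and three control
# replicates, promoter windows of 1 kb, a motif-positive background rate
# around 22% with focal sets elevated to ~27.8%, nCounter panels with six
# positive controls on the standard concentration ladder, eight negative
# controls and three reference genes, and cross-platform fold changes
# correlating around 0.93.
#
# Background promoters are rejection-sampled until motif-free on both strands
# so planted presence probabilities are exact, making the enrichment tests
# sharp rather than approximate.

#' Default parameters of the synthetic study design
#'
#' @param seed master seed.
#' @return named list of generator defaults: toy-genome layout (`n_genes`,
#'   `n_contigs`, `gene_length`, `gap`, `window`), motif-planting rates
#'   (`p0` = 0.22 background, `p1` = 0.278 focal), nCounter design
#'   (`n_endogenous`, `lane_factors` for 3 treated + 3 control lanes,
#'   multiplicative noise `sigma` = 0.1), and the target cross-platform
#'   fold-change correlation `rho` = 0.93.
#' @export
synthetic_spec <- function(seed = 1) {
  list(seed = seed,
       n_genes = 200L, n_contigs = 2L, gene_length = 300L, gap = 100L,
       window = 1000L,
       p0 = 0.22, p1 = 0.278, n_focal = 40L,
       motifs = c("AAGATTTT", "AAGATCTT"),
       n_endogenous = 30L,
       lane_factors = c(1, 1.15, 0.9, 1.05, 0.8, 1.1),
       lane_condition = c("treated", "treated", "treated",
                          "control", "control", "control"),
       sigma = 0.1, rho = 0.93)
}

#' Generate a toy genome and gene annotation
#'
#' Random ACGT contigs with genes laid out in fixed-width slots, each with at
#' least `window` bp of upstream clearance inside its own slot (so promoter
#' windows never overlap or truncate), on alternating strands. Deterministic
#' given the seed.
#'
#' @param n_genes number of genes.
#' @param n_contigs number of contigs (genes split as evenly as possible).
#' @param window promoter window the layout must clear (default 1000).
#' @param gene_length gene-body length in bp.
#' @param gap spacer between gene slots in bp.
#' @param seed RNG seed.
#' @return list with `genome` (`DNAStringSet`) and `genes` (gene-record data
#'   frame as from [read_gene_annotation()]).
#' @export
make_toy_genome <- function(n_genes = 200, n_contigs = 2, window = 1000,
                            gene_length = 300, gap = 100, seed = 1) {
  stopifnot(n_genes >= 0, n_contigs >= 1, window >= 1, gene_length >= 1)
  n_genes <- as.integer(n_genes)
  slot <- as.integer(window + gene_length + gap)
  per_contig <- rep(n_genes %/% n_contigs, n_contigs) +
    (seq_len(n_contigs) <= n_genes %% n_contigs)
  with_seed(seed, {
    contigs <- character(n_contigs)
    rows <- vector("list", n_contigs)
    gidx <- 0L
    for (ci in seq_len(n_contigs)) {
      clen <- max(slot, per_contig[ci] * slot + gap)
      contigs[ci] <- paste0(sample(c("A", "C", "G", "T"), clen,
                                   replace = TRUE), collapse = "")
      if (per_contig[ci] == 0L) next
      s0 <- (seq_len(per_contig[ci]) - 1L) * slot + 1L
      strand <- ifelse((gidx + seq_len(per_contig[ci])) %% 2L == 1L, "+", "-")
      start <- ifelse(strand == "+", s0 + window, s0)
      end <- start + gene_length - 1L
      rows[[ci]] <- data.frame(
        gene_id = sprintf("g%05d", gidx + seq_len(per_contig[ci])),
        contig = sprintf("contig_%d", ci), strand = strand,
        start = start, end = end,
        tss = ifelse(strand == "+", start, end),
        stringsAsFactors = FALSE)
      gidx <- gidx + per_contig[ci]
    }
    genome <- Biostrings::DNAStringSet(contigs)
    names(genome) <- sprintf("contig_%d", seq_len(n_contigs))
    genes <- if (n_genes > 0L) do.call(rbind, rows) else empty_gene_table()
    list(genome = genome, genes = genes)
  })
}

# Random ACGT string of length n (caller manages the RNG state).
random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Plant motifs in promoter windows at known rates
#'
#' Rewrites every gene's promoter window: background sequence is
#' rejection-sampled until it contains no motif k-mer on either strand, then
#' focal genes receive one planted occurrence (uniform random position and
#' strand) with probability `p1` and background genes with probability `p0`.
#' Planted presence is therefore exact, and the returned truth table records
#' each gene's `has_hit` status.
#'
#' @param genome `DNAStringSet` (e.g. from [make_toy_genome()]).
#' @param genes gene-record data frame; every promoter window must lie fully
#'   inside its contig (use [make_toy_genome()] layouts).
#' @param motifset a [motif_set()].
#' @param p0 background planting probability.
#' @param p1 focal-set planting probability.
#' @param focal_set character vector of focal gene ids.
#' @param seed RNG seed.
#' @param window promoter window width (default 1000).
#' @param max_iter rejection-sampling cap per promoter (default 100).
#' @return list with `genome` (modified `DNAStringSet`) and `truth` (data
#'   frame `gene_id`, `focal`, `has_hit`).
#' @export
plant_motifs <- function(genome, genes, motifset, p0 = 0.22, p1 = 0.278,
                         focal_set = character(0), seed = 1, window = 1000,
                         max_iter = 100) {
  stopifnot(inherits(motifset, "motif_set"), length(motifset$kmers) >= 1L,
            p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1)
  window <- as.integer(window)
  if (motifset$k > window) stop("motif length exceeds the promoter window")
  pats <- scan_patterns(motifset, both_strands = TRUE)
  contig_chars <- setNames(as.character(genome), names(genome))
  is_focal <- genes$gene_id %in% focal_set
  k <- motifset$k
  with_seed(seed, {
    has_hit <- logical(nrow(genes))
    for (i in seq_len(nrow(genes))) {
      # genomic coordinates of the window, and whether it must be written
      # back reverse-complemented
      if (genes$strand[i] == "+") {
        from <- genes$tss[i] - window
        to <- genes$tss[i] - 1L
      } else {
        from <- genes$tss[i] + 1L
        to <- genes$tss[i] + window
      }
      if (from < 1L || to > nchar(contig_chars[[genes$contig[i]]])) {
        stop("promoter window of ", genes$gene_id[i],
             " extends beyond its contig; use a layout with upstream clearance")
      }
      prom <- NULL
      for (iter in seq_len(max_iter)) {
        cand <- random_dna(window)
        if (count_matches(cand, pats, k) == 0L) {
          prom <- cand
          break
        }
      }
      if (is.null(prom)) {
        stop("rejection sampling failed for ", genes$gene_id[i], " after ",
             max_iter, " draws; use longer/fewer k-mers or a larger window")
      }
      p_hit <- if (is_focal[i]) p1 else p0
      has_hit[i] <- runif(1L) < p_hit
      if (has_hit[i]) {
        pos <- sample.int(window - k + 1L, 1L)
        kmer <- sample(motifset$kmers, 1L)
        if (runif(1L) < 0.5) kmer <- rev_comp(kmer)
        substr(prom, pos, pos + k - 1L) <- kmer
      }
      genomic <- if (genes$strand[i] == "+") prom else rev_comp(prom)
      substr(contig_chars[[genes$contig[i]]], from, to) <- genomic
    }
    out <- Biostrings::DNAStringSet(contig_chars)
    names(out) <- names(contig_chars)
    list(genome = out,
         truth = data.frame(gene_id = genes$gene_id, focal = is_focal,
                            has_hit = has_hit, stringsAsFactors = FALSE))
  })
}

# Minimal exact window-membership counter used inside rejection sampling
# (independent of the Biostrings scanning path).
count_matches <- function(seq, pats, k) {
  n <- nchar(seq)
  if (!length(pats) || k > n) return(0L)
  wins <- substring(seq, seq_len(n - k + 1L), k:n)
  sum(wins %in% pats)
}

#' Simulate a gene universe with planted motif-presence rates
#'
#' Flag-level counterpart of [plant_motifs()] for large universes: per-gene
#' motif presence is drawn directly as Bernoulli(`p1`) for a random focal set
#' and Bernoulli(`p0`) for the background, without generating sequence.
#'
#' @param n_genes universe size (default 30000).
#' @param n_focal focal-set size (default 2890).
#' @param p0,p1 background and focal presence probabilities.
#' @param seed RNG seed.
#' @return list with `universe` (a [gene_universe()]), `focal_ids`, and
#'   `truth` (data frame `gene_id`, `focal`, `has_hit`).
#' @export
simulate_hit_universe <- function(n_genes = 30000, n_focal = 2890,
                                  p0 = 0.22, p1 = 0.278, seed = 1) {
  stopifnot(n_focal <= n_genes)
  with_seed(seed, {
    ids <- sprintf("g%06d", seq_len(n_genes))
    focal <- logical(n_genes)
    focal[sample.int(n_genes, n_focal)] <- TRUE
    has_hit <- runif(n_genes) < ifelse(focal, p1, p0)
    truth <- data.frame(gene_id = ids, focal = focal, has_hit = has_hit,
                        stringsAsFactors = FALSE)
    list(universe = gene_universe(truth[, c("gene_id", "has_hit")]),
         focal_ids = ids[focal], truth = truth)
  })
}

#' Simulate an nCounter panel with known ground truth
#'
#' The expected count of probe `p` in lane `j` is
#' `lane_factor[j] * (baseline[p] * effect[p, j] + bg)`, with `bg` the
#' nonspecific-binding background every probe sits on (negative controls have
#' baseline 0, so they measure it directly). When `sigma > 0`, endogenous
#' probes receive multiplicative log-normal noise `exp(N(0, sigma^2))` on
#' their expression level — per-transcript variability across the independent
#' hybridizations — and every probe receives Poisson counting noise. Spike-in
#' positive controls (standard six-point concentration ladder) and the
#' reference genes carry counting noise only: they are exactly the stability
#' anchors the normalization assumes. `sigma = 0` switches all noise off, so
#' normalization recovers the planted ratios exactly (up to rounding).
#'
#' Endogenous effects are `2^log2fc` in treated lanes; `log2fc = -Inf`
#' encodes a transcript absent from treated samples (and `+Inf` absent from
#' controls), which the normalization should flag `nd`.
#'
#' @param n_endogenous number of endogenous probes.
#' @param true_log2fc per-probe true log2 fold change (default drawn
#'   `N(0, 1.5^2)`); may contain `-Inf`/`Inf`, see above.
#' @param lane_factors per-lane scale factors (length 6 by default).
#' @param lane_condition `"treated"`/`"control"` per lane.
#' @param sigma log-normal noise SD for endogenous probes (default 0.1);
#'   0 disables all noise.
#' @param bg background level in counts (default 10).
#' @param pos_scale counts per fM of the positive ladder (default 2000).
#' @param ref_baseline reference-gene expression level (default 20000).
#' @param seed RNG seed.
#' @return list with `panel` (a [nanostring_panel()]) and `truth` (list:
#'   `log2fc` named by endogenous probe, `lane_factors`, `baseline`, `bg`,
#'   `sigma`).
#' @export
simulate_nanostring_panel <- function(n_endogenous = 30, true_log2fc = NULL,
                                      lane_factors = c(1, 1.15, 0.9, 1.05, 0.8, 1.1),
                                      lane_condition = c("treated", "treated",
                                                         "treated", "control",
                                                         "control", "control"),
                                      sigma = 0.1, bg = 10, pos_scale = 2000,
                                      ref_baseline = 20000, seed = 1) {
  stopifnot(sigma >= 0, all(lane_factors > 0),
            length(lane_factors) == length(lane_condition))
  pos_conc <- c(128, 32, 8, 2, 0.5, 0.125)
  with_seed(seed, {
    if (is.null(true_log2fc)) true_log2fc <- rnorm(n_endogenous, 0, 1.5)
    stopifnot(length(true_log2fc) == n_endogenous)
    # baselines snapped to multiples of 8 so noiseless panels with fold
    # changes in 2^{-3..3} have integer expected counts (the exactness the
    # sigma = 0 case promises)
    endo_base <- 8 * round(exp(rnorm(n_endogenous, log(800), 0.8)) / 8)
    endo_base <- pmax(endo_base, 104)
    probes <- c(sprintf("endo_%03d", seq_len(n_endogenous)),
                sprintf("pos_%s", LETTERS[seq_along(pos_conc)]),
                sprintf("neg_%02d", 1:8),
                sprintf("ref_%d", 1:3))
    classes <- rep(c("endogenous", "positive", "negative", "reference"),
                   c(n_endogenous, length(pos_conc), 8L, 3L))
    baseline <- c(endo_base, pos_conc * pos_scale, rep(0, 8L),
                  rep(ref_baseline, 3L))
    nlane <- length(lane_factors)
    counts <- matrix(0, nrow = length(probes), ncol = nlane,
                     dimnames = list(probes, sprintf("lane_%d", seq_len(nlane))))
    effect <- matrix(1, nrow = length(probes), ncol = nlane)
    treated <- lane_condition == "treated"
    fold <- 2^true_log2fc
    endo <- seq_len(n_endogenous)
    effect[endo, treated] <-
      ifelse(is.infinite(fold) & fold > 0, 1,
             ifelse(fold == 0 | (is.infinite(true_log2fc) & true_log2fc < 0),
                    0, fold))
    effect[endo, !treated] <-
      ifelse(is.infinite(true_log2fc) & true_log2fc > 0, 0, 1)
    for (j in seq_len(nlane)) {
      expr <- baseline * effect[, j]
      if (sigma > 0) {
        expr[endo] <- expr[endo] * exp(rnorm(n_endogenous, 0, sigma))
        counts[, j] <- rpois(length(probes),
                             lane_factors[j] * (expr + bg))
      } else {
        counts[, j] <- round(lane_factors[j] * (expr + bg))
      }
    }
    panel <- nanostring_panel(counts, classes, lane_condition, pos_conc)
    names(true_log2fc) <- probes[endo]
    list(panel = panel,
         truth = list(log2fc = true_log2fc, lane_factors = lane_factors,
                      baseline = setNames(baseline, probes), bg = bg,
                      sigma = sigma))
  })
}

#' Simulate paired cross-platform fold changes with a target correlation
#'
#' Pairs drawn from a bivariate normal with unit variances and correlation
#' `rho`, emulating the same genes' log2 fold changes measured on two
#' platforms.
#'
#' @param n number of gene pairs.
#' @param rho target correlation in `[-1, 1]` (default 0.93).
#' @param seed RNG seed.
#' @return data frame `gene_id`, `log2fc_a`, `log2fc_b`.
#' @export
simulate_paired_foldchanges <- function(n, rho = 0.93, seed = 1) {
  stopifnot(abs(rho) <= 1, n >= 1)
  with_seed(seed, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    data.frame(gene_id = sprintf("g%05d", seq_len(n)),
               log2fc_a = x, log2fc_b = y, stringsAsFactors = FALSE)
  })
}

#' Simulate a differential-expression table
#'
#' Gene-level DE calls with a planted up/down split, for exercising direction
#' summaries and overlap analyses. FDR values are drawn uniformly below the
#' cutoff so every row passes ingestion filtering.
#'
#' @param n number of DE genes.
#' @param frac_up fraction up-regulated (default 0.6, typical of
#'   cytokinin-treated root tissue).
#' @param gene_ids optional gene ids (default generated).
#' @param fdr_threshold upper bound for simulated FDRs (default 1e-4).
#' @param effect_sd SD of log2 fold-change magnitudes.
#' @param seed RNG seed.
#' @return DE table data frame (`gene_id`, `log2fc`, `fdr`).
#' @export
simulate_de_table <- function(n, frac_up = 0.6, gene_ids = NULL,
                              fdr_threshold = 1e-4, effect_sd = 1.5,
                              seed = 1) {
  stopifnot(frac_up >= 0, frac_up <= 1, n >= 0)
  with_seed(seed, {
    if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(n))
    stopifnot(length(gene_ids) == n, !anyDuplicated(gene_ids))
    up <- runif(n) < frac_up
    lfc <- abs(rnorm(n, 0, effect_sd)) + 0.1
    lfc[!up] <- -lfc[!up]
    data.frame(gene_id = gene_ids, log2fc = lfc,
               fdr = runif(n, 0, fdr_threshold), stringsAsFactors = FALSE)
  })
}
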