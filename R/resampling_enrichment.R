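# The core statistic: is the fraction of a gene set whose promoters contain a
# binding motif unusually high or low, relative to random gene samples of the
# same size drawn from a gene universe?
#
# The empirical test draws N same-size samples without replacement from the
# full universe (focal genes are not excluded) and counts samples whose
# presence fraction is strictly higher (enrichment) or strictly lower
# (depletion) than the observed one; ties are tracked separately. Because
# per-gene motif presence is a fixed binary attribute sampled without
# replacement, the exact null is Hypergeometric(M, K, n), reported alongside
# the Monte-Carlo estimate as a closed-form cross-check.

#' Construct a gene universe
#'
#' The sampling frame of the enrichment test: every gene eligible for random
#' sampling (typically all genes with an extractable promoter, optionally
#' restricted to expressed genes) with its motif-presence status.
#'
#' @param hit_table data frame with `gene_id` and `has_hit` columns
#'   (e.g. from [scan_promoters()]).
#' @return object of class `gene_universe`: list with `gene_ids`, `has_hit`,
#'   `M` (universe size) and `K` (number of motif-positive genes).
#' @export
gene_universe <- function(hit_table) {
  stopifnot(is.data.frame(hit_table),
            all(c("gene_id", "has_hit") %in% names(hit_table)))
  if (anyDuplicated(hit_table$gene_id)) {
    stop("duplicated gene_id in hit table")
  }
  structure(list(gene_ids = as.character(hit_table$gene_id),
                 has_hit = as.logical(hit_table$has_hit),
                 M = nrow(hit_table), K = sum(hit_table$has_hit)),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("gene_universe: M = %d genes, K = %d with motif (%.1f%%)\n",
              x$M, x$K, 100 * x$K / max(1L, x$M)))
  invisible(x)
}

#' Observed motif-presence fraction of a gene set
#'
#' @param gene_set character vector of gene ids.
#' @param hit_table data frame with `gene_id`, `has_hit` (or a
#'   `gene_universe`).
#' @return fraction of the set's genes whose promoter contains at least one
#'   motif occurrence.
#' @export
presence_fraction <- function(gene_set, hit_table) {
  if (inherits(hit_table, "gene_universe")) {
    hit_table <- data.frame(gene_id = hit_table$gene_ids,
                            has_hit = hit_table$has_hit,
                            stringsAsFactors = FALSE)
  }
  gene_set <- as.character(gene_set)
  if (!length(gene_set)) stop("empty gene set")
  idx <- match(gene_set, hit_table$gene_id)
  if (anyNA(idx)) {
    stop("gene_id(s) absent from hit table: ",
         paste(head(gene_set[is.na(idx)], 5L), collapse = ", "))
  }
  mean(hit_table$has_hit[idx])
}

#' Monte-Carlo resampling enrichment test
#'
#' Draws `N` random samples of `n` genes (without replacement) from the
#' universe and compares each sample's motif-presence fraction with the
#' observed fraction `f_obs` of the focal set. `p_enriched` is the fraction of
#' samples strictly higher, `p_depleted` the fraction strictly lower; ties are
#' counted separately so the three always sum to `N`. Exact hypergeometric
#' tail probabilities (`P(X > x_obs)` and `P(X < x_obs)` for
#' `X ~ Hypergeometric(M, K, n)`) are reported as a closed-form cross-check,
#' together with the conservative estimators `(r + 1) / (N + 1)`.
#'
#' @param universe a [gene_universe()].
#' @param n focal-set size (1 <= n <= M).
#' @param f_obs observed presence fraction of the focal set.
#' @param N number of resamples (default 1000).
#' @param seed RNG seed; drawn at random (and recorded) when `NULL`.
#' @param set_label label carried into reports.
#' @return object of class `enrichment_result`: list with `set_label`, `n`,
#'   `f_obs`, `N`, `n_higher`, `n_lower`, `n_tied`, `p_enriched`,
#'   `p_depleted`, conservative variants `p_enriched_cons`/`p_depleted_cons`,
#'   exact tails `p_exact_enriched`/`p_exact_depleted`, `seed`, and the `N`
#'   null fractions (`null_fractions`) for histogramming.
#' @export
resampling_test <- function(universe, n, f_obs, N = 1000, seed = NULL,
                            set_label = "") {
  stopifnot(inherits(universe, "gene_universe"))
  M <- universe$M
  K <- universe$K
  n <- as.integer(n)
  N <- as.integer(N)
  if (n < 1L || n > M) stop("focal-set size n must satisfy 1 <= n <= M")
  if (N < 1L) stop("number of resamples N must be >= 1")
  stopifnot(f_obs >= 0, f_obs <= 1)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  hit <- universe$has_hit
  null_counts <- with_seed(seed, {
    vapply(seq_len(N), function(i) sum(hit[sample.int(M, n)]), integer(1L))
  })
  x_obs <- f_obs * n
  eps <- 1e-9
  n_higher <- sum(null_counts > x_obs + eps)
  n_lower <- sum(null_counts < x_obs - eps)
  n_tied <- N - n_higher - n_lower
  x_int <- round(x_obs)
  structure(list(
    set_label = set_label, n = n, f_obs = f_obs, N = N,
    n_higher = n_higher, n_lower = n_lower, n_tied = n_tied,
    p_enriched = n_higher / N,
    p_depleted = n_lower / N,
    p_enriched_cons = (n_higher + 1) / (N + 1),
    p_depleted_cons = (n_lower + 1) / (N + 1),
    p_exact_enriched = phyper(floor(x_obs + eps), K, M - K, n,
                              lower.tail = FALSE),
    p_exact_depleted = phyper(ceiling(x_obs - eps) - 1, K, M - K, n),
    M = M, K = K, x_obs = x_int, seed = as.integer(seed),
    null_fractions = null_counts / n
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0(
    "enrichment_result '%s': n = %d, f_obs = %.3f (universe M = %d, K = %d)\n",
    "  N = %d resamples: %d higher / %d lower / %d tied\n",
    "  p_enriched = %.4g (exact %.4g), p_depleted = %.4g (exact %.4g), seed = %d\n"),
    x$set_label, x$n, x$f_obs, x$M, x$K, x$N, x$n_higher, x$n_lower,
    x$n_tied, x$p_enriched, x$p_exact_enriched, x$p_depleted,
    x$p_exact_depleted, x$seed))
  invisible(x)
}

#' Null-fraction histogram of an enrichment result
#'
#' Bin counts of the resampled presence fractions, for plotting the null
#' distribution with the observed fraction marked.
#'
#' @param result an `enrichment_result`.
#' @param bins number of equal-width bins over the observed null range.
#' @return data frame `bin_left`, `bin_right`, `count`.
#' @export
null_histogram <- function(result, bins = 30) {
  stopifnot(inherits(result, "enrichment_result"))
  f <- result$null_fractions
  rng <- range(c(f, result$f_obs))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) / result$n
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  h <- hist(f, breaks = breaks, plot = FALSE)
  data.frame(bin_left = h$breaks[-length(h$breaks)],
             bin_right = h$breaks[-1L], count = h$counts)
}

#' Enrichment report over multiple gene sets
#'
#' Runs [resampling_test()] for each gene set (e.g. up- and down-regulated DE
#' lists) against one universe, with per-set seeds derived from one master
#' seed. When more than one set is tested, Benjamini-Hochberg adjusted values
#' are appended (`p_enriched_bh`, `p_depleted_bh`); the raw empirical values
#' remain primary.
#'
#' @param universe a [gene_universe()].
#' @param gene_sets named list of gene-id character vectors; every gene must
#'   be present in the universe.
#' @param N resamples per set (default 1000).
#' @param seed master seed.
#' @return list with `results` (named list of `enrichment_result`),
#'   `summary` (one data-frame row per set) and `histograms` (named list of
#'   [null_histogram()] frames).
#' @export
enrichment_report <- function(universe, gene_sets, N = 1000, seed = NULL) {
  stopifnot(inherits(universe, "gene_universe"), is.list(gene_sets),
            length(gene_sets) >= 1L)
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("gene_sets must be a named list")
  }
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  seeds <- derive_seeds(seed, length(gene_sets))
  results <- vector("list", length(gene_sets))
  names(results) <- names(gene_sets)
  for (i in seq_along(gene_sets)) {
    set <- gene_sets[[i]]
    f <- presence_fraction(set, universe)
    results[[i]] <- resampling_test(universe, length(set), f, N = N,
                                    seed = seeds[i],
                                    set_label = names(gene_sets)[i])
  }
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(set_label = r$set_label, n = r$n, f_obs = r$f_obs, N = r$N,
               n_higher = r$n_higher, n_lower = r$n_lower, n_tied = r$n_tied,
               p_enriched = r$p_enriched, p_depleted = r$p_depleted,
               p_exact_enriched = r$p_exact_enriched,
               p_exact_depleted = r$p_exact_depleted,
               seed = r$seed, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  if (nrow(summary) > 1L) {
    summary$p_enriched_bh <- p.adjust(summary$p_enriched, "BH")
    summary$p_depleted_bh <- p.adjust(summary$p_depleted, "BH")
  }
  list(results = results, summary = summary,
       histograms = lapply(results, null_histogram))
}

#' Write an enrichment summary as TSV
#'
#' @param report result of [enrichment_report()].
#' @param path output path.
#' @param manifest extra manifest entries.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(report, path, manifest = list()) {
  write_tsv_manifest(report$summary, path, manifest)
}
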