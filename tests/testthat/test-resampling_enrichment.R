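universe_from_flags <- function(flags) {
  gene_universe(data.frame(gene_id = sprintf("g%04d", seq_along(flags)),
                           has_hit = flags, stringsAsFactors = FALSE))
}

test_that("presence_fraction counts hit genes and validates membership", {
  ht <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   has_hit = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(presence_fraction(c("g1", "g2", "g3", "g4"), ht), 0.5)
  expect_equal(presence_fraction(c("g1", "g3"), ht), 1.0)
  expect_error(presence_fraction(character(0), ht), "empty")
  expect_error(presence_fraction(c("g1", "gz"), ht), "gz")
})

test_that("sampling the whole universe is degenerate and results are deterministic", {
  u <- universe_from_flags(c(rep(TRUE, 5), rep(FALSE, 7)))
  r <- resampling_test(u, n = u$M, f_obs = u$K / u$M, N = 500, seed = 11)
  expect_equal(r$n_higher, 0L)
  expect_equal(r$n_lower, 0L)
  expect_equal(r$n_tied, 500L)
  expect_equal(r$p_enriched, 0)
  expect_equal(r$p_depleted, 0)

  a <- resampling_test(u, 5, 0.8, N = 2000, seed = 99)
  b <- resampling_test(u, 5, 0.8, N = 2000, seed = 99)
  expect_identical(a, b)

  expect_error(resampling_test(u, 13, 0.5, seed = 1), "1 <= n <= M")
  expect_error(resampling_test(u, 5, 0.5, N = 0, seed = 1), "N")
})

test_that("tail bookkeeping is exact: counts sum to N and p-values match them", {
  set.seed(5)
  u <- universe_from_flags(runif(200) < 0.3)
  for (i in 1:10) {
    n <- sample(2:150, 1)
    f <- sample(0:n, 1) / n
    r <- resampling_test(u, n, f, N = 300, seed = i)
    expect_equal(r$n_higher + r$n_lower + r$n_tied, r$N)
    expect_equal(r$p_enriched, r$n_higher / r$N)
    expect_equal(r$p_depleted, r$n_lower / r$N)
    expect_equal(r$p_enriched + r$p_depleted + r$n_tied / r$N, 1)
  }
})

test_that("Monte-Carlo tails agree with the hypergeometric closed form", {
  # M = 12, K = 5, n = 5, observed 4/5: P(null fraction > 0.8) = P(X = 5)
  #   = choose(5, 5) * choose(7, 0) / choose(12, 5) = 1/792
  u <- universe_from_flags(c(rep(TRUE, 5), rep(FALSE, 7)))
  r <- resampling_test(u, 5, 4 / 5, N = 20000, seed = 42)
  expect_equal(r$p_exact_enriched, 1 / 792, tolerance = 1e-12)
  expect_lt(abs(r$p_enriched - 1 / 792),
            4 * sqrt((1 / 792) * (791 / 792) / 20000))

  # a small grid of configurations, each within the 4-sigma binomial bound
  grid <- list(c(M = 30, K = 10, n = 8, x = 5),
               c(M = 50, K = 25, n = 10, x = 7),
               c(M = 20, K = 4, n = 6, x = 2))
  for (g in grid) {
    u <- universe_from_flags(c(rep(TRUE, g[["K"]]), rep(FALSE, g[["M"]] - g[["K"]])))
    f <- g[["x"]] / g[["n"]]
    r <- resampling_test(u, g[["n"]], f, N = 20000, seed = 7)
    p_exact <- phyper(g[["x"]], g[["K"]], g[["M"]] - g[["K"]], g[["n"]],
                      lower.tail = FALSE)
    expect_equal(r$p_exact_enriched, p_exact, tolerance = 1e-12)
    expect_lt(abs(r$p_enriched - p_exact),
              4 * sqrt(p_exact * (1 - p_exact) / 20000) + 1e-12)
  }
})

test_that("relabeling hit and non-hit genes swaps enrichment and depletion exactly", {
  set.seed(17)
  flags <- runif(100) < 0.4
  u <- universe_from_flags(flags)
  uf <- universe_from_flags(!flags)
  n <- 20
  f <- 0.33  # not attainable as k/20, so no ties blur the swap
  r <- resampling_test(u, n, f, N = 1000, seed = 13)
  rf <- resampling_test(uf, n, 1 - f, N = 1000, seed = 13)
  expect_equal(r$n_higher, rf$n_lower)
  expect_equal(r$n_lower, rf$n_higher)
})

test_that("enrichment_report detects planted enrichment and depletion", {
  sim <- simulate_hit_universe(n_genes = 3000, n_focal = 200, p0 = 0.2,
                               p1 = 0.6, seed = 21)
  # a depleted set: 200 background genes with the lowest possible hit load
  bg <- sim$truth[!sim$truth$focal, ]
  depleted <- bg$gene_id[order(bg$has_hit)][1:200]
  rep <- enrichment_report(sim$universe,
                           list(up = sim$focal_ids, down = depleted),
                           N = 1000, seed = 8)
  expect_lt(rep$results$up$p_enriched, 0.05)
  expect_lt(rep$results$down$p_depleted, 0.05)
  expect_true(all(c("p_enriched_bh", "p_depleted_bh") %in% names(rep$summary)))
  expect_equal(nrow(rep$summary), 2L)
  # histogram bins cover all resamples
  expect_equal(sum(rep$histograms$up$count), 1000L)

  expect_error(enrichment_report(sim$universe, list(sim$focal_ids), seed = 1),
               "named")
})

test_that("null p-values are approximately uniform for random focal sets", {
  # quick calibration check (the full 500-replicate version backs the
  # acceptance suite): 150 random sets, N = 400 resamples
  set.seed(29)
  flags <- runif(1000) < 0.4
  u <- universe_from_flags(flags)
  ids <- sprintf("g%04d", seq_len(1000))
  set.seed(123)
  pvals <- vapply(1:150, function(i) {
    focal <- sample(ids, 80)
    resampling_test(u, 80, presence_fraction(focal, u), N = 400,
                    seed = 1000 + i)$p_enriched
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
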