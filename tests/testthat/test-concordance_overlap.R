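paired_df <- function(a, b, ids = sprintf("g%03d", seq_along(a))) {
  data.frame(gene_id = ids, log2fc_a = a, log2fc_b = b,
             stringsAsFactors = FALSE)
}

test_that("concordance on exact lines and degenerate inputs", {
  r <- platform_concordance(paired_df(c(-1, 0, 2, 3), c(-1, 0, 2, 3)))
  expect_equal(r$pearson_r, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)

  r2 <- platform_concordance(paired_df(c(-1, 0, 2), c(1, 0, -2)))
  expect_equal(r2$pearson_r, -1)

  expect_error(platform_concordance(paired_df(c(1, NA), c(2, 3))), "fewer than 2")
  expect_error(platform_concordance(paired_df(c(1, 1, 1), c(1, 2, 3))),
               "zero variance")
})

test_that("nd policies exclude or zero-substitute missing fold changes", {
  df <- paired_df(c(1, 2, NA, 4), c(1.1, 2.2, 3.0, NA))
  rex <- platform_concordance(df, "exclude")
  expect_equal(rex$n_pairs, 2L)
  expect_equal(rex$excluded_nd, 2L)
  rz <- platform_concordance(df, "zero")
  expect_equal(rz$n_pairs, 4L)
  expect_equal(rz$excluded_nd, 0L)
  expect_equal(rz$pearson_r, cor(c(1, 2, 0, 4), c(1.1, 2.2, 3.0, 0)))
})

test_that("Pearson r respects affine transforms and matches the hand formula", {
  set.seed(8)
  x <- rnorm(60)
  y <- 0.8 * x + rnorm(60, 0, 0.4)
  base <- platform_concordance(paired_df(x, y))$pearson_r
  expect_equal(platform_concordance(paired_df(3 * x + 2, y))$pearson_r, base,
               tolerance = 1e-12)
  expect_equal(platform_concordance(paired_df(-2 * x, y))$pearson_r, -base,
               tolerance = 1e-12)
  expect_equal(base, hand_pearson(x, y), tolerance = 1e-12)
})

test_that("set overlap decomposes the intersection by direction and is symmetric", {
  A <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1.5, -2))
  B <- data.frame(gene_id = c("g2", "g3"), log2fc = c(0.5, -1))
  ov <- set_overlap(A, B)
  expect_equal(ov$n_intersect, 1L)
  expect_equal(ov$n_same_direction, 0L)
  expect_equal(ov$n_opposite, 1L)

  dj <- set_overlap(data.frame(gene_id = "a", log2fc = 1),
                    data.frame(gene_id = "b", log2fc = 1))
  expect_equal(dj$n_intersect, 0L)
  expect_equal(dj$n_same_direction + dj$n_opposite + dj$n_undirected, 0L)

  # brute-force oracle on a planted co-membership design
  set.seed(55)
  ids <- sprintf("g%03d", 1:200)
  a_ids <- sample(ids, 120)
  b_ids <- c(sample(a_ids, 72), sample(setdiff(ids, a_ids), 40))
  A2 <- data.frame(gene_id = a_ids, log2fc = rnorm(120))
  B2 <- data.frame(gene_id = b_ids, log2fc = rnorm(112))
  ov2 <- set_overlap(A2, B2)
  common <- intersect(a_ids, b_ids)
  sa <- sign(A2$log2fc[match(common, A2$gene_id)])
  sb <- sign(B2$log2fc[match(common, B2$gene_id)])
  expect_equal(ov2$n_intersect, length(common))
  expect_equal(ov2$n_same_direction, sum(sa == sb))
  expect_equal(ov2$n_opposite, sum(sa != sb))
  ba <- set_overlap(B2, A2)
  expect_equal(ba$n_intersect, ov2$n_intersect)
  expect_equal(ba$n_same_direction, ov2$n_same_direction)
  expect_equal(ba$n_opposite, ov2$n_opposite)

  expect_error(set_overlap(data.frame(gene_id = c("a", "a"), log2fc = 1:2), B),
               "duplicated")
})

test_that("ortholog concordance uses the same > opposite > not-DE precedence", {
  de_src <- data.frame(gene_id = c("a1", "a2", "a3"), log2fc = c(1, 1, -1))
  de_tgt <- data.frame(gene_id = c("r1", "r2", "r3"), log2fc = c(2, -2, 1))

  # one-to-one, all same sign
  map11 <- data.frame(source_id = "a1", target_id = "r1")
  r <- ortholog_concordance(map11, de_src[1, ], de_tgt)
  expect_equal(r$frac_same_direction, 1.0)

  # a2 has no ortholog -> excluded from the denominator
  map <- data.frame(source_id = c("a1", "a3"), target_id = c("r1", "r2"))
  r2 <- ortholog_concordance(map, de_src, de_tgt)
  expect_equal(r2$n_source, 3L)
  expect_equal(r2$n_with_ortholog, 2L)
  expect_equal(r2$frac_with_ortholog, 2 / 3)
  expect_equal(r2$n_same_direction, 2L)  # a3 (down) -> r2 (down)

  # many-to-many: a1 up maps to one up and one down target -> same wins
  mapmm <- data.frame(source_id = c("a1", "a1"), target_id = c("r1", "r2"))
  r3 <- ortholog_concordance(mapmm, de_src[1, ], de_tgt)
  expect_equal(r3$n_same_direction, 1L)
  expect_equal(r3$n_opposite_direction, 0L)

  # orthologs present but none DE -> not-DE
  map_nde <- data.frame(source_id = "a1", target_id = "rx")
  r4 <- ortholog_concordance(map_nde, de_src[1, ], de_tgt)
  expect_equal(r4$n_not_de, 1L)

  expect_error(ortholog_concordance(map[0, ], de_src, de_tgt), "empty")
})

test_that("simulated paired fold changes hit their target correlation", {
  d1 <- simulate_paired_foldchanges(50, rho = 1, seed = 2)
  expect_equal(cor(d1$log2fc_a, d1$log2fc_b), 1, tolerance = 1e-12)
  hits <- vapply(1:20, function(s) {
    d <- simulate_paired_foldchanges(500, rho = 0.93, seed = s)
    abs(cor(d$log2fc_a, d$log2fc_b) - 0.93) <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the bundled validation panel reproduces its published concordance", {
  vp <- nanostring_validation_panel()
  expect_equal(nrow(vp), 32L)
  # one root probe undetected after treatment, one shoot probe in neither
  expect_equal(vp$gene_id[vp$root_nano_code == "nd"], "Os03g42070")
  expect_equal(vp$gene_id[vp$shoot_nano_code == "ND"], "Os07g06860")
  ok <- !is.na(vp$root_rnaseq) & !is.na(vp$root_nano)
  r <- platform_concordance(paired_df(vp$root_rnaseq, vp$root_nano,
                                      ids = vp$gene_id), "exclude")
  expect_gt(r$pearson_r, 0.9)
  expect_equal(r$pearson_r, hand_pearson(vp$root_rnaseq[ok], vp$root_nano[ok]),
               tolerance = 1e-12)
})
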