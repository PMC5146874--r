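test_that("background threshold is mean + 2 sample SD of the negatives", {
  panel <- toy_panel(neg = c(4, 6, 5, 5, 5, 5))
  B <- background_threshold(panel)
  expect_equal(unname(B), rep(5 + 2 * sqrt(0.4), 2), tolerance = 1e-12)

  # all-zero negatives give B = 0, and a count of 0 is then not detected
  p0 <- toy_panel(neg = rep(0, 8), endo = 0)
  cor0 <- subtract_background(p0)
  expect_equal(unname(attr(cor0, "B")), c(0, 0))
  expect_true(all(is.na(cor0["e1", ])))

  expect_error(nanostring_panel(matrix(5, 3, 2),
                                c("negative", "positive", "reference"),
                                c("treated", "control")),
               "negative")
})

test_that("background subtraction flags rather than floors", {
  panel <- toy_panel(neg = c(4, 6, 5, 5, 5, 5), endo = c(10, 6))
  cor <- subtract_background(panel)
  B <- 5 + 2 * sqrt(0.4)
  expect_equal(unname(cor["e1", 1]), 10 - B, tolerance = 1e-12)
  expect_true(all(is.na(cor["e2", ])))  # 6 <= 6.265
})

test_that("positive-control scaling uses geometric means against the lane average", {
  p <- toy_panel(pos = c(100, 200, 400, 100, 200, 400), neg = rep(0, 8))
  s <- positive_control_scale(p)
  expect_equal(unname(attr(s, "geomeans")), rep(200, 2))
  expect_equal(as.numeric(s), c(1, 1))

  # doubling one lane's positives halves its factor; scale x geomean constant
  p2 <- toy_panel(pos = c(100, 200, 400, 100, 200, 400), neg = rep(0, 8),
                  lane_mult = c(1, 2))
  s2 <- positive_control_scale(p2)
  expect_equal(s2[[2]], s2[[1]] / 2)
  expect_equal(as.numeric(s2 * attr(s2, "geomeans")), rep(300, 2))

  expect_error(positive_control_scale(toy_panel(pos = c(0, 10, 10, 10, 10, 10),
                                                neg = rep(0, 8))),
               "not detected")
})

test_that("reference scaling follows positive scaling and reports failures by name", {
  p <- toy_panel(ref = c(800, 900, 1000))
  norm <- normalize_nanostring(p)
  expect_equal(unname(norm$s_ref), c(1, 1))

  # one lane with references uniformly 4x gets a quarter the relative factor
  # (zero negatives so background subtraction preserves exact ratios)
  p4 <- toy_panel(neg = rep(0, 8))
  p4$counts[c("r1", "r2", "r3"), 2] <- p4$counts[c("r1", "r2", "r3"), 2] * 4
  n4 <- normalize_nanostring(p4)
  expect_equal(n4$s_ref[[2]] / n4$s_ref[[1]], 1 / 4, tolerance = 1e-9)

  plow <- toy_panel()
  plow$counts["r2", 2] <- 0
  expect_error(normalize_nanostring(plow), "r2")
})

test_that("normalized values are scale-invariant up to one global factor", {
  sim <- simulate_nanostring_panel(n_endogenous = 12, seed = 4)
  base <- normalize_nanostring(sim$panel)
  scaled_panel <- sim$panel
  scaled_panel$counts[, 3] <- scaled_panel$counts[, 3] * 3
  scaled <- normalize_nanostring(scaled_panel)
  ratio <- scaled$values / base$values
  # one common factor across every detected cell in every lane ...
  expect_lt(diff(range(ratio, na.rm = TRUE)), 1e-9)
  # ... so fold changes are exactly invariant
  expect_equal(nanostring_log2fc(scaled)$log2fc,
               nanostring_log2fc(base)$log2fc, tolerance = 1e-12)
})

test_that("raising an endogenous count never lowers its normalized value", {
  sim <- simulate_nanostring_panel(n_endogenous = 6, seed = 12)
  base <- normalize_nanostring(sim$panel)
  bumped_panel <- sim$panel
  bumped_panel$counts["endo_003", 2] <- bumped_panel$counts["endo_003", 2] + 50
  bumped <- normalize_nanostring(bumped_panel)
  expect_gte(bumped$values["endo_003", 2], base$values["endo_003", 2])
})

test_that("fold changes use detected condition means and propagate nd codes", {
  p <- toy_panel(neg = rep(0, 8), endo = c(8, 5, 5), lanes = 2)
  p$counts["e1", ] <- c(8, 2)
  p$counts["e2", ] <- c(5, 5)
  p$counts["e3", ] <- c(0, 7)
  fc <- nanostring_log2fc(normalize_nanostring(p))
  expect_equal(fc$log2fc[fc$probe == "e1"], 2)
  expect_equal(fc$log2fc[fc$probe == "e2"], 0)
  expect_equal(fc$status[fc$probe == "e3"], "nd-treated")

  sim0 <- simulate_nanostring_panel(n_endogenous = 4,
                                    true_log2fc = c(2, 0, -1, Inf),
                                    lane_factors = rep(1, 6), sigma = 0,
                                    seed = 2)
  fc0 <- nanostring_log2fc(normalize_nanostring(sim0$panel))
  expect_equal(fc0$log2fc[1:3], c(2, 0, -1), tolerance = 1e-12)
  expect_equal(fc0$status[4], "nd-control")
})

test_that("simulated panels recover lane factors and fold changes", {
  sim <- simulate_nanostring_panel(seed = 31)
  norm <- normalize_nanostring(sim$panel)
  combined <- norm$s_pos * norm$s_ref * sim$truth$lane_factors
  expect_lt(max(abs(combined / mean(combined) - 1)), 0.05)
  fc <- nanostring_log2fc(norm)
  err <- fc$log2fc - sim$truth$log2fc[fc$probe]
  expect_lt(abs(mean(err, na.rm = TRUE)), 0.1)
  # QC: ladder counts are linear in known concentration
  expect_true(all(norm$qc$r_squared > 0.99))
  expect_equal(norm$qc$slope, rep(1, 6), tolerance = 0.05)
})

test_that("panels round-trip through their TSV representation", {
  sim <- simulate_nanostring_panel(n_endogenous = 5, seed = 6)
  d <- withr::local_tempdir()
  f <- file.path(d, c("c.tsv", "p.tsv", "l.tsv"))
  write_nanostring_panel(sim$panel, f[1], f[2], f[3])
  back <- read_nanostring_panel(f[1], f[2], f[3])
  expect_equal(back$counts, sim$panel$counts)
  expect_equal(back$probe_class, sim$panel$probe_class)
  expect_equal(back$lane_condition, sim$panel$lane_condition)
  expect_equal(back$positive_conc, sim$panel$positive_conc)
})
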