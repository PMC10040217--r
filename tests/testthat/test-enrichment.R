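test_that("bonferroni adjustment equals min(1, m * p)", {
  expect_equal(bonferroni_adjust(c(0.01, 0.5), 2), c(0.02, 1.0))
  expect_equal(bonferroni_adjust(1.0, 5), 1.0)
  set.seed(3)
  for (i in 1:50) {
    p <- stats::runif(sample(1:20, 1))
    m <- length(p) + sample(0:5, 1)
    expect_equal(bonferroni_adjust(p, m), pmin(1, m * p))
  }
  # agrees with stats::p.adjust when m == length(p)
  p <- stats::runif(10)
  expect_equal(bonferroni_adjust(p), stats::p.adjust(p, "bonferroni"))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(stats::runif(5), m = 3), "at least")
})

test_that("a comparison identical to the anchor hits the p floor, enriched", {
  g <- toy_genome(c(chrA = 50000, chrB = 30000))
  anchor <- iv("chrA", c(100, 5000, 20000), c(400, 5600, 20900))
  e <- permutation_enrichment(anchor, anchor, g, n_perm = 99, seed = 1)
  expect_equal(e$p_enrich, 1 / 100)
  expect_equal(e$direction, "enriched")
  expect_equal(e$observed_bp, covered_bp(anchor))
  expect_gt(e$log2_fold_enrichment, 0)
})

test_that("zero observed overlap of a tiny anchor gives p_enrich near 1", {
  g <- toy_genome(c(chrA = 100000))
  anchor <- iv("chrA", 0, 50)
  comparison <- iv("chrA", c(60000, 80000), c(60100, 80100))
  e <- permutation_enrichment(anchor, comparison, g, n_perm = 200, seed = 2)
  expect_equal(e$observed_bp, 0)
  expect_gt(e$p_enrich, 0.9)
  expect_equal(e$p_deplete, 1)
})

test_that("null mean matches the exhaustive-placement expectation", {
  # closed-form-by-enumeration oracle: average overlap of each comparison
  # length over every possible start, summed over comparison intervals
  g <- toy_genome(c(chrA = 6000, chrB = 4000))
  anchor <- iv("chrA", c(500, 2000, 4000), c(1200, 2600, 4800))
  comparison <- iv(c("chrA", "chrB"), c(100, 300), c(150, 380))
  e <- permutation_enrichment(anchor, comparison, g, n_perm = 200, seed = 5)
  expected <- sum(vapply(comparison$end - comparison$start,
                         expected_overlap_exhaustive, numeric(1),
                         anchor = anchor, genome = g))
  se <- e$null_sd_bp / sqrt(e$n_perm)
  expect_lt(abs(e$null_mean_bp - expected), 3 * se + 1e-9)
})

test_that("empirical p-values include the observed tie term on both sides", {
  g <- toy_genome(c(chrA = 20000))
  set.seed(9)
  for (i in 1:5) {
    a <- random_intervals(g, 5, max_len = 200)
    b <- random_intervals(g, 5, max_len = 200)
    e <- permutation_enrichment(a, b, g, n_perm = 50, seed = i)
    expect_gte(e$p_enrich, 1 / 51)
    expect_gte(e$p_deplete, 1 / 51)
    expect_gte(e$p_enrich + e$p_deplete, 1 + 1 / 51)
  }
})

test_that("identical seed and config reproduce the result bit for bit", {
  g <- toy_genome(c(chrA = 30000, chrB = 10000))
  set.seed(1)
  anchor <- random_intervals(g, 10, 300)
  cmps <- list(x = random_intervals(g, 8, 300), y = random_intervals(g, 8, 300))
  s1 <- enrichment_screen(anchor, cmps, g, n_perm = 50, seed = 42)
  s2 <- enrichment_screen(anchor, cmps, g, n_perm = 50, seed = 42)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(attr(s1, "nulls"), attr(s2, "nulls"))
  # and the global RNG stream is left untouched by seeded runs
  set.seed(7); before <- stats::runif(1)
  set.seed(7); invisible(enrichment_screen(anchor, cmps, g, n_perm = 10, seed = 1))
  expect_identical(stats::runif(1), before)
})

test_that("adding a comparison does not perturb the others' nulls", {
  g <- toy_genome(c(chrA = 30000))
  set.seed(2)
  anchor <- random_intervals(g, 10, 300)
  a <- random_intervals(g, 6, 200)
  b <- random_intervals(g, 6, 200)
  c3 <- random_intervals(g, 6, 200)
  s_two <- enrichment_screen(anchor, list(a = a, b = b), g, n_perm = 40, seed = 5)
  s_three <- enrichment_screen(anchor, list(a = a, b = b, c3 = c3), g,
                               n_perm = 40, seed = 5)
  expect_identical(attr(s_two, "nulls")$a, attr(s_three, "nulls")$a)
  expect_identical(attr(s_two, "nulls")$b, attr(s_three, "nulls")$b)
})

test_that("a single-comparison screen leaves the p-value unadjusted", {
  g <- toy_genome(c(chrA = 20000))
  set.seed(4)
  anchor <- random_intervals(g, 8, 200)
  cmp <- random_intervals(g, 8, 200)
  s <- enrichment_screen(anchor, list(only = cmp), g, n_perm = 50, seed = 3)
  expect_equal(s$p_adj, min(s$p_enrich, s$p_deplete))
  expect_error(enrichment_screen(anchor, setNames(list(cmp, cmp), c("x", "x")),
                                 g, n_perm = 10), "duplicate")
})

test_that("log2 fold enrichment never decreases with planted overlap", {
  g <- simulate_genome(2, 1e6)
  anchor <- simulate_anchor_peaks(g, 80, c(200, 600), seed = 10)
  lfc <- vapply(c(0.1, 0.5, 0.9), function(theta) {
    cmp <- simulate_colocalized_peaks(anchor, g, theta, 80, c(200, 600), seed = 11)
    permutation_enrichment(anchor, cmp, g, n_perm = 100, seed = 12)$log2_fold_enrichment
  }, numeric(1))
  expect_true(all(diff(lfc) >= 0))
})

test_that("differential enrichment is symmetric and sign-correct", {
  g <- simulate_genome(2, 1e6)
  anchor1 <- simulate_anchor_peaks(g, 60, c(200, 600), seed = 20)
  anchor2 <- simulate_anchor_peaks(g, 60, c(200, 600), seed = 21)
  coloc1 <- simulate_colocalized_peaks(anchor1, g, 0.9, 60, c(200, 600), seed = 22)

  # same anchor on both sides: deltas are null jitter around zero
  d_same <- differential_enrichment(anchor1, anchor1, list(c1 = coloc1), g,
                                    n_perm = 100, seed = 30)
  expect_lt(abs(d_same$delta_log2_fc), 0.5)

  # comparison co-located only with anchor1: positive delta
  d <- differential_enrichment(anchor1, anchor2, list(c1 = coloc1), g,
                               n_perm = 100, seed = 31)
  expect_gt(d$delta_log2_fc, 0)
  expect_equal(d$delta_log2_fc, d$log2_fc_anchor1 - d$log2_fc_anchor2)
})

test_that("planted differential overlap is recovered against a two-screen oracle", {
  g <- simulate_genome(2, 2e6)
  anchor1 <- simulate_anchor_peaks(g, 80, c(200, 600), seed = 40)
  anchor2 <- simulate_anchor_peaks(g, 80, c(200, 600), seed = 41)
  # one comparison overlapping anchor1 at 0.9 and anchor2 at 0.1
  cmp <- dplyr::bind_rows(
    simulate_colocalized_peaks(anchor1, g, 1, 45, c(200, 600), seed = 42),
    simulate_colocalized_peaks(anchor2, g, 1, 5, c(200, 600), seed = 43))
  d <- differential_enrichment(anchor1, anchor2, list(cmp = cmp), g,
                               n_perm = 150, seed = 44)
  e1 <- permutation_enrichment(anchor1, cmp, g, n_perm = 150, seed = 91)
  e2 <- permutation_enrichment(anchor2, cmp, g, n_perm = 150, seed = 92)
  expect_lt(abs(d$delta_log2_fc -
                  (e1$log2_fold_enrichment - e2$log2_fold_enrichment)), 0.3)
})
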