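make_long_counts <- function(ip, control) {
  # ip/control: matrices protein x replicate
  n <- nrow(ip)
  prot <- sprintf("p%02d", seq_len(n))
  dplyr::bind_rows(
    tidyr::expand_grid(protein = prot, replicate = seq_len(ncol(ip))) |>
      dplyr::mutate(condition = "ip",
                    count = as.vector(t(ip))),
    tidyr::expand_grid(protein = prot, replicate = seq_len(ncol(control))) |>
      dplyr::mutate(condition = "control",
                    count = as.vector(t(control))))
}

test_that("pooling sums replicates and carries condition totals", {
  counts <- make_long_counts(matrix(c(2, 3, 5), 1), matrix(c(1, 1, 0), 1))
  pooled <- pool_counts(counts)
  expect_equal(pooled$ip_count, 10)
  expect_equal(pooled$control_count, 2)
  expect_equal(attr(pooled, "ip_total"), 10)

  single <- make_long_counts(matrix(4), matrix(7))
  p1 <- pool_counts(single)
  expect_equal(c(p1$ip_count, p1$control_count), c(4, 7))

  # all-zero protein is retained and flagged untestable downstream
  counts2 <- make_long_counts(matrix(c(5, 0), 2), matrix(c(3, 0), 2))
  v <- volcano_table(counts2)
  expect_true(v$untestable[v$protein == "p02"])
  expect_false(v$significant[v$protein == "p02"])
})

test_that("Fisher p matches hypergeometric enumeration on random tables", {
  expect_equal(fisher_protein(5, 5, 100, 100), 1.0)
  expect_equal(fisher_protein(0, 0, 50, 50), 1.0)
  set.seed(8)
  for (i in 1:60) {
    ip_total <- sample(20:2000, 1)
    control_total <- sample(20:2000, 1)
    a <- sample(0:min(60, ip_total), 1)
    b <- sample(0:min(60, control_total), 1)
    expect_equal(fisher_protein(a, b, ip_total, control_total),
                 fisher_oracle(a, b, ip_total, control_total),
                 tolerance = 1e-12)
  }
  expect_error(fisher_protein(10, 2, 5, 100), "exceeds")
})

test_that("fold enrichment uses raw counts with the zero-control rule", {
  expect_equal(fold_enrichment(10, 5), 2.0)
  expect_equal(fold_enrichment(8, 0), 8.0)
  expect_equal(fold_enrichment(3, 6), 0.5)
  expect_error(fold_enrichment(0, 0), "undefined")
  # scale equivariance in the IP count at fixed control
  expect_equal(fold_enrichment(30, 5), 3 * fold_enrichment(10, 5))
})

test_that("significance needs both p < 0.05 and fold >= 2; display p floored", {
  # planted strong protein among a quiet background
  set.seed(5)
  bg_ip <- matrix(rpois(60 * 3, 20), 60)
  bg_ct <- matrix(rpois(60 * 3, 20), 60)
  bg_ip[1, ] <- rpois(3, 160)   # ~8-fold planted
  v <- volcano_table(make_long_counts(bg_ip, bg_ct))
  expect_true(v$significant[v$protein == "p01"])
  expect_equal(v$protein[1], "p01")  # sorted by fold enrichment

  # fold below the cutoff is never significant, however small the p
  below <- v |> dplyr::mutate(sig2 = p_value < 0.05 & fold_enrichment >= 2)
  expect_equal(v$significant, below$sig2)

  # display flooring at 0.0010, raw p untouched
  expect_lt(v$p_value[v$protein == "p01"], 0.0010)
  expect_equal(v$p_display[v$protein == "p01"], 0.0010)
  expect_equal(pmax(v$p_value, 0.0010), v$p_display)
})

test_that("a fold-1.9 protein with tiny p is called not significant", {
  # construct pooled counts directly: fold 1.9 with a deep table
  counts <- make_long_counts(
    rbind(matrix(c(1900, 0, 0), 1), matrix(rep(3000, 3), 1)),
    rbind(matrix(c(1000, 0, 0), 1), matrix(rep(3000, 3), 1)))
  v <- volcano_table(counts)
  p1 <- v[v$protein == "p01", ]
  expect_equal(p1$fold_enrichment, 1.9)
  expect_lt(p1$p_value, 0.05)
  expect_false(p1$significant)
})

test_that("null tables stay quiet and planted enrichments are recovered", {
  # null calibration: shared abundance distribution in both conditions
  hits <- vapply(1:20, function(s) {
    counts <- simulate_spectral_counts(80, mean_lambda = 12, seed = s)
    v <- volcano_table(counts)
    mean(v$p_value[!v$untestable] < 0.05)
  }, numeric(1))
  expect_lte(mean(hits), 0.08)

  # power: a >= 4-fold protein with decent depth is nearly always caught
  called <- vapply(1:40, function(s) {
    counts <- simulate_spectral_counts(
      60, mean_lambda = 10,
      planted = tibble::tibble(protein = 1, fold = 4), seed = 1000 + s)
    v <- volcano_table(counts)
    v$significant[v$protein == "protein_001"]
  }, logical(1))
  expect_gte(mean(called), 0.9)
})

test_that("spectral-count tables round-trip through long and wide TSV", {
  counts <- simulate_spectral_counts(10, seed = 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(counts, tf)
  back <- read_spectral_counts(tf)
  expect_equal(dplyr::arrange(back, protein, condition, replicate) |>
                 dplyr::mutate(replicate = as.integer(replicate)),
               dplyr::arrange(counts, protein, condition, replicate))

  wide <- counts |>
    tidyr::pivot_wider(names_from = c(condition, replicate),
                       values_from = count, names_sep = "_")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, tf2)
  back2 <- read_spectral_counts(tf2)
  expect_equal(sum(back2$count), sum(counts$count))
  expect_setequal(unique(back2$condition), c("ip", "control"))
  expect_error(read_spectral_counts(write_tmp("protein\nonly_one_column", ".tsv")),
               "sample columns")
})
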