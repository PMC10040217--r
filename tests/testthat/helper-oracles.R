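# Independent oracles and tiny fixture builders used across the suite.
# Every oracle deliberately takes the dumbest correct route (per-base
# boolean arrays, full hypergeometric enumeration, exhaustive placement)
# so it shares no code path with the implementation it checks.

# Per-base brute-force overlap on a toy genome: paint each set onto boolean
# vectors, one element per base, and count the AND.
brute_overlap_bp <- function(a, b, genome) {
  total <- 0
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    v_a <- logical(genome$size[i])
    v_b <- logical(genome$size[i])
    aa <- a[a$chrom == ch, ]
    bb <- b[b$chrom == ch, ]
    for (j in seq_len(nrow(aa))) v_a[(aa$start[j] + 1):aa$end[j]] <- TRUE
    for (j in seq_len(nrow(bb))) v_b[(bb$start[j] + 1):bb$end[j]] <- TRUE
    total <- total + sum(v_a & v_b)
  }
  total
}

# Random interval set on a toy genome (may contain overlapping/nested peaks).
random_intervals <- function(genome, n, max_len = 50) {
  rows <- lapply(seq_len(n), function(i) {
    ci <- sample.int(nrow(genome), 1)
    len <- sample.int(min(max_len, genome$size[ci]), 1)
    s <- sample.int(genome$size[ci] - len + 1, 1) - 1
    tibble::tibble(chrom = genome$chrom[ci], start = s, end = s + len)
  })
  dplyr::arrange(dplyr::bind_rows(rows), chrom, start, end)
}

# Two-sided Fisher p by direct hypergeometric enumeration: sum the
# probabilities of all tables (same margins) no more likely than the
# observed one. The (1 + 1e-7) factor is the conventional tolerance for
# ties among floating-point table probabilities.
fisher_oracle <- function(a, b, ip_total, control_total) {
  k <- a + b
  lo <- max(0, k - control_total)
  hi <- min(k, ip_total)
  x <- lo:hi
  d <- stats::dhyper(x, ip_total, control_total, k)
  d_obs <- stats::dhyper(a, ip_total, control_total, k)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

# Exact expected overlap of one interval of length L, placed uniformly over
# all valid starts of a toy genome (no mask), against a fixed set: average
# the brute-force overlap over every possible placement.
expected_overlap_exhaustive <- function(L, anchor, genome) {
  tot <- 0
  n_pos <- 0
  for (i in seq_len(nrow(genome))) {
    if (genome$size[i] < L) next
    for (s in 0:(genome$size[i] - L)) {
      iv <- tibble::tibble(chrom = genome$chrom[i], start = s, end = s + L)
      tot <- tot + brute_overlap_bp(iv, anchor, genome)
      n_pos <- n_pos + 1
    }
  }
  tot / n_pos
}

toy_genome <- function(sizes = c(chrA = 600, chrB = 400)) {
  colocshuffle::genome(names(sizes), unname(sizes))
}

iv <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

write_tmp <- function(lines, ext = ".bed") {
  tf <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}
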