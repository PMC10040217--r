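# Length-matched genome-wide shuffling.
#
# Placement is a direct inverse-CDF draw: for an interval of length L, every
# start position that keeps the interval entirely inside one allowed run
# (the complement of the exclusion mask within its chromosome) is equally
# likely, genome-wide. A chromosome is therefore chosen with probability
# proportional to its number of valid starts for that length — no rejection
# sampling, no bias against lengths that barely fit.

# Precompute the allowed-run geometry once per (genome, mask).
make_placer <- function(genome, mask = NULL) {
  runs <- allowed_runs(genome, mask)
  offs <- chrom_offsets(genome)
  list(run_start_lin = unname(offs[runs$chrom] + runs$start),
       run_len = runs$end - runs$start,
       genome = genome)
}

# Draw one uniform start (linear coordinates) for each length in `lens`.
place_lengths <- function(placer, lens) {
  out <- numeric(length(lens))
  for (L in unique(lens)) {
    valid <- placer$run_len - L + 1
    valid[valid < 0] <- 0
    tot <- sum(valid)
    if (tot == 0) {
      abort(sprintf(
        "no allowed placement exists for an interval of length %s bp; use a larger genome or a smaller exclusion mask",
        format(L, scientific = FALSE)))
    }
    cum <- cumsum(valid)
    which_l <- which(lens == L)
    k <- sample.int(tot, length(which_l), replace = TRUE)
    ri <- findInterval(k, c(0, cum), left.open = TRUE)
    out[which_l] <- placer$run_start_lin[ri] + (k - c(0, cum)[ri] - 1)
  }
  out
}

#' Shuffle an interval set genome-wide, preserving lengths
#'
#' Produces a random relocation of `x`: the multiset of interval lengths is
#' preserved exactly, no shuffled interval intersects the exclusion mask, and
#' each interval lands uniformly over all valid start positions genome-wide.
#' Shuffled intervals may overlap one another, mirroring common shuffle
#' semantics (`bedtools shuffle` without `-noOverlapping`).
#'
#' @param x Interval tibble to relocate.
#' @param genome Genome tibble.
#' @param mask Merged exclusion mask tibble, or `NULL`.
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched and the result is reproducible.
#' @return A sorted interval tibble with the same number of intervals and the
#'   same sorted lengths as `x`.
#' @export
shuffle_intervals <- function(x, genome, mask = NULL, seed = NULL) {
  check_genome(genome)
  check_intervals(x, genome, "shuffle input")
  if (nrow(x) == 0L) return(empty_mask())
  placer <- make_placer(genome, mask)
  lens <- x$end - x$start
  s <- with_seed_if(seed, place_lengths(placer, lens))
  delinearize(s, lens, genome) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}
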