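# Synthetic-data generators with planted structure. These emulate the
# statistical shape of the real inputs — peak sets with a controlled
# co-localization fraction, spectral-count tables with planted
# fold-enrichments, coverage tracks whose peak amplitude differs between
# conditions — so every analysis stage can be validated end-to-end without
# any external download.

#' Simulate a small multi-chromosome genome
#'
#' @param n_chrom Number of chromosomes (ignored when `lengths` is given).
#' @param chrom_length Length of each chromosome in bp.
#' @param lengths Optional explicit vector of chromosome lengths.
#' @return A genome tibble (`chrom`, `size`).
#' @export
simulate_genome <- function(n_chrom = 2, chrom_length = 5e6, lengths = NULL) {
  if (is.null(lengths)) lengths <- rep(chrom_length, n_chrom)
  genome(paste0("chr", seq_along(lengths)), lengths)
}

#' Simulate an exclusion mask covering a target genome fraction
#'
#' Random fixed-length regions are drawn uniformly and merged; the number of
#' draws is chosen so the expected merged coverage equals
#' `fraction * genome size` (coupon-collector correction for self-overlap).
#'
#' @param genome Genome tibble.
#' @param fraction Target excluded fraction in \[0, 1).
#' @param region_len Length of each raw masked region (default 2000 bp).
#' @param seed Integer seed.
#' @return A merged interval tibble (empty when `fraction = 0`).
#' @export
simulate_exclusion_mask <- function(genome, fraction = 0.1, region_len = 2000,
                                    seed = 1) {
  check_genome(genome)
  if (fraction < 0 || fraction >= 1) abort("`fraction` must be in [0, 1)")
  if (fraction == 0) return(empty_mask())
  total <- sum(genome$size)
  n <- ceiling(-log(1 - fraction) * total / region_len)
  placer <- make_placer(genome, NULL)
  s <- with_seed_if(seed, place_lengths(placer, rep(region_len, n)))
  merge_intervals(delinearize(s, region_len, genome))
}

#' Simulate an anchor peak set
#'
#' Peaks of random lengths placed uniformly in the allowed space (they may
#' overlap one another, as called peak sets occasionally do).
#'
#' @param genome Genome tibble.
#' @param n_peaks Number of peaks (default 500).
#' @param len_range Length range `(min, max)` in bp, sampled uniformly.
#' @param mask Optional exclusion mask the peaks must avoid.
#' @param seed Integer seed.
#' @return A sorted interval tibble.
#' @export
simulate_anchor_peaks <- function(genome, n_peaks = 500,
                                  len_range = c(200, 1000), mask = NULL,
                                  seed = 1) {
  check_genome(genome)
  stopifnot_scalar_count(n_peaks, "n_peaks")
  placer <- make_placer(genome, mask)
  with_seed_if(seed, {
    lens <- sample(seq(len_range[1L], len_range[2L]), n_peaks, replace = TRUE)
    s <- place_lengths(placer, lens)
    delinearize(s, lens, genome)
  }) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

#' Simulate a comparison peak set with planted co-localization
#'
#' A fraction `overlap_fraction` of the peaks are placed over randomly
#' chosen anchor peaks — centered on the anchor center plus Gaussian jitter,
#' then clipped so at least one bp of overlap with the chosen anchor is
#' retained — and the remainder are placed uniformly in the allowed space.
#' The realized [fraction_peaks_overlapping()] is therefore
#' `overlap_fraction` plus whatever overlap the uniform peaks hit by chance.
#'
#' @param anchor Non-empty anchor interval tibble.
#' @param genome Genome tibble.
#' @param overlap_fraction Planted per-peak overlap fraction in \[0, 1\].
#' @param n_peaks Number of comparison peaks.
#' @param len_range Length range `(min, max)` in bp.
#' @param jitter_sd SD of the Gaussian center offset in bp (default 100).
#' @param mask Optional exclusion mask for the uniform remainder.
#' @param seed Integer seed.
#' @return A sorted interval tibble.
#' @export
simulate_colocalized_peaks <- function(anchor, genome, overlap_fraction,
                                       n_peaks = 500, len_range = c(200, 1000),
                                       jitter_sd = 100, mask = NULL, seed = 1) {
  check_genome(genome)
  check_intervals(anchor, genome, "anchor")
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    abort("`overlap_fraction` must be in [0, 1]")
  }
  n_hit <- round(overlap_fraction * n_peaks)
  if (n_hit > 0 && nrow(anchor) == 0L) {
    abort("cannot plant overlapping peaks against an empty anchor set")
  }
  sizes <- setNames(genome$size, genome$chrom)
  with_seed_if(seed, {
    lens <- sample(seq(len_range[1L], len_range[2L]), n_peaks, replace = TRUE)
    placed <- vector("list", 2L)
    if (n_hit > 0) {
      idx <- sample.int(nrow(anchor), n_hit, replace = TRUE)
      a_s <- anchor$start[idx]
      a_e <- anchor$end[idx]
      ch <- anchor$chrom[idx]
      L <- lens[seq_len(n_hit)]
      ctr <- floor((a_s + a_e) / 2) + round(rnorm(n_hit, 0, jitter_sd))
      st <- round(ctr - L / 2)
      # clip: keep >= 1 bp overlap with the chosen anchor, stay on-chromosome
      st <- pmin(pmax(st, a_s - L + 1, 0), a_e - 1, unname(sizes[ch]) - L)
      st <- pmax(st, 0)
      placed[[1L]] <- tibble(chrom = ch, start = st, end = st + L)
    }
    if (n_peaks - n_hit > 0) {
      placer <- make_placer(genome, mask)
      L <- lens[seq_len(n_peaks - n_hit) + n_hit]
      s <- place_lengths(placer, L)
      placed[[2L]] <- delinearize(s, L, genome)
    }
    dplyr::bind_rows(placed)
  }) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

#' Simulate an IP-MS spectral-count table with planted enrichments
#'
#' Per-protein baseline abundances are gamma-distributed; control counts are
#' Poisson at the baseline and IP counts Poisson at `fold x` baseline, with
#' fold 1 for unplanted proteins. Replicates are independent draws.
#'
#' @param n_proteins Number of proteins.
#' @param mean_lambda Mean of the per-replicate baseline abundance
#'   distribution (gamma with shape 1.5).
#' @param planted Tibble with columns `protein` (indices in
#'   `1:n_proteins`) and `fold` (positive), or `NULL` for an all-null table.
#' @param n_replicates Replicates per condition (default 3).
#' @param seed Integer seed.
#' @return A long count tibble (`protein`, `condition`, `replicate`,
#'   `count`) with conditions `"ip"` and `"control"`.
#' @export
simulate_spectral_counts <- function(n_proteins = 300, mean_lambda = 10,
                                     planted = NULL, n_replicates = 3,
                                     seed = 1) {
  stopifnot_scalar_count(n_proteins, "n_proteins")
  stopifnot_scalar_count(n_replicates, "n_replicates")
  fold <- rep(1, n_proteins)
  if (!is.null(planted)) {
    if (any(planted$fold <= 0)) abort("planted folds must be positive")
    fold[planted$protein] <- planted$fold
  }
  prot <- sprintf("protein_%03d", seq_len(n_proteins))
  with_seed_if(seed, {
    lambda <- stats::rgamma(n_proteins, shape = 1.5, rate = 1.5 / mean_lambda)
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      dplyr::bind_rows(
        tibble(protein = prot, condition = "control", replicate = r,
               count = rpois(n_proteins, lambda)),
        tibble(protein = prot, condition = "ip", replicate = r,
               count = rpois(n_proteins, fold * lambda)))
    })
  })
}

#' Simulate condition-structured coverage tracks
#'
#' One track per condition: a flat background plus, over every peak, a
#' triangular bump (height = the condition's amplitude at the peak center,
#' zero at the peak edges) evaluated at bin midpoints, plus Gaussian noise
#' per bin, floored at zero. Differing amplitudes between conditions emulate
#' a depletion that reduces signal at binding sites without touching the
#' background.
#'
#' @param peaks Interval tibble of signal peaks.
#' @param genome Genome tibble.
#' @param amplitudes Named numeric vector of per-condition peak amplitudes,
#'   e.g. `c(control = 1, depletion = 0.6)`.
#' @param background Flat background level (default 0.1).
#' @param noise_sd Per-bin Gaussian noise SD (default 0.05).
#' @param bin_width Bin width in bp (default 50).
#' @param seed Integer seed.
#' @return A named list of coverage tibbles, one per condition.
#' @export
simulate_coverage <- function(peaks, genome, amplitudes = c(control = 1),
                              background = 0.1, noise_sd = 0.05,
                              bin_width = 50, seed = 1) {
  check_genome(genome)
  check_intervals(peaks, genome, "peaks")
  if (is.null(names(amplitudes)) || any(!nzchar(names(amplitudes)))) {
    abort("`amplitudes` must be a named vector (one name per condition)")
  }
  if (any(amplitudes < 0)) abort("amplitudes must be non-negative")
  if (bin_width > min(genome$size)) abort("`bin_width` exceeds the smallest chromosome")

  bins <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$size[i] - 1, by = bin_width)
    tibble(chrom = genome$chrom[i], start = starts,
           end = pmin(starts + bin_width, genome$size[i]))
  })
  mid <- (bins$start + bins$end) / 2

  # kernel contribution of every peak at bin midpoints, one pass per peak
  bump <- numeric(nrow(bins))
  for (i in seq_len(nrow(peaks))) {
    sel <- which(bins$chrom == peaks$chrom[i] & mid >= peaks$start[i] &
                   mid < peaks$end[i])
    if (!length(sel)) next
    ctr <- (peaks$start[i] + peaks$end[i]) / 2
    half <- (peaks$end[i] - peaks$start[i]) / 2
    bump[sel] <- bump[sel] + pmax(0, 1 - abs(mid[sel] - ctr) / half)
  }

  with_seed_if(seed, {
    purrr::imap(as.list(amplitudes), function(a, nm) {
      v <- background + a * bump + rnorm(nrow(bins), 0, noise_sd)
      dplyr::mutate(bins, value = pmax(0, v))
    })
  })
}
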