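#' Mean-signal matrix around peak centers
#'
#' For each peak, the window `[center - halfwidth, center + halfwidth)` —
#' with center `floor((start + end) / 2)` — is partitioned into bins of
#' `bin_width` bp and the mean track signal over each bin is recorded.
#' Windows extending past chromosome ends are truncated: a bin's mean uses
#' only its covered bases, and bins with no covered bases are `NA` and
#' excluded from the column means. The column means are the metaprofile
#' (mean signal as a function of distance from the peak center).
#'
#' @param track Coverage tibble.
#' @param peaks Non-empty interval tibble.
#' @param halfwidth Window half-width in bp (default 1000).
#' @param bin_width Bin width in bp (default 50); must divide `2 * halfwidth`.
#' @param genome Optional genome tibble; needed for end truncation (derived
#'   from the data when omitted).
#' @return An object of class `profile_matrix`: list with `matrix` (peaks x
#'   bins), `column_means`, `positions` (bin centers relative to the peak
#'   center), `bin_width`, `halfwidth`, `n_peaks`. Use [tidy()] for a long
#'   tibble and [autoplot()] for the metaprofile plot.
#' @export
profile_matrix <- function(track, peaks, halfwidth = 1000, bin_width = 50,
                           genome = NULL) {
  check_track(track, genome)
  check_intervals(peaks, genome, "peaks")
  if (nrow(peaks) == 0L) abort("`peaks` is empty")
  stopifnot_scalar_count(halfwidth, "halfwidth")
  stopifnot_scalar_count(bin_width, "bin_width")
  if ((2 * halfwidth) %% bin_width != 0) {
    abort("`bin_width` must divide 2 * halfwidth")
  }
  n_bins <- as.integer(2 * halfwidth / bin_width)
  g <- if (is.null(genome)) implied_genome(track, peaks) else genome

  ord <- order(track$chrom, track$start)
  lt <- linearize(track[ord, ], g)
  fi <- integral_fun(lt$s, lt$e, track$value[ord])

  offs <- chrom_offsets(g)
  sizes <- setNames(g$size, g$chrom)
  centers <- unname(offs[peaks$chrom]) + floor((peaks$start + peaks$end) / 2)
  chrom_lo <- unname(offs[peaks$chrom])
  chrom_hi <- chrom_lo + unname(sizes[peaks$chrom])

  n <- nrow(peaks)
  edges <- seq(-halfwidth, halfwidth, by = bin_width)
  lo <- outer(centers, edges[-length(edges)], `+`)
  hi <- outer(centers, edges[-1L], `+`)
  lo_c <- pmin(pmax(lo, chrom_lo), chrom_hi)
  hi_c <- pmin(pmax(hi, chrom_lo), chrom_hi)
  covered <- hi_c - lo_c
  vals <- matrix(fi(as.vector(hi_c)) - fi(as.vector(lo_c)), nrow = n)
  m <- ifelse(covered > 0, vals / covered, NA_real_)
  dimnames(m) <- list(NULL, paste0("bin", seq_len(n_bins)))

  structure(list(matrix = m,
                 column_means = colMeans(m, na.rm = TRUE),
                 positions = (edges[-length(edges)] + edges[-1L]) / 2,
                 bin_width = bin_width, halfwidth = halfwidth,
                 n_peaks = n),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("Profile matrix: %d peaks x %d bins (%d bp bins, +/-%d bp window)\n",
              x$n_peaks, length(x$positions), x$bin_width, x$halfwidth))
  cat(sprintf("  center-bin mean %.4g; flank mean %.4g\n",
              x$column_means[length(x$column_means) %/% 2 + 1L],
              mean(x$column_means[c(1L, length(x$column_means))])))
  invisible(x)
}

#' @describeIn profile_matrix Long tibble: one row per (peak, bin).
#' @param x A `profile_matrix`.
#' @param ... Unused.
#' @method tidy profile_matrix
#' @export
tidy.profile_matrix <- function(x, ...) {
  tibble(peak = rep(seq_len(x$n_peaks), times = length(x$positions)),
         bin = rep(seq_along(x$positions), each = x$n_peaks),
         position = rep(x$positions, each = x$n_peaks),
         signal = as.vector(x$matrix))
}

#' @describeIn profile_matrix One-row summary (peak/bin counts, center and
#'   flank means).
#' @method glance profile_matrix
#' @export
glance.profile_matrix <- function(x, ...) {
  nb <- length(x$positions)
  tibble(n_peaks = x$n_peaks, n_bins = nb,
         bin_width = x$bin_width, halfwidth = x$halfwidth,
         center_mean = unname(x$column_means[nb %/% 2 + 1L]),
         flank_mean = mean(x$column_means[c(1L, nb)]))
}

#' Center-bin mean of a profile matrix
#'
#' Convenience accessor for the metaprofile value at the peak center, the
#' quantity compared between conditions (e.g. control vs depletion).
#'
#' @param x A `profile_matrix`.
#' @return A single number.
#' @export
center_signal <- function(x) {
  if (!inherits(x, "profile_matrix")) abort("`x` must be a profile_matrix")
  unname(x$column_means[length(x$column_means) %/% 2 + 1L])
}
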