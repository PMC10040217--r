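#' Build an exclusion mask from BED files
#'
#' Shuffles must avoid assembly gaps and blacklisted regions. This reader
#' takes one or more BED files, unions them, and returns the merged
#' (disjoint) mask.
#'
#' @param paths Character vector of BED file paths.
#' @param genome Genome tibble the mask is bound to.
#' @return A merged interval tibble (`chrom`, `start`, `end`).
#' @export
read_exclusion <- function(paths, genome) {
  check_genome(genome)
  beds <- lapply(paths, read_bed, genome = genome)
  merge_intervals(dplyr::bind_rows(beds))
}

#' An empty exclusion mask
#' @return A zero-row interval tibble.
#' @export
empty_mask <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric())
}

#' Allowed space per chromosome under a mask
#'
#' @param genome Genome tibble.
#' @param mask Merged exclusion mask (or `NULL` for no mask).
#' @return A tibble with columns `chrom`, `size`, `excluded_bp`, `allowed_bp`.
#' @export
allowed_space <- function(genome, mask = NULL) {
  check_genome(genome)
  if (is.null(mask) || nrow(mask) == 0L) {
    return(tibble(chrom = genome$chrom, size = genome$size,
                  excluded_bp = 0, allowed_bp = genome$size))
  }
  m <- merge_intervals(mask)
  check_intervals(m, genome, "exclusion mask")
  ex <- m |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(excluded_bp = sum(.data$end - .data$start), .groups = "drop")
  genome |>
    dplyr::left_join(ex, by = "chrom") |>
    dplyr::mutate(excluded_bp = dplyr::coalesce(.data$excluded_bp, 0),
                  allowed_bp = .data$size - .data$excluded_bp)
}

# Complement of the mask within the genome: maximal runs of allowed bases.
allowed_runs <- function(genome, mask = NULL) {
  check_genome(genome)
  if (is.null(mask) || nrow(mask) == 0L) {
    return(tibble(chrom = genome$chrom, start = 0, end = genome$size))
  }
  m <- merge_intervals(mask)
  check_intervals(m, genome, "exclusion mask")
  runs <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    sz <- genome$size[i]
    mm <- m[m$chrom == ch, ]
    edges_s <- c(0, mm$end)
    edges_e <- c(mm$start, sz)
    keep <- edges_e > edges_s
    tibble(chrom = ch, start = edges_s[keep], end = edges_e[keep])
  })
  dplyr::bind_rows(runs)
}
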