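#' Read a BED file into an interval tibble
#'
#' Intervals are plain tibbles with columns `chrom`, `start`, `end` in BED
#' convention: 0-based starts, half-open ends. The first three columns of the
#' file are used; any further columns (name, score, strand, ...) are retained
#' verbatim but never affect overlap arithmetic, which is unstranded. Lines
#' beginning with `track`, `browser` or `#` are skipped.
#'
#' @param path Path to a BED3+ file (tab or whitespace delimited).
#' @param genome Optional genome tibble (see [read_chrom_sizes()]); when
#'   supplied, chromosome names and bounds are validated.
#' @return A tibble sorted by (chrom, start, end).
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  df <- read.table(text = lines, header = FALSE, sep = "",
                   stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(df) < 3L) abort(sprintf("BED file %s has fewer than 3 columns", path))
  extra <- if (ncol(df) > 3L) df[-(1:3)] else NULL
  out <- tibble(chrom = as.character(df[[1L]]),
                start = as.numeric(df[[2L]]),
                end = as.numeric(df[[3L]]))
  if (!is.null(extra)) {
    names(extra) <- c("name", "score", "strand",
                      paste0("V", seq_len(max(0, ncol(extra) - 3L)) + 6L))[seq_len(ncol(extra))]
    out <- dplyr::bind_cols(out, as_tibble(extra))
  }
  check_intervals(out, genome, what = path)
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write an interval tibble as BED
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional extra columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  write.table(as.data.frame(x)[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_intervals <- function(x, genome = NULL, what = "interval set") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("%s: intervals must have columns `chrom`, `start`, `end`", what))
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    abort(sprintf("%s: non-numeric interval coordinates", what))
  }
  if (any(x$start < 0)) abort(sprintf("%s: negative start coordinate", what))
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    abort(sprintf("%s: start >= end at %s:%s-%s (BED intervals are half-open and must be non-empty)",
                  what, x$chrom[bad[1L]], x$start[bad[1L]], x$end[bad[1L]]))
  }
  if (!is.null(genome)) {
    check_genome(genome)
    miss <- setdiff(unique(x$chrom), genome$chrom)
    if (length(miss)) {
      abort(sprintf("%s: chromosome %s not in genome", what, miss[1L]))
    }
    sz <- setNames(genome$size, genome$chrom)
    over <- which(x$end > sz[x$chrom])
    if (length(over)) {
      abort(sprintf("%s: interval %s:%s-%s extends past chromosome end (%s bp)",
                    what, x$chrom[over[1L]], x$start[over[1L]], x$end[over[1L]],
                    sz[x$chrom[over[1L]]]))
    }
  }
  invisible(x)
}

# Derive a minimal genome from interval sets when the caller supplies none.
implied_genome <- function(...) {
  sets <- purrr::compact(list(...))
  all <- dplyr::bind_rows(lapply(sets, function(x) x[c("chrom", "start", "end")]))
  if (nrow(all) == 0L) return(genome("empty", 1))
  g <- dplyr::summarise(dplyr::group_by(all, .data$chrom),
                        size = max(.data$end), .groups = "drop")
  genome(g$chrom, g$size)
}

#' Merge an interval set
#'
#' Collapses a set of intervals to the minimal set of disjoint intervals
#' covering the same bases. Touching intervals (`[0,10)` and `[10,20)`) are
#' merged. Idempotent and coverage-preserving.
#'
#' @param x Interval tibble.
#' @return A tibble with columns `chrom`, `start`, `end`, sorted and disjoint.
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chrA", start = c(0, 5), end = c(10, 15)))
#' @export
merge_intervals <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0L) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  x |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      .grp = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -Inf))
    ) |>
    dplyr::group_by(.data$chrom, .data$.grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::select("chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

#' Total covered base pairs of an interval set
#'
#' @param x Interval tibble.
#' @return Covered bp after merging (overlapping bases counted once).
#' @export
covered_bp <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

#' Base-pair overlap between two interval sets
#'
#' Counts the bases covered by both sets. With `merge = TRUE` (default) each
#' set is collapsed first, so duplicated or nested peaks within one set are
#' not double-counted and the statistic is symmetric and bounded by each
#' set's covered bp. With `merge = FALSE` the raw sum of pairwise
#' intersection lengths is returned instead.
#'
#' @param a,b Interval tibbles on the same genome.
#' @param genome Optional genome tibble for validation.
#' @param merge Collapse each set before counting? Default `TRUE`.
#' @return Overlap in bp (a single number).
#' @export
total_overlap_bp <- function(a, b, genome = NULL, merge = TRUE) {
  check_intervals(a, genome, "set `a`")
  check_intervals(b, genome, "set `b`")
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  g <- if (is.null(genome)) implied_genome(a, b) else genome
  if (!merge) {
    tot <- 0
    for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
      aa <- a[a$chrom == ch, ]
      bb <- b[b$chrom == ch, ]
      ov <- pmin(rep(aa$end, times = nrow(bb)), rep(bb$end, each = nrow(aa))) -
        pmax(rep(aa$start, times = nrow(bb)), rep(bb$start, each = nrow(aa)))
      tot <- tot + sum(pmax(0, ov))
    }
    return(tot)
  }
  la <- linearize(merge_intervals(a), g)
  lb <- linearize(merge_intervals(b), g)
  cov <- coverage_fun(la$s, la$e)
  sum(cov(lb$e) - cov(lb$s))
}

#' Fraction of peaks in one set that overlap another
#'
#' The region-level co-localization statistic: the proportion of intervals of
#' `a` sharing at least one base with any interval of `b` (e.g. "98% of
#' anchor peaks overlap comparison binding sites").
#'
#' @param a Interval tibble whose peaks are counted (must be non-empty).
#' @param b Interval tibble overlapped against.
#' @param genome Optional genome tibble for validation.
#' @return A fraction in \[0, 1\].
#' @export
fraction_peaks_overlapping <- function(a, b, genome = NULL) {
  check_intervals(a, genome, "set `a`")
  check_intervals(b, genome, "set `b`")
  if (nrow(a) == 0L) abort("set `a` is empty: the peak-overlap fraction is undefined")
  if (nrow(b) == 0L) return(0)
  g <- if (is.null(genome)) implied_genome(a, b) else genome
  lb <- linearize(merge_intervals(b), g)
  la <- linearize(a, g)
  cov <- coverage_fun(lb$s, lb$e)
  mean(cov(la$e) - cov(la$s) > 0)
}
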