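#' Read a bedGraph coverage track
#'
#' A coverage track is a tibble with columns `chrom`, `start`, `end`,
#' `value`: a stepwise non-negative signal, zero wherever no run covers a
#' base. Runs must not overlap (touching runs are fine).
#'
#' @param path Path to a 4-column bedGraph (0-based, half-open).
#' @param genome Optional genome tibble for bounds validation.
#' @return A sorted coverage tibble.
#' @export
read_bedgraph <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(sprintf("bedGraph file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  value = numeric()))
  }
  df <- read.table(text = lines[keep], header = FALSE, sep = "")
  if (ncol(df) < 4L) abort(sprintf("bedGraph %s must have 4 columns", path))
  out <- tibble(chrom = as.character(df[[1L]]), start = as.numeric(df[[2L]]),
                end = as.numeric(df[[3L]]), value = as.numeric(df[[4L]]))
  check_track(out, genome, what = path)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write a coverage track as bedGraph
#' @param x Coverage tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  write.table(as.data.frame(x)[c("chrom", "start", "end", "value")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_track <- function(x, genome = NULL, what = "coverage track") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end", "value") %in% names(x))) {
    abort(sprintf("%s: a coverage track needs columns chrom, start, end, value", what))
  }
  if (nrow(x) == 0L) return(invisible(x))
  check_intervals(x, genome, what)
  if (any(x$value < 0)) abort(sprintf("%s: negative signal value", what))
  ord <- x[order(x$chrom, x$start), ]
  same <- ord$chrom[-1L] == ord$chrom[-nrow(ord)]
  if (any(same & ord$start[-1L] < ord$end[-nrow(ord)])) {
    i <- which(same & ord$start[-1L] < ord$end[-nrow(ord)])[1L]
    abort(sprintf("%s: overlapping runs at %s:%s", what, ord$chrom[i + 1L],
                  ord$start[i + 1L]))
  }
  invisible(x)
}

#' Total integrated signal of a track
#'
#' Sum of value times run width — the coverage analogue of a read count.
#'
#' @param x Coverage tibble.
#' @return A single number.
#' @export
track_total <- function(x) {
  if (nrow(x) == 0L) return(0)
  sum(x$value * (x$end - x$start))
}

#' Integrated signal of a track over query regions
#'
#' @param track Coverage tibble.
#' @param regions Interval tibble.
#' @param genome Optional genome tibble.
#' @return Numeric vector, one integrated value per region.
#' @export
region_signal <- function(track, regions, genome = NULL) {
  g <- if (is.null(genome)) implied_genome(track, regions) else genome
  lt <- linearize(track[order(track$chrom, track$start), ], g)
  tv <- track$value[order(track$chrom, track$start)]
  fi <- integral_fun(lt$s, lt$e, tv)
  lr <- linearize(regions, g)
  fi(lr$e) - fi(lr$s)
}

#' Sample random background regions
#'
#' Draws `n_regions` intervals of exactly `region_len` bp, uniformly over all
#' valid start positions genome-wide (chromosomes shorter than `region_len`
#' are excluded; duplicates are permitted). Defaults follow the background
#' normalization recipe of 25,000 regions of 250 bp.
#'
#' @param genome Genome tibble.
#' @param n_regions Number of regions (default 25000).
#' @param region_len Region length in bp (default 250).
#' @param seed Optional integer seed for reproducibility.
#' @return A sorted interval tibble with `n_regions` rows.
#' @export
sample_background_regions <- function(genome, n_regions = 25000,
                                      region_len = 250, seed = NULL) {
  check_genome(genome)
  stopifnot_scalar_count(n_regions, "n_regions")
  stopifnot_scalar_count(region_len, "region_len")
  ok <- genome$size >= region_len
  if (!any(ok)) {
    abort(sprintf("no chromosome can host a %s bp region",
                  format(region_len, scientific = FALSE)))
  }
  g <- genome[ok, ]
  placer <- make_placer(g, NULL)
  s <- with_seed_if(seed, place_lengths(placer, rep(region_len, n_regions)))
  delinearize(s, region_len, g) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

#' Scale coverage tracks to the lowest background total
#'
#' Computes each track's total integrated signal over the sampled background
#' regions and scales every track down to the track with the smallest total:
#' `factor_i = min_j(total_j) / total_i`. The minimum-total track keeps
#' factor 1; after scaling, all tracks have equal totals over the regions.
#'
#' @param tracks Named list of at least two coverage tibbles on one genome.
#' @param regions Background regions (see [sample_background_regions()]).
#' @param genome Optional genome tibble.
#' @return A list with elements `tracks` (scaled, same names) and `report`
#'   (tibble with columns `track`, `total`, `factor`).
#' @export
background_scale <- function(tracks, regions, genome = NULL) {
  if (!is.list(tracks) || length(tracks) < 2L || is.null(names(tracks))) {
    abort("`tracks` must be a named list of at least two coverage tracks")
  }
  totals <- vapply(tracks, function(t) sum(region_signal(t, regions, genome)),
                   numeric(1))
  zero <- names(tracks)[totals == 0]
  if (length(zero)) {
    abort(sprintf("track %s has zero signal in the background regions", zero[1L]))
  }
  fac <- min(totals) / totals
  scaled <- purrr::map2(tracks, fac, function(t, f) {
    t$value <- t$value * f
    t
  })
  list(tracks = scaled,
       report = tibble(track = names(tracks), total = unname(totals),
                       factor = unname(fac)))
}

#' Counts-per-million scaling
#'
#' Rescales a track so its total integrated signal equals one million.
#'
#' @param x Coverage tibble with positive total signal.
#' @return The rescaled track.
#' @export
cpm_scale <- function(x) {
  tot <- track_total(x)
  if (tot <= 0) abort("cannot CPM-scale a track with zero total signal")
  x$value <- x$value * (1e6 / tot)
  x
}

#' Jointly rescale replicate track groups to a reference maximum
#'
#' Within each replicate group, every track is multiplied by one common
#' factor chosen so the reference track's maximum equals `target_max`.
#' Cross-track ratios within a replicate are unchanged; the factor differs
#' between replicates, absorbing depth and intensity differences between
#' replicate experiments.
#'
#' @param groups Named list of replicate groups; each group is a named list
#'   of coverage tibbles and must contain `reference`.
#' @param reference Name of the reference track present in each group.
#' @param target_max Maximum the reference is scaled to (default 1).
#' @return A list with elements `groups` (scaled, same structure) and
#'   `report` (tibble with `replicate`, `reference_max`, `factor`).
#' @export
joint_rescale <- function(groups, reference, target_max = 1) {
  if (!is.list(groups) || is.null(names(groups))) {
    abort("`groups` must be a named list of replicate groups")
  }
  report <- purrr::imap_dfr(groups, function(g, nm) {
    if (!reference %in% names(g)) {
      abort(sprintf("replicate %s has no reference track `%s`", nm, reference))
    }
    mx <- if (nrow(g[[reference]])) max(g[[reference]]$value) else 0
    if (mx <= 0) abort(sprintf("reference track `%s` in replicate %s has zero maximum",
                               reference, nm))
    tibble(replicate = nm, reference_max = mx, factor = target_max / mx)
  })
  scaled <- purrr::map2(groups, report$factor, function(g, f) {
    lapply(g, function(t) {
      t$value <- t$value * f
      t
    })
  })
  list(groups = scaled, report = report)
}
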