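#' Read a UCSC-style chrom.sizes file
#'
#' A genome is represented throughout the package as a tibble with columns
#' `chrom` (character) and `size` (numeric bp), one row per chromosome in
#' file order. It is the coordinate frame every interval set and coverage
#' track is validated against.
#'
#' @param path Path to a two-column whitespace-delimited file
#'   (chromosome name, length in bp).
#' @return A tibble with columns `chrom` and `size`.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr2L\t23513712", "chr2R\t25286936"), tf)
#' read_chrom_sizes(tf)
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) abort(sprintf("chrom.sizes file not found: %s", path))
  raw <- tryCatch(
    read.table(path, header = FALSE, colClasses = c("character", "numeric"),
               col.names = c("chrom", "size")),
    error = function(e) abort(sprintf("cannot parse chrom.sizes file %s: %s",
                                      path, conditionMessage(e)))
  )
  genome(raw$chrom, raw$size)
}

#' Construct a genome tibble
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param size Numeric vector of chromosome lengths in bp (positive integers).
#' @return A tibble with columns `chrom` and `size`.
#' @export
genome <- function(chrom, size) {
  if (length(chrom) == 0L) abort("a genome needs at least one chromosome")
  if (anyDuplicated(chrom)) {
    abort(sprintf("duplicate chromosome name: %s",
                  chrom[duplicated(chrom)][1L]))
  }
  if (any(!is.finite(size)) || any(size <= 0) || any(size != floor(size))) {
    abort("chromosome sizes must be positive integers")
  }
  tibble(chrom = as.character(chrom), size = as.numeric(size))
}

check_genome <- function(g) {
  if (!is.data.frame(g) || !all(c("chrom", "size") %in% names(g))) {
    abort("`genome` must be a data frame with columns `chrom` and `size` (see read_chrom_sizes())")
  }
  invisible(g)
}

# Cumulative linear offsets; bounds has length nrow(g) + 1 so that chromosome
# i occupies linear coordinates [bounds[i], bounds[i + 1]).
chrom_bounds <- function(g) {
  b <- cumsum(c(0, g$size))
  names(b) <- c(g$chrom, "")
  b
}

chrom_offsets <- function(g) {
  setNames(cumsum(c(0, g$size))[seq_len(nrow(g))], g$chrom)
}

# Map interval tibble columns into genome-wide linear coordinates.
linearize <- function(x, g) {
  offs <- chrom_offsets(g)
  if (!all(x$chrom %in% names(offs))) {
    bad <- setdiff(unique(x$chrom), names(offs))
    abort(sprintf("chromosome not in genome: %s", bad[1L]))
  }
  o <- offs[x$chrom]
  list(s = unname(o + x$start), e = unname(o + x$end))
}

# Inverse of linearize for start positions; lengths carried separately.
delinearize <- function(s, len, g) {
  bounds <- chrom_bounds(g)
  ci <- findInterval(s, bounds)
  tibble(chrom = g$chrom[ci],
         start = s - unname(bounds[ci]),
         end = s - unname(bounds[ci]) + len)
}
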