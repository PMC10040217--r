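#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests `m` and caps at 1. Unlike
#' [stats::p.adjust()], `m` may exceed the length of the vector (e.g. when a
#' screen is split across batches).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests; defaults to `length(p)` and must be at least that.
#' @return Adjusted p-values, order preserved.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  if (m < length(p)) abort("`m` must be at least length(p)")
  pmin(1, p * m)
}

# Inner permutation loop on prebuilt linear structures. Returns the vector of
# null overlaps. `cov` is coverage_fun() of the merged anchor; `placer` the
# allowed-run geometry; `lens` the comparison interval lengths.
null_overlaps_loop <- function(cov, placer, lens, n_perm, merge = TRUE) {
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    s <- place_lengths(placer, lens)
    e <- s + lens
    if (merge) {
      m <- merge_linear(s, e)
      null[i] <- sum(cov(m$e) - cov(m$s))
    } else {
      null[i] <- sum(cov(e) - cov(s))
    }
  }
  null
}

enrichment_row <- function(observed, null, n_perm) {
  null_mean <- mean(null)
  p_enrich <- (sum(null >= observed) + 1) / (n_perm + 1)
  p_deplete <- (sum(null <= observed) + 1) / (n_perm + 1)
  pseud <- if (observed == 0 || null_mean == 0) 1 else 0
  list(observed_bp = observed,
       null_mean_bp = null_mean,
       null_sd_bp = sd(null),
       p_enrich = p_enrich,
       p_deplete = p_deplete,
       log2_fold_enrichment = log2((observed + pseud) / (null_mean + pseud)),
       direction = if (observed > null_mean) "enriched"
                   else if (observed < null_mean) "depleted" else "neutral")
}

#' Permutation test of base-pair overlap between two peak sets
#'
#' Quantifies whether the observed base-pair overlap between a fixed anchor
#' set and a comparison set is more or less than expected by chance. The
#' anchor stays put; the comparison set is shuffled genome-wide `n_perm`
#' times with its length distribution preserved and the exclusion mask
#' avoided, and the overlap is recomputed for each shuffle. Empirical
#' p-values use the add-one estimator `(k + 1) / (n_perm + 1)`, so the
#' smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param anchor Interval tibble held fixed (e.g. ORC2 peaks).
#' @param comparison Interval tibble to be shuffled.
#' @param genome Genome tibble.
#' @param mask Merged exclusion mask tibble (gaps + blacklist), or `NULL`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param merge Collapse each set before measuring overlap? Default `TRUE`.
#' @param anchor_name,comparison_name Labels carried into the result.
#' @return An object of class `overlap_enrichment`: observed and null overlap
#'   summaries, the full null distribution, empirical p-values for enrichment
#'   and depletion, and the log2 fold enrichment of observed over expected
#'   overlap. Use [tidy()] for a one-row tibble.
#' @export
permutation_enrichment <- function(anchor, comparison, genome, mask = NULL,
                                   n_perm = 1000, seed = 1, merge = TRUE,
                                   anchor_name = "anchor",
                                   comparison_name = "comparison") {
  check_genome(genome)
  check_intervals(anchor, genome, "anchor")
  check_intervals(comparison, genome, "comparison")
  stopifnot_scalar_count(n_perm, "n_perm")
  if (nrow(anchor) == 0L) abort("anchor set is empty")
  if (nrow(comparison) == 0L) abort("comparison set is empty")

  anc <- linearize(merge_intervals(anchor), genome)
  cov <- coverage_fun(anc$s, anc$e)
  cmp <- if (merge) merge_intervals(comparison) else comparison
  lens <- cmp$end - cmp$start
  lc <- linearize(cmp, genome)
  observed <- if (merge) {
    sum(cov(lc$e) - cov(lc$s))
  } else {
    total_overlap_bp(anchor, comparison, genome, merge = FALSE)
  }

  placer <- make_placer(genome, mask)
  null <- with_seed_if(seed, null_overlaps_loop(cov, placer, lens, n_perm, merge))

  row <- enrichment_row(observed, null, n_perm)
  structure(c(list(anchor_name = anchor_name,
                   comparison_name = comparison_name),
              row,
              list(p_adjusted = min(1, min(row$p_enrich, row$p_deplete)),
                   null_overlaps = null, n_perm = n_perm, seed = seed)),
            class = "overlap_enrichment")
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat(sprintf("Overlap permutation test: %s vs %s\n", x$anchor_name, x$comparison_name))
  cat(sprintf("  observed %s bp; null %.1f +/- %.1f bp over %d permutations\n",
              format(x$observed_bp, big.mark = ","), x$null_mean_bp,
              x$null_sd_bp, x$n_perm))
  cat(sprintf("  log2 fold enrichment %.3f (%s); p_enrich %.4g, p_deplete %.4g\n",
              x$log2_fold_enrichment, x$direction, x$p_enrich, x$p_deplete))
  invisible(x)
}

#' @describeIn permutation_enrichment One-row tibble summary.
#' @param x An `overlap_enrichment` object.
#' @param ... Unused.
#' @method tidy overlap_enrichment
#' @export
tidy.overlap_enrichment <- function(x, ...) {
  tibble(anchor = x$anchor_name, comparison = x$comparison_name,
         observed_bp = x$observed_bp, null_mean = x$null_mean_bp,
         null_sd = x$null_sd_bp, log2_fc = x$log2_fold_enrichment,
         p_enrich = x$p_enrich, p_deplete = x$p_deplete,
         p_adj = x$p_adjusted, direction = x$direction)
}

#' Screen many comparison sets against one anchor
#'
#' Runs [permutation_enrichment()] for each comparison set, Bonferroni-adjusts
#' the directional p-values over the screen, and returns one row per
#' comparison sorted by log2 fold enrichment (descending). Each comparison
#' gets a child seed derived by hashing its name together with the master
#' seed, so adding or removing a comparison leaves the others' null
#' distributions untouched.
#'
#' @inheritParams permutation_enrichment
#' @param comparisons Named list of interval tibbles (names must be unique).
#' @return A tibble of class `enrichment_screen` with columns `comparison`,
#'   `observed_bp`, `null_mean`, `null_sd`, `log2_fc`, `p_enrich`,
#'   `p_deplete`, `p_adj`, `direction`. The full null distributions are kept
#'   in the `"nulls"` attribute.
#' @export
enrichment_screen <- function(anchor, comparisons, genome, mask = NULL,
                              n_perm = 1000, seed = 1, merge = TRUE,
                              anchor_name = "anchor") {
  if (!is.list(comparisons) || length(comparisons) == 0L) {
    abort("`comparisons` must be a non-empty named list of interval tibbles")
  }
  nms <- names(comparisons)
  if (is.null(nms) || any(!nzchar(nms))) abort("every comparison set must be named")
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate comparison name: %s", nms[duplicated(nms)][1L]))
  }
  res <- purrr::map2(comparisons, nms, function(cmp, nm) {
    permutation_enrichment(anchor, cmp, genome, mask = mask, n_perm = n_perm,
                           seed = child_seed(seed, nm), merge = merge,
                           anchor_name = anchor_name, comparison_name = nm)
  })
  tbl <- purrr::map_dfr(res, function(r) {
    tibble(comparison = r$comparison_name, observed_bp = r$observed_bp,
           null_mean = r$null_mean_bp, null_sd = r$null_sd_bp,
           log2_fc = r$log2_fold_enrichment, p_enrich = r$p_enrich,
           p_deplete = r$p_deplete, direction = r$direction)
  })
  tbl$p_adj <- bonferroni_adjust(pmin(tbl$p_enrich, tbl$p_deplete), length(res))
  tbl <- tbl[order(-tbl$log2_fc), c("comparison", "observed_bp", "null_mean",
                                    "null_sd", "log2_fc", "p_enrich",
                                    "p_deplete", "p_adj", "direction")]
  structure(tbl,
            class = c("enrichment_screen", class(tibble())),
            nulls = setNames(lapply(res, `[[`, "null_overlaps"), nms)[tbl$comparison],
            n_perm = n_perm, seed = seed, anchor_name = anchor_name)
}

#' Summarize an enrichment screen
#' @param x An `enrichment_screen`.
#' @param ... Unused.
#' @method glance enrichment_screen
#' @export
glance.enrichment_screen <- function(x, ...) {
  tibble(anchor = attr(x, "anchor_name"),
         n_comparisons = nrow(x),
         n_perm = attr(x, "n_perm"),
         seed = attr(x, "seed"),
         n_enriched = sum(x$direction == "enriched" & x$p_adj <= 0.05),
         n_depleted = sum(x$direction == "depleted" & x$p_adj <= 0.05))
}

#' Enrichment screen as a plain tibble
#' @param x An `enrichment_screen`.
#' @param ... Unused.
#' @method tidy enrichment_screen
#' @export
tidy.enrichment_screen <- function(x, ...) {
  as_tibble(x)
}

#' Differential enrichment between two anchor sets
#'
#' Runs the same screen against two anchors with independent child seeds and
#' reports, per comparison set, the difference in log2 fold enrichment
#' (anchor1 minus anchor2). Used to find factors preferentially co-located
#' with one anchor class (e.g. sites bound by both Elys and ORC2) over
#' another (Elys-only sites).
#'
#' @inheritParams enrichment_screen
#' @param anchor1,anchor2 Interval tibbles; both held fixed in their screens.
#' @param anchor1_name,anchor2_name Labels.
#' @return A tibble with columns `comparison`, `log2_fc_anchor1`,
#'   `log2_fc_anchor2`, `delta_log2_fc`, `p_adj_anchor1`, `p_adj_anchor2`,
#'   sorted by `delta_log2_fc` descending.
#' @export
differential_enrichment <- function(anchor1, anchor2, comparisons, genome,
                                    mask = NULL, n_perm = 1000, seed = 1,
                                    merge = TRUE,
                                    anchor1_name = "anchor1",
                                    anchor2_name = "anchor2") {
  s1 <- enrichment_screen(anchor1, comparisons, genome, mask, n_perm,
                          seed = child_seed(seed, anchor1_name), merge = merge,
                          anchor_name = anchor1_name)
  s2 <- enrichment_screen(anchor2, comparisons, genome, mask, n_perm,
                          seed = child_seed(seed, anchor2_name), merge = merge,
                          anchor_name = anchor2_name)
  out <- dplyr::inner_join(
    dplyr::select(as_tibble(s1), "comparison", log2_fc_anchor1 = "log2_fc",
                  p_adj_anchor1 = "p_adj"),
    dplyr::select(as_tibble(s2), "comparison", log2_fc_anchor2 = "log2_fc",
                  p_adj_anchor2 = "p_adj"),
    by = "comparison")
  out$delta_log2_fc <- out$log2_fc_anchor1 - out$log2_fc_anchor2
  out |>
    dplyr::select("comparison", "log2_fc_anchor1", "log2_fc_anchor2",
                  "delta_log2_fc", "p_adj_anchor1", "p_adj_anchor2") |>
    dplyr::arrange(dplyr::desc(.data$delta_log2_fc))
}
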