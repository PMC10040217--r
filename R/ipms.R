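#' Read a spectral-count table
#'
#' Accepts either a long TSV with columns `protein`, `condition`,
#' `replicate`, `count`, or a wide matrix whose first column is the protein
#' identifier and whose remaining columns are named `<condition>_<replicate>`
#' (e.g. `ip_1`, `control_2`). The wide form is pivoted to long.
#'
#' @param path Path to a TSV file.
#' @param format `"auto"` (default), `"long"`, or `"wide"`.
#' @return A long tibble with columns `protein`, `condition`, `replicate`,
#'   `count`.
#' @export
read_spectral_counts <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  long_cols <- c("protein", "condition", "replicate", "count")
  if (format == "auto") {
    format <- if (all(long_cols %in% names(df))) "long" else "wide"
  }
  if (format == "long") {
    if (!all(long_cols %in% names(df))) {
      abort(sprintf("long spectral-count table %s must have columns %s",
                    path, paste(long_cols, collapse = ", ")))
    }
    out <- df[long_cols]
  } else {
    if (ncol(df) < 2L) abort(sprintf("wide spectral-count table %s needs sample columns", path))
    names(df)[1L] <- "protein"
    out <- tidyr::pivot_longer(df, -"protein", names_to = c("condition", "replicate"),
                               names_pattern = "^(.*)[._]([^._]+)$",
                               values_to = "count")
  }
  check_counts(out, path)
  out
}

check_counts <- function(x, what = "spectral-count table") {
  need <- c("protein", "condition", "replicate", "count")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("%s: expected columns %s", what, paste(need, collapse = ", ")))
  }
  if (nrow(x) == 0L) abort(sprintf("%s: table is empty", what))
  if (any(!is.finite(x$count)) || any(x$count < 0) || any(x$count != floor(x$count))) {
    abort(sprintf("%s: counts must be non-negative integers", what))
  }
  invisible(x)
}

#' Pool spectral counts across replicates
#'
#' Sums counts over replicates within each condition, per protein, and
#' attaches the per-condition grand totals used as the margins of the
#' 2x2 Fisher tables.
#'
#' @param counts Long count tibble (`protein`, `condition`, `replicate`,
#'   `count`).
#' @param ip,control Condition labels for the immunoprecipitation and the
#'   negative control.
#' @return A tibble with columns `protein`, `ip_count`, `control_count`, and
#'   attributes `ip_total`, `control_total`.
#' @export
pool_counts <- function(counts, ip = "ip", control = "control") {
  check_counts(counts)
  missing <- setdiff(c(ip, control), unique(counts$condition))
  if (length(missing)) {
    abort(sprintf("condition %s not present in the count table", missing[1L]))
  }
  wide <- counts |>
    dplyr::filter(.data$condition %in% c(ip, control)) |>
    dplyr::group_by(.data$protein, .data$condition) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "count",
                       values_fill = 0)
  out <- tibble(protein = wide$protein,
                ip_count = wide[[ip]],
                control_count = wide[[control]])
  if (sum(out$ip_count) == 0 || sum(out$control_count) == 0) {
    abort("a condition has zero total spectral counts; Fisher margins are degenerate")
  }
  attr(out, "ip_total") <- sum(out$ip_count)
  attr(out, "control_total") <- sum(out$control_count)
  out
}

#' Per-protein Fisher exact test on pooled spectral counts
#'
#' Two-sided Fisher exact p-value for the 2x2 table
#' `[[ip_count, ip_total - ip_count], [control_count, control_total -
#' control_count]]`, vectorised over proteins.
#'
#' @param ip_count,control_count Pooled counts for one or more proteins.
#' @param ip_total,control_total Condition totals (summed over all proteins
#'   and replicates).
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_protein <- function(ip_count, control_count, ip_total, control_total) {
  if (any(ip_count < 0) || any(control_count < 0)) abort("counts must be non-negative")
  if (any(ip_count > ip_total) || any(control_count > control_total)) {
    abort("a protein's count exceeds its condition total")
  }
  mapply(function(a, b) {
    fisher.test(matrix(c(a, ip_total - a, b, control_total - b), nrow = 2,
                       byrow = TRUE))$p.value
  }, ip_count, control_count)
}

#' Fold enrichment from raw spectral counts
#'
#' Ratio of IP to control counts. When the control count is zero the
#' denominator is set to 1 so the value stays finite (flag such proteins via
#' the `zero_control` column of [volcano_table()]).
#'
#' @param ip_count,control_count Pooled counts (both zero is an error).
#' @return Positive numeric vector.
#' @export
fold_enrichment <- function(ip_count, control_count) {
  if (any(ip_count < 0) || any(control_count < 0)) abort("counts must be non-negative")
  if (any(ip_count + control_count == 0)) {
    abort("fold enrichment undefined for a protein with zero counts in both conditions")
  }
  ip_count / pmax(control_count, 1)
}

#' Volcano table: enrichment and significance per protein
#'
#' Pools replicates, computes fold enrichment from the raw pooled counts,
#' runs a two-sided Fisher exact test per protein against the per-condition
#' totals, floors the display p-value, and flags significance with the joint
#' cutoff p < `alpha` and fold enrichment >= `fold_cutoff`.
#'
#' @inheritParams pool_counts
#' @param alpha Significance level on the raw Fisher p (default 0.05).
#' @param fold_cutoff Minimum fold enrichment (default 2).
#' @param p_floor Display floor: p-values at or below this are reported as
#'   the floor itself in `p_display` (default 0.0010). `p_value` is never
#'   floored.
#' @return A tibble of class `volcano_table`, sorted by fold enrichment
#'   descending, with columns `protein`, `ip_count`, `control_count`,
#'   `fold_enrichment`, `mean_replicate_fold`, `p_value`, `p_display`,
#'   `significant`, `zero_control`, `untestable`.
#' @export
volcano_table <- function(counts, ip = "ip", control = "control",
                          alpha = 0.05, fold_cutoff = 2, p_floor = 0.0010) {
  pooled <- pool_counts(counts, ip = ip, control = control)
  ip_total <- attr(pooled, "ip_total")
  control_total <- attr(pooled, "control_total")

  per_rep <- counts |>
    dplyr::filter(.data$condition %in% c(ip, control)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "count",
                       values_fill = 0) |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      mean_replicate_fold = mean(.data[[ip]] / pmax(.data[[control]], 1)),
      .groups = "drop")

  out <- pooled |>
    dplyr::mutate(
      untestable = .data$ip_count + .data$control_count == 0,
      zero_control = .data$control_count == 0 & !.data$untestable,
      fold_enrichment = ifelse(.data$untestable, NA_real_,
                               .data$ip_count / pmax(.data$control_count, 1)),
      p_value = fisher_protein(.data$ip_count, .data$control_count,
                               ip_total, control_total),
      p_display = pmax(.data$p_value, p_floor),
      significant = !.data$untestable &
        .data$p_value < alpha &
        .data$fold_enrichment >= fold_cutoff
    ) |>
    dplyr::left_join(per_rep, by = "protein") |>
    dplyr::select("protein", "ip_count", "control_count", "fold_enrichment",
                  "mean_replicate_fold", "p_value", "p_display",
                  "significant", "zero_control", "untestable") |>
    dplyr::arrange(dplyr::desc(.data$fold_enrichment))
  structure(out, class = c("volcano_table", class(tibble())),
            ip_total = ip_total, control_total = control_total,
            alpha = alpha, fold_cutoff = fold_cutoff, p_floor = p_floor)
}

#' Summarize a volcano table
#' @param x A `volcano_table`.
#' @param ... Unused.
#' @method glance volcano_table
#' @export
glance.volcano_table <- function(x, ...) {
  tibble(n_proteins = nrow(x),
         ip_total = attr(x, "ip_total"),
         control_total = attr(x, "control_total"),
         n_significant = sum(x$significant, na.rm = TRUE),
         n_untestable = sum(x$untestable))
}
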