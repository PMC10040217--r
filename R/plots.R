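# ggplot2 autoplot methods for the three result types.

#' Plot an enrichment screen
#'
#' Lollipop chart of log2 fold enrichment per comparison, colored by
#' Bonferroni-adjusted significance.
#'
#' @param object An `enrichment_screen` tibble.
#' @param alpha Adjusted-p significance threshold for coloring (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_screen
#' @export
autoplot.enrichment_screen <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$comparison <- factor(df$comparison, levels = rev(df$comparison))
  df$status <- ifelse(df$p_adj <= alpha,
                      paste0("adj. p ≤ ", alpha), "not significant")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = .data$comparison)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$log2_fc,
                                       yend = .data$comparison),
                          color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$status), size = 2.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 fold enrichment (observed / expected overlap)",
                  y = NULL, color = NULL,
                  title = paste("Overlap enrichment vs", attr(object, "anchor_name"))) +
    ggplot2::theme_minimal()
}

#' Volcano plot of IP-MS enrichment
#'
#' Log2 fold enrichment against -log10 of the floored display p-value,
#' highlighting proteins passing the joint significance cutoff.
#'
#' @param object A `volcano_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot volcano_table
#' @export
autoplot.volcano_table <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!df$untestable, ]
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fold_enrichment),
                                   y = -log10(.data$p_display),
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey50"),
                                labels = c(`TRUE` = "enriched",
                                           `FALSE` = "not significant")) +
    ggplot2::geom_vline(xintercept = log2(attr(object, "fold_cutoff")),
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = 2) +
    ggplot2::labs(x = "log2 fold enrichment (IP / control)",
                  y = "-log10 p (Fisher, floored)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Metaprofile plot
#'
#' Column means of a profile matrix as a function of distance from the peak
#' center.
#'
#' @param object A `profile_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot profile_matrix
#' @export
autoplot.profile_matrix <- function(object, ...) {
  df <- tibble(position = object$positions, signal = object$column_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::labs(x = "distance from peak center (bp)", y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Compare metaprofiles across conditions
#'
#' @param profiles Named list of `profile_matrix` objects (one per
#'   condition).
#' @return A ggplot object with one line per condition.
#' @export
plot_metaprofiles <- function(profiles) {
  if (is.null(names(profiles))) abort("`profiles` must be a named list")
  df <- purrr::imap_dfr(profiles, function(p, nm) {
    tibble(condition = nm, position = p$positions, signal = p$column_means)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$signal,
                                   color = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::labs(x = "distance from peak center (bp)", y = "mean signal",
                  color = NULL) +
    ggplot2::theme_minimal()
}
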