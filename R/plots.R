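#' Violin plot of tile methylation levels per sample
#'
#' @param tile_levels Named list of [tile_methylation()] tibbles, or one
#'   tibble with a `sample` column.
#' @return A ggplot.
#' @export
plot_tile_methylation <- function(tile_levels) {
  if (is.data.frame(tile_levels)) {
    df <- tile_levels
  } else {
    df <- purrr::imap(tile_levels, function(x, nm) {
      x$sample <- nm
      x
    }) |> list_rbind()
  }
  df <- df[!is.na(df$level), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$level)) +
    ggplot2::geom_violin(scale = "width", fill = "grey85") +
    ggplot2::stat_summary(fun = median, geom = "point") +
    ggplot2::labs(x = NULL, y = "CpG methylation (tile level)") +
    ggplot2::theme_classic()
}

#' Plot a scaled gene methylation metaprofile
#'
#' @param profile Output of [gene_metaprofile()] (optionally with a
#'   `sample` column to facet colours by).
#' @return A ggplot with TSS/TES guides at the zone boundaries.
#' @export
plot_metaprofile <- function(profile) {
  n_up <- sum(profile$zone == "upstream" & !duplicated(profile$bin))
  n_body <- sum(profile$zone == "body" & !duplicated(profile$bin))
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin, y = .data$level))
  if (!is.null(profile[["sample"]])) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$sample))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::geom_vline(xintercept = c(n_up + 0.5, n_up + n_body + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "-5 kb | TSS  scaled gene body  TES | +5 kb",
                  y = "mean CpG methylation") +
    ggplot2::theme_classic()
}

#' Plot windowed female:male expression ratios along chrX
#'
#' @param windows Output of [fm_ratio_windows()].
#' @return A ggplot (log2 ratio vs window midpoint).
#' @export
plot_fm_windows <- function(windows) {
  df <- windows[!is.na(windows$median_fm_ratio), ]
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = log2(.data$median_fm_ratio))) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "chrX position (Mb)", y = "log2 median F:M ratio") +
    ggplot2::theme_classic()
}

#' Plot per-cell X:autosome bootstrap ratios by group
#'
#' @param ratios Output of [x_to_alla_bootstrap()] joined with a `group`
#'   column (e.g. XC state or sex).
#' @param group Column name to group by.
#' @return A ggplot.
#' @export
plot_x_to_alla <- function(ratios, group = "group") {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data[[group]],
                                       y = .data$x_to_alla)) +
    ggplot2::geom_hline(yintercept = c(1, 2), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4) +
    ggplot2::labs(x = NULL, y = "X : autosome expression ratio") +
    ggplot2::theme_classic()
}

#' Plot TE-family enrichment scores
#'
#' @param object A `te_enrichment` result.
#' @param ... Unused.
#' @return A ggplot of ES per family, enriched families highlighted.
#' @export
autoplot.te_enrichment <- function(object, ...) {
  df <- tidy(object)
  df$family <- factor(df$family, levels = rev(df$family))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$es, y = .data$family,
                                   fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 2, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "enrichment score (escapee vs background overlap)",
                  y = NULL, fill = "ES > 2, p < 0.001") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
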