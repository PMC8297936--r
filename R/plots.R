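#' Plot the phase distribution of rhythmic genes
#'
#' Bar histogram of peak phases per population, shaded by subjective
#' day/night.
#'
#' @param object A `rhythm_scan` object.
#' @param bin_width Bin width in hours.
#' @param day_boundaries `c(day_start, night_start)` hours.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rhythm_scan
#' @export
autoplot.rhythm_scan <- function(object, bin_width = 4,
                                 day_boundaries = c(0, 14), ...) {
  res <- object$result
  period <- object$params$period
  hist_tbl <- purrr::map_dfr(unique(res$population), function(p)
    mutate(phase_histogram(filter(res, .data$population == p),
                           bin_width = bin_width,
                           day_boundaries = day_boundaries,
                           period = period),
           population = p))
  ggplot2::ggplot(hist_tbl,
                  ggplot2::aes(x = .data$bin_start + bin_width / 2,
                               y = .data$n, fill = .data$phase_of_day)) +
    ggplot2::geom_col(width = bin_width * 0.9) +
    ggplot2::facet_wrap(~population) +
    ggplot2::scale_fill_manual(values = c(day = "goldenrod2",
                                          night = "grey30")) +
    ggplot2::labs(x = "peak phase (CT, h)", y = "rhythmic genes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Differential-rhythmicity component plot
#'
#' Scatter of the periodicity z-score against the amplitude z-score, one
#' point per gene, coloured by significance; the diagonal mean of the two
#' is the S_DR score.
#'
#' @param sdr Output of [sdr_pvalues()] (or [sdr_scores()]; then no
#'   significance colouring).
#' @param fdr Significance threshold on `q` when present.
#' @return A ggplot.
#' @export
plot_sdr <- function(sdr, fdr = 0.05) {
  has_q <- "q" %in% names(sdr)
  gg <- ggplot2::ggplot(sdr, ggplot2::aes(x = .data$Z_P, y = .data$Z_R)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70")
  gg <- if (has_q)
    gg + ggplot2::geom_point(ggplot2::aes(colour = .data$q < fdr),
                             alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                              `FALSE` = "grey40"),
                                   name = sprintf("q < %g", fdr))
  else gg + ggplot2::geom_point(alpha = 0.6)
  gg + ggplot2::labs(x = "periodicity z-score (Z_P)",
                     y = "amplitude z-score (Z_R)") +
    ggplot2::theme_minimal()
}

#' Sliding-window motif enrichment profile
#'
#' -log10 Fisher p per circular window center, one line per motif.
#'
#' @param enrichment Output of [phase_window_enrichment()], optionally
#'   with a `motif` column.
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  gg <- ggplot2::ggplot(enrichment,
                        ggplot2::aes(x = .data$window_center,
                                     y = -log10(.data$p)))
  if ("motif" %in% names(enrichment))
    gg <- gg + ggplot2::geom_line(ggplot2::aes(colour = .data$motif)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$motif))
  else gg <- gg + ggplot2::geom_line() + ggplot2::geom_point()
  gg + ggplot2::labs(x = "window center (CT, h)",
                     y = expression(-log[10] ~ "Fisher p")) +
    ggplot2::theme_minimal()
}
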