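#' Signed minimal distance between two clock times
#'
#' The difference `b - a` wrapped into `(-period/2, period/2]`: the minimum
#' distance around a circular clock, signed so that positive values mean
#' `b` peaks later than `a`. The antipodal tie (`|shift| = period/2`) is
#' assigned `+period/2` from both directions, a deterministic convention.
#'
#' @param a,b Clock times in hours (vectorized).
#' @param period Clock period in hours.
#' @return Signed shifts in `(-period/2, period/2]`.
#' @examples
#' circular_phase_distance(23, 1)   # +2, wrapping midnight
#' circular_phase_distance(2, 14)   # +12 by the antipodal convention
#' @export
circular_phase_distance <- function(a, b, period = 24) {
  stopifnot(period > 0)
  d <- (b - a) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Population-level phase-shift test
#'
#' Given per-gene peak phases in a reference and an alternate population,
#' computes signed circular shifts (positive = later peak in the alternate
#' population) for genes rhythmic in both (`p <` `max_p` in each), and
#' tests the shifts against a zero median with a Wilcoxon signed-rank test
#' (zero differences dropped, the standard convention).
#'
#' @param results_ref,results_alt Rhythm tables with `gene`, `p`, `phase`.
#' @param max_p Per-population rhythmicity p cut for inclusion (default
#'   0.05).
#' @param period Hours.
#' @return A list with `records` (tibble: `gene`, `phase_ref`, `phase_alt`,
#'   `signed_shift`, `antipodal`) and `summary` (tibble: `n`, `mean_shift`,
#'   `median_shift`, `p`).
#' @export
phase_shift_test <- function(results_ref, results_alt, max_p = 0.05,
                             period = 24) {
  records <- inner_join(
    select(filter(results_ref, .data$p < max_p), "gene", phase_ref = "phase"),
    select(filter(results_alt, .data$p < max_p), "gene", phase_alt = "phase"),
    by = "gene") %>%
    mutate(signed_shift = circular_phase_distance(.data$phase_ref,
                                                  .data$phase_alt, period),
           antipodal = abs(.data$signed_shift - period / 2) < 1e-9)
  if (nrow(records) < 6)
    abort("need >= 6 genes rhythmic in both populations")
  d <- records$signed_shift
  p <- if (all(d == 0)) 1 else
    suppressWarnings(wilcox.test(d, mu = 0)$p.value)
  list(records = records,
       summary = tibble(n = nrow(records), mean_shift = mean(d),
                        median_shift = median(d), p = p))
}

#' Circular histogram of peak phases of rhythmic genes
#'
#' Bins the phases of rhythmic-labelled genes into bins tiling
#' `[0, period)` and annotates each bin as subjective day or night.
#'
#' @param results Rhythm table with `phase` and `label` columns; only rows
#'   labelled `"rhythmic"` are counted.
#' @param bin_width Bin width in hours; must divide `period`.
#' @param day_boundaries Length-2 vector `c(day_start, night_start)` in
#'   hours; default `c(0, 14)` (14:10 subjective day:night).
#' @param period Hours.
#' @return Tibble: `bin_start`, `bin_end`, `n`, `phase_of_day`.
#' @export
phase_histogram <- function(results, bin_width = 4, day_boundaries = c(0, 14),
                            period = 24) {
  if (abs(period / bin_width - round(period / bin_width)) > 1e-9)
    abort("`bin_width` must divide `period`")
  phases <- results$phase[results$label == "rhythmic"] %% period
  starts <- seq(0, period - bin_width, by = bin_width)
  n <- vapply(starts, function(s)
    sum(phases >= s & phases < s + bin_width), 0L)
  tibble(bin_start = starts, bin_end = starts + bin_width, n = n,
         phase_of_day = ifelse(
           starts >= day_boundaries[1] & starts < day_boundaries[2],
           "day", "night"))
}

#' Median absolute phase shift against a reference-species phase table
#'
#' Compares estimated peak phases with phases of orthologs from a
#' reference species (e.g. zebrafish core-clock genes) on the same clock,
#' reporting the median absolute circular distance over shared genes.
#'
#' @param results Rhythm table with `gene` and `phase`.
#' @param reference Tibble with `gene` and `phase` on the same period.
#' @param period Hours.
#' @return Tibble: `n`, `median_abs_shift`.
#' @export
reference_phase_comparison <- function(results, reference, period = 24) {
  tbl <- inner_join(select(results, "gene", phase = "phase"),
                    select(reference, "gene", ref_phase = "phase"),
                    by = "gene")
  if (nrow(tbl) == 0) abort("no genes shared with the reference table")
  shifts <- circular_phase_distance(tbl$ref_phase, tbl$phase, period)
  tibble(n = nrow(tbl), median_abs_shift = median(abs(shifts)))
}
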