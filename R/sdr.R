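#' Differential rhythmicity scores between two populations
#'
#' For each gene with a rhythmicity p-value < `inclusion_p` in either
#' population, computes the differential rhythmicity score
#' \deqn{S_{DR} = (Z_P + Z_R)/2}
#' where \eqn{Z_P} is the z-score of the periodicity change
#' \eqn{\log p_1 - \log p_2} and \eqn{Z_R} the z-score of the amplitude
#' change \eqn{\log_2(A_2/A_1)}, each standardized against the empirical
#' mean and SD across the included genes of this pair. With these delta
#' definitions a positive score means population 2 is the more rhythmic
#' one (smaller p, larger amplitude); to read "positive = more rhythmic in
#' the reference", pass the reference as `results_pop2`.
#'
#' Zero amplitudes would make the log-ratio infinite; they are floored at
#' half the smallest positive amplitude observed in the pair (recorded in
#' attribute `amplitude_floor`).
#'
#' @param results_pop1,results_pop2 Per-gene rhythm tables (tibbles with
#'   `gene`, `p`, `amplitude`), e.g. [tidy()] of a [rhythm_scan()] filtered
#'   to one population.
#' @param inclusion_p Include genes with `p <` this value in either
#'   population (default 1, i.e. any tested gene).
#' @return Tibble: `gene`, `pop1`, `pop2`, `delta_period`, `delta_amp`,
#'   `Z_P`, `Z_R`, `S_DR`.
#' @export
sdr_scores <- function(results_pop1, results_pop2, inclusion_p = 1) {
  need <- c("gene", "p", "amplitude")
  stopifnot(all(need %in% names(results_pop1)),
            all(need %in% names(results_pop2)))
  p1 <- if ("population" %in% names(results_pop1))
    unique(results_pop1$population) else "pop1"
  p2 <- if ("population" %in% names(results_pop2))
    unique(results_pop2$population) else "pop2"
  stopifnot(length(p1) == 1, length(p2) == 1)

  tbl <- inner_join(
    select(results_pop1, "gene", p1 = "p", a1 = "amplitude"),
    select(results_pop2, "gene", p2 = "p", a2 = "amplitude"),
    by = "gene") %>%
    filter(.data$p1 < inclusion_p | .data$p2 < inclusion_p)
  amps <- c(tbl$a1, tbl$a2)
  floor_amp <- if (any(amps > 0)) min(amps[amps > 0]) / 2 else 1
  # p = 0 (possible only as numerical underflow of an exact null) would
  # make log(p) infinite; floor at half the smallest positive p observed
  ps <- c(tbl$p1, tbl$p2)
  floor_p <- if (any(ps > 0)) min(ps[ps > 0]) / 2 else 1e-300
  tbl <- tbl %>%
    mutate(a1 = pmax(.data$a1, floor_amp),
           a2 = pmax(.data$a2, floor_amp),
           p1 = pmax(.data$p1, floor_p),
           p2 = pmax(.data$p2, floor_p),
           delta_period = log(.data$p1) - log(.data$p2),
           delta_amp = log2(.data$a2 / .data$a1),
           Z_P = zscore(.data$delta_period),
           Z_R = zscore(.data$delta_amp),
           S_DR = (.data$Z_P + .data$Z_R) / 2,
           pop1 = .env$p1, pop2 = .env$p2) %>%
    select("gene", "pop1", "pop2", "delta_period", "delta_amp",
           "Z_P", "Z_R", "S_DR")
  attr(tbl, "amplitude_floor") <- floor_amp
  tbl
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    warn("degenerate spread: all deltas equal; z-scores set to 0")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Gaussian p-values for differential rhythmicity scores
#'
#' Fits a Gaussian to the empirical S_DR distribution (its mean and SD) and
#' assigns each gene a tail p-value, plus Benjamini-Hochberg q-values.
#'
#' @param table Output of [sdr_scores()] (needs >= 10 genes for a stable
#'   fit).
#' @param tail `"upper"` (population 1 more rhythmic; default), `"lower"`,
#'   or `"two_sided"`.
#' @return `table` with `p` and `q` columns added.
#' @export
sdr_pvalues <- function(table, tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  if (nrow(table) < 10)
    abort("need >= 10 genes to fit the empirical Gaussian")
  mu <- mean(table$S_DR)
  s <- sd(table$S_DR)
  if (!is.finite(s) || s == 0) {
    warn("degenerate S_DR distribution; p set to 1")
    p <- rep(1, nrow(table))
  } else {
    z <- (table$S_DR - mu) / s
    p <- switch(tail,
                upper = pnorm(z, lower.tail = FALSE),
                lower = pnorm(z),
                two_sided = 2 * pnorm(abs(z), lower.tail = FALSE))
    p <- pmin(p, 1)
  }
  mutate(table, p = p, q = bh_adjust(p))
}

#' Rhythmicity-loss gene sets across populations
#'
#' Builds the standard comparative sets from per-population labels: genes
#' rhythmic in the reference population; of those, the ones arrhythmic in
#' every comparison population (`lost_in_all`), in at least one
#' (`lost_in_at_least_one`); and genes rhythmic in all populations.
#'
#' @param labels Tibble with `gene`, `population`, `label` (from
#'   [classify_rhythmicity()] / [rhythm_scan()]).
#' @param reference Name of the reference (surface) population.
#' @param comparisons Comparison populations; default all others present.
#' @return Named list of character vectors of gene ids.
#' @export
loss_sets <- function(labels, reference, comparisons = NULL) {
  pops <- unique(labels$population)
  if (!reference %in% pops)
    abort(paste("unknown reference population:", reference))
  if (is.null(comparisons)) comparisons <- setdiff(pops, reference)
  if (!all(comparisons %in% pops))
    abort(paste("unknown population(s):",
                paste(setdiff(comparisons, pops), collapse = ", ")))
  wide <- labels %>%
    select("gene", "population", "label") %>%
    tidyr::pivot_wider(names_from = "population", values_from = "label")
  ref_rhy <- wide$gene[wide[[reference]] == "rhythmic"]
  arr <- sapply(comparisons, function(p) wide[[p]] == "arrhythmic")
  arr <- matrix(arr, nrow = nrow(wide))
  rhy <- sapply(c(reference, comparisons),
                function(p) wide[[p]] == "rhythmic")
  rhy <- matrix(rhy, nrow = nrow(wide))
  list(
    rhythmic_in_reference = ref_rhy,
    lost_in_all = wide$gene[wide[[reference]] == "rhythmic" &
                              rowSums(arr) == length(comparisons)],
    lost_in_at_least_one = wide$gene[wide[[reference]] == "rhythmic" &
                                       rowSums(arr) >= 1],
    rhythmic_in_all = wide$gene[rowSums(rhy) == length(comparisons) + 1]
  )
}

#' Hypergeometric overlap test for two gene sets
#'
#' Upper-tail probability of observing an overlap at least as large as the
#' one seen, for two sets drawn from a common universe.
#'
#' @param setA,setB Character vectors of gene ids.
#' @param universe_size Size of the common gene universe.
#' @return Tibble: `overlap`, `size_a`, `size_b`, `universe`, `p`.
#' @export
set_overlap_test <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(setA) > universe_size || length(setB) > universe_size)
    abort("set sizes cannot exceed the universe size")
  k <- length(intersect(setA, setB))
  p <- phyper(k - 1, length(setA), universe_size - length(setA),
              length(setB), lower.tail = FALSE)
  tibble(overlap = k, size_a = length(setA), size_b = length(setB),
         universe = universe_size, p = p)
}

#' Paired shift test on rhythmicity p-values for a gene set
#'
#' Wilcoxon signed-rank test on per-gene differences of rhythmicity
#' p-values between two populations, restricted to a gene set (e.g.
#' annotated clock genes); reports which population is stochastically more
#' rhythmic (smaller p-values).
#'
#' @param gene_set Character vector of gene ids (>= 6 present in both
#'   tables).
#' @param results_ref,results_other Rhythm tables with `gene` and `p`.
#' @return Tibble: `n`, `direction`, `p`.
#' @export
pvalue_shift_test <- function(gene_set, results_ref, results_other) {
  tbl <- inner_join(
    select(filter(results_ref, .data$gene %in% gene_set), "gene", pr = "p"),
    select(filter(results_other, .data$gene %in% gene_set), "gene", po = "p"),
    by = "gene")
  if (nrow(tbl) < 6) abort("need >= 6 genes present in both tables")
  d <- tbl$pr - tbl$po
  if (all(d == 0))
    return(tibble(n = nrow(tbl), direction = "none", p = 1))
  wt <- suppressWarnings(wilcox.test(tbl$pr, tbl$po, paired = TRUE))
  dir <- if (median(d[d != 0]) < 0) "reference more rhythmic"
         else "other more rhythmic"
  tibble(n = nrow(tbl), direction = dir, p = wt$p.value)
}
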