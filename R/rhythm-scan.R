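#' Drop genes with low total counts
#'
#' Removes genes whose summed count across all samples falls below
#' `min_total` (default 100, the conventional low-expression cut for this
#' design). Gene order is preserved; the number of dropped genes is
#' reported via a message and stored in attribute `n_dropped`.
#'
#' @param counts Tibble with a `gene` column and one numeric column per
#'   sample.
#' @param min_total Minimum total count (inclusive) to retain a gene.
#' @return The filtered counts tibble.
#' @export
filter_low_expression <- function(counts, min_total = 100) {
  stopifnot(min_total >= 0, "gene" %in% names(counts))
  tot <- rowSums(counts[setdiff(names(counts), "gene")])
  keep <- tot >= min_total
  if (any(!keep))
    message(sum(!keep), " gene(s) below ", min_total, " total counts removed")
  out <- counts[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Cosine reference waveforms over a sampling design
#'
#' One template per candidate peak lag in `{0, lag_step, ..., period -
#' lag_step}`; each template is `cos(2*pi*(t - lag)/period)` evaluated at
#' every sample's circadian time, so replicates at the same CT receive
#' identical (tied) values.
#'
#' @param design A [sampling_design()].
#' @param period Period in hours.
#' @param lag_step Lag grid spacing in hours; must divide `period`.
#' @return A tibble with columns `lag`, `sample`, `CT`, `value`.
#' @export
reference_waveforms <- function(design, period = design$period, lag_step = 4) {
  mat <- template_matrix(design$samples$CT, period, lag_step)
  tidyr::expand_grid(lag = as.numeric(colnames(mat)),
                     sample = design$samples$sample) %>%
    left_join(design$samples[c("sample", "CT")], by = "sample") %>%
    mutate(value = cos(2 * pi * (.data$CT - .data$lag) / period))
}

template_matrix <- function(ct, period, lag_step) {
  if (abs(period / lag_step - round(period / lag_step)) > 1e-9)
    abort("`lag_step` must divide `period`")
  lags <- seq(0, period - lag_step, by = lag_step)
  mat <- vapply(lags, function(l) cos(2 * pi * (ct - l) / period),
                numeric(length(ct)))
  colnames(mat) <- lags
  mat
}

# tie signature of a numeric vector: multiset of duplicate-group sizes
tie_signature <- function(x) {
  tab <- sort(as.integer(table(x)), decreasing = TRUE)
  paste(tab, collapse = ",")
}

# canonical vector reproducing a tie signature: values 1..k with the
# signature's multiplicities (null distribution depends only on these)
pattern_vector <- function(sig) {
  sizes <- as.integer(strsplit(sig, ",", fixed = TRUE)[[1]])
  rep(seq_along(sizes), times = sizes)
}

# Monte-Carlo null of the max-over-lags tau for one data tie signature.
# Seeded from (seed, signature) so results do not depend on the order in
# which signatures are encountered. Returns the sorted draws.
null_max_tau <- function(sig, group_sizes, csign, denom, n_null, seed) {
  x <- as.numeric(pattern_vector(sig))
  set.seed(substream_seed(seed, paste0("null:", sig)))
  draws <- perm_null_tau(x, group_sizes, csign, denom,
                         as.integer(n_null))$max_tau
  sort(draws)
}

# sign of the template difference for each timepoint pair (t<u), per lag
timepoint_pair_signs <- function(tps, period, lag_step) {
  Yt <- template_matrix(tps, period, lag_step)
  k <- length(tps)
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  # C++ enumerates (t,u) with t<u in t-major order
  ord <- order(pairs[, "row"], pairs[, "col"])
  m <- vapply(seq_len(ncol(Yt)), function(l)
    sign(Yt[pairs[ord, "col"], l] - Yt[pairs[ord, "row"], l]),
    numeric(nrow(pairs)))
  matrix(m, nrow = nrow(pairs))
}

mc_upper_p <- function(sorted_null, obs) {
  n <- length(sorted_null)
  (1 + n - findInterval(obs - 1e-12, sorted_null)) / (n + 1)
}

#' Nonparametric 24-h rhythmicity test for one expression series
#'
#' JTK_cycle-style test: Kendall's tau-b between the series and cosine
#' reference waveforms at every candidate peak lag; the best lag gives the
#' phase estimate, and the p-value measures how extreme the best
#' correlation is under permutation of the data.
#'
#' Two p-value conventions are available. `"maxstat"` (default) compares
#' the observed max-over-lags tau with its Monte-Carlo permutation null
#' conditioned on the series' tie pattern (`n_null` seeded draws;
#' exactly calibrated). `"bonferroni"` follows the classical JTK-style
#' convention: the best tau is converted through the exact single-template
#' null (tie-free data assumed) and multiplied by `bonferroni_factor`
#' (default `2 *` the number of lags — one alternative per lag and sign),
#' capped at 1. The classical convention is conservative, with an atom of
#' p-values at 1; the conventional "arrhythmic at p > 0.5" call was
#' calibrated by the field against p-values of this kind.
#'
#' @param series Numeric vector, one value per sample of `design`.
#' @param design A [sampling_design()].
#' @param period Period in hours (fixed-period test).
#' @param lag_step Lag grid spacing in hours.
#' @param p_method `"maxstat"` or `"bonferroni"`.
#' @param n_null Monte-Carlo null size for `"maxstat"`.
#' @param bonferroni_factor Multiplicity factor for `"bonferroni"`;
#'   `NULL` means the number of lags.
#' @param amplitude_method `"range_median"` (half the max minus min of
#'   per-timepoint medians) or `"hodges_lehmann"` (median of pairwise
#'   half-differences between samples in the peak and trough quarters of
#'   the fitted cycle).
#' @param seed Integer seed for the Monte-Carlo null.
#' @return A one-row tibble: `tau`, `p`, `phase`, `amplitude`, `period`,
#'   `degenerate`.
#' @examples
#' d <- sampling_design()
#' y <- 100 + 50 * cos(2 * pi * (d$samples$CT - 8) / 24)
#' jtk_test(y, d)
#' @export
jtk_test <- function(series, design = sampling_design(), period = 24,
                     lag_step = 4, p_method = c("maxstat", "bonferroni"),
                     n_null = 1e5, bonferroni_factor = NULL,
                     amplitude_method = c("range_median", "hodges_lehmann"),
                     seed = 1L) {
  p_method <- match.arg(p_method)
  amplitude_method <- match.arg(amplitude_method)
  ct <- design$samples$CT
  if (length(series) != length(ct))
    abort("`series` length must equal the design's sample count")
  X <- matrix(as.numeric(series), nrow = 1)
  res <- rhythm_engine(X, genes = "series", ct = ct, period = period,
                       lag_step = lag_step, p_method = p_method,
                       n_null = n_null, bonferroni_factor = bonferroni_factor,
                       amplitude_method = amplitude_method, seed = seed)
  select(res, "tau", "p", "phase", "amplitude", "period", "degenerate")
}

# Shared engine: X is a genes x samples matrix.
rhythm_engine <- function(X, genes, ct, period, lag_step, p_method, n_null,
                          bonferroni_factor, amplitude_method, seed) {
  Y <- template_matrix(ct, period, lag_step)
  psign <- pair_signs(Y)
  n <- length(ct)
  n0 <- n * (n - 1) / 2
  ty <- colSums(psign == 0)        # tied pairs per template
  denom_y <- sqrt(n0 - ty)         # lag-specific part of the tau-b denominator
  lags <- as.numeric(colnames(Y))

  obs <- observed_s(X, psign)
  tx <- obs$Tx
  degenerate <- tx == n0
  # scaled statistic: S_l / sqrt(n0 - Ty_l); equals tau * sqrt(n0 - Tx)
  scaled <- sweep(obs$S, 2, denom_y, "/")
  best_lag_idx <- max.col(scaled, ties.method = "first")
  best_scaled <- scaled[cbind(seq_len(nrow(X)), best_lag_idx)]
  tau <- ifelse(degenerate, 0,
                best_scaled / sqrt(n0 - tx))
  phase <- lags[best_lag_idx]
  phase[degenerate] <- 0

  p <- rep(1, nrow(X))
  if (p_method == "maxstat") {
    tps <- sort(unique(ct))
    group_sizes <- as.integer(table(factor(ct, levels = tps)))
    csign <- timepoint_pair_signs(tps, period, lag_step)
    sigs <- apply(X, 1, tie_signature)
    cache <- new.env(parent = emptyenv())
    for (sig in unique(sigs[!degenerate])) {
      assign(sig, null_max_tau(sig, group_sizes, csign, denom_y,
                               n_null, seed),
             envir = cache)
    }
    idx <- which(!degenerate)
    if (length(idx)) {
      # null draws are on the same S/sqrt(n0 - Ty) scale as best_scaled;
      # the gene-constant sqrt(n0 - Tx) factor cancels from the comparison
      p[idx] <- vapply(idx, function(i) {
        mc_upper_p(get(sigs[i], envir = cache), best_scaled[i])
      }, 0)
    }
  } else {
    # classical convention: factor = number of lag/sign alternatives
    if (is.null(bonferroni_factor)) bonferroni_factor <- 2 * length(lags)
    null_by_ty <- lapply(unique(ty), function(t1) {
      sizes <- template_group_sizes(Y[, which(ty == t1)[1]])
      exact_tau_null(tie_pattern = sizes)
    })
    names(null_by_ty) <- unique(ty)
    idx <- which(!degenerate)
    p[idx] <- vapply(idx, function(i) {
      l <- best_lag_idx[i]
      nul <- null_by_ty[[as.character(ty[l])]]
      # floor at the convolution's numerical resolution so perfect
      # rhythms do not underflow to p = 0
      min(1, bonferroni_factor *
            max(tau_null_upper_p(nul, obs$S[i, l]), 1e-16))
    }, 0)
  }

  amplitude <- amplitude_estimate(X, ct, phase, period, amplitude_method)
  amplitude[degenerate] <- 0

  tibble(gene = genes, tau = as.numeric(tau), p = p, phase = phase,
         amplitude = amplitude, period = period, degenerate = degenerate)
}

template_group_sizes <- function(yvec) {
  as.integer(table(round(yvec, 9)))
}

amplitude_estimate <- function(X, ct, phase, period, method) {
  tps <- sort(unique(ct))
  med <- vapply(tps, function(t) apply(X[, ct == t, drop = FALSE], 1, median),
                numeric(nrow(X)))
  med <- matrix(med, nrow = nrow(X))
  if (method == "range_median")
    return((apply(med, 1, max) - apply(med, 1, min)) / 2)
  # Hodges-Lehmann flavor: median of pairwise half-differences between
  # samples in the quarter-cycle around the fitted peak and trough
  vapply(seq_len(nrow(X)), function(i) {
    dpk <- abs(((ct - phase[i] + period / 2) %% period) - period / 2)
    dtr <- abs(((ct - phase[i] + period) %% period) - period / 2)
    pk <- X[i, dpk <= period / 4 + 1e-9]
    tr <- X[i, dtr < period / 4 - 1e-9]
    if (!length(pk) || !length(tr)) return(0)
    median(outer(pk, tr, "-")) / 2
  }, 0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, preserving input order. A thin validated wrapper
#' over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify genes as rhythmic, arrhythmic, or indeterminate
#'
#' A gene is called rhythmic when its FDR-adjusted q-value is below
#' `fdr_threshold` (default 5\% FDR), arrhythmic when its raw p-value
#' exceeds `arrhythmic_threshold` (default 0.5, a conservative non-cycling
#' call), and indeterminate otherwise.
#'
#' @param results Tibble with columns `p` and `q` (e.g. from
#'   [rhythm_scan()]).
#' @param fdr_threshold Rhythmic call: `q < fdr_threshold`.
#' @param arrhythmic_threshold Arrhythmic call: `p > arrhythmic_threshold`.
#' @return `results` with a `label` factor column added.
#' @export
classify_rhythmicity <- function(results, fdr_threshold = 0.05,
                                 arrhythmic_threshold = 0.5) {
  stopifnot(all(c("p", "q") %in% names(results)))
  results %>%
    mutate(label = factor(
      dplyr::case_when(
        .data$q < fdr_threshold ~ "rhythmic",
        .data$p > arrhythmic_threshold ~ "arrhythmic",
        TRUE ~ "indeterminate"),
      levels = c("rhythmic", "arrhythmic", "indeterminate")))
}

#' Scan a count matrix for 24-h rhythmic genes, per population
#'
#' Runs the rank-based rhythmicity test gene-by-gene within each
#' population, adjusts p-values by Benjamini-Hochberg within population,
#' estimates phase (peak lag) and amplitude, and labels each gene
#' rhythmic / arrhythmic / indeterminate.
#'
#' @param counts Tibble: `gene` column plus one column per sample.
#' @param meta Tibble: `sample`, `population`, `CT`, `replicate`.
#' @param period,lag_step Hours; `lag_step` must divide `period`.
#' @param min_total Low-expression filter applied before testing
#'   ([filter_low_expression()]); set 0 to disable.
#' @param fdr,arrhythmic_p Classification thresholds
#'   ([classify_rhythmicity()]).
#' @param p_method,n_null,bonferroni_factor,amplitude_method,seed Passed to
#'   the per-gene test; see [jtk_test()].
#' @return A `rhythm_scan` object; `tidy()` returns the per-gene tibble
#'   (`gene`, `population`, `tau`, `p`, `q`, `phase`, `amplitude`,
#'   `period`, `label`), `glance()` per-population counts.
#' @examples
#' sim <- simulate_expression(simulate_gene_truth(30, seed = 2), seed = 2)
#' scan <- rhythm_scan(sim$counts, sim$meta, n_null = 2000, seed = 2)
#' glance(scan)
#' @export
rhythm_scan <- function(counts, meta, period = 24, lag_step = 4,
                        min_total = 100, fdr = 0.05, arrhythmic_p = 0.5,
                        p_method = c("maxstat", "bonferroni"), n_null = 1e5,
                        bonferroni_factor = NULL,
                        amplitude_method = c("range_median", "hodges_lehmann"),
                        seed = 1L) {
  p_method <- match.arg(p_method)
  amplitude_method <- match.arg(amplitude_method)
  stopifnot("gene" %in% names(counts),
            all(c("sample", "population", "CT") %in% names(meta)))
  missing_smp <- setdiff(meta$sample, names(counts))
  if (length(missing_smp))
    abort(paste("samples missing from counts:",
                paste(missing_smp, collapse = ", ")))
  counts <- filter_low_expression(counts, min_total)
  out <- purrr::map_dfr(unique(meta$population), function(pop) {
    m <- meta[meta$population == pop, ]
    X <- as.matrix(counts[m$sample])
    res <- rhythm_engine(X, genes = counts$gene, ct = m$CT, period = period,
                         lag_step = lag_step, p_method = p_method,
                         n_null = n_null,
                         bonferroni_factor = bonferroni_factor,
                         amplitude_method = amplitude_method, seed = seed)
    res %>%
      mutate(population = pop, q = bh_adjust(.data$p)) %>%
      select("gene", "population", "tau", "p", "q", "phase", "amplitude",
             "period", "degenerate")
  })
  out <- classify_rhythmicity(out, fdr, arrhythmic_p)
  structure(list(result = out,
                 params = list(period = period, lag_step = lag_step,
                               min_total = min_total, fdr = fdr,
                               arrhythmic_p = arrhythmic_p,
                               p_method = p_method, n_null = n_null,
                               seed = seed)),
            class = "rhythm_scan")
}

#' @export
print.rhythm_scan <- function(x, ...) {
  cat("<rhythm_scan>\n")
  print(glance(x))
  invisible(x)
}

#' @rdname rhythm_scan
#' @param x A `rhythm_scan` object.
#' @param ... Unused.
#' @method tidy rhythm_scan
#' @export
tidy.rhythm_scan <- function(x, ...) x$result

#' @rdname rhythm_scan
#' @method glance rhythm_scan
#' @export
glance.rhythm_scan <- function(x, ...) {
  x$result %>%
    group_by(.data$population) %>%
    summarise(n_genes = n(),
              n_rhythmic = sum(.data$label == "rhythmic"),
              n_arrhythmic = sum(.data$label == "arrhythmic"),
              median_p = median(.data$p),
              .groups = "drop")
}
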