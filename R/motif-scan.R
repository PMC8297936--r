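# integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else NA
encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "")[[1]], DNA)
  code
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Exact score-distribution p-values for a PWM
#'
#' Dynamic programme over motif positions and discretized log-odds scores:
#' the log-odds of each (base, position) cell is mapped to an integer on a
#' shared grid, and the exact distribution of the integer score of a
#' background-drawn word is accumulated position by position. The returned
#' table maps any word's integer score to `P(background word scores >= s)`
#' — the same machinery FIMO uses to convert match scores to p-values.
#' Words are scored on the identical integer grid, so lookups are exact
#' with respect to the discretized score; discretization only coarsens
#' score resolution (p is taken from the bin's lower edge, the
#' conservative side).
#'
#' @param pwm A [pwm_from_counts()] object.
#' @param background Background composition for both the log-odds and the
#'   null word distribution; defaults to the PWM's own.
#' @param bins Number of discretization bins across the attainable score
#'   range (1e4 for production; smaller is fine for tests).
#' @return A `pwm_pvalue_table`: list with `pwm`, `delta` (bin width in
#'   log2-odds units), `int_scores` (4 x width integer cell scores),
#'   `min_sum`, `tail` (vector; `tail[k - min_sum + 1]` =
#'   P(score_int >= k)), `background`.
#' @export
score_pvalue_table <- function(pwm, background = pwm$background,
                               bins = 1e4) {
  stopifnot(inherits(pwm, "pwm"))
  background <- background / sum(background)
  lo <- log2(pwm$prob / background)
  if (any(!is.finite(lo)))
    abort("PWM has zero probabilities; use a positive pseudocount")
  span <- sum(apply(lo, 2, max)) - sum(apply(lo, 2, min))
  delta <- if (span > 0) span / bins else 1
  int_scores <- round(lo / delta)
  mode(int_scores) <- "integer"

  # pmf over integer score sums, accumulated across positions
  offset <- sum(apply(int_scores, 2, min))
  width_range <- sum(apply(int_scores, 2, max)) - offset
  pmf <- numeric(width_range + 1)
  pmf[1] <- 1
  for (j in seq_len(pwm$width)) {
    nxt <- numeric(length(pmf))
    col <- int_scores[, j] - min(int_scores[, j])
    for (b in 1:4) {
      sh <- col[b]
      if (background[b] > 0)
        nxt[(1 + sh):length(pmf)] <- nxt[(1 + sh):length(pmf)] +
          background[b] * pmf[1:(length(pmf) - sh)]
    }
    pmf <- nxt
  }
  tail <- rev(cumsum(rev(pmf)))
  tail <- pmin(tail, 1)
  structure(list(pwm = pwm, delta = delta, int_scores = int_scores,
                 min_sum = offset, tail = tail, background = background,
                 log_odds = lo),
            class = "pwm_pvalue_table")
}

# integer score -> p lookup (clamped to the table's range)
int_score_p <- function(table, int_sum) {
  k <- int_sum - table$min_sum + 1
  k <- pmin(pmax(k, 1), length(table$tail))
  table$tail[k]
}

#' Scan a sequence for PWM matches above a p-value threshold
#'
#' Scores every window on the requested strands with the PWM's log-odds
#' and reports windows whose exact background p-value
#' ([score_pvalue_table()]) is below `p_threshold` (conventional default
#' 1e-4). Reverse-strand hits are reported in forward coordinates; windows
#' containing non-ACGT characters are skipped.
#'
#' @param sequence A DNA string.
#' @param pwm A `pwm` object.
#' @param p_threshold Report hits with `p < p_threshold`.
#' @param strands Character subset of `c("+", "-")`.
#' @param pvalue_table Optional precomputed [score_pvalue_table()] (reuse
#'   across sequences for speed).
#' @return Tibble: `offset` (0-based, forward coordinates), `strand`,
#'   `score` (log2-odds), `p`.
#' @export
scan_sequence <- function(sequence, pwm, p_threshold = 1e-4,
                          strands = c("+", "-"), pvalue_table = NULL) {
  stopifnot(inherits(pwm, "pwm"), all(strands %in% c("+", "-")))
  if (is.null(pvalue_table)) pvalue_table <- score_pvalue_table(pwm)
  w <- pwm$width
  L <- nchar(sequence)
  empty <- tibble(offset = integer(), strand = character(),
                  score = numeric(), p = numeric())
  if (L < w) return(empty)
  out <- list()
  for (st in strands) {
    seq_st <- if (st == "+") sequence else revcomp(sequence)
    code <- encode_dna(seq_st)
    n_off <- L - w + 1
    int_sum <- integer(n_off)
    real <- numeric(n_off)
    ok <- rep(TRUE, n_off)
    for (j in seq_len(w)) {
      b <- code[j:(n_off + j - 1)]
      ok <- ok & !is.na(b)
      bi <- ifelse(is.na(b), 1L, b)
      int_sum <- int_sum + pvalue_table$int_scores[cbind(bi, j)]
      real <- real + pvalue_table$log_odds[cbind(bi, j)]
    }
    p <- int_score_p(pvalue_table, int_sum)
    keep <- ok & p < p_threshold
    if (any(keep)) {
      off <- which(keep) - 1L
      fwd_off <- if (st == "+") off else L - w - off
      out[[st]] <- tibble(offset = as.integer(fwd_off), strand = st,
                          score = real[keep], p = p[keep])
    }
  }
  if (!length(out)) return(empty)
  arrange(bind_rows(out), .data$offset, .data$strand)
}

#' Scan a promoter set with one or more PWMs
#'
#' @param promoters A promoter tibble ([extract_promoters()] /
#'   [simulate_promoters()]) with `gene` and `seq` columns, or a named
#'   character vector of sequences.
#' @param pwms A `pwm` or named list of them.
#' @param p_threshold,strands As in [scan_sequence()].
#' @return Tibble: `gene`, `motif`, `offset`, `strand`, `score`, `p`.
#' @export
scan_promoters <- function(promoters, pwms, p_threshold = 1e-4,
                           strands = c("+", "-")) {
  if (is.character(promoters))
    promoters <- tibble(gene = names(promoters), seq = unname(promoters))
  if (inherits(pwms, "pwm")) pwms <- setNames(list(pwms), pwms$name)
  purrr::imap_dfr(pwms, function(pwm, nm) {
    tab <- score_pvalue_table(pwm)
    purrr::map_dfr(seq_len(nrow(promoters)), function(i) {
      hits <- scan_sequence(promoters$seq[i], pwm, p_threshold, strands, tab)
      if (nrow(hits)) mutate(hits, gene = promoters$gene[i], motif = nm)
      else NULL
    })
  }) %>%
    { if (nrow(.)) select(., "gene", "motif", "offset", "strand",
                          "score", "p")
      else tibble(gene = character(), motif = character(),
                  offset = integer(), strand = character(),
                  score = numeric(), p = numeric()) }
}
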