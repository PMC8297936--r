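#' Simulate promoter sequences with phase-linked planted motifs
#'
#' Draws background promoter sequences i.i.d. from a stated base
#' composition and plants each motif's consensus, at a recorded offset and
#' strand, into the promoters of genes whose peak phase falls inside that
#' motif's circular phase window — with the stated planting probability.
#' This emulates the association between circadian cis-elements and the
#' phase of their target genes that the enrichment scan is meant to
#' recover.
#'
#' @param gene_phases Tibble: `gene`, `phase` (hours).
#' @param motif_library Named list of `pwm` objects ([motif_library()]).
#' @param planting_rule Tibble: `motif`, `window_start`, `window_end`
#'   (hours, circular window `[start, end)`), `prob` (planting
#'   probability).
#' @param length Promoter length in bases (must be >= the widest motif).
#' @param background Base composition (A, C, G, T); uniform by default.
#' @param period Clock period in hours.
#' @param seed Integer seed.
#' @return List: `promoters` (tibble `gene`, `seq`), `truth` (tibble
#'   `gene`, `motif`, `offset` (0-based), `strand`).
#' @export
simulate_promoters <- function(gene_phases, motif_library = NULL,
                               planting_rule, length = 1200,
                               background = rep(0.25, 4), period = 24,
                               seed = 1L) {
  if (is.null(motif_library)) motif_library <- cavechrono::motif_library()
  stopifnot(all(c("gene", "phase") %in% names(gene_phases)),
            all(c("motif", "window_start", "window_end", "prob") %in%
                  names(planting_rule)),
            all(planting_rule$motif %in% names(motif_library)),
            all(planting_rule$prob >= 0 & planting_rule$prob <= 1))
  widths <- vapply(motif_library[planting_rule$motif], `[[`, 0L, "width")
  if (any(widths > length))
    abort("motif wider than the promoter length")
  background <- background / sum(background)
  set.seed(substream_seed(seed, "promoters"))

  in_window <- function(phase, s, e) {
    ph <- phase %% period; s <- s %% period; e <- e %% period
    if (s == e) TRUE                     # full-circle window
    else if (s < e) ph >= s & ph < e
    else ph >= s | ph < e
  }

  truth <- list()
  seqs <- character(nrow(gene_phases))
  for (i in seq_len(nrow(gene_phases))) {
    g <- gene_phases$gene[i]
    s <- paste(sample(DNA, length, replace = TRUE, prob = background),
               collapse = "")
    used <- integer(0)                   # occupied positions
    for (k in seq_len(nrow(planting_rule))) {
      rule <- planting_rule[k, ]
      if (!in_window(gene_phases$phase[i], rule$window_start,
                     rule$window_end)) next
      if (runif(1) >= rule$prob) next
      cons <- motif_library[[rule$motif]]$consensus
      w <- nchar(cons)
      for (try in 1:50) {
        off <- sample.int(length - w + 1, 1) - 1L
        if (!any((off + seq_len(w)) %in% used)) break
        off <- NA_integer_
      }
      if (is.na(off)) next               # no free slot; skip, not recorded
      substr(s, off + 1, off + w) <- cons
      used <- c(used, off + seq_len(w))
      truth[[base::length(truth) + 1]] <-
        tibble(gene = g, motif = rule$motif, offset = off, strand = "+")
    }
    seqs[i] <- s
  }
  list(promoters = tibble(gene = gene_phases$gene, seq = seqs),
       truth = if (base::length(truth)) bind_rows(truth)
               else tibble(gene = character(), motif = character(),
                           offset = integer(), strand = character()))
}
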