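#' Sliding-window phase enrichment of motif targets
#'
#' Tests, for each circular time window tiling the clock, whether genes
#' whose promoters carry the motif are over-represented among genes
#' peaking inside the window: a two-sided Fisher's exact test on the 2 x 2
#' table (has motif x peaks in window) over all genes with a phase.
#'
#' @param gene_phases Tibble with `gene` and `phase` (hours).
#' @param target_genes Character vector of genes whose promoters carry the
#'   motif (must all have phases).
#' @param window Window width in hours.
#' @param step Window start spacing in hours.
#' @param period Clock period in hours.
#' @return Tibble: `window_start`, `window_center`, `n_in`, `n_motif_in`,
#'   `odds_ratio`, `p`, `empty` (flag for windows with an empty margin,
#'   reported with p = 1).
#' @export
phase_window_enrichment <- function(gene_phases, target_genes, window = 6,
                                    step = 2, period = 24) {
  stopifnot(window <= period, step > 0)
  miss <- setdiff(target_genes, gene_phases$gene)
  if (length(miss))
    abort(paste("phases missing for flagged gene(s):",
                paste(utils::head(miss, 5), collapse = ", ")))
  ph <- gene_phases$phase %% period
  has_motif <- gene_phases$gene %in% target_genes
  starts <- seq(0, period - step, by = step)
  purrr::map_dfr(starts, function(s) {
    e <- (s + window) %% period
    in_win <- if (s + window <= period) ph >= s & ph < s + window
              else ph >= s | ph < e
    n11 <- sum(has_motif & in_win); n12 <- sum(has_motif & !in_win)
    n21 <- sum(!has_motif & in_win); n22 <- sum(!has_motif & !in_win)
    degenerate <- (n11 + n21 == 0) || (n12 + n22 == 0) ||
      (n11 + n12 == 0) || (n21 + n22 == 0)
    if (degenerate) {
      or <- 1; p <- 1
    } else {
      ft <- fisher.test(matrix(c(n11, n21, n12, n22), 2))
      or <- unname(ft$estimate); p <- ft$p.value
    }
    tibble(window_start = s,
           window_center = (s + window / 2) %% period,
           n_in = n11 + n21, n_motif_in = n11,
           odds_ratio = or, p = p, empty = degenerate)
  })
}

#' Compare motif presence between two promoter sets
#'
#' For a gene set scanned against the same PWM at the same threshold in
#' two populations' promoters, lists genes that lost the motif (at least
#' one hit in the reference, none in the alternate) and tests presence
#' counts with a 2 x 2 Fisher's exact test.
#'
#' @param hits_ref,hits_alt Hit tables ([scan_promoters()]) with a `gene`
#'   column.
#' @param gene_set Genes to compare; genes absent from either promoter set
#'   (given via `genes_ref` / `genes_alt`) are excluded with a warning.
#' @param genes_ref,genes_alt Genes whose promoters were actually scanned
#'   in each population; defaults to `gene_set`.
#' @return List: `losses` (character), `gains` (character), `table` (2 x
#'   2), `odds_ratio`, `p`.
#' @export
motif_presence_comparison <- function(hits_ref, hits_alt, gene_set,
                                      genes_ref = gene_set,
                                      genes_alt = gene_set) {
  usable <- intersect(intersect(gene_set, genes_ref), genes_alt)
  dropped <- setdiff(gene_set, usable)
  if (length(dropped))
    warn(paste(length(dropped),
               "gene(s) absent from one promoter set; excluded"))
  pres_ref <- usable %in% hits_ref$gene
  pres_alt <- usable %in% hits_alt$gene
  tab <- matrix(c(sum(pres_ref), sum(!pres_ref),
                  sum(pres_alt), sum(!pres_alt)), 2,
                dimnames = list(c("present", "absent"),
                                c("reference", "alternate")))
  ft <- if (any(rowSums(tab) == 0)) NULL else fisher.test(tab)
  list(losses = usable[pres_ref & !pres_alt],
       gains = usable[!pres_ref & pres_alt],
       table = tab,
       odds_ratio = if (is.null(ft)) 1 else unname(ft$estimate),
       p = if (is.null(ft)) 1 else ft$p.value)
}
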