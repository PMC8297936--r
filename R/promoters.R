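#' Extract promoter sequences around transcription start sites
#'
#' Cuts the putative promoter window — by convention 1 kb upstream to 200
#' bp downstream of the TSS — out of a genome, honouring strand: for a
#' forward-strand gene with 0-based TSS `t` the window is
#' `[t - upstream, t + downstream)`; for a minus-strand gene it is
#' `[t - downstream + 1, t + upstream + 1)` reverse-complemented. Windows
#' clipped at a contig edge are flagged.
#'
#' @param annotation Tibble: `gene`, `contig`, `tss` (0-based), `strand`
#'   (`"+"`/`"-"`).
#' @param genome Named character vector of contig sequences (or a
#'   `DNAStringSet`).
#' @param upstream,downstream Window extent in bases.
#' @return Promoter tibble: `gene`, `contig`, `tss`, `strand`, `start`,
#'   `end` (0-based half-open, forward coordinates), `clipped`, `fwd_seq`
#'   (forward-strand window), `seq` (promoter-oriented sequence).
#' @export
extract_promoters <- function(annotation, genome, upstream = 1000,
                              downstream = 200) {
  if (inherits(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  stopifnot(all(c("gene", "contig", "tss", "strand") %in% names(annotation)),
            all(annotation$strand %in% c("+", "-")))
  missing_ctg <- setdiff(annotation$contig, names(genome))
  if (length(missing_ctg)) {
    bad <- annotation$gene[annotation$contig %in% missing_ctg]
    abort(paste("contig missing from genome for gene(s):",
                paste(bad, collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    len <- nchar(genome[[g$contig]])
    if (g$tss < 0 || g$tss >= len)
      abort(paste("TSS outside contig for gene", g$gene))
    if (g$strand == "+") {
      s <- g$tss - upstream; e <- g$tss + downstream
    } else {
      s <- g$tss - downstream + 1; e <- g$tss + upstream + 1
    }
    cs <- max(0, s); ce <- min(len, e)
    fwd <- substr(genome[[g$contig]], cs + 1, ce)
    tibble(gene = g$gene, contig = g$contig, tss = g$tss, strand = g$strand,
           start = cs, end = ce, clipped = (cs != s) | (ce != e),
           fwd_seq = fwd,
           seq = if (g$strand == "+") fwd else revcomp(fwd))
  })
}

#' Substitute population-major alleles into promoter sequences
#'
#' Builds a population-specific promoter set by replacing the reference
#' allele with the alternate wherever the alternate's frequency in the
#' population exceeds `freq_threshold` (default 0.5, i.e. the population's
#' major allele). SNVs and simple indels are supported; coordinates within
#' each promoter are remapped after indels. Overlapping indels are
#' rejected.
#'
#' @param promoters Promoter tibble from [extract_promoters()].
#' @param variants Tibble: `contig`, `pos` (1-based, as in VCF), `ref`,
#'   `alt`, `freq` (alternate-allele frequency in the population).
#' @param freq_threshold Substitute when `freq > freq_threshold`.
#' @return The promoter tibble with substituted `fwd_seq`/`seq` and an
#'   `n_substituted` column; the substitution log is in attribute
#'   `substitutions`.
#' @export
apply_variants <- function(promoters, variants, freq_threshold = 0.5) {
  stopifnot(all(c("contig", "pos", "ref", "alt", "freq") %in% names(variants)))
  vs <- filter(variants, .data$freq > freq_threshold)
  log <- list()
  out <- promoters
  out$n_substituted <- 0L
  for (i in seq_len(nrow(out))) {
    p <- out[i, ]
    v <- vs %>%
      filter(.data$contig == p$contig,
             .data$pos - 1 >= p$start,
             .data$pos - 1 + nchar(.data$ref) <= p$end) %>%
      arrange(.data$pos)
    if (!nrow(v)) next
    off <- v$pos - 1 - p$start           # 0-based offset in window
    ends <- off + nchar(v$ref)
    if (nrow(v) > 1 && any(off[-1] < ends[-nrow(v)]))
      abort(paste("overlapping variants in promoter of", p$gene, "at",
                  paste(v$pos[which(off[-1] < ends[-nrow(v)]) + 1],
                        collapse = ", ")))
    s <- p$fwd_seq
    for (k in rev(seq_len(nrow(v)))) {   # right to left: offsets stay valid
      have <- substr(s, off[k] + 1, ends[k])
      if (toupper(have) != toupper(v$ref[k]))
        abort(paste0("reference mismatch at ", p$contig, ":", v$pos[k],
                     " (expected ", v$ref[k], ", found ", have, ")"))
      s <- paste0(substr(s, 1, off[k]), v$alt[k],
                  substring(s, ends[k] + 1))
    }
    out$fwd_seq[i] <- s
    out$seq[i] <- if (p$strand == "+") s else revcomp(s)
    out$n_substituted[i] <- nrow(v)
    log[[p$gene]] <- v
  }
  attr(out, "substitutions") <- log
  out
}
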