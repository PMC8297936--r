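# Internals operate on a genotype tibble (`contig`, `pos`, `ref`, `alt`,
# one 0/1/2/NA dosage column per individual) plus a pop_map tibble
# (`individual`, `population`). VCF input is 1-based; gene intervals are
# 0-based half-open (BED convention); read_vcf_genotypes()/read_bed_genes()
# are the only places translation happens.

geno_matrix <- function(genotypes, pop_map, population) {
  inds <- pop_map$individual[pop_map$population == population]
  if (!length(inds)) abort(paste("unknown population:", population))
  as.matrix(genotypes[inds])
}

#' Per-site alternate-allele frequencies in one population
#'
#' Frequency = alternate-allele count / called-allele count; missing
#' genotypes are excluded. All-missing sites get `NA` frequency and are
#' flagged.
#'
#' @param genotypes Genotype tibble (see [simulate_genotypes()]).
#' @param pop_map Tibble: `individual`, `population`.
#' @param population Population name.
#' @return Tibble: `contig`, `pos`, `freq`, `n_called` (called alleles),
#'   `all_missing`.
#' @export
allele_frequencies <- function(genotypes, pop_map, population) {
  G <- geno_matrix(genotypes, pop_map, population)
  n_called <- rowSums(!is.na(G)) * 2
  alt <- rowSums(G, na.rm = TRUE)
  tibble(contig = genotypes$contig, pos = genotypes$pos,
         freq = ifelse(n_called > 0, alt / n_called, NA_real_),
         n_called = n_called, all_missing = n_called == 0)
}

site_in_gene <- function(genotypes, gene_intervals) {
  # pos is 1-based; intervals 0-based half-open: site in gene iff
  # start < pos <= end, i.e. 0-based pos-1 in [start, end)
  purrr::map_dfr(seq_len(nrow(gene_intervals)), function(i) {
    g <- gene_intervals[i, ]
    idx <- which(genotypes$contig == g$contig &
                   genotypes$pos - 1 >= g$start & genotypes$pos - 1 < g$end)
    if (length(idx)) tibble(gene = g$gene, site = idx) else NULL
  })
}

#' Per-gene nucleotide diversity (pi) in one population
#'
#' Per-site pi is the unbiased expected heterozygosity
#' `(n/(n-1)) * 2p(1-p)` with `n` the called-allele count; per-gene pi
#' sums site values over the gene's coding interval and divides by its
#' length, so monomorphic positions contribute zero.
#'
#' @param genotypes,pop_map,population As in [allele_frequencies()].
#' @param gene_intervals Tibble: `gene`, `contig`, `start`, `end` (0-based
#'   half-open coding intervals).
#' @return Tibble: `gene`, `population`, `n_sites`, `pi`.
#' @export
nucleotide_diversity <- function(genotypes, pop_map, population,
                                 gene_intervals) {
  stopifnot(all(gene_intervals$end > gene_intervals$start))
  af <- allele_frequencies(genotypes, pop_map, population)
  site_pi <- ifelse(af$n_called >= 2,
                    (af$n_called / (af$n_called - 1)) *
                      2 * af$freq * (1 - af$freq), NA_real_)
  map <- site_in_gene(genotypes, gene_intervals)
  purrr::map_dfr(seq_len(nrow(gene_intervals)), function(i) {
    g <- gene_intervals[i, ]
    idx <- map$site[map$gene == g$gene]
    vals <- site_pi[idx]
    tibble(gene = g$gene, population = population,
           n_sites = length(idx),
           pi = sum(vals, na.rm = TRUE) / (g$end - g$start))
  })
}

# Weir & Cockerham (1984) two-population variance components per site.
wc_components <- function(genotypes, pop_map, popA, popB) {
  GA <- geno_matrix(genotypes, pop_map, popA)
  GB <- geno_matrix(genotypes, pop_map, popB)
  nA <- rowSums(!is.na(GA)); nB <- rowSums(!is.na(GB))
  pA <- ifelse(nA > 0, rowSums(GA, na.rm = TRUE) / (2 * nA), NA)
  pB <- ifelse(nB > 0, rowSums(GB, na.rm = TRUE) / (2 * nB), NA)
  hA <- ifelse(nA > 0, rowSums(GA == 1, na.rm = TRUE) / nA, NA)
  hB <- ifelse(nB > 0, rowSums(GB == 1, na.rm = TRUE) / nB, NA)
  usable <- nA >= 2 & nB >= 2
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  mono <- !is.na(pbar) & (pbar == 0 | pbar == 1)
  usable <- usable & !mono & is.finite(a + b + cc)
  a[!usable] <- 0; b[!usable] <- 0; cc[!usable] <- 0
  tibble(contig = genotypes$contig, pos = genotypes$pos,
         a = a, b = b, c = cc, usable = usable)
}

#' Weir-Cockerham F_ST between two populations
#'
#' Per-site variance components (a, b, c) of the Weir & Cockerham (1984)
#' two-population estimator, aggregated per gene as the ratio of averages
#' `sum(a) / sum(a + b + c)` over the gene's sites — the standard
#' less-biased aggregate. Sites monomorphic across both populations or
#' with fewer than 2 called diploids in either population contribute zero
#' and are excluded from the sums.
#'
#' @param genotypes,pop_map As in [allele_frequencies()].
#' @param popA,popB Population names.
#' @param gene_intervals Optional gene interval tibble; when omitted a
#'   single genome-wide estimate is returned under gene `"genome"`.
#' @return Tibble: `gene`, `pop1`, `pop2`, `n_sites` (usable sites),
#'   `fst` (NA when no usable site; raw value retained, so slightly
#'   negative estimates are possible).
#' @export
weir_cockerham_fst <- function(genotypes, pop_map, popA, popB,
                               gene_intervals = NULL) {
  comp <- wc_components(genotypes, pop_map, popA, popB)
  agg <- function(idx, gene) {
    k <- idx[comp$usable[idx]]
    tot <- sum(comp$a[k] + comp$b[k] + comp$c[k])
    tibble(gene = gene, pop1 = popA, pop2 = popB, n_sites = length(k),
           fst = if (length(k) && tot != 0) sum(comp$a[k]) / tot else NA_real_)
  }
  if (is.null(gene_intervals)) return(agg(seq_len(nrow(comp)), "genome"))
  map <- site_in_gene(genotypes, gene_intervals)
  purrr::map_dfr(gene_intervals$gene, function(g)
    agg(map$site[map$gene == g], g))
}

#' Between-population sequence divergence d_XY per gene
#'
#' Per-site `d = pA(1 - pB) + pB(1 - pA)`; per-gene d_XY sums sites over
#' the coding interval and divides by its length. Sites with an undefined
#' frequency in either population are skipped and counted.
#'
#' @inheritParams weir_cockerham_fst
#' @param gene_intervals Gene interval tibble (`gene`, `contig`, `start`,
#'   `end`, 0-based half-open).
#' @return Tibble: `gene`, `pop1`, `pop2`, `n_sites`, `n_skipped`, `dxy`.
#' @export
dxy <- function(genotypes, pop_map, popA, popB, gene_intervals) {
  fA <- allele_frequencies(genotypes, pop_map, popA)$freq
  fB <- allele_frequencies(genotypes, pop_map, popB)$freq
  d <- fA * (1 - fB) + fB * (1 - fA)
  map <- site_in_gene(genotypes, gene_intervals)
  purrr::map_dfr(seq_len(nrow(gene_intervals)), function(i) {
    g <- gene_intervals[i, ]
    idx <- map$site[map$gene == g$gene]
    vals <- d[idx]
    tibble(gene = g$gene, pop1 = popA, pop2 = popB,
           n_sites = sum(!is.na(vals)), n_skipped = sum(is.na(vals)),
           dxy = sum(vals, na.rm = TRUE) / (g$end - g$start))
  })
}

#' Flag F_ST outlier genes per comparison
#'
#' Flags genes at or above the `(1 - quantile)` empirical quantile of
#' per-gene F_ST within each population comparison (default: the largest
#' 5\%), plus an any-comparison union flag. Genes tied at the threshold
#' are all flagged.
#'
#' @param fst_table Long tibble with `gene`, `pop1`, `pop2`, `fst` (NA
#'   rows are ignored for the quantile and never flagged).
#' @param quantile Upper tail fraction (default 0.05).
#' @return `fst_table` with an `outlier` flag added, plus attribute
#'   `any_outlier`: tibble `gene`, `outlier_any`.
#' @export
fst_outliers <- function(fst_table, quantile = 0.05) {
  stopifnot(length(unique(fst_table$gene)) >= 20)
  out <- fst_table %>%
    group_by(.data$pop1, .data$pop2) %>%
    mutate(outlier = !is.na(.data$fst) &
             .data$fst >= stats::quantile(.data$fst, 1 - quantile,
                                          na.rm = TRUE)) %>%
    ungroup()
  anyf <- out %>%
    group_by(.data$gene) %>%
    summarise(outlier_any = any(.data$outlier), .groups = "drop")
  attr(out, "any_outlier") <- anyf
  out
}

#' High-frequency cave-specific variants
#'
#' Retains variants at frequency >= `threshold` in at least one cave
#' population and absent (frequency exactly 0, with at least
#' `min_called` called alleles) from the surface population.
#'
#' @param freqs Wide tibble: `contig`, `pos`, plus one alternate-allele
#'   frequency column per population (and optionally
#'   `<population>_n_called` columns for the missingness guard).
#' @param cave_populations,surface_population Column names in `freqs`.
#' @param threshold Inclusive cave-frequency threshold (default 0.8).
#' @param min_called Minimum called alleles in the surface population for
#'   "absent" to be trusted (used only when an `_n_called` column is
#'   present).
#' @return The retained rows of `freqs`.
#' @export
high_frequency_variants <- function(freqs, cave_populations,
                                    surface_population, threshold = 0.8,
                                    min_called = 2) {
  stopifnot(all(cave_populations %in% names(freqs)),
            surface_population %in% names(freqs))
  cave_hit <- Reduce(`|`, lapply(cave_populations, function(p)
    !is.na(freqs[[p]]) & freqs[[p]] >= threshold))
  surf <- freqs[[surface_population]]
  absent <- !is.na(surf) & surf == 0
  ncol_name <- paste0(surface_population, "_n_called")
  if (ncol_name %in% names(freqs))
    absent <- absent & freqs[[ncol_name]] >= min_called
  freqs[cave_hit & absent, ]
}

#' Permutation null for gene-set enrichment of binary flags
#'
#' Draws `focal_size` genes without replacement `n_perm` times from the
#' gene universe and counts how often the number of flagged genes reaches
#' the observed count; p uses the add-one (Phipson-Smyth) estimator
#' `(1 + #{null >= observed}) / (n_perm + 1)`, so it is bounded below by
#' `1/(n_perm + 1)` and converges to the hypergeometric upper tail.
#'
#' @param flags Tibble with `gene` and logical `relaxed` (or a plain
#'   logical vector).
#' @param focal_size Focal set size (conventional default 18).
#' @param observed_count Flagged genes observed in the focal set.
#' @param n_perm Number of permutations (conventional default 1000).
#' @param seed Integer seed.
#' @return List: `p`, `observed`, `null_counts` (integer vector of length
#'   `n_perm`).
#' @export
permutation_set_enrichment <- function(flags, focal_size = 18,
                                       observed_count, n_perm = 1000,
                                       seed = 1L) {
  fl <- if (is.logical(flags)) flags else flags$relaxed
  stopifnot(focal_size <= length(fl), observed_count <= focal_size)
  set.seed(substream_seed(seed, "perm"))
  null_counts <- vapply(seq_len(n_perm), function(i)
    sum(sample(fl, focal_size)), 0L)
  list(p = (1 + sum(null_counts >= observed_count)) / (n_perm + 1),
       observed = observed_count, null_counts = null_counts)
}

#' Per-gene population-genetic summary across populations
#'
#' Convenience wrapper: pi per population, Weir-Cockerham F_ST and d_XY
#' per population pair, per gene, with F_ST outlier flags.
#'
#' @param genotypes,pop_map As in [allele_frequencies()].
#' @param gene_intervals Gene interval tibble.
#' @param pairs Tibble with `pop1`, `pop2`; default all unordered pairs.
#' @param outlier_quantile Upper tail for [fst_outliers()] (applied when
#'   at least 20 genes are present).
#' @return List: `pi` (long tibble), `pairwise` (long tibble with `fst`,
#'   `dxy`, `outlier`).
#' @export
popgen_stats <- function(genotypes, pop_map, gene_intervals, pairs = NULL,
                         outlier_quantile = 0.05) {
  pops <- unique(pop_map$population)
  if (is.null(pairs)) {
    cmb <- utils::combn(pops, 2)
    pairs <- tibble(pop1 = cmb[1, ], pop2 = cmb[2, ])
  }
  pi_tbl <- purrr::map_dfr(pops, function(p)
    nucleotide_diversity(genotypes, pop_map, p, gene_intervals))
  pw <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    fst <- weir_cockerham_fst(genotypes, pop_map, pairs$pop1[i],
                              pairs$pop2[i], gene_intervals)
    dx <- dxy(genotypes, pop_map, pairs$pop1[i], pairs$pop2[i],
              gene_intervals)
    left_join(fst, select(dx, "gene", "dxy"), by = "gene")
  })
  if (length(unique(pw$gene)) >= 20) pw <- fst_outliers(pw, outlier_quantile)
  list(pi = pi_tbl, pairwise = pw)
}
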