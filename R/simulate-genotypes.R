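#' Simulate two-population diploid genotypes of controlled differentiation
#'
#' Sites are independent (no linkage — sufficient for testing estimators).
#' Per-population allele frequencies are drawn either from a
#' Balding-Nichols model around a shared ancestral frequency with a target
#' F_ST, or supplied explicitly; diploid genotypes are then binomial(2,
#' freq) draws.
#'
#' @param n_sites Number of variant sites.
#' @param sample_sizes Named integer vector, diploids per population (>= 2
#'   each).
#' @param allele_frequency_model Either
#'   `list(type = "balding_nichols", fst = F, anc_range = c(lo, hi))`
#'   (default F = 0.2, ancestral frequencies uniform on `anc_range`), or
#'   `list(type = "fixed", freq = M)` with `M` an `n_sites` x
#'   `n_populations` matrix of alternate-allele frequencies.
#' @param contig Contig name for the site table.
#' @param seed Integer seed.
#' @return List of class `genotype_sim`: `genotypes` (tibble: `contig`,
#'   `pos`, `ref`, `alt`, one integer column per individual with 0/1/2
#'   alternate-allele dosage), `pop_map` (tibble: `individual`,
#'   `population`), `truth` (list with the per-population frequency matrix
#'   and the target F_ST, `NA` for fixed frequencies).
#' @export
simulate_genotypes <- function(n_sites, sample_sizes,
                               allele_frequency_model =
                                 list(type = "balding_nichols", fst = 0.2),
                               contig = "chr1", seed = 1L) {
  stopifnot(n_sites >= 1, all(sample_sizes >= 2),
            !is.null(names(sample_sizes)))
  pops <- names(sample_sizes)
  set.seed(substream_seed(seed, "genotypes"))
  m <- allele_frequency_model
  if (identical(m$type, "fixed")) {
    freq <- as.matrix(m$freq)
    if (any(freq < 0 | freq > 1)) abort("frequencies must lie in [0, 1]")
    stopifnot(nrow(freq) == n_sites, ncol(freq) == length(pops))
    target_fst <- NA_real_
  } else if (identical(m$type, "balding_nichols")) {
    target_fst <- if (is.null(m$fst)) 0.2 else m$fst
    stopifnot(target_fst >= 0, target_fst < 1)
    rng <- if (is.null(m$anc_range)) c(0.1, 0.9) else m$anc_range
    p_anc <- runif(n_sites, rng[1], rng[2])
    freq <- vapply(pops, function(pp) {
      if (target_fst == 0) p_anc
      else stats::rbeta(n_sites,
                        p_anc * (1 - target_fst) / target_fst,
                        (1 - p_anc) * (1 - target_fst) / target_fst)
    }, numeric(n_sites))
    freq <- matrix(freq, nrow = n_sites)
  } else abort("unknown allele_frequency_model type")
  colnames(freq) <- pops

  inds <- unlist(lapply(pops, function(pp)
    sprintf("%s_i%02d", pp, seq_len(sample_sizes[[pp]]))))
  pop_map <- tibble(individual = inds,
                    population = rep(pops, times = sample_sizes))
  G <- vapply(seq_along(inds), function(j) {
    rbinom(n_sites, 2, freq[, pop_map$population[j]])
  }, integer(n_sites))
  G <- matrix(G, nrow = n_sites, dimnames = list(NULL, inds))
  sites <- tibble(contig = contig, pos = seq_len(n_sites) * 10L,
                  ref = "A", alt = "G")
  genotypes <- dplyr::bind_cols(sites, as_tibble(G))
  structure(list(genotypes = genotypes, pop_map = pop_map,
                 truth = list(freq = freq, target_fst = target_fst)),
            class = "genotype_sim")
}

#' Simulate per-gene relaxed-selection flags and a focal gene set
#'
#' Flags each gene independently as under relaxed selection with
#' probability `relaxed_fraction`, and samples a focal set (e.g. core-clock
#' orthologs) without replacement — the input shape consumed by
#' [permutation_set_enrichment()].
#'
#' @param n_genes Number of genes.
#' @param relaxed_fraction Per-gene flag probability in `[0, 1]`.
#' @param focal_set_size Size of the focal set (<= `n_genes`).
#' @param seed Integer seed.
#' @return List: `flags` (tibble `gene`, `relaxed`), `focal` (character).
#' @export
simulate_relaxed_flags <- function(n_genes, relaxed_fraction = 0.1,
                                   focal_set_size = 18, seed = 1L) {
  stopifnot(relaxed_fraction >= 0, relaxed_fraction <= 1,
            focal_set_size <= n_genes)
  set.seed(substream_seed(seed, "relaxed"))
  genes <- sprintf("g%04d", seq_len(n_genes))
  flags <- tibble(gene = genes,
                  relaxed = runif(n_genes) < relaxed_fraction)
  list(flags = flags, focal = sample(genes, focal_set_size))
}
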