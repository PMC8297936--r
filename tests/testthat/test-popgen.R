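geno_tbl <- function(G, pops, pos = NULL) {
  n <- ncol(G)
  inds <- sprintf("i%02d", seq_len(n))
  colnames(G) <- inds
  list(genotypes = dplyr::bind_cols(
         tibble::tibble(contig = "chr1",
                        pos = pos %||% seq_len(nrow(G)),
                        ref = "A", alt = "G"),
         tibble::as_tibble(G)),
       pop_map = tibble::tibble(individual = inds, population = pops))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("allele frequencies count called alleles only", {
  g <- geno_tbl(matrix(c(0, 1, 2), 1), rep("a", 3))
  af <- allele_frequencies(g$genotypes, g$pop_map, "a")
  expect_equal(af$freq, 0.5)
  expect_equal(af$n_called, 6)
  g2 <- geno_tbl(matrix(c(2, 2, 2), 1), rep("a", 3))
  expect_equal(allele_frequencies(g2$genotypes, g2$pop_map, "a")$freq, 1)
  g3 <- geno_tbl(matrix(c(NA, 0, 0, 2), 1), rep("a", 4))
  af3 <- allele_frequencies(g3$genotypes, g3$pop_map, "a")
  expect_equal(af3$freq, 2 / 6)
  g4 <- geno_tbl(matrix(rep(NA_integer_, 2), 1), rep("a", 2))
  expect_true(allele_frequencies(g4$genotypes, g4$pop_map, "a")$all_missing)
})

test_that("nucleotide diversity uses the unbiased per-site formula", {
  iv <- tibble::tibble(gene = "g1", contig = "chr1", start = 0, end = 100)
  mono <- geno_tbl(matrix(0, 3, 4), rep("a", 4))
  expect_equal(nucleotide_diversity(mono$genotypes, mono$pop_map, "a",
                                    iv)$pi, 0)
  # one site, p = 0.5 with 4 called alleles: site pi = (4/3) * 0.5
  g <- geno_tbl(matrix(c(0, 2), 1), rep("a", 2))
  out <- nucleotide_diversity(g$genotypes, g$pop_map, "a", iv)
  expect_equal(out$pi, (4 / 3) * 0.5 / 100)
  # doubling the coding length halves gene pi
  iv2 <- dplyr::mutate(iv, end = 200)
  expect_equal(nucleotide_diversity(g$genotypes, g$pop_map, "a", iv2)$pi,
               out$pi / 2)
})

test_that("Weir-Cockerham F_ST is exactly 1 for a fixed difference", {
  G <- cbind(matrix(2, 1, 5), matrix(0, 1, 5))
  g <- geno_tbl(G, rep(c("a", "b"), each = 5))
  iv <- tibble::tibble(gene = "g1", contig = "chr1", start = 0, end = 100)
  out <- weir_cockerham_fst(g$genotypes, g$pop_map, "a", "b", iv)
  expect_equal(out$fst, 1)
  # d_XY for one fixed difference in a 100-bp gene is exactly 0.01
  dx <- dxy(g$genotypes, g$pop_map, "a", "b", iv)
  expect_equal(dx$dxy, 0.01)
  # symmetry in population order
  expect_equal(dxy(g$genotypes, g$pop_map, "b", "a", iv)$dxy, 0.01)
})

test_that("estimators are invariant to site and individual order", {
  set.seed(19)
  G <- matrix(rbinom(20 * 12, 2, 0.4), 20, 12)
  g <- geno_tbl(G, rep(c("a", "b"), each = 6))
  iv <- tibble::tibble(gene = "g1", contig = "chr1", start = 0, end = 300)
  base_fst <- weir_cockerham_fst(g$genotypes, g$pop_map, "a", "b", iv)$fst
  # permute sites (positions travel with their rows, all inside the gene)
  g2 <- g$genotypes[sample(20), ]
  expect_equal(weir_cockerham_fst(g2, g$pop_map, "a", "b", iv)$fst,
               base_fst)
  # permute individuals (columns)
  cols <- c("contig", "pos", "ref", "alt",
            sample(g$pop_map$individual))
  g3 <- g$genotypes[cols]
  expect_equal(weir_cockerham_fst(g3, g$pop_map, "a", "b", iv)$fst,
               base_fst)
})

test_that("identical populations give near-zero F_ST on average", {
  set.seed(29)
  p <- runif(1000, 0.2, 0.8)
  G <- matrix(rbinom(1000 * 20, 2, rep(p, 20)), 1000, 20)
  g <- geno_tbl(G, rep(c("a", "b"), each = 10))
  comp <- cavechrono:::wc_components(g$genotypes, g$pop_map, "a", "b")
  est <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  # site-level spread gives the Monte-Carlo SE of the ratio estimate
  site_fst <- comp$a[comp$usable] / (comp$a + comp$b + comp$c)[comp$usable]
  se <- sd(site_fst) / sqrt(sum(comp$usable))
  expect_lt(abs(est), 3 * se)
})

test_that("d_XY of a population against its own copy matches heterozygosity", {
  set.seed(37)
  G <- matrix(rbinom(30 * 5, 2, 0.3), 30, 5)
  g <- geno_tbl(cbind(G, G), rep(c("a", "b"), each = 5))
  iv <- tibble::tibble(gene = "g1", contig = "chr1", start = 0, end = 50)
  p <- rowSums(G) / 10
  expected <- sum(2 * p * (1 - p)) / 50
  expect_equal(dxy(g$genotypes, g$pop_map, "a", "b", iv)$dxy, expected)
})

test_that("F_ST outlier flagging takes the top tail with ties", {
  tbl <- tibble::tibble(gene = sprintf("g%03d", 1:100), pop1 = "a",
                        pop2 = "b", fst = seq(0.01, 1, length.out = 100))
  out <- fst_outliers(tbl, 0.05)
  expect_equal(sum(out$outlier), 5)
  expect_true(all(out$gene[out$outlier] == sprintf("g%03d", 96:100)))
  tbl40 <- tibble::tibble(gene = paste0("g", 1:40), pop1 = "a", pop2 = "b",
                          fst = 1:40)
  out40 <- fst_outliers(tbl40, 0.05)
  expect_setequal(out40$gene[out40$outlier], c("g39", "g40"))
  tied <- dplyr::mutate(tbl, fst = 0.5)
  expect_true(all(fst_outliers(tied, 0.05)$outlier))
})

test_that("high-frequency cave variants require surface absence", {
  freqs <- tibble::tibble(contig = "chr1", pos = 1:4,
                          cave1 = c(0.9, 0.9, 0.7, 0.85),
                          cave2 = c(0.1, 0.2, 0.7, 0.9),
                          surface = c(0, 0.05, 0, 0))
  out <- high_frequency_variants(freqs, c("cave1", "cave2"), "surface")
  expect_equal(out$pos, c(1L, 4L))      # >= 0.8 in a cave AND surface 0
  # inclusive threshold at exactly 0.8
  f2 <- tibble::tibble(contig = "chr1", pos = 1L, cave1 = 0.8, surface = 0)
  expect_equal(nrow(high_frequency_variants(f2, "cave1", "surface")), 1)
})

test_that("permutation enrichment p converges to the hypergeometric tail", {
  flags <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                          relaxed = c(rep(TRUE, 10), rep(FALSE, 90)))
  out <- permutation_set_enrichment(flags, focal_size = 18,
                                    observed_count = 5, n_perm = 2e4,
                                    seed = 2)
  exact <- phyper(4, 10, 90, 18, lower.tail = FALSE)
  se <- sqrt(exact * (1 - exact) / 2e4)
  expect_lt(abs(out$p - exact), 3 * se + 1 / 2e4)
  # bounds of the add-one estimator
  expect_gte(out$p, 1 / (2e4 + 1))
  expect_lte(out$p, 1)
  # all genes flagged: p = 1 regardless of the observed count
  all_f <- dplyr::mutate(flags, relaxed = TRUE)
  expect_equal(permutation_set_enrichment(all_f, 18, 18, 200, seed = 1)$p, 1)
})

test_that("popgen_stats summarises pi, F_ST, d_XY per gene and pair", {
  sim <- simulate_genotypes(200, c(surface = 8, cave = 8),
                            list(type = "balding_nichols", fst = 0.2),
                            seed = 13)
  iv <- tibble::tibble(gene = sprintf("g%02d", 1:20), contig = "chr1",
                       start = seq(0, 1900, 100), end = seq(100, 2000, 100))
  st <- popgen_stats(sim$genotypes, sim$pop_map, iv)
  expect_equal(nrow(st$pi), 40)          # 20 genes x 2 populations
  expect_equal(nrow(st$pairwise), 20)
  expect_true(all(st$pi$pi >= 0))
  expect_true(all(st$pairwise$dxy >= 0, na.rm = TRUE))
  expect_true("outlier" %in% names(st$pairwise))
})
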