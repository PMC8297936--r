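test_that("promoter extraction honours window, strand, and clipping", {
  contig <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
                  collapse = "")
  genome <- c(chr1 = contig)
  ann <- tibble::tibble(gene = c("fwd", "clip", "rev"),
                        contig = "chr1", tss = c(5000, 100, 5000),
                        strand = c("+", "+", "-"))
  ps <- extract_promoters(ann, genome)
  expect_equal(ps$start[1], 4000); expect_equal(ps$end[1], 5200)
  expect_equal(nchar(ps$seq[1]), 1200)
  expect_equal(ps$seq[1], substr(contig, 4001, 5200))
  expect_false(ps$clipped[1])
  # clipped at the contig edge
  expect_equal(ps$start[2], 0); expect_equal(ps$end[2], 300)
  expect_true(ps$clipped[2])
  # minus strand: reverse complement of the mirrored window
  expect_equal(ps$start[3], 4801); expect_equal(ps$end[3], 6001)
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(substr(contig, 4802, 6001), "")[[1]]),
                     collapse = ""))
  expect_equal(ps$seq[3], rc)
  expect_error(extract_promoters(
    tibble::tibble(gene = "x", contig = "nope", tss = 1, strand = "+"),
    genome), "x")
})

test_that("variant application substitutes the population-major allele", {
  genome <- c(chr1 = strrep("ACGT", 500))
  ann <- tibble::tibble(gene = "g", contig = "chr1", tss = 1500,
                        strand = "+")
  ps <- extract_promoters(ann, genome)
  # no qualifying variant: identity
  v0 <- tibble::tibble(contig = "chr1", pos = 700, ref = "T", alt = "A",
                       freq = 0.2)
  expect_equal(apply_variants(ps, v0)$seq, ps$seq)
  # one fixed SNV: exactly one base differs
  pos <- 701                       # 1-based; base at offset 200 in window
  refb <- substr(genome[["chr1"]], pos, pos)
  v1 <- tibble::tibble(contig = "chr1", pos = pos, ref = refb, alt = "G",
                       freq = 1)
  mod <- apply_variants(ps, v1)
  diff <- which(strsplit(mod$seq, "")[[1]] != strsplit(ps$seq, "")[[1]])
  expect_equal(diff, pos - 1 - ps$start + 1)
  expect_equal(mod$n_substituted, 1L)
  # mismatching reference allele is an error
  v2 <- tibble::tibble(contig = "chr1", pos = pos, ref = "N", alt = "G",
                       freq = 1)
  expect_error(apply_variants(ps, v2), "mismatch")
})

test_that("a variant destroying a planted motif removes its scan hit", {
  lib <- motif_library()
  set.seed(33)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = "")
  cons <- lib$Ebox$consensus                  # planted at window offset 600
  w <- nchar(cons)
  genome <- c(chr1 = paste0(substr(bg, 1, 1100), cons,
                            substring(bg, 1101 + w)))
  ann <- tibble::tibble(gene = "g", contig = "chr1", tss = 1500,
                        strand = "+")
  ps <- extract_promoters(ann, genome)        # window [500, 1700)
  expect_equal(substr(ps$seq, 601, 600 + w), cons)
  hits_before <- scan_promoters(ps, lib["Ebox"])
  expect_true(any(hits_before$offset == 600))
  # SNV knocking out the core base at window offset 604 (genome pos 1105)
  pos <- 1105
  v <- tibble::tibble(contig = "chr1", pos = pos,
                      ref = substr(ps$fwd_seq, pos - ps$start,
                                   pos - ps$start),
                      alt = "T", freq = 1)
  mod <- apply_variants(ps, v)
  hits_after <- scan_promoters(mod, lib["Ebox"])
  expect_false(any(hits_after$offset == 600))
  cmp <- suppressWarnings(
    motif_presence_comparison(hits_before, hits_after, "g"))
  if (nrow(hits_after) == 0) expect_equal(cmp$losses, "g")
})

test_that("PWM construction normalizes counts with pseudocounts", {
  m <- matrix(25, 4, 3)
  p <- pwm_from_counts(m, pseudocount = 1)
  expect_equal(unname(p$prob), matrix(0.25, 4, 3))
  det <- pwm_from_counts(matrix(c(100, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(unname(det$prob[, 1]), c(1, 0, 0, 0))
  mixed <- pwm_from_counts(matrix(c(8, 2, 0, 0), 4, 1), pseudocount = 1)
  expect_equal(unname(mixed$prob[, 1]), c(8.25, 2.25, 0.25, 0.25) / 11)
  expect_error(pwm_from_counts(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 4, 2)),
               "positive count")
})

test_that("score p-value table equals brute-force word enumeration", {
  for (bg in list(rep(0.25, 4), c(0.4, 0.1, 0.1, 0.4))) {
    for (w in c(2, 4, 6)) {
      set.seed(w * 10 + round(bg[1] * 10))
      counts <- matrix(rpois(4 * w, 20) + 1, 4, w)
      pwm <- pwm_from_counts(counts, pseudocount = 1, background = bg)
      tab <- score_pvalue_table(pwm, background = bg, bins = 5000)
      words <- as.matrix(expand.grid(rep(list(1:4), w)))
      int_sums <- vapply(seq_len(nrow(words)), function(i)
        sum(tab$int_scores[cbind(words[i, ], seq_len(w))]), 0L)
      wprob <- apply(words, 1, function(b) prod(bg[b]))
      for (s in sort(unique(int_sums))) {
        expect_equal(cavechrono:::int_score_p(tab, s),
                     sum(wprob[int_sums >= s]), tolerance = 1e-12)
      }
    }
  }
})

test_that("a deterministic width-6 consensus has max-score p of 4^-6", {
  pwm <- pwm_from_counts(cavechrono:::consensus_counts("CACGTG"),
                         pseudocount = 1)
  tab <- score_pvalue_table(pwm, background = rep(0.25, 4))
  best <- sum(tab$int_scores[cbind(match(strsplit("CACGTG", "")[[1]],
                                         c("A", "C", "G", "T")), 1:6)])
  expect_equal(cavechrono:::int_score_p(tab, best), 4^-6, tolerance = 1e-9)
  # p at the minimum attainable score is 1
  worst <- sum(apply(tab$int_scores, 2, min))
  expect_equal(cavechrono:::int_score_p(tab, worst), 1)
})

test_that("scanning is strand-consistent and respects the threshold", {
  lib <- motif_library()
  pwm <- lib$RRE
  set.seed(44)
  seq0 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  planted <- paste0(substr(seq0, 1, 37), pwm$consensus,
                    substring(seq0, 38 + pwm$width))
  hits <- scan_sequence(planted, pwm, p_threshold = 1e-4)
  expect_true(any(hits$offset == 37 & hits$strand == "+"))
  # reverse complement: same hits in forward coordinates, strands swapped
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(planted, "")[[1]]), collapse = ""))
  hits_rc <- scan_sequence(rc, pwm, p_threshold = 1e-4)
  remapped <- sort(nchar(planted) - pwm$width - hits_rc$offset)
  expect_equal(sort(hits$offset), remapped)
  # a sequence shorter than the motif yields no hits
  expect_equal(nrow(scan_sequence("ACG", pwm)), 0)
  # windows containing N are skipped
  withN <- paste0(substr(planted, 1, 40), "N", substring(planted, 42))
  hitsN <- scan_sequence(withN, pwm, p_threshold = 1e-4)
  expect_false(any(hitsN$offset == 37 & hitsN$strand == "+"))
})

test_that("phase-window enrichment matches Fisher/hypergeometric logic", {
  # full-period window: degenerate margin, p = 1
  gp <- tibble::tibble(gene = letters[1:8], phase = seq(0, 21, 3))
  full <- phase_window_enrichment(gp, letters[1:4], window = 24, step = 24)
  expect_equal(full$p, 1)
  # complete separation with margins (2,2): two-sided p = 1/3
  gp2 <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        phase = c(1, 1, 13, 13))
  enr <- phase_window_enrichment(gp2, c("a", "b"), window = 6, step = 6)
  w0 <- enr[enr$window_start == 0, ]
  expect_equal(w0$p, 1/3)
  expect_equal(w0$n_motif_in, 2)
  # flagged gene without a phase is an error
  expect_error(phase_window_enrichment(gp2, "zz"), "missing")
  # Fisher agreement with direct hypergeometric summation on small tables
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(rpois(4, 6), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    f <- fisher.test(m)$p.value
    lo <- max(0, sum(m[1, ]) - (sum(m[, 2])))
    hi <- min(sum(m[1, ]), sum(m[, 1]))
    probs <- dhyper(lo:hi, sum(m[1, ]), sum(m[2, ]), sum(m[, 1]))
    direct <- sum(probs[probs <= dhyper(m[1, 1], sum(m[1, ]), sum(m[2, ]),
                                        sum(m[, 1])) * (1 + 1e-7)])
    expect_equal(f, direct, tolerance = 1e-7)
  }
})

test_that("planted phase-window enrichment is recovered", {
  lib <- motif_library()
  set.seed(55)
  gp <- tibble::tibble(gene = sprintf("g%03d", 1:120),
                       phase = runif(120, 0, 24))
  rule <- tibble::tibble(motif = "Ebox", window_start = 0, window_end = 4,
                         prob = 0.9)
  sim <- simulate_promoters(gp, lib, rule, length = 600, seed = 55)
  hits <- scan_promoters(sim$promoters, lib["Ebox"])
  enr <- phase_window_enrichment(gp, unique(hits$gene), window = 6,
                                 step = 2)
  best <- enr$window_center[which.min(enr$p)]
  expect_lte(abs(circular_phase_distance(2, best)), 3)
})

test_that("MEME round trip preserves motif probabilities", {
  lib <- motif_library()
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(lib, path)
  back <- read_meme(path)
  expect_equal(names(back), names(lib))
  expect_equal(back$Ebox$prob, lib$Ebox$prob, tolerance = 1e-3)
})
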