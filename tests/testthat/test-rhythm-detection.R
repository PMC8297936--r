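test_that("low-expression filter keeps genes at or above the total-count cut", {
  counts <- tibble::tibble(gene = c("a", "b", "c"),
                           s1 = c(25L, 50L, 75L), s2 = c(25L, 50L, 75L))
  suppressMessages({
    kept <- filter_low_expression(counts, 100)
  })
  expect_equal(kept$gene, c("b", "c"))     # 100 total is retained, 50 dropped
  expect_equal(attr(kept, "n_dropped"), 1L)
  counts99 <- tibble::tibble(gene = "x", s1 = 99L)
  suppressMessages(expect_equal(nrow(filter_low_expression(counts99, 100)), 0))
  expect_equal(filter_low_expression(counts, 0), counts, ignore_attr = TRUE)
})

test_that("reference waveforms tile the lag grid with replicate-tied values", {
  d <- sampling_design()
  wf <- reference_waveforms(d, lag_step = 4)
  expect_equal(length(unique(wf$lag)), 6)
  expect_equal(nrow(wf), 6 * 36)
  lag0 <- dplyr::filter(wf, lag == 0)
  expect_equal(lag0$CT[which.max(lag0$value)], 0)  # peak at CT0
  # replicates at one CT share the template value
  expect_equal(length(unique(lag0$value[lag0$CT == 8])), 1)
  expect_error(reference_waveforms(d, lag_step = 5), "divide")
})

test_that("kendall_tau matches hand enumeration and base R", {
  expect_equal(kendall_tau(1:4, 1:4), 1)
  expect_equal(kendall_tau(1:3, 3:1), -1)
  expect_equal(kendall_tau(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)  # C = D = 1
  set.seed(9)
  for (i in 1:10) {
    x <- sample(20, 12, replace = TRUE)
    y <- sample(20, 12, replace = TRUE)
    expect_equal(as.numeric(kendall_tau(x, y)),
                 cor(x, y, method = "kendall"))
  }
  deg <- kendall_tau(rep(1, 5), 1:5)
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
})

test_that("exact tau null equals brute-force enumeration", {
  # n = 3, tie-free: closed form
  nul3 <- exact_tau_null(3)
  expect_equal(nul3$tau, c(-1, -1/3, 1/3, 1))
  expect_equal(nul3$prob, c(1, 2, 2, 1) / 6)
  # tie-free n = 5 and n = 7 against full enumeration
  for (n in c(5, 7)) {
    bf <- brute_s_null(seq_len(n))
    ex <- exact_tau_null(n)
    expect_equal(ex$S, bf$S)
    expect_equal(ex$prob, bf$prob, tolerance = 1e-12)
  }
  # tied templates against enumeration of tie-free data
  for (sizes in list(c(2, 2, 1), c(3, 2), c(2, 2, 2))) {
    y <- rep(seq_along(sizes), times = sizes)
    bf <- brute_s_null(y)
    ex <- exact_tau_null(tie_pattern = sizes)
    expect_equal(ex$S, bf$S)
    expect_equal(ex$prob, bf$prob, tolerance = 1e-12)
  }
  # normalization holds generally
  expect_equal(sum(exact_tau_null(tie_pattern = c(6, 12, 12, 6))$prob), 1)
})

test_that("jtk_test recovers noiseless cosines and flags degenerate input", {
  d <- sampling_design()
  res <- jtk_test(cosine_series(8), d, n_null = 5e4, seed = 2)
  expect_equal(res$phase, 8)
  expect_equal(res$tau, 1)
  expect_equal(res$p, 1 / (5e4 + 1))      # minimum attainable MC p
  flat <- jtk_test(rep(7, 36), d, n_null = 1000, seed = 2)
  expect_equal(flat$p, 1)
  expect_equal(flat$amplitude, 0)
  expect_true(flat$degenerate)
})

test_that("amplitude is half the range of per-timepoint medians", {
  d <- sampling_design()
  y <- rep(c(10, 2, 2, 2, 2, 2), each = 6)
  res <- jtk_test(y, d, n_null = 1000, seed = 1)
  expect_equal(res$amplitude, 4)
  # Hodges-Lehmann flavour is available and positive for a real rhythm
  hl <- jtk_test(cosine_series(8, amplitude = 50), d, n_null = 1000,
                 amplitude_method = "hodges_lehmann", seed = 1)
  expect_gt(hl$amplitude, 0)
})

test_that("bonferroni convention gives valid, more conservative p-values", {
  d <- sampling_design()
  res <- jtk_test(cosine_series(4, amplitude = 30), d,
                  p_method = "bonferroni", seed = 3)
  expect_lt(res$p, 0.01)
  expect_equal(res$phase, 4)
  set.seed(14)
  y <- rnorm(36, 100, 5)
  pb <- jtk_test(y, d, p_method = "bonferroni", seed = 3)$p
  expect_true(pb >= 0 && pb <= 1)
})

test_that("maxstat p agrees with an independent permutation oracle", {
  d <- sampling_design()
  set.seed(31)
  y <- rnbinom(36, mu = 60, size = 8) +
    round(20 * cos(2 * pi * (d$samples$CT - 12) / 24))  # tie-bearing input
  n_oracle <- 2e4
  res <- jtk_test(y, d, n_null = n_oracle, seed = 5)
  lags <- seq(0, 20, 4)
  Y <- sapply(lags, function(l) cos(2 * pi * (d$samples$CT - l) / 24))
  obs <- max(sapply(1:6, function(l) cor(y, Y[, l], method = "kendall")))
  set.seed(77)
  null <- replicate(n_oracle, {
    yp <- sample(y)
    max(sapply(1:6, function(l) cor(yp, Y[, l], method = "kendall")))
  })
  p_oracle <- (1 + sum(null >= obs - 1e-12)) / (n_oracle + 1)
  se <- sqrt(2 * p_oracle * (1 - p_oracle) / n_oracle)
  expect_lt(abs(res$p - p_oracle), 3 * se + 1e-9)
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  # order preserved and q >= p
  set.seed(8)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_equal(order(p), order(q, p))
})

test_that("rhythmic / arrhythmic / indeterminate labels follow thresholds", {
  tbl <- tibble::tibble(p = c(0.001, 0.6, 0.2), q = c(0.04, 0.9, 0.3))
  lab <- classify_rhythmicity(tbl, 0.05, 0.5)$label
  expect_equal(as.character(lab),
               c("rhythmic", "arrhythmic", "indeterminate"))
})

test_that("rhythm_scan separates planted rhythmic from flat genes", {
  tr <- simulate_gene_truth(60, populations = "surface",
                            rhythmic_fraction = 0.5, amplitude = 1,
                            dispersion = 0.05, seed = 17)
  sim <- simulate_expression(tr, seed = 17)
  scan <- rhythm_scan(sim$counts, sim$meta, n_null = 2e4, seed = 17)
  res <- dplyr::inner_join(tidy(scan), tr, by = c("gene", "population"))
  sens <- mean(res$label[res$rhythmic] == "rhythmic")
  expect_gte(sens, 0.9)
  fp <- mean(res$label[!res$rhythmic] == "rhythmic")
  expect_lte(fp, 0.1)
  # phase of detected genes within one lag step of truth
  det <- res[res$rhythmic & res$label == "rhythmic", ]
  err <- abs(circular_phase_distance(det$phase.y, det$phase.x))
  expect_gte(mean(err <= 4 + 1e-9), 0.9)
  # tidy/glance accessors
  expect_s3_class(tidy(scan), "tbl_df")
  expect_equal(glance(scan)$n_genes, 60L)
})

test_that("increasing planted amplitude does not decrease median |tau|", {
  med_tau <- sapply(c(0.25, 0.5, 1), function(a) {
    tr <- simulate_gene_truth(40, populations = "surface",
                              rhythmic_fraction = 1, amplitude = a,
                              dispersion = 0.05, seed = 23)
    sim <- simulate_expression(tr, seed = 23)
    scan <- rhythm_scan(sim$counts, sim$meta, n_null = 500, seed = 23)
    median(abs(tidy(scan)$tau))
  })
  expect_true(all(diff(med_tau) >= -1e-9))
})
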