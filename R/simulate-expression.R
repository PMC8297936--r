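#' Build a per-gene, per-population truth table for simulation
#'
#' Convenience constructor for the truth table consumed by
#' [simulate_expression()]. Each gene gets, per population, a rhythmic flag,
#' a baseline log-mean, a cosine amplitude (log scale, half peak-to-trough),
#' a peak phase (hours) and a negative-binomial dispersion. Population-level
#' effects emulate the comparative design: a set of genes can lose
#' rhythmicity (amplitude set to 0) in chosen populations, and whole
#' populations can have their phases delayed.
#'
#' @param n_genes Number of genes.
#' @param populations Character vector of population names; the first is the
#'   reference (surface) population.
#' @param rhythmic_fraction Fraction of genes rhythmic in the reference.
#' @param amplitude Cosine amplitude (log units) of rhythmic genes.
#' @param baseline_range Range of per-gene baseline log-means (natural log).
#' @param dispersion Negative-binomial dispersion (variance = mu + d mu^2).
#' @param loss_fraction Fraction of the reference-rhythmic genes that lose
#'   rhythmicity (amplitude 0) in every population listed in
#'   `loss_populations`.
#' @param loss_populations Populations in which the loss genes are flat;
#'   defaults to all non-reference populations.
#' @param phase_delay Named numeric vector, hours added to every rhythmic
#'   phase of the named populations (circular).
#' @param period Period in hours.
#' @param seed Integer seed.
#' @return A tibble with columns `gene`, `population`, `rhythmic`,
#'   `baseline`, `amplitude`, `phase`, `dispersion`, plus attributes
#'   `loss_genes` and `reference`.
#' @export
simulate_gene_truth <- function(n_genes, populations = c("surface", "cave"),
                                rhythmic_fraction = 0.3, amplitude = 1,
                                baseline_range = c(4, 7), dispersion = 0.05,
                                loss_fraction = 0, loss_populations = NULL,
                                phase_delay = NULL, period = 24, seed = 1L) {
  stopifnot(n_genes >= 1, rhythmic_fraction >= 0, rhythmic_fraction <= 1,
            loss_fraction >= 0, loss_fraction <= 1)
  set.seed(substream_seed(seed, "truth"))
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_r <- round(rhythmic_fraction * n_genes)
  rhythmic <- c(rep(TRUE, n_r), rep(FALSE, n_genes - n_r))
  baseline <- runif(n_genes, baseline_range[1], baseline_range[2])
  phase <- ifelse(rhythmic, runif(n_genes, 0, period), 0)
  ref <- populations[1]
  if (is.null(loss_populations)) loss_populations <- setdiff(populations, ref)
  loss_genes <- sample(genes[rhythmic], round(loss_fraction * n_r))

  truth <- tidyr::expand_grid(gene = genes, population = populations) %>%
    left_join(tibble(gene = genes, rhythmic = rhythmic, baseline = baseline,
                     phase = phase),
              by = "gene") %>%
    mutate(
      lost = .data$gene %in% loss_genes & .data$population %in% loss_populations,
      rhythmic = .data$rhythmic & !.data$lost,
      amplitude = ifelse(.data$rhythmic, amplitude, 0),
      phase = ifelse(.data$rhythmic, .data$phase, 0),
      dispersion = dispersion
    )
  if (!is.null(phase_delay)) {
    for (p in names(phase_delay)) {
      idx <- truth$population == p & truth$rhythmic
      truth$phase[idx] <- (truth$phase[idx] + phase_delay[[p]]) %% period
    }
  }
  truth <- select(truth, "gene", "population", "rhythmic", "baseline",
                  "amplitude", "phase", "dispersion")
  attr(truth, "loss_genes") <- loss_genes
  attr(truth, "reference") <- ref
  truth
}

#' Simulate a circadian RNA-seq count matrix
#'
#' Draws negative-binomial counts whose log-means follow per-gene,
#' per-population cosine signals:
#' \deqn{\mu_{g,s} = \exp(b_g + A_g \cos(2\pi (t_s - \phi_g)/T))}
#' with variance \eqn{\mu + d\,\mu^2}. Identical `(seed, truth, design)`
#' reproduce identical matrices.
#'
#' @param truth Truth table as from [simulate_gene_truth()]: one row per
#'   gene per population with columns `gene`, `population`, `rhythmic`,
#'   `baseline`, `amplitude`, `phase`, `dispersion`.
#' @param design A [sampling_design()]; the default design is used when
#'   omitted.
#' @param seed Integer seed.
#' @return A list of class `expression_sim` with elements `counts` (tibble,
#'   `gene` column plus one integer column per sample), `meta` (tibble:
#'   `sample`, `population`, `CT`, `replicate`) and `truth`.
#' @examples
#' tr <- simulate_gene_truth(20, seed = 7)
#' sim <- simulate_expression(tr, seed = 7)
#' sim$counts[1:3, 1:4]
#' @export
simulate_expression <- function(truth, design = sampling_design(), seed = 1L) {
  stopifnot(inherits(design, "sampling_design"))
  need <- c("gene", "population", "baseline", "amplitude", "phase", "dispersion")
  if (!all(need %in% names(truth)))
    abort(paste("truth table must have columns:", paste(need, collapse = ", ")))
  bad <- !stats::complete.cases(truth[need]) |
    !is.finite(truth$baseline) | !is.finite(truth$amplitude) |
    !is.finite(truth$phase) | !is.finite(truth$dispersion)
  if (any(bad))
    abort(paste("non-finite truth parameters for gene(s):",
                paste(unique(truth$gene[bad]), collapse = ", ")))
  if (any(truth$dispersion < 0)) abort("dispersions must be >= 0")
  if (any(truth$amplitude < 0)) abort("amplitudes must be >= 0")

  set.seed(substream_seed(seed, "expression"))
  period <- design$period
  pops <- unique(truth$population)
  meta <- purrr::map_dfr(pops, function(p) {
    design$samples %>%
      mutate(population = p,
             sample = paste0(p, "_", .data$sample)) %>%
      select("sample", "population", "CT", "replicate")
  })

  genes <- unique(truth$gene)
  counts <- matrix(0L, nrow = length(genes), ncol = nrow(meta),
                   dimnames = list(genes, meta$sample))
  for (p in pops) {
    tr_p <- truth[truth$population == p, ]
    tr_p <- tr_p[match(genes, tr_p$gene), ]
    smp <- meta$population == p
    t_s <- meta$CT[smp]
    mu <- exp(outer(tr_p$baseline, rep(1, sum(smp))) +
                tr_p$amplitude * cos(2 * pi * outer(tr_p$phase, t_s, function(ph, t) (t - ph)) / period))
    size <- ifelse(tr_p$dispersion > 0, 1 / tr_p$dispersion, Inf)
    draw <- matrix(rnbinom(length(mu), mu = mu,
                           size = rep(size, times = sum(smp))),
                   nrow = length(genes))
    counts[, smp] <- draw
  }
  counts_tbl <- as_tibble(counts, rownames = "gene")
  structure(list(counts = counts_tbl, meta = meta, truth = truth),
            class = "expression_sim")
}

#' @export
print.expression_sim <- function(x, ...) {
  cat(sprintf("<expression_sim> %d genes x %d samples (%d population(s))\n",
              nrow(x$counts), nrow(x$meta), length(unique(x$meta$population))))
  invisible(x)
}
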