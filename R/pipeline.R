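#' Assemble and validate a pipeline configuration
#'
#' Collects every stage's tunable parameters with their conventional
#' defaults (one 24-h cycle sampled every 4 h, low-expression cut 100
#' total reads, rhythmic FDR 0.05, arrhythmic p > 0.5, promoter window
#' -1000/+200, motif scan p < 1e-4, 6-h/2-h enrichment windows, top-5%
#' F_ST outliers, cave-frequency threshold 0.8, 18-gene focal set with
#' 1000 permutations) plus either a `simulation` block or an `inputs`
#' block of file paths.
#'
#' @param simulation Named list passed to the simulators (see
#'   [run_pipeline()]); mutually exclusive with `inputs`.
#' @param inputs Named list of paths: `counts`, `meta` (TSV as written by
#'   [write_counts_tsv()] / [write_meta_tsv()]).
#' @param reference Reference (surface) population name.
#' @param period,lag_step,min_total,fdr,arrhythmic_p,upstream,downstream
#'   Stage parameters (hours / counts / probabilities).
#' @param motif_p,enrich_window,enrich_step,outlier_quantile,hf_threshold
#'   Stage parameters.
#' @param focal_size,n_perm Permutation-test parameters.
#' @param p_method Rhythm-test p-value convention (see [rhythm_scan()]);
#'   the pipeline defaults to the classical `"bonferroni"` convention,
#'   whose conservative p-values (with an atom at 1) are what the
#'   arrhythmic `p > 0.5` call and the `p < 1` S_DR inclusion rule
#'   presuppose.
#' @param n_null Monte-Carlo null size for the `"maxstat"` rhythm test.
#' @param seed Master seed; every stage derives a named substream from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            reference = "surface", period = 24,
                            lag_step = 4, min_total = 100, fdr = 0.05,
                            arrhythmic_p = 0.5, upstream = 1000,
                            downstream = 200, motif_p = 1e-4,
                            enrich_window = 6, enrich_step = 2,
                            outlier_quantile = 0.05, hf_threshold = 0.8,
                            focal_size = 18, n_perm = 1000,
                            p_method = c("bonferroni", "maxstat"),
                            n_null = 1e5, seed = 1L) {
  p_method <- match.arg(p_method)
  if (is.null(simulation) && is.null(inputs))
    abort("either a `simulation` block or an `inputs` block is required")
  stopifnot(period > 0, lag_step > 0, min_total >= 0,
            fdr > 0, fdr < 1, arrhythmic_p > 0, arrhythmic_p <= 1,
            motif_p > 0, motif_p < 1, enrich_window <= period,
            outlier_quantile > 0, outlier_quantile < 1,
            hf_threshold >= 0, hf_threshold <= 1, focal_size >= 1,
            n_perm >= 1)
  sim_defaults <- list(n_genes = 300, populations = c("surface", "cave"),
                       rhythmic_fraction = 0.3, amplitude = 1,
                       dispersion = 0.05, loss_fraction = 0.3,
                       phase_delay = NULL, n_sites = 400,
                       samples_per_population = 10, target_fst = 0.2,
                       relaxed_fraction = 0.1, plant_prob = 0.9)
  if (!is.null(simulation))
    simulation <- utils::modifyList(sim_defaults, simulation)
  structure(list(simulation = simulation, inputs = inputs,
                 reference = reference, period = period,
                 lag_step = lag_step, min_total = min_total, fdr = fdr,
                 arrhythmic_p = arrhythmic_p, upstream = upstream,
                 downstream = downstream, motif_p = motif_p,
                 enrich_window = enrich_window, enrich_step = enrich_step,
                 outlier_quantile = outlier_quantile,
                 hf_threshold = hf_threshold, focal_size = focal_size,
                 n_perm = n_perm, p_method = p_method, n_null = n_null,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

default_planting_rule <- function() {
  tibble(motif = c("Ebox", "RRE", "Dbox"),
         window_start = c(0, 12, 0), window_end = c(4, 18, 6),
         prob = c(0.9, 0.9, 0.9))
}

#' Run the full comparative circadian pipeline
#'
#' Orchestrates the stages end to end from one configuration: (optional)
#' simulation of all inputs, low-expression filtering, per-population
#' rhythm detection and classification, differential rhythmicity per
#' reference-vs-other pair, loss sets, phase-shift analysis, promoter
#' motif scanning with phase-window enrichment and cross-population motif
#' presence comparison, and per-gene population-genetic summaries with
#' outlier flags, high-frequency cave variants, and the
#' relaxed-selection permutation test. One TSV per stage plus a JSON
#' summary (embedding the resolved configuration and seed) are written to
#' `out_dir`; identical configuration and seed reproduce byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main stage results and the summary.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name) message(format(Sys.time(), "%H:%M:%S"),
                                  " stage: ", name)
  truth_bundle <- list()

  ## ---- inputs -------------------------------------------------------
  if (!is.null(config$simulation)) {
    stage("simulate")
    sm <- config$simulation
    delay <- sm$phase_delay
    if (!is.null(delay)) delay <- unlist(delay)
    truth <- simulate_gene_truth(
      n_genes = sm$n_genes, populations = sm$populations,
      rhythmic_fraction = sm$rhythmic_fraction, amplitude = sm$amplitude,
      dispersion = sm$dispersion, loss_fraction = sm$loss_fraction,
      phase_delay = delay, period = config$period,
      seed = substream_seed(seed, "truth"))
    sim <- simulate_expression(truth, sampling_design(period = config$period),
                               seed = substream_seed(seed, "expr"))
    counts <- sim$counts; meta <- sim$meta
    truth_bundle$expression <- truth
    write_counts_tsv(counts, file.path(out_dir, "counts.tsv"))
    write_meta_tsv(meta, file.path(out_dir, "meta.tsv"))
  } else {
    stage("load")
    counts <- read_counts_tsv(config$inputs$counts)
    meta <- read_meta_tsv(config$inputs$meta)
  }
  ref <- config$reference
  pops <- unique(meta$population)
  if (!ref %in% pops) abort(paste("reference population", ref,
                                  "not present in metadata"))
  others <- setdiff(pops, ref)

  ## ---- rhythm detection --------------------------------------------
  stage("rhythm")
  scan <- rhythm_scan(counts, meta, period = config$period,
                      lag_step = config$lag_step,
                      min_total = config$min_total, fdr = config$fdr,
                      arrhythmic_p = config$arrhythmic_p,
                      p_method = config$p_method, n_null = config$n_null,
                      seed = substream_seed(seed, "rhythm"))
  rhythm <- tidy(scan)
  write_tsv_plain(rhythm, file.path(out_dir, "rhythm.tsv"))

  ## ---- differential rhythmicity ------------------------------------
  stage("sdr")
  ref_tbl <- filter(rhythm, .data$population == ref)
  # pop1 = cave, pop2 = reference: positive S_DR = more rhythmic in the
  # reference, so the headline set is the upper tail
  sdr_all <- purrr::map_dfr(others, function(pop) {
    sdr_scores(filter(rhythm, .data$population == .env$pop), ref_tbl) %>%
      sdr_pvalues()
  })
  write_tsv_plain(sdr_all, file.path(out_dir, "sdr.tsv"))
  sets <- loss_sets(rhythm, reference = ref)
  membership <- tibble(
    set = rep(names(sets), lengths(sets)),
    gene = unlist(sets, use.names = FALSE))
  write_tsv_plain(membership, file.path(out_dir, "loss_sets.tsv"))

  ## ---- phase analysis ----------------------------------------------
  stage("phase")
  shifts <- purrr::map_dfr(others, function(pop) {
    res <- tryCatch(
      phase_shift_test(ref_tbl,
                       filter(rhythm, .data$population == .env$pop),
                       period = config$period),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    mutate(res$summary, pop1 = ref, pop2 = pop)
  })
  hist_tbl <- purrr::map_dfr(pops, function(pop)
    mutate(phase_histogram(filter(rhythm, .data$population == .env$pop),
                           bin_width = config$lag_step,
                           period = config$period),
           population = pop))
  write_tsv_plain(hist_tbl, file.path(out_dir, "phase_histogram.tsv"))
  if (nrow(shifts))
    write_tsv_plain(shifts, file.path(out_dir, "phase_shifts.tsv"))

  ## ---- motif analysis ----------------------------------------------
  stage("motif")
  lib <- motif_library()
  motif_out <- NULL
  if (!is.null(config$simulation)) {
    # generator: promoters planted from the reference population's truth
    ref_truth <- filter(truth_bundle$expression,
                        .data$population == ref, .data$rhythmic)
    plant <- default_planting_rule()
    plant$prob <- config$simulation$plant_prob
    prom <- simulate_promoters(
      select(ref_truth, "gene", "phase"), lib, plant,
      length = config$upstream + config$downstream,
      period = config$period, seed = substream_seed(seed, "prom"))
    write_fasta(prom$promoters, file.path(out_dir, "promoters.fasta"))
    write_tsv_plain(prom$truth, file.path(out_dir, "promoter_truth.tsv"))

    hits <- scan_promoters(prom$promoters, lib, config$motif_p)
    write_tsv_plain(hits, file.path(out_dir, "motif_hits.tsv"))
    est_phase <- filter(rhythm, .data$population == ref,
                        .data$q < 2 * config$fdr) %>%
      select("gene", "phase")
    enr <- purrr::map_dfr(names(lib), function(m) {
      targets <- intersect(unique(hits$gene[hits$motif == m]),
                           est_phase$gene)
      if (length(targets) < 2) return(NULL)
      mutate(phase_window_enrichment(est_phase, targets,
                                     window = config$enrich_window,
                                     step = config$enrich_step,
                                     period = config$period),
             motif = m)
    })
    if (nrow(enr))
      write_tsv_plain(enr, file.path(out_dir, "motif_enrichment.tsv"))
    motif_out <- list(hits = hits, enrichment = enr,
                      n_planted = nrow(prom$truth))
  }

  ## ---- population genetics -----------------------------------------
  stage("popgen")
  popgen_out <- NULL
  if (!is.null(config$simulation)) {
    sm <- config$simulation
    gsim <- simulate_genotypes(
      sm$n_sites,
      setNames(rep(sm$samples_per_population, 2), c(ref, others[1])),
      list(type = "balding_nichols", fst = sm$target_fst),
      seed = substream_seed(seed, "geno"))
    write_vcf(gsim$genotypes, file.path(out_dir, "variants.vcf"))
    write_popmap_tsv(gsim$pop_map, file.path(out_dir, "pop_map.tsv"))
    genes <- unique(counts$gene)
    sites_per_gene <- max(1, floor(sm$n_sites / length(genes)))
    span <- 10 * sites_per_gene
    intervals <- tibble(gene = genes, contig = "chr1",
                        start = (seq_along(genes) - 1) * span,
                        end = seq_along(genes) * span)
    write_bed_genes(intervals, file.path(out_dir, "genes.bed"))
    stats <- popgen_stats(gsim$genotypes, gsim$pop_map, intervals,
                          outlier_quantile = config$outlier_quantile)
    write_tsv_plain(stats$pi, file.path(out_dir, "popgen_pi.tsv"))
    write_tsv_plain(stats$pairwise, file.path(out_dir, "popgen_pairwise.tsv"))
    freqs <- tibble(contig = gsim$genotypes$contig, pos = gsim$genotypes$pos)
    for (p in c(ref, others[1])) {
      af <- allele_frequencies(gsim$genotypes, gsim$pop_map, p)
      freqs[[p]] <- af$freq
      freqs[[paste0(p, "_n_called")]] <- af$n_called
    }
    hf <- high_frequency_variants(freqs, others[1], ref,
                                  threshold = config$hf_threshold)
    write_tsv_plain(hf, file.path(out_dir, "hf_variants.tsv"))
    rf <- simulate_relaxed_flags(length(genes), sm$relaxed_fraction,
                                 config$focal_size,
                                 seed = substream_seed(seed, "relax"))
    observed <- sum(rf$flags$relaxed[rf$flags$gene %in% rf$focal])
    perm <- permutation_set_enrichment(rf$flags, config$focal_size,
                                       observed, config$n_perm,
                                       seed = substream_seed(seed, "permtest"))
    popgen_out <- list(stats = stats, hf = hf,
                       perm = list(p = perm$p, observed = observed))
  }

  ## ---- summary ------------------------------------------------------
  stage("summary")
  summary <- list(
    config = unclass(config)[setdiff(names(config), "inputs")],
    seed = seed,
    rhythmic_per_population = as.list(setNames(
      glance(scan)$n_rhythmic, glance(scan)$population)),
    loss_set_sizes = lapply(sets, base::length),
    top_sdr_genes = utils::head(
      arrange(sdr_all, dplyr::desc(.data$S_DR))$gene, 10),
    phase_shift = if (nrow(shifts))
      lapply(seq_len(nrow(shifts)), function(i) as.list(shifts[i, ]))
      else NULL,
    motif = if (!is.null(motif_out))
      list(n_hits = nrow(motif_out$hits),
           n_planted = motif_out$n_planted) else NULL,
    popgen = if (!is.null(popgen_out))
      list(n_outliers = sum(popgen_out$stats$pairwise$outlier %||% FALSE),
           n_hf_variants = nrow(popgen_out$hf),
           permutation_p = popgen_out$perm$p) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(rhythm = scan, sdr = sdr_all, loss_sets = sets,
                 phase_shifts = shifts, motif = motif_out,
                 popgen = popgen_out, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
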