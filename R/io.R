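# Format adapters. Counts/metadata/gene tables are TSV; sequences FASTA
# (via Biostrings); variants VCF (read via vcfR, written as minimal
# uncompressed VCF text); motifs MEME format (motif-pwm.R); reports JSON.

#' Write / read a gene-by-sample counts table as TSV
#'
#' @param counts Tibble with `gene` plus integer sample columns.
#' @param path File path.
#' @return `path` (write) or the counts tibble (read).
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (!"gene" %in% names(df)) abort("counts TSV must have a `gene` column")
  smp <- setdiff(names(df), "gene")
  for (cn in smp) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad))
      abort(sprintf("non-integer count at row %d, column '%s'",
                    bad[1], cn))
    df[[cn]] <- as.integer(v)
  }
  as_tibble(df)
}

#' Write / read sample metadata TSV (sample, population, CT, replicate)
#' @param meta Metadata tibble.
#' @param path File path.
#' @export
write_meta_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_tsv
#' @export
read_meta_tsv <- function(path) {
  df <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  need <- c("sample", "population", "CT", "replicate")
  if (!all(need %in% names(df)))
    abort(paste("metadata TSV must have columns:",
                paste(need, collapse = ", ")))
  df
}

#' Write / read FASTA sequence sets
#'
#' @param seqs Named character vector, or a tibble with `gene` and `seq`.
#' @param path File path.
#' @return Named character vector (read) or `path` (write).
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$gene)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write / read a BED-like gene interval table
#'
#' Columns contig, start, end, gene (0-based half-open intervals), tab
#' separated, no header — the BED convention.
#' @param genes Tibble: `gene`, `contig`, `start`, `end`.
#' @param path File path.
#' @export
write_bed_genes <- function(genes, path) {
  utils::write.table(genes[c("contig", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_genes
#' @export
read_bed_genes <- function(path) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("contig", "start", "end", "gene"))
  as_tibble(df)[c("gene", "contig", "start", "end")]
}

#' Write a genotype table as a minimal uncompressed VCF
#'
#' Diploid GT fields (`0/0`, `0/1`, `1/1`, `./.`), one column per
#' individual.
#'
#' @param genotypes Genotype tibble (see [simulate_genotypes()]).
#' @param path File path.
#' @export
write_vcf <- function(genotypes, path) {
  inds <- setdiff(names(genotypes), c("contig", "pos", "ref", "alt"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", inds),
                     collapse = "\t")), con)
  G <- as.matrix(genotypes[inds])
  body <- vapply(seq_len(nrow(genotypes)), function(i) {
    gts <- ifelse(is.na(G[i, ]), "./.", gt_code[as.character(G[i, ])])
    paste(c(genotypes$contig[i], genotypes$pos[i], ".", genotypes$ref[i],
            genotypes$alt[i], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a genotype dosage table
#'
#' Parses diploid GT fields into 0/1/2 alternate-allele dosage (`NA` for
#' missing) via vcfR.
#'
#' @param path VCF path.
#' @return Genotype tibble: `contig`, `pos`, `ref`, `alt`, one column per
#'   individual.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- function(g) {
    g <- sub("\\|", "/", g)
    ifelse(is.na(g) | g %in% c("./.", "."), NA_integer_,
           vapply(strsplit(g, "/"), function(a)
             sum(as.integer(a)), integer(1)))
  }
  G <- apply(gt, 2, dose)
  G <- matrix(G, nrow = nrow(gt), dimnames = dimnames(gt))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dplyr::bind_cols(tibble(contig = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT),
                   as_tibble(G))
}

#' Write / read a population map TSV (individual, population)
#' @param pop_map Tibble: `individual`, `population`.
#' @param path File path.
#' @export
write_popmap_tsv <- function(pop_map, path) {
  utils::write.table(pop_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_popmap_tsv
#' @export
read_popmap_tsv <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              colClasses = "character"))
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
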