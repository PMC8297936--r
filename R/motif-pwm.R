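DNA <- c("A", "C", "G", "T")

#' Build a position weight matrix from base counts
#'
#' Converts a 4 x width count matrix (rows A, C, G, T) into per-position
#' probabilities with a background-weighted pseudocount:
#' `(count + pseudocount * background) / (colsum + pseudocount)`.
#'
#' @param count_matrix Numeric 4 x width matrix of non-negative counts;
#'   rows in A, C, G, T order (row names optional but checked when
#'   present).
#' @param pseudocount Total pseudocount distributed by `background`.
#' @param background Background base composition (A, C, G, T); uniform by
#'   default.
#' @param name Optional motif name.
#' @return A `pwm` object: list with `name`, `width`, `prob` (4 x width),
#'   `background`, `pseudocount`, `consensus`.
#' @examples
#' pwm_from_counts(matrix(c(8, 2, 0, 0), 4, 1), pseudocount = 1)
#' @export
pwm_from_counts <- function(count_matrix, pseudocount = 1,
                            background = rep(0.25, 4), name = "motif") {
  count_matrix <- as.matrix(count_matrix)
  stopifnot(nrow(count_matrix) == 4, all(count_matrix >= 0),
            length(background) == 4, all(background > 0))
  if (!is.null(rownames(count_matrix)) &&
      !identical(toupper(rownames(count_matrix)), DNA))
    abort("count matrix rows must be in A, C, G, T order")
  if (any(colSums(count_matrix) == 0))
    abort("every column must have at least one positive count")
  background <- background / sum(background)
  prob <- sweep(count_matrix + pseudocount * background, 2,
                colSums(count_matrix) + pseudocount, "/")
  dimnames(prob) <- list(DNA, NULL)
  structure(list(name = name, width = ncol(prob), prob = prob,
                 background = background, pseudocount = pseudocount,
                 consensus = paste(DNA[apply(prob, 2, which.max)],
                                   collapse = "")),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s\n",
              x$name, x$width, x$consensus))
  invisible(x)
}

# counts matrix for a consensus string: `strong` for the consensus base,
# `weak` elsewhere (IUPAC codes R,Y,W,S,K,M,N split the strong count)
consensus_counts <- function(consensus, strong = 91, weak = 3) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
                K = c("G", "T"), M = c("A", "C"), N = DNA)
  chars <- strsplit(toupper(consensus), "")[[1]]
  m <- vapply(chars, function(ch) {
    bases <- iupac[[ch]]
    col <- rep(weak, 4)
    col[match(bases, DNA)] <- strong / length(bases) + weak
    col
  }, numeric(4))
  rownames(m) <- DNA
  m
}

#' Built-in circadian cis-element motif models
#'
#' Consensus-derived PWMs for the three canonical clock cis-elements:
#' the E-box (CLOCK-ARNTL binding, with one informative flank on each side
#' of the CACGTG core), the RRE (ROR/NR1D accessory-loop element) and the
#' D-box (bZip factors such as NFIL3/DBP). Widths are >= 8 so that a
#' perfect match can clear the conventional scan threshold of p < 1e-4
#' under a uniform background (a 6-bp consensus cannot: its best attainable
#' p is 4^-6, about 2.4e-4). These are test-grade stand-ins; production
#' scans should supply PWMs in MEME format via [read_meme()].
#'
#' @return Named list of `pwm` objects (`Ebox`, `RRE`, `Dbox`).
#' @export
motif_library <- function() {
  cons <- c(Ebox = "GCACGTGC", RRE = "AAWNTAGGTCA", Dbox = "TTATGTAA")
  purrr::imap(as.list(cons), function(cs, nm)
    pwm_from_counts(consensus_counts(cs), pseudocount = 1, name = nm))
}

#' Read motifs from a MEME-format file
#'
#' Parses minimal MEME motif format (letter-probability matrices) into
#' `pwm` objects.
#'
#' @param path File path.
#' @param pseudocount Pseudocount applied when re-normalizing (guards
#'   against zero probabilities).
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 1) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s+", lines)
  if (!length(starts)) abort("no MOTIF records found")
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  out <- lapply(starts, function(i) {
    name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[i:length(lines)])[1] + i - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    # scale to large pseudo-observations so the pseudocount barely
    # perturbs the stored probabilities while still removing zeros
    pwm_from_counts(t(m) * 1e4, pseudocount = pseudocount, background = bg,
                    name = name)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write motifs to a MEME-format file
#'
#' @param pwms A `pwm` object or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3],
                       bg[4]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       p$width), con)
    for (j in seq_len(p$width))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", p$prob[1, j], p$prob[2, j],
                         p$prob[3, j], p$prob[4, j]), con)
    writeLines("", con)
  }
  invisible(path)
}
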