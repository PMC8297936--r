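#' Circadian sampling design
#'
#' Describes the time-course layout shared by the simulator and the rhythm
#' test: circadian times (CT, hours) at which samples were taken, the number
#' of replicates per timepoint, and the period of the cycle. The default is
#' the standard one-cycle design: 6 timepoints every 4 h over a 24-h cycle,
#' 6 replicates each.
#'
#' @param timepoints Numeric vector of circadian times in hours; strictly
#'   increasing, all in `[0, period)`.
#' @param replicates Positive integer, replicates per timepoint.
#' @param period Cycle length in hours.
#' @return A `sampling_design` object (list with `timepoints`, `replicates`,
#'   `period`, and a `samples` tibble with one row per sample).
#' @examples
#' d <- sampling_design()
#' d$samples
#' @export
sampling_design <- function(timepoints = seq(0, 20, by = 4), replicates = 6,
                            period = 24) {
  stopifnot(is.numeric(timepoints), length(timepoints) >= 2,
            is.numeric(replicates), length(replicates) == 1, replicates >= 1,
            is.numeric(period), period > 0)
  if (any(diff(timepoints) <= 0))
    abort("`timepoints` must be strictly increasing")
  if (any(timepoints < 0 | timepoints >= period))
    abort("`timepoints` must lie in [0, period)")
  replicates <- as.integer(replicates)
  samples <- tidyr::expand_grid(CT = timepoints,
                                replicate = seq_len(replicates)) %>%
    mutate(sample = sprintf("CT%02g_r%d", .data$CT, .data$replicate)) %>%
    select("sample", "CT", "replicate")
  structure(list(timepoints = timepoints, replicates = replicates,
                 period = period, samples = samples),
            class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf("<sampling_design> %d timepoints x %d replicates, period %g h\n",
              length(x$timepoints), x$replicates, x$period))
  cat("  CT:", paste(x$timepoints, collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(design) length(design$timepoints) * design$replicates

# Derive a reproducible 31-bit substream seed from a master seed and a
# stage label, so each pipeline stage gets independent randomness.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
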