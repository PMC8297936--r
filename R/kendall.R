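#' Kendall's tau-b rank correlation
#'
#' Tau-b between two equal-length sequences:
#' \eqn{\tau_b = (C - D)/\sqrt{(n_0 - T_x)(n_0 - T_y)}} with
#' \eqn{n_0 = n(n-1)/2} and tie terms \eqn{T = \sum t(t-1)/2} over tied
#' groups. This is the correlation the rhythm test is built on; base R's
#' `cor(..., method = "kendall")` is used as an independent cross-check in
#' the test suite, never as the implementation.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Tau-b in `[-1, 1]`. When either vector is entirely tied the
#'   statistic is undefined; 0 is returned with attribute
#'   `degenerate = TRUE`.
#' @examples
#' kendall_tau(1:4, c(2, 1, 4, 3))
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  s <- sum(sx[up] * sy[up])
  n0 <- sum(up)
  tx <- sum(sx[up] == 0)
  ty <- sum(sy[up] == 0)
  if (tx == n0 || ty == n0)
    return(structure(0, degenerate = TRUE))
  s / sqrt((n0 - tx) * (n0 - ty))
}

# Null probability mass of the Mann-Whitney U(m, n) statistic
# (u = 0..m*n), i.e. normalized Gaussian-binomial coefficients of
# [m+n choose n]_q. Exact in doubles for the sizes used here.
mw_dist <- function(m, n) {
  coef <- 1
  for (i in seq_len(n)) {
    # multiply by (1 - q^(m+i))
    len <- length(coef)
    up <- c(coef, numeric(m + i)) - c(numeric(m + i), coef)
    # exact divide by (1 - q^i): c'[k] = up[k] + c'[k-i]
    out <- numeric(length(up))
    for (k in seq_along(up)) {
      out[k] <- up[k] + if (k > i) out[k - i] else 0
    }
    coef <- out[seq_len(len + m)]
  }
  coef / sum(coef)
}

# Exact null pmf of the Jonckheere-Terpstra statistic for ordered groups of
# the given sizes: the convolution of successive Mann-Whitney nulls.
jt_dist <- function(group_sizes) {
  stopifnot(all(group_sizes >= 1))
  pmf <- 1
  cum <- group_sizes[1]
  for (g in group_sizes[-1]) {
    pmf <- as.vector(stats::convolve(pmf, rev(mw_dist(cum, g)), type = "open"))
    cum <- cum + g
  }
  pmf[pmf < 0] <- 0   # convolve() round-off
  pmf / sum(pmf)
}

#' Exact null distribution of Kendall's S against a (possibly tied) template
#'
#' Distribution of \eqn{S = C - D} between a tie-free data vector and a
#' fixed template with tied groups of the given sizes, under uniform
#' permutation of the data. Computed by a Harding-style dynamic programme:
#' S = 2 JT - M where JT is the Jonckheere-Terpstra statistic over the
#' template's ordered groups and M the number of cross-group pairs; the JT
#' null is the convolution of Mann-Whitney null distributions.
#'
#' @param n Number of observations; used when `tie_pattern` is omitted
#'   (tie-free template, i.e. `n` groups of size 1).
#' @param tie_pattern Integer vector of template tied-group sizes (in
#'   template-value order); must sum to `n` when both given.
#' @return A tibble with columns `S`, `tau` (tau-b value assuming tie-free
#'   data) and `prob`; probabilities sum to 1 and the distribution is
#'   symmetric about 0.
#' @examples
#' exact_tau_null(3)   # tau in {-1,-1/3,1/3,1} with probs {1,2,2,1}/6
#' @export
exact_tau_null <- function(n = NULL, tie_pattern = NULL) {
  if (is.null(tie_pattern)) {
    stopifnot(!is.null(n))
    tie_pattern <- rep(1L, n)
  }
  if (!is.null(n) && sum(tie_pattern) != n)
    abort("`tie_pattern` must sum to `n`")
  n <- sum(tie_pattern)
  n0 <- n * (n - 1) / 2
  ty <- sum(tie_pattern * (tie_pattern - 1) / 2)
  m_cross <- n0 - ty
  pmf <- jt_dist(tie_pattern)
  s_vals <- 2 * (seq_along(pmf) - 1) - m_cross
  keep <- pmf > 0
  tibble(S = s_vals[keep],
         tau = s_vals[keep] / sqrt(n0 * (n0 - ty)),
         prob = pmf[keep])
}

# Upper-tail p-value P(S >= s) from an exact_tau_null table.
tau_null_upper_p <- function(null_tbl, s) {
  vapply(s, function(si) sum(null_tbl$prob[null_tbl$S >= si - 1e-9]), 0)
}
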