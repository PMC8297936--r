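#include <Rcpp.h>
using namespace Rcpp;

// Kendall-S machinery for the rhythm test. Templates are functions of the
// timepoint only (replicates tied), so S between a data vector and a
// template decomposes over timepoint pairs:
//   S_l = sum_{t<u} sign(y_l(u) - y_l(t)) * D(t,u),
//   D(t,u) = sum_{i in t, j in u} sign(x_j - x_i).
// This makes the permutation null cheap: per draw, only the D(t,u) sums
// over cross-timepoint sample pairs are recomputed.

// [[Rcpp::export]]
IntegerMatrix pair_signs(NumericMatrix templ) {
  const int n = templ.nrow(), L = templ.ncol();
  const int np = n * (n - 1) / 2;
  IntegerMatrix out(np, L);
  for (int l = 0; l < L; ++l) {
    int p = 0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j, ++p) {
        double d = templ(j, l) - templ(i, l);
        out(p, l) = (d > 0) - (d < 0);
      }
  }
  return out;
}

// Observed Kendall S per gene (rows of X) per lag, plus the tie count
// Tx = #tied pairs of each gene's values.
// [[Rcpp::export]]
List observed_s(NumericMatrix X, IntegerMatrix psign) {
  const int G = X.nrow(), n = X.ncol(), L = psign.ncol();
  IntegerMatrix S(G, L);
  IntegerVector Tx(G);
  for (int g = 0; g < G; ++g) {
    int p = 0, tx = 0;
    std::vector<int> s(n * (n - 1) / 2);
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j, ++p) {
        double d = X(g, j) - X(g, i);
        int sg = (d > 0) - (d < 0);
        s[p] = sg;
        if (sg == 0) ++tx;
      }
    Tx[g] = tx;
    for (int l = 0; l < L; ++l) {
      long acc = 0;
      const int *tp = &psign(0, l);
      for (int q = 0; q < (int)s.size(); ++q) acc += s[q] * tp[q];
      S(g, l) = (int)acc;
    }
  }
  return List::create(_["S"] = S, _["Tx"] = Tx);
}

// Monte-Carlo permutation null of the per-lag tau and the max-over-lags
// tau, conditioned on the tie pattern of `x`. `group_sizes` gives the
// number of replicates per timepoint; because the permutation is uniform,
// timepoint groups can be taken as contiguous blocks of the shuffled
// vector. `csign` holds the sign of the template difference for each
// timepoint pair (t<u, t-major rows; one column per lag), `denom[l]` the
// lag-dependent part sqrt(n0 - Ty_l) of the tau-b denominator (the
// gene-constant sqrt(n0 - Tx) cancels from max comparisons and is applied
// by the caller). Uses R's RNG for set.seed() reproducibility.
// [[Rcpp::export]]
List perm_null_tau(NumericVector x, IntegerVector group_sizes,
                   NumericMatrix csign, NumericVector denom, int ndraw) {
  const int n = x.size(), L = csign.ncol();
  const int n_groups = group_sizes.size();
  const int npair = n_groups * (n_groups - 1) / 2;
  if (csign.nrow() != npair) stop("csign rows must match timepoint pairs");
  NumericVector maxtau(ndraw), tau0(ndraw);
  std::vector<double> xs(x.begin(), x.end());
  std::vector<int> start(n_groups + 1, 0);
  for (int t = 0; t < n_groups; ++t) start[t + 1] = start[t] + group_sizes[t];
  if (start[n_groups] != n) stop("group sizes must sum to length(x)");
  std::vector<double> D(npair);
  // column-major copy of csign for tight access
  std::vector<double> cs(npair * L);
  for (int l = 0; l < L; ++l)
    for (int q = 0; q < npair; ++q) cs[l * npair + q] = csign(q, l);
  RNGScope scope;
  for (int d = 0; d < ndraw; ++d) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(xs[i], xs[j]);
    }
    int p = 0;
    for (int t = 0; t < n_groups - 1; ++t)
      for (int u = t + 1; u < n_groups; ++u, ++p) {
        int acc = 0;
        for (int a = start[t]; a < start[t + 1]; ++a) {
          const double xa = xs[a];
          for (int b = start[u]; b < start[u + 1]; ++b) {
            acc += (xs[b] > xa) - (xs[b] < xa);
          }
        }
        D[p] = acc;
      }
    double best = R_NegInf;
    for (int l = 0; l < L; ++l) {
      const double *c = &cs[l * npair];
      double s = 0;
      for (int q = 0; q < npair; ++q) s += c[q] * D[q];
      double tau = s / denom[l];
      if (l == 0) tau0[d] = tau;
      if (tau > best) best = tau;
    }
    maxtau[d] = best;
  }
  return List::create(_["max_tau"] = maxtau, _["tau_lag1"] = tau0);
}
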