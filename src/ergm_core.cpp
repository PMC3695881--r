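#include <Rcpp.h>
using namespace Rcpp;

// Term codes (must match ERGM_TERMS order on the R side):
// 1 edge, 2 two_star, 3 three_star, 4 triangle,
// 5 alt_k_star, 6 alt_k_triangle, 7 alt_k_two_path

static inline int shared_partners(const IntegerMatrix &adj, int u, int v) {
  int n = adj.nrow(), cnt = 0;
  for (int h = 0; h < n; ++h)
    if (adj(u, h) && adj(v, h)) ++cnt;
  return cnt;
}

// Change statistics for ADDING the tie (i, j); adj must not contain it.
static NumericVector change_stats(const IntegerMatrix &adj, int i, int j,
                                  const IntegerVector &terms, double lambda) {
  int n = adj.nrow();
  double q = 1.0 - 1.0 / lambda;
  int di = 0, dj = 0;
  for (int h = 0; h < n; ++h) { di += adj(i, h); dj += adj(j, h); }

  NumericVector delta(terms.size());
  for (int t = 0; t < terms.size(); ++t) {
    switch (terms[t]) {
    case 1:  // edge
      delta[t] = 1.0;
      break;
    case 2:  // 2-star: C(d+1,2) - C(d,2) = d, per endpoint
      delta[t] = (double)(di + dj);
      break;
    case 3:  // 3-star: C(d,2) per endpoint
      delta[t] = 0.5 * (double)(di * (di - 1) + dj * (dj - 1));
      break;
    case 4: {  // triangle: common neighbours of i and j
      delta[t] = (double)shared_partners(adj, i, j);
      break;
    }
    case 5:  // alternating k-star: lambda * (1 - q^d) per endpoint
      delta[t] = lambda * (2.0 - std::pow(q, (double)di)
                               - std::pow(q, (double)dj));
      break;
    case 6: {  // alternating k-triangle
      // new tie contributes lambda*(1 - q^sp_ij); each tie (i,h) or (j,h)
      // with h a common neighbour gains one shared partner: + q^sp
      int spij = 0;
      double d = 0.0;
      for (int h = 0; h < n; ++h) {
        if (adj(i, h) && adj(j, h)) {
          ++spij;
          d += std::pow(q, (double)shared_partners(adj, i, h));
          d += std::pow(q, (double)shared_partners(adj, j, h));
        }
      }
      delta[t] = d + lambda * (1.0 - std::pow(q, (double)spij));
      break;
    }
    case 7: {  // alternating independent two-paths
      // pair (i,h) gains a two-path through j when j~h, and vice versa
      double d = 0.0;
      for (int h = 0; h < n; ++h) {
        if (h == i || h == j) continue;
        if (adj(j, h))
          d += std::pow(q, (double)shared_partners(adj, i, h));
        if (adj(i, h))
          d += std::pow(q, (double)shared_partners(adj, j, h));
      }
      delta[t] = d;
      break;
    }
    default:
      stop("unknown term code");
    }
  }
  return delta;
}

// [[Rcpp::export]]
NumericVector cpp_change_stats(IntegerMatrix adj, int i, int j,
                               IntegerVector terms, double lambda) {
  if (adj(i, j) != 0) stop("internal error: dyad tie must be absent");
  return change_stats(adj, i, j, terms, lambda);
}

// Metropolis single-dyad-toggle run.  Starts from `adj`, proposes
// `nsteps` uniform random dyad toggles, accepts with probability
// min(1, exp(+/- theta . delta)).  Uses R's RNG so set.seed() on the R
// side makes the whole trajectory reproducible.  Returns the final
// adjacency; `adj` itself is not modified.
// [[Rcpp::export]]
IntegerMatrix cpp_mh_run(IntegerMatrix adj, NumericVector theta,
                         IntegerVector terms, double lambda, int nsteps) {
  IntegerMatrix x = clone(adj);
  int n = x.nrow();
  if (n < 2) return x;
  RNGScope scope;
  for (int s = 0; s < nsteps; ++s) {
    int i = (int)(unif_rand() * n);
    int j = (int)(unif_rand() * (n - 1));
    if (j >= i) ++j;
    if (i >= n) i = n - 1;  // guard against unif_rand() == 1
    if (j >= n) j = n - 1;
    if (i == j) continue;
    int present = x(i, j);
    if (present) { x(i, j) = 0; x(j, i) = 0; }
    NumericVector delta = change_stats(x, i, j, terms, lambda);
    double lr = 0.0;
    for (int t = 0; t < theta.size(); ++t) lr += theta[t] * delta[t];
    if (present) lr = -lr;
    bool accept = (lr >= 0.0) || (unif_rand() < std::exp(lr));
    // acceptance toggles the dyad; rejection restores the original state
    int tie_after = present ? (accept ? 0 : 1) : (accept ? 1 : 0);
    x(i, j) = tie_after;
    x(j, i) = tie_after;
  }
  return x;
}
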