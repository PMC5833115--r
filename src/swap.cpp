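#include <Rcpp.h>
using namespace Rcpp;

// One checkerboard step: draw a random 2x2 submatrix; if it equals
// [[1,0],[0,1]] or [[0,1],[1,0]], flip it.  Returns 1 on success.
static inline int try_swap(IntegerMatrix &M, int nr, int nc) {
  int r1 = (int)(unif_rand() * nr);
  int r2 = (int)(unif_rand() * (nr - 1));
  if (r2 >= r1) r2++;
  int c1 = (int)(unif_rand() * nc);
  int c2 = (int)(unif_rand() * (nc - 1));
  if (c2 >= c1) c2++;
  int a = M(r1, c1), b = M(r1, c2), c = M(r2, c1), d = M(r2, c2);
  if (a == d && b == c && a != b) {
    M(r1, c1) = b; M(r1, c2) = a;
    M(r2, c1) = d; M(r2, c2) = c;
    return 1;
  }
  return 0;
}

// count_attempts: every draw counts toward n_swaps (trial-swap chain,
// uniform stationary distribution over the margin class).  Otherwise only
// successful flips count, capped at max_attempts draws.
static void run_swaps(IntegerMatrix &M, int n_swaps, bool count_attempts,
                      int max_attempts, int *successes, int *attempts) {
  int nr = M.nrow(), nc = M.ncol();
  int s = 0, t = 0;
  if (count_attempts) {
    for (t = 0; t < n_swaps; t++) s += try_swap(M, nr, nc);
  } else {
    while (s < n_swaps && t < max_attempts) {
      s += try_swap(M, nr, nc);
      t++;
    }
  }
  *successes = s;
  *attempts = t;
}

// [[Rcpp::export]]
List cpp_swap(IntegerMatrix m, int n_swaps, bool count_attempts,
              int max_attempts) {
  IntegerMatrix M = clone(m);
  int s = 0, t = 0;
  run_swaps(M, n_swaps, count_attempts, max_attempts, &s, &t);
  return List::create(_["matrix"] = M, _["successes"] = s,
                      _["attempts"] = t);
}

// Streaming permutation ensemble.  For each of n_perm replicates the
// observed matrix is copied, swapped, and scored for every requested pair:
// pos = #rows with (1,1), neg = #rows with (1,0)+(0,1).  Pairs may be
// trait-trait (both columns of m) or trait-fixed (column b taken from the
// never-permuted matrix `fixed`, e.g. an environment column).  Only running
// sums and exceedance tallies against the supplied observed counts are
// kept, so memory is O(pairs).
// [[Rcpp::export]]
List cpp_ensemble(IntegerMatrix m, IntegerMatrix fixed, IntegerVector pa,
                  IntegerVector pb, LogicalVector b_fixed,
                  IntegerVector obs_pos, IntegerVector obs_neg, int n_perm,
                  int n_swaps, bool count_attempts, int max_attempts) {
  int nr = m.nrow(), np = pa.size();
  NumericVector pos_sum(np), neg_sum(np);
  IntegerVector pos_ge(np), neg_ge(np);
  IntegerMatrix M(nr, m.ncol());
  for (int rep = 0; rep < n_perm; rep++) {
    std::copy(m.begin(), m.end(), M.begin());
    int s = 0, t = 0;
    run_swaps(M, n_swaps, count_attempts, max_attempts, &s, &t);
    for (int k = 0; k < np; k++) {
      int ca = pa[k], cb = pb[k];
      int pos = 0, neg = 0;
      if (b_fixed[k]) {
        for (int i = 0; i < nr; i++) {
          int a = M(i, ca), b = fixed(i, cb);
          pos += a & b;
          neg += a ^ b;
        }
      } else {
        for (int i = 0; i < nr; i++) {
          int a = M(i, ca), b = M(i, cb);
          pos += a & b;
          neg += a ^ b;
        }
      }
      pos_sum[k] += pos;
      neg_sum[k] += neg;
      if (pos >= obs_pos[k]) pos_ge[k]++;
      if (neg >= obs_neg[k]) neg_ge[k]++;
    }
  }
  return List::create(_["pos_sum"] = pos_sum, _["neg_sum"] = neg_sum,
                      _["pos_ge"] = pos_ge, _["neg_ge"] = neg_ge);
}
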