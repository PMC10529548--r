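#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Felsenstein pruning over site patterns for a rooted binary tree with a
// GTR+Gamma(+I) mixture. The rate matrix enters through its (reversible)
// eigensystem: Q = U diag(eigval) Uinv, so P(t) = U diag(exp(eigval t)) Uinv.
//
// edges: 2-column integer matrix (parent, child), 1-based ape node numbers,
//        in postorder (children before parents). Root = n_tips + 1.
// tip_states: n_tips x n_patterns, codes 0..3 = ACGT, 4 = missing (gap/N).
// brlens: expected substitutions per site per edge (same order as edges).
// rates / cat_weights: discrete-gamma category rates and weights.
// p_inv: weight of an additional zero-rate class (plain mixture).
//
// Returns the total log-likelihood sum(weights * log site likelihood).
// [[Rcpp::export]]
double cpp_pruning_loglik(IntegerMatrix edges, int n_tips,
                          IntegerMatrix tip_states, NumericVector weights,
                          NumericVector pi, NumericMatrix U, NumericMatrix Uinv,
                          NumericVector eigval, NumericVector brlens,
                          NumericVector rates, NumericVector cat_weights,
                          double p_inv) {
  const int n_pat = tip_states.ncol();
  const int n_edge = edges.nrow();
  const int n_node = 2 * n_tips - 1;
  const int n_cat = rates.size();
  const int root = n_tips;  // 0-based index of ape node n_tips + 1

  std::vector<int> par(n_edge), ch(n_edge);
  for (int e = 0; e < n_edge; ++e) {
    par[e] = edges(e, 0) - 1;
    ch[e] = edges(e, 1) - 1;
  }
  std::vector<int> ts((size_t)n_tips * n_pat);
  for (int p = 0; p < n_pat; ++p)
    for (int nd = 0; nd < n_tips; ++nd)
      ts[(size_t)p * n_tips + nd] = tip_states(nd, p);

  // tip partial template (category-independent), pattern-major blocks of 4
  std::vector<double> tip_part((size_t)n_tips * n_pat * 4);
  for (int p = 0; p < n_pat; ++p) {
    for (int nd = 0; nd < n_tips; ++nd) {
      double* tp = &tip_part[((size_t)nd * n_pat + p) * 4];
      int st = ts[(size_t)p * n_tips + nd];
      if (st < 0 || st >= 4) {
        tp[0] = tp[1] = tp[2] = tp[3] = 1.0;
      } else {
        tp[0] = tp[1] = tp[2] = tp[3] = 0.0;
        tp[st] = 1.0;
      }
    }
  }

  double Um[16], Uim[16], ev[4], piv[4];
  for (int a = 0; a < 4; ++a) {
    ev[a] = eigval[a];
    piv[a] = pi[a];
    for (int b = 0; b < 4; ++b) {
      Um[a * 4 + b] = U(a, b);
      Uim[a * 4 + b] = Uinv(a, b);
    }
  }

  std::vector<double> partial((size_t)n_node * n_pat * 4);
  std::vector<double> logscale(n_pat);
  std::vector<double> site_mix(n_pat, 0.0);

  for (int c = 0; c < n_cat; ++c) {
    std::fill(logscale.begin(), logscale.end(), 0.0);
    // tips: copy template; internals: ones
    std::memcpy(&partial[0], &tip_part[0],
                sizeof(double) * (size_t)n_tips * n_pat * 4);
    std::fill(partial.begin() + (size_t)n_tips * n_pat * 4, partial.end(),
              1.0);
    for (int e = 0; e < n_edge; ++e) {
      double t = brlens[e] * rates[c];
      double ex[4], P[16];
      for (int s = 0; s < 4; ++s) ex[s] = std::exp(ev[s] * t);
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          double v = 0.0;
          for (int s = 0; s < 4; ++s) v += Um[a * 4 + s] * ex[s] * Uim[s * 4 + b];
          P[a * 4 + b] = (v > 0.0) ? v : 0.0;
        }
      const double* cp0 = &partial[(size_t)ch[e] * n_pat * 4];
      double* pp0 = &partial[(size_t)par[e] * n_pat * 4];
      for (int p = 0; p < n_pat; ++p) {
        const double* cp = cp0 + (size_t)p * 4;
        double* pp = pp0 + (size_t)p * 4;
        double mx = 0.0;
        for (int a = 0; a < 4; ++a) {
          double v = P[a * 4] * cp[0] + P[a * 4 + 1] * cp[1] +
                     P[a * 4 + 2] * cp[2] + P[a * 4 + 3] * cp[3];
          pp[a] *= v;
          if (pp[a] > mx) mx = pp[a];
        }
        if (mx > 0.0 && mx < 1e-200) {
          for (int a = 0; a < 4; ++a) pp[a] /= mx;
          logscale[p] += std::log(mx);
        }
      }
    }
    const double* rp = &partial[(size_t)root * n_pat * 4];
    double wc = cat_weights[c];
    for (int p = 0; p < n_pat; ++p) {
      const double* pr = rp + (size_t)p * 4;
      double lik = piv[0] * pr[0] + piv[1] * pr[1] + piv[2] * pr[2] +
                   piv[3] * pr[3];
      site_mix[p] += wc * lik * std::exp(logscale[p]);
    }
  }

  double total = 0.0;
  for (int p = 0; p < n_pat; ++p) {
    double lik = (1.0 - p_inv) * site_mix[p];
    if (p_inv > 0.0) {
      // invariant class: probability mass on bases compatible with every tip
      double inv = 0.0;
      for (int a = 0; a < 4; ++a) {
        bool ok = true;
        const int* col = &ts[(size_t)p * n_tips];
        for (int nd = 0; nd < n_tips && ok; ++nd) {
          int st = col[nd];
          if (st >= 0 && st < 4 && st != a) ok = false;
        }
        if (ok) inv += piv[a];
      }
      lik += p_inv * inv;
    }
    if (!(lik > 0.0) || !R_finite(lik))
      stop("non-finite site likelihood (pattern %d)", p + 1);
    total += weights[p] * std::log(lik);
  }
  return total;
}
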