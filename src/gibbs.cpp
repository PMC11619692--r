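#include <Rcpp.h>
using namespace Rcpp;

// Data-augmentation Gibbs sampler for the two-class conditional-independence
// latent class model of four binary diagnostic tests, operating on the
// 16-cell pattern counts (sufficient statistic).
//
// Model: cell probability = pi * prod_i Se_i^t (1-Se_i)^(1-t)
//                         + (1-pi) * prod_i Sp_i^(1-t) (1-Sp_i)^t
// Priors: Beta(1,1) on pi, Se_i, Sp_i, truncated to {Se_i >= 1 - Sp_i}
// (rules out the label-switching mirror mode).
//
// One sweep:
//   (a) split each cell count between the classes with the conditional
//       class-membership probability implied by the current parameters;
//   (b) pi ~ Beta(1 + n_diseased, 1 + n_healthy);
//   (c) Se_i ~ Beta full conditional truncated to [1 - Sp_i, 1], then
//       Sp_i ~ Beta full conditional truncated to [1 - Se_i(new), 1],
//       both via inverse-CDF sampling.

static double rtrunc_beta(double a, double b, double lo) {
  if (lo <= 0.0) return R::rbeta(a, b);
  double Flo = R::pbeta(lo, a, b, 1, 0);
  if (Flo >= 1.0 - 1e-14) {
    // essentially all mass below the truncation point: return the boundary
    return lo;
  }
  double u = R::runif(Flo, 1.0);
  double x = R::qbeta(u, a, b, 1, 0);
  if (x < lo) x = lo;
  if (x > 1.0) x = 1.0;
  return x;
}

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
NumericMatrix gibbs_chain_cpp(IntegerVector counts, NumericVector init,
                              int n_burnin, int n_iter, bool fix_allocation,
                              IntegerVector fixed_y) {
  if (counts.size() != 16) stop("counts must have 16 cells");
  if (init.size() != 9) stop("init must hold 9 parameters");
  int n = 0;
  for (int k = 0; k < 16; ++k) n += counts[k];
  if (n <= 0) stop("counts must sum to a positive total");

  // pattern bits, k = 8 t1 + 4 t2 + 2 t3 + t4
  int t[16][4];
  for (int k = 0; k < 16; ++k) {
    t[k][0] = (k >> 3) & 1; t[k][1] = (k >> 2) & 1;
    t[k][2] = (k >> 1) & 1; t[k][3] = k & 1;
  }

  double pi = init[0];
  double se[4], sp[4];
  for (int i = 0; i < 4; ++i) { se[i] = init[1 + i]; sp[i] = init[5 + i]; }

  NumericMatrix draws(n_iter, 9);
  int total = n_burnin + n_iter;
  int y[16];

  for (int it = 0; it < total; ++it) {
    // (a) latent class allocation per cell
    int S = 0;
    for (int k = 0; k < 16; ++k) {
      if (counts[k] == 0) { y[k] = 0; continue; }
      if (fix_allocation) {
        y[k] = fixed_y[k];
      } else {
        double a = pi, b = 1.0 - pi;
        for (int i = 0; i < 4; ++i) {
          a *= t[k][i] ? se[i] : (1.0 - se[i]);
          b *= t[k][i] ? (1.0 - sp[i]) : sp[i];
        }
        double denom = a + b;
        double p1 = denom > 0.0 ? a / denom : 0.5;
        y[k] = (int) R::rbinom((double) counts[k], p1);
      }
      S += y[k];
    }
    if (!R_FINITE((double) S)) stop("non-finite latent allocation");

    // (b) prevalence
    pi = R::rbeta(1.0 + S, 1.0 + (n - S));

    // (c) accuracies under the Se_i >= 1 - Sp_i constraint
    for (int i = 0; i < 4; ++i) {
      int s_pos = 0, sp_neg = 0;
      for (int k = 0; k < 16; ++k) {
        if (t[k][i]) s_pos += y[k];
        else sp_neg += counts[k] - y[k];
      }
      int s_neg = S - s_pos;              // diseased, test negative
      int sp_pos = (n - S) - sp_neg;      // healthy, test positive
      se[i] = rtrunc_beta(1.0 + s_pos, 1.0 + s_neg, 1.0 - sp[i]);
      sp[i] = rtrunc_beta(1.0 + sp_neg, 1.0 + sp_pos, 1.0 - se[i]);
      if (!R_FINITE(se[i]) || !R_FINITE(sp[i])) {
        stop("non-finite full-conditional draw");
      }
    }

    if (it >= n_burnin) {
      int row = it - n_burnin;
      draws(row, 0) = pi;
      for (int i = 0; i < 4; ++i) { draws(row, 1 + i) = se[i]; draws(row, 5 + i) = sp[i]; }
    }
  }
  return draws;
}
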