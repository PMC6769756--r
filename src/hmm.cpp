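#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a 2-state HMM with per-interval transition
// matrices built from a switch scale s_i in [0,1] and stationary IBD
// probability F:
//   A_i = [[1 - F*s_i,      F*s_i     ],
//          [(1 - F)*s_i, 1 - (1-F)*s_i]]
// State 1 = non-IBD, state 2 = IBD; initial distribution (1-F, F).
// emis: n x 2 emission probabilities; sw: length n-1 switch scales.
// Returns log-likelihood, posteriors gamma (n x 2) and pairwise
// posteriors xi (n-1 x 4, columns 11, 12, 21, 22).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix emis, NumericVector sw, double F) {
  const int n = emis.nrow();
  if (n == 0) stop("no sites");
  if (sw.size() != n - 1) stop("sw must have length n - 1");
  NumericMatrix alpha(n, 2), beta(n, 2), gamma(n, 2);
  NumericMatrix xi(std::max(n - 1, 0), 4);
  NumericVector c(n);

  const double tiny = 1e-300;
  alpha(0, 0) = (1.0 - F) * emis(0, 0);
  alpha(0, 1) = F * emis(0, 1);
  c[0] = alpha(0, 0) + alpha(0, 1);
  if (c[0] < tiny) c[0] = tiny;
  alpha(0, 0) /= c[0]; alpha(0, 1) /= c[0];

  for (int i = 1; i < n; ++i) {
    const double s = sw[i - 1];
    const double a11 = 1.0 - F * s,        a12 = F * s;
    const double a21 = (1.0 - F) * s,      a22 = 1.0 - (1.0 - F) * s;
    alpha(i, 0) = (alpha(i - 1, 0) * a11 + alpha(i - 1, 1) * a21) * emis(i, 0);
    alpha(i, 1) = (alpha(i - 1, 0) * a12 + alpha(i - 1, 1) * a22) * emis(i, 1);
    c[i] = alpha(i, 0) + alpha(i, 1);
    if (c[i] < tiny) c[i] = tiny;
    alpha(i, 0) /= c[i]; alpha(i, 1) /= c[i];
  }

  beta(n - 1, 0) = 1.0; beta(n - 1, 1) = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    const double s = sw[i];
    const double a11 = 1.0 - F * s,        a12 = F * s;
    const double a21 = (1.0 - F) * s,      a22 = 1.0 - (1.0 - F) * s;
    const double b0 = emis(i + 1, 0) * beta(i + 1, 0);
    const double b1 = emis(i + 1, 1) * beta(i + 1, 1);
    beta(i, 0) = (a11 * b0 + a12 * b1) / c[i + 1];
    beta(i, 1) = (a21 * b0 + a22 * b1) / c[i + 1];
  }

  double loglik = 0.0;
  for (int i = 0; i < n; ++i) loglik += std::log(c[i]);

  for (int i = 0; i < n; ++i) {
    double g0 = alpha(i, 0) * beta(i, 0);
    double g1 = alpha(i, 1) * beta(i, 1);
    const double z = g0 + g1;
    gamma(i, 0) = g0 / z; gamma(i, 1) = g1 / z;
  }

  for (int i = 0; i < n - 1; ++i) {
    const double s = sw[i];
    const double a11 = 1.0 - F * s,        a12 = F * s;
    const double a21 = (1.0 - F) * s,      a22 = 1.0 - (1.0 - F) * s;
    const double b0 = emis(i + 1, 0) * beta(i + 1, 0) / c[i + 1];
    const double b1 = emis(i + 1, 1) * beta(i + 1, 1) / c[i + 1];
    double x11 = alpha(i, 0) * a11 * b0;
    double x12 = alpha(i, 0) * a12 * b1;
    double x21 = alpha(i, 1) * a21 * b0;
    double x22 = alpha(i, 1) * a22 * b1;
    const double z = x11 + x12 + x21 + x22;
    xi(i, 0) = x11 / z; xi(i, 1) = x12 / z;
    xi(i, 2) = x21 / z; xi(i, 3) = x22 / z;
  }

  return List::create(Named("loglik") = loglik,
                      Named("gamma") = gamma,
                      Named("xi") = xi);
}

// Simulate a 2-state Markov chain along ordered sites with the same
// distance-scaled transition kernel as the HMM above. Uses R's RNG so
// results follow set.seed(). Returns 0 (non-IBD) / 1 (IBD) per site.
// [[Rcpp::export]]
IntegerVector sim_two_state_chain(NumericVector sw, double F) {
  const int n = sw.size() + 1;
  IntegerVector state(n);
  state[0] = (R::unif_rand() < F) ? 1 : 0;
  for (int i = 1; i < n; ++i) {
    const double s = sw[i - 1];
    const double p_ibd = (state[i - 1] == 1) ? 1.0 - (1.0 - F) * s : F * s;
    state[i] = (R::unif_rand() < p_ibd) ? 1 : 0;
  }
  return state;
}
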