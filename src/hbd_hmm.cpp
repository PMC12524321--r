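#include <Rcpp.h>
using namespace Rcpp;

// Hidden Markov model core for homozygosity-by-descent inference.
//
// State k leaves itself between adjacent markers with probability
// stay(t,k) = exp(-R_k * d_t); otherwise the segment ends and the next
// state is drawn from the mixing weights (self-transition included).
// The structure gives O(K) forward/backward updates per locus.

// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix emis, NumericMatrix stay, NumericVector mix) {
  const int L = emis.nrow(), K = emis.ncol();
  if (stay.nrow() != L - 1 && L > 1)
    stop("stay must have L-1 rows");
  NumericMatrix alpha(L, K), beta(L, K), gamma(L, K);
  NumericVector cvec(L);

  // forward (scaled)
  double c = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = mix[k] * emis(0, k);
    c += alpha(0, k);
  }
  if (c <= 0) stop("zero forward mass at locus 1");
  cvec[0] = c;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c;

  for (int t = 1; t < L; ++t) {
    double reset = 0.0;
    for (int j = 0; j < K; ++j) reset += alpha(t - 1, j) * (1.0 - stay(t - 1, j));
    c = 0.0;
    for (int k = 0; k < K; ++k) {
      double pred = alpha(t - 1, k) * stay(t - 1, k) + reset * mix[k];
      alpha(t, k) = pred * emis(t, k);
      c += alpha(t, k);
    }
    if (c <= 0) stop("zero forward mass at locus " + std::to_string(t + 1));
    cvec[t] = c;
    for (int k = 0; k < K; ++k) alpha(t, k) /= c;
  }

  // backward (scaled by the forward constants)
  for (int k = 0; k < K; ++k) beta(L - 1, k) = 1.0;
  NumericVector reset_expect(K); // expected draws from the mixing weights
  for (int t = L - 2; t >= 0; --t) {
    double mixsum = 0.0;
    for (int k = 0; k < K; ++k) mixsum += mix[k] * emis(t + 1, k) * beta(t + 1, k);
    for (int j = 0; j < K; ++j) {
      beta(t, j) = (stay(t, j) * emis(t + 1, j) * beta(t + 1, j) +
                    (1.0 - stay(t, j)) * mixsum) / cvec[t + 1];
    }
    // expected reset transitions into each class between t and t+1
    double rmass = 0.0;
    for (int j = 0; j < K; ++j) rmass += alpha(t, j) * (1.0 - stay(t, j));
    for (int k = 0; k < K; ++k)
      reset_expect[k] += rmass * mix[k] * emis(t + 1, k) * beta(t + 1, k) / cvec[t + 1];
  }

  double loglik = 0.0;
  for (int t = 0; t < L; ++t) loglik += std::log(cvec[t]);

  for (int t = 0; t < L; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  for (int k = 0; k < K; ++k) reset_expect[k] += gamma(0, k);

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["reset_expect"] = reset_expect);
}

// EM for the mixing weights over a set of independent sequences
// (chromosomes, possibly of several individuals) given concatenated
// emissions and stay probabilities. Rates are fixed; only the class
// mixing weights are updated. Rows of `stay` align with `emis`; the last
// row of each block is unused. `len` holds the block lengths.
// [[Rcpp::export(name = ".em_cpp")]]
List em_cpp(NumericMatrix emis, NumericMatrix stay, IntegerVector len,
            NumericVector mix0, int max_iter, double tol) {
  const int K = emis.ncol();
  const int NR = emis.nrow();
  const double *pe = REAL(emis);
  const double *ps = REAL(stay);
  std::vector<double> mix(mix0.begin(), mix0.end());
  std::vector<double> alpha((size_t) NR * K);
  std::vector<double> beta((size_t) NR * K);
  std::vector<double> cvec(NR);
  std::vector<double> trace;
  bool floored = false;
  double ll_old = -std::numeric_limits<double>::infinity();
  // column-major access helpers
  #define EM_AT(M, r, k) (M)[(size_t) (k) * NR + (r)]

  for (int it = 0; it < max_iter; ++it) {
    double ll = 0.0;
    std::vector<double> counts(K, 0.0);
    int off = 0;
    for (int b = 0; b < len.size(); ++b) {
      const int L = len[b];
      // forward
      double c = 0.0;
      for (int k = 0; k < K; ++k) {
        alpha[(size_t) off * K + k] = mix[k] * EM_AT(pe, off, k);
        c += alpha[(size_t) off * K + k];
      }
      if (c <= 0) stop("zero forward mass");
      cvec[off] = c;
      for (int k = 0; k < K; ++k) alpha[(size_t) off * K + k] /= c;
      for (int t = 1; t < L; ++t) {
        const int row = off + t, prev = row - 1;
        double reset = 0.0;
        for (int j = 0; j < K; ++j)
          reset += alpha[(size_t) prev * K + j] * (1.0 - EM_AT(ps, prev, j));
        c = 0.0;
        for (int k = 0; k < K; ++k) {
          double pred = alpha[(size_t) prev * K + k] * EM_AT(ps, prev, k) +
            reset * mix[k];
          alpha[(size_t) row * K + k] = pred * EM_AT(pe, row, k);
          c += alpha[(size_t) row * K + k];
        }
        if (c <= 0) stop("zero forward mass");
        cvec[row] = c;
        for (int k = 0; k < K; ++k) alpha[(size_t) row * K + k] /= c;
      }
      // backward + expected reset draws
      for (int k = 0; k < K; ++k) beta[(size_t) (off + L - 1) * K + k] = 1.0;
      for (int t = L - 2; t >= 0; --t) {
        const int row = off + t, nxt = row + 1;
        double mixsum = 0.0;
        for (int k = 0; k < K; ++k)
          mixsum += mix[k] * EM_AT(pe, nxt, k) * beta[(size_t) nxt * K + k];
        for (int j = 0; j < K; ++j) {
          beta[(size_t) row * K + j] =
            (EM_AT(ps, row, j) * EM_AT(pe, nxt, j) * beta[(size_t) nxt * K + j] +
             (1.0 - EM_AT(ps, row, j)) * mixsum) / cvec[nxt];
        }
        double rmass = 0.0;
        for (int j = 0; j < K; ++j)
          rmass += alpha[(size_t) row * K + j] * (1.0 - EM_AT(ps, row, j));
        for (int k = 0; k < K; ++k)
          counts[k] += rmass * mix[k] * EM_AT(pe, nxt, k) *
            beta[(size_t) nxt * K + k] / cvec[nxt];
      }
      // gamma at the first locus of the block
      double s = 0.0;
      std::vector<double> g0(K);
      for (int k = 0; k < K; ++k) {
        g0[k] = alpha[(size_t) off * K + k] * beta[(size_t) off * K + k];
        s += g0[k];
      }
      for (int k = 0; k < K; ++k) counts[k] += g0[k] / s;
      for (int t = 0; t < L; ++t) ll += std::log(cvec[off + t]);
      off += L;
    }
    trace.push_back(ll);
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += counts[k];
    for (int k = 0; k < K; ++k) mix[k] = counts[k] / tot;
    double mn = *std::min_element(mix.begin(), mix.end());
    if (mn < 1e-12) {
      floored = true;
      double s2 = 0.0;
      for (int k = 0; k < K; ++k) { mix[k] = std::max(mix[k], 1e-12); s2 += mix[k]; }
      for (int k = 0; k < K; ++k) mix[k] /= s2;
    }
    if (std::isfinite(ll_old) && ll - ll_old < tol) break;
    ll_old = ll;
  }
  return List::create(_["mix"] = NumericVector(mix.begin(), mix.end()),
                      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["floored"] = floored);
}

// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix emis, NumericMatrix stay,
                          NumericVector mix) {
  const int L = emis.nrow(), K = emis.ncol();
  NumericMatrix delta(L, K);
  IntegerMatrix psi(L, K);
  const double NEG = -std::numeric_limits<double>::infinity();
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(mix[k]) + std::log(emis(0, k));
  for (int t = 1; t < L; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = NEG; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double tr = (1.0 - stay(t - 1, j)) * mix[k];
        if (j == k) tr += stay(t - 1, j);
        double v = delta(t - 1, j) + std::log(tr);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + std::log(emis(t, k));
      psi(t, k) = arg;
    }
  }
  IntegerVector path(L);
  double best = NEG;
  for (int k = 0; k < K; ++k)
    if (delta(L - 1, k) > best) { best = delta(L - 1, k); path[L - 1] = k; }
  for (int t = L - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < L; ++t) path[t] += 1; // 1-based classes
  return path;
}
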