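#include <Rcpp.h>
using namespace Rcpp;

// Multivariate sample-entropy match counts.
//
// x: p x N matrix (one already coarse-grained segment, channels in rows).
// m, tau: per-channel embedding dimensions and delays (length p).
// r: similarity threshold (Chebyshev / max-coordinate distance).
//
// Composite delay vectors
//   X(i) = [x_1(i), x_1(i+tau_1), ..., x_1(i+(m_1-1)tau_1), x_2(i), ...]
// are formed for i = 1..M with M = N - n*, n* = max_k m_k tau_k, so the
// (m+1)-dimension extension x_k(i + m_k tau_k) exists for every i.
//
// Counting uses ordered pairs with DISTINCT TIME ORIGINS (i != j) at both
// dimensions: B_m over the M base vectors; B_{m+1} over the p*M extended
// vectors (base extended by one further delayed sample of one variate),
// excluding pairs that share the origin i. Same-origin pairs have base
// distance zero by construction and would otherwise dominate the m+1 count
// for short, strongly inter-correlated segments.
//
// Returns integer counts; the fractions and the -log ratio are formed in R
// so that zero-match conditions can be signalled explicitly.
// [[Rcpp::export(name = ".msampen_counts")]]
List msampen_counts(NumericMatrix x, IntegerVector m, IntegerVector tau,
                    double r) {
  const int p = x.nrow(), N = x.ncol();
  if (m.size() != p || tau.size() != p)
    stop("m and tau must have one entry per channel");
  int nstar = 0;
  int dim = 0;
  for (int k = 0; k < p; ++k) {
    if (m[k] < 1 || tau[k] < 1) stop("m and tau entries must be >= 1");
    if (m[k] * tau[k] > nstar) nstar = m[k] * tau[k];
    dim += m[k];
  }
  const int M = N - nstar;
  if (M < 2) stop("segment too short for the requested embedding");

  // Flatten the base vectors into a dim x M matrix (column-major access).
  std::vector<double> base((size_t)dim * M);
  {
    int row = 0;
    for (int k = 0; k < p; ++k)
      for (int t = 0; t < m[k]; ++t, ++row)
        for (int i = 0; i < M; ++i)
          base[(size_t)i * dim + row] = x(k, i + t * tau[k]);
  }
  // Extension samples: ext[k][i] = x_k(i + m_k tau_k).
  std::vector<double> ext((size_t)p * M);
  for (int k = 0; k < p; ++k)
    for (int i = 0; i < M; ++i)
      ext[(size_t)k * M + i] = x(k, i + m[k] * tau[k]);

  double bm = 0.0, bm1 = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    const double* vi = &base[(size_t)i * dim];
    for (int j = i + 1; j < M; ++j) {
      const double* vj = &base[(size_t)j * dim];
      bool match = true;
      for (int d = 0; d < dim; ++d) {
        if (std::fabs(vi[d] - vj[d]) > r) { match = false; break; }
      }
      if (!match) continue;
      bm += 2.0;  // ordered pairs (i,j) and (j,i)
      int cnt = 0;
      for (int k = 0; k < p; ++k) {
        const double eik = ext[(size_t)k * M + i];
        for (int l = 0; l < p; ++l)
          if (std::fabs(eik - ext[(size_t)l * M + j]) <= r) ++cnt;
      }
      bm1 += 2.0 * cnt;
    }
  }
  return List::create(_["bm_count"] = bm, _["bm1_count"] = bm1,
                      _["n_vectors"] = M, _["dim"] = dim);
}
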