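#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Inverse-distance-weighted kNN class probabilities, cumulative over a k grid.
//
// train:  n x d matrix (feature space; Euclidean metric)
// labels: n x m 0/1 matrix (one column per outcome; neighbor sets are shared)
// query:  q x d matrix
// kgrid:  strictly increasing neighbor counts, max(kgrid) <= n
//
// Returns a q x (nk*m) matrix; column (j*nk + t) holds the positive-class
// probability for outcome j at kgrid[t] (0-based j, t).
//
// Ties at the k-th distance expand the neighbor set (order-independent).
// Zero-distance neighbors take the whole probability mass, split uniformly
// over the zero-distance points' labels (the limit of 1/d weighting).
//
// The kmax nearest are selected in one fused pass with an amortized
// filter-and-compact buffer (classic replacement selection without a heap):
// candidates at or below the running kmax-th-distance bound are appended and
// the buffer is periodically re-tightened with nth_element. Acceptance uses
// <=, so points tied with the bound are never silently dropped.
// [[Rcpp::export(name = ".wknnCumProb")]]
NumericMatrix wknnCumProb(const NumericMatrix& train,
                          const IntegerMatrix& labels,
                          const NumericMatrix& query,
                          const IntegerVector& kgrid) {
  const int n = train.nrow(), d = train.ncol();
  const int q = query.nrow(), m = labels.ncol(), nk = kgrid.size();
  if (labels.nrow() != n) stop("labels must have one row per training point");
  if (query.ncol() != d) stop("query dimension mismatch");
  for (int t = 0; t < nk; ++t) {
    if (kgrid[t] < 1 || kgrid[t] > n)
      stop("k = %d out of range [1, %d]", (int)kgrid[t], n);
    if (t > 0 && kgrid[t] <= kgrid[t - 1]) stop("kgrid must be strictly increasing");
  }
  const int kmax = kgrid[nk - 1];

  // row-major copies: point i at trm[i*d..], its labels at lrm[i*m..]
  std::vector<double> trm((size_t)n * d);
  for (int a = 0; a < d; ++a)
    for (int i = 0; i < n; ++i)
      trm[(size_t)i * d + a] = train(i, a);
  std::vector<unsigned char> lrm((size_t)n * m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      lrm[(size_t)i * m + j] = (unsigned char)(labels(i, j) != 0);

  NumericMatrix out(q, nk * m);
  std::vector<double> qv(d);
  typedef std::pair<double, int> DI;   // (squared distance, train row)
  std::vector<DI> nb;
  nb.reserve(4 * (size_t)kmax + 64);
  const int cap = kmax + 64;
  std::vector<double> wcum(cap + 1);
  std::vector<double> wposcum((size_t)m * (cap + 1));

  for (int iq = 0; iq < q; ++iq) {
    for (int a = 0; a < d; ++a) qv[a] = query(iq, a);

    // amortized selection of the kmax smallest squared distances:
    // append candidates with s <= tau; when the buffer overflows, take the
    // kmax-th smallest by nth_element, tighten tau to it, and drop strictly
    // larger entries. Accepting equality keeps ties with the bound.
    nb.clear();
    double tau = R_PosInf;
    size_t limit = 2 * (size_t)kmax;
    const double* tp = trm.data();
    for (int i = 0; i < n; ++i, tp += d) {
      double s;
      if (d == 5) {                    // dominant case: break the FP chain
        const double d0 = tp[0] - qv[0], d1 = tp[1] - qv[1], d2 = tp[2] - qv[2],
                     d3 = tp[3] - qv[3], d4 = tp[4] - qv[4];
        s = (d0 * d0 + d1 * d1) + (d2 * d2 + d3 * d3) + d4 * d4;
      } else {
        s = 0.0;
        for (int a = 0; a < d; ++a) {
          const double diff = tp[a] - qv[a];
          s += diff * diff;
        }
      }
      if (s <= tau) {
        nb.push_back(DI(s, i));
        if (nb.size() >= limit && (int)nb.size() > kmax) {
          std::nth_element(nb.begin(), nb.begin() + (kmax - 1), nb.end());
          tau = nb[kmax - 1].first;
          size_t keep = 0;
          for (size_t b = 0; b < nb.size(); ++b)
            if (nb[b].first <= tau) nb[keep++] = nb[b];
          nb.resize(keep);
          limit = std::max(2 * (size_t)kmax, nb.size() + (size_t)kmax);
        }
      }
    }
    if ((int)nb.size() > kmax) {
      std::nth_element(nb.begin(), nb.begin() + (kmax - 1), nb.end());
      tau = nb[kmax - 1].first;
      size_t keep = 0;
      for (size_t b = 0; b < nb.size(); ++b)
        if (nb[b].first <= tau) nb[keep++] = nb[b];
      nb.resize(keep);
    }
    std::sort(nb.begin(), nb.end());

    // zero-distance block (exact limit rule)
    int nzero = 0;
    while (nzero < (int)nb.size() && nb[nzero].first <= 0.0) ++nzero;

    // cumulative inverse-distance weights
    const int nn = (int)nb.size();
    if (nn + 1 > (int)wcum.size()) {
      wcum.resize(nn + 1);
      wposcum.resize((size_t)m * (nn + 1));
    }
    const size_t stride = wcum.size();
    wcum[0] = 0.0;
    for (int j = 0; j < m; ++j) wposcum[(size_t)j * stride] = 0.0;
    for (int i = 0; i < nn; ++i) {
      const double w = nb[i].first > 0.0 ? 1.0 / std::sqrt(nb[i].first) : 0.0;
      wcum[i + 1] = wcum[i] + w;
      const unsigned char* lr = &lrm[(size_t)nb[i].second * m];
      for (int j = 0; j < m; ++j) {
        const size_t o = (size_t)j * stride;
        wposcum[o + i + 1] = wposcum[o + i] + (lr[j] ? w : 0.0);
      }
    }

    for (int t = 0; t < nk; ++t) {
      int kk = std::min((int)kgrid[t], nn);
      // expand across ties with the kk-th neighbor
      const double dk = nb[kk - 1].first;
      const double tol = dk * 1e-12 + 1e-300;
      while (kk < nn && nb[kk].first <= dk + tol) ++kk;
      for (int j = 0; j < m; ++j) {
        double p;
        if (nzero > 0) {
          int pos = 0;
          for (int i = 0; i < nzero; ++i)
            if (lrm[(size_t)nb[i].second * m + j]) ++pos;
          p = (double)pos / (double)nzero;
        } else {
          p = wposcum[(size_t)j * stride + kk] / wcum[kk];
        }
        out(iq, j * nk + t) = p;
      }
    }
  }
  return out;
}
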