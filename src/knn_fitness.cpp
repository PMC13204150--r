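#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// k-nearest-neighbour CV accuracy over a masked column subset.
// Xt is the transposed feature table (features x samples) so one sample is
// contiguous in memory; the selected features are compacted into a dense
// buffer before the distance loops. fold holds 1-based fold ids; y holds
// 0/1 labels. Returns mean over folds of (N_s - E_s)/N_s * 100.
static double knn_cv_one(const double* xt, int p, int n,
                         const std::vector<int>& sel,
                         const int* fold, const int* y, int k, int nfold,
                         std::vector<double>& buf) {
  const int ns = (int)sel.size();
  buf.resize((size_t)ns * n);
  for (int i = 0; i < n; ++i) {
    const double* src = xt + (size_t)p * i;
    double* dst = &buf[(size_t)ns * i];
    for (int f = 0; f < ns; ++f) dst[f] = src[sel[f]];
  }
  double acc_sum = 0.0;
  int folds_used = 0;
  std::vector<int> train_idx; train_idx.reserve(n);
  std::vector<int> test_idx; test_idx.reserve(n);
  std::vector<double> bestd; std::vector<int> bestl;
  for (int s = 1; s <= nfold; ++s) {
    train_idx.clear(); test_idx.clear();
    for (int i = 0; i < n; ++i) {
      if (fold[i] == s) test_idx.push_back(i); else train_idx.push_back(i);
    }
    if (test_idx.empty() || train_idx.empty()) continue;
    const int ntr = (int)train_idx.size();
    const int kk = std::min(k, ntr);
    bestd.assign(kk, 0.0); bestl.assign(kk, 0);
    int correct = 0;
    for (size_t ti = 0; ti < test_idx.size(); ++ti) {
      const double* xi = &buf[(size_t)ns * test_idx[ti]];
      int filled = 0;
      double worst = 0.0;   // current k-th distance once filled
      for (int tj = 0; tj < ntr; ++tj) {
        const int j = train_idx[tj];
        const double* xj = &buf[(size_t)ns * j];
        double d = 0.0;
        for (int f = 0; f < ns; ++f) {
          const double diff = xi[f] - xj[f];
          d += diff * diff;
        }
        if (filled < kk) {
          bestd[filled] = d; bestl[filled] = y[j]; ++filled;
          if (filled == kk) {
            worst = *std::max_element(bestd.begin(), bestd.end());
          }
        } else if (d < worst) {
          // replace the current worst neighbour
          int wi = 0;
          for (int a = 1; a < kk; ++a) if (bestd[a] > bestd[wi]) wi = a;
          bestd[wi] = d; bestl[wi] = y[j];
          worst = *std::max_element(bestd.begin(), bestd.end());
        }
      }
      int votes1 = 0;
      for (int a = 0; a < filled; ++a) votes1 += bestl[a];
      const int pred = (2 * votes1 > filled) ? 1 : 0;
      if (pred == y[test_idx[ti]]) ++correct;
    }
    acc_sum += 100.0 * (double)correct / (double)test_idx.size();
    ++folds_used;
  }
  return folds_used > 0 ? acc_sum / folds_used : 0.0;
}

// [[Rcpp::export]]
double knn_cv_fitness_cpp(NumericMatrix X, IntegerVector mask,
                          IntegerVector fold, IntegerVector y,
                          int k, int nfold) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xt((size_t)p * n);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) xt[(size_t)p * i + j] = X(i, j);
  std::vector<int> sel;
  for (int f = 0; f < mask.size(); ++f) if (mask[f] != 0) sel.push_back(f);
  if (sel.empty()) stop("mask selects no features");
  std::vector<double> buf;
  return knn_cv_one(xt.data(), p, n, sel, INTEGER(fold), INTEGER(y), k,
                    nfold, buf);
}

// Batch evaluation: one row of `masks` per candidate.
// [[Rcpp::export]]
NumericVector knn_cv_fitness_batch_cpp(NumericMatrix X, IntegerMatrix masks,
                                       IntegerVector fold, IntegerVector y,
                                       int k, int nfold) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xt((size_t)p * n);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) xt[(size_t)p * i + j] = X(i, j);
  const int m = masks.nrow();
  NumericVector out(m);
  std::vector<int> sel;
  std::vector<double> buf;
  for (int r = 0; r < m; ++r) {
    sel.clear();
    for (int f = 0; f < masks.ncol(); ++f) if (masks(r, f) != 0) sel.push_back(f);
    if (sel.empty()) stop("mask selects no features");
    out[r] = knn_cv_one(xt.data(), p, n, sel, INTEGER(fold), INTEGER(y), k,
                        nfold, buf);
  }
  return out;
}
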