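#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Two-pass union-find labelling of a logical matrix, 4-connected neighbourhood.
// Labels are renumbered in raster-scan order of first occurrence so the result
// is deterministic and independent of the merge history.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused

  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!img(i, j)) continue;
      int up = (i > 0 && img(i - 1, j)) ? lab(i - 1, j) : 0;
      int lf = (j > 0 && img(i, j - 1)) ? lab(i, j - 1) : 0;
      if (!up && !lf) {
        parent.push_back(++next);
        lab(i, j) = next;
      } else if (up && lf) {
        int ru = find(up), rl = find(lf);
        lab(i, j) = ru < rl ? ru : rl;
        if (ru != rl) parent[ru > rl ? ru : rl] = ru < rl ? ru : rl;
      } else {
        lab(i, j) = up ? up : lf;
      }
    }
  }

  // renumber roots in raster order (column-major matches R's storage; first
  // occurrence order is what callers rely on, not the particular scan axis)
  std::vector<int> newlab(next + 1, 0);
  int k = 0;
  for (int idx = 0; idx < nr * nc; ++idx) {
    int i = idx % nr, j = idx / nr;
    if (lab(i, j)) {
      int r = find(lab(i, j));
      if (!newlab[r]) newlab[r] = ++k;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}

// Binary erosion/dilation with an arbitrary structuring element given as
// integer offsets (dy, dx). Pixels outside the image count as background.
// [[Rcpp::export(name = ".morph_op")]]
LogicalMatrix morph_op(LogicalMatrix img, IntegerVector dy, IntegerVector dx,
                       bool erode) {
  int nr = img.nrow(), nc = img.ncol(), m = dy.size();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool v = erode;
      for (int k = 0; k < m; ++k) {
        int ii = i + dy[k], jj = j + dx[k];
        bool px = (ii >= 0 && ii < nr && jj >= 0 && jj < nc) ? (bool)img(ii, jj) : false;
        if (erode) { if (!px) { v = false; break; } }
        else       { if (px)  { v = true;  break; } }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Sequential minimal optimisation for a binary soft-margin SVM on a
// precomputed kernel matrix. Simplified Platt SMO; adequate at the problem
// sizes used here (a few thousand examples).
// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix K, NumericVector y, double C, double tol,
               int max_passes, int max_iter) {
  int n = y.size();
  std::vector<double> alpha(n, 0.0);
  double b = 0.0;
  // cached decision values f(i) = sum_j alpha_j y_j K(i,j) + b
  auto fx = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j)
      if (alpha[j] > 0) s += alpha[j] * y[j] * K(i, j);
    return s;
  };
  GetRNGstate();
  int passes = 0, iter = 0;
  while (passes < max_passes && iter < max_iter) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = fx(i) - y[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)) {
        int j = (int)(unif_rand() * (n - 1));
        if (j >= i) ++j;
        double Ej = fx(j) - y[j];
        double ai = alpha[i], aj = alpha[j];
        double L, H;
        if (y[i] != y[j]) { L = std::max(0.0, aj - ai); H = std::min(C, C + aj - ai); }
        else              { L = std::max(0.0, ai + aj - C); H = std::min(C, ai + aj); }
        if (L >= H) continue;
        double eta = 2 * K(i, j) - K(i, i) - K(j, j);
        if (eta >= 0) continue;
        double ajn = aj - y[j] * (Ei - Ej) / eta;
        ajn = ajn > H ? H : (ajn < L ? L : ajn);
        if (std::fabs(ajn - aj) < 1e-5) continue;
        double ain = ai + y[i] * y[j] * (aj - ajn);
        alpha[i] = ain; alpha[j] = ajn;
        double b1 = b - Ei - y[i] * (ain - ai) * K(i, i) - y[j] * (ajn - aj) * K(i, j);
        double b2 = b - Ej - y[i] * (ain - ai) * K(i, j) - y[j] * (ajn - aj) * K(j, j);
        if (ain > 0 && ain < C) b = b1;
        else if (ajn > 0 && ajn < C) b = b2;
        else b = (b1 + b2) / 2;
        ++changed;
      }
    }
    ++iter;
    passes = changed == 0 ? passes + 1 : 0;
  }
  PutRNGstate();
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iter"] = iter);
}
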