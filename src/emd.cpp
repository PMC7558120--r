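#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Local extrema (0-based sample indices); plateaus contribute their
// midpoint.
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& mx, std::vector<int>& mn) {
  const int n = (int)x.size();
  mx.clear(); mn.clear();
  std::vector<int> nz; std::vector<int> s;
  nz.reserve(n); s.reserve(n);
  for (int i = 0; i + 1 < n; ++i) {
    double d = x[i + 1] - x[i];
    if (d != 0.0) { nz.push_back(i); s.push_back(d > 0 ? 1 : -1); }
  }
  for (size_t k = 0; k + 1 < nz.size(); ++k) {
    if (s[k] == s[k + 1]) continue;
    int pos = (nz[k] + nz[k + 1] + 1) / 2;   // plateau midpoint
    if (s[k] > 0) mx.push_back(pos); else mn.push_back(pos);
  }
}

// Natural cubic spline through (px, py), evaluated at 0..n-1.
static void spline_eval(const std::vector<double>& px,
                        const std::vector<double>& py,
                        int n, std::vector<double>& out) {
  const int k = (int)px.size();
  out.assign(n, 0.0);
  if (k == 2) {
    double slope = (py[1] - py[0]) / (px[1] - px[0]);
    for (int t = 0; t < n; ++t) out[t] = py[0] + slope * (t - px[0]);
    return;
  }
  std::vector<double> h(k - 1), l(k), mu(k), z(k), M(k);
  for (int i = 0; i < k - 1; ++i) h[i] = px[i + 1] - px[i];
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    double alpha = 3.0 * ((py[i + 1] - py[i]) / h[i] -
                          (py[i] - py[i - 1]) / h[i - 1]);
    l[i] = 2.0 * (px[i + 1] - px[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha - h[i - 1] * z[i - 1]) / l[i];
  }
  M[k - 1] = 0.0;
  for (int i = k - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  int j = 0;
  for (int t = 0; t < n; ++t) {
    double tt = (double)t;
    while (j < k - 2 && tt > px[j + 1]) ++j;
    double hj = h[j];
    double a = px[j + 1] - tt, b = tt - px[j];
    out[t] = M[j] * a * a * a / (6.0 * hj) +
             M[j + 1] * b * b * b / (6.0 * hj) +
             (py[j] / hj - M[j] * hj / 6.0) * a +
             (py[j + 1] / hj - M[j + 1] * hj / 6.0) * b;
  }
}

// Envelope through the extrema `idx` of `x`, with the two outermost
// extrema mirrored beyond each end to control edge swings.
static bool envelope(const std::vector<double>& x,
                     const std::vector<int>& idx,
                     int n, std::vector<double>& out) {
  const int m = (int)idx.size();
  if (m < 2) return false;
  std::vector<double> px, py;
  int kext = std::min(2, m);
  for (int i = kext - 1; i >= 0; --i) {           // mirror about sample 0
    px.push_back(-(double)idx[i]); py.push_back(x[idx[i]]);
  }
  for (int i = 0; i < m; ++i) { px.push_back(idx[i]); py.push_back(x[idx[i]]); }
  for (int i = 0; i < kext; ++i) {                // mirror about sample n-1
    px.push_back(2.0 * (n - 1) - idx[m - 1 - i]);
    py.push_back(x[idx[m - 1 - i]]);
  }
  // sort & dedupe knot positions (mirrors can coincide with ends)
  std::vector<int> ord(px.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return px[a] < px[b]; });
  std::vector<double> sx, sy;
  for (int o : ord) {
    if (!sx.empty() && px[o] == sx.back()) continue;
    sx.push_back(px[o]); sy.push_back(py[o]);
  }
  if (sx.size() < 2) return false;
  spline_eval(sx, sy, n, out);
  return true;
}

static double energy(const std::vector<double>& v) {
  double e = 0.0;
  for (double d : v) e += d * d;
  return e;
}

static int zero_crossings(const std::vector<double>& x) {
  int count = 0, prev = 0;
  for (double d : x) {
    int s = (d > 0) - (d < 0);
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++count;
    prev = s;
  }
  return count;
}

// Core sifting loop; see the R wrapper emd() for the stop-criterion
// semantics (resolution / residual energy in dB).
// [[Rcpp::export]]
List emd_cpp(NumericVector x, double resolution_db, double residual_db,
             int max_imfs, int max_sift) {
  const int n = x.size();
  std::vector<double> residue(x.begin(), x.end());
  const double e_signal = energy(residue);
  std::vector<std::vector<double> > imfs;
  std::vector<int> mx, mn;
  std::vector<double> upper(n), lower(n);

  while (true) {
    find_extrema(residue, mx, mn);
    if ((int)(mx.size() + mn.size()) < 3) break;   // monotone-ish residue
    std::vector<double> h = residue;
    for (int it = 0; it < max_sift; ++it) {
      find_extrema(h, mx, mn);
      if (!envelope(h, mx, n, upper)) break;
      if (!envelope(h, mn, n, lower)) break;
      double e_m = 0.0, e_h = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = 0.5 * (upper[i] + lower[i]);
        e_m += m * m;
        e_h += h[i] * h[i];
        h[i] -= m;
      }
      if (e_m == 0.0 || 10.0 * std::log10(e_h / e_m) >= resolution_db) {
        // accept only an admissible mode: extrema and zero-crossing
        // counts may differ by at most one
        find_extrema(h, mx, mn);
        int n_ext = (int)(mx.size() + mn.size());
        if (std::abs(n_ext - zero_crossings(h)) <= 1) break;
      }
    }
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) residue[i] -= h[i];
    if ((int)imfs.size() >= max_imfs) break;
    double e_r = energy(residue);
    if (e_r == 0.0 || 10.0 * std::log10(e_signal / e_r) >= residual_db)
      break;
  }

  List out_imfs(imfs.size());
  for (size_t i = 0; i < imfs.size(); ++i)
    out_imfs[i] = NumericVector(imfs[i].begin(), imfs[i].end());
  return List::create(_["imfs"] = out_imfs,
                      _["residue"] = NumericVector(residue.begin(),
                                                   residue.end()));
}
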