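#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Natural cubic spline through (t, v), evaluated on the integer grid 0..n-1.
// Knots may extend beyond [0, n-1] (mirror extension). Second derivatives are
// zero at both end knots.
// ---------------------------------------------------------------------------

static void spline_eval_grid(const std::vector<double>& t,
                             const std::vector<double>& v,
                             int n, double* out) {
  const int k = (int)t.size();
  if (k == 1) { for (int i = 0; i < n; ++i) out[i] = v[0]; return; }
  if (k == 2) {
    const double slope = (v[1] - v[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = v[0] + slope * (i - t[0]);
    return;
  }
  std::vector<double> y2(k, 0.0), u(k, 0.0);
  for (int i = 1; i < k - 1; ++i) {
    const double sig = (t[i] - t[i - 1]) / (t[i + 1] - t[i - 1]);
    const double p = sig * y2[i - 1] + 2.0;
    y2[i] = (sig - 1.0) / p;
    double ui = (v[i + 1] - v[i]) / (t[i + 1] - t[i]) -
                (v[i] - v[i - 1]) / (t[i] - t[i - 1]);
    u[i] = (6.0 * ui / (t[i + 1] - t[i - 1]) - sig * u[i - 1]) / p;
  }
  y2[k - 1] = 0.0;
  for (int i = k - 2; i >= 0; --i) y2[i] = y2[i] * y2[i + 1] + u[i];

  int seg = 0;
  for (int i = 0; i < n; ++i) {
    const double x = (double)i;
    while (seg < k - 2 && t[seg + 1] < x) ++seg;
    const double h = t[seg + 1] - t[seg];
    const double a = (t[seg + 1] - x) / h, b = (x - t[seg]) / h;
    out[i] = a * v[seg] + b * v[seg + 1] +
             ((a * a * a - a) * y2[seg] + (b * b * b - b) * y2[seg + 1]) *
                 (h * h) / 6.0;
  }
}

// Mirror the first/last two anchor points about the signal ends so the
// spline is anchored on both sides of [0, n-1] (suppresses end swings).
static void mirror_extend(const std::vector<int>& idx,
                          const std::vector<double>& val, int n,
                          std::vector<double>& t, std::vector<double>& v) {
  const int k = (int)idx.size();
  t.clear(); v.clear();
  const int nm = std::min(2, k);
  for (int j = nm - 1; j >= 0; --j) {
    const double tm = -(double)idx[j];
    if (tm < (double)idx[0]) { t.push_back(tm); v.push_back(val[j]); }
  }
  for (int j = 0; j < k; ++j) { t.push_back((double)idx[j]); v.push_back(val[j]); }
  for (int j = 0; j < nm; ++j) {
    const double tm = 2.0 * (n - 1) - (double)idx[k - 1 - j];
    if (tm > (double)idx[k - 1]) { t.push_back(tm); v.push_back(val[k - 1 - j]); }
  }
}

// Local extrema. Continuous-valued signals almost never repeat a value, so
// the strict three-point test is the fast path; when consecutive equal
// samples exist (e.g. a sinusoid peak sampled symmetrically on two equal
// values), fall back to a run-based scan in which an interior run of equal
// values strictly above (below) both neighbouring runs is one maximum
// (minimum), anchored at the run's middle sample.
static void local_extrema(const double* x, int n,
                          std::vector<int>& maxima, std::vector<int>& minima) {
  maxima.clear(); minima.clear();
  bool ties = false;
  for (int i = 1; i < n; ++i) if (x[i] == x[i - 1]) { ties = true; break; }
  if (!ties) {
    for (int i = 1; i < n - 1; ++i) {
      if (x[i] > x[i - 1] && x[i] > x[i + 1]) maxima.push_back(i);
      else if (x[i] < x[i - 1] && x[i] < x[i + 1]) minima.push_back(i);
    }
    return;
  }
  int runStart = 0;
  double prevVal = 0.0;
  bool havePrev = false;
  for (int i = 1; i <= n; ++i) {
    if (i < n && x[i] == x[runStart]) continue;
    if (havePrev && i < n) {
      const double v = x[runStart];
      const int mid = (runStart + i - 1) / 2;
      if (v > prevVal && v > x[i]) maxima.push_back(mid);
      else if (v < prevVal && v < x[i]) minima.push_back(mid);
    }
    if (i < n) {
      prevVal = x[runStart];
      havePrev = true;
      runStart = i;
    }
  }
}

// Sign changes; a run of exact zeros between non-zero samples counts once.
static int zero_crossings(const double* x, int n) {
  int cnt = 0, prev = 0;
  bool saw_zero = false;
  for (int i = 0; i < n; ++i) {
    const int s = (x[i] > 0.0) - (x[i] < 0.0);
    if (s == 0) { saw_zero = true; continue; }
    if (prev != 0 && (s != prev || saw_zero)) ++cnt;
    prev = s; saw_zero = false;
  }
  return cnt;
}

// [[Rcpp::export(name = ".count_extrema")]]
int count_extrema_cpp(NumericVector x) {
  std::vector<int> mx, mn;
  local_extrema(x.begin(), x.size(), mx, mn);
  return (int)(mx.size() + mn.size());
}

// [[Rcpp::export(name = ".count_zero_crossings")]]
int count_zero_crossings_cpp(NumericVector x) {
  return zero_crossings(x.begin(), x.size());
}

// Upper/lower/mean envelopes of one channel. ok = FALSE when the signal has
// fewer than two maxima or two minima (monotone-residue classification).
// [[Rcpp::export(name = ".envelopes_cpp")]]
List envelopes_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<int> mx, mn;
  local_extrema(x.begin(), n, mx, mn);
  if ((int)mx.size() < 2 || (int)mn.size() < 2)
    return List::create(_["ok"] = false,
                        _["n_max"] = (int)mx.size(), _["n_min"] = (int)mn.size());
  std::vector<double> vmax(mx.size()), vmin(mn.size()), t, v;
  for (size_t j = 0; j < mx.size(); ++j) vmax[j] = x[mx[j]];
  for (size_t j = 0; j < mn.size(); ++j) vmin[j] = x[mn[j]];
  NumericVector up(n), lo(n), me(n);
  mirror_extend(mx, vmax, n, t, v);
  spline_eval_grid(t, v, n, up.begin());
  mirror_extend(mn, vmin, n, t, v);
  spline_eval_grid(t, v, n, lo.begin());
  for (int i = 0; i < n; ++i) me[i] = 0.5 * (up[i] + lo[i]);
  return List::create(_["ok"] = true, _["upper"] = up, _["lower"] = lo,
                      _["mean"] = me,
                      _["n_max"] = (int)mx.size(), _["n_min"] = (int)mn.size());
}

static bool imf_count_condition(const double* h, int n) {
  std::vector<int> mx, mn;
  local_extrema(h, n, mx, mn);
  const int ne = (int)(mx.size() + mn.size());
  return std::abs(ne - zero_crossings(h, n)) <= 1;
}

// Univariate EMD by iterative sifting. Stops sifting one IMF when the
// Cauchy-type criterion sum(m^2)/sum(h^2) < sd_thresh AND the
// extrema/zero-crossing count condition holds, or after max_sift passes.
// Decomposition ends at a monotone (extrema-poor) residue or max_imf.
// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, double sd_thresh, int max_sift, int max_imf) {
  const int n = x.size();
  std::vector<double> residual(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> mx, mn;
  std::vector<double> t, v, vv;
  NumericVector up(n), lo(n);

  for (int im = 0; im < max_imf; ++im) {
    local_extrema(residual.data(), n, mx, mn);
    if ((int)mx.size() < 2 || (int)mn.size() < 2) break;
    std::vector<double> h = residual;
    for (int s = 0; s < max_sift; ++s) {
      local_extrema(h.data(), n, mx, mn);
      if ((int)mx.size() < 2 || (int)mn.size() < 2) break;
      vv.resize(mx.size());
      for (size_t j = 0; j < mx.size(); ++j) vv[j] = h[mx[j]];
      mirror_extend(mx, vv, n, t, v);
      spline_eval_grid(t, v, n, up.begin());
      vv.resize(mn.size());
      for (size_t j = 0; j < mn.size(); ++j) vv[j] = h[mn[j]];
      mirror_extend(mn, vv, n, t, v);
      spline_eval_grid(t, v, n, lo.begin());
      double sm = 0.0, sh = 0.0;
      for (int i = 0; i < n; ++i) {
        const double m = 0.5 * (up[i] + lo[i]);
        sm += m * m; sh += h[i] * h[i];
        h[i] -= m;
      }
      if (sh <= 0.0) break;
      if (sm / sh < sd_thresh && imf_count_condition(h.data(), n)) break;
    }
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) residual[i] -= h[i];
  }

  NumericMatrix M(n, (int)imfs.size());
  for (size_t j = 0; j < imfs.size(); ++j)
    std::copy(imfs[j].begin(), imfs[j].end(), M.begin() + j * n);
  return List::create(_["imfs"] = M,
                      _["residue"] = NumericVector(residual.begin(), residual.end()));
}

// Multivariate mean envelope: project the p-channel signal onto each
// direction vector, take the projection's maxima as anchor times, spline
// every channel through its values at those times, and average over the
// usable directions. usable = directions whose projection has >= 2 maxima.
struct MvWorkspace {
  std::vector<double> proj, t, v, env, vv;
  std::vector<int> mx, mn;
};

static bool mv_mean_envelope(const std::vector<double>& h, int n, int p,
                             const NumericMatrix& dirs,
                             std::vector<double>& menv, int& usable,
                             MvWorkspace& ws) {
  const int K = dirs.nrow();
  std::fill(menv.begin(), menv.end(), 0.0);
  usable = 0;
  std::vector<double>& proj = ws.proj; proj.resize(n);
  std::vector<double>& t = ws.t;
  std::vector<double>& v = ws.v;
  std::vector<double>& env = ws.env; env.resize(n);
  std::vector<double>& vv = ws.vv;
  std::vector<int>& mx = ws.mx;
  std::vector<int>& mn = ws.mn;
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) s += h[(size_t)c * n + i] * dirs(k, c);
      proj[i] = s;
    }
    local_extrema(proj.data(), n, mx, mn);
    if ((int)mx.size() < 2) continue;
    ++usable;
    for (int c = 0; c < p; ++c) {
      vv.resize(mx.size());
      for (size_t j = 0; j < mx.size(); ++j) vv[j] = h[(size_t)c * n + mx[j]];
      mirror_extend(mx, vv, n, t, v);
      spline_eval_grid(t, v, n, env.data());
      double* mc = &menv[(size_t)c * n];
      for (int i = 0; i < n; ++i) mc[i] += env[i];
    }
  }
  if (usable * 2 < K) return false;  // too few oscillatory projections
  const double inv = 1.0 / (double)usable;
  for (size_t i = 0; i < menv.size(); ++i) menv[i] *= inv;
  return true;
}

// [[Rcpp::export(name = ".mv_envelope_cpp")]]
List mv_envelope_cpp(NumericMatrix X, NumericMatrix dirs) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> h(X.begin(), X.end()), menv((size_t)n * p, 0.0);
  int usable = 0;
  MvWorkspace ws;
  const bool ok = mv_mean_envelope(h, n, p, dirs, menv, usable, ws);
  NumericMatrix M(n, p);
  std::copy(menv.begin(), menv.end(), M.begin());
  return List::create(_["ok"] = ok, _["mean"] = M, _["usable"] = usable);
}

// Multivariate EMD. Sifting stops on the Cauchy criterion applied to the
// norm of the mean envelope: sum||m||^2 / sum||h||^2 < sd_thresh.
// [[Rcpp::export(name = ".memd_cpp")]]
List memd_cpp(NumericMatrix X, NumericMatrix dirs, double sd_thresh,
              int max_sift, int max_imf) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> residual(X.begin(), X.end());
  std::vector<std::vector<double> > imfs;
  std::vector<double> menv((size_t)n * p);
  int usable = 0;
  MvWorkspace ws;

  for (int im = 0; im < max_imf; ++im) {
    std::vector<double> h = residual;
    bool residue_reached = false;
    for (int s = 0; s < max_sift; ++s) {
      if (!mv_mean_envelope(h, n, p, dirs, menv, usable, ws)) {
        residue_reached = (s == 0);
        break;
      }
      double sm = 0.0, sh = 0.0;
      for (size_t i = 0; i < h.size(); ++i) {
        sm += menv[i] * menv[i]; sh += h[i] * h[i];
        h[i] -= menv[i];
      }
      if (sh <= 0.0) { residue_reached = (s == 0); break; }
      if (sm / sh < sd_thresh) break;
    }
    if (residue_reached) break;
    imfs.push_back(h);
    for (size_t i = 0; i < residual.size(); ++i) residual[i] -= h[i];
  }

  const int q = (int)imfs.size();
  List out(p);
  for (int c = 0; c < p; ++c) {
    NumericMatrix M(n, q);
    for (int j = 0; j < q; ++j)
      std::copy(imfs[j].begin() + (size_t)c * n,
                imfs[j].begin() + (size_t)(c + 1) * n, M.begin() + (size_t)j * n);
    out[c] = M;
  }
  NumericMatrix R(n, p);
  std::copy(residual.begin(), residual.end(), R.begin());
  return List::create(_["imfs"] = out, _["residue"] = R);
}

// ---------------------------------------------------------------------------
// Sample-entropy template counting (Chebyshev distance, <= r, self-matches
// excluded). Returns c(A, B): matching template pairs at length m+1 and m.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, int delay, double r) {
  const int n = x.size();
  const int nt = n - m * delay;  // templates for which the m+1 extension exists
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int q = 0; q < m; ++q) {
        if (std::fabs(x[i + q * delay] - x[j + q * delay]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m * delay] - x[j + m * delay]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Multivariate sample entropy counts. Composite delay vectors stack all p
// channels at embedding m and common lag; B counts matching pairs among
// them. For A the embedding is extended by one sample in each channel in
// turn and all p*(n - m*delay) extended vectors are pooled; A counts
// matching pairs in the pooled set.
// [[Rcpp::export(name = ".mvsampen_counts")]]
NumericVector mvsampen_counts(NumericMatrix X, int m, int delay, double r) {
  const int n = X.nrow(), p = X.ncol();
  const int nt = n - m * delay;
  double A = 0.0, B = 0.0;
  // Pooled pairs sharing a time index differ only in the extension
  // coordinate (their composite parts coincide and trivially match).
  for (int i = 0; i < nt; ++i)
    for (int e1 = 0; e1 < p - 1; ++e1)
      for (int e2 = e1 + 1; e2 < p; ++e2)
        if (std::fabs(X(i + m * delay, e1) - X(i + m * delay, e2)) <= r) A += 1.0;
  // One pass over distinct-time pairs: the composite m-space check feeds B
  // directly and gates the p x p extension combinations that feed A.
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int c = 0; c < p && ok; ++c)
        for (int q = 0; q < m; ++q)
          if (std::fabs(X(i + q * delay, c) - X(j + q * delay, c)) > r) { ok = false; break; }
      if (!ok) continue;
      B += 1.0;
      for (int e1 = 0; e1 < p; ++e1)
        for (int e2 = 0; e2 < p; ++e2)
          if (std::fabs(X(i + m * delay, e1) - X(j + m * delay, e2)) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
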