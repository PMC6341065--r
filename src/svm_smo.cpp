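// Small deterministic C-SVM (Platt SMO) and the inner leave-one-out
// sweep over the (m, k) trimming lattice.  Kept in C++ because one
// floating-window run needs ~1e5 SVM fits on <= ~100-sample problems.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct KernelSpec {
  int type;       // 0 = linear, 1 = polynomial
  double gamma;   // > 0; caller resolves "auto" = 1/d before or passes <= 0
  double coef0;
  int degree;
};

inline double kern_dot(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int j = 0; j < d; ++j) s += a[j] * b[j];
  return s;
}

inline double kern_eval(double dot, const KernelSpec& ks) {
  if (ks.type == 0) return dot;
  return std::pow(ks.gamma * dot + ks.coef0, ks.degree);
}

// Platt's SMO on a precomputed kernel matrix (column-major, lead = n).
// y in {-1, +1}.  Returns alpha and intercept b with f(x) = sum a_i y_i K + b.
struct SmoResult {
  std::vector<double> alpha;
  double b;
};

class Smo {
public:
  Smo(const double* K, int lead, int n, const double* y, double C)
      : K_(K), lead_(lead), n_(n), y_(y), C_(C),
        alpha_(n, 0.0), err_(n), b_(0.0) {
    for (int i = 0; i < n_; ++i) err_[i] = -y_[i];
  }

  SmoResult solve() {
    int num_changed = 0;
    bool examine_all = true;
    long iter = 0;
    const long max_iter = 200L * std::max(n_, 50) * 50L;
    while ((num_changed > 0 || examine_all) && iter < max_iter) {
      num_changed = 0;
      if (examine_all) {
        for (int i = 0; i < n_; ++i) num_changed += examine(i);
      } else {
        for (int i = 0; i < n_; ++i)
          if (alpha_[i] > 0.0 && alpha_[i] < C_) num_changed += examine(i);
      }
      if (examine_all) examine_all = false;
      else if (num_changed == 0) examine_all = true;
      ++iter;
    }
    SmoResult res;
    res.alpha = alpha_;
    res.b = b_;
    return res;
  }

private:
  inline double K(int i, int j) const { return K_[i + (size_t)lead_ * j]; }

  int examine(int i2) {
    const double y2 = y_[i2], a2 = alpha_[i2], E2 = err_[i2];
    const double r2 = E2 * y2;
    if ((r2 < -tol_ && a2 < C_) || (r2 > tol_ && a2 > 0.0)) {
      // heuristic 1: max |E1 - E2| over free points
      int best = -1;
      double best_gap = -1.0;
      for (int i = 0; i < n_; ++i) {
        if (i == i2 || alpha_[i] <= 0.0 || alpha_[i] >= C_) continue;
        double gap = std::fabs(err_[i] - E2);
        if (gap > best_gap) { best_gap = gap; best = i; }
      }
      if (best >= 0 && take_step(best, i2)) return 1;
      for (int i = 0; i < n_; ++i) {
        if (i == i2 || alpha_[i] <= 0.0 || alpha_[i] >= C_) continue;
        if (take_step(i, i2)) return 1;
      }
      for (int i = 0; i < n_; ++i) {
        if (i == i2) continue;
        if (take_step(i, i2)) return 1;
      }
    }
    return 0;
  }

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    const double a1 = alpha_[i1], a2 = alpha_[i2];
    const double y1 = y_[i1], y2 = y_[i2];
    const double E1 = err_[i1], E2 = err_[i2];
    const double s = y1 * y2;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C_, C_ + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C_);
      H = std::min(C_, a1 + a2);
    }
    if (L >= H) return false;
    const double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    const double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > 0.0) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L;
      else if (a2new > H) a2new = H;
    } else {
      // objective at the clipping bounds
      const double f1 = y1 * (E1 + b_) - a1 * k11 - s * a2 * k12;
      const double f2 = y2 * (E2 + b_) - s * a1 * k12 - a2 * k22;
      const double L1 = a1 + s * (a2 - L);
      const double H1 = a1 + s * (a2 - H);
      const double objL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                          0.5 * L * L * k22 + s * L * L1 * k12;
      const double objH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                          0.5 * H * H * k22 + s * H * H1 * k12;
      if (objL < objH - eps_) a2new = L;
      else if (objL > objH + eps_) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < eps_ * (a2new + a2 + eps_)) return false;
    const double a1new = a1 + s * (a2 - a2new);

    const double b_old = b_;
    const double b1 = -E1 - y1 * (a1new - a1) * k11 - y2 * (a2new - a2) * k12 + b_;
    const double b2 = -E2 - y1 * (a1new - a1) * k12 - y2 * (a2new - a2) * k22 + b_;
    if (a1new > 0.0 && a1new < C_) b_ = b1;
    else if (a2new > 0.0 && a2new < C_) b_ = b2;
    else b_ = 0.5 * (b1 + b2);

    alpha_[i1] = a1new;
    alpha_[i2] = a2new;
    const double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
    for (int i = 0; i < n_; ++i)
      err_[i] += d1 * K(i1, i) + d2 * K(i2, i) + (b_ - b_old);
    return true;
  }

  const double* K_;
  int lead_, n_;
  const double* y_;
  double C_;
  std::vector<double> alpha_, err_;
  double b_;
  static constexpr double tol_ = 1e-3;
  static constexpr double eps_ = 1e-12;
};

}  // namespace

// Fit on Xtr/y (y in {-1,+1}) and return decision values for rows of Xte.
// gamma <= 0 means sklearn-style "auto" = 1/n_features.
// [[Rcpp::export]]
NumericVector cpp_svm_fit_predict(const NumericMatrix& Xtr,
                                  const NumericVector& y,
                                  const NumericMatrix& Xte,
                                  double C, int kernel_type, double gamma,
                                  double coef0, int degree) {
  const int n = Xtr.nrow(), d = Xtr.ncol(), nt = Xte.nrow();
  KernelSpec ks{kernel_type, gamma > 0 ? gamma : 1.0 / std::max(d, 1),
                coef0, degree};

  // row-major copies for contiguous dot products
  std::vector<double> xr((size_t)n * d), xe((size_t)nt * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) xr[(size_t)i * d + j] = Xtr(i, j);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < d; ++j) xe[(size_t)i * d + j] = Xte(i, j);

  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double v = kern_eval(kern_dot(&xr[(size_t)i * d], &xr[(size_t)j * d], d), ks);
      K[i + (size_t)n * j] = v;
      K[j + (size_t)n * i] = v;
    }

  std::vector<double> yv(y.begin(), y.end());
  Smo smo(K.data(), n, n, yv.data(), C);
  SmoResult fit = smo.solve();

  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    double f = fit.b;
    for (int i = 0; i < n; ++i) {
      if (fit.alpha[i] > 0.0)
        f += fit.alpha[i] * yv[i] *
             kern_eval(kern_dot(&xr[(size_t)i * d], &xe[(size_t)t * d], d), ks);
    }
    out[t] = f;
  }
  return out;
}

// Expose the fitted dual solution (alpha, b) for diagnostic checks against
// an independent QP solver.
// [[Rcpp::export]]
List cpp_svm_fit(const NumericMatrix& Xtr, const NumericVector& y, double C,
                 int kernel_type, double gamma, double coef0, int degree) {
  const int n = Xtr.nrow(), d = Xtr.ncol();
  KernelSpec ks{kernel_type, gamma > 0 ? gamma : 1.0 / std::max(d, 1),
                coef0, degree};
  std::vector<double> xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) xr[(size_t)i * d + j] = Xtr(i, j);
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double v = kern_eval(kern_dot(&xr[(size_t)i * d], &xr[(size_t)j * d], d), ks);
      K[i + (size_t)n * j] = v;
      K[j + (size_t)n * i] = v;
    }
  std::vector<double> yv(y.begin(), y.end());
  Smo smo(K.data(), n, n, yv.data(), C);
  SmoResult fit = smo.solve();
  return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["b"] = fit.b);
}

// Inner leave-one-out predictions over the (m, k) lattice for one training
// set.  X: n x d, y in {-1,+1}.  Returns:
//   pred  : (n_m * n_k) x n matrix, cell index = mi + n_m * ki (column-major
//           over the lattice); NA where the cell is invalid for that point
//   valid : logical vector length n_m * n_k (false iff any point's trim died)
// mode: 0 = hard label on the paper's 0/100 scale, 1 = signed decision value.
// scale_dist: 1 = z-score each masked feature by the training-fold sd for
// the distance computation only (zero-variance features contribute 0).
// Exploits that the feature mask only changes at the distinct per-feature
// flanking caps, so SVM fits are cached per (point, distinct mask, k).
// [[Rcpp::export]]
List cpp_inner_loo_cells(const NumericMatrix& X, const NumericVector& y,
                         const IntegerVector& m_values,
                         const IntegerVector& k_values,
                         double C, int kernel_type, double gamma, double coef0,
                         int degree, int mode, int scale_dist) {
  const int n = X.nrow(), d = X.ncol();
  const int nm = m_values.size(), nk = k_values.size();
  const int ncell = nm * nk;
  NumericMatrix pred(ncell, n);
  LogicalVector valid(ncell, true);
  std::fill(pred.begin(), pred.end(), NA_REAL);

  std::vector<double> xrow((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) xrow[(size_t)i * d + j] = X(i, j);

  const int ntr = n - 1;
  std::vector<int> tr_idx(ntr);
  std::vector<int> mvm(d);
  std::vector<double> dist(ntr);
  std::vector<int> ord(ntr);
  std::vector<double> Kord((size_t)ntr * ntr), ktest(ntr), ytr(ntr);
  std::vector<double> Ksub, ysub;
  std::vector<double> masked_tr((size_t)ntr * d), masked_val(d);

  for (int i = 0; i < n; ++i) {
    int t = 0;
    for (int r = 0; r < n; ++r)
      if (r != i) tr_idx[t++] = r;

    // per-feature flanking caps: min(#strictly below, #strictly above)
    for (int j = 0; j < d; ++j) {
      int below = 0, above = 0;
      const double v = X(i, j);
      for (int r = 0; r < ntr; ++r) {
        const double w = X(tr_idx[r], j);
        if (w < v) ++below;
        else if (w > v) ++above;
      }
      mvm[j] = std::min(below, above);
    }

    // group requested m values by identical mask {j : mvm[j] >= m}
    // masks are nested in m; signature = number of surviving features is
    // not unique, so key on the threshold position among sorted caps
    std::vector<int> caps_sorted(mvm.begin(), mvm.end());
    std::sort(caps_sorted.begin(), caps_sorted.end());
    std::vector<int> group_of_m(nm);
    std::vector<int> group_rep;  // representative m per distinct mask
    {
      std::vector<long long> seen_key;
      for (int mi = 0; mi < nm; ++mi) {
        const int m = m_values[mi];
        // number of features failing the condition at this m
        long long key = std::lower_bound(caps_sorted.begin(), caps_sorted.end(), m)
                        - caps_sorted.begin();
        int g = -1;
        for (size_t q = 0; q < seen_key.size(); ++q)
          if (seen_key[q] == key) { g = (int)q; break; }
        if (g < 0) {
          seen_key.push_back(key);
          group_rep.push_back(m);
          g = (int)seen_key.size() - 1;
        }
        group_of_m[mi] = g;
      }
    }

    const int ngroup = (int)group_rep.size();
    // per (group, k) cached prediction; NaN marks invalid (empty mask)
    std::vector<double> cell_pred((size_t)ngroup * nk,
                                  std::numeric_limits<double>::quiet_NaN());
    std::vector<char> group_ok(ngroup, 1);

    for (int g = 0; g < ngroup; ++g) {
      const int m = group_rep[g];
      int dm = 0;
      for (int j = 0; j < d; ++j)
        if (mvm[j] >= m) ++dm;
      if (dm == 0) { group_ok[g] = 0; continue; }

      // masked copies (row-major) for the training set and validation point
      {
        int jj = 0;
        for (int j = 0; j < d; ++j) {
          if (mvm[j] < m) continue;
          masked_val[jj] = X(i, j);
          for (int r = 0; r < ntr; ++r)
            masked_tr[(size_t)r * dm + jj] = X(tr_idx[r], j);
          ++jj;
        }
      }

      std::vector<double> wj(dm, 1.0);
      if (scale_dist) {
        for (int j = 0; j < dm; ++j) {
          double mu = 0.0;
          for (int r = 0; r < ntr; ++r) mu += masked_tr[(size_t)r * dm + j];
          mu /= ntr;
          double ss = 0.0;
          for (int r = 0; r < ntr; ++r) {
            const double e = masked_tr[(size_t)r * dm + j] - mu;
            ss += e * e;
          }
          const double sd = std::sqrt(ss / std::max(ntr - 1, 1));
          wj[j] = sd > 0 ? 1.0 / sd : 0.0;
        }
      }
      for (int r = 0; r < ntr; ++r) {
        double s = 0.0;
        for (int j = 0; j < dm; ++j) {
          const double diff =
              (masked_tr[(size_t)r * dm + j] - masked_val[j]) * wj[j];
          s += diff * diff;
        }
        dist[r] = s;
        ord[r] = r;
      }
      // ties broken by ascending training index (ord holds 0..ntr-1 which
      // is ascending original index order since tr_idx is ascending)
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int a, int b) { return dist[a] < dist[b]; });

      KernelSpec ks{kernel_type, gamma > 0 ? gamma : 1.0 / dm, coef0, degree};
      for (int r = 0; r < ntr; ++r) {
        const double* xa = &masked_tr[(size_t)ord[r] * dm];
        ktest[r] = kern_eval(kern_dot(xa, masked_val.data(), dm), ks);
        ytr[r] = y[tr_idx[ord[r]]];
        for (int q = r; q < ntr; ++q) {
          const double* xb = &masked_tr[(size_t)ord[q] * dm];
          const double v = kern_eval(kern_dot(xa, xb, dm), ks);
          Kord[r + (size_t)ntr * q] = v;
          Kord[q + (size_t)ntr * r] = v;
        }
      }

      for (int ki = 0; ki < nk; ++ki) {
        const int kk = std::min<int>(k_values[ki], ntr);
        int npos = 0;
        for (int r = 0; r < kk; ++r)
          if (ytr[r] > 0) ++npos;
        double decision;
        if (npos == 0 || npos == kk) {
          // single-class window: emit that class without fitting
          decision = (npos == kk) ? 1.0 : -1.0;
        } else if (kk == ntr) {
          std::vector<double> yv(ytr.begin(), ytr.begin() + kk);
          Smo smo(Kord.data(), ntr, kk, yv.data(), C);
          SmoResult fit = smo.solve();
          decision = fit.b;
          for (int r = 0; r < kk; ++r)
            if (fit.alpha[r] > 0.0) decision += fit.alpha[r] * yv[r] * ktest[r];
        } else {
          Ksub.assign((size_t)kk * kk, 0.0);
          for (int q = 0; q < kk; ++q)
            for (int r = 0; r < kk; ++r)
              Ksub[r + (size_t)kk * q] = Kord[r + (size_t)ntr * q];
          ysub.assign(ytr.begin(), ytr.begin() + kk);
          Smo smo(Ksub.data(), kk, kk, ysub.data(), C);
          SmoResult fit = smo.solve();
          decision = fit.b;
          for (int r = 0; r < kk; ++r)
            if (fit.alpha[r] > 0.0) decision += fit.alpha[r] * ysub[r] * ktest[r];
        }
        cell_pred[(size_t)g * nk + ki] =
            (mode == 0) ? (decision > 0 ? 100.0 : 0.0) : decision;
      }
    }

    for (int mi = 0; mi < nm; ++mi) {
      const int g = group_of_m[mi];
      for (int ki = 0; ki < nk; ++ki) {
        const int cell = mi + nm * ki;
        if (!group_ok[g]) {
          valid[cell] = false;
        } else {
          pred(cell, i) = cell_pred[(size_t)g * nk + ki];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["pred"] = pred, _["valid"] = valid);
}
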