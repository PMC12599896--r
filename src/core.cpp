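#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Second-order-sections IIR filter, direct form I, one pass over x.
// sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1.
// zi: n_sections x 4 matrix of per-section state (x1 x2 y1 y2); modified copy
// is returned so callers can continue streaming.
// [[Rcpp::export]]
List cpp_sosfilt(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int ns = sos.nrow();
  const int n = x.size();
  NumericVector y(n);
  NumericMatrix z = clone(zi);
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      const double out = b0 * v + b1 * z(s, 0) + b2 * z(s, 1)
                       - a1 * z(s, 2) - a2 * z(s, 3);
      z(s, 1) = z(s, 0); z(s, 0) = v;
      z(s, 3) = z(s, 2); z(s, 2) = out;
      v = out;
    }
    y[i] = v;
  }
  return List::create(_["y"] = y, _["zi"] = z);
}

static inline double phase_deg(double b, double a) {
  double p = std::atan2(b, a) * 180.0 / M_PI;
  if (p < 0) p += 360.0;
  if (p >= 360.0) p -= 360.0;
  return p;
}

// Single-stream harmonic-oscillator phase tracker.
// Recursion per sample: e = x - a; a* = a + G e; report
// phi = atan2(b, a*), M = sqrt(a*^2 + b^2); then rotate
// (a, b) <- R(theta) (a*, b) with theta = 2 pi fc / fs.
// [[Rcpp::export]]
List cpp_tracker_run(NumericVector x, double fc, double fs, double G,
                     double a0, double b0) {
  const int n = x.size();
  const double theta = 2.0 * M_PI * fc / fs;
  const double c = std::cos(theta), s = std::sin(theta);
  NumericVector phi(n), M(n), e(n);
  double a = a0, b = b0;
  for (int i = 0; i < n; ++i) {
    const double err = x[i] - a;
    const double astar = a + G * err;
    phi[i] = phase_deg(b, astar);
    M[i] = std::sqrt(astar * astar + b * b);
    e[i] = err;
    a = c * astar - s * b;
    b = s * astar + c * b;
  }
  return List::create(_["phi"] = phi, _["M"] = M, _["e"] = e,
                      _["a"] = a, _["b"] = b);
}

// Exact rectangular-window running mean (partial window before W samples).
// [[Rcpp::export]]
NumericVector cpp_moving_average(NumericVector x, int W) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> buf(W, 0.0);
  double sum = 0.0;
  long seen = 0;
  for (int i = 0; i < n; ++i) {
    const int pos = i % W;
    if (seen >= W) sum -= buf[pos];
    buf[pos] = x[i];
    sum += x[i];
    ++seen;
    out[i] = sum / std::min<long>(seen, W);
  }
  return out;
}

struct RunningMean {
  std::vector<double> buf;
  double sum;
  long seen;
  int W;
  explicit RunningMean(int W_) : buf(W_, 0.0), sum(0.0), seen(0), W(W_) {}
  void push(double v) {
    const int pos = seen % W;
    if (seen >= W) sum -= buf[pos];
    buf[pos] = v;
    sum += v;
    ++seen;
  }
  double value() const {
    if (seen == 0) return 0.0;
    return sum / std::min<long>(seen, W);
  }
};

// Full adaptive bank: 3 axes x n_fc streams stepped every sample over the
// (already high-pass filtered) triaxial signal X (n x 3). Stream selection
// every interval_samples samples: axis = argmax mu_axis, then fc = argmin
// mu_error among that axis's streams; ties keep the incumbent, otherwise
// fall back to axis order x,y,z / ascending fc.
// Returns per-sample locked outputs and the selection log.
// [[Rcpp::export]]
List cpp_bank_run(NumericMatrix X, double fs, NumericVector grid, double G,
                  int interval_samples, int ma_window,
                  int init_axis, int init_fc_idx) {
  const int n = X.nrow();
  const int nf = grid.size();
  const int nstream = 3 * nf;

  std::vector<double> theta_c(nf), theta_s(nf);
  for (int f = 0; f < nf; ++f) {
    const double th = 2.0 * M_PI * grid[f] / fs;
    theta_c[f] = std::cos(th);
    theta_s[f] = std::sin(th);
  }

  std::vector<double> a(nstream, 0.0), b(nstream, 0.0);
  std::vector<RunningMean> mu_err;
  mu_err.reserve(nstream);
  for (int k = 0; k < nstream; ++k) mu_err.emplace_back(ma_window);
  RunningMean mu_axis[3] = {RunningMean(ma_window), RunningMean(ma_window),
                            RunningMean(ma_window)};

  int sel_axis = init_axis - 1;     // 0-based
  int sel_fc = init_fc_idx - 1;

  NumericVector phi(n), M(n), e_locked(n);
  IntegerVector axis_out(n);
  NumericVector fc_out(n);

  const int nsel = (interval_samples > 0) ? n / interval_samples : 0;
  NumericMatrix sel_log(nsel, 3 + 3 + nf);  // time_s, axis, fc, mu_axis x3, mu_error x nf
  int sel_row = 0;

  for (int i = 0; i < n; ++i) {
    double phi_cur = 0.0, M_cur = 0.0, e_cur = 0.0;
    for (int ax = 0; ax < 3; ++ax) {
      const double xin = X(i, ax);
      mu_axis[ax].push(std::fabs(xin));
      for (int f = 0; f < nf; ++f) {
        const int k = ax * nf + f;
        const double err = xin - a[k];
        const double astar = a[k] + G * err;
        mu_err[k].push(std::fabs(err));
        if (ax == sel_axis && f == sel_fc) {
          phi_cur = phase_deg(b[k], astar);
          M_cur = std::sqrt(astar * astar + b[k] * b[k]);
          e_cur = err;
        }
        const double bn = theta_s[f] * astar + theta_c[f] * b[k];
        a[k] = theta_c[f] * astar - theta_s[f] * b[k];
        b[k] = bn;
      }
    }
    phi[i] = phi_cur;
    M[i] = M_cur;
    e_locked[i] = e_cur;
    axis_out[i] = sel_axis + 1;
    fc_out[i] = grid[sel_fc];

    if (interval_samples > 0 && (i + 1) % interval_samples == 0) {
      // dominant axis: largest mu_axis; incumbent wins ties
      double best = mu_axis[0].value();
      for (int ax = 1; ax < 3; ++ax) best = std::max(best, mu_axis[ax].value());
      int new_axis = sel_axis;
      if (mu_axis[sel_axis].value() < best) {
        for (int ax = 0; ax < 3; ++ax) {
          if (mu_axis[ax].value() == best) { new_axis = ax; break; }
        }
      }
      // center frequency on that axis: smallest mu_error; incumbent wins ties
      // only if the axis is unchanged
      double best_err = mu_err[new_axis * nf].value();
      for (int f = 1; f < nf; ++f)
        best_err = std::min(best_err, mu_err[new_axis * nf + f].value());
      int new_fc = -1;
      if (new_axis == sel_axis &&
          mu_err[new_axis * nf + sel_fc].value() == best_err) {
        new_fc = sel_fc;
      } else {
        for (int f = 0; f < nf; ++f) {
          if (mu_err[new_axis * nf + f].value() == best_err) { new_fc = f; break; }
        }
      }
      sel_axis = new_axis;
      sel_fc = new_fc;
      if (sel_row < nsel) {
        sel_log(sel_row, 0) = (i + 1) / fs;
        sel_log(sel_row, 1) = sel_axis + 1;
        sel_log(sel_row, 2) = grid[sel_fc];
        for (int ax = 0; ax < 3; ++ax) sel_log(sel_row, 3 + ax) = mu_axis[ax].value();
        for (int f = 0; f < nf; ++f)
          sel_log(sel_row, 6 + f) = mu_err[sel_axis * nf + f].value();
        ++sel_row;
      }
    }
  }

  return List::create(_["phi"] = phi, _["M"] = M, _["e"] = e_locked,
                      _["axis"] = axis_out, _["fc"] = fc_out,
                      _["selection_log"] = sel_log);
}

// Sign-flip resampling null for the median of a set of per-trial changes.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_signflip_medians(NumericVector changes, int ndraws) {
  const int n = changes.size();
  NumericVector out(ndraws);
  std::vector<double> draw(n);
  RNGScope scope;
  for (int d = 0; d < ndraws; ++d) {
    for (int i = 0; i < n; ++i) {
      const double s = (unif_rand() < 0.5) ? -1.0 : 1.0;
      draw[i] = s * changes[i];
    }
    std::sort(draw.begin(), draw.end());
    out[d] = (n % 2 == 1) ? draw[n / 2]
                          : 0.5 * (draw[n / 2 - 1] + draw[n / 2]);
  }
  return out;
}
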