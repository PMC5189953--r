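// Core numerics: fixed-step RK4 integrators (method of steps for the delayed
// clock network, plain RK4 for the 3-stage prototypes), cubic Hermite
// interpolation of the stored solution for delayed terms, and the
// peak-interval limit-cycle classifier used by every analysis stage.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// power with fast path for small integer exponents (Hill exponents are
// usually 2-4; pow() would dominate the census otherwise)
static inline double pow_h(double base, double h) {
  double r = std::round(h);
  if (std::fabs(h - r) < 1e-12 && r >= 0.0 && r <= 12.0) {
    int n = (int)r;
    double acc = 1.0;
    for (int i = 0; i < n; ++i) acc *= base;
    return acc;
  }
  return std::pow(base, h);
}

// bounded saturating regulation factor (1 + s*u) / (1 + u),
// u = (y / ybar)^h; s > 1 activates (range [1, s]), s < 1 inhibits
// (range [s, 1])
static inline double reg_factor(double s, double u) {
  return (1.0 + s * u) / (1.0 + u);
}

// ---------------------------------------------------------------------------
// clock network model (plain-old-data mirror of the R-side object)

struct ClockNet {
  int ng;
  std::vector<double> V, d, tau, ybar;
  int ne;
  std::vector<int> src, tgt;
  std::vector<double> strength, hexp;
  std::vector<int> eclamp;          // 1 = edge clamped
  std::vector<int> nclamp;          // 1 = node clamped
  std::vector<double> nclamp_val;   // level a clamped node is held at
  std::vector<double> clamp_mean;   // per-gene limit-cycle means for clamps
  // derived
  std::vector<double> base_prod;            // V_i * prod of clamped factors
  std::vector<std::vector<int> > in_edges;  // active incoming edges per gene

  void prepare() {
    base_prod.assign(ng, 0.0);
    in_edges.assign(ng, std::vector<int>());
    for (int i = 0; i < ng; ++i) base_prod[i] = V[i];
    for (int e = 0; e < ne; ++e) {
      int s = src[e], t = tgt[e];
      if (eclamp[e] || nclamp[s]) {
        // clamped edge (or edge out of a clamped node): constant factor,
        // evaluated at the regulator's clamp level
        double lvl = nclamp[s] ? nclamp_val[s] : clamp_mean[s];
        double u = pow_h(std::max(lvl, 0.0) / ybar[s], hexp[e]);
        base_prod[t] *= reg_factor(strength[e], u);
      } else {
        in_edges[t].push_back(e);
      }
    }
  }
};

static ClockNet net_from_list(const List& m) {
  ClockNet n;
  NumericVector V = m["V"], d = m["d"], tau = m["tau"], ybar = m["ybar"];
  IntegerVector src = m["src"], tgt = m["tgt"];
  NumericVector strength = m["strength"], hexp = m["hexp"];
  IntegerVector eclamp = m["eclamp"], nclamp = m["nclamp"];
  NumericVector nclamp_val = m["nclamp_val"], clamp_mean = m["clamp_mean"];
  n.ng = V.size();
  n.V = as<std::vector<double> >(V);
  n.d = as<std::vector<double> >(d);
  n.tau = as<std::vector<double> >(tau);
  n.ybar = as<std::vector<double> >(ybar);
  n.ne = src.size();
  n.src = as<std::vector<int> >(src);
  n.tgt = as<std::vector<int> >(tgt);
  n.strength = as<std::vector<double> >(strength);
  n.hexp = as<std::vector<double> >(hexp);
  n.eclamp = as<std::vector<int> >(eclamp);
  n.nclamp = as<std::vector<int> >(nclamp);
  n.nclamp_val = as<std::vector<double> >(nclamp_val);
  n.clamp_mean = as<std::vector<double> >(clamp_mean);
  n.prepare();
  return n;
}

// ---------------------------------------------------------------------------
// DDE solver: uniform grid, RK4, cubic Hermite lookup into the stored
// solution; initial history is a sampled function on [-max(tau), 0]

struct DDESolver {
  const ClockNet* net;
  double step;
  int nsteps;                 // number of steps taken so far
  std::vector<double> y;      // (nsteps+1) * ng, row-major
  std::vector<double> f;      // derivatives at grid points
  // history on t <= 0
  std::vector<double> ht;     // ascending, last element 0
  std::vector<double> hy;     // nh * ng

  double hist_value(int g, double q) const {
    int nh = (int)ht.size();
    if (nh == 1 || q <= ht[0]) return hy[0 * net->ng + g];
    if (q >= ht[nh - 1]) return hy[(nh - 1) * net->ng + g];
    int lo = 0, hi = nh - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; (ht[mid] <= q ? lo : hi) = mid; }
    double w = (q - ht[lo]) / (ht[hi] - ht[lo]);
    return (1.0 - w) * hy[lo * net->ng + g] + w * hy[hi * net->ng + g];
  }

  // solution (or history) value of gene g at time q; q never exceeds the
  // last computed grid point because step <= min positive delay
  double value_at(int g, double q) const {
    if (net->nclamp[g]) return net->nclamp_val[g];
    if (q <= 0.0) return hist_value(g, q);
    double pos = q / step;
    int k = (int)std::floor(pos + 1e-9);
    double th = pos - k;
    if (k >= nsteps) return y[nsteps * net->ng + g];
    if (th < 1e-9) return y[k * net->ng + g];
    const int ng = net->ng;
    double y0 = y[k * ng + g], y1 = y[(k + 1) * ng + g];
    double f0 = f[k * ng + g], f1 = f[(k + 1) * ng + g];
    // cubic Hermite on [t_k, t_k+step]
    double th2 = th * th, th3 = th2 * th;
    double h00 = 2 * th3 - 3 * th2 + 1, h10 = th3 - 2 * th2 + th;
    double h01 = -2 * th3 + 3 * th2, h11 = th3 - th2;
    return h00 * y0 + h10 * step * f0 + h01 * y1 + h11 * step * f1;
  }

  void deriv(double t, const double* x, double* dx) const {
    const ClockNet& m = *net;
    for (int i = 0; i < m.ng; ++i) {
      if (m.nclamp[i]) { dx[i] = 0.0; continue; }
      double prod = m.base_prod[i];
      const std::vector<int>& ie = m.in_edges[i];
      for (size_t k = 0; k < ie.size(); ++k) {
        int e = ie[k];
        int s = m.src[e];
        double ys;
        if (m.tau[s] <= 0.0) ys = x[s];
        else ys = value_at(s, t - m.tau[s]);
        double u = pow_h(std::max(ys, 0.0) / m.ybar[s], m.hexp[e]);
        prod *= reg_factor(m.strength[e], u);
      }
      dx[i] = prod - m.d[i] * x[i];
    }
  }

  // returns false on NaN/overflow, with *bad_t set to the failure time
  bool run(double t_end, double* bad_t) {
    const int ng = net->ng;
    int n = (int)std::ceil(t_end / step - 1e-9);
    y.assign((size_t)(n + 1) * ng, 0.0);
    f.assign((size_t)(n + 1) * ng, 0.0);
    // initial state = history at t = 0 (clamped nodes at their level)
    for (int g = 0; g < ng; ++g)
      y[g] = net->nclamp[g] ? net->nclamp_val[g] : hist_value(g, 0.0);
    std::vector<double> k1(ng), k2(ng), k3(ng), k4(ng), tmp(ng);
    nsteps = 0;
    for (int it = 0; it < n; ++it) {
      double t = it * step;
      const double* yn = &y[(size_t)it * ng];
      deriv(t, yn, &k1[0]);
      for (int g = 0; g < ng; ++g) f[(size_t)it * ng + g] = k1[g];
      for (int g = 0; g < ng; ++g) tmp[g] = yn[g] + 0.5 * step * k1[g];
      deriv(t + 0.5 * step, &tmp[0], &k2[0]);
      for (int g = 0; g < ng; ++g) tmp[g] = yn[g] + 0.5 * step * k2[g];
      deriv(t + 0.5 * step, &tmp[0], &k3[0]);
      for (int g = 0; g < ng; ++g) tmp[g] = yn[g] + step * k3[g];
      deriv(t + step, &tmp[0], &k4[0]);
      double* y1 = &y[(size_t)(it + 1) * ng];
      for (int g = 0; g < ng; ++g) {
        y1[g] = yn[g] + step / 6.0 * (k1[g] + 2 * k2[g] + 2 * k3[g] + k4[g]);
        if (!std::isfinite(y1[g]) || std::fabs(y1[g]) > 1e12) {
          *bad_t = t + step;
          return false;
        }
      }
      nsteps = it + 1;
    }
    double tl = n * step;
    deriv(tl, &y[(size_t)n * ng], &k1[0]);
    for (int g = 0; g < ng; ++g) f[(size_t)n * ng + g] = k1[g];
    return true;
  }
};

// [[Rcpp::export]]
List cpp_integrate_clock(List model, double t_end, double step,
                         NumericVector hist_times, NumericMatrix hist_values) {
  ClockNet net = net_from_list(model);
  DDESolver sol;
  sol.net = &net;
  sol.step = step;
  sol.ht = as<std::vector<double> >(hist_times);
  sol.hy.resize((size_t)hist_values.nrow() * net.ng);
  for (int i = 0; i < hist_values.nrow(); ++i)
    for (int g = 0; g < net.ng; ++g)
      sol.hy[(size_t)i * net.ng + g] = hist_values(i, g);
  double bad_t = NA_REAL;
  bool ok = sol.run(t_end, &bad_t);
  if (!ok)
    stop("integration failed (NaN/overflow) at t = %f h", bad_t);
  int n = sol.nsteps;
  NumericVector tout(n + 1);
  NumericMatrix yout(n + 1, net.ng);
  for (int i = 0; i <= n; ++i) {
    tout[i] = i * step;
    for (int g = 0; g < net.ng; ++g) yout(i, g) = sol.y[(size_t)i * net.ng + g];
  }
  return List::create(_["time"] = tout, _["y"] = yout);
}

// ---------------------------------------------------------------------------
// linear delayed-feedback test system dx/dt = -k x(t - tau), integrated with
// the same scheme; used to validate the stepper against the characteristic
// equation of the scalar delay equation

// [[Rcpp::export]]
List cpp_integrate_linear_dde(double k, double tau, double t_end, double step,
                              double hist_const) {
  int n = (int)std::ceil(t_end / step - 1e-9);
  std::vector<double> y(n + 1), f(n + 1);
  y[0] = hist_const;
  int nsteps = 0;
  // value lookup with cubic Hermite as in the clock solver
  struct Lk {
    const std::vector<double>* y; const std::vector<double>* f;
    double step, hist; int* nsteps;
    double operator()(double q) const {
      if (q <= 0.0) return hist;
      double pos = q / step;
      int kk = (int)std::floor(pos + 1e-9);
      double th = pos - kk;
      if (kk >= *nsteps) return (*y)[*nsteps];
      if (th < 1e-9) return (*y)[kk];
      double y0 = (*y)[kk], y1 = (*y)[kk + 1], f0 = (*f)[kk], f1 = (*f)[kk + 1];
      double th2 = th * th, th3 = th2 * th;
      return (2 * th3 - 3 * th2 + 1) * y0 + (th3 - 2 * th2 + th) * step * f0 +
             (-2 * th3 + 3 * th2) * y1 + (th3 - th2) * step * f1;
    }
  } look = { &y, &f, step, hist_const, &nsteps };
  for (int it = 0; it < n; ++it) {
    double t = it * step;
    double k1 = -k * look(t - tau);
    f[it] = k1;
    double k2 = -k * look(t + 0.5 * step - tau);
    double k3 = k2; // derivative independent of current state
    double k4 = -k * look(t + step - tau);
    y[it + 1] = y[it] + step / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
    nsteps = it + 1;
  }
  f[n] = -k * look(n * step - tau);
  NumericVector tout(n + 1), yout(n + 1);
  for (int i = 0; i <= n; ++i) { tout[i] = i * step; yout[i] = y[i]; }
  return List::create(_["time"] = tout, _["x"] = yout);
}

// ---------------------------------------------------------------------------
// limit-cycle classifier: strict local extrema, prominence pruning,
// quadratic peak refinement, peak-interval statistics

struct ClassifyResult {
  bool oscillating, torus, damped;
  int npeaks;
  double period, cv, rel_amp, mean_level, decay_per_cycle;
  std::vector<double> peak_times, peak_heights;
};

static void refine_quadratic(const std::vector<double>& t,
                             const std::vector<double>& x, int i,
                             double* tpk, double* xpk) {
  // parabola through (i-1, i, i+1)
  double y0 = x[i - 1], y1 = x[i], y2 = x[i + 1];
  double denom = y0 - 2.0 * y1 + y2;
  double dt = t[i] - t[i - 1];
  if (std::fabs(denom) < 1e-300) { *tpk = t[i]; *xpk = y1; return; }
  double off = 0.5 * (y0 - y2) / denom;
  if (off > 1.0) off = 1.0;
  if (off < -1.0) off = -1.0;
  *tpk = t[i] + off * dt;
  *xpk = y1 - 0.25 * (y0 - y2) * off;
}

static ClassifyResult classify_series(const std::vector<double>& tt,
                                      const std::vector<double>& xx,
                                      double transient, double eps_amp,
                                      double eps_cv, double decay_tol,
                                      int min_peaks, double prom_frac) {
  ClassifyResult r;
  r.oscillating = false; r.torus = false; r.damped = false;
  r.npeaks = 0; r.period = NA_REAL; r.cv = NA_REAL;
  r.rel_amp = 0.0; r.mean_level = NA_REAL; r.decay_per_cycle = NA_REAL;

  int n = (int)tt.size();
  int i0 = 0;
  while (i0 < n && tt[i0] < transient) ++i0;
  if (n - i0 < 5) return r;

  double mn = xx[i0], mx = xx[i0], sum = 0.0;
  for (int i = i0; i < n; ++i) {
    if (xx[i] < mn) mn = xx[i];
    if (xx[i] > mx) mx = xx[i];
    sum += xx[i];
  }
  double mean = sum / (n - i0);
  r.mean_level = mean;
  double range = mx - mn;
  double scale = std::fabs(mean) > 1e-12 ? std::fabs(mean) : 1.0;
  r.rel_amp = range / scale;

  // alternating strict extrema (index, is_max)
  std::vector<int> idx; std::vector<int> ismax;
  for (int i = i0 + 1; i < n - 1; ++i) {
    bool mx_ = xx[i] > xx[i - 1] && xx[i] > xx[i + 1];
    bool mn_ = xx[i] < xx[i - 1] && xx[i] < xx[i + 1];
    if (!mx_ && !mn_) continue;
    if (!idx.empty() && ismax.back() == (mx_ ? 1 : 0)) {
      // two maxima (or minima) in a row can only arise from flat stretches;
      // keep the more extreme one
      if ((mx_ && xx[i] > xx[idx.back()]) || (!mx_ && xx[i] < xx[idx.back()]))
        idx.back() = i;
      continue;
    }
    idx.push_back(i); ismax.push_back(mx_ ? 1 : 0);
  }

  // prominence pruning: repeatedly drop the adjacent extrema pair with the
  // smallest height difference while it is below prom_frac * range
  double thresh = prom_frac * range;
  while (idx.size() >= 2) {
    int best = -1; double bestd = 1e300;
    for (size_t i = 0; i + 1 < idx.size(); ++i) {
      double d = std::fabs(xx[idx[i]] - xx[idx[i + 1]]);
      if (d < bestd) { bestd = d; best = (int)i; }
    }
    if (bestd >= thresh || best < 0) break;
    idx.erase(idx.begin() + best, idx.begin() + best + 2);
    ismax.erase(ismax.begin() + best, ismax.begin() + best + 2);
  }

  std::vector<double> ptime, pheight, ttime, theight;
  for (size_t i = 0; i < idx.size(); ++i) {
    double tp, xp;
    refine_quadratic(tt, xx, idx[i], &tp, &xp);
    if (ismax[i]) { ptime.push_back(tp); pheight.push_back(xp); }
    else { ttime.push_back(tp); theight.push_back(xp); }
  }
  r.peak_times = ptime; r.peak_heights = pheight;
  r.npeaks = (int)ptime.size();
  if (r.npeaks < min_peaks || r.rel_amp < eps_amp) return r;

  int np = r.npeaks;
  double ivsum = 0.0;
  std::vector<double> iv(np - 1);
  for (int i = 0; i + 1 < np; ++i) { iv[i] = ptime[i + 1] - ptime[i]; ivsum += iv[i]; }
  double ivmean = ivsum / (np - 1);
  double ivvar = 0.0;
  for (int i = 0; i + 1 < np; ++i) ivvar += (iv[i] - ivmean) * (iv[i] - ivmean);
  ivvar /= (np - 1 > 1 ? np - 2 : 1);
  r.period = ivmean;
  r.cv = ivmean > 0 ? std::sqrt(ivvar) / ivmean : NA_REAL;

  // per-cycle amplitude = peak height minus the deepest trough before the
  // next peak; geometric decay estimated by regressing log amplitude on
  // cycle index
  std::vector<double> amp;
  for (int i = 0; i + 1 < np; ++i) {
    double tr = 1e300;
    for (size_t j = 0; j < ttime.size(); ++j)
      if (ttime[j] > ptime[i] && ttime[j] < ptime[i + 1] && theight[j] < tr)
        tr = theight[j];
    if (tr < 1e300) amp.push_back(std::max(pheight[i] - tr, 1e-300));
  }
  if (amp.size() >= 2) {
    double sx = 0, sy = 0, sxx = 0, sxy = 0; int m = (int)amp.size();
    for (int i = 0; i < m; ++i) {
      sx += i; sy += std::log(amp[i]); sxx += (double)i * i; sxy += i * std::log(amp[i]);
    }
    double slope = (m * sxy - sx * sy) / (m * sxx - sx * sx);
    r.decay_per_cycle = std::exp(slope);
    r.damped = r.decay_per_cycle < 1.0 - decay_tol;
  }
  if (r.damped) return r;
  r.oscillating = true;
  r.torus = r.cv > eps_cv;
  return r;
}

static List classify_to_list(const ClassifyResult& r) {
  return List::create(
      _["oscillating"] = r.oscillating, _["period"] = r.period,
      _["cv"] = r.cv, _["rel_amp"] = r.rel_amp, _["torus"] = r.torus,
      _["damped"] = r.damped, _["n_peaks"] = r.npeaks,
      _["mean_level"] = r.mean_level,
      _["decay_per_cycle"] = r.decay_per_cycle,
      _["peak_times"] = wrap(r.peak_times),
      _["peak_heights"] = wrap(r.peak_heights));
}

// [[Rcpp::export]]
List cpp_classify_series(NumericVector time, NumericVector x, double transient,
                         double eps_amp, double eps_cv, double decay_tol,
                         int min_peaks, double prom_frac) {
  ClassifyResult r = classify_series(
      as<std::vector<double> >(time), as<std::vector<double> >(x), transient,
      eps_amp, eps_cv, decay_tol, min_peaks, prom_frac);
  return classify_to_list(r);
}

// [[Rcpp::export]]
List cpp_detect_peaks(NumericVector time, NumericVector x, double prom_frac) {
  ClassifyResult r = classify_series(
      as<std::vector<double> >(time), as<std::vector<double> >(x), -1e300,
      0.0, 1e300, 1e300, 1000000, prom_frac);
  return List::create(_["peak_times"] = wrap(r.peak_times),
                      _["peak_heights"] = wrap(r.peak_heights));
}

// ---------------------------------------------------------------------------
// exhaustive / subsampled edge-clamp census: iterate ON/OFF configurations,
// simulate, classify the reference gene

// [[Rcpp::export]]
NumericMatrix cpp_census(List model, IntegerMatrix configs, double t_end,
                         double step, double transient, double eps_amp,
                         double eps_cv, double decay_tol, int min_peaks,
                         double prom_frac, int ref_gene) {
  ClockNet base = net_from_list(model);
  int nc = configs.nrow();
  if (configs.ncol() != base.ne) stop("config matrix must have one column per edge");
  NumericMatrix out(nc, 5); // oscillating, period, rel_amp, cv, torus
  colnames(out) = CharacterVector::create("oscillating", "period", "rel_amp",
                                          "cv", "torus");
  DDESolver sol;
  sol.step = step;
  sol.ht.assign(1, 0.0);
  sol.hy.assign(base.ng, 0.0);
  for (int g = 0; g < base.ng; ++g) sol.hy[g] = base.clamp_mean[g];
  int n_expect = (int)std::ceil(t_end / step - 1e-9);
  std::vector<double> tt(n_expect + 1), xx(n_expect + 1);
  for (int i = 0; i <= n_expect; ++i) tt[i] = i * step;

  for (int c = 0; c < nc; ++c) {
    if (c % 256 == 0) Rcpp::checkUserInterrupt();
    ClockNet net = base;
    for (int e = 0; e < net.ne; ++e) net.eclamp[e] = configs(c, e) ? 0 : 1;
    net.prepare();
    sol.net = &net;
    double bad_t;
    bool ok = sol.run(t_end, &bad_t);
    if (!ok) {
      out(c, 0) = 0; out(c, 1) = NA_REAL; out(c, 2) = NA_REAL;
      out(c, 3) = NA_REAL; out(c, 4) = 0;
      continue;
    }
    for (int i = 0; i <= sol.nsteps; ++i)
      xx[i] = sol.y[(size_t)i * net.ng + ref_gene];
    ClassifyResult r = classify_series(tt, xx, transient, eps_amp, eps_cv,
                                       decay_tol, min_peaks, prom_frac);
    out(c, 0) = r.oscillating ? 1 : 0;
    out(c, 1) = r.oscillating ? r.period : NA_REAL;
    out(c, 2) = r.rel_amp;
    out(c, 3) = r.cv;
    out(c, 4) = r.torus ? 1 : 0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3-stage prototype oscillators (ordinary ODEs): Goodwin chain (single Hill
// repression, linear stages) and the symmetric-topology repressilator (a Hill
// repression at every stage)

struct Proto {
  int family; // 0 = goodwin, 1 = repressilator
  double v1, v2, v3, d1, d2, d3, h;
  void deriv(const double* x, double* dx) const {
    if (family == 0) {
      dx[0] = v1 / (1.0 + pow_h(std::max(x[2], 0.0), h)) - d1 * x[0];
      dx[1] = v2 * x[0] - d2 * x[1];
      dx[2] = v3 * x[1] - d3 * x[2];
    } else {
      dx[0] = v1 / (1.0 + pow_h(std::max(x[2], 0.0), h)) - d1 * x[0];
      dx[1] = v2 / (1.0 + pow_h(std::max(x[0], 0.0), h)) - d2 * x[1];
      dx[2] = v3 / (1.0 + pow_h(std::max(x[1], 0.0), h)) - d3 * x[2];
    }
  }
  // unique positive fixed point via bisection on the (monotone decreasing)
  // composed map for x3
  void fixed_point(double* xs) const {
    double lo = 0.0, hi;
    if (family == 0) hi = (v1 / d1) * (v2 / d2) * (v3 / d3) + 1.0;
    else hi = v3 / d3 + 1.0;
    for (int it = 0; it < 200; ++it) {
      double x3 = 0.5 * (lo + hi), x1, x2, g;
      if (family == 0) {
        x1 = v1 / (d1 * (1.0 + pow_h(x3, h)));
        x2 = v2 * x1 / d2;
        g = v3 * x2 / d3 - x3;
      } else {
        x1 = v1 / (d1 * (1.0 + pow_h(x3, h)));
        x2 = v2 / (d2 * (1.0 + pow_h(x1, h)));
        g = v3 / (d3 * (1.0 + pow_h(x2, h))) - x3;
      }
      if (g > 0) lo = x3; else hi = x3;
    }
    double x3 = 0.5 * (lo + hi);
    double x1 = v1 / (d1 * (1.0 + pow_h(x3, h)));
    double x2 = family == 0 ? v2 * x1 / d2
                            : v2 / (d2 * (1.0 + pow_h(x1, h)));
    xs[0] = x1; xs[1] = x2; xs[2] = x3;
  }
};

static ClassifyResult simulate_and_classify_proto(const Proto& p, double t_end,
                                                  double step, double transient,
                                                  double eps_amp, double eps_cv,
                                                  double decay_tol, int min_peaks,
                                                  double prom_frac,
                                                  std::vector<double>* keep_t,
                                                  std::vector<double>* keep_x,
                                                  NumericMatrix* keep_traj) {
  double xs[3];
  p.fixed_point(xs);
  // start off the fixed point so an unstable focus actually spirals out
  double x[3] = { xs[0] * 1.3 + 1e-6, xs[1] * 0.7 + 1e-6, xs[2] * 1.1 + 1e-6 };
  int n = (int)std::ceil(t_end / step - 1e-9);
  std::vector<double> tt(n + 1), x3(n + 1);
  tt[0] = 0.0; x3[0] = x[2];
  if (keep_traj) (*keep_traj)(0, 0) = x[0], (*keep_traj)(0, 1) = x[1], (*keep_traj)(0, 2) = x[2];
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  for (int it = 0; it < n; ++it) {
    p.deriv(x, k1);
    for (int g = 0; g < 3; ++g) tmp[g] = x[g] + 0.5 * step * k1[g];
    p.deriv(tmp, k2);
    for (int g = 0; g < 3; ++g) tmp[g] = x[g] + 0.5 * step * k2[g];
    p.deriv(tmp, k3);
    for (int g = 0; g < 3; ++g) tmp[g] = x[g] + step * k3[g];
    p.deriv(tmp, k4);
    for (int g = 0; g < 3; ++g)
      x[g] += step / 6.0 * (k1[g] + 2 * k2[g] + 2 * k3[g] + k4[g]);
    tt[it + 1] = (it + 1) * step;
    x3[it + 1] = x[2];
    if (keep_traj)
      (*keep_traj)(it + 1, 0) = x[0], (*keep_traj)(it + 1, 1) = x[1],
      (*keep_traj)(it + 1, 2) = x[2];
  }
  if (keep_t) *keep_t = tt;
  if (keep_x) *keep_x = x3;
  return classify_series(tt, x3, transient, eps_amp, eps_cv, decay_tol,
                         min_peaks, prom_frac);
}

// [[Rcpp::export]]
List cpp_prototype_sim(int family, NumericVector pars, double t_end,
                       double step) {
  Proto p = { family, pars[0], pars[1], pars[2], pars[3], pars[4], pars[5],
              pars[6] };
  int n = (int)std::ceil(t_end / step - 1e-9);
  NumericMatrix traj(n + 1, 3);
  std::vector<double> tt;
  simulate_and_classify_proto(p, t_end, step, 0.0, 1e-3, 0.01, 0.01, 4, 0.05,
                              &tt, NULL, &traj);
  return List::create(_["time"] = wrap(tt), _["y"] = traj);
}

// [[Rcpp::export]]
NumericMatrix cpp_prototype_batch(int family, NumericMatrix pars, double t_end,
                                  double step, double transient,
                                  double eps_amp, double eps_cv,
                                  double decay_tol, int min_peaks,
                                  double prom_frac) {
  int n = pars.nrow();
  if (pars.ncol() != 7) stop("parameter matrix must have 7 columns");
  NumericMatrix out(n, 2);
  colnames(out) = CharacterVector::create("oscillating", "period");
  for (int i = 0; i < n; ++i) {
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
    Proto p = { family, pars(i, 0), pars(i, 1), pars(i, 2), pars(i, 3),
                pars(i, 4), pars(i, 5), pars(i, 6) };
    ClassifyResult r = simulate_and_classify_proto(
        p, t_end, step, transient, eps_amp, eps_cv, decay_tol, min_peaks,
        prom_frac, NULL, NULL, NULL);
    out(i, 0) = r.oscillating ? 1 : 0;
    out(i, 1) = r.oscillating ? r.period : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_prototype_fixed_point(int family, NumericVector pars) {
  Proto p = { family, pars[0], pars[1], pars[2], pars[3], pars[4], pars[5],
              pars[6] };
  double xs[3];
  p.fixed_point(xs);
  return NumericVector::create(xs[0], xs[1], xs[2]);
}
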