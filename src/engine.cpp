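// Pacing engine: adaptive Dormand-Prince 5(4) with dense output (default) and
// a fixed-step classical RK4 reference integrator, plus the pace loop with a
// square stimulus pulse and uniform output sampling.
//
// The environment ships no stiff ODE library for R, so the adaptive solver is
// implemented here; its accuracy contract is checked against the fixed-step
// reference in the test suite.

#include <Rcpp.h>
#include "apsweep.h"
#include <cmath>
#include <cstring>

using namespace Rcpp;

typedef void (*rhs_fn)(double, const double*, const double*, double, double*);

struct NativeModel {
  rhs_fn rhs;
  int n_state;
};

static NativeModel lookup_model(const std::string& native) {
  if (native == "sixcurrent") {
    NativeModel m;
    m.rhs = six_rhs;
    m.n_state = six_n_state();
    return m;
  }
  stop("unknown native model id '%s'", native.c_str());
}

// [[Rcpp::export(name = ".cpp_six_param_names")]]
CharacterVector cpp_six_param_names() {
  std::vector<std::string> nm = six_param_names();
  return wrap(nm);
}

// [[Rcpp::export(name = ".cpp_rhs")]]
NumericVector cpp_rhs(std::string native, double t, NumericVector state,
                      NumericVector params, double stim) {
  NativeModel m = lookup_model(native);
  if ((int)state.size() != m.n_state)
    stop("state has length %d, model expects %d", (int)state.size(), m.n_state);
  NumericVector dy(m.n_state);
  m.rhs(t, state.begin(), params.begin(), stim, dy.begin());
  return dy;
}

// ---------------------------------------------------------------------------
// Dormand-Prince 5(4), Hairer's DOPRI5 coefficients with the 4th-order dense
// interpolant; PI step-size control.

static const double c2 = 1.0 / 5.0, c3 = 3.0 / 10.0, c4 = 4.0 / 5.0,
                    c5 = 8.0 / 9.0;
static const double a21 = 1.0 / 5.0;
static const double a31 = 3.0 / 40.0, a32 = 9.0 / 40.0;
static const double a41 = 44.0 / 45.0, a42 = -56.0 / 15.0, a43 = 32.0 / 9.0;
static const double a51 = 19372.0 / 6561.0, a52 = -25360.0 / 2187.0,
                    a53 = 64448.0 / 6561.0, a54 = -212.0 / 729.0;
static const double a61 = 9017.0 / 3168.0, a62 = -355.0 / 33.0,
                    a63 = 46732.0 / 5247.0, a64 = 49.0 / 176.0,
                    a65 = -5103.0 / 18656.0;
static const double a71 = 35.0 / 384.0, a73 = 500.0 / 1113.0,
                    a74 = 125.0 / 192.0, a75 = -2187.0 / 6784.0,
                    a76 = 11.0 / 84.0;
static const double e1 = 71.0 / 57600.0, e3 = -71.0 / 16695.0,
                    e4 = 71.0 / 1920.0, e5 = -17253.0 / 339200.0,
                    e6 = 22.0 / 525.0, e7 = -1.0 / 40.0;
static const double d1 = -12715105075.0 / 11282082432.0,
                    d3 = 87487479700.0 / 32700410799.0,
                    d4 = -10690763975.0 / 1880347072.0,
                    d5 = 701980252875.0 / 199316789632.0,
                    d6 = -1453857185.0 / 822651844.0,
                    d7 = 69997945.0 / 29380423.0;

struct DenseSeg {
  // dense-output coefficients over one accepted step [t, t+h]
  std::vector<double> r1, r2, r3, r4, r5;
  double t, h;
  int n;
  void eval(double tq, double* out) const {
    double th = (tq - t) / h;
    double th1 = 1.0 - th;
    for (int i = 0; i < n; ++i)
      out[i] = r1[i] +
               th * (r2[i] + th1 * (r3[i] + th * (r4[i] + th1 * r5[i])));
  }
};

// Integrate y over [t0, t1] with constant stimulus `stim`, sampling dense
// output at the query times out_t[iq..] that fall inside the interval
// (advancing iq). Voltage (state 0) only is stored in out_v; full dense state
// is available through `sample_all` when non-null (row-major n_q x n).
static void dopri5_segment(const NativeModel& M, const double* p, double stim,
                           double t0, double t1, std::vector<double>& y,
                           double abs_tol, double rel_tol,
                           const std::vector<double>& out_t, size_t& iq,
                           double* out_v, double* sample_all) {
  const int n = M.n_state;
  if (t1 <= t0) return;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);
  std::vector<double> ytmp(n), ynew(n), yerr(n);
  DenseSeg seg;
  seg.n = n;
  seg.r1.resize(n); seg.r2.resize(n); seg.r3.resize(n);
  seg.r4.resize(n); seg.r5.resize(n);

  double t = t0;
  double h = std::min(0.1, t1 - t0); // conservative initial step (ms)
  double err_old = 1e-4;             // PI controller memory
  const double beta = 0.04, alpha = 0.2 - beta * 0.75;
  bool first = true;
  std::vector<double> k1_saved(n);

  M.rhs(t, y.data(), p, stim, k1.data());

  int n_steps = 0;
  const int max_steps = 10000000;
  while (t < t1 - 1e-12) {
    if (++n_steps > max_steps)
      stop("ODE solver exceeded %d steps at t = %g ms", max_steps, t);
    if (h < 1e-12)
      stop("ODE solver step size collapsed at t = %g ms (V = %g)", t, y[0]);
    if (t + h > t1) h = t1 - t;

    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    M.rhs(t + c2 * h, ytmp.data(), p, stim, k2.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    M.rhs(t + c3 * h, ytmp.data(), p, stim, k3.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    M.rhs(t + c4 * h, ytmp.data(), p, stim, k4.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    M.rhs(t + c5 * h, ytmp.data(), p, stim, k5.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    M.rhs(t + h, ytmp.data(), p, stim, k6.data());
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (a71 * k1[i] + a73 * k3[i] + a74 * k4[i] +
                            a75 * k5[i] + a76 * k6[i]);
    M.rhs(t + h, ynew.data(), p, stim, k7.data()); // FSAL

    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                      e6 * k6[i] + e7 * k7[i]);
      double sk = abs_tol + rel_tol * std::max(std::fabs(y[i]),
                                               std::fabs(ynew[i]));
      double r = e / sk;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) err = 2.0; // NaN in stages: shrink and retry
    if (!std::isfinite(ynew[0])) err = 2.0;

    if (err <= 1.0) {
      // accept: build dense coefficients, emit queued outputs in [t, t+h]
      for (int i = 0; i < n; ++i) {
        double ydiff = ynew[i] - y[i];
        double bspl = h * k1[i] - ydiff;
        seg.r1[i] = y[i];
        seg.r2[i] = ydiff;
        seg.r3[i] = bspl;
        seg.r4[i] = ydiff - h * k7[i] - bspl;
        seg.r5[i] = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                         d6 * k6[i] + d7 * k7[i]);
      }
      seg.t = t;
      seg.h = h;
      std::vector<double> yq(n);
      while (iq < out_t.size() && out_t[iq] <= t + h + 1e-9) {
        seg.eval(out_t[iq], yq.data());
        out_v[iq] = yq[0];
        if (sample_all)
          std::memcpy(sample_all + iq * n, yq.data(), n * sizeof(double));
        ++iq;
      }
      t += h;
      y = ynew;
      k1 = k7; // FSAL reuse
      double fac = std::pow(err > 1e-16 ? err : 1e-16, -alpha) *
                   std::pow(err_old, beta) * 0.9;
      fac = std::min(5.0, std::max(0.2, fac));
      err_old = std::max(err, 1e-4);
      h *= fac;
      first = false;
    } else {
      double fac = std::max(0.2, 0.9 * std::pow(err, -0.2));
      h *= first ? std::min(fac, 0.5) : fac;
    }
  }
}

// Fixed-step classical RK4 over [t0, t1], sampling states at queried times
// (which must coincide with step boundaries to within 1e-9).
static void rk4_segment(const NativeModel& M, const double* p, double stim,
                        double t0, double t1, std::vector<double>& y,
                        double dt, const std::vector<double>& out_t,
                        size_t& iq, double* out_v, double* sample_all) {
  const int n = M.n_state;
  if (t1 <= t0) return;
  long nstep = (long)std::lround((t1 - t0) / dt);
  if (nstep < 1) nstep = 1;
  double h = (t1 - t0) / nstep;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), ytmp(n);
  double t = t0;
  while (iq < out_t.size() && out_t[iq] <= t + 1e-9) {
    out_v[iq] = y[0];
    if (sample_all)
      std::memcpy(sample_all + iq * n, y.data(), n * sizeof(double));
    ++iq;
  }
  for (long s = 0; s < nstep; ++s) {
    M.rhs(t, y.data(), p, stim, k1.data());
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
    M.rhs(t + 0.5 * h, ytmp.data(), p, stim, k2.data());
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + 0.5 * h * k2[i];
    M.rhs(t + 0.5 * h, ytmp.data(), p, stim, k3.data());
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * k3[i];
    M.rhs(t + h, ytmp.data(), p, stim, k4.data());
    for (int i = 0; i < n; ++i)
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    t = t0 + (s + 1) * h;
    if (!std::isfinite(y[0]))
      stop("fixed-step integration diverged at t = %g ms", t);
    while (iq < out_t.size() && out_t[iq] <= t + 1e-9) {
      out_v[iq] = y[0];
      if (sample_all)
        std::memcpy(sample_all + iq * n, y.data(), n * sizeof(double));
      ++iq;
    }
  }
}

struct PaceSetup {
  NativeModel M;
  std::vector<double> out_t;
  double period, stim_amp, stim_dur, stim_offset;
  double abs_tol, rel_tol, rk4_dt;
  bool use_rk4;
};

// One pace: integrate across the three stimulus segments, fill trace voltages.
static void run_one_pace(const PaceSetup& S, const double* p,
                         std::vector<double>& y, double* out_v,
                         double* sample_all) {
  size_t iq = 0;
  double s1 = S.stim_offset, s2 = S.stim_offset + S.stim_dur;
  bool stim_on = S.stim_amp != 0.0 && S.stim_dur > 0.0;
  double b0 = 0.0, b1 = stim_on ? s1 : S.period;
  if (S.use_rk4) {
    rk4_segment(S.M, p, 0.0, b0, b1, y, S.rk4_dt, S.out_t, iq, out_v,
                sample_all);
    if (stim_on) {
      rk4_segment(S.M, p, S.stim_amp, s1, s2, y, S.rk4_dt, S.out_t, iq, out_v,
                  sample_all);
      rk4_segment(S.M, p, 0.0, s2, S.period, y, S.rk4_dt, S.out_t, iq, out_v,
                  sample_all);
    }
  } else {
    // emit t = 0 sample before stepping
    if (iq < S.out_t.size() && S.out_t[iq] <= 1e-9) {
      out_v[iq] = y[0];
      if (sample_all)
        std::memcpy(sample_all + iq * S.M.n_state, y.data(),
                    S.M.n_state * sizeof(double));
      ++iq;
    }
    dopri5_segment(S.M, p, 0.0, b0, b1, y, S.abs_tol, S.rel_tol, S.out_t, iq,
                   out_v, sample_all);
    if (stim_on) {
      dopri5_segment(S.M, p, S.stim_amp, s1, s2, y, S.abs_tol, S.rel_tol,
                     S.out_t, iq, out_v, sample_all);
      dopri5_segment(S.M, p, 0.0, s2, S.period, y, S.abs_tol, S.rel_tol,
                     S.out_t, iq, out_v, sample_all);
    }
  }
  // numerical safety: any unfilled trailing samples (t == period rounding)
  while (iq < S.out_t.size()) {
    out_v[iq] = y[0];
    if (sample_all)
      std::memcpy(sample_all + iq * S.M.n_state, y.data(),
                  S.M.n_state * sizeof(double));
    ++iq;
  }
}

static PaceSetup make_setup(const std::string& native, double period,
                            double stim_amp, double stim_dur,
                            double stim_offset, double abs_tol, double rel_tol,
                            double output_step, const std::string& method,
                            double rk4_dt) {
  PaceSetup S;
  S.M = lookup_model(native);
  S.period = period;
  S.stim_amp = stim_amp;
  S.stim_dur = stim_dur;
  S.stim_offset = stim_offset;
  S.abs_tol = abs_tol;
  S.rel_tol = rel_tol;
  S.rk4_dt = rk4_dt;
  S.use_rk4 = (method == "rk4");
  long n_out = (long)std::lround(period / output_step) + 1;
  S.out_t.resize(n_out);
  for (long j = 0; j < n_out; ++j) S.out_t[j] = j * output_step;
  S.out_t[n_out - 1] = period; // exact endpoint
  return S;
}

// [[Rcpp::export(name = ".cpp_simulate_pace")]]
List cpp_simulate_pace(std::string native, NumericVector state,
                       NumericVector params, double period, double stim_amp,
                       double stim_dur, double stim_offset, double abs_tol,
                       double rel_tol, double output_step, std::string method,
                       double rk4_dt) {
  PaceSetup S = make_setup(native, period, stim_amp, stim_dur, stim_offset,
                           abs_tol, rel_tol, output_step, method, rk4_dt);
  if ((int)state.size() != S.M.n_state)
    stop("state has length %d, model expects %d", (int)state.size(),
         S.M.n_state);
  std::vector<double> y(state.begin(), state.end());
  NumericVector out_v(S.out_t.size());
  run_one_pace(S, params.begin(), y, REAL(out_v), nullptr);
  NumericVector times(S.out_t.begin(), S.out_t.end());
  NumericVector end_state(y.begin(), y.end());
  return List::create(_["times"] = times, _["voltages"] = out_v,
                      _["end_state"] = end_state);
}

// [[Rcpp::export(name = ".cpp_pace_to_steady")]]
List cpp_pace_to_steady(std::string native, NumericVector state,
                        NumericVector params, double period, double stim_amp,
                        double stim_dur, double stim_offset, double abs_tol,
                        double rel_tol, double output_step, std::string method,
                        double rk4_dt, int max_paces, double steady_tol) {
  PaceSetup S = make_setup(native, period, stim_amp, stim_dur, stim_offset,
                           abs_tol, rel_tol, output_step, method, rk4_dt);
  if ((int)state.size() != S.M.n_state)
    stop("state has length %d, model expects %d", (int)state.size(),
         S.M.n_state);
  if (max_paces < 1) stop("max_paces must be >= 1");
  const int n = S.M.n_state;
  std::vector<double> y(state.begin(), state.end());
  std::vector<double> v_last(S.out_t.size()), v_prev(S.out_t.size());
  std::vector<double> prev_end(n);
  std::vector<double> norms;
  bool converged = false;
  double final_norm = NA_REAL;
  int pace = 0;
  bool have_prev_trace = false;
  for (pace = 1; pace <= max_paces; ++pace) {
    if (pace > 1) {
      v_prev = v_last;
      have_prev_trace = true;
      prev_end = y;
    }
    try {
      run_one_pace(S, params.begin(), y, v_last.data(), nullptr);
    } catch (std::exception& e) {
      stop("solver failure on pace %d: %s", pace, e.what());
    }
    if (pace > 1) {
      double nr = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = y[i] - prev_end[i];
        nr += d * d;
      }
      nr = std::sqrt(nr);
      norms.push_back(nr);
      final_norm = nr;
      if (nr < steady_tol) {
        converged = true;
        break;
      }
    }
  }
  if (pace > max_paces) pace = max_paces;
  NumericVector times(S.out_t.begin(), S.out_t.end());
  NumericVector vl(v_last.begin(), v_last.end());
  NumericVector end_state(y.begin(), y.end());
  NumericVector nrm(norms.begin(), norms.end());
  List out = List::create(
      _["times"] = times, _["v_last"] = vl,
      _["v_prev"] = have_prev_trace
                        ? NumericVector(v_prev.begin(), v_prev.end())
                        : NumericVector(0),
      _["end_state"] = end_state, _["paces_run"] = pace,
      _["converged"] = converged, _["final_norm"] = final_norm,
      _["norms"] = nrm);
  return out;
}
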