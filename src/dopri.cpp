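// Single-compartment motoneuron model: 8 ionic currents, Ca2+ dynamics with
// calcium-induced calcium release. Integrated with the Dormand-Prince 5(4)
// embedded Runge-Kutta pair with 5th-order dense output.
//
// State vector (length 8):
//   0 V      membrane potential, mV
//   1 hNaF   fast Na+ inactivation
//   2 mKdr   delayed-rectifier K+ activation
//   3 mKv12  Kv1.2 activation
//   4 hKv12  Kv1.2 inactivation (slow)
//   5 mCaL   L-type Ca2+ activation
//   6 hCaL   L-type Ca2+ inactivation
//   7 Ca     intracellular Ca2+, mM
//
// Units: mV, ms, uA/cm2, mS/cm2, uF/cm2, mM throughout.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Parameter vector layout (kept in sync with R/params.R param_vector()).
enum ParIdx {
  P_C = 0, P_gNaF, P_gKdr, P_gNaP, P_gKv12, P_gCaL, P_gCAN, P_gKCa, P_gL,
  P_ENa, P_ECa, P_ECAN, P_EL, P_EK,
  P_KCAN, P_Kd, P_f, P_alpha, P_kCICR, P_tauCa, P_tauCaLm, P_tauCaLh,
  P_NPAR
};

static const int NSTATE = 8;

struct Segment {
  double t0, t1, v0, v1;
  double value(double t) const {
    if (t1 <= t0) return v0;
    double th = (t - t0) / (t1 - t0);
    if (th < 0.0) th = 0.0;
    if (th > 1.0) th = 1.0;
    return v0 + th * (v1 - v0);
  }
};

static inline double boltz(double v, double vh, double k) {
  // 1 / (1 + exp(-(v - vh)/k)); k > 0 gives rising curve
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

static void model_rhs(double /*t*/, const double* y, double iinj,
                      const double* p, double* dy) {
  const double V = y[0], hNaF = y[1], mKdr = y[2], mKv12 = y[3],
               hKv12 = y[4], mCaL = y[5], hCaL = y[6], Ca = y[7];
  const double EK = p[P_EK];

  // instantaneous activations
  const double mNaF = boltz(V, -35.0, 7.8);
  const double mNaP = boltz(V, -53.0, 3.0);

  const double INaF = p[P_gNaF] * mNaF * mNaF * mNaF * hNaF * (V - p[P_ENa]);
  const double INaP = p[P_gNaP] * mNaP * (V - p[P_ENa]);
  const double m2 = mKdr * mKdr;
  const double IKdr = p[P_gKdr] * m2 * m2 * (V - EK);
  const double IKv12 = p[P_gKv12] * mKv12 * hKv12 * (V - EK);
  const double ICaL = p[P_gCaL] * mCaL * hCaL * (V - p[P_ECa]);
  const double ICAN = p[P_gCAN] * Ca / (Ca + p[P_KCAN]) * (V - p[P_ECAN]);
  const double IKCa = p[P_gKCa] * Ca / (Ca + p[P_Kd]) * (V - EK);
  const double IL = p[P_gL] * (V - p[P_EL]);

  dy[0] = (-(INaF + INaP + IKdr + IKv12 + ICaL + ICAN + IKCa + IL) + iinj) /
          p[P_C];

  // gating kinetics
  const double tauNaF =
      30.0 / (std::exp((V + 50.0) / 15.0) + std::exp(-(V + 50.0) / 16.0));
  const double hNaFinf = boltz(V, -55.0, -7.0);
  dy[1] = (hNaFinf - hNaF) / tauNaF;

  const double tauKdr =
      7.0 / (std::exp((V + 40.0) / 40.0) + std::exp(-(V + 40.0) / 50.0));
  const double mKdrinf = boltz(V, -28.0, 15.0);
  dy[2] = (mKdrinf - mKdr) / tauKdr;

  const double tauKv12m =
      2.44 + 18.387 / (std::exp(-(V - 25.645) / 21.633) +
                       std::exp((V + 4.42) / 45.9));
  const double mKv12inf = boltz(V, -46.0, 6.9);
  dy[3] = (mKv12inf - mKv12) / tauKv12m;

  const double tauKv12h =
      74.74 / (0.00015 * std::exp(-(V + 13.0) / 15.0) +
               0.06 / (1.0 + std::exp(-(V + 68.0) / 12.0)));
  const double hKv12inf = boltz(V, -54.0, -7.1);
  dy[4] = (hKv12inf - hKv12) / tauKv12h;

  const double mCaLinf = boltz(V, -27.5, 5.7);
  dy[5] = (mCaLinf - mCaL) / p[P_tauCaLm];
  const double hCaLinf = boltz(V, -52.4, -5.2);
  dy[6] = (hCaLinf - hCaL) / p[P_tauCaLh];

  // calcium balance: influx through I_CaL, CICR release, pump clearance
  dy[7] = -p[P_f] * p[P_alpha] * ICaL + p[P_kCICR] * Ca - Ca / p[P_tauCa];
}

// [[Rcpp::export(name = ".mn_rhs_cpp")]]
NumericVector mn_rhs_cpp(double t, NumericVector state, double iinj,
                         NumericVector params) {
  if (state.size() != NSTATE) stop("state must have length 8");
  if (params.size() != P_NPAR) stop("bad parameter vector");
  NumericVector dy(NSTATE);
  model_rhs(t, REAL(state), iinj, REAL(params), REAL(dy));
  return dy;
}

// [[Rcpp::export(name = ".mn_currents_cpp")]]
NumericVector mn_currents_cpp(NumericVector state, double iinj,
                              NumericVector params) {
  // returns the eight membrane currents (outward positive), uA/cm2
  const double* y = REAL(state);
  const double* p = REAL(params);
  const double V = y[0], Ca = y[7];
  const double EK = p[P_EK];
  const double mNaF = boltz(V, -35.0, 7.8);
  const double mNaP = boltz(V, -53.0, 3.0);
  const double m2 = y[2] * y[2];
  NumericVector out = NumericVector::create(
      Named("I_NaF") = p[P_gNaF] * mNaF * mNaF * mNaF * y[1] * (V - p[P_ENa]),
      Named("I_NaP") = p[P_gNaP] * mNaP * (V - p[P_ENa]),
      Named("I_Kdr") = p[P_gKdr] * m2 * m2 * (V - EK),
      Named("I_Kv1.2") = p[P_gKv12] * y[3] * y[4] * (V - EK),
      Named("I_CaL") = p[P_gCaL] * y[5] * y[6] * (V - p[P_ECa]),
      Named("I_CAN") = p[P_gCAN] * Ca / (Ca + p[P_KCAN]) * (V - p[P_ECAN]),
      Named("I_KCa") = p[P_gKCa] * Ca / (Ca + p[P_Kd]) * (V - EK),
      Named("I_L") = p[P_gL] * (V - p[P_EL]));
  (void)iinj;
  return out;
}

// ---------------------------------------------------------------------------
// Dormand-Prince 5(4) with dense output (Hairer, Norsett & Wanner coefficients)

static const double C2 = 1.0 / 5.0, C3 = 3.0 / 10.0, C4 = 4.0 / 5.0,
                    C5 = 8.0 / 9.0;
static const double A21 = 1.0 / 5.0;
static const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
static const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
static const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
                    A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
static const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
                    A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
                    A65 = -5103.0 / 18656.0;
static const double A71 = 35.0 / 384.0, A73 = 500.0 / 1113.0,
                    A74 = 125.0 / 192.0, A75 = -2187.0 / 6784.0,
                    A76 = 11.0 / 84.0;
// error coefficients (b5 - b4)
static const double E1 = 71.0 / 57600.0, E3 = -71.0 / 16695.0,
                    E4 = 71.0 / 1920.0, E5 = -17253.0 / 339200.0,
                    E6 = 22.0 / 525.0, E7 = -1.0 / 40.0;
// dense-output coefficients
static const double D1 = -12715105075.0 / 11282082432.0,
                    D3 = 87487479700.0 / 32700410799.0,
                    D4 = -10690763975.0 / 1880347072.0,
                    D5 = 701980252875.0 / 199316789632.0,
                    D6 = -1453857185.0 / 822651844.0,
                    D7 = 69997945.0 / 29380423.0;

struct DenseStep {
  double t0, h;
  double r1[NSTATE], r2[NSTATE], r3[NSTATE], r4[NSTATE], r5[NSTATE];
  void eval(double t, double* y) const {
    double th = (t - t0) / h;
    if (th < 0.0) th = 0.0;
    if (th > 1.0) th = 1.0;
    const double th1 = 1.0 - th;
    for (int i = 0; i < NSTATE; ++i) {
      y[i] = r1[i] + th * (r2[i] + th1 * (r3[i] + th * (r4[i] + th1 * r5[i])));
    }
  }
};

struct SpikeDetector {
  double threshold, refractory, scan_dt;
  bool in_spike = false;
  double last_cross = -1e300;
  double peak_v = -1e300, peak_t = 0.0;
  double prev_v = -1e300, prev_t = 0.0;
  bool have_prev = false;
  std::vector<double> spike_t;  // time of spike peak

  void feed(double t, double v) {
    if (!have_prev) {
      prev_t = t;
      prev_v = v;
      have_prev = true;
      in_spike = v >= threshold;  // never count a spike already in progress
      return;
    }
    if (!in_spike) {
      if (prev_v < threshold && v >= threshold &&
          (t - last_cross) >= refractory) {
        in_spike = true;
        last_cross = t;
        peak_v = v;
        peak_t = t;
      }
    } else {
      if (v > peak_v) {
        peak_v = v;
        peak_t = t;
      }
      if (v < threshold) {
        if (last_cross > -1e299) spike_t.push_back(peak_t);
        in_spike = false;
      }
    }
    prev_t = t;
    prev_v = v;
  }
};

// [[Rcpp::export(name = ".mn_integrate_cpp")]]
List mn_integrate_cpp(NumericVector y0, NumericVector params,
                      NumericMatrix segments,  // columns t0, t1, v0, v1
                      double dt_out, double rtol, double atol,
                      bool keep_trace, double spike_threshold,
                      double refractory, double scan_dt,
                      double max_step = 1e300) {
  if (y0.size() != NSTATE) stop("initial state must have length 8");
  if (params.size() != P_NPAR) stop("bad parameter vector");
  const int nseg = segments.nrow();
  if (nseg < 1) stop("current program needs at least one segment");
  std::vector<Segment> segs(nseg);
  for (int i = 0; i < nseg; ++i) {
    segs[i] = Segment{segments(i, 0), segments(i, 1), segments(i, 2),
                      segments(i, 3)};
    if (!(segs[i].t1 > segs[i].t0))
      stop("program segment durations must be positive");
  }
  const double t_start = segs.front().t0;
  const double t_end = segs.back().t1;
  const double* p = REAL(params);

  // output grid
  std::vector<double> tout;
  if (keep_trace) {
    const long n = (long)std::floor((t_end - t_start) / dt_out + 1e-9) + 1;
    tout.reserve(n + 1);
    for (long i = 0; i < n; ++i) tout.push_back(t_start + i * dt_out);
    if (tout.back() < t_end - 1e-9) tout.push_back(t_end);
  }
  NumericMatrix trace;
  NumericVector trace_iinj;
  if (keep_trace) {
    trace = NumericMatrix((int)tout.size(), NSTATE);
    trace_iinj = NumericVector((int)tout.size());
  }
  size_t out_idx = 0;

  double y[NSTATE], ynew[NSTATE], ysta[NSTATE];
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
      k6[NSTATE], k7[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];

  SpikeDetector det{spike_threshold, refractory, scan_dt};
  std::vector<double> spike_iinj;

  int iseg = 0;
  double t = t_start;
  double h = 1e-3;
  const double hmin = 1e-12;
  long naccept = 0, nreject = 0;
  bool first = true;
  double facold = 1e-4;

  // record initial sample
  if (keep_trace && out_idx < tout.size() && tout[out_idx] <= t + 1e-12) {
    for (int i = 0; i < NSTATE; ++i) trace(out_idx, i) = y[i];
    trace_iinj[out_idx] = segs[iseg].value(t);
    ++out_idx;
  }
  det.feed(t, y[0]);

  model_rhs(t, y, segs[iseg].value(t), p, k1);  // FSAL seed

  while (t < t_end - 1e-12) {
    // do not step across a segment boundary (Iinj may jump there)
    const double seg_end = segs[iseg].t1;
    if (h > max_step) h = max_step;
    if (t + h > seg_end) h = seg_end - t;
    if (h < hmin) stop("step size underflow at t=%f ms", t);

    const double iinj2 = segs[iseg].value(t + C2 * h);
    const double iinj3 = segs[iseg].value(t + C3 * h);
    const double iinj4 = segs[iseg].value(t + C4 * h);
    const double iinj5 = segs[iseg].value(t + C5 * h);
    const double iinj6 = segs[iseg].value(t + h);

    for (int i = 0; i < NSTATE; ++i) ysta[i] = y[i] + h * A21 * k1[i];
    model_rhs(t + C2 * h, ysta, iinj2, p, k2);
    for (int i = 0; i < NSTATE; ++i)
      ysta[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    model_rhs(t + C3 * h, ysta, iinj3, p, k3);
    for (int i = 0; i < NSTATE; ++i)
      ysta[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    model_rhs(t + C4 * h, ysta, iinj4, p, k4);
    for (int i = 0; i < NSTATE; ++i)
      ysta[i] = y[i] +
                h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] + A54 * k4[i]);
    model_rhs(t + C5 * h, ysta, iinj5, p, k5);
    for (int i = 0; i < NSTATE; ++i)
      ysta[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                            A64 * k4[i] + A65 * k5[i]);
    model_rhs(t + h, ysta, iinj6, p, k6);
    for (int i = 0; i < NSTATE; ++i)
      ynew[i] = y[i] + h * (A71 * k1[i] + A73 * k3[i] + A74 * k4[i] +
                            A75 * k5[i] + A76 * k6[i]);
    model_rhs(t + h, ynew, iinj6, p, k7);

    // error estimate
    double err = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      const double ei = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] +
                             E5 * k5[i] + E6 * k6[i] + E7 * k7[i]);
      const double sk =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double r = ei / sk;
      err += r * r;
    }
    err = std::sqrt(err / NSTATE);
    if (!std::isfinite(err)) {
      h *= 0.1;
      ++nreject;
      if (h < hmin) stop("integration produced non-finite state at t=%f", t);
      continue;
    }

    // PI step-size controller (beta = 0.04)
    const double expo = 0.2 - 0.04 * 0.75;
    double fac = std::pow(err, expo) / std::pow(facold, 0.04);
    fac = std::max(1.0 / 10.0, std::min(1.0 / 0.2, fac / 0.9));
    double hnew = h / fac;

    if (err <= 1.0) {
      // accepted
      facold = std::max(err, 1e-4);
      // dense output coefficients
      DenseStep ds;
      ds.t0 = t;
      ds.h = h;
      for (int i = 0; i < NSTATE; ++i) {
        const double ydiff = ynew[i] - y[i];
        const double bspl = h * k1[i] - ydiff;
        ds.r1[i] = y[i];
        ds.r2[i] = ydiff;
        ds.r3[i] = bspl;
        ds.r4[i] = ydiff - h * k7[i] - bspl;
        ds.r5[i] = h * (D1 * k1[i] + D3 * k3[i] + D4 * k4[i] + D5 * k5[i] +
                        D6 * k6[i] + D7 * k7[i]);
      }
      const double t_new = t + h;

      // spike scan across the step at scan_dt resolution
      {
        double ts = det.prev_t + scan_dt;
        double yv[NSTATE];
        while (ts < t_new - 1e-12) {
          ds.eval(ts, yv);
          const size_t before = det.spike_t.size();
          det.feed(ts, yv[0]);
          if (det.spike_t.size() > before)
            spike_iinj.push_back(segs[iseg].value(det.spike_t.back()));
          ts += scan_dt;
        }
        const size_t before = det.spike_t.size();
        det.feed(t_new, ynew[0]);
        if (det.spike_t.size() > before)
          spike_iinj.push_back(segs[iseg].value(det.spike_t.back()));
      }

      // trace sampling via dense output
      if (keep_trace) {
        while (out_idx < tout.size() && tout[out_idx] <= t_new + 1e-12) {
          double yv[NSTATE];
          ds.eval(tout[out_idx], yv);
          for (int i = 0; i < NSTATE; ++i) trace(out_idx, i) = yv[i];
          trace_iinj[out_idx] = segs[iseg].value(tout[out_idx]);
          ++out_idx;
        }
      }

      t = t_new;
      for (int i = 0; i < NSTATE; ++i) y[i] = ynew[i];
      if (y[7] < 0.0) y[7] = 0.0;  // Ca cannot be negative
      for (int i = 0; i < NSTATE; ++i) k1[i] = k7[i];  // FSAL
      ++naccept;
      first = false;

      // advance segment cursor; re-seed k1 because Iinj may jump
      if (t >= segs[iseg].t1 - 1e-12 && iseg + 1 < nseg) {
        ++iseg;
        t = segs[iseg].t0;
        model_rhs(t, y, segs[iseg].value(t), p, k1);
      }
      h = hnew;
    } else {
      hnew = h / std::min(1.0 / 0.2, std::pow(err, expo) / 0.9);
      if (!first) h = hnew;
      else h *= 0.1;
      ++nreject;
    }
    if ((naccept + nreject) % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector yfin(NSTATE);
  for (int i = 0; i < NSTATE; ++i) yfin[i] = y[i];

  List out = List::create(
      Named("final_state") = yfin,
      Named("spike_times") = wrap(det.spike_t),
      Named("spike_iinj") = wrap(spike_iinj),
      Named("n_accepted") = (double)naccept,
      Named("n_rejected") = (double)nreject);
  if (keep_trace) {
    out["time"] = wrap(tout);
    out["states"] = trace;
    out["iinj"] = trace_iinj;
  }
  return out;
}
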