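#include <Rcpp.h>
using namespace Rcpp;

// One-compartment model with first-order absorption from a subcutaneous
// depot and time-varying linear elimination:
//   dAa/dt = -ka * Aa
//   V dCp/dt = ka * Aa - CL(t) * Cp
// with CL(t) = cl0 * exp(emax * t / (t50h + t)), t in hours, t50h = 24 * T50[day].
// Doses are boluses into the depot. The system is smooth and non-stiff for
// antibody-scale rate constants, so classical RK4 with a capped step is used;
// steps always land exactly on dose and output times. Output at a time that
// coincides with a dose event is the pre-dose (trough) value.
//
// The batched solver integrates all parameter sets in lockstep over a shared
// dose schedule and output grid; when every row shares emax and t50 (the
// common case: finite-difference eta perturbations, population simulation
// with fixed effects on the time term) the clearance multiplier is evaluated
// once per stage time for the whole batch, which removes the dominant exp()
// cost.

static inline double frac_t(const double t, const double t50h) {
  return t / (t50h + t);
}

struct Batch {
  int m;                       // number of parameter sets
  std::vector<double> ka, v, cl0, emax, t50h;
  bool shared_time_term;       // all rows share emax and t50h
};

// derivative of all rows at stage time t, given per-row states (aa, cp)
static inline void deriv_batch(const Batch& b, const double t,
                               const double* aa, const double* cp,
                               double* daa, double* dcp) {
  if (b.shared_time_term) {
    const double mult = std::exp(b.emax[0] * frac_t(t, b.t50h[0]));
    for (int j = 0; j < b.m; ++j) {
      daa[j] = -b.ka[j] * aa[j];
      dcp[j] = (b.ka[j] * aa[j] - b.cl0[j] * mult * cp[j]) / b.v[j];
    }
  } else {
    for (int j = 0; j < b.m; ++j) {
      const double mult = std::exp(b.emax[j] * frac_t(t, b.t50h[j]));
      daa[j] = -b.ka[j] * aa[j];
      dcp[j] = (b.ka[j] * aa[j] - b.cl0[j] * mult * cp[j]) / b.v[j];
    }
  }
}

static void solve_batch(const std::vector<double>& dose_time,
                        const std::vector<double>& dose_amt,
                        const NumericVector& times, const Batch& b,
                        const double hmax, NumericMatrix& out) {
  const int n_out = times.size();
  const int n_dose = dose_time.size();
  const int m = b.m;

  std::vector<double> knots;
  knots.reserve(n_out + n_dose + 1);
  knots.push_back(0.0);
  for (int i = 0; i < n_dose; ++i) knots.push_back(dose_time[i]);
  for (int i = 0; i < n_out; ++i) knots.push_back(times[i]);
  std::sort(knots.begin(), knots.end());
  knots.erase(std::unique(knots.begin(), knots.end()), knots.end());

  std::vector<double> aa(m, 0.0), cp(m, 0.0);
  std::vector<double> k1a(m), k1c(m), k2a(m), k2c(m), k3a(m), k3c(m),
      k4a(m), k4c(m), ta(m), tc(m);
  double t = 0.0;
  int i_dose = 0, i_out = 0;

  for (size_t k = 0; k < knots.size(); ++k) {
    const double tk = knots[k];
    if (tk > t) {
      const int nsub = (int)std::ceil((tk - t) / hmax);
      const double h = (tk - t) / nsub;
      for (int s = 0; s < nsub; ++s) {
        deriv_batch(b, t, aa.data(), cp.data(), k1a.data(), k1c.data());
        for (int j = 0; j < m; ++j) {
          ta[j] = aa[j] + 0.5 * h * k1a[j];
          tc[j] = cp[j] + 0.5 * h * k1c[j];
        }
        deriv_batch(b, t + 0.5 * h, ta.data(), tc.data(), k2a.data(),
                    k2c.data());
        for (int j = 0; j < m; ++j) {
          ta[j] = aa[j] + 0.5 * h * k2a[j];
          tc[j] = cp[j] + 0.5 * h * k2c[j];
        }
        deriv_batch(b, t + 0.5 * h, ta.data(), tc.data(), k3a.data(),
                    k3c.data());
        for (int j = 0; j < m; ++j) {
          ta[j] = aa[j] + h * k3a[j];
          tc[j] = cp[j] + h * k3c[j];
        }
        deriv_batch(b, t + h, ta.data(), tc.data(), k4a.data(), k4c.data());
        for (int j = 0; j < m; ++j) {
          aa[j] += h / 6.0 * (k1a[j] + 2.0 * k2a[j] + 2.0 * k3a[j] + k4a[j]);
          cp[j] += h / 6.0 * (k1c[j] + 2.0 * k2c[j] + 2.0 * k3c[j] + k4c[j]);
        }
        t += h;
      }
      t = tk;  // guard against roundoff drift
    }
    while (i_out < n_out && times[i_out] == tk) {
      for (int j = 0; j < m; ++j) out(i_out, j) = cp[j];
      ++i_out;
    }
    while (i_dose < n_dose && dose_time[i_dose] == tk) {
      for (int j = 0; j < m; ++j) aa[j] += dose_amt[i_dose];
      ++i_dose;
    }
  }
}

// Batched solver: one row of `theta` per parameter set, columns
// (ka, v, cl0, emax, t50h); shared dose schedule and output grid.
// [[Rcpp::export(name = ".solve_onecomp_multi_cpp")]]
NumericMatrix solve_onecomp_multi_cpp(NumericVector dose_time,
                                      NumericVector dose_amt,
                                      NumericVector times, NumericMatrix theta,
                                      double hmax) {
  const int m = theta.nrow();
  Batch b;
  b.m = m;
  b.ka.resize(m); b.v.resize(m); b.cl0.resize(m);
  b.emax.resize(m); b.t50h.resize(m);
  for (int j = 0; j < m; ++j) {
    b.ka[j] = theta(j, 0);
    b.v[j] = theta(j, 1);
    b.cl0[j] = theta(j, 2);
    b.emax[j] = theta(j, 3);
    b.t50h[j] = theta(j, 4);
  }
  b.shared_time_term = true;
  for (int j = 1; j < m; ++j) {
    if (b.emax[j] != b.emax[0] || b.t50h[j] != b.t50h[0]) {
      b.shared_time_term = false;
      break;
    }
  }
  NumericMatrix out(times.size(), m);
  std::vector<double> dt(dose_time.begin(), dose_time.end());
  std::vector<double> da(dose_amt.begin(), dose_amt.end());
  solve_batch(dt, da, times, b, hmax, out);
  return out;
}

// [[Rcpp::export(name = ".solve_onecomp_cpp")]]
NumericVector solve_onecomp_cpp(NumericVector dose_time, NumericVector dose_amt,
                                NumericVector times, double ka, double v,
                                double cl0, double emax, double t50h,
                                double hmax) {
  NumericMatrix theta(1, 5);
  theta(0, 0) = ka; theta(0, 1) = v; theta(0, 2) = cl0;
  theta(0, 3) = emax; theta(0, 4) = t50h;
  NumericMatrix out = solve_onecomp_multi_cpp(dose_time, dose_amt, times,
                                              theta, hmax);
  return out(_, 0);
}
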