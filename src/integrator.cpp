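// Trajectory engine for the coupled Morse-Morse-harmonic (bond-bond-bend)
// Hamiltonian with kinetic momentum-momentum coupling:
//
//   H = sum_i [ (1/2) G_ii p_i^2 + V_i(q_i) ] + eps * sum_{i<j} G_ij p_i p_j
//
// V_1, V_2 Morse; V_3 harmonic. All quantities in atomic units (hbar = 1).
// Propagation uses the Dormand-Prince 8(5,3) adaptive Runge-Kutta method with
// optional co-integration of the variational (tangent) equations for the fast
// Lyapunov indicator, and event detection for bond dissociation (q > q_diss)
// with bisection refinement of the crossing time.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "dop853_coefficients.h"

using namespace Rcpp;

struct Model {
  double G11, G22, G33, G12, G13, G23;
  double D1, D2, a1, a2;
  double q01, q02, q03;
  double w3;     // bend angular frequency, au
  double eps;    // coupling scale
  double qdiss;  // dissociation threshold, bohr
};

static Model make_model(const NumericVector &p) {
  Model m;
  m.G11 = p[0];  m.G22 = p[1];  m.G33 = p[2];
  m.G12 = p[3];  m.G13 = p[4];  m.G23 = p[5];
  m.D1 = p[6];   m.D2 = p[7];   m.a1 = p[8];  m.a2 = p[9];
  m.q01 = p[10]; m.q02 = p[11]; m.q03 = p[12];
  m.w3 = p[13];  m.eps = p[14]; m.qdiss = p[15];
  return m;
}

// Morse potential and derivatives at displacement x = q - q0
static inline double morse_v(double D, double a, double x) {
  double e = std::exp(-a * x);
  double u = 1.0 - e;
  return D * u * u;
}
static inline double morse_dv(double D, double a, double x) {
  double e = std::exp(-a * x);
  return 2.0 * D * a * e * (1.0 - e);
}
static inline double morse_d2v(double D, double a, double x) {
  double e = std::exp(-a * x);
  return 2.0 * D * a * a * e * (2.0 * e - 1.0);
}

static inline double hamiltonian(const Model &m, const double *y) {
  const double q1 = y[0], q2 = y[1], q3 = y[2];
  const double p1 = y[3], p2 = y[4], p3 = y[5];
  double kin = 0.5 * (m.G11 * p1 * p1 + m.G22 * p2 * p2 + m.G33 * p3 * p3) +
               m.eps * (m.G12 * p1 * p2 + m.G13 * p1 * p3 + m.G23 * p2 * p3);
  double x3 = q3 - m.q03;
  double pot = morse_v(m.D1, m.a1, q1 - m.q01) +
               morse_v(m.D2, m.a2, q2 - m.q02) +
               0.5 * m.w3 * m.w3 * x3 * x3 / m.G33;
  return kin + pot;
}

// Equations of motion; if n == 12 the tangent (variational) block follows.
static inline void rhs(const Model &m, const double *y, double *dy, int n) {
  const double p1 = y[3], p2 = y[4], p3 = y[5];
  dy[0] = m.G11 * p1 + m.eps * (m.G12 * p2 + m.G13 * p3);
  dy[1] = m.G22 * p2 + m.eps * (m.G12 * p1 + m.G23 * p3);
  dy[2] = m.G33 * p3 + m.eps * (m.G13 * p1 + m.G23 * p2);
  dy[3] = -morse_dv(m.D1, m.a1, y[0] - m.q01);
  dy[4] = -morse_dv(m.D2, m.a2, y[1] - m.q02);
  dy[5] = -(m.w3 * m.w3 / m.G33) * (y[2] - m.q03);
  if (n == 12) {
    const double dq1 = y[6], dq2 = y[7], dq3 = y[8];
    const double dp1 = y[9], dp2 = y[10], dp3 = y[11];
    dy[6] = m.G11 * dp1 + m.eps * (m.G12 * dp2 + m.G13 * dp3);
    dy[7] = m.G22 * dp2 + m.eps * (m.G12 * dp1 + m.G23 * dp3);
    dy[8] = m.G33 * dp3 + m.eps * (m.G13 * dp1 + m.G23 * dp2);
    dy[9]  = -morse_d2v(m.D1, m.a1, y[0] - m.q01) * dq1;
    dy[10] = -morse_d2v(m.D2, m.a2, y[1] - m.q02) * dq2;
    dy[11] = -(m.w3 * m.w3 / m.G33) * dq3;
  }
}

struct Stepper {
  const Model *m;
  int n;
  double rtol, atol;
  double h;            // current step size
  long n_steps, n_rejected;
  double K[DOP_NSTAGES][12];

  Stepper(const Model *m_, int n_, double rtol_, double atol_, double h0)
    : m(m_), n(n_), rtol(rtol_), atol(atol_), h(h0),
      n_steps(0), n_rejected(0) {}

  // One adaptive step from (t, y); returns the accepted step size taken.
  // hmax caps the step (to land on output/event boundaries).
  double step(double &t, double *y, double hmax) {
    double ynew[12], err5[12], err3[12];
    for (;;) {
      double htry = std::min(h, hmax);
      if (htry <= 1e-14)
        stop("step size underflow in trajectory integration");
      // stages
      rhs(*m, y, K[0], n);
      for (int s = 1; s < DOP_NSTAGES; ++s) {
        double ytmp[12];
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int j = 0; j < s; ++j) acc += DOP_A[s][j] * K[j][i];
          ytmp[i] = y[i] + htry * acc;
        }
        rhs(*m, ytmp, K[s], n);
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < DOP_NSTAGES; ++j) acc += DOP_B[j] * K[j][i];
        ynew[i] = y[i] + htry * acc;
      }
      // embedded error estimate (5th and 3rd order correctors)
      double e5n = 0.0, e3n = 0.0;
      for (int i = 0; i < n; ++i) {
        double a5 = 0.0, a3 = 0.0;
        for (int j = 0; j < DOP_NSTAGES; ++j) {
          a5 += DOP_E5[j] * K[j][i];
          a3 += DOP_E3[j] * K[j][i];
        }
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        err5[i] = a5 / sc; err3[i] = a3 / sc;
        e5n += err5[i] * err5[i];
        e3n += err3[i] * err3[i];
      }
      double err;
      if (e5n == 0.0 && e3n == 0.0) {
        err = 0.0;
      } else {
        double denom = e5n + 0.01 * e3n;
        err = std::fabs(htry) * e5n / std::sqrt(denom * n);
      }
      double factor = (err == 0.0) ? 5.0
        : std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -1.0 / 8.0)));
      if (err <= 1.0) {
        t += htry;
        for (int i = 0; i < n; ++i) y[i] = ynew[i];
        ++n_steps;
        if (htry >= h || factor > 1.0) h = htry * factor;
        return htry;
      }
      ++n_rejected;
      h = htry * factor;
    }
  }

  // Advance exactly to t_target.
  void advance_to(double &t, double *y, double t_target) {
    while (t < t_target - 1e-12) step(t, y, t_target - t);
  }
};

// Bisection refinement of the first q_k > qdiss crossing inside (t0, t1],
// starting from state y0 at t0. Returns crossing time; tol_t in au.
static double refine_event(const Model &m, int n, double rtol, double atol,
                           double t0, const double *y0, double t1, int bond,
                           double tol_t) {
  double lo = t0, hi = t1;
  double base[12];
  for (int i = 0; i < n; ++i) base[i] = y0[i];
  double tb = t0;
  while (hi - lo > tol_t) {
    double mid = 0.5 * (lo + hi);
    double y[12];
    for (int i = 0; i < n; ++i) y[i] = base[i];
    Stepper st(&m, n, rtol, atol, mid - tb);
    double t = tb;
    st.advance_to(t, y, mid);
    double q = (bond == 1) ? y[0] : y[1];
    if (q > m.qdiss) {
      hi = mid;
    } else {
      lo = mid;
      for (int i = 0; i < n; ++i) base[i] = y[i];
      tb = mid;
    }
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
List integrate_cpp(NumericVector y0, NumericVector pars, double t_final,
                   double dt_out, double rtol, double atol,
                   bool event_enabled, bool with_tangent,
                   NumericVector v0, bool store_series,
                   double renorm_log10 = 6.0) {
  Model m = make_model(pars);
  const int n = with_tangent ? 12 : 6;
  double y[12];
  for (int i = 0; i < 6; ++i) y[i] = y0[i];
  if (with_tangent) {
    double vn = 0.0;
    for (int i = 0; i < 6; ++i) vn += v0[i] * v0[i];
    vn = std::sqrt(vn);
    if (!(vn > 0.0)) stop("initial tangent vector must be non-zero");
    for (int i = 0; i < 6; ++i) y[6 + i] = v0[i] / vn;
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(y[i])) stop("non-finite initial state");

  const double E0 = hamiltonian(m, y);
  const double Escale = std::max(std::fabs(E0), 1e-12);
  const int n_out = (int) std::floor(t_final / dt_out + 1e-9) + 1;

  std::vector<double> t_out, fli_out;
  std::vector<double> series;  // row-major 6 columns if store_series
  t_out.reserve(n_out);
  if (with_tangent) fli_out.reserve(n_out);
  if (store_series) series.reserve((size_t) n_out * 6);

  double log10_acc = 0.0;   // accumulated log10 norm from renormalizations
  double fli_run = 0.0;     // running sup of log10 ||v||
  double drift_max = 0.0;
  double lifetime = NA_REAL;
  int bond = 0;
  bool dissociated = false;

  Stepper st(&m, n, rtol, atol, dt_out > 0 ? std::min(dt_out, 50.0) : 50.0);
  double t = 0.0;

  auto record = [&](double tt) {
    t_out.push_back(tt);
    if (store_series)
      for (int i = 0; i < 6; ++i) series.push_back(y[i]);
    if (with_tangent) fli_out.push_back(fli_run);
    double dr = std::fabs(hamiltonian(m, y) - E0) / Escale;
    if (dr > drift_max) drift_max = dr;
  };

  record(0.0);
  double yprev[12];
  for (int k = 1; k < n_out && !dissociated; ++k) {
    double t_target = k * dt_out;
    while (t < t_target - 1e-12) {
      double tstep0 = t;
      for (int i = 0; i < n; ++i) yprev[i] = y[i];
      st.step(t, y, t_target - t);
      if (with_tangent) {
        double vn = 0.0;
        for (int i = 6; i < 12; ++i) vn += y[i] * y[i];
        double l10 = 0.5 * std::log10(vn);
        if (log10_acc + l10 > fli_run) fli_run = log10_acc + l10;
        if (l10 > renorm_log10) {
          double inv = std::pow(10.0, -l10);
          for (int i = 6; i < 12; ++i) y[i] *= inv;
          log10_acc += l10;
        }
      }
      if (event_enabled && (y[0] > m.qdiss || y[1] > m.qdiss)) {
        bond = (y[0] > m.qdiss) ? 1 : 2;
        // refine to <= 1 fs (41.34 au)
        lifetime = refine_event(m, n, rtol, atol, tstep0, yprev, t, bond, 41.34);
        dissociated = true;
        record(lifetime);
        break;
      }
    }
    if (!dissociated) record(t_target);
  }

  int nr = (int) t_out.size();
  NumericVector tv(nr);
  for (int i = 0; i < nr; ++i) tv[i] = t_out[i];
  List out = List::create(
    _["t"] = tv,
    _["lifetime"] = lifetime,
    _["bond"] = bond,
    _["dissociated"] = dissociated,
    _["drift_max"] = drift_max,
    _["energy0"] = E0,
    _["n_steps"] = (double) st.n_steps,
    _["n_rejected"] = (double) st.n_rejected,
    _["y_final"] = NumericVector(y, y + 6));
  if (store_series) {
    NumericMatrix Y(nr, 6);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < 6; ++j) Y(i, j) = series[(size_t) i * 6 + j];
    out["y"] = Y;
  }
  if (with_tangent) {
    NumericVector fv(nr);
    for (int i = 0; i < nr; ++i) fv[i] = fli_out[i];
    out["fli"] = fv;
    out["fli_final"] = fli_run;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector hamiltonian_cpp(NumericMatrix Y, NumericVector pars) {
  Model m = make_model(pars);
  int nr = Y.nrow();
  NumericVector out(nr);
  double y[6];
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < 6; ++j) {
      y[j] = Y(i, j);
      if (!std::isfinite(y[j])) stop("non-finite phase-space point (row %d)", i + 1);
    }
    out[i] = hamiltonian(m, y);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix eom_cpp(NumericMatrix Y, NumericVector pars) {
  Model m = make_model(pars);
  int nr = Y.nrow();
  NumericMatrix out(nr, 6);
  double y[6], dy[6];
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < 6; ++j) y[j] = Y(i, j);
    rhs(m, y, dy, 6);
    for (int j = 0; j < 6; ++j) out(i, j) = dy[j];
  }
  return out;
}
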