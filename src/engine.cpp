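// Explicit time-stepping loop for the plain and TENG-coupled cable
// equation. Mirrors the pure-R reference steppers (step_plain,
// step_coupled): forward-Euler voltage update with denominator C_m - C(x)
// on coupled compartments, exponential-Euler gating at the pre-step
// voltage, sealed ends, triangular gap trajectory and piecewise-linear
// device-curve interpolation with node-derivative tables.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// a * x / (exp(x/b) - 1) with the removable singularity at x = 0
static inline double vtrap(double a, double x, double b) {
  if (std::fabs(x / b) < 1e-6) return a * b * (1.0 - x / (2.0 * b));
  return a * x / expm1(x / b);
}

struct Rates { double an, bn, am, bm, ah, bh; };

static inline Rates rates_at(double V, double V_rest) {
  double u = V - V_rest;
  Rates r;
  r.an = vtrap(0.01, 10.0 - u, 10.0);
  r.bn = 0.125 * std::exp(-u / 80.0);
  r.am = vtrap(0.1, 25.0 - u, 10.0);
  r.bm = 4.0 * std::exp(-u / 18.0);
  r.ah = 0.07 * std::exp(-u / 20.0);
  r.bh = 1.0 / (std::exp((30.0 - u) / 10.0) + 1.0);
  return r;
}

// linear interpolation matching stats::approx arithmetic
static inline double lin(const NumericVector& gx, const NumericVector& gy,
                         double x, int& hint) {
  int n = gx.size();
  if (x <= gx[0]) return gy[0];
  if (x >= gx[n - 1]) return gy[n - 1];
  int k = hint;
  if (k < 0 || k >= n - 1 || x < gx[k] || x > gx[k + 1]) {
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2;
      if (gx[mid] <= x) lo = mid; else hi = mid; }
    k = lo;
  }
  hint = k;
  return gy[k] + (x - gx[k]) * (gy[k + 1] - gy[k]) / (gx[k + 1] - gx[k]);
}

// triangular contact-release trajectory; t in ms, x in cm, dxdt in cm/s
static inline void trajectory(double t, double v, double x_min,
                              double x_max, double t_start,
                              double& x, double& dxdt) {
  if (v == 0.0) { x = x_max; dxdt = 0.0; return; }
  double D = x_max - x_min;
  double dtms = t - t_start;
  if (dtms < 0.0) { x = x_max; dxdt = 0.0; return; }
  if (dtms == 0.0) { x = x_max; dxdt = -v; return; }
  double tau = dtms * (v / 1000.0);
  // periodic reduction; same arithmetic as R's %% operator
  double period = 2.0 * D;
  double s = tau - std::floor(tau / period) * period;
  if (s == 0.0)      { x = x_max; dxdt = v; }
  else if (s < D)    { x = x_max - s; dxdt = -v; }
  else if (s == D)   { x = x_min; dxdt = -v; }
  else               { x = x_min + (s - D); dxdt = v; }
}

// [[Rcpp::export]]
List run_axon_cpp(NumericVector V0, NumericVector n0, NumericVector m0,
                  NumericVector h0, double dt, int nsteps, int every,
                  double lap_k, double dz,
                  double E_Na, double E_K, double E_L,
                  double gbar_Na, double gbar_K, double g_L,
                  double C_m, double V_rest,
                  IntegerVector stim_idx, double stim_amp,
                  double stim_on, double stim_off,
                  bool coupled, IntegerVector coupled_idx,
                  NumericVector prof,
                  NumericVector cg, NumericVector cvoc, NumericVector ccap,
                  NumericVector cdvoc, NumericVector cdcap) {
  const int n = V0.size();
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> gn(n0.begin(), n0.end());
  std::vector<double> gm(m0.begin(), m0.end());
  std::vector<double> gh(h0.begin(), h0.end());
  std::vector<double> Vn(n), d2(n);
  std::vector<char> is_stim(n, 0), is_coup(n, 0);
  for (int k = 0; k < stim_idx.size(); ++k) is_stim[stim_idx[k]] = 1;
  for (int k = 0; k < coupled_idx.size(); ++k) is_coup[coupled_idx[k]] = 1;
  const double v_sp = prof[0], x_min = prof[1], x_max = prof[2],
               t_start = prof[3];
  const double dz2 = dz * dz;

  const int nrec = nsteps / every + 1;
  NumericMatrix Vrec(nrec, n);
  NumericVector times(nrec), xrec(nrec);
  for (int j = 0; j < n; ++j) Vrec(0, j) = V[j];
  times[0] = 0.0;
  if (coupled) {
    double x0, dx0; trajectory(0.0, v_sp, x_min, x_max, t_start, x0, dx0);
    xrec[0] = x0;
  } else xrec[0] = NA_REAL;
  int rec = 0, hint = -1;

  for (int s = 1; s <= nsteps; ++s) {
    const double t = (s - 1) * dt;
    double cap = 0.0, a_drv = 0.0, b_drv = 0.0, voc = 0.0;
    if (coupled) {
      double x, dxdt;
      trajectory(t, v_sp, x_min, x_max, t_start, x, dxdt);
      voc  = lin(cg, cvoc, x, hint);
      cap  = lin(cg, ccap, x, hint);
      double dvoc = lin(cg, cdvoc, x, hint);
      double dcap = lin(cg, cdcap, x, hint);
      if (cap >= C_m)
        stop("device capacitance reaches C_m at gap %g cm", x);
      double v_ms = dxdt / 1000.0;
      a_drv = -dcap * v_ms;          // multiplies (voc - V)
      b_drv = -cap * dvoc * v_ms;
    }
    const bool stim_now = (stim_amp != 0.0 && t >= stim_on && t < stim_off);

    // sealed-end Laplacian
    d2[0] = V[1] - V[0];
    d2[n - 1] = V[n - 2] - V[n - 1];
    for (int j = 1; j < n - 1; ++j)
      d2[j] = V[j - 1] - 2.0 * V[j] + V[j + 1];

    for (int j = 0; j < n; ++j) {
      const double Vj = V[j];
      const double n4 = gn[j] * gn[j] * gn[j] * gn[j];
      const double m3 = gm[j] * gm[j] * gm[j];
      const double Iion = gbar_K * n4 * (Vj - E_K)
                        + gbar_Na * m3 * gh[j] * (Vj - E_Na)
                        + g_L * (Vj - E_L);
      const double Is = (stim_now && is_stim[j]) ? stim_amp : 0.0;
      double drive = 0.0, denom = C_m;
      if (coupled && is_coup[j]) {
        drive = a_drv * (voc - Vj) + b_drv;
        denom = C_m - cap;
      }
      const double lap = lap_k * d2[j] / dz2;
      Vn[j] = Vj + (dt / denom) * (lap + Is + drive - Iion);
      if (!std::isfinite(Vn[j]))
        stop("instability: non-finite voltage at t=%g ms (dt=%g, dz=%g)",
             t, dt, dz);
      // exponential-Euler gating at the pre-step voltage
      const Rates r = rates_at(Vj, V_rest);
      double xinf;
      xinf = r.an / (r.an + r.bn);
      gn[j] = xinf + (gn[j] - xinf) * std::exp(-dt * (r.an + r.bn));
      xinf = r.am / (r.am + r.bm);
      gm[j] = xinf + (gm[j] - xinf) * std::exp(-dt * (r.am + r.bm));
      xinf = r.ah / (r.ah + r.bh);
      gh[j] = xinf + (gh[j] - xinf) * std::exp(-dt * (r.ah + r.bh));
    }
    std::swap(V, Vn);

    if (s % every == 0) {
      ++rec;
      for (int j = 0; j < n; ++j) Vrec(rec, j) = V[j];
      const double ts = s * dt;
      times[rec] = ts;
      if (coupled) {
        double x, dxdt;
        trajectory(ts, v_sp, x_min, x_max, t_start, x, dxdt);
        xrec[rec] = x;
      } else xrec[rec] = NA_REAL;
    }
  }
  return List::create(_["times"] = times, _["V"] = Vrec, _["x"] = xrec,
                      _["n"] = NumericVector(gn.begin(), gn.end()),
                      _["m"] = NumericVector(gm.begin(), gm.end()),
                      _["h"] = NumericVector(gh.begin(), gh.end()));
}
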