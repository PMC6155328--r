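// Fewest-switches surface hopping on a two-state diabatic model:
// per-state constant + linear + diagonal-quadratic diabatic surfaces with a
// Gaussian (or constant) coupling, velocity Verlet nuclei, RK4 electronic
// substeps in the adiabatic basis with analytic derivative couplings from the
// 2x2 diabatic-to-adiabatic rotation. Coordinates are mass-weighted (unit
// mass), energies hartree, time atomic units.
#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;

struct DiabModel {
  int n;
  double e0[2];
  std::vector<double> x0, g, w2;  // 2*n each, state-major
  double cs, cw;                  // coupling strength / width (Inf = constant)
  std::vector<double> cc;         // coupling center
  bool const_cpl;
};

static DiabModel parse_model(const List& m) {
  DiabModel md;
  NumericVector e0 = m["e0"];
  NumericMatrix x0 = m["centers"], g = m["linear"], w2 = m["quad"];
  md.n = x0.ncol();
  md.e0[0] = e0[0]; md.e0[1] = e0[1];
  md.x0.resize(2 * md.n); md.g.resize(2 * md.n); md.w2.resize(2 * md.n);
  for (int s = 0; s < 2; ++s)
    for (int i = 0; i < md.n; ++i) {
      md.x0[s * md.n + i] = x0(s, i);
      md.g[s * md.n + i] = g(s, i);
      md.w2[s * md.n + i] = w2(s, i);
    }
  md.cs = as<double>(m["coupling_strength"]);
  md.cw = as<double>(m["coupling_width"]);
  NumericVector cc = m["coupling_center"];
  md.cc.assign(cc.begin(), cc.end());
  md.const_cpl = !R_finite(md.cw);
  return md;
}

// Diabatic energies and gradients at x.
static void diabatic(const DiabModel& md, const std::vector<double>& x,
                     double V[2], double V12[1],
                     std::vector<double>& dV1, std::vector<double>& dV2,
                     std::vector<double>& dV12) {
  for (int s = 0; s < 2; ++s) {
    double e = md.e0[s];
    std::vector<double>& dV = (s == 0) ? dV1 : dV2;
    for (int i = 0; i < md.n; ++i) {
      double dx = x[i] - md.x0[s * md.n + i];
      e += md.g[s * md.n + i] * dx + 0.5 * md.w2[s * md.n + i] * dx * dx;
      dV[i] = md.g[s * md.n + i] + md.w2[s * md.n + i] * dx;
    }
    V[s] = e;
  }
  if (md.const_cpl) {
    V12[0] = md.cs;
    std::fill(dV12.begin(), dV12.end(), 0.0);
  } else {
    double r2 = 0;
    for (int i = 0; i < md.n; ++i) {
      double d = x[i] - md.cc[i];
      r2 += d * d;
    }
    double v = md.cs * std::exp(-r2 / (2 * md.cw * md.cw));
    V12[0] = v;
    for (int i = 0; i < md.n; ++i)
      dV12[i] = -v * (x[i] - md.cc[i]) / (md.cw * md.cw);
  }
}

// Adiabatic energies, gradients, 2x2 eigenvector matrix U (columns = lower,
// upper states in the diabatic basis) and derivative coupling d01.
struct AdiabPoint {
  double E[2];
  std::vector<double> grad0, grad1, d01;
  double U[2][2];   // U[diabatic][adiabatic]
  double gap, V12;
};

static void adiabatic(const DiabModel& md, const std::vector<double>& x,
                      AdiabPoint& ap, const double* Uprev) {
  double V[2], V12;
  std::vector<double> dV1(md.n), dV2(md.n), dV12(md.n);
  diabatic(md, x, V, &V12, dV1, dV2, dV12);
  double h = 0.5 * (V[0] - V[1]);
  double avg = 0.5 * (V[0] + V[1]);
  double rho = std::sqrt(h * h + V12 * V12);
  ap.E[0] = avg - rho;
  ap.E[1] = avg + rho;
  ap.gap = 2 * rho;
  ap.V12 = V12;
  // eigenvectors: H = [[V11, V12], [V12, V22]]
  // lower eigenvector v0 with H v0 = E0 v0
  double v0[2], v1[2];
  if (std::fabs(V12) < 1e-300) {
    if (V[0] <= V[1]) { v0[0] = 1; v0[1] = 0; v1[0] = 0; v1[1] = 1; }
    else { v0[0] = 0; v0[1] = 1; v1[0] = 1; v1[1] = 0; }
  } else {
    double t0[2] = { V12, ap.E[0] - V[0] };
    double n0 = std::sqrt(t0[0] * t0[0] + t0[1] * t0[1]);
    v0[0] = t0[0] / n0; v0[1] = t0[1] / n0;
    v1[0] = -v0[1]; v1[1] = v0[0];
  }
  // phase continuity with the previous step's eigenvectors
  if (Uprev) {
    if (v0[0] * Uprev[0] + v0[1] * Uprev[1] < 0) { v0[0] = -v0[0]; v0[1] = -v0[1]; }
    if (v1[0] * Uprev[2] + v1[1] * Uprev[3] < 0) { v1[0] = -v1[0]; v1[1] = -v1[1]; }
  }
  ap.U[0][0] = v0[0]; ap.U[1][0] = v0[1];
  ap.U[0][1] = v1[0]; ap.U[1][1] = v1[1];
  ap.grad0.resize(md.n); ap.grad1.resize(md.n); ap.d01.resize(md.n);
  double denom = ap.E[1] - ap.E[0];
  for (int i = 0; i < md.n; ++i) {
    double davg = 0.5 * (dV1[i] + dV2[i]);
    double dh = 0.5 * (dV1[i] - dV2[i]);
    double drho = (rho > 1e-300) ? (h * dh + V12 * dV12[i]) / rho : 0.0;
    ap.grad0[i] = davg - drho;
    ap.grad1[i] = davg + drho;
    // d01 = <v0| dH |v1> / (E1 - E0); dH = [[dV1, dV12], [dV12, dV2]]
    double num = v0[0] * (dV1[i] * v1[0] + dV12[i] * v1[1]) +
                 v0[1] * (dV12[i] * v1[0] + dV2[i] * v1[1]);
    ap.d01[i] = (denom > 1e-12) ? num / denom : 0.0;
  }
}

// d/dt of adiabatic amplitudes: dc0 = -i E0 c0 - D c1 ; dc1 = -i E1 c1 + D c0
// with D = v . d01 (d10 = -d01).
static inline void el_deriv(double E0, double E1, double D,
                            const cplx c[2], cplx out[2]) {
  out[0] = cplx(0, -1) * E0 * c[0] - D * c[1];
  out[1] = cplx(0, -1) * E1 * c[1] + D * c[0];
}

// [[Rcpp::export(name = ".fssh_trajectory_cpp")]]
List fssh_trajectory_cpp(List model, NumericVector x_init, NumericVector p_init,
                         int active_init, double dt, int n_steps, int substeps,
                         int record_stride, bool allow_hops,
                         bool reverse_frustrated) {
  DiabModel md = parse_model(model);
  std::vector<double> x(x_init.begin(), x_init.end());
  std::vector<double> v(p_init.begin(), p_init.end());  // unit mass: p = v
  int active = active_init;                             // 0 = lower adiabatic
  cplx c[2] = { cplx(0, 0), cplx(0, 0) };
  c[active] = cplx(1, 0);

  AdiabPoint ap, ap_new;
  adiabatic(md, x, ap, nullptr);
  double e_total0 = ap.E[active];
  for (int i = 0; i < md.n; ++i) e_total0 += 0.5 * v[i] * v[i];

  int n_rec = n_steps / record_stride + 1;
  NumericVector r_time(n_rec), r_pop0(n_rec), r_gap(n_rec), r_dcpl(n_rec),
      r_pdiab1(n_rec), r_etot(n_rec), r_norm(n_rec);
  IntegerVector r_active(n_rec);
  NumericMatrix r_x(n_rec, md.n);
  std::vector<double> hop_time, hop_prob, hop_xi, hop_ke;
  std::vector<int> hop_from, hop_to, hop_acc;

  double max_drift = 0, max_norm_dev = 0;
  int irec = 0;
  auto record = [&](double t) {
    r_time[irec] = t;
    r_pop0[irec] = std::norm(c[0]);
    r_active[irec] = active;
    r_gap[irec] = ap.gap;
    double D = 0;
    for (int i = 0; i < md.n; ++i) D += v[i] * ap.d01[i];
    r_dcpl[irec] = D;
    cplx cd0 = ap.U[0][0] * c[0] + ap.U[0][1] * c[1];
    r_pdiab1[irec] = std::norm(cd0);
    double etot = ap.E[active];
    for (int i = 0; i < md.n; ++i) etot += 0.5 * v[i] * v[i];
    r_etot[irec] = etot;
    r_norm[irec] = std::norm(c[0]) + std::norm(c[1]);
    for (int i = 0; i < md.n; ++i) r_x(irec, i) = x[i];
    ++irec;
  };
  record(0.0);

  for (int step = 0; step < n_steps; ++step) {
    // velocity Verlet on the active adiabatic surface
    const std::vector<double>& grad = (active == 0) ? ap.grad0 : ap.grad1;
    std::vector<double> a_old(md.n);
    for (int i = 0; i < md.n; ++i) {
      a_old[i] = -grad[i];
      x[i] += v[i] * dt + 0.5 * a_old[i] * dt * dt;
    }
    adiabatic(md, x, ap_new, &ap.U[0][0]);
    const std::vector<double>& grad_new = (active == 0) ? ap_new.grad0 : ap_new.grad1;
    double D_old = 0, D_new = 0;
    for (int i = 0; i < md.n; ++i) {
      double v_half = v[i] + 0.5 * a_old[i] * dt;  // mid-step velocity estimate
      D_old += v_half * ap.d01[i];
      v[i] += 0.5 * (a_old[i] - grad_new[i]) * dt;
      D_new += v[i] * ap_new.d01[i];
    }

    // electronic propagation across the step: RK4 substeps, linear
    // interpolation of E and of the scalar coupling D = v . d01
    double g_hop = 0.0;
    double h = dt / substeps;
    for (int ss = 0; ss < substeps; ++ss) {
      double f0 = (double)ss / substeps, f1 = (double)(ss + 1) / substeps;
      double fm = (f0 + f1) / 2;
      double E0a = ap.E[0] + f0 * (ap_new.E[0] - ap.E[0]);
      double E1a = ap.E[1] + f0 * (ap_new.E[1] - ap.E[1]);
      double Da = D_old + f0 * (D_new - D_old);
      double E0m = ap.E[0] + fm * (ap_new.E[0] - ap.E[0]);
      double E1m = ap.E[1] + fm * (ap_new.E[1] - ap.E[1]);
      double Dm = D_old + fm * (D_new - D_old);
      double E0b = ap.E[0] + f1 * (ap_new.E[0] - ap.E[0]);
      double E1b = ap.E[1] + f1 * (ap_new.E[1] - ap.E[1]);
      double Db = D_old + f1 * (D_new - D_old);
      cplx k1[2], k2[2], k3[2], k4[2], ct[2];
      el_deriv(E0a, E1a, Da, c, k1);
      ct[0] = c[0] + 0.5 * h * k1[0]; ct[1] = c[1] + 0.5 * h * k1[1];
      el_deriv(E0m, E1m, Dm, ct, k2);
      ct[0] = c[0] + 0.5 * h * k2[0]; ct[1] = c[1] + 0.5 * h * k2[1];
      el_deriv(E0m, E1m, Dm, ct, k3);
      ct[0] = c[0] + h * k3[0]; ct[1] = c[1] + h * k3[1];
      el_deriv(E0b, E1b, Db, ct, k4);
      c[0] += h / 6.0 * (k1[0] + 2.0 * k2[0] + 2.0 * k3[0] + k4[0]);
      c[1] += h / 6.0 * (k1[1] + 2.0 * k2[1] + 2.0 * k3[1] + k4[1]);
      // fewest-switches flux out of the active state: with D = v.d01 and
      // d10 = -d01, b_{other,active} = -2 Re(c_other^* c_active) D_{other,active}
      // = +2 D Re(c_active^* c_other) for active = 0 (lower), -2 D Re(...) for
      // active = 1.
      int other = 1 - active;
      double Dsub = Dm * ((active == 0) ? 1.0 : -1.0);
      double b = 2.0 * std::real(std::conj(c[active]) * c[other]) * Dsub;
      double pop = std::norm(c[active]);
      if (pop > 1e-12) g_hop += h * b / pop;
    }
    double norm = std::norm(c[0]) + std::norm(c[1]);
    max_norm_dev = std::max(max_norm_dev, std::fabs(norm - 1.0));

    if (allow_hops && g_hop > 0) {
      double xi = unif_rand();
      if (xi < std::min(g_hop, 1.0)) {
        int other = 1 - active;
        int from_state = active;
        double dE = ap_new.E[other] - ap_new.E[active];
        // rescale velocity along the coupling direction to conserve energy
        double dn = 0;
        for (int i = 0; i < md.n; ++i) dn += ap_new.d01[i] * ap_new.d01[i];
        std::vector<double> dir(md.n);
        if (dn > 1e-24) {
          for (int i = 0; i < md.n; ++i) dir[i] = ap_new.d01[i] / std::sqrt(dn);
        } else {
          double vn = 0;
          for (int i = 0; i < md.n; ++i) vn += v[i] * v[i];
          vn = std::sqrt(std::max(vn, 1e-300));
          for (int i = 0; i < md.n; ++i) dir[i] = v[i] / vn;
        }
        double vd = 0;
        for (int i = 0; i < md.n; ++i) vd += v[i] * dir[i];
        double disc = vd * vd - 2.0 * dE;
        double ke_avail = 0.5 * vd * vd;
        bool accepted = disc >= 0;
        if (accepted) {
          double s = std::sqrt(disc);
          double gamma = (vd >= 0) ? (vd - s) : (vd + s);  // smaller |gamma|
          for (int i = 0; i < md.n; ++i) v[i] -= gamma * dir[i];
          active = other;
        } else if (reverse_frustrated) {
          for (int i = 0; i < md.n; ++i) v[i] -= 2.0 * vd * dir[i];
        }
        hop_time.push_back((step + 1) * dt);
        hop_from.push_back(from_state);
        hop_to.push_back(other);
        hop_prob.push_back(std::min(g_hop, 1.0));
        hop_xi.push_back(xi);
        hop_ke.push_back(ke_avail);
        hop_acc.push_back(accepted ? 1 : 0);
      }
    }

    ap = ap_new;
    double etot = ap.E[active];
    for (int i = 0; i < md.n; ++i) etot += 0.5 * v[i] * v[i];
    max_drift = std::max(max_drift, std::fabs(etot - e_total0));
    if ((step + 1) % record_stride == 0) record((step + 1) * dt);
  }

  // diabatic character of the final active adiabatic state
  double final_diab1 = ap.U[0][active] * ap.U[0][active];
  return List::create(
      _["time"] = r_time, _["pop_lower"] = r_pop0, _["active"] = r_active,
      _["gap"] = r_gap, _["coupling"] = r_dcpl, _["pop_diab1"] = r_pdiab1,
      _["e_total"] = r_etot, _["norm"] = r_norm, _["x"] = r_x,
      _["final_active"] = active, _["final_diab1_weight"] = final_diab1,
      _["max_energy_drift"] = max_drift, _["max_norm_dev"] = max_norm_dev,
      _["hops"] = List::create(
          _["time"] = wrap(hop_time), _["from"] = wrap(hop_from),
          _["to"] = wrap(hop_to), _["prob"] = wrap(hop_prob),
          _["xi"] = wrap(hop_xi), _["ke_available"] = wrap(hop_ke),
          _["accepted"] = wrap(hop_acc)));
}
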