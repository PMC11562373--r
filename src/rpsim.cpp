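// Ring-polymer molecular dynamics engine for few-atom model potentials.
//
// Velocity-Verlet integration with exact normal-mode propagation of the free
// ring polymer (the standard splitting for stiff chain modes) and a PILE
// Langevin thermostat applied in the normal-mode representation: centroid
// friction 1/tau, internal-mode friction 2*omega_k (the scheme's
// standard choice, scalable). The simulation temperature is P*T: masses are
// physical, the chain frequency is omega_P = P/(beta*hbar), and every bead
// feels the full physical potential.
//
// Models: 1D harmonic oscillator, Morse diatomic, and a triatomic water
// model (two bonds, harmonic or Morse, plus a harmonic angle bend).
//
// All quantities are in Hartree atomic units.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Model {
  int kind;  // 0 harmonic1d, 1 morse_diatomic, 2 water_harmonic, 3 water_anharmonic
  std::vector<double> par;
};

// forces in f (accumulated fresh), returns potential energy of one bead
double bead_force(const Model& mod, const double* x, double* f, int natoms) {
  for (int i = 0; i < natoms * 3; ++i) f[i] = 0.0;
  double V = 0.0;
  switch (mod.kind) {
    case 0: {  // V = 1/2 k |x|^2 for a single atom about the origin
      double k = mod.par[0];
      for (int d = 0; d < 3; ++d) {
        V += 0.5 * k * x[d] * x[d];
        f[d] -= k * x[d];
      }
      break;
    }
    case 1: {  // Morse bond between atoms 0 and 1: D, a, r0
      double D = mod.par[0], a = mod.par[1], r0 = mod.par[2];
      double dr[3], r2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        dr[d] = x[3 + d] - x[d];
        r2 += dr[d] * dr[d];
      }
      double r = std::sqrt(r2);
      double e = std::exp(-a * (r - r0));
      V += D * (1.0 - e) * (1.0 - e);
      double dVdr = 2.0 * D * a * e * (1.0 - e);
      for (int d = 0; d < 3; ++d) {
        double g = dVdr * dr[d] / r;
        f[d] += g;        // force on atom 0
        f[3 + d] -= g;    // force on atom 1
      }
      break;
    }
    case 2:
    case 3: {  // water O,H,H: two bonds + harmonic angle
      // par: (kr, r0, ktheta, theta0) harmonic, (D, a, r0, ktheta, theta0) Morse
      double r0, ktheta, theta0, D = 0, a = 0, kr = 0;
      if (mod.kind == 2) {
        kr = mod.par[0]; r0 = mod.par[1]; ktheta = mod.par[2]; theta0 = mod.par[3];
      } else {
        D = mod.par[0]; a = mod.par[1]; r0 = mod.par[2];
        ktheta = mod.par[3]; theta0 = mod.par[4];
      }
      double b1[3], b2[3], r1 = 0, r2 = 0;
      for (int d = 0; d < 3; ++d) {
        b1[d] = x[3 + d] - x[d];      // O->H1
        b2[d] = x[6 + d] - x[d];      // O->H2
        r1 += b1[d] * b1[d];
        r2 += b2[d] * b2[d];
      }
      r1 = std::sqrt(r1);
      r2 = std::sqrt(r2);
      const double* bs[2] = {b1, b2};
      double rs[2] = {r1, r2};
      for (int ib = 0; ib < 2; ++ib) {
        double r = rs[ib];
        double dVdr;
        if (mod.kind == 2) {
          V += 0.5 * kr * (r - r0) * (r - r0);
          dVdr = kr * (r - r0);
        } else {
          double e = std::exp(-a * (r - r0));
          V += D * (1.0 - e) * (1.0 - e);
          dVdr = 2.0 * D * a * e * (1.0 - e);
        }
        int ia = 3 * (ib + 1);
        for (int d = 0; d < 3; ++d) {
          double g = dVdr * bs[ib][d] / r;
          f[d] += g;
          f[ia + d] -= g;
        }
      }
      // angle H1-O-H2
      double dot = b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2];
      double ct = dot / (r1 * r2);
      ct = std::max(-1.0, std::min(1.0, ct));
      double theta = std::acos(ct);
      double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
      V += 0.5 * ktheta * (theta - theta0) * (theta - theta0);
      double dVdth = ktheta * (theta - theta0);
      double c = -dVdth / st;  // dV/d(cos theta)
      for (int d = 0; d < 3; ++d) {
        double dH1 = (b2[d] / (r1 * r2)) - ct * b1[d] / (r1 * r1);
        double dH2 = (b1[d] / (r1 * r2)) - ct * b2[d] / (r2 * r2);
        f[3 + d] -= c * dH1;
        f[6 + d] -= c * dH2;
        f[d] += c * (dH1 + dH2);
      }
      break;
    }
    default:
      stop("unknown model kind");
  }
  return V;
}

}  // namespace

// [[Rcpp::export]]
List cpp_bead_potential(int kind, NumericVector par, NumericVector x, int natoms) {
  Model mod{kind, std::vector<double>(par.begin(), par.end())};
  std::vector<double> f(natoms * 3);
  double V = bead_force(mod, x.begin(), f.data(), natoms);
  return List::create(_["V"] = V, _["force"] = NumericVector(f.begin(), f.end()));
}

// [[Rcpp::export]]
List cpp_rp_integrate(NumericVector x0, NumericVector v0, NumericVector mass,
                      int P, double beta, int kind, NumericVector par,
                      double dt, int n_steps, int thermostat, double tau,
                      double pile_scale, bool constrain_1d, bool fix_com,
                      int record_stride, bool record_beads,
                      bool remove_global) {
  const int natoms = mass.size();
  const int nd = natoms * 3;
  Model mod{kind, std::vector<double>(par.begin(), par.end())};

  // normal-mode transform matrix C[k][j] (orthogonal), centroid row k = 0
  std::vector<double> C(P * P);
  for (int j = 0; j < P; ++j) C[j] = std::sqrt(1.0 / P);
  for (int k = 1; k <= (P - 1) / 2; ++k)
    for (int j = 0; j < P; ++j)
      C[k * P + j] = std::sqrt(2.0 / P) * std::cos(2.0 * M_PI * k * j / P);
  if (P % 2 == 0)
    for (int j = 0; j < P; ++j)
      C[(P / 2) * P + j] = std::sqrt(1.0 / P) * ((j % 2) ? -1.0 : 1.0);
  for (int k = P / 2 + 1; k < P; ++k)
    for (int j = 0; j < P; ++j)
      C[k * P + j] = std::sqrt(2.0 / P) * std::sin(2.0 * M_PI * k * j / P);

  const double omegaP = P / beta;  // chain frequency, hbar = 1
  std::vector<double> omk(P), c_cos(P), c_sin(P), th_c1(P), th_c2f(P);
  for (int k = 0; k < P; ++k) {
    omk[k] = 2.0 * omegaP * std::sin(M_PI * k / P);
    c_cos[k] = std::cos(omk[k] * dt);
    c_sin[k] = std::sin(omk[k] * dt);
    double gam = (k == 0) ? ((tau > 0) ? 1.0 / tau : 0.0)
                          : pile_scale * 2.0 * omk[k];
    double c1 = std::exp(-gam * dt * 0.5);
    th_c1[k] = c1;
    th_c2f[k] = std::sqrt((1.0 - c1 * c1) * P / beta);  // * 1/sqrt(m)
  }

  std::vector<double> x(x0.begin(), x0.end()), v(v0.begin(), v0.end());
  std::vector<double> f(P * nd);
  double msum = 0.0;
  for (int i = 0; i < natoms; ++i) msum += mass[i];

  auto project = [&](std::vector<double>& a) {
    // 1D constraint: zero y,z components for every bead/atom
    if (constrain_1d)
      for (int j = 0; j < P; ++j)
        for (int i = 0; i < natoms; ++i) {
          a[j * nd + i * 3 + 1] = 0.0;
          a[j * nd + i * 3 + 2] = 0.0;
        }
    if (fix_com)
      for (int j = 0; j < P; ++j)
        for (int d = 0; d < 3; ++d) {
          double s = 0.0;
          for (int i = 0; i < natoms; ++i) s += mass[i] * a[j * nd + i * 3 + d];
          s /= msum;
          for (int i = 0; i < natoms; ++i) a[j * nd + i * 3 + d] -= s;
        }
  };

  auto forces = [&]() {
    double V = 0.0;
    for (int j = 0; j < P; ++j)
      V += bead_force(mod, &x[j * nd], &f[j * nd], natoms);
    return V;  // sum over beads
  };

  // normal-mode transforms in a transposed (dof-major) packing: the inner
  // loops become contiguous length-P dot products, which vectorize
  std::vector<double> Ct(P * P);
  for (int k = 0; k < P; ++k)
    for (int j = 0; j < P; ++j) Ct[j * P + k] = C[k * P + j];
  // 1D-constrained runs only ever move the x components; restrict the
  // normal-mode work to the active degrees of freedom
  std::vector<int> act;
  for (int i = 0; i < nd; ++i)
    if (!constrain_1d || i % 3 == 0) act.push_back(i);
  const int na_dof = (int)act.size();
  std::vector<double> xt(na_dof * P), vt(na_dof * P), qxt(na_dof * P),
      qvt(na_dof * P), sqm(na_dof);
  for (int u = 0; u < na_dof; ++u) sqm[u] = std::sqrt(mass[act[u] / 3]);
  auto pack = [&](const std::vector<double>& a, std::vector<double>& t) {
    for (int j = 0; j < P; ++j)
      for (int u = 0; u < na_dof; ++u) t[u * P + j] = a[j * nd + act[u]];
  };
  auto unpack = [&](const std::vector<double>& t, std::vector<double>& a) {
    for (int j = 0; j < P; ++j)
      for (int u = 0; u < na_dof; ++u) a[j * nd + act[u]] = t[u * P + j];
  };
  // q[u*P+k] = sum_j M[k*P+j] t[u*P+j]
  auto mm = [&](const std::vector<double>& M, const std::vector<double>& t,
                std::vector<double>& q) {
    for (int u = 0; u < na_dof; ++u) {
      const double* ti = &t[u * P];
      double* qi = &q[u * P];
      for (int k = 0; k < P; ++k) {
        const double* Mk = &M[k * P];
        double s = 0.0;
        for (int j = 0; j < P; ++j) s += Mk[j] * ti[j];
        qi[k] = s;
      }
    }
  };

  auto thermo_half = [&]() {
    pack(v, vt);
    mm(C, vt, qvt);
    for (int u = 0; u < na_dof; ++u) {
      double* qi = &qvt[u * P];
      for (int k = 0; k < P; ++k)
        qi[k] = th_c1[k] * qi[k] + th_c2f[k] / sqm[u] * norm_rand();
    }
    mm(Ct, qvt, vt);
    unpack(vt, v);
    project(v);
  };

  auto drift = [&]() {
    pack(x, xt);
    pack(v, vt);
    mm(C, xt, qxt);
    mm(C, vt, qvt);
    for (int u = 0; u < na_dof; ++u) {
      double* xk = &qxt[u * P];
      double* vk = &qvt[u * P];
      xk[0] += vk[0] * dt;               // centroid free flight
      for (int k = 1; k < P; ++k) {
        const double cc = c_cos[k], ss = c_sin[k], w = omk[k];
        const double xn = xk[k] * cc + vk[k] / w * ss;
        vk[k] = -xk[k] * w * ss + vk[k] * cc;
        xk[k] = xn;
      }
    }
    mm(Ct, qxt, xt);
    mm(Ct, qvt, vt);
    unpack(xt, x);
    unpack(vt, v);
  };

  GetRNGstate();
  project(x);
  project(v);
  double Vtot = forces();

  int n_rec = n_steps / record_stride;
  NumericMatrix cent_v(n_rec, nd);
  NumericMatrix cent_x(n_rec, nd);
  NumericMatrix bead_v(record_beads ? n_rec : 1, record_beads ? P * nd : 1);
  NumericMatrix est(n_rec, 5);
  NumericVector times(n_rec);
  std::vector<double> vrec(P * nd);

  int irec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (thermostat == 1) thermo_half();
    for (int j = 0; j < P; ++j)
      for (int i = 0; i < nd; ++i)
        v[j * nd + i] += 0.5 * dt * f[j * nd + i] / mass[i / 3];
    project(v);
    drift();
    project(x);
    project(v);
    Vtot = forces();
    for (int j = 0; j < P; ++j)
      for (int i = 0; i < nd; ++i)
        v[j * nd + i] += 0.5 * dt * f[j * nd + i] / mass[i / 3];
    project(v);
    if (thermostat == 1) thermo_half();

    if (!std::isfinite(Vtot))
      stop("cpp_rp_integrate: non-finite coordinates (integration blow-up) at step %d", step);

    if (step % record_stride == 0) {
      // estimators
      double KE = 0.0, spring = 0.0;
      for (int j = 0; j < P; ++j) {
        int jn = (j + 1) % P;
        for (int i = 0; i < nd; ++i) {
          double m = mass[i / 3];
          KE += 0.5 * m * v[j * nd + i] * v[j * nd + i];
          double dxb = x[j * nd + i] - x[jn * nd + i];
          spring += 0.5 * m * omegaP * omegaP * dxb * dxb;
        }
      }
      int dof_bead = constrain_1d ? natoms : nd;
      if (fix_com) dof_bead -= (constrain_1d ? 1 : 3);
      double prim = dof_bead * P / (2.0 * beta) - spring / P;
      est(irec, 0) = Vtot / P;          // bead-averaged potential
      est(irec, 1) = KE;                // total classical kinetic energy
      est(irec, 2) = spring / P;        // spring energy per bead
      est(irec, 3) = prim;              // primitive kinetic-energy estimator
      est(irec, 4) = KE + spring + Vtot;  // conserved RPMD energy
      times[irec] = step * dt;

      std::copy(v.begin(), v.end(), vrec.begin());
      if (remove_global && !constrain_1d) {
        for (int j = 0; j < P; ++j) {
          double* vb = &vrec[j * nd];
          const double* xb = &x[j * nd];
          double com[3] = {0, 0, 0}, vc[3] = {0, 0, 0};
          for (int i = 0; i < natoms; ++i)
            for (int d = 0; d < 3; ++d) {
              com[d] += mass[i] * xb[i * 3 + d];
              vc[d] += mass[i] * vb[i * 3 + d];
            }
          for (int d = 0; d < 3; ++d) {
            com[d] /= msum;
            vc[d] /= msum;
          }
          for (int i = 0; i < natoms; ++i)
            for (int d = 0; d < 3; ++d) vb[i * 3 + d] -= vc[d];
          if (natoms > 1) {
            // remove rigid rotation: omega = I^+ L about the bead COM
            double I[3][3] = {{0}}, L[3] = {0, 0, 0};
            for (int i = 0; i < natoms; ++i) {
              double r[3];
              for (int d = 0; d < 3; ++d) r[d] = xb[i * 3 + d] - com[d];
              double m = mass[i];
              double rr = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
              for (int d = 0; d < 3; ++d) {
                for (int e = 0; e < 3; ++e) I[d][e] -= m * r[d] * r[e];
                I[d][d] += m * rr;
              }
              L[0] += m * (r[1] * vb[i * 3 + 2] - r[2] * vb[i * 3 + 1]);
              L[1] += m * (r[2] * vb[i * 3 + 0] - r[0] * vb[i * 3 + 2]);
              L[2] += m * (r[0] * vb[i * 3 + 1] - r[1] * vb[i * 3 + 0]);
            }
            // Tikhonov-regularized solve (linear molecules have a singular
            // axis carrying no angular momentum)
            double tr = I[0][0] + I[1][1] + I[2][2];
            for (int d = 0; d < 3; ++d) I[d][d] += 1e-10 * tr;
            // Cramer's rule
            double det =
                I[0][0] * (I[1][1] * I[2][2] - I[1][2] * I[2][1]) -
                I[0][1] * (I[1][0] * I[2][2] - I[1][2] * I[2][0]) +
                I[0][2] * (I[1][0] * I[2][1] - I[1][1] * I[2][0]);
            double w[3];
            for (int c = 0; c < 3; ++c) {
              double A[3][3];
              for (int d = 0; d < 3; ++d)
                for (int e = 0; e < 3; ++e) A[d][e] = I[d][e];
              for (int d = 0; d < 3; ++d) A[d][c] = L[d];
              double dc =
                  A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                  A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                  A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
              w[c] = dc / det;
            }
            for (int i = 0; i < natoms; ++i) {
              double r[3];
              for (int d = 0; d < 3; ++d) r[d] = xb[i * 3 + d] - com[d];
              vb[i * 3 + 0] -= w[1] * r[2] - w[2] * r[1];
              vb[i * 3 + 1] -= w[2] * r[0] - w[0] * r[2];
              vb[i * 3 + 2] -= w[0] * r[1] - w[1] * r[0];
            }
          }
        }
      }
      for (int i = 0; i < nd; ++i) {
        double s = 0.0, sx = 0.0;
        for (int j = 0; j < P; ++j) {
          s += vrec[j * nd + i];
          sx += x[j * nd + i];
        }
        cent_v(irec, i) = s / P;
        cent_x(irec, i) = sx / P;
      }
      if (record_beads)
        for (int j = 0; j < P; ++j)
          for (int i = 0; i < nd; ++i) bead_v(irec, j * nd + i) = vrec[j * nd + i];
      ++irec;
    }
  }
  PutRNGstate();

  List out = List::create(
      _["times"] = times, _["centroid_velocities"] = cent_v,
      _["centroid_positions"] = cent_x,
      _["estimators"] = est, _["x"] = NumericVector(x.begin(), x.end()),
      _["v"] = NumericVector(v.begin(), v.end()));
  if (record_beads) out["bead_velocities"] = bead_v;
  return out;
}

// [[Rcpp::export]]
List cpp_rp_energy(NumericVector x, NumericVector v, NumericVector mass,
                   int P, double beta, int kind, NumericVector par) {
  const int natoms = mass.size();
  const int nd = natoms * 3;
  Model mod{kind, std::vector<double>(par.begin(), par.end())};
  std::vector<double> f(nd);
  double V = 0.0, KE = 0.0, spring = 0.0;
  const double omegaP = P / beta;
  for (int j = 0; j < P; ++j) {
    V += bead_force(mod, &x[j * nd], f.data(), natoms);
    int jn = (j + 1) % P;
    for (int i = 0; i < nd; ++i) {
      double m = mass[i / 3];
      KE += 0.5 * m * v[j * nd + i] * v[j * nd + i];
      double dxb = x[j * nd + i] - x[jn * nd + i];
      spring += 0.5 * m * omegaP * omegaP * dxb * dxb;
    }
  }
  return List::create(_["kinetic"] = KE, _["spring"] = spring,
                      _["potential"] = V / P, _["potential_total"] = V);
}
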