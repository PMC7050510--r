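// Force-field energy/gradient and numeric accessible-surface-area kernels.
//
// The force field is a simplified AMBER-like potential: harmonic bonds and
// angles, one cosine torsion per assigned central bond, 12-6 Lennard-Jones
// over all pairs separated by >= 3 bonds (1-4 scaled upstream), plus
// optional harmonic ring-closure restraints. No electrostatic term by
// construction: conformer energetics must be transferable between water
// and membrane, whose dielectric constants differ widely, so polarity
// enters only through the solvation model.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void axpy3(double *g, int a, double f,
                         double vx, double vy, double vz) {
  g[3 * a] += f * vx;
  g[3 * a + 1] += f * vy;
  g[3 * a + 2] += f * vz;
}

// Lennard-Jones with linear extension below rcap so that overlapping atoms
// give a large but finite, smoothly decreasing-with-r repulsion.
static inline void lj_eval(double r, double rm, double eps, double rcap,
                           double &e, double &dedr) {
  double rr = r < rcap ? rcap : r;
  double q = rm / rr;
  double q6 = q * q * q;
  q6 = q6 * q6;
  double q12 = q6 * q6;
  double ecap = eps * (q12 - 2.0 * q6);
  double dcap = eps * (-12.0 * q12 + 12.0 * q6) / rr;
  if (r < rcap) {
    e = ecap + dcap * (r - rcap);
    dedr = dcap;
  } else {
    e = ecap;
    dedr = dcap;
  }
}

// [[Rcpp::export]]
List ff_eval_cpp(NumericVector x,
                 NumericMatrix bonds,     // i j k r0
                 NumericMatrix angles,    // i j k kth th0   (j = center)
                 NumericMatrix torsions,  // i j k l V n gamma
                 NumericMatrix pairs,     // i j rm eps      (eps pre-scaled)
                 NumericMatrix restraints, // i j k r0
                 double rcap = 0.7) {
  const int n3 = x.size();
  NumericVector grad(n3);
  double *g = grad.begin();
  const double *p = x.begin();
  double E = 0.0;

  auto harm = [&](int i, int j, double k, double r0) {
    double dx = p[3 * i] - p[3 * j];
    double dy = p[3 * i + 1] - p[3 * j + 1];
    double dz = p[3 * i + 2] - p[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-8) r = 1e-8;
    double d = r - r0;
    E += k * d * d;
    double f = 2.0 * k * d / r;
    axpy3(g, i, f, dx, dy, dz);
    axpy3(g, j, -f, dx, dy, dz);
  };

  for (int b = 0; b < bonds.nrow(); ++b)
    harm((int)bonds(b, 0) - 1, (int)bonds(b, 1) - 1, bonds(b, 2), bonds(b, 3));
  for (int b = 0; b < restraints.nrow(); ++b)
    harm((int)restraints(b, 0) - 1, (int)restraints(b, 1) - 1,
         restraints(b, 2), restraints(b, 3));

  for (int a = 0; a < angles.nrow(); ++a) {
    int i = (int)angles(a, 0) - 1, j = (int)angles(a, 1) - 1,
        k = (int)angles(a, 2) - 1;
    double kth = angles(a, 3), th0 = angles(a, 4);
    double ux = p[3 * i] - p[3 * j], uy = p[3 * i + 1] - p[3 * j + 1],
           uz = p[3 * i + 2] - p[3 * j + 2];
    double vx = p[3 * k] - p[3 * j], vy = p[3 * k + 1] - p[3 * j + 1],
           vz = p[3 * k + 2] - p[3 * j + 2];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-8) nu = 1e-8;
    if (nv < 1e-8) nv = 1e-8;
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double d = th - th0;
    E += kth * d * d;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-6) s = 1e-6;
    double fact = -2.0 * kth * d / s;
    // dtheta/dri etc.
    double gix = fact * (vx / (nu * nv) - c * ux / (nu * nu));
    double giy = fact * (vy / (nu * nv) - c * uy / (nu * nu));
    double giz = fact * (vz / (nu * nv) - c * uz / (nu * nu));
    double gkx = fact * (ux / (nu * nv) - c * vx / (nv * nv));
    double gky = fact * (uy / (nu * nv) - c * vy / (nv * nv));
    double gkz = fact * (uz / (nu * nv) - c * vz / (nv * nv));
    g[3 * i] += gix; g[3 * i + 1] += giy; g[3 * i + 2] += giz;
    g[3 * k] += gkx; g[3 * k + 1] += gky; g[3 * k + 2] += gkz;
    g[3 * j] -= gix + gkx; g[3 * j + 1] -= giy + gky;
    g[3 * j + 2] -= giz + gkz;
  }

  for (int t = 0; t < torsions.nrow(); ++t) {
    int i = (int)torsions(t, 0) - 1, j = (int)torsions(t, 1) - 1,
        k = (int)torsions(t, 2) - 1, l = (int)torsions(t, 3) - 1;
    double V = torsions(t, 4);
    double nn = torsions(t, 5);
    double gamma = torsions(t, 6);
    double b1x = p[3 * j] - p[3 * i], b1y = p[3 * j + 1] - p[3 * i + 1],
           b1z = p[3 * j + 2] - p[3 * i + 2];
    double b2x = p[3 * k] - p[3 * j], b2y = p[3 * k + 1] - p[3 * j + 1],
           b2z = p[3 * k + 2] - p[3 * j + 2];
    double b3x = p[3 * l] - p[3 * k], b3y = p[3 * l + 1] - p[3 * k + 1],
           b3z = p[3 * l + 2] - p[3 * k + 2];
    double n1x = b1y * b2z - b1z * b2y, n1y = b1z * b2x - b1x * b2z,
           n1z = b1x * b2y - b1y * b2x;
    double n2x = b2y * b3z - b2z * b3y, n2y = b2z * b3x - b2x * b3z,
           n2z = b2x * b3y - b2y * b3x;
    double n1sq = n1x * n1x + n1y * n1y + n1z * n1z;
    double n2sq = n2x * n2x + n2y * n2y + n2z * n2z;
    double b2n = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (n1sq < 1e-10 || n2sq < 1e-10 || b2n < 1e-8) continue; // collinear
    double mx = n1y * n2z - n1z * n2y, my = n1z * n2x - n1x * n2z,
           mz = n1x * n2y - n1y * n2x;
    double ss = (mx * b2x + my * b2y + mz * b2z) / b2n;
    double cc = n1x * n2x + n1y * n2y + n1z * n2z;
    double phi = std::atan2(ss, cc);
    E += 0.5 * V * (1.0 + std::cos(nn * phi - gamma));
    double dEdphi = -0.5 * V * nn * std::sin(nn * phi - gamma);
    // dphi/dri distribution (standard torsion gradient)
    double f1 = -b2n / n1sq;
    double f4 = b2n / n2sq;
    double g1x = f1 * n1x, g1y = f1 * n1y, g1z = f1 * n1z;
    double g4x = f4 * n2x, g4y = f4 * n2y, g4z = f4 * n2z;
    double sdot = (b1x * b2x + b1y * b2y + b1z * b2z) / (b2n * b2n);
    double tdot = (b3x * b2x + b3y * b2y + b3z * b2z) / (b2n * b2n);
    double g2x = -(1.0 + sdot) * g1x + tdot * g4x;
    double g2y = -(1.0 + sdot) * g1y + tdot * g4y;
    double g2z = -(1.0 + sdot) * g1z + tdot * g4z;
    double g3x = sdot * g1x - (1.0 + tdot) * g4x;
    double g3y = sdot * g1y - (1.0 + tdot) * g4y;
    double g3z = sdot * g1z - (1.0 + tdot) * g4z;
    axpy3(g, i, dEdphi, g1x, g1y, g1z);
    axpy3(g, j, dEdphi, g2x, g2y, g2z);
    axpy3(g, k, dEdphi, g3x, g3y, g3z);
    axpy3(g, l, dEdphi, g4x, g4y, g4z);
  }

  for (int q = 0; q < pairs.nrow(); ++q) {
    int i = (int)pairs(q, 0) - 1, j = (int)pairs(q, 1) - 1;
    double rm = pairs(q, 2), eps = pairs(q, 3);
    double dx = p[3 * i] - p[3 * j];
    double dy = p[3 * i + 1] - p[3 * j + 1];
    double dz = p[3 * i + 2] - p[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-8) r = 1e-8;
    double e, dedr;
    lj_eval(r, rm, eps, rcap, e, dedr);
    E += e;
    double f = dedr / r;
    axpy3(g, i, f, dx, dy, dz);
    axpy3(g, j, -f, dx, dy, dz);
  }

  return List::create(Named("energy") = E, Named("gradient") = grad);
}

// Shrake-Rupley accessible surface area with a deterministic Fibonacci
// sphere. Returns the per-atom accessible area (Angstrom^2).
// [[Rcpp::export]]
NumericVector asa_cpp(NumericMatrix xyz, NumericVector radii,
                      double probe = 1.4, int npoints = 240) {
  const int n = xyz.nrow();
  NumericVector area(n);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  for (int k = 0; k < npoints; ++k) {
    double zz = 1.0 - 2.0 * (k + 0.5) / npoints;
    double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
    double th = golden * k;
    px[k] = rr * std::cos(th);
    py[k] = rr * std::sin(th);
    pz[k] = zz;
  }
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    // neighbor prefilter
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      double rj = radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < (ri + rj) * (ri + rj)) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double sx = xyz(i, 0) + ri * px[k];
      double sy = xyz(i, 1) + ri * py[k];
      double sz = xyz(i, 2) + ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = radii[j] + probe;
        double dx = sx - xyz(j, 0);
        double dy = sy - xyz(j, 1);
        double dz = sz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / npoints;
  }
  return area;
}
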