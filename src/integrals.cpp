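// Gaussian-basis integral engine (McMurchie-Davidson scheme) and grid
// numerics. Basis functions are general contracted Cartesian Gaussians:
// each AO is a list of primitives (exponent, angular powers, center,
// coefficient with all normalization folded in), which uniformly covers
// segmented shells, spherical-harmonic combinations from Molden files, and
// single-primitive toy densities.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <array>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// Boys function F_m(x), m = 0..mmax, written into F.
// Series (downward-stable) for small x, erf + upward recursion for large x.
static void boys(int mmax, double x, double* F) {
  if (x < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (x > 2.0 * mmax + 12.0) {
    // F0 via erf, then upward recursion (stable here)
    double sx = std::sqrt(x);
    F[0] = 0.5 * std::sqrt(PI / x) * std::erf(sx);
    double ex = (x > 700.0) ? 0.0 : std::exp(-x);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - ex) / (2.0 * x);
    return;
  }
  // series at top order, then downward recursion
  double term = 1.0 / (2.0 * mmax + 1.0);
  double sum = term;
  for (int i = 1; i < 200; ++i) {
    term *= 2.0 * x / (2.0 * mmax + 2.0 * i + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  double ex = std::exp(-x);
  F[mmax] = ex * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} for a 1D Gaussian product,
// filled for i=0..imax, j=0..jmax, t=0..i+j. Layout E[i][j][t].
struct ETable {
  int imax, jmax;
  std::vector<double> v;
  ETable(int i, int j) : imax(i), jmax(j), v((i + 1) * (j + 1) * (i + j + 1), 0.0) {}
  inline double& at(int i, int j, int t) {
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
  inline double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
};

static void build_E(ETable& E, double a, double b, double AB) {
  // AB = A_x - B_x
  double p = a + b;
  double mu = a * b / p;
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  double PA = -b / p * AB;  // P - A
  double PB = a / p * AB;   // P - B
  for (int i = 0; i <= E.imax; ++i) {
    for (int j = 0; j <= E.jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val;
        if (i > 0) {
          val = (1.0 / (2.0 * p)) * E.get(i - 1, j, t - 1)
              + PA * E.get(i - 1, j, t)
              + (t + 1.0) * E.get(i - 1, j, t + 1);
        } else {
          val = (1.0 / (2.0 * p)) * E.get(i, j - 1, t - 1)
              + PB * E.get(i, j - 1, t)
              + (t + 1.0) * E.get(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  }
}

// Hermite Coulomb integrals R^0_{tuv}(p, A) for t+u+v <= L, A = P - C.
// Layout R[t][u][v] in a dense (L+1)^3 array (upper corner unused).
struct RTable {
  int L;
  std::vector<double> v;
  RTable(int Lmax) : L(Lmax), v((Lmax + 1) * (Lmax + 1) * (Lmax + 1), 0.0) {}
  inline double& at(int t, int u, int w) {
    return v[(t * (L + 1) + u) * (L + 1) + w];
  }
};

static void build_R(RTable& R, int L, double p, double Ax, double Ay, double Az) {
  double r2 = Ax * Ax + Ay * Ay + Az * Az;
  double Fm[32];
  boys(L, p * r2, Fm);
  // R^n_{000} = (-2p)^n F_n
  // iterate: for each total order, raise indices one at a time
  // use a temporary over the auxiliary index n
  int dim = L + 1;
  static thread_local std::vector<double> work;
  work.assign((L + 1) * dim * dim * dim, 0.0);
  auto W = [&](int n, int t, int u, int w) -> double& {
    return work[((n * dim + t) * dim + u) * dim + w];
  };
  double f = 1.0;
  for (int n = 0; n <= L; ++n) { W(n, 0, 0, 0) = f * Fm[n]; f *= -2.0 * p; }
  for (int total = 1; total <= L; ++total) {
    for (int t = 0; t <= total; ++t) {
      for (int u = 0; u + t <= total; ++u) {
        int w = total - t - u;
        for (int n = 0; n <= L - total; ++n) {
          double val;
          if (t > 0) {
            val = Ax * W(n + 1, t - 1, u, w);
            if (t > 1) val += (t - 1.0) * W(n + 1, t - 2, u, w);
          } else if (u > 0) {
            val = Ay * W(n + 1, t, u - 1, w);
            if (u > 1) val += (u - 1.0) * W(n + 1, t, u - 2, w);
          } else {
            val = Az * W(n + 1, t, u, w - 1);
            if (w > 1) val += (w - 1.0) * W(n + 1, t, u, w - 2);
          }
          W(n, t, u, w) = val;
        }
      }
    }
  }
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u + t <= L; ++u)
      for (int w = 0; w + t + u <= L; ++w)
        R.at(t, u, w) = W(0, t, u, w);
}

// ---------------------------------------------------------------------------
// AO basis container unpacked from R

struct Prim {
  double a;        // exponent
  int lx, ly, lz;
  double cx, cy, cz;  // center
  double c;        // coefficient incl. normalization
};

struct Basis {
  int nbf;
  std::vector<std::vector<Prim>> ao;
};

static Basis unpack_basis(List basis) {
  IntegerVector nprim = basis["nprim"];
  NumericVector exps = basis["exp"];
  NumericVector coefs = basis["coef"];
  IntegerMatrix lpow = basis["l"];
  NumericMatrix cent = basis["center"];
  Basis B;
  B.nbf = nprim.size();
  B.ao.resize(B.nbf);
  int k = 0;
  for (int i = 0; i < B.nbf; ++i) {
    for (int q = 0; q < nprim[i]; ++q, ++k) {
      Prim pr;
      pr.a = exps[k]; pr.c = coefs[k];
      pr.lx = lpow(k, 0); pr.ly = lpow(k, 1); pr.lz = lpow(k, 2);
      pr.cx = cent(k, 0); pr.cy = cent(k, 1); pr.cz = cent(k, 2);
      B.ao[i].push_back(pr);
    }
  }
  return B;
}

// one-electron primitive overlap / kinetic
static inline double overlap_1d(const ETable& Ex, int i, int j, double p) {
  return Ex.get(i, j, 0) * std::sqrt(PI / p);
}

static void prim_ST(const Prim& A, const Prim& B, double& S, double& T) {
  double p = A.a + B.a;
  int ix = A.lx, jx = B.lx, iy = A.ly, jy = B.ly, iz = A.lz, jz = B.lz;
  ETable Ex(ix + 2, jx + 2), Ey(iy + 2, jy + 2), Ez(iz + 2, jz + 2);
  build_E(Ex, A.a, B.a, A.cx - B.cx);
  build_E(Ey, A.a, B.a, A.cy - B.cy);
  build_E(Ez, A.a, B.a, A.cz - B.cz);
  double sx = overlap_1d(Ex, ix, jx, p);
  double sy = overlap_1d(Ey, iy, jy, p);
  double sz = overlap_1d(Ez, iz, jz, p);
  S = sx * sy * sz;
  double b = B.a;
  auto kin1d = [&](const ETable& E, int i, int j) {
    double t = -2.0 * b * b * E.get(i, j + 2, 0)
             + b * (2.0 * j + 1.0) * E.get(i, j, 0);
    if (j >= 2) t -= 0.5 * j * (j - 1.0) * E.get(i, j - 2, 0);
    return t * std::sqrt(PI / p);
  };
  double tx = kin1d(Ex, ix, jx), ty = kin1d(Ey, iy, jy), tz = kin1d(Ez, iz, jz);
  T = tx * sy * sz + sx * ty * sz + sx * sy * tz;
}

// [[Rcpp::export]]
List cpp_one_electron(List basis, NumericMatrix nuc_coords, NumericVector nuc_charges) {
  Basis B = unpack_basis(basis);
  int n = B.nbf;
  NumericMatrix S(n, n), T(n, n), V(n, n);
  int nnuc = nuc_coords.nrow();
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = 0.0, t = 0.0, v = 0.0;
      for (const Prim& A : B.ao[i]) {
        for (const Prim& Bp : B.ao[j]) {
          double ps, pt;
          prim_ST(A, Bp, ps, pt);
          double cc = A.c * Bp.c;
          s += cc * ps;
          t += cc * pt;
          // nuclear attraction
          double p = A.a + Bp.a;
          double Px = (A.a * A.cx + Bp.a * Bp.cx) / p;
          double Py = (A.a * A.cy + Bp.a * Bp.cy) / p;
          double Pz = (A.a * A.cz + Bp.a * Bp.cz) / p;
          int L = A.lx + A.ly + A.lz + Bp.lx + Bp.ly + Bp.lz;
          ETable Ex(A.lx, Bp.lx), Ey(A.ly, Bp.ly), Ez(A.lz, Bp.lz);
          build_E(Ex, A.a, Bp.a, A.cx - Bp.cx);
          build_E(Ey, A.a, Bp.a, A.cy - Bp.cy);
          build_E(Ez, A.a, Bp.a, A.cz - Bp.cz);
          double pref = 2.0 * PI / p;
          for (int nu = 0; nu < nnuc; ++nu) {
            RTable R(L);
            build_R(R, L, p, Px - nuc_coords(nu, 0), Py - nuc_coords(nu, 1),
                    Pz - nuc_coords(nu, 2));
            double acc = 0.0;
            for (int tt = 0; tt <= A.lx + Bp.lx; ++tt)
              for (int uu = 0; uu <= A.ly + Bp.ly; ++uu)
                for (int ww = 0; ww <= A.lz + Bp.lz; ++ww)
                  acc += Ex.get(A.lx, Bp.lx, tt) * Ey.get(A.ly, Bp.ly, uu)
                       * Ez.get(A.lz, Bp.lz, ww) * R.at(tt, uu, ww);
            v -= nuc_charges[nu] * cc * pref * acc;
          }
        }
      }
      S(i, j) = S(j, i) = s;
      T(i, j) = T(j, i) = t;
      V(i, j) = V(j, i) = v;
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// ---------------------------------------------------------------------------
// two-electron repulsion integrals, full (nbf^4) array, 8-fold symmetry

static double prim_eri(const Prim& A, const Prim& B, const Prim& C, const Prim& D) {
  double p = A.a + B.a, q = C.a + D.a;
  double Px = (A.a * A.cx + B.a * B.cx) / p;
  double Py = (A.a * A.cy + B.a * B.cy) / p;
  double Pz = (A.a * A.cz + B.a * B.cz) / p;
  double Qx = (C.a * C.cx + D.a * D.cx) / q;
  double Qy = (C.a * C.cy + D.a * D.cy) / q;
  double Qz = (C.a * C.cz + D.a * D.cz) / q;
  int L1 = A.lx + A.ly + A.lz + B.lx + B.ly + B.lz;
  int L2 = C.lx + C.ly + C.lz + D.lx + D.ly + D.lz;
  ETable E1x(A.lx, B.lx), E1y(A.ly, B.ly), E1z(A.lz, B.lz);
  ETable E2x(C.lx, D.lx), E2y(C.ly, D.ly), E2z(C.lz, D.lz);
  build_E(E1x, A.a, B.a, A.cx - B.cx);
  build_E(E1y, A.a, B.a, A.cy - B.cy);
  build_E(E1z, A.a, B.a, A.cz - B.cz);
  build_E(E2x, C.a, D.a, C.cx - D.cx);
  build_E(E2y, C.a, D.a, C.cy - D.cy);
  build_E(E2z, C.a, D.a, C.cz - D.cz);
  double zeta = p * q / (p + q);
  RTable R(L1 + L2);
  build_R(R, L1 + L2, zeta, Px - Qx, Py - Qy, Pz - Qz);
  double acc = 0.0;
  for (int t1 = 0; t1 <= A.lx + B.lx; ++t1)
    for (int u1 = 0; u1 <= A.ly + B.ly; ++u1)
      for (int w1 = 0; w1 <= A.lz + B.lz; ++w1) {
        double e1 = E1x.get(A.lx, B.lx, t1) * E1y.get(A.ly, B.ly, u1)
                  * E1z.get(A.lz, B.lz, w1);
        if (std::fabs(e1) < 1e-18) continue;
        for (int t2 = 0; t2 <= C.lx + D.lx; ++t2)
          for (int u2 = 0; u2 <= C.ly + D.ly; ++u2)
            for (int w2 = 0; w2 <= C.lz + D.lz; ++w2) {
              double e2 = E2x.get(C.lx, D.lx, t2) * E2y.get(C.ly, D.ly, u2)
                        * E2z.get(C.lz, D.lz, w2);
              if (std::fabs(e2) < 1e-18) continue;
              double sign = ((t2 + u2 + w2) % 2 == 0) ? 1.0 : -1.0;
              acc += e1 * e2 * sign * R.at(t1 + t2, u1 + u2, w1 + w2);
            }
      }
  double pref = 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q));
  return pref * acc;
}

// [[Rcpp::export]]
NumericVector cpp_eri(List basis) {
  Basis B = unpack_basis(basis);
  int n = B.nbf;
  NumericVector out((R_xlen_t)n * n * n * n);
  auto idx = [n](int i, int j, int k, int l) {
    return ((R_xlen_t)((i * n + j) * n + k)) * n + l;
  };
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j)
      for (int k = 0; k <= i; ++k)
        for (int l = 0; l <= ((k == i) ? j : k); ++l) {
          double val = 0.0;
          for (const Prim& A : B.ao[i])
            for (const Prim& Bp : B.ao[j])
              for (const Prim& C : B.ao[k])
                for (const Prim& D : B.ao[l])
                  val += A.c * Bp.c * C.c * D.c * prim_eri(A, Bp, C, D);
          out[idx(i, j, k, l)] = out[idx(j, i, k, l)] = out[idx(i, j, l, k)] =
            out[idx(j, i, l, k)] = out[idx(k, l, i, j)] = out[idx(l, k, i, j)] =
            out[idx(k, l, j, i)] = out[idx(l, k, j, i)] = val;
        }
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  return out;
}

// Coulomb + exchange contraction: G = J - 0.5*K with
// J_{mn} = sum_{ls} D_{ls} (mn|ls), K_{mn} = sum_{ls} D_{ls} (ml|ns)
// [[Rcpp::export]]
NumericMatrix cpp_fock_2e(NumericVector eri, NumericMatrix D) {
  IntegerVector dim = eri.attr("dim");
  int n = dim[0];
  NumericMatrix G(n, n);
  auto idx = [n](int i, int j, int k, int l) {
    return ((R_xlen_t)((i * n + j) * n + k)) * n + l;
  };
  for (int m = 0; m < n; ++m)
    for (int nn = 0; nn < n; ++nn) {
      double j = 0.0, kx = 0.0;
      for (int l = 0; l < n; ++l)
        for (int s = 0; s < n; ++s) {
          double d = D(l, s);
          j += d * eri[idx(m, nn, l, s)];
          kx += d * eri[idx(m, l, nn, s)];
        }
      G(m, nn) = j - 0.5 * kx;
    }
  return G;
}

// ---------------------------------------------------------------------------
// density, gradient and electrostatic potential on arbitrary points

// [[Rcpp::export]]
List cpp_density_grad(List basis, NumericMatrix D, NumericMatrix pts) {
  Basis B = unpack_basis(basis);
  int n = B.nbf;
  int M = pts.nrow();
  NumericVector rho(M);
  NumericMatrix grad(M, 3);
  std::vector<double> chi(n), dchix(n), dchiy(n), dchiz(n);
  for (int m = 0; m < M; ++m) {
    double x = pts(m, 0), y = pts(m, 1), z = pts(m, 2);
    for (int i = 0; i < n; ++i) {
      double v = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
      for (const Prim& P : B.ao[i]) {
        double dx = x - P.cx, dy = y - P.cy, dz = z - P.cz;
        double r2 = dx * dx + dy * dy + dz * dz;
        double ex = P.c * std::exp(-P.a * r2);
        if (ex == 0.0) continue;
        double px = 1.0, py = 1.0, pz = 1.0;
        for (int t = 0; t < P.lx; ++t) px *= dx;
        for (int t = 0; t < P.ly; ++t) py *= dy;
        for (int t = 0; t < P.lz; ++t) pz *= dz;
        double val = px * py * pz * ex;
        v += val;
        // d/dx [x^l e^-ar2] = (l x^{l-1} - 2 a x^{l+1}) e^-ar2 (per dim)
        double dpx = -2.0 * P.a * dx * px;
        if (P.lx > 0) { double pxm = 1.0; for (int t = 0; t < P.lx - 1; ++t) pxm *= dx; dpx += P.lx * pxm; }
        double dpy = -2.0 * P.a * dy * py;
        if (P.ly > 0) { double pym = 1.0; for (int t = 0; t < P.ly - 1; ++t) pym *= dy; dpy += P.ly * pym; }
        double dpz = -2.0 * P.a * dz * pz;
        if (P.lz > 0) { double pzm = 1.0; for (int t = 0; t < P.lz - 1; ++t) pzm *= dz; dpz += P.lz * pzm; }
        gx += dpx * py * pz * ex;
        gy += px * dpy * pz * ex;
        gz += px * py * dpz * ex;
      }
      chi[i] = v; dchix[i] = gx; dchiy[i] = gy; dchiz[i] = gz;
    }
    double r = 0.0, g1 = 0.0, g2 = 0.0, g3 = 0.0;
    for (int i = 0; i < n; ++i) {
      double di = 0.0, gxi = 0.0, gyi = 0.0, gzi = 0.0;
      for (int j = 0; j < n; ++j) {
        double d = D(i, j);
        di += d * chi[j];
        gxi += d * dchix[j];
        gyi += d * dchiy[j];
        gzi += d * dchiz[j];
      }
      r += chi[i] * di;
      g1 += dchix[i] * di + chi[i] * gxi;
      g2 += dchiy[i] * di + chi[i] * gyi;
      g3 += dchiz[i] * di + chi[i] * gzi;
    }
    rho[m] = r;
    grad(m, 0) = g1; grad(m, 1) = g2; grad(m, 2) = g3;
  }
  return List::create(_["rho"] = rho, _["grad"] = grad);
}

// Electrostatic potential of the electron density at points:
// v(r) = sum_{mn} D_{mn} (mn | 1/|r-r'|). Positive for positive density.
// Hermite density coefficients are precontracted per primitive pair.
struct HermitePair {
  double p;           // total exponent
  double Px, Py, Pz;  // product center
  int L;              // max t+u+v
  int lxa, lya, lza;  // per-dimension maxima (t <= lxa etc.)
  std::vector<double> D;  // Hermite density coeffs, dense (L+1)^3
};

// [[Rcpp::export]]
NumericVector cpp_esp(List basis, NumericMatrix D, NumericMatrix pts) {
  Basis B = unpack_basis(basis);
  int n = B.nbf;
  // Hermite charge distributions merged over all AO pairs sharing the same
  // product Gaussian (p, P) — e.g. all component pairs of two sp shells —
  // which cuts the per-point work by roughly the contraction depth squared.
  const int LMAX = 8;  // supports up to d x d AO pairs
  std::vector<HermitePair> pairs;
  std::map<std::array<double, 4>, int> index;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      double dfac = (i == j) ? D(i, j) : 2.0 * D(i, j);
      if (std::fabs(dfac) < 1e-16) continue;
      for (const Prim& A : B.ao[i])
        for (const Prim& Bp : B.ao[j]) {
          double p = A.a + Bp.a;
          double mu = A.a * Bp.a / p;
          double ab2 = (A.cx - Bp.cx) * (A.cx - Bp.cx)
                     + (A.cy - Bp.cy) * (A.cy - Bp.cy)
                     + (A.cz - Bp.cz) * (A.cz - Bp.cz);
          double cc = dfac * A.c * Bp.c;
          if (std::fabs(cc) * std::exp(-mu * ab2) < 1e-15) continue;
          int lx = A.lx + Bp.lx, ly = A.ly + Bp.ly, lz = A.lz + Bp.lz;
          int L = lx + ly + lz;
          if (L > LMAX) stop("angular momentum too high for ESP kernel");
          ETable Ex(A.lx, Bp.lx), Ey(A.ly, Bp.ly), Ez(A.lz, Bp.lz);
          build_E(Ex, A.a, Bp.a, A.cx - Bp.cx);
          build_E(Ey, A.a, Bp.a, A.cy - Bp.cy);
          build_E(Ez, A.a, Bp.a, A.cz - Bp.cz);
          double Px = (A.a * A.cx + Bp.a * Bp.cx) / p;
          double Py = (A.a * A.cy + Bp.a * Bp.cy) / p;
          double Pz = (A.a * A.cz + Bp.a * Bp.cz) / p;
          std::array<double, 4> key = {p, Px, Py, Pz};
          auto it = index.find(key);
          int pos;
          if (it == index.end()) {
            HermitePair hp;
            hp.p = p; hp.Px = Px; hp.Py = Py; hp.Pz = Pz;
            hp.L = 0; hp.lxa = 0; hp.lya = 0; hp.lza = 0;
            hp.D.assign((LMAX + 1) * (LMAX + 1) * (LMAX + 1), 0.0);
            pairs.push_back(std::move(hp));
            pos = pairs.size() - 1;
            index[key] = pos;
          } else pos = it->second;
          HermitePair& hp = pairs[pos];
          if (lx > hp.lxa) hp.lxa = lx;
          if (ly > hp.lya) hp.lya = ly;
          if (lz > hp.lza) hp.lza = lz;
          if (L > hp.L) hp.L = L;
          double pref = cc * 2.0 * PI / p;
          for (int t = 0; t <= lx; ++t)
            for (int u = 0; u <= ly; ++u)
              for (int w = 0; w <= lz; ++w)
                hp.D[(t * (LMAX + 1) + u) * (LMAX + 1) + w] +=
                  pref * Ex.get(A.lx, Bp.lx, t) * Ey.get(A.ly, Bp.ly, u)
                       * Ez.get(A.lz, Bp.lz, w);
        }
    }
  int M = pts.nrow();
  NumericVector out(M);
  int Lmax_all = 0;
  for (const HermitePair& hp : pairs) if (hp.L > Lmax_all) Lmax_all = hp.L;
  RTable R(Lmax_all);
  for (int m = 0; m < M; ++m) {
    double x = pts(m, 0), y = pts(m, 1), z = pts(m, 2);
    double acc = 0.0;
    for (const HermitePair& hp : pairs) {
      double Ax = hp.Px - x, Ay = hp.Py - y, Az = hp.Pz - z;
      if (hp.L == 0) {
        // pure s-type distribution: D[0] * F0(p r^2) directly
        double r2 = Ax * Ax + Ay * Ay + Az * Az;
        double xarg = hp.p * r2;
        double F0;
        if (xarg < 1e-14) F0 = 1.0;
        else F0 = 0.5 * std::sqrt(PI / xarg) * std::erf(std::sqrt(xarg));
        acc += hp.D[0] * F0;
        continue;
      }
      build_R(R, hp.L, hp.p, Ax, Ay, Az);
      for (int t = 0; t <= hp.lxa; ++t)
        for (int u = 0; u <= hp.lya; ++u)
          for (int w = 0; w <= hp.lza; ++w)
            acc += hp.D[(t * (LMAX + 1) + u) * (LMAX + 1) + w] * R.at(t, u, w);
    }
    out[m] = acc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Becke partition weights: for each point (attached to a parent atom),
// w = P_parent / sum_A P_A with cell functions from the k-times iterated
// smoothing polynomial f(mu) = 1.5 mu - 0.5 mu^3 (k = 3).

// [[Rcpp::export]]
NumericVector cpp_becke_weights(NumericMatrix pts, IntegerVector parent,
                                NumericMatrix atoms, int k_iter = 3) {
  int M = pts.nrow(), nat = atoms.nrow();
  NumericVector w(M);
  std::vector<double> rA(nat);
  std::vector<double> Rij(nat * nat);
  for (int a = 0; a < nat; ++a)
    for (int b = 0; b < nat; ++b) {
      double dx = atoms(a, 0) - atoms(b, 0);
      double dy = atoms(a, 1) - atoms(b, 1);
      double dz = atoms(a, 2) - atoms(b, 2);
      Rij[a * nat + b] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  std::vector<double> P(nat);
  for (int m = 0; m < M; ++m) {
    for (int a = 0; a < nat; ++a) {
      double dx = pts(m, 0) - atoms(a, 0);
      double dy = pts(m, 1) - atoms(a, 1);
      double dz = pts(m, 2) - atoms(a, 2);
      rA[a] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    double tot = 0.0;
    for (int a = 0; a < nat; ++a) {
      double p = 1.0;
      for (int b = 0; b < nat; ++b) {
        if (a == b) continue;
        double mu = (rA[a] - rA[b]) / Rij[a * nat + b];
        for (int it = 0; it < k_iter; ++it) mu = 1.5 * mu - 0.5 * mu * mu * mu;
        p *= 0.5 * (1.0 - mu);
      }
      P[a] = p;
      tot += p;
    }
    int par = parent[m] - 1;  // 1-based from R
    w[m] = (tot > 0.0) ? P[par] / tot : 0.0;
  }
  return w;
}

// ---------------------------------------------------------------------------
// Boys function exposed for tests
// [[Rcpp::export]]
NumericVector cpp_boys(int mmax, double x) {
  NumericVector out(mmax + 1);
  double F[32];
  boys(mmax, x, F);
  for (int m = 0; m <= mmax; ++m) out[m] = F[m];
  return out;
}
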