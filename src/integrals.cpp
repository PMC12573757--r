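// McMurchie-Davidson integral engine over uncontracted (single-primitive)
// spherical-harmonic Gaussian shells, with nuclear-coordinate derivatives.
//
// All shells carry exactly one primitive (the package uncontracts every basis
// before integrals are evaluated), which keeps the kernels free of
// contraction loops.  Supported angular momenta: s, p, d (spherical).
// Cartesian intermediates internally go one unit higher for derivatives.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------- utilities

static inline int ncart_l(int l) { return (l + 1) * (l + 2) / 2; }

struct CartList { std::vector<int> ix, iy, iz; };

static CartList cart_list(int l) {
  CartList c;
  for (int i = l; i >= 0; --i)
    for (int j = l - i; j >= 0; --j) {
      c.ix.push_back(i); c.iy.push_back(j); c.iz.push_back(l - i - j);
    }
  return c;
}

// real solid-harmonic coefficients, rows = 2l+1 spherical components,
// cols = Cartesian components in cart_list order.  All rows have equal norm
// so a single per-shell normalisation constant applies.
static std::vector<double> c2s_mat(int l) {
  const int nc = ncart_l(l), ns = 2 * l + 1;
  std::vector<double> m((size_t)ns * nc, 0.0);
  const double s3 = std::sqrt(3.0);
  if (l == 0) {
    m[0] = 1.0;
  } else if (l == 1) {               // carts x,y,z ; spherical kept as x,y,z
    m[0 * 3 + 0] = 1.0; m[1 * 3 + 1] = 1.0; m[2 * 3 + 2] = 1.0;
  } else if (l == 2) {               // carts xx,xy,xz,yy,yz,zz ; m=-2..2
    m[0 * 6 + 1] = s3;                                     // xy
    m[1 * 6 + 4] = s3;                                     // yz
    m[2 * 6 + 0] = -0.5; m[2 * 6 + 3] = -0.5; m[2 * 6 + 5] = 1.0; // 3z2-r2
    m[3 * 6 + 2] = s3;                                     // xz
    m[4 * 6 + 0] = 0.5 * s3; m[4 * 6 + 3] = -0.5 * s3;     // x2-y2
  } else {
    stop("angular momentum l > 2 is not supported (shells through d functions)");
  }
  return m;
}

static double dfact(int n) {           // (n)!!, with (-1)!! = 1
  double r = 1.0;
  for (int k = n; k > 1; k -= 2) r *= k;
  return r;
}

// normalisation of the raw solid harmonic r^l Y_lm exp(-a r^2)
static double shell_norm(double a, int l) {
  double n2 = std::pow(M_PI / (2.0 * a), 1.5) * dfact(2 * l - 1) /
              std::pow(4.0 * a, l);
  return 1.0 / std::sqrt(n2);
}

// ---------------------------------------------------------------- Boys F_m

static void boys(int m, double T, double* F) {
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    double eT = (T > 700.0) ? 0.0 : std::exp(-T);
    for (int k = 0; k < m; ++k) F[k + 1] = ((2 * k + 1) * F[k] - eT) / (2.0 * T);
  } else {
    double eT = std::exp(-T);
    double term = 1.0 / (2 * m + 1), s = term;
    for (int k = 1; k < 250; ++k) {
      term *= 2.0 * T / (2 * m + 2 * k + 1);
      s += term;
      if (term < s * 1e-17) break;
    }
    F[m] = eT * s;
    for (int k = m; k > 0; --k) F[k - 1] = (2.0 * T * F[k] + eT) / (2 * k - 1);
  }
}

// ------------------------------------------------- Hermite expansion tables

struct Etab {
  int im, jm, tm;
  std::vector<double> v;
  inline double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(size_t)(i * (jm + 1) + j) * (tm + 1) + t];
  }
};

static Etab buildE(int im, int jm, double a, double b, double A, double B) {
  Etab E; E.im = im; E.jm = jm; E.tm = im + jm;
  E.v.assign((size_t)(im + 1) * (jm + 1) * (E.tm + 1), 0.0);
  const double p = a + b, mu = a * b / p, X = A - B;
  const double XPA = -b * X / p, XPB = a * X / p;
  auto set = [&](int i, int j, int t, double val) {
    E.v[(size_t)(i * (jm + 1) + j) * (E.tm + 1) + t] = val;
  };
  set(0, 0, 0, std::exp(-mu * X * X));
  for (int i = 0; i < im; ++i)
    for (int t = 0; t <= i + 1; ++t)
      set(i + 1, 0, t, (t > 0 ? E.at(i, 0, t - 1) / (2.0 * p) : 0.0) +
                       XPA * E.at(i, 0, t) + (t + 1) * E.at(i, 0, t + 1));
  for (int j = 0; j < jm; ++j)
    for (int i = 0; i <= im; ++i)
      for (int t = 0; t <= i + j + 1; ++t)
        set(i, j + 1, t, (t > 0 ? E.at(i, j, t - 1) / (2.0 * p) : 0.0) +
                         XPB * E.at(i, j, t) + (t + 1) * E.at(i, j, t + 1));
  return E;
}

// ------------------------------------------------------ Hermite R integrals

struct Rtens {
  int L;
  std::vector<double> v;
  inline double at(int t, int u, int w) const {
    return v[(size_t)(t * (L + 1) + u) * (L + 1) + w];
  }
};

static void buildR(Rtens& R, int L, double p, double X, double Y, double Z) {
  const int n1 = L + 1;
  R.L = L;
  R.v.assign((size_t)n1 * n1 * n1, 0.0);
  const double T = p * (X * X + Y * Y + Z * Z);
  std::vector<double> F(L + 1);
  boys(L, T, F.data());
  std::vector<double> Rn((size_t)(L + 1) * n1 * n1 * n1, 0.0);
  auto idx = [&](int n, int t, int u, int w) {
    return (((size_t)n * n1 + t) * n1 + u) * n1 + w;
  };
  double pw = 1.0;
  for (int n = 0; n <= L; ++n) { Rn[idx(n, 0, 0, 0)] = pw * F[n]; pw *= -2.0 * p; }
  for (int sum = 1; sum <= L; ++sum)
    for (int n = 0; n <= L - sum; ++n)
      for (int t = 0; t <= sum; ++t)
        for (int u = 0; u <= sum - t; ++u) {
          const int w = sum - t - u;
          double val;
          if (t > 0)
            val = (t > 1 ? (t - 1) * Rn[idx(n + 1, t - 2, u, w)] : 0.0) +
                  X * Rn[idx(n + 1, t - 1, u, w)];
          else if (u > 0)
            val = (u > 1 ? (u - 1) * Rn[idx(n + 1, t, u - 2, w)] : 0.0) +
                  Y * Rn[idx(n + 1, t, u - 1, w)];
          else
            val = (w > 1 ? (w - 1) * Rn[idx(n + 1, t, u, w - 2)] : 0.0) +
                  Z * Rn[idx(n + 1, t, u, w - 1)];
          Rn[idx(n, t, u, w)] = val;
        }
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u <= L - t; ++u)
      for (int w = 0; w <= L - t - u; ++w)
        R.v[(size_t)(t * n1 + u) * n1 + w] = Rn[idx(0, t, u, w)];
}

// ----------------------------------------------------------------- shells

struct Shell {
  double x, y, z, e;
  int l, atom, off, nsph, ncart;
  double nrm;
};

static std::vector<Shell> parse_shells(const NumericMatrix& sm) {
  const int ns = sm.nrow();
  std::vector<Shell> S((size_t)ns);
  int off = 0;
  for (int i = 0; i < ns; ++i) {
    Shell s;
    s.atom = (int)sm(i, 0) - 1;
    s.l = (int)sm(i, 1);
    s.e = sm(i, 2);
    s.x = sm(i, 3); s.y = sm(i, 4); s.z = sm(i, 5);
    if (s.l < 0 || s.l > 2)
      stop("angular momentum l > 2 is not supported (shells through d functions)");
    s.ncart = ncart_l(s.l);
    s.nsph = 2 * s.l + 1;
    s.off = off;
    off += s.nsph;
    s.nrm = shell_norm(s.e, s.l);
    S[i] = s;
  }
  return S;
}

static int nbf_total(const std::vector<Shell>& S) {
  int n = 0;
  for (auto& s : S) n += s.nsph;
  return n;
}

// scaled solid-harmonic coefficients (normalisation folded in)
static std::vector<double> c2s_scaled(const Shell& s) {
  std::vector<double> m = c2s_mat(s.l);
  for (auto& x : m) x *= s.nrm;
  return m;
}

// ------------------------------------------------------------ pair context
// one-electron pair workspace: 1D overlap building blocks

struct PairCtx {
  const Shell *A, *B;
  double p, Px, Py, Pz, sp;  // sp = sqrt(pi/p)
  Etab Ex, Ey, Ez;
  inline double S1(int dim, int i, int j) const {
    const Etab& E = (dim == 0 ? Ex : (dim == 1 ? Ey : Ez));
    return E.at(i, j, 0) * sp;
  }
  // kinetic 1D: operator acts on ket exponent b
  inline double T1(int dim, int i, int j) const {
    const double b = B->e;
    double t = -2.0 * b * b * S1(dim, i, j + 2) + b * (2 * j + 1) * S1(dim, i, j);
    if (j >= 2) t -= 0.5 * j * (j - 1) * S1(dim, i, j - 2);
    return t;
  }
};

static PairCtx make_pair(const Shell& A, const Shell& B, int im, int jm) {
  PairCtx P;
  P.A = &A; P.B = &B;
  P.p = A.e + B.e;
  P.Px = (A.e * A.x + B.e * B.x) / P.p;
  P.Py = (A.e * A.y + B.e * B.y) / P.p;
  P.Pz = (A.e * A.z + B.e * B.z) / P.p;
  P.sp = std::sqrt(M_PI / P.p);
  P.Ex = buildE(im, jm, A.e, B.e, A.x, B.x);
  P.Ey = buildE(im, jm, A.e, B.e, A.y, B.y);
  P.Ez = buildE(im, jm, A.e, B.e, A.z, B.z);
  return P;
}

// 3D overlap over cartesian triples
static inline double S3(const PairCtx& P, int ix, int iy, int iz,
                        int jx, int jy, int jz) {
  if (ix < 0 || iy < 0 || iz < 0 || jx < 0 || jy < 0 || jz < 0) return 0.0;
  return P.S1(0, ix, jx) * P.S1(1, iy, jy) * P.S1(2, iz, jz);
}

static inline double T3(const PairCtx& P, int ix, int iy, int iz,
                        int jx, int jy, int jz) {
  if (ix < 0 || iy < 0 || iz < 0 || jx < 0 || jy < 0 || jz < 0) return 0.0;
  return P.T1(0, ix, jx) * P.S1(1, iy, jy) * P.S1(2, iz, jz) +
         P.S1(0, ix, jx) * P.T1(1, iy, jy) * P.S1(2, iz, jz) +
         P.S1(0, ix, jx) * P.S1(1, iy, jy) * P.T1(2, iz, jz);
}

// nuclear attraction for one nucleus (R tensor prepared for that nucleus);
// returns the positive integral <a| 1/|r-C| |b>
static inline double V3(const PairCtx& P, const Rtens& R,
                        int ix, int iy, int iz, int jx, int jy, int jz) {
  if (ix < 0 || iy < 0 || iz < 0 || jx < 0 || jy < 0 || jz < 0) return 0.0;
  double s = 0.0;
  for (int t = 0; t <= ix + jx; ++t) {
    const double ex = P.Ex.at(ix, jx, t);
    if (ex == 0.0) continue;
    for (int u = 0; u <= iy + jy; ++u) {
      const double ey = P.Ey.at(iy, jy, u);
      if (ey == 0.0) continue;
      for (int w = 0; w <= iz + jz; ++w)
        s += ex * ey * P.Ez.at(iz, jz, w) * R.at(t, u, w);
    }
  }
  return 2.0 * M_PI / P.p * s;
}

// electronic moment <a| x_k |b> about the global origin (expansion about B)
static inline double M3(const PairCtx& P, int k, int ix, int iy, int iz,
                        int jx, int jy, int jz) {
  int j1[3] = {jx, jy, jz};
  const double Bk = (k == 0 ? P.B->x : (k == 1 ? P.B->y : P.B->z));
  j1[k] += 1;
  return S3(P, ix, iy, iz, j1[0], j1[1], j1[2]) +
         Bk * S3(P, ix, iy, iz, jx, jy, jz);
}

// ----------------------------------------------- cart block -> sph in place

static void sph_transform(const Shell& A, const Shell& B,
                          const std::vector<double>& blk,  // [ncartA][ncartB]
                          std::vector<double>& out) {      // [nsphA][nsphB]
  const std::vector<double> Ca = c2s_scaled(A), Cb = c2s_scaled(B);
  out.assign((size_t)A.nsph * B.nsph, 0.0);
  for (int ma = 0; ma < A.nsph; ++ma)
    for (int ca = 0; ca < A.ncart; ++ca) {
      const double fa = Ca[(size_t)ma * A.ncart + ca];
      if (fa == 0.0) continue;
      for (int mb = 0; mb < B.nsph; ++mb) {
        double acc = 0.0;
        for (int cb = 0; cb < B.ncart; ++cb)
          acc += Cb[(size_t)mb * B.ncart + cb] * blk[(size_t)ca * B.ncart + cb];
        out[(size_t)ma * B.nsph + mb] += fa * acc;
      }
    }
}

// =======================================================================
//  base one-electron integrals
// =======================================================================

// [[Rcpp::export]]
List cpp_oei(NumericMatrix shellmat, NumericMatrix atoms, NumericVector origin) {
  std::vector<Shell> sh = parse_shells(shellmat);
  const int n = nbf_total(sh), ns = (int)sh.size(), nat = atoms.nrow();
  const double Ox = origin[0], Oy = origin[1], Oz = origin[2];

  NumericMatrix S(n, n), T(n, n), V(n, n);
  NumericMatrix MX(n, n), MY(n, n), MZ(n, n);
  NumericMatrix LX(n, n), LY(n, n), LZ(n, n);
  NumericMatrix QXX(n, n), QXY(n, n), QXZ(n, n), QYY(n, n), QYZ(n, n), QZZ(n, n);

  Rtens R;
  for (int ia = 0; ia < ns; ++ia)
    for (int jb = 0; jb < ns; ++jb) {
      const Shell &A = sh[ia], &B = sh[jb];
      PairCtx P = make_pair(A, B, A.l, B.l + 2);
      CartList ca = cart_list(A.l), cb = cart_list(B.l);
      const int nca = A.ncart, ncb = B.ncart;
      std::vector<double> bS(nca * ncb), bT(nca * ncb), bV(nca * ncb, 0.0);
      std::vector<double> bM[3], bL[3], bQ[6];
      for (int k = 0; k < 3; ++k) { bM[k].assign(nca * ncb, 0.0); bL[k].assign(nca * ncb, 0.0); }
      for (int k = 0; k < 6; ++k) bQ[k].assign(nca * ncb, 0.0);

      // nuclear attraction: accumulate -Z_C V_C
      std::vector<Rtens> Rc(nat);
      for (int c = 0; c < nat; ++c)
        buildR(Rc[c], A.l + B.l, P.p, P.Px - atoms(c, 1), P.Py - atoms(c, 2),
               P.Pz - atoms(c, 3));

      const double BO[3] = {B.x - Ox, B.y - Oy, B.z - Oz};
      const double bexp = B.e;

      for (int a = 0; a < nca; ++a) {
        const int ix = ca.ix[a], iy = ca.iy[a], iz = ca.iz[a];
        for (int b = 0; b < ncb; ++b) {
          const int jx = cb.ix[b], jy = cb.iy[b], jz = cb.iz[b];
          const size_t id = (size_t)a * ncb + b;
          bS[id] = S3(P, ix, iy, iz, jx, jy, jz);
          bT[id] = T3(P, ix, iy, iz, jx, jy, jz);
          double v = 0.0;
          for (int c = 0; c < nat; ++c)
            v -= atoms(c, 0) * V3(P, Rc[c], ix, iy, iz, jx, jy, jz);
          bV[id] = v;
          for (int k = 0; k < 3; ++k)
            bM[k][id] = M3(P, k, ix, iy, iz, jx, jy, jz);

          // second moments about O: per-dimension moment factors
          const int ii[3] = {ix, iy, iz};
          const int jj[3] = {jx, jy, jz};
          double s1[3], m1[3], m2[3];
          for (int k = 0; k < 3; ++k) {
            s1[k] = P.S1(k, ii[k], jj[k]);
            m1[k] = P.S1(k, ii[k], jj[k] + 1) + BO[k] * s1[k];
            m2[k] = P.S1(k, ii[k], jj[k] + 2) + 2.0 * BO[k] * P.S1(k, ii[k], jj[k] + 1) +
                    BO[k] * BO[k] * s1[k];
          }
          bQ[0][id] = m2[0] * s1[1] * s1[2];               // xx
          bQ[1][id] = m1[0] * m1[1] * s1[2];               // xy
          bQ[2][id] = m1[0] * s1[1] * m1[2];               // xz
          bQ[3][id] = s1[0] * m2[1] * s1[2];               // yy
          bQ[4][id] = s1[0] * m1[1] * m1[2];               // yz
          bQ[5][id] = s1[0] * s1[1] * m2[2];               // zz

          // angular momentum about O; d/dq |b> = j|b-1> - 2b|b+1> per dim
          auto sfac = [&](int k2, int dj) { return P.S1(k2, ii[k2], jj[k2] + dj); };
          auto dfac = [&](int k2) {        // <i| d/dq |j> in dimension k2
            double r = -2.0 * bexp * sfac(k2, +1);
            if (jj[k2] >= 1) r += jj[k2] * sfac(k2, -1);
            return r;
          };
          auto mfac = [&](int k2) {        // <i| (q-O) |j> in dimension k2
            return sfac(k2, +1) + BO[k2] * sfac(k2, 0);
          };
          // L_x = (y-Oy) d/dz - (z-Oz) d/dy  etc.
          const double sx = sfac(0, 0), sy = sfac(1, 0), sz = sfac(2, 0);
          bL[0][id] = mfac(1) * dfac(2) * sx - mfac(2) * dfac(1) * sx;
          bL[1][id] = mfac(2) * dfac(0) * sy - mfac(0) * dfac(2) * sy;
          bL[2][id] = mfac(0) * dfac(1) * sz - mfac(1) * dfac(0) * sz;
        }
      }

      std::vector<double> out;
      auto put = [&](NumericMatrix& Mmat, const std::vector<double>& blk) {
        sph_transform(A, B, blk, out);
        for (int ma = 0; ma < A.nsph; ++ma)
          for (int mb = 0; mb < B.nsph; ++mb)
            Mmat(A.off + ma, B.off + mb) = out[(size_t)ma * B.nsph + mb];
      };
      put(S, bS); put(T, bT); put(V, bV);
      put(MX, bM[0]); put(MY, bM[1]); put(MZ, bM[2]);
      put(LX, bL[0]); put(LY, bL[1]); put(LZ, bL[2]);
      put(QXX, bQ[0]); put(QXY, bQ[1]); put(QXZ, bQ[2]);
      put(QYY, bQ[3]); put(QYZ, bQ[4]); put(QZZ, bQ[5]);
    }

  return List::create(_["S"] = S, _["T"] = T, _["V"] = V,
                      _["MX"] = MX, _["MY"] = MY, _["MZ"] = MZ,
                      _["LX"] = LX, _["LY"] = LY, _["LZ"] = LZ,
                      _["QXX"] = QXX, _["QXY"] = QXY, _["QXZ"] = QXZ,
                      _["QYY"] = QYY, _["QYZ"] = QYZ, _["QZZ"] = QZZ);
}

// =======================================================================
//  one-electron derivative integrals
// =======================================================================
// Returns per atom, per direction: S1, H1 (= T1+V1 incl. Hellmann-Feynman
// operator term), and the derivatives of the electronic moment matrices.

// [[Rcpp::export]]
List cpp_oei_grad(NumericMatrix shellmat, NumericMatrix atoms) {
  std::vector<Shell> sh = parse_shells(shellmat);
  const int n = nbf_total(sh), ns = (int)sh.size(), nat = atoms.nrow();

  // storage: [atom][dir] -> matrices
  std::vector<std::vector<NumericMatrix>> dS(nat), dH(nat),
      dMX(nat), dMY(nat), dMZ(nat);
  for (int a = 0; a < nat; ++a)
    for (int d = 0; d < 3; ++d) {
      dS[a].push_back(NumericMatrix(n, n));
      dH[a].push_back(NumericMatrix(n, n));
      dMX[a].push_back(NumericMatrix(n, n));
      dMY[a].push_back(NumericMatrix(n, n));
      dMZ[a].push_back(NumericMatrix(n, n));
    }

  std::vector<double> out;
  for (int ia = 0; ia < ns; ++ia)
    for (int jb = 0; jb < ns; ++jb) {
      const Shell &A = sh[ia], &B = sh[jb];
      PairCtx P = make_pair(A, B, A.l + 1, B.l + 3);
      CartList ca = cart_list(A.l), cb = cart_list(B.l);
      const int nca = A.ncart, ncb = B.ncart;
      const double ae = A.e;

      std::vector<Rtens> Rc(nat);
      for (int c = 0; c < nat; ++c)
        buildR(Rc[c], A.l + 1 + B.l, P.p, P.Px - atoms(c, 1),
               P.Py - atoms(c, 2), P.Pz - atoms(c, 3));

      // per direction blocks
      std::vector<double> bS[3], bT[3], bM[3][3];
      std::vector<std::vector<double>> bVc[3];  // [dir][nucleus]
      for (int d = 0; d < 3; ++d) {
        bS[d].assign(nca * ncb, 0.0);
        bT[d].assign(nca * ncb, 0.0);
        for (int k = 0; k < 3; ++k) bM[d][k].assign(nca * ncb, 0.0);
        bVc[d].assign(nat, std::vector<double>(nca * ncb, 0.0));
      }

      for (int a = 0; a < nca; ++a) {
        int ii[3] = {ca.ix[a], ca.iy[a], ca.iz[a]};
        for (int b = 0; b < ncb; ++b) {
          int jj[3] = {cb.ix[b], cb.iy[b], cb.iz[b]};
          const size_t id = (size_t)a * ncb + b;
          for (int d = 0; d < 3; ++d) {
            int ip[3] = {ii[0], ii[1], ii[2]}, im[3] = {ii[0], ii[1], ii[2]};
            ip[d] += 1; im[d] -= 1;
            const double ci = ii[d];
            // overlap derivative (w.r.t. bra centre)
            bS[d][id] = 2.0 * ae * S3(P, ip[0], ip[1], ip[2], jj[0], jj[1], jj[2]);
            if (ci > 0)
              bS[d][id] -= ci * S3(P, im[0], im[1], im[2], jj[0], jj[1], jj[2]);
            bT[d][id] = 2.0 * ae * T3(P, ip[0], ip[1], ip[2], jj[0], jj[1], jj[2]);
            if (ci > 0)
              bT[d][id] -= ci * T3(P, im[0], im[1], im[2], jj[0], jj[1], jj[2]);
            for (int k = 0; k < 3; ++k) {
              bM[d][k][id] = 2.0 * ae * M3(P, k, ip[0], ip[1], ip[2], jj[0], jj[1], jj[2]);
              if (ci > 0)
                bM[d][k][id] -= ci * M3(P, k, im[0], im[1], im[2], jj[0], jj[1], jj[2]);
            }
            for (int c = 0; c < nat; ++c) {
              double v = 2.0 * ae * V3(P, Rc[c], ip[0], ip[1], ip[2], jj[0], jj[1], jj[2]);
              if (ci > 0)
                v -= ci * V3(P, Rc[c], im[0], im[1], im[2], jj[0], jj[1], jj[2]);
              bVc[d][c][id] = -atoms(c, 0) * v;   // -Z_C * d/dA <a|1/r_C|b>
            }
          }
        }
      }

      // mirror-write accumulation: each bra-derivative block contributes to
      // the bra atom at [mu][nu] and [nu][mu]; the nuclear-centre term gets
      // the negative by translational invariance.
      auto addsym = [&](NumericMatrix& Mmat, const std::vector<double>& blk,
                        double fac) {
        sph_transform(A, B, blk, out);
        for (int ma = 0; ma < A.nsph; ++ma)
          for (int mb = 0; mb < B.nsph; ++mb) {
            const double v = fac * out[(size_t)ma * B.nsph + mb];
            Mmat(A.off + ma, B.off + mb) += v;
            Mmat(B.off + mb, A.off + ma) += v;
          }
      };

      const int atA = A.atom;
      for (int d = 0; d < 3; ++d) {
        addsym(dS[atA][d], bS[d], 1.0);
        addsym(dH[atA][d], bT[d], 1.0);
        addsym(dMX[atA][d], bM[d][0], 1.0);
        addsym(dMY[atA][d], bM[d][1], 1.0);
        addsym(dMZ[atA][d], bM[d][2], 1.0);
        for (int c = 0; c < nat; ++c) {
          addsym(dH[atA][d], bVc[d][c], 1.0);
          addsym(dH[c][d], bVc[d][c], -1.0);   // operator-centre term
        }
      }
    }

  List res(nat);
  for (int a = 0; a < nat; ++a) {
    List dirs(3);
    for (int d = 0; d < 3; ++d)
      dirs[d] = List::create(_["S1"] = dS[a][d], _["H1"] = dH[a][d],
                             _["MX1"] = dMX[a][d], _["MY1"] = dMY[a][d],
                             _["MZ1"] = dMZ[a][d]);
    res[a] = dirs;
  }
  return res;
}

// =======================================================================
//  two-electron integrals
// =======================================================================

struct HermList {
  int L, nh;
  std::vector<std::array<int, 3>> h;
};

static HermList herm_list(int L) {
  HermList H; H.L = L;
  for (int s = 0; s <= L; ++s)
    for (int t = s; t >= 0; --t)
      for (int u = s - t; u >= 0; --u)
        H.h.push_back({t, u, s - t - u});
  H.nh = (int)H.h.size();
  return H;
}

struct EPair {
  int a, b;                 // shell indices (a >= b)
  double p, Px, Py, Pz;
  int L, nsab;
  std::vector<double> SEH;           // [nsab][nh(L)]
  std::vector<double> dSEH[6];       // A_x,A_y,A_z,B_x,B_y,B_z : [nsab][nh(L+1)]
  double Q;                          // Cauchy-Schwarz factor
};

// build spherical x hermite contraction tables for a shell pair
static void build_pair_tables(const std::vector<Shell>& sh, int ia, int ib,
                              bool derivs, const HermList& HB, const HermList& HD,
                              EPair& EP) {
  const Shell &A = sh[ia], &B = sh[ib];
  EP.a = ia; EP.b = ib;
  EP.p = A.e + B.e;
  EP.Px = (A.e * A.x + B.e * B.x) / EP.p;
  EP.Py = (A.e * A.y + B.e * B.y) / EP.p;
  EP.Pz = (A.e * A.z + B.e * B.z) / EP.p;
  EP.L = A.l + B.l;
  EP.nsab = A.nsph * B.nsph;

  const int im = A.l + (derivs ? 1 : 0), jm = B.l + (derivs ? 1 : 0);
  Etab Ex = buildE(im, jm, A.e, B.e, A.x, B.x);
  Etab Ey = buildE(im, jm, A.e, B.e, A.y, B.y);
  Etab Ez = buildE(im, jm, A.e, B.e, A.z, B.z);

  CartList ca = cart_list(A.l), cb = cart_list(B.l);
  const int nca = A.ncart, ncb = B.ncart;
  const std::vector<double> Ca = c2s_scaled(A), Cb = c2s_scaled(B);

  auto contract = [&](int braShift, int ketShift, int dim, double wplus,
                      double wminus, const HermList& H, std::vector<double>& out) {
    // generic: E-product with bra index shifted by +/-1 in `dim`
    // (wplus multiplies +1 term, wminus the -1 term; shift applies to bra if
    //  braShift!=0 else to ket)
    out.assign((size_t)EP.nsab * H.nh, 0.0);
    std::vector<double> EH((size_t)nca * ncb * H.nh, 0.0);
    for (int a = 0; a < nca; ++a) {
      int ii[3] = {ca.ix[a], ca.iy[a], ca.iz[a]};
      for (int b = 0; b < ncb; ++b) {
        int jj[3] = {cb.ix[b], cb.iy[b], cb.iz[b]};
        for (int hh = 0; hh < H.nh; ++hh) {
          const int t = H.h[hh][0], u = H.h[hh][1], w = H.h[hh][2];
          const int tuv[3] = {t, u, w};
          double val = 0.0;
          if (braShift == 0 && ketShift == 0) {
            double f = 1.0;
            const Etab* Es[3] = {&Ex, &Ey, &Ez};
            for (int k = 0; k < 3; ++k) f *= Es[k]->at(ii[k], jj[k], tuv[k]);
            val = f;
          } else {
            const Etab* Es[3] = {&Ex, &Ey, &Ez};
            // factors for the two unshifted dims
            double base = 1.0;
            for (int k = 0; k < 3; ++k)
              if (k != dim) base *= Es[k]->at(ii[k], jj[k], tuv[k]);
            double fd = 0.0;
            if (braShift != 0) {
              fd = wplus * Es[dim]->at(ii[dim] + 1, jj[dim], tuv[dim]);
              if (ii[dim] > 0)
                fd += wminus * ii[dim] * Es[dim]->at(ii[dim] - 1, jj[dim], tuv[dim]);
            } else {
              fd = wplus * Es[dim]->at(ii[dim], jj[dim] + 1, tuv[dim]);
              if (jj[dim] > 0)
                fd += wminus * jj[dim] * Es[dim]->at(ii[dim], jj[dim] - 1, tuv[dim]);
            }
            val = base * fd;
          }
          EH[((size_t)a * ncb + b) * H.nh + hh] = val;
        }
      }
    }
    // spherical transform
    for (int ma = 0; ma < A.nsph; ++ma)
      for (int ca2 = 0; ca2 < nca; ++ca2) {
        const double fa = Ca[(size_t)ma * nca + ca2];
        if (fa == 0.0) continue;
        for (int mb = 0; mb < B.nsph; ++mb) {
          const double* src0 = nullptr;
          for (int cb2 = 0; cb2 < ncb; ++cb2) {
            const double f = fa * Cb[(size_t)mb * ncb + cb2];
            if (f == 0.0) continue;
            src0 = &EH[((size_t)ca2 * ncb + cb2) * H.nh];
            double* dst = &out[((size_t)(ma * B.nsph + mb)) * H.nh];
            for (int hh = 0; hh < H.nh; ++hh) dst[hh] += f * src0[hh];
          }
        }
      }
  };

  contract(0, 0, 0, 0.0, 0.0, HB, EP.SEH);
  if (derivs) {
    for (int d = 0; d < 3; ++d) {
      contract(1, 0, d, 2.0 * A.e, -1.0, HD, EP.dSEH[d]);       // d/dA_d
      contract(0, 1, d, 2.0 * B.e, -1.0, HD, EP.dSEH[3 + d]);   // d/dB_d
    }
  }
}

// base quartet: fills g[nsab][nscd] (spherical)
static void quartet(const EPair& Pb, const EPair& Pk,
                    const HermList& Hb, const HermList& Hk,
                    Rtens& R, std::vector<double>& mid, std::vector<double>& g) {
  const double psum = Pb.p + Pk.p;
  const double alpha = Pb.p * Pk.p / psum;
  buildR(R, Pb.L + Pk.L, alpha, Pb.Px - Pk.Px, Pb.Py - Pk.Py, Pb.Pz - Pk.Pz);
  const double pref = 2.0 * std::pow(M_PI, 2.5) /
                      (Pb.p * Pk.p * std::sqrt(psum));
  const int nab = Pb.nsab, ncd = Pk.nsab;
  mid.assign((size_t)nab * Hk.nh, 0.0);
  for (int ab = 0; ab < nab; ++ab) {
    const double* eb = &Pb.SEH[(size_t)ab * Hb.nh];
    double* m = &mid[(size_t)ab * Hk.nh];
    for (int h1 = 0; h1 < Hb.nh; ++h1) {
      const double f = eb[h1];
      if (f == 0.0) continue;
      const int t1 = Hb.h[h1][0], u1 = Hb.h[h1][1], v1 = Hb.h[h1][2];
      for (int h2 = 0; h2 < Hk.nh; ++h2)
        m[h2] += f * R.at(t1 + Hk.h[h2][0], u1 + Hk.h[h2][1], v1 + Hk.h[h2][2]);
    }
  }
  g.assign((size_t)nab * ncd, 0.0);
  for (int ab = 0; ab < nab; ++ab) {
    const double* m = &mid[(size_t)ab * Hk.nh];
    for (int cd = 0; cd < ncd; ++cd) {
      const double* ek = &Pk.SEH[(size_t)cd * Hk.nh];
      double acc = 0.0;
      for (int h2 = 0; h2 < Hk.nh; ++h2) {
        const int sg = (Hk.h[h2][0] + Hk.h[h2][1] + Hk.h[h2][2]) & 1;
        acc += (sg ? -ek[h2] : ek[h2]) * m[h2];
      }
      g[(size_t)ab * ncd + cd] = pref * acc;
    }
  }
}

static inline size_t tri(size_t i) { return i * (i + 1) / 2; }

// [[Rcpp::export]]
List cpp_eri(NumericMatrix shellmat, double thresh) {
  std::vector<Shell> sh = parse_shells(shellmat);
  const int ns = (int)sh.size(), n = nbf_total(sh);
  const size_t np = tri((size_t)n - 1) + (size_t)n;  // n(n+1)/2
  const size_t len = tri(np - 1) + np;
  if (len > 250000000ULL) stop("two-electron integral store exceeds capacity (%d basis functions)", n);
  NumericVector packed((R_xlen_t)len);

  // pair list (shell-level, a >= b)
  std::vector<EPair> pairs;
  HermList H[5];
  for (int L = 0; L <= 4; ++L) H[L] = herm_list(L);
  for (int a = 0; a < ns; ++a)
    for (int b = 0; b <= a; ++b) {
      EPair EP;
      build_pair_tables(sh, a, b, false, H[sh[a].l + sh[b].l], H[0], EP);
      pairs.push_back(std::move(EP));
    }
  // Schwarz factors
  Rtens R; std::vector<double> mid, g;
  for (auto& EP : pairs) {
    quartet(EP, EP, H[EP.L], H[EP.L], R, mid, g);
    double q = 0.0;
    const int nab = EP.nsab;
    for (int ab = 0; ab < nab; ++ab) {
      const double d = std::fabs(g[(size_t)ab * nab + ab]);
      if (d > q) q = d;
    }
    EP.Q = std::sqrt(q);
  }

  const int npair = (int)pairs.size();
  for (int pp = 0; pp < npair; ++pp) {
    const EPair& Pb = pairs[pp];
    const Shell &A = sh[Pb.a], &B = sh[Pb.b];
    for (int qq = 0; qq <= pp; ++qq) {
      const EPair& Pk = pairs[qq];
      if (Pb.Q * Pk.Q < thresh) continue;
      const Shell &C = sh[Pk.a], &D = sh[Pk.b];
      quartet(Pb, Pk, H[Pb.L], H[Pk.L], R, mid, g);
      const int nsb = B.nsph, nsd = D.nsph, nsc = C.nsph;
      for (int ma = 0; ma < A.nsph; ++ma)
        for (int mb = 0; mb < nsb; ++mb) {
          const int ib = (ma * nsb + mb);
          const int AA = A.off + ma, BB = B.off + mb;
          const size_t P1 = (AA >= BB) ? tri((size_t)AA) + BB : tri((size_t)BB) + AA;
          for (int mc = 0; mc < nsc; ++mc)
            for (int md = 0; md < nsd; ++md) {
              const int CC = C.off + mc, DD = D.off + md;
              const size_t P2 = (CC >= DD) ? tri((size_t)CC) + DD : tri((size_t)DD) + CC;
              const size_t idx = (P1 >= P2) ? tri(P1) + P2 : tri(P2) + P1;
              packed[(R_xlen_t)idx] = g[(size_t)ib * (nsc * nsd) + mc * nsd + md];
            }
        }
    }
  }

  NumericMatrix schwarz(ns, ns);
  for (auto& EP : pairs) {
    schwarz(EP.a, EP.b) = EP.Q;
    schwarz(EP.b, EP.a) = EP.Q;
  }
  return List::create(_["packed"] = packed, _["n"] = n, _["schwarz"] = schwarz);
}

// General-density Fock contraction G(D)_uv = sum_rs D_rs (2 g_uvrs - g_usrv).
// A fast path assuming D symmetric is used unless `general` is set.
// [[Rcpp::export]]
NumericMatrix cpp_fock2e(NumericVector packed, int n, NumericMatrix D,
                         bool general = false) {
  const size_t np = tri((size_t)n - 1) + (size_t)n;
  NumericMatrix F(n, n);
  std::vector<int> pa(np), pb(np);
  {
    size_t P = 0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j <= i; ++j) { pa[P] = i; pb[P] = j; ++P; }
  }
  const double* Dp = D.begin();
  double* Fp = F.begin();
  const double* G = packed.begin();
  if (general) {
    auto acc = [&](int i, int j, int k, int l, double v) {
      Fp[i + (size_t)n * j] += 2.0 * v * Dp[k + (size_t)n * l];
      Fp[i + (size_t)n * l] -= v * Dp[k + (size_t)n * j];
    };
    size_t idx = 0;
    for (size_t P = 0; P < np; ++P) {
      const int a = pa[P], b = pb[P];
      for (size_t Q = 0; Q <= P; ++Q, ++idx) {
        double v = G[idx];
        if (v == 0.0) continue;
        const int c = pa[Q], d = pb[Q];
        if (a == b) v *= 0.5;
        if (c == d) v *= 0.5;
        if (P == Q) v *= 0.5;
        acc(a, b, c, d, v); acc(b, a, c, d, v);
        acc(a, b, d, c, v); acc(b, a, d, c, v);
        acc(c, d, a, b, v); acc(d, c, a, b, v);
        acc(c, d, b, a, v); acc(d, c, b, a, v);
      }
    }
    return F;
  }
  // symmetric-density path: Coulomb on packed pairs, exchange on 8 updates
  std::vector<double> Jp(np, 0.0), dP(np);
  {
    size_t P = 0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j <= i; ++j, ++P)
        dP[P] = Dp[i + (size_t)n * j] * (i == j ? 1.0 : 2.0);
  }
  std::vector<double> K((size_t)n * n, 0.0);
  size_t idx = 0;
  for (size_t P = 0; P < np; ++P) {
    const int a = pa[P], b = pb[P];
    for (size_t Q = 0; Q <= P; ++Q, ++idx) {
      double v = G[idx];
      if (v == 0.0) continue;
      const int c = pa[Q], d = pb[Q];
      double vj = (P == Q) ? 0.5 * v : v;
      Jp[P] += vj * dP[Q];
      Jp[Q] += vj * dP[P];
      if (a == b) v *= 0.5;
      if (c == d) v *= 0.5;
      if (P == Q) v *= 0.5;
      K[a + (size_t)n * d] += v * Dp[c + (size_t)n * b];
      K[b + (size_t)n * d] += v * Dp[c + (size_t)n * a];
      K[a + (size_t)n * c] += v * Dp[d + (size_t)n * b];
      K[b + (size_t)n * c] += v * Dp[d + (size_t)n * a];
      K[c + (size_t)n * b] += v * Dp[a + (size_t)n * d];
      K[d + (size_t)n * b] += v * Dp[a + (size_t)n * c];
      K[c + (size_t)n * a] += v * Dp[b + (size_t)n * d];
      K[d + (size_t)n * a] += v * Dp[b + (size_t)n * c];
    }
  }
  for (size_t P = 0; P < np; ++P) {
    const int a = pa[P], b = pb[P];
    Fp[a + (size_t)n * b] = 2.0 * Jp[P];
    Fp[b + (size_t)n * a] = 2.0 * Jp[P];
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      Fp[i + (size_t)n * j] -= K[i + (size_t)n * j];
  return F;
}

// dense 4-index array for small systems (test oracles, complex-field runs)
// [[Rcpp::export]]
NumericVector cpp_eri_dense(NumericMatrix shellmat) {
  std::vector<Shell> sh = parse_shells(shellmat);
  const int ns = (int)sh.size(), n = nbf_total(sh);
  if (n > 72) stop("dense two-electron tensor limited to 72 basis functions");
  NumericVector out((R_xlen_t)n * n * n * n);
  HermList H[5];
  for (int L = 0; L <= 4; ++L) H[L] = herm_list(L);
  std::vector<EPair> pairs;
  for (int a = 0; a < ns; ++a)
    for (int b = 0; b <= a; ++b) {
      EPair EP;
      build_pair_tables(sh, a, b, false, H[sh[a].l + sh[b].l], H[0], EP);
      pairs.push_back(std::move(EP));
    }
  Rtens R; std::vector<double> mid, g;
  double* O = out.begin();
  auto put = [&](int i, int j, int k, int l, double v) {
    O[((size_t)i * n + j) * n * n + (size_t)k * n + l] = v;
  };
  const int npair = (int)pairs.size();
  for (int pp = 0; pp < npair; ++pp) {
    const EPair& Pb = pairs[pp];
    const Shell &A = sh[Pb.a], &B = sh[Pb.b];
    for (int qq = 0; qq <= pp; ++qq) {
      const EPair& Pk = pairs[qq];
      const Shell &C = sh[Pk.a], &D = sh[Pk.b];
      quartet(Pb, Pk, H[Pb.L], H[Pk.L], R, mid, g);
      for (int ma = 0; ma < A.nsph; ++ma)
        for (int mb = 0; mb < B.nsph; ++mb)
          for (int mc = 0; mc < C.nsph; ++mc)
            for (int md = 0; md < D.nsph; ++md) {
              const double v = g[(size_t)(ma * B.nsph + mb) * (C.nsph * D.nsph) +
                                 mc * D.nsph + md];
              const int i = A.off + ma, j = B.off + mb,
                        k = C.off + mc, l = D.off + md;
              put(i, j, k, l, v); put(j, i, k, l, v);
              put(i, j, l, k, v); put(j, i, l, k, v);
              put(k, l, i, j, v); put(l, k, i, j, v);
              put(k, l, j, i, v); put(l, k, j, i, v);
            }
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  return out;
}

// =======================================================================
//  two-electron gradient contraction:  per atom Tr(D Ge^(1)(D))
// =======================================================================

// [[Rcpp::export]]
NumericMatrix cpp_eri_grad(NumericMatrix shellmat, NumericMatrix D, int natom,
                           double thresh) {
  std::vector<Shell> sh = parse_shells(shellmat);
  const int ns = (int)sh.size(), n = nbf_total(sh);
  NumericMatrix grad(natom, 3);

  HermList H[6];
  for (int L = 0; L <= 5; ++L) H[L] = herm_list(L);

  std::vector<EPair> pairs;
  for (int a = 0; a < ns; ++a)
    for (int b = 0; b <= a; ++b) {
      EPair EP;
      build_pair_tables(sh, a, b, true, H[sh[a].l + sh[b].l],
                        H[sh[a].l + sh[b].l + 1], EP);
      pairs.push_back(std::move(EP));
    }
  Rtens R; std::vector<double> mid, g;
  for (auto& EP : pairs) {
    quartet(EP, EP, H[EP.L], H[EP.L], R, mid, g);
    double q = 0.0;
    for (int ab = 0; ab < EP.nsab; ++ab)
      q = std::max(q, std::fabs(g[(size_t)ab * EP.nsab + ab]));
    EP.Q = std::sqrt(q);
  }

  // shell-block max |D| for screening
  std::vector<double> DS((size_t)ns * ns, 0.0);
  for (int a = 0; a < ns; ++a)
    for (int b = 0; b < ns; ++b) {
      double m = 0.0;
      for (int i = 0; i < sh[a].nsph; ++i)
        for (int j = 0; j < sh[b].nsph; ++j)
          m = std::max(m, std::fabs(D(sh[a].off + i, sh[b].off + j)));
      DS[(size_t)a * ns + b] = m;
    }

  const int npair = (int)pairs.size();
  std::vector<double> Gm, Vb, M2, V2;
  for (int pp = 0; pp < npair; ++pp) {
    const EPair& Pb = pairs[pp];
    const Shell &A = sh[Pb.a], &B = sh[Pb.b];
    const HermList &Hb = H[Pb.L], &HbD = H[Pb.L + 1];
    for (int qq = 0; qq <= pp; ++qq) {
      const EPair& Pk = pairs[qq];
      const Shell &C = sh[Pk.a], &D2 = sh[Pk.b];
      const double dmax =
          16.0 * DS[(size_t)Pb.a * ns + Pb.b] * DS[(size_t)Pk.a * ns + Pk.b] +
          4.0 * DS[(size_t)Pb.a * ns + Pk.a] * DS[(size_t)Pb.b * ns + Pk.b] +
          4.0 * DS[(size_t)Pb.a * ns + Pk.b] * DS[(size_t)Pb.b * ns + Pk.a];
      if (Pb.Q * Pk.Q * dmax < thresh) continue;
      const HermList &Hk = H[Pk.L], &HkD = H[Pk.L + 1];

      double s = 1.0;
      if (Pb.a == Pb.b) s *= 0.5;
      if (Pk.a == Pk.b) s *= 0.5;
      if (pp == qq) s *= 0.5;

      const int nab = Pb.nsab, ncd = Pk.nsab;
      const int nsb = B.nsph, nsd = D2.nsph, nsc = C.nsph;

      // symmetrised two-particle density for this quartet
      Gm.assign((size_t)nab * ncd, 0.0);
      for (int ma = 0; ma < A.nsph; ++ma)
        for (int mb = 0; mb < nsb; ++mb) {
          const int ia = A.off + ma, ib = B.off + mb;
          const double Dab = D(ia, ib);
          for (int mc = 0; mc < nsc; ++mc)
            for (int md = 0; md < nsd; ++md) {
              const int ic = C.off + mc, id = D2.off + md;
              Gm[(size_t)(ma * nsb + mb) * ncd + mc * nsd + md] =
                  s * (16.0 * Dab * D(ic, id) -
                       4.0 * D(ia, ic) * D(ib, id) -
                       4.0 * D(ia, id) * D(ib, ic));
            }
        }

      // R tensor to combined order +1
      const double psum = Pb.p + Pk.p;
      const double alpha = Pb.p * Pk.p / psum;
      buildR(R, Pb.L + Pk.L + 1, alpha, Pb.Px - Pk.Px, Pb.Py - Pk.Py,
             Pb.Pz - Pk.Pz);
      const double pref = 2.0 * std::pow(M_PI, 2.5) /
                          (Pb.p * Pk.p * std::sqrt(psum));

      // --- bra-centre derivatives ---
      // M[ab][h2] = sum_cd Gm * SEH_ket ; V[ab][h1'] = sum_h2 s2 M R(h1'+h2)
      mid.assign((size_t)nab * Hk.nh, 0.0);
      for (int ab = 0; ab < nab; ++ab) {
        double* m = &mid[(size_t)ab * Hk.nh];
        const double* gr = &Gm[(size_t)ab * ncd];
        for (int cd = 0; cd < ncd; ++cd) {
          const double f = gr[cd];
          if (f == 0.0) continue;
          const double* ek = &Pk.SEH[(size_t)cd * Hk.nh];
          for (int h2 = 0; h2 < Hk.nh; ++h2) m[h2] += f * ek[h2];
        }
      }
      Vb.assign((size_t)nab * HbD.nh, 0.0);
      for (int ab = 0; ab < nab; ++ab) {
        const double* m = &mid[(size_t)ab * Hk.nh];
        double* vv = &Vb[(size_t)ab * HbD.nh];
        for (int h2 = 0; h2 < Hk.nh; ++h2) {
          double f = m[h2];
          if (f == 0.0) continue;
          const int sg = (Hk.h[h2][0] + Hk.h[h2][1] + Hk.h[h2][2]) & 1;
          if (sg) f = -f;
          const int t2 = Hk.h[h2][0], u2 = Hk.h[h2][1], w2 = Hk.h[h2][2];
          for (int h1 = 0; h1 < HbD.nh; ++h1)
            vv[h1] += f * R.at(HbD.h[h1][0] + t2, HbD.h[h1][1] + u2,
                               HbD.h[h1][2] + w2);
        }
      }
      double dAB[6];
      for (int m6 = 0; m6 < 6; ++m6) {
        double acc = 0.0;
        const std::vector<double>& dt = Pb.dSEH[m6];
        for (int ab = 0; ab < nab; ++ab) {
          const double* a1 = &dt[(size_t)ab * HbD.nh];
          const double* vv = &Vb[(size_t)ab * HbD.nh];
          for (int h1 = 0; h1 < HbD.nh; ++h1) acc += a1[h1] * vv[h1];
        }
        dAB[m6] = pref * acc;
      }

      // --- ket-centre derivatives (both C and D computed directly) ---
      M2.assign((size_t)ncd * Hb.nh, 0.0);
      for (int cd = 0; cd < ncd; ++cd) {
        double* m = &M2[(size_t)cd * Hb.nh];
        for (int ab = 0; ab < nab; ++ab) {
          const double f = Gm[(size_t)ab * ncd + cd];
          if (f == 0.0) continue;
          const double* eb = &Pb.SEH[(size_t)ab * Hb.nh];
          for (int h1 = 0; h1 < Hb.nh; ++h1) m[h1] += f * eb[h1];
        }
      }
      V2.assign((size_t)ncd * HkD.nh, 0.0);
      for (int cd = 0; cd < ncd; ++cd) {
        const double* m = &M2[(size_t)cd * Hb.nh];
        double* vv = &V2[(size_t)cd * HkD.nh];
        for (int h1 = 0; h1 < Hb.nh; ++h1) {
          const double f = m[h1];
          if (f == 0.0) continue;
          const int t1 = Hb.h[h1][0], u1 = Hb.h[h1][1], w1 = Hb.h[h1][2];
          for (int h2 = 0; h2 < HkD.nh; ++h2)
            vv[h2] += f * R.at(t1 + HkD.h[h2][0], u1 + HkD.h[h2][1],
                               w1 + HkD.h[h2][2]);
        }
      }
      double dCD[6];
      for (int m6 = 0; m6 < 6; ++m6) {
        double acc = 0.0;
        const std::vector<double>& dt = Pk.dSEH[m6];
        for (int cd = 0; cd < ncd; ++cd) {
          const double* a1 = &dt[(size_t)cd * HkD.nh];
          const double* vv = &V2[(size_t)cd * HkD.nh];
          for (int h2 = 0; h2 < HkD.nh; ++h2) {
            const int sg = (HkD.h[h2][0] + HkD.h[h2][1] + HkD.h[h2][2]) & 1;
            acc += (sg ? -a1[h2] : a1[h2]) * vv[h2];
          }
        }
        dCD[m6] = pref * acc;
      }

      const int atA = A.atom, atB = B.atom, atC = C.atom, atD = D2.atom;
      for (int d = 0; d < 3; ++d) {
        grad(atA, d) += dAB[d];
        grad(atB, d) += dAB[3 + d];
        grad(atC, d) += dCD[d];
        grad(atD, d) += dCD[3 + d];
      }
    }
  }
  return grad;
}
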