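// Gaussian-basis one- and two-electron integrals and derivative contractions,
// McMurchie-Davidson scheme (Hermite expansion of Cartesian Gaussian products,
// Hermite Coulomb R-tensor with Boys function).  Cartesian shells of arbitrary
// angular momentum; derivatives with respect to Gaussian centers obtained from
// the angular-momentum raising/lowering identity
//   d/dAx E_t(i,j) = 2a E_t(i+1,j) - i E_t(i-1,j)
// which is exact because the product-Gaussian center P is unchanged when only
// the polynomial part is raised.  Operator-center derivatives follow from
// translational invariance.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------- shell data

struct Shell {
  int l;                    // angular momentum
  int atom;                 // 0-based atom index
  double R[3];              // center (bohr)
  std::vector<double> a;    // primitive exponents
  std::vector<double> c;    // primitive coefficients, normalized for (l,0,0)
  std::vector<double> fcomp; // per-component normalization factor
  std::vector<int> lx, ly, lz; // Cartesian component powers
  int off;                  // AO offset (0-based)
  int ncart() const { return (l + 1) * (l + 2) / 2; }
};

static double dfact(int n) { // (n)!! with (-1)!! = 1
  double r = 1.0;
  for (int k = n; k > 1; k -= 2) r *= k;
  return r;
}

static std::vector<Shell> parse_shells(const List& basis) {
  std::vector<Shell> sh(basis.size());
  for (int s = 0; s < basis.size(); ++s) {
    List b = basis[s];
    Shell& S = sh[s];
    S.l = as<int>(b["l"]);
    S.atom = as<int>(b["atom"]) - 1;
    NumericVector R = b["center"];
    for (int k = 0; k < 3; ++k) S.R[k] = R[k];
    S.a = as<std::vector<double> >(b["alpha"]);
    S.c = as<std::vector<double> >(b["coef"]);
    S.off = as<int>(b["offset"]) - 1;
    for (int ix = S.l; ix >= 0; --ix)
      for (int iy = S.l - ix; iy >= 0; --iy) {
        int iz = S.l - ix - iy;
        S.lx.push_back(ix); S.ly.push_back(iy); S.lz.push_back(iz);
        S.fcomp.push_back(std::sqrt(dfact(2 * S.l - 1) /
          (dfact(2 * ix - 1) * dfact(2 * iy - 1) * dfact(2 * iz - 1))));
      }
  }
  return sh;
}

static int nao_of(const std::vector<Shell>& sh) {
  int n = 0;
  for (size_t s = 0; s < sh.size(); ++s) n += sh[s].ncart();
  return n;
}

// ------------------------------------------------------------ E coefficients

// E[i][j][t] Hermite expansion coefficients along one dimension.
struct Etab {
  int imax, jmax, tdim;
  std::vector<double> v;
  void build(int im, int jm, double a, double b, double AB) {
    imax = im; jmax = jm; tdim = im + jm + 1;
    v.assign((im + 1) * (jm + 1) * tdim, 0.0);
    double p = a + b, mu = a * b / p;
    double PA = -b / p * AB, PB = a / p * AB;
    at(0, 0, 0) = std::exp(-mu * AB * AB);
    for (int i = 1; i <= im; ++i)
      for (int t = 0; t <= i; ++t) {
        double x = 0.0;
        if (t > 0) x += at(i - 1, 0, t - 1) / (2.0 * p);
        x += PA * at(i - 1, 0, t);
        if (t + 1 <= i - 1) x += (t + 1) * at(i - 1, 0, t + 1);
        at(i, 0, t) = x;
      }
    for (int j = 1; j <= jm; ++j)
      for (int i = 0; i <= im; ++i)
        for (int t = 0; t <= i + j; ++t) {
          double x = 0.0;
          if (t > 0) x += at(i, j - 1, t - 1) / (2.0 * p);
          x += PB * at(i, j - 1, t);
          if (t + 1 <= i + j - 1) x += (t + 1) * at(i, j - 1, t + 1);
          at(i, j, t) = x;
        }
  }
  double& at(int i, int j, int t) { return v[(i * (jmax + 1) + j) * tdim + t]; }
  double get(int i, int j, int t) const {
    if (i < 0 || j < 0 || t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * tdim + t];
  }
  // derivative of E_t(i,j) with respect to the first center coordinate
  double dA(int i, int j, int t, double a) const {
    return 2.0 * a * get(i + 1, j, t) - i * get(i - 1, j, t);
  }
  // derivative with respect to the second center coordinate
  double dB(int i, int j, int t, double b) const {
    return 2.0 * b * get(i, j + 1, t) - j * get(i, j - 1, t);
  }
};

// --------------------------------------------------------------------- Boys

static void boys(int mmax, double T, double* F) {
  if (T < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T <= 35.0) {
    // series for F_mmax, then downward recursion
    double num = 1.0, den = 2.0 * mmax + 1.0, term = 1.0 / den, sum = term;
    for (int i = 1; i < 200; ++i) {
      num *= 2.0 * T;
      den *= 2.0 * mmax + 2.0 * i + 1.0;
      term = num / den;
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    double eT = std::exp(-T);
    F[mmax] = eT * sum;
    for (int m = mmax; m >= 1; --m)
      F[m - 1] = (2.0 * T * F[m] + eT) / (2.0 * m - 1.0);
  } else {
    double eT = std::exp(-T);
    F[0] = 0.5 * std::sqrt(PI / T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - eT) / (2.0 * T);
  }
}

// ------------------------------------------------------------ Hermite R tensor

// R[t][u][v] = (d/dPx)^t (d/dPy)^u (d/dPz)^v F0(alpha, |P-C|^2) Coulomb kernel
struct Rtab {
  int tx, ty, tz;
  std::vector<double> v;
  std::vector<double> F, Rn;  // persistent scratch (grown once, reused)
  void build(int tx_, int ty_, int tz_, double alpha,
             double X, double Y, double Z) {
    tx = tx_; ty = ty_; tz = tz_;
    int N = tx + ty + tz;
    F.resize(N + 1);
    double r2 = X * X + Y * Y + Z * Z;
    boys(N, alpha * r2, &F[0]);
    int d1 = (ty + 1) * (tz + 1), sz = (tx + 1) * d1;
    Rn.assign((size_t)(N + 1) * sz, 0.0);
    double pw = 1.0;
    for (int n = 0; n <= N; ++n) { Rn[n * sz] = pw * F[n]; pw *= -2.0 * alpha; }
    for (int n = N - 1; n >= 0; --n) {
      // only entries with t+u+w <= N-n are ever consumed
      int cap = N - n;
      for (int t = 0; t <= tx && t <= cap; ++t)
        for (int u = 0; u <= ty && t + u <= cap; ++u)
          for (int w = 0; w <= tz && t + u + w <= cap; ++w) {
            if (t + u + w == 0) continue;
            double x = 0.0;
            int b = (n + 1) * sz;
            if (t > 0) {
              if (t > 1) x += (t - 1) * Rn[b + (t - 2) * d1 + u * (tz + 1) + w];
              x += X * Rn[b + (t - 1) * d1 + u * (tz + 1) + w];
            } else if (u > 0) {
              if (u > 1) x += (u - 1) * Rn[b + t * d1 + (u - 2) * (tz + 1) + w];
              x += Y * Rn[b + t * d1 + (u - 1) * (tz + 1) + w];
            } else {
              if (w > 1) x += (w - 1) * Rn[b + t * d1 + u * (tz + 1) + w - 2];
              x += Z * Rn[b + t * d1 + u * (tz + 1) + w - 1];
            }
            Rn[n * sz + t * d1 + u * (tz + 1) + w] = x;
          }
    }
    v.assign(Rn.begin(), Rn.begin() + sz);
  }
  double get(int t, int u, int w) const {
    return v[t * (ty + 1) * (tz + 1) + u * (tz + 1) + w];
  }
};

// ------------------------------------------------------- overlap and kinetic

// [[Rcpp::export]]
List cpp_overlap_kinetic(List basis) {
  std::vector<Shell> sh = parse_shells(basis);
  int nao = nao_of(sh);
  NumericMatrix S(nao, nao), T(nao, nao);
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
      const Shell &sa = sh[A], &sb = sh[B];
      double AB[3];
      for (int k = 0; k < 3; ++k) AB[k] = sa.R[k] - sb.R[k];
      int na = sa.ncart(), nb = sb.ncart();
      std::vector<double> Sblk(na * nb, 0.0), Tblk(na * nb, 0.0);
      for (size_t pa = 0; pa < sa.a.size(); ++pa)
        for (size_t pb = 0; pb < sb.a.size(); ++pb) {
          double a = sa.a[pa], b = sb.a[pb], p = a + b;
          double cc = sa.c[pa] * sb.c[pb];
          Etab Ex, Ey, Ez;
          Ex.build(sa.l, sb.l + 2, a, b, AB[0]);
          Ey.build(sa.l, sb.l + 2, a, b, AB[1]);
          Ez.build(sa.l, sb.l + 2, a, b, AB[2]);
          double fac = std::pow(PI / p, 1.5);
          for (int ca = 0; ca < na; ++ca)
            for (int cb = 0; cb < nb; ++cb) {
              int ix = sa.lx[ca], iy = sa.ly[ca], iz = sa.lz[ca];
              int jx = sb.lx[cb], jy = sb.ly[cb], jz = sb.lz[cb];
              double sx = Ex.get(ix, jx, 0), sy = Ey.get(iy, jy, 0),
                     sz = Ez.get(iz, jz, 0);
              // 1D kinetic via l+/-2 overlaps
              double tx = -2.0 * b * b * Ex.get(ix, jx + 2, 0)
                          + b * (2.0 * jx + 1.0) * sx
                          - 0.5 * jx * (jx - 1.0) * Ex.get(ix, jx - 2, 0);
              double ty = -2.0 * b * b * Ey.get(iy, jy + 2, 0)
                          + b * (2.0 * jy + 1.0) * sy
                          - 0.5 * jy * (jy - 1.0) * Ey.get(iy, jy - 2, 0);
              double tz = -2.0 * b * b * Ez.get(iz, jz + 2, 0)
                          + b * (2.0 * jz + 1.0) * sz
                          - 0.5 * jz * (jz - 1.0) * Ez.get(iz, jz - 2, 0);
              double w = cc * fac * sa.fcomp[ca] * sb.fcomp[cb];
              Sblk[ca * nb + cb] += w * sx * sy * sz;
              Tblk[ca * nb + cb] += w * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
            }
        }
      for (int ca = 0; ca < na; ++ca)
        for (int cb = 0; cb < nb; ++cb) {
          int i = sa.off + ca, j = sb.off + cb;
          S(i, j) = S(j, i) = Sblk[ca * nb + cb];
          T(i, j) = T(j, i) = Tblk[ca * nb + cb];
        }
    }
  return List::create(_["S"] = S, _["T"] = T);
}

// --------------------------------------------- generic point-charge potential

// accumulate  <mu| 1/|r - C| |nu>  for one shell pair into blk (na*nb),
// optionally also derivative blocks w.r.t. A, B (each 3*na*nb); the operator
// center derivative is -(dA+dB).
static void pair_point(const Shell& sa, const Shell& sb, const double* C,
                       std::vector<double>& blk,
                       std::vector<double>* dAblk, std::vector<double>* dBblk) {
  double AB[3];
  for (int k = 0; k < 3; ++k) AB[k] = sa.R[k] - sb.R[k];
  int na = sa.ncart(), nb = sb.ncart();
  bool deriv = (dAblk != 0);
  int raise = deriv ? 1 : 0;
  for (size_t pa = 0; pa < sa.a.size(); ++pa)
    for (size_t pb = 0; pb < sb.a.size(); ++pb) {
      double a = sa.a[pa], b = sb.a[pb], p = a + b;
      double cc = sa.c[pa] * sb.c[pb];
      double P[3];
      for (int k = 0; k < 3; ++k) P[k] = (a * sa.R[k] + b * sb.R[k]) / p;
      Etab E[3];
      for (int k = 0; k < 3; ++k)
        E[k].build(sa.l + raise, sb.l + raise, a, b, AB[k]);
      int tm = sa.l + sb.l + raise;
      Rtab R;
      R.build(tm, tm, tm, p, P[0] - C[0], P[1] - C[1], P[2] - C[2]);
      double fac = 2.0 * PI / p * cc;
      for (int ca = 0; ca < na; ++ca)
        for (int cb = 0; cb < nb; ++cb) {
          int ia[3] = { sa.lx[ca], sa.ly[ca], sa.lz[ca] };
          int jb[3] = { sb.lx[cb], sb.ly[cb], sb.lz[cb] };
          double w = fac * sa.fcomp[ca] * sb.fcomp[cb];
          double val = 0.0, dA[3] = {0, 0, 0}, dB[3] = {0, 0, 0};
          for (int t = 0; t <= ia[0] + jb[0] + raise; ++t)
            for (int u = 0; u <= ia[1] + jb[1] + raise; ++u)
              for (int v = 0; v <= ia[2] + jb[2] + raise; ++v) {
                double r = R.get(t, u, v);
                if (r == 0.0) continue;
                double e0 = E[0].get(ia[0], jb[0], t);
                double e1 = E[1].get(ia[1], jb[1], u);
                double e2 = E[2].get(ia[2], jb[2], v);
                val += e0 * e1 * e2 * r;
                if (deriv) {
                  dA[0] += E[0].dA(ia[0], jb[0], t, a) * e1 * e2 * r;
                  dA[1] += e0 * E[1].dA(ia[1], jb[1], u, a) * e2 * r;
                  dA[2] += e0 * e1 * E[2].dA(ia[2], jb[2], v, a) * r;
                  dB[0] += E[0].dB(ia[0], jb[0], t, b) * e1 * e2 * r;
                  dB[1] += e0 * E[1].dB(ia[1], jb[1], u, b) * e2 * r;
                  dB[2] += e0 * e1 * E[2].dB(ia[2], jb[2], v, b) * r;
                }
              }
          blk[ca * nb + cb] += w * val;
          if (deriv)
            for (int k = 0; k < 3; ++k) {
              (*dAblk)[(k * na + ca) * nb + cb] += w * dA[k];
              (*dBblk)[(k * na + ca) * nb + cb] += w * dB[k];
            }
        }
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_nuclear(List basis, NumericVector Z, NumericMatrix Rn) {
  std::vector<Shell> sh = parse_shells(basis);
  int nao = nao_of(sh);
  NumericMatrix V(nao, nao);
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
      const Shell &sa = sh[A], &sb = sh[B];
      int na = sa.ncart(), nb = sb.ncart();
      std::vector<double> blk(na * nb, 0.0);
      for (int n = 0; n < Rn.nrow(); ++n) {
        double C[3] = { Rn(n, 0), Rn(n, 1), Rn(n, 2) };
        std::vector<double> tmp(na * nb, 0.0);
        pair_point(sa, sb, C, tmp, 0, 0);
        for (int q = 0; q < na * nb; ++q) blk[q] += Z[n] * tmp[q];
      }
      for (int ca = 0; ca < na; ++ca)
        for (int cb = 0; cb < nb; ++cb) {
          int i = sa.off + ca, j = sb.off + cb;
          V(i, j) = V(j, i) = blk[ca * nb + cb];
        }
    }
  return V;
}

// full point-potential matrices, array nao x nao x npts
// [[Rcpp::export]]
NumericVector cpp_point_matrices(List basis, NumericMatrix pts) {
  std::vector<Shell> sh = parse_shells(basis);
  int nao = nao_of(sh), np = pts.nrow();
  NumericVector out(Dimension(nao, nao, np));
  for (int n = 0; n < np; ++n) {
    double C[3] = { pts(n, 0), pts(n, 1), pts(n, 2) };
    for (size_t A = 0; A < sh.size(); ++A)
      for (size_t B = 0; B <= A; ++B) {
        const Shell &sa = sh[A], &sb = sh[B];
        int na = sa.ncart(), nb = sb.ncart();
        std::vector<double> blk(na * nb, 0.0);
        pair_point(sa, sb, C, blk, 0, 0);
        for (int ca = 0; ca < na; ++ca)
          for (int cb = 0; cb < nb; ++cb) {
            int i = sa.off + ca, j = sb.off + cb;
            out[(size_t)n * nao * nao + j * nao + i] = blk[ca * nb + cb];
            out[(size_t)n * nao * nao + i * nao + j] = blk[ca * nb + cb];
          }
      }
  }
  return out;
}

// Tr(M V_k) for each point k
// [[Rcpp::export]]
NumericVector cpp_point_contract(List basis, NumericMatrix pts, NumericMatrix M) {
  std::vector<Shell> sh = parse_shells(basis);
  int np = pts.nrow();
  NumericVector out(np);
  for (int n = 0; n < np; ++n) {
    double C[3] = { pts(n, 0), pts(n, 1), pts(n, 2) };
    double acc = 0.0;
    for (size_t A = 0; A < sh.size(); ++A)
      for (size_t B = 0; B <= A; ++B) {
        const Shell &sa = sh[A], &sb = sh[B];
        int na = sa.ncart(), nb = sb.ncart();
        std::vector<double> blk(na * nb, 0.0);
        pair_point(sa, sb, C, blk, 0, 0);
        double w = (A == B) ? 1.0 : 2.0;
        for (int ca = 0; ca < na; ++ca)
          for (int cb = 0; cb < nb; ++cb)
            acc += w * M(sa.off + ca, sb.off + cb) * blk[ca * nb + cb];
      }
    out[n] = acc;
  }
  return out;
}

// d Tr(M V_k) / d(atom coordinates) and d/d(point position).
// Returns np x (3*natoms + 3); the last three columns are the derivative with
// respect to the grid point position itself (= -sum of center derivatives).
// [[Rcpp::export]]
NumericMatrix cpp_point_grad_contract(List basis, NumericMatrix pts,
                                      NumericMatrix M, int natoms) {
  std::vector<Shell> sh = parse_shells(basis);
  int np = pts.nrow();
  NumericMatrix out(np, 3 * natoms + 3);
  for (int n = 0; n < np; ++n) {
    double C[3] = { pts(n, 0), pts(n, 1), pts(n, 2) };
    for (size_t A = 0; A < sh.size(); ++A)
      for (size_t B = 0; B <= A; ++B) {
        const Shell &sa = sh[A], &sb = sh[B];
        int na = sa.ncart(), nb = sb.ncart();
        std::vector<double> blk(na * nb, 0.0),
            dA(3 * na * nb, 0.0), dB(3 * na * nb, 0.0);
        pair_point(sa, sb, C, blk, &dA, &dB);
        double w = (A == B) ? 1.0 : 2.0;
        for (int k = 0; k < 3; ++k) {
          double accA = 0.0, accB = 0.0;
          for (int ca = 0; ca < na; ++ca)
            for (int cb = 0; cb < nb; ++cb) {
              double m = M(sa.off + ca, sb.off + cb);
              accA += w * m * dA[(k * na + ca) * nb + cb];
              accB += w * m * dB[(k * na + ca) * nb + cb];
            }
          out(n, 3 * sa.atom + k) += accA;
          out(n, 3 * sb.atom + k) += accB;
          out(n, 3 * natoms + k) -= accA + accB;
        }
      }
  }
  return out;
}

// ESPF charge operators Q_A = sum_k Tplus[A,k] V_k  (array nao x nao x nqm)
// [[Rcpp::export]]
NumericVector cpp_espf_q(List basis, NumericMatrix pts, NumericMatrix Tplus) {
  std::vector<Shell> sh = parse_shells(basis);
  int nao = nao_of(sh), np = pts.nrow(), nqm = Tplus.nrow();
  NumericVector out(Dimension(nao, nao, nqm));
  for (int n = 0; n < np; ++n) {
    double C[3] = { pts(n, 0), pts(n, 1), pts(n, 2) };
    for (size_t A = 0; A < sh.size(); ++A)
      for (size_t B = 0; B <= A; ++B) {
        const Shell &sa = sh[A], &sb = sh[B];
        int na = sa.ncart(), nb = sb.ncart();
        std::vector<double> blk(na * nb, 0.0);
        pair_point(sa, sb, C, blk, 0, 0);
        for (int q = 0; q < nqm; ++q) {
          double tp = Tplus(q, n);
          if (tp == 0.0) continue;
          for (int ca = 0; ca < na; ++ca)
            for (int cb = 0; cb < nb; ++cb) {
              int i = sa.off + ca, j = sb.off + cb;
              double v = tp * blk[ca * nb + cb];
              out[(size_t)q * nao * nao + j * nao + i] += v;
              // same-shell blocks already enumerate both orientations
              if (A != B) out[(size_t)q * nao * nao + i * nao + j] += v;
            }
        }
      }
  }
  return out;
}

// --------------------------------------------------- one-electron grad blocks

// sum_{mu nu} M_{mu nu} dS_{mu nu}/dR  -> natoms x 3
// [[Rcpp::export]]
NumericMatrix cpp_grad_overlap(List basis, NumericMatrix M, int natoms) {
  std::vector<Shell> sh = parse_shells(basis);
  NumericMatrix out(natoms, 3);
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
      const Shell &sa = sh[A], &sb = sh[B];
      if (sa.atom == sb.atom) continue; // same-center overlap has zero gradient
      double AB[3];
      for (int k = 0; k < 3; ++k) AB[k] = sa.R[k] - sb.R[k];
      int na = sa.ncart(), nb = sb.ncart();
      double w = (A == B) ? 1.0 : 2.0;
      for (size_t pa = 0; pa < sa.a.size(); ++pa)
        for (size_t pb = 0; pb < sb.a.size(); ++pb) {
          double a = sa.a[pa], b = sb.a[pb], p = a + b;
          double cc = sa.c[pa] * sb.c[pb] * std::pow(PI / p, 1.5);
          Etab E[3];
          for (int k = 0; k < 3; ++k) E[k].build(sa.l + 1, sb.l, a, b, AB[k]);
          for (int ca = 0; ca < na; ++ca)
            for (int cb = 0; cb < nb; ++cb) {
              int ia[3] = { sa.lx[ca], sa.ly[ca], sa.lz[ca] };
              int jb[3] = { sb.lx[cb], sb.ly[cb], sb.lz[cb] };
              double m = w * cc * sa.fcomp[ca] * sb.fcomp[cb] *
                         M(sa.off + ca, sb.off + cb);
              double s[3], d[3];
              for (int k = 0; k < 3; ++k) {
                s[k] = E[k].get(ia[k], jb[k], 0);
                d[k] = E[k].dA(ia[k], jb[k], 0, a);
              }
              double g[3] = { d[0] * s[1] * s[2], s[0] * d[1] * s[2],
                              s[0] * s[1] * d[2] };
              for (int k = 0; k < 3; ++k) {
                out(sa.atom, k) += m * g[k];
                out(sb.atom, k) -= m * g[k]; // dB = -dA for overlap
              }
            }
        }
    }
  return out;
}

// sum M dT/dR
// [[Rcpp::export]]
NumericMatrix cpp_grad_kinetic(List basis, NumericMatrix M, int natoms) {
  std::vector<Shell> sh = parse_shells(basis);
  NumericMatrix out(natoms, 3);
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
      const Shell &sa = sh[A], &sb = sh[B];
      if (sa.atom == sb.atom) continue;
      double AB[3];
      for (int k = 0; k < 3; ++k) AB[k] = sa.R[k] - sb.R[k];
      int na = sa.ncart(), nb = sb.ncart();
      double w = (A == B) ? 1.0 : 2.0;
      for (size_t pa = 0; pa < sa.a.size(); ++pa)
        for (size_t pb = 0; pb < sb.a.size(); ++pb) {
          double a = sa.a[pa], b = sb.a[pb], p = a + b;
          double cc = sa.c[pa] * sb.c[pb] * std::pow(PI / p, 1.5);
          Etab E[3];
          for (int k = 0; k < 3; ++k)
            E[k].build(sa.l + 1, sb.l + 2, a, b, AB[k]);
          for (int ca = 0; ca < na; ++ca)
            for (int cb = 0; cb < nb; ++cb) {
              int ia[3] = { sa.lx[ca], sa.ly[ca], sa.lz[ca] };
              int jb[3] = { sb.lx[cb], sb.ly[cb], sb.lz[cb] };
              double m = w * cc * sa.fcomp[ca] * sb.fcomp[cb] *
                         M(sa.off + ca, sb.off + cb);
              double s[3], ds[3], t[3], dt[3];
              for (int k = 0; k < 3; ++k) {
                int i = ia[k], j = jb[k];
                s[k] = E[k].get(i, j, 0);
                ds[k] = E[k].dA(i, j, 0, a);
                t[k] = -2.0 * b * b * E[k].get(i, j + 2, 0)
                       + b * (2.0 * j + 1.0) * E[k].get(i, j, 0)
                       - 0.5 * j * (j - 1.0) * E[k].get(i, j - 2, 0);
                dt[k] = -2.0 * b * b * E[k].dA(i, j + 2, 0, a)
                        + b * (2.0 * j + 1.0) * E[k].dA(i, j, 0, a)
                        - 0.5 * j * (j - 1.0) * E[k].dA(i, j - 2, 0, a);
              }
              double g[3] = {
                dt[0] * s[1] * s[2] + ds[0] * (t[1] * s[2] + s[1] * t[2]),
                dt[1] * s[0] * s[2] + ds[1] * (t[0] * s[2] + s[0] * t[2]),
                dt[2] * s[0] * s[1] + ds[2] * (t[0] * s[1] + s[0] * t[1]) };
              for (int k = 0; k < 3; ++k) {
                out(sa.atom, k) += m * g[k];
                out(sb.atom, k) -= m * g[k];
              }
            }
        }
    }
  return out;
}

// sum M d(sum_n Z_n <mu|1/|r-R_n||nu>)/dR, nuclei at Rn rows = atoms 1..natoms
// [[Rcpp::export]]
NumericMatrix cpp_grad_nuclear(List basis, NumericMatrix M, NumericVector Z,
                               NumericMatrix Rn, int natoms) {
  std::vector<Shell> sh = parse_shells(basis);
  NumericMatrix out(natoms, 3);
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
      const Shell &sa = sh[A], &sb = sh[B];
      int na = sa.ncart(), nb = sb.ncart();
      double w = (A == B) ? 1.0 : 2.0;
      for (int n = 0; n < Rn.nrow(); ++n) {
        double C[3] = { Rn(n, 0), Rn(n, 1), Rn(n, 2) };
        std::vector<double> blk(na * nb, 0.0),
            dA(3 * na * nb, 0.0), dB(3 * na * nb, 0.0);
        pair_point(sa, sb, C, blk, &dA, &dB);
        for (int k = 0; k < 3; ++k) {
          double accA = 0.0, accB = 0.0;
          for (int ca = 0; ca < na; ++ca)
            for (int cb = 0; cb < nb; ++cb) {
              double m = M(sa.off + ca, sb.off + cb);
              accA += w * m * dA[(k * na + ca) * nb + cb];
              accB += w * m * dB[(k * na + ca) * nb + cb];
            }
          out(sa.atom, k) += Z[n] * accA;
          out(sb.atom, k) += Z[n] * accB;
          out(n, k) -= Z[n] * (accA + accB); // operator-center term
        }
      }
    }
  return out;
}

// -------------------------------------------------------------------- ERIs

struct PairPrim {
  double a, b, p, K;     // K = |cc| exp(-mu |AB|^2), screening magnitude
  double P[3];
  Etab E[3];
  double cc;
};

struct PairData {
  int sa, sb;
  std::vector<PairPrim> pp;
};

static void build_pairs(const std::vector<Shell>& sh, int raise,
                        std::vector<PairData>& pairs) {
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
      PairData pd;
      pd.sa = A; pd.sb = B;
      const Shell &sa = sh[A], &sb = sh[B];
      double AB[3];
      for (int k = 0; k < 3; ++k) AB[k] = sa.R[k] - sb.R[k];
      for (size_t pa = 0; pa < sa.a.size(); ++pa)
        for (size_t pb = 0; pb < sb.a.size(); ++pb) {
          PairPrim q;
          q.a = sa.a[pa]; q.b = sb.a[pb]; q.p = q.a + q.b;
          q.cc = sa.c[pa] * sb.c[pb];
          double ab2 = 0.0;
          for (int k = 0; k < 3; ++k) {
            q.P[k] = (q.a * sa.R[k] + q.b * sb.R[k]) / q.p;
            q.E[k].build(sa.l + raise, sb.l + raise, q.a, q.b, AB[k]);
            ab2 += AB[k] * AB[k];
          }
          q.K = std::fabs(q.cc) * std::exp(-q.a * q.b / q.p * ab2);
          pd.pp.push_back(q);
        }
      pairs.push_back(pd);
    }
}

// full ERI array (chemists' notation (mu nu|la si)), nao^4
// [[Rcpp::export]]
NumericVector cpp_eri(List basis) {
  std::vector<Shell> sh = parse_shells(basis);
  int nao = nao_of(sh);
  std::vector<PairData> pairs;
  build_pairs(sh, 0, pairs);
  NumericVector out((size_t)nao * nao * nao * nao);
  out.attr("dim") = IntegerVector::create(nao, nao, nao, nao);
  double* O = REAL(out);
  size_t n1 = nao, n2 = (size_t)nao * nao, n3 = n2 * nao;
  for (size_t pb_ = 0; pb_ < pairs.size(); ++pb_)
    for (size_t pk_ = 0; pk_ <= pb_; ++pk_) {
      const PairData &bra = pairs[pb_], &ket = pairs[pk_];
      const Shell &sa = sh[bra.sa], &sb = sh[bra.sb];
      const Shell &sc = sh[ket.sa], &sd = sh[ket.sb];
      int na = sa.ncart(), nb = sb.ncart(), nc = sc.ncart(), nd = sd.ncart();
      std::vector<double> blk(na * nb * nc * nd, 0.0);
      int tmax = sa.l + sb.l, smax = sc.l + sd.l;
      Rtab R;
      for (size_t q1 = 0; q1 < bra.pp.size(); ++q1)
        for (size_t q2 = 0; q2 < ket.pp.size(); ++q2) {
          const PairPrim &B = bra.pp[q1], &Kq = ket.pp[q2];
          double alpha = B.p * Kq.p / (B.p + Kq.p);
          double pref = 2.0 * std::pow(PI, 2.5) /
                        (B.p * Kq.p * std::sqrt(B.p + Kq.p));
          if (pref * B.K * Kq.K < 1e-16) continue;
          R.build(tmax + smax, tmax + smax, tmax + smax, alpha,
                  B.P[0] - Kq.P[0], B.P[1] - Kq.P[1], B.P[2] - Kq.P[2]);
          double fac = pref * B.cc * Kq.cc;
          for (int cc_ = 0; cc_ < nc; ++cc_)
            for (int cd = 0; cd < nd; ++cd) {
              int kc[3] = { sc.lx[cc_], sc.ly[cc_], sc.lz[cc_] };
              int kd[3] = { sd.lx[cd], sd.ly[cd], sd.lz[cd] };
              // ket Hermite coefficients with (-1)^(tau+nu+phi)
              for (int ca = 0; ca < na; ++ca)
                for (int cb = 0; cb < nb; ++cb) {
                  int ia[3] = { sa.lx[ca], sa.ly[ca], sa.lz[ca] };
                  int jb[3] = { sb.lx[cb], sb.ly[cb], sb.lz[cb] };
                  double val = 0.0;
                  for (int t = 0; t <= ia[0] + jb[0]; ++t) {
                    double e0 = B.E[0].get(ia[0], jb[0], t);
                    if (e0 == 0.0) continue;
                    for (int u = 0; u <= ia[1] + jb[1]; ++u) {
                      double e1 = B.E[1].get(ia[1], jb[1], u);
                      if (e1 == 0.0) continue;
                      for (int v = 0; v <= ia[2] + jb[2]; ++v) {
                        double e2 = B.E[2].get(ia[2], jb[2], v);
                        if (e2 == 0.0) continue;
                        double inner = 0.0;
                        for (int tt = 0; tt <= kc[0] + kd[0]; ++tt) {
                          double f0 = Kq.E[0].get(kc[0], kd[0], tt);
                          if (f0 == 0.0) continue;
                          for (int uu = 0; uu <= kc[1] + kd[1]; ++uu) {
                            double f1 = Kq.E[1].get(kc[1], kd[1], uu);
                            if (f1 == 0.0) continue;
                            for (int vv = 0; vv <= kc[2] + kd[2]; ++vv) {
                              double f2 = Kq.E[2].get(kc[2], kd[2], vv);
                              if (f2 == 0.0) continue;
                              double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                              inner += sgn * f0 * f1 * f2 *
                                       R.get(t + tt, u + uu, v + vv);
                            }
                          }
                        }
                        val += e0 * e1 * e2 * inner;
                      }
                    }
                  }
                  blk[((ca * nb + cb) * nc + cc_) * nd + cd] +=
                      fac * val * sa.fcomp[ca] * sb.fcomp[cb] *
                      sc.fcomp[cc_] * sd.fcomp[cd];
                }
            }
        }
      // scatter with 8-fold permutational symmetry
      for (int ca = 0; ca < na; ++ca)
        for (int cb = 0; cb < nb; ++cb)
          for (int cc_ = 0; cc_ < nc; ++cc_)
            for (int cd = 0; cd < nd; ++cd) {
              double v = blk[((ca * nb + cb) * nc + cc_) * nd + cd];
              size_t i = sa.off + ca, j = sb.off + cb,
                     k = sc.off + cc_, l = sd.off + cd;
              O[i + j * n1 + k * n2 + l * n3] = v;
              O[j + i * n1 + k * n2 + l * n3] = v;
              O[i + j * n1 + l * n2 + k * n3] = v;
              O[j + i * n1 + l * n2 + k * n3] = v;
              O[k + l * n1 + i * n2 + j * n3] = v;
              O[l + k * n1 + i * n2 + j * n3] = v;
              O[k + l * n1 + j * n2 + i * n3] = v;
              O[l + k * n1 + j * n2 + i * n3] = v;
            }
    }
  return out;
}

// gradient contraction sum_{mnls} G4[m,n,l,s] d(mn|ls)/dR with G4 symmetric
// under all 8 index permutations.  Returns natoms x 3.
// Ket Hermite sums are precomputed per ket component pair and reused across
// all bra components; quartets with negligible density factors are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_grad_eri(List basis, NumericVector G4, int natoms) {
  std::vector<Shell> sh = parse_shells(basis);
  int nao = nao_of(sh);
  const double* G = REAL(G4);
  size_t n1 = nao, n2 = (size_t)nao * nao, n3 = n2 * nao;
  std::vector<PairData> pairs;
  build_pairs(sh, 1, pairs); // E tables with one raise on both indices
  NumericMatrix out(natoms, 3);
  std::vector<double> M;  // ket sums: [cd-pair][4][t][u][v]
  for (size_t pb_ = 0; pb_ < pairs.size(); ++pb_)
    for (size_t pk_ = 0; pk_ <= pb_; ++pk_) {
      const PairData &bra = pairs[pb_], &ket = pairs[pk_];
      const Shell &sa = sh[bra.sa], &sb = sh[bra.sb];
      const Shell &sc = sh[ket.sa], &sd = sh[ket.sb];
      // all four centers on one atom: total derivative zero
      if (sa.atom == sb.atom && sb.atom == sc.atom && sc.atom == sd.atom)
        continue;
      int na = sa.ncart(), nb = sb.ncart(), nc = sc.ncart(), nd = sd.ncart();
      double deg = 1.0;
      if (bra.sa != bra.sb) deg *= 2.0;
      if (ket.sa != ket.sb) deg *= 2.0;
      if (pb_ != pk_) deg *= 2.0;
      // density screening over the quartet's components
      double gmax = 0.0;
      for (int ca = 0; ca < na; ++ca)
        for (int cb = 0; cb < nb; ++cb)
          for (int cc_ = 0; cc_ < nc; ++cc_)
            for (int cd = 0; cd < nd; ++cd) {
              double g = std::fabs(G[(sa.off + ca) + (sb.off + cb) * n1 +
                                     (sc.off + cc_) * n2 + (sd.off + cd) * n3]);
              if (g > gmax) gmax = g;
            }
      if (deg * gmax < 1e-13) continue;
      int tb = sa.l + sb.l + 1;           // bra Hermite order (with raise)
      int tk = sc.l + sd.l + 1;           // ket Hermite order (dC raise)
      int td = tb + 1, td3 = td * td * td;
      M.assign((size_t)nc * nd * 4 * td3, 0.0);
      double gA[3], gB[3], gC[3];
      Rtab R;
      for (size_t q1 = 0; q1 < bra.pp.size(); ++q1)
        for (size_t q2 = 0; q2 < ket.pp.size(); ++q2) {
          const PairPrim &B = bra.pp[q1], &Kq = ket.pp[q2];
          double alpha = B.p * Kq.p / (B.p + Kq.p);
          double pref = deg * 2.0 * std::pow(PI, 2.5) /
                        (B.p * Kq.p * std::sqrt(B.p + Kq.p));
          // primitive screening: the Hermite prefactors carry K_bra K_ket
          if (pref * B.K * Kq.K * gmax < 1e-14) continue;
          R.build(tb + tk, tb + tk, tb + tk, alpha,
                  B.P[0] - Kq.P[0], B.P[1] - Kq.P[1], B.P[2] - Kq.P[2]);
          double fac = pref * B.cc * Kq.cc;
          // ket Hermite sums for every ket component pair:
          // M[cdp][0][tuv] = sum_ket (-1)^s f0 f1 f2 R[t+tt,...]
          // M[cdp][1..3][tuv] = same with dC along x,y,z
          std::fill(M.begin(), M.end(), 0.0);
          for (int cc_ = 0; cc_ < nc; ++cc_)
            for (int cd = 0; cd < nd; ++cd) {
              int kc[3] = { sc.lx[cc_], sc.ly[cc_], sc.lz[cc_] };
              int kd[3] = { sd.lx[cd], sd.ly[cd], sd.lz[cd] };
              double* Mp = &M[((size_t)(cc_ * nd + cd)) * 4 * td3];
              for (int tt = 0; tt <= kc[0] + kd[0] + 1; ++tt) {
                double f0 = Kq.E[0].get(kc[0], kd[0], tt);
                double d0 = Kq.E[0].dA(kc[0], kd[0], tt, Kq.a);
                for (int uu = 0; uu <= kc[1] + kd[1] + 1; ++uu) {
                  double f1 = Kq.E[1].get(kc[1], kd[1], uu);
                  double d1 = Kq.E[1].dA(kc[1], kd[1], uu, Kq.a);
                  for (int vv = 0; vv <= kc[2] + kd[2] + 1; ++vv) {
                    double f2 = Kq.E[2].get(kc[2], kd[2], vv);
                    double d2 = Kq.E[2].dA(kc[2], kd[2], vv, Kq.a);
                    double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                    double w0 = sgn * f0 * f1 * f2;
                    double wx = sgn * d0 * f1 * f2;
                    double wy = sgn * f0 * d1 * f2;
                    double wz = sgn * f0 * f1 * d2;
                    if (w0 == 0 && wx == 0 && wy == 0 && wz == 0) continue;
                    for (int t = 0; t < td; ++t)
                      for (int u = 0; t + u < td; ++u) {
                        const int base = (t * td + u) * td;
                        for (int v = 0; t + u + v < td; ++v) {
                          double r = R.get(t + tt, u + uu, v + vv);
                          if (r == 0.0) continue;
                          Mp[base + v] += w0 * r;
                          Mp[td3 + base + v] += wx * r;
                          Mp[2 * td3 + base + v] += wy * r;
                          Mp[3 * td3 + base + v] += wz * r;
                        }
                      }
                  }
                }
              }
            }
          // bra contraction
          for (int ca = 0; ca < na; ++ca)
            for (int cb = 0; cb < nb; ++cb) {
              int ia[3] = { sa.lx[ca], sa.ly[ca], sa.lz[ca] };
              int jb[3] = { sb.lx[cb], sb.ly[cb], sb.lz[cb] };
              size_t ij = (sa.off + ca) + (sb.off + cb) * n1;
              double fab = fac * sa.fcomp[ca] * sb.fcomp[cb];
              for (int cc_ = 0; cc_ < nc; ++cc_)
                for (int cd = 0; cd < nd; ++cd) {
                  double g = G[ij + (sc.off + cc_) * n2 + (sd.off + cd) * n3];
                  if (std::fabs(g) < 1e-14) continue;
                  double w = fab * g * sc.fcomp[cc_] * sd.fcomp[cd];
                  const double* Mp = &M[((size_t)(cc_ * nd + cd)) * 4 * td3];
                  for (int k3 = 0; k3 < 3; ++k3)
                    gA[k3] = gB[k3] = gC[k3] = 0.0;
                  for (int t = 0; t <= ia[0] + jb[0] + 1; ++t) {
                    double e0 = B.E[0].get(ia[0], jb[0], t);
                    double dA0 = B.E[0].dA(ia[0], jb[0], t, B.a);
                    double dB0 = B.E[0].dB(ia[0], jb[0], t, B.b);
                    for (int u = 0; u <= ia[1] + jb[1] + 1 && t + u < td; ++u) {
                      double e1 = B.E[1].get(ia[1], jb[1], u);
                      double dA1 = B.E[1].dA(ia[1], jb[1], u, B.a);
                      double dB1 = B.E[1].dB(ia[1], jb[1], u, B.b);
                      const int base = (t * td + u) * td;
                      for (int v = 0; v <= ia[2] + jb[2] + 1 && t + u + v < td; ++v) {
                        double e2 = B.E[2].get(ia[2], jb[2], v);
                        double dA2 = B.E[2].dA(ia[2], jb[2], v, B.a);
                        double dB2 = B.E[2].dB(ia[2], jb[2], v, B.b);
                        double m0 = Mp[base + v];
                        if (m0 != 0.0) {
                          gA[0] += dA0 * e1 * e2 * m0;
                          gA[1] += e0 * dA1 * e2 * m0;
                          gA[2] += e0 * e1 * dA2 * m0;
                          gB[0] += dB0 * e1 * e2 * m0;
                          gB[1] += e0 * dB1 * e2 * m0;
                          gB[2] += e0 * e1 * dB2 * m0;
                        }
                        double ee = e0 * e1 * e2;
                        if (ee != 0.0) {
                          gC[0] += ee * Mp[td3 + base + v];
                          gC[1] += ee * Mp[2 * td3 + base + v];
                          gC[2] += ee * Mp[3 * td3 + base + v];
                        }
                      }
                    }
                  }
                  for (int k3 = 0; k3 < 3; ++k3) {
                    out(sa.atom, k3) += w * gA[k3];
                    out(sb.atom, k3) += w * gB[k3];
                    out(sc.atom, k3) += w * gC[k3];
                    // dD = -(dA+dB+dC) by translational invariance
                    out(sd.atom, k3) -= w * (gA[k3] + gB[k3] + gC[k3]);
                  }
                }
            }
        }
    }
  return out;
}
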