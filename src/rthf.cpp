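// Core numerical kernels: Gaussian integrals (McMurchie-Davidson), screened
// two-electron storage, Fock assembly from the stored quartet list, and the
// exponential-midpoint predictor-corrector propagator for the complex
// one-electron density matrix in the orthonormalized representation.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Boys function F_m(x), m = 0..mmax, by downward recursion from a series
// (x < 35) or the asymptotic form (x >= 35; relative error < 1e-14 there).
// ---------------------------------------------------------------------------
static void boys(int mmax, double x, double* F) {
  const double ex = std::exp(-x);
  if (x < 35.0) {
    // F_mmax by the convergent series e^{-x} sum_k (2x)^k / (2m+2k+1)!! * (2m-1)!!
    double term = 1.0 / (2.0 * mmax + 1.0);
    double sum = term;
    for (int k = 1; k < 200; ++k) {
      term *= 2.0 * x / (2.0 * mmax + 2.0 * k + 1.0);
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    F[mmax] = sum * ex;
  } else {
    // asymptotic: F_m(x) ~ (2m-1)!! / 2^{m+1} * sqrt(pi / x^{2m+1})
    double df = 1.0;                      // (2m-1)!!
    for (int k = 1; k <= 2 * mmax - 1; k += 2) df *= k;
    F[mmax] = df / std::pow(2.0, mmax + 1) * std::sqrt(M_PI / std::pow(x, 2 * mmax + 1));
  }
  for (int m = mmax - 1; m >= 0; --m)
    F[m] = (2.0 * x * F[m + 1] + ex) / (2.0 * m + 1.0);
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} for a 1-D Gaussian product.
// out must hold i+j+1 entries; includes the exp(-mu*AB^2) prefactor.
// ---------------------------------------------------------------------------
static void ecoef(int imax, int jmax, double a, double b, double AB, double out[][8]) {
  // out[j][t] finally holds E_t^{imax, j}; internal table E[i][j][t]
  const int TMAX = 8;
  double E[6][6][TMAX];
  const double p = a + b, mu = a * b / p;
  const double XPA = -b / p * AB, XPB = a / p * AB;
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j <= jmax; ++j)
      for (int t = 0; t < TMAX; ++t) E[i][j][t] = 0.0;
  E[0][0][0] = std::exp(-mu * AB * AB);
  for (int i = 1; i <= imax; ++i)
    for (int t = 0; t <= i; ++t) {
      double v = XPA * E[i - 1][0][t];
      if (t > 0) v += E[i - 1][0][t - 1] / (2.0 * p);
      if (t + 1 <= i - 1) v += (t + 1) * E[i - 1][0][t + 1];
      E[i][0][t] = v;
    }
  for (int j = 1; j <= jmax; ++j)
    for (int i = 0; i <= imax; ++i)
      for (int t = 0; t <= i + j; ++t) {
        double v = XPB * E[i][j - 1][t];
        if (t > 0) v += E[i][j - 1][t - 1] / (2.0 * p);
        if (t + 1 <= i + j - 1) v += (t + 1) * E[i][j - 1][t + 1];
        E[i][j][t] = v;
      }
  for (int j = 0; j <= jmax; ++j)
    for (int t = 0; t < TMAX; ++t) out[j][t] = E[imax][j][t];
}

// single E_t row for fixed (i,j)
static void ecoef_row(int i, int j, double a, double b, double AB, double* out) {
  double tmp[6][8];
  ecoef(i, j, a, b, AB, tmp);
  for (int t = 0; t <= i + j; ++t) out[t] = tmp[j][t];
}

// ---------------------------------------------------------------------------
// Hermite Coulomb integrals R^0_{tuv}(p, PC) for t+u+v <= L.
// ---------------------------------------------------------------------------
static void rtensor(int L, double p, const double* PC, double R0[8][8][8]) {
  const double x = p * (PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2]);
  double F[16];
  boys(L, x, F);
  // R[n][t][u][v], n + t + u + v <= L
  static thread_local double R[9][8][8][8];
  for (int n = 0; n <= L; ++n) R[n][0][0][0] = std::pow(-2.0 * p, n) * F[n];
  for (int total = 1; total <= L; ++total) {
    for (int t = 0; t <= total; ++t)
      for (int u = 0; u + t <= total; ++u) {
        int v = total - t - u;
        for (int n = 0; n <= L - total; ++n) {
          double val;
          if (t > 0) {
            val = PC[0] * R[n + 1][t - 1][u][v];
            if (t > 1) val += (t - 1) * R[n + 1][t - 2][u][v];
          } else if (u > 0) {
            val = PC[1] * R[n + 1][t][u - 1][v];
            if (u > 1) val += (u - 1) * R[n + 1][t][u - 2][v];
          } else {
            val = PC[2] * R[n + 1][t][u][v - 1];
            if (v > 1) val += (v - 1) * R[n + 1][t][u][v - 2];
          }
          R[n][t][u][v] = val;
        }
      }
  }
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u + t <= L; ++u)
      for (int v = 0; v + t + u <= L; ++v) R0[t][u][v] = R[0][t][u][v];
}

// ---------------------------------------------------------------------------
// Basis container (3 primitives per contracted function, STO-3G).
// ---------------------------------------------------------------------------
struct Basis {
  int n;
  arma::imat lmn;     // n x 3
  arma::mat cen;      // n x 3 (bohr)
  arma::mat ex, co;   // n x 3
};

static Basis unpack_basis(const List& b) {
  Basis B;
  B.lmn = as<arma::imat>(b["lmn"]);
  B.cen = as<arma::mat>(b["centers"]);
  B.ex = as<arma::mat>(b["exps"]);
  B.co = as<arma::mat>(b["coefs"]);
  B.n = B.cen.n_rows;
  return B;
}

// primitive 1-D overlap <x^i exp(-a(x-A)^2) | x^j exp(-b(x-B)^2)>
static double s1d(int i, int j, double a, double b, double A, double B) {
  double E[8];
  ecoef_row(i, j, a, b, A - B, E);
  return E[0] * std::sqrt(M_PI / (a + b));
}

// primitive 3-D overlap
static double sprim(const int* l1, const double* A, double a,
                    const int* l2, const double* B, double b) {
  return s1d(l1[0], l2[0], a, b, A[0], B[0]) *
         s1d(l1[1], l2[1], a, b, A[1], B[1]) *
         s1d(l1[2], l2[2], a, b, A[2], B[2]);
}

// primitive kinetic energy via the overlap ladder in the ket
static double tprim(const int* l1, const double* A, double a,
                    const int* l2, const double* B, double b) {
  int lb = l2[0], mb = l2[1], nb = l2[2];
  double t = b * (2.0 * (lb + mb + nb) + 3.0) * sprim(l1, A, a, l2, B, b);
  int up[3], dn[3];
  for (int d = 0; d < 3; ++d) {
    for (int k = 0; k < 3; ++k) { up[k] = l2[k]; dn[k] = l2[k]; }
    up[d] += 2;
    t -= 2.0 * b * b * sprim(l1, A, a, up, B, b);
    if (l2[d] >= 2) {
      dn[d] -= 2;
      t -= 0.5 * l2[d] * (l2[d] - 1.0) * sprim(l1, A, a, dn, B, b);
    }
  }
  return t;
}

// [[Rcpp::export]]
arma::vec self_overlaps_cpp(List basis) {
  Basis B = unpack_basis(basis);
  arma::vec s(B.n);
  for (int i = 0; i < B.n; ++i) {
    int l[3] = {(int)B.lmn(i,0), (int)B.lmn(i,1), (int)B.lmn(i,2)};
    double A[3] = {B.cen(i,0), B.cen(i,1), B.cen(i,2)};
    double acc = 0.0;
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q)
        acc += B.co(i,p) * B.co(i,q) * sprim(l, A, B.ex(i,p), l, A, B.ex(i,q));
    s(i) = acc;
  }
  return s;
}

// [[Rcpp::export]]
List one_electron_cpp(List basis, arma::vec Z, arma::mat nucpos, arma::vec origin) {
  Basis B = unpack_basis(basis);
  const int n = B.n, nat = Z.n_elem;
  arma::mat S(n, n, arma::fill::zeros), T(n, n, arma::fill::zeros),
            V(n, n, arma::fill::zeros);
  arma::mat Dx(n, n, arma::fill::zeros), Dy(n, n, arma::fill::zeros),
            Dz(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    int l1[3] = {(int)B.lmn(i,0), (int)B.lmn(i,1), (int)B.lmn(i,2)};
    double A[3] = {B.cen(i,0), B.cen(i,1), B.cen(i,2)};
    for (int j = 0; j <= i; ++j) {
      int l2[3] = {(int)B.lmn(j,0), (int)B.lmn(j,1), (int)B.lmn(j,2)};
      double Bc[3] = {B.cen(j,0), B.cen(j,1), B.cen(j,2)};
      double s = 0, t = 0, v = 0, dx = 0, dy = 0, dz = 0;
      for (int p = 0; p < 3; ++p) {
        double a = B.ex(i,p);
        for (int q = 0; q < 3; ++q) {
          double b = B.ex(j,q), c = B.co(i,p) * B.co(j,q);
          double sp = sprim(l1, A, a, l2, Bc, b);
          s += c * sp;
          t += c * tprim(l1, A, a, l2, Bc, b);
          // dipole: (x - Ox) = (x - Ax) + (Ax - Ox); raise the bra exponent
          int lr[3];
          for (int d = 0; d < 3; ++d) {
            for (int k = 0; k < 3; ++k) lr[k] = l1[k];
            lr[d] += 1;
            double dip = sprim(lr, A, a, l2, Bc, b) + (A[d] - origin(d)) * sp;
            if (d == 0) dx += c * dip;
            else if (d == 1) dy += c * dip;
            else dz += c * dip;
          }
          // nuclear attraction (McMurchie-Davidson)
          double pp = a + b;
          double P[3] = {(a * A[0] + b * Bc[0]) / pp,
                         (a * A[1] + b * Bc[1]) / pp,
                         (a * A[2] + b * Bc[2]) / pp};
          int tx = l1[0] + l2[0], ty = l1[1] + l2[1], tz = l1[2] + l2[2];
          double Exr[8], Eyr[8], Ezr[8];
          ecoef_row(l1[0], l2[0], a, b, A[0] - Bc[0], Exr);
          ecoef_row(l1[1], l2[1], a, b, A[1] - Bc[1], Eyr);
          ecoef_row(l1[2], l2[2], a, b, A[2] - Bc[2], Ezr);
          int L = tx + ty + tz;
          double R0[8][8][8];
          for (int at = 0; at < nat; ++at) {
            double PC[3] = {P[0] - nucpos(at,0), P[1] - nucpos(at,1), P[2] - nucpos(at,2)};
            rtensor(L, pp, PC, R0);
            double acc = 0.0;
            for (int tt = 0; tt <= tx; ++tt)
              for (int uu = 0; uu <= ty; ++uu)
                for (int vv = 0; vv <= tz; ++vv)
                  acc += Exr[tt] * Eyr[uu] * Ezr[vv] * R0[tt][uu][vv];
            v += -Z(at) * c * 2.0 * M_PI / pp * acc;
          }
        }
      }
      S(i,j) = S(j,i) = s;  T(i,j) = T(j,i) = t;  V(i,j) = V(j,i) = v;
      Dx(i,j) = Dx(j,i) = dx; Dy(i,j) = Dy(j,i) = dy; Dz(i,j) = Dz(j,i) = dz;
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V,
                      _["Dx"] = Dx, _["Dy"] = Dy, _["Dz"] = Dz);
}

// ---------------------------------------------------------------------------
// Two-electron integrals. Pair data (Hermite expansions per primitive pair)
// are precomputed once; quartets are Schwarz-screened.
// ---------------------------------------------------------------------------
struct PrimPair {
  double p, c;
  double P[3];
  double Ex[8], Ey[8], Ez[8];
};
struct ShPair {
  int i, j;
  int nx, ny, nz; // Hermite orders per dimension
  double q;       // Schwarz factor sqrt((ij|ij))
  std::vector<PrimPair> pp;
};

static void build_pair(const Basis& B, int i, int j, ShPair& sp) {
  sp.i = i; sp.j = j;
  sp.nx = B.lmn(i,0) + B.lmn(j,0);
  sp.ny = B.lmn(i,1) + B.lmn(j,1);
  sp.nz = B.lmn(i,2) + B.lmn(j,2);
  double A[3] = {B.cen(i,0), B.cen(i,1), B.cen(i,2)};
  double Bc[3] = {B.cen(j,0), B.cen(j,1), B.cen(j,2)};
  sp.pp.clear();
  for (int p = 0; p < 3; ++p)
    for (int q = 0; q < 3; ++q) {
      PrimPair P;
      double a = B.ex(i,p), b = B.ex(j,q);
      P.p = a + b;
      P.c = B.co(i,p) * B.co(j,q);
      for (int d = 0; d < 3; ++d) P.P[d] = (a * B.cen(i,d) + b * B.cen(j,d)) / P.p;
      ecoef_row(B.lmn(i,0), B.lmn(j,0), a, b, A[0] - Bc[0], P.Ex);
      ecoef_row(B.lmn(i,1), B.lmn(j,1), a, b, A[1] - Bc[1], P.Ey);
      ecoef_row(B.lmn(i,2), B.lmn(j,2), a, b, A[2] - Bc[2], P.Ez);
      sp.pp.push_back(P);
    }
}

static double eri_pairs(const ShPair& a, const ShPair& b) {
  double val = 0.0;
  const int L = a.nx + a.ny + a.nz + b.nx + b.ny + b.nz;
  double R0[8][8][8];
  for (size_t ip = 0; ip < a.pp.size(); ++ip) {
    const PrimPair& pa = a.pp[ip];
    for (size_t jp = 0; jp < b.pp.size(); ++jp) {
      const PrimPair& pb = b.pp[jp];
      const double p = pa.p, q = pb.p;
      const double alpha = p * q / (p + q);
      double PQ[3] = {pa.P[0] - pb.P[0], pa.P[1] - pb.P[1], pa.P[2] - pb.P[2]};
      rtensor(L, alpha, PQ, R0);
      const double pref = 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
      double acc = 0.0;
      for (int t = 0; t <= a.nx; ++t)
        for (int u = 0; u <= a.ny; ++u)
          for (int v = 0; v <= a.nz; ++v) {
            const double eb = pa.Ex[t] * pa.Ey[u] * pa.Ez[v];
            if (eb == 0.0) continue;
            for (int tt = 0; tt <= b.nx; ++tt)
              for (int uu = 0; uu <= b.ny; ++uu)
                for (int vv = 0; vv <= b.nz; ++vv) {
                  double ek = pb.Ex[tt] * pb.Ey[uu] * pb.Ez[vv];
                  if (ek == 0.0) continue;
                  double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                  acc += eb * ek * sgn * R0[t + tt][u + uu][v + vv];
                }
          }
      val += pa.c * pb.c * pref * acc;
    }
  }
  return val;
}

// [[Rcpp::export]]
NumericVector eri_dense_cpp(List basis) {
  Basis B = unpack_basis(basis);
  const int n = B.n;
  if (n > 40) stop("dense two-electron reference restricted to small systems");
  std::vector<ShPair> pairs;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      ShPair sp; build_pair(B, i, j, sp); pairs.push_back(sp);
    }
  NumericVector out(((size_t)n) * n * n * n);
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  const size_t N = n;
  for (size_t a = 0; a < pairs.size(); ++a)
    for (size_t b = 0; b <= a; ++b) {
      double v = eri_pairs(pairs[a], pairs[b]);
      int i = pairs[a].i, j = pairs[a].j, k = pairs[b].i, l = pairs[b].j;
      size_t idx[8][4] = {{(size_t)i,(size_t)j,(size_t)k,(size_t)l},
                          {(size_t)j,(size_t)i,(size_t)k,(size_t)l},
                          {(size_t)i,(size_t)j,(size_t)l,(size_t)k},
                          {(size_t)j,(size_t)i,(size_t)l,(size_t)k},
                          {(size_t)k,(size_t)l,(size_t)i,(size_t)j},
                          {(size_t)l,(size_t)k,(size_t)i,(size_t)j},
                          {(size_t)k,(size_t)l,(size_t)j,(size_t)i},
                          {(size_t)l,(size_t)k,(size_t)j,(size_t)i}};
      for (int r = 0; r < 8; ++r)
        out[idx[r][0] + N*idx[r][1] + N*N*idx[r][2] + N*N*N*idx[r][3]] = v;
    }
  return out;
}

// [[Rcpp::export]]
List eri_screened_cpp(List basis, double threshold, double memory_budget_gb) {
  Basis B = unpack_basis(basis);
  const int n = B.n;
  std::vector<ShPair> pairs;
  pairs.reserve((size_t)n * (n + 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      ShPair sp; build_pair(B, i, j, sp);
      sp.q = std::sqrt(std::max(0.0, eri_pairs(sp, sp)));
      pairs.push_back(sp);
    }
  double qmax = 0.0;
  for (auto& p : pairs) qmax = std::max(qmax, p.q);
  std::vector<int> sig;
  for (size_t a = 0; a < pairs.size(); ++a)
    if (pairs[a].q * qmax >= threshold) sig.push_back((int)a);
  // storage estimate: 4 int + 1 double + 1 byte per retained quartet
  double est_gb = (double)sig.size() * sig.size() / 2.0 * 25.0 / 1e9;
  if (est_gb > memory_budget_gb)
    stop("estimated two-electron storage %.2f GB exceeds memory budget %.2f GB",
         est_gb, memory_budget_gb);
  std::vector<int> I, J, K, L;
  std::vector<double> val;
  std::vector<unsigned char> code;
  for (size_t ai = 0; ai < sig.size(); ++ai) {
    const ShPair& pa = pairs[sig[ai]];
    for (size_t bi = 0; bi <= ai; ++bi) {
      const ShPair& pb = pairs[sig[bi]];
      if (pa.q * pb.q < threshold) continue;   // Schwarz bound on the quartet
      double v = eri_pairs(pa, pb);
      int i = pa.i, j = pa.j, k = pb.i, l = pb.j;
      I.push_back(i); J.push_back(j); K.push_back(k); L.push_back(l);
      val.push_back(v);
      unsigned char c = (i == j ? 1 : 0) + (k == l ? 2 : 0) +
                        ((i == k && j == l) ? 4 : 0);
      code.push_back(c);
    }
  }
  IntegerVector sig_i(sig.size()), sig_j(sig.size());
  NumericVector sig_q(sig.size());
  for (size_t a = 0; a < sig.size(); ++a) {
    sig_i[a] = pairs[sig[a]].i + 1;
    sig_j[a] = pairs[sig[a]].j + 1;
    sig_q[a] = pairs[sig[a]].q;
  }
  return List::create(
    _["i"] = IntegerVector(I.begin(), I.end()),
    _["j"] = IntegerVector(J.begin(), J.end()),
    _["k"] = IntegerVector(K.begin(), K.end()),
    _["l"] = IntegerVector(L.begin(), L.end()),
    _["val"] = NumericVector(val.begin(), val.end()),
    _["code"] = IntegerVector(code.begin(), code.end()),
    _["sig_pairs"] = DataFrame::create(_["i"] = sig_i, _["j"] = sig_j, _["q"] = sig_q),
    _["n_pairs_total"] = (double)pairs.size(),
    _["n_quartets"] = (double)val.size());
}

// ---------------------------------------------------------------------------
// Fock contraction from the canonical quartet list.
// J[mu,nu]  = sum_{ls} (mn|ls) P[l,s]    (real part of P only; the
//             antisymmetric imaginary part contracts to zero by symmetry)
// K[mu,nu]  = sum_{ls} (ml|ns) P[l,s]    (complex, Hermitian)
// K is accumulated as A + A^dagger over one representative of each
// bra<->ket orbit of the distinct index permutations.
// ---------------------------------------------------------------------------
static void fock_raw(int n, R_xlen_t nq,
                     const int* I, const int* J, const int* K, const int* L,
                     const double* val, const int* code,
                     const double* Pre, const double* Pim,
                     double* Jm, double* Are, double* Aim) {
  const int N = n;
  for (R_xlen_t q = 0; q < nq; ++q) {
    const int i = I[q], j = J[q], k = K[q], l = L[q];
    const double v = val[q];
    switch (code[q]) {
    case 0: { // all four distinct patterns: i>j, k>l, (ij)!=(kl)
      Jm[i + N*j] += 2.0 * v * Pre[k + N*l];
      Jm[k + N*l] += 2.0 * v * Pre[i + N*j];
      Are[i + N*k] += v * Pre[j + N*l];
      Are[j + N*k] += v * Pre[i + N*l];
      Are[i + N*l] += v * Pre[j + N*k];
      Are[j + N*l] += v * Pre[i + N*k];
      if (Pim) {
        Aim[i + N*k] += v * Pim[j + N*l];
        Aim[j + N*k] += v * Pim[i + N*l];
        Aim[i + N*l] += v * Pim[j + N*k];
        Aim[j + N*l] += v * Pim[i + N*k];
      }
      break; }
    case 1: { // i == j
      Jm[i + N*i] += 2.0 * v * Pre[k + N*l];
      Jm[k + N*l] += v * Pre[i + N*i];
      Are[i + N*k] += v * Pre[i + N*l];
      Are[i + N*l] += v * Pre[i + N*k];
      if (Pim) {
        Aim[i + N*k] += v * Pim[i + N*l];
        Aim[i + N*l] += v * Pim[i + N*k];
      }
      break; }
    case 2: { // k == l
      Jm[i + N*j] += v * Pre[k + N*k];
      Jm[k + N*k] += 2.0 * v * Pre[i + N*j];
      Are[i + N*k] += v * Pre[j + N*k];
      Are[j + N*k] += v * Pre[i + N*k];
      if (Pim) {
        Aim[i + N*k] += v * Pim[j + N*k];
        Aim[j + N*k] += v * Pim[i + N*k];
      }
      break; }
    case 3: { // i == j, k == l, i != k
      Jm[i + N*i] += v * Pre[k + N*k];
      Jm[k + N*k] += v * Pre[i + N*i];
      Are[i + N*k] += v * Pre[i + N*k];
      if (Pim) Aim[i + N*k] += v * Pim[i + N*k];
      break; }
    case 4: { // (i,j) == (k,l) as pairs, i != j
      Jm[i + N*j] += 2.0 * v * Pre[i + N*j];
      Are[i + N*i] += 0.5 * v * Pre[j + N*j];
      Are[j + N*j] += 0.5 * v * Pre[i + N*i];
      Are[j + N*i] += v * Pre[i + N*j];
      if (Pim) {
        Aim[i + N*i] += 0.5 * v * Pim[j + N*j];
        Aim[j + N*j] += 0.5 * v * Pim[i + N*i];
        Aim[j + N*i] += v * Pim[i + N*j];
      }
      break; }
    case 7: { // i == j == k == l
      Jm[i + N*i] += v * Pre[i + N*i];
      Are[i + N*i] += 0.5 * v * Pre[i + N*i];
      if (Pim) Aim[i + N*i] += 0.5 * v * Pim[i + N*i];
      break; }
    }
  }
}

// [[Rcpp::export]]
List fock_jk_cpp(int n, IntegerVector I, IntegerVector J, IntegerVector K,
                 IntegerVector L, NumericVector val, IntegerVector code,
                 arma::mat Pre, Nullable<NumericMatrix> Pim_) {
  arma::mat Jm(n, n, arma::fill::zeros), Are(n, n, arma::fill::zeros),
            Aim(n, n, arma::fill::zeros);
  const double* pim = nullptr;
  arma::mat Pim;
  if (Pim_.isNotNull()) { Pim = as<arma::mat>(Pim_); pim = Pim.memptr(); }
  fock_raw(n, val.size(), I.begin(), J.begin(), K.begin(), L.begin(),
           val.begin(), code.begin(), Pre.memptr(), pim,
           Jm.memptr(), Are.memptr(), Aim.memptr());
  // mirror the canonical triangle of J; Hermitize K
  for (int c = 0; c < n; ++c)
    for (int r = c + 1; r < n; ++r) Jm(c, r) = Jm(r, c);
  arma::mat Kre = Are + Are.t();
  arma::mat Kim = Aim - Aim.t();
  return List::create(_["J"] = Jm, _["Kre"] = Kre, _["Kim"] = Kim);
}

// Fock matrix in the orthonormal representation for a complex orth density
static arma::cx_mat fock_orth(const arma::cx_mat& Porth, const arma::mat& X,
                              const arma::mat& Hcore,
                              const int* I, const int* J, const int* K,
                              const int* L, const double* val, const int* code,
                              R_xlen_t nq, arma::mat& Pao_re, arma::mat& Pao_im,
                              arma::mat& Fao_re, arma::mat& Fao_im) {
  const int n = X.n_rows;
  Pao_re = X * arma::real(Porth) * X.t();
  Pao_im = X * arma::imag(Porth) * X.t();
  arma::mat Jm(n, n, arma::fill::zeros), Are(n, n, arma::fill::zeros),
            Aim(n, n, arma::fill::zeros);
  fock_raw(n, nq, I, J, K, L, val, code, Pao_re.memptr(), Pao_im.memptr(),
           Jm.memptr(), Are.memptr(), Aim.memptr());
  for (int c = 0; c < n; ++c)
    for (int r = c + 1; r < n; ++r) Jm(c, r) = Jm(r, c);
  Fao_re = Hcore + Jm - 0.5 * (Are + Are.t());
  Fao_im = -0.5 * (Aim - Aim.t());
  arma::cx_mat Fp(X.t() * Fao_re * X, X.t() * Fao_im * X);
  return Fp;
}

static arma::cx_mat expstep(const arma::cx_mat& Fp, double dt) {
  arma::vec eval;
  arma::cx_mat evec;
  arma::eig_sym(eval, evec, arma::cx_mat(0.5 * (Fp + Fp.t())));
  arma::cx_vec ph = arma::exp(arma::cx_double(0, -dt) * arma::conv_to<arma::cx_vec>::from(eval));
  return evec * arma::diagmat(ph) * evec.t();
}

// [[Rcpp::export]]
List propagate_cpp(arma::mat X, arma::mat Hcore, IntegerVector I, IntegerVector J,
                   IntegerVector K, IntegerVector L, NumericVector val,
                   IntegerVector code, arma::cx_mat P0orth,
                   arma::mat Dx, arma::mat Dy, arma::mat Dz,
                   double enuc, double n_electrons,
                   double dt, int nsteps, double corrector_tol, int max_corrector) {
  const int n = X.n_rows;
  const R_xlen_t nq = val.size();
  const int* Ip = I.begin(); const int* Jp = J.begin();
  const int* Kp = K.begin(); const int* Lp = L.begin();
  const double* vp = val.begin(); const int* cp = code.begin();

  arma::cx_mat P = P0orth;
  arma::mat Pre, Pim, Fre, Fim;
  arma::cx_mat Fcur = fock_orth(P, X, Hcore, Ip, Jp, Kp, Lp, vp, cp, nq,
                                Pre, Pim, Fre, Fim);
  arma::cx_mat Fprev = Fcur;

  arma::mat dip(nsteps, 3), pbx(nsteps, n), pby(nsteps, n), pbz(nsteps, n);
  arma::vec times(nsteps), drift(nsteps), energy(nsteps);
  double corr_total = 0.0;
  int consecutive_fail = 0;

  for (int s = 0; s < nsteps; ++s) {
    // predictor: linear extrapolation of the midpoint Fock
    arma::cx_mat Fmid = (s == 0) ? Fcur : arma::cx_mat(1.5 * Fcur - 0.5 * Fprev);
    arma::cx_mat U = expstep(Fmid, dt);
    arma::cx_mat Pnew = U * P * U.t();
    arma::cx_mat Fnew;
    bool converged = false;
    int it = 0;
    for (; it < max_corrector; ++it) {
      Fnew = fock_orth(Pnew, X, Hcore, Ip, Jp, Kp, Lp, vp, cp, nq,
                       Pre, Pim, Fre, Fim);
      arma::cx_mat Fm2 = 0.5 * (Fcur + Fnew);
      U = expstep(Fm2, dt);
      arma::cx_mat P2 = U * P * U.t();
      double delta = arma::abs(P2 - Pnew).max();
      Pnew = P2;
      if (delta < corrector_tol) { converged = true; ++it; break; }
    }
    corr_total += it;
    if (!converged) {
      if (++consecutive_fail > 10)
        stop("corrector failed to converge for more than 10 consecutive steps (step %d)", s + 1);
    } else consecutive_fail = 0;

    Fprev = Fcur;
    Fcur = Fnew;  // Fock at a density within corrector_tol of the accepted one
    P = Pnew;

    // observables at the accepted density
    arma::mat Pr = X * arma::real(P) * X.t();
    arma::mat Pi = X * arma::imag(P) * X.t();
    times(s) = (s + 1) * dt;
    // electronic dipole mu_a = -Tr(P D_a); per-basis Mulliken-symmetrized split
    arma::vec cx = -arma::sum(Pr % Dx, 1);
    arma::vec cy = -arma::sum(Pr % Dy, 1);
    arma::vec cz = -arma::sum(Pr % Dz, 1);
    pbx.row(s) = cx.t(); pby.row(s) = cy.t(); pbz.row(s) = cz.t();
    dip(s, 0) = arma::accu(cx); dip(s, 1) = arma::accu(cy); dip(s, 2) = arma::accu(cz);
    // idempotency drift: Tr(P'^2)/2 should equal the electron count
    double tr2 = arma::accu(arma::square(arma::abs(P)));
    drift(s) = std::abs(tr2 / 2.0 - n_electrons) / n_electrons;
    // total energy (field-free after the kick)
    double eH = arma::accu(Pr % Hcore);
    // need F at the accepted density in the AO basis: recompute cheaply from Fcur
    // Fcur corresponds to the last corrector density (within tol); use it.
    arma::mat Fao_r = Fre, Fao_i = Fim;
    // Re Tr(PF) = sum Pre*Fre^T + sum Pim*Fim (Fre symmetric, Fim antisymmetric)
    double eF = arma::accu(Pr % Fao_r) + arma::accu(Pi % Fao_i);
    energy(s) = 0.5 * (eH + eF) + enuc;
  }
  return List::create(_["times"] = times, _["dipole"] = dip,
                      _["per_basis_x"] = pbx, _["per_basis_y"] = pby,
                      _["per_basis_z"] = pbz, _["drift"] = drift,
                      _["energy"] = energy,
                      _["mean_corrector_iters"] = corr_total / nsteps);
}
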