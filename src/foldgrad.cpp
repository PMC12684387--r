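// McCaskill inside/outside partition functions over the extended
// alphabet {A,C,G,U,6}, their analytic derivatives with respect to the
// 15 trainable m6A stacking parameters, the SGD training loop, and
// Zuker MFE folding.  Raw floating point (no rescaling); sequence
// length is capped at 200 in the R layer.
//
// Conventions (1-based indices, padded tables):
//   Z(i,j)  : full partition function, == 1 for empty intervals (i > j)
//   Z1(i,j) : i paired to some l in (i,j], bases l+1..j unpaired
//   Zb(i,j) : (i,j) paired (0 if the pair is disallowed)
//   Zm(i,j) : >= 1 multiloop branch on [i,j], every unpaired base
//             weighted exp(-beta*f4)
//   Zm1(i,j): exactly one branch starting at i, trailing bases weighted
//   Wb(i,j) : outside weight of pair (i,j)
// Multiloop model: E = f3 + f4 * (#unpaired) + f5 * (#inner branches);
// the f5 factor for a branch is applied where it is attached (in Zm,
// and once in the Zb / Wb multiloop terms).
//
// Derivative tables for all requested parameter classes are filled in
// one sweep sharing the loop traversal (K-interleaved storage);
// because theta enters only through the stack case of f2, the only
// derivative seeds are the stack-class indicators, and dZb/dWb vanish
// wherever Zb/Wb do.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

static const double BIG = 1e9;

struct Model {
  std::vector<double> theta;      // 15, kcal/mol
  std::vector<double> thW;        // exp(-beta*theta)
  std::vector<int> stackTheta;    // 5^4: -1 invalid, 0 canonical, 1..15
  std::vector<double> stackW;     // 5^4: canonical Boltzmann weight
  std::vector<double> stackEc;    // 5^4: canonical energy
  int pairable[5][5];
  std::vector<double> wH, wB, wI; // Boltzmann loop weights, index = size
  std::vector<double> eH, eB, eI; // loop energies (BIG if forbidden)
  std::vector<double> powf4;      // exp(-beta*f4*t)
  double f3, f4, f5, beta, e35, e5;
  int minLoop, N;
};

static inline int soff(int a, int b, int c, int d) {
  return (a - 1) + 5 * (b - 1) + 25 * (c - 1) + 125 * (d - 1);
}

static Model makeModel(const List& par, int N) {
  Model M;
  M.N = N;
  M.theta = as<std::vector<double> >(par["theta"]);
  M.stackTheta = as<std::vector<int> >(par["stackTheta"]);
  M.stackEc = as<std::vector<double> >(par["stackE"]);
  IntegerMatrix pr = par["pairable"];
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b) M.pairable[a][b] = pr(a, b);
  M.f3 = as<double>(par["f3"]);
  M.f4 = as<double>(par["f4"]);
  M.f5 = as<double>(par["f5"]);
  M.beta = as<double>(par["beta"]);
  M.minLoop = as<int>(par["minLoop"]);
  M.e35 = std::exp(-M.beta * (M.f3 + M.f5));
  M.e5 = std::exp(-M.beta * M.f5);
  M.thW.resize(15);
  for (int k = 0; k < 15; ++k) M.thW[k] = std::exp(-M.beta * M.theta[k]);
  M.stackW.resize(M.stackEc.size());
  for (size_t t = 0; t < M.stackEc.size(); ++t)
    M.stackW[t] = std::exp(-M.beta * M.stackEc[t]);

  NumericVector hp = par["hairpin"], bl = par["bulge"], in = par["internal"];
  double RT = 1.0 / M.beta;
  int maxLoop = N + 1;
  M.wH.assign(maxLoop + 1, 0.0); M.wB.assign(maxLoop + 1, 0.0);
  M.wI.assign(maxLoop + 1, 0.0);
  M.eH.assign(maxLoop + 1, BIG); M.eB.assign(maxLoop + 1, BIG);
  M.eI.assign(maxLoop + 1, BIG);
  for (int sz = 1; sz <= maxLoop; ++sz) {
    double h, b, i;
    if (sz <= 30) { h = hp[sz - 1]; b = bl[sz - 1]; i = in[sz - 1]; }
    else {
      double js = 1.75 * RT * std::log(sz / 30.0);
      h = hp[29] + js; b = bl[29] + js; i = in[29] + js;
    }
    if (R_finite(h)) { M.eH[sz] = h; M.wH[sz] = std::exp(-M.beta * h); }
    if (R_finite(b)) { M.eB[sz] = b; M.wB[sz] = std::exp(-M.beta * b); }
    if (R_finite(i)) { M.eI[sz] = i; M.wI[sz] = std::exp(-M.beta * i); }
  }
  M.powf4.resize(N + 2);
  for (int t = 0; t <= N + 1; ++t) M.powf4[t] = std::exp(-M.beta * M.f4 * t);
  return M;
}

// per-row ascending lists of pairable partners (the only cells where
// Zb can be nonzero); cuts the two-loop scans to live cells
struct Live {
  std::vector<std::vector<int> > row;
  Live(const std::vector<int>& s, const Model& M) {
    int N = M.N;
    row.assign(N + 2, std::vector<int>());
    for (int i = 1; i <= N; ++i)
      for (int j = i + M.minLoop + 1; j <= N; ++j)
        if (M.pairable[s[i] - 1][s[j] - 1]) row[i].push_back(j);
  }
};

struct Tab {
  int N, W;
  std::vector<double> z, z1, zb, zm, zm1, wb;
  Tab(int n) : N(n), W(n + 2) {
    size_t sz = (size_t)W * W;
    z.assign(sz, 0.0); z1.assign(sz, 0.0); zb.assign(sz, 0.0);
    zm.assign(sz, 0.0); zm1.assign(sz, 0.0); wb.assign(sz, 0.0);
  }
  inline size_t at(int i, int j) const { return (size_t)i * W + j; }
  inline double Z(int i, int j) const { return i > j ? 1.0 : z[at(i, j)]; }
  inline double Z1(int i, int j) const { return i >= j ? 0.0 : z1[at(i, j)]; }
  inline double Zb(int i, int j) const { return i >= j ? 0.0 : zb[at(i, j)]; }
  inline double Zm(int i, int j) const { return i > j ? 0.0 : zm[at(i, j)]; }
  inline double Zm1(int i, int j) const { return i >= j ? 0.0 : zm1[at(i, j)]; }
  inline double Wb(int i, int j) const { return i >= j ? 0.0 : wb[at(i, j)]; }
};

// K-interleaved derivative tables: value for class slot k at cell
// (i,j) lives at [at(i,j) * K + k]
struct GradTab {
  int N, W, K;
  std::vector<double> z, z1, zb, zm, zm1, wb;
  GradTab(int n, int k) : N(n), W(n + 2), K(k) {
    size_t sz = (size_t)W * W * K;
    z.assign(sz, 0.0); z1.assign(sz, 0.0); zb.assign(sz, 0.0);
    zm.assign(sz, 0.0); zm1.assign(sz, 0.0); wb.assign(sz, 0.0);
  }
  inline size_t at(int i, int j) const { return ((size_t)i * W + j) * K; }
  void reset() {
    std::fill(z.begin(), z.end(), 0.0);
    std::fill(z1.begin(), z1.end(), 0.0);
    std::fill(zb.begin(), zb.end(), 0.0);
    std::fill(zm.begin(), zm.end(), 0.0);
    std::fill(zm1.begin(), zm1.end(), 0.0);
    std::fill(wb.begin(), wb.end(), 0.0);
  }
};

// two-loop Boltzmann weight, outer pair (i,j), inner pair (h,l)
static inline double w2loop(const std::vector<int>& s, const Model& M,
                            int i, int j, int h, int l) {
  int ll = h - i - 1, rl = j - l - 1;
  if (ll == 0 && rl == 0) {
    int off = soff(s[i], s[h], s[j], s[l]);
    int k = M.stackTheta[off];
    if (k < 0) return 0.0;
    return k == 0 ? M.stackW[off] : M.thW[k - 1];
  }
  int tot = ll + rl;
  return (ll == 0 || rl == 0) ? M.wB[tot] : M.wI[tot];
}

static void insideFill(const std::vector<int>& s, const Model& M,
                       const Live& L, Tab& T) {
  int N = M.N;
  for (int j = 1; j <= N; ++j) {
    for (int i = j; i >= 1; --i) {
      // Zb
      if (M.pairable[s[i] - 1][s[j] - 1] && j - i - 1 >= M.minLoop) {
        double acc = M.wH[j - i - 1];
        for (int h = i + 1; h <= j - 2; ++h) {
          const std::vector<int>& ls = L.row[h];
          for (size_t q = 0; q < ls.size(); ++q) {
            int l = ls[q];
            if (l > j - 1) break;
            double zb = T.zb[T.at(h, l)];
            if (zb == 0.0) continue;
            acc += zb * w2loop(s, M, i, j, h, l);
          }
        }
        for (int h = i + 2; h <= j - 2; ++h) {
          double zm = T.Zm(i + 1, h - 1);
          if (zm == 0.0) continue;
          acc += zm * T.Zm1(h, j - 1) * M.e35;
        }
        T.zb[T.at(i, j)] = acc;
      }
      // Zm1
      if (i < j) {
        double acc = 0.0;
        const std::vector<int>& ls = L.row[i];
        for (size_t q = 0; q < ls.size(); ++q) {
          int l = ls[q];
          if (l > j) break;
          acc += T.zb[T.at(i, l)] * M.powf4[j - l];
        }
        T.zm1[T.at(i, j)] = acc;
      }
      // Zm
      {
        double acc = 0.0;
        for (int h = i; h <= j - 1; ++h) {
          double zm1 = T.Zm1(h, j);
          if (zm1 == 0.0) continue;
          acc += (M.powf4[h - i] + T.Zm(i, h - 1)) * zm1 * M.e5;
        }
        T.zm[T.at(i, j)] = acc;
      }
      // Z1
      if (i < j) {
        double acc = 0.0;
        const std::vector<int>& ls = L.row[i];
        for (size_t q = 0; q < ls.size(); ++q) {
          if (ls[q] > j) break;
          acc += T.zb[T.at(i, ls[q])];
        }
        T.z1[T.at(i, j)] = acc;
      }
      // Z
      {
        double acc = 1.0;
        for (int h = i; h <= j - 1; ++h) {
          double z1 = T.Z1(h, j);
          if (z1 != 0.0) acc += T.Z(i, h - 1) * z1;
        }
        T.z[T.at(i, j)] = acc;
      }
    }
  }
}

static void outsideFill(const std::vector<int>& s, const Model& M,
                        const Live& L, Tab& T) {
  int N = M.N;
  for (int d = N - 1; d >= M.minLoop + 1; --d) {
    for (int i = 1; i + d <= N; ++i) {
      int j = i + d;
      if (T.Zb(i, j) == 0.0) continue;
      double acc = T.Z(1, i - 1) * T.Z(j + 1, N);
      for (int k = 1; k <= i - 1; ++k) {
        const std::vector<int>& ls = L.row[k];
        for (size_t q = ls.size(); q-- > 0; ) {
          int l = ls[q];
          if (l <= j) break;
          double wb = T.wb[T.at(k, l)];
          if (wb == 0.0) continue;
          acc += wb * w2loop(s, M, k, l, i, j);
          double Ml = T.Zm(k + 1, i - 1), Mr = T.Zm(j + 1, l - 1);
          if (Ml != 0.0 || Mr != 0.0)
            acc += wb * M.e35 *
              (Ml * M.powf4[l - 1 - j] + M.powf4[i - 1 - k] * Mr + Ml * Mr);
        }
      }
      T.wb[T.at(i, j)] = acc;
    }
  }
}

// Derivative inside pass for the K classes ks[0..K-1] (values 1..15),
// single sweep.  th2pos maps a theta class to its slot (or -1).
static void gradInsideFill(const std::vector<int>& s, const Model& M,
                           const Live& L, const Tab& T,
                           const std::vector<int>& th2pos, GradTab& D) {
  int N = M.N, K = D.K;
  double mb = -M.beta;
  std::vector<double> acc(K);
  for (int j = 1; j <= N; ++j) {
    for (int i = j; i >= 1; --i) {
      size_t cij = T.at(i, j);
      if (T.zb[cij] != 0.0 && j > i) {
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int h = i + 1; h <= j - 2; ++h) {
          const std::vector<int>& ls = L.row[h];
          for (size_t q = 0; q < ls.size(); ++q) {
            int l = ls[q];
            if (l > j - 1) break;
            double zb = T.zb[T.at(h, l)];
            if (zb == 0.0) continue;
            double w = w2loop(s, M, i, j, h, l);
            const double* dzb = &D.zb[D.at(h, l)];
            for (int k = 0; k < K; ++k) acc[k] += dzb[k] * w;
            if (h == i + 1 && l == j - 1) {
              int t = M.stackTheta[soff(s[i], s[h], s[j], s[l])];
              if (t > 0 && th2pos[t] >= 0) acc[th2pos[t]] += zb * mb * w;
            }
          }
        }
        for (int h = i + 2; h <= j - 2; ++h) {
          double zm = T.Zm(i + 1, h - 1), zm1 = T.Zm1(h, j - 1);
          if (zm == 0.0 && zm1 == 0.0) continue;
          const double* dzm = &D.zm[D.at(i + 1, h - 1)];
          const double* dzm1 = &D.zm1[D.at(h, j - 1)];
          for (int k = 0; k < K; ++k)
            acc[k] += (dzm[k] * zm1 + zm * dzm1[k]) * M.e35;
        }
        double* out = &D.zb[D.at(i, j)];
        for (int k = 0; k < K; ++k) out[k] = acc[k];
      }
      if (i < j) {
        // dZm1 and dZ1
        std::fill(acc.begin(), acc.end(), 0.0);
        std::vector<double> acc1(K, 0.0);
        const std::vector<int>& ls = L.row[i];
        for (size_t q = 0; q < ls.size(); ++q) {
          int l = ls[q];
          if (l > j) break;
          const double* dzb = &D.zb[D.at(i, l)];
          double pf = M.powf4[j - l];
          for (int k = 0; k < K; ++k) {
            acc[k] += dzb[k] * pf;
            acc1[k] += dzb[k];
          }
        }
        double* om1 = &D.zm1[D.at(i, j)];
        double* o1 = &D.z1[D.at(i, j)];
        for (int k = 0; k < K; ++k) { om1[k] = acc[k]; o1[k] = acc1[k]; }
      }
      {
        // dZm
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int h = i; h <= j - 1; ++h) {
          if (h >= j) break;
          double zm1 = T.Zm1(h, j);
          const double* dzm1 = &D.zm1[D.at(h, j)];
          double pre = M.powf4[h - i] + T.Zm(i, h - 1);
          if (h - 1 >= i) {
            const double* dzm = &D.zm[D.at(i, h - 1)];
            if (zm1 != 0.0)
              for (int k = 0; k < K; ++k) acc[k] += dzm[k] * zm1 * M.e5;
          }
          for (int k = 0; k < K; ++k) acc[k] += pre * dzm1[k] * M.e5;
        }
        double* om = &D.zm[D.at(i, j)];
        for (int k = 0; k < K; ++k) om[k] = acc[k];
      }
      {
        // dZ
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int h = i; h <= j - 1; ++h) {
          double z1 = T.Z1(h, j);
          const double* dz1 = &D.z1[D.at(h, j)];
          double zpre = T.Z(i, h - 1);
          if (h - 1 >= i && z1 != 0.0) {
            const double* dz = &D.z[D.at(i, h - 1)];
            for (int k = 0; k < K; ++k) acc[k] += dz[k] * z1;
          }
          for (int k = 0; k < K; ++k) acc[k] += zpre * dz1[k];
        }
        double* oz = &D.z[D.at(i, j)];
        for (int k = 0; k < K; ++k) oz[k] = acc[k];
      }
    }
  }
}

static void gradOutsideFill(const std::vector<int>& s, const Model& M,
                            const Live& L, const Tab& T,
                            const std::vector<int>& th2pos, GradTab& D) {
  int N = M.N, K = D.K;
  double mb = -M.beta;
  std::vector<double> acc(K);
  for (int d = N - 1; d >= M.minLoop + 1; --d) {
    for (int i = 1; i + d <= N; ++i) {
      int j = i + d;
      if (T.Zb(i, j) == 0.0) continue;
      std::fill(acc.begin(), acc.end(), 0.0);
      {
        double zr = T.Z(j + 1, N), zl = T.Z(1, i - 1);
        if (i - 1 >= 1) {
          const double* dzl = &D.z[D.at(1, i - 1)];
          for (int k = 0; k < K; ++k) acc[k] += dzl[k] * zr;
        }
        if (j + 1 <= N) {
          const double* dzr = &D.z[D.at(j + 1, N)];
          for (int k = 0; k < K; ++k) acc[k] += zl * dzr[k];
        }
      }
      for (int kr = 1; kr <= i - 1; ++kr) {
        const std::vector<int>& ls = L.row[kr];
        for (size_t q = ls.size(); q-- > 0; ) {
          int l = ls[q];
          if (l <= j) break;
          double wb = T.wb[T.at(kr, l)];
          if (wb == 0.0) continue;       // dWb == 0 wherever Wb == 0
          const double* dwb = &D.wb[D.at(kr, l)];
          double w = w2loop(s, M, kr, l, i, j);
          for (int k = 0; k < K; ++k) acc[k] += dwb[k] * w;
          if (i == kr + 1 && j == l - 1) {
            int t = M.stackTheta[soff(s[kr], s[i], s[l], s[j])];
            if (t > 0 && th2pos[t] >= 0) acc[th2pos[t]] += wb * mb * w;
          }
          double Ml = T.Zm(kr + 1, i - 1), Mr = T.Zm(j + 1, l - 1);
          const double* dMl = (i - 1 >= kr + 1) ?
            &D.zm[D.at(kr + 1, i - 1)] : NULL;
          const double* dMr = (l - 1 >= j + 1) ?
            &D.zm[D.at(j + 1, l - 1)] : NULL;
          if (Ml != 0.0 || Mr != 0.0 || dMl || dMr) {
            double pfR = M.powf4[l - 1 - j], pfL = M.powf4[i - 1 - kr];
            double br = Ml * pfR + pfL * Mr + Ml * Mr;
            for (int k = 0; k < K; ++k) {
              double dml = dMl ? dMl[k] : 0.0, dmr = dMr ? dMr[k] : 0.0;
              double dbr = dml * pfR + pfL * dmr + dml * Mr + Ml * dmr;
              acc[k] += M.e35 * (dwb[k] * br + wb * dbr);
            }
          }
        }
      }
      double* out = &D.wb[D.at(i, j)];
      for (int k = 0; k < K; ++k) out[k] = acc[k];
    }
  }
}

// theta classes that can occur as a stack anywhere in the sequence
static std::vector<int> activeClasses(const std::vector<int>& s,
                                      const Model& M) {
  std::vector<bool> seen(16, false);
  int N = M.N;
  for (int i = 1; i + 3 <= N; ++i)
    for (int j = i + 3 + M.minLoop; j <= N; ++j) {
      if (!M.pairable[s[i] - 1][s[j] - 1]) continue;
      if (!M.pairable[s[i + 1] - 1][s[j - 1] - 1]) continue;
      int k = M.stackTheta[soff(s[i], s[i + 1], s[j], s[j - 1])];
      if (k > 0) seen[k] = true;
    }
  std::vector<int> out;
  for (int k = 1; k <= 15; ++k) if (seen[k]) out.push_back(k);
  return out;
}

static NumericMatrix bppMatrix(const Tab& T, int N) {
  NumericMatrix P(N, N);
  double Z = T.Z(1, N);
  for (int i = 1; i <= N; ++i)
    for (int j = i + 1; j <= N; ++j) {
      double p = T.Zb(i, j) * T.Wb(i, j) / Z;
      P(i - 1, j - 1) = p; P(j - 1, i - 1) = p;
    }
  return P;
}

static NumericMatrix tabToMatrix(const std::vector<double>& v, int N,
                                 int W) {
  NumericMatrix out(N, N);
  for (int i = 1; i <= N; ++i)
    for (int j = 1; j <= N; ++j)
      out(i - 1, j - 1) = v[(size_t)i * W + j];
  return out;
}

static NumericMatrix gradToMatrix(const std::vector<double>& v, int N,
                                  int W, int K, int k) {
  NumericMatrix out(N, N);
  for (int i = 1; i <= N; ++i)
    for (int j = 1; j <= N; ++j)
      out(i - 1, j - 1) = v[((size_t)i * W + j) * K + k];
  return out;
}

// [[Rcpp::export]]
List cpp_fold(IntegerVector seqv, List par, bool withTables = false) {
  int N = seqv.size();
  std::vector<int> s(N + 1);
  for (int i = 0; i < N; ++i) s[i + 1] = seqv[i];
  Model M = makeModel(par, N);
  Live L(s, M);
  Tab T(N);
  insideFill(s, M, L, T);
  outsideFill(s, M, L, T);
  NumericMatrix P = bppMatrix(T, N);
  NumericVector mb(N);
  for (int i = 0; i < N; ++i) {
    double acc = 0.0;
    for (int j = 0; j < N; ++j) acc += P(i, j);
    mb[i] = acc;
  }
  List out = List::create(_["Z"] = T.Z(1, N), _["P"] = P, _["mbpp"] = mb);
  if (withTables) {
    out["tables"] = List::create(
      _["Z"] = tabToMatrix(T.z, N, T.W),
      _["Z1"] = tabToMatrix(T.z1, N, T.W),
      _["Zb"] = tabToMatrix(T.zb, N, T.W),
      _["Zm"] = tabToMatrix(T.zm, N, T.W),
      _["Zm1"] = tabToMatrix(T.zm1, N, T.W),
      _["Wb"] = tabToMatrix(T.wb, N, T.W));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_grad(IntegerVector seqv, List par, IntegerVector which,
              bool withTables = false) {
  int N = seqv.size();
  std::vector<int> s(N + 1);
  for (int i = 0; i < N; ++i) s[i + 1] = seqv[i];
  Model M = makeModel(par, N);
  Live L(s, M);
  Tab T(N);
  insideFill(s, M, L, T);
  outsideFill(s, M, L, T);
  double Z = T.Z(1, N);

  std::vector<int> ks;
  if (which.size() == 0) ks = activeClasses(s, M);
  else ks = as<std::vector<int> >(which);
  int K = (int)ks.size();
  std::vector<int> th2pos(16, -1);
  for (int k = 0; k < K; ++k) th2pos[ks[k]] = k;

  List perK(15);
  LogicalVector active(15, false);
  if (K > 0) {
    GradTab D(N, K);
    gradInsideFill(s, M, L, T, th2pos, D);
    gradOutsideFill(s, M, L, T, th2pos, D);
    for (int k = 0; k < K; ++k) {
      int kk = ks[k];
      double dZ1N = D.z[D.at(1, N) + k];
      NumericMatrix dP(N, N);
      NumericVector dmb(N);
      for (int i = 1; i <= N; ++i)
        for (int j = i + 1; j <= N; ++j) {
          double zb = T.Zb(i, j);
          double dp = 0.0;
          if (zb != 0.0) {
            double num = (D.zb[D.at(i, j) + k] * T.Wb(i, j) +
                          zb * D.wb[D.at(i, j) + k]) * Z -
                         zb * T.Wb(i, j) * dZ1N;
            dp = num / (Z * Z);
          }
          dP(i - 1, j - 1) = dp; dP(j - 1, i - 1) = dp;
        }
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int j = 0; j < N; ++j) acc += dP(i, j);
        dmb[i] = acc;
      }
      List g = List::create(_["dP"] = dP, _["dmbpp"] = dmb,
                            _["dZ"] = dZ1N);
      if (withTables) {
        g["tables"] = List::create(
          _["dZ"] = gradToMatrix(D.z, N, D.W, K, k),
          _["dZb"] = gradToMatrix(D.zb, N, D.W, K, k),
          _["dZm"] = gradToMatrix(D.zm, N, D.W, K, k),
          _["dZm1"] = gradToMatrix(D.zm1, N, D.W, K, k),
          _["dWb"] = gradToMatrix(D.wb, N, D.W, K, k));
      }
      perK[kk - 1] = g;
      active[kk - 1] = true;
    }
  }
  return List::create(_["perTheta"] = perK, _["active"] = active,
                      _["mbppLen"] = N);
}

// loss and its gradient at the current parameters (theta from par)
static void lossAndGrad(const std::vector<int>& s, const Model& M,
                        const Live& L, const std::vector<int>& act,
                        const NumericVector& gt,
                        double& loss, std::vector<double>& grad) {
  int N = M.N;
  Tab T(N);
  insideFill(s, M, L, T);
  outsideFill(s, M, L, T);
  double Z = T.Z(1, N);
  std::vector<double> sgn(N + 1, 0.0);
  loss = 0.0;
  for (int i = 1; i <= N; ++i) {
    double acc = 0.0;
    for (int j = 1; j <= N; ++j) {
      if (j == i) continue;
      int a = i < j ? i : j, b = i < j ? j : i;
      acc += T.Zb(a, b) * T.Wb(a, b) / Z;
    }
    double diff = acc - gt[i - 1];
    loss += std::fabs(diff);
    sgn[i] = (diff > 0.0) ? 1.0 : (diff < 0.0 ? -1.0 : 0.0);
  }
  std::fill(grad.begin(), grad.end(), 0.0);
  int K = (int)act.size();
  if (K == 0) return;
  std::vector<int> th2pos(16, -1);
  for (int k = 0; k < K; ++k) th2pos[act[k]] = k;
  GradTab D(N, K);
  gradInsideFill(s, M, L, T, th2pos, D);
  gradOutsideFill(s, M, L, T, th2pos, D);
  std::vector<double> dZ1N(K);
  for (int k = 0; k < K; ++k) dZ1N[k] = D.z[D.at(1, N) + k];
  std::vector<double> g(K, 0.0);
  for (int i = 1; i <= N; ++i)
    for (int j = i + 1; j <= N; ++j) {
      double zb = T.Zb(i, j);
      if (zb == 0.0) continue;
      double sij = sgn[i] + sgn[j];      // dP_ij feeds both marginals
      if (sij == 0.0) continue;
      double wb = T.Wb(i, j);
      const double* dzb = &D.zb[D.at(i, j)];
      const double* dwb = &D.wb[D.at(i, j)];
      for (int k = 0; k < K; ++k) {
        double num = (dzb[k] * wb + zb * dwb[k]) * Z - zb * wb * dZ1N[k];
        g[k] += sij * num / (Z * Z);
      }
    }
  for (int k = 0; k < K; ++k) grad[act[k] - 1] = g[k];
}

// [[Rcpp::export]]
List cpp_loss_grad(IntegerVector seqv, List par, NumericVector gt) {
  int N = seqv.size();
  std::vector<int> s(N + 1);
  for (int i = 0; i < N; ++i) s[i + 1] = seqv[i];
  Model M = makeModel(par, N);
  Live L(s, M);
  std::vector<int> act = activeClasses(s, M);
  double loss;
  std::vector<double> grad(15, 0.0);
  lossAndGrad(s, M, L, act, gt, loss, grad);
  return List::create(_["loss"] = loss, _["grad"] = wrap(grad));
}

// [[Rcpp::export]]
List cpp_train(List seqs, List gts, List par, NumericVector theta0,
               int epochs, double lr, double guard, bool trace) {
  int nseq = seqs.size();
  std::vector<std::vector<int> > S(nseq);
  std::vector<NumericVector> G(nseq);
  for (int q = 0; q < nseq; ++q) {
    IntegerVector sv = seqs[q];
    int N = sv.size();
    S[q].assign(N + 1, 0);
    for (int i = 0; i < N; ++i) S[q][i + 1] = sv[i];
    G[q] = gts[q];
  }
  List parLocal = clone(par);
  std::vector<double> theta = as<std::vector<double> >(theta0);

  // active classes and live rows are theta-independent
  std::vector<std::vector<int> > act(nseq);
  std::vector<Live> live;
  live.reserve(nseq);
  for (int q = 0; q < nseq; ++q) {
    Model M0 = makeModel(parLocal, (int)S[q].size() - 1);
    act[q] = activeClasses(S[q], M0);
    live.push_back(Live(S[q], M0));
  }

  int nUpd = epochs * nseq;
  NumericVector lossOut(nUpd);
  IntegerVector epochOut(nUpd), seqOut(nUpd);
  NumericMatrix traj(trace ? nUpd : 0, 15);

  std::vector<double> grad(15, 0.0);
  int u = 0;
  for (int ep = 1; ep <= epochs; ++ep) {
    for (int q = 0; q < nseq; ++q) {
      int N = (int)S[q].size() - 1;
      parLocal["theta"] = wrap(theta);
      Model M = makeModel(parLocal, N);
      double loss;
      lossAndGrad(S[q], M, live[q], act[q], G[q], loss, grad);
      for (int k = 0; k < 15; ++k) theta[k] -= lr * grad[k];
      for (int k = 0; k < 15; ++k)
        if (std::fabs(theta[k]) > guard)
          stop("divergence guard: |theta| exceeded %.1f kcal/mol", guard);
      lossOut[u] = loss; epochOut[u] = ep; seqOut[u] = q + 1;
      if (trace) for (int k = 0; k < 15; ++k) traj(u, k) = theta[k];
      ++u;
      if (u % 256 == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["theta"] = wrap(theta), _["loss"] = lossOut,
                      _["epoch"] = epochOut, _["seqIndex"] = seqOut,
                      _["traj"] = traj);
}

// ---- Zuker MFE ------------------------------------------------------------

static inline double e2loop(const std::vector<int>& s, const Model& M,
                            int i, int j, int h, int l) {
  int ll = h - i - 1, rl = j - l - 1;
  if (ll == 0 && rl == 0) {
    int off = soff(s[i], s[h], s[j], s[l]);
    int k = M.stackTheta[off];
    if (k < 0) return BIG;
    return k == 0 ? M.stackEc[off] : M.theta[k - 1];
  }
  int tot = ll + rl;
  return (ll == 0 || rl == 0) ? M.eB[tot] : M.eI[tot];
}

struct MfeTab {
  int N, W;
  std::vector<double> vb, vm, vm1, we;
  MfeTab(int n) : N(n), W(n + 2) {
    size_t sz = (size_t)W * W;
    vb.assign(sz, BIG); vm.assign(sz, BIG); vm1.assign(sz, BIG);
    we.assign(n + 1, 0.0);
  }
  inline size_t at(int i, int j) const { return (size_t)i * W + j; }
  inline double Vb(int i, int j) const { return i >= j ? BIG : vb[at(i, j)]; }
  inline double Vm(int i, int j) const { return i > j ? BIG : vm[at(i, j)]; }
  inline double Vm1(int i, int j) const { return i >= j ? BIG : vm1[at(i, j)]; }
};

static void mfeFill(const std::vector<int>& s, const Model& M, MfeTab& V) {
  int N = M.N;
  for (int j = 1; j <= N; ++j) {
    for (int i = j; i >= 1; --i) {
      if (M.pairable[s[i] - 1][s[j] - 1] && j - i - 1 >= M.minLoop) {
        double best = M.eH[j - i - 1];
        for (int h = i + 1; h <= j - 2; ++h)
          for (int l = h + 1; l <= j - 1; ++l) {
            double v = V.Vb(h, l);
            if (v >= BIG / 2) continue;
            double cand = v + e2loop(s, M, i, j, h, l);
            if (cand < best) best = cand;
          }
        for (int h = i + 2; h <= j - 2; ++h) {
          double a = V.Vm(i + 1, h - 1), b = V.Vm1(h, j - 1);
          if (a >= BIG / 2 || b >= BIG / 2) continue;
          double cand = a + b + M.f3 + M.f5;
          if (cand < best) best = cand;
        }
        V.vb[V.at(i, j)] = best;
      }
      if (i < j) {
        double best = BIG;
        for (int l = i + 1; l <= j; ++l) {
          double v = V.Vb(i, l);
          if (v >= BIG / 2) continue;
          double cand = v + M.f4 * (j - l);
          if (cand < best) best = cand;
        }
        V.vm1[V.at(i, j)] = best;
      }
      {
        double best = BIG;
        for (int h = i; h <= j - 1; ++h) {
          double b = V.Vm1(h, j);
          if (b >= BIG / 2) continue;
          double pre = M.f4 * (h - i);
          double vm = V.Vm(i, h - 1);
          if (vm < pre) pre = vm;
          double cand = pre + b + M.f5;
          if (cand < best) best = cand;
        }
        V.vm[V.at(i, j)] = best;
      }
    }
  }
  for (int j = 1; j <= N; ++j) {
    double best = V.we[j - 1];
    for (int h = 1; h <= j - 1; ++h) {
      double v = V.Vb(h, j);
      if (v >= BIG / 2) continue;
      double cand = V.we[h - 1] + v;
      if (cand < best) best = cand;
    }
    V.we[j] = best;
  }
}

static void traceVb(const std::vector<int>& s, const Model& M,
                    const MfeTab& V, int i, int j,
                    std::vector<std::pair<int, int> >& pairs);

static void traceVm1(const std::vector<int>& s, const Model& M,
                     const MfeTab& V, int i, int j,
                     std::vector<std::pair<int, int> >& pairs) {
  double v = V.Vm1(i, j);
  for (int l = i + 1; l <= j; ++l) {
    double b = V.Vb(i, l);
    if (b >= BIG / 2) continue;
    if (b + M.f4 * (j - l) == v) { traceVb(s, M, V, i, l, pairs); return; }
  }
  stop("MFE traceback failed in Vm1");
}

static void traceVm(const std::vector<int>& s, const Model& M,
                    const MfeTab& V, int i, int j,
                    std::vector<std::pair<int, int> >& pairs) {
  double v = V.Vm(i, j);
  for (int h = i; h <= j - 1; ++h) {
    double b = V.Vm1(h, j);
    if (b >= BIG / 2) continue;
    if (M.f4 * (h - i) + b + M.f5 == v) {
      traceVm1(s, M, V, h, j, pairs); return;
    }
    double vm = V.Vm(i, h - 1);
    if (vm < BIG / 2 && vm + b + M.f5 == v) {
      traceVm(s, M, V, i, h - 1, pairs);
      traceVm1(s, M, V, h, j, pairs);
      return;
    }
  }
  stop("MFE traceback failed in Vm");
}

static void traceVb(const std::vector<int>& s, const Model& M,
                    const MfeTab& V, int i, int j,
                    std::vector<std::pair<int, int> >& pairs) {
  pairs.push_back(std::make_pair(i, j));
  double v = V.Vb(i, j);
  if (v == M.eH[j - i - 1]) return;                       // hairpin first
  for (int h = i + 1; h <= j - 2; ++h)                    // then two-loop
    for (int l = h + 1; l <= j - 1; ++l) {
      double b = V.Vb(h, l);
      if (b >= BIG / 2) continue;
      if (b + e2loop(s, M, i, j, h, l) == v) {
        traceVb(s, M, V, h, l, pairs); return;
      }
    }
  for (int h = i + 2; h <= j - 2; ++h) {                  // then multiloop
    double a = V.Vm(i + 1, h - 1), b = V.Vm1(h, j - 1);
    if (a >= BIG / 2 || b >= BIG / 2) continue;
    if (a + b + M.f3 + M.f5 == v) {
      traceVm(s, M, V, i + 1, h - 1, pairs);
      traceVm1(s, M, V, h, j - 1, pairs);
      return;
    }
  }
  stop("MFE traceback failed in Vb");
}

// [[Rcpp::export]]
List cpp_mfe(IntegerVector seqv, List par) {
  int N = seqv.size();
  std::vector<int> s(N + 1);
  for (int i = 0; i < N; ++i) s[i + 1] = seqv[i];
  Model M = makeModel(par, N);
  MfeTab V(N);
  mfeFill(s, M, V);
  double e = V.we[N];
  std::vector<std::pair<int, int> > pairs;
  if (e < 0.0) {                 // trace exterior only if better than open
    int j = N;
    while (j >= 1) {
      if (V.we[j] == V.we[j - 1]) { --j; continue; }
      bool found = false;
      for (int h = 1; h <= j - 1; ++h) {
        double v = V.Vb(h, j);
        if (v >= BIG / 2) continue;
        if (V.we[h - 1] + v == V.we[j]) {
          traceVb(s, M, V, h, j, pairs);
          j = h - 1; found = true; break;
        }
      }
      if (!found) stop("MFE traceback failed in exterior");
    }
  } else {
    e = 0.0;
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t q = 0; q < pairs.size(); ++q) {
    pm(q, 0) = pairs[q].first; pm(q, 1) = pairs[q].second;
  }
  return List::create(_["pairs"] = pm, _["energy"] = e);
}
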