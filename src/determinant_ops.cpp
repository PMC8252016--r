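// Determinant-basis operator construction for the 1s/3p/3d model space.
// Determinants are 18-bit occupation masks; spin-orbital bit index is
// 2*(orbital-1) + spin with orbitals ordered s, p(-1,0,1), d(-2..2) and
// spin 0 = alpha, 1 = beta.

#include <Rcpp.h>
#include <unordered_map>
#include <complex>
#include <vector>

using namespace Rcpp;

static const int NSO = 18;

static inline int popcnt(unsigned int x) { return __builtin_popcount(x); }

// parity (+1/-1) of the number of occupied spin-orbitals below bit p
static inline int parityBelow(unsigned int mask, int p) {
  return (popcnt(mask & ((1u << p) - 1u)) & 1) ? -1 : 1;
}

static inline int ctz(unsigned int x) { return __builtin_ctz(x); }

// Build the dense many-body Hamiltonian by Slater-Condon rules.
// h1r/h1i: real/imag parts of the one-electron operator (18 x 18, Hermitian).
// eriA: antisymmetrized two-electron integrals <pq||rs> in physicist
// notation, flattened with 0-based index ((p*18+q)*18+r)*18+s.
// [[Rcpp::export]]
ComplexMatrix cpp_build_hamiltonian(IntegerVector masks,
                                    NumericMatrix h1r, NumericMatrix h1i,
                                    NumericVector eriA) {
  const int N = masks.size();
  ComplexMatrix H(N, N);
  const double *A = REAL(eriA);
  auto aidx = [](int p, int q, int r, int s) {
    return ((p * NSO + q) * NSO + r) * NSO + s;
  };

  std::vector<unsigned int> mk(N);
  for (int i = 0; i < N; ++i) mk[i] = (unsigned int)masks[i];

  for (int c = 0; c < N; ++c) {
    unsigned int mc = mk[c];
    for (int r = c; r < N; ++r) {
      unsigned int mr = mk[r];
      unsigned int x = mc ^ mr;
      int nd = popcnt(x);
      double vr = 0.0, vi = 0.0;
      if (nd == 0) {
        // diagonal
        unsigned int occ = mc;
        while (occ) {
          int p = ctz(occ); occ &= occ - 1u;
          vr += h1r(p, p); vi += h1i(p, p);
          unsigned int occ2 = mc & (((1u << p) - 1u));  // q < p once
          while (occ2) {
            int q = ctz(occ2); occ2 &= occ2 - 1u;
            vr += A[aidx(p, q, p, q)];
          }
        }
      } else if (nd == 2) {
        // single excitation i (in c) -> a (in r)
        unsigned int ann = mc & ~mr, cre = mr & ~mc;
        int i = ctz(ann), a = ctz(cre);
        int sgn = parityBelow(mc, i) * parityBelow(mc & ~(1u << i), a);
        double sr = h1r(a, i), si = h1i(a, i);
        unsigned int common = mc & mr;
        while (common) {
          int q = ctz(common); common &= common - 1u;
          sr += A[aidx(a, q, i, q)];
        }
        vr = sgn * sr; vi = sgn * si;
      } else if (nd == 4) {
        unsigned int ann = mc & ~mr, cre = mr & ~mc;
        if (popcnt(ann) == 2) {
          int i = ctz(ann); ann &= ann - 1u;
          int j = ctz(ann);
          int a = ctz(cre); cre &= cre - 1u;
          int b = ctz(cre);
          unsigned int m = mc;
          int sgn = parityBelow(m, i); m &= ~(1u << i);
          sgn *= parityBelow(m, j);   m &= ~(1u << j);
          sgn *= parityBelow(m, b);   m |= (1u << b);
          sgn *= parityBelow(m, a);
          vr = sgn * A[aidx(a, b, i, j)];
        }
      } else {
        continue;
      }
      H(r, c).r = vr; H(r, c).i = vi;
      if (r != c) { H(c, r).r = vr; H(c, r).i = -vi; }
    }
  }
  return H;
}

// Matrix <bra_i | c_b | ket_j> of a pure annihilation operator (used for the
// sudden-approximation ionization populations).
// [[Rcpp::export]]
NumericMatrix cpp_annihilate(IntegerVector masksBra, IntegerVector masksKet,
                             int b) {
  const int NB = masksBra.size(), NK = masksKet.size();
  NumericMatrix M(NB, NK);
  std::unordered_map<unsigned int, int> lookup;
  lookup.reserve(NB * 2);
  for (int i = 0; i < NB; ++i) lookup[(unsigned int)masksBra[i]] = i;
  for (int k = 0; k < NK; ++k) {
    unsigned int mk = (unsigned int)masksKet[k];
    if (!(mk & (1u << b))) continue;
    int sgn = parityBelow(mk, b);
    auto it = lookup.find(mk & ~(1u << b));
    if (it == lookup.end()) continue;
    M(it->second, k) = sgn;
  }
  return M;
}

// Many-body matrix of a one-body operator sum_t coef[t] * c^dag_{a[t]} c_{b[t]}
// between a ket basis and a (possibly different) bra basis. Indices a, b are
// 0-based spin-orbital bits; returns the real matrix <bra_i | O | ket_j>.
// [[Rcpp::export]]
NumericMatrix cpp_one_body(IntegerVector masksBra, IntegerVector masksKet,
                           IntegerVector aIdx, IntegerVector bIdx,
                           NumericVector coef) {
  const int NB = masksBra.size(), NK = masksKet.size(), NT = aIdx.size();
  NumericMatrix M(NB, NK);
  std::unordered_map<unsigned int, int> lookup;
  lookup.reserve(NB * 2);
  for (int i = 0; i < NB; ++i) lookup[(unsigned int)masksBra[i]] = i;

  for (int k = 0; k < NK; ++k) {
    unsigned int mk = (unsigned int)masksKet[k];
    for (int t = 0; t < NT; ++t) {
      int b = bIdx[t], a = aIdx[t];
      if (!(mk & (1u << b))) continue;
      unsigned int m1 = mk & ~(1u << b);
      if (m1 & (1u << a)) continue;
      int sgn = parityBelow(mk, b) * parityBelow(m1, a);
      unsigned int m2 = m1 | (1u << a);
      auto it = lookup.find(m2);
      if (it == lookup.end()) continue;
      M(it->second, k) += sgn * coef[t];
    }
  }
  return M;
}
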