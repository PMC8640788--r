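// Minimum-free-energy folding of a single DNA strand under a simplified
// nearest-neighbour model: stacking energies for Watson-Crick steps,
// length-dependent hairpin/bulge/interior-loop penalties, and an affine
// multibranch term. Nested structures only (no pseudoknots, no coaxial
// stacking, no dangles). Interior loops are capped at `maxloop` unpaired
// bases. Energies are handled as integer centi-kcal/mol so that the
// traceback reproduces the DP minimum exactly.
#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int INF = 100000000;

struct FoldParams {
  int n;
  const int *s;
  int stack[4][4];
  bool pair[5][5];
  int wobble_stack;
  std::vector<int> hairpin, bulge, interior; // 1-indexed by loop size
  int ml_a, ml_b, ml_c;
  int maxloop, min_hairpin;
};

static inline bool can_pair(const FoldParams &P, int a, int b) {
  return a < 4 && b < 4 && P.pair[a][b];
}

static inline bool is_wc(int a, int b) { return a + b == 3; }

// stack term for helix step from pair (i,j) to pair (i+1,j-1)
static inline int stackE(const FoldParams &P, int i, int j) {
  int a = P.s[i], b = P.s[i + 1], x = P.s[j], y = P.s[j - 1];
  if (is_wc(a, x) && is_wc(b, y)) return P.stack[a][b];
  return P.wobble_stack;
}

static inline int loop_pen(const std::vector<int> &tab, int L) {
  if (L < 1) return INF;
  if (L <= (int)tab.size()) return tab[L - 1];
  return tab.back();
}

class Fold {
public:
  const FoldParams &P;
  int n;
  std::vector<int> V, M;
  std::vector<int> W;

  Fold(const FoldParams &p) : P(p), n(p.n),
    V((size_t)p.n * p.n, INF), M((size_t)p.n * p.n, INF), W(p.n + 1, 0) {}

  int &v(int i, int j) { return V[(size_t)i * n + j]; }
  int &m(int i, int j) { return M[(size_t)i * n + j]; }

  int hairpinE(int i, int j) {
    int L = j - i - 1;
    if (L < P.min_hairpin) return INF;
    return loop_pen(P.hairpin, L);
  }

  int interiorE(int i, int j, int k, int l) {
    int l1 = k - i - 1, l2 = j - l - 1;
    if (l1 == 0 && l2 == 0) return stackE(P, i, j);
    if (l1 == 0 || l2 == 0) return loop_pen(P.bulge, l1 + l2);
    return loop_pen(P.interior, l1 + l2);
  }

  void fill() {
    for (int d = P.min_hairpin + 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        // V(i,j)
        if (can_pair(P, P.s[i], P.s[j])) {
          int best = hairpinE(i, j);
          int l1max = std::min(P.maxloop, j - i - 2);
          for (int l1 = 0; l1 <= l1max; ++l1) {
            int k = i + 1 + l1;
            int l2max = std::min(P.maxloop - l1, j - k - 2);
            for (int l2 = 0; l2 <= l2max; ++l2) {
              int l = j - 1 - l2;
              if (l <= k) break;
              if (!can_pair(P, P.s[k], P.s[l])) continue;
              int e = v(k, l);
              if (e >= INF) continue;
              e += interiorE(i, j, k, l);
              if (e < best) best = e;
            }
          }
          // multibranch closing
          for (int k = i + 2; k <= j - 2; ++k) {
            int e1 = m(i + 1, k), e2 = m(k + 1, j - 1);
            if (e1 >= INF || e2 >= INF) continue;
            int e = P.ml_a + P.ml_b + e1 + e2;
            if (e < best) best = e;
          }
          v(i, j) = best;
        }
        // M(i,j)
        int best = INF;
        if (d >= 1 && m(i + 1, j) < INF) best = std::min(best, m(i + 1, j) + P.ml_c);
        if (d >= 1 && m(i, j - 1) < INF) best = std::min(best, m(i, j - 1) + P.ml_c);
        if (v(i, j) < INF) best = std::min(best, v(i, j) + P.ml_b);
        for (int k = i; k < j; ++k) {
          if (m(i, k) >= INF || m(k + 1, j) >= INF) continue;
          best = std::min(best, m(i, k) + m(k + 1, j));
        }
        m(i, j) = best;
      }
    }
    // M base cases handled implicitly (INF for d <= min_hairpin spans)
    for (int j = 1; j <= n; ++j) {
      int best = W[j - 1];
      for (int i = 0; i < j; ++i) {
        if (v(i, j - 1) >= INF || W[i] >= INF) continue;
        int e = W[i] + v(i, j - 1);
        if (e < best) best = e;
      }
      W[j] = best;
    }
  }

  // ---- traceback (deterministic: first candidate in recurrence order) ----
  std::string structure;

  void traceV(int i, int j) {
    structure[i] = '(';
    structure[j] = ')';
    int target = v(i, j);
    if (target == hairpinE(i, j)) return;
    int l1max = std::min(P.maxloop, j - i - 2);
    for (int l1 = 0; l1 <= l1max; ++l1) {
      int k = i + 1 + l1;
      int l2max = std::min(P.maxloop - l1, j - k - 2);
      for (int l2 = 0; l2 <= l2max; ++l2) {
        int l = j - 1 - l2;
        if (l <= k) break;
        if (!can_pair(P, P.s[k], P.s[l])) continue;
        if (v(k, l) < INF && v(k, l) + interiorE(i, j, k, l) == target) {
          traceV(k, l);
          return;
        }
      }
    }
    for (int k = i + 2; k <= j - 2; ++k) {
      if (m(i + 1, k) < INF && m(k + 1, j - 1) < INF &&
          P.ml_a + P.ml_b + m(i + 1, k) + m(k + 1, j - 1) == target) {
        traceM(i + 1, k);
        traceM(k + 1, j - 1);
        return;
      }
    }
    Rcpp::stop("traceback failure in V"); // unreachable by construction
  }

  void traceM(int i, int j) {
    int target = m(i, j);
    while (true) {
      if (i < j && m(i + 1, j) < INF && m(i + 1, j) + P.ml_c == target) {
        ++i; target = m(i, j); continue;
      }
      if (i < j && m(i, j - 1) < INF && m(i, j - 1) + P.ml_c == target) {
        --j; target = m(i, j); continue;
      }
      break;
    }
    if (v(i, j) < INF && v(i, j) + P.ml_b == target) {
      traceV(i, j);
      return;
    }
    for (int k = i; k < j; ++k) {
      if (m(i, k) < INF && m(k + 1, j) < INF &&
          m(i, k) + m(k + 1, j) == target) {
        traceM(i, k);
        traceM(k + 1, j);
        return;
      }
    }
    Rcpp::stop("traceback failure in M");
  }

  void trace() {
    structure.assign(n, '.');
    int j = n;
    while (j > 0) {
      if (W[j] == W[j - 1]) { --j; continue; }
      bool found = false;
      for (int i = 0; i < j; ++i) {
        if (v(i, j - 1) < INF && W[i] + v(i, j - 1) == W[j]) {
          traceV(i, j - 1);
          j = i;
          found = true;
          break;
        }
      }
      if (!found) Rcpp::stop("traceback failure in W");
    }
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector s, NumericMatrix stack, LogicalMatrix pairmat,
                  double wobble_stack, NumericVector hairpin,
                  NumericVector bulge, NumericVector interior,
                  double ml_a, double ml_b, double ml_c,
                  int maxloop, int min_hairpin) {
  FoldParams P;
  P.n = s.size();
  std::vector<int> sv(s.begin(), s.end());
  P.s = sv.data();
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      P.stack[a][b] = (int)std::lround(stack(a, b) * 100.0);
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b)
      P.pair[a][b] = (a < 4 && b < 4) ? (bool)pairmat(a, b) : false;
  P.wobble_stack = (int)std::lround(wobble_stack * 100.0);
  auto cvt = [](NumericVector x) {
    std::vector<int> out(x.size());
    for (int i = 0; i < x.size(); ++i)
      out[i] = (int)std::lround(x[i] * 100.0);
    return out;
  };
  P.hairpin = cvt(hairpin);
  P.bulge = cvt(bulge);
  P.interior = cvt(interior);
  P.ml_a = (int)std::lround(ml_a * 100.0);
  P.ml_b = (int)std::lround(ml_b * 100.0);
  P.ml_c = (int)std::lround(ml_c * 100.0);
  P.maxloop = maxloop;
  P.min_hairpin = min_hairpin;

  if (P.n == 0)
    return List::create(_["delta_g"] = 0.0, _["structure"] = "");
  Fold F(P);
  F.fill();
  F.trace();
  double dg = F.W[P.n] / 100.0;
  if (dg > 0) dg = 0;
  return List::create(_["delta_g"] = dg,
                      _["structure"] = F.structure);
}
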