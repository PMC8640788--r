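// Exhaustive maximal-motif scanners for inverted repeats, mirror repeats,
// and tandem periodicities. Sequences arrive as integer codes
// A=0, C=1, G=2, T=3, N=4; N never pairs and never matches.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline bool wc_pair(int a, int b) {
  return a < 4 && b < 4 && a + b == 3; // A-T (0,3) and C-G (1,2)
}

// purine {A,G} = even codes, pyrimidine {C,T} = odd codes
static inline int base_class(int b) { return (b < 4) ? (b & 1) : -1; }

// [[Rcpp::export(name = ".find_ir_cpp")]]
DataFrame find_ir_cpp(IntegerVector s, int min_arm, int smin, int smax) {
  const int n = s.size();
  std::vector<int> vstart, vend, varm, vsp;
  for (int g = 0; g <= n; ++g) {
    for (int sp = smin; sp <= smax; ++sp) {
      if (g + sp > n) break;
      // inward-extendable hits are not maximal
      if (sp >= 2 && wc_pair(s[g], s[g + sp - 1])) continue;
      int a = 0;
      while (g - a - 1 >= 0 && g + sp + a < n &&
             wc_pair(s[g - a - 1], s[g + sp + a])) ++a;
      if (a >= min_arm) {
        vstart.push_back(g - a);
        vend.push_back(g + sp + a);
        varm.push_back(a);
        vsp.push_back(sp);
      }
    }
  }
  return DataFrame::create(_["start"] = vstart, _["end"] = vend,
                           _["arm_len"] = varm, _["spacer_len"] = vsp);
}

// Maximal mirror repeats with homopurine or homopyrimidine arms; the spacer
// is unconstrained in composition. Containment collapse happens in R.
// [[Rcpp::export(name = ".find_mirror_cpp")]]
DataFrame find_mirror_cpp(IntegerVector s, int min_arm, int smin, int smax,
                          int min_tract) {
  const int n = s.size();
  std::vector<int> vstart, vend, varm, vsp, vcls;
  for (int g = 0; g <= n; ++g) {
    for (int sp = smin; sp <= smax; ++sp) {
      if (g + sp > n) break;
      int a = 0, cls = -1;
      while (true) {
        int l = g - a - 1, r = g + sp + a;
        if (l < 0 || r >= n) break;
        if (s[l] != s[r] || s[l] >= 4) break;
        int c = base_class(s[l]);
        if (cls == -1) cls = c;
        else if (c != cls) break;
        ++a;
      }
      if (a < min_arm || 2 * a + sp < min_tract) continue;
      // inward extension through the spacer ends makes this non-maximal
      if (sp >= 2 && s[g] == s[g + sp - 1] && s[g] < 4 &&
          base_class(s[g]) == cls) continue;
      vstart.push_back(g - a);
      vend.push_back(g + sp + a);
      varm.push_back(a);
      vsp.push_back(sp);
      vcls.push_back(cls);
    }
  }
  return DataFrame::create(_["start"] = vstart, _["end"] = vend,
                           _["arm_len"] = varm, _["spacer_len"] = vsp,
                           _["arm_class"] = vcls);
}

// All maximal runs of period p for p in 1..max_period: a run is a maximal
// stretch where s[i] == s[i - p] (N never matches). Reported when the run
// region spans at least two full units.
// [[Rcpp::export(name = ".find_tandem_cpp")]]
DataFrame find_tandem_cpp(IntegerVector s, int max_period) {
  const int n = s.size();
  std::vector<int> vstart, vend, vper;
  for (int p = 1; p <= max_period && p * 2 <= n; ++p) {
    int run = 0; // number of consecutive matches ending at i - 1
    for (int i = p; i <= n; ++i) {
      bool m = (i < n) && s[i] < 4 && s[i] == s[i - p];
      if (m) {
        ++run;
      } else {
        if (run > 0) {
          int start = i - run - p, len = run + p;
          if (len >= 2 * p) {
            vstart.push_back(start);
            vend.push_back(start + len);
            vper.push_back(p);
          }
        }
        run = 0;
      }
    }
  }
  return DataFrame::create(_["start"] = vstart, _["end"] = vend,
                           _["period"] = vper);
}
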