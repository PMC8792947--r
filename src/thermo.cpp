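// Reduced nearest-neighbor RNA thermodynamics:
//  - intermolecular duplex minimum free energy (stacks + linear bulge/internal
//    penalties, no intramolecular pairs, no branching), RNAhybrid-style;
//  - Zuker-style MFE folding with hard unpaired constraints (stacks +
//    linear hairpin/internal/bulge penalties + affine multiloops; no dangles,
//    no coaxial stacking, no lone-pair prohibition).
// Bases are encoded A=0, C=1, G=2, U=3. Pair indices follow the order
// AU, UA, CG, GC, GU, UG used by the stack table shipped from R.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e18;
static const double EPS = 1e-7;

static inline int pair_idx(int a, int b) {
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 3 && b == 0) return 1;  // UA
  if (a == 1 && b == 2) return 2;  // CG
  if (a == 2 && b == 1) return 3;  // GC
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

struct Params {
  double stack[6][6];
  double hairpin_base, hairpin_per_nt;
  double internal_base, internal_per_nt;
  double bulge_base, bulge_per_nt;
  double ml_a, ml_b, ml_c;
  int min_hairpin, max_internal;
};

static Params read_params(const List& par) {
  Params p;
  NumericMatrix st = par["stack"];
  if (st.nrow() != 6 || st.ncol() != 6) stop("stack table must be 6x6");
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) p.stack[i][j] = st(i, j);
  p.hairpin_base   = as<double>(par["hairpin_base"]);
  p.hairpin_per_nt = as<double>(par["hairpin_per_nt"]);
  p.internal_base   = as<double>(par["internal_base"]);
  p.internal_per_nt = as<double>(par["internal_per_nt"]);
  p.bulge_base   = as<double>(par["bulge_base"]);
  p.bulge_per_nt = as<double>(par["bulge_per_nt"]);
  p.ml_a = as<double>(par["multiloop_a"]);
  p.ml_b = as<double>(par["multiloop_b"]);
  p.ml_c = as<double>(par["multiloop_c"]);
  p.min_hairpin  = as<int>(par["min_hairpin"]);
  p.max_internal = as<int>(par["max_internal"]);
  return p;
}

// Energy of the two-loop (stack / bulge / internal) closed by outer pair and
// inner pair with g1, g2 unpaired nucleotides on the two sides.
static inline double two_loop_e(const Params& p, int po, int pi, int g1, int g2) {
  if (g1 == 0 && g2 == 0) return p.stack[po][pi];
  if (g1 > 0 && g2 > 0) return p.internal_base + p.internal_per_nt * (g1 + g2);
  return p.bulge_base + p.bulge_per_nt * (g1 + g2);
}

// ---------------------------------------------------------------- duplex ---

// [[Rcpp::export(name = ".rcpp_duplex")]]
List rcpp_duplex(IntegerVector mir, IntegerVector tgt, List par) {
  Params p = read_params(par);
  int m = mir.size(), n = tgt.size();
  // E(i,j): best energy of an antiparallel chain of pairs ending with
  // miRNA i paired to target j (miRNA index ascending, target descending).
  std::vector<double> E((size_t)m * n, INF);
  std::vector<int> bt((size_t)m * n, -1);  // predecessor, encoded i2 * n + j2
  double best = INF;
  int best_ij = -1;
  for (int i = 0; i < m; ++i) {
    for (int j = n - 1; j >= 0; --j) {
      int pij = pair_idx(mir[i], tgt[j]);
      if (pij < 0) continue;
      double e = 0.0;  // chain starting at this pair
      int arg = -1;
      for (int i2 = 0; i2 < i; ++i2) {
        for (int j2 = n - 1; j2 > j; --j2) {
          size_t k2 = (size_t)i2 * n + j2;
          if (E[k2] >= INF / 2) continue;
          int p2 = pair_idx(mir[i2], tgt[j2]);
          double cand = E[k2] + two_loop_e(p, p2, pij, i - i2 - 1, j2 - j - 1);
          if (cand < e) { e = cand; arg = (int)k2; }
        }
      }
      size_t k = (size_t)i * n + j;
      E[k] = e;
      bt[k] = arg;
      if (e < best) { best = e; best_ij = (int)k; }
    }
  }
  if (best_ij < 0)
    return List::create(_["dg"] = R_PosInf,
                        _["pairing"] = IntegerMatrix(0, 2));
  // traceback
  std::vector<std::pair<int, int>> chain;
  for (int k = best_ij; k >= 0; k = bt[k])
    chain.push_back(std::make_pair(k / n, k % n));
  IntegerMatrix pm(chain.size(), 2);
  for (size_t q = 0; q < chain.size(); ++q) {
    pm(q, 0) = chain[chain.size() - 1 - q].first;
    pm(q, 1) = chain[chain.size() - 1 - q].second;
  }
  return List::create(_["dg"] = best, _["pairing"] = pm);
}

// ------------------------------------------------------------------ fold ---

// [[Rcpp::export(name = ".rcpp_fold")]]
List rcpp_fold(IntegerVector seq, IntegerVector forced_unpaired, List par) {
  Params p = read_params(par);
  int n = seq.size();
  std::vector<bool> fu(n, false);
  for (int k = 0; k < forced_unpaired.size(); ++k) {
    int idx = forced_unpaired[k];
    if (idx < 0 || idx >= n) stop("forced-unpaired index out of range");
    fu[idx] = true;
  }
  auto at = [n](int i, int j) { return (size_t)i * n + j; };
  std::vector<double> V((size_t)n * n, INF), M((size_t)n * n, INF);

  for (int span = p.min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // V(i,j): MFE given i pairs j
      double v = INF;
      if (!fu[i] && !fu[j]) {
        int pij = pair_idx(seq[i], seq[j]);
        if (pij >= 0) {
          v = p.hairpin_base + p.hairpin_per_nt * (j - i - 1);
          // stack / bulge / internal via inner pair (k,l)
          for (int k = i + 1; k <= j - 1 - p.min_hairpin - 1; ++k) {
            int g1 = k - i - 1;
            if (g1 > p.max_internal) break;
            for (int l = j - 1; l > k + p.min_hairpin; --l) {
              int g2 = j - l - 1;
              if (g1 + g2 > p.max_internal) break;
              size_t kl = at(k, l);
              if (V[kl] >= INF / 2) continue;
              double cand = V[kl] + two_loop_e(p, pij, pair_idx(seq[k], seq[l]), g1, g2);
              if (cand < v) v = cand;
            }
          }
          // multiloop: closing pair + >=2 enclosed branches
          for (int h = i + 1; h < j - 1; ++h) {
            double a = M[at(i + 1, h)], b = M[at(h + 1, j - 1)];
            if (a >= INF / 2 || b >= INF / 2) continue;
            double cand = p.ml_a + p.ml_b + a + b;
            if (cand < v) v = cand;
          }
        }
      }
      V[at(i, j)] = v;

      // M(i,j): >=1 branch in [i,j], multiloop-interior costs
      double mm = INF;
      if (M[at(i, j - 1)] < INF / 2) mm = M[at(i, j - 1)] + p.ml_c;
      for (int k = i; k <= j - 1 - p.min_hairpin; ++k) {
        size_t kj = at(k, j);
        if (V[kj] >= INF / 2) continue;
        double vb = V[kj] + p.ml_b;
        double cand = vb + p.ml_c * (k - i);          // unpaired prefix
        if (cand < mm) mm = cand;
        if (k > i && M[at(i, k - 1)] < INF / 2) {      // >=1 branch before k
          cand = M[at(i, k - 1)] + vb;
          if (cand < mm) mm = cand;
        }
      }
      M[at(i, j)] = mm;
    }
    // seed M for spans shorter than pairable is implicit INF
  }
  // short spans of M (j - i <= min_hairpin): no branch fits -> INF (already)

  // external loop
  std::vector<double> W(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    double w = W[j - 1];
    for (int i = 0; i < j; ++i) {
      if (V[at(i, j - 1)] >= INF / 2) continue;
      double cand = W[i] + V[at(i, j - 1)];
      if (cand < w) w = cand;
    }
    W[j] = w;
  }
  double energy = W[n];

  // ---- traceback to dot-bracket ----
  std::string db(n, '.');
  struct Task { int type; int i; int j; };  // 0 = W[0..j), 1 = V(i,j), 2 = M(i,j)
  std::vector<Task> st;
  st.push_back({0, 0, n});
  while (!st.empty()) {
    Task t = st.back();
    st.pop_back();
    if (t.type == 0) {
      int j = t.j;
      while (j > 0) {
        if (std::fabs(W[j] - W[j - 1]) < EPS) { --j; continue; }  // unpaired wins ties
        bool found = false;
        for (int i = 0; i < j && !found; ++i) {
          if (V[at(i, j - 1)] < INF / 2 &&
              std::fabs(W[i] + V[at(i, j - 1)] - W[j]) < EPS) {
            st.push_back({1, i, j - 1});
            j = i;
            found = true;
          }
        }
        if (!found) --j;  // numerical fallback: leave unpaired
      }
    } else if (t.type == 1) {
      int i = t.i, j = t.j;
      db[i] = '(';
      db[j] = ')';
      double v = V[at(i, j)];
      int pij = pair_idx(seq[i], seq[j]);
      if (std::fabs(v - (p.hairpin_base + p.hairpin_per_nt * (j - i - 1))) < EPS)
        continue;
      bool found = false;
      for (int k = i + 1; k <= j - 1 - p.min_hairpin - 1 && !found; ++k) {
        int g1 = k - i - 1;
        if (g1 > p.max_internal) break;
        for (int l = j - 1; l > k + p.min_hairpin; --l) {
          int g2 = j - l - 1;
          if (g1 + g2 > p.max_internal) break;
          if (V[at(k, l)] >= INF / 2) continue;
          if (std::fabs(V[at(k, l)] +
                        two_loop_e(p, pij, pair_idx(seq[k], seq[l]), g1, g2) - v) < EPS) {
            st.push_back({1, k, l});
            found = true;
            break;
          }
        }
      }
      if (found) continue;
      for (int h = i + 1; h < j - 1 && !found; ++h) {
        double a = M[at(i + 1, h)], b = M[at(h + 1, j - 1)];
        if (a >= INF / 2 || b >= INF / 2) continue;
        if (std::fabs(p.ml_a + p.ml_b + a + b - v) < EPS) {
          st.push_back({2, i + 1, h});
          st.push_back({2, h + 1, j - 1});
          found = true;
        }
      }
      if (!found) warning("fold traceback: unresolved V cell");
    } else {
      int i = t.i, j = t.j;
      double mm = M[at(i, j)];
      if (M[at(i, j - 1)] < INF / 2 && std::fabs(M[at(i, j - 1)] + p.ml_c - mm) < EPS) {
        st.push_back({2, i, j - 1});
        continue;
      }
      bool found = false;
      for (int k = i; k <= j - 1 - p.min_hairpin && !found; ++k) {
        if (V[at(k, j)] >= INF / 2) continue;
        double vb = V[at(k, j)] + p.ml_b;
        if (std::fabs(vb + p.ml_c * (k - i) - mm) < EPS) {
          st.push_back({1, k, j});
          found = true;
        } else if (k > i && M[at(i, k - 1)] < INF / 2 &&
                   std::fabs(M[at(i, k - 1)] + vb - mm) < EPS) {
          st.push_back({2, i, k - 1});
          st.push_back({1, k, j});
          found = true;
        }
      }
      if (!found) warning("fold traceback: unresolved M cell");
    }
  }

  return List::create(_["energy"] = energy, _["structure"] = db);
}
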