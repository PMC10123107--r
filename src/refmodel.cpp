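// Reference thermodynamic model: a deliberately small nested-structure
// energy model (stacking terms by pair class plus constant loop
// penalties) with exact integer centi-kcal energies, so that folding,
// suboptimal enumeration and partition-function quantities are
// reproducible to the bit and verifiable against exhaustive
// enumeration at small n.  This is not the nearest-neighbor model.
//
// Base coding: 1=A, 2=C, 3=G, 4=U.
// Pair types: 0 = not pairable, 1=AU, 2=UA, 3=GC, 4=CG, 5=GU, 6=UG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const int INF_E = INT32_MAX / 4;

static inline int pair_type(int a, int b) {
  if (a == 1 && b == 4) return 1;
  if (a == 4 && b == 1) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}

struct RefParams {
  int stack[7][7]; // [outer type][inner type], centi-kcal
  int hairpin, bulge, internal, multi;
  int min_hp;
  double rt; // kcal/mol
};

static RefParams parse_params(const List& par) {
  RefParams p;
  IntegerMatrix st = par["stack"];
  if (st.nrow() != 6 || st.ncol() != 6) stop("stack table must be 6x6");
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b) p.stack[a][b] = st(a - 1, b - 1);
  p.hairpin = as<int>(par["hairpin"]);
  p.bulge = as<int>(par["bulge"]);
  p.internal = as<int>(par["internal"]);
  p.multi = as<int>(par["multiloop"]);
  p.min_hp = as<int>(par["min_hairpin"]);
  p.rt = as<double>(par["rt"]);
  return p;
}

// Two-loop penalty for outer pair (i,j) enclosing inner pair (k,l),
// i < k < l < j.  Adjacent pairs stack; otherwise bulge (one side
// empty) or internal loop (both sides non-empty).
static inline int two_loop(const RefParams& p, int pt_out, int pt_in,
                           int i, int j, int k, int l) {
  if (k == i + 1 && l == j - 1) return p.stack[pt_out][pt_in];
  if (k == i + 1 || l == j - 1) return p.bulge;
  return p.internal;
}

struct DP {
  int n;
  std::vector<int> V, Mb, M2; // n*n, index i*n+j
  std::vector<int> W;         // external prefix, size n+1 (W[0] = empty)
  std::vector<int> pt;        // pair type per (i,j)
};

// Fill MFE matrices.  V(i,j): [i..j] with (i,j) paired.  Mb: >=1
// multiloop branch in [i..j], unpaired positions free.  M2: >=2
// branches.  W[j+1]: external minimum over [0..j].
static void fill_dp(const std::vector<int>& s, const RefParams& p, DP& d) {
  int n = (int)s.size();
  d.n = n;
  d.V.assign((size_t)n * n, INF_E);
  d.Mb.assign((size_t)n * n, INF_E);
  d.M2.assign((size_t)n * n, INF_E);
  d.pt.assign((size_t)n * n, 0);
  d.W.assign(n + 1, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) d.pt[(size_t)i * n + j] = pair_type(s[i], s[j]);

  for (int len = p.min_hp + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      size_t ij = (size_t)i * n + j;
      // --- V ---
      if (d.pt[ij] != 0) {
        int best = p.hairpin; // hairpin always available at this length
        for (int k = i + 1; k < j; ++k) {
          for (int l = k + p.min_hp + 1; l < j; ++l) {
            int v = d.V[(size_t)k * n + l];
            if (v >= INF_E) continue;
            int e = two_loop(p, d.pt[ij], d.pt[(size_t)k * n + l], i, j, k, l) + v;
            if (e < best) best = e;
          }
        }
        if (j - i - 1 >= 2) { // room for >=2 branches is checked by M2 itself
          int m2 = d.M2[(size_t)(i + 1) * n + (j - 1)];
          if (m2 < INF_E && p.multi + m2 < best) best = p.multi + m2;
        }
        d.V[ij] = best;
      }
      // --- Mb / M2 (computed for every interval length >= 1) ---
    }
    // second pass so that V of this length is available to Mb/M2
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      size_t ij = (size_t)i * n + j;
      int mb = (j - 1 >= i) ? d.Mb[(size_t)i * n + (j - 1)] : INF_E;
      int m2 = (j - 1 >= i) ? d.M2[(size_t)i * n + (j - 1)] : INF_E;
      for (int k = i; k <= j - p.min_hp - 1; ++k) {
        int v = d.V[(size_t)k * n + j];
        if (v >= INF_E) continue;
        if (v < mb) mb = v; // rightmost branch, left side all unpaired
        if (k - 1 >= i) {
          int lm = d.Mb[(size_t)i * n + (k - 1)];
          if (lm < INF_E) {
            if (lm + v < mb) mb = lm + v;
            if (lm + v < m2) m2 = lm + v;
          }
        }
      }
      d.Mb[ij] = mb;
      d.M2[ij] = m2;
    }
  }
  // shorter intervals: Mb/M2 stay INF (no branch fits), V stays INF
  for (int j = 0; j < n; ++j) {
    int best = d.W[j]; // j unpaired
    for (int k = 0; k <= j - p.min_hp - 1; ++k) {
      int v = d.V[(size_t)k * n + j];
      if (v >= INF_E) continue;
      int e = d.W[k] + v;
      if (e < best) best = e;
    }
    d.W[j + 1] = best;
  }
}

static std::vector<int> seq_from_R(const IntegerVector& seq) {
  std::vector<int> s(seq.size());
  for (int i = 0; i < seq.size(); ++i) {
    s[i] = seq[i];
    if (s[i] < 1 || s[i] > 4) stop("sequence codes must be in 1..4");
  }
  return s;
}

// [[Rcpp::export(name = ".rf_mfe")]]
int rf_mfe(IntegerVector seq, List params) {
  RefParams p = parse_params(params);
  std::vector<int> s = seq_from_R(seq);
  DP d;
  fill_dp(s, p, d);
  return d.W[s.size()];
}

// ---------------------------------------------------------------------------
// Energy of a given structure (1-based pair map, pm[i] == i if unpaired).

// [[Rcpp::export(name = ".rf_energy")]]
int rf_energy(IntegerVector seq, IntegerVector pairmap, List params) {
  RefParams p = parse_params(params);
  std::vector<int> s = seq_from_R(seq);
  int n = (int)s.size();
  if (pairmap.size() != n) stop("sequence/structure length mismatch");
  std::vector<int> pm(n);
  for (int i = 0; i < n; ++i) pm[i] = pairmap[i] - 1; // 0-based
  int e = 0;
  for (int i = 0; i < n; ++i) {
    int j = pm[i];
    if (j <= i) continue; // unpaired or closing index handled at opener
    if (pair_type(s[i], s[j]) == 0)
      stop("non-canonical pair at positions %d and %d", i + 1, j + 1);
    if (j - i - 1 < p.min_hp)
      stop("hairpin below minimum size at pair (%d, %d)", i + 1, j + 1);
    // identify the loop closed by (i,j)
    int branches = 0, first_k = -1, first_l = -1;
    int k = i + 1;
    while (k < j) {
      if (pm[k] > k) {
        if (branches == 0) { first_k = k; first_l = pm[k]; }
        ++branches;
        k = pm[k] + 1;
      } else {
        ++k;
      }
    }
    if (branches == 0) {
      e += p.hairpin;
    } else if (branches == 1) {
      e += two_loop(p, pair_type(s[i], s[j]), pair_type(s[first_k], s[first_l]),
                    i, j, first_k, first_l);
    } else {
      e += p.multi;
    }
  }
  return e;
}

// ---------------------------------------------------------------------------
// Wuchty-style complete suboptimal enumeration: all structures with
// energy <= MFE + delta, generated by threshold-pruned traceback over
// the exact DP matrices (unambiguous decomposition, no duplicates).

struct Item { int i, j, kind; }; // kind: 0 ext [0..j], 1 V, 2 Mb, 3 M2

struct SubState {
  std::vector<std::pair<int,int>> pairs;
  std::vector<Item> todo;
  int e;
};

// [[Rcpp::export(name = ".rf_subopt")]]
List rf_subopt(IntegerVector seq, List params, int delta, int max_structures) {
  RefParams p = parse_params(params);
  std::vector<int> s = seq_from_R(seq);
  int n = (int)s.size();
  DP d;
  fill_dp(s, p, d);
  int thresh = d.W[n] + delta;

  std::vector<SubState> stack;
  std::vector<IntegerVector> out_maps;
  std::vector<int> out_energies;
  bool complete = true;

  SubState init;
  init.e = d.W[n];
  if (n > 0) init.todo.push_back({0, n - 1, 0});
  stack.push_back(init);

  auto Vb = [&](int i, int j) { return d.V[(size_t)i * n + j]; };
  auto Mbb = [&](int i, int j) { return (i <= j) ? d.Mb[(size_t)i * n + j] : INF_E; };
  auto M2b = [&](int i, int j) { return (i <= j) ? d.M2[(size_t)i * n + j] : INF_E; };

  while (!stack.empty()) {
    SubState st = std::move(stack.back());
    stack.pop_back();
    // drop degenerate external items
    while (!st.todo.empty() && st.todo.back().kind == 0 && st.todo.back().j < 0)
      st.todo.pop_back();
    if (st.todo.empty()) {
      if ((int)out_maps.size() >= max_structures) { complete = false; break; }
      IntegerVector pm(n);
      for (int i = 0; i < n; ++i) pm[i] = i + 1;
      for (auto& pr : st.pairs) { pm[pr.first] = pr.second + 1; pm[pr.second] = pr.first + 1; }
      out_maps.push_back(pm);
      out_energies.push_back(st.e);
      continue;
    }
    Item it = st.todo.back();
    st.todo.pop_back();
    int i = it.i, j = it.j;
    auto push_child = [&](int new_e, std::initializer_list<Item> items,
                          int pi = -1, int pj = -1) {
      if (new_e > thresh) return;
      SubState ch;
      ch.pairs = st.pairs;
      if (pi >= 0) ch.pairs.push_back({pi, pj});
      ch.todo = st.todo;
      for (auto& x : items) ch.todo.push_back(x);
      ch.e = new_e;
      stack.push_back(std::move(ch));
    };
    if (it.kind == 0) { // external [0..j]
      int base = st.e - d.W[j + 1];
      push_child(base + d.W[j], {Item{0, j - 1, 0}});
      for (int k = 0; k <= j - p.min_hp - 1; ++k) {
        int v = Vb(k, j);
        if (v >= INF_E) continue;
        push_child(base + d.W[k] + v, {Item{0, k - 1, 0}, Item{k, j, 1}});
      }
    } else if (it.kind == 1) { // V(i,j), emits pair (i,j)
      int base = st.e - Vb(i, j);
      push_child(base + p.hairpin, {}, i, j);
      size_t ij = (size_t)i * n + j;
      for (int k = i + 1; k < j; ++k) {
        for (int l = k + p.min_hp + 1; l < j; ++l) {
          int v = Vb(k, l);
          if (v >= INF_E) continue;
          int pen = two_loop(p, d.pt[ij], d.pt[(size_t)k * n + l], i, j, k, l);
          push_child(base + pen + v, {Item{k, l, 1}}, i, j);
        }
      }
      int m2 = M2b(i + 1, j - 1);
      if (m2 < INF_E)
        push_child(base + p.multi + m2, {Item{i + 1, j - 1, 3}}, i, j);
    } else if (it.kind == 2) { // Mb(i,j)
      int base = st.e - Mbb(i, j);
      if (j - 1 >= i && Mbb(i, j - 1) < INF_E)
        push_child(base + Mbb(i, j - 1), {Item{i, j - 1, 2}});
      for (int k = i; k <= j - p.min_hp - 1; ++k) {
        int v = Vb(k, j);
        if (v >= INF_E) continue;
        push_child(base + v, {Item{k, j, 1}});
        if (k - 1 >= i && Mbb(i, k - 1) < INF_E)
          push_child(base + Mbb(i, k - 1) + v, {Item{i, k - 1, 2}, Item{k, j, 1}});
      }
    } else { // M2(i,j)
      int base = st.e - M2b(i, j);
      if (j - 1 >= i && M2b(i, j - 1) < INF_E)
        push_child(base + M2b(i, j - 1), {Item{i, j - 1, 3}});
      for (int k = i; k <= j - p.min_hp - 1; ++k) {
        int v = Vb(k, j);
        if (v >= INF_E) continue;
        if (k - 1 >= i && Mbb(i, k - 1) < INF_E)
          push_child(base + Mbb(i, k - 1) + v, {Item{i, k - 1, 2}, Item{k, j, 1}});
      }
    }
  }
  return List::create(_["pair_maps"] = wrap(out_maps),
                      _["energies"] = wrap(out_energies),
                      _["mfe"] = d.W[n],
                      _["complete"] = complete);
}

// ---------------------------------------------------------------------------
// Partition function (inside) and base-pair probabilities (outside),
// mirroring the MFE decomposition exactly.

struct PF {
  int n;
  std::vector<double> Qb, QMb, QM2; // n*n
  std::vector<double> Qpre;         // size n+1, external [0..j-1]
  std::vector<double> Qsuf;         // size n+1, external [i..n-1]
};

static void fill_pf(const std::vector<int>& s, const RefParams& p, PF& q) {
  int n = (int)s.size();
  q.n = n;
  double beta = 1.0 / (100.0 * p.rt); // energies are centi-kcal
  auto w = [&](int e) { return std::exp(-beta * e); };
  q.Qb.assign((size_t)n * n, 0.0);
  q.QMb.assign((size_t)n * n, 0.0);
  q.QM2.assign((size_t)n * n, 0.0);
  std::vector<int> pt((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) pt[(size_t)i * n + j] = pair_type(s[i], s[j]);

  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      size_t ij = (size_t)i * n + j;
      if (len >= p.min_hp + 2 && pt[ij] != 0) {
        double z = w(p.hairpin);
        for (int k = i + 1; k < j; ++k)
          for (int l = k + p.min_hp + 1; l < j; ++l) {
            double zb = q.Qb[(size_t)k * n + l];
            if (zb == 0.0) continue;
            z += w(two_loop(p, pt[ij], pt[(size_t)k * n + l], i, j, k, l)) * zb;
          }
        if (j - i - 1 >= 2)
          z += w(p.multi) * q.QM2[(size_t)(i + 1) * n + (j - 1)];
        q.Qb[ij] = z;
      }
      // QMb/QM2 use Qb of this length only for k == i (same cell computed above)
      double mb = (j - 1 >= i) ? q.QMb[(size_t)i * n + (j - 1)] : 0.0;
      double m2 = (j - 1 >= i) ? q.QM2[(size_t)i * n + (j - 1)] : 0.0;
      for (int k = i; k <= j - p.min_hp - 1; ++k) {
        double zb = q.Qb[(size_t)k * n + j];
        if (zb == 0.0) continue;
        mb += zb; // left side all unpaired
        if (k - 1 >= i) {
          double lm = q.QMb[(size_t)i * n + (k - 1)];
          mb += lm * zb;
          m2 += lm * zb;
        }
      }
      q.QMb[ij] = mb;
      q.QM2[ij] = m2;
    }
  }
  q.Qpre.assign(n + 1, 1.0);
  for (int j = 0; j < n; ++j) {
    double z = q.Qpre[j]; // j unpaired
    for (int k = 0; k <= j - p.min_hp - 1; ++k) {
      double zb = q.Qb[(size_t)k * n + j];
      if (zb != 0.0) z += q.Qpre[k] * zb;
    }
    q.Qpre[j + 1] = z;
  }
  q.Qsuf.assign(n + 1, 1.0);
  for (int i = n - 1; i >= 0; --i) {
    double z = q.Qsuf[i + 1]; // i unpaired
    for (int l = i + p.min_hp + 1; l < n; ++l) {
      double zb = q.Qb[(size_t)i * n + l];
      if (zb != 0.0) z += zb * q.Qsuf[l + 1];
    }
    q.Qsuf[i] = z;
  }
}

// [[Rcpp::export(name = ".rf_pf")]]
List rf_pf(IntegerVector seq, List params, bool want_bpp) {
  RefParams p = parse_params(params);
  std::vector<int> s = seq_from_R(seq);
  int n = (int)s.size();
  PF q;
  fill_pf(s, p, q);
  double Z = q.Qpre[n];
  double beta = 1.0 / (100.0 * p.rt);
  auto w = [&](int e) { return std::exp(-beta * e); };
  NumericMatrix bpp(0, 0);
  if (want_bpp && n > 0) {
    std::vector<int> pt((size_t)n * n, 0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) pt[(size_t)i * n + j] = pair_type(s[i], s[j]);
    // outside values, by decreasing span
    std::vector<double> Ob((size_t)n * n, 0.0);
    auto Q0 = [&](int a, int b) { // empty-or-branches, unpaired free
      if (a > b) return 1.0;
      return 1.0 + q.QMb[(size_t)a * n + b];
    };
    for (int len = n; len >= p.min_hp + 2; --len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        size_t ij = (size_t)i * n + j;
        if (q.Qb[ij] == 0.0) continue;
        double o = q.Qpre[i] * q.Qsuf[j + 1]; // exterior context
        for (int k = 0; k < i; ++k) {
          for (int l = j + 1; l < n; ++l) {
            size_t kl = (size_t)k * n + l;
            if (pt[kl] == 0) continue;
            double ob = Ob[kl];
            if (ob == 0.0) continue;
            o += ob * w(two_loop(p, pt[kl], pt[ij], k, l, i, j));
            double extra = Q0(k + 1, i - 1) * Q0(j + 1, l - 1) - 1.0;
            if (extra > 0.0) o += ob * w(p.multi) * extra;
          }
        }
        Ob[ij] = o;
      }
    }
    bpp = NumericMatrix(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        size_t ij = (size_t)i * n + j;
        if (q.Qb[ij] == 0.0) continue;
        double pr = q.Qb[ij] * Ob[ij] / Z;
        bpp(i, j) = pr;
        bpp(j, i) = pr;
      }
  }
  return List::create(_["log_z"] = std::log(Z), _["bpp"] = bpp);
}
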