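// RNA thermodynamics dynamic programs: MFE folding over a stacking energy
// model, McCaskill-style inside/outside partition function with base-pair
// probabilities, and intermolecular duplex alignment.
//
// Sequence encoding: A=0, C=1, G=2, U=3.
// Pair types: 0 = unpairable, 1=AU, 2=UA, 3=GC, 4=CG, 5=GU, 6=UG.
// The stacking table is indexed [outer pair type - 1, inner pair type - 1];
// structure energy is the sum over adjacent pair stacks (i,j)/(i+1,j-1).
// Isolated pairs contribute 0, so the empty structure has energy 0 and the
// MFE is always <= 0.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 1 && b == 2) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

// Grammar (unambiguous) used for both optimization and summation, on the
// closed region [i..j]:
//   W(i,j)  = all nested structures              = Wn(i,j) (+) V(i,j)
//   Wn(i,j) = structures without the pair (i,j)  = [j unpaired] W(i,j-1)
//             (+) sum_{k=i+1} W(i,k-1) * V(k,j)
//   V(i,j)  = structures where (i,j) is a pair   = stack(i,j) * V(i+1,j-1)
//             (+) Wn(i+1,j-1)
// Pairs require pair_type > 0 and j - i - 1 >= min_loop.

struct FoldMat {
  int n;
  std::vector<double> W, Wn, V;
  FoldMat(int n_, double init) : n(n_), W((size_t)n_ * n_, init),
    Wn((size_t)n_ * n_, init), V((size_t)n_ * n_, init) {}
  inline size_t at(int i, int j) const { return (size_t)i * n + j; }
};

static const double NOPAIR = 1e18;

// [[Rcpp::export]]
List cpp_fold_mfe(IntegerVector seq, NumericMatrix stack, int min_loop) {
  int n = seq.size();
  IntegerVector partner(n, -1);
  if (n == 0) return List::create(_["energy"] = 0.0, _["partner"] = partner);

  FoldMat M(n, 0.0);
  std::fill(M.V.begin(), M.V.end(), NOPAIR);
  // W(i,j) for j < i is the empty region, energy 0 (handled by bounds checks)
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // V
      double v = NOPAIR;
      if (pair_type(seq[i], seq[j]) > 0 && j - i - 1 >= min_loop) {
        double inner_wn = (j - 1 >= i + 1) ? M.Wn[M.at(i + 1, j - 1)] : 0.0;
        v = inner_wn;
        int pt_in = pair_type(seq[i + 1], seq[j - 1]);
        if (pt_in > 0 && M.V[M.at(i + 1, j - 1)] < NOPAIR / 2) {
          double sv = stack(pair_type(seq[i], seq[j]) - 1, pt_in - 1) +
            M.V[M.at(i + 1, j - 1)];
          if (sv < v) v = sv;
        }
      }
      M.V[M.at(i, j)] = v;
      // Wn: j unpaired, or j paired to k in (i, j)
      double wn = (j - 1 >= i) ? M.W[M.at(i, j - 1)] : 0.0;
      for (int k = i + 1; k <= j - min_loop - 1; ++k) {
        if (M.V[M.at(k, j)] >= NOPAIR / 2) continue;
        double left = (k - 1 >= i) ? M.W[M.at(i, k - 1)] : 0.0;
        double cand = left + M.V[M.at(k, j)];
        if (cand < wn) wn = cand;
      }
      M.Wn[M.at(i, j)] = wn;
      M.W[M.at(i, j)] = std::min(wn, v);
    }
  }

  // Deterministic traceback. Tie-breaking: at W prefer the paired branch
  // (smallest i pairs first); at Wn prefer pairing j with the smallest k
  // over leaving j unpaired; at V prefer the stacked continuation.
  std::vector<std::array<int, 3> > todo; // (i, j, state) state 0=W 1=Wn 2=V
  todo.push_back({0, n - 1, 0});
  while (!todo.empty()) {
    int i = todo.back()[0], j = todo.back()[1], st = todo.back()[2];
    todo.pop_back();
    if (j <= i) continue;
    if (st == 0) {
      double v = M.V[M.at(i, j)];
      if (v < NOPAIR / 2 && v <= M.Wn[M.at(i, j)]) todo.push_back({i, j, 2});
      else todo.push_back({i, j, 1});
    } else if (st == 1) {
      double wn = M.Wn[M.at(i, j)];
      int best_k = -1;
      for (int k = i + 1; k <= j - min_loop - 1; ++k) {
        if (M.V[M.at(k, j)] >= NOPAIR / 2) continue;
        double left = (k - 1 >= i) ? M.W[M.at(i, k - 1)] : 0.0;
        if (left + M.V[M.at(k, j)] == wn) { best_k = k; break; }
      }
      if (best_k >= 0) {
        if (best_k - 1 >= i) todo.push_back({i, best_k - 1, 0});
        todo.push_back({best_k, j, 2});
      } else if (j - 1 >= i) {
        todo.push_back({i, j - 1, 0});
      }
    } else {
      partner[i] = j;
      partner[j] = i;
      if (j - 1 < i + 1) continue;
      double v = M.V[M.at(i, j)];
      int pt_in = pair_type(seq[i + 1], seq[j - 1]);
      bool took_stack = false;
      if (pt_in > 0 && M.V[M.at(i + 1, j - 1)] < NOPAIR / 2) {
        double sv = stack(pair_type(seq[i], seq[j]) - 1, pt_in - 1) +
          M.V[M.at(i + 1, j - 1)];
        if (sv == v) { todo.push_back({i + 1, j - 1, 2}); took_stack = true; }
      }
      if (!took_stack) todo.push_back({i + 1, j - 1, 1});
    }
  }

  return List::create(_["energy"] = M.W[M.at(0, n - 1)],
                      _["partner"] = partner);
}

// [[Rcpp::export]]
List cpp_partition(IntegerVector seq, NumericMatrix stack, double kT,
                   int min_loop) {
  int n = seq.size();
  NumericMatrix pmat(n, n);
  if (n == 0) return List::create(_["Z"] = 1.0, _["p"] = pmat);

  FoldMat Z(n, 0.0);   // inside: ZW, ZWn, ZV
  // empty regions have weight 1; encode via bounds checks
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double zv = 0.0;
      int pt = pair_type(seq[i], seq[j]);
      if (pt > 0 && j - i - 1 >= min_loop) {
        // regions of length < 2 hold only the empty structure (weight 1)
        zv = (j - 1 > i + 1) ? Z.Wn[Z.at(i + 1, j - 1)] : 1.0;
        int pt_in = pair_type(seq[i + 1], seq[j - 1]);
        if (pt_in > 0 && j - i - 3 >= min_loop) {
          zv += std::exp(-stack(pt - 1, pt_in - 1) / kT) *
            Z.V[Z.at(i + 1, j - 1)];
        }
      }
      Z.V[Z.at(i, j)] = zv;
      double zwn = (j - 1 > i) ? Z.W[Z.at(i, j - 1)] : 1.0;
      for (int k = i + 1; k <= j - min_loop - 1; ++k) {
        if (Z.V[Z.at(k, j)] <= 0.0) continue;
        double left = 1.0;
        if (k - 1 > i) left = Z.W[Z.at(i, k - 1)];
        zwn += left * Z.V[Z.at(k, j)];
      }
      Z.Wn[Z.at(i, j)] = zwn;
      Z.W[Z.at(i, j)] = zwn + zv;
    }
  }
  // length-1 regions: W = Wn = 1 (empty structure); store for outside pass
  for (int i = 0; i < n; ++i) {
    Z.W[Z.at(i, i)] = 1.0;
    Z.Wn[Z.at(i, i)] = 1.0;
  }

  // Outside pass, regions in order of decreasing length.
  FoldMat O(n, 0.0);
  O.W[O.at(0, n - 1)] = 1.0;
  for (int len = n; len >= 2; --len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int pt = pair_type(seq[i], seq[j]);
      bool v_valid = (pt > 0 && j - i - 1 >= min_loop);
      // W = Wn + V
      double ow = O.W[O.at(i, j)];
      O.Wn[O.at(i, j)] += ow;
      if (v_valid) O.V[O.at(i, j)] += ow;
      // Wn children
      double own = O.Wn[O.at(i, j)];
      if (own != 0.0) {
        if (j - 1 >= i) O.W[O.at(i, j - 1)] += own;
        for (int k = i + 1; k <= j - min_loop - 1; ++k) {
          if (Z.V[Z.at(k, j)] <= 0.0) continue;
          double left = (k - 1 >= i) ? Z.W[Z.at(i, k - 1)] : 1.0;
          if (k - 1 >= i) O.W[O.at(i, k - 1)] += own * Z.V[Z.at(k, j)];
          O.V[O.at(k, j)] += own * left;
        }
      }
      // V children
      if (v_valid) {
        double ov = O.V[O.at(i, j)];
        if (ov != 0.0 && j - 1 >= i + 1) {
          if (j - 1 > i + 1) O.Wn[O.at(i + 1, j - 1)] += ov;
          int pt_in = pair_type(seq[i + 1], seq[j - 1]);
          if (pt_in > 0 && j - i - 3 >= min_loop) {
            O.V[O.at(i + 1, j - 1)] += ov * std::exp(-stack(pt - 1, pt_in - 1) / kT);
          }
        }
      }
    }
  }

  double Ztot = Z.W[Z.at(0, n - 1)];
  if (n == 1) Ztot = 1.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (Z.V[Z.at(i, j)] > 0.0) {
        double p = Z.V[Z.at(i, j)] * O.V[O.at(i, j)] / Ztot;
        if (p < 0) p = 0;
        if (p > 1) p = 1;
        pmat(i, j) = p;
        pmat(j, i) = p;
      }
    }
  }
  return List::create(_["Z"] = Ztot, _["p"] = pmat);
}

// Intermolecular duplex alignment: pairs (i, j) with i ascending along a
// (5'->3') and j descending along b (5'->3'), no intramolecular pairs.
// Adjacent pairs score the stacking table; non-adjacent consecutive pairs
// pay loop_cost per unpaired nucleotide on either strand, with at most
// max_loop unpaired per strand between consecutive pairs.
// [[Rcpp::export]]
List cpp_duplex(IntegerVector a, IntegerVector b, NumericMatrix stack,
                double loop_cost, int max_loop) {
  int n = a.size(), m = b.size();
  std::vector<double> D((size_t)n * m, NOPAIR);
  std::vector<int> par((size_t)n * m, -1);
  double best = 0.0;
  int best_idx = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int pt = pair_type(a[i], b[j]);
      if (pt == 0) continue;
      double d = 0.0; // open a new duplex at (i, j)
      int p = -1;
      int lo_i = std::max(0, i - max_loop - 1);
      for (int ip = i - 1; ip >= lo_i; --ip) {
        int hi_j = std::min(m - 1, j + max_loop + 1);
        for (int jp = j + 1; jp <= hi_j; ++jp) {
          size_t idx = (size_t)ip * m + jp;
          if (D[idx] >= NOPAIR / 2) continue;
          int ptp = pair_type(a[ip], b[jp]);
          double cost;
          if (ip == i - 1 && jp == j + 1) cost = stack(ptp - 1, pt - 1);
          else cost = loop_cost * ((i - ip - 1) + (jp - j - 1));
          double cand = D[idx] + cost;
          if (cand < d) { d = cand; p = (int)idx; }
        }
      }
      size_t here = (size_t)i * m + j;
      D[here] = d;
      par[here] = p;
      if (d < best) { best = d; best_idx = (int)here; }
    }
  }
  std::vector<int> ai, bj;
  int cur = best_idx;
  while (cur >= 0) {
    ai.push_back(cur / m + 1);
    bj.push_back(cur % m + 1);
    cur = par[cur];
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
  return List::create(_["energy"] = best,
                      _["a_pos"] = wrap(ai), _["b_pos"] = wrap(bj));
}
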