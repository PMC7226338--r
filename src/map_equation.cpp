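// Two-level map equation on an undirected weighted graph, plus the greedy
// node-move / module-merge search used by detect_communities().
//
// Node visit rate p_a = strength(a) / 2W; module exit rate q_i = cut_i / 2W.
// With plogp(x) = x log2 x (and 0 log 0 = 0) the map equation expands to
//   L = plogp(q) - 2 * sum_i plogp(q_i) + sum_i plogp(q_i + P_i)
//       - sum_a plogp(p_a)
// where q = sum_i q_i and P_i = sum_{a in i} p_a.  Only the module terms
// change under node moves, which is what makes the greedy sweep cheap.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double plogp(double x) {
  return x > 0.0 ? x * std::log2(x) : 0.0;
}

// Module contribution excluding the global plogp(q) term.
static inline double mod_term(double cut, double sumS, double W2) {
  double q = cut / W2;
  return -2.0 * plogp(q) + plogp(q + sumS / W2);
}

namespace {

struct Graph {
  int n;
  double W2;  // total edge weight times two
  std::vector<double> s;                 // node strengths
  std::vector<int> adj_start;            // CSR adjacency
  std::vector<int> adj_node;
  std::vector<double> adj_w;

  Graph(int n_, const IntegerVector& from, const IntegerVector& to,
        const NumericVector& w)
      : n(n_), W2(0.0), s(n_, 0.0) {
    int m = from.size();
    std::vector<int> deg(n, 0);
    for (int e = 0; e < m; ++e) {
      int a = from[e] - 1, b = to[e] - 1;
      s[a] += w[e];
      s[b] += w[e];
      W2 += 2.0 * w[e];
      deg[a]++; deg[b]++;
    }
    adj_start.assign(n + 1, 0);
    for (int v = 0; v < n; ++v) adj_start[v + 1] = adj_start[v] + deg[v];
    adj_node.resize(2 * m);
    adj_w.resize(2 * m);
    std::vector<int> fill(adj_start.begin(), adj_start.end() - 1);
    for (int e = 0; e < m; ++e) {
      int a = from[e] - 1, b = to[e] - 1;
      adj_node[fill[a]] = b; adj_w[fill[a]++] = w[e];
      adj_node[fill[b]] = a; adj_w[fill[b]++] = w[e];
    }
  }
};

struct PartitionState {
  const Graph& g;
  std::vector<int> mod;           // node -> module (0-based, may be sparse)
  std::vector<double> cutw, sumS; // per-module raw cut weight / strength sum
  std::vector<int> size;
  double sumCut;

  PartitionState(const Graph& g_, const std::vector<int>& init) : g(g_), mod(init) {
    int nmod = 0;
    for (int v = 0; v < g.n; ++v) nmod = std::max(nmod, mod[v] + 1);
    cutw.assign(nmod, 0.0);
    sumS.assign(nmod, 0.0);
    size.assign(nmod, 0);
    for (int v = 0; v < g.n; ++v) {
      sumS[mod[v]] += g.s[v];
      size[mod[v]]++;
    }
    // cut_i = sum of strengths in i minus twice the internal weight
    std::vector<double> internal(nmod, 0.0);
    for (int v = 0; v < g.n; ++v) {
      for (int k = g.adj_start[v]; k < g.adj_start[v + 1]; ++k) {
        int u = g.adj_node[k];
        if (u > v && mod[u] == mod[v]) internal[mod[v]] += g.adj_w[k];
      }
    }
    sumCut = 0.0;
    for (int i = 0; i < nmod; ++i) {
      cutw[i] = sumS[i] - 2.0 * internal[i];
      if (cutw[i] < 0 && cutw[i] > -1e-12) cutw[i] = 0.0;
      sumCut += cutw[i];
    }
  }

  double L() const {
    double out = plogp(sumCut / g.W2);
    for (size_t i = 0; i < cutw.size(); ++i) {
      if (size[i] > 0) out += mod_term(cutw[i], sumS[i], g.W2);
    }
    for (int v = 0; v < g.n; ++v) out -= plogp(g.s[v] / g.W2);
    return out;
  }

  // One full sweep of best single-node moves; returns total improvement.
  double sweep(const std::vector<int>& order, std::vector<double>& wt,
               std::vector<int>& touched) {
    double gained = 0.0;
    for (int idx = 0; idx < g.n; ++idx) {
      int v = order[idx];
      int a = mod[v];
      touched.clear();
      for (int k = g.adj_start[v]; k < g.adj_start[v + 1]; ++k) {
        int mu = mod[g.adj_node[k]];
        if (wt[mu] == 0.0) touched.push_back(mu);
        wt[mu] += g.adj_w[k];
      }
      double sv = g.s[v];
      double cutA_new = cutw[a] - sv + 2.0 * wt[a];
      double sumSA_new = sumS[a] - sv;
      double baseA = mod_term(cutw[a], sumS[a], g.W2);
      double termA_new = (size[a] > 1) ? mod_term(cutA_new, sumSA_new, g.W2) : 0.0;

      // candidate target modules: neighbours plus (if v not alone) a fresh one
      std::vector<int> cand(touched);
      int freeLab = -1;
      if (size[a] > 1) {
        for (size_t i = 0; i < size.size(); ++i) {
          if (size[i] == 0) { freeLab = (int)i; break; }
        }
        if (freeLab < 0) { freeLab = (int)size.size(); }
        cand.push_back(freeLab);
      }
      std::sort(cand.begin(), cand.end());  // lowest label wins ties

      double bestDelta = 0.0;
      int bestMod = a;
      for (int b : cand) {
        if (b == a) continue;
        double wtb = (b < (int)wt.size()) ? wt[b] : 0.0;
        double cutB = (b < (int)cutw.size()) ? cutw[b] : 0.0;
        double sumSB = (b < (int)sumS.size()) ? sumS[b] : 0.0;
        double cutB_new = cutB + sv - 2.0 * wtb;
        double sumCut_new = sumCut + (cutA_new - cutw[a]) + (cutB_new - cutB);
        double delta = plogp(sumCut_new / g.W2) - plogp(sumCut / g.W2)
                     + termA_new - baseA
                     + mod_term(cutB_new, sumSB + sv, g.W2)
                     - mod_term(cutB, sumSB, g.W2);
        if (delta < bestDelta - 1e-12) {
          bestDelta = delta;
          bestMod = b;
        }
      }
      if (bestMod != a) {
        int b = bestMod;
        if (b >= (int)cutw.size()) {
          cutw.push_back(0.0); sumS.push_back(0.0); size.push_back(0);
          wt.push_back(0.0);
        }
        double wtb = wt[b];
        sumCut += (cutA_new - cutw[a]) + (cutw[b] + sv - 2.0 * wtb - cutw[b]);
        cutw[a] = cutA_new; sumS[a] = sumSA_new; size[a]--;
        cutw[b] += sv - 2.0 * wtb; sumS[b] += sv; size[b]++;
        mod[v] = b;
        gained -= bestDelta;
      }
      for (int mu : touched) wt[mu] = 0.0;
    }
    return gained;
  }

  // Greedy module merges; returns total improvement.
  double merge_pass() {
    double gained = 0.0;
    bool improved = true;
    while (improved) {
      improved = false;
      // between-module weights
      std::map<std::pair<int, int>, double> between;
      for (int v = 0; v < g.n; ++v) {
        for (int k = g.adj_start[v]; k < g.adj_start[v + 1]; ++k) {
          int u = g.adj_node[k];
          if (u <= v) continue;
          int a = mod[v], b = mod[u];
          if (a == b) continue;
          if (a > b) std::swap(a, b);
          between[std::make_pair(a, b)] += g.adj_w[k];
        }
      }
      double bestDelta = -1e-12;
      std::pair<int, int> bestPair(-1, -1);
      double bestWab = 0.0;
      for (auto& kv : between) {
        int a = kv.first.first, b = kv.first.second;
        double wab = kv.second;
        double cutM = cutw[a] + cutw[b] - 2.0 * wab;
        double sumCut_new = sumCut - cutw[a] - cutw[b] + cutM;
        double delta = plogp(sumCut_new / g.W2) - plogp(sumCut / g.W2)
                     + mod_term(cutM, sumS[a] + sumS[b], g.W2)
                     - mod_term(cutw[a], sumS[a], g.W2)
                     - mod_term(cutw[b], sumS[b], g.W2);
        if (delta < bestDelta) {
          bestDelta = delta; bestPair = kv.first; bestWab = wab;
        }
      }
      if (bestPair.first >= 0) {
        int a = bestPair.first, b = bestPair.second;
        double cutM = cutw[a] + cutw[b] - 2.0 * bestWab;
        sumCut += cutM - cutw[a] - cutw[b];
        cutw[a] = cutM; sumS[a] += sumS[b]; size[a] += size[b];
        cutw[b] = 0.0; sumS[b] = 0.0; size[b] = 0;
        for (int v = 0; v < g.n; ++v) if (mod[v] == b) mod[v] = a;
        gained -= bestDelta;
        improved = true;
      }
    }
    return gained;
  }
};

}  // namespace

// [[Rcpp::export]]
double cpp_map_L(int n, IntegerVector from, IntegerVector to,
                 NumericVector w, IntegerVector modules) {
  Graph g(n, from, to, w);
  std::vector<int> init(n);
  for (int v = 0; v < n; ++v) init[v] = modules[v] - 1;
  PartitionState st(g, init);
  return st.L();
}

// [[Rcpp::export]]
List cpp_greedy(int n, IntegerVector from, IntegerVector to, NumericVector w,
                IntegerMatrix orders, double tol) {
  Graph g(n, from, to, w);
  double bestL = R_PosInf;
  std::vector<int> bestMod;
  int n_restarts = orders.nrow();
  for (int r = 0; r < n_restarts; ++r) {
    std::vector<int> order(n);
    for (int v = 0; v < n; ++v) order[v] = orders(r, v) - 1;
    std::vector<int> init(n);
    for (int v = 0; v < n; ++v) init[v] = v;  // singletons
    PartitionState st(g, init);
    std::vector<double> wt(2 * n + 1, 0.0);
    std::vector<int> touched;
    touched.reserve(64);
    bool any = true;
    while (any) {
      any = false;
      while (st.sweep(order, wt, touched) >= tol) any = true;
      if (st.merge_pass() >= tol) any = true;
    }
    double L = st.L();
    if (L < bestL - 1e-12) {
      bestL = L;
      bestMod = st.mod;
    }
  }
  // relabel contiguously by first appearance
  std::vector<int> relabel(2 * n + 1, -1);
  int next = 1;
  IntegerVector assignment(n);
  for (int v = 0; v < n; ++v) {
    int m = bestMod[v];
    if (relabel[m] < 0) relabel[m] = next++;
    assignment[v] = relabel[m];
  }
  return List::create(_["assignment"] = assignment, _["L"] = bestL);
}
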