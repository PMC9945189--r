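// Exact MAF by brute force: enumerate k-subsets of the first tree's
// edges for increasing k and return the first edge set whose induced
// leaf-label partition is a feasible agreement forest (all components
// compatible, pairwise non-overlapping in the second tree; first-tree
// disjointness is automatic for edge-deletion forests).
//
// Node universes here are tiny (the R wrapper caps the label count), so
// label sets are 64-bit masks and per-node spans are 64-bit node masks.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Tree {
  int N;                       // node count
  std::vector<int> parent;     // -1 at root
  std::vector<int> depth;
  std::vector<uint64_t> below; // label mask below each node
  std::vector<std::vector<int>> kids;

  void init(const IntegerVector& par, const IntegerVector& tips, int nlab) {
    N = par.size();
    parent.assign(N, -1);
    kids.assign(N, {});
    for (int v = 0; v < N; ++v) {
      parent[v] = par[v];
      if (par[v] >= 0) kids[par[v]].push_back(v);
    }
    depth.assign(N, 0);
    // depth via repeated passes (N tiny)
    for (int pass = 0; pass < N; ++pass)
      for (int v = 0; v < N; ++v)
        if (parent[v] >= 0) depth[v] = depth[parent[v]] + 1;
    below.assign(N, 0);
    for (int i = 0; i < nlab; ++i) below[tips[i]] |= (uint64_t(1) << i);
    // accumulate bottom-up: order nodes by decreasing depth
    std::vector<int> order(N);
    for (int v = 0; v < N; ++v) order[v] = v;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return depth[a] > depth[b]; });
    for (int v : order)
      if (parent[v] >= 0) below[parent[v]] |= below[v];
  }

  int lca(int a, int b) const {
    while (a != b) {
      if (depth[a] < depth[b]) b = parent[b];
      else a = parent[a];
    }
    return a;
  }
};

struct Instance {
  Tree t1, t2;
  int nlab;
  std::vector<int> tip1, tip2;           // node of each label per tree
  std::vector<std::vector<int>> lcaP1, lcaP2; // pairwise label lcas
  std::vector<uint64_t> badTriple;       // masks of incompatible triples

  // cherry of a label triple in tree t: 0 -> (a,b), 1 -> (a,c), 2 -> (b,c)
  int cherry(const Tree& t, const std::vector<std::vector<int>>& lcaP,
             int a, int b, int c) const {
    int lab = lcaP[a][b], lac = lcaP[a][c], lbc = lcaP[b][c];
    int da = t.depth[lab], db = t.depth[lac], dc = t.depth[lbc];
    if (da >= db && da >= dc) return 0;
    if (db >= dc) return 1;
    return 2;
  }

  void build(const IntegerVector& p1, const IntegerVector& tips1v,
             const IntegerVector& p2, const IntegerVector& tips2v, int n) {
    nlab = n;
    tip1.assign(tips1v.begin(), tips1v.end());
    tip2.assign(tips2v.begin(), tips2v.end());
    t1.init(p1, tips1v, n);
    t2.init(p2, tips2v, n);
    lcaP1.assign(n, std::vector<int>(n));
    lcaP2.assign(n, std::vector<int>(n));
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        lcaP1[i][j] = t1.lca(tip1[i], tip1[j]);
        lcaP2[i][j] = t2.lca(tip2[i], tip2[j]);
      }
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b)
        for (int c = b + 1; c < n; ++c)
          if (cherry(t1, lcaP1, a, b, c) != cherry(t2, lcaP2, a, b, c))
            badTriple.push_back((uint64_t(1) << a) | (uint64_t(1) << b) |
                                (uint64_t(1) << c));
  }

  bool compatible(uint64_t mask) const {
    for (uint64_t t : badTriple)
      if ((mask & t) == t) return false;
    return true;
  }

  // node mask of the second tree spanned by a label mask
  uint64_t span2(uint64_t mask) const {
    int k = __builtin_popcountll(mask);
    if (k == 0) return 0;
    uint64_t nodes = 0;
    int lcaNode = -1, lcaDepth = -1;
    for (int v = 0; v < t2.N; ++v) {
      int c = __builtin_popcountll(t2.below[v] & mask);
      if (c >= 1 && c < k) nodes |= (uint64_t(1) << v);
      if (c == k && t2.depth[v] > lcaDepth) { lcaDepth = t2.depth[v]; lcaNode = v; }
    }
    nodes |= (uint64_t(1) << lcaNode);
    return nodes;
  }

  // partition induced by cutting the parent edges of `cuts` in T1
  bool feasible(const std::vector<int>& cuts,
                std::vector<uint64_t>& comps) const {
    std::vector<int> compOf(t1.N, 0);
    std::vector<char> isCut(t1.N, 0);
    for (int v : cuts) isCut[v] = 1;
    int nc = 1;
    // preorder: order by increasing depth
    std::vector<int> order(t1.N);
    for (int v = 0; v < t1.N; ++v) order[v] = v;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return t1.depth[a] < t1.depth[b]; });
    for (int v : order) {
      if (t1.parent[v] < 0) compOf[v] = 0;
      else compOf[v] = isCut[v] ? nc++ : compOf[t1.parent[v]];
    }
    std::vector<uint64_t> masks(nc, 0);
    for (int i = 0; i < nlab; ++i)
      masks[compOf[tip1[i]]] |= (uint64_t(1) << i);
    comps.clear();
    for (uint64_t m : masks)
      if (m) comps.push_back(m);
    uint64_t used = 0;
    for (uint64_t m : comps) {
      if (!compatible(m)) return false;
      uint64_t s = span2(m);
      if (s & used) return false;
      used |= s;
    }
    return true;
  }
};

bool searchK(const Instance& inst, const std::vector<int>& edges, int k,
             std::vector<int>& cur, size_t start,
             std::vector<uint64_t>& comps) {
  if ((int)cur.size() == k)
    return inst.feasible(cur, comps);
  for (size_t i = start; i + (k - cur.size()) <= edges.size() + 0u; ++i) {
    cur.push_back(edges[i]);
    if (searchK(inst, edges, k, cur, i + 1, comps)) return true;
    cur.pop_back();
  }
  return false;
}

} // namespace

// [[Rcpp::export(name = ".exact_maf_cpp")]]
List exact_maf_cpp(IntegerVector parent1, IntegerVector tips1,
                   IntegerVector parent2, IntegerVector tips2,
                   int nlab, int cap) {
  if (nlab > 60) stop("too many labels for the mask-based oracle");
  Instance inst;
  inst.build(parent1, tips1, parent2, tips2, nlab);
  std::vector<int> edges;   // cuttable: every non-root node's parent edge
  for (int v = 0; v < inst.t1.N; ++v)
    if (inst.t1.parent[v] >= 0) edges.push_back(v);
  std::vector<uint64_t> comps;
  for (int k = 0; k <= cap; ++k) {
    std::vector<int> cur;
    if (searchK(inst, edges, k, cur, 0, comps)) {
      List compList(comps.size());
      for (size_t i = 0; i < comps.size(); ++i) {
        std::vector<int> lab;
        for (int j = 0; j < nlab; ++j)
          if (comps[i] & (uint64_t(1) << j)) lab.push_back(j + 1);
        compList[i] = wrap(lab);
      }
      return List::create(_["k"] = k, _["components"] = compList);
    }
  }
  return List::create(_["k"] = -1, _["components"] = List(0));
}
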