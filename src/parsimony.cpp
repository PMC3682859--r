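// Core parsimony engines: bit-parallel Fitch scoring, exact branch-and-bound
// enumeration of all most-parsimonious trees, TBR-based heuristic search.
//
// State encoding: each cell of a binary character is a 2-bit set,
//   1 = {0}, 2 = {1}, 3 = {0,1} (missing / inapplicable / polymorphic).
// Characters are packed 32 per 64-bit word so a whole-tree Fitch pass is a
// handful of word operations per node.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <set>
#include <string>
#include <algorithm>
#include <random>
#include <functional>
#include <utility>

using namespace Rcpp;

typedef std::pair<int, int> TEdge;
typedef std::vector<TEdge> EdgeList;

// ----------------------------------------------------------------------------
// packed character data
// ----------------------------------------------------------------------------

struct CharData {
  int ntip, nchar, W;
  std::vector<uint64_t> leaf;   // ntip * W words
  std::vector<uint64_t> slot01; // W words: low bit of every occupied slot
};

static CharData pack_states(const IntegerMatrix& st) {
  CharData d;
  d.ntip = st.nrow();
  d.nchar = st.ncol();
  d.W = (d.nchar + 31) / 32;
  if (d.W == 0) d.W = 1;
  d.leaf.assign((size_t)d.ntip * d.W, 0);
  d.slot01.assign(d.W, 0);
  for (int c = 0; c < d.nchar; c++) {
    int w = c / 32, s = (c % 32) * 2;
    d.slot01[w] |= (1ULL << s);
    for (int i = 0; i < d.ntip; i++) {
      int m = st(i, c);
      if (m < 1 || m > 3) stop("internal: state mask out of range");
      d.leaf[(size_t)i * d.W + w] |= ((uint64_t)m) << s;
    }
  }
  return d;
}

// ----------------------------------------------------------------------------
// Fitch length of an unrooted binary tree given as an undirected edge list
// (leaves 0..ntip-1, internal nodes >= ntip). Workspace is reused.
// ----------------------------------------------------------------------------

struct FitchWS {
  const CharData* d;
  int maxnode;
  std::vector<int> head, nxt, to;
  std::vector<int> po, stk, pa;
  std::vector<uint64_t> sets;
  FitchWS(const CharData* dd, int maxnode_) : d(dd), maxnode(maxnode_) {
    head.assign(maxnode, -1);
    pa.assign(maxnode, -1);
    po.assign(maxnode, 0);
    stk.assign(maxnode, 0);
    int me = 2 * maxnode; // generous
    nxt.assign(me, 0);
    to.assign(me, 0);
    sets.assign((size_t)maxnode * dd->W, 0);
  }

  int length(const EdgeList& ed, int rootleaf) {
    const int W = d->W;
    std::fill(head.begin(), head.end(), -1);
    int m = 0;
    for (size_t i = 0; i < ed.size(); i++) {
      int a = ed[i].first, b = ed[i].second;
      to[m] = b; nxt[m] = head[a]; head[a] = m; m++;
      to[m] = a; nxt[m] = head[b]; head[b] = m; m++;
    }
    // preorder DFS from rootleaf
    int sp = 0, np = 0;
    stk[sp++] = rootleaf;
    pa[rootleaf] = -1;
    while (sp) {
      int u = stk[--sp];
      po[np++] = u;
      for (int e = head[u]; e != -1; e = nxt[e]) {
        int v = to[e];
        if (v != pa[u]) { pa[v] = u; stk[sp++] = v; }
      }
    }
    int steps = 0;
    for (int i = np - 1; i >= 0; i--) {
      int u = po[i];
      if (u == rootleaf) continue;
      uint64_t* S = &sets[(size_t)u * W];
      if (u < d->ntip) {
        const uint64_t* L = &d->leaf[(size_t)u * W];
        for (int w = 0; w < W; w++) S[w] = L[w];
        continue;
      }
      bool first = true;
      for (int e = head[u]; e != -1; e = nxt[e]) {
        int v = to[e];
        if (v == pa[u]) continue;
        const uint64_t* C = &sets[(size_t)v * W];
        if (first) {
          for (int w = 0; w < W; w++) S[w] = C[w];
          first = false;
        } else {
          for (int w = 0; w < W; w++) {
            uint64_t a = S[w], b = C[w], x = a & b;
            uint64_t nz = (x | (x >> 1)) & d->slot01[w];
            uint64_t el = d->slot01[w] & ~nz;
            steps += __builtin_popcountll(el);
            uint64_t em = el | (el << 1);
            S[w] = x | ((a | b) & em);
          }
        }
      }
    }
    // fold in the root leaf itself
    int c = to[head[rootleaf]];
    const uint64_t* A = &sets[(size_t)c * W];
    const uint64_t* B = &d->leaf[(size_t)rootleaf * W];
    for (int w = 0; w < W; w++) {
      uint64_t x = A[w] & B[w];
      uint64_t nz = (x | (x >> 1)) & d->slot01[w];
      steps += __builtin_popcountll(d->slot01[w] & ~nz);
    }
    return steps;
  }
};

// ----------------------------------------------------------------------------
// Newick serialisation of an edge list; leaves labelled t<k> with k the
// 1-based taxon number given in leafmap.
// ----------------------------------------------------------------------------

static void subtree_newick(int u, int par,
                           const std::vector<std::vector<int>>& adj,
                           const std::vector<int>& leafmap, int ntip,
                           std::string& out) {
  if (u < ntip) {
    out += "t";
    out += std::to_string(leafmap[u]);
    return;
  }
  out += "(";
  bool first = true;
  for (int v : adj[u]) {
    if (v == par) continue;
    if (!first) out += ",";
    first = false;
    subtree_newick(v, u, adj, leafmap, ntip, out);
  }
  out += ")";
}

static std::string edgelist_newick(const EdgeList& ed,
                                   const std::vector<int>& leafmap, int ntip) {
  int maxn = 0;
  for (auto& e : ed) maxn = std::max(maxn, std::max(e.first, e.second));
  std::vector<std::vector<int>> adj(maxn + 1);
  for (auto& e : ed) {
    adj[e.first].push_back(e.second);
    adj[e.second].push_back(e.first);
  }
  // root display at the internal node adjacent to the lowest-numbered leaf
  int lf = -1;
  for (int i = 0; i <= maxn; i++)
    if (i < ntip && !adj[i].empty()) { lf = i; break; }
  int root = adj[lf][0];
  std::string s;
  if (root < ntip) { // two-leaf tree
    s = "(t" + std::to_string(leafmap[lf]) + ",t" +
        std::to_string(leafmap[root]) + ");";
    return s;
  }
  subtree_newick(root, -1, adj, leafmap, ntip, s);
  s += ";";
  return s;
}

// ----------------------------------------------------------------------------
// canonical topology key: sorted leaf-set bitmasks of the non-trivial splits,
// each normalised to the side excluding the lowest-numbered leaf present.
// Requires <= 64 leaves.
// ----------------------------------------------------------------------------

static void split_masks(int u, int par,
                        const std::vector<std::vector<int>>& adj, int ntip,
                        uint64_t& mask, std::vector<uint64_t>& acc,
                        uint64_t fullmask, int nleaf) {
  mask = 0;
  for (int v : adj[u]) {
    if (v == par) continue;
    uint64_t sub = 0;
    if (v < ntip) {
      sub = 1ULL << v;
    } else {
      split_masks(v, u, adj, ntip, sub, acc, fullmask, nleaf);
    }
    int pc = __builtin_popcountll(sub);
    if (pc >= 2 && pc <= nleaf - 2) {
      uint64_t norm = (sub & 1ULL) ? (fullmask & ~sub) : sub;
      // normalise on lowest leaf present in fullmask
      uint64_t low = fullmask & (~fullmask + 1);
      norm = (sub & low) ? (fullmask & ~sub) : sub;
      acc.push_back(norm);
    }
    mask |= sub;
  }
}

static std::vector<uint64_t> canon_key(const EdgeList& ed, int ntip) {
  int maxn = 0;
  for (auto& e : ed) maxn = std::max(maxn, std::max(e.first, e.second));
  std::vector<std::vector<int>> adj(maxn + 1);
  uint64_t fullmask = 0;
  int nleaf = 0;
  for (auto& e : ed) {
    adj[e.first].push_back(e.second);
    adj[e.second].push_back(e.first);
  }
  for (int i = 0; i <= maxn && i < ntip; i++)
    if (!adj[i].empty()) { fullmask |= 1ULL << i; nleaf++; }
  int lf = -1;
  for (int i = 0; i < ntip; i++)
    if (i <= maxn && !adj[i].empty()) { lf = i; break; }
  int root = adj[lf][0];
  std::vector<uint64_t> acc;
  uint64_t m = 0;
  if (root >= ntip) split_masks(root, -1, adj, ntip, m, acc, fullmask, nleaf);
  std::sort(acc.begin(), acc.end());
  return acc;
}

// ----------------------------------------------------------------------------
// TBR neighbourhood. Calls visit(neighbour) for every tree obtained by
// bisecting an edge and reconnecting the two pieces across any edge pair;
// the pair reconstituting the input is skipped. visit returns false to stop.
// ----------------------------------------------------------------------------

template <typename F>
static bool for_each_tbr(const EdgeList& ed, int ntip, F visit) {
  int maxn = 0;
  for (auto& e : ed) maxn = std::max(maxn, std::max(e.first, e.second));
  std::vector<std::vector<int>> adj(maxn + 1);
  for (size_t i = 0; i < ed.size(); i++) {
    adj[ed[i].first].push_back(ed[i].second);
    adj[ed[i].second].push_back(ed[i].first);
  }
  std::vector<char> inA(maxn + 1);
  std::vector<int> stk;
  EdgeList nb;
  nb.reserve(ed.size() + 2);

  for (size_t ei = 0; ei < ed.size(); ei++) {
    int u = ed[ei].first, v = ed[ei].second;
    // mark component of u (excluding edge ei)
    std::fill(inA.begin(), inA.end(), 0);
    stk.clear();
    stk.push_back(u);
    inA[u] = 1;
    while (!stk.empty()) {
      int x = stk.back();
      stk.pop_back();
      for (int y : adj[x]) {
        if ((x == u && y == v) || inA[y]) continue;
        inA[y] = 1;
        stk.push_back(y);
      }
    }
    if (inA[v]) continue; // parallel edge; cannot happen in a tree

    // base edges of each component after splicing out u and/or v
    EdgeList eA, eB;
    int spliceA = -1, spliceB = -1; // index of the edge created by splicing
    for (size_t j = 0; j < ed.size(); j++) {
      if (j == ei) continue;
      int a = ed[j].first, b = ed[j].second;
      if (inA[a]) {
        if (a != u && b != u) eA.push_back(ed[j]);
      } else {
        if (a != v && b != v) eB.push_back(ed[j]);
      }
    }
    bool uLeaf = (u < ntip), vLeaf = (v < ntip);
    if (!uLeaf) { // splice u: connect its two remaining neighbours
      int x = -1, y = -1;
      for (int w : adj[u])
        if (w != v) { if (x < 0) x = w; else y = w; }
      eA.push_back(TEdge(x, y));
      spliceA = (int)eA.size() - 1;
    }
    if (!vLeaf) {
      int x = -1, y = -1;
      for (int w : adj[v])
        if (w != u) { if (x < 0) x = w; else y = w; }
      eB.push_back(TEdge(x, y));
      spliceB = (int)eB.size() - 1;
    }

    if (!uLeaf && !vLeaf) {
      for (size_t ia = 0; ia < eA.size(); ia++) {
        for (size_t ib = 0; ib < eB.size(); ib++) {
          if ((int)ia == spliceA && (int)ib == spliceB) continue; // original
          nb.clear();
          for (size_t j = 0; j < eA.size(); j++)
            if (j != ia) nb.push_back(eA[j]);
          for (size_t j = 0; j < eB.size(); j++)
            if (j != ib) nb.push_back(eB[j]);
          nb.push_back(TEdge(eA[ia].first, u));
          nb.push_back(TEdge(u, eA[ia].second));
          nb.push_back(TEdge(eB[ib].first, v));
          nb.push_back(TEdge(v, eB[ib].second));
          nb.push_back(TEdge(u, v));
          if (!visit(nb)) return false;
        }
      }
    } else if (!uLeaf && vLeaf) {
      // v is a pruned leaf; reinsert it (with node u) on any edge of A
      for (size_t ia = 0; ia < eA.size(); ia++) {
        if ((int)ia == spliceA) continue;
        nb.clear();
        for (size_t j = 0; j < eA.size(); j++)
          if (j != ia) nb.push_back(eA[j]);
        nb.push_back(TEdge(eA[ia].first, u));
        nb.push_back(TEdge(u, eA[ia].second));
        nb.push_back(TEdge(u, v));
        if (!visit(nb)) return false;
      }
    } else if (uLeaf && !vLeaf) {
      for (size_t ib = 0; ib < eB.size(); ib++) {
        if ((int)ib == spliceB) continue;
        nb.clear();
        for (size_t j = 0; j < eB.size(); j++)
          if (j != ib) nb.push_back(eB[j]);
        nb.push_back(TEdge(eB[ib].first, v));
        nb.push_back(TEdge(v, eB[ib].second));
        nb.push_back(TEdge(v, u));
        if (!visit(nb)) return false;
      }
    }
  }
  return true;
}

// ----------------------------------------------------------------------------
// exported: per-character Fitch step counts for an arbitrary tree given as an
// ape edge matrix (1-based; tips 1..ntip; root may be a multifurcation).
// ----------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector fitch_counts_cpp(IntegerMatrix edge, int ntip,
                               IntegerMatrix states) {
  int nc = states.ncol();
  int maxn = ntip;
  for (int i = 0; i < edge.nrow(); i++)
    maxn = std::max(maxn, std::max(edge(i, 0), edge(i, 1)));
  std::vector<std::vector<int>> kids(maxn + 1);
  std::vector<char> isChild(maxn + 1, 0);
  for (int i = 0; i < edge.nrow(); i++) {
    kids[edge(i, 0)].push_back(edge(i, 1));
    isChild[edge(i, 1)] = 1;
  }
  int root = -1;
  for (int i = 1; i <= maxn; i++)
    if ((!kids[i].empty() || i <= ntip) && !isChild[i]) { root = i; break; }
  if (root < 0) stop("tree has no root node");
  // postorder
  std::vector<int> order, stk;
  stk.push_back(root);
  while (!stk.empty()) {
    int u = stk.back();
    stk.pop_back();
    order.push_back(u);
    for (int v : kids[u]) stk.push_back(v);
  }
  IntegerVector steps(nc);
  std::vector<int> set(maxn + 1);
  for (int c = 0; c < nc; c++) {
    int st = 0;
    for (int k = (int)order.size() - 1; k >= 0; k--) {
      int u = order[k];
      if (kids[u].empty()) {
        if (u > ntip) stop("internal node without children");
        set[u] = states(u - 1, c);
      } else {
        int cur = 0;
        bool first = true;
        for (int v : kids[u]) {
          if (first) { cur = set[v]; first = false; }
          else {
            int x = cur & set[v];
            if (x) cur = x;
            else { st++; cur |= set[v]; }
          }
        }
        set[u] = cur;
      }
    }
    steps[c] = st;
  }
  return steps;
}

// ----------------------------------------------------------------------------
// exported: Fitch total length for a list of trees (undirected edge matrices
// are rebuilt from newick on the R side; here we take ape edge matrices of
// unrooted trees and score them bit-parallel)
// ----------------------------------------------------------------------------

// [[Rcpp::export]]
int fitch_length_cpp(IntegerMatrix edge, int ntip, IntegerMatrix states) {
  CharData d = pack_states(states);
  EdgeList ed;
  for (int i = 0; i < edge.nrow(); i++)
    ed.push_back(TEdge(edge(i, 0) - 1, edge(i, 1) - 1));
  int maxn = 0;
  for (auto& e : ed) maxn = std::max(maxn, std::max(e.first, e.second));
  FitchWS ws(&d, maxn + 1);
  return ws.length(ed, 0);
}

// ----------------------------------------------------------------------------
// stepwise addition helper (shared by search routines)
// ----------------------------------------------------------------------------

static void insert_leaf(EdgeList& ed, int leaf, int node, size_t eidx) {
  TEdge old = ed[eidx];
  ed[eidx] = TEdge(old.first, node);
  ed.push_back(TEdge(node, old.second));
  ed.push_back(TEdge(node, leaf));
}

static void undo_insert(EdgeList& ed, size_t eidx) {
  int node = ed[eidx].second;
  int v = ed[ed.size() - 2].second;
  ed[eidx] = TEdge(ed[eidx].first, v);
  ed.pop_back();
  ed.pop_back();
  (void)node;
}

static EdgeList stepwise_addition(const CharData& d, FitchWS& ws,
                                  const std::vector<int>& order) {
  int n = (int)order.size();
  EdgeList ed;
  int c0 = d.ntip; // first internal node
  ed.push_back(TEdge(c0, order[0]));
  ed.push_back(TEdge(c0, order[1]));
  ed.push_back(TEdge(c0, order[2]));
  for (int k = 3; k < n; k++) {
    int node = d.ntip + k - 2;
    int bestLen = INT_MAX;
    size_t bestE = 0;
    size_t ne = ed.size();
    for (size_t e = 0; e < ne; e++) {
      insert_leaf(ed, order[k], node, e);
      int L = ws.length(ed, order[0]);
      undo_insert(ed, e);
      if (L < bestLen) { bestLen = L; bestE = e; }
    }
    insert_leaf(ed, order[k], node, bestE);
  }
  return ed;
}

// ----------------------------------------------------------------------------
// exported: exact branch-and-bound search for all most-parsimonious trees
// ----------------------------------------------------------------------------

// [[Rcpp::export]]
List bab_cpp(IntegerMatrix states, int upper, int max_trees) {
  CharData d = pack_states(states);
  int n = d.ntip;
  if (n < 3) stop("need at least 3 taxa");
  int maxnode = 2 * n; // capacity
  FitchWS ws(&d, maxnode);

  // --- addition order: core triple maximising 3-taxon length, then
  // max-min stepwise addition on a greedily grown reference tree ---
  std::vector<int> order;
  std::vector<char> used(n, 0);
  {
    int bi = 0, bj = 1, bk = 2, bl = -1;
    EdgeList tri;
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++)
        for (int k = j + 1; k < n; k++) {
          tri.clear();
          tri.push_back(TEdge(n, i));
          tri.push_back(TEdge(n, j));
          tri.push_back(TEdge(n, k));
          int L = ws.length(tri, i);
          if (L > bl) { bl = L; bi = i; bj = j; bk = k; }
        }
    order.push_back(bi); order.push_back(bj); order.push_back(bk);
    used[bi] = used[bj] = used[bk] = 1;
  }
  EdgeList ref;
  ref.push_back(TEdge(n, order[0]));
  ref.push_back(TEdge(n, order[1]));
  ref.push_back(TEdge(n, order[2]));
  int refLen = 0;
  for (int step = 3; step < n; step++) {
    int node = n + step - 2;
    int pick = -1, pickLen = -1;
    size_t pickE = 0;
    for (int t = 0; t < n; t++) {
      if (used[t]) continue;
      int bestLen = INT_MAX;
      size_t bestE = 0;
      for (size_t e = 0; e < ref.size(); e++) {
        insert_leaf(ref, t, node, e);
        int L = ws.length(ref, order[0]);
        undo_insert(ref, e);
        if (L < bestLen) { bestLen = L; bestE = e; }
      }
      if (bestLen > pickLen) { pickLen = bestLen; pick = t; pickE = bestE; }
    }
    insert_leaf(ref, pick, node, pickE);
    used[pick] = 1;
    order.push_back(pick);
    refLen = pickLen;
  }
  if (n == 3) refLen = ws.length(ref, order[0]);

  // --- per-level admissible lower bound on remaining steps ---
  // a character contributes 1 at level j if some not-yet-added taxon carries
  // an unambiguous state absent from the unambiguous states of the first j
  std::vector<int> bound(n + 1, 0);
  {
    int nc = d.nchar;
    IntegerMatrix st(states);
    std::vector<int> suffix0(n + 1, 0), suffix1(n + 1, 0);
    for (int c = 0; c < nc; c++) {
      std::vector<char> h0(n + 1, 0), h1(n + 1, 0);
      for (int j = n - 1; j >= 0; j--) {
        int m = st(order[j], c);
        h0[j] = h0[j + 1] || (m == 1);
        h1[j] = h1[j + 1] || (m == 2);
      }
      int P = 0;
      for (int j = 0; j <= n; j++) {
        if ((h0[j] && !(P & 1)) || (h1[j] && !(P & 2))) bound[j] += 1;
        if (j < n) {
          int m = st(order[j], c);
          if (m != 3) P |= m;
        }
      }
    }
  }

  int best = std::min(upper, refLen);
  std::vector<EdgeList> archive;
  double nodes_expanded = 0;
  int bound_updates = 0;
  bool overflow = false;

  EdgeList ed;
  ed.push_back(TEdge(n, order[0]));
  ed.push_back(TEdge(n, order[1]));
  ed.push_back(TEdge(n, order[2]));

  // iterative recursion
  std::function<void(int)> rec = [&](int k) {
    size_t ne = ed.size();
    int node = n + k - 2;
    for (size_t e = 0; e < ne; e++) {
      insert_leaf(ed, order[k], node, e);
      int L = ws.length(ed, order[0]);
      nodes_expanded += 1;
      if (k + 1 == n) {
        if (L < best) {
          best = L;
          archive.clear();
          bound_updates++;
          overflow = false;
        }
        if (L == best) {
          if ((int)archive.size() < max_trees) archive.push_back(ed);
          else overflow = true;
        }
      } else if (L + bound[k + 1] <= best) {
        rec(k + 1);
      }
      undo_insert(ed, e);
    }
  };
  if (n == 3) {
    best = ws.length(ed, order[0]);
    archive.push_back(ed);
  } else {
    rec(3);
  }

  std::vector<int> leafmap(n);
  for (int i = 0; i < n; i++) leafmap[i] = i + 1;
  CharacterVector trees(archive.size());
  for (size_t i = 0; i < archive.size(); i++)
    trees[i] = edgelist_newick(archive[i], leafmap, n);
  IntegerVector ord(n);
  for (int i = 0; i < n; i++) ord[i] = order[i] + 1;
  return List::create(_["best_length"] = best, _["trees"] = trees,
                      _["nodes_expanded"] = nodes_expanded,
                      _["bound_updates"] = bound_updates,
                      _["order"] = ord, _["overflow"] = overflow,
                      _["reference_length"] = refLen);
}

// ----------------------------------------------------------------------------
// exported: heuristic search (random stepwise addition + TBR, retain all)
// ----------------------------------------------------------------------------

// [[Rcpp::export]]
List heuristic_cpp(IntegerMatrix states, int nrep, int seed, int max_trees) {
  CharData d = pack_states(states);
  int n = d.ntip;
  if (n > 64) stop("heuristic search supports at most 64 taxa");
  if (n < 4) stop("need at least 4 taxa");
  FitchWS ws(&d, 2 * n);
  std::mt19937 rng((uint32_t)seed);

  int best = INT_MAX;
  std::set<std::vector<uint64_t>> keys;
  std::vector<EdgeList> arch;
  double scored = 0;

  auto tryAdd = [&](const EdgeList& t) -> bool {
    if ((int)arch.size() >= max_trees) return false;
    std::vector<uint64_t> k = canon_key(t, n);
    if (keys.count(k)) return false;
    keys.insert(k);
    arch.push_back(t);
    return true;
  };

  // first-improvement TBR descent
  auto descend = [&](EdgeList T, int L) -> std::pair<EdgeList, int> {
    bool improved = true;
    while (improved) {
      improved = false;
      for_each_tbr(T, n, [&](const EdgeList& N) -> bool {
        int l = ws.length(N, 0 /*any leaf: use lowest in N*/);
        scored += 1;
        if (l < L) {
          T = N;
          L = l;
          improved = true;
          return false;
        }
        return true;
      });
    }
    return std::make_pair(T, L);
  };

  IntegerVector repBest(nrep);
  for (int rep = 0; rep < nrep; rep++) {
    std::vector<int> order(n);
    for (int i = 0; i < n; i++) order[i] = i;
    std::shuffle(order.begin(), order.end(), rng);
    EdgeList T = stepwise_addition(d, ws, order);
    int L = ws.length(T, order[0]);
    std::pair<EdgeList, int> r = descend(T, L);
    repBest[rep] = r.second;
    if (r.second > best) continue;
    if (r.second < best) {
      best = r.second;
      keys.clear();
      arch.clear();
    }
    tryAdd(r.first);
    // closure: swap from every archived tree, keeping all equal-length trees
    size_t idx = 0;
    while (idx < arch.size()) {
      EdgeList cur = arch[idx];
      bool reset = false;
      for_each_tbr(cur, n, [&](const EdgeList& N) -> bool {
        int l = ws.length(N, 0);
        scored += 1;
        if (l < best) {
          std::pair<EdgeList, int> rr = descend(N, l);
          best = rr.second;
          keys.clear();
          arch.clear();
          tryAdd(rr.first);
          reset = true;
          return false;
        }
        if (l == best) tryAdd(N);
        return true;
      });
      if (reset) idx = 0; else idx++;
    }
  }

  std::vector<int> leafmap(n);
  for (int i = 0; i < n; i++) leafmap[i] = i + 1;
  CharacterVector trees(arch.size());
  for (size_t i = 0; i < arch.size(); i++)
    trees[i] = edgelist_newick(arch[i], leafmap, n);
  return List::create(_["best_length"] = best, _["trees"] = trees,
                      _["trees_scored"] = scored,
                      _["replicate_best"] = repBest,
                      _["hit_max_trees"] = ((int)arch.size() >= max_trees));
}

// ----------------------------------------------------------------------------
// exported: TBR neighbourhood of one tree (deduplicated, input excluded)
// ----------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector tbr_cpp(IntegerMatrix edge, int ntip) {
  if (ntip > 64) stop("TBR enumeration supports at most 64 taxa");
  EdgeList ed;
  for (int i = 0; i < edge.nrow(); i++)
    ed.push_back(TEdge(edge(i, 0) - 1, edge(i, 1) - 1));
  std::vector<uint64_t> self = canon_key(ed, ntip);
  std::set<std::vector<uint64_t>> seen;
  std::vector<std::string> out;
  std::vector<int> leafmap(ntip);
  for (int i = 0; i < ntip; i++) leafmap[i] = i + 1;
  for_each_tbr(ed, ntip, [&](const EdgeList& N) -> bool {
    std::vector<uint64_t> k = canon_key(N, ntip);
    if (k != self && !seen.count(k)) {
      seen.insert(k);
      out.push_back(edgelist_newick(N, leafmap, ntip));
    }
    return true;
  });
  return wrap(out);
}

// ----------------------------------------------------------------------------
// exported: exhaustive enumeration of unrooted binary topologies (n <= 10)
// ----------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector enumerate_cpp(int n) {
  if (n < 3 || n > 10) stop("enumeration guarded to 3..10 leaves");
  std::vector<std::string> out;
  std::vector<int> leafmap(n);
  for (int i = 0; i < n; i++) leafmap[i] = i + 1;
  EdgeList ed;
  ed.push_back(TEdge(n, 0));
  ed.push_back(TEdge(n, 1));
  ed.push_back(TEdge(n, 2));
  std::function<void(int)> rec = [&](int k) {
    if (k == n) {
      out.push_back(edgelist_newick(ed, leafmap, n));
      return;
    }
    size_t ne = ed.size();
    int node = n + k - 2;
    for (size_t e = 0; e < ne; e++) {
      insert_leaf(ed, k, node, e);
      rec(k + 1);
      undo_insert(ed, e);
    }
  };
  if (n == 3)
    out.push_back(edgelist_newick(ed, leafmap, n));
  else
    rec(3);
  return wrap(out);
}
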