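// Core parsimony machinery: Fitch scoring on unrooted cladograms,
// branch-and-bound enumeration of most parsimonious trees, stepwise
// addition and NNI/SPR/TBR hill climbing.
//
// Trees are held as adjacency lists over nodes 0..2n-3 (leaves 0..n-1,
// internal nodes n..2n-3, all internal nodes degree 3 in the unrooted
// binary form).  Character data arrive as per-leaf state bitmasks
// (bit s set <=> state s allowed at that leaf; missing = all observed
// states of the alphabet).  Duplicate columns are collapsed upstream and
// carried here as integer weights.

#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

typedef std::vector<std::array<int, 3>> Adj;

static inline void slot_add(Adj& adj, int u, int v) {
  for (int i = 0; i < 3; i++)
    if (adj[u][i] < 0) { adj[u][i] = v; return; }
  Rcpp::stop("internal error: node degree overflow");
}
static inline void slot_del(Adj& adj, int u, int v) {
  for (int i = 0; i < 3; i++)
    if (adj[u][i] == v) { adj[u][i] = -1; return; }
  Rcpp::stop("internal error: edge not present");
}
static inline void link2(Adj& adj, int u, int v) {
  slot_add(adj, u, v);
  slot_add(adj, v, u);
}
static inline void unlink2(Adj& adj, int u, int v) {
  slot_del(adj, u, v);
  slot_del(adj, v, u);
}

// ---------------------------------------------------------------------------
// Fitch scorer over an adjacency tree, rooted for traversal at a leaf.
// ---------------------------------------------------------------------------
struct Scorer {
  int ntax, nchar;
  std::vector<uint8_t> leafmask;  // ntax x nchar, row-major by leaf
  std::vector<int> weight;        // nchar
  // work buffers
  std::vector<uint8_t> nodemask;
  std::vector<int> parent, prefifo;

  void init(const IntegerMatrix& masks, const IntegerVector& w) {
    ntax = masks.nrow();
    nchar = masks.ncol();
    leafmask.assign((size_t)ntax * nchar, 0);
    for (int i = 0; i < ntax; i++)
      for (int c = 0; c < nchar; c++)
        leafmask[(size_t)i * nchar + c] = (uint8_t)masks(i, c);
    weight.assign(w.begin(), w.end());
    int maxnode = 2 * ntax;  // slack
    nodemask.assign((size_t)maxnode * nchar, 0);
    parent.assign(maxnode, -1);
    prefifo.reserve(maxnode);
  }

  // Minimum weighted changes over the tree reachable from startLeaf.
  // cap >= 0 enables early abort once the score exceeds cap (returned
  // value is then only a lower bound).  perchar, if non-null, receives
  // per-character weighted step counts (no early abort in that mode).
  int score(const Adj& adj, int startLeaf, int cap, int* perchar = nullptr) {
    int r = adj[startLeaf][0];
    if (r < 0) return 0;  // isolated leaf
    prefifo.clear();
    prefifo.push_back(r);
    parent[r] = startLeaf;
    for (size_t i = 0; i < prefifo.size(); i++) {
      int u = prefifo[i];
      for (int s = 0; s < 3; s++) {
        int nb = adj[u][s];
        if (nb >= 0 && nb != parent[u]) {
          parent[nb] = u;
          prefifo.push_back(nb);
        }
      }
    }
    int total = 0;
    for (int i = (int)prefifo.size() - 1; i >= 0; i--) {
      int u = prefifo[i];
      uint8_t* M = &nodemask[(size_t)u * nchar];
      if (u < ntax) {
        std::copy(leafmask.begin() + (size_t)u * nchar,
                  leafmask.begin() + (size_t)(u + 1) * nchar, M);
        continue;
      }
      int ch[3], nch = 0;
      for (int s = 0; s < 3; s++) {
        int nb = adj[u][s];
        if (nb >= 0 && nb != parent[u]) ch[nch++] = nb;
      }
      if (nch == 0) Rcpp::stop("internal error: childless internal node");
      const uint8_t* A = &nodemask[(size_t)ch[0] * nchar];
      if (nch == 1) {
        std::copy(A, A + nchar, M);
        continue;
      }
      const uint8_t* B = &nodemask[(size_t)ch[1] * nchar];
      for (int c = 0; c < nchar; c++) {
        uint8_t in = A[c] & B[c];
        if (in) M[c] = in;
        else {
          M[c] = A[c] | B[c];
          total += weight[c];
          if (perchar) perchar[c] += weight[c];
        }
      }
      if (nch == 3) {  // traversal root of an unrooted tree, or a polytomy
        const uint8_t* C = &nodemask[(size_t)ch[2] * nchar];
        for (int c = 0; c < nchar; c++) {
          uint8_t in = M[c] & C[c];
          if (in) M[c] = in;
          else {
            M[c] |= C[c];
            total += weight[c];
            if (perchar) perchar[c] += weight[c];
          }
        }
      }
      if (cap >= 0 && total > cap && !perchar) return total;
    }
    // startLeaf itself against its neighbour's set
    {
      const uint8_t* A = &leafmask[(size_t)startLeaf * nchar];
      const uint8_t* B = &nodemask[(size_t)r * nchar];
      for (int c = 0; c < nchar; c++) {
        if (!(A[c] & B[c])) {
          total += weight[c];
          if (perchar) perchar[c] += weight[c];
        }
      }
    }
    return total;
  }
};

// ---------------------------------------------------------------------------
// Conversions between adjacency form and ape-style edge matrices.
// ---------------------------------------------------------------------------

// Convert adjacency (subset of leaves present, given by presence in tree
// reachable from startLeaf) to an ape edge matrix rooted at the internal
// node adjacent to startLeaf.  Tip numbers keep their original 1-based ids.
static IntegerMatrix adj_to_edge(const Adj& adj, int ntax, int startLeaf) {
  int r = adj[startLeaf][0];
  // count present leaves / internals by DFS
  std::vector<int> order;
  std::vector<int> par(adj.size(), -2);
  order.push_back(r);
  par[r] = -1;
  for (size_t i = 0; i < order.size(); i++) {
    int u = order[i];
    for (int s = 0; s < 3; s++) {
      int nb = adj[u][s];
      if (nb >= 0 && par[nb] == -2) {
        par[nb] = u;
        order.push_back(nb);
      }
    }
  }
  int nint = 0;
  for (int u : order)
    if (u >= ntax) nint++;
  // internal renumbering: preorder, root first => ntax+1, ...
  std::vector<int> newid(adj.size(), 0);
  int nexti = ntax + 1;
  for (int u : order) {
    if (u >= ntax) newid[u] = nexti++;
    else newid[u] = u + 1;
  }
  IntegerMatrix edge((int)order.size() - 1, 2);
  int k = 0;
  for (size_t i = 1; i < order.size(); i++) {  // skip root
    int u = order[i];
    edge(k, 0) = newid[par[u]];
    edge(k, 1) = newid[u];
    k++;
  }
  return edge;
}

// Build adjacency from an ape edge matrix (tips 1..ntip).  Root of degree
// 2 is kept as-is (scorer tolerates it).  Returns adjacency over nodes
// 0..max-1 using ape numbering minus one.
static Adj edge_to_adj(const IntegerMatrix& edge, int nnode_total) {
  Adj adj(nnode_total, {-1, -1, -1});
  for (int i = 0; i < edge.nrow(); i++)
    link2(adj, edge(i, 0) - 1, edge(i, 1) - 1);
  return adj;
}

// Collapse a degree-2 node (ape root of a rooted binary tree) so search
// moves operate on a strictly unrooted tree.
static void suppress_degree2(Adj& adj, int ntax) {
  for (int u = ntax; u < (int)adj.size(); u++) {
    int deg = 0, nb[3];
    for (int s = 0; s < 3; s++)
      if (adj[u][s] >= 0) nb[deg++] = adj[u][s];
    if (deg == 2) {
      unlink2(adj, u, nb[0]);
      unlink2(adj, u, nb[1]);
      link2(adj, nb[0], nb[1]);
    }
  }
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_fitch_counts")]]
IntegerVector cpp_fitch_counts(IntegerMatrix edge, int ntip,
                               IntegerMatrix masks, IntegerVector weights) {
  if (ntip < 2) return IntegerVector(masks.ncol(), 0);
  int maxnode = ntip;
  for (int i = 0; i < edge.nrow(); i++)
    maxnode = std::max(maxnode, std::max(edge(i, 0), edge(i, 1)));
  Adj adj = edge_to_adj(edge, maxnode);
  Scorer sc;
  sc.init(masks, weights);
  sc.nodemask.assign((size_t)maxnode * sc.nchar, 0);
  sc.parent.assign(maxnode, -1);
  IntegerVector out(masks.ncol(), 0);
  if (ntip == 2) {
    for (int c = 0; c < masks.ncol(); c++)
      if (!(masks(0, c) & masks(1, c))) out[c] = weights[c];
    return out;
  }
  std::vector<int> perchar(masks.ncol(), 0);
  sc.score(adj, 0, -1, perchar.data());
  for (int c = 0; c < masks.ncol(); c++) out[c] = perchar[c];
  return out;
}

// ---------------------------------------------------------------------------
// Branch and bound / exhaustive enumeration
// ---------------------------------------------------------------------------
struct BB {
  Scorer sc;
  int ntax;
  std::vector<int> order;       // addition order, 0-based leaf ids
  std::vector<int> boundrest;   // boundrest[k]: lower bound increment for order[k..]
  Adj adj;
  std::vector<std::pair<int, int>> edges;
  long long neval = 0;
  int best;
  bool use_bound, track_all;
  int maxtrees;
  bool overflow = false;
  std::vector<IntegerMatrix> found;

  void attach(int leaf, int eidx, int w) {
    int u = edges[eidx].first, v = edges[eidx].second;
    unlink2(adj, u, v);
    link2(adj, u, w);
    link2(adj, w, v);
    link2(adj, w, leaf);
    edges[eidx] = {u, w};
    edges.push_back({w, v});
    edges.push_back({w, leaf});
  }
  void detach(int leaf, int eidx, int w, int u, int v) {
    edges.pop_back();
    edges.pop_back();
    edges[eidx] = {u, v};
    unlink2(adj, w, leaf);
    unlink2(adj, u, w);
    unlink2(adj, w, v);
    link2(adj, u, v);
  }

  void rec(int k) {
    int t = order[k];
    int w = ntax + k - 2;
    size_t ecnt = edges.size();
    for (size_t i = 0; i < ecnt; i++) {
      int u = edges[i].first, v = edges[i].second;
      attach(t, (int)i, w);
      neval++;
      int cap = use_bound ? best - boundrest[k + 1] : -1;
      int s = sc.score(adj, order[0], cap);
      if (k + 1 == ntax) {
        if (s < best) {
          best = s;
          found.clear();
          overflow = false;
        }
        if (s == best && track_all) {
          if ((int)found.size() < maxtrees)
            found.push_back(adj_to_edge(adj, ntax, order[0]));
          else overflow = true;
        }
      } else if (!use_bound || s + boundrest[k + 1] <= best) {
        rec(k + 1);
      }
      detach(t, (int)i, w, u, v);
    }
  }
};

// masks_full: missing = full alphabet mask; masks_obs: missing = 0.
// incumbent: known-achievable upper bound on the optimum (INT-like large
// value when unknown).  Enumerates every binary unrooted topology via
// sequential insertion (each topology generated exactly once).
// [[Rcpp::export(name = ".cpp_bab")]]
List cpp_bab(IntegerMatrix masks_full, IntegerMatrix masks_obs,
             IntegerVector weights, IntegerVector order0, int incumbent,
             bool use_bound, int maxtrees) {
  int ntax = masks_full.nrow(), nchar = masks_full.ncol();
  if (ntax < 3) Rcpp::stop("need at least 3 taxa");
  BB bb;
  bb.sc.init(masks_full, weights);
  bb.ntax = ntax;
  bb.order.assign(order0.begin(), order0.end());
  bb.best = incumbent;
  bb.use_bound = use_bound;
  bb.track_all = true;
  bb.maxtrees = maxtrees;

  // per-level lower-bound increments: states present among unplaced taxa
  // (observed cells only) but absent among placed taxa
  bb.boundrest.assign(ntax + 1, 0);
  {
    std::vector<uint8_t> pre(nchar, 0);
    std::vector<std::vector<uint8_t>> sufs(ntax + 1,
                                           std::vector<uint8_t>(nchar, 0));
    for (int k = ntax - 1; k >= 0; k--) {
      for (int c = 0; c < nchar; c++)
        sufs[k][c] =
            sufs[k + 1][c] | (uint8_t)masks_obs(bb.order[k], c);
    }
    for (int k = 0; k <= ntax; k++) {
      if (k > 0)
        for (int c = 0; c < nchar; c++)
          pre[c] |= (uint8_t)masks_obs(bb.order[k - 1], c);
      int b = 0;
      for (int c = 0; c < nchar; c++) {
        uint8_t extra = sufs[k][c] & (uint8_t)~pre[c];
        int pc = 0;
        while (extra) { pc += extra & 1; extra >>= 1; }
        b += pc * weights[c];
      }
      bb.boundrest[k] = b;
    }
  }

  bb.adj.assign(2 * ntax, {-1, -1, -1});
  int root = ntax;  // first internal node
  for (int i = 0; i < 3; i++) link2(bb.adj, root, bb.order[i]);
  bb.edges = {{root, bb.order[0]}, {root, bb.order[1]}, {root, bb.order[2]}};

  if (ntax == 3) {
    bb.best = bb.sc.score(bb.adj, bb.order[0], -1);
    bb.neval = 1;
    bb.found.push_back(adj_to_edge(bb.adj, ntax, bb.order[0]));
  } else {
    bb.rec(3);
  }
  return List::create(Named("L") = bb.best, Named("trees") = wrap(bb.found),
                      Named("n_evaluated") = (double)bb.neval,
                      Named("overflow") = bb.overflow);
}

// ---------------------------------------------------------------------------
// Stepwise addition
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_stepwise")]]
List cpp_stepwise(IntegerMatrix masks_full, IntegerVector weights,
                  IntegerVector order0, int seed) {
  int ntax = masks_full.nrow();
  if (ntax < 3) Rcpp::stop("need at least 3 taxa");
  std::mt19937 rng((uint32_t)seed);
  BB bb;
  bb.sc.init(masks_full, weights);
  bb.ntax = ntax;
  bb.order.assign(order0.begin(), order0.end());
  bb.adj.assign(2 * ntax, {-1, -1, -1});
  int root = ntax;
  for (int i = 0; i < 3; i++) link2(bb.adj, root, bb.order[i]);
  bb.edges = {{root, bb.order[0]}, {root, bb.order[1]}, {root, bb.order[2]}};
  int L = bb.sc.score(bb.adj, bb.order[0], -1);
  for (int k = 3; k < ntax; k++) {
    int t = bb.order[k], w = ntax + k - 2;
    int bestS = INT_MAX, nties = 0, pick = -1;
    size_t ecnt = bb.edges.size();
    for (size_t i = 0; i < ecnt; i++) {
      int u = bb.edges[i].first, v = bb.edges[i].second;
      bb.attach(t, (int)i, w);
      int s = bb.sc.score(bb.adj, bb.order[0], bestS);
      bb.detach(t, (int)i, w, u, v);
      if (s < bestS) {
        bestS = s;
        nties = 1;
        pick = (int)i;
      } else if (s == bestS) {
        nties++;
        if ((int)(rng() % nties) == 0) pick = (int)i;
      }
    }
    bb.attach(t, pick, w);
    L = bestS;
  }
  return List::create(Named("edge") = adj_to_edge(bb.adj, ntax, bb.order[0]),
                      Named("L") = L);
}

// ---------------------------------------------------------------------------
// Branch swapping (NNI / SPR / TBR) hill climbing
// ---------------------------------------------------------------------------
struct Climber {
  Scorer sc;
  int ntax;
  int startLeaf = 0;

  // component edge collection avoiding one blocked node
  void comp_edges(const Adj& adj, int from, int avoid,
                  std::vector<std::pair<int, int>>& out,
                  std::vector<int>& seen, int stamp) {
    out.clear();
    std::vector<int> fifo{from};
    seen[from] = stamp;
    for (size_t i = 0; i < fifo.size(); i++) {
      int u = fifo[i];
      for (int s = 0; s < 3; s++) {
        int nb = adj[u][s];
        if (nb < 0 || nb == avoid) continue;
        if (u < nb) out.push_back({u, nb});
        if (seen[nb] != stamp) {
          seen[nb] = stamp;
          fifo.push_back(nb);
        }
      }
    }
  }

  template <typename F>
  void neighbors(const Adj& adj, int move, F&& visit) {
    std::vector<std::pair<int, int>> all;
    std::vector<int> seen(adj.size(), -1);
    int stamp = 0;
    for (int u = 0; u < (int)adj.size(); u++)
      for (int s = 0; s < 3; s++)
        if (adj[u][s] > u) all.push_back({u, adj[u][s]});

    if (move == 0) {  // NNI
      for (auto& e : all) {
        int u = e.first, v = e.second;
        if (u < ntax || v < ntax) continue;
        int a[2], b[2], na = 0, nb2 = 0;
        for (int s = 0; s < 3; s++) {
          if (adj[u][s] >= 0 && adj[u][s] != v) a[na++] = adj[u][s];
          if (adj[v][s] >= 0 && adj[v][s] != u) b[nb2++] = adj[v][s];
        }
        for (int j = 0; j < 2; j++) {
          Adj cand = adj;
          unlink2(cand, u, a[0]);
          unlink2(cand, v, b[j]);
          link2(cand, u, b[j]);
          link2(cand, v, a[0]);
          visit(cand);
        }
      }
      return;
    }
    if (move == 1) {  // SPR
      std::vector<std::pair<int, int>> rem;
      for (auto& e : all) {
        for (int dir = 0; dir < 2; dir++) {
          int p = dir ? e.second : e.first;  // attachment node, stays with rest
          int x = dir ? e.first : e.second;  // pruned subtree root
          if (p < ntax) continue;            // need internal attachment
          int q[2], nq = 0;
          for (int s = 0; s < 3; s++)
            if (adj[p][s] >= 0 && adj[p][s] != x) q[nq++] = adj[p][s];
          Adj base = adj;
          unlink2(base, p, q[0]);
          unlink2(base, p, q[1]);
          link2(base, q[0], q[1]);
          comp_edges(base, q[0], p, rem, seen, ++stamp);
          for (auto& t : rem) {
            if ((t.first == q[0] && t.second == q[1]) ||
                (t.first == q[1] && t.second == q[0]))
              continue;  // original position
            Adj cand = base;
            unlink2(cand, t.first, t.second);
            link2(cand, t.first, p);
            link2(cand, p, t.second);
            visit(cand);
          }
        }
      }
      return;
    }
    // TBR: bisect internal edges and reconnect any edge pair; terminal
    // edges contribute their SPR-style moves.
    std::vector<std::pair<int, int>> eA, eB;
    for (auto& e : all) {
      int u = e.first, v = e.second;
      if (u >= ntax && v >= ntax) {
        int a[2], b[2], na = 0, nb2 = 0;
        for (int s = 0; s < 3; s++) {
          if (adj[u][s] >= 0 && adj[u][s] != v) a[na++] = adj[u][s];
          if (adj[v][s] >= 0 && adj[v][s] != u) b[nb2++] = adj[v][s];
        }
        Adj base = adj;
        unlink2(base, u, v);
        unlink2(base, u, a[0]);
        unlink2(base, u, a[1]);
        link2(base, a[0], a[1]);
        unlink2(base, v, b[0]);
        unlink2(base, v, b[1]);
        link2(base, b[0], b[1]);
        comp_edges(base, a[0], -1, eA, seen, ++stamp);
        comp_edges(base, b[0], -1, eB, seen, ++stamp);
        for (auto& ea : eA) {
          bool origA = (ea.first == std::min(a[0], a[1]) &&
                        ea.second == std::max(a[0], a[1]));
          for (auto& eb : eB) {
            bool origB = (eb.first == std::min(b[0], b[1]) &&
                          eb.second == std::max(b[0], b[1]));
            if (origA && origB) continue;  // recreates the input tree
            Adj cand = base;
            unlink2(cand, ea.first, ea.second);
            link2(cand, ea.first, u);
            link2(cand, u, ea.second);
            unlink2(cand, eb.first, eb.second);
            link2(cand, eb.first, v);
            link2(cand, v, eb.second);
            link2(cand, u, v);
            visit(cand);
          }
        }
      } else if (u >= ntax || v >= ntax) {
        // terminal edge: re-insert the leaf anywhere (SPR on that leaf)
        int p = (u >= ntax) ? u : v;
        int x = (u >= ntax) ? v : u;
        int q[2], nq = 0;
        for (int s = 0; s < 3; s++)
          if (adj[p][s] >= 0 && adj[p][s] != x) q[nq++] = adj[p][s];
        Adj base = adj;
        unlink2(base, p, q[0]);
        unlink2(base, p, q[1]);
        link2(base, q[0], q[1]);
        comp_edges(base, q[0], p, eA, seen, ++stamp);
        for (auto& t : eA) {
          if ((t.first == std::min(q[0], q[1]) &&
               t.second == std::max(q[0], q[1])))
            continue;
          Adj cand = base;
          unlink2(cand, t.first, t.second);
          link2(cand, t.first, p);
          link2(cand, p, t.second);
          visit(cand);
        }
      }
    }
  }
};

// move: 0 = NNI, 1 = SPR, 2 = TBR
// [[Rcpp::export(name = ".cpp_hillclimb")]]
List cpp_hillclimb(IntegerMatrix edge, int ntip, IntegerMatrix masks_full,
                   IntegerVector weights, int move, bool collect_equal,
                   int maxequal) {
  Climber cl;
  cl.sc.init(masks_full, weights);
  cl.ntax = ntip;
  int maxnode = ntip;
  for (int i = 0; i < edge.nrow(); i++)
    maxnode = std::max(maxnode, std::max(edge(i, 0), edge(i, 1)));
  Adj adj(2 * ntip, {-1, -1, -1});
  for (int i = 0; i < edge.nrow(); i++)
    link2(adj, edge(i, 0) - 1, edge(i, 1) - 1);
  suppress_degree2(adj, ntip);
  cl.sc.nodemask.assign((size_t)2 * ntip * cl.sc.nchar, 0);
  cl.sc.parent.assign(2 * ntip, -1);

  int cur = cl.sc.score(adj, 0, -1);
  long long neval = 0;
  bool improved = true;
  while (improved && ntip >= 4) {
    improved = false;
    Adj bestadj;
    int bestsc = cur;
    cl.neighbors(adj, move, [&](const Adj& cand) {
      neval++;
      int s = cl.sc.score(cand, 0, bestsc);
      if (s < bestsc) {
        bestsc = s;
        bestadj = cand;
      }
    });
    if (bestsc < cur) {
      adj = bestadj;
      cur = bestsc;
      improved = true;
    }
  }
  std::vector<IntegerMatrix> equals;
  if (collect_equal && ntip >= 4) {
    cl.neighbors(adj, move, [&](const Adj& cand) {
      if ((int)equals.size() >= maxequal) return;
      int s = cl.sc.score(cand, 0, cur);
      if (s == cur) equals.push_back(adj_to_edge(cand, ntip, 0));
    });
  }
  return List::create(Named("edge") = adj_to_edge(adj, ntip, 0),
                      Named("L") = cur, Named("equal") = wrap(equals),
                      Named("n_evaluated") = (double)neval);
}
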