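// Pathgroups engine: greedy cycle maximization for the gene-order median
// and small phylogeny problems under DCJ distance.
//
// Vertices are gene extremities 1..2n (gene g: tail 2g-1, head 2g).
// For every tree edge we keep one shared alternating-path structure over
// the breakpoint graph of that edge: far[v] is the far endpoint of the
// path having v as an open endpoint (CAP = path runs into a chromosome
// cap, 0 = v is interior, far[v] == v = both remaining open slots of the
// component sit at v).  A leaf side of an edge is complete from the
// start; an ancestor's side grows as red edges are chosen.  The same red
// edge an ancestor picks is added to all three of its incident edges at
// once, and is seen as blue material by a neighbouring ancestor.
//
// Priorities: (cycles now, best next-step cycles, net change in potential
// cycles over affected groups, best second-step cycles), compared
// lexicographically; the three schemes use prefixes of this key.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <array>
#include <algorithm>
using namespace Rcpp;

static const int CAP = -1;

enum Scheme { BASIC = 0, REFINED = 1, LOOKAHEAD2 = 2 };

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Priority level index (0 = highest priority).  The basic scheme has 7
// levels, the refined 55, the two-step look-ahead 165.
static int level_of(int scheme, int c, int b, int d, int s) {
  int base;
  if (c >= 3) {
    base = 0;
  } else {
    int cc = clampi(c, 1, 2), bb = clampi(b, 1, 3);
    if (scheme == BASIC) return 1 + (2 - cc) * 3 + (3 - bb);
    int dd = clampi(d, -4, 4);
    base = 1 + (2 - cc) * 27 + (3 - bb) * 9 + (4 - dd);
  }
  if (scheme == BASIC) return 0;
  if (scheme == REFINED) return base;
  return base * 3 + (3 - clampi(s, 1, 3));
}

static int n_levels(int scheme) {
  return scheme == BASIC ? 7 : (scheme == REFINED ? 55 : 165);
}

struct Edge {
  int anc1;        // acting ancestor index owning side 1 (always >= 0)
  int anc2;        // ancestor on side 2, or -1 if side 2 is a leaf
  std::vector<int> far;  // size nv+1
};

struct Change {
  int kind;   // 0 far, 1 done, 2 frag, 3 red
  int i, v, old;
};

struct GroupRef {
  int a, v;
  bool operator==(const GroupRef& o) const { return a == o.a && v == o.v; }
};

struct Engine {
  int n, nv, A, scheme;
  std::vector<Edge> edges;
  std::vector<std::array<int, 3>> beid;          // branch -> edge id, per ancestor
  std::vector<std::vector<char>> done;           // A x nv+1
  std::vector<std::vector<int>> fragOther;       // A x nv+1
  std::vector<std::vector<int>> redTo;           // A x nv+1
  std::vector<std::vector<signed char>> gc;      // cached cycles value
  std::vector<std::vector<int>> lvl;             // current level, -1 none
  std::vector<std::vector<int>> tgt;             // chosen red target
  std::vector<std::deque<long long>> buckets;
  int minLvl;
  std::vector<Change> log;
  bool logging;

  long long steps, cyclesMade, liveCount;
  int maxSec, maxTer;
  bool conservationOk;

  // ---- state mutation with optional undo log ----
  void setFar(int e, int v, int val) {
    if (logging) log.push_back({0, e, v, edges[e].far[v]});
    edges[e].far[v] = val;
  }
  void setDone(int a, int v, char val) {
    if (logging) log.push_back({1, a, v, done[a][v]});
    done[a][v] = val;
  }
  void setFrag(int a, int v, int val) {
    if (logging) log.push_back({2, a, v, fragOther[a][v]});
    fragOther[a][v] = val;
  }
  void undoTo(size_t mark) {
    while (log.size() > mark) {
      const Change& ch = log.back();
      if (ch.kind == 0) edges[ch.i].far[ch.v] = ch.old;
      else if (ch.kind == 1) done[ch.i][ch.v] = (char)ch.old;
      else fragOther[ch.i][ch.v] = ch.old;
      log.pop_back();
    }
  }

  bool live(int a, int v) const { return !done[a][v]; }

  // Is the colour of the side opposite `a` present at v on edge e?
  // Leaf sides are complete; an ancestor side has its edge at v iff that
  // ancestor has fixed its red edge at v.
  bool hasOther(int e, int a, int v) const {
    const Edge& E = edges[e];
    int other = (E.anc1 == a) ? E.anc2 : E.anc1;
    if (other < 0) return true;
    return done[other][v] != 0;
  }

  // Add the edge of ancestor a's colour between x and y on edge e.
  // Returns 1 if a complete alternating cycle was closed.  Appends the
  // remaining open-slot vertices of the merged component to `affected`
  // as (edge, vertex) pairs.
  int applyEdgeOnBranch(int e, int a, int x, int y,
                        std::vector<std::pair<int, int>>& affected) {
    std::vector<int>& far = edges[e].far;
    int fx = far[x], fy = far[y];
    if (fx == y) {
      bool ax = !hasOther(e, a, x), ay = !hasOther(e, a, y);
      if (!ax && !ay) { setFar(e, x, 0); setFar(e, y, 0); return 1; }
      if (ax && ay) {
        affected.push_back({e, x}); affected.push_back({e, y});
      } else if (ax) {
        setFar(e, x, x); setFar(e, y, 0); affected.push_back({e, x});
      } else {
        setFar(e, y, y); setFar(e, x, 0); affected.push_back({e, y});
      }
      return 0;
    }
    const int NONE = -2;
    int ls, rs;
    if (fx == x) {
      ls = hasOther(e, a, x) ? NONE : x;
      if (ls == NONE) setFar(e, x, 0);
    } else { ls = fx; setFar(e, x, 0); }
    if (fy == y) {
      rs = hasOther(e, a, y) ? NONE : y;
      if (rs == NONE) setFar(e, y, 0);
    } else { rs = fy; setFar(e, y, 0); }
    if (ls == NONE && rs == NONE) return 1;   // merged component closed & complete
    if (ls == NONE) {
      if (rs > 0) { setFar(e, rs, rs); affected.push_back({e, rs}); }
      return 0;                               // rs == CAP: no open slot left
    }
    if (rs == NONE) {
      if (ls > 0) { setFar(e, ls, ls); affected.push_back({e, ls}); }
      return 0;
    }
    if (ls == CAP && rs == CAP) return 0;     // cap-to-cap path: dead
    if (ls == CAP) { setFar(e, rs, CAP); affected.push_back({e, rs}); return 0; }
    if (rs == CAP) { setFar(e, ls, CAP); affected.push_back({e, ls}); return 0; }
    setFar(e, ls, rs); setFar(e, rs, ls);
    affected.push_back({e, ls}); affected.push_back({e, rs});
    return 0;
  }

  // Full application of red edge x-y at ancestor a (all three branches,
  // done flags, fragment join).  Returns cycles closed; records fragment
  // endpoints p,q of the joined fragment.
  int applyRed(int a, int x, int y,
               std::vector<std::pair<int, int>>& affected, int& p, int& q) {
    int cyc = 0;
    for (int k = 0; k < 3; ++k)
      cyc += applyEdgeOnBranch(beid[a][k], a, x, y, affected);
    setDone(a, x, 1); setDone(a, y, 1);
    p = fragOther[a][x]; q = fragOther[a][y];
    setFrag(a, x, 0); setFrag(a, y, 0);
    setFrag(a, p, q); setFrag(a, q, p);
    return cyc;
  }

  // Candidate red targets of group (a,x) and the cycles each creates now.
  // cands/cyc filled; returns max cycles (0 when no candidate creates a
  // cycle, i.e. the group currently has no priority).
  int computeCycles(int a, int x, std::vector<int>* candsOut = nullptr) {
    if (!live(a, x)) return 0;
    int cands[3], cyc[3], nc = 0;
    for (int k = 0; k < 3; ++k) {
      int e = beid[a][k];
      int f = edges[e].far[x];
      if (f <= 0 || f == x) continue;
      if (!live(a, f)) continue;
      if (fragOther[a][x] == f) continue;     // would close a circular chromosome
      bool seen = false;
      for (int i = 0; i < nc; ++i) if (cands[i] == f) { seen = true; break; }
      if (seen) continue;
      // net cycle count of adding red x-f: +1 per branch whose path closes
      // into a complete alternating cycle, -1 per branch where the edge
      // would merge two cap-ended paths into a single frozen component
      // (caps never receive red edges, so that join forfeits one capping
      // cycle for certain)
      int c = 0;
      for (int k2 = 0; k2 < 3; ++k2) {
        int e2 = beid[a][k2];
        int fx = edges[e2].far[x], ff = edges[e2].far[f];
        if (fx == f) {
          if (hasOther(e2, a, x) && hasOther(e2, a, f)) ++c;
        } else if (fx == CAP && ff == CAP) {
          --c;
        }
      }
      cands[nc] = f; cyc[nc] = c; ++nc;
    }
    int cmax = 0;
    for (int i = 0; i < nc; ++i) cmax = std::max(cmax, cyc[i]);
    if (cmax == 0) return 0;
    if (candsOut) {
      candsOut->clear();
      for (int i = 0; i < nc; ++i)
        if (cyc[i] == cmax) candsOut->push_back(cands[i]);
      std::sort(candsOut->begin(), candsOut->end());
    }
    return cmax;
  }

  // Collect the groups affected by an application whose per-branch slot
  // changes are in `affected`: for each (edge, vertex) both incident
  // ancestors' live groups at that vertex.
  void affectedGroups(const std::vector<std::pair<int, int>>& affected,
                      std::vector<GroupRef>& out) {
    out.clear();
    for (const auto& ev : affected) {
      const Edge& E = edges[ev.first];
      int nds[2] = {E.anc1, E.anc2};
      for (int nd : nds) {
        if (nd < 0) continue;
        if (!live(nd, ev.second)) continue;
        GroupRef g{nd, ev.second};
        if (std::find(out.begin(), out.end(), g) == out.end())
          out.push_back(g);
      }
    }
  }

  // Partners (tertiary groups) of the groups in G2, excluding x, y and
  // the members of G2 themselves.
  void tertiaryGroups(const std::vector<GroupRef>& G2, int x, int y,
                      std::vector<GroupRef>& out) {
    out.clear();
    for (const auto& g : G2) {
      for (int k = 0; k < 3; ++k) {
        int e = beid[g.a][k];
        int w = edges[e].far[g.v];
        if (w <= 0 || w == g.v || w == x || w == y) continue;
        if (!live(g.a, w)) continue;
        GroupRef t{g.a, w};
        if (std::find(G2.begin(), G2.end(), t) != G2.end()) continue;
        if (std::find(out.begin(), out.end(), t) == out.end())
          out.push_back(t);
      }
    }
  }

  // One-candidate look-ahead: simulate red x-f at a, measure
  // (best_next, net_delta, second_step).  State is restored via the log.
  void lookahead(int a, int x, int f, int& bOut, int& dOut, int& sOut) {
    size_t mark = log.size();
    bool wasLogging = logging;
    logging = true;
    std::vector<std::pair<int, int>> aff;
    int p, q;
    applyRed(a, x, f, aff, p, q);
    std::vector<GroupRef> G2;
    affectedGroups(aff, G2);
    int b = 0;
    std::vector<int> postC(G2.size());
    for (size_t i = 0; i < G2.size(); ++i) {
      postC[i] = computeCycles(G2[i].a, G2[i].v);
      b = std::max(b, postC[i]);
    }
    bOut = clampi(b, 1, 3);
    dOut = 0;
    if (scheme >= REFINED) {
      std::vector<GroupRef> T, F;
      tertiaryGroups(G2, x, f, T);
      for (int w : {p, q}) {
        if (w <= 0 || w == x || w == f || !live(a, w)) continue;
        GroupRef g{a, w};
        if (std::find(G2.begin(), G2.end(), g) != G2.end()) continue;
        if (std::find(T.begin(), T.end(), g) != T.end()) continue;
        if (std::find(F.begin(), F.end(), g) == F.end()) F.push_back(g);
      }
      int d = 0;
      for (size_t i = 0; i < G2.size(); ++i)
        d += postC[i] - gc[G2[i].a][G2[i].v];
      for (const auto& g : T) d += computeCycles(g.a, g.v) - gc[g.a][g.v];
      for (const auto& g : F) d += computeCycles(g.a, g.v) - gc[g.a][g.v];
      dOut = d;
    }
    sOut = 1;
    if (scheme >= LOOKAHEAD2) {
      // best next group and its best candidate, then the cycles available
      // one step beyond it
      int besti = -1, bestc = 0;
      for (size_t i = 0; i < G2.size(); ++i)
        if (postC[i] > bestc) { bestc = postC[i]; besti = (int)i; }
      if (besti >= 0) {
        std::vector<int> cands2;
        computeCycles(G2[besti].a, G2[besti].v, &cands2);
        if (!cands2.empty()) {
          int f2 = cands2[0];
          std::vector<std::pair<int, int>> aff2;
          int p2, q2;
          applyRed(G2[besti].a, G2[besti].v, f2, aff2, p2, q2);
          std::vector<GroupRef> G3;
          affectedGroups(aff2, G3);
          int s = 0;
          for (const auto& g : G3)
            s = std::max(s, computeCycles(g.a, g.v));
          sOut = clampi(s, 1, 3);
        }
      }
    }
    undoTo(mark);
    logging = wasLogging;
  }

  void pushBucket(int a, int x) {
    int l = lvl[a][x];
    if (l < 0) return;
    buckets[l].push_back((long long)a * (nv + 1) + x);
    if (l < minLvl) minLvl = l;
  }

  // Recompute the full priority of group (a,x); update caches and bucket.
  void priorityOf(int a, int x) {
    if (!live(a, x)) { lvl[a][x] = -1; gc[a][x] = 0; tgt[a][x] = 0; return; }
    std::vector<int> cands;
    int cmax = computeCycles(a, x, &cands);
    gc[a][x] = (signed char)cmax;
    if (cmax == 0) { lvl[a][x] = -1; tgt[a][x] = 0; return; }
    if (cmax == 3 && scheme != LOOKAHEAD2) {
      // top basic/refined level; any 3-cycle candidate is equivalent
      lvl[a][x] = 0; tgt[a][x] = cands[0]; pushBucket(a, x);
      return;
    }
    int bb = -1, bd = 0, bs = 0, bf = 0;
    for (int f : cands) {
      int b, d, s;
      lookahead(a, x, f, b, d, s);
      bool better;
      if (bb < 0) better = true;
      else if (b != bb) better = b > bb;
      else if (scheme >= REFINED && d != bd) better = d > bd;
      else if (scheme >= LOOKAHEAD2 && s != bs) better = s > bs;
      else better = false;   // equal key: keep smaller f (cands ascending)
      if (better) { bb = b; bd = d; bs = s; bf = f; }
    }
    lvl[a][x] = level_of(scheme, cmax, bb, bd, bs);
    tgt[a][x] = bf;
    pushBucket(a, x);
  }

  // Instrumentation per the structural bound: secondary groups are the
  // live groups of the acting node at the merged-path endpoints; tertiary
  // groups their partners.
  void instrument(int a, int x, int y,
                  const std::vector<std::pair<int, int>>& aff) {
    std::vector<GroupRef> sec;
    for (const auto& ev : aff) {
      int v = ev.second;
      if (v == x || v == y || !live(a, v)) continue;
      GroupRef g{a, v};
      if (std::find(sec.begin(), sec.end(), g) == sec.end()) sec.push_back(g);
    }
    std::vector<GroupRef> ter;
    tertiaryGroups(sec, x, y, ter);
    maxSec = std::max(maxSec, (int)sec.size());
    maxTer = std::max(maxTer, (int)ter.size());
  }

  // ---- main loop ----
  void solve() {
    steps = 0; cyclesMade = 0; maxSec = 0; maxTer = 0;
    conservationOk = true;
    long long init = liveCount;
    while (true) {
      int a = -1, x = -1;
      while (minLvl < (int)buckets.size()) {
        std::deque<long long>& q = buckets[minLvl];
        bool found = false;
        while (!q.empty()) {
          long long id = q.front();
          int ca = (int)(id / (nv + 1)), cx = (int)(id % (nv + 1));
          if (live(ca, cx) && lvl[ca][cx] == minLvl) {
            a = ca; x = cx; found = true; break;
          }
          q.pop_front();
        }
        if (found) break;
        ++minLvl;
      }
      if (a < 0) break;
      buckets[minLvl].pop_front();
      int y = tgt[a][x];
      std::vector<std::pair<int, int>> aff;
      int p, q;
      int cyc = applyRed(a, x, y, aff, p, q);
      cyclesMade += cyc;
      redTo[a][x] = y; redTo[a][y] = x;
      ++steps;
      liveCount -= 2;
      if (liveCount != init - 2 * steps) conservationOk = false;
      instrument(a, x, y, aff);
      // priority updates: affected groups, their partners, the fragment
      // endpoint groups
      std::vector<GroupRef> G2, T;
      affectedGroups(aff, G2);
      tertiaryGroups(G2, x, y, T);
      for (const auto& g : G2) priorityOf(g.a, g.v);
      for (const auto& g : T) priorityOf(g.a, g.v);
      for (int w : {p, q})
        if (w > 0 && w != x && w != y && live(a, w)) priorityOf(a, w);
    }
  }
};

// [[Rcpp::export]]
List pg_solve_cpp(int n, IntegerMatrix btype, IntegerMatrix bpeer,
                  List leaf_partner, int scheme,
                  bool init_levels = false) {
  Engine E;
  E.n = n; E.nv = 2 * n; E.A = btype.nrow(); E.scheme = scheme;
  E.logging = false;
  int A = E.A, nv = E.nv;
  E.beid.resize(A);
  // build edges: internal edges shared between two ancestors
  std::vector<std::vector<int>> seen(A, std::vector<int>(A, -1));
  for (int a = 0; a < A; ++a) {
    for (int k = 0; k < 3; ++k) {
      if (btype(a, k) == 0) {
        Edge e; e.anc1 = a; e.anc2 = -1;
        IntegerVector lp = leaf_partner[bpeer(a, k) - 1];
        if (lp.size() != nv) stop("leaf partner vector has wrong length");
        e.far.assign(nv + 1, 0);
        for (int v = 1; v <= nv; ++v)
          e.far[v] = (lp[v - 1] == 0) ? CAP : lp[v - 1];
        E.edges.push_back(e);
        E.beid[a][k] = (int)E.edges.size() - 1;
      } else {
        int b = bpeer(a, k) - 1;
        if (seen[a][b] >= 0) { E.beid[a][k] = seen[a][b]; continue; }
        Edge e; e.anc1 = a; e.anc2 = b;
        e.far.assign(nv + 1, 0);
        for (int v = 1; v <= nv; ++v) e.far[v] = v;
        E.edges.push_back(e);
        E.beid[a][k] = (int)E.edges.size() - 1;
        seen[a][b] = seen[b][a] = E.beid[a][k];
      }
    }
  }
  E.done.assign(A, std::vector<char>(nv + 1, 0));
  E.fragOther.assign(A, std::vector<int>(nv + 1, 0));
  E.redTo.assign(A, std::vector<int>(nv + 1, 0));
  E.gc.assign(A, std::vector<signed char>(nv + 1, 0));
  E.lvl.assign(A, std::vector<int>(nv + 1, -1));
  E.tgt.assign(A, std::vector<int>(nv + 1, 0));
  for (int a = 0; a < A; ++a)
    for (int g = 1; g <= n; ++g) {
      E.fragOther[a][2 * g - 1] = 2 * g;
      E.fragOther[a][2 * g] = 2 * g - 1;
    }
  E.buckets.assign(n_levels(scheme), std::deque<long long>());
  E.minLvl = n_levels(scheme);
  E.liveCount = (long long)A * nv;
  // seed the potential-cycles cache of every group before any look-ahead
  // reads it, so initial priorities do not depend on initialization order
  for (int a = 0; a < A; ++a)
    for (int v = 1; v <= nv; ++v)
      E.gc[a][v] = (signed char)E.computeCycles(a, v);
  for (int a = 0; a < A; ++a)
    for (int v = 1; v <= nv; ++v) E.priorityOf(a, v);

  IntegerMatrix initLvl;
  if (init_levels) {
    initLvl = IntegerMatrix(A, nv);
    for (int a = 0; a < A; ++a)
      for (int v = 1; v <= nv; ++v) initLvl(a, v - 1) = E.lvl[a][v];
  }

  E.solve();

  IntegerMatrix red(A, nv);
  for (int a = 0; a < A; ++a)
    for (int v = 1; v <= nv; ++v) red(a, v - 1) = E.redTo[a][v];
  List out = List::create(
    _["red"] = red,
    _["steps"] = (double)E.steps,
    _["cycles_made"] = (double)E.cyclesMade,
    _["init_groups"] = (double)((long long)A * nv),
    _["final_groups"] = (double)E.liveCount,
    _["conservation_ok"] = E.conservationOk,
    _["max_secondary"] = E.maxSec,
    _["max_tertiary"] = E.maxTer);
  if (init_levels) out["init_levels"] = initLvl;
  return out;
}

// Level index for a priority key; used to enumerate the distinct
// comparison classes of each scheme.
// [[Rcpp::export]]
IntegerVector pg_level_of_cpp(int scheme, IntegerVector c, IntegerVector b,
                              IntegerVector d, IntegerVector s) {
  int m = c.size();
  IntegerVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = level_of(scheme, c[i], b[i], d[i], s[i]);
  return out;
}

// [[Rcpp::export]]
int pg_n_levels_cpp(int scheme) { return n_levels(scheme); }
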