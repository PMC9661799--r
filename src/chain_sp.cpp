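// Lazy (on-demand) composition + shortest path for a chain of weighted
// finite-state transducers over the tropical semiring.
//
// The chain  x o M1 o M2 o ... o Mm o y  (x, y linear acceptors) is never
// materialized: a best-first (Dijkstra) search runs over the implicit
// product automaton.  All machines here are synchronous (every transition
// consumes one input symbol and emits one output symbol), so the product
// state is (position, per-machine states) and can be bit-packed into 64
// bits.  Search granularity is per machine arc: a "fine" state additionally
// carries how many machines have already consumed the current symbol and
// the symbol currently flowing between machines.  Ties in cost are broken
// on the packed state, which makes reported optimal paths deterministic.
//
// A second entry point exploits the separator structure of the MED event
// chain: segmental event machines are forced back to their idle state at
// every chromosome separator "X", and only the genome-wide WGD commitment
// survives across separators.  The shortest distance therefore factorizes
// exactly into per-chromosome-per-haplotype pieces conditional on the WGD
// counts, which turns one large search into many tiny ones and allows
// piece results to be memoized across all pairs of a cohort.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <map>
#include <vector>
#include <cstdint>
#include <limits>
#include <cmath>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Machine {
  int n_states;
  int initial;            // 0-based
  double lambda;
  std::vector<double> final_w;        // +Inf = non-final
  std::vector<int> src, in, out, dst; // 0-based
  std::vector<double> w;
  std::vector<std::vector<int>> idx;  // (state, in-symbol) -> rows
};

Machine parse_machine(List mj, int n_symbols) {
  Machine mm;
  mm.n_states = as<int>(mj["n_states"]);
  mm.initial = as<int>(mj["initial"]) - 1;
  mm.lambda = as<double>(mj["lambda"]);
  NumericVector fw = mj["final_w"];
  mm.final_w.assign(fw.begin(), fw.end());
  IntegerMatrix tr = mj["trans"];
  NumericVector w = mj["w"];
  const int nt = tr.nrow();
  mm.src.resize(nt); mm.in.resize(nt); mm.out.resize(nt); mm.dst.resize(nt);
  mm.w.resize(nt);
  mm.idx.assign((size_t)mm.n_states * n_symbols, {});
  for (int r = 0; r < nt; ++r) {
    mm.src[r] = tr(r, 0) - 1;
    mm.in[r]  = tr(r, 1);
    mm.out[r] = tr(r, 2);
    mm.dst[r] = tr(r, 3) - 1;
    mm.w[r]   = w[r];
    if (mm.w[r] < 0) stop("negative transition weight");
    if (mm.in[r] < 0 || mm.in[r] >= n_symbols || mm.out[r] < 0 ||
        mm.out[r] >= n_symbols)
      stop("symbol code out of range");
    mm.idx[(size_t)mm.src[r] * n_symbols + mm.in[r]].push_back(r);
  }
  return mm;
}

inline int bits_for(int n) {
  int b = 1;
  while ((1LL << b) < n) ++b;
  return b;
}

struct PQItem {
  double cost;
  uint64_t key;
  bool operator>(const PQItem& o) const {
    if (cost != o.cost) return cost > o.cost;
    return key > o.key;
  }
};

struct ArcStep { int pos, machine, in, out, src, dst; double w; };

// core best-first search over x o M1 o ... o Mm o y
double run_chain_sp(const std::vector<Machine>& M, const std::vector<int>& x,
                    const std::vector<int>& y, int n_symbols, bool want_path,
                    std::vector<ArcStep>* path) {
  const int L = (int)x.size();
  const int m = (int)M.size();

  const int b_pos = bits_for(L + 1);
  const int b_j = bits_for(m + 1);
  const int b_sym = bits_for(n_symbols);
  std::vector<int> b_q(m), off_q(m);
  int total = b_pos + b_j + b_sym;
  int shift = 0;
  for (int j = 0; j < m; ++j) {
    b_q[j] = bits_for(M[j].n_states);
    off_q[j] = shift;
    shift += b_q[j];
    total += b_q[j];
  }
  if (total > 64)
    stop("product state space too large to bit-pack (more than 64 bits)");
  const int off_sym = shift;
  const int off_j = off_sym + b_sym;
  const int off_pos = off_j + b_j;

  auto get = [](uint64_t key, int off, int bits) -> int {
    return (int)((key >> off) & ((1ULL << bits) - 1));
  };
  auto setf = [](uint64_t key, int off, int bits, int v) -> uint64_t {
    uint64_t mask = ((1ULL << bits) - 1) << off;
    return (key & ~mask) | ((uint64_t)v << off);
  };

  uint64_t start = 0;
  double lam = 0.0;
  for (int j = 0; j < m; ++j) {
    start = setf(start, off_q[j], b_q[j], M[j].initial);
    lam += M[j].lambda;
  }
  start = setf(start, off_sym, b_sym, x[0]);

  std::unordered_map<uint64_t, double> dist;
  std::unordered_map<uint64_t, std::pair<uint64_t, int64_t>> parent;
  std::priority_queue<PQItem, std::vector<PQItem>, std::greater<PQItem>> pq;
  dist[start] = lam;
  pq.push({lam, start});

  std::vector<int64_t> arc_off(m + 1, 0);
  for (int j = 0; j < m; ++j) arc_off[j + 1] = arc_off[j] + (int64_t)M[j].w.size();

  double best = INF;
  uint64_t best_key = 0;
  bool found = false;

  auto relax = [&](uint64_t to, double nd, uint64_t from, int64_t arc) {
    auto it = dist.find(to);
    if (it == dist.end() || nd < it->second) {
      dist[to] = nd;
      if (want_path) parent[to] = {from, arc};
      pq.push({nd, to});
    }
  };

  while (!pq.empty()) {
    PQItem top = pq.top();
    pq.pop();
    uint64_t key = top.key;
    double d = top.cost;
    auto it = dist.find(key);
    if (it == dist.end() || d > it->second) continue; // stale
    int pos = get(key, off_pos, b_pos);
    if (pos == L) { best = d; best_key = key; found = true; break; }
    int j = get(key, off_j, b_j);
    int sym = get(key, off_sym, b_sym);
    if (j == m) {
      if (sym != y[pos]) continue;
      if (pos + 1 == L) {
        double fin = d;
        bool ok = true;
        for (int k = 0; k < m; ++k) {
          double fw = M[k].final_w[get(key, off_q[k], b_q[k])];
          if (fw == INF) { ok = false; break; }
          fin += fw;
        }
        if (ok) {
          uint64_t to = setf(key, off_pos, b_pos, L);
          to = setf(to, off_j, b_j, 0);
          to = setf(to, off_sym, b_sym, 0);
          relax(to, fin, key, -1);
        }
      } else {
        uint64_t to = setf(key, off_pos, b_pos, pos + 1);
        to = setf(to, off_j, b_j, 0);
        to = setf(to, off_sym, b_sym, x[pos + 1]);
        relax(to, d, key, -1);
      }
    } else {
      const Machine& mm = M[j];
      int q = get(key, off_q[j], b_q[j]);
      const std::vector<int>& rows = mm.idx[(size_t)q * n_symbols + sym];
      for (int r : rows) {
        uint64_t to = setf(key, off_q[j], b_q[j], mm.dst[r]);
        to = setf(to, off_j, b_j, j + 1);
        to = setf(to, off_sym, b_sym, mm.out[r]);
        relax(to, d + mm.w[r], key, arc_off[j] + r);
      }
    }
  }

  if (!found || !want_path || path == nullptr) return found ? best : INF;

  // walk back; collect machine arcs in forward order
  std::vector<std::pair<uint64_t, int64_t>> steps;
  uint64_t cur = best_key;
  while (cur != start) {
    auto pit = parent.find(cur);
    if (pit == parent.end()) stop("internal error: broken parent chain");
    steps.push_back({cur, pit->second.second});
    cur = pit->second.first;
  }
  for (auto rit = steps.rbegin(); rit != steps.rend(); ++rit) {
    int64_t arc = rit->second;
    if (arc < 0) continue;
    int j = 0;
    while (j + 1 <= m && arc >= arc_off[j + 1]) ++j;
    int64_t r = arc - arc_off[j];
    ArcStep s;
    s.pos = get(rit->first, off_pos, b_pos) + 1; // 1-based
    s.machine = j + 1;
    s.in = M[j].in[r]; s.out = M[j].out[r];
    s.src = M[j].src[r] + 1; s.dst = M[j].dst[r] + 1;
    s.w = M[j].w[r];
    path->push_back(s);
  }
  return best;
}

} // namespace

// [[Rcpp::export]]
List chain_shortest_path_cpp(IntegerVector x, List machines, IntegerVector y,
                             int n_symbols, bool want_path) {
  const int L = x.size();
  if (L == 0 || y.size() != L)
    stop("input and output sequences must be non-empty and of equal length");
  std::vector<Machine> M;
  for (int j = 0; j < machines.size(); ++j)
    M.push_back(parse_machine(machines[j], n_symbols));
  std::vector<int> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  std::vector<ArcStep> path;
  double w = run_chain_sp(M, xv, yv, n_symbols, want_path, &path);
  if (!std::isfinite(w))
    return List::create(_["weight"] = R_PosInf, _["arcs"] = R_NilValue);
  if (!want_path)
    return List::create(_["weight"] = w, _["arcs"] = R_NilValue);
  IntegerMatrix arcs((int)path.size(), 6);
  colnames(arcs) = CharacterVector::create("pos", "machine", "in", "out",
                                           "src", "dst");
  NumericVector aw((int)path.size());
  for (size_t i = 0; i < path.size(); ++i) {
    arcs(i, 0) = path[i].pos; arcs(i, 1) = path[i].machine;
    arcs(i, 2) = path[i].in; arcs(i, 3) = path[i].out;
    arcs(i, 4) = path[i].src; arcs(i, 5) = path[i].dst;
    aw[i] = path[i].w;
  }
  return List::create(_["weight"] = w, _["arcs"] = arcs,
                      _["arc_weights"] = aw);
}

// ---------------------------------------------------------------------
// Specialized minimum-event-distance dynamic program.
//
// The event chain factorizes at chromosome separators: segmental event
// machines are forced idle at "X" and only the WGD count spans the
// genome.  Conditional on the WGD count(s), each chromosome-haplotype
// piece is solved independently by a layered DP over positions whose
// state holds the number of open event layers (LOH-phase losses,
// segmental losses, gains) per side.  The DP is weight-equivalent to the
// shortest path through the transducer chain (asserted against the chain
// engine in the test suite) but prunes by monotone dominance: a state
// with more open layers at no higher cost can mimic any continuation of
// a smaller state by closing layers for free, so only the Pareto
// frontier survives and the per-piece work stays small even for distant
// profile pairs.

namespace {

struct SideOpt { int a, b, c, cost; };

// enumerate the per-position options of one direction (ancestor value z
// -> target u under w committed WGDs), given current open-layer counts
// (a, b, c); semantics: LOH-phase losses may reach 0 and act on every
// non-zero position they span; after the WGD shift s = min(z - a' + w,
// cap), segmental losses keep results >= 1 and cannot span a copy-1
// position; gains act on non-zero positions and saturate at the cap;
// zero positions are skipped (layer counts are maintained for free).
inline void gen_side(int z, int u, int w, int cap, int a, int b, int c,
                     std::vector<SideOpt>& out) {
  out.clear();
  if (z == 0) {
    if (u == 0) out.push_back({a, b, c, 0});  // all layers skip the zero
    return;
  }
  if (u == 0) {
    // a full LOH-phase deletion; once earlier layers reach 0, further
    // open layers skip the position, so any open count a2 >= z works
    for (int a2 = z; a2 <= cap; ++a2)
      out.push_back({a2, b, c, std::max(0, a2 - a)});
    return;
  }
  // gain options given the pre-gain value t >= 1: for u < cap the open
  // count is forced to u - t (every open layer acts); at u == cap extra
  // layers may ride across the saturated position, so any count at
  // least cap - t (and at most cap - 1, the largest ever useful) works
  auto push_gains = [&](int a2, int b2, int rab, int t) {
    if (u < cap) {
      const int c2 = u - t;
      if (c2 >= 0) out.push_back({a2, b2, c2, rab + std::max(0, c2 - c)});
    } else {
      for (int c2 = std::max(0, cap - t); c2 <= cap - 1; ++c2)
        out.push_back({a2, b2, c2, rab + std::max(0, c2 - c)});
    }
  };
  if (w == 0) {
    // without a WGD between them, the segmental-loss phase is redundant:
    // any loss run moves into the LOH phase at identical cost, so only
    // the LOH and gain layers remain (b stays 0)
    for (int a2 = 0; a2 < z; ++a2)
      push_gains(a2, b, std::max(0, a2 - a), z - a2);
    return;
  }
  for (int a2 = 0; a2 < z; ++a2) {
    const int m = z - a2;
    const int s = std::min(m + w, cap);
    const int ra = std::max(0, a2 - a);
    if (s == 1) {
      // a copy-1 position closes every loss run; t = 1
      push_gains(a2, 0, ra, 1);
    } else {
      const int b_lo = (u < cap) ? std::max(0, s - u) : 0;
      for (int b2 = b_lo; b2 <= s - 1; ++b2)
        push_gains(a2, b2, ra + std::max(0, b2 - b), s - b2);
    }
  }
}

// state packing: six 5-bit fields (a1,b1,c1,a2,b2,c2)
inline uint32_t pack6(int a1, int b1, int c1, int a2, int b2, int c2) {
  return (uint32_t)a1 | ((uint32_t)b1 << 5) | ((uint32_t)c1 << 10) |
         ((uint32_t)a2 << 15) | ((uint32_t)b2 << 20) | ((uint32_t)c2 << 25);
}
inline int fld(uint32_t s, int i) { return (int)((s >> (5 * i)) & 31u); }

// componentwise >= on all six fields
inline bool dominates_state(uint32_t s1, uint32_t s2) {
  for (int i = 0; i < 6; ++i) if (fld(s1, i) < fld(s2, i)) return false;
  return true;
}

// cumulative count of DP state insertions; lets tests assert that the
// search effort scales linearly with the number of segments
static uint64_t g_dp_ops = 0;

struct Frontier {
  // Pareto set of (state, cost); rec = traceback record id
  std::vector<uint32_t> state;
  std::vector<int> cost;
  std::vector<int> rec;
  void insert(uint32_t st, int co, int rc) {
    ++g_dp_ops;
    for (size_t i = 0; i < state.size(); ++i)
      if (cost[i] <= co && dominates_state(state[i], st)) return;
    size_t keep = 0;
    for (size_t i = 0; i < state.size(); ++i) {
      if (!(co <= cost[i] && dominates_state(st, state[i]))) {
        state[keep] = state[i]; cost[keep] = cost[i]; rec[keep] = rec[i];
        ++keep;
      }
    }
    state.resize(keep); cost.resize(keep); rec.resize(keep);
    state.push_back(st); cost.push_back(co); rec.push_back(rc);
  }
};

struct TraceRec { int parent; uint8_t z; uint32_t st; };

// DP over one piece.  mode 0 (asymmetric distance): the source value z
// is pinned to x and only the side toward y (WGD count w2) runs.
// mode 1 (symmetric kernel): the ancestor value z is free at every
// position and both sides run (targets x and y, counts w1 and w2).
// mode 2 (evolutionary phasing): x and y hold the major and minor copy
// numbers, z in {0, 1} encodes the orientation choice (z = 0: major on
// haplotype A), both sides start from the diploid value 1, side 1 runs
// toward haplotype A with w1 and side 2 toward haplotype B with w2.
// States
// whose cost reaches `limit` are pruned (the caller knows they cannot
// improve the running optimum).  Returns the minimal conditioned cost
// (excluding the WGD costs themselves), or +Inf if no solution below
// `limit` exists; with trace != nullptr, fills one row per position:
// (z, a1, b1, c1, a2, b2, c2).
double piece_dp(const std::vector<int>& x, const std::vector<int>& y,
                int w1, int w2, int cap, int mode, int limit,
                std::vector<std::array<int, 7>>* trace) {
  const int L = (int)x.size();
  Frontier cur;
  std::vector<TraceRec> recs;
  const bool tracing = trace != nullptr;
  cur.insert(pack6(0, 0, 0, 0, 0, 0), 0, -1);
  std::vector<SideOpt> o1, o2;
  for (int pos = 0; pos < L; ++pos) {
    Frontier nxt;
    for (size_t i = 0; i < cur.state.size(); ++i) {
      const uint32_t st = cur.state[i];
      const int a1 = fld(st, 0), b1 = fld(st, 1), c1 = fld(st, 2);
      const int a2 = fld(st, 3), b2 = fld(st, 4), c2 = fld(st, 5);
      const int zlo = (mode == 1) ? 0 : (mode == 2 ? 0 : x[pos]);
      const int zhi = (mode == 1) ? cap : (mode == 2 ? 1 : x[pos]);
      for (int z = zlo; z <= zhi; ++z) {
        const int u1 = (mode == 2) ? (z ? y[pos] : x[pos]) : x[pos];
        const int u2 = (mode == 2) ? (z ? x[pos] : y[pos]) : y[pos];
        if (mode == 0) {
          o1.clear(); o1.push_back({a1, b1, c1, 0});
        } else {
          gen_side(mode == 2 ? 1 : z, u1, w1, cap, a1, b1, c1, o1);
          if (o1.empty()) continue;
        }
        gen_side(mode == 2 ? 1 : z, u2, w2, cap, a2, b2, c2, o2);
        if (o2.empty()) continue;
        for (const SideOpt& s1 : o1) {
          for (const SideOpt& s2 : o2) {
            const int nc = cur.cost[i] + s1.cost + s2.cost;
            if (nc >= limit) continue;
            const uint32_t ns = pack6(s1.a, s1.b, s1.c, s2.a, s2.b, s2.c);
            int rc = -1;
            if (tracing) {
              rc = (int)recs.size();
              recs.push_back({cur.rec[i], (uint8_t)z, ns});
            }
            nxt.insert(ns, nc, rc);
          }
        }
      }
    }
    if (nxt.state.empty()) return INF;
    cur = std::move(nxt);
  }
  int best = INT32_MAX;
  size_t bi = 0;
  for (size_t i = 0; i < cur.state.size(); ++i)
    if (cur.cost[i] < best ||
        (cur.cost[i] == best && cur.state[i] < cur.state[bi])) {
      best = cur.cost[i]; bi = i;
    }
  if (tracing) {
    trace->assign(L, {0, 0, 0, 0, 0, 0, 0});
    int r = cur.rec[bi];
    for (int pos = L - 1; pos >= 0; --pos) {
      const TraceRec& tr = recs[r];
      (*trace)[pos] = {tr.z, fld(tr.st, 0), fld(tr.st, 1), fld(tr.st, 2),
                       fld(tr.st, 3), fld(tr.st, 4), fld(tr.st, 5)};
      r = tr.parent;
    }
  }
  return best;
}

// iterative deepening around piece_dp: run with a small cost budget and
// double it until a solution appears (or `limit` is reached), so the
// dominance frontier only ever holds states below about the true
// optimum.  Any finite piece value is below 6 * cap * L (six layer
// fields, each raised at most cap times per position), so exceeding
// that bound means genuinely no solution.
double piece_dp_deep(const std::vector<int>& x, const std::vector<int>& y,
                     int w1, int w2, int cap, int mode, int limit,
                     std::vector<std::array<int, 7>>* trace,
                     int lb_start = 0) {
  const int hard = 6 * cap * (int)x.size() + 1;
  int lim = std::max(2, lb_start + 1);
  for (;;) {
    const int eff = std::min(lim, limit);
    double v = piece_dp(x, y, w1, w2, cap, mode, eff, trace);
    if (std::isfinite(v)) return v;
    if (eff >= limit || eff >= hard) return INF;
    // geometric growth while cheap, additive afterwards: overshooting
    // the optimum inflates the pruned frontier exponentially
    lim = (lim < 8) ? 2 * lim : lim + 3;
  }
}

// minimal total number of open layers needed at a single position to
// turn ancestor value z into targets (u, v) under WGD counts (w1, w2);
// since every open layer at a position is a distinct event, the maximum
// of this quantity over a piece's positions is a valid lower bound on
// the piece cost.  For the asymmetric direction z is pinned (pass
// z_pinned >= 0).
int min_layers_at(int u, int v, int w1, int w2, int cap, int z_pinned) {
  std::vector<SideOpt> o1, o2;
  int best = INT32_MAX;
  const int zlo = z_pinned >= 0 ? z_pinned : 0;
  const int zhi = z_pinned >= 0 ? z_pinned : cap;
  for (int z = zlo; z <= zhi; ++z) {
    int c1 = 0;
    if (z_pinned < 0) {
      gen_side(z, u, w1, cap, 0, 0, 0, o1);
      if (o1.empty()) continue;
      c1 = INT32_MAX;
      for (const SideOpt& o : o1) c1 = std::min(c1, o.cost);
    } else if (u != z) {
      continue;  // z pinned to u by construction
    }
    gen_side(z, v, w2, cap, 0, 0, 0, o2);
    if (o2.empty()) continue;
    int c2 = INT32_MAX;
    for (const SideOpt& o : o2) c2 = std::min(c2, o.cost);
    best = std::min(best, c1 + c2);
  }
  return best;  // INT32_MAX: position infeasible (piece cost is +Inf)
}

struct PieceKeyHash {
  size_t operator()(const std::pair<int64_t, int>& k) const {
    return std::hash<int64_t>()(k.first * 131 + k.second);
  }
};

// memoized piece value with a validity bound: val < limit means exact;
// val == +Inf means "no solution below limit"
struct MemoEntry { double val; int limit; };

} // namespace

// Batched MED computation over a cohort of encoded profiles.
//
// enc: list of integer symbol vectors over {0..cap, X = xsym}; pairs:
// 2-column (1-based) index matrix.  The WGD event is handled by
// conditioning: the total distance is the minimum over the WGD count w
// (asymmetric) or the pair (w1, w2) (symmetric kernel) of the
// conditioned per-piece sums plus the WGD costs.  Combos are scanned in
// order of increasing WGD cost; a per-pair upper bound from an explicit
// witness ancestor, per-combo lower bounds from zero-cost compatibility,
// and a shrinking cost budget inside the piece DP keep the work small.
// Piece solutions are memoized by piece content across all pairs of the
// call.  mode: 0 = distances per pair; 1 = full conditioned grid for a
// single pair (exact, no pruning); 2 = c(distance, w1, w2) for a single
// pair (an optimal combination; deterministic for identical calls).
// [[Rcpp::export]]
SEXP med_batch_cpp(List enc, IntegerMatrix pairs, int cap, int xsym,
                   int wmax, bool symmetric, int mode) {
  const int nseq = enc.size();
  std::map<std::vector<int>, int> piece_ids;
  std::vector<std::vector<int>> pieces;     // by pid
  std::vector<std::vector<int>> seq_pieces(nseq);
  for (int i = 0; i < nseq; ++i) {
    IntegerVector s = enc[i];
    std::vector<int> curp;
    for (int t = 0; t <= s.size(); ++t) {
      if (t == s.size() || s[t] == xsym) {
        if (!curp.empty()) {
          auto it = piece_ids.find(curp);
          int pid;
          if (it == piece_ids.end()) {
            pid = (int)pieces.size();
            piece_ids[curp] = pid;
            pieces.push_back(curp);
          } else pid = it->second;
          seq_pieces[i].push_back(pid);
          curp.clear();
        } else if (t < s.size()) {
          stop("empty chromosome piece in encoded sequence");
        }
      } else {
        if (s[t] < 0 || s[t] > cap) stop("symbol out of range");
        curp.push_back(s[t]);
      }
    }
  }

  const int W = wmax + 1;
  const int grid = symmetric ? W * W : W;
  std::unordered_map<std::pair<int64_t, int>, MemoEntry, PieceKeyHash> memo;

  auto piece_cost = [&](int pid1, int pid2, int combo, int limit,
                        int lb) -> double {
    std::pair<int64_t, int> key((int64_t)pid1 * (int64_t)pieces.size() + pid2,
                                combo);
    auto it = memo.find(key);
    if (it != memo.end()) {
      if (std::isfinite(it->second.val)) return it->second.val;  // exact
      if (it->second.limit >= limit) return INF;  // known >= limit
      lb = std::max(lb, it->second.limit);        // learned bound
    }
    double v;
    if (symmetric)
      v = piece_dp_deep(pieces[pid1], pieces[pid2], combo / W, combo % W, cap,
                        1, limit, nullptr, lb);
    else
      v = piece_dp_deep(pieces[pid1], pieces[pid2], 0, combo, cap, 0, limit,
                        nullptr, lb);
    memo[key] = {v, limit};
    return v;
  };

  // upper bound via the explicit witness ancestor z = positionwise
  // minimum of the non-zero values (0 where both are 0), no WGDs
  auto upper_bound_pair = [&](const std::vector<int>& pi,
                              const std::vector<int>& pj) -> double {
    double ub = 0;
    for (size_t c = 0; c < pi.size() && std::isfinite(ub); ++c) {
      const std::vector<int>& u = pieces[pi[c]];
      const std::vector<int>& v = pieces[pj[c]];
      std::vector<int> z(u.size());
      for (size_t i = 0; i < u.size(); ++i) {
        if (u[i] == 0 && v[i] == 0) z[i] = 0;
        else {
          int m = cap;
          if (u[i] > 0) m = std::min(m, u[i]);
          if (v[i] > 0) m = std::min(m, v[i]);
          z[i] = std::max(1, m);
        }
      }
      ub += piece_dp_deep(z, u, 0, 0, cap, 0, INT32_MAX, nullptr);
      ub += piece_dp_deep(z, v, 0, 0, cap, 0, INT32_MAX, nullptr);
    }
    return ub;
  };

  std::vector<int> order(grid);
  for (int g = 0; g < grid; ++g) order[g] = g;
  std::sort(order.begin(), order.end(), [&](int g1, int g2) {
    int s1 = symmetric ? g1 / W + g1 % W : g1;
    int s2 = symmetric ? g2 / W + g2 % W : g2;
    if (s1 != s2) return s1 < s2;
    return g1 < g2;
  });

  // per-piece lower bound under one combo: max over positions of the
  // minimal open-layer count (memoized; -1 marks an infeasible piece)
  std::unordered_map<std::pair<int64_t, int>, int, PieceKeyHash> lb_memo;
  auto piece_lb = [&](int pid1, int pid2, int g) -> int {
    std::pair<int64_t, int> key((int64_t)pid1 * (int64_t)pieces.size() + pid2,
                                g);
    auto it = lb_memo.find(key);
    if (it != lb_memo.end()) return it->second;
    const std::vector<int>& u = pieces[pid1];
    const std::vector<int>& v = pieces[pid2];
    const int w1 = symmetric ? g / W : 0;
    const int w2 = symmetric ? g % W : g;
    int lb = 0;
    for (size_t i = 0; i < u.size(); ++i) {
      int m = min_layers_at(u[i], v[i], w1, w2, cap,
                            symmetric ? -1 : u[i]);
      if (m == INT32_MAX) { lb = -1; break; }
      lb = std::max(lb, m);
    }
    lb_memo[key] = lb;
    return lb;
  };

  // evaluate one pair; returns (best, argmin combo); with out != nullptr
  // (exact grid mode) no pruning is applied and every combo is filled in
  auto pair_eval = [&](int i, int j, std::vector<double>* out)
      -> std::pair<double, int> {
    const std::vector<int>& pi = seq_pieces[i];
    const std::vector<int>& pj = seq_pieces[j];
    if (pi.size() != pj.size())
      stop("profiles have differing numbers of chromosome pieces");
    const bool exact = out != nullptr;
    const size_t np = pi.size();
    double best = INF;
    int best_g = -1;
    if (symmetric && !exact) {
      double ub = upper_bound_pair(pi, pj);
      if (std::isfinite(ub)) best = ub + 1;  // combos matching ub still run
    }
    // per-combo lower bounds, then scan combos best-first (most
    // promising lower bound first; ties by WGD cost, then index)
    std::vector<double> combo_lb(grid, INF);
    std::vector<std::vector<int>> combo_lbs(grid);
    for (int g : order) {
      double lb_sum = symmetric ? (g / W + g % W) : g;
      std::vector<int>& l = combo_lbs[g];
      l.assign(np, 0);
      bool feasible = true;
      for (size_t c = 0; c < np; ++c) {
        int lb = piece_lb(pi[c], pj[c], g);
        if (lb < 0) { feasible = false; break; }
        std::pair<int64_t, int> key(
            (int64_t)pi[c] * (int64_t)pieces.size() + pj[c], g);
        auto it = memo.find(key);
        if (it != memo.end()) {
          if (std::isfinite(it->second.val)) lb = (int)it->second.val;
          else lb = std::max(lb, it->second.limit);
        }
        l[c] = lb;
        lb_sum += lb;
      }
      if (feasible) combo_lb[g] = lb_sum;
    }
    std::vector<int> corder = order;
    std::stable_sort(corder.begin(), corder.end(), [&](int g1, int g2) {
      return combo_lb[g1] < combo_lb[g2];
    });
    for (int g : corder) {
      const double wgd_cost = symmetric ? (g / W + g % W) : g;
      double tot = wgd_cost;
      if (!std::isfinite(combo_lb[g])) { if (out) (*out)[g] = INF; continue; }
      // refresh the bounds: the memo has learned from earlier combos
      std::vector<int>& lbs = combo_lbs[g];
      double lb_sum = wgd_cost;
      for (size_t c = 0; c < np; ++c) {
        std::pair<int64_t, int> key(
            (int64_t)pi[c] * (int64_t)pieces.size() + pj[c], g);
        auto it = memo.find(key);
        if (it != memo.end()) {
          if (std::isfinite(it->second.val))
            lbs[c] = (int)it->second.val;
          else lbs[c] = std::max(lbs[c], it->second.limit);
        }
        lb_sum += lbs[c];
      }
      if (!exact && lb_sum >= best) {
        if (out) (*out)[g] = INF;
        continue;
      }
      if (exact) {
        for (size_t c = 0; c < np; ++c) {
          tot += piece_cost(pi[c], pj[c], g, INT32_MAX, lbs[c]);
          if (!std::isfinite(tot)) break;
        }
        (*out)[g] = tot;
        if (tot < best) { best = tot; best_g = g; }
        continue;
      }
      // refine piece values in shallow increments: probe each piece
      // with a small budget above its current bound, abandoning the
      // combo as soon as the accumulated bounds reach the incumbent;
      // expensive pieces of losing combos are never solved exactly
      std::vector<double> val(np,
          std::numeric_limits<double>::quiet_NaN());  // exact where known
      double sum_bound = wgd_cost;
      for (size_t c = 0; c < np; ++c) {
        if (lbs[c] == 0) {  // cheap exact probe for trivial pieces
          double v = piece_cost(pi[c], pj[c], g, 3, 0);
          if (std::isfinite(v)) { val[c] = v; lbs[c] = (int)v; }
          else lbs[c] = 3;
        }
        sum_bound += lbs[c];
      }
      bool abandoned = false;
      for (;;) {
        if (sum_bound >= best) { abandoned = true; break; }
        Rcpp::checkUserInterrupt();
        bool all_exact = true;
        for (size_t c = 0; c < np && !abandoned; ++c) {
          if (!std::isnan(val[c])) continue;  // exact value known
          all_exact = false;
          // beyond the hard bound no finite solution exists at all
          const int hardc = 6 * cap * (int)pieces[pi[c]].size() + 1;
          if (lbs[c] >= hardc) { abandoned = true; break; }
          const int room = std::isfinite(best)
            ? (int)(best - (sum_bound - lbs[c])) : hardc;
          const int probe = std::min(lbs[c] + 3, room);
          double v = piece_cost(pi[c], pj[c], g, probe, lbs[c]);
          if (std::isfinite(v)) {
            val[c] = v;
            sum_bound += v - lbs[c];
            lbs[c] = (int)v;
          } else {
            sum_bound += probe - lbs[c];
            lbs[c] = probe;
          }
          if (sum_bound >= best) abandoned = true;
        }
        if (abandoned || all_exact) break;
      }
      if (!abandoned) {
        tot = sum_bound;
        if (tot < best) { best = tot; best_g = g; }
      }
    }
    return {best, best_g};
  };

  if (mode == 1) {
    if (pairs.nrow() != 1) stop("grid mode expects exactly one pair");
    std::vector<double> g(grid);
    pair_eval(pairs(0, 0) - 1, pairs(0, 1) - 1, &g);
    if (symmetric) {
      NumericMatrix out(W, W);
      for (int a = 0; a < W; ++a)
        for (int b = 0; b < W; ++b)
          out(a, b) = g[a * W + b];
      return out;
    }
    return NumericVector(g.begin(), g.end());
  }

  if (mode == 2) {
    if (pairs.nrow() != 1) stop("argmin mode expects exactly one pair");
    auto r = pair_eval(pairs(0, 0) - 1, pairs(0, 1) - 1, nullptr);
    NumericVector out(3);
    out[0] = r.first;
    out[1] = symmetric && r.second >= 0 ? r.second / W : r.second;
    out[2] = symmetric && r.second >= 0 ? r.second % W : 0;
    return out;
  }

  NumericVector res(pairs.nrow());
  for (int r = 0; r < pairs.nrow(); ++r) {
    res[r] = pair_eval(pairs(r, 0) - 1, pairs(r, 1) - 1, nullptr).first;
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return res;
}

// Read (and optionally reset) the cumulative DP operation counter.
// [[Rcpp::export]]
double dp_op_counter_cpp(bool reset) {
  double v = (double)g_dp_ops;
  if (reset) g_dp_ops = 0;
  return v;
}

// Traceback for one chromosome piece at fixed WGD counts: returns the
// minimal conditioned cost and, per position, the ancestor value z
// (orientation choice in phasing mode) and the open-layer counts of
// both sides (columns z, a1, b1, c1, a2, b2, c2).  mode 0: asymmetric
// (z equals x, second side meaningful); mode 1: symmetric kernel;
// mode 2: evolutionary phasing of (major, minor) toward the diploid.
// [[Rcpp::export]]
List med_piece_trace_cpp(IntegerVector x, IntegerVector y, int w1, int w2,
                         int cap, int mode) {
  std::vector<int> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  if (xv.size() != yv.size() || xv.empty())
    stop("piece vectors must be non-empty and of equal length");
  std::vector<std::array<int, 7>> tr;
  double v = piece_dp_deep(xv, yv, w1, w2, cap, mode, INT32_MAX, &tr);
  if (!std::isfinite(v))
    return List::create(_["weight"] = R_PosInf, _["trace"] = R_NilValue);
  IntegerMatrix m((int)tr.size(), 7);
  colnames(m) = CharacterVector::create("z", "a1", "b1", "c1", "a2", "b2",
                                        "c2");
  for (size_t i = 0; i < tr.size(); ++i)
    for (int k = 0; k < 7; ++k) m(i, k) = tr[i][k];
  return List::create(_["weight"] = v, _["trace"] = m);
}
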