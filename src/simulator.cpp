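// Euler-Maruyama simulator for branched cells on edge networks.
//
// The cell is a connected subtree of the network with N >= 2 tips.  Each
// leading edge (tip) carries three variables: arm length x, adhesion-bond
// concentration n, and actin treadmilling flow v.  A conserved inhibitory
// polarity cue is advected by the net flows along the one-dimensional cell
// body and sets the steady-state flow targets at the tips.  Topology events
// (splitting at junctions, pinning of tips at branch vertices, merging of
// elements when a branch empties) are handled exactly so that the total cell
// length is continuous across every event.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// counter-based RNG: each arm owns an independent stream derived from the run
// seed and its birth counter, so topology changes do not scramble the noise.
static inline uint64_t splitmix64(uint64_t &s) {
  uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct ArmRng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  void seed(uint64_t run_seed, uint64_t birth) {
    uint64_t x = run_seed * 0x9e3779b97f4a7c15ULL + birth * 0xda942042e4dd58b5ULL + 1ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    has_spare = false;
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double norm() {  // Box-Muller (polar form avoided: deterministic count per draw)
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return m * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------
struct Net {
  int nn;
  std::vector<double> px, py;
  std::vector<std::vector<int>> adj;
  double elen(int a, int b) const {
    double dx = px[b] - px[a], dy = py[b] - py[a];
    return std::sqrt(dx * dx + dy * dy);
  }
};

struct Params {
  double beta0, k, c, D, delta, sigma, fs, kappa, r;
  double wmax, gamma_min, n_floor, dt, eps_split;
};

// chemokine field -> actin activity at a tip
struct Field {
  int kind;          // 0 none, 1 junction_bias, 2 point_exp, 3 line_exp, 4 linear
  double eps, c0, Csat, decay;
  double sx, sy;     // point source / y_source
  double slope_len;  // linear profile length scale
  double onset;      // field inactive for t < onset
  int biased_node;   // junction_bias: far node of the favoured branch (-1 none)

  double conc(double x, double y) const {
    if (kind == 2) {
      double rr = std::sqrt((x - sx) * (x - sx) + (y - sy) * (y - sy));
      return c0 * std::exp(-rr / decay);
    } else if (kind == 3) {
      return c0 * std::exp(-std::fabs(y - sy) / decay);
    } else if (kind == 4) {
      double rel = 1.0 - (sy - y) / slope_len;
      return c0 * std::max(0.0, std::min(1.0, rel));
    }
    return 0.0;
  }
  double beta_tip(double t, double beta0, double x, double y, int branch) const {
    if (kind == 0 || t < onset) return beta0;
    if (kind == 1) return (branch == biased_node) ? beta0 * (1.0 + eps) : beta0;
    double cc = conc(x, y);
    if (kind == 4) return beta0 * (1.0 + eps * cc / c0);
    // saturating response, normalized to be maximal at the source
    return beta0 * (1.0 + eps * (1.0 + Csat / c0) * cc / (cc + Csat));
  }
};

// ---------------------------------------------------------------------------
// cell topology
struct Arm {
  int id;                    // persistent identity (birth counter)
  int base;                  // base junction node
  std::vector<int> nodes;    // interior nodes crossed, base-side first
  int tip_to;                // node the tip edge points toward
  double tip_off;            // arclength of tip along its current edge
  double x;                  // total arm length
  double n, v;
  ArmRng rng;
  int branch0;               // first node after base (outcome classification)
};

struct Seg {
  std::vector<int> nodes;    // junction ... junction (inclusive)
  double len;
};

struct Path {                // N == 2 cell: tipA ... tipB
  std::vector<int> nodes;    // interior nodes (may be empty)
  int a_to, b_to;            // nodes the two tip edges point toward
  double a_off, b_off;       // tip offsets (from nodes.front()/back(), or from
                             // each other when nodes is empty: see below)
  int a_anchor, b_anchor;    // when nodes empty: both tips on edge
                             // a_anchor->a_to with a_off, b_off from a_anchor
};

struct Cell {
  bool is_path;              // N == 2 representation
  Path path;                 // valid when is_path
  double pa_n, pa_v, pb_n, pb_v;  // tip states for path cell
  ArmRng pa_rng, pb_rng;
  int pa_id, pb_id;
  std::vector<Arm> arms;     // N >= 3 representation
  std::vector<Seg> segs;
  int next_id = 0;
};

// ---------------------------------------------------------------------------
struct Event { double t; int kind; int arm; int node; };
// kinds: 1 split, 2 pin, 3 merge/collapse, 4 junction_pass, 5 regrow

struct Recorder {
  std::vector<double> t, comx, comy, L, N;
  std::vector<int> ev;
  // long per-arm table
  bool arms_on;
  std::vector<double> at, ax, an, av, abeta, atx, aty;
  std::vector<int> aid, abase;
  std::vector<Event> events;
};

class Sim {
public:
  Net net;
  Params P;
  Field F;
  Cell cell;
  uint64_t run_seed;
  double t = 0.0;
  int pending_event = 0;

  // scratch
  std::vector<double> u_arm, ctip, beta_arm, vstar;
  std::vector<double> u_seg;
  double weight_err_max = 0.0;   // worst violation of the 2^-m identity

  bool finite_ok = true;
  bool boundary_hit = false;

  int n_arms() const { return cell.is_path ? 2 : (int)cell.arms.size(); }

  double total_len() const {
    if (cell.is_path) {
      const Path &p = cell.path;
      if (p.nodes.empty()) return p.b_off - p.a_off;
      double L = p.a_off + p.b_off;
      for (size_t i = 0; i + 1 < p.nodes.size(); ++i)
        L += net.elen(p.nodes[i], p.nodes[i + 1]);
      return L;
    }
    double L = 0.0;
    for (const Arm &a : cell.arms) L += a.x;
    for (const Seg &s : cell.segs) L += s.len;
    return L;
  }

  void tip_pos(double &tx, double &ty, int from, int to, double off) const {
    double ex = net.px[to] - net.px[from], ey = net.py[to] - net.py[from];
    double el = std::sqrt(ex * ex + ey * ey);
    tx = net.px[from] + ex / el * off;
    ty = net.py[from] + ey / el * off;
  }

  void arm_tip(const Arm &a, double &tx, double &ty) const {
    int from = a.nodes.empty() ? a.base : a.nodes.back();
    tip_pos(tx, ty, from, a.tip_to, a.tip_off);
  }

  void path_tips(double &ax_, double &ay_, double &bx_, double &by_) const {
    const Path &p = cell.path;
    if (p.nodes.empty()) {
      tip_pos(ax_, ay_, p.a_anchor, p.a_to, p.a_off);
      tip_pos(bx_, by_, p.a_anchor, p.a_to, p.b_off);
    } else {
      tip_pos(ax_, ay_, p.nodes.front(), p.a_to, p.a_off);
      tip_pos(bx_, by_, p.nodes.back(), p.b_to, p.b_off);
    }
  }

  // arclength-weighted centroid of the occupied subtree
  void com(double &cx, double &cy) const {
    double M = 0.0, sx = 0.0, sy = 0.0;
    auto add_piece = [&](double x1, double y1, double x2, double y2) {
      double l = std::hypot(x2 - x1, y2 - y1);
      M += l; sx += l * 0.5 * (x1 + x2); sy += l * 0.5 * (y1 + y2);
    };
    auto add_chain = [&](const std::vector<int> &nd) {
      for (size_t i = 0; i + 1 < nd.size(); ++i)
        add_piece(net.px[nd[i]], net.py[nd[i]], net.px[nd[i + 1]], net.py[nd[i + 1]]);
    };
    if (cell.is_path) {
      const Path &p = cell.path;
      double ax_, ay_, bx_, by_;
      path_tips(ax_, ay_, bx_, by_);
      if (p.nodes.empty()) { add_piece(ax_, ay_, bx_, by_); }
      else {
        add_piece(ax_, ay_, net.px[p.nodes.front()], net.py[p.nodes.front()]);
        add_chain(p.nodes);
        add_piece(net.px[p.nodes.back()], net.py[p.nodes.back()], bx_, by_);
      }
    } else {
      for (const Arm &a : cell.arms) {
        double tx, ty; arm_tip(a, tx, ty);
        std::vector<int> ch; ch.push_back(a.base);
        for (int nd : a.nodes) ch.push_back(nd);
        add_chain(ch);
        int from = a.nodes.empty() ? a.base : a.nodes.back();
        add_piece(net.px[from], net.py[from], tx, ty);
      }
      for (const Seg &s : cell.segs) add_chain(s.nodes);
    }
    if (M <= 0) {
      // degenerate: all mass at a point
      if (cell.is_path) { double bx_, by_; path_tips(cx, cy, bx_, by_); }
      else { cx = net.px[cell.arms[0].base]; cy = net.py[cell.arms[0].base]; }
    } else { cx = sx / M; cy = sy / M; }
  }

  // -------------------------------------------------------------------------
  // flow routing: each arm's flow v_j enters the tree at its base junction and
  // halves at every spanned junction it passes; u per element follows.
  // elements: arms (orientation base->tip, u>0 means flow toward the base,
  // i.e. retrograde) and segments (orientation nodes.front()->nodes.back()).
  void flows() {
    int N = (int)cell.arms.size();
    u_arm.assign(N, 0.0);
    u_seg.assign(cell.segs.size(), 0.0);
    for (int i = 0; i < N; ++i) u_arm[i] = cell.arms[i].v;
    // junction adjacency: node -> attached elements (arm id +i, seg id -1-i)
    // distribute each arm's flow
    for (int j = 0; j < N; ++j) {
      double vj = cell.arms[j].v;
      // BFS over junction structure; `unit` tracks the abstract splitting
      // weight so the sum-of-2^-m identity can be checked independently of v
      struct Front { int junc; int from_elem; double w; double unit; };
      std::vector<Front> stack;
      stack.push_back({cell.arms[j].base, j, vj, 1.0});
      double unit_to_arms = 0.0;
      while (!stack.empty()) {
        Front f = stack.back(); stack.pop_back();
        // elements attached at f.junc other than from_elem each get w/2
        for (int i = 0; i < N; ++i) {
          if (i == f.from_elem) continue;
          if (cell.arms[i].base == f.junc) {
            u_arm[i] -= f.w * 0.5;
            unit_to_arms += f.unit * 0.5;
          }
        }
        for (size_t s = 0; s < cell.segs.size(); ++s) {
          int se = -1 - (int)s;
          if (se == f.from_elem) continue;
          const Seg &sg = cell.segs[s];
          if (sg.nodes.front() == f.junc) {
            u_seg[s] += f.w * 0.5;
            stack.push_back({sg.nodes.back(), se, f.w * 0.5, f.unit * 0.5});
          } else if (sg.nodes.back() == f.junc) {
            u_seg[s] -= f.w * 0.5;
            stack.push_back({sg.nodes.front(), se, f.w * 0.5, f.unit * 0.5});
          }
        }
      }
      weight_err_max = std::max(weight_err_max, std::fabs(unit_to_arms - 1.0));
    }
  }

  // stable log((e^z - 1)/z), z != 0
  static double log_h(double z) {
    if (std::fabs(z) < 1e-8) return z * 0.5;
    if (z > 33.0) return z - std::log(z);
    if (z < -33.0) return -std::log(-z);
    return std::log(std::expm1(z) / z) * (z > 0 ? 1.0 : 1.0) + 0.0 * z;
  }
  static double log_h_safe(double z) {
    if (std::fabs(z) < 1e-8) return z * 0.5;
    if (z > 33.0) return z - std::log(z);
    if (z < -33.0) return -std::log(-z);
    double val = std::expm1(z) / z;  // > 0 for all z
    return std::log(val);
  }

  // steady-state cue concentrations at the tips (conserved total mass P.c)
  void cue() {
    int N = (int)cell.arms.size();
    ctip.assign(N, 0.0);
    // node log-potentials over junctions
    // collect junction nodes
    std::vector<int> juncs;
    auto add_junc = [&](int nd) {
      if (std::find(juncs.begin(), juncs.end(), nd) == juncs.end())
        juncs.push_back(nd);
    };
    for (const Arm &a : cell.arms) add_junc(a.base);
    for (const Seg &sg : cell.segs) { add_junc(sg.nodes.front()); add_junc(sg.nodes.back()); }
    std::vector<double> logphi(juncs.size(), 0.0);
    std::vector<char> seen(juncs.size(), 0);
    auto jidx = [&](int node) {
      for (size_t i = 0; i < juncs.size(); ++i) if (juncs[i] == node) return (int)i;
      return -1;
    };
    // BFS through segments
    std::vector<int> bfs; bfs.push_back(0); seen[0] = 1;
    while (!bfs.empty()) {
      int q = bfs.back(); bfs.pop_back();
      for (size_t s = 0; s < cell.segs.size(); ++s) {
        const Seg &sg = cell.segs[s];
        int fa = jidx(sg.nodes.front()), fb = jidx(sg.nodes.back());
        double dphi = u_seg[s] * sg.len / P.D;  // c(b) = c(a) e^{+u l / D}
        if (fa == q && !seen[fb]) { logphi[fb] = logphi[fa] + dphi; seen[fb] = 1; bfs.push_back(fb); }
        else if (fb == q && !seen[fa]) { logphi[fa] = logphi[fb] - dphi; seen[fa] = 1; bfs.push_back(fa); }
      }
    }
    // mass (logsumexp) over elements
    double maxlog = -1e300;
    std::vector<double> logm;
    logm.reserve(N + cell.segs.size());
    for (int i = 0; i < N; ++i) {
      const Arm &a = cell.arms[i];
      if (a.x <= 0) { logm.push_back(-1e300); continue; }
      double z = -u_arm[i] * a.x / P.D;
      double lm = logphi[jidx(a.base)] + std::log(a.x) + log_h_safe(z);
      logm.push_back(lm);
      if (lm > maxlog) maxlog = lm;
    }
    for (size_t s = 0; s < cell.segs.size(); ++s) {
      const Seg &sg = cell.segs[s];
      double z = u_seg[s] * sg.len / P.D;
      double lm = logphi[jidx(sg.nodes.front())] + std::log(sg.len) + log_h_safe(z);
      logm.push_back(lm);
      if (lm > maxlog) maxlog = lm;
    }
    double acc = 0.0;
    for (double lm : logm) acc += std::exp(lm - maxlog);
    double logM = maxlog + std::log(acc);
    for (int i = 0; i < N; ++i) {
      const Arm &a = cell.arms[i];
      double logc = logphi[jidx(a.base)] - u_arm[i] * a.x / P.D - logM + std::log(P.c);
      ctip[i] = (logc < -700) ? 0.0 : std::exp(std::min(logc, 700.0));
    }
  }

  // N == 2 cue: single 1D element
  void cue_path(double L, double va, double vb, double &ca, double &cb) {
    double u = va - vb;  // net flow from tip A toward tip B
    double g = u * L / P.D;
    if (std::fabs(g) < 1e-9) { ca = cb = P.c / L; return; }
    double base = P.c / L;
    // ca = base * g / (e^g - 1); cb = base * g / (1 - e^-g)
    if (g > 60) { ca = 0.0; cb = base * g; }
    else if (g < -60) { ca = base * (-g); cb = 0.0; }
    else { ca = base * g / std::expm1(g); cb = base * g / (-std::expm1(-g)); }
  }

  // single-arm deterministic rates, shared by both representations
  inline double friction_ret(double n) const {
    return std::max(n * P.kappa, P.gamma_min);
  }
  inline double xdot(double v, double Fel, double n) const {
    double cand = v - Fel;
    return (cand >= 0) ? cand : cand / friction_ret(n);
  }
  inline double ndot(double v, double Fel, double n) const {
    double q = (Fel - v) / (P.fs * n);
    double woff = (q > 50) ? P.wmax : std::min(std::exp(q), P.wmax);
    return P.r * (1.0 - n) - n * woff;
  }

  // -------------------------------------------------------------------------
  int free_dirs(int node, std::vector<int> &out) {
    // network neighbours of `node` not occupied by the cell
    out.clear();
    for (int nb : net.adj[node]) if (!edge_occupied(node, nb)) out.push_back(nb);
    return (int)out.size();
  }

  bool edge_occupied(int a, int b) const {
    auto on_chain = [&](const std::vector<int> &nd, int extra_front, int extra_back) {
      // chain of nodes with optional virtual endpoints
      std::vector<int> full;
      if (extra_front >= 0) full.push_back(extra_front);
      for (int q : nd) full.push_back(q);
      if (extra_back >= 0) full.push_back(extra_back);
      for (size_t i = 0; i + 1 < full.size(); ++i)
        if ((full[i] == a && full[i + 1] == b) || (full[i] == b && full[i + 1] == a))
          return true;
      return false;
    };
    if (cell.is_path) {
      const Path &p = cell.path;
      if (p.nodes.empty()) return (p.a_anchor == a && p.a_to == b) || (p.a_anchor == b && p.a_to == a);
      if (on_chain(p.nodes, -1, -1)) return true;
      if ((p.nodes.front() == a && p.a_to == b) || (p.nodes.front() == b && p.a_to == a)) return true;
      if ((p.nodes.back() == a && p.b_to == b) || (p.nodes.back() == b && p.b_to == a)) return true;
      return false;
    }
    for (const Arm &ar : cell.arms) {
      std::vector<int> full; full.push_back(ar.base);
      for (int q : ar.nodes) full.push_back(q);
      for (size_t i = 0; i + 1 < full.size(); ++i)
        if ((full[i] == a && full[i + 1] == b) || (full[i] == b && full[i + 1] == a)) return true;
      int from = full.back();
      if (ar.x > 0 && ((from == a && ar.tip_to == b) || (from == b && ar.tip_to == a))) return true;
    }
    for (const Seg &sg : cell.segs)
      if (on_chain(sg.nodes, -1, -1)) return true;
    return false;
  }

  // -------------------------------------------------------------------------
  void step(Recorder &rec) {
    if (cell.is_path) step_path(rec); else step_tree(rec);
    t += P.dt;
  }

  void step_path(Recorder &rec) {
    Path &p = cell.path;
    double L = total_len();
    double Fel = P.k * (L - 1.0);
    double ax_, ay_, bx_, by_;
    path_tips(ax_, ay_, bx_, by_);
    double ba = F.beta_tip(t, P.beta0, ax_, ay_, branch_of_path_tip(true));
    double bb = F.beta_tip(t, P.beta0, bx_, by_, branch_of_path_tip(false));
    double ca, cb;
    cue_path(L, cell.pa_v, cell.pb_v, ca, cb);
    double vsa = ba / (1.0 + ca), vsb = bb / (1.0 + cb);
    double xda = xdot(cell.pa_v, Fel, cell.pa_n);
    double xdb = xdot(cell.pb_v, Fel, cell.pb_n);
    cell.pa_n = std::min(1.0, std::max(P.n_floor, cell.pa_n + ndot(cell.pa_v, Fel, cell.pa_n) * P.dt));
    cell.pb_n = std::min(1.0, std::max(P.n_floor, cell.pb_n + ndot(cell.pb_v, Fel, cell.pb_n) * P.dt));
    double sq = std::sqrt(P.dt);
    cell.pa_v += -P.delta * (cell.pa_v - vsa) * P.dt + P.sigma * sq * cell.pa_rng.norm();
    cell.pb_v += -P.delta * (cell.pb_v - vsb) * P.dt + P.sigma * sq * cell.pb_rng.norm();
    if (!std::isfinite(cell.pa_v) || !std::isfinite(cell.pb_v)) { finite_ok = false; return; }
    move_path_tip(true, xda * P.dt, rec);
    if (cell.is_path) move_path_tip(false, xdb * P.dt, rec);
  }

  int branch_of_path_tip(bool a_side) const {
    const Path &p = cell.path;
    return a_side ? p.a_to : (p.nodes.empty() ? p.a_to : p.b_to);
  }

  // move a path tip by dx (positive outward); handles node crossings
  void move_path_tip(bool a_side, double dx, Recorder &rec) {
    Path &p = cell.path;
    if (p.nodes.empty()) {
      // both tips on edge a_anchor -> a_to; outward for A is toward a_anchor
      if (a_side) {
        p.a_off -= dx;
        if (p.a_off < 0) {  // tip A reaches a_anchor
          if (dx > 0) { cross_empty_path_node(true, rec); }
          else p.a_off = 0;  // retracting: cannot pass its own far end here
        }
      } else {
        p.b_off += dx;
        double el = net.elen(p.a_anchor, p.a_to);
        if (p.b_off > el + 2 * P.eps_split) cross_empty_path_node(false, rec);
        else if (p.b_off < p.a_off) p.b_off = p.a_off;  // guard
      }
      return;
    }
    if (a_side) {
      p.a_off += dx;
      double el = net.elen(p.nodes.front(), p.a_to);
      if (p.a_off > el + 2 * P.eps_split) tip_reaches_node(true, rec);
      else if (p.a_off < 0) {  // retracting past nodes.front()
        int nd = p.nodes.front();
        p.nodes.erase(p.nodes.begin());
        rec.events.push_back({t, 4, cell.pa_id, nd});
        if (p.nodes.empty()) {
          // cell now inside edge nd.front-side: tips on edge (old second node?)
          // reconstruct: tip A beyond nd toward a_to is gone; cell between
          // tip A (on edge nd->a_to at offset -p.a_off measured...) hmm:
          // tip A passed nd moving inward: now both tips on edge nd->b_to
          double el2 = net.elen(nd, p.b_to);
          p.a_anchor = nd; p.a_to = p.b_to;
          p.a_off = -p.a_off;          // distance from nd along nd->b_to
          p.b_off = p.b_off;           // b_off already measured from nd
          if (p.a_off > p.b_off) p.a_off = p.b_off;
          (void)el2;
        } else {
          p.a_to = nd;
          p.a_off += net.elen(p.nodes.front(), nd);
        }
      }
    } else {
      p.b_off += dx;
      double el = net.elen(p.nodes.back(), p.b_to);
      if (p.b_off > el + 2 * P.eps_split) tip_reaches_node(false, rec);
      else if (p.b_off < 0) {
        int nd = p.nodes.back();
        p.nodes.pop_back();
        rec.events.push_back({t, 4, cell.pb_id, nd});
        if (p.nodes.empty()) {
          double keep_a = p.a_off;
          p.a_anchor = nd; int old_a_to = p.a_to;
          p.a_to = old_a_to;
          p.b_off = -p.b_off;  // distance from nd along nd->a_to
          p.a_off = keep_a;    // also from nd along nd->a_to? no: a_off was from nd already
          // after removing the last interior node, tips lie on edge nd->a_to:
          // A at a_off from nd, B at b_off from nd; ensure ordering a<b means
          // A farther out: our convention in empty-path is both offsets from
          // a_anchor along a_anchor->a_to with a_off < b_off.
          if (p.a_off > p.b_off) std::swap(p.a_off, p.b_off);  // orientation guard
        } else {
          p.b_to = nd;
          p.b_off += net.elen(p.nodes.back(), nd);
        }
      }
    }
  }

  // an outward-moving path tip reaches a node: split (2 free) or pass (1 free)
  void cross_empty_path_node(bool a_side, Recorder &rec) {
    Path &p = cell.path;
    // only for nodes.empty() case; bring into generic form then recurse
    if (a_side) {
      double q = -p.a_off;        // overshoot past a_anchor
      p.nodes.push_back(p.a_anchor);
      int anchor = p.a_anchor;
      p.b_to = p.a_to;            // B tip still on the same edge
      // b_off stays measured from anchor
      // choose new direction for A at `anchor`
      p.a_off = q;
      resolve_tip_at_node(true, anchor, rec);
    } else {
      double el = net.elen(p.a_anchor, p.a_to);
      double q = p.b_off - el;
      p.nodes.push_back(p.a_to);
      p.b_off = q;
      // A tip keeps anchor edge: reorient: nodes.front() = a_to, tip A points
      // back toward a_anchor at offset el - a_off
      p.a_off = el - p.a_off;
      int old_anchor = p.a_anchor;
      p.a_to = old_anchor;
      resolve_tip_at_node(false, p.nodes.back(), rec);
    }
  }

  void tip_reaches_node(bool a_side, Recorder &rec) {
    Path &p = cell.path;
    if (a_side) {
      int nd = p.a_to;
      double el = net.elen(p.nodes.front(), nd);
      double q = p.a_off - el;
      p.nodes.insert(p.nodes.begin(), nd);
      p.a_off = q;
      resolve_tip_at_node(true, nd, rec);
    } else {
      int nd = p.b_to;
      double el = net.elen(p.nodes.back(), nd);
      double q = p.b_off - el;
      p.nodes.push_back(nd);
      p.b_off = q;
      resolve_tip_at_node(false, nd, rec);
    }
  }

  // path tip sits just past `node` with overshoot stored in its offset;
  // decide split vs pass-through vs boundary
  void resolve_tip_at_node(bool a_side, int node, Recorder &rec) {
    Path &p = cell.path;
    std::vector<int> free;
    free_dirs(node, free);
    double q = a_side ? p.a_off : p.b_off;
    if ((int)free.size() >= 2) {
      // split into two daughters; cell becomes a 3-arm tree
      to_tree_split(a_side, node, free[0], free[1], q, rec);
    } else if (free.size() == 1) {
      if (a_side) p.a_to = free[0]; else p.b_to = free[0];
      rec.events.push_back({t, 4, a_side ? cell.pa_id : cell.pb_id, node});
    } else {
      boundary_hit = true;
      if (a_side) p.a_off = 0; else p.b_off = 0;
    }
  }

  // convert path cell into 3-arm tree at `node` (daughters along d1, d2)
  void to_tree_split(bool a_side, int node, int d1, int d2, double q, Recorder &rec) {
    Path p = cell.path;  // copy
    Arm rear;
    rear.base = node;
    if (a_side) {
      // rear path: node(=nodes.front()) ... nodes.back(), tip = B
      rear.nodes.assign(p.nodes.begin() + 1, p.nodes.end());
      rear.tip_to = p.b_to; rear.tip_off = p.b_off;
      rear.n = cell.pb_n; rear.v = cell.pb_v; rear.rng = cell.pb_rng; rear.id = cell.pb_id;
    } else {
      rear.nodes.assign(p.nodes.rbegin() + 1, p.nodes.rend());
      rear.tip_to = p.a_to; rear.tip_off = p.a_off;
      rear.n = cell.pa_n; rear.v = cell.pa_v; rear.rng = cell.pa_rng; rear.id = cell.pa_id;
    }
    // rear length = chain length + tip_off
    double L = 0.0;
    {
      std::vector<int> full; full.push_back(node);
      for (int nd : rear.nodes) full.push_back(nd);
      for (size_t i = 0; i + 1 < full.size(); ++i) L += net.elen(full[i], full[i + 1]);
      L += rear.tip_off;
    }
    rear.x = L;
    rear.branch0 = rear.nodes.empty() ? rear.tip_to : rear.nodes.front();
    double pn = a_side ? cell.pa_n : cell.pb_n;
    double pv = a_side ? cell.pa_v : cell.pb_v;
    Arm c1, c2;
    c1.base = c2.base = node;
    c1.tip_to = d1; c2.tip_to = d2;
    c1.tip_off = q * 0.5; c2.tip_off = q * 0.5;
    c1.x = c2.x = q * 0.5;
    c1.n = c2.n = pn;
    c1.v = pv * (1.0 + 1e-9); c2.v = pv * (1.0 - 1e-9);
    c1.id = cell.next_id++; c2.id = cell.next_id++;
    c1.rng.seed(run_seed, (uint64_t)c1.id);
    c2.rng.seed(run_seed, (uint64_t)c2.id);
    c1.branch0 = d1; c2.branch0 = d2;
    cell.is_path = false;
    cell.arms.clear(); cell.segs.clear();
    cell.arms.push_back(rear);
    cell.arms.push_back(c1);
    cell.arms.push_back(c2);
    rec.events.push_back({t, 1, rear.id, node});
  }

  // -------------------------------------------------------------------------
  void step_tree(Recorder &rec) {
    int N = (int)cell.arms.size();
    double L = total_len();
    double Fel = P.k * (L - 1.0);
    flows();
    cue();
    double sq = std::sqrt(P.dt);
    std::vector<double> dxs(N);
    for (int i = 0; i < N; ++i) {
      Arm &a = cell.arms[i];
      double tx, ty; arm_tip(a, tx, ty);
      double bt = F.beta_tip(t, P.beta0, tx, ty, a.branch0);
      double vs = bt / (1.0 + ctip[i]);
      dxs[i] = xdot(a.v, Fel, a.n) * P.dt;
      a.n = std::min(1.0, std::max(P.n_floor, a.n + ndot(a.v, Fel, a.n) * P.dt));
      a.v += -P.delta * (a.v - vs) * P.dt + P.sigma * sq * a.rng.norm();
      if (!std::isfinite(a.v)) { finite_ok = false; return; }
    }
    // move tips, keyed on stable arm ids (splits reshuffle the arm vector)
    std::vector<std::pair<int, double>> moves(N);
    for (int i = 0; i < N; ++i) moves[i] = {cell.arms[i].id, dxs[i]};
    for (auto &mv : moves) {
      if (cell.is_path) break;
      int idx = -1;
      for (int i = 0; i < (int)cell.arms.size(); ++i)
        if (cell.arms[i].id == mv.first) { idx = i; break; }
      if (idx < 0) continue;  // arm no longer exists
      move_arm_tip(idx, mv.second, rec);
    }
    if (!cell.is_path) removal_cascade(rec);
  }

  void move_arm_tip(int i, double dx, Recorder &rec) {
    Arm &a = cell.arms[i];
    if (a.x <= 0 && dx <= 0) return;  // pinned
    double was_zero = (a.x <= 0);
    a.x += dx;
    a.tip_off += dx;
    if (was_zero && a.x > 0) rec.events.push_back({t, 5, a.id, a.base});
    if (a.x <= 0) {  // pin at base junction
      a.x = 0; a.tip_off = 0; a.nodes.clear();
      // tip_to: keep pointing along its original branch for regrowth
      a.tip_to = a.branch0;
      rec.events.push_back({t, 2, a.id, a.base});
      return;
    }
    if (dx > 0) {
      int from = a.nodes.empty() ? a.base : a.nodes.back();
      double el = net.elen(from, a.tip_to);
      if (a.tip_off > el + 2 * P.eps_split) {
        double q = a.tip_off - el;
        int node = a.tip_to;
        std::vector<int> free;
        free_dirs(node, free);
        if ((int)free.size() >= 2) {
          split_arm(i, node, free[0], free[1], q, rec);
        } else if (free.size() == 1) {
          a.nodes.push_back(node);
          a.tip_to = free[0];
          a.tip_off = q;
          rec.events.push_back({t, 4, a.id, node});
        } else {
          boundary_hit = true;
          a.x -= q; a.tip_off = el;  // hold at the node
        }
      }
    } else if (a.tip_off < 0) {
      // retracting across an interior node of the arm
      while (a.tip_off < 0 && !a.nodes.empty()) {
        int nd = a.nodes.back();
        a.nodes.pop_back();
        int from = a.nodes.empty() ? a.base : a.nodes.back();
        a.tip_to = nd;
        a.tip_off += net.elen(from, nd);
        rec.events.push_back({t, 4, a.id, nd});
      }
      if (a.tip_off < 0) { a.tip_off = 0; }  // at base (x should be ~0 too)
    }
  }

  // arm i's tip splits at `node`: arm becomes a segment, two daughters appear
  void split_arm(int i, int node, int d1, int d2, double q, Recorder &rec) {
    Arm a = cell.arms[i];  // copy
    Seg sg;
    sg.nodes.push_back(a.base);
    for (int nd : a.nodes) sg.nodes.push_back(nd);
    sg.nodes.push_back(node);
    sg.len = 0.0;
    for (size_t j = 0; j + 1 < sg.nodes.size(); ++j)
      sg.len += net.elen(sg.nodes[j], sg.nodes[j + 1]);
    Arm c1, c2;
    c1.base = c2.base = node;
    c1.tip_to = d1; c2.tip_to = d2;
    c1.tip_off = c2.tip_off = q * 0.5;
    c1.x = c2.x = q * 0.5;
    c1.n = c2.n = a.n;
    // infinitesimal deterministic tiebreak: exactly equal daughters would
    // otherwise deadlock noise-free runs on the symmetric manifold
    c1.v = a.v * (1.0 + 1e-9); c2.v = a.v * (1.0 - 1e-9);
    c1.id = cell.next_id++; c2.id = cell.next_id++;
    c1.rng.seed(run_seed, (uint64_t)c1.id);
    c2.rng.seed(run_seed, (uint64_t)c2.id);
    c1.branch0 = d1; c2.branch0 = d2;
    cell.arms.erase(cell.arms.begin() + i);
    cell.segs.push_back(sg);
    cell.arms.push_back(c1);
    cell.arms.push_back(c2);
    rec.events.push_back({t, 1, c1.id, node});
  }

  // count occupied directions at junction `node`, excluding zero-length arms
  int live_dirs(int node, int skip_arm) {
    int cnt = 0;
    for (int i = 0; i < (int)cell.arms.size(); ++i) {
      if (i == skip_arm) continue;
      if (cell.arms[i].base == node && cell.arms[i].x > 0) cnt++;
    }
    for (const Seg &sg : cell.segs)
      if (sg.nodes.front() == node || sg.nodes.back() == node) cnt++;
    return cnt;
  }

  void removal_cascade(Recorder &rec) {
    bool changed = true;
    while (changed && !cell.is_path) {
      changed = false;
      for (int i = 0; i < (int)cell.arms.size(); ++i) {
        Arm &a = cell.arms[i];
        if (a.x > 0) continue;
        int live = live_dirs(a.base, i);
        if (live == 1) {
          remove_zero_arm(i, rec);
          changed = true;
          break;
        }
      }
    }
  }

  void remove_zero_arm(int i, Recorder &rec) {
    int node = cell.arms[i].base;
    rec.events.push_back({t, 3, cell.arms[i].id, node});
    Arm dead = cell.arms[i];
    cell.arms.erase(cell.arms.begin() + i);
    // elements still attached at node (arms incl. zero ones + segs)
    std::vector<int> at_arms, at_segs;
    for (int j = 0; j < (int)cell.arms.size(); ++j)
      if (cell.arms[j].base == node) at_arms.push_back(j);
    for (int s = 0; s < (int)cell.segs.size(); ++s)
      if (cell.segs[s].nodes.front() == node || cell.segs[s].nodes.back() == node)
        at_segs.push_back(s);
    int tot = (int)at_arms.size() + (int)at_segs.size();
    if (tot >= 3) return;             // node still a junction
    if (tot == 2) {
      if (at_arms.size() == 2) {
        // two arms -> N==2 path cell (only possible when they are the last two)
        if (cell.arms.size() == 2 && cell.segs.empty()) to_path(at_arms[0], at_arms[1], node);
        // otherwise (cannot happen on a tree) leave as-is
      } else if (at_arms.size() == 1) {
        // arm + segment -> extended arm based at segment's far junction
        Arm &a = cell.arms[at_arms[0]];
        Seg sg = cell.segs[at_segs[0]];
        std::vector<int> chain;  // far junction ... node
        if (sg.nodes.back() == node) chain = sg.nodes;
        else { chain.assign(sg.nodes.rbegin(), sg.nodes.rend()); }
        int newbase = chain.front();
        std::vector<int> newnodes(chain.begin() + 1, chain.end());  // ... node
        for (int nd : a.nodes) newnodes.push_back(nd);
        a.base = newbase;
        a.nodes = newnodes;
        a.x += sg.len;
        a.branch0 = newnodes.empty() ? a.tip_to : newnodes.front();
        cell.segs.erase(cell.segs.begin() + at_segs[0]);
      } else {
        // segment + segment -> merged segment
        Seg s1 = cell.segs[at_segs[0]], s2 = cell.segs[at_segs[1]];
        std::vector<int> c1 = s1.nodes, c2 = s2.nodes;
        if (c1.front() == node) std::reverse(c1.begin(), c1.end());
        if (c2.back() == node) std::reverse(c2.begin(), c2.end());
        // c1 ends at node, c2 starts at node
        Seg m; m.nodes = c1;
        for (size_t j = 1; j < c2.size(); ++j) m.nodes.push_back(c2[j]);
        m.len = s1.len + s2.len;
        cell.segs.erase(cell.segs.begin() + std::max(at_segs[0], at_segs[1]));
        cell.segs.erase(cell.segs.begin() + std::min(at_segs[0], at_segs[1]));
        cell.segs.push_back(m);
      }
    } else if (tot == 1) {
      // the whole cell is a single arm (plus possibly zero-arm siblings gone):
      // becomes an N==2 path with a tail tip at `node` inheriting dead state
      if (at_arms.size() == 1 && cell.arms.size() == 1 && cell.segs.empty()) {
        Arm a = cell.arms[0];
        Path p;
        p.nodes.push_back(node);
        for (int nd : a.nodes) p.nodes.push_back(nd);
        // A tip = tail at node (length 0 into dead's branch), B tip = arm tip
        // Represent tail as offset 0 pointing into the dead arm's branch.
        p.a_to = dead.branch0;
        p.a_off = 0.0;
        p.b_to = a.tip_to; p.b_off = a.tip_off;
        cell.is_path = true;
        cell.path = p;
        cell.pa_n = dead.n; cell.pa_v = dead.v; cell.pa_rng = dead.rng; cell.pa_id = dead.id;
        cell.pb_n = a.n; cell.pb_v = a.v; cell.pb_rng = a.rng; cell.pb_id = a.id;
        cell.arms.clear(); cell.segs.clear();
      }
    }
    // if a surviving junction arrangement leaves exactly 2 arms total and no
    // segments anywhere, collapse to path form
    if (!cell.is_path && cell.arms.size() == 2 && cell.segs.empty()) {
      if (cell.arms[0].base == cell.arms[1].base)
        to_path(0, 1, cell.arms[0].base);
    }
  }

  void to_path(int ia, int ib, int node) {
    Arm A = cell.arms[ia], B = cell.arms[ib];
    Path p;
    // nodes: A-side reversed ... node ... B-side
    for (auto it = A.nodes.rbegin(); it != A.nodes.rend(); ++it) p.nodes.push_back(*it);
    p.nodes.push_back(node);
    for (int nd : B.nodes) p.nodes.push_back(nd);
    p.a_to = A.tip_to; p.a_off = A.tip_off;
    p.b_to = B.tip_to; p.b_off = B.tip_off;
    cell.is_path = true;
    cell.path = p;
    cell.pa_n = A.n; cell.pa_v = A.v; cell.pa_rng = A.rng; cell.pa_id = A.id;
    cell.pb_n = B.n; cell.pb_v = B.v; cell.pb_rng = B.rng; cell.pb_id = B.id;
    cell.arms.clear(); cell.segs.clear();
  }
};

// ---------------------------------------------------------------------------
// helpers to parse R structures
static Net parse_net(List net) {
  Net N;
  NumericMatrix xy = net["xy"];
  List adj = net["adj"];
  N.nn = xy.nrow();
  N.px.resize(N.nn); N.py.resize(N.nn);
  for (int i = 0; i < N.nn; ++i) { N.px[i] = xy(i, 0); N.py[i] = xy(i, 1); }
  N.adj.resize(N.nn);
  for (int i = 0; i < N.nn; ++i) {
    IntegerVector a = adj[i];
    for (int j = 0; j < a.size(); ++j) N.adj[i].push_back(a[j] - 1);
  }
  return N;
}

static Params parse_params(List p) {
  Params P;
  P.beta0 = p["beta0"]; P.k = p["k"]; P.c = p["c_amount"]; P.D = p["D"];
  P.delta = p["delta"]; P.sigma = p["sigma"]; P.fs = p["f_s"];
  P.kappa = p["kappa"]; P.r = p["r"]; P.wmax = p["omega_max"];
  P.gamma_min = p["gamma_min"]; P.n_floor = p["n_floor"]; P.dt = p["dt"];
  P.eps_split = p["eps_split"];
  return P;
}

static Field parse_field(List f) {
  Field F;
  std::string kind = as<std::string>(f["kind"]);
  F.kind = (kind == "none") ? 0 : (kind == "junction_bias") ? 1 :
           (kind == "point_exp") ? 2 : (kind == "line_exp") ? 3 : 4;
  F.eps = f.containsElementNamed("eps") ? as<double>(f["eps"]) : 0.0;
  F.c0 = f.containsElementNamed("c0") ? as<double>(f["c0"]) : 1.0;
  F.Csat = f.containsElementNamed("C_sat") ? as<double>(f["C_sat"]) : 1.0;
  F.decay = f.containsElementNamed("decay") ? as<double>(f["decay"]) : 1.0;
  F.sx = f.containsElementNamed("source_x") ? as<double>(f["source_x"]) : 0.0;
  F.sy = f.containsElementNamed("source_y") ? as<double>(f["source_y"]) : 0.0;
  F.slope_len = f.containsElementNamed("slope_len") ? as<double>(f["slope_len"]) : 1.0;
  F.onset = f.containsElementNamed("onset") ? as<double>(f["onset"]) : -1e300;
  F.biased_node = f.containsElementNamed("biased_node") ?
    (as<int>(f["biased_node"]) - 1) : -1;
  return F;
}

// [[Rcpp::export(name = ".sim_run")]]
List sim_run(List net, List cell0, List params, List field, List control,
             double seed) {
  Sim S;
  S.net = parse_net(net);
  S.P = parse_params(params);
  S.F = parse_field(field);
  S.run_seed = (uint64_t)seed;

  double t_max = control["t_max"];
  double record_every = control["record_every"];
  bool record_arms = control.containsElementNamed("record_arms") ?
    as<bool>(control["record_arms"]) : false;
  double t0 = control.containsElementNamed("t0") ? as<double>(control["t0"]) : 0.0;
  double stop_y = control.containsElementNamed("stop_y") ?
    as<double>(control["stop_y"]) : R_PosInf;
  bool stop_escape = control.containsElementNamed("stop_escape") ?
    as<bool>(control["stop_escape"]) : false;
  int escape_node = control.containsElementNamed("escape_node") ?
    (as<int>(control["escape_node"]) - 1) : -1;

  // initial cell
  std::string ckind = as<std::string>(cell0["kind"]);
  if (ckind == "two_arm") {
    // cell inside the single edge (node_a -> node_b), tips at offsets
    S.cell.is_path = true;
    Path p;
    p.a_anchor = as<int>(cell0["node_a"]) - 1;
    p.a_to = as<int>(cell0["node_b"]) - 1;
    NumericVector off = cell0["offsets"];   // increasing along a->b
    p.a_off = off[0]; p.b_off = off[1];
    S.cell.path = p;
    NumericVector nn = cell0["n"], vv = cell0["v"];
    S.cell.pa_n = nn[0]; S.cell.pb_n = nn[1];
    S.cell.pa_v = vv[0]; S.cell.pb_v = vv[1];
    S.cell.pa_id = S.cell.next_id++;
    S.cell.pb_id = S.cell.next_id++;
    S.cell.pa_rng.seed(S.run_seed, (uint64_t)S.cell.pa_id);
    S.cell.pb_rng.seed(S.run_seed, (uint64_t)S.cell.pb_id);
  } else {  // "star": N arms from a junction node along given neighbours
    S.cell.is_path = false;
    int base = as<int>(cell0["node"]) - 1;
    IntegerVector toward = cell0["toward"];
    NumericVector xs = cell0["x"], nn = cell0["n"], vv = cell0["v"];
    for (int i = 0; i < toward.size(); ++i) {
      Arm a;
      a.base = base;
      a.tip_to = toward[i] - 1;
      a.branch0 = a.tip_to;
      a.tip_off = xs[i]; a.x = xs[i];
      a.n = nn[i]; a.v = vv[i];
      a.id = S.cell.next_id++;
      a.rng.seed(S.run_seed, (uint64_t)a.id);
      S.cell.arms.push_back(a);
    }
  }

  S.t = t0;
  Recorder rec;
  rec.arms_on = record_arms;

  int nstep = (int)std::llround((t_max - t0) / S.P.dt);
  int every = std::max(1, (int)std::llround(record_every / S.P.dt));
  double arrival_t = NA_REAL;
  int escape_branch = NA_INTEGER;
  double escape_t = NA_REAL;
  bool done = false;
  // escape requires the cell to have engaged the junction first
  bool engaged = !S.cell.is_path;
  if (!engaged && escape_node >= 0)
    for (int nd : S.cell.path.nodes) if (nd == escape_node) engaged = true;

  auto sample = [&](int evcode) {
    double cx, cy; S.com(cx, cy);
    rec.t.push_back(S.t); rec.comx.push_back(cx); rec.comy.push_back(cy);
    rec.L.push_back(S.total_len()); rec.N.push_back(S.n_arms());
    rec.ev.push_back(evcode);
    if (rec.arms_on) {
      if (S.cell.is_path) {
        double ax_, ay_, bx_, by_; S.path_tips(ax_, ay_, bx_, by_);
        double Lh = S.total_len() * 0.5;
        const int ids[2] = {S.cell.pa_id, S.cell.pb_id};
        const double ns[2] = {S.cell.pa_n, S.cell.pb_n};
        const double vs[2] = {S.cell.pa_v, S.cell.pb_v};
        const double txs[2] = {ax_, bx_}, tys[2] = {ay_, by_};
        for (int i = 0; i < 2; ++i) {
          rec.at.push_back(S.t); rec.aid.push_back(ids[i]);
          rec.ax.push_back(Lh); rec.an.push_back(ns[i]); rec.av.push_back(vs[i]);
          rec.abeta.push_back(S.F.beta_tip(S.t, S.P.beta0, txs[i], tys[i], -2));
          rec.atx.push_back(txs[i]); rec.aty.push_back(tys[i]);
          rec.abase.push_back(NA_INTEGER);
        }
      } else {
        for (const Arm &a : S.cell.arms) {
          double tx, ty; S.arm_tip(a, tx, ty);
          rec.at.push_back(S.t); rec.aid.push_back(a.id);
          rec.ax.push_back(a.x); rec.an.push_back(a.n); rec.av.push_back(a.v);
          rec.abeta.push_back(S.F.beta_tip(S.t, S.P.beta0, tx, ty, a.branch0));
          rec.atx.push_back(tx); rec.aty.push_back(ty);
          rec.abase.push_back(a.base + 1);
        }
      }
    }
  };

  sample(0);
  size_t ev_seen = 0;
  for (int s = 1; s <= nstep && !done; ++s) {
    S.step(rec);
    if (!S.finite_ok) break;
    // stopping rules
    if (R_finite(stop_y)) {
      double best = -1e300;
      if (S.cell.is_path) {
        double ax_, ay_, bx_, by_; S.path_tips(ax_, ay_, bx_, by_);
        best = std::max(ay_, by_);
      } else {
        for (const Arm &a : S.cell.arms) {
          double tx, ty; S.arm_tip(a, tx, ty);
          best = std::max(best, ty);
        }
      }
      if (best >= stop_y) { arrival_t = S.t; done = true; }
    }
    if (!engaged) {
      if (!S.cell.is_path) engaged = true;
      else if (escape_node >= 0)
        for (int nd : S.cell.path.nodes) if (nd == escape_node) engaged = true;
    }
    if (stop_escape && engaged && S.cell.is_path && S.cell.path.nodes.empty()) {
      // cell entirely within one edge: which branch of the escape node?
      int a = S.cell.path.a_anchor, b = S.cell.path.a_to;
      if (escape_node < 0 || a == escape_node || b == escape_node) {
        escape_branch = (a == escape_node) ? b + 1 : a + 1;
        // branch id = far node if anchored at centre, else anchor itself
        if (escape_node >= 0 && a != escape_node && b != escape_node)
          escape_branch = NA_INTEGER;  // drifted elsewhere (network case)
        escape_t = S.t;
        done = true;
      }
    }
    if (s % every == 0 || done) {
      int code = 0;
      for (; ev_seen < rec.events.size(); ++ev_seen)
        code = std::max(code, rec.events[ev_seen].kind);
      sample(code);
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  // final per-arm state (for timeout classification etc.)
  List final_arms;
  if (S.cell.is_path) {
    final_arms = List::create(
      _["kind"] = "path",
      _["ids"] = IntegerVector::create(S.cell.pa_id, S.cell.pb_id),
      _["x"] = NumericVector::create(S.total_len() / 2, S.total_len() / 2),
      _["a_to"] = S.cell.path.nodes.empty() ? S.cell.path.a_to + 1 : S.cell.path.a_to + 1,
      _["b_to"] = S.cell.path.nodes.empty() ? S.cell.path.a_to + 1 : S.cell.path.b_to + 1);
  } else {
    int N = (int)S.cell.arms.size();
    IntegerVector ids(N), branch(N);
    NumericVector xs(N), ns(N), vs(N);
    for (int i = 0; i < N; ++i) {
      ids[i] = S.cell.arms[i].id; xs[i] = S.cell.arms[i].x;
      ns[i] = S.cell.arms[i].n; vs[i] = S.cell.arms[i].v;
      branch[i] = S.cell.arms[i].branch0 + 1;
    }
    final_arms = List::create(_["kind"] = "tree", _["ids"] = ids, _["x"] = xs,
                              _["n"] = ns, _["v"] = vs, _["branch"] = branch);
  }

  int ne = (int)rec.events.size();
  NumericVector ev_t(ne); IntegerVector ev_kind(ne), ev_arm(ne), ev_node(ne);
  for (int i = 0; i < ne; ++i) {
    ev_t[i] = rec.events[i].t; ev_kind[i] = rec.events[i].kind;
    ev_arm[i] = rec.events[i].arm; ev_node[i] = rec.events[i].node + 1;
  }

  List out = List::create(
    _["time"] = rec.t, _["com_x"] = rec.comx, _["com_y"] = rec.comy,
    _["L"] = rec.L, _["N"] = rec.N, _["event"] = rec.ev,
    _["events"] = List::create(_["time"] = ev_t, _["kind"] = ev_kind,
                               _["arm"] = ev_arm, _["node"] = ev_node),
    _["final"] = final_arms,
    _["arrival_time"] = arrival_t,
    _["escape_branch"] = escape_branch,
    _["escape_time"] = escape_t,
    _["finite_ok"] = S.finite_ok,
    _["boundary_hit"] = S.boundary_hit,
    _["weight_err_max"] = S.weight_err_max);
  if (record_arms) {
    out["arms"] = List::create(
      _["time"] = rec.at, _["arm_id"] = rec.aid, _["x"] = rec.ax,
      _["n"] = rec.an, _["v"] = rec.av, _["beta_tip"] = rec.abeta,
      _["tip_x"] = rec.atx, _["tip_y"] = rec.aty, _["base"] = rec.abase);
  }
  return out;
}
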