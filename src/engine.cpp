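// Lattice Monte Carlo engine.
//
// The membrane is an L x L periodic square lattice. Every site is either a
// lipid (carrying an Ising spin +1/-1) or part of a disk-shaped inclusion.
// Lipids evolve by Kawasaki (spin-exchange) dynamics, inclusions by unit
// translation moves; both use Metropolis acceptance and therefore satisfy
// detailed balance. Contact reactions run once per sweep and are the only
// detailed-balance-violating step.
//
// Hot loops live here; configuration, analysis and the enumeration oracle
// stay in R. All randomness comes from two PCG32 streams (movement and
// reactions) derived from a single integer seed, so runs are bit-reproducible
// and enabling reactions with static partitioning leaves the configurational
// trajectory untouched.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// PCG32 (O'Neill) — small, fast, reproducible across platforms.
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    inc = (seq << 1u) | 1u;
    state = 0u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xs = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xs >> rot) | (xs << ((-rot) & 31u));
  }
  double unif() { return std::ldexp((double)next(), -32); }  // [0, 1)
  uint32_t bounded(uint32_t n) {                             // [0, n)
    return (uint32_t)(((uint64_t)next() * n) >> 32);
  }
};

const int DX[4] = {1, -1, 0, 0};
const int DY[4] = {0, 0, 1, -1};

// Per-species geometry and state table.
struct TypeInfo {
  int radius;
  double mobility;              // translation attempts per sweep (C)
  std::vector<int> dx, dy;      // footprint offsets, dx^2+dy^2 <= r^2
  std::vector<char> isb;        // offset is on the disk boundary
  std::vector<int> bpref;       // boundary spin per state
  // Move bookkeeping per direction d: offsets (relative to the NEW centre)
  // newly covered by the move, and the mirrored offsets (relative to the OLD
  // centre) they vacate. The mirror is an involution, which keeps forward and
  // reverse proposals symmetric (detailed balance).
  std::vector<int> lead[4];     // indices into dx/dy
  std::vector<int> trl_x[4], trl_y[4];
};

struct Rule {
  int at, as;       // actor type, actor state (0-based)
  int st, ss, ps;   // substrate type, substrate pre-state, product state
  double rate;
  int sign;
};

struct Contact { int a, b; };

struct Engine {
  int L = 0, nsite = 0;
  double J = 1.0, Jint = 1.0, beta = 0.0;
  std::vector<int> spin;   // +1/-1 on lipids, 0 on inclusion sites
  std::vector<int> occ;    // -1 lipid, else inclusion index
  std::vector<int> fld;    // lipid spin / boundary b / 0 (interior)
  std::vector<int> nbr;    // 4*nsite neighbour table
  std::vector<TypeInfo> types;
  std::vector<int> inc_type, inc_cx, inc_cy, inc_state;  // 0-based
  std::vector<Rule> rules;
  Pcg32 mv, rx;
  std::vector<int> stamp;
  int stampc = 0;
  std::vector<int> modified;  // substrate-modified-this-sweep flags
  // acceptance diagnostics
  long long lip_att = 0, lip_acc = 0, incl_att = 0, incl_acc = 0;
  // fast path for integer couplings: exp(-beta*k) table
  bool tab_ok = false;
  double etab[64];
  // preallocated scratch (hot loop: avoid per-sweep heap churn)
  std::vector<std::pair<uint32_t, int>> slots_buf;
  std::vector<Contact> cp_buf;
  std::vector<int> U_buf, sv_spin_buf, sv_occ_buf, sv_fld_buf, lead_spin_buf;

  Engine(uint64_t seed) : mv(seed, 1), rx(seed, 2) {}

  int wrap(int a) const { int r = a % L; return r < 0 ? r + L : r; }
  int site(int x, int y) const { return wrap(x) + wrap(y) * L; }

  void build_tables() {
    nbr.assign(4 * (size_t)nsite, 0);
    for (int y = 0; y < L; ++y)
      for (int x = 0; x < L; ++x)
        for (int d = 0; d < 4; ++d)
          nbr[4 * (size_t)(x + y * L) + d] = site(x + DX[d], y + DY[d]);
    stamp.assign(nsite, 0);
    stampc = 0;
    tab_ok = (J == std::floor(J)) && (Jint == std::floor(Jint)) &&
             std::abs(J) <= 4 && std::abs(Jint) <= 4;
    if (tab_ok)
      for (int k = 0; k < 64; ++k) etab[k] = std::exp(-beta * k);
  }

  double accept_prob_exp(double dE) {
    if (tab_ok) {
      int k = (int)std::llround(dE);
      if (k >= 0 && k < 64 && (double)k == dE) return etab[k];
    }
    return std::exp(-beta * dE);
  }

  // Rebuild occupancy and the interaction field from the inclusion registry.
  void place_inclusions() {
    occ.assign(nsite, -1);
    fld.resize(nsite);
    for (int s = 0; s < nsite; ++s) fld[s] = (occ[s] < 0) ? spin[s] : 0;
    for (size_t i = 0; i < inc_type.size(); ++i) {
      const TypeInfo& T = types[inc_type[i]];
      int b = T.bpref[inc_state[i]];
      for (size_t k = 0; k < T.dx.size(); ++k) {
        int s = site(inc_cx[i] + T.dx[k], inc_cy[i] + T.dy[k]);
        if (occ[s] >= 0) stop("inclusion footprints overlap");
        occ[s] = (int)i;
        spin[s] = 0;
        fld[s] = T.isb[k] ? b : 0;
      }
    }
    for (int s = 0; s < nsite; ++s)
      if (occ[s] < 0) fld[s] = spin[s];
    modified.assign(inc_type.size(), 0);
  }

  // Energy of the bond (u, v). Lipid-lipid pairs couple with J; pairs that
  // straddle an inclusion boundary couple with Jint; pairs inside one
  // inclusion contribute nothing (interior sites carry no spin and fld = 0
  // there makes interior-lipid pairs vanish automatically).
  double bond(int u, int v) const {
    int ou = occ[u], ov = occ[v];
    if (ou < 0 && ov < 0) return -J * spin[u] * spin[v];
    if (ou == ov) return 0.0;
    return -Jint * (double)fld[u] * fld[v];
  }

  void total_energy(double& Emem, double& Eint) const {
    Emem = Eint = 0.0;
    for (int y = 0; y < L; ++y)
      for (int x = 0; x < L; ++x) {
        int u = x + y * L;
        int vs[2] = {site(x + 1, y), site(x, y + 1)};
        for (int v : vs) {
          if (occ[u] < 0 && occ[v] < 0)
            Emem += -J * spin[u] * spin[v];
          else if (occ[u] != occ[v])
            Eint += -Jint * (double)fld[u] * fld[v];
        }
      }
  }

  // Sum of coupling-weighted neighbour fields of u, excluding site excl.
  double hsum(int u, int excl) const {
    double h = 0.0;
    const int* nb = &nbr[4 * (size_t)u];
    for (int k = 0; k < 4; ++k) {
      int w = nb[k];
      if (w == excl) continue;
      h += (occ[w] < 0) ? J * spin[w] : Jint * fld[w];
    }
    return h;
  }

  void attempt_swap() {
    ++lip_att;
    int u = (int)mv.bounded(nsite);
    int v = nbr[4 * (size_t)u + mv.bounded(4)];
    if (occ[u] >= 0 || occ[v] >= 0) return;  // counted, rejected
    if (spin[u] == spin[v]) return;
    double dE = (spin[u] - spin[v]) * (hsum(u, v) - hsum(v, u));
    if (dE <= 0 || mv.unif() < accept_prob_exp(dE)) {
      std::swap(spin[u], spin[v]);
      fld[u] = spin[u];
      fld[v] = spin[v];
      ++lip_acc;
    }
  }

  // Local energy over bonds touching the marked set U (stamp == stampc).
  double localE(const std::vector<int>& U) const {
    double e = 0.0;
    for (int u : U) {
      const int* nb = &nbr[4 * (size_t)u];
      for (int k = 0; k < 4; ++k) {
        int v = nb[k];
        e += (stamp[v] == stampc ? 0.5 : 1.0) * bond(u, v);
      }
    }
    return e;
  }

  // One translation attempt for inclusion i in direction d (d < 0: random).
  // Lipids on the leading edge are relocated to the mirrored trailing sites,
  // the full local energy change is Metropolis-tested, and the move is
  // reverted if rejected. Returns 1 if accepted.
  int attempt_inclusion(int i, int d = -1) {
    ++incl_att;
    if (d < 0) d = (int)mv.bounded(4);
    TypeInfo& T = types[inc_type[i]];
    int cx = inc_cx[i], cy = inc_cy[i];
    int ncx = wrap(cx + DX[d]), ncy = wrap(cy + DY[d]);
    for (int li : T.lead[d]) {
      int s = site(ncx + T.dx[li], ncy + T.dy[li]);
      if (occ[s] >= 0) return 0;  // excluded volume
    }
    ++stampc;
    std::vector<int>& U = U_buf;
    U.clear();
    for (size_t k = 0; k < T.dx.size(); ++k) {
      int s1 = site(cx + T.dx[k], cy + T.dy[k]);
      if (stamp[s1] != stampc) { stamp[s1] = stampc; U.push_back(s1); }
      int s2 = site(ncx + T.dx[k], ncy + T.dy[k]);
      if (stamp[s2] != stampc) { stamp[s2] = stampc; U.push_back(s2); }
    }
    double e0 = localE(U);
    std::vector<int>& sv_spin = sv_spin_buf;
    std::vector<int>& sv_occ = sv_occ_buf;
    std::vector<int>& sv_fld = sv_fld_buf;
    sv_spin.resize(U.size()); sv_occ.resize(U.size()); sv_fld.resize(U.size());
    for (size_t k = 0; k < U.size(); ++k) {
      sv_spin[k] = spin[U[k]]; sv_occ[k] = occ[U[k]]; sv_fld[k] = fld[U[k]];
    }
    size_t nl = T.lead[d].size();
    std::vector<int>& lead_spin = lead_spin_buf;
    lead_spin.resize(nl);
    for (size_t k = 0; k < nl; ++k) {
      int li = T.lead[d][k];
      lead_spin[k] = spin[site(ncx + T.dx[li], ncy + T.dy[li])];
    }
    for (size_t k = 0; k < T.dx.size(); ++k) {
      int s = site(cx + T.dx[k], cy + T.dy[k]);
      occ[s] = -1; spin[s] = 0; fld[s] = 0;
    }
    int b = T.bpref[inc_state[i]];
    for (size_t k = 0; k < T.dx.size(); ++k) {
      int s = site(ncx + T.dx[k], ncy + T.dy[k]);
      occ[s] = (int)i; spin[s] = 0; fld[s] = T.isb[k] ? b : 0;
    }
    for (size_t k = 0; k < nl; ++k) {
      int s = site(cx + T.trl_x[d][k], cy + T.trl_y[d][k]);
      occ[s] = -1; spin[s] = lead_spin[k]; fld[s] = lead_spin[k];
    }
    double dE = localE(U) - e0;
    if (dE <= 0 || mv.unif() < std::exp(-beta * dE)) {
      inc_cx[i] = ncx; inc_cy[i] = ncy;
      ++incl_acc;
      return 1;
    }
    for (size_t k = 0; k < U.size(); ++k) {
      spin[U[k]] = sv_spin[k]; occ[U[k]] = sv_occ[k]; fld[U[k]] = sv_fld[k];
    }
    return 0;
  }

  // Unordered pairs of inclusions whose footprints are four-adjacent.
  void contacts(std::vector<Contact>& out) const {
    out.clear();
    for (size_t i = 0; i < inc_type.size(); ++i) {
      const TypeInfo& T = types[inc_type[i]];
      for (size_t k = 0; k < T.dx.size(); ++k) {
        int s = site(inc_cx[i] + T.dx[k], inc_cy[i] + T.dy[k]);
        const int* nb = &nbr[4 * (size_t)s];
        for (int q = 0; q < 4; ++q) {
          int j = occ[nb[q]];
          if (j >= 0 && j != (int)i)
            out.push_back({std::min((int)i, j), std::max((int)i, j)});
        }
      }
    }
    std::sort(out.begin(), out.end(), [](const Contact& a, const Contact& b) {
      return a.a < b.a || (a.a == b.a && a.b < b.b);
    });
    out.erase(std::unique(out.begin(), out.end(),
                          [](const Contact& a, const Contact& b) {
                            return a.a == b.a && a.b == b.b;
                          }),
              out.end());
  }

  // One reaction pass over the current (post-movement) configuration.
  // Pairs and, within a pair, eligible rules are visited in randomized order;
  // a substrate modified this sweep is not modified again. A firing changes
  // only the substrate's state label and (possibly) its boundary field —
  // this is the detailed-balance-violating step.
  struct Firing { int rule, actor, sub; };
  void reaction_pass(int sweep, bool log_events, std::vector<int>& ev) {
    if (rules.empty() || inc_type.empty()) return;
    std::vector<Contact>& cp = cp_buf;
    contacts(cp);
    for (size_t k = cp.size(); k > 1; --k)
      std::swap(cp[k - 1], cp[rx.bounded((uint32_t)k)]);
    std::fill(modified.begin(), modified.end(), 0);
    std::vector<Firing> cand;
    for (const Contact& c : cp) {
      cand.clear();
      for (size_t r = 0; r < rules.size(); ++r) {
        const Rule& R = rules[r];
        if (inc_type[c.a] == R.at && inc_type[c.b] == R.st)
          cand.push_back({(int)r, c.a, c.b});
        if (inc_type[c.b] == R.at && inc_type[c.a] == R.st)
          cand.push_back({(int)r, c.b, c.a});
      }
      for (size_t k = cand.size(); k > 1; --k)
        std::swap(cand[k - 1], cand[rx.bounded((uint32_t)k)]);
      for (const Firing& f : cand) {
        const Rule& R = rules[f.rule];
        if (modified[f.sub]) continue;
        if (inc_state[f.actor] != R.as || inc_state[f.sub] != R.ss) continue;
        if (rx.unif() >= R.rate) continue;
        inc_state[f.sub] = R.ps;
        const TypeInfo& T = types[inc_type[f.sub]];
        int b = T.bpref[R.ps];
        for (size_t k = 0; k < T.dx.size(); ++k)
          if (T.isb[k])
            fld[site(inc_cx[f.sub] + T.dx[k], inc_cy[f.sub] + T.dy[k])] = b;
        modified[f.sub] = 1;
        if (log_events) {
          ev.push_back(sweep); ev.push_back(f.rule + 1);
          ev.push_back(f.actor + 1); ev.push_back(f.sub + 1);
        }
      }
    }
  }

  // Nonconserved single-spin-flip attempt (internal testing dynamics; the
  // production dynamics are Kawasaki). Samples the unconstrained ensemble.
  void attempt_flip() {
    ++lip_att;
    int u = (int)mv.bounded(nsite);
    if (occ[u] >= 0) return;
    double dE = 2.0 * spin[u] * hsum(u, -1);
    if (dE <= 0 || mv.unif() < std::exp(-beta * dE)) {
      spin[u] = -spin[u];
      fld[u] = spin[u];
      ++lip_acc;
    }
  }

  bool glauber = false;

  // One sweep of movement: L^2 lipid exchange attempts with the per-sweep
  // inclusion attempts interleaved at uniformly random points.
  void sweep_movement(bool move_lipids, bool move_inclusions) {
    std::vector<std::pair<uint32_t, int>>& slots = slots_buf;
    slots.clear();
    if (move_inclusions && !inc_type.empty()) {
      for (size_t i = 0; i < inc_type.size(); ++i) {
        double C = types[inc_type[i]].mobility;
        int n = (int)std::floor(C);
        if (mv.unif() < C - std::floor(C)) ++n;
        for (int k = 0; k < n; ++k)
          slots.push_back({mv.bounded((uint32_t)nsite), (int)i});
      }
      std::sort(slots.begin(), slots.end());
    }
    size_t si = 0;
    for (int a = 0; a < nsite; ++a) {
      while (si < slots.size() && (int)slots[si].first <= a)
        attempt_inclusion(slots[si++].second);
      if (move_lipids) {
        if (glauber) attempt_flip(); else attempt_swap();
      }
    }
    while (si < slots.size()) attempt_inclusion(slots[si++].second);
  }

  int64_t config_key() const {
    int64_t bits = 0;
    for (int s = 0; s < nsite; ++s)
      if (occ[s] < 0 && spin[s] > 0) bits |= ((int64_t)1 << s);
    int64_t cpart = 0;
    if (!inc_type.empty())
      cpart = inc_cx[0] + (int64_t)inc_cy[0] * L;
    return cpart * ((int64_t)1 << nsite) + bits;
  }
};

// --- marshalling -----------------------------------------------------------

void disk_offsets(int r, std::vector<int>& dx, std::vector<int>& dy,
                  std::vector<char>& isb) {
  dx.clear(); dy.clear(); isb.clear();
  int r2 = r * r;
  std::vector<std::pair<int, int>> off;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if (a * a + b * b <= r2) off.push_back({a, b});
  auto inside = [&](int a, int b) { return a * a + b * b <= r2; };
  for (auto& o : off) {
    dx.push_back(o.first);
    dy.push_back(o.second);
    bool bdy = !inside(o.first + 1, o.second) || !inside(o.first - 1, o.second) ||
               !inside(o.first, o.second + 1) || !inside(o.first, o.second - 1);
    isb.push_back(bdy ? 1 : 0);
  }
}

void build_move_tables(TypeInfo& T) {
  int n = (int)T.dx.size();
  auto member = [&](int a, int b) {
    for (int k = 0; k < n; ++k)
      if (T.dx[k] == a && T.dy[k] == b) return true;
    return false;
  };
  for (int d = 0; d < 4; ++d) {
    T.lead[d].clear(); T.trl_x[d].clear(); T.trl_y[d].clear();
    for (int k = 0; k < n; ++k) {
      if (!member(T.dx[k] + DX[d], T.dy[k] + DY[d])) {
        T.lead[d].push_back(k);
        // mirror: negate the offset component along the move axis
        int tx = (DX[d] != 0) ? -T.dx[k] : T.dx[k];
        int ty = (DY[d] != 0) ? -T.dy[k] : T.dy[k];
        T.trl_x[d].push_back(tx);
        T.trl_y[d].push_back(ty);
      }
    }
  }
}

Engine* make_engine(List st, List net, double tau, double J, double Jint,
                    double tc_bare, int seed) {
  Engine* E = new Engine((uint64_t)(uint32_t)seed);
  E->L = as<int>(st["L"]);
  E->nsite = E->L * E->L;
  E->J = J;
  E->Jint = Jint;
  if (tau <= 0) stop("tau must be > 0");
  E->beta = 1.0 / (tau * tc_bare);
  IntegerVector sp = st["spins"];
  if ((int)sp.size() != E->nsite) stop("spin vector has wrong length");
  E->spin.assign(sp.begin(), sp.end());

  List tls = net["types"];
  for (int t = 0; t < tls.size(); ++t) {
    List tl = tls[t];
    TypeInfo T;
    T.radius = as<int>(tl["radius"]);
    T.mobility = as<double>(tl["mobility"]);
    IntegerVector bp = tl["bpref"];
    T.bpref.assign(bp.begin(), bp.end());
    disk_offsets(T.radius, T.dx, T.dy, T.isb);
    build_move_tables(T);
    E->types.push_back(T);
  }
  IntegerVector it = st["inc_type"], ix = st["inc_cx"], iy = st["inc_cy"],
                is_ = st["inc_state"];
  for (int i = 0; i < it.size(); ++i) {
    E->inc_type.push_back(it[i] - 1);
    E->inc_cx.push_back(ix[i] - 1);
    E->inc_cy.push_back(iy[i] - 1);
    E->inc_state.push_back(is_[i] - 1);
  }
  List rl = net["rules"];
  if (rl.size() > 0) {
    IntegerVector at = rl["actor_type"], as_ = rl["actor_state"],
                  stp = rl["sub_type"], ss = rl["sub_state"],
                  ps = rl["product_state"], sg = rl["sign"];
    NumericVector rt = rl["rate"];
    for (int r = 0; r < at.size(); ++r)
      E->rules.push_back({at[r] - 1, as_[r] - 1, stp[r] - 1, ss[r] - 1,
                          ps[r] - 1, rt[r], sg[r]});
  }
  E->build_tables();
  E->place_inclusions();
  return E;
}

List export_state(const Engine& E) {
  IntegerVector sp(E.nsite), oc(E.nsite);
  for (int s = 0; s < E.nsite; ++s) {
    sp[s] = E.spin[s];
    oc[s] = E.occ[s] + 1;  // 0 = lipid for R
  }
  int n = (int)E.inc_type.size();
  IntegerVector it(n), ix(n), iy(n), is_(n);
  for (int i = 0; i < n; ++i) {
    it[i] = E.inc_type[i] + 1;
    ix[i] = E.inc_cx[i] + 1;
    iy[i] = E.inc_cy[i] + 1;
    is_[i] = E.inc_state[i] + 1;
  }
  return List::create(_["L"] = E.L, _["spins"] = sp, _["occ"] = oc,
                      _["inc_type"] = it, _["inc_cx"] = ix, _["inc_cy"] = iy,
                      _["inc_state"] = is_);
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(List st, List net, double tau, double J, double Jint,
             double tc_bare, int sweeps, int record_every, int snapshot_every,
             bool move_lipids, bool move_inclusions, bool do_reactions,
             bool log_events, int seed, bool glauber = false) {
  Engine* E = make_engine(st, net, tau, J, Jint, tc_bare, seed);
  E->glauber = glauber;
  int ntype = (int)E->types.size();
  std::vector<int> state_off(ntype + 1, 0);
  for (int t = 0; t < ntype; ++t)
    state_off[t + 1] = state_off[t] + (int)E->types[t].bpref.size();
  int nslot = state_off[ntype];

  int nrec = 1 + (record_every > 0 ? sweeps / record_every : 0);
  IntegerMatrix counts(nrec, nslot);
  IntegerVector rec_sweep(nrec);
  NumericVector rec_emem(nrec), rec_eint(nrec);
  int rec = 0;
  auto record = [&](int sw) {
    rec_sweep[rec] = sw;
    for (int k = 0; k < nslot; ++k) counts(rec, k) = 0;
    for (size_t i = 0; i < E->inc_type.size(); ++i)
      counts(rec, state_off[E->inc_type[i]] + E->inc_state[i])++;
    double em, ei;
    E->total_energy(em, ei);
    rec_emem[rec] = em;
    rec_eint[rec] = ei;
    ++rec;
  };
  record(0);

  std::vector<int> ev;
  List snaps;
  std::vector<List> snap_list;
  for (int sw = 1; sw <= sweeps; ++sw) {
    E->sweep_movement(move_lipids, move_inclusions);
    if (do_reactions) E->reaction_pass(sw, log_events, ev);
    if (record_every > 0 && sw % record_every == 0) record(sw);
    if (snapshot_every > 0 && sw % snapshot_every == 0) {
      List s = export_state(*E);
      s["sweep"] = sw;
      snap_list.push_back(s);
    }
    if (sw % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  int nev = (int)ev.size() / 4;
  IntegerMatrix events(nev, 4);
  for (int e = 0; e < nev; ++e)
    for (int k = 0; k < 4; ++k) events(e, k) = ev[4 * e + k];

  List out = List::create(
      _["state"] = export_state(*E),
      _["rec_sweep"] = rec_sweep, _["counts"] = counts,
      _["e_mem"] = rec_emem, _["e_int"] = rec_eint,
      _["events"] = events,
      _["snapshots"] = wrap(snap_list),
      _["acc"] = NumericVector::create(
          _["lipid_attempts"] = (double)E->lip_att,
          _["lipid_accepts"] = (double)E->lip_acc,
          _["inclusion_attempts"] = (double)E->incl_att,
          _["inclusion_accepts"] = (double)E->incl_acc));
  delete E;
  return out;
}

// [[Rcpp::export]]
List cpp_total_energy(List st, List net, double J, double Jint) {
  Engine* E = make_engine(st, net, 1.0, J, Jint, 1.0, 1);
  double em, ei;
  E->total_energy(em, ei);
  delete E;
  return List::create(_["mem"] = em, _["int"] = ei);
}

// [[Rcpp::export]]
List cpp_inclusion_attempt(List st, List net, double tau, double J,
                           double Jint, double tc_bare, int inc, int dir,
                           int seed) {
  Engine* E = make_engine(st, net, tau, J, Jint, tc_bare, seed);
  if (inc < 1 || inc > (int)E->inc_type.size()) stop("no such inclusion");
  int acc = E->attempt_inclusion(inc - 1, dir >= 1 && dir <= 4 ? dir - 1 : -1);
  List out = List::create(_["accepted"] = (acc == 1),
                          _["state"] = export_state(*E));
  delete E;
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_contacts(List st, List net) {
  Engine* E = make_engine(st, net, 1.0, 1.0, 1.0, 1.0, 1);
  std::vector<Contact> cp;
  E->contacts(cp);
  IntegerMatrix out((int)cp.size(), 2);
  for (size_t k = 0; k < cp.size(); ++k) {
    out((int)k, 0) = cp[k].a + 1;
    out((int)k, 1) = cp[k].b + 1;
  }
  delete E;
  return out;
}

// Movement-only sampling run that tabulates the configuration key after each
// sweep; used to compare long-run frequencies against the enumeration oracle.
// [[Rcpp::export]]
List cpp_sample_keys(List st, List net, double tau, double J, double Jint,
                     double tc_bare, int sweeps, bool move_inclusions,
                     int seed) {
  Engine* E = make_engine(st, net, tau, J, Jint, tc_bare, seed);
  if (E->nsite > 40) stop("configuration keys require L*L <= 40");
  std::unordered_map<int64_t, int64_t> tab;
  for (int sw = 1; sw <= sweeps; ++sw) {
    E->sweep_movement(true, move_inclusions);
    ++tab[E->config_key()];
    if (sw % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector keys((int)tab.size()), cnt((int)tab.size());
  int k = 0;
  for (auto& kv : tab) {
    keys[k] = (double)kv.first;
    cnt[k] = (double)kv.second;
    ++k;
  }
  delete E;
  return List::create(_["key"] = keys, _["count"] = cnt);
}
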