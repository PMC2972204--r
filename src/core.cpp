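// Core lattice kernels: MOS Monte-Carlo moves (bead flip, crankshaft,
// 3-D crankshaft rebridge), hook-insertion chain growth, and exhaustive
// enumeration of constrained walks.  All randomness comes from R's RNG so
// set.seed() makes every routine reproducible.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdint>
using namespace Rcpp;

typedef std::array<int, 3> Site;

// Fixed step order (+x,-x,+y,-y,+z,-z); enumeration order and symbol codes
// elsewhere rely on this.
static const int DIRS[6][3] = {
  {1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1}
};

struct Box {
  int nx, ny, nz;
  bool bounded;
  bool contains(const Site& s) const {
    if (!bounded) return true;
    return s[0] >= 0 && s[0] < nx && s[1] >= 0 && s[1] < ny &&
           s[2] >= 0 && s[2] < nz;
  }
  long index(const Site& s) const {
    return s[0] + (long)nx * (s[1] + (long)ny * s[2]);
  }
  long volume() const { return (long)nx * ny * nz; }
};

static Box make_box(const IntegerVector& dim) {
  Box b;
  if (dim.size() == 0 || dim[0] < 0) {
    b.nx = b.ny = b.nz = 0; b.bounded = false;
  } else {
    b.nx = dim[0]; b.ny = dim[1]; b.nz = dim[2]; b.bounded = true;
  }
  return b;
}

static inline int axis_of(const Site& a, const Site& b) {
  // axis of the unit step a -> b, or -1 if not a unit step
  int dx = b[0] - a[0], dy = b[1] - a[1], dz = b[2] - a[2];
  int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
  if (m != 1) return -1;
  if (dx != 0) return 0;
  if (dy != 0) return 1;
  return 2;
}

static inline Site add(const Site& a, const int d[3]) {
  Site r = {{a[0] + d[0], a[1] + d[1], a[2] + d[2]}};
  return r;
}

static inline int runif_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// ---------------------------------------------------------------------------
// chain state shared by the sampler and growth routines

struct Chain {
  std::vector<Site> sites;
  bool closed;
  std::vector<char> pinned;
  int n() const { return (int)sites.size(); }
  int bonds() const { return closed ? n() : n() - 1; }
};

struct State {
  std::vector<Chain> chains;
  Box box;
  bool saw;                    // self-avoidance / mutual exclusion on
  std::vector<int> grid;       // occupancy counts (only if saw)

  void build_grid() {
    if (!saw) return;
    if (!box.bounded) stop("self-avoiding sampling requires a bounded box");
    grid.assign(box.volume(), 0);
    for (size_t c = 0; c < chains.size(); ++c)
      for (int i = 0; i < chains[c].n(); ++i)
        grid[box.index(chains[c].sites[i])]++;
    for (size_t k = 0; k < grid.size(); ++k)
      if (grid[k] > 1) stop("initial configuration violates self-avoidance");
  }
  bool free_site(const Site& s) const { return grid[box.index(s)] == 0; }
};

static State state_from_r(List chain_sites, LogicalVector chain_closed,
                          List chain_pinned, IntegerVector box_dim,
                          bool self_avoiding) {
  State st;
  st.box = make_box(box_dim);
  st.saw = self_avoiding;
  int nc = chain_sites.size();
  for (int c = 0; c < nc; ++c) {
    IntegerMatrix m = chain_sites[c];
    LogicalVector pv = chain_pinned[c];
    Chain ch;
    ch.closed = chain_closed[c];
    ch.sites.resize(m.nrow());
    ch.pinned.resize(m.nrow());
    for (int i = 0; i < m.nrow(); ++i) {
      ch.sites[i] = {{m(i, 0), m(i, 1), m(i, 2)}};
      ch.pinned[i] = (char)(pv[i] == TRUE);
      if (!st.box.contains(ch.sites[i])) stop("site outside box");
    }
    st.chains.push_back(ch);
  }
  st.build_grid();
  return st;
}

static IntegerMatrix sites_to_r(const Chain& ch) {
  IntegerMatrix m(ch.n(), 3);
  for (int i = 0; i < ch.n(); ++i) {
    m(i, 0) = ch.sites[i][0]; m(i, 1) = ch.sites[i][1]; m(i, 2) = ch.sites[i][2];
  }
  return m;
}

// ---------------------------------------------------------------------------
// moves
//
// outcome codes: 0 accepted, 1 inapplicable, 2 pin, 3 volume, 4 occupancy

static int try_bead_flip(State& st, Chain& ch, int i, bool commit = true) {
  int n = ch.n();
  int ip, in_;
  if (ch.closed) { ip = (i - 1 + n) % n; in_ = (i + 1) % n; }
  else {
    if (i <= 0 || i >= n - 1) return 1;
    ip = i - 1; in_ = i + 1;
  }
  const Site& p = ch.sites[ip];
  const Site& q = ch.sites[in_];
  const Site& cur = ch.sites[i];
  int a1 = axis_of(p, cur), a2 = axis_of(cur, q);
  if (a1 < 0 || a2 < 0 || a1 == a2) return 1;   // straight or reversal bead
  if (ch.pinned[i]) return 2;
  Site t = {{p[0] + q[0] - cur[0], p[1] + q[1] - cur[1], p[2] + q[2] - cur[2]}};
  if (!st.box.contains(t)) return 3;
  if (st.saw && !st.free_site(t)) return 4;
  if (commit) {
    if (st.saw) { st.grid[st.box.index(cur)]--; st.grid[st.box.index(t)]++; }
    ch.sites[i] = t;
  }
  return 0;
}

// Window beads i..i+3 (mod n for closed chains); returns beads indices or
// false if the window does not exist.
static bool window_idx(const Chain& ch, int i, int idx[4]) {
  int n = ch.n();
  if (ch.closed) {
    if (n < 4) return false;
    for (int k = 0; k < 4; ++k) idx[k] = (i + k) % n;
  } else {
    if (i < 0 || i + 3 > n - 1) return false;
    for (int k = 0; k < 4; ++k) idx[k] = i + k;
  }
  return true;
}

// branch < 0: choose uniformly with R's RNG (sampling); branch in 0..2:
// deterministic choice (used to enumerate the proposal set).
static int try_crankshaft(State& st, Chain& ch, int i, int branch,
                          bool commit = true) {
  int idx[4];
  if (!window_idx(ch, i, idx)) return 1;
  const Site& s0 = ch.sites[idx[0]];
  const Site& s1 = ch.sites[idx[1]];
  const Site& s2 = ch.sites[idx[2]];
  const Site& s3 = ch.sites[idx[3]];
  int a[3] = {s1[0] - s0[0], s1[1] - s0[1], s1[2] - s0[2]};
  int b[3] = {s2[0] - s1[0], s2[1] - s1[1], s2[2] - s1[2]};
  int c2[3] = {s3[0] - s2[0], s3[1] - s2[1], s3[2] - s2[2]};
  if (std::abs(a[0]) + std::abs(a[1]) + std::abs(a[2]) != 1) return 1;
  if (std::abs(b[0]) + std::abs(b[1]) + std::abs(b[2]) != 1) return 1;
  if (c2[0] != -a[0] || c2[1] != -a[1] || c2[2] != -a[2]) return 1; // not a,b,-a
  bool aligned = (a[0] == b[0] && a[1] == b[1] && a[2] == b[2]) ||
                 (a[0] == -b[0] && a[1] == -b[1] && a[2] == -b[2]);
  if (aligned) return 1;                                    // a must be perp b
  // rotation targets for the displaced direction: -a, a x b, -(a x b)
  int cr[3] = {a[1] * b[2] - a[2] * b[1],
               a[2] * b[0] - a[0] * b[2],
               a[0] * b[1] - a[1] * b[0]};
  int alts[3][3] = {{-a[0], -a[1], -a[2]},
                    {cr[0], cr[1], cr[2]},
                    {-cr[0], -cr[1], -cr[2]}};
  int k = branch >= 0 ? branch : runif_int(3);
  Site n1 = add(s0, alts[k]);
  Site n2 = add(n1, b);
  if (ch.pinned[idx[1]] || ch.pinned[idx[2]]) return 2;
  if (!st.box.contains(n1) || !st.box.contains(n2)) return 3;
  if (st.saw && (!st.free_site(n1) || !st.free_site(n2))) return 4;
  if (commit) {
    if (st.saw) {
      st.grid[st.box.index(s1)]--; st.grid[st.box.index(s2)]--;
      st.grid[st.box.index(n1)]++; st.grid[st.box.index(n2)]++;
    }
    ch.sites[idx[1]] = n1; ch.sites[idx[2]] = n2;
  }
  return 0;
}

// All 3-step lattice paths from `from` to `to`; interior beads returned.
static int window_paths(const Site& from, const Site& to,
                        Site mids1[36], Site mids2[36]) {
  int cnt = 0;
  int d[3] = {to[0] - from[0], to[1] - from[1], to[2] - from[2]};
  for (int i = 0; i < 6; ++i) {
    for (int j = 0; j < 6; ++j) {
      int r[3] = {d[0] - DIRS[i][0] - DIRS[j][0],
                  d[1] - DIRS[i][1] - DIRS[j][1],
                  d[2] - DIRS[i][2] - DIRS[j][2]};
      if (std::abs(r[0]) + std::abs(r[1]) + std::abs(r[2]) != 1) continue;
      Site m1 = add(from, DIRS[i]);
      Site m2 = add(m1, DIRS[j]);
      mids1[cnt] = m1; mids2[cnt] = m2; ++cnt;
    }
  }
  return cnt;
}

// 3-D crankshaft: atomic rebridge of a 3-bond window.  The proposal picks
// uniformly among all alternative interior placements; the alternative count
// depends only on the conserved endpoint displacement, so the kernel is
// symmetric.
static int try_crankshaft3d(State& st, Chain& ch, int i, int branch,
                            int* nbranch_out, bool commit = true) {
  int idx[4];
  if (!window_idx(ch, i, idx)) return 1;
  const Site& s0 = ch.sites[idx[0]];
  const Site& s1 = ch.sites[idx[1]];
  const Site& s2 = ch.sites[idx[2]];
  const Site& s3 = ch.sites[idx[3]];
  Site m1[36], m2[36];
  int np = window_paths(s0, s3, m1, m2);
  // drop the current interior
  int alt = 0;
  Site a1[36], a2[36];
  for (int k = 0; k < np; ++k) {
    if (m1[k] == s1 && m2[k] == s2) continue;
    a1[alt] = m1[k]; a2[alt] = m2[k]; ++alt;
  }
  if (nbranch_out) *nbranch_out = alt;
  if (alt == 0) return 1;
  int k = branch >= 0 ? branch : runif_int(alt);
  if (k >= alt) return 1;
  if (ch.pinned[idx[1]] || ch.pinned[idx[2]]) return 2;
  if (!st.box.contains(a1[k]) || !st.box.contains(a2[k])) return 3;
  if (st.saw) {
    long i1 = st.box.index(s1), i2 = st.box.index(s2);
    st.grid[i1]--; st.grid[i2]--;
    bool ok = st.free_site(a1[k]);
    if (ok) { st.grid[st.box.index(a1[k])]++; ok = st.free_site(a2[k]); st.grid[st.box.index(a1[k])]--; }
    st.grid[i1]++; st.grid[i2]++;
    if (!ok) return 4;
  }
  if (commit) {
    if (st.saw) {
      st.grid[st.box.index(s1)]--; st.grid[st.box.index(s2)]--;
      st.grid[st.box.index(a1[k])]++; st.grid[st.box.index(a2[k])]++;
    }
    ch.sites[idx[1]] = a1[k]; ch.sites[idx[2]] = a2[k];
  }
  return 0;
}

// [[Rcpp::export]]
List apply_move_cpp(IntegerMatrix sites, bool closed, LogicalVector pinned,
                    IntegerVector box_dim, bool self_avoiding,
                    int i, int kind, int branch) {
  // i: 0-based bead / window-start index; kind: 0 flip, 1 crank, 2 crank3d;
  // branch: -1 random, else deterministic branch id
  List cs = List::create(sites);
  LogicalVector cl = LogicalVector::create(closed);
  List cp = List::create(pinned);
  State st = state_from_r(cs, cl, cp, box_dim, self_avoiding);
  Chain& ch = st.chains[0];
  int code;
  if (kind == 0) code = try_bead_flip(st, ch, i);
  else if (kind == 1) code = try_crankshaft(st, ch, i, branch);
  else code = try_crankshaft3d(st, ch, i, branch, NULL);
  return List::create(_["code"] = code, _["sites"] = sites_to_r(ch));
}

// [[Rcpp::export]]
List move_neighbors_cpp(IntegerMatrix sites, bool closed, LogicalVector pinned,
                        IntegerVector box_dim, bool self_avoiding) {
  // every accepted outcome of every move at every index (for BFS tests)
  List cs = List::create(sites);
  LogicalVector cl = LogicalVector::create(closed);
  List cp = List::create(pinned);
  List out;
  int n = sites.nrow();
  for (int i = 0; i < n; ++i) {
    {
      State st = state_from_r(cs, cl, cp, box_dim, self_avoiding);
      if (try_bead_flip(st, st.chains[0], i) == 0)
        out.push_back(sites_to_r(st.chains[0]));
    }
    for (int b = 0; b < 3; ++b) {
      State st = state_from_r(cs, cl, cp, box_dim, self_avoiding);
      if (try_crankshaft(st, st.chains[0], i, b) == 0)
        out.push_back(sites_to_r(st.chains[0]));
    }
    int nb = 0;
    {
      State st = state_from_r(cs, cl, cp, box_dim, self_avoiding);
      try_crankshaft3d(st, st.chains[0], i, 0, &nb, false);
    }
    for (int b = 0; b < nb; ++b) {
      State st = state_from_r(cs, cl, cp, box_dim, self_avoiding);
      if (try_crankshaft3d(st, st.chains[0], i, b, NULL) == 0)
        out.push_back(sites_to_r(st.chains[0]));
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// full invariant audit (used by the fuzz tests via validate_every)

static void audit_state(const State& st,
                        const std::vector<std::vector<Site> >& pin_sites0) {
  std::vector<long> seen;
  for (size_t c = 0; c < st.chains.size(); ++c) {
    const Chain& ch = st.chains[c];
    int nb = ch.bonds();
    for (int j = 0; j < nb; ++j) {
      const Site& a = ch.sites[j];
      const Site& b = ch.sites[(j + 1) % ch.n()];
      if (axis_of(a, b) < 0) stop("audit: broken bond");
    }
    size_t pk = 0;
    for (int i = 0; i < ch.n(); ++i) {
      if (!st.box.contains(ch.sites[i])) stop("audit: site outside box");
      if (ch.pinned[i]) {
        if (!(ch.sites[i] == pin_sites0[c][pk])) stop("audit: pin moved");
        ++pk;
      }
      if (st.saw) seen.push_back(st.box.index(ch.sites[i]));
    }
  }
  if (st.saw) {
    std::sort(seen.begin(), seen.end());
    for (size_t k = 1; k < seen.size(); ++k)
      if (seen[k] == seen[k - 1]) stop("audit: self-avoidance violated");
  }
}

// ---------------------------------------------------------------------------
// MOS sampler

// [[Rcpp::export]]
List mos_run_cpp(List chain_sites, LogicalVector chain_closed,
                 List chain_pinned, IntegerVector box_dim, bool self_avoiding,
                 int n_samples, double burn_in, double thinning,
                 NumericVector move_weights,
                 bool record_walks, bool record_z, bool profile, bool density,
                 int validate_every) {
  RNGScope scope;
  State st = state_from_r(chain_sites, chain_closed, chain_pinned, box_dim,
                          self_avoiding);
  int nc = (int)st.chains.size();

  std::vector<std::vector<Site> > pin_sites0(nc);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < st.chains[c].n(); ++i)
      if (st.chains[c].pinned[i]) pin_sites0[c].push_back(st.chains[c].sites[i]);

  // chain selection proportional to length
  std::vector<double> cum(nc);
  double tot = 0;
  for (int c = 0; c < nc; ++c) { tot += st.chains[c].bonds(); cum[c] = tot; }

  double w0 = move_weights[0], w1 = move_weights[0] + move_weights[1];

  std::vector<std::vector<double> > sum_z(nc), sumsq_z(nc);
  std::vector<std::vector<double> > dens(nc);
  if (profile)
    for (int c = 0; c < nc; ++c) {
      sum_z[c].assign(st.chains[c].n(), 0.0);
      sumsq_z[c].assign(st.chains[c].n(), 0.0);
    }
  if (density) {
    if (!st.box.bounded) stop("density accumulation requires a bounded box");
    for (int c = 0; c < nc; ++c) dens[c].assign(st.box.volume(), 0.0);
  }
  List samples(record_walks ? n_samples : 0);
  std::vector<IntegerMatrix> zrec(nc);
  if (record_z)
    for (int c = 0; c < nc; ++c)
      zrec[c] = IntegerMatrix(n_samples, st.chains[c].n());

  double attempts[3] = {0, 0, 0}, accepts[3] = {0, 0, 0};
  double rejects[4] = {0, 0, 0, 0};  // inapplicable, pin, volume, occupancy

  double total_moves = burn_in + (double)n_samples * thinning;
  double move = 0;
  int taken = 0;
  double next_sample = burn_in + thinning;

  while (taken < n_samples) {
    ++move;
    // select chain
    int c = 0;
    if (nc > 1) {
      double u = unif_rand() * tot;
      while (c < nc - 1 && u > cum[c]) ++c;
    }
    Chain& ch = st.chains[c];
    int i = runif_int(ch.n());
    double u = unif_rand();
    int kind = u < w0 ? 0 : (u < w1 ? 1 : 2);
    int code;
    if (kind == 0) code = try_bead_flip(st, ch, i);
    else if (kind == 1) code = try_crankshaft(st, ch, i, -1);
    else code = try_crankshaft3d(st, ch, i, -1, NULL);
    attempts[kind] += 1;
    if (code == 0) accepts[kind] += 1; else rejects[code - 1] += 1;

    if (validate_every > 0 && ((long)move % validate_every) == 0)
      audit_state(st, pin_sites0);

    if (move >= next_sample) {
      for (int cc = 0; cc < nc; ++cc) {
        Chain& chc = st.chains[cc];
        if (profile)
          for (int b = 0; b < chc.n(); ++b) {
            double z = chc.sites[b][2];
            sum_z[cc][b] += z; sumsq_z[cc][b] += z * z;
          }
        if (density)
          for (int b = 0; b < chc.n(); ++b)
            dens[cc][st.box.index(chc.sites[b])] += 1.0;
        if (record_z)
          for (int b = 0; b < chc.n(); ++b)
            zrec[cc](taken, b) = chc.sites[b][2];
      }
      if (record_walks) {
        List snap(nc);
        for (int cc = 0; cc < nc; ++cc) snap[cc] = sites_to_r(st.chains[cc]);
        samples[taken] = snap;
      }
      ++taken;
      next_sample += thinning;
      if ((taken & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    if (move > total_moves + 1) break;  // safety; should not trigger
  }

  List prof, densL, zL, finals(nc);
  if (profile) {
    prof = List(nc);
    for (int c = 0; c < nc; ++c)
      prof[c] = List::create(_["sum_z"] = NumericVector(sum_z[c].begin(), sum_z[c].end()),
                             _["sumsq_z"] = NumericVector(sumsq_z[c].begin(), sumsq_z[c].end()));
  }
  if (density) {
    densL = List(nc);
    for (int c = 0; c < nc; ++c)
      densL[c] = NumericVector(dens[c].begin(), dens[c].end());
  }
  if (record_z) {
    zL = List(nc);
    for (int c = 0; c < nc; ++c) zL[c] = zrec[c];
  }
  for (int c = 0; c < nc; ++c) finals[c] = sites_to_r(st.chains[c]);

  return List::create(
    _["samples"] = samples, _["profile"] = prof, _["density"] = densL,
    _["z"] = zL, _["final"] = finals, _["n_samples"] = taken,
    _["attempts"] = NumericVector(attempts, attempts + 3),
    _["accepts"] = NumericVector(accepts, accepts + 3),
    _["rejects"] = NumericVector(rejects, rejects + 4));
}

// ---------------------------------------------------------------------------
// hook growth

// Perpendicular direction r (0..3) for a bond along axis `ax`: the two other
// axes in x<y<z order, each +/-.
static void perp_dir(int ax, int r, int d[3]) {
  int axes[2], k = 0;
  for (int a = 0; a < 3; ++a) if (a != ax) axes[k++] = a;
  int which = r / 2, sign = (r % 2 == 0) ? 1 : -1;
  d[0] = d[1] = d[2] = 0;
  d[axes[which]] = sign;
}

// [[Rcpp::export]]
List hook_step_cpp(IntegerMatrix sites, bool closed, LogicalVector pinned,
                   IntegerVector box_dim, bool self_avoiding,
                   int bond, int dir) {
  // bond: 0-based bond index or -1 for random; dir: 0..3 or -1 for random.
  // Returns code (0 accepted, 3 volume, 4 occupancy), new sites and pins.
  RNGScope scope;
  List cs = List::create(sites);
  LogicalVector cl = LogicalVector::create(closed);
  List cp = List::create(pinned);
  State st = state_from_r(cs, cl, cp, box_dim, self_avoiding);
  Chain& ch = st.chains[0];
  int nb = ch.bonds();
  int j = bond >= 0 ? bond : runif_int(nb);
  if (j >= nb) stop("bond index out of range");
  const Site& a = ch.sites[j];
  const Site& b = ch.sites[(j + 1) % ch.n()];
  int ax = axis_of(a, b);
  int d[3];
  perp_dir(ax, dir >= 0 ? dir : runif_int(4), d);
  Site na = add(a, d), nb2 = add(b, d);
  int code = 0;
  if (!st.box.contains(na) || !st.box.contains(nb2)) code = 3;
  else if (st.saw && (!st.free_site(na) || !st.free_site(nb2))) code = 4;
  if (code == 0) {
    ch.sites.insert(ch.sites.begin() + j + 1, nb2);
    ch.sites.insert(ch.sites.begin() + j + 1, na);
    ch.pinned.insert(ch.pinned.begin() + j + 1, 0);
    ch.pinned.insert(ch.pinned.begin() + j + 1, 0);
  }
  LogicalVector pout(ch.n());
  for (int i = 0; i < ch.n(); ++i) pout[i] = ch.pinned[i] != 0;
  return List::create(_["code"] = code, _["sites"] = sites_to_r(ch),
                      _["pinned"] = pout);
}

// [[Rcpp::export]]
List grow_segments_cpp(IntegerMatrix sites, bool closed, LogicalVector pinned,
                       IntegerVector box_dim, bool self_avoiding,
                       IntegerVector segment_targets, double max_attempts,
                       IntegerMatrix blocked) {
  // Grow by hook insertion until each contour segment (delimited by pinned
  // beads, in contour order) reaches its target bond count.  For a walk with
  // no pins (or a single pin on a closed walk) there is one segment.
  RNGScope scope;
  List cs = List::create(sites);
  LogicalVector cl = LogicalVector::create(closed);
  List cp = List::create(pinned);
  State st = state_from_r(cs, cl, cp, box_dim, self_avoiding);
  Chain& ch = st.chains[0];
  if (st.saw)
    for (int k = 0; k < blocked.nrow(); ++k) {
      Site s = {{blocked(k, 0), blocked(k, 1), blocked(k, 2)}};
      if (!st.box.contains(s)) stop("blocked site outside box");
      if (!st.free_site(s)) stop("blocked site collides with the walk");
      st.grid[st.box.index(s)]++;
    }

  // segment boundaries: pinned bead indices in contour order
  std::vector<int> bnd;
  for (int i = 0; i < ch.n(); ++i) if (ch.pinned[i]) bnd.push_back(i);
  int nseg;
  if (ch.closed) nseg = bnd.size() >= 2 ? (int)bnd.size() : 1;
  else {
    // endpoints are implicit boundaries
    if (bnd.empty() || bnd.front() != 0) bnd.insert(bnd.begin(), 0);
    if (bnd.back() != ch.n() - 1) bnd.push_back(ch.n() - 1);
    nseg = (int)bnd.size() - 1;
  }
  if (segment_targets.size() != nseg)
    stop("need %d segment targets, got %d", nseg, (int)segment_targets.size());

  // current bond count per segment
  std::vector<long> cur(nseg), tgt(nseg);
  for (int s = 0; s < nseg; ++s) tgt[s] = segment_targets[s];
  if (ch.closed && bnd.size() < 2) cur[0] = ch.bonds();
  else if (ch.closed) {
    for (size_t s = 0; s < bnd.size(); ++s) {
      int from = bnd[s], to = bnd[(s + 1) % bnd.size()];
      cur[s] = ((to - from) % ch.n() + ch.n()) % ch.n();
    }
  } else {
    for (int s = 0; s < nseg; ++s) cur[s] = bnd[s + 1] - bnd[s];
  }
  for (int s = 0; s < nseg; ++s) {
    if (cur[s] > tgt[s]) stop("segment %d already longer than its target", s + 1);
    if (((tgt[s] - cur[s]) % 2) != 0)
      stop("target length has wrong parity for segment %d (growth adds 2 bonds)", s + 1);
  }

  // map a segment + offset to a bond index
  double attempts = 0, rejected = 0;
  while (true) {
    long need_total = 0;
    std::vector<int> eligible;
    std::vector<long> ecum;
    long etot = 0;
    for (int s = 0; s < nseg; ++s) {
      if (cur[s] < tgt[s]) { eligible.push_back(s); etot += cur[s]; ecum.push_back(etot); }
      need_total += tgt[s] - cur[s];
    }
    if (need_total == 0) break;
    if (attempts >= max_attempts)
      stop("hook growth jammed: %0.f attempts, %ld bonds still to add",
           attempts, need_total);
    ++attempts;
    // pick an eligible bond uniformly (segment weighted by bond count)
    long u = (long)(unif_rand() * etot); if (u >= etot) u = etot - 1;
    size_t e = 0; while (e < ecum.size() - 1 && u >= ecum[e]) ++e;
    int s = eligible[e];
    long off = u - (e == 0 ? 0 : ecum[e - 1]);
    int start;
    if (ch.closed && nseg == 1 && bnd.size() < 2) start = 0;
    else start = bnd[s];
    int j = (int)((start + off) % (ch.closed ? ch.n() : ch.n() - 1));
    if (!ch.closed) j = (int)(start + off);

    const Site& a = ch.sites[j];
    const Site& b = ch.sites[(j + 1) % ch.n()];
    int ax = axis_of(a, b);
    int d[3];
    perp_dir(ax, runif_int(4), d);
    Site na = add(a, d), nb2 = add(b, d);
    if (!st.box.contains(na) || !st.box.contains(nb2)) { ++rejected; continue; }
    if (st.saw && (!st.free_site(na) || !st.free_site(nb2))) { ++rejected; continue; }
    if (st.saw) { st.grid[st.box.index(na)]++; st.grid[st.box.index(nb2)]++; }
    ch.sites.insert(ch.sites.begin() + j + 1, nb2);
    ch.sites.insert(ch.sites.begin() + j + 1, na);
    ch.pinned.insert(ch.pinned.begin() + j + 1, 0);
    ch.pinned.insert(ch.pinned.begin() + j + 1, 0);
    cur[s] += 2;
    // shift boundaries after insertion point
    for (size_t k2 = 0; k2 < bnd.size(); ++k2) if (bnd[k2] > j) bnd[k2] += 2;
    if (((long)attempts & 8191) == 0) Rcpp::checkUserInterrupt();
  }

  LogicalVector pout(ch.n());
  for (int i = 0; i < ch.n(); ++i) pout[i] = ch.pinned[i] != 0;
  return List::create(_["sites"] = sites_to_r(ch), _["pinned"] = pout,
                      _["attempts"] = attempts, _["rejected"] = rejected);
}

// ---------------------------------------------------------------------------
// exhaustive enumeration (depth-first with Manhattan/parity pruning)

struct EnumCtx {
  Box box;
  bool saw, closed, return_walks;
  int n_bonds;
  double cap;
  std::vector<int> pin_at;      // bead index -> pin id or -1
  std::vector<Site> pin_site;   // by pin id; for closed, virtual pin at n_bonds = start
  Site start;
  bool have_end_pin;            // open walks: pin at last bead?
  // occupancy for SAW (bounded box or shifted virtual grid)
  std::vector<char> occ;
  Box occ_box;
  int shift[3];
  // results
  double count = 0;
  std::vector<double> sum_z, sumsq_z;
  std::vector<double> dens;
  std::vector<IntegerMatrix> walks;
  std::vector<Site> path;

  long occ_index(const Site& s) {
    Site t = {{s[0] + shift[0], s[1] + shift[1], s[2] + shift[2]}};
    return occ_box.index(t);
  }
};

static int manhattan(const Site& a, const Site& b) {
  return std::abs(a[0] - b[0]) + std::abs(a[1] - b[1]) + std::abs(a[2] - b[2]);
}

static void enum_dfs(EnumCtx& C, int t) {
  // path[0..t] laid down; t beads placed after start (path index t)
  if (t == C.n_bonds) {
    C.count += 1;
    if (C.count > C.cap)
      stop("enumeration exceeds cap (%.0f walks); raise the cap or shrink the instance", C.cap);
    int nb = C.closed ? C.n_bonds : C.n_bonds + 1;
    for (int i = 0; i < nb; ++i) {
      double z = C.path[i][2];
      C.sum_z[i] += z; C.sumsq_z[i] += z * z;
      if (!C.dens.empty()) C.dens[C.box.index(C.path[i])] += 1.0;
    }
    if (C.return_walks) {
      IntegerMatrix m(nb, 3);
      for (int i = 0; i < nb; ++i)
        for (int k = 0; k < 3; ++k) m(i, k) = C.path[i][k];
      C.walks.push_back(m);
    }
    return;
  }
  const Site& cur = C.path[t];
  // next pinned bead at or beyond t+1
  int np = -1;
  for (int b = t + 1; b <= C.n_bonds; ++b)
    if (C.pin_at[b] >= 0) { np = b; break; }
  for (int d = 0; d < 6; ++d) {
    Site nxt = add(cur, DIRS[d]);
    if (!C.box.contains(nxt)) continue;
    if (C.pin_at[t + 1] >= 0 && !(nxt == C.pin_site[C.pin_at[t + 1]])) continue;
    if (np >= 0) {
      int dist = manhattan(nxt, C.pin_site[C.pin_at[np]]);
      int rem = np - (t + 1);
      if (dist > rem || ((rem - dist) % 2) != 0) continue;
    }
    bool last = (t + 1 == C.n_bonds);
    bool skip_occ = C.closed && last;  // closure bead is the start bead
    if (C.saw && !skip_occ) {
      long oi = C.occ_index(nxt);
      if (C.occ[oi]) continue;
      C.occ[oi] = 1;
      C.path[t + 1] = nxt;
      enum_dfs(C, t + 1);
      C.occ[oi] = 0;
    } else {
      if (C.closed && last && !(nxt == C.start)) continue;
      C.path[t + 1] = nxt;
      enum_dfs(C, t + 1);
    }
  }
}

// [[Rcpp::export]]
List enumerate_cpp(IntegerVector box_dim, IntegerMatrix pin_sites,
                   IntegerVector pin_index, int n_bonds, bool closed,
                   bool self_avoiding, double cap, bool return_walks,
                   bool with_density) {
  // pin_index: 0-based bead indices, ascending, first must be 0 (bead 0 fixed:
  // the R wrapper supplies a start site as pin 0).
  EnumCtx C;
  C.box = make_box(box_dim);
  C.saw = self_avoiding;
  C.closed = closed;
  C.return_walks = return_walks;
  C.n_bonds = n_bonds;
  C.cap = cap;
  if (pin_index.size() == 0 || pin_index[0] != 0)
    stop("enumeration requires bead 1 to be pinned (a start site)");
  int n_beads = closed ? n_bonds : n_bonds + 1;
  C.pin_at.assign(n_bonds + 1, -1);
  for (int k = 0; k < pin_index.size(); ++k) {
    if (pin_index[k] < 0 || pin_index[k] >= n_beads) stop("pin index out of range");
    C.pin_at[pin_index[k]] = k;
    Site s = {{pin_sites(k, 0), pin_sites(k, 1), pin_sites(k, 2)}};
    C.pin_site.push_back(s);
    if (!C.box.contains(s)) stop("pin outside box");
  }
  C.start = C.pin_site[0];
  if (closed) {
    // closure: virtual pin at bead n_bonds = start
    if (C.pin_at[n_bonds] < 0) {
      C.pin_at[n_bonds] = (int)C.pin_site.size();
      C.pin_site.push_back(C.start);
    }
  }
  C.sum_z.assign(n_bonds + 1, 0.0);
  C.sumsq_z.assign(n_bonds + 1, 0.0);
  if (C.box.bounded && with_density) C.dens.assign(C.box.volume(), 0.0);
  if (C.saw) {
    if (C.box.bounded) {
      C.occ_box = C.box;
      C.shift[0] = C.shift[1] = C.shift[2] = 0;
    } else {
      int ext = 2 * n_bonds + 1;
      C.occ_box.nx = C.occ_box.ny = C.occ_box.nz = ext;
      C.occ_box.bounded = true;
      for (int k = 0; k < 3; ++k) C.shift[k] = n_bonds - C.start[k];
    }
    C.occ.assign(C.occ_box.volume(), 0);
    C.occ[C.occ_index(C.start)] = 1;
  }
  C.path.assign(n_bonds + 1, C.start);
  enum_dfs(C, 0);

  int nb = closed ? n_bonds : n_bonds + 1;
  NumericVector sz(C.sum_z.begin(), C.sum_z.begin() + nb);
  NumericVector sz2(C.sumsq_z.begin(), C.sumsq_z.begin() + nb);
  List walksL(C.walks.size());
  for (size_t k = 0; k < C.walks.size(); ++k) walksL[k] = C.walks[k];
  return List::create(_["count"] = C.count, _["sum_z"] = sz, _["sumsq_z"] = sz2,
                      _["density"] = C.dens.empty() ? R_NilValue
                        : (SEXP)NumericVector(C.dens.begin(), C.dens.end()),
                      _["walks"] = walksL);
}
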