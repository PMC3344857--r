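#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bond-fluctuation model (BFM) kernels.
//
// Conventions: a monomer occupies the 2x2x2 cube of lattice sites whose
// lower corner is its integer position p, 0 <= p[a] <= L-2.  Bonds between
// consecutive monomers are restricted to the canonical 108-vector set
// (permutations and sign flips of (2,0,0),(2,1,0),(2,1,1),(2,2,1),(3,0,0),
// (3,1,0)), which together with the cube exclusion guarantees both excluded
// volume and chain uncrossability.  All randomness is drawn from R's RNG so
// a single set.seed() governs a run.

namespace {

// xoshiro256++ PRNG, seeded from R's RNG so set.seed() governs a run while
// the hot loop avoids per-call R API overhead.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double runif() { return (next() >> 11) * 0x1.0p-53; }
  int below(int n) { return (int)(runif() * n); }
};

uint64_t seed_from_R() {
  uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  return (hi << 32) ^ lo;
}

struct BondTable {
  // allowed[dx+3][dy+3][dz+3], components in [-3,3]
  bool allowed[7][7][7];
  BondTable() {
    for (int i = 0; i < 7; ++i)
      for (int j = 0; j < 7; ++j)
        for (int k = 0; k < 7; ++k) allowed[i][j][k] = false;
    const int base[6][3] = {{2,0,0},{2,1,0},{2,1,1},{2,2,1},{3,0,0},{3,1,0}};
    for (int b = 0; b < 6; ++b) {
      int v[3] = {base[b][0], base[b][1], base[b][2]};
      // all permutations
      int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
      for (int p = 0; p < 6; ++p) {
        int w[3] = {v[perms[p][0]], v[perms[p][1]], v[perms[p][2]]};
        for (int sx = -1; sx <= 1; sx += 2)
          for (int sy = -1; sy <= 1; sy += 2)
            for (int sz = -1; sz <= 1; sz += 2)
              allowed[sx*w[0]+3][sy*w[1]+3][sz*w[2]+3] = true;
      }
    }
  }
  inline bool ok(int dx, int dy, int dz) const {
    if (dx < -3 || dx > 3 || dy < -3 || dy > 3 || dz < -3 || dz > 3)
      return false;
    return allowed[dx+3][dy+3][dz+3];
  }
};

const BondTable BONDS;

// valid BFM bonds have squared length in {4,5,6,9,10}; inverse square
// roots are precomputed to keep the energy evaluation in the hot path cheap
struct InvSqrtTable {
  double v[11];
  InvSqrtTable() { for (int k = 1; k <= 10; ++k) v[k] = 1.0 / std::sqrt((double)k); v[0] = 0.0; }
};
const InvSqrtTable ISQ;

inline double dot_tangent(const int* b1, const int* b2) {
  int n1 = b1[0]*b1[0] + b1[1]*b1[1] + b1[2]*b1[2];
  int n2 = b2[0]*b2[0] + b2[1]*b2[1] + b2[2]*b2[2];
  double inv = (n1 <= 10 && n2 <= 10) ? ISQ.v[n1] * ISQ.v[n2]
    : 1.0 / std::sqrt((double)n1 * n2);
  return (b1[0]*b2[0] + b1[1]*b2[1] + b1[2]*b2[2]) * inv;
}

class System {
public:
  int L, nc, nm;
  double kappa;
  bool tethered;
  std::vector<int> pos;            // nc*nm*3, cube corners
  std::vector<uint8_t> occ;        // L^3 site occupancy
  double energy;

  inline int* P(int c, int m) { return &pos[3 * (c * nm + m)]; }
  inline const int* P(int c, int m) const { return &pos[3 * (c * nm + m)]; }
  inline size_t site(int x, int y, int z) const {
    return ((size_t)x * L + y) * L + z;
  }

  void build_occupancy() {
    occ.assign((size_t)L * L * L, 0);
    for (int c = 0; c < nc; ++c)
      for (int m = 0; m < nm; ++m) {
        const int* p = P(c, m);
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy)
            for (int dz = 0; dz < 2; ++dz)
              occ[site(p[0]+dx, p[1]+dy, p[2]+dz)] += 1;
      }
  }

  double chain_energy(int c) const {
    double e = 0.0;
    for (int i = 0; i + 2 < nm; ++i) {
      int b1[3], b2[3];
      for (int a = 0; a < 3; ++a) {
        b1[a] = P(c, i+1)[a] - P(c, i)[a];
        b2[a] = P(c, i+2)[a] - P(c, i+1)[a];
      }
      e += 1.0 - dot_tangent(b1, b2);
    }
    return kappa * e;
  }

  double total_energy() const {
    double e = 0.0;
    for (int c = 0; c < nc; ++c) e += chain_energy(c);
    return e;
  }

  inline bool on_boundary(const int* p) const {
    for (int a = 0; a < 3; ++a)
      if (p[a] == 0 || p[a] == L - 2) return true;
    return false;
  }

  // local bending-energy contribution of angle terms touching bonds m-1, m
  double local_energy(int c, int m, const int* pm) const {
    double e = 0.0;
    // angle terms (i, i+1) for i in {m-2, m-1, m} intersect bonds {m-1, m}
    for (int i = m - 2; i <= m; ++i) {
      if (i < 0 || i + 2 >= nm + 1) continue;      // need bonds i and i+1
      if (i + 1 >= nm - 1 + 1) continue;            // bond index <= nm-2
      if (i > nm - 3) continue;
      int b1[3], b2[3];
      for (int a = 0; a < 3; ++a) {
        const int* q0 = (i == m)     ? pm : P(c, i);
        const int* q1 = (i + 1 == m) ? pm : P(c, i + 1);
        const int* q2 = (i + 2 == m) ? pm : P(c, i + 2);
        b1[a] = q1[a] - q0[a];
        b2[a] = q2[a] - q1[a];
      }
      e += 1.0 - dot_tangent(b1, b2);
    }
    return kappa * e;
  }

  // attempt a single elementary move; returns:
  // 0 = constraint-rejected, 1 = metropolis-rejected, 2 = accepted
  int attempt(int c, int m, int dir, Xoshiro& rng) {
    static const int DIRS[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},
                                   {0,0,1},{0,0,-1}};
    const int* d = DIRS[dir];
    int* p = P(c, m);
    int np[3] = {p[0]+d[0], p[1]+d[1], p[2]+d[2]};

    // confinement
    for (int a = 0; a < 3; ++a)
      if (np[a] < 0 || np[a] > L - 2) return 0;
    // tether: end monomers must keep touching the envelope
    if (tethered && (m == 0 || m == nm - 1) && !on_boundary(np)) return 0;
    // bond validity with neighbors
    if (m > 0) {
      const int* q = P(c, m - 1);
      if (!BONDS.ok(np[0]-q[0], np[1]-q[1], np[2]-q[2])) return 0;
    }
    if (m < nm - 1) {
      const int* q = P(c, m + 1);
      if (!BONDS.ok(q[0]-np[0], q[1]-np[1], q[2]-np[2])) return 0;
    }
    // excluded volume: the 4 newly covered sites must be free
    int a0 = (d[0] != 0) ? 0 : ((d[1] != 0) ? 1 : 2);
    int lead = (d[a0] > 0) ? np[a0] + 1 : np[a0];
    for (int u = 0; u < 2; ++u)
      for (int v = 0; v < 2; ++v) {
        int s[3];
        s[a0] = lead;
        s[(a0+1)%3] = np[(a0+1)%3] + u;
        s[(a0+2)%3] = np[(a0+2)%3] + v;
        if (occ[site(s[0], s[1], s[2])]) return 0;
      }

    // bending-energy Metropolis step
    double dE = 0.0;
    if (kappa > 0.0 && nm >= 3)
      dE = local_energy(c, m, np) - local_energy(c, m, p);
    if (dE > 0.0 && rng.runif() >= std::exp(-dE)) return 1;

    // apply: update occupancy (clear trailing face, set leading face)
    int trail = (d[a0] > 0) ? p[a0] : p[a0] + 1;
    for (int u = 0; u < 2; ++u)
      for (int v = 0; v < 2; ++v) {
        int s[3];
        s[a0] = trail;
        s[(a0+1)%3] = p[(a0+1)%3] + u;
        s[(a0+2)%3] = p[(a0+2)%3] + v;
        occ[site(s[0], s[1], s[2])] -= 1;
        s[a0] = lead;
        s[(a0+1)%3] = np[(a0+1)%3] + u;
        s[(a0+2)%3] = np[(a0+2)%3] + v;
        occ[site(s[0], s[1], s[2])] += 1;
      }
    p[0] = np[0]; p[1] = np[1]; p[2] = np[2];
    energy += dE;
    return 2;
  }
};

System make_system(List positions, int L, double kappa, bool tethered) {
  System sys;
  sys.L = L;
  sys.kappa = kappa;
  sys.tethered = tethered;
  sys.nc = positions.size();
  IntegerMatrix first = positions[0];
  sys.nm = first.nrow();
  sys.pos.resize((size_t)sys.nc * sys.nm * 3);
  for (int c = 0; c < sys.nc; ++c) {
    IntegerMatrix pm = positions[c];
    if (pm.nrow() != sys.nm)
      stop("all chains must have the same number of monomers");
    for (int m = 0; m < sys.nm; ++m)
      for (int a = 0; a < 3; ++a)
        sys.pos[3 * (c * sys.nm + m) + a] = pm(m, a);
  }
  sys.build_occupancy();
  sys.energy = sys.total_energy();
  return sys;
}

List positions_out(const System& sys) {
  List out(sys.nc);
  for (int c = 0; c < sys.nc; ++c) {
    IntegerMatrix pm(sys.nm, 3);
    for (int m = 0; m < sys.nm; ++m)
      for (int a = 0; a < 3; ++a) pm(m, a) = sys.P(c, m)[a];
    out[c] = pm;
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
LogicalVector bfm_bond_ok_cpp(IntegerMatrix d) {
  int n = d.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = BONDS.ok(d(i,0), d(i,1), d(i,2));
  return out;
}

// [[Rcpp::export]]
double bfm_energy_cpp(List positions, double kappa) {
  if (kappa == 0.0) return 0.0;
  double e = 0.0;
  for (int c = 0; c < positions.size(); ++c) {
    IntegerMatrix pm = positions[c];
    int nm = pm.nrow();
    for (int i = 0; i + 2 < nm; ++i) {
      int b1[3], b2[3];
      for (int a = 0; a < 3; ++a) {
        b1[a] = pm(i+1, a) - pm(i, a);
        b2[a] = pm(i+2, a) - pm(i+1, a);
      }
      e += 1.0 - dot_tangent(b1, b2);
    }
  }
  return kappa * e;
}

// Run n_sweeps sweeps (one sweep = nc*nm elementary proposals).  Records the
// per-chain squared end-to-end distance every record_r2ee_every sweeps and,
// when record_conf_every > 0, a full conformation snapshot every that many
// sweeps.  Returns counters needed for the athermal acceptance identity.
// [[Rcpp::export]]
List bfm_run_cpp(List positions, int L, double kappa, bool tethered,
                 int n_sweeps, int record_conf_every,
                 int record_r2ee_every) {
  System sys = make_system(positions, L, kappa, tethered);
  Xoshiro rng(seed_from_R());
  int nc = sys.nc, nm = sys.nm;
  long total = 0, satisfying = 0, accepted = 0;

  if (record_r2ee_every < 1) record_r2ee_every = 1;
  int n_rec = n_sweeps / record_r2ee_every;
  NumericMatrix r2ee(std::max(n_rec, 0), nc);
  IntegerVector r2ee_sweeps(std::max(n_rec, 0));
  int rec = 0;
  std::vector<List> confs;
  std::vector<int> conf_sweeps;

  for (int s = 0; s < n_sweeps; ++s) {
    int proposals = nc * nm;
    for (int k = 0; k < proposals; ++k) {
      int idx = rng.below(nc * nm);
      if (idx >= nc * nm) idx = nc * nm - 1;
      int dir = rng.below(6);
      if (dir >= 6) dir = 5;
      int res = sys.attempt(idx / nm, idx % nm, dir, rng);
      ++total;
      if (res >= 1) ++satisfying;   // passed all hard constraints
      if (res == 2) ++accepted;
    }
    if ((s + 1) % record_r2ee_every == 0 && rec < n_rec) {
      for (int c = 0; c < nc; ++c) {
        const int* p0 = sys.P(c, 0);
        const int* p1 = sys.P(c, nm - 1);
        double dx = p1[0]-p0[0], dy = p1[1]-p0[1], dz = p1[2]-p0[2];
        r2ee(rec, c) = dx*dx + dy*dy + dz*dz;
      }
      r2ee_sweeps[rec++] = s + 1;
    }
    if (record_conf_every > 0 && (s + 1) % record_conf_every == 0) {
      confs.push_back(positions_out(sys));
      conf_sweeps.push_back(s + 1);
    }
  }

  List conf_list(confs.size());
  for (size_t i = 0; i < confs.size(); ++i) conf_list[i] = confs[i];

  return List::create(
    _["positions"] = positions_out(sys),
    _["energy"] = sys.energy,
    _["energy_full"] = sys.total_energy(),
    _["r2ee"] = r2ee,
    _["r2ee_sweeps"] = r2ee_sweeps,
    _["conformations"] = conf_list,
    _["conformation_sweeps"] = wrap(conf_sweeps),
    _["n_proposed"] = (double)total,
    _["n_satisfying"] = (double)satisfying,
    _["n_accepted"] = (double)accepted);
}

// Single elementary proposal at a caller-chosen (chain, monomer, direction);
// exposes the Metropolis step at move granularity for tests.
// [[Rcpp::export]]
List bfm_step_cpp(List positions, int L, double kappa, bool tethered,
                  int chain, int monomer, int dir) {
  System sys = make_system(positions, L, kappa, tethered);
  Xoshiro rng(seed_from_R());
  int res = sys.attempt(chain, monomer, dir, rng);
  return List::create(
    _["positions"] = positions_out(sys),
    _["result"] = res,                 // 0 constraint, 1 metropolis, 2 accept
    _["energy"] = sys.energy);
}

// Full invariant validation: bond set, excluded volume, confinement, tether.
// Returns a character vector of violations (empty = valid).
// [[Rcpp::export]]
CharacterVector bfm_validate_cpp(List positions, int L, bool tethered) {
  std::vector<std::string> bad;
  int nc = positions.size();
  std::vector<uint8_t> occ((size_t)L * L * L, 0);
  for (int c = 0; c < nc; ++c) {
    IntegerMatrix pm = positions[c];
    int nm = pm.nrow();
    for (int m = 0; m < nm; ++m) {
      for (int a = 0; a < 3; ++a)
        if (pm(m, a) < 0 || pm(m, a) > L - 2) {
          bad.push_back("confinement violated");
          goto done;
        }
      for (int dx = 0; dx < 2; ++dx)
        for (int dy = 0; dy < 2; ++dy)
          for (int dz = 0; dz < 2; ++dz) {
            size_t s = ((size_t)(pm(m,0)+dx) * L + (pm(m,1)+dy)) * L
                       + (pm(m,2)+dz);
            if (occ[s]) { bad.push_back("excluded volume violated"); goto done; }
            occ[s] = 1;
          }
      if (m > 0 && !BONDS.ok(pm(m,0)-pm(m-1,0), pm(m,1)-pm(m-1,1),
                             pm(m,2)-pm(m-1,2))) {
        bad.push_back("bond outside allowed set");
        goto done;
      }
    }
    if (tethered) {
      for (int end = 0; end < 2; ++end) {
        int m = end == 0 ? 0 : nm - 1;
        bool on = false;
        for (int a = 0; a < 3; ++a)
          if (pm(m, a) == 0 || pm(m, a) == L - 2) on = true;
        if (!on) { bad.push_back("tether violated"); goto done; }
      }
    }
  }
done:
  return wrap(bad);
}
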