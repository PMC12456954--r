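// Simulation core: overdamped Langevin propagation of domain-sphere
// particles with harmonic/Gaussian bonds, soft excluded volume, implicit
// membrane and confinement potentials, stochastic valency-exclusive
// binding reactions, and virial pressure accumulation.
//
// Units: nm, ns, kJ/mol, K.  Periodic (minimum-image) boundaries in all
// three axes for every mode.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-free xoshiro256++ stream (single stream per run, explicit state)

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss();  // ziggurat, defined below
};

// Marsaglia-Tsang ziggurat tables for the standard normal (128 layers).
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    double m1 = 2147483648.0, dn = 3.442619855899, tn = dn,
           vn = 9.91256303526217e-3, q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1); kn[1] = 0;
    wn[0] = q / m1; wn[127] = dn / m1;
    fn[0] = 1.0; fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1); tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn); wn[i] = dn / m1;
    }
  }
};
static const ZigTables zig;

inline double Xoshiro::gauss() {
  const double r = 3.442619855899;
  for (;;) {
    int32_t hz = (int32_t)(uint32_t)next();
    uint32_t iz = (uint32_t)hz & 127u;
    uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (ahz < zig.kn[iz]) return hz * zig.wn[iz];
    // edge/tail handling
    double x = hz * zig.wn[iz];
    if (iz == 0) {
      double y;
      do {
        x = -std::log(unif()) / r;
        y = -std::log(unif());
      } while (y + y < x * x);
      return hz > 0 ? r + x : -(r + x);
    }
    if (zig.fn[iz] + unif() * (zig.fn[iz - 1] - zig.fn[iz]) <
        std::exp(-0.5 * x * x)) {
      return x;
    }
  }
}

// pack/unpack rng state as 8 int32 (hi/lo per 64-bit word) + cache flag/value
static IntegerVector rng_pack(const Xoshiro &r) {
  IntegerVector out(8);
  for (int i = 0; i < 4; ++i) {
    out[2 * i]     = (int32_t)(uint32_t)(r.s[i] >> 32);
    out[2 * i + 1] = (int32_t)(uint32_t)(r.s[i] & 0xFFFFFFFFULL);
  }
  return out;
}
static void rng_unpack(Xoshiro &r, const IntegerVector &v) {
  for (int i = 0; i < 4; ++i) {
    r.s[i] = ((uint64_t)(uint32_t)v[2 * i] << 32) |
             (uint64_t)(uint32_t)v[2 * i + 1];
  }
}

// ---------------------------------------------------------------------------

struct Sys {
  int N;
  std::vector<double> x, y, z;          // positions
  double box[3];
  std::vector<double> radius, diff;     // per particle
  std::vector<int> comp;                // 0 cytoplasm, 1 membrane
  std::vector<int> mol;
  // structural bonds
  std::vector<int> bi, bj;
  std::vector<double> brest, bk;
  // sites
  std::vector<int> site_particle, site_type;
  std::vector<int> site_active;         // 0/1
  std::vector<std::vector<int>> sites_of;  // per particle site indices
  // rules
  int n_types = 0;
  std::vector<int> rule_ta, rule_tb;
  std::vector<double> rule_rr, rule_pon, rule_poff, rule_rest, rule_k;
  std::vector<std::vector<int>> rmap;   // [ta][tb] -> rule id or -1
  // live specific bonds
  std::vector<int> bsa, bsb, brule, bformed;
  std::vector<int> occ;                 // per site: live-bond slot or -1
  // potentials
  bool membrane_on = false;
  double k_mem = 10.0, d_mem2 = 2.5;
  bool conf_on = false;
  double conf_lo = 0, conf_hi = 0, conf_k = 0;
  int conf_release = -1;
  double k_rep = 10.0, kT = 1.0, dt = 0.25;
  // bonded-pair exclusion lookup (structural bonds only)
  std::unordered_set<int64_t> excl;
  double max_cut = 0.0;

  // Positions are kept wrapped to [0, box); pair separations then lie in
  // (-box, box) and one conditional shift gives the minimum image.
  double minimg(double d, int a) const {
    if (d > 0.5 * box[a]) return d - box[a];
    if (d < -0.5 * box[a]) return d + box[a];
    return d;
  }
  static double fullwrap(double v, double L) {
    v -= L * std::floor(v / L);
    if (v < 0) v += L;
    if (v >= L) v -= L;
    return v;
  }
  void wrap_all() {
    for (int i = 0; i < N; ++i) {
      x[i] = fullwrap(x[i], box[0]);
      y[i] = fullwrap(y[i], box[1]);
      z[i] = fullwrap(z[i], box[2]);
    }
  }
};

static Sys make_sys(NumericMatrix pos, NumericVector box,
                    NumericVector radius, NumericVector diff,
                    IntegerVector comp, IntegerVector mol,
                    IntegerMatrix sbond, NumericVector sbond_rest,
                    NumericVector sbond_k,
                    IntegerVector site_particle, IntegerVector site_type,
                    IntegerVector site_active,
                    List rules, IntegerMatrix bonds0,
                    bool membrane_on, double k_mem, double d_mem2,
                    bool conf_on, double conf_lo, double conf_hi,
                    double conf_k, int conf_release,
                    double k_rep, double kT, double dt) {
  Sys s;
  s.N = pos.nrow();
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  for (int a = 0; a < 3; ++a) s.box[a] = box[a];
  s.radius.assign(radius.begin(), radius.end());
  s.diff.assign(diff.begin(), diff.end());
  s.comp.assign(comp.begin(), comp.end());
  s.mol.assign(mol.begin(), mol.end());
  int nb = sbond.nrow();
  for (int b = 0; b < nb; ++b) {
    s.bi.push_back(sbond(b, 0)); s.bj.push_back(sbond(b, 1));
    s.brest.push_back(sbond_rest[b]); s.bk.push_back(sbond_k[b]);
    int i = sbond(b, 0), j = sbond(b, 1);
    s.excl.insert((int64_t)std::min(i, j) * s.N + std::max(i, j));
  }
  int ns = site_particle.size();
  s.site_particle.assign(site_particle.begin(), site_particle.end());
  s.site_type.assign(site_type.begin(), site_type.end());
  s.site_active.assign(site_active.begin(), site_active.end());
  s.sites_of.resize(s.N);
  for (int k = 0; k < ns; ++k) s.sites_of[s.site_particle[k]].push_back(k);
  // rules
  IntegerVector ta = rules["ta"], tb = rules["tb"];
  NumericVector rr = rules["r_react"], lon = rules["lambda_on"],
                loff = rules["lambda_off"], rrest = rules["bond_rest"],
                rk = rules["bond_k"];
  int nr = ta.size();
  int tmax = 0;
  for (int k = 0; k < ns; ++k) tmax = std::max(tmax, s.site_type[k]);
  for (int r = 0; r < nr; ++r) tmax = std::max(tmax, std::max(ta[r], tb[r]));
  s.n_types = tmax + 1;
  s.rmap.assign(s.n_types, std::vector<int>(s.n_types, -1));
  for (int r = 0; r < nr; ++r) {
    s.rule_ta.push_back(ta[r]); s.rule_tb.push_back(tb[r]);
    s.rule_rr.push_back(rr[r]);
    s.rule_pon.push_back(1.0 - std::exp(-lon[r] * dt));
    s.rule_poff.push_back(1.0 - std::exp(-loff[r] * dt));
    s.rule_rest.push_back(rrest[r]); s.rule_k.push_back(rk[r]);
    s.rmap[ta[r]][tb[r]] = r;
    s.rmap[tb[r]][ta[r]] = r;
  }
  // live bonds
  s.occ.assign(ns, -1);
  for (int b = 0; b < bonds0.nrow(); ++b) {
    int sa = bonds0(b, 0), sb = bonds0(b, 1);
    s.bsa.push_back(sa); s.bsb.push_back(sb);
    s.brule.push_back(bonds0(b, 2)); s.bformed.push_back(bonds0(b, 3));
    s.occ[sa] = (int)s.bsa.size() - 1;
    s.occ[sb] = (int)s.bsa.size() - 1;
  }
  s.membrane_on = membrane_on; s.k_mem = k_mem; s.d_mem2 = d_mem2;
  s.conf_on = conf_on; s.conf_lo = conf_lo; s.conf_hi = conf_hi;
  s.conf_k = conf_k; s.conf_release = conf_release;
  s.k_rep = k_rep; s.kT = kT; s.dt = dt;
  double rmax = 0.0;
  for (int i = 0; i < s.N; ++i) rmax = std::max(rmax, s.radius[i]);
  double cut = 2.0 * rmax;
  for (size_t r = 0; r < s.rule_rr.size(); ++r)
    cut = std::max(cut, s.rule_rr[r]);
  s.max_cut = cut;
  s.wrap_all();
  return s;
}

// Linked-cell list over the periodic box; arrays persist across steps.
// Each cell stores a precomputed half-space stencil (self + 13 forward
// neighbors) so the pair sweep visits every cell pair exactly once.
struct CellList {
  int nc[3] = {0, 0, 0};
  double inv[3];
  std::vector<int> head, nxt;
  std::vector<int> nbr;   // 14 neighbor cell ids per cell
  bool brute = false;

  void build(const Sys &s) {
    int want[3];
    for (int a = 0; a < 3; ++a) {
      want[a] = (int)std::floor(s.box[a] / std::max(s.max_cut, 1e-9));
      // keep the cell count near the particle count
      int cap = std::max(3, (int)std::floor(std::cbrt((double)s.N)) + 1);
      if (want[a] > cap) want[a] = cap;
      if (want[a] < 1) want[a] = 1;
    }
    if (want[0] < 3 || want[1] < 3 || want[2] < 3 || s.N < 32) {
      brute = true;
      return;
    }
    brute = false;
    bool changed = want[0] != nc[0] || want[1] != nc[1] || want[2] != nc[2];
    for (int a = 0; a < 3; ++a) {
      nc[a] = want[a];
      inv[a] = nc[a] / s.box[a];
    }
    size_t ncell = (size_t)nc[0] * nc[1] * nc[2];
    if (changed) {
      // half-space stencil: offsets with (ox,oy,oz) lexicographically > 0,
      // plus the cell itself
      nbr.assign(ncell * 14, 0);
      int k = 0;
      int offs[13][3];
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            if (ox > 0 || (ox == 0 && (oy > 0 || (oy == 0 && oz > 0)))) {
              offs[k][0] = ox; offs[k][1] = oy; offs[k][2] = oz; ++k;
            }
          }
      for (int cx = 0; cx < nc[0]; ++cx)
        for (int cy = 0; cy < nc[1]; ++cy)
          for (int cz = 0; cz < nc[2]; ++cz) {
            size_t c = (size_t)(cx * nc[1] + cy) * nc[2] + cz;
            nbr[c * 14] = (int)c;
            for (int q = 0; q < 13; ++q) {
              int nx = (cx + offs[q][0] + nc[0]) % nc[0];
              int ny = (cy + offs[q][1] + nc[1]) % nc[1];
              int nz = (cz + offs[q][2] + nc[2]) % nc[2];
              nbr[c * 14 + 1 + q] = (nx * nc[1] + ny) * nc[2] + nz;
            }
          }
    }
    head.assign(ncell, -1);
    nxt.resize(s.N);
    for (int i = 0; i < s.N; ++i) {
      // positions are maintained in [0, box)
      int cx = (int)(s.x[i] * inv[0]); if (cx >= nc[0]) cx = nc[0] - 1;
      int cy = (int)(s.y[i] * inv[1]); if (cy >= nc[1]) cy = nc[1] - 1;
      int cz = (int)(s.z[i] * inv[2]); if (cz >= nc[2]) cz = nc[2] - 1;
      size_t c = (size_t)(cx * nc[1] + cy) * nc[2] + cz;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  template <class F>
  void for_pairs(const Sys &s, F fn) const {
    if (brute) {
      for (int i = 0; i < s.N; ++i)
        for (int j = i + 1; j < s.N; ++j) fn(i, j);
      return;
    }
    size_t ncell = (size_t)nc[0] * nc[1] * nc[2];
    for (size_t c = 0; c < ncell; ++c) {
      int h = head[c];
      if (h < 0) continue;
      for (int i = h; i >= 0; i = nxt[i])
        for (int j = nxt[i]; j >= 0; j = nxt[j]) fn(i, j);
      for (int q = 1; q < 14; ++q) {
        int o = head[nbr[c * 14 + q]];
        if (o < 0) continue;
        for (int i = h; i >= 0; i = nxt[i])
          for (int j = o; j >= 0; j = nxt[j]) fn(i, j);
      }
    }
  }
};

struct Candidate { int sa, sb, rule; };

struct ForceResult {
  double e_bond = 0, e_spe = 0, e_nonspe = 0, e_sys = 0;
  double vir[6] = {0, 0, 0, 0, 0, 0};  // xx yy zz xy xz yz
};

// Pair force pass; optionally collects reaction candidates and virial.
static ForceResult compute_forces(const Sys &s, const CellList &cl,
                                  std::vector<double> &fx,
                                  std::vector<double> &fy,
                                  std::vector<double> &fz,
                                  bool do_virial, bool step_confined,
                                  std::vector<Candidate> *cand) {
  ForceResult res;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);

  auto add_pair = [&](int i, int j, double fmag_over_r, double dx, double dy,
                      double dz) {
    // force on i = fmag_over_r * (r_i - r_j)
    double fxx = fmag_over_r * dx, fyy = fmag_over_r * dy,
           fzz = fmag_over_r * dz;
    fx[i] += fxx; fy[i] += fyy; fz[i] += fzz;
    fx[j] -= fxx; fy[j] -= fyy; fz[j] -= fzz;
    if (do_virial) {
      res.vir[0] += dx * fxx; res.vir[1] += dy * fyy; res.vir[2] += dz * fzz;
      res.vir[3] += dx * fyy; res.vir[4] += dx * fzz; res.vir[5] += dy * fzz;
    }
  };

  // structural bonds
  for (size_t b = 0; b < s.bi.size(); ++b) {
    int i = s.bi[b], j = s.bj[b];
    double dx = s.minimg(s.x[i] - s.x[j], 0);
    double dy = s.minimg(s.y[i] - s.y[j], 1);
    double dz = s.minimg(s.z[i] - s.z[j], 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double de = r - s.brest[b];
    res.e_bond += 0.5 * s.bk[b] * de * de;
    if (r > 1e-12) add_pair(i, j, -s.bk[b] * de / r, dx, dy, dz);
  }
  // live specific bonds (harmonic restraints between owner particles)
  for (size_t b = 0; b < s.bsa.size(); ++b) {
    int i = s.site_particle[s.bsa[b]];
    int j = s.site_particle[s.bsb[b]];
    int r_ = s.brule[b];
    double dx = s.minimg(s.x[i] - s.x[j], 0);
    double dy = s.minimg(s.y[i] - s.y[j], 1);
    double dz = s.minimg(s.z[i] - s.z[j], 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double de = r - s.rule_rest[r_];
    res.e_spe += 0.5 * s.rule_k[r_] * de * de;
    if (r > 1e-12) add_pair(i, j, -s.rule_k[r_] * de / r, dx, dy, dz);
  }
  // excluded volume + reaction candidates
  double cut2 = s.max_cut * s.max_cut;
  cl.for_pairs(s, [&](int i, int j) {
    double dx = s.minimg(s.x[i] - s.x[j], 0);
    double dy = s.minimg(s.y[i] - s.y[j], 1);
    double dz = s.minimg(s.z[i] - s.z[j], 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > cut2) return;
    double contact = s.radius[i] + s.radius[j];
    if (r2 < contact * contact &&
        s.excl.count((int64_t)std::min(i, j) * s.N + std::max(i, j)) == 0) {
      double r = std::sqrt(r2);
      double de = r - contact;
      res.e_nonspe += 0.5 * s.k_rep * de * de;
      if (r > 1e-12) add_pair(i, j, -s.k_rep * de / r, dx, dy, dz);
    }
    if (cand && s.mol[i] != s.mol[j] && !s.sites_of[i].empty() &&
        !s.sites_of[j].empty()) {
      for (int sa : s.sites_of[i]) {
        if (!s.site_active[sa] || s.occ[sa] >= 0) continue;
        for (int sb : s.sites_of[j]) {
          if (!s.site_active[sb] || s.occ[sb] >= 0) continue;
          int rid = s.rmap[s.site_type[sa]][s.site_type[sb]];
          if (rid < 0) continue;
          if (r2 <= s.rule_rr[rid] * s.rule_rr[rid]) {
            cand->push_back({sa, sb, rid});
          }
        }
      }
    }
  });
  // external potentials (membrane, confinement): no virial contribution
  if (s.membrane_on) {
    for (int i = 0; i < s.N; ++i) {
      double zz = s.minimg(s.z[i], 2);
      if (s.comp[i] == 1) {  // membrane domain: flat inside |z| < d_mem2
        double az = std::fabs(zz);
        if (az >= s.d_mem2) {
          double de = az - s.d_mem2;
          res.e_sys += 0.5 * s.k_mem * de * de;
          fz[i] += -s.k_mem * de * (zz > 0 ? 1.0 : -1.0);
        }
      } else {               // cytoplasmic domain: flat below -d_mem2
        if (zz >= -s.d_mem2) {
          double de = zz + s.d_mem2;
          res.e_sys += 0.5 * s.k_mem * de * de;
          fz[i] += -s.k_mem * de;
        } else {
          // soft floor closing the periodic image of the cytosol: both
          // sides of the z boundary repel, so the membrane potential is
          // never traversed through the wrapped image
          double zfloor = -0.5 * s.box[2] + s.d_mem2;
          if (zz < zfloor) {
            double de = zz - zfloor;
            res.e_sys += 0.5 * s.k_mem * de * de;
            fz[i] += -s.k_mem * de;
          }
        }
      }
    }
  }
  if (s.conf_on && step_confined) {
    for (int i = 0; i < s.N; ++i) {
      double zz = s.minimg(s.z[i], 2);
      if (zz < s.conf_lo) {
        double de = zz - s.conf_lo;
        res.e_sys += 0.5 * s.conf_k * de * de;
        fz[i] += -s.conf_k * de;
      } else if (zz > s.conf_hi) {
        double de = zz - s.conf_hi;
        res.e_sys += 0.5 * s.conf_k * de * de;
        fz[i] += -s.conf_k * de;
      }
    }
  }
  return res;
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericVector box,
             NumericVector radius, NumericVector diff,
             IntegerVector comp, IntegerVector mol,
             IntegerMatrix sbond, NumericVector sbond_rest,
             NumericVector sbond_k,
             IntegerVector site_particle, IntegerVector site_type,
             IntegerVector site_active,
             List rules, IntegerMatrix bonds0,
             bool membrane_on, double k_mem, double d_mem2,
             bool conf_on, double conf_lo, double conf_hi,
             double conf_k, int conf_release,
             double k_rep, double kT, double dt,
             int n_steps, int step0,
             int sample_stride, int traj_stride,
             double seed, Nullable<IntegerVector> rng_state) {
  Sys s = make_sys(pos, box, radius, diff, comp, mol, sbond, sbond_rest,
                   sbond_k, site_particle, site_type, site_active, rules,
                   bonds0, membrane_on, k_mem, d_mem2, conf_on, conf_lo,
                   conf_hi, conf_k, conf_release, k_rep, kT, dt);
  Xoshiro rng;
  if (rng_state.isNotNull()) rng_unpack(rng, rng_state.get());
  else rng.seed((uint64_t)seed);

  CellList cl;
  std::vector<double> fx(s.N), fy(s.N), fz(s.N);
  std::vector<Candidate> cand;
  double vol = s.box[0] * s.box[1] * s.box[2];

  std::vector<double> samp;           // step, P(6), nbond, energies(4)
  List frames;
  int ncol_samp = 12;

  auto snapshot_bonds = [&]() {
    int nb = (int)s.bsa.size();
    IntegerMatrix bm(nb, 4);
    for (int b = 0; b < nb; ++b) {
      bm(b, 0) = s.bsa[b]; bm(b, 1) = s.bsb[b];
      bm(b, 2) = s.brule[b]; bm(b, 3) = s.bformed[b];
    }
    return bm;
  };
  auto snapshot_pos = [&]() {
    NumericMatrix pm(s.N, 3);
    for (int i = 0; i < s.N; ++i) {
      pm(i, 0) = s.x[i]; pm(i, 1) = s.y[i]; pm(i, 2) = s.z[i];
    }
    return pm;
  };

  for (int step = 0; step < n_steps; ++step) {
    int gstep = step0 + step;
    bool do_sample = sample_stride > 0 && (gstep % sample_stride == 0);
    bool step_confined = s.conf_on &&
      (s.conf_release < 0 || gstep < s.conf_release);
    cl.build(s);
    cand.clear();
    ForceResult fr = compute_forces(s, cl, fx, fy, fz, do_sample,
                                    step_confined, &cand);
    if (do_sample) {
      samp.push_back((double)gstep);
      double ideal = s.N * s.kT / vol;
      samp.push_back(ideal + fr.vir[0] / vol);
      samp.push_back(ideal + fr.vir[1] / vol);
      samp.push_back(ideal + fr.vir[2] / vol);
      samp.push_back(fr.vir[3] / vol);
      samp.push_back(fr.vir[4] / vol);
      samp.push_back(fr.vir[5] / vol);
      samp.push_back((double)s.bsa.size());
      samp.push_back(fr.e_bond);
      samp.push_back(fr.e_spe);
      samp.push_back(fr.e_nonspe);
      samp.push_back(fr.e_sys);
    }
    if (traj_stride > 0 && (gstep % traj_stride == 0)) {
      frames.push_back(List::create(_["step"] = gstep,
                                    _["pos"] = snapshot_pos(),
                                    _["bonds"] = snapshot_bonds()));
    }
    // BD move: dx = D F dt / kT + sqrt(2 D dt) xi   (fixed particle order)
    for (int i = 0; i < s.N; ++i) {
      double mob = s.diff[i] * s.dt / s.kT;
      double sig = std::sqrt(2.0 * s.diff[i] * s.dt);
      double ddx = mob * fx[i] + sig * rng.gauss();
      double ddy = mob * fy[i] + sig * rng.gauss();
      double ddz = mob * fz[i] + sig * rng.gauss();
      if (!std::isfinite(ddx) || !std::isfinite(ddy) || !std::isfinite(ddz)) {
        stop("non-finite force/displacement at particle %d (step %d)",
             i + 1, gstep);
      }
      double nx = s.x[i] + ddx, ny = s.y[i] + ddy, nz = s.z[i] + ddz;
      if (nx < 0) nx += s.box[0]; else if (nx >= s.box[0]) nx -= s.box[0];
      if (ny < 0) ny += s.box[1]; else if (ny >= s.box[1]) ny -= s.box[1];
      if (nz < 0) nz += s.box[2]; else if (nz >= s.box[2]) nz -= s.box[2];
      if (nx < 0 || nx >= s.box[0]) nx = Sys::fullwrap(nx, s.box[0]);
      if (ny < 0 || ny >= s.box[1]) ny = Sys::fullwrap(ny, s.box[1]);
      if (nz < 0 || nz >= s.box[2]) nz = Sys::fullwrap(nz, s.box[2]);
      s.x[i] = nx; s.y[i] = ny; s.z[i] = nz;
    }
    // binding sweep in RNG-shuffled candidate order; a site claimed earlier
    // in the sweep is unavailable later (valency exclusion)
    int nc = (int)cand.size();
    if (nc > 1) {
      for (int a = nc - 1; a > 0; --a) {  // Fisher-Yates
        int b = (int)(rng.unif() * (a + 1));
        if (b > a) b = a;
        std::swap(cand[a], cand[b]);
      }
    }
    for (int a = 0; a < nc; ++a) {
      const Candidate &c = cand[a];
      if (s.occ[c.sa] >= 0 || s.occ[c.sb] >= 0) continue;
      if (rng.unif() < s.rule_pon[c.rule]) {
        s.bsa.push_back(c.sa); s.bsb.push_back(c.sb);
        s.brule.push_back(c.rule); s.bformed.push_back(gstep);
        s.occ[c.sa] = (int)s.bsa.size() - 1;
        s.occ[c.sb] = (int)s.bsa.size() - 1;
      }
    }
    // unbinding sweep; freed sites become eligible next step
    for (int b = (int)s.bsa.size() - 1; b >= 0; --b) {
      if (rng.unif() < s.rule_poff[s.brule[b]]) {
        s.occ[s.bsa[b]] = -1; s.occ[s.bsb[b]] = -1;
        int last = (int)s.bsa.size() - 1;
        if (b != last) {
          s.bsa[b] = s.bsa[last]; s.bsb[b] = s.bsb[last];
          s.brule[b] = s.brule[last]; s.bformed[b] = s.bformed[last];
          s.occ[s.bsa[b]] = b; s.occ[s.bsb[b]] = b;
        }
        s.bsa.pop_back(); s.bsb.pop_back();
        s.brule.pop_back(); s.bformed.pop_back();
      }
    }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  int nsamp = (int)samp.size() / ncol_samp;
  NumericMatrix sm(nsamp, ncol_samp);
  for (int r = 0; r < nsamp; ++r)
    for (int c = 0; c < ncol_samp; ++c) sm(r, c) = samp[r * ncol_samp + c];
  colnames(sm) = CharacterVector::create(
    "step", "Pxx", "Pyy", "Pzz", "Pxy", "Pxz", "Pyz", "n_bonds",
    "E_bond", "E_spe", "E_nonspe", "E_system");

  return List::create(
    _["pos"] = snapshot_pos(),
    _["bonds"] = snapshot_bonds(),
    _["samples"] = sm,
    _["frames"] = frames,
    _["step"] = step0 + n_steps,
    _["rng_state"] = rng_pack(rng));
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector box,
                       NumericVector radius, NumericVector diff,
                       IntegerVector comp, IntegerVector mol,
                       IntegerMatrix sbond, NumericVector sbond_rest,
                       NumericVector sbond_k,
                       IntegerVector site_particle, IntegerVector site_type,
                       IntegerVector site_active,
                       List rules, IntegerMatrix bonds0,
                       bool membrane_on, double k_mem, double d_mem2,
                       bool conf_on, double conf_lo, double conf_hi,
                       double conf_k, int conf_release,
                       double k_rep, double kT, double dt,
                       bool step_confined) {
  Sys s = make_sys(pos, box, radius, diff, comp, mol, sbond, sbond_rest,
                   sbond_k, site_particle, site_type, site_active, rules,
                   bonds0, membrane_on, k_mem, d_mem2, conf_on, conf_lo,
                   conf_hi, conf_k, conf_release, k_rep, kT, dt);
  CellList cl;
  cl.build(s);
  std::vector<double> fx(s.N), fy(s.N), fz(s.N);
  ForceResult fr = compute_forces(s, cl, fx, fy, fz, true, step_confined,
                                  nullptr);
  NumericMatrix F(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
  }
  double vol = s.box[0] * s.box[1] * s.box[2];
  double ideal = s.N * s.kT / vol;
  NumericVector P = NumericVector::create(
    _["Pxx"] = ideal + fr.vir[0] / vol,
    _["Pyy"] = ideal + fr.vir[1] / vol,
    _["Pzz"] = ideal + fr.vir[2] / vol,
    _["Pxy"] = fr.vir[3] / vol,
    _["Pxz"] = fr.vir[4] / vol,
    _["Pyz"] = fr.vir[5] / vol);
  return List::create(
    _["energy"] = NumericVector::create(
      _["V_bond"] = fr.e_bond, _["V_angle"] = 0.0, _["V_dihedral"] = 0.0,
      _["V_spe"] = fr.e_spe, _["V_nonspe"] = fr.e_nonspe,
      _["V_system"] = fr.e_sys,
      _["V_total"] = fr.e_bond + fr.e_spe + fr.e_nonspe + fr.e_sys),
    _["forces"] = F,
    _["pressure"] = P);
}

// Inter-molecule particle pairs within contact distance (+ margin),
// minimum-image.  Used by cluster detection and interaction counting.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, NumericVector box,
                                NumericVector radius, IntegerVector mol,
                                double margin) {
  int N = pos.nrow();
  Sys s;
  s.N = N;
  s.x.resize(N); s.y.resize(N); s.z.resize(N);
  for (int i = 0; i < N; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  for (int a = 0; a < 3; ++a) s.box[a] = box[a];
  s.radius.assign(radius.begin(), radius.end());
  double rmax = 0.0;
  for (int i = 0; i < N; ++i) rmax = std::max(rmax, s.radius[i]);
  s.max_cut = 2.0 * rmax + margin;
  s.wrap_all();
  CellList cl;
  cl.build(s);
  std::vector<int> pi, pj;
  cl.for_pairs(s, [&](int i, int j) {
    if (mol[i] == mol[j]) return;
    double dx = s.minimg(s.x[i] - s.x[j], 0);
    double dy = s.minimg(s.y[i] - s.y[j], 1);
    double dz = s.minimg(s.z[i] - s.z[j], 2);
    double cut = s.radius[i] + s.radius[j] + margin;
    if (dx * dx + dy * dy + dz * dz <= cut * cut) {
      pi.push_back(i + 1); pj.push_back(j + 1);
    }
  });
  IntegerMatrix out((int)pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k]; out(k, 1) = pj[k];
  }
  return out;
}
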