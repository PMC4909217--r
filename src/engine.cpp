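// Monte Carlo core for bead-bond filament assembly.
//
// Geometry conventions: coordinates are unwrapped (periodic wrapping is
// applied only to inter-end distance queries), lengths in nm, angles as
// cosines of the bending angle between consecutive bond vectors.
// All randomness is drawn from R's RNG so that set.seed() on the R side
// makes every run reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <utility>

using namespace Rcpp;

namespace {

struct Par {
  double bmin, bmax, bmin2, bmax2;
  double alpha_rad, cos_alpha;
  double max_disp;
  double react_dist, react_dist2, cos_react;
  bool theta_measure;  // uniform-in-bending-angle stationary measure
};

const double SIN_EPS = 1e-12;

Par par_from_list(const List& p) {
  Par q;
  q.bmin = as<double>(p["bond_min"]);
  q.bmax = as<double>(p["bond_max"]);
  q.bmin2 = q.bmin * q.bmin;
  q.bmax2 = q.bmax * q.bmax;
  q.alpha_rad = as<double>(p["max_bond_angle"]) * M_PI / 180.0;
  q.cos_alpha = std::cos(q.alpha_rad);
  q.max_disp = as<double>(p["max_displacement"]);
  q.react_dist = as<double>(p["reaction_distance"]);
  q.react_dist2 = q.react_dist * q.react_dist;
  q.cos_react = std::cos(as<double>(p["reaction_angle"]) * M_PI / 180.0);
  std::string m = as<std::string>(p["angle_measure"]);
  q.theta_measure = (m == "uniform_theta");
  return q;
}

// xoshiro256++ with SplitMix64 seeding, seeded from R's RNG at entry to
// every exported routine: set.seed() on the R side fixes entire runs while
// the hot loop avoids the overhead of calling back into R's generator.
struct RNG {
  uint64_t s[4];
  RNG() {
    uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t x = (a << 32) ^ b;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double u01() { return (next() >> 11) * 1.1102230246251565e-16; }
  inline int below(int n) {
    int j = (int)(u01() * n);
    return (j >= n) ? n - 1 : j;
  }
  inline void unit(double& x, double& y, double& z) {
    // Marsaglia (1972) rejection sampling of a uniform direction
    double u, v, ss;
    do {
      u = 2.0 * u01() - 1.0;
      v = 2.0 * u01() - 1.0;
      ss = u * u + v * v;
    } while (ss >= 1.0 || ss == 0.0);
    double f = 2.0 * std::sqrt(1.0 - ss);
    x = u * f;
    y = v * f;
    z = 1.0 - 2.0 * ss;
  }
};

struct Sys {
  std::vector<double> X, Y, Z;       // bead coordinates, unwrapped
  std::vector<int> prv, nxt, fid;    // chain links and filament id per bead
  std::vector<int> head, tail, nbeads;
  std::vector<char> alive;
  int nfil;                          // number of alive filaments

  int n() const { return (int)X.size(); }
};

// hard-cap check: bending angle of bonds u, v within acos(ca), sqrt-free
inline bool angle_within(double ux, double uy, double uz,
                         double vx, double vy, double vz, double ca) {
  double dot = ux * vx + uy * vy + uz * vz;
  double n2 = (ux * ux + uy * uy + uz * uz) * (vx * vx + vy * vy + vz * vz);
  if (ca >= 0.0) return dot >= 0.0 && dot * dot >= ca * ca * n2;
  return dot >= 0.0 || dot * dot <= ca * ca * n2;
}

// cosine of bending angle at b for points a -> b -> c
inline double bend_cos(const Sys& S, int a, int b, int c) {
  double ux = S.X[b] - S.X[a], uy = S.Y[b] - S.Y[a], uz = S.Z[b] - S.Z[a];
  double vx = S.X[c] - S.X[b], vy = S.Y[c] - S.Y[b], vz = S.Z[c] - S.Z[b];
  double un = std::sqrt(ux * ux + uy * uy + uz * uz);
  double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
  double cc = (ux * vx + uy * vy + uz * vz) / (un * vn);
  if (cc > 1.0) cc = 1.0;
  if (cc < -1.0) cc = -1.0;
  return cc;
}

inline double sin_from_cos(double c) {
  double s2 = 1.0 - c * c;
  return (s2 > 0.0) ? std::sqrt(s2) : 0.0;
}

// cosine of bending angle at b when bead m takes candidate position (mx,my,mz)
inline double bend_cos_moved(const Sys& S, int a, int b, int c, int m,
                             double mx, double my, double mz) {
  double ax = (a == m) ? mx : S.X[a], ay = (a == m) ? my : S.Y[a], az = (a == m) ? mz : S.Z[a];
  double bx = (b == m) ? mx : S.X[b], by = (b == m) ? my : S.Y[b], bz = (b == m) ? mz : S.Z[b];
  double cx = (c == m) ? mx : S.X[c], cy = (c == m) ? my : S.Y[c], cz = (c == m) ? mz : S.Z[c];
  double ux = bx - ax, uy = by - ay, uz = bz - az;
  double vx = cx - bx, vy = cy - by, vz = cz - bz;
  double un = std::sqrt(ux * ux + uy * uy + uz * uz);
  double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
  double cc = (ux * vx + uy * vy + uz * vz) / (un * vn);
  if (cc > 1.0) cc = 1.0;
  if (cc < -1.0) cc = -1.0;
  return cc;
}

// attempt one trial move of bead i with displacement (dx,dy,dz); applies on accept
bool attempt_displacement(Sys& S, const Par& P, int i,
                          double dx, double dy, double dz, RNG& rng) {
  double mx = S.X[i] + dx, my = S.Y[i] + dy, mz = S.Z[i] + dz;
  int p = S.prv[i], n = S.nxt[i];
  int pp = (p >= 0) ? S.prv[p] : -1;
  int nn = (n >= 0) ? S.nxt[n] : -1;

  // bond vectors touching i at the candidate position
  double pbx = 0, pby = 0, pbz = 0, nbx = 0, nby = 0, nbz = 0;
  if (p >= 0) {
    pbx = mx - S.X[p]; pby = my - S.Y[p]; pbz = mz - S.Z[p];
    double r2 = pbx * pbx + pby * pby + pbz * pbz;
    if (r2 < P.bmin2 || r2 > P.bmax2) return false;
  }
  if (n >= 0) {
    nbx = S.X[n] - mx; nby = S.Y[n] - my; nbz = S.Z[n] - mz;
    double r2 = nbx * nbx + nby * nby + nbz * nbz;
    if (r2 < P.bmin2 || r2 > P.bmax2) return false;
  }

  if (!P.theta_measure) {
    // pure geometric cutoff on the (at most three) angles touching i
    if (p >= 0 && n >= 0 &&
        !angle_within(pbx, pby, pbz, nbx, nby, nbz, P.cos_alpha))
      return false;
    if (pp >= 0 &&
        !angle_within(S.X[p] - S.X[pp], S.Y[p] - S.Y[pp], S.Z[p] - S.Z[pp],
                      pbx, pby, pbz, P.cos_alpha))
      return false;
    if (nn >= 0 &&
        !angle_within(nbx, nby, nbz, S.X[nn] - S.X[n], S.Y[nn] - S.Y[n],
                      S.Z[nn] - S.Z[n], P.cos_alpha))
      return false;
  } else {
    // cutoff plus the Jacobian factor that makes the bending angle uniform
    double ratio = 1.0;
    if (p >= 0 && n >= 0) {
      double cn = bend_cos_moved(S, p, i, n, i, mx, my, mz);
      if (cn < P.cos_alpha) return false;
      double so = sin_from_cos(bend_cos(S, p, i, n));
      ratio *= std::max(so, SIN_EPS) / std::max(sin_from_cos(cn), SIN_EPS);
    }
    if (pp >= 0) {
      double cn = bend_cos_moved(S, pp, p, i, i, mx, my, mz);
      if (cn < P.cos_alpha) return false;
      double so = sin_from_cos(bend_cos(S, pp, p, i));
      ratio *= std::max(so, SIN_EPS) / std::max(sin_from_cos(cn), SIN_EPS);
    }
    if (nn >= 0) {
      double cn = bend_cos_moved(S, i, n, nn, i, mx, my, mz);
      if (cn < P.cos_alpha) return false;
      double so = sin_from_cos(bend_cos(S, i, n, nn));
      ratio *= std::max(so, SIN_EPS) / std::max(sin_from_cos(cn), SIN_EPS);
    }
    if (ratio < 1.0 && rng.u01() >= ratio) return false;
  }

  S.X[i] = mx;
  S.Y[i] = my;
  S.Z[i] = mz;
  return true;
}

inline bool try_move_bead(Sys& S, const Par& P, int i, RNG& rng) {
  double ux, uy, uz;
  rng.unit(ux, uy, uz);
  double m = rng.u01() * P.max_disp;
  return attempt_displacement(S, P, i, ux * m, uy * m, uz * m, rng);
}

// one sweep: every bead attempts one move, in fresh random order
double do_sweep(Sys& S, const Par& P, std::vector<int>& perm, RNG& rng) {
  int N = S.n();
  for (int k = N - 1; k > 0; --k) {
    int j = rng.below(k + 1);
    std::swap(perm[k], perm[j]);
  }
  int acc = 0;
  for (int k = 0; k < N; ++k) acc += try_move_bead(S, P, perm[k], rng);
  return (double)acc / N;
}

inline double wrap0(double x, double edge) {
  double w = x - edge * std::floor(x / edge);
  return (w >= edge) ? w - edge : w;
}

inline double min_image_1d(double d, double edge) {
  return d - edge * std::nearbyint(d / edge);
}

// all pairs of points (given by wrapped coords) with minimum-image distance
// below rc and distinct group ids; cell list with fall-back to brute force
void collect_pairs(const std::vector<double>& px, const std::vector<double>& py,
                   const std::vector<double>& pz, const std::vector<int>& grp,
                   double edge, double rc, bool force_brute,
                   std::vector<std::pair<int, int> >& out) {
  int ne = (int)px.size();
  double rc2 = rc * rc;
  int m = (int)std::floor(edge / rc);
  if (m < 3 || force_brute) {
    for (int a = 0; a < ne; ++a)
      for (int b = a + 1; b < ne; ++b) {
        if (grp[a] == grp[b]) continue;
        double dx = min_image_1d(px[b] - px[a], edge);
        double dy = min_image_1d(py[b] - py[a], edge);
        double dz = min_image_1d(pz[b] - pz[a], edge);
        if (dx * dx + dy * dy + dz * dz < rc2) out.push_back(std::make_pair(a, b));
      }
    return;
  }
  double cw = edge / m;
  std::vector<int> cell_head((size_t)m * m * m, -1), nxt_in(ne, -1);
  std::vector<int> cxv(ne), cyv(ne), czv(ne);
  for (int e = 0; e < ne; ++e) {
    int cx = (int)(px[e] / cw); if (cx >= m) cx = m - 1;
    int cy = (int)(py[e] / cw); if (cy >= m) cy = m - 1;
    int cz = (int)(pz[e] / cw); if (cz >= m) cz = m - 1;
    cxv[e] = cx; cyv[e] = cy; czv[e] = cz;
    int c = cx + m * (cy + m * cz);
    nxt_in[e] = cell_head[c];
    cell_head[c] = e;
  }
  for (int a = 0; a < ne; ++a) {
    for (int ix = -1; ix <= 1; ++ix)
      for (int iy = -1; iy <= 1; ++iy)
        for (int iz = -1; iz <= 1; ++iz) {
          int cx = (cxv[a] + ix + m) % m;
          int cy = (cyv[a] + iy + m) % m;
          int cz = (czv[a] + iz + m) % m;
          int c = cx + m * (cy + m * cz);
          for (int b = cell_head[c]; b != -1; b = nxt_in[b]) {
            if (b <= a) continue;
            if (grp[a] == grp[b]) continue;
            double dx = min_image_1d(px[b] - px[a], edge);
            double dy = min_image_1d(py[b] - py[a], edge);
            double dz = min_image_1d(pz[b] - pz[a], edge);
            if (dx * dx + dy * dy + dz * dz < rc2) out.push_back(std::make_pair(a, b));
          }
        }
  }
}

void reverse_fil(Sys& S, int f) {
  int cur = S.head[f];
  while (cur != -1) {
    int t = S.nxt[cur];
    S.nxt[cur] = S.prv[cur];
    S.prv[cur] = t;
    cur = t;
  }
  std::swap(S.head[f], S.tail[f]);
}

// attempt to join filaments at terminal beads a and b (already known to be
// within reaction distance); the new bond is the minimum-image gap vector
bool try_merge(Sys& S, const Par& P, double edge, int a, int b) {
  double gx = min_image_1d(S.X[b] - S.X[a], edge);
  double gy = min_image_1d(S.Y[b] - S.Y[a], edge);
  double gz = min_image_1d(S.Z[b] - S.Z[a], edge);
  double g2 = gx * gx + gy * gy + gz * gz;
  if (g2 < P.bmin2 || g2 > P.bmax2) return false;
  double gn = std::sqrt(g2);

  int ia = (S.nxt[a] == -1) ? S.prv[a] : S.nxt[a];  // inner neighbour of a
  int ib = (S.nxt[b] == -1) ? S.prv[b] : S.nxt[b];  // inner neighbour of b

  // junction angle on the a side: bond (ia -> a) against the gap vector
  {
    double ux = S.X[a] - S.X[ia], uy = S.Y[a] - S.Y[ia], uz = S.Z[a] - S.Z[ia];
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    double cc = (ux * gx + uy * gy + uz * gz) / (un * gn);
    if (cc < P.cos_react) return false;
  }
  // junction angle on the b side: gap vector against bond (b -> ib)
  {
    double vx = S.X[ib] - S.X[b], vy = S.Y[ib] - S.Y[b], vz = S.Z[ib] - S.Z[b];
    double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
    double cc = (gx * vx + gy * vy + gz * vz) / (gn * vn);
    if (cc < P.cos_react) return false;
  }

  int fa = S.fid[a], fb = S.fid[b];
  if (S.prv[a] == -1) reverse_fil(S, fa);  // a must become the tail of fa
  if (S.nxt[b] == -1) reverse_fil(S, fb);  // b must become the head of fb

  // translate fb into the image adjacent to a so the new bond is the gap
  double sx = (S.X[a] + gx) - S.X[b];
  double sy = (S.Y[a] + gy) - S.Y[b];
  double sz = (S.Z[a] + gz) - S.Z[b];
  for (int c = S.head[fb]; c != -1; c = S.nxt[c]) {
    S.X[c] += sx;
    S.Y[c] += sy;
    S.Z[c] += sz;
    S.fid[c] = fa;
  }

  S.nxt[a] = b;
  S.prv[b] = a;
  S.tail[fa] = S.tail[fb];
  S.nbeads[fa] += S.nbeads[fb];
  S.alive[fb] = 0;
  S.nfil--;
  return true;
}

// one annealing pass: detect reactive end pairs, shuffle, let each end react
// at most once; returns number of merges
int anneal_pass(Sys& S, const Par& P, double edge,
                std::vector<double>& ev_sweep, std::vector<int>& ev_a,
                std::vector<int>& ev_b, double sweep_now, RNG& rng) {
  std::vector<int> ends;
  ends.reserve(2 * (size_t)S.nfil);
  for (size_t f = 0; f < S.head.size(); ++f)
    if (S.alive[f]) {
      ends.push_back(S.head[f]);
      ends.push_back(S.tail[f]);
    }
  int ne = (int)ends.size();
  std::vector<double> px(ne), py(ne), pz(ne);
  std::vector<int> grp(ne);
  for (int e = 0; e < ne; ++e) {
    px[e] = wrap0(S.X[ends[e]], edge);
    py[e] = wrap0(S.Y[ends[e]], edge);
    pz[e] = wrap0(S.Z[ends[e]], edge);
    grp[e] = S.fid[ends[e]];
  }
  std::vector<std::pair<int, int> > cand;
  collect_pairs(px, py, pz, grp, edge, P.react_dist, false, cand);
  for (int k = (int)cand.size() - 1; k > 0; --k) {
    int j = rng.below(k + 1);
    std::swap(cand[k], cand[j]);
  }
  int merges = 0;
  for (size_t k = 0; k < cand.size(); ++k) {
    int a = ends[cand[k].first], b = ends[cand[k].second];
    // stale or already-used ends: an end reacts at most once per pass,
    // and a merge may have re-joined the two candidates' filaments
    if (S.nxt[a] != -1 && S.prv[a] != -1) continue;
    if (S.nxt[b] != -1 && S.prv[b] != -1) continue;
    if (S.fid[a] == S.fid[b]) continue;
    if (try_merge(S, P, edge, a, b)) {
      ev_sweep.push_back(sweep_now);
      ev_a.push_back(a + 1);
      ev_b.push_back(b + 1);
      ++merges;
    }
  }
  return merges;
}

Sys sys_from_r(const NumericMatrix& coords, const List& filaments) {
  Sys S;
  int N = coords.nrow();
  S.X.resize(N); S.Y.resize(N); S.Z.resize(N);
  for (int i = 0; i < N; ++i) {
    S.X[i] = coords(i, 0);
    S.Y[i] = coords(i, 1);
    S.Z[i] = coords(i, 2);
  }
  S.prv.assign(N, -1);
  S.nxt.assign(N, -1);
  S.fid.assign(N, -1);
  int nf = filaments.size();
  S.head.resize(nf); S.tail.resize(nf); S.nbeads.resize(nf);
  S.alive.assign(nf, 1);
  S.nfil = nf;
  for (int f = 0; f < nf; ++f) {
    IntegerVector idx = filaments[f];
    int len = idx.size();
    if (len < 2) stop("each filament needs at least 2 beads");
    for (int k = 0; k < len; ++k) {
      int i = idx[k] - 1;
      if (i < 0 || i >= N) stop("bead index out of range");
      S.fid[i] = f;
      if (k > 0) S.prv[i] = idx[k - 1] - 1;
      if (k < len - 1) S.nxt[i] = idx[k + 1] - 1;
    }
    S.head[f] = idx[0] - 1;
    S.tail[f] = idx[len - 1] - 1;
    S.nbeads[f] = len;
  }
  return S;
}

List sys_to_r(const Sys& S) {
  int N = S.n();
  NumericMatrix coords(N, 3);
  for (int i = 0; i < N; ++i) {
    coords(i, 0) = S.X[i];
    coords(i, 1) = S.Y[i];
    coords(i, 2) = S.Z[i];
  }
  List fil(S.nfil);
  int k = 0;
  for (size_t f = 0; f < S.head.size(); ++f) {
    if (!S.alive[f]) continue;
    IntegerVector idx(S.nbeads[f]);
    int j = 0;
    for (int c = S.head[f]; c != -1; c = S.nxt[c]) idx[j++] = c + 1;
    fil[k++] = idx;
  }
  return List::create(_["coords"] = coords, _["filaments"] = fil);
}

double chain_rg2(const Sys& S) {
  int N = S.n();
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < N; ++i) { cx += S.X[i]; cy += S.Y[i]; cz += S.Z[i]; }
  cx /= N; cy /= N; cz /= N;
  double s = 0;
  for (int i = 0; i < N; ++i) {
    double dx = S.X[i] - cx, dy = S.Y[i] - cy, dz = S.Z[i] - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return s / N;
}

void chain_bonds(const Sys& S, double& mean_bond, double& clen) {
  int N = S.n();
  double s = 0;
  for (int i = 1; i < N; ++i) {
    double dx = S.X[i] - S.X[i - 1], dy = S.Y[i] - S.Y[i - 1], dz = S.Z[i] - S.Z[i - 1];
    s += std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  clen = s;
  mean_bond = s / (N - 1);
}

// draw one chain of n beads from the exact equilibrium measure:
// bond lengths with density ~ r^2 on [bmin,bmax], bending angles from the
// configured measure, free torsion; first bond uniformly oriented
void draw_equilibrium_chain(int n_beads, const Par& P, RNG& rng,
                            std::vector<double>& X, std::vector<double>& Y,
                            std::vector<double>& Z) {
  X.assign(n_beads, 0.0);
  Y.assign(n_beads, 0.0);
  Z.assign(n_beads, 0.0);
  double b3min = P.bmin * P.bmin * P.bmin;
  double b3max = P.bmax * P.bmax * P.bmax;
  double ux, uy, uz;
  rng.unit(ux, uy, uz);
  for (int i = 1; i < n_beads; ++i) {
    if (i > 1) {
      double th = P.theta_measure
                      ? P.alpha_rad * rng.u01()
                      : std::acos(1.0 - rng.u01() * (1.0 - P.cos_alpha));
      double ph = 2.0 * M_PI * rng.u01();
      // orthonormal frame around the previous bond direction
      double tx, ty, tz;
      if (std::fabs(ux) < 0.9) { tx = 1; ty = 0; tz = 0; } else { tx = 0; ty = 1; tz = 0; }
      double dp = tx * ux + ty * uy + tz * uz;
      double e1x = tx - dp * ux, e1y = ty - dp * uy, e1z = tz - dp * uz;
      double e1n = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
      e1x /= e1n; e1y /= e1n; e1z /= e1n;
      double e2x = uy * e1z - uz * e1y;
      double e2y = uz * e1x - ux * e1z;
      double e2z = ux * e1y - uy * e1x;
      double st = std::sin(th), ct = std::cos(th);
      double nx = ct * ux + st * (std::cos(ph) * e1x + std::sin(ph) * e2x);
      double ny = ct * uy + st * (std::cos(ph) * e1y + std::sin(ph) * e2y);
      double nz = ct * uz + st * (std::cos(ph) * e1z + std::sin(ph) * e2z);
      double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
      ux = nx / nn; uy = ny / nn; uz = nz / nn;
    }
    double r = std::cbrt(b3min + rng.u01() * (b3max - b3min));
    X[i] = X[i - 1] + r * ux;
    Y[i] = Y[i - 1] + r * uy;
    Z[i] = Z[i - 1] + r * uz;
  }
}

Sys single_chain_sys(const std::vector<double>& X, const std::vector<double>& Y,
                     const std::vector<double>& Z) {
  Sys S;
  int N = (int)X.size();
  S.X = X; S.Y = Y; S.Z = Z;
  S.prv.resize(N);
  S.nxt.resize(N);
  S.fid.assign(N, 0);
  for (int i = 0; i < N; ++i) {
    S.prv[i] = i - 1;
    S.nxt[i] = (i == N - 1) ? -1 : i + 1;
  }
  S.head.assign(1, 0);
  S.tail.assign(1, N - 1);
  S.nbeads.assign(1, N);
  S.alive.assign(1, 1);
  S.nfil = 1;
  return S;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_assembly(NumericMatrix coords, List filaments, List params,
                      double edge, int n0_ulfs, int target_nfil,
                      double max_sweeps, double record_every, double sweep0,
                      int react_every) {
  Par P = par_from_list(params);
  Sys S = sys_from_r(coords, filaments);
  std::vector<int> perm(S.n());
  for (int i = 0; i < S.n(); ++i) perm[i] = i;

  std::vector<double> tr_sweep, tr_nfil, tr_ln, tr_acc;
  std::vector<double> ev_sweep;
  std::vector<int> ev_a, ev_b;

  RNGScope scope;
  RNG rng;
  long long max_sw = R_FINITE(max_sweeps) ? (long long)max_sweeps
                                          : (long long)9e18;
  long long rec = (long long)record_every;
  long long sweeps_done = 0;
  double acc_accum = 0;
  double acc_n = 0;
  tr_sweep.push_back(sweep0);
  tr_nfil.push_back(S.nfil);
  tr_ln.push_back((double)n0_ulfs / S.nfil);
  tr_acc.push_back(NA_REAL);

  while (sweeps_done < max_sw && S.nfil > target_nfil) {
    acc_accum += do_sweep(S, P, perm, rng);
    acc_n += 1;
    sweeps_done += 1;
    if (react_every > 0 && sweeps_done % react_every == 0)
      anneal_pass(S, P, edge, ev_sweep, ev_a, ev_b, sweep0 + sweeps_done,
                  rng);
    bool due = rec > 0 && sweeps_done % rec == 0;
    bool stopping = (S.nfil <= target_nfil) || (sweeps_done >= max_sw);
    if (due || stopping) {
      tr_sweep.push_back(sweep0 + (double)sweeps_done);
      tr_nfil.push_back(S.nfil);
      tr_ln.push_back((double)n0_ulfs / S.nfil);
      tr_acc.push_back(acc_n > 0 ? acc_accum / acc_n : NA_REAL);
      acc_accum = 0;
      acc_n = 0;
    }
    if (sweeps_done % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  List out_state = sys_to_r(S);
  return List::create(
      _["trajectory"] = DataFrame::create(
          _["sweep"] = tr_sweep, _["n_filaments"] = tr_nfil,
          _["mean_ln"] = tr_ln, _["acceptance"] = tr_acc),
      _["coords"] = out_state["coords"],
      _["filaments"] = out_state["filaments"],
      _["events"] = DataFrame::create(_["sweep"] = ev_sweep,
                                      _["bead_a"] = ev_a, _["bead_b"] = ev_b),
      _["sweeps_done"] = sweeps_done,
      _["n_filaments"] = S.nfil,
      _["reached"] = (S.nfil <= target_nfil));
}

// [[Rcpp::export]]
List cpp_sim_chain(NumericMatrix coords, List params, double equil_sweeps,
                   double n_sweeps, double sample_every) {
  Par P = par_from_list(params);
  int N = coords.nrow();
  std::vector<double> X(N), Y(N), Z(N);
  for (int i = 0; i < N; ++i) { X[i] = coords(i, 0); Y[i] = coords(i, 1); Z[i] = coords(i, 2); }
  Sys S = single_chain_sys(X, Y, Z);
  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;

  RNGScope scope;
  RNG rng;
  long long n_eq = (long long)equil_sweeps;
  long long n_sw = (long long)n_sweeps;
  long long stride = (long long)sample_every;
  if (stride < 1) stride = 1;
  for (long long s = 0; s < n_eq; ++s) {
    do_sweep(S, P, perm, rng);
    if (s % 5000 == 0) Rcpp::checkUserInterrupt();
  }
  std::vector<double> rg2s, bonds, clens;
  double acc_sum = 0;
  double ns = 0;
  for (long long s = 1; s <= n_sw; ++s) {
    acc_sum += do_sweep(S, P, perm, rng);
    ns += 1;
    if (s % stride == 0) {
      double mb, cl;
      chain_bonds(S, mb, cl);
      rg2s.push_back(chain_rg2(S));
      bonds.push_back(mb);
      clens.push_back(cl);
    }
    if (s % 5000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i) {
    out(i, 0) = S.X[i];
    out(i, 1) = S.Y[i];
    out(i, 2) = S.Z[i];
  }
  return List::create(_["rg2"] = rg2s, _["mean_bond"] = bonds,
                      _["contour_length"] = clens,
                      _["acceptance"] = (ns > 0 ? acc_sum / ns : NA_REAL),
                      _["coords"] = out);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_chain(int n_beads, List params) {
  Par P = par_from_list(params);
  RNGScope scope;
  RNG rng;
  std::vector<double> X, Y, Z;
  draw_equilibrium_chain(n_beads, P, rng, X, Y, Z);
  NumericMatrix out(n_beads, 3);
  for (int i = 0; i < n_beads; ++i) {
    out(i, 0) = X[i];
    out(i, 1) = Y[i];
    out(i, 2) = Z[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_rg2_replicates(int n_beads, List params, int n_rep,
                        double equil_sweeps, double n_sweeps,
                        double sample_every) {
  Par P = par_from_list(params);
  RNGScope scope;
  RNG rng;
  NumericVector rg2_mean(n_rep), clen_mean(n_rep);
  double acc_sum = 0, acc_n = 0;
  std::vector<int> perm(n_beads);
  std::vector<double> X, Y, Z;
  for (int r = 0; r < n_rep; ++r) {
    draw_equilibrium_chain(n_beads, P, rng, X, Y, Z);
    Sys S = single_chain_sys(X, Y, Z);
    for (int i = 0; i < n_beads; ++i) perm[i] = i;
    long long n_eq = (long long)equil_sweeps;
    long long n_sw = (long long)n_sweeps;
    long long stride = (long long)sample_every;
    if (stride < 1) stride = 1;
    for (long long s = 0; s < n_eq; ++s) do_sweep(S, P, perm, rng);
    double rg_acc = 0, cl_acc = 0;
    int k = 0;
    for (long long s = 1; s <= n_sw; ++s) {
      acc_sum += do_sweep(S, P, perm, rng);
      acc_n += 1;
      if (s % stride == 0) {
        double mb, cl;
        chain_bonds(S, mb, cl);
        rg_acc += chain_rg2(S);
        cl_acc += cl;
        ++k;
      }
    }
    rg2_mean[r] = rg_acc / k;
    clen_mean[r] = cl_acc / k;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["rg2"] = rg2_mean, _["contour_length"] = clen_mean,
                      _["acceptance"] = acc_sum / acc_n);
}

// [[Rcpp::export]]
IntegerMatrix cpp_detect_pairs(NumericMatrix pos, IntegerVector group,
                               double edge, double rc, bool brute) {
  int ne = pos.nrow();
  std::vector<double> px(ne), py(ne), pz(ne);
  std::vector<int> grp(ne);
  for (int e = 0; e < ne; ++e) {
    px[e] = wrap0(pos(e, 0), edge);
    py[e] = wrap0(pos(e, 1), edge);
    pz[e] = wrap0(pos(e, 2), edge);
    grp[e] = group[e];
  }
  std::vector<std::pair<int, int> > out;
  collect_pairs(px, py, pz, grp, edge, rc, brute, out);
  IntegerMatrix res((int)out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    res(k, 0) = out[k].first + 1;
    res(k, 1) = out[k].second + 1;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_trial_move(NumericMatrix coords, int bead, NumericVector disp,
                    List params) {
  Par P = par_from_list(params);
  int N = coords.nrow();
  std::vector<double> X(N), Y(N), Z(N);
  for (int i = 0; i < N; ++i) { X[i] = coords(i, 0); Y[i] = coords(i, 1); Z[i] = coords(i, 2); }
  Sys S = single_chain_sys(X, Y, Z);
  RNGScope scope;
  RNG rng;
  bool acc = attempt_displacement(S, P, bead - 1, disp[0], disp[1], disp[2],
                                  rng);
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i) {
    out(i, 0) = S.X[i];
    out(i, 1) = S.Y[i];
    out(i, 2) = S.Z[i];
  }
  return List::create(_["accepted"] = acc, _["coords"] = out);
}
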