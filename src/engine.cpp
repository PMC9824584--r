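// Core Langevin-dynamics engine for a bead-spring chain in (and released
// from) a reflecting spherical cavity.
//
// Force field: purely repulsive WCA pair potential (cutoff 2^(1/6) sigma,
// applied to every pair, bonded included) plus stiff harmonic bonds.
// Integrator: BAOAB splitting of the Langevin equation; at eta*dt/m = 0.1
// its free-particle velocity variance is exact and its free-particle
// diffusion constant matches kBT/eta to <0.1%.
// Neighbour search: cell list rebuilt every step (cutoff is ~1.12 sigma, so
// rebuild cost is O(N) and dominates nothing).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 for seeding / seed-splitting, xoshiro256++ for the stream,
// Box-Muller for Gaussians.  Deterministic for a given 64-bit seed.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  explicit Xoshiro(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1); never exactly 0 (safe for log())
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// [[Rcpp::export]]
NumericVector cpp_split_seeds(double master, int n) {
  // 31-bit, strictly positive, deterministic seed sequence from one master
  uint64_t sm = (uint64_t)master * 0x9E3779B97f4A7C15ULL + 0x1234567ULL;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t v = splitmix64_next(sm);
    out[i] = (double)((v >> 33) | 1ULL);  // odd => distinct-ish, nonzero
  }
  return out;
}

// ---------------------------------------------------------------------------
// Forces
// ---------------------------------------------------------------------------

struct Params {
  double eps, sigma, b0, k, mass, kBT, eta, dt, fcap;
};

struct CellList {
  std::vector<int> head, nxt, used;
  int ncx = 0, ncy = 0, ncz = 0;
  double ox = 0, oy = 0, oz = 0, inv_edge = 1.0;

  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, int N, double cutoff) {
    double minx = x[0], maxx = x[0], miny = y[0], maxy = y[0],
           minz = z[0], maxz = z[0];
    for (int i = 1; i < N; ++i) {
      if (x[i] < minx) minx = x[i]; if (x[i] > maxx) maxx = x[i];
      if (y[i] < miny) miny = y[i]; if (y[i] > maxy) maxy = y[i];
      if (z[i] < minz) minz = z[i]; if (z[i] > maxz) maxz = z[i];
    }
    double Lx = maxx - minx, Ly = maxy - miny, Lz = maxz - minz;
    // cell edge >= cutoff; cap the total cell count at ~4N so the clear
    // stays O(N) even for a fully expanded coil
    double edge = cutoff;
    auto count = [&](double e) {
      long nx = std::max(1L, (long)(Lx / e));
      long ny = std::max(1L, (long)(Ly / e));
      long nz = std::max(1L, (long)(Lz / e));
      return nx * ny * nz;
    };
    long cap = 4L * N + 8L;
    while (count(edge) > cap) edge *= 1.2599210498948732;  // 2^(1/3)
    ncx = std::max(1, (int)(Lx / edge));
    ncy = std::max(1, (int)(Ly / edge));
    ncz = std::max(1, (int)(Lz / edge));
    inv_edge = 1.0 / edge;
    ox = minx; oy = miny; oz = minz;
    size_t tot = (size_t)ncx * ncy * ncz;
    if (head.size() < tot) head.assign(tot, -1);
    for (int c : used) head[c] = -1;
    used.clear();
    if ((int)nxt.size() < N) nxt.resize(N);
    for (int i = 0; i < N; ++i) {
      int cx = (int)((x[i] - ox) * inv_edge); if (cx >= ncx) cx = ncx - 1;
      int cy = (int)((y[i] - oy) * inv_edge); if (cy >= ncy) cy = ncy - 1;
      int cz = (int)((z[i] - oz) * inv_edge); if (cz >= ncz) cz = ncz - 1;
      int c = (cz * ncy + cy) * ncx + cx;
      nxt[i] = head[c];
      if (head[c] < 0) used.push_back(c);
      head[c] = i;
    }
  }
};

// WCA pair force accumulation between i and j given squared distance parts.
// Returns true if the pair was inside the cutoff (for min-distance tracking).
static inline void pair_force(int i, int j, const std::vector<double> &x,
                              const std::vector<double> &y,
                              const std::vector<double> &z,
                              std::vector<double> &fx, std::vector<double> &fy,
                              std::vector<double> &fz, double cut2,
                              const Params &p, double &min_nb2, int nb_gap) {
  double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= cut2) return;
  if (std::abs(i - j) >= nb_gap && r2 < min_nb2) min_nb2 = r2;
  double s2 = (p.sigma * p.sigma) / r2;
  double s6 = s2 * s2 * s2;
  double fr = 24.0 * p.eps * (2.0 * s6 * s6 - s6) / r2;  // F/r
  if (p.fcap > 0.0) {
    double r = std::sqrt(r2);
    if (fr * r > p.fcap) fr = p.fcap / r;
  }
  fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
  fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
}

// Full force evaluation: harmonic bonds + WCA on all pairs (cell list).
// min_nb2 tracks the minimum squared distance over non-bonded pairs seen
// inside the cutoff (monitors the no-chain-crossing invariant).
static void compute_forces(const std::vector<double> &x,
                           const std::vector<double> &y,
                           const std::vector<double> &z, int N,
                           const Params &p, CellList &cl,
                           std::vector<double> &fx, std::vector<double> &fy,
                           std::vector<double> &fz, double &min_nb2) {
  const double cutoff = 1.122462048309373 * p.sigma;
  const double cut2 = cutoff * cutoff;
  std::fill(fx.begin(), fx.begin() + N, 0.0);
  std::fill(fy.begin(), fy.begin() + N, 0.0);
  std::fill(fz.begin(), fz.begin() + N, 0.0);

  // bonds
  for (int i = 0; i + 1 < N; ++i) {
    double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
    double b = std::sqrt(dx * dx + dy * dy + dz * dz);
    double fb = -p.k * (b - p.b0) / b;  // along (r_{i+1}-r_i), on bead i+1
    fx[i + 1] += fb * dx; fy[i + 1] += fb * dy; fz[i + 1] += fb * dz;
    fx[i] -= fb * dx; fy[i] -= fb * dy; fz[i] -= fb * dz;
  }

  if (N < 40) {  // brute force cheaper than list management for tiny chains
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j)
        pair_force(i, j, x, y, z, fx, fy, fz, cut2, p, min_nb2, 2);
    return;
  }

  cl.build(x, y, z, N, cutoff);
  const int ncx = cl.ncx, ncy = cl.ncy, ncz = cl.ncz;
  for (int c : cl.used) {
    int cx = c % ncx, cy = (c / ncx) % ncy, cz = c / (ncx * ncy);
    for (int i = cl.head[c]; i >= 0; i = cl.nxt[i]) {
      // within own cell: j later in list
      for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j])
        pair_force(i, j, x, y, z, fx, fy, fz, cut2, p, min_nb2, 2);
      // half stencil of 13 forward neighbour cells
      static const int st[13][3] = {
        {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
        {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
      for (int s = 0; s < 13; ++s) {
        int nx = cx + st[s][0], ny = cy + st[s][1], nz = cz + st[s][2];
        if (nx < 0 || nx >= ncx || ny < 0 || ny >= ncy || nz < 0 || nz >= ncz)
          continue;
        int nc = (nz * ncy + ny) * ncx + nx;
        for (int j = cl.head[nc]; j >= 0; j = cl.nxt[j])
          pair_force(i, j, x, y, z, fx, fy, fz, cut2, p, min_nb2, 2);
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_total_forces(NumericMatrix pos, double eps, double sigma,
                               double b0, double k, double fcap) {
  int N = pos.nrow();
  Params p{eps, sigma, b0, k, 1.0, 1.0, 0.0, 0.0, fcap};
  std::vector<double> x(N), y(N), z(N), fx(N), fy(N), fz(N);
  for (int i = 0; i < N; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  CellList cl;
  double min_nb2 = std::numeric_limits<double>::infinity();
  compute_forces(x, y, z, N, p, cl, fx, fy, fz, min_nb2);
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i) { out(i,0) = fx[i]; out(i,1) = fy[i]; out(i,2) = fz[i]; }
  return out;
}

// ---------------------------------------------------------------------------
// Specular wall reflection about radius Rw (bead centres)
// ---------------------------------------------------------------------------

static inline void reflect(std::vector<double> &x, std::vector<double> &y,
                           std::vector<double> &z, std::vector<double> &vx,
                           std::vector<double> &vy, std::vector<double> &vz,
                           int N, double Rw) {
  double Rw2 = Rw * Rw;
  for (int i = 0; i < N; ++i) {
    double r2 = x[i]*x[i] + y[i]*y[i] + z[i]*z[i];
    if (r2 <= Rw2) continue;
    double r = std::sqrt(r2);
    double ux = x[i] / r, uy = y[i] / r, uz = z[i] / r;
    double rn = 2.0 * Rw - r;          // mirror about the bounding sphere
    if (rn < 0.0) rn = 0.0;            // pathological overshoot guard
    x[i] = rn * ux; y[i] = rn * uy; z[i] = rn * uz;
    double vr = vx[i]*ux + vy[i]*uy + vz[i]*uz;
    vx[i] -= 2.0 * vr * ux; vy[i] -= 2.0 * vr * uy; vz[i] -= 2.0 * vr * uz;
  }
}

// [[Rcpp::export]]
List cpp_reflect_wall(NumericMatrix pos, NumericMatrix vel, double Rw) {
  int N = pos.nrow();
  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2);
    vx[i] = vel(i,0); vy[i] = vel(i,1); vz[i] = vel(i,2);
  }
  reflect(x, y, z, vx, vy, vz, N, Rw);
  NumericMatrix np(N,3), nv(N,3);
  for (int i = 0; i < N; ++i) {
    np(i,0)=x[i]; np(i,1)=y[i]; np(i,2)=z[i];
    nv(i,0)=vx[i]; nv(i,1)=vy[i]; nv(i,2)=vz[i];
  }
  return List::create(_["positions"] = np, _["velocities"] = nv);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin run with sampling of Rg^2 and the gyration tensor
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos0, NumericMatrix vel0,
                double eps, double sigma, double b0, double k, double mass,
                double kBT, double eta, double dt,
                double wall_radius,       // <= 0: no wall
                int nsteps,
                IntegerVector sample_at,  // sorted step indices in [0,nsteps]
                double t0, double seed, double fcap,
                bool record_traj) {
  int N = pos0.nrow();
  Params p{eps, sigma, b0, k, mass, kBT, eta, dt, fcap};
  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N),
      fx(N), fy(N), fz(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos0(i,0); y[i] = pos0(i,1); z[i] = pos0(i,2);
    vx[i] = vel0(i,0); vy[i] = vel0(i,1); vz[i] = vel0(i,2);
  }
  Xoshiro rng((uint64_t)seed);
  CellList cl;

  const double hdtm = 0.5 * dt / mass;
  const double hdt = 0.5 * dt;
  const double c1 = std::exp(-eta * dt / mass);
  const double c2 = std::sqrt(kBT / mass * (1.0 - c1 * c1));

  int ns = sample_at.size();
  NumericVector s_time(ns), s_rg2(ns), s_minnb(ns), s_maxrad(ns), s_ke(ns);
  NumericMatrix s_gyr(ns, 6);  // xx, yy, zz, xy, xz, yz
  NumericVector traj(record_traj ? (R_xlen_t)ns * N * 3 : 0);

  double min_nb2 = std::numeric_limits<double>::infinity();
  int si = 0;

  auto sample_now = [&](int step) {
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < N; ++i) { cx += x[i]; cy += y[i]; cz += z[i]; }
    cx /= N; cy /= N; cz /= N;
    double gxx=0, gyy=0, gzz=0, gxy=0, gxz=0, gyz=0, maxr2 = 0;
    for (int i = 0; i < N; ++i) {
      double dx = x[i]-cx, dy = y[i]-cy, dz = z[i]-cz;
      gxx += dx*dx; gyy += dy*dy; gzz += dz*dz;
      gxy += dx*dy; gxz += dx*dz; gyz += dy*dz;
      double r2 = x[i]*x[i] + y[i]*y[i] + z[i]*z[i];
      if (r2 > maxr2) maxr2 = r2;
    }
    gxx/=N; gyy/=N; gzz/=N; gxy/=N; gxz/=N; gyz/=N;
    s_time[si] = t0 + step * dt;
    s_rg2[si] = gxx + gyy + gzz;
    s_gyr(si,0)=gxx; s_gyr(si,1)=gyy; s_gyr(si,2)=gzz;
    s_gyr(si,3)=gxy; s_gyr(si,4)=gxz; s_gyr(si,5)=gyz;
    s_minnb[si] = std::sqrt(min_nb2);
    s_maxrad[si] = std::sqrt(maxr2);
    double ke = 0;
    for (int i = 0; i < N; ++i)
      ke += vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i];
    s_ke[si] = 0.5 * mass * ke;
    min_nb2 = std::numeric_limits<double>::infinity();
    if (record_traj) {
      for (int i = 0; i < N; ++i) {
        traj[(R_xlen_t)si*N*3 + i*3 + 0] = x[i];
        traj[(R_xlen_t)si*N*3 + i*3 + 1] = y[i];
        traj[(R_xlen_t)si*N*3 + i*3 + 2] = z[i];
      }
    }
    ++si;
  };

  compute_forces(x, y, z, N, p, cl, fx, fy, fz, min_nb2);
  if (si < ns && sample_at[si] == 0) sample_now(0);

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < N; ++i) {            // B then A, fused
      vx[i] += hdtm * fx[i]; vy[i] += hdtm * fy[i]; vz[i] += hdtm * fz[i];
      x[i] += hdt * vx[i]; y[i] += hdt * vy[i]; z[i] += hdt * vz[i];
    }
    for (int i = 0; i < N; ++i) {            // O then A, fused
      vx[i] = c1 * vx[i] + c2 * rng.norm();
      vy[i] = c1 * vy[i] + c2 * rng.norm();
      vz[i] = c1 * vz[i] + c2 * rng.norm();
      x[i] += hdt * vx[i]; y[i] += hdt * vy[i]; z[i] += hdt * vz[i];
    }
    if (wall_radius > 0.0)
      reflect(x, y, z, vx, vy, vz, N, wall_radius);
    compute_forces(x, y, z, N, p, cl, fx, fy, fz, min_nb2);  // for next B
    for (int i = 0; i < N; ++i) {            // B
      vx[i] += hdtm * fx[i]; vy[i] += hdtm * fy[i]; vz[i] += hdtm * fz[i];
    }
    if (si < ns && sample_at[si] == step) sample_now(step);
  }

  for (int i = 0; i < N; ++i) {
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
      stop("integration failure: non-finite coordinates at bead %d", i + 1);
  }

  NumericMatrix pos(N,3), vel(N,3);
  for (int i = 0; i < N; ++i) {
    pos(i,0)=x[i]; pos(i,1)=y[i]; pos(i,2)=z[i];
    vel(i,0)=vx[i]; vel(i,1)=vy[i]; vel(i,2)=vz[i];
  }
  List out = List::create(
      _["times"] = s_time, _["rg2"] = s_rg2, _["gyr"] = s_gyr,
      _["min_nonbonded"] = s_minnb, _["max_radius"] = s_maxrad,
      _["kinetic"] = s_ke,
      _["positions"] = pos, _["velocities"] = vel,
      _["time"] = t0 + (double)nsteps * dt);
  if (record_traj) {
    traj.attr("dim") = IntegerVector::create(3, N, ns);
    out["trajectory"] = traj;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Chain initializers
// ---------------------------------------------------------------------------

// Growth-style self-avoiding chain in free space: each bead placed at
// distance b0 from its predecessor in a random direction, rejected if closer
// than min_sep to any earlier non-bonded bead.  Restarts on dead ends.
// [[Rcpp::export]]
NumericMatrix cpp_saw_chain(int N, double b0, double min_sep, double seed) {
  Xoshiro rng((uint64_t)seed);
  std::vector<double> x(N), y(N), z(N);
  double ms2 = min_sep * min_sep;
  for (int attempt = 0; attempt < 1000; ++attempt) {
    x[0] = y[0] = z[0] = 0.0;
    bool ok = true;
    for (int i = 1; i < N && ok; ++i) {
      bool placed = false;
      for (int trial = 0; trial < 400; ++trial) {
        // uniform direction
        double u = 2.0 * rng.unif() - 1.0;
        double a = 6.283185307179586 * rng.unif();
        double s = std::sqrt(1.0 - u * u);
        double px = x[i-1] + b0 * s * std::cos(a);
        double py = y[i-1] + b0 * s * std::sin(a);
        double pz = z[i-1] + b0 * u;
        bool clash = false;
        for (int j = 0; j < i - 1; ++j) {
          double dx = px-x[j], dy = py-y[j], dz = pz-z[j];
          if (dx*dx + dy*dy + dz*dz < ms2) { clash = true; break; }
        }
        if (!clash) { x[i] = px; y[i] = py; z[i] = pz; placed = true; break; }
      }
      if (!placed) ok = false;
    }
    if (ok) {
      NumericMatrix out(N, 3);
      for (int i = 0; i < N; ++i) { out(i,0)=x[i]; out(i,1)=y[i]; out(i,2)=z[i]; }
      return out;
    }
  }
  stop("failed to grow a self-avoiding chain after bounded retries");
}

// Random-walk chain confined to a sphere of radius Rw (bead centres), with a
// soft self-avoidance criterion that is relaxed progressively; overlaps left
// over are removed by a capped-force push-off run on the R side.
// [[Rcpp::export]]
NumericMatrix cpp_pack_chain(int N, double b0, double Rw, double seed) {
  Xoshiro rng((uint64_t)seed);
  std::vector<double> x(N), y(N), z(N);
  double Rin = std::max(0.0, Rw - 1e-9);
  for (int attempt = 0; attempt < 2000; ++attempt) {
    // random start inside the sphere
    for (;;) {
      double px = (2*rng.unif()-1) * Rin, py = (2*rng.unif()-1) * Rin,
             pz = (2*rng.unif()-1) * Rin;
      if (px*px + py*py + pz*pz <= Rin*Rin) { x[0]=px; y[0]=py; z[0]=pz; break; }
    }
    bool ok = true;
    for (int i = 1; i < N && ok; ++i) {
      double best = -1.0, bx=0, by=0, bz=0;
      for (int trial = 0; trial < 60; ++trial) {
        double u = 2.0 * rng.unif() - 1.0;
        double a = 6.283185307179586 * rng.unif();
        double s = std::sqrt(1.0 - u * u);
        double px = x[i-1] + b0 * s * std::cos(a);
        double py = y[i-1] + b0 * s * std::sin(a);
        double pz = z[i-1] + b0 * u;
        if (px*px + py*py + pz*pz > Rin*Rin) continue;
        double dmin = std::numeric_limits<double>::infinity();
        for (int j = 0; j < i - 1; ++j) {
          double dx = px-x[j], dy = py-y[j], dz = pz-z[j];
          double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 < dmin) dmin = d2;
        }
        if (dmin > best) { best = dmin; bx = px; by = py; bz = pz; }
        if (best >= 0.81) break;  // 0.9^2: good enough, stop trying
      }
      if (best < 0.25) { ok = false; break; }  // hopeless clash (<0.5 sigma)
      x[i] = bx; y[i] = by; z[i] = bz;
    }
    if (ok) {
      NumericMatrix out(N, 3);
      for (int i = 0; i < N; ++i) { out(i,0)=x[i]; out(i,1)=y[i]; out(i,2)=z[i]; }
      return out;
    }
  }
  stop("failed to pack the chain into the cavity after bounded retries");
}

// Maxwell-Boltzmann velocities at temperature kBT for mass m
// [[Rcpp::export]]
NumericMatrix cpp_mb_velocities(int N, double mass, double kBT, double seed) {
  Xoshiro rng((uint64_t)seed ^ 0xABCDEF0123456789ULL);
  double sd = std::sqrt(kBT / mass);
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = sd * rng.norm();
  return out;
}

// Pivot Monte Carlo on a hard-core chain: rotates the tail [p+1, N-1]
// about bead p by a uniform random rotation and accepts the move if no
// non-bonded pair comes closer than min_sep.  Pivot moves decorrelate the
// global conformation in O(N) accepted moves, which makes them the
// standard way to equilibrate long excluded-volume coils; a short Langevin
// run afterwards thermalizes the local (bond/velocity) degrees of freedom.
// [[Rcpp::export]]
NumericMatrix cpp_pivot_chain(NumericMatrix pos0, double min_sep,
                              int n_moves, double seed) {
  int N = pos0.nrow();
  Xoshiro rng((uint64_t)seed ^ 0x5DEECE66DULL);
  std::vector<double> x(N), y(N), z(N);
  for (int i = 0; i < N; ++i) { x[i]=pos0(i,0); y[i]=pos0(i,1); z[i]=pos0(i,2); }
  double ms2 = min_sep * min_sep;
  std::vector<double> tx(N), ty(N), tz(N);
  for (int mv = 0; mv < n_moves; ++mv) {
    int p = 1 + (int)(rng.unif() * (N - 2));
    if (p > N - 2) p = N - 2;
    // uniform random rotation from a random unit quaternion
    double q0, q1, q2, q3, qq;
    do {
      q0 = 2*rng.unif()-1; q1 = 2*rng.unif()-1;
      q2 = 2*rng.unif()-1; q3 = 2*rng.unif()-1;
      qq = q0*q0 + q1*q1 + q2*q2 + q3*q3;
    } while (qq > 1.0 || qq < 1e-12);
    double s = 1.0 / qq;
    double R[3][3] = {
      {1-2*s*(q2*q2+q3*q3), 2*s*(q1*q2-q0*q3),   2*s*(q1*q3+q0*q2)},
      {2*s*(q1*q2+q0*q3),   1-2*s*(q1*q1+q3*q3), 2*s*(q2*q3-q0*q1)},
      {2*s*(q1*q3-q0*q2),   2*s*(q2*q3+q0*q1),   1-2*s*(q1*q1+q2*q2)}};
    double px = x[p], py = y[p], pz = z[p];
    bool ok = true;
    for (int i = p + 1; i < N && ok; ++i) {
      double dx = x[i]-px, dy = y[i]-py, dz = z[i]-pz;
      double nx = px + R[0][0]*dx + R[0][1]*dy + R[0][2]*dz;
      double ny = py + R[1][0]*dx + R[1][1]*dy + R[1][2]*dz;
      double nz = pz + R[2][0]*dx + R[2][1]*dy + R[2][2]*dz;
      // overlap against the untouched head; tail-internal and head-internal
      // distances are preserved by the rigid rotation
      for (int j = 0; j < p; ++j) {
        double ddx = nx-x[j], ddy = ny-y[j], ddz = nz-z[j];
        if (ddx*ddx + ddy*ddy + ddz*ddz < ms2) { ok = false; break; }
      }
      tx[i] = nx; ty[i] = ny; tz[i] = nz;
    }
    if (!ok) continue;
    for (int i = p + 1; i < N; ++i) { x[i]=tx[i]; y[i]=ty[i]; z[i]=tz[i]; }
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i) { out(i,0)=x[i]; out(i,1)=y[i]; out(i,2)=z[i]; }
  return out;
}

// Metropolis pivot moves on the WCA energy itself.  A pivot rotation is an
// isometry of the tail, so bond and tail-internal WCA energies are
// unchanged; the move is accepted with probability exp(-dU/kBT) where dU
// sums WCA pair energies between the rotated tail and the untouched head.
// Alternated with Langevin dynamics this samples the exact Boltzmann
// ensemble of the chain while decorrelating the global conformation in
// O(N) accepted moves.
// [[Rcpp::export]]
List cpp_wca_pivot(NumericMatrix pos0, double eps, double sigma,
                   double kBT, int n_moves, double seed) {
  int N = pos0.nrow();
  Xoshiro rng((uint64_t)seed ^ 0x9E3779B9ULL);
  std::vector<double> x(N), y(N), z(N), tx(N), ty(N), tz(N);
  for (int i = 0; i < N; ++i) { x[i]=pos0(i,0); y[i]=pos0(i,1); z[i]=pos0(i,2); }
  const double cut2 = std::pow(2.0, 1.0/3.0) * sigma * sigma;
  auto wca = [&](double r2) {
    double s2 = sigma * sigma / r2, s6 = s2 * s2 * s2;
    return 4.0 * eps * (s6 * s6 - s6 + 0.25);
  };
  int accepted = 0;
  for (int mv = 0; mv < n_moves; ++mv) {
    int p = 1 + (int)(rng.unif() * (N - 2));
    if (p > N - 2) p = N - 2;
    double q0, q1, q2, q3, qq;
    do {
      q0 = 2*rng.unif()-1; q1 = 2*rng.unif()-1;
      q2 = 2*rng.unif()-1; q3 = 2*rng.unif()-1;
      qq = q0*q0 + q1*q1 + q2*q2 + q3*q3;
    } while (qq > 1.0 || qq < 1e-12);
    double s = 1.0 / qq;
    double R[3][3] = {
      {1-2*s*(q2*q2+q3*q3), 2*s*(q1*q2-q0*q3),   2*s*(q1*q3+q0*q2)},
      {2*s*(q1*q2+q0*q3),   1-2*s*(q1*q1+q3*q3), 2*s*(q2*q3-q0*q1)},
      {2*s*(q1*q3-q0*q2),   2*s*(q2*q3+q0*q1),   1-2*s*(q1*q1+q2*q2)}};
    double px = x[p], py = y[p], pz = z[p];
    double dU = 0.0;
    for (int i = p + 1; i < N; ++i) {
      double dx = x[i]-px, dy = y[i]-py, dz = z[i]-pz;
      double nx = px + R[0][0]*dx + R[0][1]*dy + R[0][2]*dz;
      double ny = py + R[1][0]*dx + R[1][1]*dy + R[1][2]*dz;
      double nz = pz + R[2][0]*dx + R[2][1]*dy + R[2][2]*dz;
      tx[i] = nx; ty[i] = ny; tz[i] = nz;
      for (int j = 0; j < p; ++j) {
        double ddx = nx-x[j], ddy = ny-y[j], ddz = nz-z[j];
        double r2n = ddx*ddx + ddy*ddy + ddz*ddz;
        if (r2n < cut2) dU += wca(r2n);
        ddx = x[i]-x[j]; ddy = y[i]-y[j]; ddz = z[i]-z[j];
        double r2o = ddx*ddx + ddy*ddy + ddz*ddz;
        if (r2o < cut2) dU -= wca(r2o);
      }
    }
    if (dU <= 0.0 || rng.unif() < std::exp(-dU / kBT)) {
      for (int i = p + 1; i < N; ++i) { x[i]=tx[i]; y[i]=ty[i]; z[i]=tz[i]; }
      ++accepted;
    }
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i) { out(i,0)=x[i]; out(i,1)=y[i]; out(i,2)=z[i]; }
  return List::create(_["positions"] = out, _["accepted"] = accepted);
}
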