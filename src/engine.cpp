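// Solvent-free coarse-grained MD core: velocity-Verlet integration with a
// Nose-Hoover chain thermostat and the three-site lipid pair interactions
// (WCA repulsion, smoothstep hydrophobic cohesion, shifted 12-6
// protein-head attraction) plus harmonic bond/straightening springs.
//
// The force kernels use cell decompositions with per-cell packed
// coordinate arrays instead of Verlet pair lists: every inner loop runs
// over contiguous single-precision arrays with branch-free masked
// arithmetic, which lets the compiler vectorise without gather
// instructions.  Cell membership is refreshed only when a site has moved
// more than half the stencil margin; the packed coordinates themselves
// are refreshed every step (O(N)).
//
// Units: length nm, energy kcal/mol, mass 1 per site, kB in kcal/mol/K.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <chrono>

#ifdef __GNUC__
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

using namespace Rcpp;

// ---- vectorisable pair blocks --------------------------------------
// One row (site a) against a contiguous slot range [b0, b1).  All
// selects are flat so the compiler turns the loop into masked SIMD; a
// tiny additive epsilon keeps r2 > 0 so the discarded lanes stay finite
// until blended away.  NEWTON controls whether reaction forces are
// written to the packed arrays.

template <bool NEWTON, bool WITH_E>
static inline void coh_block(const float *RESTRICT px, const float *RESTRICT py,
                             const float *RESTRICT pz, const int *RESTRICT plip,
                             float *RESTRICT pfx, float *RESTRICT pfy,
                             float *RESTRICT pfz,
                             float xa, float ya, float za, int la,
                             int b0, int b1,
                             float eps, float rmin, float rc2,
                             float eps_att, float inv_w2,
                             float Lxf, float Lyf, float Lzf,
                             float iLxf, float iLyf, float iLzf,
                             float *RESTRICT out /* fx, fy, fz, e */) {
  float ax = 0.f, ay = 0.f, az = 0.f, ae = 0.f;
  for (int b = b0; b < b1; ++b) {
    // minimum image on top of the cell shifts: a site that crossed the
    // periodic boundary since the last rebin keeps its stale cell, so
    // raw differences can be off by one box length
    float dx = xa - px[b], dy = ya - py[b], dz = za - pz[b];
    dx -= Lxf * std::nearbyintf(dx * iLxf);
    dy -= Lyf * std::nearbyintf(dy * iLyf);
    dz -= Lzf * std::nearbyintf(dz * iLzf);
    float r2 = dx * dx + dy * dy + dz * dz + 1e-6f;
    float ir = 1.0f / std::sqrt(r2);
    float r = r2 * ir;
    float grep = eps * (rmin * ir - 1.0f); // -dV/dr / r of the harmonic core
    float u = (rc2 - r2) * inv_w2;
    float gatt = -12.0f * eps_att * u * (1.0f - u) * inv_w2;
    float g = (r < rmin) ? grep : gatt;
    g = (r2 < rc2) ? g : 0.0f;
    g = (plip[b] != la) ? g : 0.0f;
    g = (r2 > 1e-5f) ? g : 0.0f;
    ax += g * dx; ay += g * dy; az += g * dz;
    if (NEWTON) { pfx[b] -= g * dx; pfy[b] -= g * dy; pfz[b] -= g * dz; }
    if (WITH_E) {
      float dr = r - rmin;
      float erep = 0.5f * eps * dr * dr - eps_att;
      float eatt = -eps_att * u * u * (3.0f - 2.0f * u);
      float ee = (r < rmin) ? erep : eatt;
      ee = (r2 < rc2) ? ee : 0.0f;
      ee = (plip[b] != la) ? ee : 0.0f;
      ee = (r2 > 1e-5f) ? ee : 0.0f;
      ae += ee;
    }
  }
  out[0] += ax; out[1] += ay; out[2] += az;
  if (WITH_E) out[3] += ae;
}

template <bool NEWTON, bool WITH_E>
static inline void wca_block(const float *RESTRICT px, const float *RESTRICT py,
                             const float *RESTRICT pz, const int *RESTRICT plip,
                             const float *RESTRICT psig,
                             float *RESTRICT pfx, float *RESTRICT pfy,
                             float *RESTRICT pfz,
                             float xa, float ya, float za, int la, float sa,
                             int b0, int b1, float eps,
                             float Lxf, float Lyf, float Lzf,
                             float iLxf, float iLyf, float iLzf,
                             float *RESTRICT out) {
  float ax = 0.f, ay = 0.f, az = 0.f, ae = 0.f;
  for (int b = b0; b < b1; ++b) {
    float dx = xa - px[b], dy = ya - py[b], dz = za - pz[b];
    dx -= Lxf * std::nearbyintf(dx * iLxf);
    dy -= Lyf * std::nearbyintf(dy * iLyf);
    dz -= Lzf * std::nearbyintf(dz * iLzf);
    float r2 = dx * dx + dy * dy + dz * dz + 1e-6f;
    float sij = 0.5f * (sa + psig[b]);
    float rmin = 1.12246f * sij; // contact radius of the soft core
    float ir = 1.0f / std::sqrt(r2);
    float r = r2 * ir;
    float g = eps * (rmin * ir - 1.0f);
    g = (r < rmin) ? g : 0.0f;
    g = (plip[b] != la) ? g : 0.0f;
    g = (r2 > 1e-5f) ? g : 0.0f;
    ax += g * dx; ay += g * dy; az += g * dz;
    if (NEWTON) { pfx[b] -= g * dx; pfy[b] -= g * dy; pfz[b] -= g * dz; }
    if (WITH_E) {
      float dr = r - rmin;
      float ee = 0.5f * eps * dr * dr;
      ee = (r < rmin) ? ee : 0.0f;
      ee = (plip[b] != la) ? ee : 0.0f;
      ee = (r2 > 1e-5f) ? ee : 0.0f;
      ae += ee;
    }
  }
  out[0] += ax; out[1] += ay; out[2] += az;
  if (WITH_E) out[3] += ae;
}

template <bool WITH_E>
static inline void lj_block(const float *RESTRICT px, const float *RESTRICT py,
                            const float *RESTRICT pz,
                            float xa, float ya, float za,
                            int b0, int b1,
                            float eps, float sig2, float rc2, float eshift,
                            float Lxf, float Lyf, float Lzf,
                            float iLxf, float iLyf, float iLzf,
                            float *RESTRICT out) {
  float ax = 0.f, ay = 0.f, az = 0.f, ae = 0.f;
  for (int b = b0; b < b1; ++b) {
    float dx = xa - px[b], dy = ya - py[b], dz = za - pz[b];
    dx -= Lxf * std::nearbyintf(dx * iLxf);
    dy -= Lyf * std::nearbyintf(dy * iLyf);
    dz -= Lzf * std::nearbyintf(dz * iLzf);
    float r2 = dx * dx + dy * dy + dz * dz + 1e-8f;
    float rcap2 = 0.81f * sig2; // force cap below 0.9 sigma
    float r2e = (r2 > rcap2) ? r2 : rcap2;
    float ir2 = 1.0f / r2e;
    float sr2 = sig2 * ir2, sr6 = sr2 * sr2 * sr2;
    float g = 24.0f * eps * sr6 * (2.0f * sr6 - 1.0f) * ir2;
    g = (r2 < rc2) ? g : 0.0f;
    ax += g * dx; ay += g * dy; az += g * dz;
    if (WITH_E) {
      // inside the cap the potential continues linearly in r
      float ee = 4.0f * eps * (sr6 * sr6 - sr6) - eshift;
      float rcap = 0.9f * std::sqrt(sig2);
      float fcap = 24.0f * eps * sr6 * (2.0f * sr6 - 1.0f) / rcap;
      float r = std::sqrt(r2);
      float eecap = ee + fcap * (rcap - r);
      ae += (r2 < rc2) ? ((r2 > rcap2) ? ee : eecap) : 0.0f;
    }
  }
  out[0] += ax; out[1] += ay; out[2] += az;
  if (WITH_E) out[3] += ae;
}


// form 1: harmonic soft core (repulsive only); form 2: soft core plus the
// smoothstep cohesive well; form 3: 12-6 LJ, energy-shifted at the cutoff
// and force-capped below 0.9 sigma so scaffold contacts stay integrable
enum PairForm { PAIR_NONE = 0, PAIR_SOFT = 1, PAIR_SOFT_ATT = 2, PAIR_LJ_SHIFT = 3 };

// parameters of one interaction channel
struct Chan {
  float eps, sig2, rmin2, rc2, eps_att, inv_w2, eshift;
  bool active;
};

// a cell decomposition over a subset of sites with packed per-slot arrays
struct CellGrid {
  int nm = 0, ncx = 1, ncy = 1, ncz = 1, ncells = 1;
  double cwx = 0, cwy = 0, cwz = 0;
  std::vector<int> order, cstart;        // slot -> site; CSR cell starts
  std::vector<float> px, py, pz, psig;   // packed coords / head sigma
  std::vector<int> plip;                 // packed lipid id
  std::vector<float> pfx, pfy, pfz;      // packed force accumulators
};

struct Engine {
  int n;
  std::vector<double> x, y, z, vx, vy, vz;
  std::vector<float> xf, yf, zf, fxf, fyf, fzf;
  std::vector<int> type, frozen, lipid;
  std::vector<float> sig_site;           // per-site bead sigma
  double Lx, Ly, Lz;
  double skin;
  double rc_hb, rc_hh; // capture radii for the head WCA kernels
  double cellA_frac = 1.0; // hydrophobic cell size as a fraction of capture radius
  Chan att;        // hydrophobic-hydrophobic (WCA core + smooth well)
  Chan wca_hh;     // head-head WCA (sigma from psig combining)
  Chan wca_hb;     // head-hydrophobic WCA
  Chan lj_ph;      // protein-head 12-6, energy-shifted
  CellGrid Ghyd, Ghead, Gprot;
  std::vector<double> x0, y0, z0;        // positions at last rebin
  std::vector<int> bi, bj;
  std::vector<double> bk, br0;
  static const int M = 3;
  double xi[M], vxi[M];
  int nmobile, nf;
  double pe;

  inline double wrap(double v, double L) const {
    v -= L * std::floor(v / L);
    if (v >= L) v -= L;
    return v;
  }
  inline double mi(double d, double L) const {
    if (d > 0.5 * L) d -= L; else if (d < -0.5 * L) d += L;
    return d;
  }

  void sync_float() {
    for (int i = 0; i < n; ++i) {
      xf[i] = (float)x[i]; yf[i] = (float)y[i]; zf[i] = (float)z[i];
    }
  }

  void bin_grid(CellGrid &G, const std::vector<int> &members, double cell_t) {
    const int nm = (int)members.size();
    G.nm = nm;
    G.ncx = std::max(1, (int)std::floor(Lx / cell_t));
    G.ncy = std::max(1, (int)std::floor(Ly / cell_t));
    G.ncz = std::max(1, (int)std::floor(Lz / cell_t));
    G.ncells = G.ncx * G.ncy * G.ncz;
    G.cwx = Lx / G.ncx; G.cwy = Ly / G.ncy; G.cwz = Lz / G.ncz;
    G.order.resize(nm);
    G.cstart.assign(G.ncells + 1, 0);
    std::vector<int> cidx(nm);
    double ix = G.ncx / Lx, iy = G.ncy / Ly, iz = G.ncz / Lz;
    for (int m = 0; m < nm; ++m) {
      int i = members[m];
      int cx = std::max(0, std::min(G.ncx - 1, (int)(x[i] * ix)));
      int cy = std::max(0, std::min(G.ncy - 1, (int)(y[i] * iy)));
      int cz = std::max(0, std::min(G.ncz - 1, (int)(z[i] * iz)));
      int c = (cz * G.ncy + cy) * G.ncx + cx;
      cidx[m] = c; G.cstart[c + 1]++;
    }
    for (int c = 0; c < G.ncells; ++c) G.cstart[c + 1] += G.cstart[c];
    std::vector<int> fill(G.cstart.begin(), G.cstart.end() - 1);
    for (int m = 0; m < nm; ++m) G.order[fill[cidx[m]]++] = members[m];
    G.px.resize(nm); G.py.resize(nm); G.pz.resize(nm);
    G.psig.resize(nm); G.plip.resize(nm);
    G.pfx.assign(nm, 0.0f); G.pfy.assign(nm, 0.0f); G.pfz.assign(nm, 0.0f);
    for (int s = 0; s < nm; ++s) {
      int i = G.order[s];
      G.plip[s] = lipid[i];
      G.psig[s] = sig_site[i];
    }
  }

  void repack(CellGrid &G) {
    const int nm = G.nm;
    const int *RESTRICT ord = G.order.data();
    float *RESTRICT px = G.px.data(), *RESTRICT py = G.py.data(),
          *RESTRICT pz = G.pz.data();
    for (int s = 0; s < nm; ++s) {
      int i = ord[s];
      px[s] = xf[i]; py[s] = yf[i]; pz[s] = zf[i];
    }
    std::memset(G.pfx.data(), 0, nm * sizeof(float));
    std::memset(G.pfy.data(), 0, nm * sizeof(float));
    std::memset(G.pfz.data(), 0, nm * sizeof(float));
  }

  void scatter(const CellGrid &G) {
    for (int s = 0; s < G.nm; ++s) {
      int i = G.order[s];
      fxf[i] += G.pfx[s]; fyf[i] += G.pfy[s]; fzf[i] += G.pfz[s];
    }
  }

  // ---- force kernels ------------------------------------------------
  // cohesive same-grid kernel: WCA core + smoothstep well, same-lipid
  // pairs masked out.  Cross-cell pairs use Newton's third law; in-cell
  // pairs are evaluated directed (both directions), hence the 0.5 energy
  // factor for that part.
  template <bool WITH_E>
  void k_cohesive(CellGrid &G, const Chan &ch, double rc_eff, double &e_out) {
    if (!ch.active || G.nm == 0) return;
    const float eps = ch.eps, rmin = std::sqrt(ch.rmin2),
                rc2 = ch.rc2, eps_att = ch.eps_att, inv_w2 = ch.inv_w2;
    const float Lxf = (float)Lx, Lyf = (float)Ly, Lzf = (float)Lz;
    const float iLxf = 1.0f / Lxf, iLyf = 1.0f / Lyf, iLzf = 1.0f / Lzf;
    const float *RESTRICT px = G.px.data(), *RESTRICT py = G.py.data(),
                *RESTRICT pz = G.pz.data();
    const int *RESTRICT plip = G.plip.data();
    float *RESTRICT pfx = G.pfx.data(), *RESTRICT pfy = G.pfy.data(),
          *RESTRICT pfz = G.pfz.data();
    double ecross = 0.0, eself = 0.0;
    int Rx = (int)std::ceil(rc_eff / G.cwx), Ry = (int)std::ceil(rc_eff / G.cwy),
        Rz = (int)std::ceil(rc_eff / G.cwz);
    bool small = (G.ncx < 2 * Rx + 1) || (G.ncy < 2 * Ry + 1) ||
                 (G.ncz < 2 * Rz + 1);
    if (small) {
      for (int a = 0; a < G.nm; ++a) {
        const float xa = px[a], ya = py[a], za = pz[a];
        const int la = plip[a];
        float ax = 0, ay = 0, az = 0, ae = 0;
        for (int b = 0; b < G.nm; ++b) {
          float dx = xa - px[b], dy = ya - py[b], dz = za - pz[b];
          dx -= Lxf * std::nearbyintf(dx * iLxf);
          dy -= Lyf * std::nearbyintf(dy * iLyf);
          dz -= Lzf * std::nearbyintf(dz * iLzf);
          float r2 = dx * dx + dy * dy + dz * dz + 1e-6f;
          float ir = 1.0f / std::sqrt(r2);
          float r = r2 * ir;
          float grep = eps * (rmin * ir - 1.0f);
          float u = (rc2 - r2) * inv_w2;
          float gatt = -12.0f * eps_att * u * (1.0f - u) * inv_w2;
          float g = (r < rmin) ? grep : gatt;
          g = (r2 < rc2) ? g : 0.0f;
          g = (plip[b] != la) ? g : 0.0f;
          g = (r2 > 1e-5f) ? g : 0.0f;
          ax += g * dx; ay += g * dy; az += g * dz;
          if (WITH_E) {
            float dr = r - rmin;
            float erep = 0.5f * eps * dr * dr - eps_att;
            float eatt = -eps_att * u * u * (3.0f - 2.0f * u);
            float ee = (r < rmin) ? erep : eatt;
            ee = (r2 < rc2) ? ee : 0.0f;
            ee = (plip[b] != la) ? ee : 0.0f;
            ee = (r2 > 1e-5f) ? ee : 0.0f;
            ae += ee;
          }
        }
        pfx[a] += ax; pfy[a] += ay; pfz[a] += az;
        eself += ae;
      }
      e_out += 0.5 * eself;
      return;
    }
    // Row-merged traversal: for each (dy, dz) row of the stencil the
    // x-adjacent cells form contiguous slot ranges (split in at most two
    // segments by the periodic wrap), so inner trips cover ~2Rx+1 cells.
    // The (0, 0) row is swept directed (both orientations; energy halved);
    // rows with dz > 0 or (dz == 0, dy > 0) use Newton's third law.
    struct Seg { int b0, b1; float sx; };
    Seg segs[2];
    auto xsegs = [&](int cy, int cz, int cxc, float sxbase) -> int {
      // contiguous slot segments covering cells cxc-Rx .. cxc+Rx in row
      int lo = cxc - Rx, hi = cxc + Rx;
      int rowbase = (cz * G.ncy + cy) * G.ncx;
      if (lo >= 0 && hi < G.ncx) {
        segs[0] = {G.cstart[rowbase + lo], G.cstart[rowbase + hi + 1], sxbase};
        return 1;
      }
      if (lo < 0) {
        segs[0] = {G.cstart[rowbase + lo + G.ncx], G.cstart[rowbase + G.ncx],
                   sxbase + Lxf};
        segs[1] = {G.cstart[rowbase], G.cstart[rowbase + hi + 1], sxbase};
      } else { // hi >= ncx
        segs[0] = {G.cstart[rowbase + lo], G.cstart[rowbase + G.ncx], sxbase};
        segs[1] = {G.cstart[rowbase], G.cstart[rowbase + hi - G.ncx + 1],
                   sxbase - Lxf};
      }
      return 2;
    };
    for (int czc = 0; czc < G.ncz; ++czc)
      for (int cyc = 0; cyc < G.ncy; ++cyc)
        for (int cxc = 0; cxc < G.ncx; ++cxc) {
          const int c = (czc * G.ncy + cyc) * G.ncx + cxc;
          const int a0 = G.cstart[c], a1 = G.cstart[c + 1];
          if (a0 == a1) continue;
          for (int dz = 0; dz <= Rz; ++dz)
            for (int dy = (dz == 0 ? 0 : -Ry); dy <= Ry; ++dy) {
              // prune rows whose closest approach exceeds the capture radius
              double gy = dy > 0 ? (dy - 1) * G.cwy : (dy < 0 ? (-dy - 1) * G.cwy : 0);
              double gz = dz > 0 ? (dz - 1) * G.cwz : 0;
              if (gy * gy + gz * gz > rc_eff * rc_eff) continue;
              int oy = cyc + dy, oz = czc + dz;
              float sys = 0, szs = 0;
              if (oy < 0) { oy += G.ncy; sys = Lyf; }
              else if (oy >= G.ncy) { oy -= G.ncy; sys = -Lyf; }
              if (oz >= G.ncz) { oz -= G.ncz; szs = -Lzf; }
              const bool selfrow = (dz == 0 && dy == 0);
              const int nseg = xsegs(oy, oz, cxc, 0.0f);
              for (int a = a0; a < a1; ++a) {
                float out[4] = {0, 0, 0, 0};
                for (int sgi = 0; sgi < nseg; ++sgi) {
                  if (selfrow)
                    coh_block<false, WITH_E>(px, py, pz, plip, pfx, pfy, pfz,
                                             px[a] + segs[sgi].sx, py[a] + sys,
                                             pz[a] + szs, plip[a],
                                             segs[sgi].b0, segs[sgi].b1,
                                             eps, rmin, rc2, eps_att, inv_w2,
                                             Lxf, Lyf, Lzf, iLxf, iLyf, iLzf,
                                             out);
                  else
                    coh_block<true, WITH_E>(px, py, pz, plip, pfx, pfy, pfz,
                                            px[a] + segs[sgi].sx, py[a] + sys,
                                            pz[a] + szs, plip[a],
                                            segs[sgi].b0, segs[sgi].b1,
                                            eps, rmin, rc2, eps_att, inv_w2,
                                            Lxf, Lyf, Lzf, iLxf, iLyf, iLzf,
                                            out);
                }
                pfx[a] += out[0]; pfy[a] += out[1]; pfz[a] += out[2];
                if (WITH_E) { if (selfrow) eself += out[3]; else ecross += out[3]; }
              }
            }
        }
    e_out += ecross + 0.5 * eself;
  }

  template <bool WITH_E, bool SAME>
  void k_wca(CellGrid &A, CellGrid &B, const Chan &ch, double rc_eff,
             double &e_out) {
    if (!ch.active || A.nm == 0 || B.nm == 0) return;
    const float eps = ch.eps;
    const float Lxf = (float)Lx, Lyf = (float)Ly, Lzf = (float)Lz;
    const float iLxf = 1.0f / Lxf, iLyf = 1.0f / Lyf, iLzf = 1.0f / Lzf;
    double ecross = 0.0, eself = 0.0;
    for (int acz = 0; acz < A.ncz; ++acz)
      for (int acy = 0; acy < A.ncy; ++acy)
        for (int acx = 0; acx < A.ncx; ++acx) {
          const int ca = (acz * A.ncy + acy) * A.ncx + acx;
          const int a0 = A.cstart[ca], a1 = A.cstart[ca + 1];
          if (a0 == a1) continue;
          int bxlo = (int)std::floor((acx * A.cwx - rc_eff) / B.cwx);
          int bxhi = (int)std::floor(((acx + 1) * A.cwx + rc_eff) / B.cwx);
          int bylo = (int)std::floor((acy * A.cwy - rc_eff) / B.cwy);
          int byhi = (int)std::floor(((acy + 1) * A.cwy + rc_eff) / B.cwy);
          int bzlo = (int)std::floor((acz * A.cwz - rc_eff) / B.cwz);
          int bzhi = (int)std::floor(((acz + 1) * A.cwz + rc_eff) / B.cwz);
          if (bxhi - bxlo + 1 > B.ncx) { bxlo = 0; bxhi = B.ncx - 1; }
          if (byhi - bylo + 1 > B.ncy) { bylo = 0; byhi = B.ncy - 1; }
          if (bzhi - bzlo + 1 > B.ncz) { bzlo = 0; bzhi = B.ncz - 1; }
          for (int oz = bzlo; oz <= bzhi; ++oz) {
            int mz = oz;
            while (mz < 0) mz += B.ncz;
            while (mz >= B.ncz) mz -= B.ncz;
            for (int oy = bylo; oy <= byhi; ++oy) {
              int my = oy;
              while (my < 0) my += B.ncy;
              while (my >= B.ncy) my -= B.ncy;
              for (int ox = bxlo; ox <= bxhi; ++ox) {
                int mx = ox;
                while (mx < 0) mx += B.ncx;
                while (mx >= B.ncx) mx -= B.ncx;
                const int cb = (mz * B.ncy + my) * B.ncx + mx;
                if (SAME && cb < ca) continue; // half coverage for A == B
                const int b0 = B.cstart[cb], b1 = B.cstart[cb + 1];
                if (b0 == b1) continue;
                if (SAME && cb == ca) {
                  // directed in-cell sweep; energy halved below
                  for (int a = a0; a < a1; ++a) {
                    float out[4] = {0, 0, 0, 0};
                    wca_block<false, WITH_E>(
                        B.px.data(), B.py.data(), B.pz.data(),
                        B.plip.data(), B.psig.data(),
                        B.pfx.data(), B.pfy.data(), B.pfz.data(),
                        A.px[a], A.py[a], A.pz[a], A.plip[a], A.psig[a],
                        b0, b1, eps, Lxf, Lyf, Lzf, iLxf, iLyf, iLzf, out);
                    A.pfx[a] += out[0]; A.pfy[a] += out[1]; A.pfz[a] += out[2];
                    if (WITH_E) eself += out[3];
                  }
                } else {
                  for (int a = a0; a < a1; ++a) {
                    float out[4] = {0, 0, 0, 0};
                    wca_block<true, WITH_E>(
                        B.px.data(), B.py.data(), B.pz.data(),
                        B.plip.data(), B.psig.data(),
                        B.pfx.data(), B.pfy.data(), B.pfz.data(),
                        A.px[a], A.py[a], A.pz[a], A.plip[a], A.psig[a],
                        b0, b1, eps, Lxf, Lyf, Lzf, iLxf, iLyf, iLzf, out);
                    A.pfx[a] += out[0]; A.pfy[a] += out[1]; A.pfz[a] += out[2];
                    if (WITH_E) ecross += out[3];
                  }
                }
              }
            }
          }
        }
    e_out += ecross + 0.5 * eself;
  }

  // protein-head LJ: directed from static protein cells onto head sites;
  // forces land on heads only (protein sites are frozen anyway)
  template <bool WITH_E>
  void k_lj(CellGrid &A /* heads */, CellGrid &P, const Chan &ch,
            double rc_eff, double &e_out) {
    if (!ch.active || A.nm == 0 || P.nm == 0) return;
    const float eps = ch.eps, sig2 = ch.sig2, rc2 = ch.rc2, eshift = ch.eshift;
    const float Lxf = (float)Lx, Lyf = (float)Ly, Lzf = (float)Lz;
    const float iLxf = 1.0f / Lxf, iLyf = 1.0f / Lyf, iLzf = 1.0f / Lzf;
    double eacc = 0.0;
    for (int acz = 0; acz < A.ncz; ++acz)
      for (int acy = 0; acy < A.ncy; ++acy)
        for (int acx = 0; acx < A.ncx; ++acx) {
          const int ca = (acz * A.ncy + acy) * A.ncx + acx;
          const int a0 = A.cstart[ca], a1 = A.cstart[ca + 1];
          if (a0 == a1) continue;
          int bxlo = (int)std::floor((acx * A.cwx - rc_eff) / P.cwx);
          int bxhi = (int)std::floor(((acx + 1) * A.cwx + rc_eff) / P.cwx);
          int bylo = (int)std::floor((acy * A.cwy - rc_eff) / P.cwy);
          int byhi = (int)std::floor(((acy + 1) * A.cwy + rc_eff) / P.cwy);
          int bzlo = (int)std::floor((acz * A.cwz - rc_eff) / P.cwz);
          int bzhi = (int)std::floor(((acz + 1) * A.cwz + rc_eff) / P.cwz);
          if (bxhi - bxlo + 1 > P.ncx) { bxlo = 0; bxhi = P.ncx - 1; }
          if (byhi - bylo + 1 > P.ncy) { bylo = 0; byhi = P.ncy - 1; }
          if (bzhi - bzlo + 1 > P.ncz) { bzlo = 0; bzhi = P.ncz - 1; }
          for (int oz = bzlo; oz <= bzhi; ++oz) {
            int mz = oz;
            while (mz < 0) mz += P.ncz;
            while (mz >= P.ncz) mz -= P.ncz;
            for (int oy = bylo; oy <= byhi; ++oy) {
              int my = oy;
              while (my < 0) my += P.ncy;
              while (my >= P.ncy) my -= P.ncy;
              for (int ox = bxlo; ox <= bxhi; ++ox) {
                int mx = ox;
                while (mx < 0) mx += P.ncx;
                while (mx >= P.ncx) mx -= P.ncx;
                const int cb = (mz * P.ncy + my) * P.ncx + mx;
                const int b0 = P.cstart[cb], b1 = P.cstart[cb + 1];
                if (b0 == b1) continue;
                for (int a = a0; a < a1; ++a) {
                  float out[4] = {0, 0, 0, 0};
                  lj_block<WITH_E>(P.px.data(), P.py.data(), P.pz.data(),
                                   A.px[a], A.py[a], A.pz[a], b0, b1,
                                   eps, sig2, rc2, eshift,
                                   Lxf, Lyf, Lzf, iLxf, iLyf, iLzf, out);
                  A.pfx[a] += out[0]; A.pfy[a] += out[1]; A.pfz[a] += out[2];
                  if (WITH_E) eacc += out[3];
                }
              }
            }
          }
        }
    e_out += eacc;
  }

  bool need_rebin() const {
    double half = 0.5 * skin, h2 = half * half;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      double dx = mi(x[i] - x0[i], Lx);
      double dy = mi(y[i] - y0[i], Ly);
      double dz = mi(z[i] - z0[i], Lz);
      if (dx * dx + dy * dy + dz * dz > h2) return true;
    }
    return false;
  }

  void rebin() {
    std::vector<int> hyd, hed;
    hyd.reserve(2 * n / 3); hed.reserve(n / 3);
    for (int i = 0; i < n; ++i) {
      if (type[i] == 2 || type[i] == 3) hyd.push_back(i);
      else if (type[i] <= 1) hed.push_back(i);
    }
    double rcA = std::sqrt((double)att.rc2) + skin;
    bin_grid(Ghyd, hyd, std::max(cellA_frac * rcA, 0.45));
    bin_grid(Ghead, hed, std::max(rc_hb, 0.45));
    x0 = x; y0 = y; z0 = z;
  }

  template <bool WITH_E>
  void forces() {
    sync_float();
    std::memset(fxf.data(), 0, n * sizeof(float));
    std::memset(fyf.data(), 0, n * sizeof(float));
    std::memset(fzf.data(), 0, n * sizeof(float));
    repack(Ghyd);
    repack(Ghead);
    double e = 0.0;
    double rcA = std::sqrt((double)att.rc2) + skin;
    k_cohesive<WITH_E>(Ghyd, att, rcA, e);
    k_wca<WITH_E, false>(Ghead, Ghyd, wca_hb, rc_hb, e);
    k_wca<WITH_E, true>(Ghead, Ghead, wca_hh, rc_hh, e);
    if (lj_ph.active && Gprot.nm > 0) {
      double rcP = std::sqrt((double)lj_ph.rc2) + skin;
      k_lj<WITH_E>(Ghead, Gprot, lj_ph, rcP, e);
    }
    scatter(Ghyd);
    scatter(Ghead);
    // bonded springs (double precision; one sqrt per spring)
    const int nb = (int)bi.size();
    for (int b = 0; b < nb; ++b) {
      int i = bi[b], j = bj[b];
      double dx = mi(x[i] - x[j], Lx);
      double dy = mi(y[i] - y[j], Ly);
      double dz = mi(z[i] - z[j], Lz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - br0[b];
      double g = -bk[b] * dr / r;
      fxf[i] += (float)(g * dx); fyf[i] += (float)(g * dy); fzf[i] += (float)(g * dz);
      fxf[j] -= (float)(g * dx); fyf[j] -= (float)(g * dy); fzf[j] -= (float)(g * dz);
      if (WITH_E) e += 0.5 * bk[b] * dr * dr;
    }
    if (WITH_E) pe = e;
  }

  double kinetic() const {
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    }
    return 0.5 * ke;
  }

  // weak-coupling rescale used for the equilibration ramp; robust to the
  // large potential-energy release of a freshly built lattice.  Single
  // sites are additionally speed-capped: a relaxing bad contact dumps its
  // energy into two sites, and the cap absorbs the release instead of
  // letting a ballistic site punch through the membrane core.
  void berendsen(double dt, double kT, double tau) {
    double ke2 = 2.0 * kinetic();
    if (ke2 <= 0) return;
    double Tcur = ke2 / nf;
    double lam2 = 1.0 + (dt / tau) * (kT / Tcur - 1.0);
    if (lam2 < 0.25) lam2 = 0.25;
    if (lam2 > 4.0) lam2 = 4.0;
    double lam = std::sqrt(lam2);
    double vcap = 3.5 * std::sqrt(3.0 * kT); // ~3.5x rms site speed
    double vcap2 = vcap * vcap;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      vx[i] *= lam; vy[i] *= lam; vz[i] *= lam;
      double v2 = vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      if (v2 > vcap2) {
        double s = vcap / std::sqrt(v2);
        vx[i] *= s; vy[i] *= s; vz[i] *= s;
      }
    }
  }

  void nhc(double dt2, double kT, double tau) {
    double ke2 = 2.0 * kinetic();
    double Q1 = nf * kT * tau * tau;
    double Qk = kT * tau * tau;
    double G[M];
    G[0] = (ke2 - nf * kT) / Q1;
    for (int k = 1; k < M; ++k) {
      double Qp = (k == 1) ? Q1 : Qk;
      G[k] = (Qp * vxi[k - 1] * vxi[k - 1] - kT) / Qk;
    }
    double dt4 = 0.5 * dt2, dt8 = 0.25 * dt2;
    vxi[M - 1] += G[M - 1] * dt4;
    for (int k = M - 2; k >= 0; --k) {
      double s = std::exp(-dt8 * vxi[k + 1]);
      vxi[k] = (vxi[k] * s + G[k] * dt4) * s;
    }
    // bound the chain velocities so a violent transient cannot wind the
    // thermostat up into a state that quenches or boils the system
    for (int k = 0; k < M; ++k) {
      double vcap = 10.0 / tau;
      if (vxi[k] > vcap) vxi[k] = vcap;
      if (vxi[k] < -vcap) vxi[k] = -vcap;
    }
    double scale = std::exp(-dt2 * vxi[0]);
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      vx[i] *= scale; vy[i] *= scale; vz[i] *= scale;
    }
    ke2 *= scale * scale;
    for (int k = 0; k < M; ++k) xi[k] += dt2 * vxi[k];
    G[0] = (ke2 - nf * kT) / Q1;
    for (int k = 0; k < M - 1; ++k) {
      double s = std::exp(-dt8 * vxi[k + 1]);
      vxi[k] = (vxi[k] * s + G[k] * dt4) * s;
      double Qp = (k == 0) ? Q1 : Qk;
      G[k + 1] = (Qp * vxi[k] * vxi[k] - kT) / Qk;
    }
    vxi[M - 1] += G[M - 1] * dt4;
  }
};

// detect an axial window empty of hydrophobic sites (fast in-engine scission
// guard; the rigorous contact-graph detector lives on the R side)
static bool axial_gap(const Engine &E, double width, double *where) {
  const double binw = 0.25;
  int nb = std::max(4, (int)std::floor(E.Lx / binw));
  std::vector<int> occ(nb, 0);
  for (int i = 0; i < E.n; ++i) {
    if (E.type[i] <= 1 || E.frozen[i]) continue; // hydrophobic classes >= 2
    int b = (int)(E.x[i] / E.Lx * nb);
    if (b >= nb) b = nb - 1; if (b < 0) b = 0;
    occ[b]++;
  }
  int need = (int)std::ceil(width / (E.Lx / nb));
  int run = 0, best = 0, pos = -1;
  for (int b = 0; b < 2 * nb; ++b) {
    if (occ[b % nb] == 0) { run++; if (run > best) { best = run; pos = b % nb; } }
    else run = 0;
    if (run >= need) break;
  }
  if (best >= need) {
    *where = (pos + 0.5) * (E.Lx / nb);
    return true;
  }
  return false;
}

static Engine make_engine(List sys, List ff) {
  Engine E;
  NumericMatrix pos = sys["pos"], vel = sys["vel"];
  IntegerVector type = sys["type_id"], frozen = sys["frozen_i"], lipid = sys["lipid_i"];
  NumericVector box = sys["box"];
  NumericMatrix bonds = sys["bond_tab"];
  E.n = pos.nrow();
  E.x.resize(E.n); E.y.resize(E.n); E.z.resize(E.n);
  E.vx.resize(E.n); E.vy.resize(E.n); E.vz.resize(E.n);
  E.xf.resize(E.n); E.yf.resize(E.n); E.zf.resize(E.n);
  E.fxf.resize(E.n); E.fyf.resize(E.n); E.fzf.resize(E.n);
  E.type.assign(type.begin(), type.end());
  E.frozen.assign(frozen.begin(), frozen.end());
  E.lipid.assign(lipid.begin(), lipid.end());
  E.Lx = box[0]; E.Ly = box[1]; E.Lz = box[2];
  for (int i = 0; i < E.n; ++i) {
    E.x[i] = E.wrap(pos(i, 0), E.Lx);
    E.y[i] = E.wrap(pos(i, 1), E.Ly);
    E.z[i] = E.wrap(pos(i, 2), E.Lz);
    E.vx[i] = vel(i, 0); E.vy[i] = vel(i, 1); E.vz[i] = vel(i, 2);
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    E.bi.push_back((int)bonds(b, 0)); E.bj.push_back((int)bonds(b, 1));
    E.bk.push_back(bonds(b, 2)); E.br0.push_back(bonds(b, 3));
  }
  // interaction channels from the 5x5 pair table (types: head_pc,
  // head_ps, body, tail, protein)
  IntegerVector form = ff["form"];
  NumericVector eps = ff["eps"], sig2 = ff["sig2"], rmin2 = ff["rmin2"],
                rc2 = ff["rc2"], eps_att = ff["eps_att"], eshift = ff["eshift"];
  int nt = (int)std::lround(std::sqrt((double)form.size()));
  auto chan = [&](int a, int c) {
    Chan ch;
    int k = a * nt + c;
    ch.active = form[k] != PAIR_NONE;
    ch.eps = (float)eps[k]; ch.sig2 = (float)sig2[k];
    ch.rmin2 = (float)rmin2[k]; ch.rc2 = (float)rc2[k];
    ch.eps_att = (float)eps_att[k]; ch.eshift = (float)eshift[k];
    ch.inv_w2 = (rc2[k] > rmin2[k]) ? (float)(1.0 / (rc2[k] - rmin2[k])) : 0.0f;
    return ch;
  };
  E.att = chan(3, 3);      // hydrophobic channel (body/tail classes share it)
  E.wca_hh = chan(0, 0);   // head-head (per-site sigma combining)
  E.wca_hb = chan(0, 3);   // head-hydrophobic
  E.lj_ph = chan(0, 4);    // protein-head
  E.skin = as<double>(ff["skin"]);
  // per-site bead sigma (head scale, PS hook)
  NumericVector bead_sig = ff["bead_sigma"]; // length nt
  E.sig_site.resize(E.n);
  for (int i = 0; i < E.n; ++i) E.sig_site[i] = (float)bead_sig[E.type[i]];
  double sig_head_max = std::max(bead_sig[0], bead_sig[1]);
  double sig_hyd = std::max(bead_sig[2], bead_sig[3]);
  E.rc_hh = std::pow(2.0, 1.0 / 6.0) * sig_head_max + E.skin;
  E.rc_hb = std::pow(2.0, 1.0 / 6.0) * 0.5 * (sig_head_max + sig_hyd) + E.skin;
  if (ff.containsElementNamed("cell_frac"))
    E.cellA_frac = as<double>(ff["cell_frac"]);
  // grids
  E.rebin();
  std::vector<int> prot;
  for (int i = 0; i < E.n; ++i) if (E.type[i] == 4) prot.push_back(i);
  if (!prot.empty()) {
    double rcP = std::sqrt((double)E.lj_ph.rc2) + E.skin;
    E.bin_grid(E.Gprot, prot, std::max(rcP, 0.5));
    E.repack(E.Gprot);
  }
  E.nmobile = 0;
  for (int i = 0; i < E.n; ++i) if (!E.frozen[i]) E.nmobile++;
  E.nf = 3 * E.nmobile;
  for (int k = 0; k < Engine::M; ++k) { E.xi[k] = 0.0; E.vxi[k] = 0.0; }
  return E;
}

// [[Rcpp::export(name = ".cg_md_run")]]
List cg_md_run(List sys, List ff, List ctl) {
  Engine E = make_engine(sys, ff);
  const double dt = as<double>(ctl["dt"]);
  const int nsteps = as<int>(ctl["n_steps"]);
  const int dump_every = as<int>(ctl["dump_every"]);
  const double kB = as<double>(ctl["kB"]);
  const double T0 = as<double>(ctl["T_start"]);
  const double T1 = as<double>(ctl["T_end"]);
  const double tau = as<double>(ctl["damping"]);
  // 0 = none (NVE), 1 = Nose-Hoover chain, 2 = Berendsen rescale (ramp)
  const int thermo = as<int>(ctl["thermostat"]);
  const bool stop_gap = as<bool>(ctl["stop_on_gap"]);
  const double gapw = as<double>(ctl["gap_width"]);
  const int check_every = as<int>(ctl["check_every"]);
  const double vguard = as<double>(ctl["velocity_guard"]);
  const bool force_rebin = ctl.containsElementNamed("force_rebin") ?
    as<bool>(ctl["force_rebin"]) : false;

  if (ctl.containsElementNamed("chain")) {
    NumericVector ch = ctl["chain"];
    if (ch.size() == 2 * Engine::M)
      for (int k = 0; k < Engine::M; ++k) { E.xi[k] = ch[k]; E.vxi[k] = ch[Engine::M + k]; }
  }

  E.forces<true>();
  long n_rebins = 0;
  double t_build = 0, t_force = 0, t_other = 0;
  auto clk = []() { return std::chrono::steady_clock::now(); };
  auto since = [](std::chrono::steady_clock::time_point a,
                  std::chrono::steady_clock::time_point b) {
    return std::chrono::duration<double>(b - a).count();
  };
  auto tp0 = clk();

  int nsnap = (dump_every > 0) ? nsteps / dump_every : 0;
  List snaps(nsnap);
  IntegerVector snap_step(nsnap);
  NumericVector snap_T(nsnap), snap_pe(nsnap);
  int isnap = 0;
  bool stopped = false; int stop_step = -1; double gap_x = NA_REAL;
  bool diverged = false;

  for (int s = 1; s <= nsteps; ++s) {
    double Tt = (nsteps > 1) ? T0 + (T1 - T0) * ((double)s / nsteps) : T1;
    double kT = kB * Tt;
    if (thermo == 1) E.nhc(0.5 * dt, kT, tau);
    else if (thermo == 2) E.berendsen(dt, kT, tau);
    for (int i = 0; i < E.n; ++i) {
      if (E.frozen[i]) continue;
      E.vx[i] += 0.5 * dt * E.fxf[i];
      E.vy[i] += 0.5 * dt * E.fyf[i];
      E.vz[i] += 0.5 * dt * E.fzf[i];
      E.x[i] = E.wrap(E.x[i] + dt * E.vx[i], E.Lx);
      E.y[i] = E.wrap(E.y[i] + dt * E.vy[i], E.Ly);
      E.z[i] = E.wrap(E.z[i] + dt * E.vz[i], E.Lz);
    }
    if (force_rebin || E.need_rebin()) {
      auto tb = clk(); t_other += since(tp0, tb);
      E.rebin();
      tp0 = clk(); t_build += since(tb, tp0);
      n_rebins++;
    }
    bool dump = (dump_every > 0) && (s % dump_every == 0);
    { auto tf = clk(); t_other += since(tp0, tf);
      if (dump) E.forces<true>(); else E.forces<false>();
      tp0 = clk(); t_force += since(tf, tp0); }
    for (int i = 0; i < E.n; ++i) {
      if (E.frozen[i]) continue;
      E.vx[i] += 0.5 * dt * E.fxf[i];
      E.vy[i] += 0.5 * dt * E.fyf[i];
      E.vz[i] += 0.5 * dt * E.fzf[i];
    }
    if (thermo == 1) E.nhc(0.5 * dt, kT, tau);

    if (dump) {
      NumericMatrix sp(E.n, 3);
      for (int i = 0; i < E.n; ++i) { sp(i, 0) = E.x[i]; sp(i, 1) = E.y[i]; sp(i, 2) = E.z[i]; }
      snaps[isnap] = sp;
      snap_step[isnap] = s;
      snap_T[isnap] = 2.0 * E.kinetic() / (E.nf * kB);
      snap_pe[isnap] = E.pe;
      isnap++;
      double vmax2 = 0.0;
      for (int i = 0; i < E.n; ++i) {
        double v2 = E.vx[i] * E.vx[i] + E.vy[i] * E.vy[i] + E.vz[i] * E.vz[i];
        if (v2 > vmax2) vmax2 = v2;
      }
      if (vmax2 > vguard * vguard) { diverged = true; stop_step = s; break; }
    }
    if (stop_gap && check_every > 0 && (s % check_every == 0)) {
      double where;
      if (axial_gap(E, gapw, &where)) {
        stopped = true; stop_step = s; gap_x = where; break;
      }
    }
  }

  if (isnap < nsnap) {
    if (isnap == 0) {
      snaps = List(0);
      snap_step = IntegerVector(0);
      snap_T = NumericVector(0);
      snap_pe = NumericVector(0);
    } else {
      snaps = snaps[Range(0, isnap - 1)];
      snap_step = head(snap_step, isnap);
      snap_T = head(snap_T, isnap);
      snap_pe = head(snap_pe, isnap);
    }
  }

  NumericMatrix pos(E.n, 3), vel(E.n, 3);
  for (int i = 0; i < E.n; ++i) {
    pos(i, 0) = E.x[i]; pos(i, 1) = E.y[i]; pos(i, 2) = E.z[i];
    vel(i, 0) = E.vx[i]; vel(i, 1) = E.vy[i]; vel(i, 2) = E.vz[i];
  }
  NumericVector chain(2 * Engine::M);
  for (int k = 0; k < Engine::M; ++k) { chain[k] = E.xi[k]; chain[Engine::M + k] = E.vxi[k]; }
  E.forces<true>();
  return List::create(
    _["pos"] = pos, _["vel"] = vel, _["chain"] = chain,
    _["snapshots"] = snaps, _["snap_step"] = snap_step,
    _["snap_T"] = snap_T, _["snap_pe"] = snap_pe,
    _["pe"] = E.pe, _["T_kin"] = 2.0 * E.kinetic() / (E.nf * kB),
    _["stopped_on_gap"] = stopped, _["diverged"] = diverged,
    _["stop_step"] = stop_step, _["gap_x"] = gap_x,
    _["n_rebuilds"] = (double)n_rebins,
    _["t_build"] = t_build, _["t_force"] = t_force, _["t_other"] = t_other);
}

// displacement-capped steepest descent, used to relax built lattices
// before the thermalisation ramp
// [[Rcpp::export(name = ".cg_minimize")]]
List cg_minimize(List sys, List ff, int n_iter, double dmax) {
  Engine E = make_engine(sys, ff);
  double alpha = 5e-4;
  NumericVector pe_trace(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    E.forces<true>();
    pe_trace[it] = E.pe;
    for (int i = 0; i < E.n; ++i) {
      if (E.frozen[i]) continue;
      double fx = E.fxf[i], fy = E.fyf[i], fz = E.fzf[i];
      double fm = std::sqrt(fx * fx + fy * fy + fz * fz);
      double s = (fm > 1e-12) ? std::min(alpha * fm, dmax) / fm : 0.0;
      if (!std::isfinite(s)) s = 0.0;
      E.x[i] = E.wrap(E.x[i] + s * fx, E.Lx);
      E.y[i] = E.wrap(E.y[i] + s * fy, E.Ly);
      E.z[i] = E.wrap(E.z[i] + s * fz, E.Lz);
    }
    if (E.need_rebin()) E.rebin();
  }
  E.forces<true>();
  NumericMatrix pos(E.n, 3);
  for (int i = 0; i < E.n; ++i) {
    pos(i, 0) = E.x[i]; pos(i, 1) = E.y[i]; pos(i, 2) = E.z[i];
  }
  return List::create(_["pos"] = pos, _["pe"] = E.pe, _["pe_trace"] = pe_trace);
}

// single-point energy/force for one pair interaction (double precision);
// used by the R-level potential functions and consistency tests
// [[Rcpp::export(name = ".cg_pair_eval")]]
NumericMatrix cg_pair_eval(NumericVector r, int form, double eps, double sig2,
                           double rmin2, double rc2, double eps_att,
                           double eshift) {
  double inv_w2 = (rc2 > rmin2) ? 1.0 / (rc2 - rmin2) : 0.0;
  double rmin = std::sqrt(rmin2);
  NumericMatrix out(r.size(), 2); // energy, radial force (-dV/dr)
  for (int q = 0; q < r.size(); ++q) {
    double r2 = r[q] * r[q];
    double e = 0.0, g = 0.0; // g: -dV/dr / r
    if (r2 < rc2) {
      switch (form) {
      case PAIR_SOFT:
        if (r[q] < rmin) {
          g = eps * (rmin / r[q] - 1.0);
          e = 0.5 * eps * (r[q] - rmin) * (r[q] - rmin);
        }
        break;
      case PAIR_SOFT_ATT:
        if (r[q] < rmin) {
          g = eps * (rmin / r[q] - 1.0);
          e = 0.5 * eps * (r[q] - rmin) * (r[q] - rmin) - eps_att;
        } else {
          double u = (rc2 - r2) * inv_w2;
          g = -12.0 * eps_att * u * (1.0 - u) * inv_w2;
          e = -eps_att * u * u * (3.0 - 2.0 * u);
        }
        break;
      case PAIR_LJ_SHIFT: {
        double rcap = 0.9 * std::sqrt(sig2);
        double rr = std::max(r[q], rcap);
        double sr2 = sig2 / (rr * rr), sr6 = sr2 * sr2 * sr2;
        g = 24.0 * eps * sr6 * (2.0 * sr6 - 1.0) / (rr * rr);
        e = 4.0 * eps * (sr6 * sr6 - sr6) - eshift;
        if (r[q] < rcap) {
          double fcap = g * rr;
          e += fcap * (rcap - r[q]);
          g = fcap / r[q];
        }
        break;
      }
      default: break;
      }
    }
    out(q, 0) = e;
    out(q, 1) = g * r[q];
  }
  return out;
}

// potential energy of a configuration (tests / analysis)
// [[Rcpp::export(name = ".cg_energy")]]
double cg_energy(List sys, List ff) {
  Engine E = make_engine(sys, ff);
  E.forces<true>();
  return E.pe;
}

// forces on every site for a configuration (consistency tests)
// [[Rcpp::export(name = ".cg_forces")]]
NumericMatrix cg_forces(List sys, List ff) {
  Engine E = make_engine(sys, ff);
  E.forces<true>();
  NumericMatrix f(E.n, 3);
  for (int i = 0; i < E.n; ++i) {
    f(i, 0) = E.fxf[i]; f(i, 1) = E.fyf[i]; f(i, 2) = E.fzf[i];
  }
  return f;
}

// minimum distance between sites of different lipids (and protein sites);
// separations above 1.5 nm are reported as 1.5 (cell-limited search)
// [[Rcpp::export(name = ".cg_min_dist")]]
double cg_min_dist(NumericMatrix pos, IntegerVector lipid, NumericVector box) {
  int n = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  auto wrapc = [](double v, double L) {
    v -= L * std::floor(v / L);
    if (v >= L) v -= L;
    return v;
  };
  auto mi = [](double d, double L) {
    if (d > 0.5 * L) d -= L; else if (d < -0.5 * L) d += L;
    return d;
  };
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) {
    X[i] = wrapc(pos(i, 0), Lx); Y[i] = wrapc(pos(i, 1), Ly);
    Z[i] = wrapc(pos(i, 2), Lz);
  }
  double best = 1.5 * 1.5;
  if (n <= 600) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (lipid[i] != NA_INTEGER && lipid[i] == lipid[j]) continue;
        double dx = mi(X[i] - X[j], Lx), dy = mi(Y[i] - Y[j], Ly),
               dz = mi(Z[i] - Z[j], Lz);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < best) best = r2;
      }
    return std::sqrt(best);
  }
  double cell = 1.5;
  int ncx = std::max(3, (int)(Lx / cell));
  int ncy = std::max(3, (int)(Ly / cell));
  int ncz = std::max(3, (int)(Lz / cell));
  std::vector<int> head(ncx * ncy * ncz, -1), nxt(n, -1);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncx - 1, (int)(X[i] / Lx * ncx));
    int cy = std::min(ncy - 1, (int)(Y[i] / Ly * ncy));
    int cz = std::min(ncz - 1, (int)(Z[i] / Lz * ncz));
    int c = (cz * ncy + cy) * ncx + cx;
    nxt[i] = head[c]; head[c] = i;
  }
  for (int cz = 0; cz < ncz; ++cz)
    for (int cy = 0; cy < ncy; ++cy)
      for (int cx = 0; cx < ncx; ++cx) {
        int c = (cz * ncy + cy) * ncx + cx;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int c2 = (((cz + dz + ncz) % ncz) * ncy + (cy + dy + ncy) % ncy) * ncx +
                       (cx + dx + ncx) % ncx;
              for (int i = head[c]; i >= 0; i = nxt[i]) {
                for (int j = head[c2]; j >= 0; j = nxt[j]) {
                  if (j <= i) continue;
                  if (lipid[i] != NA_INTEGER && lipid[i] == lipid[j]) continue;
                  double ddx = mi(X[i] - X[j], Lx);
                  double ddy = mi(Y[i] - Y[j], Ly);
                  double ddz = mi(Z[i] - Z[j], Lz);
                  double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
                  if (r2 < best) best = r2;
                }
              }
            }
      }
  return std::sqrt(best);
}
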