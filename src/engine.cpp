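// Core numerical engine: energies, analytic forces/torques, discrete
// writhe/twist bookkeeping and the overdamped Euler-Maruyama integrator.
//
// Geometry conventions (0-based):
//   * beads of ring r occupy a contiguous index block [start, start+n).
//   * edge i runs from bead i to its ring successor; closed rings have one
//     edge per bead, open chains have none for the last bead.
//   * junction i sits at vertex i between edge (i-1) and edge i; its twist
//     angle phi_i is the rotation from the parallel-transported frame of
//     edge (i-1) to the frame of edge i, measured about the new tangent.
// With transport-measured twist and the exact Gauss double-sum writhe,
// Lk = Tw + Wr holds as a discrete identity, so topology is conserved to
// measurement precision unless segments cross.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925287;

// ---------------------------------------------------------------- small vec

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, const V3& a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }
static inline V3 hat(const V3& a) {
  double n = norm(a);
  return V3(a.x / n, a.y / n, a.z / n);
}

// rotate v about unit axis by angle (Rodrigues)
static inline V3 rot_about(const V3& v, const V3& axis, double ang) {
  double c = std::cos(ang), s = std::sin(ang);
  return c * v + s * cross(axis, v) + (dot(axis, v) * (1.0 - c)) * axis;
}

// parallel transport: rotate v by the rotation taking unit a to unit b
// (Rodrigues with the rotation's cos/sin taken directly from a.b, |a x b|)
static inline V3 transport(const V3& v, const V3& a, const V3& b) {
  V3 ax = cross(a, b);
  double s = norm(ax), c = dot(a, b);
  if (s < 1e-14) {
    if (c > 0.0) return v;               // parallel: identity
    stop("parallel transport undefined for antiparallel tangents");
  }
  V3 u = (1.0 / s) * ax;
  return c * v + s * cross(u, v) + (dot(u, v) * (1.0 - c)) * u;
}

// ------------------------------------------------------------------ system

struct Ring {
  int start, n;
  bool closed;
};

struct FF {
  double k_bond, r0;
  double k_bend;
  double k_dih, phi0;
  double eps_ev, sigma_ev, rcut_ev;   // WCA-style purely repulsive term
  double aff_sigma, aff_rcut;
  std::vector<int> aff_a, aff_b;
  std::vector<double> aff_eps;
  std::vector<int> xb_a, xb_b;        // extra (tether) bonds
  std::vector<double> xb_k, xb_r0;
  double box;                          // <= 0: unbounded
};

struct Sys {
  std::vector<V3> x;     // positions (unwrapped)
  std::vector<V3> f;     // per-edge material frames (unit, perp to tangent)
  std::vector<Ring> rings;
  std::vector<int> ring_of, local_of;
  int n() const { return (int)x.size(); }
  // successor bead along the ring, -1 at an open end
  int succ(int i) const {
    const Ring& r = rings[ring_of[i]];
    int l = local_of[i];
    if (l == r.n - 1) return r.closed ? r.start : -1;
    return i + 1;
  }
  int pred(int i) const {
    const Ring& r = rings[ring_of[i]];
    int l = local_of[i];
    if (l == 0) return r.closed ? (r.start + r.n - 1) : -1;
    return i - 1;
  }
  bool has_edge(int i) const { return succ(i) >= 0; }
};

static inline V3 mimg(V3 d, double box) {
  if (box > 0) {
    d.x -= box * std::nearbyint(d.x / box);
    d.y -= box * std::nearbyint(d.y / box);
    d.z -= box * std::nearbyint(d.z / box);
  }
  return d;
}

static Sys make_sys(const NumericMatrix& pos, const NumericMatrix& frm,
                    const IntegerMatrix& rings) {
  Sys s;
  int n = pos.nrow();
  s.x.resize(n);
  s.f.resize(n);
  for (int i = 0; i < n; ++i) {
    s.x[i] = V3(pos(i, 0), pos(i, 1), pos(i, 2));
    s.f[i] = V3(frm(i, 0), frm(i, 1), frm(i, 2));
  }
  s.ring_of.assign(n, -1);
  s.local_of.assign(n, -1);
  for (int r = 0; r < rings.nrow(); ++r) {
    Ring rg;
    rg.start = rings(r, 0);
    rg.n = rings(r, 1);
    rg.closed = rings(r, 2) != 0;
    s.rings.push_back(rg);
    for (int l = 0; l < rg.n; ++l) {
      s.ring_of[rg.start + l] = r;
      s.local_of[rg.start + l] = l;
    }
  }
  return s;
}

static FF make_ff(const List& ff) {
  FF p;
  p.k_bond = as<double>(ff["k_bond"]);
  p.r0 = as<double>(ff["rest_length"]);
  p.k_bend = as<double>(ff["k_bend"]);
  p.k_dih = as<double>(ff["k_dihedral"]);
  p.phi0 = as<double>(ff["phi0"]);
  p.eps_ev = as<double>(ff["eps_ev"]);
  p.sigma_ev = as<double>(ff["sigma_ev"]);
  p.rcut_ev = p.sigma_ev * std::pow(2.0, 1.0 / 6.0);
  p.aff_sigma = as<double>(ff["sigma_lj"]);
  p.aff_rcut = as<double>(ff["r_cut"]);
  IntegerMatrix ap = as<IntegerMatrix>(ff["aff_pairs"]);
  NumericVector ae = as<NumericVector>(ff["aff_eps"]);
  for (int k = 0; k < ap.nrow(); ++k) {
    p.aff_a.push_back(ap(k, 0));
    p.aff_b.push_back(ap(k, 1));
    p.aff_eps.push_back(ae[k]);
  }
  IntegerMatrix xb = as<IntegerMatrix>(ff["extra_bonds"]);
  NumericVector xk = as<NumericVector>(ff["extra_k"]);
  NumericVector xr = as<NumericVector>(ff["extra_r0"]);
  for (int k = 0; k < xb.nrow(); ++k) {
    p.xb_a.push_back(xb(k, 0));
    p.xb_b.push_back(xb(k, 1));
    p.xb_k.push_back(xk[k]);
    p.xb_r0.push_back(xr[k]);
  }
  p.box = as<double>(ff["box"]);
  return p;
}

// ------------------------------------------------------------------- twist

// twist angle at junction v (vertex with both a predecessor edge and an
// outgoing edge); returns in (-pi, pi]
static double junction_phi(const Sys& s, int v) {
  int p = s.pred(v);
  int nv = s.succ(v);
  if (p < 0 || nv < 0) stop("junction does not exist at an open end");
  V3 e0 = s.x[v] - s.x[p];
  V3 e1 = s.x[nv] - s.x[v];
  double l0 = norm(e0), l1 = norm(e1);
  if (l0 < 1e-12 || l1 < 1e-12) stop("degenerate (zero-length) segment");
  V3 t0 = (1.0 / l0) * e0, t1 = (1.0 / l1) * e1;
  V3 fp = transport(s.f[p], t0, t1);
  const V3& fc = s.f[v];
  return std::atan2(dot(cross(fp, fc), t1), dot(fp, fc));
}

// twist angle using cached unit tangents (t[i] = tangent of edge i)
static inline double junction_phi_t(const Sys& s, int v,
                                    const std::vector<V3>& tang) {
  int p = s.pred(v);
  const V3& t0 = tang[p];
  const V3& t1 = tang[v];
  V3 fp = transport(s.f[p], t0, t1);
  const V3& fc = s.f[v];
  return std::atan2(dot(cross(fp, fc), t1), dot(fp, fc));
}

static void edge_tangents(const Sys& s, std::vector<V3>& tang,
                          std::vector<double>& len) {
  int n = s.n();
  tang.assign(n, V3(1, 0, 0));
  len.assign(n, 1.0);
  for (int i = 0; i < n; ++i) {
    int j = s.succ(i);
    if (j < 0) continue;
    V3 e = s.x[j] - s.x[i];
    double l = norm(e);
    if (l < 1e-12) stop("degenerate (zero-length) segment");
    tang[i] = (1.0 / l) * e;
    len[i] = l;
  }
}

// collect junction vertices of a ring (all for closed, interior for open)
static void ring_junctions(const Sys& s, int r, std::vector<int>& out) {
  out.clear();
  const Ring& rg = s.rings[r];
  if (rg.closed) {
    for (int l = 0; l < rg.n; ++l) out.push_back(rg.start + l);
  } else {
    for (int l = 1; l < rg.n - 1; ++l) out.push_back(rg.start + l);
  }
}

// ------------------------------------------------------------------ writhe

// signed solid angle of the spherical triangle (a, b, c), unit vectors
// (Van Oosterom-Strackee: stable near degenerate/planar configurations)
static inline double tri_solid(const V3& a, const V3& b, const V3& c) {
  double num = dot(a, cross(b, c));
  double den = 1.0 + dot(a, b) + dot(a, c) + dot(b, c);
  if (num == 0.0) return 0.0;   // coplanar with the origin: zero area
  return 2.0 * std::atan2(num, den);
}

// exact solid-angle contribution of the segment pair p1->p2, p3->p4 to
// the Gauss double integral: the signed area of the spherical
// quadrilateral of the four end-to-end directions, split into two
// triangles; exactly zero for coplanar configurations
static double seg_pair_writhe(const V3& p1, const V3& p2, const V3& p3, const V3& p4) {
  V3 r13 = p3 - p1, r14 = p4 - p1, r24 = p4 - p2, r23 = p3 - p2;
  double m13 = norm(r13), m14 = norm(r14), m24 = norm(r24), m23 = norm(r23);
  if (m13 < 1e-12 || m14 < 1e-12 || m24 < 1e-12 || m23 < 1e-12) return 0.0;
  V3 u13 = (1.0 / m13) * r13, u14 = (1.0 / m14) * r14;
  V3 u24 = (1.0 / m24) * r24, u23 = (1.0 / m23) * r23;
  // vertex order traverses the quadrilateral against the Gauss
  // orientation, hence the sign flip
  double omega = tri_solid(u13, u14, u24) + tri_solid(u13, u24, u23);
  return -omega / (4.0 * M_PI);
}

static double ring_writhe(const Sys& s, int r) {
  const Ring& rg = s.rings[r];
  if (!rg.closed) return NA_REAL;
  int n = rg.n, st = rg.start;
  double wr = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;  // adjacent around the seam
      wr += seg_pair_writhe(s.x[st + i], s.x[st + (i + 1) % n],
                            s.x[st + j], s.x[st + (j + 1) % n]);
    }
  }
  return 2.0 * wr;
}

// ---------------------------------------------------------------- energies

struct Energies {
  double bond = 0, bend = 0, torsion = 0, ev = 0, aff = 0;
  double total() const { return bond + bend + torsion + ev + aff; }
};

static double lj_trunc(double r, double eps, double sigma, double rcut) {
  if (r >= rcut) return 0.0;
  double sr6 = std::pow(sigma / r, 6);
  return 4.0 * eps * (sr6 * sr6 - sr6);
}

static double wca(double r, double eps, double sigma, double rcut) {
  if (r >= rcut) return 0.0;
  double sr6 = std::pow(sigma / r, 6);
  return 4.0 * eps * (sr6 * sr6 - sr6) + eps;  // shifted to 0 at the cut
}

// encode unordered pair
static inline int64_t pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (int64_t)i * n + j;
}

static inline bool is_bonded(const Sys& s, const FF& ff, int i, int j) {
  if (s.succ(i) == j || s.succ(j) == i) return true;
  for (size_t k = 0; k < ff.xb_a.size(); ++k) {
    if ((ff.xb_a[k] == i && ff.xb_b[k] == j) ||
        (ff.xb_a[k] == j && ff.xb_b[k] == i))
      return true;
  }
  return false;
}

static Energies compute_energy(const Sys& s, const FF& ff,
                               const std::vector<std::pair<int, int> >* pairs) {
  Energies e;
  int n = s.n();
  // bonds
  for (int i = 0; i < n; ++i) {
    int j = s.succ(i);
    if (j < 0) continue;
    double d = norm(s.x[j] - s.x[i]);
    e.bond += 0.5 * ff.k_bond * (d - ff.r0) * (d - ff.r0);
  }
  for (size_t k = 0; k < ff.xb_a.size(); ++k) {
    double d = norm(s.x[ff.xb_b[k]] - s.x[ff.xb_a[k]]);
    e.bond += 0.5 * ff.xb_k[k] * (d - ff.xb_r0[k]) * (d - ff.xb_r0[k]);
  }
  // bend + torsion over junctions
  std::vector<int> J;
  for (size_t r = 0; r < s.rings.size(); ++r) {
    ring_junctions(s, (int)r, J);
    bool closed = s.rings[r].closed;
    for (size_t q = 0; q < J.size(); ++q) {
      int v = J[q];
      int p = s.pred(v), nx = s.succ(v);
      V3 t0 = hat(s.x[v] - s.x[p]), t1 = hat(s.x[nx] - s.x[v]);
      e.bend += ff.k_bend * (1.0 - dot(t0, t1));
      if (closed && ff.k_dih > 0) {
        double phi = junction_phi(s, v);
        e.torsion += 0.5 * ff.k_dih * (1.0 - std::cos(phi - ff.phi0));
      }
    }
  }
  // excluded volume
  if (pairs) {
    for (size_t q = 0; q < pairs->size(); ++q) {
      int i = (*pairs)[q].first, j = (*pairs)[q].second;
      double r = norm(mimg(s.x[j] - s.x[i], ff.box));
      if (r < 1e-10) stop("overlapping beads (r = 0)");
      e.ev += wca(r, ff.eps_ev, ff.sigma_ev, ff.rcut_ev);
    }
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (is_bonded(s, ff, i, j)) continue;
        double r = norm(mimg(s.x[j] - s.x[i], ff.box));
        if (r < 1e-10) stop("overlapping beads (r = 0)");
        e.ev += wca(r, ff.eps_ev, ff.sigma_ev, ff.rcut_ev);
      }
  }
  // affinity
  for (size_t k = 0; k < ff.aff_a.size(); ++k) {
    double r = norm(mimg(s.x[ff.aff_b[k]] - s.x[ff.aff_a[k]], ff.box));
    if (r < 1e-10) stop("overlapping beads (r = 0)");
    e.aff += lj_trunc(r, ff.aff_eps[k], ff.aff_sigma, ff.aff_rcut);
  }
  return e;
}

// ------------------------------------------------------------------ forces

// accumulates -dE/dx into F and frame torques (-dE/dtheta) into T
static void compute_forces(const Sys& s, const FF& ff,
                           const std::vector<std::pair<int, int> >* pairs,
                           std::vector<V3>& F, std::vector<double>& T,
                           const std::vector<V3>* tang_in = 0,
                           const std::vector<double>* len_in = 0) {
  int n = s.n();
  F.assign(n, V3());
  T.assign(n, 0.0);
  static thread_local std::vector<V3> tang_loc;
  static thread_local std::vector<double> len_loc;
  const std::vector<V3>* tang = tang_in;
  const std::vector<double>* len = len_in;
  if (!tang) {
    edge_tangents(s, tang_loc, len_loc);
    tang = &tang_loc;
    len = &len_loc;
  }
  // bonds
  for (int i = 0; i < n; ++i) {
    int j = s.succ(i);
    if (j < 0) continue;
    double fmag = ff.k_bond * ((*len)[i] - ff.r0);
    V3 fv = fmag * (*tang)[i];
    F[i] = F[i] + fv;
    F[j] = F[j] - fv;
  }
  for (size_t k = 0; k < ff.xb_a.size(); ++k) {
    int a = ff.xb_a[k], b = ff.xb_b[k];
    V3 d = s.x[b] - s.x[a];
    double r = norm(d);
    double fmag = ff.xb_k[k] * (r - ff.xb_r0[k]) / r;
    F[a] = F[a] + fmag * d;
    F[b] = F[b] - fmag * d;
  }
  // bend + torsion
  std::vector<int> J;
  for (size_t rr = 0; rr < s.rings.size(); ++rr) {
    ring_junctions(s, (int)rr, J);
    bool closed = s.rings[rr].closed;
    for (size_t q = 0; q < J.size(); ++q) {
      int v = J[q];
      int p = s.pred(v), nx = s.succ(v);
      double lu = (*len)[p], lw = (*len)[v];
      const V3& tu = (*tang)[p];
      const V3& tw_ = (*tang)[v];
      double c = dot(tu, tw_);
      // bending: E = k (1 - c);  F = k * grad(c)
      V3 dc_du = (1.0 / lu) * (tw_ - c * tu);
      V3 dc_dw = (1.0 / lw) * (tu - c * tw_);
      F[p] = F[p] - ff.k_bend * dc_du;          // d u / d x_p = -I
      F[v] = F[v] + ff.k_bend * (dc_du - dc_dw);
      F[nx] = F[nx] + ff.k_bend * dc_dw;
      if (closed && ff.k_dih > 0) {
        double phi = junction_phi_t(s, v, *tang);
        double dV = 0.5 * ff.k_dih * std::sin(phi - ff.phi0);
        // frame torques: rotating frame of edge (p->v) by delta lowers phi,
        // rotating frame of edge (v->nx) raises it
        T[p] += dV;    // -dE/dtheta_p = -dV * dphi/dtheta_p = -dV * (-1)
        T[v] -= dV;
        // positional gradient of transport twist (discrete elastic rods
        // curvature binormal kb): grad_{x_p} phi = -kb/(2 lu),
        // grad_{x_nx} phi = +kb/(2 lw), grad_{x_v} phi = -(sum of both)
        double denom = 1.0 + c;
        if (denom > 1e-12) {
          V3 kb = (2.0 / denom) * cross(tu, tw_);
          V3 gp = (-0.5 / lu) * kb;
          V3 gn = (0.5 / lw) * kb;
          V3 gv = V3() - gp - gn;
          F[p] = F[p] - dV * gp;
          F[v] = F[v] - dV * gv;
          F[nx] = F[nx] - dV * gn;
        }
      }
    }
  }
  // excluded volume (WCA derivative)
  double rc2 = ff.rcut_ev * ff.rcut_ev;
  if (pairs) {
    for (size_t q = 0; q < pairs->size(); ++q) {
      int i = (*pairs)[q].first, j = (*pairs)[q].second;
      V3 d = mimg(s.x[j] - s.x[i], ff.box);
      double r2 = dot(d, d);
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      if (r < 1e-10) stop("overlapping beads (r = 0)");
      double sr6 = std::pow(ff.sigma_ev / r, 6);
      double fmag = 24.0 * ff.eps_ev * (2.0 * sr6 * sr6 - sr6) / r2;  // F = fmag * d on j
      F[j] = F[j] + fmag * d;
      F[i] = F[i] - fmag * d;
    }
  } else {
    int nn = n;
    for (int i = 0; i < nn; ++i)
      for (int j = i + 1; j < nn; ++j) {
        if (is_bonded(s, ff, i, j)) continue;
        V3 d = mimg(s.x[j] - s.x[i], ff.box);
        double r2 = dot(d, d);
        if (r2 >= rc2) continue;
        double r = std::sqrt(r2);
        if (r < 1e-10) stop("overlapping beads (r = 0)");
        double sr6 = std::pow(ff.sigma_ev / r, 6);
        double fmag = 24.0 * ff.eps_ev * (2.0 * sr6 * sr6 - sr6) / r2;
        F[j] = F[j] + fmag * d;
        F[i] = F[i] - fmag * d;
      }
  }
  // affinity (truncated LJ derivative)
  for (size_t k = 0; k < ff.aff_a.size(); ++k) {
    int a = ff.aff_a[k], b = ff.aff_b[k];
    V3 d = mimg(s.x[b] - s.x[a], ff.box);
    double r = norm(d);
    if (r >= ff.aff_rcut) continue;
    if (r < 1e-10) stop("overlapping beads (r = 0)");
    double sr6 = std::pow(ff.aff_sigma / r, 6);
    double fmag = 24.0 * ff.aff_eps[k] * (2.0 * sr6 * sr6 - sr6) / (r * r);
    F[b] = F[b] + fmag * d;
    F[a] = F[a] - fmag * d;
  }
}

// ------------------------------------------------------------ neighbor list

struct NeighborList {
  std::vector<std::pair<int, int> > pairs;
  std::vector<V3> ref;  // positions at build time
  double skin;
  bool valid(const Sys& s) const {
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < s.n(); ++i) {
      V3 d = s.x[i] - ref[i];
      if (dot(d, d) > lim) return false;
    }
    return true;
  }
};

static void build_nl(const Sys& s, const FF& ff, double rnl, NeighborList& nl) {
  nl.pairs.clear();
  nl.ref = s.x;
  int n = s.n();
  double rnl2 = rnl * rnl;
  double L = ff.box;
  int m = (L > 0) ? (int)std::floor(L / rnl) : 0;
  if (L > 0 && m >= 3) {
    // cell binning on wrapped coordinates
    double cw = L / m;
    std::vector<std::vector<int> > cells(m * m * m);
    std::vector<int> cx(n), cy(n), cz(n);
    for (int i = 0; i < n; ++i) {
      double wx = s.x[i].x - L * std::floor(s.x[i].x / L);
      double wy = s.x[i].y - L * std::floor(s.x[i].y / L);
      double wz = s.x[i].z - L * std::floor(s.x[i].z / L);
      cx[i] = std::min(m - 1, (int)(wx / cw));
      cy[i] = std::min(m - 1, (int)(wy / cw));
      cz[i] = std::min(m - 1, (int)(wz / cw));
      cells[(cx[i] * m + cy[i]) * m + cz[i]].push_back(i);
    }
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        for (int c = 0; c < m; ++c) {
          const std::vector<int>& ci = cells[(a * m + b) * m + c];
          if (ci.empty()) continue;
          for (int da = -1; da <= 1; ++da)
            for (int db = -1; db <= 1; ++db)
              for (int dc = -1; dc <= 1; ++dc) {
                int a2 = (a + da + m) % m, b2 = (b + db + m) % m, c2 = (c + dc + m) % m;
                int id2 = (a2 * m + b2) * m + c2, id1 = (a * m + b) * m + c;
                if (id2 < id1) continue;
                const std::vector<int>& cj = cells[id2];
                for (size_t p = 0; p < ci.size(); ++p) {
                  size_t q0 = (id1 == id2) ? p + 1 : 0;
                  for (size_t q = q0; q < cj.size(); ++q) {
                    int i = ci[p], j = cj[q];
                    V3 d = mimg(s.x[j] - s.x[i], L);
                    if (dot(d, d) > rnl2) continue;
                    if (is_bonded(s, ff, i, j)) continue;
                    nl.pairs.push_back(std::make_pair(i, j));
                  }
                }
              }
        }
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        V3 d = mimg(s.x[j] - s.x[i], L);
        if (dot(d, d) > rnl2) continue;
        if (is_bonded(s, ff, i, j)) continue;
        nl.pairs.push_back(std::make_pair(i, j));
      }
  }
}

// --------------------------------------------------------------------- rng

struct Rng {
  uint64_t st[4];
  double spare;
  bool has_spare;
  explicit Rng(uint64_t seed) : has_spare(false) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      st[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {  // xoshiro256++
    uint64_t result = rotl(st[0] + st[3], 23) + st[0];
    uint64_t t = st[1] << 17;
    st[2] ^= st[0];
    st[3] ^= st[1];
    st[1] ^= st[2];
    st[0] ^= st[3];
    st[2] ^= t;
    st[3] = rotl(st[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double gauss() {  // Marsaglia polar, deterministic for a given stream
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double g = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * g;
    has_spare = true;
    return u * g;
  }
};

// ----------------------------------------------------------------- exports

static List energies_to_list(const Energies& e) {
  return List::create(_["bond"] = e.bond, _["bend"] = e.bend,
                      _["torsion"] = e.torsion, _["excluded_volume"] = e.ev,
                      _["affinity"] = e.aff, _["total"] = e.total());
}

// [[Rcpp::export]]
List cs_energy(NumericMatrix pos, NumericMatrix frm, IntegerMatrix rings, List ff) {
  Sys s = make_sys(pos, frm, rings);
  FF p = make_ff(ff);
  Energies e = compute_energy(s, p, 0);
  return energies_to_list(e);
}

// [[Rcpp::export]]
List cs_forces(NumericMatrix pos, NumericMatrix frm, IntegerMatrix rings, List ff) {
  Sys s = make_sys(pos, frm, rings);
  FF p = make_ff(ff);
  std::vector<V3> F;
  std::vector<double> T;
  compute_forces(s, p, 0, F, T);
  int n = s.n();
  NumericMatrix Fm(n, 3);
  NumericVector Tv(n);
  for (int i = 0; i < n; ++i) {
    Fm(i, 0) = F[i].x;
    Fm(i, 1) = F[i].y;
    Fm(i, 2) = F[i].z;
    Tv[i] = T[i];
  }
  return List::create(_["forces"] = Fm, _["torques"] = Tv);
}

// [[Rcpp::export]]
NumericVector cs_writhe(NumericMatrix pos, IntegerMatrix rings) {
  NumericMatrix dummy(pos.nrow(), 3);
  Sys s = make_sys(pos, dummy, rings);
  NumericVector out(s.rings.size());
  for (size_t r = 0; r < s.rings.size(); ++r) out[r] = ring_writhe(s, (int)r);
  return out;
}

// per-bead junction twist angles; NA where no junction exists
// [[Rcpp::export]]
NumericVector cs_phis(NumericMatrix pos, NumericMatrix frm, IntegerMatrix rings) {
  Sys s = make_sys(pos, frm, rings);
  NumericVector out(s.n(), NA_REAL);
  std::vector<int> J;
  for (size_t r = 0; r < s.rings.size(); ++r) {
    if (!s.rings[r].closed) continue;
    ring_junctions(s, (int)r, J);
    for (size_t q = 0; q < J.size(); ++q) out[J[q]] = junction_phi(s, J[q]);
  }
  return out;
}

// build frames realizing prescribed junction twists (junctions 1..n-1 of
// each closed ring; the seam junction's angle follows from ribbon closure)
// [[Rcpp::export]]
NumericMatrix cs_build_frames(NumericMatrix pos, IntegerMatrix rings, NumericVector twist) {
  NumericMatrix dummy(pos.nrow(), 3);
  Sys s = make_sys(pos, dummy, rings);
  int n = s.n();
  NumericMatrix out(n, 3);
  for (size_t r = 0; r < s.rings.size(); ++r) {
    const Ring& rg = s.rings[r];
    if (!rg.closed) continue;
    int st = rg.start, m = rg.n;
    V3 t0 = hat(s.x[st + 1] - s.x[st]);
    // pick a stable seed vector not parallel to t0
    V3 seed = std::fabs(t0.x) < 0.9 ? V3(1, 0, 0) : V3(0, 1, 0);
    V3 f = hat(seed - dot(seed, t0) * t0);
    out(st, 0) = f.x;
    out(st, 1) = f.y;
    out(st, 2) = f.z;
    V3 tprev = t0, fprev = f;
    for (int l = 1; l < m; ++l) {
      int v = st + l;
      int nx = (l == m - 1) ? st : v + 1;
      V3 t1 = hat(s.x[nx] - s.x[v]);
      V3 ft = transport(fprev, tprev, t1);
      ft = rot_about(ft, t1, twist[v]);
      ft = hat(ft - dot(ft, t1) * t1);
      out(v, 0) = ft.x;
      out(v, 1) = ft.y;
      out(v, 2) = ft.z;
      tprev = t1;
      fprev = ft;
    }
  }
  return out;
}

// transport frames from the tangents of `pos_old` to those of `pos_new`
// (used by the finite-difference oracle and by frame bookkeeping in R)
// [[Rcpp::export]]
NumericMatrix cs_transport_frames(NumericMatrix pos_old, NumericMatrix pos_new,
                                  NumericMatrix frm, IntegerMatrix rings) {
  Sys so = make_sys(pos_old, frm, rings);
  Sys sn = make_sys(pos_new, frm, rings);
  int n = so.n();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    if (!so.has_edge(i)) continue;
    int j = so.succ(i);
    V3 t_old = hat(so.x[j] - so.x[i]);
    V3 t_new = hat(sn.x[j] - sn.x[i]);
    V3 f = transport(so.f[i], t_old, t_new);
    f = hat(f - dot(f, t_new) * t_new);
    out(i, 0) = f.x;
    out(i, 1) = f.y;
    out(i, 2) = f.z;
  }
  return out;
}

// ---------------------------------------------------------------- BD run

// [[Rcpp::export]]
List cs_run(NumericMatrix pos, NumericMatrix frm, IntegerMatrix rings, List ff,
            double dt, double n_steps_d, int sample_every, double seed,
            double kT, double gamma_r, bool record_frames,
            IntegerMatrix track_pairs, bool use_nl, bool record_energy,
            double max_disp) {
  Sys s = make_sys(pos, frm, rings);
  FF p = make_ff(ff);
  long n_steps = (long)n_steps_d;
  int n = s.n();
  int n_rings = (int)s.rings.size();
  int n_pairs = track_pairs.nrow();
  Rng rng((uint64_t)seed);

  double skin = 0.7;
  double rnl = p.rcut_ev + skin;
  NeighborList nl;
  nl.skin = skin;
  bool nl_on = use_nl;
  if (nl_on) build_nl(s, p, rnl, nl);

  long n_samples = n_steps / sample_every + 1;
  NumericVector times(n_samples);
  NumericMatrix wr(n_samples, n_rings), tw(n_samples, n_rings);
  NumericVector rg(n_samples);
  NumericMatrix dists(n_samples, n_pairs);
  NumericMatrix energies(record_energy ? n_samples : 0, 6);
  List snaps(record_frames ? n_samples : 0);

  std::vector<V3> F;
  std::vector<double> T;
  std::vector<int> J;
  std::vector<V3> tang, tang_new;
  std::vector<double> len, len_new;
  edge_tangents(s, tang, len);

  double noise_x = std::sqrt(2.0 * kT * dt);
  double noise_r = std::sqrt(2.0 * kT * dt / gamma_r);
  bool thermal = kT > 0;

  long isample = 0;
  for (long step = 0; step <= n_steps; ++step) {
    if (step % sample_every == 0) {
      times[isample] = step * dt;
      for (int r = 0; r < n_rings; ++r) {
        wr(isample, r) = s.rings[r].closed ? ring_writhe(s, r) : NA_REAL;
        if (s.rings[r].closed) {
          ring_junctions(s, r, J);
          double tt = 0.0;
          for (size_t q = 0; q < J.size(); ++q) tt += junction_phi(s, J[q]);
          tw(isample, r) = tt / TWO_PI;
        } else {
          tw(isample, r) = NA_REAL;
        }
      }
      V3 cm;
      for (int i = 0; i < n; ++i) cm = cm + s.x[i];
      cm = (1.0 / n) * cm;
      double rg2 = 0.0;
      for (int i = 0; i < n; ++i) {
        V3 d = s.x[i] - cm;
        rg2 += dot(d, d);
      }
      rg[isample] = std::sqrt(rg2 / n);
      for (int k = 0; k < n_pairs; ++k) {
        V3 d = mimg(s.x[track_pairs(k, 1)] - s.x[track_pairs(k, 0)], p.box);
        dists(isample, k) = norm(d);
      }
      if (record_energy) {
        Energies e = compute_energy(s, p, nl_on ? &nl.pairs : 0);
        energies(isample, 0) = e.bond;
        energies(isample, 1) = e.bend;
        energies(isample, 2) = e.torsion;
        energies(isample, 3) = e.ev;
        energies(isample, 4) = e.aff;
        energies(isample, 5) = e.total();
      }
      if (record_frames) {
        NumericMatrix snap(n, 6);
        for (int i = 0; i < n; ++i) {
          snap(i, 0) = s.x[i].x;
          snap(i, 1) = s.x[i].y;
          snap(i, 2) = s.x[i].z;
          snap(i, 3) = s.f[i].x;
          snap(i, 4) = s.f[i].y;
          snap(i, 5) = s.f[i].z;
        }
        snaps[isample] = snap;
      }
      ++isample;
      if ((isample & 0x3f) == 0) Rcpp::checkUserInterrupt();
    }
    if (step == n_steps) break;

    if (nl_on && !nl.valid(s)) build_nl(s, p, rnl, nl);
    compute_forces(s, p, nl_on ? &nl.pairs : 0, F, T, &tang, &len);

    // positions: overdamped Euler-Maruyama, gamma = 1
    bool any_closed = false;
    for (int r = 0; r < n_rings; ++r)
      if (s.rings[r].closed) any_closed = true;
    for (int i = 0; i < n; ++i) {
      double fx = F[i].x, fy = F[i].y, fz = F[i].z;
      if (!std::isfinite(fx) || !std::isfinite(fy) || !std::isfinite(fz))
        stop("non-finite force on bead %d at step %ld (timestep too large or overlap blow-up)",
             i + 1, step);
      V3 dx(fx * dt, fy * dt, fz * dt);
      if (thermal) {
        dx.x += noise_x * rng.gauss();
        dx.y += noise_x * rng.gauss();
        dx.z += noise_x * rng.gauss();
      }
      if (max_disp > 0) {
        double dn = norm(dx);
        if (dn > max_disp) dx = (max_disp / dn) * dx;
      }
      s.x[i] = s.x[i] + dx;
    }
    // frames: transport with the moving edge, then twist by the torque and
    // rotational noise about the (new) tangent
    edge_tangents(s, tang_new, len_new);
    if (any_closed) {
      for (int r = 0; r < n_rings; ++r) {
        const Ring& rgg = s.rings[r];
        if (!rgg.closed) continue;
        for (int l = 0; l < rgg.n; ++l) {
          int i = rgg.start + l;
          const V3& t_old = tang[i];
          const V3& t_new = tang_new[i];
          V3 f = transport(s.f[i], t_old, t_new);
          double delta = (T[i] / gamma_r) * dt;
          if (thermal) delta += noise_r * rng.gauss();
          f = rot_about(f, t_new, delta);
          f = hat(f - dot(f, t_new) * t_new);
          s.f[i] = f;
        }
      }
    }
    tang.swap(tang_new);
    len.swap(len_new);
  }

  NumericMatrix pos_out(n, 3), frm_out(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = s.x[i].x;
    pos_out(i, 1) = s.x[i].y;
    pos_out(i, 2) = s.x[i].z;
    frm_out(i, 0) = s.f[i].x;
    frm_out(i, 1) = s.f[i].y;
    frm_out(i, 2) = s.f[i].z;
  }
  return List::create(_["times"] = times, _["wr"] = wr, _["tw"] = tw,
                      _["rg"] = rg, _["dists"] = dists,
                      _["energies"] = energies, _["snapshots"] = snaps,
                      _["positions"] = pos_out, _["frames"] = frm_out);
}
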