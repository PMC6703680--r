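// Multiband Monte Carlo canopy radiative transfer on a toroidal unit tile.
//
// The scene is a set of planar elliptical lamina patches inside one tile of a
// regular stand; the tile wraps in x and y, which is the exact limit of
// replicating the stand infinitely in both directions. Three bands are
// traced (red, far-red, PAR). Forward rays (cosine-weighted diffuse sky)
// deliver energy and drive absorption bookkeeping; backward "gather" rays
// from organ sensor points estimate locally perceived red and far-red flux
// through transmission-only attenuation, which is what the phytochrome-style
// R:FR signal needs. Petioles are treated as sensors of negligible area:
// they perceive light but do not intercept it.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Patch {
  double cx, cy, cz;       // ellipse centre
  double ux, uy, uz;       // unit major axis
  double vx, vy, vz;       // unit minor axis
  double nx, ny, nz;       // unit normal
  double a, b;             // semi-axes (a major, b minor)
  double zlo, zhi;         // vertical extent, for quick rejection
  int organ;               // index into the caller's organ table (0-based)
};

struct Ray {
  double ox, oy, oz;
  double dx, dy, dz;
  double e[3];             // per-band energy
  int bounces;
  int reflections;         // reflection events along the path
};

// Periodic images: each source ellipse is replicated at every tile offset at
// which its bounding box can intersect the base tile, so large leaves in
// small tiles (high density) wrap correctly.
void build_patches(const NumericMatrix& geom, double Lx, double Ly,
                   std::vector<Patch>& out) {
  int n = geom.nrow();
  for (int i = 0; i < n; ++i) {
    Patch p;
    p.cx = geom(i, 0); p.cy = geom(i, 1); p.cz = geom(i, 2);
    p.ux = geom(i, 3); p.uy = geom(i, 4); p.uz = geom(i, 5);
    p.vx = geom(i, 6); p.vy = geom(i, 7); p.vz = geom(i, 8);
    p.a  = geom(i, 9); p.b  = geom(i, 10);
    p.organ = (int) geom(i, 11);
    // normal = u x v
    p.nx = p.uy * p.vz - p.uz * p.vy;
    p.ny = p.uz * p.vx - p.ux * p.vz;
    p.nz = p.ux * p.vy - p.uy * p.vx;
    double extx = std::fabs(p.ux) * p.a + std::fabs(p.vx) * p.b;
    double exty = std::fabs(p.uy) * p.a + std::fabs(p.vy) * p.b;
    double extz = std::fabs(p.uz) * p.a + std::fabs(p.vz) * p.b;
    p.zlo = p.cz - extz - 1e-9;
    p.zhi = p.cz + extz + 1e-9;
    int ox_lo = (int) std::ceil((-(p.cx + extx)) / Lx);
    int ox_hi = (int) std::floor((Lx - (p.cx - extx)) / Lx);
    int oy_lo = (int) std::ceil((-(p.cy + exty)) / Ly);
    int oy_hi = (int) std::floor((Ly - (p.cy - exty)) / Ly);
    for (int ox = ox_lo; ox <= ox_hi; ++ox)
      for (int oy = oy_lo; oy <= oy_hi; ++oy) {
        Patch q = p;
        q.cx += ox * Lx;
        q.cy += oy * Ly;
        out.push_back(q);
      }
  }
}

inline double wrap_coord(double x, double L) {
  double w = x - L * std::floor(x / L);
  if (w >= L) w -= L;   // guard against floating-point edge
  return w;
}

// Nearest intersection of a ray (restricted to t in (t_eps, t_max)) with the
// patch list; returns index or -1. skip_organ excludes a sensor's own lamina.
int nearest_hit(const std::vector<Patch>& patches, const Ray& r,
                double t_max, double& t_hit, int skip_organ = -1) {
  const double t_eps = 1e-9;
  int best = -1;
  double tb = t_max;
  double z0 = r.oz, z1 = r.oz + tb * r.dz;
  if (z0 > z1) { double tmp = z0; z0 = z1; z1 = tmp; }
  for (size_t j = 0; j < patches.size(); ++j) {
    const Patch& p = patches[j];
    if (p.zhi < z0 || p.zlo > z1) continue;
    if (skip_organ >= 0 && p.organ == skip_organ) continue;
    double denom = r.dx * p.nx + r.dy * p.ny + r.dz * p.nz;
    if (std::fabs(denom) < 1e-12) continue;
    double t = ((p.cx - r.ox) * p.nx + (p.cy - r.oy) * p.ny +
                (p.cz - r.oz) * p.nz) / denom;
    if (t <= t_eps || t >= tb) continue;
    double wx = r.ox + t * r.dx - p.cx;
    double wy = r.oy + t * r.dy - p.cy;
    double wz = r.oz + t * r.dz - p.cz;
    double su = (wx * p.ux + wy * p.uy + wz * p.uz) / p.a;
    double sv = (wx * p.vx + wy * p.vy + wz * p.vz) / p.b;
    if (su * su + sv * sv > 1.0) continue;
    tb = t;
    best = (int) j;
  }
  t_hit = tb;
  return best;
}

// Advance a ray across the toroidal tile; finds the nearest patch hit before
// the ray leaves the slab [0, ztop] vertically. Horizontal exits wrap.
// Returns patch index, or -1 when the ray escapes (esc_up / ground).
int trace_periodic(const std::vector<Patch>& patches, Ray& r,
                   double Lx, double Ly, double ztop,
                   double& t_hit, bool& escaped_up, int skip_organ = -1) {
  const int max_seg = 512;
  r.ox = wrap_coord(r.ox, Lx);
  r.oy = wrap_coord(r.oy, Ly);
  for (int seg = 0; seg < max_seg; ++seg) {
    // t at which the ray leaves the current tile horizontally
    double t_exit = 1e30;
    if (r.dx > 1e-12)  t_exit = std::min(t_exit, (Lx - r.ox) / r.dx);
    if (r.dx < -1e-12) t_exit = std::min(t_exit, (0.0 - r.ox) / r.dx);
    if (r.dy > 1e-12)  t_exit = std::min(t_exit, (Ly - r.oy) / r.dy);
    if (r.dy < -1e-12) t_exit = std::min(t_exit, (0.0 - r.oy) / r.dy);
    // t at which the ray leaves vertically
    double t_z = 1e30;
    if (r.dz > 1e-12)  t_z = (ztop - r.oz) / r.dz;
    if (r.dz < -1e-12) t_z = (0.0 - r.oz) / r.dz;
    double t_stop = std::min(t_exit, t_z);
    int hit = nearest_hit(patches, r, t_stop + 1e-9, t_hit, skip_organ);
    if (hit >= 0) return hit;
    if (t_z <= t_exit) { escaped_up = (r.dz > 0); return -1; }
    // advance to the tile boundary and wrap
    r.ox = wrap_coord(r.ox + (t_exit + 1e-9) * r.dx, Lx);
    r.oy = wrap_coord(r.oy + (t_exit + 1e-9) * r.dy, Ly);
    r.oz += (t_exit + 1e-9) * r.dz;
  }
  escaped_up = true;  // give residual pathological rays to the escape budget
  return -1;
}

// A gather ray never changes direction (transmission only), so all ellipse
// crossings along its periodic path can be counted in one sweep per tile
// segment; the per-band weight is then tr_b^crossings.
// Returns the crossing count, or -1 if the ray leaves through the ground.
int count_crossings(const std::vector<Patch>& patches, Ray r,
                    double Lx, double Ly, double ztop, int skip_organ) {
  const int max_seg = 512;
  const double t_eps = 1e-9;
  int count = 0;
  r.ox = wrap_coord(r.ox, Lx);
  r.oy = wrap_coord(r.oy, Ly);
  for (int seg = 0; seg < max_seg; ++seg) {
    double t_exit = 1e30;
    if (r.dx > 1e-12)  t_exit = std::min(t_exit, (Lx - r.ox) / r.dx);
    if (r.dx < -1e-12) t_exit = std::min(t_exit, (0.0 - r.ox) / r.dx);
    if (r.dy > 1e-12)  t_exit = std::min(t_exit, (Ly - r.oy) / r.dy);
    if (r.dy < -1e-12) t_exit = std::min(t_exit, (0.0 - r.oy) / r.dy);
    double t_z = 1e30;
    if (r.dz > 1e-12)  t_z = (ztop - r.oz) / r.dz;
    if (r.dz < -1e-12) t_z = (0.0 - r.oz) / r.dz;
    double t_stop = std::min(t_exit, t_z);
    double z0 = r.oz, z1 = r.oz + t_stop * r.dz;
    if (z0 > z1) { double tmp = z0; z0 = z1; z1 = tmp; }
    for (size_t j = 0; j < patches.size(); ++j) {
      const Patch& p = patches[j];
      if (p.zhi < z0 || p.zlo > z1) continue;
      if (skip_organ >= 0 && p.organ == skip_organ) continue;
      double denom = r.dx * p.nx + r.dy * p.ny + r.dz * p.nz;
      if (std::fabs(denom) < 1e-12) continue;
      double t = ((p.cx - r.ox) * p.nx + (p.cy - r.oy) * p.ny +
                  (p.cz - r.oz) * p.nz) / denom;
      if (t <= t_eps || t >= t_stop) continue;
      double wx = r.ox + t * r.dx - p.cx;
      double wy = r.oy + t * r.dy - p.cy;
      double wz = r.oz + t * r.dz - p.cz;
      double su = (wx * p.ux + wy * p.uy + wz * p.uz) / p.a;
      double sv = (wx * p.vx + wy * p.vy + wz * p.vz) / p.b;
      if (su * su + sv * sv > 1.0) continue;
      ++count;
    }
    if (t_z <= t_exit) return (r.dz > 0) ? count : -1;
    r.ox = wrap_coord(r.ox + (t_exit + 1e-9) * r.dx, Lx);
    r.oy = wrap_coord(r.oy + (t_exit + 1e-9) * r.dy, Ly);
    r.oz += (t_exit + 1e-9) * r.dz;
  }
  return count;
}

inline void cosine_dir(double& dx, double& dy, double& dz, int sign_z) {
  double u1 = R::runif(0.0, 1.0), u2 = R::runif(0.0, 1.0);
  double st = std::sqrt(u1);            // sin(theta), cosine-weighted
  double ct = std::sqrt(1.0 - u1);      // cos(theta)
  double phi = 2.0 * M_PI * u2;
  dx = st * std::cos(phi);
  dy = st * std::sin(phi);
  dz = sign_z * ct;
}

// cosine-weighted direction about an arbitrary unit normal
inline void cosine_dir_about(double nx, double ny, double nz,
                             double& dx, double& dy, double& dz) {
  double lx, ly, lz;
  cosine_dir(lx, ly, lz, +1);
  // orthonormal frame around n
  double t1x, t1y, t1z;
  if (std::fabs(nz) < 0.999) { t1x = -ny; t1y = nx; t1z = 0.0; }
  else                       { t1x = 1.0; t1y = 0.0; t1z = 0.0; }
  double nrm = std::sqrt(t1x * t1x + t1y * t1y + t1z * t1z);
  t1x /= nrm; t1y /= nrm; t1z /= nrm;
  double t2x = ny * t1z - nz * t1y;
  double t2y = nz * t1x - nx * t1z;
  double t2z = nx * t1y - ny * t1x;
  dx = lx * t1x + ly * t2x + lz * nx;
  dy = lx * t1y + ly * t2y + lz * ny;
  dz = lx * t1z + ly * t2z + lz * nz;
}

} // namespace

// geom: one row per (non-senesced) lamina patch:
//   cx cy cz ux uy uz vx vy vz a b organ_index(0-based)
// sensors: one row per sensor point: x y z own_organ_index(0-based, -1 none)
//   nx ny nz (unit sensor normal; gather rays are cosine-weighted about it,
//   so a tilted blade receives sky light at its projection and "sees"
//   neighbouring vegetation through its side-facing directions)
// n_organs: length of the caller's organ table
// absorb: absorptance per band (red, farred, par); the non-absorbed
//   remainder is split equally between specular reflection and forward
//   transmission.
// flux: per-band emitted flux on a horizontal plane (red, farred, par).
// [[Rcpp::export]]
List trace_canopy_cpp(NumericMatrix geom, NumericMatrix sensors,
                      int n_organs, double Lx, double Ly,
                      NumericVector absorb, NumericVector flux,
                      int n_rays, int n_gather, int max_bounces) {
  std::vector<Patch> patches;
  build_patches(geom, Lx, Ly, patches);
  double ztop = 1e-3;
  for (size_t j = 0; j < patches.size(); ++j)
    ztop = std::max(ztop, patches[j].cz + patches[j].a + 1e-3);

  NumericVector abs_par(n_organs), abs_red(n_organs), abs_fr(n_organs);
  // incident energy arriving via >= 1 reflection: the scattered component
  // of perception (the gather pass covers direct + pure transmission)
  NumericVector refl_red(n_organs), refl_fr(n_organs), refl_par(n_organs);
  NumericVector emitted(3), escaped(3), absorbed_tot(3);
  double area_tile = Lx * Ly;
  for (int b = 0; b < 3; ++b) emitted[b] = flux[b] * area_tile;

  // ---- forward pass ----
  if (!patches.empty() && n_rays > 0) {
    double e0[3];
    for (int b = 0; b < 3; ++b) e0[b] = flux[b] * area_tile / n_rays;
    std::vector<Ray> stack;
    for (int i = 0; i < n_rays; ++i) {
      Ray r;
      r.ox = R::runif(0.0, Lx);
      r.oy = R::runif(0.0, Ly);
      r.oz = ztop;
      cosine_dir(r.dx, r.dy, r.dz, -1);
      for (int b = 0; b < 3; ++b) r.e[b] = e0[b];
      r.bounces = 0;
      r.reflections = 0;
      stack.clear();
      stack.push_back(r);
      while (!stack.empty()) {
        Ray cur = stack.back();
        stack.pop_back();
        double t_hit;
        bool esc_up = false;
        int hit = trace_periodic(patches, cur, Lx, Ly, ztop, t_hit, esc_up);
        if (hit < 0) {
          for (int b = 0; b < 3; ++b) escaped[b] += cur.e[b];
          continue;
        }
        const Patch& p = patches[hit];
        int org = p.organ;
        double hx = cur.ox + t_hit * cur.dx;
        double hy = cur.oy + t_hit * cur.dy;
        double hz = cur.oz + t_hit * cur.dz;
        // absorb
        double ab[3];
        for (int b = 0; b < 3; ++b) {
          ab[b] = cur.e[b] * absorb[b];
          absorbed_tot[b] += ab[b];
        }
        abs_red[org] += ab[0];
        abs_fr[org]  += ab[1];
        abs_par[org] += ab[2];
        if (cur.reflections > 0) {
          refl_red[org] += cur.e[0];
          refl_fr[org]  += cur.e[1];
          refl_par[org] += cur.e[2];
        }
        if (cur.bounces >= max_bounces) {
          // residual scattered energy leaves the accounting as escaped
          for (int b = 0; b < 3; ++b) escaped[b] += cur.e[b] - ab[b];
          continue;
        }
        // transmitted: same direction
        Ray tr = cur;
        tr.ox = hx; tr.oy = hy; tr.oz = hz;
        tr.bounces = cur.bounces + 1;
        for (int b = 0; b < 3; ++b) tr.e[b] = (cur.e[b] - ab[b]) * 0.5;
        // reflected: specular about the patch normal
        double dn = cur.dx * p.nx + cur.dy * p.ny + cur.dz * p.nz;
        Ray rf = tr;
        rf.dx = cur.dx - 2.0 * dn * p.nx;
        rf.dy = cur.dy - 2.0 * dn * p.ny;
        rf.dz = cur.dz - 2.0 * dn * p.nz;
        rf.reflections = cur.reflections + 1;
        if (tr.e[0] + tr.e[1] + tr.e[2] > 1e-14) {
          stack.push_back(tr);
          stack.push_back(rf);
        }
      }
    }
  } else {
    for (int b = 0; b < 3; ++b) escaped[b] = emitted[b];
  }

  // ---- gather pass: perceived red / far-red / PAR at sensor points ----
  int ns = sensors.nrow();
  NumericVector perc_red(ns), perc_fr(ns), perc_par(ns);
  double tr_share[3];  // transmission share per band
  for (int b = 0; b < 3; ++b) tr_share[b] = (1.0 - absorb[b]) * 0.5;
  for (int s = 0; s < ns; ++s) {
    int own = (int) sensors(s, 3);
    double acc[3] = {0.0, 0.0, 0.0};
    for (int g = 0; g < n_gather; ++g) {
      Ray r;
      r.ox = sensors(s, 0);
      r.oy = sensors(s, 1);
      r.oz = sensors(s, 2) + 1e-7;
      cosine_dir_about(sensors(s, 4), sensors(s, 5), sensors(s, 6),
                       r.dx, r.dy, r.dz);
      int c = count_crossings(patches, r, Lx, Ly, ztop, own);
      if (c >= 0 && c < 60)
        for (int b = 0; b < 3; ++b)
          acc[b] += std::pow(tr_share[b], (double) c);
    }
    if (n_gather > 0) {
      perc_red[s] = flux[0] * acc[0] / n_gather;
      perc_fr[s]  = flux[1] * acc[1] / n_gather;
      perc_par[s] = flux[2] * acc[2] / n_gather;
    }
  }

  return List::create(
    _["absorbed_par"] = abs_par,
    _["absorbed_red"] = abs_red,
    _["absorbed_farred"] = abs_fr,
    _["reflected_incident_red"] = refl_red,
    _["reflected_incident_farred"] = refl_fr,
    _["reflected_incident_par"] = refl_par,
    _["perceived_red"] = perc_red,
    _["perceived_farred"] = perc_fr,
    _["perceived_par"] = perc_par,
    _["emitted"] = emitted,
    _["escaped"] = escaped,
    _["absorbed_total"] = absorbed_tot);
}

// Minimum toroidal distance from each tip point to any other leaf's tip.
// tips: rows (x, y, z); returns Inf for a single leaf.
// [[Rcpp::export]]
NumericVector min_tip_distance_cpp(NumericMatrix tips, double Lx, double Ly) {
  int n = tips.nrow();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = std::fabs(tips(i, 0) - tips(j, 0));
      double dy = std::fabs(tips(i, 1) - tips(j, 1));
      dx = std::min(dx, Lx - dx);
      dy = std::min(dy, Ly - dy);
      double dz = tips(i, 2) - tips(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}
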