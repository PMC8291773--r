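// Brownian-dynamics integrator over precomputed axisymmetric force, current
// and diffusivity tables. Positions are 3-D Cartesian (nm, z along the pore
// axis); fields are interpolated bilinearly in the meridional (r, z) plane.
// The discretized overdamped Langevin update is
//   x' = x + dt (div D) + dt D F / kT + sqrt(2 dt) C xi,   D = C C^T,
// with the spurious-drift term div D evaluated by central differences of the
// interpolated tensor field. Hard walls are enforced by shortening any step
// that would cross the protein-inflated wall surface. Random numbers come
// from R's RNG so trajectories are reproducible via set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Tables {
  NumericVector rg, zg;          // grid coordinates (nm), ascending
  NumericMatrix Fr, Fz;          // force (N), cylindrical components
  NumericMatrix J;               // current (A)
  NumericMatrix fpar, fperp;     // diffusivity factors (dimensionless)
  NumericMatrix n_r, n_z;        // nearest-wall normal (meridional)
  double D0;                     // bulk diffusivity (m^2/s)
};

static inline void locate(const NumericVector& g, double x, int& i, double& w) {
  int n = g.size();
  if (x <= g[0]) { i = 0; w = 0.0; return; }
  if (x >= g[n - 1]) { i = n - 2; w = 1.0; return; }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (g[mid] <= x) lo = mid; else hi = mid; }
  i = lo; w = (x - g[lo]) / (g[lo + 1] - g[lo]);
}

static inline double bilin(const NumericMatrix& M, int i, int j, double wr, double wz) {
  return M(i, j) * (1 - wr) * (1 - wz) + M(i + 1, j) * wr * (1 - wz) +
         M(i, j + 1) * (1 - wr) * wz + M(i + 1, j + 1) * wr * wz;
}

struct FieldSample {
  double Fr, Fz, J, fpar, fperp, nr, nz;
};

static inline FieldSample sample_tables(const Tables& T, double r, double z) {
  int i, j; double wr, wz;
  locate(T.rg, r, i, wr);
  locate(T.zg, z, j, wz);
  FieldSample s;
  s.Fr = bilin(T.Fr, i, j, wr, wz);
  s.Fz = bilin(T.Fz, i, j, wr, wz);
  s.J  = bilin(T.J,  i, j, wr, wz);
  s.fpar  = bilin(T.fpar,  i, j, wr, wz);
  s.fperp = bilin(T.fperp, i, j, wr, wz);
  s.nr = bilin(T.n_r, i, j, wr, wz);
  s.nz = bilin(T.n_z, i, j, wr, wz);
  return s;
}

// 3x3 diffusion tensor at Cartesian x (nm): D = a I + b n3 n3^T
static inline void tensor_at(const Tables& T, const double* x,
                             double& alpha, double& beta, double n3[3]) {
  double r = std::sqrt(x[0] * x[0] + x[1] * x[1]);
  FieldSample s = sample_tables(T, r, x[2]);
  double nn = std::sqrt(s.nr * s.nr + s.nz * s.nz);
  double nr_ = (nn > 1e-12) ? s.nr / nn : 1.0;
  double nz_ = (nn > 1e-12) ? s.nz / nn : 0.0;
  if (r > 1e-9) {
    n3[0] = nr_ * x[0] / r; n3[1] = nr_ * x[1] / r; n3[2] = nz_;
  } else {
    n3[0] = nr_; n3[1] = 0.0; n3[2] = nz_;
  }
  alpha = T.D0 * s.fpar;
  beta  = T.D0 * (s.fperp - s.fpar);
}

// distance (nm) from meridional point (r, z) to the nearest wall segment
static inline double wall_dist(const NumericMatrix& segs, double r, double z) {
  double best = 1e30;
  for (int s = 0; s < segs.nrow(); ++s) {
    double ar = segs(s, 0), az = segs(s, 1), br = segs(s, 2), bz = segs(s, 3);
    double abr = br - ar, abz = bz - az;
    double len2 = abr * abr + abz * abz;
    double t = len2 > 0 ? ((r - ar) * abr + (z - az) * abz) / len2 : 0.0;
    if (t < 0) t = 0; if (t > 1) t = 1;
    double dr = r - (ar + t * abr), dz = z - (az + t * abz);
    double d = std::sqrt(dr * dr + dz * dz);
    if (d < best) best = d;
  }
  return best;
}

// [[Rcpp::export]]
List cpp_bd_trajectory(List tables, NumericMatrix wall_segs,
                       double protein_radius, NumericVector start,
                       double dt, double kT, int max_steps,
                       double z_translocate, NumericVector escape_box,
                       List binding_zones, int store_stride,
                       double stencil_h = 0.05) {
  Tables T;
  T.rg = as<NumericVector>(tables["r"]);
  T.zg = as<NumericVector>(tables["z"]);
  T.Fr = as<NumericMatrix>(tables["Fr"]);
  T.Fz = as<NumericMatrix>(tables["Fz"]);
  T.J  = as<NumericMatrix>(tables["J"]);
  T.fpar = as<NumericMatrix>(tables["fpar"]);
  T.fperp = as<NumericMatrix>(tables["fperp"]);
  T.n_r = as<NumericMatrix>(tables["n_r"]);
  T.n_z = as<NumericMatrix>(tables["n_z"]);
  T.D0 = as<double>(tables["D0"]);

  const double nm = 1e-9;
  double x[3] = { start[0], start[1], start[2] };
  const double bx = escape_box[0], by = escape_box[1], ztop = escape_box[2];
  const double eps_wall = 1e-3;
  const double rmax = T.rg[T.rg.size() - 1] - 1e-6;
  const double zmin = T.zg[0] + 1e-6, zmax = T.zg[T.zg.size() - 1] - 1e-6;

  int nzone = binding_zones.size();
  std::vector<int> zone_type(nzone);             // 0 sphere, 1 wall
  std::vector<std::vector<double>> zone_par(nzone);
  std::vector<std::vector<double>> rec_t, rec_F, rec_J;
  rec_t.resize(nzone); rec_F.resize(nzone); rec_J.resize(nzone);
  for (int k = 0; k < nzone; ++k) {
    List zk = binding_zones[k];
    std::string ty = as<std::string>(zk["type"]);
    if (ty == "sphere") {
      zone_type[k] = 0;
      NumericVector c = zk["center"];
      double rb = as<double>(zk["r_b"]);
      zone_par[k] = { c[0], c[1], c[2], rb };
    } else {
      zone_type[k] = 1;
      zone_par[k] = { as<double>(zk["z0"]), as<double>(zk["z1"]),
                      protein_radius + as<double>(zk["r_b"]) };
    }
  }

  std::vector<double> xs, ys, zs;
  int status = 0;                                // 0 max_steps, 1 transloc, 2 escape
  long nsteps = 0;
  double sumJ = 0.0;
  double sqrt2dt = std::sqrt(2.0 * dt);

  for (int step = 0; step < max_steps; ++step) {
    if (store_stride > 0 && step % store_stride == 0) {
      xs.push_back(x[0]); ys.push_back(x[1]); zs.push_back(x[2]);
    }
    double r = std::sqrt(x[0] * x[0] + x[1] * x[1]);
    FieldSample s = sample_tables(T, r, x[2]);
    sumJ += s.J;
    // binding-zone bookkeeping
    for (int k = 0; k < nzone; ++k) {
      bool inzone = false;
      if (zone_type[k] == 0) {
        double dx0 = x[0] - zone_par[k][0], dy0 = x[1] - zone_par[k][1],
               dz0 = x[2] - zone_par[k][2];
        inzone = dx0 * dx0 + dy0 * dy0 + dz0 * dz0 <=
                 zone_par[k][3] * zone_par[k][3];
      } else {
        if (x[2] >= zone_par[k][0] && x[2] <= zone_par[k][1]) {
          double wd = wall_dist(wall_segs, r, x[2]);
          inzone = wd <= zone_par[k][2];
        }
      }
      if (inzone) {
        rec_t[k].push_back(step * dt);
        rec_F[k].push_back(std::sqrt(s.Fr * s.Fr + s.Fz * s.Fz));
        rec_J[k].push_back(s.J);
      }
    }
    // force in 3-D (rotate cylindrical components)
    double F3[3];
    if (r > 1e-9) {
      F3[0] = s.Fr * x[0] / r; F3[1] = s.Fr * x[1] / r; F3[2] = s.Fz;
    } else { F3[0] = 0; F3[1] = 0; F3[2] = s.Fz; }
    // diffusion tensor and divergence
    double alpha, beta, n3[3];
    tensor_at(T, x, alpha, beta, n3);
    double divD[3] = {0, 0, 0};
    for (int dim = 0; dim < 3; ++dim) {
      double xp[3] = { x[0], x[1], x[2] }, xm[3] = { x[0], x[1], x[2] };
      xp[dim] += stencil_h; xm[dim] -= stencil_h;
      double ap, bp, np3[3], am, bm, nm3[3];
      tensor_at(T, xp, ap, bp, np3);
      tensor_at(T, xm, am, bm, nm3);
      for (int i = 0; i < 3; ++i) {
        double Dp = (i == dim ? ap : 0.0) + bp * np3[i] * np3[dim];
        double Dm = (i == dim ? am : 0.0) + bm * nm3[i] * nm3[dim];
        divD[i] += (Dp - Dm) / (2.0 * stencil_h * nm);
      }
    }
    // noise: C = sqrt(alpha) I + (sqrt(alpha+beta) - sqrt(alpha)) n n^T
    double sa = std::sqrt(std::max(alpha, 0.0));
    double sab = std::sqrt(std::max(alpha + beta, 0.0));
    double xi[3] = { norm_rand(), norm_rand(), norm_rand() };
    double ndx = n3[0] * xi[0] + n3[1] * xi[1] + n3[2] * xi[2];
    double prop[3];
    for (int i = 0; i < 3; ++i) {
      double drift = dt * divD[i] +
        dt * ((i == 0 ? alpha * F3[0] : i == 1 ? alpha * F3[1] : alpha * F3[2]) +
              beta * n3[i] * (n3[0] * F3[0] + n3[1] * F3[1] + n3[2] * F3[2])) / kT;
      double noise = sqrt2dt * (sa * xi[i] + (sab - sa) * n3[i] * ndx);
      prop[i] = x[i] + (drift + noise) / nm;
    }
    // clamp to table coverage
    double rp = std::sqrt(prop[0] * prop[0] + prop[1] * prop[1]);
    if (rp > rmax) {
      double f = rmax / rp; prop[0] *= f; prop[1] *= f; rp = rmax;
    }
    if (prop[2] < zmin) prop[2] = zmin;
    if (prop[2] > zmax) prop[2] = zmax;
    // hard-wall reflection: shorten the step to stop just before contact
    double wd_prop = wall_dist(wall_segs, rp, prop[2]);
    if (wd_prop < protein_radius + eps_wall) {
      double lo = 0.0, hi = 1.0;  // fraction of the step that is admissible
      for (int it = 0; it < 20; ++it) {
        double mid = 0.5 * (lo + hi);
        double xm2[3] = { x[0] + mid * (prop[0] - x[0]),
                          x[1] + mid * (prop[1] - x[1]),
                          x[2] + mid * (prop[2] - x[2]) };
        double rm2 = std::sqrt(xm2[0] * xm2[0] + xm2[1] * xm2[1]);
        if (wall_dist(wall_segs, rm2, xm2[2]) >= protein_radius + eps_wall)
          lo = mid;
        else hi = mid;
      }
      for (int i = 0; i < 3; ++i) prop[i] = x[i] + lo * (prop[i] - x[i]);
    }
    x[0] = prop[0]; x[1] = prop[1]; x[2] = prop[2];
    nsteps = step + 1;
    // termination rules
    if (x[2] <= z_translocate) { status = 1; break; }
    if (std::fabs(x[0]) > bx || std::fabs(x[1]) > by || x[2] > ztop) {
      status = 2; break;
    }
  }

  List zones_out(nzone);
  for (int k = 0; k < nzone; ++k) {
    zones_out[k] = DataFrame::create(
      _["t"] = wrap(rec_t[k]), _["F"] = wrap(rec_F[k]), _["J"] = wrap(rec_J[k]));
  }
  return List::create(
    _["n_steps"] = (double)nsteps,
    _["duration"] = nsteps * dt,
    _["status"] = status,
    _["mean_J"] = nsteps > 0 ? sumJ / nsteps : NA_REAL,
    _["final"] = NumericVector::create(x[0], x[1], x[2]),
    _["positions"] = DataFrame::create(_["x"] = wrap(xs), _["y"] = wrap(ys),
                                       _["z"] = wrap(zs)),
    _["zones"] = zones_out);
}

// single BD step, exposed for unit tests of the discretized update
// [[Rcpp::export]]
NumericVector cpp_bd_step(List tables, NumericMatrix wall_segs,
                          double protein_radius, NumericVector x0,
                          double dt, double kT, double stencil_h = 0.05) {
  NumericVector esc = NumericVector::create(1e30, 1e30, 1e30);
  List empty_zones(0);
  List res = cpp_bd_trajectory(tables, wall_segs, protein_radius, x0, dt, kT,
                               1, -1e30, esc, empty_zones, 0, stencil_h);
  return as<NumericVector>(res["final"]);
}
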