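#include <Rcpp.h>
using namespace Rcpp;

// Stable-fluids kernel: unconditionally stable incompressible 2-D solver
// (implicit Gauss-Seidel diffusion, semi-Lagrangian advection, pressure
// projection) on a marker-and-cell (MAC) staggered grid with a solid-cell
// mask. Mask value 1 = fluid, 0 = solid (outer wall ring and internal
// boundaries).
//
// Layout: u[i,j] is the x-flux through the EAST face of cell (i,j), v[i,j]
// the y-flux through its NORTH face; dye and pressure are cell-centered.
// A face bordering a solid cell carries zero flux (no through-flow), which
// makes the discrete divergence telescope to exactly zero over the domain,
// so the projection solve is compatible and its residual -> 0 with
// iterations. Dye uses zero-flux (mask-aware) stencils at all walls.

static inline int at(int i, int j, int nx) { return i + j * nx; }

// zero the flux of any face touching a solid cell
static void enforce_solid_faces(NumericVector u, NumericVector v,
                                const IntegerVector &mask, int nx, int ny) {
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int id = at(i, j, nx);
      if (!mask[id]) { u[id] = 0.0; v[id] = 0.0; continue; }
      if (i == nx - 1 || !mask[at(i + 1, j, nx)]) u[id] = 0.0;
      if (j == ny - 1 || !mask[at(i, j + 1, nx)]) v[id] = 0.0;
    }
  }
}

// Mirror scalar field values into solid cells (zero-flux closure for
// bilinear sampling near walls).
static void set_bnd_scalar(NumericVector f, const IntegerVector &mask,
                           int nx, int ny) {
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int id = at(i, j, nx);
      if (mask[id]) continue;
      double s = 0.0; int c = 0;
      if (i > 0      && mask[at(i - 1, j, nx)]) { s += f[at(i - 1, j, nx)]; ++c; }
      if (i < nx - 1 && mask[at(i + 1, j, nx)]) { s += f[at(i + 1, j, nx)]; ++c; }
      if (j > 0      && mask[at(i, j - 1, nx)]) { s += f[at(i, j - 1, nx)]; ++c; }
      if (j < ny - 1 && mask[at(i, j + 1, nx)]) { s += f[at(i, j + 1, nx)]; ++c; }
      f[id] = c ? s / c : 0.0;
    }
  }
}

// is this u-face (east of cell i,j) an interior fluid-fluid face?
static inline bool u_face_open(const IntegerVector &mask, int i, int j,
                               int nx, int ny) {
  return i < nx - 1 && mask[at(i, j, nx)] && mask[at(i + 1, j, nx)];
}
static inline bool v_face_open(const IntegerVector &mask, int i, int j,
                               int nx, int ny) {
  return j < ny - 1 && mask[at(i, j, nx)] && mask[at(i, j + 1, nx)];
}

// Implicit diffusion (I - a L) x = x0 over the open faces of one velocity
// component (comp 1 = u, 2 = v); mask-aware zero-flux stencil.
static void diffuse_vel(NumericVector x, const NumericVector &x0,
                        const IntegerVector &mask, int nx, int ny,
                        double a, int iters, int comp) {
  for (int it = 0; it < iters; ++it) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        bool open = comp == 1 ? u_face_open(mask, i, j, nx, ny)
                              : v_face_open(mask, i, j, nx, ny);
        if (!open) continue;
        int id = at(i, j, nx);
        double s = 0.0; int nf = 0;
        if (comp == 1) {
          if (u_face_open(mask, i - 1, j, nx, ny)) { s += x[at(i - 1, j, nx)]; ++nf; }
          if (u_face_open(mask, i + 1, j, nx, ny)) { s += x[at(i + 1, j, nx)]; ++nf; }
          if (j > 0 && u_face_open(mask, i, j - 1, nx, ny)) { s += x[at(i, j - 1, nx)]; ++nf; }
          if (j < ny - 1 && u_face_open(mask, i, j + 1, nx, ny)) { s += x[at(i, j + 1, nx)]; ++nf; }
        } else {
          if (i > 0 && v_face_open(mask, i - 1, j, nx, ny)) { s += x[at(i - 1, j, nx)]; ++nf; }
          if (i < nx - 1 && v_face_open(mask, i + 1, j, nx, ny)) { s += x[at(i + 1, j, nx)]; ++nf; }
          if (v_face_open(mask, i, j - 1, nx, ny)) { s += x[at(i, j - 1, nx)]; ++nf; }
          if (v_face_open(mask, i, j + 1, nx, ny)) { s += x[at(i, j + 1, nx)]; ++nf; }
        }
        x[id] = (x0[id] + a * s) / (1.0 + a * nf);
      }
    }
  }
}

// Implicit diffusion of a cell-centered scalar with zero-flux stencil;
// conserves the fluid-cell sum at convergence.
static void diffuse_scalar(NumericVector x, const NumericVector &x0,
                           const IntegerVector &mask, int nx, int ny,
                           double a, int iters) {
  for (int it = 0; it < iters; ++it) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int id = at(i, j, nx);
        if (!mask[id]) continue;
        double s = 0.0; int nf = 0;
        if (i > 0      && mask[at(i - 1, j, nx)]) { s += x[at(i - 1, j, nx)]; ++nf; }
        if (i < nx - 1 && mask[at(i + 1, j, nx)]) { s += x[at(i + 1, j, nx)]; ++nf; }
        if (j > 0      && mask[at(i, j - 1, nx)]) { s += x[at(i, j - 1, nx)]; ++nf; }
        if (j < ny - 1 && mask[at(i, j + 1, nx)]) { s += x[at(i, j + 1, nx)]; ++nf; }
        x[id] = (x0[id] + a * s) / (1.0 + a * nf);
      }
    }
  }
}

// generic bilinear sample on a lattice whose node (i,j) sits at
// (i + offx, j + offy) in cell units; clamped to the lattice hull
static double sample_lattice(const NumericVector &f, int nx, int ny,
                             double offx, double offy, double x, double y) {
  double gx = x - offx, gy = y - offy;
  if (gx < 0) gx = 0; if (gx > nx - 1) gx = nx - 1;
  if (gy < 0) gy = 0; if (gy > ny - 1) gy = ny - 1;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
  if (i0 > nx - 2) i0 = nx - 2;
  if (j0 > ny - 2) j0 = ny - 2;
  double fx = gx - i0, fy = gy - j0;
  return (1 - fx) * (1 - fy) * f[at(i0, j0, nx)] +
         fx * (1 - fy) * f[at(i0 + 1, j0, nx)] +
         (1 - fx) * fy * f[at(i0, j0 + 1, nx)] +
         fx * fy * f[at(i0 + 1, j0 + 1, nx)];
}

// Projection: solve the mask-aware Neumann Poisson system L p = div with
// SOR Gauss-Seidel and subtract the face-gradient, driving the MAC
// divergence of every fluid cell to the solver residual.
static void project(NumericVector u, NumericVector v, NumericVector p,
                    NumericVector div, const IntegerVector &mask,
                    int nx, int ny, int iters, double omega) {
  enforce_solid_faces(u, v, mask, nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int id = at(i, j, nx);
      p[id] = 0.0;
      div[id] = 0.0;
      if (!mask[id]) continue;
      double uw = i > 0 ? u[at(i - 1, j, nx)] : 0.0;
      double vs = j > 0 ? v[at(i, j - 1, nx)] : 0.0;
      div[id] = u[id] - uw + v[id] - vs;
    }
  }
  for (int it = 0; it < iters; ++it) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int id = at(i, j, nx);
        if (!mask[id]) continue;
        double s = 0.0; int nf = 0;
        if (i > 0      && mask[at(i - 1, j, nx)]) { s += p[at(i - 1, j, nx)]; ++nf; }
        if (i < nx - 1 && mask[at(i + 1, j, nx)]) { s += p[at(i + 1, j, nx)]; ++nf; }
        if (j > 0      && mask[at(i, j - 1, nx)]) { s += p[at(i, j - 1, nx)]; ++nf; }
        if (j < ny - 1 && mask[at(i, j + 1, nx)]) { s += p[at(i, j + 1, nx)]; ++nf; }
        if (!nf) continue;
        double gs = (s - div[id]) / nf;
        p[id] += omega * (gs - p[id]);
      }
    }
  }
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int id = at(i, j, nx);
      if (u_face_open(mask, i, j, nx, ny))
        u[id] -= p[at(i + 1, j, nx)] - p[id];
      if (v_face_open(mask, i, j, nx, ny))
        v[id] -= p[at(i, j + 1, nx)] - p[id];
    }
  }
  enforce_solid_faces(u, v, mask, nx, ny);
}

// Semi-Lagrangian advection of the velocity field (self-advection).
static void advect_vel(NumericVector u, NumericVector v,
                       const NumericVector &u0, const NumericVector &v0,
                       const IntegerVector &mask, int nx, int ny,
                       double dt0) {
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int id = at(i, j, nx);
      if (u_face_open(mask, i, j, nx, ny)) {
        double x = i + 1.0, y = j + 0.5;   // u-face position, cell units
        double ux = u0[id];
        double uy = sample_lattice(v0, nx, ny, 0.5, 1.0, x, y);
        u[id] = sample_lattice(u0, nx, ny, 1.0, 0.5,
                               x - dt0 * ux, y - dt0 * uy);
      } else u[id] = 0.0;
      if (v_face_open(mask, i, j, nx, ny)) {
        double x = i + 0.5, y = j + 1.0;   // v-face position
        double vx = sample_lattice(u0, nx, ny, 1.0, 0.5, x, y);
        double vy = v0[id];
        v[id] = sample_lattice(v0, nx, ny, 0.5, 1.0,
                               x - dt0 * vx, y - dt0 * vy);
      } else v[id] = 0.0;
    }
  }
}

// Semi-Lagrangian advection of a cell-centered scalar.
static void advect_scalar(NumericVector d, const NumericVector &d0,
                          const NumericVector &u, const NumericVector &v,
                          const IntegerVector &mask, int nx, int ny,
                          double dt0) {
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int id = at(i, j, nx);
      if (!mask[id]) { d[id] = 0.0; continue; }
      double x = i + 0.5, y = j + 0.5;
      double uw = i > 0 ? u[at(i - 1, j, nx)] : 0.0;
      double vs = j > 0 ? v[at(i, j - 1, nx)] : 0.0;
      double ux = 0.5 * (uw + u[id]);
      double uy = 0.5 * (vs + v[id]);
      d[id] = sample_lattice(d0, nx, ny, 0.5, 0.5,
                             x - dt0 * ux, y - dt0 * uy);
    }
  }
}

// [[Rcpp::export]]
bool cpp_fluid_step(NumericVector u, NumericVector v, List dye,
                    IntegerVector mask, int nx, int ny,
                    double dt, double h, double visc, double ddiff,
                    double evap, int iters, double omega,
                    IntegerVector f_idx, NumericVector f_fx, NumericVector f_fy,
                    IntegerVector s_idx, IntegerVector s_chan,
                    NumericVector s_rate) {
  int n = nx * ny;
  NumericVector tmp(n), p(n), div(n);

  // forces: per-step velocity increments (wind sources + robot
  // perturbation), applied to the cell's faces
  for (int k = 0; k < f_idx.size(); ++k) {
    int id = f_idx[k];
    if (!mask[id]) continue;
    u[id] += f_fx[k];
    v[id] += f_fy[k];
  }
  enforce_solid_faces(u, v, mask, nx, ny);

  double a = visc * dt / (h * h);
  if (a > 0.0) {
    std::copy(u.begin(), u.end(), tmp.begin());
    diffuse_vel(u, tmp, mask, nx, ny, a, iters, 1);
    std::copy(v.begin(), v.end(), tmp.begin());
    diffuse_vel(v, tmp, mask, nx, ny, a, iters, 2);
    enforce_solid_faces(u, v, mask, nx, ny);
    // re-project the diffused field before self-advection; with zero
    // viscosity the field is already divergence-free up to the force
    // increments and the single post-advection projection suffices
    project(u, v, p, div, mask, nx, ny, iters, omega);
  }

  double dt0 = dt / h;
  NumericVector u0 = clone(u), v0 = clone(v);
  advect_vel(u, v, u0, v0, mask, nx, ny, dt0);
  project(u, v, p, div, mask, nx, ny, iters, omega);

  double ad = ddiff * dt / (h * h);
  double keep = std::exp(-evap * dt);
  int K = dye.size();
  for (int c = 0; c < K; ++c) {
    NumericVector d = dye[c];
    for (int k = 0; k < s_idx.size(); ++k) {
      if (s_chan[k] == c && mask[s_idx[k]]) d[s_idx[k]] += s_rate[k] * dt;
    }
    if (ad > 0.0) {
      std::copy(d.begin(), d.end(), tmp.begin());
      diffuse_scalar(d, tmp, mask, nx, ny, ad, iters);
    }
    set_bnd_scalar(d, mask, nx, ny);
    std::copy(d.begin(), d.end(), tmp.begin());
    advect_scalar(d, tmp, u, v, mask, nx, ny, dt0);
    for (int k = 0; k < n; ++k) {
      if (!mask[k]) { d[k] = 0.0; continue; }
      d[k] *= keep;
      if (d[k] < 0.0) d[k] = 0.0;
    }
  }

  for (int k = 0; k < n; ++k)
    if (!R_finite(u[k]) || !R_finite(v[k])) return false;
  for (int c = 0; c < K; ++c) {
    NumericVector d = dye[c];
    for (int k = 0; k < n; ++k) if (!R_finite(d[k])) return false;
  }
  return true;
}

// [[Rcpp::export]]
double cpp_bilinear_sample(NumericVector f, int nx, int ny,
                           double x, double y) {
  return sample_lattice(f, nx, ny, 0.5, 0.5, x, y);
}
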