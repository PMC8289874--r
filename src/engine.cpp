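// Coarse-grained bead-spring engine for nanopore ejection in a slit.
//
// Reduced units throughout: sigma = eps = bead mass = 1, t_u = sigma*sqrt(m/eps).
// Geometry: slit planes at z = 0 and z = H; cavity sphere (wall diameter D_C)
// centred at (0, 0, H/2); pore cylinder along +x with entrance plane tangent to
// the sphere of diameter D at x_ent = D/2 and exit at x_ent + lp.  D = Inf
// (translocation mode) replaces the sphere by a flat membrane at the entrance
// plane.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Geom {
  double H;          // slit gap height
  double x_ent;      // pore entrance plane
  double x_exit;     // pore exit plane
  double rpw;        // pore wall cylinder radius (= (dp + 0.52)/2)
  double Rcw;        // cavity wall sphere radius (= (D + 0.52)/2)
  bool   finiteD;
  double eps_w, sigma_w;
  double k, b0;
  double mouth;      // axial extent of the funnel zone in front of the entrance
};

struct FF {
  double rc2_pair;   // (2^{1/6})^2
  double rc_wall;    // (2/5)^{1/6} sigma_w
  double wall_shift; // (2/3) sqrt(5/2) eps_w
};

inline Geom read_geom(const List& g) {
  Geom G;
  G.H = as<double>(g["H"]);
  G.x_ent = as<double>(g["x_ent"]);
  G.x_exit = as<double>(g["x_exit"]);
  G.rpw = as<double>(g["rpw"]);
  double Rcw = as<double>(g["Rcw"]);
  G.finiteD = R_finite(Rcw);
  G.Rcw = Rcw;
  G.eps_w = as<double>(g["eps_w"]);
  G.sigma_w = as<double>(g["sigma_w"]);
  G.k = as<double>(g["k_spring"]);
  G.b0 = as<double>(g["b0"]);
  G.mouth = 1.5;  // pore-cylinder reach into the cavity (junction smoothing)
  return G;
}

// LJ 9-3 wall, shifted to zero at its minimum r = (2/5)^{1/6} sigma_w.
inline double wall_u(double r, const Geom& G, const FF& ff) {
  if (r >= ff.rc_wall) return 0.0;
  double x3 = std::pow(G.sigma_w / r, 3.0);
  double x9 = x3 * x3 * x3;
  return G.eps_w * ((2.0 / 15.0) * x9 - x3) + ff.wall_shift;
}
// -dU/dr (positive = repulsion away from the wall surface)
inline double wall_f(double r, const Geom& G, const FF& ff) {
  if (r >= ff.rc_wall) return 0.0;
  double s3 = std::pow(G.sigma_w, 3.0), s9 = s3 * s3 * s3;
  return G.eps_w * ((6.0 / 5.0) * s9 / std::pow(r, 10.0) -
                    3.0 * s3 / std::pow(r, 4.0));
}

// Accumulate the wall contribution for one bead; returns energy.
// fx/fy/fz may be null (energy-only evaluation).
//
// The accessible space is the union of the cavity sphere (wall radius Rcw),
// the pore cylinder (wall radius rpw, reaching a depth `mouth` into the
// cavity so the sphere-cylinder junction carries no spurious barrier) and
// the outer slit beyond the exit plane.  A bead interacts with the union
// boundary through the largest of the signed inside-distances, which makes
// the wall energy continuous everywhere; the slit planes act in addition.
inline double bead_wall(const double* p, const Geom& G, const FF& ff,
                        double* fx, double* fy, double* fz) {
  const double x = p[0], y = p[1], z = p[2];
  double U = 0.0;
  const double dmin = 1e-6;  // distance floor inside a wall

  // slit planes (always active)
  double dzl = std::max(z, dmin);
  double dzu = std::max(G.H - z, dmin);
  U += wall_u(dzl, G, ff) + wall_u(dzu, G, ff);
  if (fz) {
    *fz += wall_f(dzl, G, ff);
    *fz -= wall_f(dzu, G, ff);
  }

  const double dy = y, dz = z - G.H / 2.0;
  const double rho = std::sqrt(dy * dy + dz * dz);

  // candidate branches: signed inside-distance and unit gradient
  double d = -1e30, gx = 0, gy = 0, gz = 0;
  auto consider = [&](double di, double gxi, double gyi, double gzi) {
    if (di > d) { d = di; gx = gxi; gy = gyi; gz = gzi; }
  };

  // pore cylinder (radial margin, axially capped on the cavity side for
  // finite D; uncapped in translocation mode where the cis slit is open)
  double drad = G.rpw - rho;
  double grx = 0, gry = 0, grz = 0;
  if (rho > 1e-12) { gry = -dy / rho; grz = -dz / rho; }
  if (G.finiteD) {
    double dcap = x - (G.x_ent - G.mouth);
    if (dcap < drad) consider(dcap, 1, 0, 0);
    else consider(drad, grx, gry, grz);
  } else {
    consider(drad, grx, gry, grz);
  }

  // cavity sphere (finite D) or open cis half-space (D = Inf)
  if (G.finiteD) {
    double rr = std::sqrt(x * x + dy * dy + dz * dz);
    if (rr > 1e-12)
      consider(G.Rcw - rr, -x / rr, -dy / rr, -dz / rr);
    else
      consider(G.Rcw, 0, 0, 1);
  } else {
    consider(G.x_ent - x, -1, 0, 0);
  }

  // outer slit beyond the membrane
  consider(x - G.x_exit, 1, 0, 0);

  if (d < ff.rc_wall) {
    double dd = std::max(d, dmin);
    U += wall_u(dd, G, ff);
    if (fx) {
      double f = wall_f(dd, G, ff);
      *fx += f * gx; *fy += f * gy; *fz += f * gz;
    }
  }
  return U;
}

// Pair + bond + wall forces.  Returns potential energy; sets abort flag on
// bead overlap below `floor2`.
double compute_forces(const NumericMatrix& pos, const Geom& G, const FF& ff,
                      NumericMatrix* F, bool* overlap, double floor2) {
  const int N = pos.nrow();
  double U = 0.0;
  if (F)
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) (*F)(i, k) = 0.0;

  // non-bonded pairs (WCA), brute force below 64 beads, cell list above
  auto do_pair = [&](int i, int j) {
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= ff.rc2_pair) return;
    if (r2 < floor2) *overlap = true;
    double inv2 = 1.0 / r2;
    double inv6 = inv2 * inv2 * inv2;
    U += 4.0 * inv6 * (inv6 - 1.0) + 1.0;
    if (F) {
      double fr = 24.0 * inv6 * (2.0 * inv6 - 1.0) * inv2;
      (*F)(i, 0) += fr * dx; (*F)(j, 0) -= fr * dx;
      (*F)(i, 1) += fr * dy; (*F)(j, 1) -= fr * dy;
      (*F)(i, 2) += fr * dz; (*F)(j, 2) -= fr * dz;
    }
  };

  if (N <= 64) {
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) do_pair(i, j);
  } else {
    const double cell = 1.2;
    double xmin = pos(0, 0), xmax = xmin, ymin = pos(0, 1), ymax = ymin;
    for (int i = 1; i < N; ++i) {
      xmin = std::min(xmin, pos(i, 0)); xmax = std::max(xmax, pos(i, 0));
      ymin = std::min(ymin, pos(i, 1)); ymax = std::max(ymax, pos(i, 1));
    }
    int nx = std::max(1, (int)((xmax - xmin) / cell) + 1);
    int ny = std::max(1, (int)((ymax - ymin) / cell) + 1);
    std::vector<int> head((size_t)nx * ny, -1), nxt(N, -1), cx(N), cy(N);
    for (int i = 0; i < N; ++i) {
      int ix = std::min(nx - 1, (int)((pos(i, 0) - xmin) / cell));
      int iy = std::min(ny - 1, (int)((pos(i, 1) - ymin) / cell));
      cx[i] = ix; cy[i] = iy;
      int c = ix + nx * iy;
      nxt[i] = head[c]; head[c] = i;
    }
    for (int i = 0; i < N; ++i) {
      for (int ddx = -1; ddx <= 1; ++ddx) {
        int ix = cx[i] + ddx; if (ix < 0 || ix >= nx) continue;
        for (int ddy = -1; ddy <= 1; ++ddy) {
          int iy = cy[i] + ddy; if (iy < 0 || iy >= ny) continue;
          for (int j = head[ix + nx * iy]; j >= 0; j = nxt[j])
            if (j > i) do_pair(i, j);
        }
      }
    }
  }

  // bonds
  for (int i = 0; i < N - 1; ++i) {
    double dx = pos(i, 0) - pos(i + 1, 0);
    double dy = pos(i, 1) - pos(i + 1, 1);
    double dz = pos(i, 2) - pos(i + 1, 2);
    double b = std::sqrt(dx * dx + dy * dy + dz * dz);
    double stretch = b - G.b0;
    U += 0.5 * G.k * stretch * stretch;
    if (F && b > 1e-12) {
      double fr = -G.k * stretch / b;
      (*F)(i, 0) += fr * dx; (*F)(i + 1, 0) -= fr * dx;
      (*F)(i, 1) += fr * dy; (*F)(i + 1, 1) -= fr * dy;
      (*F)(i, 2) += fr * dz; (*F)(i + 1, 2) -= fr * dz;
    }
  }

  // walls
  for (int i = 0; i < N; ++i) {
    double fx = 0, fy = 0, fz = 0;
    const double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    U += bead_wall(p, G, ff, F ? &fx : nullptr, F ? &fy : nullptr,
                   F ? &fz : nullptr);
    if (F) { (*F)(i, 0) += fx; (*F)(i, 1) += fy; (*F)(i, 2) += fz; }
  }
  return U;
}

inline FF make_ff(const Geom& G) {
  FF ff;
  ff.rc2_pair = std::pow(2.0, 1.0 / 3.0);
  ff.rc_wall = std::pow(0.4, 1.0 / 6.0) * G.sigma_w;
  ff.wall_shift = (2.0 / 3.0) * std::sqrt(2.5) * G.eps_w;
  return ff;
}

}  // namespace

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, List geom) {
  Geom G = read_geom(geom);
  FF ff = make_ff(G);
  bool ov = false;
  return compute_forces(pos, G, ff, nullptr, &ov, 0.0);
}

// [[Rcpp::export]]
List cpp_total_forces(NumericMatrix pos, List geom) {
  Geom G = read_geom(geom);
  FF ff = make_ff(G);
  NumericMatrix F(pos.nrow(), 3);
  bool ov = false;
  double U = compute_forces(pos, G, ff, &F, &ov, 0.09);
  return List::create(_["forces"] = F, _["energy"] = U, _["overlap"] = ov);
}

// [[Rcpp::export]]
double cpp_wall_energy_at(NumericVector p, List geom) {
  Geom G = read_geom(geom);
  FF ff = make_ff(G);
  const double q[3] = {p[0], p[1], p[2]};
  return bead_wall(q, G, ff, nullptr, nullptr, nullptr);
}

// Langevin dynamics (BAOAB splitting).  With damp <= 0 the OU step is the
// identity and the scheme reduces to velocity Verlet.
//
// status: 0 = step count exhausted normally, 1 = terminated (s == N),
//         2 = aborted (overlap / non-finite coordinates).
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos, NumericMatrix vel, List geom,
                  double n_steps, double dt, double damp, double temperature,
                  double t0, int seed,
                  bool head_fixed, bool reflect_head, bool record_events,
                  bool terminate_on_exit, double fmax, int ke_stride) {
  Geom G = read_geom(geom);
  FF ff = make_ff(G);
  const int N = pos.nrow();
  NumericMatrix x = clone(pos), v = clone(vel);
  NumericMatrix F(N, 3);

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);

  const bool thermo = damp > 0.0;
  const double a = thermo ? std::exp(-dt / damp) : 1.0;
  const double b = thermo ? std::sqrt(temperature * (1.0 - a * a)) : 0.0;

  std::vector<double> ev_t, ke_hist;
  std::vector<int> ev_m, ev_s;
  int last_m = -1, last_s = -1;

  auto counts = [&](int* m, int* s) {
    int cm = 0, cs = 0;
    for (int i = 0; i < N; ++i) {
      if (x(i, 0) < G.x_ent) ++cm;
      else if (x(i, 0) >= G.x_exit) ++cs;
    }
    *m = cm; *s = cs;
  };
  auto cap = [&](int i) {
    if (fmax <= 0) return;
    double f2 = F(i, 0) * F(i, 0) + F(i, 1) * F(i, 1) + F(i, 2) * F(i, 2);
    if (f2 > fmax * fmax) {
      double sc = fmax / std::sqrt(f2);
      F(i, 0) *= sc; F(i, 1) *= sc; F(i, 2) *= sc;
    }
  };

  bool overlap = false;
  int status = 0;
  double t = t0;
  compute_forces(x, G, ff, &F, &overlap, 0.09);
  if (record_events) {
    counts(&last_m, &last_s);
    ev_t.push_back(t); ev_m.push_back(last_m); ev_s.push_back(last_s);
  }

  double step = 0;
  for (step = 0; step < n_steps; ++step) {
    // B half
    for (int i = head_fixed ? 1 : 0; i < N; ++i) {
      cap(i);
      for (int k = 0; k < 3; ++k) v(i, k) += 0.5 * dt * F(i, k);
    }
    // A half, O, A half
    for (int i = head_fixed ? 1 : 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) x(i, k) += 0.5 * dt * v(i, k);
    if (thermo)
      for (int i = head_fixed ? 1 : 0; i < N; ++i)
        for (int k = 0; k < 3; ++k) v(i, k) = a * v(i, k) + b * gauss(rng);
    for (int i = head_fixed ? 1 : 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) x(i, k) += 0.5 * dt * v(i, k);

    // reflective wall at the pore entrance, head monomer only
    if (reflect_head && x(0, 0) < G.x_ent) {
      x(0, 0) = 2.0 * G.x_ent - x(0, 0);
      v(0, 0) = -v(0, 0);
    }

    overlap = false;
    compute_forces(x, G, ff, &F, &overlap, 0.09);
    // B half
    for (int i = head_fixed ? 1 : 0; i < N; ++i) {
      cap(i);
      for (int k = 0; k < 3; ++k) v(i, k) += 0.5 * dt * F(i, k);
    }
    t = t0 + (step + 1) * dt;

    if (overlap && fmax <= 0) { status = 2; break; }
    if (!R_finite(x(0, 0)) || !R_finite(x(N - 1, 2))) { status = 2; break; }

    if (ke_stride > 0 && ((long long)(step + 1)) % ke_stride == 0) {
      double ke = 0;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < 3; ++k) ke += 0.5 * v(i, k) * v(i, k);
      ke_hist.push_back(ke);
    }

    if (record_events) {
      int cm, cs;
      counts(&cm, &cs);
      if (cm != last_m || cs != last_s) {
        ev_t.push_back(t); ev_m.push_back(cm); ev_s.push_back(cs);
        last_m = cm; last_s = cs;
      }
      if (terminate_on_exit && cs == N) { status = 1; ++step; break; }
    }
  }

  return List::create(
      _["positions"] = x, _["velocities"] = v, _["time"] = t,
      _["status"] = status, _["steps"] = step,
      _["events"] = DataFrame::create(_["t"] = ev_t, _["m"] = ev_m,
                                      _["s"] = ev_s),
      _["kinetic"] = NumericVector(ke_hist.begin(), ke_hist.end()));
}
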