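// Quasi-static relaxation core.
//
// One call runs up to max_iter gradient iterations on a fixed topology:
//   1. refit free-boundary arc radii so every boundary cell keeps its target
//      area (isolated cells update their disk radius analytically);
//   2. boundary-cell pressures from the Laplace law P = eta_out / r;
//   3. interior-cell pressures from the area-constraint system
//      sigma * grad(A_i) . F(P) = clamp(target_i - A_i), a symmetric
//      positive-definite Gram system solved matrix-free by preconditioned
//      conjugate gradients (warm-started);
//   4. vertex update v += sigma * F with a per-vertex displacement cap.
// The call returns early when the maximum vertex force falls below eps
// (stationary state) or when a new short inner edge appears (so the caller
// can dispatch a T1 event before geometry degenerates).
//
// Index conventions: all indices are 0-based and compacted by the R caller;
// cell -1 is the exterior.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double R_FLAT_C = 1e6;

struct Mesh {
  // half-edges
  std::vector<int> origin, twin, next, cell, kind; // kind: 0 inner, 1 outer
  std::vector<double> eta;                         // physical eta (cell side)
  // vertices
  std::vector<double> vx, vy;
  // cells
  std::vector<int> boundary;   // half-edge index or -1 (isolated)
  std::vector<double> eta_out, target, arc_r, radius;
  std::vector<int> interior;   // 1 if fully polygonal
  std::vector<int> major;      // single-arc cells: arc spans more than pi
  std::vector<int> n_arc;      // number of outer edges
  // derived
  std::vector<std::vector<int>> cyc;  // boundary cycle per cell
  int nhe, nvx, ncl;
};

static double seg_area(double r, double half_chord) {
  double s = half_chord / r;
  if (s > 1.0) s = 1.0;
  double th = 2.0 * std::asin(s);
  return r * r * (th - std::sin(th)) / 2.0;
}

// polygon (chord) area of a cell cycle
static double poly_area(const Mesh& M, int c) {
  const std::vector<int>& cy = M.cyc[c];
  double a = 0.0;
  size_t n = cy.size();
  for (size_t k = 0; k < n; ++k) {
    int v1 = M.origin[cy[k]];
    int v2 = M.origin[cy[(k + 1) % n]];
    a += M.vx[v1] * M.vy[v2] - M.vx[v2] * M.vy[v1];
  }
  return a / 2.0;
}

// chord lengths of the outer (arc) edges of cell c
static void outer_chords(const Mesh& M, int c, std::vector<double>& L) {
  L.clear();
  const std::vector<int>& cy = M.cyc[c];
  size_t n = cy.size();
  for (size_t k = 0; k < n; ++k) {
    int h = cy[k];
    if (M.kind[h] == 1) {
      int v1 = M.origin[h];
      int v2 = M.origin[cy[(k + 1) % n]];
      double dx = M.vx[v2] - M.vx[v1], dy = M.vy[v2] - M.vy[v1];
      L.push_back(std::sqrt(dx * dx + dy * dy));
    }
  }
}

// total segment area of arcs with shared radius r
static double seg_sum(const std::vector<double>& L, double r) {
  double s = 0.0;
  for (double l : L) s += seg_area(r, l / 2.0);
  return s;
}

// single-arc cells: solve the central angle theta so the segment area
// equals |need| (strictly increasing in theta); outward arcs may be major
// (theta up to ~2*pi), inward arcs stay minor (theta up to pi)
static double refit_theta(double L, double need, double hi_cap) {
  auto seg_of = [&](double th) {
    double r = L / (2.0 * std::sin(th / 2.0));
    return r * r * (th - std::sin(th)) / 2.0;
  };
  double lo = 1e-6, hi = hi_cap;
  if (seg_of(hi) <= need) return hi;
  for (int i = 0; i < 70; ++i) {
    double th = (lo + hi) / 2.0;
    if (seg_of(th) < need) lo = th; else hi = th;
  }
  return (lo + hi) / 2.0;
}

// refit the shared arc radius of cell c so area == target (monotone
// decreasing in r; clamped at half circles / flat)
static double refit_radius(const std::vector<double>& L, double need) {
  double lmax = 0.0;
  for (double l : L) if (l > lmax) lmax = l;
  if (lmax <= 0.0) return R_FLAT_C;
  if (need <= 0.0) return R_FLAT_C;
  double rlo = lmax / 2.0;
  if (seg_sum(L, rlo) <= need) return rlo;  // clamp at half circles
  double rhi = R_FLAT_C;
  for (int i = 0; i < 70; ++i) {
    double rm = std::sqrt(rlo * rhi);
    if (seg_sum(L, rm) > need) rlo = rm; else rhi = rm;
    if (rhi / rlo < 1.0 + 1e-13) break;
  }
  return std::sqrt(rlo * rhi);
}

// [[Rcpp::export]]
List relax_core(IntegerVector he_origin, IntegerVector he_twin,
                IntegerVector he_next, IntegerVector he_cell,
                IntegerVector he_kind, NumericVector he_eta,
                NumericVector vxx, NumericVector vxy,
                IntegerVector cl_boundary, NumericVector cl_eta_out,
                NumericVector cl_target, NumericVector cl_arc_r,
                NumericVector cl_radius, LogicalVector cl_arc_major,
                NumericVector P_warm,
                double sigma, double eps, int max_iter, int mode,
                double dmax, double dA_max, double area_tol,
                double t1_length, LogicalVector short_ok,
                NumericVector vel_x, NumericVector vel_y,
                NumericVector fire_state) {
  Mesh M;
  M.nhe = he_origin.size();
  M.nvx = vxx.size();
  M.ncl = cl_boundary.size();
  M.origin.assign(he_origin.begin(), he_origin.end());
  M.twin.assign(he_twin.begin(), he_twin.end());
  M.next.assign(he_next.begin(), he_next.end());
  M.cell.assign(he_cell.begin(), he_cell.end());
  M.kind.assign(he_kind.begin(), he_kind.end());
  M.eta.assign(he_eta.begin(), he_eta.end());
  M.vx.assign(vxx.begin(), vxx.end());
  M.vy.assign(vxy.begin(), vxy.end());
  M.boundary.assign(cl_boundary.begin(), cl_boundary.end());
  M.eta_out.assign(cl_eta_out.begin(), cl_eta_out.end());
  M.target.assign(cl_target.begin(), cl_target.end());
  M.arc_r.assign(cl_arc_r.begin(), cl_arc_r.end());
  M.radius.assign(cl_radius.begin(), cl_radius.end());
  M.major.assign(cl_arc_major.begin(), cl_arc_major.end());

  // input sanity: every index in range (a corrupted mesh must fail loudly
  // here, not scribble over the heap)
  for (int h = 0; h < M.nhe; ++h) {
    if (M.origin[h] < 0 || M.origin[h] >= M.nvx)
      Rcpp::stop("half-edge %d: origin out of range", h + 1);
    if (M.twin[h] < 0 || M.twin[h] >= M.nhe)
      Rcpp::stop("half-edge %d: twin out of range", h + 1);
    if (M.next[h] < 0 || M.next[h] >= M.nhe)
      Rcpp::stop("half-edge %d: next out of range", h + 1);
    if (M.cell[h] < -1 || M.cell[h] >= M.ncl)
      Rcpp::stop("half-edge %d: cell out of range", h + 1);
  }
  for (int c = 0; c < M.ncl; ++c) {
    if (M.boundary[c] >= M.nhe)
      Rcpp::stop("cell %d: boundary out of range", c + 1);
  }

  // build cycles, interior flags, arc counts
  M.cyc.assign(M.ncl, std::vector<int>());
  M.interior.assign(M.ncl, 0);
  M.n_arc.assign(M.ncl, 0);
  for (int c = 0; c < M.ncl; ++c) {
    int b = M.boundary[c];
    if (b < 0) continue;   // isolated
    int h = b;
    int na = 0;
    do {
      M.cyc[c].push_back(h);
      if ((int)M.cyc[c].size() > M.nhe)
        Rcpp::stop("boundary cycle of a cell does not close");
      if (M.kind[h] == 1) ++na;
      h = M.next[h];
      if (h < 0 || h >= M.nhe) Rcpp::stop("broken next pointer");
    } while (h != b);
    M.n_arc[c] = na;
    M.interior[c] = na == 0 ? 1 : 0;
  }
  std::vector<int> interior_ids;
  for (int c = 0; c < M.ncl; ++c) if (M.interior[c]) interior_ids.push_back(c);
  int ni = (int)interior_ids.size();

  // physical inner edges (cell side, one per pair) and cell-side arcs
  std::vector<int> inner_edges, arc_edges;
  for (int h = 0; h < M.nhe; ++h) {
    if (M.cell[h] < 0) continue;
    if (M.kind[h] == 0) { if (h < M.twin[h] || M.cell[M.twin[h]] < 0) inner_edges.push_back(h); }
    else arc_edges.push_back(h);
  }
  // deduplicate inner pairs properly: keep h if h < twin(h)
  {
    std::vector<int> tmp;
    for (int h : inner_edges) if (h < M.twin[h]) tmp.push_back(h);
    inner_edges.swap(tmp);
  }

  std::vector<double> P(M.ncl, 0.0);
  for (int c = 0; c < M.ncl; ++c) P[c] = P_warm[c];
  std::vector<double> area(M.ncl, 0.0), polyar(M.ncl, 0.0);
  std::vector<double> F0x(M.nvx), F0y(M.nvx), Fx(M.nvx), Fy(M.nvx);
  std::vector<double> wx(M.nvx), wy(M.nvx);
  // area gradients of interior cells, stored per (cell, cycle position)
  std::vector<std::vector<double>> gx(ni), gy(ni);
  std::vector<double> pvec(ni, 0.0), rvec(ni), zvec(ni), dvec(ni), qvec(ni),
      diag(ni), rhs(ni);
  for (int a = 0; a < ni; ++a) {
    size_t n = M.cyc[interior_ids[a]].size();
    gx[a].resize(n); gy[a].resize(n);
    pvec[a] = P[interior_ids[a]];
  }
  std::vector<double> chords;

  int it = 0;
  double maxF = R_PosInf;
  bool converged = false, guard = false;
  int guard_he = -1;
  // FIRE (fast inertial relaxation engine) state: semi-implicit Euler with
  // velocity mixing and adaptive time step; quenches on uphill power.
  // Velocities persist across calls (passed in/out) so chunked execution
  // does not lose momentum.
  std::vector<double> velx(vel_x.begin(), vel_x.end());
  std::vector<double> vely(vel_y.begin(), vel_y.end());
  const double dt_max = 50.0 * sigma, dt_min = 0.02 * sigma;
  double dt = fire_state.size() > 0 && fire_state[0] > 0 ? fire_state[0] : sigma;
  double alpha = fire_state.size() > 1 && fire_state[1] > 0 ? fire_state[1] : 0.1;
  int n_pos = fire_state.size() > 2 ? (int)fire_state[2] : 0;

  for (it = 0; it < max_iter; ++it) {
    // ---- geometry + arc refit + boundary pressures ----
    double area_err = 0.0;
    for (int c = 0; c < M.ncl; ++c) {
      if (M.boundary[c] < 0) {              // isolated disk
        M.radius[c] = std::sqrt(std::max(M.target[c], 1e-12) / M_PI);
        area[c] = M_PI * M.radius[c] * M.radius[c];
        polyar[c] = area[c];
        P[c] = M.eta_out[c] / M.radius[c];
        continue;
      }
      double ap = poly_area(M, c);
      polyar[c] = ap;
      if (M.interior[c]) {
        area[c] = ap;
        double e = std::fabs(M.target[c] - ap);
        if (e > area_err) area_err = e;
      } else {
        // Free-boundary bulge dynamics. The target-area fit gives a radius
        // r_fit; rather than adopting it instantly (which makes pressure an
        // extremely stiff function of the junction positions and sets off
        // oscillations at deeply bulged arcs), the shared bulge moves toward
        // the fit with the same per-iteration displacement cap as a vertex.
        // The smooth parameter is the sagitta s of the largest-chord arc:
        // s in (0, L/2) minor outward, s > L/2 major, s < 0 inward; the
        // radius, branch and Laplace pressure follow from s.
        outer_chords(M, c, chords);
        double need = M.target[c] - ap;
        double sgn = need < 0.0 ? -1.0 : 1.0;   // negative: inward bulge
        double mag = std::fabs(need);
        double Lmax = 0.0;
        for (double l : chords) if (l > Lmax) Lmax = l;
        // fitted radius and branch
        double r_fit; int major_fit = 0;
        if (mag < 1e-14) {
          r_fit = sgn * R_FLAT_C;
        } else if (M.n_arc[c] == 1) {
          double cap_th = sgn > 0.0 ? 2.0 * M_PI - 0.05 : M_PI;
          double th = refit_theta(chords[0], mag, cap_th);
          double r = chords[0] / (2.0 * std::sin(th / 2.0));
          if (r > R_FLAT_C) r = R_FLAT_C;
          r_fit = sgn * r;
          major_fit = (sgn > 0.0 && th > M_PI) ? 1 : 0;
        } else {
          r_fit = sgn * refit_radius(chords, mag);
        }
        auto sag_of = [&](double r_signed, int major) {
          double r = std::fabs(r_signed);
          if (r < Lmax / 2.0) r = Lmax / 2.0;
          double h = std::sqrt(std::max(r * r - Lmax * Lmax / 4.0, 0.0));
          double sagn = r_signed < 0 ? -1.0 : 1.0;
          return sagn * (major ? r + h : r - h);
        };
        double s_cur = sag_of(M.arc_r[c], M.major[c]);
        double s_fit = sag_of(r_fit, major_fit);
        double ds = s_fit - s_cur;
        double scap = dmax;
        if (ds > scap) ds = scap;
        if (ds < -scap) ds = -scap;
        double s_new = s_cur + ds;
        // back to radius and branch (s -> r is smooth through s = L/2)
        double s_abs = std::fabs(s_new);
        double r_new;
        if (s_abs < 1e-7) {
          r_new = R_FLAT_C;
          M.major[c] = 0;
        } else {
          r_new = (s_abs * s_abs + Lmax * Lmax / 4.0) / (2.0 * s_abs);
          if (r_new > R_FLAT_C) r_new = R_FLAT_C;
          M.major[c] = (s_new > 0 && s_abs > Lmax / 2.0) ? 1 : 0;
        }
        M.arc_r[c] = (s_new < 0 ? -1.0 : 1.0) * r_new;
        // actual area with the relaxed bulge
        double s_act;
        if (M.n_arc[c] == 1 && M.major[c]) {
          double thm = 2.0 * std::asin(std::min(1.0, chords[0] / (2.0 * r_new)));
          double th = 2.0 * M_PI - thm;
          s_act = r_new * r_new * (th - std::sin(th)) / 2.0;
        } else {
          s_act = seg_sum(chords, r_new);
        }
        area[c] = ap + (M.arc_r[c] < 0 ? -s_act : s_act);
        double aerr = std::fabs(M.target[c] - area[c]);
        if (aerr > area_err) area_err = aerr;
        P[c] = M.eta_out[c] / M.arc_r[c];
      }
    }

    // ---- base forces: tension everywhere + pressure from known cells ----
    std::fill(F0x.begin(), F0x.end(), 0.0);
    std::fill(F0y.begin(), F0y.end(), 0.0);
    double min_new_short = R_PosInf;
    for (int h : inner_edges) {
      int a = M.origin[h], b = M.origin[M.twin[h]];
      double ex = M.vx[b] - M.vx[a], ey = M.vy[b] - M.vy[a];
      double L = std::sqrt(ex * ex + ey * ey);
      if (L < t1_length && !short_ok[h]) {
        if (L < min_new_short) { min_new_short = L; guard_he = h; }
      }
      if (L < 1e-14) continue;
      double ux = ex / L, uy = ey / L;
      double m = (mode == 1) ? M.eta[h] * L : M.eta[h];
      F0x[a] += m * ux; F0y[a] += m * uy;
      F0x[b] -= m * ux; F0y[b] -= m * uy;
      // pressure: per-side contribution P_c * L/2 * n_out(c); add only for
      // cells with known pressure (non-interior); interior handled in solve
      int ci = M.cell[h], cj = M.cell[M.twin[h]];
      double nx = ey / L, ny = -ex / L;    // outward normal of cell ci
      if (!M.interior[ci]) {
        F0x[a] += P[ci] * L / 2.0 * nx; F0y[a] += P[ci] * L / 2.0 * ny;
        F0x[b] += P[ci] * L / 2.0 * nx; F0y[b] += P[ci] * L / 2.0 * ny;
      }
      if (!M.interior[cj]) {
        F0x[a] -= P[cj] * L / 2.0 * nx; F0y[a] -= P[cj] * L / 2.0 * ny;
        F0x[b] -= P[cj] * L / 2.0 * nx; F0y[b] -= P[cj] * L / 2.0 * ny;
      }
    }
    for (int h : arc_edges) {
      int c = M.cell[h];
      int a = M.origin[h], b = M.origin[M.twin[h]];
      double ex = M.vx[b] - M.vx[a], ey = M.vy[b] - M.vy[a];
      double L = std::sqrt(ex * ex + ey * ey);
      if (L < t1_length && !short_ok[h]) {
        if (guard_he < 0) guard_he = h;
      }
      if (L < 1e-14) continue;
      bool inward = M.arc_r[c] < 0.0;
      double r = std::max(std::fabs(M.arc_r[c]), L / 2.0);
      double h2 = std::sqrt(std::max(r * r - L * L / 4.0, 0.0));
      // major and inward arcs have the center on the exterior side
      if (M.major[c] || inward) h2 = -h2;
      // interior is left of a->b
      double cxm = (M.vx[a] + M.vx[b]) / 2.0 - ey / L * h2;
      double cym = (M.vy[a] + M.vy[b]) / 2.0 + ex / L * h2;
      double th = 2.0 * std::asin(std::min(1.0, L / (2.0 * r)));
      if (M.major[c]) th = 2.0 * M_PI - th;
      double m = (mode == 1) ? M.eta[h] * r * th : M.eta[h];
      double sweep = inward ? -1.0 : 1.0;
      // travel tangent t(p) = sweep * perp(p - center)
      double tax = sweep * -(M.vy[a] - cym), tay = sweep * (M.vx[a] - cxm);
      double tn = std::sqrt(tax * tax + tay * tay);
      if (tn > 1e-14) { F0x[a] += m * tax / tn; F0y[a] += m * tay / tn; }
      double tbx = sweep * -(M.vy[b] - cym), tby = sweep * (M.vx[b] - cxm);
      tn = std::sqrt(tbx * tbx + tby * tby);
      if (tn > 1e-14) { F0x[b] -= m * tbx / tn; F0y[b] -= m * tby / tn; }
    }
    if (guard_he >= 0) { guard = true; break; }

    // ---- interior pressure solve (PCG on the area-gradient Gram matrix) ---
    if (ni > 0) {
      for (int a = 0; a < ni; ++a) {
        int c = interior_ids[a];
        const std::vector<int>& cy = M.cyc[c];
        size_t n = cy.size();
        double dsum = 0.0, fdot = 0.0;
        for (size_t k = 0; k < n; ++k) {
          int vp = M.origin[cy[(k + n - 1) % n]];
          int v = M.origin[cy[k]];
          int vn = M.origin[cy[(k + 1) % n]];
          double gxx = (M.vy[vn] - M.vy[vp]) / 2.0;
          double gyy = (M.vx[vp] - M.vx[vn]) / 2.0;
          gx[a][k] = gxx; gy[a][k] = gyy;
          dsum += gxx * gxx + gyy * gyy;
          fdot += gxx * F0x[v] + gyy * F0y[v];
        }
        diag[a] = dsum > 1e-14 ? dsum : 1.0;
        // restore area errors gradually (rate-limited feedback): demanding
        // the full correction in one step makes the constraint a stiff
        // oscillator against the displacement cap
        double err = 0.2 * (M.target[interior_ids[a]] - area[interior_ids[a]]);
        if (err > dA_max) err = dA_max;
        if (err < -dA_max) err = -dA_max;
        rhs[a] = err / sigma - fdot;
      }
      // matrix-free y = G p
      auto applyG = [&](const std::vector<double>& p, std::vector<double>& y) {
        std::fill(wx.begin(), wx.end(), 0.0);
        std::fill(wy.begin(), wy.end(), 0.0);
        for (int a = 0; a < ni; ++a) {
          const std::vector<int>& cy = M.cyc[interior_ids[a]];
          for (size_t k = 0; k < cy.size(); ++k) {
            int v = M.origin[cy[k]];
            wx[v] += p[a] * gx[a][k];
            wy[v] += p[a] * gy[a][k];
          }
        }
        for (int a = 0; a < ni; ++a) {
          const std::vector<int>& cy = M.cyc[interior_ids[a]];
          double s = 0.0;
          for (size_t k = 0; k < cy.size(); ++k) {
            int v = M.origin[cy[k]];
            s += gx[a][k] * wx[v] + gy[a][k] * wy[v];
          }
          y[a] = s;
        }
      };
      applyG(pvec, qvec);
      double rnorm0 = 0.0;
      for (int a = 0; a < ni; ++a) {
        rvec[a] = rhs[a] - qvec[a];
        rnorm0 += rvec[a] * rvec[a];
      }
      double tol2 = 1e-20 * (ni > 0 ? ni : 1);
      if (rnorm0 > tol2) {
        double rz = 0.0;
        for (int a = 0; a < ni; ++a) { zvec[a] = rvec[a] / diag[a]; rz += rvec[a] * zvec[a]; }
        dvec = zvec;
        for (int cg = 0; cg < 200; ++cg) {
          applyG(dvec, qvec);
          double dq = 0.0;
          for (int a = 0; a < ni; ++a) dq += dvec[a] * qvec[a];
          if (std::fabs(dq) < 1e-300) break;
          double alpha = rz / dq;
          double rnorm = 0.0;
          for (int a = 0; a < ni; ++a) {
            pvec[a] += alpha * dvec[a];
            rvec[a] -= alpha * qvec[a];
            rnorm += rvec[a] * rvec[a];
          }
          if (rnorm < tol2 || rnorm < 1e-16 * rnorm0) break;
          double rz_new = 0.0;
          for (int a = 0; a < ni; ++a) { zvec[a] = rvec[a] / diag[a]; rz_new += rvec[a] * zvec[a]; }
          double beta = rz_new / rz;
          rz = rz_new;
          for (int a = 0; a < ni; ++a) dvec[a] = zvec[a] + beta * dvec[a];
        }
      }
      for (int a = 0; a < ni; ++a) P[interior_ids[a]] = pvec[a];
    }

    // ---- total forces ----
    std::copy(F0x.begin(), F0x.end(), Fx.begin());
    std::copy(F0y.begin(), F0y.end(), Fy.begin());
    for (int a = 0; a < ni; ++a) {
      const std::vector<int>& cy = M.cyc[interior_ids[a]];
      for (size_t k = 0; k < cy.size(); ++k) {
        int v = M.origin[cy[k]];
        Fx[v] += pvec[a] * gx[a][k];
        Fy[v] += pvec[a] * gy[a][k];
      }
    }
    maxF = 0.0;
    for (int v = 0; v < M.nvx; ++v) {
      double f = std::sqrt(Fx[v] * Fx[v] + Fy[v] * Fy[v]);
      if (f > maxF) maxF = f;
    }
    if (maxF <= eps && area_err <= area_tol) { converged = true; break; }

    // ---- FIRE vertex update ----
    double power = 0.0, v2 = 0.0, f2 = 0.0;
    for (int v = 0; v < M.nvx; ++v) {
      power += Fx[v] * velx[v] + Fy[v] * vely[v];
      v2 += velx[v] * velx[v] + vely[v] * vely[v];
      f2 += Fx[v] * Fx[v] + Fy[v] * Fy[v];
    }
    if (power > 0.0) {
      if (++n_pos > 5) { dt = std::min(dt * 1.1, dt_max); alpha *= 0.99; }
      double ratio = f2 > 0.0 ? std::sqrt(v2 / f2) : 0.0;
      for (int v = 0; v < M.nvx; ++v) {
        velx[v] = (1.0 - alpha) * velx[v] + alpha * Fx[v] * ratio;
        vely[v] = (1.0 - alpha) * vely[v] + alpha * Fy[v] * ratio;
      }
    } else {
      n_pos = 0; dt = std::max(dt * 0.5, dt_min); alpha = 0.1;
      std::fill(velx.begin(), velx.end(), 0.0);
      std::fill(vely.begin(), vely.end(), 0.0);
    }
    // per-vertex displacement cap: a fraction of the shortest incident
    // element, so stiff features (deep small arcs, short walls) advance in
    // small steps without throttling the rest of the tissue
    std::vector<double> dcap(M.nvx, dmax);
    for (int h = 0; h < M.nhe; ++h) {
      if (M.cell[h] < 0) continue;
      int a = M.origin[h], b = M.origin[M.twin[h]];
      double ex = M.vx[b] - M.vx[a], ey = M.vy[b] - M.vy[a];
      double L = 0.2 * std::sqrt(ex * ex + ey * ey);
      if (L < dcap[a]) dcap[a] = L;
      if (L < dcap[b]) dcap[b] = L;
    }
    for (int v = 0; v < M.nvx; ++v) {
      double cap = std::max(dcap[v], 0.2 * t1_length);
      velx[v] += dt * Fx[v];
      vely[v] += dt * Fy[v];
      double dx = dt * velx[v], dy = dt * vely[v];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > cap) {
        double f = cap / d;
        dx *= f; dy *= f;
        velx[v] *= f; vely[v] *= f;   // bleed capped momentum
      }
      M.vx[v] += dx;
      M.vy[v] += dy;
    }
  }

  return List::create(
    _["vx"] = NumericVector(M.vx.begin(), M.vx.end()),
    _["vy"] = NumericVector(M.vy.begin(), M.vy.end()),
    _["arc_r"] = NumericVector(M.arc_r.begin(), M.arc_r.end()),
    _["arc_major"] = LogicalVector(M.major.begin(), M.major.end()),
    _["radius"] = NumericVector(M.radius.begin(), M.radius.end()),
    _["pressure"] = NumericVector(P.begin(), P.end()),
    _["area"] = NumericVector(area.begin(), area.end()),
    _["poly_area"] = NumericVector(polyar.begin(), polyar.end()),
    _["fx"] = NumericVector(Fx.begin(), Fx.end()),
    _["fy"] = NumericVector(Fy.begin(), Fy.end()),
    _["vel_x"] = NumericVector(velx.begin(), velx.end()),
    _["vel_y"] = NumericVector(vely.begin(), vely.end()),
    _["fire_state"] = NumericVector::create(dt, alpha, (double)n_pos),
    _["iterations"] = it,
    _["max_force"] = maxF,
    _["converged"] = converged,
    _["guard"] = guard,
    _["guard_he"] = guard_he);
}
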