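// Compiled core of the mechanochemical cell model: elastic membrane forces,
// Green-Lagrange surface strain, and the full overdamped simulation loop
// (adaptive linearly implicit integration + Monte Carlo adhesion chemistry +
// stress-fiber lifecycle + lamellipodial protrusion).
//
// Units: nm, s, pN throughout (1 pN/nm = 1e-3 N/m; 1 pN s/nm = 1e-3 N s/m;
// 1 pN/um^2 = 1 Pa).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Elastic forces: exact negative gradient of
//   E = k_line/2 sum_e (L - L0)^2  +  k_area/2 sum_t (A - A0)^2 / A0.
// Edge and triangle indices are 0-based.
// [[Rcpp::export]]
NumericMatrix elastic_forces_cpp(NumericMatrix pos, IntegerMatrix edges,
                                 IntegerMatrix tris, NumericVector refL,
                                 NumericVector refA, double k_line,
                                 double k_area) {
  const int n = pos.nrow();
  NumericMatrix F(n, 3);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    double d[3] = {pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1),
                   pos(i, 2) - pos(j, 2)};
    double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (L <= 0) stop("degenerate edge %d", e + 1);
    double c = -k_line * (L - refL[e]) / L;
    for (int ax = 0; ax < 3; ++ax) {
      F(i, ax) += c * d[ax];
      F(j, ax) -= c * d[ax];
    }
  }
  for (int t = 0; t < tris.nrow(); ++t) {
    int a = tris(t, 0), b = tris(t, 1), c = tris(t, 2);
    double u[3] = {pos(b, 0) - pos(a, 0), pos(b, 1) - pos(a, 1),
                   pos(b, 2) - pos(a, 2)};
    double v[3] = {pos(c, 0) - pos(a, 0), pos(c, 1) - pos(a, 1),
                   pos(c, 2) - pos(a, 2)};
    double nrm[3];
    cross3(u, v, nrm);
    double n2 = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] +
                          nrm[2] * nrm[2]);
    if (n2 <= 0) stop("degenerate triangle %d", t + 1);
    double A = n2 / 2.0;
    for (int ax = 0; ax < 3; ++ax) nrm[ax] /= n2;
    double coef = -k_area * (A - refA[t]) / refA[t];
    // grad_a A = 0.5 nhat x (xc - xb), cyclic
    double eBC[3] = {pos(c, 0) - pos(b, 0), pos(c, 1) - pos(b, 1),
                     pos(c, 2) - pos(b, 2)};
    double eCA[3] = {pos(a, 0) - pos(c, 0), pos(a, 1) - pos(c, 1),
                     pos(a, 2) - pos(c, 2)};
    double eAB[3] = {pos(b, 0) - pos(a, 0), pos(b, 1) - pos(a, 1),
                     pos(b, 2) - pos(a, 2)};
    double g[3];
    cross3(nrm, eBC, g);
    for (int ax = 0; ax < 3; ++ax) F(a, ax) += coef * 0.5 * g[ax];
    cross3(nrm, eCA, g);
    for (int ax = 0; ax < 3; ++ax) F(b, ax) += coef * 0.5 * g[ax];
    cross3(nrm, eAB, g);
    for (int ax = 0; ax < 3; ++ax) F(c, ax) += coef * 0.5 * g[ax];
  }
  return F;
}

// Per-triangle 2-D Green-Lagrange strain pushed to 3-D (components on the
// current triangle basis), area-weight averaged at nodes, projected onto the
// node tangent plane; returns principal values and 3-D directions.
// [[Rcpp::export]]
List surface_strain_cpp(NumericMatrix pos, NumericMatrix refpos,
                        IntegerMatrix tris, NumericMatrix normals) {
  const int n = pos.nrow();
  std::vector<double> Eacc(9 * n, 0.0), Wacc(n, 0.0);
  for (int t = 0; t < tris.nrow(); ++t) {
    int a = tris(t, 0), b = tris(t, 1), c = tris(t, 2);
    double u0[3], v0[3], u[3], v[3];
    for (int ax = 0; ax < 3; ++ax) {
      u0[ax] = refpos(b, ax) - refpos(a, ax);
      v0[ax] = refpos(c, ax) - refpos(a, ax);
      u[ax] = pos(b, ax) - pos(a, ax);
      v[ax] = pos(c, ax) - pos(a, ax);
    }
    double n0[3], nc[3];
    cross3(u0, v0, n0);
    cross3(u, v, nc);
    double ln0 = std::sqrt(n0[0] * n0[0] + n0[1] * n0[1] + n0[2] * n0[2]);
    double lnc = std::sqrt(nc[0] * nc[0] + nc[1] * nc[1] + nc[2] * nc[2]);
    if (ln0 <= 0) stop("degenerate reference triangle %d", t + 1);
    if (lnc <= 0) stop("degenerate triangle %d", t + 1);
    double lu0 = std::sqrt(u0[0] * u0[0] + u0[1] * u0[1] + u0[2] * u0[2]);
    double lu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    // local orthonormal bases (e1 along first edge, e2 in-plane)
    double e2r[3], e2c[3];
    double nh0[3] = {n0[0] / ln0, n0[1] / ln0, n0[2] / ln0};
    double nhc[3] = {nc[0] / lnc, nc[1] / lnc, nc[2] / lnc};
    double e1r[3] = {u0[0] / lu0, u0[1] / lu0, u0[2] / lu0};
    double e1c[3] = {u[0] / lu, u[1] / lu, u[2] / lu};
    cross3(nh0, e1r, e2r);
    cross3(nhc, e1c, e2c);
    // 2-D coordinates of the third vertex
    double p3x = v0[0] * e1r[0] + v0[1] * e1r[1] + v0[2] * e1r[2];
    double p3y = v0[0] * e2r[0] + v0[1] * e2r[1] + v0[2] * e2r[2];
    double q3x = v[0] * e1c[0] + v[1] * e1c[1] + v[2] * e1c[2];
    double q3y = v[0] * e2c[0] + v[1] * e2c[1] + v[2] * e2c[2];
    // F = Q P^{-1}, P = [[lu0, p3x],[0, p3y]], Q = [[lu, q3x],[0, q3y]]
    double F11 = lu / lu0;
    double F12 = (q3x - F11 * p3x) / p3y;
    double F21 = 0.0;
    double F22 = q3y / p3y;
    double E11 = 0.5 * (F11 * F11 + F21 * F21 - 1.0);
    double E12 = 0.5 * (F11 * F12 + F21 * F22);
    double E22 = 0.5 * (F12 * F12 + F22 * F22 - 1.0);
    double A = lnc / 2.0;
    for (int vi = 0; vi < 3; ++vi) {
      int node = tris(t, vi);
      double* Ea = &Eacc[9 * node];
      for (int r = 0; r < 3; ++r) {
        for (int s = 0; s < 3; ++s) {
          double val = E11 * e1c[r] * e1c[s] + E22 * e2c[r] * e2c[s] +
                       E12 * (e1c[r] * e2c[s] + e2c[r] * e1c[s]);
          Ea[3 * r + s] += A * val;
        }
      }
      Wacc[node] += A;
    }
  }
  NumericVector emin(n), emax(n);
  NumericMatrix dmin(n, 3), dmax(n, 3);
  for (int i = 0; i < n; ++i) {
    double nrm[3] = {normals(i, 0), normals(i, 1), normals(i, 2)};
    // tangent basis
    double t1[3];
    if (std::fabs(nrm[0]) < 0.9) {
      t1[0] = 1 - nrm[0] * nrm[0];
      t1[1] = -nrm[0] * nrm[1];
      t1[2] = -nrm[0] * nrm[2];
    } else {
      t1[0] = -nrm[1] * nrm[0];
      t1[1] = 1 - nrm[1] * nrm[1];
      t1[2] = -nrm[1] * nrm[2];
    }
    double lt = std::sqrt(t1[0] * t1[0] + t1[1] * t1[1] + t1[2] * t1[2]);
    for (int ax = 0; ax < 3; ++ax) t1[ax] /= lt;
    double t2[3];
    cross3(nrm, t1, t2);
    double* Ea = &Eacc[9 * i];
    double w = Wacc[i] > 0 ? Wacc[i] : 1.0;
    double m11 = 0, m12 = 0, m22 = 0;
    for (int r = 0; r < 3; ++r) {
      for (int s = 0; s < 3; ++s) {
        double e = Ea[3 * r + s] / w;
        m11 += t1[r] * e * t1[s];
        m12 += t1[r] * e * t2[s];
        m22 += t2[r] * e * t2[s];
      }
    }
    double tr = m11 + m22;
    double disc = std::sqrt(0.25 * (m11 - m22) * (m11 - m22) + m12 * m12);
    double lmin = tr / 2 - disc, lmax = tr / 2 + disc;
    emin[i] = lmin;
    emax[i] = lmax;
    // eigenvector for lmin
    double vx, vy;
    if (std::fabs(m12) > 1e-14) {
      vx = m12;
      vy = lmin - m11;
    } else if (m11 <= m22) {
      vx = 1;
      vy = 0;
    } else {
      vx = 0;
      vy = 1;
    }
    double lv = std::sqrt(vx * vx + vy * vy);
    vx /= lv;
    vy /= lv;
    for (int ax = 0; ax < 3; ++ax) {
      dmin(i, ax) = vx * t1[ax] + vy * t2[ax];
      dmax(i, ax) = -vy * t1[ax] + vx * t2[ax];
    }
  }
  return List::create(emin, emax, dmin, dmax);
}

// ---------------------------------------------------------------------------
// Full simulation engine
// ---------------------------------------------------------------------------

struct Field {
  const double* vx;
  const double* vy;
  const int* t0;
  const int* t1;
  const int* t2;
  int ntri, nx, ny;
  double x0, y0, dx, dy;
  std::vector<int> free_lig;
  const int* mask;

  // O(1) point location; returns -1 outside
  int locate(double x, double y) const {
    int jr = (int)std::floor((y - y0) / dy);
    int nxm = nx - 1;
    if (jr < 0 || jr > ny - 2) return -1;
    int ic = (int)std::floor((x - x0) / dx);
    for (int cc = ic - 1; cc <= ic + 1; ++cc) {
      if (cc < 0 || cc > nxm - 1) continue;
      int base = jr * 2 * nxm + 2 * cc;
      for (int k = 0; k < 2; ++k) {
        int tid = base + k;
        if (tid < 0 || tid >= ntri) continue;
        double x1 = vx[t0[tid]], y1 = vy[t0[tid]];
        double x2 = vx[t1[tid]], y2 = vy[t1[tid]];
        double x3 = vx[t2[tid]], y3 = vy[t2[tid]];
        double d = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
        double l1 = ((y2 - y3) * (x - x3) + (x3 - x2) * (y - y3)) / d;
        double l2 = ((y3 - y1) * (x - x3) + (x1 - x3) * (y - y3)) / d;
        double l3 = 1 - l1 - l2;
        if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) return tid;
      }
    }
    return -1;
  }
};

struct SF {
  int kind;    // 0 nuclear, 1 ventral
  int a, b;    // a: integrin node; b: nucleus node (nuclear) / integrin node
  int Nsf;
  double La0;
  int phase;   // 0 poly, 1 motor, 2 depoly, 3 expired
  double clock;
  double birth;
  double motor_start;
  int lead;    // 1 leading, 0 trailing (classified at birth)
};

// [[Rcpp::export]]
List run_sim_cpp(NumericMatrix cpos0, IntegerMatrix cedges,
                 IntegerMatrix ctris, NumericVector crefL,
                 NumericVector crefA, NumericMatrix npos0,
                 IntegerMatrix nedges, IntegerMatrix ntris,
                 NumericVector nrefL, NumericVector nrefA,
                 NumericMatrix fverts, IntegerMatrix ftris,
                 IntegerVector fmask, IntegerVector finit,
                 NumericVector farea, List cfg) {
  const int N = cpos0.nrow(), Nn = npos0.nrow();
  const int nE = cedges.nrow(), nT = ctris.nrow();
  const int nEn = nedges.nrow(), nTn = ntris.nrow();

  auto getd = [&](const char* nm) { return as<double>(cfg[nm]); };
  auto geti = [&](const char* nm) { return as<int>(cfg[nm]); };
  const double duration = getd("duration");
  const double frame_interval = getd("frame_interval");
  const double dt_min = getd("dt_min"), dt_max = getd("dt_max");
  const double tol_nm = getd("tol_nm");
  const double k_c_line = getd("k_c_line"), k_c_area = getd("k_c_area");
  const double k_n_line = getd("k_n_line"), k_n_area = getd("k_n_area");
  const double C_c = getd("C_c"), C_n = getd("C_n");
  const double k_b = getd("k_b"), lambda = getd("lambda"), h_c = getd("h_c");
  const double k_f = getd("k_f"), k_off0 = getd("k_off0");
  const double x_b = getd("x_b"), kBT = getd("kBT");
  const int budget = geti("receptor_budget");
  const double E_SF = getd("E_SF"), A_SF = getd("A_SF");
  const double v_m0 = getd("v_m0"), F_m = getd("F_m"), hill_a = getd("hill_a");
  const double t_poly = getd("t_poly"), t_depoly = getd("t_depoly");
  const double floor_frac = getd("contraction_floor");
  const double L_init = getd("L_init"), motor_min = getd("motor_min_s");
  const double ventral_prob = getd("ventral_prob");
  const double ventral_cos = std::cos(getd("ventral_angle_deg") * M_PI / 180);
  const double vmin_nm = getd("ventral_min_um") * 1000.0;
  const double vmax_nm = getd("ventral_max_um") * 1000.0;
  const double F_L = getd("F_L");
  const double pol_interval = getd("pol_interval");
  const double pol_sigma = getd("pol_sigma_deg") * M_PI / 180;
  const double pol_min_disp = getd("pol_min_disp_nm");
  const bool migration = geti("migration_mode") != 0;
  const int compat_every = geti("compat_interval_steps");
  const bool nuclear_sf_on = geti("nuclear_sf_enabled") != 0;

  // --- state ---------------------------------------------------------------
  std::vector<double> cp(3 * N), np(3 * Nn);
  std::vector<double> cref(3 * N);  // strain reference
  for (int i = 0; i < N; ++i)
    for (int ax = 0; ax < 3; ++ax) {
      cp[3 * i + ax] = cpos0(i, ax);
      cref[3 * i + ax] = cpos0(i, ax);
    }
  for (int i = 0; i < Nn; ++i)
    for (int ax = 0; ax < 3; ++ax) np[3 * i + ax] = npos0(i, ax);

  Field fld;
  std::vector<double> fvx(fverts.nrow()), fvy(fverts.nrow());
  std::vector<int> ft0(ftris.nrow()), ft1(ftris.nrow()), ft2(ftris.nrow());
  std::vector<int> fmaskv(fmask.size());
  for (int i = 0; i < fverts.nrow(); ++i) {
    fvx[i] = fverts(i, 0);
    fvy[i] = fverts(i, 1);
  }
  for (int i = 0; i < ftris.nrow(); ++i) {
    ft0[i] = ftris(i, 0);
    ft1[i] = ftris(i, 1);
    ft2[i] = ftris(i, 2);
  }
  for (int i = 0; i < fmask.size(); ++i) fmaskv[i] = fmask[i];
  fld.vx = fvx.data();
  fld.vy = fvy.data();
  fld.t0 = ft0.data();
  fld.t1 = ft1.data();
  fld.t2 = ft2.data();
  fld.ntri = ftris.nrow();
  fld.nx = geti("field_nx");
  fld.ny = geti("field_ny");
  fld.x0 = getd("field_x0");
  fld.y0 = getd("field_y0");
  fld.dx = getd("field_dx");
  fld.dy = getd("field_dy");
  fld.mask = fmaskv.data();
  fld.free_lig.assign(finit.begin(), finit.end());

  // adhesion state
  std::vector<int> nb(N, 0), btri(N, -1);
  std::vector<double> rootx(N), rooty(N), rootz(N), fa_age(N, 0.0);
  std::vector<int> node_nsf(N, -1), node_vsf(N, -1), node_block(N, 0);

  std::vector<SF> sfs;
  std::vector<double> log_birth, log_motor_start, log_dur;
  std::vector<int> log_kind, log_lead, log_node;

  // topology helpers
  std::vector<std::vector<int>> nbrs(N), inc_tris(N);
  for (int e = 0; e < nE; ++e) {
    nbrs[cedges(e, 0)].push_back(cedges(e, 1));
    nbrs[cedges(e, 1)].push_back(cedges(e, 0));
  }
  for (int t = 0; t < nT; ++t)
    for (int v = 0; v < 3; ++v) inc_tris[ctris(t, v)].push_back(t);

  // geometry caches (cell)
  std::vector<double> tri_nrm(3 * nT), tri_area(nT), node_nrm(3 * N);
  auto update_cell_geom = [&]() {
    std::fill(node_nrm.begin(), node_nrm.end(), 0.0);
    for (int t = 0; t < nT; ++t) {
      int a = ctris(t, 0), b = ctris(t, 1), c = ctris(t, 2);
      double u[3], v[3], w[3];
      for (int ax = 0; ax < 3; ++ax) {
        u[ax] = cp[3 * b + ax] - cp[3 * a + ax];
        v[ax] = cp[3 * c + ax] - cp[3 * a + ax];
      }
      cross3(u, v, w);
      double l = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
      tri_area[t] = l / 2;
      for (int ax = 0; ax < 3; ++ax) {
        tri_nrm[3 * t + ax] = l > 0 ? w[ax] / l : 0.0;
        double contrib = tri_area[t] * tri_nrm[3 * t + ax];
        node_nrm[3 * a + ax] += contrib;
        node_nrm[3 * b + ax] += contrib;
        node_nrm[3 * c + ax] += contrib;
      }
    }
    for (int i = 0; i < N; ++i) {
      double* nn = &node_nrm[3 * i];
      double l = std::sqrt(nn[0] * nn[0] + nn[1] * nn[1] + nn[2] * nn[2]);
      if (l > 0)
        for (int ax = 0; ax < 3; ++ax) nn[ax] /= l;
    }
  };

  // elastic force accumulation into F (3n flat), generic mesh
  auto add_elastic = [](const std::vector<double>& P, double* F,
                        const IntegerMatrix& edges, const IntegerMatrix& tris,
                        const NumericVector& refL, const NumericVector& refA,
                        double kl, double ka) {
    for (int e = 0; e < edges.nrow(); ++e) {
      int i = edges(e, 0), j = edges(e, 1);
      double d[3] = {P[3 * i] - P[3 * j], P[3 * i + 1] - P[3 * j + 1],
                     P[3 * i + 2] - P[3 * j + 2]};
      double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (L <= 0) continue;
      double c = -kl * (L - refL[e]) / L;
      for (int ax = 0; ax < 3; ++ax) {
        F[3 * i + ax] += c * d[ax];
        F[3 * j + ax] -= c * d[ax];
      }
    }
    for (int t = 0; t < tris.nrow(); ++t) {
      int a = tris(t, 0), b = tris(t, 1), c = tris(t, 2);
      double u[3], v[3], w[3];
      for (int ax = 0; ax < 3; ++ax) {
        u[ax] = P[3 * b + ax] - P[3 * a + ax];
        v[ax] = P[3 * c + ax] - P[3 * a + ax];
      }
      cross3(u, v, w);
      double l = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
      if (l <= 0) continue;
      double A = l / 2;
      double nh[3] = {w[0] / l, w[1] / l, w[2] / l};
      double coef = -ka * (A - refA[t]) / refA[t] * 0.5;
      double eBC[3], eCA[3], eAB[3], g[3];
      for (int ax = 0; ax < 3; ++ax) {
        eBC[ax] = P[3 * c + ax] - P[3 * b + ax];
        eCA[ax] = P[3 * a + ax] - P[3 * c + ax];
        eAB[ax] = P[3 * b + ax] - P[3 * a + ax];
      }
      cross3(nh, eBC, g);
      for (int ax = 0; ax < 3; ++ax) F[3 * a + ax] += coef * g[ax];
      cross3(nh, eCA, g);
      for (int ax = 0; ax < 3; ++ax) F[3 * b + ax] += coef * g[ax];
      cross3(nh, eAB, g);
      for (int ax = 0; ax < 3; ++ax) F[3 * c + ax] += coef * g[ax];
    }
  };

  // protrusion forces, refreshed once per step
  std::vector<double> Fprot(3 * N, 0.0);
  double pol[2] = {1.0, 0.0};
  if (migration) {
    double a0 = unif_rand() * 2 * M_PI;
    pol[0] = std::cos(a0);
    pol[1] = std::sin(a0);
  }
  auto refresh_protrusion = [&]() {
    std::fill(Fprot.begin(), Fprot.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      if (cp[3 * i + 2] >= h_c) continue;
      bool rim = false;
      for (int j : nbrs[i])
        if (cp[3 * j + 2] >= h_c) {
          rim = true;
          break;
        }
      if (!rim) continue;
      int tid = fld.locate(cp[3 * i] / 1000.0, cp[3 * i + 1] / 1000.0);
      if (tid < 0 || !fld.mask[tid]) continue;
      double nx = node_nrm[3 * i], ny = node_nrm[3 * i + 1];
      if (migration && nx * pol[0] + ny * pol[1] <= 0) continue;
      double l = std::sqrt(nx * nx + ny * ny);
      if (l < 1e-12) continue;
      Fprot[3 * i] = F_L * nx / l;
      Fprot[3 * i + 1] = F_L * ny / l;
    }
  };

  // soft forces (everything except the implicit FA spring)
  std::vector<double> Fc(3 * N), Fn(3 * Nn);
  auto soft_forces = [&](const std::vector<double>& P,
                         const std::vector<double>& Q, double* FC,
                         double* FN) {
    std::fill(FC, FC + 3 * N, 0.0);
    std::fill(FN, FN + 3 * Nn, 0.0);
    add_elastic(P, FC, cedges, ctris, crefL, crefA, k_c_line, k_c_area);
    add_elastic(Q, FN, nedges, ntris, nrefL, nrefA, k_n_line, k_n_area);
    for (size_t s = 0; s < sfs.size(); ++s) {
      SF& f = sfs[s];
      if (f.phase != 1) continue;
      const double* pa = &P[3 * f.a];
      const double* pb = (f.kind == 0) ? &Q[3 * f.b] : &P[3 * f.b];
      double d[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
      double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (L <= 1e-9) continue;
      double rest = f.Nsf * f.La0;
      double K = (E_SF * A_SF / f.La0) / f.Nsf;
      double ten = K * (L - rest);
      if (ten <= 0) continue;
      for (int ax = 0; ax < 3; ++ax) {
        double comp = ten * d[ax] / L;
        FC[3 * f.a + ax] += comp;
        if (f.kind == 0)
          FN[3 * f.b + ax] -= comp;
        else
          FC[3 * f.b + ax] -= comp;
      }
    }
    for (int i = 0; i < 3 * N; ++i) FC[i] += Fprot[i];
  };

  // one linearly implicit substep of length h (exponential on the FA spring)
  std::vector<double> cbuf(3 * N), nbuf(3 * Nn);
  auto substep = [&](const std::vector<double>& Pin,
                     const std::vector<double>& Qin, const double* FC,
                     const double* FN, double h, std::vector<double>& Pout,
                     std::vector<double>& Qout) {
    for (int i = 0; i < N; ++i) {
      double k = 0.0, tgt[3] = {0, 0, 0};
      if (nb[i] > 0) {
        double dvec[3] = {Pin[3 * i] - rootx[i], Pin[3 * i + 1] - rooty[i],
                          Pin[3 * i + 2] - rootz[i]};
        double L = std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1] +
                             dvec[2] * dvec[2]);
        if (L > lambda) {
          k = nb[i] * k_b;
          for (int ax = 0; ax < 3; ++ax) {
            double root = (ax == 0) ? rootx[i] : (ax == 1 ? rooty[i]
                                                          : rootz[i]);
            tgt[ax] = root + lambda * dvec[ax] / L;
          }
        }
      }
      if (k > 0) {
        double decay = std::exp(-k * h / C_c);
        for (int ax = 0; ax < 3; ++ax) {
          double xeq = tgt[ax] + FC[3 * i + ax] / k;
          Pout[3 * i + ax] = xeq + (Pin[3 * i + ax] - xeq) * decay;
        }
      } else {
        for (int ax = 0; ax < 3; ++ax)
          Pout[3 * i + ax] = Pin[3 * i + ax] + FC[3 * i + ax] * h / C_c;
      }
    }
    for (int i = 0; i < 3 * Nn; ++i) Qout[i] = Qin[i] + FN[i] * h / C_n;
  };

  // strain direction at one node, on demand (ventral SF alignment)
  auto strain_dir_min = [&](int node, double* out) {
    double Ea[9] = {0};
    double W = 0;
    for (int t : inc_tris[node]) {
      int a = ctris(t, 0), b = ctris(t, 1), c = ctris(t, 2);
      double u0[3], v0[3], u[3], v[3];
      for (int ax = 0; ax < 3; ++ax) {
        u0[ax] = cref[3 * b + ax] - cref[3 * a + ax];
        v0[ax] = cref[3 * c + ax] - cref[3 * a + ax];
        u[ax] = cp[3 * b + ax] - cp[3 * a + ax];
        v[ax] = cp[3 * c + ax] - cp[3 * a + ax];
      }
      double n0[3], nc2[3];
      cross3(u0, v0, n0);
      cross3(u, v, nc2);
      double ln0 = std::sqrt(n0[0] * n0[0] + n0[1] * n0[1] + n0[2] * n0[2]);
      double lnc = std::sqrt(nc2[0] * nc2[0] + nc2[1] * nc2[1] +
                             nc2[2] * nc2[2]);
      if (ln0 <= 0 || lnc <= 0) continue;
      double lu0 = std::sqrt(u0[0] * u0[0] + u0[1] * u0[1] + u0[2] * u0[2]);
      double lu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      double nh0[3] = {n0[0] / ln0, n0[1] / ln0, n0[2] / ln0};
      double nhc[3] = {nc2[0] / lnc, nc2[1] / lnc, nc2[2] / lnc};
      double e1r[3] = {u0[0] / lu0, u0[1] / lu0, u0[2] / lu0};
      double e1c[3] = {u[0] / lu, u[1] / lu, u[2] / lu};
      double e2r[3], e2c[3];
      cross3(nh0, e1r, e2r);
      cross3(nhc, e1c, e2c);
      double p3x = v0[0] * e1r[0] + v0[1] * e1r[1] + v0[2] * e1r[2];
      double p3y = v0[0] * e2r[0] + v0[1] * e2r[1] + v0[2] * e2r[2];
      double q3x = v[0] * e1c[0] + v[1] * e1c[1] + v[2] * e1c[2];
      double q3y = v[0] * e2c[0] + v[1] * e2c[1] + v[2] * e2c[2];
      double F11 = lu / lu0, F12 = (q3x - F11 * p3x) / p3y, F22 = q3y / p3y;
      double E11 = 0.5 * (F11 * F11 - 1.0);
      double E12 = 0.5 * (F11 * F12);
      double E22 = 0.5 * (F12 * F12 + F22 * F22 - 1.0);
      double A = lnc / 2;
      for (int r = 0; r < 3; ++r)
        for (int s = 0; s < 3; ++s)
          Ea[3 * r + s] += A * (E11 * e1c[r] * e1c[s] + E22 * e2c[r] * e2c[s] +
                                E12 * (e1c[r] * e2c[s] + e2c[r] * e1c[s]));
      W += A;
    }
    if (W <= 0) W = 1;
    double nrm[3] = {node_nrm[3 * node], node_nrm[3 * node + 1],
                     node_nrm[3 * node + 2]};
    double t1[3];
    if (std::fabs(nrm[0]) < 0.9) {
      t1[0] = 1 - nrm[0] * nrm[0];
      t1[1] = -nrm[0] * nrm[1];
      t1[2] = -nrm[0] * nrm[2];
    } else {
      t1[0] = -nrm[1] * nrm[0];
      t1[1] = 1 - nrm[1] * nrm[1];
      t1[2] = -nrm[1] * nrm[2];
    }
    double lt = std::sqrt(t1[0] * t1[0] + t1[1] * t1[1] + t1[2] * t1[2]);
    for (int ax = 0; ax < 3; ++ax) t1[ax] /= lt;
    double t2[3];
    cross3(nrm, t1, t2);
    double m11 = 0, m12 = 0, m22 = 0;
    for (int r = 0; r < 3; ++r)
      for (int s = 0; s < 3; ++s) {
        double e = Ea[3 * r + s] / W;
        m11 += t1[r] * e * t1[s];
        m12 += t1[r] * e * t2[s];
        m22 += t2[r] * e * t2[s];
      }
    double tr = m11 + m22;
    double disc = std::sqrt(0.25 * (m11 - m22) * (m11 - m22) + m12 * m12);
    double lmin = tr / 2 - disc;
    double vx2, vy2;
    if (std::fabs(m12) > 1e-14) {
      vx2 = m12;
      vy2 = lmin - m11;
    } else if (m11 <= m22) {
      vx2 = 1;
      vy2 = 0;
    } else {
      vx2 = 0;
      vy2 = 1;
    }
    double lv = std::sqrt(vx2 * vx2 + vy2 * vy2);
    for (int ax = 0; ax < 3; ++ax)
      out[ax] = (vx2 * t1[ax] + vy2 * t2[ax]) / lv;
  };

  auto nucleus_center = [&](double* c) {
    c[0] = c[1] = c[2] = 0;
    for (int i = 0; i < Nn; ++i)
      for (int ax = 0; ax < 3; ++ax) c[ax] += np[3 * i + ax] / Nn;
  };

  auto nucleate_nuclear = [&](int i, double t_now) {
    double best = 1e300;
    int bestj = -1;
    for (int j = 0; j < Nn; ++j) {
      double d2 = 0;
      for (int ax = 0; ax < 3; ++ax) {
        double d = np[3 * j + ax] - cp[3 * i + ax];
        d2 += d * d;
      }
      if (d2 < best) {
        best = d2;
        bestj = j;
      }
    }
    double dist = std::sqrt(best);
    SF f;
    f.kind = 0;
    f.a = i;
    f.b = bestj;
    f.Nsf = std::max(1, (int)std::lround(dist / L_init));
    f.La0 = L_init;
    f.phase = 0;
    f.clock = 0;
    f.birth = t_now;
    f.motor_start = -1;
    double ncen[3];
    nucleus_center(ncen);
    double dx = cp[3 * i] - ncen[0], dy = cp[3 * i + 1] - ncen[1];
    f.lead = (!migration || dx * pol[0] + dy * pol[1] >= 0) ? 1 : 0;
    node_nsf[i] = (int)sfs.size();
    sfs.push_back(f);
  };

  // one ventral attempt with probability ventral_prob; on success pairs the
  // node with the best strain-aligned live-FA partner in the length window
  std::vector<double> next_vattempt(N, 0.0);
  auto attempt_ventral = [&](int i, double t_now) {
    next_vattempt[i] = t_now + t_poly;  // one attempt per fiber cycle
    if (unif_rand() >= ventral_prob) return;
    double dirm[3];
    strain_dir_min(i, dirm);
    int bestk = -1;
    double bestc = ventral_cos;
    double bestd = 0;
    for (int k = 0; k < N; ++k) {
      if (k == i || nb[k] == 0 || node_vsf[k] >= 0 || node_block[k] > 0)
        continue;
      double v[3] = {cp[3 * k] - cp[3 * i], cp[3 * k + 1] - cp[3 * i + 1],
                     cp[3 * k + 2] - cp[3 * i + 2]};
      double d = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
      if (d < vmin_nm || d > vmax_nm) continue;
      double ca = std::fabs(v[0] * dirm[0] + v[1] * dirm[1] +
                            v[2] * dirm[2]) / d;
      if (ca >= bestc) {
        bestc = ca;
        bestk = k;
        bestd = d;
      }
    }
    if (bestk >= 0) {
      SF f;
      f.kind = 1;
      f.a = i;
      f.b = bestk;
      f.Nsf = std::max(1, (int)std::lround(bestd / L_init));
      f.La0 = L_init;
      f.phase = 0;
      f.clock = 0;
      f.birth = t_now;
      f.motor_start = -1;
      double ncen[3];
      nucleus_center(ncen);
      double dx = cp[3 * i] - ncen[0], dy = cp[3 * i + 1] - ncen[1];
      f.lead = (!migration || dx * pol[0] + dy * pol[1] >= 0) ? 1 : 0;
      node_vsf[i] = node_vsf[bestk] = (int)sfs.size();
      sfs.push_back(f);
    }
  };

  auto fa_formed = [&](int i, double t_now) {
    if (nuclear_sf_on && node_nsf[i] < 0 && node_block[i] == 0)
      nucleate_nuclear(i, t_now);
    if (node_vsf[i] < 0 && node_block[i] == 0) attempt_ventral(i, t_now);
  };

  // --- frames --------------------------------------------------------------
  std::vector<double> fr_t, fr_nc_x, fr_nc_y, fr_nc_z, fr_cc_x, fr_cc_y;
  std::vector<double> fr_contact, fr_traction, fr_tang;
  std::vector<int> fr_nfa, fr_nbonds, fr_nsf_motor;

  auto emit_frame = [&](double t_now) {
    double ncen[3];
    nucleus_center(ncen);
    double ccx = 0, ccy = 0;
    for (int i = 0; i < N; ++i) {
      ccx += cp[3 * i] / N;
      ccy += cp[3 * i + 1] / N;
    }
    double area_nm2 = 0, tang = 0;
    int nfa = 0, nbonds = 0;
    for (int i = 0; i < N; ++i) {
      if (nb[i] == 0) continue;
      ++nfa;
      nbonds += nb[i];
      double ar = 0;
      for (int tt : inc_tris[i]) ar += tri_area[tt] / 3.0;
      area_nm2 += ar;
      double dvec[3] = {rootx[i] - cp[3 * i], rooty[i] - cp[3 * i + 1],
                        rootz[i] - cp[3 * i + 2]};
      double L = std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1] +
                           dvec[2] * dvec[2]);
      if (L > lambda) {
        double mag = nb[i] * k_b * (L - lambda);
        tang += mag * std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1]) / L;
      }
    }
    int nmotor = 0;
    for (auto& f : sfs)
      if (f.phase == 1) ++nmotor;
    double area_um2 = area_nm2 / 1e6;
    fr_t.push_back(t_now);
    fr_nc_x.push_back(ncen[0]);
    fr_nc_y.push_back(ncen[1]);
    fr_nc_z.push_back(ncen[2]);
    fr_cc_x.push_back(ccx);
    fr_cc_y.push_back(ccy);
    fr_contact.push_back(area_um2);
    fr_traction.push_back(area_um2 > 0 ? tang / area_um2 : 0.0);
    fr_tang.push_back(tang);
    fr_nfa.push_back(nfa);
    fr_nbonds.push_back(nbonds);
    fr_nsf_motor.push_back(nmotor);
  };

  // --- main loop -----------------------------------------------------------
  update_cell_geom();
  refresh_protrusion();
  double t = 0, dt = dt_max;
  double next_frame = frame_interval;
  double pol_next_t = pol_interval;
  double pol_last_c[3];
  nucleus_center(pol_last_c);
  long n_steps = 0, n_rejects = 0, n_corr = 0;
  double min_z = 1e300, dt_acc_min = 1e300, dt_acc_sum = 0;
  emit_frame(0);

  std::vector<double> c_full(3 * N), n_full(3 * Nn);
  std::vector<double> c_half(3 * N), n_half(3 * Nn);
  std::vector<double> Fc2(3 * N), Fn2(3 * Nn);

  while (t < duration - 1e-9) {
    // ---- mechanics: adaptive linearly implicit step ----
    soft_forces(cp, np, Fc.data(), Fn.data());
    double h_acc = 0;
    for (;;) {
      double h = std::min(dt, duration - t);
      substep(cp, np, Fc.data(), Fn.data(), h, c_full, n_full);
      substep(cp, np, Fc.data(), Fn.data(), h / 2, c_half, n_half);
      soft_forces(c_half, n_half, Fc2.data(), Fn2.data());
      substep(c_half, n_half, Fc2.data(), Fn2.data(), h / 2, cbuf, nbuf);
      double err = 0;
      for (int i = 0; i < 3 * N; ++i)
        err = std::max(err, std::fabs(c_full[i] - cbuf[i]));
      for (int i = 0; i < 3 * Nn; ++i)
        err = std::max(err, std::fabs(n_full[i] - nbuf[i]));
      if (!std::isfinite(err)) stop("non-finite forces at t = %g s", t);
      if (err < tol_nm || h <= dt_min * (1 + 1e-12)) {
        cp.swap(cbuf);
        np.swap(nbuf);
        t += h;
        h_acc = h;
        ++n_steps;
        dt_acc_sum += h;
        if (h < dt_acc_min) dt_acc_min = h;
        if (err < tol_nm / 4) dt = std::min(dt_max, dt * 1.5);
        break;
      }
      dt = std::max(dt_min, dt / 2);
      ++n_rejects;
    }

    // ---- geometric compatibility: substrate every step, nucleus-in-cell
    // every compat_every steps (violations develop on much slower scales) ----
    for (int i = 0; i < N; ++i)
      if (cp[3 * i + 2] < 0) {
        cp[3 * i + 2] = 1.0;
        ++n_corr;
      }
    update_cell_geom();
    if (n_steps % compat_every == 0) {
      for (int i = 0; i < Nn; ++i) {
        if (np[3 * i + 2] < 0) {
          np[3 * i + 2] = 1.0;
          ++n_corr;
        }
        double best = 1e300;
        int bj = -1;
        for (int j = 0; j < N; ++j) {
          double d2 = 0;
          for (int ax = 0; ax < 3; ++ax) {
            double d = np[3 * i + ax] - cp[3 * j + ax];
            d2 += d * d;
          }
          if (d2 < best) {
            best = d2;
            bj = j;
          }
        }
        double depth = 0;
        for (int ax = 0; ax < 3; ++ax)
          depth += (np[3 * i + ax] - cp[3 * bj + ax]) * node_nrm[3 * bj + ax];
        if (depth > 0) {
          for (int ax = 0; ax < 3; ++ax)
            np[3 * i + ax] -= (depth + 1.0) * node_nrm[3 * bj + ax];
          ++n_corr;
        }
      }
    }
    for (int i = 0; i < N; ++i) min_z = std::min(min_z, cp[3 * i + 2]);

    // ---- adhesion chemistry: one binding + one rupture test per node ----
    for (int i = 0; i < N; ++i) {
      double nz = node_nrm[3 * i + 2];
      bool eligible = false;
      int hit_tri = -1;
      double root_hit[3] = {0, 0, 0};
      if (nz < 0 && cp[3 * i + 2] >= 0) {
        double d[3];
        if (nz > -0.2) {
          d[0] = 0;
          d[1] = 0;
          d[2] = -1;
        } else {
          d[0] = node_nrm[3 * i];
          d[1] = node_nrm[3 * i + 1];
          d[2] = nz;
        }
        double t_hit = -cp[3 * i + 2] / d[2];
        if (t_hit < h_c) {
          root_hit[0] = cp[3 * i] + t_hit * d[0];
          root_hit[1] = cp[3 * i + 1] + t_hit * d[1];
          root_hit[2] = 0;
          hit_tri = fld.locate(root_hit[0] / 1000.0, root_hit[1] / 1000.0);
          eligible = hit_tri >= 0 && fld.mask[hit_tri];
        }
      }
      if (eligible && nb[i] < budget) {
        int tid = nb[i] > 0 ? btri[i] : hit_tri;
        int nfree = fld.free_lig[tid];
        if (nfree > 0) {
          double pb = 1.0 - std::exp(-k_f * nfree * h_acc);
          if (unif_rand() < pb) {
            if (nb[i] == 0) {
              rootx[i] = root_hit[0];
              rooty[i] = root_hit[1];
              rootz[i] = root_hit[2];
              btri[i] = hit_tri;
              fa_age[i] = 0;
              tid = hit_tri;
              nb[i] = 1;
              fld.free_lig[tid] -= 1;
              fa_formed(i, t);
            } else {
              nb[i] += 1;
              fld.free_lig[tid] -= 1;
            }
          }
        }
      }
      if (nb[i] > 0) {
        double dvec[3] = {cp[3 * i] - rootx[i], cp[3 * i + 1] - rooty[i],
                          cp[3 * i + 2] - rootz[i]};
        double L = std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1] +
                             dvec[2] * dvec[2]);
        double per_bond = k_b * std::max(0.0, L - lambda);
        double koff = k_off0 * std::exp(per_bond * x_b / kBT);
        double pr = 1.0 - std::exp(-koff * h_acc);
        if (unif_rand() < pr) {
          fld.free_lig[btri[i]] += 1;
          nb[i] -= 1;
          if (nb[i] == 0) {
            btri[i] = -1;
            fa_age[i] = 0;
            next_vattempt[i] = 0.0;  // fresh FA lifetime: attempt allowed
          }
        }
        if (nb[i] > 0) fa_age[i] += h_acc;
      }
    }

    // ---- stress-fiber lifecycle ----
    // FA-bearing nodes without a fiber re-nucleate one (the polymerize /
    // contract / disassemble cycle repeats while the adhesion persists);
    // nodes with a depolymerizing fiber are blocked from nucleating.
    for (int i = 0; i < N; ++i) {
      if (nb[i] > 0 && node_nsf[i] < 0 && node_block[i] == 0 && nuclear_sf_on)
        nucleate_nuclear(i, t);
      if (nb[i] > 0 && node_vsf[i] < 0 && node_block[i] == 0 &&
          t >= next_vattempt[i])
        attempt_ventral(i, t);
    }
    for (size_t s = 0; s < sfs.size(); ++s) {
      SF& f = sfs[s];
      if (f.phase == 3) continue;
      bool fa_alive = nb[f.a] > 0 && (f.kind == 0 || nb[f.b] > 0);
      if (f.phase == 0) {
        f.clock += h_acc;
        if (!fa_alive) {
          f.phase = 3;
          if (f.kind == 0)
            node_nsf[f.a] = -1;
          else
            node_vsf[f.a] = node_vsf[f.b] = -1;
        } else if (f.clock >= t_poly) {
          f.phase = 1;
          f.clock = 0;
          f.motor_start = t;
        }
      } else if (f.phase == 1) {
        // current tension for the Hill velocity
        const double* pa = &cp[3 * f.a];
        const double* pb = (f.kind == 0) ? &np[3 * f.b] : &cp[3 * f.b];
        double d[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
        double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        double rest = f.Nsf * f.La0;
        double K = (E_SF * A_SF / f.La0) / f.Nsf;
        double ten = std::max(0.0, K * (L - rest));
        double vm = 0;
        if (ten < F_m) vm = v_m0 * (1 - ten / F_m) / (1 + ten / hill_a);
        double floor_nm = floor_frac * L_init;
        f.La0 = std::max(floor_nm, f.La0 - 2 * vm * h_acc);
        f.clock += h_acc;
        bool at_floor = f.La0 <= floor_nm + 1e-9;
        if (!fa_alive || (at_floor && f.clock >= motor_min)) {
          log_birth.push_back(f.birth);
          log_motor_start.push_back(f.motor_start);
          log_dur.push_back(f.clock);
          log_kind.push_back(f.kind);
          log_lead.push_back(f.lead);
          log_node.push_back(f.a + 1);
          f.phase = 2;
          f.clock = 0;
          node_block[f.a] += 1;
          if (f.kind == 1) node_block[f.b] += 1;
        }
      } else if (f.phase == 2) {
        f.clock += h_acc;
        if (f.clock >= t_depoly) {
          f.phase = 3;
          node_block[f.a] -= 1;
          if (f.kind == 0)
            node_nsf[f.a] = -1;
          else {
            node_block[f.b] -= 1;
            node_vsf[f.a] = node_vsf[f.b] = -1;
          }
        }
      }
    }

    // ---- polarity refresh (migration mode) ----
    if (migration && t >= pol_next_t) {
      double c[3];
      nucleus_center(c);
      double dx = c[0] - pol_last_c[0], dy = c[1] - pol_last_c[1];
      if (std::sqrt(dx * dx + dy * dy) >= pol_min_disp) {
        double ang = std::atan2(dy, dx) + norm_rand() * pol_sigma;
        pol[0] = std::cos(ang);
        pol[1] = std::sin(ang);
      }
      for (int ax = 0; ax < 3; ++ax) pol_last_c[ax] = c[ax];
      pol_next_t += pol_interval;
    }

    // ---- leading edge / protrusion for the next step ----
    refresh_protrusion();

    if (t >= next_frame - 1e-9) {
      emit_frame(t);
      next_frame += frame_interval;
    }
    if (n_steps % 50000 == 0) Rcpp::checkUserInterrupt();
  }

  // ---- outputs ------------------------------------------------------------
  int nf = (int)fr_t.size();
  NumericMatrix frames(nf, 12);
  for (int i = 0; i < nf; ++i) {
    frames(i, 0) = fr_t[i];
    frames(i, 1) = fr_nc_x[i];
    frames(i, 2) = fr_nc_y[i];
    frames(i, 3) = fr_nc_z[i];
    frames(i, 4) = fr_cc_x[i];
    frames(i, 5) = fr_cc_y[i];
    frames(i, 6) = fr_contact[i];
    frames(i, 7) = fr_traction[i];
    frames(i, 8) = fr_tang[i];
    frames(i, 9) = fr_nfa[i];
    frames(i, 10) = fr_nbonds[i];
    frames(i, 11) = fr_nsf_motor[i];
  }
  colnames(frames) = CharacterVector::create(
      "t", "nuc_x", "nuc_y", "nuc_z", "cell_x", "cell_y", "contact_area_um2",
      "traction_Pa", "tangential_force_pN", "n_fa", "n_bonds", "n_sf_motor");

  int nl = (int)log_dur.size();
  NumericMatrix sflog(nl, 6);
  for (int i = 0; i < nl; ++i) {
    sflog(i, 0) = log_birth[i];
    sflog(i, 1) = log_motor_start[i];
    sflog(i, 2) = log_dur[i];
    sflog(i, 3) = log_kind[i];
    sflog(i, 4) = log_lead[i];
    sflog(i, 5) = log_node[i];
  }
  colnames(sflog) = CharacterVector::create(
      "birth_s", "motor_start_s", "motor_duration_s", "kind", "leading",
      "node");

  NumericMatrix cfin(N, 3), nfin(Nn, 3);
  IntegerVector nb_out(N);
  NumericVector fa_mag(N), fa_tang(N);
  for (int i = 0; i < N; ++i) {
    for (int ax = 0; ax < 3; ++ax) cfin(i, ax) = cp[3 * i + ax];
    nb_out[i] = nb[i];
    if (nb[i] > 0) {
      double dvec[3] = {rootx[i] - cp[3 * i], rooty[i] - cp[3 * i + 1],
                        rootz[i] - cp[3 * i + 2]};
      double L = std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1] +
                           dvec[2] * dvec[2]);
      if (L > lambda) {
        fa_mag[i] = nb[i] * k_b * (L - lambda);
        fa_tang[i] =
            fa_mag[i] * std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1]) / L;
      }
    }
  }
  for (int i = 0; i < Nn; ++i)
    for (int ax = 0; ax < 3; ++ax) nfin(i, ax) = np[3 * i + ax];

  // ligand audit: bound count per substrate triangle from live FAs
  IntegerVector free_out(fld.ntri), bound_out(fld.ntri);
  for (int j = 0; j < fld.ntri; ++j) free_out[j] = fld.free_lig[j];
  for (int i = 0; i < N; ++i)
    if (nb[i] > 0 && btri[i] >= 0) bound_out[btri[i]] += nb[i];

  return List::create(
      Named("frames") = frames, Named("sf_log") = sflog,
      Named("cell_pos") = cfin, Named("nucleus_pos") = nfin,
      Named("n_b") = nb_out, Named("fa_force_pN") = fa_mag,
      Named("fa_tangential_pN") = fa_tang, Named("ligand_free") = free_out,
      Named("ligand_bound") = bound_out,
      Named("polarity") = NumericVector::create(pol[0], pol[1]),
      Named("diag") = List::create(
          Named("n_steps") = (double)n_steps,
          Named("n_rejects") = (double)n_rejects,
          Named("n_corrections") = (double)n_corr,
          Named("min_cell_z_nm") = min_z,
          Named("dt_min_accepted") = dt_acc_min,
          Named("dt_mean_accepted") = n_steps ? dt_acc_sum / n_steps : 0.0));
}
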