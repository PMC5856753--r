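#include <Rcpp.h>
using namespace Rcpp;

// Per-step force/torque kernel.
//
// Cells are spherocylinders discretized as 6 balls equally spaced along the
// axis (ball 1 at the old pole).  Ball-ball forces between distinct cells
// follow the Yukawa-derived law (linear repulsion below r0, exponential
// attractive tail above); link forces follow the worm-like chain.  Forces are
// exactly antisymmetric within a pair; links act only on their own cell.
// Torques are taken about each cell's center of mass with the ball center
// (cell-cell) or the attachment point (links) as lever arm.
//
// Links with extension >= L0 get tension = +Inf and contribute no force (the
// caller must rupture them this step); rigid fixture pins are skipped.
//
// Repulsion energy: each overlapping unordered ball pair stores the elastic
// spring energy 0.5*k_rep*(r0-r)^2 once in the total, split equally between
// the two cells, so that -dE/dx reproduces the repulsive force branch.

// [[Rcpp::export]]
List colony_forces_cpp(NumericVector cm_x, NumericVector cm_y,
                       NumericVector theta, NumericVector d_c,
                       IntegerVector link_cell, NumericVector link_frac,
                       NumericVector link_lat, NumericVector link_ax,
                       NumericVector link_ay, LogicalVector link_rigid,
                       double k_rep, double r0, double V0, double r1,
                       double kT, double Lp, double L0) {
  const int n = cm_x.size();
  const int m = link_cell.size();
  const double rcut = r0 + 5.0 * r1;

  NumericVector fx(n), fy(n), tq(n), e_rep_cell(n);
  NumericVector bx(n * 6), by(n * 6), ux(n), uy(n);
  double e_rep_total = 0.0;

  for (int i = 0; i < n; ++i) {
    ux[i] = std::cos(theta[i]);
    uy[i] = std::sin(theta[i]);
    for (int k = 0; k < 6; ++k) {
      double s = d_c[i] * (k / 5.0 - 0.5);
      bx[i * 6 + k] = cm_x[i] + s * ux[i];
      by[i * 6 + k] = cm_y[i] + s * uy[i];
    }
  }

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = cm_x[j] - cm_x[i], dy = cm_y[j] - cm_y[i];
      double reach = 0.5 * (d_c[i] + d_c[j]) + rcut;
      if (dx * dx + dy * dy > reach * reach) continue;
      for (int b = 0; b < 6; ++b) {
        double xb = bx[i * 6 + b], yb = by[i * 6 + b];
        for (int b2 = 0; b2 < 6; ++b2) {
          double rx = xb - bx[j * 6 + b2];  // from ball b' (cell j) to b (cell i)
          double ry = yb - by[j * 6 + b2];
          double r2 = rx * rx + ry * ry;
          if (r2 > rcut * rcut) continue;
          double r = std::sqrt(r2);
          if (r <= 0.0)
            stop("degenerate geometry: coincident ball centers between cells");
          double f;
          if (r < r0) {
            f = k_rep * (r0 - r);
            double de = 0.5 * k_rep * (r0 - r) * (r0 - r);
            e_rep_total += de;
            e_rep_cell[i] += 0.5 * de;
            e_rep_cell[j] += 0.5 * de;
          } else {
            f = -V0 * (1.0 / r + 1.0 / r1) * (1.0 / r) *
                std::exp(-(r - r0) / r1);
          }
          double fxp = f * rx / r, fyp = f * ry / r;  // force on ball b, cell i
          fx[i] += fxp;           fy[i] += fyp;
          fx[j] -= fxp;           fy[j] -= fyp;
          // torque about each CM, z component of lever x force
          double lxi = xb - cm_x[i], lyi = yb - cm_y[i];
          double lxj = bx[j * 6 + b2] - cm_x[j], lyj = by[j * 6 + b2] - cm_y[j];
          tq[i] += lxi * fyp - lyi * fxp;
          tq[j] += lxj * (-fyp) - lyj * (-fxp);
        }
      }
    }
  }

  NumericVector lfx(m), lfy(m), ltq(m), lext(m), lten(m);
  for (int l = 0; l < m; ++l) {
    int i = link_cell[l] - 1;
    if (i < 0 || i >= n) stop("link references a cell row out of range");
    double s = link_frac[l] * d_c[i];
    double ax = cm_x[i] + s * ux[i] - link_lat[l] * uy[i];
    double ay = cm_y[i] + s * uy[i] + link_lat[l] * ux[i];
    double dx = link_ax[l] - ax, dy = link_ay[l] - ay;  // attachment -> anchor
    double L = std::sqrt(dx * dx + dy * dy);
    if (link_rigid[l]) { lext[l] = 0.0; continue; }
    lext[l] = L;
    if (L >= L0) { lten[l] = R_PosInf; continue; }  // certain rupture pending
    if (L <= 0.0) continue;
    double x = L / L0;
    double T = (kT / Lp) * (x + 0.25 / ((1.0 - x) * (1.0 - x)) - 0.25);
    lten[l] = T;
    double fxl = T * dx / L, fyl = T * dy / L;  // restoring pull toward anchor
    lfx[l] = fxl; lfy[l] = fyl;
    double lx = ax - cm_x[i], ly = ay - cm_y[i];
    ltq[l] = lx * fyl - ly * fxl;
    fx[i] += fxl; fy[i] += fyl; tq[i] += ltq[l];
  }

  return List::create(
      _["fx"] = fx, _["fy"] = fy, _["torque"] = tq,
      _["e_rep_cell"] = e_rep_cell, _["e_rep_total"] = e_rep_total,
      _["link_fx"] = lfx, _["link_fy"] = lfy, _["link_torque"] = ltq,
      _["link_ext"] = lext, _["link_tension"] = lten);
}
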