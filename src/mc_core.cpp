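#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Coulomb constant k = 1/(4 pi eps0) and eps0, CODATA 2018
static const double EPS0 = 8.8541878128e-12;
static const double KCOUL = 1.0 / (4.0 * M_PI * EPS0);
static const double KBOLTZ = 1.380649e-23;

// ---- Carlson symmetric elliptic integrals (Carlson 1995 duplication) ----
// R_F(x, y, z)
static double carlson_rf(double x, double y, double z) {
  const double errtol = 1e-10;
  double xt = x, yt = y, zt = z;
  double mu, dx, dy, dz;
  do {
    double sx = std::sqrt(xt), sy = std::sqrt(yt), sz = std::sqrt(zt);
    double lam = sx * (sy + sz) + sy * sz;
    xt = 0.25 * (xt + lam);
    yt = 0.25 * (yt + lam);
    zt = 0.25 * (zt + lam);
    mu = (xt + yt + zt) / 3.0;
    dx = (mu - xt) / mu; dy = (mu - yt) / mu; dz = (mu - zt) / mu;
  } while (std::max(std::fabs(dx), std::max(std::fabs(dy), std::fabs(dz))) > errtol);
  double e2 = dx * dy - dz * dz;
  double e3 = dx * dy * dz;
  return (1.0 + (e2 / 24.0 - 0.1 - 3.0 * e3 / 44.0) * e2 + e3 / 14.0) /
         std::sqrt(mu);
}

// R_D(x, y, z)
static double carlson_rd(double x, double y, double z) {
  const double errtol = 1e-10;
  double xt = x, yt = y, zt = z;
  double sum = 0.0, fac = 1.0;
  double mu, dx, dy, dz;
  do {
    double sx = std::sqrt(xt), sy = std::sqrt(yt), sz = std::sqrt(zt);
    double lam = sx * (sy + sz) + sy * sz;
    sum += fac / (sz * (zt + lam));
    fac *= 0.25;
    xt = 0.25 * (xt + lam);
    yt = 0.25 * (yt + lam);
    zt = 0.25 * (zt + lam);
    mu = (xt + yt + 3.0 * zt) / 5.0;
    dx = (mu - xt) / mu; dy = (mu - yt) / mu; dz = (mu - zt) / mu;
  } while (std::max(std::fabs(dx), std::max(std::fabs(dy), std::fabs(dz))) > errtol);
  double ea = dx * dy, eb = dz * dz, ec = ea - eb, ed = ea - 6.0 * eb;
  double ee = ed + ec + ec;
  return 3.0 * sum + fac * (1.0 + ed * (-3.0 / 14.0 + 9.0 / 88.0 * ed -
         4.5 / 26.0 * dz * ee) + dz * (ee / 6.0 + dz * (-9.0 / 22.0 * ec +
         3.0 / 26.0 * dz * ea))) / (mu * std::sqrt(mu));
}

// Complete elliptic integral of the second kind E(k), parameterised by the
// modulus k in [0, 1]: E(k) = RF(0, 1-k^2, 1) - (k^2/3) RD(0, 1-k^2, 1).
// [[Rcpp::export]]
double ellip_e_cpp(double k) {
  if (k < 0.0 || k > 1.0) stop("modulus k outside [0, 1]");
  if (k == 1.0) return 1.0;
  double m = k * k;
  return carlson_rf(0.0, 1.0 - m, 1.0) - (m / 3.0) * carlson_rd(0.0, 1.0 - m, 1.0);
}

// In-plane potential of a uniformly charged disk (surface density sigma,
// radius R) at radial distance rho <= R, 3D Coulomb kernel:
// V(rho) = sigma R E(rho / R) / (pi eps0).
// [[Rcpp::export]]
double bg_potential_cpp(double rho, double sigma, double R) {
  if (rho < 0.0 || rho > R) stop("rho outside [0, R]");
  if (sigma == 0.0) return 0.0;
  return sigma * R * ellip_e_cpp(rho / R) / (M_PI * EPS0);
}

static inline double dist2(double ax, double ay, double bx, double by) {
  double dx = ax - bx, dy = ay - by;
  return dx * dx + dy * dy;
}

// Energy breakdown of a configuration: u1 (ion-site), u2 (ion-ion, each pair
// once), u3 (ion-background). Distances below min_sep raise an error.
// [[Rcpp::export]]
NumericVector energy_breakdown_cpp(NumericVector x, NumericVector y,
                                   NumericVector sx, NumericVector sy,
                                   double q, double q_site,
                                   double sigma, double R, double min_sep) {
  int n = x.size(), ns = sx.size();
  double ms2 = min_sep * min_sep;
  double u1 = 0.0, u2 = 0.0, u3 = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < ns; ++j) {
      double d2 = dist2(x[i], y[i], sx[j], sy[j]);
      if (d2 < ms2) stop("ion-site distance below min_separation (singularity)");
      u1 += 1.0 / std::sqrt(d2);
    }
    for (int j = i + 1; j < n; ++j) {
      double d2 = dist2(x[i], y[i], x[j], y[j]);
      if (d2 < ms2) stop("ion-ion distance below min_separation (singularity)");
      u2 += 1.0 / std::sqrt(d2);
    }
    double rho = std::sqrt(x[i] * x[i] + y[i] * y[i]);
    if (rho > R) rho = R; // guard rounding at the boundary
    u3 += bg_potential_cpp(rho, sigma, R);
  }
  u1 *= KCOUL * q * q_site;
  u2 *= KCOUL * q * q;
  u3 *= q;
  return NumericVector::create(_["u1"] = u1, _["u2"] = u2, _["u3"] = u3);
}

// Energy difference for moving ion i (0-based) to (nx, ny); only the terms
// involving ion i are touched. Returns NA if the move violates min_sep.
static double delta_u_move(const NumericVector& x, const NumericVector& y,
                           const NumericVector& sx, const NumericVector& sy,
                           double q, double q_site, double sigma, double R,
                           double min_sep, int i, double nx, double ny,
                           bool* bad) {
  int n = x.size(), ns = sx.size();
  double ms2 = min_sep * min_sep;
  *bad = false;
  double s_old = 0.0, s_new = 0.0;
  for (int j = 0; j < ns; ++j) {
    double d2n = dist2(nx, ny, sx[j], sy[j]);
    if (d2n < ms2) { *bad = true; return NA_REAL; }
    s_new += 1.0 / std::sqrt(d2n);
    s_old += 1.0 / std::sqrt(dist2(x[i], y[i], sx[j], sy[j]));
  }
  double p_old = 0.0, p_new = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double d2n = dist2(nx, ny, x[j], y[j]);
    if (d2n < ms2) { *bad = true; return NA_REAL; }
    p_new += 1.0 / std::sqrt(d2n);
    p_old += 1.0 / std::sqrt(dist2(x[i], y[i], x[j], y[j]));
  }
  double rho_old = std::sqrt(x[i] * x[i] + y[i] * y[i]);
  double rho_new = std::sqrt(nx * nx + ny * ny);
  if (rho_old > R) rho_old = R;
  if (rho_new > R) rho_new = R;
  double du = KCOUL * q * q_site * (s_new - s_old) +
              KCOUL * q * q * (p_new - p_old) +
              q * (bg_potential_cpp(rho_new, sigma, R) -
                   bg_potential_cpp(rho_old, sigma, R));
  return du;
}

// [[Rcpp::export]]
double delta_energy_cpp(NumericVector x, NumericVector y,
                        NumericVector sx, NumericVector sy,
                        double q, double q_site, double sigma, double R,
                        double min_sep, int i, double nx, double ny) {
  if (i < 0 || i >= x.size()) stop("ion index out of range");
  double rho_new = std::sqrt(nx * nx + ny * ny);
  if (rho_new > R * (1.0 + 1e-12)) stop("new position outside the disk");
  bool bad = false;
  double du = delta_u_move(x, y, sx, sy, q, q_site, sigma, R, min_sep,
                           i, nx, ny, &bad);
  if (bad) stop("proposed position closer than min_separation to another charge");
  return du;
}

// 0-based ring index of rho given equal-area edges (length M + 1).
static inline int ring_of(double rho, const NumericVector& edges) {
  int M = edges.size() - 1;
  // first edge index with edges[idx] > rho, minus one
  int idx = int(std::upper_bound(edges.begin() + 1, edges.end(), rho) -
                (edges.begin() + 1));
  if (idx >= M) idx = M - 1; // rho == R -> outermost ring
  return idx;
}

// Metropolis sampler: one iteration = one attempted single-ion move.
// Records energy per ion and window acceptance every record_every
// iterations, accumulates equal-area ring counts every sample_every
// iterations after burn_in_iter, and (optionally, hist_nr > 0) a polar
// occupancy histogram every hist_every iterations after burn_in_iter.
// [[Rcpp::export]]
List run_mc_cpp(NumericVector x0, NumericVector y0,
                NumericVector sx, NumericVector sy,
                double q, double q_site, double sigma, double R,
                double temperature, double barrier,
                NumericVector edges, double step, double min_sep,
                double n_iter, int record_every, int sample_every,
                double burn_in_iter,
                int hist_nr, int hist_ntheta, int hist_every) {
  NumericVector x = clone(x0), y = clone(y0);
  int n = x.size();
  int M = edges.size() - 1;
  double beta = 1.0 / (KBOLTZ * temperature);
  long long niter = (long long)n_iter;
  long long burn = (long long)burn_in_iter;

  NumericVector e0 = energy_breakdown_cpp(x, y, sx, sy, q, q_site, sigma, R, min_sep);
  double utot = e0[0] + e0[1] + e0[2];
  double u_initial = utot;

  long long nrec = (record_every > 0) ? niter / record_every : 0;
  NumericVector rec_iter(nrec), rec_energy(nrec), rec_acc(nrec);
  long long irec = 0, win_acc = 0, win_att = 0;

  NumericVector ring_counts(M);
  long long n_profile_samples = 0;

  NumericMatrix hist(std::max(hist_nr, 1), std::max(hist_ntheta, 1));
  bool do_hist = hist_nr > 0 && hist_ntheta > 0 && hist_every > 0;
  long long hist_samples = 0;

  long long n_accept = 0;
  RNGScope scope;

  for (long long it = 1; it <= niter; ++it) {
    if (n > 0) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      // isotropic displacement uniform in a disk of radius `step`
      double dx, dy;
      do {
        dx = (2.0 * unif_rand() - 1.0) * step;
        dy = (2.0 * unif_rand() - 1.0) * step;
      } while (dx * dx + dy * dy > step * step);
      double nx = x[i] + dx, ny = y[i] + dy;
      double rho_new = std::sqrt(nx * nx + ny * ny);
      ++win_att;
      if (rho_new <= R) { // proposals outside the seed disk auto-reject
        bool bad = false;
        double du = delta_u_move(x, y, sx, sy, q, q_site, sigma, R, min_sep,
                                 i, nx, ny, &bad);
        if (!bad) {
          if (!std::isfinite(du)) stop("non-finite energy difference at iteration %lld", it);
          double rho_old = std::sqrt(x[i] * x[i] + y[i] * y[i]);
          if (rho_old > R) rho_old = R;
          int ncross = std::abs(ring_of(rho_new, edges) - ring_of(rho_old, edges));
          double p = std::exp(-beta * barrier * ncross);
          if (du > 0.0) p *= std::exp(-beta * du);
          if (p >= 1.0 || unif_rand() < p) {
            x[i] = nx; y[i] = ny;
            utot += du;
            ++n_accept; ++win_acc;
          }
        }
      }
    }

    if (record_every > 0 && it % record_every == 0 && irec < nrec) {
      rec_iter[irec] = (double)it;
      rec_energy[irec] = (n > 0) ? utot / n : 0.0;
      rec_acc[irec] = (win_att > 0) ? (double)win_acc / (double)win_att : NA_REAL;
      win_acc = 0; win_att = 0;
      ++irec;
    }
    if (it > burn && sample_every > 0 && it % sample_every == 0) {
      for (int j = 0; j < n; ++j) {
        double rho = std::sqrt(x[j] * x[j] + y[j] * y[j]);
        if (rho > R) rho = R;
        ring_counts[ring_of(rho, edges)] += 1.0;
      }
      ++n_profile_samples;
    }
    if (do_hist && it > burn && it % hist_every == 0) {
      for (int j = 0; j < n; ++j) {
        double rho = std::sqrt(x[j] * x[j] + y[j] * y[j]);
        if (rho > R) rho = R;
        double th = std::atan2(y[j], x[j]);
        if (th < 0) th += 2.0 * M_PI;
        int ir = (int)(hist_nr * rho / R);
        if (ir >= hist_nr) ir = hist_nr - 1;
        int itheta = (int)(hist_ntheta * th / (2.0 * M_PI));
        if (itheta >= hist_ntheta) itheta = hist_ntheta - 1;
        hist(ir, itheta) += 1.0;
      }
      ++hist_samples;
    }
  }

  NumericVector efin = energy_breakdown_cpp(x, y, sx, sy, q, q_site, sigma, R, min_sep);
  double u_recomputed = efin[0] + efin[1] + efin[2];

  return List::create(
    _["x"] = x, _["y"] = y,
    _["iteration"] = rec_iter,
    _["energy_per_ion"] = rec_energy,
    _["acceptance_rate"] = rec_acc,
    _["ring_counts"] = ring_counts,
    _["n_profile_samples"] = (double)n_profile_samples,
    _["hist"] = hist,
    _["hist_samples"] = (double)hist_samples,
    _["n_accept"] = (double)n_accept,
    _["initial_energy"] = u_initial,
    _["tracked_energy"] = utot,
    _["recomputed_energy"] = u_recomputed
  );
}
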