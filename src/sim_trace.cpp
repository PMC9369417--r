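#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brownian dynamics of point emitters in a periodic box with a 3D Gaussian
// molecular detection function (MDF) centred at the origin:
//   W(x,y,z) = exp(-2 (x^2 + y^2) / w0^2 - 2 z^2 / (S w0)^2).
// Each molecule carries a peak brightness q (kHz at the MDF maximum) and an
// optional two-state triplet (bright/dark) Markov chain. Photon counts per
// bin are Poisson with mean sum_m q_m W(r_m) * 1000 * dt + background.
//
// Uses R's RNG so results are reproducible under set.seed().
//
// occupancy: if requested, also records per-step the number of molecules
// inside an axis-aligned ellipsoid whose volume equals the effective volume
// pi^{3/2} S w0^3 (semi-axes r*w0, r*w0, r*S*w0 with r = (3 sqrt(pi)/4)^{1/3});
// the time average is the direct occupancy oracle for the expected number of
// molecules in the confocal volume.

// [[Rcpp::export(name = ".sim_trace_cpp")]]
List sim_trace_cpp(int n_bins,
                   int steps_per_bin,
                   double dt,
                   NumericVector diff_coef,    // per molecule, um^2/s
                   NumericVector brightness,   // per molecule, kHz at MDF peak
                   double w0,
                   double s_param,
                   NumericVector box,          // full box lengths, um (x, y, z)
                   double background_khz,
                   double triplet_T,
                   double triplet_tau,         // s
                   bool origin_start,
                   bool track_occupancy) {
  const int n_mol = diff_coef.size();
  if (brightness.size() != n_mol) stop("diff_coef/brightness length mismatch");
  const double bx = box[0], by = box[1], bz = box[2];
  const double z0 = s_param * w0;
  const double inv_w02 = 2.0 / (w0 * w0);
  const double inv_z02 = 2.0 / (z0 * z0);
  const double occ_r = std::cbrt(0.75 * std::sqrt(M_PI));
  const double ax = occ_r * w0, az = occ_r * z0;

  std::vector<double> x(n_mol), y(n_mol), z(n_mol), sigma(n_mol);
  std::vector<int> bright_state(n_mol, 1);
  RNGScope scope;
  for (int i = 0; i < n_mol; ++i) {
    if (origin_start) {
      x[i] = 0.0; y[i] = 0.0; z[i] = 0.0;
    } else {
      x[i] = (unif_rand() - 0.5) * bx;
      y[i] = (unif_rand() - 0.5) * by;
      z[i] = (unif_rand() - 0.5) * bz;
    }
    sigma[i] = std::sqrt(2.0 * diff_coef[i] * dt);
    if (triplet_T > 0 && unif_rand() < triplet_T) bright_state[i] = 0;
  }
  // two-state chain: equilibrium dark probability T, relaxation time tau_T
  double p_to_dark = 0.0, p_to_bright = 0.0;
  if (triplet_T > 0) {
    p_to_dark = (triplet_T / triplet_tau) * dt;
    p_to_bright = ((1.0 - triplet_T) / triplet_tau) * dt;
    if (p_to_dark > 1.0 || p_to_bright > 1.0)
      stop("timestep too coarse for the requested triplet relaxation time");
  }

  IntegerVector counts(n_bins);
  NumericVector occupancy(track_occupancy ? n_bins : 0);

  for (int b = 0; b < n_bins; ++b) {
    double lam = 0.0;
    double occ_acc = 0.0;
    for (int ss = 0; ss < steps_per_bin; ++ss) {
      for (int i = 0; i < n_mol; ++i) {
        if (sigma[i] > 0.0) {
          x[i] += sigma[i] * norm_rand();
          y[i] += sigma[i] * norm_rand();
          z[i] += sigma[i] * norm_rand();
          // periodic wrapping
          if (x[i] < -0.5 * bx) x[i] += bx; else if (x[i] >= 0.5 * bx) x[i] -= bx;
          if (y[i] < -0.5 * by) y[i] += by; else if (y[i] >= 0.5 * by) y[i] -= by;
          if (z[i] < -0.5 * bz) z[i] += bz; else if (z[i] >= 0.5 * bz) z[i] -= bz;
        }
        if (triplet_T > 0) {
          if (bright_state[i] == 1) {
            if (unif_rand() < p_to_dark) bright_state[i] = 0;
          } else {
            if (unif_rand() < p_to_bright) bright_state[i] = 1;
          }
        }
        if (bright_state[i] == 1 && brightness[i] > 0.0) {
          double w = std::exp(-(x[i] * x[i] + y[i] * y[i]) * inv_w02
                              - z[i] * z[i] * inv_z02);
          lam += brightness[i] * w;
        }
        if (track_occupancy) {
          double rx = x[i] / ax, ry = y[i] / ax, rz = z[i] / az;
          if (rx * rx + ry * ry + rz * rz <= 1.0) occ_acc += 1.0;
        }
      }
    }
    // lam is in kHz summed over sub-steps; convert to expected counts per bin
    double mu = (lam / steps_per_bin + background_khz) * 1000.0 *
                (dt * steps_per_bin);
    counts[b] = (int) R::rpois(mu);
    if (track_occupancy) occupancy[b] = occ_acc / steps_per_bin;
  }

  List out = List::create(_["counts"] = counts);
  if (track_occupancy) out["occupancy"] = occupancy;
  return out;
}
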