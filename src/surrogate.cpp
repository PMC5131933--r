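#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-variable Aliev-Panfilov excitable medium, used as a fast surrogate
// spiral-wave generator. Dimensionless kinetics:
//   du/dt' = D' lap(u) + k u (u - a)(1 - u) - u z
//   dz/dt' = (eps0 + mu1 z / (u + mu2)) * (-z - k u (u - a - 1))
// One time unit t' corresponds to time_scale_ms milliseconds; u in [0,1]
// maps to pseudo-voltage V = v_rest + v_amp * u.
// Spiral initiation: a plane wave is launched from the left edge at t'=0;
// at t' = t_cut the lower half of the excited variable is reset to 0,
// leaving a broken wavefront that curls into a rotor.
// [[Rcpp::export]]
List sim_aliev_panfilov_cpp(int H, int W, double duration_ms,
                            double sample_interval_ms,
                            double a, double k, double eps0, double mu1,
                            double mu2, double Dprime, double h_prime,
                            double dt_prime, double time_scale_ms,
                            double t_cut_ms, double v_rest, double v_amp,
                            double noise_sd, bool do_cut = true) {
  const int N = H * W;
  std::vector<double> u(N, 0.0), z(N, 0.0), lap(N);
  const double dco = Dprime / (h_prime * h_prime);
  if (dco * dt_prime * 4.0 > 1.0)
    stop("surrogate diffusion step unstable");

  // plane-wave seed on the left edge
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < 3 && c < W; ++c) u[r * W + c] = 1.0;
  if (noise_sd > 0.0) {
    RNGScope scope;
    for (int i = 0; i < N; ++i) {
      u[i] += R::rnorm(0.0, noise_sd);
      if (u[i] < 0.0) u[i] = 0.0;
      if (u[i] > 1.0) u[i] = 1.0;
    }
  }

  int n_frames = (int)std::floor(duration_ms / sample_interval_ms + 1e-9) + 1;
  NumericVector frames((R_xlen_t)H * W * n_frames);
  frames.attr("dim") = IntegerVector::create(H, W, n_frames);

  double t_ms = 0.0;
  int iframe = 0;
  bool cut_done = !do_cut;
  double next_rec = 0.0;
  double dt_ms = dt_prime * time_scale_ms;

  while (iframe < n_frames) {
    if (t_ms >= next_rec - 1e-9) {
      double* f = REAL(frames) + (size_t)iframe * H * W;
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r)
          f[r + (size_t)H * c] = v_rest + v_amp * u[r * W + c];
      ++iframe;
      next_rec += sample_interval_ms;
      if (iframe >= n_frames) break;
      Rcpp::checkUserInterrupt();
    }
    if (!cut_done && t_ms >= t_cut_ms) {
      for (int r = H / 2; r < H; ++r)
        for (int c = 0; c < W; ++c) u[r * W + c] = 0.0;
      cut_done = true;
    }
    for (int r = 0; r < H; ++r) {
      const int rw = r * W;
      const int ru = (r > 0 ? r - 1 : r) * W;
      const int rd = (r < H - 1 ? r + 1 : r) * W;
      for (int c = 0; c < W; ++c) {
        int cl = c > 0 ? c - 1 : c;
        int cr = c < W - 1 ? c + 1 : c;
        lap[rw + c] = dco * (u[ru + c] + u[rd + c] + u[rw + cl] + u[rw + cr] -
                             4.0 * u[rw + c]);
      }
    }
    for (int i = 0; i < N; ++i) {
      double ui = u[i], zi = z[i];
      double du = lap[i] + k * ui * (ui - a) * (1.0 - ui) - ui * zi;
      double dz = (eps0 + mu1 * zi / (ui + mu2)) *
                  (-zi - k * ui * (ui - a - 1.0));
      u[i] = ui + dt_prime * du;
      z[i] = zi + dt_prime * dz;
      if (u[i] < -0.2) u[i] = -0.2;
    }
    t_ms += dt_ms;
  }

  // activity level in the final frames, for wave-death reporting
  double umax_late = 0.0;
  for (int i = 0; i < N; ++i) umax_late = std::max(umax_late, u[i]);
  return List::create(_["frames"] = frames, _["n_frames"] = iframe,
                      _["u_final_max"] = umax_late);
}
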