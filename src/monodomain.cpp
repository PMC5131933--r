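#include <Rcpp.h>
#include "crn_model.h"
using namespace Rcpp;

// scenario multiplier vector layout (fixed order, see R/scenario.R):
// g_Na, g_to, g_CaL, g_Kur, g_K1, k_NaCa_max, sr_leak
static crn::CellConst make_consts(const NumericVector& mult) {
  crn::CellConst p = crn::default_consts();
  p.gNa        *= mult[0];
  p.gto        *= mult[1];
  p.gCaL       *= mult[2];
  p.gKur_scale *= mult[3];
  p.gK1        *= mult[4];
  p.inaca_max  *= mult[5];
  p.leak_scale *= mult[6];
  return p;
}

// Single-cell Courtemanche integration with the production stepper.
// stim_start/stim_dur/stim_amp: one entry per pulse; amplitude in pA/pF,
// positive = depolarizing (applied as a negative membrane current).
// Returns time vector, V trace and the final full state.
// [[Rcpp::export]]
List sim_cell_cpp(double duration_ms, double sample_interval_ms,
                  double dt_min, double dt_max, double dv_max,
                  NumericVector mult,
                  NumericVector stim_start, NumericVector stim_dur,
                  NumericVector stim_amp,
                  Nullable<NumericVector> init_state = R_NilValue) {
  crn::CellConst P = make_consts(mult);
  int per_sample = (int)std::ceil(sample_interval_ms / dt_max - 1e-9);
  double dt_full = sample_interval_ms / per_sample;
  int n_sub = (int)std::ceil(dt_full / dt_min - 1e-9);
  double dt_sub = dt_full / n_sub;
  crn::Table T;
  T.build(dt_sub, dt_full);

  double s[crn::NSTATE];
  if (init_state.isNotNull()) {
    NumericVector is(init_state);
    for (int i = 0; i < crn::NSTATE; ++i) s[i] = is[i];
  } else {
    crn::rest_state(s);
  }

  int n_samp = (int)std::floor(duration_ms / sample_interval_ms + 1e-9) + 1;
  NumericVector tout(n_samp), vout(n_samp);
  tout[0] = 0.0; vout[0] = s[0];
  crn::Eval e;
  double t = 0.0;
  int isamp = 1;
  int nstim = stim_start.size();
  while (isamp < n_samp) {
    for (int k = 0; k < per_sample; ++k) {
      double Ist = 0.0;
      for (int q = 0; q < nstim; ++q)
        if (t >= stim_start[q] && t < stim_start[q] + stim_dur[q])
          Ist -= stim_amp[q];
      crn::step_cell(s, Ist, 0.0, dv_max, n_sub, P, T, e);
      t += dt_full;
    }
    if (!std::isfinite(s[0]) || std::fabs(s[0]) > 300.0)
      stop("numerical blow-up in single-cell run at t = %.3f ms (V = %g)",
           t, s[0]);
    tout[isamp] = t;
    vout[isamp] = s[0];
    ++isamp;
  }
  NumericVector fin(crn::NSTATE);
  for (int i = 0; i < crn::NSTATE; ++i) fin[i] = s[i];
  return List::create(_["time_ms"] = tout, _["V"] = vout, _["state"] = fin);
}

// 2D monodomain solver, explicit 5-point Laplacian, no-flux boundaries
// (cell-face reflection), diffusion advanced at the macro step dt_full
// with per-cell sub-stepping of the reaction term (see crn::step_cell).
//
// stim_rect: nstim x 4 integer matrix (r0, r1, c0, c1), 0-based inclusive.
// stim_time: nstim x 3 numeric matrix (start_ms, duration_ms, amplitude).
// Output frames H x W x T (column-major, frame-contiguous), sampled every
// sample_interval_ms from record_from_ms onward.
// [[Rcpp::export]]
List sim_monodomain_cpp(int H, int W, double dx_mm, double D_cm2_ms,
                        double dt_min, double dt_max, double dv_max,
                        double duration_ms, double record_from_ms,
                        double sample_interval_ms,
                        NumericVector mult,
                        IntegerMatrix stim_rect, NumericMatrix stim_time,
                        bool passive = false,
                        Nullable<NumericMatrix> init_v = R_NilValue) {
  const int N = H * W;
  crn::CellConst P = make_consts(mult);
  int per_sample = (int)std::ceil(sample_interval_ms / dt_max - 1e-9);
  double dt_full = sample_interval_ms / per_sample;
  int n_sub = (int)std::ceil(dt_full / dt_min - 1e-9);
  double dt_sub = dt_full / n_sub;
  crn::Table T;
  T.build(dt_sub, dt_full);

  double D_mm = D_cm2_ms * 100.0;        // cm^2/ms -> mm^2/ms
  double dcoef = D_mm / (dx_mm * dx_mm);
  if (!passive && dcoef * dt_full * 4.0 > 2.0)
    stop("explicit diffusion unstable: D*dt/dx^2 too large");

  std::vector<double> state((size_t)N * crn::NSTATE);
  double s0[crn::NSTATE];
  crn::rest_state(s0);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < crn::NSTATE; ++k)
      state[(size_t)i * crn::NSTATE + k] = s0[k];

  std::vector<double> V(N), lap(N), prev_dvdt(N, 0.0);
  for (int i = 0; i < N; ++i) V[i] = s0[0];
  if (init_v.isNotNull()) {
    NumericMatrix iv(init_v);
    if (iv.nrow() != H || iv.ncol() != W)
      stop("init_v must be an H x W matrix");
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        V[r * W + c] = iv(r, c);
        state[(size_t)(r * W + c) * crn::NSTATE] = iv(r, c);
      }
  }

  int n_frames =
      (int)std::floor((duration_ms - record_from_ms) / sample_interval_ms + 1e-9) + 1;
  if (n_frames < 1) stop("record_from_ms must lie within the simulated time");
  NumericVector frames((R_xlen_t)H * W * n_frames);
  frames.attr("dim") = IntegerVector::create(H, W, n_frames);

  int nstim = stim_rect.nrow();
  crn::Eval e;
  double t = 0.0;
  int iframe = 0;
  double next_rec = record_from_ms;
  long n_macro = (long)std::llround(duration_ms / dt_full);

  // record t = record_from if it is 0
  if (record_from_ms <= 1e-9) {
    double* f = REAL(frames);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) f[r + (size_t)H * c] = V[r * W + c];
    iframe = 1;
    next_rec = record_from_ms + sample_interval_ms;
  }

  // V is stored row-major internally: idx = r*W + c
  for (long step = 0; step < n_macro && iframe < n_frames; ++step) {
    // Laplacian with no-flux boundaries
    for (int r = 0; r < H; ++r) {
      const int rw = r * W;
      const int ru = (r > 0 ? r - 1 : r) * W;
      const int rd = (r < H - 1 ? r + 1 : r) * W;
      for (int c = 0; c < W; ++c) {
        int cl = c > 0 ? c - 1 : c;
        int cr = c < W - 1 ? c + 1 : c;
        lap[rw + c] = dcoef * (V[ru + c] + V[rd + c] + V[rw + cl] +
                               V[rw + cr] - 4.0 * V[rw + c]);
      }
    }
    // active stimuli this step
    double t_mid = t + 0.5 * dt_full;
    if (passive) {
      for (int i = 0; i < N; ++i) V[i] += dt_full * lap[i];
    } else {
      // settled-cell fast path: fully repolarized cells with no incoming
      // diffusion or stimulus are at the model's resting steady state and
      // skip the ionic evaluation; every 100th step everything is
      // re-evaluated. The scheme is deterministic.
      bool force_all = (step % 100 == 0);
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          int i = r * W + c;
          double Ist = 0.0;
          for (int q = 0; q < nstim; ++q) {
            if (t_mid >= stim_time(q, 0) &&
                t_mid < stim_time(q, 0) + stim_time(q, 1) &&
                r >= stim_rect(q, 0) && r <= stim_rect(q, 1) &&
                c >= stim_rect(q, 2) && c <= stim_rect(q, 3))
              Ist -= stim_time(q, 2);
          }
          if (!force_all && Ist == 0.0 && V[i] < -72.0 &&
              std::fabs(lap[i]) < 0.02 && std::fabs(prev_dvdt[i]) < 0.02) {
            V[i] += dt_full * lap[i];
            state[(size_t)i * crn::NSTATE] = V[i];
            continue;
          }
          double* s = &state[(size_t)i * crn::NSTATE];
          crn::step_cell(s, Ist, lap[i], dv_max, n_sub, P, T, e);
          prev_dvdt[i] = e.dVdt;
          V[i] = s[0];
          if (!(std::fabs(V[i]) <= 300.0))  // catches NaN too
            stop("numerical blow-up at t = %.2f ms, cell (row %d, col %d): V = %g",
                 t, r + 1, c + 1, V[i]);
        }
      }
    }
    t += dt_full;
    if (t >= next_rec - 1e-9) {
      double* f = REAL(frames) + (size_t)iframe * H * W;
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) f[r + (size_t)H * c] = V[r * W + c];
      ++iframe;
      next_rec += sample_interval_ms;
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["frames"] = frames, _["n_frames"] = iframe,
                      _["t0_ms"] = record_from_ms,
                      _["dt_full"] = dt_full, _["dt_sub"] = dt_sub);
}

// Current breakdown at a given state (diagnostic / cross-checking).
// [[Rcpp::export]]
NumericVector crn_currents_cpp(NumericVector state, NumericVector mult) {
  crn::CellConst P = make_consts(mult);
  crn::Table T;
  T.build(0.01, 0.1);
  double s[crn::NSTATE];
  for (int i = 0; i < crn::NSTATE; ++i) s[i] = state[i];
  crn::Eval e;
  crn::eval_cell(s, 0.0, 0.0, P, T, e);
  return NumericVector::create(
      _["INa"] = e.INa, _["IK1"] = e.IK1, _["Ito"] = e.Ito,
      _["IKur"] = e.IKur, _["IKr"] = e.IKr, _["IKs"] = e.IKs,
      _["ICaL"] = e.ICaL, _["IpCa"] = e.IpCa, _["INaK"] = e.INaK,
      _["INaCa"] = e.INaCa, _["IbNa"] = e.IbNa, _["IbCa"] = e.IbCa,
      _["Iion"] = e.Iion, _["dVdt"] = e.dVdt);
}
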