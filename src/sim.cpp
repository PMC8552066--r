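// Monodomain tissue integrator: explicit RK4 on a triangulated surface
// graph with per-edge coupling coefficients D_{k,i}/d_{k,i}^2 and the
// three-variable phenomenological atrial ionic model.  Formulas mirror
// atrial3v_rhs() in R/ionic.R, which serves as the independent oracle.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct P3v {
  double tau_d, tau_0, tau_r, tau_si, tau_vp, tau_vm1, tau_vm2,
         tau_wp, tau_wm, u_c, u_v, u_csi, k_si, C_m;
};

static inline void rhs3v(const P3v& p, int n,
                         const double* u, const double* v, const double* w,
                         const int* row_ptr, const int* col_idx,
                         const double* coef, const double* stim,
                         double* du, double* dv, double* dw) {
  for (int k = 0; k < n; ++k) {
    const double uk = u[k];
    const bool on = uk >= p.u_c;
    double jfi = 0.0, jso, jsi;
    if (on) {
      jfi = -v[k] * (1.0 - uk) * (uk - p.u_c) / p.tau_d;
      jso = 1.0 / p.tau_r;
    } else {
      jso = uk / p.tau_0;
    }
    jsi = -w[k] * (1.0 + std::tanh(p.k_si * (uk - p.u_csi))) / (2.0 * p.tau_si);
    double diff = 0.0;
    for (int j = row_ptr[k]; j < row_ptr[k + 1]; ++j)
      diff += coef[j] * (u[col_idx[j]] - uk);
    du[k] = -(jfi + jso + jsi) / p.C_m + diff + stim[k];
    if (on) {
      dv[k] = -v[k] / p.tau_vp;
      dw[k] = -w[k] / p.tau_wp;
    } else {
      const double tau_vm = (uk >= p.u_v) ? p.tau_vm1 : p.tau_vm2;
      dv[k] = (1.0 - v[k]) / tau_vm;
      dw[k] = (1.0 - w[k]) / p.tau_wm;
    }
  }
}

// Stimuli: each row of stim_spec is (t_start_ms, duration_ms, amplitude),
// node sets given as a list of 0-based integer vectors.
static void fill_stim(double t, int n, const NumericMatrix& stim_spec,
                      const std::vector<std::vector<int>>& stim_nodes,
                      double* stim) {
  std::fill(stim, stim + n, 0.0);
  for (int s = 0; s < stim_spec.nrow(); ++s) {
    if (t >= stim_spec(s, 0) && t < stim_spec(s, 0) + stim_spec(s, 1)) {
      const double amp = stim_spec(s, 2);
      for (int idx : stim_nodes[s]) stim[idx] += amp;
    }
  }
}

// [[Rcpp::export(name = ".sim_monodomain")]]
List sim_monodomain(IntegerVector row_ptr, IntegerVector col_idx,
                    NumericVector coef, NumericVector params,
                    NumericMatrix init_state, double dt_ms, int n_steps,
                    int record_every, NumericMatrix stim_spec,
                    List stim_nodes_list) {
  const int n = init_state.nrow();
  P3v p;
  p.tau_d = params["tau_d"];  p.tau_0 = params["tau_0"];
  p.tau_r = params["tau_r"];  p.tau_si = params["tau_si"];
  p.tau_vp = params["tau_vp"]; p.tau_vm1 = params["tau_vm1"];
  p.tau_vm2 = params["tau_vm2"]; p.tau_wp = params["tau_wp"];
  p.tau_wm = params["tau_wm"]; p.u_c = params["u_c"];
  p.u_v = params["u_v"]; p.u_csi = params["u_csi"];
  p.k_si = params["k_si"]; p.C_m = params["C_m"];

  std::vector<std::vector<int>> stim_nodes(stim_nodes_list.size());
  for (int s = 0; s < stim_nodes_list.size(); ++s) {
    IntegerVector v = stim_nodes_list[s];
    stim_nodes[s].assign(v.begin(), v.end());
  }

  std::vector<double> u(n), v(n), w(n);
  for (int k = 0; k < n; ++k) {
    u[k] = init_state(k, 0); v[k] = init_state(k, 1); w[k] = init_state(k, 2);
  }
  const int n_frames = n_steps / record_every + 1;
  NumericMatrix vm(n, n_frames);
  for (int k = 0; k < n; ++k) vm(k, 0) = u[k];

  std::vector<double> k1u(n), k1v(n), k1w(n), k2u(n), k2v(n), k2w(n),
      k3u(n), k3v(n), k3w(n), k4u(n), k4v(n), k4w(n),
      tu(n), tv(n), tw(n), stim(n);
  const int* rp = row_ptr.begin();
  const int* ci = col_idx.begin();
  const double* cf = coef.begin();

  int frame = 1;
  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt_ms;
    fill_stim(t, n, stim_spec, stim_nodes, stim.data());
    rhs3v(p, n, u.data(), v.data(), w.data(), rp, ci, cf, stim.data(),
          k1u.data(), k1v.data(), k1w.data());
    for (int k = 0; k < n; ++k) {
      tu[k] = u[k] + 0.5 * dt_ms * k1u[k];
      tv[k] = v[k] + 0.5 * dt_ms * k1v[k];
      tw[k] = w[k] + 0.5 * dt_ms * k1w[k];
    }
    fill_stim(t + 0.5 * dt_ms, n, stim_spec, stim_nodes, stim.data());
    rhs3v(p, n, tu.data(), tv.data(), tw.data(), rp, ci, cf, stim.data(),
          k2u.data(), k2v.data(), k2w.data());
    for (int k = 0; k < n; ++k) {
      tu[k] = u[k] + 0.5 * dt_ms * k2u[k];
      tv[k] = v[k] + 0.5 * dt_ms * k2v[k];
      tw[k] = w[k] + 0.5 * dt_ms * k2w[k];
    }
    rhs3v(p, n, tu.data(), tv.data(), tw.data(), rp, ci, cf, stim.data(),
          k3u.data(), k3v.data(), k3w.data());
    for (int k = 0; k < n; ++k) {
      tu[k] = u[k] + dt_ms * k3u[k];
      tv[k] = v[k] + dt_ms * k3v[k];
      tw[k] = w[k] + dt_ms * k3w[k];
    }
    fill_stim(t + dt_ms, n, stim_spec, stim_nodes, stim.data());
    rhs3v(p, n, tu.data(), tv.data(), tw.data(), rp, ci, cf, stim.data(),
          k4u.data(), k4v.data(), k4w.data());
    for (int k = 0; k < n; ++k) {
      u[k] += dt_ms / 6.0 * (k1u[k] + 2 * k2u[k] + 2 * k3u[k] + k4u[k]);
      v[k] += dt_ms / 6.0 * (k1v[k] + 2 * k2v[k] + 2 * k3v[k] + k4v[k]);
      w[k] += dt_ms / 6.0 * (k1w[k] + 2 * k2w[k] + 2 * k3w[k] + k4w[k]);
    }
    if ((step + 1) % record_every == 0 && frame < n_frames) {
      bool bad = false;
      for (int k = 0; k < n; ++k) {
        vm(k, frame) = u[k];
        if (!std::isfinite(u[k])) bad = true;
      }
      if (bad)
        stop("non-finite transmembrane potential at recorded frame %d "
             "(t = %.1f ms); reduce dt or diffusion", frame, t);
      ++frame;
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix final_state(n, 3);
  for (int k = 0; k < n; ++k) {
    final_state(k, 0) = u[k]; final_state(k, 1) = v[k];
    final_state(k, 2) = w[k];
  }
  return List::create(_["vm"] = vm, _["final_state"] = final_state);
}
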