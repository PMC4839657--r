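#include <Rcpp.h>
using namespace Rcpp;

// Explicit flux-form finite-volume step of 1-D diffusion in a channel coupled
// to two well-mixed finite reservoirs (sink at x = 0, source at x = L).
// Reservoir concentrations reset to their initial values every refresh_s
// seconds (0 disables refreshment). The time step is chosen from the
// positivity/stability limit dt <= dx^2/(3D) (the factor 3 accounts for the
// half-cell boundary exchange), scaled by `safety`; steps are clipped to land
// exactly on refresh and output times, so instability can never arise
// silently.
// [[Rcpp::export]]
List fv_diffuse_cpp(int n_cells, double length_m, double area_m2, double D,
                    double res_vol_m3, double source0, double sink0,
                    double init_conc, double refresh_s,
                    NumericVector out_times_s, double safety) {
  const double dx = length_m / n_cells;
  const double cell_vol = area_m2 * dx;
  const double dt_max = safety * dx * dx / (3.0 * D);
  const double kI = D * area_m2 / dx;        // interior conductance
  const double kB = D * area_m2 / (dx / 2.0); // reservoir-boundary conductance

  std::vector<double> C(n_cells, init_conc);
  double c_sink = sink0, c_src = source0;

  const int n_out = out_times_s.size();
  NumericMatrix conc(n_out, n_cells);
  NumericVector sink_res(n_out), src_res(n_out), mass(n_out);

  double t = 0.0;
  int i_out = 0;
  int i_ref = 1;

  auto record = [&](int k) {
    double m = 0.0;
    for (int i = 0; i < n_cells; ++i) { conc(k, i) = C[i]; m += C[i] * cell_vol; }
    sink_res[k] = c_sink; src_res[k] = c_src;
    mass[k] = m + (c_sink + c_src) * res_vol_m3;
  };

  std::vector<double> flux(n_cells + 1);
  while (i_out < n_out) {
    double t_next = out_times_s[i_out];
    // snapshot (and then refresh) at coincident event times
    if (t >= t_next - 1e-9) {
      record(i_out++);
      continue;
    }
    double t_stop = t_next;
    if (refresh_s > 0) {
      double t_refresh = i_ref * refresh_s;
      if (t >= t_refresh - 1e-9) { c_sink = sink0; c_src = source0; ++i_ref; continue; }
      if (t_refresh < t_stop) t_stop = t_refresh;
    }
    double dt = dt_max;
    if (t + dt > t_stop) dt = t_stop - t;
    // fluxes, positive in +x direction
    flux[0] = kB * (c_sink - C[0]);
    for (int i = 1; i < n_cells; ++i) flux[i] = kI * (C[i - 1] - C[i]);
    flux[n_cells] = kB * (C[n_cells - 1] - c_src);
    for (int i = 0; i < n_cells; ++i)
      C[i] += dt * (flux[i] - flux[i + 1]) / cell_vol;
    c_sink -= dt * flux[0] / res_vol_m3;
    c_src += dt * flux[n_cells] / res_vol_m3;
    t += dt;
  }

  NumericVector x_um(n_cells);
  for (int i = 0; i < n_cells; ++i) x_um[i] = (i + 0.5) * dx * 1e6;
  return List::create(_["x_um"] = x_um, _["conc"] = conc,
                      _["sink_res"] = sink_res, _["source_res"] = src_res,
                      _["mass"] = mass);
}
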