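#include <Rcpp.h>
using namespace Rcpp;

// Depth-dependent biodiffusivity: K0 * (1 - tanh((z - z0)/z_scale)) / 2.
// ~K0 within the well-mixed layer, decaying with e-folding z_scale below it.
static inline double kv(double z, double K0, double z0, double zs) {
  return K0 * (1.0 - std::tanh((z - z0) / zs)) / 2.0;
}

// Lagrangian point-event mixing. All n particles are deposited at the
// sediment-water interface at t = 0. Per step the undisturbed horizon is
// buried by w_s*dt while the particle takes a Gaussian diffusive step with
// variance Kv(z)*dt (Kv evaluated at the pre-step depth), reflected at the
// interface. The state variable u = z - w_s*t is the downward deviation from
// the undisturbed horizon, so the K0 = 0 limit gives exactly zero
// displacement. Once Kv falls below `freeze_eps` the particle's remaining
// motion is pure burial and its displacement is final; it is dropped from the
// active set (its residual diffusive spread over the rest of the run is
// << dz). Returns the final upward displacement (-u) per particle, in cm.
//
// Uses R's RNG: seed with set.seed() on the R side.
// [[Rcpp::export(name = ".simulate_point_event_cpp")]]
NumericVector simulate_point_event_cpp(int n_particles,
                                       double ws, double K0,
                                       double z0, double z_scale,
                                       double dt_kyr, double T_kyr,
                                       double freeze_eps = 1e-7) {
  const int nsteps = (int)std::lround(T_kyr / dt_kyr);
  const double dh = ws * dt_kyr;
  NumericVector u(n_particles);           // downward deviation from horizon
  std::vector<int> active(n_particles);
  std::vector<double> Kcur(n_particles);  // Kv at each particle's depth
  const double K_surface = kv(0.0, K0, z0, z_scale);
  for (int i = 0; i < n_particles; ++i) { active[i] = i; Kcur[i] = K_surface; }
  RNGScope scope;
  double h = 0.0;                          // depth of undisturbed horizon
  for (int k = 0; k < nsteps && !active.empty(); ++k) {
    const double h_new = h + dh;
    size_t m = 0;
    for (size_t a = 0; a < active.size(); ++a) {
      const int i = active[a];
      const double K = Kcur[i];            // Kv at the pre-step depth
      double ui = u[i];
      if (K > 0.0) ui += norm_rand() * std::sqrt(K * dt_kyr);
      double z = h_new + ui;
      if (z < 0.0) { z = -z; ui = z - h_new; }   // reflect at interface
      u[i] = ui;
      const double K_new = kv(z, K0, z0, z_scale);
      if (K_new >= freeze_eps) { Kcur[i] = K_new; active[m++] = i; }
    }
    active.resize(m);
    h = h_new;
  }
  NumericVector disp(n_particles);
  for (int i = 0; i < n_particles; ++i) disp[i] = -u[i];
  return disp;
}
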