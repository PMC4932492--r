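#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled stochastic shuttling agents on the maze's longitudinal axis.
//
// Each agent carries a goal wall (C while seeking, A while returning) and a
// drift velocity goal_gain * speed toward it, plus a saturating attraction
// coupling_eff * speed * tanh(separation / sat_cm) toward its partner, plus
// an Ornstein-Uhlenbeck velocity noise term (stationary sd noise_sd,
// relaxation tau) so path length is sampling-rate invariant. On reaching a
// wall (within arrive_tol_cm) the agent pauses - drink_pause_s at C,
// rearm_pause_s at A - then heads the other way. Positions are clipped to
// [0, length_cm]. Uses R's RNG; seed with set.seed() on the R side.

// [[Rcpp::export]]
NumericMatrix simulate_agents_cpp(int n_steps, double dt, double length_cm,
                                  NumericVector speed, NumericVector noise_sd,
                                  double noise_tau_s,
                                  NumericVector goal_gain,
                                  NumericVector coupling_eff, double sat_cm,
                                  NumericVector drink_pause_s,
                                  double rearm_pause_s, double arrive_tol_cm,
                                  NumericVector x0) {
  const int m = speed.size();
  NumericMatrix X(n_steps, m);
  std::vector<double> x(m), u(m, 0.0), pause(m, 0.0);
  std::vector<int> goal(m, 1);  // +1 toward C wall, -1 toward A wall
  for (int j = 0; j < m; ++j) x[j] = x0[j];
  const double ou_decay = dt / noise_tau_s;
  const double ou_scale = std::sqrt(2.0 * dt / noise_tau_s);

  for (int k = 0; k < n_steps; ++k) {
    double xprev0 = x[0], xprev1 = (m == 2) ? x[1] : x[0];
    for (int j = 0; j < m; ++j) {
      if (pause[j] > 0.0) {
        pause[j] -= dt;
        u[j] = 0.0;  // stationary while drinking / re-arming
      } else {
        const double xo = (j == 0) ? xprev1 : xprev0;
        double v = speed[j] * goal_gain[j] * goal[j];
        if (m == 2)
          v += speed[j] * coupling_eff[j] * std::tanh((xo - x[j]) / sat_cm);
        u[j] += -ou_decay * u[j] + noise_sd[j] * ou_scale * norm_rand();
        double nx = x[j] + (v + u[j]) * dt;
        if (nx < 0.0) nx = 0.0;
        if (nx > length_cm) nx = length_cm;
        x[j] = nx;
        if (goal[j] == 1 && x[j] >= length_cm - arrive_tol_cm) {
          goal[j] = -1;
          pause[j] = drink_pause_s[j];
        } else if (goal[j] == -1 && x[j] <= arrive_tol_cm) {
          goal[j] = 1;
          pause[j] = rearm_pause_s;
        }
      }
      X(k, j) = x[j];
    }
  }
  return X;
}
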