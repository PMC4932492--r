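#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trial state machine over zone-coded samples (1 = A, 2 = B, 3 = C).
//
// Phases: 0 PREARM (waiting for the first simultaneous A occupancy),
// 1 ARMED (both in A, trial armed), 2 ACTIVE (coordination rules enforced),
// 3 BROKEN (between an outcome and re-arming; rules suspended), 4 DONE.
//
// Per-sample tie-break order: session caps first, then two-zones-apart
// break, then mismatch timeout, then reward.
//
// Event kinds: 1 trial_armed, 2 reward, 3 break, 4 session_end.
// Detail codes: breaks 1 two_zones_apart, 2 mismatch_timeout,
// 3 session_end(interrupted trial); session_end 1 time_cap, 2 trial_cap,
// 3 track_end.

// [[Rcpp::export]]
List run_session_cpp(IntegerVector z1, IntegerVector z2, double t0, double dt,
                     double max_mismatch_s, int max_rewarded_trials,
                     double max_session_s, bool solitary) {
  const int n = z1.size();
  const double eps = 1e-9;

  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_z1, ev_z2, ev_detail;
  std::vector<double> tr_armed, tr_out;
  std::vector<int> tr_outcome, tr_cause;  // outcome 1 reward 2 break

  int phase = 0;
  int mism_n = 0;               // consecutive different-zone samples
  bool b1 = false, b2 = false;  // visited B since arming
  int rewards = 0;
  double t_arm = NA_REAL;
  double scored = (n > 0) ? t0 : 0.0;
  int end_cause = 3;  // track_end unless a cap fires

  for (int k = 0; k < n; ++k) {
    const double t = t0 + k * dt;
    const int a = z1[k];
    const int b = solitary ? a : z2[k];
    if (a < 1 || a > 3 || b < 1 || b > 3)
      stop("invalid zone code at t = %f", t);

    // session caps, checked before anything else at each sample
    if (t >= max_session_s - eps || rewards >= max_rewarded_trials) {
      end_cause = (rewards >= max_rewarded_trials &&
                   t < max_session_s - eps) ? 2 : 1;
      if (phase == 1 || phase == 2) {  // interrupted open trial
        tr_armed.push_back(t_arm); tr_out.push_back(t);
        tr_outcome.push_back(2); tr_cause.push_back(3);
      }
      ev_t.push_back(t); ev_kind.push_back(4);
      ev_z1.push_back(a); ev_z2.push_back(b); ev_detail.push_back(end_cause);
      scored = t;
      phase = 4;
      break;
    }
    scored = t;

    if (phase == 0 || phase == 3) {  // waiting to (re-)arm
      if (a == 1 && b == 1) {
        phase = 1; t_arm = t; b1 = b2 = false; mism_n = 0;
        ev_t.push_back(t); ev_kind.push_back(1);
        ev_z1.push_back(a); ev_z2.push_back(b); ev_detail.push_back(0);
      }
      continue;
    }

    if (phase == 1 && (a != 1 || b != 1)) phase = 2;
    if (phase != 2) continue;

    if (!solitary) {
      const int dist = (a > b) ? (a - b) : (b - a);
      if (dist == 2) {
        ev_t.push_back(t); ev_kind.push_back(3);
        ev_z1.push_back(a); ev_z2.push_back(b); ev_detail.push_back(1);
        tr_armed.push_back(t_arm); tr_out.push_back(t);
        tr_outcome.push_back(2); tr_cause.push_back(1);
        phase = 3;
        continue;
      }
      if (a != b) {
        ++mism_n;
        if (mism_n * dt > max_mismatch_s + eps) {
          ev_t.push_back(t); ev_kind.push_back(3);
          ev_z1.push_back(a); ev_z2.push_back(b); ev_detail.push_back(2);
          tr_armed.push_back(t_arm); tr_out.push_back(t);
          tr_outcome.push_back(2); tr_cause.push_back(2);
          phase = 3;
          continue;
        }
      } else {
        mism_n = 0;
      }
    }

    if (a == 2) b1 = true;
    if (b == 2) b2 = true;

    if (a == 3 && b == 3 && b1 && (solitary || b2)) {
      ev_t.push_back(t); ev_kind.push_back(2);
      ev_z1.push_back(a); ev_z2.push_back(b); ev_detail.push_back(0);
      tr_armed.push_back(t_arm); tr_out.push_back(t);
      tr_outcome.push_back(1); tr_cause.push_back(0);
      ++rewards;
      phase = 3;  // coordination suspended until both return to A
    }
  }

  if (phase != 4 && n > 0) {  // track ended before any cap
    const double t_last = t0 + (n - 1) * dt;
    if (phase == 1 || phase == 2) {
      tr_armed.push_back(t_arm); tr_out.push_back(t_last);
      tr_outcome.push_back(2); tr_cause.push_back(3);
    }
    ev_t.push_back(t_last); ev_kind.push_back(4);
    ev_z1.push_back(z1[n - 1]);
    ev_z2.push_back(solitary ? z1[n - 1] : z2[n - 1]);
    ev_detail.push_back(3);
    scored = t_last;
  }

  return List::create(
      _["ev_t"] = wrap(ev_t), _["ev_kind"] = wrap(ev_kind),
      _["ev_z1"] = wrap(ev_z1), _["ev_z2"] = wrap(ev_z2),
      _["ev_detail"] = wrap(ev_detail),
      _["tr_armed"] = wrap(tr_armed), _["tr_out"] = wrap(tr_out),
      _["tr_outcome"] = wrap(tr_outcome), _["tr_cause"] = wrap(tr_cause),
      _["rewards"] = rewards, _["scored_s"] = scored,
      _["end_cause"] = end_cause);
}
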