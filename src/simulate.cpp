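#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward-Euler simulation of the bounded, resetting Ornstein-Uhlenbeck
// decision process over a sequence of stimulus segments.
//
// State update (unfrozen steps):
//   x' = x + (mu * sqrt(I) - lam * x) * dt + sigma * sqrt(dt) * N(0,1)
// A decision event is registered when |x| >= B at the end of a step; the
// state is then set to r * sign(x) * B and frozen for ceil(delta/dt) steps
// starting with the following step. The inter-event clock keeps running
// during the delay.
//
// Segments sharing a session id form one continuous process: state and the
// inter-event clock carry over across segment boundaries within a session
// and are re-initialised (x = x0, clock = session start) at a new session.
//
// Uses R's RNG (one standard-normal draw per unfrozen step), so results are
// reproducible under set.seed().
// [[Rcpp::export]]
DataFrame sim_ou_events(double sigma, double mu, double lam, double r,
                        double delta, double dt, double bound, double x0,
                        NumericVector seg_coherence, NumericVector seg_duration,
                        IntegerVector seg_phase, IntegerVector seg_trial,
                        IntegerVector seg_session) {
  const int nseg = seg_coherence.size();
  if (seg_duration.size() != nseg || seg_phase.size() != nseg ||
      seg_trial.size() != nseg || seg_session.size() != nseg)
    stop("segment vectors must have equal length");
  if (dt <= 0) stop("dt must be positive");
  if (bound <= 0) stop("bound must be positive");

  RNGScope scope;
  const double sdt = sigma * std::sqrt(dt);
  const int delay_steps = (delta > 0) ? (int)std::ceil(delta / dt - 1e-9) : 0;
  const double guard = 10.0 * bound;

  std::vector<double> ev_time, ev_isi, ev_coh;
  std::vector<int> ev_label, ev_trial, ev_phase, ev_session;

  double x = x0;
  double t = 0.0;            // time within current session
  double last_event = NA_REAL;
  int frozen = 0;
  int cur_session = nseg > 0 ? seg_session[0] : 0;

  for (int s = 0; s < nseg; ++s) {
    if (seg_session[s] != cur_session || s == 0) {
      // new session: reset state and clocks
      x = x0;
      t = 0.0;
      last_event = NA_REAL;
      frozen = 0;
      cur_session = seg_session[s];
    }
    const double drive = mu * std::sqrt(seg_coherence[s]);
    const long nsteps = (long)std::llround(seg_duration[s] / dt);
    for (long i = 0; i < nsteps; ++i) {
      t += dt;
      if (frozen > 0) {
        --frozen;
        continue;
      }
      x += (drive - lam * x) * dt + sdt * norm_rand();
      if (!std::isfinite(x) || std::fabs(x) > guard) {
        stop("decision variable diverged (|x| > 10*B) at t=%f for sigma=%f, mu=%f, lam=%f, r=%f, delta=%f",
             t, sigma, mu, lam, r, delta);
      }
      if (std::fabs(x) >= bound) {
        const int sgn = (x > 0) ? 1 : -1;
        const double isi = ISNAN(last_event) ? t : t - last_event;
        ev_time.push_back(t);
        ev_isi.push_back(isi);
        ev_label.push_back(sgn);
        ev_coh.push_back(seg_coherence[s]);
        ev_trial.push_back(seg_trial[s]);
        ev_phase.push_back(seg_phase[s]);
        ev_session.push_back(seg_session[s]);
        last_event = t;
        x = r * sgn * bound;
        frozen = delay_steps;
      }
    }
  }

  return DataFrame::create(
      _["time_s"] = ev_time, _["isi_s"] = ev_isi, _["label_sign"] = ev_label,
      _["coherence"] = ev_coh, _["trial_id"] = ev_trial,
      _["phase_code"] = ev_phase, _["session"] = ev_session);
}

// Bootstrap distribution of |median(A*) - median(B*)| under pooled
// resampling at the original group sizes. Returns n_boot statistics.
// [[Rcpp::export]]
NumericVector boot_median_diff(NumericVector pooled, int n_a, int n_b,
                               int n_boot) {
  RNGScope scope;
  const int n = pooled.size();
  if (n_a <= 0 || n_b <= 0 || n_a + n_b != n)
    stop("group sizes must be positive and sum to the pooled length");
  NumericVector out(n_boot);
  std::vector<double> a(n_a), b(n_b);
  for (int it = 0; it < n_boot; ++it) {
    for (int i = 0; i < n_a; ++i) a[i] = pooled[(int)(unif_rand() * n)];
    for (int i = 0; i < n_b; ++i) b[i] = pooled[(int)(unif_rand() * n)];
    std::sort(a.begin(), a.end());
    std::sort(b.begin(), b.end());
    const double ma = (n_a % 2) ? a[n_a / 2] : 0.5 * (a[n_a / 2 - 1] + a[n_a / 2]);
    const double mb = (n_b % 2) ? b[n_b / 2] : 0.5 * (b[n_b / 2 - 1] + b[n_b / 2]);
    out[it] = std::fabs(ma - mb);
  }
  return out;
}

// Bootstrap medians of a single sample (for percentile CIs).
// [[Rcpp::export]]
NumericVector boot_medians(NumericVector x, int n_boot) {
  RNGScope scope;
  const int n = x.size();
  if (n <= 0) stop("x must be nonempty");
  NumericVector out(n_boot);
  std::vector<double> s(n);
  for (int it = 0; it < n_boot; ++it) {
    for (int i = 0; i < n; ++i) s[i] = x[(int)(unif_rand() * n)];
    std::sort(s.begin(), s.end());
    out[it] = (n % 2) ? s[n / 2] : 0.5 * (s[n / 2 - 1] + s[n / 2]);
  }
  return out;
}
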